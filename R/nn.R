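# Minimal CNN engine: a static computation graph over im2col/col2im kernels
# (BLAS matmul does the heavy lifting), with hand-derived backward rules and
# Adam. Single-sample (one patch per gradient step); tensors are R arrays in
# (h, w, c) order for 2D nets and (d, h, w, c) for 3D nets.
#
# Graph representation: node list; node i = list(op, args = input node ids,
# p = parameter slot, ...). Node 1 is the network input. Parameters live in a
# flat list of list(W, b). The same interpreter runs 2D and 3D graphs (ops
# carry a `nd` field).

new_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list(list(op = "input"))
  g$pinit <- list()   # per-parameter: list(fan_in, shape W, shape b)
  g
}

g_add_node <- function(g, node) {
  g$nodes[[length(g$nodes) + 1L]] <- node
  length(g$nodes)
}

# conv with stride 1, zero-padded "same"; k odd
g_conv <- function(g, input, cin, cout, k, nd = 2) {
  kk <- k^nd
  g$pinit[[length(g$pinit) + 1L]] <-
    list(wrows = kk * cin, cout = cout, fan_in = kk * cin)
  g_add_node(g, list(op = "conv", args = input, p = length(g$pinit),
                     k = k, cin = cin, cout = cout, nd = nd))
}

g_op <- function(g, op, ..., extra = NULL) {
  g_add_node(g, c(list(op = op, args = c(...)), extra))
}

init_params <- function(g, seed) {
  with_seed(seed, lapply(g$pinit, function(p) {
    list(W = matrix(rnorm(p$wrows * p$cout, sd = sqrt(2 / p$fan_in)),
                    p$wrows, p$cout),
         b = numeric(p$cout))
  }))
}

# --- forward/backward primitives ---------------------------------------

conv_apply <- function(x, W, b, k, nd) {
  d <- dim(x)
  cols <- if (nd == 2) {
    .im2col2d_cpp(as.vector(x), d[1], d[2], d[3], k)
  } else {
    .im2col3d_cpp(as.vector(x), d[1], d[2], d[3], d[4], k)
  }
  out <- cols %*% W
  out <- sweep(out, 2, b, "+")
  dim(out) <- c(d[-length(d)], ncol(W))
  list(out = out, cols = cols, xdim = d)
}

conv_grad <- function(dy, cache, W, k, nd) {
  cout <- dim(dy)[length(dim(dy))]
  dym <- matrix(as.vector(dy), ncol = cout)
  dW <- crossprod(cache$cols, dym)
  db <- colSums(dym)
  dcols <- tcrossprod(dym, W)
  d <- cache$xdim
  dx <- if (nd == 2) {
    .col2im2d_cpp(dcols, d[1], d[2], d[3], k)
  } else {
    .col2im3d_cpp(dcols, d[1], d[2], d[3], d[4], k)
  }
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

downsum2 <- function(dy) {
  d <- dim(dy)
  h <- d[1] / 2; w <- d[2] / 2
  dim(dy) <- c(2, h, 2, w, d[3])
  out <- colSums(aperm(dy, c(1, 3, 2, 4, 5)), dims = 2)
  dim(out) <- c(h, w, d[3])
  out
}

graph_forward <- function(g, params, x, keep_cache = TRUE) {
  n <- length(g$nodes)
  vals <- vector("list", n)
  caches <- vector("list", n)
  vals[[1]] <- x
  for (i in seq(2, n)) {
    nd <- g$nodes[[i]]
    a <- nd$args
    vals[[i]] <- switch(nd$op,
      conv = {
        p <- params[[nd$p]]
        r <- conv_apply(vals[[a]], p$W, p$b, nd$k, nd$nd)
        if (keep_cache) caches[[i]] <- list(cols = r$cols, xdim = r$xdim)
        r$out
      },
      relu = pmax(vals[[a]], 0),
      sigmoid = 1 / (1 + exp(-vals[[a]])),
      add = vals[[a[1]]] + vals[[a[2]]],
      mul = vals[[a[1]]] * vals[[a[2]]],
      # gated mix for highway blocks: t*h + (1-t)*x
      gate = vals[[a[1]]] * vals[[a[2]]] +
             (1 - vals[[a[1]]]) * vals[[a[3]]],
      concat = do.call(abind_last, vals[a]),
      pool = {
        d <- dim(vals[[a]])
        r <- .maxpool2_cpp(as.vector(vals[[a]]), d[1], d[2], d[3])
        out <- r$out
        dim(out) <- c(d[1] / 2, d[2] / 2, d[3])
        if (keep_cache) caches[[i]] <- list(arg = r$arg, xdim = d)
        out
      },
      upsample = upsample2(vals[[a]]),
      stop("unknown op ", nd$op)
    )
  }
  list(out = vals[[n]], vals = vals, caches = caches)
}

# concatenate along the last (channel) axis
abind_last <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  nd <- length(d)
  chans <- vapply(xs, function(x) dim(x)[nd], 0)
  out <- array(0, c(d[-nd], sum(chans)))
  at <- 0L
  for (x in xs) {
    cx <- dim(x)[nd]
    if (nd == 3) out[, , at + seq_len(cx)] <- x else out[, , , at + seq_len(cx)] <- x
    at <- at + cx
  }
  out
}

graph_backward <- function(g, params, fwd, dout) {
  n <- length(g$nodes)
  dvals <- vector("list", n)
  dvals[[n]] <- dout
  grads <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  acc <- function(slot, g_) {
    if (is.null(dvals[[slot]])) dvals[[slot]] <<- g_
    else dvals[[slot]] <<- dvals[[slot]] + g_
  }
  for (i in seq(n, 2)) {
    dy <- dvals[[i]]
    if (is.null(dy)) next
    nd <- g$nodes[[i]]
    a <- nd$args
    switch(nd$op,
      conv = {
        r <- conv_grad(dy, fwd$caches[[i]], params[[nd$p]]$W, nd$k, nd$nd)
        grads[[nd$p]]$W <- grads[[nd$p]]$W + r$dW
        grads[[nd$p]]$b <- grads[[nd$p]]$b + r$db
        acc(a, r$dx)
      },
      relu = acc(a, dy * (fwd$vals[[a]] > 0)),
      sigmoid = {
        s <- fwd$vals[[i]]
        acc(a, dy * s * (1 - s))
      },
      add = { acc(a[1], dy); acc(a[2], dy) },
      mul = {
        acc(a[1], dy * fwd$vals[[a[2]]])
        acc(a[2], dy * fwd$vals[[a[1]]])
      },
      gate = {
        t_ <- fwd$vals[[a[1]]]
        acc(a[1], dy * (fwd$vals[[a[2]]] - fwd$vals[[a[3]]]))
        acc(a[2], dy * t_)
        acc(a[3], dy * (1 - t_))
      },
      concat = {
        ndim <- length(dim(dy))
        at <- 0L
        for (src in a) {
          cx <- dim(fwd$vals[[src]])[ndim]
          piece <- if (ndim == 3) dy[, , at + seq_len(cx), drop = FALSE]
                   else dy[, , , at + seq_len(cx), drop = FALSE]
          acc(src, piece)
          at <- at + cx
        }
      },
      pool = {
        cache <- fwd$caches[[i]]
        dx <- numeric(prod(cache$xdim))
        dyv <- as.vector(dy)
        # argmax indices are unique per pooling window
        dx[cache$arg] <- dyv
        dim(dx) <- cache$xdim
        acc(a, dx)
      },
      upsample = acc(a, downsum2(dy)),
      stop("unknown op ", nd$op)
    )
  }
  list(grads = grads, dx = dvals[[1]])
}

# --- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)),
       v = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    for (f in c("W", "b")) {
      state$m[[i]][[f]] <- beta1 * state$m[[i]][[f]] + (1 - beta1) * grads[[i]][[f]]
      state$v[[i]][[f]] <- beta2 * state$v[[i]][[f]] + (1 - beta2) * grads[[i]][[f]]^2
      params[[i]][[f]] <- params[[i]][[f]] -
        lr * (state$m[[i]][[f]] / bc1) / (sqrt(state$v[[i]][[f]] / bc2) + eps)
    }
  }
  list(params = params, state = state)
}
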