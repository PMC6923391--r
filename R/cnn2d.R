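# 2D CNN segmentation engine: four topologies (unet / resnet / highway /
# dense), five loss functions (square / softmax / entropy / dice / logistic),
# dihedral augmentation, patch-based training and tiled inference.
#
# "Epochs" count gradient steps on randomly sampled patches: with 1-10
# training slices a pass-over-the-data notion is meaningless, and reported
# settings like "2000 training epochs" only make sense as steps.

VALID_TOPOLOGIES <- c("unet", "resnet", "highway", "dense")
VALID_LOSSES <- c("square", "softmax", "entropy", "dice", "logistic")
VALID_AUGMENTATIONS <- c("fliplr", "flipud", "rot90", "transpose")

#' Configuration for the 2D CNN engine
#'
#' @param topology one of `"unet"`, `"resnet"`, `"highway"`, `"dense"`.
#' @param n_layers number of convolution layers (ignored by `unet`, whose
#'   4-level contracting/expansive architecture is fixed); minimum 3 for the
#'   full-resolution topologies.
#' @param loss one of `"square"` (MSE on sigmoid outputs), `"softmax"`
#'   (per-pixel cross-entropy across channels), `"entropy"` (per-channel
#'   sigmoid cross-entropy, multi-label), `"dice"` (1 - soft Dice),
#'   `"logistic"` (single-channel sigmoid cross-entropy).
#' @param epochs gradient steps to run.
#' @param patch_size square training-patch side in pixels; must be divisible
#'   by 16 for `unet` (its downsampling factor).
#' @param base_filters channel width of the first convolution.
#' @param augmentations subset of `"fliplr"`, `"flipud"`, `"rot90"`,
#'   `"transpose"`; empty means no augmentation.
#' @param seed integer seed controlling initialization and patch sampling.
#' @param learning_rate Adam step size.
#' @return a `cnn2d_config` list.
#' @export
cnn2d_config <- function(topology = "resnet", n_layers = 9, loss = "square",
                         epochs = 2000, patch_size = 64, base_filters = 32,
                         augmentations = character(), seed = 0,
                         learning_rate = 1e-3) {
  if (!topology %in% VALID_TOPOLOGIES) {
    stop("unknown topology '", topology, "'; valid: ",
         paste(VALID_TOPOLOGIES, collapse = ", "))
  }
  if (!loss %in% VALID_LOSSES) {
    stop("unknown loss '", loss, "'; valid: ",
         paste(VALID_LOSSES, collapse = ", "))
  }
  if (n_layers < 1) stop("n_layers must be positive")
  if (topology != "unet" && n_layers < 3) {
    stop("config error: ", topology, " needs n_layers >= 3 (stem + head + blocks)")
  }
  if (topology == "unet" && patch_size %% 16 != 0) {
    stop("config error: unet patch_size must be divisible by 16")
  }
  if (length(augmentations) && !all(augmentations %in% VALID_AUGMENTATIONS)) {
    stop("augmentations must be a subset of ",
         paste(VALID_AUGMENTATIONS, collapse = ", "))
  }
  structure(list(topology = topology, n_layers = n_layers, loss = loss,
                 epochs = as.integer(epochs), patch_size = as.integer(patch_size),
                 base_filters = as.integer(base_filters),
                 augmentations = augmentations, seed = as.integer(seed),
                 learning_rate = learning_rate),
            class = "cnn2d_config")
}

# --- topology graph builders --------------------------------------------

build_resnet_graph <- function(g, n_layers, cin, cout, F) {
  x <- g_conv(g, 1L, cin, F, 3)          # stem
  x <- g_op(g, "relu", x)
  n_blocks <- (n_layers - 2) %/% 2
  for (b in seq_len(n_blocks)) {
    h <- g_conv(g, x, F, F, 3)
    h <- g_op(g, "relu", h)
    h <- g_conv(g, h, F, F, 3)
    x <- g_op(g, "add", x, h)
    x <- g_op(g, "relu", x)
  }
  if ((n_layers - 2) %% 2 == 1) {
    x <- g_conv(g, x, F, F, 3)
    x <- g_op(g, "relu", x)
  }
  g_conv(g, x, F, cout, 1)               # head
}

build_highway_graph <- function(g, n_layers, cin, cout, F) {
  x <- g_conv(g, 1L, cin, F, 3)
  x <- g_op(g, "relu", x)
  n_blocks <- (n_layers - 2) %/% 2
  for (b in seq_len(n_blocks)) {
    t_ <- g_conv(g, x, F, F, 3)
    t_ <- g_op(g, "sigmoid", t_)
    h <- g_conv(g, x, F, F, 3)
    h <- g_op(g, "relu", h)
    x <- g_op(g, "gate", t_, h, x)       # t*h + (1-t)*x
  }
  if ((n_layers - 2) %% 2 == 1) {
    x <- g_conv(g, x, F, F, 3)
    x <- g_op(g, "relu", x)
  }
  g_conv(g, x, F, cout, 1)
}

build_dense_graph <- function(g, n_layers, cin, cout, F, growth = 16) {
  x <- g_conv(g, 1L, cin, F, 3)
  x <- g_op(g, "relu", x)
  feats <- c(x)
  widths <- c(F)
  for (l in seq_len(n_layers - 2)) {
    inp <- if (length(feats) > 1) do.call(g_op, c(list(g, "concat"), as.list(feats)))
           else feats[1]
    h <- g_conv(g, inp, sum(widths), growth, 3)
    h <- g_op(g, "relu", h)
    feats <- c(feats, h)
    widths <- c(widths, growth)
  }
  inp <- if (length(feats) > 1) do.call(g_op, c(list(g, "concat"), as.list(feats)))
         else feats[1]
  g_conv(g, inp, sum(widths), cout, 1)
}

build_unet_graph <- function(g, cin, cout, F, levels = 4) {
  enc_block <- function(x, ci, co) {
    x <- g_conv(g, x, ci, co, 3); x <- g_op(g, "relu", x)
    x <- g_conv(g, x, co, co, 3); g_op(g, "relu", x)
  }
  skips <- integer(0)
  widths <- integer(0)
  x <- 1L
  ci <- cin
  w <- F
  for (l in seq_len(levels)) {
    x <- enc_block(x, ci, w)
    skips <- c(skips, x)
    widths <- c(widths, w)
    x <- g_op(g, "pool", x)
    ci <- w
    w <- w * 2L
  }
  x <- enc_block(x, ci, w)               # bottleneck
  for (l in rev(seq_len(levels))) {
    x <- g_op(g, "upsample", x)
    x <- g_op(g, "concat", x, skips[l])
    x <- enc_block(x, w + widths[l], widths[l])
    w <- widths[l]
  }
  g_conv(g, x, w, cout, 1)
}

#' Build an untrained 2D segmentation model
#'
#' Returns a model mapping an `(h, w, in_channels)` patch to
#' `(h, w, out_channels)` raw scores. `unet` uses 4 contracting/expansive
#' levels with skip connections; `resnet` / `highway` / `dense` are
#' `n_layers`-deep residual / gated / densely-connected stacks at full
#' resolution.
#'
#' @param config a [cnn2d_config()].
#' @param in_channels 1 (grayscale) or 3 (RGB).
#' @param out_channels number of output score channels.
#' @return a `cnn2d_model` with untrained weights (He-initialized from
#'   `config$seed`).
#' @export
build_model <- function(config, in_channels = 1, out_channels = 1) {
  if (!in_channels %in% c(1, 3)) stop("in_channels must be 1 or 3")
  if (config$loss == "softmax" && out_channels < 2) {
    stop("config error: softmax loss needs out_channels >= 2")
  }
  if (config$loss == "logistic" && out_channels != 1) {
    stop("config error: logistic loss is single-channel")
  }
  g <- new_graph()
  F <- config$base_filters
  switch(config$topology,
    resnet = build_resnet_graph(g, config$n_layers, in_channels, out_channels, F),
    highway = build_highway_graph(g, config$n_layers, in_channels, out_channels, F),
    dense = build_dense_graph(g, config$n_layers, in_channels, out_channels, F),
    unet = build_unet_graph(g, in_channels, out_channels, F)
  )
  params <- init_params(g, config$seed)
  structure(list(graph = g, params = params, config = config,
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels)),
            class = "cnn2d_model")
}

#' @export
print.cnn2d_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), 0))
  cat(sprintf("<cnn2d_model> %s, %d layers, loss %s, %d params, %d->%d channels\n",
              x$config$topology, x$config$n_layers, x$config$loss, np,
              x$in_channels, x$out_channels))
  invisible(x)
}

model_forward <- function(model, x, keep_cache = FALSE) {
  graph_forward(model$graph, model$params, x, keep_cache)
}

# --- losses --------------------------------------------------------------

#' Loss functions for score maps
#'
#' Returns the named loss as a function of raw scores and targets (same
#' shapes), producing `list(value, grad)` with the gradient taken with respect
#' to the scores. `square` is mean squared error between `sigmoid(scores)` and
#' targets; `softmax` per-pixel softmax cross-entropy across channels;
#' `entropy` per-channel sigmoid cross-entropy (multi-label); `dice` is
#' `1 - soft Dice` (smoothing 1); `logistic` single-channel sigmoid
#' cross-entropy.
#'
#' @param name one of `"square"`, `"softmax"`, `"entropy"`, `"dice"`,
#'   `"logistic"`.
#' @param out_channels number of score channels the loss will see.
#' @return a function `(scores, targets) -> list(value, grad)`; the attached
#'   attribute `link` names the probability link (`"sigmoid"`/`"softmax"`).
#' @export
make_loss <- function(name, out_channels = 1) {
  if (!name %in% VALID_LOSSES) {
    stop("unknown loss '", name, "'; valid: ",
         paste(VALID_LOSSES, collapse = ", "))
  }
  if (name == "softmax" && out_channels < 2) {
    stop("config error: softmax loss needs out_channels >= 2")
  }
  if (name == "logistic" && out_channels != 1) {
    stop("config error: logistic loss is single-channel")
  }
  eps <- 1e-12
  fn <- switch(name,
    square = function(scores, targets) {
      p <- 1 / (1 + exp(-scores))
      n <- length(p)
      list(value = mean((p - targets)^2),
           grad = 2 * (p - targets) * p * (1 - p) / n)
    },
    logistic = ,
    entropy = function(scores, targets) {
      p <- 1 / (1 + exp(-scores))
      n <- length(p)
      list(value = -mean(targets * log(pmax(p, eps)) +
                         (1 - targets) * log(pmax(1 - p, eps))),
           grad = (p - targets) / n)
    },
    softmax = function(scores, targets) {
      d <- dim(scores)
      C <- d[length(d)]
      m <- matrix(scores, ncol = C)
      m <- m - apply(m, 1, max)
      e <- exp(m)
      p <- e / rowSums(e)
      tm <- matrix(targets, ncol = C)
      npix <- nrow(m)
      g <- (p - tm) / npix
      dim(g) <- d
      list(value = -sum(tm * log(pmax(p, eps))) / npix, grad = g)
    },
    dice = function(scores, targets) {
      p <- 1 / (1 + exp(-scores))
      sm <- 1
      num <- 2 * sum(p * targets) + sm
      den <- sum(p) + sum(targets) + sm
      dLdp <- -(2 * targets * den - num) / den^2
      list(value = 1 - num / den, grad = dLdp * p * (1 - p))
    }
  )
  attr(fn, "link") <- if (name == "softmax") "softmax" else "sigmoid"
  attr(fn, "name") <- name
  fn
}

# --- augmentation --------------------------------------------------------

apply_dihedral <- function(x, op) {
  flip2 <- function(m, dimn) {
    idx <- rev(seq_len(dim(m)[dimn]))
    if (dimn == 1) {
      if (length(dim(m)) == 3) m[idx, , , drop = FALSE] else m[idx, , drop = FALSE]
    } else {
      if (length(dim(m)) == 3) m[, idx, , drop = FALSE] else m[, idx, drop = FALSE]
    }
  }
  tr <- function(m) {
    if (length(dim(m)) == 3) aperm(m, c(2, 1, 3)) else t(m)
  }
  switch(op,
    none = x,
    fliplr = flip2(x, 2),
    flipud = flip2(x, 1),
    rot90 = flip2(tr(x), 1),
    transpose = tr(x),
    stop("unknown augmentation '", op, "'"))
}

#' Randomly augment an image/label patch pair
#'
#' Draws one transform uniformly from `augmentations` (identity when the set
#' is empty) and applies it to both patches, keeping them aligned.
#'
#' @param image,label matrices or `(h, w, c)` arrays of equal spatial shape.
#' @param augmentations subset of `"fliplr"`, `"flipud"`, `"rot90"`,
#'   `"transpose"`.
#' @param choice force a specific transform (bypasses random selection).
#' @return `list(image, label, op)`.
#' @export
augment <- function(image, label, augmentations = character(), choice = NULL) {
  if (!all(dim(image)[1:2] == dim(label)[1:2])) {
    stop("image and label patches must share spatial shape")
  }
  op <- if (!is.null(choice)) choice
        else if (length(augmentations) == 0) "none"
        else sample(augmentations, 1)
  list(image = apply_dihedral(image, op),
       label = apply_dihedral(label, op),
       op = op)
}

# --- training ------------------------------------------------------------

normalize_stack <- function(images) {
  as_array3d(images) / dtype_max(images$dtype) - 0.5
}

# crop a (possibly reflect-padded) patch with top-left (y0, x0), 1-based;
# slice is a (h, w) matrix or (h, w, c) array
crop_patch <- function(slice, y0, x0, ps) {
  h <- dim(slice)[1]; w <- dim(slice)[2]
  yy <- reflect_index(y0 + seq_len(ps) - 1L, h)
  xx <- reflect_index(x0 + seq_len(ps) - 1L, w)
  if (length(dim(slice)) == 3) slice[yy, xx, , drop = FALSE]
  else slice[yy, xx, drop = FALSE]
}

reflect_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  ifelse(j < n, j + 1L, period - j + 1L)
}

targets_for <- function(gtpatch, loss, out_channels) {
  fg <- (gtpatch > 0) * 1
  if (loss == "softmax") {
    array(c(1 - fg, fg), c(dim(fg), 2L))
  } else {
    array(fg, c(dim(fg), out_channels))
  }
}

#' Train a 2D segmentation model
#'
#' Runs `config$epochs` gradient steps. Each step samples a random slice and a
#' random `patch_size` crop (reflect-padded when the image is smaller),
#' applies one random augmentation to the image/label pair, and takes an Adam
#' step on the configured loss. Binary targets are `label > 0`. Deterministic
#' for a fixed `config$seed`.
#'
#' @param images an [image_stack()] of training slices.
#' @param labels an aligned [label_volume()] (binary or instance ids; any
#'   nonzero id is foreground).
#' @param config a [cnn2d_config()].
#' @param model optionally continue training an existing [build_model()]
#'   handle.
#' @return a `trained_model2d`: the model plus `loss_history`, a numeric
#'   vector of length `config$epochs`.
#' @export
train2d <- function(images, labels, config, model = NULL) {
  x <- normalize_stack(images)
  gt <- as_array3d(labels)
  if (!all(dim(x)[1:3] == dim(gt))) stop("labels must align with images")
  if (!any(gt > 0)) warning("labels contain no foreground voxels")
  in_channels <- if (length(dim(x)) == 4) 3L else 1L
  out_channels <- if (config$loss == "softmax") 2L else 1L
  if (is.null(model)) model <- build_model(config, in_channels, out_channels)
  loss_fn <- make_loss(config$loss, out_channels)
  ps <- config$patch_size
  nz <- dim(x)[1]; h <- dim(x)[2]; w <- dim(x)[3]

  loss_history <- numeric(config$epochs)
  state <- adam_init(model$params)
  with_seed(config$seed + 1L, {
    for (step in seq_len(config$epochs)) {
      z <- sample.int(nz, 1)
      y0 <- sample.int(max(h - ps + 1L, 1L), 1)
      x0 <- sample.int(max(w - ps + 1L, 1L), 1)
      sl <- if (in_channels == 3L) x[z, , , ] else x[z, , ]
      img <- crop_patch(sl, y0, x0, ps)
      lab <- crop_patch(gt[z, , ], y0, x0, ps)
      aug <- augment(img, lab, config$augmentations)
      xin <- array(aug$image, c(ps, ps, in_channels))
      tgt <- targets_for(aug$label, config$loss, out_channels)
      fwd <- graph_forward(model$graph, model$params, xin, keep_cache = TRUE)
      l <- loss_fn(fwd$out, tgt)
      loss_history[step] <- l$value
      bwd <- graph_backward(model$graph, model$params, fwd, l$grad)
      upd <- adam_step(model$params, bwd$grads, state, config$learning_rate)
      model$params <- upd$params
      state <- upd$state
    }
  })
  structure(list(model = model, config = config, loss_history = loss_history),
            class = "trained_model2d")
}

#' @export
print.trained_model2d <- function(x, ...) {
  cat(sprintf("<trained_model2d> %s/%s, %d steps, final loss %.4g\n",
              x$config$topology, x$config$loss, length(x$loss_history),
              tail(x$loss_history, 1)))
  invisible(x)
}

# --- inference -----------------------------------------------------------

apply_link <- function(scores, link) {
  if (link == "softmax") {
    d <- dim(scores)
    m <- matrix(scores, ncol = d[length(d)])
    m <- m - apply(m, 1, max)
    e <- exp(m)
    p <- e / rowSums(e)
    dim(p) <- d
    p
  } else {
    1 / (1 + exp(-scores))
  }
}

#' Tiled 2D inference over an image stack
#'
#' Each slice is covered by `tile`-sized model windows laid out so their
#' central cores (the window minus an `overlap`-wide context margin) tile the
#' slice exactly; only core predictions are kept, so any output pixel farther
#' than `overlap` plus the network's receptive-field radius from the slice
#' border is identical to a whole-slice forward pass. Windows extending past
#' the slice are reflect-padded. Scores pass through the loss's link function
#' (sigmoid or per-pixel softmax), so outputs lie in `[0, 1]`.
#'
#' @param trained a `trained_model2d` (or bare `cnn2d_model`).
#' @param images an [image_stack()].
#' @param tile model window side in pixels (rounded up to a multiple of 16
#'   for `unet`).
#' @param overlap context margin in pixels; must satisfy `overlap < tile/2`.
#'   For seamless stitching use at least the receptive-field radius
#'   (`n_layers` for the full-resolution topologies).
#' @return a [prob_map()]: 3D `(z, y, x)` for single-channel models, 4D
#'   `(z, y, x, class)` for softmax models.
#' @export
infer2d <- function(trained, images, tile = 96, overlap = 16) {
  model <- if (inherits(trained, "trained_model2d")) trained$model else trained
  if (overlap >= tile / 2) stop("overlap must be smaller than tile/2")
  if (model$config$topology == "unet" && tile %% 16 != 0) {
    tile <- 16 * ceiling(tile / 16)
  }
  link <- if (model$config$loss == "softmax") "softmax" else "sigmoid"
  x <- normalize_stack(images)
  nz <- dim(x)[1]; h <- dim(x)[2]; w <- dim(x)[3]
  core <- tile - 2L * overlap
  C <- model$out_channels
  out <- array(0, c(nz, h, w, C))
  in_channels <- model$in_channels
  for (z in seq_len(nz)) {
    slice <- if (in_channels == 3L) x[z, , , ] else x[z, , ]
    for (y0 in seq(1L, h, by = core)) {
      for (x0 in seq(1L, w, by = core)) {
        win <- crop_patch(slice, y0 - overlap, x0 - overlap, tile)
        xin <- array(win, c(tile, tile, in_channels))
        p <- apply_link(graph_forward(model$graph, model$params, xin,
                                      keep_cache = FALSE)$out, link)
        cy <- seq_len(min(core, h - y0 + 1L))
        cx <- seq_len(min(core, w - x0 + 1L))
        out[z, y0 + cy - 1L, x0 + cx - 1L, ] <-
          p[overlap + cy, overlap + cx, , drop = FALSE]
      }
    }
  }
  if (C == 1L) {
    dim(out) <- c(nz, h, w)
  }
  prob_map(out, spacing_of(images))
}

# --- checkpointing -------------------------------------------------------

#' Save / load a trained model checkpoint
#'
#' A checkpoint is a single portable file holding the weights together with
#' the configuration.
#'
#' @param trained a `trained_model2d` (or any model object).
#' @param path checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` the restored
#'   object.
#' @export
save_model <- function(trained, path) {
  saveRDS(trained, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
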