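# Independent oracles used by the property and acceptance tests. These are
# deliberately implemented by a different route than the package internals:
# explicit voxel iteration, vectorized breadth-first search, direct formula
# evaluation.

# brute-force BFS connected-component labeling over either stencil
bfs_label3d <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, ]
  }
  lab <- array(0L, d)
  nextid <- 0L
  coord <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(coord))) {
    v <- coord[i, ]
    if (lab[v[1], v[2], v[3]] != 0) next
    nextid <- nextid + 1L
    frontier <- matrix(v, 1)
    lab[frontier] <- nextid
    while (nrow(frontier) > 0) {
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
        sweep(frontier, 2, offs[k, ], "+")))
      keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
              nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[keep, , drop = FALSE]
      nb <- nb[mask[nb] & lab[nb] == 0L, , drop = FALSE]
      if (nrow(nb)) {
        nb <- unique(nb)
        lab[nb] <- nextid
      }
      frontier <- nb
    }
  }
  lab
}

# independent Rand-score implementation: explicit voxel iteration into a
# string-keyed joint histogram, then direct evaluation of the defining
# equation
rand_oracle <- function(gt, pred, alpha, semantic = FALSE, restricted = TRUE) {
  g <- as.vector(gt)
  p <- as.vector(pred)
  if (semantic) {
    g <- as.integer(g > 0)
    p <- as.integer(p > 0)
  }
  joint <- new.env(parent = emptyenv())
  n <- 0L
  for (i in seq_along(g)) {
    if (restricted && g[i] == 0) next
    k <- paste(p[i], g[i])
    joint[[k]] <- (if (is.null(joint[[k]])) 0 else joint[[k]]) + 1
    n <- n + 1L
  }
  counts <- unlist(as.list(joint))
  keys <- do.call(rbind, strsplit(names(counts), " "))
  pij <- counts / n
  s <- tapply(pij, keys[, 1], sum)
  t_ <- tapply(pij, keys[, 2], sum)
  sum(pij^2) / (alpha * sum(s^2) + (1 - alpha) * sum(t_^2))
}

# do two label volumes agree up to an id bijection (background fixed)?
labels_equivalent <- function(a, b) {
  a <- as.vector(a)
  b <- as.vector(b)
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  fa <- a[a != 0L]
  fb <- b[b != 0L]
  pairs <- unique(paste(fa, fb))
  length(pairs) == length(unique(fa)) &&
    length(pairs) == length(unique(fb))
}

digitized_sphere <- function(side, radius, center = rep((side + 1) / 2, 3)) {
  a <- array(0L, c(side, side, side))
  r2 <- (slice.index(a, 1) - center[1])^2 + (slice.index(a, 2) - center[2])^2 +
        (slice.index(a, 3) - center[3])^2
  a[r2 <= radius^2] <- 1L
  a
}

random_label_volume <- function(dim, max_id, seed) {
  withr::with_seed(seed, array(sample(0:max_id, prod(dim), replace = TRUE), dim))
}

as_array_for_test <- function(x) {
  if (inherits(x, "label_volume")) x$labels else x$voxels
}

# forward difference along one axis, same shape (last plane zero)
diff_along <- function(arr, axis) {
  d <- dim(arr)
  out <- array(0, d)
  idx_hi <- lapply(seq_along(d), function(a) if (a == axis) 2:d[a] else seq_len(d[a]))
  idx_lo <- lapply(seq_along(d), function(a) if (a == axis) seq_len(d[a] - 1) else seq_len(d[a]))
  out_idx <- idx_lo
  out[out_idx[[1]], out_idx[[2]], out_idx[[3]]] <-
    arr[idx_hi[[1]], idx_hi[[2]], idx_hi[[3]]] -
    arr[idx_lo[[1]], idx_lo[[2]], idx_lo[[3]]]
  out
}
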