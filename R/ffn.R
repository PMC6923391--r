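# Desk-scale flood-filling network: a recurrent 3D CNN that predicts, within
# a moving field of view (FOV), which voxels belong to the object at the FOV
# center, combined with a flood-filling inference loop that grows one object
# at a time from seed points. Scaled for CPU use: small FOVs, shallow nets,
# hundreds of training steps.

#' Configuration for the flood-filling network
#'
#' @param fov odd `(z, y, x)` field-of-view size in voxels.
#' @param depth number of residual 3D conv blocks.
#' @param delta `(z, y, x)` move step in voxels; each component must be
#'   smaller than the corresponding FOV radius.
#' @param seed_prob initial center probability written at a seed voxel.
#' @param move_threshold face-center probability required to enqueue a move,
#'   in `(0.5, 1)`.
#' @param segment_threshold probability above which a voxel joins the object.
#' @param min_segment_size objects smaller than this many voxels are
#'   discarded.
#' @param steps training steps.
#' @param filters channel width of the 3D conv trunk.
#' @param n_refine mask-refinement iterations per FOV inference.
#' @param learning_rate Adam step size.
#' @param dark_objects objects are darker than background (used by the seed
#'   policy's intensity threshold).
#' @param seed integer seed for initialization and example order.
#' @return an `ffn_config`.
#' @export
ffn_config <- function(fov = c(17, 17, 17), depth = 2, delta = c(4, 4, 4),
                       seed_prob = 0.95, move_threshold = 0.9,
                       segment_threshold = 0.6, min_segment_size = 27,
                       steps = 500, filters = 12, n_refine = 2,
                       learning_rate = 1e-3, dark_objects = TRUE, seed = 0) {
  fov <- as.integer(fov)
  delta <- as.integer(delta)
  if (any(fov %% 2 == 0)) stop("fov components must be odd")
  if (any(delta >= fov %/% 2)) {
    stop("delta components must be smaller than the fov radius")
  }
  if (move_threshold <= 0.5 || move_threshold >= 1) {
    stop("move_threshold must lie in (0.5, 1)")
  }
  if (segment_threshold <= 0 || segment_threshold >= 1) {
    stop("segment_threshold must lie in (0, 1)")
  }
  structure(list(fov = fov, depth = as.integer(depth), delta = delta,
                 seed_prob = seed_prob, move_threshold = move_threshold,
                 segment_threshold = segment_threshold,
                 min_segment_size = as.integer(min_segment_size),
                 steps = as.integer(steps), filters = as.integer(filters),
                 n_refine = as.integer(n_refine),
                 learning_rate = learning_rate, dark_objects = dark_objects,
                 seed = as.integer(seed)),
            class = "ffn_config")
}

build_ffn_graph <- function(config) {
  g <- new_graph()
  F <- config$filters
  x <- g_conv(g, 1L, 2L, F, 3, nd = 3)
  x <- g_op(g, "relu", x)
  for (b in seq_len(config$depth)) {
    h <- g_conv(g, x, F, F, 3, nd = 3)
    h <- g_op(g, "relu", h)
    h <- g_conv(g, h, F, F, 3, nd = 3)
    x <- g_op(g, "add", x, h)
    x <- g_op(g, "relu", x)
  }
  g_conv(g, x, F, 1L, 1, nd = 3)
  g
}

# voxelwise logistic (sigmoid cross-entropy) loss on mask logits
ffn_logistic_loss <- function(logits, targets) {
  p <- 1 / (1 + exp(-logits))
  eps <- 1e-12
  n <- length(p)
  list(value = -mean(targets * log(pmax(p, eps)) +
                     (1 - targets) * log(pmax(1 - p, eps))),
       grad = (p - targets) / n)
}

logit <- function(p) log(p / (1 - p))
BG_PROB <- 0.05

# cut an FOV centered at `center` (z,y,x, 1-based) out of a 3D array, padding
# with `fill` where the FOV leaves the volume; returns the cut and the
# in-volume index ranges for write-back
cut_fov <- function(arr, center, fov, fill = 0) {
  d <- dim(arr)
  r <- fov %/% 2
  lo <- center - r
  hi <- center + r
  out <- array(fill, fov)
  slo <- pmax(lo, 1L)
  shi <- pmin(hi, d)
  if (any(slo > shi)) return(list(cut = out, src = NULL, dst = NULL))
  dlo <- slo - lo + 1L
  dhi <- shi - lo + 1L
  out[dlo[1]:dhi[1], dlo[2]:dhi[2], dlo[3]:dhi[3]] <-
    arr[slo[1]:shi[1], slo[2]:shi[2], slo[3]:shi[3]]
  list(cut = out,
       src = list(slo[1]:shi[1], slo[2]:shi[2], slo[3]:shi[3]),
       dst = list(dlo[1]:dhi[1], dlo[2]:dhi[2], dlo[3]:dhi[3]))
}

normalize_volume <- function(images) {
  v <- as_array3d(images)
  (v - mean(v)) / max(stats::sd(v), 1e-9)
}

# 3D summed-area box count of an indicator, window = center +/- r (same shape,
# zero-padded outside)
box_count <- function(ind, fov) {
  r <- fov %/% 2
  d <- dim(ind)
  a <- array(0, d + 2 * r + 1)
  a[r[1] + 1 + seq_len(d[1]), r[2] + 1 + seq_len(d[2]),
    r[3] + 1 + seq_len(d[3])] <- ind
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(a, perm)
    da <- dim(a)
    a <- array(apply(matrix(a, da[1]), 2, cumsum), da)
    a <- aperm(a, order(perm))
  }
  pick <- function(oz, oy, ox) {
    a[oz + seq_len(d[1]), oy + seq_len(d[2]), ox + seq_len(d[3])]
  }
  f <- 2 * r + 1
  pick(f[1], f[2], f[3]) - pick(0, f[2], f[3]) - pick(f[1], 0, f[3]) -
    pick(f[1], f[2], 0) + pick(0, 0, f[3]) + pick(0, f[2], 0) +
    pick(f[1], 0, 0) - pick(0, 0, 0)
}

#' Enumerate balanced FFN training coordinates
#'
#' For every voxel whose FOV lies fully inside the volume and whose center is
#' on a foreground object, the fraction of the FOV occupied by that object is
#' computed and bucketed into `n_classes` equal-width classes on `(0, 1]`.
#' The returned set is balanced: an equal number of coordinates per occupied
#' class (`n_per_class`, default the smallest class count), shuffled with
#' `seed`.
#'
#' @param labels a [label_volume()].
#' @param fov odd `(z, y, x)` field-of-view.
#' @param n_classes number of fill-fraction buckets.
#' @param n_per_class coordinates sampled per class (capped by availability);
#'   `NULL` uses the smallest occupied class count.
#' @param seed shuffle seed.
#' @return a [tibble::tibble()] with columns `z`, `y`, `x`, `object_id`,
#'   `partition_class`, `fill_fraction`.
#' @export
partition_examples <- function(labels, fov, n_classes = 9, n_per_class = NULL,
                               seed = 0) {
  lab <- as_array3d(labels)
  fov <- as.integer(fov)
  d <- dim(lab)
  r <- fov %/% 2
  if (!any(lab > 0)) {
    warning("no foreground in labels; returning empty coordinate set")
    return(tibble::tibble(z = integer(), y = integer(), x = integer(),
                          object_id = integer(), partition_class = integer(),
                          fill_fraction = numeric()))
  }
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  frac <- array(0, d)
  for (id in ids) {
    cnt <- box_count((lab == id) * 1, fov)
    sel <- lab == id
    frac[sel] <- cnt[sel] / prod(fov)
  }
  valid <- array(FALSE, d)
  valid[(r[1] + 1):(d[1] - r[1]), (r[2] + 1):(d[2] - r[2]),
        (r[3] + 1):(d[3] - r[3])] <- TRUE
  sel <- which(valid & lab > 0, arr.ind = TRUE)
  fr <- frac[sel]
  cls <- pmin(floor(fr * n_classes) + 1L, n_classes)
  tab <- tibble::tibble(z = sel[, 1], y = sel[, 2], x = sel[, 3],
                        object_id = lab[sel], partition_class = as.integer(cls),
                        fill_fraction = fr)
  counts <- table(tab$partition_class)
  if (is.null(n_per_class)) n_per_class <- min(counts)
  with_seed(seed, {
    keep <- unlist(lapply(names(counts), function(cl) {
      idx <- which(tab$partition_class == as.integer(cl))
      sample(idx, min(length(idx), n_per_class))
    }))
    tab <- tab[sample(keep), ]
  })
  tab
}

#' Write / read FFN training coordinates (HDF5)
#'
#' Coordinate tables travel as HDF5 with datasets `centers` (N x 3, zyx),
#' `ids` (N) and `classes` (N).
#'
#' @param coords tibble from [partition_examples()].
#' @param path `.h5` file path.
#' @return `ffn_write_coords` returns `path`; `ffn_read_coords` the tibble.
#' @export
ffn_write_coords <- function(coords, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(cbind(coords$z, coords$y, coords$x), path, "centers")
  rhdf5::h5write(coords$object_id, path, "ids")
  rhdf5::h5write(coords$partition_class, path, "classes")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname ffn_write_coords
#' @export
ffn_read_coords <- function(path) {
  centers <- rhdf5::h5read(path, "centers")
  tibble::tibble(z = as.integer(centers[, 1]), y = as.integer(centers[, 2]),
                 x = as.integer(centers[, 3]),
                 object_id = as.integer(rhdf5::h5read(path, "ids")),
                 partition_class = as.integer(rhdf5::h5read(path, "classes")))
}

#' Train a flood-filling network
#'
#' Each step cuts an FOV example at one training coordinate: the input is the
#' normalized intensity plus the current soft mask (seed probability at the
#' center, background elsewhere), the target the binary mask of the center
#' object within the FOV. The network predicts a residual update to the mask
#' logits; `n_refine` refinement iterations feed the updated mask back as the
#' mask channel (gradients do not flow across iterations). The loss is
#' voxelwise logistic. Deterministic for a fixed `config$seed`.
#'
#' @param images an [image_stack()].
#' @param labels the aligned ground-truth [label_volume()].
#' @param coords coordinate tibble from [partition_examples()];
#'   out-of-bounds coordinates are dropped with a warning.
#' @param config an [ffn_config()].
#' @return a `trained_ffn` with `loss_history` of length `config$steps`.
#' @export
train_ffn <- function(images, labels, coords, config) {
  x <- normalize_volume(images)
  lab <- as_array3d(labels)
  d <- dim(x)
  fov <- config$fov
  r <- fov %/% 2
  ok <- coords$z > r[1] & coords$z <= d[1] - r[1] &
        coords$y > r[2] & coords$y <= d[2] - r[2] &
        coords$x > r[3] & coords$x <= d[3] - r[3]
  if (!all(ok)) {
    warning(sprintf("dropped %d out-of-bounds coordinates", sum(!ok)))
    coords <- coords[ok, ]
  }
  if (nrow(coords) == 0) stop("no valid training coordinates")

  g <- build_ffn_graph(config)
  params <- init_params(g, config$seed)
  state <- adam_init(params)
  seed_logit <- logit(config$seed_prob)
  bg_logit <- logit(BG_PROB)
  ctr <- r + 1L
  loss_history <- numeric(config$steps)

  with_seed(config$seed + 1L, {
    order_idx <- rep_len(sample.int(nrow(coords)), config$steps)
    for (step in seq_len(config$steps)) {
      row <- coords[order_idx[step], ]
      center <- c(row$z, row$y, row$x)
      intens <- cut_fov(x, center, fov)$cut
      target <- (cut_fov(lab, center, fov)$cut == row$object_id) * 1
      mask_logits <- array(bg_logit, fov)
      mask_logits[ctr[1], ctr[2], ctr[3]] <- seed_logit
      step_loss <- 0
      grads_sum <- NULL
      for (it in seq_len(config$n_refine)) {
        xin <- array(c(intens, mask_logits), c(fov, 2L))
        fwd <- graph_forward(g, params, xin, keep_cache = TRUE)
        new_logits <- mask_logits + fwd$out[, , , 1]
        l <- ffn_logistic_loss(new_logits, target)
        step_loss <- step_loss + l$value / config$n_refine
        dout <- array(l$grad / config$n_refine, c(fov, 1L))
        bwd <- graph_backward(g, params, fwd, dout)
        grads_sum <- if (is.null(grads_sum)) bwd$grads else {
          mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                 grads_sum, bwd$grads, SIMPLIFY = FALSE)
        }
        mask_logits <- new_logits  # fed back, detached
      }
      loss_history[step] <- step_loss
      upd <- adam_step(params, grads_sum, state, config$learning_rate)
      params <- upd$params
      state <- upd$state
    }
  })
  structure(list(graph = g, params = params, config = config,
                 loss_history = loss_history),
            class = "trained_ffn")
}

#' @export
print.trained_ffn <- function(x, ...) {
  cat(sprintf("<trained_ffn> fov %s, depth %d, %d steps, final loss %.4g\n",
              paste(x$config$fov, collapse = "x"), x$config$depth,
              length(x$loss_history), tail(x$loss_history, 1)))
  invisible(x)
}

# predictor contract: function(intensity_fov, mask_prob_fov, center) -> FOV of
# membership probabilities for the object at the FOV center
ffn_predictor <- function(trained) {
  config <- trained$config
  function(intens, mask_prob, center) {
    logits <- logit(pmin(pmax(mask_prob, 1e-4), 1 - 1e-4))
    for (it in seq_len(config$n_refine)) {
      xin <- array(c(intens, logits), c(config$fov, 2L))
      out <- graph_forward(trained$graph, trained$params, xin,
                           keep_cache = FALSE)$out
      logits <- logits + out[, , , 1]
    }
    1 / (1 + exp(-logits))
  }
}

#' Ground-truth membership oracle
#'
#' Builds a predictor that returns the true membership mask of the object at
#' the FOV center (all-background FOVs return zeros); used to validate the
#' flood-filling loop independently of any trained network.
#'
#' @param labels ground-truth [label_volume()].
#' @return a predictor function usable as the `model` of
#'   [flood_fill_segment()].
#' @export
ffn_oracle <- function(labels) {
  lab <- as_array3d(labels)
  function(intens, mask_prob, center) {
    fov <- dim(intens)
    id <- lab[center[1], center[2], center[3]]
    if (id == 0) return(array(0, fov))
    (cut_fov(lab, center, fov)$cut == id) * 1
  }
}

#' Rank seed points for flood filling
#'
#' Unvisited voxels are ranked by a distance-transform peak criterion: the
#' intensity volume is thresholded (Otsu; the darker side is foreground when
#' `config$dark_objects`), claimed/visited voxels are removed, and local
#' maxima of the Euclidean distance transform are returned ordered by
#' decreasing distance with deterministic ties (z, then y, then x ascending).
#'
#' @param canvas list with `labels` (claimed ids) and `visited` (logical
#'   array), as maintained by [flood_fill_segment()]; pass arrays of zeros /
#'   `FALSE` for a fresh volume.
#' @param images the intensity [image_stack()].
#' @param config an [ffn_config()].
#' @return integer matrix with columns `z`, `y`, `x`, one row per seed.
#' @export
seed_policy <- function(canvas, images, config = ffn_config()) {
  v <- as_array3d(images)
  d <- dim(v)
  th <- EBImage::otsu(EBImage::Image(matrix(v / max(v, 1), nrow = d[2])))
  fg <- if (config$dark_objects) v / max(v, 1) < th else v / max(v, 1) >= th
  fg <- fg & !canvas$visited & canvas$labels == 0
  if (!any(fg)) {
    return(matrix(integer(), 0, 3, dimnames = list(NULL, c("z", "y", "x"))))
  }
  dist <- distance_transform(binary_volume(fg), anisotropic = FALSE)
  mx <- .maxfilter3_cpp(as.vector(dist), d)
  dim(mx) <- d
  cand <- which(fg & dist >= mx - 1e-12 & dist > 0, arr.ind = TRUE)
  dv <- dist[cand]
  ord <- order(-dv, cand[, 1], cand[, 2], cand[, 3])
  out <- cand[ord, , drop = FALSE]
  colnames(out) <- c("z", "y", "x")
  out
}

#' Flood-filling 3D instance segmentation
#'
#' For each seed in [seed_policy()] order: initialize the object's soft mask
#' at the seed, repeatedly run the model over the FOV and write the refreshed
#' mask back; enqueue moves of `delta` toward each FOV face whose center-face
#' probability reaches `move_threshold`, never revisiting a move location for
#' the same object. When the move queue empties, voxels at or above
#' `segment_threshold` become the object (first-come priority: voxels already
#' claimed by an earlier object are never overwritten); objects smaller than
#' `min_segment_size` are discarded.
#'
#' @param model a `trained_ffn`, or a predictor
#'   `function(intensity_fov, mask_prob_fov, center) -> probability FOV`
#'   such as [ffn_oracle()].
#' @param images the intensity [image_stack()].
#' @param config an [ffn_config()].
#' @return a [label_volume()] of instance ids (possibly empty).
#' @export
flood_fill_segment <- function(model, images, config = ffn_config()) {
  predictor <- if (inherits(model, "trained_ffn")) ffn_predictor(model)
               else model
  x <- normalize_volume(images)
  d <- dim(x)
  fov <- config$fov
  r <- fov %/% 2
  ctr_off <- r + 1L
  labels <- array(0L, d)
  visited <- array(FALSE, d)
  probability <- array(0, d)
  seeds <- seed_policy(list(labels = labels, visited = visited), images, config)
  next_id <- 0L

  for (s in seq_len(nrow(seeds))) {
    seed <- seeds[s, ]
    if (labels[seed[1], seed[2], seed[3]] != 0 ||
        visited[seed[1], seed[2], seed[3]]) next
    obj_prob <- array(BG_PROB, d)
    obj_prob[seed[1], seed[2], seed[3]] <- config$seed_prob
    queue <- list(seed)
    qhead <- 1L
    moved <- new.env(parent = emptyenv())  # per-object move locations
    key <- function(p) paste(p, collapse = ",")
    assign(key(seed), TRUE, envir = moved)

    while (qhead <= length(queue)) {
      pos <- queue[[qhead]]
      qhead <- qhead + 1L
      ic <- cut_fov(x, pos, fov)
      mc <- cut_fov(obj_prob, pos, fov, fill = BG_PROB)
      p <- predictor(ic$cut, mc$cut, pos)
      if (!is.null(mc$src)) {
        obj_prob[mc$src[[1]], mc$src[[2]], mc$src[[3]]] <-
          p[mc$dst[[1]], mc$dst[[2]], mc$dst[[3]]]
      }
      # face-center probabilities decide the moves
      for (axis in 1:3) {
        for (dir in c(-1L, 1L)) {
          face <- ctr_off
          face[axis] <- if (dir > 0) fov[axis] else 1L
          if (p[face[1], face[2], face[3]] >= config$move_threshold) {
            np <- pos
            np[axis] <- np[axis] + dir * config$delta[axis]
            if (np[axis] < 1L || np[axis] > d[axis]) next
            k <- key(np)
            if (!exists(k, envir = moved)) {
              assign(k, TRUE, envir = moved)
              queue[[length(queue) + 1L]] <- np
            }
          }
        }
      }
    }

    obj_mask <- obj_prob >= config$segment_threshold & labels == 0L
    visited[seed[1], seed[2], seed[3]] <- TRUE
    if (sum(obj_mask) >= config$min_segment_size) {
      next_id <- next_id + 1L
      labels[obj_mask] <- next_id
      visited[obj_mask] <- TRUE
      probability[obj_mask] <- pmax(probability[obj_mask], obj_prob[obj_mask])
    }
  }
  label_volume(labels, spacing_of(images))
}

#' Compact FFN output ids and render a colored preview
#'
#' Ids are compacted to `1..K` preserving first-appearance order, and a
#' deterministic palette (golden-angle hues) renders an RGB preview stack for
#' visual inspection; optionally written as PNG slices.
#'
#' @param labels a [label_volume()].
#' @param out_dir optional directory for the preview PNGs.
#' @return `list(labels, preview, files)`; `preview` is an RGB
#'   [image_stack()], `files` the written paths (or `NULL`).
#' @export
ffn_postprocess <- function(labels, out_dir = NULL) {
  compacted <- compact_labels(labels)
  lab <- as_array3d(compacted)
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  pal <- label_palette(max(ids, 0L))
  d <- dim(lab)
  preview <- array(0L, c(d, 3L))
  for (ch in 1:3) {
    plane <- array(0L, d)
    for (id in ids) plane[lab == id] <- pal[id, ch]
    preview[, , , ch] <- plane
  }
  preview <- image_stack(preview, compacted$spacing, "uint8")
  files <- NULL
  if (!is.null(out_dir)) {
    files <- write_stack(preview, out_dir, "png", prefix = "preview")
  }
  list(labels = compacted, preview = preview, files = files)
}

# deterministic distinct colors: golden-angle hue walk
label_palette <- function(n) {
  if (n < 1) return(matrix(integer(), 0, 3))
  h <- (0.618033988749895 * seq_len(n)) %% 1
  t(vapply(h, function(hh) as.integer(grDevices::col2rgb(grDevices::hsv(hh, 0.65, 1))),
           integer(3)))
}
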