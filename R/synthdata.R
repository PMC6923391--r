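# Synthetic EM-like fixtures: oval mitochondria in textured cytosol and
# membrane-bounded cell mosaics. Intensity model mimics SEM contrast
# qualitatively (dark organelles/membranes on bright cytosol, Gaussian noise);
# no claim of physical realism.

#' Specification for a synthetic volume
#'
#' @param shape `(z, y, x)` volume size in voxels.
#' @param mode `"mitochondria"` (dark ellipsoids with internal stripes) or
#'   `"mosaic"` (membrane-bounded columnar cells).
#' @param n_objects number of objects (ellipsoids or cells).
#' @param intensity_fg mean gray level of organelles/membranes (dark).
#' @param intensity_bg mean gray level of cytosol (bright).
#' @param noise_sd additive Gaussian noise, gray levels.
#' @param membrane_width membrane thickness in voxels (mosaic mode).
#' @param seed integer seed; generation is bit-reproducible.
#' @return a `synth_spec`.
#' @export
synth_spec <- function(shape = c(20, 128, 128), mode = "mitochondria",
                       n_objects = 10, intensity_fg = 80, intensity_bg = 180,
                       noise_sd = 10, membrane_width = 2, seed = 0) {
  if (!mode %in% c("mitochondria", "mosaic")) {
    stop("mode must be 'mitochondria' or 'mosaic'")
  }
  if (n_objects < 0) stop("n_objects must be >= 0")
  if (intensity_fg < 0 || intensity_bg > 255) {
    stop("gray levels must lie within the uint8 range")
  }
  structure(list(shape = as.integer(shape), mode = mode,
                 n_objects = as.integer(n_objects),
                 intensity_fg = intensity_fg, intensity_bg = intensity_bg,
                 noise_sd = noise_sd, membrane_width = membrane_width,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# smooth low-frequency texture: blurred white noise, zero mean, unit-ish sd
smooth_texture <- function(shape, sigma = 4) {
  n <- array(rnorm(prod(shape)), shape)
  k <- gauss_kernel(sigma)
  n <- filter_axis(n, k, 2)
  n <- filter_axis(n, k, 3)
  n / max(stats::sd(n), 1e-9)
}

#' Generate an ellipsoid ("mitochondria") fixture
#'
#' Places `n_objects` random non-overlapping 3D ellipsoids (random semi-axes
#' and in-plane orientation, so every slice cuts an oval), rendered darker
#' than the textured background with brighter internal stripes emulating
#' cristae, plus Gaussian noise. Objects keep a 2-voxel separation so
#' connected components are unambiguous at either connectivity.
#'
#' @param spec a [synth_spec()] with `mode = "mitochondria"`.
#' @return `list(images = image_stack, labels = label_volume)`.
#' @export
gen_mitochondria <- function(spec) {
  if (spec$mode != "mitochondria") stop("spec mode must be 'mitochondria'")
  d <- spec$shape
  with_seed(spec$seed, {
    labels <- array(0L, d)
    occupied <- array(FALSE, d)  # objects dilated by the separation margin
    placed <- 0L
    margin <- 2
    for (obj in seq_len(spec$n_objects)) {
      ok <- FALSE
      for (try in seq_len(100)) {
        az <- min(runif(1, 1.5, 3.5), max(0.6, (d[1] - 1) / 2))
        ay <- min(runif(1, 4, 10), max(2, (d[2] - 2) / 2))
        ax <- min(runif(1, 4, 10), max(2, (d[3] - 2) / 2))
        theta <- runif(1, 0, pi)
        safe_center <- function(n, a) {
          if (n - 2 * a > 2) runif(1, a + 1, n - a) else (n + 1) / 2
        }
        cz <- safe_center(d[1], az)
        cy <- safe_center(d[2], ay)
        cx <- safe_center(d[3], ax)
        bb <- list(z = max(1, floor(cz - az - margin)):min(d[1], ceiling(cz + az + margin)),
                   y = max(1, floor(cy - ay - margin)):min(d[2], ceiling(cy + ay + margin)),
                   x = max(1, floor(cx - ax - margin)):min(d[3], ceiling(cx + ax + margin)))
        gz <- rep(bb$z, times = length(bb$y) * length(bb$x))
        gy <- rep(rep(bb$y, each = length(bb$z)), times = length(bb$x))
        gx <- rep(bb$x, each = length(bb$z) * length(bb$y))
        u <- (gx - cx) * cos(theta) + (gy - cy) * sin(theta)
        v <- -(gx - cx) * sin(theta) + (gy - cy) * cos(theta)
        w <- gz - cz
        q <- (u / ax)^2 + (v / ay)^2 + (w / az)^2
        qm <- (u / (ax + margin))^2 + (v / (ay + margin))^2 +
              (w / (az + margin))^2
        inside <- q <= 1
        if (!any(inside)) next
        idx <- cbind(gz, gy, gx)
        if (any(occupied[idx[qm <= 1, , drop = FALSE]])) next
        labels[idx[inside, , drop = FALSE]] <- obj
        occupied[idx[qm <= 1, , drop = FALSE]] <- TRUE
        ok <- TRUE
        break
      }
      if (!ok) {
        stop(sprintf("placement error: placed %d of %d objects without overlap",
                     placed, spec$n_objects))
      }
      placed <- placed + 1L
    }

    img <- spec$intensity_bg + 12 * smooth_texture(d)
    fg <- labels > 0
    if (any(fg)) {
      # cristae-like stripes: brighter bands across the organelle interior
      xi <- slice.index(labels, 3)[fg]
      yi <- slice.index(labels, 2)[fg]
      stripes <- 25 * (sin(2 * pi * (xi + 0.7 * yi) / 5) > 0)
      img[fg] <- spec$intensity_fg + stripes
    }
    img <- img + rnorm(length(img), sd = spec$noise_sd)
    img <- array(as.integer(pmin(pmax(round(img), 0), 255)), d)
    list(images = image_stack(img, dtype = "uint8"),
         labels = label_volume(labels))
  })
}

#' Generate a cell-mosaic ("neurite") fixture
#'
#' Partitions the volume into `n_objects` columnar cells by nearest-generator
#' tessellation (generator points drift slightly from slice to slice), with
#' `membrane_width`-thick dark boundaries between cells. Labels are cell ids;
#' membrane voxels are background (0). With `membrane_width = 0` the cells
#' tile the volume with no background.
#'
#' @param spec a [synth_spec()] with `mode = "mosaic"` and `n_objects >= 2`.
#' @return `list(images = image_stack, labels = label_volume,
#'   generators = array)` where `generators` is `(n_objects, z, 2)` drifted
#'   generator coordinates `(y, x)` per slice.
#' @export
gen_mosaic <- function(spec) {
  if (spec$mode != "mosaic") stop("spec mode must be 'mosaic'")
  if (spec$n_objects < 2) stop("parameter error: mosaic needs n_objects >= 2")
  d <- spec$shape
  n <- spec$n_objects
  with_seed(spec$seed, {
    gy0 <- runif(n, 1, d[2])
    gx0 <- runif(n, 1, d[3])
    # per-slice drift: cumulative random walk, sd 0.75 voxels per slice
    drift_y <- apply(matrix(rnorm(n * d[1], sd = 0.75), d[1], n), 2, cumsum)
    drift_x <- apply(matrix(rnorm(n * d[1], sd = 0.75), d[1], n), 2, cumsum)
    gens <- array(0, c(n, d[1], 2))
    labels <- array(0L, d)
    membrane <- array(FALSE, d)
    py <- rep(seq_len(d[2]), times = d[3])
    px <- rep(seq_len(d[3]), each = d[2])
    for (z in seq_len(d[1])) {
      gy <- gy0 + drift_y[z, ]
      gx <- gx0 + drift_x[z, ]
      gens[, z, 1] <- gy
      gens[, z, 2] <- gx
      dist2 <- outer(py, gy, function(a, b) (a - b)^2) +
               outer(px, gx, function(a, b) (a - b)^2)
      ord1 <- max.col(-dist2, ties.method = "first")
      d1 <- sqrt(dist2[cbind(seq_along(ord1), ord1)])
      dist2[cbind(seq_along(ord1), ord1)] <- Inf
      d2 <- sqrt(dist2[cbind(seq_along(ord1), max.col(-dist2, ties.method = "first"))])
      lab <- ord1
      memb <- (d2 - d1) < spec$membrane_width
      lab[memb] <- 0L
      labels[z, , ] <- matrix(lab, d[2], d[3])
      membrane[z, , ] <- matrix(memb, d[2], d[3])
    }
    img <- spec$intensity_bg + 10 * smooth_texture(d)
    # mild per-cell brightness offsets so cells are distinguishable by eye
    cell_off <- runif(n, -12, 12)
    nzm <- labels > 0
    img[nzm] <- img[nzm] + cell_off[labels[nzm]]
    img[membrane] <- spec$intensity_fg
    img <- img + rnorm(length(img), sd = spec$noise_sd)
    img <- array(as.integer(pmin(pmax(round(img), 0), 255)), d)
    list(images = image_stack(img, dtype = "uint8"),
         labels = label_volume(labels),
         generators = gens)
  })
}

# Two dark spheres in a small cube: the canonical desk-scale 3D instance
# fixture used by the flood-filling tests and examples.
#' Generate a two-sphere fixture
#'
#' Two dark spheres on a bright noisy background in a cubic volume; used as a
#' minimal 3D instance-segmentation problem.
#'
#' @param side cube side in voxels.
#' @param radius sphere radius in voxels.
#' @param noise_sd Gaussian noise, gray levels.
#' @param seed integer seed.
#' @return `list(images, labels)` as in [gen_mitochondria()].
#' @export
gen_two_spheres <- function(side = 32, radius = 6, noise_sd = 8, seed = 0) {
  d <- c(side, side, side)
  centers <- rbind(c(0.3, 0.3, 0.3), c(0.7, 0.7, 0.7)) * side
  labels <- array(0L, d)
  zi <- slice.index(labels, 1); yi <- slice.index(labels, 2)
  xi <- slice.index(labels, 3)
  for (i in 1:2) {
    r2 <- (zi - centers[i, 1])^2 + (yi - centers[i, 2])^2 +
          (xi - centers[i, 3])^2
    labels[r2 <= radius^2] <- i
  }
  with_seed(seed, {
    img <- 180 + 10 * smooth_texture(d)
    img[labels > 0] <- 70
    img <- img + rnorm(length(img), sd = noise_sd)
    img <- array(as.integer(pmin(pmax(round(img), 0), 255)), d)
    list(images = image_stack(img, dtype = "uint8"),
         labels = label_volume(labels))
  })
}
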