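# Classic 2D/3D preprocessing filters, chainable in a single execution.
#
# CLAHE is implemented natively because the paper's parameterization (block
# size / histogram bins / max slope) needs an explicit slope-to-clip mapping:
# each tile's histogram is clipped at max_slope/bins of the tile's pixel mass
# (a uniform histogram has mass 1/bins per bin, so the transfer-function slope
# is limited to about max_slope times the identity slope), the clipped
# histogram is renormalized, and the equalization mapping
# (cdf - cdf_min)/(1 - cdf_min) is anchored at the lowest occupied gray level.
# A tile with a single gray level maps identity (no contrast information), so
# constant slices are exact fixed points. Tile mappings are blended by
# bilinear interpolation between tile centers; slices are processed
# independently.

clahe_lut <- function(vals, bins, max_slope, maxval) {
  npix <- length(vals)
  b <- pmin(floor(vals / (maxval + 1) * bins), bins - 1) + 1L
  hist <- tabulate(b, nbins = bins)
  occupied <- which(hist > 0)
  lut <- seq(0, maxval, length.out = bins)  # identity fallback
  if (length(occupied) > 1) {
    clip <- max_slope / bins * npix
    h <- pmin(hist, clip)
    cdf <- cumsum(h) / sum(h)
    cdf_min <- cdf[occupied[1]]
    if (cdf_min < 1) {
      lut <- pmax(cdf - cdf_min, 0) / (1 - cdf_min) * maxval
    }
  }
  lut
}

clahe_slice <- function(slice, block_size, bins, max_slope, maxval) {
  h <- nrow(slice); w <- ncol(slice)
  nty <- max(1L, ceiling(h / block_size))
  ntx <- max(1L, ceiling(w / block_size))
  ybrk <- round(seq(0, h, length.out = nty + 1))
  xbrk <- round(seq(0, w, length.out = ntx + 1))
  yc <- (head(ybrk, -1) + tail(ybrk, -1) + 1) / 2  # tile centers
  xc <- (head(xbrk, -1) + tail(xbrk, -1) + 1) / 2

  luts <- matrix(0, bins, nty * ntx)
  for (tx in seq_len(ntx)) {
    for (ty in seq_len(nty)) {
      px <- slice[(ybrk[ty] + 1):ybrk[ty + 1], (xbrk[tx] + 1):xbrk[tx + 1]]
      luts[, ty + nty * (tx - 1)] <- clahe_lut(as.vector(px), bins,
                                               max_slope, maxval)
    }
  }

  # bilinear blend of the 4 surrounding tile mappings, clamped at borders
  interp_axis <- function(coord, centers) {
    n <- length(centers)
    lo <- pmin(pmax(findInterval(coord, centers), 1L), max(n - 1L, 1L))
    hi <- pmin(lo + 1L, n)
    span <- centers[hi] - centers[lo]
    whi <- ifelse(span > 0, pmin(pmax((coord - centers[lo]) / span, 0), 1), 0)
    list(lo = lo, hi = hi, whi = whi)
  }
  ay <- interp_axis(seq_len(h), yc)
  ax <- interp_axis(seq_len(w), xc)

  bidx <- pmin(floor(slice / (maxval + 1) * bins), bins - 1) + 1L
  ylo <- ay$lo[row(slice)]; yhi <- ay$hi[row(slice)]; wy <- ay$whi[row(slice)]
  xlo <- ax$lo[col(slice)]; xhi <- ax$hi[col(slice)]; wx <- ax$whi[col(slice)]
  tile_at <- function(ty, tx) ty + nty * (tx - 1)
  v <- (1 - wy) * (1 - wx) * luts[cbind(as.vector(bidx), tile_at(ylo, xlo))] +
       (1 - wy) * wx       * luts[cbind(as.vector(bidx), tile_at(ylo, xhi))] +
       wy * (1 - wx)       * luts[cbind(as.vector(bidx), tile_at(yhi, xlo))] +
       wy * wx             * luts[cbind(as.vector(bidx), tile_at(yhi, xhi))]
  matrix(as.integer(round(v)), h, w)
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Slice-wise CLAHE with the parameterization block size / histogram bins /
#' max slope (defaults 127 / 256 / 1.50). The clip limit is
#' `max_slope / bins` of each tile's histogram mass; see the package vignette
#' for the exact mapping. Output has the same shape and dtype as the input and
#' spans the input dtype range.
#'
#' @param stack a single-channel [image_stack()].
#' @param block_size odd tile size in pixels, smaller than both slice sides.
#' @param bins number of histogram bins.
#' @param max_slope slope limit, `>= 1` (larger means less limiting;
#'   effectively plain adaptive equalization as it grows).
#' @return an [image_stack()].
#' @export
apply_clahe <- function(stack, block_size = 127, bins = 256, max_slope = 1.5) {
  arr <- as_array3d(stack)
  if (length(dim(arr)) != 3) stop("CLAHE expects a single-channel stack")
  h <- dim(arr)[2]; w <- dim(arr)[3]
  if (block_size %% 2 == 0) stop("parameter error: block_size must be odd")
  if (block_size >= min(h, w)) {
    stop("parameter error: block_size must be smaller than the image sides")
  }
  if (bins < 2) stop("parameter error: bins must be >= 2")
  if (max_slope < 1) stop("parameter error: max_slope must be >= 1")
  maxval <- dtype_max(stack$dtype)
  out <- arr
  for (z in seq_len(dim(arr)[1])) {
    out[z, , ] <- clahe_slice(arr[z, , ], block_size, bins, max_slope, maxval)
  }
  image_stack(out, stack$spacing, stack$dtype)
}

# --- filter catalog -------------------------------------------------------

#' Describe one filter application
#'
#' @param name filter identifier; see [filter_catalog()].
#' @param params named list of parameters for the filter.
#' @param dimensionality `"2d"` (slice-wise) or `"3d"` (volumetric kernel).
#' @return a `filter_spec`.
#' @export
filter_spec <- function(name, params = list(), dimensionality = "2d") {
  if (!name %in% filter_catalog()) {
    stop("unknown filter '", name, "'; valid filters: ",
         paste(filter_catalog(), collapse = ", "))
  }
  if (!dimensionality %in% c("2d", "3d")) {
    stop("dimensionality must be '2d' or '3d'")
  }
  structure(list(name = name, params = params,
                 dimensionality = dimensionality),
            class = "filter_spec")
}

#' Names of the registered filters
#' @return character vector of filter identifiers.
#' @export
filter_catalog <- function() c("gaussian", "median", "clahe", "invert",
                               "threshold")

# separable 1D convolution along a given axis with reflect padding
filter_axis <- function(arr, kernel, axis) {
  r <- (length(kernel) - 1) / 2
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- matrix(a, d[1], d[2] * d[3])
  pad <- reflect_index(c((1 - r):0, seq_len(d[1]), d[1] + 1:r), d[1])
  mp <- m[pad, , drop = FALSE]
  f <- stats::filter(mp, kernel, sides = 2)
  m <- f[r + seq_len(d[1]), , drop = FALSE]
  dim(m) <- d
  aperm(m, order(perm))
}

gauss_kernel <- function(sigma) {
  r <- max(1, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

apply_one_filter <- function(stack, spec) {
  arr <- as_array3d(stack)
  maxval <- dtype_max(stack$dtype)
  p <- spec$params
  out <- switch(spec$name,
    clahe = {
      return(apply_clahe(stack,
                         block_size = p$block_size %||% 127,
                         bins = p$bins %||% 256,
                         max_slope = p$max_slope %||% 1.5))
    },
    invert = maxval - arr,
    threshold = {
      t_ <- p$t %||% 128
      ifelse(arr >= t_, maxval, 0L) * array(1L, dim(arr))
    },
    gaussian = {
      sigma <- p$sigma %||% 1
      if (spec$dimensionality == "3d") {
        k <- gauss_kernel(sigma)
        a <- filter_axis(arr, k, 1)
        a <- filter_axis(a, k, 2)
        a <- filter_axis(a, k, 3)
        round(a)
      } else {
        a <- arr
        for (z in seq_len(dim(arr)[1])) {
          a[z, , ] <- round(EBImage::gblur(arr[z, , ] / maxval,
                                           sigma = sigma) * maxval)
        }
        a
      }
    },
    median = {
      radius <- p$radius %||% 1
      if (spec$dimensionality == "3d") {
        median3d(arr, radius)
      } else {
        a <- arr
        for (z in seq_len(dim(arr)[1])) {
          a[z, , ] <- round(EBImage::medianFilter(arr[z, , ] / maxval,
                                                  size = radius) * maxval)
        }
        a
      }
    },
    stop("unknown filter '", spec$name, "'")
  )
  out <- pmin(pmax(out, 0), maxval)
  image_stack(array(as.integer(out), dim(arr)), stack$spacing, stack$dtype)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force 3D median over a cubic window; intended for small volumes
median3d <- function(arr, radius) {
  d <- dim(arr)
  offs <- expand.grid(dz = -radius:radius, dy = -radius:radius,
                      dx = -radius:radius)
  stackmat <- matrix(0, length(arr), nrow(offs))
  zi <- slice.index(arr, 1); yi <- slice.index(arr, 2); xi <- slice.index(arr, 3)
  for (i in seq_len(nrow(offs))) {
    z2 <- pmin(pmax(zi + offs$dz[i], 1), d[1])
    y2 <- pmin(pmax(yi + offs$dy[i], 1), d[2])
    x2 <- pmin(pmax(xi + offs$dx[i], 1), d[3])
    stackmat[, i] <- arr[cbind(as.vector(z2), as.vector(y2), as.vector(x2))]
  }
  out <- apply(stackmat, 1, median)
  array(round(out), d)
}

#' Apply an ordered chain of filters
#'
#' Filters are applied left to right in one execution; the result is
#' bit-identical to applying each filter separately in sequence.
#'
#' @param stack an [image_stack()].
#' @param chain list of [filter_spec()]s (an empty chain returns the input
#'   unchanged).
#' @return an [image_stack()].
#' @export
apply_filter_chain <- function(stack, chain) {
  for (spec in chain) {
    if (!inherits(spec, "filter_spec")) {
      spec <- filter_spec(spec$name, spec$params %||% list(),
                          spec$dimensionality %||% "2d")
    }
    stack <- apply_one_filter(stack, spec)
  }
  stack
}
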