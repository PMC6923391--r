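#' @useDynLib emsegkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif median quantile setNames
#' @importFrom utils head tail write.csv read.csv
#' @importFrom grDevices col2rgb hsv
NULL

# Default physical voxel spacing in nanometres (z, y, x): 30 nm sections,
# 6 nm in-plane, the common ATUM-SEM acquisition geometry. Overridable
# everywhere a spacing argument exists.
DEFAULT_SPACING <- c(30, 6, 6)

#' Construct an image stack
#'
#' An `image_stack` holds a 3D grayscale intensity volume in `(z, y, x)` axis
#' order (slice index = z, 0-based voxel semantics, 1-based R indexing), or a
#' 4D `(z, y, x, channel)` array for RGB stacks, together with the physical
#' voxel spacing in nanometres.
#'
#' @param voxels 3D numeric/integer array `(z, y, x)` (single channel) or 4D
#'   `(z, y, x, 3)` (RGB). Values are stored as integers in the range of
#'   `dtype`.
#' @param spacing numeric length-3 `(sz, sy, sx)` in nanometres, all `> 0`.
#' @param dtype `"uint8"` or `"uint16"` storage convention.
#' @return An `image_stack` object.
#' @export
image_stack <- function(voxels, spacing = DEFAULT_SPACING, dtype = NULL) {
  nd <- length(dim(voxels))
  if (!nd %in% c(3L, 4L)) {
    stop("image_stack voxels must be a 3D (z,y,x) or 4D (z,y,x,3) array")
  }
  if (nd == 4L && dim(voxels)[4] != 3L) {
    stop("4D image_stack must have exactly 3 channels")
  }
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 positive values (sz, sy, sx) in nm")
  }
  v <- as.numeric(voxels)
  if (is.null(dtype)) dtype <- if (max(v, 0) > 255) "uint16" else "uint8"
  if (!dtype %in% c("uint8", "uint16")) stop("dtype must be uint8 or uint16")
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, spacing = as.numeric(spacing), dtype = dtype),
            class = "image_stack")
}

#' Construct a label volume
#'
#' A `label_volume` is a 3D array of nonnegative integer object ids in
#' `(z, y, x)` order. Id 0 is background by convention; ids need not be
#' contiguous.
#'
#' @param labels 3D integer array `(z, y, x)`, all values `>= 0`.
#' @param spacing voxel spacing `(sz, sy, sx)` in nanometres.
#' @return A `label_volume` object.
#' @export
label_volume <- function(labels, spacing = DEFAULT_SPACING) {
  if (length(dim(labels)) != 3L) stop("label_volume must be a 3D (z,y,x) array")
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 positive values (sz, sy, sx) in nm")
  }
  if (min(labels) < 0) stop("label ids must be nonnegative")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = as.numeric(spacing)),
            class = "label_volume")
}

#' Construct a probability map
#'
#' Per-voxel values in `[0, 1]` emitted by inference; 3D `(z, y, x)` for a
#' single output channel or 4D `(z, y, x, class)` for multi-class outputs.
#'
#' @param values numeric array with values in `[0, 1]`.
#' @param spacing voxel spacing in nm.
#' @return A `prob_map` object.
#' @export
prob_map <- function(values, spacing = DEFAULT_SPACING) {
  nd <- length(dim(values))
  if (!nd %in% c(3L, 4L)) stop("prob_map must be 3D or 4D")
  if (min(values) < -1e-9 || max(values) > 1 + 1e-9) {
    stop("prob_map values must lie in [0, 1]")
  }
  structure(list(values = values, spacing = as.numeric(spacing)),
            class = "prob_map")
}

#' Construct a binary volume
#'
#' @param mask 3D logical array `(z, y, x)`.
#' @param spacing voxel spacing in nm.
#' @return A `binary_volume` object.
#' @export
binary_volume <- function(mask, spacing = DEFAULT_SPACING) {
  if (length(dim(mask)) != 3L) stop("binary_volume must be a 3D array")
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, spacing = as.numeric(spacing)),
            class = "binary_volume")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %s voxels (z,y,x%s), dtype %s, spacing %s nm\n",
              paste(d[1:3], collapse = "x"),
              if (length(d) == 4) ",c" else "", x$dtype,
              paste(x$spacing, collapse = "/")))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  ids <- setdiff(unique(as.vector(x$labels)), 0L)
  cat(sprintf("<label_volume> %s voxels (z,y,x), %d objects, spacing %s nm\n",
              paste(dim(x$labels), collapse = "x"), length(ids),
              paste(x$spacing, collapse = "/")))
  invisible(x)
}

#' @export
print.prob_map <- function(x, ...) {
  cat(sprintf("<prob_map> %s, range [%.3f, %.3f]\n",
              paste(dim(x$values), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  cat(sprintf("<binary_volume> %s, %d foreground voxels\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask)))
  invisible(x)
}

# dtype helpers ---------------------------------------------------------

dtype_max <- function(dtype) if (dtype == "uint16") 65535L else 255L

# Coerce any of the volume classes (or a bare array) to a plain 3D array.
as_array3d <- function(x) {
  if (inherits(x, "image_stack")) return(x$voxels)
  if (inherits(x, "label_volume")) return(x$labels)
  if (inherits(x, "prob_map")) return(x$values)
  if (inherits(x, "binary_volume")) return(x$mask)
  x
}

spacing_of <- function(x, default = DEFAULT_SPACING) {
  if (is.list(x) && !is.null(x$spacing)) x$spacing else default
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so package internals never perturb user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
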