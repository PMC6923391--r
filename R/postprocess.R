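# Probability maps -> labeled 3D objects: binarize, 3D connected components,
# marker-based 3D watershed on the (anisotropic) Euclidean distance transform,
# small-object removal.

#' Binarize a probability map or image stack
#'
#' Foreground is `value >= threshold` (a value exactly at the threshold is
#' foreground). Default threshold: 0.5 for probability maps, 128 for image
#' stacks.
#'
#' @param map a [prob_map()], [image_stack()] or numeric 3D array.
#' @param threshold cut value; `NULL` picks the default for the input type.
#' @return a [binary_volume()].
#' @export
binarize <- function(map, threshold = NULL) {
  arr <- as_array3d(map)
  # multi-class maps: the last channel is the foreground class by convention
  if (length(dim(arr)) == 4) {
    arr <- arr[, , , dim(arr)[4], drop = FALSE]
    dim(arr) <- dim(arr)[1:3]
  }
  if (is.null(threshold)) {
    threshold <- if (inherits(map, "image_stack")) 128 else 0.5
  }
  binary_volume(arr >= threshold, spacing_of(map))
}

#' Label connected 3D components
#'
#' Each maximal connected foreground component receives a distinct id
#' `1..K`, assigned in storage scan order of the component's first voxel;
#' background stays 0.
#'
#' @param mask a [binary_volume()] or logical 3D array.
#' @param connectivity 6 (faces) or 26 (faces + edges + corners). 6 is the
#'   conservative default for thin EM structures.
#' @return a [label_volume()].
#' @export
label3d <- function(mask, connectivity = 6) {
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  m <- as_array3d(mask)
  storage.mode(m) <- "logical"
  lab <- .label3d_cpp(as.vector(m), dim(m), as.integer(connectivity))
  dim(lab) <- dim(m)
  label_volume(lab, spacing_of(mask))
}

#' Euclidean distance transform of a 3D mask
#'
#' Exact distance from each foreground voxel to the nearest background voxel,
#' computed with the separable lower-envelope algorithm. With
#' `anisotropic = TRUE` distances are physical (nanometres, using the mask's
#' voxel spacing); otherwise they are in voxel units.
#'
#' @param mask a [binary_volume()] or logical array.
#' @param anisotropic use physical spacing (default) or unit voxels.
#' @return numeric 3D array of distances (0 on background).
#' @export
distance_transform <- function(mask, anisotropic = TRUE) {
  m <- as_array3d(mask)
  storage.mode(m) <- "logical"
  sp <- if (anisotropic) spacing_of(mask) else c(1, 1, 1)
  d <- .edt3d_cpp(as.vector(m), dim(m), as.numeric(sp))
  dim(d) <- dim(m)
  attr(d, "unit") <- sp
  d
}

# Distance-transform peak markers: h-maxima of the EDT. Shallow local maxima
# (plateaus along thin necks, digitization ripples) are suppressed by grayscale
# reconstruction: peaks must rise at least `h` above their surrounding saddle
# to seed a region. Surviving peak plateaus are merged (26-connected).
derive_markers <- function(mask, dist, h = NULL) {
  m <- as_array3d(mask)
  d <- dim(m)
  if (is.null(h)) h <- min(attr(dist, "unit") %||% 1)
  recon <- pmax(dist - h, 0)
  repeat {
    nxt <- .maxfilter3_cpp(as.vector(recon), d)
    dim(nxt) <- d
    nxt <- pmin(nxt, dist)
    if (max(abs(nxt - recon)) < 1e-9) break
    recon <- nxt
  }
  cand <- m & (dist - recon >= h - 1e-9) & dist > 0
  label3d(binary_volume(cand, spacing_of(mask)), connectivity = 26)
}

#' Marker-based 3D watershed
#'
#' Floods the mask ascending on the negative distance transform (equivalently,
#' descending from distance peaks), so fused objects separate at their necks.
#' When `markers` is absent they are derived as local maxima of the Euclidean
#' distance transform (3-voxel window, plateau-merged). Every foreground voxel
#' receives exactly one marker's id; background is untouched. Flood order is
#' deterministic: higher distance first, then discovery (BFS) order, then
#' marker id — so equal-distance fronts grow in lock step and a straight bar
#' with markers at both ends splits in half.
#'
#' @param mask a [binary_volume()] or logical array.
#' @param markers optional [label_volume()] (or integer array) of nonzero
#'   marker ids lying within the mask.
#' @param connectivity neighborhood stencil, 6 or 26.
#' @param anisotropic weight the distance transform by voxel spacing.
#' @return a [label_volume()]; empty when no markers are derivable.
#' @export
watershed3d <- function(mask, markers = NULL, connectivity = 6,
                        anisotropic = TRUE) {
  m <- as_array3d(mask)
  storage.mode(m) <- "logical"
  if (!any(m)) {
    return(label_volume(array(0L, dim(m)), spacing_of(mask)))
  }
  dist <- distance_transform(mask, anisotropic)
  if (is.null(markers)) {
    markers <- derive_markers(mask, dist)
  }
  mk <- as_array3d(markers)
  if (any(mk[!m] != 0)) stop("markers must lie within the mask")
  lab <- .watershed_flood_cpp(as.vector(m), as.vector(dist),
                              as.integer(as.vector(mk)), dim(m),
                              as.integer(connectivity))
  dim(lab) <- dim(m)
  label_volume(lab, spacing_of(mask))
}

#' Remove small objects from a label volume
#'
#' Objects with fewer than `min_size` voxels are set to background; the
#' remaining ids are unchanged.
#'
#' @param labels a [label_volume()].
#' @param min_size minimum voxel count to survive (`>= 0`).
#' @return a [label_volume()].
#' @export
remove_small <- function(labels, min_size) {
  if (min_size < 0) stop("min_size must be >= 0")
  lab <- as_array3d(labels)
  if (min_size > 0 && any(lab > 0)) {
    counts <- table(lab[lab > 0])
    drop <- as.integer(names(counts)[counts < min_size])
    lab[lab %in% drop] <- 0L
  }
  label_volume(lab, spacing_of(labels))
}

#' Compact label ids to 1..K
#'
#' Ids are renumbered to consecutive integers preserving the order of first
#' appearance in storage scan order; background stays 0.
#'
#' @param labels a [label_volume()].
#' @return a [label_volume()].
#' @export
compact_labels <- function(labels) {
  lab <- as_array3d(labels)
  ids <- unique(as.vector(lab))
  ids <- ids[ids != 0L]
  if (length(ids)) {
    remap <- setNames(seq_along(ids), ids)
    nz <- lab != 0L
    lab[nz] <- remap[as.character(lab[nz])]
  }
  storage.mode(lab) <- "integer"
  label_volume(lab, spacing_of(labels))
}
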