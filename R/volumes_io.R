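# Stack I/O: PNG (8-bit gray, 24-bit RGB), TIFF (8/16/32-bit, multipage),
# HDF5 (single dataset "stack", zyx). Label volumes with ids > 255 are stored
# RGB-packed in PNG (little-endian: id = R + 256*G + 65536*B, the Dojo/VAST
# convention) or as 32-bit TIFF.

#' Pack label ids into RGB triples
#'
#' Little-endian packing: `id = R + 256*G + 65536*B`. A bijection on
#' `[0, 2^24)`.
#'
#' @param ids integer vector of nonnegative ids `< 2^24`.
#' @return integer matrix with columns `r`, `g`, `b`.
#' @export
pack_label_rgb <- function(ids) {
  ids <- as.numeric(ids)
  if (any(ids < 0) || any(ids >= 2^24)) {
    stop("label ids must lie in [0, 2^24) for RGB packing")
  }
  cbind(r = as.integer(ids %% 256),
        g = as.integer((ids %/% 256) %% 256),
        b = as.integer(ids %/% 65536))
}

#' Unpack RGB triples into label ids
#'
#' Inverse of [pack_label_rgb()].
#'
#' @param r,g,b integer vectors/arrays of 8-bit channel values.
#' @return numeric ids `r + 256*g + 65536*b` (shape of `r` preserved).
#' @export
unpack_label_rgb <- function(r, g, b) {
  r + 256 * g + 65536 * b
}

# natural sort key: the last run of digits in the file name (without extension)
slice_order <- function(files) {
  base <- tools::file_path_sans_ext(basename(files))
  num <- suppressWarnings(as.numeric(sub(".*?(\\d+)\\D*$", "\\1", base)))
  if (anyNA(num)) order(base) else order(num, base)
}

read_slice <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "png") {
    x <- png::readPNG(file)
    if (length(dim(x)) == 3 && dim(x)[3] == 4) x <- x[, , 1:3, drop = FALSE]
    round(x * 255)
  } else if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(file, as.is = TRUE)
    if (length(dim(x)) == 3 && dim(x)[3] == 4) x <- x[, , 1:3, drop = FALSE]
    x
  } else {
    stop(sprintf("unsupported slice format '%s' (expected png/tif/tiff)", ext))
  }
}

slices_to_volume <- function(slices, kind, spacing) {
  dims <- lapply(slices, function(s) dim(s)[1:2])
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    stop("dimension mismatch: slices do not share height/width")
  }
  nz <- length(slices)
  h <- dims[[1]][1]; w <- dims[[1]][2]
  rgb <- length(dim(slices[[1]])) == 3
  if (kind == "label") {
    labels <- array(0L, c(nz, h, w))
    for (z in seq_len(nz)) {
      s <- slices[[z]]
      labels[z, , ] <- if (length(dim(s)) == 3) {
        unpack_label_rgb(s[, , 1], s[, , 2], s[, , 3])
      } else s  # grayscale ground truth taken verbatim
    }
    label_volume(labels, spacing)
  } else if (rgb) {
    voxels <- array(0L, c(nz, h, w, 3))
    for (z in seq_len(nz)) voxels[z, , , ] <- slices[[z]]
    image_stack(voxels, spacing)
  } else {
    voxels <- array(0L, c(nz, h, w))
    for (z in seq_len(nz)) voxels[z, , ] <- slices[[z]]
    image_stack(voxels, spacing)
  }
}

#' Read an image stack or label volume
#'
#' Accepts a directory of numbered PNG/TIFF slice files (stacked in ascending
#' numeric filename order), a multipage TIFF, or an HDF5 file with a dataset
#' named `"stack"`. RGB label slices are decoded as
#' `id = R + 256*G + 65536*B`; grayscale label slices are taken verbatim.
#'
#' @param path file or directory path.
#' @param kind `"image"` or `"label"`.
#' @param spacing voxel spacing `(sz, sy, sx)` in nm; default `c(30, 6, 6)`.
#' @return An [image_stack()] or [label_volume()].
#' @export
read_stack <- function(path, kind = c("image", "label"),
                       spacing = DEFAULT_SPACING) {
  kind <- match.arg(kind)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0) stop(sprintf("no slice files found in '%s'", path))
    files <- files[slice_order(files)]
    return(slices_to_volume(lapply(files, read_slice), kind, spacing))
  }
  if (!file.exists(path)) stop(sprintf("path '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    slices_to_volume(pages, kind, spacing)
  } else if (ext %in% c("h5", "hdf5")) {
    x <- rhdf5::h5read(path, "stack")
    sp <- tryCatch(as.numeric(rhdf5::h5read(path, "spacing")),
                   error = function(e) spacing)
    if (length(sp) != 3 || any(!is.finite(sp)) || any(sp <= 0)) sp <- spacing
    if (kind == "label") label_volume(x, sp) else image_stack(x, sp)
  } else if (ext == "png") {
    slices_to_volume(list(read_slice(path)), kind, spacing)
  } else {
    stop(sprintf("unsupported stack format '.%s'", ext))
  }
}

write_slice_png <- function(mat, file) {
  png::writePNG(mat / 255, file)
}

#' Write an image stack or label volume
#'
#' PNG and TIFF write one numbered file per slice (`slice0000.png`, ...);
#' `path` is treated as a directory unless `format = "tiff"` and `path` ends
#' in `.tif`/`.tiff` (single multipage file) or `format = "hdf5"` (`path` is
#' the `.h5` file). Label ids greater than 255 are written RGB-packed in PNG
#' or as 32-bit samples in TIFF; ids at or above `2^24` are a range error for
#' PNG. Round trips through [read_stack()] are bit-exact.
#'
#' @param volume an [image_stack()] or [label_volume()].
#' @param path output directory (PNG/TIFF) or file (HDF5, multipage TIFF).
#' @param format `"png"`, `"tiff"` or `"hdf5"`.
#' @param prefix slice filename prefix, default `"slice"`.
#' @return character vector of written file paths, invisibly.
#' @export
write_stack <- function(volume, path, format = c("png", "tiff", "hdf5"),
                        prefix = "slice") {
  format <- match.arg(format)
  is_label <- inherits(volume, "label_volume")
  arr <- as_array3d(volume)
  vmax <- if (length(arr)) max(arr) else 0L

  if (format == "hdf5") {
    if (!grepl("\\.(h5|hdf5)$", path)) path <- paste0(path, ".h5")
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(arr, path, "stack")
    rhdf5::h5write(volume$spacing, path, "spacing")
    rhdf5::h5closeAll()
    return(invisible(path))
  }

  nz <- dim(arr)[1]
  ext <- if (format == "png") "png" else "tif"
  multipage <- format == "tiff" && grepl("\\.(tif|tiff)$", path)
  if (!multipage) {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    files <- file.path(path, sprintf("%s%04d.%s", prefix, seq_len(nz) - 1, ext))
  }

  take_slice <- function(z) {
    if (length(dim(arr)) == 4) arr[z, , , ] else arr[z, , ]
  }

  if (format == "png") {
    if (is_label && vmax >= 2^24) {
      stop("range error: label ids >= 2^24 cannot be RGB-packed into PNG")
    }
    if (!is_label && volume$dtype != "uint8") {
      stop("PNG output supports 8-bit grayscale or 24-bit RGB images only")
    }
    pack <- is_label && vmax > 255
    for (z in seq_len(nz)) {
      s <- take_slice(z)
      if (pack) {
        rgb <- array(0, c(dim(s), 3))
        rgb[, , 1] <- s %% 256
        rgb[, , 2] <- (s %/% 256) %% 256
        rgb[, , 3] <- s %/% 65536
        write_slice_png(rgb, files[z])
      } else {
        write_slice_png(s, files[z])
      }
    }
    return(invisible(files))
  }

  # TIFF: pick sample depth from the value range / dtype
  bits <- if (is_label) {
    if (vmax > 65535) 32L else if (vmax > 255) 16L else 8L
  } else if (volume$dtype == "uint16") 16L else 8L
  denom <- if (bits == 32L) 2^32 - 1 else if (bits == 16L) 65535 else 255
  if (multipage) {
    pages <- lapply(seq_len(nz), function(z) take_slice(z) / denom)
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
    return(invisible(path))
  }
  for (z in seq_len(nz)) {
    tiff::writeTIFF(take_slice(z) / denom, files[z], bits.per.sample = bits)
  }
  invisible(files)
}
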