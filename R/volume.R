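#' 3D volume image with physical geometry
#'
#' A `VolumeImage` wraps a 3D numeric array of voxel intensities together
#' with an isotropic voxel edge length and a physical origin. The world
#' coordinate of the center of voxel `(i, j, k)` (0-based) is
#' `origin + voxel_size * (i, j, k)`; all physical quantities are in
#' micrometres. The third array index is the slice (z) index.
#'
#' @param values 3D numeric array of finite intensities.
#' @param voxel_size voxel edge length in micrometres (isotropic, > 0).
#' @param origin world position (um) of the center of voxel (0,0,0).
#' @return An object of class `VolumeImage`.
#' @export
volume_image <- function(values, voxel_size, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (um); ",
         "anisotropic voxels are not supported")
  if (any(dim(values) < 1L)) stop("all dimensions must be >= 1")
  if (!all(is.finite(values))) stop("intensities must be finite")
  structure(
    list(values = values, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "VolumeImage"
  )
}

#' 3D binary mask sharing VolumeImage geometry
#'
#' @param values 3D logical array.
#' @inheritParams volume_image
#' @return An object of class `BinaryMask`.
#' @export
binary_mask <- function(values, voxel_size, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  if (!is.logical(values)) {
    if (!all(values %in% c(0, 1, 255))) stop("mask values must be 0/1 or 0/255")
    values <- array(values > 0, dim = dim(values))
  }
  if (any(is.na(values))) stop("mask must not contain NA")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (um)")
  structure(
    list(values = values, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "BinaryMask"
  )
}

#' @export
print.VolumeImage <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("VolumeImage %d x %d x %d voxels, %.3g um/voxel, origin (%s) um\n",
              d[1], d[2], d[3], x$voxel_size,
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.BinaryMask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("BinaryMask %d x %d x %d voxels, %.3g um/voxel, %d on (%.2f%%)\n",
              d[1], d[2], d[3], x$voxel_size, sum(x$values),
              100 * mean(x$values)))
  invisible(x)
}

#' @export
dim.VolumeImage <- function(x) dim(x$values)

#' @export
dim.BinaryMask <- function(x) dim(x$values)

is_vol_like <- function(x) inherits(x, c("VolumeImage", "BinaryMask"))

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

# read one TIFF page as an integer x-by-y matrix (TIFF rows are y)
.page_to_xy <- function(page) {
  if (length(dim(page)) == 3L) page <- page[, , 1L]  # drop extra channels
  t(page)
}

#' Read a TIFF stack as a VolumeImage
#'
#' Reads either a multi-page grayscale TIFF or a directory of equally sized
#' single-page TIFFs (stacked in lexicographic filename order). The page
#' index becomes the z index. 8-bit sources load losslessly to integers in
#' `[0, 255]`.
#'
#' @param path path to a multi-page TIFF file or a directory of pages.
#' @param voxel_size isotropic voxel edge length in micrometres.
#' @param origin world position (um) of voxel (0,0,0); default (0,0,0).
#' @return A [volume_image()].
#' @export
read_stack <- function(path, voxel_size, origin = c(0, 0, 0)) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF pages found in ", path)
    pages <- lapply(files, function(f) {
      p <- tiff::readTIFF(f, as.is = TRUE)
      .page_to_xy(p)
    })
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    raw <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(raw)) raw <- list(raw)
    if (length(raw) == 0L) stop("TIFF has zero pages: ", path)
    pages <- lapply(raw, .page_to_xy)
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent page dimensions in ", path)
  vol <- array(0, dim = c(dims[1, 1], dims[2, 1], length(pages)))
  for (k in seq_along(pages)) vol[, , k] <- pages[[k]]
  volume_image(vol, voxel_size, origin)
}

#' Write a VolumeImage or BinaryMask as a multi-page 8-bit TIFF
#'
#' Masks are written as 0/255 for compatibility with external viewers.
#' Intensities outside `[0, 255]` are an error (no silent rescale).
#'
#' @param vol a [volume_image()] or [binary_mask()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(vol, path) {
  stopifnot(is_vol_like(vol))
  v <- vol$values
  if (is.logical(v)) v <- v * 255
  if (min(v) < 0 || max(v) > 255)
    stop("intensities must lie in [0, 255] for 8-bit TIFF export")
  pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Crop a rectangular block from a volume or mask
#'
#' The physical origin of the result is shifted so that the world
#' coordinates of retained voxels are unchanged. Indices are 0-based.
#'
#' @param vol a [volume_image()] or [binary_mask()].
#' @param origin_voxel integer triple (i, j, k), 0-based block corner.
#' @param size_voxels integer triple of block extents in voxels.
#' @return Object of the same class as `vol`.
#' @export
crop_block <- function(vol, origin_voxel, size_voxels) {
  stopifnot(is_vol_like(vol))
  o <- as.integer(origin_voxel)
  s <- as.integer(size_voxels)
  d <- dim(vol$values)
  if (length(o) != 3L || length(s) != 3L) stop("origin and size must be triples")
  if (any(s < 1L)) stop("block size must be >= 1 in every axis")
  if (any(o < 0L) || any(o + s > d))
    stop(sprintf("block [%s]+[%s] extends outside volume [%s]",
                 paste(o, collapse = ","), paste(s, collapse = ","),
                 paste(d, collapse = ",")))
  vals <- vol$values[o[1] + seq_len(s[1]), o[2] + seq_len(s[2]),
                     o[3] + seq_len(s[3]), drop = FALSE]
  out <- vol
  out$values <- vals
  out$origin <- vol$origin + vol$voxel_size * o
  out
}
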