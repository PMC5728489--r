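#' Construct a volume image
#'
#' A volume image is a plain 3D numeric array of scalar intensities on a
#' regular grid, carrying the physical (isotropic) voxel size in micrometers
#' as an attribute. All pipeline functions accept either a bare array or a
#' `volume_image`.
#'
#' @param data 3D numeric array (nx x ny x nz).
#' @param voxel_size_um isotropic voxel edge length in micrometers.
#' @return the array with class `volume_image` and a `voxel_size_um`
#'   attribute.
#' @export
volume_image <- function(data, voxel_size_um = NA_real_) {
  if (length(dim(data)) != 3L)
    stop("volume_image: `data` must be a 3D array")
  if (!all(is.finite(data)))
    stop("volume_image: intensities must all be finite")
  attr(data, "voxel_size_um") <- voxel_size_um
  class(data) <- c("volume_image", class(data))
  data
}

#' Voxel size of a volume
#' @param x a `volume_image` (or any array with a `voxel_size_um` attribute).
#' @return voxel edge length in micrometers, or `NA` if unknown.
#' @export
voxel_size <- function(x) {
  vs <- attr(x, "voxel_size_um")
  if (is.null(vs)) NA_real_ else vs
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume_image> %d x %d x %d voxels, voxel size %s um\n",
              d[1], d[2], d[3],
              ifelse(is.na(voxel_size(x)), "unknown", format(voxel_size(x)))))
  cat(sprintf("  intensity range [%g, %g]\n", min(x), max(x)))
  invisible(x)
}

# strip image classes/attributes down to a bare array
as_bare_array <- function(x) {
  a <- array(as.vector(x), dim = dim(x))
  a
}

check_volume <- function(x, what = "image") {
  if (length(dim(x)) != 3L)
    stop(sprintf("%s must be a 3D array", what))
  if (!all(is.finite(x)))
    stop(sprintf("%s contains non-finite values", what))
  invisible(x)
}

check_mask <- function(mask, what = "mask") {
  if (length(dim(mask)) != 3L)
    stop(sprintf("%s must be a 3D array", what))
  invisible(mask)
}

mask_as_int <- function(mask) {
  m <- array(as.integer(as.logical(mask) & !is.na(mask)), dim = dim(mask))
  m
}

#' Exact Euclidean distance transform
#'
#' Distance (in voxel units) from every foreground voxel center to the
#' nearest background voxel center; 0 on background. Exact, via the
#' separable lower-envelope algorithm.
#'
#' @param mask logical/integer 3D array; nonzero = foreground.
#' @return numeric 3D array of distances.
#' @export
distance_map_3d <- function(mask) {
  check_mask(mask)
  m <- mask_as_int(mask)
  d <- .cpp_edt(as.vector(m), dim(m))
  array(d, dim = dim(m))
}

#' Label connected components
#'
#' @param mask logical/integer 3D array; nonzero voxels are labelled.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return integer 3D array with dense labels 1..L (0 off-mask), assigned in
#'   raster order (deterministic).
#' @export
label_components <- function(mask, connectivity = 26) {
  check_mask(mask)
  if (!connectivity %in% c(6, 26))
    stop("connectivity must be 6 or 26")
  m <- mask_as_int(mask)
  lab <- .cpp_label_components(as.vector(m), dim(m), as.integer(connectivity))
  array(lab, dim = dim(m))
}

#' Downsample a volume by 2x mean pooling
#'
#' Averages non-overlapping 2x2x2 blocks; trailing odd slices are dropped.
#' The voxel size attribute, when present, doubles.
#'
#' @param vol 3D numeric array.
#' @return downsampled array.
#' @export
downsample2 <- function(vol) {
  check_volume(vol, "vol")
  d <- dim(vol)
  d2 <- d %/% 2L
  if (any(d2 < 1L)) stop("volume too small to downsample")
  v <- vol[seq_len(2L * d2[1]), seq_len(2L * d2[2]), seq_len(2L * d2[3])]
  arr <- array(v, dim = c(2L, d2[1], 2L, d2[2], 2L, d2[3]))
  out <- apply(arr, c(2L, 4L, 6L), mean)
  vs <- voxel_size(vol)
  if (!is.na(vs)) out <- volume_image(out, 2 * vs)
  out
}

# linear index helpers (1-based)
voxel_linear_index <- function(xyz, dims) {
  # xyz: matrix of 1-based (x, y, z) rows
  as.integer(xyz[, 1] + dims[1] * (xyz[, 2] - 1L) +
               dims[1] * dims[2] * (xyz[, 3] - 1L))
}

voxel_coords <- function(idx, dims) {
  # inverse of voxel_linear_index; returns 1-based (x, y, z) matrix
  idx0 <- idx - 1L
  z <- idx0 %/% (dims[1] * dims[2])
  rem <- idx0 - z * dims[1] * dims[2]
  y <- rem %/% dims[1]
  x <- rem - y * dims[1]
  cbind(x = x + 1L, y = y + 1L, z = z + 1L)
}
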