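#' Parameters for strip-restricted local thresholding
#'
#' Foreground is decided by comparing each voxel against the mean intensity
#' of its cubic neighborhood restricted to a strip `S` around the mineralized
#' layer: a voxel `x` is foreground iff `x` lies in `S` and
#' `I(x) > t_n * mean(I over B(x, l) intersect S)` (strict inequality).
#' The strip is grown from a tolerant global threshold and keeps far-away
#' background out of the neighborhood statistics.
#'
#' @param box_length edge length `l` of the cubic neighborhood `B(x, l)`, in
#'   voxels; odd, >= 3. Pick roughly two to three times the layer thickness.
#' @param t_n dimensionless ratio threshold (> 0); 1 by default.
#' @param t_g tolerant global threshold seeding the strip; should be below
#'   the lowest expected foreground intensity.
#' @param grow_radius Euclidean dilation radius (voxels, >= 0) growing the
#'   strip from its seed; `box_length / 2` is a good ceiling, since strip
#'   voxels further than that from the layer see no foreground in their box.
#' @return a `threshold_params` list.
#' @export
threshold_params <- function(box_length, t_n = 1, t_g, grow_radius = 0) {
  box_length <- as.integer(box_length)
  if (box_length < 3L || box_length %% 2L == 0L)
    stop("box_length must be odd and >= 3")
  if (t_n <= 0) stop("t_n must be > 0")
  if (grow_radius < 0) stop("grow_radius must be >= 0")
  if (missing(t_g)) stop("t_g (strip global threshold) is required")
  structure(list(box_length = box_length, t_n = t_n, t_g = t_g,
                 grow_radius = grow_radius),
            class = "threshold_params")
}

#' Build the strip around the mineralized layer
#'
#' Thresholds the (smoothed) image at `t_g` and dilates the resulting seed
#' mask by a Euclidean ball of radius `grow_radius`. The strip always
#' contains its seed.
#'
#' @param image 3D numeric array.
#' @param params a [threshold_params()] object.
#' @return logical 3D array `S`.
#' @export
make_strip <- function(image, params) {
  check_volume(image, "image")
  stopifnot(inherits(params, "threshold_params"))
  seed <- as_bare_array(image) > params$t_g
  if (!any(seed))
    stop("make_strip: global threshold t_g produced an empty seed mask")
  if (params$grow_radius == 0) return(seed)
  d <- distance_map_3d(!seed) # distance from non-seed voxels to the seed
  d <= params$grow_radius
}

# cumulative sum of a 3D array along dimension k
cumsum_dim <- function(a, k) {
  perm <- c(k, setdiff(1:3, k))
  ap <- aperm(a, perm)
  ap <- array(apply(ap, c(2, 3), cumsum), dim(ap))
  aperm(ap, order(perm))
}

# clipped box sums over B(x, l) for every voxel, via a padded integral image
box_sum <- function(a, l) {
  d <- dim(a)
  h <- (l - 1L) %/% 2L
  C <- array(0, d + 1L)
  C[-1, -1, -1] <- cumsum_dim(cumsum_dim(cumsum_dim(a, 1), 2), 3)
  lo <- lapply(1:3, function(k) pmax(seq_len(d[k]) - h, 1L))       # C index lo
  hi <- lapply(1:3, function(k) pmin(seq_len(d[k]) + h, d[k]) + 1L) # C index hi+1
  C[hi[[1]], hi[[2]], hi[[3]]] -
    C[lo[[1]], hi[[2]], hi[[3]]] -
    C[hi[[1]], lo[[2]], hi[[3]]] -
    C[hi[[1]], hi[[2]], lo[[3]]] +
    C[lo[[1]], lo[[2]], hi[[3]]] +
    C[lo[[1]], hi[[2]], lo[[3]]] +
    C[hi[[1]], lo[[2]], lo[[3]]] -
    C[lo[[1]], lo[[2]], lo[[3]]]
}

#' Strip-restricted local thresholding
#'
#' Applies the ratio criterion `I(x) > t_n * mean(I over B(x,l) intersect S)`
#' (strict) at every strip voxel; voxels outside the strip are background.
#' The box is clipped at volume borders. Implemented with 3D integral images,
#' which match the naive per-voxel box mean exactly.
#'
#' @param image 3D numeric array (typically the smoothed image).
#' @param strip logical 3D array `S` from [make_strip()].
#' @param params a [threshold_params()] object.
#' @return logical foreground mask `F` with `F` a subset of `S`.
#' @export
local_threshold <- function(image, strip, params) {
  check_volume(image, "image")
  stopifnot(inherits(params, "threshold_params"))
  if (!identical(dim(image), dim(strip)))
    stop("image and strip dimensions differ")
  s <- array(as.numeric(as.logical(strip)), dim = dim(strip))
  if (!any(s > 0)) stop("local_threshold: strip is empty")
  I <- as_bare_array(image)
  num <- box_sum(I * s, params$box_length)
  den <- box_sum(s, params$box_length)
  fg <- (s > 0) & (I * den > params$t_n * num) # I > t_n * num/den, den >= 1 on S
  fg
}

#' Fill enclosed background cavities
#'
#' Background components (6-connected) that do not touch the volume border
#' are switched to foreground; everything else is unchanged. Idempotent and
#' monotone (only adds voxels).
#'
#' @param mask logical 3D array.
#' @return logical 3D array.
#' @export
fill_enclosed <- function(mask) {
  check_mask(mask)
  m <- array(as.logical(mask), dim = dim(mask))
  bg <- label_components(!m, connectivity = 6)
  d <- dim(m)
  border <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                     bg[, , 1], bg[, , d[3]]))
  border <- border[border > 0]
  enclosed <- bg > 0 & !(bg %in% border)
  m | array(enclosed, dim = d)
}

#' Foreground segmentation (strip + local threshold + cavity fill)
#'
#' Convenience wrapper chaining [make_strip()], [local_threshold()] and
#' [fill_enclosed()].
#'
#' @inheritParams local_threshold
#' @return list with elements `strip` and `mask`.
#' @export
segment_foreground <- function(image, params) {
  strip <- make_strip(image, params)
  fg <- local_threshold(image, strip, params)
  list(strip = strip, mask = fill_enclosed(fg))
}
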