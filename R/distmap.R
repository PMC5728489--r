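#' Equidistributed directions on the unit sphere
#'
#' Deterministic Fibonacci-sphere construction: `count` unit vectors whose
#' mean vector shrinks toward zero as `count` grows (near-uniform coverage).
#'
#' @param count number of directions (>= 1).
#' @return `count` x 3 matrix of unit row vectors.
#' @export
sphere_directions <- function(count) {
  count <- as.integer(count)
  if (count < 1L) stop("count must be >= 1")
  i <- seq_len(count) - 1L
  z <- 1 - 2 * (i + 0.5) / count
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

default_ray_cap <- function(mask) {
  # generous default: the largest grid extent
  max(dim(mask))
}

#' Fit the locally best-approximating plane at a foreground voxel
#'
#' Casts rays from the voxel through the foreground until the first
#' background voxel (Bresenham-style dominant-axis traversal), then fits the
#' least-squares plane to the hit points: the plane normal is the direction
#' of least scatter of the hits about their centroid. The returned plane
#' passes through the query voxel.
#'
#' @param mask logical 3D foreground mask.
#' @param x voxel coordinates, 0-based `c(x, y, z)`; must be foreground.
#' @param dirs direction matrix from [sphere_directions()].
#' @param cap maximum ray length in voxels; rays that reach the cap (or
#'   leave the grid) contribute no hit point. Fewer than 3 hits is an error.
#' @return a `fit_plane` list: `point` (0-based voxel), unit `normal`,
#'   `n_hits`, and the hit points (0-based voxel centers).
#' @export
fit_plane <- function(mask, x, dirs, cap = default_ray_cap(mask)) {
  check_mask(mask)
  m <- mask_as_int(mask)
  x <- as.integer(round(x))
  if (length(x) != 3L) stop("x must be c(x, y, z), 0-based")
  if (any(x < 0L) || any(x >= dim(m)))
    stop("x outside the volume")
  if (m[x[1] + 1L, x[2] + 1L, x[3] + 1L] == 0L)
    stop("x is not a foreground voxel")
  res <- .cpp_fit_plane(as.vector(m), dim(m), x, dirs, cap)
  structure(list(point = x, normal = as.numeric(res$normal),
                 n_hits = res$n_hits, hits = res$hits),
            class = "fit_plane")
}

#' In-plane ray-cast distance at one voxel
#'
#' Casts `m` rays at equal angles within the given plane from its base voxel
#' and returns the distance to the nearest first-background hit (voxel
#' center to voxel center); returns `cap` if no ray meets background.
#'
#' @param mask logical 3D foreground mask.
#' @param plane a [fit_plane()] result (base point must be foreground).
#' @param m number of in-plane rays.
#' @param cap maximum ray length in voxels.
#' @return scalar distance in voxel units.
#' @export
distance2d_at <- function(mask, plane, m = 361L, cap = default_ray_cap(mask)) {
  stopifnot(inherits(plane, "fit_plane"))
  mk <- mask_as_int(mask)
  .cpp_distance2d_at(as.vector(mk), dim(mk), plane$point,
                     plane$normal, as.integer(m), cap)
}

#' Locally-planar 2D distance map
#'
#' For every foreground voxel, fits the plane that locally best approximates
#' the thin layer (via `n` 3D rays) and measures the in-plane ray-cast
#' distance to the nearest background voxel (via `m` rays in that plane).
#' Background voxels get 0. Unlike the standard 3D distance map, the result
#' is not capped by the layer thickness: on a thin sheet it measures the
#' in-sheet distance to pores, which is the shape cue separating tiles.
#'
#' @param mask logical 3D foreground mask (nonempty).
#' @param n number of 3D rays for the plane fit.
#' @param m number of in-plane rays.
#' @param cap maximum ray length in voxels.
#' @return numeric 3D array of distances (voxel units).
#' @export
distance_map_2d <- function(mask, n = 1214L, m = 361L,
                            cap = default_ray_cap(mask)) {
  check_mask(mask)
  mk <- mask_as_int(mask)
  if (!any(mk > 0L)) stop("distance_map_2d: empty mask")
  dirs <- sphere_directions(n)
  d <- .cpp_distance_map_2d(as.vector(mk), dim(mk), dirs, as.integer(m), cap)
  array(d, dim = dim(mk))
}
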