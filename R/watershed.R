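#' Build a hierarchical watershed of a distance map
#'
#' Floods the inverted distance map `-dist` (so tile centers, the locally
#' deepest points, become basin minima) with 26-connectivity, restricted to
#' the foreground. Connected minima plateaus collapse to single basins.
#' The first contact between two basins records a saddle event; events come
#' out sorted ascending by saddle value, so any persistence / minimum-size
#' segmentation can later be extracted by replaying events, without
#' re-flooding.
#'
#' @param dist numeric 3D distance map, zero exactly off the mask.
#' @param mask logical 3D foreground mask (nonempty).
#' @return a `watershed_hierarchy`: base label field at persistence 0,
#'   per-basin minima (value, voxel, size) and the saddle-ordered merge
#'   events.
#' @export
build_hierarchy <- function(dist, mask) {
  check_mask(mask)
  m <- mask_as_int(mask)
  if (!identical(dim(dist), dim(m)))
    stop("dist and mask dimensions differ")
  if (!any(m > 0L)) stop("build_hierarchy: empty mask")
  if (any(dist[m == 0L] != 0))
    stop("build_hierarchy: dist must be zero exactly off the mask")
  values <- -as.vector(dist) # invert: deep basins at large distances
  res <- .cpp_watershed_hierarchy(values, as.vector(m), dim(m))
  base <- array(res$labels, dim = dim(m))
  nb <- length(res$basin_min)
  structure(list(
    base_labels = base,
    basin_min = as.numeric(res$basin_min),
    basin_voxel = as.integer(res$basin_voxel),
    basin_size = tabulate(res$labels[res$labels > 0L], nbins = nb),
    events = data.frame(saddle = as.numeric(res$saddle),
                        a = as.integer(res$a), b = as.integer(res$b)),
    dims = dim(m)
  ), class = "watershed_hierarchy")
}

#' @export
print.watershed_hierarchy <- function(x, ...) {
  cat(sprintf("<watershed_hierarchy> %d basins, %d saddle events, grid %s\n",
              length(x$basin_min), nrow(x$events),
              paste(x$dims, collapse = " x ")))
  invisible(x)
}

# replay merge events; returns the root basin id for each base basin
replay_events <- function(h, t_p, t_v) {
  nb <- length(h$basin_min)
  parent <- seq_len(nb)
  minv <- h$basin_min
  size <- h$basin_size
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ev <- h$events
  for (k in seq_len(nrow(ev))) {
    ra <- find(ev$a[k])
    rb <- find(ev$b[k])
    if (ra == rb) next
    persistence <- ev$saddle[k] - max(minv[ra], minv[rb])
    if (persistence < t_p || size[ra] < t_v || size[rb] < t_v) {
      # the merged region keeps the deeper minimum
      keep <- if (minv[ra] < minv[rb] || (minv[ra] == minv[rb] && ra < rb))
        ra else rb
      drop <- if (keep == ra) rb else ra
      parent[drop] <- keep
      minv[keep] <- min(minv[ra], minv[rb])
      size[keep] <- size[ra] + size[rb]
    }
  }
  vapply(seq_len(nb), find, integer(1))
}

#' Extract a segmentation at given persistence / size thresholds
#'
#' Replays the hierarchy's merge events in ascending saddle order. At each
#' event between current regions A and B (minima m_A, m_B), the regions
#' merge if `saddle - max(m_A, m_B) < t_p` (the shallower side's
#' persistence), or if either region currently holds fewer than `t_v`
#' voxels; the merged region keeps the deeper minimum. `t_p = 0, t_v = 0`
#' reproduces the base oversegmentation (one label per minimum plateau).
#'
#' @param h a [build_hierarchy()] result.
#' @param t_p persistence threshold (>= 0), in distance-map units.
#' @param t_v minimum region size in voxels (>= 0).
#' @return integer label field, dense labels 1..L, 0 off the mask.
#' @export
extract_segmentation <- function(h, t_p = 0, t_v = 0) {
  stopifnot(inherits(h, "watershed_hierarchy"))
  if (t_p < 0 || t_v < 0) stop("t_p and t_v must be >= 0")
  roots <- replay_events(h, t_p, t_v)
  newlab <- match(roots, sort(unique(roots)))
  lut <- c(0L, as.integer(newlab))
  array(lut[h$base_labels + 1L], dim = h$dims)
}

#' Label counts along a persistence sweep
#'
#' @param h a [build_hierarchy()] result.
#' @param t_p_values ascending persistence thresholds.
#' @param t_v minimum region size applied at every threshold.
#' @return data.frame with columns `t_p` and `n_labels` (non-increasing).
#' @export
persistence_curve <- function(h, t_p_values, t_v = 0) {
  stopifnot(inherits(h, "watershed_hierarchy"))
  if (is.unsorted(t_p_values)) stop("t_p_values must be sorted ascending")
  n <- vapply(t_p_values, function(tp) {
    length(unique(replay_events(h, tp, t_v)))
  }, integer(1))
  data.frame(t_p = t_p_values, n_labels = n)
}

#' Suggest a persistence threshold from the label-count curve
#'
#' Finds the knee where the label count stops dropping rapidly and levels
#' off: the curve is smoothed with a centered 3-point moving average and the
#' threshold maximizing the second central finite difference is returned.
#' Advisory only; the final choice should be checked against a rendering of
#' the data.
#'
#' @param curve data.frame from [persistence_curve()] (>= 5 points,
#'   non-increasing).
#' @return a single `t_p` value.
#' @export
suggest_persistence <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("t_p", "n_labels") %in% names(curve)))
  if (nrow(curve) < 5L) stop("need at least 5 curve points")
  n <- curve$n_labels
  if (any(diff(n) > 0)) stop("curve must be non-increasing")
  if (all(n == n[1])) {
    warning("flat label-count curve; returning the smallest threshold")
    return(curve$t_p[1])
  }
  k <- length(n)
  sm <- vapply(seq_len(k), function(i) {
    mean(n[max(1, i - 1):min(k, i + 1)])
  }, numeric(1))
  d2 <- sm[seq_len(k - 2)] - 2 * sm[seq(2, k - 1)] + sm[seq(3, k)]
  curve$t_p[which.max(d2) + 1L]
}
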