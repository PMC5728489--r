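#' Landmark-based precision / recall of a segmentation
#'
#' Counting rules: a label region hit by at least one landmark is a true
#' positive; a region with n hits contributes n - 1 false negatives (an
#' n-cluster that needs splitting); a region with zero hits is a false
#' positive (an oversegmentation fragment that needs merging). Then
#' `precision = tp / (tp + fp)` and `recall = tp / (tp + fn)`. Landmarks are
#' mapped to voxels by nearest-voxel rounding; landmarks falling on
#' background are excluded from the counts and reported as unassigned.
#'
#' @param labels integer 3D label field with at least one positive label.
#' @param landmarks data.frame with columns `x, y, z` (0-based voxel
#'   coordinates, within bounds).
#' @return a `pr_report` list: `tp`, `fn`, `fp`, `precision`, `recall`,
#'   `hits` (per-label hit counts), `zero_hit_labels`, `multi_hit_labels`,
#'   `unassigned` (row indices of background landmarks).
#' @export
landmark_pr <- function(labels, landmarks) {
  check_mask(labels, "labels")
  ids <- sort(unique(as.vector(labels[labels > 0])))
  if (length(ids) == 0) stop("landmark_pr: label field has no positive labels")
  d <- dim(labels)
  ix <- as.integer(round(landmarks$x)) + 1L
  iy <- as.integer(round(landmarks$y)) + 1L
  iz <- as.integer(round(landmarks$z)) + 1L
  if (any(ix < 1 | ix > d[1] | iy < 1 | iy > d[2] | iz < 1 | iz > d[3]))
    stop("landmark_pr: landmark outside the grid")
  at <- labels[cbind(ix, iy, iz)]
  unassigned <- which(at == 0)
  hits <- table(factor(at[at > 0], levels = ids))
  tp <- sum(hits >= 1)
  fn <- sum(pmax(as.integer(hits) - 1L, 0L))
  fp <- sum(hits == 0)
  structure(list(
    tp = tp, fn = fn, fp = fp,
    precision = tp / (tp + fp),
    recall = tp / (tp + fn),
    hits = as.integer(hits),
    labels = ids,
    zero_hit_labels = ids[hits == 0],
    multi_hit_labels = ids[hits > 1],
    unassigned = unassigned
  ), class = "pr_report")
}

#' @export
print.pr_report <- function(x, ...) {
  cat(sprintf(
    "<pr_report> tp %d, fn %d, fp %d | precision %.4f, recall %.4f\n",
    x$tp, x$fn, x$fp, x$precision, x$recall))
  if (length(x$unassigned))
    cat(sprintf("  %d landmark(s) on background (unassigned)\n",
                length(x$unassigned)))
  invisible(x)
}

check_roi <- function(a, b, roi) {
  if (!identical(dim(a), dim(b)) || !identical(dim(a), dim(roi)))
    stop("label fields and roi must have identical dimensions")
  r <- as.logical(roi)
  if (sum(r) < 2) stop("roi must contain at least 2 voxels")
  if (any(a[r] <= 0) || any(b[r] <= 0))
    stop("roi must lie within the positive-label support of both fields")
  r
}

#' Rand index of two segmentations (percent)
#'
#' Fraction of unordered voxel pairs in the ROI on which the two partitions
#' agree (co-labelled in both, or separated in both), times 100. Computed
#' from the contingency table, which matches exhaustive pair enumeration.
#'
#' @param a,b integer 3D label fields.
#' @param roi logical mask restricting the comparison (e.g. the common
#'   foreground); must lie inside the positive support of both fields.
#' @return percentage in [0, 100]; 100 means identical partitions.
#' @export
rand_index <- function(a, b, roi) {
  r <- check_roi(a, b, roi)
  tab <- table(a[r], b[r])
  n <- sum(tab)
  ch2 <- function(x) x * (x - 1) / 2
  P <- sum(ch2(tab))
  A <- sum(ch2(rowSums(tab)))
  B <- sum(ch2(colSums(tab)))
  total <- ch2(n)
  100 * (total - A - B + 2 * P) / total
}

#' Variation of information between two segmentations
#'
#' `VI = H(A) + H(B) - 2 I(A; B)` over the voxel-level contingency table in
#' the ROI. A metric on partitions: 0 iff identical, symmetric, triangle
#' inequality. Also returns the additive per-label-pair contributions
#' `-p_ij (log(p_ij / p_i) + log(p_ij / p_j))`, whose sum is the VI, so the
#' worst-contributing label pair can be inspected.
#'
#' @inheritParams rand_index
#' @param units `"nats"` (natural log, default) or `"bits"`.
#' @return a `vi_report` list: `vi`, `units`, `contributions` (data.frame
#'   `a`, `b`, `contribution`, sorted decreasing), `worst_pair`.
#' @export
variation_of_information <- function(a, b, roi, units = c("nats", "bits")) {
  units <- match.arg(units)
  r <- check_roi(a, b, roi)
  lg <- if (units == "bits") log2 else log
  tab <- table(a[r], b[r])
  n <- sum(tab)
  p <- tab / n
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  contrib <- matrix(0, nrow(p), ncol(p))
  nz <- p > 0
  PI <- matrix(pi_, nrow(p), ncol(p))
  PJ <- matrix(pj_, nrow(p), ncol(p), byrow = TRUE)
  contrib[nz] <- -p[nz] * (lg(p[nz] / PI[nz]) + lg(p[nz] / PJ[nz]))
  vi <- sum(contrib)
  df <- data.frame(
    a = as.integer(rep(rownames(tab), ncol(tab)))[as.vector(nz)],
    b = as.integer(rep(colnames(tab), each = nrow(tab)))[as.vector(nz)],
    contribution = contrib[nz])
  df <- df[order(-df$contribution), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(vi = vi, units = units, contributions = df,
                 worst_pair = if (nrow(df)) df[1, c("a", "b")] else NULL),
            class = "vi_report")
}

#' @export
print.vi_report <- function(x, ...) {
  cat(sprintf("<vi_report> VI = %.4f %s\n", x$vi, x$units))
  invisible(x)
}

#' Persistence sweep comparing 2D and 3D distance-map segmentations
#'
#' Runs the pipeline twice from the same smoothed/thresholded volume — once
#' on the locally-planar 2D distance map, once on the standard 3D map —
#' extracts a segmentation at every persistence value and scores each
#' against the landmarks.
#'
#' @param image 3D numeric array (raw intensities).
#' @param landmarks data.frame of 0-based landmark coordinates.
#' @param diffusion a [diffusion_params()] object (NULL skips smoothing).
#' @param threshold a [threshold_params()] object.
#' @param t_p_values persistence thresholds to sweep (ascending).
#' @param t_v minimum region size during merging.
#' @param n_rays,m_rays ray counts for the 2D distance map.
#' @param cap ray cap (voxels); default the largest grid extent.
#' @return data.frame with columns `variant` ("2d"/"3d"), `persistence`,
#'   `n_labels`, `precision`, `recall`.
#' @export
compare_2d_vs_3d <- function(image, landmarks, diffusion, threshold,
                             t_p_values = 0:80, t_v = 50,
                             n_rays = 1214L, m_rays = 361L, cap = NULL) {
  smoothed <- if (is.null(diffusion)) image else
    smooth_anisotropic(image, diffusion)
  fgres <- segment_foreground(smoothed, threshold)
  mask <- fgres$mask
  if (is.null(cap)) cap <- default_ray_cap(mask)
  out <- list()
  for (variant in c("2d", "3d")) {
    dmap <- if (variant == "2d")
      distance_map_2d(mask, n = n_rays, m = m_rays, cap = cap)
    else distance_map_3d(mask)
    h <- build_hierarchy(dmap, mask)
    rows <- lapply(t_p_values, function(tp) {
      seg <- extract_segmentation(h, tp, t_v)
      pr <- landmark_pr(seg, landmarks)
      data.frame(variant = variant, persistence = tp,
                 n_labels = max(seg), precision = pr$precision,
                 recall = pr$recall)
    })
    out[[variant]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
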