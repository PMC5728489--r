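# Shared fixtures. Everything here is cheap; expensive objects are cached in
# a package-local environment so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# axis-aligned slab (z layers zlo..zhi, 1-based) with optional cylindrical
# pores through the full thickness, centered at `centers` (0-based x,y) with
# radius `r`. `inset` > 0 leaves that many background voxels on every x/y
# side so the slab's lateral walls are genuine background (rays then see the
# same boundary the in-plane EDT sees).
slab_mask <- function(d, zlo, zhi, centers = NULL, r = 0, inset = 0L) {
  mask <- array(FALSE, d)
  xs <- (1L + inset):(d[1] - inset)
  ys <- (1L + inset):(d[2] - inset)
  mask[xs, ys, zlo:zhi] <- TRUE
  if (!is.null(centers)) {
    ax <- seq_len(d[1]) - 1
    ay <- seq_len(d[2]) - 1
    for (i in seq_len(nrow(centers))) {
      pore <- outer((ax - centers[i, 1])^2, (ay - centers[i, 2])^2, "+") <= r^2
      for (z in zlo:zhi) mask[, , z][pore] <- FALSE
    }
  }
  mask
}

# exact in-plane (per-z-slice) EDT of a mask, the oracle for the 2D map on
# axis-aligned slabs
slicewise_edt <- function(mask) {
  d <- dim(mask)
  ref <- array(0, d)
  for (z in seq_len(d[3])) {
    sl <- mask[, , z]
    if (!any(sl)) next
    ref[, , z] <- distance_map_3d(array(sl, c(d[1], d[2], 1)))[, , 1]
  }
  ref
}

# brute-force Euclidean distance transform (voxel centers), usable up to a
# few thousand foreground voxels
brute_edt <- function(mask) {
  out <- array(0, dim(mask))
  fgi <- which(mask, arr.ind = TRUE)
  bgi <- which(!mask, arr.ind = TRUE)
  if (nrow(bgi) == 0) stop("mask has no background")
  tb <- t(bgi)
  out[mask] <- apply(fgi, 1, function(p) sqrt(min(colSums((tb - p)^2))))
  out
}

# brute-force count of 26-connected minima plateaus of `vals` on `mask`: the
# expected watershed label count at (T_p = 0, T_v = 0). A plateau is a
# maximal 26-connected set of equal-valued masked voxels; it is a regional
# minimum iff none of its voxels has a strictly lower masked 26-neighbor.
count_minima_plateaus <- function(vals, mask) {
  d <- dim(mask)
  # does voxel (p) see a strictly lower masked neighbor?
  sees_lower <- array(FALSE, d)
  idx <- which(mask)
  xyz <- arrayInd(idx, d)
  for (r in seq_along(idx)) {
    p <- xyz[r, ]
    v <- vals[idx[r]]
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- p + c(dx, dy, dz)
      if (any(q < 1) || any(q > d)) next
      if (!mask[q[1], q[2], q[3]]) next
      if (vals[q[1], q[2], q[3]] < v) {
        sees_lower[idx[r]] <- TRUE
        break
      }
    }
  }
  n <- 0L
  for (v in unique(vals[mask])) {
    cc <- label_components(mask & vals == v, 26)
    for (l in seq_len(max(cc)))
      if (!any(sees_lower[cc == l])) n <- n + 1L
  }
  n
}

# small flat phantom reused across tests (deterministic)
small_phantom <- function() {
  cached("small_phantom", {
    generate_phantom(phantom_spec(dims = c(64, 64, 16), k = 12L, seed = 11))
  })
}

# the small phantom run through smoothing + foreground extraction
small_pipeline_front <- function() {
  cached("small_front", {
    ph <- small_phantom()
    sm <- smooth_anisotropic(ph$volume, diffusion_params(100))
    fg <- segment_foreground(sm, threshold_params(9, 1, 80, 4))
    list(phantom = ph, smoothed = sm, strip = fg$strip, mask = fg$mask)
  })
}
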