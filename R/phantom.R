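#' Specification of a synthetic tessellated-shell phantom
#'
#' The phantom emulates the imaging regime of a thin mineralized layer tiled
#' into convex cells: a flat slab or spherical-cap shell is partitioned into
#' K tiles by nearest-seed assignment from Poisson-disk-sampled seeds on the
#' mid-surface; low-intensity pores are carved at junctions of three or more
#' tiles and along the outer portion of each pairwise border, leaving a
#' bright inter-tile connection (wider than the shell is thick) at the
#' border center; small low-contrast holes are stamped inside tiles; a
#' smooth polynomial intensity drift and additive Gaussian noise complete
#' the intensity synthesis. Ground truth (label field, one landmark per
#' tile, true neighbor pairs) is recorded before intensity synthesis.
#'
#' @param dims grid dimensions in voxels, `c(nx, ny, nz)`.
#' @param voxel_size_um isotropic voxel size (micrometers).
#' @param mode `"flat"` slab or `"cap"` (spherical-cap shell, which has an
#'   analytic surface normal at every voxel).
#' @param thickness shell thickness in voxels.
#' @param k number of tiles (>= 2).
#' @param tile_diameter mean tile diameter in voxels; must exceed
#'   `thickness` (the flat-tile regime).
#' @param pore_radius pore carving radius in voxels (>= 1).
#' @param connection_fraction fraction of each pairwise border left bright,
#'   in (0, 1).
#' @param holes_per_tile expected number of intra-tile holes per tile
#'   (Poisson).
#' @param hole_radius intra-tile hole radius in voxels.
#' @param fg_mean,bg_mean mean foreground / background intensities.
#' @param hole_contrast intensity dip of intra-tile holes; must be smaller
#'   than the pore contrast `fg_mean - bg_mean`, so diffusion can remove
#'   holes without bridging pores.
#' @param drift_amplitude amplitude of the smooth intensity drift, as a
#'   fraction of `fg_mean`.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed RNG seed; the same spec and seed give bit-identical output.
#' @return a validated `phantom_spec` list.
#' @export
phantom_spec <- function(dims = c(128L, 128L, 48L), voxel_size_um = 9.78,
                         mode = c("flat", "cap"), thickness = 3L, k = 100L,
                         tile_diameter = 12, pore_radius = 1.5,
                         connection_fraction = 0.5, holes_per_tile = 1.5,
                         hole_radius = 1.2, fg_mean = 200, bg_mean = 20,
                         hole_contrast = 60, drift_amplitude = 0.15,
                         noise_sd = 8, seed = 1L) {
  mode <- match.arg(mode)
  dims <- as.integer(dims)
  spec <- list(dims = dims, voxel_size_um = voxel_size_um, mode = mode,
               thickness = as.integer(thickness), k = as.integer(k),
               tile_diameter = tile_diameter, pore_radius = pore_radius,
               connection_fraction = connection_fraction,
               holes_per_tile = holes_per_tile, hole_radius = hole_radius,
               fg_mean = fg_mean, bg_mean = bg_mean,
               hole_contrast = hole_contrast,
               drift_amplitude = drift_amplitude, noise_sd = noise_sd,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (length(s$dims) != 3L || any(s$dims < 1L))
    stop("dims must be three positive integers")
  if (s$k < 2L) stop("k must be >= 2")
  if (s$tile_diameter <= s$thickness)
    stop("tile diameter must exceed shell thickness (flat-tile regime)")
  if (s$pore_radius < 1) stop("pore_radius must be >= 1 voxel")
  if (2 * s$pore_radius >= s$tile_diameter)
    stop("infeasible geometry: tiles smaller than pores")
  if (s$connection_fraction <= 0 || s$connection_fraction >= 1)
    stop("connection_fraction must be in (0, 1)")
  if (s$hole_contrast >= s$fg_mean - s$bg_mean)
    stop("intra-tile hole contrast must be below the pore contrast")
  if (s$thickness >= s$dims[3])
    stop("shell thickness must be smaller than the z extent")
  invisible(s)
}

# run expr under a private RNG state, restoring the caller's state
with_phantom_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Poisson-disk ("dart throwing") sampling of k points; candidates come from
# `draw()` (a function returning one coordinate row); spacing relaxes by 5%
# whenever a full attempt budget fails, so k points are always produced.
poisson_disk <- function(k, spacing, draw) {
  pts <- matrix(numeric(0), ncol = 3)
  budget <- 400L * k
  while (nrow(pts) < k) {
    tries <- 0L
    while (nrow(pts) < k && tries < budget) {
      p <- draw()
      tries <- tries + 1L
      if (is.null(p)) next
      if (nrow(pts) == 0 ||
          min(sqrt(colSums((t(pts) - p)^2))) >= spacing) {
        pts <- rbind(pts, p)
      }
    }
    if (nrow(pts) < k) {
      spacing <- spacing * 0.95
      if (spacing < 1)
        stop("could not place the requested number of tile seeds")
    }
  }
  pts
}

# shell geometry: mask plus 0-based mid-surface description
phantom_shell <- function(s) {
  d <- s$dims
  ax <- seq_len(d[1]) - 1; ay <- seq_len(d[2]) - 1; az <- seq_len(d[3]) - 1
  if (s$mode == "flat") {
    z0 <- (d[3] - s$thickness) %/% 2L
    zsel <- az >= z0 & az <= z0 + s$thickness - 1L
    # the tiled patch is inset in x/y: a real skeletal element is finite, so
    # the outermost tiles border genuine background rather than the grid edge
    m <- min(max(3, ceiling(s$tile_diameter / 3)),
             floor((min(d[1], d[2]) - 2) / 2))
    xsel <- ax >= m & ax <= d[1] - 1 - m
    ysel <- ay >= m & ay <= d[2] - 1 - m
    shell <- array(FALSE, d)
    shell[which(xsel), which(ysel), which(zsel)] <- TRUE
    list(shell = shell, zmid = z0 + (s$thickness - 1) / 2,
         center = NULL, radius = NULL, margin = m)
  } else {
    R <- 0.9 * min(d[1], d[2])
    cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2
    zmid <- (d[3] - 1) / 2
    cz <- zmid - R
    X <- array(rep(ax, times = d[2] * d[3]), d)
    Y <- array(rep(rep(ay, each = d[1]), times = d[3]), d)
    Z <- array(rep(az, each = d[1] * d[2]), d)
    r <- sqrt((X - cx)^2 + (Y - cy)^2 + (Z - cz)^2)
    shell <- r >= R - s$thickness / 2 & r <= R + s$thickness / 2
    list(shell = shell, zmid = zmid, center = c(cx, cy, cz), radius = R)
  }
}

# 6-neighbor label discontinuities: per-axis pairs of full-array linear
# indices and the two labels involved
label_border_pairs <- function(lab) {
  d <- dim(lab)
  idx <- array(seq_along(lab), d)
  out <- list()
  sel <- list(
    list(i1 = list(-d[1], TRUE, TRUE), i2 = list(-1, TRUE, TRUE)),
    list(i1 = list(TRUE, -d[2], TRUE), i2 = list(TRUE, -1, TRUE)),
    list(i1 = list(TRUE, TRUE, -d[3]), i2 = list(TRUE, TRUE, -1))
  )
  for (axis in 1:3) {
    s1 <- sel[[axis]]$i1; s2 <- sel[[axis]]$i2
    A <- do.call(`[`, c(list(lab), s1, list(drop = FALSE)))
    B <- do.call(`[`, c(list(lab), s2, list(drop = FALSE)))
    I1 <- do.call(`[`, c(list(idx), s1, list(drop = FALSE)))
    I2 <- do.call(`[`, c(list(idx), s2, list(drop = FALSE)))
    m <- A > 0 & B > 0 & A != B
    if (any(m))
      out[[axis]] <- data.frame(i1 = I1[m], i2 = I2[m], a = A[m], b = B[m])
  }
  if (length(out) == 0)
    return(data.frame(i1 = integer(0), i2 = integer(0),
                      a = integer(0), b = integer(0)))
  do.call(rbind, out)
}

#' Generate a synthetic tessellated-shell phantom
#'
#' Deterministic for a fixed spec and seed. See [phantom_spec()] for the
#' construction.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [volume_image()]) and `truth`, a
#'   `phantom_truth` list holding `labels` (integer ground-truth label
#'   field; 0 on background and pores), `landmarks` (data.frame with
#'   0-based voxel coordinates `x, y, z` and `label`, one per tile, each
#'   inside its own tile), `neighbors` (two-column matrix of true neighbor
#'   label pairs, a < b), and `pores` (logical pore mask).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  with_phantom_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(s) {
  d <- s$dims
  geo <- phantom_shell(s)
  shell <- geo$shell
  if (!any(shell)) stop("empty shell; check dims/thickness")

  # --- tile seeds on the mid-surface (Poisson-disk, spacing 0.7 * diameter)
  margin <- max(2, s$tile_diameter / 4) +
    (if (is.null(geo$margin)) 0 else geo$margin)
  draw <- if (s$mode == "flat") {
    function() c(stats::runif(1, margin, d[1] - 1 - margin),
                 stats::runif(1, margin, d[2] - 1 - margin), geo$zmid)
  } else {
    function() {
      x <- stats::runif(1, margin, d[1] - 1 - margin)
      y <- stats::runif(1, margin, d[2] - 1 - margin)
      h2 <- geo$radius^2 - (x - geo$center[1])^2 - (y - geo$center[2])^2
      if (h2 <= 0) return(NULL)
      z <- geo$center[3] + sqrt(h2)
      if (z < 1 || z > d[3] - 2) return(NULL)
      c(x, y, z)
    }
  }
  seeds <- poisson_disk(s$k, 0.85 * s$tile_diameter, draw)

  # --- nearest-seed partition of the shell
  shell_idx <- which(shell)
  P <- voxel_coords(shell_idx, d) - 1L # 0-based coords
  best <- rep(Inf, length(shell_idx))
  lab_of <- integer(length(shell_idx))
  for (kk in seq_len(s$k)) {
    d2 <- (P[, 1] - seeds[kk, 1])^2 + (P[, 2] - seeds[kk, 2])^2 +
      (P[, 3] - seeds[kk, 3])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    lab_of[upd] <- kk
  }
  labels <- array(0L, d)
  labels[shell_idx] <- lab_of
  if (length(unique(lab_of)) != s$k)
    stop("degenerate tessellation: a seed captured no voxels")

  # --- borders, neighbor pairs, junction voxels
  bp <- label_border_pairs(labels)
  pair_key <- paste(pmin(bp$a, bp$b), pmax(bp$a, bp$b))
  neighbors <- unique(cbind(a = pmin(bp$a, bp$b), b = pmax(bp$a, bp$b)))
  neighbors <- neighbors[order(neighbors[, 1], neighbors[, 2]), , drop = FALSE]

  # foreign-label contacts per border voxel -> junction detection
  contact <- data.frame(idx = c(bp$i1, bp$i2), lab = c(bp$b, bp$a))
  contact <- unique(contact)
  ncontact <- table(contact$idx)
  junction_idx <- as.integer(names(ncontact)[ncontact >= 2])

  # --- carve pores: keep a central bright run of each pairwise border
  carve <- array(FALSE, d)
  keep <- array(FALSE, d)
  borders <- split(seq_len(nrow(bp)), pair_key)
  for (rows in borders) {
    vox <- unique(c(bp$i1[rows], bp$i2[rows]))
    xyz <- voxel_coords(vox, d) - 1L
    ctr <- colMeans(xyz)
    # distance from the border centroid measured within the shell surface
    # (the thickness direction is ignored), so the kept connection is a
    # full-thickness column of the border, not a mid-surface disc
    rel <- sweep(xyz, 2, ctr)
    if (s$mode == "flat") {
      dc <- sqrt(rel[, 1]^2 + rel[, 2]^2)
    } else {
      rad <- (ctr - geo$center) / sqrt(sum((ctr - geo$center)^2))
      proj <- as.vector(rel %*% rad)
      dc <- sqrt(pmax(0, rowSums(rel^2) - proj^2))
    }
    nkeep <- ceiling(s$connection_fraction * length(vox))
    ord <- order(dc, vox) # deterministic tie-break on voxel index
    keep[vox[ord[seq_len(nkeep)]]] <- TRUE
    carve[vox[ord[-seq_len(nkeep)]]] <- TRUE
  }
  carve[junction_idx] <- TRUE
  keep[junction_idx] <- FALSE
  if (any(carve)) {
    dil <- distance_map_3d(!carve) <= s$pore_radius
    pores <- shell & dil & !keep
  } else {
    pores <- array(FALSE, d)
  }
  fg <- shell & !pores
  # pore carving can slice off tiny disconnected slivers near junctions;
  # real tesserae are contiguous mineralized bodies and isolated crumbs of a
  # few voxels would not survive imaging at this resolution, so anything
  # smaller than one tessera cross-section is re-assigned to pore space
  cc <- label_components(fg, connectivity = 6L)
  if (max(cc) > 1L) {
    csz <- tabulate(cc[cc > 0L], nbins = max(cc))
    floor_vox <- s$thickness * s$tile_diameter
    drop <- which(csz < floor_vox)
    if (length(drop)) {
      crumbs <- array(cc %in% drop, d)
      pores <- pores | crumbs
      fg <- fg & !crumbs
    }
  }
  truth_labels <- labels
  truth_labels[!fg] <- 0L
  if (length(setdiff(seq_len(s$k), unique(as.vector(truth_labels)))) > 0)
    stop("infeasible geometry: pore carving removed an entire tile")

  # --- intra-tile holes (strictly interior, shallower than pores)
  holes <- array(FALSE, d)
  if (s$holes_per_tile > 0) {
    interior <- distance_map_3d(fg) > s$hole_radius + 0.5
    n_holes <- stats::rpois(s$k, s$holes_per_tile)
    ax <- seq_len(d[1]) - 1
    for (kk in seq_len(s$k)) {
      if (n_holes[kk] == 0) next
      elig <- which(interior & truth_labels == kk)
      if (length(elig) == 0) next
      ctrs <- elig[sample.int(length(elig), n_holes[kk], replace = TRUE)]
      cxyz <- voxel_coords(ctrs, d) - 1L
      for (j in seq_len(nrow(cxyz))) {
        rr <- ceiling(s$hole_radius)
        xs <- max(0, cxyz[j, 1] - rr):min(d[1] - 1, cxyz[j, 1] + rr)
        ys <- max(0, cxyz[j, 2] - rr):min(d[2] - 1, cxyz[j, 2] + rr)
        zs <- max(0, cxyz[j, 3] - rr):min(d[3] - 1, cxyz[j, 3] + rr)
        g <- expand.grid(x = xs, y = ys, z = zs)
        inside <- (g$x - cxyz[j, 1])^2 + (g$y - cxyz[j, 2])^2 +
          (g$z - cxyz[j, 3])^2 <= s$hole_radius^2
        gi <- voxel_linear_index(as.matrix(g[inside, ]) + 1L, d)
        holes[gi] <- TRUE
      }
    }
    holes <- holes & fg
  }

  # --- landmarks: tile voxel nearest the tile centroid (always inside)
  lm <- matrix(0L, nrow = s$k, ncol = 3)
  for (kk in seq_len(s$k)) {
    vox <- which(truth_labels == kk)
    xyz <- voxel_coords(vox, d) - 1L
    ctr <- colMeans(xyz)
    j <- which.min((xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 +
                     (xyz[, 3] - ctr[3])^2)
    lm[kk, ] <- xyz[j, ]
  }
  landmarks <- data.frame(x = lm[, 1], y = lm[, 2], z = lm[, 3],
                          label = seq_len(s$k))

  # --- intensity synthesis: means, holes, drift, noise
  vol <- array(s$bg_mean, d)
  vol[fg] <- s$fg_mean
  vol[holes] <- s$fg_mean - s$hole_contrast
  if (s$drift_amplitude > 0) {
    co <- stats::runif(9, -1, 1)
    u <- 2 * (seq_len(d[1]) - 1) / max(1, d[1] - 1) - 1
    v <- 2 * (seq_len(d[2]) - 1) / max(1, d[2] - 1) - 1
    w <- 2 * (seq_len(d[3]) - 1) / max(1, d[3] - 1) - 1
    U <- array(rep(u, times = d[2] * d[3]), d)
    V <- array(rep(rep(v, each = d[1]), times = d[3]), d)
    W <- array(rep(w, each = d[1] * d[2]), d)
    g <- co[1] * U + co[2] * V + co[3] * W + co[4] * U * V +
      co[5] * U * W + co[6] * V * W + co[7] * U^2 + co[8] * V^2 + co[9] * W^2
    g <- g / max(abs(g))
    vol <- vol + s$drift_amplitude * s$fg_mean * g
  }
  if (s$noise_sd > 0)
    vol <- vol + array(stats::rnorm(prod(d), 0, s$noise_sd), d)

  truth <- structure(list(labels = truth_labels, landmarks = landmarks,
                          neighbors = neighbors, pores = pores,
                          seeds = seeds),
                     class = "phantom_truth")
  list(volume = volume_image(vol, s$voxel_size_um), truth = truth,
       spec = s)
}

#' Piecewise-linear 1D profile interleaving minima and saddles
#'
#' Builds the 1D landscape `m1, s1, m2, s2, ..., mk` used as a hand-checkable
#' fixture for watershed persistence semantics.
#'
#' @param minima_values basin minimum values (length k >= 1).
#' @param saddle_values saddle values (length k - 1); each saddle must be at
#'   least as high as both flanking minima.
#' @return numeric vector of length `2k - 1`.
#' @export
generate_profile_1d <- function(minima_values, saddle_values) {
  k <- length(minima_values)
  if (k < 1) stop("need at least one minimum")
  if (length(saddle_values) != k - 1)
    stop("need exactly length(minima) - 1 saddles")
  for (i in seq_along(saddle_values)) {
    if (saddle_values[i] < minima_values[i] ||
        saddle_values[i] < minima_values[i + 1])
      stop("each saddle must be >= its flanking minima")
  }
  out <- numeric(2 * k - 1)
  out[seq(1, 2 * k - 1, by = 2)] <- minima_values
  if (k > 1) out[seq(2, 2 * k - 2, by = 2)] <- saddle_values
  out
}
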