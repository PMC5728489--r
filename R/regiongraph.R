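#' Build the region adjacency graph of a label field
#'
#' One vertex per positive label, placed at the label's voxel centroid; one
#' undirected edge per pair of labels sharing at least one voxel face
#' (6-adjacency), weighted by the number of contact faces. The tile network
#' is usually highly regular, so irregularities in this graph (odd degree,
#' odd edge lengths) point at segmentation errors.
#'
#' @param labels integer 3D label field (0 = background).
#' @return a `region_graph`: `vertices` data.frame (`label`, centroid
#'   `cx, cy, cz` in 0-based voxel coordinates, `volume`) and `edges`
#'   data.frame (`a`, `b`, `contact_faces`) with `a < b`.
#' @export
build_region_graph <- function(labels) {
  check_mask(labels, "labels")
  idx <- which(labels > 0)
  if (length(idx) == 0) stop("label field has no positive labels")
  lab <- as.integer(labels[idx])
  xyz <- voxel_coords(idx, dim(labels)) - 1L
  ids <- sort(unique(lab))
  cnt <- as.vector(table(factor(lab, levels = ids)))
  ctr <- rowsum(xyz + 0.0, group = factor(lab, levels = ids)) / cnt
  vertices <- data.frame(label = ids, cx = ctr[, 1], cy = ctr[, 2],
                         cz = ctr[, 3], volume = cnt)
  bp <- label_border_pairs(array(as.integer(labels), dim(labels)))
  if (nrow(bp) > 0) {
    key <- paste(pmin(bp$a, bp$b), pmax(bp$a, bp$b))
    tab <- table(key)
    ab <- do.call(rbind, strsplit(names(tab), " "))
    edges <- data.frame(a = as.integer(ab[, 1]), b = as.integer(ab[, 2]),
                        contact_faces = as.integer(tab))
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(a = integer(0), b = integer(0),
                        contact_faces = integer(0))
  }
  structure(list(vertices = vertices, edges = edges, dims = dim(labels)),
            class = "region_graph")
}

#' @export
print.region_graph <- function(x, ...) {
  cat(sprintf("<region_graph> %d vertices, %d edges\n",
              nrow(x$vertices), nrow(x$edges)))
  invisible(x)
}

# extent (max - min + 1) of coordinates projected on principal axes,
# ordered by decreasing variance
principal_extents <- function(xyz) {
  if (nrow(xyz) == 1) return(c(1, 1, 1))
  cv <- stats::cov(xyz)
  e <- eigen(cv, symmetric = TRUE)
  proj <- xyz %*% e$vectors
  apply(proj, 2, function(p) max(p) - min(p) + 1)
}

#' Per-label shape and network statistics
#'
#' For each label: voxel `volume`; `n_neighbors` (graph degree);
#' `nearest_vertex_dist`, the distance to the closest other vertex centroid
#' (NA when the field has a single label); `width`, the largest extent along
#' the two in-layer principal axes of the label's voxels; `height`, the
#' extent along the least-scatter axis; and a `curvature` proxy, the RMS
#' deviation of the vertex's graph neighborhood (own + neighbor centroids)
#' from its best-fit plane, normalized by the mean neighbor distance (NA
#' with fewer than 2 neighbors).
#'
#' @param labels integer 3D label field.
#' @param graph the matching [build_region_graph()] result.
#' @return data.frame with one row per label.
#' @export
compute_stats <- function(labels, graph) {
  stopifnot(inherits(graph, "region_graph"))
  v <- graph$vertices
  L <- nrow(v)
  deg <- integer(L)
  if (nrow(graph$edges) > 0) {
    tb <- table(factor(c(graph$edges$a, graph$edges$b), levels = v$label))
    deg <- as.integer(tb)
  }
  ctr <- as.matrix(v[, c("cx", "cy", "cz")])
  nearest <- rep(NA_real_, L)
  if (L > 1) {
    dd <- as.matrix(stats::dist(ctr))
    diag(dd) <- Inf
    nearest <- apply(dd, 1, min)
  }
  width <- height <- numeric(L)
  for (i in seq_len(L)) {
    xyz <- voxel_coords(which(labels == v$label[i]), dim(labels)) - 1L
    ext <- principal_extents(xyz + 0.0)
    width[i] <- max(ext[1], ext[2])
    height[i] <- ext[3]
  }
  curv <- rep(NA_real_, L)
  adj <- lapply(seq_len(L), function(i) {
    lb <- v$label[i]
    nb <- c(graph$edges$b[graph$edges$a == lb],
            graph$edges$a[graph$edges$b == lb])
    match(nb, v$label)
  })
  for (i in seq_len(L)) {
    nb <- adj[[i]]
    if (length(nb) < 2) next
    pts <- rbind(ctr[i, , drop = FALSE], ctr[nb, , drop = FALSE])
    pc <- sweep(pts, 2, colMeans(pts))
    e <- eigen(crossprod(pc), symmetric = TRUE)
    nrm <- e$vectors[, 3]
    resid <- pc %*% nrm
    scale <- mean(sqrt(rowSums((ctr[nb, , drop = FALSE] -
                                  matrix(ctr[i, ], length(nb), 3,
                                         byrow = TRUE))^2)))
    curv[i] <- sqrt(mean(resid^2)) / scale
  }
  data.frame(label = v$label, volume = v$volume, n_neighbors = deg,
             nearest_vertex_dist = nearest, width = width, height = height,
             curvature = curv)
}

#' Flag labels with unusual statistics
#'
#' Robust z-scores (median / MAD) per statistic; labels with |z| above
#' `z_cut` on any statistic are listed with the offending statistic.
#' Advisory only: nothing is corrected automatically.
#'
#' @param stats data.frame from [compute_stats()] (>= 5 labels).
#' @param z_cut robust z-score cutoff (default 3).
#' @return data.frame (`label`, `statistic`, `value`, `z`), empty when
#'   nothing is unusual.
#' @export
flag_outliers <- function(stats, z_cut = 3) {
  if (nrow(stats) < 5) stop("need at least 5 labels to flag outliers")
  cols <- setdiff(names(stats), "label")
  out <- list()
  for (cn in cols) {
    x <- stats[[cn]]
    ok <- !is.na(x)
    if (sum(ok) < 5) next
    med <- stats::median(x[ok])
    md <- stats::mad(x[ok])
    z <- rep(NA_real_, length(x))
    if (md == 0) {
      z[ok] <- ifelse(x[ok] == med, 0, Inf * sign(x[ok] - med))
    } else {
      z[ok] <- (x[ok] - med) / md
    }
    hit <- ok & abs(z) > z_cut
    if (any(hit))
      out[[cn]] <- data.frame(label = stats$label[hit], statistic = cn,
                              value = x[hit], z = z[hit])
  }
  if (length(out) == 0)
    return(data.frame(label = integer(0), statistic = character(0),
                      value = numeric(0), z = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$label), , drop = FALSE]
}

# ---- edit journal ----------------------------------------------------------

journal_of <- function(labels) {
  j <- attr(labels, "journal")
  if (is.null(j)) list() else j
}

append_journal <- function(labels, entry) {
  j <- c(journal_of(labels), list(entry))
  attr(labels, "journal") <- j
  labels
}

#' Edit journal of a label field
#'
#' Every proofreading edit appends an entry to a journal carried on the
#' label field, sufficient to replay the session from the watershed output
#' with [replay_journal()].
#'
#' @param labels an edited label field.
#' @return list of edit records.
#' @export
edit_journal <- function(labels) journal_of(labels)

#' Replay an edit journal
#'
#' @param labels the starting (unedited) label field.
#' @param journal a journal from [edit_journal()].
#' @param dist distance map, needed when the journal contains watershed
#'   splits.
#' @return the re-edited label field.
#' @export
replay_journal <- function(labels, journal, dist = NULL) {
  for (e in journal) {
    labels <- switch(e$op,
      merge = merge_labels(labels, e$ids),
      split_watershed = split_label_watershed(labels, dist, e$id, e$t_p),
      split_spectral = split_label_spectral(labels, e$id, e$k, e$cap),
      stop("unknown journal op: ", e$op))
  }
  labels
}

#' Merge labels (oversegmentation fix)
#'
#' All `ids` are replaced by the smallest id; voxel membership in the
#' foreground never changes.
#'
#' @param labels integer 3D label field.
#' @param ids labels to merge (all must be present).
#' @return edited label field (journal updated).
#' @export
merge_labels <- function(labels, ids) {
  ids <- unique(as.integer(ids))
  if (length(ids) == 0) stop("ids must be nonempty")
  present <- unique(as.vector(labels[labels > 0]))
  if (!all(ids %in% present))
    stop("unknown label id(s): ", paste(setdiff(ids, present), collapse = ", "))
  target <- min(ids)
  j <- journal_of(labels)
  out <- labels
  out[out %in% ids] <- target
  attr(out, "journal") <- NULL
  out <- append_journal(out, list(op = "merge", ids = ids))
  attr(out, "journal") <- c(j, attr(out, "journal"))
  out
}

#' Watershed-based split of one label (undersegmentation fix)
#'
#' Runs the hierarchical watershed restricted to the selected region's
#' voxels (all other labels are untouched) at a local persistence threshold;
#' the resulting parts get fresh ids. If the region does not split, the
#' field is returned unchanged with a notice.
#'
#' @param labels integer 3D label field.
#' @param dist distance map defined on the region's voxels.
#' @param id label to split.
#' @param t_p_local local persistence threshold.
#' @param t_v_local local minimum region size (default 0).
#' @return edited label field (journal updated).
#' @export
split_label_watershed <- function(labels, dist, id, t_p_local,
                                  t_v_local = 0) {
  id <- as.integer(id)
  region <- labels == id
  if (!any(region)) stop("unknown label id: ", id)
  dl <- array(0, dim(labels))
  dl[region] <- dist[region]
  h <- build_hierarchy(dl, region)
  parts <- extract_segmentation(h, t_p_local, t_v_local)
  np <- max(parts)
  if (np <= 1) {
    message("split_label_watershed: region ", id, " did not split; unchanged")
    return(labels)
  }
  out <- labels
  fresh <- max(labels) + seq_len(np)
  out[region] <- fresh[parts[region]]
  attr(out, "journal") <- journal_of(labels)
  append_journal(out, list(op = "split_watershed", id = id, t_p = t_p_local))
}

# deterministic farthest-first starting centers for k-means
farthest_first_centers <- function(X, k) {
  n <- nrow(X)
  ctr <- colMeans(X)
  d0 <- rowSums(sweep(X, 2, ctr)^2)
  chosen <- which.max(d0)
  while (length(chosen) < k) {
    dmin <- rep(Inf, n)
    for (c in chosen) {
      dc <- rowSums(sweep(X, 2, X[c, ])^2)
      dmin <- pmin(dmin, dc)
    }
    dmin[chosen] <- -Inf
    chosen <- c(chosen, which.max(dmin))
  }
  X[chosen, , drop = FALSE]
}

#' Spectral-clustering split of one label
#'
#' Builds the 6-adjacency voxel graph of the region with unit weights,
#' embeds the voxels with the first k eigenvectors of the symmetric
#' normalized graph Laplacian, clusters them into k parts with k-means
#' (deterministic farthest-first initialization), and reassigns stray
#' (disconnected) fragments to the neighboring part with the largest face
#' contact so every part ends up 26-connected.
#'
#' @param labels integer 3D label field.
#' @param id label to split.
#' @param k number of parts (>= 2).
#' @param cap maximum region size in voxels for the dense eigensolver;
#'   larger regions are rejected with advice to use the watershed split.
#' @return edited label field (journal updated).
#' @export
split_label_spectral <- function(labels, id, k, cap = 1500L) {
  id <- as.integer(id)
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  vox <- which(labels == id)
  n <- length(vox)
  if (n == 0) stop("unknown label id: ", id)
  if (n > cap)
    stop("region has ", n, " voxels (> cap ", cap,
         "); use split_label_watershed for large regions")
  if (n <= k) stop("region too small to split into ", k, " parts")

  d <- dim(labels)
  region <- array(FALSE, d)
  region[vox] <- TRUE
  pos <- integer(prod(d))
  pos[vox] <- seq_len(n)

  # 6-adjacency edge list within the region
  xyz <- voxel_coords(vox, d)
  edges <- list()
  for (axis in 1:3) {
    nb <- xyz
    nb[, axis] <- nb[, axis] + 1L
    ok <- nb[, axis] <= d[axis]
    j <- voxel_linear_index(nb[ok, , drop = FALSE], d)
    inr <- region[j]
    edges[[axis]] <- cbind(pos[vox[ok][inr]], pos[j[inr]])
  }
  E <- do.call(rbind, edges)

  A <- matrix(0, n, n)
  if (nrow(E) > 0) {
    A[E] <- 1
    A[E[, c(2, 1), drop = FALSE]] <- 1
  }
  deg <- rowSums(A)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Lsym <- diag(n) - (dinv * A) * rep(dinv, each = n)
  eg <- eigen(Lsym, symmetric = TRUE)
  X <- eg$vectors[, seq(n, n - k + 1), drop = FALSE] # k smallest eigenvalues
  rn <- sqrt(rowSums(X^2))
  X <- X / ifelse(rn > 0, rn, 1)
  km <- stats::kmeans(X, centers = farthest_first_centers(X, k),
                      iter.max = 100)
  part <- km$cluster

  # cleanup: make every part 26-connected by reassigning stray fragments
  for (pass in seq_len(10)) {
    changed <- FALSE
    for (p in sort(unique(part))) {
      pm <- array(FALSE, d)
      pm[vox[part == p]] <- TRUE
      cc <- label_components(pm, 26)
      ncc <- max(cc)
      if (ncc <= 1) next
      sizes <- tabulate(cc[cc > 0], ncc)
      main <- which.max(sizes)
      for (s in seq_len(ncc)) {
        if (s == main) next
        sv <- which(cc == s)
        # face-contact counts with other parts
        contact <- integer(0)
        sxyz <- voxel_coords(sv, d)
        for (axis in 1:3) for (dir in c(-1L, 1L)) {
          nb <- sxyz
          nb[, axis] <- nb[, axis] + dir
          ok <- nb[, axis] >= 1L & nb[, axis] <= d[axis]
          j <- voxel_linear_index(nb[ok, , drop = FALSE], d)
          j <- j[region[j]]
          contact <- c(contact, part[pos[j]])
        }
        contact <- contact[contact != p]
        if (length(contact) == 0) next
        tb <- table(contact)
        part[pos[sv]] <- as.integer(names(tb)[which.max(tb)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  parts_present <- sort(unique(part))
  if (length(parts_present) <= 1) {
    message("split_label_spectral: region ", id, " did not split; unchanged")
    return(labels)
  }
  out <- labels
  fresh <- max(labels) + seq_along(parts_present)
  out[vox] <- fresh[match(part, parts_present)]
  attr(out, "journal") <- journal_of(labels)
  append_journal(out, list(op = "split_spectral", id = id, k = k, cap = cap))
}

#' Merge several labels, then split the result
#'
#' The standard fix for a badly shaped boundary (e.g. a missing pore): merge
#' the affected labels into one and re-split with the chosen method.
#'
#' @param labels integer 3D label field.
#' @param dist distance map (needed for `method = "watershed"`).
#' @param ids labels to merge.
#' @param method `"watershed"` or `"spectral"`.
#' @param param local persistence threshold (watershed) or part count k
#'   (spectral).
#' @return edited label field (journal updated).
#' @export
merge_then_split <- function(labels, dist = NULL, ids,
                             method = c("watershed", "spectral"), param) {
  method <- match.arg(method)
  merged <- merge_labels(labels, ids)
  target <- min(as.integer(ids))
  if (method == "watershed") {
    split_label_watershed(merged, dist, target, param)
  } else {
    split_label_spectral(merged, target, param)
  }
}
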