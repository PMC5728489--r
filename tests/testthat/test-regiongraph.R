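# two 4x4x2 blocks sharing a face, plus one isolated block
toy_labels <- function() {
  lab <- array(0L, c(12, 6, 4))
  lab[2:5, 2:5, 2:3] <- 1L
  lab[6:9, 2:5, 2:3] <- 2L
  lab[11:12, 2:3, 2:3] <- 3L
  lab
}

test_that("build_region_graph: vertices at centroids, face-contact edges", {
  lab <- toy_labels()
  g <- build_region_graph(lab)
  expect_s3_class(g, "region_graph")
  expect_equal(g$vertices$label, c(1L, 2L, 3L))
  expect_equal(g$vertices$volume, c(32L, 32L, 8L))
  # 0-based centroid of block 1: x in 1..4 -> 2.5
  expect_equal(g$vertices$cx[1], 2.5)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$a, 1L)
  expect_equal(g$edges$b, 2L)
  expect_equal(g$edges$contact_faces, 4L * 2L) # 4x2 shared face
  expect_output(print(g), "3 vertices, 1 edges")
  expect_error(build_region_graph(array(0L, c(2, 2, 2))), "no positive")
})

test_that("compute_stats reports degree, extents and neighbor distances", {
  lab <- toy_labels()
  g <- build_region_graph(lab)
  st <- compute_stats(lab, g)
  expect_equal(st$n_neighbors, c(1L, 1L, 0L))
  expect_equal(st$volume, c(32L, 32L, 8L))
  # width/height from principal extents: blocks are 4x4x2
  expect_equal(st$width[1], 4)
  expect_equal(st$height[1], 2)
  # nearest vertex distance: centroids of blocks 1 and 2 are 4 apart in x
  expect_equal(st$nearest_vertex_dist[1], 4)
  # curvature needs >= 2 neighbors
  expect_true(all(is.na(st$curvature)))
})

test_that("flag_outliers uses robust z-scores and handles MAD = 0", {
  st <- data.frame(label = 1:6, volume = c(10, 10, 10, 10, 10, 500))
  fl <- flag_outliers(st, z_cut = 3)
  expect_equal(fl$label, 6L)
  expect_equal(fl$statistic, "volume")
  expect_true(is.infinite(fl$z))
  # nothing unusual -> empty frame
  st2 <- data.frame(label = 1:6, volume = c(10, 11, 12, 11, 10, 11))
  expect_equal(nrow(flag_outliers(st2, 5)), 0)
  expect_error(flag_outliers(st[1:3, ]), "at least 5")
})

test_that("merge preserves voxels and journals the edit", {
  lab <- toy_labels()
  m <- merge_labels(lab, c(1L, 2L))
  expect_identical(m > 0, lab > 0)
  expect_equal(sort(unique(as.vector(m[m > 0]))), c(1L, 3L))
  expect_equal(sum(m == 1L), 64)
  j <- edit_journal(m)
  expect_length(j, 1)
  expect_equal(j[[1]]$op, "merge")
  expect_error(merge_labels(lab, 9L), "unknown label")
})

test_that("watershed split honours the region boundary and relabels densely", {
  # one label with two deep centers connected by a shallow neck
  lab <- array(0L, c(11, 5, 3))
  lab[2:10, 2:4, 2] <- 1L
  dist <- array(0, dim(lab))
  dist[2:10, 3, 2] <- c(5, 4, 3, 2, 1, 2, 3, 4, 5)
  dist[2:10, 2, 2] <- dist[2:10, 3, 2] / 2
  dist[2:10, 4, 2] <- dist[2:10, 3, 2] / 2
  s <- split_label_watershed(lab, dist, 1L, t_p_local = 2)
  expect_identical(s > 0, lab > 0)
  parts <- sort(unique(as.vector(s[s > 0])))
  expect_length(parts, 2)
  expect_true(all(parts > 1L)) # fresh ids
  j <- edit_journal(s)
  expect_equal(j[[1]]$op, "split_watershed")
  # a region that does not split is returned unchanged, with a message
  dist2 <- array(0, dim(lab)); dist2[lab == 1L] <- 1
  expect_message(u <- split_label_watershed(lab, dist2, 1L, 0),
                 "did not split")
  expect_identical(u, lab)
})

test_that("spectral split recovers blocks and conserves the voxel set", {
  lab <- array(0L, c(17, 6, 3))
  lab[2:16, 2:5, 2] <- 1L
  s <- split_label_spectral(lab, 1L, k = 3L)
  expect_identical(s > 0, lab > 0)
  parts <- table(s[s > 0])
  expect_length(parts, 3)
  # balanced-ish parts of a 15x4 strip
  expect_true(all(parts >= 12))
  expect_error(split_label_spectral(lab, 1L, k = 1L), "k must be")
  expect_error(split_label_spectral(lab, 9L, k = 2L), "unknown label")
  expect_error(split_label_spectral(lab, 1L, k = 2L, cap = 10L), "cap")
})

test_that("journal replays reproduce the edited field", {
  lab <- toy_labels()
  e1 <- merge_labels(lab, c(1L, 2L))
  e2 <- split_label_spectral(e1, 1L, k = 2L)
  replayed <- replay_journal(lab, edit_journal(e2))
  expect_identical(array(replayed, dim(replayed)), array(e2, dim(e2)))
  expect_length(edit_journal(e2), 2)
})

test_that("merge_then_split fixes a missing-pore defect (3 tiles)", {
  # three tiles in a row; the pore between tiles 2 and 3 is missing, so the
  # watershed saw them as one region (label 2)
  lab <- array(0L, c(30, 10, 4))
  lab[2:9, 2:9, 2:3] <- 1L
  lab[11:29, 2:9, 2:3] <- 2L
  s <- merge_then_split(lab, ids = c(1L, 2L), method = "spectral", param = 3)
  expect_identical(s > 0, lab > 0)
  expect_equal(length(unique(as.vector(s[s > 0]))), 3)
})
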