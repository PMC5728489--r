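profile_volume <- function(values) {
  dist <- array(0, c(length(values), 1, 1))
  dist[, 1, 1] <- values
  list(dist = dist, mask = array(TRUE, c(length(values), 1, 1)))
}

test_that("the 1D toy [-5,-1,-4] splits at T_p = 3 and merges at T_p = 4", {
  # flooded profile [-5, -1, -4]: basins with minima -5 and -4 and a saddle
  # at -1; persistence = -1 - (-4) = 3. build_hierarchy floods the negated
  # distance, so the distance profile is the negated flooded profile.
  pv <- profile_volume(-generate_profile_1d(c(-5, -4), c(-1)))
  h <- build_hierarchy(pv$dist, pv$mask)
  expect_equal(length(h$basin_min), 2)
  expect_equal(nrow(h$events), 1)
  expect_equal(h$events$saddle, -1)
  s3 <- extract_segmentation(h, 3, 0)
  expect_equal(max(s3), 2) # still split (strict <)
  s4 <- extract_segmentation(h, 4, 0)
  expect_equal(max(s4), 1) # merged
})

test_that("base extraction equals one label per minimum plateau", {
  set.seed(8)
  for (rep in 1:4) {
    d <- c(9, 8, 5)
    mask <- array(runif(prod(d)) > 0.25, d)
    if (!any(mask)) next
    vals <- array(sample(0:6, prod(d), replace = TRUE), d)
    vals[!mask] <- 0
    h <- build_hierarchy(vals, mask)
    seg <- extract_segmentation(h, 0, 0)
    expect_equal(max(seg), count_minima_plateaus(-vals, mask))
    # labels are dense and confined to the mask
    expect_setequal(unique(as.vector(seg[mask])), seq_len(max(seg)))
    expect_true(all(seg[!mask] == 0))
  }
})

test_that("label count is monotone non-increasing over a 0-80 sweep", {
  fr <- small_pipeline_front()
  d2 <- distance_map_2d(fr$mask)
  h <- build_hierarchy(d2, fr$mask)
  curve <- persistence_curve(h, 0:80, 0)
  expect_true(all(diff(curve$n_labels) <= 0))
  expect_equal(curve$n_labels[1], max(extract_segmentation(h, 0, 0)))
  # with T_v too: still monotone
  curve_v <- persistence_curve(h, 0:80, 50)
  expect_true(all(diff(curve_v$n_labels) <= 0))
})

test_that("merging keeps the deeper minimum (chain of three basins)", {
  # distance profile with basin centers 9, 6, 4 and connections 5, 3:
  # flooded minima -9, -6, -4 with saddles -5, -3
  vals <- -generate_profile_1d(c(-9, -6, -4), c(-5, -3))
  pv <- profile_volume(vals)
  h <- build_hierarchy(pv$dist, pv$mask)
  expect_equal(length(h$basin_min), 3)
  # persistences: basin(6): saddle -5 - (-6) = 1; basin(4): -3 - (-4) = 1
  s <- extract_segmentation(h, 1.5, 0)
  expect_equal(max(s), 1)
  s2 <- extract_segmentation(h, 1.0, 0)
  expect_equal(max(s2), 3) # strict <: persistence 1 survives at t_p = 1
})

test_that("T_v merges small regions regardless of persistence", {
  # two deep basins, one tiny (3 voxels), one large
  vals <- c(9, 9, 9, 9, 9, 1, 8, 8)
  pv <- profile_volume(vals)
  h <- build_hierarchy(pv$dist, pv$mask)
  expect_equal(max(extract_segmentation(h, 0, 0)), 2)
  expect_equal(max(extract_segmentation(h, 0, 4)), 1)
})

test_that("build_hierarchy validates its inputs", {
  m <- array(TRUE, c(3, 1, 1))
  expect_error(build_hierarchy(array(0, c(4, 1, 1)), m), "dimensions")
  expect_error(build_hierarchy(array(0, c(3, 1, 1)), array(FALSE, c(3, 1, 1))),
               "empty mask")
  dist <- array(1, c(3, 1, 1))
  mask <- array(c(TRUE, TRUE, FALSE), c(3, 1, 1))
  expect_error(build_hierarchy(dist, mask), "zero exactly off")
  expect_error(extract_segmentation(build_hierarchy(dist * c(1, 1, 0), mask),
                                    -1, 0), ">= 0")
})

test_that("suggest_persistence finds the knee of the worked example", {
  curve <- data.frame(t_p = 0:5, n_labels = c(100, 40, 12, 11, 11, 10))
  expect_equal(suggest_persistence(curve), 2)
  expect_error(suggest_persistence(curve[1:3, ]), "at least 5")
  expect_error(suggest_persistence(data.frame(t_p = 0:5,
                                              n_labels = c(1, 2, 3, 4, 5, 6))),
               "non-increasing")
  expect_warning(
    flat <- suggest_persistence(data.frame(t_p = 0:5, n_labels = rep(7, 6))),
    "flat")
  expect_equal(flat, 0)
})

test_that("generate_profile_1d validates saddle/minima interleaving", {
  expect_equal(generate_profile_1d(c(-5, -4), c(-1)), c(-5, -1, -4))
  expect_equal(generate_profile_1d(-3, numeric(0)), -3)
  expect_equal(generate_profile_1d(c(-9, -2, -7), c(-1, -1)),
               c(-9, -1, -2, -1, -7))
  expect_error(generate_profile_1d(c(-5, -4), c(-6)), "saddle")
  expect_error(generate_profile_1d(c(-5, -4), numeric(0)), "saddles")
})
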