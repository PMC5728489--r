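test_that("landmark counting rules: hit, multi-hit, zero-hit, unassigned", {
  lab <- array(0L, c(10, 4, 1))
  lab[1:3, , 1] <- 1L
  lab[4:6, , 1] <- 2L
  lab[7:9, , 1] <- 3L
  # one landmark in label 1, two in label 2, none in label 3, one background
  lm <- data.frame(x = c(1, 3, 5, 9), y = c(1, 1, 2, 3), z = c(0, 0, 0, 0))
  pr <- landmark_pr(lab, lm)
  expect_equal(pr$tp, 2) # labels 1 and 2 are hit
  expect_equal(pr$fn, 1) # label 2 holds 2 landmarks -> 1 fn
  expect_equal(pr$fp, 1) # label 3 unhit
  expect_equal(pr$precision, 2 / 3)
  expect_equal(pr$recall, 2 / 3)
  expect_equal(pr$zero_hit_labels, 3)
  expect_equal(pr$multi_hit_labels, 2)
  expect_equal(pr$unassigned, 4L)
  expect_output(print(pr), "precision")
})

test_that("landmarks use nearest-voxel rounding and must stay in bounds", {
  lab <- array(1L, c(4, 4, 4))
  lab[3:4, , ] <- 2L
  # x = 1.4 rounds to voxel 1 (label 1), x = 1.6 rounds to voxel 2 (label 2)
  pr <- landmark_pr(lab, data.frame(x = c(1.4, 1.6), y = 0, z = 0))
  expect_equal(pr$hits, c(1L, 1L))
  expect_error(landmark_pr(lab, data.frame(x = 4.6, y = 0, z = 0)),
               "outside")
  expect_error(landmark_pr(array(0L, c(2, 2, 2)),
                           data.frame(x = 0, y = 0, z = 0)),
               "no positive labels")
})

test_that("RAND and VI identities on identical partitions", {
  set.seed(9)
  a <- array(sample(1:4, 5^3, replace = TRUE), c(5, 5, 5))
  roi <- array(TRUE, c(5, 5, 5))
  expect_equal(rand_index(a, a, roi), 100)
  expect_equal(variation_of_information(a, a, roi)$vi, 0, tolerance = 1e-12)
})

test_that("contingency fast paths equal brute-force pair enumeration", {
  set.seed(10)
  d <- c(7, 7, 7) # 343 voxels -> 58653 pairs
  a <- array(sample(1:3, prod(d), replace = TRUE), d)
  b <- array(sample(1:4, prod(d), replace = TRUE), d)
  roi <- array(TRUE, d)
  av <- as.vector(a); bv <- as.vector(b)
  n <- length(av)
  same_a <- outer(av, av, "==")[upper.tri(diag(n))]
  same_b <- outer(bv, bv, "==")[upper.tri(diag(n))]
  rand_bf <- 100 * mean(same_a == same_b)
  expect_equal(rand_index(a, b, roi), rand_bf, tolerance = 1e-12)
  # VI from entropies computed directly
  H <- function(x) { p <- table(x) / length(x); -sum(p * log(p)) }
  MI <- function(x, y) {
    p <- table(x, y) / length(x)
    px <- rowSums(p); py <- colSums(p)
    s <- 0
    for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
      if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    s
  }
  vi_bf <- unname(H(av) + H(bv) - 2 * MI(av, bv))
  v <- variation_of_information(a, b, roi)
  expect_equal(v$vi, vi_bf, tolerance = 1e-12)
  expect_equal(sum(v$contributions$contribution), v$vi, tolerance = 1e-12)
})

test_that("the 4-voxel crossed partition gives VI = 2 ln 2", {
  a <- array(c(1L, 1L, 2L, 2L), c(4, 1, 1))
  b <- array(c(1L, 2L, 1L, 2L), c(4, 1, 1))
  roi <- array(TRUE, c(4, 1, 1))
  expect_equal(variation_of_information(a, b, roi)$vi, 2 * log(2),
               tolerance = 1e-12)
  expect_equal(variation_of_information(a, b, roi, units = "bits")$vi, 2,
               tolerance = 1e-12)
})

test_that("VI is symmetric and satisfies the triangle inequality", {
  set.seed(11)
  d <- c(6, 6, 6)
  roi <- array(TRUE, d)
  for (rep in 1:5) {
    a <- array(sample(1:3, prod(d), TRUE), d)
    b <- array(sample(1:3, prod(d), TRUE), d)
    c_ <- array(sample(1:3, prod(d), TRUE), d)
    vab <- variation_of_information(a, b, roi)$vi
    vba <- variation_of_information(b, a, roi)$vi
    vac <- variation_of_information(a, c_, roi)$vi
    vcb <- variation_of_information(c_, b, roi)$vi
    expect_equal(vab, vba, tolerance = 1e-12)
    expect_lte(vab, vac + vcb + 1e-12)
  }
})

test_that("ROI checks reject unlabeled voxels and dimension mismatches", {
  a <- array(1L, c(3, 3, 3))
  b <- array(1L, c(3, 3, 3))
  b[1, 1, 1] <- 0L
  roi <- array(TRUE, c(3, 3, 3))
  expect_error(rand_index(a, b, roi), "positive-label")
  expect_error(rand_index(a, b, array(TRUE, c(2, 3, 3))), "dimensions")
  roi1 <- array(FALSE, c(3, 3, 3)); roi1[2, 2, 2] <- TRUE
  expect_error(variation_of_information(a, a, roi1), "at least 2")
})

test_that("compare_2d_vs_3d returns both variants over the sweep", {
  ph <- small_phantom()
  res <- compare_2d_vs_3d(ph$volume, ph$truth$landmarks,
                          diffusion_params(100),
                          threshold_params(9, 1, 80, 4),
                          t_p_values = c(0, 1, 2), t_v = 50)
  expect_setequal(unique(res$variant), c("2d", "3d"))
  expect_equal(nrow(res), 6)
  expect_true(all(res$precision >= 0 & res$precision <= 1, na.rm = TRUE))
  expect_true(all(diff(res$n_labels[res$variant == "2d"]) <= 0))
})
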