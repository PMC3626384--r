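test_that("VLV follows the pixel-count times voxel-volume arithmetic", {
  m <- matrix(0L, 40, 40)
  m[1:25, 1:40] <- 1L  # 1000 pixels
  vlv <- compute_vlv(mask_stack(m, in_plane_mm = 1.8, slice_thickness_mm = 13))
  expect_equal(vlv$per_slice_ml, 1000 * 42.12 / 1000)
  expect_equal(vlv$total_l, 42.12 / 1000)
  expect_equal(compute_vlv(mask_stack(matrix(0L, 10, 10)))$total_l, 0)

  two <- mask_stack(list(m, m))
  expect_equal(compute_vlv(two)$total_l, sum(compute_vlv(two)$per_slice_ml) / 1000)
})

test_that("Dice coefficient matches its set definition and symmetries", {
  a <- mask_stack(matrix(as.integer(runif(400) < 0.5), 20, 20))
  expect_equal(dice_coefficient(a, a), 1)

  left <- matrix(0L, 20, 20); left[, 1:10] <- 1L
  right <- matrix(0L, 20, 20); right[, 11:20] <- 1L
  expect_equal(dice_coefficient(mask_stack(left), mask_stack(right)), 0)

  # |A| = |B| = 100, overlap 96
  A <- matrix(0L, 20, 20); A[1:10, 1:10] <- 1L
  B <- A
  B[1:4, 1] <- 0L
  B[1:4, 11] <- 1L
  expect_equal(dice_coefficient(mask_stack(A), mask_stack(B)), 0.96)
  expect_equal(dice_coefficient(mask_stack(B), mask_stack(A)), 0.96)

  # subset relation: Dice = 2|A| / (|A| + |B|)
  sub <- A; sub[1:10, 1:3] <- 0L
  expect_equal(dice_coefficient(mask_stack(sub), mask_stack(A)),
               2 * sum(sub) / (sum(sub) + sum(A)))

  empty <- mask_stack(matrix(0L, 20, 20))
  expect_message(d <- dice_coefficient(empty, empty), "Dice defined as 1")
  expect_equal(d, 1)
  expect_error(dice_coefficient(a, mask_stack(matrix(0L, 10, 10))),
               "geometries differ")
})

test_that("Bland-Altman limits follow the mean +/- 1.96 SD closed form", {
  expect_equal(bland_altman(c(1, 2, 3), c(1, 2, 3)),
               list(mean_diff = 0, sd_diff = 0, loa_low = 0, loa_high = 0, n = 3))
  ba <- bland_altman(c(1, 0), c(0, 1))  # differences +1, -1
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(c(ba$loa_low, ba$loa_high), c(-1.96, 1.96) * sqrt(2))
  ba2 <- bland_altman(c(5, 6, 7) + 2, c(5, 6, 7))
  expect_equal(ba2$mean_diff, 2)
  expect_equal(ba2$sd_diff, 0)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("limits of agreement bracket about 95% of Gaussian differences", {
  set.seed(88)
  a <- rnorm(2000, 100, 10)
  b <- a - rnorm(2000, 2, 5)
  ba <- bland_altman(a, b)
  cover <- mean(a - b >= ba$loa_low & a - b <= ba$loa_high)
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
})

test_that("correlation and regression handle exact and degenerate inputs", {
  x <- c(1, 2, 3, 4, 5)
  res <- correlate(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 1)
  expect_equal(correlate(x, -x)$r, -1)
  expect_error(correlate(x, rep(3, 5)), "zero variance")
  expect_error(correlate(1:2, 2:3), "at least 3")
})

test_that("group tests cover paired, unpaired and degenerate conventions", {
  same <- c(1, 2, 3)
  res <- group_tests(same, same, paired = TRUE)
  expect_true(res$degenerate)
  expect_equal(res$p, 1)

  off <- group_tests(same + 2, same, paired = TRUE)
  expect_true(off$degenerate)
  expect_true(is.na(off$p))

  unp <- group_tests(same, same, paired = FALSE)
  expect_equal(unp$t, 0)
  expect_equal(unp$p, 1)

  set.seed(4)
  a <- rnorm(10); b <- rnorm(10, 1)
  ref <- t.test(a, b, paired = TRUE)
  mine <- group_tests(a, b, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value)
})

test_that("cohort summary statistics reproduce the reported values", {
  vlv <- study_vlv()
  spiro <- study_spirometry()
  healthy <- vlv$group == "healthy"
  expect_equal(round(summarize_values(vlv$vlv_semi_L[healthy])["mean"], 2),
               c(mean = 3.88))
  expect_equal(round(summarize_values(spiro$FEV1_L[spiro$group == "healthy"])["mean"], 2),
               c(mean = 3.71))
  expect_equal(sd(rep(5, 4)), 0)

  # VLV vs FVC correlation across all ten subjects rounds to 0.93
  r <- correlate(spiro$FVC_L, vlv$vlv_semi_L)$r
  expect_equal(round(r, 2), 0.93)
})

test_that("agreement report bundles the analyses consistently", {
  vlv <- study_vlv()
  rep <- agreement_report(vlv$vlv_semi_L, vlv$vlv_manual_L, dice = vlv$dice)
  expect_equal(rep$bland_altman$loa_low,
               rep$bland_altman$mean_diff - 1.96 * rep$bland_altman$sd_diff)
  expect_equal(round(rep$dice[["mean"]], 2), 0.96)
  expect_gt(rep$regression$r, 0.99)
  expect_false(rep$paired_t$degenerate)
})
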