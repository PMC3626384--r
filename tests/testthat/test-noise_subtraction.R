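test_that("the sampling box sits at the bottom centre with 1250 pixels", {
  slice <- matrix(0, 256, 256)
  slice[232:256, 104:153] <- 7  # exactly the expected box
  h <- sample_background(slice)
  expect_equal(h$box, c(232, 104, 256, 153))
  expect_equal(h$n_samples, 1250)
  expect_equal(h$h[h$f == 7], 1)  # every sampled pixel is 7

  # odd leftover width shifts the box left by one
  h2 <- sample_background(matrix(0, 30, 55))
  expect_equal(h2$box[2], 3)  # floor((55-50)/2) + 1

  expect_error(sample_background(matrix(0, 20, 40)), "smaller")
})

test_that("a constant-zero slice gives a single-bin histogram", {
  h <- sample_background(matrix(0, 64, 64))
  expect_equal(h$f, 0)
  expect_equal(h$h, 1)
})

test_that("the empirical mode of sampled noise sits at sigma when alpha=1, delta=0", {
  set.seed(301)
  slice <- matrix(rayleigh_noise(256 * 256, sigma = 10), 256, 256)
  h <- sample_background(slice)
  expect_lte(abs(h$f[which.max(h$h)] - 10), 2)
})

test_that("self-fit of exact model densities recovers the parameters", {
  # sigma = 12, alpha = 1, delta = 0, tabulated on f = 0..60
  h <- structure(list(f = 0:60, h = adjusted_rayleigh(0:60, 12, 1, 0),
                      n_samples = NA, box = NULL), class = "noise_histogram")
  fit <- fit_adjusted_rayleigh(h)
  expect_lt(abs(fit$sigma - 12), 1e-4)
  expect_lt(abs(fit$alpha - 1), 1e-4)
  expect_lt(abs(fit$delta - 0), 1e-4)
  expect_lt(fit$rss, 1e-10)

  # shifted curve: delta = -5
  h2 <- structure(list(f = 0:60, h = adjusted_rayleigh(0:60, 12, 1, -5),
                       n_samples = NA, box = NULL), class = "noise_histogram")
  fit2 <- fit_adjusted_rayleigh(h2)
  expect_lt(abs(fit2$delta - (-5)), 1e-3)
  expect_lt(fit2$rss, 1e-10)
})

test_that("fit is deterministic and rejects degenerate histograms", {
  set.seed(17)
  h <- noise_histogram(rayleigh_noise(1250, 8))
  f1 <- fit_adjusted_rayleigh(h)
  f2 <- fit_adjusted_rayleigh(h)
  expect_identical(f1, f2)
  expect_error(fit_adjusted_rayleigh(noise_histogram(c(3, 3, 3))),
               "degenerate")
})

test_that("sigma is recovered from seeded draws at the real box size", {
  # identifiable condition: alpha = 1, delta = 0 (plain Rayleigh density)
  set.seed(100)
  smp <- rayleigh_noise(1250, sigma = 10)
  fit <- fit_adjusted_rayleigh(noise_histogram(smp))
  expect_lt(abs(fit$sigma / fit$alpha - 10) / 10, 0.05)

  # with alpha != 1 the model is scale-degenerate; the identifiable
  # combination sigma/alpha is still recovered (sigma/alpha large enough
  # that unit-width binning resolves the curve)
  set.seed(101)
  smp2 <- (30 * sqrt(-2 * log(runif(1e5))) - 3) / 1.5
  fit2 <- fit_adjusted_rayleigh(noise_histogram(pmax(0, smp2)))
  expect_lt(abs(fit2$sigma / fit2$alpha - 30 / 1.5) / (30 / 1.5), 0.05)
})

test_that("threshold equals the brute-force error-term scan", {
  set.seed(42)
  for (sigma in c(5, 10, 20)) {
    smp <- rayleigh_noise(1250, sigma)
    h <- noise_histogram(smp)
    fit <- fit_adjusted_rayleigh(h)
    tau <- compute_threshold(fit, h)
    r <- adjusted_rayleigh(h$f, fit$sigma, fit$alpha, fit$delta)
    expect_equal(tau, oracle_threshold(r, h$h))
    expect_equal(tau, max(h$f) + 1)  # consequence of the signed error term
  }
})

test_that("a noise spike far above the fitted curve support still thresholds above it", {
  # r concentrated at f ~ 0 (tiny sigma), all observed mass at f = 9:
  # the literal error term is minimized just above the largest sample
  h <- noise_histogram(rep(9, 100))
  fit <- structure(list(sigma = 0.5, alpha = 1, delta = 0, rss = 0,
                        tau = NA_integer_), class = "noise_fit")
  tau <- compute_threshold(fit, h)
  r <- adjusted_rayleigh(h$f, 0.5, 1, 0)
  expect_equal(tau, oracle_threshold(r, h$h))
  expect_equal(tau, 10)
})

test_that("thresholding produces the indicator mask and respects per-slice fits", {
  up <- matrix(100, 30, 60)
  stack <- image_stack(list(up, matrix(10, 30, 60), cbind(matrix(30, 30, 30),
                                                          matrix(70, 30, 30))))
  m <- apply_threshold(stack, c(50, 50, 50))
  expect_true(all(m$slices[[1]] == 1L))
  expect_true(all(m$slices[[2]] == 0L))
  expect_equal(m$slices[[3]], cbind(matrix(0L, 30, 30), matrix(1L, 30, 30)))
  expect_error(apply_threshold(stack, c(50, 50)), "thresholds for")
})

test_that("shifting all intensities shifts the threshold and leaves the mask unchanged", {
  set.seed(55)
  base <- matrix(rayleigh_noise(128 * 128, 8), 128, 128)
  base[30:90, 40:90] <- 150 + rnorm(61 * 51, 0, 4)
  base <- pmax(base, 0)
  stack1 <- image_stack(round(base))
  stack2 <- image_stack(round(base) + 25)
  f1 <- fit_noise(stack1)
  f2 <- fit_noise(stack2)
  expect_equal(f2[[1]]$tau, f1[[1]]$tau + 25)
  m1 <- apply_threshold(stack1, f1)
  m2 <- apply_threshold(stack2, f2)
  expect_identical(m1$slices, m2$slices)
})

test_that("median sigma recovery error over 20 seeded simulations is within 10%", {
  errs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    fit <- fit_adjusted_rayleigh(noise_histogram(rayleigh_noise(1250, 10)))
    abs(fit$sigma / fit$alpha - 10) / 10
  }, numeric(1))
  expect_lte(median(errs), 0.10)
})
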