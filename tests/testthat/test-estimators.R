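test_that("median/MAD start: values, equivariance, degeneracy", {
  e <- median_mad(c(1, 2, 3))
  expect_equal(c(e$mu_hat, e$sigma_hat), c(2, 1.4826))
  ed <- median_mad(rep(4, 6))
  expect_true(ed$degenerate)
  expect_equal(c(ed$mu_hat, ed$sigma_hat), c(4, 0))
  set.seed(2)
  x <- rnorm(23)
  a <- 3; b <- -2
  e0 <- median_mad(x); e1 <- median_mad(a + b * x)
  expect_equal(e1$mu_hat, a + b * e0$mu_hat)
  expect_equal(e1$sigma_hat, abs(b) * e0$sigma_hat)
})

test_that("MAS biweight: symmetric case, constant case, hard outlier rejection", {
  expect_equal(tukey_biweight_mas(c(1, 2, 3)), 2)
  expect_equal(tukey_biweight_mas(rep(7, 5)), 7)
  x <- c(1:10, 1e6)
  med <- median(x); mad_u <- median(abs(x - med))
  u <- (x - med) / (5 * mad_u + 1e-4)
  expect_equal(sum(abs(u) >= 1), 1L)  # exactly the outlier is rejected
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  w_forced <- w; w_forced[11] <- 0
  expect_equal(tukey_biweight_mas(x), sum(w_forced * x) / sum(w_forced))
})

test_that("Illumina summary: retention band, outlier rejection, degeneracy", {
  e <- illumina_summary(1:10)
  expect_equal(e$mu_hat, 5.5)
  expect_equal(e$sigma_hat, sd(1:10))
  expect_equal(e$n_used, 10L)
  e2 <- illumina_summary(c(1:10, 1000))
  expect_equal(e2$mu_hat, 5.5)
  expect_equal(e2$n_used, 10L)
  e3 <- illumina_summary(rep(3, 5))
  expect_true(e3$degenerate)
  expect_equal(e3$mu_hat, 3)
})

test_that("finite-sample correction: contract and interpolation", {
  for (r in c(0, 0.05, 0.1, 0.3, 0.8)) {
    for (n in c(3, 11, 30, 120, 5000)) {
      rc <- finite_sample_correction(r, n)
      expect_gte(rc, r)
    }
  }
  ## non-increasing in n for fixed r
  expect_gte(finite_sample_correction(0.1, 11), finite_sample_correction(0.1, 100))
  expect_gte(finite_sample_correction(0.1, 5), finite_sample_correction(0.1, 11))
  ## approaches r for very large n
  expect_lt(finite_sample_correction(0.3, 1e6) - 0.3, 0.01)
  expect_error(finite_sample_correction(0.1, 2), "n")
})

test_that("shipped calibration table reproduces a recomputed cell at its seed", {
  tab <- rmxprep:::fs_correction_table()
  seed <- tab$calibration_seed[1]
  row <- tab[tab$n == 11 & abs(tab$r - 0.166) < 1e-9, ]
  expect_equal(nrow(row), 1L)
  rc <- calibrate_one_cell(11, 0.166,
                           candidates = c(seq(0.05, 1.6, by = 0.05),
                                          1.8, 2, 2.25, 2.5),
                           reps = 4000, seed = seed)
  ## the stored value is the raw cell value after monotone smoothing across
  ## the grid; the raw recomputation must match it up to that smoothing,
  ## i.e. the raw value can not exceed the stored one by more than one
  ## candidate step
  expect_lte(abs(rc - row$r_corrected), 0.051)
})

test_that("rmx k-step is affine equivariant", {
  set.seed(31)
  x <- rnorm(20)
  a <- 5; b <- 3
  e0 <- rmx_kstep(x)
  e1 <- rmx_kstep(a + b * x)
  expect_equal(e1$mu_hat, a + b * e0$mu_hat, tolerance = 1e-10)
  expect_equal(e1$sigma_hat, b * e0$sigma_hat, tolerance = 1e-10)
  ## negative scaling
  e2 <- rmx_kstep(a - b * x)
  expect_equal(e2$mu_hat, a - b * e0$mu_hat, tolerance = 1e-10)
  expect_equal(e2$sigma_hat, b * e0$sigma_hat, tolerance = 1e-10)
})

test_that("rmx location is exact at the center of a symmetric sample", {
  ## x and 2m - x paired: the odd location IC cancels at the median for
  ## every step
  set.seed(8)
  m <- 2.5
  half <- rnorm(10, 0, 1.3)
  x <- c(m + half, m - half)
  for (k in c(1, 3, 7)) {
    e <- rmx_kstep(x, k = k)
    expect_equal(e$mu_hat, m, tolerance = 1e-12)
  }
})

test_that("rmx influence of a single observation is bounded", {
  set.seed(12)
  x <- rnorm(20)
  clean <- rmx_kstep(x)
  start <- median_mad(x)
  ic <- rmxprep:::rmx_ic_for_n(20, 0, 0.05)
  big <- x; big[1] <- 1e3
  huge <- x; huge[1] <- 1e6
  d_big <- abs(rmx_kstep(big)$mu_hat - clean$mu_hat)
  d_huge <- abs(rmx_kstep(huge)$mu_hat - clean$mu_hat)
  ## moving the outlier 1000x further changes nothing beyond tolerance
  expect_lte(d_huge, d_big + 1e-6)
  ## and the total shift stays within the clipped one-observation budget
  bound <- 3 * ic$b * start$sigma_hat / 20
  expect_lt(d_big, bound)
  expect_lt(abs(rmx_kstep(big)$sigma_hat - clean$sigma_hat), bound)
})

test_that("rmx inherits the 50% breakdown of median/MAD", {
  set.seed(44)
  x <- rnorm(20)
  clean <- rmx_kstep(x)
  broken <- x
  broken[1:9] <- 1e8   # 45% gross errors
  e <- rmx_kstep(broken)
  ## the estimate stays on the scale of the clean data, nowhere near 1e8
  expect_lt(abs(e$mu_hat), 10 * max(abs(x)))
  expect_lt(e$sigma_hat, 10 * max(abs(x)))
  ## whereas the non-robust MLE is carried away entirely
  expect_gt(mle_fit(broken)$mu_hat, 1e7)
})

test_that("rmx approaches the MLE on clean data as the interval shrinks", {
  set.seed(77)
  x <- rnorm(1e4)
  e <- rmx_kstep(x, s_lo = 0, s_up = 1e-3, k = 10)
  m <- mle_fit(x)
  expect_lt(abs(e$mu_hat - m$mu_hat), 0.01)
  expect_lt(abs(e$sigma_hat - m$sigma_hat), 0.01)
})

test_that("degenerate start falls back to the flagged start", {
  e <- rmx_kstep(c(rep(1, 9), 5))
  expect_true(e$degenerate)
  expect_equal(e$mu_hat, 1)
})
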