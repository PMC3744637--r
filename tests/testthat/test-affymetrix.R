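test_that("ideal match follows the three branches and stays below PM", {
  p <- mas_params()
  expect_equal(ideal_match(10, 3, sb = 1), 3)              # MM < PM
  expect_equal(ideal_match(10, 10, sb = 1), 5)             # PM * 2^-SB
  expect_equal(ideal_match(10, 10, sb = 0),
               10 * 2^(-0.03 / (1 + 0.03 / 10)))           # smooth floor
  ## IM < PM whenever MM >= PM and SB > 0; IM <= MM when MM < PM
  sbs <- seq(0.001, 3, length.out = 50)
  expect_true(all(ideal_match(10, 12, sbs) < 10))
  expect_true(all(ideal_match(10, 12, sbs) > 0))
  expect_true(all(ideal_match(10, seq(1, 9.9, 0.5), sb = 2) <= 9.9))
})

test_that("ideal match is continuous in SB at the tau1 boundary", {
  p <- mas_params()
  eps <- 1e-10
  below <- ideal_match(10, 10, sb = p$tau1 - eps, p)
  above <- ideal_match(10, 10, sb = p$tau1 + eps, p)
  at <- ideal_match(10, 10, sb = p$tau1, p)
  expect_lt(abs(below - at), 1e-8)
  expect_lt(abs(above - at), 1e-8)
})

test_that("probe value floors at delta and is monotone in PM", {
  expect_equal(probe_value(10, 11), -20)     # pm - im <= 0 -> log2(2^-20)
  expect_equal(probe_value(10, 2), 3)
  pv <- probe_value(seq(5, 50, by = 5), im = 4)
  expect_true(all(diff(pv) >= 0))
})

test_that("specific background recovers the common log-ratio", {
  ps <- probe_set_data("a", pm = 2 * c(10, 20, 40, 80), mm = c(10, 20, 40, 80))
  expect_equal(specific_background(ps, mas_params()), 1)
  expect_equal(specific_background(ps, mas_params(estimator = "rmx")), 1)
  ## log-ratios exactly symmetric about m: both estimators return m
  m <- 1.5
  lr <- m + c(-0.4, -0.1, 0, 0.1, 0.4)
  ps2 <- probe_set_data("b", pm = 2^(10 + lr), mm = rep(2^10, 5))
  expect_equal(specific_background(ps2, mas_params()), m, tolerance = 1e-10)
  expect_equal(specific_background(ps2, mas_params(estimator = "rmx")), m,
               tolerance = 1e-8)
})

test_that("rmx specific background resists an aberrant pair better than biweight", {
  ## one wild log-ratio among 11; compare against the leave-one-out median
  lr <- c(1.02, 0.95, 1.08, 0.97, 1.01, 1.04, 0.99, 0.96, 1.06, 0.93, 2.6)
  ps <- probe_set_data("c", pm = 2^(10 + lr), mm = rep(2^10, 11))
  target <- median(lr[-11])
  sb_bi <- specific_background(ps, mas_params())
  sb_rmx <- specific_background(ps, mas_params(estimator = "rmx"))
  expect_lt(abs(sb_rmx - target), abs(sb_bi - target))
})

test_that("summarize_probe_set: single pair and symmetric cases", {
  p <- mas_params()
  one <- summarize_probe_set(probe_set_data("x", 10, 3), p)
  expect_equal(one$sig_log_val, log2(10 - 3))
  expect_equal(one$n_pairs, 1L)
  ## all MM < PM with probe values symmetric about v: estimator returns v
  pm <- c(40, 40, 40, 40, 40)
  d <- 2^c(3 - 0.4, 3 - 0.1, 3, 3 + 0.1, 3 + 0.4)  # pm - mm, symmetric PVs
  mm <- pm - d
  res_bi <- summarize_probe_set(probe_set_data("y", pm, mm), p)
  expect_equal(res_bi$sig_log_val, 3, tolerance = 1e-10)
  res_rmx <- summarize_probe_set(probe_set_data("y", pm, mm),
                                 mas_params(estimator = "rmx"))
  expect_equal(res_rmx$sig_log_val, 3, tolerance = 1e-8)
  expect_gt(res_rmx$scale_est, 0)
})

test_that("biweight summarization is invariant to probe-pair order", {
  set.seed(21)
  pm <- 2^runif(16, 8, 10)
  mm <- pm / 2^rnorm(16, 1, 0.2)
  res1 <- summarize_probe_set(probe_set_data("z", pm, mm))
  perm <- sample(16)
  res2 <- summarize_probe_set(probe_set_data("z", pm[perm], mm[perm]))
  expect_equal(res2$sig_log_val, res1$sig_log_val)
  expect_equal(res2$sb, res1$sb)
})

test_that("summarize_chip groups, orders, and skips malformed rows", {
  tab <- data.frame(
    probe_set_id = c("b", "b", "b", "a", "a", "a"),
    PM = c(40, 50, 60, 30, -1, 35),
    MM = c(20, 25, 30, 15, 10, NA))
  expect_message(res <- summarize_chip(tab), "2 malformed")
  expect_equal(res$probe_set_id, c("b", "a"))  # first-appearance order
  expect_equal(res$n_pairs, c(3L, 1L))
  expect_equal(attr(res, "n_skipped"), 2L)
})

test_that("chip summaries of a frozen fixture are byte-stable across runs", {
  cfg <- fixture_config(n_groups = 20, group_size = 11, noise_sd_log2 = 0.2,
                        seed = 99)
  run_once <- function() {
    fx <- generate_affy_fixture(cfg)
    res <- summarize_chip(fx, mas_params(estimator = "rmx"))
    path <- tempfile(fileext = ".tsv")
    write_result_tsv(res, path)
    readLines(path)
  }
  expect_identical(run_once(), run_once())
})
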