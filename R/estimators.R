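## Finite-sample location-scale estimators: median/MAD start, the rmx k-step
## construction, and the comparators used in the Monte-Carlo studies
## (MAS-variant Tukey biweight one-step, Illumina skipped mean/SD, MLE).
##
## Each estimator has a scalar-sample entry point returning a
## locscale_estimate, plus an internal matrix engine (columns = samples) used
## by the simulation and calibration code where the same estimator runs on
## 1e4-1e5 replications at once.

#' Median and MAD starting estimator
#'
#' \eqn{\hat\mu} is the sample median (midpoint convention for even n) and
#' \eqn{\hat\sigma = 1.4826 \times} the median absolute deviation about the
#' median, the standardization making the MAD consistent for \eqn{\sigma} at
#' the normal model. This is the 50%-breakdown starting estimator of the rmx
#' k-step construction.
#'
#' @param sample numeric vector, length >= 2.
#' @return A [locscale_estimate()]; `degenerate` is set when the MAD is 0.
#' @examples
#' median_mad(c(1, 2, 3))
#' @export
median_mad <- function(sample) {
  sample <- check_sample(sample, min_n = 2L)
  mu <- stats::median(sample)
  sg <- 1.4826 * stats::median(abs(sample - mu))
  locscale_estimate(mu, sg, method = "median_mad", steps = 0L,
                    n_used = length(sample), degenerate = (sg == 0))
}

#' MAS-variant Tukey biweight one-step location estimate
#'
#' Affymetrix's version of the one-step Tukey biweight: with
#' \eqn{u_i = (x_i - \mathrm{med}) / (c \cdot \mathrm{MAD} + \epsilon)}
#' (unstandardized MAD, \eqn{c = 5}, \eqn{\epsilon = 10^{-4}}), observations
#' with \eqn{|u_i| \ge 1} — i.e. outside median \eqn{\pm 5} MAD — get weight
#' 0 and the rest weight \eqn{(1 - u_i^2)^2}; the estimate is the weighted
#' mean. A zero MAD returns the median.
#'
#' @param sample numeric vector, length >= 1.
#' @param c_tuning rejection constant, default 5.
#' @param eps stabilizing constant in the denominator, default 1e-4.
#' @return The biweight location estimate (a single number).
#' @examples
#' tukey_biweight_mas(c(1, 2, 3))
#' @export
tukey_biweight_mas <- function(sample, c_tuning = 5, eps = 1e-4) {
  sample <- check_sample(sample, min_n = 1L)
  med <- stats::median(sample)
  mad_u <- stats::median(abs(sample - med))
  if (mad_u == 0) return(med)
  u <- (sample - med) / (c_tuning * mad_u + eps)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  sum(w * sample) / sum(w)
}

#' Illumina default bead summarization (skipped mean and SD)
#'
#' Retains observations within median \eqn{\pm 3 \times (1.4826 \times
#' \mathrm{MAD})} and returns the mean and the sample standard deviation
#' (divisor `n_used - 1`) of the retained values — the Huber-type skipped
#' mean/SD used by BeadStudio.
#'
#' @param sample numeric vector, length >= 3.
#' @return A [locscale_estimate()] with `method = "illumina"` and `n_used`
#'   the number retained; fewer than 2 retained (only possible for a zero
#'   MAD) flags the estimate degenerate.
#' @examples
#' illumina_summary(c(1:10, 1000))  # the outlier is rejected
#' @export
illumina_summary <- function(sample) {
  sample <- check_sample(sample, min_n = 3L)
  med <- stats::median(sample)
  smad <- 1.4826 * stats::median(abs(sample - med))
  keep <- abs(sample - med) <= 3 * smad
  x <- sample[keep]
  if (length(x) < 2L || smad == 0)
    return(locscale_estimate(med, 0, method = "illumina",
                             n_used = length(x), degenerate = TRUE))
  locscale_estimate(mean(x), stats::sd(x), method = "illumina",
                    n_used = length(x), degenerate = FALSE)
}

#' Finite-sample correction of the neighborhood radius
#'
#' The asymptotic radius \eqn{r = s\sqrt{n}} is too optimistic at small
#' sample sizes: the k-step estimator started at median/MAD carries extra
#' finite-sample variability, and a somewhat larger (more conservative)
#' radius minimizes the empirical maximum MSE. The correction interpolates a
#' calibration table shipped with the package (see
#' [calibrate_finite_sample_correction()] and the bundled
#' `scripts/calibrate_correction.R`), log-linearly in `n` and linearly in
#' `r`, and never returns less than `r`.
#'
#' @param r asymptotic radius, >= 0.
#' @param n sample size, >= 3.
#' @return Corrected radius `r' >= r`; non-increasing in `n` for fixed `r`
#'   and tending to `r` as `n` grows.
#' @examples
#' finite_sample_correction(0.1, 11)
#' @export
finite_sample_correction <- function(r, n) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r), r >= 0)
  if (!is.numeric(n) || length(n) != 1L || n < 3)
    stop("'n' must be a single sample size >= 3 (no reliable correction below)")
  tab <- fs_correction_table()
  if (r >= max(tab$r)) return(r)   # large radii need no correction
  ns <- sort(unique(tab$n))
  corr_at_n <- function(nn) {
    sub <- tab[tab$n == nn, ]
    sub <- sub[order(sub$r), ]
    ## clamp into the calibrated radius range of this n, flat extrapolation
    stats::approx(sub$r, sub$r_corrected, xout = min(max(r, min(sub$r)),
                                                     max(sub$r)), rule = 2)$y
  }
  if (n >= max(ns)) {
    ## blend towards no correction as n -> Inf
    rc <- corr_at_n(max(ns))
    return(max(r, r + (rc - r) * max(ns) / n))
  }
  if (n <= min(ns)) return(max(r, corr_at_n(min(ns))))
  i <- findInterval(n, ns)
  n1 <- ns[i]; n2 <- ns[i + 1L]
  w <- (log(n) - log(n1)) / (log(n2) - log(n1))
  max(r, (1 - w) * corr_at_n(n1) + w * corr_at_n(n2))
}

fs_correction_table <- function() {
  if (!is.null(.rmxprep_cache$fs_table)) return(.rmxprep_cache$fs_table)
  path <- system.file("extdata", "finite_sample_correction.csv",
                      package = "rmxprep")
  if (!nzchar(path))
    path <- file.path("inst", "extdata", "finite_sample_correction.csv")
  if (!file.exists(path))
    stop("finite-sample calibration table not found; run scripts/calibrate_correction.R")
  tab <- utils::read.csv(path)
  stopifnot(all(c("n", "r", "r_corrected") %in% names(tab)))
  .rmxprep_cache$fs_table <- tab
  tab
}

## The rmx IC for a sample of size n and a contamination-size interval
## [s_lo, s_up]: endpoints mapped to radii s * sqrt(n), finite-sample
## corrected, then fed to the radius-minimax search. Cached per
## (n, s_lo, s_up) because the solve dominates runtime.
rmx_ic_for_n <- function(n, s_lo = 0, s_up = 0.05) {
  key <- sprintf("rmxic_n%d_%.6f_%.6f", as.integer(n), s_lo, s_up)
  if (!is.null(.rmxprep_cache[[key]])) return(.rmxprep_cache[[key]])
  r_lo <- finite_sample_correction(s_lo * sqrt(n), n)
  r_up <- finite_sample_correction(s_up * sqrt(n), n)
  if (r_up <= r_lo + 1e-3) r_up <- r_lo + 1e-3
  ic <- radius_minimax_ic(r_lo, r_up)$ic
  assign(key, ic, envir = .rmxprep_cache)
  ic
}

#' Radius-minimax k-step estimator of normal location and scale
#'
#' The optimally robust estimator of the package: starting from median/MAD,
#' `k` additive one-step updates
#' \eqn{S^{(j)} = S^{(j-1)} + \frac{1}{n}\sum_i \psi_{S^{(j-1)}}(x_i)}
#' with the radius-minimax IC for the contamination-size interval
#' `[s_lo, s_up]` (radii \eqn{s\sqrt{n}}, finite-sample corrected). The IC at
#' parameter \eqn{(\mu,\sigma)} is the standard-model IC evaluated at
#' \eqn{(x-\mu)/\sigma} with both components multiplied by \eqn{\sigma}, so
#' the estimator is affine equivariant, has bounded influence, and inherits
#' the 50% breakdown point of median/MAD.
#'
#' @param sample numeric vector, length >= 3.
#' @param s_lo,s_up contamination-size interval, `0 <= s_lo < s_up <= 0.5`.
#' @param k number of one-step updates, default 3 (estimates are stable
#'   after the third iteration).
#' @return A [locscale_estimate()] with `method = "rmx"`. A degenerate
#'   median/MAD start (zero MAD) is returned unchanged, flagged.
#' @examples
#' set.seed(1)
#' rmx_kstep(rnorm(30))
#' @export
rmx_kstep <- function(sample, s_lo = 0, s_up = 0.05, k = 3L) {
  sample <- check_sample(sample, min_n = 3L)
  stopifnot(s_lo >= 0, s_lo < s_up, s_up <= 0.5, k >= 1)
  start <- median_mad(sample)
  if (start$degenerate) return(start)
  n <- length(sample)
  ic <- rmx_ic_for_n(n, s_lo, s_up)
  est <- rmx_kstep_mat(matrix(sample, ncol = 1L), ic, k = k,
                       mu0 = start$mu_hat, sig0 = start$sigma_hat)
  locscale_estimate(est$mu, est$sig, method = "rmx", steps = k, n_used = n,
                    degenerate = est$floored)
}

## ---- matrix engines (columns = independent samples) ----

col_medians <- function(X) apply(X, 2L, stats::median)

## k-step update applied to every column at once; mu0/sig0 optional
## overrides for the start (vectors or scalars).
rmx_kstep_mat <- function(X, ic, k = 3L, mu0 = NULL, sig0 = NULL) {
  n <- nrow(X)
  mu <- if (is.null(mu0)) col_medians(X) else rep_len(mu0, ncol(X))
  sig <- if (is.null(sig0)) {
    1.4826 * col_medians(abs(X - rep(mu, each = n)))
  } else rep_len(sig0, ncol(X))
  floored <- sig <= 1e-12
  sig <- pmax(sig, 1e-12)
  A1 <- ic$A[1, 1]; A2 <- ic$A[2, 2]; z2 <- ic$z[2]; b <- ic$b
  for (j in seq_len(k)) {
    Z <- (X - rep(mu, each = n)) / rep(sig, each = n)
    Y1 <- A1 * Z
    Y2 <- A2 * (Z^2 - 1 - z2)
    w <- if (is.finite(b)) pmin(1, b / sqrt(Y1^2 + Y2^2)) else 1
    mu <- mu + sig * colMeans(Y1 * w)
    sig <- sig + sig * colMeans(Y2 * w)
    floored <- floored | sig <= 1e-12
    sig <- pmax(sig, 1e-12)
  }
  list(mu = mu, sig = sig, floored = floored)
}

biweight_mat <- function(X, c_tuning = 5, eps = 1e-4) {
  n <- nrow(X)
  med <- col_medians(X)
  mad_u <- col_medians(abs(X - rep(med, each = n)))
  u <- (X - rep(med, each = n)) / rep(c_tuning * mad_u + eps, each = n)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  est <- colSums(w * X) / colSums(w)
  ifelse(mad_u == 0, med, est)
}

median_mad_mat <- function(X) {
  n <- nrow(X)
  mu <- col_medians(X)
  sig <- 1.4826 * col_medians(abs(X - rep(mu, each = n)))
  list(mu = mu, sig = sig)
}

illumina_mat <- function(X) {
  n <- nrow(X)
  med <- col_medians(X)
  smad <- 1.4826 * col_medians(abs(X - rep(med, each = n)))
  keep <- abs(X - rep(med, each = n)) <= rep(3 * smad, each = n)
  nk <- colSums(keep)
  sx <- colSums(X * keep)
  sxx <- colSums(X^2 * keep)
  mu <- sx / nk
  v <- pmax(sxx - nk * mu^2, 0) / pmax(nk - 1, 1)
  list(mu = ifelse(nk >= 2, mu, med), sig = ifelse(nk >= 2, sqrt(v), 0),
       n_used = nk)
}

mle_mat <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  sig <- sqrt(pmax(colMeans(X^2) - mu^2, 0))
  list(mu = mu, sig = sig)
}
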