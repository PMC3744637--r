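## Minimum Kolmogorov distance between a sample and the normal
## location-scale family: a measure of model adequacy (no formal test for
## *approximate* normality exists), its Monte-Carlo reference distribution
## under exact normality, and the heuristic translating the observed excess
## distance into a contamination-neighborhood size.

#' Kolmogorov distance between a sample and a fitted normal
#'
#' The sup-distance \eqn{\sup_x |\Phi_{\mu,\sigma}(x) - \hat F(x)|} between
#' the right-continuous empirical distribution of the sample and the
#' \eqn{N(\mu, \sigma^2)} cdf, computed exactly over the sorted sample as
#' \eqn{\max_j \max\{\Phi(x_{(j)}) - (j-1)/n,\; j/n - \Phi(x_{(j)})\}}.
#'
#' @param sample numeric vector, length >= 1.
#' @param theta a [loc_scale_param()].
#' @return The Kolmogorov distance in `(0, 1)`.
#' @examples
#' kolmogorov_distance(0, loc_scale_param(0, 1))  # 0.5
#' @export
kolmogorov_distance <- function(sample, theta) {
  sample <- check_sample(sample, min_n = 1L)
  stopifnot(inherits(theta, "locscale_param"))
  n <- length(sample)
  p <- stats::pnorm(sort(sample), theta$mu, theta$sigma)
  j <- seq_len(n)
  max(p - (j - 1) / n, j / n - p)
}

#' Minimum Kolmogorov distance to the normal location-scale family
#'
#' Minimizes [kolmogorov_distance()] over \eqn{(\mu, \sigma)}. The smallest
#' achievable value for sample size \eqn{n} is \eqn{(2n)^{-1}}, attained
#' when the sorted sample sits exactly on the quantiles
#' \eqn{\Phi^{-1}((2j-1)/(2n))} of some normal. Optimization is Nelder-Mead
#' in \eqn{(\mu, \log\sigma)} started at median and standardized MAD, with a
#' 5x5 local restart grid to escape flat regions of the piecewise-smooth
#' objective.
#'
#' @param sample numeric vector, length >= 1.
#' @param tol convergence tolerance on the distance.
#' @return A list of class `"minkd"`: `mu_star`, `sigma_star`, `distance`,
#'   `converged`, `degenerate` (all-equal sample), `n`.
#' @examples
#' min_kolmogorov_distance(qnorm((2 * 1:5 - 1) / 10))$distance  # 0.1
#' @export
min_kolmogorov_distance <- function(sample, tol = 1e-8) {
  sample <- check_sample(sample, min_n = 1L)
  n <- length(sample)
  if (n == 1L)
    return(structure(list(mu_star = sample, sigma_star = 1, distance = 0.5,
                          converged = TRUE, degenerate = FALSE, n = 1L),
                     class = "minkd"))
  med <- stats::median(sample)
  smad <- 1.4826 * stats::median(abs(sample - med))
  if (smad == 0) {
    ## all-equal sample: distance -> 1/(2n) as sigma -> 0
    return(structure(list(mu_star = med, sigma_star = .Machine$double.eps,
                          distance = 1 / (2 * n), converged = TRUE,
                          degenerate = TRUE, n = n), class = "minkd"))
  }
  xs <- sort(sample)
  j <- seq_len(n)
  obj <- function(par) {
    p <- stats::pnorm(xs, par[1], exp(par[2]))
    max(p - (j - 1) / n, j / n - p)
  }
  best <- NULL
  for (dmu in seq(-1, 1, by = 0.5) * smad) {
    for (fs in 2^seq(-1, 1, by = 0.5)) {
      fit <- stats::optim(c(med + dmu, log(smad * fs)), obj,
                          method = "Nelder-Mead",
                          control = list(reltol = tol, maxit = 500))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  structure(list(mu_star = best$par[1], sigma_star = exp(best$par[2]),
                 distance = best$value,
                 converged = best$convergence == 0 || best$value <= 1 / (2 * n) + tol,
                 degenerate = FALSE, n = n),
            class = "minkd")
}

#' @export
print.minkd <- function(x, ...) {
  cat(sprintf(
    "minimum Kolmogorov distance: %.6g (floor %.6g) at mu = %.6g, sigma = %.6g\n",
    x$distance, 1 / (2 * x$n), x$mu_star, x$sigma_star))
  invisible(x)
}

#' Reference distribution of the minimum Kolmogorov distance
#'
#' Minimum Kolmogorov distances of `M` independent standard normal samples
#' of size `n` — the yardstick against which observed distances of real
#' probe sets or bead types are compared.
#'
#' @param n sample size >= 3.
#' @param M Monte-Carlo replications.
#' @param seed RNG seed (two runs with the same seed are identical).
#' @return Numeric vector of `M` distances with attribute `summary`
#'   (median, 95% and 99% quantiles).
#' @examples
#' d <- minkd_reference(11, M = 50, seed = 1)
#' attr(d, "summary")
#' @export
minkd_reference <- function(n, M = 50000, seed = 1) {
  stopifnot(n >= 3, M >= 1)
  set.seed(seed)
  d <- vapply(seq_len(M),
              function(i) min_kolmogorov_distance(stats::rnorm(n))$distance,
              numeric(1))
  attr(d, "summary") <- c(median = stats::median(d),
                          stats::quantile(d, c(0.95, 0.99)))
  d
}

#' Contamination-neighborhood size from excess Kolmogorov distance
#'
#' Contamination neighborhoods are contained in total-variation
#' neighborhoods, which are contained in Kolmogorov neighborhoods of the
#' same size, and (one-dimensional, symmetric case) the optimal ICs for a
#' contamination neighborhood of size 2s and a total-variation neighborhood
#' of size s coincide. This motivates estimating the contamination size as
#' twice the median excess of the observed minimum Kolmogorov distances
#' over the normal reference, clamped at 0.
#'
#' @param observed minimum KD values from data.
#' @param reference minimum KD values from [minkd_reference()].
#' @return The heuristic neighborhood size
#'   `max(0, 2 * (median(observed) - median(reference)))`.
#' @examples
#' neighborhood_size_heuristic(c(0.13, 0.15), c(0.12, 0.12))
#' @export
neighborhood_size_heuristic <- function(observed, reference) {
  stopifnot(length(observed) >= 1, length(reference) >= 1)
  max(0, 2 * (stats::median(observed) - stats::median(reference)))
}
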