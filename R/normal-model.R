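#' Parameter of the normal location-scale model
#'
#' Constructs the parameter \eqn{\theta = (\mu, \sigma)'} of the ideal model
#' \eqn{N(\mu, \sigma^2)}. The scale must be strictly positive.
#'
#' @param mu location, in the units of the data.
#' @param sigma scale, strictly positive.
#' @return An object of class `"locscale_param"` with components `mu`, `sigma`.
#' @examples
#' loc_scale_param(0, 1)
#' @export
loc_scale_param <- function(mu = 0, sigma = 1) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu))
    stop("'mu' must be a single finite number")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single finite number > 0")
  structure(list(mu = mu, sigma = sigma), class = "locscale_param")
}

#' @export
print.locscale_param <- function(x, ...) {
  cat(sprintf("normal location-scale parameter: mu = %g, sigma = %g\n",
              x$mu, x$sigma))
  invisible(x)
}

#' Classical scores of the normal location-scale model
#'
#' The score function \eqn{\Lambda_\theta(x)} of \eqn{N(\mu,\sigma^2)}:
#' location component \eqn{(x-\mu)/\sigma^2} and scale component
#' \eqn{((x-\mu)^2/\sigma^2 - 1)/\sigma}. Its expectation under the model is
#' zero and its covariance is the Fisher information.
#'
#' @param x numeric vector of observations.
#' @param theta a [loc_scale_param()].
#' @return A two-column matrix with columns `loc` and `scale`, one row per
#'   element of `x`.
#' @examples
#' nm_score(c(-1, 0, 1), loc_scale_param(0, 1))
#' @export
nm_score <- function(x, theta = loc_scale_param()) {
  stopifnot(inherits(theta, "locscale_param"))
  z <- (x - theta$mu) / theta$sigma
  cbind(loc = z / theta$sigma, scale = (z^2 - 1) / theta$sigma)
}

#' Fisher information of the normal location-scale model
#'
#' For \eqn{N(\mu,\sigma^2)} the Fisher information is
#' \eqn{\mathrm{diag}(1/\sigma^2, 2/\sigma^2)}; location and scale are
#' orthogonal.
#'
#' @inheritParams nm_score
#' @return A symmetric positive definite 2x2 matrix.
#' @examples
#' nm_fisher_info(loc_scale_param(0, 1))
#' @export
nm_fisher_info <- function(theta = loc_scale_param()) {
  stopifnot(inherits(theta, "locscale_param"))
  diag(c(1, 2)) / theta$sigma^2
}

#' Maximum likelihood estimate of normal location and scale
#'
#' The MLE comparator: \eqn{\hat\mu} is the arithmetic mean and
#' \eqn{\hat\sigma} the root mean squared deviation (divisor \eqn{n}, not
#' \eqn{n-1}, matching the maximum likelihood convention).
#'
#' @param sample numeric vector, length >= 2.
#' @return A [locscale_estimate()] with `method = "mle"`. An all-equal sample
#'   yields `sigma_hat = 0` with the `degenerate` flag set.
#' @examples
#' mle_fit(c(-1, 1))
#' @export
mle_fit <- function(sample) {
  sample <- check_sample(sample, min_n = 2L)
  n <- length(sample)
  mu <- mean(sample)
  sg <- sqrt(mean((sample - mu)^2))
  locscale_estimate(mu, sg, method = "mle", steps = 0L, n_used = n,
                    degenerate = (sg == 0))
}

## shared input validation for estimators
check_sample <- function(sample, min_n = 1L) {
  sample <- as.numeric(sample)
  if (anyNA(sample) || any(!is.finite(sample)))
    stop("sample must be finite and free of NA")
  if (length(sample) < min_n)
    stop(sprintf("sample must have at least %d observations", min_n))
  sample
}

#' Fitted location-scale estimate
#'
#' Container returned by all location(-scale) estimators in the package.
#'
#' @param mu_hat location estimate.
#' @param sigma_hat scale estimate, >= 0.
#' @param method one of `"median_mad"`, `"rmx"`, `"biweight"`, `"illumina"`,
#'   `"mle"`, `"mean"`, `"trim"`, `"winsorize"`.
#' @param steps number of k-step updates used (0 for closed-form estimators).
#' @param n_used observations retained after any rejection step.
#' @param degenerate logical; `TRUE` iff the scale collapsed to 0.
#' @return An object of class `"locscale_estimate"`.
#' @export
locscale_estimate <- function(mu_hat, sigma_hat, method, steps = 0L,
                              n_used = NA_integer_, degenerate = FALSE) {
  stopifnot(is.finite(mu_hat), sigma_hat >= 0)
  structure(list(mu_hat = mu_hat, sigma_hat = sigma_hat,
                 method = method, steps = as.integer(steps),
                 n_used = as.integer(n_used),
                 degenerate = isTRUE(degenerate) || sigma_hat == 0),
            class = "locscale_estimate")
}

#' @export
print.locscale_estimate <- function(x, ...) {
  cat(sprintf("%s estimate: mu_hat = %.6g, sigma_hat = %.6g (n_used = %d%s)\n",
              x$method, x$mu_hat, x$sigma_hat, x$n_used,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}
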