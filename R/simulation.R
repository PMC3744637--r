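## Monte-Carlo robustness study: contaminated sampling under the gross-error
## model with the <50%-contamination redraw rule, empirical risks, and the
## two study designs (Affymetrix-style n = 11, Illumina-style n = 30).

#' Contaminating distribution
#'
#' Constructors for the gross-error generating distributions of the
#' Monte-Carlo studies.
#'
#' @param mean,sd,df,location,scale,point distribution parameters.
#' @return A tagged list usable in [contamination_spec()].
#' @name contaminants
#' @examples
#' contaminant_normal(0, 3)   # N(0, 9)
#' contaminant_dirac(1000)
NULL

#' @rdname contaminants
#' @export
contaminant_normal <- function(mean = 0, sd = 1)
  structure(list(type = "normal", mean = mean, sd = sd),
            class = "rmx_contaminant")

#' @rdname contaminants
#' @export
contaminant_t <- function(df = 3)
  structure(list(type = "student_t", df = df), class = "rmx_contaminant")

#' @rdname contaminants
#' @export
contaminant_cauchy <- function(location = 0, scale = 1)
  structure(list(type = "cauchy", location = location, scale = scale),
            class = "rmx_contaminant")

#' @rdname contaminants
#' @export
contaminant_dirac <- function(point)
  structure(list(type = "dirac", point = point), class = "rmx_contaminant")

draw_contaminant <- function(cont, m) {
  switch(cont$type,
         normal = stats::rnorm(m, cont$mean, cont$sd),
         student_t = stats::rt(m, cont$df),
         cauchy = stats::rcauchy(m, cont$location, cont$scale),
         dirac = rep(cont$point, m),
         stop("unknown contaminant type: ", cont$type))
}

contaminant_label <- function(cont) {
  switch(cont$type,
         normal = sprintf("N(%g,%g)", cont$mean, cont$sd^2),
         student_t = sprintf("t%g", cont$df),
         cauchy = sprintf("Cauchy(%g,%g)", cont$location, cont$scale),
         dirac = sprintf("D(%g)", cont$point))
}

#' Contamination specification
#'
#' The gross-error model \eqn{(1-s) N(0,1) + s Q}: each observation is
#' independently replaced by a draw from the contaminant \eqn{Q} with
#' probability `s`.
#'
#' @param s contamination size, in `[0, 0.5)`.
#' @param contaminant one of the [contaminants] constructors.
#' @return An object of class `"contamination_spec"`.
#' @examples
#' contamination_spec(0.01, contaminant_normal(0, 3))
#' @export
contamination_spec <- function(s, contaminant = contaminant_normal(0, 3)) {
  stopifnot(is.numeric(s), length(s) == 1L, s >= 0, s < 0.5,
            inherits(contaminant, "rmx_contaminant"))
  structure(list(s = s, contaminant = contaminant),
            class = "contamination_spec")
}

#' Draw one contaminated sample
#'
#' Samples of size `n` from \eqn{(1-s)N(0,1) + sQ}; any sample in which at
#' least \eqn{\lceil n/2 \rceil} observations are contaminated is discarded
#' and redrawn (no estimator is reliable at 50% or more gross errors), with
#' the redraw count reported.
#'
#' @param n sample size >= 2.
#' @param spec a [contamination_spec()].
#' @return A list: `sample` (length `n`), `flags` (logical, contaminated
#'   positions), `redraws` (number of discarded samples). Uses the global
#'   RNG stream; seed it with [set.seed()] for reproducibility.
#' @examples
#' set.seed(1)
#' draw_contaminated_sample(11, contamination_spec(0.04, contaminant_dirac(1000)))
#' @export
draw_contaminated_sample <- function(n, spec) {
  stopifnot(n >= 2, inherits(spec, "contamination_spec"))
  d <- draw_contaminated_matrix(n, 1L, spec)
  list(sample = d$X[, 1L], flags = d$flags[, 1L], redraws = d$redraws)
}

## Matrix engine: M independent contaminated samples as columns, with the
## >= ceiling(n/2) redraw rule applied column-wise.
draw_contaminated_matrix <- function(n, M, spec) {
  thresh <- ceiling(n / 2)
  gen <- function(m) {
    flags <- matrix(stats::runif(n * m) < spec$s, n, m)
    X <- matrix(stats::rnorm(n * m), n, m)
    nc <- sum(flags)
    if (nc > 0) X[flags] <- draw_contaminant(spec$contaminant, nc)
    list(X = X, flags = flags)
  }
  d <- gen(M)
  redraws <- 0L
  repeat {
    bad <- which(colSums(d$flags) >= thresh)
    if (!length(bad)) break
    redraws <- redraws + length(bad)
    repl <- gen(length(bad))
    d$X[, bad] <- repl$X
    d$flags[, bad] <- repl$flags
  }
  list(X = d$X, flags = d$flags, redraws = redraws)
}

#' Probability of rejecting a sample under the redraw rule
#'
#' Exact binomial upper tail \eqn{P(X \ge \lceil n/2 \rceil)} for
#' \eqn{X \sim \mathrm{Bin}(n, s)} — the probability that a sample drawn
#' from the gross-error model is discarded for containing 50% or more
#' contaminated observations. The Hoeffding bound
#' \eqn{\exp\{-2n(0.5 - s)^2\}} always dominates the exact tail.
#'
#' @param n sample size.
#' @param s contamination size in `[0, 0.5)`; vectorized.
#' @param bound if `TRUE`, return the Hoeffding bound instead.
#' @return Rejection probability (or bound), same length as `s`.
#' @examples
#' rejection_probability(11, c(0.01, 0.02, 0.04))
#' @export
rejection_probability <- function(n, s, bound = FALSE) {
  stopifnot(n >= 1, all(s >= 0), all(s < 0.5))
  if (bound) return(exp(-2 * n * (0.5 - s)^2))
  stats::pbinom(ceiling(n / 2) - 1, n, s, lower.tail = FALSE)
}

#' Empirical risk of a batch of estimates
#'
#' The scaled empirical mean squared error about the standard-model truth
#' \eqn{(\mu, \sigma) = (0, 1)}: `kind = "location"` gives
#' \eqn{n \cdot \mathrm{mean}(\hat\mu^2)}, `kind = "location_scale"` gives
#' \eqn{n \cdot \mathrm{mean}(\hat\mu^2 + (\hat\sigma - 1)^2)}. Degenerate
#' estimates are excluded, with the excluded count attached.
#'
#' @param mu_hat numeric vector of location estimates, or a list of
#'   [locscale_estimate()] objects (then `sigma_hat`/`degenerate` are taken
#'   from the list).
#' @param sigma_hat scale estimates (ignored for `kind = "location"` unless
#'   given as a list).
#' @param n the sample size the estimates were computed from.
#' @param kind `"location"` or `"location_scale"`.
#' @param degenerate logical vector marking estimates to exclude.
#' @return The risk, with attributes `se` (Monte-Carlo standard error) and
#'   `n_excluded`.
#' @examples
#' empirical_risk(c(1, -1), c(1, 1), n = 4, kind = "location")  # 4
#' @export
empirical_risk <- function(mu_hat, sigma_hat = NULL, n, kind = "location",
                           degenerate = NULL) {
  if (is.list(mu_hat) && !is.null(mu_hat[[1]]$mu_hat)) {
    ests <- mu_hat
    mu_hat <- vapply(ests, `[[`, numeric(1), "mu_hat")
    sigma_hat <- vapply(ests, `[[`, numeric(1), "sigma_hat")
    degenerate <- vapply(ests, `[[`, logical(1), "degenerate")
  }
  stopifnot(length(mu_hat) >= 1, n >= 1)
  kind <- match.arg(kind, c("location", "location_scale"))
  if (is.null(degenerate)) degenerate <- rep(FALSE, length(mu_hat))
  keep <- !degenerate
  loss <- n * mu_hat[keep]^2
  if (kind == "location_scale") {
    stopifnot(!is.null(sigma_hat))
    loss <- loss + n * (sigma_hat[keep] - 1)^2
  }
  structure(mean(loss), se = stats::sd(loss) / sqrt(length(loss)),
            n_excluded = sum(!keep))
}

## One study cell: all estimators on shared samples.
## Returns rows of the risk table.
sim_study_cell <- function(n, spec, reps, platform = c("affy", "illumina"),
                           s_interval = c(0, 0.05), k = 3L) {
  platform <- match.arg(platform)
  d <- draw_contaminated_matrix(n, reps, spec)
  X <- d$X
  start <- median_mad_mat(X)
  ml <- mle_mat(X)
  ic <- rmx_ic_for_n(n, s_interval[1], s_interval[2])
  rx <- rmx_kstep_mat(X, ic, k = k, mu0 = start$mu, sig0 = start$sig)
  ests <- list(
    mle = list(mu = ml$mu, sig = ml$sig,
               deg = ml$sig == 0, label_sc = "mle"),
    median = list(mu = start$mu, sig = start$sig,
                  deg = start$sig == 0, label_sc = "median_mad"),
    rmx = list(mu = rx$mu, sig = rx$sig, deg = rx$floored, label_sc = "rmx"))
  if (platform == "affy") {
    bw <- biweight_mat(X)
    ests$biweight <- list(mu = bw, sig = start$sig,
                          deg = start$sig == 0, label_sc = "tumad")
  } else {
    il <- illumina_mat(X)
    ests$illumina <- list(mu = il$mu, sig = il$sig,
                          deg = il$n_used < 2, label_sc = "illumina")
  }
  rows <- lapply(names(ests), function(nm) {
    e <- ests[[nm]]
    rl <- empirical_risk(e$mu, e$sig, n = n, kind = "location",
                         degenerate = e$deg)
    rls <- empirical_risk(e$mu, e$sig, n = n, kind = "location_scale",
                          degenerate = e$deg)
    data.frame(
      estimator = c(nm, e$label_sc),
      contaminant = contaminant_label(spec$contaminant),
      s = spec$s,
      risk_kind = c("location", "location_scale"),
      value = c(as.numeric(rl), as.numeric(rls)),
      se = c(attr(rl, "se"), attr(rls, "se")),
      n_excluded = c(attr(rl, "n_excluded"), attr(rls, "n_excluded")),
      redraws = d$redraws)
  })
  do.call(rbind, rows)
}

default_affy_contaminants <- function() list(
  contaminant_normal(0, 3), contaminant_t(3), contaminant_cauchy(0, 1),
  contaminant_normal(3, 1), contaminant_normal(10, 1),
  contaminant_dirac(1.51), contaminant_dirac(1000))

default_illumina_contaminants <- function() list(
  contaminant_normal(0, 3), contaminant_t(3), contaminant_cauchy(0, 1),
  contaminant_normal(3, 1), contaminant_normal(10, 1),
  contaminant_dirac(3), contaminant_dirac(1000))

run_study <- function(n, reps, seed, contaminants, s_values, platform,
                      s_interval = c(0, 0.05), k = 3L) {
  stopifnot(reps >= 100)
  ## solve the rmx IC before touching the RNG: the radius search is
  ## deterministic and must not perturb the simulation stream
  invisible(rmx_ic_for_n(n, s_interval[1], s_interval[2]))
  set.seed(seed)
  rows <- list()
  for (cont in contaminants) {
    for (s in s_values) {
      spec <- contamination_spec(s, cont)
      rows[[length(rows) + 1L]] <-
        sim_study_cell(n, spec, reps, platform, s_interval, k)
    }
  }
  out <- do.call(rbind, rows)
  out$reps <- reps
  out$seed <- seed
  class(out) <- c("risk_table", "data.frame")
  out
}

#' Monte-Carlo robustness study, Affymetrix design
#'
#' Reproduces the design of the probe-level study: sample size `n = 11`
#' (the modal probe-pair count), ideal model N(0,1), contaminants N(0,9),
#' t3, Cauchy(0,1), N(3,1), N(10,1), Dirac(1.51) and Dirac(1000) at sizes
#' `s` in {0.01, 0.02, 0.04}, estimators MLE, median (with MAD), MAS-variant
#' Tukey biweight (with standardized MAD as "tumad") and the rmx 3-step.
#' Values are `n` times the empirical MSE about (0, 1).
#'
#' @param reps Monte-Carlo replications per cell (>= 100).
#' @param seed RNG seed; the returned table is reproducible given the seed.
#' @param s_values contamination sizes.
#' @param contaminants list of [contaminants].
#' @return A `risk_table` data frame with columns estimator, contaminant,
#'   s, risk_kind, value, se, n_excluded, redraws, reps, seed.
#' @examples
#' \donttest{run_affy_study(500, seed = 1, s_values = 0.01)}
#' @export
run_affy_study <- function(reps = 1e5, seed = 123,
                           s_values = c(0.01, 0.02, 0.04),
                           contaminants = default_affy_contaminants()) {
  run_study(11L, reps, seed, contaminants, s_values, platform = "affy")
}

#' Monte-Carlo robustness study, Illumina design
#'
#' As [run_affy_study()] but with `n = 30` (higher bead redundancy), the
#' Dirac measure at 3 replacing Dirac(1.51) (the approximately least
#' favorable contamination for the skipped mean), and the Illumina default
#' summarizer replacing the Tukey biweight.
#'
#' @inheritParams run_affy_study
#' @return A `risk_table` data frame.
#' @export
run_illumina_study <- function(reps = 1e5, seed = 123,
                               s_values = c(0.01, 0.02, 0.04),
                               contaminants = default_illumina_contaminants()) {
  run_study(30L, reps, seed, contaminants, s_values, platform = "illumina")
}

## Look up one cell of a risk table.
risk_cell <- function(tab, estimator, contaminant, s, kind) {
  i <- tab$estimator == estimator & tab$contaminant == contaminant &
    abs(tab$s - s) < 1e-12 & tab$risk_kind == kind
  stopifnot(sum(i) == 1L)
  tab[i, ]
}
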