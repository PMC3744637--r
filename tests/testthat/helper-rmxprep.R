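## shared helpers for the test suite

## expectation of f(x) under N(0,1) by adaptive quadrature, independent of
## the package's internal Gauss-Legendre machinery
nm_quad <- function(f, rel.tol = 1e-12) {
  stats::integrate(function(x) f(x) * stats::dnorm(x), -Inf, Inf,
                   rel.tol = rel.tol, abs.tol = 1e-13,
                   subdivisions = 500L)$value
}

## side-condition residuals of a solved IC, recomputed with stats::integrate
ic_residuals_quad <- function(ic) {
  z2 <- ic$z[2]; A1 <- ic$A[1, 1]; A2 <- ic$A[2, 2]; b <- ic$b; r <- ic$r
  nrm <- function(x) sqrt((A1 * x)^2 + (A2 * (x^2 - 1 - z2))^2)
  w <- function(x) pmin(1, b / nrm(x))
  c(eq14 = nm_quad(function(x) pmax(nrm(x) - b, 0)) - r^2 * b,
    eq15 = nm_quad(function(x) (x^2 - 1 - z2) * w(x)),
    eq16_11 = A1 * nm_quad(function(x) x^2 * w(x)) - 1,
    eq16_22 = A2 * nm_quad(function(x) (x^2 - 1 - z2)^2 * w(x)) - 1)
}

## n x empirical MSE of a vector of estimates about (0, 1)
risk_of <- function(mu, sig = NULL, n) {
  loss <- n * mu^2
  if (!is.null(sig)) loss <- loss + n * (sig - 1)^2
  c(value = mean(loss), se = stats::sd(loss) / sqrt(length(loss)))
}

## draw an M-column matrix of contaminated samples, shared across estimators
draw_study_matrix <- function(n, reps, s, contaminant, seed) {
  set.seed(seed)
  rmxprep:::draw_contaminated_matrix(n, reps,
                                     contamination_spec(s, contaminant))$X
}
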