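## Oracle used below: the worst-case MSE tr E psi psi' + r^2 b^2 is
## minimized directly over the clipped-form parameters (z2, A1, A2, b) with
## the membership constraints E psi = 0 and E psi Lambda' = I imposed by a
## quadratic penalty, using adaptive quadrature throughout — a route to the
## optimum sharing nothing with the package's fixed-point solver.
oracle_objective <- function(par, r, penalty) {
  z2 <- par[1]; A1 <- exp(par[2]); A2 <- exp(par[3]); b <- exp(par[4])
  nrm <- function(x) sqrt((A1 * x)^2 + (A2 * (x^2 - 1 - z2))^2)
  w <- function(x) pmin(1, b / nrm(x))
  tr <- nm_quad(function(x) pmin(nrm(x), b)^2)
  cons <- c(
    nm_quad(function(x) A2 * (x^2 - 1 - z2) * w(x)),      # E psi_scale = 0
    nm_quad(function(x) A1 * x^2 * w(x)) - 1,             # E psi Lambda' = I
    nm_quad(function(x) A2 * (x^2 - 1 - z2) * (x^2 - 1) * w(x)) - 1)
  tr + r^2 * b^2 + penalty * sum(cons^2)
}

test_that("r = 0 returns the classical influence curve", {
  ic <- solve_optimal_ic(0)
  expect_equal(ic$z, c(0, 0))
  expect_equal(ic$A, diag(c(1, 0.5)))
  expect_equal(ic$b, Inf)
  expect_equal(ic$as_cov_trace, 1.5)
  expect_equal(unname(evaluate_ic(ic, 2)[1, ]), c(2, (4 - 1) / 2))
  expect_equal(max_mse(ic, 0), 1.5)
  expect_equal(max_mse(ic, 0.5), Inf)
})

test_that("clipping bound decreases with the radius", {
  expect_lt(solve_optimal_ic(0.5)$b, solve_optimal_ic(0.25)$b)
  expect_lt(solve_optimal_ic(1)$b, solve_optimal_ic(0.5)$b)
})

test_that("side-condition residuals are below 1e-7 across radii (independent quadrature)", {
  for (r in c(1e-3, 0.05, 0.25, 0.5, 1, 2, 5, 10)) {
    res <- ic_residuals_quad(solve_optimal_ic(r))
    expect_lt(max(abs(res)), 1e-7)
  }
})

test_that("solved ICs are Fisher consistent: E psi Lambda' = I within 1e-6", {
  for (r in c(0.1, 0.5, 2)) {
    ic <- solve_optimal_ic(r)
    psi <- function(x, j) evaluate_ic(ic, x)[, j]
    M <- matrix(c(
      nm_quad(function(x) psi(x, 1) * x),
      nm_quad(function(x) psi(x, 1) * (x^2 - 1)),
      nm_quad(function(x) psi(x, 2) * x),
      nm_quad(function(x) psi(x, 2) * (x^2 - 1))), 2, 2, byrow = TRUE)
    expect_lt(max(abs(M - diag(2))), 1e-6)
  }
})

test_that("fixed-point solution matches a direct minimizer of the worst-case MSE", {
  r <- 0.5
  ic <- solve_optimal_ic(r)
  ## independent penalized minimization started from the classical IC, not
  ## from the solver's answer; the penalty weight is raised in stages
  par <- c(0, 0, log(0.5), log(3))
  for (pen in c(1e2, 1e5, 1e8)) {
    fit <- stats::optim(par, oracle_objective, r = r, penalty = pen,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-13, maxit = 3000))
    par <- fit$par
  }
  expect_lt(abs(par[1] - ic$z[2]), 1e-3)
  expect_lt(abs(exp(par[2]) - ic$A[1, 1]), 1e-3)
  expect_lt(abs(exp(par[3]) - ic$A[2, 2]), 1e-3)
  expect_lt(abs(exp(par[4]) - ic$b), 2e-3)
  ## penalized objective at its optimum equals the solver's max MSE
  expect_lt(abs(fit$value - max_mse(ic, r)), 1e-4)
})

test_that("evaluate_ic is clipped, odd in location and even in scale", {
  ic <- solve_optimal_ic(0.5)
  x <- seq(0.1, 5, by = 0.1)
  psi_p <- evaluate_ic(ic, x)
  psi_m <- evaluate_ic(ic, -x)
  expect_true(all(sqrt(rowSums(psi_p^2)) <= ic$b + 1e-12))
  expect_equal(psi_m[, 1], -psi_p[, 1])
  expect_equal(psi_m[, 2], psi_p[, 2])
  ## large x attains the bound
  expect_equal(sqrt(sum(evaluate_ic(ic, 50)^2)), ic$b, tolerance = 1e-10)
})

test_that("max MSE equals the supremum over Dirac contaminations (scan oracle)", {
  ic <- solve_optimal_ic(0.4)
  r <- 0.4
  ## contaminating Dirac at x shifts the estimator by r * psi(x)
  ## asymptotically; the MSE is tr-cov + r^2 |psi(x)|^2, maximized in x
  xs <- seq(-100, 100, by = 0.05)
  scan <- ic$as_cov_trace + r^2 * rowSums(evaluate_ic(ic, xs)^2)
  expect_equal(max(scan), max_mse(ic, r), tolerance = 1e-6)
  ## strictly increasing in r for finite b
  expect_lt(max_mse(ic, 0.2), max_mse(ic, 0.4))
})

test_that("relative MSE is 1 at the matching radius and > 1 otherwise", {
  for (r in c(0.1, 0.5, 1)) {
    expect_equal(rel_mse(solve_optimal_ic_cached(r), r), 1, tolerance = 1e-9)
  }
  expect_gt(rel_mse(solve_optimal_ic_cached(0.1), 1), 1)
  ## rel_mse at (s = 0.2, r = 0.6) equals the ratio of two direct max_mse
  ## computations
  ic_s <- solve_optimal_ic_cached(0.2)
  expect_equal(rel_mse(ic_s, 0.6),
               max_mse(ic_s, 0.6) / max_mse(solve_optimal_ic_cached(0.6), 0.6))
})

test_that("IC components are continuous in the radius", {
  comps <- function(r) {
    ic <- solve_optimal_ic_cached(r)
    c(ic$z[2], ic$A[1, 1], ic$A[2, 2], ic$b)
  }
  for (r in c(0.1, 0.5, 1.5)) {
    d_coarse <- max(abs(comps(r + 1e-2) - comps(r)))
    d_fine <- max(abs(comps(r + 1e-3) - comps(r)))
    ## a 10x finer step moves the components ~10x less: no jumps
    expect_lt(d_fine, max(0.2 * d_coarse, 1e-4))
  }
  ## classical limit: max MSE tends to the classical trace 1.5 as r -> 0
  expect_equal(max_mse(solve_optimal_ic(1e-3), 1e-3), 1.5, tolerance = 0.01)
})

test_that("radius-minimax IC beats every candidate on a 50-point grid", {
  ## interval [0, 0.166]: s in [0, 0.05] at n = 11
  rmx <- radius_minimax_ic(0, 0.166)
  expect_gte(rmx$s_star, 1e-4)
  expect_lte(rmx$s_star, 0.166)
  rs <- seq(1e-4, 0.166, length.out = 50)
  mm_opt <- vapply(rs, function(r) max_mse(solve_optimal_ic_cached(r), r),
                   numeric(1))
  sup_rel <- function(s) {
    ic <- solve_optimal_ic_cached(s)
    max((ic$as_cov_trace + rs^2 * ic$b^2) / mm_opt)
  }
  sup_grid <- vapply(rs, sup_rel, numeric(1))
  expect_lte(rmx$sup_rel_mse, min(sup_grid) + 1e-6)
  ## strictly better than both endpoint ICs
  expect_lt(rmx$sup_rel_mse, sup_rel(1e-4))
  expect_lt(rmx$sup_rel_mse, sup_rel(0.166))
})

test_that("degenerate radius interval returns the single-radius IC", {
  out <- radius_minimax_ic(0.5, 0.5 + 1e-6, grid_points = 5L, tol = 1e-7)
  expect_equal(out$s_star, 0.5, tolerance = 1e-5)
  ic <- solve_optimal_ic(0.5)
  expect_equal(out$ic$b, ic$b, tolerance = 1e-3)
})

test_that("ICs round-trip through JSON", {
  ic <- solve_optimal_ic(0.7)
  txt <- ic_to_json(ic)
  ic2 <- ic_from_json(txt)
  expect_equal(ic2$z, ic$z)
  expect_equal(ic2$A, ic$A)
  expect_equal(ic2$b, ic$b)
  expect_equal(evaluate_ic(ic2, c(-3, 0.5, 8)), evaluate_ic(ic, c(-3, 0.5, 8)))
})
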