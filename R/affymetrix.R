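## MAS 5.0-variant probe-set summarization for PM/MM probe-level data:
## ideal match, specific background, probe values, signal log values, with
## a pluggable location(-scale) estimator (Tukey biweight or rmx).

#' Probe-set data
#'
#' One probe set's perfect-match and mismatch intensity vectors.
#'
#' @param probe_set_id identifier.
#' @param pm,mm numeric vectors of strictly positive intensities, equal
#'   length >= 1.
#' @return An object of class `"probe_set_data"`.
#' @export
probe_set_data <- function(probe_set_id, pm, mm) {
  pm <- as.numeric(pm); mm <- as.numeric(mm)
  if (length(pm) != length(mm) || length(pm) < 1L)
    stop("pm and mm must have equal length >= 1")
  if (any(!is.finite(pm)) || any(!is.finite(mm)) || any(pm <= 0) || any(mm <= 0))
    stop("intensities must be finite and strictly positive")
  structure(list(probe_set_id = as.character(probe_set_id), pm = pm, mm = mm),
            class = "probe_set_data")
}

#' Parameters of the MAS 5.0-variant summarization
#'
#' @param tau1 contrast tau, the specific-background threshold below which
#'   the smooth third branch of the ideal match applies (default 0.03).
#' @param tau2 scale tau controlling how fast that branch flattens
#'   (default 10).
#' @param delta floor for the background-corrected value, default
#'   \eqn{2^{-20}} (numerical stability; caps the probe value at -20 on the
#'   log2 scale).
#' @param estimator `"biweight"` (the MAS 5.0 default) or `"rmx"`.
#' @param s_interval contamination-size interval for the rmx estimator.
#' @param k k-step iterations for the rmx estimator.
#' @return An object of class `"mas_params"`.
#' @examples
#' mas_params(estimator = "rmx")
#' @export
mas_params <- function(tau1 = 0.03, tau2 = 10, delta = 2^-20,
                       estimator = c("biweight", "rmx"),
                       s_interval = c(0, 0.05), k = 3L) {
  stopifnot(tau1 > 0, tau2 > 0, delta > 0)
  structure(list(tau1 = tau1, tau2 = tau2, delta = delta,
                 estimator = match.arg(estimator),
                 s_interval = s_interval, k = as.integer(k)),
            class = "mas_params")
}

## location(-scale) estimate used by the pipeline; probe sets with fewer
## than 3 pairs fall back to median (and MAD where possible) for rmx.
mas_location <- function(x, params) {
  if (params$estimator == "biweight")
    return(list(loc = tukey_biweight_mas(x), scale = NA_real_))
  if (length(x) < 3L) {
    sc <- if (length(x) >= 2L) median_mad(x)$sigma_hat else NA_real_
    return(list(loc = stats::median(x), scale = sc))
  }
  est <- rmx_kstep(x, params$s_interval[1], params$s_interval[2], params$k)
  list(loc = est$mu_hat, scale = est$sigma_hat)
}

#' Specific background of a probe set
#'
#' Robust location of the log-ratios \eqn{\log_2(PM_j / MM_j)} within a
#' probe set, using the estimator selected in `params`.
#'
#' @param ps a [probe_set_data()].
#' @param params a [mas_params()].
#' @return The specific background SB (log2 scale).
#' @examples
#' specific_background(probe_set_data("a", c(4, 8), c(2, 4)), mas_params())
#' @export
specific_background <- function(ps, params = mas_params()) {
  stopifnot(inherits(ps, "probe_set_data"))
  mas_location(log2(ps$pm / ps$mm), params)$loc
}

#' Ideal match value of one probe pair
#'
#' The background quantity subtracted from PM, guaranteed below PM: when
#' MM < PM the mismatch itself is used; otherwise PM is scaled down by
#' \eqn{2^{-SB}} if the specific background is informative (SB > tau1), or
#' by the smooth floor \eqn{2^{-\tau_1 / (1 + (\tau_1 - SB)/\tau_2)}} when
#' it is not (SB <= tau1). The two non-trivial branches agree at SB = tau1,
#' so the ideal match is continuous in SB.
#'
#' @param pm,mm intensities of the pair, > 0.
#' @param sb specific background of the probe set.
#' @param params a [mas_params()].
#' @return The ideal match IM > 0; vectorized over pairs.
#' @examples
#' ideal_match(10, 3, sb = 1)   # 3: the mismatch
#' ideal_match(10, 10, sb = 1)  # 5: PM * 2^-SB
#' @export
ideal_match <- function(pm, mm, sb, params = mas_params()) {
  stopifnot(all(pm > 0), all(mm > 0))
  smooth_exp <- params$tau1 / (1 + (params$tau1 - sb) / params$tau2)
  ifelse(mm < pm, mm,
         ifelse(sb > params$tau1, pm * 2^(-sb), pm * 2^(-smooth_exp)))
}

#' Probe value of one probe pair
#'
#' \eqn{\log_2 \max\{PM - IM, \delta\}}: the log2 background-corrected
#' intensity, floored at `delta` so a non-positive difference maps to
#' \eqn{\log_2 \delta = -20} at the default.
#'
#' @param pm perfect-match intensity > 0.
#' @param im ideal match > 0.
#' @param params a [mas_params()].
#' @return The probe value PV (log2 scale); vectorized.
#' @examples
#' probe_value(10, 2)  # 3
#' @export
probe_value <- function(pm, im, params = mas_params()) {
  stopifnot(all(pm > 0), all(im > 0))
  log2(pmax(pm - im, params$delta))
}

#' Summarize one probe set to an expression value
#'
#' Runs the full per-probe-set chain: specific background from the
#' log-ratios, ideal match and probe value per pair, then the selected
#' estimator's location of the probe values as the signal log value. With
#' the rmx estimator the joint scale estimate is kept as a per-probe-set
#' dispersion diagnostic.
#'
#' @param ps a [probe_set_data()].
#' @param params a [mas_params()].
#' @return A one-row data frame: `probe_set_id`, `sb`, `sig_log_val`,
#'   `scale_est` (NA for the biweight), `n_pairs`.
#' @examples
#' summarize_probe_set(probe_set_data("a", c(40, 80, 60), c(20, 30, 35)))
#' @export
summarize_probe_set <- function(ps, params = mas_params()) {
  stopifnot(inherits(ps, "probe_set_data"))
  sb <- specific_background(ps, params)
  im <- ideal_match(ps$pm, ps$mm, sb, params)
  pv <- probe_value(ps$pm, im, params)
  est <- mas_location(pv, params)
  data.frame(probe_set_id = ps$probe_set_id, sb = sb,
             sig_log_val = est$loc, scale_est = est$scale,
             n_pairs = length(ps$pm))
}

#' Summarize a probe-level table chip-wide
#'
#' @param table data frame with columns `probe_set_id`, `PM`, `MM`, one row
#'   per probe pair. Malformed rows (missing or non-positive intensities)
#'   are skipped and reported via a message and the `n_skipped` attribute.
#' @param params a [mas_params()].
#' @return A data frame with one row per probe set, in first-appearance
#'   order.
#' @examples
#' tab <- data.frame(probe_set_id = "a", PM = c(40, 80, 60), MM = c(20, 30, 35))
#' summarize_chip(tab)
#' @export
summarize_chip <- function(table, params = mas_params()) {
  stopifnot(all(c("probe_set_id", "PM", "MM") %in% names(table)))
  bad <- !is.finite(table$PM) | !is.finite(table$MM) |
    is.na(table$probe_set_id) | table$PM <= 0 | table$MM <= 0
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    ids <- unique(table$probe_set_id[bad])
    message(sprintf("skipping %d malformed probe-level row(s) in probe set(s): %s",
                    sum(bad), paste(utils::head(ids, 5), collapse = ", ")))
    table <- table[!bad, , drop = FALSE]
  }
  ids <- unique(table$probe_set_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    i <- table$probe_set_id == id
    summarize_probe_set(probe_set_data(id, table$PM[i], table$MM[i]), params)
  }))
  attr(out, "n_skipped") <- sum(bad)
  out
}
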