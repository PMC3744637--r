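## Bead-level to bead-summary aggregation on the log2 scale, with the rmx
## estimator as the default and the Illumina skipped mean/SD plus the simple
## textbook estimators (mean/SD, median/MAD, trimmed, winsorized) as
## comparators.

#' Bead-type data
#'
#' One bead type's background-subtracted intensities; values <= 0 can occur
#' after background subtraction and are dropped (with a count) before the
#' log2 transform.
#'
#' @param bead_type_id identifier.
#' @param intensities numeric vector, non-empty.
#' @return An object of class `"bead_type_data"`.
#' @export
bead_type_data <- function(bead_type_id, intensities) {
  intensities <- as.numeric(intensities)
  if (length(intensities) < 1L || any(!is.finite(intensities)))
    stop("intensities must be non-empty and finite")
  structure(list(bead_type_id = as.character(bead_type_id),
                 intensities = intensities),
            class = "bead_type_data")
}

bead_methods <- c("rmx", "illumina", "mean", "median", "trim", "winsorize")

## location/scale of log2 values for each comparator method
bead_locscale <- function(x, method, s_interval, k, trim_frac = 0.05) {
  n <- length(x)
  switch(method,
    rmx = {
      e <- rmx_kstep(x, s_interval[1], s_interval[2], k)
      list(mu = e$mu_hat, sd = e$sigma_hat, n_used = n, deg = e$degenerate)
    },
    illumina = {
      e <- illumina_summary(x)
      list(mu = e$mu_hat, sd = e$sigma_hat, n_used = e$n_used,
           deg = e$degenerate)
    },
    mean = list(mu = mean(x), sd = stats::sd(x), n_used = n,
                deg = stats::sd(x) == 0),
    median = {
      e <- median_mad(x)
      list(mu = e$mu_hat, sd = e$sigma_hat, n_used = n, deg = e$degenerate)
    },
    trim = {
      lo <- stats::quantile(x, trim_frac, type = 7)
      hi <- stats::quantile(x, 1 - trim_frac, type = 7)
      xt <- x[x >= lo & x <= hi]
      list(mu = mean(xt), sd = stats::sd(xt), n_used = length(xt),
           deg = length(xt) < 2 || stats::sd(xt) == 0)
    },
    winsorize = {
      lo <- stats::quantile(x, trim_frac, type = 7)
      hi <- stats::quantile(x, 1 - trim_frac, type = 7)
      xw <- pmin(pmax(x, lo), hi)
      list(mu = mean(xw), sd = stats::sd(xw), n_used = n,
           deg = stats::sd(xw) == 0)
    },
    stop("unknown method: ", method))
}

#' Summarize one bead type
#'
#' Drops non-positive intensities (counted, not shifted — the log-normal
#' model only applies to positive values), log2-transforms the remainder,
#' and applies the selected estimator. Fewer than 3 usable beads yields a
#' degenerate summary carrying the median (or the single value).
#'
#' @param bt a [bead_type_data()].
#' @param method one of `"rmx"`, `"illumina"`, `"mean"`, `"median"`,
#'   `"trim"`, `"winsorize"` (trim/winsorize: 5% per tail, symmetric).
#' @param s_interval,k rmx parameters, see [rmx_kstep()].
#' @return A one-row data frame: `bead_type_id`, `mean_log2`, `sd_log2`,
#'   `n_beads_used`, `n_dropped_nonpositive`, `degenerate`.
#' @examples
#' summarize_bead_type(bead_type_data("bt1", c(2, 4, 8)), method = "illumina")
#' @export
summarize_bead_type <- function(bt, method = "rmx", s_interval = c(0, 0.05),
                                k = 3L) {
  stopifnot(inherits(bt, "bead_type_data"))
  method <- match.arg(method, bead_methods)
  pos <- bt$intensities > 0
  n_dropped <- sum(!pos)
  x <- log2(bt$intensities[pos])
  if (length(x) < 3L) {
    mu <- if (length(x)) stats::median(x) else NA_real_
    return(data.frame(bead_type_id = bt$bead_type_id, mean_log2 = mu,
                      sd_log2 = NA_real_, n_beads_used = length(x),
                      n_dropped_nonpositive = n_dropped, degenerate = TRUE))
  }
  e <- bead_locscale(x, method, s_interval, k)
  data.frame(bead_type_id = bt$bead_type_id, mean_log2 = e$mu,
             sd_log2 = e$sd, n_beads_used = e$n_used,
             n_dropped_nonpositive = n_dropped, degenerate = e$deg)
}

#' Summarize a bead-level table array-wide
#'
#' @param table data frame with columns `bead_type_id`, `intensity`.
#'   Malformed rows (missing values) are skipped and counted.
#' @param method,s_interval,k see [summarize_bead_type()].
#' @return A data frame with one row per bead type, in first-appearance
#'   order, with attribute `n_skipped`.
#' @examples
#' tab <- data.frame(bead_type_id = rep("bt1", 4), intensity = c(2, 4, 8, 16))
#' summarize_array(tab, method = "illumina")
#' @export
summarize_array <- function(table, method = "rmx", s_interval = c(0, 0.05),
                            k = 3L) {
  stopifnot(all(c("bead_type_id", "intensity") %in% names(table)))
  bad <- !is.finite(table$intensity) | is.na(table$bead_type_id)
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    message(sprintf("skipping %d malformed bead-level row(s)", sum(bad)))
    table <- table[!bad, , drop = FALSE]
  }
  ids <- unique(table$bead_type_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    x <- table$intensity[table$bead_type_id == id]
    summarize_bead_type(bead_type_data(id, x), method, s_interval, k)
  }))
  attr(out, "n_skipped") <- sum(bad)
  out
}
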