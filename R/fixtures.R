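## Synthetic fixture generation for both pipelines. The generators emulate
## the structure both summarizers assume: approximately log-normal raw
## intensities within a probe set / bead type, i.e. normal log2 values
## around a true level, optionally contaminated by a gross-error model.
## Ground truth is attached so pipeline tests are closed-loop without any
## external dataset.

#' Fixture generator configuration
#'
#' @param n_groups probe sets (Affymetrix) or bead types (Illumina).
#' @param group_size probe pairs per set / beads per type: a single number
#'   or a `c(min, max)` range sampled uniformly (Illumina default 15-65,
#'   the typical span of bead counts per type).
#' @param log2_expression_range range of true log2 signal levels, sampled
#'   uniformly per group.
#' @param noise_sd_log2 SD of the per-observation normal log2 noise.
#' @param sb_true true specific background (Affymetrix: mean log2(PM/MM)).
#' @param contamination a [contamination_spec()], or `NULL` for clean data;
#'   a contaminated observation's log2 intensity is replaced by a draw from
#'   the contaminant (so `contaminant_dirac(16)` is a stuck value at
#'   \eqn{2^{16}}).
#' @param seed RNG seed.
#' @return An object of class `"fixture_config"`.
#' @examples
#' fixture_config(n_groups = 5, group_size = 11, seed = 1)
#' @export
fixture_config <- function(n_groups = 20, group_size = c(15, 65),
                           log2_expression_range = c(6, 12),
                           noise_sd_log2 = 0.25, sb_true = 2,
                           contamination = NULL, seed = 1) {
  stopifnot(n_groups >= 1, all(group_size >= 1),
            diff(range(log2_expression_range)) >= 0, noise_sd_log2 >= 0,
            is.null(contamination) || inherits(contamination, "contamination_spec"))
  structure(list(n_groups = as.integer(n_groups),
                 group_size = as.integer(group_size),
                 log2_expression_range = log2_expression_range,
                 noise_sd_log2 = noise_sd_log2, sb_true = sb_true,
                 contamination = contamination, seed = seed),
            class = "fixture_config")
}

draw_group_sizes <- function(cfg) {
  if (length(cfg$group_size) == 1L) {
    rep(cfg$group_size, cfg$n_groups)
  } else {
    sample(seq(cfg$group_size[1], cfg$group_size[2]), cfg$n_groups,
           replace = TRUE)
  }
}

## log2 values around a true level, possibly contaminated; a contaminated
## draw replaces the whole log2 value (gross errors such as a stuck bead at
## 2^16 do not scale with the true signal), so e.g. contaminant_dirac(16)
## models raw intensity 2^16 regardless of level
fixture_log2 <- function(m, level, cfg) {
  v <- level + stats::rnorm(m, 0, cfg$noise_sd_log2)
  if (!is.null(cfg$contamination) && cfg$contamination$s > 0) {
    flag <- stats::runif(m) < cfg$contamination$s
    if (any(flag))
      v[flag] <- draw_contaminant(cfg$contamination$contaminant, sum(flag))
  } else flag <- rep(FALSE, m)
  list(v = v, flags = flag)
}

#' Generate a synthetic Affymetrix probe-level fixture
#'
#' Per probe set a true log2 signal is drawn uniformly from the configured
#' range; `PM = 2^(signal + noise)` and `MM = 2^(signal - sb_true + noise)`
#' with independent per-pair normal log2 noise (so
#' `log2(PM/MM) = sb_true + noise difference`), optionally contaminated.
#'
#' @param cfg a [fixture_config()].
#' @return A data frame `probe_set_id`, `PM`, `MM`, with the ground truth
#'   (per-set `signal_log2`, `sb_true`) attached as attribute `truth` (a
#'   data frame suitable for a sidecar TSV).
#' @examples
#' fx <- generate_affy_fixture(fixture_config(n_groups = 3, group_size = 11))
#' attr(fx, "truth")
#' @export
generate_affy_fixture <- function(cfg = fixture_config(group_size = 11)) {
  stopifnot(inherits(cfg, "fixture_config"))
  set.seed(cfg$seed)
  sizes <- draw_group_sizes(cfg)
  signal <- stats::runif(cfg$n_groups, cfg$log2_expression_range[1],
                         cfg$log2_expression_range[2])
  ids <- sprintf("ps%04d", seq_len(cfg$n_groups))
  rows <- lapply(seq_len(cfg$n_groups), function(i) {
    n <- sizes[i]
    pm <- fixture_log2(n, signal[i], cfg)
    mm <- fixture_log2(n, signal[i] - cfg$sb_true, cfg)
    data.frame(probe_set_id = ids[i], PM = 2^pm$v, MM = 2^mm$v)
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- data.frame(probe_set_id = ids,
                                   signal_log2 = signal,
                                   sb_true = cfg$sb_true,
                                   n_pairs = sizes)
  out
}

#' Generate a synthetic Illumina bead-level fixture
#'
#' Per bead type a true log2 level is drawn uniformly; intensities are
#' `2^(level + noise)` with optional contamination of the log2 noise.
#'
#' @param cfg a [fixture_config()].
#' @return A data frame `bead_type_id`, `intensity` with attribute `truth`.
#' @examples
#' fx <- generate_bead_fixture(fixture_config(n_groups = 3, seed = 2))
#' head(fx)
#' @export
generate_bead_fixture <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  set.seed(cfg$seed)
  sizes <- draw_group_sizes(cfg)
  level <- stats::runif(cfg$n_groups, cfg$log2_expression_range[1],
                        cfg$log2_expression_range[2])
  ids <- sprintf("bt%04d", seq_len(cfg$n_groups))
  rows <- lapply(seq_len(cfg$n_groups), function(i) {
    n <- sizes[i]
    v <- fixture_log2(n, level[i], cfg)
    data.frame(bead_type_id = ids[i], intensity = 2^v$v)
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- data.frame(bead_type_id = ids, level_log2 = level,
                                   n_beads = sizes)
  out
}
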