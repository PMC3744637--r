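# rmxprep

Optimally robust summarization of gene-expression intensities with
radius-minimax (rmx) estimators of normal location and scale.

Expression preprocessing aggregates many raw intensities into one value per
feature: the PM/MM probe pairs of an Affymetrix probe set, or the replicate
beads of an Illumina bead type. The estimators classically used there —
Tukey's biweight one-step (MAS 5.0) and the skipped mean/SD (median ± 3
standardized MAD rejection; BeadStudio) — have high breakdown points but
give away 15–50% efficiency against the best robust estimators. This
package is for bioinformaticians and statisticians who want that efficiency
back without giving up robustness: it provides the optimally robust
estimator for the normal location-scale model under contamination
neighborhoods, drop-in summarization pipelines for both platforms, a
model-adequacy module, and a Monte-Carlo engine that quantifies the gains.

## The estimator

Within a probe set / bead type the log2 intensities are modeled as
N(μ, σ²) with a fraction *s* of gross errors (the contamination
neighborhood (1−s)·N(μ,σ²) + s·Q, s = r/√n). An asymptotically linear
estimator with influence curve ψ has worst-case asymptotic mean squared
error

    maxMSE(ψ, r) = tr E[ψψ'] + r² (sup|ψ|)²

and the optimal ψ for known radius r has the clipped form
ψ\* = A(Λ − z)·min{1, b/|A(Λ − z)|} with Λ(x) = (x, x² − 1)' the normal
scores; `solve_optimal_ic()` finds (z, A, b) by a fixed point over the
defining side conditions. Since the radius is unknown in practice,
`radius_minimax_ic()` picks the ψ minimizing the worst case over a radius
interval of relMSE(ψₛ, r) = maxMSE(ψₛ, r)/maxMSE(ψᵣ\*, r). The estimator
itself (`rmx_kstep()`) is a 3-step construction from median/MAD —
S⁽ʲ⁾ = S⁽ʲ⁻¹⁾ + mean ψ(xᵢ; S⁽ʲ⁻¹⁾) — inheriting their 50% breakdown point,
with the asymptotic radius s·√n replaced by a simulation-calibrated
finite-sample correction (`finite_sample_correction()`).

## Worked example

Thirty beads around log2 level 8 (SD 0.25), plus two aberrant beads at
log2 intensities 12.4 and 16:

```r
library(rmxprep)
set.seed(1)
x <- c(rnorm(28, mean = 8, sd = 0.25), 12.4, 16)

rmx_kstep(x)
#> rmx estimate: mu_hat = 8.04813, sigma_hat = 0.261741 (n_used = 30)
illumina_summary(x)
#> illumina estimate: mu_hat = 8.04397, sigma_hat = 0.212735 (n_used = 27)
mle_fit(x)
#> mle estimate: mu_hat = 8.43445, sigma_hat = 1.62515 (n_used = 30)
```

The MLE is dragged 0.4 log2 units off target and its scale explodes; both
robust estimators stay on target. The difference shows up in *efficiency*:
across the bundled Monte-Carlo designs the rmx estimator's risk is 15–20%
below the biweight's in every probe-level study cell, and below the skipped
mean's where the contamination is inconspicuous (t₃ tails, N(3,1) shifts).

Model adequacy before trusting the normal model:

```r
min_kolmogorov_distance(x)
#> minimum Kolmogorov distance: 0.0674183 (floor 0.0166667) at mu = 8.06553, sigma = 0.234919
```

Pipelines operate on plain tables (`probe_set_id, PM, MM` /
`bead_type_id, intensity`):

```r
fx <- generate_bead_fixture(fixture_config(n_groups = 5, seed = 1))
summarize_array(fx, method = "rmx")          # bead summaries, log2 scale
tab <- run_affy_study(reps = 2e4, seed = 1)  # n = 11 robustness study
```

A command-line interface with the same operations ships in `inst/cli/rmxprep`
(subcommands `summarize-affy`, `summarize-illumina`, `simulate`, `minkd`,
`make-fixture`, `calibrate-correction`).

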