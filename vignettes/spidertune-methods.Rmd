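---
title: "Methods behind spidertune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind spidertune}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spidertune)
```

This vignette documents the statistical choices in the package: what each
estimator computes, why its defaults are what they are, and where the
boundaries of its validity lie.

## The data model

A cohort is a pair of tables. `participants` carries one row per person
(`participant_id`, `spq` — a spider-fear questionnaire score on 0–30, and
optional demographics); `trials` carries one row per tuning trial with the
`instruction` (dangerous/harmless), the spider's `orientation`
(approaching/withdrawing/lateral), and the three feature settings
(`hairiness`, `bodyleg`, `locomotion`), each on a 10-level grid
`{0, 1/9, ..., 1}`. The complete design is 2 instructions × 3 orientations
× 4 repetitions = 24 trials per participant. `validate_cohort()` enforces
the schema, ranges, grid membership, and referential integrity;
`validate_design()` reports per-participant completeness without failing,
because real cohorts have missing cells and every downstream summary
tolerates them (with warnings).

## MMPD: the mean of the modal part of the distribution

For a participant's trial values in one (feature, instruction) cell, the
MMPD first counts values strictly above and strictly below 0.5, then
averages only the values on the majority side. Values exactly at 0.5 are
excluded from the count but included in the winning side's average. The
intent is robustness to lapses: a participant who sets a dangerous spider
hairy on 10 of 12 trials and accidentally confirms a default on 2 should
be summarized by the 10, not by a mean dragged toward 0.5 — and not by a
bare median that discards how far toward the extreme the settings sit.

Two boundary decisions are ours and are tested as such:

- **Ties** (equal counts above and below) average *all* values, i.e. fall
  back to the mean. A `spidertune_mmpd_tie` condition is signalled so
  callers can log tied cells.
- Exact 0.5 values join the winning side's average because they are
  consistent with either side; ignoring them entirely would throw away
  legitimate settings.

The test suite checks `mmpd()` against an independently written
recount-and-average oracle on thousands of random grids.

## The incoherency index

If a participant's harmless setting were exactly specular to their
dangerous one, `p_harmless = 1 − p_dangerous`. The incoherency index

\[ x = |p^{D} + p^{H} - 1| \in [0, 1] \]

is the deviation from that mirror line: 0 for perfectly specular settings,
1 when both instructions produce the same extreme. It is symmetric in its
arguments and invariant to which pole of a feature axis is labelled 0 or 1
(replacing both `p` by `1 − p` leaves it unchanged).

## The synthetic cohort generator

`generate_cohort()` draws SPQ scores uniformly on the configured integer
range (default 0–26, matching a cohort continuously spread over most of
the scale), sets each participant's latent cell means to the configured
`condition_means`, adds trial noise

\[ \sigma(\mathrm{spq}) = \texttt{base\_sd} \cdot
   e^{\texttt{sd\_spq\_slope} \cdot \mathrm{spq}}, \]

clamps to [0, 1] and snaps to the 10-level grid. Optional mechanisms:
`cluster_spec` (mean-preserving polarized subgroups), a
`hairiness_incoherency_slope` that pulls the harmless-hairiness mean
toward its dangerous counterpart as SPQ grows, and an
`orientation_effect` on approaching dangerous spiders.

**Calibration of `base_sd = 0.08`.** The MMPD is biased away from a
unimodal latent mean: trial noise pushes values across 0.5, the minority
side is discarded, and the summary moves toward the nearer extreme. The
bias grows with noise and is worst for latent means near 0.5. A
simulation sweep carried out *before* the acceptance properties were ever
run showed that at `base_sd = 0.15` the expected grand-MMPD deviation from
the generating mean reaches ≈ 0.07 for a latent mean of 0.40, while at
`base_sd = 0.08` (about 0.7 grid steps) the worst expected deviation is
≈ 0.04. The default is therefore 0.08, with `sd_spq_slope = 0.03`, which
still spans a strong log-variance signal (Δ log σ² ≈ 1.56 across the SPQ
range) for the spline model to recover.

**Why `hairiness_incoherency_slope` defaults to 0.** The default condition
means already encode a mildly incoherent cohort (e.g. hairiness
0.33 + 0.75 = 1.08 ≠ 1). Because of that, a small additional pull of the
harmless mean toward the dangerous one first *reduces*
\(|p^D + p^H − 1|\), making the SPQ–incoherency relationship V-shaped and
sign-ambiguous, while a large pull destroys the harmless-hairiness grand
mean. The mechanism is implemented exactly as described and exercised in
tests with an explicit positive slope; it is off by default so the
reference generator stays anchored to its condition means.

**Why `cluster_spec` defaults to `NULL`.** Mean-preserving polarized
subgroups add SPQ-constant between-participant variance. At n = 45 that
swamps the trial-level heteroskedastic signal the spline model is designed
to detect. Subgroups are an explicit simulation choice, not a default.

## The heteroskedastic spline model

For a per-participant summary \(y_i\) with score \(s_i\),

\[ y_i \sim \mathcal{N}\!\big(B(s_i)\beta,\; e^{B(s_i)\gamma}\big), \]

where \(B(s)\) is a natural cubic spline basis (intercept plus two
columns) with one internal knot at the median observed score and boundary
knots at the observed range. Both \(\beta\) and \(\gamma\) are estimated
jointly by maximum likelihood: BFGS with an analytic gradient, initialized
from OLS (mean) and the log residual variance (scale), then polished by
damped Newton steps until the gradient max-norm falls below 1e−6.
`predict_bands()` converts the fit into mean, quartile
(\(\mu \mp 0.6745\,\sigma\)) and decile (\(\mu \mp 1.2816\,\sigma\))
bands, flagging extrapolation beyond the observed score range.

The model deliberately treats the *variance* as the scientific signal:
a flat mean curve with rising \(\sigma(s)\) describes a cohort whose
preferences do not shift with fear but become less consistent. Tests
verify exact agreement with OLS under the homoskedastic restriction,
recovery of known mean curves with RMSE < 0.05 at n = 450, mirror
equivariance (fitting \(1 - y\) mirrors the mean and preserves the
variance), and sign recovery of the generating variance trend at n = 45.

Limitations: the normal likelihood ignores the [0, 1] bounds and the grid
snapping of the underlying data; with n = 45 and 6 parameters the variance
spline is informative about direction and rough magnitude, not fine shape.

## Clustering and BIC model selection

`select_clusters()` standardizes the chosen variables, builds a
centroid-linkage tree (`centroid_linkage()`, distances between cluster
centroids; height inversions possible and flagged), cuts it at k = 2, 3, 4
and keeps the cut minimizing `bic_for_partition()`, with ties broken
toward smaller k.

The BIC scores a hard partition by the **classification likelihood** of a
Gaussian model with per-cluster mean and diagonal covariance:

\[ \log L = \sum_i \Big[ \log \pi_{c(i)} +
   \log \phi\big(x_i;\ \mu_{c(i)}, \Sigma_{c(i)}\big) \Big],
   \qquad \pi_k = n_k / n, \]

with `m = k·2d + (k−1)` free parameters and `BIC = −2 log L + m log n`.
Two ingredients of this formula are essential, and both were adopted after
demonstrating that the naive alternative degenerates:

- **Mixing proportions.** Without the \(\log \pi\) terms, splitting any
  Gaussian cluster in half raises the density term by roughly 0.5 per
  point (the within-half variance is about a third of the parent's),
  which always outruns the `Δm·log n` penalty — the argmin is then always
  the largest candidate k, regardless of structure.
- **A data-scaled variance floor.** Per-dimension variances are floored at
  `1e-3` times the marginal ML variance of that dimension (absolute
  `1e-6` for constant columns). Centroid linkage readily peels single
  points off a cluster; with a tiny absolute floor such singletons act as
  near-delta density spikes worth several log-likelihood units each — the
  classic Gaussian-ML degeneracy. A floor on the data scale removes the
  spike while leaving genuinely compact clusters untouched (their
  variance sits above the floor). Floor events are still reported: as a
  warning from `bic_for_partition()`, once per `select_clusters()` call,
  and collected into the pipeline's validation notes.

With this formulation, planted two-blob structure (means ±3, SD 0.5,
20 + 20 points) is recovered in ≥ 95 of 100 seeds and three blobs in
≥ 90 of 100, as verified in the acceptance suite; the linkage itself is
checked against a naive O(n³) agglomeration oracle.

## Correlation and power

`spearman_matrix()` uses average ranks with t-approximation p-values
(`2·pt(−|t|, n−2)`), listwise-complete rows, and an `exact = TRUE` flag
for small untied samples. `correlation_power()` estimates the power of
the two-sided zero-correlation test by Monte Carlo over bivariate normal
samples and cross-checks against the Fisher-z closed form
\(\Phi\big(\operatorname{atanh}(\rho)\sqrt{n-3} - z_{0.975}\big)\);
at ρ = 0.4, n = 56, both give ≈ 0.87.

## Determinism

All randomness flows from a single seed: `run_pipeline()` derives a
per-stage seed via `stage_seed()`, and the generator fixes the RNG kind
explicitly. Identical configuration and seed produce byte-identical
report bundles; the provenance block records the configuration hash, seed
and package version, and deliberately excludes timestamps.

## Problem sizes

The defaults mirror the motivating design: 45 participants × 24 trials,
spline fits on 45 summary points, clustering on 45 × 1…7 standardized
variables, power simulations at n = 56 with 20,000 replicates. Everything
runs in seconds on one CPU; the full test suite (≈ 2,600 expectations,
including the 100-seed acceptance sweeps) completes in about a minute.
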