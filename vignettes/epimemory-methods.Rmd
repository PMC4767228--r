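---
title: "Models and methods behind epimemory"
author: "epimemory authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epimemory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimemory)
```

# The scientific problem

Fibroblasts cultured from different sampling locations of the same donor —
the scalp and the dura mater are the motivating pair — remain morphologically
indistinguishable after multiple passages, yet can retain an "epigenetic
memory" of where they came from. `epimemory` implements the statistical
pipeline for detecting that memory in Illumina 450k-style DNA methylation
data at several spatial scales, for quantifying location-dependent
variability and aging, and for reading the epigenetic differences out in the
transcriptome. Because the interesting properties of such a pipeline are
calibration and recovery rather than any single dataset, the package ships a
synthetic-data generator with known ground truth; every claim the test suite
makes is a claim about what the pipeline does to data whose answer is known.

# The models

## Probe-level location effects

For probe $i$ and sample $j$, normalized proportion methylation (the beta
value, in $[0,1]$) is modeled as

$$y_{ij} = \alpha_i + \beta_i\,\mathrm{Loc}_j + \zeta_i\,\mathrm{SV}_j + \varepsilon_{ij},$$

where $\mathrm{Loc}_j$ is the binary sampling location (dura = 0, scalp = 1),
so $\alpha_i$ is the dura level and $\beta_i$ the scalp--dura difference, and
$\mathrm{SV}_j$ are surrogate variables (default 6) absorbing unmodeled
structure — batch, residual cell heterogeneity, and the donor pairing, which
this stage deliberately leaves implicit. The model is fitted by OLS per
probe; variances are moderated by empirical Bayes (a scaled inverse
chi-squared prior whose hyperparameters $d_0, s_0^2$ are estimated by
matching moments of the log residual variances to a scaled F; $d_0$ is
reported infinite when the observed spread does not exceed chi-squared
sampling noise, in which case the prior scale is the mean variance). The
moderated $t$ uses $\tilde s_i^2 = (d_0 s_0^2 + d\,s_i^2)/(d_0+d)$ on $d +
d_0$ degrees of freedom, two-sided, with Benjamini–Hochberg q-values.

Surrogate variables are estimated by a two-step scheme: SVD of the residual
matrix after removing the design fit, then re-estimation of each candidate
direction from the probes most associated with it, followed by
orthogonalization against the design (so the protected location effect can
never leak into the SVs), centering and orthonormalization. The scheme is
deterministic given a seed; when the dimension is requested as `"auto"` it
is chosen by a permutation (parallel-analysis) criterion comparing residual
singular values with row-permuted ones.

## Regions and blocks

Differentially methylated regions are found by bump hunting: probes are
clustered at a 500 bp gap; within a cluster, maximal runs of probes whose
location coefficients all exceed the cutoff (default 0.1, i.e. a 10%
methylation difference) in the same direction form candidates, summarized by
their area $\sum_i |\beta_i|$. Significance is a family-wise error rate
estimated from a residual bootstrap: the null model (no location term) is
fitted, whole per-sample residual vectors are resampled with replacement —
preserving the correlation of nearby probes — the coefficient vector is
re-estimated, and the maximum candidate area recorded; over $B$ iterations
this yields the null sample, and
$\mathrm{FWER} = (\#\{\text{null} \ge \text{area}\}+1)/(B+1)$ (the add-one
estimator, never exactly zero). Calls use FWER $\le$ 0.1 with $B = 1000$ in
production (tests use smaller $B$; the estimator is the same).

Long-range blocks reuse the identical machinery at a collapsed scale:
open-sea probes (island, shore and shelf probes never contribute) are
clustered at 500 bp, each cluster averaged per sample, the collapsed units
grouped at 250 kb, and the candidate/bootstrap/FWER steps run on the
collapsed matrix. No smoothing is applied to coefficients before the cutoff
at either scale; the candidate definition is the pure run scanner, kept
exact so it can be verified against a brute-force oracle.

## Differential variability

Variance differences between locations are tested per probe with Levene's
test: a one-way ANOVA F on absolute deviations from the group center, mean
centering by default (median centering — Brown–Forsythe — is a flag).
Because beta values are bounded, mean shifts inflate variance mechanically,
so probes already significant for mean differences (q < 0.05) are removed
first and the variability FDR is recomputed on the retained set. The
direction bookkeeping (`more_variable_in`) follows the larger mean absolute
deviation.

## Paired age divergence

Within-donor differences $\Delta y_{ij} = y^{scalp}_{ij} - y^{dura}_{ij}$
(only donors with both locations; the analysis is sized by donors, not
samples) are regressed on donor age:

$$\Delta y_{ij} = \gamma_i + \delta_i\,\mathrm{Age}_j + \zeta\,\mathrm{SV}_j + \varepsilon_{ij},$$

with 3 surrogate variables estimated on the difference matrix by default.
$\gamma_i$ is the location difference at birth and $\delta_i$ its change per
year; the Wald test on $\delta_i$ uses the t reference with the OLS residual
degrees of freedom (exact at these small donor counts, unlike the normal),
and divergence is called at q < 0.10. On SV-free data this difference model
is algebraically identical to the location-by-age interaction of the paired
two-location model, which the tests assert to 10 decimal places. Post-hoc
per-location slopes (and percent change per decade, slope × 1000) are
computed by OLS within each location; significant probes are clustered by
k-means (fixed seed, 20 restarts) on the z-scored concatenation of their
fitted scalp and dura trajectories over an 18-point age grid, default k = 8.
Standardizing the concatenated pair — rather than each half — preserves the
relative level of the two trajectories, which is what distinguishes
diverging from converging shapes.

## Distances, integration, variants

Methylome distances are plain Euclidean distances on the beta scale; joint
analysis of several datasets first intersects probes, drops SNP/sex-chromosome
probes, and applies a single stratified quantile normalization across all
samples. Distance-set contrasts use a Welch t plus an F variance ratio; the
pairwise distances in a set share samples and are not independent, so these
p-values are labeled descriptive. Gene-set separation is a permutation test
(mean between-group distance on the set versus equal-size random sets, add-one
p-value). Methylation–expression association is the simple bivariate linear
model per probe–gene pair within 5 kb (boundary inclusive, arithmetic
distance to the nearest edge); directionality is summarized per island
relation × methylation bin (cutpoints 0.2/0.8) with the exact binomial test;
2×2 enrichments use Pearson's chi-squared with Yates' continuity correction
(the correction floored at zero when $|O-E| < 0.5$). Chromatin-state
enrichment is coverage-based: basepair overlap fractions of features versus
a background across an 18-state segmentation, folds beyond 1.5× highlighted,
sex and mitochondrial chromosomes dropped. Variant filtering applies the
post-call thresholds — depth < 20, any of the four bias-test p-values
< 0.05, inbreeding-test p < 0.05, or homozygote-bias p > 0.05 — and
annotates every removal with all triggered reasons.

# The synthetic-data generator

`simulateStudy()` emulates the statistical structure of a paired scalp/dura
fibroblast cohort. Its defaults are the study conditions the pipeline is
calibrated against: 11 donors aged 0.1–85 years (ages drawn to span the
range, endpoints included), two samples per donor, 22% of probes carrying a
location effect of |Δβ| = 0.2 with balanced signs, planted multi-probe
regions (|Δβ| = 0.2, ≥3 contiguous probes) and long-range open-sea blocks
(|Δβ| = 0.15 across ≥200 kb), variance-inflated loci (SD × 2, 83% of them
scalp-inflated — the share reported for such cohorts), age-divergent probes
with |δ| = 0.003/yr following eight trajectory archetypes
(diverge-from-equal, converge-to-equal, scalp-only drift, dura-only drift,
each in two directions), donor-level batches shifting 30% of probes, and
expression for a configurable number of genes coupled to a nearby probe at a
target correlation.

Design choices worth knowing:

* **Noise is drawn on the logit scale** and inverse-transformed, with the
  logit SD scaled by $1/(\mu(1-\mu))$ so the beta-scale SD matches
  `noiseSd`. This keeps betas strictly inside (0,1) without clipping and
  reproduces the mean–variance damping near the boundaries. Variance-inflated
  loci are planted away from extreme baselines (0.1–0.9), where the logistic
  saturation would otherwise compress the planted SD ratio.
* **Intensities are back-computed** from beta at a global scale of 10,000
  with per-sample multiplicative jitter and the offset-100 convention, so the
  quantile normalizer has a real per-sample scale to remove.
* **Island geography is generated, not labeled**: islands are laid down as
  intervals and each probe's island/shore/shelf/open-sea label is derived by
  interval arithmetic (shore 0–2 kb, shelf 2–4 kb — the standard array
  convention). A small fraction of probes sits on chrX and a small fraction
  carries a SNP flag, so the filtering stage has real work.
* **Residual noise level**: the within-group beta SD of real cohorts is not
  something the generator can know; the default 0.03 is chosen for
  testability (effects of 0.1–0.2 are comfortably detectable at n = 10–11
  donors, as in the emulated design), not as an estimate of any dataset.
* **Infeasible configurations error before clipping**: any planted
  combination that would push an expected beta outside [0.02, 0.98] is an
  argument error, never silently truncated.
* The `SimulationConfig` fields `nVarloci`, `varScalpShare`, `blockEffect`
  and `batchFraction` parameterize effects the scenario needs but whose
  counts are scenario-specific; their defaults (300 loci, 0.83, 0.15, 0.3)
  are the emulated study conditions.

What the generator does **not** emulate: probe-type chemistry biases beyond
the stratum label, spatial autocorrelation of noise along the array,
cell-composition drift, genotype-driven outliers, or non-linear age
trajectories. Passing tests therefore demonstrate calibration and recovery
under a clean paired design — they do not certify behavior under artifacts
the generator does not model.

# Numerical and procedural choices

* Stratified quantile normalization uses strata = design type × island
  relation; ties receive the mean of the tied order statistics; beta is
  recomputed with offset 100. The transform is idempotent and equalizes
  within-stratum sorted intensities exactly. In `jointNormalize` probe
  filtering precedes normalization so the returned object satisfies that
  property exactly.
* OLS residual variances below machine epsilon are treated as exact fits
  (t = 0) rather than producing noise-ratio t statistics.
* The trigamma inverse for the moderation hyperparameters is solved by
  Newton iteration to 1e-10 relative precision.
* k-means clustering uses 20 restarts under a fixed seed; all stochastic
  stages (generation, bootstrap, permutation tests, SV dimension selection)
  run under caller-supplied seeds and are bit-reproducible.
* Regions are reported 1-based inclusive internally; BED export converts to
  0-based half-open.
* The bootstrap resamples whole per-sample residual vectors (not per-probe
  scalars): inter-probe correlation is what makes region areas large under
  the null, and destroying it would anti-conservatively shrink the null.
  Whether to resample per probe instead is a known sensitivity; the
  per-sample choice is the conservative one for spatially correlated arrays.

# Calibration scales used by the tests

The test suite and `scripts/acceptance.R` size their simulations for a
single CPU: 100 replicates × 5,000 probes for probe-level null calibration
and power; 100 (50 in the script) × 3,000 probes with B = 100 for the
global-null region FWER; one 200 kb block at Δβ = 0.15 for block recovery;
five replicates × 5,000 probes at 20 donors for the Levene size. The
mean-centered Levene F is known to run liberal at small group sizes
(~0.058 at n = 10 on normal data) and to be sensitive to skew; on bounded
beta values with logit-scale noise the size at 20 donors per group sits at
about 0.060, right at the upper edge of the 0.05 ± 0.01 calibration band —
users wanting a strictly conservative variant should use median centering
(Brown–Forsythe), available via `center = "median"`. Then 2,000 of 5,000 loci
variance-inflated for the direction-share round trip (the share check
targets bookkeeping among detectable loci, so the planted fraction is set
high enough that true calls dominate false positives at n = 11); 100 × 200
probes for the age-slope recovery; and 400 planted probes for archetype
clustering. These sizes are the package's stated calibration conditions,
chosen before the checks were run and not tuned afterwards.

# Known limitations

* The probe-level model follows the unpaired location + SVs form; donor
  pairing is absorbed by the surrogate variables rather than modeled as a
  random effect.
* Distance-contrast p-values ignore the dependence between pairwise
  distances; they rank and describe, but are not exact tests.
* The empirical-Bayes moderation is the untrended, unweighted form; no
  mean-variance trend is fitted.
* Age trajectories are linear in age, both in the generator and in the
  fitted summaries; real trajectories need not be.
* The block finder targets array-like designs with sparse open-sea probes;
  it is not a WGBS-scale block caller.
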