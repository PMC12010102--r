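---
title: "Methods: from bullying victimization to short-video addiction, in behavior and brain"
author: "svapath package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from bullying victimization to short-video addiction, in behavior and brain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svapath)
```

## Scope and model

`svapath` implements an analysis chain for studying how bullying
victimization (BV) relates to short-video addiction (SVA) in
adolescents, with negative affect (NA) as the hypothesized mediator,
and how SVA relates to spontaneous brain activity measured at rest.
The chain has four statistical layers:

1. **Psychometrics** — sum-scoring of 6-point Likert scales (a 10-item
   SVA scale; verbal, physical and relational bullying subdimensions;
   10-item negative/positive affect scales), gender-specific addiction
   cutoffs (score ≥ 33 for females, ≥ 31 for males), Cronbach's α,
   Harman's single-factor test, correlation tables, pooled-variance t
   tests and 2×2 χ².
2. **Mediation** — the three-regression single-mediator model with a
   percentile case bootstrap for the indirect effect.
3. **ALFF** — the amplitude of low-frequency fluctuations of a BOLD-like
   series: mean square-root spectral power in 0.01–0.1 Hz.
4. **IS-RSA** — inter-subject representational similarity: does the
   dissimilarity structure of subjects' SVA item profiles match the
   dissimilarity structure of their voxel-wise ALFF patterns, parcel by
   parcel?

Because the behavioral and imaging data this design targets are not
publicly deposited, the package ships generators that emulate both
layers with *known* ground truth; every downstream stage is validated
against planted structure rather than against irreproducible empirical
effect sizes.

## The questionnaire generator

`gen_questionnaire_cohort()` draws standardized latent variables

$$\mathrm{BV}\sim N(0,1),\qquad
\mathrm{NA}=a\,\mathrm{BV}+e_1,\qquad
\mathrm{SVA}^{*}=c'\,\mathrm{BV}+b\,\mathrm{NA}+e_2,$$

with residual variances solved analytically so that every latent has
unit variance. This choice makes the path coefficients equal to
(partial) correlations, so closed-form oracles apply: the implied
correlations are $r_{\mathrm{BV,NA}}=a$,
$r_{\mathrm{BV,SVA}}=c=c'+ab$ and $r_{\mathrm{NA,SVA}}=b+ac'$
(`implied_latent_cor()`). Defaults $a=0.4$, $b=0.3$, $c'=0.18$ give a
moderate partial mediation of the size typically reported for
affect-mediated pathways to behavioral addictions.

Bullying subdimension latents load 0.9 on the common BV factor (survey
instruments for bullying victimization report subscale–total
correlations around 0.88–0.96, which this loading reproduces). Each
item is `loading × latent + noise` with unit total variance (default
loading 0.8, a strong-instrument value consistent with the α ≈ 0.85–0.95
internal consistencies such scales report), then discretized to 1..6 by
**equiprobable normal thresholds**. Equiprobable cuts make item
marginals uniform, maximizing item information and avoiding floor
effects that nothing in the target design documents; discretization is
monotone, so higher latent values give stochastically higher responses.
Gender is Bernoulli (default female proportion 0.5915, matching the
cohort the package emulates) and independent of the latents — gender
differences are a reporting target, not a generative claim here.
Positive affect is generated as an unrelated latent: it is scored but
not analyzed, mirroring the intended analysis battery.

Each generator uses one local RNG stream, seeded at `seed + offset`
(offset 0 for the questionnaire generator, 101 for the resting-state
generator) and restoring the caller's RNG state on exit, so identical
seeds give byte-identical outputs regardless of surrounding code.

One visible consequence of uniform item marginals: sum scores center at
$3.5k$ (35 for a 10-item scale), higher than the means real
addiction-scale cohorts report, so with the default cutoffs the
addicted stratum is larger than in typical survey data. Subgroup
analyses on generated cohorts are therefore tests of machinery, not of
realistic prevalence.

What the generator does **not** emulate: differential item functioning,
missingness mechanisms, response styles (acquiescence, careless
responding), or the enrolment/exclusion process of a real survey.
Passing tests therefore certify the estimators, not robustness to those
real-data complications.

## The resting-state generator

`gen_resting_parcels()` simulates, per subject, `n_parcels × n_voxels ×
n_timepoints` series on the acquisition grid of a typical resting-state
protocol (TR = 2 s, 300 volumes, 200 parcels). Each voxel is a sum of
`n_components` (default 4) sinusoids with parcel-specific frequencies
drawn uniformly in 0.01–0.1 Hz, voxel-specific phases, plus white noise
(default SD 1). Two kinds of structure can be planted:

* **Amplitude coupling** (`coupling_parcels`): sinusoid amplitudes are
  scaled by $1+\gamma\,z(\mathrm{trait})$, so parcel-mean ALFF tracks
  the trait. Default $\gamma = 0.5$.
* **Pattern coupling** (`pattern_coupling_parcels`): each subject's
  voxel-amplitude pattern is a shared template modulated by a fixed
  random projection of the subject's standardized item profile, so
  behaviorally similar subjects get similar spatial patterns — the
  signature IS-RSA is designed to detect.

The voxel count per parcel (default 12) and the noise SD are the
package's own choices; they set a signal-to-noise regime in which a
planted coupling of 0.5 is comfortably detectable at n ≈ 100 subjects,
which is what the validation suite requires. Not emulated: spatial
autocorrelation between parcels, head motion, physiological noise,
scanner drift beyond the linear trend, and registration error. The
generator validates its grid: the 0.01–0.1 Hz band must contain at
least 3 DFT bins, otherwise the configuration is rejected.

`simulate_alff_maps()` streams the identical generative process one
subject at a time and reduces directly to amplitude maps; it is tested
to be numerically identical to `alff_maps(gen_resting_parcels(...))`
and exists so large simulations never hold all series in memory.

## Scoring and descriptive statistics

Scores are plain item sums (a 10-item 6-point scale spans 10–60); the
BV total is the sum of its subdimensions by construction. Missing any
item of a scale flags the subject and sets that scale's totals to `NA`
(listwise within scale; listwise per analysis downstream). The
addiction cutoff is **inclusive** (≥), following the source
instrument's convention. Bullying subdimension item counts are
configurable (defaults 4/4/4) because published descriptions of such
scales are not always arithmetically self-consistent about subscale
ranges.

Two conventions matter for reproducing published statistics and are
fixed deliberately:

* `pooled_t_test()` uses Student's pooled variance, not Welch — a
  printed df of $n_1+n_2-2$ identifies the pooled test.
* `chi_square_2x2()` applies no continuity correction — published
  group-by-gender χ² values are only reproduced exactly without it.

Harman's single-factor test is operationalized as the unrotated
principal-component extraction (eigendecomposition of the item
correlation matrix): factor count = eigenvalues above 1, first-factor
share = $100\,\lambda_1/p$, flagged above 40%. "Unrotated exploratory
factor analysis" is underspecified in most reports; PCA is the standard
operationalization of this bias check.

## Mediation estimation

`mediate()` fits `m ~ x`, `y ~ x + m`, `y ~ x` (plus optional
covariates in all three; the default is none, since mediation
covariates are rarely stated explicitly in the literature this package
mirrors). On any one sample the OLS identity $c = c' + ab$ holds to
machine precision — the suite asserts 1e-10. The indirect-effect CI is
a **percentile case bootstrap** (default 5000 resamples): subjects are
resampled with replacement, all paths refitted, and the
$\alpha/2,\,1-\alpha/2$ quantiles reported. Percentile is the common
default of the macro-style mediation tools this analysis implies;
resampling is by subject, stratified within subgroup analyses (each
subgroup is bootstrapped within itself). The proportion mediated is
$100\,ab/c$, reported as undefined when $|c|$ is numerically zero
rather than returning an unstable ratio.

`mediate_from_correlations()` carries the same algebra on a printed
correlation matrix: with standardized variables, $a=r_{xm}$,
$b=(r_{my}-r_{xy}r_{xm})/(1-r_{xm}^2)$, indirect $=ab$. This is how
the package cross-checks published mediation tables without raw data.

Validated properties (all in the test suite): parameter recovery within
±0.05 at n = 5000; 95% CI coverage of the true indirect effect between
93% and 97% over 500 replicates at n = 1000 with 1000 bootstrap
resamples each (replicate and bootstrap counts chosen to keep the
default validation run to a few minutes while leaving the binomial
uncertainty of the coverage estimate at about ±1%); CI width shrinking
like $1/\sqrt n$.

## ALFF

`compute_alff()` linearly detrends, takes the raw periodogram (no
taper — tapering is a preprocessing choice outside this scope and
would bias amplitudes of narrow-band signals), and averages the
single-sided amplitude $2|X_k|/N$ over bins with
$f_{\mathrm{low}} \le k/(N\,\mathrm{TR}) \le f_{\mathrm{high}}$,
edges inclusive. The **mean** (not sum) over bins keeps the measure
invariant to how many bins the band happens to contain. Linear
detrending is the minimum needed so slow drift does not swamp the
0.01 Hz bin; it makes ALFF of any affine series exactly 0 and is
idempotent. Analytic anchors used as oracles: a sinusoid of amplitude
$A$ at a bin frequency contributes $A$; white noise of SD $\sigma$ has
expected per-bin amplitude $\sigma\sqrt{\pi/N}$ (Rayleigh mean); an
out-of-band sinusoid leaks < 1% at the default grid. Maps may be
z-scored per subject (mean 0, SD 1 across all voxels); the default is
raw, since standardization before group analysis is an unsettled
convention and both paths are provided.

## Parcel-level association

`parcel_association()` replaces voxel-cluster inference (mixed-effects
GLM with Gaussian-random-field cluster correction), which requires
contiguous smoothed voxel grids that are out of scope, by the
parcel-mean regression `ALFF ~ trait + covariates`. The statistic is
the partial correlation obtained by residualizing both sides on the
covariates — numerically identical to the regression-coefficient t
test and easy to verify against `lm()`. Correction across parcels is
Bonferroni by default (Benjamini-Hochberg optional). Collinear
covariates are a hard error: silently dropping a confounder changes
the estimand.

## IS-RSA

The behavioral representational dissimilarity matrix (RDM) is the
Euclidean distance between subjects' 10-item SVA profiles; the neural
RDM per parcel is $1-r$ between subjects' voxel-wise ALFF patterns
(unsmoothed maps, as pattern analyses require). The map statistic is
the Pearson correlation between the two RDMs' **strictly lower
triangles in column-major order** — fixed and documented so every
reported r is reproducible bit for bit; the vector length is exactly
$n(n-1)/2$. Subject order must match between RDMs; mismatches are hard
errors, never silent reindexing.

Parametric p-values use the t transform with $n(n-1)/2$ pairs and
Bonferroni correction over parcels, for fidelity with common practice.
But pair distances sharing a subject are **dependent**, so this p is
anticonservative — demonstrated in the suite by a null simulation in
which the parametric one-sided test rejects well above its nominal
rate while `mantel_permutation()` (jointly permuting one RDM's rows
and columns, $p=(1+\#\{r_\pi\ge r\})/(1+n_\pi)$) stays calibrated and
uniform under the null. Pearson (not Spearman) RDM correlation is used
throughout, matching the analysis convention this package mirrors;
Anna-Karenina-style similarity models are deliberately not offered as
analysis defaults.

## Validation problem sizes

The validation suite runs, among others: implied-moment checks at
n = 5000 (tolerance 0.03); bootstrap coverage over 500 replicates of
n = 1000; Mantel calibration over 500 null replicates with 199
permutations each; and IS-RSA power over 100 replicates of 100
subjects × 200 parcels with pattern coupling planted in parcels 3 and
40 — requiring both planted parcels to lead the map and survive
Bonferroni in at least 80% of replicates. The power replicates use 12
voxels per parcel and 150 timepoints (28 in-band bins), sizes chosen so
the whole suite stays a matter of minutes while keeping every planted
effect in a realistic detectability regime.

## Pipeline and degenerate inputs

`run_pipeline()` executes simulate → score → stats → mediate → alff →
assoc → isrsa from a plain-text `key = value` config with `[section]`
headers. Unknown keys are rejected before any stage runs. Every
artifact embeds the stage, seed and a config checksum; identical
config+seed give byte-identical outputs, and a disabled stage's
artifact is only reused when its recorded checksum matches. Error
handling is typed (config / data / numerical), which the thin
command-line wrapper in `inst/scripts/run_pipeline.R` maps to exit
codes 2/3/4.

Degenerate inputs fail loudly by design: zero total-score variance
(α), singular item correlation (Harman), constant variables
(correlations), zero pooled variance (t), empty marginals (χ²),
rank-deficient designs (OLS), zero-variance ALFF patterns (neural
RDM), bands with no DFT bins (ALFF), and subject-order mismatches
(IS-RSA) all raise errors rather than returning quietly wrong numbers.

## Known limitations

* Parcel-level association is not a substitute for voxel-wise cluster
  inference; spatial extent information is lost by construction.
* The generators' noise models are intentionally simple; power and
  calibration results transfer to real data only to the extent that
  real noise resembles white noise plus band-limited oscillations.
* The parametric IS-RSA p-value is reported for comparability but
  should not be trusted near threshold; use the Mantel permutation p.
* Mediation here is associational: with cross-sectional data the
  "indirect effect" is a model-implied decomposition, not evidence of
  causal ordering.
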