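---
title: "Methods: trait spaces, representational similarity, and cross-classified models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait spaces, representational similarity, and cross-classified models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(traitspace)
```

## The scientific problem

Trait impressions from faces are intercorrelated, and the pattern of those
correlations — the *face-trait space* — need not be the same for every
social group a target belongs to. If perceivers' learned stereotypes about
a group shape how they read that group's faces, then the correlation
structure of abstract stereotype ratings for a group should track the
correlation structure of face ratings for the same group, over and above
whatever structure all groups share. `traitspace` implements that test at
two levels: aggregated across perceivers (representational similarity of
two stacked correlation structures) and within perceivers (a
cross-classified multilevel model linking each perceiver's own stereotype
associations to their own face-rating correlations).

## Units of correlation: why three different ones

A trait-pair correlation is only meaningful relative to the unit it is
computed over, and the three study designs force three different units,
made explicit by the `unit` argument of `trait_correlation_matrix()`:

* **targets** — in the aggregate face design every rater scores each face
  on a *single* trait (between-subjects trait assignment), so within-rater
  correlations do not exist. Ratings are first averaged to unweighted
  target-level means (`target_trait_means()`), and traits are correlated
  across targets within a group. Weighting targets by their number of
  contributing ratings was considered and rejected: unweighted means keep
  the estimand independent of the rating-allocation process, at the cost of
  slightly noisier cells (this can move third-decimal correlations).
* **perceivers** — abstract stereotype ratings are one value per perceiver,
  group, and trait; traits are correlated across perceivers within a group.
* **within_perceiver_targets** — in the within-perceiver design each
  perceiver rates every target on all traits, so each perceiver has their
  own trait-pair correlations per group, computed across that perceiver's
  targets.

Pairs with fewer than 3 complete units raise an error (a Pearson
correlation on 2 points is degenerate); pairs where a trait has zero
variance are marked missing, propagate as missing, and are dropped
pairwise downstream with a logged count — never imputed.

## Restructuring and ordering conventions

Per-group matrices are reduced to their strict upper triangle in *row-major
canonical order* of the declared trait list (pairs (1,2), (1,3), ..., (2,3),
...). The declared orders are `study1_traits()` (14 traits, 91 pairs) and
`study2_traits()` (6 traits, 15 pairs); group order is race-major
(`default_groups()`). No ordering is forced by the substance of the
analysis — Spearman's rho and the ANOVA are order-invariant — but a single
deterministic convention makes stacks alignable and outputs reproducible.

Fisher's transform z = atanh(r) is applied *after* vectorization, at the
pair level (`to_z_scale()`). Correlations of exactly ±1, which occur in
small within-perceiver samples, are clamped to 1 − 1e−12 in magnitude
rather than rejected, so a single degenerate pair does not abort a
perceiver; the resulting |z| ≈ 13.8 is finite and extreme, as it should be.

## The centered similarity statistic

Trait pairs differ enormously in their *shared* correlation level
(dominance–strength is high for every group). To keep that shared structure
from inflating the face–stereotype association, `compare_spaces()` first
subtracts each pair's mean across the six groups from each stack
*independently* (`center_by_pair_mean()`), then computes Spearman's rho on
the aligned rows. Spearman rather than Pearson is used because the data are
themselves (transformed) correlations — only monotone correspondence is
claimed. Double-centering is a state error, not a silent no-op.

Two interval methods are provided because the construction of a CI for this
statistic is not canonical: a seeded percentile bootstrap over rows
(default, 10,000 resamples) and the Fisher approximation
tanh(atanh ρ ± 1.96/√(n−3)). Both are reported with method metadata. The
bootstrap resamples rows of the centered stack; exact third-decimal
agreement with any particular published CI is not promised. A
within-pair permutation of group labels (`permutation_null()`) provides a
null distribution that respects the pair structure; its mean is zero by
exchangeability.

The two-sided p for Spearman's rho uses full permutation enumeration for
n ≤ 9 and the t approximation t = ρ√((n−2)/(1−ρ²)) otherwise; ties get
average ranks.

## Homogeneity ANOVA

`restructure_wide()` pivots the stack to a trait-pair × group matrix;
`rm_anova_2x3()` treats trait pairs as repeated-measures subjects in a
2 (gender) × 3 (race) within design. Sums of squares are computed in closed
form for the balanced design (each effect tested against its own
effect-by-subject interaction); rows with any missing cell are deleted
listwise with a logged count. Mauchly's W uses the likelihood-ratio form on
the covariance of orthonormal contrast scores with the standard chi-square
approximation (df = 2 for the race factor and for the interaction);
Greenhouse–Geisser epsilon comes from the eigenvalues of the same
covariance, and GG-corrected p values are reported alongside uncorrected
ones. A two-level factor has a single difference variance, so sphericity
holds trivially (ε = 1, Mauchly skipped). The implementation is
cross-checked against `car::Anova` in the test suite.

Two deliberate decisions:

* **Analysis scale.** The pipeline stacks Fisher-z values, but marginal
  means of trait-pair correlations are conventionally read on the r scale.
  Default behavior runs the ANOVA on z and reports marginal means
  back-transformed through tanh (SE by the delta method), flagged as such;
  `analysis_scale = "r"` reruns everything on raw correlations for exact
  replication attempts on that scale.
* **Reported N.** The number of repeated-measures units is the number of
  complete trait-pair rows (91 for 14 traits) and is reported as such. A
  published chi-square for this design citing N = 182 could not be derived
  from the 91-unit structure; the package reports its own N alongside its
  statistics rather than reproducing an unexplained value.

Marginal-mean standard errors are within-design descriptive SEs (SD across
trait-pair units of the unit-level mean over the relevant columns, divided
by √n, with t-based CIs) — each level gets its own SE, matching how such
tables are usually read.

## The cross-classified model

`build_mlm_dataset()` emits one row per perceiver × race group × trait
pair: the outcome y is the perceiver's Fisher-z face-rating correlation;
the predictor x is the perceiver's pairwise stereotype-likelihood rating
for the same group and pair. The two directed question forms are averaged
into one undirected value (direction is randomized at collection;
`average_directions = FALSE` keeps the first direction for sensitivity).
x is centered within perceiver (CWC), isolating each perceiver's
group-to-group and pair-to-pair stereotype variation from their overall
response level; the perceiver mean enters separately, grand-mean centered
so the fixed intercept remains the grand mean.

`fit_full()` estimates, by REML via lme4, fixed effects γ000 (grand mean),
γ010 (between-perceiver stereotype level), γ100 (the substantive
within-perceiver slope), with crossed random intercepts for perceiver and
trait pair and a random perceiver slope on the CWC predictor. The random
effects are mutually independent — the model's Level-2 specification lists
no intercept–slope covariance — with `correlated_slope = TRUE` available as
a sensitivity option. Fixed-effect inference is Wald (z); cross-classified
Satterthwaite df are out of scope. Singular fits with zero slope variance
are refit without the random slope and flagged (`slope_dropped`), a common
and benign outcome when slope heterogeneity is weak relative to the
correlation-sampling noise in y.

Intercept-only null models (`fit_null_crossclassified()`) partition
variance into ICCs; for the stereotype outcome, where three observations
(one per race) share each perceiver × pair cell, a perceiver-by-pair
interaction intercept is added. On balanced data these REML components
agree with the closed-form two-way ANOVA estimators (tested to 1e−6, with
optimizer tolerances tightened accordingly).

`r2_decomposition()` splits the model-implied total variance following the
integrated multilevel R² framework, with the random-intercept partition
adapted to carry *both* crossed intercept variances: fixed within
(γ100² · var(x_cwc)), fixed between (γ010² · var(x_pmean)), random slope
(τ11 · E[x_cwc²]), crossed intercepts (τ_perceiver + τ_pair), and residual;
the shares sum to one by construction. All five partitions are reported
separately: published summaries that pool "other" variance shares (e.g.
between-perceiver plus trait-pair differences) can be formed by adding the
intercept partition (and, if desired, the slope and between partitions),
and the package deliberately does not assert one pooling.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the statistical
skeleton the analyses assume, not any particular stimulus set or
demographic composition.

* A shared base correlation structure is drawn on the Fisher-z scale
  (mean 0.25, SD 0.25 across pairs — a positive-manifold trait space with
  realistic spread) and perturbed per group on the z scale
  (`sigma_group_scale`, default 0.15), so perturbation magnitude is
  comparable across base values. Each group's stereotype structure is the
  convex blend κ·Σ_face + (1−κ)·Σ_indep projected to the nearest valid
  correlation matrix (eigenvalue clipping + renormalization); κ = 1 returns
  Σ_face unchanged. κ is the coupling knob the recovery experiments sweep;
  the default 0.5 represents moderate coupling.
* Ratings are 4 + latent + perceiver bias + noise, rounded and clipped to
  1–7 when `likert` is set (the simplest monotone discretization; recovery
  tolerances must and do absorb this coarsening). Aggregate-study sizes
  default to the studied conditions: 3,619 face raters (one trait each,
  60–90 targets), 252 abstract raters, 873 targets over six groups.
* In within-perceiver mode (181 perceivers, 10 targets per race group),
  each perceiver's stereotype deviation has a response-style component
  (`stereo_bias_sd`), a pair-stable personal component (`stereo_idio_sd`),
  and a group-specific component (`stereo_group_sd`), which is what gives
  the stereotype outcome non-degenerate perceiver, pair, and interaction
  ICCs. Pairwise likelihood ratings map the personal z-scale association
  affinely from [−1.5, 1.5] to [1, 7] (rating = 4 + 2z, invertible on the
  interior) before discretization.
* **Slope planting.** The within-perceiver face structure is shifted by
  `slope_gamma × (emitted likelihood rating − 4)` — i.e. the slope is
  planted on the *observed*, direction-averaged predictor rather than an
  upstream latent value. This makes the planted slope the exact estimand of
  the fitted within-perceiver effect; the remaining recovery bias comes
  only from the outcome side (correlations measured from 10 coarse ratings
  per target are attenuated), which is the realistic part of the problem.
  Per-perceiver slopes vary around `slope_gamma` with SD `slope_sd`
  (default 0.02).
* **Calibration.** `halo_sd = 0.1` (a perceiver-level shift of all face-space
  z values) and the pair spread above were chosen once so that the variance
  shares of the simulated face-space correlations land near perceiver ICC
  ≈ .04 and trait-pair ICC ≈ .26 — the magnitudes such designs report.
  These defaults are calibration, not ground truth, and the recovery tests
  always compare against the generator's *recorded* truth, never against
  the calibration targets.
* One global seed fans out to named substreams (structures, targets,
  raters, ...), so subsets of a simulation are independently reproducible;
  identical config + seed gives byte-identical tables.

What passing recovery tests do **not** show: real rating data have
non-Gaussian latents, context and order effects, response styles beyond a
shift, and missingness mechanisms the generator does not emulate. The
generator validates the *estimators*, not the substantive theory.

## Problem sizes and runtime choices

The test suite validates recovery at the sizes the estimators are meant
for: crossed-ICC recovery at 200 perceivers × 15 pairs (20 replicates,
mean within ±0.05 of the planted 0.25), slope recovery at 181 perceivers
(20 seeds, mean within ±0.015 of the planted 0.05), Wald CI coverage at
100 replicates of 60 perceivers under a null slope (coverage in
[0.85, 0.99]), and monotonicity of the recovered similarity in κ over
{0, 0.25, 0.5, 0.75} with 20 replicates each at a reduced aggregate scale
(50 abstract raters, 560 face raters, 40 targets per group). Coverage is
checked under a zero planted slope because that is the calibration-critical
case — attenuation from outcome-side measurement cannot masquerade as
miscoverage there. Mauchly's test is checked for nominal size under
sphericity (400 null replicates).

## Known limitations

* Factor-analytic summaries of trait spaces (CFA/EFA/parallel analysis) are
  intentionally out of scope; the package is model-free at the trait-pair
  level.
* Exclusion counts that depend on response-time cleaning rules are not
  reproduced; `clean_participants()` exposes a predicate hook instead.
* Wald inference on fixed effects; no Bayesian estimation; no random slopes
  by trait pair.
* The bootstrap CI for the similarity statistic treats rows as
  exchangeable; rows within a group share estimation noise, so the CI is
  approximate (the permutation null, which respects pair structure, is the
  preferred significance device).
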