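---
title: "Trajectory, selection and fold-change methods in gutplane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory, selection and fold-change methods in gutplane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutplane)
```

`gutplane` analyses longitudinal shotgun-metagenomic profiles from
experimental-arthritis studies in rats: four groups (unimmunized normal
controls, an untreated adjuvant-induced arthritis model, and two treatment
arms) of seven animals, sampled at five timepoints (TP1, baseline, through
TP5, day 30). The pipeline starts from species-level relative-abundance
tables (MetaPhlAn-style, percent scale) and per-sample metadata (arthritis
score, body weight, serum cytokines), and from KO/module tables for the
functional arm. This vignette documents the statistical machinery, its
assumptions, and the design choices where the field leaves room.

## Health and disease planes

Community trajectories are summarized in Bray–Curtis principal-coordinate
space. `bray_curtis()` computes
$BC(x, y) = \sum_i |x_i - y_i| \,/\, \sum_i (x_i + y_i)$
between all sample pairs (a pair of all-zero samples is defined to have
distance 0), and `pcoa_embed()` performs classical metric scaling: the
matrix $-\tfrac12 D^2$ is double-centered and eigendecomposed, axes with
eigenvalue $\le 10^{-8}\times$ the largest are dropped (this removes the
negative-eigenvalue axes Bray–Curtis matrices produce; only the first three
coordinates are used downstream, so no Cailliez/Lingoes correction is
applied), and coordinates are scaled by $\sqrt{\lambda_k}$.

One **joint** embedding over all samples, groups and timepoints is used.
Distances from treated samples to both reference planes must live in a
single shared space; fitting a separate ordination per timepoint would make
the distances incommensurable across time.

At each timepoint the **healthy plane** (HP) is fitted to the normal-group
samples and the **disease plane** (DP) to the model-group samples, in the
first three principal coordinates. `fit_plane()` uses orthogonal (total)
least squares: the plane passes through the centroid and its normal is the
right singular vector with the smallest singular value, which minimizes the
sum of squared orthogonal residuals. This is the fit that makes "Euclidean
distance from a sample to the plane" well-defined as
$|(x - c) \cdot n|$ (`distance_to_plane()`); a regression of the third
coordinate on the first two would minimize vertical, not orthogonal,
residuals. The normal's sign is canonicalized (first nonzero component
positive) so serialized planes are reproducible. Matched HP/DP distances are
compared by a paired t test (`paired_t()`); two degenerate inputs are
handled explicitly (all-zero differences give $t=0, p=1$; constant nonzero
differences are reported as degenerate with $p=0$ rather than erroring).

`score_plane_correlation()` relates the arthritis score to the two
distances by semi-partial Spearman correlation adjusted for body weight and
group. Groups whose score does not vary (unimmunized controls, fixed at 0)
are excluded from this particular correlation: a block of tied zero ranks
carries no information about the score–distance relationship and only
dilutes the estimate.

## Selection of arthritis-correlated species

Before regression, species present in fewer than 5% of *rats* are removed
(`filter_prevalence()`; presence is counted per animal over all its
timepoints, because longitudinal samples of one animal are not independent
observations of carriage), and the profile is log10-transformed and
z-scored per species (`log_zscore()`). The pseudocount added before the log
is half the smallest nonzero value of the table — scale-aware rather than an
arbitrary constant — and the z-score uses the population (n-denominator)
standard deviation, fixed for determinism.

`fit_elastic_net_nn()` solves

$$\min_{\beta \ge 0,\,\beta_0}\;
\frac{1}{2n}\lVert y - \beta_0 - X\beta\rVert^2
+ \lambda\Big(\alpha\lVert\beta\rVert_1
+ \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\Big)$$

by cyclic coordinate descent with projected soft-thresholding (compiled
code with an active-set strategy; convergence when the largest coefficient
change in a sweep falls below $10^{-7}$). The nonnegativity bound restricts
the model to species whose abundance rises with the score. The L1/L2 mixing
defaults to $\alpha = 0.5$ and is exposed; results should be (and in our
simulations are) insensitive to moderate changes.

`repeated_cv_select()` implements the consensus scheme: ten repeats of a
five-fold shuffle split; for each of the 50 training portions an inner
five-fold cross-validation chooses $\lambda$ from a 100-value log grid
spanning four decades below $\lambda_{max}$ (the smallest $\lambda$ with an
all-zero solution), and one model is fitted on the training portion at the
chosen $\lambda$ — exactly 50 models. Models with fewer than five nonzero
coefficients are discarded, and a species is selected iff it is nonzero in
strictly more than 25 of the retained models.

The inner $\lambda$ is chosen by the **one-standard-error rule** (largest
$\lambda$ within one SE of the CV-minimum error), not the raw CV minimum.
On cohorts with a planted five-species signal among 200 species the CV
minimum admits on the order of five spuriously correlated species into the
consensus set per run, while the 1-SE rule keeps full sensitivity with
under one false selection per run on average; the raw minimum remains
available via `lambda_rule = "min"`.

All samples with a score — including the zero-scored controls — enter one
regression, matching a design in which the five timepoints are pooled.

## Fold-change significance

`normalize_to_reference()` divides each animal's abundance by the mean of
the reference (normal) group at the same timepoint (median available), with
the shared pseudocount guarding zeros; `log10_fc_vs_baseline()` then takes
each rat's log10 ratio against its own TP1 sample, so the statistic is a
within-animal trajectory. A change is called significant
(`call_significant()`) iff strictly more than 80% of the group's rats show
|log10 FC| strictly greater than $\log_{10} 16 \approx 1.20$ *and* all
passing rats share one sign ("consistent"); the call's direction is that
shared sign. Both inequalities are strict, following the rule's wording.
Consistency is evaluated within each (species, group, timepoint contrast),
not across timepoints.

Note one compositional caveat: a planted $k$-fold change in latent
abundance appears as less than $k$-fold in relative abundance whenever the
shifted species carry a non-negligible share of the community (closure
renormalization). The recovery tests therefore plant balanced, small-share
shifts well above the 16-fold threshold.

## Covariate-adjusted rank correlations

`semipartial_spearman()` computes the part (semi-partial) Spearman
correlation: ranks of x, y and the covariates are formed (average ranks for
ties; categorical covariates dummy-coded against the first observed level),
the covariate ranks are regressed out of **x only**, and the residuals are
Pearson-correlated with the y ranks. Removing the covariates from the
microbiome variable (not the clinical outcome) is the orientation exposed
as the default, with `adjust = "y"` available. The p value uses the t
approximation with $n - k - 2$ degrees of freedom.

Outliers are removed pairwise before adjustment by Tukey's $1.5\times$IQR
fences on each variable (`remove_outliers()`), with no removal below $n=8$
where quartile fences are unstable. The fence rule and the small-n guard
are this package's concrete choices for an otherwise underspecified
"outlier removal" step. No multiple-testing correction is applied by
default in `correlate_panel()` (screens of this kind conventionally report
raw p values); Benjamini–Hochberg is an option.

## KEGG orthologs and modules

`module_abundance()` aggregates KO abundances to modules as the **mean**
over member KOs present in the table (sum available); the mean makes
modules of different sizes comparable. `wilcoxon_rank_sum()` reports the
classic W — the rank sum of the first group — with a two-sided p value by
complete enumeration when $n_1+n_2 \le 12$ without ties, and a normal
approximation with tie and continuity corrections otherwise; at the study's
7-vs-7 group size the approximation agrees with enumeration to well within
0.05. `module_log2fc()` reports per-group $\log_2$ ratios of module means
between the final and baseline timepoints, with modules absent from any
reported group dropped (`complete_only`), as heatmap displays require.

## The synthetic cohort generator

`simulate_cohort()` produces the full linked design — species profile,
metadata with scores/weights/cytokines, KO table, ground truth — from one
seed (sub-seeds are split per table, so tables are independently
reproducible). The generative model:

* Species log10 baselines are normal with SD 1.2 (lognormal abundances),
  closed per sample to 100%.
* A disease subset (default 40 of 200 species) drifts in the model group by
  a factor $1 + d$ per timepoint step (default $d = 1$: 16-fold by TP5,
  deliberately at the fold-change rule's threshold scale), direction ±1 per
  species; planted score-driving species always drift upward so the
  non-negative selection can, in principle, recover them.
* Each diseased animal carries a lognormal severity multiplier
  (SD 0.1) on its drift; each treated animal draws a final reversion from a
  Beta distribution with mean `reversion_fraction` (0.7) and SD 0.3, and
  the treatment effect grows quadratically from zero at baseline to that
  final value. Treated communities therefore track the disease early and
  revert late, and a treated group spans responders (near the healthy
  community) and non-responders (near the disease community). The model
  group's compact cluster keeps the fitted disease plane a stable local
  tangent, so distance to DP retains severity information; with a very
  dispersed disease cluster the plane would span the disease axis itself
  and hide it. These three choices are what make the qualitative
  study-level signs — score positively correlated with HP distance,
  negatively with DP distance — recoverable from the simulation, as they
  are from real data.
* The arthritis score of a diseased animal is
  `score_baseline + 0.6 * z` summed over the five planted species
  (z-scores of latent log abundance across diseased samples) plus unit
  noise, clipped to the 0–16 clinical scale; the weight is scaled so scores
  span the scale without saturating the clip bounds. Controls score 0, as
  unimmunized animals do.
* Cytokines are lognormal baselines (50 pg/ml scale, SD 0.2 on the log)
  plus linear couplings (default: the first three planted species to IL-17,
  IL-1β and TNF-α at strength 15), truncated at zero.
* The KO table (200 KOs in 20 modules) gets planted multiplicative module
  shifts at the final timepoint (default ×4 and ×0.25 in the model group),
  rows closed to 100.

What the generator does **not** emulate: sequencing and profiling error,
taxonomic misassignment, compositional correlation structure beyond
closure, rare-taxon sparsity patterns, and any nonlinear score dynamics.
Passing recovery tests therefore demonstrates that the statistical
machinery recovers planted structure under idealized longitudinal designs,
not that the biological conclusions of any particular study follow.

## Numerical choices and problem sizes

Tolerances: coordinate-descent convergence $10^{-7}$ (max coefficient
change per sweep); PCoA axis cutoff $10^{-8}\times\lambda_{max}$; plane
normals unit to $10^{-12}$; rank-deficient covariates and collinear plane
points are errors, zero-variance correlation inputs are flagged degenerate
results. Ties in ranks use average ranks throughout; lexicographic
tie-breaks order the selection report.

The test-suite and acceptance computations use the full study geometry
(4 × 7 × 5 = 140 samples) with 200 species, 20-seed replication for the
recovery and sign-recovery rates, and smaller tables for unit fixtures —
sizes at which the whole suite runs in a few minutes on one core. Observed
sign-recovery rates are estimated from 20 seeded runs and carry the usual
binomial wobble of a few percentage points between seed sets; the
underlying rates measured over 60 runs during design were 0.98 (HP
positive) and 0.93 (DP negative).

## Known limitations

* The fold-change rule inherits the compositional masking described above;
  it tests relative, not absolute, change.
* The DP-distance correlation is structurally weaker than the HP one: the
  disease plane is fitted to the very samples that define maximal
  dysbiosis, so within-model-group distance to DP is mostly residual noise.
* The non-negative elastic net cannot select protective (negatively
  associated) taxa by construction; run with `nonneg = FALSE` if both signs
  are of interest.
* p values for the semi-partial correlation use the t approximation; for
  n below ~15 with several covariates a permutation test would be
  preferable.
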