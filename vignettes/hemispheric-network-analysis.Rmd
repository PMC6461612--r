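---
title: "Hemispheric brain network analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemispheric brain network analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemiconn)
```

## What this package computes

`hemiconn` analyzes paired functional and structural brain connectivity at
the hemisphere level. The input is, per subject, two 90 x 90 weighted
matrices over the AAL cerebrum parcellation (45 regions per hemisphere):
a functional matrix of interregional Pearson correlations from resting-state
fMRI time series, and a structural matrix of interregional streamline
("fiber") counts from diffusion tractography. From these it derives:

* **connection classes** — left and right intra-hemispheric weight sums,
  and inter-hemispheric sums split into *homotopic* (a region with its
  mirror partner) and *heterotopic* (all other cross-hemisphere pairs);
* **hemispheric networks** — the two 45 x 45 within-hemisphere blocks,
  obtained after thresholding and after discarding all inter-hemispheric
  entries;
* **global graph metrics** — weighted global efficiency `E_glob`, weighted
  local efficiency `E_loc`, and their ratios to degree-preserving random
  null networks (`e_glob_norm`, `e_loc_norm`; small-world organization
  shows as `e_loc_norm > 1` with `e_glob_norm` near 1);
* **nodal degrees** — each region's summed weights within its own
  hemisphere (intra) and towards the other hemisphere (inter);
* **functional–structural coupling** — the number of region pairs connected
  in both modalities (*amount*) and the Pearson correlation between
  transformed weights on those pairs (*degree*);
* **group inference** — a two-way mixed group x hemisphere ANCOVA per
  measure, post hoc t tests, Bonferroni-corrected region-wise tests,
  covariate-adjusted group tests for inter-hemispheric measures, and
  partial correlations between network measures and clinical scores (HAMD,
  illness duration) within the patient group.

Because no subject-level data are distributed with studies of this design,
the package ships a first-class synthetic cohort generator whose planted
effects give every downstream stage a ground truth to recover.

## Thresholding regimes

Two regimes mirror the two analysis arms:

* **strength mode** (primary): an absolute weight cutoff shared by all
  subjects, preserving absolute network organization. The cutoffs are not
  published for this design, so the defaults — correlations `r > 0.2`,
  streamline counts of at least 3 (`> 2.5`) — are declared assumptions and
  are configurable in `threshold_scheme()`. Comparison is strictly greater;
  negative correlations are zeroed first, because path-length-based metrics
  are undefined for negative weights.
* **density mode** (validation): every subject is forced to the same edge
  density on the grid 0.08–0.15 (step 0.01), keeping the top fraction of
  edges by weight, and surviving weights are rescaled to overall mean 1 so
  subjects also share overall connectivity strength. Ties at the cutoff are
  broken deterministically by (weight descending, row, column). Metrics are
  integrated over the grid by the trapezoid rule and the areas under the
  curve (AUC) are what enters statistics.

The grid minimum is governed by a mean-degree rule: a density `d` is
admissible for an `N`-node network when `d * (N - 1) > 2 * log10(N)`. With
`N = 45` and a 0.01 step this gives 0.08 (`check_min_density(45)`), which is
exactly where the analysis grid starts. The logarithm is taken base 10: with
a natural logarithm the rule would exclude the entire 0.08–0.15 grid it is
meant to anchor (mean degree 3.52 at `d = 0.08` versus `2 ln 45 = 7.6`), so
base 10 is the only reading consistent with the grid itself.

Density thresholding is applied to the whole-brain matrix before the
hemispheric split; for strength mode the two orders are provably identical
(thresholding is entrywise), and the test suite asserts this commutation.

## Graph metric conventions

The exact formulas behind weighted efficiency vary across the literature;
this package follows the Rubinov–Sporns / GRETNA lineage:

* weights are divided by the network's maximum weight, putting functional
  (r) and structural (count) networks on a common scale and bounding both
  efficiencies in \[0, 1\];
* shortest-path edge lengths are reciprocals `1/w` of the normalized
  weights; disconnected pairs contribute zero;
* `E_glob` is the mean inverse shortest-path distance over ordered pairs;
* `E_loc` averages, over nodes, the global efficiency of each node's
  neighbor subgraph, keeping the original (normalized) weights in the
  subgraph; nodes with fewer than two neighbors contribute zero.

All-pairs distances are computed by a vectorized Floyd–Warshall pass, which
for dense 45-node matrices is faster than constructing a graph object per
call; the test suite verifies exact agreement (1e-10) with igraph's
independent shortest-path implementation on hundreds of random graphs, plus
closed forms (complete triangle: `E_glob = E_loc = 1`; 3-path:
`E_glob = 5/6`).

**Null model.** Normalized efficiencies divide the real metric by its mean
over random networks that preserve each node's binary degree exactly:
Maslov–Sneppen edge swaps (10 x edge count successful swaps via igraph),
with the original weight multiset reassigned to the rewired edges at
random. 100 nulls per network by default, fully seeded. Complete graphs
cannot be rewired; their nulls shuffle weights only and a warning is
raised. Whether matched-weight or binary nulls were used in the original
analyses is not documented; the seeded weight-shuffle choice is declared
here.

"Degree" is weighted degree (strength) throughout, since all analyses are
weighted; a binary edge-count option exists (`nodal_degrees(binary =
TRUE)`). Connection-class summaries are reported as sums by default (their
magnitudes, e.g. intra-hemispheric functional sums of order 100–250 over
990 pairs, are what group comparisons in this design operate on); a mean
mode is available.

## Functional–structural coupling

Coupling *amount* counts unordered region pairs with surviving weight in
both modalities of the same scope (left intra, right intra, or the 45 x 45
inter-hemispheric field). Coupling *degree* correlates, on those pairs,
Fisher-z-transformed functional weights with structural weights "resampled
into a normal distribution". The resampling is implemented as the
rank-based inverse-normal (Blom) transform,
`qnorm((rank - 3/8) / (n + 1/4))` with ties averaged — the established
convention in the structure–function coupling literature — which makes the
degree invariant under any strictly monotone rescaling of streamline
counts (a property test asserts this). The degree is reported per subject
(group summaries as mean ± SD imply per-subject values in this design) and
is undefined below 3 overlapping pairs or under zero variance.

## The mixed ANCOVA

With exactly two within-subject levels (left and right hemisphere), the
two-way mixed ANOVA with covariates factorizes exactly:

* the **group** main effect is the covariate-adjusted regression of the
  subject mean `(L + R) / 2` on group;
* the **hemisphere** main effect and the **group x hemisphere interaction**
  are the intercept and group coefficient of the regression of the
  difference `R - L` on group and covariates.

Each `F` is the squared `t` of the corresponding coefficient. Covariates
are mean-centered, gender is coded 0/1, and the group indicator is
effect-coded (+/- 0.5), so the difference-model intercept is the
*unweighted* grand hemisphere effect — the classical type-III convention,
which keeps the factorization exact also for unbalanced groups. The test
suite verifies agreement to 1e-8 with an independent general-linear-model
fit (`car::Anova`, repeated-measures type III) on dozens of random
unbalanced datasets.

Covariates are age, gender and education, plus mean framewise displacement
(head motion) for all functional comparisons. Denominator df are reported
as `n - 2 - k` for `k` covariates; reporting conventions that do not
subtract covariate df will differ from these by a constant.

Post hoc tests follow the design's stated exception: the hemisphere post
hoc is a paired t test on `R - L` with *no* covariates; the group post hoc
is an independent t test on covariate-residualized values pooled across
hemispheres. Inter-hemispheric measures (homotopic/heterotopic sums, inter
coupling), which have no within-subject factor, use a covariate-adjusted
two-sample design (`group_ttest()`).

Region-wise tests run the same mixed ANCOVA per homotopic pair and correct
with Bonferroni over exactly the 45 pairs, per measure per modality — no
correction is applied across measures or modalities, and brain–clinical
partial correlations are deliberately uncorrected, matching the stated
analysis plan for small exploratory samples.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions: two groups of 35
subjects (defaults), 90 regions, with

* **structural matrices**: edges exist independently with probability
  `struct_density` (0.25), boosted for homotopic pairs (+0.5); streamline
  counts are negative-binomial around `fiber_scale` (50, dispersion 5) —
  overdispersed and integer-valued, like real tractography counts — with
  homotopic counts enhanced 8-fold, the right intra-hemispheric block
  scaled by `asym_factor` (1.08) and patients by `mdd_struct_effect`
  (1.0 = structurally intact);
* **functional matrices**: sampled as genuine Pearson correlation matrices
  of `t_points = 200` multivariate Gaussian time samples, so correlation
  noise has its true sampling distribution (this matters for Fisher-z
  behavior and threshold crossings). The population correlation combines a
  within-hemisphere base (`base_fc = 0.2`, right block x 1.08), a reduced
  heterotopic level (x 0.75), an additive homotopic boost (+0.45), a
  multiplicative patient effect (`mdd_fc_effect = 0.85` on all
  correlations), and a subject-level shift (SD `noise_sd = 0.02`);
* **coupling**: structure constrains function — on structurally connected
  pairs a term proportional to the rank-normal structural scores is added
  to the functional correlations *in Fisher-z space*. The coefficient is
  calibrated so that the *measured* intra-hemispheric coupling degree
  (which carries Fisher-z sampling noise of variance `1/(t_points - 3)`)
  targets `coupling_rho`; when the positive-definite repair of the
  population matrix shrinks the planted component, the realized coefficient
  is re-estimated on the intra-hemispheric support and rescaled (up to four
  passes). The population matrix is repaired by eigenvalue clipping at
  1e-6 plus correlation rescaling before sampling;
* **covariates and clinical scores**: age ~ N(40, 10) truncated to 18–65,
  education ~ N(12, 3), gender Bernoulli(1/2), head motion log-normal
  around 0.12 mm; patients receive HAMD >= 18 with a positive dependence
  (`hamd_slope`, 2 points per SD) on the same subject latent that raises
  functional connectivity — so the positive coupling–severity correlation
  is recoverable by the partial-correlation stage; controls receive small
  HAMD values and zero duration.

Default magnitudes were chosen once to land the summary statistics in the
regime typical of this design (intra-hemispheric functional sums of order
10^2 over 990 pairs, structural sums of order 10^4) without being fit to
any published value. Everything is driven by R's Mersenne-Twister stream
with inversion Gaussian sampling, seeded from `spec$seed`; the caller's RNG
state is saved and restored, and regenerating a cohort from its spec is
bit-identical.

**What the generator does not emulate:** spatial embedding and
distance-dependent connectivity, hemodynamics or autocorrelated BOLD noise,
tractography biases (crossing fibers, length dependence), site or motion
artifacts, and realistic lateralization topography (asymmetry is planted
as a uniform right-block scaling). Passing recovery tests therefore
demonstrates that the *pipeline* detects effects of the planted kind at
realistic noise levels — not that real resting-state data behave like the
generator.

## Validation design and problem sizes

The test suite exercises the stack end to end at the study's sample size
(35 per group) with simulation sizes chosen to keep the default run within
a desktop budget while leaving decisive statistical margins:

* efficiency oracle equivalence on 200 random graphs (n = 8–15) at 1e-10;
* small-world recovery with 100 nulls on a 45-node Watts–Strogatz-style
  lattice (3 neighbors per side, 30 shortcuts) and a 45-node random graph
  (edge probability 0.35 — dense enough for the local-efficiency ratio to
  concentrate within 0.05 of 1);
* type-I calibration of all three ANCOVA effects over 1200 null cohorts
  (40 regions; the calibrated statistic does not depend on region count),
  acceptance band 0.03–0.07 at alpha = 0.05;
* family-wise error of the Bonferroni 45-region procedure over 600 null
  cohorts at the full 90-region resolution (dev-estimated true rate ~0.03,
  well under the 0.05 bound, because nodal statistics are positively
  dependent);
* planted-effect recovery over 200 default cohorts, requiring >= 80%
  significant functional group effects and rightward hemisphere effects in
  both modalities, with structural group effects at no more than the
  nominal rate (bounded at 0.05 plus 2.6 binomial SEs);
* coupling recovery at `coupling_rho` in {0, 0.3, 0.6} over 50 subjects
  per level, generated at `base_fc = 0.4` and `struct_density = 0.5` so
  every intra-hemispheric scope has >= 300 overlapping edges — enough
  support to estimate a correlation, and far enough above the functional
  cutoff that threshold censoring does not bias the measured degree.

## Numerical and degenerate-input choices

* Matrices are symmetrized when within 1e-6 of symmetric and rejected
  beyond; nonzero diagonals are zeroed with a message (self-connections
  are excluded everywhere).
* Empty networks have efficiency 0; all-zero measures yield F = 0, p = 1
  rather than NaN, so degenerate inputs flow through region-wise testing
  without flags or errors.
* Subjects with undefined coupling degrees are dropped from that ANOVA
  only (complete-case), never from other measures.
* Partial correlations whose residuals are numerically zero (a variable
  spanned by the covariates) return an undefined flag, not a spurious 0.
* `floor(density * E_max)` edges are kept at each density; realized density
  is within one edge of the request and is reported as an attribute.

## Known limitations

* The strength-mode cutoffs are assumptions (see above); conclusions that
  depend on them should be checked across a cutoff range or with the
  density arm.
* The generator's asymmetry and group effects are uniform block scalings;
  regional heterogeneity of effects is only exercised by dedicated
  region-level tests with hand-planted patterns.
* The bundled atlas ships *synthetic placeholder* regional volumes and
  areas (flagged in the file name); they support the size-validation
  machinery but are not measured values, so size-correlation results on
  bundled data are illustrative only.
* Normalized efficiencies in the density-grid arm default to off
  (`n_nulls = 0` in `run_validation_analysis()`): with 8 densities x 2
  modalities x 2 hemispheres per subject, null ensembles multiply quickly;
  enable them explicitly when needed.
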