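---
title: "Methods: phylogenetic diversity, community structure and biomass along recovery chronosequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic diversity, community structure and biomass along recovery chronosequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and conventions behind `chronophylo`,
the choices made where several defensible conventions exist, and what the
synthetic-data tests do and do not demonstrate about real data.

## Diversity metrics and their conventions

All metrics operate on a rooted phylogeny with branch lengths (time
units) and on per-plot species sets or abundance vectors. Species labels
are matched after trimming whitespace and replacing spaces with
underscores — the usual Newick dialect for binomials.

**Faith's PD** is the summed branch length of the subtree spanning the
plot's species. We use the *root-inclusive* convention (the classic
definition): the spanning subtree always contains the path to the root,
so PD is defined for single-species plots (their root-to-tip distance)
and `faith_pd(tree, all_tips)` equals the total branch length. The
MRCA-spanning variant is available via `include_root = FALSE`. The
convention matters: the two differ by the stem path from the root to the
species' most recent common ancestor.

**PSV, PSR, PSE** are built on the phylogenetic correlation matrix C of
the plot's species: the shared root-to-MRCA branch length of each species
pair, scaled to unit diagonal (for non-ultrametric trees,
C_ij = V_ij / sqrt(V_ii V_jj)). Two details are load-bearing:

* C is **subset from the full regional tree's covariance**, never
  recomputed on a pruned tree. Pruning moves the root to the subset's
  MRCA and silently changes every shared depth; with only two species it
  would force PSV = 1 regardless of relatedness.
* PSE uses the closed form
  (N Σᵢ mᵢ C_ii − mᵀCm) / (N² − N·m̄), m̄ = N/k,
  which we validated against the reference implementation in `picante`
  before freezing; the two agree to 1e-10 on ultrametric trees. On
  non-ultrametric trees our correlation-matrix convention (above) is
  applied uniformly across PSV and PSE, which can differ from
  implementations that use the raw covariance. PSE is exactly 1 on a star
  phylogeny with equal abundances, and is invariant to scaling all
  abundances by a common factor.

**MPD and MNTD** are presence-based (unweighted means over distinct
pairs, and over nearest-neighbour distances), matching the "among all
species" reading of the standardized-structure indices. Abundance-
weighted variants exist behind the `weights` argument but are not used by
the default pipeline.

## The randomization null and NRI/NTI

The null model is *richness-preserving uniform draws from the whole
phylogeny pool*: each of 999 replicates draws k distinct species from all
tips and re-evaluates the metric. This follows the stated design of the
study the pipeline reproduces; a tip-label-shuffle null is available as
`null_model = "shuffle"`. The null standard deviation uses the sample
(n−1) estimator over replicates. Scores are

NRI = −(MPD_obs − mean)/sd,  NTI likewise with MNTD.

Degenerate nulls (sd < 1e-12, e.g. k equal to the pool size, or a star
pool for MNTD) are flagged `degenerate_null` and excluded downstream —
never silently reported as 0.

Per-plot reproducibility matters more than global reproducibility here:
each plot × level × metric gets a seed derived by hashing the master seed
with those identifiers, so adding, removing or reordering plots never
changes another plot's score.

For herb- and woody-level analyses the default pool is the corresponding
life-form subset of the phylogeny (`pool_by_level = TRUE`), since a herb
community's plausible colonists are herbs; the whole-pool alternative is
one switch away, as the choice is genuinely open.

## Biomass

AGB (g/m²) is additive: herb + woody + litter. Herb and litter densities
are means over complete-harvest boxes (defaults: three 1 m² herb boxes,
three 0.317 m × 0.317 m = 0.100489 m² litter boxes). Woody biomass sums
species-specific allometric predictions (kg per stem) over all stems and
divides by plot area. The allometric registry is an editable CSV
(taxon, form, a, b, component); lookups fall back species → genus →
life-form default, and multi-component models (stem/branch/leaf rows) are
summed. The registry shipped with the synthetic generator contains
*synthetic placeholder coefficients* (e.g. woody B = 0.05·D^2.5), chosen
to give realistic magnitudes (peak plot AGB near 2.4 × 10⁴ g/m²); they
are not literature values and should be replaced for real studies. Inputs
are assumed oven-dry; no moisture correction is applied.

## Chronosequence statistics

Trends of each diversity metric against recovery time (TVR, years) are
quadratic least-squares fits on plot-level data (n = 48 under the default
design); the peak is the analytic vertex, reported only when curvature is
negative and the vertex lies inside the observed range. Stage effects use
one-way ANOVA followed by Duncan's multiple range test: means sorted
decreasing, a span of p means homogeneous when its range is below
R_p = q(1−(1−α)^(p−1); p, df_error)·√(MSE/n_h) (harmonic-mean n for
unbalanced designs), maximal homogeneous spans sharing a letter from "a"
for the largest mean. The protection rule means a wide non-significant
span absorbs its sub-pairs; consequently two means sharing a letter are
bounded by the critical range of a covering span, not necessarily their
own — our consistency tests assert exactly that guarantee.

Normalization before model fitting tries identity → log → Box-Cox power
(profile-likelihood λ on a −2…2 grid), accepting the first transform
whose Shapiro–Wilk p exceeds 0.05; nonpositive values are shifted so the
minimum becomes 1 before log/power, with the shift reported. When nothing
passes, the best-W transform is returned flagged `passed = FALSE` rather
than failing the pipeline.

## Mixed models, variance partitioning, path model

The AGB model is a Gaussian linear mixed model (identity link) of
(transformed) AGB on the five diversity predictors with recovery stage as
a random intercept — the faithful reading of a "GLMM" applied after
transformation to normality; the predictors are z-scored so t-values are
comparable across community levels. Variance components and t-values come
from the REML fit; AIC from the matching ML fit so fixed-effect
comparisons are valid. R²m and R²c follow the variance-decomposition
definitions: var(fixed predictor) over, respectively with, the random and
residual variances added to the numerator. Singular fits (stage variance
at the boundary) are reported with a flag, not treated as failures.

Variance partitioning uses adjusted R² of the two predictor blocks
(diversity: PD + PSE; structure: NRI) and their union; unique and shared
fractions follow the standard inclusion–exclusion identities and are
reported unclipped (adjusted-R² fractions can be slightly negative), with
both total-variance and of-explained normalizations.

The PLS path model uses the conventional defaults — reflective (mode A)
outer model, path inner weighting scheme, iteration until the largest
outer-weight change is below 1e-6 — since the estimator family's many
knobs are not the object of study. Single-indicator blocks make the
latent scores equal the standardized indicators, and the model then
reproduces standardized recursive OLS path analysis to numerical
precision (one of the test suite's oracle equivalences). Communality is
the mean squared loading per block, GOF = √(mean communality × mean
endogenous R²), and path significance comes from a seeded bootstrap
(default 500 resamples). A direct TVR → AGB path is available
(`tvr_agb_path = TRUE`) but off by default, keeping the diversity- and
structure-mediated routes as the explanation under test.

## The synthetic study generator

`default_scenario()` encodes the study design the pipeline expects:
8 recovery stages (0–150 yr) × 6 plots, a 130-species pool (≈ 38% woody,
matching a 49/128 split), herb-only early stages, woody-dominated late
stages, and an AGB trajectory peaking at the 135-yr mixed-forest stage
(two codominant canopy species) before declining at the 150-yr
single-dominant climax.

* **Phylogeny**: pure-birth tree rescaled to unit root depth — adequate
  for exercising metrics, simpler than an empirical megatree.
* **Traits**: one Brownian niche trait (tip SD ≈ 1) drives filtering; a
  second, independent Brownian trait is thresholded to assign life forms,
  so herb and woody species are clade-clumped as in real floras.
* **Filtering**: sampling weights ∝ exp(−(trait − optimum)²/(2σ_f²)).
  The stage optimum is specified as a *quantile* of the realized trait
  distribution, drifting from the median (stage 0) into the upper tail
  (late stages). Anchoring on quantiles rather than absolute trait values
  is deliberate: upper-tail species are clade-clumped under Brownian
  motion on *any* simulated tree, so narrow-filter stages aggregate
  (NRI > 0) robustly, whereas an absolute optimum near the trait centre
  selects across many clades and can even produce spurious dispersion.
* **Competition**: with stage-specific probability per round, the less
  abundant member of the phylogenetically closest pair is removed and
  replaced by the same-life-form species that maximizes its nearest-
  neighbour distance to the community — a limiting-similarity proxy that
  reliably drives NRI below 0 at high intensity.
* **Abundances** are lognormal (meanlog log 15, sdlog 1, rounded, ≥ 1);
  woody stem counts follow a per-stage schedule with a dominance boost
  implementing the mixed- vs pure-forest contrast; stem diameters are
  lognormal around a stage-specific mean; harvest masses get lognormal
  noise with CV 0.2.

Schedules (richness 6→26→10, filter width 0.8→0.25→3, competition 0→0.8)
were chosen once so that the generator's three design contracts hold —
unimodal total-community PD with an interior quadratic peak, aggregation
in the filtering stages turning to dispersion at the climax stage, and
the AGB ordering 135 > 150 > 70 — and are exposed as configuration for
other designs.

**What the synthetic tests do not show.** The generator emulates the
statistical structure the analysis assumes, not forest dynamics: no
demography, no spatial structure, no measurement error in diameters, no
species turnover between neighbouring plots. Two quantitative caveats are
worth knowing. First, stratifying draws by life form induces a small
over-dispersion bias (≈ −0.1 NRI) against the unstratified pool null,
because a fixed herb/woody split has fewer within-clade pairs in
expectation than hypergeometric sampling; this is a property of
stratified assembly, not an error in the null. Second, whether a given
stage aggregates depends on the clade structure of the simulated tree's
trait tail, so stage-level NRI signs on the default scenario are stable
for the documented seeds but not for every seed; the pure-regime
contracts (strong filter ⇒ NRI > 0.5, pure competition ⇒ NRI < 0,
neutral ⇒ |NRI| ≤ 0.2) are the robust statements. Passing the end-to-end
tests therefore validates the pipeline's arithmetic and its qualitative
sensitivity, not any claim about real vegetation.

## Problem sizes and numerical choices

The default test and validation workloads are sized for a laptop: 999
null replicates per plot × 3 levels × 48 plots for the pipeline, 500
communities × 999 replicates for the null-calibration check, 100 seeded
datasets for mixed-model power, 100 random trees for oracle equivalence.
Tolerances: oracle equivalences at 1e-10, the VPA identity at 1e-8,
PLS-PM convergence at 1e-6 with a 300-iteration cap (non-convergence is
an error, not a warning), degenerate-null detection at sd < 1e-12.
Composition percentages use largest-remainder allocation to two decimals,
so each category group totals exactly 100.00 — this is also the only
rounding scheme consistent with the worked examples the package
reproduces.
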