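---
title: "Estimating genetic yield gains from multi-environment trial series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genetic yield gains from multi-environment trial series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxegain)
```

## The problem

International wheat breeding programs distribute annual replicated yield
trials — a fixed list of about fifty elite lines plus checks — to dozens of
collaborating locations. Each year brings a fresh cohort of lines, and the
question of interest is the *annual genetic gain*: how fast the yield of the
best new material improves relative to a fixed benchmark cultivar that is
included every year, and relative to the local check each cooperator grows.

`gxegain` implements the full analysis chain for such series: single-location
mixed-model quality control, a multi-environment mixed model with a
factor-analytic (FA) genotype-by-environment (G×E) covariance, BLUP-based
selection of the top decile of lines, relative-yield regressions on
trial-years, megaenvironment (ME) classification of the locations, and
site-regression (GGE) biplots. Because real trial series of this kind are not
freely redistributable, the package also ships a synthetic-series generator
with known ground truth, and simulation studies that validate every stage
against that truth.

## Models

### Single location

Each location is an α-lattice: `r` complete replicates, each split into `k`
incomplete sub-blocks. The plot model is

$$Y_{ijk} = \mu + R_j + SB_{k(j)} + G_i + \varepsilon_{ijk},$$

with replicate and genotype effects fixed, sub-block effects
$SB_{k(j)} \sim N(0, \sigma^2_{sb})$ and residuals
$N(0, \sigma^2_\varepsilon)$, fitted by REML (`fit_single_site()`). Genotype
adjusted means are the fixed-effect solutions under a sum-to-zero constraint
plus the overall mean; on balanced data they equal raw genotype means.

Heritability needs a genotype variance, which a fixed-genotype model does not
provide, so the package refits the same data with genotype random (the common
α-lattice practice) and reports the entry-mean heritability

$$h^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_\varepsilon / r},$$

clipped to $[0,1]$. Locations with $h^2 < 0.05$ (configurable) are discarded
from all combined analyses (`filter_sites()`); the drop reason
(`low_h2` / `not_converged`) is recorded. Whether the source analyses used an
entry-mean or plot basis is not documented for this trial system; the
entry-mean form is the standard definition for selecting among line means and
is what the filter uses, with `r` taken as the mean observed replication.

### Across locations

The combined model for one trial-year is

$$Y = Xb + Z_r r + Z_g g + Z_{ge}\,ge + e,$$

with fixed site effects $b$, replicate-within-site effects
$r_j \sim N(0, \sigma^2_{r_j})$ (a separate variance per site), genotype main
effects $g \sim N(0, \sigma^2_g I)$, interaction effects with
$\mathrm{var}(ge) = \Sigma_{ge} \otimes I$, and homogeneous residuals
$N(0, \sigma^2_e I)$. Four structures for $\Sigma_{ge}$ are available:

* `"fa"` (default): $\Sigma_{ge} = \Lambda\Lambda' + \Psi$ with $s \times k$
  loadings and diagonal specific variances — the factor-analytic model.
  Default order $k = 1$; the rank must stay well below the site count, and
  REML-likelihood comparison across $k$ is available to the user since the
  appropriate order is data-dependent.
* `"diagonal"`: site-specific interaction variances, no covariance.
* `"cs"`: one shared interaction variance.
* `"no_gxe"`: the interaction term dropped entirely — the "without modeling
  G×E" baseline. (A precise definition of such a baseline is not standard;
  dropping the term is the interpretation used here, with `"cs"` available
  as a compound-symmetry-flavoured alternative.)

Identifiability of $\Lambda$ is fixed by zeroing its upper triangle; every
reported quantity depends on the loadings only through
$\Lambda\Lambda' + \Psi$. Per-site residual variances are available behind
`met_spec(het_resid = TRUE)` (a slower code path); the default follows the
homogeneous-residual form of the model above.

### REML evaluation and optimization

The restricted log-likelihood is evaluated through the mixed-model-equation
identity $\log|V| + \log|X'V^{-1}X| = \log|R| + \log|G| + \log|C|$, with the
value convention of orthonormal error contrasts (the $-\log|X'X|$ term
included), so it is directly comparable with the brute-force dense
error-contrast evaluators `reml_loglik_site_dense()` /
`reml_loglik_met_dense()` that exist purely as independent references. For
the multi-environment model, genotype main and interaction effects are
merged internally into one $s$-variate effect per genotype with covariance
$\Sigma^* = \sigma^2_g 11' + \Lambda\Lambda' + \Psi$; after a Schur
complement on the small replicate block, the MME coefficient matrix is
block-diagonal over genotypes, and genotypes with identical observation
patterns (all of them, in complete data) share factorizations. One
evaluation costs $O(g s^3)$ rather than $O((gs)^3)$. Analytic gradients for
every parameter come from the standard trace identity
$\partial \ell / \partial \theta = -\tfrac12[\mathrm{tr}(P \dot V) - y'P\dot V P y]$,
reduced to the same block quantities.

Optimization uses `nlminb` on log-variances (floored at $10^{-6}$, a
negligible value on the Mg/ha scale, which keeps the optimizer off the flat
plateau near zero) and unconstrained free loadings, from a method-of-moments
warm start (eigendecomposition of the cell-mean covariance) plus seeded
random restarts (default 5). FA-REML surfaces are genuinely multimodal and
occasionally nearly flat along the ridge that trades $\sigma^2_g$ against a
near-constant loading column; convergence is therefore declared when the
restricted log-likelihood changes by less than 0.01 across an optimizer
restart. A factor-analytic fit that still fails is automatically refit with
the diagonal structure and flagged (`fallback_from = "fa"`), so downstream
stages always receive a usable fit — the same pragmatic substitution used in
practice when FA models do not fit a particular trial group.

BLUPs come from the MME solutions at the optimum. Two exact consequences of
the construction are worth knowing: genotype main-effect BLUPs sum to zero,
and interaction BLUPs sum to zero over genotypes within every site.

### Genetic gain

For each trial-year, `select_hyl()` ranks the test lines (checks excluded)
by BLUP-predicted yield in the requested scope and keeps the top
$\lceil 10\% \rceil$ — five lines for a 48-test-line trial. `relative_yield()`
expresses their mean predicted yield as a percentage of the predicted yield
of a reference check: the long-term benchmark cultivar (entry `"ATTILA"`),
or the local check (entry slot 1 at every site, aggregated to a single
scope-level BLUP; since local checks are distinct varieties per site, this
aggregate is the one-number summary a series-level regression needs).
`estimate_gain()` regresses those percentages on the trial-year index by
OLS; the slope is the annual gain in % yr⁻¹. A parallel regression of the
absolute difference (selected mean − check, in kg/ha) on years yields a
kg ha⁻¹ yr⁻¹ slope; the published convention converting between the two
scales is not defined, so both regressions are always reported. The year
covariate is the trial index (1, 2, …); any affine relabeling of calendar
years leaves the slope unchanged. The regression is unweighted — trials with
more locations are not upweighted, since each trial contributes one
(already averaged) point.

Selection is redone within each scope (all locations, or one ME), matching
separate per-ME analyses, and `compare_variants()` reruns the whole chain
under two interaction structures (default `"fa"` vs `"no_gxe"`) to expose
how much G×E modeling moves the gain estimate.

### Megaenvironment classification

`assign_me()` applies climate/management rules in a fixed, total order:

1. irrigated (or assumed irrigated where unconfirmed), normal sowing, and
   coolest-quarter minimum temperature in [3, 11) °C → **ME1** (optimal);
2. late sowing → **ME5** (heat stress imposed agronomically);
3. rainfed with wettest-quarter precipitation in [100, 400] mm → **ME4**
   (drought);
4. rainfed with ME1-like climate (irrigation withheld) → **ME4**;
5. coolest-quarter minimum in [11, 16] °C → **ME5** (heat);
6. otherwise unclassified.

Management overrides climate; boundary temperatures use a closed-lower /
open-upper ME1 interval, so exactly 11 °C is ME5. `refine_by_cluster()` then
splits each trial's locations into high- and low-yielding clusters (k-means
on site mean yield, deterministically initialized at the range extremes —
no random starts, so reruns are identical) and relabels a climatically-ME1
site to ME4 when it lands in the low cluster *and* its irrigation was never
confirmed; confirmed irrigated sites are never relabeled, and every
relabeling is logged. The exact refinement policy used in practice is not
documented anywhere authoritative; this one is a concrete, auditable
implementation with every threshold exposed.

### Site-regression biplot

`sreg_decompose()` centers each environment column of a genotype ×
environment mean table (removing environment main effects, so genotype main
effects plus G×E remain — "GGE"), optionally divides by the column standard
deviation (the default, since "scaled" country-mean analyses are typically
standardized; centered-only is a flag), and takes the SVD. Scores use
symmetric singular-value partitioning ($\sqrt{\sigma_i}$ on each side), and
the first-two-axes share of variation is
$100(\sigma_1^2+\sigma_2^2)/\sum\sigma_i^2$. Axis signs are deterministic:
each axis is oriented so the mean genotype score is nonnegative, falling
back to the largest-magnitude score when the mean is numerically zero.
`which_won_where()` takes the convex hull of genotype scores as the polygon
of most responsive genotypes and assigns each environment the hull vertex
with the largest inner product with its score — the sector construction of
the classical which-won-where plot. `environment_correlations()` and
`me_blup_correlations()` provide the companion Pearson correlation matrices
with closed-form t-test p-values.

## The synthetic trial series

`sim_config()` / `simulate_series()` emulate an international elite spring
wheat trial series:

* **Entries.** 50 per trial (configurable): entry 1 is a site-specific local
  check drawn near the 90th percentile of that trial's test lines
  (cooperators grow their best commercial variety); one entry is the
  long-term check `"ATTILA"` with true effect fixed at 0; the rest are new
  test lines each year.
* **Trend.** Test lines of trial-year $t$ have effects
  $N(\delta\, t\, \mu_{check}/100,\ \sigma_g^2)$ where $\delta$ is
  `trend_pct_per_year` and $\mu_{check}$ the check's expected yield, so the
  true annual gain is $\delta$ percent by construction. The default
  $\delta = 1.67$, with 22/9/7 locations in ME1/ME4/ME5 and site means of
  4.5–7.0 / 2.0–4.0 / 3.5–5.5 Mg/ha, mirrors the reported conditions of an
  eight-year elite spring wheat series across three megaenvironments.
* **G×E.** Per trial, site loadings $\lambda_j \sim U(0.15, 0.45)$ and
  specific variances $\psi_j \sim U(0.02, 0.08)$ define
  $\Sigma_{ge} = \Lambda\Lambda' + \Psi$; each genotype's interaction vector
  is drawn from $N_s(0, \Sigma_{ge})$. `fa_order = 0` disables G×E.
* **Design and noise.** α-lattice with 2 replicates × 5 sub-blocks of 10;
  $\sigma_g = 0.3$, $\sigma_{sb} = 0.15$, $\sigma_r = 0.10$,
  $\sigma_e = 0.35$ Mg/ha (genetic CV ≈ 6% and plot CV ≈ 7% at a 5 Mg/ha
  site — typical for replicated elite-line yield trials). A configurable
  fraction of sites (default 5%) gets a 20-fold inflated residual SD,
  exercising the heritability filter, and a configurable fraction of
  test-line × site cells can be dropped (checks are never dropped so
  reference yields stay computable).
* **Climate metadata** consistent with each site's ME, including
  late-sown heat-stress sites and ME1 sites whose irrigation status is
  unreported (`NA`) — the cases the classification and cluster-refinement
  rules exist for.

What the generator deliberately does *not* emulate: spatial field trend
within locations, genetic relatedness among lines (no pedigree), year
effects shared across locations within a trial (locations are re-drawn each
year), selection of which cooperators return data, and disease epidemics
(the benchmark-check rust susceptibility discussed in the source
literature). Passing tests on this generator therefore show that the
*estimators* recover the *modeled* structure; they cannot certify behaviour
under field artifacts outside the model.

Small implementation details: yields are truncated below at 0.01 Mg/ha
(essentially never binding at the default parameters); the replicate-effect
SD `sigma_r` exists so the MET model's per-site replicate variances have
something to estimate.

## Validation studies and their design

The `study_*()` functions are first-class package code used by both the test
suite and `scripts/acceptance.R`:

* `study_reml_oracle()` — 20 random small instances (≤ 60 plots): both
  models' MME likelihood vs the dense error-contrast reference, agreement to
  1e-8.
* `study_fa_recovery()` — 25 datasets at 6 sites × 50 entries × 2 reps with
  $k=1$ truth: relative Frobenius error of $\hat\Sigma_{ge}$, of the
  combined $\hat\sigma^2_g + \hat\Sigma_{ge}$, and the nesting of optimized
  log-likelihoods (fa ≥ diagonal ≥ no_gxe). Recovery of $\Sigma_{ge}$ alone
  is limited by two facts worth stating plainly: the sample-covariance floor
  at 50 genotypes is already ≈ 0.19 median relative error, and the
  likelihood identifies only the combined covariance — the split between
  $\sigma^2_g$ and a near-constant loading component is weakly identified,
  so the combined matrix is recovered substantially better than the split
  parts.
* `study_h2_filter()` — 500 single sites at $\sigma_g = 0.5$,
  $\sigma_e = 0.3$: mean $\hat h^2$ against the closed form; plus 100 sites
  with $20\times$ inflated $\sigma_e$ and the filter's drop rate. With 50
  entries and 2 replicates, $\hat\sigma^2_g$ has sampling SD
  $\approx (\sigma^2_g + \sigma^2_\varepsilon/2)\sqrt{2/49}$, which at the
  inflated noise level is ≈ 3.7 — far above the 0.95 decision boundary that
  $h^2 = 0.05$ implies — so a substantial share of pure-noise sites
  necessarily estimate $h^2 > 0.05$ and survive the filter; the study
  reports the measured drop rate (≈ 0.5–0.6 at these dimensions). The mean
  $\hat h^2$ sits slightly below the closed form (by ≈ 0.01 at
  $h^2 = 0.85$, $g = 50$): the ratio of noisy variance estimates is concave
  in $\hat\sigma^2_g$, a finite-entry-count effect, not an implementation
  artifact (the variance components themselves match an independent lme4
  fit to ~1e-4 in the test suite). These sites are generated without G×E:
  at a single location, genotype-by-site effects are indistinguishable
  from genetic effects, so $\sigma_g$ must be the whole genetic signal for
  the closed form to be the estimand.
* `study_gain_recovery()` — full simulate → fit → select → regress chains.
  Design: 8-trial series at 12 sites (7/3/2 across ME1/ME4/ME5) × 50
  entries, FA fits warm-started with one optimizer start at a 1e-5
  tolerance; 100 seeds for the null-trend arm (empirical type-I rate of
  the slope t-test), 50 seeds each at 1.67 and 2.7 % yr⁻¹. The site count
  matters: BLUP shrinkage attenuates a cohort-mean trend by roughly
  $1'\Sigma^*(\Sigma^* + \sigma^2_e/r\, I)^{-1}1/s$, measured ≈ 0.84 at 8
  sites and ≈ 0.98 at 14; at the chosen 12 sites the residual attenuation
  (a few hundredths of the trend) is an order of magnitude below the
  Monte-Carlo band, so the study tests trend recovery rather than BLUP
  compression. A single series estimates the slope only to ± ≈ 1.3 % yr⁻¹
  — the check's own G×E draw moves the ratio denominator between years —
  which is why the study averages across seeds.
* `study_sreg_identities()` — exact rank-2 identities and brute-force
  which-won-where agreement.
* `study_determinism()` — the pipeline run twice with one seed, artifacts
  compared byte for byte.

## Pipeline

`run_pipeline(pipeline_config(...), out_dir)` executes
input → single-site fits and $h^2$ filter → ME classification (with
per-trial cluster refinement) → MET fits per scope → gain regressions →
final-trial country-level biplot, writing `sitefits.csv`,
`assignments.csv`, `metfits.csv`, `gains.csv`, `biplot.csv` and a JSON
manifest (package version, seed, stage timings, dropped sites, FA
fallbacks). All randomness descends from the single master seed (the MET
fit of trial-year $t$ uses `seed * 100 + t`), k-means initialization is
deterministic, and CSVs are byte-identical across reruns; timings live only
in the manifest. Any stage error aborts with the stage name prefixed.

## Limitations

* No spatial (row–column) adjustment at the plot level, and no recovery of
  inter-block information beyond the stated sub-block model.
* No pedigree or genomic relationship matrix: lines are assumed unrelated.
* The FA order default is $k=1$; the appropriate order for a given series is
  an empirical question, and $k$ must remain well below the site count.
* BLUP-based gain regressions carry a mild attenuation of cohort trends at
  small site counts (quantified above); with the 28–47 locations of a real
  international series the effect is negligible, but analyses of small
  subsets should expect it.
* The local-check reference aggregates distinct per-site varieties into one
  scope-level BLUP by default; `relative_yield(aggregate =
  "per_site_ratio")` averages per-site percentages instead. Which
  convention published series-level analyses used is generally not
  documented, so the default is the simpler one.
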