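# gxegain

Estimating annual genetic yield gains from series of international
multi-environment wheat yield trials, with the genotype × environment
(G×E) interaction modeled by a factor-analytic mixed model.

## What it does

Breeding programs that distribute an annual elite yield trial — ~50 new
lines plus a long-term check cultivar and a site-specific local check,
grown as an α-lattice with two replicates at dozens of locations across
megaenvironments (ME1 optimal/irrigated, ME4 drought, ME5 heat) — need a
defensible answer to: *how fast is the new material gaining yield?*

`gxegain` implements the standard analysis chain for that question:

1. **Single-location REML** (`fit_single_site()`): the α-lattice model
   `yield = mean + replicate + genotype + subblock(replicate) + error`,
   adjusted genotype means, and line-mean heritability
   h² = σ²g / (σ²g + σ²ε/r); locations with h² < 0.05 are discarded
   (`filter_sites()`).
2. **Multi-environment mixed model** (`fit_met()`):
   `Y = Xb + Zr r + Zg g + Zge ge + e` with fixed site effects, per-site
   replicate variances, genotype effects N(0, σ²g I), and interaction
   covariance Σge ⊗ I modeled as factor-analytic (Σge = ΛΛ′ + Ψ), diagonal,
   compound-symmetric, or dropped. REML with analytic gradients,
   method-of-moments warm starts, multi-start optimization, and an
   automatic diagonal fallback when an FA fit does not converge. BLUPs for
   genotype main effects and interactions come from the mixed-model
   equations.
3. **Genetic gain** (`select_hyl()`, `relative_yield()`,
   `estimate_gain()`): the BLUP yield of the 10% highest-yielding lines per
   trial, expressed as a percentage of the long-term check (GYA) or of the
   local checks (GYLC), regressed on trial-years → % yr⁻¹ and
   kg ha⁻¹ yr⁻¹ slopes with SE and p-value. `compare_variants()` contrasts
   the FA-modeled and no-G×E answers.
4. **Megaenvironment classification** (`assign_me()`,
   `refine_by_cluster()`): climate/management rules (irrigated 3–11 °C →
   ME1; rainfed 100–400 mm → ME4; 11–16 °C or late-sown → ME5) refined by
   high/low-yield clustering.
5. **Site-regression (GGE) biplots** (`sreg_decompose()`,
   `which_won_where()`, `environment_correlations()`): SVD of the
   environment-centered genotype × environment table, symmetric score
   partitioning, variance explained by the first two axes, the
   which-won-where polygon, and environment/ME correlation matrices.
6. **Synthetic trial series with known truth** (`sim_config()`,
   `simulate_series()`) and a deterministic end-to-end pipeline
   (`run_pipeline()`) that writes per-stage CSV artifacts and a JSON
   manifest, byte-identical across reruns with one seed.

Because real international trial series are not freely redistributable,
validation is simulation-based throughout: the `study_*()` functions
measure estimator correctness against generated ground truth.

## Worked example

Simulate an 8-year series with a true gain of 1.67 % yr⁻¹ over the
long-term check, at 14 locations per year across three megaenvironments,
and run the whole pipeline:

```r
library(gxegain)
cfg <- pipeline_config(
  sim = sim_config(n_trials = 8, n_genotypes = 50,
                   n_sites_per_me = c(ME1 = 8, ME4 = 3, ME5 = 3),
                   trend_pct_per_year = 1.67),
  scopes = "all", met = met_spec(fa_order = 1, n_starts = 1), seed = 1)
out <- run_pipeline(cfg, out_dir = "demo_run")
#> h2 filter dropped 7 site(s): T3_ME4_02, T3_ME5_01, T4_ME4_02, ...
#> relabeled 1 site(s) ME1 -> ME4 (low-yield cluster, irrigation unconfirmed): T1_ME1_02

out$gains
#>  scope   reference   slope_pct   slope_kg intercept        se         p n
#>    all      attila -0.09321899   9.665726  120.6524 1.3375908 0.9467037 8
#>    all local_check -0.56428458 -31.472635  109.0029 0.9174541 0.5611053 8
```

Reading the output: the eight trial-years gave GYA points averaging ~120%
(the top decile out-yields the check by ~20%), and the fitted GYA slope for
*this particular* series is −0.09 % yr⁻¹ with a standard error of
1.34 % yr⁻¹ — a single 8-point series estimates the trend only to within
about ±1.3 % yr⁻¹, mostly because the check's own G×E draw moves the ratio
denominator from year to year. `study_gain_recovery()` runs many such
series and shows the estimator is centered on the true 1.67 (its cross-seed
mean at these dimensions is within two Monte-Carlo standard errors of the
truth, and the slope t-test holds its 5% size under a null trend).

The fitted multi-environment model and the final-trial biplot:

```r
out$met_fits$all[["8"]]
#> Multi-environment REML fit (variant: fa)
#>   sites: 12  genotypes: 50
#>   sigma2_g = 0.04323  sigma2_e = 0.1538
#>   REML log-likelihood = -793.4088  converged: TRUE
#>   GxE correlations (range): [0.21, 0.87]

select_hyl(out$met_fits$all[["8"]])
#> [1] "E08_13" "E08_35" "E08_43" "E08_30" "E08_08"

out$biplot$result
#> SREG biplot (standardized scaling): first two axes explain 91.08% of variation
#>   polygon vertices: E08_08, E08_27, E08_06, E08_34, E08_14, E08_17, E08_43, E08_35, E08_13
```

The five listed lines are the top 10% of the 48 test entries by overall
BLUP yield; the biplot polygon names the most responsive genotypes, and
each country is "won" by the vertex genotype of its sector
(`out$biplot$result$sector_winners`).

`demo_run/` now contains `sitefits.csv`, `assignments.csv`, `metfits.csv`,
`gains.csv`, `biplot.csv` and `manifest.json` — every stage re-ingestible
and byte-identical on rerun with the same seed.

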