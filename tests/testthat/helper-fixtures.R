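# Shared fixture builders.  Everything is generated in code at test time.

# a small single-trial record set
small_trial <- function(seed = 1, n_genotypes = 10, n_subblocks = 2,
                        sites = c(ME1 = 3), n_trials = 1, ...) {
  cfg <- sim_config(n_trials = n_trials, n_genotypes = n_genotypes,
                    n_subblocks = n_subblocks, n_sites_per_me = sites,
                    lowh2_site_rate = 0, seed = seed, ...)
  simulate_series(cfg)
}

# deterministic noise-free series: yields are exactly site mean + genotype
# trend effect
noise_free_trial <- function(seed = 1, trend = 1.67, n_trials = 1,
                             n_genotypes = 10, sites = c(ME1 = 2)) {
  cfg <- sim_config(n_trials = n_trials, n_genotypes = n_genotypes,
                    n_subblocks = 2, n_sites_per_me = sites,
                    trend_pct_per_year = trend, fa_order = 0,
                    sigma_g = 0, sigma_sb = 0, sigma_r = 0, sigma_e = 0,
                    lowh2_site_rate = 0, seed = seed)
  simulate_series(cfg)
}

# hand-built tiny alpha-lattice site: 3 genotypes x 2 reps x 1 sub-block
tiny_site_records <- function() {
  data.frame(
    genotype = rep(c("A", "B", "C"), 2),
    site = "S1", year = 1L,
    rep = rep(1:2, each = 3), subblock = 1L,
    yield = c(5.1, 4.7, 5.6, 5.3, 4.9, 5.9),
    stringsAsFactors = FALSE)
}

with_seed_local <- gxegain:::with_seed

# a met_fit skeleton with hand-set effects, for pure-arithmetic checks
stub_met_fit <- function(genotypes, sites, site_means, blup_g,
                         blup_ge = NULL) {
  g <- length(genotypes); s <- length(sites)
  if (is.null(blup_ge))
    blup_ge <- matrix(0, g, s, dimnames = list(genotypes, sites))
  structure(list(
    site_means = stats::setNames(site_means, sites),
    rep_variances = stats::setNames(rep(0.01, s), sites),
    sigma2_g = 0.1, loadings = NULL,
    specific_vars = stats::setNames(rep(0, s), sites),
    Sigma_ge = matrix(0, s, s, dimnames = list(sites, sites)),
    sigma2_e = 0.1,
    blup_g = stats::setNames(blup_g, genotypes),
    blup_ge = blup_ge, reml_loglik = 0, converged = TRUE,
    variant = "no_gxe", fallback_from = NULL,
    sites = sites, genotypes = genotypes, spec = met_spec()),
    class = "met_fit")
}

# a site_fit skeleton for filter tests
stub_site_fit <- function(site, h2, converged = TRUE) {
  structure(list(site = site, genotype_estimates = numeric(0),
                 replicate_effects = numeric(0), sigma2_sb = 0.01,
                 sigma2_e = 0.1, sigma2_g = 0.2, sigma2_sb_random = 0.01,
                 sigma2_e_random = 0.1, n_reps = 2, h2 = h2,
                 reml_loglik = 0, converged = converged),
            class = "site_fit")
}
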