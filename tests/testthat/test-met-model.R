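# the three evaluation routes: fast block-structured path (used by
# fit_met), general MME path (reml_loglik_met), dense error contrasts

test_that("all likelihood routes agree at random parameters", {
  sim <- small_trial(seed = 31, sites = c(ME1 = 3, ME4 = 2))
  rec <- sim$records
  s <- length(unique(rec$site))
  for (i in 1:3) {
    prm <- with_seed_local(100 + i, {
      lam <- matrix(runif(s, 0.1, 0.5), s, 1)
      list(s2r = exp(runif(s, log(0.005), log(0.1))),
           s2g = exp(runif(1, log(0.02), log(0.3))),
           lam = lam, psi = runif(s, 0.02, 0.15),
           s2e = exp(runif(1, log(0.05), log(0.3))))
    })
    Sge <- tcrossprod(prm$lam) + diag(prm$psi, s)
    ll_mme <- reml_loglik_met(rec, prm$s2r, prm$s2g, Sge, prm$s2e)
    ll_dense <- reml_loglik_met_dense(rec, prm$s2r, prm$s2g, Sge, prm$s2e)
    prep <- gxegain:::prep_met_fast(rec)
    ll_fast <- gxegain:::eval_met_fast(
      list(s2r = prm$s2r, s2g = prm$s2g, lambda = prm$lam, psi = prm$psi,
           s2e = prm$s2e), prep)$loglik
    expect_lt(abs(ll_mme - ll_dense), 1e-8)
    expect_lt(abs(ll_fast - ll_dense), 1e-8)
  }
})

test_that("likelihood routes agree with missing genotype-site cells", {
  rec <- small_trial(seed = 32, sites = c(ME1 = 3),
                     missing_site_rate = 0.25)$records
  s <- 3
  lam <- matrix(c(0.2, 0.3, 0.4), s, 1)
  Sge <- tcrossprod(lam) + diag(c(0.05, 0.08, 0.03), s)
  ll_mme <- reml_loglik_met(rec, c(0.01, 0.02, 0.03), 0.1, Sge, 0.12)
  ll_dense <- reml_loglik_met_dense(rec, c(0.01, 0.02, 0.03), 0.1, Sge,
                                    0.12)
  expect_lt(abs(ll_mme - ll_dense), 1e-8)
})

test_that("vanishing random variances reduce to the OLS site-means model", {
  rec <- small_trial(seed = 33, sites = c(ME1 = 2))$records
  s2e <- 0.09
  eps <- 1e-10
  s <- 2
  ll <- reml_loglik_met(rec, rep(eps, s), eps, diag(eps, s), s2e)
  ols <- lm(yield ~ 0 + site, data = rec)
  n <- nrow(rec); p <- s
  rss <- sum(residuals(ols)^2)
  ll_ols <- -0.5 * ((n - p) * (log(2 * pi) + log(s2e)) + rss / s2e)
  expect_lt(abs(ll - ll_ols), 1e-4)
})

test_that("duplicating records and halving the residual changes the value", {
  rec <- small_trial(seed = 34, sites = c(ME1 = 2))$records
  s <- 2
  Sge <- diag(0.05, s)
  ll1 <- reml_loglik_met(rec, c(0.01, 0.01), 0.1, Sge, 0.2)
  rec2 <- rbind(rec, transform(rec, rep = rep + 2))
  ll2 <- reml_loglik_met(rec2, c(0.01, 0.01), 0.1, Sge, 0.1)
  expect_gt(abs(ll1 - ll2), 1)
  # the perturbed instance still matches its own dense reference
  expect_lt(abs(ll2 - reml_loglik_met_dense(rec2, c(0.01, 0.01), 0.1,
                                            Sge, 0.1)), 1e-8)
})

test_that("optimized log-likelihoods respect the model nesting", {
  rec <- small_trial(seed = 35, n_genotypes = 20, n_subblocks = 4,
                     sites = c(ME1 = 4))$records
  lf <- fit_met(rec, met_spec(fa_order = 1, n_starts = 2), seed = 1)
  ld <- fit_met(rec, met_spec(model_variant = "diagonal"), seed = 1)
  lc <- fit_met(rec, met_spec(model_variant = "cs"), seed = 1)
  ln <- fit_met(rec, met_spec(model_variant = "no_gxe"), seed = 1)
  expect_gte(lf$reml_loglik, ld$reml_loglik - 1e-6)
  expect_gte(ld$reml_loglik, lc$reml_loglik - 1e-6)
  expect_gte(lc$reml_loglik, ln$reml_loglik - 1e-6)
})

test_that("BLUPs are centered by construction", {
  rec <- small_trial(seed = 36, n_genotypes = 20, n_subblocks = 4,
                     sites = c(ME1 = 3, ME5 = 2))$records
  fit <- fit_met(rec, met_spec(n_starts = 2), seed = 2)
  expect_lt(abs(mean(fit$blup_g)), 1e-8)
  expect_lt(max(abs(colMeans(fit$blup_ge))), 1e-6)
  # implied GxE correlations are proper correlations
  cm <- cov2cor(fit$Sigma_ge)
  expect_true(all(abs(cm[upper.tri(cm)]) <= 1 + 1e-12))
  expect_true(all(diag(fit$Sigma_ge) > 0))
})

test_that("no genetic signal shrinks genotype BLUPs toward zero", {
  devs <- vapply(c(501, 502, 503), function(i) {
    cfg <- sim_config(n_trials = 1, n_genotypes = 30, n_subblocks = 5,
                      n_sites_per_me = c(ME1 = 3), sigma_g = 0,
                      fa_order = 0, trend_pct_per_year = 0,
                      lowh2_site_rate = 0, seed = i)
    rec <- simulate_series(cfg)$records
    fit <- fit_met(rec, met_spec(model_variant = "no_gxe"), seed = i)
    mean(abs(fit$blup_g))
  }, 0)
  expect_lt(mean(devs), 0.02)
})

test_that("BLUPs vanish as the residual variance grows", {
  rec <- small_trial(seed = 37, sites = c(ME1 = 3))$records
  prep <- gxegain:::prep_met_fast(rec)
  s <- 3
  base <- list(s2r = rep(0.01, s), s2g = 0.1,
               lambda = matrix(0.3, s, 1), psi = rep(0.05, s))
  norms <- vapply(c(0.1, 10, 1e4), function(s2e) {
    ev <- gxegain:::eval_met_fast(c(base, list(s2e = s2e)), prep,
                                  solutions = TRUE)
    max(abs(ev$blup_g))
  }, 0)
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[3], 1e-3)
})

test_that("rank-1 interaction truth yields near-unit GxE correlations", {
  run_at <- function(g) {
    cfg <- sim_config(n_trials = 1, n_genotypes = g, n_subblocks = 5,
                      n_sites_per_me = c(ME1 = 5), psi_range = c(0, 0),
                      loading_range = c(0.55, 0.9), trend_pct_per_year = 0,
                      lowh2_site_rate = 0, seed = 38)
    rec <- simulate_series(cfg)$records
    fit <- fit_met(rec, met_spec(fa_order = 1), seed = 3)
    cm <- cov2cor(fit$Sigma_ge)
    abs(cm[upper.tri(cm)])
  }
  # separating the site-specific variances from plot noise is limited by
  # the entry count; the tolerance tightens as entries are added
  expect_true(all(abs(run_at(50) - 1) < 0.15))
  expect_true(all(abs(run_at(200) - 1) < 0.1))
})

test_that("predictions decompose and aggregate as defined", {
  rec <- small_trial(seed = 39, sites = c(ME1 = 2, ME4 = 1))$records
  fit <- fit_met(rec, met_spec(model_variant = "no_gxe"), seed = 1)
  gn <- fit$genotypes[3]
  for (st in fit$sites)
    expect_equal(unname(predict_yield(fit, gn, st)),
                 unname(fit$site_means[st] + fit$blup_g[gn]))
  expect_equal(unname(predict_yield(fit, gn)),
               mean(vapply(fit$sites, function(st)
                 unname(predict_yield(fit, gn, st)), 0)),
               tolerance = 1e-10)
  expect_error(predict_yield(fit, "NOPE"), "unknown genotype")
  expect_error(predict_yield(fit, gn, "NOSITE"), "unknown site")
})

test_that("noise-free data is reproduced by the fitted model", {
  cfg <- sim_config(n_trials = 1, n_genotypes = 10, n_subblocks = 2,
                    n_sites_per_me = c(ME1 = 3), sigma_g = 0.4,
                    sigma_sb = 0, sigma_r = 0, sigma_e = 0, fa_order = 0,
                    trend_pct_per_year = 0, lowh2_site_rate = 0, seed = 40)
  sim <- simulate_series(cfg)
  # the local check has site-specific true effects; exclude it so the
  # remaining data is exactly site mean + genotype effect
  rec <- sim$records[sim$records$genotype != "LOCAL_CHECK", ]
  fit <- fit_met(rec, met_spec(model_variant = "no_gxe"), seed = 1)
  eff <- sim$truth$trials[[1]]$genotype_effects
  means <- sim$truth$trials[[1]]$site_means
  for (st in fit$sites)
    for (gn in names(eff)[1:4])
      expect_equal(unname(predict_yield(fit, gn, st)),
                   unname(means[st] + eff[gn]), tolerance = 1e-3)
})

test_that("fit is invariant to the starting rotation of the loadings", {
  rec <- small_trial(seed = 41, n_genotypes = 30, n_subblocks = 5,
                     sites = c(ME1 = 4))$records
  f1 <- fit_met(rec, met_spec(fa_order = 1, n_starts = 3), seed = 5)
  f2 <- fit_met(rec, met_spec(fa_order = 1, n_starts = 3), seed = 99)
  expect_lt(abs(f1$reml_loglik - f2$reml_loglik), 1e-4)
  expect_lt(norm(f1$Sigma_ge - f2$Sigma_ge, "F"), 1e-2)
})

test_that("recovery improves with more genotypes", {
  err_at <- function(g, seeds) {
    vapply(seeds, function(i) {
      cfg <- sim_config(n_trials = 1, n_genotypes = g, n_subblocks = 2,
                        n_sites_per_me = c(ME1 = 4),
                        trend_pct_per_year = 0, lowh2_site_rate = 0,
                        seed = 7000 + i)
      sim <- simulate_series(cfg)
      fit <- fit_met(sim$records, met_spec(fa_order = 1, n_starts = 1),
                     seed = i)
      truth <- sim$truth$trials[[1]]$Sigma_ge
      norm(fit$Sigma_ge - truth, "F") / norm(truth, "F")
    }, 0)
  }
  seeds <- 1:8
  expect_gte(median(err_at(40, seeds)), median(err_at(200, seeds)) - 0.05)
})

test_that("heterogeneous residual variances are available behind the flag", {
  rec <- small_trial(seed = 42, sites = c(ME1 = 2, ME4 = 1))$records
  fit <- fit_met(rec, met_spec(model_variant = "diagonal",
                               het_resid = TRUE), seed = 1)
  expect_length(fit$sigma2_e, 3)
  expect_true(all(fit$sigma2_e > 0))
})

test_that("the REML information criterion penalizes unneeded structure", {
  cfg <- sim_config(n_trials = 1, n_genotypes = 30, n_subblocks = 5,
                    n_sites_per_me = c(ME1 = 4), fa_order = 0,
                    trend_pct_per_year = 0, lowh2_site_rate = 0,
                    seed = 44)
  rec <- simulate_series(cfg)$records    # no interaction in truth
  f_fa <- fit_met(rec, met_spec(fa_order = 1, n_starts = 2), seed = 1)
  f_ng <- fit_met(rec, met_spec(model_variant = "no_gxe"), seed = 1)
  expect_lt(met_aic(f_ng), met_aic(f_fa))
  expect_equal(met_aic(f_fa),
               -2 * f_fa$reml_loglik + 2 * f_fa$n_vc_params)
})

test_that("configuration errors are raised", {
  rec <- small_trial(seed = 43, sites = c(ME1 = 2))$records
  expect_error(fit_met(rec, met_spec(fa_order = 2)), "fa_order")
  one_site <- rec[rec$site == rec$site[1], ]
  expect_error(fit_met(one_site), "at least 2 sites")
  expect_error(met_spec(tol = 0), "tol")
})
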