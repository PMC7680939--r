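test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genotypes = 2), "at least 3 entries")
  expect_error(sim_config(n_genotypes = 49, n_subblocks = 5),
               "block geometry")
  expect_error(sim_config(sigma_e = -1), "sigma_e")
  expect_error(sim_config(n_sites_per_me = c(ME9 = 2),
                          site_mean_range = list()), "site_mean_range|ME9")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("noise-free limit: plot yield is site mean plus the trend term", {
  sim <- noise_free_trial(trend = 1.67, n_trials = 2)
  mu_check <- sim$truth$mu_check
  for (t in 1:2) {
    rec <- sim$records[sim$records$year == t, ]
    means <- sim$truth$trials[[t]]$site_means
    eff <- sim$truth$trials[[t]]$genotype_effects
    test_lines <- setdiff(names(eff), "ATTILA")
    expect_equal(unname(eff[test_lines]),
                 rep(1.67 * t * mu_check / 100, length(test_lines)))
    is_test <- rec$genotype %in% test_lines
    expect_equal(rec$yield[is_test],
                 means[rec$site[is_test]] + 1.67 * t * mu_check / 100,
                 ignore_attr = TRUE, tolerance = 1e-12)
    is_att <- rec$genotype == "ATTILA"
    expect_equal(rec$yield[is_att], unname(means[rec$site[is_att]]),
                 tolerance = 1e-12)
  }
})

test_that("design is a resolvable alpha-lattice", {
  sim <- small_trial(seed = 4, n_genotypes = 20, n_subblocks = 4)
  rec <- sim$records
  for (st in unique(rec$site)) {
    for (r in 1:2) {
      blk <- rec[rec$site == st & rec$rep == r, ]
      # each genotype exactly once per replicate
      expect_equal(sort(unique(blk$genotype)), sort(blk$genotype))
      expect_equal(nrow(blk), 20)
      # sub-blocks partition the entries into 4 disjoint sets of 5
      sizes <- table(blk$subblock)
      expect_equal(unname(sizes), rep(5L, 4L), ignore_attr = TRUE)
      expect_equal(anyDuplicated(blk$genotype), 0L)
    }
  }
})

test_that("zero missing rate gives a complete genotype x site table", {
  sim <- small_trial(seed = 5, missing_site_rate = 0)
  tab <- table(sim$records$genotype, sim$records$site)
  expect_true(all(tab == 2))
  sim2 <- small_trial(seed = 5, missing_site_rate = 0.3)
  tab2 <- table(sim2$records$genotype, sim2$records$site)
  expect_true(any(tab2 == 0))
  # checks are never dropped
  expect_true(all(tab2[c("LOCAL_CHECK", "ATTILA"), ] == 2))
})

test_that("GxE effects follow the factor-analytic covariance", {
  # make GxE observable: no genetic, block or residual noise
  cfg <- sim_config(n_trials = 1, n_genotypes = 1000, n_subblocks = 4,
                    n_sites_per_me = c(ME1 = 4), trend_pct_per_year = 0,
                    sigma_g = 0, sigma_sb = 0, sigma_r = 0, sigma_e = 0,
                    lowh2_site_rate = 0, seed = 42)
  sim <- simulate_series(cfg)
  truth <- sim$truth$trials[[1]]$Sigma_ge
  rec <- sim$records[sim$records$rep == 1 &
                     !(sim$records$genotype %in% c("ATTILA", "LOCAL_CHECK")), ]
  means <- sim$truth$trials[[1]]$site_means
  ge <- tapply(rec$yield - means[rec$site],
               list(rec$genotype, rec$site), mean)
  C <- crossprod(ge) / nrow(ge)
  err_big <- norm(C - truth, "F") / norm(truth, "F")
  expect_lt(err_big, 0.2)  # Monte-Carlo error at n = 998
  # error shrinks with sample size (1/sqrt(n) scaling)
  C_small <- crossprod(ge[1:80, ]) / 80
  err_small <- norm(C_small - truth, "F") / norm(truth, "F")
  expect_lt(err_big, err_small)
})

test_that("sub-block and residual variances match their configuration", {
  # sub-blocks observable when everything else is switched off
  cfg <- sim_config(n_trials = 1, n_genotypes = 10, n_subblocks = 5,
                    n_sites_per_me = c(ME1 = 50), trend_pct_per_year = 0,
                    fa_order = 0, sigma_g = 0, sigma_sb = 0.15,
                    sigma_r = 0, sigma_e = 0, lowh2_site_rate = 0,
                    seed = 8)
  sim <- simulate_series(cfg)
  rec <- sim$records
  means <- sim$truth$trials[[1]]$site_means
  sb_eff <- tapply(rec$yield - means[rec$site],
                   paste(rec$site, rec$rep, rec$subblock), mean)
  n <- length(sb_eff)
  mc_se <- 0.15^2 * sqrt(2 / n)
  expect_lt(abs(var(as.numeric(sb_eff)) - 0.15^2), 3 * mc_se)

  cfg2 <- sim_config(n_trials = 1, n_genotypes = 50, n_subblocks = 5,
                     n_sites_per_me = c(ME1 = 10), trend_pct_per_year = 0,
                     fa_order = 0, sigma_g = 0, sigma_sb = 0,
                     sigma_r = 0, sigma_e = 0.35, lowh2_site_rate = 0,
                     seed = 9)
  sim2 <- simulate_series(cfg2)
  rec2 <- sim2$records
  means2 <- sim2$truth$trials[[1]]$site_means
  resid <- rec2$yield - means2[rec2$site]
  mc_se2 <- 0.35^2 * sqrt(2 / length(resid))
  expect_lt(abs(var(resid) - 0.35^2), 3 * mc_se2)
})

test_that("records survive a disk round trip exactly", {
  sim <- small_trial(seed = 6, sites = c(ME1 = 2, ME4 = 1))
  dir <- tempfile()
  write_records(sim$records, sim$meta, dir)
  back <- read_records(dir)
  expect_identical(back$records$genotype, sim$records$genotype)
  expect_identical(back$records$site, sim$records$site)
  expect_identical(back$records$rep, sim$records$rep)
  expect_identical(back$records$subblock, sim$records$subblock)
  expect_identical(back$records$yield, sim$records$yield)
  expect_identical(back$meta$site, sim$meta$site)
  expect_equal(back$meta$tmin_coolest_quarter,
               sim$meta$tmin_coolest_quarter)
  unlink(dir, recursive = TRUE)

  # one-record file
  one <- sim$records[1, , drop = FALSE]
  dir2 <- tempfile()
  write_records(one, sim$meta[1, , drop = FALSE], dir2)
  expect_identical(read_records(dir2)$records$yield, one$yield)
  unlink(dir2, recursive = TRUE)
})

test_that("malformed files are rejected with line numbers", {
  sim <- small_trial(seed = 7)
  dir <- tempfile()
  write_records(sim$records, sim$meta, dir)
  expect_error(read_records(dir, n_subblocks = 1), "line.*subblock")

  # duplicate (genotype, site, rep)
  rec <- sim$records
  rec2 <- rbind(rec, rec[1, ])
  dir2 <- tempfile()
  write_records(rec2, sim$meta, dir2)
  expect_error(read_records(dir2), "duplicate")
  unlink(dir2, recursive = TRUE)

  # unparseable yield on a known line
  lines <- readLines(file.path(dir, "records.csv"))
  lines[3] <- sub("[0-9.]+$", "oops", lines[3])
  writeLines(lines, file.path(dir, "records.csv"))
  expect_error(read_records(dir), "line 3")
  unlink(dir, recursive = TRUE)
})

test_that("series generation is reproducible for a given seed", {
  a <- small_trial(seed = 11)
  b <- small_trial(seed = 11)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$trials[[1]]$Sigma_ge,
                   b$truth$trials[[1]]$Sigma_ge)
  c <- small_trial(seed = 12)
  expect_false(identical(a$records$yield, c$records$yield))
})
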