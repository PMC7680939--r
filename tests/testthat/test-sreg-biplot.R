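rank2_table <- function(seed = 1, g = 20, e = 8) {
  with_seed_local(seed, {
    gxe_table(5 + outer(rnorm(g), rnorm(e)) + outer(rnorm(g), rnorm(e)))
  })
}

test_that("a rank-2 table is explained exactly by the first two axes", {
  tab <- rank2_table(61)
  for (sc in c("standardized", "centered")) {
    bp <- sreg_decompose(tab, sc)
    expect_equal(bp$pct_explained_12, 100, tolerance = 1e-9)
  }
})

test_that("singular values account for the processed sum of squares and
           scores reconstruct a rank-2 table", {
  tab <- rank2_table(62)
  bp <- sreg_decompose(tab, "centered")
  M <- sweep(unclass(tab), 2, colMeans(tab))
  expect_equal(sum(bp$singular_values^2), sum(M^2), tolerance = 1e-9)
  expect_equal(bp$genotype_scores %*% t(bp$environment_scores), M,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(bp$singular_values) <= 1e-12))
})

test_that("score partitionings differ per side but agree on the product", {
  tab <- rank2_table(60)
  prods <- lapply(c("symmetric", "genotype", "environment"), function(sv) {
    bp <- sreg_decompose(tab, "centered", svp = sv)
    bp$genotype_scores %*% t(bp$environment_scores)
  })
  expect_equal(prods[[1]], prods[[2]], tolerance = 1e-9)
  expect_equal(prods[[1]], prods[[3]], tolerance = 1e-9)
})

test_that("identical genotype rows collapse to the origin", {
  tab <- gxe_table(matrix(rep(c(4, 5, 6), each = 5), 5, 3))
  bp <- sreg_decompose(tab, "centered")
  expect_true(all(abs(bp$genotype_scores) < 1e-10))
  expect_null(bp$vertex_genotypes)
})

test_that("environment-specific constants do not affect the decomposition", {
  tab <- rank2_table(63)
  shifted <- gxe_table(sweep(unclass(tab), 2, c(1:8), "+"))
  b1 <- sreg_decompose(tab, "centered")
  b2 <- sreg_decompose(shifted, "centered")
  expect_equal(b1$genotype_scores, b2$genotype_scores, tolerance = 1e-9)
  expect_equal(b1$pct_explained_12, b2$pct_explained_12, tolerance = 1e-9)
})

test_that("explained share decreases as noise is added to a rank-2 signal", {
  tab <- rank2_table(64)
  pcts <- vapply(c(0, 0.5, 2), function(sd) {
    noisy <- with_seed_local(65, unclass(tab) +
                             matrix(rnorm(length(tab), 0, sd), nrow(tab)))
    sreg_decompose(gxe_table(noisy), "centered")$pct_explained_12
  }, 0)
  expect_true(all(diff(pcts) < 0))
})

test_that("degenerate tables are rejected with clear messages", {
  expect_error(gxe_table(matrix(1, 2, 4)), "3 genotypes")
  expect_error(gxe_table(matrix(1, 5, 1)), "2 environments")
  m <- matrix(rnorm(20), 5, 4); m[2, ] <- NA
  expect_error(gxe_table(m), "fully missing genotype")
  tab <- rank2_table(66)
  tt <- unclass(tab); tt[1, 1] <- NA
  tab2 <- gxe_table(tt)
  expect_error(sreg_decompose(tab2), "missing cells")
  const <- unclass(rank2_table(67)); const[, 2] <- 7
  expect_error(sreg_decompose(gxe_table(const), "standardized"),
               "zero-variance environment.*E2")
})

test_that("which-won-where geometry picks the sector vertex", {
  res <- structure(list(
    genotype_scores = matrix(c(1, 1, -1, -1, 1, -1, 1, -1), 4, 2,
                             dimnames = list(c("G1", "G2", "G3", "G4"),
                                             c("PC1", "PC2"))),
    environment_scores = matrix(c(0.5, 0.5), 1, 2,
                                dimnames = list("E1", c("PC1", "PC2")))),
    class = "biplot_result")
  www <- which_won_where(res)
  expect_setequal(www$vertex_genotypes, c("G1", "G2", "G3", "G4"))
  expect_identical(unname(www$sector_winners["E1"]), "G1")
})

test_that("sector winners equal the brute-force rank-2 argmax", {
  for (seed in 68:70) {
    tab <- rank2_table(seed)
    bp <- sreg_decompose(tab, "centered")
    M <- sweep(unclass(tab), 2, colMeans(tab))
    bf <- rownames(tab)[apply(M, 2, which.max)]
    expect_identical(unname(bp$sector_winners[colnames(tab)]), bf)
  }
})

test_that("collinear genotype scores are a degenerate hull", {
  res <- structure(list(
    genotype_scores = matrix(c(1, 2, 3, 2, 4, 6), 3, 2,
                             dimnames = list(c("A", "B", "C"), NULL)),
    environment_scores = matrix(c(1, 1), 1, 2,
                                dimnames = list("E1", NULL))),
    class = "biplot_result")
  expect_error(which_won_where(res), "degenerate hull")
})

test_that("environment correlations use the closed-form t test", {
  # construct columns with an exact sample correlation of 0.4
  n <- 10
  xz <- with_seed_local(71, list(x = rnorm(n), z0 = rnorm(n)))
  x <- scale(xz$x)[, 1]
  z <- scale(resid(lm(xz$z0 ~ x)))[, 1]
  y <- 0.4 * x + sqrt(1 - 0.16) * z
  extra <- x + z     # third column so the table is valid
  tab <- gxe_table(cbind(E1 = x, E2 = y, E3 = extra,
                         deparse.level = 0) + 5,
                   genotype_labels = paste0("G", 1:n),
                   environment_labels = c("E1", "E2", "E3"))
  ec <- environment_correlations(tab)
  expect_equal(ec$r["E1", "E2"], 0.4, tolerance = 1e-10)
  ref <- cor.test(x, y)
  expect_lt(abs(ec$p["E1", "E2"] - ref$p.value), 1e-10)
  # duplicated environment
  tab2 <- gxe_table(cbind(E1 = x, E2 = x, E3 = y) + 5)
  ec2 <- environment_correlations(tab2)
  expect_equal(ec2$r[1, 2], 1)
  expect_lt(ec2$p[1, 2], 1e-12)
  # orthogonalized residual column
  expect_lt(abs(ec$r["E1", "E3"] - cor(x, extra)), 1e-12)
  tab3 <- gxe_table(cbind(E1 = x, E2 = z, E3 = y) + 5)
  expect_lt(abs(environment_correlations(tab3)$r["E1", "E2"]), 1e-10)
})

test_that("pairs with too few common genotypes are flagged, not errors", {
  m <- matrix(rnorm(12) + 5, 4, 3,
              dimnames = list(paste0("G", 1:4), paste0("E", 1:3)))
  m[1:2, 2] <- NA
  ec <- environment_correlations(gxe_table(m))
  expect_true(is.na(ec$r[1, 2]))
  expect_equal(ec$n[1, 2], 2L)
  expect_false(is.na(ec$r[1, 3]))
})

test_that("megaenvironment BLUP correlations behave at the extremes", {
  genos <- sprintf("L%02d", 1:15)
  f1 <- stub_met_fit(genos, c("S1", "S2"), c(5, 6),
                     blup_g = seq(-0.5, 0.5, length.out = 15))
  ec <- me_blup_correlations(list(ME1 = f1, ME4 = f1))
  expect_equal(ec$r["ME1", "ME4"], 1)
  f2 <- stub_met_fit(sprintf("X%02d", 1:15), c("S1", "S2"), c(5, 6),
                     blup_g = rnorm(15))
  expect_error(me_blup_correlations(list(ME1 = f1, ME4 = f2)),
               "fewer than 3 genotypes")
})

test_that("independent megaenvironments correlate near zero, shared
           genetics near one", {
  r_null <- vapply(1:6, function(i) {
    cfg1 <- sim_config(n_trials = 1, n_genotypes = 20, n_subblocks = 4,
                       n_sites_per_me = c(ME1 = 2), sigma_g = 0,
                       trend_pct_per_year = 0, lowh2_site_rate = 0,
                       seed = 900 + i)
    cfg2 <- cfg1; cfg2$seed <- 950 + i
    s1 <- simulate_series(cfg1); s2 <- simulate_series(cfg2)
    # same entry list, independent environments and GxE draws
    f1 <- fit_met(s1$records, met_spec(n_starts = 1), seed = i)
    f2 <- fit_met(s2$records, met_spec(n_starts = 1), seed = i)
    me_blup_correlations(list(ME1 = f1, ME4 = f2))$r["ME1", "ME4"]
  }, 0)
  expect_lt(abs(mean(r_null)), 2 * sd(r_null) / sqrt(length(r_null)) + 0.25)

  r_shared <- vapply(1:3, function(i) {
    cfg <- sim_config(n_trials = 1, n_genotypes = 20, n_subblocks = 4,
                      n_sites_per_me = c(ME1 = 2, ME4 = 2), sigma_g = 1,
                      loading_range = c(0.05, 0.1), psi_range = c(0.01, 0.02),
                      trend_pct_per_year = 0, lowh2_site_rate = 0,
                      seed = 970 + i)
    sim <- simulate_series(cfg)
    rec <- sim$records
    me1 <- sim$meta$site[sim$meta$me_true == "ME1"]
    f1 <- fit_met(rec[rec$site %in% me1, ], met_spec(n_starts = 1),
                  seed = i)
    f2 <- fit_met(rec[!rec$site %in% me1, ], met_spec(n_starts = 1),
                  seed = i)
    me_blup_correlations(list(ME1 = f1, ME4 = f2))$r["ME1", "ME4"]
  }, 0)
  expect_gt(mean(r_shared), 0.8)
})
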