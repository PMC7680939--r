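# Synthetic international elite-spring-wheat-style trial series with known
# ground truth.

#' Configuration for a synthetic international trial series
#'
#' Describes an annual series of multi-environment wheat yield trials in the
#' style of an internationally distributed elite spring wheat nursery: each
#' trial-year distributes a fresh set of test lines plus two checks (entry 1
#' is a site-specific local check; one entry is a long-term check cultivar,
#' `"ATTILA"`) to a set of locations spread over up to three megaenvironments,
#' laid out as an alpha-lattice with `n_reps` replicates each split into
#' `n_subblocks` incomplete sub-blocks.
#'
#' Genotype-by-environment (GxE) effects are drawn per trial from a
#' factor-analytic covariance \eqn{\Lambda\Lambda' + \Psi} of rank
#' `fa_order`; test-line genetic effects carry a linear trend of
#' `trend_pct_per_year` percent of the long-term check's expected yield per
#' trial-year, so the true annual gain is known exactly.
#'
#' @param n_trials number of consecutive trial-years.
#' @param n_genotypes entries per trial (local check + long-term check +
#'   test lines); must be a multiple of `n_subblocks`.
#' @param n_sites_per_me named integer vector, number of locations per
#'   megaenvironment label (`ME1`, `ME4`, `ME5`); zero entries allowed.
#' @param n_reps replicates per location.
#' @param n_subblocks sub-blocks per replicate.
#' @param trend_pct_per_year true annual genetic gain of new lines relative
#'   to the long-term check, in percent per year.
#' @param site_mean_range named list of 2-vectors, Mg/ha bounds of location
#'   mean yield per megaenvironment.
#' @param fa_order rank of the true GxE loading matrix; `0` disables GxE.
#' @param sigma_g genetic standard deviation of test lines (Mg/ha).
#' @param loading_range bounds for the uniformly drawn entries of the true
#'   GxE loading matrix (Mg/ha).
#' @param psi_range bounds for the uniformly drawn site-specific GxE
#'   variances (Mg^2/ha^2).
#' @param sigma_sb sub-block standard deviation (Mg/ha).
#' @param sigma_r replicate-within-site standard deviation (Mg/ha).
#' @param sigma_e plot residual standard deviation (Mg/ha).
#' @param missing_site_rate fraction of test-line-by-site cells dropped
#'   (checks are never dropped so reference yields stay computable).
#' @param lowh2_site_rate fraction of sites generated with a 20-fold
#'   inflated residual standard deviation, i.e. near-zero heritability.
#' @param seed integer RNG seed; all randomness in [simulate_series()] is
#'   reproducible given the seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_series()]
#' @export
sim_config <- function(n_trials = 8L,
                       n_genotypes = 50L,
                       n_sites_per_me = c(ME1 = 22L, ME4 = 9L, ME5 = 7L),
                       n_reps = 2L,
                       n_subblocks = 5L,
                       trend_pct_per_year = 1.67,
                       site_mean_range = list(ME1 = c(4.5, 7.0),
                                              ME4 = c(2.0, 4.0),
                                              ME5 = c(3.5, 5.5)),
                       fa_order = 1L,
                       sigma_g = 0.3,
                       loading_range = c(0.15, 0.45),
                       psi_range = c(0.02, 0.08),
                       sigma_sb = 0.15,
                       sigma_r = 0.10,
                       sigma_e = 0.35,
                       missing_site_rate = 0,
                       lowh2_site_rate = 0.05,
                       seed = 1L) {
  cfg <- list(n_trials = as.integer(n_trials),
              n_genotypes = as.integer(n_genotypes),
              n_sites_per_me = n_sites_per_me,
              n_reps = as.integer(n_reps),
              n_subblocks = as.integer(n_subblocks),
              trend_pct_per_year = trend_pct_per_year,
              site_mean_range = site_mean_range,
              fa_order = as.integer(fa_order),
              sigma_g = sigma_g,
              loading_range = loading_range,
              psi_range = psi_range,
              sigma_sb = sigma_sb,
              sigma_r = sigma_r,
              sigma_e = sigma_e,
              missing_site_rate = missing_site_rate,
              lowh2_site_rate = lowh2_site_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  nonneg <- c("sigma_g", "sigma_sb", "sigma_r", "sigma_e")
  for (nm in nonneg)
    if (cfg[[nm]] < 0) stop("'", nm, "' must be >= 0")
  if (cfg$n_genotypes < 3L)
    stop("need at least 3 entries: local check, long-term check, >=1 test line")
  if (cfg$n_genotypes %% cfg$n_subblocks != 0L)
    stop("inconsistent block geometry: n_genotypes (", cfg$n_genotypes,
         ") must be a multiple of n_subblocks (", cfg$n_subblocks, ")")
  if (cfg$n_reps < 1L) stop("n_reps must be >= 1")
  if (any(cfg$n_sites_per_me < 0L) || sum(cfg$n_sites_per_me) < 1L)
    stop("n_sites_per_me must be nonnegative with at least one site")
  if (is.null(names(cfg$n_sites_per_me)))
    stop("n_sites_per_me must be named by megaenvironment label")
  for (me in names(cfg$n_sites_per_me)[cfg$n_sites_per_me > 0L])
    if (is.null(cfg$site_mean_range[[me]]))
      stop("no site_mean_range entry for ", me)
  if (cfg$missing_site_rate < 0 || cfg$missing_site_rate >= 1)
    stop("missing_site_rate must be in [0, 1)")
  if (cfg$lowh2_site_rate < 0 || cfg$lowh2_site_rate > 1)
    stop("lowh2_site_rate must be in [0, 1]")
  if (cfg$fa_order < 0L) stop("fa_order must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic trial-series configuration\n")
  cat("  trials:", x$n_trials, " entries/trial:", x$n_genotypes,
      " reps:", x$n_reps, "x", x$n_subblocks, "sub-blocks\n")
  cat("  sites/ME:", paste(names(x$n_sites_per_me), x$n_sites_per_me,
                           sep = "=", collapse = ", "), "\n")
  cat("  true trend:", x$trend_pct_per_year, "% per year; GxE rank:",
      x$fa_order, "\n")
  invisible(x)
}

# evaluate expr with a private, seeded RNG stream; restores user RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# expected yield of the long-term check: site-count-weighted mean of the
# per-ME site-mean midpoints (its genetic effect is 0 by construction)
check_expected_yield <- function(cfg) {
  mes <- names(cfg$n_sites_per_me)
  mids <- vapply(mes, function(me) mean(cfg$site_mean_range[[me]]), 0)
  sum(mids * cfg$n_sites_per_me) / sum(cfg$n_sites_per_me)
}

country_pool <- c("MEX", "IND", "PAK", "EGY", "AFG", "IRN", "PRT", "ZAF",
                  "TUR", "KEN", "BGD", "NPL", "MAR", "SDN")

#' Simulate a multi-year international trial series
#'
#' Generates plot-level yield records for `n_trials` consecutive trial-years
#' under the data-generating model
#' \deqn{y = \mu_{site} + r + sb + g + ge + \epsilon,}
#' with replicate, sub-block and plot residual effects i.i.d. normal,
#' test-line genetic effects for trial-year \eqn{t} drawn from
#' \eqn{N(\delta\, t\, \mu_{check}/100,\ \sigma_g^2)} (so the long-term
#' check, fixed at effect 0, falls behind by `trend_pct_per_year` percent of
#' its expected yield each year), the local check drawn near the top decile
#' of that trial's test lines at every site, and per-trial GxE effects drawn
#' from \eqn{N_s(0, \Lambda\Lambda' + \Psi)} per genotype.
#'
#' @param config a [sim_config()] object.
#' @return A list with components
#'   \describe{
#'     \item{records}{data.frame of plot observations with columns
#'       `genotype`, `site`, `year`, `rep`, `subblock`, `yield` (Mg/ha).}
#'     \item{meta}{data.frame of location metadata: `site`, `country`,
#'       `tmin_coolest_quarter` (deg C), `precip_wettest_quarter` (mm),
#'       `irrigated` (logical, `NA` = unconfirmed), `sowing`
#'       (`"normal"`/`"late"`), `me_true`, `year`, `lowh2` (whether the site
#'       was generated with inflated residual noise).}
#'     \item{truth}{`sim_truth` list: `true_trend_pct`, `mu_check`,
#'       `true_sigma_g`, `true_sigma_e`, and per-trial `Sigma_ge`, genotype
#'       effects, local-check effects, and site means.}
#'   }
#' @export
simulate_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    all_rec <- vector("list", cfg$n_trials)
    all_meta <- vector("list", cfg$n_trials)
    trials <- vector("list", cfg$n_trials)
    mu_check <- check_expected_yield(cfg)
    g <- cfg$n_genotypes
    n_test <- g - 2L
    for (t in seq_len(cfg$n_trials)) {
      meta <- simulate_sites(cfg, t)
      s <- nrow(meta)
      genos <- c("LOCAL_CHECK", "ATTILA",
                 sprintf("E%02d_%02d", t, seq_len(n_test)))
      eff <- c(NA_real_, 0,
               rnorm(n_test, cfg$trend_pct_per_year * t * mu_check / 100,
                     cfg$sigma_g))
      names(eff) <- genos
      # local check: site-specific, near the top decile of test lines
      lc_eff <- rnorm(s, stats::quantile(eff[-(1:2)], 0.9),
                      cfg$sigma_g / 4)
      names(lc_eff) <- meta$site
      # GxE covariance and effects
      if (cfg$fa_order > 0L) {
        lam <- matrix(runif(s * cfg$fa_order, cfg$loading_range[1],
                            cfg$loading_range[2]), s, cfg$fa_order)
        psi <- runif(s, cfg$psi_range[1], cfg$psi_range[2])
        Sigma_ge <- tcrossprod(lam) + diag(psi, s)
        scores <- matrix(rnorm(g * cfg$fa_order), g, cfg$fa_order)
        spec <- matrix(rnorm(g * s), g, s) %*% diag(sqrt(psi), s)
        ge <- scores %*% t(lam) + spec            # g x s
      } else {
        Sigma_ge <- matrix(0, s, s)
        ge <- matrix(0, g, s)
      }
      dimnames(ge) <- list(genos, meta$site)
      rep_eff <- matrix(rnorm(s * cfg$n_reps, 0, cfg$sigma_r),
                        s, cfg$n_reps, dimnames = list(meta$site, NULL))
      sigma_e_site <- ifelse(meta$lowh2, 20 * cfg$sigma_e, cfg$sigma_e)
      # missing test-line cells
      drop_cell <- matrix(FALSE, g, s, dimnames = list(genos, meta$site))
      if (cfg$missing_site_rate > 0)
        drop_cell[-(1:2), ] <- matrix(
          runif(n_test * s) < cfg$missing_site_rate, n_test, s)
      per_block <- g %/% cfg$n_subblocks
      recs <- vector("list", s)
      for (j in seq_len(s)) {
        site <- meta$site[j]
        gen_eff_site <- eff
        gen_eff_site["LOCAL_CHECK"] <- lc_eff[site]
        site_rec <- vector("list", cfg$n_reps)
        for (rr in seq_len(cfg$n_reps)) {
          ord <- sample(genos)
          sb <- rep(seq_len(cfg$n_subblocks), each = per_block)
          sb_eff <- rnorm(cfg$n_subblocks, 0, cfg$sigma_sb)
          yld <- meta$site_mean[j] + rep_eff[site, rr] + sb_eff[sb] +
            gen_eff_site[ord] + ge[ord, site] +
            rnorm(g, 0, sigma_e_site[j])
          site_rec[[rr]] <- data.frame(
            genotype = ord, site = site, year = t, rep = rr,
            subblock = sb, yield = pmax(yld, 0.01),
            stringsAsFactors = FALSE)
        }
        df <- do.call(rbind, site_rec)
        keep <- !drop_cell[cbind(match(df$genotype, genos),
                                 rep(j, nrow(df)))]
        recs[[j]] <- df[keep, , drop = FALSE]
      }
      all_rec[[t]] <- do.call(rbind, recs)
      all_meta[[t]] <- meta
      trials[[t]] <- list(Sigma_ge = Sigma_ge,
                          genotype_effects = eff[-1],
                          lc_effects = lc_eff,
                          site_means = stats::setNames(meta$site_mean,
                                                       meta$site))
    }
    records <- do.call(rbind, all_rec)
    rownames(records) <- NULL
    meta <- do.call(rbind, all_meta)
    rownames(meta) <- NULL
    truth <- structure(
      list(true_trend_pct = cfg$trend_pct_per_year,
           mu_check = mu_check,
           true_sigma_g = cfg$sigma_g,
           true_sigma_e = cfg$sigma_e,
           trials = trials),
      class = "sim_truth")
    list(records = records, meta = meta, truth = truth)
  })
}

# one trial-year's locations with climate/management consistent with their ME
simulate_sites <- function(cfg, t) {
  rows <- list()
  for (me in names(cfg$n_sites_per_me)) {
    ns <- cfg$n_sites_per_me[[me]]
    if (ns == 0L) next
    rng <- cfg$site_mean_range[[me]]
    for (j in seq_len(ns)) {
      site <- sprintf("T%d_%s_%02d", t, me, j)
      country <- sample(country_pool, 1)
      if (me == "ME1") {
        # optimal: low rainfall, irrigated, cool winters; irrigation status
        # occasionally not reported back by the cooperator
        irr <- if (runif(1) < 0.85) TRUE else NA
        row <- data.frame(site = site, country = country,
                          tmin_coolest_quarter = runif(1, 3, 10.9),
                          precip_wettest_quarter = runif(1, 20, 95),
                          irrigated = irr, sowing = "normal")
      } else if (me == "ME4") {
        row <- data.frame(site = site, country = country,
                          tmin_coolest_quarter = runif(1, 3, 10.9),
                          precip_wettest_quarter = runif(1, 100, 400),
                          irrigated = FALSE, sowing = "normal")
      } else if (me == "ME5") {
        if (runif(1) < 0.3) {
          # heat stress simulated by late sowing at a cool-winter station
          row <- data.frame(site = site, country = country,
                            tmin_coolest_quarter = runif(1, 4, 10),
                            precip_wettest_quarter = runif(1, 20, 95),
                            irrigated = TRUE, sowing = "late")
        } else {
          row <- data.frame(site = site, country = country,
                            tmin_coolest_quarter = runif(1, 11, 16),
                            precip_wettest_quarter = runif(1, 420, 900),
                            irrigated = sample(c(TRUE, FALSE), 1),
                            sowing = "normal")
        }
      } else stop("unsupported megaenvironment label: ", me)
      row$me_true <- me
      row$site_mean <- runif(1, rng[1], rng[2])
      rows[[length(rows) + 1L]] <- row
    }
  }
  meta <- do.call(rbind, rows)
  meta$year <- t
  meta$lowh2 <- runif(nrow(meta)) < cfg$lowh2_site_rate
  meta
}

#' Write / read plot records and site metadata
#'
#' `write_records()` stores the plot records and location metadata of a
#' (possibly simulated) trial series as two plain CSV files,
#' `records.csv` and `sites.csv`, with yields printed at full double
#' precision so that a round trip through disk is value-exact.
#' `read_records()` reads them back and validates the design structure.
#'
#' @param records,meta data.frames as returned by [simulate_series()].
#' @param path directory to write to / read from (created if missing).
#' @param n_subblocks if given, `read_records()` rejects sub-block indices
#'   outside `1..n_subblocks`.
#' @return `read_records()` returns `list(records, meta)`.
#' @export
write_records <- function(records, meta, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  rec <- records
  rec$yield <- sprintf("%.17g", rec$yield)
  utils::write.csv(rec, file.path(path, "records.csv"), row.names = FALSE,
                   quote = FALSE)
  m <- meta
  if (!is.null(m$site_mean)) m$site_mean <- sprintf("%.17g", m$site_mean)
  if (!is.null(m$tmin_coolest_quarter))
    m$tmin_coolest_quarter <- sprintf("%.17g", m$tmin_coolest_quarter)
  if (!is.null(m$precip_wettest_quarter))
    m$precip_wettest_quarter <- sprintf("%.17g", m$precip_wettest_quarter)
  utils::write.csv(m, file.path(path, "sites.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path, n_subblocks = NULL) {
  rec_file <- file.path(path, "records.csv")
  if (!file.exists(rec_file)) stop("no records.csv under ", path)
  rec <- utils::read.csv(rec_file, stringsAsFactors = FALSE,
                         colClasses = c(genotype = "character",
                                        site = "character"))
  need <- c("genotype", "site", "year", "rep", "subblock", "yield")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("records.csv is missing columns: ", paste(miss, collapse = ", "))
  for (col in c("year", "rep", "subblock", "yield")) {
    v <- suppressWarnings(as.numeric(rec[[col]]))
    bad <- which(is.na(v) & !is.na(rec[[col]]))
    if (length(bad))
      stop("records.csv line ", bad[1] + 1L, ": cannot parse '", col, "'")
    if (anyNA(v))
      stop("records.csv line ", which(is.na(v))[1] + 1L, ": missing ", col)
    rec[[col]] <- v
  }
  rec$year <- as.integer(rec$year)
  rec$rep <- as.integer(rec$rep)
  rec$subblock <- as.integer(rec$subblock)
  bad <- which(rec$yield <= 0)
  if (length(bad))
    stop("records.csv line ", bad[1] + 1L, ": yield must be > 0")
  if (!is.null(n_subblocks)) {
    bad <- which(rec$subblock < 1L | rec$subblock > n_subblocks)
    if (length(bad))
      stop("records.csv line ", bad[1] + 1L, ": subblock ",
           rec$subblock[bad[1]], " outside 1..", n_subblocks)
  }
  key <- paste(rec$genotype, rec$site, rec$year, rec$rep, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop("records.csv line ", d + 1L, ": duplicate (genotype, site, rep): ",
         rec$genotype[d], ", ", rec$site[d], ", rep ", rec$rep[d])
  }
  meta_file <- file.path(path, "sites.csv")
  meta <- NULL
  if (file.exists(meta_file)) {
    meta <- utils::read.csv(meta_file, stringsAsFactors = FALSE,
                            colClasses = c(site = "character"))
    if (anyDuplicated(meta$site))
      stop("sites.csv: duplicate site label ",
           meta$site[duplicated(meta$site)][1])
    if (!is.null(meta$irrigated)) meta$irrigated <- as.logical(meta$irrigated)
  }
  list(records = rec, meta = meta)
}
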