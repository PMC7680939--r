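# End-to-end pipeline: (simulate | ingest) -> single-site fits + h^2 filter
# -> megaenvironment classification -> per-trial MET fits per scope ->
# gain regressions -> site-regression biplot, with stage artifacts and a
# machine-readable manifest.  All randomness derives from the single
# master seed (MET fits for trial-year t use seed * 100 + t).

#' Pipeline configuration
#'
#' Exactly one of `input_path` (a directory readable by [read_records()])
#' or `sim` (a [sim_config()], whose seed is overridden by the pipeline
#' master seed) must be given.
#'
#' @param input_path directory with `records.csv` / `sites.csv`.
#' @param sim a [sim_config()].
#' @param h2_threshold heritability threshold of the site filter.
#' @param scopes character vector of analysis scopes: `"all"` and/or
#'   megaenvironment labels (`"ME1"`, `"ME4"`, `"ME5"`).
#' @param references checks to express gains against.
#' @param met a [met_spec()].
#' @param fraction selected fraction of test lines.
#' @param biplot run the final-trial country-level SREG biplot stage.
#' @param seed master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_path = NULL, sim = NULL,
                            h2_threshold = 0.05,
                            scopes = "all",
                            references = c("attila", "local_check"),
                            met = met_spec(), fraction = 0.10,
                            biplot = TRUE, seed = 1L) {
  if (is.null(input_path) == is.null(sim))
    stop("exactly one of input_path and sim must be given")
  structure(list(input_path = input_path, sim = sim,
                 h2_threshold = h2_threshold, scopes = scopes,
                 references = references, met = met, fraction = fraction,
                 biplot = isTRUE(biplot), seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes all stages on simulated or ingested records, writes per-stage
#' CSV artifacts plus a JSON run manifest under `out_dir`, and returns the
#' in-memory results.  Reruns with the same configuration and seed produce
#' numerically identical outputs (byte-identical CSVs); timings live only
#' in the manifest.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with `records`, `meta`, `site_fits`, `filter`,
#'   `assignments`, `met_fits` (per scope), `gains` (data.frame), `biplot`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t_start <- Sys.time()
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(Sys.time() - t0, units = "secs")

  # ---- input ----
  t0 <- tic()
  inp <- run_stage("input", {
    if (!is.null(config$sim)) {
      cfg <- config$sim
      cfg$seed <- config$seed
      simulate_series(cfg)
    } else {
      read_records(config$input_path)
    }
  })
  records <- inp$records; meta <- inp$meta
  timings$input <- toc(t0)

  # ---- single-site fits and heritability filter ----
  t0 <- tic()
  site_fits <- run_stage("site_fits", {
    out <- list()
    for (yr in sort(unique(records$year))) {
      rec_y <- records[records$year == yr, , drop = FALSE]
      for (st in sort(unique(rec_y$site))) {
        f <- fit_single_site(rec_y[rec_y$site == st, , drop = FALSE])
        out[[paste(yr, st, sep = "\r")]] <- list(year = yr, fit = f)
      }
    }
    out
  })
  filt <- run_stage("h2_filter", {
    filter_sites(lapply(site_fits, `[[`, "fit"), config$h2_threshold)
  })
  if (nrow(filt$dropped))
    message("h2 filter dropped ", nrow(filt$dropped), " site(s): ",
            paste(filt$dropped$site, collapse = ", "))
  kept_by_year <- lapply(split(records$site, records$year), function(ss)
    intersect(sort(unique(ss)), filt$kept))
  timings$site_fits <- toc(t0)

  # ---- megaenvironment classification ----
  t0 <- tic()
  assignments <- run_stage("me_classify", {
    if (is.null(meta)) stop("no site metadata available")
    asg <- assign_me(meta)
    asg$year <- meta$year
    parts <- lapply(split(seq_len(nrow(asg)), asg$year), function(ix) {
      rec_y <- records[records$year == asg$year[ix[1]], , drop = FALSE]
      ymeans <- tapply(rec_y$yield, rec_y$site, mean)
      refine_by_cluster(asg[ix, , drop = FALSE], ymeans)
    })
    do.call(rbind, parts)
  })
  timings$me_classify <- toc(t0)

  # ---- MET fits per scope ----
  t0 <- tic()
  met_fits <- run_stage("met", {
    if (length(filt$kept) == 0L) stop("no sites retained")
    out <- list()
    for (sc in config$scopes) {
      sites_by_year <- lapply(kept_by_year, function(ss) {
        if (sc == "all") ss else
          intersect(ss, assignments$site[assignments$me == sc])
      })
      out[[sc]] <- fit_trial_series(records, config$met,
                                    seed = config$seed,
                                    sites_by_year = sites_by_year)
    }
    out
  })
  for (sc in names(met_fits))
    for (f in met_fits[[sc]])
      if (!is.null(f$fallback_from))
        message("scope ", sc, ": FA fit fell back to ", f$variant)
  timings$met <- toc(t0)

  # ---- gains ----
  t0 <- tic()
  gains <- run_stage("gains", {
    rows <- list()
    for (sc in config$scopes) {
      fits <- met_fits[[sc]]
      for (ref in config$references) {
        est <- tryCatch({
          ser <- gain_series(fits, ref, scope = sc,
                             fraction = config$fraction)
          estimate_gain(ser)
        }, error = function(e) NULL)
        rows[[paste(sc, ref)]] <- data.frame(
          scope = sc, reference = ref,
          slope_pct = if (is.null(est)) NA_real_ else est$slope_pct_per_year,
          slope_kg = if (is.null(est)) NA_real_ else est$slope_kg_per_ha_year,
          intercept = if (is.null(est)) NA_real_ else est$intercept,
          se = if (is.null(est)) NA_real_ else est$slope_se,
          p = if (is.null(est)) NA_real_ else est$p_value,
          n = if (is.null(est)) 0L else est$n_points)
      }
    }
    do.call(rbind, rows)
  })
  timings$gains <- toc(t0)

  # ---- biplot (final trial, country means) ----
  biplot <- NULL
  if (config$biplot) {
    t0 <- tic()
    biplot <- run_stage("biplot", {
      last <- max(records$year)
      fit <- NULL
      for (sc in c("ME1", "all"))
        if (is.null(fit) && !is.null(met_fits[[sc]]))
          fit <- met_fits[[sc]][[as.character(last)]]
      if (is.null(fit)) fit <- met_fits[[1]][[as.character(last)]]
      tryCatch({
        tab <- country_mean_table(fit, meta[meta$year == last, ,
                                            drop = FALSE])
        list(result = sreg_decompose(tab),
             correlations = environment_correlations(tab),
             year = last)
      }, error = function(e) {
        message("biplot stage skipped: ", conditionMessage(e))
        NULL
      })
    })
    timings$biplot <- toc(t0)
  }

  # ---- artifacts ----
  sf_rows <- do.call(rbind, lapply(site_fits, function(x) {
    f <- x$fit
    data.frame(year = x$year, site = f$site, sigma2_sb = f$sigma2_sb,
               sigma2_e = f$sigma2_e, sigma2_g = f$sigma2_g,
               h2 = as.numeric(f$h2), converged = f$converged)
  }))
  rownames(sf_rows) <- NULL
  sf_rows$kept <- sf_rows$site %in% filt$kept
  sf_rows$drop_reason <-
    filt$dropped$reason[match(sf_rows$site, filt$dropped$site)]
  utils::write.csv(sf_rows, file.path(out_dir, "sitefits.csv"),
                   row.names = FALSE)
  utils::write.csv(assignments, file.path(out_dir, "assignments.csv"),
                   row.names = FALSE)
  mf_rows <- list()
  for (sc in names(met_fits))
    for (yr in names(met_fits[[sc]])) {
      f <- met_fits[[sc]][[yr]]
      mf_rows[[paste(sc, yr)]] <- data.frame(
        scope = sc, year = as.integer(yr), variant = f$variant,
        fallback = !is.null(f$fallback_from), converged = f$converged,
        reml_loglik = f$reml_loglik, sigma2_g = f$sigma2_g,
        sigma2_e = mean(f$sigma2_e),
        mean_ge_var = mean(diag(f$Sigma_ge)), n_sites = length(f$sites))
    }
  utils::write.csv(do.call(rbind, mf_rows),
                   file.path(out_dir, "metfits.csv"), row.names = FALSE)
  utils::write.csv(gains, file.path(out_dir, "gains.csv"),
                   row.names = FALSE)
  if (!is.null(biplot)) {
    bp <- biplot$result
    scores <- rbind(
      data.frame(kind = "genotype", label = rownames(bp$genotype_scores),
                 PC1 = bp$genotype_scores[, 1],
                 PC2 = bp$genotype_scores[, 2],
                 sector_winner = NA_character_),
      data.frame(kind = "environment",
                 label = rownames(bp$environment_scores),
                 PC1 = bp$environment_scores[, 1],
                 PC2 = bp$environment_scores[, 2],
                 sector_winner =
                   if (is.null(bp$sector_winners)) NA_character_ else
                     unname(bp$sector_winners[rownames(bp$environment_scores)])))
    rownames(scores) <- NULL
    utils::write.csv(scores, file.path(out_dir, "biplot.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    package = "gxegain",
    package_version = as.character(utils::packageVersion("gxegain")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    h2_threshold = config$h2_threshold,
    scopes = config$scopes,
    n_records = nrow(records),
    n_sites_dropped = nrow(filt$dropped),
    dropped_sites = filt$dropped,
    fa_fallbacks = sum(vapply(unlist(met_fits, recursive = FALSE),
                              function(f) !is.null(f$fallback_from),
                              logical(1))),
    pct_explained_12 = if (is.null(biplot)) NULL else
      biplot$result$pct_explained_12,
    stage_seconds = timings,
    total_seconds = as.numeric(Sys.time() - t_start, units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(list(records = records, meta = meta,
                 site_fits = lapply(site_fits, `[[`, "fit"),
                 filter = filt, assignments = assignments,
                 met_fits = met_fits, gains = gains, biplot = biplot,
                 manifest = manifest))
}
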