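# Genetic-gain statistics: BLUP yield of the top decile of test lines,
# expressed relative to the long-term check cultivar (GYA) or to the local
# checks (GYLC), regressed on trial-years.

#' Default check entry labels
#'
#' The long-term check cultivar and the site-specific local check occupy
#' fixed entry slots in every trial of the series.
#' @export
check_labels <- c(local_check = "LOCAL_CHECK", attila = "ATTILA")

#' Select the highest-yielding lines of a trial
#'
#' Returns the `ceiling(fraction * n)` test lines (entries not in `exclude`)
#' with the highest predicted yield in the given scope.  Ties are broken by
#' label order, and the result does not depend on the ordering of the input
#' records.
#'
#' @param fit a [fit_met()] object for one trial.
#' @param fraction selected fraction of test lines, in (0, 1]; default the
#'   top 10\%.
#' @param exclude labels never eligible (the checks, by default).
#' @param scope prediction scope passed to [predict_yield()].
#' @return Character vector of genotype labels, highest predicted yield
#'   first.
#' @export
select_hyl <- function(fit, fraction = 0.10, exclude = check_labels,
                       scope = "overall") {
  stopifnot(inherits(fit, "met_fit"))
  if (!(fraction > 0 && fraction <= 1))
    stop("configuration error: fraction must be in (0, 1]")
  cand <- setdiff(fit$genotypes, exclude)
  if (length(cand) < 10L)
    stop("need at least 10 non-check entries, got ", length(cand))
  pred <- predict_yield(fit, cand, scope)
  n_sel <- ceiling(fraction * length(cand))
  cand[order(-pred, cand)][seq_len(n_sel)]
}

#' Yield of selected lines relative to a check
#'
#' Computes the mean predicted yield of the selected lines, the predicted
#' yield of the reference check in the same scope, and their ratio in
#' percent — the per-trial point of the genetic-gain regression.
#'
#' @param fit a [fit_met()] object.
#' @param hyl genotype labels (typically from [select_hyl()]).
#' @param reference `"attila"` (long-term check) or `"local_check"`.
#' @param scope prediction scope (see [predict_yield()]).
#' @param aggregate `"scope_blup"` (default): one ratio of scope-level
#'   predictions; `"per_site_ratio"`: the ratio is formed site by site and
#'   the percentages averaged — relevant mainly for the local check, which
#'   is a different variety at every site.
#' @return `list(hyl_mean, check_value, relative_pct)`.
#' @export
relative_yield <- function(fit, hyl, reference = c("attila", "local_check"),
                           scope = "overall",
                           aggregate = c("scope_blup", "per_site_ratio")) {
  reference <- match.arg(reference)
  aggregate <- match.arg(aggregate)
  ref_label <- check_labels[[reference]]
  if (!ref_label %in% fit$genotypes)
    stop("reference entry '", ref_label, "' absent from this trial")
  hyl_mean <- mean(predict_yield(fit, hyl, scope))
  check_value <- unname(predict_yield(fit, ref_label, scope))
  if (check_value <= 0)
    stop("check prediction is not positive (", signif(check_value, 4),
         " Mg/ha); relative yield undefined")
  if (aggregate == "per_site_ratio") {
    sites <- if (identical(scope, "overall")) fit$sites else scope
    pct <- vapply(sites, function(st) {
      cv <- unname(predict_yield(fit, ref_label, st))
      if (cv <= 0)
        stop("check prediction is not positive at site ", st)
      100 * mean(predict_yield(fit, hyl, st)) / cv
    }, 0)
    return(list(hyl_mean = hyl_mean, check_value = check_value,
                relative_pct = mean(pct)))
  }
  list(hyl_mean = hyl_mean, check_value = check_value,
       relative_pct = 100 * hyl_mean / check_value)
}

#' Build a gain series from per-trial fits
#'
#' Applies [select_hyl()] and [relative_yield()] to each trial-year's fit
#' and collects the per-trial points.
#'
#' @param fits named list of `met_fit` objects; names are the trial-year
#'   indices.
#' @param reference `"attila"` or `"local_check"`.
#' @param scope label recorded on the series (`"all"`, an ME label, ...).
#' @param scope_sites optional named list: for each trial-year, the site
#'   labels making up the scope (default: all sites of the fit).
#' @param fraction,exclude passed to [select_hyl()].
#' @return An object of class `gain_series` with a `points` data.frame
#'   (`trial_year`, `hyl_mean`, `check_value`, `relative_pct`).
#' @export
gain_series <- function(fits, reference = c("attila", "local_check"),
                        scope = "all", scope_sites = NULL,
                        fraction = 0.10, exclude = check_labels) {
  reference <- match.arg(reference)
  years <- as.integer(names(fits))
  stopifnot(!anyNA(years))
  pts <- lapply(seq_along(fits), function(i) {
    fit <- fits[[i]]
    sc <- if (is.null(scope_sites)) "overall" else
      scope_sites[[as.character(years[i])]]
    hyl <- select_hyl(fit, fraction, exclude, scope = sc)
    rv <- relative_yield(fit, hyl, reference, scope = sc)
    data.frame(trial_year = years[i], hyl_mean = rv$hyl_mean,
               check_value = rv$check_value,
               relative_pct = rv$relative_pct)
  })
  structure(list(points = do.call(rbind, pts), reference = reference,
                 scope = scope), class = "gain_series")
}

#' Estimate the annual genetic gain from a gain series
#'
#' Ordinary least-squares regression of the per-trial relative yield (%) on
#' the trial-year index gives the annual gain in percent per year; a
#' parallel regression of the absolute difference between the selected
#' lines' mean and the check (converted to kg/ha) gives the gain in
#' kg/ha/year.  A constant series is reported as slope 0 with a degenerate
#' flag rather than an error.
#'
#' @param series a [gain_series()] object with at least 3 points.
#' @return An object of class `gain_estimate`: `slope_pct_per_year`,
#'   `slope_kg_per_ha_year`, `intercept`, `slope_se`, `p_value`, `n_points`,
#'   `degenerate`.
#' @export
estimate_gain <- function(series) {
  stopifnot(inherits(series, "gain_series"))
  pts <- series$points
  if (nrow(pts) < 3L) stop("need at least 3 points for the gain regression")
  if (length(unique(pts$trial_year)) < 2L)
    stop("trial years are collinear (all equal); cannot regress")
  degenerate <- stats::var(pts$relative_pct) < .Machine$double.eps
  if (degenerate) {
    est <- list(slope_pct_per_year = 0,
                slope_kg_per_ha_year = 0,
                intercept = pts$relative_pct[1], slope_se = 0,
                p_value = NA_real_, n_points = nrow(pts),
                degenerate = TRUE, reference = series$reference,
                scope = series$scope)
    return(structure(est, class = "gain_estimate"))
  }
  fit_pct <- stats::lm(relative_pct ~ trial_year, data = pts)
  co <- summary(fit_pct)$coefficients
  diff_kg <- (pts$hyl_mean - pts$check_value) * 1000
  fit_kg <- stats::lm(diff_kg ~ pts$trial_year)
  structure(list(
    slope_pct_per_year = unname(co["trial_year", "Estimate"]),
    slope_kg_per_ha_year = unname(stats::coef(fit_kg)[2]),
    intercept = unname(co["(Intercept)", "Estimate"]),
    slope_se = unname(co["trial_year", "Std. Error"]),
    p_value = unname(co["trial_year", "Pr(>|t|)"]),
    n_points = nrow(pts), degenerate = FALSE,
    reference = series$reference, scope = series$scope),
    class = "gain_estimate")
}

#' @export
print.gain_estimate <- function(x, ...) {
  cat(sprintf("Annual gain (%s, scope %s): %.3f %%/yr (SE %.3f, p %.3g)\n",
              x$reference, x$scope, x$slope_pct_per_year, x$slope_se,
              x$p_value))
  cat(sprintf("  absolute: %.1f kg/ha/yr over %d trials\n",
              x$slope_kg_per_ha_year, x$n_points))
  invisible(x)
}

#' @export
print.gain_series <- function(x, ...) {
  cat(sprintf("Gain series (%s, scope %s), %d trials\n", x$reference,
              x$scope, nrow(x$points)))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Fit every trial-year of a series
#'
#' Splits a multi-year record set by trial-year and fits the
#' multi-environment model to each year separately (the entry list changes
#' every year, so years are modeled independently).
#'
#' @param records multi-year plot records.
#' @param spec a [met_spec()].
#' @param seed base seed; year `t` uses `seed * 100 + t`.
#' @param sites_by_year optional named list restricting each year to given
#'   site labels (e.g. after the heritability filter).
#' @return Named list of `met_fit` objects keyed by trial-year.
#' @export
fit_trial_series <- function(records, spec = met_spec(), seed = 1L,
                             sites_by_year = NULL) {
  years <- sort(unique(records$year))
  fits <- list()
  for (t in years) {
    rec_t <- records[records$year == t, , drop = FALSE]
    if (!is.null(sites_by_year)) {
      keep <- sites_by_year[[as.character(t)]]
      rec_t <- rec_t[rec_t$site %in% keep, , drop = FALSE]
    }
    if (length(unique(rec_t$site)) < 2L) next
    fits[[as.character(t)]] <- fit_met(rec_t, spec,
                                       seed = seed * 100L + t)
  }
  fits
}

#' Compare gain estimates across model variants
#'
#' Runs the per-trial fits, line selection and gain regression under two or
#' more interaction-model variants on the same records, and tabulates the
#' estimated gains side by side — the contrast between modeling the GxE
#' interaction (factor-analytic) and ignoring it.
#'
#' @param records multi-year plot records.
#' @param variants character vector of at least two [met_spec()] model
#'   variants (default `c("fa", "no_gxe")`).
#' @param reference `"attila"` or `"local_check"`.
#' @param spec base [met_spec()]; its `model_variant` is overridden.
#' @param seed seed for the fits.
#' @param fraction selected fraction of test lines.
#' @return data.frame with one row per variant (`variant`, `slope_pct`,
#'   `slope_kg`, `se`, `p`, `n`), plus a `"difference"` row (first minus
#'   second variant) when exactly two variants are compared.
#' @export
compare_variants <- function(records, variants = c("fa", "no_gxe"),
                             reference = "attila", spec = met_spec(),
                             seed = 1L, fraction = 0.10) {
  if (length(variants) < 2L)
    stop("configuration error: need at least two variants to compare")
  rows <- lapply(variants, function(v) {
    sp <- spec; sp$model_variant <- v
    fits <- fit_trial_series(records, sp, seed)
    est <- estimate_gain(gain_series(fits, reference, fraction = fraction))
    data.frame(variant = v, slope_pct = est$slope_pct_per_year,
               slope_kg = est$slope_kg_per_ha_year, se = est$slope_se,
               p = est$p_value, n = est$n_points)
  })
  out <- do.call(rbind, rows)
  if (length(variants) == 2L) {
    d <- data.frame(variant = "difference",
                    slope_pct = out$slope_pct[1] - out$slope_pct[2],
                    slope_kg = out$slope_kg[1] - out$slope_kg[2],
                    se = NA_real_, p = NA_real_, n = out$n[1])
    out <- rbind(out, d)
  }
  out
}
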