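# Megaenvironment classification of trial locations from climate and
# management metadata, refined by yield-based clustering.
#
# ME1: optimally irrigated, low rainfall, average minimum temperature in
#      the coolest quarter between 3 and 11 C.
# ME4: rainfed, drought-stressed: 100-400 mm precipitation in the wettest
#      quarter (or irrigation withheld at an otherwise-ME1 location).
# ME5: heat-stressed: 11-16 C minimum in the coolest quarter, or any
#      late-sown trial (late sowing is how heat stress is imposed at
#      otherwise-temperate stations).

#' Assign locations to megaenvironments
#'
#' Applies the climate/management rules in a fixed, total order; management
#' overrides climate (late sowing forces ME5; withheld irrigation at an
#' otherwise-ME1 site forces ME4).  An `NA` irrigation flag is treated as
#' climatically irrigated but unconfirmed, which makes the site eligible
#' for relabeling by [refine_by_cluster()].
#'
#' @param meta data.frame with columns `site`, `tmin_coolest_quarter` (C),
#'   `precip_wettest_quarter` (mm), `irrigated` (logical or `NA`), `sowing`
#'   (`"normal"`/`"late"`).
#' @return data.frame with columns `site`, `me` (`"ME1"`, `"ME4"`, `"ME5"`
#'   or `"unclassified"`), `rule_fired`, `irrigation_confirmed`,
#'   `cluster_refined` (all `FALSE`; see [refine_by_cluster()]).
#' @export
assign_me <- function(meta) {
  need <- c("site", "tmin_coolest_quarter", "precip_wettest_quarter",
            "irrigated", "sowing")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("meta lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(meta$tmin_coolest_quarter)) ||
      !all(is.finite(meta$precip_wettest_quarter)))
    stop("tmin and precipitation must be finite")
  one <- function(tmin, precip, irr, sow) {
    irr_ok <- is.na(irr) || isTRUE(irr)
    if (irr_ok && sow == "normal" && tmin >= 3 && tmin < 11)
      return(c("ME1", if (is.na(irr))
        "irrigated (unconfirmed), 3 <= tmin < 11, normal sowing" else
        "irrigated, 3 <= tmin < 11, normal sowing"))
    if (sow == "late")
      return(c("ME5", "late sowing (heat stress imposed)"))
    if (isFALSE(irr) && precip >= 100 && precip <= 400)
      return(c("ME4", "rainfed, 100 <= precip_wettest <= 400 mm"))
    if (isFALSE(irr) && precip < 100 && tmin >= 3 && tmin < 11)
      return(c("ME4", "irrigation withheld at otherwise-ME1 climate"))
    if (tmin >= 11 && tmin <= 16)
      return(c("ME5", "11 <= tmin_coolest <= 16"))
    c("unclassified", "")
  }
  res <- t(mapply(one, meta$tmin_coolest_quarter,
                  meta$precip_wettest_quarter, meta$irrigated, meta$sowing))
  data.frame(site = meta$site, me = res[, 1], rule_fired = res[, 2],
             irrigation_confirmed = isTRUE_vec(meta$irrigated),
             cluster_refined = FALSE, stringsAsFactors = FALSE)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Refine megaenvironment assignments by yield clustering
#'
#' Splits the locations of one trial into high- and low-yielding clusters
#' by k-means on site mean yield (deterministic initialization at the
#' range extremes), and relabels a climatically-ME1 site as ME4 when it
#' falls in the low-yield cluster and its irrigation was never confirmed —
#' the site presumably did not receive the assumed irrigation.  Confirmed
#' irrigated sites are never changed.
#'
#' @param assignments data.frame from [assign_me()].
#' @param site_mean_yields named numeric vector, mean yield per site
#'   (Mg/ha), for the sites of one trial.
#' @param k number of clusters (default 2: high vs low).
#' @return `assignments` with updated `me`, `cluster_refined`, and a
#'   `yield_cluster` column (`"high"`/`"low"`/`NA`).
#' @export
refine_by_cluster <- function(assignments, site_mean_yields, k = 2L) {
  yl <- site_mean_yields[assignments$site]
  have <- !is.na(yl)
  if (sum(have) < 2L) stop("need at least 2 sites with yields")
  if (k > sum(have))
    stop("configuration error: k (", k, ") exceeds number of sites (",
         sum(have), ")")
  assignments$yield_cluster <- NA_character_
  y <- yl[have]
  if (max(y) - min(y) < .Machine$double.eps^0.5) {
    # no separation: nothing to refine
    assignments$yield_cluster[have] <- "high"
    return(assignments)
  }
  centers <- matrix(seq(min(y), max(y), length.out = k), ncol = 1)
  km <- stats::kmeans(matrix(y, ncol = 1), centers = centers)
  low_cluster <- which.min(km$centers)
  lab <- ifelse(km$cluster == low_cluster, "low", "high")
  assignments$yield_cluster[have] <- lab
  relabel <- have & assignments$me == "ME1" &
    assignments$yield_cluster == "low" & !assignments$irrigation_confirmed
  if (any(relabel)) {
    assignments$me[relabel] <- "ME4"
    assignments$cluster_refined[relabel] <- TRUE
    assignments$rule_fired[relabel] <-
      "relabeled ME1 -> ME4: low-yield cluster, irrigation unconfirmed"
    message("relabeled ", sum(relabel), " site(s) ME1 -> ME4 (low-yield ",
            "cluster, irrigation unconfirmed): ",
            paste(assignments$site[relabel], collapse = ", "))
  }
  assignments
}
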