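# Site-regression (SREG/GGE) analysis: SVD of the environment-centered
# (optionally environment-standardized) genotype x environment table,
# biplot scores with symmetric singular-value partitioning, the
# which-won-where polygon, and environment correlation matrices.

#' Construct a genotype x environment mean-yield table
#'
#' @param values numeric matrix of mean yields (Mg/ha), genotypes in rows.
#' @param genotype_labels,environment_labels optional dimnames.
#' @return A `gxe_table` (matrix with validated dimensions and labels).
#' @export
gxe_table <- function(values, genotype_labels = rownames(values),
                      environment_labels = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(genotype_labels))
    genotype_labels <- paste0("G", seq_len(nrow(values)))
  if (is.null(environment_labels))
    environment_labels <- paste0("E", seq_len(ncol(values)))
  dimnames(values) <- list(genotype_labels, environment_labels)
  if (nrow(values) < 3L) stop("need at least 3 genotypes")
  if (ncol(values) < 2L) stop("need at least 2 environments")
  all_na_row <- rowSums(!is.na(values)) == 0L
  all_na_col <- colSums(!is.na(values)) == 0L
  if (any(all_na_row))
    stop("fully missing genotype row: ", rownames(values)[all_na_row][1])
  if (any(all_na_col))
    stop("fully missing environment column: ",
         colnames(values)[all_na_col][1])
  structure(values, class = c("gxe_table", "matrix"))
}

#' Site-regression (SREG) decomposition of a genotype x environment table
#'
#' Centers each environment column by its mean (removing the environment
#' main effect, so the decomposition carries genotype main effects plus
#' GxE — the "GGE" of a GGE biplot); under `scaling = "standardized"`
#' (default) each column is also divided by its standard deviation.  The
#' processed matrix is decomposed by SVD; genotype and environment scores
#' on the first two axes use symmetric partitioning (each axis scaled by
#' the square root of its singular value), and the share of variation
#' explained is \eqn{100 (\sigma_1^2 + \sigma_2^2) / \sum \sigma_i^2}.
#' Axis signs are fixed by orienting each axis so the mean genotype score
#' is nonnegative, making results deterministic across linear-algebra
#' backends.
#'
#' @param table a [gxe_table()] (complete; pre-fill or drop missing cells
#'   first — there is no silent imputation).
#' @param scaling `"standardized"` (centered and scaled) or `"centered"`.
#' @param svp singular-value partitioning of the scores: `"symmetric"`
#'   (default, both sides scaled by the square root of the singular value),
#'   `"genotype"` (genotype-metric: genotypes carry the full singular
#'   values) or `"environment"` (environment-metric).
#' @return An object of class `biplot_result`: `genotype_scores` (g x 2),
#'   `environment_scores` (e x 2), `singular_values`, `pct_explained_12`,
#'   `vertex_genotypes`, `sector_winners` (both `NULL` when the score
#'   polygon is degenerate), `scaling`.
#' @export
sreg_decompose <- function(table, scaling = c("standardized", "centered"),
                           svp = c("symmetric", "genotype",
                                   "environment")) {
  scaling <- match.arg(scaling)
  svp <- match.arg(svp)
  stopifnot(inherits(table, "gxe_table"))
  if (anyNA(table))
    stop("table has missing cells; pre-fill or drop them explicitly")
  M <- sweep(unclass(table), 2, colMeans(table))
  if (scaling == "standardized") {
    sds <- apply(table, 2, stats::sd)
    zero <- sds < .Machine$double.eps^0.5
    if (any(zero))
      stop("zero-variance environment under standardized scaling: ",
           colnames(table)[zero][1])
    M <- sweep(M, 2, sds, "/")
  }
  sv <- svd(M)
  d <- sv$d
  tot <- sum(d^2)
  pct <- if (tot > 0) 100 * sum(d[1:2]^2) / tot else NA_real_
  dg <- switch(svp, symmetric = sqrt(d[1:2]), genotype = d[1:2],
               environment = c(1, 1))
  de <- switch(svp, symmetric = sqrt(d[1:2]), genotype = c(1, 1),
               environment = d[1:2])
  gs <- sv$u[, 1:2, drop = FALSE] %*% diag(dg, 2)
  es <- sv$v[, 1:2, drop = FALSE] %*% diag(de, 2)
  for (ax in 1:2) {
    m <- mean(gs[, ax])
    # when the mean score is numerically zero, orient by the largest
    # genotype score instead so the sign stays reproducible
    if (abs(m) < 1e-8 * (stats::sd(gs[, ax]) + 1e-300))
      m <- gs[which.max(abs(gs[, ax])), ax]
    if (m < 0) {
      gs[, ax] <- -gs[, ax]; es[, ax] <- -es[, ax]
    }
  }
  dimnames(gs) <- list(rownames(table), c("PC1", "PC2"))
  dimnames(es) <- list(colnames(table), c("PC1", "PC2"))
  res <- structure(list(genotype_scores = gs, environment_scores = es,
                        singular_values = d, pct_explained_12 = pct,
                        vertex_genotypes = NULL, sector_winners = NULL,
                        scaling = scaling, svp = svp),
                   class = "biplot_result")
  www <- tryCatch(which_won_where(res), error = function(e) NULL)
  if (!is.null(www)) {
    res$vertex_genotypes <- www$vertex_genotypes
    res$sector_winners <- www$sector_winners
  }
  res
}

#' Which-won-where polygon of a biplot
#'
#' The convex hull of the genotype scores forms the polygon of most
#' responsive genotypes; perpendicular rays from the origin to the hull
#' edges partition the plane into sectors, and every environment is won by
#' the vertex genotype of its sector — equivalently, by the hull vertex
#' with the largest inner product with the environment's score vector.
#'
#' @param result a [sreg_decompose()] result with at least 3 genotypes at
#'   distinct, non-collinear score coordinates.
#' @return `list(vertex_genotypes, sector_winners)`; `sector_winners` is a
#'   named character vector mapping environment to winning genotype.
#' @export
which_won_where <- function(result) {
  stopifnot(inherits(result, "biplot_result"))
  gs <- result$genotype_scores
  hull <- grDevices::chull(gs[, 1], gs[, 2])
  if (length(hull) < 3L)
    stop("degenerate hull: genotype scores are coincident or collinear")
  # collinearity of >=3 hull points
  hp <- gs[hull, , drop = FALSE]
  if (abs(det(cbind(hp[2, ] - hp[1, ], hp[3, ] - hp[1, ]))) <
      .Machine$double.eps^0.5 && length(hull) == 3L)
    stop("degenerate hull: genotype scores are coincident or collinear")
  vertices <- rownames(gs)[hull]
  es <- result$environment_scores
  winners <- vapply(seq_len(nrow(es)), function(j) {
    ip <- hp %*% es[j, ]
    vertices[order(-ip, vertices)][1]
  }, "")
  names(winners) <- rownames(es)
  list(vertex_genotypes = vertices, sector_winners = winners)
}

#' Pairwise environment correlations of genotype performance
#'
#' Pearson correlation of genotype means between every pair of
#' environments, over the genotypes observed in both; two-sided p-values
#' from the t distribution with n-2 degrees of freedom.  Pairs with fewer
#' than 3 common genotypes are flagged as missing, not an error.
#'
#' @param table a [gxe_table()] (may contain missing cells).
#' @return `list(r, p, n)`: correlation, p-value and common-genotype-count
#'   matrices (diagonal of `r` is 1).
#' @export
environment_correlations <- function(table) {
  stopifnot(inherits(table, "gxe_table"))
  e <- ncol(table)
  r <- matrix(NA_real_, e, e, dimnames = list(colnames(table),
                                              colnames(table)))
  p <- r
  nmat <- matrix(0L, e, e, dimnames = dimnames(r))
  diag(r) <- 1
  for (i in seq_len(e - 1L)) {
    for (j in (i + 1L):e) {
      ok <- stats::complete.cases(table[, c(i, j)])
      n <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- n
      if (n < 3L) next
      rij <- stats::cor(table[ok, i], table[ok, j])
      r[i, j] <- r[j, i] <- rij
      if (abs(rij) >= 1) {
        pij <- 0
      } else {
        tstat <- rij * sqrt((n - 2) / (1 - rij^2))
        pij <- 2 * stats::pt(-abs(tstat), n - 2)
      }
      p[i, j] <- p[j, i] <- pij
    }
  }
  diag(nmat) <- colSums(!is.na(table))
  list(r = r, p = p, n = nmat)
}

#' Correlations of genotype BLUP yield between megaenvironments
#'
#' For one trial fitted separately per megaenvironment, correlates the
#' per-genotype scope-level BLUP yields between every pair of
#' megaenvironments, over the genotypes common to the fits.
#'
#' @param fits_by_me named list of `met_fit` objects, one per ME.
#' @return As [environment_correlations()].
#' @export
me_blup_correlations <- function(fits_by_me) {
  stopifnot(length(fits_by_me) >= 2L)
  common <- Reduce(intersect, lapply(fits_by_me, function(f) f$genotypes))
  if (length(common) < 3L)
    stop("fewer than 3 genotypes common to all megaenvironment fits")
  preds <- vapply(fits_by_me, function(f) predict_yield(f, common),
                  numeric(length(common)))
  environment_correlations(gxe_table(preds, common, names(fits_by_me)))
}

#' Genotype x country table of BLUP-adjusted yields
#'
#' Country means are unweighted means of the per-location predicted yields
#' (fixed site effect + genotype BLUPs) of the locations in each country —
#' the input to the country-level site-regression biplot.
#'
#' @param fit a [fit_met()] object.
#' @param meta location metadata with columns `site` and `country`.
#' @return A [gxe_table()] (genotypes x countries).
#' @export
country_mean_table <- function(fit, meta) {
  stopifnot(inherits(fit, "met_fit"))
  meta <- meta[meta$site %in% fit$sites, , drop = FALSE]
  countries <- sort(unique(meta$country))
  if (length(countries) < 2L)
    stop("need locations in at least 2 countries")
  vals <- vapply(countries, function(cn) {
    sites <- meta$site[meta$country == cn]
    rowMeans(vapply(sites, function(sj)
      fit$site_means[[sj]] + fit$blup_g + fit$blup_ge[, sj],
      numeric(length(fit$genotypes))))
  }, numeric(length(fit$genotypes)))
  gxe_table(vals, fit$genotypes, countries)
}

#' @export
print.biplot_result <- function(x, ...) {
  cat(sprintf("SREG biplot (%s scaling): first two axes explain %.2f%% of variation\n",
              x$scaling, x$pct_explained_12))
  if (!is.null(x$vertex_genotypes))
    cat("  polygon vertices:", paste(x$vertex_genotypes, collapse = ", "),
        "\n")
  invisible(x)
}
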