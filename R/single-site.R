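# Single-location alpha-lattice analysis: REML variance components,
# adjusted genotype means, line-mean heritability, and the h^2 site filter.

# design pieces for the fixed-genotype model
#   y = mu + rep + genotype (fixed) + subblock(rep) (random) + e
site_design_fixed <- function(rec) {
  rec$genotype <- factor(rec$genotype)
  rec$repf <- factor(rec$rep)
  rec$sbf <- factor(paste(rec$rep, rec$subblock, sep = ":"))
  X <- stats::model.matrix(~ repf + genotype, rec)
  list(y = rec$yield, X = X, terms = list(new_term_iid(rec$sbf)),
       rec = rec)
}

# random-genotype companion (supplies sigma^2_g for heritability)
#   y = mu + rep (fixed) + genotype + subblock(rep) (random) + e
site_design_random <- function(rec) {
  rec$genotype <- factor(rec$genotype)
  rec$repf <- factor(rec$rep)
  rec$sbf <- factor(paste(rec$rep, rec$subblock, sep = ":"))
  X <- stats::model.matrix(~ repf, rec)
  list(y = rec$yield, X = X,
       terms = list(new_term_iid(rec$genotype), new_term_iid(rec$sbf)),
       rec = rec)
}

check_one_site <- function(records) {
  if (length(unique(records$site)) != 1L)
    stop("records must cover exactly one site")
  reps <- sort(unique(records$rep))
  if (length(reps) < 2L)
    stop("validation error: fewer than 2 replicates at site ",
         records$site[1])
  full <- seq_len(max(reps))
  empty <- setdiff(full, reps)
  if (length(empty))
    stop("validation error: replicate ", empty[1], " has zero plots at site ",
         records$site[1])
  if (length(unique(records$genotype)) < 2L)
    stop("validation error: fewer than 2 genotypes at site ",
         records$site[1])
  invisible(records)
}

#' Restricted log-likelihood of the single-location model
#'
#' Evaluates the restricted (error-contrast) log-likelihood of the
#' alpha-lattice model with replicate and genotype fixed and sub-blocks
#' within replicates random, at given variance components.
#' `reml_loglik_site()` uses the package's mixed-model-equation evaluator;
#' `reml_loglik_site_dense()` is an independent brute-force reference that
#' assembles the full marginal covariance matrix and projects it onto an
#' orthonormal basis of error contrasts.  The two agree to numerical
#' round-off and are compared in the package's validation suite.
#'
#' @param records plot records for a single site.
#' @param sigma2_sb sub-block-within-replicate variance.
#' @param sigma2_e plot residual variance.
#' @return Restricted log-likelihood (scalar).
#' @export
reml_loglik_site <- function(records, sigma2_sb, sigma2_e) {
  check_one_site(records)
  des <- site_design_fixed(records)
  prep <- reml_prep(des$y, des$X, des$terms)
  ev <- reml_eval(c(log(sigma2_sb), log(sigma2_e)), prep)
  if (is.null(ev)) stop("covariance not positive definite")
  ev$loglik
}

#' @rdname reml_loglik_site
#' @export
reml_loglik_site_dense <- function(records, sigma2_sb, sigma2_e) {
  check_one_site(records)
  des <- site_design_fixed(records)
  n <- length(des$y)
  term <- des$terms[[1]]
  Gmats <- list(diag(sigma2_sb, term$nlev))
  V <- assemble_dense_V(list(n = n, terms = des$terms, Gmats = Gmats,
                             resid_vars_obs = rep(sigma2_e, n)))
  reml_loglik_contrasts(des$y, des$X, V)
}

#' Fit the single-location alpha-lattice model
#'
#' REML fit of \code{yield = mean + replicate + genotype + subblock(replicate)
#' + residual} with genotype and replicate fixed and sub-blocks random,
#' following standard incomplete-block practice for one location of an
#' international yield trial.  A companion refit with genotype random (and
#' replicate fixed) supplies the genotype variance needed for line-mean
#' heritability.  Optimization is on log-variances; estimates below `1e-8`
#' are reported as exactly 0.  Optimizer failure is reported through the
#' `converged` flag, never as an error.
#'
#' @param records plot records for one site (columns `genotype`, `site`,
#'   `rep`, `subblock`, `yield`).
#' @return An object of class `site_fit`: a list with `site`,
#'   `genotype_estimates` (adjusted means, Mg/ha), `replicate_effects`,
#'   `sigma2_sb`, `sigma2_e` (fixed-genotype model), `sigma2_g`,
#'   `sigma2_e_random` (random-genotype companion), `h2`, `n_reps`,
#'   `reml_loglik`, `converged`.
#' @export
fit_single_site <- function(records) {
  check_one_site(records)
  des <- site_design_fixed(records)
  prep <- reml_prep(des$y, des$X, des$terms)
  v0 <- stats::var(des$y)
  if (!is.finite(v0) || v0 <= 0) v0 <- 1e-4
  start <- log(c(0.2 * v0, 0.5 * v0))
  opt <- reml_optimize(prep, start, lower = rep(log(1e-10), 2),
                       upper = rep(log(1e6), 2))
  ev <- reml_eval(opt$theta, prep, solutions = TRUE)
  vc <- exp(opt$theta)
  vc[vc < 1e-8] <- 0
  # adjusted means: fixed solutions averaged over replicate levels
  rec <- des$rec
  glev <- levels(rec$genotype)
  rlev <- levels(rec$repf)
  beta <- ev$bhat
  names(beta) <- colnames(des$X)
  rep_coef <- c(0, beta[paste0("repf", rlev[-1])])
  names(rep_coef) <- rlev
  gen_coef <- c(0, beta[paste0("genotype", glev[-1])])
  adj <- beta[["(Intercept)"]] + mean(rep_coef) + gen_coef
  names(adj) <- glev

  desr <- site_design_random(records)
  prep_r <- reml_prep(desr$y, desr$X, desr$terms)
  startr <- log(c(0.3 * v0, 0.2 * v0, 0.5 * v0))
  optr <- reml_optimize(prep_r, startr, lower = rep(log(1e-10), 3),
                        upper = rep(log(1e6), 3))
  vcr <- exp(optr$theta)
  vcr[vcr < 1e-8] <- 0
  n_reps <- nrow(records) / length(glev)  # mean replication per entry

  fit <- structure(list(
    site = as.character(records$site[1]),
    genotype_estimates = adj,
    replicate_effects = rep_coef,
    sigma2_sb = vc[1], sigma2_e = vc[2],
    sigma2_g = vcr[1], sigma2_sb_random = vcr[2], sigma2_e_random = vcr[3],
    n_reps = n_reps,
    reml_loglik = opt$loglik,
    converged = isTRUE(opt$converged) && isTRUE(optr$converged)),
    class = "site_fit")
  fit$h2 <- estimate_heritability(fit)
  fit
}

#' Line-mean heritability from a single-site fit
#'
#' Computes the entry-mean heritability
#' \deqn{h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_\epsilon / r)}
#' from the random-genotype variance components of a [fit_single_site()]
#' object, clipped to \eqn{[0, 1]}.  If every variance component is zero the
#' value is 0 and the result carries the attribute `undefined = TRUE`.
#'
#' @param fit a `site_fit` object (must have converged).
#' @param r replications per entry; defaults to the mean replication
#'   observed in the fit.
#' @return Heritability in `[0, 1]`.
#' @export
estimate_heritability <- function(fit, r = NULL) {
  stopifnot(inherits(fit, "site_fit"))
  if (is.null(r)) r <- fit$n_reps
  s2g <- fit$sigma2_g
  s2e <- fit$sigma2_e_random
  if (s2g == 0 && s2e == 0) {
    warning("all variance components zero; heritability undefined")
    return(structure(0, undefined = TRUE))
  }
  h2 <- s2g / (s2g + s2e / r)
  min(max(h2, 0), 1)
}

#' Filter sites by heritability
#'
#' Retains sites whose converged single-location fits reach the heritability
#' threshold; everything else is dropped with a reason code, mirroring the
#' practice of discarding low-heritability locations from combined
#' multi-environment analyses.
#'
#' @param fits list of `site_fit` objects.
#' @param threshold minimum line-mean heritability (default 0.05).
#' @return `list(kept = <site labels>, dropped = <data.frame site, reason>)`
#'   with reason one of `"low_h2"`, `"not_converged"`.
#' @export
filter_sites <- function(fits, threshold = 0.05) {
  kept <- character()
  dsite <- character(); dreason <- character()
  for (f in fits) {
    stopifnot(inherits(f, "site_fit"))
    if (!isTRUE(f$converged)) {
      dsite <- c(dsite, f$site); dreason <- c(dreason, "not_converged")
    } else if (f$h2 >= threshold) {
      kept <- c(kept, f$site)
    } else {
      dsite <- c(dsite, f$site); dreason <- c(dreason, "low_h2")
    }
  }
  list(kept = kept,
       dropped = data.frame(site = dsite, reason = dreason,
                            stringsAsFactors = FALSE))
}

#' @export
print.site_fit <- function(x, ...) {
  cat("Single-site fit:", x$site, "\n")
  cat(sprintf("  sigma2_sb = %.4g  sigma2_e = %.4g  (genotype fixed)\n",
              x$sigma2_sb, x$sigma2_e))
  cat(sprintf("  sigma2_g  = %.4g  sigma2_e = %.4g  (genotype random)\n",
              x$sigma2_g, x$sigma2_e_random))
  cat(sprintf("  line-mean h2 = %.3f over %.3g reps; converged: %s\n",
              x$h2, x$n_reps, x$converged))
  invisible(x)
}
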