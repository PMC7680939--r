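# Multi-environment trial (MET) mixed model:
#   Y = X b + Z_r r + Z_g g + Z_ge ge + e
# with site effects fixed, replicate-within-site effects random with
# per-site variances, genotype effects iid N(0, sigma2_g), GxE effects with
# covariance Sigma_ge (x) I over genotypes, and iid residuals.  The GxE
# covariance is modeled as factor-analytic, Sigma_ge = Lambda Lambda' + Psi
# (variant "fa"), site-specific diagonal (variant "diagonal"), a single
# shared interaction variance (variant "cs"), or dropped entirely
# (variant "no_gxe").

#' Specification of the multi-environment model
#'
#' @param fa_order rank of the factor-analytic loading matrix (variant
#'   `"fa"`); must be smaller than the number of sites.
#' @param model_variant `"fa"`, `"diagonal"` (site-specific interaction
#'   variances, no covariance), `"cs"` (one shared interaction variance), or
#'   `"no_gxe"` (interaction term dropped).
#' @param max_iter optimizer iteration cap.
#' @param tol relative convergence tolerance on the REML log-likelihood.
#' @param n_starts number of optimizer starts (1 warm start from a
#'   method-of-moments decomposition of the cell-mean covariance, the rest
#'   seeded jitters of it).
#' @param het_resid if `TRUE`, fit per-site residual variances instead of a
#'   single homogeneous one (slower code path).
#' @param fallback if `TRUE` (default), a non-converged `"fa"` fit is
#'   automatically refit with `model_variant = "diagonal"` and flagged.
#' @return A `met_spec` list.
#' @export
met_spec <- function(fa_order = 1L,
                     model_variant = c("fa", "diagonal", "cs", "no_gxe"),
                     max_iter = 1000L, tol = 1e-8, n_starts = 5L,
                     het_resid = FALSE, fallback = TRUE) {
  model_variant <- match.arg(model_variant)
  if (tol <= 0) stop("tol must be > 0")
  if (fa_order < 0L) stop("fa_order must be >= 0")
  structure(list(fa_order = as.integer(fa_order),
                 model_variant = model_variant,
                 max_iter = as.integer(max_iter), tol = tol,
                 n_starts = as.integer(n_starts),
                 het_resid = isTRUE(het_resid),
                 fallback = isTRUE(fallback)),
            class = "met_spec")
}

n_lambda_free <- function(s, k) as.integer(s * k - k * (k - 1) / 2)

# theta layout (fast path): log s2r (s) | log s2g | lambda free | log psi
# (s, or 1 for "cs") | log s2e
unpack_met_theta <- function(theta, s, k, cs = FALSE) {
  pos <- 1L
  s2r <- exp(theta[pos:(pos + s - 1L)]); pos <- pos + s
  s2g <- exp(theta[pos]); pos <- pos + 1L
  lambda <- NULL
  if (k > 0L) {
    nl <- n_lambda_free(s, k)
    lambda <- matrix(0, s, k)
    for (m in seq_len(k)) {
      nm <- s - m + 1L
      lambda[m:s, m] <- theta[pos:(pos + nm - 1L)]
      pos <- pos + nm
    }
  }
  if (cs) {
    psi <- rep(exp(theta[pos]), s); pos <- pos + 1L
  } else {
    psi <- exp(theta[pos:(pos + s - 1L)]); pos <- pos + s
  }
  s2e <- exp(theta[pos])
  list(s2r = s2r, s2g = s2g, lambda = lambda, psi = psi, s2e = s2e)
}

pack_met_grad <- function(gr, s, k, cs = FALSE) {
  lam <- NULL
  if (k > 0L) {
    lam <- numeric(0)
    for (m in seq_len(k)) lam <- c(lam, gr$lambda[m:s, m])
  }
  psi <- if (cs) sum(gr$psi) else gr$psi
  c(gr$s2r, gr$s2g, lam, psi, gr$s2e)
}

# method-of-moments warm start from genotype x site cell means
met_warm_start <- function(prep, k, cs = FALSE) {
  s <- prep$s
  M <- prep$Sy / pmax(prep$Ngs, 1L)
  M[prep$Ngs == 0L] <- NA
  # impute missing cells for the moment estimate only
  if (anyNA(M)) {
    cm <- colMeans(M, na.rm = TRUE)
    rm_ <- rowMeans(M, na.rm = TRUE) - mean(cm)
    for (j in seq_len(s)) {
      na <- is.na(M[, j])
      M[na, j] <- cm[j] + rm_[na]
    }
  }
  Mc <- sweep(M, 2, colMeans(M))
  C <- stats::cov(Mc)
  rbar <- max(mean(prep$Ngs[prep$Ngs > 0]), 1)
  # crude residual variance from total minus between-cell spread
  s2e0 <- max(0.25 * mean(diag(C)), 1e-4)
  Cadj <- C - diag(s2e0 / rbar, s)
  off <- Cadj[upper.tri(Cadj)]
  s2g0 <- max(stats::median(off) * 0.6, 1e-3)
  Sge0 <- Cadj - s2g0
  ee <- eigen(Sge0, symmetric = TRUE)
  lam0 <- NULL
  if (k > 0L) {
    lam0 <- ee$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(ee$values[seq_len(k)], 1e-3)), k)
    # orient and zero the constrained entries
    for (m in seq_len(k)) {
      if (sum(lam0[, m]) < 0) lam0[, m] <- -lam0[, m]
      if (m > 1L) lam0[seq_len(m - 1L), m] <- 0
    }
  }
  resid_diag <- diag(Sge0)
  if (k > 0L) resid_diag <- resid_diag - rowSums(lam0^2)
  psi0 <- pmax(resid_diag, 0.05 * mean(diag(C)))
  if (cs) psi0 <- mean(psi0)
  th <- c(rep(log(max(0.3 * s2e0, 1e-4)), s), log(s2g0))
  if (k > 0L) for (m in seq_len(k)) th <- c(th, lam0[m:s, m])
  th <- c(th, log(psi0), log(s2e0))
  th
}

fit_met_fast <- function(prep, k, cs, spec, seed) {
  s <- prep$s
  nth <- s + 1L + (if (k > 0L) n_lambda_free(s, k) else 0L) +
    (if (cs) 1L else s) + 1L
  lam_idx <- if (k > 0L) s + 1L + seq_len(n_lambda_free(s, k)) else integer(0)
  # variances floored at 1e-6 (negligible on the Mg/ha scale): keeps the
  # optimizer off the flat log-variance plateau near zero
  lower <- rep(log(1e-6), nth); upper <- rep(log(1e8), nth)
  lower[lam_idx] <- -30; upper[lam_idx] <- 30
  fn <- function(th) {
    ev <- eval_met_fast(unpack_met_theta(th, s, k, cs), prep)
    if (is.null(ev) || !is.finite(ev$loglik)) return(1e10)
    -ev$loglik
  }
  gr <- function(th) {
    ev <- eval_met_fast(unpack_met_theta(th, s, k, cs), prep,
                        gradient = TRUE)
    if (is.null(ev) || !is.finite(ev$loglik)) return(rep(0, nth))
    -pack_met_grad(ev$gradient, s, k, cs)
  }
  th0 <- met_warm_start(prep, k, cs)
  starts <- list(th0)
  if (spec$n_starts > 1L) {
    jit <- with_seed(seed, lapply(seq_len(spec$n_starts - 1L), function(i)
      th0 + stats::rnorm(nth, 0, 0.4)))
    starts <- c(starts, jit)
  }
  best <- NULL
  ctrl <- list(iter.max = spec$max_iter, eval.max = 4 * spec$max_iter,
               rel.tol = spec$tol)
  for (st in starts) {
    res <- tryCatch(
      nlminb(st, fn, gr, lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    # restarts refresh the quasi-Newton curvature estimate; on the nearly
    # flat sigma2_g <-> loading ridge the optimizer can crawl for
    # thousands of iterations, so convergence is declared once the
    # restricted log-likelihood has stabilized (< 0.01 improvement)
    settled <- res$convergence == 0
    tries <- 0L
    rctrl <- ctrl
    rctrl$iter.max <- min(ctrl$iter.max, 200L)
    rctrl$eval.max <- 4L * rctrl$iter.max
    while (!settled && tries < 3L) {
      res2 <- tryCatch(
        nlminb(res$par, fn, gr, lower = lower, upper = upper,
               control = rctrl),
        error = function(e) NULL)
      if (is.null(res2)) break
      settled <- res2$convergence == 0 ||
        (res$objective - res2$objective) < 0.01
      res <- res2
      tries <- tries + 1L
    }
    res$settled <- settled
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best))
    return(list(theta = th0, loglik = -Inf, converged = FALSE))
  list(theta = best$par, loglik = -best$objective,
       converged = isTRUE(best$settled) && best$objective < 1e9)
}

#' Fit the multi-environment mixed model by REML
#'
#' Maximizes the restricted likelihood of the site-fixed, replicate- and
#' genotype-random multi-environment model over bounded parameters
#' (variances on the log scale, loadings unconstrained with the upper
#' triangle fixed at zero for rotational identifiability), using a
#' method-of-moments warm start plus seeded random restarts, and extracts
#' genotype main-effect and interaction BLUPs from the mixed-model equations
#' at the optimum.  A non-converged factor-analytic fit is refit with the
#' diagonal interaction structure and flagged (`fallback_from = "fa"`),
#' so downstream stages always receive a usable fit.
#'
#' @param records plot records spanning at least two sites (columns
#'   `genotype`, `site`, `rep`, `yield`).
#' @param spec a [met_spec()].
#' @param seed integer seed for the optimizer restarts.
#' @return An object of class `met_fit`; see Details.
#' @details The returned list contains `site_means` (fixed site effects,
#'   Mg/ha), `rep_variances` (per site), `sigma2_g`, `loadings`,
#'   `specific_vars`, `Sigma_ge` (the implied interaction covariance
#'   \eqn{\Lambda\Lambda' + \Psi}; all reported quantities depend on the
#'   loadings only through this product), `sigma2_e`, `blup_g` (named,
#'   mean exactly zero), `blup_ge` (genotype x site, site means exactly
#'   zero), `reml_loglik`, `converged`, `variant`, and `fallback_from`.
#' @export
fit_met <- function(records, spec = met_spec(), seed = 1L) {
  stopifnot(inherits(spec, "met_spec"))
  sites <- sort(unique(records$site))
  if (length(sites) < 2L) stop("records must span at least 2 sites")
  s <- length(sites)
  if (spec$model_variant == "fa" && spec$fa_order >= s)
    stop("configuration error: fa_order (", spec$fa_order,
         ") must be smaller than the number of sites (", s, ")")
  if (spec$het_resid)
    return(fit_met_slow(records, spec, seed))
  variant <- spec$model_variant
  if (variant == "no_gxe")
    return(fit_met_nogxe(records, spec, seed))
  k <- switch(variant, fa = spec$fa_order, diagonal = 0L, cs = 0L)
  cs <- variant == "cs"
  prep <- prep_met_fast(records)
  res <- fit_met_fast(prep, k, cs, spec, seed)
  fallback_from <- NULL
  if (!res$converged && variant == "fa" && spec$fallback) {
    res2 <- fit_met_fast(prep, 0L, FALSE, spec, seed + 1L)
    if (res2$converged) {
      res <- res2; k <- 0L; variant <- "diagonal"; fallback_from <- "fa"
      message("FA fit did not converge; refit with diagonal GxE structure")
    }
  }
  pars <- unpack_met_theta(res$theta, s, k, cs)
  n_vc <- length(res$theta)
  ev <- eval_met_fast(pars, prep, solutions = TRUE)
  Sigma_ge <- ev$Sigma_ge_only
  dimnames(Sigma_ge) <- list(sites, sites)
  loadings <- pars$lambda
  if (!is.null(loadings)) rownames(loadings) <- sites
  blup_ge <- t(ev$blup_ge)
  dimnames(blup_ge) <- list(prep$geno_levels, sites)
  structure(list(
    site_means = stats::setNames(ev$bhat, sites),
    rep_variances = stats::setNames(pars$s2r, sites),
    sigma2_g = pars$s2g,
    loadings = loadings,
    specific_vars = stats::setNames(pars$psi, sites),
    Sigma_ge = Sigma_ge,
    sigma2_e = pars$s2e,
    blup_g = stats::setNames(ev$blup_g, prep$geno_levels),
    blup_ge = blup_ge,
    reml_loglik = res$loglik,
    n_vc_params = n_vc,
    converged = res$converged,
    variant = variant,
    fallback_from = fallback_from,
    sites = sites,
    genotypes = prep$geno_levels,
    spec = spec), class = "met_fit")
}

#' REML information criterion for a multi-environment fit
#'
#' \eqn{-2\,\ell_R + 2\,p} with p the number of variance parameters —
#' comparable across interaction structures (and FA orders) fitted to the
#' same data with the same fixed effects, which is the situation here.
#' Offered for choosing the FA order; the default order stays at 1.
#'
#' @param fit a [fit_met()] object.
#' @return Numeric AIC (smaller is better).
#' @export
met_aic <- function(fit) {
  stopifnot(inherits(fit, "met_fit"))
  -2 * fit$reml_loglik + 2 * fit$n_vc_params
}

# no-GxE variant: genotype main effects and fixed site effects only
fit_met_nogxe <- function(records, spec, seed) {
  geno <- factor(records$genotype); site <- factor(records$site)
  s <- nlevels(site); g <- nlevels(geno)
  repf <- factor(paste(as.integer(site), records$rep, sep = ":"))
  site_of_rep <- as.integer(sub(":.*", "", levels(repf)))
  X <- stats::model.matrix(~ 0 + site)
  terms <- list(new_term_diag_groups(repf, site_of_rep),
                new_term_iid(geno))
  prep <- reml_prep(records$yield, X, terms)
  v0 <- stats::var(records$yield)
  start <- c(rep(log(0.05 * v0), s), log(0.1 * v0), log(0.3 * v0))
  res <- reml_optimize(prep, start, lower = rep(log(1e-10), length(start)),
                       upper = rep(log(1e8), length(start)),
                       max_iter = spec$max_iter, tol = spec$tol)
  ev <- reml_eval(res$theta, prep, solutions = TRUE)
  s2 <- exp(res$theta)
  uhat <- ev$uhat
  off <- prep$offsets
  blup_g <- uhat[(off[2] + 1L):(off[2] + g)]
  sites <- levels(site)
  blup_ge <- matrix(0, g, s, dimnames = list(levels(geno), sites))
  structure(list(
    site_means = stats::setNames(ev$bhat, sites),
    rep_variances = stats::setNames(s2[seq_len(s)], sites),
    sigma2_g = s2[s + 1L],
    loadings = NULL,
    specific_vars = stats::setNames(rep(0, s), sites),
    Sigma_ge = matrix(0, s, s, dimnames = list(sites, sites)),
    sigma2_e = s2[s + 2L],
    blup_g = stats::setNames(blup_g, levels(geno)),
    blup_ge = blup_ge,
    reml_loglik = res$loglik,
    n_vc_params = length(start),
    converged = res$converged,
    variant = "no_gxe",
    fallback_from = NULL,
    sites = sites,
    genotypes = levels(geno),
    spec = spec), class = "met_fit")
}

# heterogeneous-residual path through the general evaluator (slower)
fit_met_slow <- function(records, spec, seed) {
  geno <- factor(records$genotype); site <- factor(records$site)
  s <- nlevels(site); g <- nlevels(geno)
  sites <- levels(site)
  repf <- factor(paste(as.integer(site), records$rep, sep = ":"))
  site_of_rep <- as.integer(sub(":.*", "", levels(repf)))
  X <- stats::model.matrix(~ 0 + site)
  variant <- spec$model_variant
  terms <- list(new_term_diag_groups(repf, site_of_rep),
                new_term_iid(geno))
  if (variant == "fa") {
    terms <- c(terms, list(new_term_fa(geno, site, spec$fa_order)))
  } else if (variant %in% c("diagonal", "cs")) {
    cell <- new_term_fa(geno, site, 0L)
    cell$struct <- "diag_groups"
    cell$group <- if (variant == "diagonal") rep(seq_len(s), g) else
      rep(1L, g * s)
    cell$ngroup <- if (variant == "diagonal") s else 1L
    terms <- c(terms, list(cell))
  }
  prep <- reml_prep(records$yield, X, terms, resid_group = as.integer(site))
  v0 <- stats::var(records$yield)
  nth <- n_theta(prep)
  warm <- met_warm_start(prep_met_fast(records),
                         if (variant == "fa") spec$fa_order else 0L,
                         variant == "cs")
  # remap fast-path layout into the engine layout (residual expands to s)
  start <- c(warm[-length(warm)], rep(warm[length(warm)], s))
  if (variant == "no_gxe")   # drop the lambda/psi block of the warm start
    start <- c(warm[seq_len(s + 1L)], rep(warm[length(warm)], s))
  stopifnot(length(start) == nth)
  res <- reml_optimize(prep, start, max_iter = spec$max_iter,
                       tol = spec$tol)
  ev <- reml_eval(res$theta, prep, solutions = TRUE)
  sp <- split_theta(res$theta, prep)
  off <- prep$offsets
  blup_g <- ev$uhat[(off[2] + 1L):(off[2] + g)]
  if (variant == "no_gxe") {
    Sigma_ge <- matrix(0, s, s); psi <- rep(0, s); lam <- NULL
    blup_ge <- matrix(0, g, s)
  } else {
    if (variant == "fa") {
      fa <- fa_unpack(sp$slices[[3]], s, spec$fa_order)
      Sigma_ge <- fa$Sigma; psi <- fa$psi; lam <- fa$lambda
      rownames(lam) <- sites
    } else {
      vge <- exp(sp$slices[[3]])
      psi <- if (variant == "diagonal") vge else rep(vge, s)
      Sigma_ge <- diag(psi, s); lam <- NULL
    }
    ge <- ev$uhat[(off[3] + 1L):(off[3] + g * s)]
    blup_ge <- t(matrix(ge, nrow = s))          # g x s
  }
  dimnames(Sigma_ge) <- list(sites, sites)
  dimnames(blup_ge) <- list(levels(geno), sites)
  structure(list(
    site_means = stats::setNames(ev$bhat, sites),
    rep_variances = stats::setNames(exp(sp$slices[[1]]), sites),
    sigma2_g = exp(sp$slices[[2]]),
    loadings = lam,
    specific_vars = stats::setNames(psi, sites),
    Sigma_ge = Sigma_ge,
    sigma2_e = stats::setNames(sp$resid_vars, sites),
    blup_g = stats::setNames(blup_g, levels(geno)),
    blup_ge = blup_ge,
    reml_loglik = res$loglik,
    n_vc_params = nth,
    converged = res$converged,
    variant = variant,
    fallback_from = NULL,
    sites = sites,
    genotypes = levels(geno),
    spec = spec), class = "met_fit")
}

#' Restricted log-likelihood of the multi-environment model
#'
#' Evaluates the restricted log-likelihood of the multi-environment model at
#' given variance parameters.  `reml_loglik_met()` goes through the
#' mixed-model-equation evaluator; `reml_loglik_met_dense()` assembles the
#' full marginal covariance \eqn{V(Y) = Z_r R Z_r' + Z_g G Z_g' +
#' Z_{ge} GE Z_{ge}' + E} densely and projects onto orthonormal error
#' contrasts — an independent brute-force reference.
#'
#' @param records plot records spanning >= 2 sites.
#' @param rep_variances replicate-within-site variances, one per site
#'   (ordered by sorted site label, or named).
#' @param sigma2_g genetic variance.
#' @param Sigma_ge s x s positive-definite interaction covariance.
#' @param sigma2_e residual variance.
#' @return Restricted log-likelihood (scalar).
#' @export
reml_loglik_met <- function(records, rep_variances, sigma2_g, Sigma_ge,
                            sigma2_e) {
  pieces <- met_loglik_pieces(records, rep_variances, sigma2_g, Sigma_ge,
                              sigma2_e)
  prep <- reml_prep(pieces$y, pieces$X, pieces$terms)
  q <- prep$q
  Ginv <- matrix(0, q, q)
  diag(Ginv)[seq_len(pieces$q_o)] <- 1 / pieces$s2r_lev
  gidx <- pieces$q_o + seq_len(pieces$g)
  diag(Ginv)[gidx] <- 1 / sigma2_g
  ch <- chol(Sigma_ge)
  Sinv <- chol2inv(ch)
  for (i in seq_len(pieces$g)) {
    idx <- pieces$q_o + pieces$g + (i - 1L) * pieces$s + seq_len(pieces$s)
    Ginv[idx, idx] <- Sinv
  }
  logdetG <- sum(log(pieces$s2r_lev)) + pieces$g * log(sigma2_g) +
    pieces$g * 2 * sum(log(diag(ch)))
  reml_value_fixedG(prep, Ginv, logdetG, sigma2_e)
}

#' @rdname reml_loglik_met
#' @export
reml_loglik_met_dense <- function(records, rep_variances, sigma2_g,
                                  Sigma_ge, sigma2_e) {
  pieces <- met_loglik_pieces(records, rep_variances, sigma2_g, Sigma_ge,
                              sigma2_e)
  Gmats <- list(diag(pieces$s2r_lev, pieces$q_o),
                diag(sigma2_g, pieces$g),
                kronecker(diag(pieces$g), Sigma_ge))
  V <- assemble_dense_V(list(n = length(pieces$y), terms = pieces$terms,
                             Gmats = Gmats,
                             resid_vars_obs = rep(sigma2_e,
                                                  length(pieces$y))))
  reml_loglik_contrasts(pieces$y, pieces$X, V)
}

met_loglik_pieces <- function(records, rep_variances, sigma2_g, Sigma_ge,
                              sigma2_e) {
  geno <- factor(records$genotype); site <- factor(records$site)
  s <- nlevels(site); g <- nlevels(geno)
  if (s < 2L) stop("records must span at least 2 sites")
  stopifnot(nrow(Sigma_ge) == s, sigma2_g > 0, sigma2_e > 0)
  if (!is.null(names(rep_variances)))
    rep_variances <- rep_variances[levels(site)]
  stopifnot(length(rep_variances) == s, all(rep_variances > 0))
  repf <- factor(paste(as.integer(site), records$rep, sep = ":"))
  site_of_rep <- as.integer(sub(":.*", "", levels(repf)))
  X <- stats::model.matrix(~ 0 + site)
  terms <- list(new_term_diag_groups(repf, site_of_rep),
                new_term_iid(geno),
                new_term_fa(geno, site, 1L))
  list(y = records$yield, X = X, terms = terms,
       q_o = nlevels(repf), g = g, s = s,
       s2r_lev = rep_variances[site_of_rep])
}

#' Predict genotype yield from a multi-environment fit
#'
#' Site-level prediction is the fixed site effect plus the genotype's
#' main-effect BLUP plus its interaction BLUP at that site; the prediction
#' for a wider scope (several sites, a megaenvironment, or `"overall"`) is
#' the mean of the per-site predictions over the sites in scope.
#'
#' @param fit a [fit_met()] object.
#' @param genotype one or more genotype labels.
#' @param scope `"overall"`, a single site label, or a character vector of
#'   site labels (e.g. the sites of one megaenvironment).
#' @return Named numeric vector of predicted yields (Mg/ha).
#' @export
predict_yield <- function(fit, genotype, scope = "overall") {
  stopifnot(inherits(fit, "met_fit"))
  bad <- setdiff(genotype, fit$genotypes)
  if (length(bad)) stop("unknown genotype: ", paste(bad, collapse = ", "))
  sites <- if (identical(scope, "overall")) fit$sites else scope
  bad <- setdiff(sites, fit$sites)
  if (length(bad)) stop("unknown site in scope: ", paste(bad, collapse = ", "))
  pred <- vapply(genotype, function(gn) {
    mean(fit$site_means[sites] + fit$blup_g[[gn]] + fit$blup_ge[gn, sites])
  }, 0)
  stats::setNames(pred, genotype)
}

#' @export
print.met_fit <- function(x, ...) {
  cat("Multi-environment REML fit (variant:", x$variant)
  if (!is.null(x$fallback_from))
    cat(", fallback from", x$fallback_from)
  cat(")\n")
  cat("  sites:", length(x$sites), " genotypes:", length(x$genotypes), "\n")
  cat(sprintf("  sigma2_g = %.4g  sigma2_e = %s\n", x$sigma2_g,
              paste(sprintf("%.4g", unique(round(x$sigma2_e, 6))),
                    collapse = "/")))
  cat(sprintf("  REML log-likelihood = %.4f  converged: %s\n",
              x$reml_loglik, x$converged))
  if (!is.null(x$loadings)) {
    corr <- stats::cov2cor(x$Sigma_ge)
    cat(sprintf("  GxE correlations (range): [%.2f, %.2f]\n",
                min(corr[upper.tri(corr)]), max(corr[upper.tri(corr)])))
  }
  invisible(x)
}
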