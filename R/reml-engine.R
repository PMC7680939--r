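# Internal REML machinery shared by the single-site and multi-environment
# models.  The marginal model is
#
#   y = X b + sum_t Z_t u_t + e,   u_t ~ N(0, G_t),   e ~ N(0, R)
#
# with R diagonal (homogeneous or grouped by site).  The restricted
# log-likelihood is evaluated through the mixed-model-equation identity
#
#   log|V| + log|X'V^-1 X| = log|R| + log|G| + log|C|
#
# (C the MME coefficient matrix), so a single Cholesky of the q x q system
# replaces any n x n factorization.  The value convention includes the
# -log|X'X| term so that it equals the restricted likelihood of the
# orthonormal error contrasts K'y (K an orthonormal basis of the null space
# of X'), which is what `reml_loglik_*_dense()` computes independently.

# ---- random-term variance structures -------------------------------------
# A term is a list:
#   index : integer vector (n), level of each observation, 1..nlev
#   nlev  : number of levels
#   struct: "iid" | "diag_groups" | "fa"
#   group : for diag_groups, integer (nlev) mapping level -> variance group
#   fa_g, fa_s, fa_k: for "fa", levels are (genotype, site) pairs ordered
#       site-fastest within genotype (level = (i-1)*s + j), G = I_g (x) Sigma,
#       Sigma = Lambda Lambda' + diag(psi)

new_term_iid <- function(f) {
  f <- as.factor(f)
  list(index = as.integer(f), nlev = nlevels(f), struct = "iid")
}

new_term_diag_groups <- function(f, group_of_level) {
  f <- as.factor(f)
  stopifnot(length(group_of_level) == nlevels(f))
  list(index = as.integer(f), nlev = nlevels(f), struct = "diag_groups",
       group = as.integer(group_of_level), ngroup = max(group_of_level))
}

new_term_fa <- function(geno, site, k) {
  geno <- as.factor(geno); site <- as.factor(site)
  g <- nlevels(geno); s <- nlevels(site)
  idx <- (as.integer(geno) - 1L) * s + as.integer(site)
  list(index = idx, nlev = g * s, struct = "fa", fa_g = g, fa_s = s, fa_k = k)
}

# number of variance parameters a term consumes
term_npar <- function(term) {
  switch(term$struct,
    iid = 1L,
    diag_groups = term$ngroup,
    fa = {
      s <- term$fa_s; k <- term$fa_k
      as.integer(s * k - k * (k - 1) / 2 + s)  # free loadings + log psi
    })
}

# Sigma = Lambda Lambda' + diag(psi) from a term's parameter slice.
# Loadings are lower-triangular-free: column m has rows m..s.
fa_unpack <- function(par, s, k) {
  nl <- s * k - k * (k - 1) / 2
  lam <- matrix(0, s, k)
  pos <- 1L
  for (m in seq_len(k)) {
    nm <- s - m + 1L
    lam[m:s, m] <- par[pos:(pos + nm - 1L)]
    pos <- pos + nm
  }
  psi <- exp(par[pos:(pos + s - 1L)])
  list(lambda = lam, psi = psi, Sigma = tcrossprod(lam) + diag(psi, s))
}

# ---- design preparation ---------------------------------------------------
# Precompute every crossproduct the evaluator needs.  resid_group: integer
# per observation (1 = homogeneous).
reml_prep <- function(y, X, terms, resid_group = NULL) {
  n <- length(y)
  stopifnot(nrow(X) == n)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p)
    stop("fixed-effect design matrix is rank deficient")
  offs <- cumsum(c(0L, vapply(terms, function(t) t$nlev, integer(1))))
  q <- offs[length(offs)]
  ii <- seq_len(n)
  jj <- unlist(lapply(seq_along(terms),
                      function(t) offs[t] + terms[[t]]$index))
  Z <- Matrix::sparseMatrix(i = rep(ii, length(terms)), j = jj, x = 1,
                            dims = c(n, q))
  if (is.null(resid_group)) resid_group <- rep(1L, n)
  ngr <- max(resid_group)
  Czz <- vector("list", ngr); Czx <- vector("list", ngr)
  Cxx <- vector("list", ngr); Czy <- vector("list", ngr)
  Cxy <- vector("list", ngr); Cyy <- numeric(ngr); ngrp <- integer(ngr)
  for (g in seq_len(ngr)) {
    sel <- resid_group == g
    Zg <- Z[sel, , drop = FALSE]; Xg <- X[sel, , drop = FALSE]
    yg <- y[sel]
    Czz[[g]] <- as.matrix(Matrix::crossprod(Zg))
    Czx[[g]] <- as.matrix(Matrix::crossprod(Zg, Xg))
    Cxx[[g]] <- crossprod(Xg)
    Czy[[g]] <- as.numeric(Matrix::crossprod(Zg, yg))
    Cxy[[g]] <- as.numeric(crossprod(Xg, yg))
    Cyy[g] <- sum(yg^2)
    ngrp[g] <- sum(sel)
  }
  logdetXtX <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  list(y = y, X = X, Z = Z, terms = terms, offsets = offs, q = q, n = n,
       p = p, resid_group = resid_group, ngr = ngr, ngrp = ngrp,
       Czz = Czz, Czx = Czx, Cxx = Cxx, Czy = Czy, Cxy = Cxy, Cyy = Cyy,
       logdetXtX = logdetXtX)
}

# split a parameter vector into per-term slices + residual log-variances
split_theta <- function(theta, prep) {
  np <- vapply(prep$terms, term_npar, integer(1))
  ends <- cumsum(np)
  starts <- c(1L, head(ends, -1L) + 1L)
  slices <- lapply(seq_along(np), function(t) theta[starts[t]:ends[t]])
  re <- exp(theta[(ends[length(ends)] + 1L):length(theta)])
  stopifnot(length(re) == prep$ngr)
  list(slices = slices, resid_vars = re)
}

n_theta <- function(prep) {
  sum(vapply(prep$terms, term_npar, integer(1))) + prep$ngr
}

# G^-1 (dense q x q) and log|G| for a parameter split
build_ginv <- function(prep, slices) {
  q <- prep$q
  Ginv <- matrix(0, q, q)
  logdetG <- 0
  for (t in seq_along(prep$terms)) {
    term <- prep$terms[[t]]
    off <- prep$offsets[t]
    par <- slices[[t]]
    if (term$struct == "iid") {
      v <- exp(par)
      idx <- off + seq_len(term$nlev)
      diag(Ginv)[idx] <- 1 / v
      logdetG <- logdetG + term$nlev * log(v)
    } else if (term$struct == "diag_groups") {
      v <- exp(par)[term$group]
      idx <- off + seq_len(term$nlev)
      diag(Ginv)[idx] <- 1 / v
      logdetG <- logdetG + sum(log(v))
    } else { # fa
      s <- term$fa_s; g <- term$fa_g
      fa <- fa_unpack(par, s, term$fa_k)
      ch <- tryCatch(chol(fa$Sigma), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      Sinv <- chol2inv(ch)
      ld <- 2 * sum(log(diag(ch)))
      for (i in seq_len(g)) {
        idx <- off + (i - 1L) * s + seq_len(s)
        Ginv[idx, idx] <- Sinv
      }
      logdetG <- logdetG + g * ld
    }
  }
  list(Ginv = Ginv, logdetG = logdetG)
}

# ---- core evaluator -------------------------------------------------------
# Returns the restricted log-likelihood; optionally its gradient wrt theta
# and the fixed/random solutions.
reml_eval <- function(theta, prep, gradient = FALSE, solutions = FALSE) {
  sp <- split_theta(theta, prep)
  gv <- build_ginv(prep, sp$slices)
  if (is.null(gv)) return(NULL)
  re <- sp$resid_vars
  w <- 1 / re
  S <- matrix(0, prep$q, prep$q); F <- matrix(0, prep$q, prep$p)
  B0 <- matrix(0, prep$p, prep$p)
  zy <- numeric(prep$q); xy <- numeric(prep$p); yy <- 0; logdetR <- 0
  for (g in seq_len(prep$ngr)) {
    S <- S + prep$Czz[[g]] * w[g]
    F <- F + prep$Czx[[g]] * w[g]
    B0 <- B0 + prep$Cxx[[g]] * w[g]
    zy <- zy + prep$Czy[[g]] * w[g]
    xy <- xy + prep$Cxy[[g]] * w[g]
    yy <- yy + prep$Cyy[g] * w[g]
    logdetR <- logdetR + prep$ngrp[g] * log(re[g])
  }
  A <- S + gv$Ginv
  chA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(chA)) return(NULL)
  logdetA <- 2 * sum(log(diag(chA)))
  AinvF <- backsolve(chA, forwardsolve(t(chA), F))
  Ainvzy <- backsolve(chA, forwardsolve(t(chA), zy))
  B <- B0 - crossprod(F, AinvF)
  chB <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(chB)) return(NULL)
  logdetB <- 2 * sum(log(diag(chB)))
  rhs <- xy - crossprod(F, Ainvzy)
  bhat <- backsolve(chB, forwardsolve(t(chB), rhs))
  uhat <- Ainvzy - AinvF %*% bhat
  yPy <- yy - sum(bhat * xy) - sum(uhat * zy)
  ll <- -0.5 * ((prep$n - prep$p) * log(2 * pi) + logdetR + gv$logdetG +
                logdetA + logdetB + yPy - prep$logdetXtX)
  out <- list(loglik = as.numeric(ll))
  if (solutions || gradient) {
    out$bhat <- as.numeric(bhat)
    out$uhat <- as.numeric(uhat)
  }
  if (!gradient) return(out)

  # gradient: dl/dtheta = -1/2 [ tr(P dV) - y'P dV P y ]
  Ainv <- chol2inv(chA)
  Binv <- chol2inv(chB)
  SAinv <- S %*% Ainv
  ZVZ <- S - SAinv %*% S          # Z'V^-1 Z
  ZVX <- F - SAinv %*% F          # Z'V^-1 X
  Wzz <- ZVZ - ZVX %*% Binv %*% t(ZVX)   # Z'P Z
  wz <- zy - F %*% bhat - S %*% uhat     # Z'P y
  wz <- as.numeric(wz)

  # residual-level quantities
  resid <- prep$y - as.numeric(prep$X %*% bhat) -
    as.numeric(prep$Z %*% uhat)
  Py <- resid * w[prep$resid_group]
  # H = V^-1 X = R^-1 (X - Z A^-1 F)
  Hraw <- prep$X - as.matrix(prep$Z %*% AinvF)
  H <- Hraw * w[prep$resid_group]

  grad <- numeric(length(theta))
  pos <- 1L
  for (t in seq_along(prep$terms)) {
    term <- prep$terms[[t]]
    off <- prep$offsets[t]
    idx <- off + seq_len(term$nlev)
    dW <- diag(Wzz)[idx]
    wzb <- wz[idx]
    if (term$struct == "iid") {
      v <- exp(sp$slices[[t]])
      grad[pos] <- -0.5 * v * (sum(dW) - sum(wzb^2))
      pos <- pos + 1L
    } else if (term$struct == "diag_groups") {
      v <- exp(sp$slices[[t]])
      for (g in seq_len(term$ngroup)) {
        lv <- term$group == g
        grad[pos] <- -0.5 * v[g] * (sum(dW[lv]) - sum(wzb[lv]^2))
        pos <- pos + 1L
      }
    } else { # fa
      s <- term$fa_s; gg <- term$fa_g; k <- term$fa_k
      fa <- fa_unpack(sp$slices[[t]], s, k)
      Wblk <- Wzz[idx, idx]
      Wsum <- matrix(0, s, s)
      for (i in seq_len(gg)) {
        bi <- (i - 1L) * s + seq_len(s)
        Wsum <- Wsum + Wblk[bi, bi]
      }
      U <- matrix(wzb, nrow = s)
      Mtil <- Wsum - tcrossprod(U)
      Glam <- -(Mtil %*% fa$lambda)      # dl/dlambda (free entries)
      for (m in seq_len(k)) {
        nm <- s - m + 1L
        grad[pos:(pos + nm - 1L)] <- Glam[m:s, m]
        pos <- pos + nm
      }
      grad[pos:(pos + s - 1L)] <- -0.5 * fa$psi * diag(Mtil)
      pos <- pos + s
    }
  }
  # residual groups (log variances)
  for (g in seq_len(prep$ngr)) {
    sel <- prep$resid_group == g
    # tr(P D_g) = tr(V^-1 D_g) - tr(B^-1 X'V^-1 D_g V^-1 X)
    trV <- prep$ngrp[g] / re[g] -
      sum(Ainv * prep$Czz[[g]]) / re[g]^2
    Hg <- H[sel, , drop = FALSE]
    trP <- trV - sum((Hg %*% Binv) * Hg)
    grad[pos] <- -0.5 * re[g] * (trP - sum(Py[sel]^2))
    pos <- pos + 1L
  }
  out$gradient <- grad
  out
}

# ---- optimizer wrapper ----------------------------------------------------
# Maximizes reml_eval over theta with nlminb; returns best fit details.
reml_optimize <- function(prep, start, lower = NULL, upper = NULL,
                          max_iter = 200, tol = 1e-8) {
  if (is.null(lower)) lower <- rep(-25, length(start))
  if (is.null(upper)) upper <- rep(25, length(start))
  penalty <- 1e10
  fn <- function(th) {
    ev <- reml_eval(th, prep)
    if (is.null(ev) || !is.finite(ev$loglik)) return(penalty)
    -ev$loglik
  }
  gr <- function(th) {
    ev <- reml_eval(th, prep, gradient = TRUE)
    if (is.null(ev) || !is.finite(ev$loglik))
      return(rep(0, length(th)))
    -ev$gradient
  }
  ctrl <- list(iter.max = max_iter, eval.max = 4 * max_iter, rel.tol = tol)
  res <- tryCatch(
    nlminb(start, fn, gr, lower = lower, upper = upper, control = ctrl),
    error = function(e) NULL)
  if (is.null(res))
    return(list(theta = start, loglik = -penalty, converged = FALSE))
  tries <- 0L
  while (res$convergence != 0 && tries < 2L) {
    res2 <- tryCatch(
      nlminb(res$par, fn, gr, lower = lower, upper = upper,
             control = ctrl),
      error = function(e) NULL)
    if (is.null(res2)) break
    res <- res2
    tries <- tries + 1L
  }
  list(theta = res$par, loglik = -res$objective,
       converged = res$convergence == 0 && res$objective < penalty / 2,
       message = res$message)
}

# restricted log-likelihood at a user-supplied (invertible) G, through the
# same MME identity; Ginv/logdetG are passed in directly
reml_value_fixedG <- function(prep, Ginv, logdetG, resid_vars) {
  re <- resid_vars
  w <- 1 / re
  S <- matrix(0, prep$q, prep$q); F <- matrix(0, prep$q, prep$p)
  B0 <- matrix(0, prep$p, prep$p)
  zy <- numeric(prep$q); xy <- numeric(prep$p); yy <- 0; logdetR <- 0
  for (g in seq_len(prep$ngr)) {
    S <- S + prep$Czz[[g]] * w[g]
    F <- F + prep$Czx[[g]] * w[g]
    B0 <- B0 + prep$Cxx[[g]] * w[g]
    zy <- zy + prep$Czy[[g]] * w[g]
    xy <- xy + prep$Cxy[[g]] * w[g]
    yy <- yy + prep$Cyy[g] * w[g]
    logdetR <- logdetR + prep$ngrp[g] * log(re[g])
  }
  A <- S + Ginv
  chA <- chol(A)
  logdetA <- 2 * sum(log(diag(chA)))
  AinvF <- backsolve(chA, forwardsolve(t(chA), F))
  Ainvzy <- backsolve(chA, forwardsolve(t(chA), zy))
  B <- B0 - crossprod(F, AinvF)
  chB <- chol(B)
  logdetB <- 2 * sum(log(diag(chB)))
  bhat <- backsolve(chB, forwardsolve(t(chB), xy - crossprod(F, Ainvzy)))
  uhat <- Ainvzy - AinvF %*% bhat
  yPy <- yy - sum(bhat * xy) - sum(uhat * zy)
  -0.5 * ((prep$n - prep$p) * log(2 * pi) + logdetR + logdetG +
          logdetA + logdetB + yPy - prep$logdetXtX)
}

# ---- dense reference evaluator -------------------------------------------
# Restricted likelihood of the orthonormal error contrasts, computed from
# the fully assembled n x n marginal covariance.  Deliberately brute force:
# used as the independent reference for the MME path.
reml_loglik_contrasts <- function(y, X, V) {
  n <- length(y)
  p <- qr(X)$rank
  K <- qr.Q(qr(X), complete = TRUE)[, (p + 1L):n, drop = FALSE]
  M <- crossprod(K, V %*% K)
  chM <- chol(M)
  ky <- crossprod(K, y)
  quad <- sum(forwardsolve(t(chM), ky)^2)
  -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(chM))) + quad)
}

# dense V from the same term structures (indicator-matrix route)
assemble_dense_V <- function(prep_like) {
  n <- prep_like$n
  V <- diag(prep_like$resid_vars_obs, n)
  for (t in seq_along(prep_like$terms)) {
    term <- prep_like$terms[[t]]
    Zt <- matrix(0, n, term$nlev)
    Zt[cbind(seq_len(n), term$index)] <- 1
    G <- prep_like$Gmats[[t]]
    V <- V + Zt %*% G %*% t(Zt)
  }
  V
}
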