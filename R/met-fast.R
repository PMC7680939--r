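# Fast REML evaluator for the multi-environment model.
#
# The genotype main effect and the GxE interaction are combined into one
# s-variate effect per genotype, v_i = g_i 1 + ge_i, with covariance
# Sigma* = sigma2_g 11' + Lambda Lambda' + Psi.  The marginal covariance of
# the data is unchanged (Z_g Z_g' = Z_ge (I (x) 11') Z_ge'), but the MME
# coefficient matrix becomes block-diagonal over genotypes once the
# (small) replicate-within-site block is eliminated by a Schur complement,
# so one evaluation costs O(g s^3) instead of O((g s)^3).  Genotypes with
# identical observation patterns (all of them, for complete data) share
# their s x s factorizations.
#
# Verified against the general dense MME evaluator and the dense
# error-contrast reference in the test suite.

prep_met_fast <- function(rec) {
  geno <- factor(rec$genotype)
  site <- factor(rec$site)
  g <- nlevels(geno); s <- nlevels(site)
  repl <- factor(paste(as.integer(site), rec$rep, sep = ":"))
  # order replicate levels by site then rep
  lv <- levels(repl)
  parts <- do.call(rbind, strsplit(lv, ":", fixed = TRUE))
  ord <- order(as.integer(parts[, 1]), as.integer(parts[, 2]))
  repl <- factor(repl, levels = lv[ord])
  q_o <- nlevels(repl)
  site_of_rep <- as.integer(do.call(rbind, strsplit(levels(repl), ":",
                                                    fixed = TRUE))[, 1])
  gi <- as.integer(geno); sj <- as.integer(site); rl <- as.integer(repl)
  y <- rec$yield
  n <- length(y)
  Ngs <- matrix(0L, g, s)
  tt <- table(gi, sj)
  Ngs[cbind(rep(as.integer(rownames(tt)), ncol(tt)),
            rep(as.integer(colnames(tt)), each = nrow(tt)))] <- as.integer(tt)
  Ngr <- matrix(0L, g, q_o)
  tt <- table(gi, rl)
  Ngr[cbind(rep(as.integer(rownames(tt)), ncol(tt)),
            rep(as.integer(colnames(tt)), each = nrow(tt)))] <- as.integer(tt)
  Sy <- matrix(0, g, s)
  lev <- (gi - 1L) * s + sj
  agg <- rowsum(y, group = lev)
  lv <- as.integer(rownames(agg))
  Sy[cbind((lv - 1L) %/% s + 1L, (lv - 1L) %% s + 1L)] <- agg
  Ry <- as.numeric(rowsum(y, rl, reorder = TRUE))
  Xy <- as.numeric(rowsum(y, sj, reorder = TRUE))
  Nx <- as.integer(table(sj))
  N_rep <- as.integer(table(rl))
  # pattern grouping by identical replicate-level observation counts
  key <- apply(Ngr, 1, paste, collapse = ",")
  pat_of <- match(key, unique(key))
  patterns <- lapply(seq_len(max(pat_of)), function(p) {
    members <- which(pat_of == p)
    i0 <- members[1]
    Kc <- matrix(0, q_o, s)
    Kc[cbind(seq_len(q_o), site_of_rep)] <- Ngr[i0, ]
    list(members = members, m = length(members),
         ngs = Ngs[i0, ], Kc = Kc)
  })
  list(n = n, g = g, s = s, q_o = q_o, p = s,
       geno_levels = levels(geno), site_levels = levels(site),
       gi = gi, sj = sj, rl = rl, y = y, yy = sum(y^2),
       site_of_rep = site_of_rep, N_rep = N_rep, Nx = Nx,
       Ngs = Ngs, Sy = Sy, Ry = Ry, Xy = Xy,
       pat_of = pat_of, patterns = patterns,
       logdetXtX = sum(log(Nx)),
       q = q_o + g * s)
}

# pars: list(s2r (s-vector), s2g, lambda (s x k or NULL), psi (s), s2e)
eval_met_fast <- function(pars, prep, gradient = FALSE, solutions = FALSE) {
  s <- prep$s; g <- prep$g; q_o <- prep$q_o; n <- prep$n
  w <- 1 / pars$s2e
  k <- if (is.null(pars$lambda)) 0L else ncol(pars$lambda)
  Sigma_ge <- diag(pars$psi, s)
  if (k > 0) Sigma_ge <- Sigma_ge + tcrossprod(pars$lambda)
  Sigma <- Sigma_ge + pars$s2g
  chS <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(chS)) return(NULL)
  Sinv <- chol2inv(chS)
  ldS <- 2 * sum(log(diag(chS)))
  s2r_lev <- pars$s2r[prep$site_of_rep]
  Aoo <- prep$N_rep * w + 1 / s2r_lev
  logdetG <- g * ldS + sum(log(s2r_lev))
  logdetA <- 0
  npat <- length(prep$patterns)
  Bpinv <- vector("list", npat); Kw <- vector("list", npat)
  Schur <- matrix(0, q_o, q_o)
  for (p in seq_len(npat)) {
    pt <- prep$patterns[[p]]
    Bp <- Sinv + diag(pt$ngs * w, s)
    ch <- tryCatch(chol(Bp), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Bpinv[[p]] <- chol2inv(ch)
    logdetA <- logdetA + pt$m * 2 * sum(log(diag(ch)))
    Kw[[p]] <- pt$Kc * w
    Schur <- Schur + pt$m * (Kw[[p]] %*% Bpinv[[p]] %*% t(Kw[[p]]))
  }
  Atil <- diag(Aoo, q_o) - Schur
  chAt <- tryCatch(chol(Atil), error = function(e) NULL)
  if (is.null(chAt)) return(NULL)
  logdetA <- logdetA + 2 * sum(log(diag(chAt)))
  Atinv <- chol2inv(chAt)

  # rhs blocks: F (q x s) and zy (q)
  Fo <- matrix(0, q_o, s)                       # Z_rep' R^-1 X
  Fo[cbind(seq_len(q_o), prep$site_of_rep)] <- prep$N_rep * w
  zy_o <- prep$Ry * w
  # reduce to the replicate block
  rhs_o_F <- Fo; rhs_o_z <- zy_o
  BFg <- vector("list", npat)    # B^-1 (w diag(ngs)) per pattern (s x s)
  Bzy <- matrix(0, s, g)         # B^-1 (w Sy_i) per genotype
  for (p in seq_len(npat)) {
    pt <- prep$patterns[[p]]
    BFg[[p]] <- Bpinv[[p]] * rep(pt$ngs * w, each = s)  # Bpinv %*% diag
    rhs_o_F <- rhs_o_F - pt$m * (Kw[[p]] %*% BFg[[p]])
    Bz <- Bpinv[[p]] %*% (t(prep$Sy[pt$members, , drop = FALSE]) * w)
    Bzy[, pt$members] <- Bz
    rhs_o_z <- rhs_o_z - as.numeric(Kw[[p]] %*% rowSums(Bz))
  }
  u_oF <- Atinv %*% rhs_o_F                     # q_o x s
  u_oz <- as.numeric(Atinv %*% rhs_o_z)
  # back-substitute into genotype blocks
  TF <- vector("list", npat)                    # A^-1 F, ge rows (s x s)
  KtuF <- vector("list", npat)
  Vz <- matrix(0, s, g)                         # A^-1 zy, ge rows
  for (p in seq_len(npat)) {
    pt <- prep$patterns[[p]]
    KtuF[[p]] <- crossprod(Kw[[p]], u_oF)       # s x s
    TF[[p]] <- BFg[[p]] - Bpinv[[p]] %*% KtuF[[p]]
    kz <- as.numeric(crossprod(Kw[[p]], u_oz))  # s
    Vz[, pt$members] <- Bzy[, pt$members, drop = FALSE] -
      as.numeric(Bpinv[[p]] %*% kz)
  }
  # fixed-effect system
  FA_F <- crossprod(Fo, u_oF)                   # F' A^-1 F, rep part
  FA_z <- as.numeric(crossprod(Fo, u_oz))
  for (p in seq_len(npat)) {
    pt <- prep$patterns[[p]]
    D <- pt$ngs * w
    FA_F <- FA_F + pt$m * (D * TF[[p]])         # diag(D) %*% TF
    FA_z <- FA_z + D * rowSums(Vz[, pt$members, drop = FALSE])
  }
  B <- diag(prep$Nx * w, s) - FA_F
  chB <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(chB)) return(NULL)
  logdetB <- 2 * sum(log(diag(chB)))
  Binv <- chol2inv(chB)
  Xyw <- prep$Xy * w
  bhat <- as.numeric(Binv %*% (Xyw - FA_z))
  # random solutions
  u_o <- u_oz - as.numeric(u_oF %*% bhat)
  Vhat <- Vz                                    # s x g, v_i = g_i + ge_i
  for (p in seq_len(npat)) {
    pt <- prep$patterns[[p]]
    tb <- as.numeric(TF[[p]] %*% bhat)
    Vhat[, pt$members] <- Vhat[, pt$members, drop = FALSE] - tb
  }
  uzy <- sum(u_o * zy_o) + sum(Vhat * t(prep$Sy * w))
  yPy <- prep$yy * w - sum(bhat * Xyw) - uzy
  ll <- -0.5 * ((n - s) * log(2 * pi) + n * log(pars$s2e) + logdetG +
                logdetA + logdetB + yPy - prep$logdetXtX)
  out <- list(loglik = as.numeric(ll))
  if (solutions || gradient) {
    ws <- Sinv %*% Vhat                          # Z'Py, ge part (s x g)
    out$bhat <- bhat
    out$u_rep <- u_o
    out$Vhat <- Vhat
    out$blup_g <- pars$s2g * colSums(ws)
    out$blup_ge <- Sigma_ge %*% ws               # s x g
    out$Sigma <- Sigma
    out$Sigma_ge_only <- Sigma_ge
  }
  if (!gradient) return(out)

  ws <- Sinv %*% Vhat
  wz_o <- u_o / s2r_lev
  # ZVX = Ginv A^-1 F ; rep part
  ZVX_o <- u_oF / s2r_lev
  dW_o <- 1 / s2r_lev - diag(Atinv) / s2r_lev^2 -
    rowSums((ZVX_o %*% Binv) * ZVX_o)
  # genotype-block sums
  Wsum <- matrix(0, s, s)
  trAinvG_ge <- 0
  for (p in seq_len(npat)) {
    pt <- prep$patterns[[p]]
    Tp <- Bpinv[[p]] %*% t(Kw[[p]])             # s x q_o
    Aii <- Bpinv[[p]] + Tp %*% Atinv %*% t(Tp)
    SZ <- Sinv %*% TF[[p]]                      # ZVX ge rows for pattern
    Wsum <- Wsum + pt$m * (Sinv - Sinv %*% Aii %*% Sinv -
                           SZ %*% Binv %*% t(SZ))
    trAinvG_ge <- trAinvG_ge + pt$m * sum(Aii * Sinv)
  }
  Mtil <- Wsum - tcrossprod(ws)
  grad <- list()
  # replicate variances (per site, log scale)
  gr_r <- numeric(s)
  contrib <- -0.5 * pars$s2r[prep$site_of_rep] * (dW_o - wz_o^2)
  for (j in seq_len(s)) gr_r[j] <- sum(contrib[prep$site_of_rep == j])
  grad$s2r <- gr_r
  grad$s2g <- -0.5 * pars$s2g * sum(Mtil)
  if (k > 0) grad$lambda <- -(Mtil %*% pars$lambda)
  grad$psi <- -0.5 * pars$psi * diag(Mtil)
  # residual variance (log scale)
  # tr(V^-1) = n w - w^2 tr(A^-1 Z'Z), and Z'R^-1 Z = A - Ginv, so
  # tr(A^-1 Z'Z) = (q - tr(A^-1 Ginv)) / w
  trAinvG <- sum(diag(Atinv) / s2r_lev) + trAinvG_ge
  trVinv <- n * w - w * (prep$q - trAinvG)
  # H = V^-1 X
  TFstack <- do.call(rbind, TF)                 # (npat*s) x s; row = ge cell
  rowid <- (prep$pat_of[prep$gi] - 1L) * s + prep$sj
  Hraw <- -u_oF[prep$rl, , drop = FALSE] - TFstack[rowid, , drop = FALSE]
  Hraw[cbind(seq_len(n), prep$sj)] <- Hraw[cbind(seq_len(n), prep$sj)] + 1
  H <- Hraw * w
  trP <- trVinv - sum((H %*% Binv) * H)
  Py <- w * (prep$y - bhat[prep$sj] - u_o[prep$rl] -
             Vhat[cbind(prep$sj, prep$gi)])
  grad$s2e <- -0.5 * pars$s2e * (trP - sum(Py^2))
  out$gradient <- grad
  out
}
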