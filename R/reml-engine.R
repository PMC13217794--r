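# Core REML machinery for the repeated-records animal model
#
#   y = Xb + Za + Vc + Wd + e
#
# with a ~ N(0, Sigma_a (x) G), c ~ N(0, Sigma_c (x) I),
# d ~ N(0, Sigma_d (x) I) and residuals grouped (pen-hour groups for the
# univariate analyses; per-observation-unit T x T blocks for multi-trait
# models, so traits of the same bird-day-hour correlate residually).
# Estimation is average-information REML on the mixed-model equations
# (MME), with an EM fallback step whenever an AI proposal leaves the
# parameter space or decreases the restricted likelihood. The restricted
# log-likelihood is computed through the standard MME identity
#   log|V| + log|X' V^-1 X| = log|R| + sum_t log|Sigma_t (x) K_t| + log|C|
# and reported up to an additive constant.

# ---- parameter bookkeeping ------------------------------------------------

# vech index pairs for a T x T symmetric matrix (row >= col order)
vech_pairs <- function(nt) {
  out <- NULL
  for (r in seq_len(nt)) for (s in r:nt) out <- rbind(out, c(r, s))
  out
}

mat_to_vech <- function(S) {
  nt <- nrow(S)
  vp <- vech_pairs(nt)
  S[vp]
}

vech_to_mat <- function(v, nt) {
  vp <- vech_pairs(nt)
  S <- matrix(0, nt, nt)
  S[vp] <- v
  S[vp[, c(2, 1), drop = FALSE]] <- v
  S
}

# flatten a varcomp list into the engine parameter vector
vc_flatten <- function(vc) {
  unlist(c(lapply(vc$terms, mat_to_vech), lapply(vc$resid, mat_to_vech)),
         use.names = FALSE)
}

vc_unflatten <- function(theta, template) {
  nt <- template$nt
  m <- nt * (nt + 1) / 2
  vc <- template
  k <- 0L
  for (t in seq_along(template$terms)) {
    vc$terms[[t]] <- vech_to_mat(theta[k + seq_len(m)], nt)
    k <- k + m
  }
  for (g in seq_along(template$resid)) {
    vc$resid[[g]] <- vech_to_mat(theta[k + seq_len(m)], nt)
    k <- k + m
  }
  vc
}

# parameter metadata table: one row per vech entry of every matrix
vc_param_table <- function(vc) {
  nt <- vc$nt
  vp <- vech_pairs(nt)
  out <- list()
  for (t in seq_along(vc$terms)) {
    out[[length(out) + 1L]] <- tibble(
      block = "term", name = names(vc$terms)[t], index = t,
      row = vp[, 1], col = vp[, 2]
    )
  }
  for (g in seq_along(vc$resid)) {
    out[[length(out) + 1L]] <- tibble(
      block = "resid", name = names(vc$resid)[g], index = g,
      row = vp[, 1], col = vp[, 2]
    )
  }
  bind_rows(out)
}

# ---- likelihood evaluation on the MME -------------------------------------

# residual inverse blocks per unit; returns sparse Rinv, log|R| and the
# per-(group, pattern) inverse blocks for trace shortcuts
build_rinv <- function(design, vc) {
  n <- length(design$y)
  nt <- vc$nt
  cache <- new.env(parent = emptyenv())
  get_block <- function(g, mask) {
    key <- paste0(g, "_", mask)
    blk <- cache[[key]]
    if (is.null(blk)) {
      obs <- which(bitwAnd(bitwShiftL(1L, 0:(nt - 1L)), mask) > 0L)
      S <- vc$resid[[g]][obs, obs, drop = FALSE]
      ch <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(ch)) abort("residual covariance block is not positive definite.")
      blk <- list(inv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))), obs = obs)
      cache[[key]] <- blk
    }
    blk
  }

  if (nt == 1L) {
    # scalar residual groups: diagonal R
    sig <- vapply(vc$resid, function(S) S[1, 1], 0)
    w <- 1 / sig[design$rgroup]
    Rinv <- Matrix::Diagonal(n, x = w)
    logdetR <- sum(log(sig[design$rgroup]))
    return(list(Rinv = Rinv, logdetR = logdetR, get_block = get_block))
  }

  # multi-trait: order records by unit then trait, emit one dense block per unit
  ord <- design$unit_order          # record indices grouped by unit
  grp <- design$unit_sizes          # run-length of each unit within ord
  ugroup <- design$unit_rgroup      # residual group per unit
  upat <- design$unit_pattern_vec   # observed-trait bitmask per unit
  ii_l <- vector("list", length(grp))
  jj_l <- vector("list", length(grp))
  xx_l <- vector("list", length(grp))
  logdetR <- 0
  pos <- 0L
  for (k in seq_along(grp)) {
    m <- grp[k]
    rows <- ord[pos + seq_len(m)]
    pos <- pos + m
    blk <- get_block(ugroup[k], upat[k])
    logdetR <- logdetR + blk$logdet
    ii_l[[k]] <- rep(rows, each = m)
    jj_l[[k]] <- rep(rows, times = m)
    xx_l[[k]] <- as.numeric(t(blk$inv))
  }
  Rinv <- Matrix::sparseMatrix(
    i = unlist(ii_l), j = unlist(jj_l), x = unlist(xx_l), dims = c(n, n)
  )
  list(Rinv = Rinv, logdetR = logdetR, get_block = get_block)
}

# prior inverse (Sigma_t (x) K_t)^-1 as a sparse/dense block, and its logdet
term_prior <- function(term, Sigma) {
  nt <- nrow(Sigma)
  q <- term$q
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) abort(sprintf("covariance of term '%s' is not positive definite.",
                                 term$name))
  Sinv <- chol2inv(ch)
  logdetS <- 2 * sum(log(diag(ch)))
  if (is.null(term$Kinv)) {
    Ginv_blk <- Matrix::Diagonal(q)
    logdetK <- 0
  } else {
    Ginv_blk <- term$Kinv
    logdetK <- term$logdetK
  }
  prior_inv <- Matrix::kronecker(Sinv, Ginv_blk)
  list(prior_inv = prior_inv, logdet = q * logdetS + nt * logdetK,
       Sinv = Sinv)
}

# one full evaluation of the MME at vc: C, its inverse, solutions, loglik
mme_eval <- function(design, vc, want_cinv = TRUE) {
  y <- design$y
  M <- design$M
  p_tot <- ncol(M)
  rin <- build_rinv(design, vc)
  Rinv <- rin$Rinv
  MtRi <- Matrix::crossprod(M, Rinv)
  C <- as.matrix(MtRi %*% M)
  rhs <- as.numeric(MtRi %*% y)
  logdet_prior <- 0
  priors <- list()
  for (t in seq_along(design$terms)) {
    tp <- term_prior(design$terms[[t]], vc$terms[[t]])
    priors[[t]] <- tp
    idx <- design$terms[[t]]$cols
    C[idx, idx] <- C[idx, idx] + as.matrix(tp$prior_inv)
    logdet_prior <- logdet_prior + tp$logdet
  }
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    abort("mixed-model coefficient matrix is singular; check fixed-effect rank or add a diagonal bump to the GRM.")
  }
  sol <- backsolve(ch, forwardsolve(t(ch), rhs))
  logdetC <- 2 * sum(log(diag(ch)))
  ehat <- as.numeric(y - M %*% sol)
  Py <- as.numeric(Rinv %*% ehat)
  ypy <- sum(y * Py)
  loglik <- -0.5 * (rin$logdetR + logdet_prior + logdetC + ypy)
  out <- list(C = C, chol = ch, sol = sol, Py = Py, ehat = ehat,
              ypy = ypy, loglik = loglik, Rinv = Rinv, rin = rin,
              priors = priors)
  if (want_cinv) out$Cinv <- chol2inv(ch)
  out
}

# ---- gradients, AI matrix, EM updates -------------------------------------

# residual direction matrix D for group g, element (r, s), as sparse n x n
resid_direction <- function(design, g, r, s) {
  pr <- design$resid_pairs
  sel <- pr$rgroup == g &
    ((pr$ti == r & pr$tj == s) | (pr$ti == s & pr$tj == r))
  i <- pr$i[sel]
  j <- pr$j[sel]
  n <- length(design$y)
  if (r == s) {
    keep <- i == j
    Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1, dims = c(n, n))
  } else {
    keep <- i != j
    Matrix::sparseMatrix(i = c(i[keep], j[keep]), j = c(j[keep], i[keep]),
                         x = 1, dims = c(n, n))
  }
}

reml_derivatives <- function(design, vc, ev, free_mask) {
  nt <- vc$nt
  q_terms <- vapply(design$terms, function(t) t$q, 0)
  Cinv <- ev$Cinv
  Py <- ev$Py
  M <- design$M
  n <- length(design$y)
  ptab <- vc_param_table(vc)
  npar <- nrow(ptab)
  grad <- numeric(npar)
  Fmat <- matrix(0, n, npar)

  for (t in seq_along(design$terms)) {
    term <- design$terms[[t]]
    q <- term$q
    idx <- term$cols
    Sinv <- ev$priors[[t]]$Sinv
    Ct <- Cinv[idx, idx, drop = FALSE]
    # TK[i, j] = tr(C^{tt}[i,j] K^-1)
    TK <- matrix(0, nt, nt)
    for (i in seq_len(nt)) for (j in seq_len(nt)) {
      blk <- Ct[(i - 1) * q + seq_len(q), (j - 1) * q + seq_len(q), drop = FALSE]
      TK[i, j] <- if (is.null(term$Kinv)) sum(diag(blk)) else sum(blk * term$Kinv)
    }
    Gt <- matrix(as.numeric(Matrix::crossprod(M[, idx, drop = FALSE], Py)), q, nt)
    KG <- if (is.null(term$K)) Gt else term$K %*% Gt
    QK <- crossprod(Gt, KG)
    rows <- which(ptab$block == "term" & ptab$index == t)
    for (k in rows) {
      r <- ptab$row[k]; s <- ptab$col[k]
      A <- Sinv[, r, drop = FALSE] %*% Sinv[s, , drop = FALSE]
      if (r != s) A <- A + Sinv[, s, drop = FALSE] %*% Sinv[r, , drop = FALSE]
      tr1 <- q * (if (r == s) Sinv[r, r] else 2 * Sinv[r, s])
      tr2 <- sum(A * t(TK))
      quad <- if (r == s) QK[r, r] else 2 * QK[r, s]
      grad[k] <- -0.5 * ((tr1 - tr2) - quad)
      # f = Z_t (E (x) K) Z_t' Py, realised per record
      Fm <- matrix(0, q, nt)
      if (r == s) {
        Fm[, r] <- KG[, r]
      } else {
        Fm[, s] <- KG[, r]
        Fm[, r] <- KG[, s]
      }
      lvl <- design$term_level[[t]]
      Fmat[, k] <- Fm[cbind(lvl, design$trait)]
    }
  }

  # residual parameters
  rows <- which(ptab$block == "resid")
  for (k in rows) {
    g <- ptab$index[k]; r <- ptab$row[k]; s <- ptab$col[k]
    D <- resid_direction(design, g, r, s)
    if (length(D@x) == 0L && r != s) { grad[k] <- 0; next }
    tr1 <- trace_rinv_d(design, ev, g, r, s)
    B <- ev$Rinv %*% D %*% ev$Rinv
    S <- Matrix::crossprod(M, B %*% M)
    St <- methods::as(methods::as(S, "generalMatrix"), "TsparseMatrix")
    tr2 <- sum(Cinv[cbind(St@i + 1L, St@j + 1L)] * St@x)
    DPy <- as.numeric(D %*% Py)
    quad <- sum(Py * DPy)
    grad[k] <- -0.5 * ((tr1 - tr2) - quad)
    Fmat[, k] <- DPy
  }

  # AI matrix: 0.5 * F' P F
  RF <- as.matrix(ev$Rinv %*% Fmat)
  T1 <- as.matrix(Matrix::crossprod(M, RF))
  T3 <- as.matrix(M %*% (Cinv %*% T1))
  PF <- as.matrix(ev$Rinv %*% (Fmat - T3))
  AI <- 0.5 * crossprod(Fmat, PF)
  AI <- (AI + t(AI)) / 2
  list(grad = grad, AI = AI, ptab = ptab)
}

# tr(Rinv D) via the cached per-(group, pattern) inverse blocks
trace_rinv_d <- function(design, ev, g, r, s) {
  rin <- ev$rin
  pats <- design$unit_patterns  # tibble: rgroup, pattern, n_units
  sel <- pats$rgroup == g
  tot <- 0
  for (k in which(sel)) {
    mask <- pats$pattern[k]
    has_r <- bitwAnd(bitwShiftL(1L, r - 1L), mask) > 0L
    has_s <- bitwAnd(bitwShiftL(1L, s - 1L), mask) > 0L
    if (!(has_r && has_s)) next
    blk <- rin$get_block(g, mask)
    pr <- match(r, blk$obs); ps <- match(s, blk$obs)
    v <- blk$inv[pr, ps]
    tot <- tot + pats$n_units[k] * (if (r == s) v else 2 * v)
  }
  tot
}

# EM updates (used as fallback): term matrices always; residuals only in
# the scalar-per-group (univariate) case
em_update <- function(design, vc, ev, free_mask) {
  nt <- vc$nt
  Cinv <- ev$Cinv
  new_vc <- vc
  for (t in seq_along(design$terms)) {
    term <- design$terms[[t]]
    q <- term$q
    idx <- term$cols
    U <- matrix(ev$sol[idx], q, nt)
    KU <- if (is.null(term$Kinv)) U else term$Kinv %*% U
    UKU <- crossprod(U, KU)
    Ct <- Cinv[idx, idx, drop = FALSE]
    TK <- matrix(0, nt, nt)
    for (i in seq_len(nt)) for (j in seq_len(nt)) {
      blk <- Ct[(i - 1) * q + seq_len(q), (j - 1) * q + seq_len(q), drop = FALSE]
      TK[i, j] <- if (is.null(term$Kinv)) sum(diag(blk)) else sum(blk * term$Kinv)
    }
    S_new <- (UKU + (TK + t(TK)) / 2) / q
    S_old <- vc$terms[[t]]
    fixed <- vc$fixed_terms[[t]]
    S_new[fixed] <- S_old[fixed]
    new_vc$terms[[t]] <- clip_psd_quiet(S_new)
  }
  if (nt == 1L) {
    # scalar residual groups: exact EM update
    MC <- as.matrix(design$M %*% Cinv)
    h <- rowSums(MC * as.matrix(design$M))
    for (g in seq_along(vc$resid)) {
      if (vc$fixed_resid[[g]][1, 1]) next
      sel <- design$rgroup == g
      n_g <- sum(sel)
      if (n_g == 0L) next
      new_vc$resid[[g]][1, 1] <- (sum(ev$ehat[sel]^2) + sum(h[sel])) / n_g
    }
  }
  new_vc
}

# PSD projection with a relative eigenvalue floor: keeps covariance
# matrices invertible with bounded condition number (correlations cannot
# reach exactly +/-1), which keeps the prior inverse and the restricted
# likelihood numerically stable near boundaries
clip_psd_quiet <- function(S, rel_floor = 1e-6) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lo <- max(rel_floor * mean(pmax(diag(S), 0)), 1e-12)
  vals <- pmax(e$values, lo)
  S2 <- e$vectors %*% (vals * t(e$vectors))
  (S2 + t(S2)) / 2
}

vc_valid <- function(vc, floor_val) {
  ok <- TRUE
  for (S in vc$terms) {
    if (any(!is.finite(S))) return(FALSE)
    if (inherits(tryCatch(chol(S + diag(floor_val, nrow(S))),
                          error = function(e) e), "error")) ok <- FALSE
  }
  for (S in vc$resid) {
    if (any(!is.finite(S)) || any(diag(S) <= 0)) return(FALSE)
    if (inherits(tryCatch(chol(S), error = function(e) e), "error")) ok <- FALSE
  }
  ok
}

# project a parameter vector back into the feasible region
vc_project <- function(vc, floor_val) {
  for (t in seq_along(vc$terms)) {
    S <- vc$terms[[t]]
    diag(S) <- pmax(diag(S), floor_val)
    vc$terms[[t]] <- clip_psd_quiet(S)
    fixed <- vc$fixed_terms[[t]]
    vc$terms[[t]][fixed] <- vc$terms_fixed_values[[t]][fixed]
  }
  for (g in seq_along(vc$resid)) {
    S <- vc$resid[[g]]
    diag(S) <- pmax(diag(S), floor_val)
    vc$resid[[g]] <- clip_psd_quiet(S)
    fixed <- vc$fixed_resid[[g]]
    vc$resid[[g]][fixed] <- vc$resid_fixed_values[[g]][fixed]
  }
  vc
}

# ---- main iteration loop --------------------------------------------------

reml_engine <- function(design, start, max_iter = 200, tol_loglik = 1e-8,
                        tol_par = 1e-6, verbose = FALSE, n_em_start = 2) {
  vc <- start
  floor_val <- 1e-8 * (mean(design$y^2) + 1e-8)
  vc <- vc_project(vc, floor_val)
  free_mask <- !c(unlist(lapply(vc$fixed_terms, mat_to_vech)),
                  unlist(lapply(vc$fixed_resid, mat_to_vech)))
  ev <- mme_eval(design, vc)
  trace <- tibble(iter = 0L, loglik = ev$loglik, step = "start")
  converged <- FALSE
  iter <- 0L
  se_vec <- rep(NA_real_, sum(free_mask))
  last_der <- NULL

  while (iter < max_iter) {
    iter <- iter + 1L
    theta_old <- vc_flatten(vc)
    use_em <- iter <= n_em_start
    step_kind <- "em"
    cand <- NULL
    if (!use_em) {
      der <- reml_derivatives(design, vc, ev, free_mask)
      last_der <- der
      gfree <- der$grad[free_mask]
      AIfree <- der$AI[free_mask, free_mask, drop = FALSE]
      scale0 <- mean(diag(AIfree)) + 1e-12
      for (damp in c(0, 1e-2, 1)) {
        delta_free <- tryCatch(
          solve(AIfree + diag(damp * scale0, nrow(AIfree)), gfree),
          error = function(e) NULL)
        if (is.null(delta_free)) next
        step <- 1
        for (tries in 1:4) {
          theta_new <- theta_old
          theta_new[free_mask] <- theta_new[free_mask] + step * delta_free
          cand_vc <- vc_project(vc_unflatten(theta_new, vc), floor_val)
          if (vc_valid(cand_vc, floor_val)) {
            cand_ev <- tryCatch(mme_eval(design, cand_vc, want_cinv = FALSE),
                                error = function(e) NULL)
            if (!is.null(cand_ev) &&
                cand_ev$loglik >= ev$loglik - 1e-6 * (abs(ev$loglik) + 1)) {
              cand <- list(vc = cand_vc, ev = cand_ev)
              step_kind <- "ai"
              break
            }
          }
          step <- step / 2
        }
        if (!is.null(cand)) break
      }
    }
    if (is.null(cand)) {
      cand_vc <- vc_project(em_update(design, vc, ev, free_mask), floor_val)
      cand_ev <- tryCatch(mme_eval(design, cand_vc, want_cinv = FALSE),
                          error = function(e) NULL)
      if (is.null(cand_ev)) break
      cand <- list(vc = cand_vc, ev = cand_ev)
      step_kind <- if (use_em) "em" else "em_fallback"
    }
    dll <- cand$ev$loglik - ev$loglik
    theta_new <- vc_flatten(cand$vc)
    dpar <- max(abs(theta_new - theta_old) /
                  (abs(theta_old) + 1e-6))
    vc <- cand$vc
    ev <- cand$ev
    if (is.null(ev$Cinv)) ev$Cinv <- chol2inv(ev$chol)
    trace <- bind_rows(trace, tibble(iter = iter, loglik = ev$loglik,
                                     step = step_kind))
    if (verbose) message(sprintf("it %d (%s): logL = %.6f", iter, step_kind,
                                 ev$loglik))
    if (!use_em && abs(dll) < tol_loglik * (abs(ev$loglik) + 1) &&
        (dpar < tol_par || step_kind != "ai")) {
      converged <- TRUE
      break
    }
  }
  # SEs from the AI matrix at the optimum
  der <- reml_derivatives(design, vc, ev, free_mask)
  AIfree <- der$AI[free_mask, free_mask, drop = FALSE]
  covfree <- tryCatch(solve(AIfree), error = function(e) NULL)
  if (is.null(covfree) && nrow(AIfree) > 0) {
    # pseudo-inverse when the AI matrix is singular (boundary estimates)
    e <- eigen(AIfree, symmetric = TRUE)
    pos <- e$values > max(e$values, 0) * 1e-10
    if (any(pos)) {
      covfree <- e$vectors[, pos, drop = FALSE] %*%
        ((1 / e$values[pos]) * t(e$vectors[, pos, drop = FALSE]))
    }
  }
  if (!is.null(covfree)) {
    se_vec <- sqrt(pmax(diag(covfree), 0))
  }
  se_full <- rep(NA_real_, length(free_mask))
  se_full[free_mask] <- se_vec
  list(vc = vc, ev = ev, loglik = ev$loglik, converged = converged,
       n_iterations = iter, trace = trace, se = se_full,
       par_cov = covfree, free_mask = free_mask, ptab = der$ptab)
}
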