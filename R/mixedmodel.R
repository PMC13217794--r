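# user-facing model layer on top of the REML engine

#' Assemble the repeated-records animal model
#'
#' Translates an hourly phenotype table into the design structures of the
#' linear mixed model `y = Xb + Za + Vc + Wd + e`: fixed effects pen, day
#' and hour of day (reference-level coding, first level dropped),
#' optional fixed covariates, random animal (covariance GRM), random
#' pen-day-hour interaction and random permanent-environment effect, and
#' a residual grouped by pen-hour (a separate variance per group) or
#' pooled. Multi-trait models stack the traits; residuals of traits from
#' the same bird-day-hour record correlate.
#'
#' @param phenotypes tibble with columns `wingtag`, `pen`, `day`, `hour`
#'   and one column per trait (missing trait values drop that record for
#'   that trait only).
#' @param traits character vector of trait column names (length 1 or
#'   more).
#' @param grm GRM matrix with wingtag dimnames, or `NULL` to drop the
#'   animal term. All phenotyped individuals must be genotyped.
#' @param fixed factor columns fitted as fixed effects (single-level
#'   factors are dropped automatically).
#' @param covariates numeric columns fitted as fixed covariates (e.g. an
#'   EBV regression in cross-validation).
#' @param random random terms to include, a subset of
#'   `c("animal", "pdh", "pe")`.
#' @param residual_by `"pen_hour"` (heterogeneous residual variances) or
#'   `"single"` (homogeneous).
#' @param grm_bump value added to the GRM diagonal before inversion for
#'   numerical conditioning (default 1e-6).
#' @return an object of class `litter_design`.
#' @export
build_design <- function(phenotypes, traits, grm = NULL,
                         fixed = c("pen", "day", "hour"),
                         covariates = character(),
                         random = c("animal", "pdh", "pe"),
                         residual_by = c("pen_hour", "single"),
                         grm_bump = 1e-6) {
  residual_by <- match.arg(residual_by)
  dat <- as_tibble(phenotypes)
  need <- c("wingtag", "pen", "day", "hour", traits, covariates)
  if (!all(need %in% names(dat))) {
    abort(sprintf("phenotypes lack columns: %s",
                  paste(setdiff(need, names(dat)), collapse = ", ")))
  }
  if ("animal" %in% random) {
    if (is.null(grm)) abort("an animal term needs a GRM.")
    miss <- setdiff(unique(dat$wingtag), rownames(grm))
    if (length(miss) > 0) {
      abort(sprintf("phenotyped individuals missing from the GRM: %s",
                    paste(head(miss, 5), collapse = ", ")))
    }
  }
  dat$wingtag <- as.character(dat$wingtag)
  nt <- length(traits)
  n_units <- nrow(dat)

  # unit-level fixed design (shared across traits)
  fx <- dat[, fixed, drop = FALSE]
  fx[] <- lapply(fx, function(v) factor(v))
  keep_f <- vapply(fx, function(v) nlevels(v) > 1L, TRUE)
  rhs <- c("1", names(fx)[keep_f], covariates)
  fml <- stats::as.formula(paste("~", paste(rhs, collapse = " + ")))
  mf <- cbind(fx[, keep_f, drop = FALSE], dat[, covariates, drop = FALSE])
  if (ncol(mf) == 0L) mf <- data.frame(row.names = seq_len(n_units))
  Xu <- stats::model.matrix(fml, data = mf)

  # long format: one record per non-missing (unit, trait)
  recs <- list()
  for (t in seq_len(nt)) {
    yv <- dat[[traits[t]]]
    ok <- which(!is.na(yv))
    recs[[t]] <- tibble(unit = ok, trait = t, y = yv[ok])
  }
  long <- bind_rows(recs)
  long <- arrange(long, .data$unit, .data$trait)
  n <- nrow(long)
  if (n == 0L) abort("no non-missing records.")

  # block-diagonal fixed design per trait
  pf <- ncol(Xu)
  Xl <- matrix(0, n, pf * nt)
  for (t in seq_len(nt)) {
    sel <- long$trait == t
    Xl[sel, (t - 1) * pf + seq_len(pf)] <- Xu[long$unit[sel], , drop = FALSE]
  }
  colnames(Xl) <- as.vector(outer(colnames(Xu), traits,
                                  function(a, b) paste(b, a, sep = ":")))
  qrX <- qr(Xl)
  if (qrX$rank < ncol(Xl)) {
    abort("fixed-effect design is rank deficient; drop aliased factors.")
  }

  terms <- list()
  term_level <- list()
  if ("animal" %in% random) {
    ids <- rownames(grm)
    K <- unclass(as.matrix(grm)) + diag(grm_bump, nrow(grm))
    ch <- chol(K)
    terms$animal <- list(name = "animal", q = length(ids), levels = ids,
                         K = K, Kinv = chol2inv(ch),
                         logdetK = 2 * sum(log(diag(ch))))
    term_level$animal <- match(dat$wingtag[long$unit], ids)
  }
  if ("pdh" %in% random) {
    lab <- paste(dat$pen, dat$day, dat$hour, sep = "|")
    lv <- unique(lab)
    terms$pdh <- list(name = "pdh", q = length(lv), levels = lv,
                      K = NULL, Kinv = NULL, logdetK = 0)
    term_level$pdh <- match(lab[long$unit], lv)
  }
  if ("pe" %in% random) {
    lv <- unique(dat$wingtag)
    terms$pe <- list(name = "pe", q = length(lv), levels = lv,
                     K = NULL, Kinv = NULL, logdetK = 0)
    term_level$pe <- match(dat$wingtag[long$unit], lv)
  }
  if (length(terms) == 0L) abort("at least one random term is required.")

  # residual grouping (constant within unit)
  if (residual_by == "pen_hour") {
    glab <- paste(dat$pen, dat$hour, sep = "|")
  } else {
    glab <- rep("all", n_units)
  }
  glv <- unique(glab)
  rgroup <- match(glab[long$unit], glv)

  # sparse stacked design
  Xsp <- methods::as(Matrix::Matrix(Xl, sparse = TRUE), "CsparseMatrix")
  blocks <- list(Xsp)
  col_off <- ncol(Xl)
  for (nm in names(terms)) {
    q <- terms[[nm]]$q
    j <- (long$trait - 1L) * q + term_level[[nm]]
    Z <- Matrix::sparseMatrix(i = seq_len(n), j = j, x = 1,
                              dims = c(n, q * nt))
    terms[[nm]]$cols <- col_off + seq_len(q * nt)
    col_off <- col_off + q * nt
    blocks[[length(blocks) + 1L]] <- Z
  }
  M <- do.call(cbind, blocks)

  # unit bookkeeping for multi-trait residual blocks
  unit_ids <- sort(unique(long$unit))
  unit_compact <- match(long$unit, unit_ids)
  ord <- order(unit_compact, long$trait)
  sizes <- as.integer(table(unit_compact))
  u_rgroup <- rgroup[match(seq_along(unit_ids), unit_compact)]
  u_pattern <- as.integer(tapply(bitwShiftL(1L, long$trait - 1L),
                                 unit_compact, sum))
  # record pairs within unit (i <= j) for residual directions
  pair_i <- list(); pair_j <- list()
  pos <- 0L
  for (k in seq_along(sizes)) {
    m <- sizes[k]
    rows <- ord[pos + seq_len(m)]
    pos <- pos + m
    cmb <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
    pair_i[[k]] <- rows[cmb[, 1]]
    pair_j[[k]] <- rows[cmb[, 2]]
  }
  pi_ <- unlist(pair_i); pj_ <- unlist(pair_j)
  resid_pairs <- tibble(
    i = pi_, j = pj_,
    ti = long$trait[pi_], tj = long$trait[pj_],
    rgroup = rgroup[pi_]
  )
  unit_patterns <- tibble(rgroup = u_rgroup, pattern = u_pattern) |>
    count(.data$rgroup, .data$pattern, name = "n_units")

  structure(
    list(
      y = long$y, M = M, X_names = colnames(Xl), p_fixed = ncol(Xl),
      trait = long$trait, traits = traits,
      unit = unit_compact, rgroup = rgroup, rgroup_labels = glv,
      terms = terms, term_level = term_level,
      resid_pairs = resid_pairs, unit_patterns = unit_patterns,
      unit_order = ord, unit_sizes = sizes, unit_rgroup = u_rgroup,
      unit_pattern_vec = u_pattern,
      unit_wingtag = dat$wingtag, unit_meta = dat[, c("wingtag", "pen", "day", "hour")],
      residual_by = residual_by, n_records = n
    ),
    class = "litter_design"
  )
}

#' @export
print.litter_design <- function(x, ...) {
  cat(sprintf("<litter_design> %d records, %d trait(s), terms: %s; %d residual group(s)\n",
              x$n_records, length(x$traits),
              paste(names(x$terms), collapse = ", "),
              length(x$rgroup_labels)))
  invisible(x)
}

# default start values and constraint template for a design
default_varcomps <- function(design, start_frac = c(animal = 0.1, pdh = 0.1,
                                                    pe = 0.2)) {
  nt <- length(design$traits)
  vy <- vapply(seq_len(nt), function(t) {
    v <- var(design$y[design$trait == t])
    if (!is.finite(v) || v <= 0) 1e-6 else v
  }, 0)
  terms <- lapply(design$terms, function(tm) {
    diag(vy * (start_frac[[tm$name]] %||% 0.1), nt)
  })
  names(terms) <- names(design$terms)
  resid <- lapply(design$rgroup_labels, function(g) diag(vy * 0.5, nt))
  names(resid) <- design$rgroup_labels
  zero <- matrix(FALSE, nt, nt)
  zval <- matrix(0, nt, nt)
  list(nt = nt, terms = terms, resid = resid,
       fixed_terms = lapply(terms, function(x) zero),
       resid_fixed_values = lapply(resid, function(x) zval),
       terms_fixed_values = lapply(terms, function(x) zval),
       fixed_resid = lapply(resid, function(x) zero))
}

# package engine output into the exported fit object
make_fit <- function(design, res, model_label) {
  vc <- res$vc
  nt <- vc$nt
  traits <- design$traits
  ptab <- res$ptab
  est <- vc_flatten(vc)
  comp <- ptab |>
    mutate(
      estimate = est,
      se = res$se,
      trait_1 = traits[.data$row],
      trait_2 = traits[.data$col],
      fixed = !res$free_mask,
      component = ifelse(.data$block == "term", .data$name,
                         paste0("residual[", .data$name, "]"))
    ) |>
    select("component", "trait_1", "trait_2", "estimate", "se", "fixed")

  # fixed-effect solutions
  fixef <- tibble(term = design$X_names,
                  estimate = res$ev$sol[seq_len(design$p_fixed)])

  # EBVs from the animal block
  ebv <- NULL
  if ("animal" %in% names(design$terms)) {
    tm <- design$terms$animal
    idx <- tm$cols
    sol <- res$ev$sol[idx]
    pev <- diag(res$ev$Cinv)[idx]
    sig_a <- diag(vc$terms$animal)
    ebv <- bind_rows(lapply(seq_len(nt), function(t) {
      sel <- (t - 1) * tm$q + seq_len(tm$q)
      se_i <- sqrt(pmax(pev[sel], 0))
      tibble(
        wingtag = tm$levels, trait = traits[t],
        ebv = sol[sel], se = se_i,
        reliability = 1 - se_i^2 / sig_a[t]
      )
    }))
  }

  structure(
    list(
      model = model_label, traits = traits,
      varcomps = comp, fixef = fixef, ebv = ebv,
      loglik = res$loglik, converged = res$converged,
      n_iterations = res$n_iterations, trace = res$trace,
      n_records = design$n_records,
      residual_by = design$residual_by,
      vc = vc, design = design, par_cov = res$par_cov,
      free_mask = res$free_mask, ptab = res$ptab
    ),
    class = "litter_fit"
  )
}

#' Univariate AI-REML fit of the hourly animal model
#'
#' Estimates the additive-genetic, pen-day-hour, permanent-environment
#' and per-pen-hour residual variances of one trait by average-
#' information REML, with EM fallback steps and non-negativity enforced
#' by projection. Standard errors come from the inverse
#' average-information matrix; breeding values and their prediction-error
#' standard errors from the mixed-model equations at convergence.
#'
#' @param phenotypes hourly phenotype tibble (see [build_design()]).
#' @param trait trait column to analyse.
#' @param grm GRM with wingtag dimnames.
#' @param residual_by `"pen_hour"` (default) or `"single"`.
#' @param start optional named list of start values
#'   (`animal`, `pdh`, `pe`, `resid` scalars).
#' @param max_iter,tol_loglik,tol_par convergence controls.
#' @param verbose print the iteration trail.
#' @param ... passed to [build_design()].
#' @return a `litter_fit` object; see [tidy.litter_fit()].
#' @export
reml_univariate <- function(phenotypes, trait, grm,
                            residual_by = c("pen_hour", "single"),
                            start = NULL, max_iter = 200,
                            tol_loglik = 1e-8, tol_par = 1e-6,
                            verbose = FALSE, ...) {
  residual_by <- match.arg(residual_by)
  design <- build_design(phenotypes, traits = trait, grm = grm,
                         residual_by = residual_by, ...)
  vc0 <- default_varcomps(design)
  if (!is.null(start)) {
    for (nm in intersect(names(start), names(vc0$terms))) {
      vc0$terms[[nm]][1, 1] <- start[[nm]]
    }
    if (!is.null(start$resid)) {
      for (g in seq_along(vc0$resid)) vc0$resid[[g]][1, 1] <- start$resid
    }
  }
  res <- reml_engine(design, vc0, max_iter = max_iter,
                     tol_loglik = tol_loglik, tol_par = tol_par,
                     verbose = verbose)
  make_fit(design, res, model_label = paste0("univariate:", trait))
}

#' Constrained trivariate AI-REML fit
#'
#' Two-stage protocol for the three hourly traits. Stage 1 fits the
#' trivariate model with unstructured genetic, pen-day-hour and
#' permanent-environment covariance matrices and a homogeneous (single
#' group) unstructured residual covariance — the heterogeneous pen-hour
#' residual is dropped in the multi-trait model. Because the two
#' continuous traits are only observed when the binary trait is 1, the
#' data carry no information on residual covariances with the binary
#' trait; stage 2 therefore refits with the residual variances fixed at
#' their stage-1 estimates, the residual covariance between the two
#' continuous traits fixed at its stage-1 estimate, and the residual
#' covariances involving the binary trait fixed to zero, re-estimating
#' all other components.
#'
#' @param phenotypes hourly phenotype tibble.
#' @param traits the three trait columns; the first is the binary
#'   detection trait whose residual covariances are zeroed.
#' @param grm GRM with wingtag dimnames.
#' @param max_iter,tol_loglik,tol_par convergence controls.
#' @param verbose print iteration trails.
#' @param ... passed to [build_design()].
#' @return a `litter_fit` with the stage-1 fit attached as `$stage1`.
#' @export
reml_trivariate <- function(phenotypes, traits = c("dh01", "mdh", "wsh"),
                            grm, max_iter = 200, tol_loglik = 1e-8,
                            tol_par = 1e-6, verbose = FALSE, ...) {
  if (length(traits) != 3L) abort("exactly three traits are required.")
  design <- build_design(phenotypes, traits = traits, grm = grm,
                         residual_by = "single", ...)
  vc0 <- default_varcomps(design)
  res1 <- reml_engine(design, vc0, max_iter = max_iter,
                      tol_loglik = tol_loglik, tol_par = tol_par,
                      verbose = verbose)
  if (!res1$converged) {
    warn("stage-1 trivariate fit did not converge; stage-2 constraints use its final values.")
  }
  fit1 <- make_fit(design, res1, model_label = "trivariate:stage1")

  vc2 <- res1$vc
  Re <- vc2$resid[[1]]
  fixed <- matrix(FALSE, 3, 3)
  fixedval <- matrix(0, 3, 3)
  diag(fixed) <- TRUE
  diag(fixedval) <- diag(Re)
  fixed[2, 3] <- fixed[3, 2] <- TRUE
  fixedval[2, 3] <- fixedval[3, 2] <- Re[2, 3]
  fixed[1, 2] <- fixed[2, 1] <- fixed[1, 3] <- fixed[3, 1] <- TRUE
  # covariances with the binary trait fixed to zero
  Re2 <- fixedval
  vc2$resid[[1]] <- Re2
  vc2$fixed_resid[[1]] <- fixed
  vc2$resid_fixed_values[[1]] <- fixedval
  res2 <- reml_engine(design, vc2, max_iter = max_iter,
                      tol_loglik = tol_loglik, tol_par = tol_par,
                      verbose = verbose)
  fit <- make_fit(design, res2, model_label = "trivariate:constrained")
  fit$stage1 <- fit1
  fit
}

#' Likelihood-ratio test for additive genetic variance
#'
#' Compares the full model with a reduced model in which the animal term
#' is removed (additive variance fixed at zero). The statistic is twice
#' the difference in restricted log-likelihoods; because the null value
#' lies on the boundary of the parameter space, the p-value uses the
#' 50:50 mixture of a point mass at zero and a chi-square with one
#' degree of freedom (a plain chi-square(1) reference is available via
#' `mixture = FALSE`).
#'
#' @param phenotypes hourly phenotype tibble.
#' @param trait trait column.
#' @param grm GRM.
#' @param mixture use the boundary mixture reference (default TRUE).
#' @param ... passed to [reml_univariate()].
#' @return tibble with `statistic`, `p_value`, `loglik_full`,
#'   `loglik_reduced` and the full fit as attribute `"fit"`.
#' @export
lrt_genetic_variance <- function(phenotypes, trait, grm, mixture = TRUE, ...) {
  full <- reml_univariate(phenotypes, trait, grm, ...)
  red <- reml_univariate(phenotypes, trait, grm = NULL,
                         random = c("pdh", "pe"), ...)
  stat <- 2 * (full$loglik - red$loglik)
  if (stat < 0 && stat > -1e-6) stat <- 0
  if (stat < 0) warn("reduced model log-likelihood exceeds the full model; numerical failure.")
  p <- if (stat <= 0) 1 else {
    tailp <- pchisq(stat, df = 1, lower.tail = FALSE)
    if (mixture) 0.5 * tailp else tailp
  }
  out <- tibble(statistic = stat, p_value = p,
                loglik_full = full$loglik, loglik_reduced = red$loglik)
  attr(out, "fit") <- full
  out
}

#' BLUP at fixed variance components
#'
#' Solves the mixed-model equations once at supplied variance components
#' (no re-estimation), as used in cross-validation where the training
#' components are frozen. Individuals present in the GRM but without
#' records receive breeding values through their genomic relationships;
#' with an identity relationship matrix such individuals get an EBV of
#' exactly zero.
#'
#' @param phenotypes hourly phenotype tibble (possibly with some pens'
#'   records removed).
#' @param traits trait column(s).
#' @param grm GRM.
#' @param varcomps a `litter_fit` (its components are reused) or an
#'   engine varcomp list.
#' @param ... passed to [build_design()].
#' @return a `litter_fit`-like object (no iterations; `converged = TRUE`)
#'   with the EBV table in `$ebv`.
#' @export
blup_fixed_varcomps <- function(phenotypes, traits, grm, varcomps, ...) {
  vc_in <- if (inherits(varcomps, "litter_fit")) varcomps$vc else varcomps
  design <- build_design(phenotypes, traits = traits, grm = grm,
                         residual_by = if (length(vc_in$resid) > 1L ||
                                           !identical(names(vc_in$resid), "all"))
                           "pen_hour" else "single", ...)
  vc <- default_varcomps(design)
  for (nm in names(vc$terms)) {
    if (!nm %in% names(vc_in$terms)) {
      abort(sprintf("varcomps lack a value for term '%s'.", nm))
    }
    vc$terms[[nm]] <- vc_in$terms[[nm]]
  }
  for (g in seq_along(vc$resid)) {
    lab <- names(vc$resid)[g]
    src <- vc_in$resid[[lab]]
    if (is.null(src)) {
      abort(sprintf("varcomps lack a residual group '%s'.", lab))
    }
    vc$resid[[g]] <- src
  }
  ev <- mme_eval(design, vc)
  res <- list(vc = vc, ev = ev, loglik = ev$loglik, converged = TRUE,
              n_iterations = 0L,
              trace = tibble(iter = 0L, loglik = ev$loglik, step = "blup"),
              se = rep(NA_real_, length(vc_flatten(vc))),
              par_cov = NULL,
              free_mask = rep(FALSE, length(vc_flatten(vc))),
              ptab = vc_param_table(vc))
  make_fit(design, res, model_label = "blup")
}

#' Model-based (reported) EBV accuracy
#'
#' Averages, over individuals, the square root of
#' `(sigma2_a - SE_i^2) / sigma2_a`, where `SE_i` is the prediction-error
#' standard error of individual i's EBV. Negative radicands (individuals
#' whose PEV exceeds the genetic variance) are clipped to zero and
#' counted in a message.
#'
#' @param ebv_table tibble with columns `ebv` and `se` (one trait).
#' @param sigma2_a estimated additive genetic variance (> 0).
#' @return scalar mean reported accuracy.
#' @export
reported_accuracy <- function(ebv_table, sigma2_a) {
  if (sigma2_a <= 0) abort("`sigma2_a` must be positive.")
  rad <- (sigma2_a - ebv_table$se^2) / sigma2_a
  n_neg <- sum(rad < 0)
  if (n_neg > 0) {
    inform(sprintf("%d individual(s) with PEV above the genetic variance; accuracy clipped at 0.", n_neg))
  }
  mean(sqrt(pmax(rad, 0)))
}

#' Genetic correlations from a multi-trait fit
#'
#' Correlations derived from the additive covariance matrix, with
#' delta-method standard errors from the inverse average-information
#' matrix.
#'
#' @param fit a multi-trait `litter_fit`.
#' @return tibble with `trait_1`, `trait_2`, `correlation`, `se`.
#' @export
genetic_correlations <- function(fit) {
  stopifnot(inherits(fit, "litter_fit"))
  S <- fit$vc$terms$animal
  nt <- nrow(S)
  if (nt < 2L) abort("genetic correlations need a multi-trait fit.")
  ptab <- fit$ptab
  free_idx <- which(fit$free_mask)
  out <- list()
  for (r in 1:(nt - 1)) for (s in (r + 1):nt) {
    rho <- S[r, s] / sqrt(S[r, r] * S[s, s])
    se <- NA_real_
    if (!is.null(fit$par_cov)) {
      # locate the three Sigma_a parameters in the free-parameter vector
      loc <- function(a, b) {
        k <- which(ptab$block == "term" & ptab$name == "animal" &
                     ptab$row == min(a, b) & ptab$col == max(a, b))
        match(k, free_idx)
      }
      ii <- c(loc(r, r), loc(r, s), loc(s, s))
      if (!anyNA(ii)) {
        g <- c(-0.5 * rho / S[r, r], 1 / sqrt(S[r, r] * S[s, s]),
               -0.5 * rho / S[s, s])
        v <- as.numeric(t(g) %*% fit$par_cov[ii, ii] %*% g)
        se <- sqrt(max(v, 0))
      }
    }
    out[[length(out) + 1L]] <- tibble(
      trait_1 = fit$traits[r], trait_2 = fit$traits[s],
      correlation = rho, se = se
    )
  }
  bind_rows(out)
}
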