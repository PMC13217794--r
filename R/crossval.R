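# Leave-one-pen-out cross-validation of breeding-value accuracy.

#' Leave-one-pen-out breeding values
#'
#' For each pen in turn, removes that pen's phenotypes, solves BLUP with
#' all variance parameters fixed at the supplied (training) estimates,
#' and collects the masked individuals' EBVs ("EBVs from masked
#' phenotypes", EBVMP) together with their reported reliabilities from
#' the masked solve. Masked individuals receive information only through
#' their genomic relationships with the other pens, so with an identity
#' relationship matrix their EBVMP is exactly zero.
#'
#' @param phenotypes hourly phenotype tibble.
#' @param traits trait column(s).
#' @param grm GRM covering all individuals.
#' @param varcomps a fitted `litter_fit` (full-data fit) whose variance
#'   components are frozen, or an engine varcomp list.
#' @param pens pens to mask (default: all pens in the data).
#' @param ... passed to [build_design()] via [blup_fixed_varcomps()].
#' @return tibble with one row per masked individual x trait: `pen`,
#'   `wingtag`, `trait`, `ebvmp`, `se`, `reliability`,
#'   `reported_accuracy` (sqrt of clipped reliability).
#' @export
leave_one_pen_out <- function(phenotypes, traits, grm, varcomps,
                              pens = NULL, ...) {
  dat <- as_tibble(phenotypes)
  all_pens <- unique(dat$pen)
  if (length(all_pens) < 2L) abort("need at least two pens to cross-validate.")
  if (is.null(pens)) pens <- all_pens
  if (!all(pens %in% all_pens)) {
    abort(sprintf("pen(s) absent from the data: %s",
                  paste(setdiff(pens, all_pens), collapse = ", ")))
  }
  pen_of <- dat |> distinct(.data$wingtag, .data$pen)
  folds <- lapply(pens, function(p) {
    train <- dat[dat$pen != p, ]
    fit <- blup_fixed_varcomps(train, traits = traits, grm = grm,
                               varcomps = varcomps, ...)
    masked_ids <- pen_of$wingtag[pen_of$pen == p]
    ebv <- fit$ebv[fit$ebv$wingtag %in% masked_ids, ]
    ebv$pen <- p
    ebv
  })
  out <- bind_rows(folds) |>
    rename(ebvmp = "ebv") |>
    mutate(reported_accuracy = sqrt(pmax(.data$reliability, 0)))
  out[, c("pen", "wingtag", "trait", "ebvmp", "se", "reliability",
          "reported_accuracy")]
}

#' Validation regression of phenotypes on masked EBVs
#'
#' Fits, by REML, the model `y = pen + hour + day + beta * EBVMP + pdh +
#' pe + e` on the pooled masked-pen records: the animal term is replaced
#' by a fixed regression on the masked-phenotype EBVs, and the
#' pen-day-hour, permanent-environment and (pen-hour grouped) residual
#' variances are re-estimated. A slope of 1 indicates correctly
#' dispersed EBVs, below 1 overdispersion, above 1 underdispersion.
#'
#' @param phenotypes phenotype tibble (all pens; records are matched to
#'   `ebvmp` by wingtag).
#' @param ebvmp output of [leave_one_pen_out()] for one trait, or any
#'   tibble with `wingtag` and `ebvmp`.
#' @param trait trait column to validate.
#' @param residual_by `"pen_hour"` (default) or `"single"`.
#' @param ... passed to [reml_univariate()].
#' @return list with `beta_hat`, `se`, the validation variance
#'   components (`sigma2_c`, `sigma2_d`, `mean_sigma2_e`), `var_ebvmp`
#'   (variance of EBVMP among phenotyped masked individuals) and the
#'   underlying `fit`.
#' @export
validation_regression <- function(phenotypes, ebvmp, trait,
                                  residual_by = "pen_hour", ...) {
  dat <- as_tibble(phenotypes)
  eb <- as_tibble(ebvmp)
  if ("trait" %in% names(eb)) eb <- eb[eb$trait == trait, ]
  eb <- distinct(eb[, c("wingtag", "ebvmp")])
  dat <- inner_join(dat, eb, by = "wingtag")
  dat <- dat[!is.na(dat[[trait]]), ]
  if (nrow(dat) == 0L) abort("no phenotyped records with an EBVMP.")
  ids <- distinct(dat[, c("wingtag", "ebvmp")])
  v_eb <- var(ids$ebvmp)
  v_y <- var(dat[[trait]])
  if (!is.finite(v_eb) || v_eb <= 1e-8 * v_y) {
    abort("EBVMP variance is (numerically) zero among phenotyped individuals; slope unidentifiable.")
  }
  fit <- reml_univariate(dat, trait = trait, grm = NULL,
                         residual_by = residual_by,
                         covariates = "ebvmp",
                         random = c("pdh", "pe"), ...)
  bn <- paste0(trait, ":ebvmp")
  beta <- fit$fixef$estimate[fit$fixef$term == bn]
  se <- fixef_se(fit, bn)
  cm <- fit_components(fit, trait)
  list(beta_hat = beta, se = se,
       sigma2_c = cm$sigma2_c, sigma2_d = cm$sigma2_d,
       mean_sigma2_e = cm$mean_sigma2_e,
       var_ebvmp = v_eb, fit = fit)
}

# SE of one fixed effect from the final MME inverse
fixef_se <- function(fit, term) {
  i <- match(term, fit$design$X_names)
  if (is.na(i)) abort(sprintf("no fixed effect '%s'.", term))
  ev <- mme_eval(fit$design, fit$vc)
  sqrt(diag(ev$Cinv)[i])
}

#' Cross-validated accuracy of masked-phenotype EBVs
#'
#' The correlation between EBVMP and fixed-effect-corrected phenotypes,
#' expressed on the accuracy scale by dividing by the square root of the
#' (hourly) heritability:
#' `sqrt(beta^2 var(EBVMP) / (beta^2 var(EBVMP) + sigma2_c + sigma2_d +
#' mean sigma2_e)) / h`. Values above 1 are reported as computed with a
#' warning rather than clipped.
#'
#' @param beta_hat validation regression slope.
#' @param var_ebvmp variance of the masked-pen EBVs.
#' @param sigma2_c,sigma2_d,mean_sigma2_e validation-model variance
#'   components.
#' @param h2 (hourly) heritability of the trait from the full-data fit.
#' @return scalar accuracy.
#' @export
crossval_accuracy <- function(beta_hat, var_ebvmp, sigma2_c, sigma2_d,
                              mean_sigma2_e, h2) {
  if (h2 <= 0) abort("`h2` must be positive.")
  check_nonneg(var_ebvmp, sigma2_c, sigma2_d, mean_sigma2_e)
  expl <- beta_hat^2 * var_ebvmp
  den <- expl + sigma2_c + sigma2_d + mean_sigma2_e
  acc <- if (den <= 0) 0 else sqrt(expl / den) / sqrt(h2)
  if (is.finite(acc) && acc > 1) {
    warn(sprintf("cross-validated accuracy %.3f exceeds 1 (kept as computed).", acc))
  }
  acc
}

#' Full leave-one-pen-out validation summary for one trait
#'
#' Runs the complete protocol: masked-pen EBVs at frozen components, the
#' pooled validation regression, and the accuracy comparison against the
#' mean reported accuracy of the EBVMP.
#'
#' @param phenotypes phenotype tibble.
#' @param trait trait column.
#' @param grm GRM.
#' @param fit full-data `litter_fit` for the trait (source of the frozen
#'   components and of the heritability used in the accuracy).
#' @param h2 heritability used in the denominator; defaults to the
#'   hourly heritability of `fit`.
#' @param ... passed to the underlying solvers.
#' @return one-row tibble: `trait`, `beta_hat`, `beta_se`,
#'   `validation_accuracy`, `reported_accuracy`, `var_ebvmp`.
#' @export
crossval_summary <- function(phenotypes, trait, grm, fit, h2 = NULL, ...) {
  cm <- fit_components(fit, trait)
  if (is.null(h2)) {
    h2 <- heritability_hour(cm$sigma2_a, cm$sigma2_c, cm$sigma2_d,
                            cm$mean_sigma2_e)
  }
  emp <- leave_one_pen_out(phenotypes, traits = fit$traits, grm = grm,
                           varcomps = fit, ...)
  emp_tr <- emp[emp$trait == trait, ]
  vr <- validation_regression(phenotypes, emp_tr, trait = trait)
  acc <- crossval_accuracy(vr$beta_hat, vr$var_ebvmp, vr$sigma2_c,
                           vr$sigma2_d, vr$mean_sigma2_e, h2)
  tibble(
    trait = trait,
    beta_hat = vr$beta_hat, beta_se = vr$se,
    validation_accuracy = acc,
    reported_accuracy = mean(emp_tr$reported_accuracy),
    var_ebvmp = vr$var_ebvmp
  )
}
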