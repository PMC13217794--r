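#' @export
print.litter_fit <- function(x, ...) {
  cat(sprintf("<litter_fit> %s | %d records | logL = %.4f | %s in %d iterations\n",
              x$model, x$n_records, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  comp <- x$varcomps |> filter(.data$trait_1 == .data$trait_2)
  print(as.data.frame(head(comp, 12)), row.names = FALSE)
  invisible(x)
}

#' Tidy a REML fit
#'
#' One row per variance/covariance parameter: the random term or
#' residual group, the trait pair, the estimate, its standard error from
#' the inverse average-information matrix, and whether the parameter was
#' held fixed by a constraint.
#'
#' @param x a `litter_fit`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy litter_fit
#' @export
tidy.litter_fit <- function(x, ...) {
  x$varcomps
}

#' One-line summary of a REML fit
#'
#' @param x a `litter_fit`.
#' @param ... unused.
#' @return tibble with the log-likelihood, convergence flag, iteration
#'   count, record count and number of free parameters.
#' @method glance litter_fit
#' @export
glance.litter_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik,
    converged = x$converged,
    n_iterations = x$n_iterations,
    n_records = x$n_records,
    n_parameters = sum(x$free_mask)
  )
}

#' Plot variance components of a fit
#'
#' Bar chart of the estimated variance components per trait, residual
#' groups averaged, with +/- 1 SE error bars where available.
#'
#' @param object a `litter_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot litter_fit
#' @export
autoplot.litter_fit <- function(object, ...) {
  comp <- object$varcomps |>
    filter(.data$trait_1 == .data$trait_2) |>
    mutate(component = ifelse(grepl("^residual", .data$component),
                              "residual (mean)", .data$component)) |>
    group_by(.data$component, trait = .data$trait_1) |>
    summarise(estimate = mean(.data$estimate),
              se = mean(.data$se), .groups = "drop")
  ggplot2::ggplot(comp, ggplot2::aes(.data$component, .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - .data$se,
                                        ymax = .data$estimate + .data$se),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "variance") +
    ggplot2::theme_minimal()
}

# convenience extractors used across modules -------------------------------

# scalar components of a univariate fit as a named list
fit_components <- function(fit, trait = fit$traits[1]) {
  comp <- fit$varcomps
  pick <- function(name) {
    v <- comp$estimate[comp$component == name &
                         comp$trait_1 == trait & comp$trait_2 == trait]
    if (length(v) == 0) NA_real_ else v
  }
  resid <- comp |>
    filter(grepl("^residual", .data$component),
           .data$trait_1 == trait, .data$trait_2 == trait)
  list(
    sigma2_a = pick("animal"),
    sigma2_c = pick("pdh"),
    sigma2_d = pick("pe"),
    mean_sigma2_e = mean(resid$estimate),
    resid_by_group = setNames(resid$estimate,
                              gsub("^residual\\[|\\]$", "", resid$component))
  )
}

#' Mean residual variance of a fit, with standard error
#'
#' The unweighted mean of the per-pen-hour residual variances, as used in
#' the phenotypic-variance denominator, together with its standard error
#' from the inverse average-information matrix (linear combination of the
#' residual parameters).
#'
#' @param fit a univariate `litter_fit`.
#' @return tibble with `estimate` and `se`.
#' @export
mean_residual_variance <- function(fit) {
  stopifnot(inherits(fit, "litter_fit"))
  ptab <- fit$ptab
  idx <- which(ptab$block == "resid" & ptab$row == 1 & ptab$col == 1)
  est <- vc_flatten(fit$vc)[idx]
  se <- NA_real_
  if (!is.null(fit$par_cov)) {
    fpos <- match(idx, which(fit$free_mask))
    if (!anyNA(fpos)) {
      w <- rep(1 / length(idx), length(idx))
      se <- sqrt(max(drop(t(w) %*% fit$par_cov[fpos, fpos] %*% w), 0))
    }
  }
  tibble(estimate = mean(est), se = se)
}
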