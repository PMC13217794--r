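# Genetic-parameter summaries computed from fitted variance components.
# All functions are pure arithmetic on the component estimates; rounding
# is left to report time.

#' Hourly heritability
#'
#' Additive genetic variance over the total phenotypic variance of an
#' hourly record, where the phenotypic variance is the sum of all
#' modelled random components: additive, pen-day-hour, permanent
#' environment and the residual variance averaged (unweighted) over the
#' pen-hour groups.
#'
#' @param sigma2_a,sigma2_c,sigma2_d,mean_sigma2_e non-negative variance
#'   components.
#' @return scalar heritability.
#' @examples
#' heritability_hour(0.67, 0.51, 2.26, 8.56)  # ~0.06
#' @export
heritability_hour <- function(sigma2_a, sigma2_c, sigma2_d, mean_sigma2_e) {
  check_nonneg(sigma2_a, sigma2_c, sigma2_d, mean_sigma2_e)
  den <- sigma2_a + sigma2_c + sigma2_d + mean_sigma2_e
  if (den <= 0) abort("phenotypic variance is zero.")
  sigma2_a / den
}

#' Daily heritability
#'
#' Heritability of the mean performance over the recorded hours of a
#' day. Genetic and permanent-environment variances are unchanged by
#' averaging; the transient pen-day-hour and residual variances shrink
#' by the average number of recorded hours per pen-day.
#'
#' @inheritParams heritability_hour
#' @param n_hours average number of recorded hours per pen-day (> 0);
#'   10.5 in the study design this package emulates.
#' @return scalar heritability.
#' @examples
#' heritability_day(0.67, 0.51, 2.26, 8.56, n_hours = 10.5)  # ~0.18
#' @export
heritability_day <- function(sigma2_a, sigma2_c, sigma2_d, mean_sigma2_e,
                             n_hours) {
  check_nonneg(sigma2_a, sigma2_c, sigma2_d, mean_sigma2_e)
  if (n_hours <= 0) abort("`n_hours` must be positive.")
  den <- sigma2_a + sigma2_c / n_hours + sigma2_d + mean_sigma2_e / n_hours
  if (den <= 0) abort("phenotypic variance is zero.")
  sigma2_a / den
}

#' Coefficient of genetic variation
#'
#' Additive genetic standard deviation divided by the population mean of
#' the trait, both on the analysed (transformed) scale.
#'
#' @param sigma2_a additive genetic variance (>= 0).
#' @param mean_phenotype population mean (non-zero).
#' @return scalar GCV.
#' @examples
#' gcv(0.11, 2.7)  # ~0.12
#' @export
gcv <- function(sigma2_a, mean_phenotype) {
  check_nonneg(sigma2_a)
  if (mean_phenotype == 0) abort("population mean is zero.")
  sqrt(sigma2_a) / mean_phenotype
}

#' Repeatability
#'
#' Proportion of phenotypic variance attributable to the individual:
#' `(sigma2_a + sigma2_d) / sigma2_P`.
#'
#' @param sigma2_a,sigma2_d additive and permanent-environment variances.
#' @param sigma2_P phenotypic variance (> 0).
#' @return scalar repeatability.
#' @examples
#' repeatability(0.67, 2.26, 12.00)  # ~0.24
#' @export
repeatability <- function(sigma2_a, sigma2_d, sigma2_P) {
  check_nonneg(sigma2_a, sigma2_d)
  if (sigma2_P <= 0) abort("`sigma2_P` must be positive.")
  (sigma2_a + sigma2_d) / sigma2_P
}

check_nonneg <- function(...) {
  v <- c(...)
  if (any(!is.finite(v)) || any(v < 0)) {
    abort("variance components must be finite and non-negative.")
  }
  invisible(TRUE)
}

#' Genetic-parameter summary of a univariate fit
#'
#' Assembles the per-trait summary: variance components, phenotypic
#' variance, hourly and daily heritability, repeatability, GCV and the
#' mean reported EBV accuracy. The hours divisor defaults to the mean
#' number of recorded hours per pen-day computed from the data.
#'
#' @param fit a univariate `litter_fit`.
#' @param phenotypes the phenotype tibble used for the fit (for the
#'   trait mean and the hours divisor).
#' @param n_hours hours divisor for the daily heritability; `NULL`
#'   computes the mean recorded hours per pen-day from `phenotypes`.
#' @return one-row tibble.
#' @export
genetic_parameters <- function(fit, phenotypes, n_hours = NULL) {
  stopifnot(inherits(fit, "litter_fit"))
  trait <- fit$traits[1]
  cm <- fit_components(fit, trait)
  dat <- as_tibble(phenotypes)
  if (is.null(n_hours)) {
    ph <- dat |> distinct(.data$pen, .data$day, .data$hour) |>
      count(.data$pen, .data$day)
    n_hours <- mean(ph$n)
  }
  mean_ph <- mean(dat[[trait]], na.rm = TRUE)
  sigma2_P <- cm$sigma2_a + cm$sigma2_c + cm$sigma2_d + cm$mean_sigma2_e
  acc <- if (!is.null(fit$ebv) && cm$sigma2_a > 0) {
    reported_accuracy(fit$ebv[fit$ebv$trait == trait, ], cm$sigma2_a)
  } else {
    NA_real_
  }
  tibble(
    trait = trait,
    mean_phenotype = mean_ph,
    sigma2_a = cm$sigma2_a, sigma2_c = cm$sigma2_c, sigma2_d = cm$sigma2_d,
    mean_sigma2_e = cm$mean_sigma2_e, sigma2_P = sigma2_P,
    h2_hour = heritability_hour(cm$sigma2_a, cm$sigma2_c, cm$sigma2_d,
                                cm$mean_sigma2_e),
    h2_day = heritability_day(cm$sigma2_a, cm$sigma2_c, cm$sigma2_d,
                              cm$mean_sigma2_e, n_hours),
    repeatability = repeatability(cm$sigma2_a, cm$sigma2_d, sigma2_P),
    gcv = gcv(cm$sigma2_a, mean_ph),
    n_hours_divisor = n_hours,
    reported_accuracy = acc
  )
}
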