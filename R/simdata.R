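#' Simulate SNP genotypes
#'
#' Draws per-SNP allele frequencies uniformly in `maf_range` and genotypes
#' as independent binomial(2, p) allele counts across individuals, i.e. a
#' population in Hardy-Weinberg equilibrium with unlinked markers. SNP
#' metadata assigns markers round-robin to chromosomes so the autosome
#' filter in [snp_qc()] is exercisable; a fraction of SNPs can be placed
#' on the sex chromosome.
#'
#' @param n_individuals,n_snps counts (individuals >= 2, SNPs >= 1).
#' @param maf_range numeric length-2 interval within (0, 0.5].
#' @param seed integer seed.
#' @param prop_sex_chrom fraction of SNPs placed on chromosome "Z"
#'   (non-autosomal). Default 0.
#' @param wingtags optional individual ids; defaults to `"W0001"` style.
#' @param n_sires optional number of sires. When given, individuals are
#'   paternal half-sib offspring: each draws one gamete from a random
#'   sire (itself Hardy-Weinberg) and one from the base allele
#'   frequencies, mirroring a crossbred population produced with pooled
#'   semen. `NULL` (default) gives unrelated individuals.
#' @return list with `geno` (individuals x SNPs 0/1/2 matrix), `snp_meta`
#'   (tibble: snp, chrom, pos), `p` (the drawn allele frequencies) and
#'   `sire` (family index per individual, or `NULL`).
#' @export
simulate_genotypes <- function(n_individuals, n_snps,
                               maf_range = c(0.05, 0.5), seed = 1L,
                               prop_sex_chrom = 0, wingtags = NULL,
                               n_sires = NULL) {
  if (n_individuals < 2L) abort("need at least 2 individuals.")
  if (n_snps < 1L) abort("need at least 1 SNP.")
  maf_range <- sort(as.numeric(maf_range))
  if (length(maf_range) != 2L || maf_range[1L] <= 0 || maf_range[2L] > 0.5 ||
      maf_range[1L] > maf_range[2L]) {
    abort("`maf_range` must be a non-empty interval within (0, 0.5].")
  }
  set.seed(as.integer(seed))
  p <- runif(n_snps, maf_range[1L], maf_range[2L])
  sire <- NULL
  if (is.null(n_sires)) {
    geno <- matrix(rbinom(n_individuals * n_snps, 2L,
                          rep(p, each = n_individuals)),
                   nrow = n_individuals, ncol = n_snps)
  } else {
    if (n_sires < 1L) abort("`n_sires` must be at least 1.")
    sire_geno <- matrix(rbinom(n_sires * n_snps, 2L, rep(p, each = n_sires)),
                        nrow = n_sires, ncol = n_snps)
    sire <- sample.int(n_sires, n_individuals, replace = TRUE)
    pat <- matrix(rbinom(n_individuals * n_snps, 1L,
                         sire_geno[sire, , drop = FALSE] / 2),
                  nrow = n_individuals, ncol = n_snps)
    mat <- matrix(rbinom(n_individuals * n_snps, 1L,
                         rep(p, each = n_individuals)),
                  nrow = n_individuals, ncol = n_snps)
    geno <- pat + mat
  }
  if (is.null(wingtags)) wingtags <- sprintf("W%04d", seq_len(n_individuals))
  snp_ids <- sprintf("snp%05d", seq_len(n_snps))
  dimnames(geno) <- list(wingtags, snp_ids)
  n_sex <- round(prop_sex_chrom * n_snps)
  chrom <- as.character(rep_len(1:28, n_snps))
  if (n_sex > 0) chrom[sample.int(n_snps, n_sex)] <- "Z"
  snp_meta <- tibble(
    snp = snp_ids,
    chrom = chrom,
    pos = seq_len(n_snps) * 1000L
  )
  list(geno = geno, snp_meta = snp_meta, p = p, sire = sire)
}

# eigenvalue clipping to the PSD cone; warns when repair was needed
clip_psd <- function(S, label = "covariance matrix") {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1)) {
    warn(sprintf("%s is not positive semi-definite; negative eigenvalues clipped to 0.", label))
  }
  vals <- pmax(e$values, 0)
  S2 <- e$vectors %*% (vals * t(e$vectors))
  dimnames(S2) <- dimnames(S)
  (S2 + t(S2)) / 2
}

# matrix square root for sampling (psd input)
psd_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Ground-truth parameter set for the phenotype simulator
#'
#' Bundles the variance structure and fixed effects that the hourly
#' phenotype generator draws from. The defaults reproduce the scale of
#' the three litter-area traits (binary detection `dh01`, square-root
#' minutes detected `mdh`, square-root walking speed `wsh`): additive,
#' pen-day-hour, permanent-environment and mean residual variances of
#' (0.01, 0.11, 0.67), (0.01, 0.06, 0.51), (0.05, 0.24, 2.26) and
#' (0.16, 0.85, 8.56), genetic correlations (0.73, -0.28, -0.72) among
#' (dh01,mdh), (dh01,wsh), (mdh,wsh), and pen-hour residual variances
#' spread multiplicatively around their trait means.
#'
#' Any non-PSD user covariance is repaired by clipping negative
#' eigenvalues at zero, with a warning.
#'
#' @param design a [sim_design()].
#' @param traits trait names (defines the dimension T).
#' @param Sigma_a,Sigma_c,Sigma_d T x T covariance matrices of breeding
#'   values, pen-day-hour effects and permanent-environment effects.
#' @param resid_mean length-T mean residual variances.
#' @param resid_spread half-width of the multiplicative spread of the
#'   pen-hour residual variances around `resid_mean` (heteroskedastic
#'   residuals; 0 gives homogeneous residuals).
#' @param trait_means length-T population means (transformed scale).
#' @param fixed_sd standard deviation of the simulated pen/day/hour fixed
#'   effects.
#' @param seed integer seed (fixed effects and residual-variance map).
#' @return object of class `sim_truth`.
#' @export
sim_truth <- function(design,
                      traits = c("dh01", "mdh", "wsh"),
                      Sigma_a = NULL, Sigma_c = NULL, Sigma_d = NULL,
                      resid_mean = NULL, resid_spread = 0.3,
                      trait_means = NULL, fixed_sd = 0.05, seed = 1L) {
  nt <- length(traits)
  defaults <- default_trait_params()[match(traits, c("dh01", "mdh", "wsh")), ]
  if (is.null(Sigma_a)) {
    if (anyNA(defaults$sigma2_a)) abort("supply Sigma_a for non-default traits.")
    rg <- diag(nt)
    if (nt == 3L) {
      rg[1, 2] <- rg[2, 1] <- 0.73
      rg[1, 3] <- rg[3, 1] <- -0.28
      rg[2, 3] <- rg[3, 2] <- -0.72
    }
    sda <- sqrt(defaults$sigma2_a)
    Sigma_a <- rg * (sda %o% sda)
  }
  if (is.null(Sigma_c)) Sigma_c <- diag(defaults$sigma2_c, nt)
  if (is.null(Sigma_d)) Sigma_d <- diag(defaults$sigma2_d, nt)
  if (is.null(resid_mean)) resid_mean <- defaults$sigma2_e
  if (is.null(trait_means)) trait_means <- defaults$mean
  Sigma_a <- clip_psd(as_cov(Sigma_a, nt), "Sigma_a")
  Sigma_c <- clip_psd(as_cov(Sigma_c, nt), "Sigma_c")
  Sigma_d <- clip_psd(as_cov(Sigma_d, nt), "Sigma_d")
  stopifnot(all(resid_mean >= 0), resid_spread >= 0, resid_spread < 1)

  set.seed(as.integer(seed))
  pens <- sort(unique(design$slots$pen))
  days <- sort(unique(design$slots$day))
  hours <- sort(unique(design$slots$hour))
  fe <- function(levels) {
    m <- matrix(rnorm(length(levels) * nt, 0, fixed_sd), ncol = nt,
                dimnames = list(as.character(levels), traits))
    sweep(m, 2L, m[1L, ])  # first level is the reference (zero)
  }
  fixed_effects <- list(pen = fe(pens), day = fe(days), hour = fe(hours))

  ph <- unique(design$slots[, c("pen", "hour")])
  mult <- runif(nrow(ph), 1 - resid_spread, 1 + resid_spread)
  resid_by_pen_hour <- cbind(ph, matrix(mult %o% resid_mean, ncol = nt,
                                        dimnames = list(NULL, traits)))

  structure(
    list(
      traits = traits,
      Sigma_a = Sigma_a, Sigma_c = Sigma_c, Sigma_d = Sigma_d,
      resid_by_pen_hour = as_tibble(resid_by_pen_hour),
      trait_means = setNames(as.numeric(trait_means), traits),
      fixed_effects = fixed_effects,
      design = design
    ),
    class = "sim_truth"
  )
}

as_cov <- function(S, nt) {
  S <- as.matrix(S)
  if (nrow(S) != nt || ncol(S) != nt) abort("covariance dimension mismatch.")
  S
}

default_trait_params <- function() {
  tibble(
    trait = c("dh01", "mdh", "wsh"),
    mean = c(0.60, 2.7, 16.17),
    sigma2_a = c(0.01, 0.11, 0.67),
    sigma2_c = c(0.01, 0.06, 0.51),
    sigma2_d = c(0.05, 0.24, 2.26),
    sigma2_e = c(0.16, 0.85, 8.56)
  )
}

#' Pen / day / hour recording design and roster
#'
#' Builds the roster (which bird sits in which pen, with its within-pen
#' marker number) and the recording schedule (which pen-day-hour slots
#' were recorded). With a fractional `hours_per_day` the number of
#' recorded hours alternates between `floor` and `ceiling` across
#' pen-days so the mean matches.
#'
#' @param n_pens number of pens.
#' @param birds_per_pen hens per pen.
#' @param n_days recording days.
#' @param hours_per_day mean recorded hours per pen-day (default 10.5).
#' @param first_hour wall-clock hour of the first recorded slot.
#' @return list with `roster` (tibble: wingtag, pen, marker_id) and
#'   `slots` (tibble: pen, day, hour).
#' @export
sim_design <- function(n_pens = 10, birds_per_pen = 113, n_days = 7,
                       hours_per_day = 10.5, first_hour = 7L) {
  stopifnot(n_pens >= 1, birds_per_pen >= 1, n_days >= 1, hours_per_day >= 1)
  n <- n_pens * birds_per_pen
  roster <- tibble(
    wingtag = sprintf("W%04d", seq_len(n)),
    pen = rep(sprintf("P%02d", seq_len(n_pens)), each = birds_per_pen),
    marker_id = rep(100L + seq_len(birds_per_pen), times = n_pens)
  )
  slots <- list()
  k <- 0L
  for (p in seq_len(n_pens)) {
    for (d in seq_len(n_days)) {
      k <- k + 1L
      # spread fractional hours across pen-days so the long-run mean is exact
      nh <- round(k * hours_per_day) - round((k - 1) * hours_per_day)
      slots[[k]] <- tibble(
        pen = sprintf("P%02d", p),
        day = d,
        hour = first_hour + seq_len(nh) - 1L
      )
    }
  }
  list(roster = roster, slots = bind_rows(slots))
}

#' Simulate breeding values and permanent-environment effects
#'
#' Breeding values follow a matrix-normal distribution with row
#' covariance G (the genomic relationship matrix) and column covariance
#' `Sigma_a`, i.e. `vec(A) ~ N(0, Sigma_a %x% G)`. Permanent-environment
#' effects are i.i.d. across individuals with covariance `Sigma_d`. A
#' non-PSD G is repaired by eigenvalue clipping.
#'
#' @param grm individuals x individuals relationship matrix with ids as
#'   dimnames.
#' @param truth a [sim_truth()].
#' @param seed integer seed.
#' @return list with matrices `bv` and `pe` (individuals x traits).
#' @export
simulate_genetic_effects <- function(grm, truth, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  G <- unclass(as.matrix(grm))
  q <- nrow(G)
  nt <- length(truth$traits)
  if (q != ncol(G)) abort("GRM must be square.")
  set.seed(as.integer(seed))
  Lg <- psd_sqrt(clip_psd(G, "GRM"))
  Ra <- psd_sqrt(truth$Sigma_a)
  bv <- Lg %*% matrix(rnorm(q * nt), q, nt) %*% Ra
  pe <- matrix(rnorm(q * nt), q, nt) %*% psd_sqrt(truth$Sigma_d)
  dimnames(bv) <- dimnames(pe) <- list(rownames(G), truth$traits)
  list(bv = bv, pe = pe)
}

#' Simulate hourly phenotypes from the repeated-records animal model
#'
#' Each record for bird i in pen-day-hour slot (p, d, h) is
#' `y = mean + pen_p + day_d + hour_h + a_i + c_{pdh} + pe_i + e`,
#' with `a` the (possibly GRM-correlated) breeding values, `c` a
#' pen-day-hour common-environment effect shared by all birds in the
#' slot, `pe` the permanent-environment effect, and `e` drawn with the
#' residual (co)variance of the record's pen-hour group.
#'
#' With `censor = TRUE` the binary trait `dh01` is thresholded to {0,1}
#' at 0.5 and, whenever it is 0, the other traits of that record are set
#' missing — mimicking the missing-data pattern of the real stream where
#' traits are only defined for detected hours.
#'
#' @param truth a [sim_truth()].
#' @param effects output of [simulate_genetic_effects()] (or `NULL` to
#'   draw effects with an identity relationship matrix).
#' @param seed integer seed.
#' @param censor logical; apply the `dh01`-driven missingness mechanism.
#' @return tibble with columns wingtag, pen, day, hour and one column per
#'   trait; attribute `"truth_effects"` carries the effects used.
#' @export
simulate_hourly_phenotypes <- function(truth, effects = NULL, seed = 1L,
                                       censor = FALSE) {
  stopifnot(inherits(truth, "sim_truth"))
  design <- truth$design
  roster <- design$roster
  nt <- length(truth$traits)
  set.seed(as.integer(seed) + 1e6L)
  if (is.null(effects)) {
    q <- nrow(roster)
    bv <- matrix(rnorm(q * nt), q, nt) %*% psd_sqrt(truth$Sigma_a)
    pe <- matrix(rnorm(q * nt), q, nt) %*% psd_sqrt(truth$Sigma_d)
    dimnames(bv) <- dimnames(pe) <- list(roster$wingtag, truth$traits)
    effects <- list(bv = bv, pe = pe)
  }
  if (!all(roster$wingtag %in% rownames(effects$bv))) {
    abort("effects must cover every rostered wingtag.")
  }

  slots <- design$slots
  slots$slot_id <- seq_len(nrow(slots))
  cmat <- matrix(rnorm(nrow(slots) * nt), nrow(slots), nt) %*% psd_sqrt(truth$Sigma_c)

  rec <- inner_join(roster, slots, by = "pen", relationship = "many-to-many")
  n <- nrow(rec)
  fe <- truth$fixed_effects
  Y <- matrix(rep(truth$trait_means, each = n), n, nt)
  Y <- Y + fe$pen[as.character(rec$pen), , drop = FALSE] +
    fe$day[as.character(rec$day), , drop = FALSE] +
    fe$hour[as.character(rec$hour), , drop = FALSE]
  Y <- Y + effects$bv[rec$wingtag, , drop = FALSE] +
    effects$pe[rec$wingtag, , drop = FALSE] +
    cmat[rec$slot_id, , drop = FALSE]

  rkey <- paste(rec$pen, rec$hour)
  rbph <- truth$resid_by_pen_hour
  vkey <- paste(rbph$pen, rbph$hour)
  gi <- match(rkey, vkey)
  if (anyNA(gi)) abort("record falls in an unknown pen-hour residual group.")
  rv <- as.matrix(rbph[gi, truth$traits, drop = FALSE])
  E <- matrix(rnorm(n * nt), n, nt) * sqrt(rv)
  Y <- Y + E

  out <- tibble(
    wingtag = rec$wingtag, pen = rec$pen, day = rec$day, hour = rec$hour
  )
  for (j in seq_len(nt)) out[[truth$traits[j]]] <- as.numeric(Y[, j])
  if (censor && "dh01" %in% truth$traits) {
    det <- as.numeric(out$dh01 > 0.5)
    out$dh01 <- det
    for (tr in setdiff(truth$traits, "dh01")) {
      out[[tr]][det == 0] <- NA_real_
    }
  }
  attr(out, "truth_effects") <- effects
  out
}
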