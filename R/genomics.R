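#' SNP quality control
#'
#' Keeps SNPs that are autosomal, have minor allele frequency above
#' `maf_min` and per-SNP call rate above `callrate_min`. Allele
#' frequencies are computed after excluding missing genotypes. A SNP
#' failing several rules is attributed to the first failing rule in the
#' fixed order: non-autosomal, MAF, call rate.
#'
#' @param geno individuals x SNPs matrix with entries 0/1/2 (allele
#'   counts) or `NA`; column names are SNP ids, row names individual ids
#'   (wingtags).
#' @param snp_meta data frame with one row per SNP: columns `snp`,
#'   `chrom`, `pos`. Chromosome labels not in `autosomes` are removed.
#' @param maf_min minor-allele-frequency threshold; SNPs with MAF
#'   strictly greater are kept. Default 0.01.
#' @param callrate_min call-rate threshold; SNPs with call rate strictly
#'   greater are kept. Default 0.90.
#' @param autosomes character vector of chromosome labels counted as
#'   autosomal. Defaults to purely numeric labels.
#' @return list with `geno` (filtered matrix), `snp_meta` (filtered) and
#'   `report`, a one-row tibble with counts `snps_in`, `removed_nonautosomal`,
#'   `removed_maf`, `removed_callrate`, `snps_out` and the realized
#'   thresholds.
#' @export
snp_qc <- function(geno, snp_meta, maf_min = 0.01, callrate_min = 0.90,
                   autosomes = NULL) {
  geno <- as.matrix(geno)
  if (nrow(geno) == 0L || ncol(geno) == 0L) abort("empty genotype matrix.")
  snp_meta <- as_tibble(snp_meta)
  if (nrow(snp_meta) != ncol(geno)) {
    abort("`snp_meta` must have one row per genotype column.")
  }
  chrom <- as.character(snp_meta$chrom)
  if (is.null(autosomes)) {
    autosomes <- unique(chrom[grepl("^[0-9]+$", chrom)])
  }
  callrate <- colMeans(!is.na(geno))
  p <- colMeans(geno, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  maf <- pmin(p, 1 - p)

  fail_auto <- !(chrom %in% autosomes)
  fail_maf <- !fail_auto & !(maf > maf_min)
  fail_call <- !fail_auto & !fail_maf & !(callrate > callrate_min)
  keep <- !(fail_auto | fail_maf | fail_call)

  report <- tibble(
    snps_in = ncol(geno),
    removed_nonautosomal = sum(fail_auto),
    removed_maf = sum(fail_maf),
    removed_callrate = sum(fail_call),
    snps_out = sum(keep),
    maf_min = maf_min,
    callrate_min = callrate_min
  )
  if (!any(keep)) {
    abort(paste0(
      "all SNPs removed by QC (non-autosomal: ", sum(fail_auto),
      ", MAF: ", sum(fail_maf), ", call rate: ", sum(fail_call), ")."
    ))
  }
  list(
    geno = geno[, keep, drop = FALSE],
    snp_meta = snp_meta[keep, , drop = FALSE],
    report = report
  )
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Computes `G = Z Z' / (2 * sum(p * (1 - p)))` where `Z = M - 2p` is the
#' genotype matrix centred by twice the sample allele frequency of each
#' SNP. Missing genotypes are mean-imputed per SNP before centring, which
#' preserves the row-sum-zero identity. Allele frequencies are estimated
#' from the sample itself, so G is expressed relative to the current
#' population (off-diagonals average slightly below zero).
#'
#' @param geno individuals x SNPs matrix with entries 0/1/2 or `NA`;
#'   row names are individual ids.
#' @return a numeric individuals x individuals matrix of class
#'   `litter_grm`, with the per-SNP allele frequencies in attribute `"p"`.
#' @examples
#' m <- rbind(a = c(0, 2), b = c(1, 1), c = c(2, 0))
#' grm_vanraden1(m)
#' @export
grm_vanraden1 <- function(geno) {
  geno <- as.matrix(geno)
  if (ncol(geno) < 1L) abort("need at least one SNP.")
  if (any(colSums(!is.na(geno)) == 0L)) abort("a SNP is fully missing.")
  p <- colMeans(geno, na.rm = TRUE) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) abort("all SNPs monomorphic: VanRaden denominator is zero.")
  # mean imputation, then centring by 2p
  M <- geno
  if (anyNA(M)) {
    mu <- 2 * p
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- mu[idx[, 2L]]
  }
  Z <- sweep(M, 2L, 2 * p)
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(geno), rownames(geno))
  structure(G, p = p, class = c("litter_grm", "matrix", "array"))
}

#' @export
print.litter_grm <- function(x, ...) {
  cat(sprintf("<litter_grm> %d individuals; mean diagonal %.3f\n",
              nrow(x), mean(diag(x))))
  invisible(x)
}

#' Mean genomic relatedness within and between pens
#'
#' For every unordered pen pair, including each pen with itself, the mean
#' of the off-diagonal entries of G connecting individuals of the two
#' pens. Diagonal entries (self-relationships) are excluded everywhere,
#' so the within-pen mean of a single-bird pen is undefined (`NA`).
#'
#' @param grm GRM matrix with individual ids as dimnames.
#' @param pen_assignment data frame with columns `wingtag` and `pen`
#'   covering every id in `grm`.
#' @return tibble with columns `pen_a`, `pen_b`, `n_pairs`,
#'   `mean_relatedness`.
#' @export
pen_relatedness <- function(grm, pen_assignment) {
  ids <- rownames(grm)
  if (is.null(ids)) abort("`grm` must carry individual ids as dimnames.")
  pen_assignment <- as_tibble(pen_assignment)
  pen <- setNames(as.character(pen_assignment$pen),
                  as.character(pen_assignment$wingtag))
  if (!all(ids %in% names(pen))) {
    abort("every GRM id needs a pen assignment.")
  }
  pens <- sort(unique(pen[ids]))
  G <- unclass(grm)
  diag(G) <- NA_real_
  idx_by_pen <- lapply(pens, function(p) which(pen[ids] == p))
  names(idx_by_pen) <- pens
  out <- list()
  for (i in seq_along(pens)) {
    for (j in i:length(pens)) {
      block <- G[idx_by_pen[[i]], idx_by_pen[[j]], drop = FALSE]
      vals <- block[!is.na(block)]
      if (i == j) {
        n_pairs <- length(vals) / 2
      } else {
        n_pairs <- length(vals)
      }
      out[[length(out) + 1L]] <- tibble(
        pen_a = pens[i], pen_b = pens[j],
        n_pairs = n_pairs,
        mean_relatedness = if (length(vals)) mean(vals) else NA_real_
      )
    }
  }
  bind_rows(out)
}

#' Heatmap of mean pen-pair relatedness
#'
#' @param relatedness output of [pen_relatedness()].
#' @return a ggplot object.
#' @export
plot_pen_relatedness <- function(relatedness) {
  full <- bind_rows(
    relatedness,
    relatedness |>
      filter(.data$pen_a != .data$pen_b) |>
      rename(pen_a = "pen_b", pen_b = "pen_a")
  )
  ggplot2::ggplot(full, ggplot2::aes(.data$pen_a, .data$pen_b,
                                     fill = .data$mean_relatedness)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(name = "mean G") +
    ggplot2::labs(x = "pen", y = "pen") +
    ggplot2::theme_minimal()
}
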