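# Independent dense-matrix oracles and small fixture builders.
# The oracles assemble the model covariance V explicitly with base R
# (model.matrix, outer products) and never touch the package's MME code.

# dense restricted log-likelihood (up to the same additive constant as
# the engine: no (n-p)/2 log(2*pi) term)
oracle_reml_loglik <- function(ph, trait, grm, sigma2_a, sigma2_c, sigma2_d,
                               resid_by_group = NULL, sigma2_e = NULL,
                               grm_bump = 1e-6,
                               random = c("animal", "pdh", "pe")) {
  ph <- as.data.frame(ph)
  ph <- ph[!is.na(ph[[trait]]), ]
  y <- ph[[trait]]
  n <- length(y)
  fml <- "~ 1"
  for (f in c("pen", "day", "hour")) {
    if (length(unique(ph[[f]])) > 1L) fml <- paste(fml, "+ factor(", f, ")")
  }
  X <- stats::model.matrix(stats::as.formula(fml), ph)
  V <- matrix(0, n, n)
  if ("animal" %in% random) {
    ids <- rownames(grm)
    Za <- outer(ph$wingtag, ids, "==") * 1
    Gb <- unclass(as.matrix(grm)) + diag(grm_bump, nrow(grm))
    V <- V + sigma2_a * Za %*% Gb %*% t(Za)
  }
  if ("pdh" %in% random) {
    pdh <- interaction(ph$pen, ph$day, ph$hour, drop = TRUE)
    Vc <- outer(pdh, levels(pdh), "==") * 1
    V <- V + sigma2_c * tcrossprod(Vc)
  }
  if ("pe" %in% random) {
    W <- outer(ph$wingtag, unique(ph$wingtag), "==") * 1
    V <- V + sigma2_d * tcrossprod(W)
  }
  if (is.null(resid_by_group)) {
    diag(V) <- diag(V) + sigma2_e
  } else {
    key <- paste(ph$pen, ph$hour, sep = "|")
    diag(V) <- diag(V) + resid_by_group[key]
  }
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       drop(t(y) %*% P %*% y)))
}

# dense GLS / selection-index BLUP of breeding values at fixed components
oracle_blup <- function(ph, trait, grm, sigma2_a, sigma2_c, sigma2_d,
                        sigma2_e, grm_bump = 1e-6) {
  ph <- as.data.frame(ph)
  ph <- ph[!is.na(ph[[trait]]), ]
  y <- ph[[trait]]
  n <- length(y)
  ids <- rownames(grm)
  fml <- "~ 1"
  for (f in c("pen", "day", "hour")) {
    if (length(unique(ph[[f]])) > 1L) fml <- paste(fml, "+ factor(", f, ")")
  }
  X <- stats::model.matrix(stats::as.formula(fml), ph)
  Za <- outer(ph$wingtag, ids, "==") * 1
  Gb <- unclass(as.matrix(grm)) + diag(grm_bump, nrow(grm))
  pdh <- interaction(ph$pen, ph$day, ph$hour, drop = TRUE)
  Vc <- outer(pdh, levels(pdh), "==") * 1
  W <- outer(ph$wingtag, unique(ph$wingtag), "==") * 1
  V <- sigma2_a * Za %*% Gb %*% t(Za) + sigma2_c * tcrossprod(Vc) +
    sigma2_d * tcrossprod(W) + diag(sigma2_e, n)
  Vi <- solve(V)
  bhat <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  ehat <- y - X %*% bhat
  drop(sigma2_a * Gb %*% t(Za) %*% Vi %*% ehat)
}

# small genotyped population with a GRM
tiny_population <- function(n_pens = 2, birds_per_pen = 30, n_days = 2,
                            hours_per_day = 3, n_snps = 400, seed = 1) {
  des <- sim_design(n_pens = n_pens, birds_per_pen = birds_per_pen,
                    n_days = n_days, hours_per_day = hours_per_day)
  g <- simulate_genotypes(nrow(des$roster), n_snps, seed = seed,
                          wingtags = des$roster$wingtag)
  list(design = des, grm = grm_vanraden1(g$geno))
}

# identity "GRM" with wingtag dimnames
identity_grm <- function(wingtags) {
  G <- diag(length(wingtags))
  dimnames(G) <- list(wingtags, wingtags)
  G
}

# simple square-marker detection rows at given frames/positions
make_detections <- function(frames, x, y, marker_id = 101L, pen = "P01",
                            side = 32, fps = 20,
                            t0 = as.POSIXct("2026-04-18 07:00:00", tz = "UTC")) {
  half <- side / 2
  tibble::tibble(
    marker_id = marker_id,
    c1x = x - half, c1y = y - half, c2x = x + half, c2y = y - half,
    c3x = x + half, c3y = y + half, c4x = x - half, c4y = y + half,
    frame = as.integer(frames), pen = pen,
    timestamp = t0 + frames / fps
  )
}

# add derived columns the behaviour module expects (as filter_pipeline does)
with_centers <- function(det, roster = NULL) {
  det$center_x <- (det$c1x + det$c2x + det$c3x + det$c4x) / 4
  det$center_y <- (det$c1y + det$c2y + det$c3y + det$c4y) / 4
  if (!is.null(roster)) {
    det <- attach_identities(det, roster)
  }
  det
}

# one-pen zone geometry with easy rectangles for hand-built fixtures
test_zones <- function() {
  zone_set(
    focal = rect_poly(500, 300, 1800, 1000),
    yellow = rect_poly(300, 0, 2304, 1296),
    green = rect_poly(100, 0, 300, 1296),
    exclusion = rect_poly(0, 0, 100, 1296)
  )
}

default_roster1 <- function() {
  tibble::tibble(wingtag = "B1", pen = "P01", marker_id = 101L)
}

timestamp_ms_vec <- function(ts) round(as.numeric(ts) * 1000)

fit_components_of <- function(fit) litterebv:::fit_components(fit)
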