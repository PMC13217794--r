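test_that("engine restricted likelihood equals the dense oracle on small instances", {
  set.seed(4)
  q <- 5
  for (rep in 1:3) {
    n <- 24
    ph <- tibble::tibble(
      wingtag = sample(sprintf("W%d", 1:q), n, TRUE),
      pen = sample(c("P1", "P2"), n, TRUE),
      day = sample(1:2, n, TRUE), hour = sample(c(9, 10), n, TRUE),
      y = rnorm(n, 5)
    )
    gm <- matrix(rnorm(q * 8), q)
    G <- tcrossprod(gm) / 8 + diag(0.3, q)
    dimnames(G) <- list(sprintf("W%d", 1:q), sprintf("W%d", 1:q))
    fit <- reml_univariate(ph, "y", G, residual_by = "pen_hour", max_iter = 60)
    cm <- fit_components_of(fit)
    ll <- oracle_reml_loglik(ph, "y", G, cm$sigma2_a, cm$sigma2_c, cm$sigma2_d,
                             resid_by_group = cm$resid_by_group)
    expect_equal(fit$loglik, ll, tolerance = 1e-6)
  }
})

test_that("the fitted likelihood dominates a grid search around the optimum", {
  set.seed(7)
  q <- 4; n <- 12
  ph <- tibble::tibble(
    wingtag = rep(sprintf("W%d", 1:q), each = 3),
    pen = "P1", day = rep(1:3, q), hour = 9,
    y = rnorm(n, 2)
  )
  G <- identity_grm(unique(ph$wingtag))
  fit <- reml_univariate(ph, "y", G, residual_by = "single",
                         random = c("animal", "pe"), max_iter = 100)
  cm <- fit_components_of(fit)
  base <- fit$loglik
  # the engine value must match the oracle at its own optimum and beat a
  # coarse grid over (sigma2_a, sigma2_d, sigma2_e)
  grid <- expand.grid(a = c(0.01, 0.05, 0.2, 0.5, 1),
                      d = c(0.01, 0.05, 0.2, 0.5, 1),
                      e = c(0.05, 0.2, 0.5, 1, 2))
  lls <- apply(grid, 1, function(g) {
    oracle_reml_loglik(ph, "y", G, g["a"], 0, g["d"], sigma2_e = g["e"],
                       random = c("animal", "pe"))
  })
  expect_gte(base + 1e-4, max(lls))
})

test_that("balanced repeated-measures design reproduces the ANOVA closed form", {
  set.seed(8)
  q <- 30; r <- 4
  d_true <- rnorm(q, 0, sqrt(0.5))
  y <- rep(d_true, each = r) + rnorm(q * r, 0, 1)
  ph <- tibble::tibble(
    wingtag = rep(sprintf("W%02d", 1:q), each = r),
    pen = "P1", day = rep(1:r, q), hour = 9, y = y
  )
  # closed-form REML for the balanced one-way random-effects model
  ybar_i <- tapply(y, ph$wingtag, mean)
  msb <- r * var(ybar_i)
  ssw <- sum((y - rep(ybar_i[unique(ph$wingtag)], each = r))^2)
  msw <- ssw / (q * (r - 1))
  sigma_e_anova <- msw
  sigma_d_anova <- (msb - msw) / r
  G <- identity_grm(unique(ph$wingtag))
  fit <- reml_univariate(ph, "y", G, residual_by = "single",
                         random = "pe", fixed = character(), max_iter = 200)
  cm <- fit_components_of(fit)
  expect_equal(cm$sigma2_d, sigma_d_anova, tolerance = 1e-4)
  expect_equal(cm$mean_sigma2_e, sigma_e_anova, tolerance = 1e-4)
})

test_that("a constant response drives all variance estimates to the zero boundary", {
  q <- 6
  ph <- tibble::tibble(
    wingtag = rep(sprintf("W%d", 1:q), each = 2),
    pen = "P1", day = rep(1:2, q), hour = 9, y = 3
  )
  G <- identity_grm(unique(ph$wingtag))
  fit <- reml_univariate(ph, "y", G, residual_by = "single", max_iter = 30)
  expect_true(is.finite(fit$loglik))
  cm <- fit_components_of(fit)
  expect_lt(cm$sigma2_a, 1e-6)
  expect_lt(cm$sigma2_d, 1e-6)
})

test_that("BLUP at fixed components equals the dense GLS oracle on a 5-animal toy", {
  set.seed(9)
  q <- 5; n <- 15
  ph <- tibble::tibble(
    wingtag = sample(sprintf("W%d", 1:q), n, TRUE),
    pen = sample(c("P1", "P2"), n, TRUE),
    day = sample(1:2, n, TRUE), hour = 9,
    y = rnorm(n, 4)
  )
  gm <- matrix(rnorm(q * 10), q)
  G <- tcrossprod(gm) / 10 + diag(0.2, q)
  dimnames(G) <- list(sprintf("W%d", 1:q), sprintf("W%d", 1:q))
  vc <- list(animal = 0.4, pdh = 0.3, pe = 0.25, resid = 0.8)
  fit0 <- reml_univariate(ph, "y", G, residual_by = "single", max_iter = 1,
                          start = vc)
  # freeze exactly these components through the blup interface
  vc_list <- fit0$vc
  vc_list$terms$animal[1, 1] <- 0.4
  vc_list$terms$pdh[1, 1] <- 0.3
  vc_list$terms$pe[1, 1] <- 0.25
  vc_list$resid[[1]][1, 1] <- 0.8
  bl <- blup_fixed_varcomps(ph, "y", G, vc_list)
  ora <- oracle_blup(ph, "y", G, 0.4, 0.3, 0.25, 0.8)
  got <- bl$ebv$ebv[match(rownames(G), bl$ebv$wingtag)]
  expect_equal(got, unname(ora), tolerance = 1e-8)
})

test_that("EBVs vanish without genetic signal or information", {
  set.seed(10)
  q <- 6; n <- 18
  ph <- tibble::tibble(
    wingtag = sample(sprintf("W%d", 1:4), n, TRUE),  # W5, W6 recordless
    pen = "P1", day = sample(1:3, n, TRUE), hour = 9,
    y = rnorm(n, 1)
  )
  G <- identity_grm(sprintf("W%d", 1:q))
  fit <- reml_univariate(ph, "y", G, residual_by = "single", max_iter = 40)
  vc <- fit$vc
  # sigma2_a -> 0: every EBV -> 0
  vc0 <- vc; vc0$terms$animal[1, 1] <- 1e-12
  bl0 <- blup_fixed_varcomps(ph, "y", G, vc0)
  expect_lt(max(abs(bl0$ebv$ebv)), 1e-6)
  # G = I: recordless individuals have EBV exactly 0
  vc1 <- vc; vc1$terms$animal[1, 1] <- 0.5
  bl1 <- blup_fixed_varcomps(ph, "y", G, vc1)
  expect_equal(bl1$ebv$ebv[bl1$ebv$wingtag %in% c("W5", "W6")], c(0, 0),
               tolerance = 1e-10)
})

test_that("EBVs are invariant to a constant shift of the phenotypes", {
  set.seed(11)
  q <- 8; n <- 32
  ph <- tibble::tibble(
    wingtag = sample(sprintf("W%d", 1:q), n, TRUE),
    pen = sample(c("P1", "P2"), n, TRUE), day = sample(1:2, n, TRUE), hour = 9,
    y = rnorm(n)
  )
  gm <- matrix(rnorm(q * 12), q)
  G <- tcrossprod(gm) / 12 + diag(0.2, q)
  dimnames(G) <- list(sprintf("W%d", 1:q), sprintf("W%d", 1:q))
  fit <- reml_univariate(ph, "y", G, residual_by = "single", max_iter = 40)
  ph2 <- dplyr::mutate(ph, y = y + 100)
  bl1 <- blup_fixed_varcomps(ph, "y", G, fit$vc)
  bl2 <- blup_fixed_varcomps(ph2, "y", G, fit$vc)
  expect_equal(bl1$ebv$ebv, bl2$ebv$ebv, tolerance = 1e-7)
  expect_false(isTRUE(all.equal(bl1$fixef$estimate[1], bl2$fixef$estimate[1])))
})

test_that("AI and EM iterations reach the same optimum on a well-conditioned fixture", {
  set.seed(12)
  des <- sim_design(n_pens = 2, birds_per_pen = 25, n_days = 2, hours_per_day = 2)
  tr <- sim_truth(des, traits = "y", Sigma_a = matrix(0.3), Sigma_c = matrix(0.2),
                  Sigma_d = matrix(0.4), resid_mean = 1, resid_spread = 0,
                  trait_means = 0, seed = 1)
  g <- simulate_genotypes(nrow(des$roster), 500, seed = 12,
                          wingtags = des$roster$wingtag)
  G <- grm_vanraden1(g$geno)
  ph <- simulate_hourly_phenotypes(tr, effects = simulate_genetic_effects(G, tr, 2),
                                  seed = 3)
  des_obj <- build_design(ph, "y", G, residual_by = "single")
  vc0 <- litterebv:::default_varcomps(des_obj)
  ai <- litterebv:::reml_engine(des_obj, vc0, max_iter = 100)
  # the AI optimum is an EM fixed point: pure EM started there stays put
  em <- litterebv:::reml_engine(des_obj, ai$vc, max_iter = 50, n_em_start = 50,
                                tol_loglik = 1e-12, tol_par = 1e-9)
  expect_equal(em$loglik, ai$loglik, tolerance = 1e-5)
  expect_equal(litterebv:::vc_flatten(em$vc), litterebv:::vc_flatten(ai$vc),
               tolerance = 5e-2)
})

test_that("collapsing identical residual groups reproduces the homogeneous fit", {
  set.seed(13)
  q <- 30
  ph <- tibble::tibble(
    wingtag = rep(sprintf("W%02d", 1:q), each = 4),
    pen = "P1", day = rep(1:2, 2 * q), hour = 9,   # single pen-hour group
    y = rnorm(4 * q, 2)
  )
  G <- identity_grm(unique(ph$wingtag))
  f1 <- reml_univariate(ph, "y", G, residual_by = "pen_hour", max_iter = 60)
  f2 <- reml_univariate(ph, "y", G, residual_by = "single", max_iter = 60)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("likelihood-ratio test detects strong genetic variance and not its absence", {
  set.seed(14)
  des <- sim_design(n_pens = 2, birds_per_pen = 40, n_days = 2, hours_per_day = 2)
  g <- simulate_genotypes(nrow(des$roster), 80, seed = 14,
                          wingtags = des$roster$wingtag)
  G <- grm_vanraden1(g$geno)
  # strong signal
  tr_hi <- sim_truth(des, traits = "y", Sigma_a = matrix(2), Sigma_c = matrix(0.05),
                     Sigma_d = matrix(0.05), resid_mean = 0.5, resid_spread = 0,
                     trait_means = 0, seed = 5)
  ph_hi <- simulate_hourly_phenotypes(tr_hi,
                                      effects = simulate_genetic_effects(G, tr_hi, 6),
                                      seed = 7)
  lrt_hi <- lrt_genetic_variance(ph_hi, "y", G, residual_by = "single")
  expect_gt(lrt_hi$statistic, 0)
  expect_lt(lrt_hi$p_value, 0.01)
  # no genetic signal: small statistic, comfortably non-significant
  tr_lo <- sim_truth(des, traits = "y", Sigma_a = matrix(0), Sigma_c = matrix(0.05),
                     Sigma_d = matrix(0.5), resid_mean = 0.5, resid_spread = 0,
                     trait_means = 0, seed = 8)
  suppressWarnings(
    ph_lo <- simulate_hourly_phenotypes(
      tr_lo, effects = simulate_genetic_effects(G, tr_lo, 9), seed = 10)
  )
  lrt_lo <- lrt_genetic_variance(ph_lo, "y", G, residual_by = "single")
  expect_gt(lrt_lo$p_value, 0.05)
})

test_that("reported accuracy follows the PEV formula with clipping", {
  eb <- tibble::tibble(ebv = rnorm(4), se = c(0, 0, 0, 0))
  expect_equal(reported_accuracy(eb, 0.5), 1)
  eb2 <- tibble::tibble(ebv = rnorm(4), se = sqrt(0.5))
  expect_equal(reported_accuracy(eb2, 0.5), 0)
  eb3 <- tibble::tibble(ebv = rnorm(3), se = sqrt(c(0.1, 0.25, 0.4)))
  expect_equal(reported_accuracy(eb3, 0.5),
               mean(sqrt((0.5 - c(0.1, 0.25, 0.4)) / 0.5)))
  eb4 <- tibble::tibble(ebv = rnorm(2), se = sqrt(c(0.1, 0.9)))
  expect_message(acc <- reported_accuracy(eb4, 0.5), "clipped")
  expect_equal(acc, mean(c(sqrt(0.4 / 0.5), 0)))
  expect_error(reported_accuracy(eb3, 0), "positive")
})

test_that("design construction enforces its contracts", {
  ph <- tibble::tibble(
    wingtag = c("W1", "W2"), pen = "P1", day = 1, hour = 9, y = c(1, 2)
  )
  G <- identity_grm("W1")  # W2 not genotyped
  expect_error(build_design(ph, "y", G), "missing from the GRM")
  G2 <- identity_grm(c("W1", "W2"))
  d <- build_design(ph, "y", G2)
  expect_equal(d$p_fixed, 1L)  # single-level factors dropped, intercept only
  # aliased covariate: rank-deficiency is an explicit error
  ph2 <- tibble::tibble(
    wingtag = rep(c("W1", "W2"), 3), pen = "P1", day = rep(1:3, each = 2),
    hour = 9, y = rnorm(6), cv = rep(1, 6)
  )
  expect_error(build_design(ph2, "y", G2, covariates = "cv"), "rank deficient")
  # per-trait missingness: record dropped only for the missing trait
  ph3 <- tibble::tibble(
    wingtag = rep(c("W1", "W2"), 2), pen = "P1", day = rep(1:2, each = 2),
    hour = 9, t1 = rnorm(4), t2 = c(NA, rnorm(3))
  )
  d3 <- build_design(ph3, c("t1", "t2"), G2)
  expect_equal(d3$n_records, 7L)
  expect_equal(sum(d3$trait == 1), 4L)
  expect_equal(sum(d3$trait == 2), 3L)
})

test_that("trivariate constraints hold exactly and correlations are recovered", {
  set.seed(15)
  des <- sim_design(n_pens = 2, birds_per_pen = 50, n_days = 2, hours_per_day = 3)
  G <- identity_grm(des$roster$wingtag)
  # diagonal genetic covariance: estimated correlations near zero
  tr <- sim_truth(des, Sigma_a = diag(c(0.05, 0.2, 0.8)), seed = 6)
  ph <- simulate_hourly_phenotypes(tr, effects = simulate_genetic_effects(G, tr, 7),
                                  seed = 8)
  fit <- reml_trivariate(ph, grm = G, max_iter = 60)
  # constrained residual entries equal their fixed values exactly
  st1 <- fit$stage1$vc$resid[[1]]
  st2 <- fit$vc$resid[[1]]
  expect_identical(diag(st2), diag(st1))
  expect_identical(st2[2, 3], st1[2, 3])
  expect_identical(st2[1, 2], 0)
  expect_identical(st2[1, 3], 0)
  rg <- genetic_correlations(fit)
  ok <- !is.na(rg$se) & rg$se > 0
  expect_true(all(abs(rg$correlation[ok]) <= 3 * rg$se[ok] + 1e-8))
})
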