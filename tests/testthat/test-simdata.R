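test_that("genotype simulation validates arguments and recovers allele frequencies", {
  expect_error(simulate_genotypes(0, 10), "at least 2")
  expect_error(simulate_genotypes(10, 0), "at least 1")
  expect_error(simulate_genotypes(10, 10, maf_range = c(0.6, 0.7)), "maf_range")

  # p = 0.5 everywhere: per-SNP mean genotype ~ 1 within 4 binomial SEs
  g <- simulate_genotypes(500, 2000, maf_range = c(0.5, 0.5), seed = 1)
  se <- sqrt(0.5 * 0.5 / (2 * 500)) * 2  # SE of mean genotype = 2*SE(phat)
  expect_true(all(abs(colMeans(g$geno) - 1) < 4 * se))

  # drawn p recovered within 4 binomial SEs
  g2 <- simulate_genotypes(500, 2000, maf_range = c(0.05, 0.5), seed = 2)
  phat <- colMeans(g2$geno) / 2
  tol <- 4 * sqrt(g2$p * (1 - g2$p) / (2 * 500))
  expect_true(all(abs(phat - g2$p) < tol))
})

test_that("genetic effects follow the matrix-normal structure", {
  des <- sim_design(n_pens = 1, birds_per_pen = 400, n_days = 1, hours_per_day = 1)
  G <- identity_grm(des$roster$wingtag)

  # zero additive covariance: breeding values exactly zero
  tr0 <- sim_truth(des, traits = "x", Sigma_a = matrix(0), Sigma_c = matrix(0.1),
                   Sigma_d = matrix(0.1), resid_mean = 1, trait_means = 0, seed = 1)
  eff0 <- simulate_genetic_effects(G, tr0, seed = 1)
  expect_true(all(eff0$bv == 0))

  # G = I, diagonal Sigma_a: per-trait sample variance ~ diagonal
  S <- diag(c(0.5, 2, 4))
  tr1 <- sim_truth(des, traits = c("a", "b", "c"), Sigma_a = S,
                   Sigma_c = diag(0.1, 3), Sigma_d = diag(0.1, 3),
                   resid_mean = rep(1, 3), trait_means = rep(0, 3), seed = 1)
  eff1 <- simulate_genetic_effects(G, tr1, seed = 2)
  v <- apply(eff1$bv, 2, var)
  tol <- 4 * diag(S) * sqrt(2 / 400)
  expect_true(all(abs(v - diag(S)) < tol))

  # duplicated individuals in G draw identical breeding values
  G3 <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3)
  dimnames(G3) <- list(c("u", "v", "w"), c("u", "v", "w"))
  des3 <- list(roster = tibble::tibble(wingtag = c("u", "v", "w"), pen = "P1",
                                       marker_id = 1:3),
               slots = tibble::tibble(pen = "P1", day = 1, hour = 9))
  tr3 <- sim_truth(des3, traits = "x", Sigma_a = matrix(1), Sigma_c = matrix(0.1),
                   Sigma_d = matrix(0.1), resid_mean = 1, trait_means = 0, seed = 1)
  for (sd_ in 1:5) {
    e <- simulate_genetic_effects(G3, tr3, seed = sd_)
    expect_equal(e$bv["u", ], e$bv["v", ], tolerance = 1e-6)
  }
})

test_that("hourly phenotypes decompose into the configured components", {
  # all random variances zero: records equal their fixed-effect sums exactly
  des <- sim_design(n_pens = 2, birds_per_pen = 5, n_days = 2, hours_per_day = 2)
  tr <- sim_truth(des, traits = "x", Sigma_a = matrix(0), Sigma_c = matrix(0),
                  Sigma_d = matrix(0), resid_mean = 0, resid_spread = 0,
                  trait_means = 5, fixed_sd = 0.3, seed = 4)
  suppressWarnings(ph <- simulate_hourly_phenotypes(tr, seed = 5))
  fe <- tr$fixed_effects
  expected <- 5 + fe$pen[as.character(ph$pen), "x"] +
    fe$day[as.character(ph$day), "x"] + fe$hour[as.character(ph$hour), "x"]
  expect_equal(ph$x, unname(expected), tolerance = 1e-12)

  # two pen-hour residual groups with variances 1 and 4 recovered group-wise
  des2 <- sim_design(n_pens = 1, birds_per_pen = 400, n_days = 1, hours_per_day = 2)
  tr2 <- sim_truth(des2, traits = "x", Sigma_a = matrix(0), Sigma_c = matrix(0),
                   Sigma_d = matrix(0), resid_mean = 1, resid_spread = 0,
                   trait_means = 0, fixed_sd = 0, seed = 6)
  tr2$resid_by_pen_hour$x <- c(1, 4)
  suppressWarnings(ph2 <- simulate_hourly_phenotypes(tr2, seed = 7))
  v_by_hour <- tapply(ph2$x, ph2$hour, var)
  expect_equal(unname(v_by_hour[1]), 1, tolerance = 0.3)
  expect_equal(unname(v_by_hour[2]), 4, tolerance = 0.9)

  # total variance ~ sum of components at n >= 10000 records
  des3 <- sim_design(n_pens = 4, birds_per_pen = 250, n_days = 2, hours_per_day = 5)
  tr3 <- sim_truth(des3, traits = "x", Sigma_a = matrix(0.3), Sigma_c = matrix(0.2),
                   Sigma_d = matrix(0.5), resid_mean = 1, resid_spread = 0,
                   trait_means = 0, fixed_sd = 0, seed = 8)
  ph3 <- simulate_hourly_phenotypes(tr3, seed = 9)
  expect_gte(nrow(ph3), 10000)
  expect_equal(var(ph3$x), 0.3 + 0.2 + 0.5 + 1, tolerance = 0.12)
})

test_that("phenotype censoring codes the continuous traits missing when undetected", {
  des <- sim_design(n_pens = 1, birds_per_pen = 50, n_days = 1, hours_per_day = 4)
  tr <- sim_truth(des, seed = 1)
  ph <- simulate_hourly_phenotypes(tr, seed = 2, censor = TRUE)
  expect_true(all(ph$dh01 %in% c(0, 1)))
  expect_true(all(is.na(ph$mdh[ph$dh01 == 0])))
  expect_true(all(is.na(ph$wsh[ph$dh01 == 0])))
  expect_true(all(!is.na(ph$mdh[ph$dh01 == 1])))
})

test_that("tracking stream with no loss mechanisms detects every frame", {
  roster <- tibble::tibble(wingtag = c("B1", "B2"), pen = "P01",
                           marker_id = c(101L, 102L))
  cfg <- tracking_sim_config(away_rate = 0, occlusion_rate = 0,
                             flicker_prob = 0, edge_dropout_prob = 0)
  sim <- simulate_tracking_stream(cfg, roster, n_hours = 1,
                                  minutes_per_hour = 2, seed = 1)
  n_frames <- 2 * 60 * 20
  counts <- table(sim$detections$marker_id)
  expect_equal(unname(counts[c("101", "102")]), c(n_frames, n_frames),
               ignore_attr = TRUE)
  # scheduled minutes fully detected for every bird-hour
  ph <- assemble_phenotypes(filter_pipeline(sim$detections, roster)$detections,
                            sim$truth$schedule, roster)
  expect_equal(ph$minutes_detected, rep(2, 2), tolerance = 1e-9)
})

test_that("emitted detections are consistent with the ground-truth ethogram", {
  roster <- default_roster1()
  cfg <- tracking_sim_config(away_rate = 1 / 60, away_mean_s = 20,
                             occlusion_rate = 1 / 30, occlusion_mean_s = 5,
                             flicker_prob = 0.05)
  sim <- simulate_tracking_stream(cfg, roster, n_hours = 1,
                                  minutes_per_hour = 3, seed = 2)
  genuine <- sim$detections[is.na(sim$detections$artifact), ]
  st <- sim$truth$states
  key <- paste(st$wingtag, st$frame)
  idx <- match(paste("B1", genuine$frame), key)
  expect_false(anyNA(idx))
  expect_true(all(st$present[idx]))
  expect_true(all(st$detected[idx]))
  # timestamps encode frames exactly
  expect_equal(as.numeric(genuine$timestamp - genuine$timestamp[1], units = "secs"),
               (genuine$frame - genuine$frame[1]) / 20, tolerance = 1e-6)
})

test_that("roster with duplicate marker ids within a pen is rejected", {
  bad <- tibble::tibble(wingtag = c("a", "b"), pen = "P01", marker_id = c(1L, 1L))
  expect_error(simulate_tracking_stream(tracking_sim_config(), bad, 1,
                                        minutes_per_hour = 1), "unique within pen")
})
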