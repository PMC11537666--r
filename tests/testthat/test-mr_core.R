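test_that("IVW recovers exact proportionality with zero heterogeneity", {
  withr::with_seed(1, {
    pairs <- sim_pairs(10, beta = 0, sy = 1)
    pairs$beta_out <- 0.4 * pairs$beta_exp
    fit <- mr_ivw(pairs, "fixed")
    expect_equal(fit$beta, 0.4, tolerance = 1e-12)
    expect_equal(fit$q, 0, tolerance = 1e-20)
    expect_equal(fit$q_pval, 1)
  })
})

test_that("IVW equals the weighted-least-squares oracle on a printed instance", {
  pairs <- data.frame(beta_exp = c(0.1, 0.2, 0.15), se_exp = 0.01,
                      beta_out = c(0.05, 0.09, 0.08),
                      se_out = c(0.02, 0.03, 0.025))
  w <- 1 / pairs$se_out^2
  oracle <- oracle_wls(pairs$beta_exp, pairs$beta_out, w, intercept = FALSE)
  fit <- mr_ivw(pairs, "fixed")
  expect_equal(fit$beta, oracle$coef, tolerance = 1e-12)
  expect_equal(fit$se, oracle$se_unit, tolerance = 1e-12)
  expect_equal(fit$q, oracle$q, tolerance = 1e-12)
  rand <- mr_ivw(pairs, "random")
  expect_equal(rand$se, oracle$se_unit * max(1, sqrt(oracle$q / 2)), tolerance = 1e-12)

  # scaling all outcome SEs by 2 leaves the estimate, doubles the fixed SE
  scaled <- pairs
  scaled$se_out <- scaled$se_out * 2
  fit2 <- mr_ivw(scaled, "fixed")
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-12)
  expect_equal(fit2$se, 2 * fit$se, tolerance = 1e-12)
})

test_that("IVW and Egger refuse under-identified inputs; Wald ratio covers one SNP", {
  pairs <- sim_pairs(5, seed = 2)
  expect_error(mr_ivw(pairs[1, ]), class = "mrmediate_insufficient_instruments")
  expect_error(mr_egger(pairs[1:2, ]), class = "mrmediate_insufficient_instruments")
  wr <- mr_wald_ratio(pairs[1, ])
  expect_equal(wr$beta, pairs$beta_out[1] / pairs$beta_exp[1])
  expect_equal(wr$se, pairs$se_out[1] / abs(pairs$beta_exp[1]))
  expect_equal(wr$odds_ratio, exp(wr$beta))
})

test_that("Egger matches the WLS-with-intercept oracle and shifts only its intercept under translation", {
  withr::with_seed(4, {
    for (rep in 1:5) {
      pairs <- sim_pairs(5, beta = 0.25, gamma_range = c(0.05, 0.3))
      orient <- pairs
      neg <- orient$beta_exp < 0
      orient$beta_out[neg] <- -orient$beta_out[neg]
      orient$beta_exp[neg] <- -orient$beta_exp[neg]
      w <- 1 / orient$se_out^2
      oracle <- oracle_wls(orient$beta_exp, orient$beta_out, w, intercept = TRUE)
      fit <- mr_egger(pairs)
      expect_equal(fit$intercept, oracle$coef[1], tolerance = 1e-12)
      expect_equal(fit$beta, oracle$coef[2], tolerance = 1e-12)
      expect_equal(fit$se, oracle$se_unit[2] * max(1, oracle$sigma), tolerance = 1e-12)

      shifted <- orient
      shifted$beta_out <- shifted$beta_out + 0.07
      fit_s <- mr_egger(shifted)
      fit_o <- mr_egger(orient)
      expect_equal(fit_s$intercept, fit_o$intercept + 0.07, tolerance = 1e-10)
      expect_equal(fit_s$beta, fit_o$beta, tolerance = 1e-10)
    }
  })
})

test_that("Egger recovers slope and intercept of its own generative model", {
  withr::with_seed(8, {
    pairs <- sim_pairs(200, beta = 0.3, sx = 0.002, sy = 0.01,
                       gamma_range = c(0.1, 0.4))
    pairs$beta_exp <- abs(pairs$beta_exp)
    pairs$beta_out <- 0.3 * pairs$beta_exp + rnorm(200, 0, 0.01)
    fit <- mr_egger(pairs)
    expect_lt(abs(fit$beta - 0.3), 3 * fit$se)
    expect_lt(abs(fit$intercept), 3 * fit$intercept_se)
  })
})

test_that("weighted median interpolates the cumulative weight at one half", {
  pairs <- data.frame(beta_exp = c(1, 1, 1), se_exp = 0.01,
                      beta_out = c(1, 2, 3), se_out = c(1, 1, 1))
  fit <- mr_weighted_median(pairs, n_boot = 50, seed = 1)
  expect_equal(fit$beta, 2, tolerance = 1e-12)

  # near-degenerate weight: the estimate collapses onto the heavy ratio
  heavy <- data.frame(beta_exp = c(10, 0.1, 0.1), se_exp = 0.01,
                      beta_out = c(10 * 1.5, 0.1 * 5, 0.1 * 9), se_out = 1)
  fit_h <- mr_weighted_median(heavy, n_boot = 50, seed = 1)
  expect_equal(fit_h$beta, 1.5, tolerance = 0.01)

  withr::with_seed(12, {
    for (rep in 1:10) {
      p7 <- sim_pairs(7, beta = 0.2)
      b <- p7$beta_out / p7$beta_exp
      w <- p7$beta_exp^2 / p7$se_out^2
      fit7 <- mr_weighted_median(p7, n_boot = 20, seed = 3)
      expect_equal(fit7$beta, oracle_weighted_median(b, w), tolerance = 1e-12)
    }
  })
})

test_that("pairs with zero exposure effect are excluded from ratio estimators with a warning", {
  pairs <- sim_pairs(6, seed = 31)
  pairs$beta_exp[2] <- 0
  expect_warning(fit <- mr_weighted_median(pairs, n_boot = 20, seed = 1),
                 "excluded")
  expect_equal(fit$n_snp, 5)
})

test_that("mode estimators find the dominant ratio cluster, not the mean", {
  # identical ratios: a point mass at c for any bandwidth
  const <- data.frame(beta_exp = c(1, 2, 0.5, 1.5), se_exp = 0.01,
                      beta_out = 0.7 * c(1, 2, 0.5, 1.5), se_out = 0.05)
  for (bwf in c(0.5, 1, 2)) {
    fit <- mr_mode(const, "simple", bandwidth_factor = bwf, n_boot = 20, seed = 1)
    expect_equal(fit$beta, 0.7, tolerance = 1e-9)
  }

  # 70% of mass near ratio 1, 30% near ratio 3: the mode sits near 1
  bim <- data.frame(beta_exp = rep(1, 10), se_exp = 0.01,
                    beta_out = c(0.95, 1, 1.05, 0.98, 1.02, 0.9, 1.1, 3, 3.1, 2.9),
                    se_out = 0.05)
  fit_b <- mr_mode(bim, "simple", n_boot = 20, seed = 1)
  expect_lt(abs(fit_b$beta - 1), 0.3)
  b <- bim$beta_out / bim$beta_exp
  bw <- 0.9 * min(sd(b), mad(b)) * length(b)^(-1/5)
  expect_equal(fit_b$beta, oracle_mode_grid(b, rep(1, 10), bw), tolerance = 0.02)

  # equal weights make the weighted kind coincide with the simple kind
  eq <- data.frame(beta_exp = rep(1.3, 8), se_exp = 0.01,
                   beta_out = c(0.2, 0.25, 0.3, 0.31, 0.29, 0.5, 0.24, 0.28),
                   se_out = 0.04)
  fs <- mr_mode(eq, "simple", n_boot = 20, seed = 2)
  fw <- mr_mode(eq, "weighted", n_boot = 20, seed = 2)
  expect_equal(fs$beta, fw$beta, tolerance = 1e-12)
})

test_that("point estimates are invariant to the ordering of pairs", {
  withr::with_seed(6, {
    pairs <- sim_pairs(12, beta = 0.2)
    perm <- pairs[sample(nrow(pairs)), ]
    expect_equal(mr_ivw(perm, "fixed")$beta, mr_ivw(pairs, "fixed")$beta,
                 tolerance = 1e-12)
    expect_equal(mr_egger(perm)$beta, mr_egger(pairs)$beta, tolerance = 1e-12)
    expect_equal(mr_weighted_median(perm, n_boot = 10, seed = 1)$beta,
                 mr_weighted_median(pairs, n_boot = 10, seed = 1)$beta,
                 tolerance = 1e-12)
    expect_equal(mr_mode(perm, "weighted", n_boot = 10, seed = 1)$beta,
                 mr_mode(pairs, "weighted", n_boot = 10, seed = 1)$beta,
                 tolerance = 1e-9)
  })
})

test_that("all estimators are unbiased under a valid-instrument model", {
  n_sim <- 200
  est <- matrix(NA_real_, n_sim, 5,
                dimnames = list(NULL, c("ivw", "egger", "wmedian", "smode", "wmode")))
  withr::with_seed(99, {
    for (s in seq_len(n_sim)) {
      pairs <- sim_pairs(50, beta = 0.3, sx = 0.002, sy = 0.02,
                         gamma_range = c(0.15, 0.3))
      est[s, "ivw"] <- mr_ivw(pairs, "fixed")$beta
      est[s, "egger"] <- mr_egger(pairs)$beta
      est[s, "wmedian"] <- mr_weighted_median(pairs, n_boot = 2, seed = 1)$beta
      est[s, "smode"] <- mr_mode(pairs, "simple", n_boot = 2, seed = 1)$beta
      est[s, "wmode"] <- mr_mode(pairs, "weighted", n_boot = 2, seed = 1)$beta
    }
  })
  for (m in colnames(est)) {
    mc_se <- sd(est[, m]) / sqrt(n_sim)
    expect_lt(abs(mean(est[, m]) - 0.3), 3 * mc_se)
  }
})

test_that("the weighted median resists directional pleiotropy that biases IVW", {
  n_sim <- 100
  bias <- matrix(NA_real_, n_sim, 2, dimnames = list(NULL, c("ivw", "wmedian")))
  withr::with_seed(77, {
    for (s in seq_len(n_sim)) {
      pleio <- c(rep(0.2, 20), rep(0, 30))[sample(50)]
      pairs <- sim_pairs(50, beta = 0.3, sx = 0.002, sy = 0.005,
                         gamma_range = c(0.15, 0.3), pleio = pleio,
                         positive_gamma = TRUE)
      bias[s, "ivw"] <- mr_ivw(pairs, "fixed")$beta - 0.3
      bias[s, "wmedian"] <- mr_weighted_median(pairs, n_boot = 2, seed = 1)$beta - 0.3
    }
  })
  expect_lt(abs(mean(bias[, "wmedian"])), abs(mean(bias[, "ivw"])) / 2)
  expect_lt(abs(mean(bias[, "wmedian"])), 0.1 * 0.3)
})

test_that("the method dispatcher returns one row per applicable method", {
  pairs <- sim_pairs(10, seed = 15)
  res <- run_mr_methods(pairs, n_boot = 20, seed = 5)
  expect_setequal(res$method, c("IVW_fixed", "IVW_random", "Egger",
                                "weighted_median", "simple_mode", "weighted_mode"))
  expect_true(all(res$se > 0))
  expect_true(all(res$ci_low < res$ci_high))
  expect_true(all(res$pval > 0 & res$pval <= 1))
  expect_equal(res$odds_ratio, exp(res$beta))

  single <- run_mr_methods(pairs[3, ], n_boot = 5, seed = 1)
  expect_equal(single$method, "Wald_ratio")
})
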