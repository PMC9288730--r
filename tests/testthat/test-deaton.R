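test_that("stage 1 recovers household coefficients exactly on noiseless data", {
  cfg <- noiseless_config(n_clusters = 12, households_per_cluster = 6,
                          beta0 = -0.004, beta1 = 0.05,
                          gamma0 = matrix(c(-0.002, 0.001, 0.0003), 1),
                          gamma1 = matrix(c(0.02, -0.01, 0.004), 1), seed = 6)
  res <- prepare_generated(cfg)
  s1 <- deaton_stage1(res$prep)
  expect_equal(s1$beta0[1], -0.004, tolerance = 1e-8)
  expect_equal(s1$beta1[1], 0.05, tolerance = 1e-8)
  expect_equal(unname(s1$gamma0[, 1]), c(-0.002, 0.001, 0.0003), tolerance = 1e-8)
  expect_equal(unname(s1$gamma1[, 1]), c(0.02, -0.01, 0.004), tolerance = 1e-8)
  # noiseless residual covariances vanish
  expect_lt(abs(s1$Sigma11[1, 1]), 1e-16)
  expect_lt(abs(s1$Sigma01[1, 1]), 1e-16)
})

test_that("within-cluster demeaning equals the dummy-variable regression", {
  cfg <- synthetic_config(n_clusters = 5, households_per_cluster = 8,
                          goods = "asb", mean_log_price = log(47),
                          price_sd_between = 0.2, mean_share = 0.02,
                          beta0 = -0.004, beta1 = 0.05,
                          gamma0 = matrix(c(-0.002, 0.001, 0.0003), 1),
                          gamma1 = matrix(c(0.02, -0.01, 0.004), 1),
                          sigma_u0 = 0.004, sigma_u1 = 0.2, sigma_f = 0.005,
                          prevalence_by_tertile = matrix(1, 1, 3), seed = 31)
  res <- prepare_generated(cfg, min_consumers = 1)
  s1 <- deaton_stage1(res$prep)
  d <- res$prep$data
  fit <- stats::lm(share_asb ~ lnx + log_hh_size + n_children + education_years +
                     factor(cluster_id), data = d)
  expect_equal(unname(s1$coef0[, 1]),
               unname(coef(fit)[c("lnx", "log_hh_size", "n_children",
                                  "education_years")]),
               tolerance = 1e-10)
  fit1 <- stats::lm(lnuv_asb ~ lnx + log_hh_size + n_children + education_years +
                      factor(cluster_id), data = d)
  expect_equal(unname(s1$coef1[, 1]),
               unname(coef(fit1)[c("lnx", "log_hh_size", "n_children",
                                   "education_years")]),
               tolerance = 1e-10)
})

test_that("stage-1 residual covariance estimates the within-cluster noise variance", {
  cfg <- synthetic_config(n_clusters = 2000, households_per_cluster = 5,
                          goods = "asb", mean_log_price = log(47),
                          price_sd_between = 0.2, mean_share = 0.02,
                          beta0 = -0.004, beta1 = 0.05,
                          sigma_u0 = 0.006, sigma_u1 = 0.1, sigma_f = 0.003,
                          prevalence_by_tertile = matrix(1, 1, 3), seed = 17)
  s1 <- deaton_stage1(prepare_generated(cfg, min_consumers = 1)$prep)
  expect_lt(abs(s1$Sigma11[1, 1] - 0.01), 0.001)
  expect_lt(abs(s1$Sigma00[1, 1] - 0.006^2), 0.1 * 0.006^2)
})

test_that("cluster purged means reduce to raw cluster means when the purge is empty", {
  cfg <- noiseless_config(n_clusters = 10, households_per_cluster = 4,
                          beta0 = 0, beta1 = 0, seed = 13)
  res <- prepare_generated(cfg)
  d <- res$prep$data
  # hand-built stage 1 with all-zero household coefficients: purge is identity
  s1_id <- list(goods = "asb", coef0 = matrix(0, 4, 1), coef1 = matrix(0, 4, 1),
                Sigma01 = matrix(0, 1, 1), Sigma11 = matrix(0, 1, 1))
  mo <- cluster_moments(s1_id, res$prep)
  raw <- tapply(d$lnuv_asb, d$cluster_id, mean)
  expect_equal(as.numeric(mo$y1[, 1]), as.numeric(raw[as.character(mo$clusters)]),
               tolerance = 1e-12)

  # noiseless data: R equals psi^2 times the between-cluster variance of
  # the sampled true log prices
  lnp <- res$truth$cluster_log_prices[mo$clusters, 1]
  psi <- cfg$psi[1, 1]
  expect_equal(stats::cov(mo$y1[, 1], mo$y1[, 1]), psi^2 * stats::var(lnp),
               tolerance = 1e-10)

  # permuting household order leaves the moments untouched
  shuffled <- res$prep
  set.seed(1)
  shuffled$data <- shuffled$data[sample(nrow(shuffled$data)), ]
  mo2 <- cluster_moments(s1_id, shuffled)
  expect_equal(mo2$y1, mo$y1, tolerance = 1e-12)
  expect_equal(mo2$y0, mo$y0, tolerance = 1e-12)
})

test_that("stage 2 reduces to OLS without measurement error and applies the scalar attenuation formula", {
  cfg <- synthetic_config(n_clusters = 400, households_per_cluster = 5,
                          goods = "asb", mean_log_price = log(47),
                          price_sd_between = 0.2, mean_share = 0.02,
                          beta0 = -0.004, beta1 = 0.05,
                          sigma_u0 = 0.005, sigma_u1 = 0.15, sigma_f = 0.003,
                          prevalence_by_tertile = matrix(1, 1, 3), seed = 23)
  res <- prepare_generated(cfg, min_consumers = 1)
  s1 <- deaton_stage1(res$prep)
  mo <- cluster_moments(s1, res$prep)

  # no-correction limit: forcing Sigma = 0 gives the OLS slope of y0 on y1
  mo0 <- mo
  mo0$Sigma01 <- matrix(0, 1, 1)
  mo0$Sigma11 <- matrix(0, 1, 1)
  B_ols <- unname(coef(stats::lm(mo$y0[, 1] ~ mo$y1[, 1]))[2])
  expect_equal(deaton_stage2(mo0)$B[1, 1], B_ols, tolerance = 1e-10)

  # scalar attenuation oracle at constant purchaser count n+
  nplus <- 5
  expect_true(all(mo$n1 == nplus))
  B_hand <- (stats::var(mo$y1[, 1]) - s1$Sigma11[1, 1] / nplus)^-1 *
    (stats::cov(mo$y1[, 1], mo$y0[, 1]) - s1$Sigma01[1, 1] / nplus)
  expect_equal(deaton_stage2(mo)$B[1, 1], B_hand, tolerance = 1e-10)
})

test_that("the correction removes attenuation from noisy unit values", {
  truthE <- -0.9
  cfg <- synthetic_config(n_clusters = 1500, households_per_cluster = 6,
                          goods = "asb", mean_log_price = log(47),
                          price_sd_between = 0.2, mean_share = 0.02,
                          beta0 = -0.004, beta1 = 0.05,
                          elasticity = matrix(truthE),
                          sigma_u0 = 0.005, sigma_u1 = 0.3, sigma_f = 0.003,
                          prevalence_by_tertile = matrix(c(0.4, 0.5, 0.6), 1),
                          seed = 29)
  res <- prepare_generated(cfg)
  fit <- deaton_elasticity(res$prep, n_draws = 400, seed = 1)
  # attenuation direction: the uncorrected slope is smaller in magnitude
  expect_lt(abs(fit$B_uncorrected[1, 1]), abs(fit$B[1, 1]))
  # corrected estimate is consistent with the generating truth
  expect_lt(abs(fit$E[1, 1] - truthE), 3 * fit$se_E[1, 1])
  # the attenuated share slope pushes the implied elasticity towards -1,
  # i.e. uncorrected unit values OVERSTATE the price response magnitude
  uncorr <- elasticity_transform(fit$B_uncorrected,
                                 list(beta0 = -0.004, beta1 = 0.05,
                                      mean_share = fit$mean_share))
  expect_gt(abs(uncorr$E[1, 1]), abs(fit$E[1, 1]))
})

test_that("the elasticity transform matches its closed forms", {
  # single-good closed form: B/w - 1 with no quality shading
  est <- elasticity_transform(matrix(0.0012), list(beta0 = 0, beta1 = 0,
                                                   mean_share = 0.02))
  expect_equal(est$E[1, 1], -0.94, tolerance = 1e-12)

  # B = D(w): zero price response for any quality elasticity
  w <- c(0.02, 0.05, 0.1)
  est2 <- elasticity_transform(diag(w), list(beta0 = c(-0.004, 0.002, 0.001),
                                             beta1 = c(0.3, 0.1, 0.05),
                                             mean_share = w))
  expect_equal(est2$E, matrix(0, 3, 3), tolerance = 1e-12, ignore_attr = TRUE)

  # forcing zeta = 0 reduces exactly to D(w)^-1 B - I
  set.seed(5)
  B <- matrix(rnorm(9, 0, 0.01), 3, 3)
  est3 <- elasticity_transform(B, list(beta0 = c(-0.004, 0.002, 0.001),
                                       beta1 = c(0.3, 0.1, 0.05),
                                       mean_share = w),
                               quality_correction = FALSE)
  expect_equal(est3$E, diag(1 / w) %*% B - diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(est3$quality_elasticity, rep(0, 3))

  # expenditure and quality elasticities
  est4 <- elasticity_transform(matrix(0.0012), list(beta0 = -0.005, beta1 = 0.06,
                                                    mean_share = 0.017))
  expect_equal(est4$expenditure_elasticity, 1 - 0.005 / 0.017 - 0.06,
               tolerance = 1e-12)
  expect_equal(est4$quality_elasticity,
               0.06 / est4$expenditure_elasticity, tolerance = 1e-12)

  expect_error(elasticity_transform(matrix(0.001), list(beta0 = 0, beta1 = 0,
                                                        mean_share = 0)),
               "degenerate-share")
})

test_that("the cluster bootstrap is reproducible and degenerate inputs fail loudly", {
  cfg <- synthetic_config(n_clusters = 300, households_per_cluster = 5,
                          goods = "asb", mean_log_price = log(47),
                          price_sd_between = 0.2, mean_share = 0.02,
                          beta0 = -0.004, beta1 = 0.05,
                          sigma_u0 = 0.005, sigma_u1 = 0.15, sigma_f = 0.003,
                          prevalence_by_tertile = matrix(1, 1, 3), seed = 41)
  res <- prepare_generated(cfg, min_consumers = 1)
  s1 <- deaton_stage1(res$prep)
  mo <- cluster_moments(s1, res$prep)
  b1 <- deaton_bootstrap(mo, s1, n_draws = 50, seed = 7)
  b2 <- deaton_bootstrap(mo, s1, n_draws = 50, seed = 7)
  expect_identical(b1$se_E, b2$se_E)
  expect_gt(b1$se_E[1, 1], 0)

  # identical clusters carry no between-cluster price signal: every draw
  # fails the positive-definiteness check and the failure is reported
  mo_flat <- structure(list(
    goods = "asb", clusters = 1:20,
    y0 = matrix(0.01, 20, 1), y1 = matrix(3.8, 20, 1),
    n0 = rep(3, 20), n1 = matrix(3, 20, 1), n01 = matrix(3, 20, 1),
    n11 = array(3, c(20, 1, 1)),
    Sigma01 = matrix(0, 1, 1), Sigma11 = matrix(0.01, 1, 1),
    n_clusters = 20L
  ), class = "deaton_moments")
  expect_error(deaton_stage2(mo_flat), "correction-overshoot")
  expect_warning(bf <- deaton_bootstrap(mo_flat, s1, n_draws = 20, seed = 1),
                 "unstable bootstrap")
  expect_identical(bf$n_failed, 20L)
  expect_error(suppressWarnings(
    deaton_bootstrap(mo_flat, s1, n_draws = 20, seed = 1,
                     error_on_unstable = TRUE)), "unstable")
})

test_that("bootstrap standard errors calibrate against independent replicates", {
  one_fit <- function(seed, n_draws = 0) {
    cfg <- synthetic_config(n_clusters = 600, households_per_cluster = 5,
                            goods = "asb", mean_log_price = log(47),
                            price_sd_between = 0.2, mean_share = 0.02,
                            beta0 = -0.004, beta1 = 0.05,
                            elasticity = matrix(-0.9),
                            sigma_u0 = 0.005, sigma_u1 = 0.15, sigma_f = 0.003,
                            prevalence_by_tertile = matrix(c(0.5, 0.6, 0.7), 1),
                            seed = seed)
    deaton_elasticity(prepare_generated(cfg)$prep, n_draws = n_draws, seed = seed)
  }
  ests <- vapply(1:40, function(s) one_fit(s)$E[1, 1], numeric(1))
  boot_se <- mean(vapply(41:43, function(s) one_fit(s, n_draws = 300)$se_E[1, 1],
                         numeric(1)))
  expect_lt(abs(boot_se / stats::sd(ests) - 1), 0.25)
})

test_that("income-group estimation shares cluster prices across groups", {
  # homogeneous truth: group estimates agree within sampling noise
  cfg <- synthetic_config(n_clusters = 1200, households_per_cluster = 6,
                          goods = "asb", mean_log_price = log(47),
                          price_sd_between = 0.2, mean_share = 0.02,
                          beta0 = 0, beta1 = 0, elasticity = matrix(-0.9),
                          sigma_u0 = 0.006, sigma_u1 = 0.134, sigma_f = 0.003,
                          prevalence_by_tertile = matrix(c(0.3, 0.4, 0.5), 1),
                          seed = 51)
  res <- prepare_generated(cfg, tertiles = TRUE)
  fits <- estimate_by_group(res$prep, grouping = "tertile", n_draws = 200, seed = 1)
  es <- vapply(fits, function(f) f$E[1, 1], numeric(1))
  ses <- vapply(fits, function(f) f$se_E[1, 1], numeric(1))
  expect_true(all(abs(es - (-0.9)) < 3 * ses))

  # shared-price contract: a cluster whose purchasers all sit in one income
  # group still contributes its price signal (y1) to the other groups
  d <- res$prep$data
  cl_by_group <- table(d$cluster_id, d$income_tertile)
  only_high <- rownames(cl_by_group)[cl_by_group[, "high"] > 0 &
                                       cl_by_group[, "low"] == 0]
  expect_gt(length(only_high), 0)
  s1_id <- list(goods = "asb", coef0 = matrix(0, 4, 1), coef1 = matrix(0, 4, 1),
                Sigma01 = matrix(0, 1, 1), Sigma11 = matrix(0, 1, 1))
  mo_low <- cluster_moments(s1_id, res$prep,
                            rows0 = d$income_tertile == "low")
  pick <- match(as.numeric(only_high[1]), mo_low$clusters)
  expect_true(is.finite(mo_low$y1[pick, 1])) # price signal present
  expect_identical(mo_low$n0[pick], 0L)      # no low-income share households
  expect_true(is.na(mo_low$y0[pick, 1]))
})

test_that("rural and urban samples are estimated separately", {
  cfg <- synthetic_config(n_clusters = 800, households_per_cluster = 6,
                          goods = "asb", mean_log_price = log(47),
                          price_sd_between = 0.2, mean_share = 0.02,
                          beta0 = 0, beta1 = 0, elasticity = matrix(-0.9),
                          sigma_u0 = 0.006, sigma_u1 = 0.134, sigma_f = 0.003,
                          prevalence_by_tertile = matrix(0.5, 1, 3), seed = 57)
  res <- prepare_generated(cfg)
  fits <- estimate_by_group(res$prep, grouping = "sector")
  expect_named(fits, c("rural", "urban"))
  expect_true(all(vapply(fits, function(f) abs(f$E[1, 1] + 0.9) < 0.2,
                         logical(1))))
})

test_that("the estimated matrix is oriented price-of-j on quantity-of-i", {
  # finite difference on the generating process: with no quality shading
  # and no household noise, regressing cluster-mean log quantities on the
  # small cluster log-price deviations recovers each row of E
  E2 <- matrix(c(-0.9, 0.25, 0.3, -0.6), 2, 2, byrow = TRUE)
  cfg <- synthetic_config(
    n_clusters = 80, households_per_cluster = 4, goods = c("a", "b"),
    mean_log_price = c(3.8, 4.2), price_sd_between = c(0.02, 0.02),
    mean_share = c(0.02, 0.03), beta0 = c(0, 0), beta1 = c(0, 0),
    elasticity = E2, sigma_u0 = 0, sigma_u1 = 0, sigma_f = 0,
    prevalence_by_tertile = matrix(1, 2, 3), seed = 71
  )
  sim <- generate_households(cfg)
  rec <- sim$records
  lnp <- sim$truth$cluster_log_prices
  for (i in 1:2) {
    g <- c("a", "b")[i]
    # log quantity net of log expenditure is an exact function of cluster
    # prices here, so the regression residual is pure price nonlinearity
    y <- tapply(log(rec[[paste0("quantity_", g)]]) - log(rec$total_expenditure),
                rec$cluster_id, mean)
    ord <- as.integer(names(y))
    slopes <- coef(stats::lm(y ~ lnp[ord, 1] + lnp[ord, 2]))[2:3]
    expect_equal(unname(slopes), E2[i, ], tolerance = 0.02)
  }
})

test_that("relabelling goods permutes the estimate consistently", {
  cfg <- synthetic_config(
    n_clusters = 500, households_per_cluster = 5, goods = c("asb", "juice"),
    mean_log_price = c(log(47), log(65)), price_sd_between = c(0.2, 0.2),
    mean_share = c(0.02, 0.025), beta0 = c(-0.004, -0.004),
    beta1 = c(0.05, 0.08),
    elasticity = matrix(c(-0.9, 0.2, 0.3, -0.6), 2, 2, byrow = TRUE),
    sigma_u0 = c(0.006, 0.006), sigma_f = c(0.003, 0.003),
    prevalence_by_tertile = rbind(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7)),
    seed = 61
  )
  rec <- generate_households(cfg)$records
  fit_a <- deaton_elasticity(filter_for_estimation(
    compute_shares_unitvalues(rec, goods = c("asb", "juice")), "asb"),
    n_draws = 0)
  fit_b <- deaton_elasticity(filter_for_estimation(
    compute_shares_unitvalues(rec, goods = c("juice", "asb")), "asb"),
    n_draws = 0)
  expect_equal(fit_b$E[c("asb", "juice"), c("asb", "juice")], fit_a$E,
               tolerance = 1e-8)
})

test_that("cluster indicators explain the designed share of unit-value variance", {
  # no within-cluster variation at all (no noise, no expenditure effect on
  # unit values): R^2 = 1
  res1 <- prepare_generated(noiseless_config(n_clusters = 50, beta1 = 0, seed = 3))
  expect_equal(unitvalue_variance_r2(res1$prep), 1, tolerance = 1e-12)

  # no between-cluster price variation: R^2 near the overfitting floor
  cfg0 <- synthetic_config(n_clusters = 200, households_per_cluster = 50,
                           goods = "asb", mean_log_price = log(47),
                           price_sd_between = 0, mean_share = 0.02,
                           beta0 = 0, beta1 = 0, sigma_u0 = 0.005,
                           sigma_u1 = 0.2, sigma_f = 0,
                           prevalence_by_tertile = matrix(1, 1, 3), seed = 19)
  r2_0 <- unitvalue_variance_r2(prepare_generated(cfg0, min_consumers = 1)$prep)
  expect_lt(r2_0, 0.05)

  # variance-ratio design: between-cluster share of 69%
  cfg69 <- synthetic_config(n_clusters = 2000, households_per_cluster = 50,
                            goods = "asb", mean_log_price = log(47),
                            price_sd_between = 0.2, mean_share = 0.02,
                            beta0 = 0, beta1 = 0, sigma_u0 = 0.005,
                            sigma_u1 = 0.2 * sqrt(0.31 / 0.69), sigma_f = 0,
                            prevalence_by_tertile = matrix(1, 1, 3), seed = 19)
  r2 <- unitvalue_variance_r2(prepare_generated(cfg69, min_consumers = 1)$prep)
  expect_lt(abs(r2 - 0.69), 0.02)
})
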