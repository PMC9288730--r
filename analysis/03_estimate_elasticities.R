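#!/usr/bin/env Rscript
# Stage 3: price-elasticity estimation.
#
#   (a) headline own-price elasticity of aerated beverages from the
#       full-scale single-good survey, with cluster-bootstrap SEs, plus the
#       unit-value variance decomposition;
#   (b) estimates by income tertile and by sector;
#   (c) a multi-good demonstration that the matrix machinery recovers a
#       full cross-price matrix when every good has cluster-level price
#       signal (adequate purchase prevalence).
#
# Writes results/elasticity_*.csv

library(asbdemand)

seed <- 2024L

# ---- (a) headline estimate -------------------------------------------------
cfg1 <- recovery_config("headline", seed = seed)
res1 <- simulate_and_estimate(cfg1, n_draws = 1000)
fit1 <- res1$fit
cat(sprintf("headline own-price elasticity: %.3f (bootstrap SE %.3f, %d draws)\n",
            fit1$E[1, 1], fit1$se_E[1, 1], fit1$n_draws))
cat(sprintf("  ground truth %.2f | clusters retained %d | expenditure elasticity %.2f | quality elasticity %.3f\n",
            res1$truth$true_price_elasticity[1, 1], res1$n_clusters_retained,
            fit1$expenditure_elasticity[1], fit1$quality_elasticity[1]))

prep1 <- filter_for_estimation(compute_shares_unitvalues(
  generate_households(cfg1)$records), "asb")
r2 <- unitvalue_variance_r2(prep1)
cat(sprintf("  cluster indicators explain %.0f%% of log unit-value variance\n",
            100 * r2))
write.csv(data.frame(
  group = "full", estimate = fit1$E[1, 1], se = fit1$se_E[1, 1],
  expenditure_elasticity = fit1$expenditure_elasticity[1],
  quality_elasticity = fit1$quality_elasticity[1],
  truth = res1$truth$true_price_elasticity[1, 1],
  unitvalue_r2 = r2
), "results/elasticity_headline.csv", row.names = FALSE)

# ---- (b) income tertiles (shared cluster prices) and sectors ---------------
cfgT <- recovery_config("tertile", seed = seed)
resT <- simulate_and_estimate(cfgT, by_tertile = TRUE, n_draws = 400)
truthT <- resT$truth$true_price_elasticity_by_tertile
rows <- do.call(rbind, lapply(names(resT$fit), function(g) {
  f <- resT$fit[[g]]
  data.frame(group = g, estimate = f$E[1, 1], se = f$se_E[1, 1],
             truth = truthT[[g]][1, 1])
}))
cat("\nincome-tertile own-price elasticities (truth in brackets):\n")
for (i in seq_len(nrow(rows))) {
  cat(sprintf("  %-7s %6.3f (SE %.3f)  [truth %.3f]\n", rows$group[i],
              rows$estimate[i], rows$se[i], rows$truth[i]))
}
cat("the magnitude gradient runs low > middle > high: poorer households\n")
cat("respond more strongly to price.\n")

fitS <- estimate_by_group(prep1, grouping = "sector", n_draws = 400, seed = seed)
rows_s <- do.call(rbind, lapply(names(fitS), function(s) {
  data.frame(group = s, estimate = fitS[[s]]$E[1, 1], se = fitS[[s]]$se_E[1, 1],
             truth = res1$truth$true_price_elasticity[1, 1])
}))
cat("\nsector estimates (one shared truth):\n")
print(rows_s, row.names = FALSE)
write.csv(rbind(rows, rows_s), "results/elasticity_by_group.csv",
          row.names = FALSE)

# ---- (c) multi-good cross-price matrix -------------------------------------
E2 <- matrix(c(-0.9, 0.2, 0.3, -0.6), 2, 2, byrow = TRUE,
             dimnames = list(c("asb", "juice"), c("asb", "juice")))
cfg2 <- synthetic_config(
  n_clusters = 3000, households_per_cluster = 6, goods = c("asb", "juice"),
  mean_log_price = c(log(47), log(65)), price_sd_between = c(0.2, 0.2),
  mean_share = c(0.02, 0.025), beta0 = c(-0.004, -0.004),
  beta1 = c(0.05, 0.08), elasticity = E2,
  sigma_u0 = c(0.006, 0.006), sigma_f = c(0.003, 0.003),
  prevalence_by_tertile = rbind(c(0.55, 0.7, 0.85), c(0.5, 0.6, 0.75)),
  seed = seed)
res2 <- simulate_and_estimate(cfg2, n_draws = 400)
cat("\ntwo-good cross-price matrix (rows: quantity, cols: price):\n")
print(round(res2$fit$E, 3))
cat("bootstrap SEs:\n")
print(round(res2$fit$se_E, 3))
cat("generating truth:\n")
print(E2)
cat("\nAt realistic prevalence (1-10%) with independent purchase gates the\n")
cat("sparse goods carry too little cluster-level price signal for a stable\n")
cat("joint matrix; cross-price terms need overlapping purchasers, which\n")
cat("real surveys provide through correlated purchase patterns.\n")
em <- cbind(data.frame(good = rownames(res2$fit$E)), res2$fit$E,
            se = res2$fit$se_E)
write.csv(em, "results/elasticity_matrix_twogood.csv", row.names = FALSE)
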