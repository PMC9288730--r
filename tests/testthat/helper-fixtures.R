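# Small in-code fixtures shared across test files.

# Four households in two clusters, one ASB purchaser; magnitudes in the
# range typical of Indian consumer expenditure rounds (INR per 30 days).
tiny_survey <- function() {
  data.frame(
    household_id = 1:4,
    cluster_id = c(1, 1, 2, 2),
    round = "66",
    subround = c(1, 1, 2, 2),
    sector = c("rural", "rural", "urban", "urban"),
    weight = 1,
    total_expenditure = c(8000, 11753, 9500, 12000),
    household_size = c(4, 5, 3, 6),
    n_children = c(1, 2, 0, 3),
    education_years = c(5, 8, 10, 6),
    quantity_asb = c(0, 2.5, 0, 0),
    expenditure_asb = c(0, 120, 0, 0),
    quantity_milk = c(20, 25, 15, 30),
    expenditure_milk = c(500, 640, 380, 760),
    stringsAsFactors = FALSE
  )
}

# Single-good configuration with every noise source switched off; the
# demand system then holds exactly in the generated records.
noiseless_config <- function(n_clusters = 20, households_per_cluster = 5,
                             price_sd = 0.1, beta0 = -0.004, beta1 = 0.05,
                             gamma0 = matrix(0, 1, 3), gamma1 = matrix(0, 1, 3),
                             elasticity = -0.9, prevalence = c(1, 1, 1),
                             seed = 42) {
  synthetic_config(
    n_clusters = n_clusters, households_per_cluster = households_per_cluster,
    goods = "asb", mean_log_price = log(47), price_sd_between = price_sd,
    mean_share = 0.02, beta0 = beta0, beta1 = beta1,
    gamma0 = gamma0, gamma1 = gamma1,
    elasticity = matrix(elasticity),
    sigma_u0 = 0, sigma_u1 = 0, sigma_f = 0,
    prevalence_by_tertile = matrix(prevalence, 1),
    seed = seed
  )
}

# Generate -> shares/unit values -> estimation filter in one step
prepare_generated <- function(config, min_consumers = 2, tertiles = FALSE) {
  sim <- generate_households(config)
  prep <- compute_shares_unitvalues(sim$records, goods = config$goods)
  if (tertiles) prep <- assign_income_tertiles(prep)
  list(prep = filter_for_estimation(prep, focal_good = config$goods[1],
                                    min_consumers = min_consumers),
       truth = sim$truth, records = sim$records)
}
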