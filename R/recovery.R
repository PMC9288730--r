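# Simulation experiments that validate the estimator against the known
# ground truth of the synthetic survey generator. These are the package's
# evidence that the two-stage procedure recovers price elasticities at the
# scale of the pooled consumer expenditure rounds it is meant for.

#' Configuration of an estimator-recovery experiment
#'
#' Builds a single-good survey configuration at the scale of two pooled
#' consumer-expenditure rounds (about 25,000 clusters of 8 households) with
#' the focal-good purchase prevalence rising from ~1% of low-income to ~10%
#' of high-income households. Two kinds:
#'
#' * `"headline"`: one overall own-price elasticity as ground truth, with
#'   quality shading active (nonzero expenditure coefficients), so the full
#'   transform chain is exercised.
#' * `"tertile"`: tertile-specific share-equation price responses with the
#'   expenditure and covariate coefficients set to zero, so each group's
#'   true elasticity is exactly \eqn{\theta_g/\bar w - 1} -- a focused
#'   experiment isolating group price responses.
#'
#' @param kind `"headline"` or `"tertile"`.
#' @param seed RNG seed of the generated survey.
#' @param n_clusters,households_per_cluster survey scale.
#' @param own_price_elasticity ground truth for the headline kind.
#' @param tertile_elasticities length-3 ground truth (low, middle, high)
#'   for the tertile kind.
#' @return a [synthetic_config()].
#' @export
recovery_config <- function(kind = c("headline", "tertile"), seed = 1L,
                            n_clusters = 25428, households_per_cluster = 8,
                            own_price_elasticity = -0.94,
                            tertile_elasticities = c(-1.035, -0.913, -0.832)) {
  kind <- match.arg(kind)
  w <- 0.017
  prev <- matrix(c(0.010, 0.031, 0.103), 1)
  if (kind == "headline") {
    synthetic_config(
      n_clusters = n_clusters,
      households_per_cluster = households_per_cluster,
      goods = "asb",
      mean_log_price = log(47), price_sd_between = 0.20,
      mean_share = w, beta0 = -0.005, beta1 = 0.06,
      gamma0 = matrix(c(-0.002, 0.001, 0.0002), 1),
      gamma1 = matrix(c(0.02, -0.01, 0.005), 1),
      elasticity = matrix(own_price_elasticity),
      sigma_u0 = 0.006, sigma_f = 0.003,
      prevalence_by_tertile = prev,
      seed = seed
    )
  } else {
    stopifnot(length(tertile_elasticities) == 3L)
    synthetic_config(
      n_clusters = n_clusters,
      households_per_cluster = households_per_cluster,
      goods = "asb",
      mean_log_price = log(47), price_sd_between = 0.20,
      mean_share = w, beta0 = 0, beta1 = 0,
      elasticity = matrix(tertile_elasticities[2]),
      theta_by_tertile = lapply(tertile_elasticities,
                                function(e) matrix(w * (1 + e))),
      sigma_u0 = 0.006, sigma_f = 0.003,
      prevalence_by_tertile = prev,
      seed = seed
    )
  }
}

#' Generate a survey and run the estimation pipeline once
#'
#' One end-to-end pass: generate records, build shares and unit values,
#' (optionally) assign income tertiles before the estimation filter, keep
#' focal-good consumers in clusters with at least `min_consumers` of them,
#' and estimate -- overall or by tertile.
#'
#' @param config a [synthetic_config()].
#' @param by_tertile estimate per income tertile (tertiles assigned on the
#'   pre-filter sample so groups match the generator's prevalence gates)
#'   instead of the full sample.
#' @param n_draws bootstrap draws (0 to skip).
#' @param min_consumers estimation filter threshold.
#' @return list with `fit` (an `elasticity_estimate`, or a list of them for
#'   `by_tertile`), `truth` (the generator's `synthetic_truth`) and
#'   `n_clusters_retained`.
#' @export
simulate_and_estimate <- function(config, by_tertile = FALSE, n_draws = 0,
                                  min_consumers = 2) {
  sim <- generate_households(config)
  prep <- compute_shares_unitvalues(sim$records, goods = config$goods)
  if (by_tertile) prep <- assign_income_tertiles(prep)
  prep <- filter_for_estimation(prep, focal_good = config$goods[1],
                                min_consumers = min_consumers)
  fit <- if (by_tertile) {
    estimate_by_group(prep, grouping = "tertile", n_draws = n_draws,
                      seed = config$seed)
  } else {
    deaton_elasticity(prep, n_draws = n_draws, seed = config$seed)
  }
  list(fit = fit, truth = sim$truth,
       n_clusters_retained = length(unique(prep$data$cluster_id)))
}

#' Replicated recovery of the overall own-price elasticity
#'
#' Runs the headline recovery experiment over independent seeds and reports
#' per replicate the estimated focal-good own-price elasticity, its
#' bootstrap standard error and whether the normal-approximation 95%
#' bootstrap interval covers the truth.
#'
#' @param n_seeds number of independent replicates.
#' @param seed base seed; replicate r uses `seed * 1000 + r`.
#' @param n_clusters,households_per_cluster survey scale per replicate.
#' @param n_draws bootstrap draws per replicate.
#' @param own_price_elasticity ground truth.
#' @return data.frame with one row per replicate and attributes `truth`.
#' @export
elasticity_recovery_experiment <- function(n_seeds = 20, seed = 1,
                                           n_clusters = 25428,
                                           households_per_cluster = 8,
                                           n_draws = 1000,
                                           own_price_elasticity = -0.94) {
  rows <- lapply(seq_len(n_seeds), function(r) {
    cfg <- recovery_config("headline", seed = seed * 1000L + r,
                           n_clusters = n_clusters,
                           households_per_cluster = households_per_cluster,
                           own_price_elasticity = own_price_elasticity)
    res <- simulate_and_estimate(cfg, n_draws = n_draws)
    est <- res$fit$E[1, 1]
    se <- if (!is.null(res$fit$se_E)) res$fit$se_E[1, 1] else NA_real_
    data.frame(
      replicate = r, seed = cfg$seed, estimate = est, se = se,
      ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
      covered = is.finite(se) &&
        own_price_elasticity >= est - 1.96 * se &&
        own_price_elasticity <= est + 1.96 * se,
      n_clusters_retained = res$n_clusters_retained
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- own_price_elasticity
  out
}

#' Replicated recovery of tertile-specific own-price elasticities
#'
#' Runs the tertile recovery experiment over independent seeds; per
#' replicate the three group estimates are recorded, for checking that the
#' low > middle > high elasticity-magnitude gradient is recovered.
#'
#' @inheritParams elasticity_recovery_experiment
#' @param tertile_elasticities length-3 ground truth (low, middle, high).
#' @param n_draws bootstrap draws per group (0 to skip).
#' @return data.frame with one row per replicate (columns `low`, `middle`,
#'   `high`) and attribute `truth`.
#' @export
tertile_recovery_experiment <- function(n_seeds = 20, seed = 1,
                                        n_clusters = 25428,
                                        households_per_cluster = 8,
                                        n_draws = 0,
                                        tertile_elasticities = c(-1.035, -0.913, -0.832)) {
  rows <- lapply(seq_len(n_seeds), function(r) {
    cfg <- recovery_config("tertile", seed = seed * 1000L + r,
                           n_clusters = n_clusters,
                           households_per_cluster = households_per_cluster,
                           tertile_elasticities = tertile_elasticities)
    res <- simulate_and_estimate(cfg, by_tertile = TRUE, n_draws = n_draws)
    get1 <- function(g) if (is.null(res$fit[[g]])) NA_real_ else res$fit[[g]]$E[1, 1]
    data.frame(replicate = r, seed = cfg$seed,
               low = get1("low"), middle = get1("middle"), high = get1("high"),
               n_clusters_retained = res$n_clusters_retained)
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- stats::setNames(tertile_elasticities,
                                        c("low", "middle", "high"))
  out
}
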