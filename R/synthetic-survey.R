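#' Demand coefficients implied by a target elasticity matrix
#'
#' Maps a G x G price-elasticity matrix `E` (row i, column j = effect of the
#' price of good j on the quantity of good i) into the share-equation and
#' unit-value-equation price-response matrices of the two-equation demand
#' system
#' \deqn{\Theta = D(\bar w)(I + E), \qquad \Psi = I + D(\zeta) E,}
#' where \eqn{\zeta = \beta^1 / \epsilon_x} is the quality elasticity and
#' \eqn{\epsilon_x = 1 + \beta^0/\bar w - \beta^1} the expenditure
#' elasticity. Surveys generated with these coefficients carry `E` as their
#' ground truth, so estimator recovery can be checked exactly.
#'
#' @param elasticity G x G numeric matrix of target price elasticities.
#' @param mean_share per-good average budget share \eqn{\bar w} in (0,1).
#' @param beta0 per-good share-equation expenditure coefficient.
#' @param beta1 per-good unit-value expenditure coefficient (log-log).
#' @return list with matrices `theta` (share responses to log prices) and
#'   `psi` (log unit-value responses to log prices), plus `eps_x` and `zeta`.
#' @export
implied_theta_psi <- function(elasticity, mean_share, beta0 = 0, beta1 = 0) {
  E <- as.matrix(elasticity)
  G <- nrow(E)
  stopifnot(ncol(E) == G)
  w <- rep_len(mean_share, G)
  b0 <- rep_len(beta0, G)
  b1 <- rep_len(beta1, G)
  if (any(w <= 0 | w >= 1)) stop("mean shares must lie in (0, 1)")
  eps_x <- 1 + b0 / w - b1
  if (any(eps_x == 0)) stop("expenditure elasticity of zero: quality elasticity undefined")
  zeta <- b1 / eps_x
  theta <- diag(w, G) %*% (diag(G) + E)
  psi <- diag(G) + diag(zeta, G) %*% E
  if (abs(det(psi)) < 1e-12) stop("implied unit-value response matrix is singular")
  dimnames(theta) <- dimnames(psi) <- dimnames(E)
  list(theta = theta, psi = psi, eps_x = eps_x, zeta = zeta)
}

# Default elasticity matrix for the four beverage groups (aerated beverages,
# fruit juice, liquid milk, tea): own-price elasticity of aerated beverages
# near -0.94, juice and tea substitutes, milk a complement -- the patterns
# reported for Indian household expenditure surveys.
default_beverage_elasticity <- function() {
  g <- c("asb", "juice", "milk", "tea")
  matrix(c(
    -0.944, 0.206, -1.807, 0.271,
    1.533, -0.550, -0.130, -0.164,
    -0.339, -0.001, -0.389, 0.208,
    0.541, -0.041, 2.250, -0.989
  ), 4, 4, byrow = TRUE, dimnames = list(g, g))
}

#' Configuration of the synthetic household expenditure survey
#'
#' Defines the data-generating process for a clustered expenditure survey:
#' each cluster (village/urban block) draws one log market price per good;
#' households draw total expenditure, covariates and a purchase indicator
#' per good (a Bernoulli gate with income-tertile-specific prevalence); for
#' purchasers the log unit value follows
#' \eqn{\ln v = \alpha^1 + \beta^1 \ln x + \gamma^1 z + \Psi \ln\pi_c + u^1}
#' and the budget share follows
#' \eqn{w = \alpha^0 + \beta^0 \ln x + \gamma^0 z + \Theta \ln\pi_c + f_c + u^0},
#' with quantity and expenditure back-computed so that
#' expenditure/quantity = unit value and expenditure/total = share exactly.
#'
#' Defaults emulate the consumption patterns of Indian household expenditure
#' surveys pooled over two rounds: roughly 25,000 clusters of 8 households,
#' aerated-beverage purchase prevalence rising from about 1% of low-income
#' to about 10% of high-income households, budget shares falling with
#' income, and between-cluster price dispersion calibrated so that about
#' 69% of log unit-value variance lies between clusters.
#'
#' @param n_clusters number of clusters (primary sampling units).
#' @param households_per_cluster fixed count, or `c(min, max)` for a uniform
#'   integer draw per cluster.
#' @param goods ordered character vector of good labels.
#' @param mean_log_price per-good mean log price \eqn{\mu} (log INR/litre).
#' @param price_sd_between per-good between-cluster SD of log price
#'   \eqn{\sigma_\pi}.
#' @param mean_share per-good average budget share among purchasers.
#' @param beta0,beta1 per-good expenditure coefficients of the share and
#'   unit-value equations.
#' @param gamma0,gamma1 G x 3 covariate coefficient matrices on
#'   (log household size, number of children, education years); default 0.
#' @param elasticity G x G target price-elasticity matrix; used with
#'   [implied_theta_psi()] to build `theta` and `psi` unless those are given
#'   directly.
#' @param theta,psi optional explicit G x G price-response matrices.
#' @param theta_by_tertile optional list of three G x G share-response
#'   matrices (low, middle, high income), for experiments with
#'   tertile-specific price responses.
#' @param sigma_u0,sigma_u1 per-good within-cluster noise SDs of the share
#'   and log unit-value equations (these absorb measurement error).
#' @param sigma_f per-good SD of the cluster fixed effect in the share
#'   equation.
#' @param prevalence_by_tertile G x 3 matrix of purchase probabilities by
#'   income tertile (columns low, middle, high).
#' @param log_expenditure_mean_sd mean and SD of log total monthly
#'   household expenditure.
#' @param covariate_means centring constants for the three covariates.
#' @param seed integer RNG seed; every stochastic draw derives from it.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_clusters = 25428,
                             households_per_cluster = 8,
                             goods = c("asb", "juice", "milk", "tea"),
                             mean_log_price = c(asb = log(47), juice = log(65),
                                                milk = log(25.5), tea = log(3.7)),
                             price_sd_between = c(asb = 0.20, juice = 0.20,
                                                  milk = 0.15, tea = 0.15),
                             mean_share = c(asb = 0.017, juice = 0.019,
                                            milk = 0.092, tea = 0.030),
                             beta0 = c(asb = -0.008, juice = -0.008,
                                       milk = -0.002, tea = -0.020),
                             beta1 = c(asb = 0.02, juice = 0.10,
                                       milk = 0.06, tea = 0.10),
                             gamma0 = NULL,
                             gamma1 = NULL,
                             elasticity = NULL,
                             theta = NULL,
                             psi = NULL,
                             theta_by_tertile = NULL,
                             sigma_u0 = c(asb = 0.006, juice = 0.006,
                                          milk = 0.030, tea = 0.010),
                             sigma_u1 = NULL,
                             sigma_f = c(asb = 0.003, juice = 0.003,
                                         milk = 0.015, tea = 0.005),
                             prevalence_by_tertile = NULL,
                             log_expenditure_mean_sd = c(9.37, 0.55),
                             covariate_means = c(log(4.5), 1.2, 7),
                             seed = 1L) {
  if (length(goods) < 1L) stop("invalid config: goods list must be non-empty")
  if (anyDuplicated(goods)) stop("invalid config: duplicated good labels")
  G <- length(goods)
  if (!is.numeric(n_clusters) || n_clusters < 1) {
    stop("invalid config: n_clusters must be positive")
  }
  # the named per-good defaults describe the four standard beverage groups;
  # for other goods lists, untouched defaults fall back to generic scalars
  fallback <- function(x, is_missing, value) {
    if (is_missing && !is.null(names(x)) && !all(goods %in% names(x))) {
      rep(value, G)
    } else {
      x
    }
  }
  mean_log_price <- fallback(mean_log_price, missing(mean_log_price), log(47))
  price_sd_between <- fallback(price_sd_between, missing(price_sd_between), 0.2)
  mean_share <- fallback(mean_share, missing(mean_share), 0.02)
  beta0 <- fallback(beta0, missing(beta0), 0)
  beta1 <- fallback(beta1, missing(beta1), 0)
  sigma_u0 <- fallback(sigma_u0, missing(sigma_u0), 0.01)
  sigma_f <- fallback(sigma_f, missing(sigma_f), 0.003)
  mu <- pergood(mean_log_price, goods, "mean_log_price")
  sdp <- pergood(price_sd_between, goods, "price_sd_between")
  w <- pergood(mean_share, goods, "mean_share")
  b0 <- pergood(beta0, goods, "beta0")
  b1 <- pergood(beta1, goods, "beta1")
  s0 <- pergood(sigma_u0, goods, "sigma_u0")
  s1 <- if (is.null(sigma_u1)) {
    # within-cluster unit-value noise tied to between-cluster price
    # dispersion so the between-cluster share of log unit-value variance
    # is ~69% (the dummy-variable R^2 sits above this at small
    # per-cluster purchaser counts)
    sdp * sqrt(0.31 / 0.69)
  } else {
    pergood(sigma_u1, goods, "sigma_u1")
  }
  sf <- pergood(sigma_f, goods, "sigma_f")
  if (any(c(sdp, s0, s1, sf) < 0)) stop("invalid config: SDs must be >= 0")
  if (any(w <= 0 | w >= 1)) stop("invalid config: mean shares must lie in (0,1)")
  if (sum(w) >= 1) stop("invalid config: mean shares must sum to < 1")
  if (is.null(prevalence_by_tertile)) {
    default_prev <- rbind(
      asb = c(0.010, 0.031, 0.103),
      juice = c(0.008, 0.020, 0.077),
      milk = c(0.650, 0.875, 0.940),
      tea = c(0.350, 0.440, 0.490)
    )
    prevalence_by_tertile <- if (all(goods %in% rownames(default_prev))) {
      default_prev
    } else {
      matrix(0.5, G, 3)
    }
  }
  prev <- pergood_matrix(prevalence_by_tertile, goods, 3L, "prevalence_by_tertile")
  if (any(prev < 0 | prev > 1)) stop("invalid config: prevalence must lie in [0,1]")
  g0 <- if (is.null(gamma0)) matrix(0, G, 3) else pergood_matrix(gamma0, goods, 3L, "gamma0")
  g1 <- if (is.null(gamma1)) matrix(0, G, 3) else pergood_matrix(gamma1, goods, 3L, "gamma1")

  if (is.null(theta) || is.null(psi)) {
    E <- if (is.null(elasticity)) {
      defE <- default_beverage_elasticity()
      if (all(goods %in% rownames(defE))) {
        defE[goods, goods, drop = FALSE]
      } else {
        diag(-0.9, G)
      }
    } else {
      em <- as.matrix(elasticity)
      if (nrow(em) != G || ncol(em) != G) stop("invalid config: elasticity must be G x G")
      em
    }
    tp <- implied_theta_psi(E, w, b0, b1)
    if (is.null(theta)) theta <- tp$theta
    if (is.null(psi)) psi <- tp$psi
  }
  theta <- unname(as.matrix(theta))
  psi <- unname(as.matrix(psi))
  if (any(dim(theta) != G) || any(dim(psi) != G)) {
    stop("invalid config: theta and psi must be G x G")
  }
  if (!is.null(theta_by_tertile)) {
    stopifnot(is.list(theta_by_tertile), length(theta_by_tertile) == 3L)
    theta_by_tertile <- lapply(theta_by_tertile, function(m) {
      m <- unname(as.matrix(m))
      if (any(dim(m) != G)) stop("invalid config: theta_by_tertile entries must be G x G")
      m
    })
  }
  hpc <- as.integer(households_per_cluster)
  if (any(hpc < 1) || !length(hpc) %in% 1:2) {
    stop("invalid config: households_per_cluster must be a positive count or range")
  }
  structure(list(
    n_clusters = as.integer(n_clusters),
    households_per_cluster = hpc,
    goods = goods,
    mean_log_price = mu, price_sd_between = sdp,
    mean_share = w, beta0 = b0, beta1 = b1,
    gamma0 = g0, gamma1 = g1,
    theta = theta, psi = psi, theta_by_tertile = theta_by_tertile,
    sigma_u0 = s0, sigma_u1 = s1, sigma_f = sf,
    prevalence_by_tertile = prev,
    log_expenditure_mean_sd = as.numeric(log_expenditure_mean_sd),
    covariate_means = as.numeric(covariate_means),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Draw cluster-level log market prices
#'
#' One log price per cluster and good: \eqn{\ln\pi_{cG} = \mu_G +
#' N(0, \sigma_{\pi,G})}. All households of a cluster face this price; the
#' estimator exploits exactly this between-cluster variation.
#'
#' @param config a [synthetic_config()].
#' @return `n_clusters` x G matrix of log prices (columns named by good).
#' @export
generate_cluster_prices <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  C <- config$n_clusters
  G <- length(config$goods)
  eps <- matrix(stats::rnorm(C * G), C, G)
  lnp <- eps * rep(config$price_sd_between, each = C) +
    rep(config$mean_log_price, each = C)
  colnames(lnp) <- config$goods
  lnp
}

#' Generate a synthetic household expenditure survey with known truth
#'
#' Samples a full survey table from the two-equation demand system of the
#' configuration (see [synthetic_config()]) and returns it in the documented
#' survey schema together with a ground-truth object: the cluster log
#' prices, the true price-elasticity matrix implied by the generating
#' coefficients, and the true expenditure and quality elasticities.
#'
#' Share realisations falling outside (0, 1) are clipped to the boundary
#' (and counted); a clip fraction above 5% raises a warning and is flagged
#' in the truth object.
#'
#' @param config a [synthetic_config()].
#' @return list with `records` (data.frame, one row per household, the
#'   survey CSV schema) and `truth` (class `synthetic_truth`).
#' @export
generate_households <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lnp <- generate_cluster_prices(config) # seeds the stream; prices drawn first
  C <- config$n_clusters
  G <- length(config$goods)
  hpc <- config$households_per_cluster
  sizes <- if (length(hpc) == 1L) rep.int(hpc, C) else
    sample(seq(hpc[1], hpc[2]), C, replace = TRUE)
  n <- sum(sizes)
  cluster <- rep.int(seq_len(C), sizes)

  lnx <- stats::rnorm(n, config$log_expenditure_mean_sd[1], config$log_expenditure_mean_sd[2])
  x <- exp(lnx)
  hh_size <- 1L + stats::rpois(n, 3.5)
  n_children <- pmin(stats::rpois(n, 1.2), pmax(hh_size - 1L, 0L))
  educ <- pmax(0, stats::rnorm(n, 7, 4))
  Z <- cbind(log(hh_size), n_children, educ)
  Zc <- sweep(Z, 2, config$covariate_means)

  tert <- tertile_assign(x, seq_len(n))
  ti <- as.integer(tert)
  buy <- matrix(stats::runif(n * G), n, G) <
    t(config$prevalence_by_tertile)[ti, , drop = FALSE]

  LPc <- sweep(lnp, 2, config$mean_log_price)[cluster, , drop = FALSE]
  fc <- matrix(stats::rnorm(C * G), C, G) * rep(config$sigma_f, each = C)
  Fe <- fc[cluster, , drop = FALSE]
  U0 <- matrix(stats::rnorm(n * G), n, G) * rep(config$sigma_u0, each = n)
  U1 <- matrix(stats::rnorm(n * G), n, G) * rep(config$sigma_u1, each = n)
  dlnx <- lnx - config$log_expenditure_mean_sd[1]

  if (is.null(config$theta_by_tertile)) {
    P0 <- LPc %*% t(config$theta)
  } else {
    P0 <- matrix(0, n, G)
    for (k in 1:3) {
      r <- ti == k
      P0[r, ] <- LPc[r, , drop = FALSE] %*% t(config$theta_by_tertile[[k]])
    }
  }
  W <- matrix(config$mean_share, n, G, byrow = TRUE) + outer(dlnx, config$beta0) +
    Zc %*% t(config$gamma0) + P0 + Fe + U0
  LV <- matrix(config$mean_log_price, n, G, byrow = TRUE) + outer(dlnx, config$beta1) +
    Zc %*% t(config$gamma1) + LPc %*% t(config$psi) + U1

  clip_eps <- 1e-4
  out_of_range <- buy & (W <= 0 | W >= 1)
  n_clipped <- sum(out_of_range)
  n_purchases <- sum(buy)
  clip_fraction <- if (n_purchases > 0) n_clipped / n_purchases else 0
  W <- pmin(pmax(W, clip_eps), 1 - clip_eps)

  expenditure <- ifelse(buy, W * x, 0)
  quantity <- ifelse(buy, expenditure / exp(LV), 0)

  round_c <- ifelse(seq_len(C) <= ceiling(C / 2), "66", "68")
  sector_c <- sample(c("rural", "urban"), C, replace = TRUE, prob = c(0.59, 0.41))
  subround_c <- sample(1:4, C, replace = TRUE)

  records <- data.frame(
    household_id = seq_len(n),
    cluster_id = cluster,
    round = round_c[cluster],
    subround = subround_c[cluster],
    sector = sector_c[cluster],
    weight = 1,
    total_expenditure = x,
    household_size = hh_size,
    n_children = n_children,
    head_gender = sample(c("male", "female"), n, replace = TRUE, prob = c(0.88, 0.12)),
    social_group = sample(paste0("group", 1:4), n, replace = TRUE),
    religion = sample(paste0("rel", 1:3), n, replace = TRUE),
    household_type = sample(paste0("type", 1:4), n, replace = TRUE),
    education_years = educ,
    stringsAsFactors = FALSE
  )
  for (j in seq_len(G)) {
    records[[paste0("quantity_", config$goods[j])]] <- quantity[, j]
    records[[paste0("expenditure_", config$goods[j])]] <- expenditure[, j]
  }

  truth <- structure(list(
    cluster_log_prices = lnp,
    true_price_elasticity = true_elasticities(config),
    true_price_elasticity_by_tertile = if (!is.null(config$theta_by_tertile)) {
      stats::setNames(lapply(config$theta_by_tertile, function(th) {
        cfg <- config
        cfg$theta <- th
        true_elasticities(cfg)
      }), c("low", "middle", "high"))
    },
    true_expenditure_elasticity = 1 + config$beta0 / config$mean_share - config$beta1,
    true_quality_elasticity = config$beta1 /
      (1 + config$beta0 / config$mean_share - config$beta1),
    clip_fraction = clip_fraction,
    clip_warning = clip_fraction > 0.05,
    config_echo = config
  ), class = "synthetic_truth")
  if (truth$clip_warning) {
    warning(sprintf("%.1f%% of generated budget shares were clipped into (0,1)",
                    100 * clip_fraction))
  }
  list(records = records, truth = truth)
}

#' True price-elasticity matrix implied by a configuration
#'
#' Inverts the demand-coefficient mapping of [implied_theta_psi()]: from the
#' configured \eqn{(\Theta, \Psi, \bar w, \beta^0, \beta^1)} it returns the
#' elasticity matrix `E` solving \eqn{\Theta\Psi^{-1} = D(\bar w)(I + E)
#' (I + D(\zeta)E)^{-1}}. When \eqn{\Psi = I} (no quality shading) this
#' reduces exactly to \eqn{E = D(\bar w)^{-1}\Theta - I}.
#'
#' @param config a [synthetic_config()].
#' @param theta optional override of the share-response matrix (used for
#'   tertile-specific truths).
#' @return G x G elasticity matrix, rows and columns named by good.
#' @export
true_elasticities <- function(config, theta = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  w <- config$mean_share
  if (any(w <= 0)) stop("degenerate mean share: zero mean budget share")
  th <- theta %||% config$theta
  G <- length(w)
  if (max(abs(config$psi - diag(G))) < 1e-12) {
    E <- diag(1 / w, G) %*% th - diag(G)
  } else {
    B <- th %*% solve(config$psi)
    E <- elasticity_transform(B, list(beta0 = config$beta0, beta1 = config$beta1,
                                      mean_share = w))$E
  }
  dimnames(E) <- list(config$goods, config$goods)
  E
}

#' Configuration of the synthetic annual price/GDP series
#'
#' Deterministic compounding series feeding the affordability analysis: a
#' nominal retail price with a constant real annual change, a CPI index
#' compounding at the inflation rate, and nominal per-capita GDP compounding
#' at inflation times real growth. Defaults emulate a 13-year span with real
#' per-capita GDP growth of 4.9%/yr and a mild real price decline.
#'
#' @param start_year first fiscal year (labelled "YYYY/YY+1").
#' @param n_years number of years (>= 2).
#' @param initial_nominal_price INR per litre in the first year.
#' @param real_price_annual_change real price change per year (fraction).
#' @param inflation_rate CPI inflation per year (fraction).
#' @param initial_gdp_pc nominal per-capita GDP in the first year (INR/yr).
#' @param real_gdp_growth real per-capita GDP growth per year (fraction).
#' @param price_noise_sd optional lognormal noise SD on the nominal price.
#' @param seed RNG seed (used only when `price_noise_sd > 0`).
#' @return object of class `series_config`.
#' @export
series_config <- function(start_year = 2006, n_years = 13,
                          initial_nominal_price = 33,
                          real_price_annual_change = -0.022,
                          inflation_rate = 0.065,
                          initial_gdp_pc = 33000,
                          real_gdp_growth = 0.049,
                          price_noise_sd = 0,
                          seed = 1L) {
  if (n_years < 2) stop("invalid config: n_years must be >= 2")
  if (initial_nominal_price <= 0 || initial_gdp_pc <= 0) {
    stop("invalid config: prices and GDP must be positive")
  }
  structure(as.list(environment()), class = "series_config")
}

#' Generate the annual price / CPI / GDP table
#'
#' @param config a [series_config()].
#' @return data.frame with columns `year` (fiscal label), `nominal_price`
#'   (INR/litre), `cpi_index` (first year = 100) and `gdp_pc` (nominal
#'   INR/yr).
#' @export
generate_price_gdp_series <- function(config) {
  stopifnot(inherits(config, "series_config"))
  t <- seq_len(config$n_years) - 1
  yr <- config$start_year + t
  price <- config$initial_nominal_price *
    ((1 + config$inflation_rate) * (1 + config$real_price_annual_change))^t
  if (config$price_noise_sd > 0) {
    set.seed(config$seed)
    price <- price * exp(stats::rnorm(length(t), 0, config$price_noise_sd))
  }
  data.frame(
    year = sprintf("%d/%02d", yr, (yr + 1) %% 100),
    nominal_price = price,
    cpi_index = 100 * (1 + config$inflation_rate)^t,
    gdp_pc = config$initial_gdp_pc *
      ((1 + config$inflation_rate) * (1 + config$real_gdp_growth))^t,
    stringsAsFactors = FALSE
  )
}
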