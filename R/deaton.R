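# Two-stage between-cluster estimator of a beverage demand system from
# household budget shares and unit values, with cluster fixed effects,
# errors-in-variables correction of cluster-average unit values, and a
# quality-shading adjustment mapping share responses into price elasticities.

.design_matrix <- function(prepared) {
  d <- prepared$data
  X <- cbind(lnx = d$lnx, as.matrix(d[prepared$covariates]))
  storage.mode(X) <- "double"
  X
}

# Within-cluster OLS of y on X (cluster fixed effects by demeaning).
# Rows with NA in y are excluded; demeaning happens within the used rows.
.fit_within <- function(y, X, cl) {
  use <- which(is.finite(y))
  if (!length(use)) return(NULL)
  f <- cl[use]
  Xw <- demean_within(X[use, , drop = FALSE], f)
  yw <- demean_within(y[use], f)
  qx <- qr(Xw)
  if (qx$rank < ncol(Xw)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(Xw))]]
    stop("rank-deficiency error: collinear regressor(s) after demeaning: ",
         paste(bad, collapse = ", "))
  }
  b <- qr.coef(qx, yw)
  r <- yw - Xw %*% b
  list(b = as.vector(b), idx = use, resid = as.vector(r),
       n = length(use), n_clusters = length(unique(f)))
}

# Share-equation stage 1 over `rows` (all retained households by default)
.share_stage1 <- function(prepared, rows = NULL) {
  d <- prepared$data
  X <- .design_matrix(prepared)
  goods <- prepared$goods
  n <- nrow(d)
  G <- length(goods)
  k <- ncol(X)
  rows <- rows %||% rep(TRUE, n)
  resid <- matrix(NA_real_, n, G)
  b <- matrix(NA_real_, k, G, dimnames = list(colnames(X), goods))
  for (j in seq_len(G)) {
    y <- d[[paste0("share_", goods[j])]]
    y[!rows] <- NA_real_
    fit <- .fit_within(y, X, d$cluster_id)
    if (is.null(fit)) stop("no households available for the share equation of '",
                           goods[j], "'")
    b[, j] <- fit$b
    resid[fit$idx, j] <- fit$resid
  }
  shares <- as.matrix(d[rows, paste0("share_", goods), drop = FALSE])
  list(coef = b, resid = resid, w_bar = unname(colMeans(shares)),
       beta0 = unname(b["lnx", ]), n = sum(rows), k = k)
}

# Unit-value-equation stage 1 over purchasers of each good
.uv_stage1 <- function(prepared) {
  d <- prepared$data
  X <- .design_matrix(prepared)
  goods <- prepared$goods
  n <- nrow(d)
  G <- length(goods)
  k <- ncol(X)
  resid <- matrix(NA_real_, n, G)
  b <- matrix(NA_real_, k, G, dimnames = list(colnames(X), goods))
  n_purch <- integer(G)
  for (j in seq_len(G)) {
    y <- d[[paste0("lnuv_", goods[j])]]
    n_purch[j] <- sum(is.finite(y))
    if (n_purch[j] == 0L) next
    fit <- .fit_within(y, X, d$cluster_id)
    b[, j] <- fit$b
    resid[fit$idx, j] <- fit$resid
  }
  list(coef = b, resid = resid, beta1 = unname(b["lnx", ]),
       n_purch = n_purch, k = k)
}

# Residual covariance over pairwise-overlapping households, with a
# fixed-effects degrees-of-freedom correction (n - clusters - k).
.resid_cov <- function(RA, RB, cl, k) {
  G <- ncol(RA)
  H <- ncol(RB)
  out <- matrix(0, G, H)
  for (g in seq_len(G)) for (h in seq_len(H)) {
    ov <- which(is.finite(RA[, g]) & is.finite(RB[, h]))
    if (!length(ov)) next
    div <- max(length(ov) - length(unique(cl[ov])) - k, 1)
    out[g, h] <- sum(RA[ov, g] * RB[ov, h]) / div
  }
  out
}

#' Stage 1: within-cluster household regressions
#'
#' Estimates, with cluster fixed effects absorbed by within-cluster
#' demeaning, (i) the budget-share equation for every good over all retained
#' households and (ii) the log unit-value equation for every good over its
#' purchasers, on log total expenditure and the household covariates. Also
#' computes the within-cluster residual covariance matrices that feed the
#' measurement-error correction of stage 2.
#'
#' @param prepared a filtered `prepared_survey` (see
#'   [filter_for_estimation()]).
#' @return object of class `deaton_stage1`: coefficient matrices, residual
#'   tables, residual covariances `Sigma00`, `Sigma01` (unit-value x share)
#'   and `Sigma11`, mean shares and expenditure coefficients.
#' @export
deaton_stage1 <- function(prepared) {
  stopifnot(inherits(prepared, "prepared_survey"))
  d <- prepared$data
  if (length(unique(d$cluster_id)) < 2L) stop("stage 1 needs at least 2 clusters")
  goods <- prepared$goods
  uv <- .uv_stage1(prepared)
  if (any(uv$n_purch == 0L)) {
    dropped <- goods[uv$n_purch == 0L]
    warning("good(s) with zero purchasers dropped: ", paste(dropped, collapse = ", "))
    prepared$goods <- goods <- goods[uv$n_purch > 0L]
    uv <- .uv_stage1(prepared)
  }
  sh <- .share_stage1(prepared)
  cl <- d$cluster_id
  structure(list(
    goods = goods,
    covariates = prepared$covariates,
    coef0 = sh$coef, coef1 = uv$coef,
    beta0 = sh$beta0, beta1 = uv$beta1,
    gamma0 = sh$coef[-1, , drop = FALSE], gamma1 = uv$coef[-1, , drop = FALSE],
    mean_share = sh$w_bar,
    resid0 = sh$resid, resid1 = uv$resid,
    Sigma00 = .resid_cov(sh$resid, sh$resid, cl, sh$k),
    Sigma01 = .resid_cov(uv$resid, sh$resid, cl, sh$k),
    Sigma11 = .resid_cov(uv$resid, uv$resid, cl, uv$k),
    n_households = nrow(d), n_purchasers = uv$n_purch,
    k = sh$k, group = "full"
  ), class = "deaton_stage1")
}

#' Cluster-level purged moments
#'
#' Removes the household-level expenditure and covariate effects from
#' shares and log unit values using the stage-1 coefficients, then averages
#' within clusters: `y0` (purged average share over the share-side
#' households) and `y1` (purged average log unit value over purchasers --
#' the cluster price signal). Purchaser counts and pairwise purchase
#' overlaps per cluster are recorded for the attenuation corrections.
#'
#' @param stage1 a `deaton_stage1` fit (or the group-composite equivalent).
#' @param prepared the `prepared_survey` the fit came from.
#' @param rows0 optional logical selector of the households entering the
#'   share-side means (used by the income-group estimator; the unit-value
#'   side always pools all households of a cluster).
#' @return object of class `deaton_moments`.
#' @export
cluster_moments <- function(stage1, prepared, rows0 = NULL) {
  d <- prepared$data
  goods <- stage1$goods
  G <- length(goods)
  X <- .design_matrix(prepared)
  cl <- d$cluster_id
  levels <- sort(unique(cl))
  C <- length(levels)
  rows0 <- rows0 %||% rep(TRUE, nrow(d))

  shares <- as.matrix(d[paste0("share_", goods)])
  P0 <- shares - X %*% stage1$coef0
  y0 <- cluster_means(P0, cl, levels, use = which(rows0))
  n0 <- cluster_counts(cl, levels, use = which(rows0))

  lnuv <- as.matrix(d[paste0("lnuv_", goods)])
  P1 <- lnuv - X %*% stage1$coef1
  y1 <- matrix(NA_real_, C, G)
  n1 <- matrix(0L, C, G)
  n01 <- matrix(0L, C, G)
  purch <- is.finite(lnuv)
  for (j in seq_len(G)) {
    use <- which(purch[, j])
    y1[, j] <- cluster_means(P1[, j, drop = FALSE], cl, levels, use = use)
    n1[, j] <- cluster_counts(cl, levels, use = use)
    n01[, j] <- cluster_counts(cl, levels, use = which(purch[, j] & rows0))
  }
  n11 <- array(0L, c(C, G, G))
  for (g in seq_len(G)) for (h in seq_len(g)) {
    cnt <- cluster_counts(cl, levels, use = which(purch[, g] & purch[, h]))
    n11[, g, h] <- cnt
    n11[, h, g] <- cnt
  }
  colnames(y0) <- colnames(y1) <- goods
  structure(list(
    goods = goods, clusters = levels,
    y0 = y0, y1 = y1, n0 = n0, n1 = n1, n01 = n01, n11 = n11,
    Sigma01 = stage1$Sigma01, Sigma11 = stage1$Sigma11,
    n_clusters = C
  ), class = "deaton_moments")
}

# Between-cluster covariances and EIV-corrected slope matrix on a cluster
# subset (identity subset for the point estimate, resampled for bootstrap).
.stage2_core <- function(mo, idx = seq_len(mo$n_clusters), ridge = 0) {
  y0 <- mo$y0[idx, , drop = FALSE]
  y1 <- mo$y1[idx, , drop = FALSE]
  n0 <- mo$n0[idx]
  n1 <- mo$n1[idx, , drop = FALSE]
  n01 <- mo$n01[idx, , drop = FALSE]
  n11 <- mo$n11[idx, , , drop = FALSE]
  G <- ncol(y0)
  R <- M11 <- S <- M01 <- matrix(0, G, G)
  for (h in seq_len(G)) for (g in seq_len(G)) {
    v <- which(is.finite(y1[, h]) & is.finite(y1[, g]))
    if (length(v) < 3L) {
      stop("insufficient-variation error: < 3 clusters with unit values for pair (",
           mo$goods[h], ", ", mo$goods[g], ")")
    }
    R[h, g] <- stats::cov(y1[v, h], y1[v, g])
    M11[h, g] <- mo$Sigma11[h, g] * mean(n11[v, h, g] / (n1[v, h] * n1[v, g]))
    v2 <- which(is.finite(y1[, h]) & is.finite(y0[, g]))
    if (length(v2) < 3L) {
      stop("insufficient-variation error: < 3 clusters with shares and unit values for pair (",
           mo$goods[h], ", ", mo$goods[g], ")")
    }
    S[h, g] <- stats::cov(y1[v2, h], y0[v2, g])
    M01[h, g] <- mo$Sigma01[h, g] * mean(n01[v2, h] / (n1[v2, h] * n0[v2]))
  }
  A <- (R + t(R)) / 2 - (M11 + t(M11)) / 2
  if (ridge > 0) A <- A + diag(ridge, G)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("correction-overshoot error: (R - M11) is not positive definite; ",
         "a larger sample (or the ridge fallback) is needed")
  }
  B <- t(solve(A, S - M01))
  Bu <- t(solve((R + t(R)) / 2, S))
  dimnames(B) <- dimnames(Bu) <- list(mo$goods, mo$goods)
  list(B = B, B_uncorrected = Bu, R = R, M11 = M11, S = S, M01 = M01,
       n_clusters_used = length(idx))
}

#' Stage 2: errors-in-variables between-cluster regression
#'
#' Regresses the purged cluster-average shares on the purged cluster-average
#' log unit values across clusters, subtracting from the second-moment
#' matrices the attenuation terms implied by the within-cluster residual
#' covariances and purchaser counts:
#' \eqn{B^\top = (R - M_{11})^{-1}(S - M_{01})}. The returned `B` is
#' oriented so that entry (g, h) is the response of good-g's share to
#' good-h's (error-purged) log unit value, i.e. the estimate of
#' \eqn{\Theta\Psi^{-1}}.
#'
#' @param moments a `deaton_moments` object.
#' @param ridge optional non-negative ridge added to `(R - M11)`; off by
#'   default, and using it is reported loudly.
#' @return list with corrected `B`, uncorrected `B_uncorrected`, and the
#'   moment matrices `R`, `M11`, `S`, `M01`.
#' @export
deaton_stage2 <- function(moments, ridge = 0) {
  stopifnot(inherits(moments, "deaton_moments"))
  if (ridge > 0) {
    message(sprintf("NOTE: ridge fallback enabled in stage 2 (ridge = %g)", ridge))
  }
  .stage2_core(moments, ridge = ridge)
}

#' Map share responses into price elasticities
#'
#' From the corrected slope matrix `B` (share response to log unit values),
#' the mean shares and the stage-1 expenditure coefficients, computes the
#' expenditure elasticity \eqn{\epsilon_x = 1 + \beta^0/\bar w - \beta^1},
#' the quality elasticity \eqn{\zeta = \beta^1/\epsilon_x}, and the price
#' elasticity matrix solving the quality-shading system
#' \eqn{\Theta = D(\bar w)(I+E)}, \eqn{\Psi = I + D(\zeta)E},
#' \eqn{B = \Theta\Psi^{-1}}:
#' \deqn{E = (I - D(\bar w)^{-1} B D(\zeta))^{-1}(D(\bar w)^{-1} B - I).}
#' With \eqn{\zeta = 0} this reduces exactly to
#' \eqn{E = D(\bar w)^{-1}B - I}.
#'
#' @param B G x G corrected slope matrix from [deaton_stage2()].
#' @param stage1 a `deaton_stage1` fit, or any list with elements `beta0`,
#'   `beta1` and `mean_share`.
#' @param quality_correction set FALSE to force \eqn{\zeta = 0} (no
#'   quality-shading adjustment).
#' @return object of class `elasticity_estimate` with the elasticity matrix
#'   `E` (row i, column j = effect of the price of good j on the quantity of
#'   good i), expenditure and quality elasticities, `B` and mean shares.
#' @export
elasticity_transform <- function(B, stage1, quality_correction = TRUE) {
  w <- stage1$mean_share
  b0 <- stage1$beta0
  b1 <- stage1$beta1
  G <- length(w)
  if (any(w <= 0)) stop("degenerate-share error: zero mean budget share")
  B <- as.matrix(B)
  stopifnot(nrow(B) == G, ncol(B) == G)
  eps_x <- 1 + b0 / w - b1
  zeta <- if (quality_correction) b1 / eps_x else rep(0, G)
  DwB <- B / w # row i divided by w[i]: D(w)^{-1} B
  if (all(zeta == 0)) {
    E <- DwB - diag(G)
  } else {
    A <- diag(G) - DwB %*% diag(zeta, G)
    rc <- rcond(A)
    if (rc < 1e-12) {
      stop(sprintf("quality-correction singularity: rcond(I - D(w)^-1 B D(zeta)) = %.3e", rc))
    }
    E <- solve(A, DwB - diag(G))
  }
  dimnames(E) <- dimnames(B)
  structure(list(
    E = E, expenditure_elasticity = eps_x, quality_elasticity = zeta,
    B = B, mean_share = w, se_E = NULL, n_draws = 0L, seed = NA_integer_,
    group = stage1$group %||% "full"
  ), class = "elasticity_estimate")
}

#' Cluster bootstrap of the second stage
#'
#' Resamples clusters with replacement and recomputes the second-stage
#' moments, the EIV correction and the elasticity transform for each draw,
#' holding the stage-1 household coefficients fixed. The standard error is
#' the SD of the elasticity across draws; draws failing (e.g. a
#' non-positive-definite corrected moment matrix) are dropped and counted.
#'
#' @param moments a `deaton_moments` object.
#' @param stage1 the stage-1 fit the moments came from.
#' @param n_draws number of bootstrap draws.
#' @param seed RNG seed for the resampling.
#' @param quality_correction as in [elasticity_transform()].
#' @param keep_draws keep the G x G draw archive.
#' @param error_on_unstable escalate the >10%-failed-draws warning to an
#'   error.
#' @return list with `se_E`, counts of draws and failures, and optionally
#'   the `draws` array (n_draws x G x G).
#' @export
deaton_bootstrap <- function(moments, stage1, n_draws = 1000, seed = 1,
                             quality_correction = TRUE, keep_draws = FALSE,
                             error_on_unstable = FALSE) {
  stopifnot(inherits(moments, "deaton_moments"), n_draws >= 1)
  set.seed(seed)
  C <- moments$n_clusters
  G <- length(moments$goods)
  draws <- array(NA_real_, c(n_draws, G, G))
  fails <- 0L
  for (i in seq_len(n_draws)) {
    idx <- sample.int(C, C, replace = TRUE)
    Ei <- tryCatch(
      elasticity_transform(.stage2_core(moments, idx)$B, stage1,
                           quality_correction)$E,
      error = function(e) NULL
    )
    if (is.null(Ei)) fails <- fails + 1L else draws[i, , ] <- Ei
  }
  if (fails > 0.1 * n_draws) {
    msg <- sprintf("unstable bootstrap: %d of %d draws failed", fails, n_draws)
    if (error_on_unstable) stop(msg) else warning(msg)
  }
  se <- apply(draws, c(2, 3), stats::sd, na.rm = TRUE)
  dimnames(se) <- list(moments$goods, moments$goods)
  out <- list(se_E = se, n_draws = n_draws, n_failed = fails, seed = seed)
  if (keep_draws) out$draws <- draws
  out
}

#' Full two-stage price-elasticity estimate
#'
#' Runs stage 1 (within-cluster household regressions), the cluster purged
#' means, the EIV-corrected second stage and the quality-shading transform,
#' with an optional cluster bootstrap of the second stage for standard
#' errors.
#'
#' @param prepared a filtered `prepared_survey`.
#' @param n_draws bootstrap draws (0 for no bootstrap).
#' @param seed RNG seed for the bootstrap.
#' @param quality_correction as in [elasticity_transform()].
#' @param ridge optional stage-2 ridge fallback (off by default).
#' @return `elasticity_estimate` with bootstrap `se_E` when requested.
#' @export
deaton_elasticity <- function(prepared, n_draws = 1000, seed = 1,
                              quality_correction = TRUE, ridge = 0) {
  s1 <- deaton_stage1(prepared)
  mo <- cluster_moments(s1, prepared)
  core <- deaton_stage2(mo, ridge = ridge)
  est <- elasticity_transform(core$B, s1, quality_correction)
  est$B_uncorrected <- core$B_uncorrected
  est$n_clusters <- mo$n_clusters
  est$n_households <- s1$n_households
  if (n_draws > 0) {
    bt <- deaton_bootstrap(mo, s1, n_draws = n_draws, seed = seed,
                           quality_correction = quality_correction)
    est$se_E <- bt$se_E
    est$n_draws <- bt$n_draws
    est$n_failed_draws <- bt$n_failed
    est$seed <- seed
  }
  est
}

#' Elasticities by income tertile or sector
#'
#' Income-tertile estimation keeps the assumption that all households of a
#' cluster face the same price: the cluster price signal `y1` (purged
#' average log unit value) is computed from all households of the cluster
#' pooled across groups, while the share-side stage 1 and the purged share
#' means use each group's households only. Rural/urban estimation simply
#' splits clusters by sector and reruns the full pipeline.
#'
#' @param prepared a filtered `prepared_survey` (with `income_tertile`
#'   assigned for tertile grouping).
#' @param grouping `"tertile"` or `"sector"`.
#' @param n_draws bootstrap draws per group (0 to skip).
#' @param seed RNG seed for the bootstrap.
#' @param quality_correction as in [elasticity_transform()].
#' @param min_clusters groups represented in fewer clusters are skipped
#'   with a warning.
#' @return named list of `elasticity_estimate` objects (NULL for skipped
#'   groups).
#' @export
estimate_by_group <- function(prepared, grouping = c("tertile", "sector"),
                              n_draws = 0, seed = 1, quality_correction = TRUE,
                              min_clusters = 10) {
  grouping <- match.arg(grouping)
  d <- prepared$data
  if (grouping == "sector") {
    res <- list()
    for (s in sort(unique(d$sector))) {
      sub <- prepared
      sub$data <- d[d$sector == s, , drop = FALSE]
      res[[s]] <- tryCatch({
        est <- deaton_elasticity(sub, n_draws = n_draws, seed = seed,
                                 quality_correction = quality_correction)
        est$group <- s
        est
      }, error = function(e) {
        warning("sector '", s, "' skipped: ", conditionMessage(e))
        NULL
      })
    }
    return(res)
  }
  if (is.null(d$income_tertile)) {
    stop("assign_income_tertiles() must be called before tertile estimation")
  }
  uv <- .uv_stage1(prepared)
  Sigma11 <- .resid_cov(uv$resid, uv$resid, d$cluster_id, uv$k)
  res <- list()
  for (g in levels(d$income_tertile)) {
    rows <- d$income_tertile == g
    res[[g]] <- tryCatch({
      if (length(unique(d$cluster_id[rows])) < min_clusters) {
        stop("group present in fewer than ", min_clusters, " clusters")
      }
      sh <- .share_stage1(prepared, rows)
      s1 <- list(
        goods = prepared$goods, coef0 = sh$coef, coef1 = uv$coef,
        beta0 = sh$beta0, beta1 = uv$beta1, mean_share = sh$w_bar,
        Sigma01 = .resid_cov(uv$resid, sh$resid, d$cluster_id, sh$k),
        Sigma11 = Sigma11, group = g
      )
      mo <- cluster_moments(s1, prepared, rows0 = rows)
      est <- elasticity_transform(.stage2_core(mo)$B, s1, quality_correction)
      if (n_draws > 0) {
        bt <- deaton_bootstrap(mo, s1, n_draws = n_draws, seed = seed,
                               quality_correction = quality_correction)
        est$se_E <- bt$se_E
        est$n_draws <- bt$n_draws
        est$seed <- seed
      }
      est
    }, error = function(e) {
      warning("income group '", g, "' skipped: ", conditionMessage(e))
      NULL
    })
  }
  res
}

#' Share of log unit-value variance explained by clusters
#'
#' The coefficient of determination from regressing log unit values on
#' cluster indicator variables -- the share of unit-value variation
#' attributable to genuine between-cluster price variation (as opposed to
#' within-cluster quality choice and measurement error).
#'
#' @param prepared a `prepared_survey`.
#' @param good good label (default the focal good or the first good).
#' @return R-squared in `[0, 1]`.
#' @export
unitvalue_variance_r2 <- function(prepared,
                                  good = prepared$focal_good %||% prepared$goods[1]) {
  d <- prepared$data
  v <- d[[paste0("lnuv_", good)]]
  use <- is.finite(v)
  v <- v[use]
  cl <- d$cluster_id[use]
  if (length(unique(cl)) < 2L) stop("need purchasers in at least 2 clusters")
  tot <- sum((v - mean(v))^2)
  if (tot == 0) return(1)
  1 - sum(demean_within(v, cl)^2) / tot
}

#' @export
print.elasticity_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("Price elasticity matrix (%s sample)%s\n", x$group,
              if (!is.null(x$se_E)) sprintf(", bootstrap SEs from %d draws", x$n_draws) else ""))
  cat("(row i, column j: effect of the price of good j on the quantity of good i)\n")
  print(round(x$E, digits))
  if (!is.null(x$se_E)) {
    cat("standard errors:\n")
    print(round(x$se_E, digits))
  }
  cat("expenditure elasticity:", paste(round(x$expenditure_elasticity, digits),
                                       collapse = ", "), "\n")
  cat("quality elasticity:    ", paste(round(x$quality_elasticity, digits),
                                       collapse = ", "), "\n")
  invisible(x)
}
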