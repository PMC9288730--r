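# GST compensation-cess simulation: the incremental tax (and the cess rate
# it translates to) needed for a target reduction in beverage consumption,
# under alternative tax pass-through scenarios.

#' Tax burden implied by exclusive statutory rates
#'
#' India's GST rates are exclusive (applied to the net-of-tax price), so a
#' GST rate g plus a compensation cess c puts a tax share of
#' `(g + c) / (1 + g + c)` into the tax-inclusive retail price. At the
#' statutory 28% GST + 12% cess this is 40/140, about 28.6%.
#'
#' @param gst ad-valorem GST rate (fraction, e.g. 0.28).
#' @param cess ad-valorem compensation-cess rate (fraction, e.g. 0.12).
#' @return tax burden as a fraction of the retail price.
#' @export
burden_from_statutory <- function(gst, cess) {
  stopifnot(gst >= 0, cess >= 0)
  (gst + cess) / (1 + gst + cess)
}

#' Baseline state of the beverage market for the tax simulation
#'
#' Defaults reproduce the GST-era baseline used in the simulation: a 60
#' INR/litre average retail price, the 28.6% tax burden implied by 28% GST
#' + 12% cess, annual sales of 5,568 million litres, and an overall
#' own-price elasticity of -0.94.
#'
#' @param retail_price tax-inclusive retail price (INR/litre).
#' @param gst,cess statutory rates (fractions).
#' @param tax_burden tax as a fraction of the retail price; the default
#'   0.286 is the commonly quoted rounded burden, `NULL` uses the exact
#'   `burden_from_statutory(gst, cess)`.
#' @param consumption_volume annual sales (million litres).
#' @param elasticity overall own-price elasticity (negative).
#' @param demand_form `"constant_elasticity"` (log-form) or `"linear"`.
#' @return object of class `tax_baseline`.
#' @export
tax_baseline <- function(retail_price = 60, gst = 0.28, cess = 0.12,
                         tax_burden = 0.286, consumption_volume = 5568,
                         elasticity = -0.94,
                         demand_form = c("constant_elasticity", "linear")) {
  demand_form <- match.arg(demand_form)
  tax_burden <- tax_burden %||% burden_from_statutory(gst, cess)
  if (tax_burden <= 0 || tax_burden >= 1) stop("tax burden must lie in (0, 1)")
  if (consumption_volume <= 0) stop("consumption volume must be positive")
  if (elasticity >= 0) stop("own-price elasticity must be negative")
  structure(list(
    retail_price = retail_price, gst = gst, cess = cess,
    tax_burden = tax_burden, tax_per_litre = retail_price * tax_burden,
    consumption_volume = consumption_volume, elasticity = elasticity,
    demand_form = demand_form
  ), class = "tax_baseline")
}

#' Retail price achieving a target consumption reduction
#'
#' Constant-elasticity (log) demand: \eqn{p_1 = p_0 (1 - r)^{1/\epsilon}};
#' linear demand: \eqn{p_1 = p_0 (1 + r/|\epsilon|)}.
#'
#' @param p0 baseline retail price.
#' @param elasticity own-price elasticity (negative).
#' @param reduction target fractional consumption reduction in (0, 1);
#'   0 returns the baseline price.
#' @param demand_form `"constant_elasticity"` or `"linear"`.
#' @return the new retail price.
#' @export
price_target_for_reduction <- function(p0, elasticity, reduction,
                                       demand_form = c("constant_elasticity", "linear")) {
  demand_form <- match.arg(demand_form)
  if (elasticity >= 0) stop("own-price elasticity must be negative")
  if (reduction < 0 || reduction >= 1) stop("reduction must lie in [0, 1)")
  if (reduction == 0) return(p0)
  if (demand_form == "constant_elasticity") {
    p0 * (1 - reduction)^(1 / elasticity)
  } else {
    p0 * (1 + reduction / abs(elasticity))
  }
}

#' Simulate one tax pass-through scenario
#'
#' Finds the retail price delivering the target consumption reduction, the
#' tax increase needed to cause it at the given pass-through (the tax rises
#' by the price increase divided by the pass-through), and the resulting
#' burden, revenues, and the compensation cess that -- on top of the
#' unchanged statutory GST applied to the net-of-tax price -- yields the new
#' tax.
#'
#' @param baseline a [tax_baseline()].
#' @param passthrough fraction of a tax increase transmitted to the retail
#'   price, in (0, 1.5].
#' @param reduction target fractional consumption reduction.
#' @return one-row data.frame (class `tax_scenario`) with prices, taxes,
#'   volumes, revenues, percent changes and the required cess.
#' @export
simulate_scenario <- function(baseline, passthrough, reduction = 0.10) {
  stopifnot(inherits(baseline, "tax_baseline"))
  if (passthrough <= 0 || passthrough > 1.5) {
    stop("passthrough must lie in (0, 1.5]")
  }
  p0 <- baseline$retail_price
  t0 <- baseline$tax_per_litre
  v0 <- baseline$consumption_volume
  p1 <- price_target_for_reduction(p0, baseline$elasticity, reduction,
                                   baseline$demand_form)
  dt <- (p1 - p0) / passthrough
  t1 <- t0 + dt
  if (t1 >= p1) {
    stop(sprintf("infeasible scenario: required tax %.2f meets or exceeds the new retail price %.2f",
                 t1, p1))
  }
  v1 <- v0 * (1 - reduction)
  rev0 <- t0 * v0
  rev1 <- t1 * v1
  out <- data.frame(
    passthrough = passthrough,
    new_retail_price = p1,
    new_tax_per_litre = t1,
    new_tax_burden = t1 / p1,
    new_volume = v1,
    baseline_revenue = rev0,
    new_revenue = rev1,
    pct_change_price = 100 * (p1 / p0 - 1),
    pct_change_consumption = -100 * reduction,
    pct_change_revenue = 100 * (rev1 / rev0 - 1),
    pct_change_tax = 100 * (t1 / t0 - 1),
    absolute_tax_increase = dt,
    required_cess = t1 / (p1 - t1) - baseline$gst
  )
  class(out) <- c("tax_scenario", "data.frame")
  out
}

#' Scenario table across pass-through assumptions
#'
#' Runs [simulate_scenario()] for each pass-through value and stacks the
#' results, full precision. Use [format_tax_table()] for a display-rounded
#' version.
#'
#' @param baseline a [tax_baseline()].
#' @param passthroughs pass-through fractions (default 50%, 75%, 100%).
#' @param reduction target fractional consumption reduction.
#' @return data.frame, one row per scenario.
#' @export
tax_simulation_table <- function(baseline, passthroughs = c(0.5, 0.75, 1),
                                 reduction = 0.10) {
  do.call(rbind, lapply(passthroughs, function(pt) {
    simulate_scenario(baseline, pt, reduction)
  }))
}

#' Round a scenario table for display
#'
#' Prices and taxes per litre to one decimal, volumes and revenues to whole
#' millions, percents to whole numbers.
#'
#' @param tab output of [tax_simulation_table()].
#' @return rounded data.frame.
#' @export
format_tax_table <- function(tab) {
  out <- tab
  for (cn in c("new_retail_price", "new_tax_per_litre", "absolute_tax_increase")) {
    out[[cn]] <- round(out[[cn]], 1)
  }
  for (cn in c("new_volume", "baseline_revenue", "new_revenue")) {
    out[[cn]] <- round(out[[cn]])
  }
  for (cn in grep("^pct_change_", names(out), value = TRUE)) {
    out[[cn]] <- round(out[[cn]])
  }
  out$new_tax_burden <- round(100 * out$new_tax_burden)
  out$required_cess <- round(100 * out$required_cess)
  out
}

#' Consumption impact by income group
#'
#' Given the retail-price increase, income-group own-price elasticities and
#' each group's share of baseline consumption, returns each group's percent
#' consumption change under constant-elasticity demand,
#' \eqn{(1+\Delta p)^{\epsilon_g} - 1}, and the share-weighted overall
#' change.
#'
#' @param price_change_pct retail price increase in percent (e.g. 11.86).
#' @param group_elasticities named vector of negative own-price
#'   elasticities.
#' @param group_consumption_shares non-negative shares summing to 1.
#' @return list with per-group percent changes and the overall percent
#'   change.
#' @export
group_impacts <- function(price_change_pct, group_elasticities,
                          group_consumption_shares) {
  if (any(group_elasticities >= 0)) stop("group elasticities must be negative")
  if (any(group_consumption_shares < 0)) stop("consumption shares must be >= 0")
  if (abs(sum(group_consumption_shares) - 1) > 1e-9) {
    stop("consumption shares must sum to 1")
  }
  dp <- price_change_pct / 100
  change <- (1 + dp)^group_elasticities - 1
  list(
    group_change_pct = 100 * change,
    overall_change_pct = 100 * sum(group_consumption_shares * change)
  )
}

#' Income-group consumption shares from a prepared survey
#'
#' Each tertile's share of total purchased quantity of a good -- the
#' weights used when aggregating group-specific consumption responses.
#'
#' @param prepared a `prepared_survey` with `income_tertile` assigned.
#' @param good good label (default the focal or first good).
#' @return named numeric vector summing to 1.
#' @export
tertile_consumption_shares <- function(prepared,
                                       good = prepared$focal_good %||% prepared$goods[1]) {
  d <- prepared$data
  if (is.null(d$income_tertile)) stop("assign_income_tertiles() first")
  q <- d[[paste0("quantity_", good)]]
  tot <- tapply(q, d$income_tertile, sum)
  tot[is.na(tot)] <- 0
  if (sum(tot) <= 0) stop("no purchased quantity of '", good, "'")
  stats::setNames(as.numeric(tot) / sum(tot), names(tot))
}
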