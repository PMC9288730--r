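# Relative income price (RIP): the percentage of annual per-capita GDP
# needed to buy 100 litres of the beverage. A falling RIP means the product
# is becoming more affordable.

# pool multi-brand rows into one price per year (weighted by observation
# count when available)
.pool_prices <- function(series) {
  if (is.null(series$brand) || !anyDuplicated(series$year)) return(series)
  wts <- series$n_obs %||% rep(1, nrow(series))
  years <- unique(series$year)
  pooled <- lapply(years, function(y) {
    rows <- series$year == y
    data.frame(
      year = y,
      nominal_price = sum(series$nominal_price[rows] * wts[rows]) / sum(wts[rows]),
      cpi_index = series$cpi_index[rows][1],
      gdp_pc = series$gdp_pc[rows][1],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, pooled)
}

#' Relative income price of a beverage
#'
#' \eqn{RIP_t = 100 \times (price_t \times 100\,L) / GDP^{pc}_t}: the percent
#' of nominal per-capita GDP required to purchase 100 litres in year t.
#' Multi-brand inputs are pooled into one annual price first (weighted by
#' `n_obs` when present). The CPI column is used to carry a real price
#' alongside (base = first year).
#'
#' @param series data.frame with columns `year`, `nominal_price`
#'   (currency/litre), `cpi_index`, `gdp_pc` (currency/yr), optionally
#'   `brand` and `n_obs`.
#' @param litres reference quantity (100 L).
#' @return data.frame with `year`, `nominal_price`, `real_price`, `gdp_pc`,
#'   `rip` (percent).
#' @export
compute_rip <- function(series, litres = 100) {
  stopifnot(all(c("year", "nominal_price", "cpi_index", "gdp_pc") %in% names(series)))
  if (any(series$gdp_pc <= 0)) stop("non-positive GDP per capita")
  if (any(series$nominal_price <= 0)) stop("non-positive price")
  s <- .pool_prices(series)
  data.frame(
    year = s$year,
    nominal_price = s$nominal_price,
    real_price = s$nominal_price * s$cpi_index[1] / s$cpi_index,
    gdp_pc = s$gdp_pc,
    rip = 100 * (s$nominal_price * litres) / s$gdp_pc,
    stringsAsFactors = FALSE
  )
}

.check_year_gaps <- function(years) {
  y <- suppressWarnings(as.integer(substr(as.character(years), 1, 4)))
  if (anyNA(y)) return(invisible(TRUE)) # opaque labels: trust the row order
  d <- diff(y)
  if (any(d != 1)) {
    miss <- unlist(mapply(function(a, b) if (b - a > 1) seq(a + 1, b - 1),
                          y[-length(y)], y[-1]))
    stop("year gap(s) in the series: missing ", paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

#' Decompose annual RIP changes into price and income effects
#'
#' For every year after the first: the total percent change in RIP, the
#' price effect (percent change in the real price) and the income effect
#' (the remainder), so that price effect + income effect = RIP change
#' exactly. Percent changes are simple year-over-year arithmetic changes by
#' default; `log_exact = TRUE` uses log differences (which make the
#' decomposition exact in logs instead).
#'
#' @param rip_rows output of [compute_rip()] (needs `rip` and `real_price`).
#' @param log_exact use 100 x log differences instead of arithmetic percent
#'   changes.
#' @return the input with `rip_change_pct`, `price_effect_pct`,
#'   `income_effect_pct` columns (NA in the first row).
#' @export
decompose_rip_change <- function(rip_rows, log_exact = FALSE) {
  stopifnot(all(c("year", "rip", "real_price") %in% names(rip_rows)))
  n <- nrow(rip_rows)
  if (n < 2L) stop("decomposition needs at least 2 years")
  .check_year_gaps(rip_rows$year)
  pct <- function(x) {
    if (log_exact) 100 * diff(log(x)) else 100 * (x[-1] / x[-n] - 1)
  }
  rip_rows$rip_change_pct <- c(NA, pct(rip_rows$rip))
  rip_rows$price_effect_pct <- c(NA, pct(rip_rows$real_price))
  rip_rows$income_effect_pct <- rip_rows$rip_change_pct - rip_rows$price_effect_pct
  rip_rows
}

#' Geometric mean annual growth rate
#'
#' \eqn{(x_n/x_1)^{1/(n-1)} - 1} for a series of positive annual values.
#'
#' @param x positive numeric vector in year order.
#' @return growth rate as a fraction per year.
#' @export
mean_growth <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values")
  if (any(x <= 0)) stop("values must be positive")
  (x[length(x)] / x[1])^(1 / (length(x) - 1)) - 1
}

#' Affordability analysis of an annual price/GDP series
#'
#' Convenience wrapper: RIP computation followed by the price/income
#' decomposition.
#'
#' @inheritParams compute_rip
#' @inheritParams decompose_rip_change
#' @return data.frame of affordability rows.
#' @export
affordability <- function(series, litres = 100, log_exact = FALSE) {
  decompose_rip_change(compute_rip(series, litres = litres), log_exact = log_exact)
}
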