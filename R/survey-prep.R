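SURVEY_BASE_COLUMNS <- c(
  "household_id", "cluster_id", "round", "subround", "sector",
  "total_expenditure", "household_size", "n_children", "education_years"
)

# Good labels implied by quantity_*/expenditure_* column pairs, in column order
detect_goods <- function(columns) {
  q <- sub("^quantity_", "", grep("^quantity_", columns, value = TRUE))
  e <- sub("^expenditure_", "", grep("^expenditure_", columns, value = TRUE))
  g <- q[q %in% e]
  if (!length(g)) stop("schema error: no quantity_<good>/expenditure_<good> column pairs found")
  g
}

validate_survey <- function(records, goods) {
  miss <- setdiff(SURVEY_BASE_COLUMNS, names(records))
  if (length(miss)) {
    stop("schema error: missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  for (g in goods) {
    qc <- paste0("quantity_", g)
    ec <- paste0("expenditure_", g)
    if (!qc %in% names(records) || !ec %in% names(records)) {
      stop("schema error: missing per-good column(s) for '", g, "'")
    }
    q <- records[[qc]]
    e <- records[[ec]]
    bad <- which(q < 0 | e < 0)
    if (length(bad)) {
      stop("validation error: negative quantity/expenditure for '", g,
           "' in row(s) ", paste(utils::head(bad, 10), collapse = ", "))
    }
    mism <- which((e > 0) != (q > 0))
    if (length(mism)) {
      stop("validation error: expenditure/quantity purchase mismatch for '", g,
           "' in row(s) ", paste(utils::head(mism, 10), collapse = ", "))
    }
  }
  if (any(records$total_expenditure <= 0)) {
    stop("validation error: non-positive total_expenditure in row(s) ",
         paste(utils::head(which(records$total_expenditure <= 0), 10), collapse = ", "))
  }
  invisible(records)
}

#' Read a household expenditure survey from CSV
#'
#' The schema is one row per household with columns `household_id`,
#' `cluster_id`, `round`, `subround`, `sector`, `total_expenditure`,
#' `household_size`, `n_children`, `education_years`, optional `weight` and
#' category columns, and wide per-good pairs `quantity_<good>` /
#' `expenditure_<good>` (litres and INR per 30 days). Unknown columns are
#' preserved untouched.
#'
#' @param path CSV file path (header required).
#' @param goods good labels to validate; by default detected from the
#'   column pairs present.
#' @return data.frame of household records with attribute `goods`.
#' @export
read_survey <- function(path, goods = NULL) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  goods <- goods %||% detect_goods(names(records))
  validate_survey(records, goods)
  message(sprintf("read %d household records (%d goods) from %s",
                  nrow(records), length(goods), path))
  attr(records, "goods") <- goods
  records
}

#' Write a household expenditure survey to CSV
#'
#' @param records household records data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_survey <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Deflate expenditures to a base period
#'
#' Multiplies every expenditure column (per-good and total) by
#' `base_index / index(round, subround)` so that all currency values are in
#' base-period INR; quantities are unchanged, so unit values computed
#' afterwards are deflated too.
#'
#' @param records household records.
#' @param cpi_table data.frame with columns `round`, `subround`, `index`.
#' @param base_index index value of the base period.
#' @return records with deflated currency columns.
#' @export
deflate_unit_values <- function(records, cpi_table, base_index) {
  stopifnot(all(c("round", "subround", "index") %in% names(cpi_table)))
  if (base_index <= 0) stop("base_index must be positive")
  key <- paste(records$round, records$subround, sep = "|")
  tab <- stats::setNames(cpi_table$index,
                         paste(cpi_table$round, cpi_table$subround, sep = "|"))
  idx <- tab[key]
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop("deflation error: no CPI index for cell(s): ", paste(bad, collapse = ", "))
  }
  scale <- base_index / as.numeric(idx)
  goods <- attr(records, "goods") %||% detect_goods(names(records))
  for (cn in c("total_expenditure", paste0("expenditure_", goods))) {
    records[[cn]] <- records[[cn]] * scale
  }
  attr(records, "goods") <- goods
  records
}

#' Construct budget shares and unit values
#'
#' Builds the analysis table behind the demand estimator: per household and
#' good the budget share `expenditure / total_expenditure` (zero when the
#' good was not purchased) and the log unit value `log(expenditure /
#' quantity)` (defined only for purchasers), plus log total expenditure and
#' the household covariates (log household size, number of children,
#' education years). Expenditures are assumed already deflated to a common
#' base period.
#'
#' @param records household records (post-deflation).
#' @param goods good labels; default from the records.
#' @return object of class `prepared_survey`: a list with the wide `data`
#'   table, the ordered `goods`, and the covariate column names.
#' @export
compute_shares_unitvalues <- function(records, goods = NULL) {
  goods <- goods %||% attr(records, "goods") %||% detect_goods(names(records))
  validate_survey(records, goods)
  d <- records
  d$lnx <- log(d$total_expenditure)
  d$log_hh_size <- log(pmax(d$household_size, 1))
  for (g in goods) {
    e <- d[[paste0("expenditure_", g)]]
    q <- d[[paste0("quantity_", g)]]
    d[[paste0("share_", g)]] <- e / d$total_expenditure
    d[[paste0("lnuv_", g)]] <- ifelse(q > 0, log(e / q), NA_real_)
  }
  structure(list(
    data = d,
    goods = goods,
    covariates = c("log_hh_size", "n_children", "education_years"),
    focal_good = NULL,
    filtered = FALSE
  ), class = "prepared_survey")
}

#' Restrict the survey to the estimation sample
#'
#' Applies the estimation filter: households not purchasing the focal good
#' are dropped, and then clusters with fewer than `min_consumers` focal-good
#' purchasers are dropped. Counts of dropped households and clusters are
#' kept as attributes.
#'
#' @param prepared a `prepared_survey`.
#' @param focal_good good whose consumers define the sample (default the
#'   first good, aerated beverages).
#' @param min_consumers minimum focal-good purchasers per retained cluster.
#' @return filtered `prepared_survey`.
#' @export
filter_for_estimation <- function(prepared, focal_good = prepared$goods[1],
                                  min_consumers = 2) {
  stopifnot(inherits(prepared, "prepared_survey"), focal_good %in% prepared$goods)
  d <- prepared$data
  n0 <- nrow(d)
  cl0 <- length(unique(d$cluster_id))
  purch <- is.finite(d[[paste0("lnuv_", focal_good)]])
  d <- d[purch, , drop = FALSE]
  keep_cl <- names(which(table(d$cluster_id) >= min_consumers))
  d <- d[as.character(d$cluster_id) %in% keep_cl, , drop = FALSE]
  if (!nrow(d)) {
    stop("empty after filter: no cluster has >= ", min_consumers,
         " purchasers of '", focal_good, "'")
  }
  out <- prepared
  out$data <- d
  out$focal_good <- focal_good
  out$filtered <- TRUE
  attr(out, "n_dropped_households") <- n0 - nrow(d)
  attr(out, "n_dropped_clusters") <- cl0 - length(unique(d$cluster_id))
  out
}

#' Assign income tertiles by total household expenditure
#'
#' Households are ranked by total expenditure (the income proxy) over the
#' sample currently in the object, so calling this before or after
#' [filter_for_estimation()] chooses whether tertile boundaries come from
#' the full or the estimation sample. Ties break on household id;
#' remainders go to the lower tertiles so sizes differ by at most one.
#'
#' @param prepared a `prepared_survey`.
#' @return `prepared_survey` with a `income_tertile` column.
#' @export
assign_income_tertiles <- function(prepared) {
  stopifnot(inherits(prepared, "prepared_survey"))
  d <- prepared$data
  if (nrow(d) < 3L) stop("tertile error: need at least 3 households")
  d$income_tertile <- tertile_assign(d$total_expenditure, d$household_id)
  prepared$data <- d
  prepared
}

#' Summary table of beverage consumption
#'
#' Per good (and income group when tertiles are present): the proportion of
#' households purchasing, and conditional means over purchasers of monthly
#' quantity, expenditure, unit value and budget share. Summaries are meant
#' for the full pre-filter sample.
#'
#' @param x a `prepared_survey` or a raw records data.frame.
#' @param weighted use the `weight` column (survey multipliers) if TRUE.
#' @return data.frame, one row per good x group.
#' @export
summarize_survey <- function(x, weighted = FALSE) {
  prepared <- if (inherits(x, "prepared_survey")) x else compute_shares_unitvalues(x)
  d <- prepared$data
  wt <- if (weighted && !is.null(d$weight)) d$weight else rep(1, nrow(d))
  groups <- list(full = rep(TRUE, nrow(d)))
  if (!is.null(d$income_tertile)) {
    for (g in levels(d$income_tertile)) groups[[g]] <- d$income_tertile == g
  }
  rows <- list()
  for (gname in names(groups)) {
    sel <- groups[[gname]]
    for (good in prepared$goods) {
      q <- d[[paste0("quantity_", good)]][sel]
      e <- d[[paste0("expenditure_", good)]][sel]
      s <- d[[paste0("share_", good)]][sel]
      w <- wt[sel]
      p <- q > 0
      wm <- function(v, keep) if (any(keep)) sum(v[keep] * w[keep]) / sum(w[keep]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        good = good, group = gname,
        pct_purchasing = 100 * sum(w[p]) / sum(w),
        mean_quantity = wm(q, p),
        mean_expenditure = wm(e, p),
        mean_unit_value = if (any(p)) sum((e[p] / q[p]) * w[p]) / sum(w[p]) else NA_real_,
        mean_budget_share = 100 * wm(s, p),
        n_purchasers = sum(p),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' @export
print.prepared_survey <- function(x, ...) {
  cat(sprintf("Prepared survey: %d households, %d clusters, goods: %s\n",
              nrow(x$data), length(unique(x$data$cluster_id)),
              paste(x$goods, collapse = ", ")))
  if (x$filtered) {
    cat(sprintf("  filtered on '%s' (dropped %s households, %s clusters)\n",
                x$focal_good,
                attr(x, "n_dropped_households") %||% "?",
                attr(x, "n_dropped_clusters") %||% "?"))
  }
  invisible(x)
}
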