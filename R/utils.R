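`%||%` <- function(a, b) if (is.null(a)) b else a

#' Within-cluster demeaning
#'
#' Subtracts cluster means from each column of a matrix. Used throughout the
#' estimator to absorb cluster fixed effects (Frisch-Waugh).
#'
#' @param m numeric matrix (or vector) of observations.
#' @param f cluster memberships, same length as `nrow(m)`.
#' @return matrix of within-cluster deviations.
#' @keywords internal
demean_within <- function(m, f) {
  m <- as.matrix(m)
  g <- as.integer(droplevels(as.factor(f)))
  cnt <- tabulate(g)
  means <- rowsum(m, g) / cnt # rowsum sorts integer groups ascending: 1..K
  m - means[g, , drop = FALSE]
}

# Cluster means over rows `use`, returned as a length(levels) x ncol matrix
# aligned to `levels`; clusters with no used rows get NA.
cluster_means <- function(m, f, levels, use = NULL) {
  m <- as.matrix(m)
  code <- match(f, levels)
  if (!is.null(use)) {
    m <- m[use, , drop = FALSE]
    code <- code[use]
  }
  out <- matrix(NA_real_, length(levels), ncol(m))
  if (length(code)) {
    cnt <- tabulate(code, nbins = length(levels))
    sums <- rowsum(m, code)
    rows <- as.integer(rownames(sums))
    out[rows, ] <- sums / cnt[rows]
  }
  out
}

# Per-cluster counts aligned to `levels`
cluster_counts <- function(f, levels, use = NULL) {
  code <- match(f, levels)
  if (!is.null(use)) code <- code[use]
  tabulate(code, nbins = length(levels))
}

#' Deterministic tertile assignment
#'
#' Households are ranked by a size variable (here total expenditure); the
#' lowest third is labelled `low`, and so on. Ties are broken by stable rank
#' on the id, and when n is not divisible by 3 the remainder goes to the
#' lowest tertile first, then the middle, so tertile sizes differ by at most
#' one.
#'
#' @param x numeric vector to rank on (total household expenditure).
#' @param id tie-breaking identifier (household id); defaults to input order.
#' @return factor with ordered levels `low`, `middle`, `high`.
#' @export
tertile_assign <- function(x, id = seq_along(x)) {
  n <- length(x)
  if (n < 3L) stop("tertile assignment needs at least 3 households")
  ord <- order(x, id)
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- base + c(rem >= 1L, rem >= 2L, 0L)
  lab <- rep(c("low", "middle", "high"), times = sizes)
  out <- character(n)
  out[ord] <- lab
  factor(out, levels = c("low", "middle", "high"))
}

# Resolve a per-good parameter: accepts a scalar (recycled), a named vector
# covering `goods`, or an unnamed vector of length G.
pergood <- function(x, goods, what) {
  g <- length(goods)
  if (is.null(x)) stop(sprintf("'%s' must be supplied", what))
  if (!is.null(names(x)) && all(goods %in% names(x))) return(unname(x[goods]))
  if (length(x) == 1L) return(rep(as.numeric(x), g))
  if (length(x) == g) return(unname(as.numeric(x)))
  stop(sprintf("'%s' must be length 1 or %d (or named by good)", what, g))
}

# Same for a goods x k matrix keyed by rownames
pergood_matrix <- function(x, goods, k, what) {
  if (is.null(x)) stop(sprintf("'%s' must be supplied", what))
  x <- as.matrix(x)
  if (!is.null(rownames(x)) && all(goods %in% rownames(x))) {
    x <- x[goods, , drop = FALSE]
  }
  if (nrow(x) == 1L && length(goods) > 1L) {
    x <- x[rep(1L, length(goods)), , drop = FALSE]
  }
  if (nrow(x) != length(goods) || ncol(x) != k) {
    stop(sprintf("'%s' must be a %d x %d matrix", what, length(goods), k))
  }
  unname(x)
}
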