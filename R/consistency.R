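#' Align two state-keyed tables on their common states
#'
#' Inner join on the state identifier, returned in alphabetical state order.
#' Columns from the two inputs get suffixes `.a` and `.b`. States present in
#' only one input are recorded in attributes `dropped_a` / `dropped_b`.
#'
#' @param a,b data frames (estimate tables or rank tables) with a `state`
#'   column.
#' @return Merged data frame; attributes `dropped_a`, `dropped_b`.
#' @export
align_states <- function(a, b) {
  if (!"state" %in% names(a) || !"state" %in% names(b))
    stop("both inputs need a 'state' column")
  common <- intersect(a$state, b$state)
  if (length(common) == 0) stop("no states in common")
  m <- merge(as.data.frame(a), as.data.frame(b), by = "state",
             suffixes = c(".a", ".b"))
  m <- m[order(m$state), , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "dropped_a") <- setdiff(a$state, common)
  attr(m, "dropped_b") <- setdiff(b$state, common)
  m
}

#' Spearman rank correlation with midrank tie correction
#'
#' Both vectors are converted to midranks (tied values share the average of
#' the positions they occupy) and the Pearson correlation of the midranks is
#' returned - the correct tie-handling for published league tables, whose
#' integer median ranks contain many ties. The two-sided p-value uses the t
#' approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom. On tie-free data this estimator coincides with the classical
#' `1 - 6*sum(d^2)/(n(n^2-1))` formula.
#'
#' @param x,y numeric vectors of equal length (ranks, or any values - the
#'   result is invariant to strictly increasing transforms of either input).
#' @return A `consistency_result` list: `rho`, `p_value`, `n_states`,
#'   `method_note`.
#' @export
spearman_ranks <- function(x, y) {
  if (length(x) != length(y)) stop("inputs must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values in rank vectors")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined correlation: zero variance in a midrank vector")
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n_states = n,
                 method_note = "midrank ties; t approximation on n-2 df"),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d states, P = %.3g)\n",
              x$rho, x$n_states, x$p_value))
  invisible(x)
}

#' Paired t test with Bonferroni adjustment
#'
#' Tests whether paired prevalence estimates differ systematically between
#' two sources: `d_i = b_i - a_i`, `t = mean(d) / (sd(d)/sqrt(n))`, two-sided
#' p on `n - 1` degrees of freedom, Bonferroni-adjusted across
#' `m_comparisons` tests (`p_adj = min(1, m * p)`). Degenerate inputs: zero
#' variance with nonzero mean difference gives `p_raw = 0`; zero variance
#' and zero mean gives `t = 0, p = 1`.
#'
#' @param a,b paired numeric vectors (percent).
#' @param m_comparisons number of tests in the Bonferroni family; default 3,
#'   one per behavior compared across the two surveys.
#' @return A `paired_comparison` list: `mean_diff`, `t_stat`, `df`, `p_raw`,
#'   `p_adjusted`, `m_comparisons`, `n_pairs`.
#' @export
paired_t <- function(a, b, m_comparisons = 3L) {
  if (length(a) != length(b)) stop("inputs must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  if (m_comparisons < 1) stop("m_comparisons must be >= 1")
  d <- b - a
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(md) * Inf; p <- 0
    }
  } else {
    t_stat <- md / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  structure(list(mean_diff = md, t_stat = t_stat, df = n - 1L, p_raw = p,
                 p_adjusted = min(1, m_comparisons * p),
                 m_comparisons = as.integer(m_comparisons),
                 n_pairs = as.integer(n)),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "Paired t: mean diff = %.2f, t(%d) = %.2f, p = %.3g (Bonferroni x%d: %.3g)\n",
    x$mean_diff, x$df, x$t_stat, x$p_raw, x$m_comparisons, x$p_adjusted))
  invisible(x)
}

#' Rank-consistency correlations for a set of table pairs
#'
#' Computes the tie-corrected Spearman correlation for each requested pair of
#' rank (or estimate) tables, on the intersection of their states.
#'
#' @param tables named list of at least two tables, each with a `state`
#'   column and the column named by `rank_col`.
#' @param pairs data frame with character columns `a` and `b` naming entries
#'   of `tables` (optionally a `label` column); default: all unordered pairs.
#' @param rank_col column correlated, default `"median_rank"` (use
#'   `"printed_rank"` to correlate the published ranks carried by the
#'   packaged fixtures).
#' @return Data frame `pair_label, n_states, rho, p_value`.
#' @export
consistency_matrix <- function(tables, pairs = NULL, rank_col = "median_rank") {
  if (length(tables) < 2) stop("need at least 2 tables")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("tables must be a named list")
  if (is.null(pairs)) {
    idx <- utils::combn(names(tables), 2)
    pairs <- data.frame(a = idx[1, ], b = idx[2, ], stringsAsFactors = FALSE)
  }
  if (!"label" %in% names(pairs))
    pairs$label <- paste(pairs$a, pairs$b, sep = " x ")
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    ta <- tables[[pairs$a[k]]]
    tb <- tables[[pairs$b[k]]]
    if (is.null(ta) || is.null(tb))
      stop("unknown table name in pair ", pairs$label[k])
    m <- align_states(ta[, c("state", rank_col)], tb[, c("state", rank_col)])
    r <- spearman_ranks(m[[paste0(rank_col, ".a")]],
                        m[[paste0(rank_col, ".b")]])
    data.frame(pair_label = pairs$label[k], n_states = r$n_states,
               rho = r$rho, p_value = r$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
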