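#' Simulation configuration for Monte Carlo ranking
#'
#' @param n_sims number of Monte Carlo replicates (default 100000, the size
#'   used for the published rankings). Below 1000 the rank CI summaries
#'   trigger a warning.
#' @param distribution sampling law for each state's prevalence:
#'   `"normal"` (default), `"truncated_normal"` (normal truncated to
#'   \[0, 100\]), `"binomial"` (counts at the effective sample size implied by
#'   the SE), or `"lognormal"` (moment-matched).
#' @param ci_level confidence level for rank intervals, default 0.95.
#' @param mode `"individual"` (per-state percentile intervals, default) or
#'   `"simultaneous"` (intervals widened until they jointly cover all states'
#'   ranks in at least `ci_level` of simulation rows).
#' @param seed integer seed; a single seed governs the whole replicate matrix
#'   through one generator stream, so runs are exactly reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sims = 100000L, distribution = "normal",
                       ci_level = 0.95, mode = "individual", seed = 1L) {
  distribution <- match.arg(distribution,
                            c("normal", "truncated_normal", "binomial",
                              "lognormal"))
  mode <- match.arg(mode, c("individual", "simultaneous"))
  n_sims <- as.integer(n_sims)
  if (is.na(n_sims) || n_sims < 1) stop("n_sims must be a positive integer")
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1)
    stop("ci_level must lie in (0, 1)")
  structure(list(n_sims = n_sims, distribution = distribution,
                 ci_level = ci_level, mode = mode, seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from a key-value text file
#'
#' One `key = value` (or `key: value`) pair per line; keys are the arguments
#' of [sim_config()]. Missing keys take the defaults; unknown keys error.
#'
#' @param path file path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[=:]", perl = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  known <- c("n_sims", "distribution", "ci_level", "mode", "seed")
  bad <- setdiff(keys, known)
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  args <- stats::setNames(as.list(vals), keys)
  for (k in intersect(c("n_sims", "ci_level", "seed"), names(args)))
    args[[k]] <- as.numeric(args[[k]])
  do.call(sim_config, args)
}

#' Effective sample size implied by a prevalence and its standard error
#'
#' The binomial sample size whose sampling standard error matches the
#' reported one: `p(1-p)/se^2` on the proportion scale. This realizes the
#' binomial sampling assumption for estimates published only as a percent
#' and SE.
#'
#' @param prevalence percent, strictly between 0 and 100.
#' @param se percent, positive.
#' @return Positive real (not rounded).
#' @examples
#' effective_sample_size(50, 5)  # 100
#' @export
effective_sample_size <- function(prevalence, se) {
  if (any(prevalence <= 0 | prevalence >= 100))
    stop("effective sample size undefined at boundary prevalence 0 or 100")
  if (any(se <= 0)) stop("se must be positive")
  p <- prevalence / 100
  p * (1 - p) / (se / 100)^2
}

#' Draw the Monte Carlo replicate matrix of simulated prevalences
#'
#' Column `j` is drawn independently from the configured distribution with
#' location equal to state `j`'s estimated prevalence and spread equal to its
#' standard error (both percent):
#' \describe{
#'   \item{normal}{`N(p, se^2)`.}
#'   \item{truncated_normal}{the same law truncated to \[0, 100\], drawn by
#'     inverse-CDF on the truncated law.}
#'   \item{binomial}{`100 * X / n` with `X ~ Binomial(n, p/100)` and `n` the
#'     [effective_sample_size()] rounded to the nearest integer, floor 1.}
#'   \item{lognormal}{parameters solved so the draw's mean is `p` and its
#'     standard deviation `se` (moment matching).}
#' }
#' States with `se = 0` yield constant columns under every law. Draws are
#' independent across states: the estimates come from independent state
#' samples, so no cross-state covariance is imposed.
#'
#' @param table an [estimate_table()].
#' @param config a [sim_config()].
#' @return Numeric matrix, `n_sims` rows by `n_states` columns, with the
#'   states as column names.
#' @export
draw_replicates <- function(table, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  p <- table$prevalence_pct
  se <- table$se_pct
  n <- length(p)
  ns <- config$n_sims
  set.seed(config$seed)
  pm <- rep(p, each = ns)
  sm <- rep(se, each = ns)
  reps <- switch(config$distribution,
    normal = stats::rnorm(ns * n, mean = pm, sd = sm),
    truncated_normal = {
      lo <- stats::pnorm(0, mean = pm, sd = sm)
      hi <- stats::pnorm(100, mean = pm, sd = sm)
      u <- lo + stats::runif(ns * n) * (hi - lo)
      x <- stats::qnorm(u, mean = pm, sd = sm)
      pmin(pmax(x, 0), 100)
    },
    binomial = {
      deg <- se > 0 & (p <= 0 | p >= 100)
      if (any(deg))
        stop("binomial draws are degenerate at prevalence 0 or 100 with ",
             "positive SE (state ", table$state[deg][1], ")")
      neff <- rep(1, n)
      ok <- se > 0
      neff[ok] <- pmax(1, round(effective_sample_size(p[ok], se[ok])))
      nm <- rep(neff, each = ns)
      100 * stats::rbinom(ns * n, size = nm, prob = pm / 100) / nm
    },
    lognormal = {
      if (any(p <= 0 & se > 0))
        stop("lognormal draws require positive prevalence (state ",
             table$state[p <= 0 & se > 0][1], ")")
      sigma2 <- log(1 + (sm / pm)^2)
      mu <- log(pm) - sigma2 / 2
      stats::rlnorm(ns * n, meanlog = mu, sdlog = sqrt(sigma2))
    })
  reps <- matrix(reps, nrow = ns, ncol = n)
  if (any(se == 0)) {
    fix <- which(se == 0)
    for (j in fix) reps[, j] <- p[j]
  }
  colnames(reps) <- table$state
  reps
}

#' Rank every simulated replicate row
#'
#' Within each row, rank 1 goes to the largest simulated prevalence (the
#' convention of the published tables: rank 1 = highest prevalence = worst
#' performance). Exact ties within a row, possible under the binomial law,
#' are broken by input column order.
#'
#' @param replicates matrix from [draw_replicates()].
#' @return A `rank_matrix`: integer matrix of the same shape in which every
#'   row is a permutation of `1..n_states`.
#' @export
rank_replicates <- function(replicates) {
  if (!all(is.finite(replicates))) stop("non-finite simulated prevalences")
  n <- ncol(replicates)
  rk <- matrix(0L, nrow = nrow(replicates), ncol = n,
               dimnames = list(NULL, colnames(replicates)))
  for (i in seq_len(nrow(replicates)))
    rk[i, ] <- as.integer(rank(-replicates[i, ], ties.method = "first"))
  structure(rk, class = c("rank_matrix", class(rk)))
}

order_stat <- function(sorted, q) sorted[max(1L, ceiling(q * length(sorted)))]

#' Summarize a rank matrix as median ranks with confidence intervals
#'
#' Per state, the point estimate is the lower median of its simulated ranks
#' (the `ceiling(n_sims/2)`-th order statistic), which is always an integer
#' and always lies inside the confidence interval. In `individual` mode the
#' CI endpoints are the 2.5th and 97.5th percentile order statistics (at
#' level `ci_level`); in `simultaneous` mode they come from
#' [simultaneous_adjust()]. Percentiles use the order statistic at
#' `ceiling(q * n)` with no interpolation, so all bounds are attained integer
#' ranks. Median ranks need not form a permutation of `1..n_states`.
#'
#' @param rank_matrix a `rank_matrix` from [rank_replicates()].
#' @param config the [sim_config()] used (records provenance and sets
#'   `ci_level` and `mode`).
#' @param table optional [estimate_table()]; if supplied, its
#'   `prevalence_pct` and `se_pct` columns are carried into the output.
#' @return A `rank_table`: data frame with columns `state`, optionally
#'   `prevalence_pct` and `se_pct`, `median_rank`, `ci_low`, `ci_high`;
#'   attribute `rank_counts` holds the per-state frequency of each rank over
#'   the simulations (an `n_states x n_states` matrix) and attribute `config`
#'   the provenance.
#' @export
summarize_ranks <- function(rank_matrix, config = sim_config(), table = NULL) {
  ns <- nrow(rank_matrix)
  n <- ncol(rank_matrix)
  if (is.null(ns) || ns == 0) stop("empty rank matrix")
  if (ns < 1000)
    warning("only ", ns, " simulations; rank CI summaries are unstable ",
            "below 1000")
  states <- colnames(rank_matrix)
  if (is.null(states)) states <- paste0("state", seq_len(n))
  sorted <- apply(rank_matrix, 2, sort)
  if (ns == 1) sorted <- matrix(sorted, nrow = 1)
  med <- sorted[max(1L, ceiling(ns / 2)), ]
  alpha <- 1 - config$ci_level
  if (config$mode == "simultaneous") {
    adj <- simultaneous_adjust(rank_matrix, config$ci_level)
    lo <- adj$intervals$ci_low
    hi <- adj$intervals$ci_high
  } else {
    lo <- apply(sorted, 2, order_stat, q = alpha / 2)
    hi <- apply(sorted, 2, order_stat, q = 1 - alpha / 2)
  }
  counts <- apply(rank_matrix, 2, tabulate, nbins = n)
  rownames(counts) <- seq_len(n)
  out <- data.frame(state = states, stringsAsFactors = FALSE)
  if (!is.null(table)) {
    i <- match(states, table$state)
    out$prevalence_pct <- table$prevalence_pct[i]
    out$se_pct <- table$se_pct[i]
  }
  out$median_rank <- as.integer(med)
  out$ci_low <- as.integer(lo)
  out$ci_high <- as.integer(hi)
  rownames(out) <- NULL
  structure(out, config = config, rank_counts = counts,
            class = c("rank_table", "data.frame"))
}

#' Widen rank intervals until they jointly cover at the nominal level
#'
#' Searches a grid of per-state tail probabilities `gamma`, starting at the
#' nominal `1 - ci_level` and shrinking, for the largest `gamma` such that
#' the per-state order-statistic intervals `[Q_i(gamma/2), Q_i(1 - gamma/2)]`
#' contain every state's rank simultaneously in at least `ci_level` of the
#' simulation rows. Joint coverage is counted directly on the rows, so the
#' guarantee is exact for the realized simulation. The result is always a
#' superset of the individual interval at the same level. If even the
#' smallest grid value fails (pathological inputs), full-range intervals are
#' returned with a warning.
#'
#' @param rank_matrix a `rank_matrix`.
#' @param ci_level joint coverage target in (0, 1).
#' @return List with `intervals` (data frame `state`, `ci_low`, `ci_high`),
#'   `gamma` (the per-state tail probability used), and `joint_coverage`
#'   (the achieved fraction of rows).
#' @export
simultaneous_adjust <- function(rank_matrix, ci_level = 0.95) {
  ns <- nrow(rank_matrix)
  n <- ncol(rank_matrix)
  if (ns < 1000)
    warning("only ", ns, " simulations; simultaneous adjustment is ",
            "unstable below 1000")
  states <- colnames(rank_matrix)
  if (is.null(states)) states <- paste0("state", seq_len(n))
  sorted <- apply(rank_matrix, 2, sort)
  if (ns == 1) sorted <- matrix(sorted, nrow = 1)
  alpha <- 1 - ci_level
  gammas <- alpha * sort(unique(c(seq(0.02, 1, by = 0.02),
                                  10^seq(-5, -1, length.out = 13))),
                         decreasing = TRUE)
  coverage_of <- function(lo, hi) {
    ok <- rep(TRUE, ns)
    for (j in seq_len(n)) ok <- ok & rank_matrix[, j] >= lo[j] &
        rank_matrix[, j] <= hi[j]
    mean(ok)
  }
  for (g in gammas) {
    lo <- apply(sorted, 2, order_stat, q = g / 2)
    hi <- apply(sorted, 2, order_stat, q = 1 - g / 2)
    cov <- coverage_of(lo, hi)
    if (cov >= ci_level)
      return(list(intervals = data.frame(state = states, ci_low = as.integer(lo),
                                         ci_high = as.integer(hi),
                                         stringsAsFactors = FALSE),
                  gamma = g, joint_coverage = cov))
  }
  warning("grid exhausted without reaching joint coverage ", ci_level,
          "; returning full-range intervals")
  list(intervals = data.frame(state = states, ci_low = 1L,
                              ci_high = as.integer(n),
                              stringsAsFactors = FALSE),
       gamma = 0, joint_coverage = 1)
}

#' Rank states with Monte Carlo uncertainty, end to end
#'
#' Convenience wrapper: [draw_replicates()], [rank_replicates()],
#' [summarize_ranks()] in one call.
#'
#' @inheritParams draw_replicates
#' @return A `rank_table` (see [summarize_ranks()]) carrying the input
#'   prevalence and SE columns.
#' @examples
#' tab <- load_packaged_table("NSDUH", "cigarette")
#' rt <- rank_states(tab, sim_config(n_sims = 2000, seed = 7))
#' rt[rt$state == "Utah", ]
#' @export
rank_states <- function(table, config = sim_config()) {
  reps <- draw_replicates(table, config)
  rk <- rank_replicates(reps)
  summarize_ranks(rk, config, table = table)
}

#' Write the per-state rank frequency distribution as delimited text
#'
#' Long format `state, rank, count`, one row per state x attained rank, for
#' reconstructing rank scatterplots.
#'
#' @param table a `rank_table` whose `rank_counts` attribute is present.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rank_distribution <- function(table, path) {
  counts <- attr(table, "rank_counts")
  if (is.null(counts)) stop("rank table carries no rank_counts attribute")
  n <- nrow(counts)
  df <- data.frame(state = rep(colnames(counts), each = n),
                   rank = rep(seq_len(n), times = ncol(counts)),
                   count = as.vector(counts))
  df <- df[df$count > 0, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.rank_table <- function(x, ...) {
  cfg <- attr(x, "config")
  hdr <- if (is.null(cfg)) "" else
    sprintf(" (%s draws, n_sims=%d, %s CIs)", cfg$distribution, cfg$n_sims,
            cfg$mode)
  cat(sprintf("<rank_table> %d states%s\n", nrow(x), hdr))
  df <- as.data.frame(x)
  print.data.frame(utils::head(df[order(df$median_rank, df$state), ], 10))
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}
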