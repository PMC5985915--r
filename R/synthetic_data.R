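synth_state_names <- function(n) sprintf("S%02d", seq_len(n))

rank_with_alpha_ties <- function(prev, state) {
  ord <- order(-prev, state)
  r <- integer(length(prev))
  r[ord] <- seq_along(prev)
  r
}

#' Generate a synthetic state estimate table with known truth
#'
#' True prevalences are drawn uniformly on `[prevalence_low,
#' prevalence_high]` and true SEs uniformly on `[se_low, se_high]`; the
#' observed prevalence is the truth plus normal noise with that SE,
#' truncated to \[0, 100\]. A uniform truth law is deliberate: the ranking
#' method's coverage should not be tested only under its own normal sampling
#' assumption, so the truth model and the noise model are kept distinct.
#' Default ranges emulate the marginal structure of the packaged adolescent
#' substance-use tables (prevalence about 4-27%, SE about 0.4-2.4%).
#'
#' @param n_states number of states (>= 2), default 51.
#' @param prevalence_low,prevalence_high truth range, percent.
#' @param se_low,se_high SE range, percent.
#' @param seed integer seed.
#' @return List with `table` (an [estimate_table()]) and `truth` (data frame
#'   `state, true_prevalence, true_se, true_rank`; rank 1 = highest true
#'   prevalence, ties broken alphabetically).
#' @export
generate_estimate_table <- function(n_states = 51L, prevalence_low = 4,
                                    prevalence_high = 27, se_low = 0.4,
                                    se_high = 2.4, seed = 1L) {
  if (n_states < 2) stop("n_states must be >= 2")
  if (!(prevalence_low >= 0 && prevalence_low < prevalence_high &&
        prevalence_high <= 100))
    stop("invalid prevalence bounds")
  if (!(se_low >= 0 && se_low < se_high)) stop("invalid SE bounds")
  set.seed(seed)
  states <- synth_state_names(n_states)
  tp <- stats::runif(n_states, prevalence_low, prevalence_high)
  ts <- stats::runif(n_states, se_low, se_high)
  lo <- stats::pnorm(0, tp, ts)
  hi <- stats::pnorm(100, tp, ts)
  obs <- stats::qnorm(lo + stats::runif(n_states) * (hi - lo), tp, ts)
  obs <- pmin(pmax(obs, 0), 100)
  truth <- data.frame(state = states, true_prevalence = tp, true_se = ts,
                      true_rank = rank_with_alpha_ties(tp, states),
                      stringsAsFactors = FALSE)
  tab <- estimate_table(
    data.frame(state = states, prevalence_pct = obs, se_pct = ts,
               stringsAsFactors = FALSE),
    survey = "SYNTH", behavior = "synthetic")
  list(table = tab, truth = truth)
}

# Intercept mu such that E[plogis(mu + sigma*Z)] = p, by Gauss-Hermite
# quadrature (20 nodes) and uniroot. Keeps the marginal prevalence unbiased
# under PSU random effects.
logit_intercept <- function(p, sigma) {
  if (p <= 0) return(-Inf)
  if (p >= 1) return(Inf)
  if (sigma == 0) return(stats::qlogis(p))
  gh <- gauss_hermite_20
  marg <- function(mu) sum(gh$w * stats::plogis(mu + sigma * gh$x)) - p
  stats::uniroot(marg, interval = stats::qlogis(p) + c(-1, 1) * (4 + 4 * sigma),
                 tol = 1e-10)$root
}

# 20-node probabilist Gauss-Hermite rule (nodes/weights for N(0,1)),
# computed from the Golub-Welsch eigendecomposition of the Jacobi matrix.
make_gh <- function(k = 20) {
  j <- sqrt(seq_len(k - 1))
  J <- matrix(0, k, k)
  J[cbind(seq_len(k - 1), seq_len(k - 1) + 1)] <- j
  J[cbind(seq_len(k - 1) + 1, seq_len(k - 1))] <- j
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = e$vectors[1, ]^2)
}
gauss_hermite_20 <- make_gh(20)

#' Generate stratified-cluster survey microdata with known truth
#'
#' Emulates a complex survey design: within each state, `strata_per_state`
#' strata each containing `psus_per_stratum` PSUs of `respondents_per_psu`
#' respondents. Clustering enters through PSU-level random effects on the
#' logit scale with variance calibrated to the requested latent-scale
#' intra-cluster correlation (`sigma_u^2 = icc * pi^2/3 / (1 - icc)`); the
#' intercept is solved numerically so the marginal prevalence equals the
#' requested truth exactly. Weights are log-normal with the requested
#' coefficient of variation, normalized to mean 1 within state.
#'
#' @param n_states number of states.
#' @param strata_per_state strata per state.
#' @param psus_per_stratum PSUs per stratum (>= 2, so Taylor variance is
#'   estimable).
#' @param respondents_per_psu respondents per PSU.
#' @param true_prevalence per-state true prevalence, percent (recycled).
#' @param icc latent-scale intra-cluster correlation in \[0, 1).
#' @param weight_cv coefficient of variation of the sampling weights
#'   (0 = equal weights).
#' @param seed integer seed.
#' @return List with `data` (a [survey_microdata()]) and `truth` (data frame
#'   `state, true_prevalence, true_rank`).
#' @export
generate_microdata <- function(n_states = 5L, strata_per_state = 10L,
                               psus_per_stratum = 2L,
                               respondents_per_psu = 30L,
                               true_prevalence = 10, icc = 0.05,
                               weight_cv = 0.5, seed = 1L) {
  if (psus_per_stratum < 2) stop("psus_per_stratum must be >= 2")
  if (icc < 0 || icc >= 1) stop("icc must lie in [0, 1)")
  if (weight_cv < 0) stop("weight_cv must be nonnegative")
  set.seed(seed)
  states <- synth_state_names(n_states)
  tp <- rep_len(true_prevalence, n_states)
  sigma_u <- sqrt(icc * pi^2 / 3 / (1 - icc))
  n_per_state <- strata_per_state * psus_per_stratum * respondents_per_psu
  rows <- vector("list", n_states)
  for (s in seq_len(n_states)) {
    mu <- logit_intercept(tp[s] / 100, sigma_u)
    u <- stats::rnorm(strata_per_state * psus_per_stratum, 0, sigma_u)
    eta <- rep(mu + u, each = respondents_per_psu)
    y <- stats::rbinom(n_per_state, 1, stats::plogis(eta))
    if (weight_cv > 0) {
      s2 <- log(1 + weight_cv^2)
      w <- stats::rlnorm(n_per_state, meanlog = -s2 / 2, sdlog = sqrt(s2))
      w <- w / mean(w)
    } else {
      w <- rep(1, n_per_state)
    }
    rows[[s]] <- data.frame(
      state = states[s],
      stratum = rep(sprintf("H%02d", seq_len(strata_per_state)),
                    each = psus_per_stratum * respondents_per_psu),
      psu = rep(rep(sprintf("P%02d", seq_len(psus_per_stratum)),
                    each = respondents_per_psu), times = strata_per_state),
      weight = w, outcome = y, stringsAsFactors = FALSE)
  }
  truth <- data.frame(state = states, true_prevalence = tp,
                      true_rank = rank_with_alpha_ties(tp, states),
                      stringsAsFactors = FALSE)
  list(data = survey_microdata(do.call(rbind, rows)), truth = truth)
}

#' Generate a paper-like two-survey, three-behavior world
#'
#' End-to-end rehearsal input: survey A covers 51 states, survey B the same
#' states minus four (dropped deterministically given the seed); each of
#' three behaviors has its own true prevalence vector, and the two surveys'
#' truths are correlated through a Gaussian copula at `truth_correlation`.
#' Survey B truths are shifted upward (school-based surveys report higher
#' adolescent substance use), and observed tables add normal noise at
#' survey-specific SE ranges.
#'
#' @param seed integer seed.
#' @param truth_correlation cross-survey correlation of true prevalences in
#'   \[-1, 1\], default 0.8.
#' @return List with `tables` (named list of six [estimate_table()]s,
#'   `A_cigarette`, `B_cigarette`, ...) and `truth` (named list of six truth
#'   data frames).
#' @export
make_paper_like_world <- function(seed = 1L, truth_correlation = 0.8) {
  if (abs(truth_correlation) > 1) stop("truth_correlation must lie in [-1, 1]")
  set.seed(seed)
  n_a <- 51L
  states <- synth_state_names(n_a)
  drop_b <- sort(sample(states, 4))
  states_b <- setdiff(states, drop_b)
  behaviors <- c("cigarette", "binge_alcohol", "marijuana")
  r <- truth_correlation
  tables <- list()
  truth <- list()
  for (bh in behaviors) {
    z1 <- stats::rnorm(n_a)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n_a)
    tp_a <- 4.5 + (14.3 - 4.5) * stats::pnorm(z1)
    tp_b <- 7.0 + (21.7 - 7.0) * stats::pnorm(z2)
    se_a <- stats::runif(n_a, 0.4, 1.4)
    se_b <- stats::runif(n_a, 0.4, 2.4)
    obs_a <- pmin(pmax(stats::rnorm(n_a, tp_a, se_a), 0), 100)
    obs_b <- pmin(pmax(stats::rnorm(n_a, tp_b, se_b), 0), 100)
    keep <- states %in% states_b
    tables[[paste0("A_", bh)]] <- estimate_table(
      data.frame(state = states, prevalence_pct = obs_a, se_pct = se_a,
                 stringsAsFactors = FALSE), survey = "A", behavior = bh)
    tables[[paste0("B_", bh)]] <- estimate_table(
      data.frame(state = states[keep], prevalence_pct = obs_b[keep],
                 se_pct = se_b[keep], stringsAsFactors = FALSE),
      survey = "B", behavior = bh)
    truth[[paste0("A_", bh)]] <- data.frame(
      state = states, true_prevalence = tp_a, true_se = se_a,
      true_rank = rank_with_alpha_ties(tp_a, states),
      stringsAsFactors = FALSE)
    truth[[paste0("B_", bh)]] <- data.frame(
      state = states[keep], true_prevalence = tp_b[keep],
      true_se = se_b[keep],
      true_rank = rank_with_alpha_ties(tp_b[keep], states[keep]),
      stringsAsFactors = FALSE)
  }
  list(tables = tables, truth = truth, dropped_from_b = drop_b)
}
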