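#' Construct validated survey microdata
#'
#' Respondent-level records from a weighted, stratified, clustered survey
#' design: one row per respondent with the state, design stratum, primary
#' sampling unit (PSU), sampling weight and binary outcome. Variance
#' estimation treats the first stage as sampled with replacement (no
#' finite-population correction), the standard approximation for national
#' surveillance public-use designs.
#'
#' @param df data frame with columns `state`, `stratum`, `psu`, `weight`,
#'   `outcome`.
#' @return A `survey_microdata` data frame.
#' @export
survey_microdata <- function(df) {
  req <- c("state", "stratum", "psu", "weight", "outcome")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df$state <- as.character(df$state)
  df$stratum <- as.character(df$stratum)
  df$psu <- as.character(df$psu)
  df$weight <- as.numeric(df$weight)
  df$outcome <- as.numeric(df$outcome)
  if (any(!is.finite(df$weight) | df$weight <= 0))
    stop("all weights must be positive and finite")
  if (!all(df$outcome %in% c(0, 1)))
    stop("outcome must be binary 0/1")
  rownames(df) <- NULL
  structure(df, class = c("survey_microdata", "data.frame"))
}

#' Read survey microdata from delimited text
#'
#' @param path CSV file with header columns `state, stratum, psu, weight,
#'   outcome`.
#' @return A [survey_microdata()].
#' @export
read_microdata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  survey_microdata(utils::read.csv(path, stringsAsFactors = FALSE))
}

state_rows <- function(data, state) {
  i <- which(data$state == state)
  if (length(i) == 0) stop("state '", state, "' not present in microdata")
  i
}

#' Weighted prevalence of a binary outcome in one state
#'
#' The design-based ratio estimator `100 * sum(w * y) / sum(w)` over the
#' state's respondents, on the percent scale.
#'
#' @param data a [survey_microdata()].
#' @param state state identifier.
#' @return Percent in \[0, 100\].
#' @export
weighted_prevalence <- function(data, state) {
  i <- state_rows(data, state)
  W <- sum(data$weight[i])
  if (W <= 0) stop("zero total weight for state '", state, "'")
  100 * sum(data$weight[i] * data$outcome[i]) / W
}

#' Taylor-series-linearization standard error of a weighted prevalence
#'
#' Design-based SE of the ratio estimator by first-order Taylor
#' linearization with a with-replacement first stage: for `p = Y/W` the
#' linearized residual of respondent `i` is `z_i = w_i (y_i - p) / W`;
#' residuals are totaled within PSU, and the variance is the stratified
#' between-PSU variance
#' `sum_h n_h/(n_h - 1) * sum_k (z_hk - zbar_h)^2`
#' over the strata represented in the state's sample (`n_h` = PSUs in
#' stratum `h`, `z_hk` = PSU residual total, `zbar_h` = their stratum mean).
#' Any contributing stratum with a single PSU is a hard error - no silent
#' centering or collapsing.
#'
#' @inheritParams weighted_prevalence
#' @return SE in percent.
#' @export
taylor_se <- function(data, state) {
  i <- state_rows(data, state)
  w <- data$weight[i]
  y <- data$outcome[i]
  W <- sum(w)
  if (W <= 0) stop("zero total weight for state '", state, "'")
  p <- sum(w * y) / W
  z <- w * (y - p) / W
  psu_id <- paste(data$stratum[i], data$psu[i], sep = "\r")
  z_psu <- tapply(z, psu_id, sum)
  strat_of_psu <- vapply(strsplit(names(z_psu), "\r", fixed = TRUE),
                         `[`, "", 1)
  v <- 0
  for (h in unique(strat_of_psu)) {
    zh <- z_psu[strat_of_psu == h]
    nh <- length(zh)
    if (nh < 2)
      stop("stratum '", h, "' has a single PSU for state '", state,
           "'; variance is not estimable (singleton stratum)")
    v <- v + nh / (nh - 1) * sum((zh - mean(zh))^2)
  }
  100 * sqrt(v)
}

#' Build a state estimate table from survey microdata
#'
#' One row per state present in the microdata, with the weighted prevalence
#' and its Taylor-linearization SE. States are estimated independently; no
#' pooling or small-area smoothing.
#'
#' @param data a [survey_microdata()].
#' @param survey,behavior labels recorded on the resulting table.
#' @return An [estimate_table()].
#' @export
estimate_table_from_microdata <- function(data, survey = "survey",
                                          behavior = "behavior") {
  states <- sort(unique(data$state))
  df <- data.frame(
    state = states,
    prevalence_pct = vapply(states, weighted_prevalence, 0, data = data),
    se_pct = vapply(states, taylor_se, 0, data = data),
    stringsAsFactors = FALSE)
  estimate_table(df, survey = survey, behavior = behavior)
}
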