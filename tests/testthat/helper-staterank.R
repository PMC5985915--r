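# Shared fixtures and independent oracles used across test files.

tiny_table <- function() {
  estimate_table(data.frame(
    state = c("Alpha", "Beta", "Gamma"),
    prevalence_pct = c(12.0, 9.5, 6.1),
    se_pct = c(1.1, 0.8, 0.6)), survey = "T", behavior = "toy")
}

# all permutations of 1..n (small n only)
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# classical tie-free Spearman formula
classical_spearman <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# stratified delete-one-PSU jackknife (JKn) SE of a weighted prevalence,
# independent of the Taylor-linearization implementation
jackknife_se <- function(data, state) {
  d <- as.data.frame(data)[data$state == state, ]
  p_hat <- sum(d$weight * d$outcome) / sum(d$weight)
  v <- 0
  for (h in unique(d$stratum)) {
    psus <- unique(d$psu[d$stratum == h])
    nh <- length(psus)
    for (k in psus) {
      drop <- d$stratum == h & d$psu == k
      dd <- d[!drop, ]
      in_h <- dd$stratum == h
      dd$weight[in_h] <- dd$weight[in_h] * nh / (nh - 1)
      p_k <- sum(dd$weight * dd$outcome) / sum(dd$weight)
      v <- v + (nh - 1) / nh * (p_k - p_hat)^2
    }
  }
  100 * sqrt(v)
}

# per-row rank by counting pairwise wins: rank_i = 1 + #{j : x_j > x_i}
pairwise_rank_oracle <- function(x) {
  n <- length(x)
  r <- integer(n)
  for (i in seq_len(n)) {
    wins <- sum(x > x[i])
    ties_before <- if (i > 1) sum(x[seq_len(i - 1)] == x[i]) else 0L
    r[i] <- 1L + wins + ties_before
  }
  r
}
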