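test_that("effective sample size matches the moment identity", {
  expect_equal(effective_sample_size(50, 5), 100)
  expect_equal(effective_sample_size(20, 2), 400)
  expect_error(effective_sample_size(0, 1), "boundary")
  expect_error(effective_sample_size(100, 1), "boundary")
  expect_error(effective_sample_size(50, 0), "positive")
})

test_that("binomial draws at the effective size reproduce the input SE", {
  tab <- estimate_table(data.frame(state = c("A", "B"),
                                   prevalence_pct = c(10, 25),
                                   se_pct = c(1.0, 1.8)))
  reps <- draw_replicates(tab, sim_config(n_sims = 100000,
                                          distribution = "binomial",
                                          seed = 5))
  for (j in 1:2) {
    expect_lt(abs(sd(reps[, j]) - tab$se_pct[j]) / tab$se_pct[j], 0.05)
    expect_lt(abs(mean(reps[, j]) - tab$prevalence_pct[j]), 0.05)
  }
})

test_that("replicate draws have the configured moments and are reproducible", {
  tab <- estimate_table(data.frame(state = c("A", "B"),
                                   prevalence_pct = c(10, 20),
                                   se_pct = c(1, 0)))
  cfg <- sim_config(n_sims = 100000, seed = 42)
  reps <- draw_replicates(tab, cfg)
  # analytic sampling-error bounds: mean within ~4 SE/sqrt(n), sd within 2%
  expect_lt(abs(mean(reps[, 1]) - 10), 0.013)
  expect_lt(abs(sd(reps[, 1]) - 1) / 1, 0.02)
  # zero-SE column is exactly the point estimate
  expect_true(all(reps[, 2] == 20))
  expect_identical(reps, draw_replicates(tab, cfg))
  # distinct seeds give distinct matrices
  expect_false(identical(reps, draw_replicates(tab, sim_config(
    n_sims = 100000, seed = 43))))
})

test_that("all four distributional families draw with matched moments", {
  tab <- estimate_table(data.frame(state = c("A", "B"),
                                   prevalence_pct = c(8, 22),
                                   se_pct = c(0.9, 1.6)))
  for (dist in c("normal", "truncated_normal", "binomial", "lognormal")) {
    reps <- draw_replicates(tab, sim_config(n_sims = 50000,
                                            distribution = dist, seed = 9))
    for (j in 1:2) {
      expect_lt(abs(mean(reps[, j]) - tab$prevalence_pct[j]), 0.1)
      expect_lt(abs(sd(reps[, j]) - tab$se_pct[j]) / tab$se_pct[j], 0.06)
    }
  }
  expect_true(all(draw_replicates(tab, sim_config(
    n_sims = 100, distribution = "truncated_normal", seed = 1)) >= 0))
  expect_error(sim_config(distribution = "gamma"))
  bad <- estimate_table(data.frame(state = c("A", "B"),
                                   prevalence_pct = c(0, 10),
                                   se_pct = c(1, 1)))
  expect_error(draw_replicates(bad, sim_config(n_sims = 10,
                                               distribution = "binomial")),
               "degenerate")
  expect_error(draw_replicates(bad, sim_config(n_sims = 10,
                                               distribution = "lognormal")),
               "positive prevalence")
})

test_that("ranking matches the pairwise-comparison oracle and is a permutation", {
  expect_equal(as.vector(rank_replicates(matrix(c(10, 5, 1), 1, 3))),
               c(1L, 2L, 3L))
  set.seed(13)
  reps <- matrix(rnorm(1000 * 3, mean = 10), 1000, 3)
  rk <- rank_replicates(reps)
  for (i in seq_len(nrow(reps)))
    expect_equal(as.vector(rk[i, ]), pairwise_rank_oracle(reps[i, ]))
  # permutation property on wider matrices, including exact ties
  reps <- matrix(sample(1:4, 200 * 8, replace = TRUE), 200, 8)
  rk <- rank_replicates(reps)
  expect_true(all(apply(rk, 1, function(r) identical(sort(r), 1:8))))
  expect_error(rank_replicates(matrix(c(1, NA), 1, 2)), "non-finite")
})

test_that("ties within a row are broken by input column order", {
  rk <- rank_replicates(matrix(c(5, 5, 5), 1, 3))
  expect_equal(as.vector(rk), c(1L, 2L, 3L))
})

test_that("zero SEs recover deterministic ranks with degenerate CIs", {
  tab <- estimate_table(data.frame(state = c("A", "B", "C"),
                                   prevalence_pct = c(7, 12, 3),
                                   se_pct = c(0, 0, 0)))
  rt <- rank_states(tab, sim_config(n_sims = 2000, seed = 1))
  expect_equal(rt$median_rank, c(2L, 1L, 3L))
  expect_equal(rt$ci_low, rt$median_rank)
  expect_equal(rt$ci_high, rt$median_rank)
})

test_that("median rank uses the lower-median order statistic", {
  # 4 simulated ranks per state; lower median = 2nd order statistic
  rk <- structure(matrix(c(1L, 1L, 2L, 2L,
                           2L, 2L, 1L, 1L), 4, 2,
                         dimnames = list(NULL, c("A", "B"))),
                  class = c("rank_matrix", "matrix", "array"))
  rt <- suppressWarnings(summarize_ranks(rk, sim_config(n_sims = 4)))
  expect_equal(rt$median_rank, c(1L, 1L))
  expect_true(all(rt$ci_low <= rt$median_rank &
                    rt$median_rank <= rt$ci_high))
  counts <- attr(rt, "rank_counts")
  expect_equal(colSums(counts), c(A = 4, B = 4))
  expect_warning(summarize_ranks(rk, sim_config(n_sims = 4)), "unstable")
})

test_that("summaries carry estimate columns and respect CI ordering", {
  tab <- tiny_table()
  rt <- rank_states(tab, sim_config(n_sims = 5000, seed = 2))
  expect_s3_class(rt, "rank_table")
  expect_named(rt, c("state", "prevalence_pct", "se_pct", "median_rank",
                     "ci_low", "ci_high"))
  expect_true(all(rt$ci_low <= rt$median_rank &
                    rt$median_rank <= rt$ci_high))
  expect_equal(colSums(attr(rt, "rank_counts")),
               setNames(rep(5000, 3), tab$state))
})

test_that("equal-SE tables rank monotonically in the point estimate", {
  tab <- estimate_table(data.frame(state = sprintf("S%02d", 1:10),
                                   prevalence_pct = seq(20, 2, length.out = 10),
                                   se_pct = 1.5))
  rt <- rank_states(tab, sim_config(n_sims = 10000, seed = 8))
  expect_true(all(diff(rt$median_rank) >= 0))
})

test_that("simultaneous intervals contain individual ones and jointly cover", {
  tab <- load_packaged_table("NSDUH", "cigarette")
  cfg_i <- sim_config(n_sims = 5000, seed = 4, mode = "individual")
  reps <- draw_replicates(tab, cfg_i)
  rk <- rank_replicates(reps)
  ind <- summarize_ranks(rk, cfg_i, table = tab)
  adj <- simultaneous_adjust(rk, 0.95)
  expect_true(all(adj$intervals$ci_low <= ind$ci_low))
  expect_true(all(adj$intervals$ci_high >= ind$ci_high))
  expect_gte(adj$joint_coverage, 0.95)
  # the same intervals flow through summarize_ranks in simultaneous mode
  sim <- summarize_ranks(rk, sim_config(n_sims = 5000, seed = 4,
                                        mode = "simultaneous"), table = tab)
  expect_equal(sim$ci_low, adj$intervals$ci_low)
  expect_equal(sim$ci_high, adj$intervals$ci_high)
  expect_equal(sim$median_rank, ind$median_rank)
})

test_that("simultaneous adjustment degenerates correctly at the extremes", {
  # single state: only one rank exists
  rk <- structure(matrix(1L, 2000, 1, dimnames = list(NULL, "A")),
                  class = c("rank_matrix", "matrix", "array"))
  adj <- simultaneous_adjust(rk, 0.95)
  expect_equal(adj$intervals$ci_low, 1L)
  expect_equal(adj$intervals$ci_high, 1L)
  expect_equal(adj$joint_coverage, 1)

  # well-separated states (gaps > 6 SE): simultaneous = individual = point
  tab <- estimate_table(data.frame(state = c("A", "B", "C"),
                                   prevalence_pct = c(30, 20, 10),
                                   se_pct = 1))
  cfg <- sim_config(n_sims = 5000, seed = 6, mode = "simultaneous")
  rt <- rank_states(tab, cfg)
  expect_equal(rt$median_rank, 1:3)
  expect_equal(rt$ci_low, 1:3)
  expect_equal(rt$ci_high, 1:3)
})

test_that("configuration files round-trip through the key-value reader", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("n_sims = 5000", "distribution: lognormal", "seed = 99",
               "# comment", "ci_level = 0.9", "mode = simultaneous"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_sims, 5000L)
  expect_equal(cfg$distribution, "lognormal")
  expect_equal(cfg$ci_level, 0.9)
  expect_equal(cfg$mode, "simultaneous")
  expect_equal(cfg$seed, 99L)
  writeLines("bogus_key = 1", path)
  expect_error(read_sim_config(path), "unknown configuration key")
  expect_error(sim_config(n_sims = 0), "positive")
  expect_error(sim_config(ci_level = 1.2), "ci_level")
})

test_that("rank distribution dumps have one row per attained rank", {
  rt <- rank_states(tiny_table(), sim_config(n_sims = 2000, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_rank_distribution(rt, path)
  df <- read.csv(path)
  expect_named(df, c("state", "rank", "count"))
  expect_equal(sum(df$count), 3 * 2000)
  expect_true(all(df$count > 0))
})
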