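resolve_input_table <- function(input, survey = NULL, behavior = NULL) {
  if (inherits(input, "estimate_table")) return(input)
  if (input %in% packaged_tables()) {
    parts <- strsplit(input, "_", fixed = TRUE)[[1]]
    return(load_packaged_table(parts[1],
                               paste(parts[-1], collapse = "_")))
  }
  read_estimate_table(input,
                      survey = if (is.null(survey)) "survey" else survey,
                      behavior = if (is.null(behavior)) "behavior" else behavior)
}

write_manifest <- function(path, config, inputs, outputs, timings) {
  lines <- c(
    sprintf("software_version: staterank %s",
            as.character(utils::packageVersion("staterank"))),
    sprintf("seed: %d", config$seed),
    sprintf("n_sims: %d", config$n_sims),
    sprintf("distribution: %s", config$distribution),
    sprintf("ci_level: %g", config$ci_level),
    sprintf("mode: %s", config$mode),
    vapply(names(inputs), function(k)
      sprintf("input: %s md5=%s", k, inputs[[k]]), ""),
    vapply(names(outputs), function(k)
      sprintf("output: %s md5=%s", k, outputs[[k]]), ""),
    vapply(names(timings), function(k)
      sprintf("timing_sec: %s %.3f", k, timings[[k]]), ""))
  writeLines(lines, path)
  invisible(path)
}

digest_files <- function(paths) {
  out <- as.character(tools::md5sum(paths))
  names(out) <- basename(paths)
  out
}

#' Run the Monte Carlo ranking stage on one table
#'
#' Loads a packaged fixture (by name, e.g. `"nsduh_cigarette"`) or a user
#' CSV, runs [rank_states()], and writes the rank table plus a run manifest
#' (configuration echo, input/output MD5 digests, timing) to `out_dir`.
#'
#' @param input fixture name, CSV path, or an [estimate_table()].
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @param name basename for the outputs; default derived from the input.
#' @return The `rank_table`, invisibly; outputs `<name>_ranks.csv`,
#'   `<name>_rankdist.csv` and `<name>_manifest.txt`.
#' @export
run_rank <- function(input, config = sim_config(), out_dir = ".",
                     name = NULL) {
  t0 <- proc.time()["elapsed"]
  tab <- resolve_input_table(input)
  if (is.null(name))
    name <- if (is.character(input)) {
      gsub("\\.csv$", "", basename(input))
    } else {
      paste(tolower(attr(tab, "survey")), attr(tab, "behavior"), sep = "_")
    }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rt <- rank_states(tab, config)
  rank_path <- file.path(out_dir, paste0(name, "_ranks.csv"))
  dist_path <- file.path(out_dir, paste0(name, "_rankdist.csv"))
  write_rank_table(rt, rank_path)
  write_rank_distribution(rt, dist_path)
  input_digest <- if (is.character(input) && file.exists(input))
    digest_files(input) else stats::setNames(character(0), character(0))
  manifest <- file.path(out_dir, paste0(name, "_manifest.txt"))
  write_manifest(manifest, config, input_digest,
                 digest_files(c(rank_path, dist_path)),
                 list(rank = proc.time()["elapsed"] - t0))
  invisible(rt)
}

#' Reproduce the full two-survey, three-behavior ranking analysis
#'
#' Runs the whole pipeline on the six packaged prevalence tables: Monte
#' Carlo rank tables for each survey x behavior; per-behavior figure data
#' (both surveys' median ranks and CIs, ordered by the NSDUH median rank);
#' cross-survey rank correlations per behavior; within-survey cross-behavior
#' correlations (computed both on the states shared by the two surveys and
#' on all states available within the survey); and paired t tests of YRBSS
#' versus NSDUH prevalence per behavior with Bonferroni adjustment across
#' the three behaviors.
#'
#' @param out_dir output directory.
#' @param seed integer seed; per-table seeds are derived deterministically.
#' @param n_sims Monte Carlo replicates per table (default 100000).
#' @param mode `"individual"` or `"simultaneous"` rank CIs.
#' @return Invisible list with the six rank tables, the correlation data
#'   frame and the paired-comparison data frame.
#' @export
run_paper <- function(out_dir = ".", seed = 1L, n_sims = 100000L,
                      mode = "individual") {
  t0 <- proc.time()["elapsed"]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fixtures <- packaged_tables()
  tables <- list()
  rank_tables <- list()
  outputs <- character(0)
  for (k in seq_along(fixtures)) {
    fx <- fixtures[k]
    tables[[fx]] <- resolve_input_table(fx)
    cfg <- sim_config(n_sims = n_sims, seed = seed + k - 1L, mode = mode)
    rank_tables[[fx]] <- rank_states(tables[[fx]], cfg)
    p <- file.path(out_dir, paste0(fx, "_ranks.csv"))
    write_rank_table(rank_tables[[fx]], p)
    outputs <- c(outputs, p)
  }
  behaviors <- c("cigarette", "binge_alcohol", "marijuana")
  # figure data: both surveys per behavior, ordered by NSDUH median rank
  for (bh in behaviors) {
    a <- rank_tables[[paste0("nsduh_", bh)]]
    b <- rank_tables[[paste0("yrbss_", bh)]]
    fig <- rbind(
      data.frame(state = a$state, median_rank = a$median_rank,
                 ci_low = a$ci_low, ci_high = a$ci_high, survey = "NSDUH"),
      data.frame(state = b$state, median_rank = b$median_rank,
                 ci_low = b$ci_low, ci_high = b$ci_high, survey = "YRBSS"))
    ord <- order(match(fig$state, a$state[order(a$median_rank, a$state)]),
                 fig$survey)
    p <- file.path(out_dir, paste0("figure_", bh, ".csv"))
    utils::write.csv(fig[ord, ], p, row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, p)
  }
  # correlations: cross-survey per behavior; within-survey cross-behavior
  pairs <- data.frame(a = paste0("nsduh_", behaviors),
                      b = paste0("yrbss_", behaviors),
                      label = paste0("cross_survey_", behaviors),
                      stringsAsFactors = FALSE)
  within <- utils::combn(behaviors, 2)
  for (sv in c("nsduh", "yrbss")) {
    pairs <- rbind(pairs, data.frame(
      a = paste0(sv, "_", within[1, ]), b = paste0(sv, "_", within[2, ]),
      label = paste0(sv, "_", within[1, ], "_x_", within[2, ]),
      stringsAsFactors = FALSE))
  }
  cons <- consistency_matrix(rank_tables, pairs)
  # within-survey correlations restricted to the cross-survey state set
  shared_tabs <- rank_tables
  for (bh in behaviors) {
    common <- intersect(rank_tables[[paste0("nsduh_", bh)]]$state,
                        rank_tables[[paste0("yrbss_", bh)]]$state)
    for (sv in c("nsduh", "yrbss")) {
      key <- paste0(sv, "_", bh)
      shared_tabs[[key]] <-
        shared_tabs[[key]][shared_tabs[[key]]$state %in% common, ]
    }
  }
  pairs_within <- pairs[-(1:3), ]
  pairs_within$label <- paste0(pairs_within$label, "_shared_states")
  cons <- rbind(cons, consistency_matrix(shared_tabs, pairs_within))
  p <- file.path(out_dir, "consistency.csv")
  utils::write.csv(cons, p, row.names = FALSE, quote = FALSE)
  outputs <- c(outputs, p)
  # paired t tests, YRBSS minus NSDUH, Bonferroni across the three behaviors
  tt <- do.call(rbind, lapply(behaviors, function(bh) {
    m <- align_states(tables[[paste0("nsduh_", bh)]],
                      tables[[paste0("yrbss_", bh)]])
    r <- paired_t(m$prevalence_pct.a, m$prevalence_pct.b, m_comparisons = 3)
    data.frame(comparison = paste0("yrbss_vs_nsduh_", bh),
               n_pairs = r$n_pairs, mean_diff = r$mean_diff, t = r$t_stat,
               p_raw = r$p_raw, p_adjusted = r$p_adjusted,
               stringsAsFactors = FALSE)
  }))
  p <- file.path(out_dir, "paired_tests.csv")
  utils::write.csv(tt, p, row.names = FALSE, quote = FALSE)
  outputs <- c(outputs, p)
  cfg <- sim_config(n_sims = n_sims, seed = seed, mode = mode)
  fixture_paths <- vapply(fixtures, function(fx)
    system.file("extdata", paste0(fx, ".csv"), package = "staterank"), "")
  write_manifest(file.path(out_dir, "manifest.txt"), cfg,
                 digest_files(fixture_paths), digest_files(outputs),
                 list(total = proc.time()["elapsed"] - t0))
  invisible(list(rank_tables = rank_tables, consistency = cons,
                 paired_tests = tt))
}
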