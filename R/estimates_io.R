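#' @keywords internal
"_PACKAGE"

SURVEYS <- c("NSDUH", "YRBSS")
BEHAVIORS <- c("cigarette", "binge_alcohol", "marijuana")

#' Construct a validated state estimate table
#'
#' An estimate table holds one row per state for a single survey x behavior
#' combination: the estimated prevalence (percent) and its standard error
#' (percent). Prevalences and standard errors are kept on the percent scale
#' throughout the package, exactly as surveillance reports print them.
#'
#' @param df data frame with columns `state`, `prevalence_pct`, `se_pct`
#'   (extra columns such as `printed_rank` are preserved).
#' @param survey survey label, e.g. `"NSDUH"` or `"YRBSS"`.
#' @param behavior behavior label, e.g. `"cigarette"`.
#' @return An `estimate_table`: a data frame with attributes `survey` and
#'   `behavior`.
#' @export
estimate_table <- function(df, survey = "survey", behavior = "behavior") {
  req <- c("state", "prevalence_pct", "se_pct")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df$state <- as.character(df$state)
  df$prevalence_pct <- as.numeric(df$prevalence_pct)
  df$se_pct <- as.numeric(df$se_pct)
  if (nrow(df) < 2)
    stop("an estimate table needs at least 2 states, got ", nrow(df))
  dup <- df$state[duplicated(df$state)]
  if (length(dup) > 0)
    stop("duplicate state identifier(s): ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(df$prevalence_pct) |
                 df$prevalence_pct < 0 | df$prevalence_pct > 100)
  if (length(bad) > 0)
    stop("prevalence outside [0, 100] in row ", bad[1],
         " (", df$state[bad[1]], ")")
  bad <- which(!is.finite(df$se_pct) | df$se_pct < 0)
  if (length(bad) > 0)
    stop("negative or non-finite SE in row ", bad[1], " (", df$state[bad[1]], ")")
  rownames(df) <- NULL
  structure(df, survey = survey, behavior = behavior,
            class = c("estimate_table", "data.frame"))
}

#' Read a state estimate table from delimited text
#'
#' Expects a comma-separated UTF-8 file with a header and at least the
#' columns `state`, `prevalence_pct`, `se_pct`. Row order is preserved.
#'
#' @param path file path.
#' @inheritParams estimate_table
#' @return An [estimate_table()].
#' @export
read_estimate_table <- function(path, survey = "survey", behavior = "behavior") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  estimate_table(df, survey = survey, behavior = behavior)
}

#' Write a state estimate table as delimited text
#'
#' Inverse of [read_estimate_table()]: `read(write(x))` reproduces `x`
#' bit-exactly on the decimal text representation.
#'
#' @param table an [estimate_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_estimate_table <- function(table, path) {
  if (!nzchar(path)) stop("empty output path")
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a packaged survey x behavior prevalence table
#'
#' Six state-level tables of adolescent (age 14-17) past-month substance-use
#' prevalence, 2011-2015, ship with the package: two surveys (NSDUH, an
#' annual in-home survey covering all 50 states plus the District of
#' Columbia; YRBSS, a biennial school-based survey covering 47 states)
#' crossed with three behaviors (cigarette smoking, binge alcohol drinking,
#' marijuana use). Values are transcribed at the printed one-decimal
#' precision. The YRBSS marijuana table has 46 states (no Hawaii data). Each
#' table also carries the survey report's published median rank in column
#' `printed_rank`, used for rank-consistency checks against published values.
#'
#' @param survey `"NSDUH"` or `"YRBSS"` (case-insensitive).
#' @param behavior `"cigarette"`, `"binge_alcohol"`, or `"marijuana"`.
#' @return An [estimate_table()] with the extra column `printed_rank`.
#' @examples
#' tab <- load_packaged_table("NSDUH", "cigarette")
#' nrow(tab)  # 51
#' @export
load_packaged_table <- function(survey, behavior) {
  survey <- toupper(survey)
  if (!survey %in% SURVEYS)
    stop("unknown survey '", survey, "'; expected one of: ",
         paste(SURVEYS, collapse = ", "))
  behavior <- match.arg(tolower(behavior), BEHAVIORS)
  fname <- paste0(tolower(survey), "_", behavior, ".csv")
  path <- system.file("extdata", fname, package = "staterank")
  if (!nzchar(path)) stop("packaged fixture not found: ", fname)
  read_estimate_table(path, survey = survey, behavior = behavior)
}

#' Names of the packaged fixtures
#'
#' @return Character vector of the six `survey_behavior` fixture names.
#' @export
packaged_tables <- function() {
  as.vector(outer(tolower(SURVEYS), BEHAVIORS, paste, sep = "_"))
}

#' Write a rank table as delimited text
#'
#' Rows are ordered by median rank, ties broken alphabetically by state, the
#' convention used throughout for printed league tables.
#'
#' @param table a `rank_table` as returned by [rank_states()] or
#'   [summarize_ranks()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rank_table <- function(table, path) {
  if (!nzchar(path)) stop("empty output path")
  req <- c("state", "median_rank", "ci_low", "ci_high")
  miss <- setdiff(req, names(table))
  if (length(miss) > 0)
    stop("not a rank table; missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(table)
  df <- df[order(df$median_rank, df$state), , drop = FALSE]
  cols <- intersect(c("state", "prevalence_pct", "se_pct",
                      "median_rank", "ci_low", "ci_high"), names(df))
  utils::write.csv(df[, cols, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Two-letter abbreviations for full state names
#'
#' Maps full names as printed in surveillance tables (50 states plus
#' "District of Columbia") to USPS two-letter codes. Unrecognized names are
#' returned unchanged.
#'
#' @param x character vector of state names.
#' @return Character vector of the same length.
#' @export
state_abbrev <- function(x) {
  full <- c(datasets::state.name, "District of Columbia")
  abb <- c(datasets::state.abb, "DC")
  i <- match(x, full)
  out <- abb[i]
  out[is.na(i)] <- x[is.na(i)]
  out
}

#' @export
print.estimate_table <- function(x, ...) {
  cat(sprintf("<estimate_table> %s / %s: %d states, prevalence %.1f-%.1f%%\n",
              attr(x, "survey"), attr(x, "behavior"), nrow(x),
              min(x$prevalence_pct), max(x$prevalence_pct)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}
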