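# Eligibility cascade: age -> biomarker -> item missingness, with a
# stage-by-stage exclusion ledger. Stages are sequential and non-overlapping:
# a row failing an earlier stage is never counted again later.

#' Build an exclusion ledger from stage counts
#'
#' The ledger records, in cascade order, how many records each eligibility
#' stage removed and enforces the identity
#' `final_n = initial_n - removed_under_age - removed_no_biomarker -
#' removed_missing`.
#'
#' @param initial_n Records before filtering.
#' @param removed_under_age Removed by the minimum-age criterion.
#' @param removed_no_biomarker Removed for unavailable biomarker data.
#' @param removed_missing Removed for missing analysis variables.
#' @return A tibble of class `exclusion_ledger` with columns `stage`,
#'   `n_removed`, `n_remaining`.
#' @export
#' @examples
#' led <- exclusion_ledger(72250, 6688, 5798, 691)
#' final_n(led)  # 59073
exclusion_ledger <- function(initial_n, removed_under_age,
                             removed_no_biomarker, removed_missing) {
  counts <- c(initial_n, removed_under_age, removed_no_biomarker, removed_missing)
  if (any(counts < 0)) abort("ledger counts must be non-negative")
  remaining <- initial_n - cumsum(c(0, removed_under_age, removed_no_biomarker,
                                    removed_missing))
  if (any(remaining < 0)) abort("stage removals exceed the available records")
  led <- tibble::tibble(
    stage = c("initial", "under_age", "no_biomarker", "missing_items"),
    n_removed = c(0L, removed_under_age, removed_no_biomarker, removed_missing),
    n_remaining = remaining
  )
  class(led) <- c("exclusion_ledger", class(led))
  led
}

#' @rdname exclusion_ledger
#' @param ledger An `exclusion_ledger`.
#' @export
final_n <- function(ledger) {
  ledger$n_remaining[nrow(ledger)]
}

#' @rdname exclusion_ledger
#' @export
initial_n <- function(ledger) {
  ledger$n_remaining[1]
}

#' Apply the eligibility cascade to a survey table
#'
#' Removes, in order: (1) respondents below `min_age`; (2) respondents with
#' `biomarker_available = 0`; (3) respondents with any missing cell among the
#' analysis variables (predictors and indicator items in the codebook).
#' Each stage is counted against the population surviving the previous stage,
#' so a row that is both under-age and biomarker-missing counts only in the
#' age stage.
#'
#' @param table Survey tibble with `age` and `biomarker_available` columns.
#' @param codebook Codebook defining the analysis variables; defaults to the
#'   codebook attached to `table`, else [default_codebook()].
#' @param min_age Minimum age in years (inclusive).
#' @return A list of class `cohort` with elements `data` (the filtered
#'   tibble) and `ledger` (an [exclusion_ledger()]).
#' @export
#' @examples
#' tab <- generate_survey(synth_config(n = 300, seed = 2))
#' coh <- apply_filters(tab)
#' coh$ledger
apply_filters <- function(table, codebook = NULL, min_age = 45) {
  if (nrow(table) == 0) abort("cannot filter an empty table")
  codebook <- codebook %||% attr(table, "codebook") %||% default_codebook()
  vars <- intersect(codebook$name, names(table))
  n0 <- nrow(table)

  keep_age <- table$age >= min_age
  removed_age <- sum(!keep_age)
  t1 <- table[keep_age, ]

  keep_bio <- t1$biomarker_available == 1
  removed_bio <- sum(!keep_bio)
  t2 <- t1[keep_bio, ]

  complete <- if (length(vars)) stats::complete.cases(t2[vars]) else rep(TRUE, nrow(t2))
  removed_miss <- sum(!complete)
  t3 <- t2[complete, ]

  led <- exclusion_ledger(n0, removed_age, removed_bio, removed_miss)
  if (nrow(t3) == 0) warn("all records removed by the eligibility cascade")
  attr(t3, "codebook") <- codebook
  structure(list(data = t3, ledger = led), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Filtered cohort:", nrow(x$data), "of", initial_n(x$ledger),
      "records retained\n")
  print(tibble::as_tibble(x$ledger))
  invisible(x)
}

#' @method tidy cohort
#' @export
tidy.cohort <- function(x, ...) {
  tibble::as_tibble(x$ledger)
}

#' @method glance cohort
#' @export
glance.cohort <- function(x, ...) {
  led <- x$ledger
  tibble::tibble(
    initial_n = initial_n(led),
    removed_under_age = led$n_removed[2],
    removed_no_biomarker = led$n_removed[3],
    removed_missing = led$n_removed[4],
    final_n = final_n(led)
  )
}

#' Serialize an exclusion ledger
#'
#' Writes the ledger both as plain text (one stage per line) and as JSON.
#'
#' @param ledger An [exclusion_ledger()].
#' @param path File path; `write_ledger_json()` writes JSON,
#'   `write_ledger_text()` a line-per-stage text rendering.
#' @return `path`, invisibly.
#' @export
write_ledger_json <- function(ledger, path) {
  jsonlite::write_json(tibble::as_tibble(ledger), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_ledger_json
#' @export
write_ledger_text <- function(ledger, path) {
  lines <- sprintf("%-14s removed %6d  remaining %6d",
                   ledger$stage, ledger$n_removed, ledger$n_remaining)
  writeLines(lines, path)
  invisible(path)
}
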