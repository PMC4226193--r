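TT_REQUIRED_COLS <- c("therapeutic_class", unname(PHASE_PROB_COLS))
TT_OPTIONAL_COLS <- "printed_overall_success"

#' Read a phase-transition probability table
#'
#' Reads a CSV of per-class clinical phase-transition probabilities. The file
#' stores probabilities as percentages (0–100), exactly as such tables are
#' printed; the returned tibble holds fractions in \[0, 1\]. Conversion
#' divides by 100 exactly once, here at parse time — everything downstream
#' works in fractions.
#'
#' Required header:
#' `therapeutic_class,p_phase1_to_2,p_phase2_to_3,p_phase3_to_rr,p_rr_to_approval`
#' with an optional trailing `printed_overall_success` column carrying the
#' source's printed overall clinical-approval success rate, used by
#' [check_printed_success()].
#'
#' @param path Path to the CSV file.
#' @return A tibble with one row per therapeutic class and all probabilities
#'   as fractions.
#' @seealso [dimasi_transitions()] for the packaged table,
#'   [write_transition_table()] for the inverse.
#' @examples
#' tab <- dimasi_transitions()
#' tab
#' @export
read_transition_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Transition table file not found: %s", path))
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) abort(sprintf("Cannot parse %s as CSV: %s", path, conditionMessage(e)))
  )
  missing_cols <- setdiff(TT_REQUIRED_COLS, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Transition table %s is missing required column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  unknown <- setdiff(names(raw), c(TT_REQUIRED_COLS, TT_OPTIONAL_COLS))
  if (length(unknown) > 0) {
    abort(sprintf("Transition table %s has unrecognised column(s): %s",
                  path, paste(unknown, collapse = ", ")))
  }
  if (nrow(raw) == 0) abort(sprintf("Transition table %s contains no data rows", path))

  num_cols <- intersect(c(unname(PHASE_PROB_COLS), TT_OPTIONAL_COLS), names(raw))
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric or missing value in column '%s' at data row %d of %s",
                    col, bad[1], path))
    }
    out_of_range <- which(vals < 0 | vals > 100)
    if (length(out_of_range) > 0) {
      abort(sprintf(
        "Percentage out of range [0, 100] in column '%s' at data row %d of %s (value %s)",
        col, out_of_range[1], path, raw[[col]][out_of_range[1]]))
    }
    raw[[col]] <- vals / 100
  }

  cls <- raw$therapeutic_class
  if (any(is.na(cls) | !nzchar(trimws(cls)))) {
    abort(sprintf("Empty therapeutic_class name at data row %d of %s",
                  which(is.na(cls) | !nzchar(trimws(cls)))[1], path))
  }
  dup <- cls[duplicated(cls)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate therapeutic_class '%s' at data row %d of %s",
                  dup[1], which(duplicated(cls))[1], path))
  }
  as_tibble(raw)
}

#' Write a phase-transition probability table
#'
#' Inverse of [read_transition_table()]: fractions are written back as
#' percentages with trailing zeros trimmed (`0.582` becomes `58.2`, `1`
#' becomes `100`), the canonical form of the packaged fixture, which therefore
#' round-trips byte-for-byte.
#'
#' @param table A transition-table tibble as returned by
#'   [read_transition_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transition_table <- function(table, path) {
  table <- validate_transition_table(table)
  out <- table
  for (col in intersect(c(unname(PHASE_PROB_COLS), TT_OPTIONAL_COLS), names(out))) {
    out[[col]] <- vapply(out[[col]] * 100, format_pct, character(1))
  }
  lines <- c(
    paste(names(out), collapse = ","),
    do.call(paste, c(unname(as.list(out)), sep = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

# canonical percentage formatting: plain decimal, trailing zeros trimmed
format_pct <- function(x) {
  s <- format(round(x, 6), scientific = FALSE, trim = TRUE)
  if (grepl("\\.", s)) s <- sub("\\.?0+$", "", s)
  s
}

# internal invariant check shared by consumers of a table
validate_transition_table <- function(table) {
  if (!is.data.frame(table)) abort("`table` must be a data frame of transition probabilities")
  missing_cols <- setdiff(TT_REQUIRED_COLS, names(table))
  if (length(missing_cols) > 0) {
    abort(sprintf("Transition table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  for (col in intersect(c(unname(PHASE_PROB_COLS), TT_OPTIONAL_COLS), names(table))) {
    p <- table[[col]]
    if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
      abort(sprintf("Column '%s' must hold probabilities as fractions in [0, 1]", col))
    }
  }
  if (anyDuplicated(table$therapeutic_class)) abort("Duplicate therapeutic_class names")
  as_tibble(table)
}

#' Per-class phase-transition probabilities, 1993–2004
#'
#' The packaged transition table: probabilities of advancing between clinical
#' development stages (Phase I to II, II to III, III to regulatory review,
#' review to approval) for eight therapeutic classes of drugs first tested in
#' humans between 1993 and 2004, as reported by DiMasi and colleagues. The
#' `printed_overall_success` column carries the source's printed overall
#' clinical-approval success rate for cross-validation; the product of the
#' four transition probabilities reproduces it to within 0.1 percentage
#' points for every class (see [check_printed_success()]).
#'
#' Systemic anti-infectives show the pattern motivating antibiotic-incentive
#' design: a low Phase I-to-II transition but high late-stage success, so
#' overall risk is concentrated early where investment is cheapest.
#'
#' @return A tibble with one row per therapeutic class; probabilities as
#'   fractions.
#' @examples
#' dimasi_transitions()
#' @export
dimasi_transitions <- function() {
  read_transition_table(
    system.file("extdata", "dimasi_phase_transitions.csv", package = "oma", mustWork = TRUE)
  )
}

#' Cumulative probability of approval from a given phase
#'
#' The probability that a candidate entering `from_phase` ultimately reaches
#' approval: the product of the per-phase transition probabilities from
#' `from_phase` through regulatory review. From `"approved"` the probability
#' is exactly 1 (empty product). Later entry phases can only raise or keep
#' the probability, since every factor is at most 1.
#'
#' @param table A transition-table tibble (see [read_transition_table()]).
#' @param class_name Therapeutic class name(s) present in `table`.
#' @param from_phase Phase(s) at which the candidate currently sits; recycled
#'   against `class_name`.
#' @return A numeric vector of approval probabilities (fractions).
#' @examples
#' tab <- dimasi_transitions()
#' cumulative_success(tab, "Systemic anti-infective", "phase1")
#' cumulative_success(tab, "Systemic anti-infective", "rr")
#' @export
cumulative_success <- function(table, class_name, from_phase = "phase1") {
  table <- validate_transition_table(table)
  unknown <- setdiff(unique(class_name), table$therapeutic_class)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown therapeutic class(es): %s. Available: %s.",
                  paste(sQuote(unknown), collapse = ", "),
                  paste(sQuote(table$therapeutic_class), collapse = ", ")))
  }
  n <- max(length(class_name), length(from_phase))
  class_name <- rep_len(class_name, n)
  from_phase <- rep_len(as.character(as_oma_phase(from_phase)), n)
  map2_dbl(class_name, from_phase, function(cl, ph) {
    row <- table[table$therapeutic_class == cl, , drop = FALSE]
    cols <- PHASE_PROB_COLS[remaining_phases(ph)]
    prod(as.numeric(as.matrix(row[1, cols, drop = FALSE])))
  })
}

#' Check a transition table against its printed overall success rates
#'
#' For each class with a `printed_overall_success` entry, compares 100 times
#' the product of its four transition probabilities against the printed
#' overall clinical-approval success rate. Deviations are reported in
#' percentage points; the default tolerance of 0.1 pp is the smallest bound
#' accommodating the rounding of all eight packaged rows (one class's
#' product rounds one tenth above its printed value — flagged in the report,
#' not failed).
#'
#' @param table A transition-table tibble.
#' @param tol_pp Tolerance in percentage points.
#' @return A tibble with one row per checked class: `product_pct` (computed),
#'   `printed_pct`, `deviation_pp` and `within_tol`. Empty when the table has
#'   no printed column.
#' @examples
#' check_printed_success(dimasi_transitions())
#' @export
check_printed_success <- function(table, tol_pp = 0.1) {
  table <- validate_transition_table(table)
  if (!"printed_overall_success" %in% names(table)) {
    return(tibble(therapeutic_class = character(0), product_pct = numeric(0),
                  printed_pct = numeric(0), deviation_pp = numeric(0),
                  within_tol = logical(0)))
  }
  product <- cumulative_success(table, table$therapeutic_class, "phase1")
  tibble(
    therapeutic_class = table$therapeutic_class,
    product_pct = 100 * product,
    printed_pct = 100 * table$printed_overall_success,
    deviation_pp = abs(100 * product - 100 * table$printed_overall_success),
    within_tol = abs(100 * product - 100 * table$printed_overall_success) <= tol_pp
  )
}
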