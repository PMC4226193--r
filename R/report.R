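# serializable view of each result type
as_report <- function(x, ...) UseMethod("as_report")

#' @export
as_report.default <- function(x, ...) x

#' @export
as_report.oma_simulation <- function(x, include_replicates = FALSE, ...) {
  out <- list(
    summary = as.list(x$summary),
    contracts = x$contracts,
    n_replicates = x$n_replicates,
    seed = x$seed,
    method = x$method
  )
  if (include_replicates) out$replicates <- x$replicates
  out
}

#' @export
as_report.oma_valuation <- function(x, ...) {
  list(
    drug_class = x$project$drug_class,
    current_phase = x$project$current_phase,
    npv = x$npv,
    terminal_payoff = x$terminal_payoff,
    phases = x$phases
  )
}

#' Serialize a result to JSON or CSV
#'
#' JSON output wraps the result with reproducibility metadata — package
#' version, the seed (when the result carries one or `seed` is given), and a
#' hash of the result — and serializes numbers at full precision; values
#' round-trip through [read_report()] unchanged. CSV output writes the
#' result's tabular form (its [tidy()] record for fitted objects, e.g. one
#' row per phase for a valuation) and suits spreadsheet consumption, at the
#' cost of the metadata envelope.
#'
#' @param result A package result (simulation, valuation, tibble, or any
#'   list of numbers).
#' @param path Output file path.
#' @param format `"json"` or `"csv"`.
#' @param seed Optional seed to record in the metadata.
#' @param ... Passed to the result's `as_report()` method (e.g.
#'   `include_replicates = TRUE` for simulations).
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("json", "csv"), seed = NULL, ...) {
  format <- match.arg(format)
  if (format == "csv") {
    tab <- if (inherits(result, c("oma_simulation", "oma_valuation"))) {
      generics::tidy(result)
    } else if (is.data.frame(result)) {
      result
    } else {
      abort("CSV reports require a tabular result; use format = 'json'")
    }
    readr::write_csv(tab, path)
    return(invisible(path))
  }
  body <- as_report(result, ...)
  if (is.null(seed) && is.list(body) && !is.null(body$seed)) seed <- body$seed
  payload <- list(
    metadata = list(
      package = "oma",
      version = as.character(utils::packageVersion("oma")),
      seed = seed,
      result_hash = rlang::hash(body)
    ),
    result = body
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", dataframe = "rows")
  invisible(path)
}

#' Reload a JSON report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return A list with `metadata` and `result` components; data frames come
#'   back as data frames.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
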