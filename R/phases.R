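# Development pipeline stages. Preclinical stages carry no transition
# probabilities in the packaged table and are deliberately absent: a config
# naming one is rejected rather than silently assigned a probability.
OMA_PHASES <- c("phase1", "phase2", "phase3", "rr", "approved")

# transition probability column governing the exit from each live phase
PHASE_PROB_COLS <- c(
  phase1 = "p_phase1_to_2",
  phase2 = "p_phase2_to_3",
  phase3 = "p_phase3_to_rr",
  rr     = "p_rr_to_approval"
)

#' Development phases
#'
#' The ordered stages of the modelled development pipeline: Phase I, Phase II,
#' Phase III, regulatory review (`"rr"`) and the terminal `"approved"` state.
#' Stages earlier than Phase I are not representable because the packaged
#' transition table supplies no probabilities for them.
#'
#' @param terminal If `FALSE`, drop the terminal `"approved"` state and return
#'   only the four live phases.
#' @return A character vector of phase names, ordered from earliest to latest.
#' @examples
#' oma_phases()
#' oma_phases(terminal = FALSE)
#' @export
oma_phases <- function(terminal = TRUE) {
  if (terminal) OMA_PHASES else OMA_PHASES[-length(OMA_PHASES)]
}

#' Coerce to a development phase
#'
#' Accepts phase names (case-insensitive; `"regulatory_review"` and `"review"`
#' are aliases for `"rr"`) and returns an ordered factor so phases compare
#' with `<` and `>=`.
#'
#' @param x Character vector of phase names.
#' @return An ordered factor with levels `phase1 < phase2 < phase3 < rr <
#'   approved`.
#' @examples
#' as_oma_phase("phase2") < as_oma_phase("rr")
#' @export
as_oma_phase <- function(x) {
  x <- tolower(as.character(x))
  x[x %in% c("regulatory_review", "regulatory review", "review")] <- "rr"
  bad <- unique(x[!x %in% OMA_PHASES & !is.na(x)])
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown development phase(s): %s. Phases earlier than phase1 are not supported; valid phases: %s.",
      paste(sQuote(bad), collapse = ", "), paste(OMA_PHASES, collapse = ", ")
    ))
  }
  factor(x, levels = OMA_PHASES, ordered = TRUE)
}

# live phases (and hence transition-probability columns) remaining between
# `from_phase` and approval; empty for "approved"
remaining_phases <- function(from_phase) {
  from_phase <- as_oma_phase(from_phase)
  stopifnot(length(from_phase) == 1)
  if (from_phase == "approved") return(character(0))
  live <- oma_phases(terminal = FALSE)
  live[match(as.character(from_phase), live):length(live)]
}
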