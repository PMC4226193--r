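#' Describe a development project from the firm's side
#'
#' The firm-side view of an antibiotic development programme: per-phase
#' investment costs and durations, option premiums received at each phase
#' (cash inflow from selling dose-options), the terminal payoff `M` earned at
#' approval (typically a market payout from [market_payout()] plus any
#' launch revenue being modelled), and the firm's annual discount rate.
#' `current_phase` marks where the programme currently sits, so a project
#' entering regulatory review is a single remaining stage.
#'
#' @param drug_class Therapeutic class name (matched to the transition table
#'   at valuation time).
#' @param phase_costs Named numeric phase->currency map of investment costs;
#'   unnamed phases default to 0.
#' @param phase_durations Named phase->years map; default 1 year per phase.
#' @param premiums_received Named phase->currency map of premiums collected
#'   at the start of each phase; default 0.
#' @param terminal_payoff Payoff `M` at approval (>= 0).
#' @param discount_rate Annual discount rate (fraction/year, >= 0).
#' @param current_phase Phase the programme is in now (default `"phase1"`).
#' @return A list of class `oma_project`.
#' @examples
#' development_project(
#'   "Systemic anti-infective",
#'   phase_costs = c(phase1 = 5e6, phase2 = 20e6, phase3 = 60e6, rr = 5e6),
#'   terminal_payoff = 5e8
#' )
#' @export
development_project <- function(drug_class, phase_costs,
                                phase_durations = NULL,
                                premiums_received = NULL,
                                terminal_payoff = 0,
                                discount_rate = 0,
                                current_phase = "phase1") {
  check_num(terminal_payoff, "terminal_payoff", min = 0)
  check_num(discount_rate, "discount_rate", min = 0)
  current_phase <- as_oma_phase(current_phase)
  if (current_phase == "approved") abort("`current_phase` must be a live development phase")
  structure(
    list(
      drug_class = as.character(drug_class),
      phase_costs = normalise_phase_map(phase_costs, "phase_costs", default = 0),
      phase_durations = normalise_phase_map(phase_durations, "phase_durations", default = 1),
      premiums_received = normalise_phase_map(premiums_received, "premiums_received", default = 0),
      terminal_payoff = terminal_payoff,
      discount_rate = discount_rate,
      current_phase = as.character(current_phase)
    ),
    class = "oma_project"
  )
}

#' @export
print.oma_project <- function(x, ...) {
  cat(sprintf("<oma_project> %s, from %s, terminal payoff %s, r = %s/yr\n",
              x$drug_class, x$current_phase, format(x$terminal_payoff, big.mark = ","),
              format(x$discount_rate)))
  invisible(x)
}

#' Value a staged project by backward induction
#'
#' The firm's continue/abandon decision engine. Working backwards from
#' approval, where the project is worth its terminal payoff `M`, each phase
#' `k` has continuation value
#' `-cost_k + premium_k + d_k * p_k * V(next)`, with `p_k` the class's
#' transition probability out of phase `k` and `d_k = (1 + r)^(-duration_k)`.
#' A value-maximising firm abandons whenever continuing is worth less than
#' nothing, so `V(k) = max(0, continuation_k)` — the abandonment floor is the
#' firm's real option, and it is why premiums paid at early phases can flip
#' a decision from abandon to continue. Premiums are credited at the start
#' of the phase in which they are received, before that phase's cost. At a
#' continuation value of exactly zero the firm continues (value-indifferent;
#' keeps decisions monotone in `M`).
#'
#' @param project A project from [development_project()].
#' @param table A transition table (see [read_transition_table()]).
#' @return An object of class `oma_valuation`: see [tidy.oma_valuation()] for
#'   the per-phase record and [glance.oma_valuation()] for the one-row
#'   summary. The overall project NPV is the value at the current phase.
#' @examples
#' tab <- dimasi_transitions()
#' proj <- development_project(
#'   "Systemic anti-infective",
#'   phase_costs = c(phase1 = 5e6, phase2 = 20e6, phase3 = 60e6, rr = 5e6),
#'   terminal_payoff = 5e8
#' )
#' val <- backward_induction_value(proj, tab)
#' tidy(val)
#' glance(val)
#' @export
backward_induction_value <- function(project, table) {
  stopifnot(inherits(project, "oma_project"))
  table <- validate_transition_table(table)
  if (!project$drug_class %in% table$therapeutic_class) {
    abort(sprintf("Unknown therapeutic class %s. Available: %s.",
                  sQuote(project$drug_class),
                  paste(sQuote(table$therapeutic_class), collapse = ", ")))
  }
  row <- table[table$therapeutic_class == project$drug_class, , drop = FALSE]
  phases <- remaining_phases(project$current_phase)

  v_next <- project$terminal_payoff
  records <- vector("list", length(phases))
  for (i in rev(seq_along(phases))) {
    ph <- phases[i]
    p_k <- as.numeric(row[[PHASE_PROB_COLS[[ph]]]])
    d_k <- (1 + project$discount_rate)^(-project$phase_durations[[ph]])
    cont <- -project$phase_costs[[ph]] + project$premiums_received[[ph]] +
      d_k * p_k * v_next
    v_k <- max(0, cont)
    records[[i]] <- tibble(
      phase = ph,
      cost = project$phase_costs[[ph]],
      premium = project$premiums_received[[ph]],
      p_transition = p_k,
      discount_factor = d_k,
      continuation = cont,
      value = v_k,
      decision = if (cont >= 0) "continue" else "abandon"
    )
    v_next <- v_k
  }
  per_phase <- bind_rows(records)
  structure(
    list(
      phases = per_phase,
      npv = v_next,
      terminal_payoff = project$terminal_payoff,
      project = project
    ),
    class = "oma_valuation"
  )
}

#' @export
print.oma_valuation <- function(x, ...) {
  cat(sprintf("<oma_valuation> %s from %s: NPV = %s (%s at %s)\n",
              x$project$drug_class, x$project$current_phase,
              format(x$npv, big.mark = ","),
              x$phases$decision[1], x$phases$phase[1]))
  print(x$phases)
  invisible(x)
}

#' Per-phase record of a backward-induction valuation
#'
#' @param x An `oma_valuation` from [backward_induction_value()].
#' @param ... Unused.
#' @return A tibble with one row per remaining phase: cost, premium,
#'   transition probability, discount factor, continuation value, value after
#'   the abandonment floor, and the continue/abandon decision.
#' @method tidy oma_valuation
#' @export
tidy.oma_valuation <- function(x, ...) x$phases

#' One-row summary of a backward-induction valuation
#'
#' @param x An `oma_valuation` from [backward_induction_value()].
#' @param ... Unused.
#' @return A one-row tibble: `npv`, the decision at the current phase, the
#'   number of phases abandoned, and the terminal payoff.
#' @method glance oma_valuation
#' @export
glance.oma_valuation <- function(x, ...) {
  tibble(
    drug_class = x$project$drug_class,
    current_phase = x$project$current_phase,
    npv = x$npv,
    decision = x$phases$decision[1],
    n_abandon = sum(x$phases$decision == "abandon"),
    terminal_payoff = x$terminal_payoff
  )
}

#' Smallest terminal payoff sustaining development
#'
#' The minimum payoff `M*` at approval for which the firm's decision at the
#' project's current phase is to continue. When premiums already cover every
#' phase's costs, `M* = 0`: push financing alone sustains the project. When
#' some phase is unreachable (a zero transition probability upstream of
#' positive net costs), no finite payoff helps and `Inf` is returned with a
#' warning. Otherwise `M*` is found by bisection to a relative tolerance of
#' `tol`, exploiting that the current-phase continuation value is
#' non-decreasing in the terminal payoff.
#'
#' @param project A project from [development_project()]; its
#'   `terminal_payoff` is ignored.
#' @param table A transition table.
#' @param tol Relative bisection tolerance.
#' @return A single number: the minimum viable terminal payoff (possibly
#'   `Inf`).
#' @examples
#' tab <- dimasi_transitions()
#' proj <- development_project("Systemic anti-infective",
#'                             phase_costs = c(phase1 = 1e6), current_phase = "phase1")
#' minimum_viable_payout(proj, tab)
#' @export
minimum_viable_payout <- function(project, table, tol = 1e-9) {
  stopifnot(inherits(project, "oma_project"))
  cont_at <- function(m) {
    project$terminal_payoff <- m
    val <- backward_induction_value(project, table)
    val$phases$continuation[1]
  }
  if (cont_at(0) >= 0) return(0)
  lo <- 0
  hi <- max(1, sum(project$phase_costs) * 2)
  while (cont_at(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e18) {
      warn("No finite terminal payoff makes continuation viable (a zero transition probability blocks the payoff); returning Inf")
      return(Inf)
    }
  }
  while ((hi - lo) > tol * max(hi, 1)) {
    mid <- (lo + hi) / 2
    if (cont_at(mid) >= 0) hi <- mid else lo <- mid
  }
  hi
}
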