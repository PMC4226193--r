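#' Net payoff of a vanilla call option
#'
#' The textbook payoff used to motivate the options market: having paid
#' `premium` for the right to buy at `strike`, the holder nets
#' `max(share_price - strike, 0) - premium`. Exercise occurs only when the
#' price is strictly above the strike; at equality the option is left
#' unexercised (the payoff is identical either way, the convention just makes
#' the decision deterministic). The net is never below `-premium`.
#'
#' @param share_price Current price of the underlying (vectorised).
#' @param strike Strike price.
#' @param premium Premium paid for the option.
#' @return Numeric vector of net payoffs.
#' @examples
#' vanilla_call_net(14, 15, 1)   # below strike: lose the premium
#' vanilla_call_net(16, 15, 1)   # break-even
#' vanilla_call_net(20, 15, 1)   # price minus (strike + premium)
#' @export
vanilla_call_net <- function(share_price, strike, premium) {
  check_num(share_price, "share_price", min = 0)
  check_num(strike, "strike", min = 0)
  check_num(premium, "premium", min = 0)
  pmax(share_price - strike, 0) - premium
}

#' Net present value of a single-stage binomial project
#'
#' Values one development stage with two outcomes: pay `cost` now; with
#' probability `p_success` receive `payout_success`, otherwise
#' `payout_failure`, both discounted by `discount_factor`. The valuation is
#' the probability-weighted sum of the discounted payouts minus the cost. A
#' project whose success payout merely equals its cost has negative value for
#' any success probability below 1 — it can be made attractive only by
#' raising the payout or lowering the upfront cost, which is exactly the
#' lever the options market pulls.
#'
#' @param cost Upfront cost of the stage.
#' @param p_success Probability of success, in \[0, 1\].
#' @param payout_success,payout_failure Payouts in each outcome.
#' @param discount_factor Discount factor applied to the payouts, in \[0, 1\].
#' @return Numeric vector of net present values.
#' @examples
#' single_stage_npv(5000, 0.5, 5000, 0)   # negative: not worth undertaking
#' single_stage_npv(5000, 0.9, 10000, 0)
#' @export
single_stage_npv <- function(cost, p_success, payout_success,
                             payout_failure = 0, discount_factor = 1) {
  check_num(p_success, "p_success", min = 0, max = 1)
  check_num(discount_factor, "discount_factor", min = 0, max = 1)
  check_num(cost, "cost")
  discount_factor * (p_success * payout_success + (1 - p_success) * payout_failure) - cost
}

#' Describe a market scenario
#'
#' The market-side assumptions under which options are priced: the
#' anticipated launch price per dose, the marginal cost of production per
#' dose (which fixes the strike price — redemption is triggered by approval,
#' not by price movement, so the strike is set where the manufacturer loses
#' nothing per optioned dose), an annual discount rate, and per-phase
#' durations in years used to discount the time to approval.
#'
#' @param market_price_per_dose Anticipated launch price per dose; at least
#'   the marginal cost.
#' @param marginal_cost_per_dose Marginal production cost per dose (the
#'   strike).
#' @param discount_rate Annual discount rate (fraction/year, >= 0). Default 0:
#'   undiscounted nominal accounting.
#' @param phase_durations Named numeric vector of years spent in each live
#'   phase (`phase1`, `phase2`, `phase3`, `rr`). Default 1 year per phase.
#' @return A list of class `oma_scenario`.
#' @examples
#' market_scenario(10, 8, discount_rate = 0.1,
#'                 phase_durations = c(phase1 = 2, phase2 = 2, phase3 = 2, rr = 1))
#' @export
market_scenario <- function(market_price_per_dose, marginal_cost_per_dose,
                            discount_rate = 0,
                            phase_durations = c(phase1 = 1, phase2 = 1, phase3 = 1, rr = 1)) {
  check_num(marginal_cost_per_dose, "marginal_cost_per_dose", min = 0)
  check_num(market_price_per_dose, "market_price_per_dose", min = marginal_cost_per_dose)
  check_num(discount_rate, "discount_rate", min = 0)
  phase_durations <- normalise_phase_map(phase_durations, "phase_durations", default = 1)
  structure(
    list(
      market_price_per_dose = market_price_per_dose,
      marginal_cost_per_dose = marginal_cost_per_dose,
      discount_rate = discount_rate,
      phase_durations = phase_durations
    ),
    class = "oma_scenario"
  )
}

#' @export
print.oma_scenario <- function(x, ...) {
  cat("<oma_scenario>\n")
  cat(sprintf("  market price/dose: %s   marginal cost (strike)/dose: %s\n",
              format(x$market_price_per_dose), format(x$marginal_cost_per_dose)))
  cat(sprintf("  discount rate: %s/yr   durations (yr): %s\n",
              format(x$discount_rate),
              paste(sprintf("%s=%s", names(x$phase_durations),
                            format(unname(x$phase_durations))), collapse = " ")))
  invisible(x)
}

# expand a possibly-partial named phase->value map over the live phases
normalise_phase_map <- function(x, field, default = 0) {
  live <- oma_phases(terminal = FALSE)
  if (is.null(x)) x <- setNames(rep(default, length(live)), live)
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x)) && length(x) == length(live)) names(x) <- live
  nm <- as.character(as_oma_phase(names(x)))
  if ("approved" %in% nm) abort(sprintf("`%s` may not assign a value to the terminal 'approved' state", field))
  if (anyDuplicated(nm)) abort(sprintf("Duplicate phase names in `%s`", field))
  check_num(unname(x), field, min = 0)
  out <- setNames(rep(default, length(live)), live)
  out[nm] <- as.numeric(x)
  out
}

#' Construct option contracts on antibiotics in development
#'
#' One row per contract: the right, bought today at `premium_per_dose` for a
#' drug of `drug_class` currently in `purchase_phase`, to buy `quantity`
#' doses at `strike_per_dose` if and when the drug is approved. The strike is
#' conventionally the marginal cost of production; [read_scenario_config()]
#' enforces that equality when contracts are assembled from a configuration.
#' Arguments are vectorised and recycled, so one call can build a portfolio.
#'
#' @param drug_class Therapeutic class name (matched against the transition
#'   table at pricing time).
#' @param purchase_phase Development phase at purchase.
#' @param premium_per_dose Premium paid per dose-option (>= 0).
#' @param strike_per_dose Redemption price per dose (>= 0).
#' @param quantity Number of dose-options (>= 0).
#' @return A tibble with one row per contract and a `contract_id` column.
#' @examples
#' call_contract("Systemic anti-infective", "phase1",
#'               premium_per_dose = 0.2, strike_per_dose = 8, quantity = 1e6)
#' @export
call_contract <- function(drug_class, purchase_phase, premium_per_dose,
                          strike_per_dose, quantity) {
  check_num(premium_per_dose, "premium_per_dose", min = 0)
  check_num(strike_per_dose, "strike_per_dose", min = 0)
  check_num(quantity, "quantity", min = 0)
  out <- tibble(
    drug_class = as.character(drug_class),
    purchase_phase = as.character(as_oma_phase(purchase_phase)),
    premium_per_dose = premium_per_dose,
    strike_per_dose = strike_per_dose,
    quantity = quantity
  )
  mutate(out, contract_id = row_number(), .before = 1)
}

#' Actuarially fair value of option contracts
#'
#' Prices each contract as the probability-weighted, time-discounted value of
#' the discount it secures: `P_approve * (market price - strike) * quantity *
#' (1 + r)^(-T)`, where `P_approve` is the cumulative approval probability
#' from the purchase phase and `T` the summed durations of the remaining
#' phases. Success probabilities stand in for price volatility — an
#' antibiotic option redeems on approval, not on a market-price barrier, so
#' historical-volatility option formulas do not apply. The fair total divided
#' by quantity is the fair premium per dose: low for early-phase purchases
#' (cheap but risky), and converging to the full market-minus-strike discount
#' as the drug nears approval.
#'
#' @param contracts A contracts tibble from [call_contract()].
#' @param scenario A scenario from [market_scenario()].
#' @param table A transition table (see [read_transition_table()]).
#' @return The contracts tibble with columns `p_approve`,
#'   `years_to_approval`, `discount_factor`, `fair_value` and
#'   `fair_premium_per_dose` appended.
#' @examples
#' tab <- dimasi_transitions()
#' sc <- market_scenario(10, 8)
#' call_contract("Systemic anti-infective", "phase1", 0.2, 8, 1e6) |>
#'   expected_option_value(sc, tab)
#' @export
expected_option_value <- function(contracts, scenario, table) {
  stopifnot(inherits(scenario, "oma_scenario"))
  table <- validate_transition_table(table)
  if (any(contracts$quantity == 0)) {
    warn("Contract(s) with quantity 0 have fair value 0")
  }
  p <- cumulative_success(table, contracts$drug_class, contracts$purchase_phase)
  t_rem <- map_dbl(contracts$purchase_phase,
                   function(ph) sum(scenario$phase_durations[remaining_phases(ph)]))
  d <- (1 + scenario$discount_rate)^(-t_rem)
  fair <- p * (scenario$market_price_per_dose - contracts$strike_per_dose) *
    contracts$quantity * d
  mutate(contracts,
         p_approve = p,
         years_to_approval = t_rem,
         discount_factor = d,
         fair_value = fair,
         fair_premium_per_dose = ifelse(.data$quantity > 0, fair / .data$quantity, 0))
}

#' Option holder's net savings at resolution
#'
#' Nominal accounting of the holder's position once development resolves. If
#' the drug is approved, the holder redeems: gross savings of
#' `realized_discount_per_dose` on each of `quantity` doses, minus the
#' premium outlay. If it never reaches market, the entire premium outlay is
#' lost. A strict accounting would also charge interest foregone on the
#' premium during development; set `discount_factor` below 1 to discount the
#' gross savings accordingly (the default matches the nominal arithmetic of
#' the headline example).
#'
#' @param contracts A contracts tibble from [call_contract()].
#' @param approved Logical, recycled over contracts: did the drug reach
#'   approval?
#' @param realized_discount_per_dose Realised discount per dose at launch
#'   (market price minus strike, or any negotiated figure); >= 0. Defaults to
#'   `scenario` market price minus the contract strike when `scenario` is
#'   given.
#' @param scenario Optional [market_scenario()] used to default the realised
#'   discount.
#' @param discount_factor Factor applied to gross savings (1 = nominal).
#' @return The contracts tibble with `approved`, `outlay`, `gross_savings`
#'   and `net_savings` columns appended.
#' @examples
#' ct <- call_contract("Systemic anti-infective", "phase1", 0.2, 8, 1e6)
#' holder_net_savings(ct, approved = TRUE, realized_discount_per_dose = 2)
#' holder_net_savings(ct, approved = FALSE)
#' @export
holder_net_savings <- function(contracts, approved,
                               realized_discount_per_dose = NULL,
                               scenario = NULL, discount_factor = 1) {
  if (is.null(realized_discount_per_dose)) {
    if (is.null(scenario)) {
      realized_discount_per_dose <- 0
    } else {
      realized_discount_per_dose <- scenario$market_price_per_dose - contracts$strike_per_dose
    }
  }
  check_num(realized_discount_per_dose, "realized_discount_per_dose", min = 0)
  check_num(discount_factor, "discount_factor", min = 0, max = 1)
  n <- nrow(contracts)
  approved <- rep_len(as.logical(approved), n)
  outlay <- contracts$premium_per_dose * contracts$quantity
  gross <- ifelse(approved,
                  contracts$quantity * rep_len(realized_discount_per_dose, n) * discount_factor,
                  0)
  mutate(contracts,
         approved = approved,
         outlay = outlay,
         gross_savings = gross,
         net_savings = gross - outlay)
}
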