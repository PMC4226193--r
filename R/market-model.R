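# internal: validation helper naming the offending field
check_num <- function(x, field, min = -Inf, max = Inf, allow_na = FALSE) {
  if (allow_na) x <- x[!is.na(x)]
  if (!is.numeric(x) || any(is.na(x)) || any(x < min) || any(x > max)) {
    abort(sprintf("`%s` must be numeric in [%s, %s]", field,
                  format(min, trim = TRUE), format(max, trim = TRUE)))
  }
  invisible(x)
}

#' Describe an advance market commitment fund
#'
#' An advance market commitment (AMC) guarantees developers a price per dose
#' for a qualifying drug: purchasers pay a small copayment and the sponsor
#' tops up the difference, for up to a committed number of doses, capped by
#' the sponsor's total commitment.
#'
#' @param total_commitment Total sponsor commitment (currency, major units).
#' @param guaranteed_price_per_dose Guaranteed price per dose.
#' @param copay_per_dose Purchaser copayment per dose; between 0 and the
#'   guaranteed price.
#' @param committed_units Number of doses covered by the guarantee.
#' @return A one-row tibble describing the fund.
#' @examples
#' amc_fund(3e9, 15, 1, 200e6)
#' @export
amc_fund <- function(total_commitment, guaranteed_price_per_dose,
                     copay_per_dose = 0, committed_units = 0) {
  check_num(total_commitment, "total_commitment")
  if (total_commitment <= 0) abort("`total_commitment` must be > 0")
  check_num(guaranteed_price_per_dose, "guaranteed_price_per_dose", min = 0)
  check_num(copay_per_dose, "copay_per_dose", min = 0, max = guaranteed_price_per_dose)
  check_num(committed_units, "committed_units", min = 0)
  tibble(
    total_commitment = total_commitment,
    guaranteed_price_per_dose = guaranteed_price_per_dose,
    copay_per_dose = copay_per_dose,
    committed_units = committed_units
  )
}

#' Describe a drug's novelty profile
#'
#' The triple scoring a candidate drug for market-payout purposes:
#' `q` in \[0, 1\] is the novelty score assigned by an advisory panel (1 for a
#' completely novel drug addressing an unmet need with superb efficacy);
#' `n` is the count of drugs already available in the same therapeutic class;
#' `e` in (0, 1\] is the mean efficacy of those existing drugs. `e` applies
#' only to existing competitors — the candidate itself contributes through
#' `q` — and is ignored for a first-in-class drug (`n = 0`).
#'
#' @param q Novelty score in \[0, 1\].
#' @param n Non-negative integer count of existing same-class drugs.
#' @param e Mean efficacy of existing competitors, in (0, 1\]; required when
#'   `n >= 1`, ignored when `n = 0`.
#' @return A one-row tibble with columns `q`, `n`, `e`.
#' @examples
#' drug_novelty(q = 1, n = 0)           # first in class
#' drug_novelty(q = 0.5, n = 5, e = 0.8)
#' @export
drug_novelty <- function(q, n, e = NA_real_) {
  check_num(q, "q", min = 0, max = 1)
  check_num(n, "n", min = 0)
  if (any(n != floor(n))) abort("`n` must be a non-negative integer count of existing drugs")
  needs_e <- n >= 1
  if (any(needs_e & (is.na(e) | e <= 0 | e > 1))) {
    abort("`e` must be in (0, 1] when the class has existing drugs (n >= 1)")
  }
  tibble(q = q, n = n, e = ifelse(needs_e, e, NA_real_))
}

#' Market payout for a candidate drug under an advance commitment
#'
#' Converts a sponsor's total advance market commitment into a drug-specific
#' prize `M = AMC * q / (n * e)`: novelty scales the payout up, class
#' crowding (`n` competitors) and effective competition (`e`) scale it down,
#' so a truly unique, highly novel drug earns the full commitment while a
#' me-too drug entering a crowded, effective field earns little. For a
#' first-in-class drug (`n = 0`) the divisor is 1, reproducing the
#' full-commitment outcome. The payout is clamped to `[0, amc_total]` — the
#' commitment is the maximal prize — with the unclamped value reported
#' alongside, since an ineffective crowded field (`e` small) would otherwise
#' imply a payout larger than the fund.
#'
#' @param amc_total Total advance market commitment (currency, > 0). May also
#'   be a fund tibble from [amc_fund()], in which case its
#'   `total_commitment` is used.
#' @param q,n,e Novelty profile components (see [drug_novelty()]); ignored if
#'   `profile` is supplied.
#' @param profile Optionally, a profile tibble from [drug_novelty()].
#' @return A tibble with columns `payout` (clamped prize), `payout_unclamped`
#'   and `clamped`, one row per profile row.
#' @examples
#' market_payout(3e9, q = 1, n = 1, e = 1)       # full commitment
#' market_payout(1.25e9, q = 0.5, n = 5, e = 0.8)
#' @export
market_payout <- function(amc_total, q = NULL, n = NULL, e = NA_real_, profile = NULL) {
  if (is.data.frame(amc_total) && "total_commitment" %in% names(amc_total)) {
    amc_total <- amc_total$total_commitment
  }
  check_num(amc_total, "amc_total")
  if (any(amc_total <= 0)) abort("`amc_total` must be > 0")
  if (is.null(profile)) {
    if (is.null(q) || is.null(n)) abort("Supply either `profile` or `q` and `n`")
    profile <- drug_novelty(q, n, e)
  }
  n_eff <- pmax(profile$n, 1)
  e_eff <- ifelse(profile$n >= 1, profile$e, 1)
  unclamped <- amc_total * profile$q / (n_eff * e_eff)
  payout <- pmin(pmax(unclamped, 0), amc_total)
  tibble(payout = payout, payout_unclamped = unclamped, clamped = payout != unclamped)
}

#' Sponsor top-up outlay under an advance market commitment
#'
#' The sponsor's total outlay when `units_purchased` doses are bought under
#' the fund's guarantee: the per-dose difference between guaranteed price and
#' copayment, paid on each dose up to the committed number. Doses beyond the
#' commitment sell at a reduced price directly to purchasers and cost the
#' sponsor nothing, so outlay is piecewise linear in units with slope zero
#' past the cap.
#'
#' @param fund A fund tibble from [amc_fund()].
#' @param units_purchased Number of doses purchased (vectorised).
#' @return Numeric vector of sponsor outlays (currency).
#' @examples
#' cgd <- amc_fund(3e9, 15, 1, 200e6)
#' amc_sponsor_topup(cgd, 200e6)
#' amc_sponsor_topup(cgd, 250e6)  # capped at the committed units
#' @export
amc_sponsor_topup <- function(fund, units_purchased) {
  check_num(units_purchased, "units_purchased", min = 0)
  (fund$guaranteed_price_per_dose - fund$copay_per_dose) *
    pmin(units_purchased, fund$committed_units)
}
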