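#' Fair option value across purchase phases
#'
#' The risk/price trade-off at a glance: for each therapeutic class, the
#' actuarially fair premium per dose of an option bought at each development
#' phase. Early purchases are cheap because approval is unlikely; as the
#' drug nears approval the fair premium climbs towards the full
#' market-minus-strike discount.
#'
#' @param table A transition table.
#' @param scenario A [market_scenario()].
#' @param classes Classes to show; default all in `table`.
#' @param quantity Doses per contract (scales the y axis only).
#' @return A ggplot object.
#' @export
plot_option_value_by_phase <- function(table, scenario, classes = NULL, quantity = 1) {
  table <- validate_transition_table(table)
  classes <- classes %||% table$therapeutic_class
  grid <- tidyr::expand_grid(drug_class = classes,
                             purchase_phase = oma_phases(terminal = FALSE))
  contracts <- call_contract(grid$drug_class, grid$purchase_phase,
                             premium_per_dose = 0,
                             strike_per_dose = scenario$marginal_cost_per_dose,
                             quantity = quantity)
  priced <- expected_option_value(contracts, scenario, table)
  priced$purchase_phase <- factor(priced$purchase_phase,
                                  levels = oma_phases(terminal = FALSE))
  ggplot2::ggplot(priced, ggplot2::aes(x = .data$purchase_phase,
                                       y = .data$fair_premium_per_dose,
                                       group = .data$drug_class,
                                       colour = .data$drug_class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "purchase phase", y = "fair premium per dose",
                  colour = "therapeutic class") +
    ggplot2::theme_minimal()
}

#' @describeIn backward_induction_value Per-phase continuation values and
#'   decisions as a bar chart.
#' @param object An `oma_valuation`.
#' @param ... Unused.
#' @method autoplot oma_valuation
#' @export
autoplot.oma_valuation <- function(object, ...) {
  d <- object$phases
  d$phase <- factor(d$phase, levels = oma_phases(terminal = FALSE))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phase, y = .data$value,
                                  fill = .data$decision)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "phase", y = "project value at phase entry", fill = "decision") +
    ggplot2::theme_minimal()
}

#' @describeIn simulate_portfolio Histogram of per-replicate total net
#'   savings, with the mean marked.
#' @param object An `oma_simulation`.
#' @param ... Unused.
#' @method autoplot oma_simulation
#' @export
autoplot.oma_simulation <- function(object, ...) {
  ggplot2::ggplot(object$replicates, ggplot2::aes(x = .data$net_savings)) +
    ggplot2::geom_histogram(bins = 50) +
    ggplot2::geom_vline(xintercept = object$summary$mean_net_savings,
                        linetype = "dashed") +
    ggplot2::labs(x = "portfolio net savings per replicate", y = "replicates") +
    ggplot2::theme_minimal()
}
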