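#' Assemble a portfolio of option contracts under a market scenario
#'
#' Joins contracts to the scenario quantities the simulator needs: the
#' realised per-dose discount at launch (market price minus strike) and the
#' time-discount factor for the discounted savings mode.
#'
#' @param contracts A contracts tibble from [call_contract()].
#' @param scenario A [market_scenario()].
#' @return The contracts tibble with `realized_discount_per_dose` and
#'   `discount_factor` columns appended.
#' @export
portfolio <- function(contracts, scenario) {
  stopifnot(inherits(scenario, "oma_scenario"))
  t_rem <- map_dbl(contracts$purchase_phase,
                   function(ph) sum(scenario$phase_durations[remaining_phases(ph)]))
  mutate(contracts,
         realized_discount_per_dose =
           scenario$market_price_per_dose - .data$strike_per_dose,
         discount_factor = (1 + scenario$discount_rate)^(-t_rem))
}

# deterministic per-contract substream seed: a multiplicative integer hash of
# (root seed, contract index), so adding a contract never perturbs the draws
# of the others
contract_seed <- function(seed, i) {
  v <- ((as.double(seed) %% 2147483647) * 48271 + i * 1103515245) %% 2147483647
  as.integer(v)
}

#' Simulate a portfolio of antibiotic option purchases
#'
#' Seeded Monte Carlo over development outcomes. For each replicate, each
#' contract's drug is advanced through its remaining phases with independent
#' Bernoulli draws at the class's transition probabilities
#' (`method = "phasewise"`), or approved in a single draw at the
#' pre-multiplied cumulative probability (`method = "single"`); the two are
#' distributionally identical. Approved contracts realise the holder's net
#' savings (quantity times realised discount minus premium outlay); failed
#' contracts lose the outlay. Savings are nominal by default; set
#' `discounted = TRUE` to apply each contract's time-discount factor to the
#' gross savings.
#'
#' Each contract draws from its own substream derived from `seed`, so the
#' same seed and portfolio reproduce the result exactly, and appending a
#' contract leaves the other contracts' draws untouched. The global RNG
#' state is not modified.
#'
#' @param portfolio A portfolio tibble from [portfolio()], or a contracts
#'   tibble that already carries a `realized_discount_per_dose` column. A
#'   zero-row portfolio yields an all-zero result.
#' @param table A transition table (see [read_transition_table()]).
#' @param n_replicates Number of Monte Carlo replicates (>= 1).
#' @param seed Integer root seed.
#' @param method `"phasewise"` (default) or `"single"`.
#' @param discounted Apply time discounting to realised savings?
#' @return An object of class `oma_simulation` with components `replicates`
#'   (per-replicate totals), `contracts` (per-contract approval counts and
#'   mean savings) and `summary`; see [tidy.oma_simulation()] and
#'   [glance.oma_simulation()].
#' @examples
#' tab <- dimasi_transitions()
#' sc <- market_scenario(10, 8)
#' pf <- portfolio(call_contract("Systemic anti-infective", "phase1", 0.2, 8, 1e6), sc)
#' sim <- simulate_portfolio(pf, tab, n_replicates = 1000, seed = 42)
#' glance(sim)
#' @export
simulate_portfolio <- function(portfolio, table, n_replicates = 10000, seed = 1L,
                               method = c("phasewise", "single"),
                               discounted = FALSE) {
  method <- match.arg(method)
  table <- validate_transition_table(table)
  if (length(n_replicates) != 1 || is.na(n_replicates) || n_replicates < 1) {
    abort("`n_replicates` must be a single integer >= 1")
  }
  n_replicates <- as.integer(n_replicates)
  if (!"realized_discount_per_dose" %in% names(portfolio)) {
    abort("`portfolio` must carry a realized_discount_per_dose column; build it with portfolio()")
  }
  if (nrow(portfolio) > 0) {
    unknown <- setdiff(portfolio$drug_class, table$therapeutic_class)
    if (length(unknown) > 0) {
      abort(sprintf("Unknown therapeutic class(es) in portfolio: %s",
                    paste(sQuote(unknown), collapse = ", ")))
    }
  }

  net <- matrix(0, nrow = n_replicates, ncol = nrow(portfolio))
  approved <- matrix(FALSE, nrow = n_replicates, ncol = nrow(portfolio))
  for (i in seq_len(nrow(portfolio))) {
    ct <- portfolio[i, ]
    row <- table[table$therapeutic_class == ct$drug_class, , drop = FALSE]
    probs <- as.numeric(as.matrix(
      row[1, PHASE_PROB_COLS[remaining_phases(ct$purchase_phase)], drop = FALSE]))
    ok <- withr::with_seed(contract_seed(seed, i), {
      if (method == "single" || length(probs) == 0) {
        runif(n_replicates) < prod(probs)
      } else {
        u <- matrix(runif(n_replicates * length(probs)), nrow = n_replicates)
        rowSums(u < rep(probs, each = n_replicates)) == length(probs)
      }
    })
    outlay <- ct$premium_per_dose * ct$quantity
    d <- if (discounted && "discount_factor" %in% names(ct)) ct$discount_factor else 1
    gross <- ct$quantity * ct$realized_discount_per_dose * d
    approved[, i] <- ok
    net[, i] <- ifelse(ok, gross - outlay, -outlay)
  }

  replicates <- tibble(
    replicate = seq_len(n_replicates),
    net_savings = rowSums(net),
    n_approved = rowSums(approved)
  )
  per_contract <- mutate(
    select(portfolio, dplyr::any_of(c("contract_id", "drug_class", "purchase_phase",
                                      "premium_per_dose", "quantity"))),
    approvals = colSums(approved),
    approval_fraction = colSums(approved) / n_replicates,
    mean_net_savings = colMeans(net)
  )
  q <- if (n_replicates > 1) {
    quantile(replicates$net_savings, c(0.025, 0.5, 0.975), names = FALSE)
  } else rep(replicates$net_savings, 3)
  summary <- tibble(
    mean_net_savings = mean(replicates$net_savings),
    sd_net_savings = if (n_replicates > 1) sd(replicates$net_savings) else 0,
    q2.5 = q[1], median = q[2], q97.5 = q[3],
    p_any_approval = mean(replicates$n_approved >= 1)
  )
  structure(
    list(replicates = replicates, contracts = per_contract, summary = summary,
         n_replicates = n_replicates, seed = as.integer(seed), method = method,
         discounted = discounted),
    class = "oma_simulation"
  )
}

#' @export
print.oma_simulation <- function(x, ...) {
  cat(sprintf("<oma_simulation> %d contract(s), %d replicates, seed %d (%s)\n",
              nrow(x$contracts), x$n_replicates, x$seed, x$method))
  print(x$summary)
  invisible(x)
}

#' Per-replicate results of a portfolio simulation
#'
#' @param x An `oma_simulation` from [simulate_portfolio()].
#' @param ... Unused.
#' @return A tibble with one row per replicate: total `net_savings` across
#'   the portfolio and the number of contracts approved.
#' @method tidy oma_simulation
#' @export
tidy.oma_simulation <- function(x, ...) x$replicates

#' One-row summary of a portfolio simulation
#'
#' @param x An `oma_simulation` from [simulate_portfolio()].
#' @param ... Unused.
#' @return A one-row tibble: mean and sd of total net savings, 2.5/50/97.5%
#'   quantiles, probability of at least one approval, and the replicate
#'   count and seed.
#' @method glance oma_simulation
#' @export
glance.oma_simulation <- function(x, ...) {
  mutate(x$summary, n_replicates = x$n_replicates, seed = x$seed)
}
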