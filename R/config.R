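# recognised configuration keys, by block
CONFIG_SCHEMA <- list(
  config_version = NULL,
  amc = c("total_commitment", "guaranteed_price_per_dose", "copay_per_dose",
          "committed_units"),
  drug = c("q", "n", "e"),
  market = c("price_per_dose", "marginal_cost_per_dose", "discount_rate",
             "phase_durations"),
  option = c("premium_per_dose", "strike_per_dose", "quantity",
             "purchase_phase", "drug_class"),
  project = c("drug_class", "phase_costs", "phase_durations",
              "premiums_received", "terminal_payoff", "discount_rate",
              "current_phase"),
  portfolio = c("contracts"),
  simulation = c("n_replicates", "seed")
)

#' Read and validate a scenario configuration
#'
#' Loads a YAML or JSON configuration describing any combination of an AMC
#' fund (`amc` block), a drug novelty profile (`drug`), market assumptions
#' (`market`), an option contract or a portfolio of them (`option`,
#' `portfolio`), a firm-side project (`project`) and simulation settings
#' (`simulation`). Unknown keys anywhere are rejected, as is a missing
#' `config_version`. Defaults — a zero discount rate, one year per phase,
#' and a strike equal to the marginal cost — are applied where omitted and
#' recorded in the `defaulted` attribute. A strike price differing from the
#' market block's marginal cost is rejected: the model sets the strike at
#' the marginal cost of production, so redemption never costs the
#' manufacturer money per dose.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return The validated configuration list, classed `oma_config`, with
#'   attribute `defaulted` listing every key that received a default.
#'   Assembled objects are available via [config_scenario()],
#'   [config_contracts()], [config_fund()], [config_profile()] and
#'   [config_project()].
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE),
    abort(sprintf("Unsupported config format '.%s' (use YAML or JSON): %s", ext, path))
  )
  if (!is.list(cfg)) abort(sprintf("Config %s is not a mapping", path))

  unknown_top <- setdiff(names(cfg), names(CONFIG_SCHEMA))
  if (length(unknown_top) > 0) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown_top, collapse = ", ")))
  }
  if (is.null(cfg$config_version)) {
    abort("Config is missing `config_version`; add `config_version: 1` (current schema version)")
  }
  if (!identical(as.numeric(cfg$config_version), 1)) {
    abort(sprintf("Unsupported config_version %s (this release reads version 1)",
                  cfg$config_version))
  }
  for (block in setdiff(names(cfg), "config_version")) {
    allowed <- CONFIG_SCHEMA[[block]]
    bad <- setdiff(names(cfg[[block]]), allowed)
    if (length(bad) > 0) {
      abort(sprintf("Unknown key(s) under `%s`: %s", block,
                    paste(paste0(block, ".", bad), collapse = ", ")))
    }
  }
  if (!is.null(cfg$portfolio$contracts)) {
    walk(seq_along(cfg$portfolio$contracts), function(i) {
      bad <- setdiff(names(cfg$portfolio$contracts[[i]]), CONFIG_SCHEMA$option)
      if (length(bad) > 0) {
        abort(sprintf("Unknown key(s) in portfolio.contracts[%d]: %s", i,
                      paste(bad, collapse = ", ")))
      }
    })
  }

  defaulted <- character(0)
  note_default <- function(key, value) {
    defaulted <<- c(defaulted, key)
    value
  }
  if (!is.null(cfg$market)) {
    if (is.null(cfg$market$discount_rate)) {
      cfg$market$discount_rate <- note_default("market.discount_rate", 0)
    }
    if (is.null(cfg$market$phase_durations)) {
      cfg$market$phase_durations <- note_default(
        "market.phase_durations", as.list(setNames(rep(1, 4), oma_phases(FALSE))))
    }
  }
  fill_strike <- function(ct, label) {
    if (is.null(ct$strike_per_dose)) {
      if (is.null(cfg$market$marginal_cost_per_dose)) {
        abort(sprintf("%s.strike_per_dose missing and no market.marginal_cost_per_dose to default from", label))
      }
      ct$strike_per_dose <- note_default(paste0(label, ".strike_per_dose"),
                                         cfg$market$marginal_cost_per_dose)
    } else if (!is.null(cfg$market$marginal_cost_per_dose) &&
               ct$strike_per_dose != cfg$market$marginal_cost_per_dose) {
      abort(sprintf(
        "%s.strike_per_dose (%s) must equal market.marginal_cost_per_dose (%s): the strike price is set as the marginal cost of production",
        label, ct$strike_per_dose, cfg$market$marginal_cost_per_dose))
    }
    ct
  }
  if (!is.null(cfg$option)) cfg$option <- fill_strike(cfg$option, "option")
  if (!is.null(cfg$portfolio$contracts)) {
    cfg$portfolio$contracts <- imap(cfg$portfolio$contracts, function(ct, i) {
      fill_strike(ct, sprintf("portfolio.contracts[%d]", i))
    })
  }

  structure(cfg, class = "oma_config", defaulted = defaulted)
}

#' @export
print.oma_config <- function(x, ...) {
  cat("<oma_config> blocks:", paste(setdiff(names(x), "config_version"), collapse = ", "), "\n")
  d <- attr(x, "defaulted")
  if (length(d) > 0) cat("  defaulted:", paste(d, collapse = ", "), "\n")
  invisible(x)
}

#' Assemble objects from a validated configuration
#'
#' Accessors turning the blocks of an [read_scenario_config()] result into
#' the package's working objects.
#'
#' @param cfg An `oma_config`.
#' @return `config_scenario()` a [market_scenario()]; `config_contracts()` a
#'   contracts tibble (from the `option` block or the `portfolio` block);
#'   `config_fund()` an [amc_fund()] tibble; `config_profile()` a
#'   [drug_novelty()] tibble; `config_project()` an [development_project()].
#' @name config-accessors
NULL

#' @rdname config-accessors
#' @export
config_scenario <- function(cfg) {
  m <- cfg$market %||% abort("Config has no `market` block")
  market_scenario(
    market_price_per_dose = m$price_per_dose,
    marginal_cost_per_dose = m$marginal_cost_per_dose,
    discount_rate = m$discount_rate %||% 0,
    phase_durations = m$phase_durations
  )
}

#' @rdname config-accessors
#' @export
config_contracts <- function(cfg) {
  cts <- if (!is.null(cfg$portfolio$contracts)) cfg$portfolio$contracts
         else if (!is.null(cfg$option)) list(cfg$option)
         else abort("Config has neither an `option` nor a `portfolio` block")
  bind_rows(map(cts, function(ct) {
    call_contract(
      drug_class = ct$drug_class %||% abort("Contract is missing drug_class"),
      purchase_phase = ct$purchase_phase %||% abort("Contract is missing purchase_phase"),
      premium_per_dose = ct$premium_per_dose %||% abort("Contract is missing premium_per_dose"),
      strike_per_dose = ct$strike_per_dose,
      quantity = ct$quantity %||% abort("Contract is missing quantity")
    )
  })) |> mutate(contract_id = row_number())
}

#' @rdname config-accessors
#' @export
config_fund <- function(cfg) {
  a <- cfg$amc %||% abort("Config has no `amc` block")
  amc_fund(a$total_commitment, a$guaranteed_price_per_dose,
           a$copay_per_dose %||% 0, a$committed_units %||% 0)
}

#' @rdname config-accessors
#' @export
config_profile <- function(cfg) {
  d <- cfg$drug %||% abort("Config has no `drug` block")
  drug_novelty(d$q, d$n, d$e %||% NA_real_)
}

#' @rdname config-accessors
#' @export
config_project <- function(cfg) {
  p <- cfg$project %||% abort("Config has no `project` block")
  terminal <- p$terminal_payoff
  if (is.null(terminal) && !is.null(cfg$amc) && !is.null(cfg$drug)) {
    terminal <- market_payout(config_fund(cfg), profile = config_profile(cfg))$payout
  }
  development_project(
    drug_class = p$drug_class,
    phase_costs = p$phase_costs,
    phase_durations = p$phase_durations,
    premiums_received = p$premiums_received,
    terminal_payoff = terminal %||% 0,
    discount_rate = p$discount_rate %||% 0,
    current_phase = p$current_phase %||% "phase1"
  )
}
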