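# oma — options-market valuation and simulation for antibiotic development

New antibiotics are chronically under-developed: courses are short,
prescribing is deliberately restrained, and the drugs most needed against
resistant pathogens have the weakest markets. One proposed remedy is an
options market: a payer (an NGO, a government, a "super fund") buys call
options on an antibiotic while it is still in clinical trials — paying a
small premium per future dose — and, if the drug is ever approved, redeems
them to buy doses at the marginal cost of production. The developer gets cash
at the early stages where capital is scarcest (a push incentive); the payer
gets a deep discount at launch if development succeeds (a pull incentive),
and loses only the premium if it fails.

`oma` implements this valuation and simulation toolkit:

- **Phase model** — per-class clinical phase-transition probabilities
  (Phase I→II→III→regulatory review→approval), shipped as a packaged table
  of DiMasi's 1993–2004 estimates, with cumulative approval probabilities
  from any phase.
- **Market model** — advance-market-commitment (AMC) mechanics and the
  drug-specific market payout `M = AMC · Q / (N · E)`, where `Q ∈ [0, 1]`
  scores novelty, `N` counts existing same-class drugs and `E ∈ (0, 1]` is
  their mean efficacy. A fully novel first-in-class drug earns the entire
  commitment; a me-too drug in a crowded, effective field earns little.
- **Option pricing** — actuarially fair option values
  `P(approve) · (market price − strike) · quantity · (1 + r)^(−T)`,
  vanilla call payoffs, single-stage binomial NPV, and the option holder's
  realised savings.
- **Project valuation** — the firm's continue/abandon decision by backward
  induction with an abandonment floor,
  `V(k) = max(0, −I_k + premium_k + d_k · p_k · V(k+1))`, plus the minimum
  terminal payoff that keeps a programme alive.
- **Simulation** — seeded Monte Carlo over portfolios of option purchases,
  with per-contract substreams so results are exactly reproducible.

Everything takes and returns tibbles, chains with the pipe, and has
`tidy()`/`glance()`/`autoplot()` methods for the fitted objects.

## Worked example

A payer buys options on 1 million doses of a systemic anti-infective in
Phase I at $0.20 per dose. The anticipated launch price is $10/dose and the
marginal production cost (hence the strike) is $8/dose:

```r
library(oma)

tab <- dimasi_transitions()
sc  <- market_scenario(market_price_per_dose = 10, marginal_cost_per_dose = 8)
ct  <- call_contract("Systemic anti-infective", "phase1",
                     premium_per_dose = 0.2, strike_per_dose = 8, quantity = 1e6)

expected_option_value(ct, sc, tab)
#>   p_approve years_to_approval fair_value fair_premium_per_dose
#> 1     0.239                 4    477580.                 0.478
```

Only 23.9% of Phase I anti-infectives reach approval (the product of the
four transition probabilities 0.582 × 0.522 × 0.786 × 1.00), so the
actuarially fair price of the $2/dose discount is about $0.48/dose — the
$0.20 contract is a bargain for the payer and a subsidy decision for the
seller. If the drug is approved:

```r
holder_net_savings(ct, approved = TRUE, realized_discount_per_dose = 2)
#>   outlay gross_savings net_savings
#> 1 200000       2000000     1800000
```

$200,000 of premium buys $2,000,000 of discounted doses: net savings of
$1.8 million. If the drug fails, the $200,000 is lost. Simulating that bet
100,000 times:

```r
sim <- simulate_portfolio(portfolio(ct, sc), tab, n_replicates = 1e5, seed = 1)
glance(sim)
#>   mean_net_savings sd_net_savings   q2.5  median   q97.5 p_any_approval
#> 1           278420        853207. -2e+05 -2e+05  1800000          0.239
```

The mean net savings ($278k) equals the fair value minus the outlay
(477,580 − 200,000 = 277,580) to within Monte Carlo error, and the approval
fraction recovers the transition-table product.

A thin command-line interface over the same functions ships at
`inst/cli/oma` (subcommands `success-prob`, `market-payout`, `price-option`,
`savings`, `project-value`, `min-payout`, `simulate`, `validate-table`), and
scenario inputs can be read from YAML/JSON via `read_scenario_config()`.

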