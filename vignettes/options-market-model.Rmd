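---
title: "The options-market model for antibiotic development: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The options-market model for antibiotic development: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oma)
```

## The problem and the mechanism

Antibiotic development fails as a market: short treatment courses, stewardship
that deliberately suppresses volume, and demand that only materialises once a
resistance crisis has arrived. Push incentives (grants, tax credits) lower a
developer's costs but do not reward delivery; pull incentives (prizes,
advance market commitments) reward delivery but arrive too late to relieve
the early-stage capital shortage where most programmes die.

The mechanism this package models blends the two. A payer buys call options
on an antibiotic in clinical development: a premium per future dose, paid
now, in exchange for the right to buy doses at a fixed strike price if the
drug is ever approved. Premium revenue is push money at the phases where it
is most valuable; the redemption right is a pull commitment. Unlike an
equity call, redemption is triggered by *approval*, not by a price crossing
a barrier — so the strike is set at the marginal cost of production, the
lowest price at which the manufacturer loses nothing per optioned dose. The
package enforces that equality when contracts are assembled from
configuration files.

## The phase model

Development is a chain of four live stages — Phase I, Phase II, Phase III,
regulatory review — each exited successfully with a class-specific
transition probability. The packaged table (`dimasi_transitions()`) carries
DiMasi's estimates for drugs first tested in humans in 1993–2004, for eight
therapeutic classes. The cumulative approval probability from phase $k$ is
the product of the remaining transition probabilities:

$$P_k = \prod_{j \ge k} p_j, \qquad P_{\text{approved}} \equiv 1 .$$

Files store percentages exactly as such tables are printed; in memory
everything is a fraction, converted once at parse time. The table's own
printed overall success column is used only for validation:
`check_printed_success()` recomputes each product and reports deviations in
percentage points. The tolerance of 0.1 pp is the smallest bound
accommodating all eight rows' rounding — the antineoplastic row's product
(19.456%) rounds to 19.5 against a printed 19.4, a 0.06 pp discrepancy we
flag rather than fail. Stages earlier than Phase I carry no probabilities in
the table and are therefore rejected outright rather than guessed at.

## Market payout from an advance commitment

An advance market commitment (AMC) of total size $\mathrm{AMC}$ is converted
into a drug-specific prize

$$M = \mathrm{AMC} \cdot \frac{Q}{N \cdot E},$$

where $Q \in [0,1]$ is a panel-assigned novelty score, $N$ the number of
drugs already on the market in the same class, and $E \in (0,1]$ their mean
efficacy. The division by $N$ steers the subsidy toward novel classes and
away from me-too entrants; the division by $E$ makes fields with ineffective
incumbents more attractive. Setting $Q = N = E = 1$ — a unique, fully novel
drug — pays the entire commitment.

Two edge cases required decisions:

* **First-in-class (`N = 0`).** The formula would divide by zero. We define
  the divisor as $\max(N, 1)$ with $E$ ignored when there are no
  incumbents, which reproduces the full-commitment outcome a truly unique
  drug should earn. $E$ measures *existing* competitors only; the candidate
  itself enters through $Q$.
* **Clamping.** With few but ineffective incumbents ($N = 1$, $E$ small) the
  raw formula exceeds the fund. Whether the prize may exceed the commitment
  is genuinely open; we take the conservative reading — the commitment is
  the maximal prize — and clamp $M$ to $[0, \mathrm{AMC}]$, while always
  reporting the unclamped value alongside so the choice is visible.

The sponsor-side cost of the commitment is `amc_sponsor_topup()`: the gap
between guaranteed price and copayment on each dose up to the committed
number, and nothing beyond it.

## Pricing the option

Standard option-pricing formulas estimate exercise probability from
historical price volatility. No such history exists for an unapproved
antibiotic, and redemption here depends on a development outcome, not a
price path. We therefore price actuarially: the fair total value of a
contract bought at phase $k$ is

$$C_k = P_k \,(\text{market price} - \text{strike}) \cdot \text{quantity}
        \cdot (1+r)^{-T_k},$$

with $T_k$ the summed durations of the remaining phases. This yields the
risk/price trade-off the mechanism is designed around: early options are
cheap because $P_k$ is small; as the drug approaches approval, $P_k \to 1$,
$T_k \to 0$, and the fair premium converges to the full market-minus-strike
discount. `expected_option_value()` is monotone non-decreasing across
purchase phases for every class and any $r \ge 0$, and exactly equal to
$(\text{market} - \text{strike}) \cdot \text{quantity}$ at the approval
boundary with $r = 0$ — both are enforced by property tests.

Defaults, chosen once and documented rather than tuned: the annual discount
rate defaults to 0 (nominal accounting, matching the worked purchase
arithmetic), and phase durations default to one year each. Both are plain
scenario inputs with units (fraction/year and years). The realised discount
per dose at redemption is likewise an input — actual launch discounts are
negotiated, not derived — with `market price − strike` available as the
natural default. Premiums are quoted per dose, with the lump sum always
`premium_per_dose × quantity`. Exercise at share price exactly equal to the
strike is defined as no-exercise; the payoff is identical either way and the
convention keeps decisions deterministic.

## The firm's decision: backward induction with abandonment

The developer values the programme stage by stage from approval backwards:

$$V(\text{approved}) = M, \qquad
  V(k) = \max\!\bigl(0,\; -I_k + \pi_k + d_k\, p_k\, V(k{+}1)\bigr),$$

where $I_k$ is the phase's investment cost, $\pi_k$ the option premiums
received at that phase, and $d_k = (1+r)^{-\text{duration}_k}$. The
$\max(0, \cdot)$ is the firm's real option to abandon, and it is the channel
through which early option purchases work: a premium $\pi_k$ injected at a
continuing phase raises $V(k)$ — and every upstream value — by exactly its
discounted amount, and can flip an abandon decision to continue. At a
continuation value of exactly zero the firm continues (it is indifferent,
and this tie-break keeps decisions monotone in $M$). With a single remaining
stage the recursion collapses to the clipped single-stage binomial NPV,
which the test suite verifies to machine precision across a thousand
randomised instances — that equivalence anchors the multi-stage recursion to
the elementary two-outcome model.

`minimum_viable_payout()` inverts the recursion: the smallest $M^*$ for
which the current-phase decision is continue, found by bisection (relative
tolerance $10^{-9}$) on the continuation value, which is non-decreasing in
$M$. Premiums covering all costs give $M^* = 0$ — push financing alone
sustains the programme — and a zero transition probability upstream of
positive net costs makes $M^*$ infinite, reported with a warning rather
than an error.

## Monte Carlo simulation

`simulate_portfolio()` draws development outcomes for a portfolio of
contracts. The generator's defaults are the study conditions used
throughout: the packaged transition table supplies the per-phase success
probabilities; outcomes are independent across contracts and phases
(correlated scientific risk across same-class projects is real but
unquantified here, and is a documented non-goal); savings are nominal by
default, with a discounted mode applying the pricing discount factor.

Each contract draws from its own substream, seeded by an integer hash of
the root seed and the contract's index. Consequences: the same seed and
portfolio reproduce results byte for byte; appending a contract never
perturbs the other contracts' draws; and the global RNG state is untouched
(`withr::with_seed`). Two simulation methods are provided — phase-wise
Bernoulli chains and a single draw at the pre-multiplied cumulative
probability — which are distributionally identical; the suite checks their
approval fractions agree within three standard errors at $10^5$ replicates,
and that simulated means match the analytic expectations (approval fraction
against the table product, mean savings against
$P \cdot \text{quantity} \cdot \text{discount} - \text{outlay}$, and the
fair option value against mean savings plus outlay).

Problem sizes: the distributional checks use $10^5$ replicates (binomial
standard error $\approx 0.0013$ on the anti-infective approval fraction),
property sweeps use 20–30 randomised scenarios over all eight classes, and
the oracle equivalence uses 1,000 randomised single-stage projects. These
sizes make the checks sharp while keeping the whole suite under a minute.

## What the tests do and do not show

The synthetic portfolios emulate the decision arithmetic of the mechanism:
staged attrition at published class-level rates, fixed prices, independent
projects. They do not emulate features of real markets that the model itself
excludes — demand dynamics, resistance epidemiology, correlated trial
failures, strategic entry, hidden late-stage regulatory costs (representable
by editing `phase_costs`, but not stochastically modelled), or the
Ramsey-style allocation of options across countries. Passing tests therefore
show the implementation is faithful to the model, not that the model's
policy outcomes (aggregate global savings, induced innovation) would be
realised. Literature context — such as the reported 15.6–27% range for
overall anti-infective success — is context, not a quantity this package
computes; the packaged table yields a single product per class.

## Numerical notes

Currency amounts are plain doubles in one configured currency; no FX.
Percent-to-fraction conversion happens exactly once, at parse time, and the
CSV writer trims trailing zeros so the packaged fixture round-trips byte for
byte. Discounting is discrete annual compounding $(1+r)^{-T}$. Bisection
brackets $M^*$ by doubling and gives up at $10^{18}$, reporting infinity.
Degenerate inputs are defined rather than accidental: empty portfolios
simulate to all-zero results, zero-quantity contracts are worth zero with a
warning, and the cumulative success of an approved drug is the empty
product, 1.
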