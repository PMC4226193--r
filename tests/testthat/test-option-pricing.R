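test_that("vanilla call nets the three textbook payoff regions", {
  expect_equal(vanilla_call_net(14, 15, 1), -1)     # below strike: premium lost
  expect_equal(vanilla_call_net(16, 15, 1), 0)      # break-even at strike + premium
  expect_equal(vanilla_call_net(20, 15, 1), 4)      # above break-even: price - 16
  expect_equal(vanilla_call_net(15.5, 15, 1), -0.5) # exercised but still losing
  expect_error(vanilla_call_net(-1, 15, 1), "share_price")
})

test_that("call payoff is floored at -premium, binding whenever price <= strike", {
  withr::with_seed(11, {
    price <- runif(200, 0, 40)
    strike <- runif(200, 0, 30)
    premium <- runif(200, 0, 5)
    net <- vanilla_call_net(price, strike, premium)
    expect_true(all(net >= -premium))
    expect_equal(net[price <= strike], -premium[price <= strike])
  })
})

test_that("single-stage NPV is the probability-weighted discounted payout minus cost", {
  expect_equal(single_stage_npv(5000, 1.0, 5000), 0)
  expect_equal(single_stage_npv(5000, 0.5, 5000), -2500)
  expect_equal(single_stage_npv(5000, 0.9, 10000), 4000)
  expect_equal(single_stage_npv(100, 0.5, 300, 100, 0.5), 0)
  expect_error(single_stage_npv(5000, 1.5, 5000), "p_success")
  expect_error(single_stage_npv(5000, 0.5, 5000, discount_factor = 2), "discount_factor")
})

test_that("fair option value is the discounted probability-weighted discount secured", {
  tab <- dimasi_transitions()
  ct <- call_contract("Systemic anti-infective", "phase1", 0.2, 8, 1e6)
  # undiscounted: cumulative approval probability times (market - strike) * qty
  r0 <- expected_option_value(ct, market_scenario(10, 8), tab)
  expect_equal(r0$fair_value, ANTI_INFECTIVE_P * 2e6)
  expect_equal(r0$p_approve, ANTI_INFECTIVE_P)
  expect_equal(r0$years_to_approval, 4)
  # discounting at 10%/yr over 2+2+2+1 years
  sc <- market_scenario(10, 8, discount_rate = 0.1,
                        phase_durations = c(phase1 = 2, phase2 = 2, phase3 = 2, rr = 1))
  r1 <- expected_option_value(ct, sc, tab)
  expect_equal(r1$years_to_approval, 7)
  expect_equal(r1$fair_value, ANTI_INFECTIVE_P * 2e6 * 1.1^-7)
  # at the approval boundary the option is worth the full market discount
  boundary <- call_contract("Systemic anti-infective", "approved", 0.2, 8, 1e6)
  rb <- expected_option_value(boundary, market_scenario(10, 8, 0.25), tab)
  expect_equal(rb$fair_value, 2e6)
  expect_equal(rb$p_approve, 1)
  expect_equal(rb$discount_factor, 1)
})

test_that("fair value rises with later purchase phases for every class and random scenario", {
  tab <- dimasi_transitions()
  withr::with_seed(21, {
    for (rep in 1:20) {
      strike <- runif(1, 0, 20)
      market <- strike + runif(1, 0, 30)
      r <- runif(1, 0, 0.3)
      durations <- setNames(runif(4, 0.25, 3), oma_phases(terminal = FALSE))
      sc <- market_scenario(market, strike, r, durations)
      for (cl in tab$therapeutic_class) {
        ct <- call_contract(cl, oma_phases(), 0, strike, 1e6)
        fv <- expected_option_value(ct, sc, tab)$fair_value
        expect_true(all(diff(fv) >= -1e-9),
                    info = sprintf("%s, r=%.2f", cl, r))
      }
    }
  })
})

test_that("zero-quantity contracts are worth zero, with a warning", {
  tab <- dimasi_transitions()
  ct <- call_contract("CNS", "phase2", 0.2, 8, 0)
  expect_warning(res <- expected_option_value(ct, market_scenario(10, 8), tab),
                 "quantity 0")
  expect_equal(res$fair_value, 0)
  expect_equal(res$fair_premium_per_dose, 0)
})

test_that("holder savings follow the worked purchase arithmetic", {
  ct <- worked_example_contract()
  on_success <- holder_net_savings(ct, approved = TRUE, realized_discount_per_dose = 2)
  expect_equal(on_success$outlay, 200000)
  expect_equal(on_success$gross_savings, 2e6)
  expect_equal(on_success$net_savings, 1800000)
  on_failure <- holder_net_savings(ct, approved = FALSE)
  expect_equal(on_failure$net_savings, -200000)
  # zero doses: nothing at stake either way
  zero <- call_contract("CNS", "phase1", 0.2, 8, 0)
  expect_equal(holder_net_savings(zero, TRUE, 2)$net_savings, 0)
  expect_error(holder_net_savings(ct, TRUE, -2), "realized_discount_per_dose")
})

test_that("approval is worth exactly quantity times the realised discount", {
  withr::with_seed(31, {
    for (i in 1:25) {
      ct <- call_contract("CNS", "phase2", runif(1, 0, 1), 5, round(runif(1, 0, 1e7)))
      disc <- runif(1, 0, 5)
      gap <- holder_net_savings(ct, TRUE, disc)$net_savings -
        holder_net_savings(ct, FALSE, disc)$net_savings
      expect_equal(gap, ct$quantity * disc)
    }
  })
  # the discounted accounting variant shrinks gross savings only
  ct <- worked_example_contract()
  d <- holder_net_savings(ct, TRUE, 2, discount_factor = 0.9)
  expect_equal(d$net_savings, 0.9 * 2e6 - 2e5)
})

test_that("scenario construction enforces market-side invariants", {
  expect_error(market_scenario(5, 8), "market_price_per_dose")
  expect_error(market_scenario(10, 8, discount_rate = -0.1), "discount_rate")
  expect_error(market_scenario(10, 8, phase_durations = c(approved = 1)), "approved")
  expect_error(market_scenario(10, 8, phase_durations = c(phase0 = 1)), "phase")
  # partial duration maps fill unnamed phases with the default 1 year
  sc <- market_scenario(10, 8, phase_durations = c(rr = 0.5))
  expect_equal(sc$phase_durations[["rr"]], 0.5)
  expect_equal(sc$phase_durations[["phase1"]], 1)
})
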