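test_that("a project with no terminal payoff is abandoned at every phase", {
  tab <- dimasi_transitions()
  proj <- development_project("Systemic anti-infective",
                              phase_costs = c(phase1 = 1e6, phase2 = 5e6,
                                              phase3 = 2e7, rr = 1e6),
                              terminal_payoff = 0)
  val <- backward_induction_value(proj, tab)
  expect_equal(val$npv, 0)
  expect_true(all(tidy(val)$decision == "abandon"))
  expect_true(all(tidy(val)$value == 0))
})

test_that("with zero costs the value collapses to cumulative success times the payoff", {
  tab <- dimasi_transitions()
  proj <- development_project("Systemic anti-infective", phase_costs = c(phase1 = 0),
                              terminal_payoff = 1e9)
  val <- backward_induction_value(proj, tab)
  expect_equal(val$npv, ANTI_INFECTIVE_P * 1e9)
  expect_true(all(tidy(val)$decision == "continue"))
})

test_that("a single remaining stage reduces exactly to the clipped single-stage NPV", {
  tab <- uniform_table(0.5, "X")
  withr::with_seed(41, {
    for (i in 1:50) {
      cost <- runif(1, 0, 2e4)
      premium <- runif(1, 0, 1e4)
      m <- runif(1, 0, 5e4)
      r <- runif(1, 0, 0.3)
      dur <- runif(1, 0.5, 3)
      proj <- development_project("X", phase_costs = c(rr = cost),
                                  premiums_received = c(rr = premium),
                                  phase_durations = c(rr = dur),
                                  terminal_payoff = m, discount_rate = r,
                                  current_phase = "rr")
      val <- backward_induction_value(proj, tab)
      oracle <- max(0, single_stage_npv(cost, 0.5, m, 0, (1 + r)^(-dur)) + premium)
      expect_equal(val$npv, oracle, tolerance = 1e-12)
    }
  })
})

test_that("a premium injected at a continuing phase raises the value there by its amount", {
  tab <- dimasi_transitions()
  base <- development_project("Musculoskeletal",
                              phase_costs = c(phase1 = 1e6, phase2 = 4e6,
                                              phase3 = 1e7, rr = 5e5),
                              terminal_payoff = 4e8)
  v0 <- backward_induction_value(base, tab)
  expect_equal(tidy(v0)$decision[1], "continue")
  boosted <- development_project("Musculoskeletal",
                                 phase_costs = base$phase_costs,
                                 premiums_received = c(phase1 = 3e6),
                                 terminal_payoff = 4e8)
  v1 <- backward_induction_value(boosted, tab)
  expect_equal(v1$npv, v0$npv + 3e6)
})

test_that("value is monotone in payoff and premiums, anti-monotone in costs, and floored at 0", {
  tab <- dimasi_transitions()
  withr::with_seed(43, {
    for (i in 1:25) {
      costs <- setNames(runif(4, 0, 1e7), oma_phases(FALSE))
      m <- runif(1, 0, 5e8)
      proj <- function(mm, costs_, prem = NULL) {
        development_project("CNS", phase_costs = costs_, premiums_received = prem,
                            terminal_payoff = mm, discount_rate = 0.1)
      }
      v <- backward_induction_value(proj(m, costs), tab)
      expect_true(all(tidy(v)$value >= 0))
      v_up <- backward_induction_value(proj(m * 1.5, costs), tab)
      expect_gte(v_up$npv, v$npv)
      v_cost <- backward_induction_value(proj(m, costs * 1.5), tab)
      expect_lte(v_cost$npv, v$npv)
      v_prem <- backward_induction_value(proj(m, costs, c(phase2 = 1e6)), tab)
      expect_gte(v_prem$npv, v$npv)
    }
  })
})

test_that("minimum viable payout matches closed-form cases", {
  tab <- uniform_table(0.5, "X")
  # costless development needs no payoff at all
  free <- development_project("X", phase_costs = c(phase1 = 0))
  expect_equal(minimum_viable_payout(free, tab), 0)
  # one stage, cost 5000, p = 0.5, undiscounted: 0.5 * M = 5000
  one <- development_project("X", phase_costs = c(rr = 5000), current_phase = "rr")
  expect_equal(minimum_viable_payout(one, tab), 10000, tolerance = 1e-8)
  # premiums covering all costs: push financing alone sustains continuation
  pushed <- development_project("X", phase_costs = c(rr = 5000),
                                premiums_received = c(rr = 5000), current_phase = "rr")
  expect_equal(minimum_viable_payout(pushed, tab), 0)
})

test_that("adding premiums never raises the minimum viable payout", {
  tab <- dimasi_transitions()
  withr::with_seed(47, {
    for (i in 1:10) {
      costs <- setNames(runif(4, 0, 1e6), oma_phases(FALSE))
      base <- development_project("Respiratory", phase_costs = costs)
      prem <- development_project("Respiratory", phase_costs = costs,
                                  premiums_received = c(phase1 = runif(1, 0, 5e5)))
      expect_lte(minimum_viable_payout(prem, tab),
                 minimum_viable_payout(base, tab) + 1e-6)
    }
  })
})

test_that("an unreachable payoff reports as infinite with an explanation", {
  blocked <- uniform_table(1, "B")
  blocked$p_phase3_to_rr <- 0
  proj <- development_project("B", phase_costs = c(phase1 = 1000))
  expect_warning(m <- minimum_viable_payout(proj, blocked), "Inf")
  expect_identical(m, Inf)
})

test_that("project validation rejects malformed inputs", {
  tab <- dimasi_transitions()
  expect_error(development_project("CNS", c(phase1 = -5)), "phase_costs")
  expect_error(development_project("CNS", c(phase1 = 5), terminal_payoff = -1),
               "terminal_payoff")
  expect_error(development_project("CNS", c(phase1 = 5), current_phase = "approved"),
               "live")
  proj <- development_project("Nonexistent", c(phase1 = 5))
  expect_error(backward_induction_value(proj, tab), "Available")
})
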