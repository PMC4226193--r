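# shared fixtures, built in code

# a minimal transition table with the same probability at every transition
uniform_table <- function(p = 1, class_name = "Uniform") {
  tibble::tibble(
    therapeutic_class = class_name,
    p_phase1_to_2 = p, p_phase2_to_3 = p, p_phase3_to_rr = p, p_rr_to_approval = p
  )
}

# write a transition-table CSV (percent units) from raw lines
write_table_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

tt_header <- "therapeutic_class,p_phase1_to_2,p_phase2_to_3,p_phase3_to_rr,p_rr_to_approval"

# write a YAML config from a list
write_config_yaml <- function(cfg) {
  path <- withr::local_tempfile(fileext = ".yaml", .local_envir = parent.frame())
  yaml::write_yaml(cfg, path)
  path
}

# canonical anti-infective worked-example contract: $0.20/dose on 1M doses
worked_example_contract <- function(strike = 8) {
  call_contract("Systemic anti-infective", "phase1",
                premium_per_dose = 0.2, strike_per_dose = strike, quantity = 1e6)
}

# exact product of the packaged anti-infective row, used as the analytic oracle
ANTI_INFECTIVE_P <- 0.582 * 0.522 * 0.786 * 1.00
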