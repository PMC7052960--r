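# Shared fixtures, built once per test run.

.fix <- new.env()

fix_lt <- function() {
  if (is.null(.fix$lt)) .fix$lt <- gompertz_life_table()
  .fix$lt
}

fix_params <- function() transition_params()
fix_costs <- function() cost_set()
fix_utils <- function() utility_set()
fix_config <- function(...) model_config(...)

# zero-uncertainty variants used by the PSA determinism tests
fix_params0 <- function() {
  transition_params(ci_m0bcr_m1bcr = c(0.0288, 0.0288),
                    ci_m0bcr_m0crpc = c(0.0279, 0.0279),
                    ci_m0crpc_m1crpc = c(0.1520, 0.1520),
                    ci_m1bcr_m1crpc = c(0.2055, 0.2055))
}
fix_costs0 <- function() {
  cost_set(ci_m0bcr_first_year = c(3524, 3524),
           ci_m0bcr_subsequent = c(1844, 1844),
           ci_m1bcr_first_year = c(4816, 4816),
           ci_m1bcr_subsequent = c(4815, 4815),
           ci_m0crpc_annual = c(5717, 5717),
           ci_m1crpc_annual = c(12346, 12346))
}
fix_utils0 <- function() {
  utility_set(sd_m0bcr = 0, sd_m1bcr = 0, sd_m0crpc = 0, sd_m1crpc = 0)
}

# degenerate blocks for reduction-to-survival tests
null_params <- function() {
  transition_params(p_m0bcr_m1bcr = 0, ci_m0bcr_m1bcr = c(0, 0),
                    p_m0bcr_m0crpc = 0, ci_m0bcr_m0crpc = c(0, 0),
                    p_m0crpc_m1crpc = 0, ci_m0crpc_m1crpc = c(0, 0),
                    p_m1bcr_m1crpc = 0, ci_m1bcr_m1crpc = c(0, 0),
                    excess_death_m0crpc = 0, excess_death_m1bcr = 0,
                    excess_death_m1crpc = 0)
}
zero_costs <- function() {
  cost_set(m0bcr_first_year = 0, ci_m0bcr_first_year = c(0, 0),
           m0bcr_subsequent = 0, ci_m0bcr_subsequent = c(0, 0),
           m1bcr_first_year = 0, ci_m1bcr_first_year = c(0, 0),
           m1bcr_subsequent = 0, ci_m1bcr_subsequent = c(0, 0),
           m0crpc_annual = 0, ci_m0crpc_annual = c(0, 0),
           m1crpc_annual = 0, ci_m1crpc_annual = c(0, 0),
           imaging_cost = c(NaF = 0, FCH = 0, `DW-MRI` = 0))
}
unit_utils <- function() {
  utility_set(u_m0bcr = 1, sd_m0bcr = 0, u_m1bcr = 1, sd_m1bcr = 0,
              u_m0crpc = 1, sd_m0crpc = 0, u_m1crpc = 1, sd_m1crpc = 0)
}

unit_alloc <- function(state) {
  a <- stats::setNames(numeric(length(health_states())), health_states())
  a[state] <- 1
  a
}
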