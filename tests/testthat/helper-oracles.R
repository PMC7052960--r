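# Independent oracles. These re-derive expected behaviour without calling
# the engine code paths they are used to check.

# Transition matrix derived directly from the published rules, written as
# plain arithmetic (independent of build_transition_row).
oracle_matrix <- function(params, q, fp_policy = "m1_dynamics") {
  comb <- function(...) 1 - prod(1 - c(...))
  s <- c("m0_bcr", "m1_bcr", "m0_crpc", "m1_crpc", "fn_tunnel", "fp_misdx",
         "death")
  P <- matrix(0, 7, 7, dimnames = list(s, s))
  if (q == 1) {
    P[, "death"] <- 1
    P["death", ] <- c(0, 0, 0, 0, 0, 0, 1)
    return(P)
  }
  p1 <- params$p_m0bcr_m1bcr; p2 <- params$p_m0bcr_m0crpc
  P["m0_bcr", c("m1_bcr", "m0_crpc", "m1_crpc", "death")] <-
    c(p1, p2, comb(p1, p2), q)
  P["m0_bcr", "m0_bcr"] <- 1 - sum(P["m0_bcr", ])
  m1_out <- c(params$p_m1bcr_m1crpc, comb(params$excess_death_m1bcr, q))
  P["m1_bcr", c("m1_crpc", "death")] <- m1_out
  P["m1_bcr", "m1_bcr"] <- 1 - sum(m1_out)
  P["m0_crpc", c("m1_crpc", "death")] <-
    c(params$p_m0crpc_m1crpc, comb(params$excess_death_m0crpc, q))
  P["m0_crpc", "m0_crpc"] <- 1 - sum(P["m0_crpc", ])
  P["m1_crpc", "death"] <- comb(params$excess_death_m1crpc, q)
  P["m1_crpc", "m1_crpc"] <- 1 - P["m1_crpc", "death"]
  P["fn_tunnel", c("m1_crpc", "death")] <- m1_out
  P["fn_tunnel", "m1_bcr"] <- 1 - sum(m1_out)
  if (fp_policy %in% c("m1_dynamics", "m1_state")) {
    P["fp_misdx", c("m1_crpc", "death")] <- m1_out
    P["fp_misdx", "fp_misdx"] <- 1 - sum(m1_out)
  } else if (fp_policy == "m1_row_merge") {
    P["fp_misdx", c("m1_crpc", "death")] <- m1_out
    P["fp_misdx", "m0_bcr"] <- 1 - sum(m1_out)
  } else {
    P["fp_misdx", c("m1_bcr", "m0_crpc", "m1_crpc", "death")] <-
      P["m0_bcr", c("m1_bcr", "m0_crpc", "m1_crpc", "death")]
    P["fp_misdx", "m0_bcr"] <- 1 - sum(P["fp_misdx", ])
  }
  P["death", "death"] <- 1
  P
}

# Per-patient Monte Carlo simulation of the same transition rules, with
# life-table occupancy counting and (1+d)^-(t-1) discounting. Returns means
# and standard errors of discounted QALYs and costs per patient.
microsim_oracle <- function(config, params, lt, alloc, costs, utils,
                            n = 200000L, seed = 42L) {
  set.seed(seed)
  states <- health_states()
  n_cycles <- config$terminal_age - config$start_age + 1L
  cur <- sample.int(7L, n, replace = TRUE, prob = alloc)
  qaly <- numeric(n)
  cost <- numeric(n)
  fp_m1 <- config$fp_transition_policy == "m1_state"
  for (t in seq_len(n_cycles)) {
    age <- config$start_age + t - 1L
    q <- death_prob(lt, age)
    P <- oracle_matrix(params, q, config$fp_transition_policy)
    cum <- t(apply(P, 1L, cumsum))
    u <- stats::runif(n)
    nxt <- integer(n)
    for (s in 1:7) {
      idx <- which(cur == s)
      if (length(idx)) {
        nxt[idx] <- findInterval(u[idx], cum[s, ], left.open = TRUE) + 1L
      }
    }
    first <- t == 1L
    uvec <- c(utils$u_m0bcr, utils$u_m1bcr, utils$u_m0crpc, utils$u_m1crpc,
              utils$u_m0bcr,
              if (first || fp_m1) utils$u_m1bcr else utils$u_m0bcr, 0)
    cvec <- c(if (first) costs$m0bcr_first_year else costs$m0bcr_subsequent,
              if (first) costs$m1bcr_first_year else costs$m1bcr_subsequent,
              costs$m0crpc_annual, costs$m1crpc_annual,
              costs[[config$fn_cost_policy]],
              if (fp_m1) {
                if (first) costs$m1bcr_first_year else costs$m1bcr_subsequent
              } else if (first) {
                costs[[config$fp_cost_policy]]
              } else {
                costs$m0bcr_subsequent
              }, 0)
    disc <- (1 + config$discount_rate)^-(t - 1)
    w_u <- (uvec[cur] + uvec[nxt]) / 2     # life-table counting
    w_c <- (cvec[cur] + cvec[nxt]) / 2
    qaly <- qaly + w_u * disc
    cost <- cost + w_c * disc
    cur <- nxt
    if (all(cur == 7L)) break
  }
  list(qalys = mean(qaly), qalys_se = stats::sd(qaly) / sqrt(n),
       cost = mean(cost), cost_se = stats::sd(cost) / sqrt(n))
}
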