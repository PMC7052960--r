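# Decision tree + Markov cohort engine.
#
# Seven engine states: the five disease states (m0-BCR, m1-BCR, m0-CRPC,
# m1-CRPC, death) plus two misdiagnosis entry states — a one-cycle tunnel
# for false negatives and a false-positive state whose mechanics are set by
# `fp_transition_policy`. Cycles are annual; the cohort ages one year per
# cycle and background mortality is read from a period life table.

#' Engine health states
#'
#' @return Character vector of state names in engine order.
#' @export
health_states <- function() {
  c("m0_bcr", "m1_bcr", "m0_crpc", "m1_crpc", "fn_tunnel", "fp_misdx",
    "death")
}

#' Convert an annual probability to an annual rate
#'
#' @param p Probability in `[0, 1)`.
#' @return `-log(1 - p)`.
#' @export
prob_to_rate <- function(p) {
  if (any(p < 0 | p > 1)) stop("`p` must be in [0, 1]", call. = FALSE)
  if (any(p == 1)) stop("p = 1 corresponds to an infinite rate", call. = FALSE)
  -log1p(-p)
}

#' Convert an annual rate to an annual probability
#'
#' @param r Non-negative rate.
#' @return `1 - exp(-r)`.
#' @export
rate_to_prob <- function(r) {
  if (any(r < 0)) stop("`r` must be >= 0", call. = FALSE)
  -expm1(-r)
}

#' Combine annual probabilities of competing/independent events
#'
#' Adds probabilities on the rate scale:
#' `1 - exp(-sum(-log(1 - p_i)))`, algebraically `1 - prod(1 - p_i)`. Used
#' for "excess disease mortality + background mortality" transitions.
#'
#' @param ps Numeric vector of probabilities in `[0, 1]`.
#' @return Combined annual probability.
#' @export
combine_probs <- function(ps) {
  if (any(ps < 0 | ps > 1)) stop("probabilities must be in [0, 1]",
                                 call. = FALSE)
  if (any(ps == 1)) return(1)
  -expm1(sum(log1p(-ps)))
}

.fix_row <- function(v, stay_state, row_name, renormalize) {
  out <- sum(v)
  if (out > 1 + 1e-12) {
    if (!renormalize) {
      stop(sprintf(
        "outgoing probabilities from %s sum to %.6f > 1; tighten the %s",
        row_name, out, "parameters or set renormalize = TRUE"),
        call. = FALSE)
    }
    v <- v / out
    out <- 1
  }
  v[stay_state] <- v[stay_state] + (1 - out)
  v
}

#' Transition probability row for one state
#'
#' Builds the outgoing probability vector of `state` at a given age:
#' disease transitions per the base-case annual probabilities, death as the
#' rate-scale combination of the state's excess mortality and the life-table
#' `qx` at that age. The false-negative tunnel uses the m1-BCR row with its
#' residual mass sent to m1-BCR (one-cycle tunnel); the false-positive state
#' row depends on `fp_policy` (see [model_config()]).
#'
#' @param state One of [health_states()].
#' @param params A [transition_params()].
#' @param lt A [life_table()].
#' @param age Age used for the background mortality lookup.
#' @param fp_policy False-positive transition policy.
#' @param renormalize Clamp rows whose outflow exceeds 1 instead of erroring.
#' @return Named probability vector over [health_states()] summing to 1.
#' @export
build_transition_row <- function(state, params, lt, age,
                                 fp_policy = "m1_dynamics",
                                 renormalize = FALSE) {
  states <- health_states()
  v <- stats::setNames(numeric(length(states)), states)
  q <- death_prob(lt, age)
  if (q == 1 && state != "death") {
    # life-table closure: background mortality empties every living state
    v["death"] <- 1
    return(v)
  }

  m0_row <- function(stay) {
    v["m1_bcr"] <- params$p_m0bcr_m1bcr
    v["m0_crpc"] <- params$p_m0bcr_m0crpc
    v["m1_crpc"] <- combine_probs(c(params$p_m0bcr_m1bcr,
                                    params$p_m0bcr_m0crpc))
    v["death"] <- q
    .fix_row(v, stay, state, renormalize)
  }
  m1_row <- function(stay) {
    v["m1_crpc"] <- params$p_m1bcr_m1crpc
    v["death"] <- combine_probs(c(params$excess_death_m1bcr, q))
    .fix_row(v, stay, state, renormalize)
  }

  switch(state,
    m0_bcr = m0_row("m0_bcr"),
    m1_bcr = m1_row("m1_bcr"),
    m0_crpc = {
      v["m1_crpc"] <- params$p_m0crpc_m1crpc
      v["death"] <- combine_probs(c(params$excess_death_m0crpc, q))
      .fix_row(v, "m0_crpc", state, renormalize)
    },
    m1_crpc = {
      v["death"] <- combine_probs(c(params$excess_death_m1crpc, q))
      .fix_row(v, "m1_crpc", state, renormalize)
    },
    fn_tunnel = m1_row("m1_bcr"),
    fp_misdx = switch(fp_policy,
      m1_dynamics = m1_row("fp_misdx"),
      m1_state = m1_row("fp_misdx"),
      m1_row_merge = m1_row("m0_bcr"),
      m0_row = m0_row("m0_bcr"),
      stop(sprintf("unknown fp_policy '%s'", fp_policy), call. = FALSE)),
    death = {
      v["death"] <- 1
      v
    },
    stop(sprintf("unknown state '%s'", state), call. = FALSE))
}

#' Full transition matrix at an age
#'
#' @inheritParams build_transition_row
#' @return Row-stochastic matrix over [health_states()].
#' @export
transition_matrix <- function(params, lt, age, fp_policy = "m1_dynamics",
                              renormalize = FALSE) {
  states <- health_states()
  t(vapply(states, build_transition_row, numeric(length(states)),
           params = params, lt = lt, age = age, fp_policy = fp_policy,
           renormalize = renormalize))
}

#' Decision-tree allocation of the cohort at entry
#'
#' Splits the cohort by true bone-metastasis status (prevalence) and test
#' outcome: true positives enter m1-BCR, false negatives the one-cycle
#' tunnel, true negatives m0-BCR and false positives the misdiagnosis state.
#'
#' @param prevalence Bone-metastasis prevalence at entry.
#' @param strat A [strategy()].
#' @return Named probability vector over [health_states()] summing to 1.
#' @export
initial_allocation <- function(prevalence, strat) {
  .chk_prob(prevalence, "prevalence")
  stopifnot(inherits(strat, "strategy"))
  v <- stats::setNames(numeric(length(health_states())), health_states())
  v["m1_bcr"] <- prevalence * strat$se
  v["fn_tunnel"] <- prevalence * (1 - strat$se)
  v["m0_bcr"] <- (1 - prevalence) * strat$sp
  v["fp_misdx"] <- (1 - prevalence) * (1 - strat$sp)
  v
}

# Per-cycle reward vectors (cost EUR/year, utility, alive indicator).
# The fp state's rewards depend on the policy: under "m1_state" the patient
# is managed as metastatic throughout the misdiagnosis (m1-BCR costs and
# utility); under the other policies the m1-BCR attribution lasts one cycle.
.cycle_costs <- function(cycle, costs, config) {
  first <- cycle == 1L
  fp_cost <- if (config$fp_transition_policy == "m1_state") {
    if (first) costs$m1bcr_first_year else costs$m1bcr_subsequent
  } else if (first) {
    costs[[config$fp_cost_policy]]
  } else {
    costs$m0bcr_subsequent
  }
  c(m0_bcr = if (first) costs$m0bcr_first_year else costs$m0bcr_subsequent,
    m1_bcr = if (first) costs$m1bcr_first_year else costs$m1bcr_subsequent,
    m0_crpc = costs$m0crpc_annual,
    m1_crpc = costs$m1crpc_annual,
    fn_tunnel = costs[[config$fn_cost_policy]],
    fp_misdx = fp_cost,
    death = 0)
}

.cycle_utils <- function(cycle, utils, config) {
  first <- cycle == 1L
  fp_util <- if (first || config$fp_transition_policy == "m1_state") {
    utils$u_m1bcr
  } else {
    utils$u_m0bcr
  }
  c(m0_bcr = utils$u_m0bcr, m1_bcr = utils$u_m1bcr,
    m0_crpc = utils$u_m0crpc, m1_crpc = utils$u_m1crpc,
    fn_tunnel = utils$u_m0bcr,
    fp_misdx = fp_util,
    death = utils$u_death)
}

#' Run the Markov cohort model for one initial allocation
#'
#' Evolves the cohort over annual cycles from `start_age` until the
#' life-table closure age empties all living states, accumulating per-patient
#' (un)discounted life-years, QALYs and costs. Cycle-t rewards are weighted
#' by the occupancy counting method and discounted by
#' `(1 + discount_rate)^-(t-1)`; the imaging cost is added once,
#' undiscounted, at entry.
#'
#' @param config A [model_config()].
#' @param params A [transition_params()].
#' @param lt A [life_table()].
#' @param alloc Initial distribution over [health_states()] summing to 1.
#' @param costs A [cost_set()].
#' @param utils A [utility_set()].
#' @param imaging_cost Per-patient entry cost (EUR).
#' @param name Optional strategy label carried into the result.
#' @return An object of class `strategy_result`: list with the per-cycle
#'   `trace` (cohort counts, cycles 0..T in rows) and per-patient
#'   `life_years`, `life_years_disc`, `qalys`, `qalys_undisc`, `cost`,
#'   `cost_undisc`.
#' @export
run_markov <- function(config, params, lt, alloc, costs, utils,
                       imaging_cost = 0, name = NULL) {
  states <- health_states()
  stopifnot(inherits(config, "model_config"))
  alloc <- alloc[states]
  if (anyNA(alloc) || abs(sum(alloc) - 1) > 1e-9) {
    stop("`alloc` must be a distribution over health_states()", call. = FALSE)
  }
  if (alloc["death"] > 0 && alloc["death"] < 1) {
    stop("initial allocation must not place partial mass in death",
         call. = FALSE)
  }
  n_cycles <- config$terminal_age - config$start_age + 1L
  if (n_cycles < 1L) stop("horizon shorter than one cycle", call. = FALSE)

  trace <- matrix(0, nrow = n_cycles + 1L, ncol = length(states),
                  dimnames = list(0:n_cycles, states))
  trace[1L, ] <- alloc * config$cohort_size

  ly <- ly_disc <- qaly <- qaly_undisc <- cost <- cost_undisc <- 0
  alive <- stats::setNames(c(rep(1, length(states) - 1L), 0), states)

  for (t in seq_len(n_cycles)) {
    age <- config$start_age + t - 1L
    P <- transition_matrix(params, lt, age,
                           fp_policy = config$fp_transition_policy,
                           renormalize = config$renormalize)
    trace[t + 1L, ] <- trace[t, ] %*% P
    w <- switch(config$counting_method,
                `life-table` = (trace[t, ] + trace[t + 1L, ]) / 2,
                start = trace[t + 1L, ],
                end = trace[t, ])
    disc <- (1 + config$discount_rate)^-(t - 1)
    cvec <- .cycle_costs(t, costs, config)
    uvec <- .cycle_utils(t, utils, config)
    ly <- ly + sum(w * alive)
    ly_disc <- ly_disc + sum(w * alive) * disc
    qaly <- qaly + sum(w * uvec) * disc
    qaly_undisc <- qaly_undisc + sum(w * uvec)
    cost <- cost + sum(w * cvec) * disc
    cost_undisc <- cost_undisc + sum(w * cvec)
  }

  per <- config$cohort_size
  structure(list(
    name = name,
    trace = trace,
    life_years = ly / per,
    life_years_disc = ly_disc / per,
    qalys = qaly / per,
    qalys_undisc = qaly_undisc / per,
    cost = cost / per + imaging_cost,
    cost_undisc = cost_undisc / per + imaging_cost,
    imaging_cost = imaging_cost),
    class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf(
    "<strategy_result>%s LY %.3f (disc %.3f)  QALY %.3f  cost %.0f EUR\n",
    if (is.null(x$name)) "" else paste0(" ", x$name),
    x$life_years, x$life_years_disc, x$qalys, x$cost))
  invisible(x)
}

#' Run the decision tree + Markov model for a set of strategies
#'
#' @param config A [model_config()].
#' @param params A [transition_params()].
#' @param lt A [life_table()].
#' @param costs A [cost_set()].
#' @param utils A [utility_set()].
#' @param prevalence Bone-metastasis prevalence at entry.
#' @param strategies List of [strategy()] objects (unique names).
#' @return Named list of `strategy_result`, keyed by strategy name.
#' @export
run_strategy_set <- function(config, params, lt, costs, utils, prevalence,
                             strategies) {
  if (length(strategies) < 1L) stop("need at least one strategy",
                                    call. = FALSE)
  nms <- vapply(strategies, function(s) s$name, "")
  if (anyDuplicated(nms)) {
    stop(sprintf("duplicate strategy name '%s'", nms[anyDuplicated(nms)]),
         call. = FALSE)
  }
  out <- lapply(strategies, function(s) {
    run_markov(config, params, lt,
               alloc = initial_allocation(prevalence, s),
               costs = costs, utils = utils,
               imaging_cost = s$imaging_cost, name = s$name)
  })
  names(out) <- nms
  out
}

#' Internal-validity life expectancies
#'
#' Runs the model without imaging (no misdiagnosis states, no imaging
#' costs, no discounting of life-years) and reports undiscounted life
#' expectancy starting all patients in m0-BCR, all in m1-BCR, and a
#' weighted mix of the two.
#'
#' @param config A [model_config()].
#' @param params A [transition_params()].
#' @param lt A [life_table()].
#' @param m1_weight Weight of the m1-BCR value in the `overall` mix. The
#'   default 0.5 reports the midpoint of the m0/m1 range, matching the
#'   published validation convention; set to the cohort prevalence (e.g.
#'   [default_prevalence()]) for a prevalence-weighted cohort expectancy.
#' @return Named numeric vector `c(overall, m0_only, m1_only)` in years.
#' @export
validate_life_expectancy <- function(config, params, lt, m1_weight = 0.5) {
  costs <- cost_set()
  utils <- utility_set()
  states <- health_states()
  base <- stats::setNames(numeric(length(states)), states)
  le_from <- function(state) {
    a <- base
    a[state] <- 1
    run_markov(config, params, lt, a, costs, utils)$life_years
  }
  m0 <- le_from("m0_bcr")
  m1 <- le_from("m1_bcr")
  c(overall = (1 - m1_weight) * m0 + m1_weight * m1,
    m0_only = m0, m1_only = m1)
}

#' Write a cohort trace to a delimited file
#'
#' @param result A `strategy_result`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_trace <- function(result, path) {
  df <- data.frame(cycle = as.integer(rownames(result$trace)), result$trace,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
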