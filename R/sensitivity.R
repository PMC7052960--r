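# One-way deterministic sensitivity analysis (tornado) and probabilistic
# sensitivity analysis (Monte Carlo over the stated parameter distributions).

#' Apply named parameter overrides
#'
#' Resolves override names among the transition probabilities (`p_*`),
#' utilities (`u_*`) and cost fields, returning modified copies of the three
#' blocks. Unknown names are an error.
#'
#' @param params A [transition_params()].
#' @param costs A [cost_set()].
#' @param utils A [utility_set()].
#' @param overrides Named list of replacement values.
#' @return List with elements `params`, `costs`, `utils`.
#' @export
apply_overrides <- function(params, costs, utils, overrides) {
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    if (nm %in% names(params)) {
      params[[nm]] <- v
    } else if (nm %in% names(utils)) {
      utils[[nm]] <- v
    } else if (nm %in% names(costs)) {
      costs[[nm]] <- v
    } else {
      stop(sprintf("unknown parameter '%s'", nm), call. = FALSE)
    }
  }
  list(params = params, costs = costs, utils = utils)
}

#' Default one-way sensitivity ranges
#'
#' The published one-way analysis varies the transition probability of
#' developing bone metastases over its 95% CI, each state utility over mean
#' +/- 1.96 SD (clipped to `[0, 1]`) and the grouped m0-BCR / m1-BCR
#' treatment costs over their 95% CIs (first-year and subsequent-year
#' components moved jointly to their bounds).
#'
#' @param params A [transition_params()].
#' @param costs A [cost_set()].
#' @param utils A [utility_set()].
#' @return List of range entries `list(name, low, high)` where `low`/`high`
#'   are named override lists understood by [apply_overrides()].
#' @export
default_dsa_ranges <- function(params = transition_params(),
                               costs = cost_set(),
                               utils = utility_set()) {
  rng <- list()
  rng[["p_m0bcr_m1bcr"]] <- list(
    name = "p_m0bcr_m1bcr",
    low = list(p_m0bcr_m1bcr = params$ci_m0bcr_m1bcr[1L]),
    high = list(p_m0bcr_m1bcr = params$ci_m0bcr_m1bcr[2L]))
  for (st in c("m0bcr", "m1bcr", "m0crpc", "m1crpc")) {
    u <- utils[[paste0("u_", st)]]
    s <- utils[[paste0("sd_", st)]]
    rng[[paste0("u_", st)]] <- list(
      name = paste0("u_", st),
      low = stats::setNames(list(max(0, u - 1.96 * s)), paste0("u_", st)),
      high = stats::setNames(list(min(1, u + 1.96 * s)), paste0("u_", st)))
  }
  rng[["m0bcr_cost"]] <- list(
    name = "m0bcr_cost",
    low = list(m0bcr_first_year = costs$ci_m0bcr_first_year[1L],
               m0bcr_subsequent = costs$ci_m0bcr_subsequent[1L]),
    high = list(m0bcr_first_year = costs$ci_m0bcr_first_year[2L],
                m0bcr_subsequent = costs$ci_m0bcr_subsequent[2L]))
  rng[["m1bcr_cost"]] <- list(
    name = "m1bcr_cost",
    low = list(m1bcr_first_year = costs$ci_m1bcr_first_year[1L],
               m1bcr_subsequent = costs$ci_m1bcr_subsequent[1L]),
    high = list(m1bcr_first_year = costs$ci_m1bcr_first_year[2L],
                m1bcr_subsequent = costs$ci_m1bcr_subsequent[2L]))
  rng
}

#' One-way deterministic sensitivity analysis
#'
#' Reruns the model twice per parameter (all other parameters at base case)
#' and records the ICER of the designated strategy pair at each bound.
#' Entries are sorted by descending ICER spread (tornado order).
#'
#' @param config A [model_config()].
#' @param params A [transition_params()].
#' @param lt A [life_table()].
#' @param costs A [cost_set()].
#' @param utils A [utility_set()].
#' @param prevalence Bone-metastasis prevalence at entry.
#' @param strategies Named list of [strategy()] objects.
#' @param ranges Range entries as from [default_dsa_ranges()].
#' @param comparator Length-2 character: comparator strategy then the more
#'   effective strategy whose ICER is tracked.
#' @return Data frame of class `tornado` with columns `parameter`,
#'   `icer_low`, `icer_high`, `spread`, and attribute `base_icer`.
#' @export
one_way_dsa <- function(config, params, lt, costs, utils, prevalence,
                        strategies, ranges = default_dsa_ranges(params, costs,
                                                                utils),
                        comparator = c("DW-MRI", "FCH")) {
  if (!all(comparator %in% names(strategies))) {
    stop("comparator strategies not found", call. = FALSE)
  }
  pair_icer <- function(p, co, ut) {
    res <- run_strategy_set(config, p, lt, co, ut, prevalence,
                            strategies[comparator])
    icer(res[[comparator[1L]]], res[[comparator[2L]]])
  }
  base_icer <- pair_icer(params, costs, utils)
  if (length(ranges) == 0L) {
    out <- data.frame(parameter = character(), icer_low = numeric(),
                      icer_high = numeric(), spread = numeric())
    attr(out, "base_icer") <- base_icer
    class(out) <- c("tornado", "data.frame")
    return(out)
  }
  rows <- lapply(ranges, function(r) {
    at <- function(ov) {
      mod <- tryCatch(apply_overrides(params, costs, utils, ov),
                      error = function(e) {
        stop(sprintf("parameter '%s': %s", r$name, conditionMessage(e)),
             call. = FALSE)
      })
      tryCatch(pair_icer(mod$params, mod$costs, mod$utils),
               error = function(e) {
        stop(sprintf("bound of parameter '%s' invalid: %s", r$name,
                     conditionMessage(e)), call. = FALSE)
      })
    }
    data.frame(parameter = r$name, icer_low = at(r$low), icer_high = at(r$high),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$spread <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$spread), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  class(out) <- c("tornado", "data.frame")
  out
}

.beta_draw <- function(m, s) {
  if (s == 0) return(m)
  v <- s^2
  if (v >= m * (1 - m)) {
    stop(sprintf("utility mean %g / sd %g has no matching beta distribution",
                 m, s), call. = FALSE)
  }
  k <- m * (1 - m) / v - 1
  stats::rbeta(1L, m * k, (1 - m) * k)
}

.gamma_draw <- function(m, ci) {
  s <- (ci[2L] - ci[1L]) / 3.92
  if (s == 0) return(m)
  if (!is.finite(s) || m <= 0) {
    stop(sprintf("cost mean %g / CI width %g has non-finite gamma moments",
                 m, ci[2L] - ci[1L]), call. = FALSE)
  }
  stats::rgamma(1L, shape = m^2 / s^2, rate = m / s^2)
}

.binom_prob_draw <- function(p, ci) {
  se <- (ci[2L] - ci[1L]) / 3.92
  if (se == 0) return(p)
  n_eff <- max(1L, round(p * (1 - p) / se^2))
  stats::rbinom(1L, n_eff, p) / n_eff
}

#' Draw one perturbed parameter set
#'
#' Samples each uncertain parameter from its stated distribution: transition
#' probabilities as `k / n_eff` with `k ~ Binomial(n_eff, p)` and `n_eff`
#' inferred from the 95% CI half-width; treatment costs from gamma
#' distributions moment-matched to the mean and `SD = CI width / 3.92`;
#' utilities from moment-matched beta distributions (the stated SDs); and
#' strategy sensitivities/specificities binomially with the trial
#' denominators. Parameters whose uncertainty collapses to zero are returned
#' unchanged. Sampling is independent across parameters.
#'
#' @param params A [transition_params()].
#' @param costs A [cost_set()].
#' @param utils A [utility_set()].
#' @param strategies Named list of [strategy()] objects.
#' @param trial_denoms `c(pos = 7, neg = 48)` trial denominators for the
#'   binomial accuracy draws; `NULL` keeps se/sp fixed.
#' @return List with perturbed `params`, `costs`, `utils`, `strategies`.
#'   Uses the current RNG state; seed control belongs to the caller.
#' @export
sample_parameters <- function(params, costs, utils, strategies,
                              trial_denoms = c(pos = 7, neg = 48)) {
  for (nm in c("m0bcr_m1bcr", "m0bcr_m0crpc", "m0crpc_m1crpc",
               "m1bcr_m1crpc")) {
    params[[paste0("p_", nm)]] <-
      .binom_prob_draw(params[[paste0("p_", nm)]],
                       params[[paste0("ci_", nm)]])
  }
  for (nm in c("m0bcr_first_year", "m0bcr_subsequent", "m1bcr_first_year",
               "m1bcr_subsequent", "m0crpc_annual", "m1crpc_annual")) {
    costs[[nm]] <- .gamma_draw(costs[[nm]], costs[[paste0("ci_", nm)]])
  }
  for (st in c("m0bcr", "m1bcr", "m0crpc", "m1crpc")) {
    utils[[paste0("u_", st)]] <- .beta_draw(utils[[paste0("u_", st)]],
                                            utils[[paste0("sd_", st)]])
  }
  if (!is.null(trial_denoms)) {
    strategies <- lapply(strategies, function(s) {
      s$se <- stats::rbinom(1L, trial_denoms[["pos"]], s$se) /
        trial_denoms[["pos"]]
      s$sp <- stats::rbinom(1L, trial_denoms[["neg"]], s$sp) /
        trial_denoms[["neg"]]
      s
    })
  }
  list(params = params, costs = costs, utils = utils, strategies = strategies)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo over the parameter distributions of [sample_parameters()]:
#' per iteration, draws a parameter set and reruns every strategy, then
#' summarises the incremental cost and QALYs of `comparator[2]` vs
#' `comparator[1]`. The headline ICER is the ratio of the mean incremental
#' cost to the mean incremental QALYs; the (sign-unstable) mean of per-draw
#' ICERs is also reported. Fully reproducible given `seed`.
#'
#' @param config A [model_config()].
#' @param params A [transition_params()].
#' @param lt A [life_table()].
#' @param costs A [cost_set()].
#' @param utils A [utility_set()].
#' @param prevalence Bone-metastasis prevalence at entry.
#' @param strategies Named list of [strategy()] objects.
#' @param n_iter Number of Monte Carlo iterations (default 1000).
#' @param seed RNG seed.
#' @param comparator Length-2 character, comparator then intervention.
#' @param trial_denoms Passed to [sample_parameters()].
#' @return An object of class `psa_result`: list with `draws` (data frame
#'   `iteration`, `strategy`, `cost`, `qalys`), `incremental` (per-draw
#'   delta cost/qalys/icer), `mean_incremental_cost`,
#'   `mean_incremental_qalys`, `mean_icer` (ratio of means),
#'   `mean_of_icers`, `n_iter`, `seed`, `comparator`.
#' @export
run_psa <- function(config, params, lt, costs, utils, prevalence, strategies,
                    n_iter = 1000L, seed = 1L,
                    comparator = c("DW-MRI", "FCH"),
                    trial_denoms = c(pos = 7, neg = 48)) {
  if (n_iter < 1L) stop("`n_iter` must be >= 1", call. = FALSE)
  if (!all(comparator %in% names(strategies))) {
    stop("comparator strategies not found", call. = FALSE)
  }
  set.seed(seed)
  nms <- names(strategies)
  draws <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    d <- sample_parameters(params, costs, utils, strategies, trial_denoms)
    res <- run_strategy_set(config, d$params, lt, d$costs, d$utils,
                            prevalence, d$strategies)
    draws[[it]] <- data.frame(
      iteration = it, strategy = nms,
      cost = vapply(res, function(r) r$cost, 0),
      qalys = vapply(res, function(r) r$qalys, 0),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  draws <- do.call(rbind, draws)
  a <- draws[draws$strategy == comparator[1L], ]
  b <- draws[draws$strategy == comparator[2L], ]
  dc <- b$cost - a$cost
  dq <- b$qalys - a$qalys
  inc <- data.frame(iteration = a$iteration, delta_cost = dc,
                    delta_qalys = dq,
                    icer = ifelse(dq == 0, NA_real_, dc / dq))
  structure(list(
    draws = draws,
    incremental = inc,
    mean_incremental_cost = mean(dc),
    mean_incremental_qalys = mean(dq),
    mean_icer = mean(dc) / mean(dq),
    mean_of_icers = mean(inc$icer[is.finite(inc$icer)]),
    n_iter = n_iter, seed = seed, comparator = comparator),
    class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    paste0("<psa_result> %d iterations (seed %d): %s vs %s\n",
           "  mean delta cost %.0f EUR, mean delta QALYs %.3f, ",
           "ICER (ratio of means) %.0f EUR/QALY\n"),
    x$n_iter, x$seed, x$comparator[2L], x$comparator[1L],
    x$mean_incremental_cost, x$mean_incremental_qalys, x$mean_icer))
  invisible(x)
}
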