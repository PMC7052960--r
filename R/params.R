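# Model parameter blocks: disease transition probabilities, state utilities,
# annual costs, run configuration, imaging strategies. Defaults are the
# published base-case values for recurrent prostate cancer; every field can
# be overridden via the config file or constructor arguments.

.chk_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

.chk_ci <- function(p, lo, hi, name) {
  if (!(lo <= p && p <= hi)) {
    stop(sprintf("CI bounds (%g, %g) must bracket `%s` = %g", lo, hi, name, p),
         call. = FALSE)
  }
  invisible(p)
}

#' Annual disease transition probabilities
#'
#' Point estimates (with 95% CI where available) of the annual probabilities
#' driving the five-state disease model: progression from non-metastatic
#' biochemical recurrence (m0-BCR) to bone-metastatic BCR (m1-BCR) or to
#' non-metastatic castration-resistant disease (m0-CRPC), progression of
#' either to m1-CRPC, and the disease-specific (excess) death probabilities
#' that are combined with age-dependent background mortality.
#'
#' @param p_m0bcr_m1bcr,p_m0bcr_m0crpc,p_m0crpc_m1crpc,p_m1bcr_m1crpc Annual
#'   transition probabilities.
#' @param ci_m0bcr_m1bcr,ci_m0bcr_m0crpc,ci_m0crpc_m1crpc,ci_m1bcr_m1crpc
#'   Length-2 95% confidence intervals for the above.
#' @param excess_death_m0crpc,excess_death_m1bcr,excess_death_m1crpc Annual
#'   excess death probabilities added (on the rate scale) to background
#'   mortality.
#' @return An object of class `transition_params`.
#' @export
transition_params <- function(p_m0bcr_m1bcr = 0.0288,
                              ci_m0bcr_m1bcr = c(0.0279, 0.0297),
                              p_m0bcr_m0crpc = 0.0279,
                              ci_m0bcr_m0crpc = c(0.0249, 0.0308),
                              p_m0crpc_m1crpc = 0.1520,
                              ci_m0crpc_m1crpc = c(0.1080, 0.1940),
                              p_m1bcr_m1crpc = 0.2055,
                              ci_m1bcr_m1crpc = c(0.1813, 0.2251),
                              excess_death_m0crpc = 0.0413,
                              excess_death_m1bcr = 0.1306,
                              excess_death_m1crpc = 0.2933) {
  out <- list(
    p_m0bcr_m1bcr = p_m0bcr_m1bcr, ci_m0bcr_m1bcr = ci_m0bcr_m1bcr,
    p_m0bcr_m0crpc = p_m0bcr_m0crpc, ci_m0bcr_m0crpc = ci_m0bcr_m0crpc,
    p_m0crpc_m1crpc = p_m0crpc_m1crpc, ci_m0crpc_m1crpc = ci_m0crpc_m1crpc,
    p_m1bcr_m1crpc = p_m1bcr_m1crpc, ci_m1bcr_m1crpc = ci_m1bcr_m1crpc,
    excess_death_m0crpc = excess_death_m0crpc,
    excess_death_m1bcr = excess_death_m1bcr,
    excess_death_m1crpc = excess_death_m1crpc)
  for (nm in c("p_m0bcr_m1bcr", "p_m0bcr_m0crpc", "p_m0crpc_m1crpc",
               "p_m1bcr_m1crpc", "excess_death_m0crpc", "excess_death_m1bcr",
               "excess_death_m1crpc")) {
    .chk_prob(out[[nm]], nm)
  }
  for (nm in c("m0bcr_m1bcr", "m0bcr_m0crpc", "m0crpc_m1crpc",
               "m1bcr_m1crpc")) {
    ci <- out[[paste0("ci_", nm)]]
    .chk_prob(ci[1L], paste0("ci_", nm, "[1]"))
    .chk_prob(ci[2L], paste0("ci_", nm, "[2]"))
    .chk_ci(out[[paste0("p_", nm)]], ci[1L], ci[2L], paste0("p_", nm))
  }
  structure(out, class = "transition_params")
}

#' Health-state utilities
#'
#' Quality-of-life weights in `[0, 1]` per health state, with standard
#' deviations used by the sensitivity analyses. Death has utility 0.
#'
#' @param u_m0bcr,u_m1bcr,u_m0crpc,u_m1crpc State utilities.
#' @param sd_m0bcr,sd_m1bcr,sd_m0crpc,sd_m1crpc Their standard deviations.
#' @return An object of class `utility_set`.
#' @export
utility_set <- function(u_m0bcr = 0.89, sd_m0bcr = 0.14,
                        u_m1bcr = 0.74, sd_m1bcr = 0.27,
                        u_m0crpc = 0.86, sd_m0crpc = 0.17,
                        u_m1crpc = 0.83, sd_m1crpc = 0.13) {
  out <- list(u_m0bcr = u_m0bcr, sd_m0bcr = sd_m0bcr,
              u_m1bcr = u_m1bcr, sd_m1bcr = sd_m1bcr,
              u_m0crpc = u_m0crpc, sd_m0crpc = sd_m0crpc,
              u_m1crpc = u_m1crpc, sd_m1crpc = sd_m1crpc,
              u_death = 0)
  for (nm in c("u_m0bcr", "u_m1bcr", "u_m0crpc", "u_m1crpc")) {
    .chk_prob(out[[nm]], nm)
  }
  structure(out, class = "utility_set")
}

#' Annual health-state costs
#'
#' Mean annual per-patient management costs in euros, with 95% confidence
#' intervals, plus per-scan imaging production costs by strategy. First-year
#' BCR costs include one-off salvage radiotherapy and apply only in the
#' entry cycle for correctly diagnosed patients.
#'
#' @param m0bcr_first_year,m0bcr_subsequent,m1bcr_first_year,
#'   m1bcr_subsequent,m0crpc_annual,m1crpc_annual Mean annual costs (EUR).
#' @param ci_m0bcr_first_year,ci_m0bcr_subsequent,ci_m1bcr_first_year,
#'   ci_m1bcr_subsequent,ci_m0crpc_annual,ci_m1crpc_annual Length-2 95% CIs.
#' @param imaging_cost Named numeric vector of per-scan production costs.
#' @return An object of class `cost_set`.
#' @export
cost_set <- function(m0bcr_first_year = 3524,
                     ci_m0bcr_first_year = c(2277, 5246),
                     m0bcr_subsequent = 1844,
                     ci_m0bcr_subsequent = c(1354, 2434),
                     m1bcr_first_year = 4816,
                     ci_m1bcr_first_year = c(1615, 9234),
                     m1bcr_subsequent = 4815,
                     ci_m1bcr_subsequent = c(1689, 9308),
                     m0crpc_annual = 5717,
                     ci_m0crpc_annual = c(1634, 11869),
                     m1crpc_annual = 12346,
                     ci_m1crpc_annual = c(3109, 27740),
                     imaging_cost = c(NaF = 302, FCH = 881, `DW-MRI` = 112)) {
  out <- list(
    m0bcr_first_year = m0bcr_first_year,
    ci_m0bcr_first_year = ci_m0bcr_first_year,
    m0bcr_subsequent = m0bcr_subsequent,
    ci_m0bcr_subsequent = ci_m0bcr_subsequent,
    m1bcr_first_year = m1bcr_first_year,
    ci_m1bcr_first_year = ci_m1bcr_first_year,
    m1bcr_subsequent = m1bcr_subsequent,
    ci_m1bcr_subsequent = ci_m1bcr_subsequent,
    m0crpc_annual = m0crpc_annual,
    ci_m0crpc_annual = ci_m0crpc_annual,
    m1crpc_annual = m1crpc_annual,
    ci_m1crpc_annual = ci_m1crpc_annual,
    imaging_cost = imaging_cost)
  for (nm in c("m0bcr_first_year", "m0bcr_subsequent", "m1bcr_first_year",
               "m1bcr_subsequent", "m0crpc_annual", "m1crpc_annual")) {
    if (out[[nm]] < 0) stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)
    ci <- out[[paste0("ci_", nm)]]
    if (any(ci < 0)) stop(sprintf("ci_%s must be >= 0", nm), call. = FALSE)
    .chk_ci(out[[nm]], ci[1L], ci[2L], nm)
  }
  if (any(imaging_cost < 0)) stop("imaging costs must be >= 0", call. = FALSE)
  structure(out, class = "cost_set")
}

#' Cohort run configuration
#'
#' @param start_age Cohort entry age in years (default 70).
#' @param cohort_size Number of simulated patients (default 10,000; results
#'   are reported per patient, so this only sets the trace scale).
#' @param discount_rate Annual discount rate applied to costs and outcomes
#'   (default 0.04).
#' @param terminal_age Life-table closure age bounding the lifetime horizon.
#' @param counting_method Cycle occupancy counting: `"life-table"` (mean of
#'   the occupancies before and after each annual transition; the default of
#'   this model family), `"start"` (occupancy after the transition) or
#'   `"end"` (occupancy before the transition).
#' @param half_year Half-year continuity term used by life-table life
#'   expectancies (affects only [life_expectancy()] comparisons).
#' @param fp_cost_policy Cycle-1 cost attributed to false positives:
#'   `"m0bcr_subsequent"` (m0-BCR costs without first-year salvage
#'   radiotherapy; default) or `"m1bcr_first_year"`.
#' @param fn_cost_policy Cycle-1 cost attributed to false negatives:
#'   `"m0bcr_first_year"` (default) or `"m0bcr_subsequent"`.
#' @param fp_transition_policy Mechanics of the false-positive misdiagnosis
#'   state: `"m1_dynamics"` (m1-BCR transition row, non-progressors remain
#'   in the misdiagnosis state, m1-BCR costs/utility for one cycle only;
#'   default, see vignette), `"m1_state"` (as `"m1_dynamics"` but with
#'   m1-BCR costs and utility throughout the misdiagnosis),
#'   `"m1_row_merge"` (m1-BCR row for one cycle, non-progressors merge into
#'   m0-BCR) or `"m0_row"` (m0-BCR row for one cycle, then merge).
#' @param renormalize Clamp-and-renormalise transition rows whose outflows
#'   exceed 1 (default `FALSE`: such rows are an error).
#' @param seed Base seed recorded with the run.
#' @return An object of class `model_config`.
#' @export
model_config <- function(start_age = 70L,
                         cohort_size = 10000,
                         discount_rate = 0.04,
                         terminal_age = 110L,
                         counting_method = c("life-table", "start", "end"),
                         half_year = TRUE,
                         fp_cost_policy = c("m0bcr_subsequent",
                                            "m1bcr_first_year"),
                         fn_cost_policy = c("m0bcr_first_year",
                                            "m0bcr_subsequent"),
                         fp_transition_policy = c("m1_dynamics", "m1_state",
                                                  "m1_row_merge", "m0_row"),
                         renormalize = FALSE,
                         seed = 1L) {
  counting_method <- match.arg(counting_method)
  fp_cost_policy <- match.arg(fp_cost_policy)
  fn_cost_policy <- match.arg(fn_cost_policy)
  fp_transition_policy <- match.arg(fp_transition_policy)
  if (discount_rate < 0) stop("`discount_rate` must be >= 0", call. = FALSE)
  if (cohort_size <= 0) stop("`cohort_size` must be > 0", call. = FALSE)
  if (terminal_age <= start_age) {
    stop("`terminal_age` must exceed `start_age`", call. = FALSE)
  }
  structure(list(start_age = as.integer(start_age),
                 cohort_size = cohort_size,
                 discount_rate = discount_rate,
                 terminal_age = as.integer(terminal_age),
                 counting_method = counting_method,
                 half_year = half_year,
                 fp_cost_policy = fp_cost_policy,
                 fn_cost_policy = fn_cost_policy,
                 fp_transition_policy = fp_transition_policy,
                 renormalize = renormalize,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Imaging strategy
#'
#' A named diagnostic strategy characterised by its sensitivity, specificity
#' and per-scan imaging cost.
#'
#' @param name Strategy label.
#' @param se,sp Sensitivity and specificity in `[0, 1]`.
#' @param imaging_cost Per-scan cost (EUR), added once at model entry.
#' @return An object of class `strategy`.
#' @export
strategy <- function(name, se, sp, imaging_cost = 0) {
  .chk_prob(se, "se")
  .chk_prob(sp, "sp")
  if (imaging_cost < 0) stop("`imaging_cost` must be >= 0", call. = FALSE)
  structure(list(name = as.character(name), se = se, sp = sp,
                 imaging_cost = imaging_cost),
            class = "strategy")
}

# Trial confusion counts per modality and reading (2x2 cells among the
# 7 metastatic / 48 non-metastatic patients of the diagnostic trial).
.trial_counts <- list(
  onsite = list(
    `NaF` = c(tp = 5, fn = 2, tn = 44, fp = 4),
    `FCH` = c(tp = 3, fn = 4, tn = 48, fp = 0),
    `DW-MRI` = c(tp = 4, fn = 3, tn = 40, fp = 8)),
  central = list(
    `NaF` = c(tp = 6, fn = 1, tn = 45, fp = 3),
    `FCH` = c(tp = 4, fn = 3, tn = 47, fp = 1),
    `DW-MRI` = c(tp = 3, fn = 4, tn = 45, fp = 3)))

#' Trial confusion counts per modality for a reading
#'
#' The observed 2x2 cell counts (tp, fn, tn, fp) per imaging modality among
#' the 55 trial patients (7 with bone metastases), for either the on-site or
#' the central expert reading.
#'
#' @param reading `"onsite"` or `"central"`.
#' @return Named list of `confusion_counts`.
#' @export
default_trial_counts <- function(reading = c("onsite", "central")) {
  reading <- match.arg(reading)
  lapply(.trial_counts[[reading]], function(x) {
    confusion_counts(tp = x["tp"], fp = x["fp"], fn = x["fn"], tn = x["tn"])
  })
}

#' Default imaging strategies for a reading
#'
#' Builds the three imaging strategies (NaF PET/CT, FCH PET/CT, DW-MRI) with
#' sensitivities/specificities taken from the trial confusion counts for the
#' chosen reading and the per-scan production costs.
#'
#' @param reading `"onsite"` or `"central"`.
#' @param costs A [cost_set()] supplying `imaging_cost`.
#' @return Named list of [strategy()] objects.
#' @export
default_strategies <- function(reading = c("onsite", "central"),
                               costs = cost_set()) {
  reading <- match.arg(reading)
  cc <- .trial_counts[[reading]]
  out <- lapply(names(cc), function(nm) {
    x <- cc[[nm]]
    strategy(nm,
             se = unname(x["tp"] / (x["tp"] + x["fn"])),
             sp = unname(x["tn"] / (x["tn"] + x["fp"])),
             imaging_cost = unname(costs$imaging_cost[[nm]]))
  })
  names(out) <- names(cc)
  out
}

#' Trial bone-metastasis prevalence
#'
#' @return 7/55, the proportion of trial patients with at least one bone
#'   metastasis.
#' @export
default_prevalence <- function() 7 / 55
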