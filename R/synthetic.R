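# Synthetic inputs: a diagnostic-trial generator, gamma-distributed annual
# cost logs, and Gompertz life tables standing in for national mortality.

#' Specification of a synthetic diagnostic trial
#'
#' Defaults emulate the source trial: 55 patients, 12.7% (7/55)
#' bone-metastasis prevalence, three imaging modalities each read on-site
#' and centrally at the observed sensitivities/specificities.
#'
#' @param n_patients Number of patients.
#' @param prevalence Proportion with bone metastases; in `exact_counts` mode
#'   `prevalence * n_patients` must be an integer.
#' @param accuracy Nested list `accuracy[[modality]][[reading]] = c(se, sp)`.
#' @param mode `"exact_counts"` (deterministic, reproduces the implied 2x2
#'   counts) or `"sampled"` (Bernoulli draws given truth).
#' @param seed RNG seed used by `"sampled"` mode.
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(n_patients = 55L,
                       prevalence = 7 / 55,
                       accuracy = default_trial_accuracy(),
                       mode = c("exact_counts", "sampled"),
                       seed = 1L) {
  mode <- match.arg(mode)
  for (mod in names(accuracy)) {
    for (rd in names(accuracy[[mod]])) {
      a <- accuracy[[mod]][[rd]]
      .chk_prob(a[["se"]], sprintf("se[%s,%s]", mod, rd))
      .chk_prob(a[["sp"]], sprintf("sp[%s,%s]", mod, rd))
    }
  }
  n_pos <- prevalence * n_patients
  if (mode == "exact_counts" && abs(n_pos - round(n_pos)) > 1e-9) {
    stop("prevalence * n_patients must be integral in exact_counts mode",
         call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 prevalence = prevalence, accuracy = accuracy,
                 mode = mode, seed = as.integer(seed)),
            class = "trial_spec")
}

#' Observed trial accuracies per modality and reading
#'
#' @return Nested list `[[modality]][[reading]] = c(se, sp)` built from the
#'   trial confusion counts.
#' @export
default_trial_accuracy <- function() {
  out <- list()
  for (rd in c("onsite", "central")) {
    for (mod in names(.trial_counts[[rd]])) {
      x <- .trial_counts[[rd]][[mod]]
      out[[mod]][[rd]] <- c(se = unname(x["tp"] / (x["tp"] + x["fn"])),
                            sp = unname(x["tn"] / (x["tn"] + x["fp"])))
    }
  }
  out
}

#' Generate a synthetic diagnostic trial
#'
#' In `exact_counts` mode the implied 2x2 counts per (modality, reading) are
#' reproduced deterministically: truth-positive patients come first and
#' calls are assigned by a greedy fill in patient-index order, so
#' per-modality marginals match exactly. The joint assignment across
#' modalities is underdetermined by marginals alone, so cross-modality
#' statistics on exact-count data are fixture-dependent. In `sampled` mode,
#' truth is Bernoulli(prevalence) and calls are conditionally independent
#' Bernoulli(se) / Bernoulli(1 - sp) given truth.
#'
#' @param spec A [trial_spec()].
#' @return A `paired_readings` data frame (see [as_paired_readings()]).
#' @export
generate_trial <- function(spec = trial_spec()) {
  stopifnot(inherits(spec, "trial_spec"))
  n <- spec$n_patients
  df <- data.frame(patient_id = seq_len(n))
  if (spec$mode == "exact_counts") {
    n_pos <- as.integer(round(spec$prevalence * n))
    df$truth <- as.integer(seq_len(n) <= n_pos)
    n_neg <- n - n_pos
    for (mod in names(spec$accuracy)) {
      for (rd in names(spec$accuracy[[mod]])) {
        a <- spec$accuracy[[mod]][[rd]]
        tp <- a[["se"]] * n_pos
        fp <- (1 - a[["sp"]]) * n_neg
        if (abs(tp - round(tp)) > 1e-9 || abs(fp - round(fp)) > 1e-9) {
          stop(sprintf(
            "accuracies of %s/%s do not yield integer counts for n = %d",
            mod, rd, n), call. = FALSE)
        }
        call <- integer(n)
        call[seq_len(round(tp))] <- 1L                 # first positives
        call[n_pos + seq_len(round(fp))] <- 1L         # first negatives
        df[[paste0("call_", mod, "_", rd)]] <- call
      }
    }
  } else {
    set.seed(spec$seed)
    df$truth <- stats::rbinom(n, 1L, spec$prevalence)
    if (spec$prevalence == 0) {
      warning("prevalence is 0: no positive-truth patients, ",
              "sensitivity is undefined", call. = FALSE)
    }
    for (mod in names(spec$accuracy)) {
      for (rd in names(spec$accuracy[[mod]])) {
        a <- spec$accuracy[[mod]][[rd]]
        p_call <- ifelse(df$truth == 1L, a[["se"]], 1 - a[["sp"]])
        df[[paste0("call_", mod, "_", rd)]] <- stats::rbinom(n, 1L, p_call)
      }
    }
  }
  as_paired_readings(df)
}

#' Confusion counts of one modality/reading in a readings table
#'
#' @param readings A `paired_readings` object.
#' @param modality,reading Labels selecting the `call_<modality>_<reading>`
#'   column.
#' @return A [confusion_counts()].
#' @export
count_readings <- function(readings, modality, reading) {
  col <- paste0("call_", modality, "_", reading)
  if (!col %in% names(readings)) {
    stop(sprintf("column `%s` not found", col), call. = FALSE)
  }
  call <- readings[[col]]
  truth <- readings$truth
  confusion_counts(tp = sum(truth == 1 & call == 1),
                   fp = sum(truth == 0 & call == 1),
                   fn = sum(truth == 1 & call == 0),
                   tn = sum(truth == 0 & call == 0))
}

#' Write a paired-readings table to a delimited file
#'
#' @param readings A `paired_readings` object.
#' @param path Output path (comma-separated).
#' @return `path`, invisibly.
#' @export
write_readings <- function(readings, path) {
  utils::write.table(as.data.frame(readings), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a gamma-distributed annual cost log
#'
#' Draws from a gamma distribution moment-matched to `mean` and
#' `SD = (ci[2] - ci[1]) / 3.92` (the symmetric 95% CI width convention used
#' by the probabilistic sensitivity analysis). A degenerate CI returns a
#' constant log.
#'
#' @param mean Mean annual cost (EUR).
#' @param ci Length-2 95% confidence interval.
#' @param n Number of draws.
#' @param seed RNG seed.
#' @return Numeric vector of `n` non-negative costs.
#' @export
generate_cost_log <- function(mean, ci, n, seed = 1L) {
  if (!(ci[1L] <= mean && mean <= ci[2L])) {
    stop("CI must bracket the mean", call. = FALSE)
  }
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  s <- (ci[2L] - ci[1L]) / 3.92
  if (s == 0) return(rep(mean, n))
  set.seed(seed)
  stats::rgamma(n, shape = mean^2 / s^2, rate = mean / s^2)
}

#' Gompertz life table
#'
#' Builds a period life table from a Gompertz hazard
#' `mu(x) = a * exp(b * x)`:
#' `qx(x) = 1 - exp(-(a / b) * (exp(b (x + 1)) - exp(b x)))` for `b > 0`,
#' constant `qx = 1 - exp(-a)` for `b = 0`. The default parameters
#' (`a = 2.5e-5`, `b = 0.095`) give a residual life expectancy at age 70 in
#' the 12-16-year range typical of a low-mortality male population; this is
#' a fixture standing in for a national period table, not an estimate of
#' any country's mortality.
#'
#' @param a Baseline hazard per year (`> 0`).
#' @param b Log-hazard slope per year (`>= 0`).
#' @param ages Integer ages to tabulate (default `0:110`).
#' @param terminal_age Closure age (default `max(ages)`).
#' @return A [life_table()].
#' @export
gompertz_life_table <- function(a = 2.5e-5, b = 0.095, ages = 0:110,
                                terminal_age = max(ages)) {
  if (a <= 0) stop("`a` must be > 0", call. = FALSE)
  if (b < 0) stop("`b` must be >= 0", call. = FALSE)
  qx <- if (b == 0) {
    rep(-expm1(-a), length(ages))
  } else {
    -expm1(-(a / b) * (exp(b * (ages + 1)) - exp(b * ages)))
  }
  life_table(ages, qx, terminal_age = terminal_age)
}
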