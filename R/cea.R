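# Decision outputs: ICERs, efficiency frontier with strict and extended
# dominance, net monetary benefit, cost-effectiveness acceptability curves.

#' Incremental cost-effectiveness ratio
#'
#' `(cost_b - cost_a) / (qalys_b - qalys_a)`, in EUR per QALY gained. A zero
#' QALY difference returns `NA` (undefined ICER; the caller decides
#' dominance). A negative ICER flags a dominance situation.
#'
#' @param a,b `strategy_result` objects (or lists with `cost` and `qalys`),
#'   `a` the comparator.
#' @return EUR per QALY, or `NA` when the QALY difference is zero.
#' @export
icer <- function(a, b) {
  dq <- b$qalys - a$qalys
  if (dq == 0) return(NA_real_)
  (b$cost - a$cost) / dq
}

#' Efficiency frontier with strict and extended dominance
#'
#' Sorts strategies by ascending QALYs (ties by ascending cost), removes
#' strictly dominated strategies (at least as costly and no more effective
#' than another, with one inequality strict), then iteratively removes
#' extended-dominated strategies until the frontier ICERs strictly increase.
#' Strategies tied on both cost and QALYs are kept with an undefined ICER
#' between them.
#'
#' @param results Named list of `strategy_result` objects.
#' @return A data frame of class `efficiency_frontier` with columns
#'   `strategy`, `qalys`, `cost`, `status` (`on_frontier`, `dominated`,
#'   `extended_dominated`) and `icer` (vs the previous frontier member;
#'   `NA` for the cheapest member).
#' @export
efficiency_frontier <- function(results) {
  if (length(results) < 1L) stop("no results supplied", call. = FALSE)
  nms <- names(results)
  if (is.null(nms)) nms <- vapply(results, function(r) r$name, "")
  df <- data.frame(strategy = nms,
                   qalys = vapply(results, function(r) r$qalys, 0),
                   cost = vapply(results, function(r) r$cost, 0),
                   stringsAsFactors = FALSE)
  df <- df[order(df$qalys, df$cost), , drop = FALSE]
  n <- nrow(df)
  df$status <- "on_frontier"

  # strict dominance against any other strategy
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$cost[j] <= df$cost[i] && df$qalys[j] >= df$qalys[i] &&
          (df$cost[j] < df$cost[i] || df$qalys[j] > df$qalys[i])) {
        df$status[i] <- "dominated"
        break
      }
    }
  }

  # extended dominance: iterative ICER-monotonicity sweep over the survivors
  repeat {
    idx <- which(df$status == "on_frontier")
    if (length(idx) < 3L) break
    removed <- FALSE
    for (m in seq_len(length(idx) - 2L)) {
      i <- idx[m]; j <- idx[m + 1L]; k <- idx[m + 2L]
      icer_ji <- (df$cost[j] - df$cost[i]) / (df$qalys[j] - df$qalys[i])
      icer_ki <- (df$cost[k] - df$cost[i]) / (df$qalys[k] - df$qalys[i])
      if (is.finite(icer_ji) && is.finite(icer_ki) && icer_ji >= icer_ki) {
        df$status[j] <- "extended_dominated"
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  df$icer <- NA_real_
  idx <- which(df$status == "on_frontier")
  if (length(idx) > 1L) {
    for (m in seq_along(idx)[-1L]) {
      i <- idx[m - 1L]; j <- idx[m]
      dq <- df$qalys[j] - df$qalys[i]
      df$icer[j] <- if (dq == 0) NA_real_ else (df$cost[j] - df$cost[i]) / dq
    }
  }
  rownames(df) <- NULL
  class(df) <- c("efficiency_frontier", "data.frame")
  df
}

#' Net monetary benefit
#'
#' @param result A `strategy_result` (or list with `cost`, `qalys`).
#' @param lambda Willingness-to-pay threshold (EUR per QALY), `>= 0`;
#'   vectorised.
#' @return `lambda * qalys - cost` in EUR.
#' @export
nmb <- function(result, lambda) {
  if (any(lambda < 0)) stop("`lambda` must be >= 0", call. = FALSE)
  lambda * result$qalys - result$cost
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay threshold, the fraction of probabilistic
#' draws in which each strategy attains the highest net monetary benefit
#' (ties split equally).
#'
#' @param psa_draws Data frame with columns `iteration`, `strategy`, `cost`,
#'   `qalys` (as produced by [run_psa()]'s `draws` element).
#' @param lambdas Threshold grid in EUR per QALY (default 0 to 20,000 by
#'   100).
#' @return Data frame of class `ceac` with columns `lambda`, `strategy`,
#'   `probability`; probabilities sum to 1 at each lambda.
#' @export
ceac <- function(psa_draws, lambdas = seq(0, 20000, by = 100)) {
  need <- c("iteration", "strategy", "cost", "qalys")
  if (!all(need %in% names(psa_draws))) {
    stop("`psa_draws` must have columns iteration, strategy, cost, qalys",
         call. = FALSE)
  }
  if (nrow(psa_draws) == 0L) stop("empty PSA draw set", call. = FALSE)
  strategies <- sort(unique(psa_draws$strategy))
  iters <- unique(psa_draws$iteration)
  tab <- table(psa_draws$iteration, psa_draws$strategy)
  if (any(tab != 1L)) {
    stop("every draw must contain every strategy exactly once", call. = FALSE)
  }
  # iterations x strategies matrices
  o <- order(psa_draws$iteration, psa_draws$strategy)
  cost <- matrix(psa_draws$cost[o], nrow = length(iters), byrow = TRUE,
                 dimnames = list(NULL, strategies))
  qaly <- matrix(psa_draws$qalys[o], nrow = length(iters), byrow = TRUE,
                 dimnames = list(NULL, strategies))
  out <- lapply(lambdas, function(l) {
    b <- l * qaly - cost
    best <- b == apply(b, 1L, max)
    share <- best / rowSums(best)
    data.frame(lambda = l, strategy = strategies,
               probability = colMeans(share), row.names = NULL)
  })
  out <- do.call(rbind, out)
  class(out) <- c("ceac", "data.frame")
  out
}
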