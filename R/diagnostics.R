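# Diagnostic accuracy from 2x2 counts and paired comparisons of modalities:
# Cochran Q over correctness indicators, McNemar post hoc, Cohen's kappa.

#' 2x2 diagnostic confusion counts
#'
#' @param tp,fp,fn,tn Non-negative integer patient counts (true positive,
#'   false positive, false negative, true negative against the standard of
#'   truth).
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  x <- c(tp = as.numeric(tp)[1L], fp = as.numeric(fp)[1L],
         fn = as.numeric(fn)[1L], tn = as.numeric(tn)[1L])
  if (anyNA(x)) stop("counts must be numeric", call. = FALSE)
  if (any(x < 0) || any(x != floor(x))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(x) == 0) stop("all counts are zero", call. = FALSE)
  structure(as.list(x), class = "confusion_counts")
}

.cp_interval <- function(k, n, conf = 0.95) {
  # Clopper-Pearson exact interval; chosen over Wilson because the positive
  # class is tiny (n = 7 in the trial).
  if (is.na(k) || n == 0) return(c(NA_real_, NA_real_))
  a <- 1 - conf
  lo <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  c(lo, hi)
}

#' Diagnostic accuracy statistics from confusion counts
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' values and overall accuracy, each with an exact (Clopper-Pearson) 95%
#' confidence interval. Undefined denominators (e.g. PPV with no positive
#' calls) are reported as `NA`, not zero.
#'
#' @param cc A [confusion_counts()].
#' @param conf Confidence level (default 0.95).
#' @return An object of class `diagnostic_accuracy`: a list with elements
#'   `se`, `sp`, `ppv`, `npv`, `acc`, each a list of `est`, `lo`, `hi`, `k`,
#'   `n`.
#' @export
accuracy_from_counts <- function(cc, conf = 0.95) {
  stopifnot(inherits(cc, "confusion_counts"))
  stat <- function(k, n) {
    est <- if (n > 0) k / n else NA_real_
    ci <- .cp_interval(k, n, conf)
    list(est = est, lo = ci[1L], hi = ci[2L], k = k, n = n)
  }
  n <- cc$tp + cc$fp + cc$fn + cc$tn
  if (cc$tp + cc$fn == 0 || cc$tn + cc$fp == 0) {
    stop("need at least one positive and one negative truth patient",
         call. = FALSE)
  }
  structure(list(
    se = stat(cc$tp, cc$tp + cc$fn),
    sp = stat(cc$tn, cc$tn + cc$fp),
    ppv = stat(cc$tp, cc$tp + cc$fp),
    npv = stat(cc$tn, cc$tn + cc$fn),
    acc = stat(cc$tp + cc$tn, n)), class = "diagnostic_accuracy")
}

#' @export
print.diagnostic_accuracy <- function(x, ...) {
  for (nm in names(x)) {
    s <- x[[nm]]
    cat(sprintf("%-4s %5.1f%% (%d/%d) [%.1f%%, %.1f%%]\n", nm,
                100 * s$est, s$k, s$n, 100 * s$lo, 100 * s$hi))
  }
  invisible(x)
}

#' Read patient-level paired readings from a delimited file
#'
#' One row per patient; columns `patient_id`, `truth` (0/1 bone-metastasis
#' status per the standard of truth) and one `call_<modality>_<reading>`
#' binary column per modality/reading pair.
#'
#' @param path Path to a comma- or tab-separated file.
#' @return A `paired_readings` data frame with attributes `modalities` and
#'   `readings`.
#' @export
read_readings <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_paired_readings(df)
}

#' Validate a paired-readings data frame
#'
#' @param df Data frame with `patient_id`, `truth` and `call_*_*` columns.
#' @return The validated `paired_readings` object.
#' @export
as_paired_readings <- function(df) {
  if (!all(c("patient_id", "truth") %in% names(df))) {
    stop("need `patient_id` and `truth` columns", call. = FALSE)
  }
  calls <- grep("^call_", names(df), value = TRUE)
  if (length(calls) == 0L) stop("no `call_*` columns found", call. = FALSE)
  parts <- strsplit(sub("^call_", "", calls), "_")
  if (any(lengths(parts) != 2L)) {
    stop("call columns must be named call_<modality>_<reading>", call. = FALSE)
  }
  for (col in c("truth", calls)) {
    v <- df[[col]]
    if (anyNA(v) || !all(v %in% c(0, 1))) {
      stop(sprintf("column `%s` must be binary with no missing values", col),
           call. = FALSE)
    }
  }
  attr(df, "modalities") <- unique(vapply(parts, `[`, "", 1L))
  attr(df, "readings") <- unique(vapply(parts, `[`, "", 2L))
  class(df) <- c("paired_readings", "data.frame")
  df
}

#' Per-modality correctness indicators for one reading
#'
#' @param readings A `paired_readings` object.
#' @param reading Reading label (e.g. `"onsite"`).
#' @return Binary matrix, patients x modalities; 1 where the call equals the
#'   truth.
#' @export
correctness_matrix <- function(readings, reading) {
  mods <- attr(readings, "modalities")
  cols <- paste0("call_", mods, "_", reading)
  miss <- setdiff(cols, names(readings))
  if (length(miss)) {
    stop(sprintf("missing call columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  m <- sapply(cols, function(cl) as.integer(readings[[cl]] == readings$truth))
  colnames(m) <- mods
  m
}

#' Cochran Q test over matched binary outcomes
#'
#' Compares k >= 3 matched proportions; here the per-patient correctness
#' indicators of the imaging modalities under one reading. When every row is
#' concordant the statistic is 0 with p = 1 by convention.
#'
#' @param x Binary matrix, subjects x treatments (or a `paired_readings`
#'   object, in which case `reading` selects the correctness matrix).
#' @param reading Reading label when `x` is a `paired_readings` object.
#' @return List with `statistic`, `df`, `p.value`, `k`, `n`.
#' @export
cochran_q <- function(x, reading = NULL) {
  if (inherits(x, "paired_readings")) {
    x <- correctness_matrix(x, reading)
  }
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least two treatments", call. = FALSE)
  if (!all(x %in% c(0, 1))) stop("matrix must be binary", call. = FALSE)
  k <- ncol(x)
  cj <- colSums(x)
  ri <- rowSums(x)
  denom <- k * sum(ri) - sum(ri^2)
  if (denom == 0) {
    q <- 0
    p <- 1
  } else {
    q <- k * (k - 1) * sum((cj - mean(cj))^2) / denom
    p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  }
  list(statistic = q, df = k - 1L, p.value = p, k = k, n = nrow(x))
}

#' McNemar test on paired binary vectors
#'
#' Chi-square (without continuity correction) on the discordant counts, or
#' an exact binomial test when the discordant total is below `exact_below`.
#' No discordant pairs gives p = 1 by convention.
#'
#' @param a,b Equal-length binary vectors (e.g. correctness indicators of
#'   two modalities).
#' @param exact_below Use the exact binomial test when `b01 + b10` is below
#'   this threshold (default 25); set to 0 to force the asymptotic test.
#' @return List with `statistic` (chi-square, `NA` for the exact branch),
#'   `p.value`, `b01`, `b10`, `method`.
#' @export
mcnemar <- function(a, b, exact_below = 25L) {
  if (length(a) != length(b)) stop("vectors must have equal length",
                                   call. = FALSE)
  if (!all(c(a, b) %in% c(0, 1))) stop("vectors must be binary", call. = FALSE)
  b01 <- sum(a == 0 & b == 1)
  b10 <- sum(a == 1 & b == 0)
  nd <- b01 + b10
  if (nd == 0) {
    return(list(statistic = 0, p.value = 1, b01 = b01, b10 = b10,
                method = "none discordant"))
  }
  if (nd < exact_below) {
    p <- min(1, 2 * stats::pbinom(min(b01, b10), nd, 0.5))
    list(statistic = NA_real_, p.value = p, b01 = b01, b10 = b10,
         method = "exact binomial")
  } else {
    stat <- (b01 - b10)^2 / nd
    list(statistic = stat,
         p.value = stats::pchisq(stat, 1, lower.tail = FALSE),
         b01 = b01, b10 = b10, method = "chi-square")
  }
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement between two paired binary call vectors (e.g.
#' on-site vs central reading of one modality). When both raters are
#' constant and equal, chance agreement is 1 and kappa is reported as 1 with
#' attribute `degenerate = TRUE`.
#'
#' @param r1,r2 Equal-length binary vectors.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(r1, r2) {
  if (length(r1) != length(r2)) stop("vectors must have equal length",
                                     call. = FALSE)
  if (!all(c(r1, r2) %in% c(0, 1))) stop("vectors must be binary",
                                         call. = FALSE)
  n <- length(r1)
  po <- mean(r1 == r2)
  p1 <- mean(r1)
  p2 <- mean(r2)
  pe <- p1 * p2 + (1 - p1) * (1 - p2)
  if (pe >= 1) {
    return(structure(1, degenerate = TRUE))
  }
  (po - pe) / (1 - pe)
}
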