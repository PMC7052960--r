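# Period life tables: validation, lookup, residual life expectancy.

#' Construct a period life table
#'
#' A life table holds, for each integer age, the annual probability `qx` of
#' dying within the year `[age, age + 1)`. The table is closed at
#' `terminal_age`: `qx` is forced to 1 there so every cohort run has a finite
#' horizon.
#'
#' @param age Integer vector of contiguous, strictly increasing ages.
#' @param qx Numeric vector of annual death probabilities in `[0, 1]`.
#' @param terminal_age Closure age; a row with `qx = 1` is appended (or
#'   enforced) at this age. Defaults to `max(age)`.
#'
#' @return An object of class `life_table`: a data frame with columns `age`
#'   and `qx` and attribute `terminal_age`.
#' @export
#' @examples
#' lt <- life_table(age = 60:100, qx = seq(0.01, 0.4, length.out = 41))
#' death_prob(lt, 70)
#' life_expectancy(lt, 70)
life_table <- function(age, qx, terminal_age = NULL) {
  if (length(age) != length(qx)) {
    stop("`age` and `qx` must have the same length", call. = FALSE)
  }
  if (length(age) == 0L) stop("life table is empty", call. = FALSE)
  if (anyNA(age) || anyNA(qx)) {
    bad <- which(is.na(age) | is.na(qx))[1L]
    stop(sprintf("non-numeric or missing cell in life table row %d", bad),
         call. = FALSE)
  }
  if (any(age != floor(age))) {
    stop("ages must be integers", call. = FALSE)
  }
  o <- order(age)
  age <- as.integer(age[o])
  qx <- as.numeric(qx[o])
  if (anyDuplicated(age)) {
    stop(sprintf("duplicate age %d in life table", age[anyDuplicated(age)]),
         call. = FALSE)
  }
  if (any(diff(age) != 1L)) {
    gap <- age[which(diff(age) != 1L)[1L]]
    stop(sprintf("ages must be contiguous; gap after age %d", gap),
         call. = FALSE)
  }
  bad <- which(qx < 0 | qx > 1)
  if (length(bad)) {
    stop(sprintf("qx = %g at age %d outside [0, 1]", qx[bad[1L]], age[bad[1L]]),
         call. = FALSE)
  }
  if (is.null(terminal_age)) terminal_age <- max(age)
  terminal_age <- as.integer(terminal_age)
  if (terminal_age < max(age)) {
    stop("`terminal_age` must be at least the last tabulated age", call. = FALSE)
  }
  if (terminal_age > max(age)) {
    ext <- seq.int(max(age) + 1L, terminal_age)
    age <- c(age, ext)
    qx <- c(qx, rep(qx[length(qx)], length(ext)))
  }
  qx[length(qx)] <- 1  # table closure
  out <- data.frame(age = age, qx = qx)
  attr(out, "terminal_age") <- terminal_age
  class(out) <- c("life_table", "data.frame")
  out
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> ages %d-%d (closure qx = 1 at %d)\n",
              min(x$age), max(x$age), attr(x, "terminal_age")))
  invisible(x)
}

#' Read a life table from a delimited text file
#'
#' The file must have a header naming an `age` column and a `qx` column
#' (comma- or tab-separated; extra metadata columns such as `year` or `sex`
#' are ignored). A closure row with `qx = 1` is appended at `terminal_age`
#' when absent.
#'
#' @param path Path to the file.
#' @param terminal_age Closure age (default 110).
#' @return A [life_table()].
#' @export
#' @examples
#' # bundled synthetic Gompertz table (a stand-in for a national table)
#' path <- system.file("extdata", "gompertz_male_lifetable_synthetic.csv",
#'                     package = "imgcea")
#' lt <- load_life_table(path)
#' life_expectancy(lt, 70)
load_life_table <- function(path, terminal_age = 110L) {
  if (!file.exists(path)) {
    stop(sprintf("life table file not found: '%s'", path), call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  names(df) <- tolower(names(df))
  if (!all(c("age", "qx") %in% names(df))) {
    stop("life table file must have `age` and `qx` columns", call. = FALSE)
  }
  age <- suppressWarnings(as.numeric(df$age))
  qx <- suppressWarnings(as.numeric(df$qx))
  if (anyNA(age) || anyNA(qx)) {
    bad <- which(is.na(age) | is.na(qx))[1L]
    stop(sprintf("non-numeric cell in life table row %d of '%s'", bad, path),
         call. = FALSE)
  }
  life_table(age, qx, terminal_age = max(terminal_age, max(age)))
}

#' Write a life table to a delimited text file
#'
#' @param lt A [life_table()].
#' @param path Output path; `.tsv` extension selects tab separation,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(as.data.frame(lt)[, c("age", "qx")], path,
                     sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Annual death probability at an age
#'
#' Looks up `qx` at `floor(age)`; ages beyond the closure age return 1.
#'
#' @param lt A [life_table()].
#' @param age Age in years (vectorised).
#' @return Probability of death within one year.
#' @export
death_prob <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  age <- floor(age)
  if (any(age < lt$age[1L])) {
    stop(sprintf("age %g below first tabulated age %d", min(age), lt$age[1L]),
         call. = FALSE)
  }
  idx <- match(pmin(age, attr(lt, "terminal_age")), lt$age)
  out <- lt$qx[idx]
  out[age > attr(lt, "terminal_age")] <- 1
  out
}

#' Residual life expectancy from a life table
#'
#' Computes the curtate expectation `e(age) = sum_k S(k)` with
#' `S(k) = prod_{j<k} (1 - qx(age + j))`, plus a half-year continuity
#' correction when `half_year = TRUE` (the default), the usual adjustment
#' for deaths occurring mid-year.
#'
#' @param lt A [life_table()].
#' @param age Starting age (integer years).
#' @param half_year Add the 0.5-year continuity term?
#' @return Expected remaining years of life.
#' @export
life_expectancy <- function(lt, age, half_year = TRUE) {
  stopifnot(inherits(lt, "life_table"))
  age <- as.integer(age)
  if (age < lt$age[1L] || age > attr(lt, "terminal_age")) {
    stop("age outside life table", call. = FALSE)
  }
  q <- lt$qx[lt$age >= age]
  s <- cumprod(1 - q)
  sum(s) + if (half_year) 0.5 else 0
}
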