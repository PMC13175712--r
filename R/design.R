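#' Define a robust-design sampling layout
#'
#' A robust-design study consists of `n_primary` primary periods (typically
#' years), between which the population is open to mortality and temporary
#' emigration, each containing a number of secondary occasions (sampling
#' events within a season) during which the population is assumed closed.
#'
#' @param n_primary Number of primary periods (>= 1).
#' @param secondaries Integer vector of length `n_primary`: number of
#'   secondary occasions within each primary period (each >= 1). A single
#'   value is recycled.
#' @param intervals Elapsed time (in units of the survival probability,
#'   typically years) between consecutive primary periods; length
#'   `n_primary - 1`, all > 0. Defaults to 1 between every pair.
#'
#' @return An object of class `"study_design"`: a list with elements
#'   `n_primary`, `secondaries`, `intervals`, and `n_occasions` (total
#'   number of secondary occasions).
#' @examples
#' study_design(3, c(2, 2, 2))
#' study_design(3, 5, intervals = c(1, 2))
#' @export
study_design <- function(n_primary, secondaries, intervals = NULL) {
  n_primary <- as.integer(n_primary)
  if (length(n_primary) != 1L || is.na(n_primary) || n_primary < 1L)
    stop("`n_primary` must be a single integer >= 1", call. = FALSE)
  if (length(secondaries) == 1L) secondaries <- rep(secondaries, n_primary)
  secondaries <- as.integer(secondaries)
  if (length(secondaries) != n_primary)
    stop("`secondaries` must have one entry per primary period", call. = FALSE)
  if (anyNA(secondaries) || any(secondaries < 1L))
    stop("every `secondaries` entry must be >= 1", call. = FALSE)
  if (is.null(intervals)) intervals <- rep(1, max(n_primary - 1L, 0L))
  intervals <- as.numeric(intervals)
  if (length(intervals) != n_primary - 1L)
    stop("`intervals` must have length `n_primary` - 1", call. = FALSE)
  if (anyNA(intervals) || any(intervals <= 0))
    stop("all `intervals` must be > 0", call. = FALSE)
  structure(
    list(n_primary = n_primary, secondaries = secondaries,
         intervals = intervals, n_occasions = sum(secondaries)),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Robust-design study layout\n")
  cat("  primary periods :", x$n_primary, "\n")
  cat("  secondaries     :", paste(x$secondaries, collapse = ", "), "\n")
  if (x$n_primary > 1L)
    cat("  intervals       :", paste(x$intervals, collapse = ", "), "\n")
  invisible(x)
}

# Map flat occasion columns 1..n_occasions to their primary period.
primary_of_column <- function(design) {
  rep.int(seq_len(design$n_primary), design$secondaries)
}

# Occasion index within its primary period, for each flat column.
occasion_of_column <- function(design) {
  unlist(lapply(design$secondaries, seq_len), use.names = FALSE)
}
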