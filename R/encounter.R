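#' Construct a set of encounter histories
#'
#' The central data object: one row per captured individual, one column per
#' secondary occasion (flattened across primary periods in study order), with
#' binary detections and an optional shell-length covariate. Individuals that
#' were never captured are unobservable and therefore not representable:
#' all-zero rows are rejected.
#'
#' @param detections Binary matrix (or coercible), individuals x occasions;
#'   the number of columns must equal `design$n_occasions`.
#' @param design A [study_design()].
#' @param id Optional unique identifiers (default `"ind1"`, `"ind2"`, ...).
#' @param length_mm Optional per-individual shell length in mm
#'   (anteroposterior axis); positive, `NA` allowed (records lacking length
#'   are rejected only by length-dependent models at fit time).
#' @param site Optional free-text site label.
#'
#' @return An object of class `"encounter_histories"`: a list with elements
#'   `detections` (integer matrix), `design`, `id`, `length_mm`, `site`.
#' @examples
#' d <- study_design(2, c(2, 2))
#' encounter_histories(rbind(c(1, 1, 0, 1), c(0, 1, 0, 0)), d)
#' @export
encounter_histories <- function(detections, design, id = NULL,
                                length_mm = NULL, site = NULL) {
  if (!inherits(design, "study_design"))
    stop("`design` must be a study_design object", call. = FALSE)
  detections <- as.matrix(detections)
  storage.mode(detections) <- "integer"
  if (nrow(detections) > 0 && ncol(detections) != design$n_occasions)
    stop("detections must have ", design$n_occasions,
         " columns to match the design", call. = FALSE)
  if (anyNA(detections) || !all(detections %in% c(0L, 1L)))
    stop("detections must be 0/1 with no missing values", call. = FALSE)
  if (nrow(detections) > 0 && any(rowSums(detections) == 0L))
    stop("all-zero encounter histories are not observable and cannot be ",
         "included", call. = FALSE)
  n <- nrow(detections)
  if (is.null(id)) id <- if (n == 0) character(0) else
    paste0("ind", seq_len(n))
  id <- as.character(id)
  if (length(id) != n) stop("`id` must have one entry per row", call. = FALSE)
  if (anyDuplicated(id)) stop("`id` values must be unique", call. = FALSE)
  if (!is.null(length_mm)) {
    length_mm <- as.numeric(length_mm)
    if (length(length_mm) != n)
      stop("`length_mm` must have one entry per row", call. = FALSE)
    if (any(!is.na(length_mm) & length_mm <= 0))
      stop("`length_mm` must be positive where present", call. = FALSE)
  }
  dimnames(detections) <- NULL
  structure(
    list(detections = detections, design = design, id = id,
         length_mm = length_mm, site = site),
    class = "encounter_histories")
}

#' Number of individuals ever captured
#'
#' Count of distinct captured individuals, written \eqn{M_{t+1}} in the
#' capture-recapture literature; the records of an encounter-history set.
#'
#' @param x An [encounter_histories()] object.
#' @return Integer count.
#' @export
n_captured <- function(x) {
  stopifnot(inherits(x, "encounter_histories"))
  nrow(x$detections)
}

# Distinct individuals detected within each primary period (M_t).
captured_per_primary <- function(x) {
  cp <- collapse_primary(x)
  if (nrow(cp) == 0) return(integer(x$design$n_primary))
  colSums(cp)
}

#' Collapse secondary detections to the primary-period level
#'
#' Returns the per-individual binary detection indicator by primary period:
#' 1 if the individual was detected on at least one secondary occasion of
#' that period. This is the view of the data seen by the open-population
#' (between-year) component of the robust design.
#'
#' @param x An [encounter_histories()] object.
#' @return Integer matrix, individuals x primary periods.
#' @examples
#' d <- study_design(2, c(2, 2))
#' h <- encounter_histories(rbind(c(1, 1, 0, 0), c(0, 1, 0, 1)), d)
#' collapse_primary(h)
#' @export
collapse_primary <- function(x) {
  stopifnot(inherits(x, "encounter_histories"))
  pid <- primary_of_column(x$design)
  out <- vapply(seq_len(x$design$n_primary), function(t) {
    cols <- which(pid == t)
    if (nrow(x$detections) == 0) return(integer(0))
    as.integer(rowSums(x$detections[, cols, drop = FALSE]) > 0L)
  }, integer(nrow(x$detections)))
  if (nrow(x$detections) == 1L) out <- matrix(out, nrow = 1L)
  if (nrow(x$detections) == 0L)
    out <- matrix(integer(0), 0L, x$design$n_primary)
  rownames(out) <- x$id
  out
}

#' @export
print.encounter_histories <- function(x, ...) {
  cat("Encounter histories:", n_captured(x), "individuals,",
      x$design$n_primary, "primary periods (",
      paste(x$design$secondaries, collapse = "+"), "occasions )\n")
  if (!is.null(x$site)) cat("  site:", x$site, "\n")
  if (!is.null(x$length_mm))
    cat("  shell length (mm): median",
        stats::median(x$length_mm, na.rm = TRUE), "\n")
  invisible(x)
}

#' @export
summary.encounter_histories <- function(object, ...) {
  mt <- captured_per_primary(object)
  structure(list(
    n = n_captured(object),
    per_primary = mt,
    total_detections = sum(object$detections),
    design = object$design,
    site = object$site,
    length_mm = object$length_mm
  ), class = "summary.encounter_histories")
}

#' @export
print.summary.encounter_histories <- function(x, ...) {
  cat("Encounter-history summary\n")
  cat("  individuals ever captured (M_t+1):", x$n, "\n")
  cat("  captured per primary period     :",
      paste(x$per_primary, collapse = ", "), "\n")
  cat("  total capture events            :", x$total_detections, "\n")
  invisible(x)
}

#' @export
as.data.frame.encounter_histories <- function(x, ...) {
  design <- x$design
  n <- n_captured(x)
  pid <- primary_of_column(design)
  occ <- occasion_of_column(design)
  k <- design$n_occasions
  data.frame(
    id = rep(x$id, each = k),
    primary = rep(pid, times = n),
    secondary = rep(occ, times = n),
    detected = as.integer(t(x$detections)),
    length_mm = if (is.null(x$length_mm)) NA_real_ else
      rep(x$length_mm, each = k),
    site = if (is.null(x$site)) NA_character_ else x$site,
    stringsAsFactors = FALSE)
}
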