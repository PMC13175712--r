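#' Read a Program MARK encounter-history (.inp) file
#'
#' Parses the MARK interchange dialect: one record per line, a contiguous
#' 0/1 history string whose length equals the total number of secondary
#' occasions, an optional positive integer frequency column, and an optional
#' numeric covariate column interpreted as shell length in mm. Records may be
#' terminated by `";"` or a bare newline; `/* ... */` comments are ignored.
#' Frequencies > 1 are expanded into that many identical individuals.
#'
#' @param path Path to the `.inp` file.
#' @param design A [study_design()] giving the primary/secondary layout;
#'   occasions are contiguous blocks left-to-right in file order.
#' @param site Optional site label attached to the result.
#' @return An [encounter_histories()] object.
#' @seealso [write_inp()]
#' @export
read_inp <- function(path, design, site = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # strip /* ... */ comments (may span lines)
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("/\\*.*?\\*/", "", txt, perl = TRUE)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  k <- design$n_occasions
  hist_rows <- list()
  freq_rows <- integer(0)
  cov_rows <- numeric(0)
  any_cov <- FALSE
  for (ln in seq_along(lines)) {
    raw <- lines[[ln]]
    # one line may hold several ";"-terminated records
    recs <- strsplit(raw, ";", fixed = TRUE)[[1]]
    for (rec in recs) {
      rec <- trimws(rec)
      if (!nzchar(rec)) next
      fields <- strsplit(rec, "[[:space:]]+")[[1]]
      hstr <- fields[[1]]
      if (!grepl("^[01]+$", hstr))
        stop("line ", ln, ": history contains non-binary characters: ",
             hstr, call. = FALSE)
      if (nchar(hstr) != k)
        stop("line ", ln, ": history length ", nchar(hstr),
             " does not match design (", k, " occasions)", call. = FALSE)
      bits <- as.integer(strsplit(hstr, "", fixed = TRUE)[[1]])
      if (sum(bits) == 0L)
        stop("line ", ln, ": all-zero history is not observable",
             call. = FALSE)
      freq <- 1L
      cov <- NA_real_
      if (length(fields) >= 2L) {
        fr <- suppressWarnings(as.numeric(fields[[2]]))
        if (is.na(fr) || fr != round(fr) || fr < 1)
          stop("line ", ln, ": frequency must be a positive integer, got ",
               fields[[2]], call. = FALSE)
        freq <- as.integer(fr)
      }
      if (length(fields) >= 3L) {
        cov <- suppressWarnings(as.numeric(fields[[3]]))
        if (is.na(cov))
          stop("line ", ln, ": covariate is not numeric: ", fields[[3]],
               call. = FALSE)
        any_cov <- TRUE
      }
      if (length(fields) > 3L)
        stop("line ", ln, ": at most one covariate column (shell length) ",
             "is supported", call. = FALSE)
      hist_rows[[length(hist_rows) + 1L]] <- bits
      freq_rows <- c(freq_rows, freq)
      cov_rows <- c(cov_rows, cov)
    }
  }
  if (length(hist_rows) == 0L) {
    return(encounter_histories(matrix(integer(0), 0L, k), design,
                               site = site))
  }
  idx <- rep.int(seq_along(hist_rows), freq_rows)
  det <- do.call(rbind, hist_rows)[idx, , drop = FALSE]
  encounter_histories(
    det, design,
    length_mm = if (any_cov) cov_rows[idx] else NULL,
    site = site)
}

#' Write encounter histories in MARK .inp format
#'
#' Identical (history, length) records are aggregated into a single line with
#' a frequency column; the covariate column is emitted only when lengths are
#' present. Reading the result back with [read_inp()] reproduces the multiset
#' of (detection matrix, covariate) records up to id relabelling.
#'
#' @param x An [encounter_histories()] object.
#' @param path Output path; if `NULL` the text is returned invisibly
#'   without writing.
#' @return Character vector of file lines, invisibly.
#' @export
write_inp <- function(x, path = NULL) {
  stopifnot(inherits(x, "encounter_histories"))
  n <- n_captured(x)
  if (n == 0L) {
    out <- character(0)
  } else {
    hstr <- apply(x$detections, 1L, paste, collapse = "")
    has_cov <- !is.null(x$length_mm)
    key <- if (has_cov) paste(hstr, x$length_mm) else hstr
    first <- !duplicated(key)
    freq <- as.integer(table(factor(key, levels = key[first])))
    if (has_cov) {
      cov_str <- vapply(x$length_mm[first], function(v)
        format(v, trim = TRUE), "")
      out <- sprintf("%s %d %s;", hstr[first], freq, cov_str)
    } else {
      out <- sprintf("%s %d;", hstr[first], freq)
    }
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Read encounter histories from long-format CSV
#'
#' Expected columns: `id`, `primary`, `secondary`, `detected` and optionally
#' `length_mm` and `site`. One row per (individual, occasion); missing
#' (id, occasion) combinations are treated as non-detections.
#'
#' @param path CSV path.
#' @param design Optional [study_design()]; inferred from the maximum
#'   secondary index per primary when omitted.
#' @return An [encounter_histories()] object.
#' @export
read_encounter_csv <- function(path, design = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "primary", "secondary", "detected")
  if (!all(need %in% names(df)))
    stop("CSV must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(design)) {
    tt <- sort(unique(df$primary))
    if (!identical(tt, seq_along(tt))) tt <- seq_len(max(df$primary))
    sec <- vapply(seq_along(tt), function(t)
      max(df$secondary[df$primary == t], 1L), numeric(1))
    design <- study_design(length(tt), as.integer(sec))
  }
  ids <- unique(df$id)
  det <- matrix(0L, length(ids), design$n_occasions)
  offs <- c(0L, cumsum(design$secondaries))
  col <- offs[df$primary] + df$secondary
  det[cbind(match(df$id, ids), col)] <- as.integer(df$detected > 0)
  len <- NULL
  if ("length_mm" %in% names(df)) {
    len <- df$length_mm[match(ids, df$id)]
    if (all(is.na(len))) len <- NULL
  }
  site <- if ("site" %in% names(df)) df$site[[1]] else NULL
  encounter_histories(det, design, id = ids, length_mm = len, site = site)
}

#' Write encounter histories as long-format CSV
#'
#' @param x An [encounter_histories()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_encounter_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
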