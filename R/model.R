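#' Specify a candidate robust-design model
#'
#' A declarative description of one candidate model: which sources of
#' variation enter annual survival and capture probability, whether
#' recapture probability is shared with capture probability (no behavioural
#' response to first handling) or has its own constant value, and the
#' temporary-emigration scenario.
#'
#' Allowed terms, combined additively on the link (logit) scale:
#' * survival `phi`: `~1` (constant), `year` (varies across primary
#'   periods), `length` (individual shell length);
#' * capture `p`: `~1`, `year`, `occasion` (secondary-occasion index within
#'   a primary period, shared across periods), `length`.
#'
#' @param phi Formula for survival, e.g. `~1`, `~year`, `~year + length`.
#' @param p Formula for first-capture probability, e.g. `~occasion + year`.
#' @param recapture `"shared"` (recapture probability equals capture
#'   probability) or `"constant"` (a single separate recapture probability).
#' @param movement Temporary-emigration scenario: `"none"`, `"random"`
#'   (unavailability independent of previous state) or `"markovian"`
#'   (transition probabilities conditioned on the previous availability
#'   state).
#' @return An object of class `"rd_model"`.
#' @examples
#' rd_model()                                  # the null model
#' rd_model(phi = ~year, p = ~occasion + length)
#' @export
rd_model <- function(phi = ~1, p = ~1,
                     recapture = c("shared", "constant"),
                     movement = c("none", "random", "markovian")) {
  recapture <- match.arg(recapture)
  movement <- match.arg(movement)
  phi_terms <- parse_terms(phi, allowed = c("year", "length"), "phi")
  p_terms <- parse_terms(p, allowed = c("occasion", "year", "length"), "p")
  structure(list(phi_terms = phi_terms, p_terms = p_terms,
                 recapture = recapture, movement = movement),
            class = "rd_model")
}

parse_terms <- function(f, allowed, what) {
  if (is.character(f)) {
    # already a term vector (internal use)
    vars <- f
  } else if (inherits(f, "formula")) {
    vars <- all.vars(f)
  } else stop("`", what, "` must be a one-sided formula", call. = FALSE)
  bad <- setdiff(vars, allowed)
  if (length(bad))
    stop("unsupported term(s) for ", what, ": ",
         paste(bad, collapse = ", "), " (allowed: ",
         paste(allowed, collapse = ", "), ")", call. = FALSE)
  # canonical order for deterministic naming
  intersect(allowed, vars)
}

#' @export
format.rd_model <- function(x, ...) {
  fterm <- function(v) if (length(v) == 0) "~1" else
    paste0("~", paste(v, collapse = "+"))
  sprintf("phi(%s) c(%s) r(%s) move(%s)",
          fterm(x$phi_terms), fterm(x$p_terms), x$recapture, x$movement)
}

#' @export
print.rd_model <- function(x, ...) {
  cat("Robust-design model:", format(x), "\n")
  invisible(x)
}

#' Enumerate a candidate model set
#'
#' Builds the Cartesian product of the model grammar: survival in
#' \{constant, year, length, year+length\}; capture probability over all
#' additive combinations of \{year, occasion, length\} plus constant;
#' recapture shared or separately constant; movement scenarios as requested.
#' With `include_length = FALSE` the length terms are dropped, and with
#' `include_movement = FALSE` only the no-emigration scenario is kept.
#' The full grammar therefore yields `4 * 8 * 2 * 3 = 192` distinct models,
#' `2 * 4 * 2 * 1 = 16` with both flags off; intermediate counts follow the
#' same product rule. Duplicates are never emitted.
#'
#' @param include_length Include shell-length terms (requires the data to
#'   carry `length_mm` at fit time).
#' @param include_movement Include random and Markovian temporary-emigration
#'   scenarios.
#' @return A list of [rd_model()] objects, named by their formula string.
#' @export
rd_candidate_set <- function(include_length = FALSE,
                             include_movement = FALSE) {
  subsets <- function(vars) {
    out <- list(character(0))
    for (v in vars) out <- c(out, lapply(out, c, v))
    out
  }
  phi_opts <- subsets(if (include_length) c("year", "length") else "year")
  p_opts <- subsets(if (include_length) c("occasion", "year", "length")
                    else c("occasion", "year"))
  r_opts <- c("shared", "constant")
  m_opts <- if (include_movement) c("none", "random", "markovian") else "none"
  out <- list()
  for (ph in phi_opts) for (pp in p_opts) for (r in r_opts) for (m in m_opts) {
    mod <- structure(list(phi_terms = intersect(c("year", "length"), ph),
                          p_terms = intersect(c("occasion", "year", "length"), pp),
                          recapture = r, movement = m),
                     class = "rd_model")
    out[[format(mod)]] <- mod
  }
  out
}
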