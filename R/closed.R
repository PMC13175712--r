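# Log-normal interval on the estimated-unseen part of an abundance estimate:
# with f0 = n_hat - anchor and C = exp(z * sqrt(log(1 + (se/f0)^2))), the
# interval is [anchor + f0/C, anchor + f0*C]. Respects n_hat >= anchor.
lognormal_f0_ci <- function(anchor, f0, se, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (!is.finite(f0) || f0 <= 0 || !is.finite(se) || se <= 0) {
    # boundary: nothing estimated beyond the anchor
    se0 <- if (is.finite(se)) max(se, 0) else 0
    return(c(lcl = anchor, ucl = anchor + z * se0, C = NA_real_))
  }
  C <- exp(z * sqrt(log(1 + (se / f0)^2)))
  c(lcl = anchor + f0 / C, ucl = anchor + f0 * C, C = C)
}

#' Lincoln-Petersen two-occasion abundance estimate
#'
#' Classic index `n_hat = n1 * n2 / m2` or the Chapman bias-corrected form
#' `n_hat = (n1 + 1)(n2 + 1)/(m2 + 1) - 1` (the default, defined even when
#' no animals are recaptured). The default 95% interval is log-normal on
#' `n_hat - m2`, mirroring the interval used for likelihood-based abundance
#' estimators so the two are comparable; a normal-approximation interval is
#' available via `ci = "normal"`.
#'
#' @param n1,n2 Animals captured on occasions 1 and 2.
#' @param m2 Animals captured on both occasions (`m2 <= min(n1, n2)`).
#' @param method `"chapman"` (default) or `"classic"`.
#' @param ci `"lognormal"` (default) or `"normal"`.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `"lp_estimate"`: list with `n1`, `n2`, `m2`,
#'   `n_hat`, `se`, `ci_low`, `ci_high`, `method`.
#' @examples
#' lincoln_petersen(100, 100, 50, method = "classic") # n_hat = 200
#' lincoln_petersen(50, 40, 20)                       # Chapman, 98.57
#' @export
lincoln_petersen <- function(n1, n2, m2,
                             method = c("chapman", "classic"),
                             ci = c("lognormal", "normal"),
                             conf = 0.95) {
  method <- match.arg(method)
  ci <- match.arg(ci)
  if (n1 < 0 || n2 < 0 || m2 < 0) stop("counts must be non-negative",
                                       call. = FALSE)
  if (m2 > min(n1, n2))
    stop("m2 cannot exceed min(n1, n2)", call. = FALSE)
  if (method == "classic") {
    if (m2 == 0)
      stop("classic Lincoln-Petersen is undefined when m2 = 0; ",
           "use method = \"chapman\"", call. = FALSE)
    n_hat <- n1 * n2 / m2
    var <- n1 * n2 * (n1 - m2) * (n2 - m2) / m2^3
  } else {
    n_hat <- (n1 + 1) * (n2 + 1) / (m2 + 1) - 1
    var <- (n1 + 1) * (n2 + 1) * (n1 - m2) * (n2 - m2) /
      ((m2 + 1)^2 * (m2 + 2))
  }
  se <- sqrt(var)
  if (ci == "normal") {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    lcl <- max(n_hat - z * se, max(n1, n2) - (method == "chapman"))
    ucl <- n_hat + z * se
  } else {
    b <- lognormal_f0_ci(m2, n_hat - m2, se, conf)
    lcl <- b[["lcl"]]; ucl <- b[["ucl"]]
  }
  structure(list(n1 = n1, n2 = n2, m2 = m2, n_hat = n_hat, se = se,
                 ci_low = lcl, ci_high = ucl, method = method, conf = conf),
            class = "lp_estimate")
}

#' @export
print.lp_estimate <- function(x, ...) {
  cat(sprintf(
    "Lincoln-Petersen (%s): n_hat = %.2f (SE %.2f, %g%% CI %.2f-%.2f)\n",
    x$method, x$n_hat, x$se, 100 * x$conf, x$ci_low, x$ci_high))
  cat(sprintf("  n1 = %d, n2 = %d, m2 = %d\n", x$n1, x$n2, x$m2))
  invisible(x)
}

#' Lincoln-Petersen estimate from encounter histories
#'
#' Maps the two secondary occasions of one primary period onto the
#' (n1, n2, m2) summary and delegates to [lincoln_petersen()].
#'
#' @param x An [encounter_histories()] object.
#' @param primary Index of the primary period; it must contain exactly two
#'   secondary occasions.
#' @param ... Passed to [lincoln_petersen()].
#' @return An `"lp_estimate"` object.
#' @export
lp_from_histories <- function(x, primary, ...) {
  stopifnot(inherits(x, "encounter_histories"))
  design <- x$design
  if (primary < 1 || primary > design$n_primary)
    stop("`primary` out of range", call. = FALSE)
  if (design$secondaries[primary] != 2L)
    stop("Lincoln-Petersen requires exactly 2 secondary occasions in the ",
         "indexed primary period (found ", design$secondaries[primary], ")",
         call. = FALSE)
  cols <- which(primary_of_column(design) == primary)
  d <- x$detections[, cols, drop = FALSE]
  lincoln_petersen(sum(d[, 1]), sum(d[, 2]), sum(d[, 1] & d[, 2]), ...)
}

#' Closed-population M0 maximum-likelihood abundance estimate
#'
#' Fits the null closed-population model (one shared capture probability
#' across occasions and individuals) to a single primary period by
#' maximizing the full likelihood
#' \deqn{\binom{N}{M} p^{y} (1-p)^{Nk - y}}
#' over `(N, p)`, where `M` individuals were detected, `k` is the number of
#' occasions and `y` the total number of detections. `N` is treated as
#' continuous through a log link on `f0 = N - M` and reported unrounded;
#' the interval on `N` is log-normal on `f0`.
#'
#' @param x An [encounter_histories()] object.
#' @param primary Index of the primary period to fit (>= 2 occasions).
#' @param conf Confidence level for the abundance interval.
#' @return An object of class `"closed_fit"`: list with `p_hat`, `n_hat`,
#'   `f0_hat`, `log_lik`, `se`, `ci_low`, `ci_high`, `M`, `k`, and flags
#'   `boundary` (p or f0 at a boundary) and `converged`.
#' @export
fit_m0 <- function(x, primary = 1L, conf = 0.95) {
  stopifnot(inherits(x, "encounter_histories"))
  design <- x$design
  k <- design$secondaries[primary]
  if (k < 2L) stop("M0 needs at least 2 secondary occasions", call. = FALSE)
  cols <- which(primary_of_column(design) == primary)
  d <- x$detections[, cols, drop = FALSE]
  d <- d[rowSums(d) > 0L, , drop = FALSE]
  M <- nrow(d)
  if (M < 1L) stop("no individuals detected in primary ", primary,
                   call. = FALSE)
  y <- sum(d)
  if (y == M * k) {
    # everyone detected always: p_hat = 1, N = M, zero-width boundary
    return(structure(list(p_hat = 1, n_hat = as.numeric(M), f0_hat = 0,
                          log_lik = 0, se = 0, ci_low = M, ci_high = M,
                          M = M, k = k, boundary = TRUE, converged = TRUE),
                     class = "closed_fit"))
  }
  nll <- function(par) {
    f0 <- exp(par[1]); p <- stats::plogis(par[2])
    N <- M + f0
    -(lgamma(N + 1) - lgamma(f0 + 1) - lgamma(M + 1) +
        y * log(p) + (N * k - y) * log1p(-p))
  }
  p0 <- min(max(y / (M * k), 0.02), 0.98)
  pstar0 <- 1 - (1 - p0)^k
  f00 <- max(M * (1 - pstar0) / pstar0, 0.5)
  opt <- stats::nlminb(c(log(f00), stats::qlogis(p0)), nll,
                       lower = c(-10, -12), upper = c(25, 12),
                       control = list(rel.tol = 1e-12))
  f0 <- exp(opt$par[1]); p <- stats::plogis(opt$par[2])
  n_hat <- M + f0
  no_recaps <- y == M       # every animal seen exactly once: N unidentified
  diverged <- opt$par[1] >= 25 - 1e-6 || no_recaps
  se_f0 <- NA_real_
  H <- try(stats::optimHess(opt$par, nll), silent = TRUE)
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && V[1, 1] > 0)
      se_f0 <- f0 * sqrt(V[1, 1])   # delta method from log scale
  }
  b <- lognormal_f0_ci(M, f0, se_f0, conf)
  structure(list(p_hat = p, n_hat = n_hat, f0_hat = f0,
                 log_lik = -opt$objective, se = se_f0,
                 ci_low = unname(b["lcl"]), ci_high = unname(b["ucl"]),
                 M = M, k = k,
                 boundary = opt$par[1] <= -10 + 1e-6,
                 converged = opt$convergence == 0 && !diverged),
            class = "closed_fit")
}

#' @export
print.closed_fit <- function(x, ...) {
  cat(sprintf(
    "Closed M0 fit: N_hat = %.2f (f0 = %.2f, SE %.2f), p_hat = %.3f\n",
    x$n_hat, x$f0_hat, x$se, x$p_hat))
  cat(sprintf("  M = %d over k = %d occasions; 95%% CI %.2f-%.2f\n",
              x$M, x$k, x$ci_low, x$ci_high))
  if (!x$converged) cat("  WARNING: fit did not converge (N unidentified?)\n")
  if (x$boundary) cat("  note: boundary estimate\n")
  invisible(x)
}
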