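#' Fit a robust-design capture-recapture model
#'
#' Maximizes the robust-design likelihood for one candidate model by
#' box-constrained quasi-Newton optimization on the link scale, from a
#' deterministic data-driven start plus (by default) two fixed
#' perturbations of it; the best of the starts is reported. Standard errors
#' come from the numerically differentiated Hessian at the optimum.
#'
#' Two likelihood modes exist. `"full"` carries an explicit `f0` parameter
#' (log link) for the number of individuals present but never captured, so
#' abundance is `M + f0`; it requires a model without individual covariates.
#' `"conditional"` (Huggins-type) conditions on first capture and derives
#' abundance by Horvitz-Thompson weighting; it is required — and selected by
#' `"auto"` — whenever shell length enters the model. AICc values are only
#' comparable between fits sharing a likelihood mode.
#'
#' @param x An [encounter_histories()] object.
#' @param model An [rd_model()] (default: the null model).
#' @param likelihood `"auto"`, `"full"` or `"conditional"`.
#' @param conf Confidence level used by [abundance()] intervals.
#' @param control List of optimizer options: `n_start` (number of starts,
#'   default 3), `rel.tol`, `iter.max`, `eval.max`.
#' @return An object of class `"rd_fit"` with components `par` (link-scale
#'   estimates), `par_names`, `vcov`, `log_lik`, `K` (number of
#'   parameters), `model`, `likelihood`, `converged`, `grad_norm`,
#'   `boundary`, `f0_hat`, `data` (the histories) and `ess` (effective
#'   sample size used for AICc).
#' @seealso [abundance()], [rank_models()], [rd_nll()]
#' @examples
#' cfg <- sim_config(120, phi = 0.9, p = 0.4, design = study_design(3, 3),
#'                   seed = 7)
#' h <- simulate_captures(simulate_alive(cfg), cfg)
#' fit <- rd_fit(h)
#' summary(fit)
#' @export
rd_fit <- function(x, model = rd_model(),
                   likelihood = c("auto", "full", "conditional"),
                   conf = 0.95, control = list()) {
  likelihood <- match.arg(likelihood)
  has_len <- "length" %in% c(model$phi_terms, model$p_terms)
  if (likelihood == "auto") likelihood <- if (has_len) "conditional" else "full"
  ld <- rd_likelihood_data(x, model, likelihood)
  ctrl <- utils::modifyList(
    list(n_start = 3L, rel.tol = 1e-12, iter.max = 400L, eval.max = 600L),
    control)

  # deterministic start from data moments
  p0 <- min(max(sum(ld$m_g * rowSums(ld$D)) / (ld$Mtot * ld$K), 0.02), 0.98)
  start <- numeric(ld$npar)
  names(start) <- ld$par_names
  if (length(ld$phi)) start[ld$phi[1]] <- stats::qlogis(0.85)
  start[ld$c[1]] <- stats::qlogis(p0)
  if (length(ld$r)) start[ld$r] <- stats::qlogis(p0)
  if (length(ld$mov)) start[ld$mov] <- stats::qlogis(0.1)
  if (length(ld$lf0)) {
    pstar_tot <- 1 - (1 - p0)^ld$K
    start[ld$lf0] <- log(max(ld$Mtot * (1 - pstar_tot) / pstar_tot, 0.5))
  }
  lower <- rep(-12, ld$npar); upper <- rep(12, ld$npar)
  if (length(ld$lf0)) {
    lower[ld$lf0] <- -10
    upper[ld$lf0] <- log(100 * ld$Mtot)
  }
  starts <- list(start)
  if (ctrl$n_start >= 2) starts <- c(starts, list(start + 0.5))
  if (ctrl$n_start >= 3) starts <- c(starts, list(start - 0.5))
  obj <- function(par) rd_nll_impl(par, ld)
  best <- NULL
  for (s in starts) {
    opt <- stats::nlminb(s, obj, lower = lower, upper = upper,
                         control = list(rel.tol = ctrl$rel.tol,
                                        iter.max = ctrl$iter.max,
                                        eval.max = ctrl$eval.max))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  par <- best$par
  names(par) <- ld$par_names
  nll <- best$objective
  gn <- sqrt(sum(num_grad(obj, par)^2))
  at_bound <- par <= lower + 1e-6 | par >= upper - 1e-6
  f0_hat <- if (length(ld$lf0)) exp(par[[ld$lf0]]) else NA_real_
  f0_boundary <- length(ld$lf0) > 0 && par[[ld$lf0]] <= lower[ld$lf0] + 1e-6
  diverged <- length(ld$lf0) > 0 && par[[ld$lf0]] >= upper[ld$lf0] - 1e-6
  # f0 pinned at its tiny lower bound is a boundary estimate, not failure;
  # convergence is judged by the gradient at the reported optimum (nlminb's
  # own codes are over-strict at tight tolerances)
  interior_bound <- at_bound
  if (length(ld$lf0)) interior_bound[ld$lf0] <- diverged
  converged <- !diverged && all(!interior_bound) &&
    (gn < 1e-6 * max(1, abs(nll)) || best$convergence == 0)
  V <- matrix(NA_real_, ld$npar, ld$npar,
              dimnames = list(ld$par_names, ld$par_names))
  se_ok <- FALSE
  H <- try(stats::optimHess(par, obj), silent = TRUE)
  if (!inherits(H, "try-error")) {
    Vi <- try(solve(H), silent = TRUE)
    if (!inherits(Vi, "try-error") && all(is.finite(diag(Vi))) &&
        all(diag(Vi) >= 0)) {
      V <- Vi
      dimnames(V) <- list(ld$par_names, ld$par_names)
      se_ok <- TRUE
    }
  }
  structure(list(
    par = par, par_names = ld$par_names, vcov = V, se_ok = se_ok,
    log_lik = -nll, K = ld$npar, model = model, likelihood = likelihood,
    converged = converged, grad_norm = gn,
    boundary = any(at_bound), f0_boundary = f0_boundary,
    diverged = diverged, f0_hat = f0_hat,
    conf = conf, data = x, ld = ld,
    ess = ld$Mtot * ld$K), class = "rd_fit")
}

#' @export
logLik.rd_fit <- function(object, ...) {
  structure(object$log_lik, df = object$K, nobs = object$ess,
            class = "logLik")
}

#' @export
coef.rd_fit <- function(object, type = c("link", "real"), ...) {
  type <- match.arg(type)
  if (type == "link") return(object$par)
  ld <- object$ld
  out <- stats::plogis(object$par)
  if (length(ld$lf0)) out[ld$lf0] <- exp(object$par[ld$lf0])
  # slopes and non-intercept contrasts have no single real-scale value
  keep <- seq_along(out) %in% c(
    if (length(ld$phi)) ld$phi[1], if (length(ld$c)) ld$c[1],
    ld$r, ld$mov, ld$lf0)
  out[!keep] <- NA_real_
  out
}

#' @export
vcov.rd_fit <- function(object, ...) object$vcov

#' @export
print.rd_fit <- function(x, ...) {
  cat("Robust-design fit:", format(x$model), "\n")
  cat(sprintf("  likelihood: %s; logLik = %.3f; K = %d\n",
              x$likelihood, x$log_lik, x$K))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  if (x$f0_boundary) cat("  note: f0 at boundary 0\n")
  print(round(x$par, 4))
  invisible(x)
}

#' @export
summary.rd_fit <- function(object, ...) {
  se <- sqrt(pmax(diag(object$vcov), 0))
  tab <- cbind(Estimate = object$par, SE = se,
               z = object$par / se)
  ab <- try(abundance(object), silent = TRUE)
  structure(list(model = format(object$model),
                 likelihood = object$likelihood,
                 coefficients = tab, log_lik = object$log_lik,
                 K = object$K, converged = object$converged,
                 abundance = if (inherits(ab, "try-error")) NULL else ab),
            class = "summary.rd_fit")
}

#' @export
print.summary.rd_fit <- function(x, ...) {
  cat("Robust-design model:", x$model, "\n")
  cat(sprintf("Likelihood: %s; logLik = %.3f; K = %d; converged: %s\n\n",
              x$likelihood, x$log_lik, x$K, x$converged))
  cat("Link-scale coefficients:\n")
  print(round(x$coefficients, 4))
  if (!is.null(x$abundance)) {
    cat("\nDerived abundance by primary period:\n")
    print(x$abundance)
  }
  invisible(x)
}

#' Derived abundance per primary period
#'
#' The default (`type = "session"`) is the session-specific abundance a
#' robust-design analysis conventionally reports: the closed-population
#' component of period t alone, the Horvitz-Thompson sum of `1/p*_i(t)`
#' over individuals detected in t, where `p*_i(t)` is the probability of
#' at least one detection within the period for an available animal (for
#' homogeneous models this reduces to `M_t / p*_t`, i.e.
#' `n_hat[t] = M_t + f0_t` with `f0_t` the estimated number of available
#' animals missed in period t). Between-period information enters only
#' through the shared capture-probability parameters. `type = "realized"`
#' instead returns the model's posterior expectation of the number of
#' alive-and-available animals (observed histories plus the `f0`
#' never-captured ones projected through survival); it is typically much
#' more precise but is a different estimand summary and is only available
#' for full-likelihood fits.
#'
#' Intervals are log-normal on `f0_t = n_hat[t] - M_t`, which keeps the
#' lower bound at or above `M_t`; standard errors combine parameter
#' uncertainty (delta method) with the binomial sampling/prediction
#' variance of the period count.
#'
#' @param fit An `"rd_fit"` object.
#' @param conf Confidence level (defaults to the one stored in the fit).
#' @param type `"session"` (default) or `"realized"` (full likelihood
#'   only); see Details.
#' @return A data frame with columns `primary`, `M_t`, `n_hat`, `se`,
#'   `ci_low`, `ci_high`, `boundary`.
#' @export
abundance <- function(fit, conf = fit$conf,
                      type = c("session", "realized")) {
  stopifnot(inherits(fit, "rd_fit"))
  type <- match.arg(type)
  ld <- fit$ld
  if (type == "realized" && fit$likelihood != "full")
    stop("realized abundance requires a full-likelihood fit", call. = FALSE)
  fun <- if (type == "realized") rd_realized_N else rd_ht_N
  res <- fun(fit$par, ld)
  Nfun <- function(par) fun(par, ld)$N
  vpar <- rep(NA_real_, ld$T)
  if (fit$se_ok) {
    J <- num_jacobian(Nfun, fit$par)
    vpar <- pmax(rowSums((J %*% fit$vcov) * J), 0)
  }
  se <- sqrt(vpar + res$vpred)
  M_t <- ld$M_t
  f0_t <- res$N - M_t
  lcl <- ucl <- numeric(ld$T)
  boundary <- logical(ld$T)
  for (t in seq_len(ld$T)) {
    b <- lognormal_f0_ci(M_t[t], f0_t[t], se[t], conf)
    lcl[t] <- b[["lcl"]]; ucl[t] <- b[["ucl"]]
    boundary[t] <- !is.finite(f0_t[t]) || f0_t[t] <= 1e-6 ||
      fit$f0_boundary
  }
  data.frame(primary = seq_len(ld$T), M_t = M_t, n_hat = res$N, se = se,
             ci_low = lcl, ci_high = ucl, boundary = boundary)
}

#' @export
predict.rd_fit <- function(object,
                           type = c("abundance", "phi", "p"), ...) {
  type <- match.arg(type)
  ld <- object$ld
  fw <- rd_forward(object$par, ld)
  switch(type,
    abundance = abundance(object),
    phi = {
      if (is.null(fw$PHI)) stop("single primary period: no survival",
                                call. = FALSE)
      # per-interval effective survival at the (standardized) mean length
      if (ld$has_len_phi) fw$PHI[which(abs(ld$z_g) == min(abs(ld$z_g)))[1], ]
      else fw$PHI[1, ]
    },
    p = {
      eta <- as.vector(ld$Xc %*% object$par[ld$c])
      stats::plogis(eta)
    })
}

#' @export
simulate.rd_fit <- function(object, nsim = 1, seed = 1L, ...) {
  m <- object$model
  if (length(m$phi_terms) || length(m$p_terms) || m$movement != "none" ||
      object$likelihood != "full")
    stop("parametric simulation is implemented for the constant (null) ",
         "full-likelihood model only", call. = FALSE)
  ld <- object$ld
  phi <- if (length(ld$phi)) stats::plogis(object$par[[ld$phi[1]]]) else 1
  p <- stats::plogis(object$par[[ld$c[1]]])
  N <- max(1L, round(ld$Mtot + object$f0_hat))
  cfg <- sim_config(N, phi = phi, p = p, design = object$data$design,
                    seed = seed, n_reps = nsim)
  lapply(simulate_study(cfg), `[[`, "histories")
}

#' @export
residuals.rd_fit <- function(object, ...) {
  ld <- object$ld
  fw <- rd_forward(object$par, ld)
  if (object$likelihood == "full") {
    N <- ld$Mtot + object$f0_hat
    expected <- N * fw$pi
  } else {
    expected <- ld$Mtot * fw$pi / (1 - fw$pi0)
  }
  (ld$m_g - expected) / sqrt(pmax(expected, 1e-12))
}

#' @export
plot.rd_fit <- function(x, ...) {
  ab <- abundance(x)
  plot_abundance_series(ab, main = format(x$model), ...)
  invisible(ab)
}
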