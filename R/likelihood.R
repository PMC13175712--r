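# Internal likelihood engine for the robust-design model.
#
# The model is a hidden-state (alive-available / alive-unavailable / dead)
# process across primary periods with a closed detection model within each
# period. The full likelihood treats the population as a superpopulation of
# N = M + f0 individuals present at the first primary period (no
# recruitment): M observed encounter histories plus f0 all-zero histories,
# with the exact multinomial coefficient so that the probabilities of all
# possible datasets sum to one. The conditional (Huggins-type) likelihood
# conditions each individual on having been detected at least once and
# carries no abundance parameter; it is required when individual covariates
# (shell length) enter, because the covariate of never-seen animals is
# unknown.

# Precompute data structures for fast repeated likelihood evaluation.
rd_likelihood_data <- function(x, model, likelihood) {
  stopifnot(inherits(x, "encounter_histories"), inherits(model, "rd_model"))
  design <- x$design
  T <- design$n_primary
  K <- design$n_occasions
  kmax <- max(design$secondaries)
  has_len <- "length" %in% c(model$phi_terms, model$p_terms)
  if (has_len && likelihood == "full")
    stop("length-covariate models require the conditional likelihood",
         call. = FALSE)
  if (has_len) {
    if (is.null(x$length_mm))
      stop("model includes a length term but the data carry no length_mm",
           call. = FALSE)
    if (anyNA(x$length_mm))
      stop(sum(is.na(x$length_mm)),
           " record(s) lack length_mm and are rejected by ",
           "length-dependent models", call. = FALSE)
  }
  pid <- primary_of_column(design)
  occ <- occasion_of_column(design)
  det <- x$detections
  n <- nrow(det)
  if (n == 0L) stop("no encounter histories to fit", call. = FALSE)

  # aggregate identical rows (and covariate values) into weighted groups
  if (has_len) {
    z_raw <- x$length_mm
    key <- paste(apply(det, 1, paste, collapse = ""), z_raw)
  } else {
    z_raw <- NULL
    key <- apply(det, 1, paste, collapse = "")
  }
  first <- which(!duplicated(key))
  m_g <- as.integer(table(factor(key, levels = key[first])))
  D <- det[first, , drop = FALSE]
  G <- nrow(D)
  len_center <- len_scale <- NA_real_
  z_g <- NULL
  if (has_len) {
    len_center <- mean(x$length_mm)
    len_scale <- stats::sd(x$length_mm)
    if (!is.finite(len_scale) || len_scale == 0) len_scale <- 1
    z_g <- (z_raw[first] - len_center) / len_scale
  }

  # recapture indicator: occasion strictly after the first within-primary
  # detection uses the recapture probability r
  U <- matrix(FALSE, G, K)
  Pcols <- split(seq_len(K), pid)
  for (t in seq_len(T)) {
    cols <- Pcols[[t]]
    sub <- D[, cols, drop = FALSE]
    fd <- apply(sub, 1, function(r) {
      w <- which(r == 1L); if (length(w)) w[1] else Inf
    })
    for (j in seq_along(cols)) U[, cols[j]] <- j > fd
  }
  Z <- matrix(0L, G, T)
  for (t in seq_len(T)) Z[, t] <- as.integer(
    rowSums(D[, Pcols[[t]], drop = FALSE]) == 0L)

  # design matrices on the logit scale (length handled as an extra slope)
  nm_c <- "c"
  Xc <- matrix(1, K, 1)
  if ("year" %in% model$p_terms && T >= 2) {
    for (t in 2:T) {
      Xc <- cbind(Xc, as.numeric(pid == t))
      nm_c <- c(nm_c, paste0("c:year", t))
    }
  }
  if ("occasion" %in% model$p_terms && kmax >= 2) {
    for (j in 2:kmax) {
      Xc <- cbind(Xc, as.numeric(occ == j))
      nm_c <- c(nm_c, paste0("c:occ", j))
    }
  }
  has_len_p <- "length" %in% model$p_terms
  has_len_phi <- "length" %in% model$phi_terms
  nm_phi <- character(0)
  Xphi <- NULL
  if (T >= 2) {
    nm_phi <- "phi"
    Xphi <- matrix(1, T - 1, 1)
    if ("year" %in% model$phi_terms && T >= 3) {
      for (t in 2:(T - 1)) {
        Xphi <- cbind(Xphi, as.numeric(seq_len(T - 1) == t))
        nm_phi <- c(nm_phi, paste0("phi:year", t))
      }
    }
  }
  par_names <- c(nm_phi,
                 if (has_len_phi) "phi:length",
                 nm_c,
                 if (has_len_p) "c:length",
                 if (model$recapture == "constant") "r",
                 switch(model$movement, none = NULL, random = "gamma",
                        markovian = c("gamma_prime", "gamma_dprime")),
                 if (likelihood == "full") "log_f0")
  idx <- list()
  pos <- 0L
  take <- function(k) { v <- pos + seq_len(k); pos <<- pos + k; v }
  idx$phi <- take(length(nm_phi))
  idx$phi_len <- take(as.integer(has_len_phi))
  idx$c <- take(length(nm_c))
  idx$c_len <- take(as.integer(has_len_p))
  idx$r <- take(as.integer(model$recapture == "constant"))
  idx$mov <- take(switch(model$movement, none = 0L, random = 1L,
                         markovian = 2L))
  idx$lf0 <- take(as.integer(likelihood == "full"))

  c(idx, list(D = D, U = U, Z = Z, m_g = m_g, G = G, K = K, T = T, kmax = kmax,
       Mtot = n, M_t = captured_per_primary(x),
       Pcols = Pcols, intervals = design$intervals,
       Xc = Xc, Xphi = Xphi, z_g = z_g,
       len_center = len_center, len_scale = len_scale,
       has_len_p = has_len_p, has_len_phi = has_len_phi,
       separate_r = model$recapture == "constant",
       movement = model$movement, likelihood = likelihood,
       par_names = par_names, npar = pos, design = design))
}

# Forward (and optionally backward) pass. Returns the per-group history
# probabilities pi_g, the never-detected probability pi0 (per group), and,
# when posterior = TRUE, the posterior probability of being alive and
# available in each primary period.
rd_forward <- function(par, ld, posterior = FALSE) {
  if (length(par) != ld$npar)
    stop("expected ", ld$npar, " parameters (",
         paste(ld$par_names, collapse = ", "), "), got ", length(par),
         call. = FALSE)
  if (any(is.nan(par)))
    stop("non-finite parameter value", call. = FALSE)
  G <- ld$G; T <- ld$T
  # capture / recapture probabilities per (group, occasion)
  eta_c <- as.vector(ld$Xc %*% par[ld$c])
  CMAT <- matrix(eta_c, G, ld$K, byrow = TRUE)
  if (ld$has_len_p) CMAT <- CMAT + par[ld$c_len] * ld$z_g
  CMAT <- stats::plogis(CMAT)
  if (ld$separate_r) {
    r <- stats::plogis(par[ld$r])
    PM <- CMAT
    PM[ld$U] <- r
  } else PM <- CMAT
  LL <- ld$D * log(PM) + (1 - ld$D) * log1p(-PM)
  LL0 <- log1p(-CMAT)
  E <- E0 <- matrix(0, G, T)
  for (t in seq_len(T)) {
    cols <- ld$Pcols[[t]]
    E[, t] <- exp(rowSums(LL[, cols, drop = FALSE]))
    E0[, t] <- exp(rowSums(LL0[, cols, drop = FALSE]))
  }
  # survival per transition (effective over the interval length)
  if (T >= 2) {
    eta_phi <- as.vector(ld$Xphi %*% par[ld$phi])
    if (ld$has_len_phi) {
      PHI <- stats::plogis(matrix(eta_phi, G, T - 1, byrow = TRUE) +
                             par[ld$phi_len] * ld$z_g)
    } else {
      PHI <- matrix(stats::plogis(eta_phi), G, T - 1, byrow = TRUE)
    }
    PHI <- sweep(PHI, 2, ld$intervals, function(p, d) p^d)
  } else PHI <- NULL
  # temporary-emigration transition probabilities
  mv <- ld$movement
  if (mv == "none") {
    gAU <- 0; gUU <- 0; g1 <- 0
  } else if (mv == "random") {
    g <- stats::plogis(par[ld$mov]); gAU <- g; gUU <- g; g1 <- g
  } else {
    gUU <- stats::plogis(par[ld$mov[1]])   # gamma': stay unavailable
    gAU <- stats::plogis(par[ld$mov[2]])   # gamma'': become unavailable
    g1 <- gAU                              # entry treated as previously available
  }
  run <- function(Emat, Zmat, store = FALSE) {
    fA <- (1 - g1) * Emat[, 1]
    fU <- g1 * Zmat[, 1]
    fD <- numeric(G)
    if (store) {
      FA <- FU <- FD <- matrix(0, G, T)
      FA[, 1] <- fA; FU[, 1] <- fU
    }
    if (T >= 2) for (t in seq_len(T - 1)) {
      s <- PHI[, t]
      fA2 <- ((1 - gAU) * fA + (1 - gUU) * fU) * s * Emat[, t + 1]
      fU2 <- (gAU * fA + gUU * fU) * s * Zmat[, t + 1]
      fD2 <- (fD + (fA + fU) * (1 - s)) * Zmat[, t + 1]
      fA <- fA2; fU <- fU2; fD <- fD2
      if (store) { FA[, t + 1] <- fA; FU[, t + 1] <- fU; FD[, t + 1] <- fD }
    }
    out <- list(pi = fA + fU + fD)
    if (store) { out$FA <- FA; out$FU <- FU; out$FD <- FD }
    out
  }
  ones <- matrix(1, G, T)
  fw <- run(E, ld$Z, store = posterior)
  fw0 <- run(E0, ones, store = posterior)
  res <- list(pi = fw$pi, pi0 = fw0$pi, E = E, E0 = E0, PHI = PHI)
  if (posterior) {
    backward <- function(Emat, Zmat) {
      bA <- bU <- bD <- matrix(1, G, T)
      if (T >= 2) for (t in (T - 1):1) {
        s <- PHI[, t]
        ea <- Emat[, t + 1] * bA[, t + 1]
        zu <- Zmat[, t + 1] * bU[, t + 1]
        zd <- Zmat[, t + 1] * bD[, t + 1]
        bA[, t] <- s * ((1 - gAU) * ea + gAU * zu) + (1 - s) * zd
        bU[, t] <- s * ((1 - gUU) * ea + gUU * zu) + (1 - s) * zd
        bD[, t] <- zd
      }
      list(bA = bA, bU = bU, bD = bD)
    }
    bw <- backward(E, ld$Z)
    bw0 <- backward(E0, ones)
    res$PA <- fw$FA * bw$bA / fw$pi          # P(available in t | history)
    res$PA0 <- fw0$FA * bw0$bA / fw0$pi      # same for a never-seen animal
  }
  res
}

# Negative log-likelihood given precomputed data.
rd_nll_impl <- function(par, ld) {
  fw <- rd_forward(par, ld)
  if (ld$likelihood == "full") {
    f0 <- exp(par[ld$lf0])
    pi0 <- fw$pi0[1]
    ll <- lgamma(ld$Mtot + f0 + 1) - lgamma(f0 + 1) -
      sum(lgamma(ld$m_g + 1)) + sum(ld$m_g * log(fw$pi)) +
      (if (f0 > 0) f0 * log(pi0) else 0)
  } else {
    ll <- sum(ld$m_g * (log(fw$pi) - log1p(-fw$pi0)))
  }
  -ll
}

#' Robust-design negative log-likelihood
#'
#' Evaluates the negative log joint probability of an encounter-history set
#' under a given candidate model at a parameter vector on the link scale
#' (logit for survival, capture, recapture and emigration parameters; log
#' for `f0`, the number of individuals never captured). The full likelihood
#' includes the exact multinomial coefficient over histories together with
#' an `f0` term for the unobservable all-zero history, so that summing the
#' likelihood over every possible dataset of a fixed superpopulation yields
#' one. The conditional (Huggins-type) likelihood divides each history
#' probability by the probability of being seen at least once and has no
#' `f0` parameter.
#'
#' @param par Numeric parameter vector in the canonical order reported by
#'   [rd_fit()] (see `$par_names` of a fitted object). `log_f0 = -Inf`
#'   (that is, `f0 = 0`) is accepted.
#' @param x An [encounter_histories()] object.
#' @param model An [rd_model()].
#' @param likelihood `"full"` or `"conditional"`.
#' @return The negative log-likelihood (scalar).
#' @examples
#' d <- study_design(1, 2)
#' h <- encounter_histories(matrix(c(1, 1), 1), d)
#' # p = 0.5 and f0 = 0: the [1,1] history has probability 1/4
#' rd_nll(c(0, -Inf), h, rd_model(), likelihood = "full")  # log(4)
#' @export
rd_nll <- function(par, x, model = rd_model(),
                   likelihood = c("full", "conditional")) {
  likelihood <- match.arg(likelihood)
  ld <- rd_likelihood_data(x, model, likelihood)
  rd_nll_impl(par, ld)
}

# Realized available-population size per primary period: posterior expected
# number of alive-and-available animals among the M observed histories plus
# the f0 never-observed ones. Also returns the binomial prediction variance
# of that realized count.
rd_realized_N <- function(par, ld) {
  fw <- rd_forward(par, ld, posterior = TRUE)
  f0 <- if (length(ld$lf0)) exp(par[ld$lf0]) else 0
  PA0 <- fw$PA0[1, ]
  N <- as.vector(ld$m_g %*% fw$PA) + f0 * PA0
  vpred <- as.vector(ld$m_g %*% (fw$PA * (1 - fw$PA))) +
    f0 * PA0 * (1 - PA0)
  list(N = N, vpred = vpred)
}

# Horvitz-Thompson abundance for conditional (length-covariate) fits:
# sum over individuals detected in period t of 1 / p*_i(t), where p*_i(t)
# is the probability of at least one detection in t for an available animal.
rd_ht_N <- function(par, ld) {
  fw <- rd_forward(par, ld)
  pstar <- 1 - fw$E0                      # G x T
  det_t <- 1 - ld$Z
  N <- colSums(ld$m_g * det_t / pstar)
  vht <- colSums(ld$m_g * det_t * (1 - pstar) / pstar^2)
  list(N = N, vpred = vht)
}

num_grad <- function(f, par, h = 1e-5) {
  vapply(seq_along(par), function(i) {
    e <- numeric(length(par)); e[i] <- h
    (f(par + e) - f(par - e)) / (2 * h)
  }, numeric(1))
}

num_jacobian <- function(f, par, h = 1e-5) {
  f0 <- f(par)
  J <- matrix(0, length(f0), length(par))
  for (i in seq_along(par)) {
    e <- numeric(length(par)); e[i] <- h
    J[, i] <- (f(par + e) - f(par - e)) / (2 * h)
  }
  J
}
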