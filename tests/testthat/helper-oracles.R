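# Independent oracles and shared fixtures for the test suite.

# --- independent null-model robust-design likelihood ------------------------
# Computes the dataset negative log-likelihood for the constant
# (phi, p, f0) model by direct enumeration over the unobserved death time,
# a different algorithm from the package's hidden-state recursion.
oracle_null_nll <- function(phi, p, f0, det, design) {
  T <- design$n_primary
  k <- design$secondaries
  pid <- rep(seq_len(T), k)
  pat_prob <- function(counts) {
    # counts: detections per primary; sum over death after primary tau
    L <- if (any(counts > 0)) max(which(counts > 0)) else 0L
    tot <- 0
    for (tau in max(L, 1L):T) {
      # alive through primary tau, dead afterwards
      pr <- 1
      for (t in seq_len(tau))
        pr <- pr * p^counts[t] * (1 - p)^(k[t] - counts[t])
      if (tau > 1) pr <- pr * phi^(tau - 1)
      if (tau < T) pr <- pr * (1 - phi)
      tot <- tot + pr
    }
    tot
  }
  counts <- t(apply(det, 1, function(r) tapply(r, pid, sum)))
  if (nrow(det) == 1L) counts <- matrix(counts, 1L)
  pis <- apply(counts, 1, pat_prob)
  pi0 <- pat_prob(rep(0L, T))
  M <- nrow(det)
  key <- apply(det, 1, paste, collapse = "")
  mult <- table(key)
  ll <- lgamma(M + f0 + 1) - lgamma(f0 + 1) - sum(lgamma(as.numeric(mult) + 1)) +
    sum(log(pis)) + (if (f0 > 0) f0 * log(pi0) else 0)
  -ll
}

# Coarse lattice minimization of the null-model NLL (the package's own
# objective is a smooth function; the lattice bounds its minimum from above).
grid_null_nll_min <- function(h, phis = seq(0.05, 0.95, by = 0.05),
                              ps = seq(0.05, 0.95, by = 0.05),
                              f0s = seq(0, 10, by = 0.25)) {
  best <- Inf
  for (phi in phis) for (p in ps) for (f0 in f0s) {
    v <- oracle_null_nll(phi, p, f0, h$detections, h$design)
    if (is.finite(v) && v < best) best <- v
  }
  best
}

# Brute-force grid maximization of the closed M0 likelihood.
grid_m0 <- function(M, k, y, Nmax = 2000, by = 0.5) {
  Ns <- seq(M, Nmax, by = by)
  best <- c(-Inf, NA)
  for (N in Ns) {
    p <- y / (N * k)   # profile MLE of p given N
    if (p <= 0 || p >= 1) next
    ll <- lgamma(N + 1) - lgamma(N - M + 1) + y * log(p) +
      (N * k - y) * log(1 - p)
    if (ll > best[1]) best <- c(ll, N)
  }
  best[2]
}

# --- simulation fixtures ----------------------------------------------------
sim_histories <- function(n0, phi, p, T, k, seed) {
  cfg <- sim_config(n0, phi = phi, p = p, design = study_design(T, k),
                    seed = seed)
  truth <- simulate_alive(cfg)
  list(h = simulate_captures(truth, cfg), truth = truth, cfg = cfg)
}

# --- shared heavy computations (memoized across test files) -----------------
.cache <- new.env(parent = emptyenv())

# Full-scale power cell at study conditions: 1000 replicates,
# null model, one-sided CI-exclusion rule, decline grid 0..95 by 5.
power_cell_cached <- function(n0, k, p = 0.3, seed = 20260927) {
  key <- sprintf("cell_%d_%d_%g_%d", n0, k, p, seed)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  g <- run_power_grid(n_initial = n0, n_secondary = k,
                      decline_pct = seq(0, 95, by = 5),
                      phi = 0.9, p = p, n_primary = 3,
                      n_reps = 1000, seed = seed)
  .cache[[key]] <- g
  g
}

cell_power <- function(g, d) g$power[g$decline_pct == d]
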