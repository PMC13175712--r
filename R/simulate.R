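#' Configure a population / capture-history simulation
#'
#' The simulator emulates a declining, closed-to-recruitment population
#' monitored under a robust design: every individual is alive in the first
#' primary period, survives each between-year interval independently with
#' probability `phi^interval`, and while alive is detected on each secondary
#' occasion independently with probability `p` (the null model M0:
#' homogeneous capture probability). Individuals never detected over the
#' whole study are removed from the returned capture histories, exactly as a
#' field study can only tag animals it has seen.
#'
#' @param n_initial Initial population size (>= 1).
#' @param phi Annual survival probability in `[0, 1]`.
#' @param p Per-secondary-occasion capture probability in `[0, 1]`.
#' @param design A [study_design()].
#' @param seed Master integer seed; all replicate randomness derives from it.
#' @param n_reps Number of replicate studies (>= 1).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_initial, phi = 0.9, p = 0.3,
                       design = study_design(3, 2), seed = 1L,
                       n_reps = 1L) {
  stopifnot(inherits(design, "study_design"))
  if (n_initial < 1) stop("`n_initial` must be >= 1", call. = FALSE)
  if (phi < 0 || phi > 1) stop("`phi` must be in [0, 1]", call. = FALSE)
  if (p < 0 || p > 1) stop("`p` must be in [0, 1]", call. = FALSE)
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  structure(
    list(n_initial = as.integer(n_initial), phi = phi, p = p,
         design = design, seed = as.integer(seed),
         n_reps = as.integer(n_reps)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  n_initial = %d, phi = %g, p = %g, reps = %d, seed = %d\n",
              x$n_initial, x$phi, x$p, x$n_reps, x$seed))
  print(x$design)
  invisible(x)
}

# Deterministic child seeds below 2^31, derived from the master seed.
child_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate the true alive/dead trajectory of a population
#'
#' Every individual is alive in primary period 1; survival between periods
#' t and t+1 is an independent Bernoulli draw with probability
#' `phi^interval`. There is no recruitment, so rows are monotone
#' non-increasing (no resurrection).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for this draw (defaults to `config$seed`).
#' @return An object of class `"truth_record"`: list with `alive`
#'   (logical matrix, individuals x primary periods) and `n_true`
#'   (true alive count per primary period).
#' @export
simulate_alive <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_initial
  T <- config$design$n_primary
  alive <- matrix(FALSE, n, T)
  alive[, 1] <- TRUE
  if (T > 1) {
    for (t in seq_len(T - 1)) {
      s <- config$phi^config$design$intervals[t]
      surv <- stats::runif(n) < s
      alive[, t + 1] <- alive[, t] & surv
    }
  }
  structure(list(alive = alive, n_true = colSums(alive)),
            class = "truth_record")
}

#' Simulate capture histories given a true trajectory
#'
#' Detection of individual i on secondary occasion j of primary period t is
#' an independent Bernoulli(p) draw if i is alive in t, and impossible
#' otherwise. Individuals with all-zero histories are removed; the number
#' removed is retained as the `"n_removed"` attribute and the retained row
#' indices into the truth as `"kept"`.
#'
#' @param truth A `"truth_record"` from [simulate_alive()].
#' @param config The [sim_config()] used to create `truth`.
#' @param seed Integer seed for the capture draws.
#' @return An [encounter_histories()] object with attributes `n_removed`
#'   and `kept`.
#' @export
simulate_captures <- function(truth, config, seed = config$seed + 1L) {
  stopifnot(inherits(truth, "truth_record"), inherits(config, "sim_config"))
  set.seed(seed)
  design <- config$design
  n <- nrow(truth$alive)
  pid <- primary_of_column(design)
  K <- design$n_occasions
  aliveK <- truth$alive[, pid, drop = FALSE]
  det <- matrix(0L, n, K)
  det[aliveK] <- as.integer(stats::runif(sum(aliveK)) < config$p)
  keep <- rowSums(det) > 0L
  h <- encounter_histories(det[keep, , drop = FALSE], design,
                           id = if (any(keep)) paste0("ind", which(keep))
                                else character(0))
  attr(h, "n_removed") <- sum(!keep)
  attr(h, "kept") <- which(keep)
  h
}

#' Simulate replicate robust-design studies
#'
#' Each replicate uses deterministic child seeds derived from the master
#' seed, so an identical configuration yields bit-identical output.
#'
#' @param config A [sim_config()].
#' @return A list of length `config$n_reps`; each element is a list with
#'   components `histories` (an [encounter_histories()]) and `truth`
#'   (a `"truth_record"`). The child seeds used are attached as the
#'   `"seeds"` attribute.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- matrix(child_seeds(config$seed, 2L * config$n_reps),
                  ncol = 2L)
  out <- lapply(seq_len(config$n_reps), function(r) {
    truth <- simulate_alive(config, seed = seeds[r, 1])
    hist <- simulate_captures(truth, config, seed = seeds[r, 2])
    list(histories = hist, truth = truth)
  })
  attr(out, "seeds") <- seeds
  attr(out, "config") <- config
  out
}
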