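test_that("Lincoln-Petersen reproduces hand arithmetic", {
  # complete overlap: everyone seen both times
  e <- lincoln_petersen(50, 50, 50, method = "classic")
  expect_equal(e$n_hat, 50)
  e2 <- lincoln_petersen(100, 100, 50, method = "classic")
  expect_equal(e2$n_hat, 200)
  e3 <- lincoln_petersen(50, 40, 20, method = "chapman")
  expect_equal(e3$n_hat, 51 * 41 / 21 - 1, tolerance = 1e-12)
  expect_equal(round(e3$n_hat, 2), 98.57)
  # Chapman variance formula
  expect_equal(e3$se^2, 51 * 41 * 30 * 20 / (21^2 * 22), tolerance = 1e-12)
})

test_that("classic estimator is undefined at m2 = 0, Chapman is not", {
  expect_error(lincoln_petersen(10, 5, 0, method = "classic"), "m2 = 0")
  e <- lincoln_petersen(1, 1, 0, method = "chapman")
  expect_equal(e$n_hat, 2 * 2 / 1 - 1)
  expect_error(lincoln_petersen(10, 5, 6), "m2")
  expect_error(lincoln_petersen(-1, 5, 0), "non-negative")
})

test_that("Chapman never exceeds the classic estimate and both decrease in m2", {
  set.seed(17)
  for (i in 1:50) {
    n1 <- sample(5:100, 1); n2 <- sample(5:100, 1)
    m2 <- sample(seq_len(min(n1, n2)), 1)
    ch <- lincoln_petersen(n1, n2, m2, method = "chapman")$n_hat
    cl <- lincoln_petersen(n1, n2, m2, method = "classic")$n_hat
    expect_lte(ch, cl + 1e-9)
    if (m2 < min(n1, n2)) {
      cl2 <- lincoln_petersen(n1, n2, m2 + 1, method = "classic")$n_hat
      expect_lte(cl2, cl + 1e-9)
    }
  }
})

test_that("lp_from_histories counts occasion totals correctly", {
  d <- study_design(1, 2)
  h <- encounter_histories(rbind(c(1, 1), c(1, 0), c(0, 1)), d)
  e <- lp_from_histories(h, 1, method = "classic")
  expect_equal(c(e$n1, e$n2, e$m2), c(2, 2, 1))
  expect_equal(e$n_hat, 4)
  # everyone seen twice: estimate equals the count
  hk <- encounter_histories(matrix(1, 5, 2), d)
  expect_equal(lp_from_histories(hk, 1, method = "classic")$n_hat, 5)
  # single [1,0] individual: classic undefined, Chapman = 1
  h1 <- encounter_histories(matrix(c(1, 0), 1), d)
  expect_error(lp_from_histories(h1, 1, method = "classic"), "m2 = 0")
  expect_equal(lp_from_histories(h1, 1, method = "chapman")$n_hat, 1)
  # design guard
  d3 <- study_design(1, 3)
  h3 <- encounter_histories(matrix(c(1, 0, 1), 1), d3)
  expect_error(lp_from_histories(h3, 1), "exactly 2 secondary")
})

test_that("M0 likelihood maximization agrees with a brute-force grid", {
  # n1 = 20, n2 = 16, m2 = 6 -> M = 30, y = 36 over k = 2
  set.seed(2)
  det <- rbind(matrix(rep(c(1, 1), 6), ncol = 2, byrow = TRUE),
               matrix(rep(c(1, 0), 14), ncol = 2, byrow = TRUE),
               matrix(rep(c(0, 1), 10), ncol = 2, byrow = TRUE))
  h <- encounter_histories(det, study_design(1, 2))
  fit <- fit_m0(h, 1)
  expect_equal(fit$M, 30)
  oracle <- grid_m0(30, 2, 36)
  expect_lt(abs(fit$n_hat - oracle), 0.5)
  # a handful of random instances against the same oracle
  for (i in 1:8) {
    k <- sample(2:4, 1)
    dd <- matrix(rbinom(40 * k, 1, runif(1, 0.3, 0.7)), 40)
    dd <- dd[rowSums(dd) > 0, , drop = FALSE]
    hh <- encounter_histories(dd, study_design(1, k))
    ff <- fit_m0(hh, 1)
    if (!ff$converged || ff$boundary) next
    expect_lt(abs(ff$n_hat - grid_m0(ff$M, k, sum(dd))), 0.5)
  }
})

test_that("M0 boundary and degenerate data are flagged", {
  d <- study_design(1, 2)
  h <- encounter_histories(matrix(1, 10, 2), d)
  fit <- fit_m0(h, 1)
  expect_equal(fit$p_hat, 1)
  expect_equal(fit$n_hat, 10)
  expect_true(fit$boundary)
  expect_equal(fit$ci_low, fit$ci_high)
  # no recaptures at all: N unidentified -> nonconvergence flag
  h1 <- encounter_histories(rbind(c(1, 0), c(0, 1), c(1, 0)), d)
  expect_false(fit_m0(h1, 1)$converged)
})

test_that("M0 recovers a known simulated abundance", {
  # N = 200, p = 0.5, k = 4: median estimate over 200 reps within 5
  ests <- vapply(1:200, function(r) {
    cfg <- sim_config(200, phi = 1, p = 0.5, design = study_design(1, 4),
                      seed = 700 + r)
    h <- simulate_captures(simulate_alive(cfg), cfg)
    fit_m0(h, 1)$n_hat
  }, numeric(1))
  expect_lt(abs(median(ests) - 200), 5)
})

test_that("M0 matches classic Lincoln-Petersen under symmetric capture", {
  # with k = 2 and n1 = n2 = n, the classical M0 estimating equation
  # 1 - M/N = (1 - y/(kN))^k has root N = n^2/m2, the classic
  # Lincoln-Petersen index; the exact-likelihood optimum sits within its
  # digamma correction (about 0.5 * N/f0 animals) of that root
  set.seed(91)
  for (i in 1:25) {
    n <- sample(12:40, 1); m2 <- sample(3:(n - 2), 1)
    M <- 2 * n - m2; y <- 2 * n
    lp <- n * n / m2
    ee <- function(N) (1 - M / N) - (1 - y / (2 * N))^2
    root <- uniroot(ee, c(M + 1e-9, 1e5))$root
    expect_lt(abs(root - lp), 1)
    # the exact-likelihood optimum deviates from LP only by its digamma
    # correction, which scales with N/f0
    oracle <- grid_m0(M, 2, y)
    expect_lt(abs(oracle - lp), 1 + lp * (0.5 / max(lp - M, 1) + 0.02))
  }
})

test_that("Chapman interval covers the truth at its nominal rate", {
  # two-occasion closed population, N = 300, p = 0.8
  set.seed(55)
  N <- 300; p <- 0.8
  hits <- vapply(1:500, function(r) {
    c1 <- rbinom(N, 1, p); c2 <- rbinom(N, 1, p)
    e <- lincoln_petersen(sum(c1), sum(c2), sum(c1 & c2))
    e$ci_low <= N && N <= e$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})
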