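test_that("survival simulation honours certainty cases", {
  cfg1 <- sim_config(40, phi = 1, p = 0.5, design = study_design(3, 2),
                     seed = 1)
  tr <- simulate_alive(cfg1)
  expect_equal(tr$n_true, rep(40, 3))
  cfg0 <- sim_config(40, phi = 0, p = 0.5, design = study_design(3, 2),
                     seed = 1)
  tr0 <- simulate_alive(cfg0)
  expect_equal(tr0$n_true, c(40, 0, 0))
})

test_that("alive trajectories are monotone with matching counts", {
  cfg <- sim_config(120, phi = 0.8, p = 0.3, design = study_design(4, 2),
                    seed = 3)
  tr <- simulate_alive(cfg)
  expect_true(all(tr$alive[, 1]))
  expect_true(all(diff(t(tr$alive)) <= 0))   # no resurrection
  expect_equal(tr$n_true, colSums(tr$alive))
})

test_that("mean final-year population matches the binomial expectation", {
  # 300 * 0.9^2 = 243; Monte-Carlo mean over 1000 reps within 3
  cfg <- sim_config(300, phi = 0.9, p = 0.3, design = study_design(3, 2),
                    seed = 11, n_reps = 1000)
  finals <- vapply(seq_len(1000), function(r)
    simulate_alive(cfg, seed = r + 50000L)$n_true[3], numeric(1))
  expect_lt(abs(mean(finals) - 243), 3)
})

test_that("captures obey certainty cases and never detect the dead", {
  cfg <- sim_config(25, phi = 0.6, p = 1, design = study_design(3, 2),
                    seed = 5)
  tr <- simulate_alive(cfg)
  h <- simulate_captures(tr, cfg)
  expect_equal(n_captured(h), 25)     # p = 1: everyone seen in year 1
  cp <- collapse_primary(h)
  expect_equal(unname(colSums(cp)), unname(tr$n_true))
  # no detection after death
  pid <- rep(1:3, each = 2)
  for (t in 1:3) {
    dead <- !tr$alive[attr(h, "kept"), t]
    expect_true(all(h$detections[dead, pid == t] == 0))
  }
  cfg0 <- sim_config(25, phi = 0.6, p = 0, design = study_design(3, 2),
                     seed = 5)
  h0 <- simulate_captures(tr, cfg0)
  expect_equal(n_captured(h0), 0)
  expect_equal(attr(h0, "n_removed"), 25)
})

test_that("records plus removals equal the initial population", {
  for (seed in 1:5) {
    cfg <- sim_config(80, phi = 0.85, p = 0.25,
                      design = study_design(3, 3), seed = seed)
    h <- simulate_captures(simulate_alive(cfg), cfg)
    expect_equal(n_captured(h) + attr(h, "n_removed"), 80)
  }
})

test_that("expected number of captured records matches the binomial mean", {
  # 1 primary x 2 secondary, p = 0.3: P(seen) = 1 - 0.7^2 = 0.51
  cfg <- sim_config(1000, phi = 0.9, p = 0.3, design = study_design(1, 2),
                    seed = 9)
  h <- simulate_captures(simulate_alive(cfg), cfg)
  tol <- 4 * sqrt(1000 * 0.51 * 0.49)
  expect_lt(abs(n_captured(h) - 510), tol)
})

test_that("replicates are deterministic and composable", {
  cfg <- sim_config(60, phi = 0.9, p = 0.3, design = study_design(3, 2),
                    seed = 21, n_reps = 3)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(lapply(a, function(x) x$histories$detections),
                   lapply(b, function(x) x$histories$detections))
  # n_reps = 1 equals one simulate_alive + simulate_captures at child seeds
  cfg1 <- sim_config(60, phi = 0.9, p = 0.3, design = study_design(3, 2),
                     seed = 21, n_reps = 1)
  s1 <- simulate_study(cfg1)
  seeds <- attr(s1, "seeds")
  tr <- simulate_alive(cfg1, seed = seeds[1, 1])
  h <- simulate_captures(tr, cfg1, seed = seeds[1, 2])
  expect_identical(s1[[1]]$histories$detections, h$detections)
})

test_that("captured counts under phi = 1 follow the stated binomial law", {
  # with no mortality, distinct-captured ~ Bin(n, 1 - (1-p)^K)
  n0 <- 120; p <- 0.3; K <- 6
  cfg <- sim_config(n0, phi = 1, p = p, design = study_design(3, 2),
                    seed = 33, n_reps = 1000)
  reps <- simulate_study(cfg)
  counts <- vapply(reps, function(r) n_captured(r$histories), numeric(1))
  pr <- 1 - (1 - p)^K
  # chi-square goodness of fit against the exact binomial, alpha = 0.01
  qs <- qbinom(seq(0.1, 0.9, by = 0.2), n0, pr)
  breaks <- c(-Inf, qs, Inf)
  obs <- table(cut(counts, breaks))
  expp <- diff(pbinom(c(-Inf, qs, Inf), n0, pr))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = expp,
                                     rescale.p = TRUE))
  expect_gt(gof$p.value, 0.01)
})
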