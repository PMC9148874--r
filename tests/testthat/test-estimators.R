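beta1 <- thermo_state(1 / k_boltzmann) # beta = 1 in kcal/mol units

test_that("Zwanzig estimator on simple closed forms", {
  # constant perturbation transfers exactly
  expect_equal(zwanzig_fep(rep(2.5, 40), beta1)$delta_A, 2.5,
               tolerance = 1e-12)
  # two-point series at beta = 1: -log(mean(exp(-dU))) = -log(1.25)
  est <- zwanzig_fep(c(-log(2), log(2)), beta1)
  expect_equal(est$delta_A, -log(1.25), tolerance = 1e-12)
  # Gaussian dU: dA -> mu - beta sigma^2 / 2
  set.seed(1)
  du <- rnorm(2e5, mean = 2, sd = 1)
  est <- zwanzig_fep(du, beta1)
  expect_lt(abs(est$delta_A - 1.5), 3 * est$block_sd)
})

test_that("Zwanzig is overflow-safe and permutation invariant; block SD is
           reported absent for tiny series", {
  huge <- c(1e4, -1e4, 5e3, 0)
  est <- zwanzig_fep(huge, beta1)
  expect_true(is.finite(est$delta_A))
  set.seed(2)
  du <- rnorm(500, 1, 2)
  a <- zwanzig_fep(du, beta1)$delta_A
  b <- zwanzig_fep(sample(du), beta1)$delta_A
  expect_equal(a, b, tolerance = 1e-12)
  expect_true(is.na(zwanzig_fep(rnorm(8), beta1)$block_sd))
  expect_error(zwanzig_fep(numeric(1), beta1), "at least 2")
})

test_that("Jensen inequality holds exactly on empirical series", {
  set.seed(3)
  for (trial in 1:20) {
    du <- rnorm(200, runif(1, -3, 3), runif(1, 0.1, 4))
    est <- zwanzig_fep(du, beta1)
    expect_lte(est$delta_A, est$mean_du + 1e-12)
  }
})

test_that("BAR solves the harmonic pair and is antisymmetric", {
  set.seed(4)
  k1 <- 1; k2 <- 4
  exact <- 0.5 * log(k2 / k1)
  x0 <- harmonic_samples(1e5, k1, 1)
  x1 <- harmonic_samples(1e5, k2, 1)
  wf <- (k2 - k1) * x0^2
  wr <- (k1 - k2) * x1^2
  est <- bar(wf, wr, beta1)$delta_A
  # analytic BAR variance is below the one-sided FEP variance; 3 sigma with
  # a generous empirical scale
  expect_lt(abs(est - exact), 0.01)
  expect_equal(bar(wr, wf, beta1)$delta_A, -est, tolerance = 1e-9)
  expect_equal(bar(rep(0, 100), rep(0, 100), beta1)$delta_A, 0,
               tolerance = 1e-10)
})

test_that("MBAR: identical states, BAR agreement at K = 2, harmonic ladder
           at K = 3", {
  set.seed(5)
  # identical states give all-zero free energies
  u <- matrix(rnorm(300), 3, 100)
  u_id <- rbind(u[1, ], u[1, ], u[1, ])
  sol <- mbar(u_id, c(40, 30, 30))
  expect_equal(sol$f, c(0, 0, 0), tolerance = 1e-9)

  # K = 2 equals BAR to 1e-8
  k1 <- 1; k2 <- 4
  x0 <- harmonic_samples(2e4, k1, 1)
  x1 <- harmonic_samples(2e4, k2, 1)
  ub <- rbind(c(k1 * x0^2, k1 * x1^2), c(k2 * x0^2, k2 * x1^2))
  sol2 <- mbar(ub, c(2e4, 2e4))
  est_bar <- bar((k2 - k1) * x0^2, (k1 - k2) * x1^2, beta1,
                 tol = 1e-12)$delta_A
  expect_equal(sol2$f[2], est_bar, tolerance = 1e-8)

  # K = 3 ladder k in {1, 2, 4}: pairwise dA = 0.5 log(kj / ki)
  ks <- c(1, 2, 4)
  xs <- lapply(ks, function(k) harmonic_samples(3e4, k, 1))
  pooled <- unlist(xs)
  u3 <- do.call(rbind, lapply(ks, function(k) k * pooled^2))
  sol3 <- mbar(u3, rep(3e4, 3))
  for (j in 2:3)
    expect_lt(abs(sol3$f[j] - 0.5 * log(ks[j])), 0.02)
  expect_error(mbar(u3, c(1, 1, 1)), "match")
})

test_that("restraint release FEP: zero branch, one-point reduction,
           duplication invariance, never positive", {
  rs <- restraint_spec(1, 2, K = 1.5, r0 = 5.5)
  st <- thermo_state(298.15)
  expect_equal(restraint_off_fep(runif(50, 2, 5.4), rs, st)$delta_A, 0)
  expect_equal(restraint_off_fep(6.5, rs, st)$delta_A, -0.75,
               tolerance = 1e-12)
  set.seed(6)
  r <- runif(200, 4, 7)
  a <- restraint_off_fep(r, rs, st)$delta_A
  expect_equal(restraint_off_fep(rep(r, 2), rs, st)$delta_A, a,
               tolerance = 1e-12)
  expect_lte(a, 0)
})

test_that("standard-state correction: exact values and monotonicity", {
  st <- thermo_state(298.15)
  r_v0 <- (3 * 1661 / (4 * pi))^(1 / 3)   # ~7.35 A
  expect_equal(standard_state_correction(
    standard_state_spec(0, r_v0), st)$delta_A, 0, tolerance = 1e-10)
  # V_eff = V0 / 10 costs -kT log 10
  r10 <- (3 * 166.1 / (4 * pi))^(1 / 3)
  expect_equal(standard_state_correction(
    standard_state_spec(0, r10), st)$delta_A,
    -k_boltzmann * 298.15 * log(10), tolerance = 1e-10)
  # the r_min volume term at 0.27 A
  ss <- standard_state_correction(standard_state_spec(0.27, 6), st)
  expect_equal(ss$v_min_contribution, 4 / 3 * pi * 0.27^3,
               tolerance = 1e-12)
  expect_equal(round(ss$v_min_contribution, 2), 0.08)
  # releasing a wider restraint is less favourable: monotone increasing in
  # r_max (larger V_eff shrinks the V0/V_eff ratio)
  vals <- vapply(seq(5, 12, by = 0.5), function(rmax)
    standard_state_correction(standard_state_spec(0, rmax), st)$delta_A, 0)
  expect_true(all(diff(vals) > 0))
  expect_error(standard_state_spec(3, 2))
})

test_that("BAR variance does not exceed one-sided FEP variance on shared
           data", {
  set.seed(7)
  k1 <- 1; k2 <- 3
  reps <- 24
  ests <- t(vapply(seq_len(reps), function(r) {
    x0 <- harmonic_samples(2000, k1, 1)
    x1 <- harmonic_samples(2000, k2, 1)
    c(fep = zwanzig_fep((k2 - k1) * x0^2, beta1)$delta_A,
      bar = bar((k2 - k1) * x0^2, (k1 - k2) * x1^2, beta1)$delta_A)
  }, c(fep = 0, bar = 0)))
  expect_lt(var(ests[, "bar"]), var(ests[, "fep"]))
})
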