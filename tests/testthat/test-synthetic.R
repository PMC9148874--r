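test_that("toy systems have the advertised charge and region structure", {
  neu <- make_toy_system("chain-neutral", seed = 1)
  expect_equal(sum(neu$topology$atoms$charge), 0)
  chg <- make_toy_system("chain-charged", seed = 1)
  expect_equal(sum(chg$topology$atoms$charge), 1)
  cage <- make_toy_system("guest-in-cage", seed = 1)
  expect_equal(cage$topology$alchemical, 1:5)
  expect_setequal(cage$topology$frozen, 6:17)
  # at least one term of every bonded class
  for (sys in list(neu, chg, cage)) {
    expect_gt(nrow(sys$topology$bonds), 0)
    expect_gt(nrow(sys$topology$angles), 0)
    expect_gt(nrow(sys$topology$dihedrals), 0)
    expect_gt(nrow(sys$topology$impropers), 0)
  }
  expect_error(make_toy_system("no-such-kind", seed = 1))
  # deterministic given seed
  again <- make_toy_system("guest-in-cage", seed = 1)
  expect_identical(again$coords, cage$coords)
})

test_that("Metropolis chain reproduces the Gaussian of a 1-D harmonic
           coordinate", {
  # a tethered atom: U = k (x^2 + y^2 + z^2), each Cartesian coordinate is
  # an independent Gaussian with variance kT / (2k)
  k <- 1
  temp <- 1 / k_boltzmann           # beta = 1
  topo <- tethered_atom(k)
  cfg <- sampler_config(sweeps = 1e5, temperature = temp, width = 0.9,
                        thin = 1, burn = 500, seed = 31)
  tr <- metropolis_sample(topo, matrix(0, 1, 3), cfg)
  xs <- vapply(tr$coords, function(m) m[1, 1], 0)
  v <- var(xs)
  # standard error of the variance with autocorrelation-inflated n_eff
  rho <- cor(xs[-1], xs[-length(xs)])
  neff <- length(xs) * (1 - rho) / (1 + rho)
  se_v <- sqrt(2 / max(neff - 1, 1)) * 0.5
  expect_lt(abs(v - 0.5), 3 * se_v)
  expect_lt(abs(mean(xs)), 3 * sqrt(0.5 / neff))
})

test_that("mean potential energy satisfies equipartition for a harmonic
           system", {
  # three tethered atoms: 9 quadratic degrees of freedom
  topo <- topology(
    atoms = data.frame(name = c("A", "B", "C"), mass = 12, charge = 0,
                       epsilon = 0, sigma = 3),
    tethers = data.frame(atom = 1:3, k = c(2, 5, 11),
                         x = c(0, 4, -4), y = 0, z = 0))
  temp <- 300
  cfg <- sampler_config(sweeps = 3e4, temperature = temp, width = 0.25,
                        thin = 2, burn = 500, seed = 13)
  start <- matrix(c(0, 4, -4, 0, 0, 0, 0, 0, 0), 3, 3)
  tr <- metropolis_sample(topo, start, cfg)
  kT <- k_boltzmann * temp
  expected <- 9 / 2 * kT
  u <- tr$energy
  rho <- cor(u[-1], u[-length(u)])
  neff <- length(u) * (1 - rho) / (1 + rho)
  expect_lt(abs(mean(u) - expected), 3 * sd(u) / sqrt(neff))
})

test_that("degenerate proposal widths behave as documented", {
  topo <- tethered_atom(1)
  cfg0 <- sampler_config(sweeps = 50, temperature = 300, width = 0,
                         thin = 1, burn = 0, seed = 5)
  tr <- metropolis_sample(topo, matrix(1, 1, 3), cfg0)
  expect_equal(tr$acceptance, 1.0)
  expect_true(all(vapply(tr$coords, function(m) all(m == 1), TRUE)))
})

test_that("sampling is reproducible given the seed and records it", {
  sys <- make_toy_system("chain-neutral", seed = 2)
  cfg <- sampler_config(sweeps = 200, width = 0.12, thin = 5, burn = 50,
                        seed = 99)
  t1 <- metropolis_sample(sys$topology, sys$coords, cfg)
  t2 <- metropolis_sample(sys$topology, sys$coords, cfg)
  expect_identical(t1$coords, t2$coords)
  expect_equal(t1$seed, 99L)
})

test_that("parameter perturbation: identity, determinism and positivity", {
  topo <- make_toy_system("chain-neutral", seed = 1)$topology
  id <- perturb_parameters(topo, perturbation_spec(seed = 3))
  expect_equal(id$bonds, topo$bonds)
  expect_equal(id$angles, topo$angles)
  expect_equal(id$dihedrals, topo$dihedrals)
  expect_equal(id$atoms$charge, topo$atoms$charge)

  spec <- perturbation_spec(k_scale = c(0.8, 1.2), b0_shift = 0.05,
                            theta0_shift = 0.1, phase_shift = 0.2,
                            charge_scale = 0.9, seed = 17)
  p1 <- perturb_parameters(topo, spec)
  p2 <- perturb_parameters(topo, spec)
  expect_identical(p1, p2)
  expect_identical(p1$dihedrals$n, topo$dihedrals$n)  # multiplicities fixed
  expect_true(all(p1$bonds$kb > 0))
  expect_error(perturbation_spec(k_scale = c(-0.5, 1)), "k_scale")
})

test_that("harmonic force-constant perturbation has the analytic free-energy
           difference", {
  # tethered atom, k -> k2: Delta A = (3 / (2 beta)) log(k2 / k1) per atom
  k1 <- 1; k2 <- 1.3
  beta <- 1 / (k_boltzmann * 300)
  exact <- 3 / (2 * beta) * log(k2 / k1)
  topo1 <- tethered_atom(k1)
  topo2 <- tethered_atom(k2)
  cfg <- sampler_config(sweeps = 4e4, temperature = 300, width = 0.35,
                        thin = 2, burn = 500, seed = 77)
  tr <- metropolis_sample(topo1, matrix(0, 1, 3), cfg)
  du <- vapply(tr$coords, function(x)
    total_energy(topo2, x)$energy - total_energy(topo1, x)$energy, 0)
  est <- zwanzig_fep(du, thermo_state(300))
  expect_lt(abs(est$delta_A - exact), 3 * max(est$block_sd, 0.005))
})
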