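test_that("harmonic bond follows U = k (b - b0)^2 with zero force at rest", {
  topo <- two_atom_bond(kb = 100, b0 = 1.0)
  x_eq <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  ev <- bonded_energy_forces(topo, x_eq)
  expect_equal(ev$energy, 0)
  expect_equal(max(abs(ev$forces)), 0)

  x <- matrix(c(0, 0, 0, 1.1, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(bonded_energy_forces(topo, x)$energy, 100 * 0.1^2,
               tolerance = 1e-12)
})

test_that("analytic forces match central finite differences everywhere", {
  sys <- make_toy_system("chain-neutral", seed = 3)
  set.seed(11)
  for (trial in 1:4) {
    x <- sys$coords + matrix(rnorm(15, sd = 0.25), 5, 3)
    for (lam in list(lambda_state(1, 1), lambda_state(0.4, 0.7))) {
      fa <- total_energy(sys$topology, x, lam, forces = TRUE)$forces
      fn <- fd_forces(sys$topology, x, lam)
      expect_lt(max(abs(fa - fn)) / max(1, max(abs(fa))), 1e-6)
    }
  }
  # guest-in-cage exercises soft-core, restraint and frozen sites
  cage <- make_toy_system("guest-in-cage", seed = 3)
  x <- cage$coords
  x[1:5, ] <- x[1:5, ] + matrix(rnorm(15, sd = 0.2), 5, 3)
  for (lam in list(lambda_state(1, 1), lambda_state(0, 0.49))) {
    fa <- total_energy(cage$topology, x, lam, forces = TRUE)$forces
    fn <- fd_forces(cage$topology, x, lam)
    expect_lt(max(abs(fa - fn)) / max(1, max(abs(fa))), 1e-6)
  }
})

test_that("intramolecular forces sum to zero and energy is frame-invariant", {
  sys <- make_toy_system("chain-neutral", seed = 5)
  set.seed(21)
  x <- sys$coords + matrix(rnorm(15, sd = 0.2), 5, 3)
  ev <- total_energy(sys$topology, x, forces = TRUE)
  expect_equal(colSums(ev$forces), c(0, 0, 0), tolerance = 1e-10)

  shift <- matrix(rep(c(3.1, -2.2, 0.7), each = 5), 5, 3)
  expect_equal(total_energy(sys$topology, x + shift)$energy, ev$energy,
               tolerance = 1e-9)
  R <- rotation_matrix(c(1, 2, 3), 1.1)
  expect_equal(total_energy(sys$topology, x %*% t(R))$energy, ev$energy,
               tolerance = 1e-9)
})

test_that("colinear angle geometry yields finite energy and forces", {
  topo <- topology(
    atoms = data.frame(name = c("A", "B", "C"), mass = rep(12, 3),
                       charge = 0, epsilon = 0, sigma = 3),
    bonds = data.frame(i = c(1, 2), j = c(2, 3), kb = 300, b0 = 1.5),
    angles = data.frame(i = 1, j = 2, k = 3, ktheta = 50, theta0 = 1.9))
  x <- matrix(c(0, 0, 0, 1.5, 0, 0, 3, 0, 0), 3, 3, byrow = TRUE)
  ev <- total_energy(topo, x, forces = TRUE)
  expect_true(all(is.finite(ev$forces)))
  expect_true(is.finite(ev$energy))
})

test_that("soft-core LJ matches the closed form and its limits", {
  # lambda = 0: prefactor kills the interaction at any separation
  expect_equal(softcore_lj_pair(c(0, 0.5, 3), 0.3, 3.1, 0), c(0, 0, 0))
  # lambda = 1 recovers the standard LJ minimum at r = 2^(1/6) sigma
  expect_equal(softcore_lj_pair(2^(1 / 6) * 3.4, 0.25, 3.4, 1), -0.25,
               tolerance = 1e-12)
  # direct evaluation at lambda = 0.5, r = sigma, eps = 1
  expect_equal(softcore_lj_pair(1, 1, 1, 0.5),
               2 * ((1 / 1.5)^12 - (1 / 1.5)^6), tolerance = 1e-12)
  expect_equal(softcore_lj_pair(1, 1, 1, 0.5), -0.16017, tolerance = 1e-4)
  # finite at r = 0 for lambda < 1
  expect_true(is.finite(softcore_lj_pair(0, 1, 3.4, 0.99)))
  # equals plain LJ at lambda = 1 to machine precision
  r <- seq(0.8, 6, by = 0.37)
  plain <- 4 * 0.2 * ((3.2 / r)^12 - (3.2 / r)^6)
  expect_equal(softcore_lj_pair(r, 0.2, 3.2, 1), plain, tolerance = 1e-15)
})

test_that("alchemical scaling: identity at (1,1), dead electrostatics at 0", {
  cage <- make_toy_system("guest-in-cage", seed = 2)
  x <- cage$coords
  full <- nonbonded_energy_forces(cage$topology, x, lambda_state(1, 1))
  ref <- nonbonded_energy_forces(cage$topology, x)
  expect_equal(full$elec, ref$elec)
  expect_equal(full$vdw, ref$vdw)

  off <- nonbonded_energy_forces(cage$topology, x, lambda_state(0, 1))
  # all pairs involve at least one guest atom (cage sites are excluded from
  # nothing but carry charges too) - guest-guest and guest-cage terms die;
  # cage-cage pairs survive
  region <- cage$topology$alchemical
  topo_env <- cage$topology
  topo_env$atoms$charge[region] <- 0
  env_only <- nonbonded_energy_forces(topo_env, x, lambda_state(1, 1))
  expect_equal(off$elec, env_only$elec, tolerance = 1e-12)

  # intra-region pairs scale as lambda^2 (annihilation semantics)
  chain <- make_toy_system("chain-neutral", seed = 2)
  chain$topology$alchemical <- 1:5
  e1 <- nonbonded_energy_forces(chain$topology, chain$coords,
                                lambda_state(1, 1))$elec
  e05 <- nonbonded_energy_forces(chain$topology, chain$coords,
                                 lambda_state(0.5, 1))$elec
  expect_equal(e05, 0.25 * e1, tolerance = 1e-12)
})

test_that("flat-bottom restraint is zero below r0 and harmonic beyond", {
  rs <- restraint_spec(1, 2, K = 1.5, r0 = 5.5)
  expect_equal(flat_bottom_restraint(5.0, rs), 0)
  expect_equal(flat_bottom_restraint(5.5, rs), 0)
  expect_equal(flat_bottom_restraint(6.5, rs), 0.75)
  # continuity and differentiability at the boundary
  eps <- 1e-9
  expect_lt(flat_bottom_restraint(5.5 + eps, rs), 1e-15)
  # full-K convention
  rs2 <- restraint_spec(1, 2, K = 1.5, r0 = 5.5, half_factor = FALSE)
  expect_equal(flat_bottom_restraint(6.5, rs2), 1.5)
})

test_that("COM distance is symmetric, mass-scale invariant and validated", {
  x <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(com_distance(x, 1, 2, c(1, 1)), 2)
  expect_equal(com_distance(x, 1:2, 1:2, c(1, 1)), 0)
  set.seed(4)
  y <- matrix(rnorm(18), 6, 3)
  m <- runif(6, 1, 20)
  d1 <- com_distance(y, 1:3, 4:6, m)
  expect_equal(com_distance(y, 4:6, 1:3, m), d1)
  expect_equal(com_distance(y, 1:3, 4:6, 2 * m), d1)
  expect_error(com_distance(y, integer(0), 4:6, m), "non-empty")
})

test_that("invalid term indices and singular geometries raise errors", {
  expect_error(topology(
    atoms = data.frame(name = "A", mass = 12, charge = 0, epsilon = 0.1,
                       sigma = 3),
    bonds = data.frame(i = 1, j = 2, kb = 100, b0 = 1)),
    "out of range")
  expect_error(topology(
    atoms = data.frame(name = c("A", "B"), mass = 12, charge = 0,
                       epsilon = 0.1, sigma = 3),
    bonds = data.frame(i = 1, j = 1, kb = 100, b0 = 1)),
    "distinct")
  # overlapping charged pair: plain Coulomb is singular
  topo <- topology(atoms = data.frame(name = c("A", "B"), mass = 12,
                                      charge = c(0.5, -0.5), epsilon = 0,
                                      sigma = 3))
  x <- matrix(0, 2, 3)
  expect_error(total_energy(topo, x), "singular")
})
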