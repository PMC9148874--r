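make_training <- function(kind = "chain-neutral", target = NULL, n = 400,
                          seed = 7, noise = 0) {
  sys <- make_toy_system(kind, seed = seed)
  cfg <- sampler_config(sweeps = n * 4, width = 0.12, thin = 4, burn = 200,
                        seed = seed + 50)
  tr <- metropolis_sample(sys$topology, sys$coords, cfg)
  if (is.null(target)) target <- sys$topology
  tr <- evaluate_forces(target, tr)
  if (noise > 0) {
    set.seed(seed + 99)
    tr$forces <- lapply(tr$forces, function(f)
      f + matrix(rnorm(length(f), sd = noise), nrow(f), 3))
  }
  list(sys = sys, target = target,
       ts = training_set(sys$topology, tr, provenance = "target"))
}

test_that("noise-free synthetic forces give exact parameter recovery", {
  target <- perturb_parameters(
    make_toy_system("chain-neutral", seed = 7)$topology,
    perturbation_spec(k_scale = c(0.8, 1.2), b0_shift = 0.03,
                      theta0_shift = 0.05, phase_shift = 0, seed = 9))
  tt <- make_training(target = target)
  fit <- fit_bonded_parameters(tt$ts, prior_strength = 0)
  rel <- function(a, b) max(abs(a / b - 1))
  expect_lt(rel(fit$topology$bonds$kb, target$bonds$kb), 1e-8)
  expect_lt(rel(fit$topology$bonds$b0, target$bonds$b0), 1e-8)
  expect_lt(rel(fit$topology$angles$ktheta, target$angles$ktheta), 1e-8)
  expect_lt(rel(fit$topology$angles$theta0, target$angles$theta0), 1e-8)
  expect_lt(rel(fit$topology$dihedrals$K, target$dihedrals$K), 1e-7)
  expect_lt(rel(fit$topology$impropers$kpsi, target$impropers$kpsi), 1e-8)
  expect_lt(fit$rmse, 1e-5)
  expect_null(fit$negative_k)
})

test_that("with frozen equilibrium values only force constants move", {
  tt <- make_training()
  fit <- fit_bonded_parameters(tt$ts, prior_strength = 0, fit_x0 = FALSE)
  expect_equal(fit$topology$bonds$b0, tt$sys$topology$bonds$b0)
  expect_equal(fit$topology$angles$theta0, tt$sys$topology$angles$theta0)
  expect_lt(max(abs(fit$topology$bonds$kb / tt$sys$topology$bonds$kb - 1)),
            1e-8)
})

test_that("noisy forces give unbiased recovery within 3 standard errors", {
  tt <- make_training(n = 1200, noise = 0.1, seed = 12)
  fit <- fit_bonded_parameters(tt$ts, prior_strength = 1e-8)
  truth <- tt$sys$topology
  tab <- fit$param_table
  k_true <- c(truth$bonds$kb, truth$angles$ktheta, truth$dihedrals$K,
              truth$impropers$kpsi)
  k_fit <- tab$k
  k_se <- tab$se_k
  expect_true(all(abs(k_fit - k_true) <= 3 * k_se))
  x0_true <- c(truth$bonds$b0, truth$angles$theta0)
  harm <- tab$class %in% c("bond", "angle")
  expect_true(all(abs(tab$x0[harm] - x0_true) <= 3 * tab$se_x0[harm]))
})

test_that("residual after subtraction equals the pure bonded forces", {
  tt <- make_training(seed = 21)
  ts <- subtract_nonbonded_forces(tt$ts)
  sysc <- compile_system(tt$sys$topology, include_nonbonded = FALSE,
                         include_tethers = FALSE,
                         include_restraint = FALSE)
  for (s in seq(1, length(ts$coords), by = 37)) {
    fb <- bonded_energy_forces(tt$sys$topology, ts$coords[[s]])$forces
    expect_lt(max(abs(ts$forces[[s]] - fb)), 1e-9)
  }
  # with all charges and epsilons zero, subtraction is the identity
  topo0 <- tt$sys$topology
  topo0$atoms$charge[] <- 0
  topo0$atoms$epsilon[] <- 0
  tr0 <- evaluate_forces(topo0, trajectory(tt$ts$coords,
                                           species = topo0$atoms$name))
  ts0 <- subtract_nonbonded_forces(training_set(topo0, tr0))
  for (s in seq(1, length(ts0$coords), by = 61))
    expect_equal(ts0$forces[[s]], tr0$forces[[s]], tolerance = 1e-14)
})

test_that("charged species: external and internal subtraction give the same
           fit", {
  tt <- make_training("chain-charged", seed = 4)
  fit_internal <- fit_bonded_parameters(tt$ts, prior_strength = 1e-6)
  ts_ext <- subtract_nonbonded_forces(tt$ts)
  topo0 <- tt$sys$topology
  topo0$atoms$charge[] <- 0   # fit proceeds with charges zeroed
  ts_ext$topology <- topo0
  fit_external <- fit_bonded_parameters(ts_ext, prior_strength = 1e-6)
  expect_lt(max(abs(fit_internal$coef - fit_external$coef)), 1e-10)
})

test_that("ridge limits behave: infinite prior pulls to the prior mean,
           rank deficiency without prior errors out", {
  tt <- make_training(n = 120, seed = 31)
  fit_inf <- fit_bonded_parameters(tt$ts, prior_strength = 1e12)
  expect_lt(max(abs(fit_inf$coef)), 1e-3)

  # duplicated bond term makes the design collinear
  topo_dup <- tt$sys$topology
  topo_dup$bonds <- rbind(topo_dup$bonds, topo_dup$bonds[1, ])
  ts_dup <- tt$ts
  ts_dup$topology <- topo_dup
  expect_error(fit_bonded_parameters(ts_dup, prior_strength = 0),
               "prior_strength")
  fit_dup <- fit_bonded_parameters(ts_dup, prior_strength = 1e-6)
  expect_true(is.finite(fit_dup$rmse))
})

test_that("estimator consistency: residual RMSE decreases with the noise
           level", {
  rmses <- vapply(c(0.3, 0.1, 0.03), function(noise) {
    tt <- make_training(n = 300, noise = noise, seed = 42)
    fit_bonded_parameters(tt$ts, prior_strength = 1e-8)$rmse
  }, 0)
  expect_true(all(diff(rmses) < 0))
})

test_that("unfeasible dihedral amplitudes are flagged, not altered", {
  topo <- make_toy_system("chain-neutral", seed = 1)$topology
  topo$dihedrals$K <- c(60, 0.5, -55)
  fake_fit <- structure(list(topology = topo), class = "fit_result")
  fl <- flag_unfeasible_dihedrals(fake_fit, threshold = 50)
  expect_equal(fl$term, c(1L, 3L))
  expect_equal(fl$K, c(60, -55))
  expect_equal(nrow(flag_unfeasible_dihedrals(fake_fit, threshold = 100)), 0)
  # zero threshold flags every nonzero-amplitude term
  expect_equal(nrow(flag_unfeasible_dihedrals(fake_fit, threshold = 0)), 3)
})

test_that("force RMSE: zero at the generating parameters, |c| under a
           constant offset, permutation invariant", {
  tt <- make_training(seed = 51)
  expect_lt(force_rmse(tt$sys$topology, tt$ts), 1e-10)
  ts_off <- subtract_nonbonded_forces(tt$ts)
  c_off <- c(0.2, -0.1, 0.4)
  ts_off$forces <- lapply(ts_off$forces, function(f)
    sweep(f, 2, c_off, "+"))
  expect_equal(force_rmse(tt$sys$topology, ts_off),
               sqrt(mean(c_off^2)), tolerance = 1e-10)
})
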