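#' Monte Carlo sampler configuration
#'
#' @param sweeps number of recorded sweeps (one sweep = one trial move per
#'   movable atom); at least 1.
#' @param temperature Kelvin; 300 K matches the gas-phase fitting ensembles,
#'   298.15 K solution-style runs.
#' @param width per-coordinate uniform proposal half-width in Angstrom.
#' @param thin record every `thin`-th sweep.
#' @param burn discarded equilibration sweeps before recording starts.
#' @param trans_width half-width (Angstrom) of an additional rigid
#'   translation move of the whole movable group, attempted once per sweep;
#'   0 disables it. Essential for decorrelating the centre of mass of a
#'   weakly coupled guest inside a restraint volume.
#' @param rot_width half-width (radians) of an additional rigid rotation of
#'   the movable group about its centroid, attempted once per sweep; 0
#'   disables it. Decorrelates the orientation of a guest inside a cage.
#' @param seed integer seed (mandatory; echoed into trajectory output).
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(sweeps, temperature = 300, width = 0.15,
                           thin = 10, burn = 200, trans_width = 0,
                           rot_width = 0, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(sweeps >= 1, temperature > 0, width >= 0, thin >= 1, burn >= 0,
            trans_width >= 0, rot_width >= 0)
  structure(list(sweeps = as.integer(sweeps), temperature = temperature,
                 width = width, thin = as.integer(thin),
                 burn = as.integer(burn), trans_width = trans_width,
                 rot_width = rot_width, seed = as.integer(seed)),
            class = "sampler_config")
}

#' Metropolis Monte Carlo sampling of a topology at a lambda state
#'
#' Generates a Markov chain targeting the Boltzmann distribution
#' `exp(-U / kB T)` of the full potential (bonded, alchemically modified
#' nonbonded, tethers, COM restraint) using single-atom displacement moves.
#' Frozen atoms never move. Reproducible given `config$seed`.
#'
#' @param topo a [topology()].
#' @param start N x 3 starting coordinates (finite).
#' @param config a [sampler_config()].
#' @param lambda a [lambda_state()].
#' @return A [trajectory()] with per-frame energies, COM distances (when the
#'   topology carries restraint groups), the acceptance rate and the seed.
#' @export
metropolis_sample <- function(topo, start, config,
                              lambda = lambda_state()) {
  stopifnot(inherits(topo, "topology"), inherits(config, "sampler_config"),
            inherits(lambda, "lambda_state"))
  start <- check_coords(topo, start)
  sys <- compile_system(topo)
  if (length(sys$movable) == 0) stop("all atoms are frozen; nothing to move")
  beta <- 1 / (k_boltzmann * config$temperature)
  set.seed(config$seed)
  res <- cpp_metropolis(start, sys, lambda$elec, lambda$vdw, beta,
                        config$sweeps, config$width, config$thin,
                        config$burn, config$trans_width, config$rot_width)
  if (res$acceptance == 0)
    stop("Metropolis chain accepted no moves; reduce the proposal width")
  nsnap <- length(res$energy)
  arr <- array(res$coords, dim = c(nrow(start), 3, nsnap))
  coords <- lapply(seq_len(nsnap), function(s)
    matrix(arr[, , s], ncol = 3))
  trajectory(coords,
             species = topo$atoms$name,
             energy = as.numeric(res$energy),
             r_com = if (length(res$r_com)) as.numeric(res$r_com) else NULL,
             seed = config$seed,
             acceptance = res$acceptance)
}

#' Evaluate model forces over a trajectory
#'
#' Full analytic forces (bonded + nonbonded at full coupling, tethers,
#' restraint) for every frame; used to manufacture target-level training
#' forces from a stand-in high-level topology.
#'
#' @param topo a [topology()].
#' @param traj a [trajectory()].
#' @return A new [trajectory()] carrying force blocks.
#' @export
evaluate_forces <- function(topo, traj) {
  stopifnot(inherits(traj, "trajectory"))
  sys <- compile_system(topo)
  forces <- lapply(traj$coords, function(x)
    cpp_eval(check_coords(topo, x), sys, 1, 1, TRUE)$forces)
  trajectory(traj$coords, forces = forces, species = traj$species,
             energy = traj$energy, r_com = traj$r_com, seed = traj$seed,
             acceptance = traj$acceptance)
}
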