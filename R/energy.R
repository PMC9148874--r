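#' Bonded energy and analytic forces
#'
#' Evaluates bonds, angles, proper dihedral Fourier terms and impropers with
#' CHARMM conventions (`U = k (x - x0)^2` for harmonic terms, no 1/2).
#' Forces are analytic gradients; over a closed system they sum to the zero
#' vector.
#'
#' @param topo a [topology()].
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @param decompose if `TRUE`, return per-class energies.
#' @return list with `energy` (kcal/mol), `forces` (N x 3, kcal/mol/A) and,
#'   when requested, `components` (bond, angle, dihedral, improper).
#' @export
bonded_energy_forces <- function(topo, coords, decompose = FALSE) {
  coords <- check_coords(topo, coords)
  sys <- compile_system(topo, include_nonbonded = FALSE,
                        include_tethers = FALSE, include_restraint = FALSE)
  ev <- cpp_eval(coords, sys, 1, 1, TRUE)
  out <- list(energy = ev$total, forces = ev$forces)
  if (decompose)
    out$components <- c(bond = ev$components[1], angle = ev$components[2],
                        dihedral = ev$components[3],
                        improper = ev$components[4])
  out
}

#' Nonbonded energy components and forces at an alchemical state
#'
#' Electrostatics are computed with alchemical-region charges multiplied by
#' `lambda$elec` (annihilation semantics: intra-region pairs scale as
#' `lambda^2`). Lennard-Jones interactions between the region and its
#' environment use the soft-core form at `lambda$vdw`; all other LJ pairs are
#' unmodified. No cutoffs are applied.
#'
#' @param topo a [topology()].
#' @param coords N x 3 coordinate matrix.
#' @param lambda a [lambda_state()]; the default `(1, 1)` recovers the
#'   unmodified interactions.
#' @return list with `elec`, `vdw` (kcal/mol) and `forces` (N x 3).
#' @export
nonbonded_energy_forces <- function(topo, coords, lambda = lambda_state()) {
  coords <- check_coords(topo, coords)
  stopifnot(inherits(lambda, "lambda_state"))
  sys <- compile_system(topo, include_bonded = FALSE,
                        include_tethers = FALSE, include_restraint = FALSE)
  ev <- cpp_eval(coords, sys, lambda$elec, lambda$vdw, TRUE)
  list(elec = ev$components[5], vdw = ev$components[6], forces = ev$forces)
}

#' Total potential energy at an alchemical state
#'
#' Sum of bonded, nonbonded (at the given lambda state), tether and COM
#' restraint contributions.
#'
#' @inheritParams nonbonded_energy_forces
#' @param forces if `TRUE`, also return analytic forces.
#' @return list with `energy`, `components` (named, kcal/mol) and optionally
#'   `forces`.
#' @export
total_energy <- function(topo, coords, lambda = lambda_state(),
                         forces = FALSE) {
  coords <- check_coords(topo, coords)
  sys <- compile_system(topo)
  ev <- cpp_eval(coords, sys, lambda$elec, lambda$vdw, forces)
  out <- list(energy = ev$total,
              components = setNames(ev$components,
                                    c("bond", "angle", "dihedral",
                                      "improper", "elec", "vdw", "tether",
                                      "restraint")))
  if (forces) out$forces <- ev$forces
  out
}

#' Soft-core Lennard-Jones pair energy
#'
#' `U = 4 lambda epsilon [ (sigma / (r + sigma (1 - lambda)))^12 -
#' (sigma / (r + sigma (1 - lambda)))^6 ]`. Finite at r = 0 for
#' `lambda < 1`; at `lambda = 1` it reduces to the standard LJ pair energy.
#'
#' @param r pair distance in Angstrom (vectorised), r >= 0.
#' @param epsilon well depth in kcal/mol, `>= 0`.
#' @param sigma combined pair diameter in Angstrom, `> 0`.
#' @param lambda_vdw coupling in `[0, 1]`.
#' @return energy in kcal/mol.
#' @examples
#' softcore_lj_pair(2^(1 / 6) * 3.4, 0.1, 3.4, 1) # -0.1, the LJ minimum
#' @export
softcore_lj_pair <- function(r, epsilon, sigma, lambda_vdw) {
  stopifnot(all(r >= 0), all(epsilon >= 0), all(sigma > 0),
            all(lambda_vdw >= 0 & lambda_vdw <= 1))
  d <- r + sigma * (1 - lambda_vdw)
  s6 <- (sigma / d)^6
  4 * lambda_vdw * epsilon * (s6^2 - s6)
}

#' Flat-bottom restraint energy
#'
#' Zero for r < r0, `(1/2) K (r - r0)^2` at or beyond the offset
#' (`K (r - r0)^2` when the spec's `half_factor` is `FALSE`). Continuous and
#' once-differentiable at `r0`.
#'
#' @param r_com COM distance in Angstrom (vectorised), `>= 0`.
#' @param spec a [restraint_spec()].
#' @return energy in kcal/mol.
#' @export
flat_bottom_restraint <- function(r_com, spec) {
  stopifnot(inherits(spec, "restraint_spec"), all(r_com >= 0))
  pref <- if (spec$half_factor) 0.5 else 1
  ifelse(r_com < spec$r0, 0, pref * spec$K * (r_com - spec$r0)^2)
}

#' Mass-weighted centre-of-mass distance between two atom groups
#'
#' @param coords N x 3 coordinate matrix.
#' @param group_a,group_b non-empty integer vectors of atom indices.
#' @param masses per-atom masses (amu), length N.
#' @return Euclidean distance between the two mass-weighted centroids
#'   (Angstrom); symmetric in group order and invariant under a common
#'   rescaling of all masses.
#' @export
com_distance <- function(coords, group_a, group_b, masses) {
  stopifnot(is.matrix(coords), ncol(coords) == 3,
            length(masses) == nrow(coords), all(masses > 0))
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("groups must be non-empty")
  com <- function(g) colSums(coords[g, , drop = FALSE] * masses[g]) /
    sum(masses[g])
  sqrt(sum((com(group_a) - com(group_b))^2))
}

check_coords <- function(topo, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(topo$atoms) || ncol(coords) != 3)
    stop("coords must be an N x 3 matrix matching the topology")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  storage.mode(coords) <- "double"
  coords
}
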