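# Toy molecular systems used throughout: a five-atom branched chain with at
# least one term of every bonded class, optionally charged, optionally
# placed inside a rigid ring of charged LJ sites acting as a host cage.

guest_atoms <- function(charged) {
  data.frame(
    name = c("C1", "C2", "N3", "O4", "C5"),
    mass = c(12.011, 12.011, 14.007, 15.999, 12.011),
    charge = if (charged) c(0.45, -0.10, 0.30, 0.15, 0.20)
             else c(0.18, -0.32, 0.24, -0.20, 0.10),
    epsilon = c(0.10, 0.08, 0.12, 0.10, 0.05),
    sigma = c(3.4, 3.3, 3.5, 3.2, 2.8))
}

guest_bonded <- function() {
  list(
    bonds = data.frame(i = c(1, 2, 3, 2), j = c(2, 3, 4, 5),
                       kb = c(300, 280, 320, 260),
                       b0 = c(1.50, 1.48, 1.52, 1.45)),
    angles = data.frame(i = c(1, 2, 1, 5), j = c(2, 3, 2, 2),
                        k = c(3, 4, 5, 3),
                        ktheta = c(55, 60, 50, 48),
                        theta0 = c(1.95, 1.98, 1.91, 1.88)),
    dihedrals = data.frame(i = c(1, 1, 5), j = c(2, 2, 2), k = c(3, 3, 3),
                           l = c(4, 4, 4),
                           K = c(1.4, 0.5, 0.8), n = c(3, 1, 2),
                           delta = c(0, 0, pi)),
    impropers = data.frame(i = 2, j = 1, k = 3, l = 5, kpsi = 10,
                           psi0 = 0.5))
}

guest_coords <- function() {
  matrix(c(0.00, 0.00, 0.00,
           1.50, 0.00, 0.00,
           2.20, 1.30, 0.10,
           3.70, 1.35, 0.25,
           1.95, -1.05, 0.85), ncol = 3, byrow = TRUE)
}

#' Construct a toy molecular system
#'
#' Three deterministic test systems exercising every term class:
#' `"chain-neutral"` (net charge 0), `"chain-charged"` (net charge +1 e, the
#' case where internal nonbonded subtraction with the true charges matters),
#' and `"guest-in-cage"` (the neutral chain as an alchemical guest bound
#' inside a rigid icosahedral shell of twelve charged LJ sites, with a
#' flat-bottom COM restraint between guest and cage).
#'
#' @param kind one of `"chain-neutral"`, `"chain-charged"`,
#'   `"guest-in-cage"`.
#' @param seed integer seed; applies a small reproducible jitter to the
#'   reference coordinates so replicate systems are distinct but
#'   deterministic.
#' @return list with `topology` (a [topology()]), `coords` (N x 3 starting
#'   configuration), `kind` and `seed`.
#' @examples
#' sys <- make_toy_system("chain-neutral", seed = 1)
#' sum(sys$topology$atoms$charge) # 0
#' @export
make_toy_system <- function(kind = c("chain-neutral", "chain-charged",
                                     "guest-in-cage"), seed = 1) {
  kind <- match.arg(kind)
  b <- guest_bonded()
  gx <- guest_coords()
  if (kind %in% c("chain-neutral", "chain-charged")) {
    topo <- topology(guest_atoms(kind == "chain-charged"), b$bonds,
                     b$angles, b$dihedrals, b$impropers)
    coords <- gx
  } else {
    # rigid icosahedral shell of charged LJ sites: a closed cage whose
    # interior dispersion well binds the guest by several kcal/mol, so the
    # COM restraint rarely engages in the coupled bound state (the
    # assumption behind treating its release by one-sided FEP)
    ncage <- 12
    phi <- (1 + sqrt(5)) / 2
    ico <- rbind(c(0, 1, phi), c(0, 1, -phi), c(0, -1, phi), c(0, -1, -phi),
                 c(1, phi, 0), c(1, -phi, 0), c(-1, phi, 0), c(-1, -phi, 0),
                 c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
    cage_xyz <- 4.2 * ico / sqrt(1 + phi^2)
    cage <- data.frame(
      name = paste0("Q", seq_len(ncage)),
      mass = 16.0,
      charge = rep(c(0.25, -0.25), length.out = ncage),
      epsilon = 0.30, sigma = 3.0)
    atoms <- rbind(guest_atoms(FALSE), cage)
    restraint <- restraint_spec(group_a = 1:5, group_b = 5 + seq_len(ncage),
                                K = 1.5, r0 = 5.5)
    topo <- topology(atoms, b$bonds, b$angles, b$dihedrals, b$impropers,
                     alchemical = 1:5, frozen = 5 + seq_len(ncage),
                     restraint = restraint)
    centred <- sweep(gx, 2, colMeans(gx))
    coords <- rbind(centred, cage_xyz)
  }
  set.seed(seed)
  jit <- matrix(rnorm(length(coords), sd = 0.01), nrow = nrow(coords))
  if (length(topo$frozen)) jit[topo$frozen, ] <- 0
  list(topology = topo, coords = coords + jit, kind = kind, seed = seed)
}

#' Perturbation specification for a stand-in high-level Hamiltonian
#'
#' Defines a reproducible random perturbation of a parameter set, playing
#' the role of the gap between a classical force field and a higher-level
#' target Hamiltonian. Functional forms and dihedral multiplicities are
#' never changed.
#'
#' @param k_scale length-2 multiplicative range for all force constants
#'   (bonds, angles, dihedral amplitudes, impropers); must keep them
#'   positive.
#' @param b0_shift,theta0_shift,phase_shift maximum magnitudes of uniform
#'   additive shifts for bond lengths (A), equilibrium angles (rad), and
#'   dihedral phases / improper equilibria (rad).
#' @param charge_scale multiplicative factor applied to all partial charges.
#' @param seed integer seed making the perturbation deterministic.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(k_scale = c(1, 1), b0_shift = 0,
                              theta0_shift = 0, phase_shift = 0,
                              charge_scale = 1, seed = 1) {
  stopifnot(length(k_scale) == 2, all(k_scale > 0),
            b0_shift >= 0, theta0_shift >= 0, phase_shift >= 0,
            charge_scale > 0)
  structure(list(k_scale = sort(k_scale), b0_shift = b0_shift,
                 theta0_shift = theta0_shift, phase_shift = phase_shift,
                 charge_scale = charge_scale, seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Apply a parameter perturbation
#'
#' Returns a new topology with force constants scaled and equilibrium values
#' shifted according to `spec`; atom identities, functional forms and
#' dihedral multiplicities are untouched. Deterministic given `spec$seed`.
#'
#' @param topo a [topology()].
#' @param spec a [perturbation_spec()].
#' @return A perturbed [topology()].
#' @export
perturb_parameters <- function(topo, spec) {
  stopifnot(inherits(topo, "topology"), inherits(spec, "perturbation_spec"))
  set.seed(spec$seed)
  scale_k <- function(k) k * runif(length(k), spec$k_scale[1],
                                   spec$k_scale[2])
  shift <- function(x, s) x + runif(length(x), -s, s)
  out <- topo
  if (nrow(out$bonds)) {
    out$bonds$kb <- scale_k(out$bonds$kb)
    out$bonds$b0 <- shift(out$bonds$b0, spec$b0_shift)
  }
  if (nrow(out$angles)) {
    out$angles$ktheta <- scale_k(out$angles$ktheta)
    out$angles$theta0 <- shift(out$angles$theta0, spec$theta0_shift)
  }
  if (nrow(out$dihedrals)) {
    out$dihedrals$K <- scale_k(out$dihedrals$K)
    out$dihedrals$delta <- shift(out$dihedrals$delta, spec$phase_shift)
  }
  if (nrow(out$impropers)) {
    out$impropers$kpsi <- scale_k(out$impropers$kpsi)
    out$impropers$psi0 <- shift(out$impropers$psi0, spec$phase_shift)
  }
  out$atoms$charge <- out$atoms$charge * spec$charge_scale
  if (any(c(out$bonds$kb, out$angles$ktheta, out$impropers$kpsi) <= 0))
    stop("perturbation produced a non-positive force constant")
  out
}
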