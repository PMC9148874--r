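# shared fixtures, all built in code

# central finite-difference forces of the full potential
fd_forces <- function(topo, coords, lambda = lambda_state(), h = 1e-5) {
  n <- nrow(coords)
  f <- matrix(0, n, 3)
  for (i in seq_len(n)) for (d in 1:3) {
    xp <- coords; xm <- coords
    xp[i, d] <- xp[i, d] + h
    xm[i, d] <- xm[i, d] - h
    f[i, d] <- -(total_energy(topo, xp, lambda)$energy -
                   total_energy(topo, xm, lambda)$energy) / (2 * h)
  }
  f
}

# two-atom system with a single bond
two_atom_bond <- function(kb = 100, b0 = 1.0, charge = c(0, 0)) {
  topology(
    atoms = data.frame(name = c("A", "B"), mass = c(12, 12),
                       charge = charge, epsilon = c(0, 0),
                       sigma = c(3, 3)),
    bonds = data.frame(i = 1, j = 2, kb = kb, b0 = b0))
}

# one free atom on a Cartesian tether: three independent Gaussian
# coordinates with variance kT / (2 k) each
tethered_atom <- function(k = 1) {
  topology(
    atoms = data.frame(name = "A", mass = 12, charge = 0, epsilon = 0,
                       sigma = 3),
    tethers = data.frame(atom = 1, k = k, x = 0, y = 0, z = 0))
}

# samples of a 1-D harmonic oscillator U = k x^2 at inverse temperature b
harmonic_samples <- function(n, k, b) rnorm(n, sd = sqrt(1 / (2 * b * k)))

random_chain_coords <- function(n = 5, sd = 1.2) {
  matrix(rnorm(3 * n, sd = sd), n, 3)
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
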