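#' Molecular topology with CHARMM-style parameters
#'
#' Container for atoms and bonded/nonbonded parameters of a small molecular
#' system. Energy conventions: bonds and angles are `U = k (x - x0)^2`
#' (CHARMM, no factor 1/2), proper dihedrals are Fourier terms
#' `U = K (1 + cos(n phi - delta))`, impropers are harmonic in the dihedral
#' angle `U = k (psi - psi0)^2`. Nonbonded pairs use Lorentz-Berthelot
#' combination (`sigma_ij = (sigma_i + sigma_j)/2`,
#' `epsilon_ij = sqrt(epsilon_i epsilon_j)`), with 1-2 and 1-3 pairs excluded
#' and 1-4 pairs included at full strength. All angles are radians internally.
#'
#' @param atoms data.frame with columns `name`, `mass` (amu), `charge` (e),
#'   `epsilon` (kcal/mol), `sigma` (Angstrom).
#' @param bonds data.frame with columns `i`, `j`, `kb` (kcal/mol/A^2),
#'   `b0` (A); 1-based atom indices.
#' @param angles data.frame with columns `i`, `j`, `k`, `ktheta`
#'   (kcal/mol/rad^2), `theta0` (rad).
#' @param dihedrals data.frame with columns `i`, `j`, `k`, `l`, `K`
#'   (kcal/mol), `n` (positive integer multiplicity), `delta` (rad); one row
#'   per Fourier term, several rows may share the same atom quadruple.
#' @param impropers data.frame with columns `i`, `j`, `k`, `l`, `kpsi`
#'   (kcal/mol/rad^2), `psi0` (rad).
#' @param alchemical integer vector of atom indices forming the alchemical
#'   (decoupled) region.
#' @param tethers data.frame with columns `atom`, `k` (kcal/mol/A^2), `x`,
#'   `y`, `z`: Cartesian harmonic tethers `U = k |r - r_ref|^2` summed per
#'   coordinate.
#' @param frozen integer vector of atom indices held fixed during sampling.
#' @param restraint optional [restraint_spec()] bound to this system.
#' @return An object of class `topology`.
#' @export
topology <- function(atoms, bonds = NULL, angles = NULL, dihedrals = NULL,
                     impropers = NULL, alchemical = integer(),
                     tethers = NULL, frozen = integer(), restraint = NULL) {
  atoms <- as.data.frame(atoms)
  need <- c("name", "mass", "charge", "epsilon", "sigma")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  n <- nrow(atoms)
  if (n < 1) stop("topology needs at least one atom")
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("atom masses must be positive")
  if (any(atoms$epsilon < 0) || any(atoms$sigma <= 0))
    stop("LJ epsilon must be >= 0 and sigma > 0")

  empty <- function(cols) as.data.frame(setNames(
    rep(list(numeric(0)), length(cols)), cols))
  bonds <- if (is.null(bonds)) empty(c("i", "j", "kb", "b0")) else
    as.data.frame(bonds)
  angles <- if (is.null(angles)) empty(c("i", "j", "k", "ktheta", "theta0"))
    else as.data.frame(angles)
  dihedrals <- if (is.null(dihedrals))
    empty(c("i", "j", "k", "l", "K", "n", "delta")) else
    as.data.frame(dihedrals)
  impropers <- if (is.null(impropers))
    empty(c("i", "j", "k", "l", "kpsi", "psi0")) else as.data.frame(impropers)
  tethers <- if (is.null(tethers)) empty(c("atom", "k", "x", "y", "z")) else
    as.data.frame(tethers)

  check_idx <- function(df, cols, what) {
    for (cn in cols) {
      v <- df[[cn]]
      if (any(v < 1 | v > n | v != round(v)))
        stop(what, " atom indices out of range")
    }
    if (nrow(df) > 0) {
      idx <- as.matrix(df[cols])
      if (any(apply(idx, 1, function(r) anyDuplicated(r) > 0)))
        stop(what, " terms must reference distinct atoms")
    }
  }
  check_idx(bonds, c("i", "j"), "bond")
  check_idx(angles, c("i", "j", "k"), "angle")
  check_idx(dihedrals, c("i", "j", "k", "l"), "dihedral")
  check_idx(impropers, c("i", "j", "k", "l"), "improper")
  if (nrow(dihedrals) > 0 &&
      any(dihedrals$n < 1 | dihedrals$n != round(dihedrals$n)))
    stop("dihedral multiplicities must be positive integers")
  if (any(bonds$kb < 0) || any(angles$ktheta < 0) || any(impropers$kpsi < 0))
    stop("harmonic force constants must be >= 0")
  alchemical <- as.integer(alchemical)
  if (any(alchemical < 1 | alchemical > n))
    stop("alchemical region indices out of range")
  frozen <- as.integer(frozen)
  if (any(frozen < 1 | frozen > n)) stop("frozen indices out of range")
  if (nrow(tethers) > 0 && (any(tethers$atom < 1 | tethers$atom > n) ||
                            any(tethers$k < 0)))
    stop("invalid tether specification")
  if (!is.null(restraint) && !inherits(restraint, "restraint_spec"))
    stop("restraint must be a restraint_spec")

  structure(list(atoms = atoms, bonds = bonds, angles = angles,
                 dihedrals = dihedrals, impropers = impropers,
                 alchemical = alchemical, tethers = tethers,
                 frozen = frozen, restraint = restraint),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf(paste0("topology: %d atoms (net charge %+.3f e), %d bonds, ",
                     "%d angles, %d dihedral terms, %d impropers\n"),
              nrow(x$atoms), sum(x$atoms$charge), nrow(x$bonds),
              nrow(x$angles), nrow(x$dihedrals), nrow(x$impropers)))
  if (length(x$alchemical))
    cat("  alchemical region:", paste(x$alchemical, collapse = " "), "\n")
  if (length(x$frozen))
    cat("  frozen atoms:", paste(x$frozen, collapse = " "), "\n")
  if (!is.null(x$restraint))
    cat(sprintf("  COM restraint: K = %g kcal/mol/A^2, r0 = %g A\n",
                x$restraint$K, x$restraint$r0))
  invisible(x)
}

#' Flat-bottom centre-of-mass restraint specification
#'
#' The restraint is zero for COM distances below `r0` and
#' `(1/2) K (r - r0)^2` at or beyond it, holding a guest near its host
#' without biasing the bound ensemble.
#'
#' @param group_a,group_b disjoint, non-empty integer vectors of atom indices.
#' @param K force constant in kcal/mol/A^2 (default 1.5).
#' @param r0 offset distance in Angstrom (default 5.5).
#' @param half_factor logical; `TRUE` (default) uses the explicit 1/2 in the
#'   harmonic branch. Set `FALSE` for the `K (r - r0)^2` convention.
#' @return An object of class `restraint_spec`.
#' @export
restraint_spec <- function(group_a, group_b, K = 1.5, r0 = 5.5,
                           half_factor = TRUE) {
  group_a <- as.integer(group_a); group_b <- as.integer(group_b)
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("restraint groups must be non-empty")
  if (length(intersect(group_a, group_b)) > 0)
    stop("restraint groups must be disjoint")
  stopifnot(K >= 0, r0 > 0)
  structure(list(group_a = group_a, group_b = group_b, K = K, r0 = r0,
                 half_factor = isTRUE(half_factor)),
            class = "restraint_spec")
}

#' An alchemical lambda state
#'
#' @param elec electrostatic coupling in `[0, 1]` (scales region charges).
#' @param vdw van der Waals coupling in `[0, 1]` (soft-core strength for
#'   region-environment pairs).
#' @param index optional integer state index.
#' @export
lambda_state <- function(elec = 1, vdw = 1, index = NA_integer_) {
  stopifnot(is.numeric(elec), is.numeric(vdw),
            elec >= 0, elec <= 1, vdw >= 0, vdw <= 1)
  structure(list(elec = elec, vdw = vdw, index = as.integer(index)),
            class = "lambda_state")
}

# Build the flat C++-facing system description. 1-based R indices become
# 0-based. Exclusions: 1-2 and 1-3 pairs removed from the nonbonded list.
compile_system <- function(topo, include_nonbonded = TRUE,
                           include_bonded = TRUE, include_tethers = TRUE,
                           include_restraint = TRUE, zero_charges = FALSE) {
  n <- nrow(topo$atoms)
  adj <- vector("list", n)
  if (nrow(topo$bonds) > 0) {
    for (t in seq_len(nrow(topo$bonds))) {
      i <- topo$bonds$i[t]; j <- topo$bonds$j[t]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  excl <- new.env(hash = TRUE)
  mark <- function(i, j) assign(paste(min(i, j), max(i, j)), TRUE,
                                envir = excl)
  for (i in seq_len(n)) {
    for (j in adj[[i]]) {
      mark(i, j)                       # 1-2
      for (k in adj[[j]]) if (k != i) mark(i, k)  # 1-3
    }
  }
  pi <- integer(0); pj <- integer(0)
  if (include_nonbonded && n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (!exists(paste(i, j), envir = excl)) {
        pi <- c(pi, i); pj <- c(pj, j)
      }
    }
  }
  region <- rep(FALSE, n); region[topo$alchemical] <- TRUE
  q <- if (zero_charges) rep(0, n) else topo$atoms$charge
  qq <- q[pi] * q[pj] * cpp_coulomb_constant()
  eps <- sqrt(topo$atoms$epsilon[pi] * topo$atoms$epsilon[pj])
  sig <- (topo$atoms$sigma[pi] + topo$atoms$sigma[pj]) / 2
  escale <- as.integer(region[pi]) + as.integer(region[pj])
  softcore <- as.integer(xor(region[pi], region[pj]))

  tomat <- function(df, cols) {
    m <- as.matrix(df[cols]); storage.mode(m) <- "integer"
    matrix(m - 1L, nrow = nrow(df))
  }
  b <- topo$bonds; a <- topo$angles; d <- topo$dihedrals; im <- topo$impropers
  if (!include_bonded) {
    b <- b[0, ]; a <- a[0, ]; d <- d[0, ]; im <- im[0, ]
  }
  te <- if (include_tethers) topo$tethers else topo$tethers[0, ]
  restr <- list(on = FALSE, ga = integer(0), gb = integer(0),
                masses = topo$atoms$mass, K = 0, r0 = 1)
  rs <- topo$restraint
  if (!is.null(rs)) {
    restr$ga <- rs$group_a - 1L
    restr$gb <- rs$group_b - 1L
    if (include_restraint) {
      restr$on <- TRUE
      restr$K <- if (rs$half_factor) rs$K else 2 * rs$K
      restr$r0 <- rs$r0
    }
  }
  movable <- setdiff(seq_len(n), topo$frozen) - 1L
  list(natoms = n,
       pairs = list(i = pi - 1L, j = pj - 1L, qq = as.numeric(qq),
                    eps = as.numeric(eps), sig = as.numeric(sig),
                    softcore = softcore, escale = escale),
       bonds = tomat(b, c("i", "j")), kb = as.numeric(b$kb),
       b0 = as.numeric(b$b0),
       angles = tomat(a, c("i", "j", "k")), kt = as.numeric(a$ktheta),
       t0 = as.numeric(a$theta0),
       dih = tomat(d, c("i", "j", "k", "l")), dK = as.numeric(d$K),
       dn = as.integer(d$n), ddelta = as.numeric(d$delta),
       imp = tomat(im, c("i", "j", "k", "l")), kimp = as.numeric(im$kpsi),
       psi0 = as.numeric(im$psi0),
       teth_atom = as.integer(te$atom) - 1L, teth_k = as.numeric(te$k),
       teth_pos = matrix(c(te$x, te$y, te$z), nrow = nrow(te)),
       restr = restr,
       movable = as.integer(movable))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Write a topology to a structured-text parameter file
#'
#' Sections `[atoms]`, `[bonds]`, `[angles]`, `[dihedrals]`, `[impropers]`,
#' `[tethers]`, `[alchemical]`, `[frozen]`, `[restraint]`. Angular quantities
#' are written in degrees; the reader converts back to radians, so
#' `read_topology(write_topology(x, f))` round-trips.
#'
#' @param topo a [topology()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_topology <- function(topo, file) {
  fmt <- function(x) sprintf("%.12g", x)
  ln <- c("# alchemfep topology file",
          "# units: kcal/mol, Angstrom, degrees (angles in file)")
  ln <- c(ln, "[atoms]", "# name mass charge epsilon sigma")
  a <- topo$atoms
  ln <- c(ln, paste(a$name, fmt(a$mass), fmt(a$charge), fmt(a$epsilon),
                    fmt(a$sigma)))
  if (nrow(topo$bonds)) {
    b <- topo$bonds
    ln <- c(ln, "[bonds]", "# i j kb b0",
            paste(b$i, b$j, fmt(b$kb), fmt(b$b0)))
  }
  if (nrow(topo$angles)) {
    g <- topo$angles
    ln <- c(ln, "[angles]", "# i j k ktheta theta0_deg",
            paste(g$i, g$j, g$k, fmt(g$ktheta), fmt(rad2deg(g$theta0))))
  }
  if (nrow(topo$dihedrals)) {
    d <- topo$dihedrals
    ln <- c(ln, "[dihedrals]", "# i j k l K n delta_deg",
            paste(d$i, d$j, d$k, d$l, fmt(d$K), d$n, fmt(rad2deg(d$delta))))
  }
  if (nrow(topo$impropers)) {
    im <- topo$impropers
    ln <- c(ln, "[impropers]", "# i j k l kpsi psi0_deg",
            paste(im$i, im$j, im$k, im$l, fmt(im$kpsi),
                  fmt(rad2deg(im$psi0))))
  }
  if (nrow(topo$tethers)) {
    te <- topo$tethers
    ln <- c(ln, "[tethers]", "# atom k x y z",
            paste(te$atom, fmt(te$k), fmt(te$x), fmt(te$y), fmt(te$z)))
  }
  if (length(topo$alchemical))
    ln <- c(ln, "[alchemical]", paste(topo$alchemical, collapse = " "))
  if (length(topo$frozen))
    ln <- c(ln, "[frozen]", paste(topo$frozen, collapse = " "))
  if (!is.null(topo$restraint)) {
    r <- topo$restraint
    ln <- c(ln, "[restraint]",
            paste0("group_a = ", paste(r$group_a, collapse = " ")),
            paste0("group_b = ", paste(r$group_b, collapse = " ")),
            paste0("K = ", fmt(r$K)), paste0("r0 = ", fmt(r$r0)),
            paste0("half_factor = ", ifelse(r$half_factor, "true", "false")))
  }
  writeLines(ln, file)
  invisible(file)
}

#' Read a topology from a structured-text parameter file
#'
#' @param file path written by [write_topology()] (or hand-edited in the same
#'   schema; angles in degrees).
#' @return A [topology()].
#' @export
read_topology <- function(file) {
  raw <- readLines(file)
  raw <- trimws(sub("#.*$", "", raw))
  raw <- raw[nzchar(raw)]
  sec <- NULL
  parts <- list()
  for (line in raw) {
    if (grepl("^\\[", line)) {
      sec <- gsub("[][]", "", line)
      parts[[sec]] <- character(0)
    } else {
      if (is.null(sec)) stop("content before first section in ", file)
      parts[[sec]] <- c(parts[[sec]], line)
    }
  }
  tok <- function(lines) lapply(strsplit(lines, "\\s+"), identity)
  num <- function(tt, k) vapply(tt, function(x) as.numeric(x[k]), 0)
  int <- function(tt, k) vapply(tt, function(x) as.integer(x[k]), 0L)

  tt <- tok(parts[["atoms"]])
  atoms <- data.frame(name = vapply(tt, `[`, "", 1), mass = num(tt, 2),
                      charge = num(tt, 3), epsilon = num(tt, 4),
                      sigma = num(tt, 5))
  getdf <- function(name, fn) if (is.null(parts[[name]])) NULL else
    fn(tok(parts[[name]]))
  bonds <- getdf("bonds", function(tt) data.frame(
    i = int(tt, 1), j = int(tt, 2), kb = num(tt, 3), b0 = num(tt, 4)))
  angles <- getdf("angles", function(tt) data.frame(
    i = int(tt, 1), j = int(tt, 2), k = int(tt, 3), ktheta = num(tt, 4),
    theta0 = deg2rad(num(tt, 5))))
  dihedrals <- getdf("dihedrals", function(tt) data.frame(
    i = int(tt, 1), j = int(tt, 2), k = int(tt, 3), l = int(tt, 4),
    K = num(tt, 5), n = int(tt, 6), delta = deg2rad(num(tt, 7))))
  impropers <- getdf("impropers", function(tt) data.frame(
    i = int(tt, 1), j = int(tt, 2), k = int(tt, 3), l = int(tt, 4),
    kpsi = num(tt, 5), psi0 = deg2rad(num(tt, 6))))
  tethers <- getdf("tethers", function(tt) data.frame(
    atom = int(tt, 1), k = num(tt, 2), x = num(tt, 3), y = num(tt, 4),
    z = num(tt, 5)))
  alch <- if (is.null(parts[["alchemical"]])) integer() else
    as.integer(unlist(strsplit(parts[["alchemical"]], "\\s+")))
  frozen <- if (is.null(parts[["frozen"]])) integer() else
    as.integer(unlist(strsplit(parts[["frozen"]], "\\s+")))
  restraint <- NULL
  if (!is.null(parts[["restraint"]])) {
    kv <- list()
    for (line in parts[["restraint"]]) {
      sp <- strsplit(line, "=")[[1]]
      kv[[trimws(sp[1])]] <- trimws(sp[2])
    }
    restraint <- restraint_spec(
      group_a = as.integer(strsplit(kv$group_a, "\\s+")[[1]]),
      group_b = as.integer(strsplit(kv$group_b, "\\s+")[[1]]),
      K = as.numeric(kv$K), r0 = as.numeric(kv$r0),
      half_factor = identical(tolower(kv$half_factor), "true"))
  }
  topology(atoms, bonds, angles, dihedrals, impropers, alch, tethers,
           frozen, restraint)
}
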