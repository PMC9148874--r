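#' Trajectory of configurations
#'
#' @param coords list of N x 3 coordinate matrices (Angstrom).
#' @param forces optional list of N x 3 force matrices (kcal/mol/A),
#'   congruent with `coords`.
#' @param species character vector of atom names (recycled across frames).
#' @param energy optional per-frame potential energies (kcal/mol).
#' @param r_com optional per-frame COM distances (Angstrom).
#' @param seed seed used to generate the trajectory, echoed into file
#'   headers.
#' @param acceptance Monte Carlo acceptance rate, if applicable.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(coords, forces = NULL, species = NULL, energy = NULL,
                       r_com = NULL, seed = NA_integer_, acceptance = NA) {
  stopifnot(is.list(coords), length(coords) >= 1)
  n <- nrow(coords[[1]])
  for (x in coords)
    if (!is.matrix(x) || nrow(x) != n || ncol(x) != 3 || !all(is.finite(x)))
      stop("coords must be a list of congruent finite N x 3 matrices")
  if (!is.null(forces)) {
    if (length(forces) != length(coords))
      stop("forces must be congruent with coords")
    for (f in forces)
      if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3 ||
          !all(is.finite(f)))
        stop("forces must be a list of congruent finite N x 3 matrices")
  }
  if (is.null(species)) species <- rep("X", n)
  structure(list(coords = coords, forces = forces, species = species,
                 energy = energy, r_com = r_com, seed = seed,
                 acceptance = acceptance),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, %d atoms%s%s\n", length(x$coords),
              nrow(x$coords[[1]]),
              if (!is.null(x$forces)) ", with forces" else "",
              if (!is.na(x$acceptance))
                sprintf(", MC acceptance %.3f", x$acceptance) else ""))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$coords)

#' Write a trajectory to extended-XYZ
#'
#' One block per frame: atom count, a comment line carrying a `Properties=`
#' descriptor plus `key=value` metadata (seed, energy), then one row per atom
#' with species, position and, when present, force columns `fx fy fz`.
#'
#' @param traj a [trajectory()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_xyz <- function(traj, file) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(file, "w")
  on.exit(close(con))
  nat <- nrow(traj$coords[[1]])
  has_f <- !is.null(traj$forces)
  props <- if (has_f) "Properties=species:S:1:pos:R:3:forces:R:3" else
    "Properties=species:S:1:pos:R:3"
  for (s in seq_along(traj$coords)) {
    meta <- props
    if (!is.na(traj$seed)) meta <- paste0(meta, " seed=", traj$seed)
    if (!is.null(traj$energy))
      meta <- paste0(meta, sprintf(" energy=%.10g", traj$energy[s]))
    writeLines(c(as.character(nat), meta), con)
    x <- traj$coords[[s]]
    if (has_f) {
      f <- traj$forces[[s]]
      writeLines(sprintf("%s %.10g %.10g %.10g %.10g %.10g %.10g",
                         traj$species, x[, 1], x[, 2], x[, 3],
                         f[, 1], f[, 2], f[, 3]), con)
    } else {
      writeLines(sprintf("%s %.10g %.10g %.10g", traj$species,
                         x[, 1], x[, 2], x[, 3]), con)
    }
  }
  invisible(file)
}

#' Read an extended-XYZ trajectory
#'
#' Recognises a `forces:R:3` block in the `Properties=` descriptor; per-frame
#' `energy=` and `seed=` metadata are recovered when present.
#'
#' @param file path to an extended-XYZ file.
#' @return A [trajectory()].
#' @export
read_xyz <- function(file) {
  ln <- readLines(file)
  pos <- 1
  coords <- list(); forces <- list(); energies <- numeric(0)
  species <- NULL; seed <- NA_integer_; any_forces <- FALSE
  while (pos <= length(ln)) {
    if (!nzchar(trimws(ln[pos]))) { pos <- pos + 1; next }
    nat <- as.integer(trimws(ln[pos]))
    if (is.na(nat)) stop("malformed XYZ: expected atom count at line ", pos)
    comment <- ln[pos + 1]
    has_f <- grepl("forces:R:3", comment, fixed = TRUE)
    m <- regmatches(comment, regexec("energy=([-0-9.eE+]+)", comment))[[1]]
    if (length(m) == 2) energies <- c(energies, as.numeric(m[2]))
    m <- regmatches(comment, regexec("seed=([0-9]+)", comment))[[1]]
    if (length(m) == 2) seed <- as.integer(m[2])
    rows <- ln[(pos + 2):(pos + 1 + nat)]
    tt <- strsplit(trimws(rows), "\\s+")
    if (is.null(species)) species <- vapply(tt, `[`, "", 1)
    xyz <- t(vapply(tt, function(r) as.numeric(r[2:4]), numeric(3)))
    coords[[length(coords) + 1]] <- xyz
    if (has_f) {
      any_forces <- TRUE
      forces[[length(forces) + 1]] <-
        t(vapply(tt, function(r) as.numeric(r[5:7]), numeric(3)))
    }
    pos <- pos + 2 + nat
  }
  trajectory(coords,
             forces = if (any_forces) forces else NULL,
             species = species,
             energy = if (length(energies) == length(coords)) energies else
               NULL,
             seed = seed)
}
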