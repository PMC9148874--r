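#' Training set for force matching
#'
#' Couples a topology (supplying the functional forms, multiplicities and
#' phases to be kept fixed) with configurations carrying target-level
#' per-atom forces.
#'
#' @param topo a [topology()].
#' @param traj a [trajectory()] whose frames carry force blocks.
#' @param provenance free-text tag recording which Hamiltonian produced the
#'   forces.
#' @return An object of class `training_set`.
#' @export
training_set <- function(topo, traj, provenance = "") {
  stopifnot(inherits(topo, "topology"), inherits(traj, "trajectory"))
  if (is.null(traj$forces))
    stop("training set requires target forces on every configuration")
  if (nrow(traj$coords[[1]]) != nrow(topo$atoms))
    stop("trajectory and topology atom counts differ")
  structure(list(topology = topo, coords = traj$coords,
                 forces = traj$forces, provenance = provenance,
                 subtracted = FALSE),
            class = "training_set")
}

#' Subtract classical nonbonded forces from target forces
#'
#' Removes LJ and Coulomb forces computed with the molecule's actual partial
#' charges (never auto-neutralised, which matters for charged species) from
#' the target forces, leaving the bonded residual that the fit sees.
#'
#' @param ts a [training_set()].
#' @return The training set with residual forces and `subtracted = TRUE`.
#' @export
subtract_nonbonded_forces <- function(ts) {
  stopifnot(inherits(ts, "training_set"))
  if (ts$subtracted) return(ts)
  sys <- compile_system(ts$topology, include_bonded = FALSE,
                        include_tethers = FALSE, include_restraint = FALSE)
  for (s in seq_along(ts$coords)) {
    nb <- cpp_eval(ts$coords[[s]], sys, 1, 1, TRUE)$forces
    ts$forces[[s]] <- ts$forces[[s]] - nb
  }
  ts$subtracted <- TRUE
  ts
}

# Linearised bonded parameter space: harmonic terms enter through the pair
# (k, 2 k x0); each dihedral Fourier amplitude is linear at fixed (n, delta).
param_layout <- function(topo, fit_x0) {
  per_harm <- if (fit_x0) 2L else 1L
  nb <- nrow(topo$bonds); na <- nrow(topo$angles)
  nd <- nrow(topo$dihedrals); ni <- nrow(topo$impropers)
  list(per_harm = per_harm,
       n_par = per_harm * (nb + na + ni) + nd,
       nb = nb, na = na, nd = nd, ni = ni)
}

# Collapse the raw two-column harmonic basis to one column per term when
# equilibrium values are frozen at their input values:
# -grad (b - b0)^2 = -grad b^2 + 2 b0 grad b.
reduce_basis <- function(X, topo, fit_x0) {
  if (fit_x0) return(X)
  lay <- param_layout(topo, TRUE)
  cols <- list(); x0s <- c(topo$bonds$b0, topo$angles$theta0)
  idx <- 1
  out <- matrix(0, nrow(X), param_layout(topo, FALSE)$n_par)
  oc <- 1
  for (t in seq_len(lay$nb + lay$na)) {
    out[, oc] <- X[, idx] + 2 * x0s[t] * X[, idx + 1]
    idx <- idx + 2; oc <- oc + 1
  }
  if (lay$nd > 0) {
    out[, oc:(oc + lay$nd - 1)] <- X[, idx:(idx + lay$nd - 1)]
    idx <- idx + lay$nd; oc <- oc + lay$nd
  }
  if (lay$ni > 0) {
    p0 <- topo$impropers$psi0
    for (t in seq_len(lay$ni)) {
      out[, oc] <- X[, idx] + 2 * p0[t] * X[, idx + 1]
      idx <- idx + 2; oc <- oc + 1
    }
  }
  out
}

#' Fit bonded parameters to residual target forces
#'
#' Ridge-regularised linear least squares in the linearised parameter space
#' (the maximum a posteriori estimate under an isotropic zero-mean Gaussian
#' prior on the linear coefficients). Functional forms, dihedral
#' multiplicities and phases are fixed to those in the training topology.
#' If nonbonded forces have not been subtracted yet, they are removed
#' internally using the molecule's true charges.
#'
#' @param ts a [training_set()].
#' @param prior_strength ridge strength (>= 0; default 1e-6). Zero is only
#'   valid when the design matrix has full rank.
#' @param fit_x0 if `TRUE` (default), equilibrium values are recovered from
#'   the linear reparameterisation; if `FALSE` they stay frozen at their
#'   input values.
#' @return An object of class `fit_result`: fitted `topology`, linear
#'   coefficients with standard errors, a `param_table`, residual force
#'   `rmse` (kcal/mol/A), the reciprocal condition number of the normal
#'   matrix, and rows describing any negative recovered force constants
#'   (flagged, never silently clamped).
#' @export
fit_bonded_parameters <- function(ts, prior_strength = 1e-6,
                                  fit_x0 = TRUE) {
  stopifnot(inherits(ts, "training_set"), prior_strength >= 0)
  ts <- subtract_nonbonded_forces(ts)
  topo <- ts$topology
  lay <- param_layout(topo, fit_x0)
  if (lay$n_par == 0) stop("topology has no bonded terms to fit")
  sys <- compile_system(topo, include_nonbonded = FALSE,
                        include_tethers = FALSE, include_restraint = FALSE)
  P <- lay$n_par
  XtX <- matrix(0, P, P); Xty <- numeric(P); yty <- 0; nobs <- 0
  for (s in seq_along(ts$coords)) {
    X <- reduce_basis(cpp_basis(ts$coords[[s]], sys), topo, fit_x0)
    y <- as.vector(t(ts$forces[[s]]))
    XtX <- XtX + crossprod(X)
    Xty <- Xty + crossprod(X, y)
    yty <- yty + sum(y * y)
    nobs <- nobs + length(y)
  }
  A <- XtX + diag(prior_strength, P)
  cond <- rcond(A)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch))
    stop("design matrix is rank-deficient; use a nonzero prior_strength")
  a <- backsolve(ch, forwardsolve(t(ch), Xty))
  a <- as.numeric(a)
  rss <- max(yty - 2 * sum(a * Xty) + as.numeric(t(a) %*% XtX %*% a), 0)
  rmse <- sqrt(rss / nobs)
  sigma2 <- rss / max(nobs - P, 1)
  Ainv <- chol2inv(ch)
  vcov_a <- sigma2 * (Ainv %*% XtX %*% Ainv)
  se_a <- sqrt(pmax(diag(vcov_a), 0))

  fitted <- topo
  tab <- list(); flagged <- list()
  idx <- 1
  map_harm <- function(cls, term, k_in, x0_in) {
    if (fit_x0) {
      a1 <- a[idx]; a2 <- a[idx + 1]
      se1 <- se_a[idx]
      if (a1 > 0) {
        x0 <- a2 / (2 * a1)
        # delta method on x0 = a2 / (2 a1)
        g <- c(-a2 / (2 * a1^2), 1 / (2 * a1))
        v <- vcov_a[idx:(idx + 1), idx:(idx + 1)]
        se_x0 <- sqrt(max(as.numeric(t(g) %*% v %*% g), 0))
      } else {
        x0 <- x0_in; se_x0 <- NA_real_
        flagged[[length(flagged) + 1]] <<- data.frame(
          class = cls, term = term, k = a1)
      }
      idx <<- idx + 2
      list(k = a1, x0 = x0, se_k = se1, se_x0 = se_x0)
    } else {
      a1 <- a[idx]; se1 <- se_a[idx]
      if (a1 <= 0) flagged[[length(flagged) + 1]] <<- data.frame(
        class = cls, term = term, k = a1)
      idx <<- idx + 1
      list(k = a1, x0 = x0_in, se_k = se1, se_x0 = NA_real_)
    }
  }
  for (t in seq_len(lay$nb)) {
    m <- map_harm("bond", t, topo$bonds$kb[t], topo$bonds$b0[t])
    fitted$bonds$kb[t] <- m$k; fitted$bonds$b0[t] <- m$x0
    tab[[length(tab) + 1]] <- data.frame(class = "bond", term = t,
                                         k = m$k, x0 = m$x0,
                                         se_k = m$se_k, se_x0 = m$se_x0)
  }
  for (t in seq_len(lay$na)) {
    m <- map_harm("angle", t, topo$angles$ktheta[t], topo$angles$theta0[t])
    fitted$angles$ktheta[t] <- m$k; fitted$angles$theta0[t] <- m$x0
    tab[[length(tab) + 1]] <- data.frame(class = "angle", term = t,
                                         k = m$k, x0 = m$x0,
                                         se_k = m$se_k, se_x0 = m$se_x0)
  }
  for (t in seq_len(lay$nd)) {
    fitted$dihedrals$K[t] <- a[idx]
    tab[[length(tab) + 1]] <- data.frame(class = "dihedral", term = t,
                                         k = a[idx], x0 = NA_real_,
                                         se_k = se_a[idx],
                                         se_x0 = NA_real_)
    idx <- idx + 1
  }
  for (t in seq_len(lay$ni)) {
    m <- map_harm("improper", t, topo$impropers$kpsi[t],
                  topo$impropers$psi0[t])
    fitted$impropers$kpsi[t] <- m$k; fitted$impropers$psi0[t] <- m$x0
    tab[[length(tab) + 1]] <- data.frame(class = "improper", term = t,
                                         k = m$k, x0 = m$x0,
                                         se_k = m$se_k, se_x0 = m$se_x0)
  }
  structure(list(topology = fitted, coef = a, se = se_a, vcov = vcov_a,
                 param_table = do.call(rbind, tab), rmse = rmse,
                 conditioning = cond, prior_strength = prior_strength,
                 fit_x0 = fit_x0,
                 negative_k = if (length(flagged))
                   do.call(rbind, flagged) else NULL,
                 nobs = nobs),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(paste0("fit_result: %d parameters from %d force components; ",
                     "residual RMSE %.4g kcal/mol/A (prior %.3g, rcond ",
                     "%.3g)\n"),
              length(x$coef), x$nobs, x$rmse, x$prior_strength,
              x$conditioning))
  if (!is.null(x$negative_k))
    cat("  WARNING:", nrow(x$negative_k), "negative force constant(s)\n")
  invisible(x)
}

#' Flag unfeasibly large dihedral amplitudes
#'
#' Advisory listing of fitted dihedral Fourier amplitudes whose magnitude
#' exceeds the threshold (default 50 kcal/mol), the symptom of an
#' ill-chosen multiplicity; adjusting multiplicities is a manual step
#' outside the fit.
#'
#' @param fit a fit result from [fit_bonded_parameters()] (or any
#'   topology-bearing list).
#' @param threshold amplitude threshold in kcal/mol.
#' @return data.frame of flagged terms (possibly empty) with atom indices,
#'   multiplicity and amplitude.
#' @export
flag_unfeasible_dihedrals <- function(fit, threshold = 50) {
  topo <- if (inherits(fit, "fit_result")) fit$topology else fit
  d <- topo$dihedrals
  out <- d[abs(d$K) > threshold, , drop = FALSE]
  out$term <- which(abs(d$K) > threshold)
  rownames(out) <- NULL
  out
}

#' Root-mean-square force residual of a parameter set
#'
#' RMS over all atoms, Cartesian components and snapshots of the difference
#' between model bonded forces and the (nonbonded-subtracted) target forces.
#'
#' @param topo the parameter set to evaluate (a [topology()]).
#' @param ts a [training_set()]; subtracted internally if needed, using the
#'   training topology's charges.
#' @return RMSE in kcal/mol/A.
#' @export
force_rmse <- function(topo, ts) {
  stopifnot(inherits(topo, "topology"), inherits(ts, "training_set"))
  ts <- subtract_nonbonded_forces(ts)
  sys <- compile_system(topo, include_nonbonded = FALSE,
                        include_tethers = FALSE, include_restraint = FALSE)
  ss <- 0; nobs <- 0
  for (s in seq_along(ts$coords)) {
    fb <- cpp_eval(ts$coords[[s]], sys, 1, 1, TRUE)$forces
    d <- fb - ts$forces[[s]]
    ss <- ss + sum(d * d); nobs <- nobs + length(d)
  }
  sqrt(ss / nobs)
}
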