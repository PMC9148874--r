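logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Per-snapshot energy-difference series
#'
#' Ordered potential-energy differences from the sampled state to a target
#' state, the raw input of one-sided free-energy estimation.
#'
#' @param du numeric vector of energy differences (kcal/mol), finite.
#' @param from,to labels of the sampled and target states.
#' @param temperature Kelvin at which the series was sampled.
#' @return An object of class `energy_series`.
#' @export
energy_series <- function(du, from = "MM", to = "QM/MM",
                          temperature = 298.15) {
  du <- as.numeric(du)
  if (!all(is.finite(du))) stop("energy differences must be finite")
  structure(list(du = du, from = from, to = to, temperature = temperature,
                 n = length(du)),
            class = "energy_series")
}

#' @export
print.energy_series <- function(x, ...) {
  cat(sprintf("energy_series %s -> %s: N = %d, mean %.4g, sd %.4g kcal/mol\n",
              x$from, x$to, x$n, mean(x$du), sd(x$du)))
  invisible(x)
}

as_du <- function(x) if (inherits(x, "energy_series")) x$du else
  as.numeric(x)

block_delta_a <- function(du, beta, nblocks = 10) {
  bs <- length(du) %/% nblocks
  if (bs < 1) return(list(sd = NA_real_, se = NA_real_, estimates = NULL))
  est <- vapply(seq_len(nblocks), function(b) {
    blk <- du[((b - 1) * bs + 1):(b * bs)]
    -(logsumexp(-beta * blk) - log(length(blk))) / beta
  }, 0)
  list(sd = sd(est), se = sd(est) / sqrt(nblocks), estimates = est)
}

#' One-sided exponential-average (Zwanzig) free-energy estimate
#'
#' `Delta A = -(1/beta) log < exp(-beta Delta U) >`, computed with max-shift
#' (log-sum-exp) stabilisation so arbitrarily large `|Delta U|` cannot
#' overflow. The uncertainty is the standard deviation of 10 contiguous
#' equal-size block estimates (tail remainder snapshots dropped); it is
#' reported as `NA` rather than fabricated when fewer than 10 snapshots are
#' available.
#'
#' @param series an [energy_series()] or plain numeric vector of
#'   `Delta U` (kcal/mol); at least 2 entries.
#' @param state a [thermo_state()]; defaults to the series temperature.
#' @return An object of class `fep_estimate` with `delta_A`, `mean_du`,
#'   `sigma_du` (sample SD, N-1), `block_sd`, `block_se`, `n`. The Jensen
#'   bound `delta_A <= mean_du` holds exactly on every empirical series.
#' @export
zwanzig_fep <- function(series, state = NULL) {
  du <- as_du(series)
  if (length(du) < 2) stop("need at least 2 snapshots")
  if (is.null(state)) {
    state <- if (inherits(series, "energy_series"))
      thermo_state(series$temperature) else thermo_state()
  }
  state <- as_thermo_state(state)
  beta <- state$beta
  delta_a <- -(logsumexp(-beta * du) - log(length(du))) / beta
  blocks <- block_delta_a(du, beta, 10)
  structure(list(delta_A = delta_a, mean_du = mean(du), sigma_du = sd(du),
                 block_sd = blocks$sd, block_se = blocks$se,
                 block_estimates = blocks$estimates, n = length(du),
                 temperature = state$temperature),
            class = "fep_estimate")
}

#' @export
print.fep_estimate <- function(x, ...) {
  cat(sprintf(paste0("fep_estimate: delta_A = %.4f kcal/mol (block SD %s), ",
                     "<dU> = %.4f, sigma[dU] = %.4f, N = %d\n"),
              x$delta_A,
              ifelse(is.na(x$block_sd), "NA", sprintf("%.4f", x$block_sd)),
              x$mean_du, x$sigma_du, x$n))
  invisible(x)
}

#' Bennett acceptance ratio between two sampled states
#'
#' Solves the self-consistent Bennett equation for the free-energy
#' difference `A_1 - A_0` given forward work values (`Delta U` from state 0
#' samples, evaluated 0 -> 1) and reverse work values (from state 1,
#' evaluated 1 -> 0). Antisymmetric under swapping the two series.
#'
#' @param forward,reverse [energy_series()] or numeric vectors (kcal/mol).
#' @param state a [thermo_state()].
#' @param tol solver tolerance on `Delta A` (kcal/mol).
#' @return list with `delta_A` (kcal/mol) and the sample counts.
#' @export
bar <- function(forward, reverse, state = thermo_state(), tol = 1e-10) {
  wf <- as_du(forward); wr <- as_du(reverse)
  if (length(wf) == 0 || length(wr) == 0)
    stop("both work series must be non-empty")
  state <- as_thermo_state(state)
  beta <- state$beta
  m <- log(length(wf) / length(wr))
  fermi_sum_log <- function(x) {
    # log sum_i 1/(1+exp(x_i)), stable for large |x|
    logsumexp(-log1p(exp(-abs(x))) - pmax(x, 0))
  }
  g <- function(da) {
    fermi_sum_log(beta * (wf - da) + m) - fermi_sum_log(beta * (wr + da) - m)
  }
  lo <- min(-wr, wf); hi <- max(-wr, wf)
  span <- max(hi - lo, 1)
  lo <- lo - 10 * span - 10; hi <- hi + 10 * span + 10
  sol <- stats::uniroot(g, c(lo, hi), tol = tol / 10)
  list(delta_A = sol$root, n_forward = length(wf),
       n_reverse = length(wr))
}

#' Multistate Bennett acceptance ratio (MBAR)
#'
#' Self-consistent fixed-point solution of the MBAR equations for reduced
#' (dimensionless) free energies of K states from pooled samples, with the
#' first state anchored at zero.
#'
#' @param u_kn K x N matrix of reduced potentials: `u_kn[k, n]` is
#'   `beta * U_k` of pooled sample `n` evaluated in state `k`.
#' @param n_k integer vector of sample counts per state (summing to N);
#'   every state must have at least one sample.
#' @param tol convergence tolerance on the reduced free energies.
#' @param max_iter iteration cap.
#' @param f_init optional warm-start vector of reduced free energies.
#' @return list with `f` (reduced free energies, `f[1] = 0`), iterations
#'   used, and the final update size.
#' @export
mbar <- function(u_kn, n_k, tol = 1e-10, max_iter = 20000, f_init = NULL) {
  u_kn <- as.matrix(u_kn)
  K <- nrow(u_kn); N <- ncol(u_kn)
  n_k <- as.integer(n_k)
  if (length(n_k) != K || sum(n_k) != N)
    stop("sample counts must match the reduced potential matrix")
  if (any(n_k < 1)) stop("every state needs at least one sample")
  if (!all(is.finite(u_kn))) stop("reduced potentials must be finite")
  logn <- log(n_k)
  if (is.null(f_init)) {
    # initial guess: forward exponential averaging along the state ladder
    f <- numeric(K)
    ends <- cumsum(n_k); starts <- c(1, utils::head(ends, -1) + 1)
    for (k in seq_len(K - 1)) {
      idx <- starts[k]:ends[k]
      d <- u_kn[k + 1, idx] - u_kn[k, idx]
      f[k + 1] <- f[k] - (logsumexp(-d) - log(length(idx)))
    }
  } else {
    stopifnot(length(f_init) == K)
    f <- f_init - f_init[1]
  }
  colmax <- function(M) apply(M, 2, max)
  for (iter in seq_len(max_iter)) {
    # log denominator per sample: log sum_k N_k exp(f_k - u_kn)
    A <- logn + f - u_kn            # K x N (column recycling of logn + f)
    mx <- colmax(A)
    logden <- mx + log(colSums(exp(sweep(A, 2, mx))))
    B <- -u_kn - rep(logden, each = K)
    mxb <- apply(B, 1, max)
    fnew <- -(mxb + log(rowSums(exp(B - mxb))))
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) break
  }
  if (delta >= tol)
    stop("MBAR failed to converge within ", max_iter, " iterations")
  list(f = f, iterations = iter, final_delta = delta)
}

#' Free energy of releasing the flat-bottom restraint in the bound state
#'
#' One-sided FEP over the restrained ensemble with the piecewise
#' perturbation energy `Delta U(on -> off) = 0` for r < r0 and
#' `-(1/2) K (r - r0)^2` beyond. Because every `Delta U <= 0`, the result is
#' always `<= 0`: releasing a restraint cannot raise the free energy.
#'
#' @param r_com numeric vector of COM distances sampled with the restraint
#'   active (Angstrom).
#' @param spec the [restraint_spec()] that was active.
#' @param state a [thermo_state()].
#' @return A [zwanzig_fep()] estimate of the release free energy (kcal/mol).
#' @export
restraint_off_fep <- function(r_com, spec, state = thermo_state()) {
  stopifnot(inherits(spec, "restraint_spec"), all(r_com >= 0))
  du <- -flat_bottom_restraint(r_com, spec)
  if (length(du) == 1) du <- rep(du, 2) # one-point series: FEP = -dU
  zwanzig_fep(energy_series(du, from = "restrained", to = "unrestrained",
                            temperature = as_thermo_state(state)$temperature))
}

#' Standard-state specification for the unbound restraint correction
#'
#' @param r_min,r_max minimum and maximum observed COM distances (Angstrom),
#'   `0 <= r_min < r_max`.
#' @param v0 standard-state volume per molecule (default 1661 A^3, the 1 M
#'   volume).
#' @export
standard_state_spec <- function(r_min, r_max, v0 = v_standard_state) {
  stopifnot(r_min >= 0, r_max > r_min, v0 > 0)
  structure(list(r_min = r_min, r_max = r_max, v0 = v0),
            class = "standard_state_spec")
}

#' Standard-state correction for releasing the unbound restraint
#'
#' With the guest fully decoupled, the restraint only limits the volume the
#' guest explores; releasing it is the free energy of changing from the
#' effective shell volume `V_eff = (4/3) pi (r_max^3 - r_min^3)` to the
#' standard-state volume `V0`:
#' `Delta A = -(1/beta) log(V0 / V_eff)`.
#'
#' @param spec a [standard_state_spec()].
#' @param state a [thermo_state()].
#' @return list with `delta_A` (kcal/mol), `v_eff` (A^3) and
#'   `v_min_contribution` (the `(4/3) pi r_min^3` volume term, A^3).
#' @export
standard_state_correction <- function(spec, state = thermo_state()) {
  stopifnot(inherits(spec, "standard_state_spec"))
  state <- as_thermo_state(state)
  v_eff <- 4 / 3 * pi * (spec$r_max^3 - spec$r_min^3)
  list(delta_A = -log(spec$v0 / v_eff) / state$beta,
       v_eff = v_eff,
       v_min_contribution = 4 / 3 * pi * spec$r_min^3)
}

#' Write / read an energy-difference series as CSV
#'
#' One row per snapshot; state labels and the temperature travel in `#`
#' comment headers so a round trip is lossless at printed precision.
#'
#' @param series an [energy_series()].
#' @param file path.
#' @return `file` invisibly / the recovered [energy_series()].
#' @export
write_energy_series <- function(series, file) {
  stopifnot(inherits(series, "energy_series"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# from=%s", series$from),
               sprintf("# to=%s", series$to),
               sprintf("# temperature=%.10g", series$temperature),
               "du"), con)
  writeLines(sprintf("%.12g", series$du), con)
  invisible(file)
}

#' @rdname write_energy_series
#' @export
read_energy_series <- function(file) {
  ln <- readLines(file)
  hdr <- ln[startsWith(ln, "#")]
  get <- function(key, default) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, "="), "", m[1]) else default
  }
  body <- ln[!startsWith(ln, "#")]
  body <- body[nzchar(trimws(body))][-1] # drop the column header
  energy_series(as.numeric(body), from = get("from", "MM"),
                to = get("to", "QM/MM"),
                temperature = as.numeric(get("temperature", "298.15")))
}
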