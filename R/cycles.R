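#' The 16-state alchemical decoupling schedule
#'
#' Electrostatics are switched off linearly over states 0-5
#' (`lambda_elec = 1.0, 0.8, 0.6, 0.4, 0.2, 0.0`) with van der Waals fully
#' coupled, then the soft-core vdW coupling descends through the squares
#' `0.81, 0.64, ..., 0.01, 0.00` over states 6-15 (state `k >= 5` has
#' `lambda_vdw = ((15 - k)/10)^2`).
#'
#' @return data.frame of class `lambda_schedule` with columns `state`
#'   (0-based index), `lambda_elec`, `lambda_vdw`.
#' @export
lambda_schedule <- function() {
  k <- 0:15
  sched <- data.frame(
    state = k,
    lambda_elec = c(1.0, 0.8, 0.6, 0.4, 0.2, rep(0, 11)),
    lambda_vdw = c(rep(1.0, 6), ((15 - 6:15) / 10)^2))
  class(sched) <- c("lambda_schedule", "data.frame")
  sched
}

validate_schedule <- function(sched) {
  stopifnot(is.data.frame(sched),
            all(c("lambda_elec", "lambda_vdw") %in% names(sched)))
  le <- sched$lambda_elec; lv <- sched$lambda_vdw
  if (le[1] != 1 || lv[1] != 1) stop("first state must be (1, 1)")
  n <- nrow(sched)
  if (le[n] != 0 || lv[n] != 0) stop("last state must be (0, 0)")
  if (any(lv[le > 0] != 1))
    stop("lambda_elec must reach 0 before lambda_vdw departs from 1")
  invisible(sched)
}

#' Ledger of double-decoupling cycle legs
#'
#' Collects the four legs of the double-decoupling binding cycle with their
#' uncertainties: the decoupling free energies in the bound complex
#' (`ddm_bound`) and free in solution (`ddm_free`), and the two
#' restraint-release corrections (`restr_off_bound` from the restrained
#' bound ensemble, `restr_off_free` the standard-state correction).
#'
#' @param ddm_bound,ddm_free,restr_off_bound,restr_off_free leg values in
#'   kcal/mol.
#' @param sd named or positional numeric vector of per-leg uncertainties
#'   (same order); defaults to zeros.
#' @return An object of class `cycle_ledger`.
#' @export
cycle_ledger <- function(ddm_bound, ddm_free, restr_off_bound,
                         restr_off_free, sd = c(0, 0, 0, 0)) {
  vals <- c(ddm_bound = ddm_bound, ddm_free = ddm_free,
            restr_off_bound = restr_off_bound,
            restr_off_free = restr_off_free)
  if (any(!is.finite(vals))) stop("all four legs must be present and finite")
  sd <- rep_len(as.numeric(sd), 4)
  structure(list(legs = vals, sd = sd), class = "cycle_ledger")
}

#' Double-decoupling binding free energy
#'
#' Assembles the binding free energy from the four cycle legs:
#' `Delta A_bind = ddm_free - restr_off_free - ddm_bound +
#' restr_off_bound`, with leg uncertainties combined in quadrature (legs
#' are simulated independently).
#'
#' @param ledger a [cycle_ledger()].
#' @return list with `delta_A` and `sd` (kcal/mol).
#' @export
ddm_binding <- function(ledger) {
  stopifnot(inherits(ledger, "cycle_ledger"))
  l <- ledger$legs
  list(delta_A = unname(l["ddm_free"] - l["restr_off_free"] -
                          l["ddm_bound"] + l["restr_off_bound"]),
       sd = sqrt(sum(ledger$sd^2)))
}

#' Indirect end-state correction of a binding free energy
#'
#' Closes the reference-potential thermodynamic cycle: the target-level
#' binding free energy equals the classical one plus the low-to-high
#' end-state correction of the bound complex minus that of the free guest.
#'
#' @param delta_A_bind_mm classical binding free energy (kcal/mol).
#' @param corr_bound,corr_free one-sided end-state corrections (kcal/mol)
#'   computed at matching end states.
#' @param sd length-3 uncertainties, combined in quadrature.
#' @return list with `delta_A` and `sd` (kcal/mol).
#' @export
indirect_correction <- function(delta_A_bind_mm, corr_bound, corr_free,
                                sd = c(0, 0, 0)) {
  sd <- rep_len(as.numeric(sd), 3)
  list(delta_A = delta_A_bind_mm + corr_bound - corr_free,
       sd = sqrt(sum(sd^2)))
}

#' Protonation-state (pKa) thermodynamic cycle
#'
#' Couples the binding free energies of the protonated and neutral forms of
#' a titratable guest with its aqueous pKa to give the bound-state pKa and
#' the pH-dependent binding free energy. The double difference uses the
#' convention `ddA = delta_A_bind_neutral - delta_A_bind_protonated`.
#'
#' @param pka_aq aqueous pKa of the guest (default 7.5, a ketamine-like
#'   amine).
#' @param delta_A_bind_prot,delta_A_bind_neut binding free energies of the
#'   protonated and neutral forms (kcal/mol).
#' @param ph pH of interest (default 7.4, the experimental condition).
#' @param temperature Kelvin.
#' @return An object of class `pka_cycle` carrying the inputs, `ddA`, and
#'   the derived `pka_bound`.
#' @export
pka_cycle <- function(pka_aq = 7.5, delta_A_bind_prot, delta_A_bind_neut,
                      ph = 7.4, temperature = 298.15) {
  stopifnot(is.finite(pka_aq), is.finite(delta_A_bind_prot),
            is.finite(delta_A_bind_neut), is.finite(ph))
  st <- thermo_state(temperature)
  dda <- delta_A_bind_neut - delta_A_bind_prot
  pka_bnd <- pka_aq + dda / (k_boltzmann * temperature * log(10))
  structure(list(pka_aq = pka_aq,
                 delta_A_bind_prot = delta_A_bind_prot,
                 delta_A_bind_neut = delta_A_bind_neut,
                 ddA = dda, pka_bound = pka_bnd, ph = ph,
                 temperature = temperature, beta = st$beta),
            class = "pka_cycle")
}

#' Bound-state pKa from the protonation cycle
#'
#' `pKa(bound) = pKa(aq) + ddA / (RT ln 10)` with
#' `ddA = delta_A_bind_neutral - delta_A_bind_protonated`.
#'
#' @param cycle a [pka_cycle()].
#' @return the bound-state pKa (dimensionless).
#' @export
bound_pka <- function(cycle) {
  stopifnot(inherits(cycle, "pka_cycle"))
  cycle$pka_bound
}

#' pH-dependent binding free energy
#'
#' Evaluates the titration-corrected binding free energy from the
#' protonated leg,
#' `dA(pH) = dA(G+) - (1/beta) ln[(1 + 10^(pH - pKa_bnd)) /
#' (1 + 10^(pH - pKa_aq))]`,
#' and independently from the neutral leg (exponents reversed in sign,
#' binding legs and pKa roles swapped). The two routes are algebraically
#' identical when the cycle is consistent; a disagreement beyond `tol`
#' signals a corrupted cycle and raises an error.
#'
#' @param cycle a [pka_cycle()].
#' @param tol internal-consistency tolerance (kcal/mol).
#' @return the common value (kcal/mol).
#' @export
ph_dependent_binding <- function(cycle, tol = 1e-10) {
  stopifnot(inherits(cycle, "pka_cycle"))
  kt <- 1 / cycle$beta
  ph <- cycle$ph
  from_prot <- cycle$delta_A_bind_prot -
    kt * log((1 + 10^(ph - cycle$pka_bound)) /
               (1 + 10^(ph - cycle$pka_aq)))
  from_neut <- cycle$delta_A_bind_neut -
    kt * log((1 + 10^(cycle$pka_bound - ph)) /
               (1 + 10^(cycle$pka_aq - ph)))
  if (abs(from_prot - from_neut) > tol)
    stop(sprintf(paste0("protonated and neutral routes disagree by %.3g ",
                        "kcal/mol: inconsistent cycle"),
                 abs(from_prot - from_neut)))
  from_prot
}

#' Assemble an end-state energy-difference series with PBC bookkeeping
#'
#' When low- and high-level energies are both evaluated without periodic
#' boundary contributions, and the periodic contribution
#' `U_PBC = U_MM_withPBC - U_MM_noPBC` is assumed identical at both levels,
#' it cancels identically from the per-snapshot difference:
#' `Delta U = U_high_noPBC - U_low_noPBC`. With-PBC energies may be supplied
#' for bookkeeping but never enter the result.
#'
#' @param u_low_nopbc,u_high_nopbc per-snapshot energies (kcal/mol) at the
#'   two levels, no periodic contributions.
#' @param u_low_withpbc optional per-snapshot low-level energies with
#'   periodic contributions (recorded, not used).
#' @param temperature Kelvin.
#' @return An [energy_series()] with an attached `u_pbc` attribute when
#'   with-PBC energies were given.
#' @export
assemble_endstate_du <- function(u_low_nopbc, u_high_nopbc,
                                 u_low_withpbc = NULL,
                                 temperature = 298.15) {
  if (length(u_low_nopbc) != length(u_high_nopbc))
    stop("energy series lengths differ")
  es <- energy_series(u_high_nopbc - u_low_nopbc, from = "MM",
                      to = "QM/MM", temperature = temperature)
  if (!is.null(u_low_withpbc)) {
    if (length(u_low_withpbc) != length(u_low_nopbc))
      stop("energy series lengths differ")
    attr(es, "u_pbc") <- u_low_withpbc - u_low_nopbc
  }
  es
}
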