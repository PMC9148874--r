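---
title: "Indirect alchemical binding free energies: models, estimators and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect alchemical binding free energies: models, estimators and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alchemfep)
```

## The problem

Absolute binding free energies of host-guest complexes can be computed
classically by the double-decoupling method (DDM): the guest's nonbonded
interactions are switched off alchemically both in the bound complex and
free in solution, and the two decoupling legs are closed by restraint
corrections,

\[
\Delta A^{\mathrm{bind}} =
\Delta A^{\mathbf{G+H}}_{\mathrm{DDM}}
- \Delta A^{\mathbf{G+H}}_{\mathrm{restr\,off}}
- \Delta A^{\mathbf{GH}}_{\mathrm{DDM}}
+ \Delta A^{\mathbf{GH}}_{\mathrm{restr\,off}}.
\]

When a higher-level (e.g. semi-empirical QM/MM) description of the guest is
wanted, rerunning the whole cycle at that level is prohibitive. The
*indirect* (reference-potential) scheme instead corrects each fully coupled
end state from the classical to the target Hamiltonian with one-sided
exponential averaging (the Zwanzig relation),

\[
\Delta A^{\mathrm{low}\to\mathrm{high}}
= -\tfrac{1}{\beta}\,
\ln\bigl\langle e^{-\beta\,\Delta U}\bigr\rangle_{\mathrm{low}},
\qquad
\Delta A^{\mathrm{bind}}_{\mathrm{high}} =
\Delta A^{\mathrm{bind}}_{\mathrm{low}}
+ \Delta A^{\mathrm{corr}}_{\mathrm{bound}}
- \Delta A^{\mathrm{corr}}_{\mathrm{free}},
\]

which only needs target-level *energies* on snapshots of the classical
ensembles. The catch is configurational overlap: one-sided estimates
converge only when the sampled ensemble resembles the target's. Force
matching (refitting the classical bonded parameters to target-level forces)
is the package's mechanism for closing that gap, and Lambert-W-based bias
diagnostics quantify whether it worked. This package implements the whole
chain - energy models, sampling, fitting, estimators, cycle bookkeeping,
diagnostics and challenge statistics - at desk scale, on toy systems where
every step can be validated against analytic results.

## Energy model and conventions

All terms follow CHARMM functional forms: bonds and angles are
\(U = k(x - x_0)^2\) (no explicit 1/2), proper dihedrals are Fourier terms
\(K_n (1 + \cos(n\phi - \delta))\), impropers are harmonic in the dihedral
angle. Units are kcal/mol, Angstrom and radians internally (degrees at the
file boundary), with \(k_B = 0.0019872041\) kcal/(mol K) and the CHARMM
Coulomb constant. Nonbonded pairs use Lorentz-Berthelot combination;
1-2 and 1-3 pairs are excluded, 1-4 pairs interact at full strength; no
cutoffs anywhere (the gas-phase/toy convention - the periodic-boundary
bookkeeping of condensed-phase workflows survives only as the exact
cancellation implemented by `assemble_endstate_du()`).

Alchemical decoupling follows the published two-stage schedule
(`lambda_schedule()`): electrostatics are annihilated first by scaling the
partial charges of the alchemical region by \(\lambda_{\mathrm{elec}}\)
(so intra-region pairs scale as \(\lambda^2\)) over five steps, then the
region-environment Lennard-Jones interactions are removed through the
soft-core form

\[
U^{\mathrm{LJ}}_{\lambda} = 4\lambda\varepsilon
\left[\left(\frac{\sigma}{r + \sigma(1-\lambda)}\right)^{12}
- \left(\frac{\sigma}{r + \sigma(1-\lambda)}\right)^{6}\right]
\]

over ten further steps with \(\lambda_{\mathrm{vdw}}\) descending through
the squares \(0.81, 0.64, \dots, 0.01, 0\). Both occurrences of
\(\sigma\) are read as the combined pair parameter \(\sigma_{ij}\): the
published form prints a bare \(\sigma\) in the numerator, and the combined
parameter is the only reading under which \(\lambda = 1\) recovers the
standard LJ pair energy - which it does here to machine precision.
Charge scaling is *annihilation* (intra-region electrostatics scale too),
the literal reading of scaling the charges themselves; both decoupling
legs use identical semantics, so the cycle closes regardless.

The flat-bottom COM restraint is zero below the offset
(\(r_0 = 5.5\) A by default) and \(\tfrac12 K (r - r_0)^2\) beyond
(\(K = 1.5\) kcal/mol/A^2); here the explicit 1/2 of the published
piecewise form is kept, in contrast to the CHARMM bonded convention, and a
`half_factor` flag documents the choice per restraint.

## Synthetic systems and sampling

The toy systems (`make_toy_system()`) are a five-atom branched chain with
at least one term of every bonded class, in neutral (net 0) and charged
(net +1 e) variants, and a guest-in-cage complex. The cage is a rigid
icosahedral shell of twelve charged LJ sites (radius 4.2 A,
\(\varepsilon = 0.30\), \(\sigma = 3.0\), alternating \(\pm 0.25\) e):
a closed shell rather than a flat ring, because only a three-dimensional
trap actually binds the guest. The interior dispersion well holds the
guest by several kcal/mol, so the COM restraint almost never engages in
the coupled bound state - the situation the one-sided restraint-release
treatment assumes ("well-bound" complexes). What the toys deliberately do
not emulate: explicit solvent, periodic electrostatics, conformational
heterogeneity of drug-sized guests, or a true quantum target. Passing the
desk-scale suite therefore validates the estimators, the cycle algebra and
the fitting machinery - not the condensed-phase sampling problem.

Sampling uses Metropolis Monte Carlo rather than Langevin dynamics: it
targets exactly the same Boltzmann distribution, needs no integrator
validation, and is fast at this scale. One sweep is a single-atom trial
displacement (uniform, half-width 0.12-0.15 A) per movable atom,
optionally followed by a rigid translation and a rigid rotation of the
whole movable group. The rigid moves matter: a decoupled guest explores
the whole restraint volume, and with single-atom moves alone its centre of
mass is a slow random walk whose correlation time exceeds desk-scale chain
lengths; whole-group moves decorrelate COM position and orientation in a
few sweeps while preserving detailed balance (symmetric proposals). Seeds
are mandatory and echoed into every trajectory header.

Ensemble sizes mirror the source protocol at reduced scale: roughly
1,000-1,200 snapshots per state (against 10,000-15,000 in the original),
with thinning chosen so that successive snapshots of the harmonic test
systems are essentially decorrelated. The validation pipeline
(`toy_binding_closure()`) defaults to 12,000 sweeps, thinning 10 and
2,000 burn-in sweeps per lambda state - at those settings the bound-leg
decoupling estimate is converged well within its block error, which we
verified by doubling the chain length.

## Force matching

Bonded parameters are refit to target-level forces by ridge-regularised
linear least squares in the linearised parameter space: a harmonic term
\(k(x - x_0)^2\) contributes the coefficient pair \((k,\ 2 k x_0)\) on the
basis forces \(-\nabla x^2\) and \(+\nabla x\); each dihedral amplitude
\(K_n\) is linear at fixed multiplicity and phase. This is the MAP
estimate under an isotropic zero-mean Gaussian prior on the linear
coefficients - the Bayesian force-matching formalism reduced to its point
estimate, which is all the downstream workflow consumes. The prior
strength (default \(10^{-6}\)) is exposed because the reference
implementation does not document its regularisation; at that default it is
numerically irrelevant for well-posed fits and merely guards against rank
deficiency, for which a zero-prior fit raises an error instead of
silently pseudo-inverting.

Nonbonded (LJ + Coulomb) forces are subtracted from the target forces
before fitting, always with the molecule's true charges - never
auto-neutralised. For charged species this matters: subtracting
externally and fitting with charges zeroed must give exactly the same
parameters as internal subtraction, a property the test suite asserts to
1e-10. Urey-Bradley terms are never fitted. Fitted dihedral amplitudes
above 50 kcal/mol are flagged as unfeasible but left untouched:
multiplicity surgery is a manual decision, not something a fitting routine
should improvise. Equilibrium values are recovered from the linear
reparameterisation by default (`fit_x0 = TRUE`); freezing them reduces
each harmonic term to a single coefficient. Symmetry-equivalent terms are
fit independently (no pooling). A recovered non-positive force constant is
flagged, never clamped.

## Estimators and uncertainties

`zwanzig_fep()` computes the one-sided estimate with mandatory log-sum-exp
stabilisation (inputs of order \(\pm 10^4\) kcal/mol stay finite), and the
Jensen bound \(\Delta A \le \langle \Delta U \rangle\) holds exactly on
every empirical series. `bar()` solves the Bennett self-consistency
equation by bracketed root finding to 1e-10; `mbar()` iterates the
multistate fixed point with the first state anchored at zero, warm-started
by sequential exponential averaging along the state ladder. For two states
MBAR and BAR agree to 1e-8, and all three estimators recover
\(\Delta A = \ln(k_2/k_1)/(2\beta)\) for harmonic test states within
stochastic error.

Uncertainties follow the source convention: the series is cut into 10
contiguous equal blocks (tail remainder dropped), the estimator is applied
per block, and the *standard deviation across blocks* is reported as the
uncertainty (`block_sd`), alongside `block_sd/sqrt(10)` (`block_se`) for
readers who prefer a standard error of the mean. With fewer than 10
snapshots the block uncertainty is reported as `NA`, never fabricated.
Block estimates are not permutation invariant (the estimator itself is);
this is inherent to blocking and documented rather than hidden.

The restraint-release leg in the bound state applies one-sided FEP over
the restrained ensemble with
\(\Delta U^{\mathrm{on}\to\mathrm{off}}(r) = 0\) for \(r < r_0\) and
\(-\tfrac12 K (r - r_0)^2\) beyond; the result is necessarily
nonpositive. In the decoupled state the restraint only bounds the volume
the ghost guest explores, and its release is the standard-state change
\(\Delta A = -\tfrac{1}{\beta}\ln\!\bigl(V_0 / V_{\mathrm{eff}}\bigr)\)
with \(V_0 = 1661\) A^3 and
\(V_{\mathrm{eff}} \approx \tfrac43\pi(r_{\max}^3 - r_{\min}^3)\) from the
observed COM extremes. That shell approximation overestimates
\(V_{\mathrm{eff}}\) (the restraint tail is counted as fully accessible);
no correction factor is applied, matching the source treatment, and the
\(r_{\min}^3\) term is reported separately because it is negligible
(about 0.08 A^3 at \(r_{\min} = 0.27\) A).

## Cycle bookkeeping

`ddm_binding()` and `indirect_correction()` are deliberately dumb
arithmetic over named legs with quadrature uncertainty combination (legs
are simulated independently). The protonation cycle couples the binding
free energies of the protonated and neutral guest forms with the aqueous
pKa (default 7.5, a ketamine-like amine, at the experimental pH 7.4):

\[
\mathrm{p}K_a^{\mathrm{bnd}} = \mathrm{p}K_a^{\mathrm{aq}}
+ \frac{\Delta\Delta A}{RT \ln 10},
\qquad
\Delta\Delta A = \Delta A^{\mathrm{bind}}_{\mathrm{G}}
- \Delta A^{\mathrm{bind}}_{\mathrm{G}^+}.
\]

The sign of \(\Delta\Delta A\) is fixed as neutral minus protonated; the
published cycle-closure wording is ambiguous on this point, and this is
the convention under which the two titration-corrected binding
expressions (from the protonated and from the neutral leg, natural-log
convention) are algebraically identical - the package evaluates both and
refuses to return a value if they disagree beyond 1e-10, since that can
only mean a corrupted cycle. A property test checks the identity on 1,000
random cycles.

## Convergence diagnostics

For one-sided corrections the package computes the bias measure

\[
\Pi = \sqrt{W\!\left[\frac{(N-1)^2}{2\pi}\right]}
- \sqrt{2\beta\,\bigl(\langle\Delta U\rangle - \Delta A\bigr)},
\]

with \(W\) the principal-branch Lambert function (guarded Halley iteration
with bisection fallback, residual 1e-12, validated against an independent
bisection oracle), plus the sample standard deviation of \(\Delta U\)
with its \(4 k_B T \approx 2.4\) kcal/mol rule of thumb (inclusive
comparison at the boundary). \(\Pi > 0.5\) and
\(\sigma[\Delta U] \le 4 k_B T\) are *necessary, not sufficient*: the test
suite includes a crafted mixture distribution whose finite sample passes
both flags while the one-sided estimate is more than 1 kcal/mol from the
analytic answer. The one-sided form of \(\Pi\) additionally assumes the
spread of \(\Delta U\) is similar on both surfaces, which cannot be
verified without sampling the target state; it is an assumption, stated
here, not a checked property. On empirical series the Jensen gap is
nonnegative by construction; a negative radicand can only be float noise
and is clamped to zero with a warning.

`fm_improvement_trial()` packages the force-matching payoff experiment: a
strongly perturbed Hamiltonian (force constants scaled by 0.55-1.6,
equilibrium geometry shifts of 0.05 A / 0.1 rad) plays the target,
the unperturbed chain the baseline. Dihedral phases and multiplicities
stay shared between the levels, matching the fitting protocol, which
carries both over unchanged; when the target is pushed outside that
representable family the force-matched description can deteriorate for a
minority of seeds - the same failure mode the source reports for one of
its guests - which is why it is the documented caveat rather than the
default experiment.

## The end-to-end validation

`toy_binding_closure()` runs the full indirect workflow on the
guest-in-cage toy against a moderately perturbed high-level Hamiltonian
(force constants scaled by 0.85-1.15, small geometry and phase shifts,
charges scaled by 0.95 - enough to give corrections of a few tenths of a
kcal/mol while preserving overlap), then repeats the double-decoupling
route directly at the high level. The cycle identity predicts the two
routes agree; the package checks agreement within twice the combined
block-standard-deviation error of all legs (roughly a 95% interval under
the block-SD convention above). The binding free energy of
the toy complex is about -5.5 kcal/mol, comfortably in the range of the
host-guest systems the statistics layer describes.

## Numerical choices, degenerate inputs, limitations

* Colinear angles and degenerate dihedral geometries are handled by
  clamping the relevant denominators (defined limits, never NaN);
  overlapping *interacting* pairs raise an explicit singularity error for
  plain Coulomb/LJ, while the soft-core form stays finite at \(r = 0\) by
  construction for \(\lambda < 1\).
* A proposal width of zero is legal (the chain never moves, acceptance 1);
  a chain that accepts nothing raises an error suggesting a smaller width.
* MBAR convergence is declared at a maximum reduced-free-energy update of
  1e-10; non-convergence is an error, never a silent best-effort result.
* The improper torsion is fit through an unwrapped quadratic; systems
  whose improper angles wrap through \(\pm\pi\) during sampling would need
  the frozen-\(x_0\) mode.
* Kendall correlations use the tau-b convention (identical to tau-a on the
  tie-free seven-guest fixture).
* The packaged challenge fixture reproduces every printed statistic within
  rounding tolerance except one mean error whose printed value is
  inconsistent with its own per-guest row (the recomputed value is used
  there); the discrepancy is asserted, not papered over, in the test
  suite.
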