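---
title: "Cooperative cross-bridge group ensembles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperative cross-bridge group ensembles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xbgroup)
```

## The model

`xbgroup` simulates active force generation and ATP consumption of a
cardiac half-sarcomere with a Huxley-type cross-bridge model in which
cooperativity arises mechanistically from tropomyosin elasticity.

A cross-bridge is a myosin head identified with its nearest actin binding
site; its axial position $x \in [-d/2, d/2)$ relative to the model origin
(with $d \approx 36$ nm the regulatory-unit period) determines the force of
every attached state through $F = \partial G/\partial x$. Each site is in
one of five biochemical states: unbound blocked `T`, unbound Ca-activated
`WCa`, and three strong-binding states `S1Ca`, `S2Ca`, `S2` (pre-stroke
with Ca, post-stroke with Ca, post-stroke after Ca release). `T` and `WCa`
have constant (zero-force) free energies; the strong states have quadratic
profiles, i.e. linear elastic force.

Cooperativity enters by treating $q$ consecutive cross-bridges coupled by
one elastic tropomyosin as a *group*. Tropomyosin occupies one of three
azimuthal positions (blocked/weak/shifted) at each site, tied to the
biochemical state, and every position mismatch between neighboring sites
stretches the tropomyosin segment between them, with elastic energies
$U_{T;W}$, $U_{W;S}$, and $U_{T;S}$ derived from the segment geometry (the
fourth-root addition rule; the exact geometric form is available as an
internal oracle and agrees to about a percent at physiological energies,
see below). The group free energy is the sum of the $q+1$ segment energies
(boundary sites are permanently `T`) plus the per-site profiles. The
relaxed-baseline energy $U_{tr} = N_A K_{tr} d^2/2 \approx 3.3\times 10^3$
RT is common to every configuration and cancels in all differences, so it
is reported but never enters kinetics.

Transition rates follow a symmetric-splitting form: the per-site
free-energy difference enters as $e^{-\Delta G/2RT}$, the tropomyosin
segment-energy change as a factor $h$ on one direction of each reaction,
position dependence as continuous piecewise-linear factors $f(x)$ with
nodes at geometrically defined locations (profile minima and
intersections), and sarcomere-length dependence as symmetric factors
$p(l)$ on the Ca-binding and myosin-attachment reactions. Every
forward/backward ratio then satisfies microscopic reversibility exactly,
which the test suite asserts to machine precision for all transitions of
the $q=3$ model on the full grid.

### Chemical driving

Two reactions are flagged as ATP-consuming: detachment of the Ca-free
strong state (`S2 -> T`) and the strong-to-weak release (`S2Ca -> WCa`).
Completing a cycle through either flag hydrolyzes one ATP. In the basic
free-energy representation these transitions carry the chemical drive of
hydrolysis: their $\Delta G$ includes $-\Delta G_{ATP}$ (60 kJ/mol, about
23.3 RT at 310 K) in the detachment direction, split symmetrically into
the rate factor. This is what makes the free energy of the system descend
by one hydrolysis free energy per completed cycle. Without it every
reaction cycle of the five-state scheme has zero affinity at clamped Ca
(the two Ca-gated edges cancel around every cycle), the clamped-Ca steady
state becomes an exact per-position Boltzmann distribution, and the
steady-state active stress integrates to exactly zero — no sustained
force-Ca relation would exist. Setting `dG_ATP = 0` recovers that
undriven variant, which the tests use as an equilibrium control (zero net
ATP flux). The drive also suppresses resting attachment through the
`T <-> S2` edge, so the diastolic state carries essentially no stress.

### Ensemble dynamics and observables

All cross-bridge positions within a group are taken equal, reducing the
ensemble density to fractions $n_A(x,t)$ over the $5^q$ group states on a
one-dimensional periodic position grid. The dynamics combine first-order
reactions (with the Ca transient multiplying the two Ca-association
directions) and advection of $x$ at the half-sarcomere lengthening rate
$v(t)$. Stress is the force integral over all states and positions times
$m\,l/(2d)$ with $m$ the cross-bridge number density ($0.18$ mol/m$^3$
myosin); group force integrals are divided by $q$ so different group sizes
report per-cross-bridge stress. The ATP rate is the net flux through the
two flagged reactions; stress-strain area (SSA) is the polygon area in the
stress-strain plane bounded by the end-systolic line (isometric peak
stress versus length), the end-diastolic line, and the systolic
trajectory; efficiency is SSA over `atp_per_beat * c_myosin * dG_ATP`.

The model develops no passive stress, so the end-diastolic line is the
zero-stress axis and the SSA of an isometric beat reduces to the area
under the end-systolic line left of the beat's length. The end-systolic
line's zero-stress intercept is obtained by linear extrapolation of its
lowest segment (clamped at `l_min`).

## Numerical methods

* **Reaction integration.** The reaction system is linear in $n$ with two
  scalar time/length-dependent multipliers, so the generator is assembled
  once into four sparse flow matrices and integrated with the sparse
  stiff solver `deSolve::lsodes` (the DVODE family). Column sums are
  conserved up to integrator tolerance; densities are renormalized at
  output times and the drift is tracked (below $10^{-8}$ at the tight
  verification tolerances).
* **Rate capping.** The symmetric factor $e^{-\Delta G/2}$ grows without
  bound at extreme strain where the quadratic profiles reach tens of RT.
  Both directions of a reaction are scaled by a common factor keeping
  every rate below $10^3$/ms; ratios — and therefore all equilibria and
  detailed balance — are preserved exactly, and the cap only binds where
  occupancy is negligible ($e^{-40}$ and below).
* **Advection.** First-order upwind differencing on the periodic grid
  with internal sub-stepping at CFL $\le 1$ (exact at CFL 1), applied in
  an operator-split step at the output cadence. Total mass per state is
  conserved exactly.
* **Afterloaded protocol.** Isometric development is integrated in one
  stiff-solver call; during the isotonic phase each 1–2 ms interval
  advances the reaction once (length frozen) with a backward-Euler
  substep scheme using a cached sparse LU factor, and the constant
  lengthening rate of the interval is found by `uniroot` so end-of-interval
  stress equals the afterload (the root bracket bounds the advection shift
  below half a grid period to avoid wrap-around; intervals are quartered
  recursively down to 1/64 ms if bracketing fails). Backward Euler is used
  deliberately here: it is L-stable, conserves mass exactly
  ($\mathbf{1}^T A = 0$), and preserves positivity (the step matrix is an
  M-matrix).
* **ATP quadrature.** During shortening, freshly advected strong-state
  mass lands in bins whose detachment rates reach hundreds per ms and
  detaches within microseconds. Sampling the instantaneous ATP rate at
  interval ends would overcount these bursts several-fold; instead the
  isotonic stepper accumulates $h\,w^T y$ at the end of every implicit
  substep, which for a fast edge equals exactly the mass the step removes
  — each detachment is counted once. The smooth isometric phases use
  trapezoidal integration of the sampled rate.
* **Steady states.** At clamped Ca and $v=0$ each grid position is an
  independent linear balance; one balance row is replaced by the
  normalization constraint and solved directly (dense, up to $5^4 = 625$
  states for $q=4$).
* **Problem sizes.** The default grid is 72 points (0.5 nm); the
  verification suite and the acceptance script run at 16–24 points and
  1–2 ms output cadence, sizes at which the stress trace is converged to
  a few percent and all qualitative laws are stable. The grid-convergence
  test compares 64 against 128 points (below 1% sup-norm).

## The afterloaded-phase convention

The literature leaves the post-shortening phase of the physiologic
contraction unspecified. `xbgroup` ends the isotonic phase at the
end-systolic point — the first interval whose solved lengthening rate is
non-negative — and relaxes isometrically with the length clamped there.
This mirrors the cardiac cycle, where ejection ends at end-systolic
volume and relaxation is isovolumic at that volume; it also keeps the
beat's energetics clean. The alternative (isotonic re-lengthening back to
the end-diastolic length at the afterload) forces the relaxing muscle to
be re-stretched under load, which drives a stretch-detachment ATP churn
with no analog in the pressure-volume-area framework.

## The synthetic-data generator and the fixture

No public dataset exists for the fitting targets (per-length isometric
twitches, end-systolic points, SSA/ATP pairs of rat trabeculae), so
`generate_twitch_dataset()` emulates them from the forward model:
isometric stress traces at several half-sarcomere lengths sampled at a
fixed cadence with independent additive Gaussian noise, end-systolic
points, and SSA/ATP pairs for both protocol families. Noiseless datasets
reproduce the forward model exactly, which anchors the fitting fixed-point
tests.

The default parameter set mixes published constants ($d$, $K_{tr}$,
$U_{T;W} = 0.1$ RT, $U_{W;S} = 0.05$ RT, the 0.8–1.1 um length range,
myosin concentration, ATP free energy) with calibrated fixtures for
everything the literature reports only graphically (free-energy profiles,
rate nodal values, Ca-transient shape, beat period). The fixtures were
calibrated once, against the model's own target behaviors: peak isometric
stress in the tens of kPa at 1.05 um rising with length, relaxation
complete within the beat, a common linear SSA–ATP relation across
isometric and afterloaded beats, and conversion efficiency in the
experimentally reported 60–70% band. The Ca transient (quartic rise to a
peak at 30 ms, Gaussian decay with 35 ms time constant, 500 ms beat) is a
body-temperature rat-trabecula-like twitch. What passing tests on
synthetic data do *not* show: agreement with any real preparation's
absolute rates or fitted tropomyosin energies — those require the external
experimental dataset and the full optimization campaign.

Design choices worth noting, made where the problem was genuinely open:

* $U(W,W)$ and $U(S,S)$ are zero (equal neighbor positions leave the
  segment relaxed); only the three mismatch energies are defined by the
  theory, and this choice makes facilitated attachment between activated
  neighbors emerge correctly.
* `S2Ca` and `S2` share one quadratic profile; the Ca-binding free-energy
  difference is carried entirely by the Ca factor of the
  `S2 <-> S2Ca` reaction.
* The stress prefactor supports both conventions in circulation
  ($m\,l/2d$, the default, and $m\,l/d$ via
  `stress_prefactor_mode = "eq28"`); the two differ by an overall factor
  of two that is absorbed by the fixture calibration.
* Nodal $x$-locations are recomputed from the current free-energy
  profiles whenever parameters change (they move during fitting); nodal
  *values* are the fitted parameters.
* The fourth-root segment-energy rule deviates from the exact fragment
  geometry by about 1.4% at the default energies (the leading correction
  scales as the squared relative displacement); the property tests assert
  the honest 2% bound there and sub-1% behavior for smaller energies.

## Fitting

The three weighted residual blocks are: isometric stress records
(weighted by the headroom to the dataset's maximum stress, floored at 5%
of it), end-systolic consistency between afterloaded beats and the
isometric end-systolic line (interpolated monotonically), and the
ATP-per-SSA ratio against $\eta = 1/(0.65 \times 0.18 \times 60) = 0.1425$
m$^3$/kJ. Optimization is two-tier: an exhaustive outer grid over the
free-energy/tropomyosin parameters and an inner Levenberg–Marquardt
(`minpack.lm`) damped least squares over rate parameters, bounded below at
zero. The inner problem is deterministic given its start; noiseless
self-generated data are an exact fixed point, and the acceptance check
regenerates perturbed rate parameters to within 10%.

## Verification strategy

Three independent routes cross-check the deterministic solver:

1. closed forms (two-state relaxation, Boltzmann limits, translation
   solutions of the pure-advection system);
2. a continuous-time Markov chain simulator of a single group at fixed
   position and clamped Ca, whose time-weighted occupancies and net edge
   counts must match the deterministic steady state and its stationary
   fluxes within Monte Carlo error; and
3. internal consistency (long-time integration versus direct steady-state
   solves, group-model marginals versus the single-site model at zero
   coupling).

## Known limitations

* Only the equal-position simplification of the group ensemble is
  implemented; the general $q$-dimensional density with arbitrary initial
  distribution is out of scope.
* No passive (titin/extracellular) stress, no sarcomere inhomogeneity, no
  beat-to-beat Ca dynamics, no explicit nucleotide concentrations.
* The Hill coefficients of the default fixture are modest (near 1); large
  coefficients require strong tropomyosin coupling, as the coupling-scaling
  analysis shows.
* The boundary treatment in $x$ is periodic by default (a
  reset-to-unbound alternative would require resolving where detached
  probability should re-enter; the periodic choice conserves mass exactly
  and matches the nearest-site parameterization).
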