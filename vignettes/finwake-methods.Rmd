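---
title: "Methods: body-wave fitting and the desk-scale vortex solver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: body-wave fitting and the desk-scale vortex solver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`finwake` covers two layers of the analysis of subcarangiform (salmonid)
swimming: the kinematic layer — fitting the swimming-motion function

$$h(x,t) = (a e^{bx} + c e^{dx})\cos\{2\pi(ft - x/\lambda)\}$$

to midline landmark tracks — and a hydrodynamic layer that drives a
deforming fish-body model with the fitted motion and computes unsteady
forces on one or two parallel swimmers.  Positions $x$ are in body lengths
(BL, 0.397 m for the reference fish) measured from the snout against the
direction of travel; pair separations are in model lengths (L, 0.439 m),
following the different unit conventions used for speeds (BL/s) and
geometry.  The tail tip of the kinematic axis sits at $x \approx 1.13$ BL
because total length exceeds body length; the model section spans
$x \in [0, L/\mathrm{BL} \approx 1.106]$.

The hydrodynamic layer is deliberately a *desk-scale substitute* for
cluster-scale finite-volume RANS: a two-dimensional unsteady lumped-vortex
panel method on the horizontal midplane, with a free shed wake and an
empirical flat-plate friction correction.  It captures the phase and
separation-dependent wake-interference physics of parallel swimming, the
thrust/drag balancing procedure, and the Froude-efficiency bookkeeping, but
it is not expected to reproduce the absolute forces or velocity-field
magnitudes of a three-dimensional turbulence-resolving computation (see
*Known limitations*).

## Kinematic estimation

**Frequency.**  The common tail-beat frequency is estimated from the peak
of the station-averaged periodogram and refined by a golden-section search
on the pooled residual sum of squares of per-station single-frequency
sinusoid fits.  The refinement window is $\pm 1.5$ Fourier bins around the
peak.  A flat (zero-variance) track raises an error, as does a record
shorter than two periods.

**Amplitudes.**  Per-station amplitude is defined as the amplitude of the
best-fit single-frequency sinusoid (half the peak-to-peak excursion).  The
source analysis does not state its estimator; the sinusoid least-squares
definition is robust to sampling phase (a frame grid rarely lands on the
extrema) and is exact on model-generated data, which makes the generator
round trip a meaningful test.

**Wavelength.**  Per-station phases $\psi_i$ (defined through
$h \approx A\cos(2\pi f t + \psi)$) are unwrapped nearest-branch along the
body axis and regressed on station position; the slope is $-2\pi/\lambda$.
For the default station set the largest inter-station phase step is well
below $\pi$, so nearest-branch unwrapping realizes the assumption of a
monotonically tailward-decreasing phase.  A slope of zero (all stations in
phase) is reported as an explicit standing-wave condition (`Inf` with an
attribute) rather than an error, since the regression itself is valid.
Stations with numerically zero amplitude are excluded; at least three
usable stations are required.

**Envelope.**  Stage 1 fits $\log(\text{amplitude})$ linearly in $x$ on
stations $x > 0.4$, giving $(c, d)$; stage 2 subtracts $c e^{dx}$ from the
amplitudes at $x < 0.25$ and fits the log of the positive residuals,
giving $(a, b)$.  Stations with $0.25 \le x \le 0.4$ are used by neither
stage, mirroring the two named regions.  With `iterations = 1` this is the
literal one-pass procedure; it is biased because the head term contaminates
the stage-1 slope (on the reference constants the recovered $d$ falls below
the generating value).  The default iterates the two stages, subtracting
the current head term before stage 1, until the largest relative parameter
change falls below $10^{-10}$; the generating constants are a fixed point
of this map, so noiseless model data are recovered to numerical precision.
Degenerate cases: if no stations lie in the head region the head term is
set to zero (pure tail-term fit); if the stage-2 residuals are nonpositive
the error names the offending stations; residuals that vanish identically
(data generated with $a = 0$) yield $a = 0$ immediately, which makes the
one-pass and iterated fits agree exactly in that case.

**Goodness of fit.**  $R^2 = 1 - SSE/SST$ pooled over all stations and
frames, with a global phase offset taken from the intercept of the phase
regression so that tracks not starting at the canonical phase are
reconstructed fairly.

## The synthetic-track generator

The generator emulates 60-fps video digitization of a station-holding fish
in a circulating flume: the model is sampled at fixed body-axis stations
(defaults are estimated anatomical fractions — snout 0, eye midpoint 0.05,
pectoral landmarks 0.15 and 0.25, dorsal landmarks 0.45 and 0.60, adipose
0.75, caudal root 0.85, caudal tip 1.13 — chosen so that both envelope-fit
regions are populated; the true landmark positions were never published)
and i.i.d. Gaussian noise is added to every sample.  The default noise
standard deviation is 0.002 BL (≈0.8 mm on a 0.397 m fish), a plausible
digitization error for a tracked landmark at this image scale.  Station
holding means no mean axial drift: the fish oscillates about fixed
stations.

What the generator does *not* emulate: occlusion, lens distortion,
tracking dropouts, frame-rate jitter, correlated (systematic) digitization
error, and body-shape-dependent landmark visibility.  Passing round-trip
tests therefore demonstrates estimator correctness under the stated noise
model, not robustness to every pathology of real video tracking.

## The vortex solver

**Discretization.**  Each body is its midplane camber line, deformed by the
body wave, divided into `n_panels` cosine-clustered panels (clustering
resolves the leading-edge pressure peak).  Bound point vortices sit at
panel quarter-chord points, collocation points at three-quarter points
(the lumped-vortex rule, which is exact for a steady flat plate).  The
no-penetration condition at each collocation point and one Kelvin
circulation-conservation constraint per body close the linear system; the
Kelvin row makes the newly shed trailing-edge vortex's circulation exactly
balance the change in bound circulation, which is the discrete Kutta
condition.  Conservation holds to solver round-off at every step (the
residual is checked and stored).

**Wake.**  One point vortex per body per step is released
$0.25\,U\Delta t$ behind the trailing edge along the local tangent.  (An
alternative anchored to the trailing-edge *panel* length was tried first
and rejected: with cosine clustering that panel shrinks as $N^{-2}$, which
tied the shedding geometry to the panel count and made thrust non-monotone
under joint panel/timestep refinement.)  Wake vortices carry Lamb-type
cores of radius equal to the mean panel length — equal cores also keep the
regularized wake–wake interactions impulse-conserving — and are advected
with the free stream plus all induced velocities using the explicit
midpoint rule.  Bound vortices use their local panel length as core radius
when inducing on wake or field points; the bound-on-collocation influence
uses the exact kernel, which the quarter/three-quarter construction
requires.  Wake vortices beyond the wake cap (default 10 L downstream) are
dropped from the induction sums but their circulation is retained in the
conservation bookkeeping.  An induced speed exceeding $50\times$ the inlet
speed aborts the run with a diagnostic.

**Pressure and friction.**  The pressure jump across panel $j$ follows the
unsteady Bernoulli equation,
$\Delta p_j = -\rho(V_{t,j}\gamma_j + \mathrm{d}\Gamma^{cum}_j/\mathrm{d}t)$,
with $V_{t,j}$ the tangential external velocity relative to the moving
panel (free stream, wake, and other-body induction, minus the prescribed
panel velocity), $\gamma_j$ the panel's circulation density, and
$\Gamma^{cum}_j$ the cumulative bound circulation from the leading edge
(backward time difference).  Forces are three-dimensionalized by the model
height.  Friction is modeled, not resolved: each panel contributes
$\tfrac{1}{2}\rho C_f |V_t| V_t \cdot (2\,\Delta l\,H)$ along its tangent,
with the global $C_f = 0.074\,Re^{-1/5}$ turbulent flat-plate correlation
(both sides wetted).  A rigid symmetric body at zero incidence produces
identically zero bound circulation, hence zero pressure drag — the
d'Alembert limit — and its total drag equals the friction model exactly,
which the tests assert.

**Forces, balance, efficiency.**  The flow runs in $+x$; the fish swims
toward $-x$.  Thrust is the $-x$ component of the pressure force summed
over elements where it points that way; the $+x$ component plus friction is
drag.  Time averages use an integer number of periods after discarding the
first two periods as startup transient (configurable; the pair-symmetry
test uses three, because the exchange symmetry it checks is a property of
the periodic state).  `balance_frequency()` bisects on tail-beat frequency
until $|F_T/F_D - 1| \le 0.05$, the "largely balanced" self-propelled
state in which efficiencies are compared.  In the power sums the element
travel-direction velocity is $u_i = U$: the prescribed deformation is
purely lateral, so the element's velocity relative to the water in the
travel direction is the swimming speed itself, which is what the force
decomposition diagram defines.  $v_i$ is the analytic lateral velocity of
the element.  Lateral element forces enter the lateral power as
body-on-fluid reactions, making $P_S$ the power expended against the
lateral fluid load (nonnegative on average), so $\eta = P_T/(P_T+P_S)$
lies in $[0,1]$ for converged runs.  For pair runs the efficiency is
reported per body and pooled; the published analysis never states which
was used.

**Pair runs.**  Bodies sit at $y = \mp d/2$; antiphase means body 2's
displacement is the negative of body 1's.  Antiphase is mirror-symmetric
about the midplane at every instant, so the force histories are exact
mirror images (thrust equal, lateral negated) — a machine-precision test
of the two-body assembly.  Inphase has no instantaneous symmetry; instead,
reflection shifts the global phase by $\pi$, so body 2's history equals
body 1's advanced by half a period once the wake is periodic, and the two
bodies' mean forces agree.

## Problem sizes and tunable parameters

Defaults follow the study conditions: inlet speed 1.52 BL/s for the main
runs; fluid density 998 kg/m³ and viscosity 1.02×10⁻³ Pa·s (water, 20 °C);
timestep 1/100 of the tail-beat period; eight periods simulated with two
discarded.  The test and acceptance suites use reduced sizes chosen for
the properties they check: 20–40 panels, 30–60 steps per period, and 3–6
periods for behavioral and symmetry checks (these properties are
resolution-robust), and an 80-panel/120-step versus 160-panel/240-step
pair for the convergence check, where the time-averaged thrust changes by
less than 5% under simultaneous panel doubling and timestep halving.
Separation values 0.4–2.0 L and both phase relations mirror the published
sweep design; the sweep rebalances the frequency per cell by default.

## Known limitations

* **Absolute forces and field magnitudes are solver-dependent.**  The
  published force table and velocity-ratio figures come from a
  three-dimensional RANS computation with ~1.2×10⁶ elements; a
  two-dimensional inviscid solver with modeled friction reproduces the
  qualitative structure (thrust at twice the tail-beat frequency, lateral
  force at the fundamental, balanced-state existence, far-field pair
  decoupling, antiphase ordering) but not those numbers, and the package
  makes no claim that it does.
* **Streamwise momentum accounting.**  The impulse bookkeeping is
  verified on the lateral component, where the pressure force tracks the
  rate of change of total vortex impulse closely.  On the streamwise
  component the momentum flux of the free, rolled-up wake exceeds the
  pressure-integrated thrust severalfold: thin-plate pressure integration
  carries no edge-suction term, and a collocation panel method is not
  momentum-consistent.  Thrust here is *defined* as the pressure
  component (the definition used for the published force table), so wake
  impulse is a qualitative, not quantitative, thrust diagnostic in this
  solver.
* **Strouhal number.**  With amplitude defined as half the peak-to-peak
  excursion and the tail tip at 1.13 BL, the reference kinematics at
  1.52 BL/s give St ≈ 0.35.  The published solitary value (0.34) is not
  reconstructable exactly from the printed quantities because the
  amplitude definition and tail-tip abscissa are unstated; both choices
  are exposed as arguments rather than asserted.
* **Kinematic idealizations.**  Pure lateral deformation (no arc-length
  preservation), no burst-and-glide, no acceleration, free-slip outer
  boundaries, and a rigid planform extruded section.
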