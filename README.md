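# finwake

Kinematics and desk-scale hydrodynamics of undulatory (subcarangiform) fish
swimming, solitary and in parallel pairs.

Schooling fish are thought to save energy through hydrodynamic interaction,
but isolating the forces on an individual body is impossible in live-fish
experiments.  `finwake` provides a tested, reproducible pipeline for the
modelling route: formulate the swimming motion of a real fish from tracked
midline landmarks, drive a deforming fish-body model with that motion,
compute the unsteady fluid forces on one or two swimmers, and compare
thrust/drag balance, Froude propulsive efficiency, and wake structure across
pair separations and tail-beat phase relations.

## The model

**Body-wave kinematics.**  The lateral displacement of the body axis is a
traveling wave under a double-exponential amplitude envelope,

```
h(x, t) = f(x) g(x, t)
f(x)    = a e^(bx) + c e^(dx)
g(x, t) = cos{ 2π (f t − x/λ) }
```

with `x` the body-axis position in body lengths (BL) from the snout, `h` the
lateral displacement (BL), `λ` the wavelength (BL) and `f` the tail-beat
frequency (Hz).  The head term `a e^(bx)` decays tailward (`b < 0`); the
tail term `c e^(dx)` grows toward the caudal fin and carries the thrust-
generating motion.  The constants are fitted from digitized video by a
two-stage procedure: log-linear least squares on the amplitudes at stations
`x > 0.4` gives `(c, d)`; the tail term is then subtracted from the
amplitudes at `x < 0.25` and a second log-linear fit of the positive
residuals gives `(a, b)`.  `finwake` implements both the literal one-pass
procedure and a fixed-point iteration of it that recovers model-generated
data exactly.  Frequency comes from a spectral peak refined by least
squares; wavelength from the regression of per-station sinusoid phases on
station position (slope `−2π/λ`).

**Hydrodynamics.**  The fish body is a rectangular-plate model with a NACA
4-digit symmetric section (model length 0.439 m, height 0.0893 m, maximum
thickness 0.0451 m; fish body length 0.397 m), deformed by prescribing the
body wave as nodal displacement and analytic nodal velocity.  Forces are
computed by a two-dimensional unsteady lumped-vortex panel method on the
horizontal midplane: bound point vortices enforce no-penetration at
collocation points, a Kutta condition sheds one free vortex per body per
timestep under per-body Kelvin circulation conservation, the wake is
advected freely with Lamb-core regularization, surface pressure follows the
unsteady Bernoulli equation, and a turbulent flat-plate friction correction
(`C_f = 0.074 Re^{−1/5}`) models the viscous drag an inviscid solver cannot
resolve.  Thrust is the swimming-direction component of the pressure force;
drag is the opposite component plus friction.  The Froude efficiency is

```
η = P_T / (P_T + P_S),   P_T = Σ F_Ti · u_i,   P_S = Σ F_Si · v_i
```

with per-element thrust and lateral forces `F_Ti`, `F_Si` and element
velocities `u_i` (travel direction) and `v_i` (lateral).  A bisection on
tail-beat frequency finds the self-propelled state where time-averaged
thrust balances drag.

## Worked example

```r
library(finwake)

## 1. fit the body-wave model to a (synthetic) digitized track
params <- bodywave_reference(1.52)              # fitted constants, 1.52 BL/s
cfg <- track_gen_config(params, fps = 60, duration = 4,
                        noise_sd = 0.002, seed = 42)
track <- generate_track(cfg)
fit <- fit_bodywave(track)
print(fit)
#> Body-wave fit
#> Body-wave parameters (subcarangiform traveling wave)
#>   envelope: 0.01878*exp(-6.07 x) + 0.006397*exp(2.634 x)  [BL]
#>   wavelength: 1.051 BL   frequency: 2.12 Hz
#>   phase offset: -0.0006395 rad
#>   R-squared (pooled): 0.99712

## 2. simulate the solitary swimmer with the fitted kinematics
sim <- simulate_swimmers(sim_config(1.52, fit$params, n_panels = 40,
                                    steps_per_period = 60, n_periods = 4))
print(thrust_drag_series(sim))
#> Force series: <F_T> = 0.5025 N, <F_D> = 0.1671 N, F_T/F_D = 3.008 (2-period average)
print(froude_efficiency(sim))
#> Froude efficiency: eta = 0.3805 (P_T = 0.3032 W, P_S = 0.4936 W)
cat(sprintf("Re = %.3g, St = %.2f\n",
            reynolds_number(1.52), strouhal_number(fit$params, 1.52)))
#> Re = 2.59e+05, St = 0.35
```

The fitted envelope constants sit within a fraction of a percent of the
generating values despite the added digitization noise (0.002 BL), and the
pooled R² of 0.997 shows the reconstructed wave tracks the noisy data.  At
the measured tail-beat frequency the model over-produces thrust
(`F_T/F_D` ≈ 3 in this solver); `balance_frequency()` finds the
self-propelled frequency at which the ratio returns to 1, which is the
state in which efficiencies are compared.  `parallel_sweep()` then maps
Froude efficiency over pair separation and phase:

```r
base <- sim_config(1.52, params, n_panels = 30, steps_per_period = 50,
                   n_periods = 4)
tab <- parallel_sweep(c(0.4, 0.8, 2.0), base = base, bracket = c(1, 4))
```

Command-line wrappers for the five analyses (`fit`, `synth`, `sim`,
`sweep`, `transect`) live in `inst/cli/finwake.R`; each run writes its
outputs atomically together with a JSON manifest (config hash, seed,
package version, output list).

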