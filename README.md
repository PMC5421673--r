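# anklestiff

EMG-driven estimation of ankle joint stiffness with a square-root cubature
Kalman filter.

## What it does

Joint *quasi-stiffness* — the derivative of joint torque with respect to
joint angle, κ = ∂τ/∂φ — is modulated continuously during movement, largely
through coactivation of antagonist muscles, which stiffens a joint while
leaving the net torque almost unchanged.  Because of that, stiffness cannot
be read off external measurements alone.  `anklestiff` implements a
model-based estimator for researchers in biomechanics and wearable sensing:

* a sagittal-plane neuromusculoskeletal model of the lower extremity —
  three segments (thigh, shank, foot), a tilted talocrural hinge axis,
  six Hill-type muscles (RF, HAMS, VM, GAS, SOL, TA) with first-order
  activation dynamics, fourth-order polynomial moment-arm/length tables,
  Euler-Lagrange multibody dynamics and nonlinear passive joint torques;
* a generic third-degree **square-root cubature Kalman filter** (SCKF) that
  fuses joint-angle measurements with the EMG-driven model over the
  16-dimensional state

  x = (φ_knee, φ_ankle, φ̇_knee, φ̇_ankle, a₁…a₆, F̄₁…F̄₆),

  with the covariance carried as a triangular square root (QR
  triangularisations and triangular solves only — robust to the model's
  nonsmooth dynamics);
* torque reconstruction and ankle quasi-stiffness by the product rule
  κ = Σᵢ (∂r_i/∂φ) F_i + r_i (∂F_i/∂φ) at frozen muscle states, with the
  passive contribution reported separately;
* a forward simulator (sinusoidal hip drive, block-wise muscle activation,
  additive Gaussian state and measurement noise) that generates fully
  synthetic in-silico experiments, so every estimator claim is testable
  without recorded data.

## Worked example

```r
library(anklestiff)

model <- lower_limb_model()          # default anthropometry (79.2 kg, 1.816 m)
model
#> Sagittal-plane lower-extremity model (EMG-driven, 16 states)
#>   segments: thigh 0.440 m / 11.2 kg, shank 0.448 m / 3.4 kg, foot 0.268 m / 1.1 kg
#>   ankle axis: alpha_TC_tla 80.0 deg, alpha_TC_fml 84.0 deg
#>   geometry tables (quartic, 1 deg grid): max length fit residual 7.36e-04 m
#>   muscles: RF, HAMS, VM, GAS, SOL, TA

record <- simulate(model, seed = 1)  # 40 s in-silico experiment at 100 Hz
record
#> Forward-simulation record: 40.0 s at 100 Hz (4000 samples)
#>   knee angle range  [-16.0, 6.8] deg
#>   ankle angle range [-49.6, 18.9] deg
#>   ankle torque range [-28.24, 33.06] N m

fit <- ankle_sckf(record, model)     # square-root cubature Kalman filter
summary(fit)
#> SCKF fit: 4000 steps at 100 Hz, 44845 clamp events
#>   angle RMS error [deg]:  knee 0.1426, ankle 0.2253
#>   rate RMS error [rad/s]: knee 0.0697, ankle 0.5725
#>   torque RMS error [N m]: knee 0.3166, ankle 0.6630

ks <- quasi_stiffness_series(fit)    # N m/rad; active, passive, total
head(round(smooth_stiffness(ks)[, c("time", "kappa_active", "kappa_total")], 3), 3)
#>   time kappa_active kappa_total
#> 1 0.00        0.000      -4.587
#> 2 0.01        0.549      -4.009
#> 3 0.02        1.182      -3.393
```

The summary numbers are RMS errors of the filter's estimates against the
simulation truth: with the default noise configuration (0.3° angle
measurement noise, small process noise on all states) the filter tracks
both joint angles to fractions of a degree and the angular rates to a few
tenths of a rad/s, and reconstructs joint torque to well under 1 N m RMS.
`plot(fit)` overlays estimated and true angles, rates and ankle torque.

A coactivation experiment — ramping a torque-balanced dorsiflexor /
plantar-flexor drive at a held posture — shows the property the estimator
exists for: stiffness rises monotonically while net torque stays near zero.

```r
round(coactivation_sweep(model)[c(1, 5, 10), ], 4)
#>    scale kappa_active kappa_total tau_active
#> 1    0.1       3.1335     -1.8681    -0.0075
#> 5    0.5      15.6673     10.6657    -0.0374
#> 10   1.0      31.3346     26.3330    -0.0748
```

All shipped numeric defaults (axis tilts, muscle nodal points, passive
torque coefficients, anthropometry scaling) are plausible literature-style
placeholders and fully configurable via YAML
(`write_model_config()` / `read_model_config()`).  A thin command-line
front end (`inst/cli/anklestiff.R`) exposes `simulate`, `estimate` and
`stiffness` subcommands over CSV files.

## Package layout

| where | what |
| --- | --- |
| `R/geometry.R` | frames, tilted ankle axis, muscle paths, moment arms, quartic tables |
| `R/muscle.R` | activation dynamics, Hill-type contraction, tendon force |
| `R/dynamics.R` | Euler-Lagrange dynamics, passive/active/external torques, 16-state assembly |
| `R/sckf.R` | generic square-root cubature Kalman filter |
| `R/signals.R` | EMG envelope chain, band-limited differentiation filter |
| `R/simulate.R` | protocol, synthetic EMG, forward simulator, experiment driver |
| `R/estimate.R` | `ankle_sckf()` fit object and methods |
| `R/stiffness.R` | torque reconstruction, quasi-stiffness, coactivation sweep |
| `vignettes/` | methods vignette: model, assumptions, design decisions |
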