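---
title: "Model-based ankle stiffness estimation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based ankle stiffness estimation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science inside `anklestiff`: the biomechanical
model, the square-root cubature Kalman filter (SCKF), the synthetic
experiment that the test suite and the acceptance script run, and the design
decisions that were genuinely open.

## The estimation problem

Joint quasi-stiffness — the derivative of joint torque with respect to joint
angle, $\kappa = \partial\tau/\partial\varphi$ — changes continuously during
human movement, in large part through coactivation of antagonist muscles,
which raises stiffness while leaving the net torque almost unchanged.
External measurements (angles, torques) therefore cannot resolve stiffness
changes on their own; an EMG-driven model can.  The package implements a
model-based state observer: a sagittal-plane neuromusculoskeletal model of
the lower extremity is driven by surface-EMG envelopes, and a nonlinear
Kalman filter corrects its state with segmental-orientation (joint angle)
measurements.  Joint torques and ankle quasi-stiffness are then computed
from the estimated state.

## The lower-extremity model

**Kinematics.**  Three rigid segments (thigh, shank, foot) connect through
three sagittal hinge joints.  The upper ankle (talocrural) joint is a single
fixed hinge whose axis is tilted against both the tibia axis
(`alpha_TC_tla`) and the foot mid-line (`alpha_TC_fml`); foot-fixed points
are mapped into the shank frame by a homogeneous transform composing the
axis rotation with the fixed tilts $\beta = \alpha_{TC}^{fml}-90^\circ$ and
$\gamma = 90^\circ - \alpha_{TC}^{tla}$, and are then projected into the
sagittal plane (the global frame has x anterior, y superior, z mediolateral;
projection drops z).  Because of the tilt, the projected centre of rotation
migrates with the ankle angle; it is recovered at every angle from the
intersection of perpendicular bisectors of small-rotation displacement
chords of two tracked foot points.

Angle conventions: hip flexion positive on $(-20^\circ, 150^\circ)$; knee
flexion negative with $0^\circ$ at full extension and a $+10^\circ$
physiological hyperextension allowance; ankle dorsiflexion positive on
$(-60^\circ, 20^\circ)$.  Library calls reject out-of-range angles by
default; the filter loop clamps instead, because cubature points may
transiently leave the range.

**Muscle geometry.**  Six muscles drive the model: rectus femoris (RF),
hamstrings (HAMS), vastus medialis (VM), gastrocnemius (GAS, biarticular
over knee and ankle), soleus (SOL) and tibialis anterior (TA).  Muscle paths
are straight line segments through frame-tagged nodal points; the TA runs
under a retinaculum pair that defines its effective origin and contact
point, and the quadriceps act through a patellar pulley point fixed in the
shank frame so that their line of action never collapses onto the knee
centre in deep flexion.  The moment arm is the perpendicular distance of the
projected rotation centre from the line through effective origin and
contact, made signed by the muscle's action direction (positive torque
increases the joint angle).  MTC lengths and moment arms are evaluated on
1-degree grids over the admissible ranges and approximated by fourth-order
polynomials (a 15-term bivariate fourth-order surface for biarticular
dependencies); the maximum fit residual is stored with every table and is
below 1 mm for the shipped geometry.  The derivative-based moment arm
$\partial l_{MT}/\partial\varphi$ (principle of virtual displacements) is
available for cross-validation; it agrees in sign and overall shape with the
distance-based arm but shows an offset, because the projected centre of the
tilted axis migrates.  The distance-based arms enter the dynamics.

All nodal-point coordinates, axis angles and muscle constants shipped as
defaults are plausible literature-style values, clearly non-canonical and
fully configurable through the YAML model configuration
(`write_model_config()` / `read_model_config()`).

**Muscle dynamics.**  Each muscle contributes two states: activation $a$
(first-order bilinear lag from the EMG envelope $s$, with
$\dot a = (s/\tau_{act} + (1-s)/\tau_{deact})(s-a)$, activation faster than
deactivation) and normalised isometric force $\bar F^{isom}$, which tracks
the activation-scaled Gaussian force-length capacity with a first-order lag.
The tendon is rigid (constant slack length, calibrated so each fibre sits at
its optimal length in a mid-range reference posture), so fibre velocity is
the joint-rate times the MTC length slope over $\cos\alpha_p$.  Tendon force
is $F^T = F_{max}\,\bar F^{isom} f_v(v_M/v_{max})$ with a hyperbolic
force-velocity characteristic (zero at maximal shortening, 1 isometric,
saturating at 1.5 eccentric).  Passive muscle elasticity and viscosity are
*not* in the tendon force; they are lumped at joint level, avoiding
double-counting.

**Dynamics.**  The three-segment Euler-Lagrange equations
$M(q)\ddot q + D(q,\dot q)\dot q + k(q) = \tau$ use de Leva-style segment
anthropometry scaled from body mass and height.  The inertia matrix is
closed-form; its partials (for the Christoffel form of $D$) are analytic,
with a central-finite-difference route retained and cross-checked in the
tests — the analytic route was adopted after profiling showed the
finite-difference partials dominating the filter's runtime, and the two
agree to $10^{-7}$.  The hip is an exogenous input (angle, rate,
acceleration), so the system is reduced to the knee/ankle rows with hip
coupling terms moved to the right-hand side.  Joint torques compose active
(moment arm times tendon force), passive elastic (double-exponential
characteristics with biarticular coupling to neighbouring joints, an
extension-limit term at the knee), viscous (odd power law
$K_V\,\mathrm{sgn}(\dot q)|\dot q|^{n_V}$) and external (ground-reaction
cross product about the joint axis) contributions.

The default viscous exponent is $n_V = 1$ (linear).  A super-linear
exponent has vanishing small-signal damping
($\mathrm d|\dot q|^{n}/\mathrm d\dot q \to 0$), which leaves the light
foot's ~3 Hz mode undamped around equilibrium; under the explicit-Euler
discretisation used by both the filter model and the default simulation
model that mode then slowly accretes energy and chatters against the
passive stops.  Linear damping keeps the discretised foot mode well damped
at 100 Hz.  The exponent remains configurable.

The passive elastic defaults were chosen to give physiologically plausible
magnitudes: a few N m in mid-range, tens of N m at the range limits, and a
passive foot resonance near 3 Hz (a few N m/rad of passive ankle stiffness
at neutral).

**State space.**  The 16-dimensional state orders knee and ankle angles,
their rates, six activations and six normalised isometric forces; the
15-channel input orders six EMG envelopes, hip angle/rate/acceleration,
centre-of-pressure coordinates and ground-reaction force components.  The
measurement is the pair of joint angles, $y = (x_1, x_2)$.

## The square-root cubature Kalman filter

The filter is a generic third-degree cubature Kalman filter in square-root
form: $2n$ cubature points $\pm\sqrt{n}\,e_i$ with uniform weights $1/(2n)$
(no negative weights), the error covariance carried as a lower-triangular
factor $P = SS^\top$ maintained exclusively by QR triangularisations, and
the Kalman gain computed by two triangular solves — never an explicit
inverse.  The triangularisation normalises the sign of the diagonal so
results are deterministic across platforms.  Because the model is nonsmooth
(the sign function in the viscous torque; clamped geometry at range edges),
derivative-free cubature propagation is the appropriate linearisation-free
choice, and the square-root form keeps the covariance symmetric positive
semidefinite by construction.

State constraints are handled by clamping cubature points before
propagation (activations to $[0,1]$, normalised forces to $[0, 1.5]$,
angles to their admissible ranges); clamp events are counted and reported.
The filter-internal transition is the one-step explicit Euler
discretisation $x_{k+1} = x_k + T_s f(x_k, u_k)$ at $T_s = 10$ ms.

## The in-silico experiment

The synthetic protocol drives the hip with
$\varphi_{hip}(t) = 20^\circ \sin(\tfrac{\pi}{2}\,\mathrm{rad/s}\; t)$, all
joints starting from zero, and activates the muscle groups in smooth 5 s-on
/ 5 s-off blocks over 40 s: plantar flexors, then the dorsiflexor, then the
knee muscles, then an ankle antagonist-coactivation block.  Block levels
(0.10-0.25 of maximum) were chosen so every joint stays inside its
admissible range under the default passive parameters.  White Gaussian
noise is added to all 16 states once per estimator period (defaults:
$10^{-3}$ rad on angles, $5\times10^{-3}$ rad/s on rates, $2\times10^{-3}$
on muscle states) and to the angle measurements (0.3°, a realistic
magnitude for magnetic-angular-rate-gravity orientation sensors).  The hip
rate and acceleration supplied to the estimator come from the band-limited
differentiator $G(s) = s/((s/30+1)(s/300+1)^2)$ (bilinear-transform
realisation, applied twice for the acceleration), not from the analytic
derivatives — exactly as one would have to do with measured hip angles.

By default the truth trajectory is generated with the *same* explicit-Euler
discretisation as the filter model, so simulation and filter differ only by
the injected noise; this is the configuration under which the in-silico
error bounds (angle RMS below 0.4°, rate RMS below 0.7 rad/s) are
reproduced by `run_estimation_experiment()` and the acceptance script.  A
fixed-step classical Runge-Kutta truth integrator at 10 substeps per period
is available (`sim_protocol(integrator = "rk4")`) for studying genuine
integrator mismatch; with the light foot segment the Euler filter model's
discretisation error then dominates the rate errors, which is informative
about real deployments but is a deliberately harder condition than the
plain protocol.

What the synthetic data does *not* emulate: raw-EMG artifacts and
electrode-placement variability (envelopes are generated directly),
soft-tissue motion of orientation sensors, elastic tendons, out-of-plane
ankle motion, and ground contact (the ground-reaction input is zero in the
default protocol).  Passing the in-silico tests therefore demonstrates the
estimator's correctness and noise rejection under the model's own
assumptions, not its accuracy on recorded human data.

## Quasi-stiffness

The ankle quasi-stiffness is evaluated by the product rule over the ankle
muscles,
$\kappa = \sum_i \frac{\partial r_{ma_i}}{\partial\varphi} F_i^T +
r_{ma_i} \frac{\partial F_i^T}{\partial\varphi}$,
with the moment-arm derivative analytic from the quartic table and the
force derivative by central perturbation of the ankle angle
($10^{-4}$ rad) with the muscle states frozen — stiffness is an
instantaneous mechanical property, so activation and normalised force do
not respond to the virtual angle change.  The passive elastic derivative is
reported as a separate additive column (`kappa_passive`), with
`kappa_total` the sum: whether a reported quasi-stiffness should include
the passive term is application-dependent, so both are emitted.  A
moving-average smoother is provided because the raw series can show short
unphysiological peaks when noisy envelopes pass through the contraction
dynamics; the raw series is always retained.

With a rigid tendon and frozen states, the force derivative vanishes at
zero joint rates, so the static active stiffness is carried entirely by the
moment-arm geometry and scales linearly with the muscle drive.  The
coactivation experiment (`coactivation_sweep()`) ramps a torque-balanced
antagonist set (TA against SOL + GAS) at a held posture: stiffness rises
monotonically while the net torque stays near zero — the phenomenon that
motivates EMG-driven stiffness estimation in the first place.

## Numerical and testing choices

* Geometry tables: 1° grids; fit residuals stored; out-of-range queries
  error in library calls and clamp in the filter/simulation context.
* Explicit Euler is first-order: the torque-free energy-drift test checks
  that halving the step halves the drift; the classical Runge-Kutta truth
  option is validated against a high-accuracy `deSolve` reference.
* The linear-Gaussian equivalence test runs the SCKF against a textbook
  covariance-form Kalman filter for 1000 steps (relative error $<10^{-8}$);
  a covariance-form cubature filter serves as a second oracle on a
  nonlinear run.
* Problem sizes in the default test run: one 40 s estimation experiment at
  100 Hz (4000 filter steps, 32 cubature points each), one 8 s record for
  structural tests, and Monte-Carlo moment checks with $10^5$ samples —
  sizes chosen so the whole suite completes in a few minutes on one core.
* Fixed seeds are used throughout the tests; the acceptance script takes
  its seed from the command line.

## Known limitations

* The hamstring group (HAMS; in some muscle sets labelled by its
  semitendinosus representative, ST) is modelled as a single line; the
  quadriceps patellar mechanism is a single pulley point, so deep-flexion
  knee moment arms are coarse.
* Rigid tendons: series elasticity is deliberately excluded, which
  suppresses the force-length contribution to instantaneous stiffness at
  fixed states; reported active stiffness is geometry-dominated.
* The knee centre is fixed for the dynamics; tibiofemoral translation is
  ignored.
* All shipped numeric defaults (anthropometry, nodal points, passive
  coefficients) are plausible placeholders, not subject-specific or
  canonical values; quantitative agreement with any particular subject
  requires configuration.
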