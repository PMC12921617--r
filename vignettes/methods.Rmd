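---
title: "Models and methods behind fieldcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fieldcycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldcycle)
```

`fieldcycle` implements the computational side of a magnetic field cycling
(MFC) NMR platform: a shuttle moves the sample between the spectrometer's
9.4 T isocenter and a mu-metal shield below it, where fields from a few
nanotesla to 12 mT can be set. Around that instrument sit five analyses:
shimming of the shield, field calibration and shuttle kinematics, NMRD
(relaxation dispersion) of [1-13C]pyruvate, hyperpolarization loss
budgeting during transfer, and SABRE-SHEATH exchange kinetics. This
vignette describes the models, their assumptions, the tunable parameters,
and the choices made where the design was genuinely open.

## Field geometry and calibration

Positions along the shuttle axis are expressed in stepper microsteps, with
0 at the outside homing switch and 33,000 at the B0 isocenter; percent and
millimetre coordinates derive from the exact drive ratio 1747.2 mm per
48,000 microsteps (0.0364 mm per microstep; the full travel is 120.12 cm).

Three actuators cover the field range, and `plan_field_setting()` picks
exactly one per target:

* **z-shim coil** of the shield for |B| up to 3.16 uT (the coil responds at
  ~108 nT/mA on top of the optimized shim currents);
* **solenoid electromagnet** (SE) at the fixed 3.34% shield position up to
  12 mT, via a field-to-current lookup table;
* **NMR stray field** above 12 mT, via a field-to-position lookup table
  built from the measured flank.

Lookup tables only invert the largest strictly monotone region of a
calibration (the stray-field profile plateaus near the isocenter), use
monotone Hermite interpolation inside the calibrated range, and refuse to
extrapolate: the stray field is smooth but unknown outside the scan, and a
wrong position silently maps the sample to a very wrong field. The 12 mT
regime boundary is taken on the field axis (the equivalent current at the
~7 mT/A solenoid slope is about 1.69 A).

Shuttle motion is the standard trapezoidal profile (acceleration 6552
mm/s^2, maximum velocity 1747.2 mm/s for downward motion), triangular when
the travel is too short to reach full speed. The closed-form travel time
for the full 1201.2 mm is about 954 ms; measured shuttle times are longer
because friction in the curved guide is not modelled, so the kinematic
profile is an idealized lower bound. Composing position(t) with the
field-vs-position spline yields the field-vs-time profile a sample
experiences (`field_during_motion()`), the input to the loss integral
below.

## Shimming the mu-shield

The shield hosts nine shim coils (X, Y, Z offsets; dY/dx, dZ/dx, dZ/dy,
dY/dy, dZ/dz gradients; one quadratic d2Z/dz2). Each coil's unit response
mu_coil(z) is calibrated from scans at +/-20 mA as the symmetric
difference divided by 2|I| -- which also cancels any odd response
nonlinearity. All profiles are cubic-spline resampled to the densest
common grid before arithmetic.

**Simulative tuning** minimizes the regularized loss

L(I) = sum_sample ||B_b(z) + sum_coil I_coil mu_coil(z)||^2
       + alpha sum_coil I_coil^2,

with the analytic gradient 2 sum B . mu_coil + 2 alpha I_coil, over the
sample region (default 5 cm centred at 5.35% of travel). The loss is
linear-quadratic, so the quasi-Newton iterate is polished by one
normal-equations step; the test suite checks the optimizer against an
independently coded closed-form least-squares oracle at alpha = 0.
Confidence intervals come from the inverse Hessian, the residual variance,
and a t-quantile with n - 9 degrees of freedom (a t rather than normal
quantile; on linear-Gaussian synthetic replicates the 95% intervals cover
at the nominal rate). A near-singular Hessian (e.g. a dead coil, which is
dropped from the design with a warning) triggers a ridge fallback for the
intervals only.

The regularization weight alpha is not a physical constant; its purpose is
to suppress degenerate large-current solutions that would amplify
calibration nonlinearity and drift. The default alpha = 1e-2 nT^2/mA^2
keeps the penalty far below the unshimmed loss (~10^8 nT^2 for a 551 nT
background over 200 points) while bounding currents at the tens-of-mA
scale; it is a user-visible argument everywhere.

**Iterative tuning** then walks only the X, Y, Z currents by coordinate
descent against a live field probe at the sample position, with step sizes
from 0.1 mA down to 0.01 mA, accepting only steps that reduce the probed
magnitude (so the field never increases between accepted steps), and
stopping below 2 nT. The sweep order X, Y, Z is arbitrary; on linear
probes the result is order-independent, which the tests verify indirectly
through convergence to the closed-form nulling currents. With the
synthetic probe's default diagonal sensitivities (55, 50, 108 nT/mA) the
0.01 mA granularity bounds the reachable floor at roughly half a
nanotesla per axis, comfortably below the 2 nT target.

## NMRD of [1-13C]pyruvate

Per-field relaxation decays are fitted globally as

S_i(t) = A1_i exp(-t/tau1_i) + A2_i exp(-t/tau2) + y0_i,

with tau2 and the fraction A2/A1 shared across fields, per-field amplitude
and baseline free, and T1(B) taken as the fast constant tau1. The shared
slow component compensates a small secondary decay; its amplitude is
initialized at 5% and tau2 at twice the largest initial tau1. When the
secondary amplitude is small, tau2 itself is weakly identified (it can
drift toward a flat baseline); the per-field tau1 values are unaffected,
which is what the tests pin down. Weights are inverse variance when errors
accompany the data, unit otherwise.

R1(B) = 1/T1(B) is then fitted with the three-term dispersion model

R1 = dw1^2 tau_C1 / (1 + (w tau_C1)^2)
   + dw2^2 tau_C2 / (1 + (w tau_C2)^2)
   + (1/5) (w delta_CSA)^2 tau_CSA / (1 + (w tau_CSA)^2),

where w = gamma_13C B (gamma_13C = 2 pi x 10.7084 MHz/T is a package
constant, as are the 1H and 15N ratios). The two inner-sphere Lorentzians
produce the two dispersion elbows below 1 T; the CSA term rises as B^2 at
high field. The model is implemented exactly in this printed form, with no
spin-number or dipolar prefactors: the fitted dw are effective coupling
constants, not molecular ones, and no correction is invented for that.
Note the model is a description of the dispersion shape, not an absolute
T1 predictor at 9.4 T.

Two numerical choices matter. First, all six parameters are positive and
span nine orders of magnitude, so the fit runs in log-parameter space with
Levenberg-Marquardt and relative (or inverse-variance) weights. Second,
for a 13C nucleus w tau_CSA stays far below 1 up to tens of tesla, so the
CSA term reduces to (1/5) delta^2 tau_CSA w^2 and only the product
delta_CSA^2 tau_CSA is identifiable from data up to 9.4 T. `fit_nmrd()`
therefore holds tau_CSA at its initial value by default (3.5 ps for the
pyruvate set) and lets delta_CSA carry the fit; freeing it is a one-
argument change and raises a degeneracy warning when the fit becomes
ill-conditioned, as it also does when the two correlation times collapse
onto each other. The default initial values are the package's canonical
pyruvate parameters (dw1 = 91.6 rad/s, dw2 = 736.9 rad/s, tau_C1 = 541.8
ns, tau_C2 = 6.6 ns, delta_CSA = 46.1 ppm, tau_CSA = 3.5 ps).

`t1_interpolator()` interpolates log R1 against log B with a monotone
Hermite spline and clamps to the endpoint values outside the measured
range -- extrapolating a dispersion curve beyond its data is the one thing
worse than clamping.

The INEPT bookkeeping is pure arithmetic: averaging time to fixed SNR
scales as 1/SNR^2 and repetition time as the T1 of the polarization
source, so a 2.53-fold signal gain repeating at the 4.9 s proton T1
instead of the 45.5 s carbon T1 shortens the measurement ~59.4-fold.

## Hyperpolarization losses during transfer

With thermal repolarization neglected, the retained polarization over a
transfer is P(T)/P(0) = exp(-Int_0^T R1(B(t)) dt). The integrand is
evaluated on the profile grid (fields linear in time between samples) by
the composite trapezoid rule, with midpoint refinement until the integral
moves less than 1e-6 relative; fields are clamped at a 1 nT floor before
the T1 lookup so the interpolator is never queried below the physical
shimmed-zero scale. External interfaces use percent, internal math uses
fractions.

The measured transfer profiles behind the published scenario comparison
are not tabulated anywhere, so the generator provides stylized stand-ins:
exponential decay from the polarizer stray field (3.35 T) to a 50 uT
ambient floor, a transport segment, and an exponential rise into the 9.4 T
stray field over 19.5 s (the typical 16.8 m transfer). Magnet scenarios
floor nested time segments at 10 mT, so the three profiles dominate each
other pointwise and the retention ordering (receiver + transfer magnet >=
transfer magnet >= no magnet) is a structural property -- that ordering,
not any particular percentage, is what the package tests. Back-calculation
of the polarization at dissolution is the exact inverse of the forward
loss: observed/(1 - loss).

## SABRE-SHEATH exchange kinetics

Selective-inversion kinetics (invert free or bound pyridine, follow both
integrals over delays up to 50 s) are fitted globally with the shared
biexponential A1 exp(-tau k) + A2 exp(-tau R): one effective exchange rate
k and one effective relaxation rate R across all series, amplitudes free
per series and unconstrained in sign. Given (k, R) the amplitudes enter
linearly, so they are profiled out by linear least squares at each rate
pair (variable projection) and only (log k, log R) are optimized, seeded
by a coarse rate grid -- robust to starting values by construction.
Uncertainties come from the full-parameter Jacobian at the optimum. Rates
closer than a factor of 3, or a vanishing slow amplitude, raise
identifiability warnings. Any subset of the four series is accepted.

The rate algebra is the two-equatorial-site model: with
[Py]free = [Py]total - 3 [Ir], the dissociation rate constant is
k_d = k / (0.5 + [Ir]/[Py]free) and the effective association rate
k_a' = ([Ir]/[Py]free) k_d. The factor 0.5 reflects the two equivalent
equatorial ligand sites and is configurable for other complexes.
Uncertainty propagates first order. The mechanistic companion
`simulate_two_site_kinetics()` exchanges magnetization between the free
and exchangeable-bound pools at forward rate k_a' and backward rate
0.5 k_d, so its nonzero kinetic eigenvalue equals
k_d (0.5 + [Ir]/[Py]free) = k; it exists to exercise the fitting chain
end to end, not to replace the phenomenological fit.

PTF sweeps are read out by a local quadratic fit around the discrete
maximum (vertex = optimum field, with the half-width of the 5% near-flat
region reported, since the underlying optimum is a plateau rather than a
point) and linear interpolation at sign changes for zero crossings.

## The synthetic instrument

Every input kind has a seeded generator, so the full pipeline runs and is
tested without hardware. One root seed derives per-generator substreams;
each generator is bit-reproducible and restores the caller's RNG state.
Defaults encode the study conditions: a ~551 nT background with ~8%
relative SD dominated by the XY components (component scales ~375/395/80
nT with shared smooth Fourier variation over the 36.4 cm, 200-point
shield scan), 1 nT magnetometer noise, a 108 nT/mA z-shim axis, 2%
multiplicative relaxometry noise, 2% additive exchange noise, and 16
exchange delays over 0-50 s spaced geometrically at the short end so the
sub-second exchange decay is actually sampled. The gradient coils carry
small cross-components so the on-axis design matrix stays full rank, as
for physical coils; the solenoid model is the finite-length on-axis
formula summed over six winding layers (~6.8 mT/A, consistent with the
~7.1 mT/A calibration slope to within the fidelity of a desk model).

What the generators do *not* emulate: mu-metal hysteresis and degaussing,
field drift beyond a linear knob, temperature-dependent chemistry,
spectral artifacts, or the measured transfer profiles. Tests passing on
synthetic data therefore demonstrate that the estimators are correct and
calibrated under the stated statistical model -- not that the model
captures every behaviour of the physical instrument.

## Problem sizes and limitations

The analysis drivers and tests use 200-point field scans, 12-30 field
NMRD designs, 16-delay exchange series, and recovery studies of 50-100
seeded repeats; these sizes reproduce the printed uncertainty scales while
keeping any single analysis in seconds. Known limitations: no friction
model for the shuttle (kinematic times are lower bounds), the dispersion
model's absolute scale at 9.4 T is not tied to measured T1 values, the
transfer scenarios are stylized, and the phenomenological exchange k is
related to mechanistic rates only through the printed two-site relations.
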