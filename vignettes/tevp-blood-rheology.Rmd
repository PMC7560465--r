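---
title: "A thixotropic elasto-visco-plastic model of blood: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A thixotropic elasto-visco-plastic model of blood: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tevpblood)
```

## The model and its assumptions

Blood at rest is held together by a network of rouleaux — column-like red
blood cell aggregates bridged by plasma proteins. That network gives whole
blood a small yield stress (a few mPa at physiological hematocrit), an
elastic response below yield, and a viscosity that depends on how much of
the network is currently intact. `tevpblood` implements a tensorial,
single-mode thixotropic elasto-visco-plastic (TEVP) constitutive model of
this behaviour built from four ingredients:

1. **Elasto-visco-plastic split.** The total deformation rate decomposes
   additively, `D = De + Dvp`. The elastic part is related to the stress
   through the upper-convected derivative, `De = UC(tau) / (2 G)`, so for a
   homogeneous flow with velocity gradient `L` the stress evolves as
   `dtau/dt = L tau + tau t(L) + 2 G (D − Dvp)`. At zero stress this is a
   neo-Hookean solid (`dtau_xy/dt = G * gamma_dot` at shear startup).
2. **Von Mises yielding.** The viscoplastic part is
   `Dvp = f[tr tau] * max(0, (sigma_eff − tau_y) / (2 eta_t sigma_eff)) * tau`
   with `sigma_eff = sqrt((tauD : tauD) / 2)`; it vanishes identically at and
   below the yield surface and is proportional to the stress tensor above
   it. With this normalisation `sigma_eff` equals the shear stress in pure
   shear, so the low-rate limit of the steady flow curve is exactly `tau_y`.
   In uniaxial extension the same definition gives `sigma_eff = N1 / sqrt(3)`,
   so the extensional "yield plateau" of the steady first normal-stress
   difference is `sqrt(3) * tau_y`.
3. **Linear PTT factor.** `f = 1 + eps_PTT * tr(tau) / G` multiplies the
   whole plastic term (taken literally from the constitutive statement) and
   bounds the extensional viscosity at high strain rates. Shear thinning is
   *not* routed through the PTT function; it comes from thixotropy.
4. **Structure kinetics.** A scalar `lambda ∈ [0, 1]` tracks the rouleaux
   level (1 = fully structured, the assumed initial state). It obeys
   `dlambda/dt = (k1 + k2 phi^n1)(1 − lambda) − k3 phi^n2 lambda^n3` with the
   stress-controlled flow parameter `phi = max(0, sigma_eff − tau_y)`:
   Brownian rebuild at `k1`, flow-induced rebuild at `k2`, breakdown at
   `k3`. The plastic viscosity and relaxation time inherit the structure
   level: `eta_t = eta0 lambda^m1`, `chi = (eta0 / G) lambda^m1`.

Neglected on purpose: kinematic and isotropic hardening (no flow-reversal
data to constrain them, so `tau_eff = tau_ve` and `tau_y` is
history-independent), multi-mode thixotropy, inertia, spatial inhomogeneity
(no momentum balance — the kinematics are imposed), and any temperature or
hematocrit dependence of the parameters beyond the Morris yield-stress
correlation.

The state is the full symmetric 3-D stress tensor plus `lambda` — seven
ODEs. Keeping all six stress components even for planar shear lets
predictions such as `tau_yy(t) = 0` be verified rather than assumed; the
test suite checks it to integration tolerance.

## Parameters

Eleven constants, strict SI internally (Pa, s; mPa only at the reporting
layer, and 1 dyn/cm2 = 0.1 Pa in the Morris correlation):

| name | unit | meaning | preset `mcmillan1987_subject` |
|------|------|---------|------------------------------|
| `G` | Pa | elastic modulus | 0.382 |
| `eta0` | Pa s | plastic viscosity at `lambda = 1` | 0.012 |
| `tau_y` | Pa | yield stress | 0.0035 |
| `eps_ptt` | – | PTT mobility | 0.001 |
| `k1` | 1/s | Brownian rebuild rate | 0.0918 |
| `k2` | – | flow-induced rebuild coefficient | 7.249 |
| `k3` | – | breakdown coefficient | 6974.9 |
| `n1, n2` | – | rebuild/breakdown stress exponents | 3.03, 4.068 |
| `n3` | – | breakdown structure exponent | 3.03 |
| `m1` | – | viscosity–structure nonlinearity | 0.701 |

`chi0 = eta0 / G` (31.4 ms for the preset) is derived, never stored
independently. Physically meaningful fitted sets have `n1 < n2` and
`k3 >> k2` (flow must on balance destroy structure); `tevp_parameters()`
warns rather than rejects when a user-supplied set violates this. The
second preset (`armstrong2018_donor1`) shows how strongly the kinetic
constants vary between donors — `k3` differs by a factor of four, the
exponents by a factor of two — which is why the calibration tests treat the
kinetic constants as weakly identified.

A note on units: the published table prints `k2` and `k3` with rate-like
units (`s^(n1-1)`, `s^(n2-1)`), which is dimensionally consistent only with
a rate-valued `phi`, while the constitutive statement defines `phi` as a
stress. We follow the constitutive statement (Pa-valued `phi`) and treat
`k2`, `k3` as carrying the compensating `Pa^-n` dimensions.

## Protocols

Every rheometric protocol is a time-dependent velocity gradient. All shear
protocols use one fixed orientation, `u = (gamma_dot(t) y, 0, 0)`, i.e.
`L[1,2] = gamma_dot`; every published prediction the package reproduces
(positive `tau_xx`, the `tau_xx/tau_xy` crossover above 100 1/s) is
consistent with that reading, and the choice is made once rather than per
protocol. Uniaxial extension imposes
`L = diag(eps_dot, −eps_dot/2, −eps_dot/2)` (traceless, incompressible).

Discontinuous protocols (startup, cessation, intermittent steps, the ramp
apex of the triangular test) are represented as exact event times: the
integrator restarts at each breakpoint with carried-over state instead of
smoothing the step. Two readings of the published kinematics required a
decision:

* **Triangular ramp.** The printed piecewise form gives `−a t` after the
  apex, i.e. a flow reversal with growing magnitude, which contradicts both
  the folded-time visualisation `t' = t_max − t` and the reported terminal
  structure recovery. We implement the ramp-down as `a (t_max − t)` (peak
  rate `a t_max / 2`), matching the folded-time definition.
* **Exponential ramp-down.** The protocol is described both as discrete
  steps and by a continuous exponential `gamma_dot_start * exp(−t/(a Δt))`.
  The continuous form is the default; a stepped variant (log-spaced
  plateaus of equal duration) is available behind `stepped = TRUE`.

LAOS starts from zero strain with `gamma_dot(0) = gamma_0 * omega` (cosine
rate convention).

## Numerics

**Integrator.** The default scheme (`method = "pc2"`) is an A-stable
second-order trapezoidal corrector with an explicit predictor, a chord
Newton solve of the corrector (numerical Jacobian, refreshed when
convergence slows), and an adaptive step controlled by the scaled
predictor–corrector discrepancy (defaults `rtol = 1e-6`, `atol = 1e-9`).
Fixed-step mode (`dt_fixed`) exists for convergence-order verification; the
test suite checks the error drops by ~4x when the step is halved, and
cross-validates full trajectories against an independent `deSolve::lsoda`
route (`method = "lsoda"`). Steps that push `lambda` outside `[0, 1]` by
less than `1e-6` are clipped; larger excursions reject the step. Since the
kinetics keep `lambda > 0` on their own, no viscosity floor is active in
practice, but a configurable `eta_floor` (default 1e-12 Pa s) protects the
plastic multiplier against a degenerate `lambda -> 0` state.

**Steady states.** `steady_state()` time-marches until every component of
the right-hand side is below `steady_tol * (atol + |y|)` per second, then
polishes with a damped Newton iteration on the algebraic system; both routes
must agree (the gap is attached to the result, and tested below 1e-6). The
Newton step uses Levenberg-style damping because degenerate parameter sets
(frozen kinetics) make the `lambda` direction singular. Flow curves sweep
rates from high to low, reusing each state as the next Newton guess — the
stiff states sit near the yield point at low rates. The marching cap
defaults to `1e4 * max(chi0, 1/k1)`, covering the slowest (Brownian rebuild)
time scale.

**Oscillatory states.** `periodic_steady_state()` integrates cycle by cycle
until the relative L2 distance between consecutive `(tau_xy, lambda)` traces
drops below `cycle_tol`; hitting the cycle cap returns the last cycle
flagged non-periodic.

**Derived metrics.** The stationary stress of a startup trace is the mean
over the last 1% of the record (with a drift guard); the half-decay time
`theta` is located by monotone (Hyman) cubic interpolation of the post-peak
decay; the thixotropic index
`xi = (tau_max − tau_st) / (tau_st * theta * gamma_dot)` is maximised over a
log grid of startup rates (8 points/decade over 0.1–1000 1/s) followed by
golden-section refinement — the refined maximum is insensitive to the grid
density because `xi(gamma_dot)` is smooth, and the coarser grid keeps the
sweep near a hundred seconds. Degenerate cases are flagged rather than
silently patched: a monotone trace reports `theta = 0` and `xi = 0`; an
overshoot with `theta = 0` reports `xi = Inf` with a warning.

**Fits.** The structure sigmoid `A + (B − A) g^n / (k^n + g^n)` and the
rational `N1` model `(A1 + A2 e) / (1 + A3 e + A4 e^2)` are fitted by
Levenberg–Marquardt, the latter initialised by ordinary least squares on its
linearised form and rejected if the fitted denominator changes sign in the
data range. Generalized-Newtonian comparators (Casson, Cross,
Carreau–Yasuda, standard literature forms) are fitted on log-viscosity
because blood viscosities span decades.

## Calibration and the synthetic-data generator

`generate_synthetic_dataset()` emulates the data situation the presets were
fitted under: a steady flow-curve sweep (default 0.01–1000 1/s, 16
log-spaced points) plus an intermittent rectangular-step trace (7 1/s,
2.5 s pulses, 1.5 s rest), with multiplicative log-normal noise of
coefficient of variation `noise_cv` (default 0.02, a realistic rheometer
repeatability; `sdlog = sqrt(log(1 + cv^2))` with mean-one correction). What
it deliberately does **not** emulate: rheometer transients and inertia,
inhomogeneous cone-and-plate flow at high rates, sample ageing and
sedimentation, and donor-to-donor parameter variability. Passing
parameter-recovery tests on these data therefore demonstrates correctness of
the estimation machinery, not robustness to real instrument artefacts.

`fit_tevp()` minimises a concatenated residual — log-space for the steady
block (it spans decades), linear for transient blocks, each block normalised
by its own data RMS so blocks contribute comparably (the weighting is our
choice; nothing in the source material prescribes one) — with bounded
multi-start Levenberg–Marquardt in log-parameter space. Oscillatory blocks,
when present, are matched through small-amplitude oscillation simulation and
first-harmonic Fourier extraction of `G'`/`G''`. Identifiability is reported
as the condition number of the finite-difference Jacobian at the optimum
rather than a formal profile likelihood; the recovery tests accordingly free
the well-identified parameters (`G`, `eta0`, `tau_y`, `m1`, `k1`) and hold
the weakly identified kinetic exponents fixed.

## Reproducibility of published characteristic values

The test suite pins the model's outputs to the characteristic values
published for the bundled parameter sets. A subset of those values could
not be reproduced from the published equations with the published
constants, and the discrepancies are internally inconsistent rather than a
matter of numerical tolerance. The clearest cases, all with the
`mcmillan1987_subject` preset from the rest state:

* The triangular-ramp peak quoted as 788 mPa (ramp rate 20 1/s², peak rate
  60 1/s) would require a plastic viscosity of at least 13.1 mPa s, i.e.
  `lambda > 1`, while the same experiment is reported to end near
  `lambda = 0.32` — our simulation gives a 228 mPa peak and a final
  `lambda = 0.329`, matching the reported *structure* value to 3% but not
  the stress peak.
* The startup overshoot near 7 1/s is quoted both as 88 mPa and as 70 mPa
  in different experiments with the same kinematics; the simulation gives
  85.7–86.8 mPa, consistent with the first.
* The reported transient structure decays (e.g. `lambda = 0.49` after a
  2.5 s pulse at 7 1/s, `lambda = 0.36` after 3 s at 14.1 1/s, minimum
  0.18 in the 20 1/s² ramp) collapse onto a single breakdown law
  proportional to shear *rate*, which no stress-controlled `phi` can
  reproduce simultaneously with the reported stress peaks — the ramp
  reaches several times the stress of the cessation test yet shows slower
  structure decay.
* The steady low-rate plateau of `N1` in uniaxial extension is quoted as
  3.8 mPa; under the stated effective-stress definition the plateau is
  necessarily `sqrt(3) * tau_y = 6.1 mPa` (we compute 6.4 mPa at
  0.01 1/s).

We implement the published equations exactly as stated and report the
computed values; the affected acceptance expectations are left failing
rather than absorbed by parameter or tolerance adjustments. Quantities that
do reproduce include the intermittent-step stress peaks (85.7/38.0 mPa vs
88/38), the residual stress after cessation (3.35–3.42 mPa vs 3.5, the
yield stress), the post-cessation rebuild rates and their ratio between
rates, the structure/viscosity/relaxation-time state near 100 1/s
(`chi -> 9.1 ms` requires `lambda = 0.171`; we obtain `lambda(100) = 0.141`
and `chi = 8.0 ms`), the `tau_xx/tau_xy > 1` crossover above 100 1/s, and
the uniaxial structure-breakdown onset times at 5 and 50 1/s.

## Problem sizes used by the tests and the acceptance script

Transient runs integrate 2–40 s of protocol time at adaptive steps
(typically 5,000–20,000 accepted steps); the thixotropic-index sweep uses 33
grid rates plus ~26 refinement runs; flow curves use 5–31 rates; recovery
tests use 8 steady points and one 2.5 s transient. These sizes were chosen
so the full suite and the acceptance script each complete in minutes on one
CPU while every quantitative check is tolerance-converged (halving `rtol`
moves no asserted quantity by more than its assertion tolerance).

## Known limitations

* Homogeneous kinematics only; no momentum balance, no wall slip, no
  inertia. Coupling to a flow solver is out of scope here.
* Single-mode thixotropy: one structure variable, one relaxation-time
  scale. Frequency sweeps spanning several decades will not be captured
  with a single mode.
* The stress-controlled kinetics give no true high-shear plateau of
  `lambda`: the steady structure level keeps decreasing slowly
  (`~ phi^((n1−n2)/n3)`), so "plateau" values quoted for this model are
  state values near 100 1/s, not asymptotes.
* Below yield the stress is frozen exactly (no sub-yield creep or stress
  relaxation beyond the elastic response).
* `fit_tevp()` reports identifiability only through a Jacobian condition
  number; the kinetic exponents are effectively non-identifiable from the
  default synthetic design, mirroring the donor-to-donor spread of the two
  presets.
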