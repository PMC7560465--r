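# tevpblood

Whole blood is a thixotropic elasto-visco-plastic (TEVP) fluid: red blood
cells aggregate into rouleaux that give blood a small yield stress and an
elastic response at low stress, while flow progressively breaks the
aggregates down, so the apparent viscosity depends on the entire deformation
history. `tevpblood` implements a tensorial single-mode TEVP constitutive
model of blood as a tested simulator of homogeneous rheometric flows,
together with the derived rheometric metrics used in hemorheology and a
calibration engine that fits the model's eleven parameters to steady plus
transient rheograms simultaneously. It is aimed at rheologists and
computational biomechanics researchers who need a transparent, reproducible
reference implementation of this model class.

## The model

The extra stress is purely viscoelastic, `tau = tau_ve` (plasma is included
in the viscoelastic term). The total deformation rate splits additively into
elastic and viscoplastic parts, `D = De + Dvp`, with

- elastic part through the upper-convected derivative:
  `De = (1 / 2G) * UC(tau)`, so for homogeneous flow
  `dtau/dt = L tau + tau L' + 2G (D − Dvp)`;
- viscoplastic part gated by the von Mises criterion:
  `Dvp = f[tr(tau)] * max(0, (sigma_eff − tau_y) / (2 eta_t sigma_eff)) * tau`,
  with effective stress `sigma_eff = sqrt((tauD : tauD) / 2)` and linear
  Phan-Thien–Tanner factor `f = 1 + eps_PTT * tr(tau) / G`;
- structure kinetics for the rouleaux level `lambda ∈ [0, 1]`
  (1 = fully structured):
  `dlambda/dt = (k1 + k2 phi^n1)(1 − lambda) − k3 phi^n2 lambda^n3`,
  with the stress-controlled flow parameter
  `phi = max(0, sigma_eff − tau_y)`;
- thixotropic plastic viscosity and relaxation time:
  `eta_t = eta0 * lambda^m1`, `chi = (eta0 / G) * lambda^m1`.

The state is the full 3-D symmetric stress tensor plus `lambda` (seven ODEs),
so predictions such as `tau_yy = 0` in simple shear are tests, not
assumptions. Two fitted parameter sets for healthy blood at 45% hematocrit
are bundled as presets (`mcmillan1987_subject`, `armstrong2018_donor1`).

## Worked example

```r
library(tevpblood)
p <- tevp_preset("mcmillan1987_subject")

# intermittent rectangular shear steps: 7 1/s, 2.5 s pulses, 1.5 s rest
r <- integrate_protocol(protocol_intermittent(7, 2.5, 1.5, 2), p)
print(r)
#> rheogram: 7752 samples over 8 s (intermittent protocol, method pc2)
#>   final: tau_xy = 0.003425 Pa, tau_xx = 0.001245 Pa, lambda = 0.7458
```

The sample ends near its yield stress (3.4 mPa residual shear stress —
the stress frozen in when the effective stress falls to `tau_y`) and the
rouleaux structure has rebuilt to `lambda = 0.75` during the rests.

```r
# startup at 12 1/s: elastic overshoot, thixotropic relaxation
m <- overshoot_metrics(integrate_protocol(protocol_startup(12, 30), p))
#> tau_max = 136.1 mPa at t = 0.11 s, steady = 91.4 mPa, theta = 0.290 s
thixotropic_index(m, 12)
#> [1] 0.141

# steady flow curve with shear thinning of viscosity and relaxation time
flow_curve(p, c(0.1, 1, 10, 100, 1000))[, c("rate", "txy", "lam", "eta_app", "chi")]
#>    rate     txy     lam eta_app     chi
#> 1 1e-01 0.00470 1.00000 0.04700 0.03141
#> 2 1e+00 0.01549 0.99884 0.01549 0.03139
#> 3 1e+01 0.08247 0.55166 0.00825 0.02070
#> 4 1e+02 0.30611 0.14099 0.00306 0.00796
#> 5 1e+03 1.48231 0.05277 0.00148 0.00400

# fibrinogen concentration consistent with the fitted yield stress
fibrinogen_from_yield(0.00351, Hc = 0.45)
#> [1] 0.1617
```

At 0.1 1/s the sample is fully structured and the apparent viscosity is
dominated by the yield stress (`tau_y / rate`); by 100 1/s the structure has
collapsed to `lambda = 0.14` and the relaxation time has thinned from 31 ms
to 8 ms.

Other entry points: `protocol_cessation()`, `protocol_triangular()`,
`protocol_exp_rampdown()`, `protocol_laos()` + `periodic_steady_state()` +
`pipkin_grid()` for oscillatory work, `protocol_uniaxial()` for extension,
`steady_state()` for algebraic steady states, `gn_fit()` for
Casson/Cross/Carreau–Yasuda comparator fits, and
`generate_synthetic_dataset()` + `fit_tevp()` for calibration and
parameter-recovery studies. A thin command-line tool is installed as
`exec/tevpblood` (subcommands `simulate`, `flowcurve`, `laos`, `synth`,
`fit`, `report`).

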