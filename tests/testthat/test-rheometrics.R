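test_that("overshoot metrics: monotone and synthetic-decay traces", {
  t <- seq(0, 30, by = 0.01)
  mono <- data.frame(time = t, txy = 1 - exp(-t))
  m <- overshoot_metrics(mono)
  expect_false(m$overshoot)
  expect_identical(m$theta, 0)
  expect_equal(m$tau_max, m$tau_st, tolerance = 1e-6)
  expect_identical(thixotropic_index(m, 5), 0)
  # synthetic overshoot with analytic half-decay theta = tau_d * log(2)
  tp <- 1; st <- 0.05; pk <- 0.12; tau_d <- 0.8
  y <- ifelse(t <= tp, pk * t / tp, st + (pk - st) * exp(-(t - tp) / tau_d))
  m2 <- overshoot_metrics(data.frame(time = t, txy = y))
  expect_true(m2$overshoot)
  expect_equal(m2$tau_max, pk, tolerance = 1e-6)
  expect_equal(m2$tau_st, st, tolerance = 1e-3)
  expect_equal(m2$theta, tau_d * log(2), tolerance = 1e-3)
  # xi is invariant under stress-unit rescaling
  m3 <- overshoot_metrics(data.frame(time = t, txy = 1000 * y))
  expect_equal(thixotropic_index(m2, 5), thixotropic_index(m3, 5),
               tolerance = 1e-9)
  # an unconverged trace is refused
  expect_error(overshoot_metrics(data.frame(time = t, txy = t)),
               "not converged")
})

test_that("Morris correlation: printed value, zero root, monotonicity", {
  # hand-algebra root of the inner polynomial: cf = 0, Hc = 0.091/0.47
  expect_equal(suppressWarnings(morris_yield_stress(0.091 / 0.47, 0)), 0)
  # published pairing: Hc = 0.45, cf = 0.1617 g/dL -> about 0.00351 Pa
  expect_equal(morris_yield_stress(0.45, 0.1617), 0.00351,
               tolerance = 0.01)
  cf <- seq(0.1, 0.9, by = 0.05)
  expect_true(all(diff(morris_yield_stress(0.45, cf)) > 0))
  expect_warning(morris_yield_stress(0.30, 0.2), "validity")
})

test_that("Morris inversion round-trips and matches polyroot oracle", {
  expect_equal(fibrinogen_from_yield(0.00351, 0.45), 0.1617,
               tolerance = 0.01)
  # round trip over the validity rectangle
  for (Hc in c(0.42, 0.55, 0.7)) for (cf in c(0.12, 0.4, 0.85)) {
    ty <- morris_yield_stress(Hc, cf)
    expect_equal(fibrinogen_from_yield(ty, Hc), cf, tolerance = 1e-10)
  }
  # independent oracle: smallest positive root via polyroot
  Hc <- 0.45; ty <- 0.002
  rts <- Re(polyroot(c(-0.091 + 0.47 * Hc - sqrt(10 * ty),
                       0.22 + 0.48 * Hc, -0.14)))
  expect_equal(fibrinogen_from_yield(ty, Hc), min(rts[rts > 0]),
               tolerance = 1e-9)
  # tau_y = 0: root of the inner polynomial itself
  rts0 <- Re(polyroot(c(-0.091 + 0.47 * Hc, 0.22 + 0.48 * Hc, -0.14)))
  expect_equal(fibrinogen_from_yield(0, Hc), min(rts0[rts0 > 0]),
               tolerance = 1e-9)
})

test_that("sigmoid structure fit recovers its own generating values", {
  g <- 10^seq(-2, 3, length.out = 30)
  truth <- list(A = 1.0, B = 0.1763, k = 4.795, n = 1.262)
  lam <- truth$A + (truth$B - truth$A) * g^truth$n / (truth$k^truth$n +
                                                        g^truth$n)
  fit <- fit_sigmoid_structure(g, lam)
  expect_equal(fit$A, truth$A, tolerance = 1e-5)
  expect_equal(fit$B, truth$B, tolerance = 1e-5)
  expect_equal(fit$k, truth$k, tolerance = 1e-4)
  expect_equal(fit$n, truth$n, tolerance = 1e-4)
  expect_lt(fit$rms, 1e-8)
  # low-rate limit of the fitted curve is A
  expect_equal(predict(fit, 1e-9), fit$A, tolerance = 1e-6)
})

test_that("rational N1 fit: self-recovery and eta_e identity", {
  e <- 10^seq(-2, 2.5, length.out = 25)
  truth <- list(A1 = -1.69, A2 = 1.30, A3 = -0.427, A4 = 0.0931)
  N1 <- (truth$A1 + truth$A2 * e) / (1 + truth$A3 * e + truth$A4 * e^2)
  fit <- fit_n1_rational(e, N1)
  for (nm in names(truth))
    expect_equal(fit[[nm]], truth[[nm]], tolerance = 1e-4)
  expect_lt(fit$rms, 1e-7)
  expect_equal(extensional_viscosity(fit, e) * e, predict(fit, e),
               tolerance = 1e-12)
})

test_that("generalized-Newtonian comparators: limits and log-space fit", {
  g <- 10^seq(-2, 3, length.out = 40)
  # Casson with zero yield stress is Newtonian
  expect_equal(gn_viscosity("casson", list(tau_y = 0, eta_c = 4e-3), g),
               rep(4e-3, length(g)))
  cr <- list(eta_0 = 0.05, eta_inf = 3.5e-3, K = 2, m = 1.2)
  expect_equal(gn_viscosity("cross", cr, 1e-9), cr$eta_0, tolerance = 1e-6)
  expect_equal(gn_viscosity("cross", cr, 1e9), cr$eta_inf, tolerance = 1e-5)
  cy <- list(eta_0 = 0.05, eta_inf = 3.5e-3, lam_c = 1.5, a = 2, n = 0.4)
  expect_equal(gn_viscosity("carreau_yasuda", cy, 1e-12), cy$eta_0,
               tolerance = 1e-6)
  expect_equal(gn_viscosity("carreau_yasuda", cy, 1e9) / cy$eta_inf, 1,
               tolerance = 1e-2)
  expect_error(gn_viscosity("casson", list(tau_y = -1, eta_c = 1), g),
               "negative")
  # fit recovers a Casson curve from its own samples
  eta <- gn_viscosity("casson", list(tau_y = 0.0035, eta_c = 3.5e-3), g)
  fit <- gn_fit("casson", g, eta)
  expect_equal(fit$tau_y, 0.0035, tolerance = 1e-4)
  expect_equal(fit$eta_c, 3.5e-3, tolerance = 1e-4)
})

test_that("steady flow curve: monotone stress, normal-stress crossover", {
  rates <- 10^seq(-1, 3, length.out = 17)
  fc <- flow_curve(p47, rates)
  expect_true(all(diff(fc$txy) > 0))         # no constitutive non-monotonicity
  expect_true(all(diff(fc$lam) < 0))
  # apparent viscosity diverges as tau_y / rate at low rates
  expect_equal(fc$eta_app[1], p47$tau_y / fc$rate[1], tolerance = 0.3)
  # normal stress overtakes shear stress between 50 and 500 1/s
  ratio <- fc$txx / fc$txy
  expect_lt(max(ratio[fc$rate <= 50]), 1)
  expect_gt(max(ratio[fc$rate >= 500]), 1)
  cross <- fc$rate[which(ratio > 1)[1]]
  expect_gt(cross, 50); expect_lt(cross, 500)
})

test_that("Newtonian limit of the flow curve for degenerate parameters", {
  # with frozen kinetics the steady manifold is degenerate in lambda, so the
  # solver may settle at lambda marginally below 1; viscosity is recovered to
  # the corresponding accuracy
  pu <- ucm_params()
  fc <- suppressWarnings(flow_curve(pu, c(0.5, 5, 50)))
  expect_equal(fc$eta_app, rep(pu$eta0, 3), tolerance = 1e-3)
})

test_that("Lissajous-Bowditch and Pipkin grids carry closed projections", {
  pg <- pipkin_grid(p47, gamma_0 = c(0.001, 2), omega = c(1),
                    ctrl = ctrl_fast, n_cycles = 12)
  expect_setequal(unique(pg$gamma_0), c(0.001, 2))
  expect_true(all(pg$periodic))
  cell <- pg[pg$gamma_0 == 2, ]
  expect_equal(cell$txy[1], cell$txy[nrow(cell)], tolerance = 1e-2)
  expect_true(all(cell$lam >= 0 & cell$lam <= 1))
})
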