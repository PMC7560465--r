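test_that("a rest protocol from the rest state stays exactly at rest", {
  r <- integrate_protocol(protocol_rest(5), p47, ctrl = ctrl_fast)
  expect_true(all(abs(r$txy) < 1e-14))
  expect_true(all(abs(r$txx) < 1e-14))
  expect_true(all(r$lam == 1))
})

test_that("degenerate parameters reproduce the analytic UCM startup", {
  pu <- ucm_params()
  gd <- 5
  ctrl <- integrator_controls(rtol = 1e-10, atol = 1e-14, dt_max = 5e-3)
  r <- integrate_protocol(protocol_startup(gd, 0.3), pu, ctrl = ctrl)
  tt <- r$time[r$time > 0]
  ana_xy <- pu$eta0 * gd * (1 - exp(-tt / pu$chi0))
  expect_equal(r$txy[r$time > 0], ana_xy, tolerance = 1e-6)
  # UCM first normal stress: 2 eta chi gdot^2 (1 - e^-s (1 + s)), s = t/chi
  s <- tt / pu$chi0
  ana_xx <- 2 * pu$eta0 * pu$chi0 * gd^2 * (1 - exp(-s) * (1 + s))
  expect_equal(r$txx[r$time > 0], ana_xx, tolerance = 1e-5)
  expect_true(all(abs(r$tyy) < 1e-12))
})

test_that("fixed-step integration converges at second order", {
  # start from a yielded mid-startup state so the trajectory is smooth
  pre <- integrate_protocol(protocol_startup(5, 0.5), p47, ctrl = ctrl_fast)
  init <- final_state(pre)
  run <- function(dt) {
    # very tight corrector tolerance so iteration error does not mask the
    # O(dt^2) discretisation error
    ctrl <- integrator_controls(dt_fixed = dt, dt_init = dt,
                                rtol = 1e-12, atol = 1e-15)
    r <- integrate_protocol(protocol_startup(5, 0.2), p47, init = init,
                            ctrl = ctrl)
    unlist(r[nrow(r), c("txx", "txy", "lam")])
  }
  ref <- run(1e-4)
  e1 <- max(abs(run(8e-3) - ref) / (1e-12 + abs(ref)))
  e2 <- max(abs(run(4e-3) - ref) / (1e-12 + abs(ref)))
  expect_gt(e1 / e2, 3)
  expect_lt(e1 / e2, 5.5)
})

test_that("pc2 agrees with the independent lsoda route", {
  r1 <- integrate_protocol(protocol_startup(7, 2.5), p47,
                           ctrl = integrator_controls(rtol = 1e-8,
                                                      atol = 1e-12))
  r2 <- integrate_protocol(protocol_startup(7, 2.5), p47,
                           ctrl = integrator_controls(rtol = 1e-10,
                                                      atol = 1e-13),
                           method = "lsoda")
  a <- rheogram_at(r1, c(0.5, 1.5, 2.5), c("txy", "txx", "lam"))
  b <- rheogram_at(r2, c(0.5, 1.5, 2.5), c("txy", "txx", "lam"))
  expect_equal(a$txy, b$txy, tolerance = 2e-5)
  expect_equal(a$txx, b$txx, tolerance = 2e-5)
  expect_equal(a$lam, b$lam, tolerance = 2e-5)
})

test_that("event handling equals concatenated segment integrations", {
  ctrl <- integrator_controls(rtol = 1e-8, atol = 1e-12)
  spec <- protocol_intermittent(14.1, 1.0, 0.8, 2, t_tail = 0.5)
  whole <- integrate_protocol(spec, p47, ctrl = ctrl)
  # piecewise: startup, rest, startup, rest with carried-over state
  st <- material_state()
  segs <- list(protocol_startup(14.1, 1.0), protocol_rest(0.8),
               protocol_startup(14.1, 1.0), protocol_rest(0.5))
  for (sg in segs) {
    r <- integrate_protocol(sg, p47, init = st, ctrl = ctrl)
    st <- final_state(r)
  }
  end <- final_state(whole)
  expect_equal(unclass(st$tau), unclass(end$tau), tolerance = 1e-7)
  expect_equal(st$lam, end$lam, tolerance = 1e-9)
})

test_that("lambda stays inside [0, 1] and tau_yy stays zero in simple shear", {
  for (spec in list(protocol_startup(50, 3),
                    protocol_triangular(20, 6),
                    protocol_intermittent(7, 2.5, 1.5, 2))) {
    r <- integrate_protocol(spec, p47, ctrl = ctrl_fast)
    expect_true(all(r$lam >= 0 & r$lam <= 1))
    expect_gt(min(r$lam), 0)              # never fully unstructured
    expect_true(all(abs(r$tyy) < 1e-10))
    expect_true(all(abs(r$tzz) < 1e-10))
    # below yield the viscoplastic deformation vanishes identically
    below <- r$sigma_eff <= p47$tau_y
    expect_true(all(r$dvp_xy[below] == 0))
  }
})

test_that("steady_state: two routes agree and match long-time integration", {
  for (g in c(5, 50)) {
    st <- steady_state(g, "shear", p47)
    expect_lt(attr(st, "route_gap"), 1e-6)
    expect_lt(attr(st, "residual"), 1e-9)
    r <- integrate_protocol(protocol_startup(g, 80 / g + 30), p47,
                            ctrl = integrator_controls(rtol = 1e-8,
                                                       atol = 1e-12))
    expect_equal(r$txy[nrow(r)], st$tau[["xy"]], tolerance = 1e-5)
    expect_equal(r$lam[nrow(r)], st$lam, tolerance = 1e-5)
  }
  # low-rate limit: shear stress approaches the yield stress from above
  st0 <- steady_state(1e-3, "shear", p47)
  expect_equal(st0$tau[["xy"]], p47$tau_y, tolerance = 5e-3)
  expect_gt(st0$tau[["xy"]], p47$tau_y)
})

test_that("steady state lambda equals the structure fixed point at its own stress", {
  st <- steady_state(20, "shear", p47)
  phi <- flow_parameter(effective_stress(st$tau), p47)
  expect_equal(st$lam, structure_fixed_point(phi, p47), tolerance = 1e-7)
})

test_that("periodic LAOS state: fixed point returns early, small strain is elliptic", {
  # small amplitude, below yield: purely elastic, periodic from cycle 2
  cyc <- periodic_steady_state(protocol_laos(1e-3, 1, 10), p47,
                               ctrl = ctrl_fast)
  expect_true(attr(cyc, "periodic"))
  expect_lte(attr(cyc, "cycles_run"), 4)
  # elastic projection closes: stress at matching phase endpoints agrees
  expect_equal(cyc$txy[1], cyc$txy[nrow(cyc)], tolerance = 1e-6)
  # linear ellipse: stress ~ G * strain below yield
  expect_equal(cyc$txy, p47$G * cyc$strain, tolerance = 1e-2)
})
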