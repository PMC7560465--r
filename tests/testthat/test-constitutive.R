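test_that("PTT factor: identity cases and direct arithmetic", {
  expect_identical(ptt_factor(sym_tensor(), p47), 1)
  p0 <- ucm_params()                       # eps_ptt = 0
  expect_identical(ptt_factor(sym_tensor(xx = 5, yy = -1), p0), 1)
  # eps_ptt = 0.001, G = 0.382, tr(tau) = 0.382 -> 1.001
  expect_equal(ptt_factor(sym_tensor(xx = 0.382), p47), 1.001)
})

test_that("thixotropic viscosity and relaxation time", {
  expect_equal(thixotropic_viscosity(1, p47), 0.012)
  expect_identical(thixotropic_viscosity(0, p47), 0)
  # high-shear structure level gives a plastic viscosity 3.5-4x plasma
  expect_equal(thixotropic_viscosity(0.1763, p47), 3.5e-3, tolerance = 0.03)
  expect_equal(relaxation_time(1, p47), 0.012 / 0.382)
  expect_identical(relaxation_time(0, p47), 0)
  # monotone increasing in lambda
  lam <- seq(0, 1, by = 0.05)
  expect_true(all(diff(thixotropic_viscosity(lam, p47)) > 0))
  expect_error(thixotropic_viscosity(1.2, p47), "\\[0, 1\\]")
  expect_error(relaxation_time(-0.1, p47), "\\[0, 1\\]")
})

test_that("flow parameter clamps at the yield surface", {
  expect_identical(flow_parameter(0, p47), 0)
  expect_identical(flow_parameter(p47$tau_y, p47), 0)
  expect_equal(flow_parameter(p47$tau_y + 0.01, p47), 0.01)
  expect_error(flow_parameter(-1, p47))
})

test_that("structure kinetics match an independent hand evaluation", {
  # fully structured below yield: both terms vanish
  expect_identical(structure_rate(1, p47$tau_y / 2, p47), 0)
  # fully destructured below yield: pure Brownian rebuild at k1
  expect_equal(structure_rate(0, p47$tau_y / 2, p47), 0.0918)
  # brute-force arithmetic oracle at lam = 0.5, phi = 0.01 Pa
  phi <- 0.01
  expected <- (0.0918 + 7.249 * phi^3.03) * 0.5 -
    6974.9 * phi^4.068 * 0.5^3.03
  expect_equal(structure_rate(0.5, p47$tau_y + phi, p47), expected)
})

test_that("structure fixed point is the unique balance and attracts", {
  expect_identical(structure_fixed_point(0, p47), 1)
  for (phi in c(0.02, 0.1, 0.5)) {
    ls <- structure_fixed_point(phi, p47)
    expect_gt(ls, 0); expect_lte(ls, 1)
    expect_lt(abs(structure_rate(ls, p47$tau_y + phi, p47)), 1e-8)
    # stability: rate positive below, negative above
    expect_gt(structure_rate(ls * 0.9, p47$tau_y + phi, p47), 0)
    expect_lt(structure_rate(min(1, ls * 1.1), p47$tau_y + phi, p47), 0)
  }
  # monotone decreasing with stress excess
  ph <- c(0.01, 0.05, 0.2, 1)
  ls <- vapply(ph, structure_fixed_point, numeric(1), p = p47)
  expect_true(all(diff(ls) < 0))
})

test_that("viscoplastic deformation obeys the von Mises criterion", {
  # below yield: exactly zero
  tau <- sym_tensor(xy = p47$tau_y * 0.99)
  expect_true(all(unclass(viscoplastic_deformation(tau, 1, p47)) == 0))
  # above yield: proportional to the stress tensor
  tau <- sym_tensor(xx = 0.05, xy = 0.08)
  dvp <- viscoplastic_deformation(tau, 0.7, p47)
  expect_equal(dvp[["xy"]] / dvp[["xx"]], tau[["xy"]] / tau[["xx"]])
  # continuity across the yield surface: multiplier -> 0 from above
  eps <- 1e-10
  tau_just <- sym_tensor(xy = p47$tau_y + eps)
  dvp_just <- viscoplastic_deformation(tau_just, 1, p47)
  expect_lt(abs(dvp_just[["xy"]]), 1e-7)
})

test_that("stress rate: neo-Hookean startup limit and tensor/scalar paths agree", {
  st0 <- material_state()
  expect_true(all(unclass(stress_rate(st0, matrix(0, 3, 3), p47)) == 0))
  gd <- 3.2
  L <- matrix(c(0, 0, 0, gd, 0, 0, 0, 0, 0), 3, 3)
  r0 <- stress_rate(st0, L, p47)
  expect_equal(r0[["xy"]], p47$G * gd)
  expect_equal(unname(r0[c("xx", "yy", "zz", "xz", "yz")]), rep(0, 5))
  # the packed fast RHS must agree with the tensor-algebra path
  set.seed(3)
  for (i in 1:10) {
    tau <- random_sym_tensor() * 0.05
    lam <- stats::runif(1, 0.05, 1)
    st <- material_state(0, sym_tensor(tau[1], tau[2], tau[3],
                                       tau[4], tau[5], tau[6]), lam)
    Lr <- matrix(stats::rnorm(9), 3, 3)
    slow <- stress_rate(st, Lr, p47)
    fast <- tevpblood:::tevp_rhs(c(unclass(st$tau), lam), Lr, p47)
    expect_equal(unname(unclass(slow)), fast[1:6], tolerance = 1e-12)
    expect_equal(fast[7],
                 structure_rate(lam, effective_stress(st$tau), p47),
                 tolerance = 1e-12)
  }
})
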