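#' Overshoot metrics of a startup trace
#'
#' From a constant-rate startup rheogram that has reached steady state,
#' extracts the stress maximum `tau_max`, its time `t_peak`, the stationary
#' value `tau_st` (mean over the last 1% of the record) and the half-decay
#' time `theta`: the time for the trace to fall from the peak to
#' `tau_st + (tau_max - tau_st)/2`, located by monotone (Hyman) cubic
#' interpolation of the post-peak decay. A monotone (no-overshoot) trace
#' returns `theta = 0` with `overshoot = FALSE`.
#'
#' @param r a [rheogram] from a constant-rate startup segment.
#' @param channel stress channel name (default `"txy"`).
#' @param steady_frac fraction of the record over which the terminal value is
#'   averaged.
#' @param steady_rtol convergence check: the terminal-window drift must be
#'   below this fraction of the window mean.
#' @return list of class `overshoot_metrics`: `tau_max`, `t_peak`, `tau_st`,
#'   `theta`, `overshoot`.
#' @export
overshoot_metrics <- function(r, channel = "txy", steady_frac = 0.01,
                              steady_rtol = 1e-3) {
  y <- r[[channel]]
  t <- r$time
  n <- length(y)
  iw <- which(t >= (1 - steady_frac) * t[n])
  tau_st <- mean(y[iw])
  drift <- abs(y[n] - y[iw[1]])
  if (drift > steady_rtol * max(abs(tau_st), 1e-12))
    stop("overshoot_metrics: trace has not converged to steady state ",
         "(terminal drift ", signif(drift, 3), ")")
  ip <- which.max(y)
  tau_max <- y[ip]
  overshoot <- tau_max > tau_st * (1 + 1e-6) + 1e-15
  theta <- 0
  if (overshoot) {
    target <- tau_st + (tau_max - tau_st) / 2
    post <- ip:n
    j <- post[which(y[post] <= target)[1]]
    if (!is.na(j) && j > ip) {
      seg <- ip:j
      # strictly decreasing sub-sequence for the monotone interpolant
      keep <- seg[c(TRUE, diff(cummin(y[seg])) < 0)]
      if (length(keep) >= 3) {
        sf <- stats::splinefun(t[keep], y[keep], method = "hyman")
        theta <- stats::uniroot(function(tt) sf(tt) - target,
                                c(t[ip], t[j]))$root - t[ip]
      } else {
        theta <- stats::approx(y[c(j - 1, j)], t[c(j - 1, j)],
                               xout = target)$y - t[ip]
      }
    }
  }
  structure(list(tau_max = tau_max, t_peak = t[ip], tau_st = tau_st,
                 theta = theta, overshoot = overshoot),
            class = "overshoot_metrics")
}

#' Thixotropic index
#'
#' `xi = (tau_max - tau_st) / (tau_st * theta * gamma_dot)`: the overshoot
#' size relative to the stationary stress, the half-decay time and the
#' imposed rate. Zero when there is no overshoot; an overshoot with
#' `theta = 0` is flagged as undefined (`Inf`).
#'
#' @param m an [overshoot_metrics()] result.
#' @param gamma_dot imposed shear rate (1/s), positive.
#' @return dimensionless scalar.
#' @export
thixotropic_index <- function(m, gamma_dot) {
  stopifnot(gamma_dot > 0)
  if (!m$overshoot) return(0)
  if (m$theta <= 0) {
    warning("overshoot present but theta = 0; xi undefined")
    return(Inf)
  }
  (m$tau_max - m$tau_st) / (m$tau_st * m$theta * gamma_dot)
}

#' Thixotropic index over a sweep of startup rates
#'
#' Runs startup simulations over a logarithmic grid of shear rates, computes
#' `xi` at each, then refines the location of the maximum by golden-section
#' search.
#'
#' @param p [tevp_parameters()].
#' @param rates shear-rate grid (1/s); default log grid over
#'   `range` with `per_decade` points per decade.
#' @param range rate range (1/s).
#' @param per_decade grid density.
#' @param ctrl [integrator_controls()].
#' @param refine logical: golden-section refinement around the grid maximum.
#' @return list with the sweep `table` (rate, xi, theta, tau_max, tau_st),
#'   and the refined `xi_max`, `rate_max`.
#' @export
thixotropic_index_sweep <- function(p, rates = NULL, range = c(0.1, 1000),
                                    per_decade = 8,
                                    ctrl = integrator_controls(rtol = 1e-7),
                                    refine = TRUE) {
  if (is.null(rates))
    rates <- 10^seq(log10(range[1]), log10(range[2]),
                    by = 1 / per_decade)
  xi_at <- function(g) {
    r <- startup_to_steady(g, p, ctrl)
    m <- overshoot_metrics(r)
    c(xi = thixotropic_index(m, g), theta = m$theta,
      tau_max = m$tau_max, tau_st = m$tau_st)
  }
  tab <- t(vapply(rates, xi_at, numeric(4)))
  tab <- data.frame(rate = rates, tab)
  i <- which.max(tab$xi)
  xi_max <- tab$xi[i]; rate_max <- tab$rate[i]
  if (refine && i > 1 && i < nrow(tab)) {
    gr <- (sqrt(5) - 1) / 2
    a <- log(tab$rate[i - 1]); b <- log(tab$rate[i + 1])
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- xi_at(exp(x1))[1]; f2 <- xi_at(exp(x2))[1]
    for (it in 1:12) {
      if (f1 < f2) {
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + gr * (b - a); f2 <- xi_at(exp(x2))[1]
      } else {
        b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - gr * (b - a); f1 <- xi_at(exp(x1))[1]
      }
    }
    k <- which.max(c(f1, f2, xi_max))
    xi_max <- max(f1, f2, xi_max)
    rate_max <- c(exp(x1), exp(x2), rate_max)[k]
  }
  list(table = tab, xi_max = xi_max, rate_max = rate_max)
}

# startup at rate g integrated long enough to satisfy overshoot_metrics
startup_to_steady <- function(g, p, ctrl = integrator_controls()) {
  t_end <- max(30, 60 / g, 60 * p$chi0)
  for (try in 1:4) {
    r <- integrate_protocol(protocol_startup(g, t_end), p, ctrl = ctrl)
    ok <- tryCatch({overshoot_metrics(r); TRUE},
                   error = function(e) FALSE)
    if (ok) return(r)
    t_end <- t_end * 4
  }
  r
}

#' Apparent steady-shear viscosity
#'
#' `eta_app = tau_xy / gamma_dot` at steady state.
#'
#' @param tau_xy steady shear stress (Pa).
#' @param gamma_dot imposed rate (1/s), nonzero.
#' @return Pa s.
#' @export
apparent_viscosity <- function(tau_xy, gamma_dot) {
  stopifnot(all(gamma_dot != 0))
  tau_xy / gamma_dot
}

#' Steady flow curve
#'
#' Sweeps [steady_state()] over a grid of rates from high to low, reusing
#' each converged state as the Newton guess for the next (continuation; the
#' low-rate states near the yield point are the stiff ones).
#'
#' @param p [tevp_parameters()].
#' @param rates rates (1/s); any order, internally swept descending.
#' @param mode `"shear"` or `"uniaxial"`.
#' @param ctrl [integrator_controls()].
#' @return data.frame with rate, stress components, `lam`, `sigma_eff`,
#'   `eta_app` (shear) or `N1` and `eta_e` (uniaxial), `eta_t`, `chi`,
#'   `dvp_xx`, `dvp_xy`.
#' @export
flow_curve <- function(p, rates, mode = c("shear", "uniaxial"),
                       ctrl = integrator_controls()) {
  mode <- match.arg(mode)
  ord <- order(rates, decreasing = TRUE)
  res <- vector("list", length(rates))
  guess <- NULL
  for (k in seq_along(ord)) {
    g <- rates[ord[k]]
    st <- steady_state(g, mode, p, ctrl, guess = guess)
    guess <- st
    tau <- st$tau
    se <- effective_stress(tau)
    m <- vp_multiplier(tau, st$lam, p, ctrl$eta_floor)
    row <- data.frame(rate = g, txx = tau[1], tyy = tau[2], tzz = tau[3],
                      txy = tau[4], lam = st$lam, sigma_eff = se,
                      eta_t = thixotropic_viscosity(st$lam, p),
                      chi = relaxation_time(st$lam, p),
                      dvp_xx = m * tau[1], dvp_xy = m * tau[4])
    res[[ord[k]]] <- row
  }
  out <- do.call(rbind, res)
  if (mode == "shear") {
    out$eta_app <- apparent_viscosity(out$txy, out$rate)
  } else {
    out$N1 <- out$txx - out$tyy
    out$eta_e <- out$N1 / out$rate
  }
  rownames(out) <- NULL
  out
}

#' Morris yield-stress correlation
#'
#' Empirical correlation between blood yield stress, hematocrit `Hc` (volume
#' fraction) and fibrinogen concentration `cf` (g/dL):
#' `tau_yc = (-0.091 + 0.47 Hc + 0.22 cf - 0.14 cf^2 + 0.48 Hc cf)^2`
#' with `tau_yc` in dyn/cm2, converted here to Pa (1 dyn/cm2 = 0.1 Pa).
#' Stated validity: `Hc` in 0.40--0.80 and `cf` in 0.1--0.9 g/dL (outside,
#' a warning is raised). A negative inner expression is reported as zero
#' yield stress with attribute `flag = "inner_negative"`.
#'
#' @param Hc hematocrit (volume fraction).
#' @param cf fibrinogen concentration (g/dL).
#' @return yield stress (Pa).
#' @export
morris_yield_stress <- function(Hc, cf) {
  if (any(Hc < 0.40 | Hc > 0.80))
    warning("Hc outside the correlation's validity range [0.40, 0.80]")
  if (any(cf < 0.1 | cf > 0.9))
    warning("cf outside the correlation's validity range [0.1, 0.9] g/dL")
  inner <- -0.091 + 0.47 * Hc + 0.22 * cf - 0.14 * cf^2 + 0.48 * Hc * cf
  out <- 0.1 * inner^2                      # dyn/cm2 -> Pa
  if (any(inner < 0)) {
    out[inner < 0] <- 0
    attr(out, "flag") <- "inner_negative"
  }
  out
}

#' Fibrinogen concentration from yield stress (Morris inversion)
#'
#' Inverts the Morris correlation for `cf` at given hematocrit: solves the
#' quadratic `-0.14 cf^2 + (0.22 + 0.48 Hc) cf + (-0.091 + 0.47 Hc - s) = 0`
#' with `s = sqrt(10 * tau_y)` (the positive square root of the dyn/cm2
#' value) and returns the smallest positive root. Round-trips with
#' [morris_yield_stress()].
#'
#' @param tau_y yield stress (Pa), `>= 0`.
#' @param Hc hematocrit (volume fraction).
#' @return fibrinogen concentration (g/dL).
#' @export
fibrinogen_from_yield <- function(tau_y, Hc) {
  stopifnot(tau_y >= 0)
  s <- sqrt(10 * tau_y)
  a <- -0.14; b <- 0.22 + 0.48 * Hc; cc <- -0.091 + 0.47 * Hc - s
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("no real root: yield stress out of the invertible range")
  roots <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
  pos <- roots[roots > 0 | abs(roots) < 1e-14]
  if (!length(pos)) stop("no positive root for cf")
  min(pos)
}

#' Sigmoid fit of the steady structure parameter
#'
#' Fits `lam_s(gdot) = A + (B - A) * gdot^n / (k^n + gdot^n)` to steady
#' `lambda(gamma_dot)` samples by Levenberg--Marquardt least squares.
#'
#' @param gamma_dot rates (1/s).
#' @param lam steady structure-parameter values.
#' @param start optional named start values (`A`, `B`, `k`, `n`).
#' @return list of class `sigmoid_fit`: coefficients `A`, `B`, `k`, `n` and
#'   `rms` residual.
#' @export
fit_sigmoid_structure <- function(gamma_dot, lam, start = NULL) {
  stopifnot(length(gamma_dot) >= 8, length(lam) == length(gamma_dot))
  if (is.null(start))
    start <- list(A = max(lam), B = min(lam),
                  k = exp(mean(log(range(gamma_dot)))), n = 1.3)
  fit <- minpack.lm::nlsLM(
    lam ~ A + (B - A) * gamma_dot^n / (k^n + gamma_dot^n),
    start = start,
    lower = c(A = 0, B = 0, k = 1e-8, n = 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- as.list(stats::coef(fit))
  structure(c(co, list(rms = sqrt(mean(stats::resid(fit)^2)))),
            class = "sigmoid_fit")
}

#' @export
predict.sigmoid_fit <- function(object, gamma_dot, ...) {
  with(object, A + (B - A) * gamma_dot^n / (k^n + gamma_dot^n))
}

#' Rational fit of the steady extensional normal-stress difference
#'
#' Fits `N1(edot) = (A1 + A2 edot) / (1 + A3 edot + A4 edot^2)` (A1 in Pa,
#' A2 in Pa s, A3 in s, A4 in s^2). The fit is initialised by ordinary least
#' squares on the linearised form and polished by Levenberg--Marquardt; fits
#' whose denominator changes sign inside the data range are rejected.
#'
#' @param eps_dot elongation rates (1/s).
#' @param N1 steady first normal-stress differences (Pa).
#' @return list of class `n1_fit`: `A1`, `A2`, `A3`, `A4`, `rms`.
#' @export
fit_n1_rational <- function(eps_dot, N1) {
  stopifnot(length(eps_dot) >= 5, length(N1) == length(eps_dot))
  # N1 = A1 + A2 e - A3 e N1 - A4 e^2 N1 is linear in the coefficients
  X <- cbind(1, eps_dot, -eps_dot * N1, -eps_dot^2 * N1)
  beta <- stats::lm.fit(X, N1)$coefficients
  start <- list(A1 = beta[[1]], A2 = beta[[2]], A3 = beta[[3]],
                A4 = beta[[4]])
  fit <- minpack.lm::nlsLM(
    N1 ~ (A1 + A2 * eps_dot) / (1 + A3 * eps_dot + A4 * eps_dot^2),
    start = start, control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- as.list(stats::coef(fit))
  den <- 1 + co$A3 * eps_dot + co$A4 * eps_dot^2
  if (any(den <= 0))
    stop("fit rejected: denominator not positive over the fitted range")
  structure(c(co, list(rms = sqrt(mean(stats::resid(fit)^2)))),
            class = "n1_fit")
}

#' @export
predict.n1_fit <- function(object, eps_dot, ...) {
  with(object, (A1 + A2 * eps_dot) / (1 + A3 * eps_dot + A4 * eps_dot^2))
}

#' Extensional viscosity from an N1 fit
#'
#' `eta_e(edot) = N1(edot) / edot` by definition.
#'
#' @param fit an [fit_n1_rational()] result.
#' @param eps_dot elongation rates (1/s), positive.
#' @return Pa s.
#' @export
extensional_viscosity <- function(fit, eps_dot) {
  stopifnot(all(eps_dot > 0))
  predict(fit, eps_dot) / eps_dot
}

#' Lissajous--Bowditch projections of an oscillatory cycle
#'
#' From a periodic LAOS cycle, extracts the elastic projection (stress vs
#' strain) and the viscous projection (stress vs shear rate), plus the
#' structure-parameter channel.
#'
#' @param cycle a one-cycle [rheogram] from [periodic_steady_state()].
#' @return data.frame with `phase`, `strain`, `rate`, `txy`, `txx`, `lam`.
#' @export
lissajous_bowditch <- function(cycle) {
  if (!isTRUE(attr(cycle, "periodic")))
    warning("cycle is flagged non-periodic; projections may not close")
  data.frame(phase = cycle$phase, strain = cycle$strain, rate = cycle$rate,
             txy = cycle$txy, txx = cycle$txx, lam = cycle$lam)
}

#' Pipkin grid of Lissajous--Bowditch curves
#'
#' Runs [periodic_steady_state()] on every `(gamma_0, omega)` combination
#' and stacks the projections in long format.
#'
#' @param p [tevp_parameters()].
#' @param gamma_0 strain amplitudes.
#' @param omega angular frequencies (rad/s).
#' @param ctrl [integrator_controls()].
#' @param n_cycles cycle cap per cell.
#' @return long data.frame with `gamma_0`, `omega`, `periodic` and the
#'   [lissajous_bowditch()] columns.
#' @export
pipkin_grid <- function(p, gamma_0 = c(1, 10, 100),
                        omega = c(0.1, 1, 10),
                        ctrl = integrator_controls(), n_cycles = 20) {
  out <- list()
  for (g0 in gamma_0) for (om in omega) {
    cyc <- periodic_steady_state(protocol_laos(g0, om, n_cycles), p, ctrl)
    lb <- lissajous_bowditch(cyc)
    lb$gamma_0 <- g0; lb$omega <- om
    lb$periodic <- isTRUE(attr(cyc, "periodic"))
    out[[length(out) + 1L]] <- lb
  }
  do.call(rbind, out)
}

#' Generalized-Newtonian comparator viscosities
#'
#' Standard steady-shear viscosity models used as comparators for the TEVP
#' flow curve:
#' \describe{
#'   \item{casson}{`sqrt(tau) = sqrt(tau_y) + sqrt(eta_c * gdot)`, so
#'     `eta = (sqrt(tau_y / gdot) + sqrt(eta_c))^2`.}
#'   \item{cross}{`eta = eta_inf + (eta_0 - eta_inf) / (1 + (K gdot)^m)`.}
#'   \item{carreau_yasuda}{`eta = eta_inf + (eta_0 - eta_inf) *
#'     (1 + (lam_c gdot)^a)^((n - 1)/a)`.}
#' }
#'
#' @param model model name.
#' @param params named list of the model's parameters (see Details).
#' @param gamma_dot rates (1/s), positive.
#' @return viscosity (Pa s).
#' @export
gn_viscosity <- function(model = c("casson", "cross", "carreau_yasuda"),
                         params, gamma_dot) {
  model <- match.arg(model)
  stopifnot(all(gamma_dot > 0))
  bad <- vapply(params, function(v) !is.finite(v) || v < 0, logical(1))
  # carreau-yasuda exponent n may legitimately be < 1 but must be positive
  if (any(bad)) stop("non-physical (negative) parameter in ", model)
  with(params, switch(model,
    casson = (sqrt(tau_y / gamma_dot) + sqrt(eta_c))^2,
    cross = eta_inf + (eta_0 - eta_inf) / (1 + (K * gamma_dot)^m),
    carreau_yasuda = eta_inf + (eta_0 - eta_inf) *
      (1 + (lam_c * gamma_dot)^a)^((n - 1) / a)))
}

#' Fit a generalized-Newtonian model to a flow curve
#'
#' Least squares on log-viscosity (viscosities span decades).
#'
#' @param model model name as in [gn_viscosity()].
#' @param gamma_dot rates (1/s).
#' @param eta_app apparent viscosities (Pa s).
#' @param start optional named start list.
#' @return named list of fitted parameters with attribute `rms`
#'   (log-viscosity residual RMS).
#' @export
gn_fit <- function(model = c("casson", "cross", "carreau_yasuda"),
                   gamma_dot, eta_app, start = NULL) {
  model <- match.arg(model)
  if (is.null(start))
    start <- switch(model,
      casson = list(tau_y = 0.003, eta_c = min(eta_app)),
      cross = list(eta_0 = max(eta_app), eta_inf = min(eta_app),
                   K = 1, m = 1),
      carreau_yasuda = list(eta_0 = max(eta_app), eta_inf = min(eta_app),
                            lam_c = 1, a = 2, n = 0.4))
  ln_eta <- log(eta_app)
  fn <- function(par) {
    pl <- as.list(abs(par))
    names(pl) <- names(start)
    log(gn_viscosity(model, pl, gamma_dot)) - ln_eta
  }
  fit <- minpack.lm::nls.lm(par = unlist(start), fn = fn,
                            control = minpack.lm::nls.lm.control(maxiter = 300))
  out <- as.list(abs(fit$par))
  names(out) <- names(start)
  attr(out, "rms") <- sqrt(mean(fit$fvec^2))
  out
}
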