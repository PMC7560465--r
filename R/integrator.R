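#' Integrator controls
#'
#' Numerical controls for the time integration of the coupled
#' stress/structure system and for steady-state detection.
#'
#' @param rtol,atol relative / absolute local-error tolerances (absolute in
#'   Pa for stress components, dimensionless for `lambda`).
#' @param dt_init,dt_min,dt_max initial / minimum / maximum step (s).
#' @param newton_tol scaled residual tolerance of the implicit corrector.
#' @param steady_tol steady state is declared when every component of the
#'   right-hand side satisfies `|dy/dt| < steady_tol * (atol + |y|)` per
#'   second.
#' @param dt_fixed if not `NULL`, disables step adaptivity and uses this
#'   fixed step (used e.g. for convergence-order verification).
#' @param eta_floor guard floor on the thixotropic viscosity (Pa s).
#' @param lam_clip_tol `lambda` excursions beyond `[0, 1]` smaller than this
#'   are clipped; larger ones cause step rejection.
#' @return list of class `integrator_controls`.
#' @export
integrator_controls <- function(rtol = 1e-6, atol = 1e-9,
                                dt_init = 1e-4, dt_min = 1e-12, dt_max = 0.25,
                                newton_tol = 1e-10, steady_tol = 1e-6,
                                dt_fixed = NULL, eta_floor = 1e-12,
                                lam_clip_tol = 1e-6) {
  stopifnot(rtol > 0, atol > 0, dt_min > 0, dt_init >= dt_min,
            dt_max >= dt_init, newton_tol > 0, steady_tol > 0)
  structure(list(rtol = rtol, atol = atol, dt_init = dt_init,
                 dt_min = dt_min, dt_max = dt_max, newton_tol = newton_tol,
                 steady_tol = steady_tol, dt_fixed = dt_fixed,
                 eta_floor = eta_floor, lam_clip_tol = lam_clip_tol),
            class = "integrator_controls")
}

num_jacobian <- function(f, y, f0 = f(y), eps = 1e-7) {
  n <- length(y)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    h <- eps * max(abs(y[j]), 1e-4)
    yj <- y; yj[j] <- yj[j] + h
    J[, j] <- (f(yj) - f0) / h
  }
  J
}

# One adaptive trapezoidal predictor-corrector segment on [t0, t1].
# rhs_t(t, y) must be smooth on the open segment. Returns list(time, Y).
pc2_segment <- function(rhs_t, t0, t1, y0, ctrl, record = TRUE) {
  t <- t0; y <- y0
  fixed <- !is.null(ctrl$dt_fixed)
  dt <- if (fixed) ctrl$dt_fixed else min(ctrl$dt_init, t1 - t0)
  ny <- length(y0)
  I7 <- diag(ny)
  J <- NULL; steps_since_jac <- 1e9
  times <- if (record) c(t0) else numeric()
  Y <- if (record) list(y0) else list()
  f <- rhs_t(t, y)
  clip_events <- 0L
  repeat {
    if (t >= t1 - 1e-14 * max(1, abs(t1))) break
    dt <- min(dt, t1 - t)
    tn <- t + dt
    yp <- y + dt * f                       # explicit predictor
    if (any(!is.finite(yp))) stop("non-finite state in predictor")
    fp <- rhs_t(tn, yp)
    z <- y + (dt / 2) * (f + fp)           # Heun value = Newton start
    if (is.null(J) || steps_since_jac > 25) {
      J <- num_jacobian(function(v) rhs_t(tn, v), z, rhs_t(tn, z))
      steps_since_jac <- 0L
    }
    M <- I7 - (dt / 2) * J
    converged <- FALSE
    for (it in 1:8) {
      g <- z - y - (dt / 2) * (f + rhs_t(tn, z))
      sc <- ctrl$atol + ctrl$rtol * pmax(abs(y), abs(z))
      if (max(abs(g) / sc) < 0.01) {
        converged <- TRUE
        break
      }
      dz <- tryCatch(solve(M, -g), error = function(e) NULL)
      if (is.null(dz)) break
      z <- z + dz
      if (it == 3) {                        # slow: refresh the Jacobian
        J <- num_jacobian(function(v) rhs_t(tn, v), z, rhs_t(tn, z))
        M <- I7 - (dt / 2) * J
        steps_since_jac <- 0L
      }
    }
    lam_ok <- TRUE
    if (converged) {
      lam <- z[ny]
      if (lam < -ctrl$lam_clip_tol || lam > 1 + ctrl$lam_clip_tol) {
        lam_ok <- FALSE
      } else if (lam < 0 || lam > 1) {
        z[ny] <- min(max(lam, 0), 1)
        clip_events <- clip_events + 1L
      }
    }
    sc <- ctrl$atol + ctrl$rtol * pmax(abs(y), abs(z))
    err <- if (converged) max(abs(z - yp) / sc) / 3 else Inf
    if (fixed) {
      if (!converged || !lam_ok)
        stop("fixed-step corrector failed at t = ", signif(t, 6))
      accept <- TRUE
    } else accept <- converged && lam_ok && err <= 1
    if (accept) {
      t <- tn; y <- z
      f <- rhs_t(t, y)
      if (any(!is.finite(f))) stop("non-finite right-hand side at t = ", t)
      if (record) {
        times <- c(times, t)
        Y[[length(Y) + 1L]] <- y
      }
      steps_since_jac <- steps_since_jac + 1L
      if (!fixed) {
        fac <- if (err > 0) 0.9 / sqrt(err) else 5
        dt <- min(ctrl$dt_max, dt * min(5, max(0.2, fac)))
      }
    } else {
      dt <- dt / 2
      J <- NULL
      if (dt < ctrl$dt_min)
        stop("integrator failed: step below dt_min at t = ", signif(t, 6))
    }
  }
  list(time = times, Y = Y, y_end = y, clip_events = clip_events)
}

#' Integrate a rheometric protocol
#'
#' Time integration of the coupled stress / structure ODE system under the
#' imposed kinematics of `spec`, from the state `init`. The default scheme is
#' an A-stable second-order trapezoidal corrector with an explicit predictor
#' and an adaptive step controlled by the predictor--corrector discrepancy;
#' protocol breakpoints are exact events at which the integration restarts
#' with carried-over state. `method = "lsoda"` delegates each smooth segment
#' to [deSolve::lsoda()] (useful as an independent cross-check).
#'
#' @param spec a [protocols] object.
#' @param p [tevp_parameters()].
#' @param init initial [material_state()] (default: rest, fully structured).
#' @param ctrl [integrator_controls()].
#' @param method `"pc2"` (default) or `"lsoda"`.
#' @return a [rheogram] (data.frame of the state trajectory plus derived
#'   channels).
#' @export
integrate_protocol <- function(spec, p, init = material_state(),
                               ctrl = integrator_controls(),
                               method = c("pc2", "lsoda")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "tevp_protocol"), inherits(p, "tevp_parameters"))
  y <- c(unclass(init$tau), init$lam)
  edges <- unique(c(0, spec$breakpoints, spec$t_end))
  all_t <- 0
  all_Y <- list(y)
  clip <- 0L
  for (k in seq_len(length(edges) - 1L)) {
    t0 <- edges[k]; t1 <- edges[k + 1L]
    # evaluate the kinematics strictly inside the segment to dodge the
    # discontinuity at its edges
    rhs_t <- local({
      t0k <- t0; t1k <- t1
      function(t, yv) {
        tt <- min(max(t, t0k), t1k)
        tt <- t0k + (tt - t0k) * (1 - 1e-12) + 1e-15 * (t1k - t0k)
        tevp_rhs(yv, velocity_gradient(spec, tt), p, ctrl$eta_floor)
      }
    })
    if (method == "pc2") {
      seg <- pc2_segment(rhs_t, t0, t1, y, ctrl)
      tt <- seg$time[-1]; YY <- seg$Y[-1]
      y <- seg$y_end
      clip <- clip + seg$clip_events
    } else {
      n_out <- max(20L, min(2000L, ceiling((t1 - t0) / max(ctrl$dt_init, 1e-4))))
      times <- seq(t0, t1, length.out = n_out)
      sol <- deSolve::lsoda(y, times,
                            function(t, yv, parms) list(rhs_t(t, yv)),
                            rtol = ctrl$rtol, atol = ctrl$atol)
      tt <- sol[-1, 1]
      YY <- lapply(seq_len(nrow(sol) - 1L) + 1L, function(i) {
        v <- sol[i, -1]
        v[7] <- min(max(v[7], 0), 1)
        v
      })
      y <- YY[[length(YY)]]
    }
    all_t <- c(all_t, tt)
    all_Y <- c(all_Y, YY)
  }
  Ymat <- do.call(rbind, all_Y)
  rg <- new_rheogram(all_t, Ymat, spec, p, ctrl, method)
  attr(rg, "lam_clip_events") <- clip
  rg
}

#' Steady state under constant kinematics
#'
#' Long-time attractor of the model at a constant shear or elongation rate,
#' obtained by time-marching until the steady tolerance is met and then
#' polishing with a damped Newton iteration on the algebraic system
#' `rhs(y) = 0`. The two routes must agree; their relative discrepancy is
#' attached as `attr(, "route_gap")`.
#'
#' @param rate imposed rate (1/s), positive.
#' @param mode `"shear"` or `"uniaxial"`.
#' @param p [tevp_parameters()].
#' @param ctrl [integrator_controls()].
#' @param guess optional [material_state()] used as Newton starting point
#'   (continuation along a flow curve); time-marching is then skipped unless
#'   Newton fails.
#' @param t_cap cap on the marching time (s); default covers the slowest
#'   (Brownian rebuild) time scale.
#' @return a [material_state()] with attributes `route_gap` and `residual`.
#' @export
steady_state <- function(rate, mode = c("shear", "uniaxial"), p,
                         ctrl = integrator_controls(), guess = NULL,
                         t_cap = 1e4 * max(p$chi0, 1 / p$k1)) {
  mode <- match.arg(mode)
  stopifnot(rate > 0)
  L <- if (mode == "uniaxial") diag(c(rate, -rate / 2, -rate / 2)) else
    matrix(c(0, 0, 0, rate, 0, 0, 0, 0, 0), 3L, 3L)
  f <- function(y) tevp_rhs(y, L, p, ctrl$eta_floor)
  is_steady <- function(y) {
    all(abs(f(y)) < ctrl$steady_tol * (ctrl$atol + abs(y)))
  }
  march <- function(y0) {
    t_tot <- 0
    chunk <- max(20 * p$chi0, 5 / rate, 1)
    y <- y0
    repeat {
      seg <- pc2_segment(function(t, yv) f(yv), 0, chunk, y, ctrl,
                         record = FALSE)
      y <- seg$y_end
      t_tot <- t_tot + chunk
      if (is_steady(y)) break
      if (t_tot > t_cap)
        stop("steady_state: no convergence within t_cap = ", signif(t_cap, 4),
             " s (last max |dy/dt| = ", signif(max(abs(f(y))), 3), ")")
      chunk <- min(chunk * 2, t_cap / 4)
    }
    y
  }
  newton <- function(y0) {
    y <- y0
    for (it in 1:60) {
      F0 <- f(y)
      if (max(abs(F0)) < ctrl$newton_tol) return(y)
      J <- num_jacobian(f, y, F0)
      # Levenberg-style damping keeps the step sane when a direction is
      # degenerate (e.g. frozen structure kinetics make the lambda row ~ 0)
      JtJ <- crossprod(J)
      mu <- 1e-12 * max(diag(JtJ))
      dy <- NULL
      for (k in 1:8) {
        dy <- tryCatch(solve(JtJ + mu * diag(diag(JtJ)),
                             -crossprod(J, F0))[, 1],
                       error = function(e) NULL)
        if (!is.null(dy) && all(is.finite(dy))) break
        mu <- mu * 100
      }
      if (is.null(dy) || !all(is.finite(dy))) return(NULL)
      s <- 1
      repeat {
        yn <- y + s * dy
        yn[7] <- min(max(yn[7], 1e-12), 1)
        if (max(abs(f(yn))) < max(abs(F0)) || s < 1e-4) break
        s <- s / 2
      }
      if (max(abs(yn - y)) < 1e-15 * max(1, max(abs(y)))) { y <- yn; break }
      y <- yn
    }
    if (max(abs(f(y))) < ctrl$newton_tol) y else NULL
  }
  y_march <- NULL
  if (is.null(guess)) {
    y_march <- march(c(rep(0, 6), 1))
    y0 <- y_march
  } else {
    y0 <- c(unclass(guess$tau), guess$lam)
  }
  y_nt <- newton(y0)
  if (is.null(y_nt)) {
    if (is.null(y_march)) y_march <- march(c(rep(0, 6), 1))
    y_nt <- newton(y_march)
    if (is.null(y_nt)) {
      warning("steady_state: Newton polish failed; returning marched state")
      y_nt <- y_march
    }
  }
  if (is.null(y_march) || is.null(guess)) {
    gap <- if (is.null(y_march)) NA_real_ else
      max(abs(y_nt - y_march) / (ctrl$atol + abs(y_nt)))
  } else gap <- NA_real_
  st <- material_state(t = Inf, tau = sym_tensor(y_nt[1], y_nt[2], y_nt[3],
                                                 y_nt[4], y_nt[5], y_nt[6]),
                       lam = y_nt[7])
  attr(st, "route_gap") <- gap
  attr(st, "residual") <- max(abs(f(y_nt)))
  st
}

#' Periodic (alternance) state in LAOS
#'
#' Integrates oscillatory cycles until the relative L2 distance between the
#' `(tau_xy, lambda)` traces of consecutive cycles falls below `cycle_tol`,
#' then returns the final cycle with phase and strain channels. If the cap
#' `spec$params$n_cycles` is reached first, the returned cycle carries
#' `attr(, "periodic") = FALSE`.
#'
#' @param spec a `laos` protocol.
#' @param p [tevp_parameters()].
#' @param ctrl [integrator_controls()].
#' @param cycle_tol relative cycle-to-cycle tolerance.
#' @return a [rheogram] of one cycle with columns `phase` (radians in
#'   `[0, 2*pi)`) and `strain`, and attribute `periodic`.
#' @export
periodic_steady_state <- function(spec, p, ctrl = integrator_controls(),
                                  cycle_tol = 1e-4) {
  stopifnot(spec$kind == "laos")
  om <- spec$params$omega; g0 <- spec$params$gamma_0
  Tcyc <- 2 * pi / om
  n_max <- spec$params$n_cycles
  phase_grid <- seq(0, Tcyc, length.out = 257)[-257]
  one <- protocol_laos(g0, om, n_cycles = 1)
  state <- material_state()
  prev <- NULL
  periodic <- FALSE
  for (cyc in seq_len(n_max)) {
    rg <- integrate_protocol(one, p, init = state, ctrl = ctrl)
    cur <- cbind(stats::approx(rg$time, rg$txy, xout = phase_grid,
                               rule = 2)$y,
                 stats::approx(rg$time, rg$lam, xout = phase_grid,
                               rule = 2)$y)
    if (!is.null(prev)) {
      num <- sqrt(colSums((cur - prev)^2))
      den <- sqrt(colSums(prev^2)) + 1e-30
      if (all(num / den < cycle_tol)) { periodic <- TRUE }
    }
    n <- nrow(rg)
    state <- material_state(t = 0,
                            tau = sym_tensor(rg$txx[n], rg$tyy[n], rg$tzz[n],
                                             rg$txy[n], rg$txz[n], rg$tyz[n]),
                            lam = rg$lam[n])
    if (periodic || cyc == n_max) {
      rg$phase <- (rg$time %% Tcyc) / Tcyc * 2 * pi
      rg$strain <- g0 * sin(om * rg$time)
      attr(rg, "periodic") <- periodic
      attr(rg, "cycles_run") <- cyc
      return(rg)
    }
    prev <- cur
  }
}
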