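#' Rheometric protocol specifications
#'
#' A protocol encodes an imposed-kinematics history as a time-dependent
#' velocity gradient. Shear protocols use the fixed convention
#' `u = (gamma_dot(t) * y, 0, 0)`, i.e. the only nonzero velocity-gradient
#' component is `L[1, 2] = du_x/dy = gamma_dot(t)` (so `D_xy = gamma_dot/2`);
#' uniaxial extension imposes the traceless diagonal gradient
#' `diag(eps_dot, -eps_dot/2, -eps_dot/2)`.
#'
#' Constructors:
#' \describe{
#'   \item{`protocol_startup(gamma_dot_0, t_end)`}{constant rate from `t = 0`.}
#'   \item{`protocol_cessation(gamma_dot_0, t_ces, t_end)`}{constant rate
#'     until `t_ces`, then rest.}
#'   \item{`protocol_intermittent(gamma_dot_0, t_pulse, t_rest, n_pulses,
#'     t_tail)`}{rectangular shear steps: `n_pulses` shearing pulses of
#'     duration `t_pulse` separated by rests of duration `t_rest`, followed by
#'     a final rest of `t_tail`.}
#'   \item{`protocol_triangular(a, t_max)`}{rate ramps `a * t` up to
#'     `t_max / 2`, then `a * (t_max - t)` back to zero (peak rate
#'     `a * t_max / 2`).}
#'   \item{`protocol_exp_rampdown(gamma_dot_start, gamma_dot_end, steps_a,
#'     dt_step, stepped)`}{shear-rate decay
#'     `gamma_dot(t) = gamma_dot_start * exp(-t / (steps_a * dt_step))`,
#'     run until the rate reaches `gamma_dot_end`
#'     (duration `steps_a * dt_step * log(start/end)`); `stepped = TRUE`
#'     discretises the decay into `steps_a` equal-duration log-spaced steps.}
#'   \item{`protocol_laos(gamma_0, omega, n_cycles)`}{oscillatory strain
#'     `gamma = gamma_0 * sin(omega t)`, so
#'     `gamma_dot = gamma_0 * omega * cos(omega t)` (starts at maximum rate).}
#'   \item{`protocol_uniaxial(eps_dot_0, t_end)`}{constant elongation rate.}
#'   \item{`protocol_rest(t_end)`}{no imposed flow (relaxation segment).}
#'   \item{`protocol_steady_shear(gamma_dot_0, t_end)`}{alias of startup, for
#'     steady-state studies.}
#' }
#'
#' @param gamma_dot_0,eps_dot_0 imposed rate (1/s), positive.
#' @param t_end,t_ces,t_pulse,t_rest,t_tail,dt_step,t_max durations (s).
#' @param n_pulses,n_cycles,steps_a positive integers / counts.
#' @param a triangular ramp rate (1/s^2).
#' @param gamma_dot_start,gamma_dot_end ramp-down end points (1/s),
#'   `gamma_dot_start > gamma_dot_end > 0`.
#' @param gamma_0 strain amplitude (dimensionless).
#' @param omega angular frequency (rad/s).
#' @param stepped logical; discretise the exponential ramp-down into steps.
#' @return An object of class `tevp_protocol` with fields `kind`, `params`,
#'   `t_end`, `mode` (`"shear"` or `"uniaxial"`), `breakpoints` (event times
#'   at which the imposed kinematics is discontinuous or non-smooth) and
#'   `rate` (function of time returning the scalar imposed rate).
#' @name protocols
NULL

new_protocol <- function(kind, params, t_end, rate, breakpoints = numeric(),
                         mode = "shear") {
  for (v in params)
    if (!(is.numeric(v) || is.logical(v)) || length(v) != 1L || is.na(v))
      stop("protocol parameters must be finite scalars")
  stopifnot(is.function(rate), is.numeric(t_end), length(t_end) == 1L,
            is.finite(t_end), t_end > 0)
  structure(list(kind = kind, params = params, t_end = t_end,
                 mode = mode, rate = rate,
                 breakpoints = sort(unique(breakpoints[breakpoints > 0 &
                                                         breakpoints < t_end]))),
            class = "tevp_protocol")
}

#' @rdname protocols
#' @export
protocol_startup <- function(gamma_dot_0, t_end = 30) {
  stopifnot(gamma_dot_0 > 0)
  new_protocol("startup", list(gamma_dot_0 = gamma_dot_0), t_end,
               function(t) rep(gamma_dot_0, length(t)))
}

#' @rdname protocols
#' @export
protocol_steady_shear <- function(gamma_dot_0, t_end = 30) {
  pr <- protocol_startup(gamma_dot_0, t_end)
  pr$kind <- "steady_shear"
  pr
}

#' @rdname protocols
#' @export
protocol_cessation <- function(gamma_dot_0, t_ces = 3, t_end = t_ces + 7) {
  stopifnot(gamma_dot_0 > 0, t_ces > 0, t_end > t_ces)
  new_protocol("cessation",
               list(gamma_dot_0 = gamma_dot_0, t_ces = t_ces), t_end,
               function(t) ifelse(t < t_ces, gamma_dot_0, 0),
               breakpoints = t_ces)
}

#' @rdname protocols
#' @export
protocol_intermittent <- function(gamma_dot_0, t_pulse = 2.5, t_rest = 1.5,
                                  n_pulses = 2, t_tail = t_rest) {
  stopifnot(gamma_dot_0 > 0, t_pulse > 0, t_rest >= 0, n_pulses >= 1)
  period <- t_pulse + t_rest
  t_end <- n_pulses * t_pulse + (n_pulses - 1) * t_rest + t_tail
  bp <- numeric()
  for (i in seq_len(n_pulses)) {
    s <- (i - 1) * period
    bp <- c(bp, s, s + t_pulse)
  }
  rate <- function(t) {
    idx <- floor(t / period)          # 0-based pulse index
    tl <- t - idx * period            # time within the current period
    on <- idx < n_pulses & tl < t_pulse
    ifelse(on, gamma_dot_0, 0)
  }
  new_protocol("intermittent",
               list(gamma_dot_0 = gamma_dot_0, t_pulse = t_pulse,
                    t_rest = t_rest, n_pulses = n_pulses), t_end,
               rate, breakpoints = bp)
}

#' @rdname protocols
#' @export
protocol_triangular <- function(a, t_max) {
  stopifnot(a > 0, t_max > 0)
  new_protocol("triangular", list(a = a, t_max = t_max), t_max,
               function(t) ifelse(t < t_max / 2, a * t, a * (t_max - t)),
               breakpoints = t_max / 2)
}

#' @rdname protocols
#' @export
protocol_exp_rampdown <- function(gamma_dot_start = 800, gamma_dot_end = 0.8,
                                  steps_a = 4, dt_step = 1, stepped = FALSE) {
  stopifnot(gamma_dot_start > gamma_dot_end, gamma_dot_end > 0,
            steps_a > 0, dt_step > 0)
  tc <- steps_a * dt_step                       # e-folding time
  t_end <- tc * log(gamma_dot_start / gamma_dot_end)
  params <- list(gamma_dot_start = gamma_dot_start,
                 gamma_dot_end = gamma_dot_end,
                 steps_a = steps_a, dt_step = dt_step, stepped = stepped)
  if (!stepped) {
    rate <- function(t) pmax(gamma_dot_start * exp(-t / tc), gamma_dot_end)
    bp <- numeric()
  } else {
    # steps_a log-spaced plateaus of equal duration covering [start, end]
    n <- max(2L, as.integer(round(steps_a)))
    lev <- exp(seq(log(gamma_dot_start), log(gamma_dot_end),
                   length.out = n))
    dt_lvl <- t_end / n
    rate <- function(t) {
      i <- pmin(n, floor(t / dt_lvl) + 1)
      lev[pmax(1, i)]
    }
    bp <- dt_lvl * seq_len(n - 1)
  }
  new_protocol("exp_rampdown", params, t_end, rate, breakpoints = bp)
}

#' @rdname protocols
#' @export
protocol_laos <- function(gamma_0, omega, n_cycles = 10) {
  stopifnot(gamma_0 > 0, omega > 0, n_cycles >= 1)
  t_end <- n_cycles * 2 * pi / omega
  new_protocol("laos",
               list(gamma_0 = gamma_0, omega = omega, n_cycles = n_cycles),
               t_end, function(t) gamma_0 * omega * cos(omega * t))
}

#' @rdname protocols
#' @export
protocol_rest <- function(t_end = 10) {
  new_protocol("rest", list(), t_end, function(t) rep(0, length(t)))
}

#' @rdname protocols
#' @export
protocol_uniaxial <- function(eps_dot_0, t_end = 30) {
  stopifnot(eps_dot_0 > 0)
  new_protocol("uniaxial", list(eps_dot_0 = eps_dot_0), t_end,
               function(t) rep(eps_dot_0, length(t)), mode = "uniaxial")
}

#' @export
print.tevp_protocol <- function(x, ...) {
  cat(sprintf("tevp_protocol '%s' (%s), t_end = %g s\n",
              x$kind, x$mode, x$t_end))
  cat("  params:", paste(sprintf("%s=%g", names(x$params),
                                 unlist(x$params)), collapse = " "), "\n")
  if (length(x$breakpoints))
    cat("  breakpoints:",
        paste(signif(utils::head(x$breakpoints, 8), 6), collapse = " "),
        if (length(x$breakpoints) > 8) "...", "\n")
  invisible(x)
}

#' Velocity gradient of a protocol at time t
#'
#' @param spec a `tevp_protocol`.
#' @param t time (s), scalar, `t >= 0`.
#' @param hold_last if `TRUE`, times beyond `t_end` return the terminal
#'   kinematics instead of raising an error.
#' @return 3x3 velocity-gradient matrix `L` (1/s), `L[i, j] = du_i/dx_j`.
#' @export
velocity_gradient <- function(spec, t, hold_last = FALSE) {
  stopifnot(inherits(spec, "tevp_protocol"), length(t) == 1L, t >= 0)
  if (t > spec$t_end) {
    if (!hold_last) stop("t beyond protocol end (", spec$t_end, " s)")
    t <- spec$t_end
  }
  r <- spec$rate(t)
  if (spec$mode == "uniaxial")
    diag(c(r, -r / 2, -r / 2))
  else
    matrix(c(0, 0, 0, r, 0, 0, 0, 0, 0), 3L, 3L)  # L[1,2] = gamma_dot
}

#' Exponential ramp-down shear rate
#'
#' `gamma_dot(t) = gamma_dot_start * exp(-t / (steps_a * dt_step))`, clamped
#' below at `gamma_dot_end`.
#'
#' @param spec an `exp_rampdown` protocol.
#' @param t time (s), vectorised.
#' @return shear rate (1/s).
#' @export
exp_rampdown_rate <- function(spec, t) {
  stopifnot(inherits(spec, "tevp_protocol"), spec$kind == "exp_rampdown")
  spec$rate(t)
}

#' Folded (transformed) time of the triangular protocol
#'
#' `t' = t` on the up-ramp and `t' = t_max - t` on the down-ramp, used to
#' overlay the two branches of a hysteresis rheogram.
#'
#' @param spec a `triangular` protocol.
#' @param t time (s), vectorised, within `[0, t_max]`.
#' @return transformed time (s) in `[0, t_max / 2]`.
#' @export
transformed_time <- function(spec, t) {
  stopifnot(inherits(spec, "tevp_protocol"), spec$kind == "triangular")
  if (any(t < 0 | t > spec$t_end)) stop("t outside [0, t_max]")
  tm <- spec$params$t_max
  ifelse(t < tm / 2, t, tm - t)
}

#' Breakpoint schedule of a protocol
#'
#' A human-readable table of the protocol's segments: start/end time and the
#' imposed rate at the segment midpoint (exact for piecewise-constant
#' protocols).
#'
#' @param spec a `tevp_protocol`.
#' @return data.frame with columns `t_start`, `t_end`, `rate_mid`.
#' @export
protocol_schedule <- function(spec) {
  stopifnot(inherits(spec, "tevp_protocol"))
  edges <- unique(c(0, spec$breakpoints, spec$t_end))
  data.frame(t_start = utils::head(edges, -1),
             t_end = edges[-1],
             rate_mid = vapply((utils::head(edges, -1) + edges[-1]) / 2,
                               function(tm) spec$rate(tm), numeric(1)))
}
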