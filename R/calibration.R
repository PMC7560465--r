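#' Rheometric dataset container
#'
#' A dataset for calibration: a steady flow-curve block (required) plus any
#' number of transient blocks (a protocol with a sampled shear-stress trace)
#' and optional small-amplitude oscillatory sweeps.
#'
#' @param steady data.frame with columns `rate` (1/s) and `txy` (Pa), sorted,
#'   positive.
#' @param transients list of blocks, each `list(spec = <tevp_protocol>,
#'   data = data.frame(time, txy))`.
#' @param oscillatory optional data.frame with columns `omega` (rad/s),
#'   `G1` (storage modulus, Pa), `G2` (loss modulus, Pa).
#' @param weights optional named numeric weights per block
#'   (`steady`, `transient`, `oscillatory`); default 1 each.
#' @param label provenance label.
#' @return object of class `rheometric_dataset`.
#' @export
rheometric_dataset <- function(steady, transients = list(),
                               oscillatory = NULL,
                               weights = c(steady = 1, transient = 1,
                                           oscillatory = 1),
                               label = "unlabelled") {
  stopifnot(is.data.frame(steady), all(c("rate", "txy") %in% names(steady)),
            nrow(steady) >= 1, all(steady$rate > 0),
            !is.unsorted(steady$rate))
  for (b in transients) {
    stopifnot(inherits(b$spec, "tevp_protocol"),
              all(c("time", "txy") %in% names(b$data)),
              all(b$data$time >= 0), !is.unsorted(b$data$time))
  }
  structure(list(steady = steady, transients = transients,
                 oscillatory = oscillatory, weights = weights,
                 label = label),
            class = "rheometric_dataset")
}

#' @export
print.rheometric_dataset <- function(x, ...) {
  cat(sprintf("rheometric_dataset '%s': %d steady points, %d transient block(s)%s\n",
              x$label, nrow(x$steady), length(x$transients),
              if (!is.null(x$oscillatory))
                sprintf(", %d oscillatory points", nrow(x$oscillatory))
              else ""))
  invisible(x)
}

#' Synthetic rheometric dataset from known parameters
#'
#' Simulates exact model curves for a steady sweep and a set of transient
#' protocols, then applies multiplicative log-normal noise with coefficient
#' of variation `noise_cv`. The default design mirrors the calibration
#' conditions the bundled presets were fitted under: a steady sweep over
#' 0.01--1000 1/s and an intermittent rectangular-step test at 7 1/s
#' (2.5 s pulses, 1.5 s rest).
#'
#' @param p generating [tevp_parameters()].
#' @param design list with `steady_rates` (vector, 1/s), `transients`
#'   (list of `tevp_protocol`s) and `transient_dt` (sampling interval, s).
#' @param noise_cv multiplicative noise coefficient of variation (0 = exact).
#' @param seed integer seed; same seed, same dataset.
#' @param ctrl [integrator_controls()].
#' @return a [rheometric_dataset()].
#' @export
generate_synthetic_dataset <- function(p,
    design = list(
      steady_rates = 10^seq(-2, 3, length.out = 16),
      transients = list(protocol_intermittent(7, 2.5, 1.5, 2)),
      transient_dt = 0.05),
    noise_cv = 0.02, seed = 1,
    ctrl = integrator_controls()) {
  stopifnot(noise_cv >= 0)
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + noise_cv^2))
  noisy <- function(x) if (noise_cv == 0) x else
    x * stats::rlnorm(length(x), -sdlog^2 / 2, sdlog)
  fc <- flow_curve(p, design$steady_rates, "shear", ctrl)
  steady <- data.frame(rate = fc$rate, txy = noisy(fc$txy))
  transients <- lapply(design$transients, function(spec) {
    r <- integrate_protocol(spec, p, ctrl = ctrl)
    tg <- seq(0, spec$t_end, by = design$transient_dt)
    s <- rheogram_at(r, tg, "txy")
    list(spec = spec, data = data.frame(time = tg, txy = noisy(s$txy)))
  })
  rheometric_dataset(steady, transients,
                     label = sprintf("synthetic (cv = %g, seed = %d)",
                                     noise_cv, as.integer(seed)))
}

#' Calibration residual vector
#'
#' Concatenated weighted residuals of the model against a dataset: log-space
#' residuals for the steady block (stresses span decades), linear residuals
#' for transient blocks, each block normalised by the RMS of its own data so
#' blocks contribute comparably. Oscillatory blocks, when present, are
#' matched via small-amplitude oscillatory simulation and cycle Fourier
#' extraction of `G'`/`G''` ([saos_moduli()]). A simulation failure at a
#' trial point yields a large finite penalty residual for that block.
#'
#' @param p trial [tevp_parameters()].
#' @param d a [rheometric_dataset()].
#' @param ctrl [integrator_controls()].
#' @return numeric residual vector.
#' @export
tevp_residuals <- function(p, d, ctrl = integrator_controls(rtol = 1e-6)) {
  out <- list()
  w <- d$weights
  res_steady <- tryCatch({
    fc <- flow_curve(p, d$steady$rate, "shear", ctrl)
    log(fc$txy) - log(d$steady$txy)
  }, error = function(e) rep(1e3, nrow(d$steady)))
  rms <- sqrt(mean(log(d$steady$txy)^2))
  out$steady <- w[["steady"]] * res_steady / max(rms, 1e-12)
  for (i in seq_along(d$transients)) {
    b <- d$transients[[i]]
    res <- tryCatch({
      r <- integrate_protocol(b$spec, p, ctrl = ctrl)
      rheogram_at(r, b$data$time, "txy")$txy - b$data$txy
    }, error = function(e) rep(1e3, nrow(b$data)))
    rms <- sqrt(mean(b$data$txy^2))
    out[[paste0("transient", i)]] <- w[["transient"]] * res / max(rms, 1e-12)
  }
  if (!is.null(d$oscillatory)) {
    osc <- d$oscillatory
    res <- tryCatch({
      gm <- t(vapply(osc$omega, function(om)
        saos_moduli(p, om, ctrl = ctrl), numeric(2)))
      c(gm[, 1] - osc$G1, gm[, 2] - osc$G2)
    }, error = function(e) rep(1e3, 2 * nrow(osc)))
    rms <- sqrt(mean(c(osc$G1, osc$G2)^2))
    out$oscillatory <- w[["oscillatory"]] * res / max(rms, 1e-12)
  }
  unlist(out, use.names = FALSE)
}

#' Small-amplitude oscillatory moduli
#'
#' Simulates a small-strain oscillation to its alternance state and extracts
#' the storage and loss moduli from the first Fourier harmonic of the shear
#' stress over the final cycle.
#'
#' @param p [tevp_parameters()].
#' @param omega angular frequency (rad/s).
#' @param gamma_0 strain amplitude (small; default 1e-3).
#' @param ctrl [integrator_controls()].
#' @param n_cycles cycle cap.
#' @return c(G1, G2) in Pa.
#' @export
saos_moduli <- function(p, omega, gamma_0 = 1e-3,
                        ctrl = integrator_controls(), n_cycles = 30) {
  cyc <- periodic_steady_state(protocol_laos(gamma_0, omega, n_cycles),
                               p, ctrl)
  t <- cyc$time; y <- cyc$txy
  # trapezoidal Fourier projections on sin/cos(omega t)
  w <- diff(t)
  mid <- function(v) (utils::head(v, -1) + v[-1]) / 2
  Tcyc <- 2 * pi / omega
  a <- sum(mid(y * sin(omega * t)) * w) * 2 / Tcyc
  b <- sum(mid(y * cos(omega * t)) * w) * 2 / Tcyc
  c(G1 = a / gamma_0, G2 = b / gamma_0)
}

#' Fit the TEVP parameters to a rheometric dataset
#'
#' Multi-start bounded nonlinear least squares on the log-parameters
#' (positivity enforced by the transform), minimising [tevp_residuals()]
#' with Levenberg--Marquardt. Starts are drawn log-uniformly inside the
#' bounds; the best converged start is returned. Deterministic given `seed`.
#'
#' @param d a [rheometric_dataset()].
#' @param lower,upper named bounds on the 11 parameters (natural scale).
#' @param n_starts number of random multi-starts (in addition to the
#'   mid-bounds start).
#' @param seed integer seed for the start draws.
#' @param ctrl [integrator_controls()] used inside the objective.
#' @param start optional explicit start (`tevp_parameters` or named vector);
#'   if given it replaces the mid-bounds start.
#' @param fix optional named numeric vector of parameters held fixed at the
#'   given values (removed from the optimisation); useful for the weakly
#'   identified kinetic exponents.
#' @param maxiter Levenberg--Marquardt iteration cap per start.
#' @return list of class `tevp_fit`: `parameters` (a [tevp_parameters()]),
#'   `rms`, per-start summary `starts`, and `jacobian_condition` (condition
#'   number of the finite-difference Jacobian at the optimum, an
#'   identifiability indicator).
#' @export
fit_tevp <- function(d, lower = NULL, upper = NULL, n_starts = 8, seed = 1,
                     ctrl = integrator_controls(rtol = 1e-6),
                     start = NULL, fix = NULL, maxiter = 60) {
  pn <- c("G", "eta0", "tau_y", "eps_ptt", "k1", "k2", "k3",
          "n1", "n2", "n3", "m1")
  fix <- unlist(fix)
  if (!is.null(fix)) stopifnot(all(names(fix) %in% pn))
  free <- setdiff(pn, names(fix))
  def_lower <- c(G = 0.01, eta0 = 1e-3, tau_y = 1e-4, eps_ptt = 1e-5,
                 k1 = 1e-3, k2 = 1e-2, k3 = 1, n1 = 0.5, n2 = 0.5,
                 n3 = 0.5, m1 = 0.1)
  def_upper <- c(G = 10, eta0 = 1, tau_y = 0.1, eps_ptt = 0.1,
                 k1 = 10, k2 = 1e3, k3 = 1e6, n1 = 8, n2 = 8, n3 = 8,
                 m1 = 3)
  lo <- def_lower; up <- def_upper
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) up[names(upper)] <- unlist(upper)
  stopifnot(all(lo > 0), all(up > lo))
  lo <- lo[free]; up <- up[free]
  to_p <- function(th) {
    v <- c(stats::setNames(exp(th), free), fix)
    do.call(tevp_parameters, as.list(v[pn]))
  }
  obj <- function(th) {
    p <- suppressWarnings(to_p(th))
    tevp_residuals(p, d, ctrl)
  }
  set.seed(as.integer(seed))
  starts <- list(log((lo * up)^0.5))
  if (!is.null(start)) {
    sv <- if (inherits(start, "tevp_parameters"))
      unlist(unclass(start)[free]) else unlist(start)[free]
    starts[[1]] <- log(sv)
  }
  for (i in seq_len(n_starts))
    starts[[i + 1L]] <- log(lo) + stats::runif(length(free)) *
      (log(up) - log(lo))
  best <- NULL
  summ <- data.frame(start = integer(), rms = numeric(),
                     converged = logical())
  for (i in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[i]], fn = obj,
                         lower = log(lo), upper = log(up),
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ptol = 1e-10, ftol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) {
      summ <- rbind(summ, data.frame(start = i, rms = NA,
                                     converged = FALSE))
      next
    }
    rms <- sqrt(mean(fit$fvec^2))
    summ <- rbind(summ, data.frame(start = i, rms = rms,
                                   converged = fit$info %in% 1:4))
    if (is.null(best) || rms < best$rms) best <- list(fit = fit, rms = rms)
  }
  if (is.null(best)) stop("all optimisation starts failed")
  p_hat <- suppressWarnings(to_p(best$fit$par))
  Jc <- tryCatch({
    J <- num_jacobian(obj, best$fit$par, best$fit$fvec, eps = 1e-5)
    sv <- svd(J)$d
    max(sv) / max(min(sv), max(sv) * 1e-16, 1e-300)
  }, error = function(e) NA_real_)
  structure(list(parameters = p_hat, rms = best$rms, starts = summ,
                 jacobian_condition = Jc),
            class = "tevp_fit")
}

#' @export
print.tevp_fit <- function(x, ...) {
  cat(sprintf("tevp_fit: residual RMS %.4g over %d start(s); Jacobian condition %.3g\n",
              x$rms, nrow(x$starts), x$jacobian_condition))
  print(x$parameters)
  invisible(x)
}

#' Write / read a rheometric dataset as block-structured CSV
#'
#' Blocks are stored in a single CSV with columns
#' `block, kind, x, y` where steady blocks use `x = rate`, `y = txy` and
#' transient blocks `x = time`, `y = txy`; the transient protocol is stored
#' in a JSON side-car.
#'
#' @param d a [rheometric_dataset()].
#' @param path CSV path (side-car goes to `.json`).
#' @param overwrite allow overwriting.
#' @return invisibly, `path`.
#' @export
write_rheometric_dataset <- function(d, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("refusing to overwrite ", path)
  rows <- data.frame(block = "steady", kind = "steady",
                     x = d$steady$rate, y = d$steady$txy)
  meta <- list(label = d$label, weights = as.list(d$weights),
               transients = list())
  for (i in seq_along(d$transients)) {
    b <- d$transients[[i]]
    nm <- paste0("transient", i)
    rows <- rbind(rows, data.frame(block = nm, kind = "transient",
                                   x = b$data$time, y = b$data$txy))
    meta$transients[[nm]] <- c(list(kind = b$spec$kind,
                                    t_end = b$spec$t_end), b$spec$params)
  }
  utils::write.csv(rows, path, row.names = FALSE)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
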