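# Shared fixtures for the test suite.

# keep the progress reporter from bailing out before every file has run
options(testthat.progress.max_fails = 1000L)

# assert a named vector of computed quantities against reference values,
# each within a (possibly per-component) relative tolerance, as a single
# expectation with a full per-component report
expect_within <- function(computed, expected, tol) {
  computed <- unlist(computed)[names(expected)]
  tol <- rep_len(tol, length(expected))
  rel <- abs(computed - expected) / abs(expected)
  msg <- paste(sprintf("  %s: computed %.6g vs %.6g (rel diff %.1f%%, tol %.0f%%)",
                       names(expected), computed, expected,
                       100 * rel, 100 * tol),
               collapse = "\n")
  testthat::expect(all(rel <= tol),
                   paste0("component(s) outside tolerance:\n", msg))
  invisible(computed)
}

# fitted parameter set for the 45% hematocrit subject used throughout
p47 <- tevp_preset("mcmillan1987_subject")

# degenerate parameter set reducing the model to an upper-convected Maxwell
# fluid: negligible yield stress and structure kinetics, lambda pinned at 1
ucm_params <- function(G = 0.382, eta0 = 0.012) {
  suppressWarnings(tevp_parameters(
    G = G, eta0 = eta0, tau_y = 1e-12, eps_ptt = 0,
    k1 = 1e-12, k2 = 1e-12, k3 = 1e-12,
    n1 = 1, n2 = 2, n3 = 1, m1 = 1))
}

# moderately tight controls for quantitative checks
ctrl_tight <- integrator_controls(rtol = 1e-9, atol = 1e-13)

# loose/fast controls for smoke-level checks
ctrl_fast <- integrator_controls(rtol = 1e-5, atol = 1e-8)

random_sym_tensor <- function() {
  v <- stats::rnorm(6)
  sym_tensor(v[1], v[2], v[3], v[4], v[5], v[6])
}
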