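# shared fixtures: 80 MHz two-photon-style acquisition, harmonic 1
pr80 <- acquisition_params(80e6, 1L)

# period-wrapped monoexponential decay sampled at bin centres; its
# continuous-limit phasor is the closed form 1/(1 - i*omega*tau)
wrapped_decay <- function(tau_ns, params = pr80, n_bins = 1024L,
                          photons = 1e4) {
  tc <- (seq_len(n_bins) - 0.5) * params$period / n_bins
  tau <- tau_ns * 1e-9
  w <- exp(-tc / tau) / (1 - exp(-params$period / tau))
  list(counts = photons * w / sum(w), centers = tc)
}

expect_phasor_equal <- function(p, g, s, tol = 1e-6) {
  expect_equal(p$g, g, tolerance = tol)
  expect_equal(p$s, s, tolerance = tol)
}
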