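# shared fixtures: small device configurations used across test files

default_params <- fn_device()

# a device with gamma small enough that decay is visible within a few pulses
fast_params <- fn_device(k1 = 1e16, k0 = 2.5e16, Wc0 = 8 * log(1e19) / log(2.5e16),
                         dt_pulse = 0.25)  # gamma = 10

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual / expected - 1) < tol),
              label = sprintf("max relative deviation %.3g (tol %.3g)",
                              max(abs(actual / expected - 1)), tol))
}
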