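test_that("device parameter validation enforces the invariants", {
  p <- default_params
  expect_s3_class(p, "fn_device")
  expect_equal(p$CT, p$Cc + p$Cfg)
  expect_equal(p$k0, exp(p$k2 / p$Wc0), tolerance = 1e-9)
  expect_equal(p$gamma, p$k0 / (p$k1 * p$dt_pulse))
  expect_error(fn_device(k1 = -1), "positive")
  expect_error(fn_device(Wc0 = 0), "positive")
})

test_that("gamma presets move only the initial condition", {
  g1 <- fn_device_preset("gamma1")
  g2 <- fn_device_preset("gamma2")
  expect_equal(g1$gamma, 2e3)
  expect_equal(g2$gamma, 8e3)
  expect_equal(g1$k2, g2$k2)
  expect_true(g1$Wc0 > g2$Wc0)  # lower gamma = higher initial potential
})

test_that("tunneling slew has the FN form and its sign matches the closed form", {
  p <- default_params
  # algebraic substitution at w = k2
  expect_equal(tunneling_slew(p$k2, p), p$k1 * p$k2 / exp(1))
  # vanishes at small potentials (barrier dominates)
  expect_lt(tunneling_slew(1e-3, p), 1e-300)
  # strictly increasing
  w <- seq(5, 10, by = 0.25)
  expect_true(all(diff(tunneling_slew(w, p)) > 0))
  expect_error(tunneling_slew(0, p), "> 0")
  # -J(Wc(t)) equals dWc/dt of the closed form (central-difference oracle)
  for (t0 in c(10, 1e3, 1e5)) {
    h <- t0 * 1e-3
    num <- (wc_closed_form(t0 + h, p) - wc_closed_form(t0 - h, p)) / (2 * h)
    expect_equal(-tunneling_slew(wc_closed_form(t0, p), p), num,
                 tolerance = 1e-6)
  }
})

test_that("closed-form common mode starts at Wc0, decreases, and solves the ODE", {
  p <- default_params
  expect_equal(wc_closed_form(0, p), p$Wc0)
  t <- 10^seq(0, 4, by = 0.25)
  expect_true(all(diff(wc_closed_form(t, p)) < 0))
  expect_error(wc_closed_form(-1, p), ">= 0")
  # independent ODE-integrator oracle over four decades of t
  skip_if_not_installed("deSolve")
  sol <- deSolve::ode(y = c(wc = p$Wc0), times = c(0, t),
                      func = function(t, y, parms)
                        list(-tunneling_slew(y, p)),
                      parms = NULL, method = "ode45", rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(sol[-1, "wc"] - wc_closed_form(t, p))), 1e-6)
})

test_that("decay factor alpha lies in (0,1), grows with usage, and has the right limits", {
  p <- default_params
  n <- 1:1e4
  a <- decay_alpha(n, p)
  expect_true(all(a > 0 & a < 1))
  expect_true(all(diff(a) > 0))  # brute-force monotonicity
  expect_error(decay_alpha(0, p), ">= 1")
  # dt -> 0 makes gamma huge and alpha -> 1
  p_small_dt <- fn_device(dt_pulse = 1e-12)
  expect_true(all(decay_alpha(c(1, 10, 100), p_small_dt) > 1 - 1e-8))
  # n >> gamma: (1 - alpha(n)) * n -> 1 + 2/log(k1 dt n + k0) which is near 1
  n_big <- 1e7
  expect_equal((1 - decay_alpha(n_big, p)) * (n_big + p$gamma),
               1 + 2 / log(p$k1 * p$dt_pulse * n_big + p$k0),
               tolerance = 1e-9)
  expect_lt(abs((1 - decay_alpha(n_big, p)) * n_big - 1), 0.05)
})

test_that("pulse recursion matches the unrolled closed sum to 1e-12 V", {
  p <- default_params
  n <- 500
  set.seed(42)
  x <- sample(c(-1, 1), n, replace = TRUE) * 3e-4
  s <- fn_state(p)
  wd <- numeric(n)
  for (i in seq_len(n)) {
    s <- apply_pulse(s, x[i], 0, p)
    wd[i] <- fn_wd(s)
  }
  expect_equal(s$n_updates, n)
  # brute-force unrolling oracle with vin levels as cumulative input steps
  a <- decay_alpha(seq_len(n), p)
  vin <- cumsum(x)
  unrolled <- 0
  for (i in seq_len(n - 2))
    unrolled <- unrolled + (a[i + 1] - 1) * prod(a[(i + 2):n]) * vin[i]
  unrolled <- unrolled + (a[n] - 1) * vin[n - 1] + vin[n]
  expect_lt(abs(wd[n] - unrolled), 1e-12)
})

test_that("pure-decay pulses keep the weight at zero while the usage drops", {
  p <- default_params
  s <- fn_state(p)
  wc_trace <- numeric(50)
  for (i in 1:50) {
    s <- apply_pulse(s, 0, 0, p)
    wc_trace[i] <- fn_wc(s)
    expect_identical(fn_wd(s), 0)
  }
  expect_true(all(diff(c(p$Wc0, wc_trace)) < 0))
})

test_that("usage monotonicity holds for either input polarity", {
  p <- default_params
  for (x in c(-2e-4, 2e-4)) {
    s <- fn_state(p)
    wc_prev <- fn_wc(s)
    for (i in 1:25) {
      s <- apply_pulse(s, x, 0, p)
      expect_lt(fn_wc(s), wc_prev)
      wc_prev <- fn_wc(s)
    }
  }
})

test_that("successive identical pulses realize strictly shrinking weight updates", {
  # metaplasticity through the physical pulse response: constant-magnitude,
  # constant-width potentiation pulses
  p <- fn_device_preset("characterize")
  s <- fn_state(p)
  dwd <- numeric(100)
  prev <- fn_wd(s)
  for (i in 1:100) {
    s <- apply_timed_pulse(s, width = 0.1, magnitude = 4, params = p)
    dwd[i] <- fn_wd(s) - prev
    prev <- fn_wd(s)
  }
  expect_true(all(dwd > 0))
  expect_true(all(diff(abs(dwd)) < 0))
  # the same holds for the abstract recursion with held coupling
  s <- fn_state(p)
  dwd2 <- numeric(100)
  prev <- 0
  for (i in 1:100) {
    s <- apply_pulse(s, 3e-4, 0, p)
    dwd2[i] <- fn_wd(s) - prev
    prev <- fn_wd(s)
  }
  expect_true(all(diff(abs(dwd2)) < 0))
})

test_that("decay-rate diagnostic recovers known analytic rates", {
  # exponential trajectory: r(t) = a exactly
  a <- 0.37
  t <- seq(1, 5, length.out = 41)
  r <- decay_rate_r(t, exp(-a * t))
  expect_rel_equal(r$r, a, 1e-3)
  # FN closed form: t * r(t) -> 1 at large t
  p <- default_params
  t <- 10^seq(2, 6, length.out = 1601)
  r <- decay_rate_r(t, wc_closed_form(t, p))
  tr <- r$t * r$r
  expect_true(all(abs(tr[r$t >= 100 * p$k0 / p$k1] - 1) < 0.05))
  # beta/log(t) trajectory matches the f(x) = x/beta closed form
  # r(t) = (1/t) (1 + 2/log t)
  beta <- 20
  t <- 10^seq(1, 4, length.out = 1201)
  r <- decay_rate_r(t, beta / log(t))
  expect_rel_equal(r$r, (1 + 2 / log(r$t)) / r$t, 1e-4)
  # error handling
  expect_error(decay_rate_r(1:4, exp(-(1:4))), "5 samples")
  expect_warning(decay_rate_r(1:6, c(3, 1, 2, 1.5, 1, 0.5)), "monotone")
})

test_that("optimal flow is the FN form and reproduces the 1/log usage shape", {
  expect_equal(optimal_flow(1, 1), exp(-1))
  p <- default_params
  w <- seq(4, 9, by = 0.5)
  p_unit <- fn_device(k1 = 1, k0 = exp(p$k2 / 8), Wc0 = 8)
  expect_equal(optimal_flow(w, p_unit$k2), tunneling_slew(w, p_unit))
  expect_error(optimal_flow(-1, 1), "> 0")
  # integrate dWc/dt = -optimal_flow and fit Wc = beta/log(t + c):
  # the recovered beta matches the input within 1%
  skip_if_not_installed("deSolve")
  beta <- 40
  wc0 <- 4
  times <- c(0, 10^seq(0, 5, length.out = 60))
  sol <- deSolve::ode(y = c(wc = wc0), times = times,
                      func = function(t, y, parms)
                        list(-optimal_flow(y, beta)),
                      parms = NULL, method = "ode45", rtol = 1e-10, atol = 1e-12)
  wc <- sol[-1, "wc"]; tt <- times[-1]
  c0 <- exp(beta / wc0)  # implied time offset of the closed form
  fit <- stats::lm(I(1 / wc) ~ I(log(tt + c0)) - 1)
  beta_hat <- 1 / stats::coef(fit)[[1]]
  expect_lt(abs(beta_hat / beta - 1), 0.01)
})

test_that("write energy follows the half-C-V-squared law", {
  expect_equal(write_energy(200e-15, 2), 400e-15)
  expect_equal(write_energy(200e-15, 0), 0)
  # differential 4 V pulse: +/- 2 V on two 200 fF coupling capacitors
  expect_equal(2 * write_energy(200e-15, 4 / 2), 800e-15)
  expect_error(write_energy(-1e-15, 1), "> 0")
})

test_that("state dump/restore round-trips at full precision", {
  p <- default_params
  s <- fn_state(p)
  for (i in 1:7) s <- apply_pulse(s, 1.23456789e-4, 0, p)
  path <- tempfile(fileext = ".json")
  state_dump(s, path)
  s2 <- state_restore(path)
  expect_equal(s2$w_plus, s$w_plus, tolerance = 1e-15)
  expect_equal(s2$w_minus, s$w_minus, tolerance = 1e-15)
  expect_identical(s2$n_updates, s$n_updates)
})
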