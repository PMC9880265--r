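test_that("electron rates are the deterministic drop in electron units", {
  p <- default_params
  s <- fn_state(p)
  lam <- expected_electrons(s, p)
  det_drop <- p$Wc0 - wc_closed_form(p$dt_pulse, p)
  expect_equal(lam$lambda_plus * p$q / p$CT, det_drop, tolerance = 1e-12)
  expect_equal(lam$lambda_minus, lam$lambda_plus)
  # arithmetic anchor: CT = 1.6 pF and a 1 mV drop give about 1e4 electrons
  expect_equal(1.6e-12 * 1e-3 / 1.602176634e-19, 1e4, tolerance = 2e-3)
  # rates vanish once the potentials are below the tunneling regime
  s_off <- fn_state(w_plus = 4, w_minus = 4)
  lam_off <- expected_electrons(s_off, p)
  expect_lt(lam_off$lambda_plus, 1e-6)
})

test_that("a zero-electron step only applies the capacitive coupling", {
  p <- default_params
  s_off <- fn_state(w_plus = 4, w_minus = 4)  # lambda ~ 0: e = 0 a.s.
  set.seed(1)
  out <- stochastic_step(s_off, 2e-4, p)
  expect_identical(out$record$e_plus, 0L)
  expect_identical(out$record$e_minus, 0L)
  expect_equal(out$state$w_plus, 4 + 2e-4)
  expect_equal(out$state$w_minus, 4 - 2e-4)
  expect_equal(fn_wd(out$state), 2e-4)
})

test_that("one electron moves the node by about 100 nV", {
  p <- default_params
  dv <- p$q / p$CT
  expect_equal(dv, 1.0014e-7, tolerance = 1e-4)
  expect_gt(dv, 0.95e-7); expect_lt(dv, 1.05e-7)
})

test_that("the ensemble-mean stochastic update matches the deterministic drop", {
  p <- default_params
  n_rep <- 1e4  # identical synapses, one pulse each
  s <- fn_state(w_plus = rep(p$Wc0, n_rep), w_minus = rep(p$Wc0, n_rep))
  set.seed(11)
  out <- stochastic_step(s, 0, p)
  drop_mean <- mean(p$Wc0 - out$state$w_plus)
  lam <- expected_electrons(fn_state(p), p)$lambda_plus
  det_drop <- lam * p$q / p$CT
  se <- sqrt(lam / n_rep) * p$q / p$CT
  expect_lt(abs(drop_mean - det_drop), 3 * se)
})

test_that("ensemble means converge to the deterministic model as 1/sqrt(runs)", {
  p <- default_params
  lam <- expected_electrons(fn_state(p), p)$lambda_plus
  set.seed(5)
  sd_of_mean <- vapply(c(100, 10000), function(R) {
    devs <- replicate(40, {
      e <- stats::rpois(R, lam)
      (mean(e) - lam) * p$q / p$CT
    })
    stats::sd(devs)
  }, numeric(1))
  ratio <- sd_of_mean[1] / sd_of_mean[2]  # expect about sqrt(100) = 10
  expect_gt(ratio, 5)
  expect_lt(ratio, 20)
})

test_that("identical seeds reproduce identical electron-count sequences", {
  p <- default_params
  tr1 <- run_stochastic(30, 2e-4, p, seed = 99)
  tr2 <- run_stochastic(30, 2e-4, p, seed = 99)
  expect_identical(tr1, tr2)
  tr3 <- run_stochastic(30, 2e-4, p, seed = 100)
  expect_false(identical(tr1$e_plus, tr3$e_plus))
})

test_that("charge bookkeeping is exact", {
  p <- default_params
  set.seed(21)
  s <- fn_state(p)
  x <- sample(c(-1, 1), 50, replace = TRUE) * 2e-4
  e_tot_plus <- 0
  coupled_plus <- 0
  for (i in 1:50) {
    out <- stochastic_step(s, x[i], p)
    e_tot_plus <- e_tot_plus + out$record$e_plus
    coupled_plus <- coupled_plus + x[i]
    s <- out$state
  }
  # total tunneled charge = CT * (initial - final + coupled contribution)
  expect_equal(p$q * e_tot_plus,
               p$CT * (p$Wc0 - s$w_plus + coupled_plus),
               tolerance = 1e-9)
})

test_that("high-regime trajectories track the deterministic model within 200 uV", {
  p <- default_params
  cmp <- compare_to_deterministic(n_pulses = 60, params = p, seeds = 1:5)
  expect_lt(cmp$max_dev, 200e-6)
})

test_that("scaling up the capacitance removes the stochastic deviation", {
  # Poisson concentration: larger CT means more, smaller electrons
  p_big <- fn_device(Cfg = 1.4e-9, Cc = 200e-12)
  p <- default_params
  set.seed(2)
  cmp_small <- compare_to_deterministic(40, p, seeds = 1:3)
  cmp_big <- compare_to_deterministic(40, p_big, seeds = 1:3)
  expect_lt(cmp_big$max_dev, cmp_small$max_dev / 5)
})

test_that("the low-tunneling regime keeps the SNR power law but shifts it down", {
  p_low <- fn_device_preset("stochastic_low")
  lam <- expected_electrons(fn_state(p_low), p_low)$lambda_plus
  expect_gt(lam, 2); expect_lt(lam, 30)  # a handful of electrons per pulse
  # a small pattern amplitude puts the imprints in the few-electron regime
  # where the tunneling shot noise is visible next to the interference noise
  res <- snr_experiment(N = 50, n_patterns = 60, n_mc = 150,
                        params = p_low, engine = "stochastic",
                        pulse_amplitude = 0.03, seed = 4)
  sub <- res[res$n >= 5 & res$n <= 50, ]
  fit <- stats::lm(log(snr_mc) ~ log(n), data = sub)
  expect_lt(abs(stats::coef(fit)[["log(n)"]] + 0.5), 0.2)
  # shifted down relative to the noiseless analytic law
  expect_lt(mean(sub$snr_mc / sub$snr_analytic), 0.95)
})
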