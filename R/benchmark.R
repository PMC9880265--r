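#' Random binary pattern ensemble
#'
#' Generates the N x n matrix of +/-1 memory patterns used by the
#' consolidation benchmark: column p is the p-th pattern presented to the
#' N-synapse network, entries are i.i.d. uniform on {-1, +1} (or, with
#' \code{balanced = TRUE}, each synapse receives exactly n/2 potentiation
#' and n/2 depression pulses in random order).
#'
#' @param N number of synapses.
#' @param n number of patterns.
#' @param seed optional RNG seed; with \code{NULL} the current RNG stream
#'   is used.
#' @param balanced balance potentiation/depression per synapse (requires
#'   even \code{n}).
#' @param pulse_amplitude voltage amplitude mapping +/-1 to +/-x (V).
#'   During a presentation the input couples the full amplitude onto the
#'   synapse; the lasting imprint after the input is withdrawn is the
#'   amplitude divided by the effective age n + gamma.  The default
#'   realizes a first-imprint weight change of about 300 uV under the
#'   default device, a comfortably detectable update.
#' @return an object of class \code{fn_patterns}: list with \code{values}
#'   (N x n matrix), \code{pulse_amplitude}, \code{seed}, \code{balanced}.
#' @export
generate_patterns <- function(N, n, seed = NULL, balanced = FALSE,
                              pulse_amplitude = 1.2) {
  stopifnot(N >= 1, n >= 1)
  if (balanced && n %% 2 != 0)
    stop("generate_patterns: balanced ensembles need an even pattern count")
  if (!is.null(seed)) set.seed(seed)
  values <- if (balanced) {
    t(vapply(seq_len(N),
             function(i) sample(rep(c(-1, 1), n / 2)),
             numeric(n)))
  } else {
    matrix(sample(c(-1, 1), N * n, replace = TRUE), nrow = N)
  }
  structure(list(values = values, pulse_amplitude = pulse_amplitude,
                 seed = seed, balanced = balanced),
            class = "fn_patterns")
}

#' Imprint a pattern ensemble on a synapse network
#'
#' Presents the patterns column by column to an initially empty network.
#' Each presentation is one full pulse cycle per synapse: the input
#' \code{vin(a, p) = amplitude * pattern(a, p)} couples onto the synapse,
#' the device tunnels for one pulse width (the weight, including the
#' coupled input, decays by the usage factor alpha), and the input is
#' withdrawn before the weight is read.  The lasting imprint of pattern p
#' is therefore \code{(alpha - 1) * vin(a, p)} plus the decayed previous
#' memory,
#' \deqn{Wd(p) = \alpha(p)\,Wd(p-1) + (\alpha(p) - 1)\,v_{in}(p),}
#' whose unrolled coefficients are the analytic retrieval-signal product
#' form.  With a modulation profile, the global common-mode increment of
#' each update is computed from the network-wide mean absolute weight
#' change via [compute_increment()].
#'
#' @param ensemble an \code{fn_patterns}.
#' @param params an \code{fn_device}.
#' @param profile optional \code{fn_modulation}.
#' @param engine \code{"deterministic"} for the behavioral recursion or
#'   \code{"stochastic"} for the Poisson single-electron model.
#' @param wc_ceiling safety ceiling for modulation restores (V).
#' @return an object of class \code{fn_consolidation}: list with
#'   \code{wd_hist} (N x n matrix of weights after each pattern),
#'   \code{wc_hist} (common mode after each pattern; network mean for the
#'   stochastic engine), \code{increments} (modulation increments applied),
#'   plus the ensemble and parameters.
#' @export
run_consolidation <- function(ensemble, params, profile = NULL,
                              engine = c("deterministic", "stochastic"),
                              wc_ceiling = 9) {
  stopifnot(inherits(ensemble, "fn_patterns"))
  engine <- match.arg(engine)
  P <- ensemble$values
  N <- nrow(P); n <- ncol(P)
  vin <- ensemble$pulse_amplitude * P
  wd_hist <- matrix(0, N, n)
  wc_hist <- numeric(n)
  increments <- numeric(n)
  if (engine == "deterministic") {
    wd <- numeric(N)
    wc <- params$Wc0
    for (j in seq_len(n)) {
      wc <- wc_advance(wc, params$dt_pulse, params)
      a <- alpha_from_wc(wc, params$dt_pulse, params)
      # couple, decay during the pulse, withdraw the input
      wd_new <- a * (wd + vin[, j]) - vin[, j]
      if (!is.null(profile)) {
        inc <- compute_increment(profile, mean(abs(wd_new - wd)), j)
        increments[j] <- inc
        wc <- min(wc + inc, wc_ceiling)
      }
      wd <- wd_new
      wd_hist[, j] <- wd
      wc_hist[j] <- wc
    }
  } else {
    state <- fn_state(w_plus = rep(params$Wc0, N),
                      w_minus = rep(params$Wc0, N))
    for (j in seq_len(n)) {
      wd_old <- fn_wd(state)
      state <- stochastic_step(state, vin[, j], params)$state
      # withdraw the coupled input before readout
      state <- fn_state(w_plus = state$w_plus - vin[, j],
                        w_minus = state$w_minus + vin[, j],
                        n_updates = state$n_updates)
      if (!is.null(profile)) {
        inc <- compute_increment(profile,
                                 mean(abs(fn_wd(state) - wd_old)), j)
        increments[j] <- inc
        wc <- fn_wc(state)
        bump <- pmin(wc + inc, wc_ceiling) - wc
        state <- fn_state(w_plus = state$w_plus + bump,
                          w_minus = state$w_minus + bump,
                          n_updates = state$n_updates)
      }
      wd_hist[, j] <- fn_wd(state)
      wc_hist[j] <- mean(fn_wc(state))
    }
  }
  structure(list(wd_hist = wd_hist, wc_hist = wc_hist,
                 increments = increments, ensemble = ensemble,
                 params = params, engine = engine,
                 profile = if (!is.null(profile)) profile$label else "none"),
            class = "fn_consolidation")
}

#' Retrieval signal of one pattern
#'
#' Overlap between the stored weights and one imprinted pattern:
#' \code{(1/N) sum_a Wd(a) * vin(a, p)} with
#' \code{vin = pulse_amplitude * pattern}.  Ensemble averaging over pattern
#' realizations is done by the Monte-Carlo driver [snr_experiment()].
#'
#' @param weights weight vector (V), length N.
#' @param pattern +/-1 pattern vector, length N.
#' @param pulse_amplitude voltage amplitude of the pattern encoding.
#' @return the (dimensioned, V^2-scaled) retrieval signal.
#' @export
retrieval_signal <- function(weights, pattern, pulse_amplitude = 1) {
  if (length(weights) != length(pattern))
    stop("retrieval_signal: weights and pattern lengths differ")
  mean(weights * (pulse_amplitude * pattern))
}

#' Analytic retrieval signal
#'
#' Exact product form and simplified power-law form of the mean retrieval
#' signal of pattern p tracked after n patterns (unit pattern amplitude):
#' the exact value is \code{(alpha(p+1) - 1) * prod_{j=p+2..n} alpha(j)}
#' (extended by the empty-product convention at p = n-1 and p = n, where
#' the closed sum has special trailing terms; the magnitude is reported),
#' and the simplified magnitude is \code{1/(n + gamma)}, valid because
#' \code{1 + 2/log(k1 dt n + k0)} is close to 1 for the default constants.
#'
#' @param n number of patterns observed; scalar or vector (all >= p).
#' @param p index of the tracked pattern, \code{1 <= p <= min(n)}.
#' @param params an \code{fn_device}.
#' @return data.frame with columns \code{n}, \code{exact} (signed),
#'   \code{simplified} (magnitude \code{1/(n+gamma)}).
#' @export
analytic_signal <- function(n, p = 1, params) {
  if (any(p > n)) stop("analytic_signal: p must not exceed n")
  stopifnot(p >= 1)
  n_max <- max(n)
  a <- decay_alpha(seq_len(n_max + 1), params)
  # cumulative products of alpha(p+2 .. m) for m = p+1 .. n_max
  lead <- a[p + 1] - 1
  exact_all <- numeric(n_max)
  exact_all[p] <- lead  # empty-product convention at n = p
  if (n_max > p) {
    idx <- (p + 1):n_max
    cp <- c(1, cumprod(a[setdiff(idx, p + 1) ]))
    # cp[k] = prod alpha(p+2 .. p+k) with cp[1] = 1
    exact_all[idx] <- lead * cp
  }
  data.frame(n = n, exact = exact_all[n],
             simplified = 1 / (n + params$gamma))
}

#' Analytic noise of the retrieval signal
#'
#' Standard deviation of the retrieval signal across pattern realizations
#' (unit amplitude): \code{nu = sqrt(n/N) / (n + gamma)}.  Rises as
#' \code{sqrt(n)/(sqrt(N) gamma)} while \code{n << gamma} and falls as
#' \code{1/sqrt(N n)} once \code{n >> gamma}.  The tracked pattern's own
#' term is included (a slight overestimate that keeps the form tractable).
#'
#' @param n number of patterns observed; vectorized.
#' @param N network size.
#' @param params an \code{fn_device}.
#' @return noise standard deviation (unit amplitude scale).
#' @export
analytic_noise <- function(n, N, params) {
  stopifnot(all(n >= 1), N >= 1)
  sqrt(n / N) / (n + params$gamma)
}

#' Analytic signal-to-noise ratio
#'
#' \code{SNR(n) = sqrt(N/n)}: independent of gamma and of which pattern is
#' tracked.  The initial SNR is sqrt(N) and the memory lifetime (SNR
#' crossing 1) is n = N, so capacity scales linearly with network size.
#'
#' @param n number of patterns observed; vectorized.
#' @param N network size.
#' @return the SNR.
#' @export
analytic_snr <- function(n, N) {
  stopifnot(all(n >= 1), N >= 1)
  sqrt(N / n)
}

#' Count of patterns retained above an SNR threshold
#'
#' @param snr_by_pattern matrix of SNR values, observation times in rows
#'   and patterns in columns; entries for patterns not yet presented should
#'   be NA.
#' @param threshold retention threshold (default 1).
#' @return integer vector: per observation time, the number of patterns
#'   whose SNR exceeds the threshold.
#' @export
patterns_retained <- function(snr_by_pattern, threshold = 1) {
  stopifnot(threshold > 0)
  m <- as.matrix(snr_by_pattern)
  as.integer(rowSums(m > threshold, na.rm = TRUE))
}

#' Monte-Carlo memory consolidation experiment
#'
#' Repeats the random-pattern imprinting experiment over many pattern
#' realizations and tracks the retrieval signal of one pattern: the
#' empirical signal is the Monte-Carlo mean of [retrieval_signal()], the
#' empirical noise its standard deviation, and the empirical SNR their
#' ratio.  Results are reported on the unit-amplitude scale (normalized by
#' the squared pulse amplitude) so they are directly comparable with
#' [analytic_signal()], [analytic_noise()] and [analytic_snr()].
#'
#' @param N network size.
#' @param n_patterns patterns per run.
#' @param n_mc Monte-Carlo runs.  1000 gives close agreement with the
#'   analytic curves; 25/15 mimic small hardware-style runs.
#' @param params an \code{fn_device}.
#' @param tracked_pattern index p of the pattern whose memory is tracked
#'   (the first by default).
#' @param profile optional \code{fn_modulation} applied during imprinting.
#' @param balanced balanced potentiation/depression per synapse.
#' @param engine consolidation engine, see [run_consolidation()].
#' @param pulse_amplitude pattern pulse amplitude (V).
#' @param seed RNG seed for the whole experiment.
#' @return object of class \code{fn_snr}: a data.frame with one row per
#'   n >= p holding \code{S_mc, nu_mc, snr_mc, se_snr} and the analytic
#'   \code{S_exact, S_simplified, nu_analytic, snr_analytic}, with the
#'   experiment settings in attributes.
#' @export
snr_experiment <- function(N = 100, n_patterns = 100, n_mc = 1000,
                           params = fn_device(), tracked_pattern = 1,
                           profile = NULL, balanced = FALSE,
                           engine = "deterministic",
                           pulse_amplitude = 1.2, seed = 1) {
  set.seed(seed)
  p <- tracked_pattern
  amp <- pulse_amplitude
  sig <- matrix(0, n_mc, n_patterns)
  for (r in seq_len(n_mc)) {
    ens <- generate_patterns(N, n_patterns, seed = NULL,
                             balanced = balanced, pulse_amplitude = amp)
    if (!is.null(profile)) reset_increments_log(profile)
    sim <- run_consolidation(ens, params, profile = profile, engine = engine)
    # unit-amplitude retrieval signal of pattern p after each n
    sig[r, ] <- crossprod(sim$wd_hist, ens$values[, p])[, 1] / (N * amp)
  }
  S <- colMeans(sig)
  nu <- apply(sig, 2, stats::sd)
  snr <- abs(S) / nu
  # delta-method standard error of the SNR estimate
  se <- snr * sqrt(1 / (n_mc * snr^2) + 1 / (2 * (n_mc - 1)))
  nn <- seq_len(n_patterns)
  keep <- nn >= p
  ana <- analytic_signal(nn[keep], p, params)
  out <- data.frame(n = nn[keep], S_mc = S[keep], nu_mc = nu[keep],
                    snr_mc = snr[keep], se_snr = se[keep],
                    S_exact = ana$exact, S_simplified = ana$simplified,
                    nu_analytic = analytic_noise(nn[keep], N, params),
                    snr_analytic = analytic_snr(nn[keep], N))
  structure(out, class = c("fn_snr", "data.frame"),
            N = N, n_mc = n_mc, gamma = params$gamma,
            tracked_pattern = p, engine = engine,
            profile = if (is.null(profile)) "none" else profile$label,
            seed = seed)
}

#' @export
print.fn_snr <- function(x, ...) {
  cat(sprintf(
    "Memory SNR experiment: N = %d synapses, %d Monte-Carlo runs, gamma = %.4g\n",
    attr(x, "N"), attr(x, "n_mc"), attr(x, "gamma")))
  cat(sprintf("  tracked pattern p = %d, engine = %s, modulation = %s\n",
              attr(x, "tracked_pattern"), attr(x, "engine"),
              attr(x, "profile")))
  show <- x[x$n %in% unique(round(exp(seq(log(min(x$n)), log(max(x$n)),
                                          length.out = 8)))), ]
  print.data.frame(format(show, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
plot.fn_snr <- function(x, ...) {
  graphics::plot(x$n, x$snr_mc, log = "xy", type = "b", pch = 20,
                 xlab = "patterns observed n", ylab = "SNR",
                 main = sprintf("Memory SNR (N = %d)", attr(x, "N")), ...)
  graphics::lines(x$n, x$snr_analytic, col = 2, lwd = 2)
  graphics::abline(h = 1, lty = 3)
  graphics::legend("topright", c("Monte-Carlo", "sqrt(N/n)"),
                   col = c(1, 2), lty = 1, bty = "n")
  invisible(x)
}

#' Memory lifetime versus network size
#'
#' For each network size, runs the Monte-Carlo consolidation experiment and
#' finds the number of patterns at which the empirical SNR of the tracked
#' (first) pattern first drops below the retention threshold and stays
#' below it for a few consecutive observations.  Under the analytic
#' power law the lifetime equals N.
#'
#' @param N_values network sizes to probe.
#' @param n_mc Monte-Carlo runs per size.
#' @param params an \code{fn_device}.
#' @param threshold retention threshold.
#' @param horizon_factor patterns simulated per run, as a multiple of N.
#' @param confirm number of consecutive sub-threshold observations required.
#' @param seed RNG seed.
#' @param ... further arguments for [snr_experiment()].
#' @return data.frame with columns \code{N}, \code{lifetime} and
#'   \code{ratio} (= lifetime / N).
#' @export
memory_lifetime <- function(N_values = c(50, 100, 200, 400), n_mc = 400,
                            params = fn_device(), threshold = 1,
                            horizon_factor = 1.6, confirm = 3, seed = 1,
                            ...) {
  rows <- lapply(seq_along(N_values), function(i) {
    N <- N_values[i]
    res <- snr_experiment(N = N, n_patterns = ceiling(horizon_factor * N),
                          n_mc = n_mc, params = params,
                          seed = seed + i, ...)
    below <- res$snr_mc < threshold & res$n >= 5
    runs <- rle(below)
    ends <- cumsum(runs$lengths)
    k <- which(runs$values & runs$lengths >= confirm)
    lifetime <- if (length(k) == 0) NA_real_
                else res$n[ends[k[1]] - runs$lengths[k[1]] + 1]
    data.frame(N = N, lifetime = lifetime, ratio = lifetime / N)
  })
  do.call(rbind, rows)
}

#' Patterns-retained experiment under plasticity modulation
#'
#' Imprints a long pattern stream on a large network under a modulation
#' profile and counts, at regular observation times, how many of the
#' patterns seen so far still have SNR above the threshold.  Without
#' modulation (m0) the count rises and then collapses to zero once the
#' network reaches capacity (blackout); with proportional restore profiles
#' (m1, m2) it settles at a positive steady state (graceful forgetting);
#' the periodic m4 profile oscillates with its switch period.
#'
#' @param profile an \code{fn_modulation} (or a shorthand name like "m1").
#' @param N network size.
#' @param n_patterns patterns presented.
#' @param n_mc Monte-Carlo runs (small counts suffice for the qualitative
#'   retained-count curves).
#' @param observe_every spacing of observation times (in patterns).
#' @param threshold retention threshold.
#' @param pooled_noise estimate the noise by pooling the ensemble variance
#'   across patterns at each observation time (the interference noise is
#'   stationary across patterns at a fixed time), which sharpens the
#'   retained-count estimate at small Monte-Carlo budgets; with
#'   \code{FALSE} each (time, pattern) cell uses its own variance.
#' @param params an \code{fn_device}.
#' @param pulse_amplitude pattern pulse amplitude (V).
#' @param seed RNG seed.
#' @return object of class \code{fn_retention}: list with \code{retained}
#'   (data.frame t, retained), \code{snr} (observation x pattern matrix),
#'   \code{nu} (observation x pattern noise matrix), \code{wc_hist} (last
#'   run's common-mode trajectory) and the settings.
#' @export
retention_experiment <- function(profile, N = 1000, n_patterns = 2000,
                                 n_mc = 25, observe_every = 25,
                                 threshold = 1, pooled_noise = FALSE,
                                 params = fn_device(),
                                 pulse_amplitude = 1.2, seed = 1) {
  if (is.character(profile)) profile <- modulation_profile(profile)
  set.seed(seed)
  amp <- pulse_amplitude
  t_obs <- seq(observe_every, n_patterns, by = observe_every)
  acc <- matrix(0, length(t_obs), n_patterns)   # running sum of signals
  acc2 <- matrix(0, length(t_obs), n_patterns)  # running sum of squares
  wc_hist <- NULL
  for (r in seq_len(n_mc)) {
    ens <- generate_patterns(N, n_patterns, seed = NULL,
                             pulse_amplitude = amp)
    reset_increments_log(profile)
    sim <- run_consolidation(ens, params, profile = profile)
    # observations x patterns matrix of unit-amplitude retrieval signals
    s <- crossprod(sim$wd_hist[, t_obs, drop = FALSE],
                   ens$values) / (N * amp)
    acc <- acc + s
    acc2 <- acc2 + s^2
    wc_hist <- sim$wc_hist
  }
  S <- acc / n_mc
  nu <- sqrt(pmax(0, (acc2 - n_mc * S^2) / (n_mc - 1)))
  dim(nu) <- dim(S)
  # patterns not yet presented at an observation time do not count
  not_seen <- outer(t_obs, seq_len(n_patterns), `<`)
  if (pooled_noise) {
    v <- nu^2
    v[not_seen] <- NA_real_
    nu <- matrix(sqrt(rowMeans(v, na.rm = TRUE)),
                 nrow(nu), ncol(nu))
  }
  snr <- abs(S) / nu
  snr[not_seen] <- NA_real_
  structure(list(retained = data.frame(t = t_obs,
                                       retained = patterns_retained(snr,
                                                                    threshold)),
                 snr = snr, nu = nu, t_obs = t_obs, wc_hist = wc_hist,
                 profile = profile$label, N = N, n_mc = n_mc,
                 threshold = threshold, seed = seed),
            class = "fn_retention")
}

#' @export
print.fn_retention <- function(x, ...) {
  cat(sprintf(
    "Retained-patterns experiment: N = %d, %d patterns, profile %s (%d MC runs)\n",
    x$N, max(x$retained$t), x$profile, x$n_mc))
  cat(sprintf("  final retained count: %d (threshold SNR > %g)\n",
              x$retained$retained[nrow(x$retained)], x$threshold))
  invisible(x)
}

#' @export
plot.fn_retention <- function(x, ...) {
  graphics::plot(x$retained$t, x$retained$retained, type = "l",
                 xlab = "patterns observed", ylab = "# patterns retained",
                 main = sprintf("Profile %s (N = %d)", x$profile, x$N), ...)
  invisible(x)
}
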