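#' Expected electron counts for one pulse
#'
#' In the low-tunneling regime weight updates are carried by countably few
#' electrons.  The expected number of electrons crossing each junction
#' during one pulse is derived from the deterministic voltage drop of that
#' junction over one pulse width: \code{lambda = CT * |dW_det| / q}.  This
#' is the voltage-domain equivalent of an area-times-current-density rate
#' and makes the stochastic model consistent with the deterministic one by
#' construction: \code{lambda * q / CT} equals the deterministic drop
#' exactly.
#'
#' @param state an \code{fn_state} (scalar or vector of synapses).
#' @param params an \code{fn_device}.
#' @param dt pulse width (s); defaults to the device pulse width.
#' @return a list with components \code{lambda_plus} and
#'   \code{lambda_minus} (expected electron counts, one per synapse).
#' @export
expected_electrons <- function(state, params, dt = params$dt_pulse) {
  stopifnot(inherits(state, "fn_state"))
  d_plus <- pmax(0, state$w_plus - wc_advance(state$w_plus, dt, params))
  d_minus <- pmax(0, state$w_minus - wc_advance(state$w_minus, dt, params))
  list(lambda_plus = params$CT * d_plus / params$q,
       lambda_minus = params$CT * d_minus / params$q)
}

#' One stochastic (single-electron) pulse update
#'
#' The differential input couples capacitively onto the two junctions, the
#' electron counts for the pulse are drawn from Poisson distributions with
#' the rates of [expected_electrons()] evaluated at the coupled potentials,
#' and each junction potential drops by \code{q/CT} per electron.
#' Randomness comes from the R session RNG; seed it with
#' \code{set.seed()} for reproducibility.
#'
#' @param state an \code{fn_state} (scalar or vector of synapses).
#' @param x_pulse signed differential input step (V): \code{W+} is raised
#'   by \code{x_pulse} and \code{W-} lowered by it, so the coupled weight
#'   change is \code{x_pulse}.
#' @param params an \code{fn_device}.
#' @return a list with the new \code{state} and a \code{record}
#'   data.frame holding \code{lambda_plus, lambda_minus, e_plus, e_minus,
#'   dW_plus, dW_minus} for the step.
#' @export
stochastic_step <- function(state, x_pulse, params) {
  stopifnot(inherits(state, "fn_state"))
  wp <- state$w_plus + x_pulse
  wm <- state$w_minus - x_pulse
  coupled <- fn_state(w_plus = wp, w_minus = wm,
                      n_updates = state$n_updates)
  lam <- expected_electrons(coupled, params)
  e_plus <- stats::rpois(length(wp), lam$lambda_plus)
  e_minus <- stats::rpois(length(wm), lam$lambda_minus)
  dWp <- -params$q * e_plus / params$CT
  dWm <- -params$q * e_minus / params$CT
  new_state <- fn_state(w_plus = wp + dWp, w_minus = wm + dWm,
                        n_updates = state$n_updates + 1L)
  list(state = new_state,
       record = data.frame(lambda_plus = lam$lambda_plus,
                           lambda_minus = lam$lambda_minus,
                           e_plus = e_plus, e_minus = e_minus,
                           dW_plus = dWp, dW_minus = dWm))
}

#' Run a stochastic pulse train on one synapse
#'
#' @param n_pulses number of pulses.
#' @param x_pulses signed differential input steps (V); recycled to
#'   \code{n_pulses}.
#' @param params an \code{fn_device}.
#' @param state initial state; empty state at \code{Wc0} by default.
#' @param seed optional RNG seed.
#' @return a data.frame trace with one row per pulse:
#'   \code{pulse_index, lambda_plus, e_plus, lambda_minus, e_minus, Wd, Wc}.
#' @export
run_stochastic <- function(n_pulses, x_pulses, params,
                           state = fn_state(params), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rep_len(x_pulses, n_pulses)
  out <- vector("list", n_pulses)
  for (i in seq_len(n_pulses)) {
    step <- stochastic_step(state, x[i], params)
    state <- step$state
    out[[i]] <- cbind(pulse_index = i,
                      step$record[, c("lambda_plus", "e_plus",
                                      "lambda_minus", "e_minus")],
                      Wd = fn_wd(state), Wc = fn_wc(state))
  }
  do.call(rbind, out)
}

#' Maximum deviation of the stochastic from the deterministic model
#'
#' Runs the deterministic behavioral model and the Poisson single-electron
#' model from the same initial state through the same pulse train, for
#' several seeds, and reports the largest absolute difference in the stored
#' weight along the trajectories.  In the high-tunneling regime (default
#' preset; several hundred electrons per pulse) the two agree to within a
#' couple hundred microvolts.
#'
#' @param n_pulses pulses per trajectory.
#' @param params an \code{fn_device}.
#' @param seeds integer vector of RNG seeds, one trajectory pair per seed.
#' @param x_amplitude magnitude of the random differential steps (V); each
#'   trajectory uses an i.i.d. +/- sequence drawn under its seed and shared
#'   by both models.
#' @return a list with \code{max_dev} (volts, the maximum over pulses and
#'   seeds), and the per-seed maxima \code{per_seed}.
#' @export
compare_to_deterministic <- function(n_pulses = 100, params = fn_device(),
                                     seeds = 1:20, x_amplitude = 3e-4) {
  per_seed <- vapply(seeds, function(s) {
    set.seed(s)
    x <- sample(c(-1, 1), n_pulses, replace = TRUE) * x_amplitude
    det <- fn_state(params)
    sto <- fn_state(params)
    dev <- numeric(n_pulses)
    for (i in seq_len(n_pulses)) {
      det <- apply_pulse(det, x[i], 0, params)
      sto <- stochastic_step(sto, x[i], params)$state
      dev[i] <- abs(fn_wd(sto) - fn_wd(det))
    }
    max(dev)
  }, numeric(1))
  list(max_dev = max(per_seed), per_seed = per_seed)
}
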