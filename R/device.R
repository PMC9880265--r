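#' Device parameters for a Fowler-Nordheim tunneling synapse
#'
#' Constructs the parameter set of one FN synapse: a pair of floating-gate
#' tunneling junctions whose potentials \code{W+} and \code{W-} discharge
#' through a Fowler-Nordheim barrier.  The stored weight is the differential
#' component \code{Wd = (W+ - W-)/2} and the usage of the synapse is the
#' common-mode component \code{Wc = (W+ + W-)/2}.
#'
#' The tunneling current is parameterized in the voltage-slew domain, i.e.
#' the physical current divided by the total node capacitance \code{CT} is
#' folded into \code{k1}, so that \code{dW/dt = -(k1/k2) W^2 exp(-k2/W)} and
#' the common mode follows the closed form \code{Wc(t) = k2 / log(k1 t + k0)}
#' with \code{k0 = exp(k2/Wc0)}.
#'
#' The dimensionless constant \code{gamma = k0/(k1 * dt_pulse)} acts as the
#' initial effective age of the synapse: the retrieval signal of a stored
#' pattern decays as \code{1/(n + gamma)} with the number of updates
#' \code{n}.
#'
#' @param k1 voltage-slew prefactor (1/s).
#' @param k0 dimensionless initial condition, \code{exp(k2/Wc0)}.
#' @param Wc0 initial common-mode potential (V).
#' @param Cc input coupling capacitance (F).
#' @param Cfg floating-gate capacitance (F); \code{CT = Cc + Cfg}.
#' @param dt_pulse width of one input pulse (s).
#' @param A tunneling junction area (m^2); retained for documentation, the
#'   stochastic model derives electron rates from the voltage slew and
#'   \code{CT} instead.
#' @param q electron charge (C).
#' @return an object of class \code{fn_device}; a validated list with the
#'   additional derived fields \code{k2 = Wc0 * log(k0)}, \code{CT} and
#'   \code{gamma}.
#' @seealso [fn_device_preset()] for named presets.
#' @examples
#' p <- fn_device()
#' p$gamma     # about 4000 under defaults
#' @export
fn_device <- function(k1 = 1e16, k0 = 1e19, Wc0 = 8.0,
                      Cc = 200e-15, Cfg = 1.4e-12,
                      dt_pulse = 0.25, A = 1e-14,
                      q = 1.602176634e-19) {
  p <- list(k1 = k1, k0 = k0, Wc0 = Wc0, k2 = Wc0 * log(k0),
            Cc = Cc, Cfg = Cfg, CT = Cc + Cfg,
            dt_pulse = dt_pulse, A = A, q = q)
  p$gamma <- p$k0 / (p$k1 * p$dt_pulse)
  class(p) <- "fn_device"
  validate_fn_device(p)
  p
}

validate_fn_device <- function(p) {
  num <- c("k1", "k0", "Wc0", "k2", "Cc", "Cfg", "CT", "dt_pulse", "A", "q")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("fn_device: field '", f, "' must be a single finite positive number")
  }
  if (abs(p$CT - (p$Cc + p$Cfg)) > 1e-9 * p$CT)
    stop("fn_device: CT must equal Cc + Cfg")
  if (abs(p$k0 - exp(p$k2 / p$Wc0)) > 1e-9 * p$k0)
    stop("fn_device: k0 must equal exp(k2/Wc0)")
  if (!is.finite(p$gamma) || p$gamma <= 0)
    stop("fn_device: gamma = k0/(k1*dt_pulse) must be finite and positive")
  invisible(p)
}

#' Named device presets
#'
#' \describe{
#'   \item{default}{gamma of about 4e3 (Wc0 = 8 V, 250 ms pulses); this is
#'     also the high-tunneling regime for the stochastic model, with several
#'     hundred electrons transported per pulse.}
#'   \item{gamma1, gamma2}{gamma = 2e3 and 8e3, obtained by changing the
#'     initial condition k0 (equivalently the initial node potential Wc0) at
#'     fixed k2, the way a device would be re-initialized at a different
#'     tunneling node potential.}
#'   \item{characterize}{default constants with 100 ms pulses, the pulse
#'     width used for single-device characterization sweeps.}
#'   \item{stochastic_low}{low-tunneling regime (Wc0 = 7.35 V), of order ten
#'     electrons per pulse, for single-electron experiments.}
#' }
#'
#' @param name preset name.
#' @param ... overrides forwarded to [fn_device()].
#' @return an \code{fn_device} object.
#' @export
fn_device_preset <- function(name = c("default", "gamma1", "gamma2",
                                      "characterize", "stochastic_low"),
                             ...) {
  name <- match.arg(name)
  k2_default <- 8.0 * log(1e19)
  gamma_preset <- function(gamma_target, ...) {
    # keep k1, k2, dt fixed; move the initial condition k0 to hit gamma
    k1 <- 1e16; dt <- 0.25
    k0 <- gamma_target * k1 * dt
    fn_device(k1 = k1, k0 = k0, Wc0 = k2_default / log(k0), dt_pulse = dt, ...)
  }
  switch(name,
         default = fn_device(...),
         gamma1 = gamma_preset(2e3, ...),
         gamma2 = gamma_preset(8e3, ...),
         characterize = fn_device(dt_pulse = 0.1, ...),
         stochastic_low = {
           wc0 <- 7.35
           fn_device(k0 = exp(k2_default / wc0), Wc0 = wc0, ...)
         })
}

#' @export
print.fn_device <- function(x, ...) {
  cat("FN-synapse device parameters\n")
  cat(sprintf("  k1 = %.4g 1/s, k2 = %.6g V, k0 = %.4g (Wc0 = %.4g V)\n",
              x$k1, x$k2, x$k0, x$Wc0))
  cat(sprintf("  Cc = %.4g F, Cfg = %.4g F, CT = %.4g F\n", x$Cc, x$Cfg, x$CT))
  cat(sprintf("  pulse width = %.4g s, gamma = k0/(k1*dt) = %.6g\n",
              x$dt_pulse, x$gamma))
  invisible(x)
}

#' Synapse state
#'
#' Dynamic state of one FN synapse.  The junction potentials \code{w_plus}
#' and \code{w_minus} are the single source of truth; the weight
#' [fn_wd()] and usage [fn_wc()] are always recomputed from them.
#'
#' @param params an \code{fn_device}; when given (and \code{w_plus} missing)
#'   the state starts empty at \code{W+ = W- = Wc0} (zero weight).
#' @param w_plus,w_minus junction potentials (V).
#' @param n_updates number of pulses applied so far.
#' @return an object of class \code{fn_state}.
#' @export
fn_state <- function(params = NULL, w_plus = NULL, w_minus = NULL,
                     n_updates = 0L) {
  if (is.null(w_plus)) {
    if (is.null(params)) stop("fn_state: give either params or w_plus/w_minus")
    w_plus <- w_minus <- params$Wc0
  }
  if (is.null(w_minus)) w_minus <- w_plus
  stopifnot(is.numeric(w_plus), is.numeric(w_minus),
            all(w_plus > 0), all(w_minus > 0),
            length(w_plus) == length(w_minus),
            n_updates >= 0)
  structure(list(w_plus = as.numeric(w_plus),
                 w_minus = as.numeric(w_minus),
                 n_updates = as.integer(n_updates)),
            class = "fn_state")
}

#' @rdname fn_state
#' @param state an \code{fn_state}.
#' @export
fn_wd <- function(state) (state$w_plus - state$w_minus) / 2

#' @rdname fn_state
#' @export
fn_wc <- function(state) (state$w_plus + state$w_minus) / 2

#' @export
print.fn_state <- function(x, ...) {
  cat(sprintf(
    "FN-synapse state: Wd = %.6g V, Wc = %.6g V, n_updates = %d\n",
    fn_wd(x)[1], fn_wc(x)[1], x$n_updates))
  if (length(x$w_plus) > 1L)
    cat(sprintf("  (%d synapses)\n", length(x$w_plus)))
  invisible(x)
}

#' Fowler-Nordheim voltage slew of a tunneling node
#'
#' The discharge rate of a floating-gate node at potential \code{w}:
#' \code{J(w) = (k1/k2) w^2 exp(-k2/w)}, in volts per second (the physical
#' current divided by \code{CT} is folded into \code{k1}).  Strictly
#' increasing in \code{w}; this is the flow whose induced common-mode
#' trajectory makes the weight-decay rate scale as \code{1/t}.
#'
#' @param w node potential (V), strictly positive; vectorized.
#' @param params an \code{fn_device}.
#' @return voltage slew (V/s).
#' @export
tunneling_slew <- function(w, params) {
  if (any(!is.finite(w)) || any(w <= 0))
    stop("tunneling_slew: node potential must be finite and > 0")
  (params$k1 / params$k2) * w^2 * exp(-params$k2 / w)
}

#' Closed-form common-mode trajectory
#'
#' \code{Wc(t) = k2 / log(k1 t + k0)}: the exact solution of
#' \code{dWc/dt = -J(Wc)} from \code{Wc(0) = Wc0}, monotone decreasing in
#' \code{t}.
#'
#' @param t time since initialization (s), non-negative; vectorized.
#' @param params an \code{fn_device}.
#' @return common-mode potential (V).
#' @export
wc_closed_form <- function(t, params) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("wc_closed_form: t must be finite and >= 0")
  params$k2 / log(params$k1 * t + params$k0)
}

# advance an arbitrary node potential by dt of free FN decay (same closed
# form, re-anchored at wc): used by pulse updates and the stochastic model
wc_advance <- function(wc, dt, params) {
  params$k2 / log(params$k1 * dt + exp(params$k2 / wc))
}

#' Discrete weight-decay factor
#'
#' The per-update retention factor of the stored weight,
#' \code{alpha(n) = 1 - (1 + 2/log(k1 dt n + k0)) / (n + gamma)} with
#' \code{gamma = k0/(k1 dt)}.  \code{alpha(n)} lies in (0, 1) and increases
#' towards 1 with usage \code{n}: the more a synapse has been updated, the
#' more slowly its weight decays (metaplasticity).
#'
#' @param n update count, >= 1; vectorized.
#' @param params an \code{fn_device}.
#' @return dimensionless decay factor.
#' @export
decay_alpha <- function(n, params) {
  if (any(!is.finite(n)) || any(n < 1))
    stop("decay_alpha: n must be >= 1")
  L <- log(params$k1 * params$dt_pulse * n + params$k0)
  1 - (1 + 2 / L) / (n + params$gamma)
}

# same factor expressed through the current common-mode potential: with
# wc = k2/log(k1 dt n + k0) this is algebraically identical to decay_alpha(n)
# but it also covers modulated trajectories where wc is restored externally.
alpha_from_wc <- function(wc, dt, params) {
  L <- params$k2 / wc
  1 - (1 + 2 / L) * params$k1 * dt * exp(-L)
}

#' Apply one input pulse to a synapse
#'
#' One discrete update step: the common mode advances by one pulse width of
#' its closed-form decay, the weight decays by the usage-dependent factor
#' alpha and picks up the differential input step, and an optional
#' modulation increment restores the common mode:
#' \deqn{Wd(n) = \alpha(n) Wd(n-1) + x}
#'
#' Between pulses the device is in its non-volatile regime and the state is
#' frozen, so one call corresponds to exactly one pulse width of evolution.
#'
#' @param state an \code{fn_state} (scalar or vector of synapses).
#' @param x_pulse signed differential input step (V), i.e.
#'   \code{vin(n) - vin(n-1)}; scalar or one value per synapse.
#' @param m_increment non-negative modulation restore (V) added to the
#'   common mode after the update (0 when unmodulated).
#' @param params an \code{fn_device}.
#' @param wc_ceiling safety ceiling (V) for the restored common mode;
#'   increments pushing above it are clipped with a warning.
#' @return the new \code{fn_state}.
#' @export
apply_pulse <- function(state, x_pulse, m_increment = 0, params,
                        wc_ceiling = 9) {
  stopifnot(inherits(state, "fn_state"))
  if (any(m_increment < 0)) stop("apply_pulse: m_increment must be >= 0")
  wd <- fn_wd(state); wc <- fn_wc(state)
  wc <- wc_advance(wc, params$dt_pulse, params)
  a <- alpha_from_wc(wc, params$dt_pulse, params)
  wd <- a * wd + x_pulse
  wc <- wc + m_increment
  if (any(wc > wc_ceiling)) {
    warning("apply_pulse: modulation clipped at the Wc ceiling of ",
            wc_ceiling, " V")
    wc <- pmin(wc, wc_ceiling)
  }
  fn_state(w_plus = wc + wd, w_minus = wc - wd,
           n_updates = state$n_updates + 1L)
}

#' Apply a timed voltage pulse (physical pulse response)
#'
#' Device-level response to a single input pulse of given width and
#' magnitude, used for characterization sweeps and for the pulse-width
#' encoded updates of the continual-learning harness.  During the pulse the
#' two junctions sit at \code{Wc + |X|/2} and \code{Wc - |X|/2}; the realized
#' weight change is the differential tunneling accumulated over the pulse,
#' \deqn{\Delta Wd = \pm\, \tau \, (J(Wc+|X|/2) - J(Wc-|X|/2))/2,}
#' linear in the width \eqn{\tau} and exponential in the magnitude
#' \eqn{|X|}, while the common mode discharges by the mean of the two flows.
#' As \code{Wc} drops with usage both flows collapse exponentially, so
#' successive identical pulses realize strictly shrinking weight updates.
#'
#' @param state an \code{fn_state} (scalar or vector of synapses).
#' @param width pulse width (s), >= 0.
#' @param magnitude signed pulse magnitude (V): positive potentiates
#'   (increases Wd), negative depresses.
#' @param params an \code{fn_device}.
#' @return the new \code{fn_state}.
#' @seealso [pulse_response()] for the weight change alone, [characterize()].
#' @export
apply_timed_pulse <- function(state, width, magnitude, params) {
  stopifnot(inherits(state, "fn_state"), all(width >= 0))
  wd <- fn_wd(state); wc <- fn_wc(state)
  mag <- abs(magnitude)
  if (any(wc - mag / 2 <= 0))
    stop("apply_timed_pulse: |magnitude|/2 must stay below Wc")
  jp <- tunneling_slew(wc + mag / 2, params)
  jm <- tunneling_slew(wc - mag / 2, params)
  a <- alpha_from_wc(wc, width, params)
  wd <- a * wd + sign(magnitude) * width * (jp - jm) / 2
  wc <- wc - width * (jp + jm) / 2
  fn_state(w_plus = wc + wd, w_minus = wc - wd,
           n_updates = state$n_updates + 1L)
}

#' Weight change for a single timed pulse at fixed common mode
#'
#' @param width pulse width (s).
#' @param magnitude pulse magnitude (V), signed.
#' @param params an \code{fn_device}.
#' @param wc common-mode potential held during the pulse (V).
#' @return realized weight change (V); vectorized over width and magnitude.
#' @export
pulse_response <- function(width, magnitude, params, wc = params$Wc0) {
  mag <- abs(magnitude)
  if (any(wc - mag / 2 <= 0))
    stop("pulse_response: |magnitude|/2 must stay below Wc")
  sign(magnitude) * width *
    (tunneling_slew(wc + mag / 2, params) -
       tunneling_slew(wc - mag / 2, params)) / 2
}

#' Discrete decay-rate diagnostic
#'
#' Estimates the weight-decay rate \code{r(t) = -Wc''(t)/Wc'(t)} from a
#' sampled common-mode trajectory, using three-point finite differences that
#' accommodate non-uniform (e.g. log-spaced) sampling.  For the FN closed
#' form, \code{t * r(t)} approaches 1 at large \code{t}, the usage profile
#' under which the memory signal-to-noise ratio decays at the optimal
#' \code{1/t} rate.
#'
#' @param t sample times (s), strictly increasing, length >= 5.
#' @param wc sampled common-mode values (V), same length; a warning is
#'   issued if the trajectory is not strictly monotone.
#' @return data.frame with columns \code{t} (interior sample times) and
#'   \code{r} (estimated decay rate, 1/s).
#' @export
decay_rate_r <- function(t, wc) {
  if (length(t) < 5 || length(wc) != length(t))
    stop("decay_rate_r: need at least 5 samples with matching lengths")
  if (any(diff(t) <= 0))
    stop("decay_rate_r: sample times must be strictly increasing")
  d <- diff(wc)
  if (!(all(d < 0) || all(d > 0)))
    warning("decay_rate_r: trajectory is not strictly monotone")
  n <- length(t)
  i <- 2:(n - 1)
  h1 <- t[i] - t[i - 1]
  h2 <- t[i + 1] - t[i]
  # quadratic through (t[i-1], t[i], t[i+1]): first and second derivative at t[i]
  d1 <- (-h2 / (h1 * (h1 + h2))) * wc[i - 1] +
    ((h2 - h1) / (h1 * h2)) * wc[i] +
    (h1 / (h2 * (h1 + h2))) * wc[i + 1]
  d2 <- 2 * (wc[i - 1] / (h1 * (h1 + h2)) - wc[i] / (h1 * h2) +
               wc[i + 1] / (h2 * (h1 + h2)))
  data.frame(t = t[i], r = -d2 / d1)
}

#' Optimal consolidation flow
#'
#' The flow \code{J(Wc) = (1/beta) Wc^2 exp(-beta/Wc)} whose induced usage
#' trajectory \code{Wc = beta/log(t)} yields the \code{1/t} decay-rate
#' optimum; identical in form to [tunneling_slew()] with \code{k1 = 1},
#' \code{k2 = beta}.
#'
#' @param wc common-mode potential (V), > 0.
#' @param beta barrier constant (V), > 0.
#' @return flow in V/s.
#' @export
optimal_flow <- function(wc, beta) {
  if (any(wc <= 0) || any(beta <= 0))
    stop("optimal_flow: wc and beta must be > 0")
  (1 / beta) * wc^2 * exp(-beta / wc)
}

#' Energy of one synaptic write
#'
#' Electrostatic energy drawn from the input source to charge one coupling
#' capacitor: \code{E = Cc X^2 / 2}.  A differential pulse applied as
#' \code{+X/2} and \code{-X/2} on the two coupling capacitors dissipates
#' \code{2 * write_energy(Cc, X/2)} in total.
#'
#' @param cc coupling capacitance (F), > 0.
#' @param x_volts input voltage pulse change (V).
#' @return energy (J); vectorized.
#' @export
write_energy <- function(cc, x_volts) {
  if (any(cc <= 0)) stop("write_energy: cc must be > 0")
  0.5 * cc * x_volts^2
}

#' Dump / restore synapse state as JSON
#'
#' Full-precision round trip of the junction potentials and update count.
#'
#' @param state an \code{fn_state}.
#' @param path file path.
#' @return \code{state_restore} returns the restored \code{fn_state};
#'   \code{state_dump} returns \code{path} invisibly.
#' @export
state_dump <- function(state, path) {
  stopifnot(inherits(state, "fn_state"))
  jsonlite::write_json(unclass(state), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname state_dump
#' @export
state_restore <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  fn_state(w_plus = s$w_plus, w_minus = s$w_minus,
           n_updates = as.integer(s$n_updates))
}
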