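#' Plasticity-modulation profiles
#'
#' A modulation profile is a rule for the staircase voltage signal applied
#' globally to all synapses of a network: after each pattern update the
#' common mode of every synapse is restored upward by an increment
#' \code{m(i)}, which balances the monotone usage-driven rigidification and
#' lets the network gracefully forget old patterns instead of blacking out.
#'
#' Three kinds are supported:
#' \describe{
#'   \item{m0_constant}{constant modulation voltage, i.e. zero increments
#'     (pure consolidation).}
#'   \item{fraction_of_mean_dwd}{the increment is a fixed fraction of the
#'     network-wide mean absolute weight change of the latest update.  The
#'     conventional profiles m1, m2 and m3 use fractions 3/4, 1/2 and 1/4.}
#'   \item{periodic_switch}{(m4) alternates between the m0 rule and the m1
#'     rule every \code{switch_period} updates, producing an oscillatory
#'     steady state.}
#' }
#'
#' Applied increments are appended to an internal log, retrievable with
#' [increments_log()]; the cumulative sum of the log is the height of the
#' modulation staircase.
#'
#' @param kind profile kind; the shorthand names \code{"m0"} ...
#'   \code{"m4"} are accepted and mapped to the kinds and fractions above.
#' @param fraction fraction of the mean absolute weight change, in [0, 1].
#' @param switch_period period (in updates) of the m4 rule switch.
#' @return an object of class \code{fn_modulation}.
#' @export
modulation_profile <- function(kind = c("m0", "m1", "m2", "m3", "m4",
                                        "m0_constant", "fraction_of_mean_dwd",
                                        "periodic_switch"),
                               fraction = NULL, switch_period = 250) {
  kind <- match.arg(kind)
  shorthand <- c(m0 = "m0_constant", m1 = "fraction_of_mean_dwd",
                 m2 = "fraction_of_mean_dwd", m3 = "fraction_of_mean_dwd",
                 m4 = "periodic_switch")
  label <- kind
  if (kind %in% names(shorthand)) {
    if (is.null(fraction))
      fraction <- c(m0 = 0, m1 = 0.75, m2 = 0.5, m3 = 0.25, m4 = 0.75)[[kind]]
    kind <- shorthand[[kind]]
  }
  if (is.null(fraction)) fraction <- if (kind == "m0_constant") 0 else 0.75
  stopifnot(fraction >= 0, fraction <= 1, switch_period >= 1)
  p <- list(kind = kind, label = label, fraction = fraction,
            switch_period = as.integer(switch_period), log = new.env())
  p$log$increments <- numeric(0)
  class(p) <- "fn_modulation"
  p
}

#' @export
print.fn_modulation <- function(x, ...) {
  cat(sprintf("Modulation profile '%s' (%s)", x$label, x$kind))
  if (x$kind == "fraction_of_mean_dwd")
    cat(sprintf(", fraction = %g", x$fraction))
  if (x$kind == "periodic_switch")
    cat(sprintf(", fraction = %g, switch period = %d updates",
                x$fraction, x$switch_period))
  cat(sprintf("; %d increments applied\n", length(x$log$increments)))
  invisible(x)
}

#' Modulation increment for one update
#'
#' Evaluates the profile rule for the given update and appends the result
#' to the profile's increment log.
#'
#' @param profile an \code{fn_modulation}.
#' @param mean_abs_dwd network-wide mean absolute weight change (V) of the
#'   latest update; must be non-negative.
#' @param update_index 1-based index of the update.
#' @return the increment in volts (non-negative).
#' @export
compute_increment <- function(profile, mean_abs_dwd, update_index) {
  stopifnot(inherits(profile, "fn_modulation"))
  if (!is.finite(mean_abs_dwd) || mean_abs_dwd < 0)
    stop("compute_increment: mean_abs_dwd must be non-negative")
  inc <- switch(profile$kind,
                m0_constant = 0,
                fraction_of_mean_dwd = profile$fraction * mean_abs_dwd,
                periodic_switch = {
                  # block parity: the active rule flips at update
                  # switch_period, 2*switch_period, ...
                  if (update_index %/% profile$switch_period %% 2 == 0) 0
                  else profile$fraction * mean_abs_dwd
                })
  profile$log$increments <- c(profile$log$increments, inc)
  inc
}

#' @rdname compute_increment
#' @export
increments_log <- function(profile) {
  stopifnot(inherits(profile, "fn_modulation"))
  profile$log$increments
}

#' @rdname compute_increment
#' @export
reset_increments_log <- function(profile) {
  stopifnot(inherits(profile, "fn_modulation"))
  profile$log$increments <- numeric(0)
  invisible(profile)
}

#' Common-mode trajectory between and across modulation increments
#'
#' Between increments the common mode follows its closed-form decay
#' re-anchored at the last increment instant; at an increment instant it
#' jumps up by the increment.  Increments that would push the common mode
#' above the safety ceiling are clipped with a warning.
#'
#' @param wc_at_last_increment common mode just after the last increment (V).
#' @param elapsed_pulses number of pulse widths elapsed since then.
#' @param increment modulation increment (V) applied now (0 for none).
#' @param params an \code{fn_device}.
#' @param wc_ceiling safety ceiling (V).
#' @return common-mode potential (V) after the elapsed decay and increment.
#' @export
wc_with_modulation <- function(wc_at_last_increment, elapsed_pulses,
                               increment = 0, params, wc_ceiling = 9) {
  stopifnot(wc_at_last_increment > 0, elapsed_pulses >= 0, increment >= 0)
  wc <- wc_advance(wc_at_last_increment,
                   elapsed_pulses * params$dt_pulse, params)
  wc <- wc + increment
  if (any(wc > wc_ceiling)) {
    warning("wc_with_modulation: increment clipped at the ceiling of ",
            wc_ceiling, " V")
    wc <- pmin(wc, wc_ceiling)
  }
  wc
}
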