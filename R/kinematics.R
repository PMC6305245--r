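## Closed-form 1D motion of a charged particle ejected from the sample
## surface at time t_E with velocity v0 into a uniform extraction field E.
## With tau = delta_t - t_E and a = q e E / m the propagated distance is
##     z(tau) = v0 tau + (a/2) tau^2,
## the quadratic the whole analysis inverts.  Strict SI throughout.

#' Extraction field from accelerating voltage and gap
#'
#' @param voltage Accelerating potential in volts (> 0).
#' @param gap Length of the acceleration region in metres (> 0).
#' @return Field strength in V/m (`voltage / gap`).
#' @examples
#' field_from_voltage(4500, 0.0127)  # ~3.54e5 V/m
#' @export
field_from_voltage <- function(voltage, gap) {
  if (any(!is.finite(voltage)) || any(voltage <= 0))
    stop("voltage must be positive and finite")
  if (any(!is.finite(gap)) || any(gap <= 0))
    stop("gap must be positive and finite")
  voltage / gap
}

#' Instrument geometry for a single-stage linear TOF spectrometer
#'
#' One uniform acceleration region (`gap`, field `voltage/gap`) followed by
#' a field-free drift region.  The acceleration gap defaults to 12.7 mm,
#' the value consistent with all printed voltage/field pairs of the
#' instrument this package models (and exactly half an inch, a standard
#' ion-optics spacing).
#'
#' @param voltage Accelerating potential in volts.
#' @param gap Acceleration-region length in metres.
#' @param drift_length Field-free region length in metres.  Affects only
#'   absolute flight times, never any ejection-time result: all inference
#'   happens inside the gap.
#' @param bin_width TOF histogram bin width in seconds.
#' @return An object of class `instrument_config` with the derived `field`
#'   (V/m).
#' @examples
#' instrument_config(4500)
#' @export
instrument_config <- function(voltage, gap = 0.0127, drift_length = 1.0,
                              bin_width = 2e-9) {
  stopifnot(gap > 0, drift_length >= 0, bin_width > 0)
  field <- field_from_voltage(voltage, gap)
  structure(list(voltage = voltage, gap = gap, field = field,
                 drift_length = drift_length, bin_width = bin_width),
            class = "instrument_config")
}

#' @export
print.instrument_config <- function(x, ...) {
  cat(sprintf(
    "<instrument_config> %+.1f kV over %.3f mm (%.3g V/m), drift %.2f m, bin %.1f ns\n",
    x$voltage / 1e3, x$gap * 1e3, x$field, x$drift_length, x$bin_width * 1e9))
  invisible(x)
}

#' Kinematic state of an ion
#'
#' Position/velocity/time triple used to hand a dissociated parent's state
#' at the probe instant to [fragment_arrival()].
#'
#' @param position Metres from the sample surface along the TOF axis (>= 0).
#' @param velocity m/s.
#' @param time Seconds since the MALDI laser pulse (>= 0).
#' @return An object of class `kinematic_state`.
#' @export
kinematic_state <- function(position, velocity, time) {
  stopifnot(all(position >= 0), all(time >= 0))
  structure(list(position = position, velocity = velocity, time = time),
            class = "kinematic_state")
}

## acceleration magnitude q e E / m for one species in a given field
.accel <- function(species, field) {
  species$charge * physical_constants[["elementary_charge"]] * field /
    species$mass_kg
}

#' Propagated distance of an ion at a given observation time
#'
#' Position of an ion ejected at `t_E` with initial velocity `v0`,
#' evaluated at time `delta_t` after the MALDI pulse:
#' `z = v0 * tau + (q e E / 2 m) * tau^2` with `tau = delta_t - t_E`.
#' Ions not yet ejected (`delta_t <= t_E`) sit at the surface, position 0.
#' The result is not capped at the gap length; callers probing beyond the
#' gap must handle that themselves.
#'
#' @param t_E Ejection time(s) in seconds.
#' @param v0 Initial velocity/velocities in m/s.  Negative values are
#'   admitted only while the field term dominates (the ion must not
#'   re-enter the surface at any evaluated time).
#' @param species An [ion_species].
#' @param field Extraction field in V/m.
#' @param delta_t Observation time(s) in seconds (>= 0).
#' @return Position(s) in metres, vectorized over `t_E`, `v0`, `delta_t`.
#' @examples
#' sp <- chca_species()[["(CHCA)H+"]]
#' propagate_distance(45e-9, 500, sp, 3.54e5, 150e-9)  # ~1.04 mm
#' @export
propagate_distance <- function(t_E, v0, species, field, delta_t) {
  if (any(delta_t < 0)) stop("delta_t must be non-negative")
  a <- .accel(species, field)
  n <- max(length(t_E), length(v0), length(delta_t))
  v0 <- rep_len(v0, n)
  tau <- pmax(rep_len(delta_t, n) - rep_len(t_E, n), 0)
  neg <- v0 < 0 & tau > 0
  if (any(neg) && any(tau[neg] <= 2 * abs(v0[neg]) / a))
    stop("negative v0 would carry the ion back into the surface")
  v0 * tau + 0.5 * a * tau^2
}

#' Invert the propagation law for the ejection time
#'
#' Given an observed (probe delay, packet-centre position) pair, solves
#' `(q e E / 2 m) tau^2 + v0 tau - z = 0` for the positive root and returns
#' `t_E = delta_t - tau`.  A negative ejection time is physically
#' impossible (the ion would predate the MALDI pulse); such points are
#' returned flagged invalid, never silently dropped.
#'
#' @inheritParams propagate_distance
#' @param z Observed position(s) in metres (> 0).
#' @param delta_t Probe delay(s) in seconds (> 0).
#' @return A data frame with columns `t_E` (seconds) and `valid` (FALSE
#'   where `t_E < 0`).
#' @examples
#' sp <- chca_species()[["(CHCA)H+"]]
#' invert_ejection_time(1.1e-3, 150e-9, 500, sp, 3.54e5)  # ~42 ns
#' @export
invert_ejection_time <- function(z, delta_t, v0, species, field) {
  if (any(z <= 0)) stop("z must be positive")
  if (any(delta_t <= 0)) stop("delta_t must be positive")
  if (any(field <= 0)) stop("field must be positive")
  a <- .accel(species, field)
  disc <- v0^2 + 2 * a * z
  if (any(disc < 0)) stop("no real root: ion cannot reach z")
  ## root written to avoid cancellation when v0 > 0
  tau <- 2 * z / (sqrt(disc) + v0)
  if (any(tau <= 0)) stop("no positive root for tau")
  t_E <- delta_t - tau
  data.frame(t_E = t_E, valid = t_E >= 0)
}

#' Full flight time to the detector
#'
#' Single-stage model: uniform acceleration over the remaining gap, then a
#' field-free drift.  `t = t_E + tau_acc + drift / v_exit` where `tau_acc`
#' is the positive root of `gap = v0 tau + (a/2) tau^2` and
#' `v_exit = sqrt(v0^2 + 2 a gap)`.
#'
#' @inheritParams propagate_distance
#' @param instrument An [instrument_config].
#' @return Arrival time(s) at the detector in seconds.
#' @export
time_of_flight <- function(t_E, v0, species, instrument) {
  a <- .accel(species, instrument$field)
  v_exit <- sqrt(v0^2 + 2 * a * instrument$gap)
  tau_acc <- 2 * instrument$gap / (v_exit + v0)
  t_E + tau_acc + instrument$drift_length / v_exit
}

#' Arrival time of a fragment born inside the acceleration gap
#'
#' A parent ion photodissociated at a known kinematic state hands its
#' velocity to the fragment, which then accelerates over the remaining gap
#' with its own (smaller) mass and drifts to the detector.  Lighter
#' fragments accelerate harder, so a proper fragment always arrives before
#' its intact parent would have.
#'
#' @param state A [kinematic_state] of the parent at dissociation
#'   (vectorized fields allowed).
#' @param parent The parent [ion_species].
#' @param fragment The fragment [ion_species]; `fragment$mass` must not
#'   exceed `parent$mass`.
#' @param instrument An [instrument_config].
#' @return Detector arrival time(s) in seconds.
#' @export
fragment_arrival <- function(state, parent, fragment, instrument) {
  if (fragment$mass > parent$mass)
    stop("fragment mass exceeds parent mass")
  if (any(state$position < 0) || any(state$position > instrument$gap))
    stop("parent must dissociate inside the acceleration gap")
  a <- .accel(fragment, instrument$field)
  remaining <- instrument$gap - state$position
  v_exit <- sqrt(state$velocity^2 + 2 * a * remaining)
  tau_acc <- ifelse(remaining > 0, 2 * remaining / (v_exit + state$velocity), 0)
  state$time + tau_acc + instrument$drift_length / v_exit
}
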