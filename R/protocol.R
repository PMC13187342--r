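#' Pulsed ultrasound stimulation protocol
#'
#' Describes the DBS-like pulsed TUS protocol: short pulses at a pulse
#' repetition frequency (PRF), grouped into trains that repeat with a cooling
#' gap, delivered in blocks. Defaults are the 500 kHz / 90 microsecond /
#' 130 Hz / 800 ms-train / 2.5 s-period / 5-minute-block protocol with a
#' 600 kPa in-brain peak pressure target.
#'
#' @param fundamental_frequency carrier frequency, Hz
#' @param pulse_duration single pulse length, s
#' @param prf pulse repetition frequency within a train, Hz
#' @param train_duration pulse-train length, s
#' @param train_period train repetition period (train plus cooling gap), s
#' @param block_duration stimulation block length, s
#' @param peak_pressure_brain target peak pressure in brain tissue, Pa
#' @return object of class `pulse_protocol`
#' @examples
#' protocol_timing(pulse_protocol())
#' @export
pulse_protocol <- function(fundamental_frequency = 500e3,
                           pulse_duration = 90e-6,
                           prf = 130,
                           train_duration = 0.8,
                           train_period = 2.5,
                           block_duration = 300,
                           peak_pressure_brain = 600e3) {
  p <- structure(list(
    fundamental_frequency = fundamental_frequency,
    pulse_duration = pulse_duration,
    prf = prf,
    train_duration = train_duration,
    train_period = train_period,
    block_duration = block_duration,
    peak_pressure_brain = peak_pressure_brain
  ), class = "pulse_protocol")
  validate_protocol(p)
  p
}

#' Validate a pulse protocol against its invariants
#'
#' @param protocol a [pulse_protocol()]
#' @return the protocol, invisibly; signals a validation error naming the
#'   violated invariant otherwise
#' @export
validate_protocol <- function(protocol) {
  f <- unlist(protocol)
  if (any(!is.finite(f)) || any(f <= 0))
    abort_invalid("all protocol fields must be positive and finite")
  if (protocol$pulse_duration > 1 / protocol$prf)
    abort_invalid("pulse_duration must not exceed the pulse period 1/prf")
  if (protocol$train_duration > protocol$train_period)
    abort_invalid("train_duration must not exceed train_period")
  duty <- protocol$pulse_duration * protocol$prf
  if (duty <= 0 || duty > 1)
    abort_invalid("within-train duty cycle must lie in (0, 1]")
  invisible(protocol)
}

#' Timing summary of a pulse protocol
#'
#' @param protocol a [pulse_protocol()]
#' @return list with `duty_cycle_within_train` (fraction of on-time while a
#'   train is running), `pulses_per_train`, `train_on_fraction`
#'   (train_duration / train_period) and `intertrain_gap` (cooling time, s)
#' @export
protocol_timing <- function(protocol) {
  validate_protocol(protocol)
  list(
    duty_cycle_within_train = protocol$pulse_duration * protocol$prf,
    pulses_per_train = floor(protocol$train_duration * protocol$prf),
    train_on_fraction = protocol$train_duration / protocol$train_period,
    intertrain_gap = protocol$train_period - protocol$train_duration
  )
}

#' @export
print.pulse_protocol <- function(x, ...) {
  t <- protocol_timing(x)
  cat(sprintf(
    "Pulsed TUS protocol: %.0f kHz, %.0f us pulses at %g Hz PRF\n",
    x$fundamental_frequency / 1e3, x$pulse_duration * 1e6, x$prf))
  cat(sprintf(
    "  %g s trains every %g s (duty %.2f%% in-train, %.1f s cooling gap)\n",
    x$train_duration, x$train_period,
    100 * t$duty_cycle_within_train, t$intertrain_gap))
  cat(sprintf("  target in-brain peak pressure %.0f kPa\n",
              x$peak_pressure_brain / 1e3))
  invisible(x)
}
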