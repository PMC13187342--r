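#' Electrode-coupling model for direct sonication
#'
#' How incident acoustic pressure at the electrode tip maps into recorded
#' units: proportional to pressure (`linear_pressure`) or to its square
#' (`pressure_squared`, the default -- radiation-force-like, matching a
#' dose response of recorded power with peak pressure).
#'
#' @param mode `"pressure_squared"` or `"linear_pressure"`
#' @param gain recording units per Pa (or per Pa^2)
#' @export
coupling_model <- function(mode = c("pressure_squared", "linear_pressure"),
                           gain = 1e-11) {
  mode <- match.arg(mode)
  if (gain < 0) abort_invalid("gain must be non-negative")
  structure(list(mode = mode, gain = gain), class = "coupling_model")
}

#' Recording hardware chain of the implanted device
#'
#' @param lpf_cutoff hardware low-pass corner, Hz (100 Hz in the emulated
#'   device)
#' @param lpf_order Butterworth order (the true order is unpublished;
#'   2 by default, configurable)
#' @param rate device sampling rate, Hz
#' @param internal_rate simulation rate before decimation, Hz
#' @export
hardware_chain <- function(lpf_cutoff = 100, lpf_order = 2, rate = 250,
                           internal_rate = 10e3) {
  if (lpf_cutoff >= rate) abort_invalid("cutoff must be below the rate")
  if (lpf_order < 1) abort_invalid("lpf_order must be at least 1")
  structure(as.list(environment()), class = "hardware_chain")
}

#' Exact Fourier-series magnitudes of a unit rectangular pulse train
#'
#' For pulses of width `tau` repeating at `prf`, the harmonic at
#' `k * prf` has relative amplitude `2 * d * |sinc(k d)|` with duty
#' `d = tau * prf` (DC term `d`). Serves as the analytic oracle for the
#' artefact spectrum.
#'
#' @param protocol list-like with `pulse_duration` and `prf` (a
#'   [pulse_protocol()] works)
#' @param n_harmonics number of harmonics
#' @return data.frame with `harmonic`, `frequency` (Hz), `amplitude`
#' @export
harmonic_series <- function(protocol, n_harmonics = 20) {
  if (n_harmonics < 1) abort_invalid("need at least one harmonic")
  d <- protocol$pulse_duration * protocol$prf
  k <- seq_len(n_harmonics)
  sinc <- function(z) ifelse(z == 0, 1, sin(pi * z) / (pi * z))
  data.frame(harmonic = k, frequency = k * protocol$prf,
             amplitude = 2 * d * abs(sinc(k * d)))
}

#' Simulate the electrode recording during direct sonication
#'
#' Continuous-time model: a rectangular pulse train (width
#' `pulse_duration`, period `1/prf`, amplitude `coupling(pressure)`),
#' gated by the train envelope, sampled at the chain's internal rate,
#' passed through the hardware low-pass (causal Butterworth), then
#' decimated to the device rate by subsampling -- residual aliasing is
#' kept deliberately, as in hardware. Baseline noise is added from the
#' seed.
#'
#' @param protocol a [pulse_protocol()] (pulse width, PRF, train gating)
#' @param pressure peak pressure at the electrode, Pa
#' @param coupling a [coupling_model()]
#' @param chain a [hardware_chain()]
#' @param duration s (at least 5)
#' @param noise_sd baseline noise RMS in recording units
#' @param seed integer
#' @return object of class `artefact_recording`: `x` (recorded units at
#'   `chain$rate`), `fs`, the pre-decimation filtered signal `x_internal`
#'   at `fs_internal` (noise-free; for spectral cross-checks), plus the
#'   inputs
#' @export
artefact_timeseries <- function(protocol, pressure, coupling = coupling_model(),
                                chain = hardware_chain(), duration = 30,
                                noise_sd = 0.02, seed = 1L) {
  if (duration < 5) abort_invalid("duration must be at least 5 s")
  if (chain$internal_rate < 10 * protocol$prf)
    abort_invalid("internal rate must be at least 10x the PRF")
  fs <- chain$internal_rate
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  amp <- if (coupling$mode == "linear_pressure")
    coupling$gain * pressure else coupling$gain * pressure^2
  in_pulse <- (t %% (1 / protocol$prf)) < protocol$pulse_duration
  in_train <- (t %% protocol$train_period) < protocol$train_duration
  x <- amp * as.numeric(in_pulse & in_train)
  lp <- signal::butter(chain$lpf_order, chain$lpf_cutoff / (fs / 2),
                       type = "low")
  xf <- as.numeric(signal::filter(lp, x))   # causal, as in hardware
  dec <- round(fs / chain$rate)
  x <- xf[seq(1, length(xf), by = dec)]
  noise <- with_seed(derive_seed(seed, "artefact/baseline"),
                     rnorm(length(x), sd = noise_sd))
  structure(list(x = x + noise, fs = fs / dec,
                 x_internal = xf, fs_internal = fs,
                 protocol = protocol,
                 pressure = pressure, coupling = coupling, chain = chain,
                 noise_sd = noise_sd, seed = seed),
            class = "artefact_recording")
}

#' Beta-band power change of a sonication recording over baseline
#'
#' @param recording an [artefact_timeseries()] recording
#' @param baseline a matched recording at zero pressure (amplifier noise)
#' @param welch a [welch_config()]; normalisation is turned off internally
#'   (absolute band powers are compared)
#' @param band Hz pair or band name (default beta)
#' @return ratio of beta band power, recording / baseline
#' @export
artefact_beta_change <- function(recording, baseline,
                                 welch = welch_config(normalise = FALSE),
                                 band = "beta") {
  if (length(recording$x) != length(baseline$x))
    abort_invalid("recording and baseline must have equal duration")
  welch$normalise <- FALSE
  pr <- welch_psd(recording$x, recording$fs, welch)
  pb <- welch_psd(baseline$x, baseline$fs, welch)
  denom <- band_power(pb, band)
  if (denom <= 0) abort_invalid("baseline band power is zero")
  band_power(pr, band) / denom
}
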