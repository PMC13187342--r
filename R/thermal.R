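#' Volumetric heat source from a verified pressure field
#'
#' Uses the plane-wave absorption relation `Q = alpha |p|^2 / (rho c)`
#' per voxel. `duty_averaged` mode multiplies by the protocol's within-train
#' duty cycle times the train on-fraction (time-averaged heating over the
#' block); `pulse_peak` leaves the continuous-wave deposition (used by the
#' train-resolved bioheat mode, which applies the in-train duty and gates
#' trains on and off itself).
#'
#' @param field drive-scaled `complex_field` from [forward_verify()]
#' @param medium the [acoustic_medium()] the field was computed in
#' @param protocol [pulse_protocol()]
#' @param mode `"duty_averaged"` or `"pulse_peak"`
#' @return object of class `q_field`: `q` (W/m^3), `mode`, grid geometry
#' @export
heat_source <- function(field, medium, protocol,
                        mode = c("duty_averaged", "pulse_peak")) {
  mode <- match.arg(mode)
  if (is.na(field$drive_scale))
    abort_invalid(
      "field is not drive-scaled: run forward_verify (or set drive_scale) first")
  q <- medium$absorption * Mod(field$p)^2 /
    (medium$density * medium$sound_speed)
  t <- protocol_timing(protocol)
  if (mode == "duty_averaged")
    q <- q * t$duty_cycle_within_train * t$train_on_fraction
  structure(list(q = q, mode = mode, spacing = field$spacing,
                 origin = field$origin, protocol = protocol),
            class = "q_field")
}

#' Solve the Pennes bioheat equation for a temperature-rise field
#'
#' Explicit finite differences on the phantom grid with zero-flux
#' boundaries: `rho C dT/dt = div(k grad T) + Q - w_sink T`, `T` the rise
#' over the arterial baseline and `w_sink = rho_b C_b w` the perfusion
#' sink. `duty_averaged` mode applies the time-averaged source for the
#' whole duration; `train_resolved` mode switches the in-train source
#' (CW deposition times within-train duty) on for `train_duration` out of
#' every `train_period` seconds. The time step is 0.9 times the explicit
#' diffusion stability bound, additionally subdivided so each train sees
#' at least 8 steps.
#'
#' @param q a [heat_source()] output
#' @param medium a [thermal_medium()]
#' @param duration simulated time, s
#' @param mode `"duty_averaged"` or `"train_resolved"`
#' @param initial optional initial temperature-rise field (matrix, degrees C)
#' @param dt optional explicit time step, s; error if above the stability
#'   bound
#' @return object of class `thermal_result`: `max_rise` (degrees C, global
#'   over space and time), `hottest_location` (mm), `final` rise field,
#'   `trace` (rise at the peak-deposition voxel per step), `times`, `dt`
#' @export
simulate_bioheat <- function(q, medium, duration,
                             mode = c("duty_averaged", "train_resolved"),
                             initial = NULL, dt = NULL) {
  mode <- match.arg(mode)
  protocol <- q$protocol
  qmap <- q$q
  gated <- FALSE
  on_time <- period <- 1
  if (mode == "train_resolved") {
    if (q$mode != "pulse_peak")
      abort_invalid(
        "train_resolved mode needs a pulse_peak heat source (duty applied here)")
    tm <- protocol_timing(protocol)
    qmap <- qmap * tm$duty_cycle_within_train
    gated <- TRUE
    on_time <- protocol$train_duration
    period <- protocol$train_period
  }
  dx <- medium$spacing * 1e-3
  rhoC <- medium$density * medium$specific_heat
  # explicit stability: dt <= min over voxels of rhoC dx^2 / (4 k)
  kmax_pair <- max(medium$conductivity)
  dt_bound <- min(rhoC) * dx^2 / (4 * kmax_pair + dx^2 * max(medium$perfusion_sink))
  if (is.null(dt)) {
    dt <- 0.9 * dt_bound
    if (gated) dt <- min(dt, on_time / 8)
    # conduction-free media have an unbounded stable step; still resolve
    # the heating timeline
    dt <- min(dt, duration / 20)
  } else if (dt > dt_bound) {
    abort_invalid(sprintf(
      "requested dt %.3g s exceeds the explicit stability bound %.3g s",
      dt, dt_bound))
  }
  nt <- max(1L, ceiling(duration / dt))
  tr <- arrayInd(which.max(qmap), dim(qmap))
  init <- if (is.null(initial)) matrix(0, nrow(qmap), ncol(qmap)) else initial
  out <- .bioheat2d(medium$conductivity, rhoC, medium$perfusion_sink,
                    qmap, init, dx, dt, as.integer(nt),
                    gated, on_time, period,
                    as.integer(tr[1] - 1L), as.integer(tr[2] - 1L))
  loc <- medium$origin + (c(out$max_i, out$max_j) - 1) * medium$spacing
  structure(list(max_rise = out$max_rise, hottest_location = loc,
                 final = out$final, trace = out$trace,
                 times = seq_len(nt) * dt, dt = dt, mode = mode,
                 duration = duration), class = "thermal_result")
}

#' Safety limits for a sonication plan
#'
#' Defaults follow consortium guidance for ultrasound neuromodulation:
#' temperature rise strictly below 2 degrees C anywhere in the head, and
#' the -6 dB focus strictly more than 5 mm from the electrode.
#'
#' @param max_delta_t degrees C
#' @param min_electrode_clearance mm
#' @export
safety_limits <- function(max_delta_t = 2, min_electrode_clearance = 5) {
  if (max_delta_t <= 0 || min_electrode_clearance <= 0)
    abort_invalid("safety limits must be positive")
  structure(list(max_delta_t = max_delta_t,
                 min_electrode_clearance = min_electrode_clearance),
            class = "safety_limits")
}

#' Combined thermal and clearance safety report
#'
#' Thermal pass requires `max_rise < max_delta_t`; clearance pass requires
#' `electrode_clearance > min_electrode_clearance` (both strict, so a
#' clearance of exactly 5 mm fails the ">5 mm" rule).
#'
#' @param thermal a [simulate_bioheat()] result
#' @param focal a [focal_metrics()] result from the same phantom run
#' @param limits a [safety_limits()]
#' @return list with measured values and `thermal_pass`, `clearance_pass`,
#'   `overall_pass`
#' @export
safety_report <- function(thermal, focal, limits = safety_limits()) {
  thermal_pass <- thermal$max_rise < limits$max_delta_t
  clearance_pass <- focal$electrode_clearance > limits$min_electrode_clearance
  list(max_rise = thermal$max_rise,
       hottest_location = thermal$hottest_location,
       electrode_clearance = focal$electrode_clearance,
       targeting_error = focal$targeting_error,
       limits = unclass(limits),
       thermal_pass = thermal_pass, clearance_pass = clearance_pass,
       overall_pass = thermal_pass && clearance_pass)
}
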