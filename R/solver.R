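#' Acoustic solver configuration
#'
#' Controls the time-domain single-frequency solver. The time step is
#' derived from the Courant-Friedrichs-Lewy (CFL) number and the fastest
#' medium, then snapped so an integer number of steps fits one carrier
#' cycle (making the quadrature demodulation window exact).
#'
#' @param cfl CFL number in (0, 1); 0.28 follows common practice for
#'   heterogeneous skull simulations
#' @param pml_width absorbing boundary layer width, voxels (minimum 4)
#' @param ramp_cycles carrier cycles over which the source amplitude is
#'   ramped up (raised cosine) before steady state
#' @param record_cycles carrier cycles in the demodulation window (minimum 4)
#' @param settle_crossings number of slowest-speed grid crossings to wait
#'   for steady state before recording
#' @param min_ppw minimum points per wavelength accepted in the slowest
#'   medium before the solver refuses
#' @export
solver_config <- function(cfl = 0.28, pml_width = 10L, ramp_cycles = 10L,
                          record_cycles = 8L, settle_crossings = 2.5,
                          min_ppw = 5) {
  if (cfl <= 0 || cfl >= 1)
    abort_invalid("cfl must lie in (0, 1); larger values are unstable")
  if (pml_width < 4) abort_invalid("pml_width must be at least 4 voxels")
  if (record_cycles < 4) abort_invalid("record_cycles must be at least 4")
  structure(as.list(environment()), class = "solver_config")
}

#' Acoustic source specification
#'
#' @param kind `"point"` or `"aperture"`
#' @param position numeric mm position (point) or an n x d matrix of element
#'   positions (aperture)
#' @param amplitude per-element drive amplitude, Pa
#' @param phase per-element phase, rad
#' @param frequency carrier frequency, Hz
#' @export
source_spec <- function(kind = c("point", "aperture"), position,
                        amplitude = 1, phase = 0, frequency = 500e3) {
  kind <- match.arg(kind)
  if (frequency <= 0) abort_invalid("frequency must be positive")
  pos <- if (is.matrix(position)) position else matrix(position, nrow = 1)
  n <- nrow(pos)
  structure(list(kind = kind, position = pos,
                 amplitude = rep_len(amplitude, n),
                 phase = rep_len(phase, n), frequency = frequency),
            class = "source_spec")
}

#' Analytic free-field amplitude ratio (test oracle)
#'
#' Geometric spreading of a monochromatic point source in a homogeneous
#' medium (1/sqrt(r) in 2D, 1/r in 3D) times the absorption decay
#' `exp(-absorption * r)`. Defined up to a common constant; use ratios.
#'
#' @param distance m (may be a vector)
#' @param frequency Hz (unused by the lossless part; kept for signature
#'   symmetry with the solver)
#' @param sound_speed m/s
#' @param absorption Np/m
#' @param mode `"2D"` or `"3D"`
#' @export
analytic_free_field <- function(distance, frequency = 500e3,
                                sound_speed = 1482, absorption = 0,
                                mode = c("2D", "3D")) {
  mode <- match.arg(mode)
  if (any(distance <= 0)) abort_invalid("distance must be positive")
  g <- if (mode == "2D") 1 / sqrt(distance) else 1 / distance
  g * exp(-absorption * distance)
}

#' Steady-state single-frequency pressure field
#'
#' Time-steps linear first-order acoustics (staggered-grid FDTD with a
#' split-field PML) driven by a ramped continuous source, then demodulates
#' at the source frequency over an integer number of late cycles. The result
#' is the complex pressure amplitude per voxel: `p(t) = Re(P exp(-i w t))`,
#' so phase grows as `+2 pi f r / c` with propagation distance. Linear in
#' the source amplitude.
#'
#' @param medium an [acoustic_medium()] (2D matrix maps or 3D arrays)
#' @param source a [source_spec()]
#' @param config a [solver_config()]
#' @param energy_trace if `TRUE` (2D only) also return the total acoustic
#'   energy per step (used by conservation tests; run with `pml_width`
#'   effectively disabled by setting it to 0 via `closed_box`)
#' @param closed_box if `TRUE`, disable the PML (rigid walls); for energy
#'   conservation checks only
#' @param source_cycles if non-`NULL`, the source is switched off (raised
#'   cosine ramp-down) after this many carrier cycles and the wave left to
#'   propagate freely -- used with `energy_trace` to check conservation
#' @return object of class `complex_field`: complex `p` (Pa), `spacing`,
#'   `origin`, `frequency`, `pml_width`, `drive_scale` (NA until scaled)
#' @export
simulate_field <- function(medium, source, config = solver_config(),
                           energy_trace = FALSE, closed_box = FALSE,
                           source_cycles = NULL) {
  dims <- dim(medium$sound_speed)
  nd <- length(dims)
  dx <- medium$spacing * 1e-3  # mm -> m
  f0 <- source$frequency
  cmin <- min(medium$sound_speed); cmax <- max(medium$sound_speed)

  ppw <- cmin / (f0 * dx)
  if (ppw < config$min_ppw)
    abort_invalid(sprintf(
      "wavelength unresolved: %.1f points per wavelength (< %g); need spacing <= %.3g mm",
      ppw, config$min_ppw, 1e3 * cmin / (f0 * config$min_ppw)))

  # The 2nd-order staggered scheme is dispersive at the ~6 points per
  # wavelength this problem runs at. Because only one frequency is ever
  # simulated, the sound-speed map is pre-warped so the numerical phase
  # velocity at f0 equals the physical one (exact along grid axes):
  #   c_adj = dx sin(pi f dt) / (dt sin(pi f dx / c)).
  # dt and c_adj are interdependent; two fixed-point sweeps converge.
  c_adj <- medium$sound_speed
  for (it in 1:2) {
    dt_cfl <- config$cfl * dx / max(c_adj)
    spc <- ceiling(1 / (f0 * dt_cfl))     # steps per carrier cycle
    dt <- 1 / (f0 * spc)
    c_adj <- dx * sin(pi * f0 * dt) /
      (dt * sin(pi * f0 * dx / medium$sound_speed))
  }
  record_n <- config$record_cycles * spc
  # the kernel forms the pressure relaxation rate gamma = 2 alpha c from
  # the (warped) speed map; rescale alpha so gamma uses the physical speed
  alpha_eff <- medium$absorption * medium$sound_speed / c_adj

  # settle time: waves must cross the grid (and reverberate) before recording
  L <- sqrt(sum((dims * dx)^2))
  n_settle <- ceiling(config$settle_crossings * L / cmin / dt)
  n_ramp <- config$ramp_cycles * spc
  nt <- n_settle + n_ramp + record_n
  tt <- seq_len(nt) - 1L
  envelope <- ifelse(tt < n_ramp, 0.5 * (1 - cos(pi * tt / n_ramp)), 1)
  if (!is.null(source_cycles)) {
    # pulsed drive: hold for source_cycles, ramp down, then free propagation
    n_on <- n_ramp + as.integer(source_cycles * spc)
    down <- tt >= n_on & tt < n_on + n_ramp
    envelope[down] <- 0.5 * (1 + cos(pi * (tt[down] - n_on) / n_ramp))
    envelope[tt >= n_on + n_ramp] <- 0
  }

  idx <- round(sweep(source$position, 2, medium$origin) / medium$spacing)
  if (any(idx < 0) || any(sweep(idx, 2, dims - 1) > 0))
    abort_invalid("source position outside the grid")
  pml <- if (closed_box) 0L else as.integer(config$pml_width)

  if (nd == 2) {
    out <- .fdtd2d_cw(c_adj, medium$density, alpha_eff,
                      dx, dt, as.integer(nt),
                      as.integer(idx[, 1]), as.integer(idx[, 2]),
                      source$amplitude, source$phase, f0, envelope,
                      pml, as.integer(record_n), isTRUE(energy_trace))
  } else if (nd == 3) {
    if (any(dims > 128))
      abort_invalid("3D mode is supported on small grids only (<= 128^3)")
    out <- .fdtd3d_cw(as.numeric(c_adj),
                      as.numeric(medium$density),
                      as.numeric(alpha_eff),
                      as.integer(dims), dx, dt, as.integer(nt),
                      as.integer(idx[, 1]), as.integer(idx[, 2]),
                      as.integer(idx[, 3]),
                      source$amplitude, source$phase, f0, envelope,
                      pml, as.integer(record_n))
  } else abort_invalid("medium must be 2D or 3D")

  p <- out$re + 1i * out$im
  dim(p) <- dims
  structure(list(p = p, spacing = medium$spacing, origin = medium$origin,
                 frequency = f0, pml_width = pml, drive_scale = NA_real_,
                 energy = out$energy %||% NULL, dt = dt, nt = nt),
            class = "complex_field")
}

#' Mask excluding the absorbing boundary margin
#'
#' All field analysis excludes the PML margin (plus a two-voxel guard).
#' @param field a `complex_field`
#' @export
interior_mask <- function(field) {
  dims <- dim(field$p)
  m <- array(TRUE, dims)
  g <- field$pml_width + 2L
  if (g > 0) {
    for (d in seq_along(dims)) {
      idx <- rep(list(quote(expr = )), length(dims))
      ii <- c(seq_len(min(g, dims[d])), seq(max(dims[d] - g + 1L, 1L), dims[d]))
      idx[[d]] <- unique(ii)
      m <- do.call(`[<-`, c(list(m), idx, list(value = FALSE)))
    }
  }
  m
}

#' Receiver line geometry (2D)
#'
#' A horizontal sampling line `y = level` outside the head on which backward
#' simulations record amplitude and phase.
#'
#' @param level mm y-level of the line
#' @param span mm x-range sampled; `NULL` for the full grid width
#' @export
receiver_line <- function(level, span = NULL) {
  structure(list(axis = "y", level = level, span = span,
                 normal = c(0, -1)), class = "receiver_geometry")
}

#' Default receiver line for a phantom: a fixed standoff above the scalp
#' @param volume labelled volume
#' @param standoff mm of coupling water between scalp and receiver plane
#' @export
receiver_line_for <- function(volume, standoff = 6) {
  nx <- dim(volume$labels)[1]; ny <- dim(volume$labels)[2]
  centre_y <- (ny - 1) / 2 * volume$spacing + volume$origin[2]
  receiver_line(level = centre_y + volume$spec$head_semi_axes[2] + standoff)
}

#' Backward simulation: point source at the target, sampled on the receiver
#'
#' Runs [simulate_field()] with a point source at the deep target and
#' records complex amplitude and phase along the receiver line -- the
#' time-reversal step of lens design.
#'
#' @param medium acoustic medium
#' @param target mm target position
#' @param receiver a [receiver_line()]
#' @param config solver config
#' @param volume optional labelled volume; when given, the target is
#'   validated to lie inside the brain compartment
#' @param frequency carrier, Hz
#' @return object of class `receiver_field`: `x` (mm sample positions),
#'   `amplitude` (Pa), `phase` (rad, wrapped), plus geometry
#' @export
point_source_backward <- function(medium, target, receiver,
                                  config = solver_config(), volume = NULL,
                                  frequency = 500e3) {
  if (!is.null(volume)) {
    id <- world_to_index(target, volume)
    if (volume$labels[id[1], id[2]] != phantom_labels()[["brain"]])
      abort_invalid("backward-simulation target must lie inside the brain")
  }
  src <- source_spec("point", target, amplitude = 1, frequency = frequency)
  field <- simulate_field(medium, src, config)
  sample_receiver(field, receiver)
}

#' Sample a complex field on a receiver line
#' @param field complex_field
#' @param receiver a [receiver_line()]
#' @export
sample_receiver <- function(field, receiver) {
  dims <- dim(field$p)
  j <- round((receiver$level - field$origin[2]) / field$spacing) + 1L
  if (j < 1 || j > dims[2]) abort_invalid("receiver line outside the grid")
  g <- field$pml_width + 2L
  ii <- seq.int(g + 1L, dims[1] - g)
  if (!is.null(receiver$span)) {
    xs <- field$origin[1] + (ii - 1L) * field$spacing
    ii <- ii[xs >= receiver$span[1] & xs <= receiver$span[2]]
  }
  pv <- field$p[cbind(ii, j)]
  structure(list(x = field$origin[1] + (ii - 1L) * field$spacing,
                 amplitude = Mod(pv), phase = wrap_phase(Arg(pv)),
                 level = receiver$level, normal = receiver$normal,
                 spacing = field$spacing, frequency = field$frequency),
            class = "receiver_field")
}
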