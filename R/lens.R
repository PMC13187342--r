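#' Transducer pose on the receiver line
#'
#' @param centre mm x-position of the aperture centre on the receiver line
#' @param level mm y-level of the line
#' @param aperture_diameter mm (default 64, a single-element planar source)
#' @param normal unit vector pointing into the head
#' @param tie `TRUE` if the placement objective had multiple exact maxima
#' @export
transducer_pose <- function(centre, level, aperture_diameter = 64,
                            normal = c(0, -1), tie = FALSE) {
  structure(list(centre = centre, level = level,
                 aperture_diameter = aperture_diameter,
                 normal = normal, tie = tie), class = "transducer_pose")
}

#' Place the transducer by maximising received amplitude under the aperture
#'
#' Exhaustive search over candidate centres on the receiver grid: the pose
#' maximises the mean backward-simulated amplitude over the aperture
#' footprint. Ties take the first (smallest-x) candidate and set the tie
#' flag.
#'
#' @param receiver a `receiver_field` from [point_source_backward()]
#' @param aperture_diameter mm
#' @return a [transducer_pose()]
#' @export
place_transducer <- function(receiver, aperture_diameter = 64) {
  x <- receiver$x
  half <- aperture_diameter / 2
  fits <- x - min(x) >= half & max(x) - x >= half
  if (!any(fits))
    abort_invalid("aperture larger than the receiver plane")
  cand <- x[fits]
  obj <- vapply(cand, function(cc)
    mean(receiver$amplitude[abs(x - cc) <= half + 1e-9]), numeric(1))
  best <- max(obj)
  hits <- which(obj >= best - 1e-12 * best)
  transducer_pose(centre = cand[hits[1]], level = receiver$level,
                  aperture_diameter = aperture_diameter,
                  normal = receiver$normal, tie = length(hits) > 1L)
}

#' Lens material description
#'
#' @param sound_speed m/s; default 1030, a PDMS-like silicone
#' @param name label
#' @param base_thickness mm structural minimum thickness
#' @param coupling_speed m/s sound speed of the coupling medium (water)
#' @export
lens_material <- function(sound_speed = 1030, name = "PDMS",
                          base_thickness = 2, coupling_speed = 1482) {
  if (sound_speed <= 0) abort_invalid("sound_speed must be positive")
  structure(list(sound_speed = sound_speed, name = name,
                 base_thickness = base_thickness,
                 coupling_speed = coupling_speed), class = "lens_material")
}

#' Design a phase-conjugate lens from the backward receiver field
#'
#' The aperture phase is negated (time reversal / phase conjugation),
#' re-referenced to its circular mean so the lens encodes only relative
#' aberration, and converted to a thickness map. A thickness step of
#' `t_2pi = 1 / (f0 |1/c_lens - 1/c_medium|)` advances the transmitted
#' phase by one full turn; for a slow lens (c_lens < c_medium) thickness
#' `t` adds phase `+2 pi t / t_2pi` under the `P exp(-i w t)` convention,
#' so `thickness = base + (phase_map mod 2 pi) / (2 pi) * t_2pi` cancels
#' the propagation phase on transmission.
#'
#' @param receiver `receiver_field`
#' @param pose [transducer_pose()]
#' @param material [lens_material()]
#' @param frequency carrier, Hz
#' @return object of class `lens_design`: aperture sample positions `x`
#'   (mm), `phase_map` (rad, in (-pi, pi]), `thickness_map` (mm),
#'   `wrap_thickness` t_2pi (mm)
#' @export
design_lens <- function(receiver, pose, material = lens_material(),
                        frequency = 500e3) {
  if (abs(material$sound_speed - material$coupling_speed) < 1e-9)
    abort_invalid(
      "lens and coupling-medium sound speeds are equal: no phase control")
  half <- pose$aperture_diameter / 2
  sel <- abs(receiver$x - pose$centre) <= half + 1e-9
  if (!any(sel) || min(receiver$x) > pose$centre - half ||
      max(receiver$x) < pose$centre + half)
    abort_invalid("pose aperture footprint must lie inside the receiver plane")
  phi <- receiver$phase[sel]
  ref <- Arg(mean(exp(1i * phi)))            # circular mean reference
  phase_map <- wrap_phase(-(phi - ref))
  t2pi_m <- 1 / (frequency * abs(1 / material$sound_speed -
                                 1 / material$coupling_speed))
  t2pi <- t2pi_m * 1e3                        # mm
  thickness <- material$base_thickness + (phase_map %% (2 * pi)) /
    (2 * pi) * t2pi
  structure(list(x = receiver$x[sel], phase_map = phase_map,
                 thickness_map = thickness, wrap_thickness = t2pi,
                 base_thickness = material$base_thickness,
                 material = material, frequency = frequency,
                 pose = pose), class = "lens_design")
}

#' Forward verification of a lens design
#'
#' Drives the aperture as a phased line source (lens applied as a thin
#' phase screen, or optionally as a voxelised slab of lens material), then
#' rescales the field linearly so the peak pressure inside the brain mask
#' equals the protocol target, and computes focal metrics.
#'
#' @param medium acoustic medium of the phantom
#' @param pose [transducer_pose()]
#' @param lens [design_lens()] output; `NULL` runs the unlensed (flat phase)
#'   control
#' @param protocol [pulse_protocol()] (supplies the target peak pressure)
#' @param masks list with logical `brain` and `electrode` matrices
#' @param target mm target position
#' @param config solver config
#' @param lens_mode `"screen"` (thin phase screen, default) or `"slab"`
#'   (lens voxelised into the medium as material of the lens sound speed)
#' @return list with the drive-scaled `field` (complex_field) and `metrics`
#'   ([focal_metrics()] output plus `drive_scale`)
#' @export
forward_verify <- function(medium, pose, lens, protocol, masks, target,
                           config = solver_config(),
                           lens_mode = c("screen", "slab")) {
  lens_mode <- match.arg(lens_mode)
  if (is.null(masks$brain) || !any(masks$brain))
    abort_invalid("empty brain mask")
  half <- pose$aperture_diameter / 2
  nx <- dim(medium$sound_speed)[1]
  xs <- medium$origin[1] + (seq_len(nx) - 1L) * medium$spacing
  sel <- abs(xs - pose$centre) <= half + 1e-9
  ex <- xs[sel]
  phase <- rep(0, length(ex))
  if (!is.null(lens)) {
    if (abs(lens$pose$centre - pose$centre) > 1e-9 ||
        abs(lens$pose$aperture_diameter - pose$aperture_diameter) > 1e-9)
      abort_invalid("lens does not match the pose aperture")
    phase <- approx(lens$x, lens$phase_map, xout = ex, rule = 2)$y
  }
  med <- medium
  if (lens_mode == "slab" && !is.null(lens)) {
    # voxelise the thickness map into the rows just inside the aperture line
    jl <- round((pose$level - medium$origin[2]) / medium$spacing) + 1L
    th_vox <- round(approx(lens$x, lens$thickness_map, xout = ex,
                           rule = 2)$y / medium$spacing)
    ii <- which(sel)
    for (k in seq_along(ii)) {
      if (th_vox[k] < 1) next
      jj <- jl - seq_len(th_vox[k])
      jj <- jj[jj >= 1]
      med$sound_speed[ii[k], jj] <- lens$material$sound_speed
    }
    phase <- rep(0, length(ex))  # the slab itself imprints the phase
  }
  src <- source_spec("aperture",
                     cbind(ex, pose$level),
                     amplitude = 1, phase = phase,
                     frequency = protocol$fundamental_frequency)
  field <- simulate_field(med, src, config)
  inb <- masks$brain & interior_mask(field)
  peak_raw <- max(Mod(field$p)[inb])
  if (peak_raw <= 0) abort_invalid("zero field inside the brain mask")
  scale <- protocol$peak_pressure_brain / peak_raw
  field$p <- field$p * scale
  field$drive_scale <- scale
  metrics <- focal_metrics(field, masks$brain, target, masks$electrode)
  metrics$drive_scale <- scale
  list(field = field, metrics = metrics)
}

#' Focal and safety metrics of a (scaled) pressure field
#'
#' Peak search is voxel-level over the brain mask (excluding the PML
#' margin); equal maxima take the first voxel in R's column-major index
#' order. The -6 dB focal region is the connected component (4-neighbour)
#' containing the peak where amplitude >= 0.5 * peak.
#'
#' @param field complex_field
#' @param brain_mask logical matrix
#' @param target mm target position
#' @param electrode_mask logical matrix (may be `NULL`: clearance `Inf`)
#' @return object of class `focal_metrics`: `peak_pressure_brain` (Pa),
#'   `peak_location` (mm), `targeting_error` (mm), `focal_region` (logical
#'   mask), `focal_area` (mm^2), `electrode_clearance` (mm)
#' @export
focal_metrics <- function(field, brain_mask, target, electrode_mask = NULL) {
  amp <- Mod(field$p)
  if (!isTRUE(all(dim(brain_mask) == dim(amp))))
    abort_invalid("brain mask does not align with the field grid")
  inb <- brain_mask & interior_mask(field)
  if (!any(inb)) abort_invalid("empty brain mask")
  av <- amp
  av[!inb] <- -Inf
  pk <- which.max(av)                       # first among equals, col-major
  peak <- amp[pk]
  if (!is.finite(peak) || peak <= 0)
    abort_invalid("field has no positive amplitude inside the brain mask")
  pij <- arrayInd(pk, dim(amp))
  ploc <- field$origin + (as.numeric(pij) - 1) * field$spacing
  terr <- sqrt(sum((ploc - target)^2))

  # -6 dB region: flood fill from the peak through interior voxels
  thr <- 0.5 * peak
  ok <- amp >= thr & interior_mask(field)
  region <- matrix(FALSE, nrow(amp), ncol(amp))
  queue <- pk
  region[pk] <- TRUE
  nx <- nrow(amp); ny <- ncol(amp)
  while (length(queue)) {
    cur <- queue[length(queue)]
    queue <- queue[-length(queue)]
    ci <- ((cur - 1L) %% nx) + 1L
    cj <- ((cur - 1L) %/% nx) + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      ni <- ci + d[1]; nj <- cj + d[2]
      if (ni >= 1 && ni <= nx && nj >= 1 && nj <= ny) {
        id <- ni + nx * (nj - 1L)
        if (ok[id] && !region[id]) {
          region[id] <- TRUE
          queue <- c(queue, id)
        }
      }
    }
  }
  clearance <- Inf
  if (!is.null(electrode_mask) && any(electrode_mask)) {
    ei <- which(electrode_mask, arr.ind = TRUE)
    ri <- which(region, arr.ind = TRUE)
    d2 <- outer(ri[, 1], ei[, 1], `-`)^2 + outer(ri[, 2], ei[, 2], `-`)^2
    clearance <- sqrt(min(d2)) * field$spacing
  }
  structure(list(peak_pressure_brain = peak, peak_location = ploc,
                 targeting_error = terr, focal_region = region,
                 focal_area = sum(region) * field$spacing^2,
                 electrode_clearance = clearance),
            class = "focal_metrics")
}
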