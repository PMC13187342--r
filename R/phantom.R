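#' Specification of a synthetic 2D head phantom
#'
#' A concentric-layer desk-scale stand-in for a segmented CT: water exterior,
#' scalp-equivalent soft-tissue ring, a bone shell whose thickness varies
#' sinusoidally with angle (the aberrator), brain interior, and an embedded
#' electrode rod. All positions are mm in world coordinates
#' (world = origin + 0-based index * spacing); the default origin is (0, 0)
#' at the corner of the grid.
#'
#' @param grid_shape voxels per axis, default `c(221, 221)` (110.0 x 110.0 mm
#'   at 0.5 mm)
#' @param spacing voxel edge, mm
#' @param head_semi_axes outer scalp semi-axes (x, y), mm; the head is
#'   elliptical -- a circular shell would form a degenerate internal
#'   reverberation caustic that real heads do not have
#' @param scalp_thickness radial soft-tissue thickness outside the bone, mm
#' @param skull_thickness two-element mm range the (perturbed) shell
#'   thickness is clamped to
#' @param skull_aberration_amplitude amplitude of the sinusoidal thickness
#'   perturbation, mm
#' @param electrode_position mm position of the electrode tip
#' @param electrode_radius rod radius, mm
#' @param electrode_length rod length (extending toward +y), mm
#' @param target_gpi deep target (pallidal stand-in), mm
#' @param target_ventricle control target (ventricle stand-in), mm
#' @param seed integer; fixes the aberration phase and lobe count
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(grid_shape = c(221L, 221L), spacing = 0.5,
                         head_semi_axes = c(46, 40), scalp_thickness = 4,
                         skull_thickness = c(4, 7),
                         skull_aberration_amplitude = 1,
                         electrode_position = c(63, 50),
                         electrode_radius = 0.65,
                         electrode_length = 10,
                         target_gpi = c(47, 63),
                         target_ventricle = c(55, 68),
                         seed = 1L) {
  if (spacing <= 0) abort_invalid("spacing must be positive")
  if (length(grid_shape) != 2L)
    abort_invalid("phantom generation is 2D: grid_shape must have length 2")
  if (isTRUE(all.equal(target_gpi, target_ventricle)))
    abort_invalid("target_gpi and target_ventricle must differ")
  if (diff(range(skull_thickness)) < 0 || min(skull_thickness) <= 0)
    abort_invalid("skull_thickness must be a positive mm range")
  structure(as.list(environment()), class = "phantom_spec")
}

world_to_index <- function(pos, volume) {
  round((pos - volume$origin) / volume$spacing) + 1L
}

index_to_world <- function(idx, volume) {
  volume$origin + (idx - 1L) * volume$spacing
}

#' Generate a labelled head phantom from a spec
#'
#' Deterministic given `spec$seed`. Skull shell thickness is
#' `mean(range) + A * sin(k * theta + phi)` clamped to the stated range, with
#' the lobe count `k` and phase `phi` drawn from the seed.
#'
#' @param spec a [phantom_spec()]
#' @return object of class `labelled_volume`: integer `labels` matrix (codes
#'   per [phantom_labels()]), `spacing`, `origin`, the target annotations and
#'   the generating spec
#' @export
generate_head_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lb <- phantom_labels()
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]
  origin <- c(0, 0)
  centre <- (c(nx, ny) - 1) / 2 * spec$spacing  # head centred on the grid

  ab <- with_seed(derive_seed(spec$seed, "phantom/aberration"), {
    list(k = sample(3:6, 1L), phi = runif(1, 0, 2 * pi))
  })
  t0 <- mean(spec$skull_thickness)
  A <- spec$skull_aberration_amplitude

  x <- (seq_len(nx) - 1) * spec$spacing - centre[1]
  y <- (seq_len(ny) - 1) * spec$spacing - centre[2]
  X <- matrix(x, nx, ny)
  Y <- matrix(y, nx, ny, byrow = TRUE)
  R <- sqrt(X^2 + Y^2)
  TH <- atan2(Y, X)
  thick <- pmin(max(spec$skull_thickness),
                pmax(min(spec$skull_thickness), t0 + A * sin(ab$k * TH + ab$phi)))
  # elliptical layer boundaries as polar radii along each ray
  ea <- spec$head_semi_axes[1]; eb <- spec$head_semi_axes[2]
  r_scalp <- ea * eb / sqrt((eb * cos(TH))^2 + (ea * sin(TH))^2)
  r_skull <- r_scalp - spec$scalp_thickness
  r_inner <- r_skull - thick

  labels <- matrix(lb[["exterior_water"]], nx, ny)
  labels[R <= r_scalp] <- lb[["soft_tissue_csf"]]
  labels[R <= r_skull] <- lb[["bone"]]
  labels[R <= r_inner] <- lb[["brain"]]

  # electrode rod: tip at electrode_position, extending +y
  ex <- spec$electrode_position[1] - centre[1]
  ey <- spec$electrode_position[2] - centre[2]
  in_rod <- abs(X - ex) <= spec$electrode_radius &
    Y >= ey & Y <= ey + spec$electrode_length
  if (any(in_rod & labels != lb[["brain"]]))
    abort_invalid("electrode must lie fully inside the brain compartment")
  labels[in_rod] <- lb[["electrode"]]

  vol <- structure(list(labels = labels, spacing = spec$spacing,
                        origin = origin, spec = spec,
                        aberration = ab,
                        targets = list(gpi = spec$target_gpi,
                                       ventricle = spec$target_ventricle)),
                   class = "labelled_volume")
  for (tg in vol$targets) {
    id <- world_to_index(tg, vol)
    if (id[1] < 1 || id[2] < 1 || id[1] > nx || id[2] > ny ||
        labels[id[1], id[2]] != lb[["brain"]])
      abort_invalid("target must lie inside the brain compartment")
  }
  vol
}

#' Logical mask for one phantom label
#' @param volume labelled volume
#' @param label label name, see [phantom_labels()]
#' @export
label_mask <- function(volume, label) {
  volume$labels == phantom_labels()[[label]]
}

#' @export
print.labelled_volume <- function(x, ...) {
  cat(sprintf("Labelled volume %s at %.2g mm spacing\n",
              paste(dim(x$labels), collapse = " x "), x$spacing))
  tab <- table(factor(x$labels, levels = phantom_labels(),
                      labels = names(phantom_labels())))
  print(tab)
  invisible(x)
}
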