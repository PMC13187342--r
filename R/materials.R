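#' Phantom label codes
#'
#' Integer codes used in labelled volumes: 0 exterior/water, 1 bone,
#' 2 soft tissue/CSF, 3 brain, 4 electrode.
#' @export
phantom_labels <- function() {
  c(exterior_water = 0L, bone = 1L, soft_tissue_csf = 2L,
    brain = 3L, electrode = 4L)
}

#' Load a material property table
#'
#' Reads per-label acoustic and thermal properties from YAML. The table
#' shipped with the package holds literature substitute values (see the file
#' header); supply your own path to override.
#'
#' @param path YAML file; `NULL` for the packaged defaults
#' @return data.frame, one row per label, with columns `label`, `code`,
#'   `sound_speed`, `density`, `absorption`, `thermal_conductivity`,
#'   `specific_heat`, `perfusion_rate`
#' @export
material_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "materials.yaml", package = "betalens")
  raw <- yaml::read_yaml(path)
  codes <- phantom_labels()
  missing <- setdiff(names(codes), names(raw))
  if (length(missing))
    abort_invalid(paste0("material table missing label(s): ",
                         paste(missing, collapse = ", ")))
  tab <- do.call(rbind, lapply(names(codes), function(lb) {
    m <- raw[[lb]]
    data.frame(label = lb, code = codes[[lb]],
               sound_speed = m$sound_speed, density = m$density,
               absorption = m$absorption,
               thermal_conductivity = m$thermal_conductivity,
               specific_heat = m$specific_heat,
               perfusion_rate = m$perfusion_rate)
  }))
  if (any(tab$sound_speed <= 0) || any(tab$density <= 0) ||
      any(tab$specific_heat <= 0))
    abort_invalid("sound_speed, density and specific_heat must be positive")
  if (any(tab$absorption < 0) || any(tab$perfusion_rate < 0))
    abort_invalid("absorption and perfusion_rate must be non-negative")
  tab
}

map_property <- function(labels, materials, property) {
  lut <- numeric(max(materials$code) + 1L)
  lut[materials$code + 1L] <- materials[[property]]
  out <- lut[labels + 1L]
  dim(out) <- dim(labels)
  out
}

#' Build an acoustic medium from a labelled volume
#'
#' @param volume a [generate_head_phantom()] labelled volume
#' @param materials a [material_table()]
#' @return object of class `acoustic_medium` with per-voxel `sound_speed`,
#'   `density` and `absorption` maps sharing the volume's grid geometry
#' @export
acoustic_medium <- function(volume, materials = material_table()) {
  structure(list(
    sound_speed = map_property(volume$labels, materials, "sound_speed"),
    density = map_property(volume$labels, materials, "density"),
    absorption = map_property(volume$labels, materials, "absorption"),
    spacing = volume$spacing, origin = volume$origin
  ), class = "acoustic_medium")
}

#' Build a homogeneous acoustic medium (test and free-field use)
#'
#' @param grid_shape voxels per axis (length 2 or 3)
#' @param spacing voxel edge, mm
#' @param sound_speed m/s
#' @param density kg/m^3
#' @param absorption Np/m at the working frequency
#' @export
homogeneous_medium <- function(grid_shape, spacing = 0.5,
                               sound_speed = 1482, density = 1000,
                               absorption = 0) {
  mk <- function(v) array(v, dim = grid_shape)
  structure(list(sound_speed = mk(sound_speed), density = mk(density),
                 absorption = mk(absorption), spacing = spacing,
                 origin = rep(0, length(grid_shape))),
            class = "acoustic_medium")
}

#' Build a thermal medium from a labelled volume
#'
#' The Pennes perfusion sink uses the local tissue density and specific heat
#' for the blood-side product (configurable via `blood_rho_c`, W s/(m^3 K)).
#'
#' @param volume labelled volume
#' @param materials a [material_table()]
#' @param baseline_temperature arterial/baseline temperature, degrees C
#' @param blood_rho_c optional scalar rho_b * C_b; `NULL` uses local tissue
#' @return object of class `thermal_medium`
#' @export
thermal_medium <- function(volume, materials = material_table(),
                           baseline_temperature = 37, blood_rho_c = NULL) {
  rho <- map_property(volume$labels, materials, "density")
  ch <- map_property(volume$labels, materials, "specific_heat")
  w <- map_property(volume$labels, materials, "perfusion_rate")
  rbc <- if (is.null(blood_rho_c)) rho * ch else blood_rho_c
  structure(list(
    conductivity = map_property(volume$labels, materials,
                                "thermal_conductivity"),
    density = rho, specific_heat = ch, perfusion_rate = w,
    perfusion_sink = rbc * w,  # W/(m^3 K)
    baseline_temperature = baseline_temperature,
    spacing = volume$spacing, origin = volume$origin
  ), class = "thermal_medium")
}
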