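#' Write a gridded map (labels, amplitude, phase, temperature) as NIfTI
#'
#' Spacing is carried in the header pixdim, mm units. Complex fields are
#' written by the caller as amplitude/phase or real/imaginary pairs.
#'
#' @param x numeric matrix or 3D array
#' @param path output file (`.nii` / `.nii.gz`)
#' @param spacing voxel edge, mm
#' @export
write_nifti_map <- function(x, path, spacing = 0.5) {
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- rep(spacing, length(dim(x)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI map written by [write_nifti_map()]
#' @param path file path
#' @return list with `data` (array) and `spacing` (mm)
#' @export
read_nifti_map <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = unclass(as.array(img)),
       spacing = RNifti::pixdim(img)[1])
}

#' Export a complex pressure field as amplitude + phase NIfTI pair
#' @param field a `complex_field`
#' @param base path prefix; writes `<base>_amplitude.nii.gz` and
#'   `<base>_phase.nii.gz`
#' @export
write_field <- function(field, base) {
  write_nifti_map(Mod(field$p), paste0(base, "_amplitude.nii.gz"),
                  field$spacing)
  write_nifti_map(Arg(field$p), paste0(base, "_phase.nii.gz"),
                  field$spacing)
  invisible(base)
}

#' Export a lens design as a CSV table (and optionally NIfTI)
#'
#' @param lens a [design_lens()] output
#' @param path CSV path; columns x (mm), phase (rad), thickness (mm)
#' @export
write_lens_csv <- function(lens, path) {
  write.csv(data.frame(x = lens$x, phase = lens$phase_map,
                       thickness = lens$thickness_map),
            path, row.names = FALSE)
  invisible(path)
}
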