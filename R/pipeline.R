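#' @noRd
abort_dependency <- function(msg) {
  stop(structure(class = c("betalens_dependency_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

default_pipeline_config <- function() {
  list(
    stages = c("plan", "thermal", "ephys", "artefact", "stats"),
    seed = 1L,
    phantom = list(),                    # phantom_spec() overrides
    protocol = list(),                   # pulse_protocol() overrides
    participants = 4L,
    block_duration = 60,                 # s per rest block in ephys stage
    thermal_duration = 300,              # s simulated per active block
    thermal_mode = "train_resolved",
    artefact_pressures = c(200e3, 400e3, 600e3),
    artefact_duration = 20
  )
}

#' Run the end-to-end desk-scale pipeline
#'
#' Executes the selected stages in dependency order and writes a report
#' JSON plus CSV tables and NIfTI maps to `outdir`:
#' \describe{
#'   \item{plan}{phantom generation, backward simulation, transducer
#'     placement, lens design, forward verification (focal metrics).}
#'   \item{thermal}{heat source and bioheat solve on the plan's field,
#'     safety report (requires `plan`).}
#'   \item{ephys}{synthetic participant sessions and the sham-normalised
#'     band-power contrast tables.}
#'   \item{artefact}{electrode-sonication beta-power change for the
#'     therapeutic and low-PRF control protocols across pressures.}
#'   \item{stats}{group statistics over the ephys participants: paired t
#'     on the site contrast per channel/band with BH-FDR across the
#'     emitted family, reaction-time contrast, post-hoc power
#'     (requires `ephys`).}
#' }
#' Identical config and seed give an identical report.
#'
#' @param config list or YAML file path; see
#'   `betalens:::default_pipeline_config()` for keys
#' @param outdir output directory (created if needed)
#' @param seed optional master seed override
#' @return the report, invisibly (also written as `report.json`)
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("betalens_run"),
                         seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(default_pipeline_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages
  bad <- setdiff(stages, c("plan", "thermal", "ephys", "artefact", "stats"))
  if (length(bad))
    abort_invalid(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  report <- list(package = "betalens",
                 version = as.character(utils::packageVersion("betalens")),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 seed = cfg$seed, stages = stages,
                 config = cfg[setdiff(names(cfg), "stages")],
                 notes = c("2D desk-scale reduction of a 3D pipeline",
                           "voxel-level peak localisation (errors grid-quantised)",
                           "PSD normalisation: summed power over 4-45 Hz"))
  protocol <- do.call(pulse_protocol, cfg$protocol)
  report$protocol_timing <- protocol_timing(protocol)
  plan <- NULL

  if ("plan" %in% stages) {
    spec <- do.call(phantom_spec,
                    modifyList(list(seed = cfg$seed), cfg$phantom))
    vol <- generate_head_phantom(spec)
    med <- acoustic_medium(vol)
    rec <- receiver_line_for(vol)
    bw <- point_source_backward(med, vol$targets$gpi, rec, volume = vol)
    pose <- place_transducer(bw)
    lens <- design_lens(bw, pose)
    masks <- list(brain = label_mask(vol, "brain"),
                  electrode = label_mask(vol, "electrode"))
    fv <- forward_verify(med, pose, lens, protocol, masks, vol$targets$gpi)
    write_nifti_map(vol$labels, file.path(outdir, "labels.nii.gz"),
                    vol$spacing)
    write_field(fv$field, file.path(outdir, "forward"))
    write_lens_csv(lens, file.path(outdir, "lens.csv"))
    m <- fv$metrics
    report$plan <- list(
      targeting_error_mm = m$targeting_error,
      peak_location_mm = m$peak_location,
      electrode_clearance_mm = m$electrode_clearance,
      focal_area_mm2 = m$focal_area,
      drive_scale = m$drive_scale,
      pose_centre_mm = pose$centre, pose_tie = pose$tie,
      wrap_thickness_mm = lens$wrap_thickness)
    plan <- list(vol = vol, med = med, fv = fv)
  }

  if ("thermal" %in% stages) {
    if (is.null(plan))
      abort_dependency("thermal stage requires the plan stage in this run")
    tmed <- thermal_medium(plan$vol)
    qmode <- if (cfg$thermal_mode == "train_resolved") "pulse_peak"
             else "duty_averaged"
    q <- heat_source(plan$fv$field, plan$med, protocol, qmode)
    th <- simulate_bioheat(q, tmed, cfg$thermal_duration, cfg$thermal_mode)
    sr <- safety_report(th, plan$fv$metrics)
    write_nifti_map(th$final, file.path(outdir, "delta_t.nii.gz"),
                    tmed$spacing)
    report$thermal <- sr[c("max_rise", "hottest_location",
                           "electrode_clearance", "thermal_pass",
                           "clearance_pass", "overall_pass")]
  }

  contrasts <- NULL
  behaviours <- NULL
  if ("ephys" %in% stages) {
    sched <- session_schedule(block_duration = cfg$block_duration)
    contrasts <- list()
    behaviours <- list()
    for (p in seq_len(cfg$participants)) {
      ps <- participant_spec(seed = derive_seed(cfg$seed,
                                                paste0("participant/", p)))
      ses <- generate_session(ps, sched)
      contrasts[[p]] <- block_contrast(ses)$contrasts
      behaviours[[p]] <- generate_behaviour(ps)
    }
    tab <- do.call(rbind, lapply(seq_along(contrasts), function(p)
      cbind(participant = p, contrasts[[p]])))
    write.csv(tab, file.path(outdir, "contrasts.csv"), row.names = FALSE)
    report$ephys <- list(participants = cfg$participants,
                         contrast_table = "contrasts.csv")
  }

  if ("artefact" %in% stages) {
    rows <- list()
    base <- artefact_timeseries(protocol, 0, duration = cfg$artefact_duration,
                                seed = cfg$seed)
    theta <- pulse_protocol(prf = 5, pulse_duration = 20e-3,
                            train_duration = 2.5)  # low-PRF positive control
    base_theta <- artefact_timeseries(theta, 0,
                                      duration = cfg$artefact_duration,
                                      seed = cfg$seed)
    for (pr in cfg$artefact_pressures) {
      r130 <- artefact_timeseries(protocol, pr,
                                  duration = cfg$artefact_duration,
                                  seed = cfg$seed)
      r5 <- artefact_timeseries(theta, pr, duration = cfg$artefact_duration,
                                seed = cfg$seed)
      rows[[length(rows) + 1L]] <- data.frame(
        pressure_kpa = pr / 1e3,
        beta_change_130hz = artefact_beta_change(r130, base),
        beta_change_5hz = artefact_beta_change(r5, base_theta))
    }
    art <- do.call(rbind, rows)
    write.csv(art, file.path(outdir, "artefact.csv"), row.names = FALSE)
    report$artefact <- art
  }

  if ("stats" %in% stages) {
    if (is.null(contrasts))
      abort_dependency("stats stage requires the ephys stage in this run")
    if (cfg$participants < 2)
      abort_invalid("group statistics need at least 2 participants")
    scfg <- stats_config(seed = cfg$seed)
    family <- list()
    # site contrast of relative beta reduction, ipsilateral and
    # contralateral STN (mean over the two bipolar channels per side)
    side_vals <- list()
    for (side in c("Left", "Right")) {
      vals <- sapply(contrasts, function(ct) {
        sel <- grepl(paste0("^", side), ct$channel) & ct$band == "beta"
        mean(ct$site_rel[sel])
      })
      side_vals[[side]] <- vals
      family[[paste0("stn_", tolower(side), "_beta_site_rel")]] <-
        paired_contrast_test(vals, scfg)
    }
    rtv <- sapply(behaviours, function(b) rt_contrast(b)$site_contrast)
    family[["rt_site_contrast"]] <- paired_contrast_test(rtv, scfg)
    padj <- bh_adjust(sapply(family, `[[`, "p"))
    for (i in seq_along(family)) family[[i]]$p_fdr <- padj[i]
    eff <- family[["stn_left_beta_site_rel"]]
    report$stats <- list(
      family = names(family),
      tests = lapply(family, unclass),
      posthoc_power = posthoc_power(eff$mean, sd(side_vals[["Left"]]),
                                    length(contrasts), scfg))
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(report)
}
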