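#' Channel layout of an emulated recording session
#'
#' Four bipolar subthalamic LFP channels at 250 Hz and two bipolar
#' sensorimotor EEG channels at 4096 Hz; each channel belongs to a signal
#' group that owns its oscillatory peaks and block gains.
#' @noRd
channel_layout <- function() {
  list(
    lfp = c("Left_0-2" = "stn_left", "Left_1-3" = "stn_left",
            "Right_0-2" = "stn_right", "Right_1-3" = "stn_right"),
    eeg = c("C3Cz" = "m1_left", "C4Cz" = "m1_right"),
    lfp_rate = 250, eeg_rate = 4096
  )
}

#' Default oscillatory peaks per channel group
#'
#' Distinct low-beta (13-20 Hz) and high-beta (21-30 Hz) peaks in the STN
#' groups, weaker beta in the motor-cortex groups.
#' @noRd
default_peaks <- function() {
  rbind(
    data.frame(group = "stn_left", band = c("low_beta", "high_beta"),
               centre = c(17, 25), amplitude = c(1.0, 0.7),
               bandwidth = c(4, 6)),
    data.frame(group = "stn_right", band = c("low_beta", "high_beta"),
               centre = c(18, 26), amplitude = c(1.0, 0.7),
               bandwidth = c(4, 6)),
    data.frame(group = "m1_left", band = c("low_beta", "high_beta"),
               centre = c(17, 25), amplitude = c(0.6, 0.45),
               bandwidth = c(4, 6)),
    data.frame(group = "m1_right", band = c("low_beta", "high_beta"),
               centre = c(18, 26), amplitude = c(0.6, 0.45),
               bandwidth = c(4, 6))
  )
}

#' Virtual participant specification for the session generator
#'
#' Defines the planted signal model: 1/f aperiodic background, band-limited
#' stochastic beta oscillations per channel group, per-block log-normal
#' gain modulation shared between ipsilateral STN and M1, multiplicative
#' beta suppression during active stimulation blocks on the target day,
#' day-level baseline drift, optional tremor contamination, and the
#' reaction-time effect.
#'
#' @param aperiodic list with `slope` (1/f exponent) and `offset`
#'   (background RMS in signal units)
#' @param peaks data.frame with columns group, band, centre (Hz),
#'   amplitude (RMS units), bandwidth (Hz); see defaults
#' @param suppression_factor named amplitude multipliers in (0, 1] applied
#'   to left-STN beta during active blocks on `GPi_day`
#'   (`low_beta`, `high_beta`); the ipsilateral M1 group receives
#'   `s^coupling`
#' @param contralateral_factor same for right-STN (default 1: no planted
#'   contralateral effect)
#' @param ipsilateral_coupling named vector `c(left=, right=)` in `[0, 1]`:
#'   fraction of the STN block log-gain shared with the same-side M1
#'   channel (and exponent applied to its suppression)
#' @param gain_sigma sd of the per-block log-normal gain (log scale)
#' @param day_drift multiplicative change of beta amplitude on the second
#'   day relative to the first (diurnal/day-to-day variation stand-in)
#' @param tremor list with `centre` (Hz, 4-6) and `amplitude` (RMS units;
#'   0 disables) added to STN channels
#' @param noise_sd white measurement noise RMS
#' @param rt list with `median` (s, median reaction time above the 0.1 s
#'   floor plus the floor), `sdlog` (log-normal scale), `gpi_reduction` and
#'   `ventricle_reduction` (planted normalised-median reductions, fractions)
#' @param seed master seed; all generator randomness derives from it
#' @return object of class `participant_spec`
#' @export
participant_spec <- function(aperiodic = list(slope = 1.5, offset = 1),
                             peaks = default_peaks(),
                             suppression_factor = c(low_beta = 0.8,
                                                    high_beta = 0.9),
                             contralateral_factor = c(low_beta = 1,
                                                      high_beta = 1),
                             ipsilateral_coupling = c(left = 0.9, right = 0),
                             gain_sigma = 0.05,
                             day_drift = 1.1,
                             tremor = list(centre = 5, amplitude = 0),
                             noise_sd = 0.3,
                             rt = list(median = 0.55, sdlog = 0.35,
                                       gpi_reduction = 0.177,
                                       ventricle_reduction = 0),
                             seed = 1L) {
  if (any(suppression_factor <= 0) || any(suppression_factor > 1))
    abort_invalid("suppression factors must lie in (0, 1]")
  if (any(ipsilateral_coupling < 0) || any(ipsilateral_coupling > 1))
    abort_invalid("ipsilateral_coupling must lie in [0, 1]")
  if (any(peaks$bandwidth <= 0)) abort_invalid("bandwidths must be positive")
  if (!is.null(tremor$amplitude) && tremor$amplitude > 0 &&
      (tremor$centre < 4 || tremor$centre > 6))
    abort_invalid("tremor centre must lie in 4-6 Hz")
  structure(as.list(environment()), class = "participant_spec")
}

#' Block schedule for a two-day sham/active cross-over session
#'
#' Each day holds a sham block followed by an active block (the sham block
#' always precedes its active counterpart, mirroring the within-day
#' normalisation design).
#'
#' @param days day labels in temporal order
#' @param block_duration s per block
#' @param gap s between blocks
#' @param task task annotation for all blocks (`"rest"` or `"rdm"`)
#' @param reps sham/active pairs per day
#' @return data.frame with columns `block`, `day`, `condition`, `task`,
#'   `start`, `duration`
#' @export
session_schedule <- function(days = c("GPi_day", "Ventricle_day"),
                             block_duration = 300, gap = 60,
                             task = "rest", reps = 1L) {
  rows <- list()
  t <- 0
  b <- 1L
  for (d in days) {
    for (r in seq_len(reps)) {
      for (cond in c("sham", "active")) {
        rows[[length(rows) + 1L]] <- data.frame(
          block = b, day = d, condition = cond, task = task,
          start = t, duration = block_duration)
        t <- t + block_duration + gap
        b <- b + 1L
      }
    }
    t <- t + 3 * gap  # between-day break
  }
  do.call(rbind, rows)
}

validate_schedule <- function(schedule) {
  req <- c("block", "day", "condition", "task", "start", "duration")
  if (is.null(schedule) || !all(req %in% names(schedule)) ||
      nrow(schedule) == 0L)
    abort_invalid("schedule is empty or missing required columns")
  for (d in unique(schedule$day)) {
    sd <- schedule[schedule$day == d, ]
    sd <- sd[order(sd$start), ]
    if (any(utils::head(sd$start + sd$duration, -1) > sd$start[-1] + 1e-9))
      abort_invalid(sprintf("blocks overlap within day %s", d))
    if (!any(sd$condition == "sham") || !any(sd$condition == "active"))
      abort_invalid(sprintf("day %s must contain sham and active blocks", d))
    if (min(sd$start[sd$condition == "sham"]) >
        min(sd$start[sd$condition == "active"]))
      abort_invalid(sprintf("sham must precede active within day %s", d))
  }
  invisible(schedule)
}

#' 1/f-shaped background noise, scaled to unit RMS within the analysis band
#'
#' The aperiodic `offset` parameter is defined as the background RMS
#' inside 4-45 Hz (the analysed range), so oscillation amplitudes and the
#' background are on a common, analysis-relevant scale; the (much larger)
#' infra-slow 1/f power below the band rides along untouched.
#' @noRd
one_over_f <- function(n, fs, slope, band = c(4, 45)) {
  x <- rnorm(n)
  X <- fft(x)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                     # two-sided frequency magnitudes
  g <- c(0, (f[-1] / 1)^(-slope / 2))      # kill DC, shape the rest
  Y <- X * g
  y <- Re(fft(Y, inverse = TRUE)) / n
  inband <- f >= band[1] & f <= band[2]
  yb <- Re(fft(Y * inband, inverse = TRUE)) / n
  y / sd(yb)
}

#' Band-limited stochastic oscillation (unit RMS)
#'
#' White noise shaped in the frequency domain by a Gaussian band-pass
#' (FWHM = bandwidth) centred on the peak -- robust at any sampling rate,
#' unlike narrow IIR designs at 4096 Hz.
#' @noRd
narrowband <- function(n, fs, centre, bandwidth) {
  x <- rnorm(n)
  X <- fft(x)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  sig <- bandwidth / 2.355
  g <- exp(-(f - centre)^2 / (2 * sig^2))
  y <- Re(fft(X * g, inverse = TRUE)) / n
  y / sd(y)
}

#' Band power of a vector by direct Fourier sum (generator bookkeeping)
#' @noRd
fft_band_power <- function(x, fs, band) {
  n <- length(x)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  sel <- half & f >= band[1] & f <= band[2]
  sum(2 * Mod(X[sel])^2 / n^2)
}

#' Generate a multi-rate recording session with known ground truth
#'
#' Every channel is the sum of a 1/f background, band-limited stochastic
#' beta oscillations scaled by per-block log-normal gains (ipsilateral
#' STN and M1 share theirs according to the coupling), white noise, and --
#' in active blocks on the stimulated day -- the planted multiplicative
#' beta suppression. The ground truth records, per block, channel and
#' band, the realised oscillation power, background and noise band powers
#' (by direct Fourier sums on the clean constituents), realised gains and
#' applied suppression, enabling parameter-recovery tests downstream.
#'
#' @param spec a [participant_spec()]
#' @param schedule a [session_schedule()] data.frame
#' @param channels which channel sets to generate: `"all"`, `"lfp"` (skips
#'   the expensive 4096 Hz EEG streams), or `"eeg"`
#' @return list of class `recording_session`: `schedule`, per-block `data`
#'   (matrices `lfp` n x 4, `eeg` n x 2), `sync` (TENS pulse times per
#'   stream and the true inter-stream offset), `ground_truth`, `spec`
#' @export
generate_session <- function(spec, schedule = session_schedule(),
                             channels = c("all", "lfp", "eeg")) {
  channels <- match.arg(channels)
  stopifnot(inherits(spec, "participant_spec"))
  validate_schedule(schedule)
  lay <- channel_layout()
  days <- unique(schedule$day)
  nb <- nrow(schedule)

  groups <- unique(c(lay$lfp, lay$eeg))
  # per-block log-gains: M1 shares the same-side STN gain via the coupling
  gains <- with_seed(derive_seed(spec$seed, "session/gains"), {
    z <- matrix(rnorm(nb * 2), nb, 2,
                dimnames = list(NULL, c("stn_left", "stn_right")))
    zo <- matrix(rnorm(nb * 2), nb, 2,
                 dimnames = list(NULL, c("m1_left", "m1_right")))
    cl <- spec$ipsilateral_coupling[["left"]]
    cr <- spec$ipsilateral_coupling[["right"]]
    g <- cbind(
      stn_left = z[, "stn_left"],
      stn_right = z[, "stn_right"],
      m1_left = cl * z[, "stn_left"] + sqrt(1 - cl^2) * zo[, "m1_left"],
      m1_right = cr * z[, "stn_right"] + sqrt(1 - cr^2) * zo[, "m1_right"])
    exp(spec$gain_sigma * g)
  })

  suppression_for <- function(group, day, condition, band) {
    if (condition != "active") return(1)
    s <- 1
    if (day == days[1]) {                  # stimulated (GPi) day
      if (group == "stn_left") s <- spec$suppression_factor[[band]]
      if (group == "m1_left")
        s <- spec$suppression_factor[[band]]^
          spec$ipsilateral_coupling[["left"]]
      if (group == "stn_right") s <- spec$contralateral_factor[[band]]
    }
    s
  }

  bands <- band_defs()
  gt_rows <- list()
  data <- vector("list", nb)

  gen_channel <- function(ch, group, fs, blk, bi) {
    n <- round(blk$duration * fs)
    drift <- spec$day_drift^(match(blk$day, days) - 1)
    bg <- one_over_f(n, fs, spec$aperiodic$slope) * spec$aperiodic$offset
    pk <- spec$peaks[spec$peaks$group == group, , drop = FALSE]
    comp <- matrix(0, n, max(1L, nrow(pk)))
    s_applied <- numeric(nrow(pk))
    for (k in seq_len(nrow(pk))) {
      s <- suppression_for(group, blk$day, blk$condition, pk$band[k])
      s_applied[k] <- s
      comp[, k] <- narrowband(n, fs, pk$centre[k], pk$bandwidth[k]) *
        pk$amplitude[k] * gains[bi, group] * s * drift
    }
    trem <- 0
    if (spec$tremor$amplitude > 0 && group %in% c("stn_left", "stn_right"))
      trem <- narrowband(n, fs, spec$tremor$centre, 1.5) *
        spec$tremor$amplitude
    noise <- rnorm(n, sd = spec$noise_sd)
    x <- bg + rowSums(comp) + trem + noise
    # bookkeeping: realised powers of the clean constituents
    osc <- rowSums(comp)
    for (bn in c("beta", "low_beta", "high_beta")) {
      gt_rows[[length(gt_rows) + 1L]] <<- data.frame(
        block = blk$block, day = blk$day, condition = blk$condition,
        channel = ch, group = group, band = bn,
        osc_power = fft_band_power(osc, fs, bands[[bn]]),
        bg_power = fft_band_power(bg + trem, fs, bands[[bn]]),
        noise_power = fft_band_power(noise, fs, bands[[bn]]),
        gain = gains[bi, group],
        suppression = if (nrow(pk))
          s_applied[match(bn, pk$band, nomatch = 1L)] else 1)
    }
    gt_rows[[length(gt_rows) + 1L]] <<- data.frame(
      block = blk$block, day = blk$day, condition = blk$condition,
      channel = ch, group = group, band = "analysis",
      osc_power = fft_band_power(osc, fs, bands$analysis),
      bg_power = fft_band_power(bg + trem, fs, bands$analysis),
      noise_power = fft_band_power(noise, fs, bands$analysis),
      gain = gains[bi, group], suppression = 1)
    x
  }

  for (bi in seq_len(nb)) {
    blk <- schedule[bi, ]
    entry <- list()
    if (channels %in% c("all", "lfp")) {
      entry$lfp <- with_seed(
        derive_seed(spec$seed, paste0("session/lfp/", blk$block)),
        vapply(names(lay$lfp), function(ch)
          gen_channel(ch, lay$lfp[[ch]], lay$lfp_rate, blk, bi),
          numeric(round(blk$duration * lay$lfp_rate))))
    }
    if (channels %in% c("all", "eeg")) {
      entry$eeg <- with_seed(
        derive_seed(spec$seed, paste0("session/eeg/", blk$block)),
        vapply(names(lay$eeg), function(ch)
          gen_channel(ch, lay$eeg[[ch]], lay$eeg_rate, blk, bi),
          numeric(round(blk$duration * lay$eeg_rate))))
    }
    data[[bi]] <- entry
  }

  sync <- with_seed(derive_seed(spec$seed, "session/sync"), {
    base <- sort(runif(8, 1, min(30, schedule$duration[1])))
    off <- sample(-50:50, 1)
    list(eeg = base, lfp = base + off / lay$lfp_rate,
         true_offset_samples = off)
  })

  gt <- list(blocks = do.call(rbind, gt_rows), gains = gains,
             days = days, spec = spec)
  structure(list(schedule = schedule, data = data, sync = sync,
                 lfp_channels = names(lay$lfp), lfp_rate = lay$lfp_rate,
                 eeg_channels = names(lay$eeg), eeg_rate = lay$eeg_rate,
                 ground_truth = gt, spec = spec),
            class = "recording_session")
}

#' Planted (ground-truth) normalised band-power contrasts of a session
#'
#' Computes, from the generator's realised constituent powers, the same
#' quantities the analysis pipeline estimates: normalised band power per
#' block, per-day relative change of active vs sham, and the
#' target-day-minus-control-day site contrast. This is the oracle for
#' parameter-recovery tests.
#'
#' @param session a [generate_session()] output
#' @return data.frame per channel x band with columns `rel_day1`,
#'   `rel_day2` (percent relative reduction active vs sham) and `site_rel`
#'   (their difference, percent)
#' @export
planted_contrast <- function(session) {
  gt <- session$ground_truth$blocks
  days <- session$ground_truth$days
  tot <- gt[gt$band == "analysis", ]
  tot$total <- tot$osc_power + tot$bg_power + tot$noise_power
  out <- list()
  for (ch in unique(gt$channel)) {
    for (bn in c("beta", "low_beta", "high_beta")) {
      rels <- sapply(days, function(d) {
        pows <- sapply(c("sham", "active"), function(cond) {
          rows <- gt[gt$channel == ch & gt$band == bn &
                     gt$day == d & gt$condition == cond, ]
          trow <- tot[tot$channel == ch & tot$day == d &
                      tot$condition == cond, ]
          # normalised band power averaged over that day's blocks
          mean((rows$osc_power + rows$bg_power + rows$noise_power) /
               trow$total[match(rows$block, trow$block)])
        })
        100 * (pows[["sham"]] - pows[["active"]]) / pows[["sham"]]
      })
      out[[length(out) + 1L]] <- data.frame(
        channel = ch, band = bn, rel_day1 = rels[1], rel_day2 = rels[2],
        site_rel = rels[1] - rels[2])
    }
  }
  do.call(rbind, out)
}
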