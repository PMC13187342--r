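#' Frequency band definitions
#'
#' Beta 13-30 Hz split into low beta 13-20 Hz and high beta 21-30 Hz
#' (inclusive band edges on the 1 Hz Welch grid, so the 20 Hz bin belongs
#' to low beta and the 21 Hz bin to high beta), the 4-45 Hz analysis range,
#' and the 4-6 Hz tremor band.
#' @export
band_defs <- function() {
  list(beta = c(13, 30), low_beta = c(13, 20), high_beta = c(21, 30),
       analysis = c(4, 45), tremor = c(4, 6))
}

#' Preprocessing configuration
#'
#' @param bandpass Hz pair; zero-phase band-pass limits
#' @param order Butterworth order of the band-pass prototype (applied
#'   forward and backward, doubling the effective order)
#' @param detrend remove a linear trend
#' @param dc_remove remove the mean
#' @param target_rate Hz; higher-rate streams are resampled to this before
#'   filtering
#' @export
preprocess_config <- function(bandpass = c(4, 45), order = 8,
                              detrend = TRUE, dc_remove = TRUE,
                              target_rate = 250) {
  if (bandpass[1] <= 0 || bandpass[2] <= bandpass[1] ||
      bandpass[2] >= target_rate / 2)
    abort_invalid("need 0 < low < high < target_rate/2")
  structure(as.list(environment()), class = "preprocess_config")
}

#' Preprocess one channel: resample, detrend, DC-remove, band-pass
#'
#' Streams above `target_rate` are low-pass filtered (zero-phase
#' Butterworth at 80% of the target Nyquist) and linearly interpolated
#' onto the target clock before the band-pass. The band-pass is zero-phase
#' (forward-backward), so beta bursts keep their timing.
#'
#' @param x numeric signal
#' @param fs its sampling rate, Hz
#' @param config a [preprocess_config()]
#' @return list with `x` (clean signal) and `fs` (target rate)
#' @export
preprocess <- function(x, fs, config = preprocess_config()) {
  if (fs < 2 * config$bandpass[2])
    abort_invalid("sampling rate below twice the band-pass upper edge")
  if (length(x) < 8 * fs / config$bandpass[1])
    abort_invalid("signal too short for band-pass filter transients")
  if (fs > config$target_rate) {
    aa <- signal::butter(8, 0.8 * (config$target_rate / 2) / (fs / 2),
                         type = "low")
    x <- signal::filtfilt(aa, x)
    t_old <- (seq_along(x) - 1) / fs
    n_new <- floor(utils::tail(t_old, 1) * config$target_rate) + 1
    t_new <- (seq_len(n_new) - 1) / config$target_rate
    x <- approx(t_old, x, xout = t_new)$y
    fs <- config$target_rate
  }
  if (config$dc_remove) x <- x - mean(x)
  if (config$detrend) {
    tt <- seq_along(x)
    x <- stats::residuals(lm(x ~ tt))
  }
  bp <- signal::butter(config$order, config$bandpass / (fs / 2),
                       type = "pass")
  x <- signal::filtfilt(bp, x)
  list(x = as.numeric(x), fs = fs)
}

#' Align two event streams by cross-correlating binarised pulse trains
#'
#' Sync pulses (e.g. TENS markers) recorded on both devices are binned at
#' the common rate and the integer-sample lag maximising their
#' cross-correlation is returned: the offset to subtract from the first
#' stream's clock to land on the second's.
#'
#' @param events_a,events_b pulse times (s) in each stream
#' @param rate common clock, Hz
#' @param max_lag maximum |lag| searched, samples
#' @return integer sample offset such that `events_a - offset/rate`
#'   matches `events_b`
#' @export
align_streams <- function(events_a, events_b, rate = 250, max_lag = 250) {
  if (length(events_a) < 3 || length(events_b) < 3)
    abort_invalid("need at least 3 sync pulses in each stream")
  lo <- floor(min(events_a, events_b) * rate)
  hi <- ceiling(max(events_a, events_b) * rate)
  n <- hi - lo + 1L
  ta <- tb <- numeric(n)
  ta[round(events_a * rate) - lo + 1L] <- 1
  tb[round(events_b * rate) - lo + 1L] <- 1
  lags <- -max_lag:max_lag
  xc <- vapply(lags, function(l) {
    ia <- seq_len(n)
    ib <- ia + l
    ok <- ib >= 1 & ib <= n
    sum(ta[ia[ok]] * tb[ib[ok]])
  }, numeric(1))
  best <- max(xc)
  if (best == 0) abort_invalid("no coincident pulses at any lag")
  hits <- lags[xc == best]
  if (length(hits) > 1)
    abort_invalid(paste0("ambiguous alignment; candidate offsets: ",
                         paste(-hits, collapse = ", ")))
  -hits
}

#' Welch spectral-estimation configuration
#'
#' @param window segment length, s (Hann window; 1 s gives a 1 Hz grid)
#' @param overlap segment overlap, s
#' @param range Hz range retained
#' @param normalise divide by the summed power over `range` so the PSD
#'   sums to one there (broadband total-power normalisation)
#' @export
welch_config <- function(window = 1, overlap = 0.6, range = c(4, 45),
                         normalise = TRUE) {
  if (overlap < 0 || overlap >= window)
    abort_invalid("need 0 <= overlap < window")
  structure(as.list(environment()), class = "welch_config")
}

#' Welch power spectral density
#'
#' Hann-windowed overlapped segment averaging; one-sided density in
#' units^2/Hz, restricted to the configured range (1 Hz bin spacing for
#' the default 1 s window).
#'
#' @param x signal
#' @param fs sampling rate, Hz
#' @param config a [welch_config()]
#' @return object of class `psd`: `freq` (Hz), `power`, `df` (bin spacing),
#'   `normalised`, `n_segments`
#' @export
welch_psd <- function(x, fs, config = welch_config()) {
  nwin <- round(config$window * fs)
  hop <- nwin - round(config$overlap * fs)
  if (length(x) < 2 * nwin)
    abort_invalid("signal shorter than two Welch windows")
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nwin) - 1) / nwin)  # periodic Hann
  starts <- seq(1, length(x) - nwin + 1, by = hop)
  scale <- 1 / (fs * sum(w^2))
  acc <- numeric(nwin)
  for (s in starts) {
    X <- fft(x[s:(s + nwin - 1)] * w)
    acc <- acc + Mod(X)^2
  }
  pxx <- acc * scale / length(starts)
  half <- seq_len(floor(nwin / 2) + 1)
  pxx <- pxx[half]
  pxx[2:(length(half) - 1)] <- 2 * pxx[2:(length(half) - 1)]
  freq <- (half - 1) * fs / nwin
  sel <- freq >= config$range[1] & freq <= config$range[2]
  power <- pxx[sel]
  if (config$normalise) power <- power / sum(power)
  structure(list(freq = freq[sel], power = power, df = fs / nwin,
                 normalised = config$normalise,
                 n_segments = length(starts)), class = "psd")
}

#' Band power: sum of PSD bins whose centre frequency lies in the band
#'
#' @param psd a [welch_psd()] result
#' @param band Hz pair (inclusive on both edges) or a [band_defs()] name
#' @export
band_power <- function(psd, band) {
  if (is.character(band)) band <- band_defs()[[band]]
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  if (!any(sel)) abort_invalid("band contains no PSD bins")
  sum(psd$power[sel])
}

#' Magnitude-squared coherence via Welch cross- and auto-spectra
#'
#' @param x,y equal-length signals at the same rate
#' @param fs sampling rate, Hz
#' @param config a [welch_config()] (1 s window gives the 1 Hz grid)
#' @return object of class `coherence`: `freq`, `coherence` in `[0, 1]`,
#'   `n_segments`
#' @export
msc_coherence <- function(x, y, fs, config = welch_config()) {
  if (length(x) != length(y)) abort_invalid("signals differ in length")
  nwin <- round(config$window * fs)
  hop <- nwin - round(config$overlap * fs)
  if (length(x) < 2 * nwin)
    abort_invalid("signals shorter than two Welch windows")
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nwin) - 1) / nwin)
  starts <- seq(1, length(x) - nwin + 1, by = hop)
  pxx <- pyy <- numeric(nwin)
  pxy <- complex(real = numeric(nwin), imaginary = numeric(nwin))
  for (s in starts) {
    X <- fft(x[s:(s + nwin - 1)] * w)
    Y <- fft(y[s:(s + nwin - 1)] * w)
    pxx <- pxx + Mod(X)^2
    pyy <- pyy + Mod(Y)^2
    pxy <- pxy + X * Conj(Y)
  }
  coh <- Mod(pxy)^2 / (pxx * pyy)
  half <- seq_len(floor(nwin / 2) + 1)
  freq <- (half - 1) * fs / nwin
  sel <- freq >= config$range[1] & freq <= config$range[2]
  structure(list(freq = freq[sel],
                 coherence = pmin(pmax(coh[half][sel], 0), 1),
                 n_segments = length(starts)), class = "coherence")
}

#' Sham-normalised band-power contrasts of a recording session
#'
#' Implements the study's contrast logic: per rest block and channel,
#' preprocess and estimate the broadband-normalised Welch PSD; per day,
#' take the active-minus-sham difference of band power and the relative
#' change `100 (sham - active) / sham`; then contrast the stimulated day
#' against the control day (`site_delta`, `site_rel`). Computed for beta,
#' low beta and high beta on every LFP and EEG channel present.
#'
#' @param session a [generate_session()] output (or [read_session()])
#' @param pre a [preprocess_config()]
#' @param welch a [welch_config()] (normalisation should stay on)
#' @param day_order optional day labels `c(stimulated, control)`; default
#'   is the schedule's day order
#' @return list with `block_powers` (per block x channel x band) and
#'   `contrasts` (per channel x band deltas and relative changes)
#' @export
block_contrast <- function(session, pre = preprocess_config(),
                           welch = welch_config(), day_order = NULL) {
  sched <- session$schedule
  rest <- sched[sched$task == "rest", ]
  days <- day_order %||% unique(sched$day)
  for (d in days) {
    sd <- rest[rest$day == d, ]
    for (cond in c("sham", "active"))
      if (!any(sd$condition == cond))
        abort_invalid(sprintf("missing %s rest block on %s", cond, d))
  }
  bands <- c("beta", "low_beta", "high_beta")
  rows <- list()
  for (bi in seq_len(nrow(rest))) {
    blk <- rest[bi, ]
    idx <- which(session$schedule$block == blk$block)
    entry <- session$data[[idx]]
    chs <- list()
    if (!is.null(entry$lfp))
      for (ch in colnames(entry$lfp))
        chs[[ch]] <- list(x = entry$lfp[, ch], fs = session$lfp_rate)
    if (!is.null(entry$eeg))
      for (ch in colnames(entry$eeg))
        chs[[ch]] <- list(x = entry$eeg[, ch], fs = session$eeg_rate)
    for (ch in names(chs)) {
      cl <- preprocess(chs[[ch]]$x, chs[[ch]]$fs, pre)
      psd <- welch_psd(cl$x, cl$fs, welch)
      for (bn in bands)
        rows[[length(rows) + 1L]] <- data.frame(
          block = blk$block, day = blk$day, condition = blk$condition,
          channel = ch, band = bn, power = band_power(psd, bn))
    }
  }
  bp <- do.call(rbind, rows)
  out <- list()
  for (ch in unique(bp$channel)) {
    for (bn in bands) {
      day_stats <- lapply(days, function(d) {
        p <- sapply(c("sham", "active"), function(cond)
          mean(bp$power[bp$channel == ch & bp$band == bn &
                        bp$day == d & bp$condition == cond]))
        if (p[["sham"]] <= 0)
          abort_invalid("relative change undefined: sham band power is zero")
        c(delta = p[["active"]] - p[["sham"]],
          rel = 100 * (p[["sham"]] - p[["active"]]) / p[["sham"]])
      })
      out[[length(out) + 1L]] <- data.frame(
        channel = ch, band = bn,
        delta_day1 = day_stats[[1]][["delta"]],
        delta_day2 = day_stats[[2]][["delta"]],
        rel_day1 = day_stats[[1]][["rel"]],
        rel_day2 = day_stats[[2]][["rel"]],
        site_delta = day_stats[[1]][["delta"]] - day_stats[[2]][["delta"]],
        site_rel = day_stats[[1]][["rel"]] - day_stats[[2]][["rel"]])
    }
  }
  list(block_powers = bp, contrasts = do.call(rbind, out),
       days = days)
}
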