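test_that("preprocessing removes DC and preserves in-band tones", {
  fs <- 250
  t <- (0:(fs * 60 - 1)) / fs
  # constant signal -> all-zero output
  y0 <- preprocess(rep(3.7, length(t)), fs)$x
  expect_lt(max(abs(y0)), 1e-9)
  # 20 Hz unit tone preserved within 2% (steady-state section)
  y <- preprocess(sin(2 * pi * 20 * t), fs)$x
  amp <- sqrt(2 * mean(y[(10 * fs):(50 * fs)]^2))
  expect_lt(abs(amp - 1), 0.02)
  # 50 Hz tone attenuated by at least 20 dB
  y50 <- preprocess(sin(2 * pi * 50 * t), fs)$x
  amp50 <- sqrt(2 * mean(y50[(10 * fs):(50 * fs)]^2))
  expect_lt(20 * log10(amp50), -20)
})

test_that("EEG-rate streams are resampled to 250 Hz before filtering", {
  fs <- 4096
  t <- (0:(fs * 30 - 1)) / fs
  out <- preprocess(sin(2 * pi * 20 * t), fs)
  expect_equal(out$fs, 250)
  amp <- sqrt(2 * mean(out$x[(5 * 250):(25 * 250)]^2))
  expect_lt(abs(amp - 1), 0.02)
  expect_error(preprocess(rnorm(100), 250),
               "short", class = "betalens_validation_error")
  expect_error(preprocess(rnorm(1000), 60),
               "twice", class = "betalens_validation_error")
})

test_that("stream alignment recovers constructed offsets", {
  ev <- c(2.1, 5.3, 9.7, 14.2, 20.4)
  expect_equal(align_streams(ev + 17 / 250, ev), 17)
  expect_equal(align_streams(ev, ev), 0)
  expect_error(align_streams(numeric(0), ev),
               class = "betalens_validation_error")
  # constructed tie: a subtrain matches at two distinct lags
  expect_error(align_streams(c(1, 2, 3), c(1, 2, 3, 4), max_lag = 250),
               "ambiguous", class = "betalens_validation_error")
})

test_that("welch PSD localises tones and conserves power", {
  fs <- 250
  t <- (0:(fs * 300 - 1)) / fs
  x <- sin(2 * pi * 20 * t)
  psd <- welch_psd(x, fs, welch_config(normalise = FALSE))
  expect_equal(psd$freq[which.max(psd$power)], 20)
  expect_equal(psd$df, 1)
  # Parseval: raw total power of white noise matches its variance
  set.seed(1)
  w <- rnorm(fs * 200, sd = 2)
  pw <- welch_psd(w, fs, welch_config(range = c(0, 125), normalise = FALSE))
  tot <- sum(pw$power) * pw$df
  expect_lt(abs(tot - var(w)) / var(w), 0.05)
  # normalised PSD sums to one over the analysis range
  pn <- welch_psd(w, fs, welch_config())
  expect_equal(sum(pn$power), 1, tolerance = 1e-12)
  expect_error(welch_psd(rnorm(100), fs), "short",
               class = "betalens_validation_error")
})

test_that("band power captures in-band tones and rejects out-of-band", {
  fs <- 250
  t <- (0:(fs * 300 - 1)) / fs
  p20 <- welch_psd(sin(2 * pi * 20 * t), fs)
  expect_gte(band_power(p20, "beta"), 0.95)
  p35 <- welch_psd(sin(2 * pi * 35 * t), fs)
  expect_lte(band_power(p35, "beta"), 0.05)
  expect_equal(band_power(p35, "analysis"), 1)
  expect_error(band_power(p20, c(200, 300)),
               class = "betalens_validation_error")
  # mid-band tones land almost fully in their sub-band
  p17 <- welch_psd(sin(2 * pi * 17 * t), fs)
  expect_gte(band_power(p17, "low_beta"), 0.9)
  p24 <- welch_psd(sin(2 * pi * 24 * t), fs)
  expect_gte(band_power(p24, "high_beta"), 0.9)
  # edge convention: the 20 Hz bin belongs to low beta, 21 Hz to high
  # (Hann leakage puts ~1/6 of an edge tone into the neighbouring band)
  expect_gt(band_power(p20, "low_beta"), 4 * band_power(p20, "high_beta"))
  p21 <- welch_psd(sin(2 * pi * 21 * t), fs)
  expect_gt(band_power(p21, "high_beta"), 4 * band_power(p21, "low_beta"))
})

test_that("normalised PSDs are invariant to amplitude rescaling", {
  set.seed(3)
  x <- rnorm(250 * 60)
  p1 <- welch_psd(x, 250)
  p2 <- welch_psd(25 * x, 250)
  expect_equal(p1$power, p2$power, tolerance = 1e-12)
})

test_that("coherence behaves at its analytic anchors", {
  set.seed(7)
  fs <- 250
  x <- rnorm(fs * 120)
  cxx <- msc_coherence(x, x, fs)
  expect_true(all(cxx$coherence > 1 - 1e-9))
  # independent noises: MSC bias ~ 1/K over K Welch segments
  y <- rnorm(fs * 120)
  cxy <- msc_coherence(x, y, fs)
  k <- cxy$n_segments
  m <- mean(cxy$coherence)
  se <- sd(cxy$coherence) / sqrt(length(cxy$coherence))
  expect_lt(abs(m - 1 / k), 3 * se + 0.5 / k)
  # a shared beta-band component raises coherence inside 13-30 Hz
  s <- narrowband_test_signal(fs * 120, fs, 20, 4)
  cx <- msc_coherence(x + 2 * s, y + 2 * s, fs)
  pk <- cx$freq[which.max(cx$coherence)]
  expect_true(pk >= 13 && pk <= 30)
  expect_error(msc_coherence(x, y[-1], fs),
               class = "betalens_validation_error")
})

test_that("block contrasts vanish for identical sham and active signals", {
  sp <- participant_spec(suppression_factor = c(low_beta = 1,
                                                high_beta = 1),
                         gain_sigma = 0, day_drift = 1, seed = 5)
  ses <- generate_session(sp, session_schedule(block_duration = 30),
                          channels = "lfp")
  # force active data identical to sham within each day
  ses$data[[2]] <- ses$data[[1]]
  ses$data[[4]] <- ses$data[[3]]
  bc <- block_contrast(ses)
  expect_lt(max(abs(bc$contrasts$site_rel)), 1e-9)
  expect_lt(max(abs(bc$contrasts$delta_day1)), 1e-12)
})

test_that("missing blocks are reported with day and condition", {
  sp <- participant_spec(seed = 5)
  ses <- generate_session(sp, session_schedule(block_duration = 30),
                          channels = "lfp")
  ses$schedule$task[2] <- "rdm"     # drop the GPi-day active rest block
  expect_error(block_contrast(ses), "active.*GPi",
               class = "betalens_validation_error")
})

test_that("pipeline recovers planted suppression against ground truth", {
  errs <- sapply(1:5, function(seed) {
    sp <- participant_spec(seed = seed)
    ses <- generate_session(sp, session_schedule(block_duration = 60),
                            channels = "lfp")
    bc <- block_contrast(ses)$contrasts
    pc <- planted_contrast(ses)
    m <- merge(bc, pc, by = c("channel", "band"),
               suffixes = c(".est", ".true"))
    sel <- grepl("^Left", m$channel) & m$band == "beta"
    mean(m$site_rel.est[sel] - m$site_rel.true[sel])
  })
  expect_lt(abs(mean(errs)), 2)
  expect_lt(max(abs(errs)), 3)
})
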