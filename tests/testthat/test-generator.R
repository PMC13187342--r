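short_spec <- function(...) {
  participant_spec(...)
}

test_that("generator output is a pure function of spec and seed", {
  sp <- short_spec(seed = 4)
  sch <- session_schedule(block_duration = 10)
  s1 <- generate_session(sp, sch, channels = "lfp")
  s2 <- generate_session(sp, sch, channels = "lfp")
  s3 <- generate_session(short_spec(seed = 5), sch, channels = "lfp")
  expect_identical(s1$data, s2$data)
  expect_false(identical(s1$data[[1]]$lfp, s3$data[[1]]$lfp))
  # child streams: generating behaviour does not perturb session draws
  b <- generate_behaviour(sp)
  s4 <- generate_session(sp, sch, channels = "lfp")
  expect_identical(s1$data, s4$data)
})

test_that("no suppression means no planted effect", {
  # with all suppression factors at 1 nothing is planted: the recorded
  # suppression is 1 everywhere and the realised (finite-sample) contrast
  # averages to zero over seeds
  reals <- sapply(1:6, function(s) {
    sp <- short_spec(suppression_factor = c(low_beta = 1, high_beta = 1),
                     gain_sigma = 0, day_drift = 1, seed = s)
    ses <- generate_session(sp, session_schedule(block_duration = 20),
                            channels = "lfp")
    expect_true(all(ses$ground_truth$blocks$suppression == 1))
    mean(planted_contrast(ses)$site_rel)
  })
  expect_lt(abs(mean(reals)), 1.5)
})

test_that("an isolated beta component plants an active/sham ratio of s^2", {
  s <- 0.8
  sp <- short_spec(aperiodic = list(slope = 1.5, offset = 1e-6),
                   noise_sd = 1e-6, gain_sigma = 0, day_drift = 1,
                   suppression_factor = c(low_beta = s, high_beta = s),
                   seed = 9)
  ses <- generate_session(sp, session_schedule(block_duration = 30),
                          channels = "lfp")
  gt <- ses$ground_truth$blocks
  g <- gt[gt$channel == "Left_0-2" & gt$band == "beta" &
          gt$day == "GPi_day", ]
  ratio <- g$osc_power[g$condition == "active"] /
    g$osc_power[g$condition == "sham"]
  # independent narrowband draws per block: allow their variance
  expect_lt(abs(ratio - s^2) / s^2, 0.1)
  expect_equal(g$suppression[g$condition == "active"], s)
})

test_that("planted band power matches the direct-variance oracle", {
  sp <- short_spec(aperiodic = list(slope = 1.5, offset = 1e-9),
                   noise_sd = 1e-9, gain_sigma = 0, day_drift = 1,
                   seed = 12)
  ses <- generate_session(sp, session_schedule(block_duration = 30),
                          channels = "lfp")
  x <- ses$data[[1]]$lfp[, "Left_0-2"]
  gt <- ses$ground_truth$blocks
  booked <- gt$osc_power[gt$channel == "Left_0-2" & gt$band == "beta" &
                         gt$block == 1]
  # oracle: direct variance of the (dominant) oscillatory signal; the
  # beta components carry almost all power here
  expect_lt(abs(var(x) - booked) / var(x), 0.05)
})

test_that("schedules violating the design are refused", {
  sp <- short_spec()
  bad1 <- data.frame(block = 1, day = "GPi_day", condition = "active",
                     task = "rest", start = 0, duration = 10)
  expect_error(generate_session(sp, bad1), "sham",
               class = "betalens_validation_error")
  bad2 <- session_schedule(block_duration = 10)
  bad2$start[2] <- bad2$start[1] + 5      # overlap
  expect_error(generate_session(sp, bad2), "overlap",
               class = "betalens_validation_error")
  bad3 <- session_schedule(block_duration = 10)
  bad3$start[1:2] <- rev(bad3$start[1:2]) # active before sham
  expect_error(generate_session(sp, bad3), "precede",
               class = "betalens_validation_error")
  expect_error(generate_session(sp, bad3[0, ]), "empty",
               class = "betalens_validation_error")
})

test_that("sample counts match duration times rate for both streams", {
  sp <- short_spec(seed = 8)
  sch <- session_schedule(block_duration = 7)
  ses <- generate_session(sp, sch)
  for (e in ses$data) {
    expect_equal(nrow(e$lfp), 7 * 250)
    expect_equal(nrow(e$eeg), 7 * 4096)
  }
  expect_named(as.data.frame(ses$data[[1]]$lfp),
               c("Left_0-2", "Left_1-3", "Right_0-2", "Right_1-3"))
})

test_that("session round trip through JSON + binary payload is lossless", {
  sp <- short_spec(seed = 6)
  ses <- generate_session(sp, session_schedule(block_duration = 5))
  base <- file.path(tempdir(), "ses_roundtrip")
  write_session(ses, base)
  back <- read_session(base)
  for (i in seq_along(ses$data)) {
    expect_identical(back$data[[i]]$lfp, ses$data[[i]]$lfp)
    expect_identical(back$data[[i]]$eeg, ses$data[[i]]$eeg)
  }
  expect_equal(back$schedule$day, ses$schedule$day)
  expect_equal(back$sync$true_offset_samples,
               ses$sync$true_offset_samples)
  expect_equal(back$ground_truth$blocks$osc_power,
               ses$ground_truth$blocks$osc_power)
})

test_that("malformed session files produce named parse errors", {
  sp <- short_spec(seed = 6)
  ses <- generate_session(sp, session_schedule(block_duration = 5))
  base <- file.path(tempdir(), "ses_bad")
  write_session(ses, base)
  # truncated payload
  sz <- file.info(paste0(base, ".dat"))$size
  con <- file(paste0(base, ".dat"), "r+b")
  truncate(con, sz - 800)
  close(con)
  expect_error(read_session(base), "mismatch",
               class = "betalens_validation_error")
  # header with a required channel dropped
  h <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  h$lfp_channels <- setdiff(h$lfp_channels, "Right_1-3")
  jsonlite::write_json(h, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  expect_error(read_session(base), "Right_1-3",
               class = "betalens_validation_error")
  expect_error(read_session(file.path(tempdir(), "nope")),
               "header", class = "betalens_validation_error")
})

test_that("behaviour tables respect the task design", {
  sp <- short_spec(seed = 3)
  b <- generate_behaviour(sp)
  tr <- b$trials
  expect_equal(nrow(tr), 480)                      # 240 per day
  expect_equal(as.integer(table(tr$day)), c(240L, 240L))
  isi <- diff(tr$onset[tr$day == "GPi_day" & tr$condition == "sham"])
  expect_true(all(isi >= 1.25 - 1e-9 & isi <= 1.75 + 1e-9))
  expect_true(all(tr$rt >= 0.1 & tr$rt <= 2))
  expect_setequal(unique(tr$dot_coherence), c(0.08, 0.5))
  # csv round trip
  p <- file.path(tempdir(), "beh.csv")
  write_behaviour(b, p)
  b2 <- read_behaviour(p)
  expect_equal(b2$trials$rt, tr$rt, tolerance = 1e-12)
})

test_that("zero planted RT effect gives a near-zero contrast over seeds", {
  sp <- short_spec(rt = list(median = 0.55, sdlog = 0.35,
                             gpi_reduction = 0, ventricle_reduction = 0),
                   seed = 2)
  d <- sapply(1:12, function(s)
    rt_contrast(generate_behaviour(sp, seed = s))$site_contrast)
  expect_lt(abs(mean(d)), 3)
})

test_that("sync offsets are recovered by stream alignment", {
  for (s in c(1, 7, 23)) {
    ses <- generate_session(short_spec(seed = s),
                            session_schedule(block_duration = 5),
                            channels = "lfp")
    expect_equal(align_streams(ses$sync$lfp, ses$sync$eeg),
                 ses$sync$true_offset_samples)
  }
})
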