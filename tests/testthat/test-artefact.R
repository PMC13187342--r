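theta_protocol <- function(continuous = FALSE) {
  pulse_protocol(prf = 5, pulse_duration = 20e-3, train_duration = 2.5,
                 train_period = 2.5)
}

test_that("harmonic series has the sinc structure of a rectangular train", {
  hs <- harmonic_series(theta_protocol(), 25)
  # nulls where k * tau * prf is an integer: k = 10 (50 Hz), 20 (100 Hz)
  expect_lt(hs$amplitude[10] / hs$amplitude[1], 1e-12)
  expect_lt(hs$amplitude[20] / hs$amplitude[1], 1e-12)
  expect_equal(hs$frequency, 5 * (1:25))
  # always-on train: all AC harmonics vanish (only DC survives)
  always <- pulse_protocol(prf = 5, pulse_duration = 0.2,
                           train_duration = 2.5, train_period = 2.5)
  expect_lt(max(harmonic_series(always, 10)$amplitude), 1e-12)
  # therapeutic protocol: first harmonic at the PRF, above the 100 Hz LPF
  h130 <- harmonic_series(pulse_protocol(), 3)
  expect_equal(h130$frequency[1], 130)
  expect_gt(h130$frequency[1], hardware_chain()$lpf_cutoff)
})

test_that("zero pressure reproduces pure baseline noise", {
  r <- artefact_timeseries(pulse_protocol(), 0, duration = 6, seed = 3)
  b <- with_seed <- r$noise_sd
  expect_lt(abs(sd(r$x) - r$noise_sd) / r$noise_sd, 0.1)
  expect_equal(artefact_beta_change(r, r), 1.0)
})

test_that("low-PRF artefact is visible in the time domain at 200 kPa", {
  r <- artefact_timeseries(theta_protocol(), 200e3, duration = 6, seed = 1)
  b <- artefact_timeseries(theta_protocol(), 0, duration = 6, seed = 1)
  # pulse waveform rises clearly above the baseline noise floor
  expect_gt(max(abs(r$x)), 5 * max(abs(b$x)))
})

test_that("filtered harmonic amplitudes match the analytic oracle within 3%", {
  r <- artefact_timeseries(theta_protocol(), 600e3,
                           coupling_model("linear_pressure",
                                          gain = 1 / 600e3),
                           duration = 22, noise_sd = 0, seed = 1)
  x <- r$x_internal[-(1:(2 * r$fs_internal))]   # drop the causal transient
  n <- length(x)
  X <- fft(x) / n
  fr <- (0:(n - 1)) * r$fs_internal / n
  hs <- harmonic_series(theta_protocol(), 9)    # below the first sinc null
  meas <- sapply(hs$frequency, function(f) 2 * Mod(X[which.min(abs(fr - f))]))
  ch <- r$chain
  lp <- signal::butter(ch$lpf_order, ch$lpf_cutoff / (ch$internal_rate / 2),
                       type = "low")
  H <- function(f) {
    z <- exp(-1i * 2 * pi * f / ch$internal_rate)
    Mod(sum(lp$b * z^(0:(length(lp$b) - 1))) /
        sum(lp$a * z^(0:(length(lp$a) - 1))))
  }
  pred <- hs$amplitude * sapply(hs$frequency, H)
  expect_rel_equal(meas, pred, 0.03)
})

test_that("130 Hz PRF leaves beta power at the noise floor, 5 Hz does not", {
  p130 <- pulse_protocol()
  base130 <- artefact_timeseries(p130, 0, duration = 20, seed = 2)
  r130 <- artefact_timeseries(p130, 600e3, duration = 20, seed = 2)
  base5 <- artefact_timeseries(theta_protocol(), 0, duration = 20, seed = 2)
  r5 <- artefact_timeseries(theta_protocol(), 600e3, duration = 20,
                            seed = 2)
  c130 <- artefact_beta_change(r130, base130)
  c5 <- artefact_beta_change(r5, base5)
  expect_lt(c130, 1.5)          # within noise of unity
  expect_gt(c5, 100)
  # in-band artefact power: 130 Hz < 1% of 5 Hz at matched coupling
  expect_lt((c130 - 1), 0.01 * (c5 - 1))
})

test_that("5 Hz beta artefact grows monotonically with pressure", {
  base <- artefact_timeseries(theta_protocol(), 0, duration = 15, seed = 4)
  ratios <- sapply(c(200e3, 400e3, 600e3), function(p)
    artefact_beta_change(artefact_timeseries(theta_protocol(), p,
                                             duration = 15, seed = 4),
                         base))
  expect_true(all(diff(ratios) > 0))
})

test_that("artefact beta power scales as gain^2 for linear coupling", {
  mk <- function(g) artefact_timeseries(
    theta_protocol(), 400e3, coupling_model("linear_pressure", gain = g),
    duration = 10, noise_sd = 0, seed = 5)
  b <- artefact_timeseries(theta_protocol(), 0, duration = 10,
                           noise_sd = 1e-12, seed = 5)
  r1 <- artefact_beta_change(mk(1e-9), b)
  r2 <- artefact_beta_change(mk(2e-9), b)
  expect_lt(abs(r2 / r1 - 4), 0.01)
})

test_that("the 120 Hz alias carries the filter's 130 Hz response", {
  # decimating 130 Hz pulses to 250 Hz folds the fundamental to 120 Hz;
  # its amplitude in the recording equals the internal 130 Hz line times
  # the hardware filter's gain there
  p130 <- pulse_protocol(train_duration = 2.5)   # continuous pulsing
  r <- artefact_timeseries(p130, 600e3, duration = 10, noise_sd = 0,
                           seed = 1)
  line_amp <- function(x, fs, f0) {
    n <- length(x)
    fr <- (0:(n - 1)) * fs / n
    2 * Mod(fft(x)[which.min(abs(fr - f0))] / n)
  }
  # unfiltered internal train, same sampling grid
  t <- (seq_along(r$x_internal) - 1) / r$fs_internal
  amp <- r$coupling$gain * 600e3^2
  raw <- amp * as.numeric((t %% (1 / 130)) < 90e-6)
  a_raw_130 <- line_amp(raw, r$fs_internal, 130)
  a_dec_120 <- line_amp(r$x - mean(r$x), r$fs, 120)
  ch <- r$chain
  lp <- signal::butter(ch$lpf_order, ch$lpf_cutoff / (ch$internal_rate / 2),
                       type = "low")
  z <- exp(-1i * 2 * pi * 130 / ch$internal_rate)
  H130 <- Mod(sum(lp$b * z^(0:(length(lp$b) - 1))) /
              sum(lp$a * z^(0:(length(lp$a) - 1))))
  expect_lt(abs(a_dec_120 - H130 * a_raw_130) / (H130 * a_raw_130), 0.2)
  expect_lt(a_dec_120, 0.6 * a_raw_130)   # the filter attenuates the alias
  expect_error(artefact_timeseries(p130, 1e5, duration = 2),
               class = "betalens_validation_error")
  expect_error(artefact_timeseries(p130, 1e5, duration = 10,
                                   chain = hardware_chain(
                                     internal_rate = 1000)),
               "internal rate", class = "betalens_validation_error")
})
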