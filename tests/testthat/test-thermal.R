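mk_field <- function(p, spacing = 0.5, scaled = 1) {
  structure(list(p = p, spacing = spacing, origin = c(0, 0),
                 frequency = 5e5, pml_width = 0L, drive_scale = scaled),
            class = "complex_field")
}

uniform_tmedium <- function(n, k = 0.5, rho = 1000, ch = 3600, wsink = 0,
                            spacing = 0.5) {
  mk <- function(v) matrix(v, n, n)
  structure(list(conductivity = mk(k), density = mk(rho),
                 specific_heat = mk(ch), perfusion_rate = mk(0),
                 perfusion_sink = mk(wsink), baseline_temperature = 37,
                 spacing = spacing, origin = c(0, 0)),
            class = "thermal_medium")
}

test_that("heat source follows the plane-wave absorption relation", {
  n <- 21
  med <- homogeneous_medium(c(n, n), sound_speed = 1540, density = 1040,
                            absorption = 3.45)
  p0 <- matrix(2e5 + 0i, n, n)
  q1 <- heat_source(mk_field(p0), med, pulse_protocol(), "pulse_peak")
  expect_equal(q1$q[1, 1], 3.45 * (2e5)^2 / (1040 * 1540))
  # zero pressure -> zero deposition; doubling pressure quadruples it
  expect_equal(heat_source(mk_field(p0 * 0), med, pulse_protocol(),
                           "pulse_peak")$q[1, 1], 0)
  q2 <- heat_source(mk_field(2 * p0), med, pulse_protocol(), "pulse_peak")
  expect_equal(q2$q / q1$q, matrix(4, n, n))
})

test_that("duty-averaged deposition applies the protocol factor exactly", {
  n <- 11
  med <- homogeneous_medium(c(n, n), absorption = 1)
  p0 <- matrix(1e5 + 0i, n, n)
  qa <- heat_source(mk_field(p0), med, pulse_protocol(), "duty_averaged")
  qp <- heat_source(mk_field(p0), med, pulse_protocol(), "pulse_peak")
  expect_equal(qa$q[1, 1] / qp$q[1, 1], 0.0117 * 0.32)
  expect_equal(qa$q[1, 1] / qp$q[1, 1], 0.003744)
})

test_that("unscaled fields are refused as heat sources", {
  med <- homogeneous_medium(c(5, 5))
  f <- mk_field(matrix(1 + 0i, 5, 5), scaled = NA_real_)
  expect_error(heat_source(f, med, pulse_protocol()),
               "scale", class = "betalens_validation_error")
})

test_that("conduction/perfusion-free heating matches dT = Q t / (rho C)", {
  n <- 15
  tm <- uniform_tmedium(n, k = 0)
  med <- homogeneous_medium(c(n, n), absorption = 2)
  q <- heat_source(mk_field(matrix(3e5 + 0i, n, n)), med,
                   pulse_protocol(), "duty_averaged")
  th <- simulate_bioheat(q, tm, duration = 120)
  pred <- q$q[1, 1] * 120 / (1000 * 3600)
  expect_lt(abs(th$max_rise - pred) / pred, 0.005)
  # zero source stays at zero
  q0 <- q; q0$q[] <- 0
  expect_equal(simulate_bioheat(q0, tm, 60)$max_rise, 0)
})

test_that("perfusion-only cooling decays exponentially", {
  n <- 9
  wsink <- 30    # W/(m^3 K)
  tm <- uniform_tmedium(n, k = 0, wsink = wsink)
  q0 <- structure(list(q = matrix(0, n, n), mode = "duty_averaged",
                       spacing = 0.5, origin = c(0, 0),
                       protocol = pulse_protocol()), class = "q_field")
  t_end <- 200
  th <- simulate_bioheat(q0, tm, t_end, initial = matrix(1, n, n),
                         dt = 0.01)
  pred <- exp(-wsink * t_end / (1000 * 3600))
  expect_lt(abs(th$final[5, 5] - pred) / pred, 0.01)
})

test_that("temperature rise is linear in the deposition (duty scaling)", {
  n <- 31
  tm <- uniform_tmedium(n)
  med <- homogeneous_medium(c(n, n), absorption = 2)
  f <- mk_field(matrix(0 + 0i, n, n))
  f$p[16, 16] <- 3e5
  q1 <- heat_source(f, med, pulse_protocol(), "duty_averaged")
  q2 <- q1; q2$q <- 3 * q1$q
  t1 <- simulate_bioheat(q1, tm, 60)
  t2 <- simulate_bioheat(q2, tm, 60)
  expect_rel_equal(t2$final[t1$final > 1e-12],
                   3 * t1$final[t1$final > 1e-12], 1e-6)
})

test_that("a Gaussian hot spot spreads per the heat-kernel variance law", {
  n <- 81
  tm <- uniform_tmedium(n)
  xs <- ((seq_len(n) - 1) - (n - 1) / 2) * 0.5e-3    # m
  sig0 <- 2e-3
  T0 <- exp(-outer(xs^2, xs^2, `+`) / (2 * sig0^2))
  q0 <- structure(list(q = matrix(0, n, n), mode = "duty_averaged",
                       spacing = 0.5, origin = c(0, 0),
                       protocol = pulse_protocol()), class = "q_field")
  t_end <- 20
  th <- simulate_bioheat(q0, tm, t_end, initial = T0)
  D <- 0.5 / (1000 * 3600)
  sig2_pred <- sig0^2 + 2 * D * t_end
  w <- th$final[, (n + 1) / 2]
  sig2_meas <- sum(w * xs^2) / sum(w)
  expect_lt(abs(sig2_meas - sig2_pred) / sig2_pred, 0.02)
})

test_that("time steps beyond the stability bound are refused", {
  n <- 9
  tm <- uniform_tmedium(n)
  q0 <- structure(list(q = matrix(0, n, n), mode = "duty_averaged",
                       spacing = 0.5, origin = c(0, 0),
                       protocol = pulse_protocol()), class = "q_field")
  expect_error(simulate_bioheat(q0, tm, 10, dt = 10),
               "stability", class = "betalens_validation_error")
})

test_that("train-resolved and duty-averaged modes agree at low duty", {
  ch <- lens_chain(1)
  tm <- thermal_medium(ch$vol)
  qa <- heat_source(ch$field, ch$med, pulse_protocol(), "duty_averaged")
  qp <- heat_source(ch$field, ch$med, pulse_protocol(), "pulse_peak")
  ta <- simulate_bioheat(qa, tm, 60, "duty_averaged")
  tr <- simulate_bioheat(qp, tm, 60, "train_resolved")
  expect_lt(abs(ta$max_rise - tr$max_rise) / tr$max_rise, 0.10)
  # train_resolved refuses a pre-averaged source
  expect_error(simulate_bioheat(qa, tm, 10, "train_resolved"),
               "pulse_peak", class = "betalens_validation_error")
})

test_that("safety report applies the strict gate rules", {
  mk_th <- function(rise) list(max_rise = rise, hottest_location = c(0, 0))
  mk_fm <- function(clear) list(electrode_clearance = clear,
                                targeting_error = 0.5)
  expect_true(safety_report(mk_th(0.4), mk_fm(8))$overall_pass)
  r <- safety_report(mk_th(2.5), mk_fm(8))
  expect_false(r$thermal_pass); expect_true(r$clearance_pass)
  # exactly 5 mm fails the strict ">5 mm" rule
  expect_false(safety_report(mk_th(0.4), mk_fm(5))$clearance_pass)
  # exactly 2 degrees fails the strict "<2" rule
  expect_false(safety_report(mk_th(2), mk_fm(8))$thermal_pass)
})
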