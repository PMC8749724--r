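test_that("triangular breathing cycles have the commanded peak-to-peak amplitude", {
  p <- breathing_protocol(amplitude_um = 1000, n_breaths = 1)
  d <- breathing_displacement(p, sample_rate_hz = 1000)
  expect_equal(max(d) - min(d), 1000, tolerance = 0.11 / 1000)
  # symmetric triangle: rises to the peak at mid-cycle
  expect_equal(which.max(d) / length(d), 0.5, tolerance = 0.01)
})

test_that("displacement is frozen during scheduled apnea intervals", {
  p <- breathing_protocol(amplitude_um = 800, n_breaths = 4, rate_bpm = 40,
                          apnea_events = list(c(3, 20)))
  fs <- 500
  d <- breathing_displacement(p, sample_rate_hz = fs)
  inside <- which((seq_along(d) - 1) / fs >= 3.01 &
                  (seq_along(d) - 1) / fs < 22.99)
  expect_gt(length(inside), 100)
  expect_equal(stats::var(d[inside]), 0)
  expect_equal(diff(d[inside]), rep(0, length(inside) - 1))
})

test_that("every commanded position is a multiple of the stepper quantum", {
  p <- breathing_protocol(amplitude_um = 700, n_breaths = 3)
  d <- breathing_displacement(p, sample_rate_hz = 333)
  rem <- d %% 0.11
  expect_true(all(pmin(rem, 0.11 - rem) < 1e-9))
})

test_that("invalid protocols are rejected", {
  expect_error(breathing_protocol(rate_bpm = 0), "rate_bpm")
  expect_error(breathing_protocol(rate_bpm = 121), "rate_bpm")
  expect_error(breathing_protocol(apnea_events = list(c(5, 20), c(10, 20))),
               "overlap")
  expect_error(breathing_protocol(apnea_events = list(c(5, 10))),
               "at least 20")
})

test_that("protocol duration adds apnea time to the breathing time", {
  p <- breathing_protocol(n_breaths = 100, rate_bpm = 40,
                          apnea_events = list(c(10, 20), c(60, 20),
                                              c(120, 20)))
  d <- breathing_displacement(p, sample_rate_hz = 50)
  expect_equal(length(d), (100 * 1.5 + 3 * 20) * 50)
})

test_that("angle projection routes motion energy onto the expected axes", {
  p <- quick_protocol(n_breaths = 2)
  disp <- breathing_displacement(p, sample_rate_hz = 400)
  a90 <- displacement_to_body_accel(disp, 90, 400, include_gravity = FALSE)
  expect_equal(max(abs(a90[, "x"])), 0, tolerance = 1e-12)
  expect_gt(max(abs(a90[, "z"])), 0)

  a45 <- displacement_to_body_accel(disp, 45, 400, include_gravity = FALSE)
  a135 <- displacement_to_body_accel(disp, 135, 400, include_gravity = FALSE)
  expect_equal(abs(a45[, "z"]), abs(a135[, "z"]), tolerance = 1e-12)
  expect_equal(a45[, "x"], -a135[, "x"], tolerance = 1e-12)
  # inclined positions spread energy across two axes
  expect_gt(sum(a45[, "x"]^2), 0)
  expect_gt(sum(a45[, "z"]^2), 0)
})

test_that("rotation preserves motion energy across axes", {
  p <- quick_protocol(n_breaths = 2)
  disp <- breathing_displacement(p, sample_rate_hz = 400)
  for (ang in c(30, 45, 90, 135)) {
    a <- displacement_to_body_accel(disp, ang, 400, include_gravity = FALSE)
    total <- rowSums(a^2)
    a_axis <- displacement_to_body_accel(disp, 90, 400,
                                         include_gravity = FALSE)[, "z"]
    expect_equal(total, a_axis^2, tolerance = 1e-10)
  }
})

test_that("hammer noise is silent at zero strike rate and seeded-deterministic", {
  m <- noise_model(strike_rate_hz = 0)
  expect_equal(hammer_noise(m, 2, 1000, seed = 1), rep(0, 2000))
  m2 <- noise_model(strike_rate_hz = 3)
  x1 <- hammer_noise(m2, 2, 1000, seed = 99)
  x2 <- hammer_noise(m2, 2, 1000, seed = 99)
  expect_identical(x1, x2)
  expect_gt(max(abs(x1)), 0)
})

test_that("a single strike decays by 1/e over one time constant", {
  m <- noise_model(strike_rate_hz = 0.1, amplitude_scale_g = 0.01,
                   ring_freq_hz = 50, decay_tau_s = 0.1)
  fs <- 2000
  x <- hammer_noise(m, 2, fs, seed = 7)   # this seed yields exactly one burst
  nz <- which(abs(x) > 0)
  expect_equal(sum(diff(nz) > 1) + 1, 1)  # one contiguous burst
  i0 <- min(nz)
  half_ring <- round(fs / m$ring_freq_hz / 2)
  p_start <- max(abs(x[i0:(i0 + half_ring)]))
  i_tau <- i0 + round(m$decay_tau_s * fs)
  p_tau <- max(abs(x[i_tau:(i_tau + half_ring)]))
  expect_equal(p_tau / p_start, exp(-1), tolerance = 0.15)
})

test_that("noise coupling scales ceiling vibration by the configured gains", {
  m <- noise_model(strike_rate_hz = 2, coupling_bed = 0.5,
                   coupling_body = 0.25)
  ceil <- hammer_noise(m, 1, 1000, seed = 5)
  cp <- couple_noise(ceil, m)
  expect_equal(cp$bed, 0.5 * ceil)
  expect_equal(cp$body_additive, 0.25 * ceil)
  expect_equal(max(abs(cp$bed)), 0.5 * max(abs(ceil)))
  m_id <- noise_model(coupling_bed = 1, coupling_body = 0)
  cp2 <- couple_noise(ceil, m_id)
  expect_identical(cp2$bed, ceil)
  expect_equal(cp2$body_additive, rep(0, length(ceil)))
  expect_error(noise_model(coupling_bed = 1.5), "\\[0, 1\\]")
})

test_that("the ADC maps zero to mid-scale and clips at the rails", {
  s <- sensor_model(adc_bits = 12, range_g = 3)
  expect_identical(accelerometer_read(0, s), 2048L)
  expect_identical(accelerometer_read(3, s), 4095L)
  expect_identical(accelerometer_read(-3, s), 0L)
  expect_identical(accelerometer_read(10, s), 4095L)
  expect_identical(accelerometer_read(-10, s), 0L)
})

test_that("quantizer round-trip error is bounded by half a scale factor", {
  s <- sensor_model(adc_bits = 12, range_g = 3)
  step <- 2 * 3 / 2^12
  set.seed(42)
  x <- runif(2000, -3.5, 3.5)
  err <- abs(accelerometer_decode(accelerometer_read(x, s), s) -
             pmin(pmax(x, -3 + step / 2), 3 - step / 2))
  expect_true(all(err <= step / 2 + 1e-12))
  # half a scale factor is ~0.73 mg for the 12-bit +/-3 g chain
  expect_equal(step / 2 * 1000, 0.732, tolerance = 1e-3)
})

test_that("ADC sensitivity analytics reproduce the catalogue values", {
  expect_equal(adc_sensitivity(12, 3), list(lsb_per_g = 682L,
                                            scale_mg_per_lsb = 1.46))
  expect_equal(adc_sensitivity(10, 2), list(lsb_per_g = 256L,
                                            scale_mg_per_lsb = 3.9))
  expect_equal(adc_sensitivity(10, 1), list(lsb_per_g = 512L,
                                            scale_mg_per_lsb = 1.95))
})

test_that("the infrared transfer curve is monotone and algebraically exact", {
  s <- sensor_model(ir_noise_sd_v = 0)
  d <- seq(2, 12, by = 0.5)
  v <- ir_read(d, s)
  expect_true(all(diff(v) < 0))
  expect_equal(ir_read(s$ir_gain_vcm - s$ir_offset_cm, s), 1.0)
  expect_error(ir_read(-1, s), "non-physical")
})

test_that("a larger breathing swing yields a larger infrared swing", {
  amp <- function(a) {
    rec <- quick_recording(seed = 3, amplitude_um = a)
    det <- detect_recording(rec)
    median(det$episodes$ir_amp)
  }
  expect_gt(amp(1500), amp(500))
})

test_that("simulated recordings are reproducible and carry a faithful truth", {
  r1 <- quick_recording(seed = 10, n_breaths = 5, n_apnea_events = 1)
  r2 <- quick_recording(seed = 10, n_breaths = 5, n_apnea_events = 1)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  expect_identical(nrow(r1$truth$breaths), 5L)
  expect_identical(nrow(r1$truth$apneas), 1L)
  expect_true(all(r1$channels$body_z >= 0 & r1$channels$body_z <= 4095))
  # truth timeline covered by the recording
  dur <- nrow(r1$channels) / r1$sample_rate_hz
  expect_lte(max(r1$truth$breaths$t_end_s), dur + 1e-9)
  r3 <- quick_recording(seed = 11, n_breaths = 5, n_apnea_events = 1)
  expect_false(identical(r1$channels$bed_z, r3$channels$bed_z) &&
               identical(r1$truth$apneas, r3$truth$apneas))
})

test_that("motion-axis variance is zero inside apnea intervals before sensor noise", {
  p <- quick_protocol(n_breaths = 8)
  p <- schedule_apneas(p, n_events = 2, duration_s = 20, seed = 4)
  fs <- 400
  d <- breathing_displacement(p, sample_rate_hz = fs)
  for (i in seq_len(nrow(p$apnea_events))) {
    s <- p$apnea_events[i, 1]; e <- s + p$apnea_events[i, 2]
    idx <- which((seq_along(d) - 1) / fs >= s + 0.01 &
                 (seq_along(d) - 1) / fs < e - 0.01)
    expect_equal(stats::var(d[idx]), 0)
  }
})
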