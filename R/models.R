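#' Commanded breathing protocol
#'
#' Describes the motion the simulated platform is told to perform: triangular
#' abdominal displacement cycles of a given amplitude and rate, interrupted by
#' scheduled apnea pauses (absence of motion). Displacements are expressed in
#' micrometres on the motion axis; the stepper quantum limits the achievable
#' positions.
#'
#' @param amplitude_um Peak-to-peak displacement of one breath cycle, in
#'   micrometres. The standard bench covers 500--1500 um.
#' @param rate_bpm Breathing rate in breaths per minute; must be in (0, 120].
#' @param n_breaths Number of commanded breath cycles.
#' @param apnea_events List of `c(start_s, duration_s)` pairs (or an n x 2
#'   matrix). Protocol-standard apnea events last at least 20 s; events must
#'   not overlap.
#' @param angle_deg Body position angle in degrees (45, 90 or 135 on the
#'   standard bench; 90 is the supine analogue with motion purely along z).
#' @param step_resolution_um Stepper quantum in micrometres per step.
#' @param min_apnea_s Minimum apnea duration enforced for protocol-standard
#'   events, in seconds.
#'
#' @return An object of class `breathing_protocol`.
#' @export
#' @examples
#' breathing_protocol(amplitude_um = 1000, n_breaths = 10)
breathing_protocol <- function(amplitude_um = 1000,
                               rate_bpm = 40,
                               n_breaths = 100,
                               apnea_events = list(),
                               angle_deg = 90,
                               step_resolution_um = 0.11,
                               min_apnea_s = 20) {
  stopifnot(is.numeric(amplitude_um), length(amplitude_um) == 1L,
            amplitude_um > 0)
  if (!(rate_bpm > 0 && rate_bpm <= 120)) {
    stop("rate_bpm must be in (0, 120]", call. = FALSE)
  }
  stopifnot(n_breaths >= 0, step_resolution_um > 0)
  ev <- normalize_apnea_events(apnea_events)
  if (nrow(ev) > 0) {
    if (any(ev[, 2L] < min_apnea_s)) {
      stop("apnea events must last at least ", min_apnea_s, " s",
           call. = FALSE)
    }
    o <- order(ev[, 1L])
    ev <- ev[o, , drop = FALSE]
    ends <- ev[, 1L] + ev[, 2L]
    if (nrow(ev) > 1 && any(ev[-1L, 1L] < ends[-nrow(ev)])) {
      stop("apnea events must not overlap", call. = FALSE)
    }
  }
  structure(
    list(amplitude_um = amplitude_um, rate_bpm = rate_bpm,
         n_breaths = as.integer(n_breaths), apnea_events = ev,
         angle_deg = angle_deg, step_resolution_um = step_resolution_um,
         min_apnea_s = min_apnea_s),
    class = "breathing_protocol"
  )
}

normalize_apnea_events <- function(apnea_events) {
  if (is.null(apnea_events) || length(apnea_events) == 0L) {
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("start_s", "duration_s"))))
  }
  if (is.matrix(apnea_events)) {
    ev <- apnea_events
  } else {
    ev <- do.call(rbind, lapply(apnea_events, function(x) {
      stopifnot(length(x) == 2L)
      as.numeric(x)
    }))
  }
  colnames(ev) <- c("start_s", "duration_s")
  stopifnot(all(ev[, 1L] >= 0), all(ev[, 2L] > 0))
  ev
}

#' Hammer noise model
#'
#' The bench's servo-driven hammer strikes the structure at random times,
#' injecting impulsive vibrations. Each strike is modelled as a damped
#' sinusoid burst; strike arrivals follow a Poisson process and peak
#' amplitudes a log-normal law. The burst is observed on the ceiling channel
#' and couples into the bed and body channels with fixed gains.
#'
#' @param strike_rate_hz Mean strikes per second (Poisson arrival rate).
#' @param amplitude_scale_g Median peak amplitude of a strike on the ceiling
#'   channel, in g.
#' @param amplitude_sigma Log-normal spread (sdlog) of strike peaks.
#' @param ring_freq_hz Ringing frequency of the damped oscillation, in Hz.
#' @param decay_tau_s Exponential decay constant of the burst envelope, in s.
#' @param coupling_bed Gain ceiling -> bed, in \[0, 1\].
#' @param coupling_body Gain ceiling -> body (additive), in \[0, 1\].
#'
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(strike_rate_hz = 0.15,
                        amplitude_scale_g = 0.012,
                        amplitude_sigma = 0.9,
                        ring_freq_hz = 50,
                        decay_tau_s = 0.05,
                        coupling_bed = 0.6,
                        coupling_body = 0.3) {
  stopifnot(strike_rate_hz >= 0, amplitude_scale_g >= 0,
            amplitude_sigma >= 0, ring_freq_hz >= 0, decay_tau_s > 0)
  if (coupling_bed < 0 || coupling_bed > 1 ||
      coupling_body < 0 || coupling_body > 1) {
    stop("coupling gains must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(strike_rate_hz = strike_rate_hz,
         amplitude_scale_g = amplitude_scale_g,
         amplitude_sigma = amplitude_sigma,
         ring_freq_hz = ring_freq_hz, decay_tau_s = decay_tau_s,
         coupling_bed = coupling_bed, coupling_body = coupling_body),
    class = "noise_model"
  )
}

#' Sensor chain model
#'
#' Parameters of the acquisition chain: the accelerometer ADC (uniform
#' mid-tread quantizer over \eqn{\pm}`range_g`), the per-channel sampling rate,
#' and the infrared proximity transfer curve
#' \eqn{V = k / (d + d_0)} with additive Gaussian noise.
#'
#' @param adc_bits ADC resolution in bits (>= 8).
#' @param range_g Accelerometer half-range in g (the chain covers
#'   \eqn{\pm}`range_g`).
#' @param sample_rate_hz Per-channel sampling rate in Hz. The six-channel
#'   acquisition mode runs above 4 kHz; a three-channel mode above 26 kHz is
#'   also supported.
#' @param ir_gain_vcm Infrared numerator constant \eqn{k} in V cm.
#' @param ir_offset_cm Infrared denominator offset \eqn{d_0} in cm.
#' @param ir_noise_sd_v Standard deviation of the additive Gaussian voltage
#'   noise on the infrared channel, in V.
#' @param ir_vibration_cm_per_g Mechanical coupling of structure vibration
#'   into the infrared optical path, in cm of apparent distance per g of
#'   ceiling acceleration. The sensor pole shakes with the structure, so
#'   hammer strikes also perturb the proximity reading; set to 0 for an
#'   ideally rigid mount.
#' @param include_gravity Add the static gravity projection to the body
#'   channels.
#'
#' @return An object of class `sensor_model`.
#' @export
#' @examples
#' sensor_model()             # 12-bit, +/-3 g chain
#' adc_sensitivity(12, 3)     # its sensitivity and scale factor
sensor_model <- function(adc_bits = 12,
                         range_g = 3,
                         sample_rate_hz = 4000,
                         ir_gain_vcm = 12.0,
                         ir_offset_cm = 0.42,
                         ir_noise_sd_v = 0.002,
                         ir_vibration_cm_per_g = 0.35,
                         include_gravity = TRUE) {
  stopifnot(adc_bits >= 8, range_g > 0, sample_rate_hz > 0,
            ir_gain_vcm > 0, ir_noise_sd_v >= 0, ir_vibration_cm_per_g >= 0)
  structure(
    list(adc_bits = as.integer(adc_bits), range_g = range_g,
         sample_rate_hz = sample_rate_hz, ir_gain_vcm = ir_gain_vcm,
         ir_offset_cm = ir_offset_cm, ir_noise_sd_v = ir_noise_sd_v,
         ir_vibration_cm_per_g = ir_vibration_cm_per_g,
         include_gravity = isTRUE(include_gravity)),
    class = "sensor_model"
  )
}

#' ADC sensitivity and scale factor
#'
#' For a uniform quantizer of `adc_bits` bits spanning \eqn{\pm}`range_g`,
#' the sensitivity is the (truncated) number of codes per g,
#' \eqn{\lfloor 2^{bits} / (2\,range) \rfloor} LSB/g, and the scale factor is
#' the step size in mg/LSB, truncated at the second decimal — the catalogue
#' convention these figures are quoted in (3.90625 mg/LSB is listed as 3.9).
#' A 12-bit chain over \eqn{\pm 3} g gives 682 LSB/g and about 1.46 mg/LSB.
#'
#' @param adc_bits ADC resolution in bits (>= 1).
#' @param range_g Half-range in g.
#'
#' @return A list with integer `lsb_per_g` and numeric `scale_mg_per_lsb`
#'   (2 dp).
#' @export
#' @examples
#' adc_sensitivity(12, 3)  # 682 LSB/g, 1.46 mg/LSB
#' adc_sensitivity(10, 2)  # 256 LSB/g, 3.9 mg/LSB
adc_sensitivity <- function(adc_bits, range_g) {
  stopifnot(adc_bits >= 1, range_g > 0)
  lsb_per_g <- as.integer(floor(2^adc_bits / (2 * range_g)))
  scale <- floor(2 * range_g * 1000 / 2^adc_bits * 100 + 1e-9) / 100
  list(lsb_per_g = lsb_per_g, scale_mg_per_lsb = scale)
}

#' @export
print.breathing_protocol <- function(x, ...) {
  cat("Breathing protocol: ", x$n_breaths, " breaths, ",
      x$amplitude_um, " um p-p at ", x$rate_bpm, " bpm, angle ",
      x$angle_deg, " deg, ", nrow(x$apnea_events), " apnea event(s)\n",
      sep = "")
  invisible(x)
}

#' @export
print.noise_model <- function(x, ...) {
  cat("Hammer noise model: rate ", x$strike_rate_hz, "/s, median peak ",
      x$amplitude_scale_g, " g (sdlog ", x$amplitude_sigma, "), ring ",
      x$ring_freq_hz, " Hz, tau ", x$decay_tau_s, " s, coupling bed ",
      x$coupling_bed, " / body ", x$coupling_body, "\n", sep = "")
  invisible(x)
}

#' @export
print.sensor_model <- function(x, ...) {
  s <- adc_sensitivity(x$adc_bits, x$range_g)
  cat("Sensor chain: ", x$adc_bits, "-bit ADC over +/-", x$range_g,
      " g (", s$lsb_per_g, " LSB/g, ", s$scale_mg_per_lsb,
      " mg/LSB), fs ", x$sample_rate_hz, " Hz\n", sep = "")
  invisible(x)
}

# Total protocol duration: breaths at rate plus scheduled apnea time.
protocol_duration_s <- function(protocol) {
  protocol$n_breaths * 60 / protocol$rate_bpm +
    sum(protocol$apnea_events[, 2L])
}

# Evaluate expression with a local RNG state seeded from `seed`;
# the caller's .Random.seed is restored afterwards.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
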