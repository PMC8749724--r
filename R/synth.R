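#' Commanded breathing displacement series
#'
#' Renders the protocol's motion timeline as a sampled displacement series on
#' the motion axis. Each breath is a symmetric triangular excursion (constant
#' stepper speed per half-cycle) of peak `amplitude_um`; during a scheduled
#' apnea event the commanded position is frozen, so the series is constant
#' there. All output positions are quantized to the stepper quantum
#' `step_resolution_um`.
#'
#' @param protocol A [breathing_protocol()].
#' @param duration_s Total duration to render, in seconds. Defaults to the
#'   exact protocol duration (`n_breaths` at `rate_bpm` plus scheduled apnea
#'   time); must cover it.
#' @param sample_rate_hz Sampling rate in Hz.
#'
#' @return Numeric vector of displacements in micrometres, sampled at
#'   `sample_rate_hz`, starting at t = 0.
#' @export
#' @examples
#' p <- breathing_protocol(amplitude_um = 1000, n_breaths = 1)
#' d <- breathing_displacement(p, sample_rate_hz = 200)
#' max(d) - min(d)  # ~1000 um peak-to-peak
breathing_displacement <- function(protocol, duration_s = NULL,
                                   sample_rate_hz = 4000) {
  stopifnot(inherits(protocol, "breathing_protocol"), sample_rate_hz > 0)
  need <- protocol_duration_s(protocol)
  if (is.null(duration_s)) duration_s <- need
  if (duration_s < need - 1e-9) {
    stop("duration_s (", duration_s, ") does not cover the protocol (",
         need, " s)", call. = FALSE)
  }
  n <- max(1L, floor(duration_s * sample_rate_hz))
  t <- (seq_len(n) - 1) / sample_rate_hz
  mt <- motion_time(t, protocol$apnea_events)
  period <- 60 / protocol$rate_bpm
  mt <- pmin(mt, protocol$n_breaths * period)   # hold at rest after last breath
  phase <- (mt / period) %% 1
  phase[mt >= protocol$n_breaths * period] <- 0
  disp <- protocol$amplitude_um * (1 - abs(2 * phase - 1))
  step <- protocol$step_resolution_um
  round(disp / step) * step
}

# Zero-phase IIR filtering: one forward and one backward pass of the
# direct-form filter b/a, both through the C-level stats::filter (FIR
# numerator as one-sided convolution, AR denominator recursively). The
# series starts and ends at rest, so no edge padding is needed.
iir_filtfilt <- function(b, a, x) {
  pass <- function(x) {
    n <- length(x)
    xp <- c(numeric(length(b) - 1L), x)
    num <- stats::filter(xp, b, method = "convolution", sides = 1)
    num <- as.numeric(num)[length(b):(length(b) - 1L + n)]
    if (length(a) > 1L) {
      num <- as.numeric(stats::filter(num, -a[-1L] / a[1L],
                                      method = "recursive")) / a[1L]
    }
    num
  }
  rev(pass(rev(pass(x))))
}

# Map real time to motion time: motion is frozen during apnea events, and
# each event shifts all later motion by its duration.
motion_time <- function(t, apnea_events) {
  mt <- t
  off <- 0
  if (nrow(apnea_events) > 0) {
    ev <- apnea_events[order(apnea_events[, 1L]), , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      s <- ev[i, 1L]; d <- ev[i, 2L]
      frozen <- s - off
      inside <- t >= s & t < s + d
      after <- t >= s + d
      mt[inside] <- frozen
      mt[after] <- t[after] - off - d
      off <- off + d
    }
  }
  mt
}

# Real-time location of motion-time instant m (start-of-interval convention:
# an apnea scheduled exactly at m delays the instant when inclusive = TRUE).
real_time <- function(m, apnea_events, inclusive = TRUE) {
  if (nrow(apnea_events) == 0) return(m)
  ev <- apnea_events[order(apnea_events[, 1L]), , drop = FALSE]
  off <- 0
  starts_m <- numeric(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    starts_m[i] <- ev[i, 1L] - off
    off <- off + ev[i, 2L]
  }
  vapply(m, function(mm) {
    if (inclusive) mm + sum(ev[starts_m <= mm + 1e-12, 2L])
    else mm + sum(ev[starts_m < mm - 1e-12, 2L])
  }, numeric(1))
}

#' Ground-truth breath and apnea timeline of a protocol
#'
#' Computes, in real (recording) time, the window of every commanded breath
#' cycle and every scheduled apnea event.
#'
#' @param protocol A [breathing_protocol()].
#' @return A list with data frames `breaths` (`index`, `t_start_s`, `t_end_s`,
#'   `interrupted` — `TRUE` when an apnea event splits the cycle) and `apneas`
#'   (`t_start_s`, `t_end_s`).
#' @export
truth_timeline <- function(protocol) {
  period <- 60 / protocol$rate_bpm
  ev <- protocol$apnea_events
  k <- seq_len(protocol$n_breaths)
  m0 <- (k - 1) * period
  m1 <- k * period
  t0 <- real_time(m0, ev, inclusive = TRUE)
  t1 <- real_time(m1, ev, inclusive = FALSE)
  interrupted <- (t1 - t0) > period + 1e-9
  apneas <- data.frame(t_start_s = ev[, 1L], t_end_s = ev[, 1L] + ev[, 2L])
  list(
    breaths = data.frame(index = k, t_start_s = t0, t_end_s = t1,
                         interrupted = interrupted),
    apneas = apneas
  )
}

#' Schedule random apnea events at breath boundaries
#'
#' Places `n_events` non-adjacent apnea pauses of `duration_s` seconds at
#' randomly chosen boundaries between commanded breath cycles, mirroring the
#' bench protocol of random motion pauses inserted into a breathing run.
#'
#' @param protocol A [breathing_protocol()] without scheduled events.
#' @param n_events Number of apnea events.
#' @param duration_s Duration of each event in seconds (>= 20 for
#'   protocol-standard events).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A new `breathing_protocol` with the events scheduled.
#' @export
schedule_apneas <- function(protocol, n_events = 3, duration_s = 20,
                            seed = NULL) {
  stopifnot(inherits(protocol, "breathing_protocol"))
  if (n_events == 0) return(protocol)
  if (protocol$n_breaths < n_events + 1) {
    stop("not enough breath boundaries to place ", n_events, " apnea events",
         call. = FALSE)
  }
  draw <- function() sort(sample(seq_len(protocol$n_breaths - 1L), n_events))
  after <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  period <- 60 / protocol$rate_bpm
  # boundaries in real time, accounting for earlier inserted events
  starts <- after * period + (seq_len(n_events) - 1L) * duration_s
  breathing_protocol(
    amplitude_um = protocol$amplitude_um, rate_bpm = protocol$rate_bpm,
    n_breaths = protocol$n_breaths,
    apnea_events = lapply(starts, function(s) c(s, duration_s)),
    angle_deg = protocol$angle_deg,
    step_resolution_um = protocol$step_resolution_um,
    min_apnea_s = protocol$min_apnea_s
  )
}

#' Body acceleration from commanded displacement
#'
#' Differentiates the displacement series twice, applies a second-order
#' low-pass filter emulating the mechanical damping of clothing and mattress
#' between the platform and the body-worn sensor, and projects the motion-axis
#' acceleration onto the sensor axes by the body-position angle. The motion
#' axis lies in the x--z plane at `angle_deg` from x, so 90 degrees (supine
#' analogue) puts all motion energy on z while 45 and 135 degrees split it
#' across x and z with opposite x signs.
#'
#' @param displacement_um Displacement series in micrometres.
#' @param angle_deg Body-position angle in degrees.
#' @param sample_rate_hz Sampling rate of the series in Hz.
#' @param damping_cutoff_hz Low-pass cutoff in Hz (default 10).
#' @param include_gravity Add the static 1 g projection along the motion axis.
#'
#' @return An n x 3 matrix of accelerations in g with columns `x`, `y`, `z`.
#' @export
displacement_to_body_accel <- function(displacement_um, angle_deg,
                                       sample_rate_hz = 4000,
                                       damping_cutoff_hz = 10,
                                       include_gravity = TRUE) {
  stopifnot(damping_cutoff_hz > 0, sample_rate_hz > 2 * damping_cutoff_hz)
  n <- length(displacement_um)
  dt <- 1 / sample_rate_hz
  a <- numeric(n)
  if (n >= 3) {
    a[2:(n - 1)] <- diff(displacement_um, differences = 2) / dt^2
  }
  a <- a / 9.80665e6   # um/s^2 -> g
  bf <- signal::butter(2, damping_cutoff_hz / (sample_rate_hz / 2),
                       type = "low")
  a <- iir_filtfilt(bf$b, bf$a, a)
  th <- angle_deg * pi / 180
  u <- c(cos(th), 0, sin(th))
  g0 <- if (include_gravity) u else c(0, 0, 0)
  cbind(x = a * u[1] + g0[1], y = a * u[2] + g0[2], z = a * u[3] + g0[3])
}

#' Impulsive hammer noise on the ceiling channel
#'
#' Synthesizes the vibration injected by the servo-driven hammer: strikes
#' arrive as a Poisson process at `strike_rate_hz`, each contributing a damped
#' sinusoid burst \eqn{A e^{-(t-t_0)/\tau} \sin(2\pi f (t-t_0))} whose peak
#' amplitude A is log-normal with median `amplitude_scale_g`.
#'
#' @param model A [noise_model()].
#' @param duration_s Duration in seconds (> 0).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#'
#' @return Numeric vector of ceiling acceleration in g.
#' @export
hammer_noise <- function(model, duration_s, sample_rate_hz = 4000,
                         seed = NULL) {
  stopifnot(inherits(model, "noise_model"), duration_s > 0)
  gen <- function() hammer_noise_core(model, duration_s, sample_rate_hz)
  if (is.null(seed)) gen() else with_local_seed(seed, gen())
}

hammer_noise_core <- function(model, duration_s, sample_rate_hz) {
  n <- max(1L, floor(duration_s * sample_rate_hz))
  out <- numeric(n)
  if (model$strike_rate_hz <= 0 || model$amplitude_scale_g <= 0) return(out)
  k <- stats::rpois(1L, model$strike_rate_hz * duration_s)
  if (k == 0L) return(out)
  t0 <- sort(stats::runif(k, 0, duration_s))
  amp <- stats::rlnorm(k, meanlog = log(model$amplitude_scale_g),
                       sdlog = model$amplitude_sigma)
  dt <- 1 / sample_rate_hz
  burst_len <- min(n, max(2L, ceiling(8 * model$decay_tau_s / dt)))
  tb <- (seq_len(burst_len) - 1) * dt
  shape <- exp(-tb / model$decay_tau_s) * sin(2 * pi * model$ring_freq_hz * tb)
  for (i in seq_len(k)) {
    i0 <- floor(t0[i] / dt) + 1L
    if (i0 > n) next
    i1 <- min(n, i0 + burst_len - 1L)
    idx <- seq.int(i0, i1)
    out[idx] <- out[idx] + amp[i] * shape[seq_along(idx)]
  }
  out
}

#' Couple ceiling noise into the bed and body channels
#'
#' Applies the fixed structural transmission gains of the bench: the bed
#' accelerometer sees `coupling_bed` times the ceiling vibration and the
#' body-worn sensor receives an additive `coupling_body` fraction.
#'
#' @param ceiling_g Ceiling acceleration series in g.
#' @param model A [noise_model()] supplying the gains.
#' @return A list with numeric vectors `bed` and `body_additive` (g).
#' @export
couple_noise <- function(ceiling_g, model) {
  stopifnot(inherits(model, "noise_model"))
  list(bed = model$coupling_bed * ceiling_g,
       body_additive = model$coupling_body * ceiling_g)
}

#' Quantize an acceleration series through the ADC
#'
#' Uniform mid-tread quantization of \eqn{\pm}`range_g` onto the integer code
#' range \eqn{[0, 2^{bits} - 1]}: zero g maps to the mid-scale code
#' \eqn{2^{bits-1}}, inputs beyond the rails clip to 0 or \eqn{2^{bits}-1}.
#'
#' @param accel_g Acceleration in g (vector or matrix; matrices are quantized
#'   columnwise).
#' @param sensor A [sensor_model()].
#' @return Integer codes, same shape as the input.
#' @export
#' @examples
#' s <- sensor_model()
#' accelerometer_read(c(-3, 0, 3), s)  # 0, 2048, 4095
accelerometer_read <- function(accel_g, sensor) {
  stopifnot(inherits(sensor, "sensor_model"))
  step <- 2 * sensor$range_g / 2^sensor$adc_bits
  code <- round(accel_g * (1 / step)) + 2^(sensor$adc_bits - 1L)
  hi <- 2^sensor$adc_bits - 1
  code[code < 0] <- 0
  code[code > hi] <- hi
  if (is.matrix(accel_g)) {
    matrix(as.integer(code), nrow = nrow(accel_g),
           dimnames = dimnames(accel_g))
  } else {
    as.integer(code)
  }
}

#' Decode ADC codes back to acceleration
#'
#' Inverse of [accelerometer_read()] up to the quantization error, which is
#' bounded by half a scale factor for in-range inputs.
#'
#' @inheritParams accelerometer_read
#' @param code Integer codes from [accelerometer_read()].
#' @return Acceleration in g.
#' @export
accelerometer_decode <- function(code, sensor) {
  step <- 2 * sensor$range_g / 2^sensor$adc_bits
  (code - 2^(sensor$adc_bits - 1L)) * step
}

#' Infrared proximity reading
#'
#' Inverse-distance transfer curve of the analog IR ranger:
#' \eqn{V = k / (d + d_0)} with additive Gaussian voltage noise. The noise-free
#' curve is strictly decreasing in distance.
#'
#' @param distance_cm Distance series in cm; every value must exceed
#'   `-ir_offset_cm`.
#' @param sensor A [sensor_model()] supplying `ir_gain_vcm`, `ir_offset_cm`
#'   and `ir_noise_sd_v`.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Voltage series in V.
#' @export
ir_read <- function(distance_cm, sensor, seed = NULL) {
  stopifnot(inherits(sensor, "sensor_model"))
  if (any(distance_cm <= -sensor$ir_offset_cm)) {
    stop("non-physical distance: all values must exceed ",
         -sensor$ir_offset_cm, " cm", call. = FALSE)
  }
  v <- sensor$ir_gain_vcm / (distance_cm + sensor$ir_offset_cm)
  if (sensor$ir_noise_sd_v > 0) {
    noise <- function() stats::rnorm(length(v), 0, sensor$ir_noise_sd_v)
    v <- v + if (is.null(seed)) noise() else with_local_seed(seed, noise())
  }
  v
}

#' Simulate a full multichannel bench recording
#'
#' Composes the generator chain for one test condition: triangular breathing
#' displacement with apnea pauses, body acceleration by angle projection and
#' clothing damping, hammer noise on the ceiling coupled into bed and body,
#' ADC quantization of the five acceleration channels (body x/y/z, bed z,
#' ceiling z), and the infrared proximity voltage watching the abdomen. The
#' infrared optical path also shakes with the structure through
#' `ir_vibration_cm_per_g`, so strong strikes corrupt the proximity channel
#' as well.
#'
#' @param condition Optional list/vector with `angle_deg` and `amplitude_um`
#'   overriding the protocol (the bench's 3 angles x 3 displacements grid).
#' @param protocol A [breathing_protocol()]. When it has no scheduled apnea
#'   events and `n_apnea_events > 0`, that many events of `apnea_duration_s`
#'   seconds are placed at seeded random breath boundaries.
#' @param noise A [noise_model()].
#' @param sensor A [sensor_model()].
#' @param seed Integer seed; the whole recording is reproducible from it.
#' @param ir_distance_cm Nominal abdomen--IR distance in cm.
#' @param n_apnea_events,apnea_duration_s Apnea schedule used when the
#'   protocol carries none.
#'
#' @return An object of class `sim_recording`: list with `sample_rate_hz`,
#'   `channels` (data frame `body_x`, `body_y`, `body_z`, `bed_z`,
#'   `ceiling_z` in ADC counts and `ir` in volts), `truth` (breath windows
#'   and apnea intervals) and `metadata`.
#' @export
#' @examples
#' p <- breathing_protocol(n_breaths = 5)
#' rec <- simulate_recording(protocol = p, seed = 1, n_apnea_events = 0,
#'                           sensor = sensor_model(sample_rate_hz = 400))
#' names(rec$channels)
simulate_recording <- function(condition = NULL,
                               protocol = breathing_protocol(),
                               noise = noise_model(),
                               sensor = sensor_model(),
                               seed = 1L,
                               ir_distance_cm = 4,
                               n_apnea_events = 3,
                               apnea_duration_s = 20) {
  stopifnot(inherits(protocol, "breathing_protocol"),
            inherits(noise, "noise_model"),
            inherits(sensor, "sensor_model"))
  if (!is.null(condition)) {
    condition <- as.list(condition)
    if (!is.null(condition$angle_deg) && !is.null(condition$amplitude_um)) {
      protocol$angle_deg <- condition$angle_deg
      protocol$amplitude_um <- condition$amplitude_um
    } else if (length(condition) == 2L && is.null(names(condition))) {
      protocol$angle_deg <- condition[[1L]]
      protocol$amplitude_um <- condition[[2L]]
    } else {
      stop("condition must supply angle_deg and amplitude_um", call. = FALSE)
    }
    protocol <- do.call(breathing_protocol, protocol[
      c("amplitude_um", "rate_bpm", "n_breaths", "apnea_events",
        "angle_deg", "step_resolution_um", "min_apnea_s")])
  }
  fs <- sensor$sample_rate_hz
  with_local_seed(seed, {
    if (nrow(protocol$apnea_events) == 0L && n_apnea_events > 0) {
      protocol <- schedule_apneas(protocol, n_apnea_events, apnea_duration_s)
    }
    duration <- protocol_duration_s(protocol)
    disp <- breathing_displacement(protocol, duration, fs)
    body <- displacement_to_body_accel(disp, protocol$angle_deg, fs,
                                       include_gravity = sensor$include_gravity)
    ceiling_g <- hammer_noise_core(noise, duration, fs)
    coupled <- couple_noise(ceiling_g, noise)
    grav <- if (sensor$include_gravity) 1 else 0
    body[, "z"] <- body[, "z"] + coupled$body_additive
    bed_g <- coupled$bed + grav
    ceil_g <- ceiling_g + grav
    dist_cm <- ir_distance_cm - disp * 1e-4 +
      sensor$ir_vibration_cm_per_g * ceiling_g
    dist_cm <- pmax(dist_cm, -sensor$ir_offset_cm + 0.05)
    ir_v <- ir_read(dist_cm, sensor)
    body_code <- accelerometer_read(body, sensor)
    channels <- data.frame(
      body_x = body_code[, "x"], body_y = body_code[, "y"],
      body_z = body_code[, "z"],
      bed_z = accelerometer_read(bed_g, sensor),
      ceiling_z = accelerometer_read(ceil_g, sensor),
      ir = ir_v
    )
    structure(
      list(sample_rate_hz = fs,
           channels = channels,
           truth = truth_timeline(protocol),
           metadata = list(
             condition = list(angle_deg = protocol$angle_deg,
                              displacement_um = protocol$amplitude_um),
             seed = as.integer(seed),
             ir_distance_cm = ir_distance_cm,
             protocol = protocol,
             sensor = sensor,
             temperature_c = NA_real_, humidity_pct = NA_real_)),
      class = "sim_recording"
    )
  })
}

#' @export
print.sim_recording <- function(x, ...) {
  cat("Simulated bench recording: ", nrow(x$channels), " samples at ",
      x$sample_rate_hz, " Hz (", round(nrow(x$channels) / x$sample_rate_hz, 1),
      " s), angle ", x$metadata$condition$angle_deg, " deg, displacement ",
      x$metadata$condition$displacement_um, " um, ",
      nrow(x$truth$breaths), " breaths, ", nrow(x$truth$apneas),
      " apnea event(s), seed ", x$metadata$seed, "\n", sep = "")
  invisible(x)
}
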