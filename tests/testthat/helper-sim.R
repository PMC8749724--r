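# Small, fast configurations shared across the unit tests. The full-scale
# protocol (100 breaths, 4 kHz, three 20-s apneas) is exercised in
# test-acceptance.R; unit tests use a short protocol and a low sampling rate
# so each simulation runs in milliseconds.

quick_sensor <- function(...) sensor_model(sample_rate_hz = 400, ...)

quick_protocol <- function(n_breaths = 6, amplitude_um = 1000,
                           angle_deg = 90, ...) {
  breathing_protocol(amplitude_um = amplitude_um, n_breaths = n_breaths,
                     angle_deg = angle_deg, ...)
}

quick_recording <- function(seed = 1, amplitude_um = 1000, angle_deg = 90,
                            noise = noise_model(strike_rate_hz = 0),
                            n_breaths = 6, n_apnea_events = 0, ...) {
  simulate_recording(
    protocol = quick_protocol(n_breaths = n_breaths,
                              amplitude_um = amplitude_um,
                              angle_deg = angle_deg),
    noise = noise, sensor = quick_sensor(), seed = seed,
    n_apnea_events = n_apnea_events, ...)
}

reference_grid <- function() load_reference_fixture()

# A frame stream: `spec` is a list of c(seconds, g_body, g_bed) segments.
make_frames <- function(spec, frame_s = 0.25) {
  rows <- lapply(spec, function(s) {
    k <- round(s[[1]] / frame_s)
    data.frame(g_body = rep(s[[2]], k), g_bed = rep(s[[3]], k))
  })
  do.call(rbind, rows)
}
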