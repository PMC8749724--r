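#' Monitoring configuration
#'
#' Thresholds of the apnea monitoring loop. The timer T counts the seconds
#' since the last confirmed breath: a pause reaching `t_risk_s` (the limit
#' risk condition) raises an apnea alert and triggers the caregiver survey; a
#' pause, or a continuously unclear signal, reaching `t_apnea_s` activates
#' the rescue process. A frame is *clear* when the abdomen acceleration
#' exceeds the bed reference, and counts as a breath when it also reaches
#' `g_th`.
#'
#' @param g_th Breath acceleration threshold in g, matched to the minimum
#'   breathing displacement of interest.
#' @param t_risk_s Alert threshold for T, seconds (default 10).
#' @param t_apnea_s Apnea/rescue threshold, seconds (default 20).
#' @param frame_s Analysis frame length, seconds. Thresholds are in seconds
#'   and independent of the frame length.
#' @param sat_threshold,bpm_threshold Survey triage thresholds (critical when
#'   both vitals fall below them).
#' @param strict_below Read "below threshold" strictly (`<`, default) rather
#'   than inclusively (`<=`).
#' @param location Free-text location used to pre-fill alert records.
#' @return An object of class `monitor_config`.
#' @export
monitor_config <- function(g_th = 0.003,
                           t_risk_s = 10,
                           t_apnea_s = 20,
                           frame_s = 0.25,
                           sat_threshold = 90,
                           bpm_threshold = 90,
                           strict_below = TRUE,
                           location = "nursery") {
  stopifnot(g_th > 0, frame_s > 0)
  if (!(t_risk_s > 0 && t_risk_s < t_apnea_s)) {
    stop("need 0 < t_risk_s < t_apnea_s", call. = FALSE)
  }
  structure(list(g_th = g_th, t_risk_s = t_risk_s, t_apnea_s = t_apnea_s,
                 frame_s = frame_s, sat_threshold = sat_threshold,
                 bpm_threshold = bpm_threshold,
                 strict_below = isTRUE(strict_below), location = location),
            class = "monitor_config")
}

#' Initial monitor state
#'
#' @param time_s Stream time at which monitoring starts.
#' @return An object of class `monitor_state` with phase `monitoring`,
#'   timer T and the unclear-signal clock at zero.
#' @export
monitor_init <- function(time_s = 0) {
  structure(list(phase = "monitoring", timer_T_s = 0,
                 unclear_elapsed_s = 0, alert_pending = FALSE,
                 time_s = time_s),
            class = "monitor_state")
}

#' Advance the monitor by one frame
#'
#' One transition of the monitoring state machine. Each frame summarises
#' `frame_s` seconds of signal by the detrended peak-to-peak abdomen and bed
#' accelerations (`g_body`, `g_bed`, in g). The rules:
#'
#' * `g_body > g_bed` means the breathing signal is *clear*; a clear frame
#'   with `g_body >= g_th` is a confirmed breath and resets T (a breath also
#'   resolves a pending alert and returns the machine to monitoring).
#' * Unclear frames never reset T; they accumulate the unclear-signal clock.
#' * When T enters `[t_risk_s, t_apnea_s)`, one `apnea_alert` event is
#'   emitted for the pause and the caregiver survey is requested.
#' * T reaching `t_apnea_s`, or a continuously unclear signal exceeding it,
#'   emits `rescue` (with an `actuator_enable` event); the machine then stays
#'   in the rescue phase until [monitor_reset()].
#'
#' Malformed frames (missing or negative metrics) are skipped with a
#' `warning` event.
#'
#' @param frame List or one-row data frame with `g_body` and `g_bed` (g).
#' @param state A `monitor_state`.
#' @param config A [monitor_config()].
#' @return List with `state` (updated) and `events` (possibly empty list;
#'   each event has `type`, `time_s` and a state snapshot).
#' @export
monitor_step <- function(frame, state, config) {
  stopifnot(inherits(state, "monitor_state"),
            inherits(config, "monitor_config"))
  frame <- as.list(frame)
  t_now <- state$time_s + config$frame_s
  events <- list()
  emit <- function(type, extra = list()) {
    events[[length(events) + 1L]] <<- c(
      list(type = type, time_s = t_now, phase = state$phase,
           timer_T_s = state$timer_T_s,
           unclear_elapsed_s = state$unclear_elapsed_s), extra)
  }

  bad <- is.null(frame$g_body) || is.null(frame$g_bed) ||
    !is.finite(frame$g_body) || !is.finite(frame$g_bed) ||
    frame$g_body < 0 || frame$g_bed < 0
  if (bad) {
    state$time_s <- t_now
    emit("warning", list(message = "malformed frame skipped"))
    return(list(state = state, events = events))
  }

  if (state$phase == "rescue") {
    state$time_s <- t_now
    return(list(state = state, events = events))
  }

  clear <- frame$g_body > frame$g_bed
  breath <- clear && frame$g_body >= config$g_th

  if (clear) state$unclear_elapsed_s <- 0
  else state$unclear_elapsed_s <- state$unclear_elapsed_s + config$frame_s

  if (breath) {
    if (state$phase == "awaiting_survey") {
      emit("breathing_resumed")
      state$phase <- "monitoring"
      state$alert_pending <- FALSE
    }
    state$timer_T_s <- 0
  } else {
    # the timer is never reset by an unclear or sub-threshold frame
    state$timer_T_s <- state$timer_T_s + config$frame_s
  }

  if (state$timer_T_s >= config$t_apnea_s ||
      state$unclear_elapsed_s > config$t_apnea_s) {
    trigger <- if (state$unclear_elapsed_s >= config$t_apnea_s)
      "unclear_over_20" else "apnea_10_20"
    state$phase <- "rescue"
    emit("rescue", list(trigger = trigger))
    emit("actuator_enable")
  } else if (clear && state$phase == "monitoring" &&
             state$timer_T_s >= config$t_risk_s) {
    # the 10-20 s alert belongs to the clear-signal branch: a pause the
    # sensors see cleanly; an unclear stretch only ever escalates to rescue
    state$phase <- "awaiting_survey"
    state$alert_pending <- TRUE
    emit("apnea_alert", list(trigger = "apnea_10_20"))
    emit("survey_request")
  }

  state$time_s <- t_now
  list(state = state, events = events)
}

#' Submit a caregiver survey to the monitor
#'
#' Applies [evaluate_survey()] to a pending alert: a critical survey (both
#' vitals below threshold) activates the rescue process; an ok survey
#' restarts monitoring and resets T. Missing vitals escalate to rescue
#' (fail-safe).
#'
#' @param survey A [survey_response()].
#' @param state A `monitor_state` in phase `awaiting_survey`.
#' @param config A [monitor_config()].
#' @return List with `state` and `events` as in [monitor_step()].
#' @export
monitor_survey <- function(survey, state, config) {
  stopifnot(inherits(state, "monitor_state"))
  events <- list()
  if (state$phase != "awaiting_survey") {
    return(list(state = state, events = events))
  }
  verdict <- tryCatch(evaluate_survey(survey, config),
                      error = function(e) "critical")
  if (verdict == "critical") {
    state$phase <- "rescue"
    events[[1L]] <- list(type = "rescue", time_s = state$time_s,
                         phase = "rescue", timer_T_s = state$timer_T_s,
                         unclear_elapsed_s = state$unclear_elapsed_s,
                         trigger = "apnea_10_20", survey_critical = TRUE)
    events[[2L]] <- list(type = "actuator_enable", time_s = state$time_s,
                         phase = "rescue", timer_T_s = state$timer_T_s,
                         unclear_elapsed_s = state$unclear_elapsed_s)
  } else {
    state$phase <- "monitoring"
    state$alert_pending <- FALSE
    state$timer_T_s <- 0
    events[[1L]] <- list(type = "monitoring_restarted", time_s = state$time_s,
                         phase = "monitoring", timer_T_s = 0,
                         unclear_elapsed_s = state$unclear_elapsed_s)
  }
  list(state = state, events = events)
}

#' Reset the monitor after a rescue
#'
#' The explicit reset (the caregiver's reset button) that resumes monitoring
#' after the rescue process; nothing else leaves the rescue phase.
#'
#' @param state A `monitor_state`.
#' @return A fresh `monitor_state` continuing at the same stream time.
#' @export
monitor_reset <- function(state) {
  monitor_init(time_s = state$time_s)
}

#' Replay a frame stream through the monitor
#'
#' Feeds every frame of a stream through [monitor_step()] and collects the
#' event log. Replay is deterministic: the same stream always yields the same
#' log.
#'
#' @param frames Data frame with columns `g_body`, `g_bed` (and optionally
#'   `ir`), one row per frame.
#' @param config A [monitor_config()].
#' @param state Optional starting state.
#' @return List with the final `state` and `events` (list of event records).
#' @export
monitor_run <- function(frames, config = monitor_config(),
                        state = monitor_init()) {
  frames <- as.data.frame(frames)
  events <- list()
  for (i in seq_len(nrow(frames))) {
    res <- monitor_step(frames[i, , drop = FALSE], state, config)
    state <- res$state
    events <- c(events, res$events)
  }
  list(state = state, events = events)
}

#' Caregiver survey response
#'
#' @param sat_pct Oxygen saturation, percent, in \[0, 100\] (`NA` allowed —
#'   treated as not evaluable).
#' @param bpm Heart rate, beats per minute (>= 0, `NA` allowed).
#' @param body_position,skin_color,free_notes Free-text observations.
#' @return An object of class `survey_response`.
#' @export
survey_response <- function(sat_pct = NA_real_, bpm = NA_real_,
                            body_position = "", skin_color = "",
                            free_notes = "") {
  if (!is.na(sat_pct) && (sat_pct < 0 || sat_pct > 100)) {
    stop("sat_pct must lie in [0, 100]", call. = FALSE)
  }
  if (!is.na(bpm) && bpm < 0) stop("bpm must be >= 0", call. = FALSE)
  structure(list(sat_pct = sat_pct, bpm = bpm,
                 body_position = body_position, skin_color = skin_color,
                 free_notes = free_notes),
            class = "survey_response")
}

#' Triage a caregiver survey
#'
#' Critical exactly when both oxygen saturation and heart rate fall below
#' their thresholds (both 90 on the standard configuration, read strictly);
#' otherwise ok and monitoring restarts. Missing vitals are not evaluable and
#' raise an error so the caller can fail safe.
#'
#' @param survey A [survey_response()].
#' @param config A [monitor_config()].
#' @return `"critical"` or `"ok"`.
#' @export
#' @examples
#' evaluate_survey(survey_response(85, 80), monitor_config())  # critical
#' evaluate_survey(survey_response(95, 80), monitor_config())  # ok
evaluate_survey <- function(survey, config = monitor_config()) {
  stopifnot(inherits(survey, "survey_response"))
  if (is.na(survey$sat_pct) || is.na(survey$bpm)) {
    stop("survey vitals missing: not evaluable", call. = FALSE)
  }
  below <- if (config$strict_below) `<` else `<=`
  if (below(survey$sat_pct, config$sat_threshold) &&
      below(survey$bpm, config$bpm_threshold)) "critical" else "ok"
}

#' Build an 8Ws-structured alert record
#'
#' Collects one alert into the eight-question scheduling schema
#' (what/where/why/who/what to do/which tools/when/how). Keys that the
#' monitor can fill automatically are pre-filled; the rest are left for the
#' operator.
#'
#' @param trigger One of `"apnea_10_20"`, `"unclear_over_20"`, or `NA` for a
#'   routine log record.
#' @param timestamp Event time (any scalar; seconds or a time string).
#' @param survey Optional [survey_response()].
#' @param config A [monitor_config()].
#' @param environment List with `temperature_c` and `humidity_pct`
#'   placeholders.
#' @return An object of class `alert_record` (risk colour not yet assigned;
#'   see [classify_risk()]).
#' @export
alert_record <- function(trigger = NA_character_, timestamp = 0,
                         survey = NULL, config = monitor_config(),
                         environment = list(temperature_c = NA_real_,
                                            humidity_pct = NA_real_)) {
  if (!is.na(trigger) &&
      !trigger %in% c("apnea_10_20", "unclear_over_20")) {
    stop("unknown trigger: ", trigger, call. = FALSE)
  }
  if (!is.null(survey)) stopifnot(inherits(survey, "survey_response"))
  what <- if (is.na(trigger)) "routine monitoring record" else
    switch(trigger,
           apnea_10_20 = "apnea alert: breathing pause of 10-20 s",
           unclear_over_20 = "rescue: no clear breathing signal for over 20 s")
  structure(
    list(timestamp = timestamp, trigger = trigger, survey = survey,
         risk_color = NA_character_,
         environment = environment,
         eight_ws = list(
           what = what,
           where = config$location,
           why = "",
           who = "",
           what_to_do = "",
           which_tools = "",
           when = as.character(timestamp),
           how = "")),
    class = "alert_record"
  )
}

#' Assign the risk colour of an alert record
#'
#' Red demands immediate intervention (rescue trigger, or an apnea alert
#' whose survey is critical or missing); yellow schedules a planned check-up
#' (apnea alert with an ok survey); green marks a routine prospective-study
#' record with no alert.
#'
#' @param record An [alert_record()].
#' @param config A [monitor_config()].
#' @return The record with `risk_color` set.
#' @export
classify_risk <- function(record, config = monitor_config()) {
  stopifnot(inherits(record, "alert_record"))
  color <-
    if (is.na(record$trigger)) {
      "green"
    } else if (record$trigger == "unclear_over_20") {
      "red"
    } else {
      verdict <- if (is.null(record$survey)) "critical" else
        tryCatch(evaluate_survey(record$survey, config),
                 error = function(e) "critical")
      if (verdict == "critical") "red" else "yellow"
    }
  record$risk_color <- color
  record
}

risk_color_legend <- c(red = "immediate intervention",
                       yellow = "planned check-up",
                       green = "prospective study")

#' Render an alert record as a message
#'
#' Deterministic single-line message (colour, meaning, trigger, timestamp,
#' vitals when present) plus the full JSON serialization of the 8Ws record.
#'
#' @param record A classified [alert_record()] (see [classify_risk()]).
#' @return List with `message` (character) and `json` (character, one
#'   record).
#' @export
render_alert <- function(record) {
  stopifnot(inherits(record, "alert_record"))
  if (is.na(record$risk_color)) {
    stop("classify the record before rendering (see classify_risk)",
         call. = FALSE)
  }
  vitals <- if (!is.null(record$survey) &&
                !is.na(record$survey$sat_pct) && !is.na(record$survey$bpm)) {
    sprintf(" | SAT %g%% BPM %g", record$survey$sat_pct, record$survey$bpm)
  } else ""
  trig <- if (is.na(record$trigger)) "routine" else record$trigger
  msg <- sprintf("[%s: %s] trigger=%s t=%s%s",
                 toupper(record$risk_color),
                 risk_color_legend[[record$risk_color]],
                 trig, record$timestamp, vitals)
  payload <- record
  class(payload) <- NULL
  if (!is.null(payload$survey)) class(payload$survey) <- NULL
  list(message = msg,
       json = as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                            null = "null", na = "null")))
}

#' Summarise a recording into monitor frames
#'
#' Converts a simulated (or imported) recording into the per-frame summaries
#' the monitor consumes: detrended peak-to-peak abdomen acceleration (max
#' over the three body axes), bed reference, and infrared swing, per
#' `frame_s`-second frame, all in physical units.
#'
#' @param recording A `sim_recording`.
#' @param frame_s Frame length in seconds.
#' @return Data frame with `time_s` (frame end), `g_body`, `g_bed` (g),
#'   `ir` (V).
#' @export
frames_from_recording <- function(recording, frame_s = 0.25) {
  stopifnot(inherits(recording, "sim_recording"), frame_s > 0)
  fs <- recording$sample_rate_hz
  ch <- recording$channels
  sensor <- recording$metadata$sensor %||% sensor_model()
  step_g <- 2 * sensor$range_g / 2^sensor$adc_bits
  n <- nrow(ch)
  per <- max(2L, round(frame_s * fs))
  k <- floor(n / per)
  body <- as.matrix(ch[, c("body_x", "body_y", "body_z")])
  out <- data.frame(time_s = numeric(k), g_body = numeric(k),
                    g_bed = numeric(k), ir = numeric(k))
  for (i in seq_len(k)) {
    idx <- seq.int((i - 1L) * per + 1L, i * per)
    out$time_s[i] <- i * per / fs
    out$g_body[i] <- max(apply(body[idx, , drop = FALSE], 2L,
                               detrended_p2p)) * step_g
    out$g_bed[i] <- detrended_p2p(ch$bed_z[idx]) * step_g
    out$ir[i] <- detrended_p2p(ch$ir[idx])
  }
  out
}

#' Write a monitor event log as JSON lines
#'
#' One JSON object per line, each event with its state snapshot.
#'
#' @param events Event list from [monitor_run()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  lines <- vapply(events, function(e) {
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE, null = "null",
                                  na = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
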