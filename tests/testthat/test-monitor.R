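cfg <- monitor_config(g_th = 0.003)

test_that("a healthy breathing stream raises no events and keeps T small", {
  frames <- make_frames(list(c(60, 0.01, 0.001)))
  res <- monitor_run(frames, cfg)
  expect_identical(length(res$events), 0L)
  expect_identical(res$state$phase, "monitoring")
  expect_lte(res$state$timer_T_s, cfg$frame_s)
})

test_that("a clear 15-s pause raises exactly one apnea alert and no rescue", {
  frames <- make_frames(list(
    c(30, 0.01, 0.001),    # breathing
    c(15, 0.002, 0.001),   # pause, still a clear signal, below g_th
    c(30, 0.01, 0.001)))   # breathing resumes
  res <- monitor_run(frames, cfg)
  types <- vapply(res$events, `[[`, character(1), "type")
  expect_identical(sum(types == "apnea_alert"), 1L)
  expect_identical(sum(types == "rescue"), 0L)
  expect_identical(res$state$phase, "monitoring")
  # the alert fires when T enters [10, 20)
  t_alert <- res$events[[which(types == "apnea_alert")[1]]]$time_s
  expect_equal(t_alert, 30 + 10, tolerance = cfg$frame_s)
  # no re-firing while the same pause continues inside [10, 20)
  expect_identical(sum(types == "apnea_alert"), 1L)
})

test_that("each distinct pause gets its own alert", {
  frames <- make_frames(list(
    c(20, 0.01, 0.001), c(12, 0.002, 0.001),
    c(20, 0.01, 0.001), c(12, 0.002, 0.001),
    c(10, 0.01, 0.001)))
  res <- monitor_run(frames, cfg)
  types <- vapply(res$events, `[[`, character(1), "type")
  expect_identical(sum(types == "apnea_alert"), 2L)
  expect_identical(sum(types == "breathing_resumed"), 2L)
})

test_that("a continuously unclear signal past 20 s activates the rescue process", {
  frames <- make_frames(list(
    c(10, 0.01, 0.001),
    c(21, 0.001, 0.002)))  # g_body <= g_bed: unclear
  res <- monitor_run(frames, cfg)
  types <- vapply(res$events, `[[`, character(1), "type")
  expect_identical(sum(types == "rescue"), 1L)
  expect_identical(sum(types == "actuator_enable"), 1L)
  ev <- res$events[[which(types == "rescue")]]
  expect_identical(ev$trigger, "unclear_over_20")
  expect_identical(res$state$phase, "rescue")
  # rescue latches: further frames do nothing until an explicit reset
  res2 <- monitor_run(make_frames(list(c(10, 0.01, 0.001))), cfg,
                      state = res$state)
  expect_identical(res2$state$phase, "rescue")
  expect_identical(length(res2$events), 0L)
  fresh <- monitor_reset(res2$state)
  expect_identical(fresh$phase, "monitoring")
  expect_equal(fresh$timer_T_s, 0)
})

test_that("unclear frames never reset the timer", {
  st <- monitor_init()
  unclear <- list(g_body = 0.001, g_bed = 0.002)
  for (i in 1:20) {
    st <- monitor_step(unclear, st, cfg)$state
    expect_equal(st$timer_T_s, i * cfg$frame_s)
  }
  # a clear breath does reset it
  st <- monitor_step(list(g_body = 0.01, g_bed = 0.001), st, cfg)$state
  expect_equal(st$timer_T_s, 0)
})

test_that("a pause that outlives the survey window escalates to rescue at 20 s", {
  frames <- make_frames(list(
    c(10, 0.01, 0.001),
    c(25, 0.002, 0.001)))  # clear pause, never answered
  res <- monitor_run(frames, cfg)
  types <- vapply(res$events, `[[`, character(1), "type")
  expect_identical(sum(types == "apnea_alert"), 1L)
  expect_identical(sum(types == "rescue"), 1L)
  t_rescue <- res$events[[which(types == "rescue")]]$time_s
  expect_equal(t_rescue, 10 + 20, tolerance = cfg$frame_s)
})

test_that("survey triage follows the dual-vitals rule", {
  expect_identical(evaluate_survey(survey_response(85, 80), cfg), "critical")
  expect_identical(evaluate_survey(survey_response(95, 80), cfg), "ok")
  expect_identical(evaluate_survey(survey_response(85, 95), cfg), "ok")
  # thresholds are read strictly: exactly 90 is not below 90
  expect_identical(evaluate_survey(survey_response(90, 90), cfg), "ok")
  expect_error(evaluate_survey(survey_response(NA, 80), cfg), "missing")
  inclusive <- monitor_config(strict_below = FALSE)
  expect_identical(evaluate_survey(survey_response(90, 90), inclusive),
                   "critical")
})

test_that("survey responses drive the alert resolution", {
  frames <- make_frames(list(c(10, 0.01, 0.001), c(12, 0.002, 0.001)))
  res <- monitor_run(frames, cfg)
  expect_identical(res$state$phase, "awaiting_survey")

  ok <- monitor_survey(survey_response(97, 120), res$state, cfg)
  expect_identical(ok$state$phase, "monitoring")
  expect_equal(ok$state$timer_T_s, 0)

  crit <- monitor_survey(survey_response(85, 80), res$state, cfg)
  expect_identical(crit$state$phase, "rescue")
  types <- vapply(crit$events, `[[`, character(1), "type")
  expect_true("rescue" %in% types)

  # missing vitals fail safe
  miss <- monitor_survey(survey_response(), res$state, cfg)
  expect_identical(miss$state$phase, "rescue")
})

test_that("replaying the same stream yields an identical event log", {
  set.seed(55)
  frames <- data.frame(g_body = runif(400, 0, 0.01),
                       g_bed = runif(400, 0, 0.01))
  r1 <- monitor_run(frames, cfg)
  r2 <- monitor_run(frames, cfg)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$state, r2$state)
})

test_that("raising the breath threshold never decreases the alert count", {
  set.seed(66)
  for (rep in 1:5) {
    frames <- data.frame(g_body = runif(600, 0.0005, 0.006),
                         g_bed = rep(0.0004, 600))
    counts <- vapply(c(0.001, 0.003, 0.005, 0.007), function(gth) {
      res <- monitor_run(frames, monitor_config(g_th = gth))
      sum(vapply(res$events, `[[`, character(1), "type") == "apnea_alert") +
        sum(vapply(res$events, `[[`, character(1), "type") == "rescue")
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("malformed frames are skipped with a warning event", {
  st <- monitor_init()
  res <- monitor_step(list(g_body = -1, g_bed = 0.001), st, cfg)
  expect_identical(res$events[[1]]$type, "warning")
  expect_equal(res$state$timer_T_s, 0)
  res2 <- monitor_step(list(g_bed = 0.001), res$state, cfg)
  expect_identical(res2$events[[1]]$type, "warning")
})

test_that("risk colours follow the triage semantics", {
  red1 <- classify_risk(alert_record("unclear_over_20", 100))
  expect_identical(red1$risk_color, "red")
  yellow <- classify_risk(alert_record("apnea_10_20", 100,
                                       survey = survey_response(95, 120)))
  expect_identical(yellow$risk_color, "yellow")
  red2 <- classify_risk(alert_record("apnea_10_20", 100,
                                     survey = survey_response(85, 80)))
  expect_identical(red2$risk_color, "red")
  # apnea alert without a survey fails safe to red
  red3 <- classify_risk(alert_record("apnea_10_20", 100))
  expect_identical(red3$risk_color, "red")
  green <- classify_risk(alert_record(NA, 100))
  expect_identical(green$risk_color, "green")
  expect_error(alert_record("bogus_trigger"), "unknown trigger")
})

test_that("alert rendering is deterministic and complete", {
  rec <- classify_risk(alert_record("unclear_over_20", 123,
                                    survey = survey_response(85, 80)))
  out1 <- render_alert(rec)
  out2 <- render_alert(rec)
  expect_identical(out1, out2)
  expect_match(out1$message, "immediate intervention")
  expect_match(out1$message, "unclear_over_20")
  expect_match(out1$message, "SAT 85")
  parsed <- jsonlite::fromJSON(out1$json)
  expect_identical(sort(names(parsed$eight_ws)),
                   sort(c("what", "where", "why", "who", "what_to_do",
                          "which_tools", "when", "how")))
  # without a survey the vitals section is omitted
  bare <- render_alert(classify_risk(alert_record("unclear_over_20", 9)))
  expect_false(grepl("SAT", bare$message))
  expect_error(render_alert(alert_record("apnea_10_20")), "classify")
})

test_that("the 8Ws record pre-fills the computable keys", {
  rec <- alert_record("apnea_10_20", "2025-01-01T00:00:00",
                      config = monitor_config(location = "ward 3"))
  expect_match(rec$eight_ws$what, "apnea alert")
  expect_identical(rec$eight_ws$where, "ward 3")
  expect_identical(rec$eight_ws$when, "2025-01-01T00:00:00")
  expect_true(all(c("why", "who", "what_to_do", "which_tools", "how") %in%
                  names(rec$eight_ws)))
})

test_that("a simulated apnea drives the monitor into rescue", {
  rec <- quick_recording(seed = 8, n_breaths = 20, n_apnea_events = 1,
                         apnea_duration_s = 25)
  frames <- frames_from_recording(rec)
  res <- monitor_run(frames, monitor_config(g_th = 0.003))
  types <- vapply(res$events, `[[`, character(1), "type")
  expect_true("rescue" %in% types)
  t_rescue <- res$events[[which(types == "rescue")[1]]]$time_s
  ap <- rec$truth$apneas
  expect_gte(t_rescue, ap$t_start_s[1])
  expect_lte(t_rescue, ap$t_end_s[1] + 1)
})

test_that("event logs serialize one JSON object per line", {
  frames <- make_frames(list(c(5, 0.01, 0.001), c(22, 0.001, 0.002)))
  res <- monitor_run(frames, cfg)
  path <- tempfile(fileext = ".jsonl")
  write_event_log(res$events, path)
  lines <- readLines(path)
  expect_identical(length(lines), length(res$events))
  parsed <- lapply(lines, jsonlite::fromJSON)
  expect_identical(parsed[[length(parsed)]]$type %in%
                     c("rescue", "actuator_enable"), TRUE)
})
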