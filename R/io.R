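#' Write a recording to delimited text with a JSON sidecar
#'
#' The sampled channels go to a CSV (one `time_s` column plus one column per
#' channel); the ground-truth timeline and the metadata go to a JSON sidecar
#' at `<path>.json`.
#'
#' @param recording A `sim_recording`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "sim_recording"))
  ch <- recording$channels
  df <- cbind(time_s = (seq_len(nrow(ch)) - 1) / recording$sample_rate_hz, ch)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- recording$metadata
  side <- list(
    sample_rate_hz = recording$sample_rate_hz,
    truth = recording$truth,
    metadata = list(
      condition = meta$condition,
      seed = meta$seed,
      ir_distance_cm = meta$ir_distance_cm,
      temperature_c = meta$temperature_c,
      humidity_pct = meta$humidity_pct,
      sensor = unclass(meta$sensor),
      protocol = list(
        amplitude_um = meta$protocol$amplitude_um,
        rate_bpm = meta$protocol$rate_bpm,
        n_breaths = meta$protocol$n_breaths,
        angle_deg = meta$protocol$angle_deg,
        step_resolution_um = meta$protocol$step_resolution_um,
        apnea_events = meta$protocol$apnea_events)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path CSV path (the `<path>.json` sidecar must sit next to it).
#' @return A `sim_recording`.
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta <- side$metadata
  sensor <- if (!is.null(meta$sensor)) {
    do.call(sensor_model, meta$sensor[
      c("adc_bits", "range_g", "sample_rate_hz", "ir_gain_vcm",
        "ir_offset_cm", "ir_noise_sd_v", "ir_vibration_cm_per_g",
        "include_gravity")])
  } else sensor_model()
  truth <- list(
    breaths = as.data.frame(side$truth$breaths),
    apneas = as.data.frame(side$truth$apneas))
  structure(
    list(sample_rate_hz = side$sample_rate_hz,
         channels = df[, setdiff(names(df), "time_s"), drop = FALSE],
         truth = truth,
         metadata = list(condition = as.list(meta$condition),
                         seed = meta$seed,
                         ir_distance_cm = meta$ir_distance_cm,
                         sensor = sensor,
                         temperature_c = meta$temperature_c,
                         humidity_pct = meta$humidity_pct)),
    class = "sim_recording")
}

#' Write condition tallies
#'
#' CSV mirroring the reference layout (angle, displacement, detected and
#' unusable counts per mode), or JSON.
#'
#' @param tallies Condition-tally data frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_tallies <- function(tallies, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(tallies, path, row.names = FALSE)
  } else {
    jsonlite::write_json(tallies, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read condition tallies from CSV or JSON
#'
#' @param path Input path (`.csv` or `.json`).
#' @return Condition-tally data frame.
#' @export
read_tallies <- function(path) {
  if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path)
  }
}

#' Load a run configuration
#'
#' YAML or JSON file with optional sections `protocol`, `noise`, `sensor`,
#' `monitor`, `conditions` (`angles_deg`, `displacements_um`), `seed`,
#' `ir_fraction`. Unknown top-level sections are rejected.
#'
#' @param path Configuration file path.
#' @return List with constructed `protocol`, `noise`, `sensor`, `monitor`
#'   objects plus `conditions`, `seed` and `ir_fraction`.
#' @export
load_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("protocol", "noise", "sensor", "monitor", "conditions",
             "seed", "ir_fraction")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    stop("unknown configuration section(s): ", paste(extra, collapse = ", "),
         "; known sections are ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  build <- function(ctor, args) {
    if (is.null(args)) return(ctor())
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad) > 0) {
      stop("unknown key(s) ", paste(bad, collapse = ", "), " in section",
           call. = FALSE)
    }
    do.call(ctor, args)
  }
  list(
    protocol = build(breathing_protocol, raw$protocol),
    noise = build(noise_model, raw$noise),
    sensor = build(sensor_model, raw$sensor),
    monitor = build(monitor_config, raw$monitor),
    conditions = list(
      angles_deg = raw$conditions$angles_deg %||% c(45, 90, 135),
      displacements_um = raw$conditions$displacements_um %||%
        c(500, 1000, 1500)),
    seed = as.integer(raw$seed %||% 1L),
    ir_fraction = raw$ir_fraction %||% 0.5
  )
}

# Manifest written next to every CLI output: enough to reproduce the run.
write_manifest <- function(dir, config_path, seed, extra = list()) {
  manifest <- c(list(
    package = "apneasim",
    version = as.character(utils::packageVersion("apneasim")),
    seed = seed,
    config = config_path,
    config_md5 = if (!is.null(config_path) && file.exists(config_path))
      unname(tools::md5sum(config_path)) else NA_character_,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}
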