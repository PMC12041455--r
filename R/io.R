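#' Write / read a recording container
#'
#' The recording container is a flat binary payload of channel-major
#' little-endian 32-bit floats (microvolts) plus a JSON sidecar
#' (`<path>.json`) holding `fs_hz`, `n_channels`, `n_samples`, the electrode
#' layout, units, free-form metadata and an MD5 checksum of the payload.
#' Reading verifies the payload length and checksum; any mismatch is a hard
#' error. The round-trip is lossless at 32-bit float precision.
#'
#' @param recording An `mea_recording`.
#' @param path Payload file path (the sidecar is written next to it).
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an `mea_recording`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "mea_recording"))
  v <- recording$voltages
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  # channel-major: all samples of channel 1, then channel 2, ...
  writeBin(as.numeric(t(v)), con, size = 4, endian = "little")
  close(con)
  on.exit()
  sidecar <- list(
    fs_hz = recording$fs,
    n_channels = nrow(v),
    n_samples = ncol(v),
    units = "uV",
    layout = recording$layout,
    metadata = recording$metadata,
    checksum_md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar_path))
    abort("recording payload or JSON sidecar not found.")
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  n_ch <- meta$n_channels
  n_samp <- meta$n_samples
  expected <- 4 * n_ch * n_samp
  if (file.info(path)$size != expected)
    abort(sprintf("payload is %d bytes, sidecar implies %d (truncated or fs mismatch).",
                  file.info(path)$size, expected))
  if (!is.null(meta$checksum_md5) &&
      !identical(unname(tools::md5sum(path)), meta$checksum_md5))
    abort("payload checksum mismatch.")
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, "numeric", n = n_ch * n_samp, size = 4, endian = "little")
  v <- t(matrix(x, nrow = n_samp, ncol = n_ch))
  layout <- as_tibble(meta$layout)
  new_mea_recording(v, fs = meta$fs_hz, layout = layout,
                    duration_s = n_samp / meta$fs_hz,
                    metadata = as.list(meta$metadata))
}

#' Write / read a spike table as CSV
#'
#' Schema: `electrode,time_s,amplitude_uv`, comma-separated, `.` decimal
#' point, UTF-8, mandatory header, numeric fields in 6-decimal fixed format,
#' rows ordered by electrode then time. Reading validates the schema and row
#' ordering (the offending row number is reported) and returns a
#' `spike_trains` when `duration_s` is given.
#'
#' @param trains A `spike_trains` (or data frame with the schema columns).
#' @param path CSV file path.
#' @param duration_s Recording duration to attach on read.
#' @param layout Electrode layout to attach on read (default [mea_layout()]).
#' @return `write_spikes()` returns `path` invisibly; `read_spikes()` a
#'   `spike_trains` tibble.
#' @export
write_spikes <- function(trains, path) {
  df <- as_tibble(trains)[, c("electrode", "time_s", "amplitude_uv")]
  df <- arrange(df, .data$electrode, .data$time_s)
  out <- data.frame(
    electrode = df$electrode,
    time_s = sprintf("%.6f", df$time_s),
    amplitude_uv = ifelse(is.na(df$amplitude_uv), "",
                          sprintf("%.6f", df$amplitude_uv)))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path, duration_s = NULL, layout = mea_layout()) {
  df <- readr::read_csv(path, col_types = readr::cols(
    electrode = readr::col_integer(),
    time_s = readr::col_double(),
    amplitude_uv = readr::col_double()), progress = FALSE)
  if (!identical(names(df), c("electrode", "time_s", "amplitude_uv")))
    abort("spike CSV must have columns electrode,time_s,amplitude_uv.")
  if (nrow(df) > 1) {
    bad <- which(diff(df$electrode) < 0 |
                   (diff(df$electrode) == 0 & diff(df$time_s) <= 0))
    if (length(bad) > 0)
      abort(sprintf("spike CSV rows must be sorted by electrode then strictly increasing time; first violation at data row %d.",
                    bad[1] + 1L))
  }
  if (is.null(duration_s)) {
    attrless <- as_tibble(df)
    return(attrless)
  }
  spike_trains(df, duration_s = duration_s, layout = layout)
}

#' Write / read a trajectory as CSV
#'
#' Schema: `time_s,x_mm,y_mm,phase` with 6-decimal fixed numeric format.
#'
#' @param traj Trajectory data frame.
#' @param path CSV file path.
#' @param arena_radius,frame_rate Attached to the trajectory on read.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` an `mea_trajectory` tibble.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(all(c("time_s", "x_mm", "y_mm") %in% names(traj)))
  out <- data.frame(
    time_s = sprintf("%.6f", traj$time_s),
    x_mm = sprintf("%.6f", traj$x_mm),
    y_mm = sprintf("%.6f", traj$y_mm),
    phase = if ("phase" %in% names(traj)) traj$phase else "none")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, arena_radius = NA_real_,
                            frame_rate = NA_real_) {
  df <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(),
    x_mm = readr::col_double(),
    y_mm = readr::col_double(),
    phase = readr::col_character()), progress = FALSE)
  if (!identical(names(df), c("time_s", "x_mm", "y_mm", "phase")))
    abort("trajectory CSV must have columns time_s,x_mm,y_mm,phase.")
  if (nrow(df) > 1 && any(diff(df$time_s) <= 0))
    abort(sprintf("trajectory times must be strictly increasing; first violation at data row %d.",
                  which(diff(df$time_s) <= 0)[1] + 1L))
  new_mea_trajectory(df, arena_radius = arena_radius, frame_rate = frame_rate)
}

#' Write an analysis report as JSON
#'
#' Serializes a metric report (one-row tibble or named list) together with
#' full provenance: the resolved configuration and seed used for the run.
#' Two runs with identical configuration and seed produce byte-identical
#' files.
#'
#' @param report One-row data frame or named list of metrics.
#' @param path Output JSON path.
#' @param config Named list of resolved configuration (specs, scenario
#'   parameters) to embed.
#' @param seed Seed to embed.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, config = list(), seed = NULL) {
  if (is.data.frame(report)) report <- as.list(report)
  strip <- function(x) {
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  payload <- list(report = strip(report),
                  config = strip(config),
                  seed = seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
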