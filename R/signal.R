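#' Band-pass filter a recording
#'
#' Applies the spike-band filter (default 200 Hz - 3 kHz Butterworth, total
#' order 4) to every channel. With `zero_phase = TRUE` (default) the filter
#' runs forward and backward, so the passband gain is the square of the
#' single-pass gain and spike times are not shifted.
#'
#' @param recording An `mea_recording`, or a numeric vector/matrix of samples
#'   (rows = channels) with `fs` supplied.
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz; taken from the recording when one is given.
#' @return Same type as the input, filtered.
#' @export
bandpass_filter <- function(recording, spec = filter_spec(), fs = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  if (inherits(recording, "mea_recording")) {
    fs <- recording$fs
    out <- recording
    out$voltages <- bandpass_matrix(recording$voltages, spec, fs)
    out$metadata$filtered <- c(spec$low_hz, spec$high_hz)
    return(out)
  }
  if (is.null(fs)) abort("`fs` is required when filtering raw samples.")
  if (is.matrix(recording)) return(bandpass_matrix(recording, spec, fs))
  bandpass_vector(recording, spec, fs)
}

butter_coefs <- function(spec, fs) {
  if (spec$high_hz >= fs / 2)
    abort("filter cut-offs must satisfy 0 < low < high < fs/2.")
  signal::butter(spec$order / 2,
                 c(spec$low_hz, spec$high_hz) / (fs / 2),
                 type = "pass")
}

# forward-backward IIR pass: zero phase, squared magnitude response; edge
# transients are left in place and excluded later via edge_exclude_s
apply_filter_pass <- function(bf, x, zero_phase) {
  b <- as.numeric(bf$b)
  a <- as.numeric(bf$a)
  y <- iir_filter_cpp(b, a, x)
  if (zero_phase) y <- rev(iir_filter_cpp(b, a, rev(y)))
  y
}

bandpass_vector <- function(x, spec, fs) {
  apply_filter_pass(butter_coefs(spec, fs), x, spec$zero_phase)
}

bandpass_matrix <- function(m, spec, fs) {
  bf <- butter_coefs(spec, fs)
  for (i in seq_len(nrow(m))) {
    m[i, ] <- apply_filter_pass(bf, m[i, ], spec$zero_phase)
  }
  m
}

#' Estimate the background-noise RMS of a trace
#'
#' The default estimator is the median absolute deviation about zero scaled
#' for a Gaussian, `median(|x|) / 0.6745`: spikes present during calibration
#' then barely inflate the estimate, unlike the plain RMS. The plain root
#' mean square is available with `method = "rms"`.
#'
#' @param x Numeric vector of (filtered) samples.
#' @param method `"mad"` (default) or `"rms"`.
#' @return Estimated noise RMS in the units of `x`.
#' @export
#' @examples
#' estimate_background_rms(rnorm(1e4, sd = 3))
estimate_background_rms <- function(x, method = c("mad", "rms")) {
  method <- match.arg(method)
  if (length(x) == 0) abort("empty trace.")
  if (method == "mad") median(abs(x)) / 0.6745 else sqrt(mean(x^2))
}

#' Detect spikes by adaptive RMS thresholding
#'
#' Per channel, the detection threshold is `threshold_multiplier` (default
#' 5.5) times the calibrated background-noise RMS. An event is a contiguous
#' excursion beyond the threshold (both polarities by default); its time is
#' the extreme sample and its amplitude the signed extreme value. Events
#' closer than the dead time are merged, keeping the larger excursion (ties
#' keep the earlier event). The first and last `edge_exclude_s` of each trace
#' are excluded to avoid filter transients.
#'
#' @param recording An `mea_recording` (raw or already filtered).
#' @param filter_spec A [filter_spec()]; ignored when `apply_filter = FALSE`.
#' @param detector_spec A [detector_spec()].
#' @param apply_filter Band-pass the recording first (default `TRUE`). Set to
#'   `FALSE` for traces that are already in the spike band.
#' @param noise_rms Optional externally calibrated noise RMS (scalar, or one
#'   value per channel); overrides per-recording calibration, e.g. when the
#'   threshold was set on a separate noise segment.
#' @return A `spike_trains` tibble with columns `electrode`, `time_s`,
#'   `amplitude_uv`, carrying `duration_s`, `layout`, `fs` and the
#'   per-electrode `thresholds` as attributes. Channels whose calibrated RMS
#'   is zero are flagged with a warning and yield no events.
#' @export
detect_spikes <- function(recording,
                          filter_spec = meafish::filter_spec(),
                          detector_spec = meafish::detector_spec(),
                          apply_filter = TRUE,
                          noise_rms = NULL) {
  stopifnot(inherits(recording, "mea_recording"),
            inherits(detector_spec, "detector_spec"))
  v <- recording$voltages
  fs <- recording$fs
  n_ch <- nrow(v)
  if (!is.null(noise_rms)) {
    noise_rms <- rep_len(noise_rms, n_ch)
  }
  bf <- if (apply_filter) butter_coefs(filter_spec, fs) else NULL
  ds <- detector_spec
  edge <- round(ds$edge_exclude_s * fs)
  dead_samp <- ds$dead_time_ms / 1000 * fs

  res <- vector("list", n_ch)
  thr_out <- numeric(n_ch)
  zero_rms <- integer(0)
  for (ch in seq_len(n_ch)) {
    x <- v[ch, ]
    if (!is.null(bf)) x <- apply_filter_pass(bf, x, filter_spec$zero_phase)
    rms <- if (!is.null(noise_rms)) noise_rms[ch]
           else estimate_background_rms(x, ds$rms_method)
    thr_out[ch] <- ds$threshold_multiplier * rms
    if (rms <= 0) {
      zero_rms <- c(zero_rms, ch)
      res[[ch]] <- NULL
      next
    }
    ev <- detect_events(x, thr_out[ch], ds$polarity, edge, dead_samp)
    if (length(ev$idx) > 0) {
      res[[ch]] <- tibble(electrode = ch,
                          time_s = (ev$idx - 1) / fs,
                          amplitude_uv = ev$amp)
    }
  }
  if (length(zero_rms) > 0)
    warn(sprintf("channels with zero calibrated RMS (no detection): %s",
                 paste(zero_rms, collapse = ", ")))
  out <- bind_rows(res)
  if (nrow(out) == 0)
    out <- tibble(electrode = integer(), time_s = numeric(),
                  amplitude_uv = numeric())
  new_spike_trains(out, duration_s = recording$duration_s,
                   layout = recording$layout, fs = fs,
                   thresholds = tibble(electrode = seq_len(n_ch),
                                       threshold_uv = thr_out))
}

# threshold-excursion events on one trace: contiguous runs beyond the
# threshold, extreme-sample timing, dead-time merging
detect_events <- function(x, thr, polarity, edge, dead_samp) {
  n <- length(x)
  lo <- edge + 1L
  hi <- n - edge
  if (hi <= lo) return(list(idx = integer(0), amp = numeric(0)))
  seg <- x[lo:hi]
  over <- switch(polarity,
                 both = abs(seg) > thr,
                 negative = seg < -thr,
                 positive = seg > thr)
  if (!any(over)) return(list(idx = integer(0), amp = numeric(0)))
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  idx <- integer(length(runs)); amp <- numeric(length(runs))
  for (k in seq_along(runs)) {
    i0 <- starts[runs[k]]; i1 <- ends[runs[k]]
    seg_k <- seg[i0:i1]
    j <- which.max(abs(seg_k))
    idx[k] <- lo - 1L + i0 + j - 1L
    amp[k] <- seg_k[j]
  }
  # merge events closer than the dead time, keeping the larger |amplitude|
  # (tie -> earlier)
  if (length(idx) > 1 && dead_samp > 0) {
    keep_idx <- idx[1]; keep_amp <- amp[1]
    out_i <- integer(0); out_a <- numeric(0)
    for (k in 2:length(idx)) {
      if (idx[k] - keep_idx < dead_samp) {
        if (abs(amp[k]) > abs(keep_amp)) {
          keep_idx <- idx[k]; keep_amp <- amp[k]
        }
      } else {
        out_i <- c(out_i, keep_idx); out_a <- c(out_a, keep_amp)
        keep_idx <- idx[k]; keep_amp <- amp[k]
      }
    }
    idx <- c(out_i, keep_idx); amp <- c(out_a, keep_amp)
  }
  list(idx = idx, amp = amp)
}

#' Construct a spike-train set
#'
#' Bundles per-electrode spike times (and optional signed peak amplitudes)
#' with the recording duration and electrode layout. Times must be strictly
#' increasing within each electrode and lie in `[0, duration_s]`.
#'
#' @param spikes Data frame with columns `electrode`, `time_s` and optionally
#'   `amplitude_uv`.
#' @param duration_s Recording (or analysis) duration in seconds.
#' @param layout Electrode layout tibble (default [mea_layout()]).
#' @param fs Sampling rate, if known.
#' @param thresholds Optional per-electrode threshold table.
#' @return A `spike_trains` tibble sorted by electrode then time.
#' @export
spike_trains <- function(spikes, duration_s, layout = mea_layout(),
                         fs = NA_real_, thresholds = NULL) {
  stopifnot(is.data.frame(spikes),
            all(c("electrode", "time_s") %in% names(spikes)))
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  df <- as_tibble(spikes)
  if (!"amplitude_uv" %in% names(df)) df$amplitude_uv <- NA_real_
  df <- arrange(df[, c("electrode", "time_s", "amplitude_uv")],
                .data$electrode, .data$time_s)
  if (nrow(df) > 0) {
    if (any(df$time_s < 0 | df$time_s > duration_s))
      abort("spike times must lie in [0, duration_s].")
    bad <- df |>
      group_by(.data$electrode) |>
      summarise(ok = all(diff(.data$time_s) > 0), .groups = "drop")
    if (!all(bad$ok))
      abort("spike times must be strictly increasing within each electrode.")
  }
  new_spike_trains(df, duration_s = duration_s, layout = layout, fs = fs,
                   thresholds = thresholds)
}

new_spike_trains <- function(df, duration_s, layout, fs = NA_real_,
                             thresholds = NULL) {
  out <- as_tibble(df)
  attr(out, "duration_s") <- duration_s
  attr(out, "layout") <- layout
  attr(out, "fs") <- fs
  attr(out, "thresholds") <- thresholds
  class(out) <- unique(c("spike_trains", class(out)))
  out
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("<spike_trains> %d spikes on %d electrodes over %.1f s\n",
              nrow(x), length(unique(x$electrode)),
              attr(x, "duration_s")))
  NextMethod()
}
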