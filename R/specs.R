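#' Electrode grid layout
#'
#' Build the electrode layout table for a rectangular MEA grid. The default is
#' the 8 x 8 (64-channel) array of a 6-well CytoView-style plate. Electrodes
#' are numbered column-major: electrode 1 is (row 1, col 1), electrode 8 is
#' (row 8, col 1), electrode 9 is (row 1, col 2), and so on.
#'
#' @param n_rows,n_cols Grid dimensions (default 8 x 8).
#' @return A tibble with columns `electrode`, `row`, `col`.
#' @export
#' @examples
#' mea_layout()
mea_layout <- function(n_rows = 8, n_cols = 8) {
  check_number(n_rows, "n_rows", lower = 1)
  check_number(n_cols, "n_cols", lower = 1)
  tibble(
    electrode = seq_len(n_rows * n_cols),
    row = rep(seq_len(n_rows), times = n_cols),
    col = rep(seq_len(n_cols), each = n_rows)
  )
}

#' Default head-region electrode mask
#'
#' With a larva mounted laterally across the array, the head overlies roughly
#' two grid columns; the default mask takes the electrodes of the first
#' `head_cols` columns (16 electrodes on the 8 x 8 grid). Real mounting
#' orientation varies, so the mask is always user-overridable wherever it is
#' consumed.
#'
#' @param layout Layout tibble from [mea_layout()].
#' @param head_cols Which grid columns are under the head (default `1:2`).
#' @return Integer vector of electrode indices.
#' @export
default_head_mask <- function(layout = mea_layout(), head_cols = 1:2) {
  sort(layout$electrode[layout$col %in% head_cols])
}

#' Band-pass filter specification
#'
#' Cut-offs follow the acquisition pipeline for extracellular spikes:
#' 200 Hz to 3 kHz. The realization is a Butterworth band-pass of total order
#' `order`, applied forward-backward (zero phase) by default so spike times
#' are not shifted.
#'
#' @param low_hz,high_hz Cut-off frequencies in Hz.
#' @param order Total filter order (even; default 4).
#' @param zero_phase Apply forward-backward filtering (default `TRUE`).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 200, high_hz = 3000, order = 4,
                        zero_phase = TRUE) {
  check_number(low_hz, "low_hz", lower = 0, strict_lower = TRUE)
  check_number(high_hz, "high_hz", lower = low_hz, strict_lower = TRUE)
  check_number(order, "order", lower = 2)
  if (order %% 2 != 0) abort("`order` must be even.")
  structure(
    list(low_hz = low_hz, high_hz = high_hz, order = order,
         zero_phase = isTRUE(zero_phase)),
    class = "filter_spec"
  )
}

#' Spike detector specification
#'
#' The detection threshold is `threshold_multiplier` times the background-noise
#' RMS, applied to both polarities by default (the printed convention is
#' "+/- 5.5"). Background RMS is calibrated per recording with a robust
#' (median-absolute-deviation) estimator unless `rms_method = "rms"`.
#'
#' @param threshold_multiplier Threshold as a multiple of background RMS
#'   (default 5.5).
#' @param polarity One of `"both"`, `"negative"`, `"positive"`.
#' @param dead_time_ms Events closer than this are merged, keeping the larger
#'   excursion (default 2 ms).
#' @param rms_method `"mad"` (robust, default) or `"rms"` (plain root mean
#'   square).
#' @param edge_exclude_s Trace length excluded from detection at each end to
#'   avoid filter transients (default 0.1 s).
#' @return An object of class `detector_spec`.
#' @export
detector_spec <- function(threshold_multiplier = 5.5,
                          polarity = c("both", "negative", "positive"),
                          dead_time_ms = 2,
                          rms_method = c("mad", "rms"),
                          edge_exclude_s = 0.1) {
  check_number(threshold_multiplier, "threshold_multiplier",
               lower = 0, strict_lower = TRUE)
  check_number(dead_time_ms, "dead_time_ms", lower = 0)
  check_number(edge_exclude_s, "edge_exclude_s", lower = 0)
  structure(
    list(threshold_multiplier = threshold_multiplier,
         polarity = match.arg(polarity),
         dead_time_ms = dead_time_ms,
         rms_method = match.arg(rms_method),
         edge_exclude_s = edge_exclude_s),
    class = "detector_spec"
  )
}

#' Spike-train metric specification
#'
#' Defaults mirror the standard neural-metric conventions for larval MEA
#' recordings: an electrode is active at >= 5 spikes/min (inclusive); a burst
#' is >= 5 consecutive spikes on one active electrode with every ISI strictly
#' below 100 ms; a network burst is >= 5 consecutive pooled spikes across
#' >= 2 electrodes with pooled ISIs strictly below 100 ms and electrode
#' involvement >= 10% of the array; metrics are computed on the most active
#' contiguous 5-min window.
#'
#' `head_ratio_threshold` (head-vs-trunk rate ratio declaring brain-region
#' hyperactivity, default 2.0) is this package's own convention: no published
#' quantitative rule exists for that classification.
#'
#' @param active_threshold Active-electrode threshold in spikes/min
#'   (inclusive; default 5).
#' @param burst_min_spikes Minimum spikes per burst (default 5).
#' @param burst_max_isi_s Strict ISI cut-off within a burst, seconds
#'   (default 0.1).
#' @param nb_min_spikes Minimum pooled spikes per network burst (default 5).
#' @param nb_max_isi_s Strict pooled ISI cut-off, seconds (default 0.1).
#' @param nb_min_involvement Minimum fraction of electrodes recruited
#'   (inclusive; default 0.10).
#' @param analysis_window_s Analysis window length, seconds (default 300).
#' @param head_ratio_threshold Head/trunk WMFR ratio for the hyperactivity
#'   call (default 2.0; package convention, not a published value).
#' @return An object of class `metric_spec`.
#' @export
metric_spec <- function(active_threshold = 5,
                        burst_min_spikes = 5,
                        burst_max_isi_s = 0.1,
                        nb_min_spikes = 5,
                        nb_max_isi_s = 0.1,
                        nb_min_involvement = 0.10,
                        analysis_window_s = 300,
                        head_ratio_threshold = 2.0) {
  check_number(active_threshold, "active_threshold", lower = 0)
  check_number(burst_min_spikes, "burst_min_spikes", lower = 1)
  check_number(burst_max_isi_s, "burst_max_isi_s", lower = 0,
               strict_lower = TRUE)
  check_number(nb_min_spikes, "nb_min_spikes", lower = 1)
  check_number(nb_max_isi_s, "nb_max_isi_s", lower = 0, strict_lower = TRUE)
  check_number(nb_min_involvement, "nb_min_involvement", lower = 0,
               upper = 1, strict_lower = TRUE)
  check_number(analysis_window_s, "analysis_window_s", lower = 0,
               strict_lower = TRUE)
  check_number(head_ratio_threshold, "head_ratio_threshold", lower = 0,
               strict_lower = TRUE)
  structure(
    list(active_threshold = active_threshold,
         burst_min_spikes = as.integer(burst_min_spikes),
         burst_max_isi_s = burst_max_isi_s,
         nb_min_spikes = as.integer(nb_min_spikes),
         nb_max_isi_s = nb_max_isi_s,
         nb_min_involvement = nb_min_involvement,
         analysis_window_s = analysis_window_s,
         head_ratio_threshold = head_ratio_threshold),
    class = "metric_spec"
  )
}

#' Rotation-counting specification
#'
#' One rotation event is a full `full_turn_deg` (default 360 degrees) of
#' cumulative same-direction turning, following tracking-software convention.
#' The published parameters "threshold of 45 degrees and a minimum distance of
#' 1 mm" are read as: a counter-turn exceeding `opposing_tolerance_deg` resets
#' the accumulator, and headings are only updated between points at least
#' `min_step_mm` apart. The alternative reading (every 45-degree turn counts
#' as one event) is available by setting `full_turn_deg = 45`.
#'
#' @param full_turn_deg Cumulative turn for one rotation event (default 360).
#' @param opposing_tolerance_deg Counter-turn that resets accumulation
#'   (default 45).
#' @param min_step_mm Minimum displacement for a heading update (default 1).
#' @return An object of class `rotation_spec`.
#' @export
rotation_spec <- function(full_turn_deg = 360,
                          opposing_tolerance_deg = 45,
                          min_step_mm = 1.0) {
  check_number(full_turn_deg, "full_turn_deg", lower = 0, strict_lower = TRUE)
  check_number(opposing_tolerance_deg, "opposing_tolerance_deg",
               lower = 0, strict_lower = TRUE,
               upper = full_turn_deg, strict_upper = TRUE)
  check_number(min_step_mm, "min_step_mm", lower = 0, strict_lower = TRUE)
  structure(
    list(full_turn_deg = full_turn_deg,
         opposing_tolerance_deg = opposing_tolerance_deg,
         min_step_mm = min_step_mm),
    class = "rotation_spec"
  )
}
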