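trains_duration <- function(trains, duration_s = NULL) {
  d <- duration_s %||% attr(trains, "duration_s")
  if (is.null(d)) abort("`duration_s` is required (not carried by the input).")
  d
}

trains_layout <- function(trains, layout = NULL) {
  l <- layout %||% attr(trains, "layout")
  if (is.null(l)) l <- mea_layout()
  l
}

#' Crop a spike-train set to a time window
#'
#' Keeps spikes with `t0 <= time_s < t1` and (by default) rebases times to
#' start at zero, so the result is a valid `spike_trains` of duration
#' `t1 - t0`.
#'
#' @param trains A `spike_trains` tibble.
#' @param t0,t1 Window bounds in seconds (half-open).
#' @param rebase Shift times by `-t0` (default `TRUE`).
#' @return A `spike_trains` tibble.
#' @export
window_trains <- function(trains, t0, t1, rebase = TRUE) {
  stopifnot(t1 > t0)
  df <- trains[trains$time_s >= t0 & trains$time_s < t1, , drop = FALSE]
  if (rebase) df$time_s <- df$time_s - t0
  new_spike_trains(as_tibble(df), duration_s = t1 - t0,
                   layout = trains_layout(trains), fs = attr(trains, "fs"))
}

#' Select the most active analysis window
#'
#' Scans contiguous windows of length `analysis_window_s` (candidate starts on
#' a 1-s lattice) and returns the one maximizing total spike count; ties go to
#' the earliest start. This mirrors the convention of analyzing the 5 minutes
#' of recording showing active neural responses.
#'
#' @param trains A `spike_trains` tibble.
#' @param spec A [metric_spec()].
#' @param duration_s Recording duration; defaults to the value carried by
#'   `trains`.
#' @return One-row tibble with `t0`, `t1`, `n_spikes`.
#' @export
select_analysis_window <- function(trains, spec = metric_spec(),
                                   duration_s = NULL) {
  dur <- trains_duration(trains, duration_s)
  win <- spec$analysis_window_s
  if (dur < win)
    abort(sprintf("recording (%.1f s) shorter than the analysis window (%.1f s).",
                  dur, win))
  starts <- seq(0, floor(dur - win))
  tt <- sort(trains$time_s)
  count_lt <- function(s) findInterval(s, tt, left.open = TRUE)
  counts <- count_lt(starts + win) - count_lt(starts)
  best <- which.max(counts)   # which.max takes the earliest tie
  tibble(t0 = starts[best], t1 = starts[best] + win,
         n_spikes = as.integer(counts[best]))
}

#' Classify an electrode as active
#'
#' An electrode is active when its firing rate reaches the threshold
#' (default 5 spikes/min, inclusive: exactly 5 spikes in 60 s qualifies).
#'
#' @param times Spike times on one electrode (seconds), or a spike count.
#' @param duration_s Observation duration, seconds.
#' @param spec A [metric_spec()].
#' @return Logical.
#' @export
#' @examples
#' classify_active(seq(0, 59, length.out = 5), 60)  # TRUE
#' classify_active(seq(0, 59, length.out = 4), 60)  # FALSE
classify_active <- function(times, duration_s, spec = metric_spec()) {
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  rate_per_min <- length(times) / (duration_s / 60)
  rate_per_min >= spec$active_threshold
}

#' Per-electrode firing rates and activity status
#'
#' @param trains A `spike_trains` tibble.
#' @param spec A [metric_spec()].
#' @param duration_s Observation duration; defaults to the value carried by
#'   `trains`.
#' @return Tibble with one row per electrode in the layout: `electrode`,
#'   `n_spikes`, `rate_hz`, `rate_per_min`, `active`.
#' @export
electrode_rates <- function(trains, spec = metric_spec(), duration_s = NULL) {
  dur <- trains_duration(trains, duration_s)
  layout <- trains_layout(trains)
  counts <- trains |>
    group_by(.data$electrode) |>
    summarise(n_spikes = n(), .groups = "drop")
  out <- left_join(layout["electrode"], counts, by = "electrode")
  out$n_spikes[is.na(out$n_spikes)] <- 0L
  out$rate_hz <- out$n_spikes / dur
  out$rate_per_min <- out$n_spikes / (dur / 60)
  out$active <- out$rate_per_min >= spec$active_threshold
  out
}

#' Weighted mean firing rate
#'
#' The mean firing rate over active electrodes only. With zero active
#' electrodes the rate is undefined and `NA` is returned (never 0, which
#' would misstate complete silence as a measured rate).
#'
#' @inheritParams electrode_rates
#' @return Firing rate in Hz, or `NA_real_` when no electrode is active.
#' @export
weighted_mean_firing_rate <- function(trains, spec = metric_spec(),
                                      duration_s = NULL) {
  r <- electrode_rates(trains, spec, duration_s)
  if (!any(r$active)) {
    warn("no active electrodes: weighted mean firing rate is undefined (NA).")
    return(NA_real_)
  }
  mean(r$rate_hz[r$active])
}

# maximal runs of >= min_spikes consecutive spikes with every ISI strictly
# below max_isi (with the package's floating-point tie tolerance)
burst_runs <- function(times, min_spikes, max_isi) {
  n <- length(times)
  if (n < min_spikes)
    return(tibble(i_start = integer(), i_end = integer()))
  if (is.unsorted(times, strictly = TRUE))
    abort("spike times must be strictly increasing.")
  ok <- lt_tol(diff(times), max_isi)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values & r$lengths >= (min_spikes - 1L))
  tibble(i_start = starts[sel], i_end = ends[sel] + 1L)
}

#' Detect single-electrode bursts
#'
#' A burst is a maximal run of at least `burst_min_spikes` consecutive spikes
#' on one electrode whose every inter-spike interval is strictly below
#' `burst_max_isi_s`. By default, bursts on electrodes that fail the
#' active-electrode rule are discarded (bursts are defined on active
#' electrodes).
#'
#' @param trains A `spike_trains` tibble, or a numeric vector of spike times
#'   (then `duration_s` is required for the activity rule).
#' @param spec A [metric_spec()].
#' @param duration_s Observation duration.
#' @param active_only Discard bursts on inactive electrodes (default `TRUE`).
#' @return Tibble of disjoint, ordered bursts: `electrode`, `t_start`,
#'   `t_end`, `n_spikes`.
#' @export
#' @examples
#' detect_bursts(spike_trains(
#'   tibble::tibble(electrode = 1, time_s = seq(0, by = 0.05, length.out = 6)),
#'   duration_s = 60))
detect_bursts <- function(trains, spec = metric_spec(), duration_s = NULL,
                          active_only = TRUE) {
  if (is.numeric(trains) && !is.data.frame(trains)) {
    if (is.unsorted(trains, strictly = TRUE))
      abort("spike times must be strictly increasing.")
    dur <- duration_s %||% abort("`duration_s` required for a bare time vector.")
    trains <- spike_trains(tibble(electrode = 1L, time_s = as.numeric(trains)),
                           duration_s = dur, layout = mea_layout(1, 1))
  }
  dur <- trains_duration(trains, duration_s)
  rates <- electrode_rates(trains, spec, dur)
  empty <- tibble(electrode = integer(), t_start = numeric(),
                  t_end = numeric(), n_spikes = integer())
  if (nrow(trains) == 0) return(empty)
  out <- trains |>
    as_tibble() |>
    group_by(.data$electrode) |>
    dplyr::reframe({
      ts <- .data$time_s
      b <- burst_runs(ts, spec$burst_min_spikes, spec$burst_max_isi_s)
      tibble(t_start = ts[b$i_start],
             t_end = ts[b$i_end],
             n_spikes = b$i_end - b$i_start + 1L)
    })
  if (nrow(out) == 0) return(empty)
  if (active_only && nrow(out) > 0) {
    act <- rates$electrode[rates$active]
    out <- out[out$electrode %in% act, , drop = FALSE]
  }
  arrange(out, .data$electrode, .data$t_start)
}

#' Detect network bursts
#'
#' Pools all spikes across electrodes into one time-sorted sequence and finds
#' maximal runs of at least `nb_min_spikes` spikes with pooled inter-spike
#' intervals strictly below `nb_max_isi_s`. A run qualifies as a network burst
#' when its contributing electrodes span at least `nb_min_involvement` of the
#' array (inclusive) and at least 2 distinct electrodes ("across multiple
#' electrodes" excludes single-electrode runs even on tiny arrays).
#'
#' @param trains A `spike_trains` tibble.
#' @param spec A [metric_spec()].
#' @param denominator `"all"` (default): involvement is counted over every
#'   electrode in the layout; `"active"`: over active electrodes only.
#' @param duration_s Observation duration (for the activity rule under
#'   `denominator = "active"`).
#' @return Tibble: `t_start`, `t_end`, `n_spikes`, `n_electrodes`,
#'   `involvement`.
#' @export
detect_network_bursts <- function(trains, spec = metric_spec(),
                                  denominator = c("all", "active"),
                                  duration_s = NULL) {
  denominator <- match.arg(denominator)
  layout <- trains_layout(trains)
  n_den <- if (denominator == "all") {
    nrow(layout)
  } else {
    r <- electrode_rates(trains, spec, trains_duration(trains, duration_s))
    max(sum(r$active), 1L)
  }
  empty <- tibble(t_start = numeric(), t_end = numeric(),
                  n_spikes = integer(), n_electrodes = integer(),
                  involvement = numeric())
  if (nrow(trains) == 0) return(empty)
  ord <- order(trains$time_s, trains$electrode)
  tt <- trains$time_s[ord]
  el <- trains$electrode[ord]
  # pooled times may tie across electrodes; treat equal times as ISI 0
  ok <- lt_tol(diff(tt), spec$nb_max_isi_s) | diff(tt) == 0
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values & r$lengths >= (spec$nb_min_spikes - 1L))
  if (length(sel) == 0) return(empty)
  rows <- lapply(sel, function(k) {
    i0 <- starts[k]; i1 <- ends[k] + 1L
    els <- unique(el[i0:i1])
    tibble(t_start = tt[i0], t_end = tt[i1],
           n_spikes = i1 - i0 + 1L,
           n_electrodes = length(els),
           involvement = length(els) / n_den)
  })
  out <- bind_rows(rows)
  out[out$involvement >= spec$nb_min_involvement - 1e-12 &
        out$n_electrodes >= 2L, , drop = FALSE]
}

#' Burst and network-burst frequency
#'
#' Number of detected episodes divided by the analysis-window length, in Hz.
#'
#' @param bursts A burst (or network-burst) tibble.
#' @param window_s Window length in seconds.
#' @return Frequency in Hz.
#' @export
burst_frequency <- function(bursts, window_s) {
  check_number(window_s, "window_s", lower = 0, strict_lower = TRUE)
  nrow(bursts) / window_s
}

#' @rdname burst_frequency
#' @export
network_burst_frequency <- function(bursts, window_s)
  burst_frequency(bursts, window_s)

#' Spike-amplitude heatmap over the electrode grid
#'
#' Mean absolute spike amplitude per electrode, placed at its grid position.
#' Electrodes without spikes are `NA` (defined-missing, not 0).
#'
#' @param trains A `spike_trains` tibble with an `amplitude_uv` column.
#' @return Tibble with one row per grid electrode: `electrode`, `row`, `col`,
#'   `mean_abs_amplitude_uv`.
#' @export
amplitude_heatmap <- function(trains) {
  layout <- trains_layout(trains)
  amp <- trains |>
    as_tibble() |>
    group_by(.data$electrode) |>
    summarise(mean_abs_amplitude_uv = mean(abs(.data$amplitude_uv)),
              .groups = "drop")
  left_join(layout, amp, by = "electrode")
}

#' Raster event table
#'
#' Losslessly re-indexes a spike-train set as an ordered (electrode, time)
#' event table for raster plotting; together with the duration and layout it
#' round-trips back to the identical `spike_trains`.
#'
#' @param trains A `spike_trains` tibble.
#' @return Tibble `electrode`, `time_s`, ordered by electrode then time.
#' @export
raster_events <- function(trains) {
  ord <- order(trains$electrode, trains$time_s)
  tibble(electrode = trains$electrode[ord], time_s = trains$time_s[ord])
}

#' Classify brain-region hyperactivity
#'
#' Compares the weighted mean firing rate of the head-region electrodes with
#' that of the remaining (trunk) electrodes. The larva is called hyperactive
#' in the brain region when the head/trunk ratio reaches
#' `head_ratio_threshold` (default 2.0). This quantitative criterion is this
#' package's own convention - no published rule exists - and the supporting
#' ratio is always returned so users can apply their own cut-off. When either
#' region has no active electrode the status is indeterminate (`NA`),
#' distinct from "not hyperactive".
#'
#' @param trains A `spike_trains` tibble.
#' @param head_mask Electrode indices of the head region; must be a non-empty
#'   strict subset of the layout.
#' @param spec A [metric_spec()].
#' @param duration_s Observation duration.
#' @return One-row tibble: `hyperactive` (logical, `NA` when indeterminate),
#'   `ratio`, `head_wmfr_hz`, `trunk_wmfr_hz`.
#' @export
classify_brain_hyperactivity <- function(trains, head_mask = NULL,
                                         spec = metric_spec(),
                                         duration_s = NULL) {
  layout <- trains_layout(trains)
  if (is.null(head_mask)) head_mask <- default_head_mask(layout)
  if (length(head_mask) == 0 ||
      !all(head_mask %in% layout$electrode) ||
      length(head_mask) >= nrow(layout))
    abort("`head_mask` must be a non-empty strict subset of the electrodes.")
  dur <- trains_duration(trains, duration_s)
  r <- electrode_rates(trains, spec, dur)
  head_r <- r[r$electrode %in% head_mask, ]
  trunk_r <- r[!r$electrode %in% head_mask, ]
  head_w <- if (any(head_r$active)) mean(head_r$rate_hz[head_r$active]) else NA_real_
  trunk_w <- if (any(trunk_r$active)) mean(trunk_r$rate_hz[trunk_r$active]) else NA_real_
  ratio <- head_w / trunk_w
  hyper <- if (is.na(ratio)) NA else ratio >= spec$head_ratio_threshold
  tibble(hyperactive = hyper, ratio = ratio,
         head_wmfr_hz = head_w, trunk_wmfr_hz = trunk_w)
}

#' Full neural-metric report for one recording
#'
#' Selects the most active analysis window (default 5 min), then computes the
#' standard spike-train metrics on it: active-electrode count, weighted mean
#' firing rate, burst frequency, network-burst frequency, and the brain-region
#' hyperactivity call.
#'
#' @param trains A `spike_trains` tibble covering the whole recording.
#' @param spec A [metric_spec()].
#' @param head_mask Head-region electrodes (default [default_head_mask()]).
#' @param window Optional fixed window `c(t0, t1)`; by default the most
#'   active window is selected with [select_analysis_window()]. Recordings
#'   shorter than the analysis window are used whole.
#' @return One-row tibble: `t0`, `t1`, `n_active`, `wmfr_hz`, `n_bursts`,
#'   `burst_freq_hz`, `n_network_bursts`, `network_burst_freq_hz`,
#'   `head_hyperactive`, `head_trunk_ratio`.
#' @export
neural_metrics <- function(trains, spec = metric_spec(), head_mask = NULL,
                           window = NULL) {
  dur <- trains_duration(trains)
  if (is.null(window)) {
    window <- if (dur >= spec$analysis_window_s) {
      w <- select_analysis_window(trains, spec)
      c(w$t0, w$t1)
    } else c(0, dur)
  }
  wt <- window_trains(trains, window[1], window[2])
  win_len <- window[2] - window[1]
  rates <- electrode_rates(wt, spec)
  wmfr <- if (any(rates$active)) mean(rates$rate_hz[rates$active]) else NA_real_
  bursts <- detect_bursts(wt, spec)
  nbs <- detect_network_bursts(wt, spec)
  hyp <- classify_brain_hyperactivity(wt, head_mask, spec)
  tibble(
    t0 = window[1], t1 = window[2],
    n_active = sum(rates$active),
    wmfr_hz = wmfr,
    n_bursts = nrow(bursts),
    burst_freq_hz = burst_frequency(bursts, win_len),
    n_network_bursts = nrow(nbs),
    network_burst_freq_hz = network_burst_frequency(nbs, win_len),
    head_hyperactive = hyp$hyperactive,
    head_trunk_ratio = hyp$ratio
  )
}
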