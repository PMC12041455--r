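#' Recording scenario for the synthetic MEA generator
#'
#' Describes one simulated larva-on-MEA recording: Gaussian background noise
#' of a target RMS, tonic spiking as a gamma-renewal process with an absolute
#' refractory period, single-electrode burst episodes, and network events that
#' recruit a fixed fraction of electrodes within a short jitter window.
#' Scenario labels adjust the defaults: `napb_cr`-type scenarios elevate the
#' firing and burst rates of the head-region electrodes by
#' `head_rate_multiplier`; `*_ptz` scenarios multiply all event rates by
#' `ptz_rate_multiplier` and default to a 30-min duration.
#'
#' Published sources for this preparation give only the acquisition parameters
#' (12.5 kHz sampling, 8 x 8 array), not noise levels or firing-rate
#' magnitudes, so the amplitude/rate defaults are order-of-magnitude choices
#' typical of larval zebrafish MEA work, documented here and in the package
#' vignette; they are not calibrated to any published figure.
#'
#' @param scenario One of `"control"`, `"napb_cr"`, `"control_ptz"`,
#'   `"napb_cr_ptz"`.
#' @param n_rows,n_cols Electrode grid (default 8 x 8 = 64 channels).
#' @param fs Sampling rate, Hz (default 12500).
#' @param duration_s Recording length, seconds (default 600 spontaneous,
#'   1800 for PTZ scenarios).
#' @param noise_rms Background-noise RMS, microvolts (default 3).
#' @param spike_amplitude Spike peak amplitude as a multiple of `noise_rms`
#'   (default 10). A value below 1 triggers a warning: such spikes are
#'   undetectable by construction.
#' @param per_electrode_rate Tonic firing rate per electrode, spikes/s
#'   (default 1).
#' @param burst_rate Single-electrode burst rate, bursts/min (default 4).
#' @param spikes_per_burst Spikes per burst episode (default 5).
#' @param intra_burst_isi Within-burst ISI, seconds (default 0.05).
#' @param network_burst_rate Network-event rate, events/min (default 2).
#' @param involvement_fraction Fraction of electrodes recruited per network
#'   event; `ceiling(involvement_fraction * n_electrodes)` electrodes fire
#'   (default 0.25).
#' @param recruit_jitter_s Onset jitter of recruited electrodes within a
#'   network event, seconds (default 0.01, well below the 0.1 s pooled-ISI
#'   criterion).
#' @param episode_min_gap_s Minimum quiet gap enforced between successive
#'   episodes (bursts or network events); later-starting episodes violating
#'   it are thinned (default 1 s, so ground-truth episodes stay separable by
#'   the 0.1 s ISI criterion with a wide margin).
#' @param head_mask Electrode indices of the head region (default: first two
#'   grid columns, see [default_head_mask()]).
#' @param head_rate_multiplier Rate multiplier for head electrodes (default
#'   2.5 in `napb_cr` scenarios, 1 otherwise).
#' @param ptz_rate_multiplier Global rate multiplier in PTZ scenarios
#'   (default 2).
#' @param refractory_s Absolute refractory period of the tonic renewal
#'   process, seconds (default 0.002).
#' @param isi_shape Gamma shape of the renewal ISI distribution (default 2;
#'   1 recovers an exponential renewal above the refractory period).
#' @param pink_noise_fraction Fraction of noise variance drawn from a 1/f
#'   process (default 0, pure white Gaussian).
#' @param seed Integer seed; identical scenario + seed gives bit-identical
#'   output.
#' @return An object of class `recording_scenario`.
#' @export
recording_scenario <- function(scenario = c("control", "napb_cr",
                                            "control_ptz", "napb_cr_ptz"),
                               n_rows = 8, n_cols = 8,
                               fs = 12500,
                               duration_s = NULL,
                               noise_rms = 3,
                               spike_amplitude = 10,
                               per_electrode_rate = 1,
                               burst_rate = 4,
                               spikes_per_burst = 5,
                               intra_burst_isi = 0.05,
                               network_burst_rate = 2,
                               involvement_fraction = 0.25,
                               recruit_jitter_s = 0.01,
                               episode_min_gap_s = 1,
                               head_mask = NULL,
                               head_rate_multiplier = NULL,
                               ptz_rate_multiplier = 2,
                               refractory_s = 0.002,
                               isi_shape = 2,
                               pink_noise_fraction = 0,
                               seed = NULL) {
  scenario <- match.arg(scenario)
  is_ptz <- grepl("_ptz$", scenario)
  is_mutant <- grepl("^napb_cr", scenario)
  if (is.null(duration_s)) duration_s <- if (is_ptz) 1800 else 600
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_number(fs, "fs", lower = 2 * 3000, strict_lower = TRUE)
  check_number(noise_rms, "noise_rms", lower = 0)
  check_number(per_electrode_rate, "per_electrode_rate", lower = 0)
  check_number(burst_rate, "burst_rate", lower = 0)
  check_number(network_burst_rate, "network_burst_rate", lower = 0)
  check_number(involvement_fraction, "involvement_fraction",
               lower = 0, strict_lower = TRUE, upper = 1)
  check_number(pink_noise_fraction, "pink_noise_fraction",
               lower = 0, upper = 1)
  if (spike_amplitude < 1 && noise_rms > 0)
    warn("`spike_amplitude` below 1 x noise RMS: spikes will be buried in noise.")
  layout <- mea_layout(n_rows, n_cols)
  if (is.null(head_mask)) head_mask <- default_head_mask(layout)
  if (!all(head_mask %in% layout$electrode))
    abort("`head_mask` must be a subset of electrode indices.")
  if (is.null(head_rate_multiplier))
    head_rate_multiplier <- if (is_mutant) 2.5 else 1
  structure(
    list(scenario = scenario, layout = layout, fs = fs,
         duration_s = duration_s, noise_rms = noise_rms,
         spike_amplitude = spike_amplitude,
         per_electrode_rate = per_electrode_rate,
         burst_rate = burst_rate,
         spikes_per_burst = as.integer(spikes_per_burst),
         intra_burst_isi = intra_burst_isi,
         network_burst_rate = network_burst_rate,
         involvement_fraction = involvement_fraction,
         recruit_jitter_s = recruit_jitter_s,
         episode_min_gap_s = episode_min_gap_s,
         head_mask = as.integer(head_mask),
         head_rate_multiplier = head_rate_multiplier,
         ptz_rate_multiplier = if (is_ptz) ptz_rate_multiplier else 1,
         refractory_s = refractory_s, isi_shape = isi_shape,
         pink_noise_fraction = pink_noise_fraction,
         seed = seed),
    class = "recording_scenario"
  )
}

# gamma-renewal spike train with absolute refractory period, truncated to
# [0, duration); rate in spikes/s
renewal_train <- function(rate, duration, refractory, shape) {
  if (rate <= 0) return(numeric(0))
  mu <- 1 / rate
  if (mu <= refractory)
    abort("tonic rate incompatible with the refractory period (1/rate <= refractory).")
  times <- numeric(0)
  t_last <- 0
  repeat {
    n_draw <- max(20L, ceiling((duration - t_last) * rate * 1.5))
    isi <- refractory + rgamma(n_draw, shape = shape,
                               scale = (mu - refractory) / shape)
    new <- t_last + cumsum(isi)
    times <- c(times, new[new < duration])
    t_last <- new[length(new)]
    if (t_last >= duration) break
  }
  times
}

# zero-mean 1/f-weighted noise, unit RMS
pink_noise <- function(n) {
  white <- rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Biphasic extracellular spike template
#'
#' One full sine cycle (negative lobe first) spanning `width_ms`: exactly
#' zero-mean, with the negative trough scaled to `-amplitude_uv`. A ~1 ms
#' template concentrates its energy near 1 kHz, the middle of the
#' 200-3000 Hz detection passband.
#'
#' @param amplitude_uv Peak (trough) amplitude, microvolts.
#' @param width_ms Template width, milliseconds (default 1).
#' @param fs Sampling rate, Hz.
#' @return Numeric waveform vector with attribute `trough` (sample index of
#'   the negative peak).
#' @export
#' @examples
#' w <- spike_template(10, 1, 12500)
#' min(w)  # -10
spike_template <- function(amplitude_uv, width_ms = 1, fs = 12500) {
  check_number(amplitude_uv, "amplitude_uv", lower = 0)
  check_number(width_ms, "width_ms", lower = 0, strict_lower = TRUE)
  n <- max(4L, round(width_ms / 1000 * fs))
  raw <- -sin(2 * pi * seq(0, n - 1) / n)
  w <- if (amplitude_uv == 0) rep(0, n) else raw * (amplitude_uv / -min(raw))
  attr(w, "trough") <- which.min(raw)
  w
}

#' Simulate a multi-channel MEA recording with known ground truth
#'
#' Builds a channel x sample voltage matrix: Gaussian background noise at the
#' scenario's RMS plus biphasic spike templates added at ground-truth times
#' (overlapping spikes superpose linearly). Tonic spikes follow a
#' gamma-renewal process with refractory period; burst episodes place
#' `spikes_per_burst` spikes at `intra_burst_isi` on one electrode; network
#' events recruit `ceiling(involvement_fraction * n_electrodes)` electrodes,
#' each firing a burst with onset jittered within `recruit_jitter_s`.
#' Episode windows on one electrode never overlap (later-starting episodes
#' are thinned), and tonic spikes falling within the refractory period of an
#' episode spike are dropped, so ground-truth spike times are strictly
#' increasing and every episode's spikes survive verbatim.
#'
#' @param scenario A [recording_scenario()].
#' @return A list with elements
#'   \describe{
#'     \item{recording}{`mea_recording`: voltages (channel x sample, uV),
#'       `fs`, `layout`, `duration_s`, `metadata`.}
#'     \item{truth}{list: `spikes` (electrode, time_s, source), `bursts`
#'       (electrode, t_start, t_end, n_spikes), `network_bursts` (event,
#'       t_start, t_end, n_electrodes, electrodes), `rates` (electrode,
#'       n_spikes, rate_hz).}
#'   }
#' @export
simulate_recording <- function(scenario) {
  stopifnot(inherits(scenario, "recording_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    n_el <- nrow(sc$layout)
    dur <- sc$duration_s
    fs <- sc$fs
    mult <- rep(sc$ptz_rate_multiplier, n_el)
    head <- sc$layout$electrode %in% sc$head_mask
    rate_tonic <- sc$per_electrode_rate * mult *
      ifelse(head, sc$head_rate_multiplier, 1)
    rate_burst <- sc$burst_rate / 60 * mult *
      ifelse(head, sc$head_rate_multiplier, 1)
    rate_nb <- sc$network_burst_rate / 60 * sc$ptz_rate_multiplier

    k <- sc$spikes_per_burst
    burst_span <- (k - 1) * sc$intra_burst_isi

    # network events: onset + recruited electrodes + per-electrode jitter
    n_nb <- rpois(1, rate_nb * dur)
    nb_events <- vector("list", n_nb)
    if (n_nb > 0) {
      onsets <- sort(runif(n_nb, 0, max(0, dur - burst_span - sc$recruit_jitter_s)))
      # thin globally so network events never run into each other on the
      # pooled timeline
      keep <- rep(TRUE, n_nb)
      last <- -Inf
      span_nb <- burst_span + sc$recruit_jitter_s
      for (i in seq_len(n_nb)) {
        if (onsets[i] > last + sc$episode_min_gap_s) last <- onsets[i] + span_nb
        else keep[i] <- FALSE
      }
      onsets <- onsets[keep]
      n_nb <- length(onsets)
      nb_events <- vector("list", n_nb)
      n_recruit <- ceiling(sc$involvement_fraction * n_el)
      for (i in seq_len(n_nb)) {
        els <- sort(sample.int(n_el, n_recruit))
        nb_events[[i]] <- list(
          onset = onsets[i], electrodes = els,
          jitter = runif(n_recruit, 0, sc$recruit_jitter_s))
      }
    }

    # per-electrode episode list (bursts + network contributions), thinned so
    # episode windows never overlap on one electrode
    ep_by_el <- vector("list", n_el)
    for (e in seq_len(n_el)) {
      n_b <- rpois(1, rate_burst[e] * dur)
      eps <- list()
      if (n_b > 0) {
        b_on <- runif(n_b, 0, max(0, dur - burst_span))
        for (j in seq_len(n_b))
          eps[[length(eps) + 1L]] <- list(onset = b_on[j], kind = "burst",
                                          event = NA_integer_)
      }
      for (i in seq_len(n_nb)) {
        pos <- match(e, nb_events[[i]]$electrodes)
        if (!is.na(pos))
          eps[[length(eps) + 1L]] <- list(
            onset = nb_events[[i]]$onset + nb_events[[i]]$jitter[pos],
            kind = "network", event = i)
      }
      if (length(eps) > 0) {
        ord <- order(vapply(eps, `[[`, numeric(1), "onset"))
        eps <- eps[ord]
        kept <- list()
        last_end <- -Inf
        gap <- max(sc$refractory_s, sc$episode_min_gap_s)
        for (ep in eps) {
          if (ep$onset > last_end + gap) {
            kept[[length(kept) + 1L]] <- ep
            last_end <- ep$onset + burst_span
          }
        }
        eps <- kept
      }
      ep_by_el[[e]] <- eps
    }

    # assemble spike times per electrode
    spk <- vector("list", n_el)
    truth_bursts <- list()
    nb_kept <- lapply(seq_len(n_nb), function(i) integer(0))
    for (e in seq_len(n_el)) {
      ep_times <- numeric(0)
      src <- character(0)
      for (ep in ep_by_el[[e]]) {
        tt <- ep$onset + seq(0, k - 1) * sc$intra_burst_isi
        ep_times <- c(ep_times, tt)
        src <- c(src, rep(ep$kind, k))
        if (ep$kind == "burst") {
          truth_bursts[[length(truth_bursts) + 1L]] <- tibble(
            electrode = e, t_start = tt[1], t_end = tt[k], n_spikes = k)
        } else {
          nb_kept[[ep$event]] <- c(nb_kept[[ep$event]], e)
        }
      }
      tonic <- renewal_train(rate_tonic[e], dur, sc$refractory_s, sc$isi_shape)
      if (length(tonic) > 0 && length(ep_by_el[[e]]) > 0) {
        # keep tonic spikes clear of entire episode windows so ground-truth
        # episodes own exactly their own spikes
        w0 <- vapply(ep_by_el[[e]], function(ep) ep$onset, numeric(1)) -
          sc$refractory_s
        w1 <- w0 + burst_span + 2 * sc$refractory_s
        keep <- vapply(tonic, function(t0) all(t0 < w0 | t0 > w1), logical(1))
        tonic <- tonic[keep]
      }
      tt <- c(ep_times, tonic)
      ss <- c(src, rep("tonic", length(tonic)))
      ord <- order(tt)
      spk[[e]] <- tibble(electrode = e, time_s = tt[ord], source = ss[ord])
    }
    spikes <- bind_rows(spk)
    spikes <- spikes[spikes$time_s >= 0 & spikes$time_s < dur, ]

    truth_nb <- NULL
    if (n_nb > 0) {
      rows <- list()
      for (i in seq_len(n_nb)) {
        els <- sort(unique(nb_kept[[i]]))
        if (length(els) == 0) next
        ev_t <- spikes$time_s[spikes$electrode %in% els &
                                spikes$source == "network" &
                                spikes$time_s >= nb_events[[i]]$onset - 1e-9 &
                                spikes$time_s <= nb_events[[i]]$onset +
                                  burst_span + sc$recruit_jitter_s + 1e-9]
        rows[[length(rows) + 1L]] <- tibble(
          event = i, t_start = min(ev_t), t_end = max(ev_t),
          n_electrodes = length(els), electrodes = list(els))
      }
      truth_nb <- bind_rows(rows)
    }
    if (is.null(truth_nb) || nrow(truth_nb) == 0)
      truth_nb <- tibble(event = integer(), t_start = numeric(),
                         t_end = numeric(), n_electrodes = integer(),
                         electrodes = list())
    truth_b <- if (length(truth_bursts) > 0) {
      arrange(bind_rows(truth_bursts), .data$electrode, .data$t_start)
    } else {
      tibble(electrode = integer(), t_start = numeric(),
             t_end = numeric(), n_spikes = integer())
    }

    # voltage matrix: noise + inserted templates
    n_samp <- round(fs * dur)
    volt <- matrix(0, nrow = n_el, ncol = n_samp)
    for (e in seq_len(n_el)) {
      if (sc$noise_rms > 0) {
        x <- rnorm(n_samp, 0, sc$noise_rms)
        if (sc$pink_noise_fraction > 0) {
          x <- sqrt(1 - sc$pink_noise_fraction) * x +
            sqrt(sc$pink_noise_fraction) * sc$noise_rms * pink_noise(n_samp)
        }
        volt[e, ] <- x
      }
    }
    if (nrow(spikes) > 0 && sc$spike_amplitude > 0) {
      # spike_amplitude is a multiple of noise RMS; on a noiseless scenario
      # it is taken as microvolts directly
      amp_uv <- if (sc$noise_rms > 0) sc$spike_amplitude * sc$noise_rms
                else sc$spike_amplitude
      tmpl <- spike_template(amp_uv, width_ms = 1, fs = fs)
      trough <- attr(tmpl, "trough")
      ntw <- length(tmpl)
      for (r in seq_len(nrow(spikes))) {
        e <- spikes$electrode[r]
        c0 <- round(spikes$time_s[r] * fs) + 1L - (trough - 1L)
        idx <- c0:(c0 + ntw - 1L)
        ok <- idx >= 1L & idx <= n_samp
        if (any(ok)) volt[e, idx[ok]] <- volt[e, idx[ok]] + tmpl[ok]
      }
    }

    rates <- spikes |>
      group_by(.data$electrode) |>
      summarise(n_spikes = n(), .groups = "drop")
    rates <- left_join(tibble(electrode = seq_len(n_el)), rates,
                       by = "electrode")
    rates$n_spikes[is.na(rates$n_spikes)] <- 0L
    rates$rate_hz <- rates$n_spikes / dur

    rec <- new_mea_recording(volt, fs, sc$layout, dur,
                             metadata = list(scenario = sc$scenario,
                                             seed = sc$seed))
    list(recording = rec,
         truth = list(spikes = spikes[, c("electrode", "time_s", "source")],
                      bursts = truth_b, network_bursts = truth_nb,
                      rates = rates))
  })
}

new_mea_recording <- function(voltages, fs, layout, duration_s,
                              metadata = list()) {
  structure(
    list(voltages = voltages, fs = fs, layout = layout,
         duration_s = duration_s, metadata = metadata),
    class = "mea_recording"
  )
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> %d channels x %d samples (%.1f s at %g Hz)\n",
              nrow(x$voltages), ncol(x$voltages), x$duration_s, x$fs))
  if (length(x$metadata) > 0)
    cat("  metadata:", paste(names(x$metadata), unlist(lapply(x$metadata, format)),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}
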