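`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force enumerators used as independent oracles for the burst and
# network-burst detectors: enumerate every candidate (start, end) run, check
# the qualifying conditions directly, and keep maximal runs only.

brute_bursts <- function(times, min_spikes, max_isi) {
  n <- length(times)
  out <- list()
  if (n >= min_spikes) {
    isi <- diff(times)
    for (i in seq_len(n)) {
      for (j in i:n) {
        len <- j - i + 1
        if (len < min_spikes) next
        if (i < j && any(isi[i:(j - 1)] >= max_isi)) next
        left_max <- i == 1 || isi[i - 1] >= max_isi
        right_max <- j == n || isi[j] >= max_isi
        if (left_max && right_max)
          out[[length(out) + 1]] <- c(i_start = i, i_end = j)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      n_spikes = integer(0)))
  m <- do.call(rbind, out)
  data.frame(t_start = times[m[, 1]], t_end = times[m[, 2]],
             n_spikes = as.integer(m[, 2] - m[, 1] + 1))
}

brute_network_bursts <- function(spikes, n_electrodes, min_spikes, max_isi,
                                 min_involvement) {
  ord <- order(spikes$time_s, spikes$electrode)
  tt <- spikes$time_s[ord]
  el <- spikes$electrode[ord]
  n <- length(tt)
  out <- list()
  if (n >= min_spikes) {
    isi <- diff(tt)
    qual <- function(i, j) i == j || all(isi[i:(j - 1)] < max_isi | isi[i:(j - 1)] == 0)
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (j - i + 1 < min_spikes) next
        if (!qual(i, j)) next
        left_max <- i == 1 || !(isi[i - 1] < max_isi || isi[i - 1] == 0)
        right_max <- j == n || !(isi[j] < max_isi || isi[j] == 0)
        if (!left_max || !right_max) next
        els <- unique(el[i:j])
        if (length(els) / n_electrodes >= min_involvement &&
            length(els) >= 2)
          out[[length(out) + 1]] <- data.frame(
            t_start = tt[i], t_end = tt[j],
            n_spikes = as.integer(j - i + 1),
            n_electrodes = length(els))
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      n_spikes = integer(0), n_electrodes = integer(0)))
  do.call(rbind, out)
}

# random small spike-train instance for oracle-equivalence checks
random_instance <- function(n_electrodes_max = 5, n_spikes_max = 50,
                            t_max = 2) {
  n_el <- sample.int(n_electrodes_max, 1)
  rows <- lapply(seq_len(n_el), function(e) {
    k <- sample.int(n_spikes_max, 1)
    data.frame(electrode = e, time_s = sort(runif(k, 0, t_max)))
  })
  df <- do.call(rbind, rows)
  list(spikes = df, n_electrodes = n_el)
}

# quiescent single-channel recording with templates injected at given times
make_injected_recording <- function(peaks_uv, at_s, duration_s = 2,
                                    fs = 12500, rms_uv = 1) {
  x <- rep(0, round(duration_s * fs))
  for (i in seq_along(at_s)) {
    w <- spike_template(peaks_uv[i], 1, fs)
    tr <- attr(w, "trough")
    c0 <- round(at_s[i] * fs) + 1L - (tr - 1L)
    x[c0:(c0 + length(w) - 1L)] <- x[c0:(c0 + length(w) - 1L)] + w
  }
  meafish:::new_mea_recording(matrix(x, nrow = 1), fs = fs,
                              layout = mea_layout(1, 1),
                              duration_s = duration_s)
}

# constant-rate regular train helper
regular_train <- function(n, isi, t0 = 0, electrode = 1) {
  data.frame(electrode = electrode, time_s = t0 + (seq_len(n) - 1) * isi)
}
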