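make_trains <- function(df, duration_s = 300, layout = mea_layout()) {
  spike_trains(df, duration_s = duration_s, layout = layout)
}

test_that("the analysis window maximizes spike count with earliest-start ties", {
  # uniform spikes over 10 min: every window ties, earliest start wins
  tr <- make_trains(data.frame(electrode = 1, time_s = seq(0.5, 599.5, 1)),
                    duration_s = 600)
  w <- select_analysis_window(tr)
  expect_equal(c(w$t0, w$t1), c(0, 300))

  # all activity between minutes 3 and 8: brute-force scan agrees
  withr::with_seed(12, {
    tt <- sort(runif(500, 180, 480))
  })
  tr2 <- make_trains(data.frame(electrode = 1, time_s = tt), duration_s = 600)
  w2 <- select_analysis_window(tr2)
  brute <- vapply(0:300, function(s) sum(tt >= s & tt < s + 300), numeric(1))
  expect_equal(w2$t0, (0:300)[which.max(brute)])
  expect_equal(w2$t0, 180)
  expect_equal(w2$n_spikes, 500L)

  # recording shorter than the window is an error
  tr3 <- make_trains(data.frame(electrode = 1, time_s = 1), duration_s = 240)
  expect_error(select_analysis_window(tr3), "shorter")
})

test_that("the active-electrode rule is inclusive at 5 spikes/min", {
  expect_true(classify_active(seq(0, 59, length.out = 5), 60))
  expect_false(classify_active(seq(0, 59, length.out = 4), 60))
  expect_false(classify_active(numeric(0), 60))
  # rate scales with duration: 25 spikes over 300 s is exactly 5/min
  expect_true(classify_active(seq(1, 299, length.out = 25), 300))
  expect_false(classify_active(seq(1, 299, length.out = 24), 300))
})

test_that("weighted mean firing rate averages active electrodes only", {
  df <- rbind(
    data.frame(electrode = 1, time_s = seq(0.5, 299.5, length.out = 300)),  # 1 Hz
    data.frame(electrode = 2, time_s = seq(0.3, 299.3, length.out = 900)))  # 3 Hz
  tr <- make_trains(df)
  expect_equal(weighted_mean_firing_rate(tr), 2)

  # a single active electrode at 30 spikes / 300 s
  tr2 <- make_trains(data.frame(electrode = 5,
                                time_s = seq(1, 290, length.out = 30)))
  expect_equal(weighted_mean_firing_rate(tr2), 0.1)

  # silent electrodes never dilute the mean (they are excluded by definition:
  # the 62 empty electrodes of the layout are already ignored above)
  r <- electrode_rates(tr)
  expect_equal(sum(r$active), 2)
  expect_equal(nrow(r), 64)

  # no active electrodes: defined-missing, never 0
  tr3 <- make_trains(data.frame(electrode = 1, time_s = c(10, 150)))
  expect_warning(w <- weighted_mean_firing_rate(tr3), "undefined")
  expect_true(is.na(w))
})

test_that("burst detection follows the >=5 spikes / <100 ms rule exactly", {
  b5 <- detect_bursts(make_trains(regular_train(5, 0.05), duration_s = 60),
                      active_only = FALSE)
  expect_equal(nrow(b5), 1)
  expect_equal(b5$n_spikes, 5L)
  expect_equal(c(b5$t_start, b5$t_end), c(0, 0.2))

  expect_equal(nrow(detect_bursts(make_trains(regular_train(4, 0.05),
                                              duration_s = 60),
                                  active_only = FALSE)), 0)
  expect_equal(nrow(detect_bursts(make_trains(regular_train(10, 0.12),
                                              duration_s = 60),
                                  active_only = FALSE)), 0)

  two <- detect_bursts(make_trains(
    data.frame(electrode = 1,
               time_s = c(0, .05, .10, .15, .20, .60, .65, .70, .75, .80)),
    duration_s = 60))
  expect_equal(nrow(two), 2)
  expect_equal(two$n_spikes, c(5L, 5L))

  expect_error(detect_bursts(c(0.5, 0.2), duration_s = 10),
               "strictly increasing")
})

test_that("bursts on inactive electrodes are discarded unless asked for", {
  # 5 spikes in 300 s = 1/min: a textbook burst on an inactive electrode
  tr <- make_trains(regular_train(5, 0.05))
  expect_equal(nrow(detect_bursts(tr, active_only = TRUE)), 0)
  expect_equal(nrow(detect_bursts(tr, active_only = FALSE)), 1)
})

test_that("network-burst involvement flips between 6 and 7 of 64 electrodes", {
  mk <- function(n_el) {
    df <- do.call(rbind, lapply(seq_len(n_el), function(e)
      data.frame(electrode = e,
                 time_s = 0.001 * e + 0.007 * (0:4))))
    make_trains(df, duration_s = 60)
  }
  nb7 <- detect_network_bursts(mk(7))
  expect_equal(nrow(nb7), 1)
  expect_equal(nb7$n_electrodes, 7L)
  expect_equal(nb7$involvement, 7 / 64)
  expect_gte(nb7$involvement, 0.10)

  expect_equal(nrow(detect_network_bursts(mk(6))), 0)   # 0.094 < 0.10
})

test_that("a single electrode bursting alone is never a network burst", {
  # small array where the fraction rule alone would pass with one electrode
  tr <- spike_trains(regular_train(10, 0.01), duration_s = 60,
                     layout = mea_layout(1, 2))
  expect_equal(nrow(detect_network_bursts(tr)), 0)
})

test_that("burst frequencies are counts over the window", {
  tr <- make_trains(
    data.frame(electrode = 1,
               time_s = c(0, .05, .10, .15, .20, .60, .65, .70, .75, .80)),
    duration_s = 300)
  b <- detect_bursts(tr, active_only = FALSE)
  expect_equal(burst_frequency(b, 300), 2 / 300)
  expect_equal(burst_frequency(b[0, ], 300), 0)
  expect_error(burst_frequency(b, 0), "window_s")
  fake30 <- data.frame(t_start = 1:30)
  expect_equal(burst_frequency(fake30, 300), 0.1)
})

test_that("the amplitude heatmap places mean |amplitude| on the grid", {
  tr <- make_trains(data.frame(electrode = 10, time_s = c(1, 2),
                               amplitude_uv = c(-10, -20)))
  hm <- amplitude_heatmap(tr)
  expect_equal(nrow(hm), 64)
  expect_equal(hm$mean_abs_amplitude_uv[hm$electrode == 10], 15)
  expect_equal(sum(!is.na(hm$mean_abs_amplitude_uv)), 1)
  # electrode 10 sits at row 2, col 2 of the column-major grid
  expect_equal(unlist(hm[hm$electrode == 10, c("row", "col")]),
               c(row = 2, col = 2))

  empty <- make_trains(data.frame(electrode = integer(),
                                  time_s = numeric()))
  expect_true(all(is.na(amplitude_heatmap(empty)$mean_abs_amplitude_uv)))
})

test_that("raster events round-trip losslessly", {
  expect_equal(nrow(raster_events(make_trains(
    data.frame(electrode = integer(), time_s = numeric())))), 0)
  one <- raster_events(make_trains(data.frame(electrode = 3, time_s = 1.5)))
  expect_equal(one, tibble::tibble(electrode = 3, time_s = 1.5))

  withr::with_seed(4, {
    df <- data.frame(electrode = sample(1:8, 200, TRUE),
                     time_s = runif(200, 0, 100))
  })
  df <- df[!duplicated(df), ]
  tr <- make_trains(df, duration_s = 100)
  back <- spike_trains(raster_events(tr), duration_s = 100)
  expect_equal(as.data.frame(back[, c("electrode", "time_s")]),
               as.data.frame(tr[, c("electrode", "time_s")]))
})

test_that("brain-region hyperactivity compares head and trunk rates", {
  layout <- mea_layout()
  head <- default_head_mask(layout)
  mk_rate <- function(els, rate, dur = 300) {
    do.call(rbind, lapply(els, function(e)
      data.frame(electrode = e,
                 time_s = seq(0.001 * e, dur - 0.5,
                              length.out = rate * dur))))
  }
  # identical rates everywhere: ratio 1, not hyperactive
  tr <- make_trains(mk_rate(1:64, 1))
  h <- classify_brain_hyperactivity(tr, head)
  expect_equal(h$ratio, 1)
  expect_false(h$hyperactive)

  # head at 4 Hz, trunk at 1 Hz: hyperactive with ratio 4
  tr2 <- make_trains(rbind(mk_rate(head, 4), mk_rate(setdiff(1:64, head), 1)))
  h2 <- classify_brain_hyperactivity(tr2, head)
  expect_equal(h2$ratio, 4, tolerance = 1e-9)
  expect_true(h2$hyperactive)

  # silent fish: indeterminate, distinct from FALSE
  tr3 <- make_trains(data.frame(electrode = integer(), time_s = numeric()))
  expect_true(is.na(classify_brain_hyperactivity(tr3, head)$hyperactive))

  expect_error(classify_brain_hyperactivity(tr, integer(0)), "head_mask")
  expect_error(classify_brain_hyperactivity(tr, 1:64), "head_mask")
})

test_that("burst and network-burst detectors match brute-force enumeration", {
  withr::with_seed(31, {
    for (rep in 1:200) {
      inst <- random_instance()
      spec <- metric_spec(
        burst_min_spikes = sample(2:6, 1),
        burst_max_isi_s = runif(1, 0.02, 0.2),
        nb_min_spikes = sample(2:6, 1),
        nb_max_isi_s = runif(1, 0.02, 0.2),
        nb_min_involvement = sample(c(0.1, 0.4, 0.6), 1))
      tr <- spike_trains(inst$spikes, duration_s = 2,
                         layout = mea_layout(1, inst$n_electrodes))

      got <- detect_bursts(tr, spec, active_only = FALSE)
      want <- do.call(rbind, lapply(split(inst$spikes, inst$spikes$electrode),
        function(d) {
          b <- brute_bursts(d$time_s, spec$burst_min_spikes,
                            spec$burst_max_isi_s)
          if (nrow(b) > 0) cbind(electrode = d$electrode[1], b) else NULL
        }))
      if (is.null(want))
        want <- data.frame(electrode = integer(), t_start = numeric(),
                           t_end = numeric(), n_spikes = integer())
      rownames(want) <- NULL
      expect_equal(as.data.frame(got), want, ignore_attr = TRUE)

      # structural invariants: bursts disjoint, ordered, maximal run length
      if (nrow(got) > 1) {
        by_el <- split(got, got$electrode)
        for (g in by_el)
          if (nrow(g) > 1) expect_true(all(diff(g$t_start) > 0) &&
                                         all(g$t_end[-nrow(g)] < g$t_start[-1]))
      }

      got_nb <- detect_network_bursts(tr, spec)
      want_nb <- brute_network_bursts(inst$spikes, inst$n_electrodes,
                                      spec$nb_min_spikes, spec$nb_max_isi_s,
                                      spec$nb_min_involvement)
      expect_equal(as.data.frame(got_nb[, c("t_start", "t_end", "n_spikes",
                                            "n_electrodes")]),
                   want_nb, ignore_attr = TRUE)
    }
  })
})

test_that("doubling Poisson firing rates doubles the WMFR within sampling error", {
  withr::with_seed(77, {
    mk <- function(rate) {
      df <- do.call(rbind, lapply(1:16, function(e) {
        n <- rpois(1, rate * 300)
        data.frame(electrode = e, time_s = sort(runif(n, 0, 300)))
      }))
      spike_trains(df, duration_s = 300, layout = mea_layout(4, 4))
    }
    w1 <- weighted_mean_firing_rate(mk(1))
    w2 <- weighted_mean_firing_rate(mk(2))
  })
  # relative SE of each WMFR ~ 1/sqrt(16 * 300) < 2%
  expect_equal(w2 / w1, 2, tolerance = 0.05)
})

test_that("the full neural-metric report recovers constructed quantities", {
  df <- rbind(
    regular_train(5, 0.05, t0 = 10, electrode = 1),
    regular_train(5, 0.05, t0 = 50, electrode = 1),
    data.frame(electrode = 1, time_s = seq(100, 290, 5)),
    data.frame(electrode = 2, time_s = seq(0.3, 299.3, 1)))
  tr <- make_trains(df, duration_s = 300)
  rep <- neural_metrics(tr, window = c(0, 300))
  expect_equal(rep$n_active, 2)
  expect_equal(rep$n_bursts, 2)
  expect_equal(rep$burst_freq_hz, 2 / 300)
  expect_equal(rep$wmfr_hz, mean(c(49, 300)) / 300)
})
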