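make_rec <- function(x, fs = 2048, ...) {
  electrogram_recording(matrix(x, nrow = 1), fs, ...)
}

test_that("bandpass removes DC and passes the mid-band at unit gain", {
  fs <- 2048
  t <- seq(0, 2, by = 1 / fs)[-1]
  # constant offset: output mean ~ 0
  rec <- make_rec(rep(3, length(t)), fs)
  out <- bandpass(rec)
  expect_equal(mean(out$signal), 0, tolerance = 1e-6)
  # 100 Hz unit sinusoid: amplitude within 1 % of unity once the slow
  # 1 Hz high-pass pole has settled (its time constant is ~0.4 s)
  t6 <- seq(0, 6, by = 1 / fs)[-1]
  rec <- make_rec(sin(2 * pi * 100 * t6), fs)
  out <- bandpass(rec)
  mid <- out$signal[1, (2.5 * fs):(3.5 * fs)]
  expect_equal(max(abs(mid)), 1, tolerance = 0.01)
})

test_that("the single-pass band edges sit at half power", {
  expect_equal(bandpass_response(400), 1 / sqrt(2), tolerance = 1e-6)
  expect_equal(bandpass_response(1), 1 / sqrt(2), tolerance = 1e-4)
  # forward-backward application squares the response: -6 dB at edges
  expect_equal(bandpass_response(400, passes = 2), 0.5, tolerance = 1e-6)
  expect_gt(bandpass_response(100), 0.999)
  expect_lt(bandpass_response(800), 0.05)
})

test_that("bandpass is idempotent on pass-band content", {
  fs <- 2048
  set.seed(21)
  t <- seq(0, 2, by = 1 / fs)[-1]
  x <- sin(2 * pi * 40 * t) + 0.5 * sin(2 * pi * 120 * t + 1)
  once <- bandpass(make_rec(x, fs))
  twice <- bandpass(once)
  r1 <- expect_rms(once$signal[1, 500:3500])
  r2 <- expect_rms(twice$signal[1, 500:3500])
  expect_lt(abs(r2 - r1) / r1, 0.01)
})

test_that("band preconditions abort before filtering", {
  rec <- make_rec(rnorm(4096))
  expect_error(bandpass(rec, 400, 1), "low < high")
  expect_error(bandpass(rec, 1, 2000), "Nyquist")
})

test_that("ventricular beats are detected within 5 ms with refractory", {
  fs <- 2048
  t_ms <- seq(0, 2000, by = 1000 / fs)
  ref <- farfield_template(t_ms, 500) + farfield_template(t_ms, 1000) +
    farfield_template(t_ms, 1500)
  got <- detect_ventricular_beats(ref, fs)
  expect_length(got, 3)
  expect_true(all(abs(got - c(500, 1000, 1500)) <= 5))
  # flat reference: nothing detected
  expect_length(detect_ventricular_beats(rep(0, 3 * fs), fs), 0)
  # refractory: two complexes 100 ms apart collapse to one detection
  ref2 <- farfield_template(t_ms, 600) + farfield_template(t_ms, 700)
  expect_length(detect_ventricular_beats(ref2, fs, refractory_ms = 250), 1)
  # no reference trace: directed error
  rec <- make_rec(rnorm(3 * fs))
  expect_error(detect_ventricular_beats(rec), "reference")
})

test_that("far-field subtraction removes the template, spares atrial signal", {
  fx <- farfield_only_recording(n_channels = 9)
  rec <- fx$rec
  fs <- rec$sample_rate
  win_idx <- unique(unlist(lapply(fx$beat_times, function(b) {
    i <- epimap:::ms_to_sample(b, fs) +
      seq(round(-0.05 * fs), round(0.3 * fs))
    i[i >= 1 & i <= ncol(rec$signal)]
  })))
  sub <- subtract_farfield(rec, fx$beat_times)
  expect_lte(expect_rms(sub$signal[, win_idx]),
             0.1 * expect_rms(rec$signal[, win_idx]))

  # atrial deflections strictly outside the beat windows are untouched
  t_ms <- epimap:::rec_time_ms(rec)
  atr <- vapply(seq_len(nrow(rec$signal)), function(ci)
    deflection_waveform(t_ms, 150 + 5 * ci, 2, 1), numeric(length(t_ms)))
  rec2 <- electrogram_recording(rec$signal + t(atr), fs,
                                reference = rec$reference)
  sub2 <- subtract_farfield(rec2, fx$beat_times)
  out_idx <- setdiff(seq_along(t_ms), win_idx)
  peaks_in <- apply(abs(t(atr)[, out_idx]), 1, max)
  resid <- abs(sub2$signal[, out_idx] - rec2$signal[, out_idx])
  expect_lt(max(resid) / min(peaks_in), 0.01)

  expect_error(subtract_farfield(rec, numeric(0)), "2 beats")
  expect_error(subtract_farfield(rec, 500), "2 beats")
  expect_warning(subtract_farfield(rec, c(500, 600, 1300)), "overlap")
})

test_that("channel QC classifies flatline, noisy, saturated and good", {
  set.seed(31)
  fs <- 2048
  n <- 2 * fs
  t_ms <- seq_len(n) / fs * 1000
  clean <- deflection_waveform(t_ms, 500, 2, 1) +
    deflection_waveform(t_ms, 1500, 2, 1) + rnorm(n, sd = 0.01)
  sig <- rbind(clean,
               clean + rnorm(n, sd = 0.01),
               rep(0, n),                                  # flatline
               clean + rnorm(n, sd = 0.2),                 # 20x noise
               pmin(pmax(clean * 10, -0.05), 0.05),        # clipped
               clean + rnorm(n, sd = 0.012))
  rec <- electrogram_recording(sig, fs)
  q <- assess_channels(rec)
  expect_equal(as.character(q$flag),
               c("good", "good", "flatline", "noisy", "saturated",
                 "good"))
  expect_true(all(is.finite(q$rms_mv)))
  # permutation equivariance
  perm <- c(4, 2, 6, 1, 5, 3)
  q2 <- assess_channels(electrogram_recording(sig[perm, ], fs,
                                              channel_ids = perm))
  expect_equal(as.character(q2$flag)[order(perm)], as.character(q$flag))
})

test_that("map interpolation fills from neighbours, convexly", {
  lay <- grid_layout(4, 4, 1)
  vals <- rep(10, 16)
  names(vals) <- lay$channel_id
  # all 8 neighbours equal 10 -> exactly 10
  filled <- interpolate_map(vals, lay, bad = 6L)
  expect_equal(unname(filled["6"]), 10)
  # constant maps are filled exactly
  filled2 <- interpolate_map(vals, lay, bad = c(1L, 7L, 16L))
  expect_equal(as.vector(filled2), rep(10, 16))
  # equidistant 0/10 neighbours average to 5
  lay3 <- electrode_layout(1:4, c(0, 1, 2, 0), c(0, 0, 0, 5))
  v3 <- c(0, NA, 10, 7)
  names(v3) <- 1:4
  f3 <- interpolate_map(v3, lay3, bad = 2L,
                        graph = build_adjacency(lay3, "radius",
                                                radius_mm = 1.5))
  expect_equal(unname(f3["2"]), 5)
  # filled values never leave the neighbour range
  set.seed(13)
  vals4 <- runif(16, -3, 9)
  names(vals4) <- lay$channel_id
  bad <- sample(16, 4)
  f4 <- interpolate_map(vals4, lay, bad = bad)
  expect_true(all(f4 >= min(vals4[-bad]) & f4 <= max(vals4[-bad])))
  expect_equal(f4[-bad], vals4[-bad])            # good channels untouched
  # a bad channel whose whole neighbourhood is bad and whose nearest
  # good channel is out of reach stays missing and is flagged
  f5 <- interpolate_map(vals4, lay, bad = c(1L, 2L, 5L, 6L),
                        max_reach_mm = 0.5)
  expect_true(is.na(f5["1"]))
  expect_true(1L %in% attr(f5, "missing"))
  expect_error(interpolate_map(vals4[1:3], grid_layout(2, 2, 1),
                               bad = c(1L, 2L)),
               "3 good channels")
})
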