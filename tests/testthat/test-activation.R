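# shared clean fixture: 6x6 plane wave, 2 beats, no noise
sinus_fixture <- function(rows = 6, cols = 6, rate = 114,
                          duration_s = 2, noise = 0, seed = 1,
                          cv = 1.04) {
  lay <- grid_layout(rows, cols, 3.5)
  sc <- scenario_sinus(lay, cv_mps = cv, rate_bpm = rate)
  sim <- render_recording(lay, sc, duration_s = duration_s,
                          noise_rms = noise, seed = seed)
  list(lay = lay, sc = sc, sim = sim,
       rec = bandpass(sim$recording))
}

test_that("beat segmentation recovers the rendered schedule", {
  fx <- sinus_fixture(rate = 120, duration_s = 2)
  beats <- segment_beats(fx$rec)
  expect_equal(nrow(beats), 4)                  # 2 s at 120 beats/min
  expect_true(all(beats$end_ms > beats$start_ms))
  expect_true(all(diff(as.vector(t(beats[, c("start_ms", "end_ms")])))
                  >= 0))                        # sorted, disjoint
  # every ground-truth activation falls inside one window
  truth <- fx$sim$truth$activation_ms
  for (b in seq_len(nrow(truth)))
    expect_true(any(truth[b, 1] >= beats$start_ms &
                    truth[b, ncol(truth)] <= beats$end_ms))
  # flat recording: empty with a warning
  flat <- electrogram_recording(matrix(0, 4, 4096), 2048)
  expect_warning(b0 <- segment_beats(flat), "no beats")
  expect_equal(nrow(b0), 0)
})

test_that("activation detection matches ground truth and honours flags", {
  fx <- sinus_fixture()
  beats <- segment_beats(fx$rec)
  am <- detect_activation(fx$rec, unlist(beats[1, ]))
  truth <- fx$sim$truth$activation_ms[1, ]
  fs <- fx$rec$sample_rate
  expect_true(all(abs(am$time_ms - truth) <= 1000 / fs + 1e-9))
  expect_true(all(am$slope_mv_ms > 0))
  # steepest_absolute coincides on the simulator wavelet
  am2 <- detect_activation(fx$rec, unlist(beats[1, ]),
                           polarity = "steepest_absolute")
  expect_equal(am2$time_ms, am$time_ms)
  # channels flagged bad upstream carry no time
  q <- assess_channels(fx$rec)
  q$flag[3] <- "noisy"
  am3 <- detect_activation(fx$rec, unlist(beats[1, ]), quality = q)
  expect_true(is.na(am3$time_ms[3]))
  expect_false(am3$valid[3])
  expect_error(detect_activation(fx$rec, c(100, 100.5)), "3 samples")
})

test_that("ties at equal extremal slope resolve to the earliest sample", {
  fs <- 2048
  dt <- 1000 / fs
  t_ms <- seq(0, 1600 * dt, by = dt)
  # sample-aligned twin deflections: byte-identical extremal slopes
  x <- deflection_waveform(t_ms, 400 * dt, 2, 1) +
    deflection_waveform(t_ms, 1200 * dt, 2, 1)
  rec <- electrogram_recording(matrix(x, 1), fs)
  am <- detect_activation(rec, c(0, 1600 * dt))
  expect_equal(am$time_ms, 400 * dt, tolerance = 1e-9)
})

test_that("isochrone maps split total activation time into equal bands", {
  # 15 channels at 0..14 ms: one channel per band
  lay <- grid_layout(3, 5, 1)
  am <- structure(
    data.frame(channel_id = 1:15, time_ms = 0:14,
               slope_mv_ms = 1, valid = TRUE),
    class = c("activation_map", "data.frame"), beat = 1L)
  iso <- build_isochrones(am, 15)
  expect_equal(length(iso$edges_ms), 16)
  expect_equal(unique(round(diff(iso$edges_ms), 12)), 14 / 15)
  expect_equal(unname(iso$band), 0:14)
  expect_false(iso$degenerate)
  # the latest channel joins the last band, never band n_bands
  expect_equal(unname(iso$band["15"]), 14L)
  # band index is monotone in activation time
  expect_true(all(diff(iso$band[order(am$time_ms)]) >= 0))
  # degenerate all-equal map
  am$time_ms <- rep(7, 15)
  iso2 <- build_isochrones(am, 15)
  expect_true(iso2$degenerate)
  expect_equal(unique(unname(iso2$band)), 0L)
  expect_equal(iso2$edges_ms, rep(7, 16))
})

test_that("activation frames partition valid channels in time order", {
  am <- structure(
    data.frame(channel_id = 1:20, time_ms = seq(0, 19.8, length.out = 20),
               slope_mv_ms = 1, valid = c(rep(TRUE, 18), FALSE, TRUE)),
    class = c("activation_map", "data.frame"), beat = 1L)
  fr <- activation_frames(am, 5)
  expect_equal(length(fr), 4)                  # ceil(19.8/5)
  got <- unlist(fr)
  expect_setequal(got, am$channel_id[am$valid])
  expect_equal(anyDuplicated(got), 0L)
  expect_error(activation_frames(am, 0), "interval")
  # exact-multiple range: max time closes into the final frame
  am$time_ms <- seq(0, 20, length.out = 20)
  am$valid <- TRUE
  fr2 <- activation_frames(am, 5)
  expect_equal(length(fr2), 4)
  expect_true(20L %in% fr2[[4]])
  # plane wave: frames are contiguous column bands
  fx <- sinus_fixture()
  beats <- segment_beats(fx$rec)
  am3 <- detect_activation(fx$rec, unlist(beats[1, ]))
  fr3 <- activation_frames(am3, 5)
  for (f in fr3) {
    cols <- sort(unique(fx$lay$col[match(f, fx$lay$channel_id)]))
    expect_equal(cols, seq(min(cols), max(cols)))
  }
})

test_that("plane-fit conduction velocity is exact on analytic plane waves", {
  lay <- grid_layout(6, 6, 2)
  mk_map <- function(times) structure(
    data.frame(channel_id = lay$channel_id, time_ms = times,
               slope_mv_ms = 1, valid = TRUE),
    class = c("activation_map", "data.frame"), beat = 1L)
  # T = x / 1.0 -> 1 m/s everywhere, direction +x
  cv1 <- estimate_cv(mk_map(lay$x_mm / 1.0), lay)
  expect_equal(cv1$cv_mps[cv1$valid],
               rep(1, sum(cv1$valid)), tolerance = 1e-9)
  expect_equal(attr(cv1, "sd_mps"), 0, tolerance = 1e-9)
  cv05 <- estimate_cv(mk_map(lay$x_mm / 0.5), lay)
  expect_equal(attr(cv05, "mean_mps"), 0.5, tolerance = 1e-9)
  expect_equal(cv05$dir_x[cv05$valid], rep(1, sum(cv05$valid)),
               tolerance = 1e-9)
  expect_equal(cv05$dir_y[cv05$valid], rep(0, sum(cv05$valid)),
               tolerance = 1e-9)
  # estimator consistency: error shrinks to zero with the noise level
  set.seed(17)
  errs <- vapply(c(0, 0.01, 0.05), function(nz) {
    mean(vapply(1:20, function(rep) {
      t <- lay$x_mm / 1.0 + rnorm(36, sd = nz * max(lay$x_mm))
      abs(attr(estimate_cv(mk_map(t), lay), "mean_mps") - 1)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(errs[1], 0, tolerance = 1e-9)
  expect_true(all(diff(errs) > 0))
  expect_lt(errs[2], 0.05)
})

test_that("simulated uniform-CV fixtures recover the scenario CV", {
  fx <- sinus_fixture(rows = 8, cols = 8, cv = 1.04)
  beats <- segment_beats(fx$rec)
  am <- detect_activation(fx$rec, unlist(beats[1, ]))
  cvm <- estimate_cv(am, fx$lay)
  expect_equal(attr(cvm, "mean_mps"), 1.04, tolerance = 0.02)
})

test_that("origin localization finds focal sources and paced pairs", {
  lay <- grid_layout(9, 9, 3.5)
  g <- build_adjacency(lay)
  centre <- lay$channel_id[lay$row == 5 & lay$col == 5]
  sim <- render_recording(lay, scenario_focal(lay, centre),
                          duration_s = 2, seed = 6)
  rec <- bandpass(sim$recording)
  am <- detect_activation(rec, unlist(segment_beats(rec)[1, ]))
  orig <- localize_origin(am, lay, g)
  expect_equal(orig$channel_id, centre)
  # paced: one of the two stimulated electrodes wins
  sc <- scenario_paced(lay)
  simp <- render_recording(lay, sc, duration_s = 2, seed = 7)
  recp <- bandpass(simp$recording)
  amp <- detect_activation(recp, unlist(segment_beats(recp)[1, ]))
  origp <- localize_origin(amp, lay, g)
  expect_true(origp$channel_id %in% simp$truth$source_channels)
})

test_that("a lesion block delays the far side exactly as the geodesic says", {
  lay <- grid_layout(8, 8, 3.5)
  g <- build_adjacency(lay)
  base_sc <- scenario_sinus(lay)
  block <- lay$channel_id[lay$row %in% 4:6 & lay$col %in% 4:6]
  les_sc <- scenario_lesion(base_sc, block)
  base <- render_recording(lay, base_sc, duration_s = 1.5, seed = 8)
  les <- render_recording(lay, les_sc, duration_s = 1.5, seed = 8)
  rb <- bandpass(base$recording)
  rl <- bandpass(les$recording)
  amb <- detect_activation(rb, unlist(segment_beats(rb)[1, ]))
  aml <- detect_activation(rl, unlist(segment_beats(rl)[1, ]))
  fs <- rb$sample_rate
  # far column, shadow rows: strictly delayed vs the lesion-free run
  shadow <- lay$channel_id[lay$col == 8 & lay$row == 5]
  expect_gt(aml$time_ms[shadow], amb$time_ms[shadow])
  # and equal to the geodesic prediction within one sample
  conducting <- !(lay$channel_id %in% block)
  expect_true(all(abs(aml$time_ms[conducting] -
                      les$truth$activation_ms[1, conducting])
                  <= 1000 / fs + 1e-9))
  # lesion channels carry no deflection: flagged invalid by QC
  q <- assess_channels(rl)
  expect_true(all(as.character(q$flag[match(block, q$channel_id)])
                  == "flatline"))
})

test_that("ischemic slowing delays the zone, spares the early edge", {
  lay <- grid_layout(8, 8, 3.5)
  base_sc <- scenario_sinus(lay)
  zone <- lay$channel_id[lay$col >= 5]
  slow_sc <- scenario_ischemia(base_sc, zone, factor = 0.5)
  g <- build_adjacency(lay)
  t0 <- geodesic_activation_times(lay, g, base_sc)
  t1 <- geodesic_activation_times(lay, g, slow_sc)
  inzone <- as.character(zone)
  early <- as.character(lay$channel_id[lay$col <= 2])
  expect_true(all(t1[inzone] > t0[inzone]))
  expect_equal(t1[early], t0[early])
})
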