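#' Unipolar deflection waveform
#'
#' The elementary deflection the simulator places at each activation:
#' \deqn{V(t) = -A \, u \, e^{-u^2/2}, \qquad u = (t - t_0)/\sigma.}
#' The waveform is odd about `t0` (zero net area) and its derivative
#' attains its global minimum exactly at `t = t0`, so a steepest-negative-
#' slope detector recovers the true activation instant by construction.
#'
#' @param t_ms sample times, ms.
#' @param t0_ms activation time, ms.
#' @param sigma_ms deflection width parameter, ms (> 0).
#' @param amplitude_mv amplitude scale, mV (peak |V| is
#'   `amplitude_mv * exp(-1/2)`).
#' @return numeric vector, mV.
#' @export
deflection_waveform <- function(t_ms, t0_ms, sigma_ms = 2,
                                amplitude_mv = 1) {
  if (!is.numeric(sigma_ms) || sigma_ms <= 0)
    stop("sigma_ms must be > 0", call. = FALSE)
  u <- (t_ms - t0_ms) / sigma_ms
  -amplitude_mv * u * exp(-u^2 / 2)
}

#' Far-field ventricular QRS-T template
#'
#' The shared ventricular contamination waveform: a broad, large
#' deflection (QRS-like) followed by a smooth T-like hump 160 ms later.
#' Atrial channels receive this template scaled per channel; the
#' subtraction stage assumes exactly this common-mode character.
#'
#' @param t_ms sample times, ms.
#' @param t0_ms QRS centre time, ms.
#' @param qrs_amplitude_mv,qrs_sigma_ms QRS deflection scale and width.
#' @param t_amplitude_mv,t_sigma_ms,t_delay_ms T-hump height, width, delay.
#' @return numeric vector, mV.
#' @export
farfield_template <- function(t_ms, t0_ms, qrs_amplitude_mv = 2,
                              qrs_sigma_ms = 8, t_amplitude_mv = 0.5,
                              t_sigma_ms = 35, t_delay_ms = 160) {
  deflection_waveform(t_ms, t0_ms, qrs_sigma_ms, qrs_amplitude_mv) +
    t_amplitude_mv * exp(-((t_ms - t0_ms - t_delay_ms)^2) /
                           (2 * t_sigma_ms^2))
}

# add a deflection to a sampled trace, touching only the +/- 8 sigma window
add_deflection <- function(x, t_ms, t0_ms, sigma_ms, amplitude_mv,
                           sample_rate) {
  dt <- 1000 / sample_rate
  i0 <- max(1L, as.integer(floor((t0_ms - 8 * sigma_ms) / dt)) + 1L)
  i1 <- min(length(x), as.integer(ceiling((t0_ms + 8 * sigma_ms) / dt)) + 1L)
  if (i0 > i1) return(x)
  idx <- i0:i1
  x[idx] <- x[idx] + deflection_waveform(t_ms[idx], t0_ms, sigma_ms,
                                         amplitude_mv)
  x
}

# run expr under a seeded, restored RNG; NULL seed = use current stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

beat_onsets <- function(scenario, duration_ms, margin_ms) {
  period <- 60000 / scenario$rate_bpm
  first <- min(100, duration_ms / 10)
  if (duration_ms - margin_ms < first) return(numeric(0))
  on <- seq(first, duration_ms - margin_ms, by = period)
  if (!is.null(scenario$n_beats))
    on <- utils::head(on, scenario$n_beats)
  on
}

#' Render a synthetic multichannel electrogram recording
#'
#' Simulates what the acquisition hardware would record for a propagation
#' scenario: per-beat unipolar deflections placed at the geodesic arrival
#' times, an optional shared far-field ventricular QRS-T template at a
#' fixed atrioventricular delay with a per-channel random scale, and
#' additive white Gaussian noise.  Defaults mirror the acquisition
#' hardware (2048 Hz, 16 x 16 array) and the in vivo sinus schedule
#' (114 beats/min).  Output is byte-identical for a fixed seed.
#'
#' @param layout an [electrode_layout()].
#' @param scenario a [propagation_scenario()].
#' @param sample_rate sampling rate, Hz.
#' @param duration_s recording length, s; must fit at least one beat.
#' @param noise_rms additive white-noise RMS, mV.
#' @param farfield `"none"` or `"template"`.
#' @param farfield_scale global scale of the ventricular template.
#' @param av_delay_ms delay from atrial beat onset to the ventricular QRS.
#' @param amplitude_mv,sigma_ms deflection scale and width.
#' @param graph optional [build_adjacency()] graph (default grid8).
#' @param seed RNG seed for reproducible fixtures.
#' @return A list with `recording` (an [electrogram_recording()]; carries
#'   a reference lead when `farfield = "template"`) and `truth`, a
#'   `ground_truth` list: `activation_ms` (beats x channels), `offset_ms`
#'   (per-channel arrival offsets), `beat_onsets_ms`, `cv_mps`,
#'   `source_channels`, `lesions`, `unreachable`, `farfield_times_ms`.
#' @export
render_recording <- function(layout, scenario, sample_rate = 2048,
                             duration_s = 2, noise_rms = 0,
                             farfield = c("none", "template"),
                             farfield_scale = 1, av_delay_ms = 130,
                             amplitude_mv = 1, sigma_ms = 2,
                             graph = NULL, seed = NULL) {
  farfield <- match.arg(farfield)
  if (sigma_ms / 1000 * sample_rate < 2)
    stop("sample_rate too low to resolve the deflection width ",
         "(sigma must span >= 2 samples)", call. = FALSE)
  if (is.null(graph)) graph <- build_adjacency(layout)
  act <- geodesic_activation_times(layout, graph, scenario)
  duration_ms <- duration_s * 1000
  margin <- max(act, na.rm = TRUE) + 6 * sigma_ms +
    if (farfield == "template") av_delay_ms + 300 else 0
  onsets <- beat_onsets(scenario, duration_ms, margin)
  if (length(onsets) < 1L)
    stop("duration too short for one beat at ", scenario$rate_bpm,
         " beats/min (needs ~", round((100 + margin) / 1000, 2), " s)",
         call. = FALSE)

  n <- as.integer(round(duration_s * sample_rate))
  t_ms <- (seq_len(n) - 1L) / sample_rate * 1000
  nch <- nrow(layout)

  with_seed(seed, {
    sig <- matrix(0, nch, n)
    for (ci in seq_len(nch)) {
      if (is.na(act[ci])) next
      for (b in onsets)
        sig[ci, ] <- add_deflection(sig[ci, ], t_ms, b + act[ci],
                                    sigma_ms, amplitude_mv, sample_rate)
    }
    ff_times <- NULL
    reference <- NULL
    if (farfield == "template") {
      ff_times <- onsets + av_delay_ms
      ff <- rowSums(vapply(ff_times, function(b)
        farfield_template(t_ms, b), numeric(n)))
      ch_scale <- farfield_scale * stats::runif(nch, 0.5, 1.5)
      sig <- sig + outer(ch_scale, ff)
      reference <- ff
    }
    if (noise_rms > 0)
      sig <- sig + matrix(stats::rnorm(nch * n, sd = noise_rms), nch, n)

    rec <- electrogram_recording(sig, sample_rate, layout$channel_id,
                                 reference = reference)
    truth <- structure(list(
      activation_ms = outer(onsets, act, `+`),
      offset_ms = act,
      beat_onsets_ms = onsets,
      cv_mps = scenario_cv_field(scenario, layout),
      source_channels = vapply(resolve_sources(scenario, layout),
                               `[[`, integer(1), "channel"),
      lesions = scenario$lesions,
      unreachable = attr(act, "unreachable"),
      farfield_times_ms = ff_times,
      df_field = NULL), class = "ground_truth")
    list(recording = rec, truth = truth)
  })
}

#' Render a fibrillatory (AF-like) recording
#'
#' Emulates the low-amplitude, high-frequency fractionated electrograms of
#' atrial fibrillation: each channel carries an independent train of
#' deflections whose inter-deflection interval is the reciprocal of the
#' channel's target dominant frequency, perturbed multiplicatively by the
#' jitter coefficient.  There is no coherent global wavefront; amplitudes
#' are scaled down relative to sinus fixtures.  The ground truth carries
#' the DF field the frequency analysis should recover.
#'
#' @param layout an [electrode_layout()].
#' @param field a [df_field()].
#' @param sample_rate sampling rate, Hz.
#' @param duration_s recording length, s.
#' @param amplitude_scale fibrillatory amplitude relative to the 1 mV
#'   sinus deflection (< 1).
#' @param sigma_ms deflection width, ms.
#' @param noise_rms additive white-noise RMS, mV.
#' @param seed RNG seed.
#' @return As [render_recording()]: list of `recording` and `truth`
#'   (with `df_field` filled, `activation_ms` `NULL`).
#' @export
af_recording <- function(layout, field, sample_rate = 2048,
                         duration_s = 8, amplitude_scale = 0.3,
                         sigma_ms = 3, noise_rms = 0, seed = NULL) {
  stopifnot(inherits(field, "df_field"))
  if (sigma_ms / 1000 * sample_rate < 2)
    stop("sample_rate too low to resolve the deflection width",
         call. = FALSE)
  n <- as.integer(round(duration_s * sample_rate))
  t_ms <- (seq_len(n) - 1L) / sample_rate * 1000
  nch <- nrow(layout)
  min_interval <- 4 * sigma_ms

  with_seed(seed, {
    sig <- matrix(0, nch, n)
    clipped <- 0L
    for (ci in seq_len(nch)) {
      fi <- field[field$channel_id == layout$channel_id[ci], ]
      period <- 1000 / fi$df_hz
      tt <- stats::runif(1, 0, period)
      while (tt < duration_s * 1000) {
        amp <- amplitude_scale * stats::runif(1, 0.6, 1.0)
        sig[ci, ] <- add_deflection(sig[ci, ], t_ms, tt, sigma_ms, amp,
                                    sample_rate)
        step <- period * (1 + fi$jitter * stats::rnorm(1))
        if (step < min_interval) {
          step <- min_interval
          clipped <- clipped + 1L
        }
        tt <- tt + step
      }
    }
    if (clipped > 0L)
      warning(clipped, " jittered interval(s) clipped to ", min_interval,
              " ms", call. = FALSE)
    if (noise_rms > 0)
      sig <- sig + matrix(stats::rnorm(nch * n, sd = noise_rms), nch, n)
    rec <- electrogram_recording(sig, sample_rate, layout$channel_id)
    truth <- structure(list(
      activation_ms = NULL, offset_ms = NULL, beat_onsets_ms = NULL,
      cv_mps = NULL, source_channels = NULL, lesions = integer(0),
      unreachable = NULL, farfield_times_ms = NULL,
      df_field = field), class = "ground_truth")
    list(recording = rec, truth = truth)
  })
}
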