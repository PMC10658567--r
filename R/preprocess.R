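#' Bandpass filter a recording
#'
#' Zero-phase (forward-backward) Butterworth bandpass, the first
#' conditioning stage for unipolar electrograms.  Implemented as an
#' order-4 high-pass at `low` cascaded with an order-4 low-pass at
#' `high`, so each band edge is that section's single-pass half-power
#' point; forward-backward application squares the response (no phase
#' shift, hence no bias in activation times).  DC is removed.  The
#' reference lead, if present, is filtered identically.
#'
#' @param rec an [electrogram_recording()].
#' @param low,high band edges, Hz; default 1--400 Hz.
#' @param order Butterworth section order, default 4.
#' @return The filtered recording (same shape and channel ids).
#' @export
bandpass <- function(rec, low = 1, high = 400, order = 4L) {
  stopifnot(inherits(rec, "electrogram_recording"))
  check_band(low, high, rec$sample_rate)
  hp <- butter_coef(order, low / (rec$sample_rate / 2), "high")
  lp <- butter_coef(order, high / (rec$sample_rate / 2), "low")
  apply_both <- function(x) filtfilt_ba(lp, filtfilt_ba(hp, x))
  sig <- t(apply(rec$signal, 1L, apply_both))
  ref <- if (!is.null(rec$reference)) apply_both(rec$reference)
  electrogram_recording(sig, rec$sample_rate, rec$channel_ids, ref,
                        preprocessing = c(rec$preprocessing,
                                          sprintf("bandpass[%g-%g Hz]",
                                                  low, high)))
}

#' Detect ventricular beats on a reference lead
#'
#' Finds QRS-like complexes on the reference trace by derivative-energy
#' thresholding with a refractory period: the squared central-difference
#' derivative is smoothed, local maxima above a fraction of the global
#' maximum are candidate beats, and candidates within the refractory
#' period of an accepted beat are suppressed (earliest wins).  The
#' detected times are the prerequisite for far-field QRS-T template
#' subtraction on atrial channels.
#'
#' @param reference numeric reference trace (>= 1 s long), or an
#'   [electrogram_recording()] carrying one.
#' @param sample_rate sampling rate, Hz (ignored when a recording is
#'   supplied).
#' @param refractory_ms minimum beat separation, ms.
#' @param threshold fraction of the peak derivative energy a candidate
#'   must exceed.
#' @param smooth_ms smoothing window for the energy envelope, ms.
#' @return Sorted numeric vector of beat times, ms (empty for a flat
#'   trace).
#' @export
detect_ventricular_beats <- function(reference, sample_rate = NULL,
                                     refractory_ms = 250,
                                     threshold = 0.25, smooth_ms = 20) {
  if (inherits(reference, "electrogram_recording")) {
    sample_rate <- reference$sample_rate
    reference <- reference$reference
  }
  if (is.null(reference))
    stop("no reference trace available; supply beat times explicitly ",
         "to subtract_farfield()", call. = FALSE)
  if (is.null(sample_rate))
    stop("sample_rate is required with a bare reference trace",
         call. = FALSE)
  if (length(reference) < sample_rate)
    stop("reference trace must be at least 1 s long", call. = FALSE)

  d <- central_diff(reference, sample_rate)
  e <- d^2
  k <- max(1L, as.integer(round(smooth_ms / 1000 * sample_rate)))
  e <- as.numeric(stats::filter(e, rep(1 / k, k), sides = 2L))
  e[is.na(e)] <- 0
  peak <- max(e)
  if (peak <= .Machine$double.eps) return(numeric(0))

  thr <- threshold * peak
  n <- length(e)
  is_peak <- e > thr &
    e >= c(-Inf, e[-n]) & e >= c(e[-1L], -Inf)
  cand <- which(is_peak)
  if (!length(cand)) return(numeric(0))
  refr <- refractory_ms / 1000 * sample_rate
  keep <- cand[1L]
  for (i in cand[-1L])
    if (i - keep[length(keep)] >= refr) keep <- c(keep, i)
  (keep - 1L) / sample_rate * 1000
}

central_diff <- function(x, sample_rate) {
  # mV per ms.  Wide (+/- 2 sample) central difference: a genuine
  # deflection downstroke is sustained over ~sigma (several samples),
  # so widening the stencil halves the derivative noise while leaving
  # the argmin of a symmetric deflection exactly at its centre; a
  # 1-sample noise spike no longer outruns the true downstroke at
  # SNR 20 dB.  End samples copy their nearest interior value rather
  # than falling back to one-sided differences, whose inflated noise
  # variance would bias argmin detectors toward window edges.
  n <- length(x)
  dt_ms <- 1000 / sample_rate
  if (n < 5L) {
    d <- (x[3:n] - x[1:(n - 2L)]) / 2
    return(c(d[1L], d, d[n - 2L]) / dt_ms)
  }
  d <- (x[5:n] - x[1:(n - 4L)]) / 4
  c(d[1L], d[1L], d, d[n - 4L], d[n - 4L]) / dt_ms
}

#' Subtract the far-field ventricular template
#'
#' Removes ventricular QRS-T contamination from atrial channels before
#' atrial analysis.  Per channel, the signal in aligned windows around
#' the supplied beat times is averaged into a template, and the template
#' is subtracted at each beat.  Samples outside the beat windows are
#' untouched, so atrial deflections falling between ventricular
#' complexes are preserved exactly.
#'
#' @param rec an [electrogram_recording()].
#' @param beat_times_ms ventricular beat times, ms (>= 2 beats).
#' @param window_ms two-element window around each beat, ms
#'   (default `c(-50, 300)` covers QRS through T).
#' @return The recording with the per-channel template subtracted.
#' @export
subtract_farfield <- function(rec, beat_times_ms, window_ms = c(-50, 300)) {
  stopifnot(inherits(rec, "electrogram_recording"))
  beat_times_ms <- sort(beat_times_ms)
  if (length(beat_times_ms) < 2L)
    stop("template subtraction needs at least 2 beats", call. = FALSE)
  if (length(window_ms) != 2L || window_ms[1L] >= window_ms[2L])
    stop("window_ms must be c(start, end) with start < end", call. = FALSE)

  gaps <- diff(beat_times_ms)
  span <- window_ms[2L] - window_ms[1L]
  if (span > min(gaps)) {
    warning("beat windows overlap; truncating window to the shortest ",
            "inter-beat interval", call. = FALSE)
    window_ms[2L] <- window_ms[1L] + min(gaps)
  }
  fs <- rec$sample_rate
  n <- ncol(rec$signal)
  rel <- seq(as.integer(round(window_ms[1L] / 1000 * fs)),
             as.integer(round(window_ms[2L] / 1000 * fs)))
  centers <- ms_to_sample(beat_times_ms, fs)
  wins <- lapply(centers, function(c0) {
    i <- c0 + rel
    i[i >= 1L & i <= n]
  })
  full <- vapply(wins, length, integer(1)) == length(rel)
  if (sum(full) < 2L)
    stop("fewer than 2 beats with complete windows inside the recording",
         call. = FALSE)

  sig <- rec$signal
  for (ci in seq_len(nrow(sig))) {
    seg <- vapply(which(full), function(b) sig[ci, wins[[b]]],
                  numeric(length(rel)))
    tmpl <- rowMeans(seg)
    for (b in seq_along(wins)) {
      i <- wins[[b]]
      off <- match(i, centers[b] + rel)
      sig[ci, i] <- sig[ci, i] - tmpl[off]
    }
  }
  electrogram_recording(sig, fs, rec$channel_ids, rec$reference,
                        preprocessing = c(rec$preprocessing,
                                          "farfield-subtracted"))
}

#' Channel quality control
#'
#' Classifies every channel as `good`, `flatline`, `noisy` or
#' `saturated`, emulating the removal of channels with poor contact or
#' noise before interpolation.  Flatline: RMS below an absolute floor.
#' Saturated: the fraction of samples pinned at the channel extremes
#' exceeds a ceiling.  Noisy: high-frequency residual RMS (signal minus
#' a short moving average) exceeds `noisy_k` times the cohort median.
#' Classification is order-independent across channels.
#'
#' @param rec an [electrogram_recording()].
#' @param rms_floor_mv flatline RMS floor, mV.
#' @param clip_frac_max saturation ceiling (fraction of pinned samples).
#' @param noisy_k multiple of the cohort-median high-frequency RMS.
#' @return A data frame of class `channel_quality`: `channel_id`, `flag`
#'   (factor), `rms_mv`, `deriv_rms`, `hf_rms`, `clip_frac`.
#' @export
assess_channels <- function(rec, rms_floor_mv = 0.01,
                            clip_frac_max = 0.05, noisy_k = 3) {
  stopifnot(inherits(rec, "electrogram_recording"))
  sig <- rec$signal
  rms <- sqrt(rowMeans(sig^2))
  drms <- sqrt(rowMeans(t(apply(sig, 1L, central_diff,
                                sample_rate = rec$sample_rate))^2))
  k <- 5L
  hf <- t(apply(sig, 1L, function(x) {
    m <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2L))
    m[is.na(m)] <- x[is.na(m)]
    x - m
  }))
  hf_rms <- sqrt(rowMeans(hf^2))
  lo <- apply(sig, 1L, min)
  hi <- apply(sig, 1L, max)
  tol <- pmax(abs(hi - lo) * 1e-9, .Machine$double.eps)
  clip_frac <- vapply(seq_len(nrow(sig)), function(i)
    mean(sig[i, ] >= hi[i] - tol[i] | sig[i, ] <= lo[i] + tol[i]),
    numeric(1))
  clip_frac[rms <= rms_floor_mv] <- 0    # a flat channel is not "pinned"

  med_hf <- stats::median(hf_rms[rms > rms_floor_mv])
  flag <- rep("good", nrow(sig))
  flag[hf_rms > noisy_k * med_hf & is.finite(med_hf)] <- "noisy"
  flag[clip_frac > clip_frac_max] <- "saturated"
  flag[rms < rms_floor_mv] <- "flatline"

  out <- data.frame(channel_id = rec$channel_ids,
                    flag = factor(flag, levels = c("good", "flatline",
                                                   "noisy", "saturated")),
                    rms_mv = rms, deriv_rms = drms, hf_rms = hf_rms,
                    clip_frac = clip_frac)
  class(out) <- c("channel_quality", "data.frame")
  out
}

#' Spatially interpolate a per-channel scalar map
#'
#' Fills excluded (bad) channels of a derived scalar map -- activation
#' time, dominant frequency, conduction velocity -- by inverse-distance
#' weighting over good neighbours on the adjacency graph, falling back to
#' the `k_fallback` nearest good channels when a bad channel has no good
#' graph neighbour.  Good channels are never altered, and every filled
#' value is a convex combination of its contributors (so it lies within
#' their range).  Bad channels with no good channel within `max_reach_mm`
#' are left `NA` and flagged in the `"missing"` attribute.
#'
#' @param values named numeric vector (names = channel ids) or unnamed
#'   vector aligned with `layout`.
#' @param layout an [electrode_layout()].
#' @param bad channel ids to fill (defaults to channels with `NA` values).
#' @param graph optional [build_adjacency()] graph; default grid8 when
#'   grid indices exist, else knn(4).
#' @param k_fallback nearest-good-channel count for the fallback.
#' @param max_reach_mm maximum distance a fallback neighbour may be away.
#' @return The filled map (named numeric), with attribute `"missing"`.
#' @export
interpolate_map <- function(values, layout, bad = NULL, graph = NULL,
                            k_fallback = 4L, max_reach_mm = Inf) {
  if (is.null(names(values))) {
    if (length(values) != nrow(layout))
      stop("unnamed values must align with the layout", call. = FALSE)
    names(values) <- layout$channel_id
  }
  values <- values[as.character(layout$channel_id)]
  names(values) <- layout$channel_id
  if (is.null(bad)) bad <- layout$channel_id[is.na(values)]
  bad <- as.integer(bad)
  if (!all(bad %in% layout$channel_id))
    stop("bad set names unknown channels", call. = FALSE)
  good <- setdiff(layout$channel_id, bad)
  good <- good[!is.na(values[as.character(good)])]
  if (length(good) < 3L)
    stop("interpolation needs at least 3 good channels", call. = FALSE)
  if (!length(bad)) {
    attr(values, "missing") <- integer(0)
    return(values)
  }
  if (is.null(graph))
    graph <- if (has_grid(layout)) build_adjacency(layout, "grid8")
             else build_adjacency(layout, "knn", k = 4L)
  nb <- adjacency_neighbors(graph)
  pos <- layout_positions(layout)
  missing <- integer(0)
  out <- values
  for (ch in bad) {
    gnb <- intersect(nb[[as.character(ch)]], good)
    if (!length(gnb)) {
      d <- sqrt(colSums((t(pos[as.character(good), , drop = FALSE]) -
                         pos[as.character(ch), ])^2))
      near <- order(d)[seq_len(min(k_fallback, length(good)))]
      near <- near[d[near] <= max_reach_mm]
      if (!length(near)) {
        out[as.character(ch)] <- NA_real_
        missing <- c(missing, ch)
        next
      }
      gnb <- good[near]
    }
    d <- sqrt(colSums((t(pos[as.character(gnb), , drop = FALSE]) -
                       pos[as.character(ch), ])^2))
    w <- 1 / pmax(d, .Machine$double.eps)
    out[as.character(ch)] <-
      sum(w * values[as.character(gnb)]) / sum(w)
  }
  attr(out, "missing") <- missing
  out
}
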