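#' Activation-rate envelope preprocessing
#'
#' Conditions a fibrillatory electrogram for dominant-frequency
#' analysis.  The default `"botteron"` chain is the classical
#' activation-envelope transform: bandpass 40--250 Hz (isolating the
#' sharp deflections), full-wave rectification, then 20 Hz low-pass,
#' yielding an envelope whose spectral peak sits at the local activation
#' rate.  `"rectify_only"` applies the literal rectification reading --
#' with the documented pitfall that rectifying an oscillatory signal
#' doubles its frequency, which is exactly why the envelope chain is the
#' default.
#'
#' @param rec an [electrogram_recording()] (already bandpassed 1--400 Hz).
#' @param mode `"botteron"` or `"rectify_only"`.
#' @return The transformed recording, tagged in `preprocessing`.
#' @export
envelope_preprocess <- function(rec, mode = c("botteron", "rectify_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rec, "electrogram_recording"))
  if (mode == "botteron") {
    if (rec$sample_rate < 500)
      stop("botteron envelope needs a sample rate of at least 500 Hz",
           call. = FALSE)
    rec2 <- bandpass(rec, 40, 250)
    sig <- abs(rec2$signal)
    lp <- butter_coef(4L, 20 / (rec$sample_rate / 2), "low")
    sig <- t(apply(sig, 1L, function(x) filtfilt_ba(lp, x)))
    tag <- "envelope[botteron 40-250|rect|lp20]"
  } else {
    sig <- abs(rec$signal)
    tag <- "envelope[rectify-only]"
  }
  electrogram_recording(sig, rec$sample_rate, rec$channel_ids,
                        rec$reference,
                        preprocessing = c(rec$preprocessing, tag))
}

#' Averaged (Welch) power spectrum with a Hanning window
#'
#' Averaged periodogram of a single trace: the signal is split into
#' mean-removed, Hann-windowed segments with the given overlap and the
#' one-sided periodograms are averaged.  The density normalisation makes
#' the band-integrated power of a unit sinusoid ~ 0.5 (its variance),
#' i.e. `sum(power) * resolution ~ var(signal)` (Parseval).
#'
#' @param x numeric signal vector.
#' @param sample_rate sampling rate, Hz.
#' @param segment_s segment length, s (default 2 s: 0.5 Hz resolution).
#' @param overlap fractional overlap between segments, default 0.5.
#' @return An object of class `power_spectrum`: list with `freq_hz`,
#'   `power` (mV^2/Hz), `resolution_hz`, `n_segments`, `tag`.
#' @export
power_spectrum <- function(x, sample_rate, segment_s = 2, overlap = 0.5) {
  n <- length(x)
  L <- as.integer(round(segment_s * sample_rate))
  if (L < 8L) stop("segment too short", call. = FALSE)
  if (L > n) {
    warning("signal shorter than one segment; using a single ",
            "full-length segment", call. = FALSE)
    L <- n
  }
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))   # Hann
  scale <- 1 / (sample_rate * sum(w^2))
  nf <- L %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nf)]
    p <- (Mod(X)^2) * scale
    # one-sided: double every bin except DC (and Nyquist when L even)
    dbl <- rep(2, nf); dbl[1L] <- 1
    if (L %% 2L == 0L) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  structure(list(freq_hz = (seq_len(nf) - 1L) * sample_rate / L,
                 power = acc / length(starts),
                 resolution_hz = sample_rate / L,
                 n_segments = length(starts),
                 tag = "hann-welch"),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "<power_spectrum: 0-%.4g Hz @ %.3g Hz resolution, %d segment(s)>\n",
    max(x$freq_hz), x$resolution_hz, x$n_segments))
  invisible(x)
}

#' Dominant frequency of a spectrum
#'
#' The frequency of maximal power within the search band (default
#' 3--15 Hz, the fibrillatory range); out-of-band peaks are ignored and
#' ties resolve to the lowest frequency.
#'
#' @param spec a [power_spectrum()].
#' @param band two-element search band, Hz.
#' @return Dominant frequency, Hz.
#' @export
dominant_frequency <- function(spec, band = c(3, 15)) {
  stopifnot(inherits(spec, "power_spectrum"))
  i <- which(spec$freq_hz >= band[1L] & spec$freq_hz <= band[2L])
  if (!length(i))
    stop("empty search band [", band[1L], ", ", band[2L],
         "] Hz at resolution ", spec$resolution_hz, " Hz", call. = FALSE)
  spec$freq_hz[i[which.max(spec$power[i])]]
}

#' Regularity index
#'
#' Fraction of the search-band spectral power concentrated in a narrow
#' window around the dominant frequency:
#' `RI = P(df +/- window) / P(band)`, in `[0, 1]`.  A flat spectrum over
#' a 3--15 Hz band scores `1.5 / 12 = 0.125` and is discarded at the
#' default 0.2 threshold; a spectrum concentrated at the DF scores ~ 1.
#' Zero band power returns 0 by convention.
#'
#' @param spec a [power_spectrum()].
#' @param df dominant frequency, Hz (within `band`).
#' @param band search band, Hz.
#' @param window half-width of the DF window, Hz (default 0.75).
#' @return RI in `[0, 1]`.
#' @export
regularity_index <- function(spec, df, band = c(3, 15), window = 0.75) {
  stopifnot(inherits(spec, "power_spectrum"))
  if (df < band[1L] || df > band[2L])
    stop("df must lie within the search band", call. = FALSE)
  ib <- spec$freq_hz >= band[1L] & spec$freq_hz <= band[2L]
  denom <- sum(spec$power[ib])
  if (denom <= 0) return(0)
  iw <- ib & spec$freq_hz >= df - window & spec$freq_hz <= df + window
  sum(spec$power[iw]) / denom
}

#' The regularity-index discard rule
#'
#' A channel's dominant frequency is retained if and only if its
#' regularity index reaches the threshold (default 0.2): `ri >=
#' threshold`.  At the threshold exactly, the channel is retained.
#' This is the single predicate [df_map()] applies when discarding
#' channels.
#'
#' @param ri regularity index values.
#' @param threshold discard threshold.
#' @return logical vector: `TRUE` where retained.
#' @export
df_retained <- function(ri, threshold = 0.2) {
  !is.na(ri) & ri >= threshold
}

#' Dominant-frequency map of a fibrillatory recording
#'
#' The whole-array frequency-domain map: each channel is envelope-
#' transformed, Welch/Hann spectra are computed, the dominant frequency
#' and regularity index are extracted, channels with `RI <` threshold
#' (default 0.2) are discarded, and discarded channels are filled by
#' spatial interpolation from the retained ones.
#'
#' @param rec a bandpassed [electrogram_recording()].
#' @param layout the matching [electrode_layout()].
#' @param band DF search band, Hz.
#' @param threshold RI discard threshold (a channel is retained iff
#'   `RI >= threshold`).
#' @param segment_s,overlap Welch parameters.
#' @param mode envelope mode, see [envelope_preprocess()].
#' @param quality optional [assess_channels()] result; non-good channels
#'   are discarded before spectral analysis.
#' @return A data frame of class `df_map`: `channel_id`, `df_hz`, `ri`,
#'   `retained`, `interpolated` (the display value: measured DF where
#'   retained, interpolated fill otherwise), with attributes
#'   `resolution_hz`, `threshold` and `retained_fraction`.
#' @export
df_map <- function(rec, layout, band = c(3, 15), threshold = 0.2,
                   segment_s = 2, overlap = 0.5,
                   mode = c("botteron", "rectify_only"), quality = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(rec, "electrogram_recording"))
  env <- envelope_preprocess(rec, mode)
  nch <- nrow(env$signal)
  dfv <- riv <- rep(NA_real_, nch)
  res <- NA_real_
  bad_qc <- if (!is.null(quality))
    quality$channel_id[quality$flag != "good"] else integer(0)
  for (ci in seq_len(nch)) {
    if (env$channel_ids[ci] %in% bad_qc) next
    sp <- power_spectrum(env$signal[ci, ], env$sample_rate,
                         segment_s, overlap)
    res <- sp$resolution_hz
    dfv[ci] <- dominant_frequency(sp, band)
    riv[ci] <- regularity_index(sp, dfv[ci], band)
  }
  retained <- df_retained(riv, threshold)
  if (!any(retained))
    stop("all channels discarded (RI < ", threshold,
         "); no DF map", call. = FALSE)
  shown <- ifelse(retained, dfv, NA_real_)
  names(shown) <- env$channel_ids
  filled <- interpolate_map(shown, layout)
  out <- data.frame(channel_id = env$channel_ids, df_hz = dfv, ri = riv,
                    retained = retained,
                    interpolated = as.numeric(filled))
  class(out) <- c("df_map", "data.frame")
  attr(out, "resolution_hz") <- res
  attr(out, "threshold") <- threshold
  attr(out, "band_hz") <- band
  attr(out, "retained_fraction") <- mean(retained)
  out
}

#' @export
print.df_map <- function(x, ...) {
  cat(sprintf(
    "<df_map: %d channels, %.0f%% retained (RI >= %g), DF %.3g-%.3g Hz>\n",
    nrow(x), 100 * attr(x, "retained_fraction"), attr(x, "threshold"),
    min(x$df_hz[x$retained]), max(x$df_hz[x$retained])))
  invisible(x)
}
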