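#' Multichannel electrogram recordings
#'
#' Container for a sampled multichannel unipolar electrogram: a
#' channels-by-samples signal matrix in mV, the sampling rate (default
#' hardware rate 2048 Hz), channel ids resolving into an
#' [electrode_layout()], and an optional reference lead (a body-surface
#' ECG-like trace used for ventricular beat detection).
#'
#' @param signal numeric matrix, channels x samples, mV.
#' @param sample_rate sampling rate, Hz.
#' @param channel_ids integer channel labels, one per signal row.
#' @param reference optional numeric vector, the reference lead.
#' @param preprocessing character tag recording applied conditioning.
#' @return An object of class `electrogram_recording`.
#' @export
electrogram_recording <- function(signal, sample_rate = 2048,
                                  channel_ids = seq_len(nrow(signal)),
                                  reference = NULL,
                                  preprocessing = character(0)) {
  signal <- as.matrix(signal)
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be positive", call. = FALSE)
  if (length(channel_ids) != nrow(signal))
    stop("channel_ids must match signal rows", call. = FALSE)
  if (!all(is.finite(signal)))
    stop("signal contains non-finite samples", call. = FALSE)
  if (!is.null(reference) && length(reference) != ncol(signal))
    stop("reference lead length must equal the sample count", call. = FALSE)
  rownames(signal) <- as.character(channel_ids)
  structure(list(signal = signal, sample_rate = sample_rate,
                 channel_ids = as.integer(channel_ids),
                 reference = reference,
                 preprocessing = preprocessing),
            class = "electrogram_recording")
}

#' @export
print.electrogram_recording <- function(x, ...) {
  cat(sprintf(
    "<electrogram_recording: %d channels x %d samples @ %g Hz (%.3g s)%s%s>\n",
    nrow(x$signal), ncol(x$signal), x$sample_rate, duration_s(x),
    if (is.null(x$reference)) "" else ", reference lead",
    if (length(x$preprocessing))
      paste0("; ", paste(x$preprocessing, collapse = " -> ")) else ""))
  invisible(x)
}

#' @rdname electrogram_recording
#' @param rec an `electrogram_recording`.
#' @export
duration_s <- function(rec) ncol(rec$signal) / rec$sample_rate

# time axis in ms
rec_time_ms <- function(rec) {
  (seq_len(ncol(rec$signal)) - 1L) / rec$sample_rate * 1000
}

ms_to_sample <- function(t_ms, sample_rate) {
  as.integer(round(t_ms / 1000 * sample_rate)) + 1L
}

#' Read / write recordings as header JSON plus wide CSV
#'
#' `write_recording` stores `<stem>.json` (sample rate, channel ids,
#' units, preprocessing tags, optional provenance) and `<stem>.csv`
#' (columns: one per channel, plus `reference` if present; one row per
#' sample).  `read_recording` reverses it.
#'
#' @param rec an [electrogram_recording()].
#' @param stem path stem (without extension).
#' @param provenance optional named list stored in the header.
#' @return `write_recording` returns `stem` invisibly; `read_recording`
#'   returns the recording.
#' @export
write_recording <- function(rec, stem, provenance = NULL) {
  hdr <- list(sample_rate_hz = rec$sample_rate,
              channel_ids = rec$channel_ids,
              n_samples = ncol(rec$signal),
              units = "mV",
              has_reference = !is.null(rec$reference),
              preprocessing = rec$preprocessing)
  if (!is.null(provenance)) hdr$provenance <- provenance
  jsonlite::write_json(hdr, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  df <- as.data.frame(t(rec$signal))
  names(df) <- paste0("ch", rec$channel_ids)
  if (!is.null(rec$reference)) df$reference <- rec$reference
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_recording
#' @export
read_recording <- function(stem) {
  hdr <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(stem, ".csv"))
  ids <- as.integer(hdr$channel_ids)
  sig <- t(as.matrix(df[, paste0("ch", ids), drop = FALSE]))
  ref <- if (isTRUE(hdr$has_reference)) df$reference else NULL
  electrogram_recording(sig, hdr$sample_rate_hz, ids, ref,
                        preprocessing = as.character(hdr$preprocessing))
}
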