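#' Propagation scenarios
#'
#' A `propagation_scenario` is the generative description the wavefront
#' simulator renders: activation sources, a per-channel conduction-velocity
#' field (baseline value plus optional slow zones), non-conducting lesion
#' channels and a beat schedule.  The simulator recovers from it the
#' ground truth every downstream stage is benchmarked against.
#'
#' @param sources list of sources; each element a list with `onset_ms` and
#'   either `channel` (a channel id) or `position` (an xyz mm vector,
#'   snapped to the nearest electrode at simulation time).  A bare integer
#'   vector is accepted as channel ids with onset 0.
#' @param cv_mps baseline conduction velocity, m/s (1 m/s = 1 mm/ms).
#' @param slow_zones list of `list(channels =, factor =)` entries; each
#'   scales the CV of its channels by `factor` (0 < factor), emulating
#'   e.g. progressive ischemic conduction slowing.
#' @param lesions integer channel ids rendered non-conducting (ablation
#'   lesion block).
#' @param rate_bpm beat rate, beats/min (> 0).
#' @param n_beats optional beat count; default: as many beats as fit the
#'   rendered duration.
#' @param rhythm one of `"sinus"`, `"paced"`, `"focal"`, `"fibrillatory"`.
#' @return An object of class `propagation_scenario`.
#' @seealso [scenario_sinus()], [geodesic_activation_times()],
#'   [render_recording()]
#' @export
propagation_scenario <- function(sources, cv_mps = 1.04,
                                 slow_zones = list(),
                                 lesions = integer(0),
                                 rate_bpm = 114, n_beats = NULL,
                                 rhythm = c("sinus", "paced", "focal",
                                            "fibrillatory")) {
  rhythm <- match.arg(rhythm)
  if (is.numeric(sources) && is.null(names(sources)))
    sources <- lapply(as.integer(sources),
                      function(ch) list(channel = ch, onset_ms = 0))
  if (rhythm != "fibrillatory" && length(sources) < 1L)
    stop("non-fibrillatory scenarios need at least one source",
         call. = FALSE)
  if (!is.numeric(cv_mps) || any(cv_mps <= 0))
    stop("cv_mps must be positive", call. = FALSE)
  for (z in slow_zones)
    if (is.null(z$channels) || is.null(z$factor) || z$factor <= 0)
      stop("each slow zone needs channels and a positive factor",
           call. = FALSE)
  if (!is.numeric(rate_bpm) || rate_bpm <= 0)
    stop("rate_bpm must be positive", call. = FALSE)
  structure(list(sources = sources, cv_mps = cv_mps,
                 slow_zones = slow_zones,
                 lesions = as.integer(lesions),
                 rate_bpm = rate_bpm, n_beats = n_beats, rhythm = rhythm),
            class = "propagation_scenario")
}

#' @export
print.propagation_scenario <- function(x, ...) {
  cat(sprintf(
    "<propagation_scenario: %s, %d source(s), cv %s m/s, %d lesion(s), %g bpm>\n",
    x$rhythm, length(x$sources), paste(format(x$cv_mps), collapse = "/"),
    length(x$lesions), x$rate_bpm))
  invisible(x)
}

# resolve the per-channel CV field (m/s); lesion channels -> NA
scenario_cv_field <- function(scenario, layout) {
  cv <- rep_len(scenario$cv_mps, nrow(layout))
  names(cv) <- layout$channel_id
  for (z in scenario$slow_zones) {
    i <- match(as.integer(z$channels), layout$channel_id)
    if (anyNA(i))
      stop("slow zone names unknown channels", call. = FALSE)
    cv[i] <- cv[i] * z$factor
  }
  cv[match(scenario$lesions, layout$channel_id)] <- NA_real_
  cv
}

# snap sources to channel ids; error if a source sits on a lesion
resolve_sources <- function(scenario, layout) {
  pos <- layout_positions(layout)
  out <- lapply(scenario$sources, function(s) {
    onset <- if (is.null(s$onset_ms)) 0 else s$onset_ms
    ch <- if (!is.null(s$channel)) {
      as.integer(s$channel)
    } else if (!is.null(s$position)) {
      d2 <- colSums((t(pos) - as.numeric(s$position))^2)
      layout$channel_id[which.min(d2)]
    } else stop("source needs a channel or a position", call. = FALSE)
    if (!ch %in% layout$channel_id)
      stop("source channel ", ch, " not in layout", call. = FALSE)
    list(channel = ch, onset_ms = onset)
  })
  chs <- vapply(out, `[[`, integer(1), "channel")
  if (any(chs %in% scenario$lesions))
    stop("invalid scenario: source placed on a lesion channel",
         call. = FALSE)
  out
}

#' Canned scenarios mirroring the mapped rhythms
#'
#' Convenience constructors for the activation patterns the pipeline is
#' validated on: `scenario_sinus()` is a plane wave entering from one
#' array edge (every electrode of the first column is a simultaneous
#' source) at the in vivo default of 114 beats/min and 1.04 m/s;
#' `scenario_paced()` is bipolar pacing through two adjacent electrodes
#' with retrograde spread; `scenario_focal()` is a single ectopic source
#' (PVC-like); `scenario_lesion()` adds a non-conducting block to any
#' scenario; `scenario_ischemia()` adds a slow zone with a CV scale
#' factor.
#'
#' @param layout an [electrode_layout()] with grid indices.
#' @param cv_mps baseline conduction velocity, m/s.
#' @param rate_bpm beat rate, beats/min.
#' @param channels source channels (`scenario_paced`) or lesion channels
#'   (`scenario_lesion`) or slow-zone channels (`scenario_ischemia`).
#' @param channel focal source channel.
#' @param scenario scenario to modify.
#' @param factor slow-zone CV scale factor in (0, 1].
#' @return A [propagation_scenario()].
#' @name canned_scenarios
NULL

#' @rdname canned_scenarios
#' @export
scenario_sinus <- function(layout, cv_mps = 1.04, rate_bpm = 114) {
  if (!has_grid(layout))
    stop("scenario_sinus needs grid indices", call. = FALSE)
  src <- layout$channel_id[layout$col == min(layout$col)]
  propagation_scenario(src, cv_mps = cv_mps, rate_bpm = rate_bpm,
                       rhythm = "sinus")
}

#' @rdname canned_scenarios
#' @export
scenario_paced <- function(layout, channels = NULL, cv_mps = 1.04,
                           rate_bpm = 150) {
  if (is.null(channels)) {
    if (!has_grid(layout))
      stop("default paced channels need grid indices", call. = FALSE)
    rmax <- max(layout$row)
    cmid <- sort(unique(layout$col))
    cmid <- cmid[ceiling(length(cmid) / 2) + 0:1]
    channels <- layout$channel_id[layout$row == rmax &
                                  layout$col %in% cmid]
  }
  if (length(channels) != 2L)
    stop("bipolar pacing uses exactly two adjacent electrodes",
         call. = FALSE)
  propagation_scenario(as.integer(channels), cv_mps = cv_mps,
                       rate_bpm = rate_bpm, rhythm = "paced")
}

#' @rdname canned_scenarios
#' @export
scenario_focal <- function(layout, channel, cv_mps = 1.04,
                           rate_bpm = 100) {
  propagation_scenario(as.integer(channel), cv_mps = cv_mps,
                       rate_bpm = rate_bpm, rhythm = "focal")
}

#' @rdname canned_scenarios
#' @export
scenario_lesion <- function(scenario, channels) {
  scenario$lesions <- sort(unique(c(scenario$lesions,
                                    as.integer(channels))))
  scenario
}

#' @rdname canned_scenarios
#' @export
scenario_ischemia <- function(scenario, channels, factor = 0.5) {
  scenario$slow_zones <- c(scenario$slow_zones,
                           list(list(channels = as.integer(channels),
                                     factor = factor)))
  scenario
}

#' Dominant-frequency fields for fibrillatory fixtures
#'
#' A `df_field` assigns each channel a target local activation rate (the
#' dominant frequency the analysis should recover, Hz) and a
#' dimensionless cycle-length jitter coefficient.  `df_field_patchy()`
#' splits the array into a low-DF and a high-DF half along the column
#' axis, emulating a spatially organised fibrillatory substrate with a
#' maximal-DF region on one border.
#'
#' @param layout an [electrode_layout()].
#' @param df_hz per-channel target DF, Hz (recycled).
#' @param jitter cycle-length jitter coefficient, >= 0.
#' @param band admissible DF range, Hz (the spectral search band).
#' @param low_hz,high_hz patch frequencies for the patchy field.
#' @return A data frame of class `df_field` with columns `channel_id`,
#'   `df_hz`, `jitter`.
#' @export
df_field <- function(layout, df_hz, jitter = 0.1, band = c(3, 15)) {
  df_hz <- rep_len(as.numeric(df_hz), nrow(layout))
  if (any(df_hz < band[1]) || any(df_hz > band[2]))
    stop("df_hz must lie within the analysis band [", band[1], ", ",
         band[2], "] Hz", call. = FALSE)
  if (jitter < 0) stop("jitter must be >= 0", call. = FALSE)
  out <- data.frame(channel_id = layout$channel_id, df_hz = df_hz,
                    jitter = jitter)
  class(out) <- c("df_field", "data.frame")
  out
}

#' @rdname df_field
#' @export
df_field_patchy <- function(layout, low_hz = 5, high_hz = 8,
                            jitter = 0.1, band = c(3, 15)) {
  if (!has_grid(layout))
    stop("df_field_patchy needs grid indices", call. = FALSE)
  mid <- stats::median(unique(layout$col))
  df_field(layout, ifelse(layout$col <= mid, low_hz, high_hz),
           jitter = jitter, band = band)
}

#' Read / write scenarios as JSON
#'
#' @param scenario a [propagation_scenario()].
#' @param path file path.
#' @return `read_scenario_json` returns a scenario; `write_scenario_json`
#'   returns `path` invisibly.
#' @export
write_scenario_json <- function(scenario, path) {
  jsonlite::write_json(unclass(scenario), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_scenario_json
#' @export
read_scenario_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  propagation_scenario(
    sources = lapply(x$sources, function(s)
      list(channel = s$channel,
           position = if (!is.null(s$position)) unlist(s$position),
           onset_ms = s$onset_ms %||% 0)),
    cv_mps = unlist(x$cv_mps),
    slow_zones = lapply(x$slow_zones, function(z)
      list(channels = unlist(z$channels), factor = z$factor)),
    lesions = unlist(x$lesions) %||% integer(0),
    rate_bpm = x$rate_bpm, n_beats = x$n_beats,
    rhythm = x$rhythm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
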