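#' Segment a recording into beat windows
#'
#' Splits a preprocessed recording into per-beat analysis windows from
#' the global deflection-energy envelope: the channel-mean absolute
#' derivative is smoothed, its peaks above a fraction of the global
#' maximum (separated by at least `min_separation_ms`) mark beats, and
#' window boundaries are the midpoints between consecutive peaks.
#' Windows are sorted and disjoint; a flat recording yields an empty
#' list with a warning.
#'
#' @param rec an [electrogram_recording()].
#' @param min_separation_ms minimum peak separation, ms.
#' @param threshold fraction of the peak envelope value.
#' @param smooth_ms envelope smoothing window, ms.
#' @param max_half_width_ms cap on the half-width of the first/last
#'   window, ms.
#' @return Data frame with columns `start_ms`, `end_ms`, one row per
#'   beat.
#' @export
segment_beats <- function(rec, min_separation_ms = 200, threshold = 0.3,
                          smooth_ms = 10, max_half_width_ms = 250) {
  stopifnot(inherits(rec, "electrogram_recording"))
  fs <- rec$sample_rate
  env <- colMeans(abs(t(apply(rec$signal, 1L, central_diff,
                              sample_rate = fs))))
  k <- max(1L, as.integer(round(smooth_ms / 1000 * fs)))
  env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2L))
  env[is.na(env)] <- 0
  peak <- max(env)
  empty <- data.frame(start_ms = numeric(0), end_ms = numeric(0))
  if (peak <= .Machine$double.eps) {
    warning("no beats found (flat recording)", call. = FALSE)
    return(empty)
  }
  # threshold sits above the noise floor (envelope median), not at a
  # fraction of the raw maximum, so a broadband noise floor does not
  # masquerade as beats
  floor_ <- stats::median(env)
  thr <- floor_ + threshold * (peak - floor_)
  n <- length(env)
  cand <- which(env > thr & env >= c(-Inf, env[-n]) &
                env >= c(env[-1L], -Inf))
  if (!length(cand)) {
    warning("no beats found", call. = FALSE)
    return(empty)
  }
  sep <- min_separation_ms / 1000 * fs
  keep <- cand[1L]
  for (i in cand[-1L]) {
    last <- keep[length(keep)]
    if (i - last >= sep) keep <- c(keep, i)
    else if (env[i] > env[last]) keep[length(keep)] <- i
  }
  ctr <- (keep - 1L) / fs * 1000
  half <- if (length(ctr) > 1L) min(diff(ctr)) / 2 else max_half_width_ms
  half <- min(half, max_half_width_ms)
  start <- c(max(0, ctr[1L] - half),
             if (length(ctr) > 1L) (ctr[-length(ctr)] + ctr[-1L]) / 2)
  end <- c(if (length(ctr) > 1L) (ctr[-length(ctr)] + ctr[-1L]) / 2,
           min((n - 1L) / fs * 1000, ctr[length(ctr)] + half))
  data.frame(start_ms = start, end_ms = end)
}

#' Detect activation times within a beat window
#'
#' Per-channel activation detection at the extremal signal derivative:
#' the activation time is the instant of the steepest negative
#' deflection (the unipolar convention; `polarity =
#' "steepest_absolute"` takes the extremal `|dV/dt|` instead, the
#' literal reading of a (dV/dt)max rule).  The derivative is the
#' central difference of the conditioned trace; ties resolve to the
#' earliest sample.  Channels flagged bad upstream carry no time.
#'
#' @param rec an [electrogram_recording()] (preprocessed).
#' @param window two-element `c(start_ms, end_ms)` or a row of
#'   [segment_beats()] output; must span >= 3 samples.
#' @param polarity `"steepest_negative"` (default) or
#'   `"steepest_absolute"`.
#' @param quality optional [assess_channels()] result; non-`good`
#'   channels are marked invalid.
#' @param beat integer beat index stored on the map.
#' @return A data frame of class `activation_map`: `channel_id`,
#'   `time_ms`, `slope_mv_ms` (magnitude of the extremal derivative),
#'   `valid`.
#' @export
detect_activation <- function(rec, window = NULL,
                              polarity = c("steepest_negative",
                                           "steepest_absolute"),
                              quality = NULL, beat = 1L) {
  stopifnot(inherits(rec, "electrogram_recording"))
  polarity <- match.arg(polarity)
  fs <- rec$sample_rate
  if (is.null(window)) window <- c(0, (ncol(rec$signal) - 1L) / fs * 1000)
  window <- as.numeric(window[1:2])
  i0 <- max(1L, ms_to_sample(window[1L], fs))
  i1 <- min(ncol(rec$signal), ms_to_sample(window[2L], fs))
  if (i1 - i0 + 1L < 3L)
    stop("beat window spans fewer than 3 samples", call. = FALSE)

  bad <- if (!is.null(quality))
    quality$channel_id[quality$flag != "good"] else integer(0)
  nch <- nrow(rec$signal)
  time_ms <- rep(NA_real_, nch)
  slope <- rep(NA_real_, nch)
  valid <- !(rec$channel_ids %in% bad)
  for (ci in seq_len(nch)) {
    if (!valid[ci]) next
    # derivative over the full trace, then windowed: the window edges
    # keep true central differences
    d <- central_diff(rec$signal[ci, ], fs)[i0:i1]
    j <- if (polarity == "steepest_negative") which.min(d)
         else which.max(abs(d))
    time_ms[ci] <- (i0 + j - 2L) / fs * 1000
    slope[ci] <- abs(d[j])
  }
  if (!any(valid))
    stop("no valid channels in the activation map", call. = FALSE)
  out <- data.frame(channel_id = rec$channel_ids, time_ms = time_ms,
                    slope_mv_ms = slope, valid = valid)
  class(out) <- c("activation_map", "data.frame")
  attr(out, "beat") <- as.integer(beat)
  attr(out, "window_ms") <- window
  attr(out, "polarity") <- polarity
  out
}

#' @export
print.activation_map <- function(x, ...) {
  v <- x$time_ms[x$valid]
  cat(sprintf(
    "<activation_map: beat %d, %d/%d valid, times %.2f-%.2f ms>\n",
    attr(x, "beat"), sum(x$valid), nrow(x), min(v), max(v)))
  invisible(x)
}

#' Build an isochrone map
#'
#' Divides the total activation time of a beat (max minus min over valid
#' channels) into `n_bands` equal time segments (default 15) and assigns
#' each channel its band index (0-based); the latest channel falls in
#' band `n_bands - 1`, not a band of its own.  The display convention is
#' early = red, late = blue.  A degenerate map (all times equal) yields
#' collapsed edges, all channels in band 0 and a degenerate flag.
#'
#' @param map an [detect_activation()] map with >= 1 valid channel.
#' @param n_bands number of isochronal segments, default 15.
#' @return An object of class `isochrone_map`: list with `edges_ms`
#'   (`n_bands + 1` monotone times), `band` (named integer, `NA` for
#'   invalid channels), `n_bands`, `degenerate`, `color_convention`.
#' @export
build_isochrones <- function(map, n_bands = 15L) {
  stopifnot(inherits(map, "activation_map"))
  if (n_bands < 1L) stop("n_bands must be >= 1", call. = FALSE)
  t <- map$time_ms[map$valid]
  if (!length(t)) stop("no valid channels", call. = FALSE)
  t0 <- min(t); t1 <- max(t)
  degenerate <- t1 <= t0
  band <- rep(NA_integer_, nrow(map))
  names(band) <- map$channel_id
  if (degenerate) {
    edges <- rep(t0, n_bands + 1L)
    band[map$valid] <- 0L
  } else {
    edges <- seq(t0, t1, length.out = n_bands + 1L)
    # epsilon guard: times within rounding error of a band edge belong
    # to the upper band
    b <- floor((map$time_ms - t0) / (t1 - t0) * n_bands + 1e-9)
    band[map$valid] <- pmin(as.integer(b[map$valid]), n_bands - 1L)
  }
  structure(list(edges_ms = edges, band = band, n_bands = as.integer(n_bands),
                 degenerate = degenerate,
                 color_convention = "early=red,late=blue"),
            class = "isochrone_map")
}

#' @export
print.isochrone_map <- function(x, ...) {
  cat(sprintf("<isochrone_map: %d bands over %.2f-%.2f ms%s (%s)>\n",
              x$n_bands, x$edges_ms[1L], x$edges_ms[length(x$edges_ms)],
              if (x$degenerate) ", degenerate" else "",
              x$color_convention))
  invisible(x)
}

#' Time-lapse activation frames
#'
#' Partitions the valid channels of an activation map into ordered
#' frames of fixed duration (e.g. 5 or 10 ms): frame `k` holds the
#' channels activating in `[min + k * interval, min + (k+1) * interval)`,
#' with the latest channel closed into the final frame.  Frames
#' partition the valid channels and there are `ceil(range / interval)`
#' of them (at least 1).
#'
#' @param map an activation map.
#' @param interval_ms frame duration, ms, > 0.
#' @return List of integer channel-id vectors, one per frame, with
#'   attribute `"starts_ms"`.
#' @export
activation_frames <- function(map, interval_ms = 5) {
  stopifnot(inherits(map, "activation_map"))
  if (!is.numeric(interval_ms) || interval_ms <= 0)
    stop("interval_ms must be > 0", call. = FALSE)
  t <- map$time_ms[map$valid]
  ch <- map$channel_id[map$valid]
  t0 <- min(t)
  rng <- max(t) - t0
  nf <- max(1L, as.integer(ceiling(rng / interval_ms)))
  k <- pmin(as.integer(floor((t - t0) / interval_ms)), nf - 1L)
  frames <- lapply(seq_len(nf) - 1L, function(f) ch[k == f])
  attr(frames, "starts_ms") <- t0 + (seq_len(nf) - 1L) * interval_ms
  attr(frames, "interval_ms") <- interval_ms
  frames
}

#' Local conduction-velocity estimation
#'
#' Estimates conduction velocity at each channel by a least-squares
#' plane fit of activation time over the channel's spatial neighbourhood
#' (the channel plus its adjacency-graph neighbours, default 8 grid
#' neighbours): `T(x, y) = a + b x + c y` in surface coordinates, so the
#' local speed is `1 / sqrt(b^2 + c^2)` (mm/ms = m/s) and the local
#' propagation direction is the unit vector along the activation-time
#' gradient.  Channels with fewer than `min_neighbors` valid,
#' non-collinear neighbours -- or with a vanishing gradient -- are
#' skipped; the map-level summary is the mean and SD over estimated
#' channels.
#'
#' @param map an activation map.
#' @param layout the matching [electrode_layout()].
#' @param graph optional adjacency graph (default grid8).
#' @param min_neighbors minimum neighbourhood size (excluding the
#'   channel itself), default 3.
#' @param max_cv_mps estimates above this bound (near-flat fits) are
#'   skipped as unphysical.
#' @return A data frame of class `cv_map`: `channel_id`, `cv_mps`,
#'   `dir_x`, `dir_y`, `valid`, with attributes `mean_mps` and `sd_mps`.
#' @export
estimate_cv <- function(map, layout, graph = NULL, min_neighbors = 3L,
                        max_cv_mps = 20) {
  stopifnot(inherits(map, "activation_map"))
  if (is.null(graph))
    graph <- if (has_grid(layout)) build_adjacency(layout, "grid8")
             else build_adjacency(layout, "knn", k = 8L)
  nb <- adjacency_neighbors(graph)
  tmap <- stats::setNames(map$time_ms, map$channel_id)
  tmap[!map$valid] <- NA_real_
  pos <- layout_positions(layout)

  n <- nrow(layout)
  cv <- dirx <- diry <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ch <- layout$channel_id[i]
    if (is.na(tmap[as.character(ch)])) next
    hood <- c(ch, nb[[as.character(ch)]])
    hood <- hood[!is.na(tmap[as.character(hood)])]
    if (length(hood) < min_neighbors + 1L) next
    X <- pos[as.character(hood), 1:2, drop = FALSE]
    y <- tmap[as.character(hood)]
    A <- cbind(1, X)
    if (qr(A)$rank < 3L) next            # collinear neighbourhood
    beta <- qr.solve(A, y)
    g <- beta[2:3]
    gn <- sqrt(sum(g^2))
    if (gn < 1 / max_cv_mps) next        # flat fit: unphysically fast
    cv[i] <- 1 / gn
    dirx[i] <- g[1L] / gn
    diry[i] <- g[2L] / gn
  }
  if (all(is.na(cv)))
    stop("conduction velocity could not be estimated on any channel",
         call. = FALSE)
  out <- data.frame(channel_id = layout$channel_id, cv_mps = cv,
                    dir_x = dirx, dir_y = diry, valid = !is.na(cv))
  class(out) <- c("cv_map", "data.frame")
  attr(out, "mean_mps") <- mean(cv, na.rm = TRUE)
  attr(out, "sd_mps") <- stats::sd(cv, na.rm = TRUE)
  out
}

#' @export
print.cv_map <- function(x, ...) {
  cat(sprintf("<cv_map: %d/%d channels, %.2f +/- %.2f m/s>\n",
              sum(x$valid), nrow(x), attr(x, "mean_mps"),
              attr(x, "sd_mps")))
  invisible(x)
}

#' Localize the activation origin
#'
#' Returns the earliest-activating valid channel of a beat -- the
#' epicardial breakthrough site for sinus beats, the pacing site for
#' paced beats, the ectopic focus for PVC-like beats.  Ties at the
#' earliest time resolve to the channel with the greatest mean delay to
#' its neighbours (the truer source, since activation spreads away from
#' it).
#'
#' @param map an activation map.
#' @param layout the matching [electrode_layout()].
#' @param graph optional adjacency graph for tie-breaking.
#' @return List with `channel_id`, `position_mm` (xyz), `time_ms`.
#' @export
localize_origin <- function(map, layout, graph = NULL) {
  stopifnot(inherits(map, "activation_map"))
  t <- map$time_ms
  t[!map$valid] <- NA_real_
  t0 <- min(t, na.rm = TRUE)
  cand <- map$channel_id[!is.na(t) & t <= t0]
  if (length(cand) > 1L) {
    if (is.null(graph))
      graph <- if (has_grid(layout)) build_adjacency(layout, "grid8")
               else build_adjacency(layout, "knn", k = 4L)
    nb <- adjacency_neighbors(graph)
    tmap <- stats::setNames(t, map$channel_id)
    delay <- vapply(cand, function(ch) {
      dn <- tmap[as.character(nb[[as.character(ch)]])] - t0
      mean(dn, na.rm = TRUE)
    }, numeric(1))
    cand <- cand[which.max(delay)]
  }
  i <- match(cand, layout$channel_id)
  list(channel_id = cand,
       position_mm = unname(layout_positions(layout)[i, ]),
       time_ms = t0)
}
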