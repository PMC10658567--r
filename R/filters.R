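#' @name filters
#' @title Butterworth design and zero-phase filtering
#'
#' @description
#' Internal IIR machinery for the conditioning stages.  No DSP package is
#' assumed: `butter_coef()` designs digital Butterworth low/high-pass
#' sections via the bilinear transform of the analog prototype, and
#' `filtfilt_ba()` applies a filter forward and backward (zero phase) with
#' odd-reflection edge padding so activation times are never phase-shifted
#' by conditioning.
#'
#' @details
#' The package's 1--400 Hz electrogram band is realised as a cascade of an
#' order-4 high-pass at the low edge and an order-4 low-pass at the high
#' edge, so each printed band edge is exactly that section's half-power
#' (-3 dB) frequency in a single pass; the forward--backward application
#' squares the magnitude response (-6 dB at the edges).
NULL

# polynomial coefficients (descending powers) from roots
poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# digital Butterworth: n = order, w = cutoff / Nyquist in (0, 1)
butter_coef <- function(n, w, type = c("low", "high")) {
  type <- match.arg(type)
  if (w <= 0 || w >= 1) stop("normalized cutoff must be in (0, 1)",
                             call. = FALSE)
  fs2 <- 2                                  # bilinear with fs = 1
  warped <- 2 * fs2 * tan(pi * w / 2) / 2   # prewarped analog cutoff
  k <- seq_len(n)
  p <- warped * exp(1i * pi * (2 * k + n - 1) / (2 * n))  # LHP poles
  if (type == "low") {
    z <- complex(0)
    gain <- warped^n
  } else {
    z <- rep(0 + 0i, n)
    p <- warped^2 / p         # lp2hp of the already-scaled poles
    gain <- 1
  }
  # bilinear transform
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  gd <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- c(zd, rep(-1 + 0i, n - length(z)))
  b <- Re(poly_from_roots(zd)) * gd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# single-pass complex frequency response at f (Hz)
freq_response_ba <- function(ba, f, sample_rate) {
  w <- 2 * pi * f / sample_rate
  zi <- exp(-1i * outer(w, 0:(length(ba$b) - 1L)))
  num <- drop(zi[, seq_along(ba$b), drop = FALSE] %*% ba$b)
  den <- drop(zi[, seq_along(ba$a), drop = FALSE] %*% ba$a)
  num / den
}

# causal direct-form-I filter via C-level stats::filter, with initial
# conditions matched to a constant x[1] history (the lfilter_zi trick:
# by linearity, response(x | steady state at x[1]) =
# x[1] * H(DC) + zero-state response(x - x[1]))
filter_ba <- function(ba, x) {
  b <- ba$b / ba$a[1L]
  a <- ba$a / ba$a[1L]
  x0 <- x[1L]
  dc <- sum(b) / sum(a)
  x <- x - x0
  nb <- length(b)
  xp <- c(numeric(nb - 1L), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1L)
  v <- as.numeric(v)[nb - 1L + seq_along(x)]
  if (length(a) > 1L)
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  v + x0 * dc
}

# zero-phase forward-backward filtering with odd-reflection padding
filtfilt_ba <- function(ba, x) {
  n <- length(x)
  np <- 3L * (max(length(ba$a), length(ba$b)) - 1L)
  if (n <= np + 1L)
    stop("signal too short to filter (", n, " samples)", call. = FALSE)
  front <- 2 * x[1L] - x[(np + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - np)]
  xe <- c(front, x, back)
  y <- filter_ba(ba, xe)
  y <- rev(filter_ba(ba, rev(y)))
  y[np + seq_len(n)]
}

#' Magnitude response of the electrogram bandpass
#'
#' Magnitude of the implemented Butterworth band (high-pass low edge
#' cascaded with low-pass high edge) at the requested frequencies.  With
#' the defaults the single-pass response is 1/sqrt(2) at 400 Hz.
#'
#' @param freq_hz frequencies to evaluate, Hz.
#' @param low,high band edges, Hz.
#' @param sample_rate sampling rate, Hz.
#' @param order section order (each section), default 4.
#' @param passes 1 for the causal response, 2 for the zero-phase
#'   (forward-backward) response.
#' @return numeric vector of magnitudes.
#' @examples
#' bandpass_response(400)            # ~0.7071
#' @export
bandpass_response <- function(freq_hz, low = 1, high = 400,
                              sample_rate = 2048, order = 4L, passes = 1L) {
  check_band(low, high, sample_rate)
  hp <- butter_coef(order, low / (sample_rate / 2), "high")
  lp <- butter_coef(order, high / (sample_rate / 2), "low")
  mag <- Mod(freq_response_ba(hp, freq_hz, sample_rate)) *
    Mod(freq_response_ba(lp, freq_hz, sample_rate))
  mag^passes
}

check_band <- function(low, high, sample_rate) {
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || high <= low)
    stop("bandpass.low/high must satisfy 0 < low < high", call. = FALSE)
  if (high >= sample_rate / 2)
    stop("bandpass.high (", high, " Hz) must be below the Nyquist ",
         "frequency (", sample_rate / 2, " Hz)", call. = FALSE)
  invisible(TRUE)
}
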