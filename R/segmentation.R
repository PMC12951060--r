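#' Segment a PPG record into individual beats
#'
#' Beats are delimited foot-to-foot. Feet are located as the local minima
#' of a zero-phase low-pass-smoothed copy of the record (4th-order
#' Butterworth, 10 Hz cutoff, filtered forward and backward) immediately
#' preceding each steep systolic upstroke. Partial beats at the record
#' edges are discarded. Accepted beats must have a period in
#' `[0.3, 2.0]` s and a peak-to-peak amplitude within 4 MAD of the
#' median peak-to-peak amplitude; others are flagged rejected.
#'
#' @param record a `waveform_record` of at least 5 s.
#' @param min_beats minimum number of accepted beats (default 5); fewer
#'   raises an "insufficient beats" error.
#' @param period_range admissible beat period in seconds.
#' @param amplitude_mad rejection threshold in MADs of peak-to-peak
#'   amplitude (default 4).
#' @return object of class `beat_series`: list with `beats` (list of
#'   numeric segments, foot to next foot, the closing foot excluded),
#'   `periods` (seconds), `quality_flags` (TRUE = accepted), `feet`
#'   (sample indices of the detected feet).
#' @export
segment_beats <- function(record, min_beats = 5L,
                          period_range = c(0.3, 2.0), amplitude_mad = 4) {
  stopifnot(inherits(record, "waveform_record"))
  fs <- record$sampling_rate
  x <- record$samples
  if (length(x) < 5 * fs)
    stop("record shorter than 5 s; cannot segment")

  sm <- lowpass_smooth(x, fs, cutoff = 10)
  rng <- diff(range(sm))
  if (rng < 1e-9 * max(abs(sm), 1))
    stop("insufficient beats: record has no pulses (constant signal)")

  feet <- detect_feet(sm, fs, period_range)
  if (length(feet) < 2L)
    stop(sprintf("insufficient beats: found %d feet, need >= %d accepted beats",
                 length(feet), min_beats))

  nb <- length(feet) - 1L
  beats <- vector("list", nb)
  periods <- numeric(nb)
  ok <- logical(nb)
  p2p <- numeric(nb)
  for (j in seq_len(nb)) {
    idx <- feet[j]:(feet[j + 1L] - 1L)
    beats[[j]] <- x[idx]
    periods[j] <- length(idx) / fs
    p2p[j] <- diff(range(x[idx]))
    ok[j] <- periods[j] >= period_range[1] && periods[j] <= period_range[2]
  }
  # amplitude outlier rule on beats that passed the period check
  if (any(ok)) {
    med <- stats::median(p2p[ok])
    mad <- stats::mad(p2p[ok])
    if (mad > 1e-12 * max(med, 1e-300))
      ok <- ok & abs(p2p - med) <= amplitude_mad * mad
  }
  if (sum(ok) < min_beats)
    stop(sprintf("insufficient beats: %d accepted, need >= %d",
                 sum(ok), min_beats))
  structure(list(beats = beats, periods = periods, quality_flags = ok,
                 feet = feet),
            class = "beat_series")
}

# zero-phase Butterworth low-pass; falls back to the raw signal when the
# cutoff is at/above Nyquist
lowpass_smooth <- function(x, fs, cutoff = 10) {
  w <- cutoff / (fs / 2)
  if (w >= 1) return(x)
  bf <- signal::butter(4, w, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# feet = minima of the smoothed signal preceding steep upstrokes
detect_feet <- function(sm, fs, period_range) {
  d <- diff(sm)
  thr <- 0.4 * stats::quantile(d[d > 0], 0.95, names = FALSE)
  if (!is.finite(thr) || thr <= 0) return(integer(0))
  min_gap <- max(1L, as.integer(round(period_range[1] * fs)))

  # candidate upstrokes: local maxima of the derivative above threshold
  n <- length(d)
  cand <- which(d > thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[d[cand] >= d[cand - 1L] & d[cand] >= d[cand + 1L]]
  if (length(cand) == 0L) return(integer(0))
  # greedy non-maximum suppression: keep strongest, enforce min spacing
  ord <- cand[order(d[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in ord) {
    if (all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
  }
  ups <- sort(keep)

  # foot: minimum of the smoothed signal in the window before each upstroke;
  # must be an interior local minimum (guards against filter edge transients)
  win <- max(2L, as.integer(round(0.4 * fs)))
  feet <- vapply(ups, function(i) {
    lo <- max(1L, i - win)
    lo + which.min(sm[lo:i]) - 1L
  }, integer(1))
  m <- length(sm)
  # keep clear of the zero-phase filter warm-up/tail transients
  margin <- max(2L, as.integer(round(0.35 * fs)))
  feet <- feet[feet > margin & feet <= m - margin &
                 sm[pmax(feet - 1L, 1L)] >= sm[feet] &
                 sm[pmin(feet + 1L, m)] >= sm[feet]]
  unique(feet)
}

#' Resample one beat onto a fixed-length uniform grid
#'
#' Maps a beat of K samples (covering one period, closing foot excluded)
#' onto exactly `n_points` samples covering the same period. The default
#' method is band-limited (discrete Fourier) resampling, which is exact
#' for periodic beats whose content lies below the Nyquist order of the
#' input grid; cubic-spline interpolation is available as an alternative
#' for signals with an appreciable inter-period discontinuity.
#'
#' @param beat numeric vector with at least 24 samples.
#' @param n_points target length, at least 24.
#' @param method `"fourier"` or `"spline"`.
#' @return numeric vector of length `n_points`.
#' @export
resample_beat <- function(beat, n_points = 256L,
                          method = c("fourier", "spline")) {
  method <- match.arg(method)
  K <- length(beat)
  if (K < 24L) stop(sprintf("beat too short: %d samples < 24", K))
  if (n_points < 24L) stop(sprintf("n_points = %d < 24", n_points))
  if (K == n_points) return(beat)

  if (method == "fourier") {
    F <- stats::fft(beat) / K
    half_in <- floor(K / 2)
    half_out <- floor(n_points / 2)
    keep <- min(half_in, half_out)
    G <- complex(n_points)
    G[1L] <- F[1L]
    if (keep >= 1L) {
      n <- seq_len(keep)
      pos <- F[n + 1L]
      # split an even-length input's Nyquist bin symmetrically
      if (K %% 2L == 0L && keep == half_in && n_points > K)
        pos[keep] <- pos[keep] / 2
      G[n + 1L] <- pos
      G[n_points - n + 1L] <- Conj(pos)
      if (n_points %% 2L == 0L && keep == half_out)
        G[half_out + 1L] <- Re(G[half_out + 1L]) *
          (if (n_points < K) 2 else 1)
    }
    Re(stats::fft(G, inverse = TRUE))
  } else {
    # periodic cubic spline on grid 0..K over one period
    xg <- 0:K
    yg <- c(beat, beat[1L])
    xo <- (seq_len(n_points) - 1L) * K / n_points
    stats::spline(xg, yg, xout = xo, method = "periodic")$y
  }
}
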