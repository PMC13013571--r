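# Beat detection and amplitude handling ahead of attractor reconstruction.
# Only the mean RR interval is consumed downstream (it sets the embedding
# delay), so the detector needs to find R peaks reliably, not delineate
# them precisely.

#' Detect R peaks in a single-lead ECG
#'
#' A Pan--Tompkins-style pipeline: band-pass emphasis of the QRS complex
#' (5--15 Hz Butterworth, zero-phase), differentiation, squaring,
#' moving-window integration (150 ms), adaptive thresholding, then
#' refinement of each detection to the local maximum of the band-passed
#' signal within +/-50 ms. A 200 ms refractory period is enforced, keeping
#' the larger peak when two detections collide.
#'
#' @param signal numeric vector, millivolts; at least 2 s long.
#' @param fs sampling frequency in Hz.
#' @return Strictly increasing integer sample indices of detected R peaks.
#'   Fewer than 2 detected peaks is an error ("insufficient beats"): such
#'   records are excluded from feature extraction, never imputed.
#' @export
detect_r_peaks <- function(signal, fs) {
  if (fs <= 0) stop("fs must be positive")
  n <- length(signal)
  if (n < 2 * fs) stop("signal shorter than 2 s; cannot detect beats")
  if (max(signal) - min(signal) == 0) stop("insufficient beats: flat signal")

  ny <- fs / 2
  bp <- signal::butter(2, c(5, min(15, 0.9 * ny)) / ny, type = "pass")
  emphasised <- as.numeric(signal::filtfilt(bp, signal))
  d <- c(diff(emphasised), 0)
  sq <- d^2
  w <- max(1L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0

  thr <- 0.35 * stats::quantile(integ, 0.99, names = FALSE)
  above <- integ > thr
  if (!any(above)) stop("insufficient beats: no QRS-like activity found")
  # contiguous runs above threshold -> one candidate per run
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- mapply(function(s, e) s - 1L + which.max(integ[s:e]),
                 starts[runs$values], ends[runs$values])

  # refine to the local maximum of the QRS-emphasised signal within +/-50 ms
  half <- max(1L, as.integer(round(0.050 * fs)))
  peaks <- vapply(cand, function(i) {
    lo <- max(1L, as.integer(i) - half); hi <- min(n, as.integer(i) + half)
    lo - 1L + which.max(emphasised[lo:hi])
  }, integer(1))
  peaks <- sort(unique(peaks))

  # refractory period: drop the smaller of any pair closer than 200 ms
  refr <- round(0.200 * fs)
  keep <- integer(0)
  for (p in peaks) {
    if (length(keep) && p - keep[length(keep)] < refr) {
      if (emphasised[p] > emphasised[keep[length(keep)]])
        keep[length(keep)] <- p
    } else keep <- c(keep, p)
  }
  if (length(keep) < 2L)
    stop("insufficient beats: fewer than 2 R peaks detected")
  as.integer(keep)
}

#' Average cycle length from R-peak positions
#'
#' The mean distance between successive R peaks, in samples and seconds.
#' This is the cycle-length estimate the embedding delay is derived from.
#'
#' @param r_peaks strictly increasing sample indices (at least 2).
#' @param fs sampling frequency in Hz.
#' @return A list of class `cycle_estimate` with `r_peak_indices`,
#'   `L_samples` and `L_seconds`.
#' @export
average_cycle_length <- function(r_peaks, fs) {
  if (length(r_peaks) < 2L) stop("need at least 2 R peaks")
  if (any(diff(r_peaks) <= 0)) stop("r_peaks must be strictly increasing")
  if (fs <= 0) stop("fs must be positive")
  L <- mean(diff(r_peaks))
  structure(list(r_peak_indices = as.integer(r_peaks),
                 L_samples = L, L_seconds = L / fs),
            class = "cycle_estimate")
}

#' Min-max amplitude normalisation
#'
#' Rescales a signal to exactly \[0, 1\] so density features do not encode
#' per-record gain. Idempotent and invariant under positive affine
#' transforms of the input.
#'
#' @param signal numeric vector with nonzero range.
#' @return Numeric vector in \[0, 1\].
#' @export
normalize_amplitude <- function(signal) {
  r <- range(signal)
  if (r[1] == r[2]) stop("zero amplitude range: constant signal")
  (signal - r[1]) / (r[2] - r[1])
}
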