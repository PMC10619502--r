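## Welch overlapped-segment PSD. The sandbox has no signal-processing
## package, so the estimator is built on stats::fft with the standard
## one-sided density scaling: for a window w, segment FFT X,
##   psd[k] = s * 2 |X[k]|^2 / (fs * sum(w^2)),  s = 1/2 at DC and Nyquist,
## which makes sum(psd) * df an estimate of the signal variance
## (Parseval) and integrates a unit-amplitude sinusoid to A^2/2 = 0.5.

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

segment_starts <- function(n, seg_len, step) {
  if (n < seg_len) integer(0) else seq(1L, n - seg_len + 1L, by = step)
}

# One-sided PSD of a single segment (already windowed scaling inside).
segment_psd <- function(x, window, fs) {
  n <- length(x)
  X <- fft(x * window)
  n_one <- n %/% 2 + 1L
  p <- (Mod(X[seq_len(n_one)])^2) * (2 / (fs * sum(window^2)))
  p[1] <- p[1] / 2
  if (n %% 2 == 0) p[n_one] <- p[n_one] / 2
  p
}

#' Welch power spectral density
#'
#' Overlapped-segment PSD with the acquisition convention used for sleep
#' EEG here: 4-second Hamming segments with 2-second overlap.
#'
#' @param signal numeric vector (µV).
#' @param fs sampling rate in Hz.
#' @param seg_seconds segment length in seconds (default 4).
#' @param overlap_seconds overlap between consecutive segments (default 2).
#' @return list with `freq` (Hz), `psd` (µV²/Hz) and `n_segments`.
#' @export
welch_psd <- function(signal, fs, seg_seconds = 4, overlap_seconds = 2) {
  seg_len <- as.integer(round(seg_seconds * fs))
  step <- seg_len - as.integer(round(overlap_seconds * fs))
  if (step < 1L) stop_fmt("welch_psd: overlap must be shorter than the segment")
  if (length(signal) < seg_len) {
    stop_fmt("welch_psd: signal shorter than one %g-s segment", seg_seconds)
  }
  w <- hamming_window(seg_len)
  starts <- segment_starts(length(signal), seg_len, step)
  acc <- 0
  for (s in starts) {
    acc <- acc + segment_psd(signal[s:(s + seg_len - 1L)], w, fs)
  }
  n_one <- seg_len %/% 2 + 1L
  list(freq = (seq_len(n_one) - 1) * fs / seg_len,
       psd = acc / length(starts),
       n_segments = length(starts))
}

# Integrate a one-sided PSD over [lo, hi) (Hz).
integrate_band <- function(freq, psd, band) {
  df <- freq[2] - freq[1]
  sum(psd[freq >= band[1] & freq < band[2]]) * df
}

#' Band power from the Welch PSD
#'
#' Integrates the Welch PSD over the half-open frequency band
#' `[lo, hi)`; for a unit-amplitude sinusoid inside the band this returns
#' approximately 0.5 µV² (= A²/2), and over the full band it recovers the
#' signal variance.
#'
#' @inheritParams welch_psd
#' @param band numeric `c(lo, hi)` in Hz, inside `[0, fs/2]`.
#' @return band power in µV².
#' @export
welch_band_power <- function(signal, fs, band, seg_seconds = 4,
                             overlap_seconds = 2) {
  if (length(band) != 2L || band[1] < 0 || band[2] > fs / 2 || band[1] >= band[2]) {
    stop_fmt("welch_band_power: band must satisfy 0 <= lo < hi <= Nyquist (%g Hz)",
             fs / 2)
  }
  p <- welch_psd(signal, fs, seg_seconds, overlap_seconds)
  integrate_band(p$freq, p$psd, band)
}
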