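# Subject-adaptive amplitude threshold from the sigma-band RMS distribution.

#' Band-pass filter a signal in the spindle (sigma) band
#'
#' Second-order Butterworth band-pass design (11–16 Hz by default), applied
#' forward and backward (`signal::filtfilt`) so the output is zero-phase and
#' RMS windows stay aligned with spindle timing; the two passes double the
#' effective magnitude order.
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param low,high Cutoff frequencies in Hz, `0 < low < high < fs/2`.
#' @return Filtered signal, same length.
#' @export
sigma_bandpass <- function(signal, fs, low = 11, high = 16) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("need 0 < low < high < fs/2 (fs = ", fs, ")", call. = FALSE)
  }
  bf <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, signal))
}

#' Windowed RMS distribution of a (filtered) signal
#'
#' RMS is evaluated in successive non-overlapping windows (0.2 s by
#' default, about one period of sigma-band oscillation); a trailing partial
#' window is discarded.
#'
#' @param filtered Numeric vector, typically the output of
#'   [sigma_bandpass()].
#' @param fs Sampling rate in Hz.
#' @param window_s Window duration in seconds.
#' @param band Optional `c(low, high)` recorded as metadata.
#' @return An object of class `rms_distribution`: list with `values` (one
#'   RMS per complete window), `window_s`, `band`, `fs`.
#' @export
rms_windows <- function(filtered, fs, window_s = 0.2, band = c(11, 16)) {
  wsamp <- window_s * fs                  # need not be an integer
  nwin <- floor(length(filtered) / wsamp)
  if (nwin < 1) {
    stop("signal shorter than one RMS window (", window_s, " s)",
         call. = FALSE)
  }
  # window i covers samples floor(i*wsamp) .. floor((i+1)*wsamp)-1
  bounds <- floor((0:nwin) * wsamp)
  len <- diff(bounds)
  grp <- rep.int(seq_len(nwin), len)
  sq <- filtered[seq_len(bounds[nwin + 1])]^2
  vals <- sqrt(as.numeric(rowsum(sq, grp)) / len)
  structure(list(values = vals, window_s = window_s, band = band, fs = fs),
            class = "rms_distribution")
}

#' @export
print.rms_distribution <- function(x, ...) {
  cat("RMS distribution: ", length(x$values), " windows of ", x$window_s,
      " s, band ", x$band[1], "-", x$band[2], " Hz\n", sep = "")
  print(stats::quantile(x$values, c(0.5, 0.9, 0.95, 0.97, 0.99)))
  invisible(x)
}

#' Minimal peak-to-peak amplitude from an RMS percentile
#'
#' For a window holding roughly one period of a constant-amplitude sine,
#' peak-to-peak amplitude and RMS are related by \eqn{A = 2\sqrt{2}\,RMS}.
#' The subject-adaptive minimal spindle amplitude is therefore
#' \eqn{2\sqrt{2}} times the chosen percentile of the windowed sigma-band
#' RMS distribution.  Percentiles interpolate linearly between order
#' statistics (`stats::quantile` type 7).
#'
#' @param dist An [rms_windows()] result, or a bare numeric vector of RMS
#'   values.
#' @param percentile Percentile in `[0, 100]`.
#' @return Minimal peak-to-peak amplitude, in the signal's units.
#' @examples
#' amplitude_threshold(list(values = 10), 50)  # 2*sqrt(2)*10 = 28.28
#' @export
amplitude_threshold <- function(dist, percentile) {
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile < 0 || percentile > 100) {
    stop("'percentile' must be a single number in [0, 100]", call. = FALSE)
  }
  vals <- if (is.list(dist)) dist$values else dist
  if (length(vals) == 0) stop("empty RMS distribution", call. = FALSE)
  2 * sqrt(2) * as.numeric(stats::quantile(vals, percentile / 100,
                                           names = FALSE, type = 7))
}
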