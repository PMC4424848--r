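# Synthetic EEG-like recordings with implanted, ground-truth-annotated
# Gabor transients.  A test substrate, not a physiological simulation: the
# background is colored noise, transients are exact Gabor functions.

colored_noise <- function(n, fs, exponent = 1) {
  white <- stats::rnorm(n)
  if (exponent == 0) return(white)
  X <- stats::fft(white)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  gain <- 1 / pmax(f, 0.5)^(exponent / 2)   # 0.5 Hz floor avoids DC blow-up
  gain[1] <- 0
  x <- Re(stats::fft(X * gain, inverse = TRUE)) / n
  x / stats::sd(x)
}

# waveform of one implanted transient, scaled to an exact peak-to-peak
# amplitude; returns the sample index range and values
transient_wave <- function(u, s, f, phi, A, fs, n) {
  h <- floor(4 * s * fs)
  i0 <- max(0L, round(u * fs) - h)
  i1 <- min(n - 1L, round(u * fs) + h)
  t <- (i0:i1) / fs
  w <- exp(-pi * ((t - u) / s)^2) * cos(2 * pi * f * (t - u) + phi)
  w <- w * A / (max(w) - min(w))
  list(idx = (i0:i1) + 1L, w = w)
}

runif_range <- function(k, range) stats::runif(k, range[1], range[2])

#' Generate a synthetic EEG recording with ground truth
#'
#' Colored-noise background plus Gabor-shaped transients implanted at
#' non-overlapping random positions, each annotated exactly.  Spindle
#' parameters follow their standard definition (frequency uniform in
#' 11–16 Hz, envelope half-width uniform in 0.5–2 s); slow waves are
#' low-frequency high-amplitude analogues.  Events are placed on the
#' sample grid with phases uniform in `[0, 2pi)`.
#'
#' @param duration Recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed; the same seed reproduces the recording
#'   bit-for-bit.  The caller's RNG state is restored on exit.
#' @param background List: `exponent` of the `1/f^exponent` noise spectrum
#'   and total `rms` in µV.
#' @param spindles List: `density` (events per minute), `f`, `width`,
#'   `amplitude` ranges (`c(min, max)`; frequency in Hz, width in s,
#'   peak-to-peak amplitude in µV).
#' @param slow_waves Same structure for slow waves (default density 0).
#' @param min_gap Minimal gap in seconds between implanted events.
#' @return An `eeg_sim` list: `signal` (µV), `fs`, `duration` and `truth`,
#'   a data frame with one row per implanted event (`type`, `start`, `end`,
#'   `u`, `s`, `f`, `phi`, `amplitude`; intervals are `[u - s/2, u + s/2)`).
#' @examples
#' sim <- simulate_eeg(60, seed = 1, spindles = list(density = 3))
#' nrow(sim$truth)  # 3 spindles
#' @export
simulate_eeg <- function(duration, fs = 256, seed = NULL,
                         background = list(),
                         spindles = list(),
                         slow_waves = list(),
                         min_gap = 0.25) {
  background <- utils::modifyList(list(exponent = 1, rms = 15), background)
  spindles <- utils::modifyList(
    list(density = 2, f = c(11, 16), width = c(0.5, 2),
         amplitude = c(25, 60)), spindles)
  slow_waves <- utils::modifyList(
    list(density = 0, f = c(0.5, 2), width = c(0.5, 1.5),
         amplitude = c(80, 150)), slow_waves)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(seed)
  }
  n <- round(duration * fs)
  signal <- colored_noise(n, fs, background$exponent) * background$rms

  draw_events <- function(spec, type, occupied) {
    k <- round(spec$density * duration / 60)
    if (k == 0) {
      return(list(truth = NULL, occupied = occupied))
    }
    rows <- vector("list", k)
    for (i in seq_len(k)) {
      s <- runif_range(1, spec$width)
      placed <- FALSE
      for (try in seq_len(10000)) {
        u <- round(runif_range(1, c(s / 2 + min_gap,
                                    duration - s / 2 - min_gap)) * fs) / fs
        lo <- u - s / 2 - min_gap
        hi <- u + s / 2 + min_gap
        if (!any(lo < occupied$end & hi > occupied$start)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place ", k, " non-overlapping '", type,
             "' events: density too high for duration ", duration, " s",
             call. = FALSE)
      }
      occupied <- rbind(occupied, data.frame(start = lo, end = hi))
      rows[[i]] <- data.frame(
        type = type, u = u, s = s,
        f = runif_range(1, spec$f),
        phi = stats::runif(1, 0, 2 * pi),
        amplitude = runif_range(1, spec$amplitude))
    }
    list(truth = do.call(rbind, rows), occupied = occupied)
  }

  occupied <- data.frame(start = numeric(), end = numeric())
  sp <- draw_events(spindles, "spindle", occupied)
  sw <- draw_events(slow_waves, "slow_wave", sp$occupied)
  truth <- rbind(sp$truth, sw$truth)
  if (!is.null(truth) && nrow(truth) > 0) {
    truth$start <- truth$u - truth$s / 2
    truth$end <- truth$u + truth$s / 2
    truth <- truth[order(truth$start),
                   c("type", "start", "end", "u", "s", "f", "phi",
                     "amplitude")]
    rownames(truth) <- NULL
    for (i in seq_len(nrow(truth))) {
      tw <- transient_wave(truth$u[i], truth$s[i], truth$f[i], truth$phi[i],
                           truth$amplitude[i], fs, n)
      signal[tw$idx] <- signal[tw$idx] + tw$w
    }
  } else {
    truth <- data.frame(type = character(), start = numeric(),
                        end = numeric(), u = numeric(), s = numeric(),
                        f = numeric(), phi = numeric(),
                        amplitude = numeric())
  }
  structure(list(signal = signal, fs = fs, duration = duration,
                 truth = truth),
            class = "eeg_sim")
}

#' @export
print.eeg_sim <- function(x, ...) {
  cat("Synthetic EEG: ", x$duration, " s @ ", x$fs, " Hz, ",
      nrow(x$truth), " implanted event(s)\n", sep = "")
  if (nrow(x$truth)) print(table(x$truth$type))
  invisible(x)
}

#' Write / read reference annotations (onset/duration CSV)
#'
#' The exchange format for expert or ground-truth annotations: columns
#' `onset_s`, `duration_s` and optionally `type`.
#'
#' @param truth A data frame with `start`/`end` (e.g. `eeg_sim$truth` or
#'   `eeg_events`), or already `onset_s`/`duration_s`.
#' @param path File path.
#' @return `path` (write); a data frame with `onset_s`, `duration_s`,
#'   `type` (read).
#' @export
write_annotations <- function(truth, path) {
  df <- if (all(c("onset_s", "duration_s") %in% names(truth))) {
    truth[, intersect(c("onset_s", "duration_s", "type"), names(truth))]
  } else {
    data.frame(onset_s = truth$start, duration_s = truth$end - truth$start,
               type = if ("type" %in% names(truth)) truth$type else "event")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("onset_s", "duration_s") %in% names(df))) {
    stop("annotation file needs columns onset_s, duration_s", call. = FALSE)
  }
  if (!"type" %in% names(df)) df$type <- "event"
  df
}
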