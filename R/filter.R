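# Selection of transients (spindles, slow waves, ...) from fitted atoms.

#' Criteria defining a class of EEG transients
#'
#' A transient class is defined by limits on the fitted atoms' frequency,
#' duration and peak-to-peak amplitude.  Duration is the Gaussian envelope
#' half-width `s` of the atom (time extent `u - s/2` to `u + s/2`),
#' optionally rescaled by `duration_factor`.
#'
#' @param f_min,f_max Frequency limits in Hz.
#' @param min_duration Minimal duration in seconds (applied to
#'   `duration_factor * s`).
#' @param max_duration Optional maximal duration in seconds.
#' @param min_amplitude Minimal peak-to-peak amplitude in signal units.
#' @param duration_factor Multiplier on the envelope half-width used as the
#'   event duration (default 1).
#' @param name Label carried into detected events.
#' @return A `structure_criteria` list.
#' @seealso [spindle_criteria()], [slow_wave_criteria()]
#' @export
structure_criteria <- function(f_min, f_max, min_duration,
                               max_duration = Inf, min_amplitude = 0,
                               duration_factor = 1, name = "transient") {
  if (!(f_min < f_max)) stop("need f_min < f_max", call. = FALSE)
  if (min_duration <= 0) stop("'min_duration' must be > 0", call. = FALSE)
  if (duration_factor <= 0) stop("'duration_factor' must be > 0",
                                 call. = FALSE)
  structure(list(f_min = f_min, f_max = f_max,
                 min_duration = min_duration, max_duration = max_duration,
                 min_amplitude = min_amplitude,
                 duration_factor = duration_factor, name = name),
            class = "structure_criteria")
}

#' @export
print.structure_criteria <- function(x, ...) {
  cat("Criteria '", x$name, "': ", x$f_min, "-", x$f_max, " Hz, duration ",
      x$min_duration, if (is.finite(x$max_duration)) {
        paste0("-", x$max_duration)
      } else "+", " s, amplitude >= ", signif(x$min_amplitude, 4),
      if (x$duration_factor != 1) {
        paste0(", duration factor ", x$duration_factor)
      } else "", "\n", sep = "")
  invisible(x)
}

#' Sleep-spindle selection criteria
#'
#' The classical definition: 11–16 Hz, duration over 0.5 s.  Variants:
#' slow spindles 11–13 Hz, fast spindles 13–16 Hz.  The minimal amplitude
#' is left at `min_amplitude` (usually filled in from
#' [amplitude_threshold()]).
#'
#' @inheritParams structure_criteria
#' @export
spindle_criteria <- function(min_amplitude = 0, f_min = 11, f_max = 16,
                             min_duration = 0.5, duration_factor = 1) {
  structure_criteria(f_min, f_max, min_duration,
                     min_amplitude = min_amplitude,
                     duration_factor = duration_factor, name = "spindle")
}

#' @rdname spindle_criteria
#' @export
slow_spindle_criteria <- function(min_amplitude = 0) {
  structure_criteria(11, 13, 0.5, min_amplitude = min_amplitude,
                     name = "slow_spindle")
}

#' @rdname spindle_criteria
#' @export
fast_spindle_criteria <- function(min_amplitude = 0) {
  structure_criteria(13, 16, 0.5, min_amplitude = min_amplitude,
                     name = "fast_spindle")
}

#' Slow-wave selection criteria
#'
#' High-amplitude low-frequency transients of deep sleep: amplitude above
#' 70 µV, frequency 0.2–4 Hz, duration above 0.5 s.
#'
#' @param min_amplitude Minimal peak-to-peak amplitude in µV.
#' @export
slow_wave_criteria <- function(min_amplitude = 70) {
  structure_criteria(0.2, 4, 0.5, min_amplitude = min_amplitude,
                     name = "slow_wave")
}

#' Peak-to-peak amplitudes of fitted atoms
#'
#' The peak-to-peak amplitude of a fitted atom is `2 * coeff * max|g|`,
#' twice the maximum of its scaled unit-norm waveform — the oscillation's
#' peak-to-peak at the envelope maximum.  For spindle-like atoms (several
#' cycles under the envelope) this agrees with max-minus-min of the
#' reconstruction to within a few percent.
#'
#' @param book An `mp_book`, or a data frame with columns `u`, `s`, `f`,
#'   `phi`, `coeff`.
#' @param fs Sampling rate (taken from the book when available).
#' @return Numeric vector of amplitudes, one per atom.
#' @export
atom_amplitude <- function(book, fs = NULL) {
  at <- if (inherits(book, "mp_book")) book$atoms else book
  if (inherits(book, "mp_book")) fs <- book$fs
  if (is.null(fs)) stop("'fs' required when passing a bare atom table",
                        call. = FALSE)
  n <- if (inherits(book, "mp_book")) book$n_samples else NULL
  vapply(seq_len(nrow(at)), function(i) {
    a <- at[i, ]
    if (a$coeff == 0) return(0)
    # synthesize on the atom's own support only
    h <- floor(4 * a$s * fs)
    nn <- 2L * h + 1L
    g <- gabor_waveform(h / fs, a$s, a$f, a$phi, fs, nn)
    2 * a$coeff * max(abs(g))
  }, numeric(1))
}

#' Select transient events from a book by explicit criteria
#'
#' Keeps atoms whose frequency lies in `[f_min, f_max]`, whose duration
#' `duration_factor * s` is within the duration limits, and whose
#' peak-to-peak amplitude reaches `min_amplitude`.  Kept atoms become
#' events on the recording timeline, spanning `u - d/2` to `u + d/2`
#' (with `d = duration_factor * s`) shifted by the book's `epoch_start`.
#'
#' @param book An `mp_book`, or a list of books (e.g. from
#'   [mp_decompose_recording()]).
#' @param criteria A [structure_criteria()] object.
#' @return A data frame of class `eeg_events` with columns `start`, `end`,
#'   `center`, `frequency`, `amplitude`, `duration`, `source_epoch`,
#'   `type`, sorted by `start`.
#' @export
filter_book <- function(book, criteria) {
  stopifnot(inherits(criteria, "structure_criteria"))
  if (inherits(book, "mp_book")) book <- list(book)
  evs <- lapply(seq_along(book), function(bi) {
    bk <- book[[bi]]
    at <- bk$atoms
    if (nrow(at) == 0) return(NULL)
    amp <- atom_amplitude(bk)
    dur <- criteria$duration_factor * at$s
    keep <- at$f >= criteria$f_min & at$f <= criteria$f_max &
      dur >= criteria$min_duration & dur <= criteria$max_duration &
      amp >= criteria$min_amplitude
    if (!any(keep)) return(NULL)
    center <- at$u[keep] + bk$epoch_start
    data.frame(start = center - dur[keep] / 2,
               end = center + dur[keep] / 2,
               center = center,
               frequency = at$f[keep],
               amplitude = amp[keep],
               duration = dur[keep],
               source_epoch = bi,
               type = criteria$name)
  })
  evs <- do.call(rbind, evs)
  if (is.null(evs)) {
    evs <- data.frame(start = numeric(), end = numeric(), center = numeric(),
                      frequency = numeric(), amplitude = numeric(),
                      duration = numeric(), source_epoch = integer(),
                      type = character())
  }
  evs <- evs[order(evs$start, evs$end), , drop = FALSE]
  rownames(evs) <- NULL
  class(evs) <- c("eeg_events", "data.frame")
  evs
}

#' Merge events separated by short gaps
#'
#' Optional post-processing: events of the same type whose gap is below
#' `max_gap` seconds are merged into one event (amplitude and frequency of
#' the larger-amplitude member are kept).
#'
#' @param events An `eeg_events` data frame.
#' @param max_gap Maximal gap in seconds (default 0.1).
#' @return Merged `eeg_events`.
#' @export
merge_events <- function(events, max_gap = 0.1) {
  if (nrow(events) < 2) return(events)
  events <- events[order(events$start), , drop = FALSE]
  out <- events[1, ]
  for (i in 2:nrow(events)) {
    ev <- events[i, ]
    last <- nrow(out)
    if (ev$start - out$end[last] < max_gap &&
        identical(ev$type, out$type[last])) {
      if (ev$amplitude > out$amplitude[last]) {
        out$amplitude[last] <- ev$amplitude
        out$frequency[last] <- ev$frequency
      }
      out$end[last] <- max(out$end[last], ev$end)
      out$center[last] <- (out$start[last] + out$end[last]) / 2
      out$duration[last] <- out$end[last] - out$start[last]
    } else {
      out <- rbind(out, ev)
    }
  }
  rownames(out) <- NULL
  class(out) <- c("eeg_events", "data.frame")
  out
}

#' @export
print.eeg_events <- function(x, ...) {
  cat(nrow(x), " detected event(s)", sep = "")
  if (nrow(x) > 0) {
    cat(" [", paste(unique(x$type), collapse = ", "), "], ",
        sprintf("%.1f-%.1f s, amplitudes %.1f-%.1f",
                min(x$start), max(x$end),
                min(x$amplitude), max(x$amplitude)), sep = "")
  }
  cat("\n")
  if (nrow(x) > 0) print.data.frame(utils::head(x, 10), digits = 4)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Detect sleep spindles in a recording
#'
#' The full pipeline: (1) the minimal spindle amplitude is computed from
#' the chosen percentile of the sigma-band windowed RMS distribution of the
#' whole supplied signal ([sigma_bandpass()], [rms_windows()],
#' [amplitude_threshold()]); (2) the recording is decomposed epoch by epoch
#' with [mp_decompose_recording()]; (3) atoms are filtered with the spindle
#' criteria (11–16 Hz, duration over 0.5 s, amplitude at or above the
#' threshold).
#'
#' @inheritParams mp_decompose_recording
#' @param percentile RMS percentile defining the amplitude threshold (the
#'   detector's single free parameter; 97 was the typical optimum on
#'   overnight polysomnography).
#' @param criteria Base criteria; its `min_amplitude` is replaced by the
#'   RMS-derived threshold.
#' @param books Optional precomputed decomposition (skips step 2).
#' @param merge_gap If non-`NULL`, events closer than this gap (seconds)
#'   are merged ([merge_events()]).
#' @return `eeg_events` sorted by start, with the threshold, percentile and
#'   books attached as attributes `"threshold"`, `"percentile"`, `"books"`.
#' @export
detect_spindles <- function(signal, fs, epsilon = 0.04, M = 50,
                            percentile = 97, epoch_length = 20,
                            criteria = spindle_criteria(),
                            scale_range = NULL, books = NULL,
                            merge_gap = NULL, verbose = FALSE) {
  filt <- sigma_bandpass(signal, fs, criteria$f_min, criteria$f_max)
  dist <- rms_windows(filt, fs, band = c(criteria$f_min, criteria$f_max))
  thr <- amplitude_threshold(dist, percentile)
  if (is.null(books)) {
    books <- mp_decompose_recording(signal, fs, epoch_length = epoch_length,
                                    M = M, epsilon = epsilon,
                                    scale_range = scale_range,
                                    verbose = verbose)
  }
  criteria$min_amplitude <- thr
  ev <- filter_book(books, criteria)
  if (!is.null(merge_gap)) ev <- merge_events(ev, merge_gap)
  attr(ev, "threshold") <- thr
  attr(ev, "percentile") <- percentile
  attr(ev, "books") <- books
  ev
}

#' Detect transients with fixed criteria (e.g. slow waves)
#'
#' Decomposes the recording (or reuses `books`) and filters atoms with the
#' given criteria as-is; no RMS thresholding is applied, so
#' `criteria$min_amplitude` is used directly (e.g. the 70 µV slow-wave
#' limit).
#'
#' @inheritParams detect_spindles
#' @export
detect_transients <- function(signal, fs, criteria, epsilon = 0.04, M = 50,
                              epoch_length = 20, scale_range = NULL,
                              books = NULL, merge_gap = NULL,
                              verbose = FALSE) {
  if (is.null(books)) {
    books <- mp_decompose_recording(signal, fs, epoch_length = epoch_length,
                                    M = M, epsilon = epsilon,
                                    scale_range = scale_range,
                                    verbose = verbose)
  }
  ev <- filter_book(books, criteria)
  if (!is.null(merge_gap)) ev <- merge_events(ev, merge_gap)
  attr(ev, "books") <- books
  ev
}

#' Convert events to a per-sample boolean mask
#'
#' Sample `i` (0-based time `i/fs`) is `TRUE` iff it falls inside any
#' event's half-open interval `[start, end)`.
#'
#' @param events `eeg_events` (or any data frame with `start`/`end` in
#'   seconds).
#' @param fs Sampling rate in Hz.
#' @param n_samples Mask length.
#' @return Logical vector of length `n_samples`.
#' @export
events_to_mask <- function(events, fs, n_samples) {
  mask <- logical(n_samples)
  if (nrow(events) == 0) return(mask)
  if (any(events$start < 0) || any(events$end > n_samples / fs + 1e-9)) {
    stop("event interval outside [0, ", n_samples / fs, "] s", call. = FALSE)
  }
  for (i in seq_len(nrow(events))) {
    lo <- ceiling(events$start[i] * fs - 1e-9) + 1L     # first sample >= start
    hi <- ceiling(events$end[i] * fs - 1e-9)            # last sample < end
    if (hi >= lo) mask[lo:min(hi, n_samples)] <- TRUE
  }
  mask
}

#' Write / read detected events as CSV
#'
#' Columns `start_s,end_s,center_s,freq_hz,amp_uV,type`.  A companion
#' annotation-style export (`onset_s,duration_s,type`) is produced by
#' [write_annotations()].
#'
#' @param events `eeg_events`.
#' @param path File path.
#' @return `path` (write) / `eeg_events` (read).
#' @export
write_events <- function(events, path) {
  df <- data.frame(start_s = events$start, end_s = events$end,
                   center_s = events$center, freq_hz = events$frequency,
                   amp_uV = events$amplitude, type = events$type)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  ev <- data.frame(start = df$start_s, end = df$end_s, center = df$center_s,
                   frequency = df$freq_hz, amplitude = df$amp_uV,
                   duration = df$end_s - df$start_s,
                   source_epoch = NA_integer_,
                   type = if ("type" %in% names(df)) df$type else "event")
  class(ev) <- c("eeg_events", "data.frame")
  ev
}
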