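# Sample-resolution scoring against reference annotations, and the
# cross-validated selection of the RMS percentile.

#' Per-sample confusion counts between detector and reference masks
#'
#' At every signal sample there are four outcomes: event present in both
#' (TP), in neither (TN), only in the reference (FN), only in the detector
#' (FP).
#'
#' @param detected,reference Equal-length logical vectors (per-sample
#'   masks).
#' @return A `confusion_counts` list: `TP`, `TN`, `FP`, `FN` plus the
#'   marginals `P = TP+FN`, `Pp = TP+FP`, `N = FP+TN`, `Np = FN+TN`.
#' @export
confusion_counts <- function(detected, reference) {
  if (length(detected) != length(reference)) {
    stop("mask lengths differ (", length(detected), " vs ",
         length(reference), ")", call. = FALSE)
  }
  d <- as.logical(detected)
  r <- as.logical(reference)
  tp <- sum(d & r)
  fp <- sum(d & !r)
  fn <- sum(!d & r)
  tn <- length(d) - tp - fp - fn
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 P = tp + fn, Pp = tp + fp, N = fp + tn, Np = fn + tn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("TP =", x$TP, " FP =", x$FP, " FN =", x$FN, " TN =", x$TN, "\n")
  invisible(x)
}

#' Detector performance measures from confusion counts
#'
#' Computes sensitivity `TP/(TP+FN)`, positive predictive value
#' `TP/(FP+TP)`, Matthews correlation
#' \eqn{(TP\,TN - FP\,FN)/\sqrt{P P' N N'}}, Cohen's
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with observed agreement
#' \eqn{p_o = (TP+TN)/(P+N)} and chance agreement
#' \eqn{p_e = (P'P + N'N)/(P+N)^2}, and the F1 score
#' `2*PPV*sens/(PPV+sens)`.
#'
#' Any measure with a zero denominator is reported as `NA` (undefined, not
#' zero) and listed in the `undefined` attribute.
#'
#' @param counts A [confusion_counts()] object, or a list/vector with
#'   elements `TP`, `TN`, `FP`, `FN`.
#' @return A named numeric vector of class `detector_metrics` with elements
#'   `sensitivity`, `ppv`, `mcc`, `kappa`, `f1`.
#' @export
compute_metrics <- function(counts) {
  cn <- as.list(counts)
  tp <- as.numeric(cn$TP); tn <- as.numeric(cn$TN)
  fp <- as.numeric(cn$FP); fn <- as.numeric(cn$FN)
  P <- tp + fn; Pp <- tp + fp; N <- fp + tn; Np <- fn + tn
  total <- P + N
  sens <- if (P > 0) tp / P else NA_real_
  ppv <- if (Pp > 0) tp / Pp else NA_real_
  mcc <- {
    den <- P * Pp * N * Np
    if (den > 0) (tp * tn - fp * fn) / sqrt(den) else NA_real_
  }
  kappa <- if (total > 0) {
    pe <- (Pp * P + Np * N) / total^2
    if (pe < 1) ((tp + tn) / total - pe) / (1 - pe) else NA_real_
  } else NA_real_
  f1 <- if (!is.na(sens) && !is.na(ppv) && (sens + ppv) > 0) {
    2 * ppv * sens / (ppv + sens)
  } else NA_real_
  out <- c(sensitivity = sens, ppv = ppv, mcc = mcc, kappa = kappa, f1 = f1)
  attr(out, "undefined") <- names(out)[is.na(out)]
  class(out) <- "detector_metrics"
  out
}

#' @export
print.detector_metrics <- function(x, ...) {
  v <- unclass(x); attributes(v) <- list(names = names(x))
  print(round(v, 4))
  und <- attr(x, "undefined")
  if (length(und)) cat("undefined (zero denominator):",
                       paste(und, collapse = ", "), "\n")
  invisible(x)
}

#' Prepare a recording for threshold sweeps
#'
#' The expensive parts of spindle detection — the MP decomposition and the
#' RMS distribution — do not depend on the percentile.  This helper
#' computes them once so that any number of percentile evaluations stays
#' cheap: per percentile only the amplitude filter, mask conversion and
#' confusion counting are redone.
#'
#' @inheritParams detect_spindles
#' @param reference Reference annotations: a logical per-sample mask, or a
#'   data frame with `start`/`end` (or `onset_s`/`duration_s`) in seconds.
#' @return An object of class `spindle_prep` for [eval_at_percentile()],
#'   [optimal_percentile()] and [cross_validate()].
#' @export
prepare_recording <- function(signal, fs, reference, epsilon = 0.04, M = 50,
                              epoch_length = 20,
                              criteria = spindle_criteria(),
                              scale_range = NULL, verbose = FALSE) {
  n <- length(signal)
  ref_mask <- if (is.logical(reference)) {
    stopifnot(length(reference) == n)
    reference
  } else {
    events_to_mask(as_event_intervals(reference), fs, n)
  }
  filt <- sigma_bandpass(signal, fs, criteria$f_min, criteria$f_max)
  dist <- rms_windows(filt, fs, band = c(criteria$f_min, criteria$f_max))
  books <- mp_decompose_recording(signal, fs, epoch_length = epoch_length,
                                  M = M, epsilon = epsilon,
                                  scale_range = scale_range,
                                  verbose = verbose)
  crit0 <- criteria
  crit0$min_amplitude <- 0
  candidates <- filter_book(books, crit0)     # amplitude filtered later
  structure(list(fs = fs, n_samples = n, rms = dist, books = books,
                 candidates = candidates, ref_mask = ref_mask,
                 criteria = criteria),
            class = "spindle_prep")
}

as_event_intervals <- function(reference) {
  if (all(c("start", "end") %in% names(reference))) {
    data.frame(start = reference$start, end = reference$end)
  } else if (all(c("onset_s", "duration_s") %in% names(reference))) {
    data.frame(start = reference$onset_s,
               end = reference$onset_s + reference$duration_s)
  } else {
    stop("reference needs columns start/end or onset_s/duration_s",
         call. = FALSE)
  }
}

#' Evaluate a prepared recording at one percentile
#'
#' @param prep A [prepare_recording()] object.
#' @param percentile RMS percentile in `[0, 100]`.
#' @return [compute_metrics()] result, with the amplitude threshold as
#'   attribute `"threshold"`.
#' @export
eval_at_percentile <- function(prep, percentile) {
  stopifnot(inherits(prep, "spindle_prep"))
  thr <- amplitude_threshold(prep$rms, percentile)
  ev <- prep$candidates[prep$candidates$amplitude >= thr, , drop = FALSE]
  det <- events_to_mask(ev, prep$fs, prep$n_samples)
  m <- compute_metrics(confusion_counts(det, prep$ref_mask))
  attr(m, "threshold") <- thr
  m
}

prep_list <- function(recordings, ...) {
  lapply(recordings, function(r) {
    if (inherits(r, "spindle_prep")) r
    else prepare_recording(r$signal, r$fs, r$reference, ...)
  })
}

#' Percentile maximizing the mean Matthews correlation
#'
#' Exhaustively evaluates every percentile of `grid` on every recording and
#' returns the one maximizing the mean MCC (ties towards the lowest
#' percentile).  Undefined MCC values are excluded from the mean.
#'
#' @param recordings A list of [prepare_recording()] objects, or of lists
#'   `list(signal=, fs=, reference=)` (prepared on the fly with `...`).
#' @param grid Percentile grid; default 90 to 99.5 in steps of 0.5.
#' @param ... Passed to [prepare_recording()] when needed.
#' @return The optimal percentile, with the full `grid x recording` MCC
#'   matrix attached as attribute `"mcc"`.
#' @export
optimal_percentile <- function(recordings, grid = seq(90, 99.5, by = 0.5),
                               ...) {
  if (length(grid) == 0) stop("empty percentile grid", call. = FALSE)
  preps <- prep_list(recordings, ...)
  mcc <- vapply(preps, function(p) {
    vapply(grid, function(pc) eval_at_percentile(p, pc)[["mcc"]],
           numeric(1))
  }, numeric(length(grid)))
  mcc <- matrix(mcc, nrow = length(grid))
  mean_mcc <- rowMeans(mcc, na.rm = TRUE)
  best <- grid[which.max(mean_mcc)]           # which.max: lowest on ties
  attr(best, "mcc") <- mcc
  attr(best, "mean_mcc") <- mean_mcc
  best
}

#' Cross-validated performance of the percentile-thresholded detector
#'
#' Repeats `n_iter` times: draw a random training subset of `n_train`
#' recordings (uniform, without replacement, disjoint from the validation
#' set); compute each training recording's individually optimal percentile
#' (maximal MCC on `grid`); average those percentiles arithmetically; apply
#' the averaged percentile to every validation recording; average the
#' validation metrics.  Undefined metrics are excluded from averages and
#' counted.
#'
#' @inheritParams optimal_percentile
#' @param n_iter Number of random splits.
#' @param n_train Training-set size (must leave at least one validation
#'   recording).
#' @param seed Integer seed; the split sequence is fully reproducible.
#' @return An object of class `spindle_cv`: per-iteration table
#'   (`percentile`, `sensitivity`, `ppv`, `mcc`, `kappa`, `f1`), summary
#'   statistics (median, quartiles, mean, SD), the mean selected
#'   percentile, and the per-recording optimal percentiles.
#' @export
cross_validate <- function(recordings, n_iter = 100, n_train = 14,
                           grid = seq(90, 99.5, by = 0.5), seed = NULL,
                           ...) {
  preps <- prep_list(recordings, ...)
  nrec <- length(preps)
  if (n_train >= nrec) {
    stop("'n_train' (", n_train, ") must be smaller than the number of ",
         "recordings (", nrec, ")", call. = FALSE)
  }
  # percentile -> MCC curves are split-independent: compute once
  curves <- lapply(preps, function(p) {
    vapply(grid, function(pc) eval_at_percentile(p, pc)[["mcc"]], numeric(1))
  })
  rec_opt <- vapply(curves, function(cv) grid[which.max(cv)], numeric(1))

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(seed)
  }
  metric_names <- c("sensitivity", "ppv", "mcc", "kappa", "f1")
  res <- matrix(NA_real_, n_iter, 1 + length(metric_names),
                dimnames = list(NULL, c("percentile", metric_names)))
  n_undefined <- 0L
  for (it in seq_len(n_iter)) {
    train <- sample.int(nrec, n_train)
    valid <- setdiff(seq_len(nrec), train)
    stopifnot(length(intersect(train, valid)) == 0)
    p_bar <- mean(rec_opt[train])
    vm <- vapply(valid, function(i) {
      unclass(eval_at_percentile(preps[[i]], p_bar))[metric_names]
    }, numeric(length(metric_names)))
    vm <- matrix(vm, nrow = length(metric_names))
    n_undefined <- n_undefined + sum(is.na(vm))
    res[it, ] <- c(p_bar, rowMeans(vm, na.rm = TRUE))
  }
  summ <- apply(res[, metric_names, drop = FALSE], 2, function(v) {
    c(median = stats::median(v, na.rm = TRUE),
      q1 = unname(stats::quantile(v, 0.25, na.rm = TRUE)),
      q3 = unname(stats::quantile(v, 0.75, na.rm = TRUE)),
      mean = mean(v, na.rm = TRUE),
      sd = stats::sd(v, na.rm = TRUE))
  })
  structure(list(iterations = as.data.frame(res), summary = summ,
                 mean_percentile = mean(res[, "percentile"]),
                 recording_optima = rec_opt, grid = grid,
                 n_undefined = n_undefined,
                 n_iter = n_iter, n_train = n_train),
            class = "spindle_cv")
}

#' @export
print.spindle_cv <- function(x, ...) {
  cat("Cross-validated spindle detection (", x$n_iter, " iterations, ",
      x$n_train, " training recordings)\n", sep = "")
  cat(sprintf("  mean selected percentile: %.2f\n", x$mean_percentile))
  cat("  per-recording optima:",
      paste(x$recording_optima, collapse = ", "), "\n")
  print(round(t(x$summary), 3))
  if (x$n_undefined > 0) {
    cat("  (", x$n_undefined,
        " undefined metric value(s) excluded from averages)\n", sep = "")
  }
  invisible(x)
}
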