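# Per-epoch EEG profiles: event counts and time occupancy.

# union of possibly overlapping [start, end) intervals
union_intervals <- function(start, end) {
  if (length(start) == 0) {
    return(data.frame(start = numeric(), end = numeric()))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  us <- start[1]; ue <- end[1]
  outs <- numeric(); oute <- numeric()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ue) {
      ue <- max(ue, end[i])
    } else {
      outs <- c(outs, us); oute <- c(oute, ue)
      us <- start[i]; ue <- end[i]
    }
  }
  data.frame(start = c(outs, us), end = c(oute, ue))
}

#' Per-epoch profile of detected transients
#'
#' For consecutive epochs (20 s by default) reports the number of events
#' whose time centre falls in the epoch and the percentage of the epoch's
#' time covered by the union of event intervals (events crossing an epoch
#' border contribute their clipped portions to each side; overlapping
#' events are unioned before measuring occupancy).
#'
#' @param events `eeg_events` (or a data frame with `start`, `end`,
#'   `center` in seconds).
#' @param record_duration Total recording duration in seconds.
#' @param epoch_length Epoch length in seconds.
#' @return A data frame of class `eeg_profile`: `epoch_index`, `t_start_s`,
#'   `count`, `occupancy_pct`.  A trailing partial epoch is measured
#'   against its actual (shorter) duration.
#' @export
build_profile <- function(events, record_duration, epoch_length = 20) {
  if (epoch_length <= 0) stop("'epoch_length' must be > 0", call. = FALSE)
  n_ep <- ceiling(record_duration / epoch_length)
  t0 <- (seq_len(n_ep) - 1) * epoch_length
  t1 <- pmin(t0 + epoch_length, record_duration)
  uni <- union_intervals(events$start, events$end)
  count <- integer(n_ep)
  occ <- numeric(n_ep)
  if (nrow(events) > 0) {
    ctr <- events$center
    idx <- pmin(pmax(floor(ctr / epoch_length), 0), n_ep - 1) + 1L
    tab <- table(idx)
    count[as.integer(names(tab))] <- as.integer(tab)
  }
  for (e in seq_len(n_ep)) {
    cov <- pmin(uni$end, t1[e]) - pmax(uni$start, t0[e])
    occ[e] <- 100 * sum(pmax(cov, 0)) / (t1[e] - t0[e])
  }
  out <- data.frame(epoch_index = seq_len(n_ep), t_start_s = t0,
                    count = count, occupancy_pct = occ)
  class(out) <- c("eeg_profile", "data.frame")
  out
}

#' Band labels for epoch occupancy values
#'
#' Classifies each epoch's occupancy into `"below"`, `"20-50"` or
#' `"above"` bands (defaults follow the classical slow-wave ranges that
#' define deep-sleep stages: 20–50 % and 50–100 % of the epoch).  This is a
#' pure banding of the occupancy number, not a sleep stager.  Boundaries
#' are assigned upward: exactly `low_pct` falls into the middle band,
#' exactly `high_pct` into the upper one.
#'
#' @param profiles An [build_profile()] result, or a numeric vector of
#'   occupancy percentages.
#' @param low_pct,high_pct Band edges in percent, `0 <= low < high <= 100`.
#' @return Character vector of band labels, one per epoch.
#' @export
stage_band_flags <- function(profiles, low_pct = 20, high_pct = 50) {
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100)) {
    stop("need 0 <= low_pct < high_pct <= 100", call. = FALSE)
  }
  occ <- if (is.data.frame(profiles)) profiles$occupancy_pct else profiles
  mid_label <- paste0(low_pct, "-", high_pct)
  ifelse(occ >= high_pct, "above", ifelse(occ >= low_pct, mid_label,
                                          "below"))
}

#' Write a per-epoch profile as CSV
#'
#' @param profile An [build_profile()] result.
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
plot.eeg_profile <- function(x, events = NULL, ...) {
  old <- graphics::par(mfrow = c(if (is.null(events)) 2 else 3, 1),
                       mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(old))
  if (!is.null(events)) {
    graphics::plot(events$center, events$amplitude, type = "h",
                   col = "firebrick", xlab = "time [s]",
                   ylab = "amplitude", main = "events")
  }
  graphics::plot(x$t_start_s, x$count, type = "h", col = "forestgreen",
                 xlab = "time [s]", ylab = "count / epoch")
  graphics::plot(x$t_start_s, x$occupancy_pct, type = "h", col = "cyan4",
                 xlab = "time [s]", ylab = "occupancy [%]")
  graphics::abline(h = c(20, 50), lty = 3, col = "grey50")
  invisible(x)
}
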