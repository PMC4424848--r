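# Signal input/output: minimal EDF (continuous 16-bit) and plain-text
# column files.  No EDF reader exists in the R dependency stack used here,
# so the small subset of the format needed for single/multi-channel
# continuous recordings is implemented directly from the format
# definition (256-byte fixed-width ASCII headers, little-endian int16
# data records, linear digital-to-physical scaling).

read_edf_header <- function(con) {
  fld <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  hdr <- list(version = fld(8), patient = fld(80), recording = fld(80),
              startdate = fld(8), starttime = fld(8),
              header_bytes = as.integer(fld(8)), reserved = fld(44),
              n_records = as.integer(fld(8)),
              record_duration = as.numeric(fld(8)),
              n_signals = as.integer(fld(4)))
  ns <- hdr$n_signals
  sf <- function(nc) vapply(seq_len(ns), function(i) fld(nc), character(1))
  hdr$label <- sf(16); hdr$transducer <- sf(80); hdr$phys_dim <- sf(8)
  hdr$phys_min <- as.numeric(sf(8)); hdr$phys_max <- as.numeric(sf(8))
  hdr$dig_min <- as.numeric(sf(8)); hdr$dig_max <- as.numeric(sf(8))
  hdr$prefilter <- sf(80)
  hdr$samples_per_record <- as.integer(sf(8))
  hdr$sig_reserved <- sf(32)
  hdr
}

#' Read a channel from an EDF file
#'
#' Supports plain continuous EDF (and EDF+C) with 16-bit samples; the
#' annotations channel of EDF+ files is not parsed.
#'
#' @param path Path to the `.edf` file.
#' @param channel Channel label (e.g. `"C3"`; matched against the signal
#'   labels, ignoring reference suffixes like `"EEG C3-LER"`) or 1-based
#'   index.
#' @return A list with `signal` (numeric, physical units), `fs` (Hz),
#'   `label`, `unit`, and the parsed `header`.
#' @export
read_edf <- function(path, channel = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_edf_header(con)
  ns <- hdr$n_signals
  if (is.character(channel)) {
    hit <- which(hdr$label == channel)
    if (length(hit) == 0) {
      hit <- grep(channel, hdr$label, fixed = TRUE)
    }
    if (length(hit) == 0) {
      stop("channel '", channel, "' not found; available: ",
           paste(hdr$label, collapse = ", "), call. = FALSE)
    }
    channel <- hit[1]
  }
  if (channel < 1 || channel > ns) {
    stop("channel index out of range 1..", ns, call. = FALSE)
  }
  spr <- hdr$samples_per_record
  rec_len <- sum(spr)
  out <- integer(hdr$n_records * spr[channel])
  offset <- c(0, cumsum(spr))[channel]
  for (r in seq_len(hdr$n_records)) {
    rec <- readBin(con, "integer", n = rec_len, size = 2, signed = TRUE,
                   endian = "little")
    out[((r - 1) * spr[channel] + 1):(r * spr[channel])] <-
      rec[(offset + 1):(offset + spr[channel])]
  }
  gain <- (hdr$phys_max[channel] - hdr$phys_min[channel]) /
    (hdr$dig_max[channel] - hdr$dig_min[channel])
  phys <- hdr$phys_min[channel] + (out - hdr$dig_min[channel]) * gain
  list(signal = phys, fs = spr[channel] / hdr$record_duration,
       label = hdr$label[channel], unit = hdr$phys_dim[channel],
       header = hdr)
}

#' Write one or more channels to a minimal EDF file
#'
#' Continuous EDF with 1-s data records and 16-bit quantization over each
#' channel's observed range.  Intended for exporting synthetic or processed
#' signals; quantization error is bounded by the physical range divided by
#' 2^16.
#'
#' @param signals Numeric vector or named list of equal-length vectors.
#' @param fs Sampling rate in Hz (integer samples per 1-s record).
#' @param path Output path.
#' @param labels Channel labels (defaults to list names or `"EEG1"`, ...).
#' @param unit Physical dimension string (default `"uV"`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs, path, labels = NULL, unit = "uV") {
  if (is.numeric(signals)) signals <- list(signals)
  ns <- length(signals)
  if (is.null(labels)) {
    labels <- if (!is.null(names(signals)) && all(nzchar(names(signals)))) {
      names(signals)
    } else paste0("EEG", seq_len(ns))
  }
  spr <- as.integer(round(fs))
  n_records <- length(signals[[1]]) %/% spr
  if (n_records < 1) stop("signal shorter than one 1-s record",
                          call. = FALSE)
  phys_min <- vapply(signals, function(x) min(x, -1e-6), numeric(1))
  phys_max <- vapply(signals, function(x) max(x, 1e-6), numeric(1))
  dig <- lapply(seq_len(ns), function(i) {
    x <- signals[[i]][seq_len(n_records * spr)]
    as.integer(round(-32768 + (x - phys_min[i]) * 65535 /
                       (phys_max[i] - phys_min[i])))
  })
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, nc) {
    s <- formatC(as.character(x), width = -nc)
    writeChar(paste0(substr(s, 1, nc),
                     strrep(" ", pmax(0, nc - nchar(s)))),
              con, eos = NULL, useBytes = TRUE)
  }
  put("0", 8); put("synthetic", 80); put("synthetic", 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(256 * (1 + ns), 8); put("", 44)
  put(n_records, 8); put("1", 8); put(ns, 4)
  for (l in labels) put(l, 16)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put(unit, 8)
  for (v in formatC(phys_min, format = "g", digits = 6)) put(v, 8)
  for (v in formatC(phys_max, format = "g", digits = 6)) put(v, 8)
  for (i in seq_len(ns)) put("-32768", 8)
  for (i in seq_len(ns)) put("32767", 8)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put(spr, 8)
  for (i in seq_len(ns)) put("", 32)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      writeBin(dig[[i]][((r - 1) * spr + 1):(r * spr)], con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read / write a single-column signal file
#'
#' Plain-text numeric column with a `# fs = <Hz>` header line.
#'
#' @param path File path.
#' @param signal Numeric vector.
#' @param fs Sampling rate in Hz.
#' @return Read: list with `signal` and `fs`.  Write: `path`, invisibly.
#' @export
read_signal_csv <- function(path) {
  first <- readLines(path, n = 1)
  fs <- NA_real_
  m <- regmatches(first, regexec("^#\\s*fs\\s*=\\s*([0-9.]+)", first))[[1]]
  if (length(m) == 2) fs <- as.numeric(m[2])
  x <- utils::read.csv(path, comment.char = "#", header = FALSE)[[1]]
  list(signal = as.numeric(x), fs = fs)
}

#' @rdname read_signal_csv
#' @export
write_signal_csv <- function(signal, fs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs = %g", fs), con)
  writeLines(sprintf("%.10g", signal), con)
  invisible(path)
}
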