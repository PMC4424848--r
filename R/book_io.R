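# Plain-text book format: '#'-prefixed header lines carrying the epoch
# metadata, then a CSV table with one atom per row.

#' Write a matching-pursuit book to a plain-text file
#'
#' One atom per CSV row (`iteration,u,s,f,phi,coeff,energy`), preceded by
#' `#`-prefixed header lines with `fs`, `epoch_start`, `epoch_length`,
#' `signal_energy`, `residual_energy`, `epsilon` and `M`.  Numbers are
#' written with full double precision so a round trip is lossless.
#'
#' @param book An `mp_book`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_book <- function(book, path) {
  stopifnot(inherits(book, "mp_book"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  hdr <- c(fs = book$fs, epoch_start = book$epoch_start,
           epoch_length = book$epoch_length,
           signal_energy = book$signal_energy,
           residual_energy = book$residual_energy,
           epsilon = book$epsilon, M = book$M)
  writeLines(sprintf("# %s = %.17g", names(hdr), hdr), con)
  writeLines("iteration,u,s,f,phi,coeff,energy", con)
  if (nrow(book$atoms) > 0) {
    writeLines(sprintf("%d,%.17g,%.17g,%.17g,%.17g,%.17g,%.17g",
                       book$atoms$iteration, book$atoms$u, book$atoms$s,
                       book$atoms$f, book$atoms$phi, book$atoms$coeff,
                       book$atoms$energy), con)
  }
  invisible(path)
}

#' Read a matching-pursuit book written by [write_book()]
#'
#' @param path File path.
#' @return An `mp_book` (without the raw signal/residual vectors, which are
#'   not part of the file format; `n_samples` is recovered from the header).
#' @export
read_book <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_hdr <- grepl("^#", lines)
  hdr <- list()
  for (ln in lines[is_hdr]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)", ln))[[1]]
    if (length(m) == 3) hdr[[m[2]]] <- as.numeric(m[3])
  }
  need <- c("fs", "epoch_start", "epoch_length", "signal_energy",
            "residual_energy")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) {
    stop("book file ", path, " is missing header field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  body <- lines[!is_hdr]
  body <- body[nzchar(trimws(body))]
  cols <- c("iteration", "u", "s", "f", "phi", "coeff", "energy")
  if (length(body) == 0 ||
      !identical(trimws(strsplit(body[1], ",")[[1]]), cols)) {
    stop("malformed book file ", path, ": expected column header '",
         paste(cols, collapse = ","), "' at line ",
         which(!is_hdr)[1], call. = FALSE)
  }
  rows <- body[-1]
  if (length(rows)) {
    parsed <- strsplit(rows, ",", fixed = TRUE)
    bad <- which(lengths(parsed) != 7L)
    if (length(bad)) {
      stop("malformed book file ", path, ": wrong field count at line ",
           which(!is_hdr)[bad[1] + 1L], call. = FALSE)
    }
    vals <- suppressWarnings(
      matrix(as.numeric(unlist(parsed)), ncol = 7, byrow = TRUE))
    if (anyNA(vals)) {
      bad <- which(apply(is.na(vals), 1, any))[1]
      stop("malformed book file ", path, ": non-numeric field at line ",
           which(!is_hdr)[bad + 1L], call. = FALSE)
    }
    atoms <- as.data.frame(vals)
    names(atoms) <- cols
    atoms$iteration <- as.integer(atoms$iteration)
  } else {
    atoms <- data.frame(iteration = integer(), u = numeric(), s = numeric(),
                        f = numeric(), phi = numeric(), coeff = numeric(),
                        energy = numeric())
  }
  structure(
    list(atoms = atoms, fs = hdr$fs, epoch_start = hdr$epoch_start,
         epoch_length = hdr$epoch_length,
         signal_energy = hdr$signal_energy,
         residual_energy = hdr$residual_energy,
         epsilon = if (is.null(hdr$epsilon)) NA_real_ else hdr$epsilon,
         M = if (is.null(hdr$M)) nrow(atoms) else hdr$M,
         n_samples = round(hdr$epoch_length * hdr$fs),
         signal = NULL, residual = NULL),
    class = "mp_book"
  )
}
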