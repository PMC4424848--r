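# Matching pursuit over the Gabor dictionary.
#
# Per scale, inner products of the residual with every (u, f) grid point are
# obtained from short-time FFTs of the envelope-windowed residual (one mvfft
# per scale and iteration).  Phase is not gridded: at each grid point the
# residual is projected onto the two-dimensional span of the quadrature
# atoms E*cos(w(t-u)) and E*sin(w(t-u)), which gives the energy captured by
# the best single real Gabor with free phase in closed form,
#   E = p' G^-1 p,   p = (<x,Ecos>, <x,Esin>),  G = Gram of (Ecos, Esin).
# The Gram entries come from the FFT of the squared envelope at the doubled
# frequency, so edge-clipped windows are handled exactly.

scale_cache <- function(dictionary, i) {
  key <- paste0("s", i)
  cache <- dictionary$cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  fs <- dictionary$fs
  n <- dictionary$n_samples
  row <- dictionary$scales[i, ]
  s <- row$s
  h <- row$half_support
  L <- 2L * h + 1L
  nfft <- row$nfft
  du_samp <- max(1L, as.integer(round(row$du * fs)))
  us <- seq.int(0L, n - 1L, by = du_samp)        # 0-based centre samples
  ncol <- length(us)
  m <- seq.int(-h, h)
  E <- exp(-pi * (m / (s * fs))^2)

  # gather indices into c(0, x): out-of-epoch samples read the leading zero
  pos <- outer(m, us, "+")                       # 0-based sample positions
  idx1 <- pos + 2L
  idx1[pos < 0L | pos >= n] <- 1L
  storage.mode(idx1) <- "integer"

  kmax <- nfft %/% 2L
  k <- seq.int(0L, kmax - 1L)
  tw <- exp(2i * pi * ((k * h) %% nfft) / nfft)       # window-start phase
  tw2 <- exp(2i * pi * ((2 * k * h) %% nfft) / nfft)
  bin2 <- (2L * k) %% nfft + 1L

  gram_of <- function(e2) {
    # e2: squared (possibly edge-masked) envelope, length L
    w0 <- sum(e2)
    f2 <- stats::fft(c(e2, numeric(nfft - L)))
    w2 <- f2[bin2] * tw2
    c11 <- (w0 + Re(w2)) / 2
    c22 <- (w0 - Re(w2)) / 2
    c12 <- -Im(w2) / 2
    det <- c11 * c22 - c12^2
    list(c11 = c11, c22 = c22, c12 = c12, det = det,
         dtol = 1e-10 * w0^2)
  }

  edge <- which(us < h | us > n - 1L - h)
  interior <- if (length(edge) < ncol) gram_of(E^2) else NULL
  egram <- lapply(edge, function(j) {
    mask <- pos[, j] >= 0L & pos[, j] < n
    gram_of(E^2 * mask)
  })

  out <- list(s = s, h = h, L = L, nfft = nfft, kmax = kmax,
              us = us, ncol = ncol, E = E, idx1 = idx1, tw = tw,
              edge = edge, interior = interior, egram = egram)
  cache[[key]] <- out
  out
}

# energy captured at every (f, u) grid point of one scale, plus the raw
# quadrature inner products needed to recover phase
scan_scale <- function(x0, sc) {
  X <- matrix(x0[sc$idx1], sc$L, sc$ncol) * sc$E
  Xp <- matrix(0, sc$nfft, sc$ncol)
  Xp[seq_len(sc$L), ] <- X
  Z <- stats::mvfft(Xp)[seq_len(sc$kmax), , drop = FALSE] * sc$tw
  A <- Re(Z)
  B <- -Im(Z)
  quad_energy <- function(A, B, g) {
    en <- (g$c22 * A * A - 2 * g$c12 * A * B + g$c11 * B * B) / g$det
    bad <- g$det <= g$dtol
    if (any(bad)) {
      if (is.matrix(A)) {
        en[bad, ] <- (A * A / pmax(g$c11, 1e-300))[bad, ]
      } else {
        en[bad] <- (A * A / pmax(g$c11, 1e-300))[bad]
      }
    }
    en
  }
  if (!is.null(sc$interior)) {
    En <- quad_energy(A, B, sc$interior)     # Gram vectors recycle by row
  } else {
    En <- matrix(0, sc$kmax, sc$ncol)
  }
  for (ei in seq_along(sc$edge)) {
    j <- sc$edge[ei]
    En[, j] <- quad_energy(A[, j], B[, j], sc$egram[[ei]])
  }
  list(En = En, A = A, B = B)
}

# recover the optimal phase at a chosen grid point
optimal_phase <- function(a, b, g, kbin) {
  if (g$det[kbin] <= g$dtol || kbin == 1L) {
    return(if (a >= 0) 0 else pi)
  }
  d <- g$det[kbin]
  v1 <- (g$c22[kbin] * a - g$c12[kbin] * b) / d
  v2 <- (-g$c12[kbin] * a + g$c11[kbin] * b) / d
  atan2(-v2, v1)
}

#' Find the dictionary atom best matching a residual
#'
#' Scans every (time, frequency, scale) grid point of the dictionary,
#' optimising phase in closed form at each point, and returns the atom with
#' the largest squared inner product with the residual.  Exact ties are
#' broken towards the smallest time centre, then the lowest frequency, then
#' the smallest scale.
#'
#' @param residual Numeric vector; length must equal the dictionary's epoch
#'   in samples.
#' @param dictionary An [build_dictionary()] object.
#' @return A list with elements `u`, `s`, `f`, `phi`, `coeff` (non-negative
#'   inner-product magnitude, sign absorbed into phase), `energy`
#'   (`coeff^2`) and `degenerate` (`TRUE` for an all-zero residual).  The
#'   sampled unit-norm waveform is attached as attribute `"waveform"`.
#' @export
best_match <- function(residual, dictionary) {
  stopifnot(inherits(dictionary, "mp_dictionary"))
  n <- dictionary$n_samples
  if (length(residual) != n) {
    stop("residual length (", length(residual),
         ") does not match dictionary epoch (", n, " samples)",
         call. = FALSE)
  }
  fs <- dictionary$fs
  x0 <- c(0, residual)
  best <- NULL
  for (i in seq_len(nrow(dictionary$scales))) {
    sc <- scale_cache(dictionary, i)
    scan <- scan_scale(x0, sc)
    idx <- which.max(scan$En)                  # column-major: u then f order
    e <- scan$En[idx]
    j <- (idx - 1L) %/% sc$kmax + 1L
    kbin <- idx - (j - 1L) * sc$kmax           # 1-based bin, k = kbin - 1
    u <- sc$us[j] / fs
    f <- (kbin - 1L) * fs / sc$nfft
    better <- is.null(best) || e > best$e ||
      (e == best$e && (u < best$u || (u == best$u && f < best$f)))
    if (better) {
      g <- if (j %in% sc$edge) sc$egram[[match(j, sc$edge)]] else sc$interior
      best <- list(e = e, u = u, f = f, s = sc$s, i = i, j = j, kbin = kbin,
                   a = scan$A[idx], b = scan$B[idx], gram = g)
    }
  }
  phi <- optimal_phase(best$a, best$b, best$gram, best$kbin)
  g <- gabor_waveform(best$u, best$s, best$f, phi, fs, n)
  coeff <- sum(residual * g)
  if (coeff < 0) {
    phi <- if (phi >= pi) phi - pi else phi + pi
    g <- -g
    coeff <- -coeff
  }
  atom <- list(u = best$u, s = best$s, f = best$f, phi = phi,
               coeff = coeff, energy = coeff^2,
               degenerate = all(residual == 0))
  attr(atom, "waveform") <- g
  atom
}

#' Matching-pursuit decomposition of one epoch
#'
#' Fits the greedy Gabor expansion
#' \deqn{x \approx \sum_{n=0}^{M-1} \langle R^n x, g_{\gamma_n}\rangle
#'       g_{\gamma_n}}
#' where \eqn{R^0 x = x} and each iteration subtracts the best-matching
#' dictionary atom from the running residual.
#'
#' @param signal Numeric vector, one analysis epoch, finite-valued.
#' @param fs Sampling rate in Hz (ignored when `dictionary` is given).
#' @param M Maximum number of iterations (atoms).  Iteration stops early if
#'   the residual energy falls below `1e-12` of the signal energy.
#' @param epsilon Dictionary energy-error parameter (used when building a
#'   default dictionary).
#' @param dictionary Optional pre-built [build_dictionary()] object whose
#'   epoch matches `length(signal)`.
#' @param scale_range Passed to [build_dictionary()] when needed.
#' @param epoch_start Offset in seconds of this epoch on the recording
#'   timeline (carried into the book for event placement).
#' @return An object of class `mp_book`: atom table (`iteration`, `u`, `s`,
#'   `f`, `phi`, `coeff`, `energy`), `fs`, `epoch_start`, `epoch_length`,
#'   `signal_energy`, `residual_energy`, plus the stored signal and final
#'   residual.  `signal_energy = sum(coeff^2) + residual_energy` holds to
#'   float precision.
#' @seealso [reconstruct()], [filter_book()], [write_book()]
#' @examples
#' fs <- 128
#' d <- build_dictionary(0.1, fs, 2, scale_range = c(0.1, 0.5))
#' x <- 5 * gabor_waveform(1, d$scales$s[2], 13, 0.5, fs, 256)
#' b <- mp_decompose(x, fs, M = 1, dictionary = d)
#' b$atoms$coeff   # ~5
#' @export
mp_decompose <- function(signal, fs = NULL, M = 50, epsilon = 0.04,
                         dictionary = NULL, scale_range = NULL,
                         epoch_start = 0) {
  if (!all(is.finite(signal))) {
    stop("signal contains non-finite samples", call. = FALSE)
  }
  if (M < 1) stop("'M' must be at least 1", call. = FALSE)
  if (is.null(dictionary)) {
    if (is.null(fs)) stop("either 'fs' or 'dictionary' is required",
                          call. = FALSE)
    dictionary <- build_dictionary(epsilon, fs, length(signal) / fs,
                                   scale_range = scale_range)
  } else {
    stopifnot(inherits(dictionary, "mp_dictionary"))
    if (dictionary$n_samples != length(signal)) {
      stop("dictionary epoch (", dictionary$n_samples,
           " samples) does not match signal length (", length(signal), ")",
           call. = FALSE)
    }
    fs <- dictionary$fs
  }
  signal_energy <- sum(signal^2)
  res <- signal
  rows <- vector("list", M)
  n_fit <- 0L
  for (it in seq_len(M)) {
    if (sum(res^2) <= 1e-12 * signal_energy) break
    atom <- best_match(res, dictionary)
    if (atom$degenerate || atom$coeff == 0) break
    res <- res - atom$coeff * attr(atom, "waveform")
    n_fit <- n_fit + 1L
    rows[[n_fit]] <- data.frame(iteration = it, u = atom$u, s = atom$s,
                                f = atom$f, phi = atom$phi,
                                coeff = atom$coeff, energy = atom$energy)
  }
  atoms <- if (n_fit > 0L) {
    do.call(rbind, rows[seq_len(n_fit)])
  } else {
    data.frame(iteration = integer(), u = numeric(), s = numeric(),
               f = numeric(), phi = numeric(), coeff = numeric(),
               energy = numeric())
  }
  structure(
    list(atoms = atoms, fs = fs, epoch_start = epoch_start,
         epoch_length = dictionary$epoch_length,
         signal_energy = signal_energy, residual_energy = sum(res^2),
         epsilon = dictionary$epsilon, M = M,
         n_samples = dictionary$n_samples,
         signal = signal, residual = res),
    class = "mp_book"
  )
}

#' Reconstruct a signal from the leading atoms of a book
#'
#' @param book An `mp_book`.
#' @param n_atoms How many atoms to sum (default: all).  `0` gives the
#'   all-zero signal.
#' @return Numeric vector of the epoch's length.
#' @export
reconstruct <- function(book, n_atoms = nrow(book$atoms)) {
  stopifnot(inherits(book, "mp_book"))
  if (n_atoms > nrow(book$atoms)) {
    stop("'n_atoms' exceeds the number of fitted atoms", call. = FALSE)
  }
  out <- numeric(book$n_samples)
  for (i in seq_len(n_atoms)) {
    a <- book$atoms[i, ]
    out <- out + a$coeff *
      gabor_waveform(a$u, a$s, a$f, a$phi, book$fs, book$n_samples)
  }
  out
}

#' @export
print.mp_book <- function(x, ...) {
  cat("Matching-pursuit book: ", nrow(x$atoms), " atoms, fs = ", x$fs,
      " Hz, epoch ", x$epoch_length, " s @ ", x$epoch_start, " s\n", sep = "")
  expl <- if (x$signal_energy > 0) {
    100 * (1 - x$residual_energy / x$signal_energy)
  } else 0
  cat(sprintf("  energy explained: %.2f%%\n", expl))
  if (nrow(x$atoms) > 0) {
    print(utils::head(x$atoms, 6), row.names = FALSE, digits = 4)
    if (nrow(x$atoms) > 6) cat("  ...\n")
  }
  invisible(x)
}

#' @export
summary.mp_book <- function(object, ...) {
  at <- object$atoms
  out <- list(
    n_atoms = nrow(at),
    fs = object$fs,
    epoch_length = object$epoch_length,
    epoch_start = object$epoch_start,
    signal_energy = object$signal_energy,
    residual_energy = object$residual_energy,
    energy_explained = if (object$signal_energy > 0) {
      1 - object$residual_energy / object$signal_energy
    } else NA_real_,
    freq_range = if (nrow(at)) range(at$f) else c(NA_real_, NA_real_),
    scale_range = if (nrow(at)) range(at$s) else c(NA_real_, NA_real_)
  )
  class(out) <- "summary.mp_book"
  out
}

#' @export
print.summary.mp_book <- function(x, ...) {
  cat("MP decomposition summary\n")
  cat("  atoms:            ", x$n_atoms, "\n")
  cat("  epoch:            ", x$epoch_length, "s @", x$epoch_start, "s,",
      x$fs, "Hz\n")
  cat(sprintf("  energy explained:  %.3f\n", x$energy_explained))
  if (x$n_atoms > 0) {
    cat(sprintf("  frequencies:       %.2f - %.2f Hz\n",
                x$freq_range[1], x$freq_range[2]))
    cat(sprintf("  half-widths:       %.3f - %.3f s\n",
                x$scale_range[1], x$scale_range[2]))
  }
  invisible(x)
}

#' @export
coef.mp_book <- function(object, ...) {
  as.matrix(object$atoms[, c("u", "s", "f", "phi", "coeff")])
}

#' @export
fitted.mp_book <- function(object, ...) {
  object$signal - object$residual
}

#' @export
residuals.mp_book <- function(object, ...) {
  object$residual
}

#' @export
predict.mp_book <- function(object, n_atoms = nrow(object$atoms), ...) {
  reconstruct(object, n_atoms)
}

#' @export
plot.mp_book <- function(x, n_atoms = nrow(x$atoms), ...) {
  t <- x$epoch_start + (seq_len(x$n_samples) - 1) / x$fs
  rec <- reconstruct(x, n_atoms)
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(t, x$signal, type = "l", col = "grey40",
                 xlab = "time [s]", ylab = "signal", ...)
  graphics::lines(t, rec, col = "firebrick")
  graphics::legend("topright", c("signal", "reconstruction"),
                   col = c("grey40", "firebrick"), lty = 1, bty = "n",
                   cex = 0.8)
  if (nrow(x$atoms) > 0) {
    graphics::plot(x$epoch_start + x$atoms$u, x$atoms$f,
                   cex = 0.5 + 2 * sqrt(x$atoms$energy / max(x$atoms$energy)),
                   pch = 1, xlab = "time centre u [s]",
                   ylab = "frequency [Hz]", xlim = range(t))
  }
  invisible(x)
}

#' Decompose a whole recording in fixed epochs
#'
#' Splits a recording into consecutive non-overlapping epochs (20 s by
#' default, the traditional sleep-analysis window), decomposes each with
#' [mp_decompose()] and the same dictionary, and returns the list of books.
#' A trailing remainder of at least 1 s is decomposed with its own,
#' matching-length dictionary; a shorter remainder is dropped.
#'
#' @inheritParams mp_decompose
#' @param signal Numeric vector, the whole recording.
#' @param epoch_length Epoch length in seconds.
#' @param verbose Print one line per epoch.
#' @return List of `mp_book` objects (class `mp_books`) with the sampling
#'   rate and total duration attached as attributes.
#' @export
mp_decompose_recording <- function(signal, fs, epoch_length = 20, M = 50,
                                   epsilon = 0.04, scale_range = NULL,
                                   verbose = FALSE) {
  n_epoch <- round(epoch_length * fs)
  n <- length(signal)
  starts <- seq.int(1L, n, by = n_epoch)
  books <- list()
  dict <- NULL
  for (st in starts) {
    en <- min(st + n_epoch - 1L, n)
    seg <- signal[st:en]
    if (length(seg) == n_epoch) {
      if (is.null(dict)) {
        dict <- build_dictionary(epsilon, fs, epoch_length,
                                 scale_range = scale_range)
      }
      d <- dict
    } else {
      if (length(seg) < fs) break                  # drop remainder < 1 s
      d <- build_dictionary(epsilon, fs, length(seg) / fs,
                            scale_range = scale_range)
    }
    bk <- mp_decompose(seg, dictionary = d, M = M,
                       epoch_start = (st - 1L) / fs)
    if (verbose) {
      cat(sprintf("epoch @ %6.1f s: %d atoms, %.1f%% energy\n",
                  bk$epoch_start, nrow(bk$atoms),
                  100 * (1 - bk$residual_energy /
                           max(bk$signal_energy, .Machine$double.xmin))))
    }
    books[[length(books) + 1L]] <- bk
  }
  structure(books, class = "mp_books", fs = fs, duration = n / fs)
}

#' @export
print.mp_books <- function(x, ...) {
  cat("MP decomposition of a ", attr(x, "duration"), "-s recording: ",
      length(x), " epochs, ", sum(vapply(x, function(b) nrow(b$atoms), 0L)),
      " atoms\n", sep = "")
  invisible(x)
}
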