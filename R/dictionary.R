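#' Calibrate the dictionary dilation factor from the energy-error parameter
#'
#' The Gabor dictionary is organised as a geometric ladder of Gaussian
#' envelope half-widths, \eqn{s_{j+1} = a\,s_j}.  The dilation \eqn{a} is the
#' largest one for which the dictionary still honours its defining contract:
#' a unit-energy Gabor function whose parameters fall between grid points
#' loses at most a fraction \eqn{\epsilon} of its energy to the nearest
#' dictionary atom in a single matching-pursuit iteration.
#'
#' Two Gaussian envelopes of widths \eqn{s} and \eqn{as} have inner product
#' \eqn{\sqrt{2a/(1+a^2)}}; setting this overlap to \eqn{1-\epsilon} for
#' neighbouring scales yields the closed form
#' \deqn{a = \frac{1 + \sqrt{1-(1-\epsilon)^4}}{(1-\epsilon)^2}.}
#' With \eqn{\epsilon = 0.04} this gives \eqn{a \approx 1.506}, which at
#' 256 Hz reproduces the canonical spindle-range widths 0.53, 0.80, 1.21
#' and 1.82 s.  The worst off-grid scale (the geometric midpoint of two
#' ladder rungs) then loses \eqn{1 - 2\sqrt{a}/(1+a)} of its energy, which
#' is strictly less than \eqn{\epsilon}; the remaining budget is spent on
#' the time and frequency grids (see [build_dictionary()]).
#'
#' @param epsilon Energy-error density parameter, in (0, 1).  Smaller values
#'   give a denser dictionary (dilation closer to 1).
#' @return The dilation factor \eqn{a > 1}.
#' @examples
#' calibrate_dilation(0.04)   # ~1.506
#' @export
calibrate_dilation <- function(epsilon) {
  check_epsilon(epsilon)
  (1 + sqrt(1 - (1 - epsilon)^4)) / (1 - epsilon)^2
}

check_epsilon <- function(epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0 || epsilon >= 1) {
    stop("'epsilon' must be a single number in (0, 1)", call. = FALSE)
  }
  invisible(epsilon)
}

# Split the energy budget left after the scale ladder evenly between the
# time-shift and frequency grids.  Worst-case losses (Gaussian closed forms):
#   time offset d:       energy factor exp(-pi d^2 / (2 s^2)), d = du/2
#   frequency offset dw: energy factor exp(-dw^2 s^2 / (8 pi)), dw = 2*pi*df/2
# Solving each for the per-dimension retention r = sqrt((1-eps)/rho_s) gives
# du = alpha*s and df = beta/s with alpha = beta = 2*sqrt(log(1/r)/pi).
grid_coefficients <- function(epsilon) {
  a <- calibrate_dilation(epsilon)
  rho_s <- 2 * sqrt(a) / (1 + a)       # worst-case scale-only retention
  stopifnot(rho_s > 1 - epsilon)
  r <- sqrt((1 - epsilon) / rho_s)     # retention budget per remaining dim
  alpha <- 2 * sqrt(log(1 / r) / pi)
  list(a = a, rho_s = rho_s, alpha = alpha, beta = alpha)
}

#' Build a Gabor dictionary parameter grid
#'
#' Constructs the discrete grid of candidate Gabor parameters
#' \eqn{(u, f, s)} over one analysis epoch.  A single dimensionless
#' parameter \eqn{\epsilon} ("energy error") governs the density of the
#' whole grid: it bounds the fraction of energy that a single
#' matching-pursuit iteration can lose because the best-fitting continuous
#' Gabor falls between grid points.
#'
#' The envelope half-widths form a geometric ladder \eqn{s_j = a^j/f_s}
#' anchored at one sampling period, with dilation \eqn{a} from
#' [calibrate_dilation()].  Per scale, the time step is the largest whole
#' number of samples not exceeding \eqn{\alpha s} and the frequency grid is
#' the FFT bin spacing \eqn{f_s/N_{fft}} with \eqn{N_{fft}} the smallest
#' power of two giving a spacing no coarser than \eqn{\beta/s}
#' (\eqn{\alpha,\beta} from the same \eqn{\epsilon} calibration).  Phase is
#' not gridded; it is optimised in closed form during matching.
#'
#' @param epsilon Energy-error parameter in (0, 1).
#' @param fs Sampling rate in Hz.
#' @param epoch_length Epoch length in seconds.
#' @param scale_range Optional numeric vector `c(min_s, max_s)` in seconds
#'   restricting the envelope half-widths.  Default: 16 samples to a quarter
#'   of the epoch.
#' @return An object of class `mp_dictionary`: a list with the calibration
#'   constants and a per-scale table `$scales` (columns `s`, `du`, `df`,
#'   `n_u`, `n_f`, `nfft`, `half_support`).
#' @examples
#' d <- build_dictionary(0.04, fs = 256, epoch_length = 20)
#' d$scales$s          # geometric ladder of envelope half-widths
#' @export
build_dictionary <- function(epsilon, fs, epoch_length, scale_range = NULL) {
  check_epsilon(epsilon)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a positive number", call. = FALSE)
  }
  if (!is.numeric(epoch_length) || length(epoch_length) != 1L ||
      epoch_length <= 0) {
    stop("'epoch_length' must be a positive number", call. = FALSE)
  }
  cal <- grid_coefficients(epsilon)
  n <- round(epoch_length * fs)
  if (is.null(scale_range)) {
    scale_range <- c(16 / fs, epoch_length / 4)
  }
  if (length(scale_range) != 2L || scale_range[1] <= 0 ||
      scale_range[2] < scale_range[1]) {
    stop("'scale_range' must be c(min_s, max_s) with 0 < min_s <= max_s",
         call. = FALSE)
  }
  # ladder s_j = a^j / fs, keep rungs inside the requested range
  jmax <- ceiling(log(scale_range[2] * fs) / log(cal$a)) + 1L
  s_all <- cal$a^(0:jmax) / fs
  s <- s_all[s_all >= scale_range[1] & s_all <= scale_range[2]]
  if (length(s) == 0L) {
    stop("empty scale range: no dictionary scales between ",
         signif(scale_range[1], 3), " and ", signif(scale_range[2], 3), " s",
         call. = FALSE)
  }
  du_samp <- pmax(1L, floor(cal$alpha * s * fs))
  nfft <- 2^ceiling(log2(pmax(2 * floor(4 * s * fs) + 1, fs * s / cal$beta)))
  scales <- data.frame(
    s = s,
    du = du_samp / fs,
    df = fs / nfft,
    n_u = floor((n - 1) / du_samp) + 1L,
    n_f = nfft / 2,                     # bins k = 0 .. nfft/2 - 1
    nfft = nfft,
    half_support = floor(4 * s * fs)
  )
  structure(
    list(epsilon = epsilon, fs = fs, epoch_length = epoch_length,
         n_samples = n, scale_range = scale_range,
         a = cal$a, alpha = cal$alpha, beta = cal$beta,
         scales = scales, cache = new.env(parent = emptyenv())),
    class = "mp_dictionary"
  )
}

#' @export
print.mp_dictionary <- function(x, ...) {
  cat("Gabor dictionary (epsilon = ", x$epsilon, ", fs = ", x$fs,
      " Hz, epoch = ", x$epoch_length, " s)\n", sep = "")
  cat("  dilation a = ", signif(x$a, 6),
      ", time step = ", signif(x$alpha, 4), "*s",
      ", freq step <= ", signif(x$beta, 4), "/s\n", sep = "")
  cat("  ", nrow(x$scales), " scales, ",
      format(n_atoms(x), big.mark = ","), " atoms\n", sep = "")
  cat("  half-widths [s]: ", paste(signif(x$scales$s, 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Number of (u, f, s) grid points in a dictionary
#'
#' @param dictionary An `mp_dictionary`.
#' @return Total atom count (phase is continuous, not counted).
#' @export
n_atoms <- function(dictionary) {
  stopifnot(inherits(dictionary, "mp_dictionary"))
  sum(as.numeric(dictionary$scales$n_u) * dictionary$scales$n_f)
}

#' Synthesize a sampled, unit-norm Gabor waveform
#'
#' Discrete waveform
#' \deqn{g[t] = K\, e^{-\pi((t-u)/s)^2} \cos(2\pi f (t-u) + \phi)}
#' evaluated on the sample grid `t = (0:(n_samples-1))/fs`, truncated to
#' \eqn{|t-u| \le 4s} (beyond which the envelope is below 1e-21) and
#' normalized so the sampled vector has unit energy; the constant `K`
#' absorbs the analytic normalization.
#'
#' @param u Time center in seconds relative to the start of the window.
#' @param s Gaussian envelope half-width in seconds (> 0).
#' @param f Frequency in Hz, in `[0, fs/2]`.
#' @param phi Phase in radians.
#' @param fs Sampling rate in Hz.
#' @param n_samples Number of samples in the output vector.
#' @return Numeric vector of length `n_samples` with unit sum of squares.
#' @examples
#' g <- gabor_waveform(u = 2, s = 0.8, f = 13, phi = 0, fs = 256,
#'                     n_samples = 1024)
#' sum(g^2)  # 1
#' @export
gabor_waveform <- function(u, s, f, phi = 0, fs, n_samples) {
  if (n_samples <= 0) stop("'n_samples' must be positive", call. = FALSE)
  if (s <= 0) stop("'s' must be positive", call. = FALSE)
  if (f < 0 || f > fs / 2) stop("'f' must lie in [0, fs/2]", call. = FALSE)
  if (s * fs < 3) {
    warning("envelope half-width spans fewer than 3 samples; ",
            "waveform is under-sampled", call. = FALSE)
  }
  t <- (seq_len(n_samples) - 1) / fs
  dt <- t - u
  g <- numeric(n_samples)
  # same support rule as the matching scan: |t-u|*fs <= floor(4*s*fs)
  keep <- abs(dt) * fs <= floor(4 * s * fs)
  g[keep] <- exp(-pi * (dt[keep] / s)^2) * cos(2 * pi * f * dt[keep] + phi)
  nrm <- sqrt(sum(g^2))
  if (nrm == 0) {
    stop("Gabor support does not intersect the sampled window", call. = FALSE)
  }
  g / nrm
}

#' Serialize dictionary settings to a config block
#'
#' Writes (or returns) the four numbers that fully determine a dictionary,
#' as a YAML key-value block usable in pipeline configuration files.
#'
#' @param dictionary An `mp_dictionary`.
#' @param path Optional file path; if omitted the YAML text is returned.
#' @return The YAML string, invisibly when written to `path`.
#' @export
dictionary_config <- function(dictionary, path = NULL) {
  stopifnot(inherits(dictionary, "mp_dictionary"))
  block <- list(dictionary = list(
    epsilon = dictionary$epsilon,
    fs = dictionary$fs,
    epoch_length = dictionary$epoch_length,
    scale_range = as.numeric(dictionary$scale_range)
  ))
  txt <- yaml::as.yaml(block)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Rebuild a dictionary from a config block
#'
#' @param path Path to a YAML file produced by [dictionary_config()] (or a
#'   compatible hand-written one).
#' @return An `mp_dictionary`.
#' @export
dictionary_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)$dictionary
  if (is.null(cfg)) stop("no 'dictionary' block in ", path, call. = FALSE)
  build_dictionary(cfg$epsilon, cfg$fs, cfg$epoch_length,
                   scale_range = cfg$scale_range)
}
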