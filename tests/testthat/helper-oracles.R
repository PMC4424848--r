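# Independent reference implementations used as oracles.  These deliberately
# share no code with the package internals: plain loops, direct summation,
# textbook formulas.

# unit-norm Gabor by direct evaluation (no shared code path with the
# package: explicit ifelse masking and manual normalization)
oracle_gabor <- function(u, s, f, phi, fs, n) {
  t <- (0:(n - 1)) / fs
  dt <- t - u
  g <- ifelse(abs(dt) * fs <= floor(4 * s * fs),
              exp(-pi * (dt / s)^2) * cos(2 * pi * f * dt + phi), 0)
  g / sqrt(sum(g^2))
}

# exhaustive scan of every dictionary grid point; at each point the best
# phase is found by projecting onto the quadrature pair, with the 2x2
# system solved by base solve().  Ties: largest energy, then smallest u,
# then smallest f, then smallest s.
oracle_best_match <- function(x, dict) {
  fs <- dict$fs
  n <- dict$n_samples
  t <- (0:(n - 1)) / fs
  best <- list(energy = -Inf, u = Inf, f = Inf, s = Inf)
  for (i in seq_len(nrow(dict$scales))) {
    row <- dict$scales[i, ]
    s <- row$s
    du <- max(1, floor(dict$alpha * s * fs))
    us <- seq(0, n - 1, by = du) / fs
    nfft <- row$nfft
    ks <- 0:(nfft / 2 - 1)
    for (u in us) {
      dt <- t - u
      inside <- abs(dt) * fs <= floor(4 * s * fs)
      env <- ifelse(inside, exp(-pi * (dt / s)^2), 0)
      for (k in ks) {
        f <- k * fs / nfft
        gc <- env * cos(2 * pi * f * dt)
        gs <- env * sin(2 * pi * f * dt)
        G <- matrix(c(sum(gc * gc), sum(gc * gs),
                      sum(gc * gs), sum(gs * gs)), 2)
        p <- c(sum(x * gc), sum(x * gs))
        en <- if (abs(det(G)) <= 1e-10 * sum(env^2)^2) {
          p[1]^2 / G[1, 1]
        } else {
          drop(p %*% solve(G, p))
        }
        if (en > best$energy ||
            (en == best$energy &&
             (u < best$u || (u == best$u && f < best$f)))) {
          best <- list(energy = en, u = u, f = f, s = s)
        }
      }
    }
  }
  best
}

# exhaustive MP by repeated oracle scans; subtraction uses the package's
# public gabor_waveform only through direct projection of the residual
oracle_decompose <- function(x, dict, M) {
  res <- x
  atoms <- list()
  for (m in seq_len(M)) {
    b <- oracle_best_match(res, dict)
    # optimal phase by fine grid (independent of the analytic solution)
    phis <- seq(0, 2 * pi, length.out = 4097)[-4097]
    proj <- vapply(phis, function(ph) {
      g <- oracle_gabor(b$u, b$s, b$f, ph, dict$fs, length(x))
      sum(res * g)
    }, numeric(1))
    ph <- phis[which.max(proj)]
    g <- oracle_gabor(b$u, b$s, b$f, ph, dict$fs, length(x))
    co <- sum(res * g)
    res <- res - co * g
    atoms[[m]] <- c(u = b$u, s = b$s, f = b$f, energy = b$energy,
                    coeff = co)
  }
  do.call(rbind, atoms)
}

# textbook metric formulas, coded separately from compute_metrics
oracle_metrics <- function(tp, tn, fp, fn) {
  p <- tp + fn; pp <- tp + fp; n <- fp + tn; np <- fn + tn
  tot <- tp + tn + fp + fn
  sens <- tp / p
  ppv <- tp / pp
  mcc <- (tp * tn - fp * fn) / sqrt(p) / sqrt(pp) / sqrt(n) / sqrt(np)
  pe <- (pp * p + np * n) / tot / tot
  kappa <- ((tp + tn) / tot - pe) / (1 - pe)
  f1 <- 2 * ppv * sens / (ppv + sens)
  c(sensitivity = sens, ppv = ppv, mcc = mcc, kappa = kappa, f1 = f1)
}

# linear-interpolation percentile by explicit sort-and-index
oracle_percentile <- function(values, p) {
  v <- sort(values)
  h <- (length(v) - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# per-sample confusion loop
oracle_confusion <- function(d, r) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(d)) {
    if (d[i] && r[i]) tp <- tp + 1L
    else if (!d[i] && !r[i]) tn <- tn + 1L
    else if (d[i]) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# a small dictionary + epoch shared by the MP tests (128 Hz keeps the
# exhaustive oracle affordable)
tiny_setup <- function(epsilon = 0.2, fs = 128, epoch = 2,
                       scale_range = c(0.1, 0.5)) {
  list(fs = fs, n = round(epoch * fs),
       dict = build_dictionary(epsilon, fs, epoch,
                               scale_range = scale_range))
}

# grid-aligned atom parameters for a dictionary scale index
on_grid_params <- function(dict, i, u_target, f_target) {
  fs <- dict$fs
  row <- dict$scales[i, ]
  du <- max(1, floor(dict$alpha * row$s * fs))
  us <- seq(0, dict$n_samples - 1, by = du) / fs
  u <- us[which.min(abs(us - u_target))]
  f <- round(f_target / (fs / row$nfft)) * fs / row$nfft
  list(u = u, s = row$s, f = f)
}
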