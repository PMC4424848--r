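make_book <- function(atoms, fs = 128, epoch_start = 0, epoch_length = 2) {
  structure(list(atoms = atoms, fs = fs, epoch_start = epoch_start,
                 epoch_length = epoch_length,
                 signal_energy = sum(atoms$coeff^2),
                 residual_energy = 0, epsilon = NA, M = nrow(atoms),
                 n_samples = round(epoch_length * fs)),
            class = "mp_book")
}

atom_row <- function(u, s, f, phi, coeff, it = 1L) {
  data.frame(iteration = it, u = u, s = s, f = f, phi = phi, coeff = coeff,
             energy = coeff^2)
}

test_that("atom amplitude is twice the scaled waveform maximum", {
  fs <- 128
  # reconstruction with numerical extrema +-35 -> amplitude 70
  g <- gabor_waveform(1, 0.5, 13, 0, fs, 256)
  coeff <- 35 / max(abs(g))
  bk <- make_book(atom_row(1, 0.5, 13, 0, coeff))
  expect_equal(atom_amplitude(bk), 70, tolerance = 1e-9)
  bk0 <- make_book(atom_row(1, 0.5, 13, 0, 0))
  expect_equal(atom_amplitude(bk0), 0)
})

test_that("atom amplitude approximates the reconstruction's peak-to-peak", {
  set.seed(21)
  fs <- 128
  for (i in 1:10) {
    s <- runif(1, 0.4, 1)
    f <- runif(1, 10, 16)
    phi <- runif(1, 0, 2 * pi)
    coeff <- runif(1, 1, 10)
    bk <- make_book(atom_row(1, s, f, phi, coeff), epoch_length = 2)
    rec <- coeff * gabor_waveform(1, s, f, phi, fs, 256)
    expect_equal(atom_amplitude(bk), max(rec) - min(rec), tolerance = 0.03)
  }
})

test_that("filter_book applies all three criteria and places events", {
  crit <- spindle_criteria(min_amplitude = 30)
  fs <- 128
  g <- gabor_waveform(1, 1.0, 13, 0, fs, 512)
  co40 <- 20 / max(abs(g))                      # amplitude 40
  bk <- make_book(atom_row(1, 1.0, 13, 0, co40), fs = fs,
                  epoch_start = 10, epoch_length = 4)
  ev <- filter_book(bk, crit)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 10 + 1 - 0.5)
  expect_equal(ev$end, 10 + 1 + 0.5)
  expect_equal(ev$frequency, 13)
  # frequency just below the 11 Hz limit drops out
  bk2 <- make_book(atom_row(1, 1.0, 10.5, 0, co40), fs = fs,
                   epoch_length = 4)
  expect_equal(nrow(filter_book(bk2, crit)), 0)
})

test_that("filter_book equals the exhaustive per-atom predicate", {
  set.seed(55)
  fs <- 128
  atoms <- do.call(rbind, lapply(1:20, function(i) {
    atom_row(runif(1, 0.5, 3.5), runif(1, 0.2, 1.5), runif(1, 2, 30),
             runif(1, 0, 2 * pi), runif(1, 1, 40), it = i)
  }))
  bk <- make_book(atoms, fs = fs, epoch_length = 4)
  crit <- spindle_criteria(min_amplitude = 25)
  ev <- filter_book(bk, crit)
  amp <- atom_amplitude(bk)
  keep <- atoms$f >= 11 & atoms$f <= 16 & atoms$s >= 0.5 & amp >= 25
  expect_equal(nrow(ev), sum(keep))
  expect_equal(sort(ev$center), sort(atoms$u[keep]))
})

test_that("event masks count samples of half-open intervals", {
  fs <- 256
  ev <- data.frame(start = 1, end = 2)
  expect_equal(sum(events_to_mask(ev, fs, 1024)), 256)
  expect_equal(events_to_mask(data.frame(start = numeric(),
                                         end = numeric()), fs, 100),
               logical(100))
  # overlapping events form a union; compare to per-sample membership
  ev2 <- data.frame(start = c(0.5, 0.9), end = c(1.1, 1.4))
  m <- events_to_mask(ev2, fs, 512)
  t <- (0:511) / fs
  ora <- (t >= 0.5 & t < 1.1) | (t >= 0.9 & t < 1.4)
  expect_equal(m, ora)
  expect_error(events_to_mask(data.frame(start = -1, end = 0.5), fs, 512),
               "outside")
})

test_that("detected spindle events cover implanted high-SNR events", {
  sim <- simulate_eeg(80, seed = 202,
                      spindles = list(density = 3, amplitude = c(60, 90),
                                      width = c(0.6, 1.4)))
  ev <- detect_spindles(sim$signal, sim$fs, epsilon = 0.2, M = 8,
                        percentile = 90, scale_range = c(0.1, 2))
  expect_gte(nrow(ev), nrow(sim$truth) - 1)
  # nearly all truth events overlap a detection by at least half their length
  covered <- vapply(seq_len(nrow(sim$truth)), function(i) {
    ov <- pmin(ev$end, sim$truth$end[i]) - pmax(ev$start, sim$truth$start[i])
    max(ov) >= 0.5 * (sim$truth$end[i] - sim$truth$start[i])
  }, logical(1))
  expect_gte(sum(covered), nrow(sim$truth) - 1)
  expect_true(all(diff(ev$start) >= 0))
})

test_that("sub-threshold noise and short bursts yield no detections", {
  set.seed(17)
  fs <- 128
  # noise far below an absurdly high fixed amplitude criterion
  x <- rnorm(40 * fs)
  crit <- spindle_criteria(min_amplitude = 1e6)
  ev <- detect_transients(x, fs, crit, epsilon = 0.2, M = 5,
                          epoch_length = 20, scale_range = c(0.1, 2))
  expect_equal(nrow(ev), 0)
  # a strong but 0.3-s sigma burst fails the duration criterion: its
  # fitted atom is narrower than 0.5 s, so no spindle is reported
  sim <- simulate_eeg(20, fs = fs, seed = 9, background = list(rms = 5),
                      spindles = list(density = 3, width = c(0.28, 0.32),
                                      amplitude = c(80, 100)))
  expect_equal(nrow(sim$truth), 1)
  ev2 <- detect_spindles(sim$signal, fs, epsilon = 0.2, M = 1,
                         percentile = 90, epoch_length = 20,
                         scale_range = c(0.1, 2))
  expect_equal(nrow(ev2), 0)
})

test_that("the slow-wave preset separates 100 from 50 uV waves", {
  fs <- 128
  sim <- simulate_eeg(40, fs = fs, seed = 33, background = list(rms = 8),
                      spindles = list(density = 0),
                      slow_waves = list(density = 3, f = c(0.9, 1.1),
                                        width = c(0.9, 1.1),
                                        amplitude = c(99, 101)))
  sim_lo <- simulate_eeg(40, fs = fs, seed = 34, background = list(rms = 8),
                         spindles = list(density = 0),
                         slow_waves = list(density = 3, f = c(0.9, 1.1),
                                           width = c(0.9, 1.1),
                                           amplitude = c(49, 51)))
  crit <- slow_wave_criteria()
  ev_hi <- detect_transients(sim$signal, fs, crit, epsilon = 0.2, M = 8,
                             epoch_length = 20, scale_range = c(0.3, 3))
  ev_lo <- detect_transients(sim_lo$signal, fs, crit, epsilon = 0.2, M = 8,
                             epoch_length = 20, scale_range = c(0.3, 3))
  expect_equal(nrow(sim$truth), 2)
  expect_gte(nrow(ev_hi), nrow(sim$truth))
  for (i in seq_len(nrow(sim$truth))) {
    ov <- pmin(ev_hi$end, sim$truth$end[i]) -
      pmax(ev_hi$start, sim$truth$start[i])
    expect_gt(max(ov), 0.4)
  }
  expect_equal(nrow(ev_lo), 0)
})

test_that("events round-trip through CSV and merge across small gaps", {
  ev <- structure(
    data.frame(start = c(1, 2.05), end = c(2, 3), center = c(1.5, 2.5),
               frequency = c(13, 12), amplitude = c(40, 35),
               duration = c(1, 0.95), source_epoch = c(1L, 1L),
               type = "spindle"),
    class = c("eeg_events", "data.frame"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  ev2 <- read_events(path)
  expect_equal(ev2$start, ev$start)
  expect_equal(ev2$amplitude, ev$amplitude)
  merged <- merge_events(ev, max_gap = 0.1)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start, 1)
  expect_equal(merged$end, 3)
  expect_equal(nrow(merge_events(ev, max_gap = 0.01)), 2)
})
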