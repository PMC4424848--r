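test_that("an exact dictionary atom is self-matched with its coefficient", {
  ts <- tiny_setup()
  pr <- on_grid_params(ts$dict, 2, u_target = 1.0, f_target = 13)
  x <- 5 * gabor_waveform(pr$u, pr$s, pr$f, 0.7, ts$fs, ts$n)
  a <- best_match(x, ts$dict)
  expect_equal(a$u, pr$u)
  expect_equal(a$s, pr$s)
  expect_equal(a$f, pr$f)
  expect_equal(a$coeff, 5, tolerance = 1e-6)
})

test_that("analytic phase optimum matches a fine phase grid", {
  ts <- tiny_setup()
  pr <- on_grid_params(ts$dict, 2, 1.0, 12)
  x <- gabor_waveform(pr$u, pr$s, pr$f, 1.0, ts$fs, ts$n)
  a <- best_match(x, ts$dict)
  expect_equal(a$u, pr$u)
  expect_equal(a$f, pr$f)
  expect_equal(a$phi, 1.0, tolerance = 1e-3)
  # independent fine-grid check
  phis <- seq(0, 2 * pi, length.out = 20001)
  proj <- vapply(phis, function(ph) {
    sum(x * oracle_gabor(pr$u, pr$s, pr$f, ph, ts$fs, ts$n))
  }, numeric(1))
  expect_equal(phis[which.max(proj)], a$phi, tolerance = 1e-3)
})

test_that("best match on white noise equals the exhaustive scan", {
  ts <- tiny_setup()
  set.seed(101)
  x <- rnorm(ts$n)
  a <- best_match(x, ts$dict)
  o <- oracle_best_match(x, ts$dict)
  expect_equal(a$u, o$u)
  expect_equal(a$s, o$s)
  expect_equal(a$f, o$f)
  expect_equal(a$energy, o$energy, tolerance = 1e-9)
})

test_that("all-zero residual yields a degenerate zero-coefficient atom", {
  ts <- tiny_setup()
  a <- best_match(numeric(ts$n), ts$dict)
  expect_true(a$degenerate)
  expect_equal(a$coeff, 0)
})

test_that("mismatched residual length and non-finite signals error", {
  ts <- tiny_setup()
  expect_error(best_match(numeric(10), ts$dict), "length")
  expect_error(mp_decompose(c(rnorm(ts$n - 1), NA), dictionary = ts$dict),
               "non-finite")
})

test_that("one exact atom is captured completely in one iteration", {
  ts <- tiny_setup()
  pr <- on_grid_params(ts$dict, 1, 0.8, 20)
  x <- 3 * gabor_waveform(pr$u, pr$s, pr$f, 0.3, ts$fs, ts$n)
  b <- mp_decompose(x, dictionary = ts$dict, M = 1)
  expect_lt(b$residual_energy / b$signal_energy, 1e-10)
})

test_that("energy is conserved for arbitrary signals and M", {
  ts <- tiny_setup()
  set.seed(5)
  for (rep in 1:4) {
    x <- rnorm(ts$n) + 2 * sin(2 * pi * 9 * (1:ts$n) / ts$fs)
    b <- mp_decompose(x, dictionary = ts$dict, M = 6)
    expect_lt(abs(b$signal_energy - sum(b$atoms$coeff^2) -
                    b$residual_energy) / b$signal_energy, 1e-6)
    expect_true(all(diff(b$atoms$coeff) <= 1e-9))  # greedy ordering
  }
})

test_that("two well-separated atoms are both recovered", {
  ts <- tiny_setup()
  p1 <- on_grid_params(ts$dict, 2, 0.35, 14)
  p2 <- on_grid_params(ts$dict, 2, 1.6, 11)
  x <- 10 * gabor_waveform(p1$u, p1$s, p1$f, 0, ts$fs, ts$n) +
    5 * gabor_waveform(p2$u, p2$s, p2$f, 1, ts$fs, ts$n)
  b <- mp_decompose(x, dictionary = ts$dict, M = 2)
  expect_equal(b$atoms$coeff[1], 10, tolerance = 0.02 * 10)
  expect_equal(b$atoms$coeff[2], 5, tolerance = 0.02 * 5)
  expect_equal(sort(b$atoms$u), sort(c(p1$u, p2$u)), tolerance = 1e-9)
})

test_that("iterating further never changes the leading atoms", {
  ts <- tiny_setup()
  set.seed(31)
  x <- rnorm(ts$n)
  b3 <- mp_decompose(x, dictionary = ts$dict, M = 3)
  b6 <- mp_decompose(x, dictionary = ts$dict, M = 6)
  expect_equal(b6$atoms[1:3, ], b3$atoms[1:3, ])
})

test_that("reconstruction inverts the decomposition", {
  ts <- tiny_setup()
  set.seed(12)
  x <- rnorm(ts$n)
  b <- mp_decompose(x, dictionary = ts$dict, M = 5)
  expect_equal(reconstruct(b, 0), numeric(ts$n))
  rec <- reconstruct(b)
  res <- x - rec
  expect_equal(res, residuals(b), tolerance = 1e-9)
  expect_equal(sum(res^2), b$residual_energy, tolerance = 1e-6)
  expect_equal(fitted(b), rec, tolerance = 1e-9)
  expect_equal(predict(b, 2),
               reconstruct(b, 2))
  expect_error(reconstruct(b, 99), "exceeds")
  # noiseless on-grid input reconstructs to float accuracy
  pr <- on_grid_params(ts$dict, 1, 1.1, 18)
  y <- 2 * gabor_waveform(pr$u, pr$s, pr$f, 0.4, ts$fs, ts$n)
  by <- mp_decompose(y, dictionary = ts$dict, M = 1)
  expect_lt(sqrt(sum((y - reconstruct(by))^2) / sum(y^2)), 1e-5)
})

test_that("book methods expose the atom table", {
  ts <- tiny_setup()
  set.seed(9)
  b <- mp_decompose(rnorm(ts$n), dictionary = ts$dict, M = 3)
  cf <- coef(b)
  expect_equal(dim(cf), c(3L, 5L))
  expect_identical(colnames(cf), c("u", "s", "f", "phi", "coeff"))
  s <- summary(b)
  expect_equal(s$n_atoms, 3L)
  expect_output(print(b), "Matching-pursuit book")
})

test_that("epoched decomposition places books on the recording timeline", {
  set.seed(77)
  fs <- 128
  x <- rnorm(6 * fs)
  books <- mp_decompose_recording(x, fs, epoch_length = 2, M = 2,
                                  epsilon = 0.2,
                                  scale_range = c(0.1, 0.5))
  expect_length(books, 3)
  expect_equal(vapply(books, function(b) b$epoch_start, numeric(1)),
               c(0, 2, 4))
  # trailing remainder >= 1 s gets its own shorter epoch
  books2 <- mp_decompose_recording(rnorm(3.5 * fs), fs, epoch_length = 2,
                                   M = 1, epsilon = 0.2,
                                   scale_range = c(0.1, 0.35))
  expect_length(books2, 2)
  expect_equal(books2[[2]]$epoch_length, 1.5)
})
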