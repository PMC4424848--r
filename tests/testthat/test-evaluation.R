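test_that("confusion counts cross-tabulate per sample", {
  m <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  cc <- confusion_counts(m, m)
  expect_equal(cc$FP, 0)
  expect_equal(cc$FN, 0)
  expect_equal(cc$TP, 3)
  cc2 <- confusion_counts(m, !m)
  expect_equal(cc2$TP, 0)
  expect_equal(cc2$TN, 0)
  set.seed(14)
  d <- runif(10000) < 0.2
  r <- runif(10000) < 0.1
  cc3 <- confusion_counts(d, r)
  ora <- oracle_confusion(d, r)
  expect_equal(cc3[c("TP", "TN", "FP", "FN")], ora)
  expect_equal(cc3$TP + cc3$TN + cc3$FP + cc3$FN, 10000)
  expect_error(confusion_counts(m, m[-1]), "length")
})

test_that("a perfect detector scores 1 on all five measures", {
  m <- compute_metrics(list(TP = 40, TN = 60, FP = 0, FN = 0))
  expect_equal(unname(unclass(m)[1:5]), rep(1, 5))
})

test_that("chance-level agreement gives zero MCC and kappa", {
  m <- compute_metrics(list(TP = 25, TN = 25, FP = 25, FN = 25))
  expect_equal(m[["mcc"]], 0)
  expect_equal(m[["kappa"]], 0)
})

test_that("the worked confusion example matches the frozen oracle values", {
  m <- compute_metrics(list(TP = 63, TN = 830, FP = 70, FN = 37))
  expect_equal(m[["sensitivity"]], 0.63, tolerance = 1e-10)
  expect_equal(m[["ppv"]], 0.4736842105, tolerance = 1e-9)
  expect_equal(m[["mcc"]], 0.4878651150, tolerance = 1e-9)
  expect_equal(m[["kappa"]], 0.4815891473, tolerance = 1e-9)
  expect_equal(m[["f1"]], 0.5407725322, tolerance = 1e-9)
})

test_that("zero denominators yield flagged undefined values, not zeros", {
  m <- compute_metrics(list(TP = 0, TN = 100, FP = 0, FN = 0))
  expect_true(is.na(m[["sensitivity"]]))
  expect_true(is.na(m[["ppv"]]))
  expect_true(is.na(m[["mcc"]]))
  expect_true("sensitivity" %in% attr(m, "undefined"))
  # detector that marks everything: PPV defined, MCC undefined (N = 0)
  m2 <- compute_metrics(list(TP = 10, TN = 0, FP = 90, FN = 0))
  expect_false(is.na(m2[["ppv"]]))
  expect_true(is.na(m2[["mcc"]]))
})

# small synthetic recordings shared by the threshold-selection tests;
# built once per test file
eval_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    preps <- lapply(1:3, function(i) {
      sim <- simulate_eeg(60, seed = 300 + i,
                          spindles = list(density = 3,
                                          amplitude = c(15, 55)))
      prepare_recording(sim$signal, sim$fs,
                        reference = sim$truth[, c("start", "end")],
                        epsilon = 0.2, M = 10, epoch_length = 20,
                        scale_range = c(0.1, 2))
    })
    cache <<- preps
    preps
  }
})

test_that("percentile optimization sweeps the grid exhaustively", {
  preps <- eval_fixture()
  grid <- seq(90, 99, by = 1)
  best <- optimal_percentile(preps, grid = grid)
  mcc <- attr(best, "mean_mcc")
  expect_length(mcc, length(grid))
  expect_equal(as.numeric(best), grid[which.max(mcc)])
  # grid of one value returns that value
  expect_equal(as.numeric(optimal_percentile(preps[1], grid = 95)), 95)
  # duplicated recordings give the same optimum as the single one
  one <- optimal_percentile(preps[1], grid = grid)
  two <- optimal_percentile(list(preps[[1]], preps[[1]]), grid = grid)
  expect_equal(as.numeric(one), as.numeric(two))
  expect_error(optimal_percentile(preps, grid = numeric()), "empty")
})

test_that("eval_at_percentile agrees with the full detection pipeline", {
  sim <- simulate_eeg(60, seed = 311,
                      spindles = list(density = 3, amplitude = c(40, 70)))
  prep <- prepare_recording(sim$signal, sim$fs,
                            reference = sim$truth[, c("start", "end")],
                            epsilon = 0.2, M = 10, epoch_length = 20,
                            scale_range = c(0.1, 2))
  m <- eval_at_percentile(prep, 95)
  ev <- detect_spindles(sim$signal, sim$fs, epsilon = 0.2, M = 10,
                        percentile = 95, epoch_length = 20,
                        scale_range = c(0.1, 2))
  det <- events_to_mask(ev, sim$fs, length(sim$signal))
  ref <- events_to_mask(sim$truth, sim$fs, length(sim$signal))
  m2 <- compute_metrics(confusion_counts(det, ref))
  expect_equal(unclass(m)[1:5], unclass(m2)[1:5])
  expect_equal(attr(m, "threshold"), attr(ev, "threshold"))
})

test_that("cross-validation is seeded, reproducible and leak-free", {
  preps <- eval_fixture()
  cv1 <- cross_validate(preps, n_iter = 8, n_train = 2,
                        grid = seq(90, 99, 1), seed = 5)
  cv2 <- cross_validate(preps, n_iter = 8, n_train = 2,
                        grid = seq(90, 99, 1), seed = 5)
  expect_equal(cv1$iterations, cv2$iterations)
  expect_equal(cv1$mean_percentile, cv2$mean_percentile)
  expect_error(cross_validate(preps, n_train = 3, seed = 1), "n_train")
})

test_that("identical recordings validate at their own training optimum", {
  preps <- eval_fixture()
  same <- list(preps[[1]], preps[[1]], preps[[1]])
  grid <- seq(90, 99, 1)
  cv <- cross_validate(same, n_iter = 4, n_train = 2, grid = grid,
                       seed = 2)
  opt <- as.numeric(optimal_percentile(same[1], grid = grid))
  expect_true(all(cv$iterations$percentile == opt))
  m_opt <- eval_at_percentile(preps[[1]], opt)
  expect_equal(cv$iterations$mcc, rep(m_opt[["mcc"]], 4))
})

test_that("reference annotations can be supplied as intervals or masks", {
  sim <- simulate_eeg(30, seed = 320,
                      spindles = list(density = 2, amplitude = c(40, 60)))
  ref_df <- data.frame(onset_s = sim$truth$start,
                       duration_s = sim$truth$end - sim$truth$start)
  p1 <- prepare_recording(sim$signal, sim$fs, reference = ref_df,
                          epsilon = 0.2, M = 5, epoch_length = 30,
                          scale_range = c(0.1, 2))
  mask <- events_to_mask(sim$truth, sim$fs, length(sim$signal))
  p2 <- prepare_recording(sim$signal, sim$fs, reference = mask,
                          epsilon = 0.2, M = 5, epoch_length = 30,
                          scale_range = c(0.1, 2))
  expect_equal(p1$ref_mask, p2$ref_mask)
})
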