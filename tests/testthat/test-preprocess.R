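make_raw <- function(data, fs = 1000, eog = character()) {
  raw_recording(data, fs = fs, eog_channels = eog)
}

test_that("average reference subtracts the instantaneous channel mean", {
  raw <- make_raw(matrix(c(1, 3), 2, 1))
  out <- rereference_average(raw)
  expect_equal(unname(out$data[, 1]), c(-1, 1))
  # zero-mean data unchanged
  x <- matrix(rnorm(50), 5, 10)
  x <- sweep(x, 2, colMeans(x))
  expect_equal(rereference_average(make_raw(x))$data, x,
               ignore_attr = TRUE)
  # defining property on random input
  out2 <- rereference_average(make_raw(matrix(rnorm(200), 8, 25)))
  expect_lt(max(abs(colSums(out2$data))), 1e-9)
  expect_error(rereference_average(out2), "already")
  expect_error(rereference_average(make_raw(matrix(1, 1, 10))),
               "at least 2")
})

test_that("EOG channels are excluded from the average reference", {
  x <- rbind(matrix(rnorm(40), 4, 10), 100)
  raw <- raw_recording(x, 1000, labels = c("E1", "E2", "E3", "E4", "EOG"),
                       eog_channels = "EOG")
  out <- rereference_average(raw)
  expect_equal(out$data["EOG", ], x[5, ])
  expect_lt(max(abs(colSums(out$data[1:4, ]))), 1e-9)
})

test_that("high-pass on a recording removes constant offsets", {
  raw <- make_raw(matrix(5, 3, 2000))
  out <- highpass_recording(raw, 1)
  expect_lt(max(abs(out$data)), 1e-6)
})

test_that("EOG regression recovers the mixing coefficient and decorrelates", {
  set.seed(1)
  fs <- 500
  n <- 5000
  eog <- bandpass_filter(rnorm(n), fs, c(1, 3))
  s <- bandpass_filter(rnorm(n), fs, "alpha")
  # make s orthogonal to EOG under the centered (covariance) inner product
  ec <- eog - mean(eog)
  s <- s - ec * sum((s - mean(s)) * ec) / sum(ec^2)
  ch <- s + 0.5 * eog
  raw <- raw_recording(rbind(ch, eog), fs, labels = c("E1", "EOG"),
                       eog_channels = "EOG")
  out <- regress_eog(raw)
  expect_equal(unname(out$data["E1", ]), s, tolerance = 1e-6)
  expect_lt(abs(cor(out$data["E1", ], eog)), 1e-10)
})

test_that("zero EOG leaves channels unchanged; constant EOG is skipped", {
  set.seed(2)
  x <- matrix(rnorm(300), 3, 100)
  raw <- raw_recording(rbind(x, rnorm(100)), 100,
                       labels = c("E1", "E2", "E3", "EOG"),
                       eog_channels = "EOG")
  # channels independent of EOG: coefficients ~ 0, channels ~ unchanged
  out <- regress_eog(raw)
  expect_equal(out$data[1:3, ], x, tolerance = 0.5, ignore_attr = TRUE)
  raw0 <- raw_recording(rbind(x, 0), 100,
                        labels = c("E1", "E2", "E3", "EOG"),
                        eog_channels = "EOG")
  expect_warning(out0 <- regress_eog(raw0), "constant EOG")
  expect_equal(out0$data[1:3, ], x, ignore_attr = TRUE)
  expect_error(regress_eog(make_raw(x)), "no EOG")
})

test_that("epoching partitions the recording and discards the remainder", {
  fs <- 100
  raw <- make_raw(matrix(rnorm(3 * 300 * fs), 3), fs = fs)
  es <- epoch_recording(raw, 2)
  expect_equal(dim(es$epochs), c(150, 3, 200))
  expect_true(all(es$status == "kept"))
  raw5 <- make_raw(matrix(seq_len(3 * 500), 3), fs = fs)
  es5 <- epoch_recording(raw5, 2)
  expect_equal(dim(es5$epochs)[1], 2)
  # concatenating epochs reproduces the first 4 s
  rebuilt <- cbind(es5$epochs[1, , ], es5$epochs[2, , ])
  expect_equal(rebuilt, raw5$data[, 1:400], ignore_attr = TRUE)
})

test_that("amplitude rejection is strict at the threshold", {
  x <- array(0, c(3, 2, 200))
  x[2, 1, 50] <- 80    # exceeds
  x[3, 2, 10] <- 75    # exactly at threshold: kept
  es <- epoch_set(x, fs = 100, labels = c("E1", "E2"), epoch_len_s = 2)
  out <- reject_amplitude(es, 75)
  expect_equal(out$status, c("kept", "rejected_amplitude", "kept"))
})

test_that("amplitude rejection ignores EOG channels", {
  x <- array(0, c(1, 2, 200))
  x[1, 2, 5] <- 200
  es <- epoch_set(x, fs = 100, labels = c("E1", "EOG"),
                  eog_channels = "EOG", epoch_len_s = 2)
  expect_equal(reject_amplitude(es, 75)$status, "kept")
})

test_that("drowsiness rejection keys on the theta/alpha power ratio", {
  fs <- 1000
  t <- (0:1999) / fs
  theta_ep <- matrix(sin(2 * pi * 6 * t), 1)
  alpha_ep <- matrix(sin(2 * pi * 10 * t), 1)
  x <- array(NA_real_, c(2, 1, 2000))
  x[1, 1, ] <- theta_ep
  x[2, 1, ] <- alpha_ep
  es <- epoch_set(x, fs = fs, labels = "E1", epoch_len_s = 2)
  out <- reject_drowsy(es)
  expect_equal(out$status, c("rejected_drowsy", "kept"))
})

test_that("epoch selection keeps the first n and errors when short", {
  x <- array(rnorm(120 * 2 * 100), c(120, 2, 100))
  es <- epoch_set(x, fs = 50, labels = c("E1", "E2"), epoch_len_s = 2)
  out <- select_epochs(es, 30)
  expect_equal(sum(out$status == "kept"), 30)
  expect_equal(sum(out$status == "not_selected"), 90)
  expect_true(all(which(out$status == "kept") == 1:30))
  es30 <- epoch_set(x[1:30, , , drop = FALSE], fs = 50,
                    labels = c("E1", "E2"), epoch_len_s = 2)
  expect_identical(select_epochs(es30, 30)$status, es30$status)
  es29 <- epoch_set(x[1:29, , , drop = FALSE], fs = 50,
                    labels = c("E1", "E2"), epoch_len_s = 2,
                    subject = "sub-07")
  expect_error(select_epochs(es29, 30), "sub-07")
})

test_that("screening recovers injected corruption exactly from ground truth", {
  fm <- make_forward_model(62, 150, 100, seed = 3)
  g <- coupling_spec("hc", drowsy_fraction = 0.2, artifact_rate = 0.1)
  cs <- cohort_spec(list(g), 1, duration_s = 80, fs = 200, seed = 55)
  coh <- simulate_cohort(cs, fm)
  gt <- coh$ground_truth[[1]]
  raw <- regress_eog(highpass_recording(rereference_average(
    coh$recordings[[1]]), 1))
  es <- reject_drowsy(reject_amplitude(epoch_recording(raw, 2), 75))
  expect_identical(sort(which(es$status == "rejected_amplitude")),
                   as.integer(gt$artifact))
  expect_identical(sort(which(es$status == "rejected_drowsy")),
                   as.integer(gt$drowsy))
  # status partition invariant
  expect_true(all(es$status %in% c("kept", "rejected_amplitude",
                                   "rejected_drowsy", "not_selected")))
  expect_length(es$status, 40)
})
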