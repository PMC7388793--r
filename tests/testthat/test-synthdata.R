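test_that("forward model satisfies its shape and determinism contracts", {
  fm <- make_forward_model(62, 500, 148, seed = 1)
  expect_equal(dim(fm$gain), c(62, 500))
  expect_length(unique(fm$node_seeds), 148)
  expect_true(all(fm$node_seeds %in% seq_len(500)))
  expect_identical(fm, make_forward_model(62, 500, 148, seed = 1))
  expect_error(make_forward_model(62, 100, 148), "must not exceed")
  expect_error(make_forward_model(4, 100, 10), "at least 8 sensors")
  # sensors on the unit sphere, sources inside [0.3, 0.9]
  expect_equal(rowSums(fm$sensor_pos^2), rep(1, 62))
  rad <- sqrt(rowSums(fm$source_pos^2))
  expect_true(all(rad >= 0.3 & rad <= 0.9))
})

test_that("gain column norms fall off with source depth", {
  fm <- make_forward_model(62, 500, 148, seed = 1)
  cn <- sqrt(colSums(fm$gain^2))
  depth <- 1 - sqrt(rowSums(fm$source_pos^2))
  qs <- quantile(depth, c(0.1, 0.9))
  expect_lt(mean(cn[depth >= qs[2]]), mean(cn[depth <= qs[1]]))
})

test_that("full coupling produces identical node signals and unit PLV", {
  fm <- make_forward_model(16, 60, 12, seed = 2)
  allb <- setNames(rep(1, 6), eeg_bands()$name)
  src <- simulate_coupled_sources(fm, coupling_spec("g", coupling = allb),
                                  duration_s = 4, fs = 250, seed = 3)
  # every node receives exactly the shared drivers
  for (i in 2:12) expect_equal(src[i, ], src[1, ], tolerance = 1e-12)
  cm <- plv_matrix(src[, 1:500], 250, "theta")
  expect_true(all(cm$W[upper.tri(cm$W)] > 0.99))
})

test_that("coupling level monotonically raises expected pairwise PLV", {
  fm <- make_forward_model(16, 60, 20, seed = 2)
  mean_plv <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(cth) {
    src <- simulate_coupled_sources(
      fm, coupling_spec("g", coupling = c(theta = cth)),
      duration_s = 12, fs = 250, seed = 31)
    ep <- array(NA_real_, c(6, 20, 500))
    for (e in 1:6) ep[e, , ] <- src[, ((e - 1) * 500 + 1):(e * 500)]
    W <- plv_matrix(ep, 250, "theta")$W
    mean(W[upper.tri(W)])
  }, numeric(1))
  expect_true(all(diff(mean_plv) > 0))
})

test_that("coupling_spec validates its knobs", {
  expect_error(coupling_spec(coupling = c(sigma = 0.5)), "band names")
  expect_error(coupling_spec(coupling = c(theta = 1.2)), "0, 1")
  expect_error(coupling_spec(drowsy_fraction = 2), "0, 1")
})

test_that("scalp projection is exact in the noiseless case", {
  fm <- make_forward_model(16, 60, 12, seed = 2)
  src <- simulate_coupled_sources(fm, coupling_spec("g"), 2, 250, seed = 4)
  raw <- project_to_scalp(fm, src, fs = 250, sensor_noise_sd = 0)
  expect_equal(unname(raw$data),
               unname(fm$gain[, fm$node_seeds] %*% src), tolerance = 1e-12)
  expect_equal(ncol(raw$data), ncol(src))
  expect_error(project_to_scalp(fm, src[1:3, ]), "one row per node seed")
})

test_that("EOG contamination shows up frontally and rides along as a channel", {
  fm <- make_forward_model(32, 100, 20, seed = 5)
  src <- simulate_coupled_sources(fm, coupling_spec("g"), 10, 250, seed = 6)
  eog <- simulate_eog(10, 250, seed = 7)
  raw <- project_to_scalp(fm, src, fs = 250, sensor_noise_sd = 1,
                          eog_signal = eog, eog_gain = 0.5, seed = 8)
  expect_identical(raw$eog_channels, "EOG")
  expect_equal(raw$data["EOG", ], eog)
  frontal_pole <- c(1, 0, 0.5) / sqrt(1.25)
  d <- sqrt(colSums((t(fm$sensor_pos) - frontal_pole)^2))
  front <- which.min(d)
  expect_gt(cor(raw$data[front, ], eog), 0.3)
})

test_that("cohort bookkeeping is exact and reproducible", {
  fm <- make_forward_model(16, 60, 12, seed = 2)
  g1 <- coupling_spec("pat", coupling = c(theta = 0.4),
                      drowsy_fraction = 0.2, artifact_rate = 0.1)
  g2 <- coupling_spec("ctl", coupling = c(theta = 0.1))
  cs <- cohort_spec(list(g1, g2), c(2, 3), duration_s = 20, fs = 200,
                    seed = 77)
  coh <- simulate_cohort(cs, fm)
  expect_length(coh$recordings, 5)
  expect_equal(coh$metadata$group, c("pat", "pat", "ctl", "ctl", "ctl"))
  # drowsy fraction 0.2 of 10 segments -> exactly 2 flagged in ground truth
  expect_length(coh$ground_truth[[1]]$drowsy, 2)
  expect_length(coh$ground_truth[[1]]$artifact, 1)
  expect_length(coh$ground_truth[[3]]$drowsy, 0)
  coh2 <- simulate_cohort(cs, fm)
  expect_identical(coh$recordings[[1]]$data, coh2$recordings[[1]]$data)
  expect_identical(coh$metadata, coh2$metadata)
  expect_error(cohort_spec(list(g1), 1, fs = 100), "twice the highest")
})
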