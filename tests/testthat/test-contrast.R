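test_that("raw squared contrast matches hand-computed moments", {
  expect_equal(compute_raw_contrast(matrix(128, 8, 8)), 0)
  # mu = 1, population variance = 1 -> K^2 = 1
  expect_equal(compute_raw_contrast(matrix(c(0, 2, 0, 2), 2)), 1)
  # masking restricts the statistics to the selected pixels
  fr <- matrix(c(1, 1, 5, 5), 2)
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(compute_raw_contrast(fr, mask), 0)
  expect_error(compute_raw_contrast(matrix(0, 4, 4)), "degenerate")
  expect_error(compute_raw_contrast(numeric(0)), "degenerate")
})

test_that("fully developed speckle has unit squared contrast", {
  set.seed(101)
  frame <- matrix(stats::rexp(4e6), 2000, 2000)
  expect_lt(abs(compute_raw_contrast(frame) - 1), 0.005)
})

test_that("instrumental variance terms follow the calibration forms", {
  cam <- camera_model(gain_e_per_dn = 2, read_noise_dn = 2, bit_depth = 8)
  fr <- matrix(100, 16, 16)
  nz <- compute_noise_contrasts(fr, cam)
  expect_equal(nz$k_shot_sq, 1 / 200)
  expect_equal(nz$k_quant_sq, (1 / 12) / 1e4)
  expect_equal(nz$k_cam_sq, 4 / 1e4)
  # infinite gain disables the shot term
  nzc <- compute_noise_contrasts(fr, cam_clean())
  expect_equal(nzc$k_shot_sq, 0)
  expect_error(compute_noise_contrasts(matrix(0, 4, 4), cam), "degenerate")
})

test_that("noise correction subtracts terms and flags non-positive results", {
  a <- adjust_contrast(0.05, 0.01, 0.001, 0.004)
  expect_equal(a$k_adj_sq, 0.035)
  expect_true(a$valid)
  b <- adjust_contrast(0.07, 0, 0, 0)
  expect_equal(b$k_adj_sq, 0.07)
  c <- adjust_contrast(0.005, 0.006, 0, 0)
  expect_false(c$valid)
  expect_error(adjust_contrast(-0.1, 0, 0, 0), "non-negative")
  # vectorized with mixed validity
  v <- adjust_contrast(c(0.05, 0.004), c(0.01, 0.005), c(0, 0), c(0, 0))
  expect_equal(v$valid, c(TRUE, FALSE))
})

test_that("CBFI is the reciprocal adjusted contrast with baseline normalization", {
  tr <- data.frame(time_s = seq(0, 0.9, by = 0.1),
                   k_adj_sq = rep(0.04, 10), valid = rep(TRUE, 10))
  fl <- compute_cbfi(tr, baseline_window = c(0, 0.5))
  expect_equal(fl$cbfi, rep(25, 10))
  expect_equal(fl$cbfi_normalized, rep(1, 10))
  # invalid samples are excluded, never propagated as numbers
  tr$valid[3] <- FALSE
  fl2 <- compute_cbfi(tr, c(0, 0.5))
  expect_true(is.na(fl2$cbfi[3]))
  expect_false(anyNA(fl2$cbfi[fl2$valid]))
  tr_bad <- data.frame(time_s = 0:1, k_adj_sq = c(0.1, 0.1),
                       valid = c(FALSE, FALSE))
  expect_error(compute_cbfi(tr_bad, c(0, 1)), "baseline")
})

test_that("process_stack yields one sample per frame on the frame clock", {
  p <- params_at_x(2, c(48, 48), mean_level = 100)
  st <- simulate_speckle_stack(p, cam8(), cardiac_waveform(60, 5, 40),
                               n_frames = 200, seed = 61)
  pr <- process_stack(st, baseline_window = c(0, 5))
  expect_equal(nrow(pr$contrast), 200)
  expect_equal(pr$contrast$time_s, (0:199) / 40)
  expect_equal(max(pr$contrast$time_s), 4.975)
  expect_true(all(pr$contrast$k_adj_sq <= pr$contrast$k_raw_sq))
  expect_false(anyNA(pr$flow$cbfi_normalized[pr$flow$valid]))
})

test_that("noise correction makes the contrast independent of the mean level", {
  # identical dynamics at two intensities: raw contrast separates, adjusted
  # contrast agrees (x = 20, away from the 8-bit saturation tail)
  run <- function(lvl, seed) {
    p <- speckle_params(tau_c = 3e-4, mean_level = lvl, frame_shape = c(64, 64),
                        vol_coupling = 0)
    st <- simulate_speckle_stack(p, cam8(), NULL, n_frames = 24, seed = seed)
    pr <- process_stack(st, baseline_window = c(0, 1))
    list(raw = mean(pr$contrast$k_raw_sq), adj = pr$contrast$k_adj_sq)
  }
  lo <- run(50, 71)
  hi <- run(150, 72)
  expect_gt(lo$raw / mean(hi$adj), 1.2)
  se <- sqrt(stats::var(lo$adj) / 24 + stats::var(hi$adj) / 24)
  expect_lt(abs(mean(lo$adj) - mean(hi$adj)), 3 * se)
  # raw contrast is ordered inversely with intensity
  expect_gt(lo$raw, mean(hi$adj))
})

test_that("doubling the flow doubles CBFI in the deep linear regime", {
  cbfi_at <- function(flow, seed) {
    wf <- steady_waveform(1)
    wf$relative_flow[] <- flow
    p <- speckle_params(tau_c = 6e-4, mean_level = 100, frame_shape = c(96, 96),
                        vol_coupling = 0)
    st <- simulate_speckle_stack(p, cam8(), wf, n_frames = 16, seed = seed)
    pr <- process_stack(st, baseline_window = c(0, 1))
    mean(pr$flow$cbfi[pr$flow$valid])
  }
  ratio <- cbfi_at(2, 81) / cbfi_at(1, 82)
  expect_lt(abs(ratio - 2), 0.1)
})
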