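test_that("KL weights reproduce the closed-form visibility curve exactly", {
  for (x in c(0.05, 0.5, 2, 10, 30)) {
    kl <- scosflow:::speckle_kl_weights(x)
    total_mean <- sum(kl$lambda) + kl$tail_w + kl$tail_const
    total_var <- sum(kl$lambda^2) + kl$tail_w^2
    expect_lt(abs(total_mean - 1), 1e-9)
    expect_lt(abs(total_var - theoretical_contrast(x)) / theoretical_contrast(x), 1e-9)
  }
})

test_that("identical parameters and seed give bit-identical stacks", {
  p <- params_at_x(2, frame_shape = c(32, 32), mean_level = 100)
  wf <- cardiac_waveform(60, 0.2, 40)
  a <- simulate_speckle_stack(p, cam8(), wf, n_frames = 6, seed = 77)
  b <- simulate_speckle_stack(p, cam8(), wf, n_frames = 6, seed = 77)
  expect_identical(a$frames, b$frames)
  c2 <- simulate_speckle_stack(p, cam8(), wf, n_frames = 6, seed = 78)
  expect_false(identical(a$frames, c2$frames))
})

test_that("mean frame intensity tracks the requested mean level", {
  for (lvl in c(60, 120)) {
    p <- params_at_x(1, frame_shape = c(64, 64), mean_level = lvl)
    st <- simulate_speckle_stack(p, cam8(), NULL, n_frames = 8, seed = 21)
    expect_lt(abs(mean(st$frames) / lvl - 1), 0.02)
  }
})

test_that("static configuration hits the contrast ceiling; fast dynamics wash it out", {
  bh <- measure_beta_hat(cam_clean(), frame_shape = c(128, 128), n = 12)
  st <- simulate_speckle_stack(params_at_x(0, c(128, 128)), cam_clean(),
                               NULL, n_frames = 4, seed = 31)
  # frozen pattern: all frames carry the same speckle realization
  expect_lt(max(abs(st$frames[, , 1] - st$frames[, , 4])), 2)
  k2_static <- compute_raw_contrast(st$frames[, , 1])
  expect_lt(abs(k2_static / bh$beta_hat - 1), 0.1)

  fast <- simulate_speckle_stack(params_at_x(50, c(128, 128)), cam_clean(),
                                 NULL, n_frames = 4, seed = 32)
  expect_lt(mean_k_raw(fast), 0.05 * bh$beta_hat)
})

test_that("measured contrast is strictly decreasing in the exposure-to-decorrelation ratio", {
  xs <- c(0.1, 0.3, 1, 3, 10)
  k2 <- vapply(seq_along(xs), function(i) {
    st <- simulate_speckle_stack(params_at_x(xs[i], c(96, 96)), cam_clean(),
                                 NULL, n_frames = 8, seed = 40 + i)
    mean_k_raw(st)
  }, numeric(1))
  expect_true(all(diff(k2) < 0))
})

test_that("Monte-Carlo contrast matches the visibility oracle within 3 standard errors", {
  shape <- c(256, 256)
  bh <- measure_beta_hat(cam_clean(), frame_shape = shape, n = 32, seed0 = 900)
  for (x in c(0.1, 1, 10)) {
    st <- simulate_speckle_stack(params_at_x(x, shape), cam_clean(), NULL,
                                 n_frames = 64, seed = 1000 + round(10 * x))
    k2 <- apply(st$frames, 3, compute_raw_contrast)
    m <- mean(k2)
    theo <- theoretical_contrast(x, bh$beta_hat)
    se <- sqrt(stats::var(k2) / length(k2) + (theo / bh$beta_hat * bh$se)^2)
    expect_lt(abs(m - theo), 3 * se)
  }
})

test_that("simulator rejects invalid configurations", {
  p <- params_at_x(1, c(32, 32), mean_level = 100)
  expect_error(simulate_speckle_stack(p, cam8(), NULL, n_frames = 0, seed = 1),
               "n_frames")
  psat <- params_at_x(1, c(32, 32), mean_level = 300)
  expect_error(simulate_speckle_stack(psat, cam8(), NULL, 2, seed = 1),
               "saturation")
  wf_short <- cardiac_waveform(60, 0.5, 40)
  expect_error(simulate_speckle_stack(p, cam8(), wf_short, n_frames = 40, seed = 1),
               "cover")
  expect_error(speckle_params(tau_c = -1), "tau_c")
  expect_error(speckle_params(tau_c = 1, sp_ratio = 3), "sp_ratio")
  expect_error(speckle_params(tau_c = 1, exposure_T = 0.05, frame_rate = 40),
               "frame period")
})

test_that("scene channels scale with transmission and share the frame grid", {
  wf <- cardiac_waveform(60, 2, 40)
  p <- speckle_params(tau_c = 3e-3, mean_level = 100, frame_shape = c(32, 32))
  sc <- scene_spec(n_channels = 3, waveform = wf,
                   transmission = c(1, 0.5, 1), seed = 9)
  stacks <- simulate_scene(sc, p, cam8())
  expect_named(stacks, c("ch1", "ch2", "ch3"))
  expect_equal(dim(stacks$ch1$frames), dim(stacks$ch2$frames))
  ratio <- mean(stacks$ch2$frames) / mean(stacks$ch1$frames)
  expect_lt(abs(ratio - 0.5), 0.02)
  expect_error(scene_spec(n_channels = 3, waveform = wf,
                          transmission = c(1, 2)), "channel count mismatch")
  expect_error(scene_spec(n_channels = 3, waveform = wf,
                          altered_channels = 1), "altered_waveform")
})
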