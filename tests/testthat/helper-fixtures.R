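# Shared fixtures: cameras and small parameter sets used across test files.
# Everything is generated in code; no binary fixtures.

cam8 <- function() camera_model(gain_e_per_dn = 2, read_noise_dn = 1.5, bit_depth = 8)

# Noise-free reference sensor: no shot noise (infinite gain), no read noise,
# 16-bit so quantization is negligible at a mean of ~1000 DN.
cam_clean <- function() camera_model(gain_e_per_dn = Inf, read_noise_dn = 0,
                                     bit_depth = 16)

# Small-frame parameter set at a given exposure-to-decorrelation ratio x.
params_at_x <- function(x, frame_shape = c(96, 96), mean_level = 1000,
                        vol_coupling = 0) {
  speckle_params(tau_c = if (x == 0) Inf else 6e-3 / x,
                 mean_level = mean_level, frame_shape = frame_shape,
                 vol_coupling = vol_coupling)
}

# Mean raw squared contrast over the frames of a stack.
mean_k_raw <- function(stack) {
  mean(apply(stack$frames, 3, compute_raw_contrast))
}

# Contrast ceiling measured from the static configuration: independent
# frozen patterns from `n` seeds.
measure_beta_hat <- function(camera, frame_shape = c(96, 96),
                             mean_level = 1000, n = 16, seed0 = 5000) {
  k2 <- vapply(seq_len(n), function(s) {
    st <- simulate_speckle_stack(params_at_x(0, frame_shape, mean_level),
                                 camera, NULL, n_frames = 1, seed = seed0 + s)
    pr <- process_stack(st, camera, baseline_window = c(0, 1))
    pr$contrast$k_adj_sq[1]
  }, numeric(1))
  list(beta_hat = mean(k2), se = stats::sd(k2) / sqrt(n))
}
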