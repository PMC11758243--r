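# Direct-summation Pearson oracle (moment form), independent of stats::cor.
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

test_that("pearson correlation matches the direct-summation oracle to 1e-12", {
  set.seed(202)
  for (i in 1:20) {
    x <- stats::rnorm(100)
    y <- stats::rnorm(100) + 0.5 * x
    expect_lt(abs(pearson_correlation(x, y) - pearson_oracle(x, y)), 1e-12)
  }
})

test_that("pearson correlation limits, invariances and errors", {
  x <- stats::rnorm(50)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  # affine invariance: rho(a x + b, y) = sign(a) rho(x, y)
  y <- stats::rnorm(50)
  expect_equal(pearson_correlation(3 * x + 7, y), pearson_correlation(x, y))
  expect_equal(pearson_correlation(-2 * x + 1, y), -pearson_correlation(x, y))
  # independent white noise decorrelates as 1/sqrt(T)
  set.seed(303)
  a <- stats::rnorm(1e4)
  b <- stats::rnorm(1e4)
  expect_lt(abs(pearson_correlation(a, b)), 0.05)
  expect_error(pearson_correlation(rep(1, 10), stats::rnorm(10)), "constant")
  expect_error(pearson_correlation(1:5, 1:6), "length mismatch")
  # complete-case: NA in either trace drops the sample pairwise
  xa <- c(x, NA)
  yb <- c(y, 100)
  expect_equal(pearson_correlation(xa, yb), pearson_correlation(x, y))
})

make_set <- function(traces, intensities = NULL) {
  labels <- names(traces)
  flow <- lapply(traces, function(v) {
    f <- data.frame(time_s = seq_along(v), cbfi = v, cbfi_normalized = v,
                    valid = !is.na(v))
    class(f) <- c("flow_trace", "data.frame")
    f
  })
  if (is.null(intensities)) intensities <- stats::setNames(rep(100, length(traces)), labels)
  structure(list(flow = flow, volume = NULL, mean_intensity = intensities,
                 frame_rate = 1), class = "channel_set")
}

test_that("correlation matrix covers all unordered pairs with unit diagonal", {
  set.seed(404)
  for (n in 2:8) {
    traces <- stats::setNames(lapply(seq_len(n), function(i) stats::rnorm(60)),
                              sprintf("ch%d", seq_len(n)))
    res <- correlation_matrix(make_set(traces))
    expect_equal(res$n_pairs, choose(n, 2))
    expect_equal(unname(diag(res$matrix)), rep(1, n))
    expect_equal(res$matrix, t(res$matrix))
    expect_true(all(abs(res$matrix) <= 1 + 1e-12))
  }
  # two identical channels
  tr <- stats::rnorm(30)
  res2 <- correlation_matrix(make_set(list(a = tr, b = tr)))
  expect_equal(unname(res2$matrix), matrix(1, 2, 2))
})

test_that("two-channel summary pairs correlation with mean intensity", {
  set.seed(405)
  traces <- stats::setNames(lapply(1:6, function(i) stats::rnorm(50)),
                            sprintf("ch%d", 1:6))
  sm <- two_channel_summary(make_set(traces))
  expect_equal(nrow(sm), 15)
  expect_equal(unique(sm$pair_mean_intensity_dn), 100)
})

test_that("channel grouping is the connected components above the threshold", {
  base <- stats::rnorm(200)
  alt <- stats::rnorm(200)
  noisy <- function(v) v + 0.2 * stats::rnorm(length(v))
  set.seed(406)
  traces <- list(ch1 = noisy(alt), ch2 = noisy(alt),
                 ch3 = noisy(base), ch4 = noisy(base),
                 ch5 = noisy(base), ch6 = noisy(base))
  res <- correlation_matrix(make_set(traces))
  g <- group_channels(res, threshold = 0.6)
  g <- lapply(g, sort)
  expect_length(g, 2)
  expect_true(any(vapply(g, identical, logical(1), c("ch1", "ch2"))))
  expect_true(any(vapply(g, identical, logical(1), c("ch3", "ch4", "ch5", "ch6"))))
  # threshold above 1: no edges, all singletons
  expect_length(group_channels(res, threshold = 1.1), 6)
})

test_that("low mean intensity does not by itself destroy correlation", {
  # injured pair: shared independent waveform AND strong attenuation;
  # within-pair correlation survives while cross-group correlation drops
  wf <- cardiac_waveform(60, 8, 40)
  wf_alt <- cardiac_waveform(80, 8, 40, phase = 0.4)
  p <- speckle_params(tau_c = 3e-3, mean_level = 100, frame_shape = c(64, 64))
  sc <- scene_spec(n_channels = 4, waveform = wf,
                   transmission = c(0.3, 0.3, 1, 1),
                   altered_waveform = wf_alt, altered_channels = c(1, 2),
                   seed = 17)
  set <- process_scene(simulate_scene(sc, p, cam8()), baseline_window = c(0, 4))
  res <- correlation_matrix(set)
  M <- res$matrix
  cross <- c(M[1, 3], M[1, 4], M[2, 3], M[2, 4])
  expect_gt(M[1, 2], 0.6)              # dim but coherent pair stays correlated
  expect_gt(M[1, 2], max(cross) + 0.1) # physiology, not intensity, drives rho
  expect_gt(M[3, 4], 0.75)
  # pair intensities reflect the attenuation
  sm <- res$pairs
  dim_pair <- sm$chan_i == "ch1" & sm$chan_j == "ch2"
  expect_lt(sm$pair_mean_intensity_dn[dim_pair], 50)
})
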