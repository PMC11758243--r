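#' Closed-form speckle visibility curve
#'
#' Expected squared speckle contrast of an exposure-integrated,
#' exponentially decorrelating speckle field (single-scattering Lorentzian
#' line shape via the Siegert relation):
#' `K2(x) = beta * (exp(-2x) - 1 + 2x) / (2 x^2)` with
#' `x = T / tau_c` the exposure-to-decorrelation-time ratio. The removable
#' singularity at `x = 0` evaluates to `beta`; for large `x` the curve
#' approaches `beta / x`. This is the independent oracle the simulator is
#' tested against.
#'
#' @param x Non-negative exposure-to-decorrelation ratio(s) `T / tau_c`.
#' @param beta Contrast ceiling in (0, 1].
#' @return Expected squared contrast, same length as `x`.
#' @examples
#' theoretical_contrast(0)          # beta
#' theoretical_contrast(1)          # (exp(-2) + 1) / 2
#' theoretical_contrast(100)        # ~ 1/100
#' @export
theoretical_contrast <- function(x, beta = 1) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    stop("`x` must be numeric and >= 0", call. = FALSE)
  }
  stopifnot_scalar(beta, "beta", positive = TRUE)
  if (beta > 1) stop("`beta` must be in (0, 1]", call. = FALSE)
  out <- numeric(length(x))
  small <- x < 1e-3
  # series about x = 0 avoids catastrophic cancellation
  xs <- x[small]
  out[small] <- 1 - (2 / 3) * xs + (1 / 3) * xs^2 - (2 / 15) * xs^3
  xl <- x[!small]
  out[!small] <- (exp(-2 * xl) - 1 + 2 * xl) / (2 * xl^2)
  beta * out
}

# --- Karhunen-Loeve machinery -------------------------------------------
#
# The complex field over one exposure is a stationary Gaussian process with
# autocorrelation g1(dt) = exp(-|dt| / tau). Its Karhunen-Loeve eigenmodes
# on the exposure window are known in closed form (Ornstein-Uhlenbeck
# kernel): with a = T/2, b = x/2, v = w*a, the eigenvalues are
# lambda = b / (v^2 + b^2) where v solves v*tan(v) = b (even modes) or
# tan(v) = -v/b (odd modes), one root per half-pi interval. The
# exposure-averaged intensity at a point is then sum_m lambda_m |z_m|^2
# with z_m iid unit complex Gaussians, so each mode contributes one
# independent speckle pattern weighted by lambda_m. Truncated tail mass is
# replaced by one variance-matched extra mode plus a deterministic
# constant, which keeps both the mean and the expected K^2 exact.
speckle_kl_weights <- function(x, rel_tol = 0.02, max_modes = 4096L) {
  b <- x / 2
  k2_exact <- theoretical_contrast(x, beta = 1)
  f_even <- function(v) v * sin(v) - b * cos(v)
  f_odd <- function(v) v * cos(v) + b * sin(v)
  lambda <- numeric(0)
  cutoff <- NA_real_
  k <- 0L
  repeat {
    lo <- k * pi + 1e-10
    hi <- k * pi + pi / 2 - 1e-10
    r <- stats::uniroot(f_even, c(lo, hi), tol = 1e-13)$root
    l1 <- b / (r^2 + b^2)
    if (is.na(cutoff)) cutoff <- rel_tol * l1
    done <- FALSE
    if (l1 >= cutoff) lambda <- c(lambda, l1) else done <- TRUE
    r2 <- stats::uniroot(f_odd, c(k * pi + pi / 2 + 1e-10, (k + 1) * pi - 1e-10),
                         tol = 1e-13)$root
    l2 <- b / (r2^2 + b^2)
    if (l2 >= cutoff && !done) lambda <- c(lambda, l2) else done <- TRUE
    k <- k + 1L
    if (done || length(lambda) >= max_modes) break
  }
  s1 <- max(0, 1 - sum(lambda))
  vt <- max(0, k2_exact - sum(lambda^2))
  tail_w <- sqrt(vt)
  tail_const <- s1 - tail_w
  if (tail_const < 0) {
    # tail too heavy for the variance-matched single mode; absorb the
    # mismatch into the stochastic weight (bias < rel_tol^2, not reached at
    # the default tolerance)
    tail_w <- s1
    tail_const <- 0
  }
  list(lambda = lambda, tail_w = tail_w, tail_const = tail_const)
}

# FFT frequency coordinates in cycles per sample.
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  ifelse(k > n / 2, k - n, k) / n
}

# Pupil support for the spatial speckle statistics: indices of Fourier
# coefficients inside the disc of radius f_c (cycles per fine pixel). The
# one-dimensional speckle size is 1/(2 f_c) fine pixels.
make_pupil <- function(nr, nc, f_c) {
  fr <- fft_freqs(nr)
  fc <- fft_freqs(nc)
  which(outer(fr^2, fc^2, "+") <= f_c^2 + 1e-12)
}

# One unit-mean speckle intensity pattern on the fine grid: pupil-filtered
# white complex Gaussian field, |.|^2.
speckle_pattern <- function(nr, nc, pupil_idx) {
  np <- length(pupil_idx)
  W <- matrix(0 + 0i, nr, nc)
  W[pupil_idx] <- complex(real = stats::rnorm(np, sd = sqrt(0.5)),
                          imaginary = stats::rnorm(np, sd = sqrt(0.5)))
  a <- stats::fft(W, inverse = TRUE) / sqrt(np)
  Re(a)^2 + Im(a)^2
}

# Average u x u blocks of a matrix (pixel integration of the fine grid).
bin_mean <- function(m, u) {
  if (u == 1L) return(m)
  nr <- nrow(m) %/% u
  nc <- ncol(m) %/% u
  dim(m) <- c(u, nr, u * nc)
  m <- colSums(m)                 # [nr, u*nc]
  dim(m) <- c(nr, u, nc)
  m <- aperm(m, c(2, 1, 3))
  dim(m) <- c(u, nr * nc)
  m <- colSums(m)
  dim(m) <- c(nr, nc)
  m / u^2
}

#' Simulate a dynamic-speckle frame stack
#'
#' Forward model for one SCOS channel. The optical stage draws, for each
#' frame, the exposure-integrated intensity of an exponentially
#' decorrelating complex Gaussian speckle field (decorrelation time
#' `tau_c / relative_flow(t)`, held fixed within one exposure) whose
#' spatial statistics are set by pupil filtering so the speckle-to-pixel
#' length ratio equals `sp_ratio`; speckle smaller than a pixel is
#' generated on an upsampled grid and integrated over the pixel area. The
#' sensor stage converts to electrons via the conversion gain, applies
#' Poisson shot noise, adds Gaussian read/dark noise, converts back to DN,
#' quantizes to the camera bit depth (rounding) and clips at saturation.
#'
#' With `tau_c = Inf` (static sentinel) the speckle pattern is frozen for
#' the whole recording and the expected squared contrast equals the
#' contrast ceiling; for finite `tau_c` it follows the closed-form
#' visibility curve [theoretical_contrast()] at
#' `x = exposure_T * relative_flow(t) / tau_c`.
#'
#' @param params A [speckle_params()].
#' @param camera A [camera_model()].
#' @param waveform A `flow_waveform` covering the recording, or `NULL` for
#'   steady flow.
#' @param n_frames Number of frames to generate.
#' @param seed Integer seed; identical inputs give bit-identical stacks.
#' @return A [frame_stack()].
#' @examples
#' p <- speckle_params(tau_c = 3e-3, frame_shape = c(64, 64))
#' st <- simulate_speckle_stack(p, camera_model(), n_frames = 8, seed = 1)
#' @export
simulate_speckle_stack <- function(params, camera, waveform = NULL, n_frames,
                                   seed) {
  if (!inherits(params, "speckle_params")) stop("`params` must be speckle_params", call. = FALSE)
  if (!inherits(camera, "camera_model")) stop("`camera` must be a camera_model", call. = FALSE)
  stopifnot_scalar(n_frames, "n_frames", positive = TRUE)
  if (n_frames != round(n_frames)) stop("`n_frames` must be an integer", call. = FALSE)
  stopifnot_scalar(seed, "seed")
  if (params$mean_level >= camera$max_dn) {
    stop("saturation: `mean_level` must be below the camera saturation level",
         call. = FALSE)
  }
  times <- (seq_len(n_frames) - 1) / params$frame_rate
  if (is.null(waveform)) {
    flows <- rep(1, n_frames)
  } else {
    if (!inherits(waveform, "flow_waveform")) {
      stop("`waveform` must be a flow_waveform or NULL", call. = FALSE)
    }
    if (max(waveform$time_s) < times[n_frames] - 1e-9) {
      stop("`waveform` does not cover the requested recording duration",
           call. = FALSE)
    }
    flows <- waveform_at(waveform, times)
  }
  if (any(flows <= 0)) stop("relative flow must be > 0 everywhere", call. = FALSE)

  rows <- params$frame_shape[1]
  cols <- params$frame_shape[2]
  u <- max(1L, as.integer(ceiling(1 / params$sp_ratio - 1e-9)))
  nr <- rows * u
  nc <- cols * u
  f_c <- 1 / (2 * params$sp_ratio * u)     # cycles per fine pixel
  pupil_idx <- make_pupil(nr, nc, f_c)
  rho_c <- sqrt(params$beta)
  g <- camera$gain_e_per_dn
  rn <- camera$read_noise_dn
  npix <- rows * cols

  with_seed(seed, {
    out <- array(0L, dim = c(rows, cols, n_frames))
    static_P <- NULL
    for (t in seq_len(n_frames)) {
      x_t <- if (is.finite(params$tau_c)) {
        params$exposure_T * flows[t] / params$tau_c
      } else 0
      if (x_t < 1e-10) {
        if (is.null(static_P)) static_P <- bin_mean(speckle_pattern(nr, nc, pupil_idx), u)
        P <- static_P
      } else {
        kl <- speckle_kl_weights(x_t)
        Ff <- matrix(0, nr, nc)
        for (lam in kl$lambda) Ff <- Ff + lam * speckle_pattern(nr, nc, pupil_idx)
        if (kl$tail_w > 0) Ff <- Ff + kl$tail_w * speckle_pattern(nr, nc, pupil_idx)
        P <- bin_mean(Ff, u) + kl$tail_const
      }
      if (rho_c < 1) P <- (1 - rho_c) + rho_c * P
      lvl <- params$mean_level * (1 - params$vol_coupling * (flows[t] - 1))
      if (lvl <= 0) stop("volume coupling drove the mean level below zero", call. = FALSE)
      I <- lvl * P
      if (is.finite(g)) I <- stats::rpois(npix, I * g) / g
      if (rn > 0) I <- I + stats::rnorm(npix, sd = rn)
      Iq <- as.integer(pmin.int(pmax.int(round(I), 0), camera$max_dn))
      out[, , t] <- Iq
    }
    fs <- frame_stack(out, frame_rate = params$frame_rate,
                      exposure_T = params$exposure_T, camera = camera)
    attr(fs, "ground_truth") <- list(flows = flows, params = params, seed = seed)
    fs
  })
}

#' Multi-channel scene description
#'
#' Layout of a synthetic multi-channel recording: how many channels, their
#' optical transmission scales, which waveform drives each channel (a
#' shared baseline waveform, or an independent "altered" waveform for
#' designated injured-region channels), per-channel delays, and the seed.
#'
#' @param n_channels Number of channels (>= 1).
#' @param waveform Baseline `flow_waveform` shared by healthy channels.
#' @param transmission Per-channel transmission scale multiplying the mean
#'   level (length 1 or `n_channels`, all > 0).
#' @param altered_waveform Optional independent `flow_waveform` assigned to
#'   `altered_channels`.
#' @param altered_channels Integer indices of channels driven by
#'   `altered_waveform`.
#' @param delays Per-channel time shifts in seconds (length 1 or
#'   `n_channels`).
#' @param labels Channel labels; default `ch1..chN`.
#' @param seed Integer seed; per-channel seeds are derived from it.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(n_channels = 6, waveform, transmission = 1,
                       altered_waveform = NULL, altered_channels = integer(0),
                       delays = 0, labels = NULL, seed = 1) {
  stopifnot_scalar(n_channels, "n_channels", positive = TRUE)
  n_channels <- as.integer(n_channels)
  if (!inherits(waveform, "flow_waveform")) stop("`waveform` must be a flow_waveform", call. = FALSE)
  if (length(transmission) == 1L) transmission <- rep(transmission, n_channels)
  if (length(transmission) != n_channels) {
    stop("channel count mismatch: `transmission` must have length 1 or n_channels",
         call. = FALSE)
  }
  if (any(transmission <= 0)) stop("transmission scales must be > 0", call. = FALSE)
  if (length(delays) == 1L) delays <- rep(delays, n_channels)
  if (length(delays) != n_channels) {
    stop("channel count mismatch: `delays` must have length 1 or n_channels",
         call. = FALSE)
  }
  if (length(altered_channels)) {
    altered_channels <- as.integer(altered_channels)
    if (any(altered_channels < 1 | altered_channels > n_channels)) {
      stop("`altered_channels` out of range", call. = FALSE)
    }
    if (is.null(altered_waveform)) {
      stop("`altered_waveform` required when `altered_channels` is non-empty",
           call. = FALSE)
    }
    if (!inherits(altered_waveform, "flow_waveform")) {
      stop("`altered_waveform` must be a flow_waveform", call. = FALSE)
    }
  }
  if (is.null(labels)) labels <- sprintf("ch%d", seq_len(n_channels))
  if (length(labels) != n_channels || anyDuplicated(labels)) {
    stop("`labels` must be n_channels unique strings", call. = FALSE)
  }
  stopifnot_scalar(seed, "seed")
  structure(
    list(n_channels = n_channels, waveform = waveform,
         transmission = transmission, altered_waveform = altered_waveform,
         altered_channels = altered_channels, delays = delays,
         labels = labels, seed = seed),
    class = "scene_spec"
  )
}

# Shift a waveform in time by `delay` seconds (circular, sample-quantized).
shift_waveform <- function(waveform, delay) {
  if (abs(delay) < 1e-12) return(waveform)
  n <- length(waveform$relative_flow)
  k <- round(delay * waveform$frame_rate) %% n
  if (k == 0) return(waveform)
  waveform$relative_flow <- c(waveform$relative_flow[(n - k + 1):n],
                              waveform$relative_flow[seq_len(n - k)])
  waveform
}

#' Simulate a multi-channel scene
#'
#' Generates one frame stack per channel of a [scene_spec()]. Channels
#' sharing the baseline waveform carry synchronized flow dynamics (their
#' CBFI traces are strongly correlated after processing); channels assigned
#' the altered waveform carry independent dynamics; per-channel mean
#' intensity scales with the transmission scale.
#'
#' @param scene A [scene_spec()].
#' @param params A [speckle_params()] (mean level is per-channel scaled by
#'   the transmission).
#' @param camera A [camera_model()].
#' @return A named list of [frame_stack()]s (class `scene_stacks`) with the
#'   per-channel ground-truth waveforms attached.
#' @export
simulate_scene <- function(scene, params, camera) {
  if (!inherits(scene, "scene_spec")) stop("`scene` must be a scene_spec", call. = FALSE)
  if (!inherits(params, "speckle_params")) stop("`params` must be speckle_params", call. = FALSE)
  if (abs(scene$waveform$frame_rate - params$frame_rate) > 1e-9) {
    stop("waveform frame rate must match the simulation frame rate", call. = FALSE)
  }
  nf <- length(scene$waveform$relative_flow)
  stacks <- vector("list", scene$n_channels)
  waveforms <- vector("list", scene$n_channels)
  for (ch in seq_len(scene$n_channels)) {
    wf <- if (ch %in% scene$altered_channels) scene$altered_waveform else scene$waveform
    wf <- shift_waveform(wf, scene$delays[ch])
    p_ch <- params
    p_ch$mean_level <- params$mean_level * scene$transmission[ch]
    if (p_ch$mean_level >= camera$max_dn) {
      stop("saturation: scaled mean level exceeds the camera range", call. = FALSE)
    }
    st <- simulate_speckle_stack(p_ch, camera, wf, n_frames = nf,
                                 seed = derive_seed(scene$seed, ch))
    st$channel_id <- scene$labels[ch]
    stacks[[ch]] <- st
    waveforms[[ch]] <- wf
  }
  names(stacks) <- scene$labels
  names(waveforms) <- scene$labels
  structure(stacks, class = "scene_stacks", scene = scene, waveforms = waveforms)
}
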