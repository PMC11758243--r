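#' Pearson correlation of two channel traces
#'
#' Standard Pearson coefficient between two equally long time traces,
#' computed on jointly valid samples (complete-case: a sample flagged
#' invalid in either channel is dropped from both).
#'
#' @param trace_i,trace_j Numeric vectors of equal length (NA = invalid
#'   sample).
#' @return Correlation coefficient in [-1, 1].
#' @examples
#' pearson_correlation(1:10, 2 * (1:10) + 3)   # 1
#' @export
pearson_correlation <- function(trace_i, trace_j) {
  if (!is.numeric(trace_i) || !is.numeric(trace_j)) {
    stop("traces must be numeric", call. = FALSE)
  }
  if (length(trace_i) != length(trace_j)) {
    stop("length mismatch between traces", call. = FALSE)
  }
  ok <- is.finite(trace_i) & is.finite(trace_j)
  x <- trace_i[ok]
  y <- trace_j[ok]
  if (length(x) < 2L) stop("need at least 2 jointly valid samples", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant trace", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Process a simulated scene into a channel set
#'
#' Runs the full per-channel pipeline (contrast, noise correction, CBFI,
#' mean intensity, CBVI) over every stack of a scene and bundles the
#' results for the correlation analyses.
#'
#' @param stacks A `scene_stacks` object from [simulate_scene()], or a
#'   named list of [frame_stack()]s.
#' @param baseline_window `c(start, end)` seconds.
#' @param mask Optional logical matrix applied per frame.
#' @return A `channel_set`: list with `flow` (named list of flow traces),
#'   `volume` (named list of volume traces), `mean_intensity` (named
#'   numeric, recording-average DN per channel) and `frame_rate`.
#' @export
process_scene <- function(stacks, baseline_window = c(0, 5), mask = NULL) {
  if (!is.list(stacks) || !length(stacks) ||
      !all(vapply(stacks, inherits, logical(1), "frame_stack"))) {
    stop("`stacks` must be a non-empty list of frame_stack objects", call. = FALSE)
  }
  labels <- names(stacks)
  if (is.null(labels)) labels <- vapply(stacks, function(s) s$channel_id, character(1))
  flow <- volume <- stats::setNames(vector("list", length(stacks)), labels)
  mi <- stats::setNames(numeric(length(stacks)), labels)
  for (k in seq_along(stacks)) {
    res <- process_stack(stacks[[k]], baseline_window = baseline_window, mask = mask)
    attr(res$flow, "contrast") <- res$contrast
    flow[[k]] <- res$flow
    vol <- process_volume(stacks[[k]], baseline_window = baseline_window, mask = mask)
    volume[[k]] <- vol
    mi[k] <- mean(vol$mean_intensity)
  }
  structure(
    list(flow = flow, volume = volume, mean_intensity = mi,
         frame_rate = stacks[[1]]$frame_rate),
    class = "channel_set"
  )
}

# Extract the per-channel signal matrix used for correlation: normalized
# CBFI over the full recording by default (no detrending or filtering),
# or the linear CBVI.
channel_signals <- function(set, signal = c("cbfi", "cbvi")) {
  signal <- match.arg(signal)
  if (!inherits(set, "channel_set")) stop("`set` must be a channel_set", call. = FALSE)
  traces <- if (signal == "cbfi") {
    lapply(set$flow, function(f) ifelse(f$valid, f$cbfi_normalized, NA_real_))
  } else {
    lapply(set$volume, function(v) v$cbvi_linear)
  }
  len <- unique(vapply(traces, length, integer(1)))
  if (length(len) != 1L) stop("channels must share one sample count", call. = FALSE)
  do.call(cbind, traces)
}

#' Cross-channel correlation matrix
#'
#' Pearson correlation between every unordered pair of channels (n choose
#' 2 pairs), on the normalized CBFI traces by default. Pairs whose
#' correlation is undefined (constant trace, too few joint samples) are
#' flagged `NA` rather than aborting the analysis.
#'
#' @param set A `channel_set` from [process_scene()].
#' @param signal `"cbfi"` (normalized flow index, default) or `"cbvi"`.
#' @return A `correlation_result`: list with `matrix` (symmetric, unit
#'   diagonal), `pairs` (data frame `chan_i`, `chan_j`, `rho`,
#'   `pair_mean_intensity_dn`), `n_pairs` and `signal`.
#' @export
correlation_matrix <- function(set, signal = c("cbfi", "cbvi")) {
  signal <- match.arg(signal)
  sig <- channel_signals(set, signal)
  n <- ncol(sig)
  if (n < 2L) stop("need at least 2 channels", call. = FALSE)
  labels <- colnames(sig)
  M <- diag(1, n)
  dimnames(M) <- list(labels, labels)
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  pairs <- pairs[pairs$i < pairs$j, ]
  rho <- mi <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    r <- tryCatch(pearson_correlation(sig[, i], sig[, j]),
                  error = function(e) NA_real_)
    rho[k] <- r
    M[i, j] <- M[j, i] <- r
    mi[k] <- mean(set$mean_intensity[c(i, j)])
  }
  structure(
    list(
      matrix = M,
      pairs = data.frame(chan_i = labels[pairs$i], chan_j = labels[pairs$j],
                         rho = rho, pair_mean_intensity_dn = mi,
                         stringsAsFactors = FALSE),
      n_pairs = nrow(pairs),
      signal = signal
    ),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %d channels, %d pairs (%s)\n",
              nrow(x$matrix), x$n_pairs, x$signal))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Two-channel correlation vs intensity summary
#'
#' One point per unordered channel pair: the pair's Pearson correlation
#' against the average of the two channels' recording-mean intensities.
#' Separates physiological decorrelation from plain low-light noise: a
#' dim but physiologically coherent pair keeps a high correlation.
#'
#' @param set A `channel_set`.
#' @param signal `"cbfi"` or `"cbvi"`.
#' @return Data frame `chan_i`, `chan_j`, `pair_mean_intensity_dn`, `rho`.
#' @export
two_channel_summary <- function(set, signal = c("cbfi", "cbvi")) {
  res <- correlation_matrix(set, signal)
  res$pairs[, c("chan_i", "chan_j", "pair_mean_intensity_dn", "rho")]
}

#' Group channels by correlation
#'
#' Partitions the channels into the connected components of the graph
#' whose edges join pairs with `rho >= threshold`. Synchronized (healthy)
#' scenes form one group; a region with independent dynamics splits off as
#' its own component.
#'
#' @param result A `correlation_result`.
#' @param threshold Correlation threshold for an edge (default 0.6).
#' @return List of character vectors, one per group, ordered by first
#'   channel.
#' @export
group_channels <- function(result, threshold = 0.6) {
  if (!inherits(result, "correlation_result")) {
    stop("`result` must be a correlation_result", call. = FALSE)
  }
  stopifnot_scalar(threshold, "threshold")
  M <- result$matrix
  adj <- (!is.na(M)) & (M >= threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  labels <- rownames(M)
  split(labels, comp$membership)
}
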