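# Node-signal preparation and the sliding-window grid shared by all stages.

#' Scale a voxel-by-time matrix by its global mean at each time point
#'
#' Divides every column (time point) of a voxel-by-time matrix by that
#' column's mean, so that whole-brain signal fluctuations are removed before
#' node extraction. Every output column has mean exactly 1.
#'
#' @param voxel_matrix Numeric voxel-by-time matrix with no missing values.
#' @return Matrix of the same dimensions, each column divided by its mean.
#' @export
scale_by_global_mean <- function(voxel_matrix) {
  voxel_matrix <- as.matrix(voxel_matrix)
  if (!is.numeric(voxel_matrix) || anyNA(voxel_matrix)) {
    stop("voxel_matrix must be numeric with no missing values")
  }
  gm <- colMeans(voxel_matrix)
  bad <- which(gm == 0)
  if (length(bad) > 0L) {
    stop("global mean is zero at time point(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  sweep(voxel_matrix, 2L, gm, "/")
}

#' Extract a node signal as the mean over a voxel mask
#'
#' @param voxel_matrix Numeric voxel-by-time matrix.
#' @param mask Integer vector of voxel (row) indices belonging to the node.
#' @return Numeric time series: the unweighted mean over the mask voxels at
#'   each time point.
#' @export
extract_node_signal <- function(voxel_matrix, mask) {
  voxel_matrix <- as.matrix(voxel_matrix)
  mask <- as.integer(mask)
  if (length(mask) == 0L) stop("mask must contain at least one voxel index")
  if (anyNA(mask) || any(mask < 1L) || any(mask > nrow(voxel_matrix))) {
    stop("mask indices out of range [1, ", nrow(voxel_matrix), "]")
  }
  colMeans(voxel_matrix[mask, , drop = FALSE])
}

#' Discard leading time samples
#'
#' Removes the first `trim` samples of a time series (vector) or the first
#' `trim` columns of a node-by-time matrix, discarding the onset transient.
#'
#' @param x Numeric vector or node-by-time matrix.
#' @param trim Number of leading samples to discard (non-negative integer).
#' @return The trimmed vector or matrix.
#' @export
trim_onset <- function(x, trim) {
  trim <- as.integer(trim)
  if (length(trim) != 1L || is.na(trim) || trim < 0L) {
    stop("trim must be a single non-negative integer")
  }
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (trim >= n) {
    stop("trim (", trim, ") must be smaller than the series length (", n, ")")
  }
  if (trim == 0L) return(x)
  if (is.matrix(x)) x[, -seq_len(trim), drop = FALSE] else x[-seq_len(trim)]
}

#' Construct the sliding-window grid
#'
#' Windows are half-open index ranges `[s, s + window)` over the trimmed
#' series, with 0-based starts `s = 0, step, 2*step, ...`. With the defaults
#' used throughout (165 acquired samples, 5 trimmed, 10-sample windows,
#' step 1 — i.e. 90% overlap) the grid has 151 windows.
#'
#' @param T_trimmed Length of the trimmed series the grid spans.
#' @param window Samples per window (default 10).
#' @param step Samples between successive window starts (default 1).
#' @param trim Leading samples discarded before the grid applies (default 5);
#'   carried as metadata so series of length `T_trimmed + trim` can be
#'   trimmed on entry.
#' @return An object of class `window_grid`: a list with elements `trim`,
#'   `window`, `step`, `T_trimmed`, `starts` (0-based) and `n_windows`.
#' @export
make_window_grid <- function(T_trimmed, window = 10L, step = 1L, trim = 5L) {
  T_trimmed <- as.integer(T_trimmed)
  window <- as.integer(window)
  step <- as.integer(step)
  trim <- as.integer(trim)
  if (window < 1L) stop("window must be >= 1")
  if (step < 1L) stop("step must be >= 1")
  if (trim < 0L) stop("trim must be >= 0")
  if (window > T_trimmed) {
    stop("window (", window, ") exceeds the trimmed length (", T_trimmed, ")")
  }
  starts <- seq.int(0L, T_trimmed - window, by = step)
  structure(
    list(trim = trim, window = window, step = step, T_trimmed = T_trimmed,
         starts = starts, n_windows = length(starts)),
    class = "window_grid"
  )
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf(
    "window_grid: %d windows of %d samples, step %d, over %d trimmed samples (trim %d)\n",
    x$n_windows, x$window, x$step, x$T_trimmed, x$trim))
  invisible(x)
}

# Accept a full-length or pre-trimmed node-by-time matrix and return the
# matrix covering exactly grid$T_trimmed samples, or fail loudly.
trim_to_grid <- function(signals, grid) {
  n <- ncol(signals)
  if (n == grid$T_trimmed) return(signals)
  if (n == grid$T_trimmed + grid$trim) return(trim_onset(signals, grid$trim))
  stop("signal length (", n, ") matches neither the trimmed span (",
       grid$T_trimmed, ") nor the full span (", grid$T_trimmed + grid$trim, ")")
}

# Column indices (1-based) of the window starting at 0-based start s.
window_index <- function(grid, s) seq.int(s + 1L, s + grid$window)

#' Windowed mean activity amplitude of a network
#'
#' Control analysis companion to the cohesion index: each node series is
#' standardized (z-scored over the trimmed span), the standardized series
#' are averaged across nodes, and the averaged series is averaged again
#' within each sliding window. Differences that appear here reflect overall
#' activity level rather than inter-node coupling.
#'
#' @param subject A `subject_record` (see [subject_record()]).
#' @param network A `network_spec`.
#' @param grid A `window_grid`.
#' @return Numeric vector, one mean amplitude per window.
#' @export
network_activity_series <- function(subject, network, grid) {
  sig <- subject_network_signals(subject, network)
  sig <- trim_to_grid(sig, grid)
  sds <- apply(sig, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance node series for subject ", subject$subject_id, ": ",
         paste(rownames(sig)[sds == 0], collapse = ", "))
  }
  z <- (sig - rowMeans(sig)) / sds
  avg <- colMeans(z)
  vapply(grid$starts,
         function(s) mean(avg[window_index(grid, s)]),
         numeric(1))
}
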