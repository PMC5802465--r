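# Continuous emotion ratings, sampled at 10 Hz on a 0-21 scale (7 labelled
# levels of 3 units each), brought onto the same sliding-window grid as the
# cohesion index.

#' Construct a continuous rating trace
#'
#' @param samples Numeric vector of rating samples at `rate_hz`.
#' @param rate_hz Sampling rate in Hz (default 10).
#' @param scale_max Top of the rating scale (default 21).
#' @return An object of class `rating_trace`.
#' @export
rating_trace <- function(samples, rate_hz = 10, scale_max = 21) {
  samples <- as.numeric(samples)
  if (anyNA(samples)) stop("rating samples must not contain missing values")
  if (any(samples < 0 | samples > scale_max)) {
    stop("rating samples must lie within [0, ", scale_max, "]")
  }
  structure(list(samples = samples, rate_hz = rate_hz, scale_max = scale_max),
            class = "rating_trace")
}

#' Down-sample a rating trace onto the scanner's TR grid
#'
#' Each TR interval's value is the mean of the `rate_hz * TR_seconds` rating
#' samples it contains. The trace must cover the full acquisition.
#'
#' @param trace A `rating_trace`.
#' @param TR_seconds Sampling interval of the fMRI acquisition (default 3).
#' @param n_tr Number of TRs to produce; default uses every complete TR in
#'   the trace.
#' @return Numeric vector of per-TR ratings (length `n_tr`).
#' @export
align_to_tr <- function(trace, TR_seconds = 3, n_tr = NULL) {
  per_tr <- trace$rate_hz * TR_seconds
  if (per_tr != round(per_tr) || per_tr < 1) {
    stop("rate_hz * TR_seconds must be a positive integer")
  }
  per_tr <- as.integer(round(per_tr))
  if (is.null(n_tr)) n_tr <- length(trace$samples) %/% per_tr
  n_tr <- as.integer(n_tr)
  if (length(trace$samples) < n_tr * per_tr) {
    stop("rating trace has ", length(trace$samples),
         " samples but ", n_tr * per_tr, " are needed for ", n_tr, " TRs")
  }
  idx <- matrix(trace$samples[seq_len(n_tr * per_tr)], nrow = per_tr)
  colMeans(idx)
}

#' Average a per-TR rating series within each sliding window
#'
#' The per-TR series must already be trimmed identically to the node
#' signals (the same leading TRs removed), so ratings and NCI share one
#' clock and one grid.
#'
#' @param per_tr Numeric per-TR rating series of length `grid$T_trimmed`.
#' @param grid A `window_grid`.
#' @return Numeric vector of per-window mean ratings, length
#'   `grid$n_windows`.
#' @export
window_rating <- function(per_tr, grid) {
  per_tr <- as.numeric(per_tr)
  if (length(per_tr) != grid$T_trimmed) {
    stop("per-TR series length (", length(per_tr),
         ") must equal the grid's trimmed span (", grid$T_trimmed, ")")
  }
  vapply(grid$starts,
         function(s) mean(per_tr[window_index(grid, s)]),
         numeric(1))
}

#' Full path from a raw 10 Hz trace to the window grid
#'
#' TR-aligns the trace over the untrimmed acquisition, trims the same
#' leading TRs as the node signals, and averages within each window.
#'
#' @param trace A `rating_trace` covering `grid$T_trimmed + grid$trim` TRs.
#' @param grid A `window_grid`.
#' @param TR_seconds TR duration in seconds.
#' @return Numeric per-window rating series of length `grid$n_windows`.
#' @export
rating_to_windows <- function(trace, grid, TR_seconds = 3) {
  per_tr <- align_to_tr(trace, TR_seconds, n_tr = grid$T_trimmed + grid$trim)
  window_rating(trim_onset(per_tr, grid$trim), grid)
}
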