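# Window-wise two-group comparison of NCI, rating and activity amplitude:
# Wilcoxon rank-sum Z (normal approximation with tie correction) per window,
# Benjamini-Hochberg FDR over the comparison span.

#' Wilcoxon rank-sum statistic with normal approximation
#'
#' Two-sample Mann-Whitney/Wilcoxon location statistic expressed as a
#' standard-normal deviate, with the usual tie correction of the variance.
#' `Z > 0` when `values_a` tends to be larger than `values_b`.
#'
#' @param values_a,values_b Numeric vectors (>= 2 finite values each).
#' @return List with `Z`, two-sided `p`, and the group sizes `n_a`, `n_b`
#'   after excluding non-finite values.
#' @export
ranksum_z <- function(values_a, values_b) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  n_a <- length(a)
  n_b <- length(b)
  if (n_a < 2L || n_b < 2L) {
    stop("each group needs >= 2 finite values (got ", n_a, " and ", n_b, ")")
  }
  pooled <- c(a, b)
  n <- n_a + n_b
  rk <- rank(pooled)
  u <- sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  tie_term <- if (anyDuplicated(pooled)) {
    ties <- table(pooled)
    sum(ties^3 - ties)
  } else 0
  v <- n_a * n_b / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0) return(list(Z = 0, p = 1, n_a = n_a, n_b = n_b))
  z <- (u - mu) / sqrt(v)
  list(Z = z, p = 2 * stats::pnorm(-abs(z)), n_a = n_a, n_b = n_b)
}

# Vectorized rank-sum Z over the columns of a subjects-by-windows matrix,
# given a logical selector for group A rows. Non-finite entries are excluded
# per column; columns left with < 2 values in a group return NA.
ranksum_z_matrix <- function(x, is_a) {
  vapply(seq_len(ncol(x)), function(j) {
    col <- x[, j]
    ok <- is.finite(col)
    if (sum(ok & is_a) < 2L || sum(ok & !is_a) < 2L) return(NA_real_)
    ranksum_z(col[ok & is_a], col[ok & !is_a])$Z
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment for independent or positively dependent tests,
#' delegated to [stats::p.adjust()]. `NA` entries are propagated and not
#' counted toward the number of comparisons.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Vector of adjusted q-values, same length and order.
#' @export
fdr_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Resolve the comparison span: the full grid, or the lag-truncated central
# span shared with the cross-correlation analysis (n - 2L windows).
span_windows <- function(grid, span = c("truncated", "full"), max_lag = 10L) {
  span <- match.arg(span)
  n <- grid$n_windows
  if (span == "full") return(seq_len(n))
  max_lag <- as.integer(max_lag)
  if (n <= 2L * max_lag) stop("grid too short for a +/-", max_lag, " truncated span")
  seq.int(max_lag + 1L, n - max_lag)
}

#' Window-wise group comparison of a cohort measure
#'
#' Computes the chosen per-subject, per-window measure (network cohesion
#' index, windowed rating, or windowed mean activity amplitude), then
#' contrasts controls against patients in every window of the comparison
#' span with a two-sided rank-sum test, and adjusts the p-values by BH-FDR
#' over the span. Orientation is control minus patient: `Z > 0` means
#' controls tend larger.
#'
#' @param cohort An `nci_cohort` containing both groups.
#' @param measure One of `"nci"`, `"rating"`, `"activity"`.
#' @param grid A `window_grid`.
#' @param network A `network_spec`; required for `"nci"` and `"activity"`.
#' @param span `"truncated"` (default; the lag-truncated central span, 131
#'   windows with the default grid and `max_lag = 10`) or `"full"`.
#' @param max_lag Half-width of the truncation when `span = "truncated"`.
#' @param TR_seconds TR duration, used to align rating traces.
#' @return An object of class `group_diff_series`: data frame with columns
#'   `window_start`, `Z`, `p`, `q`, `untestable`; attributes `measure`,
#'   `orientation`, `n_comparisons`.
#' @export
groupdiff_series <- function(cohort, measure = c("nci", "rating", "activity"),
                             grid, network = NULL,
                             span = c("truncated", "full"), max_lag = 10L,
                             TR_seconds = 3) {
  measure <- match.arg(measure)
  groups <- cohort_groups(cohort)
  if (!all(c("control", "patient") %in% groups)) {
    stop("cohort must contain both a control and a patient group")
  }
  mat <- measure_matrix(cohort, measure, grid, network, TR_seconds)
  idx <- span_windows(grid, span, max_lag)
  mat <- mat[, idx, drop = FALSE]
  is_ctrl <- groups == "control"

  res <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    ok <- is.finite(col)
    if (sum(ok & is_ctrl) < 2L || sum(ok & !is_ctrl) < 2L) {
      return(c(Z = NA_real_, p = NA_real_))
    }
    r <- ranksum_z(col[ok & is_ctrl], col[ok & !is_ctrl])
    c(Z = r$Z, p = r$p)
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    window_start = grid$starts[idx],
    Z = res[, "Z"],
    p = res[, "p"],
    q = fdr_bh(res[, "p"]),
    untestable = !is.finite(res[, "Z"])
  )
  measure_label <- if (is.null(network)) measure else
    paste(measure, network$name, sep = "_")
  structure(out, class = c("group_diff_series", "data.frame"),
            measure = measure_label, orientation = "control_minus_patient",
            n_comparisons = sum(!is.na(res[, "p"])))
}

# Per-subject, per-window measure matrix used by the group tests and the
# cross-correlation null.
measure_matrix <- function(cohort, measure, grid, network = NULL,
                           TR_seconds = 3) {
  if (measure %in% c("nci", "activity") && is.null(network)) {
    stop("measure '", measure, "' requires a network_spec")
  }
  switch(measure,
    nci = cohort_nci(cohort, network, grid)$values,
    activity = {
      m <- t(vapply(cohort$subjects, network_activity_series,
                    numeric(grid$n_windows), network = network, grid = grid))
      dimnames(m) <- list(names(cohort$subjects), grid$starts)
      m
    },
    rating = {
      has <- vapply(cohort$subjects, function(s) !is.null(s$rating), logical(1))
      if (!all(has)) {
        stop("subjects without a rating trace: ",
             paste(names(cohort$subjects)[!has], collapse = ", "))
      }
      m <- t(vapply(cohort$subjects,
                    function(s) rating_to_windows(s$rating, grid, TR_seconds),
                    numeric(grid$n_windows)))
      dimnames(m) <- list(names(cohort$subjects), grid$starts)
      m
    }
  )
}

#' Significant intervals of a group-difference series
#'
#' @param gd A `group_diff_series`.
#' @param q_threshold FDR threshold (default 0.05).
#' @return Data frame of maximal runs of consecutive significant windows
#'   (`start`, `end` as 0-based window starts, `n_windows`).
#' @export
significant_intervals <- function(gd, q_threshold = 0.05) {
  sig <- which(!is.na(gd$q) & gd$q <= q_threshold)
  if (length(sig) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_windows = integer(0)))
  }
  runs <- split(sig, cumsum(c(1L, diff(sig) != 1L)))
  do.call(rbind, lapply(runs, function(r) {
    data.frame(start = gd$window_start[r[1]],
               end = gd$window_start[r[length(r)]],
               n_windows = length(r))
  }))
}
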