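# Network Cohesion Index: a sliding-window t-statistic over the Fisher
# z-transformed pairwise Pearson correlations among a network's nodes.
# High when the mean inter-node correlation is high AND its variance low.

#' Pairwise Pearson correlations within a window
#'
#' @param window_matrix Node-by-time numeric matrix (>= 3 nodes) covering
#'   one window.
#' @return Numeric vector of the \eqn{N(N-1)/2} correlations in row-major
#'   upper-triangle order (1-2, 1-3, ..., 2-3, ...), or `NULL` if any node
#'   has zero variance inside the window (the degenerate-window case callers
#'   must flag).
#' @export
pairwise_correlations <- function(window_matrix) {
  window_matrix <- as.matrix(window_matrix)
  n_nodes <- nrow(window_matrix)
  if (n_nodes < 3L) stop("need >= 3 nodes; got ", n_nodes)
  sds <- apply(window_matrix, 1L, stats::sd)
  if (any(sds == 0)) return(NULL)
  cm <- stats::cor(t(window_matrix))
  cm[upper.tri(cm)][order(row(cm)[upper.tri(cm)], col(cm)[upper.tri(cm)])]
}

#' Fisher z-transform of a correlation coefficient
#'
#' `atanh(r)`, with coefficients at exactly +/-1 clipped to
#' +/-(1 - 1e-10) first (a warning is emitted), since perfectly correlated
#' node pairs would otherwise map to infinity.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @return `atanh` of the (possibly clipped) input.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| > 1 is not a correlation")
  at_unity <- abs(r) >= 1
  if (any(at_unity, na.rm = TRUE)) {
    warning(sum(at_unity, na.rm = TRUE),
            " correlation(s) at |r| = 1 clipped before the z-transform")
    r[which(at_unity)] <- sign(r[which(at_unity)]) * (1 - 1e-10)
  }
  atanh(r)
}

#' One-sample t-statistic of Fisher-z coefficients (the cohesion index)
#'
#' \eqn{t = \bar z / (s_z / \sqrt{n})} with the sample (n-1) standard
#' deviation, testing the null of zero mean correlation. Used directly as
#' the index, without conversion to a p-value.
#'
#' @param z_values Numeric vector (length >= 3) of Fisher-z coefficients.
#' @return The t-statistic; `sign(mean) * Inf` when the sample standard
#'   deviation is zero with a nonzero mean, `NaN` when both are zero
#'   (callers flag these as degenerate).
#' @export
nci_t <- function(z_values) {
  n <- length(z_values)
  if (n < 3L) stop("need >= 3 z values; got ", n)
  m <- mean(z_values)
  s <- stats::sd(z_values)
  if (s == 0) return(sign(m) * Inf)  # NaN when m == 0
  m / (s / sqrt(n))
}

#' Compute a subject's NCI series for one network
#'
#' For every window of the grid: extract the window's node-by-time
#' submatrix, compute the pairwise Pearson correlations, Fisher z-transform
#' them, and take the one-sample t-statistic. Windows in which some node has
#' zero variance, or in which the z-values have zero spread, are flagged
#' degenerate (value `NA` in the first case, a signed-infinity sentinel in
#' the second) and are excluded from downstream rank tests.
#'
#' @param subject A `subject_record` whose signals cover the grid's full or
#'   trimmed span.
#' @param network A `network_spec`.
#' @param grid A `window_grid`.
#' @return An object of class `nci_series`: list with `subject_id`,
#'   `network`, `values` (length `grid$n_windows`), `degenerate` (logical)
#'   and `grid`.
#' @export
compute_nci_series <- function(subject, network, grid) {
  sig <- subject_network_signals(subject, network)
  sig <- trim_to_grid(sig, grid)
  values <- rep(NA_real_, grid$n_windows)
  degenerate <- rep(FALSE, grid$n_windows)
  for (w in seq_len(grid$n_windows)) {
    r <- pairwise_correlations(sig[, window_index(grid, grid$starts[w]),
                                   drop = FALSE])
    if (is.null(r)) {
      degenerate[w] <- TRUE
      next
    }
    t_val <- nci_t(suppressWarnings(fisher_z(r)))
    if (!is.finite(t_val)) degenerate[w] <- TRUE
    values[w] <- t_val
  }
  structure(list(subject_id = subject$subject_id, network = network$name,
                 values = values, degenerate = degenerate, grid = grid),
            class = "nci_series")
}

#' @export
print.nci_series <- function(x, ...) {
  cat(sprintf("nci_series: subject %s, network %s, %d windows (%d degenerate)\n",
              x$subject_id, x$network, length(x$values), sum(x$degenerate)))
  invisible(x)
}

#' NCI of every subject in a cohort, as a subjects-by-windows matrix
#'
#' @param cohort An `nci_cohort`.
#' @param network A `network_spec`.
#' @param grid A `window_grid`.
#' @return List with `values` (subjects x windows matrix, degenerate
#'   windows non-finite or `NA`), `degenerate` (logical matrix), `groups`
#'   and `grid`. Row names are subject ids; column names the 0-based
#'   window starts.
#' @export
cohort_nci <- function(cohort, network, grid) {
  series <- lapply(cohort$subjects, compute_nci_series,
                   network = network, grid = grid)
  values <- do.call(rbind, lapply(series, `[[`, "values"))
  degenerate <- do.call(rbind, lapply(series, `[[`, "degenerate"))
  dimnames(values) <- dimnames(degenerate) <-
    list(names(cohort$subjects), grid$starts)
  list(values = values, degenerate = degenerate,
       groups = cohort_groups(cohort), grid = grid)
}

#' NCI results in long format
#'
#' @param cohort_nci_result Result of [cohort_nci()].
#' @return Data frame with columns `subject_id`, `network` (attribute-free
#'   label omitted if unknown), `window_start`, `nci`, `degenerate_flag`.
#' @param network_name Label recorded in the `network` column.
#' @export
nci_long_table <- function(cohort_nci_result, network_name = "network") {
  v <- cohort_nci_result$values
  data.frame(
    subject_id = rep(rownames(v), times = ncol(v)),
    network = network_name,
    window_start = rep(as.integer(colnames(v)), each = nrow(v)),
    nci = as.vector(v),
    degenerate_flag = as.vector(cohort_nci_result$degenerate),
    stringsAsFactors = FALSE
  )
}
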