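# Lagged Spearman cross-correlation between the NCI group-difference series
# and the rating group-difference series, with significance from a
# phase-randomization surrogate bootstrap and BH-FDR over the lags.

#' Align two equal-length series at a given lag over a common central span
#'
#' Both series are truncated to the identical central span of length
#' `length(x) - 2 * L` regardless of the lag, so that every lag compares
#' equally sized series. A positive lag pairs x's earlier values with y's
#' later values, i.e. x precedes y.
#'
#' @param series_x,series_y Equal-length numeric vectors.
#' @param lag Signed integer shift of x relative to y, `|lag| <= L`.
#' @param L Maximum lag defining the truncation (default 10).
#' @return List with aligned vectors `x` and `y`, both of length
#'   `length(series_x) - 2 * L`.
#' @export
shift_align <- function(series_x, series_y, lag, L = 10L) {
  n <- length(series_x)
  if (length(series_y) != n) stop("series must have equal length")
  L <- as.integer(L)
  lag <- as.integer(lag)
  if (abs(lag) > L) stop("|lag| (", abs(lag), ") exceeds the maximum lag ", L)
  if (n <= 2L * L) stop("series too short (", n, ") for maximum lag ", L)
  core <- seq.int(L + 1L, n - L)
  list(x = series_x[core - lag], y = series_y[core])
}

#' Spearman rank correlation
#'
#' Pearson correlation of the tie-averaged ranks, via
#' [stats::cor()]. Constant input is flagged as undefined (`NA` with a
#' warning) rather than an error, matching how degenerate windows are
#' handled elsewhere.
#'
#' @param a,b Equal-length numeric vectors, length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` if either vector is constant.
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 3L) stop("need length >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = "spearman")
}

#' Phase-randomized surrogate of a time series
#'
#' Takes the discrete Fourier transform, replaces the phases of all
#' non-DC, non-Nyquist components with independent uniform draws (conjugate
#' symmetry enforced), keeps the DC and Nyquist components untouched, and
#' inverts. The surrogate has exactly the amplitude spectrum — hence the
#' mean, variance and autocorrelation structure — of the input, with the
#' temporal alignment destroyed. Uses the current RNG state.
#'
#' @param series Numeric vector, length >= 4, all finite.
#' @return Real surrogate vector of the same length.
#' @export
phase_randomize <- function(series) {
  n <- length(series)
  if (n < 4L) stop("need length >= 4")
  if (!all(is.finite(series))) stop("series must be finite")
  f <- stats::fft(series)
  half <- if (n %% 2L == 0L) n / 2L - 1L else (n - 1L) / 2L  # k = 2..half+1
  if (half > 0L) {
    k <- seq.int(2L, half + 1L)
    phases <- stats::runif(half, 0, 2 * pi)
    f[k] <- Mod(f[k]) * exp(1i * phases)
    f[n + 2L - k] <- Conj(f[k])
  }
  Re(stats::fft(f, inverse = TRUE)) / n
}

#' Lagged cross-correlation with a phase-randomization bootstrap null
#'
#' The observed profile is the Spearman correlation, at every lag in
#' `-L..L`, between the per-window rank-sum Z series contrasting the two
#' groups' NCI values (control minus patient) and a fixed rating
#' group-difference Z series, both truncated to the common central span.
#' The null is built by phase-randomizing every subject's NCI series
#' independently, recomputing the window-wise Z series, and
#' cross-correlating it with the unchanged rating series; the bootstrap
#' p-value at each lag is `(#{null |rho| >= |observed rho|} + 1) /
#' (n_boot + 1)`, two-sided on `|rho|`, and BH-FDR is applied over the
#' `2L + 1` lags. Null iterations whose Z series comes out constant are
#' discarded (counted in the `n_discarded` attribute).
#'
#' @param nci_values Subjects-by-windows matrix of NCI values (rows named
#'   by subject), e.g. `cohort_nci(...)$values`.
#' @param groups Character vector of `"control"` / `"patient"` labels, one
#'   per row of `nci_values`.
#' @param rating_z Numeric rating group-difference Z series, one value per
#'   window (same length as `ncol(nci_values)`).
#' @param L Maximum lag in window-shift units (default 10).
#' @param n_boot Number of surrogate iterations (default 1000, >= 100).
#' @return An object of class `lag_corr_profile`: data frame with columns
#'   `lag`, `rho`, `p_boot`, `q`; attributes `aligned_length`,
#'   `n_discarded`, `n_boot`.
#' @export
crosscorr_bootstrap <- function(nci_values, groups, rating_z, L = 10L,
                                n_boot = 1000L) {
  nci_values <- as.matrix(nci_values)
  if (length(groups) != nrow(nci_values)) {
    stop("groups must have one label per row of nci_values")
  }
  if (length(rating_z) != ncol(nci_values)) {
    stop("rating_z length must equal the number of windows")
  }
  if (n_boot < 100L) stop("n_boot must be >= 100")
  if (!all(is.finite(nci_values))) {
    stop("nci_values must be finite (exclude degenerate subjects first)")
  }
  is_ctrl <- groups == "control"
  if (sum(is_ctrl) < 2L || sum(!is_ctrl) < 2L) {
    stop("need >= 2 subjects per group")
  }
  lags <- seq.int(-L, L)

  profile_of <- function(z_series) {
    vapply(lags, function(lg) {
      al <- shift_align(z_series, rating_z, lg, L)
      suppressWarnings(spearman_rho(al$x, al$y))
    }, numeric(1))
  }

  obs_z <- ranksum_z_matrix(nci_values, is_ctrl)
  rho_obs <- profile_of(obs_z)
  if (anyNA(rho_obs)) {
    stop("observed cross-correlation undefined (constant Z or rating series)")
  }

  exceed <- integer(length(lags))
  n_discarded <- 0L
  done <- 0L
  while (done < n_boot) {
    surr <- t(apply(nci_values, 1L, phase_randomize))
    z_null <- ranksum_z_matrix(surr, is_ctrl)
    if (anyNA(z_null) || stats::sd(z_null) == 0) {
      n_discarded <- n_discarded + 1L
      if (n_discarded > 10L * n_boot) stop("too many degenerate null iterations")
      next
    }
    rho_null <- profile_of(z_null)
    exceed <- exceed + as.integer(abs(rho_null) >= abs(rho_obs))
    done <- done + 1L
  }
  p_boot <- (exceed + 1) / (n_boot + 1)
  out <- data.frame(lag = lags, rho = rho_obs, p_boot = p_boot,
                    q = fdr_bh(p_boot))
  structure(out, class = c("lag_corr_profile", "data.frame"),
            aligned_length = length(rating_z) - 2L * L,
            n_discarded = n_discarded, n_boot = n_boot)
}

#' Extremal lag of a cross-correlation profile
#'
#' @param profile A `lag_corr_profile`.
#' @return One-row data frame with the lag of maximal `|rho|` and its
#'   `rho`, `p_boot`, `q`.
#' @export
peak_lag <- function(profile) {
  i <- which.max(abs(profile$rho))
  profile[i, , drop = FALSE]
}
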