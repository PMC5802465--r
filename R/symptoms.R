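# Window-wise Spearman correlation between patients' NCI and PANSS symptom
# subscores, FDR-corrected over the windows of each (network, subscale)
# hypothesis family separately.

#' Window-wise symptom-NCI correlation series
#'
#' For each window of the comparison span, the Spearman correlation across
#' patients between their NCI value and a PANSS subscale score, with the
#' asymptotic two-sided p-value and BH-FDR over all windows of the span.
#' Each (network, subscale) pair is its own hypothesis family; no
#' correction across families is applied.
#'
#' @param nci_values Patients-by-windows matrix of NCI values (all windows
#'   of the grid; rows named by subject id).
#' @param scores Numeric vector of one subscale's scores, one per row.
#' @param grid A `window_grid`.
#' @param span,max_lag Comparison span, as in [groupdiff_series()].
#' @param network_name,subscale Labels recorded in the result.
#' @return An object of class `symptom_association`: data frame with
#'   columns `window_start`, `rho`, `p`, `q`, `n`, `untestable`; attributes
#'   `network`, `subscale`, `peak` (row of maximal `|rho|`).
#' @export
symptom_corr_series <- function(nci_values, scores, grid,
                                span = c("truncated", "full"), max_lag = 10L,
                                network_name = "network",
                                subscale = "subscale") {
  nci_values <- as.matrix(nci_values)
  if (length(scores) != nrow(nci_values)) {
    stop("scores must have one value per patient row")
  }
  idx <- span_windows(grid, span, max_lag)
  res <- lapply(idx, function(j) {
    col <- nci_values[, j]
    ok <- is.finite(col) & is.finite(scores)
    if (sum(ok) < 4L || stats::sd(scores[ok]) == 0 || stats::sd(col[ok]) == 0) {
      return(c(rho = NA_real_, p = NA_real_, n = sum(ok)))
    }
    ct <- suppressWarnings(
      stats::cor.test(col[ok], scores[ok], method = "spearman", exact = FALSE))
    c(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    window_start = grid$starts[idx],
    rho = res[, "rho"],
    p = res[, "p"],
    q = fdr_bh(res[, "p"]),
    n = as.integer(res[, "n"]),
    untestable = is.na(res[, "rho"])
  )
  peak <- if (all(out$untestable)) NULL else
    out[which.max(abs(out$rho)), , drop = FALSE]
  structure(out, class = c("symptom_association", "data.frame"),
            network = network_name, subscale = subscale, peak = peak)
}

#' Patient symptom scores of a cohort as a matrix
#'
#' @param cohort An `nci_cohort`.
#' @return Numeric matrix (patients x 3) with columns `positive`,
#'   `negative`, `general`; rows named by subject id. Patients without
#'   scores are dropped with a message.
#' @export
patient_symptom_scores <- function(cohort) {
  pats <- Filter(function(s) s$group == "patient", cohort$subjects)
  if (length(pats) == 0L) stop("cohort contains no patients")
  has <- vapply(pats, function(s) !is.null(s$symptoms), logical(1))
  if (!all(has)) {
    message("dropping ", sum(!has), " patient(s) without symptom scores")
    pats <- pats[has]
  }
  if (length(pats) == 0L) stop("no patient has symptom scores")
  m <- t(vapply(pats, `[[`, numeric(3), "symptoms"))
  rownames(m) <- vapply(pats, `[[`, character(1), "subject_id")
  m
}
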