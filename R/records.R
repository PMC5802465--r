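# Lightweight S3 containers for networks, subjects and cohorts.

#' Define a network of interest
#'
#' A named, ordered set of node labels. At least three nodes are required so
#' that the cohesion index — a one-sample t-statistic over the
#' \eqn{N(N-1)/2} pairwise correlations — has at least two degrees of
#' freedom.
#'
#' @param name Network label, e.g. `"ES"` or `"ToM"`.
#' @param nodes Character vector of unique node labels, length >= 3.
#' @return An object of class `network_spec`.
#' @examples
#' network_spec("ES", c("lAI_IFG", "lvAI", "dPrecuneus", "ACC", "rAI"))
#' @export
network_spec <- function(name, nodes) {
  nodes <- as.character(nodes)
  if (length(nodes) < 3L) {
    stop("a network needs at least 3 nodes (got ", length(nodes), ")")
  }
  if (anyDuplicated(nodes)) stop("node labels must be unique")
  structure(list(name = as.character(name), nodes = nodes),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("network_spec '%s': %d nodes (%s)\n", x$name, length(x$nodes),
              paste(x$nodes, collapse = ", ")))
  invisible(x)
}

#' Canonical 7-node theory-of-mind and 5-node embodied-simulation networks
#'
#' Node sets drawn from meta-analytic maps of mentalization (dorsal and
#' ventral mPFC, bilateral STS and TPJ, ventral precuneus) and of vicarious
#' pain experience (bilateral anterior insula, left AI/IFG, dorsal
#' precuneus, ACC).
#'
#' @return A named list with `network_spec` elements `ToM` (7 nodes) and
#'   `ES` (5 nodes).
#' @export
default_networks <- function() {
  list(
    ToM = network_spec("ToM", c("dmPFC", "vmPFC", "lSTS", "lTPJ",
                                "vPrecuneus", "rSTS", "rTPJ")),
    ES = network_spec("ES", c("lAI_IFG", "lvAI", "dPrecuneus", "ACC", "rAI"))
  )
}

#' Assemble a per-subject record
#'
#' @param subject_id Subject label.
#' @param group `"patient"` or `"control"`.
#' @param signals Node-by-time numeric matrix with unique rownames (node
#'   labels); no missing values.
#' @param symptoms Optional named numeric vector with elements `positive`,
#'   `negative`, `general` (PANSS subscores).
#' @param rating Optional `rating_trace` (see [rating_trace()]).
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, group, signals,
                           symptoms = NULL, rating = NULL) {
  group <- match.arg(group, c("patient", "control"))
  signals <- as.matrix(signals)
  if (!is.numeric(signals) || anyNA(signals)) {
    stop("signals must be a numeric matrix with no missing values")
  }
  if (is.null(rownames(signals)) || anyDuplicated(rownames(signals))) {
    stop("signals must have unique node labels as rownames")
  }
  if (!is.null(symptoms)) {
    need <- c("positive", "negative", "general")
    if (!all(need %in% names(symptoms))) {
      stop("symptoms must be named with: ", paste(need, collapse = ", "))
    }
    symptoms <- as.numeric(symptoms[need])
    names(symptoms) <- need
  }
  structure(list(subject_id = as.character(subject_id), group = group,
                 signals = signals, symptoms = symptoms, rating = rating),
            class = "subject_record")
}

# Node-by-time submatrix for a network, with an informative error when a
# node is absent.
subject_network_signals <- function(subject, network) {
  missing_nodes <- setdiff(network$nodes, rownames(subject$signals))
  if (length(missing_nodes) > 0L) {
    stop("subject ", subject$subject_id, " is missing node(s) of network ",
         network$name, ": ", paste(missing_nodes, collapse = ", "))
  }
  subject$signals[network$nodes, , drop = FALSE]
}

#' Assemble a cohort from subject records
#'
#' @param subjects List of `subject_record` objects with unique ids and a
#'   common signal length.
#' @return An object of class `nci_cohort` (a list with element `subjects`).
#' @export
nci_cohort <- function(subjects) {
  if (length(subjects) == 0L) stop("cohort must contain at least one subject")
  ok <- vapply(subjects, inherits, logical(1), what = "subject_record")
  if (!all(ok)) stop("all elements must be subject_record objects")
  ids <- vapply(subjects, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) stop("subject ids must be unique")
  lens <- vapply(subjects, function(s) ncol(s$signals), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all subjects must share one signal length; got: ",
         paste(unique(lens), collapse = ", "))
  }
  names(subjects) <- ids
  structure(list(subjects = subjects), class = "nci_cohort")
}

#' @export
print.nci_cohort <- function(x, ...) {
  groups <- cohort_groups(x)
  cat(sprintf("nci_cohort: %d subjects (%d control, %d patient), %d time samples\n",
              length(x$subjects), sum(groups == "control"),
              sum(groups == "patient"), ncol(x$subjects[[1]]$signals)))
  invisible(x)
}

#' Group labels of a cohort, in subject order
#' @param cohort An `nci_cohort`.
#' @return Character vector of `"control"` / `"patient"` labels named by
#'   subject id.
#' @export
cohort_groups <- function(cohort) {
  vapply(cohort$subjects, `[[`, character(1), "group")
}
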