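# Subject-level group classification from concatenated per-window NCI
# values of the two networks: k-nearest-neighbour prediction under repeated
# stratified five-fold cross-validation, with label-permutation inference.

#' Build the subject-by-feature matrix from NCI series
#'
#' Features are the per-window NCI values of the networks, concatenated in
#' the order given (e.g. ES then ToM over 151 windows each gives 302
#' features per subject).
#'
#' @param nci_list Named list of subjects-by-windows NCI matrices, one per
#'   network, identical row order.
#' @param span_idx Optional integer vector of window columns to use
#'   (default: all).
#' @return List with `features` (subjects x features matrix) and feature
#'   names of the form `<network>_w<start>`.
#' @export
build_feature_matrix <- function(nci_list, span_idx = NULL) {
  if (length(nci_list) == 0L) stop("need at least one network's NCI matrix")
  blocks <- lapply(names(nci_list), function(nm) {
    m <- as.matrix(nci_list[[nm]])
    if (!is.null(span_idx)) m <- m[, span_idx, drop = FALSE]
    if (!all(is.finite(m))) {
      bad <- rownames(m)[!apply(is.finite(m), 1L, all)]
      stop("non-finite (degenerate) NCI values for subject(s): ",
           paste(bad, collapse = ", "))
    }
    colnames(m) <- paste0(nm, "_w", colnames(m))
    m
  })
  ids <- rownames(blocks[[1]])
  for (b in blocks) {
    if (!identical(rownames(b), ids)) stop("row order differs between networks")
  }
  features <- do.call(cbind, blocks)
  list(features = features, feature_names = colnames(features))
}

# Stratified fold assignment: within each class, a random permutation of
# fold labels as balanced as possible.
stratified_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds) {
      stop("class '", cl, "' has fewer members (", length(idx),
           ") than folds (", folds, ")")
    }
    assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assign
}

# Majority-vote kNN from a precomputed distance matrix. Even-split votes
# are broken by the single nearest neighbour; neighbour order itself is the
# stable order of distances.
knn_predict <- function(dist_mat, labels, train, test, k) {
  vapply(test, function(i) {
    nb <- train[order(dist_mat[i, train])][seq_len(min(k, length(train)))]
    votes <- table(labels[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) top else as.character(labels[nb[1]])
  }, character(1))
}

# Per-repetition metrics. "Positive" class is patient.
cv_metrics <- function(pred, labels) {
  is_pat <- labels == "patient"
  c(accuracy = mean(pred == labels),
    sensitivity = mean(pred[is_pat] == "patient"),
    specificity = mean(pred[!is_pat] == "control"),
    ppv_patient = {
      calls <- pred == "patient"
      if (any(calls)) mean(labels[calls] == "patient") else NA_real_
    },
    ppv_control = {
      calls <- pred == "control"
      if (any(calls)) mean(labels[calls] == "control") else NA_real_
    })
}

#' Repeated stratified cross-validated kNN classification
#'
#' Each repetition draws a fresh stratified fold assignment; every fold is
#' predicted by unweighted k-nearest-neighbour majority vote (Euclidean
#' distance, even-split votes broken by the nearest single neighbour) from
#' the remaining folds. Accuracy, sensitivity (patients correctly
#' classified), specificity (controls correctly classified) and the
#' per-class positive predictive values are computed per repetition and
#' summarized by their mean and standard deviation. Uses the current RNG
#' state; wrap in [withr::with_seed()] for reproducibility.
#'
#' @param features Subjects-by-features numeric matrix.
#' @param labels Character vector of `"control"` / `"patient"` labels.
#' @param k Neighbour count (default 10).
#' @param folds Cross-validation folds (default 5).
#' @param reps Repetitions (default 1000).
#' @return List with `per_rep` (reps x 5 metric matrix) and `summary`
#'   (data frame metric, mean, sd) plus the config echo.
#' @export
knn_repeated_cv <- function(features, labels, k = 10L, folds = 5L,
                            reps = 1000L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(features) != length(labels)) stop("one label per feature row needed")
  if (!all(labels %in% c("control", "patient"))) {
    stop("labels must be 'control' or 'patient'")
  }
  dist_mat <- as.matrix(stats::dist(features))
  n <- length(labels)
  per_rep <- matrix(NA_real_, nrow = reps, ncol = 5L,
                    dimnames = list(NULL, c("accuracy", "sensitivity",
                                            "specificity", "ppv_patient",
                                            "ppv_control")))
  for (r in seq_len(reps)) {
    fold_of <- stratified_folds(labels, folds)
    pred <- character(n)
    for (f in seq_len(folds)) {
      test <- which(fold_of == f)
      train <- which(fold_of != f)
      pred[test] <- knn_predict(dist_mat, labels, train, test, k)
    }
    per_rep[r, ] <- cv_metrics(pred, labels)
  }
  summary <- data.frame(
    metric = colnames(per_rep),
    mean = colMeans(per_rep, na.rm = TRUE),
    sd = apply(per_rep, 2L, stats::sd, na.rm = TRUE),
    row.names = NULL
  )
  list(per_rep = per_rep, summary = summary,
       config = list(k = k, folds = folds, reps = reps))
}

#' Permutation p-value for a classification metric
#'
#' `p = (#(permuted >= original) + 1) / (k_perm + 1)`, with a
#' greater-or-equal comparison, so p is never below `1 / (k_perm + 1)`.
#'
#' @param original_metric Observed metric (scalar).
#' @param permuted_metrics Numeric vector of the metric under permuted
#'   labels, length >= 1.
#' @return The permutation p-value.
#' @export
permutation_pvalue <- function(original_metric, permuted_metrics) {
  k_perm <- length(permuted_metrics)
  if (k_perm < 1L) stop("need at least one permutation")
  (sum(permuted_metrics >= original_metric, na.rm = TRUE) + 1) / (k_perm + 1)
}

#' kNN classification with label-permutation inference
#'
#' Runs the repeated cross-validation on the original labels, then
#' `n_perm` times on labels shuffled once per permutation (the identical
#' CV procedure, at a configurable repetition count), and derives a
#' permutation p-value per metric from the permuted mean metrics.
#'
#' @inheritParams knn_repeated_cv
#' @param n_perm Number of label permutations (default 1000).
#' @param perm_reps CV repetitions inside each permutation (default:
#'   `reps`, reducible for desk-scale runs).
#' @param seed Optional integer seed for full reproducibility.
#' @return An object of class `classifier_report`: the original `summary`
#'   with a `p_perm` column, `per_rep`, the permuted mean metrics, and the
#'   config echo.
#' @export
permutation_test <- function(features, labels, k = 10L, folds = 5L,
                             reps = 1000L, n_perm = 1000L,
                             perm_reps = reps, seed = NULL) {
  run <- function() {
    orig <- knn_repeated_cv(features, labels, k, folds, reps)
    perm_means <- matrix(NA_real_, nrow = n_perm, ncol = 5L,
                         dimnames = list(NULL, orig$summary$metric))
    for (pm in seq_len(n_perm)) {
      shuffled <- sample(labels)
      perm <- knn_repeated_cv(features, shuffled, k, folds, perm_reps)
      perm_means[pm, ] <- perm$summary$mean
    }
    p_perm <- vapply(seq_len(5L), function(j) {
      permutation_pvalue(orig$summary$mean[j], perm_means[, j])
    }, numeric(1))
    summary <- cbind(orig$summary, p_perm = p_perm)
    structure(
      list(summary = summary, per_rep = orig$per_rep,
           permuted_means = perm_means,
           config = list(k = k, folds = folds, reps = reps,
                         n_perm = n_perm, perm_reps = perm_reps,
                         seed = seed)),
      class = "classifier_report")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.classifier_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("classifier_report: kNN (k=%d), %d-fold CV x %d reps, %d permutations\n",
              cfg$k, cfg$folds, cfg$reps, cfg$n_perm))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
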