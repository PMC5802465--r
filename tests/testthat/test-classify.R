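# kNN classification from NCI features with permutation inference.

make_separable_features <- function(n_per_group = 12, n_feat = 20,
                                    margin = 4, seed = 1) {
  withr::with_seed(seed, {
    f <- rbind(matrix(rnorm(n_per_group * n_feat), n_per_group),
               matrix(rnorm(n_per_group * n_feat, mean = margin), n_per_group))
    rownames(f) <- c(paste0("c", seq_len(n_per_group)),
                     paste0("p", seq_len(n_per_group)))
    list(features = f,
         labels = rep(c("control", "patient"), each = n_per_group))
  })
}

test_that("feature concatenation yields networks x windows features", {
  m_es <- matrix(rnorm(4 * 151), 4, 151,
                 dimnames = list(paste0("s", 1:4), 0:150))
  m_tom <- matrix(rnorm(4 * 151), 4, 151,
                  dimnames = list(paste0("s", 1:4), 0:150))
  fm <- build_feature_matrix(list(ES = m_es, ToM = m_tom))
  expect_equal(ncol(fm$features), 302)
  expect_equal(fm$feature_names[1], "ES_w0")
  expect_equal(fm$feature_names[152], "ToM_w0")
  one <- build_feature_matrix(list(ES = m_es[, 1:10]))
  expect_equal(ncol(one$features), 10)
  m_bad <- m_es
  m_bad[2, 5] <- NA
  expect_error(build_feature_matrix(list(ES = m_bad)), "s2")
})

test_that("kNN prediction equals the brute-force oracle", {
  sep <- make_separable_features(n_per_group = 10, margin = 1, seed = 4)
  d <- as.matrix(dist(sep$features))
  withr::with_seed(5, {
    for (i in 1:10) {
      test <- sample(20, 5)
      train <- setdiff(1:20, test)
      k <- sample(c(3, 7, 10), 1)
      expect_equal(
        netcohesion:::knn_predict(d, sep$labels, train, test, k),
        oracle_knn_predict(sep$features, sep$labels, train, test, k))
    }
  })
})

test_that("well-separated clouds classify almost perfectly, identical clouds at chance", {
  sep <- make_separable_features(seed = 6)
  res <- withr::with_seed(7,
    knn_repeated_cv(sep$features, sep$labels, k = 5, folds = 5, reps = 30))
  expect_gt(res$summary$mean[res$summary$metric == "accuracy"], 0.95)

  # one null dataset can sit off chance because its subjects are fixed
  # across repetitions; average over independent null datasets instead
  acc0 <- vapply(1:8, function(i) {
    null <- make_separable_features(margin = 0, seed = 100 + i)
    res0 <- withr::with_seed(200 + i,
      knn_repeated_cv(null$features, null$labels, k = 5, folds = 5,
                      reps = 20))
    res0$summary$mean[res0$summary$metric == "accuracy"]
  }, numeric(1))
  expect_lt(abs(mean(acc0) - 0.5), 0.07)
})

test_that("accuracy decomposes exactly into sensitivity and specificity", {
  sep <- make_separable_features(n_per_group = 9, margin = 1.2, seed = 10)
  res <- withr::with_seed(11,
    knn_repeated_cv(sep$features, sep$labels, k = 4, folds = 3, reps = 25))
  n_pat <- sum(sep$labels == "patient")
  n_con <- sum(sep$labels == "control")
  recon <- (res$per_rep[, "sensitivity"] * n_pat +
              res$per_rep[, "specificity"] * n_con) / (n_pat + n_con)
  expect_equal(unname(res$per_rep[, "accuracy"]), unname(recon))
})

test_that("a fixed seed makes the repeated CV bit-reproducible", {
  sep <- make_separable_features(seed = 12)
  r1 <- withr::with_seed(13, knn_repeated_cv(sep$features, sep$labels,
                                             reps = 5, k = 3))
  r2 <- withr::with_seed(13, knn_repeated_cv(sep$features, sep$labels,
                                             reps = 5, k = 3))
  expect_identical(r1$per_rep, r2$per_rep)
  expect_error(knn_repeated_cv(sep$features[1:6, ],
                               c(rep("control", 5), "patient"), folds = 5),
               "fewer members")
})

test_that("the permutation p-value follows the printed formula exactly", {
  expect_equal(permutation_pvalue(0.9, rep(0.5, 1000)), 1 / 1001)
  expect_equal(permutation_pvalue(0.5, rep(0.9, 1000)), 1)
  perm <- c(rep(0.95, 11), rep(0.5, 989))
  expect_equal(permutation_pvalue(0.9, perm), 12 / 1001)
  expect_true(permutation_pvalue(0, 0.5) %in% c(1))
  expect_true(permutation_pvalue(1, 0.5) == 1 / 2)
})

test_that("separable data yield the minimal permutation p; metrics echo the config", {
  sep <- make_separable_features(n_per_group = 10, margin = 5, seed = 14)
  rep_out <- permutation_test(sep$features, sep$labels, k = 5, folds = 5,
                              reps = 5, n_perm = 30, perm_reps = 3,
                              seed = 15)
  acc <- rep_out$summary[rep_out$summary$metric == "accuracy", ]
  expect_gt(acc$mean, 0.95)
  expect_equal(acc$p_perm, 1 / 31)
  expect_true(all(rep_out$summary$p_perm >= 1 / 31))
  expect_equal(rep_out$config$n_perm, 30)
})
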