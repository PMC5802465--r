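# The cohesion index: pairwise correlations -> Fisher z -> one-sample t.

test_that("pairwise correlations come in row-major upper-triangle order", {
  x <- withr::with_seed(1, rnorm(10))
  m <- rbind(a = x, b = x + 1, c = x * 2)  # three affine copies: all r = 1
  expect_equal(pairwise_correlations(m), c(1, 1, 1))

  y <- withr::with_seed(2, rnorm(10))
  m2 <- rbind(n1 = x, n2 = -x, n3 = y)
  r <- pairwise_correlations(m2)
  expect_equal(r[1], -1)
  expect_equal(r[2], -r[3])  # cor(x,y) = -cor(-x,y)

  m5 <- withr::with_seed(3, matrix(rnorm(50), 5, 10))
  r5 <- pairwise_correlations(m5)
  k <- 0
  for (i in 1:4) for (j in (i + 1):5) {
    k <- k + 1
    expect_equal(r5[k], oracle_pearson(m5[i, ], m5[j, ]))
  }
  expect_length(r5, 10)
  expect_error(pairwise_correlations(m5[1:2, ]), ">= 3 nodes")
  m5[2, ] <- 3  # zero variance -> degenerate marker
  expect_null(pairwise_correlations(m5))
})

test_that("Fisher z is the odd, increasing arctanh with unit clipping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.5493061, tolerance = 1e-6)
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_warning(z1 <- fisher_z(1), "clipped")
  expect_equal(z1, atanh(1 - 1e-10))
  expect_error(fisher_z(1.5), "not a correlation")
})

test_that("the t-statistic matches a one-sample t-test and hand computation", {
  z <- c(0.2, 0.5, 0.8)
  expect_equal(nci_t(z), 0.5 / (0.3 / sqrt(3)))
  expect_equal(nci_t(z), 2.886751, tolerance = 1e-6)
  zr <- withr::with_seed(4, rnorm(21, 0.3, 0.2))
  expect_equal(nci_t(zr), unname(t.test(zr, mu = 0)$statistic))
  # degenerate cases
  expect_true(is.nan(nci_t(c(0, 0, 0))))
  expect_equal(nci_t(c(1, 1, 1) + 1e-12 * c(0, 0, 0)), Inf)
  expect_gt(nci_t(c(1, 1, 1.0001)), 1e3)  # tiny variance -> huge t
  expect_error(nci_t(c(0.1, 0.2)), ">= 3")
})

test_that("compute_nci_series equals the independent loop oracle", {
  grid <- make_window_grid(30, window = 10, step = 1, trim = 0)
  for (n_nodes in c(5L, 7L)) {
    subj <- make_test_subject(n_nodes = n_nodes, T = 30, seed = n_nodes)
    nw <- network_spec("toy", paste0("n", seq_len(n_nodes)))
    got <- compute_nci_series(subj, nw, grid)
    expect_equal(got$values, oracle_nci_series(subj$signals),
                 tolerance = 1e-10)
    expect_false(any(got$degenerate))
  }
})

test_that("NCI is invariant to positive affine node rescaling and node order", {
  subj <- make_test_subject(n_nodes = 5, T = 25, seed = 9)
  nw <- network_spec("toy", paste0("n", 1:5))
  grid <- make_window_grid(25, trim = 0)
  base <- compute_nci_series(subj, nw, grid)$values

  rescaled <- subj
  rescaled$signals <- subj$signals * c(2, 0.5, 10, 1, 3) + c(-1, 0, 5, 2, 0)
  expect_equal(compute_nci_series(rescaled, nw, grid)$values, base)

  nw_perm <- network_spec("toy", c("n3", "n1", "n5", "n2", "n4"))
  expect_equal(compute_nci_series(subj, nw_perm, grid)$values, base)
})

test_that("for fixed mean z the index decreases as z-spread grows", {
  m <- 0.4
  spreads <- c(0.05, 0.1, 0.2, 0.4)
  ts <- vapply(spreads,
               function(s) nci_t(m + s * c(-1, -0.5, 0, 0.5, 1)),
               numeric(1))
  expect_true(all(diff(ts) < 0))
})

test_that("degenerate windows are flagged and missing nodes are named", {
  subj <- make_test_subject(n_nodes = 4, T = 30, seed = 12)
  subj$signals[2, 11:20] <- 0  # flat only inside some windows
  nw <- network_spec("toy", paste0("n", 1:4))
  grid <- make_window_grid(30, trim = 0)
  res <- compute_nci_series(subj, nw, grid)
  flat_windows <- which(res$degenerate)
  expect_true(length(flat_windows) > 0)
  expect_true(all(is.na(res$values[flat_windows])))
  expect_true(all(is.finite(res$values[-flat_windows])))

  nw_missing <- network_spec("bad", c("n1", "n2", "ghost"))
  expect_error(compute_nci_series(subj, nw_missing, grid), "ghost")
  expect_error(compute_nci_series(subj, nw_missing, grid), subj$subject_id)
})

test_that("cohort NCI matrices and the long table line up with the grid", {
  cohort <- make_null_cohort(n_per_group = 3, T = 25, seed = 21)
  grid <- make_window_grid(20, trim = 5)
  res <- cohort_nci(cohort, network_spec("t", paste0("n", 1:5)), grid)
  expect_equal(dim(res$values), c(6, grid$n_windows))
  expect_equal(rownames(res$values), names(cohort$subjects))
  long <- nci_long_table(res, "t")
  expect_equal(nrow(long), 6 * grid$n_windows)
  expect_equal(sort(unique(long$window_start)), grid$starts)
  one <- long[long$subject_id == "c2" & long$window_start == 4, "nci"]
  expect_equal(one, res$values["c2", "4"])
})
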