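# The synthetic-cohort generator and its ground truth.

test_that("configuration errors are caught", {
  expect_error(sim_config(n_per_group = 1), ">= 2")
  expect_error(sim_config(T = 12), "window")
  expect_error(sim_config(rating_noise_sd = 0), "positive")
  expect_error(coupling_profile("x", 1.0), "\\[0, 1\\)")
  expect_error(coupling_profile("x", -0.1), "\\[0, 1\\)")
  # offsets are clipped, not rejected
  cp <- coupling_profile("x", 0.9, control_offset = 0.5, T = 10)
  expect_true(all(cp$c_control < 1))
})

test_that("zero coupling gives near-zero mean correlation and NCI", {
  cfg <- sim_config(n_per_group = 20, T = 60, seed = 1,
                    coupling = list(ToM = coupling_profile("ToM", 0, T = 60),
                                    ES = coupling_profile("ES", 0, T = 60)),
                    symptom_link = NULL)
  cohort <- generate_cohort(cfg)$cohort
  grid <- make_window_grid(55)
  nci <- cohort_nci(cohort, default_networks()$ES, grid)
  # the index is unbiased under independence but heavily autocorrelated
  # across overlapping windows, so the cohort mean keeps a sizeable SE
  expect_lt(abs(mean(nci$values)), 0.3)
  rs <- unlist(lapply(cohort$subjects, function(s) {
    pairwise_correlations(s$signals[default_networks()$ES$nodes, 1:10])
  }))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("constant coupling 0.8 is recovered as the mean pairwise correlation", {
  # the sample correlation in a 10-sample window carries the classical
  # finite-n downward bias (about c(1-c^2)/(2(n-1)) ~ 0.016 here), so the
  # expected value is fixed by an independent Monte-Carlo oracle rather
  # than by the nominal c
  oracle_mean_r <- withr::with_seed(123, mean(replicate(20000, {
    f <- rnorm(10)
    x <- sqrt(0.8) * f + sqrt(0.2) * rnorm(10)
    y <- sqrt(0.8) * f + sqrt(0.2) * rnorm(10)
    oracle_pearson(x, y)
  })))
  cfg <- sim_config(n_per_group = 50, T = 60, seed = 2,
                    coupling = list(ToM = coupling_profile("ToM", 0.8, T = 60),
                                    ES = coupling_profile("ES", 0.8, T = 60)),
                    symptom_link = NULL)
  cohort <- generate_cohort(cfg)$cohort
  grid <- make_window_grid(55, step = 5, trim = 5)
  rs <- unlist(lapply(cohort$subjects, function(s) {
    sig <- s$signals[default_networks()$ES$nodes, 6:60]
    unlist(lapply(grid$starts, function(st) {
      pairwise_correlations(sig[, (st + 1):(st + 10)])
    }))
  }))
  expect_gte(length(rs), 1e4)
  expect_lt(abs(mean(rs) - oracle_mean_r), 0.02)
  expect_lt(abs(mean(rs) - 0.8), 0.05)
})

test_that("same seed reproduces the cohort bit-exactly, different seeds differ", {
  cfg <- sim_config(n_per_group = 2, T = 30, seed = 9, symptom_link = NULL)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort$subjects$hc01$signals,
                   g2$cohort$subjects$hc01$signals)
  cfg3 <- sim_config(n_per_group = 2, T = 30, seed = 10, symptom_link = NULL)
  g3 <- generate_cohort(cfg3)
  expect_false(identical(g1$cohort$subjects$hc01$signals,
                         g3$cohort$subjects$hc01$signals))
})

test_that("rating traces stay on the 0-21 scale and groups differ as planted", {
  gen <- generate_cohort(sim_config(n_per_group = 15, seed = 11))
  for (s in gen$cohort$subjects) {
    expect_true(all(s$rating$samples >= 0 & s$rating$samples <= 21))
    expect_length(s$rating$samples, 165 * 30)
  }
  # the control rating exceeds the patient rating inside the delayed bump
  grid <- make_window_grid(160)
  gd <- groupdiff_series(gen$cohort, "rating", grid, span = "full")
  bump <- gd$window_start >= 55 & gd$window_start <= 75
  expect_gt(mean(gd$Z[bump]), mean(gd$Z[!bump]))
})

test_that("AR(1) innovations keep unit marginal variance", {
  x <- withr::with_seed(12, netcohesion:::sim_innovations(20000, 0.6))
  expect_lt(abs(var(x) - 1), 0.06)
  expect_lt(abs(cor(x[-1], x[-length(x)]) - 0.6), 0.05)
})

test_that("patient symptom scores follow the planted linear link", {
  link <- list(network = "ToM", subscale = "general", window = 50L,
               slope = 8, noise_sd = 1, intercept = 40)
  gen <- generate_cohort(sim_config(n_per_group = 20, seed = 13,
                                    symptom_link = link))
  grid <- make_window_grid(160)
  scores <- patient_symptom_scores(gen$cohort)
  nci <- cohort_nci(gen$cohort, default_networks()$ToM, grid)
  vals <- nci$values[rownames(scores), "50"]
  expect_gt(cor(vals, scores[, "general"], method = "spearman"), 0.6)
  expect_equal(gen$truth$symptom_link$slope, 8)
})

test_that("cohorts round-trip through the writers bit-exactly", {
  dir <- withr::local_tempdir()
  gen <- generate_cohort(sim_config(n_per_group = 2, T = 30, seed = 14,
                                    symptom_link = NULL))
  write_cohort(gen$cohort, dir, gen$truth)
  back <- read_cohort(dir)
  for (id in names(gen$cohort$subjects)) {
    expect_identical(back$cohort$subjects[[id]]$signals,
                     gen$cohort$subjects[[id]]$signals)
    expect_identical(back$cohort$subjects[[id]]$rating$samples,
                     gen$cohort$subjects[[id]]$rating$samples)
    expect_identical(back$cohort$subjects[[id]]$group,
                     gen$cohort$subjects[[id]]$group)
  }
  expect_equal(back$truth$rating_lag, gen$truth$rating_lag)
  expect_equal(back$truth$coupling$ES$c_control,
               gen$truth$coupling$ES$c_control)
  # single-subject cohort -> one manifest row; empty cohort -> error
  solo <- nci_cohort(gen$cohort$subjects[1])
  d2 <- withr::local_tempdir()
  write_cohort(solo, d2)
  expect_equal(nrow(read.delim(file.path(d2, "manifest.tsv"))), 1)
  expect_error(write_cohort(list(), d2), "nonempty")
})
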