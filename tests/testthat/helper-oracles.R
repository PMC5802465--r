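# Independent brute-force oracles: loop-based re-derivations of every
# statistic, kept deliberately free of the package's code paths.

# Pearson correlation from first principles.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0
  dx2 <- 0
  dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx2 <- dx2 + (x[i] - mx)^2
    dy2 <- dy2 + (y[i] - my)^2
  }
  num / sqrt(dx2 * dy2)
}

# Full NCI pipeline by loops: per window, all pairs in row-major
# upper-triangle order -> atanh -> one-sample t with (n-1) sd.
oracle_nci_series <- function(signals, window = 10L, step = 1L) {
  n_nodes <- nrow(signals)
  starts <- seq(0L, ncol(signals) - window, by = step)
  out <- numeric(length(starts))
  for (w in seq_along(starts)) {
    cols <- (starts[w] + 1L):(starts[w] + window)
    z <- c()
    for (i in 1:(n_nodes - 1)) {
      for (j in (i + 1):n_nodes) {
        r <- oracle_pearson(signals[i, cols], signals[j, cols])
        if (abs(r) >= 1) r <- sign(r) * (1 - 1e-10)
        z <- c(z, atanh(r))
      }
    }
    m <- sum(z) / length(z)
    s <- sqrt(sum((z - m)^2) / (length(z) - 1))
    out[w] <- m / (s / sqrt(length(z)))
  }
  out
}

# Midranks by counting, then the rank-sum Z with tie-corrected variance.
oracle_ranksum_z <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  rk <- vapply(pooled, function(v) {
    1 + sum(pooled < v) + (sum(pooled == v) - 1) / 2
  }, numeric(1))
  ra <- sum(rk[seq_along(a)])
  u <- ra - length(a) * (length(a) + 1) / 2
  mu <- length(a) * length(b) / 2
  tie <- 0
  for (v in unique(pooled)) {
    tv <- sum(pooled == v)
    tie <- tie + tv^3 - tv
  }
  v <- length(a) * length(b) / 12 * ((n + 1) - tie / (n * (n - 1)))
  (u - mu) / sqrt(v)
}

# Midranks then Pearson-of-ranks.
oracle_spearman <- function(a, b) {
  midrank <- function(x) vapply(x, function(v) {
    1 + sum(x < v) + (sum(x == v) - 1) / 2
  }, numeric(1))
  oracle_pearson(midrank(a), midrank(b))
}

# Hand-stepped BH: sort ascending, q_i = min over j >= i of p_j * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    q_sorted[i] <- running
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Brute-force kNN with the same conventions as the package: Euclidean
# distance, majority vote, even-split broken by the nearest neighbour.
oracle_knn_predict <- function(features, labels, train, test, k) {
  vapply(test, function(i) {
    d <- apply(features[train, , drop = FALSE], 1L,
               function(row) sqrt(sum((row - features[i, ])^2)))
    nb <- train[order(d)][seq_len(min(k, length(train)))]
    tab <- table(labels[nb])
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) top else as.character(labels[nb[1]])
  }, character(1))
}

# Small deterministic subject for unit tests: named nodes, reproducible
# noise signals.
make_test_subject <- function(id = "s1", group = "control", n_nodes = 5L,
                              T = 40L, seed = 1L,
                              nodes = paste0("n", seq_len(n_nodes))) {
  withr::with_seed(seed, {
    sig <- matrix(rnorm(n_nodes * T), nrow = n_nodes,
                  dimnames = list(nodes, NULL))
    subject_record(id, group, sig)
  })
}

# Two-group cohort of pure-noise subjects (no planted effect), small grid.
make_null_cohort <- function(n_per_group = 6L, n_nodes = 5L, T = 40L,
                             seed = 1L) {
  withr::with_seed(seed, {
    subs <- list()
    for (g in c("control", "patient")) {
      for (i in seq_len(n_per_group)) {
        id <- paste0(substr(g, 1, 1), i)
        sig <- matrix(rnorm(n_nodes * T), nrow = n_nodes,
                      dimnames = list(paste0("n", seq_len(n_nodes)), NULL))
        subs[[id]] <- subject_record(id, g, sig)
      }
    }
    nci_cohort(subs)
  })
}
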