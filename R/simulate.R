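# Synthetic cohorts with the statistical structure the analysis assumes.
#
# Node signals follow a shared-factor model,
#   node_i(t) = sqrt(c_g(t)) * f(t) + sqrt(1 - c_g(t)) * eps_i(t),
# with f and eps_i independent unit-variance innovations, so the expected
# pairwise correlation of any two nodes in a window of constant coupling c
# is exactly c — which makes cohesion-index recovery testable. Group
# differences, rating lags and symptom links are planted with known ground
# truth.

#' Within-network coupling profile with per-group modulation
#'
#' @param network_name Network label the profile applies to.
#' @param base Baseline coupling: scalar or length-`T` vector, values in
#'   `[0, 1)`.
#' @param control_offset,patient_offset Additive per-group modulation:
#'   scalar or length-`T` vector. Effective couplings are clipped to
#'   `[0, 1)`.
#' @param T Acquisition length in samples.
#' @return An object of class `coupling_profile` with per-group effective
#'   coupling vectors `c_control`, `c_patient` (each length `T`).
#' @export
coupling_profile <- function(network_name, base, control_offset = 0,
                             patient_offset = 0, T = 165L) {
  T <- as.integer(T)
  base <- rep_len(as.numeric(base), T)
  if (any(base < 0 | base >= 1)) stop("base coupling must lie in [0, 1)")
  clip <- function(x) pmin(pmax(x, 0), 1 - 1e-6)
  structure(
    list(network_name = as.character(network_name),
         c_control = clip(base + rep_len(as.numeric(control_offset), T)),
         c_patient = clip(base + rep_len(as.numeric(patient_offset), T)),
         T = T),
    class = "coupling_profile")
}

# Rectangular elevation over sliding-window positions: raising the coupling
# for windows first..last (0-based starts over the trimmed series) means
# raising the underlying samples trim+first .. trim+last+window-1.
#' Per-sample offset vector elevating a span of sliding windows
#'
#' @param T Acquisition length in samples.
#' @param first_window,last_window 0-based window starts (inclusive) over
#'   the trimmed series.
#' @param height Offset added within the span.
#' @param trim,window Grid parameters locating the windows in acquisition
#'   samples.
#' @return Numeric length-`T` offset vector.
#' @export
window_span_offset <- function(T, first_window, last_window, height,
                               trim = 5L, window = 10L) {
  offs <- numeric(T)
  from <- trim + first_window + 1L
  to <- min(T, trim + last_window + window)
  if (from > T || from > to) stop("window span lies outside the acquisition")
  offs[from:to] <- height
  offs
}

#' Simulation configuration
#'
#' Defaults mirror a two-group naturalistic-viewing acquisition: a 7-node
#' mentalization (ToM) network and a 5-node embodied-simulation (ES)
#' network observed over 165 samples at TR = 3 s, baseline within-network
#' coupling 0.2, with the controls' ES coupling raised by 0.3 during two
#' "emotional peak" spans (window starts 40-70 and 100-125), a continuous
#' 0-21 rating whose group difference follows the ES coupling difference
#' with a 10-sample delay, and a patient symptom subscore linked linearly
#' to the ToM cohesion index at a designated window.
#'
#' @param n_per_group Subjects per group (>= 2; default 25).
#' @param T Acquisition length in samples (default 165).
#' @param TR_seconds Sampling interval (default 3).
#' @param networks Named list of `network_spec`s (default
#'   [default_networks()]).
#' @param coupling Named list of `coupling_profile`s, one per network;
#'   `NULL` for the defaults described above.
#' @param rating_lag Signed delay, in samples, of the rating group
#'   difference behind the ES coupling difference (default 10; positive
#'   means coupling — hence NCI — precedes rating).
#' @param rating_gain Rating units per unit of coupling difference
#'   (default 6).
#' @param rating_noise_sd Per-subject smooth rating noise sd (default 1.5).
#' @param symptom_link List `(network, subscale, window, slope, noise_sd,
#'   intercept)` planting scores = intercept + slope * NCI(window) + noise
#'   for patients (default links the general subscale to ToM NCI at window
#'   50 with slope 4 and noise sd 3).
#' @param ar_phi AR(1) coefficient of the signal innovations (default 0 =
#'   white noise; marginal variance kept at 1).
#' @param trim,window,step Grid parameters the cohort is meant to be
#'   analysed with (defaults 5, 10, 1); used for validation and by
#'   [run_pipeline()].
#' @param seed RNG seed (default 1).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 25L, T = 165L, TR_seconds = 3,
                       networks = default_networks(), coupling = NULL,
                       rating_lag = 10L, rating_gain = 6,
                       rating_noise_sd = 1.5,
                       symptom_link = list(network = "ToM",
                                           subscale = "general",
                                           window = 50L, slope = 4,
                                           noise_sd = 3, intercept = 40),
                       ar_phi = 0, trim = 5L, window = 10L, step = 1L,
                       seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  T <- as.integer(T)
  if (n_per_group < 2L) stop("n_per_group must be >= 2")
  if (T < window + trim) stop("T must be at least window + trim")
  if (rating_noise_sd <= 0) stop("rating_noise_sd must be positive")
  if (!is.null(symptom_link) && symptom_link$noise_sd <= 0) {
    stop("symptom noise_sd must be positive")
  }
  if (abs(ar_phi) >= 1) stop("ar_phi must lie in (-1, 1)")
  for (nw in networks) {
    if (length(nw$nodes) < 3L) stop("networks need >= 3 nodes")
  }
  if (is.null(coupling)) {
    # two emotional-peak spans at fixed fractions of the window range;
    # with the default 165-sample acquisition these are windows 40-70 and
    # 100-125
    nw <- T - trim - window + 1L
    pk <- function(f) as.integer(round(nw * f))
    peak_offsets <- window_span_offset(T, pk(40 / 151), pk(70 / 151), 0.3,
                                       trim, window) +
      window_span_offset(T, pk(100 / 151), pk(125 / 151), 0.3, trim, window)
    coupling <- list(
      ToM = coupling_profile("ToM", 0.2, T = T),
      ES = coupling_profile("ES", 0.2, control_offset = peak_offsets, T = T)
    )
  }
  if (!setequal(names(coupling), names(networks))) {
    stop("coupling profiles must be named like the networks")
  }
  for (nm in names(coupling)) {
    if (coupling[[nm]]$T != T) stop("coupling profile length must equal T")
  }
  structure(
    list(n_per_group = n_per_group, T = T, TR_seconds = TR_seconds,
         networks = networks, coupling = coupling,
         rating_lag = as.integer(rating_lag), rating_gain = rating_gain,
         rating_noise_sd = rating_noise_sd, symptom_link = symptom_link,
         ar_phi = ar_phi, trim = as.integer(trim),
         window = as.integer(window), step = as.integer(step),
         seed = as.integer(seed)),
    class = "sim_config")
}

# Unit-marginal-variance innovations: white noise, or AR(1) with
# innovation sd sqrt(1 - phi^2).
sim_innovations <- function(n, phi) {
  if (phi == 0) return(stats::rnorm(n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  e <- stats::rnorm(n - 1, sd = sqrt(1 - phi^2))
  for (t in 2:n) x[t] <- phi * x[t - 1] + e[t - 1]
  x
}

# Shared-factor node signals for one subject and one network.
sim_network_signals <- function(nodes, c_t, phi) {
  T <- length(c_t)
  f <- sim_innovations(T, phi)
  sig <- t(vapply(nodes, function(nd) {
    sqrt(c_t) * f + sqrt(1 - c_t) * sim_innovations(T, phi)
  }, numeric(T)))
  rownames(sig) <- nodes
  sig
}

# Group-level rating curve on the 10 Hz grid. The shared base carries the
# two emotional peaks (the normalized ES coupling elevation); the control
# group additionally carries the lagged coupling-difference bump.
sim_rating_curve <- function(config, group) {
  dc <- config$coupling$ES$c_control - config$coupling$ES$c_patient
  shape <- if (max(abs(dc)) > 0) abs(dc) / max(abs(dc)) else numeric(config$T)
  base_tr <- 5 + 8 * shape
  curve_tr <- base_tr
  if (group == "control") {
    lag <- config$rating_lag
    idx <- seq_len(config$T) - lag
    dc_shift <- dc[pmin(pmax(idx, 1L), config$T)]
    dc_shift[idx < 1L | idx > config$T] <- 0
    curve_tr <- curve_tr + config$rating_gain * dc_shift
  }
  # 10 Hz grid: TR values at interval midpoints, linear in between
  per_tr <- 10 * config$TR_seconds
  t_hz <- (seq_len(config$T * per_tr) - 0.5) / 10
  t_tr <- (seq_len(config$T) - 0.5) * config$TR_seconds
  stats::approx(t_tr, curve_tr, xout = t_hz, rule = 2)$y
}

# Smooth per-subject rating noise on the 10 Hz grid: white noise passed
# through a 3 s moving average, rescaled to the target sd.
sim_rating_noise <- function(n, sd_target) {
  w <- 31L
  raw <- stats::rnorm(n + w - 1L)
  sm <- stats::filter(raw, rep(1 / w, w), sides = 2L)
  sm <- sm[!is.na(sm)][seq_len(n)]
  sm * sd_target / stats::sd(sm)
}

#' Generate a synthetic two-group cohort with known ground truth
#'
#' See [sim_config()] for the generative model. Patients' linked symptom
#' subscore is `intercept + slope * NCI(designated window) + noise`, where
#' the NCI is the subject's own cohesion index of the designated network
#' at the designated window (computed with the config's grid), so symptom
#' recovery tests know the exact planted relation. The other two subscores
#' are independent draws.
#'
#' @param config A `sim_config`.
#' @return List with `cohort` (an `nci_cohort`) and `truth` (coupling
#'   profiles, rating lag, symptom link, seed).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  grid <- make_window_grid(config$T - config$trim, config$window,
                           config$step, config$trim)
  n_hz <- config$T * 10 * config$TR_seconds
  subjects <- list()
  for (group in c("control", "patient")) {
    curve_hz <- sim_rating_curve(config, group)
    for (i in seq_len(config$n_per_group)) {
      id <- sprintf("%s%02d", if (group == "control") "hc" else "sz", i)
      sig <- do.call(rbind, lapply(names(config$networks), function(nm) {
        cp <- config$coupling[[nm]]
        c_t <- if (group == "control") cp$c_control else cp$c_patient
        sim_network_signals(config$networks[[nm]]$nodes, c_t, config$ar_phi)
      }))
      rating_hz <- curve_hz + sim_rating_noise(n_hz, config$rating_noise_sd)
      rating <- rating_trace(pmin(pmax(rating_hz, 0), 21))
      symptoms <- NULL
      if (group == "patient") {
        symptoms <- c(positive = max(7, round(stats::rnorm(1, 20, 4))),
                      negative = max(7, round(stats::rnorm(1, 20, 4))),
                      general = max(16, round(stats::rnorm(1, 40, 6))))
        link <- config$symptom_link
        if (!is.null(link)) {
          rec <- subject_record(id, group, sig)
          nci <- compute_nci_series(rec, config$networks[[link$network]],
                                    grid)
          w <- which(grid$starts == link$window)
          if (length(w) != 1L) stop("symptom_link window not on the grid")
          val <- nci$values[w]
          if (!is.finite(val)) val <- 0
          symptoms[link$subscale] <-
            max(7, round(link$intercept + link$slope * val +
                           stats::rnorm(1, 0, link$noise_sd)))
        }
      }
      subjects[[id]] <- subject_record(id, group, sig, symptoms, rating)
    }
  }
  truth <- list(coupling = config$coupling, rating_lag = config$rating_lag,
                rating_gain = config$rating_gain,
                symptom_link = config$symptom_link, ar_phi = config$ar_phi,
                seed = config$seed)
  list(cohort = nci_cohort(subjects), truth = truth)
}

# %.17g formatting round-trips IEEE doubles through text exactly.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a cohort to a directory of plain-text files
#'
#' One node-by-time signal TSV per subject, one rating TSV per subject
#' (10 Hz grid, columns `time_seconds`, `rating`), one cohort manifest
#' (`subject_id`, `group`, `panss_positive`, `panss_negative`,
#' `panss_general`), and an optional ground-truth JSON sidecar. Numeric
#' values are written with 17 significant digits so matrices round-trip
#' through [read_cohort()] bit-exactly.
#'
#' @param cohort An `nci_cohort`.
#' @param directory Output directory (created if needed).
#' @param truth Optional ground-truth list to store as
#'   `ground_truth.json`.
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, directory, truth = NULL) {
  if (!inherits(cohort, "nci_cohort") || length(cohort$subjects) == 0L) {
    stop("cohort must be a nonempty nci_cohort")
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  files <- character(0)
  man <- data.frame(subject_id = character(0), group = character(0),
                    panss_positive = character(0),
                    panss_negative = character(0),
                    panss_general = character(0))
  for (s in cohort$subjects) {
    sig_path <- file.path(directory, paste0(s$subject_id, "_signals.tsv"))
    tab <- cbind(node = rownames(s$signals),
                 matrix(fmt_num(s$signals), nrow = nrow(s$signals),
                        dimnames = list(NULL, sprintf("t%03d",
                                        seq_len(ncol(s$signals))))))
    utils::write.table(tab, sig_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, sig_path)
    if (!is.null(s$rating)) {
      rt_path <- file.path(directory, paste0(s$subject_id, "_rating.tsv"))
      n <- length(s$rating$samples)
      rt <- data.frame(
        time_seconds = fmt_num((seq_len(n) - 1) / s$rating$rate_hz),
        rating = fmt_num(s$rating$samples))
      utils::write.table(rt, rt_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, rt_path)
    }
    sy <- s$symptoms
    man <- rbind(man, data.frame(
      subject_id = s$subject_id, group = s$group,
      panss_positive = if (is.null(sy)) "NA" else fmt_num(sy[["positive"]]),
      panss_negative = if (is.null(sy)) "NA" else fmt_num(sy[["negative"]]),
      panss_general = if (is.null(sy)) "NA" else fmt_num(sy[["general"]])))
  }
  man_path <- file.path(directory, "manifest.tsv")
  utils::write.table(man, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, man_path)
  if (!is.null(truth)) {
    truth_path <- file.path(directory, "ground_truth.json")
    jsonlite::write_json(truth_serializable(truth), truth_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, truth_path)
  }
  invisible(files)
}

truth_serializable <- function(truth) {
  truth$coupling <- lapply(truth$coupling, function(cp) {
    list(network_name = cp$network_name, c_control = cp$c_control,
         c_patient = cp$c_patient, T = cp$T)
  })
  truth
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory Directory containing `manifest.tsv` and the per-subject
#'   files.
#' @return List with `cohort` (an `nci_cohort`) and `truth` (parsed
#'   `ground_truth.json`, or `NULL`).
#' @export
read_cohort <- function(directory) {
  man_path <- file.path(directory, "manifest.tsv")
  if (!file.exists(man_path)) stop("manifest not found: ", man_path)
  man <- utils::read.delim(man_path, colClasses = "character")
  need <- c("subject_id", "group", "panss_positive", "panss_negative",
            "panss_general")
  if (!all(need %in% names(man))) {
    stop("manifest ", man_path, " lacks column(s): ",
         paste(setdiff(need, names(man)), collapse = ", "))
  }
  if (nrow(man) == 0L) stop("manifest is empty: ", man_path)
  for (col in need[3:5]) man[[col]] <- suppressWarnings(as.numeric(man[[col]]))
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    id <- man$subject_id[i]
    sig_path <- file.path(directory, paste0(id, "_signals.tsv"))
    if (!file.exists(sig_path)) stop("missing signal file: ", sig_path)
    tab <- utils::read.delim(sig_path, check.names = FALSE)
    sig <- as.matrix(tab[, -1, drop = FALSE])
    dimnames(sig) <- list(tab$node, NULL)
    rating <- NULL
    rt_path <- file.path(directory, paste0(id, "_rating.tsv"))
    if (file.exists(rt_path)) {
      rt <- utils::read.delim(rt_path)
      rating <- rating_trace(rt$rating)
    }
    symptoms <- NULL
    if (!is.na(man$panss_general[i])) {
      symptoms <- c(positive = man$panss_positive[i],
                    negative = man$panss_negative[i],
                    general = man$panss_general[i])
    }
    subject_record(id, man$group[i], sig, symptoms, rating)
  })
  truth <- NULL
  truth_path <- file.path(directory, "ground_truth.json")
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  }
  list(cohort = nci_cohort(subjects), truth = truth)
}
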