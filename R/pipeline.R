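# One reproducible run tying the stages together: simulate (or load) ->
# NCI -> group tests -> lagged cross-correlation -> symptom correlations ->
# classification, from a single configuration.

#' Default run configuration
#'
#' @param output_dir Directory for stage outputs.
#' @param cohort_dir Optional directory with an existing cohort (from
#'   [write_cohort()]); when `NULL` a cohort is simulated.
#' @param sim A `sim_config` used when simulating (default
#'   [sim_config()]).
#' @param trim,window,step Grid parameters (defaults 5, 10, 1).
#' @param max_lag Maximum cross-correlation lag (default 10).
#' @param n_boot Surrogate iterations for the cross-correlation null
#'   (default 1000).
#' @param knn_k,knn_folds,knn_reps,knn_perms,knn_perm_reps Classifier
#'   settings (defaults 10, 5, 1000, 1000, and `knn_reps`).
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "nci", "groupdiff", "xcorr", "symptoms", "classify")`.
#' @param seed Master seed; per-stage substreams are derived from it.
#' @return A `run_config` list.
#' @export
default_run_config <- function(output_dir = "netcohesion_run",
                               cohort_dir = NULL, sim = sim_config(),
                               trim = 5L, window = 10L, step = 1L,
                               max_lag = 10L, n_boot = 1000L,
                               knn_k = 10L, knn_folds = 5L,
                               knn_reps = 1000L, knn_perms = 1000L,
                               knn_perm_reps = knn_reps,
                               stages = c("simulate", "nci", "groupdiff",
                                          "xcorr", "symptoms", "classify"),
                               seed = 1L) {
  structure(
    list(output_dir = output_dir, cohort_dir = cohort_dir, sim = sim,
         trim = as.integer(trim), window = as.integer(window),
         step = as.integer(step), max_lag = as.integer(max_lag),
         n_boot = as.integer(n_boot), knn_k = as.integer(knn_k),
         knn_folds = as.integer(knn_folds), knn_reps = as.integer(knn_reps),
         knn_perms = as.integer(knn_perms),
         knn_perm_reps = as.integer(knn_perm_reps),
         stages = stages, seed = as.integer(seed)),
    class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys override the arguments of [default_run_config()]; a
#' `sim:` block overrides the arguments of [sim_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim
  raw$sim <- NULL
  known <- names(formals(default_run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown run-config field(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(sim_args)) raw$sim <- do.call(sim_config, sim_args)
  do.call(default_run_config, raw)
}

# FNV-1a hash of the serialized config (paths excluded, so relocating a
# run does not change its identity), for provenance headers.
config_hash <- function(config) {
  config$output_dir <- NULL
  config$cohort_dir <- NULL
  s <- jsonlite::serializeJSON(config)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

write_stage_tsv <- function(df, path, header_fields) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(header_fields)) {
    writeLines(sprintf("# %s: %s", nm, header_fields[[nm]]), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full cohesion-dynamics pipeline
#'
#' Executes the enabled stages in dependency order, writes each stage's
#' output as TSV/JSON under the configured output directory (every file
#' carries a provenance header with the config hash, master seed and
#' package version), and returns a machine-readable summary. A single
#' master seed spawns per-stage substreams, so runs are reproducible
#' end-to-end.
#'
#' @param config A `run_config` (see [default_run_config()]) or the path
#'   to a YAML file for [read_run_config()].
#' @return Invisibly, the run summary (also written as
#'   `run_summary.json`).
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  known_stages <- c("simulate", "nci", "groupdiff", "xcorr", "symptoms",
                    "classify")
  bad <- setdiff(config$stages, known_stages)
  if (length(bad) > 0L) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  hash <- config_hash(config)
  prov <- list(config_hash = hash, seed = config$seed,
               package_version = as.character(utils::packageVersion("netcohesion")))
  stage_seeds <- withr::with_seed(config$seed,
    sample.int(.Machine$integer.max, length(known_stages)))
  names(stage_seeds) <- known_stages
  summary <- list(provenance = prov, stages_run = character(0))
  on <- function(stage) stage %in% config$stages

  # --- cohort -------------------------------------------------------------
  cohort <- NULL
  truth <- NULL
  if (!is.null(config$cohort_dir)) {
    loaded <- tryCatch(read_cohort(config$cohort_dir),
                       error = function(e) stop("stage 'load' failed: ",
                                                conditionMessage(e)))
    cohort <- loaded$cohort
    truth <- loaded$truth
  } else if (on("simulate")) {
    sim <- config$sim
    sim$seed <- stage_seeds[["simulate"]]
    gen <- generate_cohort(sim)
    cohort <- gen$cohort
    truth <- gen$truth
    write_cohort(cohort, file.path(config$output_dir, "cohort"), truth)
    summary$stages_run <- c(summary$stages_run, "simulate")
    summary$n_subjects <- length(cohort$subjects)
  }
  needs_cohort <- intersect(config$stages,
                            c("nci", "groupdiff", "xcorr", "symptoms",
                              "classify"))
  if (is.null(cohort)) {
    if (length(needs_cohort) > 0L) {
      stop("stages ", paste(needs_cohort, collapse = ", "),
           " need a cohort: enable 'simulate' or set cohort_dir")
    }
    summary_path <- file.path(config$output_dir, "run_summary.json")
    jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(summary))
  }

  T_full <- ncol(cohort$subjects[[1]]$signals)
  grid <- make_window_grid(T_full - config$trim, config$window, config$step,
                           config$trim)
  networks <- if (!is.null(config$sim)) config$sim$networks else
    default_networks()
  networks <- Filter(function(nw) {
    all(nw$nodes %in% rownames(cohort$subjects[[1]]$signals))
  }, networks)
  summary$grid <- list(n_windows = grid$n_windows, window = grid$window,
                       step = grid$step, trim = grid$trim)

  # --- NCI ----------------------------------------------------------------
  nci <- NULL
  if (any(c("nci", "groupdiff", "xcorr", "symptoms", "classify") %in%
            config$stages)) {
    nci <- lapply(networks, function(nw) cohort_nci(cohort, nw, grid))
  }
  if (on("nci")) {
    for (nm in names(nci)) {
      write_stage_tsv(nci_long_table(nci[[nm]], nm),
                      file.path(config$output_dir,
                                paste0("nci_", nm, ".tsv")), prov)
    }
    summary$stages_run <- c(summary$stages_run, "nci")
  }

  # --- group differences --------------------------------------------------
  gd_rating <- NULL
  if (on("groupdiff") || on("xcorr")) {
    gd_rating <- groupdiff_series(cohort, "rating", grid, span = "full",
                                  TR_seconds = config$sim$TR_seconds %||% 3)
  }
  if (on("groupdiff")) {
    sig_summary <- list()
    for (nm in names(networks)) {
      for (meas in c("nci", "activity")) {
        gd <- groupdiff_series(cohort, meas, grid, network = networks[[nm]],
                               span = "truncated", max_lag = config$max_lag)
        label <- paste(meas, nm, sep = "_")
        write_stage_tsv(as.data.frame(gd),
                        file.path(config$output_dir,
                                  paste0("groupdiff_", label, ".tsv")), prov)
        sig_summary[[label]] <- significant_intervals(gd)
      }
    }
    write_stage_tsv(as.data.frame(gd_rating),
                    file.path(config$output_dir, "groupdiff_rating.tsv"),
                    prov)
    jsonlite::write_json(
      lapply(sig_summary, function(df) as.list(as.data.frame(df))),
      file.path(config$output_dir, "significant_intervals.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary$stages_run <- c(summary$stages_run, "groupdiff")
    summary$significant_windows <-
      lapply(sig_summary, function(df) sum(df$n_windows))
  }

  # --- lagged cross-correlation -------------------------------------------
  if (on("xcorr")) {
    xcorr_summary <- list()
    withr::with_seed(stage_seeds[["xcorr"]], {
      for (nm in names(networks)) {
        prof <- crosscorr_bootstrap(nci[[nm]]$values,
                                    cohort_groups(cohort), gd_rating$Z,
                                    L = config$max_lag,
                                    n_boot = config$n_boot)
        write_stage_tsv(as.data.frame(prof),
                        file.path(config$output_dir,
                                  paste0("xcorr_", nm, ".tsv")), prov)
        pk <- peak_lag(prof)
        xcorr_summary[[nm]] <- list(peak_lag = pk$lag, rho = pk$rho,
                                    q = pk$q)
      }
    })
    jsonlite::write_json(xcorr_summary,
                         file.path(config$output_dir, "xcorr_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary$stages_run <- c(summary$stages_run, "xcorr")
    summary$xcorr <- xcorr_summary
    summary$n_lags <- 2L * config$max_lag + 1L
    summary$aligned_length <- grid$n_windows - 2L * config$max_lag
  }

  # --- symptom correlations -----------------------------------------------
  if (on("symptoms")) {
    scores <- patient_symptom_scores(cohort)
    peaks <- list()
    for (nm in names(networks)) {
      pat_nci <- nci[[nm]]$values[rownames(scores), , drop = FALSE]
      for (sub in colnames(scores)) {
        sa <- symptom_corr_series(pat_nci, scores[, sub], grid,
                                  span = "truncated",
                                  max_lag = config$max_lag,
                                  network_name = nm, subscale = sub)
        label <- paste(nm, sub, sep = "_")
        write_stage_tsv(as.data.frame(sa),
                        file.path(config$output_dir,
                                  paste0("symptoms_", label, ".tsv")), prov)
        pk <- attr(sa, "peak")
        peaks[[label]] <- if (is.null(pk)) NULL else
          list(window_start = pk$window_start, rho = pk$rho, q = pk$q)
      }
    }
    jsonlite::write_json(peaks,
                         file.path(config$output_dir,
                                   "symptom_peaks.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary$stages_run <- c(summary$stages_run, "symptoms")
    summary$symptom_peaks <- peaks
  }

  # --- classification -----------------------------------------------------
  if (on("classify")) {
    fm <- build_feature_matrix(lapply(nci, `[[`, "values"))
    report <- permutation_test(fm$features, cohort_groups(cohort),
                               k = config$knn_k, folds = config$knn_folds,
                               reps = config$knn_reps,
                               n_perm = config$knn_perms,
                               perm_reps = config$knn_perm_reps,
                               seed = stage_seeds[["classify"]])
    jsonlite::write_json(
      c(list(provenance = prov, config = report$config),
        stats::setNames(
          lapply(seq_len(nrow(report$summary)), function(i) {
            list(mean = report$summary$mean[i], sd = report$summary$sd[i],
                 p_perm = report$summary$p_perm[i])
          }), report$summary$metric)),
      file.path(config$output_dir, "classification.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary$stages_run <- c(summary$stages_run, "classify")
    summary$classification <- stats::setNames(
      as.list(report$summary$mean), report$summary$metric)
    summary$n_features <- ncol(fm$features)
  }

  summary_path <- file.path(config$output_dir, "run_summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
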