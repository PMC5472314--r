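#' Experiment configuration
#'
#' Bundles everything an end-to-end run needs: the generator settings (one
#' [gait_config()] per modality, sharing the design counts and seed), the
#' schedule, which classifiers and modalities to run, fixed hyperparameters
#' or search grids, and preprocessing/evaluation flags.
#'
#' Hyperparameter search over the full default grids ([kbdr_grid()],
#' [svm_grid()]) is expensive; by default fixed mid-grid parameters are used
#' and `tune = TRUE` opts into the search (optionally with a reduced grid).
#'
#' @param n_subjects,n_sessions,n_trials,n_points,basis_rank,drift_scale,noise_scale
#'   generator settings, see [gait_config()].
#' @param modalities subset of `c("grf", "angles")`.
#' @param classifiers subset of `c("kbdr", "svm")`.
#' @param kbdr_params,svm_params fixed hyperparameters used when not tuning.
#' @param tune run [grid_search()] per subject before evaluating.
#' @param kbdr_search_grid,svm_search_grid grids used when tuning.
#' @param nested_cv use nested hyperparameter selection (slow).
#' @param fold_safe_scaling refit z-transform/scaling inside every fold.
#' @param permute_labels permute session labels (chance-floor experiment).
#' @param schedule a [session_schedule()].
#' @param seed integer master seed.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 9, n_sessions = 6, n_trials = 15,
                              n_points = 100, basis_rank = 8,
                              drift_scale = 0.04, noise_scale = 0.25,
                              modalities = c("grf", "angles"),
                              classifiers = c("kbdr", "svm"),
                              kbdr_params = list(degree = 1, alpha = 1e-5,
                                                 beta = 1),
                              svm_params = list(cost = 1),
                              tune = FALSE,
                              kbdr_search_grid = NULL,
                              svm_search_grid = NULL,
                              nested_cv = FALSE,
                              fold_safe_scaling = FALSE,
                              permute_labels = FALSE,
                              schedule = default_schedule(),
                              seed = 1L) {
  modalities <- match.arg(modalities, several.ok = TRUE)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  structure(as.list(environment()), class = "experiment_config")
}

config_for_modality <- function(config, modality) {
  # modality-specific generator seed derived from the master seed so the two
  # modalities get independent but reproducible draws
  gait_config(n_subjects = config$n_subjects,
              n_sessions = config$n_sessions, n_trials = config$n_trials,
              n_points = config$n_points, modality = modality,
              drift_scale = config$drift_scale,
              noise_scale = config$noise_scale,
              basis_rank = config$basis_rank,
              seed = config$seed + 1000L * match(modality,
                                                 c("grf", "angles")))
}

#' Simulate and write a full experiment dataset
#'
#' Generates the configured dataset for every requested modality and writes
#' trials CSV, schedule CSV and a JSON provenance sidecar per modality.
#'
#' @param config an [experiment_config()].
#' @param out_dir writable output directory (created if missing).
#' @return Named list of written trial-CSV paths, invisibly.
#' @export
simulate_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_schedule_csv(config$schedule, file.path(out_dir, "schedule.csv"))
  paths <- list()
  for (mod in config$modalities) {
    gcfg <- config_for_modality(config, mod)
    trials <- generate_dataset(gcfg, config$schedule)
    p <- file.path(out_dir, paste0("trials_", mod, ".csv"))
    write_trials_csv(trials, p)
    jsonlite::write_json(unclass(gcfg), paste0(p, ".json"),
                         auto_unbox = TRUE, digits = NA)
    paths[[mod]] <- p
  }
  invisible(paths)
}

#' Run the full multi-subject experiment
#'
#' The end-to-end pipeline: generate (or accept) a dataset per modality,
#' preprocess and evaluate every subject with every requested classifier
#' (six-session and all pairwise designs), aggregate pairwise rates into the
#' T1-T4 time intervals, and run the interval statistics per
#' classifier/modality combination.
#'
#' @param config an [experiment_config()].
#' @param datasets optional named list (`grf`, `angles`) of pre-generated
#'   `gait_trials` data frames; defaults to generating from the config.
#' @param verbose print per-stage progress.
#' @return An object of class `gait_experiment`: `reports` (one `gait_eval`
#'   per subject x modality x classifier), `summary` (data frame of
#'   six-session rates), `interval_tables` (subjects x T1-T4 matrices) and
#'   `stats` (per combination, [interval_stats()] output), plus the config.
#' @export
run_experiment <- function(config = experiment_config(), datasets = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- proc.time()[3]
  say <- function(...) if (verbose) message(sprintf("[%6.1fs] ",
                                                    proc.time()[3] - t0),
                                            sprintf(...))
  reports <- list()
  summary_rows <- list()
  interval_tables <- list()
  stats_out <- list()

  for (mod in config$modalities) {
    trials <- if (!is.null(datasets) && !is.null(datasets[[mod]]))
      datasets[[mod]]
    else {
      say("simulating %s dataset", mod)
      generate_dataset(config_for_modality(config, mod), config$schedule)
    }
    if (nrow(trials) == 0) stop("simulate stage produced an empty dataset")
    subjects <- unique(trials$subject)
    for (clf in config$classifiers) {
      imat <- matrix(NA_real_, length(subjects), 4,
                     dimnames = list(subjects, paste0("T", 1:4)))
      for (s in subjects) {
        params <- if (clf == "kbdr") config$kbdr_params else config$svm_params
        if (config$tune) {
          grid <- if (clf == "kbdr") {
            if (is.null(config$kbdr_search_grid)) kbdr_grid()
            else config$kbdr_search_grid
          } else {
            if (is.null(config$svm_search_grid)) svm_grid()
            else config$svm_search_grid
          }
          feats <- preprocess_trials(trials[trials$subject == s, ], mod,
                                     fold_safe = config$fold_safe_scaling)
          gs <- grid_search(feats, classifier = clf, grid = grid,
                            nested = config$nested_cv)
          params <- as.list(gs$best)
        }
        if (config$permute_labels) set.seed(config$seed + match(s, subjects))
        report <- run_full_design(trials, s, mod, clf, params,
                                  schedule = config$schedule,
                                  fold_safe = config$fold_safe_scaling,
                                  permute_labels = config$permute_labels)
        key <- paste(s, mod, clf, sep = ".")
        reports[[key]] <- report
        imat[s, ] <- report$intervals$means
        summary_rows[[key]] <- data.frame(
          subject = s, modality = mod, classifier = clf,
          six_session_rate = report$six_session$rate,
          correct = report$six_session$correct, n = report$six_session$n,
          stringsAsFactors = FALSE)
        say("subject %s %s %s: six-session %.1f%%", s, mod, clf,
            report$six_session$rate)
      }
      ck <- paste(mod, clf, sep = ".")
      interval_tables[[ck]] <- imat
      stats_out[[ck]] <- if (nrow(imat) >= 3) interval_stats(imat) else NULL
    }
  }
  structure(list(config = config,
                 reports = reports,
                 summary = do.call(rbind, c(summary_rows,
                                            make.row.names = FALSE)),
                 interval_tables = interval_tables,
                 stats = stats_out),
            class = "gait_experiment")
}

#' @export
print.gait_experiment <- function(x, ...) {
  cat("gait session-classification experiment\n")
  agg <- stats::aggregate(six_session_rate ~ modality + classifier,
                          data = x$summary, FUN = mean)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %s / %s: mean six-session rate %.1f%%\n",
                agg$modality[i], toupper(agg$classifier[i]),
                agg$six_session_rate[i]))
  invisible(x)
}

#' Mean pairwise-rate table across subjects
#'
#' One row per session pair (interval, sessions, duration) with the mean and
#' sd of the one-on-one rate across subjects, per classifier and modality.
#'
#' @param experiment a `gait_experiment`.
#' @return Data frame.
#' @export
experiment_pairwise_summary <- function(experiment) {
  tabs <- do.call(rbind, lapply(experiment$reports, pairwise_table))
  agg <- stats::aggregate(rate ~ interval + sessions + duration_min +
                            modality + classifier,
                          data = tabs, FUN = mean)
  sds <- stats::aggregate(rate ~ interval + sessions + duration_min +
                            modality + classifier,
                          data = tabs, FUN = stats::sd)
  agg$rate_sd <- sds$rate
  agg[order(agg$modality, agg$classifier, agg$duration_min), ]
}

#' Write the experiment report bundle
#'
#' Writes the per-subject six-session summary, the pairwise-rate table and
#' the interval statistics to CSV/JSON files under `out_dir`.
#'
#' @param experiment a `gait_experiment`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_experiment_reports <- function(experiment, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(experiment$summary,
                   file.path(out_dir, "six_session_rates.csv"),
                   row.names = FALSE)
  utils::write.csv(experiment_pairwise_summary(experiment),
                   file.path(out_dir, "pairwise_rates.csv"),
                   row.names = FALSE)
  for (ck in names(experiment$stats)) {
    if (is.null(experiment$stats[[ck]])) next
    write_stats_csv(experiment$stats[[ck]],
                    file.path(out_dir, paste0("interval_stats_", ck,
                                              ".csv")))
  }
  jsonlite::write_json(
    lapply(experiment$reports, function(r)
      list(subject = r$subject, modality = r$modality,
           classifier = r$classifier,
           six_session_rate = r$six_session$rate,
           correct = r$six_session$correct,
           pairwise = r$pairwise,
           interval_means = as.list(r$intervals$means))),
    file.path(out_dir, "reports.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
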