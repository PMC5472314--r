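#' Default hyperparameter grids
#'
#' The full search grids for the two classifiers: the signed polynomial
#' kernel degree 0.1, 0.3, ..., in steps of 0.2 (15 values), ridge
#' regulariser `alpha` in 1e-7 ... 1e-3 by decades and kernel offset `beta`
#' on a 1-3 sequence per decade from 0.01 to 10 for KBDR; SVM cost
#' `C = 2^-5, 2^-4.75, ..., 2^15`. Grid order (row order of the returned
#' data frame) is the documented tie-breaking order of [grid_search()].
#'
#' @return Data frame with one row per hyperparameter combination.
#' @export
kbdr_grid <- function() {
  expand.grid(degree = seq(0.1, 3, by = 0.2),
              alpha = 10^seq(-7, -3),
              beta = c(0.01, 0.03, 0.1, 0.3, 1, 3, 10))
}

#' @rdname kbdr_grid
#' @export
svm_grid <- function() {
  data.frame(cost = 2^seq(-5, 15, by = 0.25))
}

# Normalise classifier input: returns list(values, labels, fold_safe, z_mode)
resolve_features <- function(feats, labels = NULL) {
  if (inherits(feats, "gait_features")) {
    list(values = feats$values,
         labels = if (is.null(labels)) feats$session else factor(labels),
         fold_safe = isTRUE(feats$fold_safe),
         z_mode = if (is.null(feats$z_mode)) "global" else feats$z_mode)
  } else {
    if (is.null(labels)) stop("labels required for plain matrix input")
    list(values = as.matrix(feats), labels = factor(labels),
         fold_safe = FALSE, z_mode = "global")
  }
}

fit_classifier <- function(classifier, x, y, params) {
  if (classifier == "kbdr") {
    do.call(kbdr, c(list(x = x, y = y), params))
  } else {
    do.call(svm_l2, c(list(x = x, y = y), params))
  }
}

#' Leave-one-out cross-validated classification rate
#'
#' For every trial in the design, a classifier is fitted on all remaining
#' trials and used to predict the held-out trial; the rate is the percentage
#' of correct predictions. The six-session design uses all rows; a pairwise
#' (one-on-one) design restricts to the two named sessions.
#'
#' If the feature object was preprocessed with `fold_safe = TRUE`, the
#' z-transformation and range scaling are refitted on each fold's training
#' rows, so the held-out trial never influences any fitted quantity.
#'
#' @param feats a `gait_features` object, or a plain feature matrix.
#' @param labels class labels (defaults to the session labels).
#' @param classifier `"kbdr"` or `"svm"`.
#' @param params list of classifier hyperparameters (see [kbdr()],
#'   [svm_l2()]).
#' @param sessions optional character vector restricting the design to these
#'   sessions (e.g. one session pair).
#' @return List with `rate` (percent correct), `correct` (count), `n`,
#'   `predictions`, `truth` and the `confusion` matrix (true sessions in
#'   rows).
#' @export
loocv_rate <- function(feats, labels = NULL,
                       classifier = c("kbdr", "svm"), params = list(),
                       sessions = NULL) {
  classifier <- match.arg(classifier)
  rf <- resolve_features(feats, labels)
  x <- rf$values
  y <- rf$labels
  if (!is.null(sessions)) {
    keep <- y %in% sessions
    x <- x[keep, , drop = FALSE]
    y <- factor(y[keep], levels = sessions)
  } else {
    y <- droplevels(y)
  }
  if (any(table(y) < 2))
    stop("invalid design: every class needs at least two trials")
  n <- nrow(x)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (i in seq_len(n)) {
    xi <- if (rf$fold_safe) scale_fitted(x, rf$z_mode, setdiff(seq_len(n), i))
          else x
    fit <- fit_classifier(classifier, xi[-i, , drop = FALSE], y[-i], params)
    pred[i] <- as.character(predict(fit, xi[i, , drop = FALSE]))
  }
  correct <- sum(pred == y)
  list(rate = 100 * correct / n, correct = correct, n = n,
       predictions = pred, truth = y,
       confusion = table(truth = y, predicted = pred))
}

#' Hyperparameter grid search by leave-one-out rate
#'
#' Scores every grid row by its LOOCV rate on the design and returns the
#' first maximiser in grid order (the documented deterministic tie-break).
#' With `nested = TRUE`, hyperparameters are instead re-selected inside each
#' outer training fold (an honest generalisation estimate, considerably
#' slower); the outer LOOCV rate and the per-fold selections are returned,
#' with the modal selection reported as `best`.
#'
#' @param feats,labels,classifier,sessions as in [loocv_rate()].
#' @param grid data frame of hyperparameter combinations, one per row.
#' @param nested select within each training fold rather than once globally.
#' @return List with `best` (one-row data frame), `rate` (its LOOCV rate)
#'   and `rates` (per-grid-row rates; `NULL` when nested), plus `per_fold`
#'   selections when nested.
#' @export
grid_search <- function(feats, labels = NULL,
                        classifier = c("kbdr", "svm"), grid,
                        sessions = NULL, nested = FALSE) {
  classifier <- match.arg(classifier)
  if (NROW(grid) < 1) stop("empty grid")
  grid <- as.data.frame(grid)
  if (!nested) {
    rates <- vapply(seq_len(nrow(grid)), function(g) {
      loocv_rate(feats, labels, classifier, as.list(grid[g, , drop = FALSE]),
                 sessions)$rate
    }, numeric(1))
    best <- which.max(rates)
    return(list(best = grid[best, , drop = FALSE], rate = rates[best],
                rates = rates))
  }
  rf <- resolve_features(feats, labels)
  x <- rf$values
  y <- rf$labels
  if (!is.null(sessions)) {
    keep <- y %in% sessions
    x <- x[keep, , drop = FALSE]
    y <- factor(y[keep], levels = sessions)
  } else y <- droplevels(y)
  n <- nrow(x)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  chosen <- integer(n)
  for (i in seq_len(n)) {
    inner <- grid_search(x[-i, , drop = FALSE], y[-i], classifier, grid,
                         nested = FALSE)
    gi <- which(apply(grid, 1, function(r)
      all(r == unlist(inner$best))))[1]
    chosen[i] <- gi
    fit <- fit_classifier(classifier, x[-i, , drop = FALSE], y[-i],
                          as.list(grid[gi, , drop = FALSE]))
    pred[i] <- as.character(predict(fit, x[i, , drop = FALSE]))
  }
  mode_row <- as.integer(names(sort(table(chosen), decreasing = TRUE))[1])
  list(best = grid[mode_row, , drop = FALSE],
       rate = 100 * mean(pred == y), rates = NULL, per_fold = chosen)
}

#' Group pairwise session rates into time intervals
#'
#' Pairwise (one-on-one) session classification rates are grouped by the
#' elapsed time between the two sessions into four intervals: T1 = 10 min,
#' T2 = 30-50 min, T3 = 90-110 min, T4 = 130-150 min. For the default
#' six-session schedule the intervals contain 3, 4, 4 and 4 session pairs.
#'
#' @param pairwise data frame with columns `duration_min` and `rate`.
#' @return List with `means` (named T1-T4 mean rates), `interval` (per-pair
#'   assignment) and `counts`.
#' @export
group_into_intervals <- function(pairwise) {
  lims <- list(T1 = c(10, 10), T2 = c(30, 50), T3 = c(90, 110),
               T4 = c(130, 150))
  assign <- vapply(pairwise$duration_min, function(d) {
    hit <- names(lims)[vapply(lims, function(l)
      d >= l[1] && d <= l[2], logical(1))]
    if (length(hit) != 1)
      stop(sprintf("schedule mismatch: duration %g min outside T1-T4", d))
    hit
  }, character(1))
  assign <- factor(assign, levels = names(lims))
  means <- vapply(names(lims), function(iv)
    mean(pairwise$rate[assign == iv]), numeric(1))
  list(means = means, interval = assign, counts = table(assign))
}

#' Run the full classification design for one subject
#'
#' Preprocesses one subject's trials and computes the six-session LOOCV
#' classification rate (with confusion matrix and correct count out of the
#' 90 trials of the full design) and all pairwise one-on-one rates tagged
#' with the schedule durations, grouped into the T1-T4 time intervals.
#'
#' @param trials a `gait_trials` data frame (the subject is selected with
#'   `subject`); must carry a schedule attribute or one must be supplied.
#' @param subject subject identifier (default: first in the data).
#' @param modality `"grf"` or `"angles"`.
#' @param classifier `"kbdr"` or `"svm"`.
#' @param params classifier hyperparameters.
#' @param schedule a [session_schedule()]; default from the data.
#' @param fold_safe refit z-transform/scaling inside each fold.
#' @param permute_labels permute session labels before evaluating (chance
#'   floor check; uses the current RNG state).
#' @return An object of class `gait_eval`: `six_session` (the [loocv_rate()]
#'   result), `pairwise` (15-row data frame), `intervals`, plus design
#'   metadata.
#' @export
run_full_design <- function(trials, subject = trials$subject[1],
                            modality = c("grf", "angles"),
                            classifier = c("kbdr", "svm"),
                            params = list(),
                            schedule = attr(trials, "schedule"),
                            fold_safe = FALSE, permute_labels = FALSE) {
  modality <- match.arg(modality)
  classifier <- match.arg(classifier)
  if (is.null(schedule)) stop("no session schedule available")
  trials <- trials[trials$subject == subject, , drop = FALSE]
  if (!setequal(unique(trials$session), schedule$session))
    stop("missing sessions: trials do not cover the schedule")
  feats <- preprocess_trials(trials, modality, fold_safe = fold_safe)
  labels <- feats$session
  if (permute_labels) labels <- sample(labels)

  six <- loocv_rate(feats, labels, classifier, params)
  pairs <- session_pairs(schedule)
  pairs$rate <- vapply(seq_len(nrow(pairs)), function(k) {
    loocv_rate(feats, labels, classifier, params,
               sessions = c(pairs$session_i[k], pairs$session_j[k]))$rate
  }, numeric(1))
  intervals <- group_into_intervals(pairs)
  structure(list(subject = subject, modality = modality,
                 classifier = classifier, params = params,
                 six_session = six, pairwise = pairs,
                 intervals = intervals, fold_safe = fold_safe,
                 permuted = permute_labels),
            class = "gait_eval")
}

#' @export
print.gait_eval <- function(x, ...) {
  cat(sprintf("subject %s, %s, %s%s\n", x$subject, x$modality,
              toupper(x$classifier),
              if (x$permuted) " (permuted labels)" else ""))
  cat(sprintf("  six-session rate: %.1f%% (%d/%d correct)\n",
              x$six_session$rate, x$six_session$correct, x$six_session$n))
  m <- x$intervals$means
  cat(sprintf("  one-on-one interval means: %s\n",
              paste(sprintf("%s %.1f%%", names(m), m), collapse = ", ")))
  invisible(x)
}

#' Flatten an evaluation report to a pairwise-rate table
#'
#' @param report a `gait_eval` object.
#' @return Data frame with interval, session pair, duration and rate rows.
#' @export
pairwise_table <- function(report) {
  data.frame(subject = report$subject, modality = report$modality,
             classifier = report$classifier,
             interval = as.character(report$intervals$interval),
             sessions = paste(report$pairwise$session_i,
                              report$pairwise$session_j, sep = "-"),
             duration_min = report$pairwise$duration_min,
             rate = report$pairwise$rate,
             stringsAsFactors = FALSE)
}
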