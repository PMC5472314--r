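#' Stride segmentation by vertical force threshold
#'
#' A stride runs from right-foot heel strike to left-foot toe off, detected
#' on the vertical ground reaction force: the window starts at the first
#' sample at or above the threshold and ends at the last such sample.
#'
#' @param vertical_grf numeric series of vertical force in newtons.
#' @param threshold_newton detection threshold (default 10 N).
#' @return Integer vector `c(start, end)` of 1-based indices.
#' @examples
#' f <- c(rep(0, 29), rep(50, 50), rep(0, 21))
#' segment_stride(f)  # 30 79
#' @export
segment_stride <- function(vertical_grf, threshold_newton = 10) {
  idx <- which(vertical_grf >= threshold_newton)
  if (length(idx) == 0)
    stop("unusable trial: vertical force never reaches the threshold")
  c(start = idx[1], end = idx[length(idx)])
}

#' Zero-phase Butterworth low-pass filter
#'
#' Bidirectional (forward-backward) Butterworth filtering, the standard
#' smoothing step for optical-capture joint-angle trajectories.
#'
#' @param curve numeric series.
#' @param sample_rate_hz sampling rate (default 250 Hz).
#' @param cutoff_hz cut-off frequency (default 18 Hz); must be below the
#'   Nyquist frequency.
#' @param order filter order before the bidirectional pass (default 2).
#' @return Filtered series of the same length.
#' @export
butterworth_lowpass <- function(curve, sample_rate_hz = 250,
                                cutoff_hz = 18, order = 2) {
  if (cutoff_hz >= sample_rate_hz / 2)
    stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff_hz / (sample_rate_hz / 2), "low")
  n <- length(curve)
  # odd-reflection padding suppresses the zero-initial-condition transients
  # of the forward-backward pass at the series boundaries
  npad <- min(n - 1, max(9L, 3L * (2L * order + 1L), 30L))
  head_pad <- 2 * curve[1] - curve[(npad + 1):2]
  tail_pad <- 2 * curve[n] - curve[(n - 1):(n - npad)]
  padded <- c(head_pad, curve, tail_pad)
  out <- as.numeric(signal::filtfilt(bf, padded))
  out[(npad + 1):(npad + n)]
}

#' Body-weight normalisation of force curves
#'
#' Divides force samples by body weight (mass times gravitational
#' acceleration) so kinetic curves are in dimensionless body-weight units.
#'
#' @param grf_curves numeric vector or matrix of forces in newtons.
#' @param body_mass_kg body mass (> 0).
#' @param g gravitational acceleration (default 9.81 m/s^2).
#' @return Same shape as the input, in body-weight units.
#' @export
normalize_bodyweight <- function(grf_curves, body_mass_kg, g = 9.81) {
  if (!is.finite(body_mass_kg) || body_mass_kg <= 0)
    stop("body mass must be positive")
  grf_curves / (body_mass_kg * g)
}

#' Time normalisation of a curve
#'
#' Linear interpolation of a stride-window curve onto `n_out` equally spaced
#' points; the first and last samples are preserved exactly.
#'
#' @param curve numeric series (length >= 2).
#' @param n_out output length (default 100).
#' @return Numeric vector of length `n_out`.
#' @export
time_normalize <- function(curve, n_out = 100) {
  n <- length(curve)
  if (n < 2) stop("input curve too short to resample")
  stats::approx(x = seq(0, 1, length.out = n), y = curve,
                xout = seq(0, 1, length.out = n_out))$y
}

#' z-transformation of trial feature rows
#'
#' Standardises either each trial's joined feature vector to mean 0 / sd 1
#' across its own features (`per_trial`, the kinematic convention) or each
#' feature column to mean 0 / sd 1 across all trials of the subject
#' (`global`, the kinetic convention).
#'
#' @param m numeric matrix, trials in rows, features in columns.
#' @param mode `"per_trial"` or `"global"`.
#' @return Matrix of the same shape.
#' @export
z_transform <- function(m, mode = c("per_trial", "global")) {
  mode <- match.arg(mode)
  m <- as.matrix(m)
  if (mode == "per_trial") {
    mu <- rowMeans(m)
    sd <- apply(m, 1, stats::sd)
    if (any(sd == 0)) stop("degenerate input: constant trial vector")
    (m - mu) / sd
  } else {
    mu <- colMeans(m)
    sd <- apply(m, 2, stats::sd)
    if (any(sd == 0)) stop("degenerate input: constant feature column")
    sweep(sweep(m, 2, mu, "-"), 2, sd, "/")
  }
}

#' Affine range scaling per feature column
#'
#' Maps each feature column so its observed minimum and maximum land exactly
#' on `lo` and `hi`; constant columns map to the midpoint. Scaling to a
#' common range keeps variables with large numeric ranges from dominating a
#' kernel or margin classifier.
#'
#' @param m numeric matrix, trials in rows.
#' @param lo,hi target range (defaults -1 and 1).
#' @return Matrix of the same shape with column ranges `[lo, hi]`.
#' @export
scale_to_range <- function(m, lo = -1, hi = 1) {
  if (lo >= hi) stop("lo must be below hi")
  m <- as.matrix(m)
  cmin <- apply(m, 2, min)
  cmax <- apply(m, 2, max)
  span <- cmax - cmin
  const <- span == 0
  span[const] <- 1
  out <- sweep(sweep(m, 2, cmin, "-"), 2, span / (hi - lo), "/") + lo
  if (any(const)) out[, const] <- (lo + hi) / 2
  out
}

#' Join per-channel curves into classification vectors
#'
#' Concatenates each trial's channel curves, channel-major and time-minor,
#' in the canonical channel order of the modality, producing one feature row
#' per trial. For the full 6-session x 15-trial design this yields 90 x 1800
#' (joint angles) or 90 x 600 (GRF) matrices.
#'
#' @param trials a `gait_trials` data frame restricted to one subject.
#' @param modality `"grf"` or `"angles"`.
#' @return A list of class `gait_features`: `values` (n_trials x n_features
#'   matrix), `session` (factor), `trial`, `subject`, `feature_names`.
#' @export
join_vectors <- function(trials, modality = c("grf", "angles")) {
  modality <- match.arg(modality)
  chans <- modality_channels(modality)
  trials <- trials[trials$channel %in% chans, , drop = FALSE]
  if (nrow(trials) == 0) stop("no trials for this modality")
  chans <- chans[chans %in% unique(trials$channel)]  # canonical order
  if (length(unique(trials$subject)) != 1)
    stop("join_vectors expects a single subject")
  tcols <- grep("^t[0-9]+$", names(trials), value = TRUE)
  n_points <- length(tcols)

  key <- interaction(trials$session, trials$trial, drop = TRUE, lex.order = TRUE)
  ids <- !duplicated(key)
  n_tr <- sum(ids)
  if (nrow(trials) != n_tr * length(chans))
    stop("inconsistent channel set across trials")

  values <- matrix(NA_real_, n_tr, n_points * length(chans))
  rowkey <- paste(trials$session, trials$trial)
  ukey <- unique(rowkey)
  for (ci in seq_along(chans)) {
    sub <- trials[trials$channel == chans[ci], , drop = FALSE]
    ord <- match(ukey, paste(sub$session, sub$trial))
    if (anyNA(ord)) stop("inconsistent channel set across trials")
    values[, (ci - 1L) * n_points + seq_len(n_points)] <-
      as.matrix(sub[ord, tcols])
  }
  first <- trials[ids, c("subject", "session", "trial")]
  colnames(values) <- paste(rep(chans, each = n_points),
                            rep(tcols, length(chans)), sep = ".")
  structure(list(values = values,
                 session = factor(first$session,
                                  levels = unique(first$session)),
                 trial = first$trial,
                 subject = first$subject[1],
                 modality = modality,
                 feature_names = colnames(values)),
            class = "gait_features")
}

#' @export
print.gait_features <- function(x, ...) {
  cat(sprintf("gait feature matrix: subject %s, %s, %d trials x %d features, %d sessions\n",
              x$subject, x$modality, nrow(x$values), ncol(x$values),
              nlevels(x$session)))
  invisible(x)
}

#' Full preprocessing chain for one subject
#'
#' Applies the contracted processing order to one subject's generated or
#' recorded stride curves: body-weight normalisation (GRF only), per-curve
#' z-transformation convention (per-trial for joint angles, per-feature
#' across all of the subject's trials for GRF), range scaling to
#' `[-1, 1]`, and joining into classification vectors. Stride segmentation,
#' filtering and time normalisation belong to the raw-recording path (see
#' [preprocess_raw_curve()]); curves handed to this function are already
#' time-normalised.
#'
#' By default the z-transformation and range scaling are fitted on the full
#' trial matrix, mirroring a processing chain that is run once before any
#' cross-validation. `fold_safe = TRUE` exposes fit parameters so the
#' cross-validation harness can refit them on training rows only.
#'
#' @param trials a `gait_trials` data frame (one subject).
#' @param modality `"grf"` or `"angles"`.
#' @param fold_safe if `TRUE`, skip the full-matrix z-transform/scaling here
#'   and mark the feature object so the LOOCV harness refits both on each
#'   training fold.
#' @return A `gait_features` object; values lie in `[-1, 1]` unless
#'   `fold_safe`.
#' @export
preprocess_trials <- function(trials, modality = c("grf", "angles"),
                              fold_safe = FALSE) {
  modality <- match.arg(modality)
  if (modality == "grf") {
    tcols <- grep("^t[0-9]+$", names(trials), value = TRUE)
    keep <- trials$channel %in% grf_channels()
    trials <- trials[keep, , drop = FALSE]
    trials[, tcols] <- normalize_bodyweight(as.matrix(trials[, tcols]),
                                            trials$body_mass[1])
  }
  feats <- join_vectors(trials, modality)
  feats$z_mode <- if (modality == "angles") "per_trial" else "global"
  feats$fold_safe <- isTRUE(fold_safe)
  if (!fold_safe) {
    feats$values <- scale_to_range(z_transform(feats$values, feats$z_mode))
  }
  feats
}

# Apply the z-transform + range-scaling convention with parameters fitted on
# the rows indexed by `fit_rows` only (fold-safe path of the LOOCV harness).
# Per-trial standardisation is row-local so it needs no fitting; the global
# convention and the range scaling are fitted on the training rows.
scale_fitted <- function(values, z_mode, fit_rows) {
  tr <- values[fit_rows, , drop = FALSE]
  if (z_mode == "per_trial") {
    z <- z_transform(values, "per_trial")
    ztr <- z[fit_rows, , drop = FALSE]
  } else {
    mu <- colMeans(tr)
    sd <- apply(tr, 2, stats::sd)
    sd[sd == 0] <- 1
    z <- sweep(sweep(values, 2, mu, "-"), 2, sd, "/")
    ztr <- z[fit_rows, , drop = FALSE]
  }
  cmin <- apply(ztr, 2, min)
  cmax <- apply(ztr, 2, max)
  span <- cmax - cmin
  const <- span == 0
  span[const] <- 1
  out <- sweep(sweep(z, 2, cmin, "-"), 2, span / 2, "/") - 1
  if (any(const)) out[, const] <- 0
  out
}

#' Preprocess one raw recorded curve
#'
#' The raw-recording path: segment the stride window on the vertical force
#' series, crop, optionally low-pass filter (joint angles), optionally
#' body-weight normalise (forces), and time-normalise to `n_out` points.
#'
#' @param curve raw series for one channel.
#' @param vertical_grf raw vertical force series (newtons) used for
#'   segmentation; defaults to `curve` itself.
#' @param threshold_newton stride detection threshold.
#' @param filter apply the zero-phase Butterworth filter before resampling.
#' @param sample_rate_hz,cutoff_hz filter settings.
#' @param body_mass_kg if non-`NULL`, body-weight normalise.
#' @param n_out output samples.
#' @return Numeric vector of length `n_out`.
#' @export
preprocess_raw_curve <- function(curve, vertical_grf = curve,
                                 threshold_newton = 10, filter = FALSE,
                                 sample_rate_hz = 250, cutoff_hz = 18,
                                 body_mass_kg = NULL, n_out = 100) {
  w <- segment_stride(vertical_grf, threshold_newton)
  out <- curve[w[1]:w[2]]
  if (filter) out <- butterworth_lowpass(out, sample_rate_hz, cutoff_hz)
  if (!is.null(body_mass_kg)) out <- normalize_bodyweight(out, body_mass_kg)
  time_normalize(out, n_out)
}

#' Write a feature matrix as CSV with a JSON provenance sidecar
#'
#' @param feats a `gait_features` object.
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(feats, path) {
  df <- data.frame(session = as.character(feats$session),
                   trial = feats$trial, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(feats$values))
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(subject = feats$subject, modality = feats$modality,
               n_trials = nrow(feats$values),
               n_features = ncol(feats$values),
               z_mode = feats$z_mode, fold_safe = isTRUE(feats$fold_safe))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
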