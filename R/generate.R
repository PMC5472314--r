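#' Generator configuration
#'
#' Settings for the synthetic multi-session stride-curve generator. Each
#' generated trial curve is a subject template plus a session-level drift and
#' trial-level noise, both expressed in a smooth low-rank basis:
#'
#' * the drift is a Gaussian random walk in basis-coefficient space across
#'   the session start times, so the expected squared distance between the
#'   drift curves of two sessions grows linearly with the elapsed time
#'   between them (`basis_rank * drift_scale^2 * |t_i - t_j|`, per channel,
#'   in template-amplitude units);
#' * the trial noise is independent Gaussian basis noise with coefficient
#'   standard deviation `noise_scale`.
#'
#' Both scales are dimensionless: perturbations are multiplied by each
#' channel's template temporal standard deviation, so one dial has the same
#' meaning for ground reaction forces and joint angles.
#'
#' @param n_subjects,n_sessions,n_trials study design counts (defaults: 9
#'   subjects, 6 sessions, 15 trials per session).
#' @param n_points samples per curve (default 100).
#' @param modality `"grf"` (forces in newtons, using per-subject body mass)
#'   or `"angles"` (degrees).
#' @param drift_scale drift coefficient scale per sqrt(minute); default
#'   calibrated so pairwise session classification rates fall in the
#'   73-100\% band observed for within-day human gait.
#' @param noise_scale trial-noise coefficient scale.
#' @param basis_rank number of smooth basis functions (<= n_points).
#' @param body_mass_mean,body_mass_sd per-subject body-mass distribution in
#'   kg (GRF modality only).
#' @param seed integer seed; fixed seed gives a bit-identical dataset.
#' @return A list of class `gait_config`.
#' @export
gait_config <- function(n_subjects = 9, n_sessions = 6, n_trials = 15,
                        n_points = 100, modality = c("grf", "angles"),
                        drift_scale = 0.04, noise_scale = 0.25,
                        basis_rank = 8, body_mass_mean = 73.2,
                        body_mass_sd = 13.3, seed = 1L) {
  modality <- match.arg(modality)
  counts <- c(n_subjects, n_sessions, n_trials, n_points, basis_rank)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("design counts must be positive integers")
  if (drift_scale < 0 || noise_scale < 0)
    stop("drift_scale and noise_scale must be >= 0")
  if (basis_rank > n_points) stop("basis_rank must be <= n_points")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 n_trials = as.integer(n_trials),
                 n_points = as.integer(n_points), modality = modality,
                 drift_scale = drift_scale, noise_scale = noise_scale,
                 basis_rank = as.integer(basis_rank),
                 body_mass_mean = body_mass_mean,
                 body_mass_sd = body_mass_sd,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "gait_config")
}

#' Orthonormal smooth sine basis
#'
#' Discrete sine basis evaluated at sample midpoints; columns are exactly
#' orthonormal in the ordinary Euclidean inner product on the grid and
#' vanish towards the curve boundaries, so low-rank perturbations stay
#' physiologically smooth and leave stride endpoints nearly unloaded.
#'
#' @param n_points grid size.
#' @param rank number of basis functions (<= n_points).
#' @return `n_points` x `rank` matrix with orthonormal columns.
#' @export
smooth_basis <- function(n_points, rank) {
  if (rank > n_points) stop("rank must be <= n_points")
  i <- seq_len(n_points) - 0.5
  B <- sapply(seq_len(rank), function(k) sin(pi * k * i / n_points))
  B <- matrix(B, n_points, rank)
  sweep(B, 2, sqrt(colSums(B^2)), "/")
}

#' Generate a synthetic multi-session stride-curve dataset
#'
#' Emulates a within-day gait study: every subject walks `n_trials` trials in
#' each of `n_sessions` sessions at the schedule's start times. Curves are
#' the modality template plus session drift (Brownian in basis-coefficient
#' space over elapsed minutes) plus independent trial noise; GRF curves are
#' expressed in newtons via a per-subject body mass so that body-weight
#' normalisation is a real processing step downstream.
#'
#' @param config a [gait_config()].
#' @param schedule a [session_schedule()] with `config$n_sessions` sessions.
#' @return A long-format data frame of class `gait_trials`, one row per
#'   trial-channel: columns `subject`, `session`, `trial`, `channel`,
#'   `body_mass`, then `t000 ... t<n_points-1>`. The schedule is attached as
#'   attribute `"schedule"`.
#' @examples
#' cfg <- gait_config(n_subjects = 1, seed = 7)
#' d <- generate_dataset(cfg, default_schedule())
#' dim(d)
#' @export
generate_dataset <- function(config, schedule = default_schedule()) {
  stopifnot(inherits(config, "gait_config"))
  if (nrow(schedule) != config$n_sessions)
    stop("schedule must have n_sessions rows")
  if (!is.null(config$seed)) set.seed(config$seed)

  tpl <- modality_template(config$modality, config$n_points)
  chans <- colnames(tpl)
  amp <- apply(tpl, 2, stats::sd)
  amp[amp == 0] <- 1
  B <- smooth_basis(config$n_points, config$basis_rank)
  dt <- c(0, diff(schedule$start_min))
  n_ch <- length(chans)
  tcols <- sprintf("t%03d", seq_len(config$n_points) - 1L)

  rows <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    body_mass <- if (config$modality == "grf")
      max(40, stats::rnorm(1, config$body_mass_mean, config$body_mass_sd))
    else NA_real_
    unit <- if (config$modality == "grf") body_mass * 9.81 else 1

    # session drift: one random walk per channel in coefficient space
    drift <- array(0, c(config$basis_rank, n_ch, config$n_sessions))
    for (j in seq_len(config$n_sessions)[-1]) {
      step <- matrix(stats::rnorm(config$basis_rank * n_ch), ncol = n_ch) *
        config$drift_scale * sqrt(dt[j])
      drift[, , j] <- drift[, , j - 1] + step
    }

    n_tr <- config$n_sessions * config$n_trials
    curves <- matrix(NA_real_, n_tr * n_ch, config$n_points)
    meta <- data.frame(
      subject = sprintf("P%02d", s),
      session = rep(schedule$session, each = config$n_trials * n_ch),
      trial = rep(rep(seq_len(config$n_trials), each = n_ch),
                  config$n_sessions),
      channel = rep(chans, n_tr),
      body_mass = body_mass, stringsAsFactors = FALSE)
    r <- 1L
    for (j in seq_len(config$n_sessions)) {
      for (tr in seq_len(config$n_trials)) {
        noise <- matrix(stats::rnorm(config$basis_rank * n_ch),
                        ncol = n_ch) * config$noise_scale
        pert <- B %*% (drift[, , j] + noise)        # n_points x n_ch
        block <- (tpl + sweep(pert, 2, amp, "*")) * unit
        curves[r:(r + n_ch - 1L), ] <- t(block)
        r <- r + n_ch
      }
    }
    colnames(curves) <- tcols
    rows[[s]] <- cbind(meta, as.data.frame(curves))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "schedule") <- schedule
  class(out) <- c("gait_trials", "data.frame")
  out
}

#' Extract one trial's curves as a matrix
#'
#' @param trials a `gait_trials` data frame.
#' @param subject,session,trial identifiers of one trial.
#' @return Matrix `n_points` x n_channels in canonical channel order.
#' @export
trial_curves <- function(trials, subject, session, trial) {
  sel <- trials$subject == subject & trials$session == session &
    trials$trial == trial
  if (!any(sel)) stop("no such trial")
  sub <- trials[sel, , drop = FALSE]
  tcols <- grep("^t[0-9]+$", names(trials), value = TRUE)
  m <- t(as.matrix(sub[, tcols]))
  colnames(m) <- sub$channel
  rownames(m) <- NULL
  m
}

#' Simulate a raw force-plate recording of one stride
#'
#' Produces an unsegmented vertical-force series in newtons for a single
#' stride from right-foot heel strike to left-foot toe off: the right and
#' left contacts overlap in double support, the active region is embedded in
#' zero-force padding, and smooth boundary tapers guarantee the series rises
#' through and falls below a 10 N threshold exactly once each. Used to
#' exercise stride segmentation and time normalisation on data with a known
#' ground-truth contact window.
#'
#' @param n_active samples inside the stride window.
#' @param n_pad zero-force samples prepended and appended.
#' @param body_mass_kg body mass in kg.
#' @param noise_scale trial-noise coefficient scale (template-amplitude
#'   units, tapered to zero at the window boundaries).
#' @param basis_rank smooth-basis rank for the noise.
#' @return List with `series` (total vertical force, newtons), `window`
#'   (first and last 1-based index of the true stride window) and
#'   `n_active`.
#' @export
simulate_raw_stride <- function(n_active = 275, n_pad = 50,
                                body_mass_kg = 73.2, noise_scale = 0.1,
                                basis_rank = 8) {
  if (n_active < 20) stop("n_active too short")
  x <- seq(0, 1, length.out = n_active)
  taper <- function(u, width = 0.06) {
    w <- pmax(0, pmin(pmin(u, 1 - u) / width, 1))
    (1 - cos(pi * w)) / 2
  }
  # right stance occupies the first 75% of the window, the left contact the
  # final 45%; they overlap in double support
  ru <- x / 0.75
  right <- ifelse(x <= 0.75,
                  grf_component(pmin(ru, 1), "vertical") * taper(ru), 0)
  lu <- (x - 0.55) / 0.45
  left <- ifelse(x >= 0.55,
                 grf_component(pmax(lu, 0), "vertical") * taper(lu), 0)
  clean <- (right + left) * body_mass_kg * 9.81
  combined <- clean
  if (noise_scale > 0) {
    B <- smooth_basis(n_active, basis_rank)
    pert <- as.vector(B %*% stats::rnorm(basis_rank, sd = noise_scale)) *
      stats::sd(grf_component(x, "vertical")) * taper(x, 0.1) *
      body_mass_kg * 9.81
    combined <- pmax(0, clean + pert)
  }
  above <- which(clean >= 10)  # noiseless ground-truth contact window
  series <- c(rep(0, n_pad), combined, rep(0, n_pad))
  list(series = series,
       window = c(n_pad + above[1], n_pad + above[length(above)]),
       n_active = n_active)
}

#' Read and write stride-trial CSV files
#'
#' One row per trial-channel; columns `subject`, `session`, `trial`,
#' `channel`, `body_mass`, `t000...`. The schedule travels in a separate CSV
#' (see [write_schedule_csv()]).
#'
#' @param trials a `gait_trials` data frame.
#' @param path file path.
#' @return `read_trials_csv` returns a `gait_trials` data frame (without a
#'   schedule attribute); `write_trials_csv` returns `path` invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  class(df) <- c("gait_trials", "data.frame")
  df
}

#' Overlay plot of one subject-channel's trials
#'
#' Plots every trial curve of one channel together with the global mean and
#' a band of two standard deviations, the usual visual check that session
#' structure, not random scatter about the mean, drives the curves.
#'
#' @param x a `gait_trials` data frame.
#' @param subject,channel which curves to draw (defaults: first of each).
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, the matrix of plotted curves.
#' @export
plot.gait_trials <- function(x, subject = x$subject[1],
                             channel = x$channel[1], ...) {
  sel <- x$subject == subject & x$channel == channel
  tcols <- grep("^t[0-9]+$", names(x), value = TRUE)
  m <- t(as.matrix(x[sel, tcols]))
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  graphics::matplot(m, type = "l", lty = 1, col = "grey70",
                    xlab = "stride sample", ylab = channel, ...)
  graphics::lines(mu, col = "darkgreen", lwd = 2)
  graphics::lines(mu + 2 * s, col = "darkgreen", lty = 3)
  graphics::lines(mu - 2 * s, col = "darkgreen", lty = 3)
  invisible(m)
}
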