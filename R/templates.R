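#' Canonical channel names
#'
#' Fixed channel orders used when stride curves are concatenated into joined
#' classification vectors: 2 ground contacts x 3 force directions for the
#' kinetic modality (600 features at 100 points per curve) and 2 legs x
#' 3 joints x 3 planes for the kinematic modality (1800 features).
#'
#' @return Character vector of channel names in joining order.
#' @export
grf_channels <- function() {
  as.vector(t(outer(c("grf_right", "grf_left"),
                    c("vertical", "anterior", "lateral"), paste, sep = "_")))
}

#' @rdname grf_channels
#' @export
angle_channels <- function() {
  g <- expand.grid(plane = c("sagittal", "frontal", "transverse"),
                   joint = c("hip", "knee", "ankle"),
                   side = c("right", "left"),
                   stringsAsFactors = FALSE)
  paste("angle", g$side, g$joint, g$plane, sep = "_")
}

#' @rdname grf_channels
#' @param modality `"grf"` or `"angles"`.
#' @export
modality_channels <- function(modality = c("grf", "angles")) {
  modality <- match.arg(modality)
  if (modality == "grf") grf_channels() else angle_channels()
}

# Smooth closed-form stance curves on x in [0, 1], in body-weight units.
# Vertical: double-peaked (loading / push-off) with a mid-stance valley;
# anterior-posterior: braking then propulsive lobe, antisymmetric about
# mid-stance so it integrates to zero; mediolateral: small amplitude.
grf_component <- function(x, component) {
  switch(component,
    vertical = {
      g1 <- exp(-((x - 0.28) / 0.13)^2)
      g2 <- exp(-((x - 0.72) / 0.13)^2)
      gm <- exp(-((x - 0.50) / 0.26)^2)
      0.7506 * (g1 + g2) + 0.7144 * gm
    },
    anterior = -0.17 * sin(2 * pi * x) * sin(pi * x),
    lateral = 0.05 * sin(pi * x) * (1 + 0.3 * sin(3 * pi * x)),
    stop("unknown GRF component")
  )
}

#' Ground reaction force stance templates
#'
#' Closed-form single-stance GRF curve templates in body-weight units on a
#' normalised stance axis. The vertical component is the classic double-peak
#' curve (peaks near 1.1 body weight, mid-stance valley, unloaded
#' boundaries), the anterior-posterior component has a braking lobe followed
#' by a propulsive lobe that integrate to zero, and the mediolateral
#' component is small-amplitude. Both ground contacts share the same shapes;
#' the left contact's lateral component is mirrored.
#'
#' @param n_points number of equally spaced samples on the stance (>= 10).
#' @return Numeric matrix `n_points` x 6 with columns named as
#'   [grf_channels()].
#' @examples
#' tpl <- grf_template(100)
#' range(tpl[, "grf_right_vertical"])
#' @export
grf_template <- function(n_points = 100) {
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 10)
    stop("n_points must be a single number >= 10")
  x <- seq(0, 1, length.out = n_points)
  base <- cbind(vertical = grf_component(x, "vertical"),
                anterior = grf_component(x, "anterior"),
                lateral = grf_component(x, "lateral"))
  out <- cbind(base, base)
  colnames(out) <- grf_channels()
  out[, "grf_left_lateral"] <- -out[, "grf_left_lateral"]
  out
}

# Smooth joint-angle trajectories in degrees. Shapes are stylised (sinusoid
# and Gaussian-bump mixtures with per-joint phase offsets); only smoothness
# and the 2 x 3 x 3 channel layout are contractual.
angle_component <- function(x, joint, plane) {
  if (plane == "sagittal") {
    switch(joint,
      hip = 20 * cos(2 * pi * x) + 10,
      knee = 18 * exp(-((x - 0.12) / 0.10)^2) +
        60 * exp(-((x - 0.72) / 0.12)^2) + 3,
      ankle = 10 * sin(2 * pi * x + 0.6) - 6 * sin(4 * pi * x) - 2)
  } else {
    amp <- if (plane == "frontal") 8 else 6
    phase <- switch(joint, hip = 0.0, knee = 0.7, ankle = 1.4)
    amp * sin(2 * pi * x + phase) + 0.3 * amp * sin(4 * pi * x + phase)
  }
}

#' Lower-body joint-angle stride templates
#'
#' Smooth stylised hip/knee/ankle angle trajectories (degrees) in the
#' sagittal, frontal and transverse planes for both legs on a normalised
#' stride axis. The left leg is phase-shifted by half a stride.
#'
#' @param n_points number of equally spaced samples on the stride (>= 10).
#' @return Numeric matrix `n_points` x 18 with columns named as
#'   [angle_channels()].
#' @export
angle_template <- function(n_points = 100) {
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 10)
    stop("n_points must be a single number >= 10")
  x <- seq(0, 1, length.out = n_points)
  chans <- angle_channels()
  out <- matrix(NA_real_, n_points, length(chans),
                dimnames = list(NULL, chans))
  for (ch in chans) {
    parts <- strsplit(ch, "_", fixed = TRUE)[[1]]  # angle side joint plane
    xx <- if (parts[2] == "left") (x + 0.5) %% 1 else x
    out[, ch] <- angle_component(xx, parts[3], parts[4])
  }
  out
}

#' Stride-curve template for a modality
#'
#' @param modality `"grf"` or `"angles"`.
#' @param n_points samples per curve.
#' @return Matrix `n_points` x n_channels (6 or 18) of template curves.
#' @export
modality_template <- function(modality = c("grf", "angles"), n_points = 100) {
  modality <- match.arg(modality)
  if (modality == "grf") grf_template(n_points) else angle_template(n_points)
}
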