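#' Names of the nine model input features, in canonical order
#'
#' Raw accelerations on the three axes, their absolute sample-to-sample
#' differences, the Euclidean magnitude of the difference vector, and the
#' absolute sample-to-sample changes of the roll and pitch tilt angles.
#'
#' @return character vector of length 9.
#' @export
feature_names <- function() {
  c("x_g", "y_g", "z_g", "dx_g", "dy_g", "dz_g",
    "dnorm_g", "droll_deg", "dpitch_deg")
}

#' Device tilt (roll and pitch) from one acceleration sample
#'
#' Uses the standard accelerometer-tilt convention:
#' `roll = atan2(y, z)` and `pitch = atan2(-x, sqrt(y^2 + z^2))`, both in
#' degrees. Only sample-to-sample *changes* of these angles enter the
#' feature set, so the absolute convention is immaterial as long as it is
#' fixed; this is the dominant convention for chest-worn IMUs.
#'
#' @param x_g,y_g,z_g accelerations in g (vectorised).
#' @return a tibble with columns `roll_deg` in (-180, 180] and `pitch_deg`
#'   in \[-90, 90\].
#' @examples
#' compute_orientation(0, 0, 1)   # device flat: roll 0, pitch 0
#' compute_orientation(0, 1, 0)   # quarter rotation: roll 90
#' @export
compute_orientation <- function(x_g, y_g, z_g) {
  mag <- sqrt(x_g^2 + y_g^2 + z_g^2)
  if (any(mag == 0)) {
    abort("zero acceleration vector has no defined orientation",
          class = "harcascade_degenerate_orientation")
  }
  tibble(
    roll_deg = atan2(y_g, z_g) * 180 / pi,
    pitch_deg = atan2(-x_g, sqrt(y_g^2 + z_g^2)) * 180 / pi
  )
}

# minimal angular difference, wrap-aware (roll lives on a circle)
angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Compute the nine per-sample features from an acceleration stream
#'
#' For each sample the feature vector is
#' `[x, y, z, dx, dy, dz, dnorm, droll, dpitch]`: the raw accelerations,
#' the absolute differences against the previous sample, the Euclidean norm
#' `sqrt(dx^2 + dy^2 + dz^2)` of the difference vector, and the absolute
#' changes of roll and pitch (roll change is wrap-aware). The first sample
#' of a stream has all six delta features equal to 0, so the output always
#' has one row per input sample — important for real-time use where samples
#' arrive one at a time and the stream head must not be dropped.
#'
#' Features are per-sample, not windowed, and no scaling is applied: the
#' tree-based classifiers used downstream are scale-invariant, and all
#' algorithms in the comparison harness see identical inputs.
#'
#' @param stream a data frame with columns `t`, `x`, `y`, `z` (and optionally
#'   `label`), time-ordered.
#' @return a tibble with column `t`, the nine feature columns of
#'   [feature_names()], and `label` when present in the input.
#' @examples
#' s <- simulate_segment(activity_segment("walk", 2), sim_config(seed = 3))
#' featurize_stream(s)
#' @export
featurize_stream <- function(stream) {
  stopifnot(is.data.frame(stream))
  req <- c("t", "x", "y", "z")
  if (!all(req %in% names(stream))) {
    abort("stream needs columns t, x, y, z",
          class = "harcascade_invalid_input")
  }
  if (nrow(stream) < 1) {
    abort("stream is empty", class = "harcascade_invalid_input")
  }
  if (is.unsorted(stream$t, strictly = TRUE)) {
    abort("timestamps must be strictly increasing",
          class = "harcascade_invalid_input")
  }
  dx <- c(0, abs(diff(stream$x)))
  dy <- c(0, abs(diff(stream$y)))
  dz <- c(0, abs(diff(stream$z)))
  ori <- compute_orientation(stream$x, stream$y, stream$z)
  droll <- c(0, angle_diff(ori$roll_deg[-1],
                           ori$roll_deg[-nrow(stream)]))
  dpitch <- c(0, abs(diff(ori$pitch_deg)))
  out <- tibble(
    t = stream$t,
    x_g = stream$x, y_g = stream$y, z_g = stream$z,
    dx_g = dx, dy_g = dy, dz_g = dz,
    dnorm_g = sqrt(dx^2 + dy^2 + dz^2),
    droll_deg = droll, dpitch_deg = dpitch
  )
  if ("label" %in% names(stream)) out$label <- as.character(stream$label)
  out
}

# feature row for one incoming sample given the previous one (or NULL at
# stream start); used by the streaming step
featurize_pair <- function(sample, prev = NULL) {
  if (is.null(prev)) {
    st <- tibble(t = sample$t, x = sample$x, y = sample$y, z = sample$z)
    return(featurize_stream(st))
  }
  st <- tibble(t = c(prev$t, sample$t),
               x = c(prev$x, sample$x),
               y = c(prev$y, sample$y),
               z = c(prev$z, sample$z))
  featurize_stream(st)[2, ]
}
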