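#' Association index for pattern completion
#'
#' Quantifies completion of an ensemble's activity pattern from a
#' partial cue: `1 + (rE12 - rE11) / (rE12 + rE11)`, where `rE11` is
#' the activity of the stimulated subset and `rE12` the activity of the
#' unstimulated subset of the same ensemble. In the regime
#' `rE12 <= rE11` the index ranges from 0 (no completion) to 1 (full
#' completion, equal activity).
#'
#' @param rE11 Stimulated-subset rate (Hz, >= 0).
#' @param rE12 Unstimulated-subset rate (Hz, >= 0).
#' @return The index; error if both rates are zero.
#' @examples
#' association_index(10, 5)   # 2/3
#' association_index(10, 0)   # 0
#' @export
association_index <- function(rE11, rE12) {
  if (rE11 < 0 || rE12 < 0) stop("rates must be >= 0")
  if (rE11 + rE12 == 0)
    stop("association index undefined: both rates are zero")
  1 + (rE12 - rE11) / (rE12 + rE11)
}

#' Distance to the symmetric decision boundary
#'
#' Distance of the activity point `(x, y) = (rE1, rE2)` to the diagonal
#' decision boundary of a symmetric binary classifier:
#' `L = sqrt(x^2 + y^2) * sin(|45 - asin(x / sqrt(x^2 + y^2))|)` with
#' the inverse sine in degrees. Algebraically this equals the
#' perpendicular distance `|x - y| / sqrt(2)`; the trigonometric form is
#' evaluated here and the identity serves as a cross-check. `(0, 0)` is
#' on the boundary, distance 0 by convention.
#'
#' @param x,y Non-negative coordinates (ensemble rates, Hz).
#' @return The distance.
#' @examples
#' decision_distance(1, 0)   # sin(45 deg) ~ 0.7071
#' decision_distance(3, 3)   # 0
#' @export
decision_distance <- function(x, y) {
  if (x < 0 || y < 0) stop("coordinates must be >= 0")
  r <- sqrt(x^2 + y^2)
  if (r == 0) return(0)
  ang <- abs(45 - asin(x / r) * 180 / pi)
  r * sin(ang * pi / 180)
}

#' Relative pattern-separation index
#'
#' `(rE2 - rE1) / (rE1 + rE2)`, in `[-1, 1]`: 0 for identical ensemble
#' activities, +/-1 when one ensemble is silent.
#'
#' @param rE1,rE2 Ensemble rates (Hz, >= 0, not both zero).
#' @return The index.
#' @export
separation_index <- function(rE1, rE2) {
  if (rE1 < 0 || rE2 < 0) stop("rates must be >= 0")
  if (rE1 + rE2 == 0)
    stop("separation index undefined: both rates are zero")
  (rE2 - rE1) / (rE1 + rE2)
}

#' Amplification index
#'
#' Ratio of the evoked peak firing rate to the input strength. In
#' STP-stabilized supralinear networks this can exceed the value for a
#' linear network with identical weights by orders of magnitude, since
#' the onset transient rides the positive-feedback escape.
#'
#' @param peak_rate Evoked peak rate (Hz, >= 0).
#' @param input_strength Stimulus strength (> 0).
#' @return `peak_rate / input_strength`.
#' @export
amplification_index <- function(peak_rate, input_strength) {
  if (input_strength <= 0) stop("input_strength must be positive")
  if (peak_rate < 0) stop("peak_rate must be >= 0")
  peak_rate / input_strength
}

#' Extract onset/fixed-point features from a trajectory
#'
#' Onset peak: maximum of the rate over the stimulation window (ties
#' broken to the earliest time). Fixed-point activity: mean over the
#' middle 1 s of the canonical 2-s stimulation window (for windows of
#' other lengths the middle second is used when it fits, otherwise the
#' central 50% with a warning). Baseline: mean over the 1 s preceding
#' stimulus onset.
#'
#' @param traj A `rate_trajectory` or `network_trajectory`, or a list
#'   with fields `t` and a rate vector selected by `pop`.
#' @param stim_window Numeric `c(t0, t1)` within the trajectory span.
#' @param pop For network trajectories, the population column (name or
#'   index) to analyse; ignored for single-ensemble trajectories (rE).
#' @return Object of class `trajectory_features`: list with
#'   `onset_peak`, `onset_time`, `fixed_point`, `baseline`.
#' @export
extract_features <- function(traj, stim_window, pop = NULL) {
  if (inherits(traj, "network_trajectory")) {
    if (is.null(pop)) stop("pop must name a population column")
    tt <- traj$t; r <- traj$rates[, pop]
  } else if (inherits(traj, "rate_trajectory")) {
    tt <- traj$t; r <- traj$rE
  } else {
    tt <- traj$t; r <- traj$r
  }
  t0 <- stim_window[1]; t1 <- stim_window[2]
  if (t0 >= t1) stop("stim_window must satisfy t0 < t1")
  if (t0 < min(tt) || t1 > max(tt) + 1e-9)
    stop("stim_window outside the trajectory span")
  win <- tt >= t0 & tt < t1
  if (!any(win)) stop("no samples inside the stimulation window")
  peak_i <- which(win)[which.max(r[win])]
  delta <- t1 - t0
  if (delta >= 1) {
    mid <- tt >= t0 + (delta - 1) / 2 & tt < t0 + (delta + 1) / 2
  } else {
    warning("stimulation window shorter than 1 s; using central 50%")
    mid <- tt >= t0 + delta / 4 & tt < t1 - delta / 4
  }
  base <- tt >= max(t0 - 1, min(tt)) & tt < t0
  structure(list(
    onset_peak = r[peak_i],
    onset_time = tt[peak_i],
    fixed_point = mean(r[mid]),
    baseline = if (any(base)) mean(r[base]) else NA_real_),
    class = "trajectory_features")
}

#' @export
print.trajectory_features <- function(x, ...) {
  cat("onset peak ", signif(x$onset_peak, 6), " Hz at t = ",
      signif(x$onset_time, 6), " s; fixed point ",
      signif(x$fixed_point, 6), " Hz; baseline ",
      signif(x$baseline, 6), " Hz\n", sep = "")
  invisible(x)
}
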