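# Rule-based classification of normalized extension moment curves.
#
# The taxonomy is qualitative ("slight recovering notch before/near the
# peak", "sharp non-recovering fall right after the peak", "irregular
# mid-curve flutter"), so every quantitative threshold lives in
# classifier_config() with documented defaults. Breakpoints are detected as
# negative excursions of the curve's residual against a long-window
# local-quadratic baseline: the baseline reproduces any locally parabolic
# ("prevailing") shape exactly, so a clean curve yields a null residual while
# notches, steps and flutter survive as localized dips.

#' Classifier configuration
#'
#' All tunable thresholds of the breakpoint detector and the pattern rules.
#' Depths and amplitudes are fractions of the repetition's peak torque;
#' windows and angles are degrees of knee flexion. The defaults were
#' calibrated so the canonical simulated artifacts (10% notch, 30% step,
#' 10%/5-cycle flutter) are recovered reliably; they are operational choices,
#' not published constants.
#'
#' @param smoothing_window Width (deg, odd) of the local-quadratic
#'   (Savitzky-Golay) smoother applied before extremum detection.
#' @param baseline_window Width (deg, odd) of the long local-quadratic fit
#'   used as the prevailing-shape baseline.
#' @param min_depth Irregularity floor: minimum residual depth for a
#'   deviation to count as a breakpoint.
#' @param valley_max_depth Maximum depth still read as a "slight" (valley)
#'   notch.
#' @param drop_min_depth Minimum fall across a non-recovering step to read as
#'   a drop.
#' @param drop_min_sharpness Minimum per-degree decrease (fraction of peak
#'   per deg) inside a drop.
#' @param near_peak_window Degrees at or before the peak treated as "near the
#'   peak".
#' @param post_peak_window Degrees after the peak (extension direction)
#'   within which a drop must start.
#' @param flutter_min_oscillations Minimum number of qualifying mid-region
#'   dips for shaking.
#' @param flutter_min_amplitude Minimum dip depth counted toward flutter.
#' @param mid_region Fractional interval of the range of motion considered
#'   "the middle of the curve".
#' @param recovery_factor A breakpoint "recovers" when the curve later
#'   re-attains this fraction of its pre-break level.
#' @param edge_margin Degrees at each end of the range of motion excluded
#'   from breakpoint reporting: these samples fall in the acceleration/
#'   deceleration ramps, where torque is reconstructed by interpolation
#'   rather than measured on the isokinetic plateau.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(smoothing_window = 5,
                              baseline_window = 41,
                              min_depth = 0.05,
                              valley_max_depth = 0.15,
                              drop_min_depth = 0.20,
                              drop_min_sharpness = 0.05,
                              near_peak_window = 15,
                              post_peak_window = 10,
                              flutter_min_oscillations = 3L,
                              flutter_min_amplitude = 0.04,
                              mid_region = c(0.25, 0.75),
                              recovery_factor = 0.95,
                              edge_margin = 8) {
  if (!(min_depth > 0 && min_depth < valley_max_depth &&
        valley_max_depth < drop_min_depth && drop_min_depth <= 1)) {
    stop("require 0 < min_depth < valley_max_depth < drop_min_depth <= 1")
  }
  if (smoothing_window %% 2 != 1 || baseline_window %% 2 != 1) {
    stop("smoothing and baseline windows must be odd (degrees)")
  }
  if (edge_margin < 0) stop("edge_margin must be >= 0")
  if (any(c(near_peak_window, post_peak_window, drop_min_sharpness,
            flutter_min_amplitude) <= 0)) {
    stop("windows, sharpness and amplitude thresholds must be positive")
  }
  if (length(mid_region) != 2L || mid_region[1] >= mid_region[2] ||
      mid_region[1] < 0 || mid_region[2] > 1) {
    stop("mid_region must be an increasing fraction interval within [0, 1]")
  }
  structure(
    list(smoothing_window = smoothing_window,
         baseline_window = baseline_window,
         min_depth = min_depth, valley_max_depth = valley_max_depth,
         drop_min_depth = drop_min_depth,
         drop_min_sharpness = drop_min_sharpness,
         near_peak_window = near_peak_window,
         post_peak_window = post_peak_window,
         flutter_min_oscillations = as.integer(flutter_min_oscillations),
         flutter_min_amplitude = flutter_min_amplitude,
         mid_region = mid_region, recovery_factor = recovery_factor,
         edge_margin = edge_margin),
    class = "classifier_config"
  )
}

.sg_smooth <- function(values, window) {
  window <- min(window, if (length(values) %% 2 == 0) length(values) - 1
                else length(values))
  signal::sgolayfilt(values, p = 2, n = window)
}

#' Detect breakpoints in a normalized moment curve
#'
#' Lightly smooths the curve, fits a long local-quadratic baseline capturing
#' the prevailing parabolic shape, and reports every contiguous negative
#' residual excursion deeper than the irregularity floor. Each breakpoint
#' carries its depth (residual depth, or the total fall across the excursion
#' when that is larger, as in a sustained step), its sharpness (maximum
#' per-degree decrease inside the excursion), whether the curve recovers
#' afterwards, and its position relative to the peak.
#'
#' @param curve An `imc_curve` from [normalize_to_peak()].
#' @param config A [classifier_config()].
#' @return Data frame with one row per breakpoint: `angle`, `offset`
#'   (peak_angle - angle; positive = after the peak in extension order),
#'   `depth`, `sharpness`, `recovers`, `position` (one of `before_peak`,
#'   `near_peak`, `after_peak`). Zero rows for a clean curve.
#' @export
detect_breakpoints <- function(curve, config = classifier_config()) {
  stopifnot(inherits(curve, "imc_curve"))
  v <- .sg_smooth(curve$value, config$smoothing_window)
  baseline <- .sg_smooth(v, config$baseline_window)
  resid <- v - baseline
  below <- resid < -config$min_depth
  if (!any(below)) {
    return(data.frame(angle = numeric(0), offset = numeric(0),
                      depth = numeric(0), sharpness = numeric(0),
                      recovers = logical(0), position = character(0)))
  }
  runs <- rle(below)
  pos <- cumsum(c(1L, runs$lengths))
  rows <- list()
  slope_floor <- config$drop_min_sharpness / 2
  for (r in seq_along(runs$lengths)) {
    if (!runs$values[r]) next
    i1 <- pos[r]
    i2 <- pos[r + 1L] - 1L
    seg <- i1:i2
    depth_resid <- -min(resid[seg])
    # expand across the whole sharp descent so a sustained step is measured
    # in full, not just where the residual crosses the floor
    e1 <- i1
    while (e1 > 1L && v[e1 - 1L] - v[e1] >= slope_floor) e1 <- e1 - 1L
    e2 <- i2
    while (e2 < length(v) && v[e2] - v[e2 + 1L] >= slope_floor) e2 <- e2 + 1L
    depth_fall <- v[e1] - v[e2]
    depth <- max(depth_resid, depth_fall)
    ext <- e1:e2
    sharpness <- if (length(ext) > 1L) max(-diff(v[ext])) else depth_resid
    pre_level <- v[e1]
    tail_max <- if (e2 < length(v)) max(v[(e2 + 1L):length(v)]) else -Inf
    recovers <- tail_max >= config$recovery_factor * pre_level
    # locate the break at the steepest descent: stable under noise and
    # sits at the step/notch entry rather than where the residual bottoms out
    angle_bp <- if (length(ext) > 1L) {
      curve$angle[ext][which.max(-diff(v[ext]))]
    } else {
      curve$angle[seg][which.min(resid[seg])]
    }
    if (angle_bp > max(curve$angle) - config$edge_margin ||
        angle_bp < min(curve$angle) + config$edge_margin) {
      next  # inside the ramp margins: reconstructed, not measured, torque
    }
    offset <- curve$peak_angle - angle_bp
    position <- if (offset > 0) {
      "after_peak"
    } else if (-offset <= config$near_peak_window) {
      "near_peak"
    } else {
      "before_peak"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      angle = angle_bp, offset = offset, depth = depth,
      sharpness = sharpness, recovers = recovers, position = position
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(angle = numeric(0), offset = numeric(0),
                      depth = numeric(0), sharpness = numeric(0),
                      recovers = logical(0), position = character(0)))
  }
  do.call(rbind, rows)
}

#' Classify one repetition
#'
#' Applies the pattern rules in precedence order Shaking > Drop > Valley >
#' Normal:
#' * **Shaking** -- at least `flutter_min_oscillations` dips of depth >=
#'   `flutter_min_amplitude` lie inside the mid-region of the range of motion
#'   and their span covers the peak;
#' * **Drop** -- a non-recovering breakpoint of depth >= `drop_min_depth` and
#'   sharpness >= `drop_min_sharpness` starts within `post_peak_window`
#'   degrees after the peak;
#' * **Valley** -- a recovering breakpoint of depth between `min_depth` and
#'   `valley_max_depth` sits at or before the peak;
#' * otherwise **Normal**.
#'
#' @inheritParams detect_breakpoints
#' @return A single pattern label (character).
#' @export
classify_repetition <- function(curve, config = classifier_config()) {
  bp <- detect_breakpoints(curve, config)
  if (nrow(bp) == 0L) return("Normal")
  rom_lo <- min(curve$angle)
  rom_hi <- max(curve$angle)
  mid_lo <- rom_lo + config$mid_region[1] * (rom_hi - rom_lo)
  mid_hi <- rom_lo + config$mid_region[2] * (rom_hi - rom_lo)
  flutter <- bp[bp$depth >= config$flutter_min_amplitude &
                  bp$angle >= mid_lo & bp$angle <= mid_hi, , drop = FALSE]
  if (nrow(flutter) >= config$flutter_min_oscillations &&
      min(flutter$angle) <= curve$peak_angle &&
      max(flutter$angle) >= curve$peak_angle) {
    return("Shaking")
  }
  drop_hit <- !bp$recovers &
    bp$depth >= config$drop_min_depth &
    bp$sharpness >= config$drop_min_sharpness &
    bp$offset > 0 & bp$offset <= config$post_peak_window
  if (any(drop_hit)) return("Drop")
  valley_hit <- bp$recovers &
    bp$depth >= config$min_depth & bp$depth <= config$valley_max_depth &
    bp$offset <= 0
  if (any(valley_hit)) return("Valley")
  "Normal"
}

#' Classify a trial with the three-repetition consistency rule
#'
#' An irregular pattern is accepted only when all three analyzed repetitions
#' receive the same irregular label; any disagreement (including two
#' different irregular labels) yields Normal.
#'
#' @param reps List of exactly three `imc_curve` objects (repetitions 2-4).
#' @param config A [classifier_config()].
#' @return A single pattern label (character).
#' @export
#' @examples
#' trial <- generate_trial(curve_spec("Valley", seed = 2))
#' classify_trial(preprocess_trial(trial))
classify_trial <- function(reps, config = classifier_config()) {
  if (length(reps) != 3L) {
    stop("exactly three analyzed repetitions are required; got ",
         length(reps))
  }
  labels <- vapply(reps, classify_repetition, character(1), config = config)
  if (labels[1L] != "Normal" && all(labels == labels[1L])) labels[1L]
  else "Normal"
}

#' Classify every trial of a cohort
#'
#' Runs preprocessing and trial classification over a generated (or loaded)
#' cohort and appends the resulting labels to its manifest.
#'
#' @param cohort List with `manifest` and `trials`, as returned by
#'   [generate_cohort()].
#' @param config A [classifier_config()].
#' @return The manifest with an extra factor column `pattern`.
#' @export
classify_cohort <- function(cohort, config = classifier_config()) {
  labels <- vapply(cohort$trials, function(trial) {
    classify_trial(preprocess_trial(trial), config)
  }, character(1))
  manifest <- cohort$manifest
  manifest$pattern <- .as_pattern(labels)
  manifest
}
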