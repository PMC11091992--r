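# Preprocessing of raw repetition traces into normalized, 1-degree-gridded
# extension moment curves. Conventions: curves are indexed by knee flexion
# angle but stored and processed in extension order (90 -> 10 deg), so
# "before the peak" always means a larger flexion angle than the peak.

.grid_angles <- function(rom = c(90, 10)) seq(max(rom), min(rom), by = -1)

.reject <- function(msg) {
  stop(structure(class = c("imc_rejection", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Resample a raw repetition onto the 1-degree grid
#'
#' Linearly interpolates torque (and velocity) between the nearest raw
#' samples at every integer degree of the range of motion. Grid points
#' outside the span of the raw trace are returned as `NA` and are filled
#' later by [fill_missing()].
#'
#' @param curve Data frame with columns `angle_deg`, `torque_nm` and
#'   optionally `velocity_deg_s`, ordered by acquisition time.
#' @param rom Range of motion, `c(start, end)` flexion degrees.
#' @return Data frame `angle_deg`, `velocity_deg_s`, `torque_nm` with one row
#'   per integer degree, in extension order.
#' @export
resample_to_grid <- function(curve, rom = c(90, 10)) {
  ok <- is.finite(curve$angle_deg) & is.finite(curve$torque_nm)
  if (sum(ok) < 2L) .reject("fewer than two valid samples in repetition")
  span <- diff(range(curve$angle_deg[ok]))
  if (span < abs(diff(rom)) / 2) {
    .reject(sprintf("repetition spans only %.1f deg of the %.0f deg range",
                    span, abs(diff(rom))))
  }
  grid <- .grid_angles(rom)
  torque <- stats::approx(curve$angle_deg[ok], curve$torque_nm[ok],
                          xout = grid, ties = mean)$y
  velocity <- if ("velocity_deg_s" %in% names(curve)) {
    stats::approx(curve$angle_deg[ok], curve$velocity_deg_s[ok],
                  xout = grid, ties = mean)$y
  } else {
    rep(NA_real_, length(grid))
  }
  data.frame(angle_deg = grid, velocity_deg_s = velocity, torque_nm = torque)
}

# One-sided linear prediction at position x from up to two valid neighbours.
.one_sided_predict <- function(x, xs, ys) {
  if (length(xs) == 0L) return(NA_real_)
  if (length(xs) == 1L) return(ys[1L])
  slope <- (ys[2L] - ys[1L]) / (xs[2L] - xs[1L])
  ys[1L] + slope * (x - xs[1L])
}

#' Fill invalid grid samples by interpolation averaging
#'
#' Grid samples are invalid when their torque is missing or their angular
#' velocity is below the isokinetic plateau threshold (absolute velocity
#' < `velocity_threshold`, the acceleration/deceleration phases of the
#' movement). Each invalid run is filled by averaging two one-sided linear
#' predictions -- one extrapolated from the nearest (up to two) valid samples
#' on each flank. At the grid ends, where only one flank exists, the fill is
#' the nearest-valid extrapolation. Filled torques are clamped at zero.
#'
#' @param curve Gridded data frame from [resample_to_grid()].
#' @param velocity_threshold Plateau threshold in deg/s (default 50). Samples
#'   with unknown velocity are treated as valid unless their torque is
#'   missing.
#' @return The gridded curve with all torques populated and a logical column
#'   `filled` marking replaced samples.
#' @export
fill_missing <- function(curve, velocity_threshold = 50) {
  torque <- curve$torque_nm
  velocity <- curve$velocity_deg_s
  invalid <- !is.finite(torque)
  known_v <- is.finite(velocity)
  invalid <- invalid | (known_v & abs(velocity) < velocity_threshold)
  if (all(invalid)) .reject("no valid samples after velocity screening")
  n <- length(torque)
  out <- torque
  idx_valid <- which(!invalid)
  runs <- rle(invalid)
  pos <- cumsum(c(1L, runs$lengths))
  for (r in seq_along(runs$lengths)) {
    if (!runs$values[r]) next
    i1 <- pos[r]
    i2 <- pos[r + 1L] - 1L
    left <- rev(idx_valid[idx_valid < i1])[seq_len(min(2L, sum(idx_valid < i1)))]
    right <- idx_valid[idx_valid > i2][seq_len(min(2L, sum(idx_valid > i2)))]
    for (i in i1:i2) {
      fill <- if (length(left) == 0L) {
        torque[right[1L]]       # leading gap: nearest-valid constant
      } else if (length(right) == 0L) {
        torque[left[1L]]        # trailing gap: nearest-valid constant
      } else {
        mean(c(.one_sided_predict(i, left, torque[left]),
               .one_sided_predict(i, right, torque[right])))
      }
      out[i] <- max(fill, 0)
    }
  }
  curve$torque_nm <- out
  curve$filled <- invalid
  curve
}

#' Normalize a gridded curve to its peak moment
#'
#' Divides the torques of one repetition by that repetition's maximum. Ties
#' in the argmax are broken toward the angle closest to the mid-point of the
#' range of motion, then toward the larger flexion angle.
#'
#' @param curve Gridded, fully populated data frame (see [fill_missing()]).
#' @return Object of class `imc_curve`: list with `angle` (extension order),
#'   `value` (torque / peak, max exactly 1), `peak_angle` (deg) and
#'   `peak_torque` (N m).
#' @export
normalize_to_peak <- function(curve) {
  torque <- curve$torque_nm
  if (!all(is.finite(torque))) {
    .reject("curve has unpopulated samples; run fill_missing() first")
  }
  peak <- max(torque)
  if (peak <= 0) .reject("degenerate curve: no positive torque")
  angle <- curve$angle_deg
  mid <- (max(angle) + min(angle)) / 2
  at_max <- which(torque >= peak * (1 - 1e-12))
  ord <- at_max[order(abs(angle[at_max] - mid), -angle[at_max])]
  peak_idx <- ord[1L]
  structure(
    list(angle = angle, value = torque / peak,
         peak_angle = angle[peak_idx], peak_torque = peak),
    class = "imc_curve"
  )
}

#' @export
print.imc_curve <- function(x, ...) {
  cat(sprintf(
    "Normalized isokinetic moment curve: %d points (%g..%g deg), peak %.1f N m at %g deg\n",
    length(x$angle), x$angle[1L], x$angle[length(x$angle)],
    x$peak_torque, x$peak_angle))
  invisible(x)
}

#' Select the analyzed repetitions of a trial
#'
#' Only the 2nd, 3rd and 4th repetitions of a trial are analyzed, to avoid
#' the movement-strategy adjustments of the first and last maximal
#' contractions.
#'
#' @param trial List of repetition curves (an `imc_trial` or plain list).
#' @return List of the three analyzed repetitions, in order.
#' @export
select_repetitions <- function(trial) {
  if (length(trial) < 4L) {
    .reject(sprintf("trial has %d repetitions; at least 4 required",
                    length(trial)))
  }
  trial[2:4]
}

#' Preprocess a trial end to end
#'
#' Convenience wrapper: selects repetitions 2-4, resamples each to the
#' 1-degree grid, fills sub-threshold and missing samples, and normalizes to
#' the per-repetition peak.
#'
#' @param trial An `imc_trial` or list of raw repetition data frames.
#' @param rom Range of motion.
#' @param velocity_threshold Plateau threshold in deg/s.
#' @return List of three `imc_curve` objects.
#' @export
preprocess_trial <- function(trial, rom = c(90, 10), velocity_threshold = 50) {
  lapply(select_repetitions(trial), function(rep) {
    normalize_to_peak(fill_missing(resample_to_grid(rep, rom),
                                   velocity_threshold))
  })
}
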