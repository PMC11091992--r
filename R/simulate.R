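# Synthetic isokinetic trial generator.
#
# Torque kernel: two half-parabolas in flexion angle, zero at both range-of-
# motion endpoints and equal to peak_torque at peak_angle (a symmetric
# parabola when the peak sits at mid-range). Irregularities multiply the
# kernel: a Gaussian notch (valley), a logistic step (drop) or a bounded
# sinusoid (shaking). Measurement noise is additive Gaussian, scaled to the
# peak. Angular velocity follows a trapezoid: linear ramps over the first and
# last 8 degrees of the range, constant nominal velocity in between, so the
# acceleration/deceleration samples fall below the 50 deg/s validity
# threshold the preprocessing must handle.

#' Specification of one synthetic isokinetic trial
#'
#' @param pattern Injected morphology, one of [imc_patterns()].
#' @param peak_torque Peak extensor torque in N m (> 0).
#' @param peak_angle Flexion angle (deg) of the torque peak; must lie strictly
#'   inside the range of motion.
#' @param rom Range of motion as `c(start_flexion, end_flexion)` in degrees;
#'   extension proceeds from the first to the second value.
#' @param nominal_velocity Target angular velocity of the isokinetic phase,
#'   deg/s.
#' @param noise_sd Measurement noise standard deviation, as a fraction of the
#'   peak torque.
#' @param notch_depth,notch_offset,notch_width Valley artifact: fractional
#'   depth of the multiplicative Gaussian notch, its centre's distance before
#'   the peak (deg of flexion above `peak_angle`), and its full width at half
#'   maximum (deg).
#' @param drop_depth,drop_offset,drop_scale Drop artifact: fractional depth of
#'   the multiplicative logistic step, its centre's distance past the peak in
#'   extension direction (deg), and the logistic scale (deg; smaller = sharper).
#' @param flutter_cycles,flutter_amplitude Shaking artifact: number of
#'   sinusoid periods over the middle half of the range of motion, and the
#'   fractional amplitude of the flutter.
#' @param hq_ratio Hamstring-to-quadriceps peak torque ratio emitted as
#'   metadata (no flexor trace is generated). Defaults to 0.65 except for
#'   shaking trials, where it defaults to 1.05, mirroring the clinical
#'   observation that shaking curves co-occur with H:Q ratios near or above 1.
#' @param n_repetitions Number of maximal contractions per trial.
#' @param seed Root seed; each repetition uses a deterministically derived
#'   child seed.
#' @return Object of class `curve_spec`.
#' @export
#' @examples
#' spec <- curve_spec("Valley", noise_sd = 0)
#' rep1 <- generate_repetition(spec, 1)
#' range(rep1$angle_deg)
curve_spec <- function(pattern = "Normal",
                       peak_torque = 160,
                       peak_angle = 50,
                       rom = c(90, 10),
                       nominal_velocity = 60,
                       noise_sd = 0,
                       notch_depth = 0.10,
                       notch_offset = 10,
                       notch_width = 3,
                       drop_depth = 0.30,
                       drop_offset = 5,
                       drop_scale = 0.8,
                       flutter_cycles = 5L,
                       flutter_amplitude = 0.10,
                       hq_ratio = NULL,
                       n_repetitions = 5L,
                       seed = 1L) {
  pattern <- match.arg(pattern, imc_patterns())
  if (length(rom) != 2L || rom[1] <= rom[2]) {
    stop("rom must be c(start, end) with start > end (flexion degrees)")
  }
  if (any(rom < 0) || any(rom > 100)) stop("rom must lie within [0, 100] deg")
  if (!is.finite(peak_torque) || peak_torque <= 0) {
    stop("peak_torque must be a positive number")
  }
  if (peak_angle <= min(rom) || peak_angle >= max(rom)) {
    stop("peak_angle must lie strictly inside the range of motion")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (flutter_cycles < 0 || flutter_cycles != round(flutter_cycles)) {
    stop("flutter_cycles must be a non-negative integer")
  }
  if (n_repetitions < 1L) stop("n_repetitions must be >= 1")
  if (is.null(hq_ratio)) hq_ratio <- if (pattern == "Shaking") 1.05 else 0.65
  if (hq_ratio <= 0) stop("hq_ratio must be > 0")
  structure(
    list(
      pattern = pattern, peak_torque = peak_torque, peak_angle = peak_angle,
      rom = rom, nominal_velocity = nominal_velocity, noise_sd = noise_sd,
      notch_depth = notch_depth, notch_offset = notch_offset,
      notch_width = notch_width, drop_depth = drop_depth,
      drop_offset = drop_offset, drop_scale = drop_scale,
      flutter_cycles = as.integer(flutter_cycles),
      flutter_amplitude = flutter_amplitude, hq_ratio = hq_ratio,
      n_repetitions = as.integer(n_repetitions), seed = as.integer(seed)
    ),
    class = "curve_spec"
  )
}

# Deterministic child-seed derivation (kept inside 32-bit integer range).
.child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + 7919 * as.numeric(index)) %%
               2147483647)
}

# Run expr with a local RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Noise-free torque kernel (artifact included) evaluated at flexion angles.
.torque_kernel <- function(spec, angle) {
  hi <- max(spec$rom)
  lo <- min(spec$rom)
  pk <- spec$peak_angle
  base <- ifelse(
    angle >= pk,
    1 - ((angle - pk) / (hi - pk))^2,
    1 - ((angle - pk) / (lo - pk))^2
  )
  base <- pmax(base, 0)
  mult <- rep(1, length(angle))
  if (spec$pattern == "Valley") {
    centre <- pk + spec$notch_offset
    sigma <- spec$notch_width / (2 * sqrt(2 * log(2)))
    mult <- 1 - spec$notch_depth * exp(-((angle - centre)^2) / (2 * sigma^2))
  } else if (spec$pattern == "Drop") {
    centre <- pk - spec$drop_offset
    mult <- 1 - spec$drop_depth / (1 + exp((angle - centre) / spec$drop_scale))
  } else if (spec$pattern == "Shaking" && spec$flutter_cycles > 0L) {
    a <- lo + 0.25 * (hi - lo)
    b <- lo + 0.75 * (hi - lo)
    inside <- angle >= a & angle <= b
    phase <- 2 * pi * spec$flutter_cycles * (angle - a) / (b - a)
    mult[inside] <- 1 + spec$flutter_amplitude * sin(phase[inside])
  }
  spec$peak_torque * base * mult
}

# Trapezoidal angular-velocity profile (deg/s) at flexion angles.
.velocity_profile <- function(spec, angle, ramp = 8) {
  hi <- max(spec$rom)
  lo <- min(spec$rom)
  frac <- pmin(1, (hi - angle) / ramp, (angle - lo) / ramp)
  spec$nominal_velocity * pmax(frac, 0)
}

#' Generate one repetition of a synthetic isokinetic trial
#'
#' Samples a knee-extension torque-angle trace at 0.25 deg spacing, from the
#' start to the end of the range of motion, with the morphology requested in
#' the spec and additive Gaussian measurement noise. Identical `(spec,
#' repetition_index, seed)` always yield identical traces.
#'
#' @param spec A [curve_spec()].
#' @param repetition_index Repetition number within the trial (1-based).
#' @param seed Root seed; defaults to the spec's.
#' @return Data frame with columns `angle_deg`, `velocity_deg_s`, `torque_nm`
#'   and `repetition`, ordered by extension progress (decreasing flexion).
#' @export
generate_repetition <- function(spec, repetition_index = 1L,
                                seed = spec$seed) {
  stopifnot(inherits(spec, "curve_spec"))
  angle <- seq(max(spec$rom), min(spec$rom), by = -0.25)
  torque <- .torque_kernel(spec, angle)
  if (spec$noise_sd > 0) {
    noise <- .with_seed(
      .child_seed(seed, repetition_index),
      stats::rnorm(length(angle), sd = spec$noise_sd * spec$peak_torque)
    )
    torque <- torque + noise
  }
  data.frame(
    angle_deg = angle,
    velocity_deg_s = .velocity_profile(spec, angle),
    torque_nm = pmax(torque, 0),
    repetition = as.integer(repetition_index)
  )
}

#' Generate a full trial (consecutive maximal repetitions)
#'
#' The injected morphology is present in every repetition, so the
#' three-repetition consistency rule of [classify_trial()] can fire.
#'
#' @inheritParams generate_repetition
#' @return Object of class `imc_trial`: a list of repetition data frames, with
#'   the generating spec attached as attribute `spec`.
#' @export
#' @examples
#' trial <- generate_trial(curve_spec("Shaking", seed = 7))
#' length(trial)
generate_trial <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  reps <- lapply(seq_len(spec$n_repetitions), function(i) {
    generate_repetition(spec, i, spec$seed)
  })
  structure(reps, class = "imc_trial", spec = spec)
}

#' Specification of a synthetic cohort
#'
#' @param pattern_distribution 4 x 5 count matrix giving how many trials carry
#'   each injected pattern within each injury class; defaults to
#'   [reference_pattern_counts()].
#' @param noise_sd Measurement noise fraction applied to every trial.
#' @param seed Root seed for the cohort.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(pattern_distribution = reference_pattern_counts(),
                        noise_sd = 0, seed = 1L) {
  pattern_distribution <- .validate_count_table(pattern_distribution)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(pattern_distribution = pattern_distribution,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort of isokinetic trials
#'
#' Emits one trial per counted cell of the pattern-by-class distribution, so
#' the injected labels reproduce the requested contingency table exactly.
#' Healthy legs are generated as independent trials (two legs per control
#' subject are treated as independent observations, as the association model
#' does). Peak torque varies log-normally between trials, shaking trials
#' having systematically lower peaks, and the peak angle jitters a few
#' degrees around mid-range.
#'
#' @param spec A [cohort_spec()].
#' @return List with elements `manifest` (data frame `trial_id`,
#'   `injury_class`, `injected_pattern`) and `trials` (list of `imc_trial`
#'   objects, parallel to the manifest rows).
#' @export
#' @examples
#' small <- matrix(0L, 4, 5, dimnames = dimnames(reference_pattern_counts()))
#' small["Normal", "Healthy"] <- 2L
#' cohort <- generate_cohort(cohort_spec(small, seed = 3))
#' cohort$manifest
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  dist <- spec$pattern_distribution
  grid <- expand.grid(pattern = imc_patterns(), class = injury_classes(),
                      stringsAsFactors = FALSE)
  grid$count <- mapply(function(p, k) dist[p, k], grid$pattern, grid$class)
  grid <- grid[grid$count > 0, , drop = FALSE]
  pattern <- rep(grid$pattern, grid$count)
  class <- rep(grid$class, grid$count)
  n <- length(pattern)
  draws <- .with_seed(spec$seed, list(
    peak_mult = stats::rlnorm(n, meanlog = 0, sdlog = 0.12),
    peak_angle = stats::runif(n, 47, 53),
    hq_noise = stats::rnorm(n, 0, 0.05)
  ))
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    base_peak <- if (pattern[i] == "Shaking") 115 else 160
    hq <- if (pattern[i] == "Shaking") 1.05 else 0.65
    trials[[i]] <- generate_trial(curve_spec(
      pattern = pattern[i],
      peak_torque = base_peak * draws$peak_mult[i],
      peak_angle = draws$peak_angle[i],
      noise_sd = spec$noise_sd,
      hq_ratio = max(hq + draws$hq_noise[i], 0.1),
      seed = .child_seed(spec$seed, i)
    ))
  }
  manifest <- data.frame(
    trial_id = sprintf("trial_%03d", seq_len(n)),
    injury_class = .as_class(class),
    injected_pattern = .as_pattern(pattern)
  )
  list(manifest = manifest, trials = trials)
}

#' Specification of a simulated rater
#'
#' A rater is modelled by a row-stochastic confusion matrix: given a curve
#' whose true pattern indexes the row, the rater reports a label drawn from
#' that row's probabilities.
#'
#' @param confusion 4 x 4 row-stochastic matrix over [imc_patterns()].
#'   Defaults to the identity (an error-free rater).
#' @param seed Seed for the rater's draws.
#' @return Object of class `rater_spec`.
#' @export
rater_spec <- function(confusion = diag(4), seed = 1L) {
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(4L, 4L))) {
    stop("confusion must be a 4 x 4 matrix over the pattern labels")
  }
  dimnames(confusion) <- list(imc_patterns(), imc_patterns())
  if (any(confusion < 0) || any(abs(rowSums(confusion) - 1) > 1e-9)) {
    stop("each confusion row must be a probability vector summing to 1")
  }
  structure(list(confusion = confusion, seed = as.integer(seed)),
            class = "rater_spec")
}

#' Simulate two raters labelling the same curves
#'
#' Each rater draws independently, item by item, from the row of their
#' confusion matrix indexed by the true pattern.
#'
#' @param true_labels Vector of true pattern labels.
#' @param spec_a,spec_b [rater_spec()] objects for the two raters.
#' @return List with factor elements `labels_a` and `labels_b`.
#' @export
#' @examples
#' out <- simulate_raters(rep(imc_patterns(), 5), rater_spec(), rater_spec())
#' all(out$labels_a == out$labels_b)
simulate_raters <- function(true_labels, spec_a, spec_b) {
  stopifnot(inherits(spec_a, "rater_spec"), inherits(spec_b, "rater_spec"))
  truth <- .as_pattern(true_labels)
  if (length(truth) == 0L) stop("true_labels is empty")
  draw <- function(spec) {
    .with_seed(spec$seed, {
      vapply(as.character(truth), function(p) {
        sample(imc_patterns(), 1L, prob = spec$confusion[p, ])
      }, character(1), USE.NAMES = FALSE)
    })
  }
  list(labels_a = .as_pattern(draw(spec_a)),
       labels_b = .as_pattern(draw(spec_b)))
}
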