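# Closed-form curve builders used as independent oracles. These are written
# directly from the shape definitions (half-parabola through the range-of-
# motion endpoints, multiplicative Gaussian notch / logistic step / bounded
# sinusoid) and deliberately do not call the package's generator.

oracle_parabola <- function(angle, peak_angle = 50, lo = 10, hi = 90) {
  half <- ifelse(angle >= peak_angle, hi - peak_angle, lo - peak_angle)
  pmax(1 - ((angle - peak_angle) / half)^2, 0)
}

oracle_notch <- function(angle, centre, depth, fwhm = 3) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  1 - depth * exp(-((angle - centre)^2) / (2 * sigma^2))
}

oracle_step <- function(angle, centre, depth, scale = 0.8) {
  1 - depth / (1 + exp((angle - centre) / scale))
}

oracle_flutter <- function(angle, cycles, amplitude, lo = 30, hi = 70) {
  mult <- rep(1, length(angle))
  inside <- angle >= lo & angle <= hi
  phase <- 2 * pi * cycles * (angle - lo) / (hi - lo)
  mult[inside] <- 1 + amplitude * sin(phase[inside])
  mult
}

# Wrap a vector of torques on the 1-degree grid as a normalized curve object
# (the container is a plain list; values are normalized here so the oracle
# path does not depend on the preprocessing under test).
as_norm_curve <- function(torque, angle = seq(90, 10)) {
  stopifnot(length(torque) == length(angle), max(torque) > 0)
  value <- torque / max(torque)
  mid <- (max(angle) + min(angle)) / 2
  at_max <- which(value >= 1 - 1e-12)
  peak_idx <- at_max[order(abs(angle[at_max] - mid), -angle[at_max])][1L]
  structure(
    list(angle = angle, value = value, peak_angle = angle[peak_idx],
         peak_torque = max(torque)),
    class = "imc_curve"
  )
}

# Independent Cohen's kappa from the definition, for cross-checking.
oracle_kappa <- function(a, b) {
  lev <- sort(unique(c(a, b)))
  po <- mean(a == b)
  pe <- sum((table(factor(a, lev)) / length(a)) *
              (table(factor(b, lev)) / length(b)))
  (po - pe) / (1 - pe)
}

# Random all-positive pattern-by-class count table.
random_count_table <- function(max_count = 30) {
  matrix(sample.int(max_count, 20, replace = TRUE), nrow = 4,
         dimnames = list(pattern = imc_patterns(), class = injury_classes()))
}
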