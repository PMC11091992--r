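#' Curve pattern labels
#'
#' The closed set of morphological labels used for knee-extensor isokinetic
#' moment curves: `Normal` (smooth parabolic curve peaking near mid-range),
#' `Valley` (a slight, recovering notch before or near the peak), `Drop`
#' (a sharp, non-recovering fall right after the peak) and `Shaking`
#' (irregular flutter along the middle of the curve, spanning the peak).
#'
#' @return Character vector of the four pattern labels, in canonical order.
#' @export
#' @examples
#' imc_patterns()
imc_patterns <- function() {
  c("Normal", "Valley", "Drop", "Shaking")
}

#' Injury class labels
#'
#' The five diagnosis groups used throughout the package: isolated anterior
#' cruciate ligament rupture (`ACL`), grade-III meniscus tear (`MS`),
#' patellofemoral joint lesion (`PFJ`), combined ACL rupture plus meniscus
#' tear (`ACL+MS`), and healthy control legs (`Healthy`). `Healthy` is the
#' reference class of the association model; the order doubles as the
#' deterministic tie-break order of the predictor.
#'
#' @return Character vector of the five class labels, in canonical order.
#' @export
injury_classes <- function() {
  c("ACL", "MS", "PFJ", "ACL+MS", "Healthy")
}

.as_pattern <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), imc_patterns())
  if (length(bad) > 0L) {
    stop("unknown pattern label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = imc_patterns())
}

.as_class <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), injury_classes())
  if (length(bad) > 0L) {
    stop("unknown injury class label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = injury_classes())
}

#' Reference pattern-by-injury contingency table
#'
#' Packaged 4 x 5 count table giving the distribution of the four moment-curve
#' patterns over the five diagnosis groups in the reference clinical cohort
#' (involved leg of 74 injured subjects -- ACL n = 10, MS n = 17, PFJ n = 24,
#' ACL+MS n = 23 -- and both legs of 20 healthy controls, 114 legs in total).
#' This table is the default input of [fit_multinomial()] and
#' [evaluate_predictions()], and the default cohort composition of
#' [generate_cohort()].
#'
#' @return Integer matrix with patterns as rows and injury classes as columns.
#' @export
#' @examples
#' tab <- reference_pattern_counts()
#' colSums(tab)  # group sizes: 10, 17, 24, 23, 40
reference_pattern_counts <- function() {
  matrix(
    c(
      2L, 4L, 4L, 3L, 35L,   # Normal
      2L, 1L, 10L, 6L, 2L,   # Valley
      3L, 1L, 1L, 8L, 1L,    # Drop
      3L, 11L, 9L, 6L, 2L    # Shaking
    ),
    nrow = 4L, byrow = TRUE,
    dimnames = list(pattern = imc_patterns(), class = injury_classes())
  )
}

.validate_count_table <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == c(4L, 5L))) {
    stop("expected a 4 x 5 pattern-by-class count matrix")
  }
  if (is.null(dimnames(table))) {
    dimnames(table) <- list(pattern = imc_patterns(), class = injury_classes())
  }
  if (!identical(rownames(table), imc_patterns()) ||
      !identical(colnames(table), injury_classes())) {
    stop("count table must have rows ", paste(imc_patterns(), collapse = "/"),
         " and columns ", paste(injury_classes(), collapse = "/"))
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  if (sum(table) == 0) stop("count table is empty")
  storage.mode(table) <- "integer"
  dimnames(table) <- list(pattern = rownames(table), class = colnames(table))
  table
}

#' Expand a count table into per-observation labels
#'
#' Inverse of [build_contingency()]: emits one `(pattern, class)` row per
#' counted observation, in row-major table order.
#'
#' @param table 4 x 5 pattern-by-class count matrix.
#' @return Data frame with factor columns `pattern` and `class`.
#' @export
counts_to_labels <- function(table = reference_pattern_counts()) {
  table <- .validate_count_table(table)
  idx <- which(table > 0, arr.ind = TRUE)
  pattern <- rep(rownames(table)[idx[, 1L]], table[idx])
  class <- rep(colnames(table)[idx[, 2L]], table[idx])
  data.frame(pattern = .as_pattern(pattern), class = .as_class(class))
}

#' Cross-tabulate pattern and injury labels
#'
#' @param labels Data frame with columns `pattern` and `class`, one row per
#'   observation (leg).
#' @return 4 x 5 integer count matrix in canonical pattern/class order.
#' @export
#' @examples
#' build_contingency(counts_to_labels())
build_contingency <- function(labels) {
  if (nrow(labels) == 0L) stop("no observations to tabulate")
  tab <- table(
    pattern = .as_pattern(labels$pattern),
    class = .as_class(labels$class)
  )
  m <- matrix(as.integer(tab), nrow = 4L,
              dimnames = list(pattern = imc_patterns(),
                              class = injury_classes()))
  m
}
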