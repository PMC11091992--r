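# Cohen's kappa for paired categorical ratings, with the conventional
# agreement bands used in clinical reliability reporting.

#' Cohen's kappa between two raters
#'
#' Unweighted kappa over the shared label space of the two sequences:
#' `kappa = (po - pe) / (1 - pe)` where `po` is the fraction of identical
#' labels and `pe = sum_k p_a(k) * p_b(k)` the agreement expected from the
#' raters' marginal label frequencies. When both raters use a single common
#' label (`pe = 1` with `po = 1`) kappa is defined as 1.
#'
#' @param labels_a,labels_b Equal-length vectors of categorical labels.
#' @return Object of class `kappa_result`: list with `kappa`,
#'   `observed_agreement`, `expected_agreement`, `band` and `n`.
#' @export
#' @examples
#' cohen_kappa(c("V", "V", "N", "N"), c("V", "N", "N", "N"))  # kappa 0.5
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) == 0L) stop("empty label sequences")
  if (length(labels_a) != length(labels_b)) {
    stop("label sequences differ in length (", length(labels_a), " vs ",
         length(labels_b), ")")
  }
  a <- as.character(labels_a)
  b <- as.character(labels_b)
  if (anyNA(a) || anyNA(b)) stop("labels must not contain NA")
  levels <- sort(unique(c(a, b)))
  n <- length(a)
  po <- mean(a == b)
  pa <- table(factor(a, levels))[levels] / n
  pb <- table(factor(b, levels))[levels] / n
  pe <- sum(as.numeric(pa) * as.numeric(pb))
  kappa <- if (pe >= 1 - 1e-15) {
    if (po >= 1 - 1e-15) 1 else stop("degenerate marginals with po < 1")
  } else {
    (po - pe) / (1 - pe)
  }
  structure(
    list(kappa = kappa, observed_agreement = po, expected_agreement = pe,
         band = interpret_kappa(kappa), n = n),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %.3f (%s)\n", x$kappa, x$band))
  cat(sprintf("  observed agreement %.3f, expected %.3f, n = %d\n",
              x$observed_agreement, x$expected_agreement, x$n))
  invisible(x)
}

#' Interpret a kappa value on the conventional agreement bands
#'
#' Bands: kappa <= 0 no agreement; (0, 0.20] none to slight; (0.20, 0.40]
#' fair; (0.40, 0.60] moderate; (0.60, 0.80] substantial; (0.80, 1] almost
#' perfect. The raw (unrounded) value is compared, with each printed upper
#' bound inclusive.
#'
#' @param kappa Numeric value in `[-1, 1]`.
#' @return Character band label.
#' @export
#' @examples
#' interpret_kappa(0.82)  # "almost perfect"
interpret_kappa <- function(kappa) {
  if (!is.finite(kappa) || kappa < -1 || kappa > 1) {
    stop("kappa must lie in [-1, 1]")
  }
  if (kappa <= 0) "no agreement"
  else if (kappa <= 0.20) "none to slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}
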