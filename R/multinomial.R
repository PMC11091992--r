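# Multinomial logistic association between curve pattern and injury class.
#
# The design is saturated: one categorical predictor (pattern, reference
# Normal) and a five-level outcome (reference Healthy), so every fitted odds
# ratio equals the 2 x 2 cross-ratio of the corresponding pattern/class cells
# against the Normal/Healthy reference, and the Wald standard error of each
# log odds ratio equals the square root of the sum of the four reciprocal
# counts. The Newton fit below maximizes the grouped-count multinomial
# likelihood; the closed form serves as its analytic oracle.

#' Closed-form odds ratio from the contingency table
#'
#' For the saturated single-predictor multinomial model, the odds ratio of
#' `pattern` (vs Normal) for `outcome` (vs Healthy) is the cross-ratio
#' `n[pattern, outcome] * n[Normal, Healthy] / (n[Normal, outcome] *
#' n[pattern, Healthy])`, with standard error of the log odds ratio
#' `sqrt(sum of the four reciprocal counts)`.
#'
#' @param table 4 x 5 pattern-by-class count matrix.
#' @param pattern An irregular pattern (`Valley`, `Drop` or `Shaking`).
#' @param outcome A non-reference injury class.
#' @return List with elements `or` and `se_log_or`.
#' @export
#' @examples
#' closed_form_or(reference_pattern_counts(), "Valley", "ACL")  # OR 17.5
closed_form_or <- function(table, pattern, outcome) {
  table <- .validate_count_table(table)
  pattern <- match.arg(pattern, setdiff(imc_patterns(), "Normal"))
  outcome <- match.arg(outcome, setdiff(injury_classes(), "Healthy"))
  cells <- c(table[pattern, outcome], table["Normal", "Healthy"],
             table["Normal", outcome], table[pattern, "Healthy"])
  if (any(cells == 0L)) {
    stop("zero cell in the ", pattern, "/", outcome,
         " cross-ratio; apply a continuity correction explicitly if desired")
  }
  list(
    or = (cells[1L] * cells[2L]) / (cells[3L] * cells[4L]),
    se_log_or = sqrt(sum(1 / cells))
  )
}

# Grouped-count multinomial log-likelihood (up to a constant).
.multinom_loglik <- function(beta, X, Y, n) {
  eta <- X %*% beta
  sum(Y * eta) - sum(n * log1p(rowSums(exp(eta))))
}

#' Fit the pattern-to-injury multinomial logistic model
#'
#' Maximum-likelihood Newton-Raphson fit of a multinomial logit of injury
#' class (reference `Healthy`) on curve pattern (reference `Normal`), on the
#' grouped counts of the contingency table. Inference is Wald: the standard
#' errors come from the inverse observed information, the confidence
#' intervals are `exp(estimate +/- z * se)` and the p-values are two-sided
#' normal tail probabilities of `estimate / se`.
#'
#' Zero cells make the saturated maximum-likelihood estimate infinite and
#' raise an error; setting `continuity_correction = TRUE` adds 0.5 to every
#' cell first (an explicit, opt-in choice -- the packaged reference table has
#' no zero cells).
#'
#' @param table 4 x 5 pattern-by-class count matrix.
#' @param conf_level Confidence level of the Wald intervals.
#' @param continuity_correction Add 0.5 to every cell before fitting.
#' @param max_iter,tol Newton iteration cap and gradient convergence
#'   tolerance.
#' @return Object of class `imc_fit`: a data frame with one row per
#'   coefficient (`outcome_class`, `term`, `estimate`, `se`, `odds_ratio`,
#'   `ci_lower`, `ci_upper`, `wald_z`, `p_value`), the source table and the
#'   fit diagnostics attached as attributes.
#' @export
#' @examples
#' fit <- fit_multinomial(reference_pattern_counts())
#' subset(fit, outcome_class == "ACL" & term == "Valley")
fit_multinomial <- function(table, conf_level = 0.95,
                            continuity_correction = FALSE,
                            max_iter = 100L, tol = 1e-10) {
  table <- .validate_count_table(table)
  counts <- if (continuity_correction) table + 0.5 else table
  if (any(counts == 0)) {
    stop("zero cell(s) in the contingency table: the saturated maximum-",
         "likelihood estimate does not exist. Use continuity_correction ",
         "= TRUE to add 0.5 to every cell explicitly.")
  }
  patterns <- imc_patterns()
  outcomes <- setdiff(injury_classes(), "Healthy")
  terms <- c("Intercept", setdiff(patterns, "Normal"))
  X <- cbind(1, diag(4L)[, -1L])          # rows = patterns, ref = Normal
  dimnames(X) <- list(patterns, terms)
  Y <- counts[, outcomes, drop = FALSE]   # non-reference class counts
  n <- rowSums(counts)
  p <- ncol(X)                            # predictors per outcome equation
  K <- length(outcomes)                   # non-reference outcomes
  beta <- matrix(0, p, K, dimnames = list(terms, outcomes))
  ll <- .multinom_loglik(beta, X, Y, n)
  converged <- FALSE
  iter <- 0L
  info <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- X %*% beta
    P <- exp(eta) / (1 + rowSums(exp(eta)))
    grad <- t(X) %*% (Y - n * P)
    info <- matrix(0, p * K, p * K)
    for (k in seq_len(K)) {
      for (l in seq_len(K)) {
        w <- n * P[, k] * ((k == l) - P[, l])
        block <- t(X) %*% (X * w)
        info[(k - 1L) * p + seq_len(p), (l - 1L) * p + seq_len(p)] <- block
      }
    }
    step <- solve(info, as.vector(grad))
    # step-halving keeps the ascent monotone on badly scaled tables
    lambda <- 1
    repeat {
      cand <- beta + lambda * matrix(step, p, K)
      ll_new <- .multinom_loglik(cand, X, Y, n)
      if (ll_new >= ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    beta <- cand
    ll <- ll_new
    if (max(abs(grad)) < tol * (1 + sum(counts))) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf(
      "Newton iteration did not converge in %d steps (max |gradient| %.3g)",
      max_iter, max(abs(t(X) %*% (Y - n * exp(X %*% beta) /
                                    (1 + rowSums(exp(X %*% beta))))))))
  }
  covar <- solve(info)
  se <- matrix(sqrt(diag(covar)), p, K, dimnames = dimnames(beta))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- do.call(rbind, lapply(outcomes, function(k) {
    data.frame(
      outcome_class = k,
      term = terms,
      estimate = beta[, k],
      se = se[, k],
      odds_ratio = exp(beta[, k]),
      ci_lower = exp(beta[, k] - z * se[, k]),
      ci_upper = exp(beta[, k] + z * se[, k]),
      wald_z = beta[, k] / se[, k],
      p_value = 2 * stats::pnorm(-abs(beta[, k] / se[, k])),
      row.names = NULL
    )
  }))
  structure(out, class = c("imc_fit", "data.frame"),
            table = table, loglik = ll, iterations = iter,
            conf_level = conf_level)
}

#' @export
print.imc_fit <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Multinomial logit of injury class on curve pattern (%d obs, %d Newton steps)\n",
    sum(attr(x, "table")), attr(x, "iterations")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' Extract one coefficient row from a fit
#'
#' @param fit An `imc_fit`.
#' @param outcome Non-reference injury class.
#' @param term `"Intercept"` or an irregular pattern.
#' @return One-row data frame.
#' @export
coef_entry <- function(fit, outcome, term) {
  row <- fit[fit$outcome_class == outcome & fit$term == term, , drop = FALSE]
  if (nrow(row) != 1L) stop("no such coefficient: ", outcome, " / ", term)
  row
}
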