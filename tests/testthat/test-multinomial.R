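test_that("closed-form cross-ratios reproduce the reference coefficients", {
  tab <- reference_pattern_counts()
  va <- closed_form_or(tab, "Valley", "ACL")
  expect_equal(va$or, 17.5)
  expect_equal(va$se_log_or, sqrt(1 / 2 + 1 / 2 + 1 / 2 + 1 / 35))
  expect_equal(round(va$se_log_or, 3), 1.236)

  # a balanced cross-ratio is exactly 1
  flat <- matrix(3L, 4, 5, dimnames = dimnames(tab))
  expect_equal(closed_form_or(flat, "Drop", "MS")$or, 1)

  zero <- tab
  zero["Valley", "ACL"] <- 0L
  expect_error(closed_form_or(zero, "Valley", "ACL"), "zero cell")
})

test_that("the Newton fit reproduces the saturated closed form on the reference table", {
  fit <- fit_multinomial(reference_pattern_counts())
  expect_identical(nrow(fit), 16L)
  for (k in setdiff(injury_classes(), "Healthy")) {
    for (p in setdiff(imc_patterns(), "Normal")) {
      oracle <- closed_form_or(reference_pattern_counts(), p, k)
      row <- coef_entry(fit, k, p)
      expect_equal(row$odds_ratio, oracle$or, tolerance = 1e-6)
      expect_equal(row$se, oracle$se_log_or, tolerance = 1e-6)
    }
    intercept <- coef_entry(fit, k, "Intercept")
    tab <- reference_pattern_counts()
    expect_equal(intercept$estimate, log(tab["Normal", k] / tab["Normal", "Healthy"]),
                 tolerance = 1e-8)
  }
  # invariants of each entry
  expect_equal(fit$odds_ratio, exp(fit$estimate), tolerance = 1e-9)
  expect_true(all(fit$ci_lower < fit$odds_ratio & fit$odds_ratio < fit$ci_upper))
  expect_true(all(fit$p_value > 0 & fit$p_value <= 1))
})

test_that("the fit agrees with an independent multinomial implementation", {
  skip_if_not_installed("nnet")
  labels <- counts_to_labels()
  df <- data.frame(
    class = stats::relevel(factor(labels$class), ref = "Healthy"),
    pattern = factor(labels$pattern, levels = imc_patterns())
  )
  ind <- nnet::multinom(class ~ pattern, df, maxit = 500, trace = FALSE,
                        reltol = 1e-12)
  co <- coef(ind)
  fit <- fit_multinomial(reference_pattern_counts())
  for (k in setdiff(injury_classes(), "Healthy")) {
    for (p in setdiff(imc_patterns(), "Normal")) {
      expect_equal(coef_entry(fit, k, p)$estimate,
                   unname(co[k, paste0("pattern", p)]), tolerance = 1e-4)
    }
  }
})

test_that("Newton fit equals the closed-form oracle on random all-positive tables", {
  set.seed(19)
  for (i in 1:100) {
    tab <- random_count_table()
    fit <- fit_multinomial(tab)
    for (k in setdiff(injury_classes(), "Healthy")) {
      for (p in setdiff(imc_patterns(), "Normal")) {
        oracle <- closed_form_or(tab, p, k)
        row <- coef_entry(fit, k, p)
        expect_equal(row$odds_ratio, oracle$or, tolerance = 1e-6)
        expect_equal(row$se, oracle$se_log_or, tolerance = 1e-6)
      }
    }
  }
})

test_that("fitted probabilities reproduce the observed pattern-conditional frequencies", {
  set.seed(23)
  tab <- random_count_table()
  fit <- fit_multinomial(tab)
  beta <- matrix(fit$estimate, nrow = 4,
                 dimnames = list(fit$term[1:4], unique(fit$outcome_class)))
  X <- cbind(1, diag(4)[, -1])
  eta <- X %*% beta
  P <- cbind(exp(eta), 1) / (1 + rowSums(exp(eta)))
  observed <- tab / rowSums(tab)
  expect_equal(unname(P), unname(cbind(observed[, 1:4], observed[, 5])),
               tolerance = 1e-8)
})

test_that("independence leaves all log odds ratios near zero", {
  # exact product table: counts proportional to margin products
  margins_p <- c(10, 20, 30, 40)
  margins_k <- c(2, 3, 4, 5, 6)
  tab <- outer(margins_p, margins_k)
  dimnames(tab) <- dimnames(reference_pattern_counts())
  fit <- fit_multinomial(tab)
  ors <- fit$estimate[fit$term != "Intercept"]
  expect_true(all(abs(ors) < 1e-8))
})

test_that("significance and confidence intervals are consistent", {
  set.seed(29)
  for (i in 1:20) {
    fit <- fit_multinomial(random_count_table())
    rows <- fit[fit$term != "Intercept", ]
    outside <- rows$ci_lower > 1 | rows$ci_upper < 1
    expect_identical(rows$p_value < 0.05, outside)
  }
})

test_that("zero cells error unless a continuity correction is requested", {
  tab <- reference_pattern_counts()
  tab["Drop", "MS"] <- 0L
  expect_error(fit_multinomial(tab), "zero cell")
  corrected <- fit_multinomial(tab, continuity_correction = TRUE)
  expect_equal(coef_entry(corrected, "MS", "Drop")$odds_ratio,
               (0.5 * 35.5) / (4.5 * 1.5), tolerance = 1e-6)
})
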