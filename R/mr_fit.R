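#' Convert a log-odds effect to an odds ratio with confidence interval
#'
#' `OR = exp(beta)` with Wald limits `exp(beta -+ z * se)` at the exact
#' normal quantile for `level`.
#'
#' @param beta,se Effect estimates and standard errors (vectorized).
#' @param level Coverage, default 0.95.
#' @return A tibble with columns `or`, `ci_low`, `ci_high`.
#' @examples
#' to_odds_ratio(-0.193, 0.069)  # OR 0.824
#' @export
to_odds_ratio <- function(beta, se, level = 0.95) {
  stopifnot(all(se > 0))
  z <- qnorm(1 - (1 - level) / 2)
  tibble(
    or = exp(beta),
    ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se)
  )
}

new_mr_fit <- function(method, n_snp, beta, se, level = 0.95,
                       q = NA_real_, q_df = NA_integer_, q_pval = NA_real_,
                       i2 = NA_real_, tau2 = NA_real_,
                       egger_intercept = NA_real_, egger_intercept_se = NA_real_,
                       egger_intercept_pval = NA_real_,
                       exposure_id = NA_character_, outcome_id = NA_character_) {
  or <- to_odds_ratio(beta, se, level)
  structure(
    list(
      method = method, n_snp = as.integer(n_snp),
      beta = beta, se = se, pval = two_sided_p(beta / se),
      or = or$or, ci_low = or$ci_low, ci_high = or$ci_high, level = level,
      q = q, q_df = as.integer(q_df), q_pval = q_pval, i2 = i2, tau2 = tau2,
      egger_intercept = egger_intercept,
      egger_intercept_se = egger_intercept_se,
      egger_intercept_pval = egger_intercept_pval,
      exposure_id = exposure_id, outcome_id = outcome_id
    ),
    class = "mr_fit"
  )
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("<mr_fit> %s (%d SNPs)\n", x$method, x$n_snp))
  cat(sprintf("  beta = %.4f (se %.4f), p = %.3g\n", x$beta, x$se, x$pval))
  cat(sprintf("  OR = %.3f (%d%% CI %.3f-%.3f)\n",
              x$or, round(100 * x$level), x$ci_low, x$ci_high))
  if (is.finite(x$q)) {
    cat(sprintf("  Q = %.3f (df %d, p = %.3g), I2 = %.1f%%\n",
                x$q, x$q_df, x$q_pval, x$i2))
  }
  if (is.finite(x$tau2)) cat(sprintf("  tau2 = %.4g (REML)\n", x$tau2))
  if (is.finite(x$egger_intercept)) {
    cat(sprintf("  Egger intercept = %.4f (se %.4f), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_pval))
  }
  invisible(x)
}

#' Tidy a causal-effect fit
#'
#' @param x An `mr_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the estimate, standard error, test
#'   statistic, p-value and odds-ratio scale columns.
#' @export
tidy.mr_fit <- function(x, ...) {
  tibble(
    exposure = x$exposure_id, outcome = x$outcome_id,
    method = x$method, n_snp = x$n_snp,
    estimate = x$beta, std.error = x$se,
    statistic = x$beta / x$se, p.value = x$pval,
    or = x$or, or.ci.low = x$ci_low, or.ci.high = x$ci_high
  )
}

#' One-row model-level summary of a causal-effect fit
#'
#' @param x An `mr_fit`.
#' @param ... Unused.
#' @return A one-row tibble with heterogeneity (Q, I2, tau2) and, for
#'   MR-Egger, the intercept pleiotropy test.
#' @export
glance.mr_fit <- function(x, ...) {
  tibble(
    method = x$method, n_snp = x$n_snp,
    q = x$q, q_df = x$q_df, q_pval = x$q_pval, i2 = x$i2, tau2 = x$tau2,
    egger_intercept = x$egger_intercept,
    egger_intercept_pval = x$egger_intercept_pval
  )
}
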