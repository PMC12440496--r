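#' Per-variant Wald ratios
#'
#' `ratio = beta_out / beta_exp` with first-order delta standard error
#' `se_out / |beta_exp|` (exposure uncertainty ignored, as usual in
#' two-sample practice); `second_order = TRUE` adds the exposure-side term
#' `beta_out^2 se_exp^2 / beta_exp^4` under the square root.
#'
#' @param h A `harmonized` tibble.
#' @param second_order Use the second-order delta SE; default `FALSE`.
#' @return A tibble with `variant_id`, `ratio`, `se_ratio`, `weight`
#'   (`1 / se_ratio^2`).
#' @export
mr_wald_ratios <- function(h, second_order = FALSE) {
  zero <- which(h$beta_exp == 0)
  if (length(zero) > 0) {
    abort(paste0("degenerate instrument(s) with beta_exp = 0: ",
                 paste(head(h$variant_id[zero], 10), collapse = ", ")),
          class = "mrmediation_domain_error")
  }
  se <- if (second_order) {
    sqrt(h$se_out^2 / h$beta_exp^2 + h$beta_out^2 * h$se_exp^2 / h$beta_exp^4)
  } else {
    h$se_out / abs(h$beta_exp)
  }
  tibble(
    variant_id = h$variant_id,
    ratio = h$beta_out / h$beta_exp,
    se_ratio = se,
    weight = 1 / se^2
  )
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_j (ratio_j - center)^2)` with df `k - 1`, upper-tail
#' chi-squared p-value, and `I2 = max(0, (Q - df) / Q) * 100`.
#'
#' @param ratio,weight Wald ratios and their inverse-variance weights.
#' @param center The pooled estimate the ratios are measured against.
#' @return A list with `q`, `df`, `q_pval`, `i2`.
#' @export
cochran_q <- function(ratio, weight, center) {
  k <- length(ratio)
  if (k < 2) abort("Cochran's Q requires at least 2 ratios",
                   class = "mrmediation_domain_error")
  q <- sum(weight * (ratio - center)^2)
  df <- k - 1L
  list(
    q = q, df = df,
    q_pval = pchisq(q, df, lower.tail = FALSE),
    i2 = if (q > 0) max(0, (q - df) / q) * 100 else 0
  )
}

# REML estimate of the additive between-variant variance tau^2 on the ratio
# scale: DerSimonian-Laird start, then the standard REML fixed-point
#   tau2 <- sum(w^2 ((y - mu)^2 - s^2)) / sum(w^2) + 1 / sum(w)
# with w = 1/(s^2 + tau2), truncated at zero.
tau2_reml <- function(ratio, se_ratio, tol = 1e-10, max_iter = 100) {
  k <- length(ratio)
  w <- 1 / se_ratio^2
  mu_fe <- sum(w * ratio) / sum(w)
  q <- sum(w * (ratio - mu_fe)^2)
  c_dl <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - (k - 1)) / c_dl)
  for (i in seq_len(max_iter)) {
    wi <- 1 / (se_ratio^2 + tau2)
    mu <- sum(wi * ratio) / sum(wi)
    new <- sum(wi^2 * ((ratio - mu)^2 - se_ratio^2)) / sum(wi^2) + 1 / sum(wi)
    new <- max(0, new)
    if (abs(new - tau2) < tol) {
      tau2 <- new
      break
    }
    tau2 <- new
  }
  tau2
}

#' Inverse-variance weighted causal estimate
#'
#' Pools Wald ratios with inverse-variance weights. The fixed-effects
#' estimate is the weighted mean with `se = sqrt(1 / sum(w))`. Under
#' `model = "auto"` a random-effects model is used when either the Cochran
#' Q p-value falls below 0.05 or I2 exceeds 25%; its between-variant
#' variance tau^2 is estimated by REML (DerSimonian-Laird start, 1e-10
#' tolerance, 100-iteration cap) and enters the weights as
#' `1 / (se_ratio^2 + tau2)`. A single instrument yields a Wald fit with no
#' heterogeneity statistics.
#'
#' @param h A `harmonized` tibble.
#' @param model `"auto"`, `"fixed"` or `"random"`.
#' @param level CI coverage for the odds-ratio transform; default 0.95.
#' @param second_order Passed to [mr_wald_ratios()].
#' @return An `mr_fit`.
#' @export
mr_ivw <- function(h, model = c("auto", "fixed", "random"), level = 0.95,
                   second_order = FALSE) {
  model <- match.arg(model)
  k <- nrow(h)
  if (k == 0) abort("no instruments", class = "mrmediation_no_instrument_error")
  wr <- mr_wald_ratios(h, second_order = second_order)
  ids <- list(exposure_id = attr(h, "exposure_id"), outcome_id = attr(h, "outcome_id"))

  if (k == 1) {
    return(new_mr_fit("wald_single", 1L, wr$ratio, wr$se_ratio, level,
                      exposure_id = ids$exposure_id, outcome_id = ids$outcome_id))
  }

  beta_fe <- sum(wr$weight * wr$ratio) / sum(wr$weight)
  het <- cochran_q(wr$ratio, wr$weight, beta_fe)
  use_random <- switch(model,
    fixed = FALSE,
    random = TRUE,
    auto = het$q_pval < 0.05 || het$i2 > 25
  )

  if (!use_random) {
    return(new_mr_fit("ivw_fixed", k, beta_fe, sqrt(1 / sum(wr$weight)), level,
                      q = het$q, q_df = het$df, q_pval = het$q_pval, i2 = het$i2,
                      exposure_id = ids$exposure_id, outcome_id = ids$outcome_id))
  }
  tau2 <- tau2_reml(wr$ratio, wr$se_ratio)
  w_re <- 1 / (wr$se_ratio^2 + tau2)
  beta_re <- sum(w_re * wr$ratio) / sum(w_re)
  new_mr_fit("ivw_random", k, beta_re, sqrt(1 / sum(w_re)), level,
             q = het$q, q_df = het$df, q_pval = het$q_pval, i2 = het$i2,
             tau2 = tau2,
             exposure_id = ids$exposure_id, outcome_id = ids$outcome_id)
}

#' Leave-one-out IVW analysis
#'
#' Refits [mr_ivw()] `k` times, each excluding one variant, re-evaluating
#' the fixed/random model choice per fit. Flags single variants that drive
#' the pooled estimate.
#'
#' @param h A `harmonized` tibble with at least 2 rows.
#' @inheritParams mr_ivw
#' @return A tibble with one row per excluded variant: `excluded_variant`,
#'   `method`, `n_snp`, `beta`, `se`, `pval`, `or`, `ci_low`, `ci_high`.
#' @export
mr_leave_one_out <- function(h, model = "auto", level = 0.95) {
  if (nrow(h) < 2) abort("leave-one-out requires at least 2 instruments",
                         class = "mrmediation_domain_error")
  fits <- map(seq_len(nrow(h)), function(j) {
    fit <- mr_ivw(subset_harmonized(h, -j), model = model, level = level)
    tibble(
      excluded_variant = h$variant_id[j],
      method = fit$method, n_snp = fit$n_snp,
      beta = fit$beta, se = fit$se, pval = fit$pval,
      or = fit$or, ci_low = fit$ci_low, ci_high = fit$ci_high
    )
  })
  list_rbind(fits)
}
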