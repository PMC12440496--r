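#' Sobel test for an indirect (product) effect
#'
#' `se_indirect = sqrt(beta1^2 se2^2 + beta2^2 se1^2)`,
#' `z = beta1 beta2 / se_indirect`, `p = 2 Phi(-|z|)`. When both
#' coefficients are exactly zero the statistic is defined as `z = 0`,
#' `p = 1` (limit convention).
#'
#' @param beta1,se1 Exposure-to-mediator effect and its standard error.
#' @param beta2,se2 Mediator-to-outcome effect and its standard error.
#' @return A one-row tibble with `indirect`, `se_indirect`, `z`, `p`.
#' @examples
#' sobel_test(0.075, 0.026, -0.211, 0.068)
#' @export
sobel_test <- function(beta1, se1, beta2, se2) {
  stopifnot(all(se1 > 0), all(se2 > 0))
  se_ind <- sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
  z <- ifelse(se_ind == 0, 0, beta1 * beta2 / se_ind)
  p <- ifelse(z == 0, 1, two_sided_p(z))
  tibble(indirect = beta1 * beta2, se_indirect = se_ind, z = z, p = p)
}

extract_effect <- function(fit, what) {
  if (inherits(fit, "mr_fit")) return(list(beta = fit$beta, se = fit$se))
  if (is.list(fit) && all(c("beta", "se") %in% names(fit))) {
    return(list(beta = fit$beta[[1]], se = fit$se[[1]]))
  }
  abort(paste0(what, " must be an mr_fit or a list/row with beta and se"),
        class = "mrmediation_validation_error")
}

#' Two-step MR mediation: decompose a total effect through one mediator
#'
#' Product method. The indirect effect is `beta1 * beta2` with the Sobel
#' standard error; the direct effect is `beta_total - indirect`; the
#' proportion mediated is `indirect / beta_total`, with a delta-method
#' standard error treating the product and the total as independent
#' (different instrument sets):
#' `se_prop^2 = se_ind^2 / beta_t^2 + indirect^2 se_t^2 / beta_t^4`.
#' Negative proportions are legal (the indirect path opposes the total
#' effect); `|proportion| > 1` is reported untruncated and flagged as
#' inconsistent ("suppression") mediation.
#'
#' @param fit_xm Exposure-to-mediator fit (`mr_fit`, or any list with
#'   `beta` and `se`).
#' @param fit_my Mediator-to-outcome fit (univariable).
#' @param fit_xy Exposure-to-outcome (total-effect) fit. Its `se` may be
#'   `NA`, in which case the proportion's confidence interval is reported
#'   missing.
#' @param level CI coverage; default 0.95.
#' @param exposure,mediator,outcome Optional labels; taken from the fits'
#'   trait ids when available.
#' @return A one-row tibble of class `mediation_result` with the stage
#'   coefficients, indirect/direct/total effects, Sobel inference, the
#'   indirect-effect CI, and the proportion mediated with its CI.
#' @export
mediate <- function(fit_xm, fit_my, fit_xy, level = 0.95,
                    exposure = NULL, mediator = NULL, outcome = NULL) {
  xm <- extract_effect(fit_xm, "fit_xm")
  my <- extract_effect(fit_my, "fit_my")
  xy <- extract_effect(fit_xy, "fit_xy")
  zq <- qnorm(1 - (1 - level) / 2)

  sob <- sobel_test(xm$beta, xm$se, my$beta, my$se)
  indirect <- sob$indirect
  direct <- xy$beta - indirect

  if (is.finite(xy$beta) && xy$beta != 0) {
    proportion <- indirect / xy$beta
    if (is.finite(xy$se %||% NA_real_) && !is.na(xy$se)) {
      se_prop <- sqrt(sob$se_indirect^2 / xy$beta^2 +
                        indirect^2 * xy$se^2 / xy$beta^4)
    } else {
      se_prop <- NA_real_
    }
  } else {
    proportion <- NA_real_
    se_prop <- NA_real_
  }

  out <- tibble(
    exposure_id = exposure %||% fit_label(fit_xm, "exposure_id") %||% "exposure",
    mediator_id = mediator %||% fit_label(fit_my, "exposure_id") %||% "mediator",
    outcome_id = outcome %||% fit_label(fit_my, "outcome_id") %||% "outcome",
    beta1 = xm$beta, se1 = xm$se,
    beta2 = my$beta, se2 = my$se,
    beta_total = xy$beta, se_total = xy$se %||% NA_real_,
    indirect = indirect, se_indirect = sob$se_indirect,
    sobel_z = sob$z, sobel_p = sob$p,
    indirect_ci_low = indirect - zq * sob$se_indirect,
    indirect_ci_high = indirect + zq * sob$se_indirect,
    direct = direct,
    proportion = proportion, se_proportion = se_prop,
    proportion_ci_low = proportion - zq * se_prop,
    proportion_ci_high = proportion + zq * se_prop,
    inconsistent_mediation = is.finite(proportion) & abs(proportion) > 1
  )
  class(out) <- c("mediation_result", class(out))
  out
}

fit_label <- function(fit, field) {
  if (inherits(fit, "mr_fit")) fit[[field]] else NULL
}

#' Format a collection of mediation results as a report table
#'
#' One row per (exposure, mediator, outcome) triple, with the mediated
#' effect and its CI at 3 decimal places and the mediated proportion as a
#' signed percentage at 1 decimal place.
#'
#' @param results A `mediation_result` tibble (rows from [mediate()]).
#' @return A formatted tibble.
#' @export
proportion_summary <- function(results) {
  cols <- c("exposure_id", "mediator_id", "outcome_id")
  if (nrow(results) == 0) {
    return(tibble(exposure = character(), mediator = character(),
                  outcome = character(), mediated_effect = character(),
                  mediated_proportion = character()))
  }
  dup <- duplicated(results[cols])
  if (any(dup)) {
    abort(paste0("duplicated mediation triple(s): ",
                 paste(unique(do.call(paste, c(results[cols][dup, ], sep = " / "))),
                       collapse = "; ")),
          class = "mrmediation_validation_error")
  }
  fmt3 <- function(x) formatC(x, format = "f", digits = 3)
  fmt_pct <- function(x) {
    ifelse(is.na(x), "NA", paste0(formatC(100 * x, format = "f", digits = 1), "%"))
  }
  tibble(
    exposure = results$exposure_id,
    mediator = results$mediator_id,
    outcome = results$outcome_id,
    mediated_effect = paste0(
      fmt3(results$indirect), " (", fmt3(results$indirect_ci_low), ", ",
      fmt3(results$indirect_ci_high), ")"
    ),
    mediated_proportion = ifelse(
      is.na(results$proportion), "NA",
      paste0(fmt_pct(results$proportion), " (",
             fmt_pct(results$proportion_ci_low), ", ",
             fmt_pct(results$proportion_ci_high), ")")
    )
  )
}
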