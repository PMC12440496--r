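#' MR-Egger regression
#'
#' Weighted least squares of `beta_out` on `beta_exp` *with* an intercept,
#' weights `1 / se_out^2`, after orienting every row so `beta_exp >= 0`
#' (the usual Egger identifiability convention). The slope is the
#' pleiotropy-robust causal estimate; the intercept, its standard error and
#' two-sided normal p-value form the directional-pleiotropy test. Standard
#' errors carry a multiplicative residual-variance inflation floored at 1
#' (underdispersion is not rewarded).
#'
#' @param h A `harmonized` tibble with at least 3 rows.
#' @param level CI coverage for the odds-ratio transform.
#' @return An `mr_fit` with method `"egger"` and intercept fields populated.
#' @export
mr_egger <- function(h, level = 0.95) {
  k <- nrow(h)
  if (k < 3) abort("MR-Egger requires at least 3 instruments",
                   class = "mrmediation_insufficient_instruments_error")
  sgn <- ifelse(h$beta_exp < 0, -1, 1)
  x <- h$beta_exp * sgn
  y <- h$beta_out * sgn
  w <- 1 / h$se_out^2

  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  denom <- sw * swxx - swx^2
  if (denom <= 0) abort("degenerate design: no spread in beta_exp",
                        class = "mrmediation_domain_error")
  slope <- (sw * swxy - swx * swy) / denom
  intercept <- (swxx * swy - swx * swxy) / denom

  resid <- y - intercept - slope * x
  sigma2 <- sum(w * resid^2) / (k - 2)
  inflation <- max(1, sigma2)
  se_slope <- sqrt(sw / denom * inflation)
  se_int <- sqrt(swxx / denom * inflation)

  new_mr_fit("egger", k, slope, se_slope, level,
             egger_intercept = intercept,
             egger_intercept_se = se_int,
             egger_intercept_pval = two_sided_p(intercept / se_int),
             exposure_id = attr(h, "exposure_id"),
             outcome_id = attr(h, "outcome_id"))
}
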