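# Weighted-median point estimate: order ratios ascending, form standardized
# cumulative weights s_j = (cumsum(w)_j - w_j/2) / sum(w), and linearly
# interpolate the ratio at s = 0.5 (clamped to the end ratios outside the
# grid).
weighted_median_estimate <- function(ratio, weight) {
  o <- order(ratio)
  b <- ratio[o]
  w <- weight[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  approx(s, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' Consistent when instruments carrying at least half of the total weight
#' are valid. The point estimate interpolates the inverse-variance weighted
#' empirical quantile function of the Wald ratios at probability one half;
#' its standard error is the standard deviation of the estimate over
#' `n_boot` parametric-bootstrap replicates, each redrawing every ratio from
#' a normal with its own standard error.
#'
#' @param h A `harmonized` tibble with at least 3 rows.
#' @param n_boot Bootstrap replicates for the SE; default 5000.
#' @param seed RNG seed for the bootstrap (the caller's RNG state is left
#'   untouched); default 20250912.
#' @param level CI coverage for the odds-ratio transform.
#' @return An `mr_fit` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 5000, seed = 20250912, level = 0.95) {
  k <- nrow(h)
  if (k < 3) abort("weighted median requires at least 3 instruments",
                   class = "mrmediation_insufficient_instruments_error")
  wr <- mr_wald_ratios(h)
  est <- weighted_median_estimate(wr$ratio, wr$weight)
  boots <- with_seed(seed, {
    draws <- matrix(rnorm(n_boot * k, mean = wr$ratio, sd = wr$se_ratio),
                    nrow = k, ncol = n_boot)
    apply(draws, 2, weighted_median_estimate, weight = wr$weight)
  })
  se <- sd(boots)
  if (!is.finite(se) || se == 0) se <- .Machine$double.eps
  new_mr_fit("weighted_median", k, est, se, level,
             exposure_id = attr(h, "exposure_id"),
             outcome_id = attr(h, "outcome_id"))
}
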