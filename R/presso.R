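# Leave-one-out fixed-effects IVW estimates, vectorized: for each variant j,
# the weighted mean of all Wald ratios excluding j.
loo_ivw_fixed <- function(num, den) {
  (sum(num) - num) / (sum(den) - den)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Monte-Carlo test for horizontal pleiotropy built on the observed residual
#' sum of squares
#' `RSS = sum((beta_out_j - b(-j) * beta_exp_j)^2 / se_out_j^2)`, where
#' `b(-j)` is the fixed-effects IVW estimate excluding variant `j`. The
#' global p-value compares RSS against `n_sim` parametric simulations that
#' redraw `beta_out_j ~ N(b(-j) beta_exp_j, se_out_j)` and
#' `beta_exp_j ~ N(beta_exp_j, se_exp_j)` and recompute RSS (add-one
#' Monte-Carlo correction, so p is never exactly zero). Per-variant outlier
#' p-values come from the simulated distribution of each residual term,
#' Bonferroni-adjusted over the `k` variants; flagged outliers are removed
#' and the estimate refitted. A distortion test compares the raw-minus-
#' corrected contrast against the same contrast under random outlier-sized
#' subsets.
#'
#' @param h A `harmonized` tibble with at least 4 rows.
#' @param n_sim Number of simulations; default 10000.
#' @param outlier_alpha Significance level for the Bonferroni-adjusted
#'   outlier test; default 0.05.
#' @param seed RNG seed; all randomness flows through one seeded generator
#'   and the caller's RNG state is restored afterwards.
#' @param model IVW model for the reported raw/corrected fits, passed to
#'   [mr_ivw()]; default `"auto"`.
#' @param level CI coverage for odds-ratio transforms.
#' @return An object of class `mr_presso`: a list with `rss_obs`,
#'   `global_pval`, `n_sim`, `outlier_pvals` (tibble of raw and adjusted
#'   per-variant p-values), `outliers` (variant ids), `distortion_pval`
#'   (`NA` when no outliers are flagged), `beta_raw` and `beta_corrected`
#'   (`mr_fit` objects) and `seed`.
#' @export
mr_presso <- function(h, n_sim = 10000, outlier_alpha = 0.05,
                      seed = 20250912, model = "auto", level = 0.95) {
  k <- nrow(h)
  if (k < 4) abort("MR-PRESSO requires at least 4 instruments",
                   class = "mrmediation_insufficient_instruments_error")
  be <- h$beta_exp
  bo <- h$beta_out
  seo <- h$se_out
  see <- h$se_exp

  # Fixed-effects IVW as a ratio of sums: num = sum(be*bo/seo^2), den =
  # sum(be^2/seo^2); the per-variant contributions make leave-one-out cheap.
  num <- be * bo / seo^2
  den <- be^2 / seo^2
  b_loo <- loo_ivw_fixed(num, den)
  term_obs <- (bo - b_loo * be)^2 / seo^2
  rss_obs <- sum(term_obs)

  sims <- with_seed(seed, {
    BE <- matrix(rnorm(n_sim * k, mean = be, sd = see), nrow = k)
    BO <- matrix(rnorm(n_sim * k, mean = b_loo * be, sd = seo), nrow = k)
    NUM <- BE * BO / seo^2
    DEN <- BE^2 / seo^2
    BL <- (rep(colSums(NUM), each = k) - NUM) / (rep(colSums(DEN), each = k) - DEN)
    TERM <- (BO - BL * BE)^2 / seo^2
    rss_sim <- colSums(TERM)
    exceed_term <- rowSums(TERM >= term_obs)
    list(rss_sim = rss_sim, exceed_term = exceed_term, k = k)
  })

  global_pval <- (1 + sum(sims$rss_sim >= rss_obs)) / (n_sim + 1)
  outlier_p_raw <- (1 + sims$exceed_term) / (n_sim + 1)
  outlier_p_adj <- pmin(1, outlier_p_raw * k)
  is_outlier <- outlier_p_adj < outlier_alpha
  outliers <- h$variant_id[is_outlier]

  if (all(is_outlier)) {
    abort("every instrument flagged as an outlier; corrected estimate undefined",
          class = "mrmediation_degenerate_correction_error")
  }

  beta_raw <- mr_ivw(h, model = model, level = level)
  if (length(outliers) > 0) {
    beta_corrected <- mr_ivw(subset_harmonized(h, !is_outlier),
                             model = model, level = level)
    m <- length(outliers)
    d_obs <- beta_raw$beta - beta_corrected$beta
    d_sim <- with_seed(seed + 1, {
      vapply(seq_len(n_sim), function(i) {
        drop_idx <- sample.int(k, m)
        b_sub <- sum(num[-drop_idx]) / sum(den[-drop_idx])
        sum(num) / sum(den) - b_sub
      }, numeric(1))
    })
    distortion_pval <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
  } else {
    beta_corrected <- beta_raw
    distortion_pval <- NA_real_
  }

  structure(
    list(
      rss_obs = rss_obs, global_pval = global_pval, n_sim = as.integer(n_sim),
      outlier_pvals = tibble(
        variant_id = h$variant_id,
        pval = outlier_p_raw, pval_adj = outlier_p_adj, outlier = is_outlier
      ),
      outliers = outliers, distortion_pval = distortion_pval,
      beta_raw = beta_raw, beta_corrected = beta_corrected,
      seed = seed
    ),
    class = "mr_presso"
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("<mr_presso> RSS = %.3f, global p = %.4g (%d simulations)\n",
              x$rss_obs, x$global_pval, x$n_sim))
  if (length(x$outliers) > 0) {
    cat(sprintf("  outliers (%d): %s\n", length(x$outliers),
                paste(x$outliers, collapse = ", ")))
    cat(sprintf("  distortion p = %.4g\n", x$distortion_pval))
    cat(sprintf("  beta raw %.4f -> corrected %.4f\n",
                x$beta_raw$beta, x$beta_corrected$beta))
  } else {
    cat("  no outliers flagged; corrected estimate equals raw\n")
  }
  invisible(x)
}

#' @export
tidy.mr_presso <- function(x, ...) {
  bind_rows(
    mutate(tidy(x$beta_raw), presso = "raw"),
    mutate(tidy(x$beta_corrected), presso = "outlier_corrected")
  )
}

#' @export
glance.mr_presso <- function(x, ...) {
  tibble(
    rss_obs = x$rss_obs, global_pval = x$global_pval, n_sim = x$n_sim,
    n_outliers = length(x$outliers), distortion_pval = x$distortion_pval
  )
}
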