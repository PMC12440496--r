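# Monte-Carlo study runners shared by the calibration/recovery tests.
# Problem sizes follow the package's documented validation design:
# 30 instruments at n = 50,000/50,000 for the two-sample calibration, and
# n = 100,000 per trait for mediation recovery.

study_pair_fit <- function(seed, theta_null = FALSE) {
  tr <- if (theta_null) {
    sim_truth(theta_xm = 0, theta_xy_direct = 0, seed = seed)
  } else {
    sim_truth(seed = seed)
  }
  d <- simulate_pair(tr)
  iv <- select_by_pvalue(d$exposure)
  if (nrow(iv) < 2) return(c(beta = NA, se = NA, pval = NA))
  f <- mr_ivw(harmonize(iv, d$outcome))
  c(beta = f$beta, se = f$se, pval = f$pval)
}

study_mediation_fit <- function(seed, null_xm = FALSE) {
  tr <- sim_truth(n_exp = 1e5, n_med = 1e5, n_out = 1e5,
                  theta_xm = if (null_xm) 0 else 0.3, seed = seed)
  d <- simulate_mediation(tr)
  ivx <- select_by_pvalue(d$exposure)
  ivm <- select_by_pvalue(d$mediator)
  if (nrow(ivx) < 2 || nrow(ivm) < 2) return(c(proportion = NA, sobel_p = NA))
  f1 <- mr_ivw(harmonize(ivx, d$mediator))
  f2 <- mr_ivw(harmonize(ivm, d$outcome))
  ft <- mr_ivw(harmonize(ivx, d$outcome))
  med <- mediate(f1, f2, ft)
  c(proportion = med$proportion, sobel_p = med$sobel_p)
}

study_presso_null_pval <- function(seed, k = 30, n_sim = 1000) {
  d <- simulate_pair(sim_truth(n_snp = k, seed = seed))
  h <- harmonize(d$exposure, d$outcome)
  mr_presso(h, n_sim = n_sim, seed = seed)$global_pval
}

study_presso_detect <- function(seed, n_sim = 1000) {
  h <- simulate_outlier_demo(seed = seed)
  "rs30" %in% mr_presso(h, n_sim = n_sim, seed = seed)$outliers
}

study_steiger_rates <- function(seed) {
  tr <- sim_truth(n_snp = 500, reverse_prop = 0.1,
                  r2_range = c(2e-4, 6e-4),
                  n_exp = 1e5, n_out = 1e5, n_med = 500,
                  outcome_type = "continuous", seed = seed)
  d <- simulate_pair(tr)
  h <- harmonize(d$exposure, d$outcome)
  res <- steiger_results(steiger_filter(h))
  rev_ids <- d$exposure$variant_id[tr$delta != 0]
  is_rev <- res$variant_id %in% rev_ids
  c(reverse_excluded = mean(res$excluded[is_rev]),
    valid_lost = mean(res$excluded[!is_rev]))
}
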