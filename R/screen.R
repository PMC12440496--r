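#' Screening-pipeline configuration
#'
#' Collects every threshold of the screening cascade in one validated
#' object: instrument p-value, clumping parameters, palindrome window,
#' weak-instrument F floor, Steiger alpha, the screening alpha, the
#' Bonferroni family size, and the Monte-Carlo sizes and master seed.
#'
#' @param iv_pval Instrument selection p-value; default `1e-5`.
#' @param clump_r2,clump_kb LD clumping threshold and window; defaults
#'   0.001 and 1000 kb. Clumping is skipped when no LD matrix is supplied.
#' @param palindrome_maf_window Passed to [harmonize()].
#' @param f_min Weak-instrument F floor; default 10.
#' @param steiger_alpha Directionality-test alpha; default 0.05.
#' @param screen_alpha Nominal screening significance; default 0.05.
#' @param bonferroni_m Family size for the descriptive Bonferroni flag;
#'   default the exposure-panel size.
#' @param presso_nsim MR-PRESSO simulations; default 10000.
#' @param n_boot Weighted-median bootstrap replicates; default 5000.
#' @param strict_loo Require every leave-one-out fit to stay significant,
#'   not just sign-stable; default `FALSE`.
#' @param seed Mandatory master seed; per-trait analysis seeds are derived
#'   from it.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(iv_pval = 1e-5, clump_r2 = 0.001, clump_kb = 1000,
                          palindrome_maf_window = c(0.40, 0.60),
                          f_min = 10, steiger_alpha = 0.05,
                          screen_alpha = 0.05, bonferroni_m = NULL,
                          presso_nsim = 10000, n_boot = 5000,
                          strict_loo = FALSE, seed) {
  if (missing(seed)) abort("screen_config requires an explicit seed",
                           class = "mrmediation_config_error")
  stopifnot(
    iv_pval > 0, iv_pval <= 1, clump_r2 >= 0, clump_kb > 0,
    f_min >= 0, steiger_alpha > 0, steiger_alpha <= 1,
    screen_alpha > 0, screen_alpha <= 1, presso_nsim >= 100, n_boot >= 100
  )
  structure(
    list(iv_pval = iv_pval, clump_r2 = clump_r2, clump_kb = clump_kb,
         palindrome_maf_window = palindrome_maf_window, f_min = f_min,
         steiger_alpha = steiger_alpha, screen_alpha = screen_alpha,
         bonferroni_m = bonferroni_m, presso_nsim = presso_nsim,
         n_boot = n_boot, strict_loo = strict_loo, seed = seed),
    class = "screen_config"
  )
}

#' Read a screening configuration from YAML
#'
#' The YAML keys mirror the [screen_config()] arguments, plus optional data
#' paths (`exposures`, `mediators`, `outcome`, `ld`, `exclude`) returned in
#' the `paths` attribute for [run_pipeline()].
#'
#' @param path YAML file.
#' @return A `screen_config`.
#' @export
read_screen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  param_names <- setdiff(names(formals(screen_config)), "...")
  cfg <- do.call(screen_config, raw[intersect(names(raw), param_names)])
  attr(cfg, "paths") <- raw[intersect(names(raw),
                                      c("exposures", "mediators", "outcome",
                                        "ld", "exclude"))]
  cfg
}

#' Bonferroni adjustment with an explicit family size
#'
#' `p_adj = min(1, p * m)`; with `m = length(pvals)` this equals
#' `p.adjust(..., "bonferroni")`, but the family size may exceed the number
#' of p-values actually carried forward (e.g. the full exposure panel).
#'
#' @param pvals P-values.
#' @param m Family size; default `length(pvals)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  if (m < length(pvals)) {
    warn("Bonferroni family size m is smaller than the number of p-values")
  }
  pmin(1, pvals * m)
}

#' Directional concordance and leave-one-out stability gates
#'
#' A causal signal passes the concordance gate when the IVW,
#' weighted-median and outlier-corrected estimates agree in sign, and the
#' leave-one-out gate when every leave-one-out IVW estimate keeps the
#' full-fit sign (lenient mode, the default) and - in strict mode - also
#' stays significant at `screen_alpha`.
#'
#' @param fits A named list with `mr_fit` elements `ivw`,
#'   `weighted_median`, `presso_corrected` (the latter equals the raw IVW
#'   fit when no outliers were flagged).
#' @param loo A leave-one-out tibble from [mr_leave_one_out()].
#' @param screen_alpha Significance threshold used in strict mode.
#' @param strict Logical; default `FALSE`.
#' @return A list with logicals `concordant` and `loo_stable`.
#' @export
triple_concordance <- function(fits, loo, screen_alpha = 0.05, strict = FALSE) {
  need <- c("ivw", "weighted_median", "presso_corrected")
  if (!all(need %in% names(fits)) || any(vapply(fits[need], is.null, logical(1)))) {
    abort(paste0("incomplete evidence: fits must contain ",
                 paste(need, collapse = ", ")),
          class = "mrmediation_incomplete_evidence_error")
  }
  betas <- vapply(fits[need], function(f) f$beta, numeric(1))
  concordant <- length(unique(sign(betas))) == 1 && all(sign(betas) != 0)
  ref_sign <- sign(fits$ivw$beta)
  loo_stable <- all(sign(loo$beta) == ref_sign)
  if (strict) loo_stable <- loo_stable && all(loo$pval < screen_alpha)
  list(concordant = concordant, loo_stable = loo_stable)
}

# Instrument-preparation cascade for one exposure against one outcome:
# p-value selection -> LD clumping -> exclusion list -> harmonization ->
# Steiger filter -> weak-instrument filter. Returns the surviving
# harmonized set plus the count at every gate.
prepare_instruments <- function(exposure, outcome, cfg, ld = NULL,
                                exclude = character()) {
  counts <- list(n_total = nrow(exposure))
  iv <- select_by_pvalue(exposure, cfg$iv_pval)
  counts$n_pval <- nrow(iv)
  if (!is.null(ld) && nrow(iv) > 1) {
    iv <- clump(iv, ld, r2_max = cfg$clump_r2, window_kb = cfg$clump_kb)
  }
  counts$n_clump <- nrow(iv)
  iv <- apply_exclusion_list(iv, exclude)
  counts$n_after_exclusion <- nrow(iv)
  if (nrow(iv) == 0) {
    return(list(h = NULL, counts = c(counts, list(n_harmonized = 0L,
                                                  n_steiger = 0L, n_final = 0L))))
  }
  h <- tryCatch(
    harmonize(iv, outcome, palindrome_maf_window = cfg$palindrome_maf_window),
    mrmediation_empty_overlap_error = function(e) NULL
  )
  if (is.null(h) || nrow(h) == 0) {
    return(list(h = NULL, counts = c(counts, list(n_harmonized = 0L,
                                                  n_steiger = 0L, n_final = 0L))))
  }
  counts$n_harmonized <- nrow(h)
  h <- steiger_filter(h, alpha = cfg$steiger_alpha)
  counts$n_steiger <- nrow(h)
  f <- f_statistic(variance_explained(h$beta_exp, h$se_exp, h$n_exp), h$n_exp)
  h <- subset_harmonized(h, f >= cfg$f_min)
  counts$n_final <- nrow(h)
  list(h = if (nrow(h) > 0) h else NULL, counts = counts)
}

# Full estimator suite on one harmonized set; entries that need more
# instruments than available are NULL.
fit_suite <- function(h, cfg, seed) {
  k <- nrow(h)
  ivw <- mr_ivw(h, model = "auto")
  egger <- if (k >= 3) mr_egger(h) else NULL
  wm <- if (k >= 3) mr_weighted_median(h, n_boot = cfg$n_boot, seed = seed) else NULL
  presso <- if (k >= 4) mr_presso(h, n_sim = cfg$presso_nsim, seed = seed) else NULL
  loo <- if (k >= 2) mr_leave_one_out(h) else NULL
  presso_corrected <- if (!is.null(presso) && length(presso$outliers) > 0) {
    presso$beta_corrected
  } else {
    ivw
  }
  list(ivw = ivw, egger = egger, weighted_median = wm, presso = presso,
       presso_corrected = presso_corrected, loo = loo, h = h)
}

#' Screen a panel of exposures against one outcome
#'
#' Runs the full instrument cascade and estimator suite for every exposure
#' and applies the screening gates: IVW significance at `screen_alpha`,
#' sign concordance across IVW / weighted median / outlier-corrected
#' estimates, and leave-one-out stability. The Bonferroni flag over the
#' panel (family size `bonferroni_m`, default the panel size) is
#' descriptive, not a gate. Exposures with fewer than 3 surviving
#' instruments are recorded but cannot pass.
#'
#' @param exposures A named list of `sumstats` tables (a single table is
#'   accepted); names default to the tables' trait ids, which must be
#'   unique.
#' @param outcome A `sumstats` table.
#' @param cfg A [screen_config()].
#' @param ld Optional [ld_matrix()] for clumping.
#' @param exclude Character vector of variant ids to exclude (e.g. a
#'   confounder-lookup result).
#' @return A tibble with one row per exposure: ids, a `status`, instrument
#'   counts at each gate, per-method estimates, the gate booleans,
#'   `passes`, the Bonferroni-adjusted IVW p-value, and a `fits`
#'   list-column holding the underlying objects.
#' @export
mr_screen <- function(exposures, outcome, cfg, ld = NULL, exclude = character()) {
  if (inherits(exposures, "sumstats")) exposures <- list(exposures)
  if (is.null(names(exposures)) || any(!nzchar(names(exposures)))) {
    names(exposures) <- vapply(exposures, trait_id, character(1))
  }
  if (anyDuplicated(names(exposures))) {
    abort("duplicate exposure ids", class = "mrmediation_config_error")
  }
  seeds <- derive_seeds(cfg$seed, length(exposures))
  m <- cfg$bonferroni_m %||% length(exposures)

  rows <- imap(exposures, function(expo, id) {
    i <- match(id, names(exposures))
    prep <- prepare_instruments(expo, outcome, cfg, ld = ld, exclude = exclude)
    base <- tibble(
      exposure_id = id, outcome_id = trait_id(outcome),
      n_total = prep$counts$n_total, n_pval = prep$counts$n_pval,
      n_clump = prep$counts$n_clump,
      n_harmonized = prep$counts$n_harmonized %||% 0L,
      n_steiger = prep$counts$n_steiger %||% 0L,
      n_snp = prep$counts$n_final %||% 0L
    )
    if (is.null(prep$h)) {
      return(mutate(base, status = "no_instruments",
                    beta_ivw = NA_real_, se_ivw = NA_real_, pval_ivw = NA_real_,
                    or_ivw = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
                    ivw_model = NA_character_, q_pval = NA_real_, i2 = NA_real_,
                    beta_egger = NA_real_, egger_intercept_pval = NA_real_,
                    beta_wmedian = NA_real_, pval_wmedian = NA_real_,
                    beta_presso = NA_real_, presso_global_pval = NA_real_,
                    presso_n_outliers = NA_integer_,
                    concordant = NA, loo_stable = NA, passes = FALSE,
                    fits = list(NULL)))
    }
    fits <- fit_suite(prep$h, cfg, seeds[i])
    k <- nrow(prep$h)
    gates <- if (k >= 3) {
      triple_concordance(
        list(ivw = fits$ivw, weighted_median = fits$weighted_median,
             presso_corrected = fits$presso_corrected),
        fits$loo, screen_alpha = cfg$screen_alpha, strict = cfg$strict_loo
      )
    } else {
      list(concordant = NA, loo_stable = NA)
    }
    status <- if (k >= 3) "screened" else "insufficient_instruments"
    passes <- isTRUE(gates$concordant) && isTRUE(gates$loo_stable) &&
      fits$ivw$pval < cfg$screen_alpha
    mutate(
      base, status = status,
      beta_ivw = fits$ivw$beta, se_ivw = fits$ivw$se, pval_ivw = fits$ivw$pval,
      or_ivw = fits$ivw$or, or_ci_low = fits$ivw$ci_low,
      or_ci_high = fits$ivw$ci_high,
      ivw_model = fits$ivw$method, q_pval = fits$ivw$q_pval, i2 = fits$ivw$i2,
      beta_egger = if (is.null(fits$egger)) NA_real_ else fits$egger$beta,
      egger_intercept_pval = if (is.null(fits$egger)) NA_real_ else fits$egger$egger_intercept_pval,
      beta_wmedian = if (is.null(fits$weighted_median)) NA_real_ else fits$weighted_median$beta,
      pval_wmedian = if (is.null(fits$weighted_median)) NA_real_ else fits$weighted_median$pval,
      beta_presso = fits$presso_corrected$beta,
      presso_global_pval = if (is.null(fits$presso)) NA_real_ else fits$presso$global_pval,
      presso_n_outliers = if (is.null(fits$presso)) NA_integer_ else length(fits$presso$outliers),
      concordant = gates$concordant, loo_stable = gates$loo_stable,
      passes = passes, fits = list(fits)
    )
  })
  out <- list_rbind(unname(rows))
  out$pval_bonferroni <- bonferroni(out$pval_ivw, m = m)
  out$bonferroni_significant <- !is.na(out$pval_bonferroni) &
    out$pval_bonferroni < cfg$screen_alpha
  out
}

#' Reverse-direction screen (outcome as exposure)
#'
#' Re-runs [mr_screen()] with roles swapped: instruments are drawn from the
#' outcome GWAS and tested against each original exposure, probing reverse
#' causality.
#'
#' @param outcome_as_exposure The outcome `sumstats` table, now treated as
#'   the exposure.
#' @param targets Named list of `sumstats` tables to screen against.
#' @inheritParams mr_screen
#' @return A tibble as in [mr_screen()], one row per target.
#' @export
reverse_screen <- function(outcome_as_exposure, targets, cfg, ld = NULL,
                           exclude = character()) {
  if (inherits(targets, "sumstats")) targets <- list(targets)
  if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
    names(targets) <- vapply(targets, trait_id, character(1))
  }
  rows <- imap(targets, function(tgt, id) {
    mr_screen(setNames(list(outcome_as_exposure), trait_id(outcome_as_exposure)),
              tgt, cfg, ld = ld, exclude = exclude)
  })
  list_rbind(unname(rows))
}

#' Mediator screen
#'
#' [mr_screen()] applied to a candidate-mediator panel against the outcome;
#' the pass gate (IVW significance plus concordance and leave-one-out
#' stability, with MR-PRESSO outlier correction feeding the concordance
#' check) selects mediators carried into mediation analysis.
#'
#' @param mediators Named list of `sumstats` tables.
#' @inheritParams mr_screen
#' @return A tibble as in [mr_screen()].
#' @export
mediator_screen <- function(mediators, outcome, cfg, ld = NULL,
                            exclude = character()) {
  mr_screen(mediators, outcome, cfg, ld = ld, exclude = exclude)
}
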