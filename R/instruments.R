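#' Select instrument candidates by p-value threshold
#'
#' Strict inequality: a variant at exactly the threshold is not selected.
#'
#' @param table A `sumstats` tibble.
#' @param threshold Selection p-value; default `1e-5`, the conventional
#'   relaxed threshold for molecular-trait instruments.
#' @return The subset with `pval < threshold`, order preserved.
#' @export
select_by_pvalue <- function(table, threshold = 1e-5) {
  keep <- table$pval < threshold
  out <- table[keep, , drop = FALSE]
  attributes(out)[c("trait_id", "trait_type")] <-
    attributes(table)[c("trait_id", "trait_type")]
  out
}

#' Greedy LD clumping
#'
#' Repeatedly takes the lowest-p unclaimed variant as an index and removes
#' all unclaimed variants on the same chromosome within `window_kb` of it
#' whose pairwise r^2 with the index is at least `r2_max`. Ties in p are
#' broken by (chrom, pos, variant_id) so the result is reproducible. The
#' retained set is pairwise independent under `(r2_max, window_kb)`.
#'
#' @param table A `sumstats` tibble with `chrom` and `pos` populated.
#' @param ld An [ld_matrix()] covering (at least) the table's variants.
#' @param r2_max LD pruning threshold; default `0.001`.
#' @param window_kb Physical window in kilobases around each index variant,
#'   inclusive; default `1000`.
#' @param missing How to treat table variants absent from `ld`: drop with a
#'   warning (default) or error.
#' @return The clumped `sumstats` tibble, input row order preserved.
#' @export
clump <- function(table, ld, r2_max = 0.001, window_kb = 1000,
                  missing = c("drop", "error")) {
  missing <- match.arg(missing)
  stopifnot(inherits(ld, "ld_matrix"))
  validate_ld(ld$r2)
  absent <- setdiff(table$variant_id, ld$variant_ids)
  if (length(absent) > 0) {
    if (missing == "error") {
      abort(paste0("variants absent from LD matrix: ",
                   paste(head(absent, 10), collapse = ", ")),
            class = "mrmediation_validation_error")
    }
    warn(paste0(length(absent), " variant(s) absent from LD matrix dropped before clumping"))
  }
  work <- as_tibble(table)[!(table$variant_id %in% absent), , drop = FALSE]
  if (nrow(work) == 0) return(subset_sumstats(table, character(0)))
  if (anyNA(work$chrom) || anyNA(work$pos)) {
    abort("clumping requires chrom and pos on every variant",
          class = "mrmediation_validation_error")
  }

  ord <- order(work$pval, work$chrom, work$pos, work$variant_id)
  ids <- work$variant_id[ord]
  chrom <- work$chrom[ord]
  pos <- work$pos[ord]
  r2 <- ld$r2[ids, ids, drop = FALSE]
  window_bp <- window_kb * 1000

  state <- rep("unclaimed", length(ids))
  for (i in seq_along(ids)) {
    if (state[i] != "unclaimed") next
    state[i] <- "index"
    hit <- state == "unclaimed" &
      chrom == chrom[i] &
      abs(pos - pos[i]) <= window_bp &
      r2[i, ] >= r2_max
    state[hit] <- "removed"
  }
  subset_sumstats(table, ids[state == "index"])
}

subset_sumstats <- function(table, keep_ids) {
  out <- table[table$variant_id %in% keep_ids, , drop = FALSE]
  attributes(out)[c("trait_id", "trait_type")] <-
    attributes(table)[c("trait_id", "trait_type")]
  out
}

#' Variance in a trait explained by a single variant
#'
#' Computed from the observed association t-statistic,
#' `r2 = t^2 / (t^2 + n - 2)` with `t = beta / se`. This needs only fields
#' guaranteed present in a summary-statistic row and is exact for a
#' continuous trait fitted by least squares; for binary traits on the
#' log-odds scale it is the analogous pseudo-variance share.
#'
#' @param beta,se,n Effect estimates, standard errors and sample sizes
#'   (vectorized).
#' @return Proportions in `[0, 1)`.
#' @examples
#' variance_explained(0.1, 0.02, 10000)  # t = 5 -> 25 / 10023
#' @export
variance_explained <- function(beta, se, n) {
  if (any(n <= 2, na.rm = TRUE)) {
    abort("variance_explained requires n > 2", class = "mrmediation_domain_error")
  }
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Instrument-strength F statistic
#'
#' `F = r2 * (n - 2) / (1 - r2)`; values below 10 conventionally flag weak
#' instruments.
#'
#' @param r2 Proportion of trait variance explained, in `[0, 1)`.
#' @param n Sample size, `> 2`.
#' @return Non-negative F values (vectorized).
#' @export
f_statistic <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1, na.rm = TRUE)) {
    abort("f_statistic requires 0 <= r2 < 1", class = "mrmediation_domain_error")
  }
  if (any(n <= 2, na.rm = TRUE)) {
    abort("f_statistic requires n > 2", class = "mrmediation_domain_error")
  }
  r2 * (n - 2) / (1 - r2)
}

#' Annotate a table with per-variant r^2 and F statistic
#'
#' @param table A `sumstats` tibble.
#' @return The table with `r2_explained` and `f_stat` columns added.
#' @export
add_instrument_stats <- function(table) {
  out <- mutate(
    as_tibble(table),
    r2_explained = variance_explained(.data$beta, .data$se, .data$n),
    f_stat = f_statistic(.data$r2_explained, .data$n)
  )
  attributes(out)[c("trait_id", "trait_type")] <-
    attributes(table)[c("trait_id", "trait_type")]
  class(out) <- class(table)
  out
}

#' Drop weak instruments by F statistic
#'
#' Retains records with `f_stat >= f_min` (the boundary value is kept) and
#' reports the removed ids.
#'
#' @param table A `sumstats` tibble; `f_stat` is computed on the fly via
#'   [add_instrument_stats()] when absent.
#' @param f_min Minimum F; default 10.
#' @return The filtered table.
#' @export
filter_weak <- function(table, f_min = 10) {
  if (!"f_stat" %in% names(table)) table <- add_instrument_stats(table)
  weak <- table$f_stat < f_min
  if (any(weak)) {
    inform(paste0(
      sum(weak), " weak instrument(s) removed (F < ", f_min, "): ",
      paste(head(table$variant_id[weak], 10), collapse = ", ")
    ))
  }
  subset_sumstats(table, table$variant_id[!weak])
}

#' Steiger directionality filter
#'
#' For every harmonized variant, compares the variance explained in the
#' exposure against the outcome through a z-test on the difference of
#' Fisher-transformed correlations `r = sqrt(r2)` (variances `1/(n - 3)`).
#' A variant is excluded only when the outcome-side r^2 exceeds the
#' exposure-side r^2 *and* the difference is significant at `alpha`; a
#' non-significant reversal is retained.
#'
#' @param h A `harmonized` tibble with `n_exp` and `n_out` populated.
#' @param alpha Significance level for the directionality test; default 0.05.
#' @return The filtered `harmonized` tibble, with the per-variant test
#'   results attached as attribute `"steiger"` (see [steiger_results()]).
#' @export
steiger_filter <- function(h, alpha = 0.05) {
  usable <- is.finite(h$n_exp) & is.finite(h$n_out) & h$n_exp > 3 & h$n_out > 3
  if (any(!usable)) {
    warn(paste0(sum(!usable),
                " row(s) dropped from Steiger filtering (n missing or <= 3): ",
                paste(head(h$variant_id[!usable], 10), collapse = ", ")))
  }
  hh <- h[usable, , drop = FALSE]
  r2_exp <- variance_explained(hh$beta_exp, hh$se_exp, hh$n_exp)
  r2_out <- variance_explained(hh$beta_out, hh$se_out, hh$n_out)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (hh$n_exp - 3) + 1 / (hh$n_out - 3))
  p <- two_sided_p(z)
  p[z == 0] <- 1
  res <- tibble(
    variant_id = hh$variant_id,
    r2_exposure = r2_exp,
    r2_outcome = r2_out,
    z = z,
    p = p,
    direction_ok = r2_exp > r2_out,
    excluded = r2_out > r2_exp & p < alpha
  )
  out <- subset_harmonized(h, which(usable)[!res$excluded])
  attr(out, "steiger") <- res
  out
}

#' Per-variant Steiger directionality results
#' @param h The output of [steiger_filter()].
#' @return A tibble with one row per tested variant: exposure/outcome r^2,
#'   the z statistic, its p-value, `direction_ok` and `excluded`.
#' @export
steiger_results <- function(h) {
  attr(h, "steiger") %||%
    abort("no Steiger results attached; run steiger_filter() first")
}
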