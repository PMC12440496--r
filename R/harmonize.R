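dna_complement <- function(a) chartr("ACGT", "TGCA", a)

is_simple_snp <- function(a) !is.na(a) & nchar(a) == 1L & a %in% c("A", "C", "G", "T")

#' Harmonize exposure and outcome summary statistics
#'
#' Places exposure and outcome effects for every shared variant on a single
#' effect-allele frame (the exposure's coding). Outcome rows coded on the
#' swapped allele have their beta sign-flipped and frequency mirrored;
#' non-palindromic rows that match only after strand complement are
#' complemented first. Palindromic variants (A/T, C/G) cannot be oriented
#' from allele labels: they are aligned by allele frequency when both
#' frequencies are informative, and dropped when either minor allele
#' frequency falls inside `palindrome_maf_window` (endpoints inclusive) or
#' is missing. Indels, multi-allelic records and irreconcilable allele pairs
#' are dropped as incompatible.
#'
#' @param exposure,outcome `sumstats` tables (see [sumstats()]).
#' @param palindrome_maf_window Closed effect-allele-frequency interval in
#'   which palindromic variants are considered ambiguous; default
#'   `c(0.40, 0.60)`, i.e. minor allele frequency 0.40-0.50 on either side.
#' @return A tibble of class `harmonized` with columns `variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `beta_exp`, `se_exp`,
#'   `eaf_exp`, `n_exp`, `beta_out`, `se_out`, `eaf_out`, `n_out`, `action`;
#'   only retained rows appear. The full per-variant audit (one row per
#'   shared variant, including dropped ones) is available through
#'   [harmonization_audit()].
#' @examples
#' exp <- sumstats(data.frame(variant_id = "rs1", effect_allele = "A",
#'   other_allele = "G", eaf = 0.3, beta = 0.1, se = 0.02, pval = 1e-7,
#'   n = 10000), "x")
#' out <- sumstats(data.frame(variant_id = "rs1", effect_allele = "G",
#'   other_allele = "A", eaf = 0.7, beta = -0.05, se = 0.01, pval = 1e-4,
#'   n = 20000), "y")
#' harmonize(exp, out)  # outcome beta flipped to +0.05, eaf to 0.3
#' @export
harmonize <- function(exposure, outcome, palindrome_maf_window = c(0.40, 0.60)) {
  validate_sumstats(exposure)
  validate_sumstats(outcome)
  stopifnot(length(palindrome_maf_window) == 2, palindrome_maf_window[1] <= palindrome_maf_window[2])

  ex <- as_tibble(exposure)
  ou <- as_tibble(outcome)
  names(ou) <- paste0(names(ou), "_out")
  shared <- inner_join(ex, ou, by = c(variant_id = "variant_id_out"))
  if (nrow(shared) == 0) {
    abort(
      "no shared variant ids between exposure and outcome (check id schemes / genome builds)",
      class = "mrmediation_empty_overlap_error"
    )
  }

  ea_e <- shared$effect_allele
  oa_e <- shared$other_allele
  ea_o <- shared$effect_allele_out
  oa_o <- shared$other_allele_out

  valid <- is_simple_snp(ea_e) & is_simple_snp(oa_e) &
    is_simple_snp(ea_o) & is_simple_snp(oa_o)
  palindromic <- valid & ea_e == dna_complement(oa_e)

  same  <- valid & ea_o == ea_e & oa_o == oa_e
  swap  <- valid & ea_o == oa_e & oa_o == ea_e
  csame <- valid & dna_complement(ea_o) == ea_e & dna_complement(oa_o) == oa_e
  cswap <- valid & dna_complement(ea_o) == oa_e & dna_complement(oa_o) == ea_e

  action <- rep("dropped_incompatible", nrow(shared))
  flip <- rep(FALSE, nrow(shared))

  np <- !palindromic
  action[np & (same | csame)] <- "kept"
  action[np & !same & !csame & (swap | cswap)] <- "flipped"
  flip[np & !same & !csame & (swap | cswap)] <- TRUE

  # Palindromes: labels cannot fix strand; orientation comes from frequency.
  pal_pair_ok <- palindromic & (same | swap | csame | cswap)
  maf <- function(f) pmin(f, 1 - f)
  in_window <- function(f) {
    !is.na(f) & f >= palindrome_maf_window[1] & f <= palindrome_maf_window[2]
  }
  ambiguous <- pal_pair_ok & (
    is.na(shared$eaf) | is.na(shared$eaf_out) |
      in_window(shared$eaf) | in_window(1 - shared$eaf) |
      in_window(shared$eaf_out) | in_window(1 - shared$eaf_out)
  )
  action[ambiguous] <- "dropped_palindrome_maf"
  aligned <- pal_pair_ok & !ambiguous
  action[aligned] <- "palindrome_aligned"
  flip[aligned] <- (shared$eaf[aligned] - 0.5) * (shared$eaf_out[aligned] - 0.5) < 0

  incomplete <- !complete.cases(shared[c("beta", "se", "beta_out", "se_out")])
  action[incomplete] <- "dropped_missing"

  audit <- tibble(variant_id = shared$variant_id, action = action)

  kept <- !startsWith(action, "dropped")
  rows <- shared[kept, , drop = FALSE]
  rflip <- flip[kept]
  rows$beta_out[rflip] <- -rows$beta_out[rflip]
  rows$eaf_out[rflip] <- 1 - rows$eaf_out[rflip]

  out <- tibble(
    variant_id    = rows$variant_id,
    chrom         = rows$chrom,
    pos           = rows$pos,
    effect_allele = rows$effect_allele,
    other_allele  = rows$other_allele,
    beta_exp      = rows$beta,
    se_exp        = rows$se,
    eaf_exp       = rows$eaf,
    n_exp         = rows$n,
    beta_out      = rows$beta_out,
    se_out        = rows$se_out,
    eaf_out       = rows$eaf_out,
    n_out         = rows$n_out,
    action        = action[kept]
  )
  attr(out, "exposure_id") <- trait_id(exposure)
  attr(out, "outcome_id") <- trait_id(outcome)
  attr(out, "audit") <- audit
  class(out) <- c("harmonized", class(out))
  out
}

#' Per-variant harmonization audit
#'
#' @param h A `harmonized` tibble from [harmonize()].
#' @return A tibble with one row per shared variant and its action label in
#'   `kept`, `flipped`, `palindrome_aligned`, `dropped_palindrome_maf`,
#'   `dropped_incompatible`, `dropped_missing`.
#' @export
harmonization_audit <- function(h) {
  attr(h, "audit") %||% tibble(variant_id = h$variant_id, action = h$action)
}

#' @export
print.harmonized <- function(x, ...) {
  cat(sprintf(
    "<harmonized> %s -> %s, %d variants retained (%d shared)\n",
    attr(x, "exposure_id") %||% "exposure",
    attr(x, "outcome_id") %||% "outcome",
    nrow(x), nrow(harmonization_audit(x))
  ))
  NextMethod()
}

# Keep harmonized attributes through a row subset.
subset_harmonized <- function(h, keep) {
  out <- h[keep, , drop = FALSE]
  for (a in c("exposure_id", "outcome_id", "audit")) attr(out, a) <- attr(h, a)
  if (!inherits(out, "harmonized")) class(out) <- c("harmonized", class(out))
  out
}

# Build a harmonized set directly from effect-size vectors (used by the
# synthetic generators and tests, where both tables share one allele frame).
harmonized_set <- function(variant_id, beta_exp, se_exp, beta_out, se_out,
                           eaf_exp = NA_real_, n_exp = NA_integer_,
                           eaf_out = NA_real_, n_out = NA_integer_,
                           exposure_id = "exposure", outcome_id = "outcome") {
  out <- tibble(
    variant_id = as.character(variant_id),
    chrom = NA_character_, pos = NA_integer_,
    effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = se_exp,
    eaf_exp = eaf_exp, n_exp = as.integer(n_exp),
    beta_out = beta_out, se_out = se_out,
    eaf_out = eaf_out, n_out = as.integer(n_out),
    action = "kept"
  )
  attr(out, "exposure_id") <- exposure_id
  attr(out, "outcome_id") <- outcome_id
  attr(out, "audit") <- tibble(variant_id = out$variant_id, action = "kept")
  class(out) <- c("harmonized", class(out))
  out
}
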