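test_that("TSV parsing handles canonical and remapped headers identically", {
  df <- example_records()
  f1 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(df, f1)
  t1 <- read_sumstats(f1, trait_id = "x")
  expect_s3_class(t1, "sumstats")
  expect_equal(nrow(t1), 3)
  expect_equal(t1$variant_id, df$variant_id)
  expect_equal(t1$beta, df$beta)

  df2 <- dplyr::rename(df, SNP = variant_id, BETA = beta, SE = se, P = pval)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(df2, f2)
  t2 <- read_sumstats(
    f2, column_map = c(variant_id = "SNP", beta = "BETA", se = "SE", pval = "P"),
    trait_id = "x"
  )
  expect_equal(as.data.frame(t2), as.data.frame(t1))
})

test_that("invalid rows are rejected with row-indexed diagnostics", {
  df <- example_records()
  df$se[2] <- 0
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(df, f)
  expect_error(read_sumstats(f), class = "mrmediation_validation_error")
  expect_error(read_sumstats(f), "row\\(s\\): 2")

  df <- example_records()
  df$pval[3] <- 0
  expect_error(sumstats(df), "pval outside")

  df <- example_records()
  df$variant_id[2] <- "rs1"
  expect_error(sumstats(df), "duplicate variant_id")

  expect_error(
    read_sumstats({
      f <- withr::local_tempfile(fileext = ".tsv")
      readr::write_tsv(example_records()[, -1], f)
      f
    }),
    class = "mrmediation_format_error"
  )
})

test_that("write/read round-trips tables field for field", {
  t0 <- sumstats(example_records()[0, ], trait_id = "empty")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(t0, f)
  expect_length(readLines(f), 1)  # header only

  t3 <- sumstats(example_records(), trait_id = "x")
  write_sumstats(t3, f)
  expect_length(readLines(f), 4)

  set.seed(42)
  k <- 100
  big <- sumstats(tibble::tibble(
    variant_id = paste0("rs", 1:k),
    chrom = as.character(sample(1:22, k, TRUE)),
    pos = sample.int(1e8, k),
    effect_allele = sample(c("A", "C"), k, TRUE),
    other_allele = sample(c("G", "T"), k, TRUE),
    eaf = runif(k),
    beta = rnorm(k) / 7,
    se = runif(k, 1e-4, 0.1),
    pval = runif(k),
    n = sample.int(5e5, k)
  ), trait_id = "big")
  write_sumstats(big, f)
  back <- read_sumstats(f, trait_id = "big")
  expect_equal(as.data.frame(back), as.data.frame(big))
})

test_that("exclusion lists are a pure set difference, order preserved", {
  t3 <- sumstats(example_records(), trait_id = "x")
  expect_equal(apply_exclusion_list(t3, character(0))$variant_id, t3$variant_id)
  expect_equal(nrow(apply_exclusion_list(t3, t3$variant_id)), 0)
  expect_equal(apply_exclusion_list(t3, c("rs2"))$variant_id, c("rs1", "rs3"))
})

test_that("harmonization handles orientation, strand and palindromes", {
  exp_tbl <- sumstats(tibble::tibble(
    variant_id = c("same", "swapped", "strand", "strand_swap",
                   "pal_ambig", "pal_ok", "pal_na", "indel", "mismatch"),
    effect_allele = c("A", "A", "A", "A", "A", "A", "A", "AT", "A"),
    other_allele  = c("G", "G", "G", "G", "T", "T", "T", "A", "G"),
    eaf = c(0.3, 0.3, 0.3, 0.3, 0.45, 0.10, 0.10, 0.3, 0.3),
    beta = 0.10, se = 0.02, pval = 1e-7, n = 10000L
  ), trait_id = "exp")
  out_tbl <- sumstats(tibble::tibble(
    variant_id = c("same", "swapped", "strand", "strand_swap",
                   "pal_ambig", "pal_ok", "pal_na", "indel", "mismatch"),
    effect_allele = c("A", "G", "T", "C", "A", "T", "A", "AT", "A"),
    other_allele  = c("G", "A", "C", "T", "T", "A", "T", "A", "C"),
    eaf = c(0.3, 0.7, 0.3, 0.7, 0.44, 0.12, NA, 0.3, 0.3),
    beta = c(0.05, -0.05, 0.05, -0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
    se = 0.01, pval = 1e-4, n = 20000L
  ), trait_id = "out")

  h <- harmonize(exp_tbl, out_tbl)
  audit <- harmonization_audit(h)
  act <- setNames(audit$action, audit$variant_id)
  expect_equal(act[["same"]], "kept")
  expect_equal(act[["swapped"]], "flipped")
  expect_equal(act[["strand"]], "kept")
  expect_equal(act[["strand_swap"]], "flipped")
  expect_equal(act[["pal_ambig"]], "dropped_palindrome_maf")
  expect_equal(act[["pal_ok"]], "palindrome_aligned")
  expect_equal(act[["pal_na"]], "dropped_palindrome_maf")
  expect_equal(act[["indel"]], "dropped_incompatible")
  expect_equal(act[["mismatch"]], "dropped_incompatible")

  row <- h[h$variant_id == "swapped", ]
  expect_equal(row$beta_out, 0.05)
  expect_equal(row$eaf_out, 0.3)
  # palindrome aligned by frequency: both minor on the same side, kept as is
  expect_equal(h$beta_out[h$variant_id == "pal_ok"], 0.05)

  # conservation: every shared id is accounted for exactly once
  expect_setequal(audit$variant_id, exp_tbl$variant_id)
  expect_equal(nrow(h) + sum(startsWith(audit$action, "dropped")), nrow(audit))
})

test_that("palindrome window endpoints are ambiguous (inclusive)", {
  mk <- function(eaf_e, eaf_o) {
    e <- sumstats(tibble::tibble(variant_id = "p", effect_allele = "A",
                                 other_allele = "T", eaf = eaf_e, beta = 0.1,
                                 se = 0.02, pval = 1e-7, n = 1000L))
    o <- sumstats(tibble::tibble(variant_id = "p", effect_allele = "A",
                                 other_allele = "T", eaf = eaf_o, beta = 0.05,
                                 se = 0.01, pval = 1e-3, n = 1000L))
    harmonization_audit(harmonize(e, o))$action
  }
  expect_equal(mk(0.40, 0.1), "dropped_palindrome_maf")
  expect_equal(mk(0.60, 0.1), "dropped_palindrome_maf")
  expect_equal(mk(0.1, 0.60), "dropped_palindrome_maf")
  expect_equal(mk(0.399, 0.1), "palindrome_aligned")
})

test_that("palindromes on opposite frequency sides are sign-flipped", {
  e <- sumstats(tibble::tibble(variant_id = "p", effect_allele = "A",
                               other_allele = "T", eaf = 0.1, beta = 0.1,
                               se = 0.02, pval = 1e-7, n = 1000L))
  o <- sumstats(tibble::tibble(variant_id = "p", effect_allele = "A",
                               other_allele = "T", eaf = 0.88, beta = 0.05,
                               se = 0.01, pval = 1e-3, n = 1000L))
  h <- harmonize(e, o)
  expect_equal(h$action, "palindrome_aligned")
  expect_equal(h$beta_out, -0.05)
  expect_equal(h$eaf_out, 0.12)
})

test_that("harmonization is idempotent and flipping is an involution", {
  set.seed(7)
  k <- 40
  base <- tibble::tibble(
    variant_id = paste0("rs", 1:k),
    effect_allele = sample(c("A", "C"), k, TRUE),
    other_allele = NA_character_,
    eaf = runif(k, 0.05, 0.95),
    beta = rnorm(k, 0, 0.05),
    se = runif(k, 0.005, 0.05),
    pval = runif(k),
    n = 50000L
  )
  base$other_allele <- ifelse(base$effect_allele == "A", "G", "T")
  e <- sumstats(base, trait_id = "e")
  o_df <- base
  flip_idx <- seq(1, k, by = 2)
  o_df$beta <- rnorm(k, 0, 0.05)
  o_df[flip_idx, c("effect_allele", "other_allele")] <-
    o_df[flip_idx, c("other_allele", "effect_allele")]
  o_df$beta[flip_idx] <- -o_df$beta[flip_idx]
  o_df$eaf[flip_idx] <- 1 - o_df$eaf[flip_idx]
  o <- sumstats(o_df, trait_id = "o")

  h1 <- harmonize(e, o)
  expect_true(all(h1$action[flip_idx] == "flipped"))

  # rebuild the outcome on the harmonized frame and harmonize again:
  # nothing may change (idempotence)
  o2 <- sumstats(tibble::tibble(
    variant_id = h1$variant_id, effect_allele = h1$effect_allele,
    other_allele = h1$other_allele, eaf = h1$eaf_out, beta = h1$beta_out,
    se = h1$se_out, pval = o_df$pval, n = h1$n_out
  ), trait_id = "o")
  h2 <- harmonize(e, o2)
  expect_true(all(h2$action == "kept"))
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$eaf_out, h1$eaf_out)

  # double-flip involution restores the original coding (sign exactly;
  # the frequency mirror only up to one floating-point rounding)
  expect_identical(-(-o_df$beta), o_df$beta)
  expect_equal(1 - (1 - o_df$eaf), o_df$eaf, tolerance = 1e-15)
})

test_that("empty variant overlap raises a dedicated error", {
  e <- sumstats(example_records(), trait_id = "e")
  o_df <- example_records()
  o_df$variant_id <- paste0("chr", o_df$variant_id)
  o <- sumstats(o_df, trait_id = "o")
  expect_error(harmonize(e, o), class = "mrmediation_empty_overlap_error")
})
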