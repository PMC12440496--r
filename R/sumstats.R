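#' Construct a validated GWAS summary-statistic table
#'
#' A summary-statistic table holds one row per variant for one trait, in
#' canonical columns: `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`. Effects (`beta`) are
#' per copy of the effect allele, on the log-odds scale for binary traits
#' and in standard-deviation units for continuous traits.
#'
#' @param x A data frame with at least `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`, `n`. `chrom`, `pos`, `eaf` are
#'   optional and filled with `NA` when absent.
#' @param trait_id Label for the trait the table describes.
#' @param trait_type `"continuous"` or `"binary"`.
#' @return A tibble of class `sumstats` with `trait_id`/`trait_type`
#'   attributes, rows in the input order.
#' @examples
#' ss <- sumstats(
#'   data.frame(variant_id = "rs1", effect_allele = "A", other_allele = "G",
#'              eaf = 0.2, beta = 0.1, se = 0.02, pval = 1e-7, n = 10000),
#'   trait_id = "trait", trait_type = "continuous")
#' @export
sumstats <- function(x, trait_id = "trait", trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  x <- as_tibble(x)
  mandatory <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pval", "n")
  missing_cols <- setdiff(mandatory, names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
      class = "mrmediation_format_error"
    )
  }
  for (opt in c("chrom", "pos", "eaf")) {
    if (!opt %in% names(x)) x[[opt]] <- NA
  }
  out <- tibble(
    variant_id    = as.character(x$variant_id),
    chrom         = as.character(x$chrom),
    pos           = as.integer(x$pos),
    effect_allele = toupper(as.character(x$effect_allele)),
    other_allele  = toupper(as.character(x$other_allele)),
    eaf           = as.numeric(x$eaf),
    beta          = as.numeric(x$beta),
    se            = as.numeric(x$se),
    pval          = as.numeric(x$pval),
    n             = as.integer(round(as.numeric(x$n)))
  )
  validate_sumstats(out)
  attr(out, "trait_id") <- trait_id
  attr(out, "trait_type") <- trait_type
  class(out) <- c("sumstats", class(out))
  out
}

validate_sumstats <- function(x) {
  bad <- function(cond) which(!is.na(cond) & cond)
  problems <- list(
    "se <= 0 or missing"        = which(!(is.finite(x$se) & x$se > 0)),
    "pval outside (0, 1]"       = which(!(is.finite(x$pval) & x$pval > 0 & x$pval <= 1)),
    "beta missing"              = which(!is.finite(x$beta)),
    "n not a positive integer"  = which(!(is.finite(x$n) & x$n >= 1)),
    "eaf outside [0, 1]"        = bad(x$eaf < 0 | x$eaf > 1),
    "effect_allele == other_allele" = bad(x$effect_allele == x$other_allele),
    "missing variant_id"        = which(is.na(x$variant_id) | x$variant_id == "")
  )
  problems <- problems[lengths(problems) > 0]
  if (length(problems) > 0) {
    msg <- vapply(seq_along(problems), function(i) {
      rows <- problems[[i]]
      shown <- paste(head(rows, 10), collapse = ", ")
      if (length(rows) > 10) shown <- paste0(shown, ", ...")
      paste0(names(problems)[i], " at row(s): ", shown)
    }, character(1))
    abort(
      c("invalid summary-statistic rows:", msg),
      class = "mrmediation_validation_error"
    )
  }
  dup <- unique(x$variant_id[duplicated(x$variant_id)])
  if (length(dup) > 0) {
    abort(
      paste0("duplicate variant_id: ", paste(head(dup, 10), collapse = ", ")),
      class = "mrmediation_validation_error"
    )
  }
  invisible(x)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf(
    "<sumstats> trait '%s' (%s), %d variants\n",
    trait_id(x), trait_type(x), nrow(x)
  ))
  NextMethod()
}

#' Trait metadata of a summary-statistic table
#' @param x A `sumstats` table.
#' @return A length-one character vector.
#' @export
trait_id <- function(x) attr(x, "trait_id") %||% "trait"

#' @rdname trait_id
#' @export
trait_type <- function(x) attr(x, "trait_type") %||% "continuous"

canonical_columns <- c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pval", "n"
)

#' Read GWAS summary statistics from a tab-separated file
#'
#' Expects a header line; non-canonical headers (e.g. the GWAS-SSF spellings
#' `rsid`, `beta`, `standard_error`) are accepted through `column_map`.
#'
#' @param path Path to a TSV file.
#' @param column_map Optional named character vector mapping canonical field
#'   names to the file's headers, e.g. `c(se = "SE", beta = "BETA")`.
#'   Unmapped canonical names are looked up verbatim.
#' @param trait_type,trait_id Passed to [sumstats()].
#' @return A validated `sumstats` tibble, rows in file order.
#' @export
read_sumstats <- function(path, column_map = NULL,
                          trait_type = c("continuous", "binary"),
                          trait_id = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "mrmediation_io_error")
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  if (!is.null(column_map)) {
    bad_map <- setdiff(unname(column_map), names(raw))
    if (length(bad_map) > 0) {
      abort(
        paste0("column_map refers to absent header(s): ",
               paste(bad_map, collapse = ", ")),
        class = "mrmediation_format_error"
      )
    }
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  keep <- intersect(canonical_columns, names(raw))
  sumstats(raw[keep],
           trait_id = trait_id %||% tools::file_path_sans_ext(basename(path)),
           trait_type = trait_type)
}

#' Write a summary-statistic table as TSV
#'
#' Floats are serialized with shortest round-trip precision, so
#' `read_sumstats(write_sumstats(x, f))` reproduces `x` field for field.
#'
#' @param table A `sumstats` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  validate_sumstats(table)
  out <- as_tibble(table)[intersect(canonical_columns, names(table))]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Remove variants named on an exclusion list
#'
#' Consumes the result of an external confounder lookup (e.g. variants with
#' genome-wide significant associations to known confounders) as a plain set
#' of variant ids; the lookup itself is outside this package.
#'
#' @param table A `sumstats` tibble.
#' @param excluded_ids Character vector of variant ids to drop.
#' @return The table without the listed variants, order preserved.
#' @export
apply_exclusion_list <- function(table, excluded_ids) {
  keep <- !(table$variant_id %in% excluded_ids)
  out <- table[keep, , drop = FALSE]
  attributes(out)[c("trait_id", "trait_type")] <-
    attributes(table)[c("trait_id", "trait_type")]
  out
}

#' Read an exclusion list (one variant id per line)
#' @param path Path to a text file.
#' @return Character vector of variant ids.
#' @export
read_exclusion_list <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids[nzchar(trimws(ids))]
}
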