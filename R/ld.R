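#' Construct a pairwise LD (r-squared) matrix
#'
#' @param r2 A square numeric matrix of pairwise LD r^2 with variant ids as
#'   dimnames, symmetric with unit diagonal and values in `[0, 1]`.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2) {
  r2 <- as.matrix(r2)
  if (is.null(rownames(r2)) && !is.null(colnames(r2))) rownames(r2) <- colnames(r2)
  if (is.null(colnames(r2)) && !is.null(rownames(r2))) colnames(r2) <- rownames(r2)
  validate_ld(r2)
  structure(list(r2 = r2, variant_ids = rownames(r2)), class = "ld_matrix")
}

validate_ld <- function(r2) {
  if (nrow(r2) != ncol(r2) || is.null(rownames(r2))) {
    abort("LD matrix must be square with variant ids as dimnames",
          class = "mrmediation_validation_error")
  }
  if (!isTRUE(all.equal(rownames(r2), colnames(r2)))) {
    abort("LD matrix row/column ids disagree", class = "mrmediation_validation_error")
  }
  if (max(abs(r2 - t(r2))) > 1e-8) {
    abort("LD matrix is not symmetric", class = "mrmediation_validation_error")
  }
  if (max(abs(diag(r2) - 1)) > 1e-8) {
    abort("LD matrix diagonal must be 1", class = "mrmediation_validation_error")
  }
  if (min(r2) < -1e-12 || max(r2) > 1 + 1e-12) {
    abort("LD r^2 values must lie in [0, 1]", class = "mrmediation_validation_error")
  }
  invisible(r2)
}

#' Read a pairwise LD matrix from TSV
#'
#' Two layouts are supported: `"square"`, a full matrix whose first column
#' holds variant ids and whose header repeats them; and `"long"`, triplets
#' `id1 <tab> id2 <tab> r2` with unlisted pairs taken as r^2 = 0.
#'
#' @param path Path to the TSV file.
#' @param format `"square"` or `"long"`.
#' @return An `ld_matrix` object.
#' @export
read_ld_matrix <- function(path, format = c("square", "long")) {
  format <- match.arg(format)
  if (format == "square") {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    ids <- as.character(raw[[1]])
    m <- as.matrix(raw[-1])
    rownames(m) <- ids
    colnames(m) <- names(raw)[-1]
    return(ld_matrix(m))
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_names = c("id1", "id2", "r2"), skip = 1)
  ids <- sort(unique(c(raw$id1, raw$id2)))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(raw$id1, raw$id2)] <- raw$r2
  m[cbind(raw$id2, raw$id1)] <- raw$r2
  diag(m) <- 1
  ld_matrix(m)
}

#' Write an LD matrix as a square TSV
#' @param ld An `ld_matrix`.
#' @param path Output path.
#' @export
write_ld_matrix <- function(ld, path) {
  out <- as_tibble(ld$r2)
  out <- dplyr::bind_cols(tibble(variant_id = ld$variant_ids), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
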