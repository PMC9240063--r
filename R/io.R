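#' Read a gene-expression matrix from TSV
#'
#' Expects a wide table whose first column holds gene symbols and whose header
#' row holds sample identifiers (normalized expression values, e.g. TMM/TPM on
#' a log scale; normalization is assumed to have happened upstream).
#'
#' @param path Path to a tab-delimited file.
#' @return A numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames).
#' @export
read_expression_tsv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  assert_that(ncol(dt) >= 2, sprintf("expression file '%s' needs a gene column and at least one sample", path))
  genes <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  validate_expression(m)
  m
}

#' Write a genes-by-samples (or pathways-by-samples) matrix as TSV
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Name for the first (identifier) column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression <- function(m) {
  assert_that(!anyDuplicated(rownames(m)), "duplicate gene identifiers in expression matrix")
  assert_that(!anyDuplicated(colnames(m)), "duplicate sample identifiers in expression matrix")
  assert_that(all(is.finite(m)), "expression matrix contains non-finite values")
  invisible(m)
}

#' Read a per-sample clinical table
#'
#' Expected columns: `sample`, and any of `recist` (CR/PR/SD/PD), `response`
#' (1 = responder, 0 = non-responder), `os_time`, `os_event`, `pfs_time`,
#' `pfs_event`. When `recist` is present and `response` is not, responses are
#' derived with [recist_to_response()].
#'
#' @param path Path to a tab-delimited file with a header.
#' @return A data.frame with one row per sample.
#' @export
read_clinical_tsv <- function(path) {
  df <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  assert_that("sample" %in% names(df), sprintf("clinical file '%s' lacks a 'sample' column", path))
  df$sample <- as.character(df$sample)
  assert_that(!anyDuplicated(df$sample), "duplicate sample identifiers in clinical table")
  if (!"response" %in% names(df) && "recist" %in% names(df)) {
    df$response <- recist_to_response(df$recist)
  }
  df
}

#' Map RECIST categories to binary response labels
#'
#' Complete (CR) and partial (PR) response are responders (1); stable (SD) and
#' progressive (PD) disease are non-responders (0). Pre-binarized `R`/`NR`
#' labels are passed through.
#'
#' @param recist Character vector of RECIST categories.
#' @return Integer vector of 0/1 labels.
#' @export
recist_to_response <- function(recist) {
  recist <- toupper(trimws(as.character(recist)))
  map <- c(CR = 1L, PR = 1L, SD = 0L, PD = 0L, R = 1L, NR = 0L)
  bad <- setdiff(unique(recist), names(map))
  assert_that(length(bad) == 0,
              sprintf("unknown RECIST categories: %s", paste(bad, collapse = ", ")))
  unname(map[recist])
}
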