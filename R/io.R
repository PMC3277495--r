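#' Read a gene table and derive relative gene lengths
#'
#' Reads a tab-separated table with header columns `gene_id` and `length`
#' (coding length; amino acids or nucleotides both work since only ratios
#' matter) and derives each gene's relative length `w` as its length
#' divided by the unweighted mean length of all genes in the table.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `gene_id`, `length`, `w`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tlength", "A\t100", "B\t300"), tf)
#' read_gene_table(tf)
#' @export
read_gene_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("gene_id", "length"), names(tbl))
  if (length(miss)) {
    stop("gene table ", path, " is missing columns: ", paste(miss, collapse = ", "))
  }
  if (!is.numeric(tbl$length)) stop("gene table column `length` must be numeric")
  bad <- which(!is.finite(tbl$length) | tbl$length <= 0)
  if (length(bad)) {
    stop(
      "non-positive gene length at line(s) ",
      paste(bad + 1L, collapse = ", "), " of ", path
    )
  }
  dup <- tbl$gene_id[duplicated(tbl$gene_id)]
  if (length(dup)) {
    stop("duplicate gene_id in ", path, ": ", paste(unique(dup), collapse = ", "))
  }
  tbl$gene_id <- as.character(tbl$gene_id)
  tbl$w <- tbl$length / mean(tbl$length)
  tibble::as_tibble(tbl[c("gene_id", "length", "w")])
}

#' Read a long-format per-patient per-gene mutation count table
#'
#' Reads a tab-separated file with header columns `patient_id`, `gene_id`,
#' `count`. Absent (patient, gene) pairs are implicitly zero. Duplicate
#' pairs are summed with a warning.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `patient_id`, `gene_id`, `count`.
#' @export
read_counts_long <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("patient_id", "gene_id", "count"), names(tbl))
  if (length(miss)) {
    stop("count table ", path, " is missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(tbl) == 0L) {
    return(tibble::tibble(
      patient_id = character(), gene_id = character(), count = integer()
    ))
  }
  if (!is.numeric(tbl$count) || any(tbl$count != floor(tbl$count))) {
    stop("count table column `count` must be integer-valued in ", path)
  }
  bad <- which(tbl$count < 0)
  if (length(bad)) {
    stop(
      "negative count at line(s) ", paste(bad + 1L, collapse = ", "),
      " of ", path
    )
  }
  tbl$patient_id <- as.character(tbl$patient_id)
  tbl$gene_id <- as.character(tbl$gene_id)
  key <- paste(tbl$patient_id, tbl$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (patient_id, gene_id) pairs in ", path, "; counts summed")
    tbl <- tbl |>
      dplyr::group_by(.data$patient_id, .data$gene_id) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
  }
  tibble::as_tibble(tbl[c("patient_id", "gene_id", "count")])
}

#' Write a mutation count table to TSV
#'
#' @param counts Long-format count table.
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_counts_long <- function(counts, path) {
  counts <- validate_counts(counts)
  readr::write_tsv(counts, path)
  invisible(counts)
}
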