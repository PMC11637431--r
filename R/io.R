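# Plain-text readers and writers. Count and protein tables travel as TSV
# (first column = gene/protein id, header = sample ids) with a sidecar
# sample-metadata TSV (sample_id, subject, species, compartment, zone).

#' Read a gene x sample count table with sample metadata
#'
#' @param counts_path TSV/CSV file; first column gene ids, remaining columns
#'   one per sample. Delimiter inferred from the extension (`.csv` = comma).
#' @param meta_path TSV with columns `sample_id`, `subject`, `species`,
#'   `compartment`, `zone`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, meta_path) {
  sep <- if (grepl("\\.csv$", counts_path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(counts_path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- as.character(df[[1]])
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  count_matrix(values, meta)
}

#' Write a count or expression matrix (with metadata sidecar) as TSV
#'
#' @param x A `"count_matrix"` or `"expression_matrix"`.
#' @param values_path Output TSV for the matrix (first column `gene_id`).
#' @param meta_path Optional output TSV for the sample metadata.
#' @export
write_matrix_tsv <- function(x, values_path, meta_path = NULL) {
  stopifnot(inherits(x, c("count_matrix", "expression_matrix")))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(meta_path)) {
    utils::write.table(x$meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}

#' Read a protein x sample iBAQ table
#'
#' Expects columns `protein_id`, `unique_peptides`, `contaminant`
#' (TRUE/FALSE), followed by one column per sample. Empty cells are missing
#' values.
#'
#' @param proteins_path TSV file as described.
#' @param meta_path Sample metadata TSV.
#' @return A [protein_table()].
#' @export
read_protein_table <- function(proteins_path, meta_path) {
  df <- utils::read.table(proteins_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("protein_id", "unique_peptides", "contaminant")
  if (!all(need %in% names(df))) {
    stop("protein table needs columns: ", paste(need, collapse = ", "))
  }
  sample_cols <- setdiff(names(df), need)
  values <- as.matrix(df[, sample_cols, drop = FALSE])
  rownames(values) <- df$protein_id
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  protein_table(values, meta, df$unique_peptides, as.logical(df$contaminant))
}

#' Write an apicome fit or a plain results table as TSV
#'
#' @param x An `"apicome"` object or a data frame.
#' @param path Output TSV path.
#' @export
write_results_tsv <- function(x, path) {
  tab <- if (inherits(x, "apicome")) x$table else as.data.frame(x)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read a two-column orthology table
#'
#' @param path TSV with columns `human_id`, `mouse_id` and optionally
#'   `relationship`.
#' @return A data frame.
#' @export
read_orthology <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("human_id", "mouse_id") %in% names(df))) {
    stop("orthology table needs columns human_id and mouse_id")
  }
  df
}
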