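# Core data containers. Base-R S3: a count/expression matrix is a genes x
# samples matrix plus a sample-metadata data frame sharing the column order.

.required_meta_cols <- c("sample_id", "subject", "species", "compartment", "zone")

.validate_meta <- function(meta, sample_ids) {
  if (!is.data.frame(meta)) stop("'meta' must be a data frame")
  missing_cols <- setdiff(.required_meta_cols, names(meta))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  if (!setequal(meta$sample_id, sample_ids)) {
    stop("metadata sample ids do not match matrix column names")
  }
  core <- meta[, .required_meta_cols]
  if (anyNA(core) || any(core == "")) {
    stop("every sample needs complete metadata (subject, species, compartment, zone)")
  }
  bad <- setdiff(unique(meta$compartment), c("apical", "basal"))
  if (length(bad) > 0L) {
    stop("compartment must be 'apical' or 'basal'; found: ",
         paste(bad, collapse = ", "))
  }
  meta[match(sample_ids, meta$sample_id), , drop = FALSE]
}

#' Construct a gene x sample UMI count matrix
#'
#' Bundles a nonnegative integer count matrix with its per-sample metadata
#' (subject, species, compartment in apical/basal, zone in tip/base).
#' Duplicate gene ids are made unique by suffixing (originals are kept in the
#' `original_gene_id` attribute).
#'
#' @param values Numeric matrix of nonnegative integer counts, genes in rows
#'   (rownames = gene ids), samples in columns (colnames = sample ids).
#' @param meta Data frame with columns `sample_id`, `subject`, `species`,
#'   `compartment`, `zone`, one row per sample.
#' @return An object of class `"count_matrix"`: a list with `values` and
#'   `meta`.
#' @export
count_matrix <- function(values, meta) {
  if (!is.matrix(values)) stop("'values' must be a matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' needs gene rownames and sample colnames")
  }
  if (anyNA(values) || any(values < 0)) stop("counts must be nonnegative")
  if (any(abs(values - round(values)) > 1e-8)) stop("counts must be integers")
  values <- round(values)
  original <- rownames(values)
  if (anyDuplicated(original)) {
    rownames(values) <- make.unique(original, sep = "_dup")
    message("made ", sum(duplicated(original)), " duplicate gene ids unique")
  }
  meta <- .validate_meta(meta, colnames(values))
  structure(
    list(values = values, meta = meta, original_gene_id = original),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  cat("  species:    ", paste(unique(x$meta$species), collapse = ", "), "\n")
  cat("  subjects:   ", length(unique(x$meta$subject)), "\n")
  cat("  compartments:", paste(sort(unique(x$meta$compartment)), collapse = ", "), "\n")
  invisible(x)
}

.expression_matrix <- function(values, meta) {
  structure(list(values = values, meta = meta), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples (columns sum to 1)\n")
  invisible(x)
}

#' Construct a protein x sample iBAQ table
#'
#' @param values Numeric matrix of nonnegative iBAQ abundances (NA = not
#'   detected), proteins in rows, samples in columns.
#' @param meta Sample metadata as in [count_matrix()].
#' @param unique_peptides Integer vector, unique peptides per protein.
#' @param contaminant Logical vector flagging suspected contaminants.
#' @return An object of class `"protein_table"`.
#' @export
protein_table <- function(values, meta, unique_peptides, contaminant) {
  if (!is.matrix(values)) stop("'values' must be a matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' needs protein rownames and sample colnames")
  }
  if (any(values < 0, na.rm = TRUE)) stop("iBAQ values must be nonnegative")
  if (length(unique_peptides) != nrow(values) ||
      length(contaminant) != nrow(values)) {
    stop("per-protein annotation lengths must match the number of rows")
  }
  meta <- .validate_meta(meta, colnames(values))
  structure(
    list(values = values, meta = meta,
         unique_peptides = as.integer(unique_peptides),
         contaminant = as.logical(contaminant),
         normalized = FALSE),
    class = "protein_table"
  )
}

#' @export
print.protein_table <- function(x, ...) {
  cat("protein_table:", nrow(x$values), "proteins x", ncol(x$values), "samples\n")
  cat("  contaminants flagged:", sum(x$contaminant), "\n")
  cat("  normalized:", x$normalized, "\n")
  invisible(x)
}

# subset helper shared by the proteomics filters
.subset_protein_table <- function(x, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(x$values))
  if (is.null(cols)) cols <- seq_len(ncol(x$values))
  x$values <- x$values[rows, cols, drop = FALSE]
  x$unique_peptides <- x$unique_peptides[rows]
  x$contaminant <- x$contaminant[rows]
  x$meta <- x$meta[match(colnames(x$values), x$meta$sample_id), , drop = FALSE]
  x
}
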