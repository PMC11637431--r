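# Sample QC, gene filtering and total-count normalization for LCM RNA-seq.
# The basal compartment yields systematically fewer UMIs than the apical one,
# so all downstream ratios are taken on per-sample relative abundances.

#' Total-count (relative abundance) normalization
#'
#' Divides each value by the UMI sum of its sample, so every column of the
#' result sums to 1 and apical/basal comparisons are made on concentrations
#' rather than yields.
#'
#' @param counts A [count_matrix()].
#' @return An `"expression_matrix"` sharing the gene and sample axes.
#' @export
total_count_normalize <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  sums <- colSums(counts$values)
  if (any(sums == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(counts$values)[sums == 0], collapse = ", "))
  }
  .expression_matrix(sweep(counts$values, 2, sums, "/"), counts$meta)
}

#' Drop samples with too few UMIs
#'
#' Retains samples whose total UMI count is at least `min_umis` (inclusive:
#' the default keeps a sample at exactly 10,000). Removed sample ids are
#' reported via [message()].
#'
#' @param counts A [count_matrix()].
#' @param min_umis Minimum column sum required to keep a sample.
#' @return The filtered [count_matrix()].
#' @export
filter_samples_by_depth <- function(counts, min_umis = 10000) {
  stopifnot(inherits(counts, "count_matrix"))
  sums <- colSums(counts$values)
  keep <- sums >= min_umis
  if (!any(keep)) stop("no samples with >= ", min_umis, " UMIs")
  if (!all(keep)) {
    message("removed low-depth samples: ",
            paste(colnames(counts$values)[!keep], collapse = ", "))
  }
  counts$values <- counts$values[, keep, drop = FALSE]
  counts$meta <- counts$meta[keep, , drop = FALSE]
  counts
}

#' Keep protein-coding genes
#'
#' Filters the count matrix to genes annotated as `protein_coding` in a
#' biotype table. Genes absent from the table are dropped (conservative) and
#' reported.
#'
#' @param counts A [count_matrix()].
#' @param biotype_table Data frame with columns `gene_id` and `biotype`.
#' @return The filtered [count_matrix()].
#' @export
filter_protein_coding <- function(counts, biotype_table) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!all(c("gene_id", "biotype") %in% names(biotype_table))) {
    stop("'biotype_table' needs columns gene_id and biotype")
  }
  genes <- rownames(counts$values)
  bt <- biotype_table$biotype[match(genes, biotype_table$gene_id)]
  unannotated <- genes[is.na(bt)]
  if (length(unannotated) > 0L) {
    message("dropping ", length(unannotated),
            " gene(s) absent from the biotype table")
  }
  keep <- !is.na(bt) & bt == "protein_coding"
  if (!any(keep)) stop("no protein-coding genes remain")
  counts$values <- counts$values[keep, , drop = FALSE]
  counts
}

#' Principal components of deep, well-expressed samples
#'
#' Reproduces the QC ordination: samples with more than `min_umis` UMIs
#' (strict) are kept, genes with mean normalized expression above
#' `min_mean_expr` are centered and scaled to unit variance across samples
#' (zero-variance genes are excluded), and PCA is performed on the scaled
#' matrix.
#'
#' @param expr An `"expression_matrix"` (normalized).
#' @param counts The matching [count_matrix()] used for the depth filter.
#' @param min_umis Depth threshold (strict `>`), default 20,000.
#' @param min_mean_expr Mean-expression floor for genes, default `1e-4`.
#' @return A list with `coords` (samples x PCs), `explained_variance`
#'   (fractions), `meta` for the retained samples and `n_genes` used.
#' @export
prepare_pca <- function(expr, counts, min_umis = 20000, min_mean_expr = 1e-4) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(counts, "count_matrix"))
  depth <- colSums(counts$values)[match(colnames(expr$values),
                                        colnames(counts$values))]
  keep_s <- !is.na(depth) & depth > min_umis
  if (sum(keep_s) < 3L) stop("fewer than 3 samples pass the depth filter")
  v <- expr$values[, keep_s, drop = FALSE]
  keep_g <- rowMeans(v) > min_mean_expr
  v <- v[keep_g, , drop = FALSE]
  vars <- apply(v, 1, stats::var)
  v <- v[vars > 0, , drop = FALSE]
  if (nrow(v) < 2L) stop("fewer than 2 variable genes pass the expression filter")
  pc <- stats::prcomp(t(v), center = TRUE, scale. = TRUE)
  list(
    coords = pc$x,
    explained_variance = pc$sdev^2 / sum(pc$sdev^2),
    meta = expr$meta[keep_s, , drop = FALSE],
    n_genes = nrow(v)
  )
}
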