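# mRNA-protein concordance: ratio correlations, sign-quadrant counts with
# hypergeometric enrichment, the cell-type signature normalization, the
# enterocyte-specificity classifier, and covariate correlations.

#' Spearman correlation of mRNA and protein polarization ratios
#'
#' Rank correlation of the per-gene log2 apical/basal ratios in the two
#' modalities over shared genes, restricted to relatively highly expressed
#' genes when expression vectors are provided.
#'
#' @param mrna_ratios,protein_ratios Named numeric vectors of log2 ratios.
#' @param mrna_expr,protein_expr Optional named mean-expression vectors used
#'   with `expr_floor`.
#' @param expr_floor Expression floor (default `1e-5`); a gene must exceed it
#'   in every modality for which expression is supplied.
#' @return A list with `rho`, `p_value`, `n_genes`.
#' @export
ratio_correlation <- function(mrna_ratios, protein_ratios,
                              mrna_expr = NULL, protein_expr = NULL,
                              expr_floor = 1e-5) {
  shared <- intersect(names(mrna_ratios), names(protein_ratios))
  if (!is.null(mrna_expr)) {
    shared <- shared[!is.na(mrna_expr[shared]) & mrna_expr[shared] > expr_floor]
  }
  if (!is.null(protein_expr)) {
    shared <- shared[!is.na(protein_expr[shared]) &
                       protein_expr[shared] > expr_floor]
  }
  if (length(shared) < 3L) stop("fewer than 3 genes after filtering")
  ct <- stats::cor.test(mrna_ratios[shared], protein_ratios[shared],
                        method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p_value = ct$p.value, n_genes = length(shared))
}

#' Concordance quadrants of mRNA and protein polarization
#'
#' Classifies each gene of the universe by the signs of its mRNA and protein
#' log2 ratios into apical/apical, apical/basal, basal/apical and
#' basal/basal quadrants, reports per-quadrant one-sided hypergeometric
#' enrichment p-values given the margins, and the percentage of
#' sign-concordant genes. Genes with an exactly zero ratio in either
#' modality are excluded from the quadrant table and counted separately.
#'
#' @param mrna_ratios,protein_ratios Named numeric vectors of log2 ratios.
#' @param universe Optional character vector restricting the gene universe
#'   (default: genes present in both vectors).
#' @param two_sided If `TRUE`, doubles the smaller hypergeometric tail
#'   instead of the enrichment tail.
#' @return A list of class `"concordance"` with `counts` (2x2 matrix, rows =
#'   mRNA side), `p_values` (per quadrant), `percent_concordant`, `n_genes`,
#'   `n_zero`.
#' @export
concordance_quadrants <- function(mrna_ratios, protein_ratios,
                                  universe = NULL, two_sided = FALSE) {
  shared <- intersect(names(mrna_ratios), names(protein_ratios))
  if (!is.null(universe)) shared <- intersect(shared, universe)
  m <- mrna_ratios[shared]
  p <- protein_ratios[shared]
  zero <- m == 0 | p == 0
  n_zero <- sum(zero)
  if (n_zero > 0L) message(n_zero, " gene(s) with a zero ratio excluded from quadrants")
  m <- m[!zero]
  p <- p[!zero]
  if (length(m) == 0L) stop("no genes with nonzero ratios in both modalities")
  m_ap <- m > 0
  p_ap <- p > 0
  counts <- matrix(
    c(sum(m_ap & p_ap), sum(m_ap & !p_ap),
      sum(!m_ap & p_ap), sum(!m_ap & !p_ap)),
    nrow = 2, byrow = TRUE,
    dimnames = list(mrna = c("apical", "basal"),
                    protein = c("apical", "basal"))
  )
  n <- sum(counts)
  pvals <- counts
  for (i in 1:2) {
    for (j in 1:2) {
      k <- counts[i, j]
      K <- sum(counts[i, ])           # mRNA margin
      nn <- sum(counts[, j])          # protein margin
      upper <- stats::phyper(k - 1, K, n - K, nn, lower.tail = FALSE)
      if (two_sided) {
        lower <- stats::phyper(k, K, n - K, nn)
        pvals[i, j] <- min(1, 2 * min(upper, lower))
      } else {
        pvals[i, j] <- upper
      }
    }
  }
  structure(
    list(
      counts = counts,
      p_values = pvals,
      percent_concordant = 100 * (counts[1, 1] + counts[2, 2]) / n,
      n_genes = n,
      n_zero = n_zero
    ),
    class = "concordance"
  )
}

#' @export
print.concordance <- function(x, ...) {
  cat("mRNA/protein concordance over", x$n_genes, "genes\n")
  print(x$counts)
  cat(sprintf("  concordant: %.1f%%\n", x$percent_concordant))
  invisible(x)
}

#' Normalize a cell-type signature matrix
#'
#' Divides each cell type's values by that cell type's sum, so every row
#' sums to 1.
#'
#' @param cell_type_means Nonnegative matrix, cell types in rows, genes in
#'   columns.
#' @return The row-normalized matrix.
#' @export
signature_normalize <- function(cell_type_means) {
  if (!is.matrix(cell_type_means)) stop("input must be a matrix")
  if (any(cell_type_means < 0)) stop("signature values must be nonnegative")
  sums <- rowSums(cell_type_means)
  if (any(sums == 0)) {
    stop("all-zero cell type(s): ",
         paste(rownames(cell_type_means)[sums == 0], collapse = ", "))
  }
  cell_type_means / sums
}

#' Enterocyte-specificity classifier
#'
#' A gene is enterocyte-specific when `(E + pn) / (N + pn) > 2` and
#' `E > expr_floor`, where E is its normalized expression in mature
#' enterocytes, N the maximum across all non-enterocyte cell types, and pn
#' the smallest positive entry of the signature matrix.
#'
#' @param sig Row-normalized signature matrix (see [signature_normalize()]).
#' @param enterocyte Row name of the enterocyte cell type.
#' @param pn Pseudo-number; `NULL` (default) uses the smallest positive
#'   entry of `sig`.
#' @param expr_floor Minimum enterocyte expression (default `1e-5`).
#' @return Named logical vector over genes.
#' @export
enterocyte_specificity <- function(sig, enterocyte = "enterocyte",
                                   pn = NULL, expr_floor = 1e-5) {
  if (!enterocyte %in% rownames(sig)) {
    stop("cell type '", enterocyte, "' absent from the signature matrix")
  }
  if (is.null(pn)) {
    pos <- sig[sig > 0]
    if (length(pos) == 0L) stop("signature matrix has no positive entries")
    pn <- min(pos)
  }
  E <- sig[enterocyte, ]
  N <- apply(sig[setdiff(rownames(sig), enterocyte), , drop = FALSE], 2, max)
  (E + pn) / (N + pn) > 2 & E > expr_floor
}

#' Correlation of mRNA and protein zonation
#'
#' Computes per-gene RNA log2(tip/base) ratios from the per-zone average of
#' apical and basal normalized expression, and protein log2(tip/base) ratios
#' from the apical proteomics samples, then Spearman-correlates them over
#' genes above the expression floor in both modalities.
#'
#' @param expr An `"expression_matrix"` of normalized RNA.
#' @param tbl A normalized [protein_table()].
#' @param expr_floor Mean-expression floor in both modalities (default `1e-4`).
#' @param pn Pseudo-number for the ratio (default `1e-6`).
#' @return A list with `rho`, `p_value`, `n_genes`.
#' @export
zonation_correlation <- function(expr, tbl, expr_floor = 1e-4, pn = 1e-6) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(tbl, "protein_table"))
  zmean <- function(values, meta, sel) {
    if (!any(sel)) stop("missing zone in one modality")
    rowMeans(values[, sel, drop = FALSE], na.rm = TRUE)
  }
  rna_tip <- zmean(expr$values, expr$meta, expr$meta$zone == "tip")
  rna_base <- zmean(expr$values, expr$meta, expr$meta$zone == "base")
  ap <- tbl$meta$compartment == "apical"
  prot_tip <- zmean(tbl$values, tbl$meta, ap & tbl$meta$zone == "tip")
  prot_base <- zmean(tbl$values, tbl$meta, ap & tbl$meta$zone == "base")
  rna_ratio <- log2((rna_tip + pn) / (rna_base + pn))
  prot_ratio <- log2((prot_tip + pn) / (prot_base + pn))
  shared <- intersect(names(rna_ratio), names(prot_ratio))
  rna_mean <- (rna_tip + rna_base) / 2
  prot_mean <- (prot_tip + prot_base) / 2
  shared <- shared[rna_mean[shared] > expr_floor & prot_mean[shared] > expr_floor]
  if (length(shared) < 3L) stop("fewer than 3 genes above the zonation floor")
  ct <- stats::cor.test(rna_ratio[shared], prot_ratio[shared],
                        method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p_value = ct$p.value, n_genes = length(shared))
}

#' Correlate apicome scores with gene-level covariates
#'
#' One Spearman correlation per covariate column, with pairwise deletion of
#' missing values. Covariates with fewer than 3 matched genes are skipped
#' with a warning.
#'
#' @param scores Named numeric vector of apicome scores.
#' @param covariate_table Data frame of gene-keyed covariates (rownames =
#'   gene ids).
#' @return Data frame with `covariate`, `rho`, `p_value`, `n`.
#' @export
covariate_correlation <- function(scores, covariate_table) {
  if (is.null(names(scores))) stop("'scores' must be named")
  if (is.null(rownames(covariate_table))) {
    stop("'covariate_table' needs gene rownames")
  }
  shared <- intersect(names(scores), rownames(covariate_table))
  rows <- lapply(names(covariate_table), function(cv) {
    x <- scores[shared]
    y <- covariate_table[shared, cv]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) {
      warning("skipping covariate '", cv, "': fewer than 3 matched genes")
      return(NULL)
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
    data.frame(covariate = cv, rho = unname(ct$estimate),
               p_value = ct$p.value, n = sum(ok))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no usable covariates")
  rownames(out) <- NULL
  out
}
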