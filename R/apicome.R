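# Apicome scoring and polarization calling.
#
# The apicome score of a gene is the mean over subjects of
# log2((A_i + pn) / (B_i + pn)), i.e. the log2 geometric mean of per-subject
# apical/basal normalized-expression ratios, where pn is the smallest
# nonzero normalized expression observed anywhere in the data set. Calls are
# made with the exact paired signed-rank test on the per-subject log2 ratios
# and BH correction across tested genes.

#' Data-derived pseudo-number
#'
#' The pseudo-number pn is the minimal normalized expression across all
#' samples and all genes that is not 0. Adding it to numerator and
#' denominator keeps log ratios finite at low expression without skewing
#' well-measured ratios.
#'
#' @param expr An `"expression_matrix"` or a numeric matrix of normalized
#'   expression.
#' @return The smallest strictly positive entry.
#' @export
compute_pseudo_number <- function(expr) {
  v <- if (inherits(expr, "expression_matrix")) expr$values else expr
  pos <- v[v > 0]
  if (length(pos) == 0L) stop("matrix has no positive entries")
  min(pos)
}

#' Apicome score from paired apical/basal expression
#'
#' @param apical,basal Numeric matrices (genes x subjects) of normalized
#'   expression, columns paired by subject (same column names, same order
#'   after matching).
#' @param pn Pseudo-number (> 0), see [compute_pseudo_number()].
#' @return A list with `score` (per-gene mean log2 ratio) and `ratios`
#'   (genes x subjects matrix of per-subject log2 ratios).
#' @export
apicome_score <- function(apical, basal, pn) {
  if (pn <= 0) stop("pn must be positive")
  apical <- as.matrix(apical)
  basal <- as.matrix(basal)
  if (!identical(dim(apical), dim(basal))) stop("apical/basal dimensions differ")
  if (!is.null(colnames(apical)) && !is.null(colnames(basal))) {
    if (!setequal(colnames(apical), colnames(basal))) {
      stop("unpaired subjects: apical and basal columns do not match")
    }
    basal <- basal[, colnames(apical), drop = FALSE]
  }
  ratios <- log2((apical + pn) / (basal + pn))
  list(score = rowMeans(ratios), ratios = ratios)
}

#' Parameters of the polarization analysis
#'
#' @param pn Pseudo-number; `NULL` (default) derives it from the data via
#'   [compute_pseudo_number()].
#' @param min_mean_expr Testing floor: only genes with mean normalized
#'   expression above this are tested (default `1e-5`).
#' @param q_threshold BH q-value below which a gene is called polarized
#'   (default 0.25).
#' @return A list of class `"normalization_params"`.
#' @export
normalization_params <- function(pn = NULL, min_mean_expr = 1e-5,
                                 q_threshold = 0.25) {
  if (!is.null(pn) && pn <= 0) stop("pn must be positive")
  if (q_threshold <= 0 || q_threshold >= 1) stop("q_threshold must be in (0, 1)")
  structure(list(pn = pn, min_mean_expr = min_mean_expr,
                 q_threshold = q_threshold),
            class = "normalization_params")
}

# Per-subject compartment means (zones averaged unless zone is fixed).
# Returns genes x subjects matrix; subjects missing any required sample are
# reported via the `complete` attribute.
.subject_compartment_means <- function(expr, compartment, zone = NULL) {
  meta <- expr$meta
  sel <- meta$compartment == compartment
  if (!is.null(zone)) sel <- sel & meta$zone == zone
  subjects <- unique(meta$subject)
  out <- matrix(NA_real_, nrow(expr$values), length(subjects),
                dimnames = list(rownames(expr$values), subjects))
  for (s in subjects) {
    cols <- which(sel & meta$subject == s)
    if (length(cols) > 0L) {
      out[, s] <- rowMeans(expr$values[, cols, drop = FALSE])
    }
  }
  out
}

#' Polarization test: score, exact signed-rank p and BH q per gene
#'
#' The central fit of the package. For each gene whose mean normalized
#' expression exceeds the testing floor, computes the apicome score (mean
#' per-subject log2 apical/basal ratio; villus zones averaged per
#' compartment within subject), an exact two-sided paired signed-rank
#' p-value over subjects, and BH q-values across tested genes. A gene is
#' called polarized at `q < q_threshold`, with direction given by the sign
#' of the score.
#'
#' @param expr An `"expression_matrix"` from [total_count_normalize()].
#' @param params A [normalization_params()].
#' @return An object of class `"apicome"`: list with `table` (per-gene
#'   data frame: `gene_id`, `score`, `mean_expr`, `n_subjects`, `p_value`,
#'   `q_value`, `polarized`, `direction`), `ratios` (tested genes x
#'   subjects), `zone_ratios` (tested genes x subject-zone samples, used by
#'   the cross-species rank-sum tests), `pn`, `params` and `species`.
#' @seealso [zonal_change_test()], [interspecies_change_test()]
#' @export
polarization_test <- function(expr, params = normalization_params()) {
  stopifnot(inherits(expr, "expression_matrix"))
  pn <- if (is.null(params$pn)) compute_pseudo_number(expr) else params$pn
  A <- .subject_compartment_means(expr, "apical")
  B <- .subject_compartment_means(expr, "basal")
  complete <- colSums(is.na(A)) == 0 & colSums(is.na(B)) == 0
  A <- A[, complete, drop = FALSE]
  B <- B[, complete, drop = FALSE]
  if (ncol(A) < 2L) stop("need at least 2 subjects with paired apical/basal samples")

  mean_expr <- rowMeans(expr$values)
  tested <- mean_expr > params$min_mean_expr
  if (!any(tested)) stop("no genes above the expression floor")
  sc <- apicome_score(A[tested, , drop = FALSE], B[tested, , drop = FALSE], pn)
  # per-sample (subject x zone) ratios, kept for cross-species rank-sum tests
  zone_ratios <- NULL
  for (z in unique(expr$meta$zone)) {
    Az <- .subject_compartment_means(expr, "apical", z)[tested, , drop = FALSE]
    Bz <- .subject_compartment_means(expr, "basal", z)[tested, , drop = FALSE]
    okz <- colSums(is.na(Az)) == 0 & colSums(is.na(Bz)) == 0
    if (!any(okz)) next
    rz <- log2((Az[, okz, drop = FALSE] + pn) / (Bz[, okz, drop = FALSE] + pn))
    colnames(rz) <- paste(colnames(Az)[okz], z, sep = ".")
    zone_ratios <- cbind(zone_ratios, rz)
  }
  p <- apply(sc$ratios, 1, exact_signed_rank_test)
  q <- bh_adjust(p)
  tab <- data.frame(
    gene_id = rownames(expr$values)[tested],
    score = unname(sc$score),
    mean_expr = unname(mean_expr[tested]),
    n_subjects = ncol(A),
    p_value = unname(p),
    q_value = unname(q),
    polarized = unname(q < params$q_threshold),
    direction = ifelse(q < params$q_threshold,
                       ifelse(sc$score > 0, "apical", "basal"), "none"),
    row.names = NULL
  )
  structure(
    list(table = tab, ratios = sc$ratios, zone_ratios = zone_ratios, pn = pn,
         params = params, species = unique(expr$meta$species)),
    class = "apicome"
  )
}

#' @export
print.apicome <- function(x, ...) {
  cat("Apicome polarization fit (", paste(x$species, collapse = "/"), ")\n", sep = "")
  cat("  genes tested:  ", nrow(x$table), "\n")
  cat("  subjects:      ", x$table$n_subjects[1], "\n")
  cat("  pseudo-number: ", format(x$pn, digits = 4), "\n")
  cat("  polarized (q < ", x$params$q_threshold, "): ",
      sum(x$table$polarized), "\n", sep = "")
  invisible(x)
}

#' @method summary apicome
#' @export
summary.apicome <- function(object, ...) {
  tab <- object$table
  cat("Apicome polarization fit\n")
  cat("  genes tested:", nrow(tab), " subjects:", tab$n_subjects[1], "\n")
  cat("  polarized:", sum(tab$polarized),
      "(apical", sum(tab$direction == "apical"),
      "/ basal", sum(tab$direction == "basal"), ")\n")
  cat("  score quantiles:\n")
  print(stats::quantile(tab$score, c(0.025, 0.25, 0.5, 0.75, 0.975)))
  invisible(object)
}

#' @method coef apicome
#' @export
coef.apicome <- function(object, ...) {
  stats::setNames(object$table$score, object$table$gene_id)
}

#' MA-style plot of an apicome fit
#'
#' Mean expression (log10) against the apicome score, with polarized genes
#' highlighted.
#'
#' @param x An `"apicome"` object.
#' @param ... Passed to [graphics::plot()].
#' @method plot apicome
#' @export
plot.apicome <- function(x, ...) {
  tab <- x$table
  graphics::plot(log10(tab$mean_expr), tab$score,
                 col = ifelse(tab$polarized, "dodgerblue3", "grey60"),
                 pch = 16, cex = 0.5,
                 xlab = "log10 mean normalized expression",
                 ylab = "apicome score (log2 apical/basal)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Tip-versus-base change in polarization
#'
#' For each gene above the expression floor, computes the per-subject
#' difference between the tip-zone and base-zone log2 apical/basal ratios and
#' tests it against zero with the exact two-sided signed-rank test, BH
#' correcting over tested genes. Subjects missing either compartment in
#' either zone are dropped with a warning.
#'
#' @param expr An `"expression_matrix"`.
#' @param params A [normalization_params()].
#' @return Data frame with `gene_id`, `delta` (mean tip-minus-base ratio
#'   change), `p_value`, `q_value`.
#' @export
zonal_change_test <- function(expr, params = normalization_params()) {
  stopifnot(inherits(expr, "expression_matrix"))
  pn <- if (is.null(params$pn)) compute_pseudo_number(expr) else params$pn
  mats <- list(
    tip_a = .subject_compartment_means(expr, "apical", "tip"),
    tip_b = .subject_compartment_means(expr, "basal", "tip"),
    base_a = .subject_compartment_means(expr, "apical", "base"),
    base_b = .subject_compartment_means(expr, "basal", "base")
  )
  complete <- Reduce(`&`, lapply(mats, function(m) colSums(is.na(m)) == 0))
  if (!all(complete)) {
    warning("dropping subject(s) without both zones in both compartments: ",
            paste(colnames(mats$tip_a)[!complete], collapse = ", "))
  }
  mats <- lapply(mats, function(m) m[, complete, drop = FALSE])
  if (ncol(mats$tip_a) < 2L) stop("fewer than 2 complete subjects")

  mean_expr <- rowMeans(expr$values)
  tested <- mean_expr > params$min_mean_expr
  if (!any(tested)) stop("no genes above the expression floor")
  sub <- lapply(mats, function(m) m[tested, , drop = FALSE])
  d <- log2((sub$tip_a + pn) / (sub$tip_b + pn)) -
       log2((sub$base_a + pn) / (sub$base_b + pn))
  p <- apply(d, 1, exact_signed_rank_test)
  q <- bh_adjust(p)
  data.frame(
    gene_id = rownames(expr$values)[tested],
    delta = unname(rowMeans(d)),
    p_value = unname(p),
    q_value = unname(q),
    row.names = NULL
  )
}
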