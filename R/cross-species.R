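# Cross-species comparison of polarization: ortholog mapping, per-gene
# rank-sum tests between the human and mouse per-subject log2 ratios, the
# dual q-value significance criterion, and the mitochondrial-bias test.

#' Merge human and mouse apicome fits over one-to-one orthologs
#'
#' Renames genes via an orthology table and merges the two species' fits,
#' keeping only one-to-one pairs whose genes are present (and tested) in
#' both species. One-to-many entries and pairs labelled other than
#' `one2one` are excluded with a message.
#'
#' @param human_fit,mouse_fit `"apicome"` objects from [polarization_test()].
#' @param map Data frame with columns `human_id`, `mouse_id` and optionally
#'   `relationship` (rows other than `"one2one"` are dropped).
#' @return A list of class `"ortholog_merge"`: `table` (per pair: ids,
#'   scores and q-values in both species), `human_ratios`, `mouse_ratios`
#'   (matrices over merged genes, keyed by human id).
#' @export
map_orthologs <- function(human_fit, mouse_fit, map) {
  stopifnot(inherits(human_fit, "apicome"), inherits(mouse_fit, "apicome"))
  if (!all(c("human_id", "mouse_id") %in% names(map))) {
    stop("'map' needs columns human_id and mouse_id")
  }
  if ("relationship" %in% names(map)) {
    drop_rel <- map$relationship != "one2one"
    if (any(drop_rel)) {
      message("excluding ", sum(drop_rel), " non-one2one ortholog pair(s)")
      map <- map[!drop_rel, , drop = FALSE]
    }
  }
  map <- unique(map[, c("human_id", "mouse_id")])
  multi <- map$human_id %in% map$human_id[duplicated(map$human_id)] |
           map$mouse_id %in% map$mouse_id[duplicated(map$mouse_id)]
  if (any(multi)) {
    message("excluding ", sum(multi), " one-to-many ortholog entries")
    map <- map[!multi, , drop = FALSE]
  }
  ht <- human_fit$table
  mt <- mouse_fit$table
  keep <- map$human_id %in% ht$gene_id & map$mouse_id %in% mt$gene_id
  map <- map[keep, , drop = FALSE]
  if (nrow(map) == 0L) stop("no ortholog pairs present in both fits")
  hi <- match(map$human_id, ht$gene_id)
  mi <- match(map$mouse_id, mt$gene_id)
  tab <- data.frame(
    human_id = map$human_id,
    mouse_id = map$mouse_id,
    human_score = ht$score[hi],
    mouse_score = mt$score[mi],
    human_q = ht$q_value[hi],
    mouse_q = mt$q_value[mi],
    row.names = NULL
  )
  pick <- function(m, ids) {
    if (is.null(m)) return(NULL)
    m[match(ids, rownames(m)), , drop = FALSE]
  }
  structure(
    list(
      table = tab,
      human_ratios = pick(human_fit$ratios, map$human_id),
      mouse_ratios = pick(mouse_fit$ratios, map$mouse_id),
      human_zone_ratios = pick(human_fit$zone_ratios, map$human_id),
      mouse_zone_ratios = pick(mouse_fit$zone_ratios, map$mouse_id)
    ),
    class = "ortholog_merge"
  )
}

#' Interspecies polarization-change test
#'
#' For each ortholog pair, compares the human per-sample log2 apical/basal
#' ratios with the mouse per-sample ratios (one ratio per subject and villus
#' zone, the sampling unit of the design) by the exact two-sided Wilcoxon
#' rank-sum test, BH-corrects across genes, and flags a gene as changed when
#' the interspecies q-value is below `q_interspecies` and the smaller of the
#' two species-specific polarization q-values is below `q_species`.
#'
#' @param merged An `"ortholog_merge"` from [map_orthologs()].
#' @param q_interspecies Interspecies q-value threshold (default 0.2).
#' @param q_species Threshold on the minimum species-specific polarization
#'   q-value (default 0.1).
#' @return The merged table with `interspecies_p`, `interspecies_q` and
#'   `changed` columns appended.
#' @export
interspecies_change_test <- function(merged, q_interspecies = 0.2,
                                     q_species = 0.1) {
  stopifnot(inherits(merged, "ortholog_merge"))
  hr <- merged$human_zone_ratios
  mr <- merged$mouse_zone_ratios
  if (is.null(hr) || is.null(mr)) {
    hr <- merged$human_ratios
    mr <- merged$mouse_ratios
  }
  ok <- rowSums(!is.na(hr)) >= 2 & rowSums(!is.na(mr)) >= 2
  if (!all(ok)) {
    warning("skipping ", sum(!ok), " gene(s) with fewer than 2 per-species ratios")
  }
  p <- rep(NA_real_, nrow(hr))
  for (i in which(ok)) {
    p[i] <- exact_rank_sum_test(hr[i, !is.na(hr[i, ])], mr[i, !is.na(mr[i, ])])
  }
  tab <- merged$table
  tab$interspecies_p <- p
  tab$interspecies_q <- bh_adjust(p)
  tab$changed <- !is.na(tab$interspecies_q) &
    tab$interspecies_q < q_interspecies &
    pmin(tab$human_q, tab$mouse_q) < q_species
  tab
}

#' Mitochondrial polarization bias test
#'
#' One-sample, two-sided exact signed-rank test of the apicome scores of
#' mitochondrially encoded genes against zero, restricted to genes above an
#' expression floor.
#'
#' @param fit An `"apicome"` object.
#' @param mito_genes Character vector of mitochondrially encoded gene ids.
#' @param expr_floor Normalized-expression floor (default `1e-4`).
#' @return A list with `p_value`, `n_genes`, `median_score`.
#' @export
mito_polarization_test <- function(fit, mito_genes, expr_floor = 1e-4) {
  stopifnot(inherits(fit, "apicome"))
  tab <- fit$table
  sel <- tab$gene_id %in% mito_genes & tab$mean_expr > expr_floor
  if (sum(sel) == 0L) stop("no qualifying mitochondrial genes")
  if (sum(sel) < 2L) stop("fewer than 2 qualifying mitochondrial genes")
  scores <- tab$score[sel]
  list(
    p_value = exact_signed_rank_test(scores),
    n_genes = sum(sel),
    median_score = stats::median(scores)
  )
}

#' Spearman correlation of apicome scores between data sets
#'
#' Rank correlation of two per-gene score vectors on their shared genes,
#' optionally restricted to genes significant and expressed in both data
#' sets (q-value below `q_max` in both, expression above `expr_floor`).
#'
#' @param scores_x,scores_y Named numeric vectors of per-gene scores.
#' @param q_x,q_y Optional named q-value vectors for the significance filter.
#' @param expr_x,expr_y Optional named expression vectors for the floor.
#' @param q_max Significance cutoff applied when q-values are given.
#' @param expr_floor Expression floor applied when expression is given
#'   (a gene passes if its maximum across the two data sets exceeds it).
#' @return A list with `rho`, `p_value`, `n_genes`.
#' @export
apicome_correlation <- function(scores_x, scores_y,
                                q_x = NULL, q_y = NULL,
                                expr_x = NULL, expr_y = NULL,
                                q_max = 0.1, expr_floor = 1e-5) {
  shared <- intersect(names(scores_x), names(scores_y))
  if (!is.null(q_x) && !is.null(q_y)) {
    shared <- shared[!is.na(q_x[shared]) & !is.na(q_y[shared]) &
                       q_x[shared] < q_max & q_y[shared] < q_max]
  }
  if (!is.null(expr_x) && !is.null(expr_y)) {
    shared <- shared[pmax(expr_x[shared], expr_y[shared]) > expr_floor]
  }
  if (length(shared) < 3L) stop("fewer than 3 genes after filtering")
  ct <- stats::cor.test(scores_x[shared], scores_y[shared],
                        method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_genes = length(shared))
}
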