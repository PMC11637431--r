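# LCM proteomics: iBAQ cleaning and normalization, left-censored
# imputation, apical/basal log-ratios, negative-binomial differential
# abundance, protein-group polarization tests and the cytoplasmic refilter.

#' Clean and normalize an iBAQ protein table
#'
#' Removes suspected contaminants and proteins with fewer than
#' `min_unique_peptides` unique peptides, subtracts the minimal iBAQ value
#' (global by default; per-sample via `per_sample_min`) from all values
#' (floored at 0), drops low-quality samples with fewer than
#' `min_proteins_per_sample` detected proteins, and divides each remaining
#' column by its sum.
#'
#' @param raw A [protein_table()] of raw iBAQ values (NA = not detected).
#' @param min_unique_peptides Minimum unique peptides to keep a protein.
#' @param min_proteins_per_sample Minimum detected proteins to keep a sample.
#' @param per_sample_min If `TRUE`, subtract each sample's own minimum
#'   instead of the global minimum.
#' @return The cleaned, column-normalized [protein_table()].
#' @export
clean_protein_table <- function(raw, min_unique_peptides = 2,
                                min_proteins_per_sample = 1000,
                                per_sample_min = FALSE) {
  stopifnot(inherits(raw, "protein_table"))
  keep <- !raw$contaminant & raw$unique_peptides >= min_unique_peptides
  if (!any(keep)) stop("no proteins survive the contaminant/peptide filters")
  x <- .subset_protein_table(raw, rows = which(keep))
  if (per_sample_min) {
    mins <- apply(x$values, 2, min, na.rm = TRUE)
    x$values <- pmax(sweep(x$values, 2, mins, "-"), 0)
  } else {
    x$values <- pmax(x$values - min(x$values, na.rm = TRUE), 0)
  }
  detected <- colSums(!is.na(x$values))
  keep_s <- detected >= min_proteins_per_sample
  if (!any(keep_s)) stop("no samples with >= ", min_proteins_per_sample,
                         " detected proteins")
  if (!all(keep_s)) {
    message("removed low-quality samples: ",
            paste(colnames(x$values)[!keep_s], collapse = ", "))
  }
  x <- .subset_protein_table(x, cols = which(keep_s))
  sums <- colSums(x$values, na.rm = TRUE)
  if (any(sums == 0)) {
    stop("degenerate sample(s) with zero total abundance after minimum ",
         "subtraction: ", paste(colnames(x$values)[sums == 0], collapse = ", "))
  }
  x$values <- sweep(x$values, 2, sums, "/")
  x$normalized <- TRUE
  x
}

#' Impute missing abundances from a low, random distribution
#'
#' Missing entries are drawn in log2 space from a Gaussian centered
#' `shift` standard deviations below the observed per-sample mean, with
#' `width` times the observed per-sample SD - the standard down-shift
#' convention for left-censored mass-spectrometry data. Observed entries are
#' untouched. Proteins with no observed value in any sample are dropped with
#' a message.
#'
#' @param tbl A [protein_table()] (normalized or raw; imputation happens on
#'   the current scale).
#' @param seed Integer seed.
#' @param shift,width Down-shift and width parameters in per-sample SD units.
#' @return The table with missing values filled in.
#' @export
impute_missing <- function(tbl, seed = 1L, shift = 1.8, width = 0.3) {
  stopifnot(inherits(tbl, "protein_table"))
  all_missing <- rowSums(!is.na(tbl$values)) == 0
  if (any(all_missing)) {
    message("dropping ", sum(all_missing), " protein(s) observed in no sample")
    tbl <- .subset_protein_table(tbl, rows = which(!all_missing))
  }
  if (!anyNA(tbl$values)) return(tbl)
  set.seed(seed)
  v <- tbl$values
  for (j in seq_len(ncol(v))) {
    obs <- v[, j][!is.na(v[, j]) & v[, j] > 0]
    miss <- which(is.na(v[, j]))
    if (length(miss) == 0L) next
    if (length(obs) < 2L) stop("sample ", colnames(v)[j],
                               " has too few observed values to impute from")
    m <- mean(log2(obs))
    s <- stats::sd(log2(obs))
    v[miss, j] <- 2^stats::rnorm(length(miss), m - shift * s, width * s)
  }
  tbl$values <- v
  tbl
}

#' Protein apical/basal log2 ratio (villus tip)
#'
#' `log2((mean apical tip + pn) / (mean basal tip + pn))` per protein,
#' using tip-zone samples only.
#'
#' @param tbl A normalized [protein_table()].
#' @param pn Pseudo-number added to both sides (default `1e-6`).
#' @return Named numeric vector of per-protein log2 ratios.
#' @export
protein_log_ratio <- function(tbl, pn = 1e-6) {
  stopifnot(inherits(tbl, "protein_table"))
  if (pn <= 0) stop("pn must be positive")
  meta <- tbl$meta
  a <- meta$compartment == "apical" & meta$zone == "tip"
  b <- meta$compartment == "basal" & meta$zone == "tip"
  if (!any(a) || !any(b)) stop("missing tip-zone samples for one compartment")
  am <- rowMeans(tbl$values[, a, drop = FALSE], na.rm = TRUE)
  bm <- rowMeans(tbl$values[, b, drop = FALSE], na.rm = TRUE)
  log2((am + pn) / (bm + pn))
}

#' Differential protein abundance (negative-binomial Wald test)
#'
#' Tests each protein for apical-versus-basal abundance differences with a
#' negative-binomial Wald test (DESeq2). Normalized iBAQ abundances are
#' scaled to integer pseudo-counts (x 1e6, rounded) and per-sample size
#' factors are estimated by the median-of-ratios method (falling back to
#' total-count factors if geometric means degenerate). Missing values must
#' be imputed first ([impute_missing()]). q-values are plain BH across all
#' tested proteins (no independent filtering).
#'
#' @param tbl A normalized, imputed [protein_table()].
#' @param pseudo_count_scale Multiplier converting normalized abundances to
#'   pseudo-counts (default `1e6`).
#' @param q_threshold Significance threshold for the `significant` flag
#'   (default 0.25).
#' @return Data frame with `protein_id`, `de_log2fc` (apical over basal),
#'   `de_p`, `de_q`, `significant`.
#' @export
differential_abundance <- function(tbl, pseudo_count_scale = 1e6,
                                   q_threshold = 0.25) {
  stopifnot(inherits(tbl, "protein_table"))
  if (anyNA(tbl$values)) {
    stop("missing values present; run impute_missing() first")
  }
  meta <- tbl$meta
  if (sum(meta$compartment == "apical") < 2L ||
      sum(meta$compartment == "basal") < 2L) {
    stop("need at least 2 samples per compartment")
  }
  counts <- round(tbl$values * pseudo_count_scale)
  mode(counts) <- "integer"
  coldata <- data.frame(
    compartment = factor(meta$compartment, levels = c("basal", "apical")),
    row.names = meta$sample_id
  )
  dds <- DESeq2::DESeqDataSetFromMatrix(counts, coldata, ~compartment)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE, fitType = "local"))
  res <- DESeq2::results(dds, contrast = c("compartment", "apical", "basal"),
                         independentFiltering = FALSE)
  out <- data.frame(
    protein_id = rownames(counts),
    de_log2fc = res$log2FoldChange,
    de_p = res$pvalue,
    de_q = bh_adjust(res$pvalue),
    row.names = NULL
  )
  out$significant <- !is.na(out$de_q) & out$de_q < q_threshold
  out
}

#' Protein-group polarization test
#'
#' For each annotated group, compares the log2 apical/basal ratios of group
#' members against all non-members with the exact two-sided Wilcoxon
#' rank-sum test, BH-correcting across groups. Groups with fewer than 2
#' members or fewer than 2 non-members are skipped with a warning.
#'
#' @param log2_ratios Named numeric vector of per-protein log2 ratios.
#' @param groups Named list of character vectors of protein ids.
#' @return Data frame with `group`, `n`, `median`, `q25`, `q75`, `p_value`,
#'   `q_value`.
#' @export
group_polarization_test <- function(log2_ratios, groups) {
  if (is.null(names(log2_ratios))) stop("'log2_ratios' must be named")
  rows <- lapply(names(groups), function(g) {
    members <- names(log2_ratios) %in% groups[[g]]
    if (sum(members) < 2L || sum(!members) < 2L) {
      warning("skipping group '", g, "': degenerate size")
      return(NULL)
    }
    x <- log2_ratios[members]
    data.frame(
      group = g, n = sum(members),
      median = stats::median(x),
      q25 = unname(stats::quantile(x, 0.25)),
      q75 = unname(stats::quantile(x, 0.75)),
      p_value = exact_rank_sum_test(x, log2_ratios[!members])
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable groups")
  out$q_value <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Max-normalized apical/basal abundances
#'
#' Divides each side by the maximum of the pair, so the larger side is 1
#' (heatmap semantics). Both-zero pairs return (0, 0) with a message.
#'
#' @param apical_mean,basal_mean Nonnegative numeric vectors.
#' @return A data frame with `apical_norm` and `basal_norm`.
#' @export
max_normalize <- function(apical_mean, basal_mean) {
  if (length(apical_mean) != length(basal_mean)) stop("length mismatch")
  if (any(apical_mean < 0 | basal_mean < 0)) stop("inputs must be nonnegative")
  mx <- pmax(apical_mean, basal_mean)
  zero <- mx == 0
  if (any(zero)) message(sum(zero), " pair(s) with both sides zero -> (0, 0)")
  mx[zero] <- 1
  data.frame(apical_norm = apical_mean / mx, basal_norm = basal_mean / mx)
}

#' Restrict to cytoplasmic proteins and renormalize
#'
#' Excludes proteins annotated solely as nuclear and ECM (Matrisome)
#' proteins, then re-divides each sample column by its new sum. Used to
#' check that group-polarization conclusions survive removal of the
#' basally-enriched nuclear and matrix material.
#'
#' @param tbl A normalized [protein_table()].
#' @param nuclear_only Character vector of nuclear-only protein ids.
#' @param ecm Character vector of ECM (Matrisome) protein ids.
#' @return The filtered, renormalized [protein_table()].
#' @export
cytoplasmic_subset <- function(tbl, nuclear_only, ecm) {
  stopifnot(inherits(tbl, "protein_table"))
  drop <- rownames(tbl$values) %in% c(nuclear_only, ecm)
  if (all(drop)) stop("no proteins remain after the cytoplasmic filter")
  x <- .subset_protein_table(tbl, rows = which(!drop))
  sums <- colSums(x$values, na.rm = TRUE)
  if (any(sums == 0)) stop("sample(s) with zero abundance after refiltering")
  x$values <- sweep(x$values, 2, sums, "/")
  x$normalized <- TRUE
  x
}
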