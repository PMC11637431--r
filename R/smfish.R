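# smFISH statistics: area-normalized spot-intensity polarization,
# background-subtracted median-intensity ratio tests per subject, Fisher
# combination across subjects, and compartment-width morphometry.

#' Spot-density polarization from paired segmentations
#'
#' Spot intensity sums are normalized by segmented area and the log2
#' apical/basal density ratio is computed per paired segmentation; the mean
#' and standard error over pairs are returned. Pairs with zero basal density
#' are dropped with a warning.
#'
#' @param spots A `"fish_measurements"` data frame (or any data frame with
#'   `apical_spot_sum`, `basal_spot_sum`, `apical_area`, `basal_area`).
#' @return A list with `log2_ratios`, `mean`, `sem`, `n_pairs`.
#' @export
spot_polarization <- function(spots) {
  need <- c("apical_spot_sum", "basal_spot_sum", "apical_area", "basal_area")
  if (!all(need %in% names(spots))) {
    stop("missing columns: ", paste(setdiff(need, names(spots)), collapse = ", "))
  }
  if (any(spots$apical_area <= 0 | spots$basal_area <= 0)) {
    stop("segmented areas must be positive")
  }
  a <- spots$apical_spot_sum / spots$apical_area
  b <- spots$basal_spot_sum / spots$basal_area
  drop <- b == 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " pair(s) with zero basal spot density")
    a <- a[!drop]
    b <- b[!drop]
  }
  if (length(a) == 0L) stop("no usable segmentation pairs")
  r <- log2(a / b)
  list(log2_ratios = r, mean = mean(r),
       sem = stats::sd(r) / sqrt(length(r)), n_pairs = length(r))
}

#' Per-subject intensity-ratio tests (both one-sided alternatives)
#'
#' Subtracts the matched background from the apical and basal median
#' intensities of each cell (clamping nonpositive results at `1e-12`, with
#' clamped cells flagged), forms per-cell apical/basal ratios, and per
#' subject runs two exact one-sided signed-rank tests of the log ratios
#' against zero (one right-tailed, one left-tailed). Reports the minimum of
#' the two p-values and the winning direction per subject; subjects with
#' fewer than 2 valid cells are excluded with a warning.
#'
#' @param measurements A `"fish_measurements"` data frame.
#' @return Data frame with one row per subject: `subject`, `n_cells`,
#'   `n_clamped`, `median_ratio`, `min_p`, `direction`.
#' @export
intensity_ratio_test <- function(measurements) {
  need <- c("subject", "apical_intensity", "basal_intensity",
            "apical_background", "basal_background")
  if (!all(need %in% names(measurements))) {
    stop("missing columns: ",
         paste(setdiff(need, names(measurements)), collapse = ", "))
  }
  eps <- 1e-12
  a <- measurements$apical_intensity - measurements$apical_background
  b <- measurements$basal_intensity - measurements$basal_background
  clamped <- a <= 0 | b <= 0
  a <- pmax(a, eps)
  b <- pmax(b, eps)
  ratio <- log2(a / b)
  rows <- lapply(unique(measurements$subject), function(s) {
    sel <- measurements$subject == s
    if (sum(sel) < 2L) {
      warning("excluding subject '", s, "': fewer than 2 cells")
      return(NULL)
    }
    r <- ratio[sel]
    p_up <- exact_signed_rank_test(r, alternative = "greater")
    p_dn <- exact_signed_rank_test(r, alternative = "less")
    data.frame(
      subject = s, n_cells = sum(sel), n_clamped = sum(clamped[sel]),
      median_ratio = stats::median(r),
      min_p = min(p_up, p_dn),
      direction = if (p_up <= p_dn) "apical" else "basal"
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no subject with at least 2 valid cells")
  rownames(out) <- NULL
  out
}

#' Combine per-subject minimum p-values across a cohort
#'
#' Applies [fisher_combine()] to the per-subject `min_p` values of
#' [intensity_ratio_test()], mirroring the procedure of taking the smaller
#' of the two one-sided tests per subject and combining across subjects.
#' Note this min-of-two-one-sided construction (without doubling) is mildly
#' anti-conservative; it is reproduced as such deliberately.
#'
#' @param subject_table Output of [intensity_ratio_test()].
#' @return A list of class `"combined_test"`: `per_subject`,
#'   `fisher_statistic`, `fisher_df`, `combined_p`, `consensus_direction`.
#' @export
combine_subject_tests <- function(subject_table) {
  if (!all(c("subject", "min_p", "direction") %in% names(subject_table))) {
    stop("expected the output of intensity_ratio_test()")
  }
  fc <- fisher_combine(subject_table$min_p)
  dirs <- table(subject_table$direction)
  structure(
    list(
      per_subject = subject_table,
      fisher_statistic = fc$statistic,
      fisher_df = fc$df,
      combined_p = fc$p_value,
      consensus_direction = names(dirs)[which.max(dirs)]
    ),
    class = "combined_test"
  )
}

#' @export
print.combined_test <- function(x, ...) {
  cat("Fisher-combined intensity-ratio test over",
      nrow(x$per_subject), "subjects\n")
  cat("  X =", format(x$fisher_statistic, digits = 5),
      "on", x$fisher_df, "df; combined p =",
      format(x$combined_p, digits = 4), "\n")
  cat("  consensus direction:", x$consensus_direction, "\n")
  invisible(x)
}

#' Apical/basal compartment width morphometry
#'
#' Per-cell log2(apical width / basal width) ratios, per-side mean and
#' median summaries, and a two-sided Wilcoxon rank-sum test comparing the
#' apical and basal width samples. Cells with a nonpositive width are
#' dropped with a warning.
#'
#' @param widths Data frame with columns `apical_width` and `basal_width`,
#'   one row per cell.
#' @return A list with `log2_ratios`, `apical_mean`, `basal_mean`,
#'   `apical_median`, `basal_median`, `p_value`, `n_cells`.
#' @export
compartment_morphometry <- function(widths) {
  if (!all(c("apical_width", "basal_width") %in% names(widths))) {
    stop("need columns apical_width and basal_width")
  }
  bad <- widths$apical_width <= 0 | widths$basal_width <= 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " cell(s) with nonpositive width")
    widths <- widths[!bad, , drop = FALSE]
  }
  if (nrow(widths) == 0L) stop("no cells with positive widths")
  r <- log2(widths$apical_width / widths$basal_width)
  list(
    log2_ratios = r,
    apical_mean = mean(widths$apical_width),
    basal_mean = mean(widths$basal_width),
    apical_median = stats::median(widths$apical_width),
    basal_median = stats::median(widths$basal_width),
    p_value = exact_rank_sum_test(widths$apical_width, widths$basal_width),
    n_cells = nrow(widths)
  )
}
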