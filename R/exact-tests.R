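# Exact nonparametric tests used throughout the pipeline.
#
# Cohort sizes in LCM designs are small (5-8 subjects), so normal
# approximations to the Wilcoxon null are unreliable and every test here is
# computed from the exact null distribution. Ties are mid-ranked; doubling
# mid-ranks makes every rank score an integer, so the null distribution of
# the (doubled) statistic is obtained by the standard count-generating
# polynomial recursion, which is exact for any tie pattern.

# Distribution of the doubled signed-rank statistic over all 2^n sign
# assignments: counts[w + 1] = number of assignments with doubled statistic w.
.signed_rank_null_counts <- function(doubled_ranks) {
  total <- sum(doubled_ranks)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (s in doubled_ranks) {
    shifted <- c(numeric(s), counts[seq_len(total + 1 - s)])
    counts <- counts + shifted
  }
  counts
}

# Cache: genome-wide scans reuse the same rank multiset for almost every gene.
.null_cache <- new.env(parent = emptyenv())

.signed_rank_null_cached <- function(doubled_ranks) {
  key <- paste(sort(doubled_ranks), collapse = ",")
  got <- .null_cache[[key]]
  if (is.null(got)) {
    got <- .signed_rank_null_counts(doubled_ranks)
    if (length(.null_cache) < 4096L) .null_cache[[key]] <- got
  }
  got
}

#' Exact Wilcoxon signed-rank test
#'
#' Computes the exact p-value of the Wilcoxon signed-rank statistic for a
#' vector of paired differences (here, per-subject log2 apical/basal ratios).
#' Zeros are dropped before ranking and ties are mid-ranked; the null
#' distribution of the statistic is then computed exactly over all `2^n` sign
#' assignments of the ranked absolute differences, so the p-value is exact
#' for any tie pattern and any `n`. The two-sided p-value doubles the smaller
#' tail (capped at 1).
#'
#' @param diffs Numeric vector of paired differences.
#' @param alternative One of `"two.sided"`, `"greater"`, `"less"`. `"greater"`
#'   tests for differences shifted above zero.
#' @return The exact p-value. If all differences are zero the test is
#'   degenerate and the p-value is 1 (with a message).
#' @examples
#' exact_signed_rank_test(c(0.4, 1.1, 0.7, 2.3))  # 2/16
#' @export
exact_signed_rank_test <- function(diffs,
                                   alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is.numeric(diffs) || length(diffs) == 0L) {
    stop("'diffs' must be a non-empty numeric vector")
  }
  if (anyNA(diffs)) stop("'diffs' contains NA")
  d <- diffs[diffs != 0]
  if (length(d) == 0L) {
    message("all differences are zero; signed-rank test degenerate, p = 1")
    return(1)
  }
  r <- rank(abs(d))
  dr <- as.integer(round(2 * r))       # mid-ranks doubled: exact integers
  counts <- .signed_rank_null_cached(dr)
  w <- sum(dr[d > 0])                  # doubled statistic
  total <- 2^length(d)
  p_ge <- sum(counts[(w + 1):length(counts)]) / total
  p_le <- sum(counts[1:(w + 1)]) / total
  switch(alternative,
    greater   = p_ge,
    less      = p_le,
    two.sided = min(1, 2 * min(p_ge, p_le))
  )
}

# Number of size-k subsets of the doubled combined ranks attaining each rank
# sum; counts[[k + 1]][s + 1] over subsets of size k with doubled sum s.
.rank_sum_null_counts <- function(doubled_ranks, k) {
  total <- sum(doubled_ranks)
  tab <- vector("list", k + 1L)
  tab[[1L]] <- c(1, numeric(total))
  for (j in seq_len(k)) tab[[j + 1L]] <- numeric(total + 1)
  for (s in doubled_ranks) {
    for (j in rev(seq_len(k))) {
      shifted <- c(numeric(s), tab[[j]][seq_len(total + 1 - s)])
      tab[[j + 1L]] <- tab[[j + 1L]] + shifted
    }
  }
  tab[[k + 1L]]
}

#' Exact Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-group comparison on ranks with an exact, tie-aware null: under the
#' null every assignment of the combined mid-ranks to the two groups is
#' equally likely, and the distribution of the first group's rank sum is
#' enumerated by a subset-sum recursion. Used for cross-species per-gene
#' comparisons and protein-group-versus-rest tests. For large groups
#' (combined n > `exact_limit`) the tie-corrected normal approximation with
#' continuity correction is used instead.
#'
#' @param x,y Numeric samples for the two groups.
#' @param alternative `"two.sided"`, `"greater"` (x shifted above y) or
#'   `"less"`.
#' @param exact_limit Largest combined sample size for which the exact null
#'   is enumerated.
#' @return The p-value.
#' @examples
#' exact_rank_sum_test(c(5, 6, 7), c(1, 2, 3))  # 2/C(6,3) = 0.1
#' @export
exact_rank_sum_test <- function(x, y,
                                alternative = c("two.sided", "greater", "less"),
                                exact_limit = 40L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("inputs contain NA")
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n1 + n2 <= exact_limit) {
    dr <- as.integer(round(2 * r))
    counts <- .rank_sum_null_counts(dr, n1)
    total <- choose(n1 + n2, n1)
    w2 <- as.integer(round(2 * w))
    p_ge <- sum(counts[(w2 + 1):length(counts)]) / total
    p_le <- sum(counts[1:(w2 + 1)]) / total
  } else {
    # tie-corrected normal approximation, continuity-corrected
    n <- n1 + n2
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    p_ge <- stats::pnorm(w - 0.5, mu, sigma, lower.tail = FALSE)
    p_le <- stats::pnorm(w + 0.5, mu, sigma)
  }
  switch(alternative,
    greater   = p_ge,
    less      = p_le,
    two.sided = min(1, 2 * min(p_ge, p_le))
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1 and
#' mapped back to the input order (delegates to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`; `NA` entries are
#'   propagated.
#' @return Vector of q-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("'p_values' must be numeric")
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Combine p-values by Fisher's method
#'
#' Aggregates independent per-subject p-values into one test:
#' `X = -2 * sum(log(p_i))` is compared to a chi-square distribution with
#' `2k` degrees of freedom. With a single p-value the combined p equals the
#' input exactly.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return A list with `statistic` (X), `df` (`2 * length(p_values)`) and
#'   `p_value`.
#' @examples
#' fisher_combine(c(0.05, 0.05))
#' @export
fisher_combine <- function(p_values) {
  if (!is.numeric(p_values) || length(p_values) == 0L) {
    stop("'p_values' must be a non-empty numeric vector")
  }
  if (anyNA(p_values)) stop("'p_values' contains NA")
  if (any(p_values <= 0)) stop("p-values must be > 0 (log undefined at 0)")
  if (any(p_values > 1)) stop("p-values must be <= 1")
  x <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(
    statistic = x,
    df = df,
    p_value = stats::pchisq(x, df = df, lower.tail = FALSE)
  )
}
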