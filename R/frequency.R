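#' Mutation frequency from plating counts
#'
#' Estimates the fraction of mutant cells in a culture from parallel
#' selective and nonselective platings:
#'
#' \deqn{f = \frac{n_{sel} \times d_{sel}}{n_{nonsel} \times d_{nonsel}}}
#'
#' where the n are colony counts and the d are fold-dilution factors of the
#' plated aliquots (>= 1), so that count times factor estimates cells in the
#' undiluted suspension. The result is dimensionless (a frequency, distinct
#' from a mutation rate).
#'
#' @param n_selective,n_nonselective Colony counts (non-negative integers)
#'   on the selective and nonselective plates; `n_nonselective` must be > 0.
#' @param d_selective,d_nonselective Fold-dilution factors (>= 1).
#' @param culture_id Optional id(s) used in error messages.
#' @return Numeric vector of frequencies.
#' @examples
#' mutation_frequency(30, 1e2, 150, 1e5)  # 2e-4
#' @export
mutation_frequency <- function(n_selective, d_selective,
                               n_nonselective, d_nonselective,
                               culture_id = NULL) {
  stopifnot(all(n_selective >= 0), all(n_nonselective >= 0),
            all(d_selective >= 1), all(d_nonselective >= 1))
  bad <- which(n_nonselective == 0)
  if (length(bad) > 0) {
    who <- if (is.null(culture_id)) paste("culture", bad)
           else culture_id[bad]
    stop("undefined mutation frequency (zero nonselective count) for: ",
         paste(who, collapse = ", "))
  }
  (as.numeric(n_selective) * as.numeric(d_selective)) /
    (as.numeric(n_nonselective) * as.numeric(d_nonselective))
}

#' Read plating measurements from TSV
#'
#' Expects columns `culture_id`, `group`, `n_selective`, `d_selective`,
#' `n_nonselective`, `d_nonselective`.
#'
#' @param path TSV path.
#' @return Data frame with an added `frequency` column.
#' @export
read_plating <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("culture_id", "group", "n_selective", "d_selective",
            "n_nonselective", "d_nonselective")
  if (!all(need %in% names(df))) {
    stop("plating TSV must have columns: ", paste(need, collapse = ", "))
  }
  df$frequency <- mutation_frequency(df$n_selective, df$d_selective,
                                     df$n_nonselective, df$d_nonselective,
                                     culture_id = df$culture_id)
  df
}

#' Per-group median mutation frequencies
#'
#' Cultures are grouped by their label (replicates of the same strain and
#' guide are pooled) and summarized by the group median, the summary
#' statistic used for all frequency comparisons in this package.
#'
#' @param frequency Numeric vector of per-culture frequencies.
#' @param group Grouping vector, same length.
#' @return Data frame with columns `group`, `n`, `median`.
#' @export
frequency_summary <- function(frequency, group) {
  stopifnot(length(frequency) == length(group), length(frequency) > 0)
  groups <- unique(group)
  data.frame(
    group = groups,
    n = vapply(groups, function(g) sum(group == g), 0L),
    median = vapply(groups, function(g) stats::median(frequency[group == g]),
                    0),
    stringsAsFactors = FALSE
  )
}

#' Fold change of group medians
#'
#' @param summary Data frame from [frequency_summary()].
#' @param group Group of interest.
#' @param reference_group Group to divide by.
#' @return Ratio of medians (group over reference); `Inf` with a warning
#'   when the reference median is zero.
#' @export
fold_change <- function(summary, group, reference_group) {
  m <- summary$median[match(c(group, reference_group), summary$group)]
  if (any(is.na(m))) stop("unknown group in fold_change")
  if (m[2] == 0) {
    warning("reference group median is zero: fold change is infinite")
    return(Inf)
  }
  m[1] / m[2]
}

# Number of size-m subsets of ranks 1..N summing to s, for all s:
# dynamic-programming enumeration of the null rank-sum distribution.
ranksum_counts <- function(m, N) {
  smax <- sum((N - m + 1):N)
  # dp[k+1, s+1] = number of k-subsets of {1..i} with sum s
  dp <- matrix(0, nrow = m + 1, ncol = smax + 1)
  dp[1, 1] <- 1
  for (i in seq_len(N)) {
    for (k in min(i, m):1) {
      reach <- smax - i
      if (reach < 0) next
      idx <- 0:reach
      dp[k + 1, idx + i + 1] <- dp[k + 1, idx + i + 1] + dp[k, idx + 1]
    }
  }
  dp[m + 1, ]  # index s+1 holds count for rank sum s
}

#' Exact two-tailed Mann-Whitney U test
#'
#' Computes the Mann-Whitney U statistic with mid-ranks for ties and a
#' two-tailed p-value, `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' The null distribution is obtained by one of three routes, recorded in the
#' result: without ties and with `length(x) + length(y) <= exact_limit`, by
#' exact dynamic-programming enumeration of the rank-sum distribution; with
#' ties, by exact enumeration of all distinct group assignments of the
#' pooled mid-ranks when the number of assignments is feasible (<=
#' `max_enumeration`); otherwise by the normal approximation with tie
#' correction and continuity correction.
#'
#' Complete separation of two groups of six gives p = 2/924, which prints as
#' 0.0022 at four decimals.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_limit Largest pooled size for the no-tie exact route
#'   (default 20).
#' @param max_enumeration Cap on enumerated assignments for the tied exact
#'   route (default 2e5).
#' @return List with `U` (for sample `x`), `p`, and `method` (one of
#'   `"exact"`, `"exact_permutation"`, `"normal_approx"`).
#' @examples
#' mann_whitney_exact(7:12, 1:6)$p  # 2/924
#' @export
mann_whitney_exact <- function(x, y, exact_limit = 20L,
                               max_enumeration = 2e5) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0

  if (!ties && N <= exact_limit) {
    counts <- ranksum_counts(m, N)
    W <- U + m * (m + 1) / 2  # rank sum for x
    total <- choose(N, m)
    p_le <- sum(counts[1:(W + 1)]) / total  # counts indexed by rank sum + 1
    p_ge <- sum(counts[(W + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(U = U, p = p, method = "exact"))
  }

  if (ties && choose(N, m) <= max_enumeration) {
    combs <- utils::combn(N, m)
    offset <- m * (m + 1) / 2
    us <- colSums(matrix(r[combs], nrow = m)) - offset
    eps <- sqrt(.Machine$double.eps)
    p_le <- mean(us <= U + eps)
    p_ge <- mean(us >= U - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(U = U, p = p, method = "exact_permutation"))
  }

  # normal approximation with tie correction and continuity correction
  tie_tab <- table(r)
  mu <- m * n / 2
  sigma2 <- (m * n / 12) * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p = p, method = "normal_approx")
}

#' Spearman rank correlation
#'
#' Rank correlation with mid-ranks for ties, used e.g. to relate per-guide
#' mutation frequencies to counts of inactivating non-target-strand
#' cytosines.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Spearman's rho; `NA` with a warning for constant input.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant input: rank correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}
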