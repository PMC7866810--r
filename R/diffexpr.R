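#' Column-wise ranks of a matrix
#'
#' Replaces each column by its ranks 1..n_rows, ties receiving the mean of
#' the tied ranks. This is the rank kernel underlying the resampled Wilcoxon
#' test, implemented in plain vectorized R.
#'
#' @param m numeric matrix with finite entries.
#' @return matrix of the same shape holding column-wise ranks.
#' @examples
#' rank_columns(cbind(c(3, 1, 2), c(2, 2, 5)))
#' @export
rank_columns <- function(m) {
  m <- as.matrix(m)
  if (length(m) == 0) stop("empty matrix")
  if (any(!is.finite(m))) stop("non-finite entries")
  apply(m, 2, rank, ties.method = "average")
}

# Standardized Wilcoxon rank-sum z for every gene at once:
# ranks is genes x cells (per-gene ranks across cells), y2 a 0/1 indicator
# matrix cells x n_label_sets. Returns genes x n_label_sets.
.ranksum_z <- function(ranks, y2) {
  n <- nrow(y2)
  n2 <- colSums(y2)
  n1 <- n - n2
  e <- n2 * (n + 1) / 2
  v <- n1 * n2 * (n + 1) / 12
  sweep(sweep(ranks %*% y2, 2, e), 2, sqrt(v), "/")
}

#' Resampled Wilcoxon two-class differential expression with permutation FDR
#'
#' A significance analysis for sequencing counts: library sizes are
#' equalized by Poisson downsampling of every cell to the minimum
#' sequencing depth, the standardized Wilcoxon rank-sum statistic is
#' computed per gene on the downsampled counts, and both steps are averaged
#' over `n_resamples` draws. The null distribution comes from
#' `n_permutations` random label permutations applied to the same resampled
#' rank matrices, and q-values are estimated SAM-style: at each observed
#' |statistic| cut-point, FDR = median permuted call count / observed call
#' count, monotonized so q never decreases as the cut-point weakens.
#'
#' The test runs on raw counts with spike-ins excluded; normalized input
#' would double-correct the depths.
#'
#' @param table ExpressionTable of raw counts.
#' @param groups two-level factor (or coercible) over the cells.
#' @param n_resamples downsampling draws averaged per statistic (default 20).
#' @param n_permutations label permutations for the null (default 100).
#' @param fdr_threshold q-value call threshold (default 0.05).
#' @param fold_change_min minimum linear fold change for a call (default 1).
#' @param seed RNG seed.
#' @return `DETable`: data.frame (gene, statistic, mean_a, mean_b, log2_fc,
#'   q_value, direction, called) ordered as the input genes, with the
#'   parameters as attributes. Fold changes are log2 with pseudocount 0.5 on
#'   depth-equalized group means.
#' @export
samseq_two_class <- function(table, groups, n_resamples = 20,
                             n_permutations = 100, fdr_threshold = 0.05,
                             fold_change_min = 1, seed = 1) {
  stopifnot(inherits(table, "ExpressionTable"),
            n_resamples >= 1, n_permutations >= 10,
            fdr_threshold > 0, fdr_threshold < 1)
  counts <- table$counts[!table$is_spikein, , drop = FALSE]
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  if (any(table(groups) == 0)) stop("empty group")
  n <- ncol(counts); m <- nrow(counts)
  depth <- colSums(counts)
  rate <- min(depth) / depth
  set.seed(seed)
  y <- as.integer(groups == levels(groups)[2])
  yperm <- vapply(seq_len(n_permutations), function(p) sample(y), integer(n))
  stat <- numeric(m)
  stat_perm <- matrix(0, m, n_permutations)
  thin <- rate < 1            # cells already at the minimum depth keep
  for (r in seq_len(n_resamples)) {   # their counts (thinning rate 1)
    xr <- counts
    if (any(thin))
      xr[, thin] <- matrix(
        stats::rpois(m * sum(thin), t(t(counts[, thin, drop = FALSE]) *
                                        rate[thin])), m)
    ranks <- t(rank_columns(t(xr)))             # per-gene ranks across cells
    stat <- stat + .ranksum_z(ranks, cbind(y))[, 1]
    stat_perm <- stat_perm + .ranksum_z(ranks, yperm)
  }
  stat <- stat / n_resamples
  stat_perm <- stat_perm / n_resamples
  # SAM-style q-values on |statistic| cut-points: FDR(t) = median permuted
  # call count / observed call count, then each gene takes the minimum FDR
  # over cut-points at or below its own |statistic| (monotone in |stat|).
  a <- abs(stat)
  ord <- order(a, decreasing = TRUE)
  thr <- a[ord]
  n_ge <- function(sorted_vals, t)      # #{v >= t}, sorted_vals ascending
    length(sorted_vals) - findInterval(t, sorted_vals, left.open = TRUE)
  obs_calls <- n_ge(sort(a), thr)
  perm_cnt <- vapply(seq_len(n_permutations), function(p)
    n_ge(sort(abs(stat_perm[, p])), thr), numeric(m))
  perm_calls <- apply(perm_cnt, 1, stats::median)
  # permutation-resolution floor: a cut-point no permutation exceeds is
  # still uncertain at the resolution of the permutation ensemble, so one
  # pseudo-exceedance is added (the Phipson-Smyth correction); without it
  # the maximal observed statistic gets FDR 0 in half of all null datasets
  fdr <- pmin(1, (perm_calls + 1) / obs_calls)
  q <- numeric(m)
  q[ord] <- rev(cummin(rev(fdr)))
  q[a == 0] <- 1
  eq <- t(t(counts) * rate)                      # expected depth-equalized
  mean_a <- rowMeans(eq[, groups == levels(groups)[1], drop = FALSE])
  mean_b <- rowMeans(eq[, groups == levels(groups)[2], drop = FALSE])
  log2_fc <- log2((mean_b + 0.5) / (mean_a + 0.5))
  de_table(data.frame(gene = rownames(counts), statistic = stat,
                      mean_a = mean_a, mean_b = mean_b, log2_fc = log2_fc,
                      q_value = q, row.names = NULL,
                      stringsAsFactors = FALSE),
           fdr_threshold, fold_change_min,
           params = list(test = "samseq", n_resamples = n_resamples,
                         n_permutations = n_permutations, seed = seed,
                         groups = levels(groups)))
}

de_table <- function(df, fdr_threshold, fold_change_min, params) {
  df$direction <- ifelse(df$log2_fc >= 0, "up", "down")
  df$called <- df$q_value <= fdr_threshold &
    abs(df$log2_fc) >= log2(fold_change_min)
  structure(df, class = c("DETable", "data.frame"),
            fdr_threshold = fdr_threshold,
            fold_change_min = fold_change_min, params = params)
}

#' @export
print.DETable <- function(x, ...) {
  cat(sprintf("DETable (%s): %d genes, %d called at FDR <= %g\n",
              attr(x, "params")$test, nrow(x), sum(x$called),
              attr(x, "fdr_threshold")))
  print.data.frame(utils::head(x[order(x$q_value), ], 10))
  invisible(x)
}

#' Binomial cluster-marker test
#'
#' Marker detection for one cluster against all remaining cells by binomial
#' counting statistics: with \eqn{T} the total read count of the target
#' cluster and \eqn{p_0} the gene's count share among the remaining cells
#' (pseudocount 0.5 on numerator and denominator), the gene's target count
#' \eqn{x} is referred to Binomial(\eqn{T, p_0}); the two-sided p-value is
#' \eqn{2 \min(P(X \ge x), P(X \le x), 0.5)}. q-values are
#' Benjamini-Hochberg; fold change is \eqn{(x/T)/p_0}.
#'
#' @param table ExpressionTable of raw counts.
#' @param labels cluster labels over the cells.
#' @param target_cluster the cluster whose markers are sought.
#' @param fdr_threshold q-value call threshold (default 0.05).
#' @param fold_change_min minimum linear fold change for a call (default 1).
#' @return `DETable` (mean_a = remaining-cell mean, mean_b = target mean).
#' @export
binomial_cluster_markers <- function(table, labels, target_cluster,
                                     fdr_threshold = 0.05,
                                     fold_change_min = 1) {
  stopifnot(inherits(table, "ExpressionTable"))
  counts <- table$counts[!table$is_spikein, , drop = FALSE]
  in_t <- labels == target_cluster
  if (!any(in_t)) stop("target cluster is empty")
  if (all(in_t)) stop("target cluster is the only cluster")
  x <- rowSums(counts[, in_t, drop = FALSE])
  rest <- rowSums(counts[, !in_t, drop = FALSE])
  T_tot <- sum(x)
  if (T_tot == 0) stop("target cluster has zero total counts")
  p0 <- (rest + 0.5) / (sum(rest) + 0.5)
  upper <- stats::pbinom(x - 1, T_tot, p0, lower.tail = FALSE)
  lower <- stats::pbinom(x, T_tot, p0)
  p <- 2 * pmin(upper, lower, 0.5)
  q <- stats::p.adjust(p, method = "BH")
  fc <- (x / T_tot) / p0
  de_table(data.frame(gene = rownames(counts), statistic = x,
                      mean_a = rest / sum(!in_t), mean_b = x / sum(in_t),
                      p_value = p, log2_fc = log2(fc), q_value = q,
                      row.names = NULL, stringsAsFactors = FALSE),
           fdr_threshold, fold_change_min,
           params = list(test = "binomial", target = target_cluster))
}

#' Volcano table of a differential-expression result
#'
#' @param de DETable.
#' @return data.frame (gene, log2_fc, neg_log10_q, significant) with one row
#'   per gene; q-values are floored at machine epsilon before the log.
#' @export
volcano_table <- function(de) {
  stopifnot(inherits(de, "DETable"))
  data.frame(gene = de$gene, log2_fc = de$log2_fc,
             neg_log10_q = -log10(pmax(de$q_value, .Machine$double.eps)),
             significant = de$called, stringsAsFactors = FALSE)
}

#' Volcano plot
#'
#' @param de DETable.
#' @param ... passed to [graphics::plot()].
#' @export
plot_volcano <- function(de, ...) {
  v <- volcano_table(de)
  graphics::plot(v$log2_fc, v$neg_log10_q,
                 col = ifelse(v$significant, "red", "grey40"), pch = 16,
                 xlab = expression(log[2] ~ "fold change"),
                 ylab = expression(-log[10] ~ "q"), ...)
  invisible(v)
}
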