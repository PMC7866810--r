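#' Estimate per-cell size factors and normalize counts
#'
#' Two interpretations of depth normalization are provided. The default,
#' `scale_to_median_total`, scales every cell so that its total biological
#' count equals the median total across cells (the behaviour of the
#' instantaneous-median scaling used by RaceID-style tools). The alternative,
#' `median_of_ratios`, is the DESeq-style estimator: per cell, the median
#' over genes of the ratio of the gene's count to its across-cell geometric
#' mean, computed on genes expressed in every cell, rescaled so the factors
#' have geometric mean 1.
#'
#' Spike-in rows are excluded from factor estimation but divided by the same
#' factors, so technical noise is assessed on the normalized scale.
#'
#' @param table ExpressionTable of raw counts.
#' @param method `"scale_to_median_total"` (default) or `"median_of_ratios"`.
#' @return `NormalizationResult`: list with `size_factors` (positive, one per
#'   cell), `normalized` (genes x cells, counts / size factor), `method`,
#'   and the input `table`.
#' @examples
#' tab <- expression_table(matrix(c(10, 40, 5, 20, 20, 80), 2,
#'   dimnames = list(c("G1", "G2"), c("c1", "c2", "c3"))))
#' nr <- compute_size_factors(tab)
#' round(nr$size_factors, 3)
#' @export
compute_size_factors <- function(table,
                                 method = c("scale_to_median_total",
                                            "median_of_ratios")) {
  stopifnot(inherits(table, "ExpressionTable"))
  method <- match.arg(method)
  bio <- table$counts[!table$is_spikein, , drop = FALSE]
  totals <- colSums(bio)
  if (any(totals == 0))
    stop("cell(s) with zero total count: ",
         paste(table$cell_ids[totals == 0], collapse = ", "))
  if (method == "scale_to_median_total") {
    sf <- totals / stats::median(totals)
  } else {
    pos <- rowSums(bio > 0) == ncol(bio)
    if (!any(pos))
      stop("median_of_ratios: no gene is expressed in every cell; ",
           "consider the scale_to_median_total method or a pseudo-reference")
    ref <- exp(rowMeans(log(bio[pos, , drop = FALSE])))
    sf <- apply(bio[pos, , drop = FALSE] / ref, 2, stats::median)
    sf <- sf / exp(mean(log(sf)))
  }
  names(sf) <- table$cell_ids
  normalized <- sweep(table$counts, 2, sf, "/")
  structure(list(size_factors = sf, normalized = normalized,
                 method = method, table = table),
            class = "NormalizationResult")
}

#' @export
print.NormalizationResult <- function(x, ...) {
  cat(sprintf("NormalizationResult (%s): %d cells, size factors in [%.3g, %.3g]\n",
              x$method, length(x$size_factors),
              min(x$size_factors), max(x$size_factors)))
  invisible(x)
}

#' Filter genes by minimum expression and cells by minimum depth
#'
#' Keeps genes whose normalized expression is at least `minexpr` in at least
#' `minnumber` cells, and removes cells whose raw total count is below
#' `min_cell_counts`. The gene rule is evaluated on normalized values, the
#' cell rule on raw totals. Spike-in rows are always removed from the output,
#' which carries the matching normalized sub-matrix in its `normalized`
#' attribute for downstream clustering.
#'
#' `mode = "median10pct"` applies the conventional case-study setting:
#' `minexpr` is the overall median of the normalized biological values and
#' `minnumber` is 10% of the cells (rounded up), i.e. genes expressed below
#' the overall median in more than 90% of cells are excluded.
#'
#' @param norm NormalizationResult.
#' @param minexpr minimum normalized expression (ignored under `mode`).
#' @param minnumber minimum number of cells reaching `minexpr` (ignored
#'   under `mode`).
#' @param min_cell_counts minimum raw total per cell (default 0; the
#'   case studies use 1000).
#' @param mode optional convenience preset, currently `"median10pct"`.
#' @return Filtered ExpressionTable (raw counts, biological genes only) with
#'   attribute `normalized`.
#' @export
filter_by_expression <- function(norm, minexpr = 0, minnumber = 1,
                                 min_cell_counts = 0, mode = NULL) {
  stopifnot(inherits(norm, "NormalizationResult"))
  tab <- norm$table
  bio <- !tab$is_spikein
  keep_cells <- colSums(tab$counts) >= min_cell_counts
  if (!any(keep_cells)) stop("all cells removed by the depth filter")
  nrm <- norm$normalized[bio, keep_cells, drop = FALSE]
  if (!is.null(mode)) {
    mode <- match.arg(mode, "median10pct")
    minexpr <- stats::median(nrm)
    minnumber <- ceiling(0.10 * ncol(nrm))
  }
  stopifnot(minexpr >= 0, minnumber >= 1)
  keep_genes <- rowSums(nrm >= minexpr) >= minnumber
  if (!any(keep_genes))
    stop("all genes filtered out; relax minexpr/minnumber")
  out <- expression_table(
    tab$counts[bio, keep_cells, drop = FALSE][keep_genes, , drop = FALSE],
    is_spikein = rep(FALSE, sum(keep_genes)))
  attr(out, "normalized") <- nrm[keep_genes, , drop = FALSE]
  attr(out, "filter_params") <- list(minexpr = minexpr, minnumber = minnumber,
                                     min_cell_counts = min_cell_counts)
  out
}

#' Restrict a table to a designed gene list
#'
#' Keeps the intersection of the table's genes with `gene_list`, preserving
#' the table's gene order; list entries absent from the table are reported in
#' the `absent` attribute. Matching is exact (case-sensitive).
#'
#' @param table ExpressionTable.
#' @param gene_list character vector of gene IDs of interest.
#' @return ExpressionTable restricted to the intersection, with attribute
#'   `absent` listing the unmatched IDs.
#' @export
filter_by_gene_list <- function(table, gene_list) {
  stopifnot(inherits(table, "ExpressionTable"), length(gene_list) > 0)
  gene_list <- unique(gene_list)
  present <- table$gene_ids[table$gene_ids %in% gene_list]
  if (!length(present))
    stop("none of the listed genes are present in the table")
  out <- subset_table(table, genes = present)
  attr(out, "absent") <- setdiff(gene_list, table$gene_ids)
  out
}

#' Fit the spike-in technical-noise model
#'
#' Fits the CV-squared vs mean relation of the spike-ins,
#' \eqn{CV^2(\mu) = a_1/\mu + a_0}, by a gamma-family generalized linear
#' model with identity link on the regressor \eqn{1/\mu} (a generalized
#' least-squares fit appropriate for variance-of-variance heteroscedasticity).
#' Each biological gene is then tested for variability exceeding the
#' technical expectation inflated by a minimum biological dispersion:
#' the statistic \eqn{(n-1)\,\hat{v}_g / d_g} with
#' \eqn{d_g = (a_1 + \theta)\mu_g + (a_0 + \theta)\mu_g^2}
#' (\eqn{\theta} = `min_biol_disp`) is referred to a chi-square with
#' \eqn{n-1} degrees of freedom; genes with upper-tail p at most `alpha` are
#' flagged to keep.
#'
#' Spike-ins with mean below the `fit_quantile` quantile of positive spike-in
#' means are excluded from the curve fit (their CV-squared estimates are
#' dominated by sampling noise).
#'
#' @param norm NormalizationResult; means and variances are taken on the
#'   normalized scale.
#' @param alpha per-gene significance level (default 0.01).
#' @param min_biol_disp minimum squared biological coefficient of variation
#'   added to the technical expectation (default 0.25, i.e. CV 0.5).
#' @param fit_quantile lower quantile of spike-in means excluded from the
#'   curve fit (default 0.20).
#' @param min_spikeins minimum number of usable spike-ins (default 10).
#' @return `NoiseFit`: list with `a0`, `a1`, `min_biol_disp`, `alpha`,
#'   per-gene `p_values` and `keep` flags, and the spike-in `fit_data`.
#' @export
fit_technical_noise <- function(norm, alpha = 0.01, min_biol_disp = 0.25,
                                fit_quantile = 0.20, min_spikeins = 10) {
  stopifnot(inherits(norm, "NormalizationResult"))
  tab <- norm$table
  sp <- norm$normalized[tab$is_spikein, , drop = FALSE]
  if (nrow(sp) == 0) stop("no spike-in rows in the table")
  mu_s <- rowMeans(sp)
  usable <- mu_s > 0
  if (sum(usable) < min_spikeins)
    stop("need at least ", min_spikeins,
         " spike-ins with positive mean; have ", sum(usable))
  mu_s <- mu_s[usable]
  v_s <- apply(sp[usable, , drop = FALSE], 1, stats::var)
  cv2_s <- v_s / mu_s^2
  lo <- stats::quantile(mu_s, fit_quantile)
  use <- mu_s >= lo
  fit_df <- data.frame(cv2 = cv2_s[use], inv_mu = 1 / mu_s[use])
  start <- stats::coef(stats::lm(cv2 ~ inv_mu, data = fit_df))
  start <- pmax(start, c(1e-6, 1e-6))
  g <- tryCatch(
    stats::glm(cv2 ~ inv_mu, data = fit_df,
               family = stats::Gamma(link = "identity"),
               start = start),
    error = function(e) NULL)
  cf <- if (is.null(g)) start else stats::coef(g)
  a0 <- unname(cf[1]); a1 <- unname(cf[2])
  rng <- range(mu_s)
  if (any(a1 / rng + a0 <= 0))
    stop(sprintf("fitted noise curve non-positive on the spike-in range (a0 = %.4g, a1 = %.4g)",
                 a0, a1))
  bio <- norm$normalized[!tab$is_spikein, , drop = FALSE]
  n <- ncol(bio)
  mu_g <- rowMeans(bio)
  v_g <- apply(bio, 1, stats::var)
  denom <- (a1 + min_biol_disp) * mu_g + (a0 + min_biol_disp) * mu_g^2
  stat <- ifelse(denom > 0, v_g * (n - 1) / denom, 0)
  p <- stats::pchisq(stat, df = n - 1, lower.tail = FALSE)
  p[mu_g == 0] <- 1
  structure(list(a0 = a0, a1 = a1, min_biol_disp = min_biol_disp,
                 alpha = alpha, p_values = p, keep = p <= alpha,
                 fit_data = data.frame(mean = mu_s, cv2 = cv2_s,
                                       used = use)),
            class = "NoiseFit")
}

#' @export
print.NoiseFit <- function(x, ...) {
  cat(sprintf("NoiseFit: cv2(mu) = %.3g/mu + %.3g; %d / %d genes above noise at alpha = %g\n",
              x$a1, x$a0, sum(x$keep), length(x$keep), x$alpha))
  invisible(x)
}

#' Plot the spike-in noise fit
#'
#' Spike-in CV-squared against mean on log axes with the fitted technical
#' noise curve; biological genes flagged by the fit can be overlaid.
#'
#' @param x NoiseFit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.NoiseFit <- function(x, ...) {
  fd <- x$fit_data
  graphics::plot(fd$mean, fd$cv2, log = "xy", pch = 16,
                 col = ifelse(fd$used, "black", "grey"),
                 xlab = "mean normalized expression", ylab = expression(CV^2),
                 ...)
  mu <- exp(seq(log(min(fd$mean)), log(max(fd$mean)), length.out = 200))
  graphics::lines(mu, x$a1 / mu + x$a0, col = "red", lwd = 2)
  invisible(x)
}

#' Keep genes whose variability exceeds the technical noise level
#'
#' @param table ExpressionTable the fit's normalization was computed on
#'   (spike-ins are dropped from the output).
#' @param fit NoiseFit from [fit_technical_noise()].
#' @return ExpressionTable restricted to the kept biological genes, with the
#'   `normalized` attribute carried when the input table provides one.
#' @export
filter_by_noise <- function(table, fit) {
  stopifnot(inherits(table, "ExpressionTable"), inherits(fit, "NoiseFit"))
  bio_ids <- table$gene_ids[!table$is_spikein]
  keep <- bio_ids[bio_ids %in% names(which(fit$keep))]
  if (!length(keep))
    stop("no gene passes the technical-noise filter")
  subset_table(table, genes = keep)
}
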