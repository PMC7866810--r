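# Clustering operates on log2(x + 1) of normalized values when the table
# carries them (attribute "normalized" set by the filters), else of raw
# counts. Cells are observations (rows of the working matrix).

# Mclust resolves mclustBIC in the caller's environment, so it must be an
# explicit namespace import.
#' @importFrom mclust Mclust mclustBIC
NULL

.cluster_space <- function(table) {
  x <- attr(table, "normalized")
  if (is.null(x)) x <- table$counts
  t(log2(x[!table$is_spikein, , drop = FALSE] + 1))
}

#' Cell-to-cell distance matrix
#'
#' @param table ExpressionTable.
#' @param metric `"pearson"` (1 - Pearson correlation over genes),
#'   `"euclidean_correlation"` (Euclidean distance between rows of the
#'   cell-cell Pearson correlation matrix, the convention used for the
#'   distance heatmaps), or `"euclidean"`.
#' @return symmetric non-negative matrix with zero diagonal, cells as
#'   rows/columns.
#' @export
distance_matrix <- function(table,
                            metric = c("pearson", "euclidean_correlation",
                                       "euclidean")) {
  metric <- match.arg(metric)
  x <- .cluster_space(table)             # cells x genes
  if (nrow(x) < 2) stop("need at least 2 cells")
  if (metric != "euclidean") {
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0))
      stop("constant cell profile(s), correlation undefined: ",
           paste(rownames(x)[sds == 0], collapse = ", "))
    r <- stats::cor(t(x))
    d <- switch(metric,
                pearson = 1 - r,
                euclidean_correlation = as.matrix(stats::dist(r)))
  } else {
    d <- as.matrix(stats::dist(x))
  }
  diag(d) <- 0
  d[d < 0] <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

# Lloyd-style k-means under the 1 - Pearson dissimilarity: assignment to the
# nearest center by correlation distance, centroid recomputation in profile
# space. Returns labels, centers and the within-cluster dispersion
# W = sum_i d(x_i, center_{lab(i)}).
.kmeans_pearson <- function(x, k, iter_max = 100) {
  n <- nrow(x)
  centers <- x[sample.int(n, k), , drop = FALSE]
  lab <- rep(1L, n)
  for (it in seq_len(iter_max)) {
    d <- 1 - stats::cor(t(x), t(centers))        # n x k
    new_lab <- max.col(-d, ties.method = "first")
    for (j in seq_len(k)) {                      # re-seed empty clusters
      if (!any(new_lab == j)) {
        far <- which.max(d[cbind(seq_len(n), new_lab)])
        new_lab[far] <- j
      }
    }
    if (all(new_lab == lab) && it > 1) break
    lab <- new_lab
    centers <- do.call(rbind, lapply(seq_len(k), function(j)
      colMeans(x[lab == j, , drop = FALSE])))
  }
  d <- 1 - stats::cor(t(x), t(centers))
  list(labels = lab, centers = centers,
       W = sum(d[cbind(seq_len(n), lab)]))
}

# Within-cluster dispersion for a given k under either distance, best of
# `restarts` runs. k = 1 is the dispersion around the grand center.
.kmeans_fit <- function(x, k, distance, restarts) {
  if (k == 1) {
    ctr <- matrix(colMeans(x), 1, dimnames = list(NULL, colnames(x)))
    W <- if (distance == "euclidean") sum(sweep(x, 2, ctr)^2)
         else sum(1 - stats::cor(t(x), t(ctr)))
    return(list(labels = rep(1L, nrow(x)), centers = ctr, W = W))
  }
  if (distance == "euclidean") {
    km <- stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100)
    return(list(labels = km$cluster, centers = km$centers,
                W = km$tot.withinss))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- .kmeans_pearson(x, k)
    if (is.null(best) || fit$W < best$W) best <- fit
  }
  best
}

#' k-means clustering with gap-statistic selection of the cluster number
#'
#' Runs seeded k-means (best of `restarts` starts by within-cluster
#' dispersion) for every k in `k_range`, computes the gap statistic
#' \eqn{gap(k) = \bar{E}\log W_k^{ref} - \log W_k} against `gap_refs`
#' reference datasets drawn uniformly over the per-gene data range, and
#' chooses the smallest k whose gap reaches the saturation level:
#' \eqn{gap(k) \ge gap(k+1) - s_{k+1}} with
#' \eqn{s_k = sd_b(\log W_k^{ref})\sqrt{1 + 1/B}} (the standard
#' first-crossing rule). Under the default `"pearson"` distance, assignment
#' uses the 1 - correlation dissimilarity with centroid recomputation in
#' profile space; `"euclidean"` is classical Lloyd.
#'
#' @param table ExpressionTable (clustered on log2(normalized + 1)).
#' @param k_range candidate cluster numbers (default 1:10, truncated to
#'   n_cells - 1).
#' @param distance `"pearson"` (default) or `"euclidean"`.
#' @param gap_refs number of uniform reference datasets B (default 50).
#' @param restarts k-means restarts per k (default 10).
#' @param seed RNG seed; recorded in the result.
#' @param k_fix optional fixed k bypassing gap selection (the gap curve is
#'   still computed and stored).
#' @return `ClusteringResult` with `labels` (1..k, named by cell), `k`,
#'   `centers` (k x genes, profile space), `gap_curve` (k, logW, logWref,
#'   gap, sk), `distance`, `method = "kmeans"`, `seed`.
#' @export
cluster_kmeans_gap <- function(table, k_range = 1:10,
                               distance = c("pearson", "euclidean"),
                               gap_refs = 50, restarts = 10, seed = 1,
                               k_fix = NULL) {
  distance <- match.arg(distance)
  x <- .cluster_space(table)
  n <- nrow(x)
  if (max(k_range) >= n)
    stop("k_range maximum must be below the number of cells (", n, ")")
  stopifnot(gap_refs >= 1, restarts >= 1)
  set.seed(seed)
  ks <- sort(unique(as.integer(k_range)))
  fits <- lapply(ks, function(k) .kmeans_fit(x, k, distance, restarts))
  logW <- log(vapply(fits, `[[`, 0, "W"))
  rng_lo <- apply(x, 2, min); rng_hi <- apply(x, 2, max)
  logWref <- matrix(NA_real_, gap_refs, length(ks))
  for (b in seq_len(gap_refs)) {
    ref <- matrix(stats::runif(n * ncol(x), rep(rng_lo, each = n),
                               rep(rng_hi, each = n)), n)
    colnames(ref) <- colnames(x)
    logWref[b, ] <- log(vapply(ks, function(k)
      .kmeans_fit(ref, k, distance, restarts)$W, 0))
  }
  gap <- colMeans(logWref) - logW
  sk <- apply(logWref, 2, stats::sd) * sqrt(1 + 1 / gap_refs)
  if (is.null(k_fix)) {
    sel <- which(gap[-length(ks)] >= gap[-1] - sk[-1])
    k <- if (length(sel)) ks[min(sel)] else ks[length(ks)]
  } else {
    k <- as.integer(k_fix)
    if (!k %in% ks) stop("k_fix must lie in k_range")
  }
  fit <- fits[[match(k, ks)]]
  labels <- stats::setNames(as.integer(fit$labels), rownames(x))
  structure(list(labels = labels, k = k, centers = fit$centers,
                 gap_curve = data.frame(k = ks, logW = logW,
                                        logWref = colMeans(logWref),
                                        gap = gap, sk = sk),
                 distance = distance, method = "kmeans", seed = seed,
                 space = x),
            class = "ClusteringResult")
}

#' Model-based (Gaussian mixture) clustering with BIC selection
#'
#' Cells are log2(x + 1)-transformed, reduced to `n_pcs` principal
#' components, and a Gaussian mixture is fitted by EM for every k in
#' `k_range` over diagonal and full covariance families; the model with
#' maximal BIC wins and cells take their maximum-posterior assignment.
#'
#' @param table ExpressionTable.
#' @param k_range candidate component numbers (default 1:9).
#' @param n_pcs number of principal components (default min(20, n_cells - 1)).
#' @param seed RNG seed recorded in the result (the EM initialization by
#'   model-based hierarchical agglomeration is itself deterministic).
#' @return `ClusteringResult` with `labels`, `k`, `centers` (component means
#'   in PC space), `bic_curve` (k, bic = best over families), `model_name`,
#'   and `pc_scores` (the reduced space, used for pseudotime).
#' @export
cluster_model_based <- function(table, k_range = 1:9, n_pcs = NULL, seed = 1) {
  x <- .cluster_space(table)
  n <- nrow(x)
  if (max(k_range) > n) stop("k_range maximum exceeds the number of cells")
  if (is.null(n_pcs)) n_pcs <- min(20, n - 1)
  set.seed(seed)
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pr$x[, seq_len(min(n_pcs, ncol(pr$x))), drop = FALSE]
  families <- c("EII", "VII", "EEI", "VVI", "EEE", "VVV")
  fit <- mclust::Mclust(scores, G = sort(unique(as.integer(k_range))),
                        modelNames = families, verbose = FALSE)
  if (is.null(fit))
    stop("EM did not converge for any (k, covariance family) candidate")
  bic <- fit$BIC
  bic_curve <- data.frame(
    k = as.integer(rownames(bic)),
    bic = suppressWarnings(apply(bic, 1, max, na.rm = TRUE)))
  labels <- stats::setNames(as.integer(fit$classification), rownames(x))
  centers <- t(fit$parameters$mean)
  structure(list(labels = labels, k = fit$G, centers = centers,
                 bic_curve = bic_curve, model_name = fit$modelName,
                 distance = "euclidean", method = "model_based", seed = seed,
                 pc_scores = scores, space = x),
            class = "ClusteringResult")
}

#' @export
print.ClusteringResult <- function(x, ...) {
  cat(sprintf("ClusteringResult (%s): k = %d over %d cells; sizes: %s\n",
              x$method, x$k, length(x$labels),
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Plot the model-selection curve of a clustering result
#'
#' Gap curve with one-standard-error bars (k-means) or BIC curve
#' (model-based), with the chosen k marked.
#'
#' @param x ClusteringResult.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ClusteringResult <- function(x, ...) {
  if (x$method == "kmeans") {
    gc <- x$gap_curve
    graphics::plot(gc$k, gc$gap, type = "b", xlab = "k", ylab = "gap", ...)
    graphics::arrows(gc$k, gc$gap - gc$sk, gc$k, gc$gap + gc$sk,
                     angle = 90, code = 3, length = 0.03)
  } else {
    bc <- x$bic_curve
    graphics::plot(bc$k, bc$bic, type = "b", xlab = "k", ylab = "BIC", ...)
  }
  graphics::abline(v = x$k, lty = 2, col = "red")
  invisible(x)
}

#' Jaccard similarity of two index sets
#'
#' @param a,b vectors treated as sets.
#' @return |intersection| / |union| in \[0, 1\] (1 for two empty sets).
#' @export
jaccard_index <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Bootstrap Jaccard stability of detected clusters
#'
#' For each of `n_bootstrap` bootstrap resamples of the cells, the data are
#' reclustered with the same method and fixed k; each original cluster is
#' matched to the most similar new cluster by Jaccard similarity of the
#' member sets (both restricted to the cells present in the resample, as
#' sets of original indices). Per-cluster means over bootstraps near 1
#' indicate stable clusters; the conventional stability bar is 0.6.
#'
#' @param table ExpressionTable used for the original clustering.
#' @param result ClusteringResult.
#' @param n_bootstrap number of resamples (default 50).
#' @param seed RNG seed.
#' @return `StabilityReport` with `jaccard` (per-cluster mean) and the
#'   per-bootstrap matrix `jaccard_boot`.
#' @export
jaccard_stability <- function(table, result, n_bootstrap = 50, seed = 1) {
  stopifnot(inherits(result, "ClusteringResult"), n_bootstrap >= 1)
  x <- if (result$method == "model_based") result$pc_scores else result$space
  n <- nrow(x); k <- result$k
  set.seed(seed + 1L)
  jac <- matrix(NA_real_, n_bootstrap, k)
  for (b in seq_len(n_bootstrap)) {
    idx <- sample.int(n, replace = TRUE)
    xb <- x[idx, , drop = FALSE]
    new_lab <- if (result$method == "model_based") {
      fit <- mclust::Mclust(xb, G = k, verbose = FALSE)
      if (is.null(fit)) next
      fit$classification
    } else {
      .kmeans_fit(xb, k, result$distance, restarts = 10)$labels
    }
    sampled <- unique(idx)
    new_sets <- lapply(seq_len(max(new_lab)), function(j) unique(idx[new_lab == j]))
    for (cl in seq_len(k)) {
      a <- intersect(which(result$labels == cl), sampled)
      if (!length(a)) next
      jac[b, cl] <- max(vapply(new_sets, function(s) jaccard_index(a, s), 0))
    }
  }
  means <- colMeans(jac, na.rm = TRUE)
  vanished <- !is.finite(means)
  if (any(vanished)) {
    warning("cluster(s) absent from every bootstrap sample: ",
            paste(which(vanished), collapse = ", "))
    means[vanished] <- 0
  }
  structure(list(jaccard = means, jaccard_boot = jac,
                 n_bootstrap = n_bootstrap, seed = seed),
            class = "StabilityReport")
}

#' Silhouette widths of a clustering
#'
#' Standard silhouette \eqn{s(i) = (b_i - a_i)/\max(a_i, b_i)} where
#' \eqn{a_i} is the mean distance to the cell's own cluster and \eqn{b_i}
#' the mean distance to the nearest other cluster; members of singleton
#' clusters get width 0 by convention.
#'
#' @param dist symmetric distance matrix (e.g. from [distance_matrix()]).
#' @param labels integer cluster labels (1..k).
#' @return `StabilityReport` with `silhouette` (per-cell widths) and
#'   `cluster_mean_sil`.
#' @export
silhouette_widths <- function(dist, labels) {
  labels <- as.integer(labels)
  k <- length(unique(labels))
  if (k < 2) stop("silhouette requires at least 2 clusters")
  sil <- cluster::silhouette(labels, dmatrix = as.matrix(dist))
  w <- sil[, "sil_width"]
  w[labels %in% which(tabulate(labels) == 1)] <- 0
  names(w) <- rownames(as.matrix(dist))
  structure(list(silhouette = w,
                 cluster_mean_sil = tapply(w, labels, mean)),
            class = "StabilityReport")
}

#' @export
print.StabilityReport <- function(x, ...) {
  if (!is.null(x$jaccard))
    cat("mean bootstrap Jaccard per cluster:",
        paste(sprintf("%.3f", x$jaccard), collapse = ", "), "\n")
  if (!is.null(x$cluster_mean_sil))
    cat("mean silhouette per cluster:",
        paste(sprintf("%.3f", x$cluster_mean_sil), collapse = ", "), "\n")
  invisible(x)
}

# Upper-tail probability P(X >= x) under NB(mean mu, variance v); collapses
# to Poisson when v <= mu (the NB size would be infinite or negative).
.nb_upper_tail <- function(x, mu, v) {
  if (v <= mu)
    return(stats::ppois(x - 1, lambda = mu, lower.tail = FALSE))
  r <- mu^2 / (v - mu)
  stats::pnbinom(x - 1, size = r, mu = mu, lower.tail = FALSE)
}

#' Detect outlier cells from a per-cluster negative-binomial background model
#'
#' Within each cluster the mean-variance relation of gene counts is fitted as
#' a quadratic in log space, \eqn{\log v = c_0 + c_1 \log m + c_2 (\log m)^2},
#' across genes with positive mean. Each count is then scored by its
#' negative-binomial upper-tail probability under the cluster gene mean and
#' the fitted variance (size \eqn{r = m^2/(v - m)}, with a Poisson fallback
#' when the fitted variance does not exceed the mean). A gene is an outlier
#' gene in a cell if that probability falls below `probthr`; a cell is an
#' outlier if it has at least `outminc` outlier genes. Counts are raw
#' (non-normalized) by default.
#'
#' @param table ExpressionTable.
#' @param labels integer cluster labels (e.g. `result$labels`).
#' @param probthr per-gene outlier probability threshold (default 1e-3).
#' @param outminc minimum outlier genes per outlier cell: an integer
#'   (default 2) or `"5pct"` for 5% of the filtered gene count rounded up,
#'   the convention used on real case studies.
#' @param use_raw score raw counts (default TRUE) rather than normalized.
#' @return `OutlierReport`: per-cell `n_outlier_genes`, `min_p`, logical
#'   `outlier`, and per-cluster `fits` (coefficients or Poisson fallback).
#' @export
detect_outliers <- function(table, labels, probthr = 1e-3, outminc = 2,
                            use_raw = TRUE) {
  stopifnot(probthr > 0, probthr < 1)
  counts <- if (use_raw || is.null(attr(table, "normalized")))
    table$counts[!table$is_spikein, , drop = FALSE]
  else attr(table, "normalized")[!table$is_spikein, , drop = FALSE]
  n_genes <- nrow(counts)
  if (identical(outminc, "5pct")) outminc <- ceiling(0.05 * n_genes)
  stopifnot(outminc >= 1)
  labels <- as.integer(labels)
  n_out <- stats::setNames(rep(NA_integer_, ncol(counts)), colnames(counts))
  min_p <- stats::setNames(rep(NA_real_, ncol(counts)), colnames(counts))
  fits <- list()
  for (cl in sort(unique(labels))) {
    cells <- which(labels == cl)
    if (length(cells) < 2) {
      warning("cluster ", cl, " has fewer than 2 cells; skipped")
      next
    }
    sub <- counts[, cells, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    fit_ok <- m > 0 & v > 0
    poisson_fallback <- sum(fit_ok) < 3 || all(v[fit_ok] <= m[fit_ok])
    if (!poisson_fallback) {
      lm_fit <- stats::lm(log(v[fit_ok]) ~ log(m[fit_ok]) +
                            I(log(m[fit_ok])^2))
      cf <- stats::coef(lm_fit)
      vfit <- function(mu) exp(cf[1] + cf[2] * log(mu) + cf[3] * log(mu)^2)
      fits[[as.character(cl)]] <- cf
    } else {
      message("cluster ", cl,
              ": degenerate variance-mean fit, Poisson background used")
      vfit <- function(mu) mu
      fits[[as.character(cl)]] <- c(poisson = TRUE)
    }
    scored <- which(m > 0)
    p <- matrix(1, length(scored), length(cells))
    for (gi in seq_along(scored)) {
      g <- scored[gi]
      p[gi, ] <- .nb_upper_tail(sub[g, ], m[g], vfit(m[g]))
    }
    n_out[cells] <- colSums(p < probthr)
    min_p[cells] <- apply(p, 2, min)
  }
  outlier <- !is.na(n_out) & n_out >= outminc
  structure(list(n_outlier_genes = n_out, min_p = min_p, outlier = outlier,
                 fits = fits, probthr = probthr, outminc = outminc),
            class = "OutlierReport")
}

#' @export
print.OutlierReport <- function(x, ...) {
  cat(sprintf("OutlierReport: %d outlier cell(s) of %d (probthr = %g, outminc = %d)\n",
              sum(x$outlier, na.rm = TRUE), length(x$outlier),
              x$probthr, x$outminc))
  if (any(x$outlier, na.rm = TRUE))
    cat("  ", paste(names(which(x$outlier)), collapse = ", "), "\n")
  invisible(x)
}

#' Two-dimensional embedding of the cells
#'
#' PCA (top two components of centered log2 counts, deterministic up to
#' sign) or tSNE (Barnes-Hut, seeded).
#'
#' @param table ExpressionTable.
#' @param method `"pca"` or `"tsne"`.
#' @param seed RNG seed (tSNE).
#' @param perplexity tSNE perplexity; default min(30, floor((n-1)/3) - 1);
#'   values at or above (n_cells - 1)/3 are rejected.
#' @return `Embedding`: `coordinates` (cells x 2), `method`, `seed`; for
#'   PCA also `explained_var` and the full score matrix as attribute
#'   `scores`.
#' @export
compute_embedding <- function(table, method = c("pca", "tsne"), seed = 1,
                              perplexity = NULL) {
  method <- match.arg(method)
  x <- .cluster_space(table)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 cells")
  if (method == "pca") {
    pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    coords <- pr$x[, 1:2, drop = FALSE]
    out <- structure(list(method = "pca", coordinates = coords, seed = seed,
                          explained_var = pr$sdev^2 / sum(pr$sdev^2)),
                     class = "Embedding")
    attr(out, "scores") <- pr$x
    out
  } else {
    if (is.null(perplexity)) perplexity <- max(1, min(30, floor((n - 1) / 3) - 1))
    if (perplexity >= (n - 1) / 3)
      stop("perplexity must be below (n_cells - 1)/3 = ", (n - 1) / 3)
    set.seed(seed)
    ts <- Rtsne::Rtsne(x, dims = 2, perplexity = perplexity,
                       check_duplicates = FALSE)
    coords <- ts$Y
    rownames(coords) <- rownames(x)
    structure(list(method = "tsne", coordinates = coords, seed = seed,
                   perplexity = perplexity),
              class = "Embedding")
  }
}

#' @export
print.Embedding <- function(x, ...) {
  cat(sprintf("Embedding (%s): %d cells\n", x$method, nrow(x$coordinates)))
  invisible(x)
}

#' @export
plot.Embedding <- function(x, labels = NULL, ...) {
  col <- if (is.null(labels)) "black" else as.integer(labels) + 1L
  graphics::plot(x$coordinates, col = col, pch = 16,
                 xlab = paste(x$method, "1"), ylab = paste(x$method, "2"), ...)
  invisible(x)
}

#' Order clusters by hierarchical clustering of their centers
#'
#' Cluster-center distances are taken as the mean cell-to-cell distance
#' between the two clusters; single-linkage hierarchical clustering of that
#' k x k matrix yields the leaf order used to arrange distance heatmaps.
#'
#' @param dist cell-to-cell distance matrix.
#' @param labels integer cluster labels (1..k).
#' @return integer permutation of 1..k (the dendrogram leaf order).
#' @export
order_clusters_hierarchically <- function(dist, labels) {
  labels <- as.integer(labels)
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("need at least 2 clusters")
  d <- as.matrix(dist)
  cd <- matrix(0, length(ks), length(ks))
  for (i in seq_along(ks)) for (j in seq_along(ks)) {
    if (i < j) {
      cd[i, j] <- cd[j, i] <-
        mean(d[labels == ks[i], labels == ks[j], drop = FALSE])
    }
  }
  if (length(ks) == 2) return(ks)
  hc <- stats::hclust(stats::as.dist(cd), method = "single")
  ks[hc$order]
}
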