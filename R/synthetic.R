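#' Specification of a synthetic single-cell count dataset
#'
#' Encodes the statistical structure the pipeline assumes in real data:
#' negative-binomial counts over log-normal baseline means, cluster
#' structure carried by disjoint marker-gene sets with a fixed fold change,
#' log-normal library-size variation, optional spike-in rows obeying a
#' CV-squared vs mean technical-noise law, an optional linear trajectory,
#' and optional injected outlier cells.
#'
#' Defaults describe a modest but well-structured experiment: 500 genes by
#' 300 cells in 3 equal clusters, 10 markers per cluster at 8-fold change,
#' NB size 2, log-normal depth spread 0.35 (a typical scRNA-seq depth
#' spread), and a spike-in noise law \eqn{CV^2 = 3/\mu + 0.1}.
#'
#' @param n_genes,n_cells,k_clusters dataset dimensions.
#' @param proportions cluster proportions (default equal; must sum to 1).
#' @param base_meanlog,base_sdlog log-normal parameters of baseline gene
#'   means.
#' @param nb_size NB size parameter r (variance \eqn{\mu + \mu^2/r}).
#' @param n_markers markers per cluster (disjoint across clusters).
#' @param marker_log2fc marker log2 fold change in their cluster.
#' @param depth_sdlog log-normal sd of per-cell depth factors.
#' @param n_spikeins number of spike-in rows (0 for none).
#' @param spike_a0,spike_a1 technical-noise law coefficients.
#' @param spike_meanlog,spike_sdlog log-normal parameters of spike-in means.
#' @param trajectory generate a linear trajectory instead of discrete
#'   clusters (cluster means interpolated along a latent position).
#' @param n_outlier_cells cells receiving an injected outlier signature.
#' @param outlier_n_genes,outlier_multiplier genes per outlier cell whose
#'   counts are multiplied.
#' @param seed RNG seed.
#' @return `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_genes = 500, n_cells = 300, k_clusters = 3,
                           proportions = NULL, base_meanlog = 1,
                           base_sdlog = 1, nb_size = 2, n_markers = 10,
                           marker_log2fc = 3, depth_sdlog = 0.35,
                           n_spikeins = 0, spike_a0 = 0.1, spike_a1 = 3,
                           spike_meanlog = 3, spike_sdlog = 1.5,
                           trajectory = FALSE, n_outlier_cells = 0,
                           outlier_n_genes = 6, outlier_multiplier = 20,
                           seed = 1) {
  if (is.null(proportions)) proportions <- rep(1 / k_clusters, k_clusters)
  stopifnot(abs(sum(proportions) - 1) < 1e-8,
            length(proportions) == k_clusters)
  if (k_clusters * n_markers > n_genes)
    stop("infeasible marker allocation: k_clusters * n_markers > n_genes")
  structure(as.list(environment()), class = "SyntheticSpec")
}

#' Generate a synthetic dataset
#'
#' Counts are drawn \eqn{NB(\mu = base_g \cdot depth_c \cdot FC_{g,cl(c)},
#' size)} per the given `spec`; spike-ins have cell-independent expected
#' concentration scaled by depth, with per-draw variance matching
#' \eqn{CV^2(\mu) = a_1/\mu + a_0} (NB when that exceeds Poisson
#' variance, Poisson otherwise); outlier cells have `outlier_n_genes`
#' randomly chosen genes multiplied by `outlier_multiplier`; in trajectory
#' mode cluster means are interpolated linearly along a latent position in
#' \[0, k-1\] and the cluster label is the nearest anchor.
#'
#' @param spec [synthetic_spec()].
#' @return `SyntheticDataset`: `table` (ExpressionTable), `labels` (true
#'   clusters), `markers` (list of true marker IDs per cluster),
#'   `pseudotime` (latent positions, trajectory mode), `outlier_cells`,
#'   `spec`.
#' @export
simulate_cells <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  g <- spec$n_genes; n <- spec$n_cells; k <- spec$k_clusters
  base <- stats::rlnorm(g, spec$base_meanlog, spec$base_sdlog)
  depth <- stats::rlnorm(n, 0, spec$depth_sdlog)
  markers <- if (spec$n_markers > 0)
    split(seq_len(k * spec$n_markers), rep(seq_len(k), each = spec$n_markers))
  else rep(list(integer(0)), k)
  fc <- matrix(1, g, k)
  for (cl in seq_len(k)) fc[markers[[cl]], cl] <- 2^spec$marker_log2fc
  gene_ids <- sprintf("G%04d", seq_len(g))
  cell_ids <- sprintf("cell%04d", seq_len(n))
  if (spec$trajectory) {
    pos <- sort(stats::runif(n, 0, k - 1))
    labels <- pmin(k, pmax(1, round(pos) + 1))
    lo <- pmin(floor(pos) + 1, k - 1)
    frac <- pos - (lo - 1)
    mu <- vapply(seq_len(n), function(c)
      base * ((1 - frac[c]) * fc[, lo[c]] + frac[c] * fc[, lo[c] + 1]) *
        depth[c], numeric(g))
  } else {
    pos <- NULL
    sizes <- floor(spec$proportions * n)
    short <- n - sum(sizes)
    if (short > 0) {
      frac <- spec$proportions * n - sizes
      sizes[order(frac, decreasing = TRUE)[seq_len(short)]] <-
        sizes[order(frac, decreasing = TRUE)[seq_len(short)]] + 1L
    }
    labels <- sample(rep(seq_len(k), times = sizes))
    mu <- vapply(seq_len(n), function(c) base * fc[, labels[c]] * depth[c],
                 numeric(g))
  }
  outlier_cells <- character()
  if (spec$n_outlier_cells > 0) {
    # inject at the mean level so the aberration is realized in the draw
    # (multiplying realized counts would leave sampled zeros untouched)
    oc <- sample.int(n, spec$n_outlier_cells)
    for (c in oc) {
      og <- sample.int(g, spec$outlier_n_genes)
      mu[og, c] <- mu[og, c] * spec$outlier_multiplier
    }
    outlier_cells <- cell_ids[oc]
  }
  counts <- matrix(stats::rnbinom(g * n, mu = mu, size = spec$nb_size), g)
  if (spec$n_spikeins > 0) {
    smu <- stats::rlnorm(spec$n_spikeins, spec$spike_meanlog, spec$spike_sdlog)
    sp <- vapply(seq_len(n), function(c) {
      m <- smu * depth[c]
      v <- spec$spike_a1 * m + spec$spike_a0 * m^2
      out <- numeric(length(m))
      nb <- v > m
      if (any(nb))
        out[nb] <- stats::rnbinom(sum(nb), mu = m[nb],
                                  size = m[nb]^2 / (v[nb] - m[nb]))
      if (any(!nb)) out[!nb] <- stats::rpois(sum(!nb), m[!nb])
      out
    }, numeric(spec$n_spikeins))
    sp_ids <- sprintf("ERCC-%05d", seq_len(spec$n_spikeins))
    counts <- rbind(counts, sp)
    gene_ids <- c(gene_ids, sp_ids)
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  tab <- expression_table(counts, spikein_prefix = "ERCC-")
  structure(list(table = tab,
                 labels = stats::setNames(labels, cell_ids),
                 markers = lapply(markers, function(i) gene_ids[i]),
                 pseudotime = if (is.null(pos)) NULL
                              else stats::setNames(pos, cell_ids),
                 outlier_cells = outlier_cells, spec = spec),
            class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf(
    "SyntheticDataset: %d genes x %d cells, %d clusters%s%s (seed %d)\n",
    length(x$table$gene_ids), length(x$table$cell_ids), x$spec$k_clusters,
    if (x$spec$trajectory) ", trajectory" else "",
    if (length(x$outlier_cells))
      paste0(", ", length(x$outlier_cells), " outlier cell(s)") else "",
    x$spec$seed))
  invisible(x)
}
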