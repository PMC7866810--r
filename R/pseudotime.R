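#' Order cells along a minimum-spanning-tree trajectory over cluster centers
#'
#' Builds the Euclidean minimum spanning tree over the cluster centers in the
#' supplied coordinate space (normally the PC space the clustering was run
#' in), takes the tree diameter (the longest path, by summed edge length,
#' ties broken by lexicographic cluster index) as the trajectory backbone,
#' and projects every cell orthogonally onto its nearest backbone segment.
#' Pseudotime is the cumulative arc length from the backbone start to the
#' projection point; projections are clamped to the segments, so cells lying
#' beyond a terminal center receive the terminal arc length.
#'
#' @param coords numeric matrix, one row per cell (>= 1 column), e.g.
#'   `attr(compute_embedding(tab), "scores")` or `result$pc_scores`.
#' @param labels integer cluster labels (1..k), k >= 2.
#' @return `TrajectoryResult`: `mst_edges` (k-1 x 2 matrix of cluster
#'   indices), `backbone` (ordered cluster path), `pseudotime` (named,
#'   non-negative), `cell_order` (permutation of cells by increasing
#'   pseudotime, ties by cell index).
#' @export
build_trajectory <- function(coords, labels) {
  coords <- as.matrix(coords)
  labels <- as.integer(labels)
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("pseudotime undefined for a single cluster")
  centers <- do.call(rbind, lapply(ks, function(cl)
    colMeans(coords[labels == cl, , drop = FALSE])))
  k <- nrow(centers)
  cd <- as.matrix(stats::dist(centers))
  g <- igraph::graph_from_adjacency_matrix(cd, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  em <- igraph::as_edgelist(mst)
  mst_edges <- cbind(ks[as.integer(em[, 1])], ks[as.integer(em[, 2])])
  # tree diameter with deterministic tie-break: smallest (i, j) pair first
  pl <- igraph::distances(mst, weights = igraph::E(mst)$weight)
  best <- c(1L, 1L); best_len <- -1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j && pl[i, j] > best_len + 1e-12) { best <- c(i, j); best_len <- pl[i, j] }
  }
  path <- as.integer(igraph::shortest_paths(mst, best[1], best[2],
                                            weights = igraph::E(mst)$weight)$vpath[[1]])
  backbone <- ks[path]
  # cumulative arc length at each backbone vertex
  seg_from <- centers[path[-length(path)], , drop = FALSE]
  seg_to <- centers[path[-1], , drop = FALSE]
  seg_len <- sqrt(rowSums((seg_to - seg_from)^2))
  cum0 <- c(0, cumsum(seg_len))
  n <- nrow(coords)
  pt <- numeric(n)
  for (i in seq_len(n)) {
    p <- coords[i, ]
    best_d <- Inf; best_t <- 0
    for (s in seq_along(seg_len)) {
      a <- seg_from[s, ]; b <- seg_to[s, ]
      ab <- b - a
      t <- if (seg_len[s] == 0) 0 else sum((p - a) * ab) / sum(ab^2)
      t <- min(max(t, 0), 1)
      proj <- a + t * ab
      d2 <- sum((p - proj)^2)
      if (d2 < best_d) { best_d <- d2; best_t <- cum0[s] + t * seg_len[s] }
    }
    pt[i] <- best_t
  }
  names(pt) <- rownames(coords)
  structure(list(mst_edges = mst_edges, backbone = backbone,
                 pseudotime = pt,
                 cell_order = order(pt, seq_len(n))),
            class = "TrajectoryResult")
}

#' @export
print.TrajectoryResult <- function(x, ...) {
  cat(sprintf("TrajectoryResult: backbone %s; pseudotime range [0, %.3g]\n",
              paste(x$backbone, collapse = " - "), max(x$pseudotime)))
  invisible(x)
}

#' Expression of selected genes along the pseudotime ordering
#'
#' Returns log10(x + 1) expression of the requested genes with cells in
#' pseudotime order, for trajectory profiling; an optional centered
#' rolling-mean smoother is available for display.
#'
#' @param table ExpressionTable (normalized values used when present).
#' @param cell_order integer permutation of cells (from
#'   [build_trajectory()]).
#' @param genes character vector of gene IDs.
#' @param smooth_window optional odd window size for a rolling mean applied
#'   per gene (display only; default none).
#' @return numeric matrix, genes x ordered cells.
#' @export
expression_along_order <- function(table, cell_order, genes,
                                   smooth_window = NULL) {
  x <- attr(table, "normalized")
  if (is.null(x)) x <- table$counts
  miss <- setdiff(genes, rownames(x))
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  out <- log10(x[genes, cell_order, drop = FALSE] + 1)
  if (!is.null(smooth_window) && smooth_window > 1) {
    out <- t(apply(out, 1, function(v)
      stats::filter(v, rep(1 / smooth_window, smooth_window), sides = 2)))
    colnames(out) <- colnames(x)[cell_order]
  }
  out
}
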