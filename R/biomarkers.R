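# Node impurity for a vector of class counts.
.gini <- function(cnt) { p <- cnt / sum(cnt); 1 - sum(p^2) }
.entropy <- function(cnt) {
  p <- cnt / sum(cnt); p <- p[p > 0]; -sum(p * log2(p))
}

# Exhaustive best (feature, threshold) split of rows `idx` of x (samples x
# features) for 2-class labels y. Thresholds are midpoints of adjacent
# distinct observed values; ties broken by first feature, lowest threshold.
# criterion: "gini" minimizes weighted child impurity; "gainratio"
# maximizes information gain / split info.
.best_split <- function(x, y, idx, criterion) {
  best <- NULL
  n <- length(idx)
  parent_cnt <- tabulate(y[idx], 2)
  for (f in seq_len(ncol(x))) {
    v <- x[idx, f]
    uv <- sort(unique(v))
    if (length(uv) < 2) next
    thr <- (uv[-1] + uv[-length(uv)]) / 2
    for (t in thr) {
      left <- v < t
      nl <- sum(left); nr <- n - nl
      cl <- tabulate(y[idx][left], 2); cr <- parent_cnt - cl
      if (criterion == "gini") {
        score <- (nl * .gini(cl) + nr * .gini(cr)) / n   # minimize
        better <- is.null(best) || score < best$score - 1e-12
      } else {
        gain <- .entropy(parent_cnt) -
          (nl * .entropy(cl) + nr * .entropy(cr)) / n
        split_info <- .entropy(c(nl, nr))
        score <- if (split_info > 0) gain / split_info else 0
        better <- is.null(best) || score > best$score + 1e-12
      }
      if (better)
        best <- list(feature = f, threshold = t, score = score,
                     left_n = nl, right_n = nr)
    }
  }
  best
}

.grow_node <- function(x, y, idx, inducer, cp, minsplit, root_imp, depth) {
  cnt <- tabulate(y[idx], 2)
  node <- list(n = length(idx), counts = cnt,
               pred = which.max(cnt), leaf = TRUE)
  if (cnt[1] == 0 || cnt[2] == 0 || length(idx) < minsplit) return(node)
  crit <- if (inducer == "cart") "gini" else "gainratio"
  sp <- .best_split(x, y, idx, crit)
  if (is.null(sp)) return(node)
  if (inducer == "cart") {
    decrease <- (length(idx) * .gini(cnt) - length(idx) * sp$score) /
      root_imp
    if (decrease < cp) return(node)
  } else {
    if (sp$score <= 0) return(node)
  }
  left_idx <- idx[x[idx, sp$feature] < sp$threshold]
  right_idx <- setdiff(idx, left_idx)
  node$leaf <- FALSE
  node$gene <- colnames(x)[sp$feature]
  node$feature <- sp$feature
  node$threshold <- sp$threshold
  node$left <- .grow_node(x, y, left_idx, inducer, cp, minsplit, root_imp,
                          depth + 1)
  node$right <- .grow_node(x, y, right_idx, inducer, cp, minsplit, root_imp,
                           depth + 1)
  node
}

#' Build a decision tree over gene expressions for two cell classes
#'
#' CART-style recursive partitioning: at every node the split minimizing the
#' weighted Gini impurity is found by exhaustive search over all features
#' and all midpoint thresholds between adjacent observed values. Growth
#' stops when a node is pure, smaller than `minsplit`, or when the best
#' split's impurity decrease relative to the root impurity falls below `cp`.
#' The optional `"c45"` inducer uses the gain ratio with the same stopping
#' rules (experimental; no error-based pruning). Typical use is on the DEG
#' features from the differential-expression stage, to predict the
#' sub-population of a target cell.
#'
#' @param expr numeric matrix, samples (cells) x features (genes).
#' @param labels two-class factor (or coercible) over the samples.
#' @param inducer `"cart"` (default) or `"c45"`.
#' @param cp complexity parameter: minimum relative impurity decrease
#'   (default 0.01).
#' @param minsplit minimum node size eligible for splitting (default 20).
#' @return `DecisionTreeModel`: nested `root` node list (gene, threshold,
#'   left/right, class counts, predicted class), `classes`, `inducer`,
#'   `cp`, `minsplit`.
#' @seealso [predict.DecisionTreeModel()], [cross_validate()],
#'   [tree_to_json()]
#' @export
build_tree <- function(expr, labels, inducer = c("cart", "c45"), cp = 0.01,
                       minsplit = 20) {
  inducer <- match.arg(inducer)
  expr <- as.matrix(expr)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly 2 classes")
  if (any(table(labels) < 2)) stop("need at least 2 samples per class")
  y <- as.integer(labels)
  if (is.null(colnames(expr)))
    colnames(expr) <- paste0("feature", seq_len(ncol(expr)))
  n <- nrow(expr)
  root_imp <- n * .gini(tabulate(y, 2))
  if (root_imp == 0) stop("single-class input")
  root <- .grow_node(expr, y, seq_len(n), inducer, cp, minsplit, root_imp, 0)
  structure(list(root = root, classes = levels(labels), inducer = inducer,
                 cp = cp, minsplit = minsplit, features = colnames(expr)),
            class = "DecisionTreeModel")
}

#' Predict classes from a decision tree
#'
#' @param object DecisionTreeModel.
#' @param newdata samples x features matrix holding the model's feature
#'   columns.
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
predict.DecisionTreeModel <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  walk <- function(node, row) {
    while (!node$leaf)
      node <- if (row[node$gene] < node$threshold) node$left else node$right
    node$pred
  }
  preds <- apply(newdata, 1, function(row) walk(object$root, row))
  factor(object$classes[preds], levels = object$classes)
}

#' @export
print.DecisionTreeModel <- function(x, ...) {
  n_nodes <- function(nd) if (nd$leaf) 0 else 1 + n_nodes(nd$left) + n_nodes(nd$right)
  cat(sprintf("DecisionTreeModel (%s): %d decision node(s), classes %s vs %s\n",
              x$inducer, n_nodes(x$root), x$classes[1], x$classes[2]))
  show <- function(nd, indent) {
    pad <- strrep("  ", indent)
    if (nd$leaf) {
      cat(pad, sprintf("-> %s (%d/%d)\n", x$classes[nd$pred],
                       nd$counts[nd$pred], nd$n), sep = "")
    } else {
      cat(pad, sprintf("%s < %.4g?\n", nd$gene, nd$threshold), sep = "")
      show(nd$left, indent + 1); show(nd$right, indent + 1)
    }
  }
  show(x$root, 0)
  invisible(x)
}

#' Export a decision tree as JSON
#'
#' @param model DecisionTreeModel.
#' @param path optional output file; when omitted the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
tree_to_json <- function(model, path = NULL) {
  strip <- function(nd) {
    if (nd$leaf)
      list(leaf = TRUE, predicted = model$classes[nd$pred],
           counts = nd$counts)
    else
      list(leaf = FALSE, gene = nd$gene, threshold = nd$threshold,
           counts = nd$counts, left = strip(nd$left), right = strip(nd$right))
  }
  js <- jsonlite::toJSON(strip(model$root), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Export a decision tree as Graphviz DOT
#'
#' @param model DecisionTreeModel.
#' @param path optional output file.
#' @return DOT string (invisibly when written to file).
#' @export
tree_to_dot <- function(model, path = NULL) {
  lines <- c("digraph tree {", "  node [shape=box];")
  ctr <- 0
  emit <- function(nd) {
    ctr <<- ctr + 1
    id <- ctr
    if (nd$leaf) {
      lines <<- c(lines, sprintf("  n%d [label=\"%s\\n%d/%d\"];", id,
                                 model$classes[nd$pred], nd$counts[nd$pred],
                                 nd$n))
    } else {
      lines <<- c(lines, sprintf("  n%d [label=\"%s < %.4g\"];", id,
                                 nd$gene, nd$threshold))
      lid <- emit(nd$left); rid <- emit(nd$right)
      lines <<- c(lines,
                  sprintf("  n%d -> n%d [label=\"yes\"];", id, lid),
                  sprintf("  n%d -> n%d [label=\"no\"];", id, rid))
    }
    id
  }
  emit(model$root)
  dot <- paste(c(lines, "}"), collapse = "\n")
  if (!is.null(path)) { writeLines(dot, path); return(invisible(dot)) }
  dot
}

#' Cross-validated performance of a decision-tree classifier
#'
#' Stratified seeded folds; a tree is trained on each training split and the
#' held-out confusion counts are pooled. Sensitivity and specificity treat
#' `positive` as the positive class.
#'
#' @param expr samples x features matrix.
#' @param labels two-class labels.
#' @param inducer `"cart"` or `"c45"`.
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param positive positive class (default: second factor level, matching
#'   a target-vs-rest coding where the target is the second level).
#' @param cp,minsplit passed to [build_tree()].
#' @return `CVReport`: `confusion` (TP, FN, FP, TN), `accuracy`,
#'   `sensitivity`, `specificity`, per-fold counts, `n_folds`, `seed`.
#' @export
cross_validate <- function(expr, labels, inducer = c("cart", "c45"),
                           n_folds = 10, seed = 1, positive = NULL,
                           cp = 0.01, minsplit = 20) {
  inducer <- match.arg(inducer)
  expr <- as.matrix(expr)
  labels <- factor(labels)
  n <- nrow(expr)
  if (n_folds > n) stop("n_folds exceeds the number of samples")
  if (n_folds > min(table(labels)))
    warning("n_folds exceeds the smallest class; some folds lack a class")
  if (is.null(positive)) positive <- levels(labels)[2]
  set.seed(seed)
  ord <- unlist(lapply(levels(labels), function(l) sample(which(labels == l))))
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(n_folds), n)
  per_fold <- matrix(0L, n_folds, 4,
                     dimnames = list(NULL, c("TP", "FN", "FP", "TN")))
  for (f in seq_len(n_folds)) {
    test <- folds == f
    model <- build_tree(expr[!test, , drop = FALSE], labels[!test],
                        inducer = inducer, cp = cp, minsplit = minsplit)
    pred <- predict(model, expr[test, , drop = FALSE])
    truth <- labels[test]
    per_fold[f, ] <- c(sum(pred == positive & truth == positive),
                       sum(pred != positive & truth == positive),
                       sum(pred == positive & truth != positive),
                       sum(pred != positive & truth != positive))
  }
  cm <- colSums(per_fold)
  structure(list(confusion = cm,
                 accuracy = (cm["TP"] + cm["TN"]) / sum(cm),
                 sensitivity = cm["TP"] / (cm["TP"] + cm["FN"]),
                 specificity = cm["TN"] / (cm["TN"] + cm["FP"]),
                 per_fold = per_fold, n_folds = n_folds, seed = seed,
                 positive = positive),
            class = "CVReport")
}

#' @export
print.CVReport <- function(x, ...) {
  cat(sprintf(
    "CVReport (%d-fold): accuracy %.3f, sensitivity %.3f, specificity %.3f (positive class: %s)\n",
    x$n_folds, x$accuracy, x$sensitivity, x$specificity, x$positive))
  print(x$confusion)
  invisible(x)
}

#' Subnetwork induced by a gene list
#'
#' @param edges EdgeList (e.g. a protein-protein interaction network).
#' @param genes gene list (e.g. DEGs).
#' @return EdgeList of the edges with both endpoints in `genes`, with
#'   attribute `isolated` listing query genes carrying no induced edge.
#' @export
induced_subnetwork <- function(edges, genes) {
  stopifnot(length(genes) > 0)
  keep <- edges$gene_a %in% genes & edges$gene_b %in% genes
  sub <- edges[keep, , drop = FALSE]
  connected <- unique(c(sub$gene_a, sub$gene_b))
  out <- structure(sub, class = c("EdgeList", "data.frame"))
  attr(out, "isolated") <- setdiff(genes, connected)
  if (!nrow(sub)) warning("induced subnetwork is empty")
  out
}

#' Degree and betweenness centrality with hub ranking
#'
#' Degree is the incident edge count; betweenness is Brandes' accumulation
#' over unweighted shortest paths, each unordered pair counted once. Hubs
#' are ranked by descending degree, ties by descending betweenness, then by
#' gene ID. Edge weights are not used (confidence filtering belongs to
#' loading).
#'
#' @param network EdgeList.
#' @param normalized divide betweenness by the number of non-incident pairs
#'   (default FALSE, i.e. raw path counts).
#' @return `CentralityTable` data.frame (gene, degree, betweenness,
#'   hub_rank) ordered by rank.
#' @export
centrality <- function(network, normalized = FALSE) {
  if (!nrow(network)) stop("empty network")
  g <- igraph::graph_from_data_frame(network[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA,
                             normalized = normalized)
  ord <- order(-deg, -btw, names(deg))
  df <- data.frame(gene = names(deg)[ord], degree = as.integer(deg[ord]),
                   betweenness = as.numeric(btw[ord]),
                   hub_rank = seq_along(ord),
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(df, class = c("CentralityTable", "data.frame"))
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric upper-tail test of each set's overlap with the
#' query, against a stated gene universe; Benjamini-Hochberg q-values across
#' sets. Query genes outside the universe are dropped with a warning; set
#' members are intersected with the universe before testing.
#'
#' @param query gene list of interest (e.g. DEGs).
#' @param sets GeneSetCollection from [read_gmt()].
#' @param universe all genes that could have been selected.
#' @return `EnrichmentTable` data.frame (set, overlap, set_size,
#'   universe_size, query_size, p_value, q_value) ordered by p.
#' @export
enrich <- function(query, sets, universe) {
  stopifnot(inherits(sets, "GeneSetCollection"))
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets$sets), function(nm) {
    s <- intersect(sets$sets[[nm]], universe)
    k <- length(intersect(s, query))
    p <- stats::phyper(k - 1, length(s), N - length(s), n,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(s),
               universe_size = N, query_size = n, p_value = p,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$q_value <- stats::p.adjust(df$p_value, method = "BH")
  df <- df[order(df$p_value), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("EnrichmentTable", "data.frame"))
}
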