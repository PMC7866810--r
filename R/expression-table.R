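#' Construct an expression table
#'
#' The pipeline's universal currency: a genes x cells matrix of raw read
#' counts with unique gene and cell identifiers and a per-gene spike-in flag.
#' Spike-in rows (e.g. ERCC synthetic RNAs of known concentration) carry the
#' technical-noise signal used by [fit_technical_noise()]; they are excluded
#' from size-factor estimation and from all downstream biology.
#'
#' @param counts numeric matrix, genes as rows, cells as columns, with
#'   dimnames. Entries must be finite and non-negative.
#' @param spikein_prefix gene-ID prefix marking spike-in rows (default
#'   `"ERCC-"`). Ignored when `is_spikein` is given.
#' @param is_spikein optional logical vector, one flag per gene, overriding
#'   prefix matching.
#' @return An object of class `ExpressionTable`: a list with elements
#'   `counts` (the matrix), `gene_ids`, `cell_ids`, `is_spikein`.
#' @seealso [read_counts()], [write_counts()]
#' @export
expression_table <- function(counts, spikein_prefix = "ERCC-", is_spikein = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and cell column names")
  gene_ids <- rownames(counts)
  cell_ids <- colnames(counts)
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    stop("duplicate gene IDs: ", paste(dup_g, collapse = ", "))
  dup_c <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup_c))
    stop("duplicate cell IDs: ", paste(dup_c, collapse = ", "))
  if (!is.numeric(counts)) {
    bad <- which(!apply(counts, 2, is.numeric))
    stop("non-numeric entries in columns: ", paste(bad, collapse = ", "))
  }
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    coords <- apply(utils::head(bad, 5), 1, function(ij)
      sprintf("[%s, %s]", gene_ids[ij[1]], cell_ids[ij[2]]))
    stop("negative or non-finite counts at: ", paste(coords, collapse = ", "))
  }
  if (is.null(is_spikein)) {
    is_spikein <- startsWith(gene_ids, spikein_prefix)
  } else {
    is_spikein <- as.logical(is_spikein)
    if (length(is_spikein) != length(gene_ids))
      stop("is_spikein length must equal the number of genes")
  }
  names(is_spikein) <- gene_ids
  structure(
    list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
         is_spikein = is_spikein),
    class = "ExpressionTable")
}

#' @export
print.ExpressionTable <- function(x, ...) {
  cat(sprintf("ExpressionTable: %d genes x %d cells (%d spike-ins)\n",
              length(x$gene_ids), length(x$cell_ids), sum(x$is_spikein)))
  invisible(x)
}

#' @export
dim.ExpressionTable <- function(x) dim(x$counts)

#' Subset an expression table by gene and/or cell identifiers or indices
#'
#' @param x ExpressionTable.
#' @param genes,cells character IDs or integer/logical indices; `NULL` keeps
#'   all. Order of the selection is preserved.
#' @return ExpressionTable restricted to the selection; a `normalized`
#'   attribute, if present, is subset alongside.
#' @export
subset_table <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "ExpressionTable"))
  gi <- if (is.null(genes)) seq_along(x$gene_ids) else .resolve_idx(genes, x$gene_ids, "gene")
  ci <- if (is.null(cells)) seq_along(x$cell_ids) else .resolve_idx(cells, x$cell_ids, "cell")
  out <- expression_table(x$counts[gi, ci, drop = FALSE],
                          is_spikein = x$is_spikein[gi])
  nrm <- attr(x, "normalized")
  if (!is.null(nrm)) attr(out, "normalized") <- nrm[gi, ci, drop = FALSE]
  out
}

.resolve_idx <- function(sel, ids, what) {
  if (is.character(sel)) {
    miss <- setdiff(sel, ids)
    if (length(miss))
      stop("unknown ", what, " IDs: ", paste(miss, collapse = ", "))
    match(sel, ids)
  } else {
    seq_along(ids)[sel]
  }
}

#' Read a counts matrix from CSV/TSV or MatrixMarket files
#'
#' CSV/TSV files must have gene rows, cell columns and a header row of cell
#' IDs; the first column holds gene IDs. The delimiter is sniffed from the
#' extension (`.csv` comma, `.tsv`/`.txt` tab) unless `sep` is given.
#' A MatrixMarket file `x.mtx` must be accompanied by `x.genes.txt` and
#' `x.cells.txt` holding one row/column name per line.
#'
#' @param path file path.
#' @param spikein_prefix prefix identifying spike-in gene IDs.
#' @param sep optional delimiter override for the text formats.
#' @return An [expression_table()].
#' @export
read_counts <- function(path, spikein_prefix = "ERCC-", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    storage.mode(m) <- "double"   # pattern/logical sparse input
    stem <- sub("\\.mtx$", "", path)
    gf <- paste0(stem, ".genes.txt"); cf <- paste0(stem, ".cells.txt")
    if (!file.exists(gf) || !file.exists(cf))
      stop("MatrixMarket input needs sidecar files ", gf, " and ", cf)
    rownames(m) <- readLines(gf)
    colnames(m) <- readLines(cf)
  } else {
    if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(!apply(df[, -1, drop = FALSE], 2, is.numeric))
      stop("non-numeric entries in column(s): ",
           paste(colnames(m)[bad], collapse = ", "))
    }
    rownames(m) <- ids
    dup <- unique(ids[duplicated(ids)])
    if (length(dup)) stop("duplicate gene IDs: ", paste(dup, collapse = ", "))
  }
  expression_table(m, spikein_prefix = spikein_prefix)
}

#' Write a counts matrix
#'
#' Inverse of [read_counts()]: CSV/TSV with a `gene` ID column, or
#' MatrixMarket triplet with `.genes.txt`/`.cells.txt` sidecars. Integer
#' inputs round-trip exactly.
#'
#' @param table ExpressionTable.
#' @param path output path; format chosen by extension as in [read_counts()].
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "ExpressionTable"))
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(table$counts, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(table$gene_ids, paste0(stem, ".genes.txt"))
    writeLines(table$cell_ids, paste0(stem, ".cells.txt"))
  } else {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- data.frame(gene = table$gene_ids, table$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: set name, description, then member gene symbols, all
#' tab-separated. Symbols are de-duplicated within a set.
#'
#' @param path GMT file path.
#' @return `GeneSetCollection`: list with `sets` (named list of character
#'   vectors) and `descriptions` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    if (f[1] %in% names(sets))
      stop("duplicate gene-set name: ", f[1])
    sets[[f[1]]] <- unique(f[-(1:2)])
    desc[f[1]] <- f[2]
  }
  structure(list(sets = sets, descriptions = desc), class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, median size %s\n",
              length(x$sets),
              if (length(x$sets)) stats::median(lengths(x$sets)) else NA))
  invisible(x)
}

#' Read a protein-protein interaction edge list
#'
#' TSV with header columns `gene_a`, `gene_b`, `weight` (confidence in
#' \[0,1\], e.g. a STRING combined score / 1000). Self-loops are dropped with
#' a warning; duplicate and reversed-duplicate pairs are merged keeping the
#' maximum weight; edges below `min_weight` are removed.
#'
#' @param path TSV file path.
#' @param min_weight minimum edge confidence retained (default 0).
#' @return `EdgeList`: data.frame with columns gene_a, gene_b, weight.
#' @export
read_edge_list <- function(path, min_weight = 0) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b", "weight") %in% colnames(df)))
    stop("edge list must have columns gene_a, gene_b, weight")
  if (any(df$weight < 0 | df$weight > 1))
    stop("edge weights must lie in [0, 1]")
  edge_list(df, min_weight = min_weight)
}

#' Build an EdgeList from a data frame of undirected weighted edges
#'
#' @param df data.frame with columns gene_a, gene_b, weight.
#' @param min_weight minimum weight retained.
#' @return `EdgeList` data.frame (gene_a, gene_b, weight), one row per
#'   unordered pair.
#' @export
edge_list <- function(df, min_weight = 0) {
  loops <- df$gene_a == df$gene_b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    df <- df[!loops, , drop = FALSE]
  }
  if (nrow(df)) {
    a <- pmin(df$gene_a, df$gene_b)
    b <- pmax(df$gene_a, df$gene_b)
    key <- paste(a, b, sep = "\r")
    w <- tapply(df$weight, key, max)
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    df <- data.frame(gene_a = vapply(parts, `[`, "", 1),
                     gene_b = vapply(parts, `[`, "", 2),
                     weight = as.numeric(w),
                     stringsAsFactors = FALSE, row.names = NULL)
    df <- df[df$weight >= min_weight, , drop = FALSE]
    df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, class = c("EdgeList", "data.frame"))
}

#' @export
print.EdgeList <- function(x, ...) {
  nodes <- unique(c(x$gene_a, x$gene_b))
  cat(sprintf("EdgeList: %d edges over %d nodes\n", nrow(x), length(nodes)))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Write a result table as TSV with header
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
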