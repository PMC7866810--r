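# Small in-code fixtures shared across tests.

make_table <- function(counts, genes = NULL, cells = NULL, ...) {
  counts <- as.matrix(counts)
  rownames(counts) <- genes %||% sprintf("G%d", seq_len(nrow(counts)))
  colnames(counts) <- cells %||% sprintf("c%d", seq_len(ncol(counts)))
  expression_table(counts, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Well-separated spherical blobs in gene space; returns an ExpressionTable
# (non-negative, shifted) plus the true labels.
make_blobs <- function(k = 3, per = 20, p = 10, sep = 20, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(k * p), k)
  centers <- centers / sqrt(rowSums(centers^2)) * sep
  lab <- rep(seq_len(k), each = per)
  x <- centers[lab, ] + matrix(stats::rnorm(per * k * p, sd = sd), per * k)
  x <- t(x) - min(x)          # genes x cells, non-negative
  dimnames(x) <- list(sprintf("G%d", seq_len(p)),
                      sprintf("c%d", seq_len(per * k)))
  tab <- expression_table(2^x - 1)   # undo the log2(x+1) cluster space
  list(table = tab, labels = lab)
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
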