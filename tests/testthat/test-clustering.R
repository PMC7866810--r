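test_that("distance metrics satisfy their defining identities", {
  # two identical cells at distance 0 under every metric
  m <- cbind(a = c(1, 5, 2, 8), b = c(1, 5, 2, 8), c = c(4, 0, 9, 1))
  tab <- make_table(m, cells = colnames(m))
  for (metric in c("pearson", "euclidean_correlation", "euclidean")) {
    d <- distance_matrix(tab, metric)
    expect_equal(d["a", "b"], 0, tolerance = 1e-12)
    expect_true(isSymmetric(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0))
  }

  # perfectly anti-correlated profiles in log space: distance 1 - (-1) = 2
  x <- rbind(c(1, 3), c(2, 2), c(3, 1))          # log2(counts + 1)
  anti <- make_table(2^x - 1, cells = c("u", "v"))
  expect_equal(distance_matrix(anti, "pearson")["u", "v"], 2)

  # euclidean-of-correlation matches the brute-force two-step computation
  set.seed(5)
  m4 <- matrix(rpois(24, 20), 6, 4)
  tab4 <- make_table(m4)
  d4 <- distance_matrix(tab4, "euclidean_correlation")
  r <- cor(log2(m4 + 1))
  for (i in 1:4) for (j in 1:4)
    expect_equal(d4[i, j], sqrt(sum((r[i, ] - r[j, ])^2)), tolerance = 1e-12)

  const <- make_table(cbind(c(2, 2, 2), c(1, 5, 9)), cells = c("flat", "ok"))
  expect_error(distance_matrix(const, "pearson"), "flat")
})

test_that("gap-statistic k-means recovers well-separated blobs and a single blob", {
  blobs <- make_blobs(k = 3, per = 20, p = 10, sep = 20, sd = 1, seed = 4)
  res <- cluster_kmeans_gap(blobs$table, k_range = 1:6, distance = "euclidean",
                            gap_refs = 30, seed = 2)
  expect_equal(res$k, 3L)
  expect_equal(mclust::adjustedRandIndex(res$labels, blobs$labels), 1)
  expect_true(all(res$labels %in% 1:3))
  expect_true(all(tabulate(res$labels, res$k) > 0))

  single <- make_blobs(k = 1, per = 40, p = 6, sep = 0, sd = 1, seed = 8)
  res1 <- cluster_kmeans_gap(single$table, k_range = 1:4,
                             distance = "euclidean", gap_refs = 30, seed = 2)
  expect_equal(res1$k, 1L)
})

test_that("pearson-distance k-means separates correlation-structured clusters", {
  set.seed(12)
  p <- 40
  prof <- list(rnorm(p), rnorm(p))
  x <- sapply(rep(1:2, each = 15), function(cl) prof[[cl]] + rnorm(p, sd = 0.2))
  x <- x - min(x)
  dimnames(x) <- list(sprintf("G%d", 1:p), sprintf("c%d", 1:30))
  tab <- expression_table(2^x - 1)
  res <- cluster_kmeans_gap(tab, k_range = 1:4, distance = "pearson",
                            gap_refs = 20, seed = 3)
  expect_equal(res$k, 2L)
  expect_equal(mclust::adjustedRandIndex(res$labels, rep(1:2, each = 15)), 1)
})

test_that("a user-fixed k bypasses gap selection", {
  blobs <- make_blobs(k = 2, per = 15, p = 6, seed = 3)
  res <- cluster_kmeans_gap(blobs$table, k_range = 1:5, gap_refs = 5,
                            distance = "euclidean", seed = 1, k_fix = 4)
  expect_equal(res$k, 4L)
  expect_equal(sort(unique(unname(res$labels))), 1:4)
  expect_error(cluster_kmeans_gap(blobs$table, k_range = 1:40),
               "below the number of cells")
})

test_that("gap statistic on a single uniform blob prefers k = 1", {
  hits <- 0L
  for (rep in 1:20) {
    set.seed(1000 + rep)
    x <- matrix(runif(40 * 4, 0, 4), 40)
    dimnames(x) <- list(NULL, NULL)
    rownames(x) <- sprintf("c%d", 1:40)
    colnames(x) <- sprintf("G%d", 1:4)
    tab <- expression_table(t(2^x - 1))
    res <- cluster_kmeans_gap(tab, k_range = 1:5, distance = "euclidean",
                              gap_refs = 100, seed = rep)
    hits <- hits + (res$k == 1L)
  }
  expect_gte(hits, 18L)
})

test_that("model-based clustering selects k by BIC on separated Gaussians", {
  blobs <- make_blobs(k = 2, per = 30, p = 8, sep = 30, sd = 1, seed = 6)
  res <- cluster_model_based(blobs$table, k_range = 1:5, seed = 1)
  expect_equal(res$k, 2L)
  expect_equal(mclust::adjustedRandIndex(res$labels, blobs$labels), 1)
  expect_equal(res$bic_curve$k, 1:5)
  expect_equal(res$bic_curve$k[which.max(res$bic_curve$bic)], 2L)

  single <- make_blobs(k = 1, per = 50, p = 6, sep = 0, sd = 1, seed = 9)
  res1 <- cluster_model_based(single$table, k_range = 1:4, seed = 1)
  expect_equal(res1$k, 1L)

  # determinism: same seed, same labels
  res_b <- cluster_model_based(blobs$table, k_range = 1:5, seed = 1)
  expect_identical(res$labels, res_b$labels)
})

test_that("Jaccard index and bootstrap stability behave as defined", {
  expect_equal(jaccard_index(1:3, 1:3), 1)
  expect_equal(jaccard_index(1:3, 2:4), 0.5)
  expect_equal(jaccard_index(integer(0), integer(0)), 1)

  blobs <- make_blobs(k = 3, per = 20, p = 10, sep = 20, sd = 1, seed = 4)
  res <- cluster_kmeans_gap(blobs$table, k_range = 3, distance = "euclidean",
                            gap_refs = 2, seed = 2, k_fix = 3)
  st <- jaccard_stability(blobs$table, res, n_bootstrap = 20, seed = 5)
  expect_length(st$jaccard, 3L)
  expect_true(all(st$jaccard >= 0 & st$jaccard <= 1))
  expect_true(all(st$jaccard > 0.6))   # the conventional stability bar
})

test_that("silhouette widths match the brute-force definition and conventions", {
  set.seed(14)
  x <- rbind(matrix(rnorm(5 * 3), 5), matrix(rnorm(5 * 3, mean = 6), 5))
  d <- as.matrix(dist(x))
  lab <- rep(1:2, each = 5)
  sw <- silhouette_widths(d, lab)

  brute <- sapply(1:10, function(i) {
    a <- mean(d[i, setdiff(which(lab == lab[i]), i)])
    b <- min(sapply(setdiff(1:2, lab[i]), function(cl)
      mean(d[i, lab == cl])))
    (b - a) / max(a, b)
  })
  expect_equal(unname(sw$silhouette), brute, tolerance = 1e-12)

  # two tight, far-apart clusters: mean width near 1
  y <- rbind(matrix(rnorm(20 * 2, sd = 0.1), 20),
             matrix(rnorm(20 * 2, mean = 50, sd = 0.1), 20))
  swy <- silhouette_widths(as.matrix(dist(y)), rep(1:2, each = 20))
  expect_gt(mean(swy$silhouette), 0.9)

  # singleton cluster members get width 0 by convention
  lab3 <- c(rep(1, 5), rep(2, 4), 3)
  sw3 <- silhouette_widths(d, lab3)
  expect_equal(unname(sw3$silhouette[10]), 0)

  expect_error(silhouette_widths(d, rep(1, 10)), "at least 2")
})

test_that("NB upper tail matches direct summation of the mass function", {
  cases <- expand.grid(x = c(1, 5, 20, 100, 200), mu = c(0.5, 4, 30),
                       phi = c(1.5, 3))
  for (i in seq_len(nrow(cases))) {
    x <- cases$x[i]; mu <- cases$mu[i]; v <- cases$phi[i] * mu
    r <- mu^2 / (v - mu)
    direct <- sum(dnbinom(x:(x + 5000), size = r, mu = mu))
    expect_lt(abs(scbiodisc:::.nb_upper_tail(x, mu, v) - direct), 1e-10)
  }
  # Poisson fallback when the fitted variance does not exceed the mean
  expect_equal(scbiodisc:::.nb_upper_tail(7, 2, 1.5),
               1 - sum(dpois(0:6, 2)), tolerance = 1e-12)
})

test_that("an injected outlier cell is the only cell flagged", {
  set.seed(30)
  g <- 60; n <- 40
  mu <- rlnorm(g, 3, 0.8)
  counts <- sapply(seq_len(n), function(c) rnbinom(g, mu = mu, size = 4))
  spiked <- sample(g, 6)
  counts[spiked, 17] <- counts[spiked, 17] * 20 + 1
  dimnames(counts) <- list(sprintf("G%d", 1:g), sprintf("c%d", 1:n))
  tab <- expression_table(counts)
  rep <- detect_outliers(tab, rep(1L, n), probthr = 1e-3, outminc = 2)
  expect_equal(names(which(rep$outlier)), "c17")
  expect_gte(rep$n_outlier_genes[["c17"]], 2)
  expect_true(all(rep$n_outlier_genes <= g))
  expect_identical(unname(rep$outlier),
                   unname(rep$n_outlier_genes >= 2))

  # the 5%-of-genes convention resolves to ceiling(0.05 * n_genes)
  rep5 <- detect_outliers(tab, rep(1L, n), probthr = 1e-3, outminc = "5pct")
  expect_equal(rep5$outminc, ceiling(0.05 * g))

  expect_warning(detect_outliers(tab, c(2L, rep(1L, n - 1))), "fewer than 2")
})

test_that("PCA embedding preserves 2-D geometry and orders variance", {
  set.seed(40)
  emb_tab <- make_blobs(k = 2, per = 10, p = 6, seed = 2)$table
  emb <- compute_embedding(emb_tab, "pca")
  expect_equal(nrow(emb$coordinates), 20L)
  expect_true(all(diff(emb$explained_var) <= 1e-12))

  # data of intrinsic dimension 2: pairwise distances are reproduced
  z <- matrix(rnorm(2 * 15), 15)
  x <- cbind(z, z %*% matrix(c(1, 2, -1, 0.5, 0.3, -2, 1, 0.7), 2))  # rank 2
  x <- x - min(x)
  dimnames(x) <- list(sprintf("c%d", 1:15), sprintf("G%d", 1:6))
  tab2 <- expression_table(t(2^x - 1))
  e2 <- compute_embedding(tab2, "pca")
  expect_equal(as.matrix(dist(e2$coordinates)), as.matrix(dist(x)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("tSNE is seeded-deterministic and validates perplexity", {
  tab <- make_blobs(k = 2, per = 15, p = 8, seed = 3)$table
  e1 <- compute_embedding(tab, "tsne", seed = 7, perplexity = 5)
  e2 <- compute_embedding(tab, "tsne", seed = 7, perplexity = 5)
  expect_identical(e1$coordinates, e2$coordinates)
  expect_error(compute_embedding(tab, "tsne", perplexity = 10),
               "perplexity")
})

test_that("hierarchical center ordering is a sane heatmap order", {
  blobs <- make_blobs(k = 2, per = 10, p = 6, seed = 5)
  d <- distance_matrix(blobs$table, "euclidean")
  ord2 <- order_clusters_hierarchically(d, blobs$labels)
  expect_true(identical(ord2, c(1L, 2L)) || identical(ord2, c(2L, 1L)))

  # three collinear centers: the middle one is never a dendrogram end
  set.seed(16)
  centers <- rbind(c(0, 0), c(10, 0), c(20, 0))
  lab <- rep(1:3, each = 8)
  x <- centers[lab, ] + matrix(rnorm(48, sd = 0.3), 24)
  x <- x - min(x)
  dimnames(x) <- list(sprintf("c%d", 1:24), c("G1", "G2"))
  tab <- expression_table(t(2^x - 1))
  d3 <- distance_matrix(tab, "euclidean")
  ord3 <- order_clusters_hierarchically(d3, lab)
  expect_setequal(ord3, 1:3)
  expect_equal(ord3[2], 2L)
})

test_that("cluster labels are permutation-equivariant (model-based)", {
  blobs <- make_blobs(k = 2, per = 25, p = 8, sep = 30, seed = 11)
  res <- cluster_model_based(blobs$table, k_range = 2, seed = 1)
  perm <- sample(50)
  tab_p <- subset_table(blobs$table, cells = perm)
  res_p <- cluster_model_based(tab_p, k_range = 2, seed = 1)
  expect_equal(mclust::adjustedRandIndex(res$labels[perm], res_p$labels), 1)
})
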