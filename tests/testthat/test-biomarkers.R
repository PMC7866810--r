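test_that("a perfectly separating feature yields a depth-1 midpoint tree", {
  expr <- cbind(marker = c(5, 5, 5, 5, 10, 10, 10, 10),
                noise = c(1, 2, 1, 2, 1, 2, 1, 2))
  lab <- rep(c("a", "b"), each = 4)
  tree <- build_tree(expr, lab, cp = 0.01, minsplit = 2)
  expect_false(tree$root$leaf)
  expect_equal(tree$root$gene, "marker")
  expect_equal(tree$root$threshold, 7.5)
  expect_true(tree$root$left$leaf && tree$root$right$leaf)
  expect_equal(as.character(predict(tree, expr)), lab)

  expect_error(build_tree(expr, rep("a", 8)), "2 classes")
})

test_that("Gini impurity has its closed-form values", {
  expect_equal(scbiodisc:::.gini(c(5, 0)), 0)
  expect_equal(scbiodisc:::.gini(c(5, 5)), 0.5)
  expect_equal(scbiodisc:::.gini(c(3, 1)), 1 - (0.75^2 + 0.25^2))
})

test_that("the chosen split matches exhaustive brute-force enumeration", {
  set.seed(60)
  expr <- matrix(rnorm(20 * 3), 20, dimnames = list(NULL, c("f1", "f2", "f3")))
  lab <- factor(rep(c("x", "y"), each = 10))
  expr[lab == "y", 2] <- expr[lab == "y", 2] + 1.5  # informative feature
  tree <- build_tree(expr, lab, cp = 0.001, minsplit = 20)

  y <- as.integer(lab)
  best <- list(score = Inf)
  for (f in 1:3) {
    uv <- sort(unique(expr[, f]))
    for (t in (uv[-1] + uv[-length(uv)]) / 2) {
      left <- expr[, f] < t
      gini <- function(idx) {
        p <- mean(y[idx] == 1); 1 - p^2 - (1 - p)^2
      }
      sc <- (sum(left) * gini(left) + sum(!left) * gini(!left)) / 20
      if (sc < best$score - 1e-12) best <- list(score = sc, f = f, t = t)
    }
  }
  expect_equal(tree$root$feature, best$f)
  expect_equal(tree$root$threshold, best$t)
})

test_that("the root split agrees with rpart on the same data", {
  skip_if_not_installed("rpart")
  set.seed(61)
  expr <- matrix(rnorm(60 * 4), 60,
                 dimnames = list(NULL, paste0("g", 1:4)))
  lab <- factor(rep(c("a", "b"), each = 30))
  expr[lab == "b", 3] <- expr[lab == "b", 3] + 2
  tree <- build_tree(expr, lab, cp = 0.01, minsplit = 20)
  rp <- rpart::rpart(lab ~ ., data = data.frame(expr, lab),
                     method = "class",
                     control = rpart::rpart.control(cp = 0.01,
                                                    minsplit = 20))
  expect_equal(tree$root$gene, as.character(rp$frame$var[1]))
  expect_equal(tree$root$threshold, unname(rp$splits[1, "index"]))
})

test_that("training accuracy is non-increasing in cp", {
  set.seed(62)
  expr <- matrix(rnorm(80 * 5), 80, dimnames = list(NULL, paste0("g", 1:5)))
  lab <- factor(ifelse(expr[, 1] + 0.8 * expr[, 2] + rnorm(80, sd = 0.8) > 0,
                       "a", "b"))
  acc <- vapply(c(0.001, 0.01, 0.05, 0.2), function(cp) {
    tr <- build_tree(expr, lab, cp = cp, minsplit = 5)
    mean(predict(tr, expr) == lab)
  }, 0)
  expect_true(all(diff(acc) <= 1e-12))
})

test_that("the c45 gain-ratio inducer separates clean data too", {
  expr <- cbind(m = c(rep(0, 6), rep(4, 6)), n = rnorm(12))
  lab <- rep(c("lo", "hi"), each = 6)
  tr <- build_tree(expr, lab, inducer = "c45", minsplit = 4)
  expect_equal(tr$root$gene, "m")
  expect_equal(as.character(predict(tr, expr)), lab)
})

test_that("tree JSON and DOT exports contain the decision nodes", {
  expr <- cbind(g = c(1, 1, 9, 9), h = c(2, 3, 2, 3))
  tree <- build_tree(expr, c("a", "a", "b", "b"), minsplit = 2)
  js <- jsonlite::fromJSON(tree_to_json(tree))
  expect_equal(js$gene, "g")
  expect_equal(js$threshold, 5)
  dot <- tree_to_dot(tree)
  expect_match(dot, "digraph")
  expect_match(dot, "g < 5")
})

test_that("cross-validation metrics follow their formulas and are reproducible", {
  # closed-form check on a mocked pooled confusion
  cm <- c(TP = 99, FN = 1, FP = 0, TN = 100)
  expect_equal(unname((cm["TP"] + cm["TN"]) / sum(cm)), 0.995)
  expect_equal(unname(cm["TP"] / (cm["TP"] + cm["FN"])), 0.99)
  expect_equal(unname(cm["TN"] / (cm["TN"] + cm["FP"])), 1.0)

  set.seed(63)
  expr <- cbind(marker = c(rnorm(100, 0), rnorm(100, 10)),
                junk = rnorm(200))
  lab <- factor(rep(c("rest", "target"), each = 100),
                levels = c("rest", "target"))
  cv <- cross_validate(expr, lab, n_folds = 10, seed = 2,
                       positive = "target")
  expect_gte(cv$accuracy, 0.99)
  expect_equal(sum(cv$confusion), 200)
  expect_true(all(abs(rowSums(cv$per_fold) - 20) <= 1))
  expect_true(all(c(cv$accuracy, cv$sensitivity, cv$specificity) >= 0 &
                    c(cv$accuracy, cv$sensitivity, cv$specificity) <= 1))

  cv2 <- cross_validate(expr, lab, n_folds = 10, seed = 2,
                        positive = "target")
  expect_identical(cv$per_fold, cv2$per_fold)
  expect_error(cross_validate(expr[1:5, ], lab[1:5], n_folds = 10), "exceeds")
})

test_that("induced subnetworks keep only edges within the gene list", {
  el <- edge_list(data.frame(gene_a = c("A", "B", "C"),
                             gene_b = c("B", "C", "D"),
                             weight = c(0.9, 0.8, 0.7)))
  sub <- induced_subnetwork(el, c("A", "B", "C", "Z"))
  expect_equal(nrow(sub), 2L)
  expect_true(all(c(sub$gene_a, sub$gene_b) %in% c("A", "B", "C")))
  expect_setequal(attr(sub, "isolated"), "Z")
  expect_warning(empty <- induced_subnetwork(el, c("Q", "R")), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("centrality matches hand-computed and brute-force values", {
  path <- edge_list(data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                               weight = 1))
  ct <- centrality(path)
  expect_equal(ct$betweenness[ct$gene == "B"], 1)
  expect_equal(ct$betweenness[ct$gene != "B"], c(0, 0))
  expect_equal(ct$degree[ct$gene == "B"], 2L)
  expect_equal(ct$hub_rank, 1:3)

  star <- edge_list(data.frame(gene_a = "HUB", gene_b = c("L1", "L2", "L3"),
                               weight = 1))
  cs <- centrality(star)
  expect_equal(cs$betweenness[cs$gene == "HUB"], 3)  # C(3,2) pairs

  # brute-force all-pairs shortest-path enumeration on a random 8-node graph
  set.seed(64)
  nodes <- LETTERS[1:8]
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < 0.45
  el <- edge_list(data.frame(gene_a = pairs[keep, 1],
                             gene_b = pairs[keep, 2], weight = 1))
  ct8 <- centrality(el)
  present <- unique(c(el$gene_a, el$gene_b))
  adj <- matrix(FALSE, length(present), length(present),
                dimnames = list(present, present))
  for (i in seq_len(nrow(el))) {
    adj[el$gene_a[i], el$gene_b[i]] <- TRUE
    adj[el$gene_b[i], el$gene_a[i]] <- TRUE
  }
  # enumerate all simple paths between every pair, keep the shortest
  all_paths <- function(a, b) {
    out <- list()
    grow <- function(path) {
      last <- path[length(path)]
      if (last == b) { out[[length(out) + 1]] <<- path; return() }
      for (nxt in present[adj[last, ]])
        if (!nxt %in% path) grow(c(path, nxt))
    }
    grow(a)
    if (!length(out)) return(list())
    len <- vapply(out, length, 0L)
    out[len == min(len)]
  }
  btw <- setNames(numeric(length(present)), present)
  pp <- t(combn(present, 2))
  for (i in seq_len(nrow(pp))) {
    sp <- all_paths(pp[i, 1], pp[i, 2])
    if (!length(sp)) next
    inner <- unlist(lapply(sp, function(p) p[-c(1, length(p))]))
    if (length(inner)) {
      tab <- table(inner) / length(sp)
      btw[names(tab)] <- btw[names(tab)] + tab
    }
  }
  expect_equal(ct8$betweenness, unname(btw[ct8$gene]), tolerance = 1e-12)
  expect_equal(ct8$degree, unname(rowSums(adj)[ct8$gene]))
})

test_that("tree-graph betweenness sums satisfy the path-count identity", {
  # over a tree, each non-adjacent unordered pair contributes its single
  # path's interior vertices: sum(betweenness) = sum over pairs of
  # (path length - 1) = C(n,2) total interior visits
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:6, 1)
    parent <- vapply(2:n, function(i) sample(seq_len(i - 1), 1), 0L)
    el <- edge_list(data.frame(gene_a = paste0("N", 2:n),
                               gene_b = paste0("N", parent), weight = 1))
    ct <- centrality(el)
    g <- igraph::graph_from_data_frame(el[, 1:2], directed = FALSE)
    d <- igraph::distances(g)
    expected_sum <- sum(d[upper.tri(d)] - 1)
    expect_equal(sum(ct$betweenness), expected_sum)
  }
})

test_that("hypergeometric enrichment matches closed forms and Fisher's test", {
  gs <- structure(list(sets = list(S = paste0("g", 1:5)),
                       descriptions = c(S = "d")),
                  class = "GeneSetCollection")
  uni <- paste0("g", 1:20)
  et <- enrich(paste0("g", 1:5), gs, uni)
  expect_equal(et$p_value, 1 / choose(20, 5), tolerance = 1e-12)

  et0 <- enrich(paste0("g", 10:14), gs, uni)
  expect_equal(et0$overlap, 0L)
  expect_equal(et0$p_value, 1)

  # one-sided Fisher-exact oracle over random configurations
  set.seed(65)
  for (rep in 1:25) {
    N <- sample(20:60, 1)
    uni <- paste0("u", seq_len(N))
    set_g <- sample(uni, sample(3:10, 1))
    query <- sample(uni, sample(3:15, 1))
    gsr <- structure(list(sets = list(S = set_g), descriptions = c(S = "")),
                     class = "GeneSetCollection")
    p <- enrich(query, gsr, uni)$p_value
    k <- length(intersect(set_g, query))
    tab <- matrix(c(k, length(set_g) - k, length(query) - k,
                    N - length(set_g) - length(query) + k), 2)
    expect_equal(p, fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }

  expect_warning(enrich(c("g1", "zzz"), gs, paste0("g", 1:20)), "outside")
  expect_error(enrich("g1", gs, character()), "empty universe")
})

test_that("enrichment p-values are invariant to gene relabeling", {
  uni <- paste0("u", 1:30)
  set_g <- uni[1:8]; query <- uni[5:14]
  gs1 <- structure(list(sets = list(S = set_g), descriptions = c(S = "")),
                   class = "GeneSetCollection")
  relab <- setNames(paste0("x", 1:30), uni)
  gs2 <- structure(list(sets = list(S = unname(relab[set_g])),
                        descriptions = c(S = "")),
                   class = "GeneSetCollection")
  p1 <- enrich(query, gs1, uni)$p_value
  p2 <- enrich(unname(relab[query]), gs2, unname(relab))$p_value
  expect_equal(p1, p2, tolerance = 1e-15)
})
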