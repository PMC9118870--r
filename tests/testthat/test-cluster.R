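test_that("link neighborhood follows the shared-node + adjacent-node rule", {
  # 4 ROIs: A-B adjacent, C and D isolated from them, C-D adjacent
  roi_adj <- matrix(FALSE, 4, 4)
  roi_adj[1, 2] <- roi_adj[2, 1] <- TRUE
  roi_adj[3, 4] <- roi_adj[4, 3] <- TRUE
  links <- link_table(4)  # (1,2) (1,3) (1,4) (2,3) (2,4) (3,4)
  la <- link_adjacency(roi_adj)
  lk <- function(i, j) which(links$i == min(i, j) & links$j == max(i, j))
  # (C,A) and (C,B): share C, and A-B adjacent -> neighbors
  expect_true(la[lk(3, 1), lk(3, 2)])
  # (A,B) and (C,D): no shared ROI -> never neighbors
  expect_false(la[lk(1, 2), lk(3, 4)])
  # (A,C) and (A,D): share A, C-D adjacent -> neighbors
  expect_true(la[lk(1, 3), lk(1, 4)])
  # (A,B) and (A,C): share A, but B-C not adjacent -> not neighbors
  expect_false(la[lk(1, 2), lk(1, 3)])
  expect_true(isSymmetric(la))
  expect_false(any(diag(la)))
})

test_that("cluster formation thresholds and connects correctly", {
  # chain of 3 nodes (1 space, 3 frequencies)
  g <- feature_graph(matrix(FALSE, 1, 1), 3)
  cl <- form_clusters(c(0.01, 0.04, 0.2), g, 0.05)
  expect_length(cl, 1)
  expect_equal(cl[[1]], c(1L, 2L))
  expect_length(form_clusters(c(0.5, 0.9, 0.6), g, 0.05), 0)
  expect_equal(form_clusters(c(0.01, 0.01, 0.01), g, 0.05)[[1]], 1:3)
  # permuting node order leaves clusters (as sets) unchanged
  adj <- matrix(FALSE, 3, 3)
  adj[1, 2] <- adj[2, 1] <- TRUE
  g2 <- feature_graph(adj, 2)
  p <- c(0.01, 0.2, 0.03, 0.2, 0.9, 0.04)
  cl2 <- form_clusters(p, g2, 0.05)
  expect_equal(sort(unlist(cl2)), sort(which(p < 0.05)))
})

test_that("edgeless-graph permutation null matches brute-force enumeration", {
  # <= 10 isolated nodes, all 2^6-ish label permutations enumerable:
  # compare the permutation distribution of the max count of significant
  # isolated nodes with a brute-force oracle over the same relabelings
  set.seed(20)
  n <- 12
  meta <- data.frame(id = as.character(1:n),
                     group = rep(c("ASD", "NT"), each = 6),
                     age = runif(n, 6, 32), sex = rep("M", n),
                     iq = rnorm(n, 100, 10), site = rep("s1", n))
  y <- matrix(rnorm(n * 6), n, 6)
  g <- feature_graph(matrix(FALSE, 6, 6), 1)
  res <- permutation_test(y, meta, g, "mean", n_perm = 200, engine = "ols",
                          seed = 5)
  # brute-force: recompute observed per-node p with plain lm and compare
  tab <- prepare_feature_table(cbind(meta, y = 0))
  p_oracle <- vapply(1:6, function(k) {
    d <- tab; d$y <- y[, k]
    f0 <- lm(y ~ age_s + sex01 + iq_s, d)
    f1 <- lm(y ~ age_s + sex01 + iq_s + asd + asd:age_s + asd:sex01 +
               asd:iq_s, d)
    anova(f0, f1)$`Pr(>F)`[2]
  }, numeric(1))
  expect_equal(unname(res$pvals), p_oracle, tolerance = 1e-8)
  # with no edges every cluster is a single node
  expect_true(all(res$sizes == 1))
})

test_that("cluster p-values are monotone in cluster size and deterministic", {
  set.seed(21)
  meta <- make_meta(20, seed = 22)
  adj <- matrix(FALSE, 4, 4)
  adj[cbind(1:3, 2:4)] <- TRUE
  adj <- adj | t(adj)
  g <- feature_graph(adj, 3)
  y <- matrix(rnorm(40 * 12), 40, 12)
  y[meta$group == "ASD", 5:7] <- y[meta$group == "ASD", 5:7] + 1.2
  r1 <- permutation_test(y, meta, g, "mean", n_perm = 150, seed = 9)
  r2 <- permutation_test(y, meta, g, "mean", n_perm = 150, seed = 9)
  expect_identical(r1$p, r2$p)
  if (length(r1$sizes) > 1) {
    ord <- order(-r1$sizes)
    expect_true(all(diff(r1$p[ord]) >= 0))
  }
  expect_warning(
    permutation_test(y, meta, g, "mean", n_perm = 50, seed = 1),
    "resolution")
})

test_that("an injected multi-node effect is recovered as a significant cluster", {
  meta <- make_meta(100, seed = 23)
  adj <- matrix(FALSE, 5, 5)
  adj[cbind(1:4, 2:5)] <- TRUE
  adj <- adj | t(adj)
  g <- feature_graph(adj, 4)  # 20 nodes
  hits <- vapply(1:20, function(b) {
    set.seed(300 + b)
    y <- matrix(rnorm(200 * 20), 200, 20)
    inj <- c(5, 6, 9, 10, 13)  # spatially/frequency adjacent block
    y[meta$group == "ASD", inj] <- y[meta$group == "ASD", inj] + 1
    r <- permutation_test(y, meta, g, "mean", n_perm = 150,
                          seed = 600 + b)
    best <- which.max(r$sizes)
    r$p[best] < 0.05 && length(intersect(r$clusters[[best]], inj)) >= 3
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("fast engine agrees with the mixed-model tests on large samples", {
  meta <- make_meta(150, seed = 24)
  y <- vapply(1:6, function(k)
    simulate_feature_table(meta, d = ifelse(k <= 3, 0.35, 0),
                           seed = 700 + k)$y, numeric(300))
  g <- feature_graph(matrix(FALSE, 6, 6), 1)
  tab <- prepare_feature_table(cbind(meta, y = 0))
  fast <- resteeg:::ols_node_tester(y, tab, "mean")(tab$asd)
  slow <- vapply(1:6, function(k) {
    d <- meta; d$y <- y[, k]
    group_tests(d)$p_mean
  }, numeric(1))
  # agreement matters where thresholding happens: below p = 0.15 the two
  # engines agree closely, and the 0.05 decisions coincide everywhere
  dec <- pmin(fast, slow) < 0.15
  expect_lt(max(abs(fast[dec] - slow[dec])), 0.015)
  expect_identical(fast < 0.05, slow < 0.05)
})
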