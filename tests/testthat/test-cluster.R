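test_that("transform is log2(x+1) with exact gene centering", {
  m <- matrix(c(0, 3, 1, 3, 7, 3), 2, dimnames = list(c("g1", "g2"), NULL))
  y <- transform_counts(m)
  expect_equal(unname(y[1, 1]), log2(1) - mean(log2(m[1, ] + 1)))
  expect_true(all(abs(rowMeans(y)) < 1e-9))
  expect_equal(unname(y[2, ]), c(0, 0, 0))   # constant gene -> zero row
})

test_that("variable-gene ranking is variance-based and deterministic", {
  set.seed(2)
  m <- rbind(flat = rep(5, 30), noisy = rpois(30, 5) + c(0, 40),
             tie_a = rep(1, 30), tie_b = rep(1, 30))
  vg <- variable_genes(m, 4)
  expect_equal(vg[1], "noisy")
  # constant genes all have variance 0; ties break lexicographically
  expect_equal(vg[2:4], sort(c("flat", "tie_a", "tie_b")))
  sim <- simulate_expression(n_cell_types = 2, markers_per_type = 4,
                             n_genes = 80, n_cells = 120, depth = 1500,
                             fold_change = 20, seed = 3)
  norm <- normalize_counts(sim$counts)
  top <- variable_genes(norm$normalized, 8)
  markers <- sim$gene_meta$gene_id[!is.na(sim$gene_meta$marker_of)]
  expect_gte(sum(top %in% markers), 6)
})

test_that("PCA is exact, sign-fixed, with ordered variance", {
  # rank-1 data: PC1 explains everything
  u <- rnorm(10); v <- rnorm(6)
  m <- outer(u, v)
  p <- run_pca(m, 3)
  expect_equal(p$var_explained[1], 1)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  # two separated populations split on PC1
  sim <- simulate_expression(n_cell_types = 2, markers_per_type = 10,
                             n_genes = 100, n_cells = 80, depth = 2000,
                             fold_change = 15, seed = 5)
  norm <- normalize_counts(sim$counts)
  tr <- transform_counts(norm$normalized[variable_genes(norm$normalized, 50), ])
  pc <- run_pca(tr, 2)
  ty <- sim$cell_meta$type
  gap <- abs(mean(pc$scores[ty == "type1", 1]) - mean(pc$scores[ty == "type2", 1]))
  spread <- max(sd(pc$scores[ty == "type1", 1]), sd(pc$scores[ty == "type2", 1]))
  expect_gt(gap, 3 * spread)
  # deterministic sign convention
  pc2 <- run_pca(tr, 2)
  expect_identical(pc$scores, pc2$scores)
})

test_that("average-linkage correlation clustering matches hand computation", {
  # two identical profiles merge first at distance 0
  set.seed(6)
  base <- rnorm(20)
  m <- cbind(a = base, b = base, c = rnorm(20))
  hc <- hcluster_cells(m)
  expect_equal(sort(hc$hclust$merge[1, ]), c(-2, -1))
  expect_equal(hc$hclust$height[1], 0)
  # three cells: closest pair merges first; cluster-to-singleton distance
  # is the mean of the two cross distances (computed independently here)
  m3 <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("x", "y", "z")))
  d <- 1 - cor(m3)
  hc3 <- hcluster_cells(m3)$hclust
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  dd <- sapply(pairs, function(p) d[p[1], p[2]])
  first <- pairs[[which.min(dd)]]
  expect_equal(sort(hc3$merge[1, ]), sort(-first))
  rest <- setdiff(1:3, first)
  expect_equal(hc3$height[2], mean(d[rest, first]))
  # constant cell removed with warning
  mc <- cbind(m3, w = rep(1, 20))
  expect_warning(res <- hcluster_cells(mc), "constant")
  expect_equal(res$removed, "w")
})

test_that("cluster labels come from marker means, ties unresolved", {
  norm <- rbind(Ins1 = c(50, 50, 1, 1), Gcg = c(1, 1, 40, 40),
                other = c(5, 5, 5, 5))
  colnames(norm) <- sprintf("c%d", 1:4)
  labels <- setNames(c(1L, 1L, 2L, 2L), colnames(norm))
  got <- label_clusters(labels, norm, list(beta = "Ins1", alpha = "Gcg"))
  expect_equal(unname(got), c("beta", "alpha"))
  tie <- label_clusters(labels, norm, list(a = "other", b = "other2"))
  expect_equal(unname(tie[1]), "a")   # missing marker set scores NA
  even <- rbind(m1 = c(2, 2), m2 = c(2, 2))
  colnames(even) <- c("c1", "c2")
  got2 <- label_clusters(setNames(c(1L, 1L), colnames(even)), even,
                         list(a = "m1", b = "m2"))
  expect_equal(unname(got2), "unresolved")
  expect_error(label_clusters(labels, norm, list(a = "Ins1", b = "Ins1")),
               "disjoint")
})

test_that("cluster assignments are invariant to cell order", {
  sim <- simulate_expression(n_cell_types = 3, markers_per_type = 5,
                             n_genes = 90, n_cells = 60, depth = 1500,
                             fold_change = 10, seed = 8)
  norm <- normalize_counts(sim$counts)$normalized
  tr <- transform_counts(norm)
  l1 <- hcluster_cells(tr, k = 3)$labels
  set.seed(1); perm <- sample(ncol(tr))
  l2 <- hcluster_cells(tr[, perm], k = 3)$labels
  # same partition up to cluster renumbering
  l2 <- l2[colnames(tr)]
  expect_equal(length(unique(paste(l1, l2))), 3L)
})

test_that("pairwise correlation: identity, null, and the UMI advantage", {
  set.seed(12)
  m <- matrix(rpois(400, 5), 40, 10, dimnames = list(NULL, sprintf("c%d", 1:10)))
  r <- cell_pair_correlation(m)
  expect_equal(unname(diag(r)), rep(1, 10))
  # independent random profiles correlate near zero
  n_genes <- 400
  null <- matrix(rnorm(n_genes * 6), n_genes, 6)
  rn <- cell_pair_correlation(null, log = FALSE)
  expect_lt(max(abs(rn[upper.tri(rn)])), 3 / sqrt(n_genes) * 1.5)
  # PCR duplication noise: transcript-count correlation beats read-count
  mu <- rgamma(300, 1, 0.5) * 10
  tx <- sapply(1:12, function(i) rpois(300, mu))
  dup_reads <- apply(tx, 2, function(col)
    sapply(col, function(k) if (k == 0) 0 else sum(1 + rnbinom(k, mu = 4, size = 0.4))))
  r_tx <- median_pair_r(cell_pair_correlation(tx))
  r_rd <- median_pair_r(cell_pair_correlation(dup_reads))
  expect_gt(r_tx, r_rd)
})

test_that("the single-cell ensemble converges to the expression profile", {
  sim <- simulate_expression(n_genes = 200, n_cells = 300, depth = 2000,
                             dispersion = 0.4, seed = 9)
  bulk_like <- rowMeans(sim$counts)
  small <- rowMeans(sim$counts[, 1:5])
  big <- rowMeans(sim$counts[, 1:250])
  r_small <- cor(log2(small + 1), log2(bulk_like + 1))
  r_big <- cor(log2(big + 1), log2(bulk_like + 1))
  expect_gt(r_big, r_small)
  expect_gt(r_big, 0.95)
})
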