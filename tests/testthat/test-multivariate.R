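test_that("pairwise correlations equal the direct formula and cor.test", {
  set.seed(12)
  m <- tibble::tibble(genotype = paste0("g", 1:6),
                      a = rnorm(6), b = rnorm(6), c = rnorm(6))
  res <- trait_correlation(m)
  expect_equal(res$r["a", "b"], pearson_direct(m$a, m$b), tolerance = 1e-12)
  expect_equal(res$r["a", "c"], pearson_direct(m$a, m$c), tolerance = 1e-12)
  ct <- cor.test(m$a, m$b)
  expect_equal(res$r["a", "b"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p["a", "b"], ct$p.value, tolerance = 1e-12)
  # structure invariants
  expect_equal(diag(res$r), c(a = 1, b = 1, c = 1))
  expect_true(all(is.na(diag(res$p))))
  expect_equal(res$r, t(res$r))
  expect_equal(res$p, t(res$p))
})

test_that("correlation p-values decrease in |r| at fixed n", {
  n <- 17
  rs <- c(0.1, 0.3, 0.5, 0.7, 0.9, 0.99)
  p <- 2 * pt(abs(rs * sqrt((n - 2) / (1 - rs^2))), n - 2, lower.tail = FALSE)
  expect_true(all(diff(p) < 0))
  # and the package's own p for a strong pair is below that of a weak pair
  m <- cowpea_means()
  res <- trait_correlation(m)
  expect_lt(res$p["GWT", "PODWT"], res$p["DFF", "NPP"])
})

test_that("constant traits and tiny tables are rejected", {
  m <- tibble::tibble(genotype = c("a", "b", "c"), x = c(1, 1, 1), y = 1:3)
  expect_error(trait_correlation(m), "constant trait.*x")
  expect_error(trait_correlation(tibble::tibble(genotype = c("a", "b"),
                                                x = 1:2, y = 2:1)),
               "at least 3 genotypes")
  expect_error(trait_pca(m), "constant trait")
})

test_that("the published grain-yield correlations reproduce from the mean table", {
  res <- trait_correlation(cowpea_means())
  expect_equal(round(res$r["GWT", "PODWT"], 2), 0.95)
  expect_equal(round(res$r["GWT", "NPP"], 2), 0.87)
  expect_equal(round(res$r["GWT", "NSP"], 2), 0.84)
  expect_equal(round(res$r["DFF", "DNPM"], 2), 0.74)
  expect_equal(round(res$r["PHM", "HSW"], 2), 0.70)
  td <- tidy(res)
  expect_true(td$significant[td$trait1 == "PODWT" & td$trait2 == "GWT"])
})

test_that("eigendecomposition matches the closed-form equicorrelated spectrum", {
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  ed <- gentrial:::pca_from_cor(R)
  expect_equal(ed$values, c(2, 0.5, 0.5), tolerance = 1e-12)
  # sign convention: largest-magnitude loading of each component is positive
  for (j in 1:3) expect_gt(ed$vectors[which.max(abs(ed$vectors[, j])), j], 0)
})

test_that("PCA satisfies its spectral invariants on the reference means", {
  p <- trait_pca(cowpea_means())
  k <- length(p$eigenvalues)
  expect_equal(k, 8)
  expect_equal(sum(p$eigenvalues), 8, tolerance = 1e-8)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))  # descending
  expect_equal(p$variability_pct, 100 * p$eigenvalues / 8, tolerance = 1e-12)
  expect_equal(p$cumulative_pct[k], 100, tolerance = 1e-8)
  expect_true(all(diff(p$cumulative_pct) >= -1e-12))
  # unit-norm loading columns
  expect_equal(unname(colSums(p$loadings^2)), rep(1, k), tolerance = 1e-10)
  # reconstruction: V diag(lambda) V' = correlation matrix
  R <- cor(gentrial:::means_matrix(cowpea_means()))
  expect_equal(p$loadings %*% diag(p$eigenvalues) %*% t(p$loadings), R,
               tolerance = 1e-8, ignore_attr = TRUE)
  # scores are uncorrelated with variances equal to the eigenvalues
  S <- cov(p$scores)
  expect_equal(unname(diag(S)), p$eigenvalues, tolerance = 1e-8)
  expect_lt(max(abs(S[upper.tri(S)])), 1e-8)
})

test_that("loading importance uses a strict 0.3 threshold", {
  p <- trait_pca(cowpea_means())
  imp <- important_traits(p)
  # the published PC1 pattern: yield-complex traits load importantly
  pc1 <- setNames(imp$PC1, imp$trait)
  expect_true(all(pc1[c("NPP", "PODWT", "NSP", "GWT")]))
  expect_false(any(pc1[c("DFF", "DNPM", "PHM", "HSW")]))
  # strict inequality at the boundary
  p_fake <- p
  p_fake$loadings[1, 1] <- 0.3
  expect_false(important_traits(p_fake)$PC1[1])
  # an impossible threshold flags nothing
  none <- important_traits(p, threshold = 1.1)
  expect_false(any(as.matrix(none[, -1])))
  expect_error(important_traits(p, threshold = 0), "positive")
})

test_that("tidiers expose eigenvalues, loadings and scores as tibbles", {
  p <- trait_pca(cowpea_means())
  ev <- tidy(p, "eigenvalues")
  expect_equal(names(ev), c("component", "eigenvalue", "variability_pct",
                            "cumulative_pct"))
  ld <- tidy(p, "loadings")
  expect_equal(ld$trait, levels(cowpea_means()$trait))
  sc <- tidy(p, "scores")
  expect_equal(nrow(sc), 17)
  expect_equal(glance(p)$cum_pct_5, p$cumulative_pct[5])
})

test_that("identical genotypes merge first at height zero", {
  m <- tibble::tibble(genotype = c("a", "b", "c", "d"),
                      x = c(0, 0, 3, 5), y = c(1, 1, 4, 9))
  cl <- hierarchical_cluster(m, k = 2, scale = FALSE)
  expect_equal(min(cl$hclust$height), 0)
  first <- cl$hclust$merge[1, ]
  expect_setequal(cl$hclust$labels[-first], c("a", "b"))
})

test_that("average-linkage merges match exhaustive enumeration on 4-point toys", {
  set.seed(99)
  for (rep in 1:10) {
    X <- matrix(rnorm(8), 4, 2)
    rownames(X) <- paste0("g", 1:4)
    m <- tibble::tibble(genotype = rownames(X), x = X[, 1], y = X[, 2])
    cl <- hierarchical_cluster(m, k = 2, scale = FALSE)
    oracle <- naive_upgma(X)
    expect_equal(sort(cl$hclust$height), sort(oracle$heights), tolerance = 1e-10)
    # the 2-cluster partition agrees
    two <- oracle$partitions[[2]]
    sig_oracle <- paste(sort(vapply(two, function(i)
      paste(sort(rownames(X)[i]), collapse = ","), character(1))),
      collapse = " | ")
    sig_pkg <- partition_signature(cl$assignment$genotype, cl$assignment$cluster)
    expect_equal(sig_pkg, sig_oracle)
  }
})

test_that("merge heights are monotone and cuts give exactly k clusters", {
  cl <- hierarchical_cluster(cowpea_means(), k = 3)
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
  expect_equal(dplyr::n_distinct(cl$assignment$cluster), 3)
  expect_equal(nrow(cl$assignment), 17)
  expect_error(hierarchical_cluster(cowpea_means(), k = 0), "between 1 and")
  expect_error(hierarchical_cluster(cowpea_means(), k = 18), "between 1 and")
})

test_that("clustering is invariant to genotype input order", {
  m <- cowpea_means()
  cl1 <- hierarchical_cluster(m, k = 3)
  set.seed(2)
  perm <- sample(levels(m$genotype))
  m2 <- dplyr::arrange(m, match(as.character(genotype), perm))
  m2$genotype <- factor(as.character(m2$genotype), levels = perm)
  cl2 <- hierarchical_cluster(m2, k = 3)
  expect_equal(partition_signature(cl1$assignment$genotype, cl1$assignment$cluster),
               partition_signature(cl2$assignment$genotype, cl2$assignment$cluster))
})

test_that("Newick export writes a readable ultrametric tree", {
  skip_if_not_installed("ape")
  cl <- hierarchical_cluster(cowpea_means(), k = 3)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(cl, path)
  tr <- ape::read.tree(path)
  expect_setequal(tr$tip.label, as.character(cl$assignment$genotype))
})
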