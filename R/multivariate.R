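#' Pearson correlation among traits over genotype means
#'
#' Pairwise Pearson correlations between trait columns of a genotype-mean
#' table, with two-tailed p-values from the t distribution on n - 2 degrees
#' of freedom (n = number of genotypes). No multiplicity correction is
#' applied.
#'
#' @param m A genotype-mean table: either the long output of
#'   [genotype_means()] / [cowpea_means()] or a wide tibble (`genotype` plus
#'   one numeric column per trait).
#' @param alpha Significance level used for the `significant` flag in
#'   [tidy.trait_correlation()] and for plotting.
#' @return An object of class `trait_correlation` holding the correlation
#'   matrix `r`, the p-value matrix `p` (diagonal `NA`), `n` and `alpha`.
#' @examples
#' ctab <- trait_correlation(cowpea_means())
#' tidy(ctab)
#' @export
trait_correlation <- function(m, alpha = 0.05) {
  X <- means_matrix(m)
  n <- nrow(X)
  if (n < 3) abort("need at least 3 genotypes for a correlation test")
  if (ncol(X) < 2) abort("need at least 2 traits")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant trait (zero variance): ",
                 paste(colnames(X)[sds == 0], collapse = ", ")))
  }
  r <- cor(X)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n, alpha = alpha),
            class = "trait_correlation")
}

#' @export
print.trait_correlation <- function(x, digits = 2, ...) {
  cat(sprintf("# Pearson correlation over %d genotypes (two-tailed t, df = %d)\n",
              x$n, x$n - 2))
  out <- format(round(x$r, digits))
  out[upper.tri(out)][x$p[upper.tri(x$p)] < x$alpha] <-
    paste0(out[upper.tri(out)][x$p[upper.tri(x$p)] < x$alpha], "*")
  print(out, quote = FALSE)
  invisible(x)
}

#' Tidy a trait correlation
#'
#' @param x A `trait_correlation`.
#' @param ... Unused.
#' @return `tidy()`: one row per unordered trait pair with `trait1`, `trait2`,
#'   `r`, `p.value`, `significant`.
#' @export
tidy.trait_correlation <- function(x, ...) {
  traits <- colnames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(trait1 = traits[idx[, 1]], trait2 = traits[idx[, 2]],
         r = x$r[idx], p.value = x$p[idx],
         significant = x$p[idx] < x$alpha)
}

#' @rdname tidy.trait_correlation
#' @return `glance()`: one-row tibble with `n_genotypes`, `n_traits`,
#'   `n_pairs`, `n_significant`, `alpha`.
#' @export
glance.trait_correlation <- function(x, ...) {
  td <- tidy(x)
  tibble(n_genotypes = x$n, n_traits = ncol(x$r), n_pairs = nrow(td),
         n_significant = sum(td$significant), alpha = x$alpha)
}

# eigendecomposition of a correlation matrix with the package's sign
# convention: each component is flipped so its largest-magnitude loading is
# positive (eigenvector sign is arbitrary).
pca_from_cor <- function(R) {
  ed <- eigen(R, symmetric = TRUE)
  V <- ed$vectors
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  list(values = ed$values, vectors = V)
}

#' Genotype-by-trait principal component analysis
#'
#' PCA on the trait correlation matrix: traits are standardized to zero mean
#' and unit variance over genotypes, so eigenvalues sum to the number of
#' traits and each component's explained variability is
#' `100 * eigenvalue / n_traits`. Scores are the standardized data projected
#' on the loadings. Each component's sign is chosen so its largest-magnitude
#' loading is positive; published tables may differ by a global sign flip per
#' component.
#'
#' @inheritParams trait_correlation
#' @return An object of class `trait_pca` with elements `eigenvalues`,
#'   `loadings` (trait x component matrix, unit-norm columns), `scores`
#'   (genotype x component), `variability_pct`, `cumulative_pct`.
#' @examples
#' p <- trait_pca(cowpea_means())
#' tidy(p, matrix = "eigenvalues")
#' @export
trait_pca <- function(m) {
  X <- means_matrix(m)
  if (nrow(X) < 2) abort("need at least 2 genotypes for a PCA")
  if (ncol(X) < 2) abort("need at least 2 traits")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant trait cannot be standardized: ",
                 paste(colnames(X)[sds == 0], collapse = ", ")))
  }
  Xs <- scale(X)
  R <- cor(X)
  ed <- pca_from_cor(R)
  k <- ncol(X)
  comp <- paste0("PC", seq_len(k))
  loadings <- ed$vectors
  dimnames(loadings) <- list(colnames(X), comp)
  scores <- Xs %*% loadings
  dimnames(scores) <- list(rownames(X), comp)
  structure(
    list(eigenvalues = ed$values, loadings = loadings, scores = scores,
         variability_pct = 100 * ed$values / k,
         cumulative_pct = cumsum(100 * ed$values / k)),
    class = "trait_pca"
  )
}

#' @export
print.trait_pca <- function(x, ...) {
  k <- length(x$eigenvalues)
  cat(sprintf("# PCA of %d standardized traits over %d genotypes\n",
              k, nrow(x$scores)))
  print(tibble(component = colnames(x$loadings),
               eigenvalue = x$eigenvalues,
               variability_pct = x$variability_pct,
               cumulative_pct = x$cumulative_pct), ...)
  invisible(x)
}

#' Tidy a trait PCA
#'
#' @param x A `trait_pca`.
#' @param matrix One of `"eigenvalues"`, `"loadings"`, `"scores"`.
#' @param ... Unused.
#' @return A tibble: per-component eigenvalue/variability, per-trait loadings,
#'   or per-genotype scores.
#' @export
tidy.trait_pca <- function(x, matrix = c("eigenvalues", "loadings", "scores"),
                           ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    eigenvalues = tibble(component = colnames(x$loadings),
                         eigenvalue = x$eigenvalues,
                         variability_pct = x$variability_pct,
                         cumulative_pct = x$cumulative_pct),
    loadings = dplyr::bind_cols(tibble(trait = rownames(x$loadings)),
                                as_tibble(unclass(x$loadings))),
    scores = dplyr::bind_cols(tibble(genotype = rownames(x$scores)),
                              as_tibble(unclass(x$scores)))
  )
}

#' @rdname tidy.trait_pca
#' @return `glance()`: one-row tibble with trait/genotype counts and the
#'   cumulative variability of the first five components.
#' @export
glance.trait_pca <- function(x, ...) {
  k <- length(x$eigenvalues)
  tibble(n_traits = k, n_genotypes = nrow(x$scores),
         cum_pct_5 = x$cumulative_pct[min(5, k)])
}

#' Flag traits with important loadings
#'
#' A trait is flagged important for a component when the absolute value of
#' its loading strictly exceeds `threshold` (default 0.3, a conventional
#' cutoff for declaring a coefficient large enough to matter).
#'
#' @param p A `trait_pca`.
#' @param threshold Positive loading cutoff (strict inequality).
#' @return A tibble with `trait` and one logical column per component.
#' @export
important_traits <- function(p, threshold = 0.3) {
  stopifnot(inherits(p, "trait_pca"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    abort("`threshold` must be a single positive number")
  }
  flags <- abs(p$loadings) > threshold
  dplyr::bind_cols(tibble(trait = rownames(p$loadings)),
                   as_tibble(unclass(flags)))
}

#' UPGMA hierarchical clustering of genotype means
#'
#' Agglomerative clustering of genotypes with average linkage (UPGMA) on
#' Euclidean distances between trait means, cut to `k` clusters. By default
#' trait means are standardized first so traits with large units do not
#' dominate the distance; `scale = FALSE` clusters the raw means.
#'
#' @inheritParams trait_correlation
#' @param k Number of clusters, between 1 and the number of genotypes.
#' @param scale Standardize traits before computing distances (default TRUE).
#' @return An object of class `genotype_clusters` with elements `hclust` (the
#'   merge tree, heights in Euclidean distance units), `assignment` (tibble
#'   `genotype`, `cluster`), `k`, `scaled`.
#' @examples
#' cl <- hierarchical_cluster(cowpea_means(), k = 3, scale = FALSE)
#' tidy(cl)
#' @export
hierarchical_cluster <- function(m, k = 3, scale = TRUE) {
  X <- means_matrix(m)
  n <- nrow(X)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n || k != round(k)) {
    abort(sprintf("`k` must be an integer between 1 and %d", n))
  }
  if (scale) X <- base::scale(X)
  hc <- hclust(dist(X), method = "average")
  assignment <- cutree(hc, k = k)
  structure(
    list(hclust = hc,
         assignment = tibble(genotype = names(assignment),
                             cluster = as.integer(assignment)),
         k = as.integer(k), scaled = scale),
    class = "genotype_clusters"
  )
}

#' @export
print.genotype_clusters <- function(x, ...) {
  cat(sprintf("# UPGMA clustering of %d genotypes (%s means), k = %d\n",
              nrow(x$assignment), ifelse(x$scaled, "standardized", "raw"), x$k))
  sizes <- table(x$assignment$cluster)
  cat("cluster sizes:", paste(sprintf("%s: %d", names(sizes), sizes),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Tidy genotype clusters
#'
#' @param x A `genotype_clusters`.
#' @param ... Unused.
#' @return `tidy()`: tibble with `genotype` and `cluster`.
#' @export
tidy.genotype_clusters <- function(x, ...) x$assignment

#' @rdname tidy.genotype_clusters
#' @return `glance()`: one-row tibble with `k`, `n_genotypes`,
#'   `n_singletons`, and the smallest/largest merge heights.
#' @export
glance.genotype_clusters <- function(x, ...) {
  sizes <- table(x$assignment$cluster)
  tibble(k = x$k, n_genotypes = nrow(x$assignment),
         n_singletons = sum(sizes == 1),
         height_min = min(x$hclust$height), height_max = max(x$hclust$height))
}

#' Export a dendrogram as Newick
#'
#' Writes the UPGMA merge tree with branch lengths derived from the merge
#' heights (ultrametric), readable by any phylogenetics tool.
#'
#' @param x A `genotype_clusters`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_newick <- function(x, file) {
  stopifnot(inherits(x, "genotype_clusters"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the 'ape' package is required for Newick export")
  }
  ape::write.tree(ape::as.phylo(x$hclust), file = file)
  invisible(file)
}
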