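# Independent brute-force oracles used to check the analytical code paths.

# direct-definition sums of squares for a single-environment RCBD
brute_rcbd_ss <- function(d) {
  grand <- mean(d$value)
  ss_tot <- sum((d$value - grand)^2)
  ss_g <- sum(vapply(unique(d$genotype), function(g) {
    v <- d$value[d$genotype == g]
    length(v) * (mean(v) - grand)^2
  }, numeric(1)))
  ss_b <- sum(vapply(unique(d$block), function(b) {
    v <- d$value[d$block == b]
    length(v) * (mean(v) - grand)^2
  }, numeric(1)))
  list(genotype = ss_g, block = ss_b, error = ss_tot - ss_g - ss_b,
       total = ss_tot)
}

# direct-definition decomposition for the combined (multi-environment) layout
brute_combined_ss <- function(d) {
  grand <- mean(d$value)
  ss_tot <- sum((d$value - grand)^2)
  gs <- unique(d$genotype); es <- unique(d$environment); bs <- unique(d$block)
  g <- length(gs); e <- length(es); r <- length(bs)
  m_g <- vapply(gs, function(x) mean(d$value[d$genotype == x]), numeric(1))
  m_e <- vapply(es, function(x) mean(d$value[d$environment == x]), numeric(1))
  ss_g <- e * r * sum((m_g - grand)^2)
  ss_e <- g * r * sum((m_e - grand)^2)
  ss_b <- 0
  for (ee in seq_along(es)) for (bb in bs) {
    cell <- mean(d$value[d$environment == es[ee] & d$block == bb])
    ss_b <- ss_b + g * (cell - m_e[ee])^2
  }
  ss_ge <- 0
  for (gg in seq_along(gs)) for (ee in seq_along(es)) {
    cell <- mean(d$value[d$genotype == gs[gg] & d$environment == es[ee]])
    ss_ge <- ss_ge + r * (cell - m_g[gg] - m_e[ee] + grand)^2
  }
  list(genotype = ss_g, environment = ss_e, block = ss_b, ge = ss_ge,
       error = ss_tot - ss_g - ss_e - ss_b - ss_ge, total = ss_tot)
}

# naive average-linkage agglomeration: recompute every between-cluster mean
# distance from scratch at every step
naive_upgma <- function(X) {
  D <- as.matrix(dist(X))
  clusters <- as.list(seq_len(nrow(X)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in 2:length(clusters)) {
      for (j in 1:(i - 1)) {
        dij <- mean(D[clusters[[i]], clusters[[j]]])
        if (dij < bestd) { bestd <- dij; best <- c(j, i) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, bestd)
    partitions <- c(partitions, list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions)
}

pearson_direct <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# canonical form of a partition (for order-invariance comparisons)
partition_signature <- function(labels, cluster) {
  groups <- split(as.character(labels), cluster)
  groups <- lapply(groups, sort)
  paste(sort(vapply(groups, paste, character(1), collapse = ",")),
        collapse = " | ")
}
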