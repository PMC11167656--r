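# Shared fixtures and independent oracles, built in code at test time.

# A reduced simulation emulating the study design at desk scale.
small_sim_config <- function(seed = 11L, n_genes = 300L,
                             module_sizes = c(40L, 40L),
                             n_genotypes = 16L) {
  simulation_config(
    n_genotypes = n_genotypes,
    reps_per_genotype = c(3L, 2L),
    n_genes = n_genes,
    n_chromosomes = 4L,
    module_sizes = module_sizes,
    indel_regions = list(
      list(chromosome = "Chr01", start = 1L, end = 800000L,
           n_deletion = 3L, n_insertion = 2L)),
    trait_loadings = list(
      TH = list(module = 1L, loading = 1.0, noise_sd = 0.5),
      VF = list(module = 1L, loading = -0.9, noise_sd = 0.5),
      cMVD = list(module = 2L, loading = 1.0, noise_sd = 0.5),
      NF = list(module = 1L, loading = 0.0, noise_sd = 1.0)),
    seed = seed)
}

random_counts <- function(n_genes, n_libs, seed = 1, lambda = 60) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_libs, lambda), n_genes, n_libs,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("lib%02d", seq_len(n_libs))))
  storage.mode(m) <- "integer"
  m
}

# --- independent oracles -------------------------------------------------

# Pearson correlation by the direct sum formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# TOM by an explicit triple loop.
oracle_tom <- function(a) {
  n <- nrow(a)
  diag(a) <- 1
  k <- rowSums(a) - 1
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# Average-linkage agglomeration by exhaustive O(n^3) search over the
# original dissimilarities; returns merge heights and the partition after
# each merge.
oracle_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_h)
    part <- integer(n)
    for (ci in seq_along(clusters)) part[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1]] <- part
  }
  list(heights = heights, partitions = partitions)
}

# Upper-tail hypergeometric p by exhaustive enumeration of all C(N, n)
# module draws.
oracle_hyper <- function(N, K, n, k) {
  draws <- combn(N, n)
  term <- seq_len(K)
  hits <- apply(draws, 2, function(dr) sum(dr %in% term))
  mean(hits >= k)
}

# One-way ANOVA from the explicit sum-of-squares decomposition.
oracle_anova <- function(groups) {
  y <- unlist(groups)
  means <- vapply(groups, mean, 0)
  ssb <- sum(lengths(groups) * (means - mean(y))^2)
  ssw <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2)))
  df_b <- length(groups) - 1
  df_w <- length(y) - length(groups)
  f <- (ssb / df_b) / (ssw / df_w)
  list(F = f, p = pf(f, df_b, df_w, lower.tail = FALSE))
}

# Partitions equal up to relabeling.
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# Adjusted Rand index between two labelings (contingency-table form).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}
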