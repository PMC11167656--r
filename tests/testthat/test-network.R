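# Planted two-block expression used by several clustering tests.
planted_expression <- function(n_per_block = 40, n_samples = 20,
                               signal_sd = 3, noise_sd = 0.3, seed = 2) {
  set.seed(seed)
  f1 <- rnorm(n_samples, sd = signal_sd)
  f2 <- rnorm(n_samples, sd = signal_sd)
  x <- rbind(
    t(replicate(n_per_block, f1 + rnorm(n_samples, sd = noise_sd))),
    t(replicate(n_per_block, f2 + rnorm(n_samples, sd = noise_sd))))
  dimnames(x) <- list(sprintf("g%03d", seq_len(2 * n_per_block)),
                      sprintf("s%02d", seq_len(n_samples)))
  x
}

test_that("gene correlations match the direct sum formula", {
  set.seed(1)
  x <- matrix(rnorm(24), 4, 6,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  r <- gene_correlation_matrix(x)
  for (i in 1:4) for (j in 1:4)
    expect_equal(r[i, j], oracle_pearson(x[i, ], x[j, ]), tolerance = 1e-12)
  # duplicated gene and negated gene
  x2 <- rbind(x, dup = x[1, ], neg = -x[1, ])
  r2 <- gene_correlation_matrix(x2)
  expect_equal(r2["g1", "dup"], 1)
  expect_equal(r2["g1", "neg"], -1)
  expect_error(gene_correlation_matrix(x[, 1:2]), "3 samples")
  x3 <- rbind(x, flat = rep(1, 6))
  expect_warning(r3 <- gene_correlation_matrix(x3), "constant")
  expect_false("flat" %in% rownames(r3))
})

test_that("soft adjacency follows the signed/unsigned closed forms", {
  r <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  a <- soft_adjacency(r, network_params(soft_power = 12))
  expect_equal(a[1, 2], 0.5^12, tolerance = 1e-15)
  expect_equal(a[1, 2], 1 / 4096, tolerance = 1e-15)
  expect_equal(diag(a), c(1, 1))
  r_neg <- matrix(c(1, -0.5, -0.5, 1), 2, 2)
  a_signed <- soft_adjacency(r_neg, network_params(soft_power = 2, signed = TRUE))
  expect_equal(a_signed[1, 2], 0.0625, tolerance = 1e-15)
  expect_equal(soft_adjacency(matrix(1, 2, 2),
                              network_params(soft_power = 7))[1, 2], 1)
  expect_error(network_params(soft_power = 0), "soft_power")
})

test_that("increasing the power weakly decreases off-diagonal adjacency", {
  set.seed(6)
  x <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  r <- gene_correlation_matrix(x)
  a6 <- soft_adjacency(r, network_params(soft_power = 6))
  a12 <- soft_adjacency(r, network_params(soft_power = 12))
  off <- upper.tri(r)
  expect_true(all(a12[off] <= a6[off] + 1e-15))
})

test_that("scale-free fit index is exact on constructed power laws", {
  # genes with connectivity k and bin counts n_b chosen so that
  # log10(frequency) is an exact linear function of log10(k)
  build_adj <- function(k_target) {
    # symmetric rank-one adjacency outer(c, c) has k_i = c_i * (S - c_i);
    # solve for c by fixed point
    c_ <- sqrt(k_target / sum(sqrt(k_target)))
    for (it in 1:200) c_ <- k_target / (sum(c_) - c_)
    outer(c_, c_)
  }
  k_vals <- c(1, 2, 3, 4, 6, 8, 12, 24)
  decreasing <- rep(k_vals, times = 24 / k_vals)   # freq proportional to 1/k
  adj <- build_adj(decreasing)
  fit <- scale_free_fit_index(adj, network_params(n_bins = 24))
  expect_equal(fit$fit_R2, 1.0, tolerance = 1e-9)
  expect_equal(fit$slope, -1, tolerance = 1e-9)
  increasing <- rep(k_vals, times = k_vals)        # freq proportional to k
  fit_inc <- scale_free_fit_index(build_adj(increasing),
                                  network_params(n_bins = 24))
  expect_equal(fit_inc$fit_R2, -1.0, tolerance = 1e-9)
  expect_true(abs(fit$fit_R2) <= 1 && abs(fit_inc$fit_R2) <= 1)
  expect_error(scale_free_fit_index(matrix(0.5, 5, 5) + 0.5 * diag(5)),
               "degenerate")
})

test_that("soft power selection follows the smallest-reaching rule", {
  x <- planted_expression(n_per_block = 15, n_samples = 30, signal_sd = 1,
                          noise_sd = 1, seed = 9)
  r <- gene_correlation_matrix(x)
  params <- network_params(scale_free_target = 0.8, n_bins = 5)
  pick <- choose_soft_power(r, candidates = c(2L, 6L, 12L), params = params)
  fits_all <- sapply(c(2L, 6L, 12L), function(p)
    scale_free_fit_index(soft_adjacency(r, network_params(soft_power = p)),
                         network_params(n_bins = 5))$fit_R2)
  reaching <- c(2L, 6L, 12L)[fits_all >= 0.8]
  if (length(reaching)) {
    expect_true(pick$reached_target)
    expect_equal(pick$power, reaching[1])
  } else {
    expect_false(pick$reached_target)
    expect_equal(pick$power, c(2L, 6L, 12L)[which.max(fits_all)])
  }
  # unreachable target falls back to the argmax with a warning
  expect_warning(
    none <- choose_soft_power(r, candidates = c(2L, 6L, 12L),
                              params = network_params(scale_free_target = 0.999,
                                                      n_bins = 5)),
    "argmax")
  expect_false(none$reached_target)
  expect_equal(none$power, c(2L, 6L, 12L)[which.max(none$fits$fit_R2)])
})

test_that("TOM matches hand computation and the triple-loop oracle", {
  # 3 genes, all off-diagonal adjacency 0.5
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 1
  tom3 <- tom_matrix(a3)
  expect_equal(tom3[1, 2], (0.25 + 0.5) / (1 + 1 - 0.5), tolerance = 1e-15)
  # complete graph
  ac <- matrix(1, 6, 6)
  expect_true(all(tom_matrix(ac) == 1))
  # empty graph
  a0 <- diag(4)
  expect_true(all(tom_matrix(a0)[upper.tri(a0)] == 0))
  # random instances vs brute force, values stay in [0, 1]
  set.seed(12)
  for (rep_ in 1:5) {
    n <- sample(5:12, 1)
    r <- matrix(runif(n * n, -1, 1), n, n)
    r <- (r + t(r)) / 2; diag(r) <- 1
    a <- abs(r)^6; diag(a) <- 1
    tom <- tom_matrix(a)
    expect_equal(tom, oracle_tom(a), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_true(isSymmetric(unname(tom), tol = 1e-12))
  }
  expect_error(tom_matrix(matrix(c(1, 0.2, 0.8, 1), 2, 2)), "symmetric")
})

test_that("average-linkage tree matches the exhaustive oracle", {
  set.seed(33)
  for (rep_ in 1:4) {
    n <- sample(5:8, 1)
    p <- matrix(rnorm(n * 3), n, 3)
    d <- as.matrix(dist(p))
    dimnames(d) <- list(paste0("g", 1:n), paste0("g", 1:n))
    dend <- average_linkage_dendrogram(d)
    oracle <- oracle_upgma(d)
    expect_equal(sort(dend$height), sort(oracle$heights), tolerance = 1e-12)
    for (k in (n - 1):2) {
      ours <- cutree(dend, k = k)
      theirs <- oracle$partitions[[n - k]]
      expect_true(same_partition(unname(ours), theirs))
    }
  }
  # two identical points merge at height zero
  d0 <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3)
  expect_equal(average_linkage_dendrogram(d0)$height[1], 0)
  # permuting input order yields the same tree up to relabeling
  set.seed(34)
  p <- matrix(rnorm(21), 7, 3)
  d <- as.matrix(dist(p)); dimnames(d) <- list(paste0("g", 1:7), paste0("g", 1:7))
  perm <- sample(7)
  dp <- d[perm, perm]
  h1 <- average_linkage_dendrogram(d)
  h2 <- average_linkage_dendrogram(dp)
  expect_equal(sort(h1$height), sort(h2$height), tolerance = 1e-12)
  c1 <- cutree(h1, k = 3)[paste0("g", 1:7)]
  c2 <- cutree(h2, k = 3)[paste0("g", 1:7)]
  expect_true(same_partition(unname(c1), unname(c2)))
  dn <- d; dn[1, 2] <- NaN; dn[2, 1] <- NaN
  expect_error(average_linkage_dendrogram(dn), "NaN")
})

test_that("module cutting recovers planted blocks and applies the size rule", {
  set.seed(50)
  n <- 80
  d <- matrix(runif(n * n, 0.999, 1), n, n)
  d[1:40, 1:40] <- runif(1600, 0, 0.02)
  d[41:80, 41:80] <- runif(1600, 0, 0.02)
  d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- list(paste0("g", 1:n), paste0("g", 1:n))
  dend <- average_linkage_dendrogram(d)
  labels <- cut_modules(dend, network_params(min_module_size = 30))
  expect_equal(sort(unique(labels)), c("blue", "turquoise"))
  expect_equal(length(unique(labels[1:40])), 1)
  expect_equal(length(unique(labels[41:80])), 1)
  # blocks of 10 with min size 30 -> all grey
  labels_small <- cut_modules(dend, network_params(min_module_size = 100))
  expect_true(all(labels_small == "grey"))
  # cut height 1.0 with all dissimilarities < 1 -> a single module
  d_low <- d * 0.9
  diag(d_low) <- 0
  labels_one <- cut_modules(average_linkage_dendrogram(d_low),
                            network_params(cut_height = 1.0,
                                           min_module_size = 30))
  expect_equal(unique(labels_one), "turquoise")
  expect_error(network_params(cut_height = 1.5), "cut_height")
})

test_that("module colors are assigned by decreasing size", {
  set.seed(51)
  sizes <- c(35, 60, 45)
  n <- sum(sizes)
  d <- matrix(runif(n * n, 0.999, 1), n, n)
  offs <- cumsum(c(0, sizes))
  for (b in 1:3) {
    idx <- (offs[b] + 1):offs[b + 1]
    d[idx, idx] <- runif(length(idx)^2, 0, 0.02)
  }
  d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- list(paste0("g", 1:n), paste0("g", 1:n))
  labels <- cut_modules(average_linkage_dendrogram(d),
                        network_params(min_module_size = 30))
  tab <- sort(table(labels), decreasing = TRUE)
  expect_equal(names(tab), c("turquoise", "blue", "brown"))
  expect_equal(as.vector(tab), c(60, 45, 35))
})

test_that("eigengenes equal the standardized profile for rank-one modules", {
  set.seed(60)
  profile <- rnorm(12)
  x <- t(replicate(5, profile))
  dimnames(x) <- list(paste0("g", 1:5), paste0("s", 1:12))
  labels <- setNames(rep("turquoise", 5), rownames(x))
  me <- module_eigengenes(x, labels)
  expect_equal(unname(me["turquoise", ]),
               as.vector(scale(profile)), tolerance = 1e-10)
})

test_that("eigengenes match an independent PCA oracle and obey orientation", {
  set.seed(61)
  x <- planted_expression(n_per_block = 20, n_samples = 15, seed = 61)
  labels <- setNames(rep(c("turquoise", "blue"), each = 20), rownames(x))
  me <- module_eigengenes(x, labels)
  for (mod in c("turquoise", "blue")) {
    xs <- t(scale(t(x[labels == mod, ])))
    pc1 <- prcomp(t(xs), center = FALSE)$x[, 1]
    v1 <- pc1 / sqrt(sum(pc1^2))
    v2 <- me[mod, ] / sqrt(sum(me[mod, ]^2))
    expect_gte(abs(sum(v1 * v2)), 1 - 1e-10)
    # orientation: mean correlation with members nonnegative
    expect_gte(mean(cor(me[mod, ], t(x[labels == mod, ]))), 0)
  }
  # flipping every member's sign flips the profile but keeps orientation
  x_flip <- x; x_flip[labels == "blue", ] <- -x_flip[labels == "blue", ]
  me_flip <- module_eigengenes(x_flip, labels)
  expect_gte(mean(cor(me_flip["blue", ], t(x_flip[labels == "blue", ]))), 0)
  # unit variance rows
  expect_equal(unname(apply(me, 1, sd)), c(1, 1), tolerance = 1e-12)
  expect_error(module_eigengenes(matrix(1, 3, 5,
    dimnames = list(paste0("g", 1:3), paste0("s", 1:5))),
    setNames(rep("m", 3), paste0("g", 1:3))), "constant")
})

test_that("merging follows the eigengene-correlation threshold", {
  set.seed(70)
  base <- rnorm(30, sd = 2)
  make_block <- function(center, n, noise) {
    t(replicate(n, center + rnorm(length(center), sd = noise)))
  }
  # two highly correlated blocks and one independent block
  x <- rbind(make_block(base, 25, 0.8), make_block(base, 20, 0.8),
             make_block(rnorm(30, sd = 2), 22, 0.8))
  dimnames(x) <- list(sprintf("g%03d", 1:67), sprintf("s%02d", 1:30))
  labels <- setNames(rep(c("turquoise", "blue", "brown"), c(25, 20, 22)),
                     rownames(x))
  me <- module_eigengenes(x, labels)
  r_tb <- cor(me["turquoise", ], me["blue", ])
  expect_gte(r_tb, 0.75)
  merged <- merge_close_modules(x, labels, network_params())
  expect_equal(sort(unique(merged$labels)), c("brown", "turquoise"))
  # absorbed into the larger member's name
  expect_true(all(merged$labels[1:45] == "turquoise"))
  expect_equal(merged$merge_log$into, "turquoise")
  # modules correlated below the threshold stay separate
  high_thr <- merge_close_modules(x, labels,
                                  network_params(merge_threshold = 0.9999))
  expect_equal(sort(unique(high_thr$labels)),
               c("blue", "brown", "turquoise"))
})

test_that("three mutually correlated modules collapse into one", {
  set.seed(71)
  base <- rnorm(30, sd = 2)
  x <- do.call(rbind, lapply(c(30, 25, 20), function(n)
    t(replicate(n, base + rnorm(30, sd = 0.6)))))
  dimnames(x) <- list(sprintf("g%03d", 1:75), sprintf("s%02d", 1:30))
  labels <- setNames(rep(c("turquoise", "blue", "brown"), c(30, 25, 20)),
                     rownames(x))
  merged <- merge_close_modules(x, labels, network_params())
  expect_equal(unique(merged$labels), "turquoise")
  expect_equal(nrow(merged$merge_log), 2)
})

test_that("planted modules are stable under library resampling", {
  x <- planted_expression(n_per_block = 35, n_samples = 24, signal_sd = 3,
                          noise_sd = 0.3, seed = 80)
  params <- network_params(soft_power = 6, min_module_size = 20)
  stab <- module_stability(x, params,
                           stability_params(subsample_fraction = 0.63,
                                            n_iterations = 15, seed = 5))
  expect_true(all(stab >= 0.8))
  expect_true(all(stab >= 0 & stab <= 1))
  # same seed reproduces the stability vector exactly
  stab2 <- module_stability(x, params,
                            stability_params(subsample_fraction = 0.63,
                                             n_iterations = 15, seed = 5))
  expect_identical(stab, stab2)
  expect_error(module_stability(x[, 1:3], params,
                                stability_params(subsample_fraction = 0.63,
                                                 n_iterations = 2)),
               "too small")
})

test_that("pure-noise expression yields defined stability in [0, 1]", {
  set.seed(81)
  x <- matrix(rnorm(60 * 20), 60, 20,
              dimnames = list(sprintf("g%03d", 1:60), sprintf("s%02d", 1:20)))
  params <- network_params(soft_power = 6, min_module_size = 10,
                           cut_height = 0.999)
  stab <- tryCatch(
    module_stability(x, params,
                     stability_params(n_iterations = 5, seed = 2)),
    error = function(e) e)
  if (!inherits(stab, "error"))
    expect_true(all(stab >= 0 & stab <= 1))
  else
    expect_match(conditionMessage(stab), "no module")
})

test_that("full network pass is deterministic", {
  x <- planted_expression(n_per_block = 30, n_samples = 18, seed = 90)
  net1 <- build_network(x, network_params(soft_power = 6,
                                          min_module_size = 20))
  net2 <- build_network(x, network_params(soft_power = 6,
                                          min_module_size = 20))
  expect_identical(net1$labels, net2$labels)
  expect_equal(net1$eigengenes, net2$eigengenes)
})
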