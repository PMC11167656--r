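#' Co-expression network parameters
#'
#' @param soft_power soft thresholding exponent beta applied to the
#'   correlation-based adjacency (default 12)
#' @param signed use the signed adjacency `((1 + r)/2)^beta` instead of the
#'   unsigned `|r|^beta`
#' @param cut_height static dendrogram cut height on the topological-overlap
#'   dissimilarity (default 0.99)
#' @param min_module_size clusters smaller than this are relabeled "grey"
#' @param merge_threshold modules whose eigengenes correlate at or above
#'   this are merged (default 0.75)
#' @param scale_free_target model-fit R2 a candidate power must reach in
#'   [choose_soft_power()] (default 0.80)
#' @param n_bins connectivity histogram bins for the scale-free fit
#' @return validated parameter list
#' @export
network_params <- function(soft_power = 12L, signed = FALSE,
                           cut_height = 0.99, min_module_size = 30L,
                           merge_threshold = 0.75, scale_free_target = 0.80,
                           n_bins = 10L) {
  if (soft_power < 1) stopf("soft_power must be >= 1")
  if (cut_height <= 0 || cut_height > 1)
    stopf("cut_height must lie in (0, 1]")
  if (merge_threshold <= 0 || merge_threshold > 1)
    stopf("merge_threshold must lie in (0, 1]")
  if (scale_free_target <= 0 || scale_free_target > 1)
    stopf("scale_free_target must lie in (0, 1]")
  list(soft_power = as.integer(soft_power), signed = isTRUE(signed),
       cut_height = cut_height, min_module_size = as.integer(min_module_size),
       merge_threshold = merge_threshold,
       scale_free_target = scale_free_target, n_bins = as.integer(n_bins))
}

#' Resampling stability parameters
#' @param subsample_fraction fraction of libraries drawn per iteration
#'   (default 0.63)
#' @param n_iterations number of resampled network iterations (default 49)
#' @param seed integer seed for the resampling stream
#' @return validated parameter list
#' @export
stability_params <- function(subsample_fraction = 0.63, n_iterations = 49L,
                             seed = 1L) {
  if (subsample_fraction <= 0 || subsample_fraction >= 1)
    stopf("subsample_fraction must lie in (0, 1)")
  if (n_iterations < 1) stopf("n_iterations must be >= 1")
  list(subsample_fraction = subsample_fraction,
       n_iterations = as.integer(n_iterations), seed = as.integer(seed))
}

# Canonical module color order, by decreasing module size.
module_color_order <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "sienna3",
  "yellowgreen", "skyblue3", "plum1", "orangered4", "mediumpurple3",
  "lightsteelblue1")

#' Pearson correlation matrix over genes
#'
#' Correlates every gene pair across samples. Genes with zero variance are
#' dropped with a warning (their correlation is undefined).
#'
#' @param expression numeric matrix genes x samples, >= 3 samples
#' @return symmetric correlation matrix with unit diagonal
#' @export
gene_correlation_matrix <- function(expression) {
  if (ncol(expression) < 3) stopf("need at least 3 samples")
  sds <- apply(expression, 1, stats::sd)
  if (any(sds == 0)) {
    warnf("dropping %d constant gene(s) from the correlation matrix",
          sum(sds == 0))
    expression <- expression[sds > 0, , drop = FALSE]
  }
  r <- stats::cor(t(expression))
  diag(r) <- 1
  r
}

#' Soft-thresholded adjacency
#'
#' Unsigned: `|r|^beta`; signed: `((1 + r)/2)^beta`. The diagonal is set
#' to 1.
#'
#' @param cor_matrix correlations in [-1, 1]
#' @param params [network_params()] supplying `soft_power` and `signed`
#' @return adjacency matrix with values in [0, 1]
#' @export
soft_adjacency <- function(cor_matrix, params = network_params()) {
  if (params$soft_power < 1) stopf("soft_power must be >= 1")
  if (any(abs(cor_matrix) > 1 + 1e-8))
    stopf("correlations must lie in [-1, 1]")
  a <- if (params$signed) ((1 + cor_matrix) / 2)^params$soft_power
       else abs(cor_matrix)^params$soft_power
  diag(a) <- 1
  a
}

#' Scale-free topology fit index
#'
#' Computes each gene's connectivity `k` (adjacency row sum excluding the
#' diagonal), bins genes into `n_bins` equal-width connectivity bins, and
#' regresses log10 bin frequency on log10 mean bin connectivity. The fit
#' index is the regression R2 signed by minus the slope's sign, so a
#' decaying power law (the scale-free signature) scores positively.
#'
#' @param adjacency matrix from [soft_adjacency()]
#' @param params [network_params()] supplying `n_bins`
#' @return list with `k` (per-gene connectivity), `fit_R2` and `slope`
#' @export
scale_free_fit_index <- function(adjacency, params = network_params()) {
  k <- rowSums(adjacency) - diag(adjacency)
  if (diff(range(k)) == 0) stopf("degenerate connectivity: all k equal")
  breaks <- seq(min(k), max(k), length.out = params$n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0 & mean_k > 0
  if (sum(ok) < 2) stopf("too few nonempty connectivity bins")
  x <- log10(mean_k[ok]); y <- log10(freq[ok] / length(k))
  fit <- stats::lm(y ~ x)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  slope <- unname(stats::coef(fit)[2])
  list(k = k, fit_R2 = r2 * -sign(slope), slope = slope)
}

#' Choose the soft thresholding power
#'
#' Returns the smallest candidate power whose scale-free fit index reaches
#' `scale_free_target`; if none does, the candidate with the maximal fit is
#' returned with a warning and `reached_target = FALSE`.
#'
#' @param cor_matrix gene correlation matrix
#' @param candidates integer vector of candidate powers
#' @param params [network_params()]
#' @return list with `power`, `reached_target` and a `fits` data.frame
#'   (power, fit_R2, slope)
#' @export
choose_soft_power <- function(cor_matrix,
                              candidates = c(1:10, 12L, 14L, 16L, 18L, 20L),
                              params = network_params()) {
  if (!length(candidates)) stopf("no candidate powers supplied")
  fits <- data.frame(power = candidates, fit_R2 = NA_real_,
                     slope = NA_real_)
  for (i in seq_along(candidates)) {
    p_i <- network_params(soft_power = candidates[i], signed = params$signed,
                          cut_height = params$cut_height,
                          min_module_size = params$min_module_size,
                          merge_threshold = params$merge_threshold,
                          scale_free_target = params$scale_free_target,
                          n_bins = params$n_bins)
    sf <- scale_free_fit_index(soft_adjacency(cor_matrix, p_i), p_i)
    fits$fit_R2[i] <- sf$fit_R2
    fits$slope[i] <- sf$slope
    if (sf$fit_R2 >= params$scale_free_target)
      return(list(power = candidates[i], reached_target = TRUE, fits = fits[seq_len(i), ]))
  }
  warnf("no candidate power reaches scale-free fit %.2f; using argmax",
        params$scale_free_target)
  list(power = candidates[which.max(fits$fit_R2)], reached_target = FALSE,
       fits = fits)
}

#' Topological overlap matrix
#'
#' `TOM[i, j] = (sum_u a[i,u] a[u,j] + a[i,j]) / (min(k_i, k_j) + 1 -
#' a[i,j])` with the sum over u excluding i and j, connectivity k excluding
#' the diagonal, and `TOM[i, i] = 1`. The dissimilarity used for clustering
#' is `1 - TOM`.
#'
#' @param adjacency symmetric matrix in [0, 1] with unit diagonal
#' @return TOM similarity matrix
#' @export
tom_matrix <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stopf("adjacency must be symmetric")
  if (any(adjacency < -1e-12) || any(adjacency > 1 + 1e-12))
    stopf("adjacency values must lie in [0, 1]")
  a <- adjacency
  diag(a) <- 1
  k <- rowSums(a) - 1
  a2 <- a %*% a
  # sum_{u != i,j} a_iu a_uj = a2 - 2 a (unit diagonal); numerator adds a_ij
  num <- a2 - a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom[tom < 0] <- 0
  tom
}

#' Average-linkage (UPGMA) dendrogram of a dissimilarity matrix
#'
#' @param dissimilarity square symmetric matrix with zero diagonal and no
#'   missing values
#' @return an `hclust` tree
#' @export
average_linkage_dendrogram <- function(dissimilarity) {
  if (nrow(dissimilarity) != ncol(dissimilarity) ||
      !isSymmetric(unname(dissimilarity), tol = 1e-10))
    stopf("dissimilarity must be square and symmetric")
  if (any(!is.finite(dissimilarity))) stopf("dissimilarity contains NaN")
  if (any(abs(diag(dissimilarity)) > 1e-12))
    stopf("dissimilarity diagonal must be zero")
  stats::hclust(stats::as.dist(dissimilarity), method = "average")
}

#' Cut a dendrogram into color-labeled modules
#'
#' Clusters are the connected components below `cut_height`; clusters
#' smaller than `min_module_size` are relabeled "grey" (unassigned), and
#' the rest are named by the canonical color order (turquoise, blue,
#' brown, ...) by decreasing size, ties broken by first cluster index.
#'
#' @param dendrogram an `hclust` tree from [average_linkage_dendrogram()]
#' @param params [network_params()]
#' @return named character vector gene -> module color
#' @export
cut_modules <- function(dendrogram, params = network_params()) {
  if (params$cut_height <= 0 || params$cut_height > 1)
    stopf("cut_height must lie in (0, 1]")
  cl <- stats::cutree(dendrogram, h = params$cut_height)
  sizes <- table(cl)
  big <- as.integer(names(sizes)[sizes >= params$min_module_size])
  ord <- big[order(-sizes[as.character(big)], big)]
  labels <- rep("grey", length(cl))
  names(labels) <- names(cl)
  for (i in seq_along(ord)) {
    color <- if (i <= length(module_color_order)) module_color_order[i]
             else sprintf("module_%d", i)
    labels[cl == ord[i]] <- color
  }
  labels
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component across
#' samples of its member genes after per-gene standardization, rescaled to
#' unit variance and sign-oriented so that its mean correlation with the
#' member genes is nonnegative.
#'
#' @param expression numeric matrix genes x samples
#' @param labels gene -> module labels; "grey" genes are ignored
#' @return matrix modules x samples, one unit-variance eigengene per row
#' @export
module_eigengenes <- function(expression, labels) {
  labels <- labels[rownames(expression)]
  modules <- setdiff(unique(labels), "grey")
  modules <- modules[order(-tabulate(factor(labels, levels = modules)),
                           modules)]
  if (!length(modules)) stopf("no non-grey module to summarize")
  me <- matrix(NA_real_, length(modules), ncol(expression),
               dimnames = list(modules, colnames(expression)))
  for (mod in modules) {
    x <- expression[labels == mod, , drop = FALSE]
    if (nrow(x) < 2) stopf("module '%s' has fewer than 2 genes", mod)
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0))
      stopf("module '%s' contains constant gene(s)", mod)
    xs <- t(scale(t(x)))
    sv <- svd(xs, nu = 0, nv = 1)
    v <- sv$v[, 1]
    v <- v / stats::sd(v)
    if (mean(stats::cor(v, t(x))) < 0) v <- -v
    me[mod, ] <- v
  }
  me
}

#' Merge modules with highly correlated eigengenes
#'
#' Iteratively merges the module pair with the highest eigengene
#' correlation at or above `merge_threshold`; the merged module takes the
#' larger member's name. Stops when no pair reaches the threshold.
#'
#' @param expression numeric matrix genes x samples
#' @param labels gene -> module labels
#' @param params [network_params()]
#' @return list with `labels`, `eigengenes` (of the merged modules) and a
#'   `merge_log` data.frame (absorbed, into, correlation)
#' @export
merge_close_modules <- function(expression, labels,
                                params = network_params()) {
  labels <- labels[rownames(expression)]
  log_rows <- list()
  repeat {
    modules <- setdiff(unique(labels), "grey")
    if (length(modules) < 2) break
    me <- module_eigengenes(expression, labels)
    cc <- stats::cor(t(me))
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[best[1], best[2]] < params$merge_threshold) break
    a <- rownames(cc)[best[1]]; b <- rownames(cc)[best[2]]
    sizes <- table(labels)
    keep <- if (sizes[a] > sizes[b]) a
            else if (sizes[b] > sizes[a]) b
            else sort(c(a, b))[1]
    drop_ <- setdiff(c(a, b), keep)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      absorbed = drop_, into = keep,
      correlation = cc[best[1], best[2]], stringsAsFactors = FALSE)
    labels[labels == drop_] <- keep
  }
  me <- if (length(setdiff(unique(labels), "grey")))
    module_eigengenes(expression, labels) else NULL
  merge_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(absorbed = character(), into = character(),
               correlation = numeric(), stringsAsFactors = FALSE)
  list(labels = labels, eigengenes = me, merge_log = merge_log)
}

# One full labeling pass: correlation -> adjacency -> TOM -> tree -> cut
# -> merge. Used by build_network and by the stability resampler.
network_labels <- function(expression, params) {
  cor_m <- gene_correlation_matrix(expression)
  adj <- soft_adjacency(cor_m, params)
  tom <- tom_matrix(adj)
  dend <- average_linkage_dendrogram(1 - tom)
  labels <- cut_modules(dend, params)
  if (length(setdiff(unique(labels), "grey")) >= 2)
    labels <- merge_close_modules(expression[names(labels), , drop = FALSE],
                                  labels, params)$labels
  list(labels = labels, dendrogram = dend, tom = tom)
}

#' Build a weighted co-expression network and detect modules
#'
#' Runs the full chain: gene correlations, soft-thresholded adjacency,
#' topological overlap, average-linkage clustering, static tree cut with
#' the minimum-size rule, eigengene computation and module merging.
#'
#' @param expression numeric matrix genes x samples
#' @param params [network_params()]
#' @param stability optional [stability_params()]; when supplied, module
#'   stability is assessed by resampling
#' @return list of class `module_result` with `labels`, `dendrogram`,
#'   `eigengenes`, `merge_log`, `params` and optionally `stability`
#' @export
build_network <- function(expression, params = network_params(),
                          stability = NULL) {
  fit <- network_labels(expression, params)
  labels <- fit$labels
  me <- if (length(setdiff(unique(labels), "grey")))
    module_eigengenes(expression[names(labels), , drop = FALSE], labels)
    else NULL
  res <- list(labels = labels, dendrogram = fit$dendrogram,
              eigengenes = me, params = params)
  if (!is.null(stability))
    res$stability <- module_stability(expression, params, stability,
                                      labels = labels)
  class(res) <- "module_result"
  res
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Module stability under library resampling
#'
#' Rebuilds the module labeling on repeated random subsamples of
#' `ceiling(subsample_fraction * n)` libraries and scores each reference
#' module by its best Jaccard overlap with any module of the resampled
#' network; stability is the median best-overlap across iterations.
#'
#' @param expression numeric matrix genes x libraries
#' @param params [network_params()]
#' @param stability [stability_params()]
#' @param labels optional reference labeling; computed from the full data
#'   when omitted
#' @return named numeric vector module -> stability in [0, 1]
#' @export
module_stability <- function(expression, params = network_params(),
                             stability = stability_params(),
                             labels = NULL) {
  n <- ncol(expression)
  m <- ceiling(stability$subsample_fraction * n)
  if (m < 3) stopf("subsample of %d libraries is too small (< 3)", m)
  if (is.null(labels)) labels <- network_labels(expression, params)$labels
  ref_modules <- setdiff(unique(labels), "grey")
  if (!length(ref_modules)) stopf("reference labeling has no module")
  overlaps <- matrix(NA_real_, length(ref_modules), stability$n_iterations,
                     dimnames = list(ref_modules, NULL))
  with_seed(stability$seed, {
    for (it in seq_len(stability$n_iterations)) {
      cols <- sample(n, m)
      lab_it <- tryCatch(
        network_labels(expression[, cols, drop = FALSE], params)$labels,
        error = function(e) NULL)
      for (mod in ref_modules) {
        ref_genes <- names(labels)[labels == mod]
        best <- 0
        if (!is.null(lab_it))
          for (mod2 in setdiff(unique(lab_it), "grey"))
            best <- max(best, jaccard(ref_genes,
                                      names(lab_it)[lab_it == mod2]))
        overlaps[mod, it] <- best
      }
    }
  })
  apply(overlaps, 1, stats::median)
}
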