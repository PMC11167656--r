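#' Preprocessing parameters
#'
#' @param min_max_count genes whose maximum count over all libraries falls
#'   below this are removed (default 10)
#' @param prior_count pseudo-count added before the log2-CPM transform
#' @param logratio_trim two-sided trim fraction on M values in TMM
#' @param abundance_trim two-sided trim fraction on A values in TMM
#' @param lowess_span smoother span of the mean-variance trend
#' @return validated parameter list
#' @export
preprocess_params <- function(min_max_count = 10, prior_count = 0.5,
                              logratio_trim = 0.30, abundance_trim = 0.05,
                              lowess_span = 0.5) {
  if (min_max_count < 0) stopf("min_max_count must be >= 0")
  if (logratio_trim < 0 || logratio_trim >= 0.5 ||
      abundance_trim < 0 || abundance_trim >= 0.5)
    stopf("trim fractions must lie in [0, 0.5)")
  if (lowess_span <= 0 || lowess_span > 1)
    stopf("lowess_span must lie in (0, 1]")
  list(min_max_count = min_max_count, prior_count = prior_count,
       logratio_trim = logratio_trim, abundance_trim = abundance_trim,
       lowess_span = lowess_span)
}

#' Remove low-expressed genes
#'
#' Retains exactly the genes whose maximum count over all libraries is at
#' least `min_max_count` (default 10, so a gene topping out at 9 counts is
#' dropped and one reaching 10 is kept). Gene order is preserved.
#'
#' @param counts integer matrix genes x libraries
#' @param params [preprocess_params()]
#' @return filtered count matrix
#' @export
filter_low_expressed <- function(counts, params = preprocess_params()) {
  check_count_matrix(counts)
  keep <- apply(counts, 1, max) >= params$min_max_count
  counts[keep, , drop = FALSE]
}

# 75th-percentile count fraction per library (reference selection statistic)
.quantile_fraction <- function(counts, p = 0.75) {
  lib <- colSums(counts)
  apply(counts, 2, function(x) stats::quantile(x, p = p, names = FALSE)) / lib
}

# Trimmed, precision-weighted mean of M values of library `obs` vs `ref`.
.tmm_pair_factor <- function(obs, ref, lib_obs, lib_ref,
                             logratio_trim, abundance_trim) {
  use <- obs > 0 & ref > 0
  if (!any(use))
    stopf("a library shares no nonzero gene with the TMM reference")
  o <- obs[use]; r <- ref[use]
  m <- log2((o / lib_obs) / (r / lib_ref))
  a <- 0.5 * log2((o / lib_obs) * (r / lib_ref))
  # delta-method (binomial) variance of M
  v <- (lib_obs - o) / (lib_obs * o) + (lib_ref - r) / (lib_ref * r)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abundance_trim) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep)) return(1)
  f <- 2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
  if (!is.finite(f) || abs(log2(f)) < 1e-6) f <- 1
  f
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes between-library scaling factors by the trimmed mean of M-values
#' procedure: the reference library is the one whose 75th-percentile count
#' fraction is closest to the mean over libraries; per library, gene-wise
#' log2 expression ratios (M) and mean log2 abundances (A) versus the
#' reference are computed over genes nonzero in both, the most extreme
#' `logratio_trim` of M and `abundance_trim` of A are removed on both
#' sides, and the factor is two to the precision-weighted mean of the
#' retained M values, with inverse delta-method variances as weights.
#' Factors are rescaled to have geometric mean 1.
#'
#' @param counts integer matrix genes x libraries (>= 2 libraries, no
#'   all-zero library)
#' @param params [preprocess_params()]
#' @return named numeric vector of normalization factors, one per library
#' @export
tmm_norm_factors <- function(counts, params = preprocess_params()) {
  check_count_matrix(counts)
  if (ncol(counts) < 2) stopf("TMM needs at least two libraries")
  lib <- colSums(counts)
  if (any(lib == 0)) stopf("library with zero total count")
  f75 <- .quantile_fraction(counts, 0.75)
  ref <- which.min(abs(f75 - mean(f75)))
  factors <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    .tmm_pair_factor(counts[, j], counts[, ref], lib[j], lib[ref],
                     params$logratio_trim, params$abundance_trim)
  }, 0)
  factors <- factors / exp(mean(log(factors)))
  stats::setNames(factors, colnames(counts))
}

#' Log2 counts per million
#'
#' `log2((count + prior_count) / (library_size * factor + 1) * 1e6)`, the
#' standard moderated CPM transform on TMM-effective library sizes.
#'
#' @param counts integer matrix genes x libraries
#' @param norm_factors positive factors from [tmm_norm_factors()]
#' @param params [preprocess_params()]
#' @return numeric matrix of log2 CPM values, same shape as `counts`
#' @export
log2_cpm <- function(counts, norm_factors, params = preprocess_params()) {
  check_count_matrix(counts)
  if (length(norm_factors) != ncol(counts))
    stopf("need one normalization factor per library")
  if (any(norm_factors <= 0)) stopf("normalization factors must be positive")
  eff <- colSums(counts) * norm_factors
  log2(sweep(counts + params$prior_count, 2, eff + 1, "/") * 1e6)
}

#' Precision weights from the mean-variance trend
#'
#' Fits per-gene genotype means to the log2-CPM matrix, takes the square
#' root of each gene's residual standard deviation, smooths it against the
#' gene's average log2 abundance with lowess, and sets each observation's
#' weight to the trend interpolated at its fitted value raised to the
#' power -4 (i.e. the inverse of the predicted variance).
#'
#' @param log2cpm matrix from [log2_cpm()]
#' @param design character vector mapping each library (column) to its
#'   genotype
#' @param params [preprocess_params()]
#' @return positive weight matrix, same shape as `log2cpm`
#' @export
mean_variance_weights <- function(log2cpm, design,
                                  params = preprocess_params()) {
  if (length(design) != ncol(log2cpm))
    stopf("design must map every library to a genotype")
  groups <- unique(design)
  if (length(groups) < 2) stopf("need at least two distinct genotypes")
  n <- ncol(log2cpm)
  df_resid <- n - length(groups)
  if (df_resid < 1) stopf("zero residual degrees of freedom")

  fitted <- matrix(0, nrow(log2cpm), n, dimnames = dimnames(log2cpm))
  for (g in groups) {
    cols <- design == g
    fitted[, cols] <- rowMeans(log2cpm[, cols, drop = FALSE])
  }
  resid_sd <- sqrt(rowSums((log2cpm - fitted)^2) / df_resid)

  sx <- rowMeans(log2cpm)
  sy <- sqrt(resid_sd)
  lo <- stats::lowess(sx, sy, f = params$lowess_span)
  trend <- stats::approx(lo$x, lo$y, xout = as.vector(fitted), rule = 2,
                         ties = mean)$y
  trend <- pmax(trend, 1e-4)
  w <- matrix(trend^-4, nrow(log2cpm), n, dimnames = dimnames(log2cpm))
  if (any(!is.finite(w)) || any(w <= 0))
    stopf("non-finite or non-positive weights produced")
  w
}

#' Weighted least-squares genotype coefficients
#'
#' With a genotype-indicator design and no intercept, the weighted
#' least-squares solution per gene is the weighted mean of that genotype's
#' libraries: `coef = sum(w * y) / sum(w)`.
#'
#' @param log2cpm matrix genes x libraries
#' @param weights positive matrix, same shape
#' @param design character vector mapping libraries to genotypes
#' @return numeric matrix genes x genotypes
#' @export
genotype_coefficients <- function(log2cpm, weights, design) {
  if (!all(dim(weights) == dim(log2cpm)))
    stopf("weights must match the expression matrix shape")
  if (length(design) != ncol(log2cpm))
    stopf("design must map every library to a genotype")
  groups <- unique(design)
  coef <- matrix(NA_real_, nrow(log2cpm), length(groups),
                 dimnames = list(rownames(log2cpm), groups))
  for (g in groups) {
    cols <- design == g
    wy <- log2cpm[, cols, drop = FALSE] * weights[, cols, drop = FALSE]
    coef[, g] <- rowSums(wy) / rowSums(weights[, cols, drop = FALSE])
  }
  coef
}

#' Full preprocessing chain: filter, TMM, log2 CPM, weights, coefficients
#'
#' @param counts integer matrix genes x libraries
#' @param design character vector mapping libraries to genotypes
#' @param params [preprocess_params()]
#' @return list with `counts` (filtered), `norm_factors`, `library_sizes`,
#'   `values` (log2 CPM), `weights` and `coefficients` (genes x genotypes)
#' @export
preprocess_counts <- function(counts, design, params = preprocess_params()) {
  if (length(design) != ncol(counts))
    stopf("design must map every library to a genotype")
  filtered <- filter_low_expressed(counts, params)
  if (!nrow(filtered)) stopf("no gene passes the expression filter")
  nf <- tmm_norm_factors(filtered, params)
  values <- log2_cpm(filtered, nf, params)
  weights <- mean_variance_weights(values, design, params)
  coefficients <- genotype_coefficients(values, weights, design)
  list(counts = filtered, norm_factors = nf,
       library_sizes = colSums(filtered), values = values,
       weights = weights, coefficients = coefficients)
}
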