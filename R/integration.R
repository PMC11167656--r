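# Trait-trait and module-trait correlation analyses, gene significance
# (GS), module membership (MM), and candidate ranking.

# Pearson r with the two-sided p-value from t = r * sqrt((n-2)/(1-r^2)).
cor_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) return(list(r = NA_real_, n = n, p = NA_real_))
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(r = NA_real_, n = n, p = NA_real_))
  r <- stats::cor(x[ok], y[ok])
  if (abs(r) >= 1) return(list(r = r, n = n, p = 0))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, n = n, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Average matrix columns that share a genotype.
aggregate_by_genotype <- function(m, genotype) {
  if (length(genotype) != ncol(m))
    stopf("genotype map must cover every column")
  groups <- unique(genotype)
  out <- matrix(NA_real_, nrow(m), length(groups),
                dimnames = list(rownames(m), groups))
  for (g in groups)
    out[, g] <- rowMeans(m[, genotype == g, drop = FALSE])
  out
}

#' Pairwise Pearson correlations among traits
#'
#' Correlates every unordered trait pair over pairwise-complete genotypes,
#' with two-sided p-values from the t transform of r. Constant traits give
#' missing correlations with a warning.
#'
#' @param traits data.frame with a `genotype` column and numeric trait
#'   columns
#' @param alpha significance threshold for the flag column
#' @return data.frame with trait1, trait2, r, n, p, significant
#' @export
trait_correlation_table <- function(traits, alpha = 0.05) {
  trait_names <- setdiff(colnames(traits), "genotype")
  if (length(trait_names) < 2) stopf("need at least two traits")
  pairs <- utils::combn(trait_names, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ct <- cor_test(traits[[a]], traits[[b]])
    data.frame(trait1 = a, trait2 = b, r = ct$r, n = ct$n, p = ct$p,
               significant = isTRUE(ct$p < alpha), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(is.na(out$r)))
    warnf("%d trait pair(s) had undefined correlations (constant or < 3 shared values)",
          sum(is.na(out$r)))
  out
}

#' Module eigengene vs trait correlations
#'
#' Eigengene values are averaged over clonal replicates to genotype level,
#' then each module is tested for Pearson correlation with each trait
#' (two-sided t-based p; significance flagged at `alpha`). Genotypes
#' missing from the trait table are dropped with a warning.
#'
#' @param me eigengene matrix modules x samples
#' @param traits data.frame with `genotype` and trait columns
#' @param sample_genotype character vector mapping each ME column to its
#'   genotype
#' @param alpha significance threshold
#' @param aggregate average replicates to genotype level first (default)
#' @return data.frame with module, trait, r, n, p, significant
#' @export
module_trait_correlations <- function(me, traits, sample_genotype,
                                      alpha = 0.05, aggregate = TRUE) {
  if (aggregate) {
    me <- aggregate_by_genotype(me, sample_genotype)
    sample_genotype <- colnames(me)
  }
  shared <- intersect(sample_genotype, traits$genotype)
  if (length(shared) < 3) stopf("fewer than 3 genotypes shared with traits")
  dropped <- setdiff(unique(sample_genotype), traits$genotype)
  if (length(dropped))
    warnf("dropping genotype(s) absent from traits: %s",
          paste(dropped, collapse = ", "))
  tr <- traits[match(shared, traits$genotype), , drop = FALSE]
  me <- me[, shared, drop = FALSE]
  trait_names <- setdiff(colnames(traits), "genotype")
  rows <- list()
  for (mod in rownames(me)) for (t in trait_names) {
    ct <- cor_test(me[mod, ], tr[[t]])
    rows[[length(rows) + 1L]] <- data.frame(
      module = mod, trait = t, r = ct$r, n = ct$n, p = ct$p,
      significant = isTRUE(ct$p < alpha), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Gene significance: per-gene correlation with a trait
#'
#' Expression is averaged over clonal replicates to genotype level, then
#' each gene is correlated with the genotype-level trait. Constant genes
#' give missing GS.
#'
#' @param expression numeric matrix genes x samples
#' @param trait named numeric vector genotype -> trait value
#' @param sample_genotype genotype of each expression column
#' @param aggregate average replicates to genotype level first (default)
#' @return named numeric vector gene -> GS in [-1, 1]
#' @export
gene_significance <- function(expression, trait, sample_genotype,
                              aggregate = TRUE) {
  if (aggregate) {
    expression <- aggregate_by_genotype(expression, sample_genotype)
    sample_genotype <- colnames(expression)
  }
  shared <- intersect(sample_genotype, names(trait))
  if (length(shared) < 3) stopf("fewer than 3 genotypes shared with trait")
  x <- expression[, shared, drop = FALSE]
  y <- trait[shared]
  gs <- suppressWarnings(as.vector(stats::cor(t(x), y)))
  names(gs) <- rownames(expression)
  gs
}

#' Module membership: per-gene correlation with each module eigengene
#'
#' Computed per sample (not genotype-aggregated), following the kME
#' convention.
#'
#' @param expression numeric matrix genes x samples
#' @param me eigengene matrix modules x samples (same samples)
#' @return matrix genes x modules of correlations
#' @export
module_membership <- function(expression, me) {
  shared <- intersect(colnames(expression), colnames(me))
  if (length(shared) < 3) stopf("fewer than 3 shared samples")
  mm <- suppressWarnings(
    stats::cor(t(expression[, shared, drop = FALSE]),
               t(me[, shared, drop = FALSE])))
  mm
}

#' Rank candidate genes of a module for a trait
#'
#' Restricts to module genes annotated with at least one enriched term,
#' then ranks by the worst (maximum) of the two ranks of |GS| and MM, both
#' descending, so a candidate must score well on both axes; ties break by
#' |GS| then gene id.
#'
#' @param module module name
#' @param trait trait name (carried into the output)
#' @param labels gene -> module labels
#' @param gs named GS vector for the trait
#' @param mm MM matrix genes x modules
#' @param enriched_terms character vector of the module's overrepresented
#'   terms
#' @param go_map data.frame (gene, term)
#' @return data.frame with gene, module, trait, GS, MM, go_terms, rank,
#'   ordered by rank; empty (with a warning) if no module gene carries an
#'   enriched term
#' @export
rank_candidate_genes <- function(module, trait, labels, gs, mm,
                                 enriched_terms, go_map) {
  members <- names(labels)[labels == module]
  ann <- go_map[go_map$term %in% enriched_terms &
                  go_map$gene %in% members, , drop = FALSE]
  genes <- sort(unique(ann$gene))
  if (!length(genes)) {
    warnf("module '%s' has no gene annotated with an enriched term", module)
    return(data.frame(gene = character(), module = character(),
                      trait = character(), GS = numeric(), MM = numeric(),
                      go_terms = character(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  gs_g <- gs[genes]
  mm_g <- mm[genes, module]
  r_gs <- rank(-abs(gs_g), ties.method = "min")
  r_mm <- rank(-mm_g, ties.method = "min")
  score <- pmax(r_gs, r_mm)
  ord <- order(score, -abs(gs_g), genes)
  terms <- vapply(genes, function(g)
    paste(sort(ann$term[ann$gene == g]), collapse = ";"), "")
  out <- data.frame(gene = genes, module = module, trait = trait,
                    GS = unname(gs_g), MM = unname(mm_g),
                    go_terms = unname(terms), stringsAsFactors = FALSE)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
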