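# Dosage-QTL scan: group lines by relative dosage score (RDS) at a
# region, test each expressed gene in the region by one-way ANOVA with a
# Tukey HSD post hoc, and report the dosage-response slope.

#' Assign lines to RDS groups at a dQTL region
#'
#' Lines carrying a deletion overlapping the region score 0.5, lines with
#' an insertion 1.5, and `k_controls` control lines drawn (seeded) from
#' the non-lesion pool score 1.0.
#'
#' @param region list with `chromosome`, `start`, `end` (1-based inclusive)
#' @param indels data.frame (line, chromosome, start, end, type)
#' @param lines all lines under study; defaults to lines in `indels`
#' @param non_lesion_pool candidate control lines; defaults to lines
#'   carrying no indel event anywhere
#' @param k_controls number of RDS 1.0 control lines to draw (default 4)
#' @param seed seed for the control draw
#' @param policy overlap policy, `"any"` or `"within"`
#' @return named numeric vector line -> RDS in \{0.5, 1.0, 1.5\}
#' @export
assign_rds_groups <- function(region, indels, lines = NULL,
                              non_lesion_pool = NULL, k_controls = 4L,
                              seed = 1L, policy = c("any", "within")) {
  policy <- match.arg(policy)
  if (region$end < region$start) stopf("region end < start")
  if (is.null(lines)) lines <- unique(indels$line)
  on_chr <- indels$chromosome == region$chromosome &
    interval_overlaps(indels$start, indels$end, region$start, region$end,
                      policy = "any")
  if (policy == "within")
    on_chr <- indels$chromosome == region$chromosome &
      indels$start <= region$start & indels$end >= region$end
  hits <- indels[on_chr, , drop = FALSE]
  del <- unique(hits$line[hits$type == "deletion"])
  ins <- unique(hits$line[hits$type == "insertion"])
  both <- intersect(del, ins)
  if (length(both))
    stopf("line(s) with both deletion and insertion at the region: %s",
          paste(both, collapse = ", "))
  if (is.null(non_lesion_pool))
    non_lesion_pool <- setdiff(lines, unique(indels$line))
  non_lesion_pool <- setdiff(non_lesion_pool, c(del, ins))
  if (k_controls > length(non_lesion_pool))
    stopf("k_controls (%d) exceeds the non-lesion pool (%d)",
          k_controls, length(non_lesion_pool))
  ctrl <- with_seed(seed, sample(non_lesion_pool, k_controls))
  if (!length(del) || !length(ctrl) || !length(ins))
    stopf("empty RDS group at region %s:%d-%d (ANOVA undefined)",
          region$chromosome, region$start, region$end)
  groups <- c(stats::setNames(rep(0.5, length(del)), del),
              stats::setNames(rep(1.0, length(ctrl)), ctrl),
              stats::setNames(rep(1.5, length(ins)), ins))
  groups[order(names(groups))]
}

#' One-way fixed-effects ANOVA across RDS groups
#'
#' `F = (SSB/df_B) / (SSW/df_W)` with the upper-tail p from the F
#' distribution, computed via a standard linear-model fit.
#'
#' @param values_by_group named list of numeric vectors, one per RDS group
#' @return list with `F`, `p`, `df` (between, within), `group_means` and
#'   `degenerate` (TRUE when within-group variance is exactly zero but
#'   groups differ, in which case p is reported as 0)
#' @export
anova_across_rds <- function(values_by_group) {
  if (length(values_by_group) < 2) stopf("need at least two groups")
  if (any(lengths(values_by_group) == 0)) stopf("empty group")
  y <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(names(values_by_group), lengths(values_by_group)))
  df_w <- length(y) - nlevels(g)
  if (df_w < 1) stopf("no within-group degrees of freedom")
  means <- vapply(values_by_group, mean, 0)
  ssw <- sum(unlist(lapply(values_by_group, function(v) (v - mean(v))^2)))
  ssb <- sum(lengths(values_by_group) * (means - mean(y))^2)
  if (ssw == 0) {
    if (ssb == 0) stopf("all observations identical; ANOVA undefined")
    return(list(F = Inf, p = 0, df = c(nlevels(g) - 1L, df_w),
                group_means = means, degenerate = TRUE))
  }
  fit <- stats::anova(stats::lm(y ~ g))
  list(F = fit[["F value"]][1], p = fit[["Pr(>F)"]][1],
       df = c(fit$Df[1], fit$Df[2]), group_means = means,
       degenerate = FALSE)
}

# Maximal cliques of the "not significantly different" graph, brute force
# over subsets (group counts here are tiny).
compact_letters <- function(ns_adjacent) {
  groups <- rownames(ns_adjacent)
  n <- length(groups)
  subsets <- list()
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    ok <- all(ns_adjacent[members, members])
    if (ok) subsets[[length(subsets) + 1L]] <- members
  }
  is_maximal <- vapply(subsets, function(s)
    !any(vapply(subsets, function(t)
      length(t) > length(s) && all(s %in% t), TRUE)), TRUE)
  cliques <- subsets[is_maximal]
  cliques <- cliques[order(vapply(cliques, min, 0L))]
  letters_out <- stats::setNames(rep("", n), groups)
  for (i in seq_along(cliques))
    letters_out[cliques[[i]]] <- paste0(letters_out[cliques[[i]]],
                                        letters[i])
  letters_out
}

#' Tukey honest-significant-difference post hoc test
#'
#' Studentized-range pairwise p-values for all group pairs, with the
#' Tukey-Kramer standard error for unequal group sizes, plus a compact
#' letter display at `alpha` (groups sharing a letter are not
#' significantly different).
#'
#' @param values_by_group named list of numeric vectors
#' @param alpha significance level for the letter display
#' @return list with `pairwise` (data.frame: group1, group2, diff, p) and
#'   `letters` (named character vector)
#' @export
tukey_posthoc <- function(values_by_group, alpha = 0.05) {
  if (length(values_by_group) < 2) stopf("need at least two groups")
  if (any(lengths(values_by_group) == 0)) stopf("empty group")
  groups <- names(values_by_group)
  sizes <- lengths(values_by_group)
  means <- vapply(values_by_group, mean, 0)
  df_w <- sum(sizes) - length(groups)
  if (df_w < 1) stopf("no within-group degrees of freedom")
  msw <- sum(unlist(lapply(values_by_group,
                           function(v) (v - mean(v))^2))) / df_w
  k <- length(groups)
  pairs <- utils::combn(groups, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    d <- means[b] - means[a]
    se <- sqrt(msw / 2 * (1 / sizes[a] + 1 / sizes[b]))
    p <- if (msw == 0) {
      if (d == 0) 1 else 0
    } else {
      q <- abs(d) / se
      stats::ptukey(q, nmeans = k, df = df_w, lower.tail = FALSE)
    }
    data.frame(group1 = a, group2 = b, diff = unname(d), p = unname(p),
               stringsAsFactors = FALSE)
  })
  pairwise <- do.call(rbind, rows)
  ns <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairwise))) {
    if (pairwise$p[i] < alpha) {
      ns[pairwise$group1[i], pairwise$group2[i]] <- FALSE
      ns[pairwise$group2[i], pairwise$group1[i]] <- FALSE
    }
  }
  list(pairwise = pairwise, letters = compact_letters(ns))
}

#' Dosage-response slope
#'
#' Ordinary least-squares slope of genotype-level expression on numeric
#' RDS; in log2 expression units per dosage unit, a pure cis gene with
#' unit cis effect approaches `1 + log2(1.5)` (about 1.585) in the
#' noiseless limit.
#'
#' @param values named numeric vector line -> expression
#' @param rds named numeric vector line -> RDS
#' @return OLS slope
#' @export
dosage_slope <- function(values, rds) {
  shared <- intersect(names(values), names(rds))
  x <- rds[shared]; y <- values[shared]
  if (length(unique(x)) < 2) stopf("need at least two distinct RDS values")
  unname(stats::coef(stats::lm(y ~ x))[2])
}

#' Scan a dQTL region for dosage-responsive genes
#'
#' Restricts to annotated genes overlapping the region that are present in
#' the (filtered) expression matrix, then tests each for expression
#' differences across RDS groups by one-way ANOVA with Tukey post hoc and
#' reports the dosage-response slope; genes are flagged at `p < alpha`.
#'
#' @param region list with `chromosome`, `start`, `end`
#' @param expression genotype-level expression matrix genes x lines
#' @param annotation data.frame (gene, chromosome, start, end)
#' @param rds_groups named vector line -> RDS from [assign_rds_groups()]
#' @param alpha significance threshold (default 0.05)
#' @param policy overlap policy for gene-region overlap
#' @return data.frame with one row per tested gene: gene, coordinates,
#'   group means, F, p, slope, Tukey letters, significance flag; empty
#'   with a warning when no expressed gene overlaps the region
#' @export
dqtl_region_scan <- function(region, expression, annotation, rds_groups,
                             alpha = 0.05, policy = c("any", "within")) {
  policy <- match.arg(policy)
  on_chr <- annotation$chromosome == region$chromosome &
    interval_overlaps(annotation$start, annotation$end,
                      region$start, region$end, policy = policy)
  genes <- intersect(annotation$gene[on_chr], rownames(expression))
  if (!length(genes)) {
    warnf("no expressed gene overlaps region %s:%d-%d",
          region$chromosome, region$start, region$end)
    return(data.frame(gene = character(), stringsAsFactors = FALSE))
  }
  lines <- intersect(names(rds_groups), colnames(expression))
  if (length(lines) < length(rds_groups))
    warnf("dropping RDS line(s) absent from expression: %s",
          paste(setdiff(names(rds_groups), lines), collapse = ", "))
  rds <- rds_groups[lines]
  rows <- lapply(genes, function(g) {
    vals <- expression[g, lines]
    by_group <- split(vals, rds)
    av <- anova_across_rds(by_group)
    tk <- tukey_posthoc(by_group, alpha = alpha)
    means <- av$group_means
    ann_row <- annotation[annotation$gene == g, ][1, ]
    data.frame(gene = g, chromosome = ann_row$chromosome,
               start = ann_row$start, end = ann_row$end,
               mean_deletion = unname(means["0.5"]),
               mean_control = unname(means["1"]),
               mean_insertion = unname(means["1.5"]),
               F = av$F, p = av$p,
               slope = dosage_slope(vals, rds),
               letters = paste(sprintf("%s:%s", names(tk$letters),
                                       tk$letters), collapse = ","),
               significant = isTRUE(av$p < alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
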