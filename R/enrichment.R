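#' Hypergeometric GO-term overrepresentation within modules
#'
#' For each (module, term) pair with at least one overlapping gene, tests
#' whether the term is overrepresented in the module by the upper-tail
#' hypergeometric probability `P[X >= k]` of drawing `k` or more term
#' genes when `n` module genes are sampled from a background of `N` genes
#' containing `K` term genes. The term mapping is flat: no propagation
#' through the GO graph is performed.
#'
#' @param labels gene -> module labels; "grey" genes belong to the
#'   background but form no tested module unless `include_grey = TRUE`
#' @param go_map data.frame (gene, term)
#' @param background `"annotated"` (default: labeled genes carrying at
#'   least one term) or `"all"` (every labeled gene)
#' @param alpha significance threshold for the flag column
#' @param include_grey also test the unassigned "grey" gene set
#' @return data.frame with module, term, N, K, n, k, p, significant,
#'   sorted by p
#' @export
module_go_enrichment <- function(labels, go_map,
                                 background = c("annotated", "all"),
                                 alpha = 0.05, include_grey = FALSE) {
  background <- match.arg(background)
  if (!nrow(go_map)) stopf("go_map is empty")
  bg <- names(labels)
  if (background == "annotated")
    bg <- intersect(bg, unique(go_map$gene))
  if (!length(bg)) stopf("empty enrichment background")
  N <- length(bg)
  map <- go_map[go_map$gene %in% bg, , drop = FALSE]
  term_genes <- split(map$gene, map$term)
  modules <- setdiff(unique(labels), if (include_grey) character() else "grey")
  rows <- list()
  for (mod in modules) {
    mod_genes <- intersect(names(labels)[labels == mod], bg)
    n <- length(mod_genes)
    if (!n) next
    for (term in names(term_genes)) {
      K <- length(term_genes[[term]])
      k <- length(intersect(mod_genes, term_genes[[term]]))
      if (k == 0) next
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module = mod, term = term, N = N, K = K, n = n, k = k, p = p,
        significant = p < alpha, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(module = character(), term = character(),
                      N = integer(), K = integer(), n = integer(),
                      k = integer(), p = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$module, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
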