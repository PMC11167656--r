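#' Compute relative dosage scores from indel intervals
#'
#' Assigns each (gene, line) pair a relative dosage score (RDS): 0.5 when a
#' deletion carried by the line overlaps the gene's interval, 1.5 for an
#' insertion, and 1.0 otherwise. Overlap is interval overlap on the same
#' chromosome; under the default `"any"` policy one shared base pair
#' suffices, under `"within"` the gene must be fully contained in the event.
#'
#' @param annotation data.frame with columns gene, chromosome, start, end
#'   (1-based inclusive)
#' @param indels data.frame with columns line, chromosome, start, end, type
#' @param lines character vector of all lines to score; defaults to the
#'   lines present in `indels` (lines absent from `indels` score 1.0
#'   everywhere)
#' @param policy overlap policy, `"any"` or `"within"`
#' @return numeric matrix genes x lines with values in \{0.5, 1.0, 1.5\}
#' @export
compute_gene_dosage <- function(annotation, indels, lines = NULL,
                                policy = c("any", "within")) {
  policy <- match.arg(policy)
  if (is.null(lines)) lines <- unique(indels$line)
  if (!length(lines)) stopf("no lines to score")
  rds <- matrix(1.0, nrow = nrow(annotation), ncol = length(lines),
                dimnames = list(annotation$gene, lines))
  if (!nrow(indels)) return(rds)
  bad <- setdiff(unique(indels$type), c("deletion", "insertion"))
  if (length(bad))
    stopf("unknown indel type(s): %s", paste(bad, collapse = ", "))

  gene_rng <- IRanges::IRanges(start = annotation$start, end = annotation$end)
  for (chr in unique(indels$chromosome)) {
    on_chr_gene <- which(annotation$chromosome == chr)
    if (!length(on_chr_gene)) next
    ev <- indels[indels$chromosome == chr, , drop = FALSE]
    ev_rng <- IRanges::IRanges(start = ev$start, end = ev$end)
    hits <- IRanges::findOverlaps(
      gene_rng[on_chr_gene], ev_rng,
      type = if (policy == "within") "within" else "any")
    if (!length(hits)) next
    gi <- on_chr_gene[S4Vectors::queryHits(hits)]
    ei <- S4Vectors::subjectHits(hits)
    for (h in seq_along(gi)) {
      line <- ev$line[ei[h]]
      if (!line %in% lines) next
      val <- if (ev$type[ei[h]] == "deletion") 0.5 else 1.5
      cur <- rds[gi[h], line]
      if (cur != 1.0 && cur != val)
        stopf("gene %s overlapped by both a deletion and an insertion in line %s",
              annotation$gene[gi[h]], line)
      rds[gi[h], line] <- val
    }
  }
  rds
}

#' Neutralize cis-dosage effects on expression inside indel regions
#'
#' For each gene, the expression value of every line whose RDS differs from
#' 1.0 is replaced so that indel-driven cis effects cannot seed artificial
#' co-expression. Under the default `"reference"` mode the replacement is
#' the mean over lines with RDS = 1.0 at that gene (so no cis signal from
#' other indel lines re-enters); `"all_other"` uses the literal mean over
#' all other lines. Values at RDS = 1.0 entries are untouched. The
#' operation is idempotent in `"reference"` mode.
#'
#' @param expression numeric matrix genes x lines (e.g. genotype
#'   coefficients), or genes x libraries together with `line_of_column`
#' @param dosage_map matrix from [compute_gene_dosage()]; genes not present
#'   are treated as RDS 1.0 everywhere
#' @param line_of_column optional character vector mapping each expression
#'   column to a line, for library-level matrices
#' @param mode `"reference"` (mean over RDS = 1.0 lines) or `"all_other"`
#' @return list with `expression` (modified copy) and `log` (data.frame:
#'   gene, line, old, new), one row per replaced genotype-level value
#' @export
indel_normalize_expression <- function(expression, dosage_map,
                                       line_of_column = NULL,
                                       mode = c("reference", "all_other")) {
  mode <- match.arg(mode)
  if (is.null(line_of_column)) line_of_column <- colnames(expression)
  if (length(line_of_column) != ncol(expression))
    stopf("line_of_column must name every expression column")
  out <- expression
  log_rows <- list()
  genes <- intersect(rownames(expression), rownames(dosage_map))
  lines_scored <- colnames(dosage_map)
  for (g in genes) {
    rds_g <- dosage_map[g, ]
    hit_lines <- lines_scored[rds_g != 1.0]
    hit_lines <- intersect(hit_lines, line_of_column)
    if (!length(hit_lines)) next
    for (line in hit_lines) {
      cols_line <- which(line_of_column == line)
      if (mode == "reference") {
        ref_lines <- lines_scored[rds_g == 1.0]
        ref_cols <- which(line_of_column %in% ref_lines |
                            !(line_of_column %in% lines_scored))
      } else {
        ref_cols <- which(line_of_column != line)
      }
      if (!length(ref_cols))
        stopf("gene %s has RDS != 1.0 in every line; no reference mean exists", g)
      repl <- mean(expression[g, ref_cols])
      old <- mean(out[g, cols_line])
      out[g, cols_line] <- repl
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(gene = g, line = line, old = old, new = repl,
                   stringsAsFactors = FALSE)
    }
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(gene = character(), line = character(),
               old = numeric(), new = numeric(), stringsAsFactors = FALSE)
  list(expression = out, log = log)
}
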