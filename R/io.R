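# Readers and writers for the plain-text dataset layout.
#
# counts: TSV, first column "gene", remaining columns library ids.
# samples: CSV (library, genotype, replicate).
# annotation: TSV (gene, chromosome, start, end), 1-based inclusive.
# go_map: TSV (gene, term), one pair per row.
# indels: TSV (line, chromosome, start, end, type), 1-based inclusive by
#   default; 0-based half-open input converted on read when flagged.
# traits: CSV (genotype, one column per trait).
# truth: JSON.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, required) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stopf("%s lacks required column(s): %s", path,
          paste(missing, collapse = ", "))
  df
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits `counts.tsv`, `samples.csv`, `annotation.tsv`, `go_map.tsv`,
#' `indels.tsv`, `traits.csv` and `truth.json`. All files round-trip
#' losslessly through the corresponding readers.
#'
#' @param dataset output of [simulate_dataset()]
#' @param dir existing, writable output directory
#' @return invisibly, a named character vector of the written paths
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) stopf("directory does not exist: %s", dir)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.csv"),
             annotation = file.path(dir, "annotation.tsv"),
             go_map = file.path(dir, "go_map.tsv"),
             indels = file.path(dir, "indels.tsv"),
             traits = file.path(dir, "traits.csv"),
             truth = file.path(dir, "truth.json"))
  cnt <- data.frame(gene = rownames(dataset$counts), dataset$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(cnt, paths["counts"])
  utils::write.csv(dataset$sample_sheet, paths["samples"], row.names = FALSE,
                   quote = FALSE)
  write_tsv(dataset$annotation, paths["annotation"])
  write_tsv(dataset$go_map, paths["go_map"])
  write_tsv(dataset$indels, paths["indels"])
  utils::write.csv(dataset$traits, paths["traits"], row.names = FALSE,
                   quote = FALSE)
  truth <- dataset$truth
  truth_json <- list(
    module_label_per_gene = as.list(truth$module_label_per_gene),
    cis_genes = truth$cis_genes,
    rds = list(genes = rownames(truth$rds), lines = colnames(truth$rds),
               values = unname(truth$rds)),
    trait_loadings = truth$trait_loadings,
    module_factors = if (!is.null(truth$module_factors))
      list(modules = rownames(truth$module_factors),
           lines = colnames(truth$module_factors),
           values = unname(truth$module_factors)),
    seed = truth$seed)
  jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a gene x library count matrix from TSV
#' @param path TSV with first column `gene` and one column per library
#' @return integer matrix with gene rownames and library colnames
#' @export
read_counts <- function(path) {
  df <- read_tsv(path, "gene")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene
  check_count_matrix(m)
}

#' Read a library sample sheet from CSV
#' @param path CSV with columns library, genotype, replicate
#' @return data.frame
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("library", "genotype", "replicate"), colnames(df))
  if (length(missing))
    stopf("%s lacks required column(s): %s", path,
          paste(missing, collapse = ", "))
  df
}

#' Read a gene annotation table from TSV
#' @param path TSV with columns gene, chromosome, start, end (1-based
#'   inclusive)
#' @return data.frame
#' @export
read_annotation <- function(path) {
  df <- read_tsv(path, c("gene", "chromosome", "start", "end"))
  if (any(df$end < df$start)) stopf("annotation has end < start")
  df
}

#' Read a gene-to-GO-term map from TSV
#' @param path two-column TSV (gene, term), one pair per row
#' @return data.frame
#' @export
read_go_map <- function(path) read_tsv(path, c("gene", "term"))

#' Read indel events from a BED-like TSV
#'
#' @param path TSV with columns line, chromosome, start, end, type
#'   (`deletion` or `insertion`)
#' @param zero_based if `TRUE`, input coordinates are 0-based half-open
#'   (BED convention) and are converted to 1-based inclusive on read
#' @return data.frame with 1-based inclusive coordinates
#' @export
read_indels <- function(path, zero_based = FALSE) {
  df <- read_tsv(path, c("line", "chromosome", "start", "end", "type"))
  if (zero_based) df$start <- df$start + 1L
  bad <- setdiff(unique(df$type), c("deletion", "insertion"))
  if (length(bad))
    stopf("unknown indel type(s): %s", paste(bad, collapse = ", "))
  if (any(df$end < df$start)) stopf("indel has end < start")
  df
}

#' Read a genotype x trait table from CSV
#' @param path CSV with a `genotype` column and one numeric column per trait
#' @return data.frame
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"genotype" %in% colnames(df))
    stopf("%s lacks required column: genotype", path)
  df
}

#' Read simulation ground truth from JSON
#' @param path JSON written by [write_dataset()]
#' @return truth list with named module labels and RDS matrix restored
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- list(
    module_label_per_gene = unlist(x$module_label_per_gene),
    cis_genes = x$cis_genes,
    rds = matrix(unlist(x$rds$values), nrow = length(x$rds$genes),
                 dimnames = list(x$rds$genes, x$rds$lines)),
    trait_loadings = x$trait_loadings,
    seed = x$seed)
  if (!is.null(x$module_factors))
    truth$module_factors <- matrix(
      unlist(x$module_factors$values),
      nrow = length(x$module_factors$modules),
      dimnames = list(x$module_factors$modules, x$module_factors$lines))
  truth
}

#' Read a complete dataset directory written by [write_dataset()]
#' @param dir directory containing the dataset files
#' @return list mirroring [simulate_dataset()] output
#' @export
read_dataset <- function(dir) {
  list(counts = read_counts(file.path(dir, "counts.tsv")),
       sample_sheet = read_sample_sheet(file.path(dir, "samples.csv")),
       annotation = read_annotation(file.path(dir, "annotation.tsv")),
       go_map = read_go_map(file.path(dir, "go_map.tsv")),
       indels = read_indels(file.path(dir, "indels.tsv")),
       traits = read_traits(file.path(dir, "traits.csv")),
       truth = read_truth(file.path(dir, "truth.json")))
}
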