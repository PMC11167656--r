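#' Configuration for the synthetic indel-population generator
#'
#' Describes a clonally replicated population of genotypes ("lines") carrying
#' large chromosomal insertions/deletions, with planted co-expression modules,
#' cis-dosage effects on genes inside indel regions, and quantitative traits
#' loaded on module activity. The defaults emulate a design of 33 genotypes
#' with 2-3 clonal replicates (91 libraries), 3'-tag count depths around two
#' million reads, four planted modules of 50 genes, and two dosage-QTL
#' regions: one on chromosome 9 (6.3-6.8 Mbp; 3 deletion and 2 insertion
#' lines) and one on chromosome 16 (0-0.5 Mbp; 4 deletion and 2 insertion
#' lines).
#'
#' @param n_genotypes number of genotypes (lines)
#' @param reps_per_genotype integer vector of clonal replicate counts, one
#'   per genotype (recycled); values 2-3 mirror the emulated design
#' @param n_genes number of genes
#' @param n_chromosomes number of chromosomes
#' @param genes_per_chromosome genes laid on each chromosome; must satisfy
#'   `genes_per_chromosome * n_chromosomes >= n_genes`
#' @param gene_spacing distance in bp between successive gene starts
#' @param gene_length gene interval length in bp (must be < `gene_spacing`
#'   so intervals never overlap)
#' @param module_sizes integer vector of planted module sizes
#' @param module_factor_sd standard deviation (log2 units) of the latent
#'   genotype-level module factors
#' @param noise_dispersion negative-binomial dispersion phi > 0
#'   (variance = mean + phi * mean^2)
#' @param base_log2_mean_range range of per-gene baseline log2 abundance
#' @param library_size_range range of total read counts per library
#' @param indel_regions list of regions, each a list with `chromosome`,
#'   `start`, `end` (1-based inclusive bp), `n_deletion`, `n_insertion`
#' @param cis_effect gamma, the cis log2 fold change per log2 dosage unit;
#'   1.0 means expression tracks copy number proportionally
#' @param trait_loadings named list; each element a list with `module`
#'   (planted module index), `loading`, `noise_sd`. Default trait names
#'   follow the wood-anatomy abbreviations TH, VF, cVF, MVD, cMVD, MVC,
#'   VGI, NF, BT.
#' @param go_enrichment_fraction fraction of each planted module annotated
#'   with that module's synthetic GO term
#' @param go_background_rate probability that a gene outside the module also
#'   carries the module's synthetic term
#' @param n_background_terms size of the random background GO-term pool
#' @param seed integer seed; all generator stages derive their streams from it
#' @return a validated `simulation_config` list
#' @export
simulation_config <- function(n_genotypes = 33L,
                              reps_per_genotype = c(rep(3L, 25), rep(2L, 8)),
                              n_genes = 2000L,
                              n_chromosomes = 19L,
                              genes_per_chromosome = ceiling(n_genes / n_chromosomes),
                              gene_spacing = 350000L,
                              gene_length = 4000L,
                              module_sizes = c(50L, 50L, 50L, 50L),
                              module_factor_sd = 2,
                              noise_dispersion = 0.1,
                              base_log2_mean_range = c(3, 9),
                              library_size_range = c(1.5e6, 2.5e6),
                              indel_regions = list(
                                list(chromosome = "Chr09", start = 6300000L,
                                     end = 6800000L, n_deletion = 3L,
                                     n_insertion = 2L),
                                list(chromosome = "Chr16", start = 1L,
                                     end = 500000L, n_deletion = 4L,
                                     n_insertion = 2L)),
                              cis_effect = 1.0,
                              trait_loadings = list(
                                TH   = list(module = 1L, loading =  1.0, noise_sd = 0.5),
                                MVD  = list(module = 1L, loading =  0.8, noise_sd = 0.5),
                                VF   = list(module = 1L, loading = -0.9, noise_sd = 0.5),
                                cMVD = list(module = 2L, loading =  1.0, noise_sd = 0.5),
                                cVF  = list(module = 3L, loading =  1.0, noise_sd = 0.5),
                                MVC  = list(module = 4L, loading =  0.7, noise_sd = 0.5),
                                VGI  = list(module = 1L, loading =  0.0, noise_sd = 1.0),
                                NF   = list(module = 1L, loading =  0.0, noise_sd = 1.0),
                                BT   = list(module = 1L, loading =  0.7, noise_sd = 0.5)),
                              go_enrichment_fraction = 0.5,
                              go_background_rate = 0.02,
                              n_background_terms = 40L,
                              seed = 1L) {
  cfg <- list(
    n_genotypes = as.integer(n_genotypes),
    reps_per_genotype = as.integer(rep_len(reps_per_genotype, n_genotypes)),
    n_genes = as.integer(n_genes),
    n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    gene_spacing = as.integer(gene_spacing),
    gene_length = as.integer(gene_length),
    module_sizes = as.integer(module_sizes),
    module_factor_sd = module_factor_sd,
    noise_dispersion = noise_dispersion,
    base_log2_mean_range = base_log2_mean_range,
    library_size_range = library_size_range,
    indel_regions = indel_regions,
    cis_effect = cis_effect,
    trait_loadings = trait_loadings,
    go_enrichment_fraction = go_enrichment_fraction,
    go_background_rate = go_background_rate,
    n_background_terms = as.integer(n_background_terms),
    seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (!is_count(n_genotypes) || !is_count(n_genes) ||
        !is_count(n_chromosomes) || !is_count(genes_per_chromosome))
      stopf("n_genotypes, n_genes, n_chromosomes, genes_per_chromosome must be counts >= 1")
    if (any(reps_per_genotype < 1L))
      stopf("reps_per_genotype must all be >= 1")
    if (genes_per_chromosome * n_chromosomes < n_genes)
      stopf("genes_per_chromosome (%d) x n_chromosomes (%d) < n_genes (%d)",
            genes_per_chromosome, n_chromosomes, n_genes)
    if (gene_length >= gene_spacing)
      stopf("gene_length must be smaller than gene_spacing")
    if (sum(module_sizes) > n_genes)
      stopf("module sizes sum (%d) exceeds n_genes (%d)",
            sum(module_sizes), n_genes)
    if (noise_dispersion <= 0) stopf("noise_dispersion phi must be > 0")
    if (length(base_log2_mean_range) != 2L ||
        diff(base_log2_mean_range) < 0)
      stopf("base_log2_mean_range must be an increasing interval")
    if (length(library_size_range) != 2L || library_size_range[1] < 1 ||
        diff(library_size_range) < 0)
      stopf("library_size_range must be a positive interval")
    chrom_len <- genes_per_chromosome * gene_spacing
    for (r in indel_regions) {
      if (!all(c("chromosome", "start", "end", "n_deletion", "n_insertion")
               %in% names(r)))
        stopf("each indel region needs chromosome, start, end, n_deletion, n_insertion")
      if (r$start < 1L || r$end < r$start || r$end > chrom_len)
        stopf("indel region %s:%d-%d lies outside chromosome bounds [1, %d]",
              r$chromosome, r$start, r$end, chrom_len)
    }
    n_assigned <- sum(vapply(indel_regions,
                             function(r) r$n_deletion + r$n_insertion, 0))
    if (n_assigned > n_genotypes)
      stopf("more indel-designated lines (%d) than genotypes (%d)",
            n_assigned, n_genotypes)
    for (nm in names(trait_loadings)) {
      tl <- trait_loadings[[nm]]
      if (tl$module < 1L || tl$module > length(module_sizes))
        stopf("trait '%s' loads on nonexistent module %d", nm, tl$module)
      if (tl$noise_sd < 0) stopf("trait '%s' has negative noise_sd", nm)
    }
    if (go_enrichment_fraction <= 0 || go_enrichment_fraction > 1)
      stopf("go_enrichment_fraction must be in (0, 1]")
  })
  invisible(cfg)
}

genotype_names <- function(cfg) sprintf("gt%02d", seq_len(cfg$n_genotypes))
gene_names <- function(cfg) sprintf("gene%04d", seq_len(cfg$n_genes))
chromosome_names <- function(cfg) sprintf("Chr%02d", seq_len(cfg$n_chromosomes))

#' Generate a synthetic gene annotation with planted modules and GO terms
#'
#' Lays genes sequentially along chromosomes in non-overlapping 1-based
#' inclusive intervals, assigns each planted module a random set of member
#' genes (drawn outside the configured indel regions so module structure and
#' cis-dosage effects stay separable), and builds a gene-to-GO map in which
#' each module is enriched for one synthetic term (`GO:SIM<module>`) carried
#' by `go_enrichment_fraction` of its members plus sparse background genes,
#' on top of random background terms.
#'
#' @param config a [simulation_config()]
#' @return list with `genes` (data.frame: gene, chromosome, start, end),
#'   `go_map` (data.frame: gene, term) and `module_label` (named character
#'   vector; `"background"` for unplanted genes)
#' @export
make_annotation <- function(config) {
  validate_simulation_config(config)
  n <- config$n_genes
  idx_on_chr <- ((seq_len(n) - 1L) %% config$genes_per_chromosome) + 1L
  chr_idx <- ((seq_len(n) - 1L) %/% config$genes_per_chromosome) + 1L
  start <- (idx_on_chr - 1L) * config$gene_spacing + 1L
  genes <- data.frame(
    gene = gene_names(config),
    chromosome = chromosome_names(config)[chr_idx],
    start = start,
    end = start + config$gene_length - 1L,
    stringsAsFactors = FALSE)

  # genes overlapping any configured indel region are reserved for cis effects
  in_region <- rep(FALSE, n)
  for (r in config$indel_regions) {
    on_chr <- genes$chromosome == r$chromosome
    in_region <- in_region |
      (on_chr & interval_overlaps(genes$start, genes$end, r$start, r$end))
  }

  with_seed(config$seed + 101L, {
    module_label <- rep("background", n)
    names(module_label) <- genes$gene
    pool <- which(!in_region)
    for (m in seq_along(config$module_sizes)) {
      size <- config$module_sizes[m]
      if (length(pool) < size)
        stopf("not enough genes outside indel regions for module %d", m)
      pick <- sample(pool, size)
      module_label[pick] <- sprintf("module%d", m)
      pool <- setdiff(pool, pick)
    }

    # background GO terms: each gene draws 1-3 terms from a shared pool
    bg_terms <- sprintf("GO:BG%04d", seq_len(config$n_background_terms))
    n_terms <- sample(1:3, n, replace = TRUE)
    go_gene <- rep(genes$gene, n_terms)
    go_term <- unlist(lapply(n_terms, function(k) sample(bg_terms, k)))

    # one synthetic enrichment term per planted module
    for (m in seq_along(config$module_sizes)) {
      members <- which(module_label == sprintf("module%d", m))
      n_in <- round(config$go_enrichment_fraction * length(members))
      carriers <- sample(members, n_in)
      outside <- setdiff(seq_len(n), members)
      extra <- outside[stats::runif(length(outside)) < config$go_background_rate]
      term <- sprintf("GO:SIM%04d", m)
      go_gene <- c(go_gene, genes$gene[c(carriers, extra)])
      go_term <- c(go_term, rep(term, n_in + length(extra)))
    }
    go_map <- unique(data.frame(gene = go_gene, term = go_term,
                                stringsAsFactors = FALSE))
    go_map <- go_map[order(go_map$gene, go_map$term), , drop = FALSE]
    rownames(go_map) <- NULL
    list(genes = genes, go_map = go_map, module_label = module_label)
  })
}

#' Assign indel events to lines and derive the ground-truth dosage map
#'
#' Each configured region receives `n_deletion` deletion lines and
#' `n_insertion` insertion lines drawn without replacement from genotypes not
#' yet carrying an event, so deletion and insertion line sets are disjoint
#' within (and across) regions. Every event spans its region exactly. The
#' returned truth records the relative dosage score (RDS) of every gene in
#' every line under the overlap rule of [compute_gene_dosage()].
#'
#' @param config a [simulation_config()]
#' @param annotation output of [make_annotation()]
#' @return list with `indels` (data.frame: line, chromosome, start, end,
#'   type) and `truth` (partial ground truth: module labels, cis gene set,
#'   RDS matrix, seed)
#' @export
make_indel_population <- function(config, annotation) {
  validate_simulation_config(config)
  lines <- genotype_names(config)
  with_seed(config$seed + 202L, {
    events <- list()
    available <- lines
    for (r in config$indel_regions) {
      n_need <- r$n_deletion + r$n_insertion
      if (n_need > length(available))
        stopf("more designated lines than available genotypes in region %s:%d-%d",
              r$chromosome, r$start, r$end)
      picked <- sample(available, n_need)
      available <- setdiff(available, picked)
      if (n_need > 0)
        events[[length(events) + 1L]] <- data.frame(
          line = picked,
          chromosome = r$chromosome,
          start = r$start,
          end = r$end,
          type = rep(c("deletion", "insertion"),
                     c(r$n_deletion, r$n_insertion)),
          stringsAsFactors = FALSE)
    }
    indels <- if (length(events)) do.call(rbind, events) else
      data.frame(line = character(), chromosome = character(),
                 start = integer(), end = integer(), type = character(),
                 stringsAsFactors = FALSE)
    rownames(indels) <- NULL
    rds <- compute_gene_dosage(annotation$genes, indels, lines = lines)
    truth <- list(
      module_label_per_gene = annotation$module_label,
      cis_genes = rownames(rds)[apply(rds != 1, 1, any)],
      rds = rds,
      trait_loadings = config$trait_loadings,
      seed = config$seed)
    list(indels = indels, truth = truth)
  })
}

#' Simulate negative-binomial tag counts with planted structure
#'
#' Builds the latent log2 expression of gene i in genotype g as
#' `base_i + f[m(i), g] + gamma * log2(RDS[i, g])`, where `f` are
#' genotype-level module factors drawn from Normal(0, `module_factor_sd`)
#' and the cis term applies only to genes inside indel regions. Per-genotype
#' expression is converted to compositional proportions so that library size
#' alone sets sequencing depth, and each library's counts are drawn from a
#' negative binomial with dispersion `noise_dispersion`
#' (variance = mean + phi * mean^2). Clonal replicates share the latent
#' expression and differ only by library size and sampling noise.
#'
#' @param config a [simulation_config()]
#' @param annotation output of [make_annotation()]
#' @param indels indel table from [make_indel_population()]
#' @param truth partial truth from [make_indel_population()]
#' @return list with `counts` (integer matrix genes x libraries),
#'   `sample_sheet` (data.frame: library, genotype, replicate) and the
#'   `truth` completed with the realized `module_factors` (module x
#'   genotype matrix)
#' @export
simulate_counts <- function(config, annotation, indels, truth) {
  validate_simulation_config(config)
  if (config$noise_dispersion <= 0) stopf("noise_dispersion phi must be > 0")
  genes <- annotation$genes$gene
  lines <- genotype_names(config)
  n_mod <- length(config$module_sizes)
  with_seed(config$seed + 303L, {
    base <- stats::runif(config$n_genes, config$base_log2_mean_range[1],
                         config$base_log2_mean_range[2])
    f <- matrix(stats::rnorm(n_mod * config$n_genotypes,
                             sd = config$module_factor_sd),
                nrow = n_mod, ncol = config$n_genotypes,
                dimnames = list(sprintf("module%d", seq_len(n_mod)), lines))
    x <- matrix(base, nrow = config$n_genes, ncol = config$n_genotypes,
                dimnames = list(genes, lines))
    lab <- truth$module_label_per_gene[genes]
    for (m in seq_len(n_mod)) {
      members <- lab == sprintf("module%d", m)
      x[members, ] <- x[members, , drop = FALSE] +
        matrix(f[m, ], nrow = sum(members), ncol = config$n_genotypes,
               byrow = TRUE)
    }
    cis <- truth$rds[genes, lines, drop = FALSE] != 1
    if (any(cis))
      x[cis] <- x[cis] + config$cis_effect * log2(truth$rds[genes, lines][cis])

    # compositional proportions per genotype: depth is set by library size
    p <- 2^x
    p <- sweep(p, 2, colSums(p), "/")

    reps <- config$reps_per_genotype
    sample_sheet <- data.frame(
      library = unlist(lapply(seq_along(lines), function(i)
        sprintf("%s_r%d", lines[i], seq_len(reps[i])))),
      genotype = rep(lines, reps),
      replicate = unlist(lapply(reps, seq_len)),
      stringsAsFactors = FALSE)
    lib_sizes <- round(stats::runif(nrow(sample_sheet),
                                    config$library_size_range[1],
                                    config$library_size_range[2]))
    counts <- matrix(0L, nrow = config$n_genes, ncol = nrow(sample_sheet),
                     dimnames = list(genes, sample_sheet$library))
    size <- 1 / config$noise_dispersion
    for (s in seq_len(nrow(sample_sheet))) {
      mu <- lib_sizes[s] * p[, sample_sheet$genotype[s]]
      counts[, s] <- stats::rnbinom(config$n_genes, mu = mu, size = size)
    }
    storage.mode(counts) <- "integer"
    truth$module_factors <- f
    truth$base_log2_mean <- stats::setNames(base, genes)
    list(counts = counts, sample_sheet = sample_sheet, truth = truth)
  })
}

#' Simulate genotype-level quantitative traits loaded on module factors
#'
#' Trait value for genotype g is `loading * f[module, g] + Normal(0,
#' noise_sd)` using the module factors realized by [simulate_counts()].
#'
#' @param config a [simulation_config()]
#' @param truth completed truth containing `module_factors`
#' @return data.frame with a `genotype` column and one column per trait
#' @export
simulate_traits <- function(config, truth) {
  if (is.null(truth$module_factors))
    stopf("truth lacks module_factors; run simulate_counts first")
  f <- truth$module_factors
  lines <- colnames(f)
  with_seed(config$seed + 404L, {
    traits <- data.frame(genotype = lines, stringsAsFactors = FALSE)
    for (nm in names(config$trait_loadings)) {
      tl <- config$trait_loadings[[nm]]
      if (tl$module > nrow(f))
        stopf("trait '%s' loads on nonexistent module %d", nm, tl$module)
      traits[[nm]] <- tl$loading * f[tl$module, ] +
        stats::rnorm(length(lines), sd = tl$noise_sd)
    }
    traits
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs [make_annotation()], [make_indel_population()], [simulate_counts()]
#' and [simulate_traits()] in order and bundles their outputs.
#'
#' @param config a [simulation_config()]
#' @return list with `counts`, `sample_sheet`, `annotation`, `go_map`,
#'   `indels`, `traits` and `truth`
#' @export
simulate_dataset <- function(config = simulation_config()) {
  ann <- make_annotation(config)
  pop <- make_indel_population(config, ann)
  cnt <- simulate_counts(config, ann, pop$indels, pop$truth)
  traits <- simulate_traits(config, cnt$truth)
  list(counts = cnt$counts, sample_sheet = cnt$sample_sheet,
       annotation = ann$genes, go_map = ann$go_map, indels = pop$indels,
       traits = traits, truth = cnt$truth)
}
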