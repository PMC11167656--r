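# Configuration loading and end-to-end orchestration.

config_defaults <- function() {
  list(
    paths = list(counts = NULL, samples = NULL, annotation = NULL,
                 go_map = NULL, indels = NULL, traits = NULL),
    preprocess = preprocess_params(),
    network = network_params(),
    stability = c(stability_params(), list(run = TRUE)),
    enrichment = list(background = "annotated"),
    alpha = 0.05,
    indel_normalize = FALSE,
    indels_zero_based = FALSE,
    network_input = "libraries",
    dqtl_regions = list(),
    seed = 1L)
}

merge_config_section <- function(defaults, given, section) {
  if (is.null(given)) return(defaults)
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    stopf("unknown key(s) in config section '%s': %s", section,
          paste(unknown, collapse = ", "))
  utils::modifyList(defaults, given)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML document, fills documented defaults (soft power 12, cut
#' height 0.99, merge threshold 0.75, resampling fraction 0.63 with 49
#' iterations, alpha 0.05, indel normalization off), rejects unknown keys,
#' and checks that every referenced input file exists.
#'
#' @param path YAML configuration file
#' @return validated configuration list
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  def <- config_defaults()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- def
  for (sec in c("paths", "preprocess", "network", "stability", "enrichment"))
    cfg[[sec]] <- merge_config_section(def[[sec]], raw[[sec]], sec)
  for (key in c("alpha", "indel_normalize", "indels_zero_based",
                "network_input", "dqtl_regions", "seed"))
    if (!is.null(raw[[key]])) cfg[[key]] <- raw[[key]]
  validate_config(cfg, dirname(normalizePath(path)))
}

validate_config <- function(cfg, base_dir = ".") {
  need <- c("counts", "samples", "annotation", "go_map", "indels", "traits")
  for (p in need) {
    if (is.null(cfg$paths[[p]])) stopf("config paths.%s is required", p)
    path <- cfg$paths[[p]]
    if (!file.exists(path)) {
      rel <- file.path(base_dir, path)
      if (file.exists(rel)) cfg$paths[[p]] <- rel
      else stopf("input file for paths.%s not found: %s", p, path)
    }
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (!cfg$network_input %in% c("libraries", "coefficients"))
    stopf("network_input must be 'libraries' or 'coefficients'")
  # re-run the parameter constructors so their invariants are enforced
  cfg$preprocess <- do.call(preprocess_params, cfg$preprocess)
  st <- cfg$stability
  cfg$stability <- c(stability_params(st$subsample_fraction,
                                      st$n_iterations, st$seed),
                     list(run = isTRUE(st$run)))
  cfg$network <- do.call(network_params, cfg$network)
  for (r in cfg$dqtl_regions)
    if (!all(c("chromosome", "start", "end") %in% names(r)))
      stopf("each dqtl region needs chromosome, start, end")
  cfg
}

write_matrix_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(m[, 0, drop = FALSE], check.names = FALSE)
  df[[id_col]] <- rownames(m)
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full dosage-aware co-expression pipeline
#'
#' Executes filtering, TMM normalization, log2-CPM transformation,
#' precision weights, genotype coefficients, optional indel
#' normalization, network construction and module detection, eigengene and
#' stability computation, trait integration (trait-trait and module-trait
#' correlations, GS and MM), GO overrepresentation, and the dQTL
#' dosage-response scans. Every stage's table is written to `outdir`
#' together with a JSON manifest carrying parameters, the seed and
#' checksums of all inputs and outputs.
#'
#' @param config configuration from [load_config()] (or an equivalent
#'   list)
#' @param outdir output directory, created if missing
#' @return invisibly, a list with the main in-memory results and the
#'   manifest
#' @export
run_full_pipeline <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[dosagenet] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  log_msg("reading inputs")
  counts <- stage("read", read_counts(config$paths$counts))
  samples <- stage("read", read_sample_sheet(config$paths$samples))
  annotation <- stage("read", read_annotation(config$paths$annotation))
  go_map <- stage("read", read_go_map(config$paths$go_map))
  indels <- stage("read", read_indels(config$paths$indels,
                                      zero_based = config$indels_zero_based))
  traits <- stage("read", read_traits(config$paths$traits))
  counts <- counts[, samples$library, drop = FALSE]
  design <- samples$genotype

  log_msg("preprocessing %d genes x %d libraries", nrow(counts), ncol(counts))
  pp <- stage("preprocess", preprocess_counts(counts, design,
                                              config$preprocess))
  log_msg("%d genes pass the expression filter", nrow(pp$counts))

  lines <- unique(samples$genotype)
  dosage <- stage("dosage",
                  compute_gene_dosage(annotation, indels, lines = lines))

  values <- pp$values
  coefficients <- pp$coefficients
  replacement_log <- NULL
  if (isTRUE(config$indel_normalize)) {
    log_msg("applying indel normalization")
    norm_lib <- stage("indel_normalize",
                      indel_normalize_expression(values, dosage,
                                                 line_of_column = design))
    values <- norm_lib$expression
    norm_coef <- stage("indel_normalize",
                       indel_normalize_expression(coefficients, dosage))
    coefficients <- norm_coef$expression
    replacement_log <- norm_coef$log
  }

  net_input <- if (config$network_input == "libraries") values else coefficients
  net_genotype <- if (config$network_input == "libraries") design
                  else colnames(coefficients)

  log_msg("building network (power %d, cut %.2f, merge %.2f)",
          config$network$soft_power, config$network$cut_height,
          config$network$merge_threshold)
  stab <- if (isTRUE(config$stability$run))
    stability_params(config$stability$subsample_fraction,
                     config$stability$n_iterations,
                     seed = config$seed)
  net <- stage("network", build_network(net_input, config$network,
                                        stability = stab))
  n_mod <- length(setdiff(unique(net$labels), "grey"))
  log_msg("%d modules detected (%d genes unassigned)",
          n_mod, sum(net$labels == "grey"))

  log_msg("integrating traits")
  trait_cor <- stage("integration", trait_correlation_table(traits,
                                                            config$alpha))
  mod_trait <- if (n_mod) stage("integration",
    module_trait_correlations(net$eigengenes, traits, net_genotype,
                              alpha = config$alpha))
  trait_names <- setdiff(colnames(traits), "genotype")
  gs <- sapply(trait_names, function(t)
    gene_significance(net_input,
                      stats::setNames(traits[[t]], traits$genotype),
                      net_genotype), simplify = TRUE)
  mm <- if (n_mod) module_membership(net_input, net$eigengenes)

  log_msg("GO overrepresentation")
  enr <- if (n_mod) stage("enrichment",
    module_go_enrichment(net$labels, go_map,
                         background = config$enrichment$background,
                         alpha = config$alpha))

  scans <- list()
  for (i in seq_along(config$dqtl_regions)) {
    r <- config$dqtl_regions[[i]]
    log_msg("dQTL scan %s:%d-%d", r$chromosome, r$start, r$end)
    k_ctrl <- if (is.null(r$k_controls)) 4L else r$k_controls
    scans[[i]] <- stage("dqtl", {
      groups <- assign_rds_groups(r, indels, lines = lines,
                                  k_controls = k_ctrl,
                                  seed = config$seed + i)
      dqtl_region_scan(r, coefficients, annotation, groups,
                       alpha = config$alpha)
    })
  }

  log_msg("writing outputs to %s", outdir)
  out <- function(name) file.path(outdir, name)
  utils::write.table(
    data.frame(library = colnames(pp$counts),
               library_size = unname(pp$library_sizes),
               norm_factor = unname(pp$norm_factors)),
    out("norm_factors.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(values, out("log2cpm.tsv"))
  write_matrix_tsv(coefficients, out("coefficients.tsv"))
  utils::write.table(
    data.frame(gene = names(net$labels), module = unname(net$labels)),
    out("module_labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (n_mod) write_matrix_tsv(net$eigengenes, out("eigengenes.tsv"),
                              id_col = "module")
  if (!is.null(net$stability))
    utils::write.table(
      data.frame(module = names(net$stability),
                 stability = unname(net$stability)),
      out("stability.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(trait_cor, out("trait_correlations.tsv"))
  if (!is.null(mod_trait)) write_tsv(mod_trait, out("module_trait.tsv"))
  write_matrix_tsv(gs, out("gene_significance.tsv"))
  if (!is.null(mm)) write_matrix_tsv(mm, out("module_membership.tsv"))
  if (!is.null(enr)) write_tsv(enr, out("enrichment.tsv"))
  if (!is.null(replacement_log))
    write_tsv(replacement_log, out("indel_replacements.tsv"))
  for (i in seq_along(scans)) {
    r <- config$dqtl_regions[[i]]
    write_tsv(scans[[i]],
              out(sprintf("dqtl_%s_%d_%d.tsv", r$chromosome, r$start, r$end)))
  }

  outputs <- list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)
  out_md5 <- tools::md5sum(outputs)
  names(out_md5) <- basename(outputs)
  in_md5 <- tools::md5sum(unlist(config$paths))
  names(in_md5) <- basename(unlist(config$paths))
  manifest <- list(
    package = "dosagenet",
    package_version = as.character(utils::packageVersion("dosagenet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    params = list(preprocess = config$preprocess,
                  network = config$network,
                  stability = config$stability,
                  enrichment = config$enrichment,
                  alpha = config$alpha,
                  indel_normalize = config$indel_normalize,
                  network_input = config$network_input,
                  dqtl_regions = config$dqtl_regions),
    inputs = as.list(in_md5),
    outputs = as.list(out_md5))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (f in c(outputs, out("manifest.json")))
    if (!file.size(f) > 0) stopf("declared output %s is empty", f)

  invisible(list(preprocess = pp, dosage = dosage, network = net,
                 trait_correlations = trait_cor,
                 module_trait = mod_trait, gs = gs, mm = mm,
                 enrichment = enr, dqtl = scans,
                 replacement_log = replacement_log, manifest = manifest))
}
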