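#' Pipeline configuration
#'
#' Collects every threshold and network parameter of the full analysis with
#' the defaults the pipeline is specified at: SAM FDR 0.1, association
#' q 0.1, nominal eQTL p 0.05, enrichment q 0.05, SNP QC at MAF >= 1%,
#' HWE p >= 0.05 and missingness <= 5%, expression filter >= 3 counts in
#' >= 80% of samples, +/- 1 Mb cis window, and a signed network with power
#' 12, minimum module size 10 and merge cut height 0.25. The resolved
#' configuration is serialized with every run for provenance.
#'
#' @param sam_fdr SAM FDR threshold.
#' @param assoc_q BH q threshold of the HbA1c scan.
#' @param nominal_p nominal eQTL p threshold.
#' @param enrich_q enrichment BH q threshold.
#' @param maf_min,hwe_p_min,missing_max SNP QC thresholds.
#' @param expr_min_count,expr_min_frac expression-filter parameters.
#' @param cis_window cis half-window in bp.
#' @param power soft-thresholding power.
#' @param min_module_size minimum module size.
#' @param merge_cut_height eigengene merge height.
#' @param n_perm SAM permutations.
#' @param seed root RNG seed.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(sam_fdr = 0.1, assoc_q = 0.1, nominal_p = 0.05,
                            enrich_q = 0.05, maf_min = 0.01,
                            hwe_p_min = 0.05, missing_max = 0.05,
                            expr_min_count = 3, expr_min_frac = 0.8,
                            cis_window = 1e6, power = 12,
                            min_module_size = 10, merge_cut_height = 0.25,
                            n_perm = 1000, seed = 1L) {
  cfg <- list(sam_fdr = sam_fdr, assoc_q = assoc_q, nominal_p = nominal_p,
              enrich_q = enrich_q, maf_min = maf_min,
              hwe_p_min = hwe_p_min, missing_max = missing_max,
              expr_min_count = expr_min_count,
              expr_min_frac = expr_min_frac, cis_window = cis_window,
              power = power, min_module_size = min_module_size,
              merge_cut_height = merge_cut_height, n_perm = n_perm,
              seed = as.integer(seed))
  probs <- c("sam_fdr", "assoc_q", "nominal_p", "enrich_q", "maf_min",
             "hwe_p_min", "missing_max", "expr_min_frac",
             "merge_cut_height")
  for (nm in probs)
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("invalid config: ", nm, " must lie in [0, 1]")
  if (cfg$maf_min > 0.5) stop("invalid config: maf_min must be <= 0.5")
  if (cfg$power < 1) stop("invalid config: power must be >= 1")
  if (cfg$min_module_size < 3)
    stop("invalid config: min_module_size must be >= 3")
  if (cfg$cis_window <= 0) stop("invalid config: cis_window must be > 0")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg a `pipeline_config`.
#' @param path YAML path.
#' @return the configuration (invisibly for write).
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(cfg)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full miRNA network pipeline
#'
#' Executes the eight analysis stages in order -- differential (SAM),
#' HbA1c association, intersection into Up-Pos / Down-Neg sets, target
#' mapping with the islet-expression filter, signed co-expression network
#' over the target genes, module over-representation, SNP QC + cis-eQTL
#' scan, and risk-catalogue overlap -- writing every intermediate table and
#' a JSON run manifest (resolved configuration, seed, row counts per stage)
#' to `outdir`. A failure in any stage aborts with the stage name and
#' cause.
#'
#' `inputs` is either the list returned by [simulate_dataset()] or a list
#' of file paths with elements `cohort`, `mirna_log2`, `mrna_log2`,
#' `mrna_counts`, `interactions`, `gene_sets`, `genotypes` (VCF),
#' `mirna_positions`, `risk_catalog`.
#'
#' @param inputs input tables or paths (see Details).
#' @param config a [pipeline_config()].
#' @param outdir run directory (created if needed).
#' @return list of stage results (`sam`, `assoc`, `regulated`, `expressed`,
#'   `target_map`, `network`, `enrichment`, `eqtl`, `overlap`,
#'   `manifest`), invisibly; tables and the manifest are written to
#'   `outdir`.
#' @export
run_full_pipeline <- function(inputs, config = pipeline_config(),
                              outdir = tempfile("glycomirnet_run_")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  load_in <- function(nm, loader) {
    x <- inputs[[nm]]
    if (is.null(x)) stop("configuration error: input '", nm, "' is missing")
    if (is.character(x) && length(x) == 1) loader(x) else x
  }

  cohort <- stage("inputs", load_in("cohort", read_cohort))
  mirna <- stage("inputs", load_in("mirna_log2",
                                   function(p) read_expression(p, "log2")))
  mrna_log2 <- stage("inputs", load_in("mrna_log2",
                                       function(p) read_expression(p, "log2")))
  mrna_counts <- stage("inputs",
                       load_in("mrna_counts",
                               function(p) read_expression(p, "counts")))
  interactions <- stage("inputs", load_in("interactions", read_interactions))
  gene_sets <- stage("inputs", load_in("gene_sets", read_gmt))
  genotypes <- stage("inputs", load_in("genotypes", read_vcf_dosages))
  positions <- stage("inputs",
                     load_in("mirna_positions",
                             function(p) utils::read.delim(p,
                               stringsAsFactors = FALSE)))
  catalog <- stage("inputs", load_in("risk_catalog", read_risk_catalog))

  counts <- list()

  # 1. differential expression: IGT/T2D vs NGT
  sam <- stage("differential", {
    group <- ifelse(cohort$glycemic_status == "NGT", "control", "case")
    sam_fdr(mirna, group, n_perm = config$n_perm, fdr = config$sam_fdr,
            seed = config$seed)
  })
  utils::write.table(sam$table, file.path(outdir, "differential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$differential <- nrow(sam$table)

  # 2. HbA1c association scan
  assoc <- stage("association",
                 hba1c_scan(mirna, cohort, q_threshold = config$assoc_q))
  utils::write.table(assoc$table, file.path(outdir, "association.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$association <- nrow(assoc$table)

  # 3. intersection into Up-Pos / Down-Neg
  regulated <- stage("intersection",
                     intersect_regulated(sam$up, sam$down, assoc$pos_set,
                                         assoc$neg_set))
  writeLines(regulated$up_pos, file.path(outdir, "up_pos.txt"))
  writeLines(regulated$down_neg, file.path(outdir, "down_neg.txt"))
  counts$intersection <- length(regulated$up_pos) +
    length(regulated$down_neg)

  # 4. target mapping with islet-expression filter
  expressed <- stage("targets",
                     filter_expressed_genes(mrna_counts,
                                            config$expr_min_count,
                                            config$expr_min_frac))
  tmap <- stage("targets", suppressWarnings(
    build_target_map(interactions,
                     c(regulated$up_pos, regulated$down_neg), expressed)))
  tmap_tab <- data.frame(
    mirna_id = rep(names(tmap$targets), lengths(tmap$targets)),
    gene_id = unlist(tmap$targets, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(tmap_tab, file.path(outdir, "target_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$targets <- nrow(tmap_tab)

  # 5. signed co-expression network over the target genes
  network <- stage("network", {
    genes <- intersect(unique(unlist(tmap$targets)), rownames(mrna_log2))
    if (length(genes) < config$min_module_size)
      stop("too few target genes expressed for network analysis")
    sub <- mrna_log2[genes, , drop = FALSE]
    sub <- sub[apply(sub, 1, stats::var) > 0, , drop = FALSE]
    adj <- signed_adjacency(sub, beta = config$power)
    diss <- 1 - tom_similarity(adj)
    part <- detect_modules(diss, min_module_size = config$min_module_size)
    merged <- if (any(part > 0))
      merge_modules(sub, part, config$merge_cut_height)
    else list(partition = part, eigengenes = NULL)
    traits <- data.frame(HbA1c = cohort$HbA1c,
                         diabetic_status = match(cohort$glycemic_status,
                                                 c("NGT", "IGT", "T2D")) - 1,
                         purity = if ("purity" %in% names(cohort))
                           cohort$purity else NA)
    mtc <- if (!is.null(merged$eigengenes))
      module_trait_correlation(merged$eigengenes, traits,
                               method_map = c(HbA1c = "pearson",
                                              diabetic_status = "spearman",
                                              purity = "spearman"))
    else NULL
    list(partition = merged$partition, eigengenes = merged$eigengenes,
         module_trait = mtc)
  })
  part_tab <- data.frame(gene_id = names(network$partition),
                         module = as.integer(network$partition),
                         stringsAsFactors = FALSE)
  utils::write.table(part_tab, file.path(outdir, "modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(network$eigengenes))
    write_expression(network$eigengenes, file.path(outdir, "eigengenes.tsv"))
  if (!is.null(network$module_trait))
    utils::write.table(network$module_trait,
                       file.path(outdir, "module_trait.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  counts$network <- sum(unique(network$partition) > 0)

  # 6. module over-representation
  enrich <- stage("enrichment", {
    labs <- sort(unique(network$partition[network$partition > 0]))
    res <- lapply(labs, function(l) {
      genes <- names(network$partition)[network$partition == l]
      tab <- suppressWarnings(
        ora_scan(genes, gene_sets, expressed, config$enrich_q))
      if (nrow(tab)) tab$module <- paste0("M", l)
      tab
    })
    do.call(rbind, res)
  })
  if (!is.null(enrich) && nrow(enrich))
    utils::write.table(enrich, file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  counts$enrichment <- if (is.null(enrich)) 0L else nrow(enrich)

  # 7. SNP QC + cis-eQTL scan on the regulated miRNAs
  eqtl <- stage("eqtl", {
    qc <- snp_qc(genotypes, config$maf_min, config$hwe_p_min,
                 config$missing_max)
    scan_mirnas <- c(regulated$up_pos, regulated$down_neg)
    pos <- positions[positions$mirna_id %in% scan_mirnas, , drop = FALSE]
    recs <- eqtl_scan(mirna, qc$genotypes, cohort, pos,
                      window = config$cis_window,
                      nominal_p = config$nominal_p)
    list(qc = qc$report, records = recs, genotypes = qc$genotypes)
  })
  utils::write.table(eqtl$qc, file.path(outdir, "snp_qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(eqtl$records, file.path(outdir, "eqtl.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$eqtl <- nrow(eqtl$records)

  # 8. risk-catalogue overlap
  overlap <- stage("overlap",
                   risk_overlap(eqtl$records, catalog, gt = eqtl$genotypes,
                                nominal_p = config$nominal_p))
  utils::write.table(overlap$overlaps, file.path(outdir, "risk_overlap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$overlap <- nrow(overlap$overlaps)

  manifest <- list(
    package = "glycomirnet",
    version = as.character(utils::packageVersion("glycomirnet")),
    config = unclass(config),
    seed = config$seed,
    sex_coding = "F=0, M=1",
    stages = names(counts),
    n_stages = length(counts),
    row_counts = counts
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_pipeline_config(config, file.path(outdir, "config.yaml"))

  invisible(list(sam = sam, assoc = assoc, regulated = regulated,
                 expressed = expressed, target_map = tmap,
                 network = network, enrichment = enrich, eqtl = eqtl,
                 overlap = overlap, manifest = manifest, outdir = outdir))
}
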