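#' Generate a synthetic donor cohort
#'
#' Donors are split across the three glycemic strata in the 7:6:5
#' (NGT:IGT:T2D) proportions of the emulated study and their HbA1c is drawn
#' within the stratum ranges (NGT < 6%, IGT 6.0--6.4%, T2D 6.2--7.0% with a
#' diagnosis flag), so the whole cohort spans 4.6--7%. Glycemic status is a
#' deterministic function of HbA1c and the diagnosis flag, which keeps the
#' simulated ground truth unambiguous. Covariates use plausible ranges:
#' age ~ U(30, 75), BMI ~ N(26, 4) truncated to (17, 45), sex ~ Bernoulli(0.5),
#' culture_days ~ U{1..9}, islet purity ~ U(40, 95)%.
#'
#' @param cfg a [sim_config()].
#' @return a `data.frame` with one row per donor: `donor_id`, `age`, `sex`
#'   ("F"/"M"), `BMI`, `HbA1c` (%), `glycemic_status` ("NGT"/"IGT"/"T2D"),
#'   `diagnosed_t2d`, `culture_days`, `purity` (%), `stimulatory_index`.
#' @export
generate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  n <- cfg$n_donors
  if (n < 6) stop("invalid config: n_donors must be >= 6")
  set.seed(sim_seed(cfg$seed, "cohort"))

  n_ngt <- max(2L, round(n * 7 / 18))
  n_t2d <- max(2L, round(n * 5 / 18))
  n_igt <- n - n_ngt - n_t2d
  if (n_igt < 2) stop("invalid config: n_donors too small to populate strata")

  hba1c <- c(runif(n_ngt, 4.6, 5.95), runif(n_igt, 6.0, 6.4),
             runif(n_t2d, 6.2, 7.0))
  diagnosed <- c(rep(FALSE, n_ngt + n_igt), rep(TRUE, n_t2d))
  status <- ifelse(hba1c < 6.0, "NGT", ifelse(diagnosed, "T2D", "IGT"))

  bmi <- rnorm(n, 26, 4)
  while (any(bad <- bmi <= 17 | bmi >= 45)) bmi[bad] <- rnorm(sum(bad), 26, 4)

  data.frame(
    donor_id = sprintf("D%03d", seq_len(n)),
    age = round(runif(n, 30, 75), 1),
    sex = c("F", "M")[rbinom(n, 1, 0.5) + 1],
    BMI = round(bmi, 1),
    HbA1c = round(hba1c, 2),
    glycemic_status = status,
    diagnosed_t2d = diagnosed,
    culture_days = sample(1:9, n, replace = TRUE),
    purity = round(runif(n, 40, 95), 1),
    stimulatory_index = round(exp(rnorm(n, log(2), 0.5)), 2),
    stringsAsFactors = FALSE
  )
}

#' Generate a miRNA log2-expression matrix with planted effects
#'
#' log2 expression of each miRNA is
#' `baseline + dir * group_shift_sd * noise_sd * I(case) +
#'  dir * hba1c_beta * (HbA1c - mean) + small covariate effects + N(0, noise_sd)`
#' where `dir` is +1 for planted Up-Pos miRNAs (upregulated in IGT/T2D and
#' positively sloped on HbA1c), -1 for planted Down-Neg miRNAs, and 0
#' otherwise. Nuisance covariate effects (age, BMI, sex) are drawn per
#' feature with SD `0.2 * noise_sd`, so they vanish in the noiseless limit.
#'
#' @param cfg a [sim_config()].
#' @param cohort a cohort from [generate_cohort()].
#' @return list with `expr` (miRNA x donor log2 matrix, `scale` attribute
#'   `"log2"`) and `truth` (list with `up_pos_ids`, `down_neg_ids`,
#'   `mirna_ids`).
#' @export
generate_mirna_expression <- function(cfg, cohort) {
  validate_sim_config(cfg)
  if (cfg$noise_sd <= 0) stop("invalid config: noise_sd must be > 0")
  stopifnot(nrow(cohort) == cfg$n_donors)
  set.seed(sim_seed(cfg$seed, "mirna"))

  m <- cfg$n_mirnas
  n <- cfg$n_donors
  ids <- sprintf("miR-sim-%04d", seq_len(m))
  planted <- sample(ids, cfg$n_up_pos + cfg$n_down_neg)
  up <- sort(planted[seq_len(cfg$n_up_pos)])
  down <- sort(planted[cfg$n_up_pos + seq_len(cfg$n_down_neg)])
  dir <- setNames(numeric(m), ids)
  dir[up] <- 1
  dir[down] <- -1

  case <- as.numeric(cohort$glycemic_status != "NGT")
  hc <- cohort$HbA1c - mean(cohort$HbA1c)
  zage <- as.numeric(scale(cohort$age))
  zbmi <- as.numeric(scale(cohort$BMI))
  sexn <- as.numeric(cohort$sex == "M")

  baseline <- runif(m, 4, 14)
  b_age <- rnorm(m, 0, 0.2 * cfg$noise_sd)
  b_bmi <- rnorm(m, 0, 0.2 * cfg$noise_sd)
  b_sex <- rnorm(m, 0, 0.2 * cfg$noise_sd)
  shift <- cfg$group_shift_sd * cfg$noise_sd

  expr <- baseline +
    outer(dir * shift, case) +
    outer(dir * cfg$hba1c_beta, hc) +
    outer(b_age, zage) + outer(b_bmi, zbmi) + outer(b_sex, sexn) +
    matrix(rnorm(m * n, 0, cfg$noise_sd), m, n)
  dimnames(expr) <- list(ids, cohort$donor_id)
  attr(expr, "scale") <- "log2"

  list(expr = expr,
       truth = list(up_pos_ids = up, down_neg_ids = down, mirna_ids = ids))
}

#' Generate an mRNA panel with planted co-expression modules
#'
#' Each module `m` has a latent per-sample factor correlated
#' `module_trait_cor[m]` with the designated phenotypic trait; member genes
#' load on it as `loading * factor + sqrt(1 - loading^2) * noise`, scaled to
#' unit log2 SD, on top of a gene baseline. Background genes are pure noise.
#' A counts-scale matrix (`round(2^log2)`, floored at 0) is emitted alongside
#' so the expression filter operates on the scale it is defined on.
#'
#' @param cfg a [sim_config()].
#' @param cohort cohort from [generate_cohort()].
#' @param trait cohort column the module factors are coupled to.
#' @return list with `log2` and `counts` matrices (gene x donor) and `truth`
#'   (list with `module_assignment` -- named integer vector, 0 = background
#'   -- `factors` (module x donor matrix) and `trait`).
#' @export
generate_mrna_modules <- function(cfg, cohort, trait = "purity") {
  validate_sim_config(cfg)
  if (any(cfg$module_sizes < 3)) stop("invalid config: module size < 3")
  if (length(cfg$module_sizes) == 0) stop("invalid config: no module sizes")
  stopifnot(trait %in% names(cohort))
  set.seed(sim_seed(cfg$seed, "mrna"))

  n <- nrow(cohort)
  ng <- cfg$n_genes
  sizes <- cfg$module_sizes
  nm <- length(sizes)
  ids <- sprintf("GENE%05d", seq_len(ng))
  assignment <- setNames(rep(0L, ng), ids)
  assignment[seq_len(sum(sizes))] <- rep(seq_len(nm), sizes)

  tvec <- as.numeric(scale(cohort[[trait]]))
  factors <- matrix(0, nm, n, dimnames = list(paste0("M", seq_len(nm)),
                                              cohort$donor_id))
  for (k in seq_len(nm)) {
    r <- cfg$module_trait_cor[k]
    factors[k, ] <- r * tvec + sqrt(1 - r^2) * rnorm(n)
  }

  loading <- cfg$module_loading
  resid_sd <- sqrt(1 - loading^2)
  baseline <- runif(ng, 3, 12)
  log2m <- matrix(rnorm(ng * n), ng, n, dimnames = list(ids, cohort$donor_id))
  for (g in seq_len(ng)) {
    k <- assignment[g]
    if (k > 0) log2m[g, ] <- loading * factors[k, ] + resid_sd * log2m[g, ]
  }
  log2m <- baseline + log2m
  counts <- pmax(round(2^log2m), 0)
  attr(log2m, "scale") <- "log2"
  attr(counts, "scale") <- "counts"

  list(log2 = log2m, counts = counts,
       truth = list(module_assignment = assignment, factors = factors,
                    trait = trait))
}

#' Generate a validated-target interaction table with planted structure
#'
#' Planted (Up-Pos then Down-Neg) miRNAs are assigned to planted modules
#' round-robin and target each gene of their module independently with
#' probability `density`. Decoy rows pair random miRNAs with background
#' genes so that, in expectation, a fraction `decoy_fraction` of all rows
#' references background genes. Many-to-many targeting arises naturally:
#' miRNAs sharing a module share targets.
#'
#' @param cfg a [sim_config()].
#' @param truth combined ground truth holding `up_pos_ids`, `down_neg_ids`,
#'   `mirna_ids` and `module_assignment`.
#' @param density per-gene targeting probability in (0, 1].
#' @param decoy_fraction expected fraction of rows referencing background
#'   genes, in \[0, 1).
#' @return list with `interactions` (data.frame `mirna_id`, `gene_id`,
#'   `source_db`, `evidence_type`) and `target_map_true` (list miRNA ->
#'   character vector of planted targets).
#' @export
generate_interactions <- function(cfg, truth, density = 0.8,
                                  decoy_fraction = 0.3) {
  if (density <= 0 || density > 1)
    stop("invalid config: density must lie in (0, 1]")
  if (decoy_fraction < 0 || decoy_fraction >= 1)
    stop("invalid config: decoy_fraction must lie in [0, 1)")
  set.seed(sim_seed(cfg$seed, "interactions"))

  planted <- c(truth$up_pos_ids, truth$down_neg_ids)
  assignment <- truth$module_assignment
  nm <- max(assignment)
  if (nm < 1) stop("invalid input: no planted modules in truth")
  genes_of <- split(names(assignment)[assignment > 0],
                    assignment[assignment > 0])

  rows <- list()
  target_map_true <- list()
  for (i in seq_along(planted)) {
    mod <- ((i - 1) %% nm) + 1
    g <- genes_of[[mod]]
    keep <- if (density >= 1) rep(TRUE, length(g)) else
      runif(length(g)) < density
    tg <- g[keep]
    target_map_true[[planted[i]]] <- tg
    if (length(tg))
      rows[[length(rows) + 1]] <- data.frame(mirna_id = planted[i],
                                             gene_id = tg,
                                             stringsAsFactors = FALSE)
  }
  planted_tab <- do.call(rbind, rows)

  background <- names(assignment)[assignment == 0]
  n_decoy <- if (decoy_fraction > 0 && length(background) > 0)
    round(decoy_fraction / (1 - decoy_fraction) * nrow(planted_tab)) else 0L
  if (n_decoy > 0) {
    decoy_tab <- unique(data.frame(
      mirna_id = sample(truth$mirna_ids, n_decoy, replace = TRUE),
      gene_id = sample(background, n_decoy, replace = TRUE),
      stringsAsFactors = FALSE
    ))
    tab <- rbind(planted_tab, decoy_tab)
  } else tab <- planted_tab

  tab <- unique(tab)
  tab$source_db <- "synthdb"
  tab$evidence_type <- "synthetic"
  rownames(tab) <- NULL
  list(interactions = tab, target_map_true = target_map_true)
}

#' Deterministic genomic positions for simulated miRNAs
#'
#' miRNAs are laid out round-robin over `n_chrom` chromosomes, 3 Mb apart,
#' so that +/- 1 Mb cis windows of consecutive miRNAs on the same chromosome
#' do not overlap.
#'
#' @param mirna_ids character vector of miRNA identifiers.
#' @param n_chrom number of chromosomes to spread miRNAs over.
#' @param spacing distance (bp) between consecutive miRNA starts on a
#'   chromosome.
#' @return data.frame `mirna_id`, `chrom`, `start` (1-based bp).
#' @export
simulate_mirna_positions <- function(mirna_ids, n_chrom = 4L,
                                     spacing = 3e6) {
  i <- seq_along(mirna_ids)
  data.frame(
    mirna_id = mirna_ids,
    chrom = paste0("chr", ((i - 1) %% n_chrom) + 1),
    start = 5e6 + ((i - 1) %/% n_chrom) * spacing,
    stringsAsFactors = FALSE
  )
}

#' Generate genotypes with planted cis-eQTL effects
#'
#' Dosages are Binomial(2, MAF) per SNP with MAF ~ U(`maf_range`). Planted
#' eQTL SNPs are placed uniformly inside the +/- `cis_span` window of their
#' miRNA's start, and, when an expression matrix is supplied, the per-allele
#' effect `eqtl_beta` is added to that miRNA's log2 expression. Remaining
#' SNPs are scattered over the same chromosomes.
#'
#' @param cfg a [sim_config()].
#' @param cohort cohort from [generate_cohort()].
#' @param mirna_positions data.frame from [simulate_mirna_positions()].
#' @param expr optional miRNA log2 matrix to add planted effects to.
#' @param eqtl_mirnas miRNAs to plant eQTLs for (default: the first
#'   `cfg$n_eqtls` rows of `mirna_positions`).
#' @param missing_rate fraction of dosage entries set missing at random.
#' @return list with `genotypes` (a `genotype_data` list: `snp_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `dosage` SNP x donor matrix), `expr` (updated
#'   matrix, or NULL) and `truth` (data.frame `eqtl_pairs`: `snp_id`,
#'   `mirna_id`, `beta`).
#' @export
generate_genotypes <- function(cfg, cohort, mirna_positions, expr = NULL,
                               eqtl_mirnas = NULL, missing_rate = 0) {
  validate_sim_config(cfg)
  n <- nrow(cohort)
  if (n != cfg$n_donors) stop("dimension error: cohort does not match config")
  if (!is.null(expr) && ncol(expr) != n)
    stop("dimension error: expression columns do not match cohort")
  set.seed(sim_seed(cfg$seed, "genotypes"))

  if (is.null(eqtl_mirnas))
    eqtl_mirnas <- head(mirna_positions$mirna_id, cfg$n_eqtls)
  eqtl_mirnas <- eqtl_mirnas[eqtl_mirnas %in% mirna_positions$mirna_id]
  k <- min(length(eqtl_mirnas), cfg$n_snps)
  eqtl_mirnas <- eqtl_mirnas[seq_len(k)]

  pos_of <- mirna_positions[match(eqtl_mirnas, mirna_positions$mirna_id), ]
  planted_pos <- pmax(1, round(pos_of$start +
                                 runif(k, -cfg$cis_span, cfg$cis_span)))
  planted_chrom <- pos_of$chrom

  n_rest <- cfg$n_snps - k
  chroms <- unique(mirna_positions$chrom)
  span_max <- max(mirna_positions$start) + cfg$cis_span
  rest_chrom <- sample(chroms, n_rest, replace = TRUE)
  rest_pos <- round(runif(n_rest, 1, span_max))

  snp_id <- sprintf("rs%06d", seq_len(cfg$n_snps))
  chrom <- c(planted_chrom, rest_chrom)
  pos <- c(planted_pos, rest_pos)
  maf <- runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
  dosage <- matrix(rbinom(cfg$n_snps * n, 2, rep(maf, n)), cfg$n_snps, n,
                   dimnames = list(snp_id, cohort$donor_id))
  if (missing_rate > 0)
    dosage[runif(length(dosage)) < missing_rate] <- NA_integer_

  if (!is.null(expr)) {
    for (i in seq_len(k)) {
      d <- dosage[i, ]
      d[is.na(d)] <- mean(d, na.rm = TRUE)
      expr[eqtl_mirnas[i], ] <- expr[eqtl_mirnas[i], ] + cfg$eqtl_beta * d
    }
  }

  gt <- list(snp_id = snp_id, chrom = chrom, pos = pos,
             ref = rep("A", cfg$n_snps), alt = rep("G", cfg$n_snps),
             dosage = dosage)
  class(gt) <- "genotype_data"
  truth <- data.frame(snp_id = snp_id[seq_len(k)], mirna_id = eqtl_mirnas,
                      beta = rep(cfg$eqtl_beta, k), stringsAsFactors = FALSE)
  list(genotypes = gt, expr = expr, truth = list(eqtl_pairs = truth))
}

#' Generate a synthetic risk-SNP catalogue
#'
#' Emulates a compiled catalogue of disease-risk and insulin-secretion
#' variants: a configurable fraction of the planted eQTL SNPs is included
#' (so downstream overlap has known truth) together with background SNPs
#' drawn from the non-planted genotyped variants. Trait classes are assigned
#' at random between "T2D" and "insulin_secretion".
#'
#' @param cfg a [sim_config()].
#' @param genotypes a `genotype_data` object.
#' @param truth list holding `eqtl_pairs` (from [generate_genotypes()]).
#' @param planted_fraction fraction of planted eQTL SNPs included.
#' @param n_background number of non-planted SNPs included.
#' @return data.frame `rsid`, `chrom`, `pos`, `trait_class`, `source`.
#' @export
generate_risk_catalog <- function(cfg, genotypes, truth,
                                  planted_fraction = 1, n_background = 20) {
  if (length(genotypes$snp_id) == 0)
    stop("invalid input: empty genotype set")
  set.seed(sim_seed(cfg$seed, "risk_catalog"))

  planted <- truth$eqtl_pairs$snp_id
  n_keep <- round(planted_fraction * length(planted))
  keep <- if (n_keep > 0) planted[seq_len(n_keep)] else character(0)
  pool <- setdiff(genotypes$snp_id, planted)
  bg <- sample(pool, min(n_background, length(pool)))
  ids <- c(keep, bg)
  idx <- match(ids, genotypes$snp_id)
  if (length(ids) == 0) {
    return(data.frame(rsid = character(0), chrom = character(0),
                      pos = numeric(0), trait_class = character(0),
                      source = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    rsid = ids,
    chrom = genotypes$chrom[idx],
    pos = genotypes$pos[idx],
    trait_class = sample(c("T2D", "insulin_secretion"), length(ids),
                         replace = TRUE),
    source = "synthetic_gwas",
    stringsAsFactors = FALSE
  )
}

#' Generate gene-set collections aligned with planted modules
#'
#' One gene set per planted module (its exact member genes) plus random
#' background sets, so over-representation analysis has known positives.
#'
#' @param cfg a [sim_config()].
#' @param truth list holding `module_assignment`.
#' @param n_random number of random decoy sets.
#' @param random_size_range size range of random sets.
#' @return named list of gene sets; each element is
#'   `list(name, description, genes)`.
#' @export
generate_gene_sets <- function(cfg, truth, n_random = 20,
                               random_size_range = c(10, 50)) {
  set.seed(sim_seed(cfg$seed, "gene_sets"))
  assignment <- truth$module_assignment
  all_genes <- names(assignment)
  sets <- list()
  for (k in seq_len(max(assignment))) {
    nm <- sprintf("MODULE_SET_%d", k)
    sets[[nm]] <- list(name = nm, description = "planted module",
                       genes = names(assignment)[assignment == k])
  }
  for (j in seq_len(n_random)) {
    nm <- sprintf("RANDOM_SET_%02d", j)
    sz <- sample(random_size_range[1]:random_size_range[2], 1)
    sets[[nm]] <- list(name = nm, description = "random set",
                       genes = sample(all_genes, sz))
  }
  sets
}

#' Simulate a complete synthetic study
#'
#' Runs every generator off one configuration: cohort, miRNA expression with
#' planted Up-Pos/Down-Neg effects, mRNA panel with planted modules,
#' miRNA-target interactions, genotypes with planted cis-eQTLs (added to the
#' miRNA expression), a risk-SNP catalogue, and gene sets. Optionally writes
#' every table to `outdir` in its interchange format (TSV / GMT / VCF /
#' JSON ground truth).
#'
#' @param cfg a [sim_config()].
#' @param outdir optional directory to write the dataset to.
#' @param ... passed on to [generate_interactions()] /
#'   [generate_risk_catalog()] via named arguments `density`,
#'   `decoy_fraction`, `planted_fraction`.
#' @return list with `cohort`, `mirna_log2`, `mrna_log2`, `mrna_counts`,
#'   `interactions`, `gene_sets`, `genotypes`, `mirna_positions`,
#'   `risk_catalog`, `truth`, `config`.
#' @export
simulate_dataset <- function(cfg = sim_config(), outdir = NULL,
                             density = 0.8, decoy_fraction = 0.3,
                             planted_fraction = 1) {
  cohort <- generate_cohort(cfg)
  mi <- generate_mirna_expression(cfg, cohort)
  mr <- generate_mrna_modules(cfg, cohort)
  truth <- c(mi$truth, mr$truth)
  inter <- generate_interactions(cfg, truth, density = density,
                                 decoy_fraction = decoy_fraction)
  pos <- simulate_mirna_positions(mi$truth$mirna_ids)
  geno <- generate_genotypes(cfg, cohort, pos, expr = mi$expr,
                             eqtl_mirnas = c(mi$truth$up_pos_ids,
                                             mi$truth$down_neg_ids))
  catalog <- generate_risk_catalog(cfg, geno$genotypes, geno$truth,
                                   planted_fraction = planted_fraction)
  sets <- generate_gene_sets(cfg, truth)
  truth <- c(truth, inter["target_map_true"], geno$truth)

  out <- list(cohort = cohort, mirna_log2 = geno$expr, mrna_log2 = mr$log2,
              mrna_counts = mr$counts, interactions = inter$interactions,
              gene_sets = sets, genotypes = geno$genotypes,
              mirna_positions = pos, risk_catalog = catalog, truth = truth,
              config = cfg)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(outdir, "cohort.tsv"))
    write_expression(geno$expr, file.path(outdir, "mirna_log2.tsv"))
    write_expression(mr$log2, file.path(outdir, "mrna_log2.tsv"))
    write_expression(mr$counts, file.path(outdir, "mrna_counts.tsv"))
    write_interactions(inter$interactions,
                       file.path(outdir, "interactions.tsv"))
    write_gmt(sets, file.path(outdir, "gene_sets.gmt"))
    write_vcf(geno$genotypes, file.path(outdir, "genotypes.vcf"))
    write_risk_catalog(catalog, file.path(outdir, "risk_catalog.tsv"))
    utils::write.table(pos, file.path(outdir, "mirna_positions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(up_pos_ids = truth$up_pos_ids,
           down_neg_ids = truth$down_neg_ids,
           module_assignment = as.list(truth$module_assignment),
           target_map_true = truth$target_map_true,
           eqtl_pairs = truth$eqtl_pairs),
      file.path(outdir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
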