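test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_donors = 0), "n_donors")
  expect_error(sim_config(n_mirnas = 20, n_up_pos = 15, n_down_neg = 10),
               "exceeds n_mirnas")
  expect_error(sim_config(n_genes = 50, module_sizes = c(30, 30)),
               "module_sizes")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
})

test_that("generated cohort matches the study design", {
  cfg <- sim_config(seed = 11)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 18)
  expect_false(anyNA(co))
  expect_true(all(co$HbA1c >= 4.6 & co$HbA1c <= 7.0))
  expect_setequal(unique(co$glycemic_status), c("NGT", "IGT", "T2D"))
  # status labels are the documented deterministic function of HbA1c
  expect_true(all(co$HbA1c[co$glycemic_status == "NGT"] < 6.0))
  expect_true(all(co$HbA1c[co$glycemic_status == "IGT"] >= 6.0 &
                    co$HbA1c[co$glycemic_status == "IGT"] <= 6.4))
  expect_true(all(co$HbA1c[co$glycemic_status == "T2D"] >= 6.2 &
                    co$diagnosed_t2d[co$glycemic_status == "T2D"]))
  # determinism under a fixed seed
  expect_identical(co, generate_cohort(cfg))
  expect_error(generate_cohort(sim_config(n_donors = 6)), NA)
})

test_that("planted miRNA effects have the configured structure", {
  cfg <- sim_config(seed = 5, n_mirnas = 100)
  co <- generate_cohort(cfg)
  mi <- generate_mirna_expression(cfg, co)
  expect_length(mi$truth$up_pos_ids, 9)
  expect_length(mi$truth$down_neg_ids, 22)
  expect_true(all(c(mi$truth$up_pos_ids, mi$truth$down_neg_ids) %in%
                    rownames(mi$expr)))
  expect_identical(dim(mi$expr), c(100L, 18L))

  # noiseless limit: a planted Up-Pos miRNA is an exact affine function of
  # HbA1c, so its sample correlation with HbA1c is 1
  cfg0 <- sim_config(seed = 5, n_mirnas = 50, noise_sd = 1e-9,
                     hba1c_beta = 1, group_shift_sd = 0)
  co0 <- generate_cohort(cfg0)
  mi0 <- generate_mirna_expression(cfg0, co0)
  up1 <- mi0$truth$up_pos_ids[1]
  expect_equal(cor(mi0$expr[up1, ], co0$HbA1c), 1, tolerance = 1e-6)

  expect_error(generate_mirna_expression(sim_config(noise_sd = 0), co),
               "noise_sd")
})

test_that("null generator is calibrated: ~1% two-sample t rejections at alpha 0.01", {
  rates <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s, n_mirnas = 200, group_shift_sd = 0,
                      hba1c_beta = 0)
    co <- generate_cohort(cfg)
    mi <- generate_mirna_expression(cfg, co)
    case <- co$glycemic_status != "NGT"
    p <- apply(mi$expr, 1, function(v)
      t.test(v[case], v[!case], var.equal = TRUE)$p.value)
    mean(p < 0.01)
  }, numeric(1))
  # 20 x 200 = 4000 features; binomial 99% interval around 0.01
  expect_gt(mean(rates), 0.01 - 2.58 * sqrt(0.01 * 0.99 / 4000))
  expect_lt(mean(rates), 0.01 + 2.58 * sqrt(0.01 * 0.99 / 4000))
})

test_that("planted mRNA modules couple to the designated trait", {
  cfg <- sim_config(seed = 2, n_donors = 60, n_genes = 100,
                    module_sizes = c(20, 20, 20), module_trait_cor = 0.9,
                    module_loading = 0.95)
  co <- generate_cohort(cfg)
  mr <- generate_mrna_modules(cfg, co)
  expect_equal(sum(mr$truth$module_assignment == 0), 40)
  for (k in 1:3) {
    r <- cor(mr$truth$factors[k, ], co$purity)
    expect_true(r >= 0.8 && r <= 1.0)
  }
  expect_identical(attr(mr$counts, "scale"), "counts")
  expect_true(all(mr$counts >= 0))
  expect_equal(mr$counts, pmax(round(2^mr$log2), 0), ignore_attr = TRUE)
  expect_error(generate_mrna_modules(sim_config(module_sizes = c(2, 10)), co),
               "module size")
})

test_that("zero loading makes member genes indistinguishable from noise", {
  cors <- vapply(1:20, function(s) {
    # n = 120 samples so the null expectation E|r| ~ 0.8/sqrt(n) sits
    # well below the 0.1 bound
    cfg <- sim_config(seed = s, n_donors = 120, n_genes = 40,
                      module_sizes = c(20L), module_loading = 0,
                      module_trait_cor = 0.9, n_mirnas = 40)
    co <- generate_cohort(cfg)
    mr <- generate_mrna_modules(cfg, co)
    genes <- names(mr$truth$module_assignment)[mr$truth$module_assignment == 1]
    cm <- cor(t(mr$log2[genes, ]))
    mean(abs(cm[upper.tri(cm)]))
  }, numeric(1))
  expect_lt(mean(cors), 0.1)
})

test_that("interaction generator plants targets with the stated density", {
  cfg <- sim_config(seed = 3, n_mirnas = 50, n_genes = 100,
                    module_sizes = c(50L), n_up_pos = 1, n_down_neg = 0)
  co <- generate_cohort(cfg)
  mi <- generate_mirna_expression(cfg, co)
  mr <- generate_mrna_modules(cfg, co)
  truth <- c(mi$truth, mr$truth)
  # density 1, one planted miRNA, one 50-gene module, no decoys
  it <- generate_interactions(cfg, truth, density = 1, decoy_fraction = 0)
  planted <- mi$truth$up_pos_ids
  expect_setequal(it$interactions$gene_id[it$interactions$mirna_id == planted],
                  names(truth$module_assignment)[truth$module_assignment == 1])
  # identical target lists downstream: two miRNAs on the same module
  cfg2 <- sim_config(seed = 3, n_mirnas = 50, n_genes = 100,
                     module_sizes = c(50L), n_up_pos = 2, n_down_neg = 0)
  mi2 <- generate_mirna_expression(cfg2, co)
  it2 <- generate_interactions(cfg2, c(mi2$truth, mr$truth), density = 1,
                               decoy_fraction = 0)
  tm <- build_target_map(it2$interactions, mi2$truth$up_pos_ids)
  expect_equal(jaccard_distance(tm$targets[[1]], tm$targets[[2]]), 0)
  expect_error(generate_interactions(cfg, truth, density = 0), "density")
  expect_error(generate_interactions(cfg, truth, density = 1.2), "density")
})

test_that("decoy fraction controls the share of background-gene rows", {
  fr <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s, n_mirnas = 60, n_genes = 200,
                      module_sizes = c(40L, 40L), n_up_pos = 4,
                      n_down_neg = 4)
    co <- generate_cohort(cfg)
    mi <- generate_mirna_expression(cfg, co)
    mr <- generate_mrna_modules(cfg, co)
    it <- generate_interactions(cfg, c(mi$truth, mr$truth),
                                density = 0.9, decoy_fraction = 0.5)
    bg <- names(mr$truth$module_assignment)[mr$truth$module_assignment == 0]
    mean(it$interactions$gene_id %in% bg)
  }, numeric(1))
  n_rows <- 20 * 600  # approximate pooled row count for the interval
  expect_gt(mean(fr), 0.5 - 2.58 * sqrt(0.25 / n_rows) - 0.02)
  expect_lt(mean(fr), 0.5 + 2.58 * sqrt(0.25 / n_rows) + 0.02)
})

test_that("genotype generator plants dosages and cis-eQTL effects", {
  cfg <- sim_config(seed = 4, n_donors = 400, n_mirnas = 20, n_up_pos = 2,
                    n_down_neg = 2, n_snps = 30, n_eqtls = 5,
                    maf_range = c(0.5, 0.5))
  co <- generate_cohort(cfg)
  pos <- simulate_mirna_positions(sprintf("miR-sim-%04d", 1:20))
  ge <- generate_genotypes(cfg, co, pos)
  # MAF 0.5 -> mean dosage 1 within 3 SE
  se <- sqrt(0.5 / (400 * 30))
  expect_lt(abs(mean(ge$genotypes$dosage) - 1), 3 * se)
  # planted SNPs inside the cis window of their miRNA
  tp <- ge$truth$eqtl_pairs
  idx <- match(tp$snp_id, ge$genotypes$snp_id)
  midx <- match(tp$mirna_id, pos$mirna_id)
  expect_true(all(ge$genotypes$chrom[idx] == pos$chrom[midx]))
  expect_true(all(abs(ge$genotypes$pos[idx] - pos$start[midx]) <=
                    cfg$cis_span))
  expect_true(all(ge$genotypes$pos >= 1))
  expect_error(generate_genotypes(cfg, co[1:10, ], pos), "dimension")
})

test_that("planted eQTL effect is exactly recoverable in the noiseless limit", {
  cfg <- sim_config(seed = 8, n_donors = 50, n_mirnas = 10, n_up_pos = 1,
                    n_down_neg = 1, noise_sd = 1e-9, hba1c_beta = 0,
                    group_shift_sd = 0, n_snps = 10, n_eqtls = 3,
                    eqtl_beta = 1)
  co <- generate_cohort(cfg)
  mi <- generate_mirna_expression(cfg, co)
  pos <- simulate_mirna_positions(mi$truth$mirna_ids)
  ge <- generate_genotypes(cfg, co, pos, expr = mi$expr)
  pair <- ge$truth$eqtl_pairs[1, ]
  y <- ge$expr[pair$mirna_id, ]
  d <- ge$genotypes$dosage[pair$snp_id, ]
  slope <- coef(lm(y ~ d))[2]
  expect_equal(unname(slope), 1, tolerance = 1e-6)
})

test_that("risk catalogue covers planted eQTL SNPs per the fraction", {
  cfg <- sim_config(seed = 6, n_mirnas = 30, n_up_pos = 3, n_down_neg = 3,
                    n_snps = 40, n_eqtls = 6)
  co <- generate_cohort(cfg)
  pos <- simulate_mirna_positions(sprintf("miR-sim-%04d", 1:30))
  ge <- generate_genotypes(cfg, co, pos)
  cat1 <- generate_risk_catalog(cfg, ge$genotypes, ge$truth,
                                planted_fraction = 1)
  expect_true(all(ge$truth$eqtl_pairs$snp_id %in% cat1$rsid))
  cat0 <- generate_risk_catalog(cfg, ge$genotypes, ge$truth,
                                planted_fraction = 0)
  expect_false(any(ge$truth$eqtl_pairs$snp_id %in% cat0$rsid))
  expect_named(cat1, c("rsid", "chrom", "pos", "trait_class", "source"))
  expect_true(all(cat1$trait_class %in% c("T2D", "insulin_secretion")))
  empty <- ge$genotypes; empty$snp_id <- character(0)
  expect_error(generate_risk_catalog(cfg, empty, ge$truth), "empty")
})

test_that("the full simulated dataset is byte-identical under one seed", {
  cfg <- sim_config(seed = 42, n_mirnas = 40, n_genes = 80,
                    module_sizes = c(20L, 20L), n_up_pos = 3, n_down_neg = 3,
                    n_snps = 20, n_eqtls = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, outdir = d1)
  simulate_dataset(cfg, outdir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
})
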