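# glycomirnet

Glycemia-associated miRNA regulatory network analysis for human pancreatic
islets.

Islets from organ donors spanning normal glucose tolerance (NGT,
HbA1c < 6%), impaired glucose tolerance (IGT, 6.0–6.4%) and type 2
diabetes (T2D, ≥ 6.2% with diagnosis) differ in their microRNA
complement, and the affected miRNAs repress genes involved in insulin and
glucagon secretion. `glycomirnet` is a tested, reusable implementation of
the full analysis chain that links islet miRNAs to glycemic phenotype and
disease genetics, for analysts working with small donor cohorts
(n ≈ 18 for miRNA profiling, n ≈ 180 for transcriptomes):

1. **SAM differential expression** (IGT/T2D vs NGT):
   d = (x̄₁ − x̄₂)/(s + s₀) with permutation-estimated FDR
   (balanced label permutations, π₀-adjusted median false calls).
2. **HbA1c association scan**: per-miRNA OLS of log2 expression on HbA1c
   adjusted for age, BMI, sex, glycemic status and culture days, with
   Benjamini–Hochberg q-values.
3. **Intersection** into the concordant *Up-Pos* (up and positively
   correlated) and *Down-Neg* (down and negatively correlated) miRNA sets.
4. **Validated-target maps**: islet-expression filter (≥ 3 normalized
   counts in ≥ 80% of samples), Jaccard-distance miRNA clustering,
   random-miRNA-set targeting null, and reference-gene overlap.
5. **Signed co-expression network** over the target genes:
   a = ((1 + cor)/2)^β with β = 12, topological overlap
   TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i, k_j) + 1 − a_ij),
   deterministic tree-cut modules (minModuleSize 10), eigengenes (first
   principal components), eigengene merging at height 0.25, and
   Pearson/Spearman module–trait correlation.
6. **Hypergeometric over-representation** of modules against gene sets
   (GMT), BH-adjusted.
7. **cis-eQTL mapping**: SNP QC (call rate ≥ 95%, MAF ≥ 1%,
   HWE p ≥ 0.05), ±1 Mb windows around miRNA starts, dosage + covariate
   OLS, per-miRNA BH, and overlap of nominal (p < 0.05) eQTLs with a
   T2D / insulin-secretion risk-SNP catalogue.

A synthetic-data generator (`simulate_dataset()`) plants every effect the
pipeline is supposed to recover — group shifts, HbA1c slopes,
co-expression modules coupled to traits, miRNA→module targeting, cis-eQTLs
— so each stage is validated against known ground truth. The methods
vignette (`vignettes/methods.Rmd`) documents every model, default and
design decision.

## Worked example

Simulate a study at the emulated design (18 donors, 470 miRNAs, 9 planted
Up-Pos and 22 planted Down-Neg miRNAs, 5 planted gene modules, planted
cis-eQTLs) and run all eight stages:

```r
library(glycomirnet)

cfg <- sim_config(seed = 1)           # 18 donors, 470 miRNAs, 9 + 22 planted
sim <- simulate_dataset(cfg)
res <- run_full_pipeline(sim, pipeline_config(n_perm = 500, seed = 1),
                         outdir = tempdir())

print(res$sam)
#> SAM permutation analysis
#>   features: 470   s0: 0.06289   permutations: 500 (sampled)
#>   at FDR < 0.1 : 9 up, 23 down
print(res$assoc)
#> HbA1c association scan: 470 features
#>   at q < 0.1 : 8 positive, 22 negative
print(res$regulated)
#> Regulated miRNA sets: 8 Up-Pos, 20 Down-Neg
```

The SAM contrast calls 9 up / 23 down miRNAs at FDR < 0.1 and the HbA1c
scan finds 8 positive / 22 negative associations at q < 0.1; their
intersection — the pipeline's pivotal intermediate — recovers most of the
planted truth with no sign errors:

```r
length(intersect(res$regulated$up_pos,   sim$truth$up_pos_ids))    # 8 of 9
length(intersect(res$regulated$down_neg, sim$truth$down_neg_ids))  # 20 of 22
res$manifest$row_counts$network                                    # 5 modules
sum(res$eqtl$records$nominal)          # 8 nominal eQTLs of 25 tested pairs
res$overlap$summary                    # planted risk-SNP overlaps per class
#>         trait_class n_mirnas
#> 1 insulin_secretion        4
#> 2               T2D        4
```

Module resolution scales with the transcriptome cohort: at the 18-donor
default the eigengene merge step can collapse correlated modules, while at
the 180-sample scale the network stage recovers the planted partition
exactly (adjusted Rand index 1.0):

```r
cfg <- sim_config(seed = 1, n_donors = 180, n_genes = 600,
                  module_sizes = rep(100, 5))
co <- generate_cohort(cfg)
mr <- generate_mrna_modules(cfg, co)
diss <- 1 - tom_similarity(signed_adjacency(mr$log2, beta = 12))
part <- merge_modules(mr$log2, detect_modules(diss, 10), 0.25)
max(part$partition)                    # 5 modules, matching the 5 planted
```

Every stage is also callable on files (TSV / GMT / VCF) via the readers in
`read_expression()`, `read_cohort()`, `read_interactions()`, `read_gmt()`,
`read_vcf_dosages()`, `read_risk_catalog()`, and `run_full_pipeline()`
accepts a list of paths in place of in-memory tables.

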