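#' Hardy-Weinberg equilibrium chi-square test
#'
#' From genotype counts (`n_AA`, `n_Aa`, `n_aa`), estimates the allele
#' frequency `p = (2 n_AA + n_Aa) / (2n)`, forms the expected counts
#' `(p^2 n, 2 p (1 - p) n, (1 - p)^2 n)` and returns the 1-df chi-square
#' p value. Monomorphic data are in perfect equilibrium (`p = 1`).
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return list: `chisq`, `p`, `p_allele`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype counts")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotyped samples")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  expd <- c(p^2, 2 * p * (1 - p), (1 - p)^2) * n
  obs <- c(n_AA, n_Aa, n_aa)
  nz <- expd > 0
  chisq <- sum((obs[nz] - expd[nz])^2 / expd[nz])
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       p_allele = p)
}

#' SNP quality control
#'
#' Per SNP, computes the call rate, minor allele frequency and HWE p value
#' from the dosage matrix and fails SNPs with `call_rate < 1 - missing_max`,
#' `MAF < maf_min` or `HWE p < hwe_p_min`; every violated criterion is
#' listed in the failure reasons.
#'
#' @param gt a `genotype_data` object.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min minimum HWE p value (default 0.05).
#' @param missing_max maximum missingness fraction (default 0.05).
#' @return list: `report` (data.frame `snp_id`, `call_rate`, `maf`, `hwe_p`,
#'   `pass`, `reasons`) and `genotypes` (the passing subset).
#' @export
snp_qc <- function(gt, maf_min = 0.01, hwe_p_min = 0.05,
                   missing_max = 0.05) {
  d <- gt$dosage
  call_rate <- rowMeans(!is.na(d))
  af <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hwe_p <- vapply(seq_len(nrow(d)), function(i) {
    x <- d[i, !is.na(d[i, ])]
    hwe_test(sum(x == 2), sum(x == 1), sum(x == 0))$p
  }, numeric(1))
  reasons <- vapply(seq_len(nrow(d)), function(i) {
    r <- c(if (call_rate[i] < 1 - missing_max) "missingness",
           if (maf[i] < maf_min) "MAF",
           if (hwe_p[i] < hwe_p_min) "HWE")
    paste(r, collapse = ";")
  }, character(1))
  pass <- reasons == ""
  report <- data.frame(snp_id = gt$snp_id, call_rate = call_rate, maf = maf,
                       hwe_p = hwe_p, pass = pass, reasons = reasons,
                       stringsAsFactors = FALSE, row.names = NULL)
  filtered <- list(snp_id = gt$snp_id[pass], chrom = gt$chrom[pass],
                   pos = gt$pos[pass], ref = gt$ref[pass],
                   alt = gt$alt[pass],
                   dosage = gt$dosage[pass, , drop = FALSE])
  class(filtered) <- "genotype_data"
  list(report = report, genotypes = filtered)
}

#' SNPs in the cis window of a miRNA
#'
#' Selects SNPs on the miRNA's chromosome whose position lies within
#' `window` bp of the miRNA start, bounds inclusive (a +/- window, i.e. a
#' span of `2 * window + 1`).
#'
#' @param mirna list or one-row data.frame with `chrom` and `start`.
#' @param gt a `genotype_data` object.
#' @param window half-width of the cis window in bp (default 1 Mb).
#' @return integer indices into `gt$snp_id` (possibly empty; unknown
#'   chromosome warns).
#' @export
cis_window_snps <- function(mirna, gt, window = 1e6) {
  chrom <- mirna$chrom
  start <- mirna$start
  if (!chrom %in% gt$chrom) {
    warning("no SNPs on chromosome ", chrom)
    return(integer(0))
  }
  which(gt$chrom == chrom & abs(gt$pos - start) <= window)
}

#' cis-eQTL scan of miRNA expression
#'
#' For every (miRNA, cis SNP) pair, fits log2 expression on the
#' alternate-allele dosage plus donor covariates (age, sex, BMI, HbA1c,
#' culture days by default) by OLS and reports the per-allele effect,
#' SE, t, two-sided p and a BH q computed within each miRNA's cis SNP set
#' (per-phenotype correction). Missing dosages are mean-imputed per SNP for
#' the regression only; genotypes are expected to have passed [snp_qc()],
#' and a monomorphic SNP reaching the scan is an error (QC contract
#' breach).
#'
#' @param mirna_expr log2 miRNA matrix (features x donors).
#' @param gt QC-passed `genotype_data`.
#' @param cohort donor covariate table (rows aligned to expression columns
#'   by `donor_id`).
#' @param mirna_positions data.frame `mirna_id`, `chrom`, `start`.
#' @param window cis half-window in bp.
#' @param covariates cohort columns used as covariates; `sex` is recoded
#'   0/1.
#' @param nominal_p nominal significance threshold for the `nominal` flag.
#' @return data.frame of `eqtl_record`s: `snp_id`, `mirna_id`,
#'   `distance_bp` (SNP pos - miRNA start), `beta`, `se`, `t`, `p`, `q`,
#'   `nominal`.
#' @export
eqtl_scan <- function(mirna_expr, gt, cohort, mirna_positions,
                      window = 1e6,
                      covariates = c("age", "sex", "BMI", "HbA1c",
                                     "culture_days"),
                      nominal_p = 0.05) {
  stopifnot(is.matrix(mirna_expr))
  if (!identical(colnames(mirna_expr), cohort$donor_id))
    mirna_expr <- mirna_expr[, cohort$donor_id, drop = FALSE]
  if (!identical(colnames(gt$dosage), cohort$donor_id))
    gt$dosage <- gt$dosage[, cohort$donor_id, drop = FALSE]

  covs <- lapply(covariates, function(cv) {
    v <- cohort[[cv]]
    if (cv == "sex") v <- as.numeric(v == "M")
    if (any(is.na(v)))
      stop("missing covariate '", cv, "' for donor(s): ",
           paste(cohort$donor_id[is.na(v)], collapse = ", "))
    as.numeric(v)
  })
  Xcov <- do.call(cbind, covs)
  colnames(Xcov) <- covariates

  keep <- mirna_positions$mirna_id %in% rownames(mirna_expr)
  mirna_positions <- mirna_positions[keep, , drop = FALSE]

  out <- list()
  for (i in seq_len(nrow(mirna_positions))) {
    mid <- mirna_positions$mirna_id[i]
    idx <- suppressWarnings(
      cis_window_snps(mirna_positions[i, ], gt, window))
    if (length(idx) == 0) next
    y <- mirna_expr[mid, ]
    rows <- lapply(idx, function(j) {
      dose <- gt$dosage[j, ]
      if (any(is.na(dose))) dose[is.na(dose)] <- mean(dose, na.rm = TRUE)
      if (stats::sd(dose) == 0)
        stop("monomorphic SNP ", gt$snp_id[j],
             " reached eqtl_scan: QC contract breach")
      X <- cbind(intercept = 1, dosage = dose, Xcov)
      f <- ols_fit(y, X)
      data.frame(snp_id = gt$snp_id[j], mirna_id = mid,
                 distance_bp = gt$pos[j] - mirna_positions$start[i],
                 beta = unname(f$coefficients["dosage"]),
                 se = unname(f$se["dosage"]), t = unname(f$t["dosage"]),
                 p = unname(f$p["dosage"]), stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$q <- adjust_bh(tab$p)
    out[[mid]] <- tab
  }
  if (length(out) == 0)
    return(data.frame(snp_id = character(0), mirna_id = character(0),
                      distance_bp = numeric(0), beta = numeric(0),
                      se = numeric(0), t = numeric(0), p = numeric(0),
                      q = numeric(0), nominal = logical(0)))
  res <- do.call(rbind, out)
  res$nominal <- res$p < nominal_p
  rownames(res) <- NULL
  res
}

#' Overlap nominal eQTLs with a risk-SNP catalogue
#'
#' Joins eQTL records with nominal `p < nominal_p` to the catalogue,
#' matching by rsid first and falling back to exact (chrom, pos) equality
#' (both 1-based). A SNP listed under several trait classes yields one
#' overlap row per class. The summary counts, per trait class, the miRNAs
#' with at least one overlapping nominal eQTL.
#'
#' @param eqtls data.frame from [eqtl_scan()].
#' @param catalog risk catalogue data.frame (`rsid`, `chrom`, `pos`,
#'   `trait_class`).
#' @param gt optional `genotype_data` supplying (chrom, pos) for the
#'   positional fallback.
#' @param nominal_p nominal threshold.
#' @return list: `overlaps` (data.frame `mirna_id`, `snp_id`, `rsid`,
#'   `trait_class`, `p`, `matched_by`), `summary` (data.frame
#'   `trait_class`, `n_mirnas`, `mirnas`).
#' @export
risk_overlap <- function(eqtls, catalog, gt = NULL, nominal_p = 0.05) {
  nom <- eqtls[eqtls$p < nominal_p, , drop = FALSE]
  rows <- list()
  if (nrow(nom) > 0 && nrow(catalog) > 0) {
    for (i in seq_len(nrow(nom))) {
      hit <- which(catalog$rsid == nom$snp_id[i])
      matched_by <- "rsid"
      if (length(hit) == 0 && !is.null(gt)) {
        j <- match(nom$snp_id[i], gt$snp_id)
        if (!is.na(j)) {
          hit <- which(catalog$chrom == gt$chrom[j] &
                         catalog$pos == gt$pos[j])
          matched_by <- "position"
        }
      }
      for (h in hit) {
        rows[[length(rows) + 1]] <- data.frame(
          mirna_id = nom$mirna_id[i], snp_id = nom$snp_id[i],
          rsid = catalog$rsid[h], trait_class = catalog$trait_class[h],
          p = nom$p[i], matched_by = matched_by, stringsAsFactors = FALSE)
      }
    }
  }
  overlaps <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(mirna_id = character(0), snp_id = character(0),
               rsid = character(0), trait_class = character(0),
               p = numeric(0), matched_by = character(0),
               stringsAsFactors = FALSE)
  rownames(overlaps) <- NULL
  classes <- sort(unique(overlaps$trait_class))
  summary <- do.call(rbind, lapply(classes, function(cl) {
    mm <- sort(unique(overlaps$mirna_id[overlaps$trait_class == cl]))
    data.frame(trait_class = cl, n_mirnas = length(mm),
               mirnas = paste(mm, collapse = ","), stringsAsFactors = FALSE)
  }))
  if (is.null(summary))
    summary <- data.frame(trait_class = character(0), n_mirnas = integer(0),
                          mirnas = character(0), stringsAsFactors = FALSE)
  list(overlaps = overlaps, summary = summary)
}
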