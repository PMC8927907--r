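#' Read an expression matrix from TSV
#'
#' Expects features in rows (first column = feature id), samples in columns,
#' with a header row of sample ids. Malformed input is rejected, never
#' silently coerced: duplicate feature ids, non-numeric cells and non-finite
#' values are errors naming the offender.
#'
#' @param path TSV file path.
#' @param scale declared scale of the values, `"log2"` or `"counts"`.
#' @return numeric matrix (features x samples) with a `scale` attribute.
#' @export
read_expression <- function(path, scale = c("log2", "counts")) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression file has no sample columns: ", path)
  ids <- as.character(tab[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate feature id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  vals <- tab[, -1, drop = FALSE]
  nonnum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonnum))
    stop("non-numeric column(s) in ", path, ": ",
         paste(names(vals)[nonnum], collapse = ", "))
  x <- as.matrix(vals)
  rownames(x) <- ids
  if (any(!is.finite(x)))
    stop("non-finite values in ", path, " (feature ",
         ids[which(!is.finite(x), arr.ind = TRUE)[1, 1]], ")")
  if (scale == "counts" && any(x < 0))
    stop("negative values in counts-scale matrix: ", path)
  attr(x, "scale") <- scale
  x
}

#' Write an expression matrix to TSV
#'
#' @param x numeric matrix, features x samples, with dimnames.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a donor covariate table
#'
#' Requires the columns every association stage relies on and validates the
#' core invariants (unique donor ids, positive HbA1c). With `strict = TRUE`
#' the glycemic status labels are additionally checked against the HbA1c
#' thresholds used throughout (NGT < 6.0; IGT/T2D >= 6.0).
#'
#' @param path TSV path.
#' @param strict check status/HbA1c consistency.
#' @return data.frame of donor covariates.
#' @export
read_cohort <- function(path, strict = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("donor_id", "age", "sex", "BMI", "HbA1c", "glycemic_status",
                "culture_days")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("cohort table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(tab$donor_id))
    stop("duplicate donor_id in ", path, ": ",
         tab$donor_id[duplicated(tab$donor_id)][1])
  if (any(!is.finite(tab$HbA1c)) || any(tab$HbA1c <= 0))
    stop("invalid HbA1c values in ", path)
  if (strict) {
    bad <- (tab$glycemic_status == "NGT" & tab$HbA1c >= 6.0) |
      (tab$glycemic_status != "NGT" & tab$HbA1c < 6.0)
    if (any(bad))
      stop("glycemic_status inconsistent with HbA1c for donor(s): ",
           paste(tab$donor_id[bad], collapse = ", "))
  }
  tab
}

#' @rdname read_cohort
#' @param cohort cohort data.frame to write.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a miRNA-gene interaction table
#'
#' Exact duplicate (mirna, gene, source) rows are removed at load time with
#' a message; the row count before/after is reported on the result.
#'
#' @param path TSV with columns `mirna_id`, `gene_id`, `source_db`,
#'   `evidence_type`.
#' @return data.frame of deduplicated interactions.
#' @export
read_interactions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("mirna_id", "gene_id", "source_db")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("interaction table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  key <- paste(tab$mirna_id, tab$gene_id, tab$source_db, sep = "\r")
  ndup <- sum(duplicated(key))
  if (ndup > 0) {
    message("read_interactions: removed ", ndup,
            " duplicate (mirna, gene, source) row(s)")
    tab <- tab[!duplicated(key), , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' @rdname read_interactions
#' @param interactions interaction data.frame to write.
#' @export
write_interactions <- function(interactions, path) {
  utils::write.table(interactions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' member genes. Duplicate members within a line are deduplicated; lines
#' with fewer than three fields are errors naming the line; singleton sets
#' are kept but flagged with a warning.
#'
#' @param path GMT path.
#' @return named list of `list(name, description, genes)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(list())
  }
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 fields in ", path)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 1)
      warning("singleton gene set '", f[1], "' at line ", i)
    sets[[f[1]]] <- list(name = f[1], description = f[2], genes = genes)
  }
  sets
}

#' @rdname read_gmt
#' @param sets gene-set list to write.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Parses a VCF (v4.x) with a GT FORMAT field and converts genotypes to
#' alternate-allele dosages: `0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`, `./.` ->
#' missing; phased separators are treated like unphased. Multi-allelic
#' records are rejected with a warning naming the variant.
#'
#' @param path VCF path.
#' @return a `genotype_data` list (`snp_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `dosage` SNP x sample matrix).
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt)))
    stop("missing GT in FORMAT field of ", path)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning("rejecting ", sum(multi), " multi-allelic record(s): ",
            paste(utils::head(fix[multi, "ID"], 5), collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  dosage <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(as.numeric(alleles) > 0)
  })
  out <- list(snp_id = as.character(fix[, "ID"]),
              chrom = as.character(fix[, "CHROM"]),
              pos = as.numeric(fix[, "POS"]),
              ref = as.character(fix[, "REF"]),
              alt = as.character(fix[, "ALT"]),
              dosage = dosage)
  rownames(out$dosage) <- out$snp_id
  class(out) <- "genotype_data"
  out
}

#' Write genotypes as a minimal VCF v4.2
#'
#' @param gt a `genotype_data` object.
#' @param path output path.
#' @export
write_vcf <- function(gt, path) {
  samples <- colnames(gt$dosage)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gt$dosage + 1],
                   nrow = nrow(gt$dosage))
  gt_str[is.na(gt$dosage)] <- "./."
  body <- vapply(seq_along(gt$snp_id), function(i)
    paste(c(gt$chrom[i], format(gt$pos[i], scientific = FALSE), gt$snp_id[i],
            gt$ref[i], gt$alt[i], ".", "PASS", ".", "GT", gt_str[i, ]),
          collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write a risk-SNP catalogue
#'
#' TSV with columns `rsid`, `chrom`, `pos` (1-based), `trait_class`
#' (`T2D` or `insulin_secretion`) and `source`.
#'
#' @param path TSV path.
#' @return data.frame catalogue.
#' @export
read_risk_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("rsid", "chrom", "pos", "trait_class")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("risk catalogue ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(tab$pos)) || any(tab$pos < 1))
    stop("risk catalogue ", path, " has invalid positions")
  tab
}

#' @rdname read_risk_catalog
#' @param catalog catalogue data.frame to write.
#' @export
write_risk_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
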