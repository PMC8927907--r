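#' Ordinary least squares with full diagnostics
#'
#' Solves the least-squares problem via QR, returning coefficients, standard
#' errors, t statistics and two-sided p values from the t distribution with
#' `n - k` residual degrees of freedom. Rank-deficient designs are an error
#' naming the collinear column(s); a zero-residual (saturated) fit is
#' reported with `p = 0` and a `degenerate` flag rather than NaNs.
#'
#' @param y numeric response vector.
#' @param X design matrix (rows = observations, named columns).
#' @return list: `coefficients`, `se`, `t`, `p` (named per column of `X`),
#'   `df`, `sigma2`, `residuals`, `degenerate`.
#' @export
ols_fit <- function(y, X) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop("length(y) does not match nrow(X)")
  if (n - k < 1) stop("fewer than 1 residual degree of freedom")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(k))
  qr_x <- qr(X)
  if (qr_x$rank < k) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):k]]
    stop("singular design: collinear column(s) ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_x, y)
  res <- y - as.vector(X %*% beta)
  rss <- sum(res^2)
  df <- n - k
  sigma2 <- rss / df
  R <- qr.R(qr_x)
  xtx_inv <- chol2inv(R)[order(qr_x$pivot), order(qr_x$pivot), drop = FALSE]
  degenerate <- sigma2 < .Machine$double.eps * max(1, mean(y^2))
  se <- sqrt(pmax(sigma2 * diag(xtx_inv), 0))
  tval <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  p <- if (degenerate) ifelse(beta == 0, 1, 0) else
    2 * stats::pt(-abs(tval), df)
  names(se) <- names(tval) <- names(p) <- colnames(X)
  list(coefficients = beta, se = se, t = tval, p = p, df = df,
       sigma2 = sigma2, residuals = res, degenerate = degenerate)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment: `q_i = min over ranks j >= rank(i) of
#' p_(j) * m / j`, capped at 1. Thin validated wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return q-values, same order as `p`.
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Design matrix shared by the HbA1c scan: intercept + HbA1c + covariates.
hba1c_design <- function(cohort, status_coding = c("ordinal", "dummy")) {
  status_coding <- match.arg(status_coding)
  required <- c("HbA1c", "age", "BMI", "sex", "glycemic_status",
                "culture_days")
  for (col in required) {
    bad <- is.na(cohort[[col]])
    if (any(bad))
      stop("missing covariate '", col, "' for donor(s): ",
           paste(cohort$donor_id[bad], collapse = ", "))
  }
  sexn <- as.numeric(cohort$sex == "M")
  if (status_coding == "ordinal") {
    status <- match(cohort$glycemic_status, c("NGT", "IGT", "T2D")) - 1
    X <- cbind(intercept = 1, HbA1c = cohort$HbA1c, age = cohort$age,
               BMI = cohort$BMI, sex = sexn, status = status,
               culture_days = cohort$culture_days)
  } else {
    X <- cbind(intercept = 1, HbA1c = cohort$HbA1c, age = cohort$age,
               BMI = cohort$BMI, sex = sexn,
               status_IGT = as.numeric(cohort$glycemic_status == "IGT"),
               status_T2D = as.numeric(cohort$glycemic_status == "T2D"),
               culture_days = cohort$culture_days)
  }
  rownames(X) <- cohort$donor_id
  X
}

#' Covariate-adjusted HbA1c association scan
#'
#' Fits, per miRNA, `log2 expression ~ HbA1c + age + BMI + sex +
#' glycemic status + culture days` and reports the HbA1c coefficient with
#' its SE, t, two-sided p and BH q across all tested miRNAs. Glycemic
#' status enters as an ordinal 0/1/2 covariate by default
#' (`status_coding = "dummy"` uses two indicator columns instead). The
#' positively / negatively associated sets are those with `q <
#' q_threshold` and positive / negative HbA1c coefficient.
#'
#' All features share one design matrix, so coefficients for the whole
#' panel are obtained from a single QR decomposition; the result is
#' identical to feature-wise [ols_fit()] calls.
#'
#' @param expr log2 miRNA expression matrix (features x donors; columns
#'   must match `cohort$donor_id`).
#' @param cohort donor covariate table.
#' @param q_threshold BH q cut for the reported sets.
#' @param status_coding `"ordinal"` (default) or `"dummy"`.
#' @return an `assoc_result` list: `table` (feature, beta_hba1c, se, t, p,
#'   q, degenerate), `pos_set`, `neg_set`, `q_threshold`.
#' @export
hba1c_scan <- function(expr, cohort, q_threshold = 0.1,
                       status_coding = c("ordinal", "dummy")) {
  stopifnot(is.matrix(expr))
  if (!identical(colnames(expr), cohort$donor_id)) {
    if (!all(cohort$donor_id %in% colnames(expr)))
      stop("expression columns do not cover all donors")
    expr <- expr[, cohort$donor_id, drop = FALSE]
  }
  X <- hba1c_design(cohort, status_coding)
  n <- nrow(X); k <- ncol(X); df <- n - k
  if (df < 1) stop("fewer than 1 residual degree of freedom")
  qr_x <- qr(X)
  if (qr_x$rank < k)
    stop("singular design: collinear column(s) ",
         paste(colnames(X)[qr_x$pivot[(qr_x$rank + 1):k]], collapse = ", "))

  Y <- t(expr)                         # donors x features
  B <- qr.coef(qr_x, Y)                # k x features
  fitted <- X %*% B
  rss <- colSums((Y - fitted)^2)
  sigma2 <- rss / df
  R <- qr.R(qr_x)
  xtx_inv <- chol2inv(R)[order(qr_x$pivot), order(qr_x$pivot), drop = FALSE]
  j <- which(colnames(X) == "HbA1c")
  v_hba1c <- xtx_inv[j, j]

  beta <- B["HbA1c", ]
  se <- sqrt(sigma2 * v_hba1c)
  degenerate <- sigma2 < .Machine$double.eps * pmax(1, colMeans(Y^2))
  tval <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  p <- ifelse(degenerate, ifelse(beta == 0, 1, 0),
              2 * stats::pt(-abs(tval), df))
  q <- adjust_bh(p)

  tab <- data.frame(feature = rownames(expr), beta_hba1c = beta, se = se,
                    t = tval, p = p, q = q, degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- list(table = tab,
              pos_set = tab$feature[tab$q < q_threshold & tab$beta_hba1c > 0],
              neg_set = tab$feature[tab$q < q_threshold & tab$beta_hba1c < 0],
              q_threshold = q_threshold)
  class(res) <- "assoc_result"
  res
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("HbA1c association scan:", nrow(x$table), "features\n")
  cat("  at q <", x$q_threshold, ":", length(x$pos_set), "positive,",
      length(x$neg_set), "negative\n")
  invisible(x)
}

#' Pearson correlation of miRNAs with hormone genes
#'
#' Correlates each miRNA with each listed hormone gene across the shared
#' samples using Pearson correlation on the log2 values, reporting r, the
#' two-sided p, and a significance flag at nominal `p < p_threshold`
#' (no multiplicity correction, by design). Constant vectors make the
#' correlation undefined; such pairs are flagged `undefined` and excluded
#' from significance calls.
#'
#' @param mirna_expr log2 miRNA matrix (features x samples).
#' @param gene_expr log2 mRNA matrix (genes x samples).
#' @param gene_ids hormone genes of interest (rows of `gene_expr`).
#' @param p_threshold nominal significance threshold.
#' @return data.frame `mirna`, `gene`, `r`, `p`, `significant`, `undefined`.
#' @export
hormone_correlation <- function(mirna_expr, gene_expr,
                                gene_ids = c("INS", "GCG", "SST"),
                                p_threshold = 0.05) {
  shared <- intersect(colnames(mirna_expr), colnames(gene_expr))
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  gene_ids <- gene_ids[gene_ids %in% rownames(gene_expr)]
  if (length(gene_ids) == 0) stop("none of the hormone genes are present")
  mi <- mirna_expr[, shared, drop = FALSE]
  ge <- gene_expr[gene_ids, shared, drop = FALSE]

  out <- vector("list", nrow(mi) * length(gene_ids))
  idx <- 1
  for (g in gene_ids) {
    gv <- ge[g, ]
    g_const <- stats::sd(gv) == 0
    for (i in seq_len(nrow(mi))) {
      mv <- mi[i, ]
      if (g_const || stats::sd(mv) == 0) {
        out[[idx]] <- data.frame(mirna = rownames(mi)[i], gene = g,
                                 r = NA_real_, p = NA_real_,
                                 significant = FALSE, undefined = TRUE,
                                 stringsAsFactors = FALSE)
      } else {
        ct <- stats::cor.test(mv, gv, method = "pearson")
        out[[idx]] <- data.frame(mirna = rownames(mi)[i], gene = g,
                                 r = unname(ct$estimate), p = ct$p.value,
                                 significant = ct$p.value < p_threshold,
                                 undefined = FALSE, stringsAsFactors = FALSE)
      }
      idx <- idx + 1
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Intersect differential and HbA1c-associated miRNA sets
#'
#' The pipeline's pivotal intermediate: miRNAs both upregulated (SAM) and
#' positively associated with HbA1c form the Up-Pos set; downregulated and
#' negatively associated miRNAs form the Down-Neg set.
#'
#' @param sam_up,sam_down miRNA ids called up / down by [sam_fdr()].
#' @param pos_set,neg_set miRNA ids positively / negatively associated with
#'   HbA1c from [hba1c_scan()].
#' @return a `regulated_sets` list: `up_pos`, `down_neg`.
#' @export
intersect_regulated <- function(sam_up, sam_down, pos_set, neg_set) {
  res <- list(up_pos = sort(intersect(sam_up, pos_set)),
              down_neg = sort(intersect(sam_down, neg_set)))
  stopifnot(length(intersect(res$up_pos, res$down_neg)) == 0)
  class(res) <- "regulated_sets"
  res
}

#' @export
print.regulated_sets <- function(x, ...) {
  cat("Regulated miRNA sets: ", length(x$up_pos), " Up-Pos, ",
      length(x$down_neg), " Down-Neg\n", sep = "")
  invisible(x)
}
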