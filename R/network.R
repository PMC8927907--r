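#' Signed weighted adjacency matrix
#'
#' `a_ij = ((1 + cor(g_i, g_j)) / 2)^beta` with Pearson correlation across
#' samples: perfectly anticorrelated genes get adjacency 0 (not 1 as in an
#' unsigned network), uncorrelated genes `0.5^beta`. Requires at least 4
#' samples and no zero-variance genes.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param beta soft-thresholding power (integer >= 1).
#' @return symmetric gene x gene matrix in `[0, 1]` with unit diagonal.
#' @export
signed_adjacency <- function(expr, beta = 12) {
  stopifnot(is.matrix(expr), beta >= 1)
  if (ncol(expr) < 4) stop("need at least 4 samples")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "))
  a <- ((1 + stats::cor(t(expr))) / 2)^beta
  # guard against fp drift outside [0, 1]
  a[a > 1] <- 1; a[a < 0] <- 0
  diag(a) <- 1
  a
}

#' Scale-free-fit guided soft-threshold selection
#'
#' For each candidate power, builds the signed adjacency, computes the
#' connectivity `k_i = sum_j a_ij - 1`, bins `log10(k)` and regresses
#' `log10(frequency)` on `log10(k)`: the fit R^2, signed by the negative of
#' the regression slope (scale-free topology requires a decreasing
#' relationship), measures scale-free fit. The recommended power is the
#' smallest with signed R^2 >= `rsq_cut`, falling back to the argmax.
#' Selection is refused (with the default returned and a warning) below 30
#' genes, where the fit is meaningless.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param powers candidate powers.
#' @param rsq_cut signed R^2 acceptance threshold.
#' @param n_bins connectivity histogram bins.
#' @param default_beta power returned when selection is refused.
#' @return list: `fit` (data.frame power, rsq_signed, slope, mean_k),
#'   `recommended`.
#' @export
pick_soft_threshold <- function(expr, powers = c(1:10, 12, 14, 16, 18, 20),
                                rsq_cut = 0.8, n_bins = 10,
                                default_beta = 12) {
  if (nrow(expr) < 30) {
    warning("fewer than 30 genes: refusing selection, returning default ",
            default_beta)
    return(list(fit = NULL, recommended = default_beta))
  }
  s <- (1 + stats::cor(t(expr))) / 2
  diag(s) <- NA
  fit <- lapply(powers, function(b) {
    a <- s^b
    k <- rowSums(a, na.rm = TRUE)
    k <- k[k > 0]
    lk <- log10(k)
    cuts <- seq(min(lk), max(lk), length.out = n_bins + 1)
    bin <- cut(lk, breaks = cuts, include.lowest = TRUE)
    freq <- table(bin)
    mk <- tapply(lk, bin, mean)
    keep <- freq > 0 & is.finite(mk)
    if (sum(keep) < 3)
      return(data.frame(power = b, rsq_signed = 0, slope = NA_real_,
                        mean_k = mean(k)))
    lf <- log10(as.numeric(freq[keep]))
    lx <- mk[keep]
    f <- stats::lm(lf ~ lx)
    r2 <- summary(f)$r.squared
    sl <- stats::coef(f)[2]
    data.frame(power = b, rsq_signed = -sign(sl) * r2, slope = unname(sl),
               mean_k = mean(k))
  })
  fit <- do.call(rbind, fit)
  ok <- which(fit$rsq_signed >= rsq_cut)
  recommended <- if (length(ok)) fit$power[ok[1]] else
    fit$power[which.max(fit$rsq_signed)]
  list(fit = fit, recommended = recommended)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' for `i != j` (unit diagonal), with `k_i = sum_{j != i} a_ij`: similarity
#' that rewards shared network neighborhoods. The dissimilarity used for
#' clustering is `1 - TOM`.
#'
#' @param adj symmetric adjacency with unit diagonal (from
#'   [signed_adjacency()]).
#' @return symmetric TOM matrix in `[0, 1]` with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  stopifnot(is.matrix(adj))
  if (!isSymmetric(unname(adj), tol = 1e-10))
    stop("adjacency must be symmetric")
  k <- rowSums(adj) - 1
  # sum_{u != i,j} a_iu a_uj = (A^2)_ij - a_ii a_ij - a_ij a_jj
  #                          = (A^2)_ij - 2 a_ij   (unit diagonal)
  numer <- adj %*% adj - 2 * adj + adj
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- numer / denom
  diag(tom) <- 1
  tom[tom > 1] <- 1; tom[tom < 0] <- 0
  0.5 * (tom + t(tom))  # symmetrize fp noise
}

# --- deterministic tree cut ------------------------------------------------

# members of every internal node of an hclust tree (list over nodes 1..n-1)
hclust_node_members <- function(hc) {
  n <- nrow(hc$merge) + 1
  members <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    m <- hc$merge[i, ]
    left <- if (m[1] < 0) -m[1] else members[[m[1]]]
    right <- if (m[2] < 0) -m[2] else members[[m[2]]]
    members[[i]] <- c(left, right)
  }
  members
}

# 0.9-quantile of merge heights inside every subtree ("core height"): a
# stray gene chaining onto an otherwise tight branch raises the branch's
# root height but barely moves its core height, so gaps measured against
# the core survive stray attachments
hclust_core_heights <- function(hc, prob = 0.9) {
  n <- nrow(hc$merge) + 1
  hlist <- vector("list", n - 1)
  core <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    hs <- hc$height[i]
    for (kk in hc$merge[i, ]) if (kk > 0) hs <- c(hs, hlist[[kk]])
    hlist[[i]] <- hs
    core[i] <- stats::quantile(hs, prob)
  }
  core
}

# recursively split a branch (node index) where the node's merge height
# exceeds the core height of both children by more than split_gap of the
# tree's tallest merge
split_branch <- function(node, hc, gap_abs, members, core) {
  if (node < 0) return(list(-node))           # leaf
  kids <- hc$merge[node, ]
  child_core <- vapply(kids, function(kk) if (kk < 0) 0 else core[kk],
                       numeric(1))
  if (hc$height[node] - max(child_core) > gap_abs) {
    c(split_branch(kids[1], hc, gap_abs, members, core),
      split_branch(kids[2], hc, gap_abs, members, core))
  } else {
    list(members[[node]])
  }
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, followed by a
#' deterministic two-stage cut: (i) a constant-height cut at
#' `cut_height * max(merge height)` and (ii) recursive splitting of each
#' resulting branch wherever the branch's merge height exceeds the core
#' height (the 0.9-quantile of merge heights) of both children by more than
#' `split_gap` of the tallest merge -- a simplified, fully reproducible
#' stand-in for dynamic tree cutting. Measuring gaps against the children's
#' core heights rather than their root heights makes the split robust to
#' single stray genes chaining onto a tight branch. Branches smaller than
#' `min_module_size` are left unassigned (label 0); assigned modules are
#' labelled 1..M in decreasing size order (ties broken by first gene).
#'
#' @param diss_tom dissimilarity matrix `1 - TOM` (genes x genes, named).
#' @param min_module_size smallest reportable module (default 10).
#' @param cut_height static cut as a fraction of the tallest merge.
#' @param split_gap merge-gap (as a fraction of the tallest merge) that
#'   triggers a branch split.
#' @return a `module_partition`: named integer vector gene -> label
#'   (0 = unassigned), with attributes `sizes` and `hclust`.
#' @export
detect_modules <- function(diss_tom, min_module_size = 10,
                           cut_height = 0.99, split_gap = 0.03) {
  stopifnot(is.matrix(diss_tom))
  genes <- rownames(diss_tom)
  n <- length(genes)
  labels <- setNames(rep(0L, n), genes)
  if (n < min_module_size) {
    attr(labels, "sizes") <- integer(0)
    class(labels) <- "module_partition"
    return(labels)
  }
  hc <- stats::hclust(stats::as.dist(diss_tom), method = "average")
  h0 <- cut_height * max(hc$height)

  # static-cut branches: internal nodes at height <= h0 whose parent merge
  # is above h0 (or which are the root)
  n_nodes <- n - 1
  parent_h <- rep(Inf, n_nodes)
  for (i in seq_len(n_nodes)) {
    for (kk in hc$merge[i, ]) if (kk > 0) parent_h[kk] <- hc$height[i]
  }
  roots <- which(hc$height <= h0 & parent_h > h0)

  members <- hclust_node_members(hc)
  core <- hclust_core_heights(hc)
  gap_abs <- split_gap * max(hc$height)
  groups <- list()
  for (node in roots)
    groups <- c(groups, split_branch(node, hc, gap_abs, members, core))

  sizes <- lengths(groups)
  keep <- which(sizes >= min_module_size)
  keep <- keep[order(-sizes[keep],
                     vapply(groups[keep], min, numeric(1)))]
  for (lab in seq_along(keep)) labels[groups[[keep[lab]]]] <- lab
  attr(labels, "sizes") <- table(labels[labels > 0])
  attr(labels, "hclust") <- hc
  class(labels) <- "module_partition"
  labels
}

#' Module eigengene
#'
#' First principal component of the gene-standardized module submatrix over
#' the samples dimension: the first left singular vector of the
#' samples x genes matrix, unit norm over samples, sign-aligned so its mean
#' correlation with the member genes is non-negative. Also reports the
#' fraction of variance it explains. A single-gene module returns the
#' standardized gene itself, flagged.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param genes member gene ids.
#' @return list: `eigengene` (named by samples), `explained_variance`,
#'   `flagged`.
#' @export
module_eigengene <- function(expr, genes) {
  sub <- expr[genes, , drop = FALSE]
  std <- t(scale(t(sub)))
  if (length(genes) == 1) {
    v <- as.numeric(std)
    v <- v / sqrt(sum(v^2))
    return(list(eigengene = setNames(v, colnames(expr)),
                explained_variance = 1, flagged = TRUE))
  }
  sv <- svd(t(std))
  e <- sv$u[, 1]
  if (mean(stats::cor(e, t(std))) < 0) e <- -e
  list(eigengene = setNames(e, colnames(expr)),
       explained_variance = sv$d[1]^2 / sum(sv$d^2), flagged = FALSE)
}

#' Eigengene matrix for a module partition
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param partition module labels (named integer vector; 0 is skipped).
#' @return matrix module x sample of eigengenes, rownames `"M<label>"`,
#'   with attribute `explained_variance`.
#' @export
module_eigengenes <- function(expr, partition) {
  labs <- sort(unique(partition[partition > 0]))
  if (length(labs) == 0) stop("no assigned modules in partition")
  eg <- matrix(NA_real_, length(labs), ncol(expr),
               dimnames = list(paste0("M", labs), colnames(expr)))
  ev <- setNames(numeric(length(labs)), rownames(eg))
  for (i in seq_along(labs)) {
    me <- module_eigengene(expr, names(partition)[partition == labs[i]])
    eg[i, ] <- me$eigengene
    ev[i] <- me$explained_variance
  }
  attr(eg, "explained_variance") <- ev
  eg
}

#' Merge modules with similar eigengenes
#'
#' Clusters module eigengenes on `1 - cor` with average linkage and merges
#' every cluster formed below `merge_cut_height`, recomputing eigengenes and
#' iterating to a fixpoint. Labels are renumbered 1..M by decreasing size.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param partition module labels from [detect_modules()].
#' @param merge_cut_height eigengene dissimilarity below which modules merge.
#' @param max_iter safety bound on merge iterations.
#' @return list: `partition` (named integer vector), `eigengenes`
#'   (module x sample matrix).
#' @export
merge_modules <- function(expr, partition, merge_cut_height = 0.25,
                          max_iter = 25) {
  part <- as.integer(partition)
  names(part) <- names(partition)
  for (it in seq_len(max_iter)) {
    labs <- sort(unique(part[part > 0]))
    if (length(labs) < 2) break
    eg <- module_eigengenes(expr, part)
    d <- 1 - stats::cor(t(eg))
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    cl <- stats::cutree(hc, h = merge_cut_height)
    if (length(unique(cl)) == length(labs)) break
    remap <- setNames(cl, labs)   # old label -> merge-group
    part[part > 0] <- remap[as.character(part[part > 0])]
  }
  # renumber by decreasing size, ties by old label
  labs <- sort(unique(part[part > 0]))
  if (length(labs)) {
    sz <- vapply(labs, function(l) sum(part == l), numeric(1))
    new <- setNames(rank(-sz, ties.method = "first"), labs)
    part[part > 0] <- new[as.character(part[part > 0])]
  }
  part <- setNames(as.integer(part), names(partition))
  list(partition = part,
       eigengenes = if (length(labs)) module_eigengenes(expr, part) else NULL)
}

#' Module-trait correlation
#'
#' Correlates every module eigengene with every phenotypic trait, choosing
#' the correlation method per trait from `method_map` (Pearson for traits
#' treated as normally distributed, Spearman for ordinal or skewed ones;
#' default Pearson). p values are two-sided and BH-adjusted across modules
#' within each trait. Constant traits are excluded with a warning.
#'
#' @param eigengenes module x sample matrix from [module_eigengenes()].
#' @param traits data.frame of per-sample traits (rows aligned with the
#'   eigengene columns).
#' @param method_map named character vector trait -> "pearson"/"spearman".
#' @return data.frame `module`, `trait`, `method`, `cor`, `p`, `q`.
#' @export
module_trait_correlation <- function(eigengenes, traits,
                                     method_map = NULL) {
  stopifnot(nrow(traits) == ncol(eigengenes))
  out <- list()
  for (tr in names(traits)) {
    v <- traits[[tr]]
    if (!is.numeric(v)) v <- as.numeric(as.factor(v))
    if (stats::sd(v) == 0) {
      warning("trait '", tr, "' is constant; excluded")
      next
    }
    method <- if (!is.null(method_map) && tr %in% names(method_map))
      method_map[[tr]] else "pearson"
    res <- lapply(rownames(eigengenes), function(m) {
      ct <- suppressWarnings(
        stats::cor.test(eigengenes[m, ], v, method = method, exact = FALSE))
      data.frame(module = m, trait = tr, method = method,
                 cor = unname(ct$estimate), p = ct$p.value,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$q <- adjust_bh(res$p)
    out[[tr]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag outlier samples from an expression matrix
#'
#' Hierarchically clusters samples on Euclidean distance and flags samples
#' whose merge height into the tree exceeds the given quantile of all merge
#' heights. Samples are flagged, never dropped automatically.
#'
#' @param expr expression matrix, genes x samples.
#' @param height_quantile quantile of merge heights above which a
#'   late-joining singleton sample is flagged.
#' @return character vector of flagged sample ids (possibly empty).
#' @export
flag_outlier_samples <- function(expr, height_quantile = 0.99) {
  hc <- stats::hclust(stats::dist(t(expr)), method = "average")
  thr <- stats::quantile(hc$height, height_quantile)
  flagged <- character(0)
  for (i in seq_along(hc$height)) {
    if (hc$height[i] > thr) {
      for (kk in hc$merge[i, ])
        if (kk < 0) flagged <- c(flagged, colnames(expr)[-kk])
    }
  }
  unique(flagged)
}
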