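#' Islet-expression filter on a counts matrix
#'
#' Keeps a gene iff the fraction of samples with at least `min_count`
#' normalized counts reaches `min_frac`. The comparison is `>= min_count`
#' ("at least"); `strict_greater = TRUE` selects the `> min_count` reading
#' instead, since both phrasings circulate for this filter.
#'
#' @param counts counts-scale matrix, genes x samples.
#' @param min_count count threshold (default 3).
#' @param min_frac minimum fraction of samples in (0, 1] (default 0.8).
#' @param strict_greater use `> min_count` instead of `>= min_count`.
#' @return character vector of retained gene ids.
#' @export
filter_expressed_genes <- function(counts, min_count = 3, min_frac = 0.8,
                                   strict_greater = FALSE) {
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must lie in (0, 1]")
  stopifnot(is.matrix(counts))
  hit <- if (strict_greater) counts > min_count else counts >= min_count
  keep <- rowMeans(hit) >= min_frac
  rownames(counts)[keep]
}

#' Build per-miRNA validated-target sets
#'
#' Restricts an interaction table to the listed miRNAs, deduplicates
#' (mirna, gene) pairs, optionally intersects each target set with an
#' expressed-gene set, and summarizes: `n_interactions` is the sum of
#' per-miRNA set sizes, `n_unique_genes` the size of their union. miRNAs
#' absent from the table are kept with an empty set and a warning.
#'
#' @param interactions data.frame with `mirna_id`, `gene_id`.
#' @param mirnas miRNA ids to map.
#' @param expressed optional gene set to intersect targets with.
#' @return a `target_map` list: `targets` (named list miRNA -> gene ids),
#'   `n_unique_genes`, `n_interactions`.
#' @export
build_target_map <- function(interactions, mirnas, expressed = NULL) {
  mirnas <- unique(mirnas)
  tab <- interactions[interactions$mirna_id %in% mirnas, c("mirna_id",
                                                           "gene_id")]
  tab <- unique(tab)
  targets <- lapply(setNames(mirnas, mirnas), function(m) {
    g <- sort(unique(tab$gene_id[tab$mirna_id == m]))
    if (!is.null(expressed)) g <- intersect(g, expressed)
    g
  })
  absent <- mirnas[!mirnas %in% tab$mirna_id]
  if (length(absent))
    warning("miRNA(s) absent from interaction table: ",
            paste(absent, collapse = ", "))
  res <- list(targets = targets,
              n_unique_genes = length(unique(unlist(targets))),
              n_interactions = sum(lengths(targets)))
  class(res) <- "target_map"
  res
}

#' @export
print.target_map <- function(x, ...) {
  cat("Target map:", length(x$targets), "miRNAs,", x$n_unique_genes,
      "unique genes,", x$n_interactions, "interactions\n")
  invisible(x)
}

#' Jaccard distance between two gene sets
#'
#' `1 - |A intersect B| / |A union B|`: the proportion of targets not
#' shared. Undefined (an error) when both sets are empty.
#'
#' @param a,b character vectors of gene ids.
#' @return distance in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) stop("Jaccard distance undefined: both sets empty")
  1 - length(intersect(a, b)) / u
}

#' Cluster miRNAs by target-set similarity
#'
#' Computes the symmetric Jaccard-distance matrix over the target map and
#' clusters it with average-linkage hierarchical clustering. miRNAs are
#' processed in lexicographic id order so the dendrogram and its leaf order
#' are deterministic.
#'
#' @param tm a `target_map` from [build_target_map()].
#' @return list: `dist` (matrix), `hclust`, `order` (leaf ids in dendrogram
#'   order).
#' @export
mirna_similarity_clustering <- function(tm) {
  ids <- sort(names(tm$targets))
  if (length(ids) < 2) stop("need at least 2 miRNAs to cluster")
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- jaccard_distance(tm$targets[[ids[i]]],
                                             tm$targets[[ids[j]]])
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  list(dist = D, hclust = hc, order = ids[hc$order])
}

#' Null distribution of target-map summaries for random miRNA sets
#'
#' Repeatedly samples `k` miRNAs uniformly without replacement from the
#' profiled universe, rebuilds the target map, and records the number of
#' unique target genes and interactions -- the reference distribution
#' against which an observed miRNA set's targeting density is judged.
#'
#' @param interactions interaction table.
#' @param universe_mirnas miRNA ids to sample from.
#' @param k number of miRNAs per draw.
#' @param n_draws number of random draws.
#' @param seed RNG seed.
#' @param expressed optional expressed-gene filter applied to each draw.
#' @return data.frame with one row per draw: `n_unique_genes`,
#'   `n_interactions`.
#' @export
random_set_target_null <- function(interactions, universe_mirnas, k,
                                   n_draws = 1000, seed = 1,
                                   expressed = NULL) {
  universe_mirnas <- unique(universe_mirnas)
  if (k > length(universe_mirnas))
    stop("k exceeds the size of the miRNA universe")
  set.seed(seed)
  draws <- matrix(NA_real_, n_draws, 2)
  for (b in seq_len(n_draws)) {
    mm <- sample(universe_mirnas, k)
    tm <- suppressWarnings(build_target_map(interactions, mm, expressed))
    draws[b, ] <- c(tm$n_unique_genes, tm$n_interactions)
  }
  data.frame(n_unique_genes = draws[, 1], n_interactions = draws[, 2])
}

#' Percentile of an observed value within an empirical null
#'
#' @param null numeric vector of null draws.
#' @param observed observed value.
#' @return fraction of null draws `<= observed` (so 1 means the observation
#'   exceeds every draw).
#' @export
empirical_percentile <- function(null, observed) {
  mean(null <= observed)
}

#' Overlap of target sets with a reference gene list
#'
#' For each entity (miRNA or module), counts its genes, how many are
#' expressed (when an expressed set is given) and how many of the expressed
#' genes fall in the reference list, with the corresponding fractions.
#' Guarantees `n_in_reference <= n_expressed <= n_total`.
#'
#' @param x a `target_map`, a named list of gene-id vectors, or a single
#'   character vector of gene ids.
#' @param reference reference gene set (e.g. genes differentially expressed
#'   in T2D).
#' @param expressed optional expressed-gene set.
#' @return data.frame per entity: `entity`, `n_total`, `n_expressed`,
#'   `n_in_reference`, `frac_expressed`, `frac_in_reference` (fraction of
#'   total).
#' @export
reference_overlap <- function(x, reference, expressed = NULL) {
  if (inherits(x, "target_map")) x <- x$targets
  if (is.character(x)) x <- list(genes = x)
  if (length(reference) == 0)
    warning("empty reference set; overlaps are all zero")
  rows <- lapply(names(x), function(nm) {
    g <- unique(x[[nm]])
    ge <- if (is.null(expressed)) g else intersect(g, expressed)
    gr <- intersect(ge, reference)
    data.frame(entity = nm, n_total = length(g), n_expressed = length(ge),
               n_in_reference = length(gr),
               frac_expressed = if (length(g)) length(ge) / length(g) else 0,
               frac_in_reference = if (length(g)) length(gr) / length(g)
               else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
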