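#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` annotated genes in a query of size `n` drawn from
#' a universe of `N` genes of which `K` carry the annotation. Bounds are
#' validated (`max(0, n + K - N) <= k <= min(n, K)`); the tail is computed
#' in a numerically stable way via `stats::phyper`.
#'
#' @param k overlap count.
#' @param K annotated genes in the universe.
#' @param n query size.
#' @param N universe size.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeometric_upper <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N)
    stop("domain error: need 0 <= K, n <= N")
  if (k > min(n, K) || k < max(0, n + K - N))
    stop("domain error: k outside [max(0, n + K - N), min(n, K)]")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene list
#'
#' Tests the query against every gene set in the collection with the
#' upper-tail hypergeometric test inside the given universe; query genes
#' outside the universe are dropped with a warning, set members outside the
#' universe do not count. One record per set with a nonempty universe
#' intersection (overlap `k = 0` is reported with `p = 1`, not silently
#' filtered); BH adjustment across all tested sets; `significant` flags
#' `q < q_threshold`.
#'
#' @param query character vector of gene ids.
#' @param collection gene-set list as returned by [read_gmt()].
#' @param universe background gene set.
#' @param q_threshold BH q cut for the `significant` flag.
#' @return data.frame per tested set: `set_name`, `k`, `n`, `K`, `N`, `p`,
#'   `q`, `significant`, `genes` (overlap ids, comma-separated).
#' @export
ora_scan <- function(query, collection, universe, q_threshold = 0.05) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning("dropping ", length(outside), " query gene(s) outside universe")
    query <- intersect(query, universe)
  }
  n <- length(query)
  rows <- lapply(collection, function(s) {
    members <- intersect(unique(s$genes), universe)
    K <- length(members)
    if (K == 0) return(NULL)
    overlap <- intersect(query, members)
    k <- length(overlap)
    data.frame(set_name = s$name, k = k, n = n, K = K, N = N,
               p = hypergeometric_upper(k, K, n, N),
               genes = paste(sort(overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(set_name = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0), genes = character(0)))
  res <- do.call(rbind, rows)
  res$q <- adjust_bh(res$p)
  res$significant <- res$q < q_threshold
  res <- res[order(res$p), c("set_name", "k", "n", "K", "N", "p", "q",
                             "significant", "genes")]
  rownames(res) <- NULL
  res
}
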