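#' SAM relative-difference statistic
#'
#' Two-class unpaired SAM statistic per feature:
#' `d_i = (mean_case - mean_control) / (s_i + s0)` with
#' `s_i = sqrt((1/n1 + 1/n2) * (SS_case + SS_free) / (n1 + n2 - 2))`, the
#' pooled-SD "gene-specific scatter" of the SAM method, and `s0` the
#' exchangeability constant that damps the statistic for low-variance
#' features.
#'
#' @param x log2 expression matrix, features x samples.
#' @param group character vector over columns of `x`, values `"case"` /
#'   `"control"`, each group with at least 2 samples.
#' @param s0 exchangeability constant (>= 0).
#' @return data.frame with `feature`, `d`, `s` (pooled SD term), `r`
#'   (mean difference, case - control).
#' @export
sam_statistic <- function(x, group, s0 = 0) {
  stopifnot(is.matrix(x), length(group) == ncol(x))
  if (!all(group %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  i1 <- group == "case"
  i2 <- group == "control"
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  ss1 <- rowSums((x[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, i2, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  r <- m1 - m2
  data.frame(feature = rownames(x), d = r / (s + s0), s = s, r = r,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Estimate the SAM exchangeability constant s0
#'
#' Chooses `s0` over a percentile grid of the per-feature scatter `s`
#' (0, 0.05, ..., 1) so that the coefficient of variation of the
#' median-absolute-deviation of `d = r / (s + s0)` across `s`-quantile
#' windows is minimal -- the original SAM tuning that removes the
#' dependence of `|d|` on `s`. Fully deterministic; ties resolve to the
#' smallest percentile.
#'
#' @param s per-feature pooled SD values.
#' @param d_raw per-feature statistic at `s0 = 0` (i.e. `r / s`).
#' @return chosen `s0` (>= 0).
#' @export
estimate_s0 <- function(s, d_raw) {
  stopifnot(length(s) == length(d_raw))
  if (length(s) < 10) {
    warning("fewer than 10 features; falling back to s0 = median(s)")
    return(stats::median(s))
  }
  r <- d_raw * s
  alphas <- seq(0, 1, by = 0.05)
  breaks <- unique(stats::quantile(s, seq(0, 1, by = 0.1)))
  win <- if (length(breaks) >= 3)
    cut(s, breaks = breaks, include.lowest = TRUE) else factor(rep(1, length(s)))
  cv <- vapply(alphas, function(a) {
    s0a <- stats::quantile(s, a)
    da <- r / (s + s0a)
    v <- tapply(da, win, stats::mad)
    v <- v[is.finite(v)]
    if (length(v) < 2 || mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  best <- which.min(cv)  # all Inf -> first alpha; s0 = quantile(s, 0)
  as.numeric(stats::quantile(s, alphas[best]))
}

#' SAM permutation analysis with FDR estimation
#'
#' Permutes group labels (all distinct relabelings when their number does
#' not exceed `n_perm`, otherwise `n_perm` seeded random shuffles),
#' recomputes `d` for each permutation, and for each threshold Delta on a
#' grid calls features whose ordered `d` departs from the permutation-mean
#' order statistics by more than Delta (scanning up and down from the
#' origin, as in the original SAM procedure). The false discovery rate at
#' each Delta is `pi0 * median permutation false calls / observed calls`,
#' with `pi0` estimated from the fraction of observed `d` inside the
#' central (25th--75th) permutation quantiles. Each feature's `q` is the
#' smallest FDR at any Delta at which it is called.
#'
#' Permutations are generated from the label multiset only, so swapping the
#' case/control labels negates every `d` and swaps the up/down sets exactly.
#'
#' A paired variant is available via `pairs`: `d` becomes the one-sample SAM
#' statistic of the per-pair differences and permutations become sign flips
#' (exhaustive when `2^k <= n_perm`).
#'
#' @param x log2 expression matrix, features x samples.
#' @param group character vector of `"case"` / `"control"` labels.
#' @param s0 exchangeability constant; `NULL` (default) estimates it with
#'   [estimate_s0()].
#' @param n_perm number of permutations (>= 100).
#' @param fdr FDR threshold for the reported up/down sets.
#' @param n_delta number of Delta grid points spanning `[0, max|d|]`.
#' @param seed RNG seed for sampled permutations.
#' @param pairs optional 2-column matrix/data.frame of (case, control)
#'   sample names selecting the paired statistic.
#' @param perm_mode `"auto"` (exhaustive enumeration whenever the number of
#'   distinct relabelings does not exceed `n_perm`) or `"sampled"` (always
#'   draw random permutations).
#' @param balanced restrict sampled permutations to balanced relabelings
#'   (each pseudo-group receives its proportional share of true cases), the
#'   default; `FALSE` samples uniformly over all relabelings, the estimand
#'   of the exhaustive enumeration. Ignored when enumeration is exhaustive.
#' @return a `sam_result` list: `table` (feature, d, s, r, q), `s0`,
#'   `fdr_table` (delta, n_called, false_median, fdr), `up`, `down`,
#'   `n_perm` (used), `exhaustive`, `seed`, `fdr_threshold`.
#' @export
sam_fdr <- function(x, group, s0 = NULL, n_perm = 1000, fdr = 0.1,
                    n_delta = 50, seed = 1, pairs = NULL,
                    perm_mode = c("auto", "sampled"), balanced = TRUE) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  perm_mode <- match.arg(perm_mode)
  if (is.null(pairs)) {
    obs <- sam_statistic(x, group, s0 = 0)
  } else {
    pairs <- as.matrix(pairs)
    obs <- sam_statistic_paired(x, pairs, s0 = 0)
  }
  d_raw <- obs$r / pmax(obs$s, .Machine$double.eps)
  if (is.null(s0)) s0 <- estimate_s0(obs$s, d_raw)
  d <- obs$r / (obs$s + s0)
  m <- length(d)

  set.seed(seed)
  if (is.null(pairs)) {
    D <- sam_perm_unpaired(x, group, s0, n_perm,
                           force_sampled = perm_mode == "sampled",
                           balanced = balanced)
  } else {
    D <- sam_perm_paired(x, pairs, s0, n_perm)
  }

  dsort_perm <- apply(D$d, 2, sort)
  dbar <- rowMeans(dsort_perm)
  o <- order(d)
  ds <- d[o]

  qq <- stats::quantile(D$d, c(0.25, 0.75))
  pi0 <- min(1, sum(d >= qq[1] & d <= qq[2]) / (0.5 * m))

  deltas <- seq(0, max(abs(d)), length.out = n_delta)
  qi <- rep(Inf, m)
  fdr_tab <- data.frame(delta = deltas, n_called = NA_real_,
                        false_median = NA_real_, fdr = NA_real_)
  nonneg <- which(ds >= 0)
  nonpos <- rev(which(ds <= 0))
  exceed <- ds - dbar
  for (j in seq_along(deltas)) {
    dd <- deltas[j]
    iu <- nonneg[exceed[nonneg] > dd]
    cut_up <- if (length(iu)) ds[iu[1]] else Inf
    il <- nonpos[exceed[nonpos] < -dd]
    cut_low <- if (length(il)) ds[il[1]] else -Inf
    called <- d >= cut_up | d <= cut_low
    n_called <- sum(called)
    false_b <- colSums(D$d >= cut_up) + colSums(D$d <= cut_low)
    med_false <- stats::median(false_b)
    fdr_j <- if (n_called > 0) min(1, pi0 * med_false / n_called) else NA_real_
    fdr_tab$n_called[j] <- n_called
    fdr_tab$false_median[j] <- med_false
    fdr_tab$fdr[j] <- fdr_j
    if (n_called > 0) qi[called] <- pmin(qi[called], fdr_j)
  }
  qi[!is.finite(qi)] <- 1

  tab <- data.frame(feature = obs$feature, d = d, s = obs$s, r = obs$r,
                    q = qi, stringsAsFactors = FALSE)
  res <- list(table = tab, s0 = s0, fdr_table = fdr_tab,
              up = tab$feature[tab$q < fdr & tab$d > 0],
              down = tab$feature[tab$q < fdr & tab$d < 0],
              n_perm = D$n_perm, exhaustive = D$exhaustive, seed = seed,
              fdr_threshold = fdr)
  class(res) <- "sam_result"
  res
}

#' @export
print.sam_result <- function(x, ...) {
  cat("SAM permutation analysis\n")
  cat("  features:", nrow(x$table), "  s0:", signif(x$s0, 4),
      "  permutations:", x$n_perm,
      if (x$exhaustive) "(exhaustive)" else "(sampled)", "\n")
  cat("  at FDR <", x$fdr_threshold, ":", length(x$up), "up,",
      length(x$down), "down\n")
  invisible(x)
}

# Permutation d-matrix for the unpaired statistic. Uses indicator-matrix
# multiplication so all permutations are computed in two matrix products.
sam_perm_unpaired <- function(x, group, s0, n_perm, force_sampled = FALSE,
                              balanced = TRUE) {
  n <- ncol(x)
  n1 <- sum(group == "case")
  n2 <- n - n1
  n_all <- choose(n, n1)
  exhaustive <- n_all <= n_perm && !force_sampled
  if (exhaustive) {
    subsets <- utils::combn(n, n1)
    IND <- matrix(0, n, ncol(subsets))
    # pseudo-case sets are all size-n1 subsets; under a case/control label
    # swap these become the complements, so permuted d negate exactly
    IND[cbind(as.vector(subsets),
              rep(seq_len(ncol(subsets)), each = n1))] <- 1
  } else {
    # balanced permutations: each pseudo-case set contains (as nearly as
    # possible) the proportional share of true cases, so genuine effects
    # cancel inside the permuted groups instead of inflating the null.
    # Shuffles are drawn from the label multiset and accepted by a
    # swap-symmetric balance criterion, so a case/control label swap yields
    # exactly the complementary pseudo-case sets (and negated d).
    t_lo <- floor(n1 * n1 / n)
    t_hi <- ceiling(n1 * n1 / n)
    case_pos <- which(group == "case")
    IND <- matrix(0, n, n_perm)
    for (b in seq_len(n_perm)) {
      repeat {
        s <- which(group[sample.int(n)] == "case")
        if (!balanced) break
        t_b <- length(intersect(s, case_pos))
        if (t_b >= t_lo && t_b <= t_hi) break
      }
      IND[s, b] <- 1
    }
  }
  X2 <- x^2
  T1 <- rowSums(x); T2 <- rowSums(X2)
  S1 <- x %*% IND
  S2 <- X2 %*% IND
  m1 <- S1 / n1
  m2 <- (T1 - S1) / n2
  ss1 <- S2 - n1 * m1^2
  ss2 <- (T2 - S2) - n2 * m2^2
  ss1[ss1 < 0] <- 0; ss2[ss2 < 0] <- 0
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n - 2))
  list(d = (m1 - m2) / (s + s0), n_perm = ncol(IND),
       exhaustive = exhaustive)
}

# Permutation d-matrix for the paired statistic (sign flips of per-pair
# differences).
sam_perm_paired <- function(x, pairs, s0, n_perm) {
  diffs <- x[, pairs[, 1], drop = FALSE] - x[, pairs[, 2], drop = FALSE]
  k <- ncol(diffs)
  exhaustive <- 2^k <= n_perm
  if (exhaustive) {
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
    S <- t(S)
  } else {
    S <- matrix(sample(c(-1, 1), k * n_perm, replace = TRUE), k, n_perm)
  }
  M <- (diffs %*% S) / k
  SS <- rowSums(diffs^2)
  s2 <- (SS - k * M^2) / (k * (k - 1))
  s2[s2 < 0] <- 0
  list(d = M / (sqrt(s2) + s0), n_perm = ncol(S), exhaustive = exhaustive)
}

#' Paired SAM statistic
#'
#' One-sample SAM statistic on per-pair differences:
#' `d_i = mean(diff_i) / (s_i + s0)` with
#' `s_i = sqrt(sum((diff - mean)^2) / (k (k - 1)))` over `k` pairs.
#'
#' @param x log2 expression matrix.
#' @param pairs 2-column matrix of (case, control) sample names or indices.
#' @param s0 exchangeability constant.
#' @return data.frame `feature`, `d`, `s`, `r` (mean paired difference).
#' @export
sam_statistic_paired <- function(x, pairs, s0 = 0) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2 || nrow(pairs) < 2)
    stop("pairs must be a 2-column matrix with at least 2 pairs")
  diffs <- x[, pairs[, 1], drop = FALSE] - x[, pairs[, 2], drop = FALSE]
  k <- ncol(diffs)
  r <- rowMeans(diffs)
  s <- sqrt(rowSums((diffs - r)^2) / (k * (k - 1)))
  data.frame(feature = rownames(x), d = r / (s + s0), s = s, r = r,
             stringsAsFactors = FALSE, row.names = NULL)
}
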