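# Independent oracles and small fixture builders shared across tests.
# Every oracle is a literal, unoptimized re-statement of the defining
# formula, kept deliberately separate from the package implementation.

# literal SAM d statistic, feature by feature
oracle_sam_d <- function(x, group, s0) {
  i1 <- which(group == "case"); i2 <- which(group == "control")
  n1 <- length(i1); n2 <- length(i2)
  t(vapply(seq_len(nrow(x)), function(i) {
    a <- x[i, i1]; b <- x[i, i2]
    s <- sqrt((1 / n1 + 1 / n2) *
                (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
                (n1 + n2 - 2))
    r <- mean(a) - mean(b)
    c(d = r / (s + s0), s = s, r = r)
  }, numeric(3)))
}

# normal-equation OLS oracle
oracle_ols <- function(y, X) {
  xtx <- solve(t(X) %*% X)
  beta <- as.vector(xtx %*% t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(xtx))
  tval <- beta / se
  list(beta = beta, se = se, t = tval, p = 2 * pt(-abs(tval), df))
}

# exhaustive BH step-up oracle: q_i = min over ranks j >= rank(i) of
# p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# brute-force TOM via explicit triple loop
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - 1
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# exact upper-tail hypergeometric by combinatorial enumeration
oracle_hyper_upper <- function(k, K, n, N) {
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# brute-force average-linkage merge heights on a distance matrix
oracle_average_linkage_heights <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dd <- mean(D[clusters[[i]], clusters[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# small labelled expression matrix of iid noise
noise_expr <- function(n_feat, n_samp, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(rnorm(n_feat * n_samp, sd = sd), n_feat, n_samp,
         dimnames = list(sprintf("f%04d", seq_len(n_feat)),
                         sprintf("s%03d", seq_len(n_samp))))
}

# adjusted Rand index between two label vectors (via mclust)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
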