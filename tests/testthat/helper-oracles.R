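# Independent brute-force oracles. These deliberately use naive scalar
# loops, not the package's vectorized code paths.

# All permutations of a vector (n <= 7).
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(all_perms(v[-i]), function(p) c(v[i], p))
  }))
}

# Maximum total weight over all matchings of a non-negative weight matrix
# where 0 entries mean "no edge" (never counted, but never harmful either).
brute_force_matching <- function(W) {
  if (nrow(W) > ncol(W)) W <- t(W)
  n <- nrow(W); m <- ncol(W)
  best <- 0
  for (cols in utils::combn(m, n, simplify = FALSE)) {
    for (p in all_perms(cols)) {
      best <- max(best, sum(W[cbind(seq_len(n), p)]))
    }
  }
  best
}

# Exhaustive tripartite optimum: max total Tri-SIM over full assignments.
brute_force_tripartite <- function(c12, c13, c23) {
  n <- nrow(c12)
  best <- -Inf
  for (p in all_perms(seq_len(n))) {
    for (q in all_perms(seq_len(n))) {
      tot <- sum(c12[cbind(seq_len(n), p)] + c13[cbind(seq_len(n), q)] + c23[cbind(p, q)])
      best <- max(best, tot)
    }
  }
  best
}

# Scalar CLIP loss: double loop over cells, both directions.
oracle_clip_loss <- function(A, B, tau) {
  n <- nrow(A)
  tot <- 0
  for (i in seq_len(n)) {
    den_ab <- 0; den_ba <- 0
    for (k in seq_len(n)) {
      den_ab <- den_ab + exp(sum(A[i, ] * B[k, ]) / tau)
      den_ba <- den_ba + exp(sum(A[k, ] * B[i, ]) / tau)
    }
    pos <- exp(sum(A[i, ] * B[i, ]) / tau)
    tot <- tot - log(pos / den_ab) - log(pos / den_ba)
  }
  tot / n
}

# Scalar FOSCTTM: O(N^2) loops, both directions.
oracle_foscttm <- function(A, B) {
  n <- nrow(A)
  d <- function(x, y) sqrt(sum((x - y)^2))
  f1 <- f2 <- numeric(n)
  for (i in seq_len(n)) {
    true_d <- d(A[i, ], B[i, ])
    c1 <- 0; c2 <- 0
    for (j in seq_len(n)[-i]) {
      if (d(A[i, ], B[j, ]) < true_d) c1 <- c1 + 1
      if (d(A[j, ], B[i, ]) < true_d) c2 <- c2 + 1
    }
    f1[i] <- c1 / (n - 1); f2[i] <- c2 / (n - 1)
  }
  (mean(f1) + mean(f2)) / 2
}

# Scalar inverse Simpson over explicit neighbor lists.
oracle_simpson_inv <- function(neighbor_labels) {
  p <- table(neighbor_labels) / length(neighbor_labels)
  1 / sum(p^2)
}

# Scalar kNN accuracy; vote ties go to the nearest neighbor among the tied
# classes (mirrors the exported contract, computed with naive loops).
oracle_knn <- function(Ztr, ltr, Zte, lte, k) {
  n <- nrow(Zte)
  correct <- 0
  for (i in seq_len(n)) {
    dist <- sqrt(rowSums((Ztr - matrix(Zte[i, ], nrow(Ztr), ncol(Ztr), byrow = TRUE))^2))
    nn <- order(dist)[seq_len(k)]
    votes <- table(ltr[nn])
    top <- names(votes)[votes == max(votes)]
    pred <- if (length(top) == 1) top else {
      ltr[nn][ltr[nn] %in% top][1]
    }
    if (pred == lte[i]) correct <- correct + 1
  }
  correct / n
}

# ARI and NMI directly from the definition on a contingency table.
oracle_ari_nmi <- function(a, b) {
  n <- length(a)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2)); bj <- sum(choose(colSums(tab), 2))
  exp_idx <- ai * bj / choose(n, 2)
  ari <- (nij - exp_idx) / ((ai + bj) / 2 - exp_idx)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pa <- rowSums(tab) / n; pb <- colSums(tab) / n
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    pij <- tab[i, j] / n
    if (pij > 0) mi <- mi + pij * log(pij / (pa[i] * pb[j]))
  }
  list(ari = ari, nmi = mi / ((H(pa) + H(pb)) / 2))
}
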