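# Independent, naively-looped oracle implementations of every statistic the
# package computes in vectorized form. These stay deliberately dumb: scalar
# loops, no shared code with the package internals.

oracle_nndr <- function(H, reduced = FALSE, eps = 1e-8) {
  n <- nrow(H); d <- ncol(H)
  hbar <- numeric(d)
  for (j in 1:d) hbar[j] <- mean(H[, j])
  # pairwise Pearson correlations, zero-variance dimensions -> 0
  term2 <- 0
  for (i in 1:d) for (j in 1:d) {
    if (i == j) next
    xi <- H[, i] - mean(H[, i]); xj <- H[, j] - mean(H[, j])
    si <- sqrt(sum(xi^2)); sj <- sqrt(sum(xj^2))
    a <- if (si == 0 || sj == 0) 0 else sum(xi * xj) / (si * sj)
    term2 <- term2 + abs(a) / d^2
  }
  term3 <- 0
  for (j in 1:d) term3 <- term3 + abs(hbar[j]) / d
  if (reduced) return(term2 + term3)
  mad <- 0
  for (b in 1:n) for (j in 1:d) mad <- mad + abs(H[b, j] - hbar[j])
  mad <- mad / (n * d)
  1 / (mad + eps) + term2 + term3
}

oracle_cos <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

oracle_fa <- function(atac_H, rna_H, top_p) {
  Nu <- nrow(atac_H)
  best_sim <- numeric(Nu)
  for (b in 1:Nu) {
    sims <- numeric(nrow(rna_H))
    for (i in seq_len(nrow(rna_H)))
      sims[i] <- oracle_cos(atac_H[b, ], rna_H[i, ])
    best_sim[b] <- sims[which.max(sims)]   # which.max: lowest index on ties
  }
  m <- ceiling(top_p * Nu)
  sel <- order(-best_sim, seq_len(Nu))[1:m]
  -sum(best_sim[sel]) / m
}

oracle_ce <- function(P, labels) {
  tot <- 0
  for (b in seq_len(nrow(P))) tot <- tot - log(P[b, labels[b] + 1])
  tot / nrow(P)
}

oracle_ncl <- function(H, Hh, tau) {
  N <- nrow(H)
  sig <- function(a, b) exp(sum(a * b) / (tau * sqrt(sum(a^2)) *
                                            sqrt(sum(b^2))))
  tot <- 0
  for (b in 1:N) {
    d1 <- 0; d2 <- 0
    for (r in 1:N) {
      d1 <- d1 + sig(H[b, ], Hh[r, ])
      if (r != b) d1 <- d1 + sig(H[b, ], H[r, ])
      d2 <- d2 + sig(Hh[b, ], H[r, ])
      if (r != b) d2 <- d2 + sig(Hh[b, ], Hh[r, ])
    }
    tot <- tot + log(sig(H[b, ], Hh[b, ]) / d1) +
      log(sig(Hh[b, ], H[b, ]) / d2)
  }
  -tot / (2 * N)
}

oracle_auroc <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
  tot / (length(pos) * length(neg))
}

oracle_oscr <- function(e, pred, truth_codes, is_novel) {
  common <- which(!is_novel)
  novel <- which(is_novel)
  tot <- 0
  for (j in novel) {
    th <- e[j]
    cc <- 0
    for (i in common)
      if (pred[i] == truth_codes[i] && e[i] > th) cc <- cc + 1
    tot <- tot + cc / length(common)
  }
  tot / length(novel)
}

oracle_knn <- function(coords, k) {
  n <- nrow(coords)
  out <- matrix(0L, n, k)
  for (i in 1:n) {
    d <- numeric(n)
    for (j in 1:n) d[j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    d[i] <- Inf
    out[i, ] <- order(d, seq_len(n))[1:k]
  }
  out
}

# small random embedding batch, never degenerate
random_batch <- function(n, d) matrix(stats::rnorm(n * d), n, d)

# a small, quick benchmark configuration for pipeline tests
tiny_config <- function(seed = 42, ...) {
  args <- list(n_common_types = 3, n_novel_types = 1,
               cells_per_type_ref = 30, cells_per_type_target = 40,
               n_genes = 60, n_raw_features = 360, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_config, args)
}

tiny_train <- function(seed = 1, ...) {
  args <- list(epochs = 4, batch_size = 32, k0 = 8, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(train_config, args)
}
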