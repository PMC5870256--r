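# Independent oracles used across the suite. Each reimplements the target
# quantity by direct enumeration or closed form, never by calling the
# package's own code path.

# Exact HWE p by direct multinomial enumeration: probability of each
# heterozygote count conditional on allele counts, via log-factorials.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- 2 * n_hom_alt + n_het
  rare <- min(n_alt, 2 * n - n_alt)
  if (rare == 0) return(1)
  hs <- seq.int(rare %% 2, rare, by = 2)
  logp <- vapply(hs, function(h) {
    n_rr <- (rare - h) / 2
    n_cc <- n - h - n_rr
    lfactorial(n) - lfactorial(n_rr) - lfactorial(h) - lfactorial(n_cc) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# Quadratic-time Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(ps[i:m] * m / (i:m), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Upper-tail hypergeometric by explicit counting over subsets (combn) when
# feasible, else by the exact choose() sum.
hyper_oracle <- function(k, K, N, n, enumerate = FALSE) {
  if (k <= 0) return(1)
  if (enumerate) {
    draws <- utils::combn(N, n)
    hits <- colSums(draws <= K)       # genes 1..K carry the term
    return(mean(hits >= k))
  }
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Pairwise-complete squared Pearson correlation, textbook form.
r2_oracle <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  mx <- mean(x); my <- mean(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (den == 0) return(0)
  (num / den)^2
}

# Brute-force greedy clumping on a full r2 matrix (no windowing shortcuts
# beyond the bp radius rule itself).
clump_oracle <- function(ids, p, chrom, pos, r2mat, r2_cut, window_kb) {
  radius <- window_kb * 1000 / 2
  ord <- order(p, chrom, pos)
  processed <- logical(length(ids))
  index <- character()
  clumped <- list()
  for (j in ord) {
    if (processed[j]) next
    processed[j] <- TRUE
    nb <- which(!processed & chrom == chrom[j] & abs(pos - pos[j]) <= radius)
    hit <- nb[r2mat[j, nb] >= r2_cut]
    processed[hit] <- TRUE
    index <- c(index, ids[j])
    clumped[[ids[j]]] <- ids[hit]
  }
  list(index = index, clumped = clumped)
}

# Brute-force LD pruning: single lexicographic sweep over all pairs of a
# full r2 matrix (equivalent to the windowed scan when the window covers
# the panel).
prune_oracle <- function(ids, mafs, pos, r2mat, r2_max) {
  m <- length(ids)
  keep <- rep(TRUE, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (!keep[i] || !keep[j]) next
      if (r2mat[i, j] >= r2_max) {
        drop <- if (mafs[i] < mafs[j]) i
                else if (mafs[j] < mafs[i]) j
                else if (pos[i] > pos[j]) i else j
        keep[drop] <- FALSE
      }
    }
  }
  ids[keep]
}

# Closed-form OLS: coefficients, standard errors, t and p for one column.
ols_oracle <- function(y, X, col) {
  XtX <- solve(t(X) %*% X)
  beta <- XtX %*% t(X) %*% y
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(XtX) * sigma2)
  t <- beta[col] / se[col]
  list(beta = beta[col], se = se[col], t = t,
       p = 2 * stats::pt(-abs(t), df))
}

full_r2_matrix <- function(g) {
  m <- n_variants(g)
  out <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      out[i, j] <- out[j, i] <- r2_oracle(g$dosages[, i], g$dosages[, j])
    }
  }
  out
}
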