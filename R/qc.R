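#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test of HWE from genotype counts: conditional on the
#' observed allele counts, the two-sided p-value sums the probabilities of
#' all heterozygote counts whose conditional probability does not exceed the
#' observed one. The conditional distribution is computed by the standard
#' ratio recursion over heterozygote counts.
#'
#' @param n_hom_ref Count of reference-homozygotes.
#' @param n_het Count of heterozygotes.
#' @param n_hom_alt Count of alternate-homozygotes.
#' @return Two-sided exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("all genotype counts are zero")
  n_alt <- 2 * n_hom_alt + n_het
  rare <- min(n_alt, 2L * n - n_alt)
  if (rare == 0) return(1)                  # monomorphic: single configuration
  h0 <- rare %% 2L
  hs <- seq.int(h0, rare, by = 2L)
  # start the ratio recursion at the conditional mode so unnormalized values
  # never overflow at large genotype totals
  em <- rare * (2 * n - rare) / (2 * n)
  km <- which.min(abs(hs - em))
  probs <- numeric(length(hs))
  probs[km] <- 1
  up <- function(h) {                       # P(h+2)/P(h)
    n_rr <- (rare - h) / 2
    n_cc <- n - h - n_rr
    4 * n_rr * n_cc / ((h + 1) * (h + 2))
  }
  if (km < length(hs))
    for (k in km:(length(hs) - 1L)) probs[k + 1L] <- probs[k] * up(hs[k])
  if (km > 1)
    for (k in km:2L) probs[k - 1L] <- probs[k] / up(hs[k - 1L])
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hs)]
  if (is.na(p_obs))
    stop("heterozygote count incompatible with allele counts")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Quality-control filter for a genotype cohort
#'
#' Applies, in a fixed order, the standard pre-analysis filters: per-variant
#' missingness, per-individual missingness, minor allele frequency, and the
#' exact Hardy-Weinberg test (pooled across sites). Each filter operates on
#' the matrix surviving the previous step; the report records the removals
#' per step so counts are reproducible.
#'
#' @param g A `genotype_matrix`.
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param miss_var_max Maximum per-variant missingness (default 0.05).
#' @param miss_ind_max Maximum per-individual missingness (default 0.05).
#' @param hwe_p_min Variants with exact HWE p-value not exceeding this are
#'   removed (default 1e-4); i.e. a variant is kept when `p > hwe_p_min`.
#' @return List with `genotypes` (the filtered `genotype_matrix`) and
#'   `report` (a data frame, one row per step: step, threshold, number
#'   removed, variants and samples remaining).
#' @export
qc_filter <- function(g, maf_min = 0.01, miss_var_max = 0.05,
                      miss_ind_max = 0.05, hwe_p_min = 1e-4) {
  if (n_variants(g) == 0 || n_samples(g) == 0) stop("empty genotype matrix")
  report <- data.frame(step = character(), threshold = numeric(),
                       n_removed = integer(), n_variants = integer(),
                       n_samples = integer(), stringsAsFactors = FALSE)
  log_step <- function(step, thr, removed) {
    report[nrow(report) + 1L, ] <<- list(step, thr, removed,
                                         n_variants(g), n_samples(g))
  }
  # 1. per-variant missingness
  mv <- colMeans(is.na(g$dosages))
  keep <- mv <= miss_var_max
  if (!any(keep)) stop("all variants removed by per-variant missingness")
  g <- g[, keep]
  log_step("variant_missingness", miss_var_max, sum(!keep))
  # 2. per-individual missingness
  mi <- rowMeans(is.na(g$dosages))
  keep <- mi <= miss_ind_max
  if (!any(keep)) stop("all individuals removed by per-individual missingness")
  g <- g[keep, ]
  log_step("individual_missingness", miss_ind_max, sum(!keep))
  # 3. minor allele frequency (all-missing variants count as MAF 0)
  mafv <- maf(g)
  mafv[is.na(mafv)] <- 0
  keep <- mafv >= maf_min
  if (!any(keep)) stop("all variants removed by the MAF filter")
  g <- g[, keep]
  log_step("maf", maf_min, sum(!keep))
  # 4. Hardy-Weinberg (pooled over sites)
  d <- g$dosages
  n0 <- colSums(d == 0L, na.rm = TRUE)
  n1 <- colSums(d == 1L, na.rm = TRUE)
  n2 <- colSums(d == 2L, na.rm = TRUE)
  hp <- vapply(seq_len(ncol(d)), function(j) {
    if (n0[j] + n1[j] + n2[j] == 0) return(1)   # no observed genotypes
    hwe_exact_test(n0[j], n1[j], n2[j])
  }, numeric(1))
  keep <- hp > hwe_p_min
  if (!any(keep)) stop("all variants removed by the HWE filter")
  g <- g[, keep]
  log_step("hwe", hwe_p_min, sum(!keep))
  list(genotypes = g, report = report)
}

#' Composite linkage-disequilibrium r-squared of two dosage vectors
#'
#' Squared Pearson correlation of unphased dosages over pairwise-complete
#' observations (composite LD). If either vector has zero variance over the
#' complete pairs the result is defined as 0 and carries attribute
#' `zero_variance = TRUE`.
#'
#' @param x,y Dosage vectors (0/1/2, `NA` allowed).
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("fewer than 3 complete pairs")
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(structure(0, zero_variance = TRUE))
  unname(stats::cor(x, y)^2)
}

#' Banded pairwise-complete r-squared along the variant axis
#'
#' Computes, for every variant pair at column lag `1..max_lag` on the same
#' chromosome, the same composite-LD r-squared as [ld_r2()] (pairwise-complete
#' dosages), vectorised per lag. Used by [ld_prune()] and [clump()] so that
#' window scans do not recompute per-pair correlations.
#'
#' @param g A `genotype_matrix`.
#' @param max_lag Maximum column lag to compute.
#' @return A `max_lag` x `n_variants(g)` matrix; entry `[L, j]` is the
#'   r-squared between variant `j` and variant `j + L`, `NA` when the pair
#'   crosses a chromosome boundary, runs off the panel, or has fewer than 3
#'   complete pairs. Zero-variance pairs give 0.
#' @export
ld_r2_band <- function(g, max_lag) {
  M <- n_variants(g)
  X0 <- g$dosages
  storage.mode(X0) <- "double"
  W <- matrix(as.double(!is.na(X0)), nrow(X0), ncol(X0))
  X0[W == 0] <- 0
  X2 <- X0 * X0
  chrom <- g$variants$chrom
  band <- matrix(NA_real_, max_lag, M)
  # chunked BLAS cross-products: for a block of left columns, compute all
  # moments against the columns up to max_lag to the right in one matmul
  chunk <- 512L
  s <- 1L
  while (s <= M - 1L) {
    e <- min(s + chunk - 1L, M - 1L)
    hi <- min(e + max_lag, M)
    li <- s:e
    ri <- s:hi
    n_p <- crossprod(W[, li, drop = FALSE], W[, ri, drop = FALSE])
    sxy <- crossprod(X0[, li, drop = FALSE], X0[, ri, drop = FALSE])
    sx <- crossprod(X0[, li, drop = FALSE], W[, ri, drop = FALSE])
    sy <- crossprod(W[, li, drop = FALSE], X0[, ri, drop = FALSE])
    sxx <- crossprod(X2[, li, drop = FALSE], W[, ri, drop = FALSE])
    syy <- crossprod(W[, li, drop = FALSE], X2[, ri, drop = FALSE])
    for (L in seq_len(max_lag)) {
      j1 <- li[li + L <= M]
      if (!length(j1)) break
      a <- j1 - s + 1L                 # row index within the chunk
      b <- j1 + L - s + 1L             # column index within ri
      idx <- cbind(a, b)
      n <- n_p[idx]
      vx <- n * sxx[idx] - sx[idx]^2
      vy <- n * syy[idx] - sy[idx]^2
      num <- (n * sxy[idx] - sx[idx] * sy[idx])^2
      r2 <- ifelse(vx <= 0 | vy <= 0, 0, num / (vx * vy))
      r2[n < 3] <- NA_real_
      r2[chrom[j1] != chrom[j1 + L]] <- NA_real_
      band[L, j1] <- r2
    }
    s <- e + 1L
  }
  band
}

#' Greedy sliding-window LD pruning
#'
#' Windows of `window` variants advance by `step` within each chromosome.
#' Within a window, pairs are examined in ascending (i, j) order; whenever
#' both members are still retained and their r-squared (pairwise-complete,
#' as [ld_r2()]) is at least `r2_max`, the member with the smaller minor
#' allele frequency is dropped (tie: the one at the larger position). The
#' procedure is deterministic.
#'
#' @param g A `genotype_matrix` (typically QC-filtered).
#' @param r2_max r-squared threshold at or above which a pair is pruned
#'   (default 0.2).
#' @param window Window size in variants (default 50).
#' @param step Window advance in variants (default 5).
#' @param band Optional precomputed [ld_r2_band()] result with
#'   `max_lag >= window - 1`.
#' @return Character vector of retained variant IDs.
#' @export
ld_prune <- function(g, r2_max = 0.2, window = 50, step = 5, band = NULL) {
  M <- n_variants(g)
  if (M == 0) return(character())
  if (is.null(band)) band <- ld_r2_band(g, min(window - 1L, M - 1L))
  if (nrow(band) < min(window - 1L, M - 1L))
    stop("band max_lag smaller than window - 1")
  mafs <- maf(g)
  pos <- g$variants$pos
  # candidate pairs: lag <= window-1, r2 >= r2_max (NA = cross-chromosome)
  cand <- which(!is.na(band) & band >= r2_max, arr.ind = TRUE)
  keep <- rep(TRUE, M)
  if (nrow(cand)) {
    pi <- cand[, 2L]
    pj <- pi + cand[, 1L]
    ord <- order(pi, pj)
    pi <- pi[ord]; pj <- pj[ord]
    starts <- seq.int(1L, max(1L, M - 1L), by = step)
    first_in <- findInterval(starts - 1L, pi) + 1L
    for (w in seq_along(starts)) {
      s <- starts[w]
      e <- s + window - 1L
      k <- first_in[w]
      while (k <= length(pi) && pi[k] <= e) {
        i <- pi[k]; j <- pj[k]
        if (j <= e && keep[i] && keep[j]) {
          drop <- if (mafs[i] < mafs[j]) i
                  else if (mafs[j] < mafs[i]) j
                  else if (pos[i] > pos[j]) i else j
          keep[drop] <- FALSE
        }
        k <- k + 1L
      }
    }
  }
  g$variants$id[keep]
}
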