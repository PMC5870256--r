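test_that("genotype containers validate their invariants", {
  v <- toy_variants(3)
  s <- toy_samples(4)
  d <- matrix(0L, 4, 3)
  v2 <- v; v2$id[2] <- v2$id[1]
  expect_error(genotype_matrix(d, v2, s), "v001")
  expect_error(genotype_matrix(matrix(3L, 4, 3), v, s), "0, 1, 2")
  v3 <- v; v3$pos <- c(30, 20, 10)
  expect_error(genotype_matrix(d, v3, s), "strictly increasing")
  expect_error(genotype_matrix(d, v, s[1:3, ]), "inconsistent")
})

test_that("matrix and VCF dialects round-trip dosages losslessly", {
  g <- toy_genotypes(n = 5, m = 4, miss = 3)
  dir <- withr::local_tempdir()
  mp <- file.path(dir, "g.tsv")
  write_genotypes(g, mp, "matrix")
  smap <- file.path(dir, "map.tsv")
  write_sample_map(g$samples, smap)
  g2 <- read_genotypes(mp, "matrix", sample_map = smap)
  expect_identical(g2$dosages, g$dosages)
  expect_equal(g2$samples, g$samples)
  vp <- file.path(dir, "g.vcf")
  write_genotypes(g, vp, "vcf")
  g3 <- read_genotypes(vp, "vcf", sample_map = smap)
  expect_identical(unname(g3$dosages), unname(g$dosages))
  expect_equal(g3$variants$pos, g$variants$pos)
})

test_that("VCF GT codes parse to alt-allele counts with ./. as missing", {
  dir <- withr::local_tempdir()
  vp <- file.path(dir, "t.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="G">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "a", "b", "c", "d"),
                     collapse = "\t"),
               paste(c("1", "100", "rs1", "A", "G", ".", ".", ".", "GT",
                       "0/0", "0/1", "1/1", "./."), collapse = "\t"),
               paste(c("1", "200", "rs2", "T", "C", ".", ".", ".", "GT",
                       "1|0", "0|0", "1|1", "0/1"), collapse = "\t")), vp)
  g <- read_genotypes(vp, "vcf")
  expect_equal(unname(g$dosages[, "rs1"]), c(0L, 1L, 2L, NA))
  expect_equal(unname(g$dosages[, "rs2"]), c(1L, 0L, 2L, 1L))
})

test_that("duplicate variant IDs and unknown samples are reported by name", {
  dir <- withr::local_tempdir()
  mp <- file.path(dir, "dup.tsv")
  writeLines(c("IID\tv001\tv001", "s1\t0\t1", "s2\t1\t2"), mp)
  expect_error(read_genotypes(mp, "matrix"), "v001")
  g <- toy_genotypes(4, 3)
  mp2 <- file.path(dir, "g.tsv")
  write_genotypes(g, mp2, "matrix")
  expect_error(
    read_genotypes(mp2, "matrix",
                   sample_map = data.frame(IID = "someone_else",
                                           SITE_ID = "x")),
    "absent from the sample map")
})

test_that("the exact HWE test matches the enumeration oracle", {
  expect_equal(hwe_exact_test(50, 0, 0), 1)
  expect_equal(hwe_exact_test(5, 3, 2), hwe_oracle(5, 3, 2),
               tolerance = 1e-12)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-4)
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
  # exhaustive sweep over small totals (full sweep to 200 in acceptance)
  for (N in c(2, 5, 11, 20, 37)) {
    for (n2 in 0:N) {
      for (n1 in 0:(N - n2)) {
        n0 <- N - n1 - n2
        expect_equal(hwe_exact_test(n0, n1, n2), hwe_oracle(n0, n1, n2),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("hwe test is stable at cohort-scale counts", {
  p <- hwe_exact_test(1200, 1150, 300)
  expect_true(is.finite(p) && p > 0 && p <= 1)
  expect_equal(p, hwe_oracle(1200, 1150, 300), tolerance = 1e-9)
})

test_that("qc_filter removes exactly the offending rows and columns", {
  set.seed(42)
  n <- 40; m <- 6
  d <- matrix(rbinom(n * m, 2, 0.5), n, m)
  d[, 2] <- 0L                             # monomorphic: MAF below 1%
  d[1:(0.4 * n), 3] <- NA                  # 40% variant missingness
  d[4, ] <- NA; d[4, 1] <- 0L              # individual 83% missing
  d[, 5] <- 1L                             # all-heterozygote: HWE failure
  g <- genotype_matrix(d, toy_variants(m), toy_samples(n))
  res <- qc_filter(g)
  expect_setequal(res$genotypes$variants$id, c("v001", "v004", "v006"))
  expect_false("s004" %in% res$genotypes$samples$id)
  expect_equal(res$report$step,
               c("variant_missingness", "individual_missingness", "maf",
                 "hwe"))
  # bookkeeping: removals sum to input minus output
  expect_equal(sum(res$report$n_removed[c(1, 3, 4)]),
               m - n_variants(res$genotypes))
  expect_equal(res$report$n_removed[2], n - n_samples(res$genotypes))
})

test_that("qc_filter with extreme thresholds is the identity and it is idempotent", {
  g <- toy_genotypes(n = 20, m = 8, miss = 5)
  res <- qc_filter(g, maf_min = 0, miss_var_max = 1, miss_ind_max = 1,
                   hwe_p_min = 0)
  expect_identical(res$genotypes$dosages, g$dosages)
  once <- qc_filter(g)
  twice <- qc_filter(once$genotypes)
  expect_identical(twice$genotypes$dosages, once$genotypes$dosages)
  expect_true(all(twice$report$n_removed == 0))
})

test_that("ld_r2 is the squared pairwise-complete Pearson correlation", {
  x <- c(0, 1, 2, 0, 1, 2)
  expect_equal(as.numeric(ld_r2(x, x)), 1)
  y <- c(0, 0, 0, 2, 2, 2)
  expect_equal(as.numeric(ld_r2(x, y)), 0)
  set.seed(1)
  a <- rbinom(20, 2, 0.5); b <- rbinom(20, 2, 0.3)
  a[3] <- NA; b[7] <- NA
  expect_equal(as.numeric(ld_r2(a, b)), r2_oracle(a, b), tolerance = 1e-12)
  expect_error(ld_r2(c(0, 1, NA), c(NA, 1, 2)), "complete pairs")
  z <- rep(1, 10)
  res <- ld_r2(z, rbinom(10, 2, 0.5))
  expect_equal(as.numeric(res), 0)
  expect_true(attr(res, "zero_variance"))
})

test_that("the banded r2 agrees with per-pair ld_r2 including missing data", {
  g <- toy_genotypes(n = 30, m = 12, seed = 4, miss = 20)
  band <- ld_r2_band(g, 5)
  for (L in 1:5) {
    for (j in 1:(12 - L)) {
      expect_equal(band[L, j],
                   as.numeric(ld_r2(g$dosages[, j], g$dosages[, j + L])),
                   tolerance = 1e-12)
    }
  }
})

test_that("ld_prune keeps independent variants and drops the lower-MAF duplicate", {
  set.seed(2)
  d <- matrix(rbinom(40 * 5, 2, 0.5), 40, 5)       # independent variants
  g <- genotype_matrix(d, toy_variants(5), toy_samples(40))
  if (max(full_r2_matrix(g)[upper.tri(diag(5))]) < 0.2) {
    expect_setequal(ld_prune(g), g$variants$id)
  }
  # duplicated variant: exactly one survives, the lower-MAF one is dropped
  d2 <- cbind(d[, 1], d[, 1], d[, 3])
  d2[1:8, 1] <- 0L                                  # lowers MAF of copy 1
  d2[1:8, 2] <- 1L
  g2 <- genotype_matrix(d2, toy_variants(3), toy_samples(40))
  kept <- ld_prune(g2)
  expect_true(xor("v001" %in% kept, "v002" %in% kept))
  mafs <- maf(g2)
  dropped <- setdiff(c("v001", "v002"), kept)
  expect_equal(unname(mafs[dropped]), min(mafs[c("v001", "v002")]))
})

test_that("windowed pruning equals the brute-force sweep on a block panel", {
  cfg <- small_config(n_populations = 2, n_per_pop = 60, n_variants = 30,
                      n_chromosomes = 1, ld_block_size = 6, ld_rho = 0.85,
                      n_causal = 10, missing_rate = 0, seed = 9)
  g <- simulate_cohort(cfg)$genotypes
  kept <- ld_prune(g, r2_max = 0.2, window = 50, step = 5)
  oracle <- prune_oracle(g$variants$id, maf(g), g$variants$pos,
                         full_r2_matrix(g), 0.2)
  expect_identical(kept, oracle)
  # direct post-condition: no surviving pair in-window with r2 >= cut
  r2m <- full_r2_matrix(g)
  ki <- match(kept, g$variants$id)
  pairs <- combn(ki, 2)
  in_window <- abs(pairs[1, ] - pairs[2, ]) <= 49
  expect_true(all(r2m[t(pairs)][in_window] < 0.2))
})
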