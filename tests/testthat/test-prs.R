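make_panel <- function() {
  set.seed(8)
  d <- matrix(rbinom(30 * 5, 2, 0.5), 30, 5)
  v <- toy_variants(5)
  v$ref <- c("A", "A", "A", "T", "C")
  v$alt <- c("C", "G", "G", "G", "T")
  genotype_matrix(d, v, toy_samples(30))
}

panel_ss <- function(v, beta = seq(0.1, 0.5, by = 0.1),
                     p = c(1e-9, 1e-5, 1e-3, 0.2, 0.9)) {
  summary_stats(data.frame(id = v$id, chrom = v$chrom, pos = v$pos,
                           effect_allele = v$alt, other_allele = v$ref,
                           beta = beta, p = p, stringsAsFactors = FALSE),
                trait = "toy")
}

test_that("harmonize keeps, flips, and drops alleles per the matching rules", {
  g <- make_panel()
  ss <- panel_ss(g$variants)
  # flip variant 2 labels, mismatch variant 3
  ss$effect_allele[2] <- g$variants$ref[2]
  ss$other_allele[2] <- g$variants$alt[2]
  ss$other_allele[3] <- "T"
  h <- harmonize(ss, g)
  expect_equal(nrow(h), 4)
  expect_equal(h$beta[h$id == "v001"], 0.1)            # unchanged
  expect_equal(h$beta[h$id == "v002"], -0.2)           # sign flipped
  expect_false("v003" %in% h$id)                       # mismatch dropped
  expect_equal(attr(h, "n_flipped"), 1L)
  expect_equal(attr(h, "n_dropped_mismatch"), 1L)
  # ambiguous pairs removed on request (v004 T/G fine, v005 C/T fine)
  ss2 <- panel_ss(g$variants)
  ss2$effect_allele[1] <- "T"; ss2$other_allele[1] <- "A"
  g2 <- g; g2$variants$ref[1] <- "A"; g2$variants$alt[1] <- "T"
  h2 <- harmonize(summary_stats(ss2, "toy"), g2, drop_ambiguous = TRUE)
  expect_false("v001" %in% h2$id)
  other <- panel_ss(g$variants)
  other$id <- paste0("zz", other$id)
  expect_error(harmonize(summary_stats(other, "t"), g), "no overlapping")
})

test_that("MHC exclusion uses inclusive configurable bounds", {
  ss <- summary_stats(
    data.frame(id = c("a", "b", "c", "d"), chrom = c("6", "6", "6", "2"),
               pos = c(30e6, 25999999, 34e6, 30e6),
               effect_allele = "G", other_allele = "A", beta = 1, p = 0.5,
               stringsAsFactors = FALSE), "t")
  out <- exclude_mhc(ss)
  expect_setequal(out$id, c("b", "d"))        # boundary pos retained
  no6 <- summary_stats(as.data.frame(ss)[ss$chrom != "6", ], "t")
  expect_equal(exclude_mhc(no6)$id, "d")      # no chr6: identity
})

test_that("clumping follows the greedy p-ordered rule and matches the oracle", {
  # all pairwise r2 below the cutoff: every variant is its own index
  g <- make_panel()
  ss <- panel_ss(g$variants)
  if (max(full_r2_matrix(g)[upper.tri(diag(5))]) < 0.3) {
    cl <- clump(ss, g)
    expect_setequal(cl$index, ss$id)
    expect_true(all(lengths(cl$clumped) == 0))
  }
  # duplicated pair 10 kb apart: better p wins, other clumped
  set.seed(3)
  x <- rbinom(50, 2, 0.5)
  d <- cbind(x, x)
  v <- toy_variants(2); v$pos <- c(100000L, 110000L)
  g2 <- genotype_matrix(d, v, toy_samples(50))
  ss2 <- summary_stats(data.frame(id = v$id, chrom = v$chrom, pos = v$pos,
                                  effect_allele = v$alt,
                                  other_allele = v$ref, beta = 0.1,
                                  p = c(1e-8, 1e-4)), "t")
  cl2 <- clump(ss2, g2)
  expect_equal(cl2$index, "v001")
  expect_equal(cl2$clumped$v001, "v002")
  # 40-variant LD-block panel vs brute-force full-matrix oracle
  cfg <- small_config(n_populations = 2, n_per_pop = 80, n_variants = 40,
                      n_chromosomes = 1, ld_block_size = 8, ld_rho = 0.85,
                      missing_rate = 0, seed = 14)
  st <- simulate_study(cfg)
  g3 <- st$genotypes
  h <- harmonize(st$sumstats$trait_1, g3)
  cl3 <- clump(h, g3)
  oracle <- clump_oracle(h$id, h$p, h$chrom, h$pos, full_r2_matrix(g3),
                         0.3, 500)
  # oracle works in summary-stat order; compare as sets and per index
  expect_identical(cl3$index, oracle$index)
  for (ix in cl3$index)
    expect_setequal(cl3$clumped[[ix]], oracle$clumped[[ix]])
  # row-order invariance
  hshuf <- summary_stats(h[sample(nrow(h)), ], "t")
  cl4 <- clump(hshuf, g3)
  expect_identical(cl4$index, cl3$index)
})

test_that("scores follow the raw-sum, mean-imputed contract", {
  g <- make_panel()
  ss <- panel_ss(g$variants, beta = rep(0, 5))
  cl <- clump(ss, g)
  prs0 <- prs_score(ss, cl, g)
  expect_true(all(prs0$scores == 0))
  # single variant, beta 0.5, dosage 2 -> score 1
  v <- toy_variants(1)
  g1 <- genotype_matrix(matrix(c(2L, 0L, 1L), 3, 1), v, toy_samples(3))
  ss1 <- summary_stats(data.frame(id = "v001", chrom = "1", pos = 10000,
                                  effect_allele = "C", other_allele = "A",
                                  beta = 0.5, p = 1e-4), "t")
  cl1 <- clump(ss1, g1)
  pr1 <- suppressWarnings(prs_score(ss1, cl1, g1, thresholds = c(1e-5, 1)))
  expect_warning(prs_score(ss1, cl1, g1, thresholds = c(1e-6, 1)),
                 "score column is zero")
  expect_equal(unname(pr1$scores[, 2]), c(1, 0, 0.5))
  expect_equal(pr1$n_snps, c(0L, 1L))
  # 3-variant toy with one flipped allele and one missing genotype
  d <- rbind(c(2L, 1L, 0L), c(0L, NA, 1L), c(1L, 2L, 2L), c(1L, 1L, 1L))
  v3 <- toy_variants(3, spacing = 1000000L)   # far apart: no clumping
  g3 <- genotype_matrix(d, v3, toy_samples(4))
  ss3 <- data.frame(id = v3$id, chrom = v3$chrom, pos = v3$pos,
                    effect_allele = c(v3$alt[1], v3$ref[2], v3$alt[3]),
                    other_allele = c(v3$ref[1], v3$alt[2], v3$ref[3]),
                    beta = c(0.5, 0.3, -0.2), p = c(1e-4, 1e-3, 1e-2),
                    stringsAsFactors = FALSE)
  h3 <- harmonize(summary_stats(ss3, "t"), g3)
  cl3 <- clump(h3, g3)
  pr3 <- prs_score(h3, cl3, g3, thresholds = c(0.05))
  # hand oracle: beta2 flips to -0.3; missing dosage -> column mean 4/3
  b <- c(0.5, -0.3, -0.2)
  D <- d; storage.mode(D) <- "double"
  D[2, 2] <- mean(d[-2, 2])
  expect_equal(unname(pr3$scores[, 1]), as.vector(D %*% b),
               tolerance = 1e-12)
  expect_true(!is.unsorted(pr3$n_snps))
  # the average convention is a per-column constant rescaling of the sum
  pra <- prs_score(h3, cl3, g3, thresholds = c(0.05), average = TRUE)
  expect_equal(unname(pra$scores[, 1]),
               unname(pr3$scores[, 1]) / (2 * pr3$n_snps[1]))
})

test_that("association Z is invariant to allele relabeling and PRS rescaling", {
  st <- shared_study()
  core <- run_core_pipeline(st, K = 4)
  g <- core$genotypes
  h <- core$harmonized$trait_1
  prs <- core$prs_list$trait_1
  y <- boxcox_transform(env_broadcast(st$environment, core$sites,
                                      "winter_min_temp"))$transformed
  f0 <- fit_prs_env(prs$scores[, 12], y, core$pcs)
  # relabel ref/alt for a subset of panel variants and recompute end-to-end
  flip_ids <- g$variants$id[seq(1, n_variants(g), by = 7)]
  g2 <- g
  fi <- match(flip_ids, g2$variants$id)
  g2$dosages[, fi] <- 2L - g2$dosages[, fi]
  tmp <- g2$variants$ref[fi]
  g2$variants$ref[fi] <- g2$variants$alt[fi]
  g2$variants$alt[fi] <- tmp
  h2 <- harmonize(st$sumstats$trait_1, g2)
  cl2 <- clump(h2, g2)
  pr2 <- prs_score(h2, cl2, g2)
  expect_identical(cl2$index, core$clumps$trait_1$index)
  f2 <- fit_prs_env(pr2$scores[, 12], y, core$pcs)
  expect_equal(f2$z, f0$z, tolerance = 1e-8)
  # scores shift by a per-individual constant sum(2*beta) over flipped SNPs
  shift <- pr2$scores[, 12] - prs$scores[, 12]
  expect_lt(diff(range(shift)), 1e-8)
  # affine rescaling of the PRS column leaves Z unchanged
  f3 <- fit_prs_env(3.7 * prs$scores[, 12] - 11, y, core$pcs)
  expect_equal(f3$z, f0$z, tolerance = 1e-8)
})
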