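test_that("the generator is fully deterministic under a fixed seed", {
  s1 <- simulate_study(small_config())
  s2 <- simulate_study(small_config())
  expect_identical(s1$genotypes$dosages, s2$genotypes$dosages)
  expect_identical(s1$sumstats, s2$sumstats)
  expect_identical(s1$environment, s2$environment)
  expect_identical(s1$annotation, s2$annotation)
})

test_that("degenerate configurations are rejected", {
  expect_error(small_config(fst = 0), "fst")
  expect_error(small_config(n_per_pop = 1), "n_per_pop")
  expect_error(small_config(ld_rho = 1), "ld_rho")
  expect_error(small_config(missing_rate = 0.2), "missing_rate")
  bad <- default_env_spec()
  bad$cor[1, 2] <- bad$cor[2, 1] <- 2
  expect_error(small_config(env_spec = bad), "positive semi-definite")
  expect_error(small_config(driver = "no_such_var"), "driver")
})

test_that("F near zero collapses population differentiation", {
  cfg <- small_config(n_populations = 2, fst = 1e-4, n_variants = 2000,
                      missing_rate = 0)
  tr <- simulate_truth(cfg)
  expect_lt(mean(abs(tr$pop_freq[, 1] - tr$pop_freq[, 2])), 0.01)
})

test_that("Hudson FST on truth frequencies recovers the Balding-Nichols F", {
  cfg <- small_config(n_populations = 10, fst = 0.05, n_variants = 5000)
  tr <- simulate_truth(cfg)
  est <- fst_hudson(tr$pop_freq)
  expect_gt(est, 0.05 * 0.8)
  expect_lt(est, 0.05 * 1.2)
})

test_that("emitted genotype frequencies track truth within binomial tolerance", {
  st <- shared_study()
  cfg <- st$config
  for (k in c(1, cfg$n_populations)) {
    rows <- st$genotypes$samples$site_id == sprintf("site_%02d", k)
    phat <- colMeans(st$genotypes$dosages[rows, ], na.rm = TRUE) / 2
    p <- st$truth$pop_freq[, k]
    tol <- 4 * sqrt(pmax(p * (1 - p), 0.01) / (2 * cfg$n_per_pop))
    expect_gt(mean(abs(phat - p) <= tol, na.rm = TRUE), 0.98)
  }
})

test_that("selection gradient is an identity at s = 0 and clips at the bounds", {
  st <- shared_study()
  tr0 <- apply_selection_gradient(st$truth, st$environment, 0)
  expect_identical(tr0$pop_freq, st$truth$pop_freq)
  expect_error(apply_selection_gradient(st$truth, st$environment, -0.1),
               ">= 0")
  env2 <- st$environment
  names(env2)[2] <- "renamed"
  attr(env2, "driver") <- NULL
  expect_error(apply_selection_gradient(st$truth, env2, 0.5,
                                        driver = "winter_min_temp"),
               "missing")
  # clipping: push a causal frequency far past 1
  tr <- st$truth
  j <- tr$traits$trait_1$causal[1]
  tr$pop_freq[j, ] <- 0.98
  tr$traits$trait_1$beta[j] <- 50
  shifted <- apply_selection_gradient(tr, st$environment, 1)
  z <- as.numeric(scale(st$environment$winter_min_temp))
  expect_true(all(shifted$pop_freq[j, z > 0] == 0.99))
  expect_true(all(shifted$pop_freq[j, z < 0] == 0.01))
})

test_that("selection induces frequency clines aligned with effect signs", {
  cfg <- small_config(n_populations = 40, n_variants = 1000, n_causal = 100,
                      seed = 3)
  env <- simulate_environment(cfg)
  tr <- simulate_truth(cfg)
  sh <- apply_selection_gradient(tr, env, 0.5)
  z <- as.numeric(scale(env$winter_min_temp))
  causal <- tr$traits$trait_1$causal
  beta <- tr$traits$trait_1$beta[causal]
  cors <- apply(sh$pop_freq[causal, ], 1, function(p) cor(p, z))
  expect_gt(mean(sign(cors) == sign(beta)), 0.9)
})

test_that("summary statistics have the closed-form standard error and are unbiased", {
  st <- shared_study()
  tr <- st$truth
  # closed form: p0 = 0.5, n_gwas = 50000 -> se = 1/sqrt(25000)
  tr$p0[] <- 0.5
  ss <- simulate_sumstats(tr, n_gwas = 50000, trait = 1, swap_fraction = 0)
  # recover se from beta/p relation on a null variant
  nulls <- which(tr$traits$trait_1$beta == 0)
  z <- abs(ss$beta[nulls] * sqrt(25000))
  expect_equal(2 * pnorm(-z), ss$p[nulls], tolerance = 1e-12)
  expect_error(simulate_sumstats(tr, n_gwas = 50), "at least 100")
  # unbiasedness: replicate draws around beta_true = 0.1
  tr2 <- tr
  tr2$traits$trait_1$beta[] <- 0.1
  reps <- vapply(1:200, function(i)
    mean(simulate_sumstats(tr2, 50000, trait = 1, swap_fraction = 0,
                           seed = 1000 + i)$beta), numeric(1))
  se_mean <- (1 / sqrt(25000)) / sqrt(length(tr2$p0)) / sqrt(200) * 3
  expect_lt(abs(mean(reps) - 0.1), se_mean + 1e-4)
})

test_that("null variants reject at the nominal rate", {
  cfg <- small_config(n_variants = 10000, n_causal = 2, seed = 5)
  tr <- simulate_truth(cfg)
  ss <- simulate_sumstats(tr, 50000, trait = 1, swap_fraction = 0)
  nulls <- tr$traits$trait_1$beta == 0
  frac <- mean(ss$p[nulls] < 0.05)
  tol <- 3 * sqrt(0.05 * 0.95 / sum(nulls))
  expect_lt(abs(frac - 0.05), tol)
})

test_that("environment draws honor the specified correlation structure", {
  vars <- paste0("v", 1:4)
  idspec <- list(variables = vars, cor = diag(4))
  cfg <- small_config(n_populations = 2000, env_spec = idspec,
                      driver = "v1")
  env <- simulate_environment(cfg)
  cc <- cor(as.matrix(env[, vars]))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.06)
  # planted 0.75 at 23 sites, Spearman within +-0.15
  cfg2 <- small_config(n_populations = 23)
  env2 <- simulate_environment(cfg2)
  rho <- cor(env2$winter_min_temp, env2$winter_max_temp,
             method = "spearman")
  expect_lt(abs(rho - 0.75), 0.15)
})

test_that("the planted term is enriched among causal-variant genes", {
  st <- shared_study()
  db <- st$annotation
  causal_ids <- st$truth$variants$id[st$truth$traits$trait_1$causal]
  causal_genes <- snps_to_genes(causal_ids, db)
  planted <- unique(db$terms$gene[db$terms$term == "term_planted"])
  rate_causal <- mean(causal_genes %in% planted)
  background_genes <- snps_to_genes(st$truth$variants$id, db)
  rate_bg <- mean(background_genes %in% planted)
  expect_gt(rate_causal, 2 * rate_bg)
})

test_that("within-block LD rises with ld_rho and across-block LD is near zero", {
  med_r2 <- vapply(c(0, 0.5, 0.9), function(rho) {
    cfg <- small_config(n_populations = 1, n_per_pop = 400, n_variants = 200,
                        n_chromosomes = 1, ld_block_size = 10, ld_rho = rho,
                        missing_rate = 0, seed = 11)
    co <- simulate_cohort(cfg)
    g <- co$genotypes
    blocks <- co$truth$variants$block
    r2_adj <- vapply(which(diff(blocks) == 0), function(j)
      as.numeric(ld_r2(g$dosages[, j], g$dosages[, j + 1])), numeric(1))
    median(r2_adj)
  }, numeric(1))
  expect_true(all(diff(med_r2) > 0))
  expect_lt(med_r2[1], 0.05)
  # across-block r2 ~ 0 at high rho
  cfg <- small_config(n_populations = 1, n_per_pop = 400, n_variants = 200,
                      n_chromosomes = 1, ld_block_size = 10, ld_rho = 0.9,
                      missing_rate = 0, seed = 12)
  co <- simulate_cohort(cfg)
  blocks <- co$truth$variants$block
  cross <- which(diff(blocks) != 0)
  r2_cross <- vapply(cross, function(j)
    as.numeric(ld_r2(co$genotypes$dosages[, j],
                     co$genotypes$dosages[, j + 1])), numeric(1))
  expect_lt(median(r2_cross), 0.05)
})

test_that("a written study round-trips through its on-disk formats", {
  st <- shared_study()
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  g2 <- read_genotypes(file.path(dir, "genotypes.tsv"), "matrix",
                       sample_map = file.path(dir, "sample_map.tsv"))
  expect_identical(g2$dosages, st$genotypes$dosages)
  expect_equal(g2$variants, st$genotypes$variants)
  ss2 <- read_sumstats(file.path(dir, "sumstats_trait_1.tsv"))
  expect_equal(ss2$beta, st$sumstats$trait_1$beta, tolerance = 1e-10)
  env2 <- read_environment(file.path(dir, "environment.tsv"))
  expect_equal(env2$winter_min_temp, st$environment$winter_min_temp,
               tolerance = 1e-10)
  db2 <- read_annotation(dir)
  expect_equal(db2$genes, st$annotation$genes)
})
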