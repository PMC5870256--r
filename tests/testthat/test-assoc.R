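test_that("Box-Cox transform honors its closed forms and recovers lognormality", {
  set.seed(1)
  y <- rlnorm(100)
  b1 <- boxcox_transform(y, lambda = 1)
  expect_equal(b1$transformed, y - 1, tolerance = 1e-12)
  b0 <- boxcox_transform(y, lambda = 0)
  expect_equal(b0$transformed, log(y), tolerance = 1e-12)
  set.seed(2)
  yl <- exp(rnorm(500))
  fit <- boxcox_transform(yl)
  expect_true(fit$lambda > -0.2 && fit$lambda < 0.2)
  expect_error(boxcox_transform(rep(3, 10)), "constant")
  expect_error(boxcox_transform(c(1, 1, 1, 2, 2, 2)), "5 distinct")
  # negative values are shifted to min 1
  yn <- c(-4, rnorm(50))
  bn <- boxcox_transform(yn)
  expect_equal(bn$shift, 5)
})

test_that("Box-Cox lambda agrees with the MASS profile grid", {
  skip_if_not_installed("MASS")
  set.seed(3)
  y <- rgamma(300, shape = 2)
  fit <- boxcox_transform(y)
  mb <- MASS::boxcox(y ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  expect_lt(abs(fit$lambda - mb$x[which.max(mb$y)]), 0.02)
})

test_that("fit_prs_env matches closed-form OLS and its degenerate limits", {
  set.seed(4)
  n <- 50
  pcs <- structure(list(scores = matrix(rnorm(2 * n), n, 2,
                                        dimnames = list(NULL, c("PC1", "PC2"))),
                        explained_variance = c(.5, .3), K = 2),
                   class = "pc_matrix")
  # planted slope
  prs <- rnorm(n)
  env <- 0.4 * prs + 0.2 * pcs$scores[, 1] + rnorm(n)
  f <- fit_prs_env(prs, env, pcs)
  X <- cbind(1, prs, pcs$scores)
  o <- ols_oracle(env, X, 2)
  expect_equal(f$z, unname(o$t), tolerance = 1e-8)
  expect_equal(f$p, unname(o$p), tolerance = 1e-8)
  expect_equal(f$beta, unname(o$beta), tolerance = 1e-8)
  # PRS orthogonal to env and covariates: coefficient ~ 0
  ro <- residuals(lm(rnorm(n) ~ env + pcs$scores))
  f0 <- fit_prs_env(ro, env, pcs)
  expect_lt(abs(f0$beta) * sd(ro), 1e-10 + 1e-8 * sd(env))
  expect_lt(f0$r2_incremental, 1e-10)
  # env identical to PRS, no covariates: incremental R2 = 1
  f1 <- fit_prs_env(prs, prs)
  expect_equal(f1$r2_incremental, 1, tolerance = 1e-12)
  # no covariates equals the textbook simple-regression t
  f2 <- fit_prs_env(prs, env)
  r <- cor(prs, env)
  expect_equal(f2$z, r * sqrt((n - 2) / (1 - r^2)), tolerance = 1e-10)
  # rank deficiency is reported with the offending column
  expect_error(fit_prs_env(prs, env, pcs,
                           extra = cbind(dup = pcs$scores[, 1])),
               "dup|PC1")
})

test_that("the association grid has full bookkeeping and is deterministic", {
  st <- shared_study()
  core <- run_core_pipeline(st, K = 4)
  sub_env <- st$environment[, c("site_id", "winter_min_temp",
                                "precip_rate", "consonant_count")]
  attr(sub_env, "driver") <- "winter_min_temp"
  class(sub_env) <- class(st$environment)
  grid <- prs_env_grid(core$prs_list, sub_env, core$pcs, core$sites)
  expect_equal(nrow(grid), 2 * 3 * 12)
  expect_equal(sum(grid$best), 6)
  expect_true(all(grid$n_snps[grid$best] > 0))
  ok <- !is.na(grid$p)
  expect_true(all(grid$p[ok] > 0 & grid$p[ok] <= 1))
  expect_true(all(grid$q[ok] > 0 & grid$q[ok] <= 1))
  expect_true(all(grid$r2_incremental[ok] >= -1e-12))
  grid2 <- prs_env_grid(core$prs_list, sub_env, core$pcs, core$sites)
  expect_identical(as.data.frame(grid), as.data.frame(grid2))
  # best-cell FDR scope adjusts only the flagged cells
  gb <- prs_env_grid(core$prs_list, sub_env, core$pcs, core$sites,
                     fdr_scope = "best")
  expect_true(all(is.na(gb$q[!gb$best])))
  expect_equal(gb$p, grid$p)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(fdr_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(5)
  for (i in 1:25) {
    m <- sample(1:400, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("permutation p-values follow the add-one estimator and match refits", {
  set.seed(6)
  n <- 40
  prs <- rnorm(n)
  env <- prs + rnorm(n, 0, 0.1)          # overwhelming signal
  pn <- permutation_null(prs, env, B = 199, seed = 1)
  expect_equal(pn$perm_p, 1 / 200)
  # degenerate constant PRS
  dg <- permutation_null(rep(2, n), env, B = 100)
  expect_true(dg$degenerate)
  expect_equal(dg$perm_p, 1)
  expect_error(permutation_null(prs, env, B = 0), "at least 1")
  expect_warning(permutation_null(prs, env, B = 50, seed = 1), "coarse")
  # the residualized statistic equals a full lm refit
  pcs <- structure(list(scores = matrix(rnorm(2 * n), n, 2,
                                        dimnames = list(NULL, c("PC1", "PC2"))),
                        explained_variance = c(.5, .3), K = 2),
                   class = "pc_matrix")
  pn2 <- suppressWarnings(permutation_null(prs, env, pcs, B = 5, seed = 2))
  f <- fit_prs_env(prs, env, pcs)
  expect_equal(pn2$z_obs, f$z, tolerance = 1e-10)
  # n = 4: sampled estimate near the exhaustive enumeration over 24 perms
  set.seed(7)
  x4 <- c(0.1, 1.3, -0.4, 0.8); y4 <- c(1, 0, 2, 1.5)
  tstat <- function(x, y) {
    r <- cor(x, y); r * sqrt(2) / sqrt(1 - r^2)
  }
  perms <- gtools_permutations <- do.call(rbind, lapply(
    combinat_perms <- list(
      c(1,2,3,4),c(1,2,4,3),c(1,3,2,4),c(1,3,4,2),c(1,4,2,3),c(1,4,3,2),
      c(2,1,3,4),c(2,1,4,3),c(2,3,1,4),c(2,3,4,1),c(2,4,1,3),c(2,4,3,1),
      c(3,1,2,4),c(3,1,4,2),c(3,2,1,4),c(3,2,4,1),c(3,4,1,2),c(3,4,2,1),
      c(4,1,2,3),c(4,1,3,2),c(4,2,1,3),c(4,2,3,1),c(4,3,1,2),c(4,3,2,1)),
    identity))
  t_all <- apply(perms, 1, function(ix) tstat(x4[ix], y4))
  t_obs <- tstat(x4, y4)
  exact_p <- mean(abs(t_all) >= abs(t_obs) - 1e-12)
  B <- 4000
  pn4 <- permutation_null(x4, y4, B = B, seed = 3)
  mc_se <- sqrt(exact_p * (1 - exact_p) / B)
  # permutations exactly tied with the observed statistic can fall on
  # either side of >= under floating-point noise; allow for their mass
  tie_mass <- mean(abs(abs(t_all) - abs(t_obs)) < 1e-9)
  expect_lt(abs(pn4$perm_p - exact_p), 2 * mc_se + tie_mass + 2 / B)
})

test_that("PC-depth comparison is null for identical or orthogonal extra components", {
  set.seed(8)
  n <- 60
  prs <- rnorm(n); env <- 0.3 * prs + rnorm(n)
  pcs <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, paste0("PC", 1:3)))
  cp <- compare_pc_models(prs, env, pcs, pcs)
  expect_equal(cp$statistic, 0)
  expect_equal(cp$p, 1)
  # identically-zero extra columns are rejected as rank deficient
  pcs20 <- cbind(pcs, PC4 = 0)
  expect_error(compare_pc_models(prs, env, pcs, pcs20), "rank-deficient")
})

test_that("driver analysis isolates the true driver among correlated proxies", {
  set.seed(9)
  nsite <- 23; nper <- 20
  hits_driver <- 0; hits_proxy <- 0
  reps <- 60
  for (r in 1:reps) {
    z <- rnorm(nsite)
    proxy <- 0.9 * z + sqrt(1 - 0.81) * rnorm(nsite)
    env <- data.frame(site_id = sprintf("site_%02d", 1:nsite),
                      drv = 5 + z, prx = 5 + proxy)
    class(env) <- c("environment_table", "data.frame")
    sites <- rep(env$site_id, each = nper)
    prs <- z[rep(1:nsite, each = nper)] * 0.8 + rnorm(nsite * nper)
    da <- driver_analysis(prs, env, c("drv", "prx"), pcs = NULL,
                          sites = sites)
    hits_driver <- hits_driver + da$driver[da$variable == "drv"]
    hits_proxy <- hits_proxy + da$driver[da$variable == "prx"]
  }
  expect_gt(hits_driver / reps, 0.8)
  expect_lt(hits_proxy / reps, hits_driver / reps)
  # singleton set reduces to the marginal fit
  z <- rnorm(nsite)
  env1 <- data.frame(site_id = sprintf("site_%02d", 1:nsite), drv = 5 + z)
  class(env1) <- c("environment_table", "data.frame")
  sites <- rep(env1$site_id, each = nper)
  prs <- rnorm(nsite * nper)
  da1 <- driver_analysis(prs, env1, "drv", pcs = NULL, sites = sites)
  f <- fit_prs_env(prs, boxcox_transform(env_broadcast(env1, sites,
                                                       "drv"))$transformed)
  expect_equal(da1$z, f$z, tolerance = 1e-10)
  # perfectly collinear covariate pair errors with a condition report
  env2 <- env1; env2$cpy <- env2$drv; env2$other <- rnorm(nsite)
  class(env2) <- c("environment_table", "data.frame")
  expect_error(driver_analysis(prs, env2, c("drv", "cpy", "other"),
                               pcs = NULL, sites = sites),
               "near-singular|rank")
})

test_that("Spearman matrices match the rank-then-Pearson oracle and flag Bonferroni", {
  env <- data.frame(site_id = sprintf("s%02d", 1:5),
                    a = c(1, 2, 2, 3, 4), b = c(2, 2, 4, 5, 9),
                    cc = c(5, 4, 3, 2, 1), e = c(1.5, 2, 7, 8.1, 20))
  class(env) <- c("environment_table", "data.frame")
  sm <- spearman_matrix(env)
  expect_equal(sm$rho["e", "cc"], -1)      # strictly monotone, no ties
  oracle <- cor(rank(env$a), rank(env$b))  # average ranks under ties
  expect_equal(sm$rho["a", "b"], oracle, tolerance = 1e-12)
  # constant variable flagged
  env$d <- 1
  sm2 <- spearman_matrix(env)
  expect_true("d" %in% sm2$constant)
  expect_true(all(is.na(sm2$rho["d", c("a", "b", "cc")])))
  # Bonferroni arithmetic: m = 10 pairs, p = 0.004 is flagged at 0.05
  expect_true(0.004 <= 0.05 / 10)
  expect_error(spearman_matrix(env[1:3, ]), "at least 4")
})
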