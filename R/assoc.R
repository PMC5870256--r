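#' Box-Cox power transformation by profile likelihood
#'
#' Normalizes a variable before regression. Values are shifted to be
#' strictly positive (`shift = 0` if the minimum is already positive, else
#' `1 - min`), then the power parameter maximizing the profile
#' log-likelihood is found over \[-5, 5\] (numerical tolerance 1e-5).
#' `|lambda| < 1e-8` is treated as the log transform.
#'
#' @param values Numeric vector with at least 5 distinct values.
#' @param lambda Optional fixed power parameter; `NULL` (default) estimates
#'   it by profile likelihood.
#' @return An object of class `boxcox_fit`: `lambda`, `shift`, `loglik`,
#'   and `transformed` (same length as input).
#' @export
boxcox_transform <- function(values, lambda = NULL) {
  if (any(is.na(values))) stop("missing values not allowed")
  if (length(unique(values)) < 2) stop("constant input")
  if (length(unique(values)) < 5)
    stop("at least 5 distinct values are required")
  shift <- if (min(values) > 0) 0 else 1 - min(values)
  y <- values + shift
  n <- length(y)
  slog <- sum(log(y))
  bc <- function(l) if (abs(l) < 1e-8) log(y) else (y^l - 1) / l
  prof <- function(l) {
    z <- bc(l)
    -n / 2 * log(mean((z - mean(z))^2)) + (l - 1) * slog
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(prof, c(-5, 5), maximum = TRUE, tol = 1e-5)
    lambda <- opt$maximum
    if (abs(lambda) < 1e-8) lambda <- 0
  }
  structure(list(lambda = lambda, shift = shift, loglik = prof(lambda),
                 transformed = bc(lambda)),
            class = "boxcox_fit")
}

#' Broadcast a site-level environmental variable to individuals
#'
#' @param env An `environment_table`.
#' @param sites Character vector: each individual's site ID.
#' @param variable Variable name.
#' @return Numeric vector, one value per individual.
#' @export
env_broadcast <- function(env, sites, variable) {
  if (!variable %in% names(env))
    stop("variable '", variable, "' not in the environment table")
  k <- match(sites, env$site_id)
  if (anyNA(k))
    stop("site(s) missing from the environment table: ",
         paste(unique(sites[is.na(k)]), collapse = ", "))
  env[[variable]][k]
}

build_design <- function(prs, pcs = NULL, extra = NULL, label = "PRS") {
  X <- cbind(`(Intercept)` = rep(1, length(prs)))
  X <- cbind(X, structure(matrix(prs, ncol = 1),
                          dimnames = list(NULL, label)))
  if (!is.null(pcs)) {
    sc <- if (inherits(pcs, "pc_matrix")) pcs$scores else as.matrix(pcs)
    X <- cbind(X, sc)
  }
  if (!is.null(extra)) X <- cbind(X, as.matrix(extra))
  X
}

ols_stats <- function(y, X) {
  n <- length(y)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    drop_cols <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  coef <- qr.coef(q, y)
  res <- y - X %*% coef
  rss <- sum(res^2)
  df <- n - ncol(X)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  names(se) <- colnames(X)
  list(coef = coef, se = se, rss = rss, df = df)
}

#' Regression of an environmental variable on a polygenic score
#'
#' Ordinary least squares of the (Box-Cox-transformed) environment on
#' intercept, PRS, ancestry principal components, and any extra covariates.
#' The test statistic is the t-statistic of the PRS coefficient; the
#' incremental R-squared is the gain in R-squared over the model without
#' the PRS term.
#'
#' @param prs Numeric PRS vector, one value per individual.
#' @param env Numeric (already transformed) environment vector broadcast to
#'   individuals.
#' @param pcs Optional `pc_matrix` (or plain score matrix).
#' @param extra Optional matrix/data frame of extra covariates.
#' @return An object of class `prs_env_fit`: `beta`, `se`, `z`
#'   (t-statistic), `p` (two-sided), `r2_incremental`, `df`, `n`.
#' @export
fit_prs_env <- function(prs, env, pcs = NULL, extra = NULL) {
  if (length(prs) != length(env))
    stop("prs and env must have the same length")
  X <- build_design(prs, pcs, extra)
  fit <- ols_stats(env, X)
  z <- unname(fit$coef["PRS"] / fit$se["PRS"])
  p <- max(2 * stats::pt(-abs(z), fit$df), 1e-300)
  X0 <- X[, colnames(X) != "PRS", drop = FALSE]
  fit0 <- ols_stats(env, X0)
  tss <- sum((env - mean(env))^2)
  r2 <- if (tss > 0) (fit0$rss - fit$rss) / tss else 0
  structure(list(beta = unname(fit$coef["PRS"]), se = unname(fit$se["PRS"]),
                 z = z, p = p, r2_incremental = max(r2, 0), df = fit$df,
                 n = length(env)),
            class = "prs_env_fit")
}

#' @export
print.prs_env_fit <- function(x, ...) {
  cat(sprintf("prs_env_fit: beta = %.4g (se %.4g), Z = %.3f, p = %.3g, incremental R2 = %.4g\n",
              x$beta, x$se, x$z, x$p, x$r2_incremental))
  invisible(x)
}

#' Fit the full trait x variable x threshold association grid
#'
#' The central scan: for every trait's PRS at every inclusion threshold and
#' every environmental variable, fits [fit_prs_env()] on the Box-Cox
#' transformed, site-broadcast variable with PC adjustment. Benjamini-
#' Hochberg q-values are computed over all cells (default) or over the
#' per-pair best cells; the best (smallest-p) cell per trait x variable
#' pair is flagged. Cells whose score column is empty or constant are
#' reported with `NA` statistics and excluded from FDR.
#'
#' @param prs_list Named list of `prs_matrix` objects, one per trait.
#' @param env An `environment_table`.
#' @param pcs A `pc_matrix`.
#' @param sites Character vector of per-individual site IDs, aligned with
#'   the PRS rows.
#' @param variables Variables to test (default: all non-ID columns).
#' @param fdr_scope `"all"` (BH over every cell) or `"best"` (BH over the
#'   per-pair best cells only).
#' @param transform Apply Box-Cox to each variable (default `TRUE`).
#' @param mode `"individual"` (default): site values broadcast to
#'   individuals, the convention of standard PRS analyses; `"site"`:
#'   PRS and PC scores are averaged per site and the regression runs on
#'   one row per site. The site mode is exactly calibrated under the
#'   global null (the response is independent across its rows), at the
#'   cost of residual degrees of freedom; see the package vignette.
#' @return An object of class `assoc_grid`: a data frame with columns
#'   `trait`, `variable`, `pt`, `n_snps`, `z`, `r2_incremental`, `p`, `q`,
#'   `best`, plus attributes `fdr_scope`, `mode` and `boxcox`.
#' @export
prs_env_grid <- function(prs_list, env, pcs, sites,
                         variables = setdiff(names(env), "site_id"),
                         fdr_scope = c("all", "best"), transform = TRUE,
                         mode = c("individual", "site")) {
  fdr_scope <- match.arg(fdr_scope)
  mode <- match.arg(mode)
  if (is.null(names(prs_list)) || any(!nzchar(names(prs_list))))
    names(prs_list) <- paste0("trait_", seq_along(prs_list))
  site_mean <- function(v) {
    as.numeric(tapply(v, factor(sites, levels = env$site_id), mean))
  }
  pcs_use <- pcs
  if (mode == "site" && !is.null(pcs)) {
    sc <- if (inherits(pcs, "pc_matrix")) pcs$scores else as.matrix(pcs)
    pcs_use <- apply(sc, 2, site_mean)
    colnames(pcs_use) <- colnames(sc)
  }
  bcs <- list()
  yvars <- list()
  for (v in variables) {
    vals <- if (mode == "site") env[[v]] else env_broadcast(env, sites, v)
    if (transform) {
      bc <- boxcox_transform(vals)
      bcs[[v]] <- bc[c("lambda", "shift", "loglik")]
      yvars[[v]] <- bc$transformed
    } else {
      yvars[[v]] <- vals
    }
  }
  rows <- list()
  for (tn in names(prs_list)) {
    prs <- prs_list[[tn]]
    for (ti in seq_along(prs$thresholds)) {
      sc <- prs$scores[, ti]
      if (mode == "site") sc <- site_mean(sc)
      degenerate <- prs$n_snps[ti] == 0 || stats::sd(sc) == 0
      for (v in variables) {
        if (degenerate) {
          rows[[length(rows) + 1L]] <-
            data.frame(trait = tn, variable = v, pt = prs$thresholds[ti],
                       n_snps = prs$n_snps[ti], z = NA_real_,
                       r2_incremental = NA_real_, p = NA_real_,
                       stringsAsFactors = FALSE)
        } else {
          f <- tryCatch(fit_prs_env(sc, yvars[[v]], pcs_use),
                        error = function(e)
                          stop("grid cell (", tn, ", ", v, ", PT=",
                               prs$thresholds[ti], "): ",
                               conditionMessage(e)))
          rows[[length(rows) + 1L]] <-
            data.frame(trait = tn, variable = v, pt = prs$thresholds[ti],
                       n_snps = prs$n_snps[ti], z = f$z,
                       r2_incremental = f$r2_incremental, p = f$p,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  grid <- do.call(rbind, rows)
  grid$q <- NA_real_
  grid$best <- FALSE
  pair <- paste(grid$trait, grid$variable, sep = "\r")
  for (pr in unique(pair)) {
    i <- which(pair == pr & !is.na(grid$p))
    if (length(i)) grid$best[i[which.min(grid$p[i])]] <- TRUE
  }
  if (fdr_scope == "all") {
    ok <- !is.na(grid$p)
    grid$q[ok] <- fdr_adjust(grid$p[ok])
  } else {
    b <- which(grid$best)
    grid$q[b] <- fdr_adjust(grid$p[b])
  }
  attr(grid, "fdr_scope") <- fdr_scope
  attr(grid, "mode") <- mode
  attr(grid, "boxcox") <- bcs
  class(grid) <- c("assoc_grid", "data.frame")
  grid
}

#' @export
print.assoc_grid <- function(x, q_cut = 0.05, ...) {
  cat("assoc_grid:", nrow(x), "cells (",
      length(unique(x$trait)), "traits x",
      length(unique(x$variable)), "variables x",
      length(unique(x$pt)), "thresholds ), FDR scope:",
      attr(x, "fdr_scope"), "\n")
  sig <- x[!is.na(x$q) & x$q < q_cut, ]
  cat(" ", nrow(sig), "cells with q <", q_cut, "\n")
  if (nrow(sig)) {
    sig <- sig[order(sig$p), ]
    print.data.frame(utils::head(sig, 10), row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
summary.assoc_grid <- function(object, ...) {
  best <- object[object$best, ]
  best <- best[order(best$p), ]
  rownames(best) <- NULL
  best
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return q-values, same length as `p`.
#' @export
fdr_adjust <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Permutation null for a single association cell
#'
#' Shuffles the PRS vector across individuals (environment and covariates
#' fixed), refits, and records the PRS t-statistic of each permutation.
#' The reported empirical p-value uses the add-one estimator
#' `(1 + #{|z_b| >= |z_obs|}) / (B + 1)`. Refits use the
#' Frisch-Waugh-Lovell residualization, which reproduces the full-OLS
#' t-statistic exactly.
#'
#' @param prs PRS vector.
#' @param env Transformed, broadcast environment vector.
#' @param pcs Optional `pc_matrix` or score matrix.
#' @param extra Optional extra covariates.
#' @param B Number of permutations (default 10000).
#' @param seed Optional seed for the permutation stream.
#' @return An object of class `perm_null`: `perm_p`, `z_obs`, `z_null`
#'   (length B), `B`, `degenerate`.
#' @export
permutation_null <- function(prs, env, pcs = NULL, extra = NULL, B = 10000,
                             seed = NULL) {
  if (B < 1) stop("B must be at least 1")
  if (B < 100) warning("B < 100 gives a very coarse empirical p-value")
  n <- length(prs)
  if (stats::sd(prs) == 0)
    return(structure(list(perm_p = 1, z_obs = NA_real_, z_null = numeric(),
                          B = B, degenerate = TRUE), class = "perm_null"))
  C <- build_design(numeric(n), pcs, extra)[, -2, drop = FALSE]  # no PRS col
  Q <- qr.Q(qr(C))
  df <- n - ncol(C) - 1L
  re <- env - Q %*% crossprod(Q, env)
  partial_t <- function(RP) {
    num <- colSums(RP * as.vector(re))
    den <- sqrt(colSums(RP^2) * sum(re^2))
    r <- ifelse(den > 0, num / den, 0)
    r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    r * sqrt(df) / sqrt(1 - r^2)
  }
  z_obs <- partial_t(matrix(prs - Q %*% crossprod(Q, prs), ncol = 1))
  if (!is.null(seed)) set.seed(seed)
  z_null <- numeric(B)
  chunk <- 2000L
  done <- 0L
  while (done < B) {
    nb <- min(chunk, B - done)
    P <- matrix(0, n, nb)
    for (b in seq_len(nb)) P[, b] <- prs[sample.int(n)]
    RP <- P - Q %*% crossprod(Q, P)
    z_null[done + seq_len(nb)] <- partial_t(RP)
    done <- done + nb
  }
  perm_p <- (1 + sum(abs(z_null) >= abs(z_obs))) / (B + 1)
  structure(list(perm_p = perm_p, z_obs = as.vector(z_obs), z_null = z_null,
                 B = B, degenerate = FALSE),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  if (x$degenerate) cat("perm_null: degenerate (constant PRS), perm_p = 1\n")
  else cat(sprintf("perm_null: z_obs = %.3f, perm_p = %.4g (B = %d)\n",
                   x$z_obs, x$perm_p, x$B))
  invisible(x)
}

#' Compare PRS coefficients under two PC adjustment depths
#'
#' Refits the association with a smaller and a larger set of principal
#' components and tests the difference in PRS coefficients with a
#' Clogg-type statistic for nested covariate sets:
#' `(b1 - b2) / sqrt(|se2^2 - se1^2| + eps)`, two-sided normal.
#'
#' @param prs PRS vector.
#' @param env Transformed, broadcast environment vector.
#' @param pcs_small,pcs_large The two PC adjustments (e.g. 10 and 20
#'   components).
#' @param eps Variance floor guarding the degenerate equal-model case
#'   (default 1e-12).
#' @return List with `fit_small`, `fit_large`, `statistic`, `p`.
#' @export
compare_pc_models <- function(prs, env, pcs_small, pcs_large, eps = 1e-12) {
  f1 <- fit_prs_env(prs, env, pcs_small)
  f2 <- fit_prs_env(prs, env, pcs_large)
  stat <- (f1$beta - f2$beta) / sqrt(abs(f2$se^2 - f1$se^2) + eps)
  list(fit_small = f1, fit_large = f2, statistic = stat,
       p = 2 * stats::pnorm(-abs(stat)))
}

#' Conditional driver analysis among correlated variables
#'
#' For each candidate variable in a correlated set, refits the PRS
#' association on that variable while including the remaining set members
#' as extra covariates. The driver is the candidate whose PRS term retains
#' nominal significance conditionally.
#'
#' @param prs PRS vector.
#' @param env An `environment_table`.
#' @param variables Character vector (length >= 1) of correlated variable
#'   names.
#' @param pcs A `pc_matrix`.
#' @param sites Per-individual site IDs.
#' @param alpha Nominal significance level for the driver call
#'   (default 0.05).
#' @param kappa_max Condition-number bound on the covariate design; larger
#'   values raise an error reporting the condition number (default 1e10).
#' @return Data frame: `variable`, `z`, `p`, `r2_incremental`, `driver`.
#' @export
driver_analysis <- function(prs, env, variables, pcs, sites, alpha = 0.05,
                            kappa_max = 1e10) {
  out <- lapply(variables, function(v) {
    others <- setdiff(variables, v)
    y <- boxcox_transform(env_broadcast(env, sites, v))$transformed
    extra <- NULL
    if (length(others)) {
      extra <- sapply(others, function(o) env_broadcast(env, sites, o))
      colnames(extra) <- others
    }
    X <- build_design(prs, pcs, extra)
    kap <- kappa(X, exact = TRUE)
    if (!is.finite(kap) || kap > kappa_max)
      stop("near-singular design for candidate '", v,
           "': condition number ", format(kap, digits = 3))
    f <- fit_prs_env(prs, y, pcs, extra)
    data.frame(variable = v, z = f$z, p = f$p,
               r2_incremental = f$r2_incremental, driver = f$p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Spearman correlation matrix of environmental variables
#'
#' Pairwise Spearman's rho across sites with average ranks for ties,
#' two-sided p-values (exact for n <= 9 without ties, t-approximation
#' otherwise), and Bonferroni flags over the upper triangle.
#'
#' @param env An `environment_table` with at least 4 sites.
#' @param alpha Family-wise level for the Bonferroni flag (default 0.05).
#' @return List of class `spearman_matrix`: `rho`, `p`,
#'   `bonferroni_significant` (logical), `constant` (variables with no
#'   variation, flagged `NA` throughout), `m_tests`.
#' @export
spearman_matrix <- function(env, alpha = 0.05) {
  vars <- setdiff(names(env), "site_id")
  n <- nrow(env)
  if (n < 4) stop("at least 4 sites are required")
  nv <- length(vars)
  rho <- matrix(NA_real_, nv, nv, dimnames = list(vars, vars))
  pm <- rho
  diag(rho) <- 1
  constant <- vapply(vars, function(v) stats::var(env[[v]]) == 0, logical(1))
  m <- nv * (nv - 1) / 2
  for (i in seq_len(nv - 1)) {
    for (j in (i + 1):nv) {
      if (constant[i] || constant[j]) next
      ct <- suppressWarnings(
        stats::cor.test(env[[vars[i]]], env[[vars[j]]],
                        method = "spearman", exact = n <= 9))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pm[i, j] <- pm[j, i] <- ct$p.value
    }
  }
  flags <- !is.na(pm) & pm <= alpha / m
  structure(list(rho = rho, p = pm, bonferroni_significant = flags,
                 constant = names(constant)[constant], m_tests = m,
                 alpha = alpha),
            class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, ...) {
  cat("spearman_matrix:", nrow(x$rho), "variables,",
      sum(x$bonferroni_significant[upper.tri(x$rho)]),
      "pair(s) past Bonferroni at family alpha", x$alpha, "\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' Write an association grid to TSV
#'
#' Columns mirror the standard PRS-association report: `TRAIT`, `VARIABLE`,
#' `PT`, `SNP_N`, `R2_INC`, `Z`, `P`, `Q`, `BEST_FLAG`.
#'
#' @param grid An `assoc_grid`.
#' @param path TSV path.
#' @return `path` invisibly.
#' @export
write_grid <- function(grid, path) {
  out <- data.frame(TRAIT = grid$trait, VARIABLE = grid$variable,
                    PT = grid$pt, SNP_N = grid$n_snps,
                    R2_INC = grid$r2_incremental, Z = grid$z, P = grid$p,
                    Q = grid$q, BEST_FLAG = as.integer(grid$best))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
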