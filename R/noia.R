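#' Build a NOIA (natural and orthogonal interactions) design
#'
#' Statistical-formulation NOIA for 1-3 loci: per locus with observed
#' genotype frequencies `(f0, f1, f2)` the additive regressor is
#' `x_a(g) = g - (f1 + 2 f2)` and the dominance regressor is
#' `x_d(0) = -2 f1 f2 / D`, `x_d(1) = 4 f0 f2 / D`, `x_d(2) = -2 f0 f1 / D`
#' with `D = f0 + f2 - (f0 - f2)^2`. With frequencies taken from the
#' analyzed individuals these columns are exactly orthogonal to the mean
#' and to each other under frequency weighting, so additive estimates do
#' not shift when dominance or epistatic terms enter the model.
#' Multi-locus (epistatic) effects are element-wise products of the
#' single-locus columns (Kronecker structure of the statistical
#' formulation). Individuals missing a genotype at any modeled locus are
#' dropped.
#'
#' @param g A `genotype_matrix`.
#' @param loci Character vector of 1-3 variant IDs.
#' @param effects `"full"` (additive + dominance + all interactions) or
#'   `"additive"` (additive terms and their interactions only).
#' @return An object of class `noia_design`: `design` (individuals x
#'   effects, named columns), `genotype_freqs` (per locus), `loci`,
#'   `individuals` (IDs retained after missingness drop).
#' @export
noia_design <- function(g, loci, effects = c("full", "additive")) {
  effects <- match.arg(effects)
  if (length(loci) < 1 || length(loci) > 3)
    stop("between 1 and 3 loci are supported")
  miss <- setdiff(loci, g$variants$id)
  if (length(miss)) stop("unknown loci: ", paste(miss, collapse = ", "))
  D <- g$dosages[, loci, drop = FALSE]
  keep <- stats::complete.cases(D)
  D <- D[keep, , drop = FALSE]
  if (!nrow(D)) stop("no complete genotypes at the requested loci")
  freqs <- list()
  per_locus <- list()
  for (l in seq_along(loci)) {
    gvec <- D[, l]
    f <- c(f0 = mean(gvec == 0), f1 = mean(gvec == 1), f2 = mean(gvec == 2))
    if (f["f0"] == 1 || f["f1"] == 1 || f["f2"] == 1)
      stop("locus ", loci[l], " is monomorphic in the analyzed individuals")
    freqs[[loci[l]]] <- f
    xa <- gvec - (f["f1"] + 2 * f["f2"])
    cols <- list(a = unname(xa))
    if (effects == "full") {
      dd <- f["f0"] + f["f2"] - (f["f0"] - f["f2"])^2
      if (dd <= 0) {
        warning("dominance column omitted for locus ", loci[l],
                " (degenerate genotype-frequency pattern, D = 0)")
      } else {
        xd_vals <- c(-2 * f["f1"] * f["f2"], 4 * f["f0"] * f["f2"],
                     -2 * f["f0"] * f["f1"]) / dd
        cols$d <- unname(xd_vals[gvec + 1])
      }
    }
    per_locus[[l]] <- cols
  }
  # Kronecker structure: all products of {1, a_l, d_l} across loci,
  # excluding the all-ones term (the model mean)
  combos <- expand.grid(lapply(per_locus, function(cl)
    c("1", names(cl))), stringsAsFactors = FALSE)
  design <- NULL
  labels <- character()
  for (r in seq_len(nrow(combos))) {
    sel <- as.character(combos[r, ])
    if (all(sel == "1")) next
    col <- rep(1, nrow(D))
    parts <- character()
    for (l in seq_along(loci)) {
      if (sel[l] == "1") next
      col <- col * per_locus[[l]][[sel[l]]]
      parts <- c(parts, paste0(sel[l], l))
    }
    design <- cbind(design, col)
    labels <- c(labels, paste(parts, collapse = ":"))
  }
  colnames(design) <- labels
  # order: main effects by locus, then interactions by order
  ord <- order(lengths(strsplit(labels, ":")), match(labels, labels))
  design <- design[, ord, drop = FALSE]
  structure(list(design = design, genotype_freqs = freqs, loci = loci,
                 individuals = g$samples$id[keep], keep_idx = which(keep),
                 n_total = length(keep)),
            class = "noia_design")
}

#' Fit a NOIA model by ordinary least squares
#'
#' Regresses the phenotype (typically a Box-Cox-transformed environmental
#' variable) on the NOIA effect columns plus optional covariates (ancestry
#' PCs by default in the pipeline), and reports estimates, standard errors,
#' t-statistics and two-sided p-values per effect.
#'
#' @param design A `noia_design`.
#' @param phenotype Numeric vector aligned with the full cohort sample IDs
#'   (named, or same length/order as the genotype matrix the design came
#'   from); individuals dropped in the design are dropped here too.
#' @param covariates Optional matrix (rownames = sample IDs) or
#'   `pc_matrix`.
#' @return An object of class `noia_fit`: `table` (one row per effect:
#'   estimate, se, t, p), `residual_df`, `design`.
#' @export
fit_noia <- function(design, phenotype, covariates = NULL) {
  ids <- design$individuals
  if (!is.null(names(phenotype))) {
    y <- unname(phenotype[ids])
  } else if (length(phenotype) == design$n_total) {
    y <- phenotype[design$keep_idx]      # full-cohort order
  } else if (length(phenotype) == length(ids)) {
    y <- phenotype                       # already restricted
  } else {
    stop("phenotype length matches neither the cohort nor the analyzed set")
  }
  X <- cbind(`(Intercept)` = 1, design$design)
  if (!is.null(covariates)) {
    cv <- if (inherits(covariates, "pc_matrix")) covariates$scores
          else as.matrix(covariates)
    if (!is.null(rownames(cv))) cv <- cv[ids, , drop = FALSE]
    X <- cbind(X, cv)
  }
  if (anyNA(y)) stop("phenotype values missing for analyzed individuals")
  q <- qr(X)
  if (q$rank < ncol(X)) {
    drop_cols <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("rank-deficient NOIA design; collinear effect(s): ",
         paste(drop_cols, collapse = ", "))
  }
  st <- ols_stats(y, X)
  eff <- colnames(design$design)
  tab <- data.frame(effect = eff,
                    estimate = unname(st$coef[eff]),
                    se = unname(st$se[eff]),
                    stringsAsFactors = FALSE)
  tab$t <- tab$estimate / tab$se
  tab$p <- 2 * stats::pt(-abs(tab$t), st$df)
  structure(list(table = tab, residual_df = st$df, design = design,
                 intercept = unname(st$coef["(Intercept)"])),
            class = "noia_fit")
}

#' @export
print.noia_fit <- function(x, ...) {
  cat("noia_fit:", paste(x$design$loci, collapse = ", "),
      "| residual df:", x$residual_df, "\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-locus additive-effect tests from a NOIA fit
#'
#' @param fit A `noia_fit`.
#' @return Data frame restricted to the single-locus additive effects
#'   (`a1`, `a2`, ...), with locus IDs attached.
#' @export
test_additive <- function(fit) {
  tab <- fit$table
  add <- tab[grepl("^a[0-9]+$", tab$effect), , drop = FALSE]
  add$locus <- fit$design$loci[as.integer(sub("^a", "", add$effect))]
  rownames(add) <- NULL
  add
}

#' Write a NOIA report TSV
#' @param fit A `noia_fit`.
#' @param path TSV path (columns LOCI, EFFECT, ESTIMATE, SE, T, P).
#' @param append Append without header (default `FALSE`).
#' @return `path` invisibly.
#' @export
write_noia_report <- function(fit, path, append = FALSE) {
  out <- data.frame(LOCI = paste(fit$design$loci, collapse = ","),
                    EFFECT = fit$table$effect,
                    ESTIMATE = fit$table$estimate, SE = fit$table$se,
                    T = fit$table$t, P = fit$table$p)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !append,
                     append = append)
  invisible(path)
}
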