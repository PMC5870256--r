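#' The standard set of GWAS p-value inclusion thresholds
#'
#' Twelve thresholds spanning genome-wide significance to full inclusion,
#' used to probe oligogenic through fully polygenic score architectures.
#'
#' @return Numeric vector of 12 thresholds.
#' @export
pt_thresholds <- function() {
  c(5e-8, 1e-7, 1e-6, 1e-5, 1e-4, 0.001, 0.01, 0.05, 0.1, 0.3, 0.5, 1)
}

#' Harmonize summary statistics to a target genotype panel
#'
#' Variants are matched on ID and allele pair. When the effect allele equals
#' the panel's alt allele the effect is kept as is; when it equals the
#' panel's ref allele the beta is negated (and allele columns swapped) so
#' beta always counts the panel's alt-dosage allele. Allele-pair mismatches
#' are dropped; strand-ambiguous A/T and C/G pairs can optionally be
#' removed.
#'
#' @param ss A `summary_stats` object.
#' @param g A `genotype_matrix`.
#' @param drop_ambiguous Drop A/T and C/G allele pairs (default `FALSE`).
#' @return A harmonized `summary_stats` restricted to matched variants, with
#'   attributes `n_flipped`, `n_dropped_mismatch`, `n_dropped_ambiguous`.
#' @export
harmonize <- function(ss, g, drop_ambiguous = FALSE) {
  m <- match(ss$id, g$variants$id)
  if (!any(!is.na(m))) stop("no overlapping variants between summary ",
                            "statistics and the target panel")
  keep <- !is.na(m)
  ss <- ss[keep, ]
  pv <- g$variants[m[keep], ]
  straight <- ss$effect_allele == pv$alt & ss$other_allele == pv$ref
  flipped <- ss$effect_allele == pv$ref & ss$other_allele == pv$alt
  n_mismatch <- sum(!straight & !flipped)
  ss$beta[flipped] <- -ss$beta[flipped]
  ss$effect_allele[flipped] <- pv$alt[flipped]
  ss$other_allele[flipped] <- pv$ref[flipped]
  ok <- straight | flipped
  ss <- ss[ok, ]
  n_ambig <- 0L
  if (drop_ambiguous) {
    pair <- paste(pmin(ss$effect_allele, ss$other_allele),
                  pmax(ss$effect_allele, ss$other_allele))
    ambig <- pair %in% c("A T", "C G")
    n_ambig <- sum(ambig)
    ss <- ss[!ambig, ]
  }
  if (!nrow(ss)) stop("no variants survive harmonization")
  out <- summary_stats(ss, trait = attr(ss, "trait"))
  attr(out, "n_flipped") <- sum(flipped)
  attr(out, "n_dropped_mismatch") <- n_mismatch
  attr(out, "n_dropped_ambiguous") <- n_ambig
  out
}

#' Exclude the MHC region from summary statistics
#'
#' Removes variants inside the extended major histocompatibility complex,
#' whose long-range LD breaks the independence assumptions of clumping.
#' Bounds are inclusive and configurable (defaults 26-34 Mb on
#' chromosome 6).
#'
#' @param ss A `summary_stats` object.
#' @param chrom MHC chromosome label (default `"6"`).
#' @param start,end Inclusive bp bounds (defaults 26e6, 34e6).
#' @return The filtered `summary_stats`.
#' @export
exclude_mhc <- function(ss, chrom = "6", start = 26e6, end = 34e6) {
  drop <- ss$chrom == as.character(chrom) & ss$pos >= start & ss$pos <= end
  out <- ss[!drop, ]
  summary_stats(out, trait = attr(ss, "trait"))
}

#' P-value-informed LD clumping
#'
#' Greedy clumping against the target panel: variants are sorted by
#' ascending GWAS p-value (ties broken by chromosome, then position); the
#' best unprocessed variant becomes an index, and all unprocessed variants
#' on the same chromosome within half the window of it whose panel
#' r-squared with the index reaches `r2_cut` are removed (clumped). The
#' procedure is deterministic and independent of input row order.
#'
#' @param ss Harmonized (and typically MHC-excluded) `summary_stats`; every
#'   variant must be present in the panel.
#' @param g A `genotype_matrix`.
#' @param r2_cut LD threshold (default 0.3).
#' @param window_kb Total window span in kb; neighbors within
#'   `window_kb / 2` kb of the index are eligible (default 500).
#' @param band Optional precomputed [ld_r2_band()] on `g[, ss$id]` (panel
#'   position order) covering the largest within-window column lag.
#' @return An object of class `clump_result`: list with `index` (index
#'   variant IDs in selection order) and `clumped` (named list of removed
#'   IDs per index).
#' @export
clump <- function(ss, g, r2_cut = 0.3, window_kb = 500, band = NULL) {
  cols <- match(ss$id, g$variants$id)
  if (anyNA(cols))
    stop("variant(s) missing from the panel (run harmonize() first): ",
         paste(utils::head(ss$id[is.na(cols)], 5), collapse = ", "))
  ord_panel <- order(cols)
  ids <- ss$id[ord_panel]
  p <- ss$p[ord_panel]
  chrom <- ss$chrom[ord_panel]
  pos <- ss$pos[ord_panel]
  gs <- g[, ids]
  Msub <- length(ids)
  radius <- window_kb * 1000 / 2
  # contiguous neighbor ranges per variant (panel order, same chromosome)
  lo <- integer(Msub); hi <- integer(Msub)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pp <- pos[idx]
    lo[idx] <- idx[findInterval(pp - radius, pp, left.open = TRUE) + 1L]
    hi[idx] <- idx[findInterval(pp + radius, pp)]
  }
  max_lag <- max(c(hi - seq_len(Msub), seq_len(Msub) - lo, 1L))
  if (is.null(band)) {
    band <- ld_r2_band(gs, max_lag)
  } else if (nrow(band) < max_lag) {
    stop("supplied band covers lag ", nrow(band), " but lag ", max_lag,
         " is required for this window")
  }
  ord <- order(p, chrom, pos)
  processed <- logical(Msub)
  index <- character()
  clumped <- list()
  for (j in ord) {
    if (processed[j]) next
    processed[j] <- TRUE
    nb <- seq.int(lo[j], hi[j])
    nb <- nb[!processed[nb] & chrom[nb] == chrom[j]]
    removed <- character()
    if (length(nb)) {
      lag <- abs(nb - j)
      r2 <- band[cbind(lag, pmin(nb, j))]
      hitr <- !is.na(r2) & r2 >= r2_cut
      if (any(hitr)) {
        processed[nb[hitr]] <- TRUE
        removed <- ids[nb[hitr]]
      }
    }
    index <- c(index, ids[j])
    clumped[[ids[j]]] <- removed
  }
  structure(list(index = index, clumped = clumped), class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat("clump_result:", length(x$index), "index variants,",
      sum(lengths(x$clumped)), "clumped\n")
  invisible(x)
}

#' Compute polygenic scores at multiple p-value thresholds
#'
#' For each threshold `PT`, the contributing set is the clump-index variants
#' with GWAS `p <= PT`; each individual's score is the raw weighted dosage
#' sum `sum_j beta_j d_ij`, with missing dosages replaced by `2 p_j` (panel
#' alt-allele frequency). An empty contributing set yields a zero column
#' with a warning.
#'
#' @param ss Harmonized `summary_stats` (source of betas and p-values).
#' @param clump_res A `clump_result` from [clump()].
#' @param g A `genotype_matrix`.
#' @param thresholds Numeric thresholds (default [pt_thresholds()]).
#' @param average Divide each column by its allele count `2 * n_snps`
#'   (the "average score" convention of some scoring software). The
#'   default `FALSE` reports raw sums; the two differ by a per-column
#'   constant factor, so downstream association statistics are identical.
#' @return An object of class `prs_matrix`: `scores` (individuals x
#'   thresholds), `thresholds`, `n_snps` (contributing count per threshold),
#'   `members` (contributing variant IDs per threshold), attribute `trait`.
#' @export
prs_score <- function(ss, clump_res, g, thresholds = pt_thresholds(),
                      average = FALSE) {
  thresholds <- sort(thresholds)
  idx <- match(clump_res$index, ss$id)
  if (anyNA(idx)) stop("clump index variants missing from summary statistics")
  ssx <- ss[idx, ]
  D <- g$dosages[, ssx$id, drop = FALSE]
  storage.mode(D) <- "double"
  cm <- colMeans(D, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  na_idx <- which(is.na(D))
  if (length(na_idx))
    D[na_idx] <- cm[(na_idx - 1) %/% nrow(D) + 1]
  scores <- matrix(0, nrow(D), length(thresholds))
  n_snps <- integer(length(thresholds))
  members <- vector("list", length(thresholds))
  for (t in seq_along(thresholds)) {
    sel <- ssx$p <= thresholds[t]
    n_snps[t] <- sum(sel)
    members[[t]] <- ssx$id[sel]
    if (!any(sel)) {
      warning("no variants at threshold PT = ", thresholds[t],
              "; score column is zero")
      next
    }
    scores[, t] <- D[, sel, drop = FALSE] %*% ssx$beta[sel]
    if (average) scores[, t] <- scores[, t] / (2 * n_snps[t])
  }
  stopifnot(!is.unsorted(n_snps))          # monotone in PT by construction
  rownames(scores) <- g$samples$id
  colnames(scores) <- paste0("PT_", as.character(thresholds))
  names(members) <- colnames(scores)
  structure(list(scores = scores, thresholds = thresholds, n_snps = n_snps,
                 members = members),
            class = "prs_matrix", trait = attr(ss, "trait"))
}

#' @export
print.prs_matrix <- function(x, ...) {
  cat("prs_matrix:", nrow(x$scores), "individuals x",
      length(x$thresholds), "thresholds (trait:",
      attr(x, "trait") %||% "?", ")\n")
  cat("  n_snps:", paste(x$n_snps, collapse = " "), "\n")
  invisible(x)
}

#' Write / read a PRS matrix
#'
#' TSV with `IID` then one column per threshold; per-threshold contributing
#' SNP counts are recorded in `#`-prefixed header comment lines.
#'
#' @param prs A `prs_matrix`.
#' @param path TSV path.
#' @return `path` invisibly; reader returns a `prs_matrix` (without
#'   `members`).
#' @export
write_prs <- function(prs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# thresholds: ",
                      paste(prs$thresholds, collapse = "\t")),
               paste0("# n_snps: ", paste(prs$n_snps, collapse = "\t"))),
             con)
  out <- data.frame(IID = rownames(prs$scores), prs$scores,
                    check.names = FALSE)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prs
#' @export
read_prs <- function(path) {
  hdr <- readLines(path, n = 2)
  thresholds <- as.numeric(strsplit(sub("^# thresholds: ", "", hdr[1]),
                                    "\t")[[1]])
  n_snps <- as.integer(strsplit(sub("^# n_snps: ", "", hdr[2]), "\t")[[1]])
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  scores <- as.matrix(tab[, -1, drop = FALSE])
  rownames(scores) <- tab$IID
  structure(list(scores = scores, thresholds = thresholds, n_snps = n_snps,
                 members = NULL),
            class = "prs_matrix")
}

#' Write a clumping report
#' @param clump_res A `clump_result`.
#' @param ss The `summary_stats` used for clumping.
#' @param path TSV path (columns INDEX_SNP, P, N_CLUMPED, CLUMPED_IDS).
#' @return `path` invisibly.
#' @export
write_clump_report <- function(clump_res, ss, path) {
  p <- ss$p[match(clump_res$index, ss$id)]
  out <- data.frame(INDEX_SNP = clump_res$index, P = p,
                    N_CLUMPED = lengths(clump_res$clumped[clump_res$index]),
                    CLUMPED_IDS = vapply(clump_res$clumped[clump_res$index],
                                         paste, character(1), collapse = ","))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
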