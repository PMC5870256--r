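#' Per-SNP matching properties
#'
#' Computes, for every variant of a panel, the properties used by
#' matched-SNP-set construction: minor allele frequency, gene density
#' (genes overlapping a +/- `gene_window` bp window), distance to the
#' nearest gene (0 bp if intragenic), and LD-buddy count (panel SNPs within
#' +/- `buddy_radius` bp at r-squared >= `buddy_r2`).
#'
#' @param g A `genotype_matrix` (the background panel).
#' @param db An `annotation_db`.
#' @param gene_window Half-width of the gene-density window in bp
#'   (default 1e5).
#' @param buddy_radius Half-width of the LD-buddy window in bp
#'   (default 2.5e5).
#' @param buddy_r2 r-squared threshold for an LD buddy (default 0.3).
#' @param band Optional precomputed [ld_r2_band()] for `g` covering the
#'   largest column lag within `buddy_radius`.
#' @return Data frame of class `snp_properties`: `id`, `maf`,
#'   `gene_density`, `dist_nearest_gene`, `ld_buddies`.
#' @export
snp_properties <- function(g, db, gene_window = 1e5, buddy_radius = 2.5e5,
                           buddy_r2 = 0.3, band = NULL) {
  v <- g$variants
  M <- nrow(v)
  mafs <- maf(g)
  gene_density <- integer(M)
  dist_nearest <- rep(NA_real_, M)
  for (ch in unique(v$chrom)) {
    vi <- which(v$chrom == ch)
    gi <- which(db$genes$chrom == ch)
    if (!length(gi)) { gene_density[vi] <- 0L; next }
    gs <- db$genes$start[gi]; ge <- db$genes$end[gi]
    o <- order(gs)
    gs <- gs[o]; ge <- ge[o]
    pos <- v$pos[vi]
    # non-overlapping sorted intervals: #genes with start <= pos+W minus
    # #genes with end < pos-W
    n_before <- findInterval(pos + gene_window, gs)
    n_ended <- findInterval(pos - gene_window - 1, sort(ge))
    gene_density[vi] <- n_before - n_ended
    k <- findInterval(pos, gs)
    d_left <- ifelse(k >= 1, pmax(pos - ge[pmax(k, 1)], 0), Inf)
    d_right <- ifelse(k < length(gs), gs[pmin(k + 1, length(gs))] - pos, Inf)
    d_right[d_right < 0] <- Inf
    dist_nearest[vi] <- pmin(d_left, d_right)
    inside <- k >= 1 & pos <= ge[pmax(k, 1)]
    dist_nearest[vi][inside] <- 0
  }
  # LD buddies from the banded r2
  if (is.null(band)) {
    max_lag <- 1L
    for (ch in unique(v$chrom)) {
      pos <- v$pos[v$chrom == ch]
      hi <- findInterval(pos + buddy_radius, pos)
      max_lag <- max(max_lag, hi - seq_along(pos))
    }
    band <- ld_r2_band(g, max_lag)
  }
  buddies <- integer(M)
  pos_all <- v$pos
  chrom_all <- v$chrom
  for (L in seq_len(nrow(band))) {
    if (L >= M) break
    i1 <- seq_len(M - L)
    i2 <- i1 + L
    hit <- !is.na(band[L, i1]) & band[L, i1] >= buddy_r2 &
      chrom_all[i1] == chrom_all[i2] &
      (pos_all[i2] - pos_all[i1]) <= buddy_radius
    buddies[i1] <- buddies[i1] + hit
    buddies[i2] <- buddies[i2] + hit
  }
  structure(data.frame(id = v$id, maf = unname(mafs),
                       gene_density = gene_density,
                       dist_nearest_gene = dist_nearest,
                       ld_buddies = buddies, stringsAsFactors = FALSE),
            class = c("snp_properties", "data.frame"))
}

#' Select the variants driving a significant PRS association cell
#'
#' Candidates are the clump-index variants contributing at the cell's
#' threshold. Each is tested individually: the transformed environment is
#' regressed on its (mean-imputed) dosage plus the ancestry PCs, and the
#' variant is kept when its per-SNP p-value is below `p_cut` and the sign
#' of `beta_snp * beta_gwas` agrees with the sign of the cell's Z score.
#'
#' @param members Character vector of contributing variant IDs (e.g. from a
#'   `prs_matrix`'s `members` at the cell's threshold).
#' @param ss Harmonized `summary_stats` (source of GWAS betas).
#' @param g A `genotype_matrix`.
#' @param env Transformed, broadcast environment vector.
#' @param pcs A `pc_matrix`.
#' @param z_cell Sign-carrying Z score of the association cell.
#' @param p_cut Per-SNP nominal threshold (default 0.05).
#' @return Character vector of selected variant IDs, with attribute
#'   `stats` (per-candidate beta, t and p).
#' @export
select_prs_snps <- function(members, ss, g, env, pcs, z_cell, p_cut = 0.05) {
  if (!length(members)) {
    warning("empty candidate set")
    return(character())
  }
  D <- g$dosages[, members, drop = FALSE]
  storage.mode(D) <- "double"
  cm <- colMeans(D, na.rm = TRUE)
  nai <- which(is.na(D))
  if (length(nai)) D[nai] <- cm[(nai - 1) %/% nrow(D) + 1]
  C <- cbind(1, pcs$scores)
  Q <- qr.Q(qr(C))
  re <- env - Q %*% crossprod(Q, env)
  RD <- D - Q %*% crossprod(Q, D)
  df <- nrow(D) - ncol(C) - 1L
  num <- colSums(RD * as.vector(re))
  den2 <- colSums(RD^2)
  beta_snp <- ifelse(den2 > 0, num / den2, 0)
  r <- ifelse(den2 > 0, num / sqrt(den2 * sum(re^2)), 0)
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tt <- r * sqrt(df) / sqrt(1 - r^2)
  pp <- 2 * stats::pt(-abs(tt), df)
  beta_gwas <- ss$beta[match(members, ss$id)]
  keep <- pp < p_cut & sign(beta_snp * beta_gwas) == sign(z_cell)
  sel <- members[keep]
  if (!length(sel)) warning("no variants pass the concordance selection")
  attr(sel, "stats") <- data.frame(id = members, beta_snp = beta_snp,
                                   t = tt, p = pp, beta_gwas = beta_gwas,
                                   stringsAsFactors = FALSE)
  sel
}

#' Map SNPs to genes through eQTL links
#'
#' @param snp_ids Character vector of SNP IDs.
#' @param db An `annotation_db`.
#' @return Character vector: the union of eQTL-linked genes.
#' @export
snps_to_genes <- function(snp_ids, db) {
  sort(unique(db$eqtl$gene[db$eqtl$snp %in% snp_ids]))
}

#' Hypergeometric term enrichment of a gene set
#'
#' For each term, the upper-tail hypergeometric probability of drawing at
#' least the observed number of term genes in a query of size `n` from a
#' universe of size `N` containing `K` term genes; q-values by
#' Benjamini-Hochberg across all tested terms.
#'
#' @param query_genes Character vector of query genes.
#' @param db An `annotation_db`.
#' @param universe Gene universe; defaults to all genes carrying at least
#'   one eQTL link in `db` (the background reachable by any SNP).
#' @return Data frame of class `enrichment_result`: `term`, `K`, `k`, `N`,
#'   `n`, `p`, `q`.
#' @export
hypergeom_enrich <- function(query_genes, db, universe = NULL) {
  if (is.null(universe)) universe <- unique(db$eqtl$gene)
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  query <- intersect(unique(query_genes), universe)
  N <- length(universe)
  n <- length(query)
  tt <- db$terms[db$terms$gene %in% universe, ]
  terms <- sort(unique(tt$term))
  K <- vapply(terms, function(t) length(unique(tt$gene[tt$term == t])),
              integer(1))
  k <- vapply(terms, function(t)
    length(intersect(query, tt$gene[tt$term == t])), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms, K = K, k = k, N = N, n = n, p = p,
                    q = if (length(p)) fdr_adjust(pmin(pmax(p, 1e-300), 1))
                        else numeric(),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Build matched null SNP sets
#'
#' For each input SNP and each of `n_sets` replicates, samples (uniformly,
#' without replacement within a set) a background SNP matched on minor
#' allele frequency (within `maf_tol` percentage points), gene density
#' (within `rel_tol` relative), distance to nearest gene (relative, with
#' `dist_slack` bp absolute slack when the input distance is 0), and
#' LD-buddy count (relative, with slack `buddy_slack` when the input count
#' is 0).
#'
#' @param input_ids Character vector of input SNP IDs.
#' @param props A `snp_properties` table covering input and background; the
#'   background is every property row not in `input_ids`.
#' @param n_sets Number of matched sets (default 100).
#' @param seed Optional seed.
#' @param maf_tol MAF tolerance in frequency units (default 0.05).
#' @param rel_tol Relative tolerance for the other properties
#'   (default 0.5).
#' @param dist_slack,buddy_slack Absolute slacks at zero (defaults 5000 bp
#'   and 1).
#' @param relax Double all tolerances once (default `FALSE`).
#' @return List of class `matched_sets`: `n_sets` character vectors, each
#'   the size of the input set.
#' @export
match_snps <- function(input_ids, props, n_sets = 100, seed = NULL,
                       maf_tol = 0.05, rel_tol = 0.5, dist_slack = 5000,
                       buddy_slack = 1, relax = FALSE) {
  if (relax) {
    maf_tol <- 2 * maf_tol; rel_tol <- 2 * rel_tol
    dist_slack <- 2 * dist_slack; buddy_slack <- 2 * buddy_slack
  }
  miss <- setdiff(input_ids, props$id)
  if (length(miss))
    stop("input SNP(s) without properties: ", paste(miss, collapse = ", "))
  bg <- props[!props$id %in% input_ids, ]
  ip <- props[match(input_ids, props$id), ]
  in_rel <- function(x, x0) {
    lo <- x0 * (1 - rel_tol); hi <- x0 * (1 + rel_tol)
    x >= lo & x <= hi
  }
  candidates <- lapply(seq_along(input_ids), function(i) {
    ok <- abs(bg$maf - ip$maf[i]) <= maf_tol &
      in_rel(bg$gene_density, ip$gene_density[i]) &
      (if (ip$dist_nearest_gene[i] == 0) bg$dist_nearest_gene <= dist_slack
       else in_rel(bg$dist_nearest_gene, ip$dist_nearest_gene[i])) &
      (if (ip$ld_buddies[i] == 0) bg$ld_buddies <= buddy_slack
       else in_rel(bg$ld_buddies, ip$ld_buddies[i]))
    sort(bg$id[ok])          # canonical order: independent of input order
  })
  names(candidates) <- input_ids
  empty <- lengths(candidates) == 0
  if (any(empty)) {
    i <- which(empty)[1]
    stop("no matched candidates for SNP ", input_ids[i],
         " (maf=", signif(ip$maf[i], 3),
         ", gene_density=", ip$gene_density[i],
         ", dist_nearest_gene=", ip$dist_nearest_gene[i],
         ", ld_buddies=", ip$ld_buddies[i],
         "); consider relax = TRUE")
  }
  if (!is.null(seed)) set.seed(seed)
  # fill scarce pools first so within-set exclusivity rarely dead-ends
  fill_order <- order(lengths(candidates), input_ids)
  sets <- vector("list", n_sets)
  for (b in seq_len(n_sets)) {
    used <- character()
    pick <- character(length(input_ids))
    for (i in fill_order) {
      pool <- setdiff(candidates[[i]], used)
      if (!length(pool))
        stop("candidate pool exhausted for SNP ", input_ids[i],
             " in set ", b, "; consider relax = TRUE")
      pick[i] <- if (length(pool) == 1) pool else sample(pool, 1)
      used <- c(used, pick[i])
    }
    sets[[b]] <- pick
  }
  structure(sets, class = "matched_sets", input = input_ids)
}

#' Empirical enrichment null from matched SNP sets
#'
#' Counts significant terms (q below `q_cut`) in the observed enrichment
#' and in each matched set's enrichment, and reports the add-one empirical
#' probability of a matched set reaching the observed count.
#'
#' @param obs An `enrichment_result` for the observed SNP set.
#' @param matched List of `enrichment_result` objects, one per matched set
#'   (at least 20).
#' @param q_cut Significance threshold on q (default 0.05).
#' @return List of class `enrichment_null`: `empirical_p`, `count_obs`,
#'   `counts` (per matched set), `pooled_q` (all matched-set q-values).
#' @export
empirical_enrichment_null <- function(obs, matched, q_cut = 0.05) {
  if (length(matched) < 20)
    stop("at least 20 matched sets are required")
  count_obs <- sum(obs$q < q_cut)
  counts <- vapply(matched, function(m) sum(m$q < q_cut), integer(1))
  empirical_p <- (1 + sum(counts >= count_obs)) / (length(matched) + 1)
  structure(list(empirical_p = empirical_p, count_obs = count_obs,
                 counts = counts,
                 pooled_q = unlist(lapply(matched, `[[`, "q"))),
            class = "enrichment_null")
}

#' @export
print.enrichment_null <- function(x, ...) {
  cat(sprintf("enrichment_null: observed %d significant term(s); empirical p = %.4g over %d matched sets\n",
              x$count_obs, x$empirical_p, length(x$counts)))
  invisible(x)
}
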