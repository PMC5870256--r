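#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a low-FST,
#' European-scale structured cohort sampled at `n_populations` sites, with
#' LD blocks induced by a latent Gaussian copula, polygenic trait
#' architectures, site-level environmental variables, and gene/eQTL/term
#' annotation with one optional planted enriched term.
#'
#' @param n_populations Number of populations / sampling sites (default 23).
#' @param n_per_pop Individuals per population (default 100).
#' @param n_variants Number of variants (default 20000).
#' @param n_chromosomes Number of chromosomes the variants are laid out on
#'   (default 22).
#' @param fst Balding-Nichols differentiation parameter F, in (0, 1)
#'   (default 0.01, European-scale).
#' @param ld_block_size Variants per LD block (default 25).
#' @param ld_rho Within-block AR(1) latent correlation target, in \[0, 1)
#'   (default 0.8).
#' @param n_causal Causal variants per trait (default 200).
#' @param h2_like_effect_scale Standard deviation of causal effect sizes
#'   (default 0.05).
#' @param selection_gradient Coupling `s >= 0` between causal allele
#'   frequencies and the standardized driver variable; the default 0.5
#'   yields mean per-causal-variant frequency shifts of about 0.02 per SD of
#'   environment at the default effect scale.
#' @param n_gwas Training-GWAS sample size used to calibrate summary
#'   statistic noise (default 50000).
#' @param env_spec List with `variables` (character names) and `cor`
#'   (inter-variable correlation matrix, positive semi-definite).
#' @param driver Name of the designated driver variable (default: first
#'   variable in `env_spec`).
#' @param missing_rate Genotype missingness proportion in \[0, 0.1)
#'   (default 0.01).
#' @param n_traits Number of simulated traits, each with its own causal set
#'   and GWAS (default 3).
#' @param swap_fraction Fraction of summary-statistic rows emitted with
#'   swapped allele labels (beta negated accordingly) to exercise
#'   harmonization (default 0.1).
#' @param hwe_violation_rate Fraction of variants drawn with strong excess
#'   heterozygosity, giving the HWE filter something to remove (default 0).
#' @param mean_gap_bp Mean inter-variant spacing in bp (default 6000, so a
#'   500-kb window spans several LD blocks).
#' @param n_genes,n_terms Annotation sizes (defaults 600 genes, 40 terms).
#' @param planted_term_size Number of genes carrying the planted enriched
#'   term (default 40).
#' @param planted_term_strength Probability that a causal variant receives
#'   an eQTL link into the planted term's gene set; 0 disables planting
#'   (default 0.7).
#' @param seed Integer seed; fully determines all generator output.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_populations = 23, n_per_pop = 100,
                       n_variants = 20000, n_chromosomes = 22,
                       fst = 0.01, ld_block_size = 25, ld_rho = 0.8,
                       n_causal = 200, h2_like_effect_scale = 0.05,
                       selection_gradient = 0.5, n_gwas = 50000,
                       env_spec = default_env_spec(), driver = NULL,
                       missing_rate = 0.01, n_traits = 3,
                       swap_fraction = 0.1, hwe_violation_rate = 0,
                       mean_gap_bp = 6000, n_genes = 600, n_terms = 40,
                       planted_term_size = 40, planted_term_strength = 0.7,
                       seed = 1) {
  cfg <- as.list(environment())
  if (is.null(driver)) cfg$driver <- env_spec$variables[1]
  if (n_per_pop < 2) stop("n_per_pop must be at least 2")
  if (!(fst > 0 && fst < 1)) stop("fst must lie strictly in (0, 1)")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 0.1)
    stop("missing_rate must lie in [0, 0.1)")
  if (selection_gradient < 0) stop("selection_gradient must be >= 0")
  if (n_causal > n_variants) stop("n_causal exceeds n_variants")
  check_env_spec(env_spec)
  if (!cfg$driver %in% env_spec$variables)
    stop("driver variable '", cfg$driver, "' not in env_spec")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Default environmental variable specification
#'
#' Five site-level variables spanning the geo-climate / pathogen-diversity /
#' phonology categories typical of local-adaptation panels; the two winter
#' temperature variables are strongly inter-correlated (rho 0.75), matching
#' the scale of correlation observed among real climate variables.
#'
#' @return List with `variables` and `cor`.
#' @export
default_env_spec <- function() {
  vars <- c("winter_min_temp", "winter_max_temp", "precip_rate",
            "pathogen_diversity", "consonant_count")
  C <- diag(5)
  C[1, 2] <- C[2, 1] <- 0.75
  dimnames(C) <- list(vars, vars)
  list(variables = vars, cor = C)
}

check_env_spec <- function(env_spec) {
  if (!is.list(env_spec) || !all(c("variables", "cor") %in% names(env_spec)))
    stop("env_spec must be a list with 'variables' and 'cor'")
  nv <- length(env_spec$variables)
  C <- env_spec$cor
  if (!is.matrix(C) || nrow(C) != nv || ncol(C) != nv)
    stop("env_spec$cor must be a ", nv, " x ", nv, " matrix")
  if (max(abs(C - t(C))) > 1e-10) stop("env_spec$cor must be symmetric")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("env_spec$cor is not positive semi-definite")
  invisible(TRUE)
}

site_ids <- function(n) sprintf("site_%02d", seq_len(n))

#' Simulate the latent truth of a structured cohort
#'
#' Draws the Balding-Nichols allele-frequency truth: ancestral frequencies
#' `p0 ~ Uniform(0.05, 0.95)` and per-population frequencies
#' `p_k ~ Beta(p0(1-F)/F, (1-p0)(1-F)/F)`, lays variants out on chromosomes
#' with exponential spacing, assigns LD blocks, and draws causal sets and
#' effect sizes per trait.
#'
#' @param config A `sim_config`.
#' @param seed Seed (defaults to `config$seed`).
#' @return A `sim_truth` list: `variants`, `p0`, `pop_freq` (variants x
#'   sites), `traits` (per trait: `causal` indices and full-length `beta`),
#'   `hwe_violators`.
#' @export
simulate_truth <- function(config, seed = config$seed) {
  set.seed(seed)
  M <- config$n_variants
  nchr <- config$n_chromosomes
  per_chr <- diff(round(seq(0, M, length.out = nchr + 1)))
  chrom <- rep(as.character(seq_len(nchr)), per_chr)
  pos <- unlist(lapply(per_chr, function(m) {
    gaps <- round(stats::rexp(m, 1 / config$mean_gap_bp)) + 200
    cumsum(gaps) + 10000
  }), use.names = FALSE)
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, M, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
  block <- unlist(lapply(per_chr, function(m)
    rep(seq_len(ceiling(m / config$ld_block_size)),
        each = config$ld_block_size)[seq_len(m)]), use.names = FALSE)
  block <- cumsum(c(TRUE, diff(block) != 0 | chrom[-1] != chrom[-M]))
  variants <- data.frame(id = sprintf("rs%05d", seq_len(M)), chrom = chrom,
                         pos = as.integer(pos), ref = ref, alt = alt,
                         block = block, stringsAsFactors = FALSE)
  p0 <- stats::runif(M, 0.05, 0.95)
  F <- config$fst
  a <- p0 * (1 - F) / F
  b <- (1 - p0) * (1 - F) / F
  pop_freq <- matrix(stats::rbeta(M * config$n_populations, a, b), M,
                     config$n_populations)
  colnames(pop_freq) <- site_ids(config$n_populations)
  rownames(pop_freq) <- variants$id
  traits <- lapply(seq_len(config$n_traits), function(t) {
    causal <- sort(sample(M, config$n_causal))
    beta <- numeric(M)
    beta[causal] <- stats::rnorm(config$n_causal, 0,
                                 config$h2_like_effect_scale)
    list(causal = causal, beta = beta)
  })
  names(traits) <- sprintf("trait_%d", seq_len(config$n_traits))
  hwe_violators <- if (config$hwe_violation_rate > 0)
    sort(sample(M, max(1, round(M * config$hwe_violation_rate)))) else integer()
  structure(list(variants = variants, p0 = p0, pop_freq = pop_freq,
                 traits = traits, hwe_violators = hwe_violators,
                 config = config),
            class = "sim_truth")
}

#' Plant a clinal selection gradient in the truth frequencies
#'
#' Emulates local adaptation: for each causal variant `j` of the chosen
#' trait and each population `k`, the population frequency is shifted to
#' `clip(p_k + s * beta_j * z_k, 0.01, 0.99)` where `z_k` is the site's
#' standardized driver-variable value. Non-causal variants are untouched.
#'
#' @param truth A `sim_truth`.
#' @param environment An `environment_table` whose sites match the truth's
#'   populations.
#' @param s Selection gradient, `>= 0`. `s = 0` returns the truth unchanged.
#' @param driver Driver variable name (default: the table's driver
#'   attribute).
#' @param trait Trait index whose causal set responds to selection
#'   (default 1).
#' @return The modified `sim_truth`, with a `selection` element recording
#'   `s`, driver, and trait.
#' @export
apply_selection_gradient <- function(truth, environment, s, driver = NULL,
                                     trait = 1) {
  if (s < 0) stop("selection gradient s must be >= 0")
  if (is.null(driver)) driver <- attr(environment, "driver")
  if (is.null(driver) || !driver %in% names(environment))
    stop("driver variable '", driver %||% "<unset>",
         "' missing from the environment table")
  if (s == 0) return(truth)
  k <- match(colnames(truth$pop_freq), environment$site_id)
  if (anyNA(k)) stop("environment table does not cover all simulated sites")
  z <- as.numeric(scale(environment[[driver]][k]))
  tr <- truth$traits[[trait]]
  shift <- s * tr$beta[tr$causal] %o% z
  truth$pop_freq[tr$causal, ] <-
    pmin(pmax(truth$pop_freq[tr$causal, , drop = FALSE] + shift, 0.01), 0.99)
  truth$selection <- list(s = s, driver = driver, trait = trait)
  truth
}

#' Simulate genotypes from truth frequencies
#'
#' Draws diploid dosages per individual: two latent Gaussian haplotype
#' vectors with AR(1) within-block correlation `ld_rho` (independent across
#' blocks) are thresholded at the population-specific allele-frequency
#' quantile, so marginal per-variant genotypes are Binomial(2, p_k) in
#' Hardy-Weinberg proportions while neighboring variants are in LD.
#' Missing entries are inserted completely at random at `missing_rate`.
#'
#' @param truth A `sim_truth` (possibly selection-shifted).
#' @param config A `sim_config` (defaults to the one in `truth`).
#' @param seed Seed.
#' @return A `genotype_matrix`.
#' @export
simulate_genotypes <- function(truth, config = truth$config,
                               seed = config$seed + 1L) {
  set.seed(seed)
  M <- nrow(truth$variants)
  npop <- config$n_populations
  nper <- config$n_per_pop
  n <- npop * nper
  rho <- config$ld_rho
  sq <- sqrt(1 - rho^2)
  block <- truth$variants$block
  new_block <- c(TRUE, diff(block) != 0)
  dos <- matrix(0L, n, M)
  for (k in seq_len(npop)) {
    Z <- matrix(stats::rnorm(2L * nper * M), 2L * nper, M)
    if (rho > 0) {
      for (j in 2:M) {
        if (!new_block[j]) Z[, j] <- rho * Z[, j - 1L] + sq * Z[, j]
      }
    }
    pk <- pmin(pmax(truth$pop_freq[, k], 1e-12), 1 - 1e-12)
    thr <- matrix(stats::qnorm(pk), 2L * nper, M, byrow = TRUE)
    H <- Z < thr
    rows <- (k - 1L) * nper + seq_len(nper)
    dos[rows, ] <- H[seq_len(nper), , drop = FALSE] +
      H[nper + seq_len(nper), , drop = FALSE]
  }
  if (length(truth$hwe_violators)) {
    for (v in truth$hwe_violators)
      dos[, v] <- sample(0:2, n, replace = TRUE, prob = c(0.05, 0.9, 0.05))
  }
  if (config$missing_rate > 0) {
    nmiss <- stats::rbinom(1, n * M, config$missing_rate)
    if (nmiss > 0)
      dos[sample.int(as.double(n) * M, nmiss)] <- NA_integer_
  }
  samples <- data.frame(id = sprintf("ind_%04d", seq_len(n)),
                        site_id = rep(site_ids(npop), each = nper),
                        stringsAsFactors = FALSE)
  genotype_matrix(dos, truth$variants[, c("id", "chrom", "pos", "ref", "alt")],
                  samples)
}

#' Simulate a cohort (truth + genotypes) in one call
#'
#' @param config A `sim_config`.
#' @param truth Optional precomputed (e.g. selection-shifted) `sim_truth`;
#'   when `NULL` a fresh truth is drawn from `config`.
#' @return List with `genotypes` and `truth`.
#' @export
simulate_cohort <- function(config, truth = NULL) {
  if (is.null(truth)) truth <- simulate_truth(config)
  list(genotypes = simulate_genotypes(truth, config), truth = truth)
}

#' Simulate GWAS summary statistics for one trait
#'
#' Per variant, the standard error follows the standard GWAS approximation
#' `se = 1 / sqrt(2 n p0 (1 - p0))`, the estimated effect is
#' `beta_true + Normal(0, se)`, and the p-value is the two-sided Wald test.
#' A configurable fraction of rows is emitted with swapped allele labels
#' (beta negated) to exercise harmonization.
#'
#' @param truth A `sim_truth`.
#' @param n_gwas GWAS sample size (must be at least 100).
#' @param trait Trait index (default 1).
#' @param swap_fraction Fraction of rows with swapped allele labels.
#' @param seed Seed.
#' @return A `summary_stats` data frame (id, chrom, pos, effect_allele,
#'   other_allele, beta, p) with attribute `trait`.
#' @export
simulate_sumstats <- function(truth, n_gwas = truth$config$n_gwas, trait = 1,
                              swap_fraction = truth$config$swap_fraction,
                              seed = truth$config$seed + 100L + trait) {
  if (n_gwas < 100) stop("n_gwas must be at least 100")
  set.seed(seed)
  M <- nrow(truth$variants)
  se <- 1 / sqrt(2 * n_gwas * truth$p0 * (1 - truth$p0))
  beta_hat <- truth$traits[[trait]]$beta + stats::rnorm(M, 0, se)
  p <- pmax(2 * stats::pnorm(-abs(beta_hat / se)), 1e-300)
  ss <- data.frame(id = truth$variants$id, chrom = truth$variants$chrom,
                   pos = truth$variants$pos,
                   effect_allele = truth$variants$alt,
                   other_allele = truth$variants$ref,
                   beta = beta_hat, p = p, stringsAsFactors = FALSE)
  if (swap_fraction > 0) {
    sw <- stats::runif(M) < swap_fraction
    tmp <- ss$effect_allele[sw]
    ss$effect_allele[sw] <- ss$other_allele[sw]
    ss$other_allele[sw] <- tmp
    ss$beta[sw] <- -ss$beta[sw]
  }
  summary_stats(ss, trait = names(truth$traits)[trait])
}

#' Simulate the site-by-variable environment table
#'
#' One row per sampling site; variables drawn multivariate normal with the
#' specified inter-variable correlation (via the symmetric matrix square
#' root, so positive semi-definite but singular specifications are
#' accepted).
#'
#' @param config A `sim_config`.
#' @param seed Seed.
#' @return An `environment_table` (data frame `site_id` + one column per
#'   variable) with attribute `driver`.
#' @export
simulate_environment <- function(config, seed = config$seed + 2L) {
  check_env_spec(config$env_spec)
  set.seed(seed)
  nv <- length(config$env_spec$variables)
  npop <- config$n_populations
  eg <- eigen(config$env_spec$cor, symmetric = TRUE)
  S <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nv) %*% t(eg$vectors)
  X <- matrix(stats::rnorm(npop * nv), npop, nv) %*% S
  colnames(X) <- config$env_spec$variables
  env <- data.frame(site_id = site_ids(npop), X, stringsAsFactors = FALSE)
  attr(env, "driver") <- config$driver
  class(env) <- c("environment_table", "data.frame")
  env
}

#' Simulate gene / eQTL / term annotation
#'
#' Non-overlapping gene intervals are laid out per chromosome; each variant
#' receives eQTL links (mostly to its nearest gene, occasionally to a random
#' gene); genes receive random term memberships. When
#' `planted_term_strength > 0`, causal variants of trait 1 additionally link
#' to genes of one planted enriched term, giving enrichment tests a known
#' positive.
#'
#' @param config A `sim_config`.
#' @param truth A `sim_truth` (supplies variant positions and causal flags).
#' @param seed Seed.
#' @return An `annotation_db`.
#' @export
simulate_annotation <- function(config, truth, seed = config$seed + 3L) {
  set.seed(seed)
  v <- truth$variants
  chroms <- unique(v$chrom)
  nvc <- table(factor(v$chrom, levels = chroms))
  ngc <- pmax(2L, round(config$n_genes * as.numeric(nvc) / nrow(v)))
  genes <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    ch <- chroms[ci]
    pr <- range(v$pos[v$chrom == ch])
    lo <- max(1, pr[1] - 50000)
    hi <- pr[2] + 50000
    ng <- ngc[ci]
    slot <- (hi - lo) / ng
    start <- round(lo + (seq_len(ng) - 1) * slot +
                     stats::runif(ng, 0, 0.3 * slot))
    end <- round(start + pmax(2000, stats::runif(ng, 0.2, 0.5) * slot))
    data.frame(chrom = ch, start = as.integer(start), end = as.integer(end),
               stringsAsFactors = FALSE)
  }))
  genes$gene <- sprintf("gene_%04d", seq_len(nrow(genes)))
  genes <- genes[, c("gene", "chrom", "start", "end")]
  # gene -> term map
  term_ids <- sprintf("term_%03d", seq_len(config$n_terms))
  n_links <- stats::rpois(nrow(genes), 2)
  terms <- data.frame(
    gene = rep(genes$gene, n_links),
    term = unlist(lapply(n_links, function(k)
      if (k > 0) sample(term_ids, min(k, length(term_ids))) else character())),
    stringsAsFactors = FALSE)
  planted_genes <- character()
  if (config$planted_term_strength > 0) {
    planted_genes <- sample(genes$gene, min(config$planted_term_size,
                                            nrow(genes)))
    terms <- rbind(terms, data.frame(gene = planted_genes,
                                     term = "term_planted",
                                     stringsAsFactors = FALSE))
  }
  # SNP -> gene eQTL links
  mid <- (genes$start + genes$end) / 2
  nearest <- vapply(seq_len(nrow(v)), function(j) {
    on_chr <- which(genes$chrom == v$chrom[j])
    on_chr[which.min(abs(mid[on_chr] - v$pos[j]))]
  }, integer(1))
  take_near <- stats::runif(nrow(v)) < 0.8
  take_rand <- stats::runif(nrow(v)) < 0.15
  eqtl <- rbind(
    data.frame(snp = v$id[take_near], gene = genes$gene[nearest[take_near]],
               stringsAsFactors = FALSE),
    data.frame(snp = v$id[take_rand],
               gene = sample(genes$gene, sum(take_rand), replace = TRUE),
               stringsAsFactors = FALSE))
  if (length(planted_genes)) {
    causal <- truth$traits[[1]]$causal
    hit <- causal[stats::runif(length(causal)) < config$planted_term_strength]
    if (length(hit))
      eqtl <- rbind(eqtl, data.frame(
        snp = v$id[hit],
        gene = sample(planted_genes, length(hit), replace = TRUE),
        stringsAsFactors = FALSE))
  }
  eqtl <- unique(eqtl)
  eqtl <- eqtl[order(eqtl$snp, eqtl$gene), ]
  rownames(eqtl) <- NULL
  annotation_db(genes, eqtl, terms)
}

#' Simulate a complete study bundle
#'
#' Orchestrates the generator: environment, truth, optional selection
#' gradient on the driver variable (trait 1), genotypes, per-trait summary
#' statistics, and annotation. All stages are seeded deterministically from
#' `config$seed`.
#'
#' @param config A `sim_config`.
#' @return A `prs_study` list: `genotypes`, `truth`, `sumstats` (named list
#'   per trait), `environment`, `annotation`, `config`.
#' @export
simulate_study <- function(config) {
  set.seed(config$seed)
  seeds <- sample.int(2147483646L, 10 + config$n_traits)
  env <- simulate_environment(config, seed = seeds[1])
  truth <- simulate_truth(config, seed = seeds[2])
  if (config$selection_gradient > 0)
    truth <- apply_selection_gradient(truth, env, config$selection_gradient,
                                      config$driver, trait = 1)
  geno <- simulate_genotypes(truth, config, seed = seeds[3])
  sumstats <- lapply(seq_len(config$n_traits), function(t)
    simulate_sumstats(truth, config$n_gwas, trait = t,
                      swap_fraction = config$swap_fraction,
                      seed = seeds[10 + t]))
  names(sumstats) <- names(truth$traits)
  ann <- simulate_annotation(config, truth, seed = seeds[4])
  structure(list(genotypes = geno, truth = truth, sumstats = sumstats,
                 environment = env, annotation = ann, config = config),
            class = "prs_study")
}

#' @export
print.prs_study <- function(x, ...) {
  cat("prs_study:", n_samples(x$genotypes), "individuals,",
      n_variants(x$genotypes), "variants,",
      x$config$n_populations, "sites,",
      x$config$n_traits, "traits\n")
  cat("  selection gradient:", x$config$selection_gradient,
      " driver:", x$config$driver, " seed:", x$config$seed, "\n")
  invisible(x)
}

#' Hudson-type FST estimate from population allele frequencies
#'
#' Ratio-of-averages estimator over all variants and population pairs:
#' numerator `(p1 - p2)^2`, denominator `p1(1 - p2) + p2(1 - p1)`. Applied
#' to true (noise-free) frequencies this recovers the Balding-Nichols F.
#'
#' @param freq Variants x populations frequency matrix.
#' @return A single FST estimate.
#' @export
fst_hudson <- function(freq) {
  npop <- ncol(freq)
  num <- 0; den <- 0
  for (i in seq_len(npop - 1)) {
    for (j in (i + 1):npop) {
      p1 <- freq[, i]; p2 <- freq[, j]
      num <- num + sum((p1 - p2)^2)
      den <- den + sum(p1 * (1 - p2) + p2 * (1 - p1))
    }
  }
  num / den
}

#' Write a simulated study to disk
#'
#' Emits the on-disk forms of every component (genotypes, sample map,
#' per-trait summary statistics, environment, annotation) plus a JSON
#' manifest recording the seed, configuration, and file checksums.
#'
#' @param study A `prs_study`.
#' @param dir Output directory (created if absent).
#' @param genotype_format `"matrix"` (fast TSV dialect) or `"vcf"`.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, genotype_format = c("matrix", "vcf")) {
  genotype_format <- match.arg(genotype_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gfile <- file.path(dir, if (genotype_format == "vcf") "genotypes.vcf"
                          else "genotypes.tsv")
  write_genotypes(study$genotypes, gfile, format = genotype_format)
  write_sample_map(study$genotypes$samples, file.path(dir, "sample_map.tsv"))
  for (tn in names(study$sumstats))
    write_sumstats(study$sumstats[[tn]],
                   file.path(dir, paste0("sumstats_", tn, ".tsv")))
  write_environment(study$environment, file.path(dir, "environment.tsv"))
  write_annotation(study$annotation, dir)
  files <- list.files(dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  md5 <- as.list(tools::md5sum(files))
  names(md5) <- basename(files)
  manifest <- list(seed = study$config$seed,
                   config = unclass(study$config)[
                     setdiff(names(study$config), "env_spec")],
                   env_variables = study$config$env_spec$variables,
                   md5 = md5)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
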