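#' Build a pipeline run configuration
#'
#' Collects file paths and stage parameters for [run_pipeline()]. Either
#' point the genotype/sumstats/environment entries at existing files, or
#' set `simulate` to a list of [sim_config()] overrides to generate a
#' synthetic study into `outdir/data` first.
#'
#' @param outdir Output directory.
#' @param simulate `NULL`, or a (possibly empty) list of [sim_config()]
#'   overrides.
#' @param genotypes,sample_map,environment,annotation Input paths
#'   (annotation is a directory of genes/eqtl/terms TSVs; `NULL` disables
#'   enrichment).
#' @param sumstats Named character vector of summary-statistics TSV paths,
#'   one per trait.
#' @param genotype_format `"matrix"` or `"vcf"`.
#' @param driver Driver variable name (used for reporting only).
#' @param maf_min,miss_var_max,miss_ind_max,hwe_p_min QC thresholds.
#' @param prune_r2,prune_window,prune_step LD-pruning parameters.
#' @param clump_r2,clump_window_kb Clumping parameters.
#' @param thresholds PRS inclusion thresholds.
#' @param K Ancestry PCs for the main model.
#' @param K_check PCs for the robustness re-fit (default 2 * K).
#' @param B Permutations for validated cells.
#' @param fdr_scope `"all"` or `"best"`.
#' @param q_cut Significance threshold defining cells carried into
#'   permutation/enrichment/NOIA stages (default 0.05).
#' @param n_matched_sets Matched null sets for enrichment (default 100).
#' @param driver_set Optional character vector of correlated variables for
#'   the conditional driver analysis.
#' @param relax Double matching tolerances in enrichment.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, simulate = NULL, genotypes = NULL,
                            sample_map = NULL, environment = NULL,
                            annotation = NULL, sumstats = NULL,
                            genotype_format = "matrix", driver = NULL,
                            maf_min = 0.01, miss_var_max = 0.05,
                            miss_ind_max = 0.05, hwe_p_min = 1e-4,
                            prune_r2 = 0.2, prune_window = 50,
                            prune_step = 5, clump_r2 = 0.3,
                            clump_window_kb = 500,
                            thresholds = pt_thresholds(), K = 10,
                            K_check = 2 * K, B = 10000, fdr_scope = "all",
                            q_cut = 0.05, n_matched_sets = 100,
                            driver_set = NULL, relax = FALSE, seed = 1) {
  # note: an argument is named `environment`, so use base::environment()
  cfg <- mget(names(formals(pipeline_config)), envir = base::environment())
  structure(cfg, class = "pipeline_config")
}

pipeline_stages <- c("simulate", "qc", "pca", "prs", "assoc", "permute",
                     "enrich", "noia")

plog <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), "INFO ", ...)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order: simulate (optional), QC, PCA,
#' per-trait PRS construction, the association grid with FDR, permutation
#' validation of significant cells, PC-depth robustness comparison,
#' optional conditional driver analysis, eQTL-term enrichment with matched
#' null sets, and NOIA fits for oligogenic cells. Earlier stages a
#' requested stage depends on are recomputed in memory; only requested
#' stages write outputs. A JSON manifest recording the seed, parameters,
#' and output checksums is written at the end.
#'
#' @param config A `pipeline_config`.
#' @param stages Character vector of stages (default: all).
#' @return Invisibly, a list with the in-memory results (`study`, `core`,
#'   and per-stage outputs).
#' @export
run_pipeline <- function(config, stages = pipeline_stages) {
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(path) written <<- c(written, path)

  # ---- inputs / simulate ----
  if (!is.null(config$simulate)) {
    scfg <- do.call(sim_config, c(config$simulate,
                                  if (!"seed" %in% names(config$simulate))
                                    list(seed = config$seed)))
    plog("simulating study (seed ", scfg$seed, ")")
    study <- simulate_study(scfg)
    if ("simulate" %in% stages) {
      ddir <- file.path(outdir, "data")
      write_study(study, ddir, genotype_format = config$genotype_format)
      emit(list.files(ddir, full.names = TRUE))
      plog("simulated study written to ", ddir)
    }
    if (is.null(config$driver)) config$driver <- scfg$driver
  } else {
    for (f in c(config$genotypes, config$sample_map, config$environment,
                unlist(config$sumstats)))
      if (!file.exists(f)) stop("input file not found: ", f)
    if (!is.null(config$annotation) && !dir.exists(config$annotation))
      stop("annotation directory not found: ", config$annotation)
    plog("loading inputs")
    g <- read_genotypes(config$genotypes, format = config$genotype_format,
                        sample_map = config$sample_map)
    ss <- lapply(config$sumstats, read_sumstats)
    if (is.null(names(ss)))
      names(ss) <- paste0("trait_", seq_along(ss))
    env <- read_environment(config$environment, driver = config$driver)
    ann <- if (!is.null(config$annotation)) read_annotation(config$annotation)
    study <- list(genotypes = g, sumstats = ss, environment = env,
                  annotation = ann,
                  config = list(driver = config$driver, seed = config$seed))
  }
  if (identical(stages, "simulate")) {
    write_manifest(config, written, outdir)
    return(invisible(list(study = study)))
  }

  # ---- core: qc -> pca -> prs -> assoc ----
  plog("running core pipeline (K = ", config$K, ")")
  core <- run_core_pipeline(
    study, K = config$K, prune_r2 = config$prune_r2,
    prune_window = config$prune_window, prune_step = config$prune_step,
    clump_r2 = config$clump_r2, clump_window_kb = config$clump_window_kb,
    thresholds = config$thresholds, fdr_scope = config$fdr_scope)
  if ("qc" %in% stages) {
    utils::write.table(core$qc_report, file.path(outdir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_genotypes(core$genotypes, file.path(outdir, "qc_genotypes.tsv"))
    emit(file.path(outdir, c("qc_report.tsv", "qc_genotypes.tsv",
                             "qc_genotypes.tsv.variants.tsv")))
  }
  if ("pca" %in% stages) {
    writeLines(core$pruned_ids, file.path(outdir, "pruned_ids.txt"))
    utils::write.table(
      data.frame(IID = rownames(core$pcs$scores), core$pcs$scores),
      file.path(outdir, "pcs.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(PC = seq_len(core$pcs$K),
                 EXPLAINED = core$pcs$explained_variance),
      file.path(outdir, "explained_variance.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    emit(file.path(outdir, c("pruned_ids.txt", "pcs.tsv",
                             "explained_variance.tsv")))
  }
  if ("prs" %in% stages) {
    for (tn in names(core$prs_list)) {
      write_clump_report(core$clumps[[tn]], core$harmonized[[tn]],
                         file.path(outdir, paste0("clump_", tn, ".tsv")))
      write_prs(core$prs_list[[tn]],
                file.path(outdir, paste0("prs_", tn, ".tsv")))
      emit(file.path(outdir, paste0(c("clump_", "prs_"), tn, ".tsv")))
    }
  }
  env_vars <- setdiff(names(study$environment), "site_id")
  if ("assoc" %in% stages) {
    write_grid(core$grid, file.path(outdir, "assoc_grid.tsv"))
    sm <- spearman_matrix(study$environment)
    utils::write.table(round(sm$rho, 6),
                       file.path(outdir, "spearman_rho.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    utils::write.table(signif(sm$p, 6), file.path(outdir, "spearman_p.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    emit(file.path(outdir, c("assoc_grid.tsv", "spearman_rho.tsv",
                             "spearman_p.tsv")))
  }

  grid <- core$grid
  sig <- grid[!is.na(grid$q) & grid$q < config$q_cut, ]
  plog(nrow(sig), " significant cell(s) at q < ", config$q_cut)
  yvar <- function(v) boxcox_transform(
    env_broadcast(study$environment, core$sites, v))$transformed
  cell_prs <- function(cell) {
    prs <- core$prs_list[[cell$trait]]
    prs$scores[, match(cell$pt, prs$thresholds)]
  }

  # ---- permutation + PC robustness on significant cells ----
  if ("permute" %in% stages && nrow(sig)) {
    set.seed(config$seed + 17L)
    rows <- list(); cmp_rows <- list()
    pcs_large <- tryCatch(
      compute_pcs(core$genotypes, core$pruned_ids, config$K_check),
      error = function(e) NULL)
    for (i in seq_len(nrow(sig))) {
      cell <- sig[i, ]
      y <- yvar(cell$variable)
      pn <- permutation_null(cell_prs(cell), y, core$pcs, B = config$B)
      rows[[i]] <- data.frame(TRAIT = cell$trait, VARIABLE = cell$variable,
                              PT = cell$pt, Z_OBS = pn$z_obs,
                              PERM_P = pn$perm_p, B = pn$B)
      utils::write.table(
        data.frame(Z_NULL = pn$z_null),
        file.path(outdir, sprintf("perm_null_%s_%s_%g.tsv", cell$trait,
                                  cell$variable, cell$pt)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      emit(file.path(outdir, sprintf("perm_null_%s_%s_%g.tsv", cell$trait,
                                     cell$variable, cell$pt)))
      if (!is.null(pcs_large)) {
        cp <- compare_pc_models(cell_prs(cell), y, core$pcs, pcs_large)
        cmp_rows[[i]] <- data.frame(
          TRAIT = cell$trait, VARIABLE = cell$variable, PT = cell$pt,
          BETA_K = cp$fit_small$beta, BETA_KCHECK = cp$fit_large$beta,
          STAT = cp$statistic, P = cp$p)
      }
    }
    utils::write.table(do.call(rbind, rows),
                       file.path(outdir, "permutation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(file.path(outdir, "permutation.tsv"))
    if (length(cmp_rows)) {
      utils::write.table(do.call(rbind, cmp_rows),
                         file.path(outdir, "pc_comparison.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit(file.path(outdir, "pc_comparison.tsv"))
    }
    if (!is.null(config$driver_set) && length(config$driver_set) >= 2) {
      best <- sig[which.min(sig$p), ]
      da <- driver_analysis(cell_prs(best), study$environment,
                            config$driver_set, core$pcs, core$sites)
      utils::write.table(da, file.path(outdir, "driver_analysis.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit(file.path(outdir, "driver_analysis.tsv"))
    }
  }

  # ---- enrichment on the best significant polygenic cell ----
  enrich_out <- NULL
  if ("enrich" %in% stages && nrow(sig) && !is.null(study$annotation)) {
    poly <- sig[sig$n_snps >= 2, ]
    if (nrow(poly)) {
      cell <- poly[which.min(poly$p), ]
      prs <- core$prs_list[[cell$trait]]
      members <- prs$members[[match(cell$pt, prs$thresholds)]]
      sel <- suppressWarnings(
        select_prs_snps(members, core$harmonized[[cell$trait]],
                        core$genotypes, yvar(cell$variable), core$pcs,
                        z_cell = cell$z))
      if (length(sel) >= 2) {
        db <- study$annotation
        props <- snp_properties(core$genotypes, db, band = core$band)
        panel_eqtl <- db$eqtl[db$eqtl$snp %in% core$genotypes$variants$id, ]
        universe <- unique(panel_eqtl$gene)
        obs <- hypergeom_enrich(snps_to_genes(sel, db), db, universe)
        matched <- tryCatch(
          match_snps(sel, props, n_sets = config$n_matched_sets,
                     seed = config$seed + 23L, relax = config$relax),
          error = function(e) {
            if (config$relax)
              stop("stage enrich: ", conditionMessage(e), call. = FALSE)
            plog("strict matching failed; retrying with relaxed tolerances")
            tryCatch(
              match_snps(sel, props, n_sets = config$n_matched_sets,
                         seed = config$seed + 23L, relax = TRUE),
              error = function(e2)
                stop("stage enrich: ", conditionMessage(e2), call. = FALSE))
          })
        menr <- lapply(matched, function(s)
          hypergeom_enrich(snps_to_genes(s, db), db, universe))
        nullres <- empirical_enrichment_null(obs, menr)
        utils::write.table(obs, file.path(outdir, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(
          data.frame(SET = seq_along(nullres$counts),
                     N_SIGNIFICANT = nullres$counts),
          file.path(outdir, "enrichment_null_counts.tsv"), sep = "\t",
          quote = FALSE, row.names = FALSE)
        utils::write.table(
          data.frame(SET = rep(seq_along(matched), lengths(matched)),
                     SNP = unlist(matched)),
          file.path(outdir, "matched_sets.tsv"), sep = "\t",
          quote = FALSE, row.names = FALSE)
        writeLines(sel, file.path(outdir, "selected_snps.txt"))
        emit(file.path(outdir, c("enrichment.tsv",
                                 "enrichment_null_counts.tsv",
                                 "matched_sets.tsv",
                                 "selected_snps.txt")))
        enrich_out <- list(cell = cell, selected = sel, obs = obs,
                           null = nullres)
        plog("enrichment: ", nullres$count_obs, " significant term(s), ",
             "empirical p = ", signif(nullres$empirical_p, 3))
      } else plog("enrichment skipped: fewer than 2 concordant variants")
    } else plog("enrichment skipped: no polygenic significant cell")
  }

  # ---- NOIA for oligogenic cells ----
  noia_out <- list()
  if ("noia" %in% stages && nrow(sig)) {
    oligo <- sig[sig$n_snps >= 1 & sig$n_snps <= 3, ]
    if (nrow(oligo)) {
      path <- file.path(outdir, "noia_report.tsv")
      first <- TRUE
      for (i in seq_len(nrow(oligo))) {
        cell <- oligo[i, ]
        prs <- core$prs_list[[cell$trait]]
        loci <- prs$members[[match(cell$pt, prs$thresholds)]]
        fit <- tryCatch(
          fit_noia(noia_design(core$genotypes, loci), yvar(cell$variable),
                   covariates = core$pcs),
          error = function(e) {
            plog("NOIA skipped for ", paste(loci, collapse = ","), ": ",
                 conditionMessage(e)); NULL
          })
        if (is.null(fit)) next
        write_noia_report(fit, path, append = !first)
        first <- FALSE
        noia_out[[length(noia_out) + 1L]] <- list(cell = cell, fit = fit)
      }
      if (!first) emit(path)
    } else plog("NOIA skipped: no oligogenic significant cell")
  }

  write_manifest(config, written, outdir)
  plog("pipeline complete: ", length(unique(unlist(written))),
       " file(s) in ", outdir)
  invisible(list(study = study, core = core, significant = sig,
                 enrichment = enrich_out, noia = noia_out))
}

write_manifest <- function(config, written, outdir) {
  files <- sort(unique(unlist(written)))
  files <- files[file.exists(files)]
  cfg <- unclass(config)
  cfg$thresholds <- as.numeric(cfg$thresholds)
  manifest <- list(seed = config$seed, config = cfg,
                   outputs = as.list(tools::md5sum(files)))
  names(manifest$outputs) <- basename(files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
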