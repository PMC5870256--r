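#' Construct a genotype matrix
#'
#' The central genotype container: an individuals-by-variants matrix of
#' alt-allele dosages (0, 1, 2 or `NA` for missing) together with variant and
#' sample metadata. Dosages count copies of the alternate allele.
#'
#' @param dosages Integer matrix, individuals in rows, variants in columns.
#'   Values must be 0, 1, 2 or `NA`.
#' @param variants Data frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`. Positions must be strictly increasing within chromosome.
#' @param samples Data frame with columns `id` and `site_id` (sampling site).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants`, `samples`.
#' @export
genotype_matrix <- function(dosages, variants, samples) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need_v <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need_v %in% names(variants)))
    stop("variants must have columns: ", paste(need_v, collapse = ", "))
  if (!all(c("id", "site_id") %in% names(samples)))
    stop("samples must have columns: id, site_id")
  if (nrow(samples) != nrow(dosages) || nrow(variants) != ncol(dosages))
    stop("dosage dimensions (", nrow(dosages), " x ", ncol(dosages),
         ") inconsistent with ", nrow(samples), " samples and ",
         nrow(variants), " variants")
  dup <- variants$id[duplicated(variants$id)]
  if (length(dup))
    stop("duplicate variant ID(s): ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(samples$id))
    stop("duplicate sample IDs")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  if (any(!nzchar(variants$ref)) || any(!nzchar(variants$alt)) ||
      any(variants$ref == variants$alt))
    stop("ref and alt alleles must be non-empty and distinct")
  ord_bad <- unlist(lapply(split(variants$pos, variants$chrom),
                           function(p) any(diff(p) <= 0)))
  if (any(ord_bad))
    stop("positions must be strictly increasing within chromosome: ",
         paste(names(ord_bad)[ord_bad], collapse = ", "))
  rownames(dosages) <- samples$id
  colnames(dosages) <- variants$id
  rownames(variants) <- NULL
  rownames(samples) <- NULL
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "variants\n")
  cat("  chromosomes:", length(unique(x$variants$chrom)),
      " sites:", length(unique(x$samples$site_id)), "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missingness: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Number of samples / variants in a genotype matrix
#' @param g A `genotype_matrix`.
#' @return Integer count.
#' @export
n_samples <- function(g) nrow(g$dosages)

#' @rdname n_samples
#' @export
n_variants <- function(g) ncol(g$dosages)

#' Subset a genotype matrix
#'
#' @param x A `genotype_matrix`.
#' @param i Sample index (integer, logical, or sample IDs).
#' @param j Variant index (integer, logical, or variant IDs).
#' @param ... Ignored.
#' @return A `genotype_matrix` restricted to the selected rows/columns.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  if (is.character(i)) i <- match(i, x$samples$id)
  if (is.character(j)) j <- match(j, x$variants$id)
  if (anyNA(i)) stop("unknown sample ID in subset")
  if (anyNA(j)) stop("unknown variant ID in subset")
  genotype_matrix(x$dosages[i, j, drop = FALSE],
                  x$variants[j, , drop = FALSE],
                  x$samples[i, , drop = FALSE])
}

#' Alt-allele frequency per variant
#'
#' Frequencies are computed over non-missing genotypes.
#'
#' @param g A `genotype_matrix`.
#' @return Named numeric vector of alt-allele frequencies.
#' @export
allele_freq <- function(g) colMeans(g$dosages, na.rm = TRUE) / 2

#' Minor allele frequency per variant
#' @param g A `genotype_matrix`.
#' @return Named numeric vector, `pmin(p, 1 - p)`.
#' @export
maf <- function(g) {
  p <- allele_freq(g)
  pmin(p, 1 - p)
}

#' Write genotypes to disk
#'
#' Two on-disk dialects are supported: a plain dosage matrix TSV (header row
#' `IID` followed by variant IDs, one row per individual, `NA` for missing;
#' variant metadata in a sidecar `<path>.variants.tsv`) and VCF v4.2 with GT
#' fields only.
#'
#' @param g A `genotype_matrix`.
#' @param path Output file path.
#' @param format `"matrix"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("matrix", "vcf")) {
  format <- match.arg(format)
  if (format == "matrix") {
    m <- as.data.frame(g$dosages)
    out <- cbind(IID = g$samples$id, m)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(g$variants, paste0(path, ".variants.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##source=prsadapt",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", g$samples$id), collapse = "\t")),
               con)
    gt_code <- c("0/0", "0/1", "1/1")
    for (j in seq_len(ncol(g$dosages))) {
      d <- g$dosages[, j]
      gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
      v <- g$variants[j, ]
      writeLines(paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", ".", ".",
                         "GT", gt), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read genotypes from disk
#'
#' Reads either the dosage-matrix TSV dialect written by [write_genotypes()]
#' or a VCF v4.2 file (GT field parsed as alt-allele count; `./.` becomes
#' missing). Every sample must appear in the sample map.
#'
#' @param path Input file.
#' @param format `"matrix"` or `"vcf"`.
#' @param sample_map Data frame with columns `IID` and `SITE_ID` (or `id`,
#'   `site_id`), or a path to such a TSV.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("matrix", "vcf"),
                           sample_map = NULL) {
  format <- match.arg(format)
  if (is.character(sample_map))
    sample_map <- utils::read.delim(sample_map, stringsAsFactors = FALSE)
  if (!is.null(sample_map)) {
    names(sample_map) <- tolower(names(sample_map))
    names(sample_map)[names(sample_map) == "iid"] <- "id"
  }
  if (format == "matrix") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (names(tab)[1] != "IID")
      stop("matrix dialect requires first column 'IID' in ", path)
    ids <- tab$IID
    vids <- names(tab)[-1]           # before subsetting, which dedupes names
    dup <- vids[duplicated(vids)]
    if (length(dup))
      stop("duplicate variant ID(s) in ", path, ": ",
           paste(unique(dup), collapse = ", "))
    dos <- as.matrix(tab[, -1, drop = FALSE])
    colnames(dos) <- vids
    vpath <- paste0(path, ".variants.tsv")
    if (file.exists(vpath)) {
      variants <- utils::read.delim(vpath, stringsAsFactors = FALSE,
                                    colClasses = c(chrom = "character"))
    } else {
      variants <- data.frame(id = vids, chrom = "1", pos = seq_along(vids),
                             ref = "A", alt = "B", stringsAsFactors = FALSE)
    }
    samples <- resolve_samples(ids, sample_map, path)
    return(genotype_matrix(dos, variants, samples))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- colnames(gt)
  vids <- fix[, "ID"]
  dup <- vids[duplicated(vids)]
  if (length(dup))
    stop("duplicate variant ID(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  parse_gt <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    bad <- !is.na(x) & is.na(out) & x != "./."
    if (any(bad))
      stop("malformed GT value(s) in ", path, ": ",
           paste(unique(x[bad]), collapse = ", "))
    out
  }
  dos <- t(apply(gt, 1, parse_gt))
  dos <- matrix(as.integer(dos), nrow = nrow(gt), ncol = ncol(gt))
  variants <- data.frame(id = vids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  samples <- resolve_samples(ids, sample_map, path)
  genotype_matrix(t(dos), variants, samples)
}

resolve_samples <- function(ids, sample_map, path) {
  if (is.null(sample_map))
    return(data.frame(id = ids, site_id = NA_character_,
                      stringsAsFactors = FALSE))
  miss <- setdiff(ids, sample_map$id)
  if (length(miss)) {
    at <- which(ids %in% miss)[1]
    stop("sample '", miss[1], "' (column ", at, ") in ", path,
         " is absent from the sample map")
  }
  data.frame(id = ids,
             site_id = sample_map$site_id[match(ids, sample_map$id)],
             stringsAsFactors = FALSE)
}

#' Write / read a sample-to-site map
#' @param samples Data frame with `id`, `site_id`.
#' @param path TSV path (columns `IID`, `SITE_ID`).
#' @return `path` invisibly.
#' @export
write_sample_map <- function(samples, path) {
  utils::write.table(data.frame(IID = samples$id, SITE_ID = samples$site_id),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
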