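#' Construct a summary-statistics table
#'
#' Per-variant GWAS summary statistics for one trait: effect and other
#' allele, per-allele effect size (beta counts the effect allele), and
#' association p-value.
#'
#' @param x Data frame with columns `id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `beta`, `p`.
#' @param trait Trait label.
#' @return A `summary_stats` data frame.
#' @export
summary_stats <- function(x, trait = "trait") {
  need <- c("id", "chrom", "pos", "effect_allele", "other_allele", "beta", "p")
  if (!all(need %in% names(x)))
    stop("summary statistics need columns: ", paste(need, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)[, need]
  if (anyDuplicated(x$id))
    stop("duplicate variant ID(s) in summary statistics: ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  if (any(x$p <= 0 | x$p > 1)) stop("p-values must lie in (0, 1]")
  if (any(x$effect_allele == x$other_allele))
    stop("effect and other allele must be distinct")
  rownames(x) <- NULL
  attr(x, "trait") <- trait
  class(x) <- c("summary_stats", "data.frame")
  x
}

#' Write / read GWAS summary statistics (TSV dialect)
#'
#' Columns: `SNP`, `CHR`, `BP`, `A1` (effect allele), `A2`, `BETA`, `P`.
#'
#' @param ss A `summary_stats` object.
#' @param path TSV path.
#' @return `path` invisibly for the writer; a `summary_stats` for the reader.
#' @export
write_sumstats <- function(ss, path) {
  out <- data.frame(SNP = ss$id, CHR = ss$chrom, BP = ss$pos,
                    A1 = ss$effect_allele, A2 = ss$other_allele,
                    BETA = ss$beta, P = ss$p)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @param trait Trait label attached on read.
#' @export
read_sumstats <- function(path, trait = sub("\\.tsv$", "", basename(path))) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(CHR = "character"))
  summary_stats(data.frame(id = tab$SNP, chrom = tab$CHR, pos = tab$BP,
                           effect_allele = tab$A1, other_allele = tab$A2,
                           beta = tab$BETA, p = tab$P,
                           stringsAsFactors = FALSE),
                trait = trait)
}

#' Write / read the site-by-variable environment table
#'
#' TSV with `SITE_ID` followed by one numeric column per variable.
#'
#' @param env An `environment_table`.
#' @param path TSV path.
#' @return `path` invisibly; reader returns an `environment_table`.
#' @export
write_environment <- function(env, path) {
  out <- as.data.frame(env)
  names(out)[names(out) == "site_id"] <- "SITE_ID"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_environment
#' @param driver Optional driver-variable name to attach.
#' @export
read_environment <- function(path, driver = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab)[names(tab) == "SITE_ID"] <- "site_id"
  attr(tab, "driver") <- driver %||% names(tab)[names(tab) != "site_id"][1]
  class(tab) <- c("environment_table", "data.frame")
  tab
}
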