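#' Construct an annotation database
#'
#' Container joining gene intervals, SNP-to-gene eQTL links, and
#' gene-to-term membership, used for eQTL-mediated term enrichment and for
#' matched-SNP-set property computation. Intervals are 1-based inclusive
#' internally and in files.
#'
#' @param genes Data frame: `gene`, `chrom`, `start`, `end` (`start < end`).
#' @param eqtl Data frame: `snp`, `gene`.
#' @param terms Data frame: `gene`, `term`.
#' @return An `annotation_db` list.
#' @export
annotation_db <- function(genes, eqtl, terms) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  eqtl <- as.data.frame(eqtl, stringsAsFactors = FALSE)
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  if (!all(c("gene", "chrom", "start", "end") %in% names(genes)))
    stop("genes needs columns gene, chrom, start, end")
  if (any(genes$start >= genes$end))
    stop("gene intervals must satisfy start < end")
  if (anyDuplicated(genes$gene)) stop("duplicate gene IDs")
  bad <- setdiff(eqtl$gene, genes$gene)
  if (length(bad))
    stop("eqtl references unknown gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- setdiff(terms$gene, genes$gene)
  if (length(bad))
    stop("terms references unknown gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  structure(list(genes = genes, eqtl = eqtl, terms = terms),
            class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  cat("annotation_db:", nrow(x$genes), "genes,", nrow(x$eqtl),
      "eQTL links,", length(unique(x$terms$term)), "terms\n")
  invisible(x)
}

#' Write / read annotation TSVs
#'
#' Three files in `dir`: `genes.tsv` (GENE, CHR, START, END), `eqtl.tsv`
#' (SNP, GENE), `terms.tsv` (GENE, TERM).
#'
#' @param db An `annotation_db`.
#' @param dir Directory.
#' @return `dir` invisibly; reader returns an `annotation_db`.
#' @export
write_annotation <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(GENE = db$genes$gene, CHR = db$genes$chrom,
               START = db$genes$start, END = db$genes$end),
    file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(SNP = db$eqtl$snp, GENE = db$eqtl$gene),
                     file.path(dir, "eqtl.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(GENE = db$terms$gene, TERM = db$terms$term),
                     file.path(dir, "terms.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(dir) {
  g <- utils::read.delim(file.path(dir, "genes.tsv"),
                         stringsAsFactors = FALSE,
                         colClasses = c(CHR = "character"))
  e <- utils::read.delim(file.path(dir, "eqtl.tsv"), stringsAsFactors = FALSE)
  t <- utils::read.delim(file.path(dir, "terms.tsv"), stringsAsFactors = FALSE)
  annotation_db(
    data.frame(gene = g$GENE, chrom = g$CHR, start = g$START, end = g$END,
               stringsAsFactors = FALSE),
    data.frame(snp = e$SNP, gene = e$GENE, stringsAsFactors = FALSE),
    data.frame(gene = t$GENE, term = t$TERM, stringsAsFactors = FALSE))
}
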