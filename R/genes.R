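#' Read gene models from BED6 or GFF3
#'
#' A gene model is the coding interval (start codon through stop codon) of
#' one gene. BED intervals (half-open, 0-based) are converted to 1-based
#' inclusive coordinates. For GFF3, all CDS features belonging to the same
#' gene (via their `Parent`, falling back to `ID`) are merged to the
#' outermost start/stop. Models are returned in stable `(chrom, cds_start)`
#' order; duplicate gene identifiers are an error.
#'
#' @param path path to the annotation file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return a `data.table` with columns `gene_id`, `chrom`, `strand`,
#'   `cds_start`, `cds_end` (1-based inclusive).
#' @export
read_genes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff3\\.gz|gff\\.gz)$", path,
                        ignore.case = TRUE)) "gff3" else "bed"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    genes <- data.table(
      gene_id = if (!is.null(gr$name)) as.character(gr$name)
                else sprintf("gene%06d", seq_along(gr)),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      cds_start = GenomicRanges::start(gr),
      cds_end = GenomicRanges::end(gr))
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    cds <- gr[gr$type == "CDS"]
    if (length(cds) == 0L) stop("no CDS features in ", path)
    parent <- if (!is.null(cds$Parent) && any(lengths(cds$Parent) > 0L)) {
      vapply(cds$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
             character(1L))
    } else as.character(cds$ID)
    parent <- sub("^(gene|transcript|mRNA):", "", parent)
    dt <- data.table(
      gene_id = parent,
      chrom = as.character(GenomicRanges::seqnames(cds)),
      strand = as.character(GenomicRanges::strand(cds)),
      start = GenomicRanges::start(cds),
      end = GenomicRanges::end(cds))
    genes <- dt[, list(chrom = chrom[1L], strand = strand[1L],
                       cds_start = min(start), cds_end = max(end)),
                by = "gene_id"]
  }
  genes[strand == "*", strand := "+"]
  validate_genes(genes)
  setorder(genes, chrom, cds_start)
  genes[]
}

validate_genes <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "cds_start", "cds_end")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop("gene table is missing columns: ", paste(miss, collapse = ", "))
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup))
    stop("duplicate gene_id(s): ",
         paste(utils::head(dup, 5L), collapse = ", "))
  bad <- genes$gene_id[genes$cds_start > genes$cds_end |
                       genes$cds_start < 1L]
  if (length(bad))
    stop("invalid coordinates (need 1 <= cds_start <= cds_end) for: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  invisible(genes)
}

#' Write gene models as BED6
#'
#' @param genes a gene table as returned by [read_genes()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genes_bed <- function(genes, path) {
  validate_genes(genes)
  out <- data.table(genes$chrom, genes$cds_start - 1L, genes$cds_end,
                    genes$gene_id, 0L, genes$strand)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write gene models as GFF3 (one gene + one CDS feature per model)
#'
#' @inheritParams write_genes_bed
#' @export
write_genes_gff3 <- function(genes, path) {
  validate_genes(genes)
  lines <- c("##gff-version 3",
             sprintf("%s\tgbmtools\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$cds_start, genes$cds_end,
                     genes$strand, genes$gene_id),
             sprintf("%s\tgbmtools\tCDS\t%d\t%d\t.\t%s\t0\tID=cds.%s;Parent=%s",
                     genes$chrom, genes$cds_start, genes$cds_end,
                     genes$strand, genes$gene_id, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}
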