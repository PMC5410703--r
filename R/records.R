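#' @importFrom data.table data.table as.data.table setDT setkey setorder fread fwrite := .N .SD CJ foverlaps copy setnames setattr rbindlist
NULL

CONTEXTS <- c("CG", "CHG", "CHH")

#' Collapse trinucleotide strings to sequence-context classes
#'
#' Each cytosine is assigned exactly one of the three classes from its
#' trinucleotide: `CG` when the next base is G, `CHG` when the base after
#' next is G, `CHH` otherwise (H = A, C or T). Already-collapsed labels
#' (`"CG"`, `"CHG"`, `"CHH"`) pass through unchanged.
#'
#' @param tri character vector of trinucleotide (or context) strings.
#' @return character vector over `c("CG","CHG","CHH")`.
#' @export
#' @examples
#' context_from_tri(c("CGA", "CAG", "CTT"))
context_from_tri <- function(tri) {
  tri <- toupper(tri)
  ifelse(substr(tri, 2L, 2L) == "G", "CG",
         ifelse(substr(tri, 3L, 3L) == "G", "CHG", "CHH"))
}

# Validate a per-cytosine record table in place; returns invisibly or stops
# with the offending source line numbers (offset accounts for a skipped
# header when reading from file).
validate_records <- function(rec, line_offset = 0L) {
  need <- c("chrom", "pos", "strand", "context", "meth_reads", "total_reads")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("record table is missing columns: ", paste(miss, collapse = ", "))
  bad <- which(
    is.na(rec$pos) | rec$pos < 1L |
    !(rec$strand %in% c("+", "-")) |
    !(rec$context %in% CONTEXTS) |
    is.na(rec$meth_reads) | rec$meth_reads < 0L |
    is.na(rec$total_reads) | rec$total_reads < 0L |
    rec$meth_reads > rec$total_reads
  )
  if (length(bad)) {
    shown <- utils::head(bad + line_offset, 5L)
    stop("invalid cytosine record(s) at line(s) ",
         paste(shown, collapse = ", "),
         if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L),
         ": require pos >= 1, strand in {+,-}, context in {CG,CHG,CHH}, ",
         "0 <= meth_reads <= total_reads")
  }
  invisible(rec)
}

#' Read an allc-style per-cytosine methylation call table
#'
#' Expects 6 or 7 tab-separated columns: chromosome, 1-based position,
#' strand, trinucleotide context, methylated read count, total read count,
#' and an optional call flag (read-tolerated and ignored). Trinucleotide
#' strings are collapsed to the CG/CHG/CHH classes. Rows violating the
#' record invariants (counts non-negative, methylated <= total) are rejected
#' with their line numbers. Gzipped input is read transparently.
#'
#' @param path path to the TSV file.
#' @param header logical; set `TRUE` if the file carries a header line.
#' @return a `data.table` with columns `chrom`, `pos`, `strand`, `context`,
#'   `meth_reads`, `total_reads`, ordered as in the file.
#' @export
read_allc <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  first <- readLines(con, n = 1L + as.integer(header))
  close(con)
  empty <- length(first) <= as.integer(header)
  rec <- if (empty) data.table() else
    fread(path, header = header, sep = "\t", fill = FALSE,
          colClasses = list(character = 1L))
  if (nrow(rec) == 0L) {
    return(data.table(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      meth_reads = integer(), total_reads = integer()))
  }
  if (!ncol(rec) %in% c(6L, 7L))
    stop("allc table must have 6 or 7 tab-separated columns, found ",
         ncol(rec), " in ", path)
  rec <- rec[, 1:6]
  setnames(rec, c("chrom", "pos", "strand", "context",
                  "meth_reads", "total_reads"))
  rec[, `:=`(chrom = as.character(chrom),
             pos = as.integer(pos),
             strand = as.character(strand),
             context = context_from_tri(as.character(context)),
             meth_reads = as.integer(meth_reads),
             total_reads = as.integer(total_reads))]
  validate_records(rec, line_offset = as.integer(header))
  rec[]
}

#' Write records as an allc-style table
#'
#' Seven tab-separated columns, no header: chromosome, position, strand,
#' context, methylated reads, total reads, and a constant call flag of 1.
#' An empty record set yields a valid empty file.
#'
#' @param records a record `data.table` as returned by [read_allc()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_allc <- function(records, path) {
  validate_records(records)
  out <- data.table(records$chrom, records$pos, records$strand,
                    records$context, records$meth_reads,
                    records$total_reads, rep(1L, nrow(records)))
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
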