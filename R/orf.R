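STOP_CODONS <- c("TAA", "TAG", "TGA")

# Longest start-to-stop ORF in one reading frame of a forward-oriented
# sequence (character scalar). Returns NULL or list(start, end, length_nt)
# in the frame's own forward coordinates, stop codon included.
orf_in_frame <- function(seq, frame) {
  n <- nchar(seq)
  ncod <- (n - frame) %/% 3L
  if (ncod < 2L) return(NULL)
  at <- frame + 3L * (seq_len(ncod) - 1L) + 1L
  codons <- substring(seq, at, at + 2L)
  starts <- which(codons == "ATG")
  stops <- which(codons %in% STOP_CODONS)
  if (!length(starts) || !length(stops)) return(NULL)
  # first in-frame stop at or after each start; no internal stop by construction
  nxt <- stops[findInterval(starts - 1L, stops) + 1L]
  ok <- !is.na(nxt)
  if (!any(ok)) return(NULL)
  len <- (nxt[ok] - starts[ok] + 1L) * 3L
  best <- which.max(len)  # leftmost ATG on ties (which.max returns first)
  s <- starts[ok][best]
  list(start = at[s], end = at[nxt[ok][best]] + 2L, length_nt = len[best])
}

#' Longest open reading frame over all six frames
#'
#' Scans the three forward and three reverse-complement frames of a
#' transcript for the longest ORF that begins with ATG, ends with one of
#' the three stop codons (stop included in the span), and has no internal
#' stop. Codons containing N are neither start nor stop codons. Ties are
#' broken deterministically: forward strand first, then lower frame, then
#' leftmost start.
#'
#' @param sequence a single DNA string over A/C/G/T/N (case-insensitive).
#' @return a list with elements `strand` (`"+"`/`"-"`), `frame` (0-2),
#'   `start`, `end` (1-based inclusive, on the input's forward
#'   coordinates), and `length_nt` (a multiple of 3); or `NULL` when no
#'   qualifying ORF exists.
#' @export
#' @examples
#' longest_orf("ATGAAATAA")
longest_orf <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  seq <- toupper(as.character(sequence))
  n <- nchar(seq)
  if (n < 6L) return(NULL)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (frame in 0:2) {
      hit <- orf_in_frame(s, frame)
      if (is.null(hit)) next
      if (is.null(best) || hit$length_nt > best$length_nt) {
        if (strand == "-") {
          fwd <- c(n - hit$end + 1L, n - hit$start + 1L)
          hit$start <- fwd[1L]; hit$end <- fwd[2L]
        }
        best <- c(list(strand = strand, frame = frame), hit)
      }
    }
  }
  best
}

#' Filter transcripts by the six-frame longest-ORF rule
#'
#' Keeps only transcripts in which [longest_orf()] finds an ATG-initiated,
#' stop-terminated open reading frame, the filter applied to
#' transcriptome-only assemblies before methylation read mapping.
#'
#' @param sequences a named character vector of transcript sequences, or a
#'   path to a FASTA file (read with Biostrings).
#' @return a `data.table` with one row per input transcript:
#'   `transcript_id`, `kept` (logical), and the ORF coordinates
#'   (`strand`, `frame`, `start`, `end`, `length_nt`; NA when none).
#' @export
filter_transcripts <- function(sequences) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    ss <- Biostrings::readDNAStringSet(sequences)
    sequences <- stats::setNames(as.character(ss), names(ss))
  }
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("tx%05d", seq_along(sequences))
  rows <- lapply(seq_along(sequences), function(i) {
    orf <- longest_orf(sequences[[i]])
    if (is.null(orf)) {
      data.table(transcript_id = ids[i], kept = FALSE,
                 strand = NA_character_, frame = NA_integer_,
                 start = NA_integer_, end = NA_integer_,
                 length_nt = NA_integer_)
    } else {
      data.table(transcript_id = ids[i], kept = TRUE,
                 strand = orf$strand, frame = orf$frame,
                 start = orf$start, end = orf$end,
                 length_nt = orf$length_nt)
    }
  })
  rbindlist(rows)
}
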