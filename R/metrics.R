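#' Weighted DNA methylation level
#'
#' The coverage-weighted methylation level of a region: total methylated
#' reads divided by total (methylated plus unmethylated) reads over all
#' cytosines of the requested context, robust at low depth. Returns
#' `NA_real_` (never 0) when no read covers the region.
#'
#' @param records per-cytosine record table (see [read_allc()]).
#' @param context one of `"CG"`, `"CHG"`, `"CHH"`, or `NULL` for all.
#' @param chrom,start,end optional region filter (1-based inclusive);
#'   omit all three for the whole genome.
#' @return a level in [0,1], or `NA_real_` when the denominator is 0.
#' @export
#' @examples
#' rec <- data.table::data.table(chrom = "chr1", pos = c(10L, 20L),
#'   strand = "+", context = "CG", meth_reads = c(3L, 2L),
#'   total_reads = c(10L, 5L))
#' weighted_methylation(rec, context = "CG")  # 5/15
weighted_methylation <- function(records, context = NULL, chrom = NULL,
                                 start = NULL, end = NULL) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(context)) keep <- keep & records$context %in% context
  if (!is.null(chrom)) keep <- keep & records$chrom == chrom
  if (!is.null(start)) keep <- keep & records$pos >= start
  if (!is.null(end)) keep <- keep & records$pos <= end
  denom <- sum(records$total_reads[keep])
  if (denom == 0L) return(NA_real_)
  sum(records$meth_reads[keep]) / denom
}

# Overlap-join records onto arbitrary intervals; returns one row per
# (record, interval) hit with the interval's id columns attached.
overlap_records <- function(records, intervals) {
  rec <- data.table(chrom = records$chrom, start = records$pos,
                    end = records$pos, strand = records$strand,
                    context = records$context,
                    meth_reads = records$meth_reads,
                    total_reads = records$total_reads)
  iv <- copy(intervals)
  setkey(iv, chrom, start, end)
  hits <- foverlaps(rec, iv, type = "within", nomatch = NULL)
  hits
}

#' Per-gene methylation summaries
#'
#' For each gene and sequence context: the number of covered cytosines
#' (total reads >= 1), the number of cytosines with at least one
#' methylated read, pooled methylated and total read counts, and the
#' weighted level (`NA` when the gene has no covered site in that
#' context). A gene on a chromosome absent from the records yields a
#' zero-coverage summary, not an error.
#'
#' @param records per-cytosine record table.
#' @param genes gene model table (see [read_genes()]).
#' @return a `data.table` with one row per gene x context: `gene_id`,
#'   `context`, `covered_sites`, `meth_sites`, `meth_reads`,
#'   `total_reads`, `weighted_level`.
#' @export
summarize_genes <- function(records, genes) {
  validate_genes(genes)
  iv <- data.table(gene_id = genes$gene_id, chrom = genes$chrom,
                   start = genes$cds_start, end = genes$cds_end)
  hits <- overlap_records(records, iv)
  agg <- hits[, list(covered_sites = sum(total_reads >= 1L),
                     meth_sites = sum(meth_reads >= 1L),
                     meth_reads = sum(meth_reads),
                     total_reads = sum(total_reads)),
              by = c("gene_id", "context")]
  full <- CJ(gene_id = genes$gene_id, context = CONTEXTS, unique = TRUE)
  out <- agg[full, on = c("gene_id", "context")]
  for (col in c("covered_sites", "meth_sites", "meth_reads", "total_reads"))
    out[is.na(get(col)), (col) := 0L]
  out[, weighted_level := ifelse(total_reads > 0L,
                                 meth_reads / total_reads, NA_real_)]
  out[, gene_id := factor(gene_id, levels = genes$gene_id)]
  setorder(out, gene_id, context)
  out[, gene_id := as.character(gene_id)]
  out[]
}

# 60-row (or 20-row when flank_bp = 0) window interval table for one set of
# genes, oriented 5'->3': output index 1..20 upstream, 21..40 body, 41..60
# downstream. Body boundaries at round(i*L/20); flank windows are equal
# flank_bp/20 slices. Windows extending below position 1 are kept (they
# simply attract no records).
gene_windows <- function(genes, flank_bp = 1000L, n_windows = 20L) {
  stopifnot(flank_bp == 0L || flank_bp %% n_windows == 0L)
  i <- seq_len(n_windows)
  rows <- lapply(seq_len(nrow(genes)), function(g) {
    s <- genes$cds_start[g]; e <- genes$cds_end[g]
    L <- e - s + 1L
    plus <- genes$strand[g] == "+"
    b <- round(i * L / n_windows)
    b0 <- round((i - 1L) * L / n_windows)
    if (plus) {
      body <- data.table(start = s + b0, end = s + b - 1L)
    } else {
      body <- data.table(start = e - b + 1L, end = e - b0)
    }
    if (flank_bp == 0L) {
      body[, `:=`(region = "body", out_idx = i)]
      windows <- body
    } else {
      body[, `:=`(region = "body", out_idx = n_windows + i)]
      f <- flank_bp %/% n_windows
      if (plus) {
        up <- data.table(start = s - flank_bp + (i - 1L) * f,
                         end = s - flank_bp + i * f - 1L,
                         region = "up", out_idx = i)
        down <- data.table(start = e + 1L + (i - 1L) * f,
                           end = e + i * f,
                           region = "down", out_idx = 2L * n_windows + i)
      } else {
        up <- data.table(start = e + flank_bp - i * f + 1L,
                         end = e + flank_bp - (i - 1L) * f,
                         region = "up", out_idx = i)
        down <- data.table(start = s - (i - 1L) * f - f,
                           end = s - (i - 1L) * f - 1L,
                           region = "down", out_idx = 2L * n_windows + i)
      }
      windows <- rbindlist(list(up, body, down))
    }
    windows[, `:=`(gene_id = genes$gene_id[g], chrom = genes$chrom[g])]
    windows
  })
  rbindlist(rows)
}

#' Gene-body metaplot profile
#'
#' Divides each gene body (start to stop codon) into 20 windows and, when
#' `flank_bp > 0`, the regions `flank_bp` upstream and downstream into 20
#' windows each. The weighted methylation level is computed per window per
#' gene; the profile value of a window is the unweighted mean over genes
#' with a defined level there. Minus-strand genes are reoriented so all
#' profiles read 5' to 3'. Genes with a body shorter than `min_body_bp`
#' are excluded.
#'
#' @param records per-cytosine record table.
#' @param genes gene model table.
#' @param flank_bp flank width in bp (0 for body-only; 1000 and 4000 are
#'   the conventional choices); must be a multiple of 20.
#' @param contexts contexts to profile.
#' @param min_body_bp minimum body length for inclusion (default 20).
#' @return a `data.table` with columns `window_index` (1-60, 5'->3'),
#'   `region` (`up`/`body`/`down`), `position_index` (1-20 within the
#'   region), `context`, `mean_level`, `n_genes`; the flank width is
#'   attached as attribute `flank_bp`.
#' @export
metaplot <- function(records, genes, flank_bp = 1000L,
                     contexts = CONTEXTS, min_body_bp = 20L) {
  validate_genes(genes)
  genes <- genes[genes$cds_end - genes$cds_start + 1L >= min_body_bp, ]
  if (nrow(genes) == 0L)
    stop("no genes pass the minimum body-length filter")
  win <- gene_windows(genes, flank_bp = as.integer(flank_bp))
  hits <- overlap_records(records[records$context %in% contexts, ],
                          win[, c("gene_id", "chrom", "start", "end",
                                  "region", "out_idx")])
  per_gene <- hits[total_reads > 0L,
                   list(level = sum(meth_reads) / sum(total_reads)),
                   by = c("gene_id", "out_idx", "region", "context")]
  n_win <- if (flank_bp > 0L) 60L else 20L
  frame <- CJ(out_idx = seq_len(n_win), context = contexts, unique = TRUE)
  prof <- per_gene[, list(mean_level = mean(level), n_genes = .N),
                   by = c("out_idx", "context")]
  prof <- prof[frame, on = c("out_idx", "context")]
  prof[is.na(n_genes), n_genes := 0L]
  offset <- if (flank_bp > 0L) 20L else 0L
  prof[, region := ifelse(out_idx <= offset, "up",
                          ifelse(out_idx <= offset + 20L, "body", "down"))]
  if (flank_bp == 0L) prof[, region := "body"]
  prof[, position_index := out_idx - ifelse(region == "up", 0L,
                            ifelse(region == "body", offset, offset + 20L))]
  setnames(prof, "out_idx", "window_index")
  setorder(prof, context, window_index)
  data.table::setcolorder(prof, c("window_index", "region",
                                  "position_index", "context",
                                  "mean_level", "n_genes"))
  setattr(prof, "flank_bp", as.integer(flank_bp))
  prof[]
}

#' Resampled metaplot (bias control)
#'
#' Repeatedly draws `k` genes without replacement from a gene subset,
#' computes the metaplot of each draw, and averages across draws — the
#' control used to check that profile shape is not driven by how many
#' genes a class happens to contain (conventionally 100 draws of 100
#' gene-body-methylated genes).
#'
#' @param records per-cytosine record table.
#' @param genes the gene subset to resample from.
#' @param k genes per draw (must not exceed the subset size).
#' @param reps number of draws.
#' @param seed RNG seed; the same seed reproduces the profile exactly.
#' @inheritParams metaplot
#' @return as [metaplot()], plus `sd_level` (across-draw standard
#'   deviation) and `n_draws` (draws with a defined window mean).
#' @export
resampled_metaplot <- function(records, genes, k = 100L, reps = 100L,
                               seed = 1L, flank_bp = 1000L,
                               contexts = CONTEXTS, min_body_bp = 20L) {
  validate_genes(genes)
  if (k > nrow(genes))
    stop("k (", k, ") exceeds the gene subset size (", nrow(genes), ")")
  set.seed(seed)
  draws <- lapply(seq_len(reps), function(r) {
    idx <- sample.int(nrow(genes), k)
    p <- metaplot(records, genes[idx, ], flank_bp = flank_bp,
                  contexts = contexts, min_body_bp = min_body_bp)
    p[, draw := r]
    p
  })
  all <- rbindlist(draws)
  out <- all[, list(mean_level = mean(mean_level, na.rm = TRUE),
                    sd_level = stats::sd(mean_level, na.rm = TRUE),
                    n_draws = sum(!is.na(mean_level))),
             by = c("window_index", "region", "position_index", "context")]
  out[is.nan(mean_level), mean_level := NA_real_]
  setorder(out, context, window_index)
  setattr(out, "flank_bp", as.integer(flank_bp))
  out[]
}
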