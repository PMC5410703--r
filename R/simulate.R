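#' Default gene-body CG profile for simulated gbM genes
#'
#' A symmetric 20-window multiplier vector rising linearly from 0.3 at the
#' first and last body windows to 1.0 at windows 9-12, emulating the
#' depletion of CG methylation near the transcriptional start and
#' termination sites characteristic of gene-body-methylated genes.
#'
#' @return numeric vector of length 20 in [0.3, 1].
#' @export
default_body_profile <- function() {
  i <- 1:20
  0.3 + 0.7 * pmin((pmin(i, 21L - i) - 1L) / 8, 1)
}

#' Simulation configuration for synthetic methylomes
#'
#' Defines a mixture of gene classes laid on a single synthetic chromosome:
#' \describe{
#'   \item{unmethylated}{no true methylation; apparent methylation arises
#'     only from bisulfite non-conversion error.}
#'   \item{gbM}{CG methylation in the gene body shaped by a 20-window
#'     profile (depleted toward TSS/TTS), no non-CG methylation.}
#'   \item{TE_like}{methylated at a high level in all three contexts, the
#'     heterochromatic/transposon-like pattern.}
#' }
#' Cytosine sites are placed uniformly on both strands at the given
#' per-context densities; per-site read depth is Poisson; each read of an
#' unmethylated molecule is falsely read methylated with probability `ncr`
#' (the non-conversion rate), so the apparent per-read methylation
#' probability is `p + (1 - p) * ncr`.
#'
#' @param n_genes number of genes (>= 1).
#' @param gene_length_range min/max coding length in bp (uniform).
#' @param intergenic_bp gap between consecutive genes (and before the
#'   first/after the last), bp.
#' @param class_proportions named fractions for `unmethylated`, `gbM`,
#'   `TE_like`; must sum to 1.
#' @param p_meth 3x3 numeric matrix of true per-read methylation
#'   probabilities, rows = classes, columns = contexts (CG, CHG, CHH).
#' @param gbm_body_profile length-20 multiplier vector in [0,1] applied to
#'   the CG probability of gbM genes by body window.
#' @param site_density expected cytosines per bp per strand, named by
#'   context.
#' @param mean_coverage Poisson mean read depth per cytosine (>= 0).
#' @param ncr bisulfite non-conversion rate in [0,1].
#' @param seed integer RNG seed; identical seeds give identical methylomes.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_genes = 1000L,
    gene_length_range = c(300L, 3000L),
    intergenic_bp = 2000L,
    class_proportions = c(unmethylated = 0.7, gbM = 0.2, TE_like = 0.1),
    p_meth = rbind(unmethylated = c(CG = 0,   CHG = 0,   CHH = 0),
                   gbM          = c(CG = 0.8, CHG = 0,   CHH = 0),
                   TE_like      = c(CG = 0.8, CHG = 0.8, CHH = 0.8)),
    gbm_body_profile = default_body_profile(),
    site_density = c(CG = 0.02, CHG = 0.015, CHH = 0.05),
    mean_coverage = 20,
    ncr = 0.005,
    seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              intergenic_bp = as.integer(intergenic_bp),
              class_proportions = class_proportions,
              p_meth = p_meth,
              gbm_body_profile = gbm_body_profile,
              site_density = site_density,
              mean_coverage = mean_coverage,
              ncr = ncr,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  classes <- c("unmethylated", "gbM", "TE_like")
  if (cfg$n_genes < 1L) stop("configuration error: n_genes must be >= 1")
  if (length(cfg$gene_length_range) != 2L ||
      cfg$gene_length_range[1L] < 1L ||
      diff(cfg$gene_length_range) < 0L)
    stop("configuration error: invalid gene_length_range")
  if (cfg$intergenic_bp < 0L)
    stop("configuration error: intergenic_bp must be >= 0")
  if (!setequal(names(cfg$class_proportions), classes))
    stop("configuration error: class_proportions must be named ",
         paste(classes, collapse = ", "))
  cfg$class_proportions <- cfg$class_proportions[classes]
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9)
    stop("configuration error: class_proportions must sum to 1")
  if (any(cfg$class_proportions < 0))
    stop("configuration error: class_proportions must be non-negative")
  if (!all(rownames(cfg$p_meth) %in% classes) ||
      !setequal(colnames(cfg$p_meth), CONTEXTS))
    stop("configuration error: p_meth must have class rows and ",
         "CG/CHG/CHH columns")
  cfg$p_meth <- cfg$p_meth[classes, CONTEXTS]
  if (any(cfg$p_meth < 0 | cfg$p_meth > 1))
    stop("configuration error: p_meth entries must lie in [0,1]")
  if (length(cfg$gbm_body_profile) != 20L ||
      any(cfg$gbm_body_profile < 0 | cfg$gbm_body_profile > 1))
    stop("configuration error: gbm_body_profile must be 20 values in [0,1]")
  if (!setequal(names(cfg$site_density), CONTEXTS) ||
      any(cfg$site_density < 0))
    stop("configuration error: site_density must be non-negative and ",
         "named CG/CHG/CHH")
  cfg$site_density <- cfg$site_density[CONTEXTS]
  if (cfg$mean_coverage < 0)
    stop("configuration error: mean_coverage must be >= 0")
  if (cfg$ncr < 0 || cfg$ncr > 1)
    stop("configuration error: ncr must lie in [0,1]")
  cfg
}

# Body-window index (1..20) of a 1-based offset within a gene of length L;
# boundaries at round(i*L/20), window i = (round((i-1)L/20), round(iL/20)].
# Shared by the simulator and the metaplot so both agree bp-for-bp.
body_window_index <- function(offset, L, n_windows = 20L) {
  w <- ceiling(n_windows * offset / L)
  w <- pmin(pmax(w, 1L), n_windows)
  up <- offset > round(w * L / n_windows)
  w[up] <- w[up] + 1L
  down <- offset <= round((w - 1L) * L / n_windows)
  w[down] <- w[down] - 1L
  as.integer(w)
}

#' Simulate a ground-truthed synthetic methylome
#'
#' Lays `n_genes` non-overlapping genes on one synthetic chromosome with
#' alternating strands, draws each gene's class from the configured
#' mixture, places cytosines on both strands at the configured per-context
#' densities, and draws per-site read counts: total reads are
#' Poisson(`mean_coverage`) and methylated reads are Binomial with per-read
#' probability `p_true + (1 - p_true) * ncr`, where `p_true` is the class-
#' and context-specific probability (scaled by the body profile for gbM CG
#' sites; zero outside genes).
#'
#' @param config a [simulation_config()].
#' @return a list with elements `genes` (gene model table), `records`
#'   (per-cytosine table), `truth` (`gene_id`, `true_class`, `pCG`,
#'   `pCHG`, `pCHH`), and `genome_length`.
#' @export
simulate_methylome <- function(config) {
  config <- validate_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  classes <- c("unmethylated", "gbM", "TE_like")

  len <- config$gene_length_range[1L] +
    floor(stats::runif(n) * (diff(config$gene_length_range) + 1L))
  len <- as.integer(pmin(len, config$gene_length_range[2L]))
  gap <- config$intergenic_bp
  starts <- as.integer(gap + cumsum(c(0L, utils::head(len + gap, -1L))) + 1L)
  ends <- starts + len - 1L
  genome_length <- ends[n] + gap
  if (genome_length < 1L) stop("configuration error: zero-length genome")
  genes <- data.table(gene_id = sprintf("g%05d", seq_len(n)),
                      chrom = "chr1",
                      strand = rep(c("+", "-"), length.out = n),
                      cds_start = starts, cds_end = ends)

  cls <- sample(classes, n, replace = TRUE, prob = config$class_proportions)
  truth <- data.table(gene_id = genes$gene_id, true_class = cls,
                      pCG = config$p_meth[cls, "CG"],
                      pCHG = config$p_meth[cls, "CHG"],
                      pCHH = config$p_meth[cls, "CHH"])

  # site placement: per context and strand, Poisson site counts at the
  # configured density, positions uniform without replacement
  parts <- list()
  for (ctx in CONTEXTS) {
    for (strand in c("+", "-")) {
      m <- stats::rpois(1L, genome_length * config$site_density[[ctx]])
      m <- min(m, genome_length)
      if (m == 0L) next
      parts[[paste(ctx, strand)]] <- data.table(
        pos = sort(sample.int(genome_length, m)),
        strand = strand, context = ctx)
    }
  }
  rec <- rbindlist(parts)
  if (nrow(rec) == 0L) {
    rec <- data.table(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      meth_reads = integer(), total_reads = integer())
    return(list(genes = genes, records = rec, truth = truth,
                genome_length = genome_length))
  }
  rec <- unique(rec, by = c("pos", "strand"))

  gidx <- findInterval(rec$pos, starts)
  in_gene <- gidx >= 1L & rec$pos <= ends[pmax(gidx, 1L)]
  gidx[!in_gene] <- NA_integer_

  p_true <- numeric(nrow(rec))
  hit <- which(in_gene)
  p_true[hit] <- config$p_meth[cbind(cls[gidx[hit]], rec$context[hit])]
  gbm_cg <- hit[cls[gidx[hit]] == "gbM" & rec$context[hit] == "CG"]
  if (length(gbm_cg)) {
    g <- gidx[gbm_cg]
    offset <- ifelse(genes$strand[g] == "+",
                     rec$pos[gbm_cg] - starts[g] + 1L,
                     ends[g] - rec$pos[gbm_cg] + 1L)
    w <- body_window_index(offset, len[g])
    p_true[gbm_cg] <- p_true[gbm_cg] * config$gbm_body_profile[w]
  }

  total <- stats::rpois(nrow(rec), config$mean_coverage)
  p_app <- p_true + (1 - p_true) * config$ncr
  meth <- stats::rbinom(nrow(rec), total, p_app)
  rec[, `:=`(chrom = "chr1", meth_reads = as.integer(meth),
             total_reads = as.integer(total))]
  setorder(rec, pos, strand)
  data.table::setcolorder(rec, c("chrom", "pos", "strand", "context",
                                 "meth_reads", "total_reads"))
  list(genes = genes, records = rec[], truth = truth,
       genome_length = genome_length)
}

#' Write a simulated methylome to disk as plain-text fixtures
#'
#' Emits the allc-style call table, a BED6 (and optional GFF3) gene
#' annotation, and the ground-truth table; all round-trip losslessly
#' through [read_allc()] and [read_genes()].
#'
#' @param sim result of [simulate_methylome()].
#' @param dir output directory (created if needed).
#' @param gff3 also write a GFF3 annotation.
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(sim, dir, gff3 = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(allc = file.path(dir, "allc.tsv"),
             bed = file.path(dir, "genes.bed"),
             truth = file.path(dir, "truth.tsv"))
  write_allc(sim$records, paths[["allc"]])
  write_genes_bed(sim$genes, paths[["bed"]])
  fwrite(sim$truth, paths[["truth"]], sep = "\t")
  if (gff3) {
    paths[["gff3"]] <- file.path(dir, "genes.gff3")
    write_genes_gff3(sim$genes, paths[["gff3"]])
  }
  invisible(paths)
}
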