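test_that("weighted methylation is the pooled read ratio", {
  rec <- tiny_records()
  # CG sites at pos 10 and 20: (3+2)/(10+5)
  expect_equal(weighted_methylation(rec, context = "CG",
                                    chrom = "chr1", start = 1, end = 100),
               5 / 15)
  expect_equal(weighted_methylation(rec, context = "CHH"), 4 / 10)
  # all-unmethylated region is 0, not NA
  expect_equal(weighted_methylation(rec, context = "CHH",
                                    start = 40, end = 50), 0)
  # uncovered region is NA, never 0
  expect_true(is.na(weighted_methylation(rec, context = "CG",
                                         start = 200, end = 300)))
})

test_that("per-gene summaries match direct evaluation and conserve counts", {
  rec <- tiny_records()
  genes <- data.table::data.table(
    gene_id = c("g1", "g2"), chrom = "chr1", strand = c("+", "-"),
    cds_start = c(5L, 1000L), cds_end = c(25L, 2000L))
  s <- summarize_genes(rec, genes)
  g1cg <- s[s$gene_id == "g1" & s$context == "CG", ]
  expect_equal(g1cg$weighted_level, 5 / 15)
  expect_equal(g1cg$covered_sites, 2L)
  g2 <- s[s$gene_id == "g2", ]
  expect_equal(g2$context, c("CG", "CHG", "CHH"))
  expect_equal(g2$total_reads, c(5L, 0L, 0L))
  # per gene, totals over contexts equal the in-interval record totals
  for (g in seq_len(nrow(genes))) {
    inside <- rec$pos >= genes$cds_start[g] & rec$pos <= genes$cds_end[g]
    expect_equal(sum(s$total_reads[s$gene_id == genes$gene_id[g]]),
                 sum(rec$total_reads[inside]))
  }
  # gene on an absent chromosome: zero coverage, not an error
  far <- data.table::data.table(gene_id = "gx", chrom = "chr9",
                                strand = "+", cds_start = 1L,
                                cds_end = 100L)
  sx <- summarize_genes(rec, far)
  expect_true(all(sx$covered_sites == 0L))
  expect_true(all(is.na(sx$weighted_level)))
})

test_that("summaries equal the brute-force interval-scan oracle", {
  sim <- simulate_methylome(simulation_config(
    n_genes = 25L, gene_length_range = c(300L, 900L),
    intergenic_bp = 400L, seed = 5L))
  s <- as.data.frame(summarize_genes(sim$records, sim$genes))
  o <- brute_summarize(sim$records, sim$genes)
  o <- o[order(match(o$gene_id, sim$genes$gene_id), o$context), ]
  rownames(o) <- rownames(s) <- NULL
  expect_equal(s, o)
})

test_that("a 2000-bp body splits into twenty exact 100-bp windows", {
  genes <- data.table::data.table(gene_id = "g1", chrom = "chr1",
                                  strand = "+", cds_start = 1001L,
                                  cds_end = 3000L)
  win <- gbmtools:::gene_windows(genes, flank_bp = 1000L)
  body <- win[win$region == "body", ]
  expect_equal(body$start, 1001L + 100L * (0:19))
  expect_equal(body$end, 1000L + 100L * (1:20))
  up <- win[win$region == "up", ]
  expect_equal(up$start[1], 1L)
  expect_equal(up$end[20], 1000L)
  expect_equal(unique(up$end - up$start + 1L), 50L)
})

test_that("body windows partition each gene's cytosines exactly", {
  sim <- simulate_methylome(simulation_config(
    n_genes = 40L, gene_length_range = c(21L, 2500L),
    intergenic_bp = 300L, seed = 8L))
  win <- gbmtools:::gene_windows(sim$genes, flank_bp = 0L)
  rec <- sim$records
  for (g in sample(seq_len(nrow(sim$genes)), 12L)) {
    gw <- win[win$gene_id == sim$genes$gene_id[g], ]
    inside <- rec[rec$pos >= sim$genes$cds_start[g] &
                    rec$pos <= sim$genes$cds_end[g], ]
    assigned <- integer(nrow(inside))
    for (w in seq_len(nrow(gw)))
      assigned <- assigned +
        (inside$pos >= gw$start[w] & inside$pos <= gw$end[w])
    expect_true(all(assigned == 1L))  # no loss, no duplication
    # windows tile the body contiguously
    ord <- order(gw$start)
    expect_equal(gw$start[ord][1], sim$genes$cds_start[g])
    expect_equal(gw$end[ord][20], sim$genes$cds_end[g])
    expect_true(all(gw$start[ord][-1] == gw$end[ord][-20] + 1L))
  }
})

test_that("region level equals the read-weighted mean of window levels", {
  sim <- simulate_methylome(simulation_config(
    n_genes = 10L, gene_length_range = c(500L, 1500L),
    intergenic_bp = 300L, seed = 13L))
  g <- sim$genes[3L, ]
  win <- gbmtools:::gene_windows(g, flank_bp = 0L)
  rec <- sim$records[sim$records$context == "CG", ]
  m <- t <- numeric(20L)
  for (w in seq_len(20L)) {
    inw <- rec$pos >= win$start[w] & rec$pos <= win$end[w]
    m[w] <- sum(rec$meth_reads[inw]); t[w] <- sum(rec$total_reads[inw])
  }
  expect_equal(sum(m) / sum(t),
               weighted_methylation(rec, context = "CG", chrom = g$chrom,
                                    start = g$cds_start, end = g$cds_end))
})

test_that("a minus-strand gene mirrors its plus-strand equivalent", {
  # same per-window counts laid left-to-right vs right-to-left
  mk <- function(strand) {
    L <- 2000L; s <- 3001L
    offs <- seq(50L, 1950L, by = 100L)  # one site per 100-bp window
    pos <- if (strand == "+") s + offs - 1L else (s + L - 1L) - offs + 1L
    data.table::data.table(
      chrom = "chr1", pos = pos, strand = "+", context = "CG",
      meth_reads = as.integer(seq(0L, 19L)),
      total_reads = 20L)
  }
  gp <- data.table::data.table(gene_id = "g", chrom = "chr1",
                               strand = "+", cds_start = 3001L,
                               cds_end = 5000L)
  gm <- data.table::copy(gp); gm$strand <- "-"
  pp <- metaplot(mk("+"), gp, flank_bp = 0L, contexts = "CG")
  pm <- metaplot(mk("-"), gm, flank_bp = 0L, contexts = "CG")
  expect_equal(pp$mean_level, pm$mean_level)
  expect_equal(pp$mean_level, (0:19) / 20)
})

test_that("uniform methylation yields a flat profile at p across regions", {
  L <- 2000L
  pos <- seq(1L, 10000L, by = 10L)
  rec <- data.table::data.table(chrom = "chr1", pos = pos, strand = "+",
                                context = "CG", meth_reads = 3L,
                                total_reads = 10L)
  genes <- data.table::data.table(gene_id = "g", chrom = "chr1",
                                  strand = "+", cds_start = 4001L,
                                  cds_end = 4000L + L)
  prof <- metaplot(rec, genes, flank_bp = 1000L, contexts = "CG")
  expect_equal(nrow(prof), 60L)
  expect_true(all(prof$mean_level == 0.3))
  expect_true(all(prof$n_genes == 1L))
})

test_that("metaplot filters degenerate genes and errors when none remain", {
  rec <- tiny_records()
  short <- data.table::data.table(gene_id = "tiny", chrom = "chr1",
                                  strand = "+", cds_start = 10L,
                                  cds_end = 20L)
  expect_error(metaplot(rec, short), "body-length")
})

test_that("degenerate resampling equals the plain metaplot", {
  sim <- simulate_methylome(simulation_config(
    n_genes = 20L, gene_length_range = c(500L, 1500L),
    intergenic_bp = 500L, seed = 17L))
  full <- metaplot(sim$records, sim$genes, flank_bp = 1000L)
  res <- resampled_metaplot(sim$records, sim$genes, k = nrow(sim$genes),
                            reps = 1L, seed = 1L, flank_bp = 1000L)
  merged <- merge(full, res, by = c("window_index", "context"))
  expect_equal(merged$mean_level.x, merged$mean_level.y)
})

test_that("resampled profiles are seed-reproducible and k is validated", {
  sim <- simulate_methylome(simulation_config(
    n_genes = 20L, gene_length_range = c(500L, 1500L),
    intergenic_bp = 500L, seed = 17L))
  a <- resampled_metaplot(sim$records, sim$genes, k = 10L, reps = 5L,
                          seed = 3L)
  b <- resampled_metaplot(sim$records, sim$genes, k = 10L, reps = 5L,
                          seed = 3L)
  expect_identical(a, b)
  expect_error(resampled_metaplot(sim$records, sim$genes, k = 21L,
                                  reps = 2L, seed = 1L), "exceeds")
})
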