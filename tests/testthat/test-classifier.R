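test_that("binomial enrichment p-values match direct enumeration", {
  expect_equal(binomial_enrichment_p(0, 10, 0.1), 1)
  expect_equal(binomial_enrichment_p(1, 1, 0.25), 0.25)
  expect_equal(binomial_enrichment_p(8, 20, 0.1),
               brute_binom_tail(8, 20, 0.1), tolerance = 1e-12)
  expect_true(is.na(binomial_enrichment_p(0, 0, 0.1)))
  expect_error(binomial_enrichment_p(5, 3, 0.1))
  expect_error(binomial_enrichment_p(1, 2, 0))
})

test_that("BH adjustment matches the hand-derived step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(numeric()), numeric())
  # NA entries pass through and do not count toward m
  p <- c(0.01, NA, 0.04, 0.03, NA)
  q <- bh_adjust(p)
  expect_true(all(is.na(q[c(2, 5)])))
  expect_equal(q[!is.na(q)], bh_adjust(p[!is.na(p)]))
})

test_that("BH equals the min-over-suffix brute force on random vectors", {
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(1:80, 1))^sample(1:3, 1)
    expect_identical(bh_adjust(p), brute_bh(p))
  }
})

test_that("q-values are invariant to input ordering", {
  set.seed(7)
  p <- runif(200)
  q <- bh_adjust(p)
  perm <- sample(200)
  expect_equal(bh_adjust(p[perm]), q[perm])
})

test_that("background pooling, clamping and zero-coverage errors", {
  rec <- data.table::data.table(
    chrom = "chr1", pos = c(10L, 20L, 110L, 30L, 40L),
    strand = "+", context = c("CG", "CG", "CG", "CHG", "CHH"),
    meth_reads = c(2L, 1L, 2L, 0L, 4L),
    total_reads = c(5L, 5L, 5L, 7L, 4L))
  genes <- data.table::data.table(
    gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
    cds_start = c(1L, 100L), cds_end = c(50L, 150L))
  bg <- estimate_background(rec, genes)
  expect_equal(bg$p0[bg$context == "CG"], 5 / 15)
  expect_equal(bg$p0[bg$context == "CHG"], 1e-9)       # clamped up from 0
  expect_equal(bg$p0[bg$context == "CHH"], 1 - 1e-9)   # clamped down from 1
  # context with no covered site: explicit error asking for an override
  expect_error(
    estimate_background(rec[rec$context != "CHH", ], genes),
    "background")
})

test_that("a strongly CG-enriched, non-CG-quiet gene is labelled gbM", {
  # q-values reduce to the raw binomial tails when one gene is tested
  summaries <- data.table::data.table(
    gene_id = "g1",
    context = c("CG", "CHG", "CHH"),
    covered_sites = c(15L, 8L, 9L),
    meth_sites = c(14L, 1L, 1L),
    meth_reads = c(25L, 1L, 1L),
    total_reads = c(30L, 20L, 25L),
    weighted_level = c(25 / 30, 1 / 20, 1 / 25))
  bg <- c(CG = 0.10, CHG = 0.05, CHH = 0.05)
  res <- classify_genes(summaries, bg)
  expect_equal(as.character(res$label), "gbM")
  expect_equal(res$q_CG, brute_binom_tail(25, 30, 0.10), tolerance = 1e-12)
  expect_lt(res$q_CG, 0.05)
  expect_gt(res$q_CHG, 0.05)
  expect_gt(res$q_CHH, 0.05)
})

test_that("fewer than 10 covered CG sites means unclassified regardless", {
  summaries <- data.table::data.table(
    gene_id = "g1",
    context = c("CG", "CHG", "CHH"),
    covered_sites = c(5L, 8L, 9L),
    meth_sites = c(5L, 0L, 0L),
    meth_reads = c(90L, 0L, 0L),
    total_reads = c(100L, 20L, 25L),
    weighted_level = c(0.9, 0, 0))
  res <- classify_genes(summaries, c(CG = 0.1, CHG = 0.05, CHH = 0.05))
  expect_equal(as.character(res$label), "unclassified")
})

test_that("missing non-CG coverage blocks gbM only under strict_noncg", {
  summaries <- data.table::data.table(
    gene_id = "g1",
    context = c("CG", "CHG", "CHH"),
    covered_sites = c(20L, 0L, 0L),
    meth_sites = c(20L, 0L, 0L),
    meth_reads = c(50L, 0L, 0L),
    total_reads = c(60L, 0L, 0L),
    weighted_level = c(50 / 60, NA, NA))
  bg <- c(CG = 0.1, CHG = 0.05, CHH = 0.05)
  lax <- classify_genes(summaries, bg)
  expect_equal(as.character(lax$label), "gbM")
  strict <- classify_genes(summaries, bg, strict_noncg = TRUE)
  expect_false(as.character(strict$label) == "gbM")
})

test_that("labels are exhaustive and mutually exclusive by construction", {
  sim <- simulate_methylome(simulation_config(n_genes = 120L, seed = 19L))
  s <- summarize_genes(sim$records, sim$genes)
  bg <- estimate_background(sim$records, sim$genes)
  res <- classify_genes(s, bg)
  expect_equal(nrow(res), 120L)
  expect_false(any(is.na(res$label)))
  expect_true(all(res$q_CG >= res$p_CG, na.rm = TRUE))
})

test_that("raising alpha never shrinks the gbM set (quiet non-CG)", {
  sim <- simulate_methylome(simulation_config(
    n_genes = 150L,
    class_proportions = c(unmethylated = 0.6, gbM = 0.4, TE_like = 0),
    seed = 23L))
  s <- summarize_genes(sim$records, sim$genes)
  bg <- estimate_background(sim$records, sim$genes)
  gbm_at <- function(a)
    classify_genes(s, bg, alpha = a)[label == "gbM", gene_id]
  lo <- gbm_at(0.01)
  hi <- gbm_at(0.10)
  expect_true(all(lo %in% hi))
})

test_that("classification equals a brute-force rerun of the rule chain", {
  sim <- simulate_methylome(simulation_config(n_genes = 200L, seed = 29L))
  s <- summarize_genes(sim$records, sim$genes)
  bg <- estimate_background(sim$records, sim$genes)
  res <- classify_genes(s, bg)

  p0 <- setNames(bg$p0, bg$context)
  sd <- as.data.frame(s)
  sd$p <- mapply(brute_binom_tail, sd$meth_reads, sd$total_reads,
                 p0[sd$context])
  sd$q <- NA_real_
  for (ctx in c("CG", "CHG", "CHH")) {
    sel <- sd$context == ctx
    sd$q[sel] <- brute_bh(sd$p[sel])
  }
  wide <- reshape(sd[, c("gene_id", "context", "covered_sites", "q")],
                  idvar = "gene_id", timevar = "context",
                  direction = "wide")
  e <- function(q) !is.na(q) & q < 0.05
  n_enr <- e(wide$q.CG) + e(wide$q.CHG) + e(wide$q.CHH)
  lab <- ifelse(n_enr == 0, "unmethylated",
         ifelse(n_enr >= 2, "multi_context",
         ifelse(e(wide$q.CG), "gbM",
         ifelse(e(wide$q.CHG), "mCHG_enriched", "mCHH_enriched"))))
  lab[wide$covered_sites.CG < 10] <- "unclassified"
  m <- match(res$gene_id, wide$gene_id)
  expect_equal(as.character(res$label), lab[m])
  expect_lt(max(abs(res$q_CG - wide$q.CG[m]), na.rm = TRUE), 1e-12)
})
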