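# Independent brute-force oracles. These deliberately share no code with
# the package: each re-derives its quantity by direct enumeration or an
# O(n*m) scan so the fast implementations can be checked against them.

# upper-tail binomial probability by explicit enumeration of outcomes
brute_binom_tail <- function(k, n, p0) {
  if (n == 0) return(NA_real_)
  i <- k:n
  # term-by-term enumeration; log space keeps large n finite
  sum(exp(lchoose(n, i) + i * log(p0) + (n - i) * log(1 - p0)))
}

# BH step-up as a literal min-over-suffix on the sorted p-values
brute_bh <- function(p) {
  ok <- which(!is.na(p))
  q <- rep(NA_real_, length(p))
  if (!length(ok)) return(q)
  ps <- p[ok]
  m <- length(ps)
  o <- order(ps)
  raw <- (m / seq_len(m)) * ps[o]
  qs <- numeric(m)
  for (i in seq_len(m)) qs[i] <- min(1, min(raw[i:m]))
  q[ok[o]] <- qs
  q
}

# six-frame longest-ORF scan: try every (strand, frame, ATG, next stop)
brute_longest_orf <- function(seq) {
  seq <- toupper(seq)
  rc_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  revcomp <- function(s)
    paste(rev(rc_map[strsplit(s, "")[[1]]]), collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  n <- nchar(seq)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (frame in 0:2) {
      if (frame + 6 > n) next
      for (st in seq(frame + 1, n - 5, by = 3)) {
        if (substr(s, st, st + 2) != "ATG") next
        pos <- st + 3
        while (pos + 2 <= n) {
          cod <- substr(s, pos, pos + 2)
          if (cod %in% stops) {
            len <- pos + 2 - st + 1
            if (is.null(best) || len > best$length_nt) {
              a <- st; b <- pos + 2
              if (strand == "-") { a2 <- n - b + 1; b <- n - a + 1; a <- a2 }
              best <- list(strand = strand, frame = frame,
                           start = a, end = b, length_nt = len)
            }
            break
          }
          pos <- pos + 3
        }
      }
    }
  }
  best
}

# per-gene, per-context summary by a plain double loop over records
brute_summarize <- function(records, genes) {
  rows <- list()
  for (g in seq_len(nrow(genes))) {
    for (ctx in c("CG", "CHG", "CHH")) {
      inside <- records$chrom == genes$chrom[g] &
        records$pos >= genes$cds_start[g] &
        records$pos <= genes$cds_end[g] &
        records$context == ctx
      m <- sum(records$meth_reads[inside])
      t <- sum(records$total_reads[inside])
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = genes$gene_id[g], context = ctx,
        covered_sites = sum(records$total_reads[inside] >= 1),
        meth_sites = sum(records$meth_reads[inside] >= 1),
        meth_reads = m, total_reads = t,
        weighted_level = if (t > 0) m / t else NA_real_)
    }
  }
  do.call(rbind, rows)
}

# closed-form OLS slope/intercept from the normal equations
brute_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  list(slope = slope, intercept = intercept,
       sigma = sqrt(sum(resid^2) / (length(x) - 2)))
}

# inverse-prediction interval by scanning x in [0,1] for prediction-band
# membership of the observed y
brute_inverse_interval <- function(model, y0, step = 1e-4) {
  xs <- seq(0, 1, by = step)
  tval <- qt(0.975, df = model$df)
  half <- tval * model$sigma *
    sqrt(1 + 1 / model$n_points + (xs - model$x_mean)^2 / model$sxx)
  pred <- model$intercept + model$slope * xs
  inside <- abs(y0 - pred) <= half
  if (!any(inside)) return(NULL)
  c(min(xs[inside]), max(xs[inside]))
}

rc_string <- function(s) {
  rc_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(rc_map[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

random_dna <- function(n, with_n = FALSE) {
  alph <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alph, n, replace = TRUE), collapse = "")
}

# a small deterministic record table used across io/metrics tests
tiny_records <- function() {
  data.table::data.table(
    chrom = "chr1",
    pos = c(10L, 20L, 30L, 45L, 60L, 1500L),
    strand = c("+", "-", "+", "+", "-", "+"),
    context = c("CG", "CG", "CHG", "CHH", "CHH", "CG"),
    meth_reads = c(3L, 2L, 1L, 0L, 4L, 5L),
    total_reads = c(10L, 5L, 4L, 6L, 4L, 5L))
}
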