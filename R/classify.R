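#' Context-specific background methylation from coding sequence
#'
#' Pools all cytosines falling inside any gene interval and computes the
#' weighted methylation level per context: the background proportion the
#' per-gene binomial enrichment test is run against. In `"sites"` mode the
#' proportion is methylated sites (>= 1 methylated read) over covered
#' sites instead of read counts. Proportions are clamped to
#' `[1e-9, 1 - 1e-9]` so the binomial test is always defined.
#'
#' @param records per-cytosine record table.
#' @param genes gene model table.
#' @param unit `"reads"` (pooled read counts, the default) or `"sites"`.
#' @return a `data.table` of class `background_levels` with columns
#'   `context`, `p0`, `numerator`, `denominator`.
#' @export
estimate_background <- function(records, genes, unit = c("reads", "sites")) {
  unit <- match.arg(unit)
  validate_genes(genes)
  iv <- data.table(gene_id = genes$gene_id, chrom = genes$chrom,
                   start = genes$cds_start, end = genes$cds_end)
  hits <- overlap_records(records, iv)
  # a cytosine in several (overlapping) genes counts once
  hits <- unique(hits, by = c("chrom", "i.start", "strand", "context"))
  eps <- 1e-9
  out <- rbindlist(lapply(CONTEXTS, function(ctx) {
    h <- hits[context == ctx]
    if (unit == "reads") {
      num <- sum(h$meth_reads); den <- sum(h$total_reads)
    } else {
      num <- sum(h$meth_reads >= 1L); den <- sum(h$total_reads >= 1L)
    }
    if (den == 0L)
      stop("no covered ", ctx, " site in any coding interval; supply an ",
           "explicit background for this context")
    data.table(context = ctx, p0 = min(max(num / den, eps), 1 - eps),
               numerator = num, denominator = den)
  }))
  class(out) <- c("background_levels", class(out))
  out
}

#' One-sided binomial enrichment p-value
#'
#' Exact upper-tail probability P(X >= k) for X ~ Binomial(n, p0): the
#' evidence that a gene's methylation exceeds the background proportion.
#' Vectorised over `k`, `n`, `p0`. `n = 0` yields `NA` (no test).
#'
#' @param k methylated count(s).
#' @param n total count(s).
#' @param p0 background proportion(s) in (0,1).
#' @return p-value(s) in (0, 1], `NA` where `n = 0`.
#' @export
#' @examples
#' binomial_enrichment_p(8, 20, 0.1)
binomial_enrichment_p <- function(k, n, p0) {
  stopifnot(all(k >= 0 & k <= n, na.rm = TRUE),
            all(p0 > 0 & p0 < 1, na.rm = TRUE))
  p <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  p[n == 0] <- NA_real_
  p
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; `NA` entries (untestable
#' genes) are passed through and do not count toward the number of tests.
#'
#' @param p numeric vector of p-values in (0,1], possibly with `NA`s.
#' @return q-values in the input order, monotone in `p`.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

resolve_background <- function(background) {
  if (inherits(background, "background_levels")) {
    p0 <- stats::setNames(background$p0, background$context)
  } else if (is.numeric(background) && !is.null(names(background))) {
    p0 <- background
  } else stop("background must be a background_levels object or a named ",
              "numeric vector c(CG=, CHG=, CHH=)")
  if (!all(CONTEXTS %in% names(p0)))
    stop("background must provide CG, CHG and CHH")
  eps <- 1e-9
  pmin(pmax(p0[CONTEXTS], eps), 1 - eps)
}

#' Classify genes by context-specific methylation enrichment
#'
#' Runs the one-sided binomial test of each gene's pooled counts against
#' the context background, adjusts per context by Benjamini-Hochberg, and
#' labels each gene:
#' \describe{
#'   \item{unclassified}{fewer than `min_cg_sites` covered CG sites — the
#'     test is not attempted.}
#'   \item{gbM}{CG q-value < `alpha` and CHG and CHH q-values > `alpha`
#'     (the mCG-enriched / gene-body-methylated class).}
#'   \item{mCHG_enriched / mCHH_enriched}{only that context enriched.}
#'   \item{multi_context}{two or more contexts enriched (TE-like
#'     heterochromatic methylation).}
#'   \item{unmethylated}{no context enriched.}
#' }
#' A non-CG context with no coverage has no q-value; by default it is
#' treated as not enriched (so sparsely covered genes can still be gbM),
#' while `strict_noncg = TRUE` makes missing non-CG evidence block the
#' gbM label.
#'
#' @param summaries per-gene summaries from [summarize_genes()].
#' @param background a [estimate_background()] result or named numeric
#'   vector `c(CG=, CHG=, CHH=)`.
#' @param alpha q-value significance threshold (default 0.05).
#' @param min_cg_sites minimum covered CG sites to test a gene
#'   (default 10).
#' @param unit `"reads"`: test pooled methylated vs total reads;
#'   `"sites"`: test methylated vs covered sites.
#' @param strict_noncg treat missing non-CG q-values as enriched.
#' @param fdr_scope `"context"`: BH per context across genes (default);
#'   `"global"`: one BH across all gene x context tests.
#' @return a wide `data.table`, one row per gene: per-context
#'   `covered_sites_*`, `meth_reads_*`, `total_reads_*`, `p_*`, `q_*`,
#'   and `label`.
#' @export
classify_genes <- function(summaries, background, alpha = 0.05,
                           min_cg_sites = 10L,
                           unit = c("reads", "sites"),
                           strict_noncg = FALSE,
                           fdr_scope = c("context", "global")) {
  unit <- match.arg(unit)
  fdr_scope <- match.arg(fdr_scope)
  if (nrow(summaries) == 0L) stop("empty gene summaries")
  p0 <- resolve_background(background)
  s <- copy(as.data.table(summaries))
  if (unit == "reads") {
    s[, `:=`(k = meth_reads, n = total_reads)]
  } else {
    s[, `:=`(k = meth_sites, n = covered_sites)]
  }
  s[, p_value := binomial_enrichment_p(k, n, p0[context])]
  if (fdr_scope == "context") {
    s[, q_value := bh_adjust(p_value), by = "context"]
  } else {
    s[, q_value := bh_adjust(p_value)]
  }
  wide <- data.table::dcast(
    s, gene_id ~ context,
    value.var = c("covered_sites", "meth_reads", "total_reads",
                  "p_value", "q_value"))
  setnames(wide, sub("^p_value_", "p_", names(wide)))
  setnames(wide, sub("^q_value_", "q_", names(wide)))
  enr <- function(q) !is.na(q) & q < alpha
  miss_block <- function(q) if (strict_noncg) is.na(q) | q < alpha
                            else enr(q)
  eCG <- enr(wide$q_CG)
  eCHG <- miss_block(wide$q_CHG)
  eCHH <- miss_block(wide$q_CHH)
  n_enr <- eCG + eCHG + eCHH
  label <- ifelse(n_enr == 0L, "unmethylated",
           ifelse(n_enr >= 2L, "multi_context",
           ifelse(eCG, "gbM",
           ifelse(eCHG, "mCHG_enriched", "mCHH_enriched"))))
  label[wide$covered_sites_CG < min_cg_sites] <- "unclassified"
  wide[, label := factor(label, levels = c("gbM", "mCHG_enriched",
                                           "mCHH_enriched", "multi_context",
                                           "unmethylated", "unclassified"))]
  # restore the summaries' gene order
  wide[match(unique(summaries$gene_id), gene_id), ]
}
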