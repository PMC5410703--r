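---
title: "Detecting gene-body methylation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene-body methylation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmtools)
```

## The problem

Whole-genome bisulfite sequencing reports, per cytosine, how many aligned
reads were methylated and how many were not. In plants, methylation occurs
in three sequence contexts (CG, CHG, CHH), and one prominent gene class —
gene-body methylated (gbM) genes — is defined statistically: CG methylation
enriched over the genomic background within the coding region, depletion of
that enrichment toward the transcription start and termination sites, and
no CHG/CHH enrichment. `gbmtools` implements the measurement
(coverage-weighted levels), the visualisation (windowed metaplots), the
test (binomial enrichment with FDR control), and the low-coverage
machinery (read thinning and a deep-vs-shallow calibration line) needed to
call and interpret this class.

## Weighted methylation

For a set of cytosine records in one context, the level is

$$m = \frac{\sum_i \text{meth}_i}{\sum_i \text{total}_i},$$

the ratio of pooled read counts. Pooling weights each site by its
coverage, which keeps the estimator well behaved when mean depth is near
1×: a per-site average of noisy 0/1 calls would be far more variable and
biased by which sites happen to be covered. A region with zero covering
reads has an *undefined* level, reported as `NA` and never as 0 — windows
and genes with no data are skipped, not zero-filled, in all aggregation.

## Metaplots

Each gene body (start to stop codon) is cut into 20 windows with
boundaries at `round(i·L/20)`; flanks of 1000 or 4000 bp are cut into 20
equal windows. Both flank widths are exposed because either convention is
common; 1000 bp is the default here. Per gene and window the weighted
level is computed, then averaged across genes *unweighted* (each gene
counts once, genes without data in a window are skipped). Minus-strand
genes are mirrored first so profiles read 5′→3′.

Design points that were genuinely open:

* **Window boundaries.** `round(i·L/20)` tiles any body length exactly
  (every base in exactly one window — a property test asserts the
  partition). Genes shorter than 20 bp are excluded from metaplots (they
  cannot fill 20 windows) but still receive per-gene summaries.
* **Flank masking.** Flank windows overlapping a neighbouring gene are
  *not* masked. This matches the plain reading of the windowing procedure
  but means flank signal partly reflects neighbours when genes are dense —
  a documented caveat, visible in the simulated intergenic spacing too.
* **Resampling control.** `resampled_metaplot()` averages the profiles of
  repeated draws of *k* genes (without replacement within a draw;
  conventionally 100 draws of 100 genes). Equal-size draws make profiles
  comparable across gene classes of very different sizes; the across-draw
  standard deviation gives a Monte-Carlo error for the mean profile.

## The gbM classification

The background proportion per context, \(p_0\), is the weighted level over
*all* coding sequence (clamped to \([10^{-9}, 1-10^{-9}]\)). Each gene's
pooled counts \((k, n)\) are tested one-sided against it,

$$p = P(X \ge k), \quad X \sim \mathrm{Binomial}(n, p_0),$$

and Benjamini–Hochberg is applied per context across genes. A gene is
**gbM** when it has ≥ 10 covered CG sites, q(CG) < 0.05, and q(CHG) and
q(CHH) > 0.05. The remaining labels (`mCHG_enriched`, `mCHH_enriched`,
`multi_context`, `unmethylated`, `unclassified`) are reporting
conveniences derived from the same q-values; only the gbM rule carries the
scientific contract.

Open choices, and how they were resolved:

* **Reads vs sites as the binomial unit.** The default tests pooled *read*
  counts: the class definition counts reads mapping to CG sites, and a
  read-level test stays defined at ~1× where most sites have 0–2 reads. A
  site-level mode (`unit = "sites"`: methylated sites over covered sites)
  ships for cross-checking; with deep coverage the two agree closely on
  rankings, but read counts are not independent given per-site methylation
  states, so read-mode p-values are anticonservative for heterogeneous
  genes — acceptable here because the classification margins are wide.
* **FDR scope.** BH is applied per context (m = genes testable in that
  context), exposed as `fdr_scope = "global"` for a joint adjustment.
* **Missing non-CG evidence.** At ~1× many genes have no covered CHG/CHH
  site. Requiring non-CG q-values would empty the gbM class at low
  coverage, so an undefined non-CG q is treated as "not enriched" by
  default; `strict_noncg = TRUE` flips this.
* **Circularity.** The background is estimated from the same records being
  tested, which slightly inflates \(p_0\) when many genes are methylated.
  This is inherent to the design being implemented and is documented, not
  "corrected".

## Coverage: thinning and calibration

`downsample_records()` keeps each read independently with probability
`target / current mean coverage` (methylated and unmethylated reads thinned
identically via two binomial draws). Per-read Bernoulli thinning is
unbiased for weighted methylation and is the natural model of "randomly
sampled reads" at corpus scale; exact without-replacement subsampling per
site would differ only in second-order variance.

For species sequenced only at ~1×, a calibration line is fitted by OLS of
the shallow level (y) on the deep level (x) across reference species, and
a deep level is *inverse-predicted* from an observed shallow level:
\(\hat x = (y - a)/b\). The 95% interval is the set of x whose prediction
band for a new y covers the observation (Fieller-type inversion of the
y-on-x band), truncated to [0, 1], with the point estimate clamped inside
its interval. Whether such intervals should be confidence or prediction
bands was not fixed a priori; prediction-band inversion was chosen because
the shallow observation is itself a new noisy draw, and it empirically
covers the truth at ≈ 95% in the held-out simulation (the acceptance
script recomputes this). The direct re-regression of x on y is available
as an alternative fit for comparison but is biased when the line is used
outside the fitted range; a slope ≤ 0 aborts with an error since inverse
prediction is then meaningless.

## The synthetic methylome

The generator builds one chromosome of non-overlapping genes on
alternating strands and draws each gene's class from a mixture. Default
conditions (fixed once, used by tests and the acceptance script):

| parameter | default | rationale |
|---|---|---|
| genes | 1000 | enough for stable FDR behaviour, small enough for seconds-scale runs |
| class mix | 70% unmethylated / 20% gbM / 10% TE-like | the angiosperm-like regime: gbM a large minority, TE-like genes rarer |
| gene length | uniform 300–3000 bp | compact-plant-genome CDS range; short genes make the ≥ 10-covered-CG rule bind |
| intergenic gap | 2000 bp | accommodates 1000-bp flanks; 4000-bp flanks intentionally overlap neighbours (see caveat above) |
| p(methylation) | gbM: CG 0.8 (profiled), non-CG 0; TE-like: 0.8 all contexts; unmethylated: 0 | strong, well-separated classes: the recovery tests probe the rule chain, not borderline power |
| body profile | 0.3 at windows 1/20 rising to 1.0 at 9–12 | qualitative TSS/TTS depletion of gbM genes |
| site density /bp/strand | CG 0.02, CHG 0.015, CHH 0.05 | plant-like context frequencies; ~12 CG sites for the shortest genes, so ~1× coverage pushes some genes under the 10-site rule |
| coverage | Poisson(20) | "deep" regime |
| non-conversion rate | 0.005 | a conventional bisulfite NCR; the apparent per-read probability is \(p + (1-p)\,\mathrm{ncr}\) |

Non-conversion is modelled as false methylation only (a methylated
cytosine never reads unmethylated): under-conversion is the dominant WGBS
error mode and over-conversion is second order. The gbM window profile is
applied to CG sites only, matching the CG-specificity of the class.
Context labels are assigned directly rather than derived from a simulated
nucleotide sequence — the analysis consumes contexts, not k-mers.

What the simulation does *not* emulate — and therefore what passing tests
do not show about real data: alignment and mapping bias, PCR duplicates,
strand-asymmetric coverage, CG-island-like density variation, partially
methylated domains, and genes whose true methylation sits near the
background (borderline power). The recovery criteria (sensitivity ≥ 0.95,
no TE-like false calls, ≤ 1% unmethylated false calls) certify the
implementation of the rule chain under clearly separated classes, not the
biological error rates on any real genome.

## Numerical and degenerate-input conventions

* Undefined levels are `NA`, never 0; binomial tests with n = 0 yield `NA`
  p- and q-values that BH passes through without counting.
* Background proportions are clamped away from 0 and 1 by 1e−9 so the
  binomial tail is always defined.
* ORF ties (equal longest length) resolve forward strand first, then lower
  frame, then leftmost start — determinism, not biology; codons containing
  N can neither start nor stop an ORF.
* Every stochastic stage takes an explicit seed; the pipeline derives
  per-stage seeds from one master seed so stages are individually
  reproducible, and identical configurations produce byte-identical output
  tables.
* Problem sizes in the test-suite (25–300 genes for unit tests, the full
  1000-gene mixture for end-to-end recovery, 100-seed Monte-Carlo loops,
  500-replicate coverage studies) were chosen so the whole suite runs in
  about a minute while keeping Monte-Carlo standard errors well inside the
  asserted tolerances.

## Limitations

Symmetric CpG strand pairs are *not* merged into single units; each
strand's cytosine is an independent record, consistent with read-count
pooling (merging would require an unstated pairing rule). The classifier
inherits the circular background estimate discussed above. The metaplot
flanks are unmasked. The calibration study here is simulation-based: with
real multi-species data the scatter around the line reflects biology
(compositional differences between genomes) as well as sampling noise, and
the prediction-band inversion treats it all as noise.
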