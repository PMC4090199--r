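---
title: "Scoring phenotype-pathway clustering against a pooled resampling null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring phenotype-pathway clustering against a pooled resampling null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathlink)
```

## The model

A GWAS catalog row associates a phenotype with a SNP at some p-value.
`pathlink` asks a downstream question: once each SNP is attached to a
gene, do a phenotype's genes concentrate in particular pathways more
than random gene sets of the same size would?

The score for phenotype $i$ and pathway $j$ is the plain count
$DP_{ij} = |g_i \cap m_j|$, where $g_i$ is the phenotype's set of
pathway-universe genes ($G_i = |g_i|$) and $m_j$ the pathway's gene
set. Its null distribution is built by resampling: draw $G_i$ genes
uniformly without replacement from the universe (size $N$, the union of
all pathway sets), record the count in each of the $P$ pathways, and
repeat $R$ times. All $R \times P$ counts are pooled into one empirical
null. The observed association is significant when $DP_{ij}$ sits in
the top $\alpha$ of that pool **and** $DP_{ij} \ge$ `min_dp`.

Three consequences of pooling are worth spelling out:

* **The p-value is a function of $(G, DP)$ only.** Two phenotypes with
  the same gene-set size and the same count receive the same p-value
  regardless of which pathway produced the count. This is a deliberate
  property of the method, not an artifact; the test suite asserts it.
* **The pooled null has a closed form**, the uniform mixture of
  hypergeometric upper tails
  $\frac{1}{P}\sum_j \Pr[X_j \ge k]$, $X_j \sim
  \mathrm{Hypergeom}(N, m_j, G)$, implemented in `exact_pooled_tail()`.
  The sampler is validated against it; it also powers analytic
  detectability checks for the synthetic benchmark.
* **Pooling is conservative for large pathways and liberal for small
  ones** relative to a per-pathway conditional null. The conventional
  conditional variant (compare $DP_{ij}$ only to pathway $j$'s own
  replicate counts) is available via
  `run_enrichment(null_mode = "per_pathway")`; the pooled mode is the
  default because it is the method this package implements, and its
  constant-p structure is part of the contract.

### Why `min_dp = 2`

A single gene falling in a pathway says nothing about clustering across
genes; a count of one is also extremely common under the null for
typical pathway sizes. Requiring at least two distinct genes in the
pathway (and at least two mapped genes per phenotype — the
"testable" flag) keeps the score interpretable as clustering.

### The p-value estimator

The default estimator is the raw tail fraction, matching the
"observed $\ge$ 95% of random scores" decision rule; it can return 0
when the observation exceeds the pool maximum. A smoothed
$(c+1)/(n+1)$ estimator (`smooth = TRUE`) never reports 0 and is
preferable when p-values are consumed numerically rather than
thresholded.

## SNP-to-gene mapping

Two modes are provided. `"reported"` trusts the catalog's curated gene
column (splitting `"A - B"` intergenic placeholders into both genes by
default, since the flanking genes are the curator's candidates).
`"coordinate"` assigns a SNP to every gene interval containing it,
else to the single nearest gene within `window` base pairs (default
20,000 bp — a declared parameter, not an estimate), else to no gene.
Coordinates are 0-based half-open everywhere internally; BED files are
read verbatim through `rtracklayer`. Equidistant flanking genes are
broken toward the lexicographically smaller symbol so runs are
reproducible. Distances are gap lengths: a SNP at position $p$ past an
interval end $e$ (exclusive) is $p - e$ away.

## The global null

Per-pair p-values say nothing about how many significant associations a
whole catalog should produce by chance. The nested pseudo-phenotype
simulation answers that directly: in each of `outer_reps` replicates,
every phenotype is replaced by a uniform random draw of the same size
$G_i$, scored against inner pools of `inner_reps` resamples, and the
significant calls are summed. `summarize_global_null()` then reports
the observed total's position (median, z, resampling p; the p-value is
floored at `1/outer_reps` rather than reported as 0).

Two implementation choices matter here:

* **Pool caching.** The inner null depends only on $G$, so one pool per
  distinct $G$ is drawn and shared across phenotypes and outer
  replicates (`fresh_inner = FALSE`, the default); the literal
  draw-everything-fresh procedure is available with
  `fresh_inner = TRUE`. Caching changes the cost from
  `outer_reps * inner_reps` to `inner_reps` resamples per distinct $G$
  with the same marginal distribution.
* **Seed sharing between enrichment and calibration.** With cached
  pools, the empirical critical count $k^*(G)$ (smallest count whose
  pooled tail is $\le \alpha$) is a realization of the pool draw; when
  the pooled tail at some $k$ sits near $\alpha$, two independent pools
  can disagree by one. If the real enrichment run and the global-null
  simulation used independent pools, that disagreement would shift the
  observed total relative to the whole null band and spoil calibration.
  Both therefore derive pool seeds identically from the run seed, so
  the observed data and the pseudo phenotypes are judged by exactly the
  same thresholds; conditional on the pool, observed and null totals
  are then exchangeable under the null, which is what the calibration
  test checks. The pipeline's `globalnull` stage reuses the `enrich`
  stage seed for this reason.

## Networks and summaries

Phenotypes sharing at least one significantly associated pathway are
linked; weights count shared pathways, and the total weight always
equals $\sum_p \binom{k_p}{2}$ over pathways ($k_p$ = number of
phenotypes significant in pathway $p$), a conservation identity the
tests verify by brute force. `filter_network()` applies a minimum
weight (1 keeps the full network; 3 keeps only strongly co-associated
pairs) and reports connected components via `igraph`. Category
annotations are styling metadata only — the network itself is built
unsupervised from the significance calls. `category_fractions()` bins
phenotypes by SNP count (default edges 2, 5, 10, 20; the bins are a
reporting choice, exposed as a parameter) and contrasts association
counts with unique-pathway counts per category;
`correlation_table()` reports Pearson correlations (raw counts, via
`cor.test`) among study subjects, mapped genes and significant
pathways.

## The synthetic generator

`synthetic_spec()` fixes the benchmark conditions: 20 pathways of 15
genes sampled from a 200-gene pool (pool size = mean size /
`overlap_fraction`, so the expected pairwise intersection is
$s^2/N \approx 1.1$ genes), full pool coverage restored by swapping
uncovered genes into multiply-covered slots (sizes preserved), 50 null
phenotypes, 20 planted phenotypes with `signal_fraction = 0.8` of their
8–12 genes drawn from one causal pathway, one intragenic SNP per gene,
and study sizes $500 + 150\,\mathrm{genes} + \mathcal{N}(0, 300)$
(implying a subjects~genes correlation of
$150\sqrt{2}/\sqrt{150^2 \cdot 2 + 300^2} \approx 0.58$, in the range
reported for real catalogs). Genes occupy non-overlapping 2-kb
intervals spaced 10 kb apart, so coordinate mapping recovers the
generator's gene choices exactly — mapping correctness and statistical
behavior are tested separately. A `messy` switch moves some SNPs just
downstream of their gene to exercise the window logic without breaking
that recovery. Association p-values are sampled log-uniformly in
$[10^{-12}, 10^{-5}]$; they are filtered, never modeled, so the shape
is cosmetic.

What the generator does **not** emulate: linkage disequilibrium (SNPs
are independent given their gene), gene-length or SNP-density biases,
hierarchically curated pathway overlap, or heavy-tailed study sizes.
Tests passing on this generator show the statistics behave as designed
under clean sampling assumptions; they do not certify robustness to
LD-driven gene correlation, which the method itself (like the counting
score it implements) does not model.

## Scale choices and degenerate inputs

Simulation sizes in the tests and the acceptance script are
desk-scale choices: inner pools of 1000 resamples, 200 outer
global-null replicates, 50 repeated calibration experiments; the
procedure itself is scale-free and the defaults can be raised in
`run_config()`. Degenerate cases are defined, not guessed: $k \le 0$
has tail 1 and $k > G$ tail 0; a zero-variance null yields a flagged
infinite z; phenotypes with fewer than two mapped genes are excluded
from scoring but retained in reports; unknown phenotypes fall into
category `"other"` with a warning; malformed catalog rows fail fast by
default (`on_bad_row = "skip"` to drop them with line-numbered
warnings). Phenotype labels merge by exact match after trimming,
whitespace collapse and case-folding; further merging is the job of an
explicit synonym table, not heuristics.

## Limitations

The score treats pathways as flat gene sets and genes as exchangeable
units; p-values inherit the granularity of the resampling pool
(`1 / (reps * P)` in pooled mode); and catalog-level inputs mean the
analysis can only be as good as the upstream SNP curation and the
pathway database's coverage.
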