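---
title: "Methods and design notes for mirnetmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mirnetmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnetmeta)
```

## What the package computes

`mirnetmeta` evaluates a candidate microRNA marker across independent
expression cohorts and integrates that evidence with gene-level resources:
literature co-citation, multi-platform target prediction, pathway
membership and interaction networks. The packaged worked example is a
down-regulated liver-cancer microRNA studied across nine microarray
cohorts, one RNA-seq cohort and one qRT-PCR cohort, but every stage takes
generic tabular inputs and none is tied to that marker.

The stages, in pipeline order:

1. **Cohort statistics.** Each cohort is reduced to per-arm summaries
   (n, mean, sd with the n − 1 denominator). Welch's unequal-variance t
   is the default two-group test because expression variances routinely
   differ between tumor and normal tissue by several-fold; the
   pooled-variance variant is available, and for equal arm sizes the two
   statistics coincide. Differential-expression screening uses the
   fold-change rule FC < 0.5 or FC > 2 together with p < 0.05, both
   bounds strict. Diagnostic performance is the Mann–Whitney AUC with
   midrank ties, auto-oriented to be at least 0.5 with the direction
   reported, and DeLong confidence intervals.
2. **Meta-analysis.** Per-study standardized mean differences are pooled
   by inverse variance; DerSimonian–Laird moments estimate the
   between-study variance tau². Heterogeneity is summarized by Cochrane's
   Q and I² = max(0, (Q − df)/Q)·100, and the model is chosen by the
   rule "random effects when the heterogeneity p < 0.05 **or** I² > 50%,
   else fixed". Publication bias: Egger's regression of the standardized
   effect on precision (intercept tested on K − 2 df) and the
   Begg–Mazumdar Kendall-tau rank correlation with the
   continuity-corrected normal approximation.
3. **Literature co-citation.** For corpus constants N (articles) and n
   (disease articles), a gene seen in m articles and co-seen with the
   disease in k articles is scored by the upper-tail hypergeometric
   probability P(X ≥ k), X ~ Hypergeometric(N, n, m). Counting is at the
   article level (a gene counts once per article), so the distributional
   null is exact. The tail is evaluated through the complement of the CDF
   at k − 1 (log-space internally) because the factorial form of the pmf
   overflows double precision at bibliographic corpus sizes.
4. **Consensus target voting.** Platform nominations are binary; a gene
   is accepted when at least 4 of the 11 platforms nominate it. Symbols
   are upper-cased and alias-normalized before tallying — without a
   shared symbol space a "nominated by at least four" rule is
   ill-defined, since prediction tools disagree on synonyms.
5. **Integration, enrichment, connectivity, networks.** Set intersection
   of disease-related and predicted-target genes; pathway
   over-representation by the same hypergeometric tail (population =
   background, successes = pathway, draws = query); hub connectivity by
   standardizing each candidate gene's degree against the candidate
   population's sample mean and n − 1 sd with a one-sided upper normal
   tail; and assembly of an undirected, unweighted network from tagged
   edge sources with SIF and GraphML round-trip export.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| t-test variant | `welch` | — | robust to unequal arm variances; `pooled` kept for legacy comparisons |
| FC bounds | 0.5 / 2 | ratio | symmetric two-fold change on the linear scale, strict inequalities |
| screening alpha | 0.05 | probability | conventional two-sided level, applied jointly with the FC rule |
| SMD correction | `"none"` | — | see below; `"hedges"` applies the J factor |
| heterogeneity rule | p < 0.05 or I² > 50% | — | standard random-vs-fixed trigger; both constants configurable |
| CI multiplier | 1.96 | — | normal quantile, matching field practice for pooled SMDs |
| vote threshold | 4 of 11 | platforms | balances the high false-positive rate of single predictors against seed-match sensitivity |
| co-citation alpha | 0.05 | probability | raw per-gene p, no multiplicity correction by default; Benjamini–Hochberg behind `adjust = TRUE` |
| enrichment background | union of pathway members | genes | smallest defensible universe when no annotation universe is supplied; an integer genome size or explicit set overrides it |

## The two SMD conventions

Two textbook conventions for the standardized mean difference and its
sampling variance are implemented:

* **Hedges' g** — `g = J·d` with `J = 1 − 3/(4N − 9)` and variance
  `N/(n1·n2) + g²/(2(N − 3.94))`; the convention of mainstream
  meta-analysis software, slightly conservative for small panels.
* **Uncorrected d** — `d = (m1 − m2)/s_pooled` with variance
  `N/(n1·n2) + d²/(2(N − 2))`.

The packaged cohort panel's published forest-plot output — both pooled
estimates, both confidence intervals and both I² values — reproduces to
printed precision under the uncorrected convention and only approximately
under Hedges' g, which identifies the uncorrected form as the one the
original analysis software applied. The fixture-backed pipeline therefore
defaults to `correction = "none"`, while `hedges_g()` is recommended for
new panels with small cohorts. With every packaged cohort at N ≥ 6 the two
conventions differ in the third decimal at most.

```{r smd, eval = TRUE}
studies <- read_studies_tsv(fixture_path("studies"))
pool_random(effect_sizes(studies, correction = "none"))$pooled
pool_random(effect_sizes(studies, correction = "hedges"))$pooled
```

## What the synthetic generators emulate — and what they do not

The generators produce inputs with exactly the statistical structure each
stage assumes, so recovery tests are well-posed:

* `gen_cohort`: Gaussian arms at specified n/mean/sd. Real microarray and
  RNA-seq expression is only approximately Gaussian after normalization
  (heavier tails, occasional bimodality); passing recovery tests shows
  the estimators are correct under their own model, not that the model
  fits any platform.
* `gen_meta_panel`: study effects drawn Normal(SMD, tau²), arm summaries
  computed from raw Gaussian draws so summaries and generating effect are
  mutually consistent. No small-study bias, no outcome-dependent
  censoring — publication-bias power is exercised separately by explicit
  censoring in the tests.
* `gen_corpus`: article counts from a uniform range, co-occurrence counts
  from the exact hypergeometric null, multiplicatively inflated for
  planted genes and capped at min(n, m). Real literature counts are
  overdispersed (hot genes attract citations); the generator's null is
  the test's null by construction, which is what a calibration check
  needs.
* `gen_predictions` / `gen_pathways`: planted targets receive at least
  the threshold number of votes, decoys strictly fewer; one pathway
  over-samples the query. Correlated platform errors (shared seed-match
  logic) are not modeled.
* `gen_network`: a requested degree sequence is realized *exactly* by a
  deterministic Havel–Hakimi pairing, or rejected with an explanation
  (odd degree sum, unsaturable node). A deterministic construction was
  chosen over random rewiring so a published degree table reproduces its
  connectivity p-values bit-for-bit; the price is that only one graph per
  degree sequence is ever produced, so the generator is a fixture
  builder, not a random-graph null model.

## Numerical and degenerate-input choices

* Hypergeometric tails come from the regularized CDF complement, never
  the factorial pmf; agreement with a direct binomial-coefficient
  summation is held to 10⁻¹² across an exhaustive small-corpus grid.
* k = 0 scores p = 1 exactly (empty sum), keeping null corpora
  conservative under discreteness.
* Ranking ties are fully specified (ascending p, then descending k, then
  symbol; degree descending then symbol for connectivity) so output
  tables diff cleanly across runs.
* Both-arms-zero sd, empty ROC groups, zero pooled sd, all-equal degree
  populations, non-positive linear means and non-graphical degree plans
  raise immediate, specific errors rather than propagating NaN.
* Welch and pooled t are shift-invariant and scale-equivariant by
  construction; the test suite verifies this property on random
  summaries.
* `pool_random` with one study degenerates to that study's fixed-effect
  result; `select_model` requires at least two.

## Problem sizes used in validation

The packaged validation workloads were sized to be decisive yet quick on
a laptop core: the exhaustive hypergeometric grid runs all corpora up to
N = 40 (≈ 10⁵ tuples) plus 4000 stratified draws up to N = 200; parameter
recovery uses 500 panels of K = 30 studies at 50 subjects per arm
(mean pooled estimate within 0.05 of the generating SMD, CI coverage
required to sit in [90%, 98%]); null co-citation calibration uses 2000
genes with the flagged fraction bounded at 7% (discreteness makes the
exact test conservative, so the bound sits above the nominal 5% but well
below any signal regime); consensus recovery uses 30 planted targets
against 200 decoys.

## Known limitations

* Summary-level t tests cannot reproduce paired designs; cohorts measured
  as tissue pairs need per-pair differences, which summary rows do not
  carry. The packaged panel documents three such rows as not exactly
  reproducible for this reason.
* No moderated (empirical-Bayes) test statistics: the screening rule is
  the plain t/FC combination, by design.
* DerSimonian–Laird is the only tau² estimator; REML or Paule–Mandel
  alternatives are out of scope, as are trim-and-fill, meta-regression
  and subgroup analysis.
* The enrichment background default (union of pathway members) is the
  smallest defensible universe; p-values shrink as the universe grows, so
  cross-study comparisons should fix an explicit background.
* Networks are undirected and unweighted; directionality of regulatory
  edges is deliberately collapsed because the downstream statistic is
  degree-based.
* Gene-mention tagging is out of scope: the co-citation stage ingests
  pre-computed count tables (or pre-tagged mention lists via
  `normalize_mentions`), not raw text.
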