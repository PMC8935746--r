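---
title: "Methods and design of the stemsc package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the stemsc package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemsc)
```

## The model

`stemsc` quantifies cellular stemness from the *relative expression
orderings* (REOs) of gene pairs. Within one sample, the only information
used about a gene pair (Gi, Gj) is whether Gi > Gj or Gi < Gj. Because any
per-sample normalization (RPKM → TPM, log transformation, library-size
scaling) is a strictly increasing map of expression values, it cannot change
a single REO. This is the core assumption and the core strength: scores are
comparable across datasets without any batch correction, at the price of
discarding all magnitude information.

The pipeline has three stages.

**Stable REOs.** A pair is *stable* in a dataset when its strict ordering is
identical in all samples. Agreement between the stable sets of two datasets
is summarized as `s/n` — `n` unordered pairs stable in both, `s` of them
with the same direction — and its significance against chance agreement
comes from the upper-tail cumulative binomial probability
`P(X >= s)` with `X ~ Binomial(n, P0)`, `P0 = 0.5`. We evaluate this via the
survival tail of `stats::pbinom`, which is accurate in log-space for `n`
well past 10^6 shared pairs; naive term-by-term summation would underflow.

**Training.** Stemness-related genes are selected from differentiation time
courses: per dataset, each gene's Spearman correlation with time (average
ranks, two-sided p from the t approximation) is adjusted by
Benjamini–Hochberg within the dataset, and the panel is the intersection of
genes significant (FDR < 0.05) in *every* course. The reference signature is
then the set of gene pairs, restricted to the panel, that are stable in a
pooled single-cell ESC collection *and* in a pooled bulk ESC collection with
the same direction. Pooling happens at the sample level per pool; requiring
concordance between a sparse single-cell pool and a deep bulk pool is what
buys cross-platform robustness.

**Scoring.** For a sample, `n` counts the signature pairs *contained* in it
(both genes in its universe, values strictly unequal) and `k` counts those
ordered as in the reference; the index is `k/n`, in [0, 1], undefined when
`n = 0`. ESC-like samples sit near 1.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_samples` | 4 | minimum dataset size for stability ("more than three samples") |
| `p0` | 0.5 | chance REO agreement probability in the binomial model |
| `fdr_threshold` | 0.05 | per-dataset BH cutoff for panel membership |
| `min_detected` | 2000 | QC floor of detected genes per cell (strict `<` removes) |
| `min_cells`, `top_n` | 10, 5000 | detection floor and list size for HVG selection |
| `n_perm` | 1000 | permutations for pre-ranked enrichment |
| `ties` (scoring) | `"exclude"` | tie handling in the score denominator |

## Decisions where the design was open

**Ties disqualify stability and are excluded from scoring.** Whether the
original REO formulation treats equal values (including double dropouts) as
"certain" orderings is unstated. We require strict inequality everywhere:
only strict orderings survive arbitrary monotone transforms, and a tie
carries no directional evidence. For scoring, excluded ties also keep sparse
single-cell scores well defined; `ties = "discordant"` reproduces the
harsher reading in which a tie counts against concordance. Zero is a
measured value, not missing: a (positive, zero) pair is evaluable.

**Panel membership requires significance only.** Selection is "significantly
related to differentiation time in all datasets"; a common sign of the
correlation is *not* required by default (differentiation directions differ
between protocols). `require_sign_concordance = TRUE` exposes the stricter
rule.

**Threshold criterion is precision.** The CSC-calibrated lower limit is the
smallest observed score maximizing the CSC fraction *within* the stem-like
group (`score >= t`); on ties the smallest threshold wins, giving the
largest qualifying group. Maximizing recall instead is exposed via
`criterion = "recall"` but is degenerate (it always prefers the lowest
candidate).

**Enrichment of a full-universe gene set.** The weighted running sum
(hits weighted by |stat| normalized to +1, misses decremented uniformly by
`1/(N - N_hit)`) has no miss decrement when the set exhausts the universe —
formally 0/0. There is no contrast to measure, so ES is defined as 0 with
p = 1. Permutations relabel genes (not phenotypes), the standard choice when
only a ranked list exists; NES is ES over the mean |null ES| of matching
sign and p is the one-sided frequency among same-sign nulls with the +1
continuity correction. Numeric NES/p values from other GSEA implementations
with different settings are not expected to match.

**Sorting is byte-wise.** All gene orderings use radix (C-locale) sorting so
that serialized pair lists are bit-identical across platforms and locales.

## What the synthetic data emulates — and what it does not

The generator states one latent world per config seed: base log2 means
`N(5, 2)`, 40 of 300 genes planted with monotone log2 trends of ±1 per unit
time across time points 0..5, log-normal noise (sd 0.5), and per-dataset
library scale factors. ESC pools are replicates of the time-0 state (3×30
single-cell-like plus 2×24 bulk-like datasets by default, echoing the scale
of public ESC compendia); tumor mixtures place a CSC fraction at time 0 and
differentiated cells at a configurable latent offset.

Dropout in the single-cell generators is *expression-dependent*: each entry
drops with probability `rate * plogis((midpoint - log2 expr) * 2)`. This is
a deliberate deviation from uniform dropout, and it is load-bearing: with
uniform dropout at any realistic rate, every gene is zeroed at least once
somewhere in a ~90-cell pool, so *no* pair can be stable in all samples and
no signature could ever be trained — whereas real single-cell ESC
compendia do yield tens of thousands of stable pairs, precisely because
detection failures concentrate in weakly expressed genes. The uniform
operation is still provided (`apply_dropout`) as the contracted stress-test
primitive. Time courses are generated without dropout by default (sorted
bulk-like protocols).

What a green test on this world establishes: correctness of the REO
machinery, the training logic, the scoring arithmetic, and exact rank
invariance. What it does not establish: performance on real data with
correlated gene modules, non-monotone expression programs, cell-cycle
structure, doublets, or ambient contamination — none of which are modeled.

## Numerical notes

- Spearman p-values use the t approximation with average ranks; |rho| = 1
  maps to p = 0 and zero-variance genes to an undefined rho with p = 1,
  excluded from selection. Exact permutation p-values are out of scope.
- BH adjustment is the standard step-up `min_{j>=i} p_(j) m / j`, clipped to
  [0, 1]; it is checked against an independent enumeration oracle and
  `stats::p.adjust` in the tests.
- Undefined quantities (score with `n = 0`, consistency with no shared
  pairs) propagate as `NA` markers, never as 0, 1 or an error.
- Argmax ties in root selection break toward the lexicographically smallest
  state label, with a warning; enrichment ranking breaks statistic ties by
  gene identifier. Both rules exist for determinism, not biology.
- `recovery_rate` pools training samples (not an intersection of per-dataset
  stable sets); adding a dataset therefore only shrinks the merged stable
  set, which is why the recovered fraction rises with the number of merged
  datasets.

## Known limitations

- A signature trained on one species/identifier scheme is only usable after
  [map_gene_ids()]-style harmonization; the many-to-one collapse keeps the
  highest-mean row, a convention, not a ground truth.
- Scores of samples measuring few signature genes rest on small `n`; the
  `n_evaluable` column should be inspected before comparing such scores.
- The CSC-calibrated threshold is dataset-derived; transferring it assumes
  score comparability, which REO invariance supports but sparsity can erode.
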