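# stemsc

Rank-based stemness scoring for bulk and single-cell transcriptomes.

## The problem

Stemness — the self-renewal and differentiation potential of a cell — is
routinely estimated from transcriptomes, but absolute-expression indices
degrade when applied across datasets: normalization units (RPKM vs TPM vs
counts), platform and batch effects all shift the values a model was trained
on. That makes it hard to, say, reuse experimentally validated cancer stem
cells (CSCs) from one dataset to call stem-like cells in another.

`stemsc` implements a stemness index built on **relative expression
orderings (REOs)**: for a gene pair (Gi, Gj) within one sample, only the
direction Gi > Gj or Gi < Gj is retained. REOs are invariant to any strictly
increasing per-sample transform, so everything downstream is free of
per-sample normalization and monotone batch distortions by construction.

## The method

1. **Stable REOs.** Within a dataset (≥ 4 samples), a gene pair is *stable*
   when its strict ordering is identical in every sample. Cross-dataset
   agreement of two stable-REO sets is `s/n` (n shared pairs, s with equal
   direction), with significance from the upper-tail cumulative binomial
   model `P = P(X ≥ s)`, `X ~ Bin(n, P0 = 0.5)`.
2. **Training.** Stemness-related genes are those significantly Spearman-
   correlated with differentiation time (BH FDR < 0.05) in *every* training
   time course. Stable REOs among these genes are identified separately in a
   pooled single-cell ESC collection and a pooled bulk ESC collection; pairs
   stable in both pools with concordant direction form the **reference
   signature**.
3. **Scoring.** The StemSC index of a sample is `k/n`: of the `n` reference
   pairs contained in the sample (both genes present, values strictly
   unequal), `k` preserve the reference (ESC) direction. ESC-like samples
   score near 1; differentiated samples drift toward 0.5.
4. **Downstream.** Marker ranking by gene–score Spearman correlation,
   pre-ranked weighted-KS gene-set enrichment, CSC-calibrated thresholding
   for stem-like cell calling, trajectory-root selection (state with the
   highest mean score), CV²·mean highly-variable-gene selection, and
   two-sample comparisons.

A synthetic-data module generates differentiation courses, ESC pools, tumor
mixtures, monotone batch distortions and dropout with planted ground truth,
so the whole pipeline is testable end to end.

## Worked example

```r
library(stemsc)

cfg <- synthetic_config(seed = 1)                        # 300 genes, 40 planted
courses <- lapply(1:5, function(k)
  generate_differentiation_course(cfg, paste0("tc", k), seed = 100 + k))
panel <- select_stemness_genes(courses)
#> StemnessGenePanel: 40 genes (FDR < 0.05 in every dataset)

pool <- generate_esc_pool(cfg, seed = 200)
sig <- build_reference_signature(pool$sc, pool$bulk, panel)
#> ReferenceSignature: 273 directed pairs over 40 panel genes
#>   stable in sc pool: 277; bulk pool: 502; shared: 273; concordant: 273

held <- generate_differentiation_course(cfg, "validation", seed = 300)
scores <- score_dataset(held, sig)
head(scores, 3)
#>            sample n_evaluable k_concordant   stemsc
#> 1 validation_c001         273          273 1.000000
#> 2 validation_c002         273          272 0.996337
#> 3 validation_c003         273          273 1.000000
cor(scores$stemsc, held$sample_meta$time, method = "spearman")
#> [1] -0.9902724                      # stemness falls with differentiation time

select_root_state(scores, held$sample_meta$state)
#> RootCall: root = S1
#>   state means: S1=1.000, S2=0.980, S3=0.885, S4=0.815, S5=0.774, S6=0.755

mix <- generate_tumor_mixture(cfg, csc_fraction = 0.2, separation = 3, seed = 400)
msc <- score_dataset(mix, sig)
select_stem_threshold(msc, mix$sample_meta$csc)
#> ThresholdDecision: threshold = 0.9963, precision = 1.000,
#>   groups = 12 stem-like / 48 other (31 candidates)
```

The recovered root is the planted origin state, the score–time correlation
is strongly negative on a held-out course, and the CSC-calibrated threshold
isolates exactly the planted stem compartment.

## Command line

A CLI wrapper ships at `inst/cli/stemsc.R`:

```sh
STEMSC=$(Rscript -e 'cat(system.file("cli", "stemsc.R", package = "stemsc"))')
Rscript $STEMSC simulate course --config cfg.txt --seed 7 --out-prefix sim/run
Rscript $STEMSC train --time-datasets a.tsv,b.tsv --time-meta a.meta,b.meta \
    --sc-pool sc1.tsv,sc2.tsv --bulk-pool b1.tsv --fdr 0.05 -o signature.tsv
Rscript $STEMSC score --matrix cells.tsv --signature signature.tsv -o scores.tsv
Rscript $STEMSC threshold --scores scores.tsv --labels meta.tsv
Rscript $STEMSC root --scores scores.tsv --states meta.tsv
Rscript $STEMSC consistency --set-a reos_a.tsv --set-b reos_b.tsv
```

All subcommands exit 0 on success and nonzero with a diagnostic on stderr;
`--quiet` silences progress messages.

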