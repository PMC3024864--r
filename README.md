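# mirhairpin

Classification of microRNA precursor hairpins with an imbalance-aware
SVM ensemble.

Real pre-miRNAs are ~70–150 nt transcripts folding into stem–loop
structures; genomes contain vastly more "pseudo hairpins" (3'-UTR
fragments, other ncRNAs) that look similar. `mirhairpin` separates the
two classes for people building miRNA gene-finding pipelines, with two
distinctive ingredients:

* **Multi-loop features.** Roughly 84% of pseudo hairpins fold with more
  than one terminal loop. Four features normalized by the loop count —
  dP/n_loops and %(X−Y)/n_loops for X−Y ∈ {A−U, G−C, G−U} — make
  branching an explicit signal instead of a failure mode.
* **An ensemble against class imbalance.** With a negative:positive
  ratio near 7.79:1, the negatives are sorted by distance to the
  positive-class centroid and split into k near-equal partitions; one
  RBF-kernel SVM is trained per partition on (all positives + that
  partition). Predictions aggregate by **majority vote** (with a
  latter-half priority rule on even-k ties) or by **mean distance**
  (each sample classified once, by the submodel with the nearest
  training-set centroid).

Around that core: a self-contained dynamic-programming folding engine
(MFE + exact partition function with base-pair probabilities, under an
additive pair-energy model), a dinucleotide-preserving shuffle null for
z-scores/p-values of folding energies, the canonical 65-feature vector
(32 triplet elements, 15 base-pair features, 18 thermodynamic features),
F-score feature ranking

```
F_i = [ (mean_i(+) − mean_i)² + (mean_i(−) − mean_i)² ] /
      [ var_i(+) + var_i(−) ]        (n−1 variances)
```

and stratified outer 3-fold cross-validation reporting SE, SP, Acc and
the geometric mean Gm = √(SE·SP), the metric of record under imbalance.

## Worked example

Simulate a labeled dataset (single-loop hairpin positives, mostly
multi-branched negatives), extract features, rank them, train and apply
an ensemble:

```r
library(mirhairpin)

ds <- make_dataset(n_pos = 8, ratio = 3, multi_branch = 0.84, seed = 42)
fm <- extract_features(ds$records, labels = ds$labels,
                       n_shuffles = 25, seed = 42)
fm
#> <feature_matrix> 32 x 65 (8 positive / 24 negative)

rank_and_select(fm, m = 10)
#> <fscore_ranking> 65 features, top 10 selected (n+=8, n-=24)
#>   dP/n_loops         F = 61.02
#>   MFEI_3             F = 42.12
#>   %(G-C)/n_loops     F = 9.94
#>   dS                 F = 3.788
#>   dH                 F = 3.6

model <- train_ensemble(fm, k = 2, select_m = 10, seed = 42)
pred  <- predict(model, fm, aggregation = "mean_distance")
compute_metrics(confusion_matrix(fm$labels, pred))
#> SE=100.00% SP=100.00% Gm=100.00% Acc=100.00%
```

The two loop-normalized features and MFEI_3 (= dG/n_loops) top the
ranking — on data whose negatives are mostly multi-branched, the
multi-loop features carry the signal, and the ensemble then separates
the classes perfectly on its training data. Individual molecules are
inspectable at every stage:

```r
partition_function(ds$records[[1]])
#> <fold_result> MFE=-114.000 EFE=-119.755 Freq=8.81e-05 diversity=25.195
#> .....((((((((.(((((((((((((((.(((((((.((.((((((((.((.((((.........))))))))))))))))))))))))))))))))))))))))))))))....
```

A command-line interface wrapping the same functions ships in
`inst/scripts/mirhairpin` (subcommands `simulate`, `extract`, `select`,
`train`, `predict`, `eval`).

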