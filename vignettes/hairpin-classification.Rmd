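---
title: "Classifying microRNA precursor hairpins with an imbalance-aware SVM ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying microRNA precursor hairpins with an imbalance-aware SVM ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(mirhairpin)
```

## The problem

Mature microRNAs are excised from ~70–150 nt precursor transcripts
(pre-miRNAs) that fold into characteristic stem–loop ("hairpin")
structures. Genomes are full of segments — 3'-UTR fragments, other
non-coding RNAs, random stem-loops — that fold similarly but are not
miRNA precursors. Telling the two apart is a binary classification
problem with two awkward properties:

1. **Severe class imbalance.** Known precursors are few; hairpin-like
   pseudo precursors are plentiful. In a representative training
   collection the negative:positive ratio is 7.79:1.
2. **Multi-branched structures.** A large fraction of pseudo hairpins
   (roughly 84%) — and a small fraction of real ones — fold with more
   than one terminal loop, which single-hairpin heuristics mishandle.

`mirhairpin` addresses both: loop-count-normalized ("multi-loop")
features make branching explicit, and an ensemble of SVMs trained on
partitions of the negative class handles the imbalance without
discarding or duplicating data.

## The folding engine

Every structural and thermodynamic feature is a function of a predicted
secondary structure and its Boltzmann ensemble. The package ships a
self-contained dynamic-programming engine with an **additive base-pair
energy model**: a structure's energy is the sum of its pair energies
(defaults GC = −3, AU = −2, GU = −1 kcal/mol; no stacking or loop
terms), hairpin loops must enclose at least 3 unpaired bases, and
pseudoknots are excluded. The recursions are exact under this model:

* `fold_mfe()` computes the minimum free energy and one optimal
  structure (Nussinov-style DP). Co-optimal structures are resolved
  deterministically: pairing the 5' end is preferred over leaving it
  unpaired, and the smallest partner index wins.
* `partition_function()` computes the exact partition function
  $Z = \sum_S e^{-E(S)/RT}$ over all legal structures, the ensemble free
  energy $\mathrm{EFE} = -RT \ln Z$, the MFE structure's ensemble
  probability $\mathrm{Freq} = e^{-\mathrm{MFE}/RT}/Z$, base-pair
  probabilities $p_{ij}$ by an inside–outside recursion, and the
  ensemble diversity $2\sum_{i<j} p_{ij}(1-p_{ij})$.

The rationale for a toy model rather than a full nearest-neighbour
thermodynamic model is reproducibility: the features the classifier
consumes only require MFE, EFE and structure topology, and with a
self-contained engine every downstream number is exactly reproducible —
and testable against exhaustive structure enumeration, which the test
suite does for hundreds of short sequences. The engine is a module
boundary: all features are defined relative to whichever `FoldResult`
produced them, so a different folding engine can be substituted without
touching the feature definitions.

Numerically, the partition function is accumulated in double precision.
Under the default energies this is exact headroom-wise for hairpin-scale
inputs (the 70–150 nt candidate window, and comfortably up to ~200 nt);
an explicit overflow check refuses longer inputs rather than returning
infinities. EFE and `Freq` are reported through `log(Z)`.

Both DP recursions are implemented in C++ (via Rcpp), as is usual for
cubic-time sequence algorithms in this field.

## The 65 features

`extract_all()` assembles a canonical, fixed-order 65-vector
(`feature_names()`), in three groups:

* **32 triplet elements.** For each window of 3 adjacent bases, the
  paired/unpaired pattern (brackets collapsed to "paired", 8 patterns)
  combined with the middle base (4 choices) gives 32 categories; the
  features are window frequencies and sum to 1.
* **15 base-pair features.** G/C ratio, %C+G, base-pair density
  dP = n_bp/L, mean stem length Avg_BP_Stem = n_bp/n_stems, ensemble
  diversity, per-length pair-type densities |X−Y|/L, per-stem pair-type
  counts (X−Y)/n_stems, and the four **multi-loop features**:
  dP/n_loops and %(X−Y)/n_loops for X−Y ∈ {A−U, G−C, G−U}, where
  n_loops counts hairpin (terminal) loops and %(X−Y) is the fraction of
  X−Y pairs among all pairs. Structures with several terminal loops see
  these features shrink proportionally, which is exactly the signal that
  separates multi-branched pseudo hairpins from genuine single-loop
  precursors.
* **18 thermodynamic features.** dG = MFE/L; the MFEI family
  (MFEI₁ = dG/%(G+C), MFEI₂ = dG/n_stems, MFEI₃ = dG/n_loops,
  MFEI₄ = MFE/n_bp); Freq; NEFE = EFE/L; Diff = |MFE−EFE|/L; an
  enthalpy estimate dH from published Watson–Crick nearest-neighbour
  stack enthalpies summed over stacked pair steps (stacks involving a GU
  wobble use a single generic −8 kcal/mol term, a documented
  simplification); dS = (dH − MFE)·1000/T and Tm = 1000·dH/dS − 273.15,
  plus the per-length versions dH/L, dS/L, Tm/L; and four shuffle-null
  statistics (below).

**Loop counting.** A "loop" is a hairpin (terminal) loop: a base pair
enclosing no other pair. Single hairpins have n_loops = 1; multi-branched
structures have n_loops ≥ 2. A "stem" is a maximal run of stacked pairs.

**Degenerate denominators.** Whenever n_stems, n_loops, n_bp, count(C),
%(G+C) or dS is 0 — unpairable or C-free inputs — the affected feature is
defined as 0 (and Freq as 1), so vectors are always finite without
sentinel values.

**MFEI₃/MFEI₄.** The literature is ambiguous about which of the two
indices carries the loop normalization; the default assigns
MFEI₃ = dG/n_loops and MFEI₄ = MFE/n_bp, and
`thermo_features(mfei34 = "swapped")` exchanges them.

**Triplet windows.** All L−2 windows are used, including the terminal
loop region; restricting windows to the stem would require a segmentation
convention the feature definitions do not otherwise need.

## The shuffle null model

Real precursors have unusually low folding energies for their
composition. To quantify this, `null_statistics()` generates
dinucleotide-preserving shuffles (Euler-path construction in the
Altschul–Erickson style: exact mononucleotide and dinucleotide count
multisets, same first and last base) and folds each with the same engine.
`z_and_p()` then computes, for MFE and EFE:

* z-score: (observed − mean(null)) / sd(null), with the n−1 standard
  deviation and z = 0 when the null is degenerate;
* empirical p-value: lower-tailed with the add-one estimator,
  p = (#{null ≤ observed} + 1)/(n + 1), never exactly 0.

The default is 300 shuffles per sequence; 25 is adequate for quick runs
and is what most of the test suite uses. Batch extraction derives one
shuffle seed per record from the batch seed and the record's sequence
content, so feature tables are reproducible and invariant to record
order.

## F-score feature ranking

For feature $i$ with class means $\bar x_i^{(\pm)}$, overall mean
$\bar x_i$ and class sizes $n_\pm$:

$$
F_i = \frac{(\bar x_i^{(+)} - \bar x_i)^2 + (\bar x_i^{(-)} - \bar x_i)^2}
{\tfrac{1}{n_+ - 1}\sum_k (x_{k,i}^{(+)} - \bar x_i^{(+)})^2 +
 \tfrac{1}{n_- - 1}\sum_k (x_{k,i}^{(-)} - \bar x_i^{(-)})^2}
$$

This is the standard filter score shipped with the libsvm tool family; a
zero denominator (a feature constant within both classes) yields F = 0.
`rank_and_select()` keeps the top m features, breaking ties by canonical
order. The default m = 32 mirrors the reference workflow, but the
selection is always data-driven: which 32 features win depends on the
training split. When selection is requested inside cross-validation it is
re-run per outer fold on the training portion only, which is
leakage-safe; a single global selection would mirror the reference
workflow but lets the held-out fold influence the ranking.

## The ensemble

`train_ensemble()` implements the imbalance-aware architecture:

1. Features are min–max scaled to [−1, 1] with parameters fitted on the
   training data (required for a meaningful RBF kernel and Euclidean
   centroids), after optional F-score selection.
2. Negatives are sorted by Euclidean distance to the positive-class
   centroid in the scaled space and cut into k contiguous near-equal
   blocks (`partition_negatives()`); block 1 is the "closer set" of
   negatives most similar to real precursors. k may range from 1 to the
   negative:positive size ratio.
3. One RBF-kernel SVM is trained per block on (all positives + that
   block), so every negative is used exactly once and positives are never
   resampled. Per-submodel (C, γ) are chosen by an inner 5-fold
   cross-validated grid search over log-spaced grids (defaults
   C ∈ 2^{−5..15}, γ ∈ 2^{−15..1}, step 2⁴), selecting by the geometric
   mean of sensitivity and specificity rather than accuracy, since Gm is
   the metric of record under imbalance. Grid ties go to the first grid
   point.
4. Each sub-training-set's centroid is stored (by default over positives
   + block; `centroid = "negatives"` restricts it to the block, since
   the phrase "center of the training set" admits both readings).

Two aggregation rules are available at prediction time:

* **Majority vote** (`predict_majority()`): every submodel votes; a
  strict majority wins. On an exact tie (even k), the majority among the
  latter half of submodels decides — submodels trained on closer sets
  systematically vote positive too eagerly, so the half trained on
  farther negatives takes priority; if the latter half is itself tied,
  the highest-index submodel decides. The last rule is the package's own
  deterministic completion of the cascade.
* **Mean distance** (`predict_mean_distance()`): each sample is
  classified exactly once, by the submodel with the nearest centroid
  (Euclidean, scaled space; equidistant centroids resolve to the lowest
  index). This is k times cheaper at prediction time and empirically
  trades sensitivity for specificity.

For k = 1 the two rules coincide. Models serialize with
`save_ensemble()` / `load_ensemble()` (scaling, selected features,
hyperparameters, centroids, schema version) and predictions survive the
round-trip bit-for-bit.

## Evaluation

`compute_metrics()` reports SE = 100·TP/(TP+FN), SP = 100·TN/(TN+FP),
Acc, and Gm = √(SE·SP). `outer_3fold_cv()` runs stratified 3-fold
cross-validation: per-class fold sizes differ by at most one, the full
pipeline (selection, scaling, partitioning, tuning, training) is refitted
on each training split, and the final report is the arithmetic mean of
the three fold reports — fold-level averaging, not pooled confusion
matrices, matching the convention of averaging the three test results.

## The synthetic generators

No public miRNA database is bundled; the generators create data with
*known ground truth* so every pipeline stage is testable:

* `make_hairpin()` builds positives: a GC-biased stem (default 30–55 bp)
  with optional 5'-side bulges, a terminal loop (4–8 nt), short flanks.
  The letter layout is deliberate: purines (G/A) on the 5' arm,
  complementary pyrimidines (C/U) on the 3' arm, all-C loop, A/C flanks.
  Under the additive energy model every legal base pair then runs from
  the 5' half to the 3' half of the molecule, so all pairs are mutually
  nested and *every* legal structure — the MFE structure in particular —
  has exactly one hairpin loop. The single-loop property of generated
  positives is thus a theorem of the construction, not a statistical
  tendency.
* `make_pseudo()` builds negatives: with probability 0.84, two or three
  short stem-loops concatenated with unpairable spacers (folding with
  n_loops ≥ 2); otherwise a uniform random sequence. Lengths target the
  70–150 nt candidate window.
* `make_dataset()` combines them at a configurable imbalance, default
  7.79:1.
* `make_separable_table()` skips sequences entirely and emits a feature
  table with class-shifted informative columns (shift = 3 within-class
  standard deviations by default) plus pure-noise columns — the test bed
  for selection and the ensemble, where a correct pipeline must recover
  Gm ≥ 95% under outer 3-fold cross-validation.

What the generators do **not** emulate: real miRBase/Rfam sequence
statistics, stacking thermodynamics, conservation, or the sequence
redundancy structure of curated databases. A green test suite therefore
demonstrates that the pipeline mechanics (feature arithmetic, imbalance
handling, multi-loop discrimination) are correct, not that the shipped
defaults reach any particular accuracy on biological data — for that,
train on curated sequences through the same interface.

A small demonstration: multi-loop features dominate the ranking on
generated data, because the generator's negatives are mostly
multi-branched.

```{r demo, eval = FALSE}
ds <- make_dataset(n_pos = 8, ratio = 3, seed = 42)
fm <- extract_features(ds$records, labels = ds$labels,
                       n_shuffles = 25, seed = 42)
rank_and_select(fm, m = 10)
#> <fscore_ranking> 65 features, top 10 selected (n+=8, n-=24)
#>   dP/n_loops         F = 61.02
#>   MFEI_3             F = 42.12
#>   %(G-C)/n_loops     F = 9.94
#>   dS                 F = 3.788
#>   dH                 F = 3.6
```

## Problem sizes and numerical choices, in one place

* Folding oracle tests: a few hundred random sequences of length ≤ 20,
  checked against exhaustive structure enumeration (MFE exactly, Z and
  base-pair probabilities to 1e−9 relative).
* Shuffle tests: ~1200 shuffles across random inputs; dinucleotide count
  multisets must match exactly.
* F-score oracle: 130 random small matrices against a literal
  brute-force transcription of the formula (1e−12 relative).
* End-to-end: 60 positives + 467 negatives (7.79:1), 65 columns of which
  10 informative, outer 3-fold CV with k = 3 and m = 32.
* Seeds: every stochastic stage (shuffles, fixtures, fold assignment,
  inner CV) takes an explicit integer seed; derived streams keep all
  seeds below 2³¹.
* Tie-breaks are all deterministic and documented: DP traceback (pair,
  then smallest partner), grid search (first grid point), vote cascade
  (latter half, then last submodel), dispatch (lowest submodel index),
  feature ranking (canonical order).

## Known limitations

* The additive energy model reproduces topology-driven signals well but
  not real folding energetics; absolute MFE/EFE values are not comparable
  to thermodynamic folders, and MFE-z-scores are weaker discriminators
  than under stacking models because composition alone fixes much of the
  attainable pairing.
* dH/dS/Tm are engine-internal estimates (WC stack enthalpies plus a
  generic wobble term), not melting predictions.
* No conservation, homology or expression features; no genome scanning —
  inputs are candidate hairpins, not chromosomes.
* Probability calibration, one-class variants and synthetic oversampling
  are out of scope; the ensemble is the imbalance mechanism.
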