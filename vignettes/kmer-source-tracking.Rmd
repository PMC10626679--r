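---
title: "Methods: k-mer-matrix microbial source tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer-matrix microbial source tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmst)
```

## The problem and the model

Microbial source tracking (MST) asks: given a metagenomic sample of
unknown or doubtful provenance (the *sink*), what proportion of it comes
from each of a set of candidate *source* environments? In ancient oral
metagenomics this is the contamination question — a dental-calculus
sample is realistically a mixture of ancient oral, modern oral, skin and
sediment/soil DNA — and reference-database approaches struggle because
much ancient diversity is absent from taxonomy databases.

`kmst` is reference-free. Each sample is reduced to the *set* of its
canonical 31-mers (lexicographic minimum of a k-mer and its reverse
complement, making counting strand-insensitive), with two filters:

* **within-sample abundance**: k-mers seen only once in a sample are
  discarded as likely sequencing errors (`min_abundance = 2`);
* **cross-sample recurrence**: k-mers present in fewer than
  `min_recurrence = 3` samples of the collection are dropped — a k-mer
  seen in one sample only cannot help discriminate environments.

The sources form a binary matrix $M \in \{0,1\}^{K \times (L-1)}$ and
their labels, drawn from the ordered class set
$C = \{\mathrm{aOral}, \mathrm{mOral}, \mathrm{skin},
\mathrm{sediment/soil}\}$, are one-hot encoded as
$H \in \{0,1\}^{(L-1)\times|C|}$ with $H_{ij} = 1$ iff sample $i$ has
label $c_j$. A sink with presence vector $\mathbf m$ is scored by

$$\mathbf w = \mathbf m^\top M H,$$

which is exactly ball-and-bin counting: each (k-mer, source) pair
present in both sink and source adds one ball to the bin of the source's
environment. Proportions are $\mathbf p' = \mathbf w / \sum_i w_i$ and
sum to 1 whenever at least one ball was counted. The hard label is the
argmax of $\mathbf p'$.

The estimator is deliberately linear in the source columns: duplicating
a source doubles its class's ball count. Estimated proportions therefore
reflect *shared k-mer mass*, weighted by how many sources of each class
carry each k-mer — not read mass — and should be read as a ranking-and-
dominance signal, not a calibrated mixture weight. Accordingly the
package's simulation-based checks assert argmax and rank recovery, not
exact weight recovery, mirroring how such methods are validated on real
collections (by hard-label prediction against metadata).

## Numerical and edge-case choices

* **Ties**: if the maximal proportion is attained by several classes the
  earliest one in the class order wins and the result carries
  `tie = TRUE`. A fixed, documented tie rule keeps evaluation
  deterministic.
* **No shared k-mers** ($\sum w = 0$): proportions are undefined. The
  result is labelled `"unassigned"` with a `kmst_no_match_warning`
  rather than crashing or inventing a label; evaluation counts
  `"unassigned"` as wrong for every class, and curves give such sinks
  score 0 everywhere.
* **Unknown fraction**: the share of sink k-mers present in no source.
  It is reported as a separate column and *not* folded into the
  normalization: ball counts live on the (k-mer × source)-pair scale
  while unmatched k-mers live on the k-mer scale, so mixing them would
  make the known-class proportions depend on an incomparable quantity.
* **Partitions**: full k-mer matrices are enormous, so rows are
  subsampled to one of `num_partitions = 700` disjoint partitions — the
  partition of a k-mer being a salted 64-bit FNV-1a hash of its string
  modulo the partition count. A hash reproduces the "random subset of
  rows" contract deterministically and independently of any sample.
  When a matrix was built on one partition, `run_mst()` filters the
  sink's k-mers to that same partition, so the unknown fraction's
  numerator and denominator refer to the same random subsample of k-mer
  space and remain an unbiased estimate of the genome-wide fraction.
* **Ambiguous bases**: any k-mer window containing a non-ACGT character
  is skipped; IUPAC codes are not expanded. Sequences are uppercased on
  input.
* **Empty columns**: a sample whose k-mers are all filtered away stays
  in the matrix as an all-zero column (with a warning) — dropping
  samples silently would corrupt the evaluation designs.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 31 bases | k-mer length; odd, so no k-mer is its own reverse complement |
| `min_abundance` | 2 | within-sample count needed for presence |
| `min_recurrence` | 3 samples | cross-sample recurrence filter on matrix rows |
| `num_partitions` | 700 | disjoint hash partitions of the row space |
| `selected_partition` | 0 (`"all"` to disable) | which partition the matrix keeps |
| `class_order` | aOral, mOral, skin, sediment/soil | output order and tie-break priority |
| mono-source threshold | 0.75 | strict lower bound on the top proportion |

Toy collections in the examples and tests use `min_recurrence = 2` and
`selected_partition = "all"` because they contain only a handful of
samples; defaults suit real-scale collections.

## The evaluation harness

*Leave-one-out*: each sample in turn is the sink; its column is removed
from the sources and its row from the one-hot matrix. *Group-stratified
cross-validation*: samples are split into 5 folds such that no group
(BioProject) spans two folds — group non-overlap is an exact constraint,
never approximate — because sinks from the same sequencing initiative as
their sources look artificially easy. Within that constraint a greedy
heuristic assigns groups (largest first, ties shuffled by the seed) to
the fold where the resulting per-class counts deviate least, in squared
error, from equal counts across folds. This objective was chosen over
minimizing per-fold proportion deviation alone, which degenerates: once
a fold approximates the global class proportions it attracts every
remaining group, collapsing the split into one giant fold. Penalizing
count spread across folds balances fold sizes and class composition
simultaneously (the same idea as scikit-learn's `StratifiedGroupKFold`).

Metrics follow the multi-class convention: accuracy is the global
fraction correct; precision, recall and F1 are computed per class
one-vs-rest and macro-averaged over classes present in the truth, with
precision defined as 0 (plus a warning) for classes never predicted.
Balanced accuracy (mean per-class recall) is reported alongside since
"averaged across classes" is ambiguous for accuracy. ROC and PR curves
are one-vs-rest on the estimated proportions, with a 101-point
fixed-FPR-grid macro ROC; the AUC of the sweep is cross-checked against
`pROC` in the test suite.

## What the synthetic generator emulates — and what it does not

`sim_config()` / `generate_collection()` build labelled collections with
the statistical structure the method actually exploits:

* each environment has a pan-genome *pool* of i.i.d. random DNA
  (`pool_length`, default 100 kb — a deliberately condensed stand-in
  for the gigabases of a real pan-genome);
* related environments share contiguous blocks of their pools
  (`overlap`, default 10% between adjacent classes), emulating shared
  taxa between e.g. modern oral and skin communities;
* every sample draws a random contiguous subset
  (`sample_subset_fraction = 0.8`) of its pool, so same-environment
  samples overlap strongly but not perfectly;
* reads (100 bp) are sampled uniformly to `coverage = 5`× of the drawn
  subset with per-base substitution errors at `error_rate = 0.005`, and
  samples are assigned round-robin to pseudo-BioProject groups;
* mixture sinks draw reads from several pools with specified weights —
  the ground truth the estimator is checked against.

The generator does **not** emulate realistic taxonomic abundance
profiles, ancient-DNA damage (C→T deamination) or fragment-length
distributions, host contamination, or indel errors. Deamination and
fragmentation alter which k-mers survive the abundance filter but not
the presence/absence logic itself, so they are out of scope here. A
passing suite therefore demonstrates the correctness of the counting,
normalization, classification and evaluation machinery and the
method's qualitative behaviour (label recovery, rank recovery,
overlap-driven cross-talk) — it does not certify performance numbers on
real ancient metagenomes.

## Problem sizes in the shipped tests

The suite runs the full pipeline (simulate → extract → build → evaluate)
on condensed instances chosen to exercise every code path in seconds:
pools of 8–20 kb, 2–10 samples per environment, coverage 4, and 20
seeds for the mixture rank-recovery check (0.7/0.3 aOral/skin sinks
against balanced sources). Counting correctness is established
separately against a brute-force triple-loop oracle on hundreds of
random binary instances up to 200 k-mers × 30 sources, where exact
equality — not approximation — is asserted.

## Known limitations

* Proportions are not calibrated mixture weights (see above); use them
  for ranking, dominance (the strict 75% mono-source rule) and
  hard-label prediction.
* The recurrence filter is applied to the source collection only; a
  pipeline that rebuilds the matrix jointly over sources *and* sinks
  would admit rows recurring only thanks to sink samples. For
  presence/absence scoring over a shared row index the difference is
  the set of rows, not the counting rule.
* Unbalanced source collections bias ball counts toward the
  over-represented class, since the estimator is linear in source
  columns; balance the collection or interpret proportions accordingly.
* All k-mers are equally weighted; no attempt is made to down-weight
  low-complexity or conserved sequence.
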