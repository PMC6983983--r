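---
title: "Methods: sequential blocks, location features, and family classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential blocks, location features, and family classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboblock)
```

## The model

Riboswitch families conserve short sequence motifs at nearly fixed
positions. `riboblock` operationalises that observation as a two-part
definition of a *sequential block* for a family of un-gapped sequences:

- **prevalence**: the motif is present in at least a fraction θ of the
  family's members, and
- **positional coherence**: among those members, its 1-based
  first-occurrence location falls within ±w nucleotides of the modal
  first-occurrence location.

Block discovery (`find_blocks()`) is exhaustive rather than heuristic:
every distinct substring of length 3–8 nt occurring in any member is a
candidate (`candidate_motifs()`), each candidate's first-occurrence
location is recorded per member, and candidates failing the
prevalence-at-location test are discarded (`filter_blocks()`). Finally a
motif that is a substring of a longer surviving motif with an overlapping
placement (canonical locations within the longer motif's length) is
removed (`eliminate_redundant()`): it cannot distinguish anything the
longer block does not already distinguish.

Feature extraction (`extract_features()`) maps a sequence to an integer
vector over a fixed block order: entry *i* is the first-occurrence location
of block *i*, or 0 when absent. The location 0 is a deliberate sentinel —
"absent" is itself discriminative, since a family member typically contains
its own family's blocks and lacks most other families' blocks.

### Conventions

- **First occurrence defines location.** A motif that recurs later in the
  sequence is still scored at its first occurrence. In the packaged 129-nt
  worked example, `GGG` occurs at 12, 13 and elsewhere; its feature value
  is 12.
- **1-based coordinates** throughout, matching how the reference block
  locations are tabulated.
- **Modal location, ties toward the smallest.** The canonical location of
  a block is the mode of its per-member first occurrences; when two
  locations are equally frequent the smaller one is chosen, which makes
  discovery invariant to member order.
- The worked example's published observation vector lists the `GGAUG`
  entry as 113, but the motif's first occurrence under the convention that
  the other four non-zero entries (27, 59, 12, 12) all satisfy is 112; the
  package reports 112 and treats the published 113 as an off-by-one.
- Ambiguous IUPAC codes (N, R, Y, …) are rejected on input rather than
  expanded or skipped: the motif search is exact, and silently matching an
  N against anything would inflate prevalences unpredictably.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_len`, `max_len` | 3, 8 nt | candidate motif lengths; the 22-block reference set spans exactly 3–8 nt, and 4^3 = 64 makes shorter motifs near-ubiquitous |
| `prevalence_threshold` | 0.7 | minimum fraction of members carrying the motif near its modal location; "very high prevalence" is not quantified in the source material, so a value safely above chance co-occurrence was fixed once |
| `location_window` | 5 nt | allowed deviation w from the modal start; of the same order as the positional jitter visible in curated family alignments |
| `v` | 10 folds | cross-validation; a standard compromise between bias and cost |
| `k` | 4 | KNN neighbourhood size, the reported optimum |
| `sigma` | 1.0 | PNN Gaussian bandwidth, in standardized feature units |
| `shrinkage` | 10⁻³ | LDA pooled-covariance ridge weight |
| `min_leaf` | 5 | decision-tree minimum leaf size |

Threshold and window are reported in the `sbf_config` attribute of every
block set so results are traceable to their settings.

## Classifiers

The four classifiers deliberately span model families: a linear Gaussian
discriminant, a non-parametric kernel density rule, an axis-aligned
partition, and an instance-based rule.

- **LDA**: class means with a pooled within-class covariance S, shrunk as
  S' = (1−λ)S + λ·(tr S/p)·I, assignment to the largest linear
  discriminant score with equal priors. When the within-class scatter is
  exactly zero (perfectly separated, jitter-free toy data) the ridge
  target tr S/p vanishes; the implementation falls back to the identity
  scale so the system stays solvable.
- **PNN**: Parzen-window class-conditional densities with an isotropic
  Gaussian kernel; the class posterior follows Bayes' rule with priors
  proportional to training counts, under which the posterior is simply
  each class's kernel sum over the pooled training set. Kernel exponents
  are shifted by the per-query minimum squared distance before
  exponentiation, so the computation stays finite for small bandwidths and
  degenerates exactly to 1-NN as σ → 0⁺ (a property the tests exercise
  against the KNN implementation).
- **Decision tree**: greedy binary splits minimising Gini impurity with a
  minimum leaf size, via `rpart` with surrogate and competitor search
  disabled; raw (unstandardized) features, since axis-aligned splits are
  scale-invariant.
- **KNN**: Euclidean distance, k = 4. Distance ties are resolved by
  training-set order (stable sort); vote ties are resolved by the class of
  the nearest neighbour among the tied classes. Both rules make the
  classifier fully deterministic.

Features are standardized per column — mean and standard deviation
estimated on the training folds only, zero-variance columns left unscaled —
for LDA, PNN and KNN, because block locations span 0–200+ nucleotides and
distance-based rules are scale-sensitive.

Fold assignment is stratified by family: members of each family are
shuffled and dealt cyclically, so fold sizes differ by at most one overall
and within every family. Stratification keeps the 40-member families
present in every training split; without it a 10-fold partition of 808
observations could plausibly concentrate a small family in few folds.

## Two CCR variants

The correct classification rate is reported both as the mean of per-fold
CCRs and as the pooled trace/total of the accumulated confusion matrix.
With near-equal fold sizes the two rarely differ by much, but they are not
identical, and the published riboswitch figures are internally consistent
only under a mixture of the two: the published LDA (80.94%) and KNN
(88.86%) CCRs equal trace/total of their published matrices exactly,
whereas the published PNN (92.31%) and decision-tree (89.37%) CCRs do not
(92.33% and 87.75% from their matrices). `paper_check()` reports all four
comparisons rather than hiding the two that disagree.

Macro averages are unweighted means of per-class measures over the seven
families, computed at full precision. This choice reproduces the published
PNN macro accuracy (96.1%) exactly. One published macro figure (PNN macro
sensitivity, 83.61%) is instead the mean of the already-rounded per-class
percentages; at full precision it is 83.60%. The difference is reported,
not asserted away.

The published per-class TP/FP/TN/FN rows are used verbatim by the packaged
fixtures instead of being re-derived from the 7×7 count matrices: the
published per-class denominators (e.g. 782 rather than 808 for LDA/glycine)
demonstrably follow those rows.

## The synthetic generator

`generate_family()` emulates exactly the structure the block definition
assumes: sequence lengths drawn from a rounded normal (clamped so every
planted motif fits), an i.i.d. uniform background over {A, C, G, U}, and
each planted motif written at its canonical location plus a uniform integer
jitter in [−j, +j] with probability p, overwriting the background.

The `table1_presets()` benchmark mirrors the seven riboswitch families'
member counts (47, 430, 44, 40, 40, 155, 52 — 808 in total) and length
means/variances (183/11.06, 203/15.54, 101/15.99, 79/1.18, 116/4.13, 87/6,
85/15.4). Each preset family plants two invented 8-mers at staggered
locations with prevalence 0.95 and jitter 2. Two deliberate departures
from the real reference blocks:

- **Planted motifs are 8-mers, not the published 3–8-mers.** Under a
  uniform background a specific 3-mer occurs by chance once per ~64
  positions, so a short motif planted late (say at position 77) is almost
  always preceded by a chance occurrence, which moves its first-occurrence
  location away from the plant site and makes the planted location
  unrecoverable *by construction*. Real riboswitch composition is biased
  and the real short blocks presumably survive for that reason; uniform
  background plus long motifs gives the recovery tests a well-defined
  ground truth.
- **Uniform background, no secondary structure.** Real families share
  covarying paired regions and composition bias. Passing the benchmark
  therefore shows that the pipeline recovers location-coherent motifs and
  separates families whose members carry them — it does not show
  performance on real Rfam seeds, which additionally contain correlated
  conservation the generator does not emulate.

Problem sizes used by the test suite — the full 808-sequence benchmark for
recovery and cross-validation, 10-member families of 50-nt sequences for
brute-force oracle comparisons, 20 replicate seeds of 60 noise observations
for the chance-level check — were chosen so the whole suite exercises every
code path at realistic scale while remaining quick to run routinely.

## Known limitations

- Discovery cost grows with family size times sequence length times the
  motif-length range (exhaustive enumeration); it is comfortably fast for
  riboswitch-scale inputs (hundreds of members, ~200 nt) but is not
  designed for genome-scale sequences.
- A motif more prevalent at a *secondary* location than at its modal one is
  evaluated only at the mode; multi-modal blocks are out of scope.
- Blocks are exact substrings: no degenerate alphabets, no gapped or
  structure-aware motifs.
- Reproducing the published 22-block reference set from live Rfam seed data
  depends on an external download and on unpublished discovery settings;
  the set is shipped as data, and the discovery algorithm is validated on
  synthetic ground truth instead.
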