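---
title: "Phyloclassification from tRNA class-informative features"
author: "tRNAcif authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phyloclassification from tRNA class-informative features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tRNAcif)
```

## The method

Most genomes maintain a nearly complete tRNA gene complement — roughly
30 to 55 genes spanning 22 functional classes (the 20 elongator
isoacceptor classes named by amino-acid one-letter code, the initiator
class "X", and the CAU-anticodon isoleucine class "J").  Because tRNAs
must thread the same ribosome, their structures correspond
position-by-position across classes, and the standard Sprinzl coordinate
system makes those positions comparable across genes, genomes and
lineages.  Within a clade, particular bases at particular Sprinzl
coordinates are informative about a tRNA's functional class; these
class-informative features (CIFs) drift between lineages, so the *map*
from structural features to functional classes carries phylogenetic
signal even when nucleotide compositions converge or genomes shrink.
This package estimates that map per clade as a *function logo*, scores
whole tRNA gene complements against the logos of candidate clades, and
trains a small neural network to classify genomes — "phyloclassification"
without tree inference, orthology assignment or alignment of
protein-coding markers.

### Function logos and Gorodkin heights

For a clade $X$ with pooled gene set $T_X$, every feature $f = (b, c)$
(base $b \in \{A,C,G,U\}$ at Sprinzl coordinate $c$; gaps and ambiguity
codes never carry features) has a class-conditional distribution
$p(i \mid f)$ estimated from the $n_f$ genes carrying $f$, and a class
background $q$.  The feature's information is the corrected
Kullback–Leibler divergence

$$D_{f,X} = \max\Big(0,\ \sum_i p(i \mid f)\,
\log_2 \frac{p(i \mid f)}{q(i)} \;-\; e(n_f)\Big),$$

apportioned over classes by background-normalized odds (Gorodkin
heights):

$$h^i_{f,X} = D_{f,X}\,
\frac{p(i \mid f)/q(i)}{\sum_j p(j \mid f)/q(j)}.$$

Heights are non-negative and stack to $D_{f,X}$; features carried by no
gene in the clade are implicitly zero.

**Background.**  The default background is the clade's own class
frequencies (the fraction of genes of each class in $T_X$), with uniform
and pooled-over-clades alternatives.  A clade-aware background keeps a
logo's heights interpretable as *within-clade* class information rather
than as repertoire composition.

**Sample-size correction.**  The plug-in divergence is biased upward by
roughly $(K - 1)/(2 n_f \ln 2)$ bits, where $K$ is the number of
background-supported classes.  The default `miller_madow` correction
subtracts exactly this term, with $K$ taken from the background support
— the alphabet-size convention of classical sequence-logo small-sample
corrections.  This choice matters more than it may appear: the
leave-one-out logos used for training (below) are estimated from one
genome fewer than full-data logos, and a correction that scales
incorrectly with $n_f$ (for instance, one using the *observed* class
support, which saturates at small $n_f$) leaves a systematic residual
that marks each genome's own clade column.  On signal-free synthetic
data that residual alone drives leave-one-out accuracy to 1.0; with the
background-support correction the same pipeline sits at chance.  The
`exact_small_n` option replaces the asymptotic term by the exact
expected plug-in divergence under multinomial sampling from $q$
(computable through binomial marginals) for $n_f \le 8$.  Because
$D_{f,X}$ is clamped at zero, a small upward residual remains at very
small clade sizes even under exact correction; the calibrated
permutation scheme below accounts for it.

### Genome scoring

A genome $g$ with complement $T_g$ receives one score per clade,

$$S_g^X = \frac{1}{\lvert T_g \rvert} \sum_{t \in T_g} \sum_{f \in t}
h^{i_t}_{f,X},$$

the average over genes of the summed heights of the gene's features
taken at the gene's own class $i_t$ — bits per gene.  Features, classes
or coordinates absent from a logo contribute zero, so reduced organellar
complements score without special handling.  Training score vectors are
built *leakage-free*: genome $g$ is scored against logos re-estimated
from $T_X - T_g$, so no vector contains information contributed by its
own genes.  Only $g$'s own clade's logo changes under this removal; the
implementation exploits that by caching per-genome count arrays and
re-estimating a single clade per genome.  Score vectors are standardized
by the training means and per-clade standard deviations; zero-variance
columns divide by one (becoming identically zero) with a warning.

### The phyloclassifier

The classifier is a multilayer perceptron on standardized score
vectors: ReLU hidden layers, softmax output, cross-entropy loss with an
L2 penalty of 0.01 on the weights, optimized full-batch by L-BFGS for
at most 2000 iterations with early stopping once the per-iteration loss
decrease falls below $10^{-4}$ (the optimizer's successive-reduction
control; under a full-batch quasi-Newton contract there is no epoch
shuffling, so the stopping rule attaches to optimizer iterations).  The
random seed governs weight initialization only, making training
bit-reproducible.  The default architecture is a single hidden layer of
13 nodes; `searchArchitecture()` evaluates all width combinations over
a bounded grid (by default 1–4 layers, 8–16 nodes per layer) by
leave-one-out cross-validated accuracy, breaking ties toward fewer
parameters, then fewer layers.  The input and output dimensions equal
the number of retained clades — nothing is specific to any particular
clade count.

A classification is *equivocal* when its maximum probability falls
below 0.80 (configurable); equivocal calls are interpreted as
"none-of-the-above", the expected behavior when a query's true clade is
not represented in the model.

### Robustness battery

* **LOOCV** (`loocvAccuracy()`): each genome is scored against logos
  estimated without its genes, and the standardizer and network are
  refit on the remaining genomes' vectors within every fold.
* **Permutation null** (`permutationTest()`): the p-value is the
  positively biased estimator $(b+1)/(B+1)$.  Two schemes are provided.
  `score_labels` permutes clade labels over cached score vectors — the
  cheap, classical description of the test.  It ignores, however, that
  the leave-one-out score vectors themselves depend on the clade
  assignment; close to the null the residual estimation artifact
  described above then makes the test anti-conservative.
  `full_pipeline` permutes the genome-to-clade assignment and rebuilds
  the score matrix per replicate, making null replicates exactly
  exchangeable with the observed statistic.  Calibration studies in the
  package's tests use `full_pipeline`.
* **Site bootstrap** (`siteBootstrap()`): alignment columns are
  resampled with replacement to the original count — the same column
  multiset for training and queries, features moving with their
  coordinate identity — and the whole pipeline (logo estimation,
  standardizer, network, classification) is re-run per replicate.
  Training genomes are classified through their leave-one-out vectors.
* **Leave-clade-out** (`leaveCladeOutVariant()`): one clade's genomes
  become queries; the model's dimensions shrink so the excluded label
  cannot be predicted, and reports carry equivocality flags.
* **Oversampling balance** (`oversampleBalance()`): score vectors are
  resampled with replacement within each clade up to the best-sampled
  clade's size, originals always retained.  `loocvFromScores()` offers
  two balanced modes: `"fold"` balances inside each training fold and
  is leakage-free; `"pre"` balances the whole vector set once and
  cross-validates over the balanced set, duplicates included.  The
  `"pre"` mode reproduces the workflow behind published balanced-model
  summary tables (per-clade sample sizes equal to the largest clade);
  because duplicated vectors share information across folds, its
  metrics describe the balanced training set, not generalization — the
  vignette flags this deliberately, and comparisons between unbalanced
  and balanced metrics should be read in that light.
* **Confusion metrics** (`confusionMetrics()`): one-vs-all precision,
  recall and balanced accuracy per clade, with zero denominators
  reported as zero.

## The synthetic data generator

`generateDataset()` draws K clades of genomes with 30–55 genes per
genome (defaults) over 72 coordinates.  Each gene starts as uniform
random bases with a small gap rate (default 0.02), then shared
class-identity determinants (default 5 per class, common to all clades
— emulating universal tRNA identity elements) and clade-specific
planted determinants (default 20 per clade, disjoint across clades at
the (class, coordinate) level — the ground-truth CIFs) overwrite the
background with probability `signal`.  At `signal = 1` and gap rate 0
every planted determinant is exactly recoverable; at `signal = 0`
clades are statistically exchangeable and base composition is uniform.
`generateNovelCladeQueries()` draws genomes from a (K+1)-th clade whose
determinants never occur in training, for none-of-the-above
experiments.

What the generator does *not* emulate: secondary-structure covariation
between paired positions, tree-structured (phylogenetically correlated)
divergence between clades, compositional (G+C) drift across lineages,
and asymmetric between-clade similarity.  Passing tests on synthetic
data therefore demonstrate the estimation, scoring, training and
resampling machinery under a controlled signal model — not performance
on real tRNA gene complements, where signal strength and clade
relatedness are outside the package's control.

## Study conditions used by the validation suites

The test suite and `scripts/acceptance.R` run these studies (sizes
chosen to exercise each property at desk scale; the conditions are part
of the study design, stated here once):

* **Benchmark recovery**: 8 clades × 25 genomes × 40 genes, 20 planted
  features per clade, signal 0.9 — LOOCV accuracy is expected ≥ 0.95,
  and label permutation collapses it to the chance level 1/8.
* **Leave-clade-out**: four excluded-clade variants of the benchmark,
  pooled — excluded genomes' mean top probability sits well below
  in-model genomes' (gap ≥ 0.15), supporting the none-of-the-above
  reading of equivocal calls.
* **Permutation calibration**: 20 signal-free datasets (3 clades × 6
  genomes × 20 genes), B = 200 full-pipeline replicates each — p > 0.05
  in at least 18 of 20; a high-signal dataset (4 clades × 8 genomes)
  reaches the smallest attainable p, $1/(B+1)$.
* **Bootstrap consistency**: 100 site-bootstrap replicates on a
  high-signal design (4 clades × 10 genomes) — every genome's true
  clade recovered in ≥ 95 of 100 replicates.
* **Balancing**: imbalanced designs (clade sizes 30/27/11/5, 15–25
  genes per genome, signal 0.85, chosen so the unbalanced model makes
  minority-clade errors) — the pre-balanced workflow lifts
  minority-clade recall relative to unbalanced training in at least 8
  of 10 dataset seeds.

## Numerical and interface choices

* All sequence input is normalized to RNA (T to U, case-folded);
  IUPAC ambiguity codes become gaps because features are defined only
  over A/C/G/U.
* The gap-pruning threshold is inclusive ("99% or more gaps" removes a
  column at exactly 99%).
* Clades whose pooled gene count falls below `minGeneCount` (default
  120) are excluded from partitions and reported, and clade fusion is
  expressed through map aliases (e.g. B2 and B3 to "B2+3").  The
  synthetic generator emits clade maps with `minGeneCount = 1`, since
  synthetic designs control their own sizes.
* CAU-anticodon genes cannot be discriminated into elongator-Met,
  initiator or Ile-CAU from the anticodon; explicit labels are the
  supported path, with a configurable fallback class.
* Coordinate labels are opaque strings; insertion codes such as "20a"
  sort by input order.
* Exact probability ties in classification break toward the first clade
  in clade order and are logged.
* Architecture-search ties break toward fewest parameters, then fewest
  layers, for reproducibility.
* Leave-one-out score vectors are cached per genome and reused across
  folds and architecture candidates; within every bootstrap replicate
  the standardizer and network are refit from scratch.

## Limitations

* The leave-one-out scoring construction carries a small residual
  own-clade bias at very small clade sizes (few genomes per clade);
  the background-support correction removes its leading order and the
  full-pipeline permutation scheme is exact in its presence, but
  comparisons of raw score magnitudes across clades of very different
  sizes should be avoided.
* Balanced-model summary metrics from the `"pre"` workflow are
  training-set descriptions (see above).
* The permutation estimator $(b+1)/(B+1)$ cannot fall below
  $1/(B+1)$; significance claims are bounded by the replicate budget.
* Features are single bases; paired (covarying) features are out of
  scope.
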