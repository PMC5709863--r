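---
title: "Decision-tree decontamination: models, parameters and validation design"
author: "decontree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-tree decontamination: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A de novo eukaryotic genome assembly is rarely a single organism. Sequenced
DNA from microbiota, reagent contaminants and symbionts co-assembles with
the target into scaffolds of mixed origin, and database searches can only
label the subset of scaffolds with close relatives in public databases.
`decontree` treats post-assembly decontamination as supervised
classification: every scaffold is described by eight measurable predictors,
a classifier is trained on the scaffolds BLAST can label, and every
scaffold — including those with no database hit — is then classified as
target or contaminant.

The eight predictors are scaffold length (bp), scaffold GC fraction, and,
for a genomic (DNA) and a transcriptomic (RNA) read library aligned to the
assembly: mean per-base depth, breadth of coverage (fraction of positions
with depth at least 1) and the GC fraction of aligned read bases. They
capture complementary signals: depth separates organisms sequenced at
different abundance; GC separates compositionally distinct genomes; RNA
breadth is a proxy for gene density, which differs sharply between compact
microbial or fungal genomes and intron-rich metazoan ones; aligned-read GC
is a composition signal robust to assembly artifacts in the scaffold
sequence itself.

## Models

### Single classification tree

Trees are binary CART trees over numeric predictors. Node impurity is
either the Gini diversity index $G = \sum_i p_i (1 - p_i)$ (default) or the
Shannon entropy $H(S) = -\sum_{x \in X} p_x \log_2 p_x$; split quality is
the $n$-weighted child impurity (equivalently, for entropy, the information
gain $IG(A,S) = H(S) - \sum_{t} p(t) H(t)$). The search is exhaustive:
every candidate predictor, every threshold midway between consecutive
distinct sorted values. Leaves store class proportions, used as posterior
probabilities $\hat P(k\,|\,x)$; prediction returns
$\hat y = \arg\min_y \sum_k \hat P(k\,|\,x)\, C(y\,|\,k)$ for a
misclassification cost matrix $C$, which under the default uniform costs is
the majority class.

Numerical conventions, all of which the tests pin down:

* Values equal to a threshold route to the left ($\le$) child.
* Split ties are broken by the lower canonical predictor index
  (`length`, `gc`, `dna_mean_depth`, `rna_mean_depth`, `dna_breadth`,
  `rna_breadth`, `dna_read_gc`, `rna_read_gc`), then by the lower
  threshold; a competing candidate must be better by more than $10^{-12}$
  to displace an earlier one.
* Posterior ties at prediction go to the target class (class 1).
* Growth stops at purity, at `minLeaf` (default 1), or when a whole-tree
  split budget `maxSplits` (counted breadth-first; default unlimited) is
  exhausted. There is no pruning — variance is handled by aggregation, not
  by cost-complexity trimming.
* An impure node splits on its best valid candidate even when the
  immediate impurity decrease is zero. Greedy impurity improvement alone
  cannot enter an XOR-like interaction (every first split looks useless);
  accepting zero-gain splits lets deeper splits resolve it, and on
  continuous data such exact ties are vanishingly rare, so the choice has
  no practical cost. The exported `bestSplit()` keeps the strict
  contract — it returns nothing when no split improves impurity — and is
  verified against a brute-force enumeration oracle.

### Bagging and random forests

Bagging fits `B` (default 100) unpruned trees to bootstrap resamples of
the training rows and averages leaf posteriors:
$\hat f_{bag}(x) = \frac1B \sum_b \hat f^{*b}(x)$. A row is called target
when its averaged target posterior reaches the decision threshold
(default 0.5, ties to target — a sensitivity-favoring convention). The
number of bootstrap replicates is not prescribed by the method itself;
100 is the package default because the between-model variance reduction
this procedure exists for has plateaued well below that on the regimes the
test suite measures, and it is cheap.

The random forest variant draws a fresh uniform subset of `m` of the `p`
predictors at each split (the Breiman convention; a per-tree mode is
available behind a flag), with defaults `m = 4` and 5000 trees. When
`m = p` no drawing is performed at all, so a forest reproduces bagging
tree for tree at the same seed — the tests assert this identity.

Per-predictor Gini importance of a split is implemented as the
node-weighted impurity decrease
$(n_{node}/n_{root})\,[G_{parent} - (w_L G_L + w_R G_R)]$, summed over a
predictor's splits and averaged over trees (normalized to sum to 1). The
literal unweighted difference $G_{parent} - G_{1} - G_{2}$ is available
behind a flag for comparison; it can be negative, which makes it unusable
for ranking, and ranking is what importance is used for here.

### Boosted shallow trees

Boosting is residual regression on the 0/1 target indicator: starting from
the base rate $F_0 = \bar y$, each stage fits a regression tree with at
most `maxSplits = 2` splits (squared-error splitting) to the residuals
$y - F(x)$ and adds `shrinkage` (default 0.01) times its prediction; the
target score is $F$ clipped to $[0,1]$, with 10 stages by default. Plain
residual refitting was chosen over gradient boosting on a surrogate loss
because the procedure is defined by its residual recursion, not by a
stated loss function. With the default small shrinkage the boosted model
is deliberately weak; it is included for completeness of the model family,
while bagging is the working default throughout the pipeline.

## Labels, splits and evaluation

BLAST tabular results (outfmt 6, optionally with an appended subject-taxon
column) are reduced to the single best hit per scaffold: maximal bitscore,
ties by minimal e-value, then input order. The genus is the first
whitespace-delimited token of the subject taxon text, compared
case-insensitively against the target genus; curated overrides
(case-insensitive substring matches) take precedence, with contaminant
overrides beating target overrides, and a hit matching both lists is an
error rather than a silent choice. Scaffolds without hits are "unknown":
excluded from training and from every metric, but always classified.
Labels inherit whatever errors the database contains; no denoising is
attempted, and the synthetic generator can emulate such noise to measure
its effect.

Training sets are uniform random samples of the labeled scaffolds
(`round(fraction * n)` ids, without replacement). The split is not
class-stratified by default — the sampling is plain random — but a
stratified mode exists. Evaluation counts target scaffolds as positives:
sensitivity $TP/(TP+FN)$, specificity $TN/(TN+FP)$, error
$(FP+FN)/\text{total}$, accuracy $1 - $ error. A metric with an empty
denominator is `NA`, never a silent 0.

Two replicate experiments are provided. The training-fraction sweep
refits the model on fresh random splits across a grid of fractions
(default 1–99%) with `replicates` (default 100) draws per point. The
predictor-subset sweep ranks the eight predictors once — by the Gini
importance of a full bagged model on a seed-fixed 50% split — then
refits on the top-$k$ predictors for $k = 2..8$ (default 1000
replicates). Re-ranking per replicate would conflate ranking variance
with subset performance, so the ranking is fixed; an explicit
user-supplied ordering is accepted. Every replicate seed is derived from
the master seed by a documented counter scheme (`deriveSeed`), so any
single replicate can be reproduced in isolation. Replicates whose
training draw contains one class are recorded as failed and excluded
from the aggregates, with their count reported.

## The synthetic generator

The method consumes per-scaffold features, so the generator emulates the
joint distribution of those features directly instead of simulating reads
and re-assembling; a toy file bundle (FASTA with sequences built to the
drawn GC, alignment-summary TSVs, BLAST-style hits realizing the label
process, and a truth table) exercises the real parsers end to end.

Per scaffold: length is log-normal; GC is uniform on the class range;
DNA depth is gamma with a class mean and shape; RNA breadth is beta,
reflecting class gene density, with a small per-class probability of no
mRNA at all; DNA breadth saturates with depth
($1 - e^{-0.8\,d}$, jittered, and never exceeding mean depth so a
per-base depth vector can realize it); RNA depth is breadth times a gamma
local depth; read GC tracks scaffold GC with Gaussian noise (sd 0.01 DNA,
0.02 RNA).

Three presets encode the study regimes:

* **separable** — microbial contaminant: GC 0.50–0.69 at ~20x depth
  versus an AT-skewed target (GC 0.24–0.48) at ~100x, tight gamma shapes
  (8). GC and depth alone suffice; 3000 target / 1000 contaminant
  scaffolds by default.
* **overlapping** — fungal-like contaminant: GC 0.23–0.53 inside the
  target's 0.24–0.72, heavy-tailed depth (gamma shapes 1.0–1.2, means
  80 vs 100) so neither GC nor depth separates. The discriminative signal
  lives in the RNA predictors: contaminant RNA breadth Beta(18, 3.6)
  (mean 0.83 — a compact, gene-dense genome whose transcriptome at 10x
  leaves almost no scaffold untouched, so the no-mRNA probability is
  0.002) against target Beta(2.5, 9) (mean 0.22, no-mRNA probability
  0.02, matching the rarity of non-expressing scaffolds in real
  assemblies). 1000 + 1000 scaffolds by default.
* **empirical_like** — a nematode-like structure: contaminants are a
  7:3 mixture of low-coverage scaffolds of broad GC and
  moderate-coverage high-GC scaffolds.

The label simulator makes each scaffold unknown with probability
`unknownFraction` (preset default 0.1) and flips surviving labels with
probability `mislabelRate` (default 0), emulating database incompleteness
and database contamination respectively.

What the generator does not emulate: read-level error models, insert-size
and chimeric mate-pair artifacts, repeat-driven coverage spikes
(overdispersion here is smooth gamma), k-mer composition, or any
correlation between scaffold length and assembly quality. Passing tests
on these presets therefore demonstrate that the estimator recovers
class structure that is present in the features, not that the features
behave this way in any particular real assembly.

## Validation design and problem sizes

The test suite checks the mathematics against independent oracles
(direct-summation impurity formulas over all binary count vectors up to
n = 12 at $10^{-12}$; brute-force split enumeration on 200 random small
datasets) and reproduces the regime-level findings at desk scale: bagging's
between-model accuracy variance no larger than a single tree's (100 draws,
n = 1000, B = 100); at least 99% held-out accuracy with all eight
predictors on the overlapping regime versus at least 10% held-out error
for a tree restricted to GC + DNA depth on the same datasets (10 seeds,
n = 2000); at least 99.5% accuracy, sensitivity and specificity on the
separable regime (10 seeds, n = 4000); a flat accuracy plateau (within one
percentage point) for training fractions from 45% to 99% with 2% training
strictly worse (20 replicates, B = 25); and byte-identical serialized
models and reports for repeated seeded runs. `scripts/acceptance.R`
recomputes the three regime metrics from scratch. These sizes were chosen
so the entire suite exercises every claim in minutes on a single core
while keeping binomial noise on the asserted margins small.

## Known limitations

* Training labels come from BLAST; systematic database contamination
  biases both the model and the metrics, and only manual curation
  (override lists) counters it.
* Horizontally transferred sequence resembles its donor in composition;
  nothing in the feature set protects an HGT region beyond its coverage
  and expression looking host-like.
* Scaffolds are classified independently; no spatial or assembly-graph
  information is used.
* The pipeline reports the analogous decontamination summary for real
  data but makes no claim to reproduce any published assembly's numbers,
  which depend on the sequencing libraries and database versions used.
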