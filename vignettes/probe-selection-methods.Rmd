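---
title: "Gene-centric 450K probe selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-centric 450K probe selection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylsel)
```

## The problem and the model

An Illumina 450K array interrogates each gene with a handful to dozens of
CpG probes scattered across TSS200/TSS1500 promoter windows, the 5'UTR,
first exon, gene body and 3'UTR. Most of those probes are uninformative
for any given gene's expression; a few may carry strong regulatory
signal. `methylsel` treats the choice of probes as a supervised feature
selection problem: per gene, find the probe subset whose beta values best
predict the gene's expression *class*.

Expression is first discretized. In a paired design each sample provides
an expression ratio r (e.g. untreated over demethylating-agent-treated);
in an absolute design r is the sample's value over the per-gene median
across samples. With fold threshold t, a sample is labeled **up** when
r ≥ t, **down** when r ≤ 1/t, and **baseline** otherwise; baseline
samples are discarded and the remaining binary labels are the prediction
target. The down class is the positive class in every confusion-based
metric.

The core selector is a sequential forward selection (SFS) wrapper. Let
X be the gene's candidate probes and S the selected set (initially
empty). Each candidate is scored by the mean per-fold misclassification
count (CCE) of a classifier in a stratified 10-fold cross-validation;
the argmin candidate enters S unconditionally. Thereafter S ∪ {x} is
scored for every remaining candidate and the argmin is accepted only
while it *strictly* lowers the incumbent error (OCE); the first
non-improving round stops the search. Strict improvement means equal
error with more probes loses — the wrapper prefers the smaller set.

The wrapper's key assumption is that a greedy, univariate-start search
can find the informative subset. That holds when at least one single
probe carries signal; purely epistatic probe pairs (each useless alone)
defeat any forward selection, and no selector here claims otherwise.

## Classifiers and their parameters

* **KNN** (default, K = 1): Euclidean distance on beta values (which
  share the [0, 1] scale, so no standardization is applied). K is odd —
  1, 3 or 5 in practice. Distance ties are resolved by a stable sort on
  (distance, sample id) and a vote tie falls back to the single nearest
  neighbour's label, so predictions never depend on training-row order.
* **Decision tree**: Gini impurity via `rpart`, minimum parent size 10,
  minimum leaf size 1, no cost-complexity pruning. With fewer than 10
  training samples the root never splits and the tree predicts the
  majority class.
* **Kernel naive Bayes**: per class and feature, a Gaussian kernel
  density with Silverman's rule-of-thumb bandwidth, floored at 1e-3 beta
  units so constant features keep a proper density. Class priors are the
  training frequencies; a posterior tie goes to the first class level
  (down).
* **SVM**: linear kernel, box constraint C = 1 (`e1071`/libsvm). The
  split criterion, C and the solver are not pinned down by the method's
  definition, so the defaults are the conventional ones and are stated
  here rather than hidden.

## The cross-validation objective

One CV plan is built per gene, seeded by `gene_seed(global_seed,
gene_id)`, and reused for *every* candidate evaluation and every SFS
round of that gene. This pairs the comparisons: candidates are ranked on
identical folds, so the argmin reflects the probes, not fold luck. Folds
are stratified (samples shuffled within class and dealt cyclically), so
fold sizes differ by at most one and per-fold class counts stay within
one of proportional. The score is the mean per-fold misclassification
*count*; with near-equal fold sizes this is proportional to the error
rate, and `cv_error_rate()` rescales it to [0, 1] where a fraction is
needed (e.g. `final_cv_error` of a selection). A training fold that
degenerates to a single class — possible for SVMs with a small minority
class — falls back to majority-of-train prediction for that fold, and
the same fallback applies in leave-one-out evaluation.

Gene usability is gated before any selection: at least 10 labeled
samples (so 10-fold CV keeps ≥1 sample per fold) and at least 2 samples
per class; failing genes are skipped with a recorded reason.

## Alternative selectors

* **SVM-RFE**: a class-weighted Gaussian-kernel SVM is refit on the
  surviving features; each feature is scored by the change in the dual
  objective when it is removed from the kernel with the alphas held
  fixed, and the lowest-scoring feature is eliminated. A constant
  feature leaves the kernel unchanged and scores exactly 0. Class
  weights solve n0·w0 = n1·w1 with w1 = 1, so the minority class costs
  more to misclassify. The "correlation bias reduction" refinement of
  kernel RFE is deliberately not implemented; the standard criterion is
  used. Score ties eliminate the higher candidate index first, so
  duplicated columns land on adjacent ranks, lower index first.
* **ReliefF**: iterates over each sample once in a seeded shuffle; per
  instance, the k nearest same-class (hits) and other-class (misses)
  samples are found by Euclidean distance over all candidate features,
  and each feature's weight receives −mean(x−h)² + mean(x−m)², divided
  by the number of iterations. With one iteration and k = 1 this reduces
  to the textbook single-neighbour update (the worked value
  −0.1² + 0.3² = 0.08 is a test fixture). A class smaller than k reduces
  k for that class with a warning.
* **GA-KNN**: a binary-mask genetic algorithm minimizing
  resubLoss/(N−S) — resubstitution loss of a KNN on the selected
  features over the count of *unselected* features, so the denominator
  penalizes large subsets; masks with S = 0 or S = N get infinite
  fitness. Defaults: population 50, 100 generations, tournament size 3,
  uniform crossover at 0.8, per-bit mutation 1/N, elitism 2. Note the
  documented degeneracy: with K = 1 the resubstitution loss is 0
  whenever no two identical feature vectors carry different labels, so
  fitness then depends on subset size alone. The objective is
  implemented as stated, degeneracy included.
* **Controls**: `random` draws k probes uniformly (k matched per gene to
  the SFS selection size via `reference_selection`, mirroring the paired
  design of the comparison); `top_two` keeps the two probes with the
  largest |Pearson r| against the *continuous* expression of the labeled
  samples (a flag-free design choice; correlation against ±1 labels is
  nearly equivalent and was not added as a second code path). Constant
  probes get r = 0.
* **Annotation-driven selectors**: `all`; `upstream_cpg_island`
  (CpG-island probes whose region group for this gene is TSS200,
  TSS1500, 5'UTR or 1stExon); `tss_window` (|TSS distance| ≤ 2500 bp,
  boundary inclusive); `top_sd` (highest beta standard deviation, ties
  to the lower candidate index).

Evaluation pairs each selector with its conventional classifier: SFS
with the classifier that drove it, ReliefF/GA-KNN and the controls with
KNN, SVM-RFE with the Gaussian-kernel weighted SVM it ranked with, and
the annotation selectors with whatever classifier the caller chooses.

## Metrics and gene stratification

Leave-one-out confusion counts feed accuracy, precision, recall and
specificity exactly as their ratio definitions read, and the Matthews
correlation coefficient. Two conventions matter and are fixed here: a
zero factor in the MCC denominator yields MCC 0 (keeps per-method means
defined), and an undefined rate (0/0, e.g. precision when nothing is
predicted down) is NA and excluded from summary means rather than
coerced to 0. MCC stratification uses strict inequalities (> 0.6 high,
< 0.2 low); genes at a threshold fall in neither list. The overlap of
two gene lists against a universe is tested by explicit summation of the
hypergeometric upper tail.

## The synthetic generator

`simulation_scenario()` describes the benchmark conditions: by default
200 genes × 25 samples, 10 probes per gene of which one is informative
with class-conditional beta means 0.2 (down) / 0.8 (up) and sd 0.05
(truncated normal on [0, 1], so mean and sd are controlled directly);
the other probes are class-independent Beta(2, 2) noise. Balanced
classes; expression is generated deterministically from the planted
labels at ratios 1.5·t (up) and 1/(1.5·t) (down), so discretization at
threshold t reproduces the labels exactly and no sample is baseline.
A `probes_per_gene = c(5, 30)` range emulates the ~18-probe-per-gene
spread of a real array; a `label_noise` flip probability injects
methylation–expression disagreement and produces mid-range-MCC genes.

What the generator does *not* emulate: spatial probe–probe correlation
along the genome, beta-value compression near 0/1, batch structure,
copy-number confounding, and continuous (dose-like) expression
variation. Passing benchmarks therefore demonstrate that the
implementation recovers planted signal under clean conditions and that
methods rank as expected relative to controls — not that any particular
MCC level will be reached on real arrays.

One consequence of the deterministic default deserves emphasis: with a
single, strongly informative probe and noiseless labels, *every*
expression-aware selector that finds the planted probe — SFS, but also
the top-two-correlated control, for which the planted probe is the most
correlated feature by construction — attains perfect LOO prediction, so
their mean MCCs saturate at 1 and cannot be separated. The random
control stays near 0. Separating expression-aware methods from each
other requires imperfect genes (`label_noise > 0`), at the cost of
recovery no longer being essentially certain; the default keeps the
clean recovery benchmark.

## Problem sizes and numerical choices

The shipped benchmark (200 genes, 25 samples, 10 probes/gene, 1NN-SFS
plus both controls) completes in about a minute on one CPU; the
oracle-equivalence checks use 100 random instances of ≤5 probes × 20
samples, small enough for a nested-loop reference implementation.
Remaining numerical conventions, gathered in one place: argmin ties in
SFS go to the lowest candidate index; beta matrices must be NA-free at
load (a `drop_row` option handles public matrices with missing rows);
matrices are written with 10 significant digits, which round-trips
bit-exactly for values of that precision; all randomness flows through
explicit integer seeds, with per-gene seeds derived by a stable string
hash so results are invariant to gene processing order; coordinates are
1-based (MAPINFO convention); multi-gene manifest cells split on ";"
pairing gene i with region i, keeping the first region when a gene
repeats inconsistently.

## Known limitations

Forward selection cannot see purely interacting probe sets; the GA can
in principle, but its stated fitness is degenerate at K = 1 (above).
Probes mapping to several genes are assigned to every listed gene, which
double-counts shared promoter CpGs in gene-level summaries. The
discretization's reciprocal down-threshold (r ≤ 1/t) is a
scale-invariance choice; a −t cut on the log scale would label slightly
differently near the boundary. And the evaluation reuses the samples
that informed the selection (selection and LOO-CV run on the same
cohort), so per-gene MCCs are optimistic relative to an external
validation cohort — mirroring how such probe selections are commonly
assessed, but worth remembering when interpreting MCC > 0.6 gene lists.
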