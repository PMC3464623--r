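---
title: "otcc: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{otcc: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otcc)
```

## The model

Both class discovery and class prediction are instances of one labeling
problem.  Given a symmetric sample-similarity matrix $S = (s_{ij})$ over
$N$ samples, find continuous labels $f \in [0,1]^N$ minimizing

$$\min_f \; \tfrac12 \sum_{i,j} s_{ij} (f_i - f_j)^2 \;=\; f^\top L f,
\qquad L = D - S,\; d_{ii} = \textstyle\sum_j s_{ij},$$

subject to $f_a = 0$ for seed set $A$ (Class Zero), $f_b = 1$ for seed
set $B$ (Class One), and the box $0 \le f_i \le 1$.  Similar samples are
pushed toward similar labels; the seeds anchor the two ends of the
scale.  If all $s_{ij} \ge 0$, $L$ is positive semi-definite and the
problem is a convex QP: the global optimum is guaranteed, which is the
central advantage over center-based or greedy agglomerative clustering.
Both seed sets must be nonempty and disjoint — with either side empty
the minimizer is a constant labeling carrying no information, so
`label_problem()` refuses the construction outright.

**Assumptions.** (1) Similarity is meaningful and symmetric; the model
never looks at features, only at $S$, so feature selection and
similarity design carry all the biology.  (2) Non-negativity of $S$ for
the convexity guarantee.  (3) The two seed sets really belong to
different classes; in discovery this is the *most dissimilar
assumption*, in prediction it is the gold standard's correctness.

## Solver

`solve_iterative()` implements the customized fixed-point scheme:
initialize $f_i = 0$ for all unlabeled $i$ (seeds at their pinned
values), then sweep synchronously

$$f_i^{t+1} = \frac{\sum_j s_{ij} f_j^t}{\sum_j s_{ij}}$$

over unlabeled nodes until $\max_i |f_i^{t+1} - f_i^t|$ drops below
`tol` (default $10^{-6}$; the stopping rule is a free parameter of the
method, and $10^{-6}$ on a $[0,1]$ scale is far below any decision
boundary effect) or `max_iter` (default 10000) sweeps have run.  At a
fixed point every unlabeled label is the similarity-weighted average of
all labels — the harmonic extension of the boundary values, i.e. the KKT
point of the QP.  Three operational properties are enforced as tests
rather than re-proved: iterates never leave $[0,1]$ (each sweep is a
convex combination), the objective is non-increasing along the iterate
sequence, and the result matches `solve_exact()` — an independent direct
solve of the linear KKT system $(D_{UU} - S_{UU}) f_U = S_{UB}\mathbf 1$
on the unlabeled index set — to $10^{-6}$ in max-norm at `tol` $=
10^{-10}$ across hundreds of random connected problems.

**Numerical conventions.**

* *Diagonal entries.* $s_{ii}$ stays in the row sums.  It only damps the
  sweep (a self-loop pulls $f_i^{t+1}$ toward $f_i^t$); the fixed point
  is unchanged, which a test verifies by comparing exact solutions with
  and without the diagonal.
* *Zero row sums / seed-disconnected nodes.*  An unlabeled node with no
  positive-similarity path to any seed cannot feel the boundary; its
  equations are singular.  Such nodes simply keep the initialization
  value 0.  `solve_exact()` detects them by reachability and assigns the
  same value (the minimum-norm solution of the decoupled singular
  block), flagging the solution `degenerate`.  This convention is not
  arbitrary: it is exactly what creates the transient *pseudo-cluster*
  that lets recursive discovery resolve three or more mutually
  equivalent clusters (below).
* *Negative similarities.*  Strict mode (default for curated input)
  rejects them, preserving convexity.  Permissive mode — the default
  wherever raw Pearson or noisy simulated matrices flow in — clips them
  to 0 with a logged count.  A `unit` mode applies $(s+1)/2$ instead.
  Clipping and unit-mapping genuinely differ: clipping keeps
  anticorrelated pairs fully decoupled, the unit map turns them into
  weak positive coupling.  The discovery default is clipping, which
  reproduces the clean component separation on graph similarities.
* *Binarization.*  $f_i \ge$ cutoff goes to Class One; the tie at the
  cutoff is resolved deterministically toward Class One (the model gives
  no preference at exact equality, so the rule is a documented
  convention).  The default cutoff is the scale midpoint 0.5 — this is
  the practical advantage over spectral methods, whose eigenvector sign
  patterns need a data-dependent threshold.  `learn_cutoff()` optionally
  replaces it by stratified k-fold cross-validation on the labeled
  samples over a grid (0.05–0.95, step 0.05), with ties resolved toward
  0.5.

## Similarity construction

`pearson_similarity()` correlates sample columns over genes (first
order).  `second_order_similarity()` correlates the *rows of the
first-order matrix*: sample $i$'s vector of similarities to the whole
cohort becomes its feature vector.  Two samples are second-order similar
when they relate to everyone else similarly — a globally informed
measure that is the recommended input for subtype discovery.  Pearson's
affine invariance makes the second-order matrix identical whether the
first-order input is on the raw or unit scale, and makes the estimator
normalization (population vs sample variance) cancel; neither is
configurable for that reason.  Zero-variance samples (or constant
similarity rows) make the correlation undefined and are hard errors
naming the offender — silently dropping a sample from a clinical cohort
would be worse than stopping.

The microarray recipe in `preprocess_expression()` — clip intensities
into $[100, 16000]$, remove genes with $\max/\min \le 5$ *or*
$\max - \min \le 500$ (both thresholds configurable), then $\log_{10}$ —
is the standard informative-gene filter for the classic oligonucleotide
leukemia chips; the OR combines a fold-change and an absolute-range
criterion so that neither low-expressed noise (high fold, small range)
nor high-baseline flat genes (large range impossible, small fold)
survive.  The step order clip → filter → log is fixed; filtering on
clipped values means saturated probes cannot fake variation.
`select_biomarkers()` implements the phenotype-correlation rule
($|r| >$ 0.6 by default) used for contrasts such as normal-vs-cancer;
each contrast is one call, and callers union the resulting gene sets —
whether the original analyses computed similarity per contrast or on the
union is not documented anywhere, so the package leaves the composition
to the caller with union as the suggested default.

## Class discovery

`find_seed_pair()` encodes the most dissimilar assumption: the pair
attaining the minimal $s_{ij}$ must belong to different classes
(otherwise there is only one class, and the caller's threshold will say
so).  Ties at the minimum are re-ranked by the corresponding entries of
$S^2, S^3, \dots$ up to `max_power` (default 5, beyond which further
powers rarely separate anything that the spectrum has not already
mixed); only originally tied pairs are re-ranked — re-ranking all pairs
would let long paths override the direct-dissimilarity principle.  A tie
surviving all powers (e.g. any vertex-transitive graph similarity) falls
back to the lexicographically smallest pair with a
`otcc_degenerate_tie` warning, keeping discovery fully deterministic.
Tie detection uses a $10^{-9}$ relative tolerance because algebraically
equal correlations can differ in the last float bit depending on
summation order.

`discover()` splits recursively while any cluster's minimum
within-cluster similarity is below `threshold`, producing a binary tree
whose leaves partition the samples.  The criterion scale is decoupled
from the optimization scale: with raw Pearson input the natural
threshold is 0 — *a cluster containing an anticorrelated pair must
split* — while the solver consumes the clipped matrix.  Clusters of
size 2 below threshold split into singletons; singletons report inner
similarity $+\infty$ and never split.  Raising the threshold never
decreases the leaf count (splits are threshold-independent; the
threshold only prunes), which is tested, and `threshold = +1` drives the
recursion to all-singleton leaves, exposing the complete fine structure.

The pseudo-cluster mechanism deserves emphasis.  For three equivalent
clusters (the three-5-clique graph), the first split seeds from two of
them; the third, decoupled from both seeds after clipping, keeps the
initialization label 0 and lands in the Class-Zero leaf.  Its presence
makes that leaf's inner minimum similarity negative, so the recursion
revisits and separates it.  This is why the init-at-0 convention is
load-bearing: initializing disconnected nodes at 0.5 would scatter them
by rounding instead.

## Class prediction

`predict_binary()` pins the labeled samples of the first class at 0 and
of the second at 1; known labels are constraints, so no prediction path
can ever alter them.  For more classes:

* `predict_multiclass_tree()` recurses down a binary tree over class
  ids, using the labeled samples under each subtree as seeds.  The tree
  is prior information: a wrong tree injects wrong priors and measurably
  degrades accuracy (tested on noisy three-block data), so when no tree
  is given a left-deep tree in class order is used *with a warning*.
* `predict_one_vs_all()` scores each sample per class with the labeled
  samples of that class pinned at 1 and all other labeled samples at 0,
  then assigns the argmax (ties by class order; no cutoff is involved).
* `predict_one_vs_one()` votes over all pairwise binary models.

## Synthetic data: what it emulates and what it does not

`make_two_class_similarity()` generates the benchmark world directly in
similarity space: within-class 1, between-class 0, unit diagonal, i.i.d.
$\mathcal N(0, \sigma)$ noise on the strict upper triangle mirrored to
keep symmetry (asymmetric noise would violate the model's symmetry
assumption), diagonal noise-free.  The small class has 5 samples, the
other `ratio`-fold as many, matching the published benchmark design; the
default benchmark grid (ratios 1, 2, 5, 10; $\sigma$ 0 to 0.5 in steps
of 0.1, axes unspecified in the original figure) spans accuracy 1.0
through visible degradation.  `make_component_graph()` +
`graph_similarity()` generate the multi-cluster world: disjoint complete
graphs, optionally with between-cluster links, and Pearson correlation
of adjacency rows (for three 5-cliques: $29/44$ within, $-4/11$
between, with all cross pairs exactly tied — closed forms the tests pin
down).

These generators emulate block structure, noise level, class imbalance
and non-hierarchical cluster relations.  They do **not** emulate real
expression data: no gene-level covariance, no batch structure, no
heavy-tailed intensities, and — importantly — clipped Gaussian noise has
*positive mean* $\approx \sigma/\sqrt{2\pi}$ per cross-pair, a uniform
attractive background between classes that real (anti-correlated)
subtype similarities lack.  A green benchmark test therefore establishes
algorithmic correctness under the stated noise model, not performance on
any particular cohort.

One consequence is documented rather than hidden: in this noise world,
prediction accuracy is non-decreasing in the number of known labels
*per class* (the tested trend, with a pronounced leap from 1 to 2 known
labels per class), but adding labels to only one class while the other
keeps a single anchor can *reduce* accuracy — the aggregate positive
cross-noise ($\approx n\sigma/\sqrt{2\pi}$ per sample) competes with the
lone anchor's unit weight and drags the weakly anchored class across the
cutoff.  That is a property of the harmonic model under biased
background coupling, reproducible from the formula above, and a caveat
for strongly asymmetric gold standards on noisy similarities.

`clustering_accuracy()` scores discovery output as the maximal agreement
over all bijections between predicted and true label sets (exhaustive
over $\le 8$ labels), since cluster ids are arbitrary.
`run_discovery_benchmark()` and `run_prediction_sweep()` repeat their
protocols 1000 times per cell by default as in the published benchmarks;
the test suite runs 100 replicates under fixed seeds (documented
Monte-Carlo tolerance of one percentage point on trend assertions) to
keep desk runtime in seconds.  All generators take explicit seeds,
restore the caller's RNG stream, and the benchmark tables carry
replicate counts and standard errors so the trend tests are honest about
their uncertainty.

## Validation on the original cohorts

The published leukemia results (the 72-sample tree with its single
misplaced sample, the 98%/96% accuracies, the 3,571-gene filter count)
and the breast-cancer results require the original microarray data,
for which no public accession is recorded; they are therefore not part
of the test suite.  With those tables in hand the pipeline is:

```r
expr  <- read_expression_table("leukemia.tsv", scale = "raw_intensity")
clean <- preprocess_expression(expr)            # expect ~3571 genes
sim   <- second_order_similarity(pearson_similarity(clean))
tree  <- discover(sim, threshold = 0)           # AML/ALL at the first split
```

## Known limitations

* Dense matrices only; practical up to $N \sim 10^4$ samples.  No
  sparse backend.
* The most-dissimilar seeding is sensitive to a single outlying pair;
  the matrix-power tie-break mitigates ties, not outliers.
* Clipping negative similarities discards anticorrelation strength; the
  unit map keeps it but changes the effective graph.  Neither choice is
  universally right, hence both are exposed.
* The stopping threshold is expert knowledge, not estimated; with a
  wrong threshold the tree is still valid, just cut at the wrong depth.
* `learn_cutoff()` needs enough labeled samples per class for
  stratified folds; with one label per class it degenerates to the
  default 0.5.
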