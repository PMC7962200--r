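---
title: "Weighted visibility networks for EEG emotion recognition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted visibility networks for EEG emotion recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvgnet)
```

## The problem

Affective states are commonly described on two continuous axes — valence
(pleasantness) and arousal (intensity) — and EEG studies of emotion ask
whether scalp recordings carry enough information to place a subject on the
low or high side of each axis. `hvgnet` implements one family of answers:
map each EEG segment to a *visibility graph*, summarize the graph by a
handful of weighted-network statistics, add classical time-domain amplitude
features, and feed the result to standard classifiers.

## From a time series to a graph

Treat each sample of a segment $x_1, \dots, x_N$ as a vertical bar at
integer time $t = 1, \dots, N$. Two constructions are supported:

* **Natural visibility (VG).** Samples $i < j$ are linked when every
  intermediate bar top lies strictly below the chord joining the tops of
  bars $i$ and $j$.
* **Horizontal visibility (HVG).** Samples are linked when every
  intermediate sample is strictly lower than *both* endpoints:
  $x_i, x_j > x_k$ for all $i < k < j$. The HVG edge set is always a
  subset of the VG edge set, and adjacent samples are always linked.

The HVG is computed by a linear-time monotone-stack sweep; the package
also carries an $O(N^2)$ sweep for the VG and, in its test suite,
quadratic/cubic reference implementations straight from the definitions
that both fast paths are checked against on hundreds of random series.

### Edge weights and direction

An unweighted adjacency pattern discards amplitude information. The
weighted variants attach to each visible pair an *angle* built from two
arctangent terms. With unit time steps and gap $\Delta t = t_j - t_i$:

$$w^{f}_{ij} = \arctan\!\frac{x_j - x_i}{\Delta t} + \arctan\!\frac{x_i}{\Delta t},
\qquad
w^{b}_{ij} = \arctan\!\frac{x_i - x_j}{\Delta t} + \arctan\!\frac{x_j}{\Delta t}.$$

Reading the series forward (FWHVG) anchors the angle at the earlier bar;
reading it backward (BWHVG) anchors it at the later one. The two always
satisfy $w^f + w^b = \arctan(x_i/\Delta t) + \arctan(x_j/\Delta t)$, an
identity the tests verify to machine precision. For the six-point
demonstration series:

```{r}
s <- toy_series()
s$values
round(build_weighted_hvg(s, "forward")$weights, 3)
round(build_weighted_hvg(s, "backward")$weights, 3)
```

Three cells of the originally published version of these matrices —
forward (3,4) as 0.467, forward (3,5) as 1.123 and backward (1,2) as
2.573 — differ from the defining formulas (which give 0.464, 1.128 and
2.575) by more than the displayed rounding; the formulas are treated as
normative and the package reproduces every other printed cell to three
decimals.

### Conventions that were genuinely open

* **Ties and collinearity.** Both criteria are strict: an intermediate
  equal to an HVG endpoint, or sitting exactly on a VG chord (within an
  absolute slope tolerance of `1e-12`), blocks visibility. A linear ramp
  is therefore a path graph under both constructions; the convexity
  property is exercised in tests with strictly convex series such as
  `c(1, 2, 4, 8, 16)`, where every chord genuinely clears the
  intermediates.
* **Diagonal.** Displayed weight matrices sometimes carry 1 on the
  diagonal as a typographic filler. The package stores an explicit zero
  diagonal — there are no self-edges — and every network statistic sums
  over neighbours $j \ne i$ only.
* **Symmetry.** The weight of a pair is computed once, with the earlier
  sample as $i$, and stored symmetrically. Direction lives in the choice
  of formula, not in an asymmetric matrix.
* **Negative amplitudes.** Band-passed EEG is zero-mean while the angle
  construction reads bar heights from a zero baseline, and the entropy
  feature needs nonnegative contributions. The pipeline therefore shifts
  each segment so its minimum is 0 before graph construction
  (`shift_min = TRUE`, the default in `extract_network_features()`).
  The shift cannot change any visibility decision and makes all weights
  nonnegative. It can be disabled for raw, already-nonnegative series —
  the worked example above uses the raw values.

## Network statistics

From a weighted graph $W$ with strengths $d_i = \sum_{j \ne i} w_{ij}$ the
package extracts four numbers:

1. average weighted degree $\bar d = \frac1N \sum_i d_i$;
2. degree deviation, the sample standard deviation of the $d_i$
   (divisor $N - 1$);
3. the weighted clustering coefficient: per node
   $C_i = \sum_{\{j,k\}} w_{ij} w_{ik} w_{jk} \big/ \sum_{\{j,k\}} w_{ij} w_{ik}$
   over pairs of distinct neighbours, with $C_i = 0$ for nodes of degree
   below two, averaged over all $N$ nodes;
4. the entropy $-\sum_i P_i \log P_i$ of $P_i = C_i / \sum_j C_j$, in
   natural-log units by default (a `log_base` switch offers bits; the
   choice rescales the feature by a constant and cannot affect
   classification).

Two reading decisions are worth stating. The normalizing count $M$ that
appears alongside sums over $i = 1..N$ in the defining formulas is read as
$N$, the number of nodes — no other population is in scope for a single
graph. And the unordered-pair convention in $C_i$ is cosmetic: counting
each ordered pair twice multiplies numerator and denominator alike, which
the tests assert. Raw weights enter the clustering ratio unnormalized.

The implementation computes all four through sparse matrix algebra
(`Matrix`): the triangle sum per node is the diagonal of $W^3$, obtained
as `rowSums((W %*% W) * W)`, and the pair normalizer is
$d_i^2 - \sum_j w_{ij}^2$, so cost scales with the edge count — an HVG
has $O(N)$ edges — rather than $N^3$. A graph with no triangles at all has
no clustering distribution; its entropy is reported as 0 with a warning
rather than `NaN`.

## Time-domain features

Six classical amplitude statistics complement the network view: the mean;
the population standard deviation (divisor $N$, as the defining formula
states, in contrast to the $N-1$ of the degree deviation — both printed
conventions are honoured as written); the mean absolute first and second
differences; and the same two differences on the standardized series,
which reduce to the raw differences divided by the standard deviation and
are invariant to positive affine transforms. A constant segment gets
zeros and a warning instead of a division by zero.

## Segmentation, fusion, normalization

One-minute recordings are cut by a sliding window — 10 s with 50% overlap
by default, giving 11 segments of 1280 samples at 128 Hz; trailing partial
windows are discarded, never padded. Four layouts recur in evaluation:
the full minute with overlap (11 segments), the full minute without
(6), and the last 40 s (the first 20 s dropped via `skip_seconds = 20`)
with and without overlap (7 and 4).

Each segment, on each channel, yields a forward and a backward feature
vector; **fusion** is their elementwise sum. Each fused feature — one
feature, one channel, across all of a subject's segments — is then
min-max normalized to $[0,1]$. Normalization is fit per subject (the
`recordings` list passed to `build_design_matrix()` is treated as one
subject), matching the per-vector notation of the definition; users who
pool subjects should be aware the package does not refit across a cohort.
The design matrix has one row per (trial, segment) and columns ordered
channels-major, features-minor: 4 network columns per channel, 6
time-domain columns, or 10 combined — e.g. 128 / 192 / 320 columns for a
32-channel montage.

Ratings binarize at the midpoint of the 1–9 scale: below 5 is the low
class, 5 and above the high class, and "high" is the positive class in
all metrics.

## Classifiers and evaluation

* **SVM**: RBF-kernel C-classification (via `e1071`/libsvm) with
  $C = 2$, $\gamma = 1$ as defaults; inputs are already in $[0,1]$, so no
  internal rescaling.
* **OF-KNN**: k-nearest neighbours whose $k \in \{1..30\}$ and distance
  metric (Euclidean, cityblock, cosine) minimize 5-fold cross-validation
  loss on the training partition. The candidate grid is small enough to
  enumerate exhaustively, which finds the global optimum of the search
  space deterministically — a Bayesian acquisition loop over the same
  space could only match it. Ties go to the earlier candidate (smaller
  $k$), and the neighbour vote breaks ties toward the nearest neighbour's
  class. The kNN kernel is implemented in the package because the
  installed kNN routines expose Euclidean distance only.
* **DT**: CART with Gini impurity via `rpart`, grown with
  `minsplit = 2`.

`cross_validate()` builds seeded, class-stratified folds (stratification
keeps sensitivity/specificity stable on balanced data), trains on $k-1$
folds and reports per-fold confusion counts, accuracy, sensitivity,
specificity and precision with mean and standard deviation; 440 rows in
five folds give the 352/88 train/test split. Fold assignment is
row-independent by default, which matches segment-level evaluation
counts but lets overlapping segments of one trial straddle the
train/test boundary; `groups =` (e.g. trial ids) switches to grouped
folds for leakage-free estimates, and users should expect noticeably
lower accuracies there.

## The surrogate generator

`generate_recordings()` exists so the full pipeline can be exercised and
falsified without any external download. Each channel is band-limited
(4–45 Hz) $1/f^\alpha$ noise synthesized in the frequency domain with
random phases, multiplied by a slow (0.1–0.5 Hz) amplitude-modulation
envelope, plus white measurement noise. The two classes differ in the
spectral exponent $\alpha$ (default 0.5 vs 1.5) and the modulation depth
(0 vs 0.4) — i.e. in waveform *roughness*, the property visibility-graph
degree statistics are sensitive to — and not in mean level, which the
min-shift would erase anyway. Defaults mirror the study layout: 40
one-minute trials (20 per class) of 32 channels at 128 Hz, everything
driven by one seed. Setting both classes to identical parameters removes
the effect entirely, and cross-validated accuracy must then collapse to
chance; the acceptance tests check both regimes (at 2 channels to keep
the run short — accuracy only improves with more channels).

What the generator does **not** emulate: dipole geometry and volume
conduction (channels are independent), artifacts (ocular, muscular,
line noise), non-stationarity within a trial, or any genuine
neurophysiology of emotion. Passing tests on surrogate data therefore
demonstrate that the machinery — graphs, features, fusion,
cross-validation — works and separates classes that differ in roughness;
they do not certify recognition rates on real recordings.

A reader for the preprocessed 32-subject emotion-database layout
(40 trials × 40 channels × 63 s, ratings attached, first 32 channels
kept as EEG, 3-s pre-trial baseline dropped) is included as
`read_deap_preprocessed()`; it consumes an R-native serialization of
that array layout, and its tests run against fixtures written by the
package's own `write_deap_fixture()` — the external database is never
required.

## Numerical choices and limitations

* Problem sizes in the shipped tests: oracle equivalence on random series
  up to length 500; brute-force feature checks on graphs of up to 12
  nodes; the end-to-end classification checks use 40 trials × 2 channels
  × 60 s. These sizes make the whole suite run in about a minute while
  still exercising every code path at full 128 Hz segment length.
* Dense $N \times N$ weight matrices are the public representation
  (a 10-s segment is $N = 1280$); feature extraction internally goes
  through sparse edge lists, so the dense form is only materialized when
  a caller asks for it.
* The entropy of a triangle-free graph, constant feature vectors under
  min-max normalization, and constant segments under standardization all
  degrade to defined values (0) with warnings rather than errors, since
  all three occur naturally in degenerate windows.
* Metrics with empty denominators (e.g. sensitivity with no positive
  test rows) are reported `NA` and excluded from fold averages.
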