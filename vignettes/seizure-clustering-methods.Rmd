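---
title: "Cluster-based feature extraction and classifier benchmarking for EEG seizure detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-based feature extraction and classifier benchmarking for EEG seizure detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seizclust)
```

## The problem and the pipeline

Distinguishing ictal (seizure) from normal single-channel EEG is hard at the
raw-sample level: segments are long (the classic Bonn corpus uses 4097
samples at 173.61 Hz, about 23.6 s) and non-stationary. The workflow
implemented here reduces each segment to a short, fixed-length feature
vector by *clustering its amplitude samples* and keeping the sorted cluster
centroids — a k-point summary of the segment's amplitude distribution — and
then benchmarks ten standard classifiers on those features under stratified
10-fold cross-validation, reporting sensitivity, specificity and accuracy.
Six clusterers produce the features: two learning-based (k-means/k-median
and fuzzy c-means) and four bio-inspired population searches (cuckoo,
dragonfly, firefly and a modified firefly) that all minimize the same
within-cluster sum of squares, so their feature sets are directly
comparable.

Entropy statistics (approximate, Shannon and sample entropy) computed on
the clustered features quantify how separable the two classes are before
any classifier is trained: ictal features concentrate on fewer, larger
amplitude levels and typically score lower ApEn/Shannon entropy than
normal features.

## The shared clustering objective

All six clusterers minimize

$$J(A, B) = \sum_{k=1}^{K} \sum_{j} a_{jk} \, \lVert z_j - b_k \rVert_q^q,
\qquad \sum_k a_{jk} = 1,\; a_{jk} \in \{0, 1\},$$

with $q = 2$ (squared Euclidean; prototype = cluster mean) or $q = 1$
(Manhattan; prototype = coordinate-wise median, the k-median variant).
The metaheuristics encode a full flattened $K \times d$ centroid set per
agent and use $J$ with $q = 2$ as fitness; `clustering_objective()` is the
single implementation they all call, and every returned `cluster_model`
stores an objective that is recomputed from its centroids, so the stored
value can always be verified independently.

Numerical conventions shared by all methods:

* nearest-centroid ties break toward the lowest cluster index
  (determinism);
* an empty cluster is reseeded at the point farthest from its assigned
  centroid; if every point already coincides with a centroid (e.g. a
  constant segment) the duplicated prototypes are left in place;
* all algorithms are bit-reproducible given `(data, config, seed)`; every
  internal consumer of randomness draws through an isolated, derived seed
  (`derive_seed()`), so results do not depend on evaluation order.

## Fuzzy c-means

FCM minimizes $H = \sum_{i,q} z_{iq}^p d_{iq}^2$ with the standard coupled
updates (membership rows sum to one; a point at zero distance from a
centroid takes membership one there, the limit of the update). The
fuzziness index defaults to $p = 2$; iteration stops when $H$ changes by
less than $\xi = 10^{-6}$ or after $I_{\max} = 200$ iterations. The number
of clusters can be chosen by `fcm_select_k()`, which scans
$[k_{\min}, k_{\max}]$ (conventionally $2$ to $\lfloor\sqrt n\rfloor$) and
minimizes a validity index — Xie–Beni (compactness over separation) by
default, pluggable via a function argument.

## The bio-inspired searches

The population searches share: agents initialized as random selections of
$k$ data points (a strong, scale-free start), positions clamped to the data
bounding box (a centroid outside the hull can never improve $J$), an elite
archive of the best solution ever visited (so best-fitness traces are
monotone non-increasing by construction), and defaults of 15 agents and
200 iterations.

**Cuckoo search.** Every nest is perturbed once per generation by a
Mantegna Lévy flight ($\beta = 1.5$) whose step length is proportional to
the nest's distance from the current best (steps anneal as the population
converges; the best nest itself explores at a 10%-of-range floor), with
greedy per-nest acceptance. A fraction $p_a = 0.25$ of the worst nests is
then abandoned and rebuilt by stochastic mixing of two random nests,
keeping the better of old and new. This is the reference structure of the
published algorithm; a literal one-candidate-per-generation variant was
evaluated and converged an order of magnitude less tightly on two-blob
instances, so it was rejected.

**Dragonfly.** Per agent, separation, alignment and cohesion are computed
over the neighbours inside a radius that shrinks linearly from 25% to 5% of
the data diagonal; food is the archived best position and the enemy is the
worst of the current population (the printed enemy-distance expression in
the source method description is not dimensionally interpretable, so enemy
repulsion mirrors food attraction with opposite sign). Each force is scaled
by its weight times a fresh uniform random multiplier and the previous step
is retained with an inertia weight that decays to half over the run —
without these standard randomizations the swarm collapses onto the food
position and stalls. An agent with no neighbours takes a small Lévy walk;
with all weights zero the update degenerates to no motion. Default weights:
separation 0.1, alignment 0.1, cohesion 0.7, food 1.0, enemy 0.1,
inertia 0.5.

**Firefly.** Brightness is $1/(1 + J)$, so a lower objective is brighter;
perceived intensity and attractiveness decay as $1/(1 + \lambda q^2)$, and
the move toward a brighter firefly is
$y \leftarrow y + A_0 e^{-\lambda q^2} (y' - y) + \alpha\,\varepsilon$ with
$A_0 = 1$, $\lambda = 1$, $\alpha = 0.2$ decaying geometrically by 0.97 per
iteration and $\varepsilon$ uniform in $[-0.5, 0.5]$ scaled by the
per-coordinate data range. The distance $q$ entering the attenuation is
normalised by the search-space diagonal: in the flattened centroid space raw
squared distances are large enough that $e^{-\lambda q^2}$ underflows and
the attraction term would vanish entirely. The brightest firefly moves
randomly.

**Modified firefly.** Two changes: the attraction scale toward a brighter
firefly becomes the intensity ratio $B_0 = J_0'/J_0 \ge 1$ (intensities are
strictly positive by construction, so the singular $J_0 = 0$ case cannot
arise), and the brightest firefly replaces its random move by a directed
one: it evaluates `s_directions` (default 10) random unit vectors at step
length $\alpha$ times the mean coordinate range and moves only along the
best strictly improving direction, staying put otherwise. Its objective is
therefore non-increasing at every iteration, which the tests verify over
many seeds.

## Entropy separability report

* **Approximate entropy**: $\Phi_m - \Phi_{m+1}$ with self-inclusive
  Chebyshev template matching; embedding $m = 2$ and tolerance
  $r = 0.2\,\mathrm{sd}$ (the usual convention; the source tables state
  neither).
* **Sample entropy**: $-\ln(A/B)$ over $n - m$ templates with self-matches
  excluded; when no $(m{+}1)$-template pairs match, the value is an `Inf`
  sentinel and the report treats the cell as missing.
* **Shannon entropy**: equal-width histogram over $[\min, \max]$ with 16
  bins by default, in bits; a constant series scores 0 and a sample exactly
  uniform over the bins scores $\log_2(\text{bins})$.

Both ApEn and SampEn are validated against independent $O(n^2)$ double-loop
oracles to $10^{-10}$ on every tested series. The report computes the three
entropies per (clusterer, class) cell on the concatenated feature values
and appends an Average row equal to the column means over clusterers
(non-finite cells excluded) — the self-consistency property that the
bundled reference table's consistent columns also satisfy. Whether the
published per-class entropies were computed on clustered features or raw
segments is not stated in the source; the report uses clustered features
(its framing), and raw segments can be fed through the same kernels
directly.

## Classifiers and hyperparameter selection

The registry covers: an ANN (one sigmoid hidden layer of 32 units, input
sized to the feature count, batch gradient descent with learning rate 0.3,
momentum 0.5, 800 cycles — the stated optimizer name in the source conflicts
with its own learning-rate/momentum parameters, and the gradient-descent
reading was implemented), KNN with $k = 2$ and Euclidean distance (a split
vote falls back to the single nearest neighbour), incremental LDA (Welford
updates of class means and pooled scatter; streaming any order of the same
samples reproduces batch LDA, verified against `MASS::lda` to an angular
tolerance of $10^{-8}$), Gaussian naive Bayes, three SVMs (linear via
mini-batch averaged Pegasos SGD so that training is iteration-controllable;
polynomial of order 2 and RBF with $\gamma = 2$ via `e1071`), QDA, a
decision tree (`rpart`) and a random forest.

The `mse_hyperparam_search()` procedure mirrors the
iterations-by-grid-value tables: it trains at every (grid value, iteration
cap) cell, records the training MSE between 0/1-coded predictions and
labels, disqualifies grid values whose MSE is not non-increasing over the
final three schedule steps (the "local minima / flattened MSE" rule), and
picks the qualifying value with the lowest final MSE. For learners without
an iteration knob the column is constant and the rule reduces to the
minimum-MSE value.

The kernel-sum regularization ratio $Q = N / \sum_j K(y_j, \bar y)$ is
exposed as a utility (`svm_regularization_q`); the kernel SVMs use the
library default cost of 1, since the printed expression is typographically
ambiguous and the ratio reading is the one that stays bounded as $N$ grows.
The alarm rule median-filters a 0/1 per-window decision stream and fires
whenever the configured number of consecutive positives completes, with the
counter resetting after each alarm; the threshold is patient-dependent and
is a configuration value only, since no estimation rule is given.

## The synthetic generator

`generate_segment()` emulates the two extreme Bonn classes without claiming
physiological fidelity:

* **normal** — three sinusoids with random frequencies in the 8–12 Hz alpha
  band and random phases, total amplitude `normal_amp` (default 50,
  arbitrary units standing in for microvolts), over AR(1) noise
  (`ar_coeff` 0.9, marginal sd `noise_sd` 15);
* **ictal** — a 3 Hz spike-and-wave train: per cycle a narrow Gaussian
  spike (sd 2% of the period) and a slow negative half-sine over the last
  70% of the period, amplitude `ictal_amp` (default four times normal) with
  10% per-cycle jitter, over the same noise model.

These defaults give the ictal class higher power and lower feature-level
entropy, the qualitative structure the real classes exhibit. What the
generator does *not* emulate: inter-ictal discharges, artifacts (EMG, eye
blinks), non-stationary background drift, or inter-subject variability —
so a passing end-to-end benchmark demonstrates the pipeline's correctness
on separable data, not clinical performance. Per-segment seeds are hashes
of (master seed, class, index), so any segment can be regenerated in
isolation.

## Problem sizes used by the tests and the acceptance script

The package's own verification runs at desk scale, chosen once: synthetic
segments of 512 samples (the generator's default remains the corpus value
of 4097), 50 segments per class for the end-to-end benchmark, 10-fold CV,
and metaheuristic effort of 10 agents by 50 iterations for per-segment
feature extraction in the full six-clusterer, ten-classifier benchmark
(the clusterer defaults themselves remain 15 agents by 200 iterations, and
the optimality-gap checks run at those defaults on two-blob instances
against an exhaustively enumerated global optimum). On this geometry the
full benchmark completes in minutes and the linear SVM reaches 100%
cross-validated accuracy, consistent with a class-mean feature gap of many
pooled standard deviations.

## Known limitations

* The ICA-based artifact suppression is an opt-in approximation: the
  source names ICA but specifies no channel layout or rejection rule for
  single-channel segments, so the default pipeline standardizes only, and
  the component route (FastICA over same-class segments stacked as
  pseudo-channels, kurtosis-threshold rejection) should not be assumed to
  match the original authors' procedure.
* Reported headline accuracies from the original corpus are reproduced
  only as arithmetic identities of their printed sensitivity/specificity
  pairs; re-running the full pipeline on the real corpus requires
  downloading it and pointing a manifest at the files.
* The transpose-mode reduction (`reduce_class_matrix`) reproduces the
  printed matrix-shape reduction (e.g. 4097 × 100 to 4097 × 10) but the
  canonical pipeline classifies per segment, where sensitivity and
  specificity are well defined.
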