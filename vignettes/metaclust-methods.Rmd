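---
title: "Ensemble consensus clustering of metagenomic similarity networks: methods"
author: "metaclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble consensus clustering of metagenomic similarity networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaclust)
```

This vignette documents the models and procedures implemented in
`metaclust`, the assumptions behind them, the tunable parameters with
their defaults and rationale, the design decisions taken where the design
was genuinely open, and the limits of what the synthetic studies show.

## 1. Phylogenetic structure similarity

### Model

Two metagenomic samples are compared as L1-normalized abundance profiles
over the leaves of a shared rooted binary phylogeny. The score is the
*maximum common component* of the two profiles on the tree, accumulated
bottom-up:

* at a leaf $x$, the common abundance is $\min(a_x, b_x)$; the unmatched
  residual $a_x - \min(a_x,b_x)$ (and likewise for $b$) travels towards
  the root;
* along an edge of branch length $\ell$, a residual is scaled by
  $s = d^{\,\ell}$ where $d \in [0,1]$ is the **decay** parameter
  (zero-length edges never attenuate: $s = 1$);
* at an internal node, the common abundance is the minimum of the two
  samples' arriving residual totals, and the excess again travels up;
* the similarity is the sum of common abundance over all nodes.

The score is symmetric, lies in $[0,1]$ for normalized profiles (residual
mass can only shrink when $d \le 1$), and equals exactly 1 for identical
profiles. Missing taxa are treated as abundance zero; taxa absent from
the tree are an error rather than silently dropped.

### The decay parameter

`decay` is the package's single knob for how much credit shared deep
ancestry earns:

* `decay = 0`: only leaf-level overlap counts (along any edge of positive
  length nothing propagates) — a Bray–Curtis-style overlap;
* intermediate values discount shared ancestry by phylogenetic distance;
* `decay = 1` is **degenerate**: all residual mass reaches the root
  unattenuated, and because both normalized profiles match identical
  amounts below the root, their residual totals there are always equal —
  the final minimum closes the gap and *every* pair scores exactly 1.

The default is `decay = 0.5`. The degeneracy at 1 is easy to verify
analytically (matched mass is symmetric, so unmatched totals stay equal)
and numerically, and it is why a full-propagation default cannot drive
any downstream clustering.

This propagation scheme is a documented stand-in for tree-based
similarity scoring of this kind; it is not claimed to reproduce any
particular external tool's internal weighting.

### Non-binary trees, normalization

Multifurcating input trees are resolved deterministically into binary
trees with zero-length branches (`ape::multi2di(random = FALSE)`), which
leaves the score unchanged relative to matching at the original node.
Abundance tables are L1-normalized on load by default; profiles
constructed directly must either be normalized (tolerance `1e-9`) or ask
for normalization explicitly.

The matrix builder computes each row against all partners in one
postorder sweep (the inner loop is over tree nodes, not pairs) and is
row-parallel; the result is identical for any worker count.

## 2. Generation phase: base ensemble and consensus

### Base clusterers

Four families run on the thresholded similarity network:

| family | realization | feature space |
|---|---|---|
| `em` | Gaussian mixture, diagonal-family covariance, fitted by EM (`mclust::me`) | rows of the similarity matrix |
| `kmeans` | `stats::kmeans`, 10 starts | rows of the similarity matrix |
| `hierarchical` | average linkage on `1 − m` | distances |
| `density` | DBSCAN-style scan on `1 − m` | distances |

Treating similarity-matrix rows as feature vectors is the standard
similarity-profile embedding; it needs no external data beyond the
network itself. For the EM family the feature dimension equals the
sample count, so an unconstrained diagonal model (`VVI`) is close to
singular on small or heavily thresholded networks. The fit therefore
starts from a seed-dependent single-start k-means partition, regularizes
with mclust's conjugate prior, and falls back to the spherical diagonal
model (`EII`) when the unconstrained fit degenerates; a run where both
degenerate raises an error, which the ensemble generator logs and skips.
Density-based noise samples stay labelled as noise — they are
"unassigned", not a cluster of their own.

### Default grid

The ensemble defaults to `k ∈ {6,…,10}` (bracketing the six meta-classes
from above), three seeds each for the stochastic families, hierarchical
cuts at the same `k`, and density radii `eps ∈ {0.1, 0.2, 0.3}` with
`min_pts = 4` — roughly 40 base results. The grid is fully explicit in
`ensemble_config()` and recorded as provenance in every partition, so any
run can be audited.

### Consensus matrix

$W_{ij}$ is the fraction of base results assigning $i$ and $j$ to the
same cluster. Two conventions are deliberate:

* the diagonal is fixed at 1 — a sample always co-occurs with itself, and
  this keeps $W$ a valid similarity matrix for the factorization stage;
* a noise label never counts as a shared cluster — counting noise–noise
  pairs as co-clustered would fabricate similarity between samples about
  which the base clusterer explicitly declined to say anything.

## 3. Identification phase: symmetric KL-NMF

### Objective and update

The consensus matrix is factorized as $W \approx HH^\top$ with
$H \in \mathbb{R}^{N\times K}_{\ge 0}$ by minimising the generalized
Kullback–Leibler cost (constants in $W$ dropped) plus an L1 penalty:

$$\min_{H \ge 0} \; -\sum_{i,j}\left[W_{ij}\log (HH^\top)_{ij}
  - (HH^\top)_{ij}\right] + \beta \sum_{i,z} h_{iz}.$$

The damped multiplicative update

$$h_{iz} \leftarrow \frac{h_{iz}}{2} + \frac12 \,
  \frac{h_{iz}\sum_j W_{ij}h_{jz}/(HH^\top)_{ij}}
       {\sum_j h_{jz} + \beta/2}$$

preserves nonnegativity, locks exact zeros (why initializations must be
strictly positive), and in extensive property tests never increases the
objective (tolerance `1e-9` per step). Stopping follows
$\|H_l - H_{l-1}\|_1 < \rho$ with $\rho = 10^{-6}$, capped at 200
iterations.

### Initialization and restarts

The solver runs `restarts = 10` starts and keeps the lowest final cost:

* restart 1 is deterministic and spectrally informed — an NNDSVD-style
  start taking, for each of the $K$ leading eigenpairs of $W$, the
  dominant nonnegative part of the scaled eigenvector, with zeros floored
  at $10^{-3}\max(H)$ so the updates can still grow them;
* restarts 2…10 draw entries i.i.d. uniform on $(0,1]$, scaled so that
  $\mathrm{mean}(HH^\top) = \mathrm{mean}(W)$.

The spectral start exists because purely random restarts occasionally
*all* land in merged-cluster local minima on strongly block-structured
consensus matrices (observed at roughly one instance in twenty at desk
scale); the leading eigenvectors of a near-block-diagonal $W$ point at
the blocks, and cost-based selection still lets any random restart win
when it does better. The "ensemble-initial" variant instead starts from
a base partition via `init_from_partition()` (membership 1 for the
sample's cluster, floor $10^{-3}$ elsewhere) and runs a single start.

### Membership thresholding

`threshold_membership()` converts $H$ to binary memberships:
$h^*_{iz} = 1$ iff $h_{iz} \ge \tau$. Two modes exist because the raw
rule couples $\tau$ to the scale of $H$ (and hence to $\beta$):

* raw (`normalize = FALSE`, the function default): threshold the
  weights as they are;
* scale-invariant (`normalize = TRUE`, what the pipeline uses):
  rows are first scaled to unit maximum, so $\tau = 0.5$ reads "at least
  half as strong as the sample's best cluster".

Samples may pass the threshold in several clusters (overlap) or in none
(unassigned); empty clusters are dropped with a warning. The default
$\tau = 0.5$ under row-max normalization is a package choice — no
canonical value exists for the raw rule precisely because of the scale
coupling.

### Numerical choices

All logarithm arguments and denominators are floored at
$\varepsilon = 10^{-12}$ (the KL cost is undefined at
$(HH^\top)_{ij} = 0$), with $0\cdot\log(\cdot) := 0$. `K` defaults to 6,
matching the six meta-classes; `beta` defaults to 1.

## 4. Evaluation metrics

Reference clusters group samples sharing a meta-class (habitat
{gut, skin, oral} × gender {male, female}). The three scores are
*reconstructions from their one-line characterizations* in the
community-detection literature, not verbatim transcriptions of any
specific supplementary definition; each is an exported function so an
alternative definition can be swapped in:

* **f-measure** — a detected cluster matches a reference cluster when the
  neighbourhood affinity $|C_p\cap C_r|^2/(|C_p||C_r|)$ reaches
  $\omega = 0.25$; precision = matched detected / detected, recall =
  matched reference / reference, f = harmonic mean.
* **PR metric** — pairwise co-membership precision/recall (a pair is
  co-clustered if it shares at least one cluster, counted once under
  overlap), combined as harmonic mean.
* **F-score** — per reference class, the F1 of its best-matching
  detected cluster, averaged with weights proportional to class size.

All three equal 1 exactly when detection reproduces the reference and
are invariant to cluster order and labels. `composition_table()` and
`gender_variation()` produce the habitat/gender enrichment and
within-cluster same/opposite-gender similarity summaries; a gender side
with no pairs is reported as `NA` (absent), never as 0.

## 5. Synthetic data: what it emulates, and what it does not

Two generators provide planted ground truth:

* `planted_similarity()` — block-structured matrices with within-block
  entries $\mathcal{N}(\mu_{in},\sigma)$, between-block
  $\mathcal{N}(\mu_{out},\sigma)$, clipped to $[0,1]$, unit diagonal.
* `synth_profiles()` — a random bifurcating tree with $\mathrm{Exp}(1)$
  branch lengths; per meta-class a sparse Dirichlet center
  (concentration 0.1 over the leaves, so a few taxa dominate each class,
  as in real communities); per sample a Dirichlet draw with precision
  `dispersion` around its class center.

Defaults are fixed as the package's study conditions: 64 leaves, 120
samples apportioned over the six meta-classes proportionally to the
empirical 1920-sample cohort distribution (331/698/366/130/262/133,
giving 21/44/23/8/16/8 at $N = 120$), and `dispersion = 400`, chosen so
that within-class phylogenetic similarity sits near 0.9 — the magnitude
reported for real body-habitat communities (oral-cavity samples above
0.92). At these settings the full pipeline runs in seconds on a single
CPU; the acceptance-style tests use 10 seeds per condition and planted
solver instances with $N$ between 60 and 120.

What passing these studies does **not** show: the generator draws i.i.d.
samples around fixed class centers on a random tree — it has no
compositional zero-inflation, no sequencing-depth variation, no OTU-
picking noise, no shared structure between classes beyond chance, and
block-uniform similarity noise. Recovery at dispersion 400 therefore
demonstrates correctness of the machinery, not performance on real
cohorts, where class separation is weaker and similarity noise is
structured.

## 6. Pipeline defaults and auditability

`pipeline_config()` collects every tunable: `decay = 0.5`,
`edge_threshold = 0.7` (the lower end of the customary 0.7–0.9 sweep,
i.e. the least destructive), the default ensemble grid, `K = 6`,
`beta = 1`, `tau = 0.5`, `rho = 1e-6`, `max_iter = 200`,
`restarts = 10`. One master seed derives every stage seed, so a rerun is
byte-identical on disk. Per-restart costs are logged so the
lowest-cost-restart selection is inspectable, and every intermediate
(similarity, network, base partitions with a JSON provenance manifest,
consensus, $H$, clusters, report) is written in plain-text formats that
the package's own readers accept back.

## 7. Known limitations

* The EM base family is statistically fragile on very small networks
  (feature dimension = sample count); its failures are skipped by
  contract, so ensembles on tiny cohorts may contain no EM results.
* The solver's $K$ must be chosen by the user (default 6); there is no
  automatic model-order selection.
* The similarity scoring assumes profiles are comparable after L1
  normalization; compositional effects beyond that are out of scope.
* Pair-based metrics are quadratic in sample count; at desk scale this
  is irrelevant, but universes of $10^5$ samples would need a different
  evaluation path.
* Wall-clock performance is adequate for thousands of samples in the
  similarity stage (row-parallel), but the factorization keeps dense
  $N \times N$ matrices in memory.
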