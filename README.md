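# metaclust

Ensemble consensus clustering of metagenomic sample-similarity networks.

## What problem does this solve?

Large human-microbiome cohorts (gut, skin, oral-cavity samples from male
and female hosts) carry community structure that no single clustering
algorithm finds reliably: k-means, EM mixtures, hierarchical and
density-based clustering each impose different pattern assumptions on the
sample-similarity network, and each wins on some criteria and loses on
others. `metaclust` detects microbial community patterns by *agreement*:
it runs a whole grid of base clusterers, summarises how often each sample
pair co-clusters, and extracts possibly-overlapping communities from that
consensus. It is aimed at microbiome researchers who have a
samples-by-taxa relative-abundance table plus a phylogeny (or any
precomputed sample-similarity matrix) and want robust, meta-data-
interpretable sample clusters.

## The method

**Phylogenetic structure similarity.** Two normalized abundance profiles
are compared on their shared rooted tree. At each leaf the common
abundance is `min(a_x, b_x)`; unmatched residual abundance propagates to
the parent scaled by `decay^branch.length`, and at each internal node the
common abundance is the minimum of the two samples' arriving residuals.
The similarity is the total common abundance over all nodes:

```
Similarity(X) = CommonAbundance(X)                                  X a leaf
                CommonAbundance(X) + Sim(X.left) + Sim(X.right)     X internal
```

It lies in `[0, 1]`, is symmetric, and equals 1 for identical profiles.
With `decay = 0` it reduces to leaf-level (Bray–Curtis-style) overlap;
`decay = 1` is degenerate (every residual reaches the root, so every pair
scores 1), hence the default `decay = 0.5`.

**Generation phase.** The pairwise similarity matrix is thresholded into
a network; four base clustering families (EM Gaussian mixture, k-means,
average-linkage hierarchical, DBSCAN-style density) run over a parameter
grid (`k = 6..10`, several seeds, several density radii). The consensus
matrix is

```
W_ij = (# base results assigning i and j to the same cluster) / (# base results)
```

with noise samples co-clustering with nobody.

**Identification phase.** W is factorized as `W ≈ H Hᵀ`, `H ≥ 0` an
N×K soft membership matrix, by minimising the generalized
Kullback–Leibler cost with an L1 sparsity penalty:

```
min_{H ≥ 0}  −Σ_ij [ W_ij log (HHᵀ)_ij − (HHᵀ)_ij ]  +  β Σ_iz h_iz
```

via the damped multiplicative update

```
h_iz ← h_iz/2 + (1/2) · h_iz · Σ_j W_ij h_jz / (HHᵀ)_ij / (Σ_j h_jz + β/2)
```

iterated until `||H_l − H_{l−1}||_1 < ρ` (default `1e-6`, cap 200
iterations), over 10 restarts keeping the lowest cost. Rows of `H` are
scaled to unit maximum and thresholded at `τ = 0.5`: a sample may land in
several clusters (overlap) or in none (unassigned). Detected communities
are scored against the six habitat × gender meta-classes by three
metrics: cluster-level f-measure (neighbourhood-affinity matching,
ω = 0.25), pair-based PR, and size-weighted best-match F-score.

## Worked example

A synthetic 120-sample cohort with six planted meta-classes (sizes
apportioned 21/44/23/8/16/8 as in the reference 1920-sample cohort):

```r
library(metaclust)

sp  <- synth_profiles(n_leaves = 64, classes = 6, seed = 42)
cfg <- pipeline_config(abundance = sp$abundance, tree = sp$tree,
                       labels = sp$labels, seed = 42, verbose = FALSE)
res <- run_pipeline(cfg)

res$fit
#> <symnmf_fit> N = 120, K = 6, beta = 1: cost 4129.3 after 200 iterations (iteration cap), restart 6/10
res$community
#> <community> 6 clusters over 120 samples (0 unassigned)
#>   sizes: 21, 23, 16, 44, 9, 16

cat(sprintf("f-measure %.3f | PR %.3f | F-score %.3f\n",
            res$report$f_measure$f, res$report$pr_metric, res$report$f_score))
#> f-measure 0.909 | PR 0.980 | F-score 0.956

res$report$composition
#>          male_gut male_skin male_oral female_gut female_skin female_oral
#> cluster1       21         0         0          0           0           0
#> cluster2        0         0        23          0           0           0
#> cluster3        0         0         0          8           0           8
#> cluster4        0        44         0          0           0           0
#> cluster5        0         9         0          0           0           0
#> cluster6        0         0         0          0          16           0
```

Five of the six meta-classes come out pure; the two smallest female
classes (8 samples each) merge into `cluster3`, which is what the
f-measure's 0.909 reflects. `res$report$gender_variation` summarises
within-cluster similarity split by gender agreement.

The same pipeline is scriptable from a shell via the thin CLI installed
under `exec/`:

```sh
metaclust synth --mode profiles --out-dir fx --seed 7
metaclust run --abundance fx/abundance.tsv --tree fx/tree.nwk \
              --labels fx/meta.tsv --out-dir results/
```

## Vignette

`vignettes/metaclust-methods.Rmd` documents the model, the tunable
parameters and their defaults, the synthetic-data generator and its
limits, numerical choices, and known limitations.
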