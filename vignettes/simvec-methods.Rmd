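---
title: "Methods: similarity-enhanced knowledge-graph embeddings for polypharmacy prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity-enhanced knowledge-graph embeddings for polypharmacy prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`simvec` predicts polypharmacy side effects as multi-relational link
prediction on a heterogeneous knowledge graph of drug and protein nodes.
Every entity $i$ carries a triple of embedding parts
$\Theta_E(i) = \{e_i^1, e_i^2, e_i^3\}$ and every relation $j$ a triple
$\Theta_R(j) = \{w_j^1, w_j^2, w_j^3\}$, each part a length-$K$ real
vector. A triple $(s, p, o)$ is scored trilinearly,

$$\phi_{spo} = \sum_{k=1}^{K} e_s^1 w_p^1 e_o^3 + e_s^2 w_p^2 e_o^2 +
e_s^3 w_p^3 e_o^1,$$

an asymmetric tensor factorization in the DistMult/ComplEx family. Training
minimizes, per positive triple, the two-sided softmax ranking loss

$$L_{spo} = -\phi_{spo} + \log\!\sum_{o'} e^{\phi_{spo'}}
           -\phi_{spo} + \log\!\sum_{s'} e^{\phi_{s'po}}
           + \tfrac{\lambda}{3}\sum_{k}\sum_{m=1}^{3}
             \left(|e_s^m|^3 + |w_p^m|^3 + |e_o^m|^3\right),$$

where the candidate sets $\{o'\}$, $\{s'\}$ are the sampled corruptions of
that slot plus the true entity (a full-vocabulary softmax is
configuration-optional and unnecessary at the graph sizes we target). The
loss as written subtracts $\phi_{spo}$ once per side; with the true entity
included in each candidate set this is exactly the standard two-sided
softmax cross-entropy. Gradients of all loss terms are derived analytically
(the score is multilinear, so each part's gradient is an elementwise
product of the other two parts) and verified against central finite
differences in the test suite; optimization uses Adam.

### Why plain embeddings fail for new drugs

A drug with no training-set side-effect edges receives gradient only from
its (few) target edges, if any; its embedding stays near random
initialization, and every test triple involving it is scored essentially at
chance. The *weak-nodes split* makes this failure measurable: the $N$
drugs of lowest drug–drug degree are declared weak, every side-effect
triple touching them is removed from training, and those $M$ "weak
triples" are divided equally between test and validation (test receives
the extra triple when $M$ is odd). The split builder reports the realized
$M$ rather than enforcing a target, since $M$ is a consequence of $N$ and
the degree distribution.

### The three enhancements

1. **Chemical initialization.** Drug parts start from a 100-dimensional
   chemical profile — a folded circular (Morgan-type, radius 3)
   fingerprint, a standardized molecular-descriptor vector, or an external
   (e.g. hyperbolic VAE) embedding read from a table — copied into all
   three parts, rescaled to the Xavier standard deviation $1/\sqrt{K}$,
   plus 1 % seeded Gaussian jitter so chemically identical twins can still
   diverge during training. Copy-plus-rescale preserves the chemical
   geometry while keeping optimization conditioned like a random init.
2. **Weighted similarity edges.** A single additional relation links every
   drug pair. Under the proportional scheme the weight is
   $\mathrm{sim}(h,t)\,\mathrm{InvDeg}(h)\,\mathrm{InvDeg}(t)$ with
   $\mathrm{InvDeg}(x) = 1 - (deg_x - \min_i deg_i)/(\max_i deg_i -
   \min_i deg_i)$; under the window scheme the weight is
   $\exp(-\lVert h - t\rVert^2 / w(h,t)^2)$ with
   $w(h,t) = l + \mathrm{InvDeg}(h)\mathrm{InvDeg}(t)(u - l)$, so weakly
   connected pairs get a wider, more permissive kernel. Degrees are
   computed on the *training* drug–drug triples only — the enhancement
   must not leak held-out edges. During training these edges contribute a
   second loss pass, each edge's ranking loss scaled by its weight.
3. **Weak-node anchoring.** Each training-time weak drug (bottom 1/6 by
   train drug–drug degree, mirroring the split's $N \approx$ 1/6 of
   drugs) is pulled by an MSE loss toward the element-wise mean of the
   concatenated parts of its 6 non-weak drugs sharing the most mono
   (single-drug) side effects, ties broken by external id. The anchors are
   detached: gradient flows only into the weak drug, so well-trained
   embeddings are targets, not co-trained. Comparing to the neighbor
   *mean* (rather than each neighbor individually) was an open design
   choice; the mean is smoother and makes the 6-neighbor count an explicit
   bias–variance knob.

### Negative sampling

Uniform corruption replaces head or tail (fair coin) by a same-kind
entity, rejecting known positives with a bounded retry. Bernoulli
corruption chooses the slot with probability
$tph/(tph+hpt)$ from the relation's cardinality statistics. The cache
samplers maintain per-$(h,r)$ tail and per-$(r,t)$ head caches of hard
corruptions: each epoch, `n_random` fresh candidates (doubled for the
exploration variant) are scored together with the cache and `cache_size`
entries are retained by importance sampling proportional to the softmax of
their scores — stochastic retention follows the balanced NSCaching scheme
rather than a strict top-k, which would collapse cache diversity. Strong
NSCaching additionally redirects a weak drug's lookup to the cache keys of
its nearest strong neighbor in descriptor space with probability
$p(h) = 1/\log(deg_h)^\alpha$ (natural log; degree clamped to $\ge 2$ and
$p$ capped at 1, so degree-1 nodes redirect with certainty); both the
head and the tail key are redirected when the weak drug occupies the
corrupted slot. Similarity edges form a near-complete graph, so their
step-2 corruptions are random drug pairs without the positive filter —
"negative" there means "a random, typically less similar pair".

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `K` | 100 (64 in the desk benchmark) | embedding length per part |
| `lambda` | 0.01 | N3 regularization weight |
| `learning_rate` | 0.001 (0.005 baseline) | Adam step size |
| `early_stop_epsilon`, `patience` | 0.001, 7 | early stopping on validation macro ROC AUC |
| `batch_size` | 512 | minibatch size |
| `neg_ratio` | 1 (6 for the 6:1 cache variant) | negatives per positive |
| `cache_size`, `n_random` | 30, 30 | cache capacity and refresh draw |
| `alpha` | 1/3 | strong-redirect decay exponent |
| `n_sim_neighbors` | 6 | anchors per weak drug |
| `sigma` | $\sqrt{K_{chem}}$ | Gaussian kernel width on standardized descriptors |
| `l_bound`, `u_bound` | 1, 4 | window bounds in standardized descriptor distance |

The cache parameters and the window bounds have no canonical published
values; the defaults were fixed once at values that are conventional for
cache-based samplers (cache and refresh of equal, modest size) and that
bracket typical pairwise distances of standardized descriptors, and are
all configuration-exposed. The Gaussian width $\sqrt{K_{chem}}$ makes the
expected squared distance between independent standardized vectors of
order $\sigma^2$.

## Evaluation protocol

For each side-effect relation, every held-out positive is paired with one
uniformly corrupted negative, filtered against all known positives and
frozen under a seed so repeated evaluations (and the early-stopping
trajectory) are comparable. Per-relation ROC AUC (Mann–Whitney with
midranks) and average precision are macro-averaged with equal relation
weight; FPR/FNR are pooled over relations at the $\mathrm{sigmoid}(\phi) >
0.5$ decision threshold (threshold exposed). The ROC statistic is
cross-checked against `pROC` in the tests; average precision is computed
internally (no PR-curve package is required at run time). Since no
published test-negative protocol exists for this task beyond "one negative
per positive", the frozen-seed filtered protocol is this package's
reproducibility choice.

## The synthetic benchmark

`synth_spec()` / `make_benchmark()` generate a Decagon-shaped input at
desk scale — 60 drugs, 200 proteins, 8 side-effect relations, 20 mono
side effects by default. Drugs belong to 6 latent chemical clusters;
features are cluster prototypes (bit density 0.25) with 8 % bit flips, so
within-cluster Tanimoto similarity is high. Per-drug edge propensities
follow a power law (exponent 2), guaranteeing a weak tail. With
probability `signal_strength` (0.9 in the benchmark) an edge's partner is
drawn proportionally to sharpened pairwise Tanimoto similarity, planting
the chemistry→side-effect signal; mono side effects are cluster-correlated
(0.55 within vs 0.08 across), so shared-mono-neighbor counts track the
same latent structure. Protein–protein and drug–target edges are uniform
noise.

What the generator emulates: the heterogeneous schema, the skewed degree
distribution with a weak tail, multiple side-effect relations, and a
recoverable correlation between chemistry and shared side effects. What it
does not: the scale of the real deposit (645 drugs, 19 081 proteins, 963
side-effect relations), realistic molecular structure (synthetic drugs
carry raw binary features in place of SMILES; a real-featurization path is
exercised separately on a small molecule set), relation-specific
chemistry, or the empirical degree law of curated pharmacovigilance data.
Passing the benchmark therefore demonstrates that the implementation
recovers a planted weak-node signal under controlled conditions — not
that it attains any particular accuracy on the real deposit.

## Numerical choices and degenerate inputs

* Tanimoto of two all-zero vectors is defined as 1 (two featureless
  objects are indistinguishable; avoids 0/0).
* All drug degrees equal makes InvDeg degenerate; it returns 1 for every
  drug with a warning.
* The printed Lorentz similarity can exceed 1 for a point with itself
  (self inner product $-1$ against a positive normalizing maximum); it is
  implemented exactly as defined, not clipped, and a zero normalizing
  maximum raises a degenerate-geometry error.
* Drugs with missing or unparseable SMILES get the zero fingerprint /
  column-mean descriptor fallback, with a warning; descriptor ties on
  distinct-value counts break alphabetically.
* Degree ties in the weak-drug sort break by ascending external id, then
  entity id, making splits byte-reproducible.
* An odd number of weak triples sends the extra triple to test.
* Log-sum-exp is computed with the max-subtraction trick; non-finite
  training loss aborts with diagnostics.
* Cache retention with fewer candidates than `cache_size` keeps all;
  `n_random = 0` leaves a cache unchanged.

## Problem sizes

The shipped tests and the acceptance script run the benchmark at 60 drugs
/ 200 proteins / 8 relations with $K = 64$ and at most 40 epochs, five
seeds — sizes chosen so the full grid (two models × two splits × five
seeds) completes in a few minutes on a single core while leaving the
weak-node effect far larger than its seed-to-seed variability.

## Known limitations

* The all-pairs similarity edge set is quadratic in the number of drugs;
  `min_weight` pruning is provided but off by default to match the
  complete-graph formulation.
* The Stay Positive regularizer (a no-negative-sampling alternative) is
  out of scope: no usable formula is available, only its citation.
* The hyperbolic VAE that produces external embeddings is consumed, not
  trained, here.
* Strong NSCaching redirects both cache keys of a weak drug; published
  descriptions leave the one-sided alternative open, and our tests do not
  discriminate between the two.
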