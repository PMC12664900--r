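---
title: "Hyperspherical contrastive co-embedding and artificial pairing: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspherical contrastive co-embedding and artificial pairing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Joint multiomic assays measure two or three modalities — typically gene
expression (RNA), chromatin accessibility (ATAC), and sometimes surface
epitopes — in the same single cells, but they are expensive and noisy
compared to unimodal experiments. `spherepair` addresses the *bridge
integration* problem: given one paired dataset (the bridge), learn a common
embedding space for all modalities, project independent unimodal datasets
into that space, and then *artificially pair* unimodal profiles that appear
to come from the same cell state, producing synthetic multiomic cells at
unimodal cost.

The package consumes per-modality low-dimensional representations
$Y^{(m)} \in \mathbb{R}^{C \times r_m}$ (PCA scores, LSI components, VAE
latents, transformer embeddings) rather than raw counts; computing those
representations is deliberately upstream. Raw counts enter only through the
optional count decoders used for cross-modal imputation.

## The model

Each cell is assumed to have a latent state $z$ on the unit hypersphere
$S^{d-1}$ (default $d = 10$). Per modality, an encoder (one hidden layer of
128 units with layer normalization and ELU, then an affine head followed by
L2 normalization) maps $y^{(m)}$ to a direction $\mu^{(m)} \in S^{d-1}$. A
separate network maps the concatenation of all modalities to a positive
concentration $\kappa$ (softplus head). The variational posterior is the
Power Spherical distribution $\mathrm{PS}(\mu, \kappa)$ with density
$\propto (1 + \mu^\top z)^\kappa$; its normalizer, entropy and the KL
divergence to the uniform prior on the sphere are closed-form in
log-gamma/digamma terms, and sampling costs one Beta draw, one uniform
subsphere draw and a Householder reflection per cell — no rejection step,
which is why this family is preferred over von Mises–Fisher here.

The posterior direction is obtained from the per-modality directions by a
dropout-derived merge: during training each coordinate is copied from one
modality chosen independently and uniformly at random (probability $1/M$
each); at evaluation the coordinate-wise mean is used (the expectation of
the random mask). Because neither operation preserves unit norm, the merged
vector is renormalized before it parameterizes the posterior.

Training minimizes, over encoders and decoders,

$$-\mathcal{L}_{\mathrm{ELBO}} + \sum_{m_1 \ne m_2} \mathcal{L}_{m_1,m_2}
  + \mathcal{L}_D + \mathcal{L}_A + \mathcal{L}_B,$$

while the discriminators maximize $\mathcal{L}_D + \mathcal{L}_B$
(alternating updates, one discriminator step per encoder step). The parts:

* **ELBO** — closed-form KL to the uniform prior plus reconstruction
  log-likelihood of each $y^{(m)}$ under a unit-variance Gaussian decoder
  applied to a single posterior sample. With count decoders enabled, RNA
  counts add a negative binomial term (per-gene dispersion shared across
  cells, softmax mean scaled by the observed library size) and binarized
  ATAC counts add a Bernoulli term.
* **Contrastive** — for every ordered modality pair, a temperature-scaled
  cross-entropy over the $N \times N$ cosine-similarity matrix of a
  minibatch, positives on the diagonal. The temperature is learned in log
  space (init 0.07, clamped to $[10^{-3}, 100]$).
* **Adversarial** — a modality discriminator ($M$-class) and a batch
  discriminator ($B$-class) read every direction; encoders are trained to
  fool them. Batch labels feed only the discriminator — the inputs are
  assumed batch-corrected.
* **Alignment** — negative mean pairwise cosine similarity of matched
  directions.

All auxiliary weights default to 1 (the objective is stated unweighted);
they are exposed in `model_config()` because the sensitivity of the method
to them is itself of interest (the acceptance tests check the direction:
removing the contrastive term degrades held-out alignment).

## Gradients, initialization, and the collapse trap

There is no automatic differentiation here; every backward pass is written
by hand and verified against central finite differences in the test suite
(`test-model.R`, relative error $\le 10^{-4}$ per parameter probed; in
practice $\sim 10^{-8}$).

Two details matter for the concentration parameter:

* $\mu$ receives the full pathwise gradient of the reconstruction terms
  through the Householder reflection that maps the north-pole sample frame
  onto the merged direction.
* $\kappa$ receives the closed-form KL gradient
  $\kappa(\psi_1(\alpha) - \psi_1(\alpha + \beta))$ **and** a pathwise
  sampling gradient obtained by implicit reparameterization of the Beta
  marginal: holding the drawn quantile fixed,
  $\partial u / \partial \alpha = -\frac{\partial F / \partial \alpha}{f(u)}$,
  with $\partial F/\partial \alpha$ evaluated by a central difference of
  the Beta CDF. Without this term the only force on $\kappa$ is the KL,
  which always points downward, and the posterior collapses.

Even with correct gradients, early training can fall into the collapsed
optimum ($\kappa \to 0$, decoders ignore the latent) because the decoders
are uninformative at initialization. Two standard measures are used: the
$\kappa$-head bias is initialized so $\kappa \approx 10$ at the start, and
the KL weight is annealed linearly from 0 to 1 over the first half of
training. Both affect only optimization; the final objective is unchanged.

## Artificial pairing

Projected unimodal datasets are matched on the sphere. The candidate graph
keeps an edge between cells $i$ and $j$ only when
$\cos(z_i, z_j) \ge 1 - \varepsilon$; pruned edges are truly absent, so a
cell without a sufficiently similar partner stays unpaired rather than
being force-matched. The maximum-weight matching over surviving edges is
solved exactly (`igraph`'s weighted bipartite matching; the tests verify
exact agreement with an exhaustive permutation oracle). $\varepsilon$ has
no universal default and is a required argument in the CLI; values in the
0.02–0.1 range are sensible starting points, with smaller values for data
containing similar-but-distinct states along differentiation trajectories.
Note that at larger $\varepsilon$ ($> 0.5$, far outside the useful range) a
heavier edge can in principle displace two lighter ones, so the
pair-count-vs-$\varepsilon$ monotonicity checked in the tests is a property
of the practical regime.

For datasets too large for one assignment problem, `chunked_assign()`
splits both sides into random disjoint chunks (seeded permutation, then
contiguous blocks, independently per partition, default 10,000 cells) and
solves each chunk pair; the union is a valid matching whose weight is at
most the global optimum, and it converges to `assign_pairs()` as the chunk
size reaches the dataset size.

Tripartite matching is NP-hard, so three-modality pairing uses a
randomized greedy algorithm: draw a cell at random from the smallest
modality, pick the partner pair maximizing the triplet similarity (sum of
the three pairwise cosines), remove all three, repeat. The published
description leaves two details open, and this implementation reconstructs
them as follows: a drawn cell whose best triplet falls below `min_trisim`
is removed and left unpaired (the loop continues, so one bad draw cannot
terminate the whole pairing), and when the remaining candidate product
exceeds 20,000 the argmax is restricted to the drawn cell's top 50
neighbors in each modality. Greedy matching is near-optimal when the three
sets are noisy views of a common structure — the only regime the method
encounters in practice — and the acceptance test measures it there
(tangential noise 0.2, matched cosines ≈ 0.95); on three mutually
unrelated random clouds its ratio to the optimum is unstable because the
optimum itself is near zero. When two of the three modalities are already
paired, `paired_plus_one_assign()` reduces the problem to bipartite
matching under the summed similarity with cutoff $2 - \varepsilon$, solved
exactly.

## Metrics

`foscttm()` (fraction of samples closer than the true match, averaged over
both directions; ties at the true-match distance do not count, so identical
embeddings score exactly 0), `graph_ilisi()` (inverse Simpson index of
label proportions in kNN neighborhoods, $k = 90$ by default),
`knn_accuracy()` with the standard $k$ grid (5, 17, 29, 41, 53, 65) plus
cross-batch and 10-fold drivers, `trisim()` / `trisim_percentile()`
(exhaustive up to $10^6$ candidate pairs per cell, seeded subsampling
beyond), `pairing_consistency()` (share of pairs whose two cells carry the
same label, with a configurable denominator for downsampling protocols) and
`cluster_similarity()` (ARI and arithmetic-normalized NMI from the
contingency table). Distances on the sphere are Euclidean on unit vectors —
rank-equivalent to cosine. kNN vote ties go to the class of the nearest
neighbor among the tied classes: unlike a label-name tie-break this is
invariant under renaming the classes, which the test suite checks.

## The synthetic generator

`simulate_multiome()` / `simulate_trimodal()` produce the ground-truth data
all tests run on. Type centroids are drawn uniformly on the latent sphere
under a minimum-angle rejection rule (`type_separation`, default 1.0 rad);
cells perturb their centroid tangentially (`within_type_sd`, default 0.3)
and are re-projected; each modality observes the latent through a random
linear map scaled to give embedding coordinates unit variance — the scale
of real PCA/LSI/VAE representations, and the scale the unit-variance
Gaussian decoder implicitly assumes (at a much smaller embedding scale the
reconstruction term cannot repay the KL cost of a concentrated posterior,
and collapse becomes the *correct* optimum) — plus Gaussian noise
(`noise_sd`, default 0.1) and optional per-batch shifts. RNA counts are
negative binomial with softmax-mapped means, log-normal library sizes
(meanlog 8.5, sdlog 0.35) and per-gene dispersions uniform on [2, 10]; ATAC
counts are Bernoulli draws from sigmoid-mapped probabilities with sparse
intercepts. Batch shifts are applied in embedding space, not count space,
because the model consumes batch-corrected embeddings; raising
`batch_effect_sd` simulates *uncorrected* batches to exercise the batch
discriminator.

What passing tests on this generator do **not** show: robustness to
non-linear modality relationships, to systematic (non-Gaussian) embedding
artifacts, to doublets or ambient contamination, or to cell populations
present in one modality only. The generator is linear-Gaussian by
construction; real chromatin data in particular violate this in ways no
synthetic benchmark here captures.

`make_bridge_split()` reproduces the bridge/test protocol (disjoint split,
independently shuffled unimodal orders, a truth table of true partners);
`downsample_celltype()` and `make_dominant_type()` implement the
rare-type and dominant-type robustness manipulations.

## Problem sizes and numerical choices

The reference validation run uses 4,000 simulated cells (8 types), 3,000 as
the bridge and 1,000 held out, trained 100 epochs at the default minibatch
size of 2,000 — sizes chosen so the whole suite, including two repeat
trainings and an ablation, completes comfortably on a single CPU while
leaving wide margins on every threshold (held-out FOSCTTM $\le 0.1$,
cross-modal 5-NN accuracy $\ge 0.9$, type-consistent pairing $\ge 0.9$).
The trimodal validation uses 1,500 cells and 6 types with triplet
percentiles evaluated on 300 cells.

Numerical guards: $\kappa$ clamped to $[10^{-6}, 10^6]$, all normalizers in
log space, log-sum-exp with row-max subtraction everywhere a softmax
appears, Bernoulli probabilities clamped to $[10^{-8}, 1-10^{-8}]$, NB
means floored at $10^{-10}$, merged directions renormalized with an error
on zero-norm rows, and a hard abort naming the offending loss term if any
objective component turns non-finite during training. "Learning-rate decay
0.00006" is interpreted as additive L2 weight decay in Adam (the common
reading in this model family); a multiplicative schedule is available via
`decay_mode = "lr_schedule"`. One posterior sample per cell is used for the
ELBO expectation, as is standard for VAEs.

## Known limitations

* Exact assignment is $O(n^2)$ in memory for the similarity matrix;
  beyond ~$10^4 \times 10^4$ cells use `chunked_assign()` (the same
  trade-off the chunking approximation was designed for).
* Imputed counts are decoder means/probabilities, not sampled counts, and
  library sizes for imputed cells fall back to the training median.
* $\kappa$ is only defined when all modalities are present (its network
  reads the concatenation), so projection of unimodal data yields
  directions only — pairing and metrics use directions alone by design.
* The checkpoint format is an RDS archive: portable across platforms for
  practical purposes, but not a language-neutral interchange format.
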