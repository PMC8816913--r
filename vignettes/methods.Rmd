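---
title: "Differentially private federated learning for histopathology bags: models, accounting, and synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentially private federated learning for histopathology bags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpfedmil)
```

## The problem

A whole-slide image (WSI) is a gigapixel scan of a stained tissue section.
Slide-level labels (here: lung adenocarcinoma, LUAD, versus squamous cell
carcinoma, LUSC) attach to the slide, not to any particular region, which
makes slide classification a multiple-instance learning (MIL) problem: a
slide is a *bag* of patch feature vectors, and only some unknown subset of
patches carries the diagnostic signal. Hospitals cannot freely pool such
data, so we study the decentralized setting: several hospitals (clients)
jointly train one model by federated averaging (FedAvg), optionally under
differential privacy (DP-SGD locally), and we quantify the privacy with a
Rényi differential-privacy accountant.

This package implements the full pipeline — bag preparation, the
permutation-invariant set classifier, local (DP-)SGD, federation, and
accounting — and exercises it end to end on synthetic data, so every stage
is testable without any image download or pretrained network.

## Bag preparation

A slide-like image becomes a bag in four steps: (1) a tissue mask by colour
thresholding (luminance below a cut-off, default 0.8 — stained tissue is
darker than the bright glass background); (2) a non-overlapping row-major
grid of square patches, keeping patches whose mask coverage is at least 0.5;
(3) k-means clustering of patch descriptors (mean colour plus an intensity
histogram) into a preset number of groups; (4) sampling
`ceiling(fraction * cluster size)` patches per cluster (default 10%) into a
*mosaic*, whose patches are mapped to feature vectors by a pluggable
extractor.

Choices worth stating because the procedure leaves them open:

* *Tiling.* Coordinates are 0-based with half-open patch intervals and no
  overlap; a grid is the simplest reproducible convention.
* *Rounding.* The per-cluster sample size uses the ceiling so that no
  non-empty cluster disappears from the mosaic; consequently
  `n_clusters <= |mosaic| <= ceiling(fraction * N) + n_clusters`.
* *Clustering.* The clustering algorithm, its feature space and the cluster
  count are configuration, not doctrine; k-means with 10 restarts under a
  fixed seed is deterministic and adequate for the separable descriptors the
  generator produces.
* *Features.* The default extractor is a fixed-seed random projection of
  per-channel intensity histograms and moments. It is deterministic and
  dimension-stable, and it is *not* a stand-in claim about pretrained CNN
  features: it exists so the pipeline's plumbing (shapes, order,
  reproducibility) is testable. Patch size defaults to small tiles suitable
  for fixtures; real slides would use 1000-pixel tiles.

## The set classifier

A bag is an `n x f` matrix `X`. A *memory unit* with embedding matrix
`A_i` (`f x d`) and nonlinearity `rho` computes

    U_i = rho(X A_i)                      (n x d, not normalized)
    S_i = column-wise-softmax(U_i U_i')   (n x n)
    p_i = row-wise-average(S_i)           (length n, sums to 1)

so `p_i` is an attention distribution over instances: the cross-correlation
of embedded instances, normalized per column and averaged. Memory vectors
are deliberately not normalized — magnitude carries information through the
cross-correlation. The *column-wise* convention means the softmax normalizes
over the first index of `U_i U_i'`; the row average then yields a length-`n`
probability vector (conventions vary, so this is fixed here explicitly and
tested).

A *memory block* holds `m` such units plus a per-instance linear
encoder/decoder (`f -> h -> f`). The encoder output `C` is permutation
equivariant; the block output stacks `xhat_i = sum_j p_i[j] C_j`, an `m x h`
matrix invariant to instance order. Blocks can be stacked (the output
sequence feeds the next block). The head concatenates the final `m x h`
output and applies one dense layer with a two-class softmax.

The loss is mean cross-entropy plus `lambda_rec` (default 0.1) times the
mean encoder-reconstruction error. The decoder is trained, not constrained:
invertibility is encouraged, never enforced. All gradients are derived by
hand and verified against central finite differences (relative error below
1e-4 on small models; in practice ~1e-10).

Defaults the source material leaves unstated, chosen here once: `rho = tanh`
(bounded and smooth, which keeps finite-difference verification well
conditioned), one block with `m = 2`, `d = 4`, `h = 8` at desk scale,
scaled-Gaussian initialization with standard deviation `1/sqrt(fan-in)`
under a fixed seed, and the concatenating linear head (the simplest head
that preserves permutation invariance).

## DP-SGD and the accountant

A DP-SGD step splits the batch into microbatches (reference setting: batch
32, 32 microbatches of size one), clips each microbatch gradient to global
L2 norm `C` (one bound across all parameter arrays), sums, adds one draw of
per-coordinate Gaussian noise with standard deviation `sigma * C`, divides
by the microbatch count, and feeds the result to SGD or Adam. Noise is added
once to the sum — the construction the accountant prices. With `sigma = 0`,
`C = Inf` and one microbatch the step is bit-identical to plain training,
which the tests assert exactly.

The accountant composes the Rényi divergence of the Poisson-subsampled
Gaussian mechanism: for integer order `alpha`,

    RDP(alpha) = log( sum_k C(alpha,k) (1-q)^(alpha-k) q^k
                      exp(k(k-1)/(2 sigma^2)) ) / (alpha - 1),

evaluated in log space; non-integer orders evaluate the same moment by
numerical integration with a log-space shift. Composition over `T` steps is
linear in the RDP curve, and the conversion to `(epsilon, delta)` uses the
classical bound `epsilon = min_alpha T*RDP(alpha) + log(1/delta)/(alpha-1)`
over the order grid `{1.25, 1.5, 1.75, 2, 2.25, 2.5} ∪ {3..256}` — the grid
and conversion used by the standard accountant implementations of the
study's era, rather than newer, tighter conversions. Steps are
`T = round(epochs * N / B)`; a one-step difference moves epsilon negligibly.

Two modelling notes. First, training shuffles fixed-size minibatches while
the accountant models Poisson subsampling at rate `q = B/N`; this is the
standard, universally used mismatch. Second, accounting treats the
federation's data as one pooled dataset (`N` = the pooled training size), as
the reference configuration's "training set size" indicates; a per-client
mode is available by passing a client's own `N`.

Under this standard accounting the privacy budget cannot depend on the clip
norm — the noise scales with the sensitivity, so `C` cancels. The ablation
table states this explicitly in its output. Published clip-norm ablations
that show clip-dependent budgets at a fixed noise multiplier cannot be
produced by any standard subsampled-Gaussian accountant (we verified that no
`(q, T, delta)` configuration reproduces them jointly); this package reports
what the accountant computes.

## Federation

FedAvg: per round, broadcast the central weights; each client trains
`local_epochs` epochs locally; the server takes the sample-size-weighted
mean of the returned parameter vectors. All clients participate every round.
Client shuffle streams are keyed by `(client, epoch index)`, with the epoch
index continuing across rounds — hence a one-client federation reproduces
centralized training exactly (tested as bit equality), and runs are
reproducible regardless of scheduling.

Partitions: IID splits shuffle each class and deal round-robin (per-class
sizes within one; the deal start rotates across classes so totals also stay
within one). Non-IID partitions draw one Uniform(0,1) value per client and
class, normalize to a probability vector, and sample each bag's client from
it — heavy class skew across clients is the norm, including empty clients,
which the federation loop skips with weight zero.

Evaluation: the central model is evaluated on every client's held-out split
each round; experiment tables report the final round. For the
federated-versus-local comparison the headline numbers score *all* models on
the shared pooled test set (union of the per-client test splits). The
alternative — scoring each local model on its own skewed test split — is
also reported (`*_own` columns), but it flatters non-collaborative training:
a client that mostly holds one class can look strong by predicting that
class, which says nothing about its model's general performance.

## What the synthetic generator emulates — and what it does not

A bag draws its size uniformly from 20–50 instances of dimension 16.
Background instances are isotropic Gaussian noise (sd 1.0); a fraction
(default 0.2) of instances additionally shift by ±`class_separation/2`
along a fixed unit direction according to the bag label — the simplest
structure in which only some instances are informative, so attention-based
pooling is identifiable. Clients receive an additive constant feature-shift
vector (stain-like covariate shift; magnitude 0.4 for federation clients,
1.2 for external-validation hospitals, where shifts are plausibly larger).
The four-client cohort reproduces the study's hospital table exactly: totals
267/211/207/199 with LUAD counts 189/94/90/121, whose floored 80% splits
pool to 705 training bags.

The default class separation of 2.0 was set, once, so that the pooled task
is learnable but not trivial — a mean-pool oracle classifier sits near 0.9,
the scale of the centralized accuracies the study reports — leaving room for
the sample-size effects that federation is meant to demonstrate. Per-bag
randomness comes from substreams keyed by (client, bag index), so generated
data are independent of generation order.

What passing tests on this generator do *not* show: anything about real
stain chemistry, texture, spatial correlation between patches, label noise,
or pretrained-feature geometry. Synthetic trends are direction-level
evidence about the *pipeline*, not about histopathology accuracy; absolute
accuracies here are not comparable to published real-data numbers.

## Desk-scale experiment design

Series 1 uses 400 pooled bags, client grids n in {4, 8}, and 60
communication rounds of one local epoch, with non-collaborative and
centralized baselines given the same total epoch budget
(`rounds * local_epochs`). Sixty rounds is the point where the desk-scale
FedAvg model reaches its own convergence plateau; at half that schedule the
central model is still visibly climbing (0.78 versus 0.90 for centralized at
the matched budget) and the federated-versus-local comparison measures
optimization shortfall rather than the converged behaviour of interest (the
study itself ran 250 rounds). Five replicate seeds; tables report mean ±
standard deviation across replicates.

Series 2 runs the four-hospital cohort with DP-SGD (clip 1.0, noise
multiplier 4.0, 32 microbatches), plain FedAvg, non-collaborative and
combined baselines, evaluates on internal test splits and the pooled
external cohort, and prices the DP configuration from the realized pooled
training size. At desk scale we keep SGD with learning rate 0.01: the
reference Adam learning rate of 2e-5 belongs to the real-data feature scale
and barely moves this small model in 60 rounds.

Numerical choices: softmax columns are max-shifted before exponentiation;
cross-entropy clamps probabilities at 1e-300; k-means inputs receive
1e-9-scale jitter to break exact duplicates; zero-gradient clipping is a
no-op (`min(1, C/0) = 1`); degenerate inputs (empty bags, empty mosaics,
empty clients, zero epochs, zero steps) either error with a clear message or
return the documented neutral value.

## Known limitations

* The accountant prices the idealized Poisson-subsampled mechanism, not the
  shuffled minibatch sampler actually used (standard practice, but a real
  gap).
* The bijective transformation is linear; "bijective" holds only
  approximately and only as encouraged by the reconstruction penalty.
* Trend checks are desk-scale and stochastic: they assert directions across
  replicate seeds, not published accuracy values, which depend on real
  slides and pretrained features.
* The default feature extractor is a deterministic stand-in; plugging in a
  learned extractor changes bag geometry and may require retuning the model
  defaults.
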