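---
title: "Bayesian fuzzy clustering with owbfc: model, inference and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian fuzzy clustering with owbfc: model, inference and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owbfc)
library(dplyr)
```

## The model

Fuzzy clustering assigns each sample a membership vector on the probability
simplex rather than a hard label. `owbfc` treats this as a probability model
with three ingredients.

**Fuzzy data likelihood.** Each sample $x_k \in \mathbb{R}^D$ is tied to every
cluster center $c_n$ through a Gaussian whose isotropic precision is the
membership raised to the fuzzy index, $u_{kn}^m I$. Up to constants the log
likelihood kernel is

$$\log p(X \mid U, C) \doteq -\tfrac12 \sum_{k=1}^K \sum_{n=1}^N
  w_k\, u_{kn}^m \lVert x_k - c_n \rVert^2 ,$$

where $w_k > 0$ is a per-sample weight (all ones for raw data). The weights
are what let a handful of *representative points* stand in for the many
samples they summarise in the online framework below.

**Membership prior.** Membership rows carry a Dirichlet$(\alpha)$ prior. The
Dirichlet also serves a structural purpose: the fuzzy likelihood's awkward
normalisation constant cancels exactly against a compensating factor in the
prior, so it never has to be evaluated. What survives in the log domain is
the Dirichlet kernel $\sum_{k,n} (\alpha_n - 1) \log u_{kn}$.

**Center prior.** Centers are a priori Gaussian, $c_n \sim N(\mu_c,
\Sigma_c)$, with $\mu_c$ the (weighted) data mean and $\Sigma_c = \gamma/K
\sum_k (x_k-\mu_c)(x_k-\mu_c)^\top$ — an empirical prior whose strength is
controlled by $\gamma$. A ridge $10^{-8}\max(\mathrm{tr}\,\Sigma_c/D,1)\,I$
is always added so the precision exists even for degenerate data (a constant
image, identical rows).

Maximum a posteriori (MAP) inference minimises the joint objective

$$J(X, U, C) = \sum_{k,n} w_k u_{kn}^m \lVert x_k - c_n\rVert^2
  \;-\; 2\sum_{k,n} (\alpha_n - 1)\log u_{kn}
  \;+\; \sum_n (c_n - \mu_c)^\top \Sigma_c^{-1} (c_n - \mu_c),$$

which is $-2$ times the sum of the three log kernels; the package evaluates
both sides independently and the test suite checks the identity to
$10^{-10}$.

Because $m$ enters through the precision rather than as an exponent on a
closed-form membership update, it is not restricted to $m > 1$ as in classic
fuzzy c-means; the implementation accepts any finite $m$ (memberships are
strictly positive so $u^m$ is always defined) with the default configuration
using $m > 0$.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `m` | 1.7 | fuzzy index; softness of assignments (larger = fuzzier likelihood) |
| `alpha` | 1 | Dirichlet prior; 1 is flat on the simplex, larger values pull rows toward uniformity |
| `gamma` | 3 | center-prior strength relative to the data covariance |
| `kappa` | 50 | membership-proposal concentration; larger = smaller random-walk moves |
| `n_iter` | 200 | sweep budget |
| `tol`, `window` | 1e-6, 10 | stop when the relative drop of best-so-far $J$ over `window` sweeps falls below `tol` |
| `seed` | 0 | one RNG stream per fit; equal seed and input gives a bit-identical fit |

All three model defaults (`m`, `alpha`, `gamma`) are the conventional
settings for this model family on standardised medical tables and grayscale
intensities; they are deliberately not data-tuned.

## Inference: Metropolis-within-Gibbs with a MAP ratchet

Each sweep updates memberships and centers:

1. **Membership rows** move by two Metropolis kernels, each in detailed
   balance with the row conditional $p(u_k \mid x_k, C) \propto
   \exp\{\sum_n [-\tfrac12 w_k u_{kn}^m d_{kn}^2 + (\alpha_n - 1)\log
   u_{kn}]\}$:
   a Dirichlet random walk `Dirichlet(kappa * u_k + 0.1)` with its
   (asymmetric-proposal) Hastings correction, then — for $m > 1$ — an
   independence proposal centred on the conditional's mode, which is the
   classic fuzzy-c-means membership $u_{kn} \propto d_{kn}^{-2/(m-1)}$.
   Rows are conditionally independent given the centers, so all $K$ rows are
   proposed and accepted elementwise in one vectorised step.
2. **Centers** are redrawn from their exact Gaussian full conditional
   (precision $\Sigma_c^{-1} + \sum_k w_k u_{kn}^m I$); because the proposal
   *is* the conditional, the Metropolis acceptance probability is
   identically one.

**MAP bookkeeping.** The reported clustering is not the final chain state
but a best-so-far *star* state $(U^*, C^*)$: every proposed membership row
is screened against $C^*$ (kept if it improves $\log p(x_k, u_k \mid C^*)$)
and every fresh center draw against $U^*$ (kept if it improves $\log p(X,
c_n \mid U^*)$). Each replacement lowers $J(U^*, C^*)$, so the objective
trace is non-increasing by construction — a stochastic coordinate ascent fed
by the sampler's proposals. The membership kernels target the conditional
given $C^*$ and the center draws condition on $U^*$, so the chain explores
the neighbourhood of the ratchet rather than the fuzzy bulk of the
posterior.

This coupling is the package's central design choice, and it was forced by
the geometry of the model. The posterior has a metastable symmetric mode in
which every center sits at the global data mean: with near-uniform
memberships each center's conditional mean is the data centroid, and with
coincident centers the row conditional actually *prefers* uniform rows for
$m > 1$ (at equal distances $\sum_n u_n^m$ is smallest at the uniform row).
A plain Metropolis-within-Gibbs chain conditioned on its own current state
falls into this trap from random initialisation and stays there for any
proposal concentration we tried; center draws conditioned on fuzzy
memberships essentially never come within reach of the clump means (they are
many conditional standard deviations away). Conditioning the two halves on
the star state instead makes the ratchet self-reinforcing: crisper rows
sharpen the center conditionals, and sharper centers make crisper rows
acceptable. On the canonical three-cluster fixture this recovers the
generative centers to a few hundredths across all tested seeds, for both the
direct and the blocked fit.

Two bookkeeping quantities are reported alongside: `per_sample_best` and
`per_center_best` hold the running maxima of the star scores. When $C^*$
moves, the conditional of an already-stored row can change, so these maxima
are tracked separately from the replacement comparisons (which always use
the current star state — that is what makes $J$ exactly monotone).

**Numerical choices.** All probability computations stay in the log domain;
acceptance ratios are exponentiated log differences. Constants independent
of $(U, C)$ are dropped everywhere — they cancel in every ratio and do not
move the MAP. Memberships are floored at $10^{-12}$ and renormalised after
every draw so $\log u_{kn}$ stays finite. Hard labels take the row argmax
with ties broken toward the lowest cluster index.

## The online framework

For data that cannot (or should not) be clustered in one pass, `owbfc()`
splits the $K$ samples into $d$ near-equal blocks (contiguous by default,
optionally shuffled first; a block *ratio* $r$ maps to $d = \mathrm{round}(1/r)$,
so a 25% split gives $d = 4$):

1. Block 1 is clustered with unit weights; each later block is clustered
   with its centers warm-started from the previous block's result (disable
   with `chain = FALSE`).
2. Each block contributes its $Q$ centers as *representative points*,
   weighted by the membership mass the cluster claimed:
   $w_q = \sum_{k \in \text{block}} u_{kq}$. Row-simplex conservation makes
   each block's weights sum to its sample count, and the pooled weights sum
   to $K$ exactly — checked to $10^{-6}$ in the tests.
3. The $d \cdot Q$ weighted representatives are clustered once more with the
   weighted model into the final $Q$ centers. The center prior for this pass
   is built from the weighted representative set itself, so the full data
   never needs to be resident.
4. Full-data memberships are obtained by one membership-only pass against
   the frozen final centers (re-opening the centers would undo the
   consolidation).

Both consolidation mechanisms — warm-start chaining *and* the final weighted
clustering of the pooled representatives — are used because each solves a
different problem: chaining keeps cluster identities stable across blocks,
pooling repairs blocks that saw an unrepresentative slice. With $d = 1$
stages 2–4 are skipped and the result is bit-identical to a direct `wbfc()`
fit at the same seed (one RNG stream, seeded once per fit; the shuffle is a
no-op for a single block).

Blocks are processed strictly sequentially; there is no parallelism
contract, matching the memory-constrained framing.

## What the synthetic generators emulate — and what they do not

`make_mixture()` draws isotropic Gaussian clumps — exactly the regime the
spherical per-cluster precision $u_{kn}^m I$ assumes. Its defaults are the
package's canonical recovery fixture: three clusters at $(0,0)$, $(3,0)$,
$(0,3)$, standard deviation 0.2, 100 samples each — well-separated at about
15 within-cluster standard deviations, which is what makes exact recovery a
reasonable demand rather than a lucky outcome. `make_phantom()` builds a
concentric-ring grayscale image (default $48 \times 48$, levels 0.2/0.5/0.8)
with optional clipped Gaussian noise, a desk-scale stand-in for
intensity-based segmentation of medical images.

Passing the recovery tests on these fixtures shows the estimator is
consistent in the model's own well-specified regime. It does **not** show
robustness to what real tables and scans contain: anisotropic or correlated
features, unequal cluster scales, heavy tails, bias fields, partial-volume
effects. The generators deliberately do not simulate those; stress testing
against them is a separate exercise.

Problem sizes in the tests and the acceptance script — $K = 300$ for
mixtures, $48 \times 48 = 2304$ pixels for phantoms, 10 replicate seeds —
are the package's chosen desk-scale study conditions: large enough for the
block framework to be meaningfully exercised ($d = 4$ gives 75-sample and
576-pixel blocks), small enough that the whole suite runs in a couple of
minutes.

## Degenerate inputs and edge rules

* One cluster ($N = 1$): the membership matrix is the all-ones column; the
  fit reduces to a prior-shrunk (weighted) mean.
* Identical rows / constant images: the raw center-prior covariance is zero;
  the ridge keeps it invertible and the fit terminates normally.
* Ties in hard labels go to the lowest cluster index.
* Entropy requires at least two true classes (its $\log N_{classes}$
  normaliser is undefined otherwise) and is normalised into $[0,1]$ so it
  prints on the same scale as the other three indices.
* Accuracy uses an exact one-to-one cluster-to-class assignment computed by
  a bitmask dynamic program (at most 16 clusters/classes; unmatched rows or
  columns contribute zero).

## Known limitations

* The MAP-seeking sampler is built for point estimation; the returned
  memberships are the ratcheted star state, not posterior draws, so they
  carry no calibrated uncertainty.
* Distances are Euclidean with a shared isotropic scale; features on wildly
  different scales should be standardised first (the pipeline offers opt-in
  min-max scaling).
* The number of clusters $Q$ is an input, not estimated.
* The exact assignment behind the accuracy index is exponential in the
  number of clusters and is capped at 16.
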