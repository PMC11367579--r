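---
title: "Variational Kemeny-constant clustering of kinetic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variational Kemeny-constant clustering of kinetic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kemenet)
```

## The model

A kinetic network is a Markov chain over $N$ microstates, given either as a
rate matrix $K$ (columns sum to zero, off-diagonal entries are transition
rates) or as a column-stochastic Markov matrix $Q(\tau) = e^{K\tau}$ at lag
$\tau$. For a reversible chain with equilibrium distribution $p^{eq}$, the
spectral decomposition has real eigenvalues
$0 = \lambda_1 > \lambda_2 \ge \dots$ (or $1 = \lambda_1 > \lambda_2 \ge
\dots$ in discrete time), and the mean first passage time (MFPT) $t_{ji}$ —
the expected time for a walk started in $i$ to first reach $j$ — follows from
the deviation kernel $G = \sum_{l\ge2} \theta_l\, \psi^{(l)}\phi^{(l)T}$ as
$t_{ji} = (G_{jj} - G_{ji})/p^{eq}_j$, where $\theta_l = 1/|\lambda_l|$
(continuous) or $1/(1-\lambda_l)$ (discrete) are the relaxation times.

The Kemeny constant
$$\zeta = \sum_{j \ne i} p^{eq}_j\, t_{ji} = \sum_{l \ge 2} \theta_l$$
is independent of the start state $i$ and measures the total relaxation
content of the chain. `kemeny_constant()` evaluates *both* routes and
refuses to return if they disagree or if the start-state spread exceeds
tolerance — the identity is used as a built-in consistency check rather than
assumed.

**Coarse-graining.** A soft assignment $S \in [0,1]^{N\times M}$ (rows sum
to 1) lumps the chain by local equilibrium: with the flux matrix
$G = K\,\mathrm{diag}(p^{eq})$, the coarse generator is
$\hat K = S^T G S\, \mathrm{diag}(\hat P)^{-1}$ with cluster populations
$\hat P = S^T p^{eq}$. This construction is column-stochastic, leaves
$\hat P$ stationary, reduces to the identity at $S = I$, and keeps
reversibility for any soft $S$ (the aggregated flux stays symmetric). Its
Kemeny constant $\zeta_S$ comes from the fundamental matrix
$Z = (\hat P 1^T - \hat K)^{-1}$ as $\zeta_S = \mathrm{tr}(Z) - 1$, which is
algebraically the sum-of-relaxation-times route but differentiable through a
single linear solve. The clustering objective is
$$\Delta K(S) = \zeta - \zeta_S \in [0, \zeta],$$
the relaxation content destroyed by lumping: $0$ at the identity partition,
$\zeta$ for a single cluster, non-negative for every crisp partition of a
reversible chain (the test-suite verifies the bound exhaustively on all
bipartitions of small random chains).

## Why training uses the discrete representation

Lumping a *rate matrix* under a soft assignment is degenerate in one corner
of the simplex: at the uniform assignment $S_{iL} = 1/M$ the aggregated flux
$S^T G S$ vanishes identically (columns of $K$ sum to zero), the coarse
chain loses all dynamics, $\zeta_S \to \infty$, and the loss
$\Delta K = \zeta - \zeta_S$ is unbounded below. A gradient-based optimizer
finds this hole reliably. The *Markov matrix* has no such pathology: uniform
$S$ lumps $Q$ into the perfectly mixing coarse chain ($\hat Q_{LK} = 1/M$),
whose Kemeny constant is the *minimum* $M - 1$, so smearing the assignment is
penalized, not rewarded. All training therefore operates on the discrete
chain; `markov_from_rate()` makes the conversion explicit (default lag
$\tau = 1/\max_i |K_{ii}|$), and no function converts implicitly. Crisp
$\Delta K$ on rate matrices remains available through `coarse_grain()`.

## The partitioning models

Four architectures map node features to an $N \times M$ soft assignment:

* **Encoders** (4 layers, width $d_{hidden} = 64$, output
  $d_{embed} = 32$): *GraphSAGE* (mean-aggregate neighbours, concatenate
  with the node's own state, affine map, rectifier) or *GATv2*
  (4 attention heads; scores $a^T \mathrm{LeakyReLU}(W_l h_i + W_r h_j)$
  softmax-normalized over the neighbourhood including a self-loop).
* **Decoders** (2 layers): a *linear* stack ending in $M$ logits, or a
  *transformer* — one trainable graph layer as positional encoding, two
  post-norm self-attention blocks with feed-forward layers and dropout
  (rate 0.1) between them.
* A row-wise softmax produces $S$.

The graph the encoders message-pass on connects node pairs with symmetrized
transition probability $(Q_{ij} + Q_{ji})/2 > c$, with $c = 0.015$ by
default (strict inequality; boundary pairs excluded). Nine node-feature
families are available (`feature_spec()`): raw columns of the adjacency,
rate/Markov, or MFPT matrix; their PCA projections (uncentred SVD, default
8 components, deterministic sign convention); leading non-stationary
eigenvectors (default $\min(8, N-1)$); a trainable per-node embedding; and a
trainable linear combination of adjacency, rate and MFPT columns. MFPT and
rate columns are standardized per column by default because raw MFPTs span
orders of magnitude and destabilize the first layer; a flag disables this.

**Loss.** $\mathcal{L}(S) = \Delta K(S) + \eta \sum_L e^{-n_L^2/2\sigma^2}$
with soft cluster sizes $n_L = \sum_i S_{iL}$ and defaults $\sigma = 1$,
$\eta = 15$: an empty cluster costs exactly $\eta$, one node costs
$\eta e^{-1/2} \approx 9.1$, three nodes $\approx 0.17$ — the penalty blocks
empty clusters without discouraging small ones. Gradients flow through the
whole pipeline (including the linear solve in $\zeta_S$) by a small
reverse-mode tape written for this package; every operation is validated
against central differences in the test-suite.

**Training.** Populations of independently Glorot-initialized models are
optimized with Adam (learning rate $10^{-4}$, standard moment defaults) in
64-bit arithmetic. Runs are bit-reproducible: each run's seed derives from
the master seed by a counter ($\mathrm{seed} \cdot 1000003 + i \bmod
2^{31}-1$), each run seeds its own random stream, and the result set is
identical for any worker count. The culling hook defaults to "never" (all
runs complete their predetermined steps) and the termination hook to "all
done"; both are pluggable, with early termination restricted to sequential
execution so results stay order-independent. The reported result of a run
is the crisp argmax of its final soft assignment (ties to the lowest
cluster index); a crisp labelling that leaves a cluster empty is recorded
with $\Delta K = \infty$ so it can never win best-run selection.

## Synthetic generators

**Stochastic block models.** `sample_sbm()` draws 4-block graphs; regime A
fixes the intra-block probability at 0.5 and draws inter-block
probabilities from a Gaussian scaled into $[0, 0.25]$; regime B draws all
probabilities from that distribution. The scaling is a half-normal with
standard deviation one third of the range, clamped at the upper edge. A
per-draw min/max rescaling was rejected: it pins one block pair at exactly
0.25 in every graph, which merges those blocks kinetically and contradicts
the intent of regime A as the "clear communities" regime. Graphs with
isolated nodes (or disconnected components, which would break
irreducibility) are resampled. `laplacian_rate()` converts a graph to the
generator of its continuous-time random walk, $K = -(I - D^{-1}A)^T$ in the
column convention — reversible with stationary distribution proportional to
degree.

At desk scale an important caveat appears: with 15-node blocks the
Kemeny-optimal partition frequently differs from the planted blocks by one
or two boundary nodes, so "recover the planted labels exactly" is only a
meaningful target on instances where the planted partition is itself the
kinetic optimum. `sbm_recovery_experiment()` therefore screens instances
with `delta_k_locally_optimal()` — a single-node-move local search that
uses only the chain and the labels, never the training outcome — and runs
the population protocol on the first instance that passes. At $N = 150$ and
above the screen is rarely needed.

**Four-well chain.** `chain_from_potential()` builds a 100-node
nearest-neighbour chain from a 1D potential with four Gaussian wells
holding 20/20/20/40 nodes (widths one fifth of the well, attempt frequency
$\nu = 1$, $k_BT = 1$; all configurable). Metropolis rates give detailed
balance with respect to the Boltzmann weights exactly, and the equilibrium
profile has exactly four local maxima. The potential is a stand-in chosen
for its qualitative features — four metastable wells with barriers of a few
$k_BT$ separated by sparse linear connectivity — so experiments on it
target properties (well recovery, architecture ranking), not externally
reported numbers. The default well depths are deliberately *distinct*
(3.5, 2.5, 4, 3 $k_BT$, with 1-$k_BT$ barrier bumps): with four identical
wells the Kemeny-optimal 4-partition turns out to isolate a two-node
transition region and merge two wells instead of separating the metastable
states — small transition-state clusters buy more relaxation time than
splitting identical basins. The asymmetric default restores the intended
structure: exhaustive enumeration of all contiguous 4-partitions (via 2D
prefix sums of the flux matrix) places the optimum exactly at the well
boundaries, and the well partition is locally optimal under arbitrary
single-node moves. Both checks use only the chain, never a training
outcome, and are frozen into the test-suite.

## Problem sizes used in the checks

The automated checks run the protocols at desk scale, chosen so the full
suite completes on one CPU core: block-model recovery at $N = 60$ with 20
models of 250 steps; the four-well comparison with 100 GraphSAGE + linear
runs of 500 steps against 4 runs of each other architecture; kinetic
identities on ensembles of random reversible chains with $N \le 30$; the
variational bound exhaustively on all bipartitions at $N \le 8$. The
recovery experiments are genuinely stochastic at these sizes: a fraction of
screened instances is still missed by a 20-model population, which the
full-scale protocol (100+ models, $N \ge 150$) does not exhibit.

## Numerical choices

* Structural tolerances $10^{-10}$ (column sums, row-stochasticity),
  spectral tolerances $10^{-8}$ (biorthonormality, Kemeny identities), both
  configurable per call.
* Eigendecompositions go through the symmetrizing similarity transform
  $\mathrm{diag}(p)^{-1/2} K\, \mathrm{diag}(p)^{1/2}$, so reversible chains
  get exactly real spectra; detailed balance is checked first and its
  violation reported with the flux asymmetry and the largest imaginary
  eigenvalue magnitude.
* Equilibrium distributions come from a bordered linear solve of
  $Kp = 0,\ \sum p = 1$, which fails loudly (rather than silently
  normalizing) when the dominant eigenspace is degenerate.
* Eigenvector sign conventions: stationary mode positive; every other mode
  oriented so its largest-magnitude entry is positive. PCA components are
  ordered by descending singular value with ties kept in decomposition
  order.
* Softmax rows are max-shifted before exponentiation; attention masks use
  $-\infty$ scores outside the neighbourhood.
* The coarse fundamental matrix solve raises a degenerate-cluster error if
  any soft cluster weight falls below $10^{-12}$.

## Limitations

* Non-reversible chains are rejected by the spectral machinery (the
  detailed-balance check is a hard precondition); estimation of chains from
  trajectory data is out of scope.
* The soft loss is evaluated on the lumped *discrete* chain; on rate
  matrices only crisp partitions are meaningful (see above).
* Spectral metastability baselines are compared through label files read
  with `read_labels()`; the package does not implement them.
* Dropout is the only stochastic element of a forward pass and is disabled
  at evaluation time, so reported assignments are deterministic given the
  seeds.
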