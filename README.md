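# kemenet

Kemeny-constant variational clustering of kinetic networks.

## The problem

Markov state models of molecular systems — and kinetic networks in general —
often have far more microstates than a human (or a downstream model) can
reason about. Coarse-graining them into a handful of clusters inevitably
destroys kinetic information; the question is how to lose as little as
possible. `kemenet` is for computational chemists and network scientists who
want partitions chosen *by the kinetics itself* rather than by connectivity
heuristics.

The package optimizes the **Kemeny constant**

$$\zeta \;=\; \sum_{j \ne i} p^{eq}_j\, t_{ji} \;=\; \sum_{l \ge 2} \frac{1}{|\lambda_l|},$$

the population-weighted mean first passage time (MFPT), which is independent
of the start state $i$ and equals the sum of the chain's relaxation times.
Lumping the chain under a soft node-to-cluster assignment
$S \in [0,1]^{N \times M}$ (local-equilibrium aggregation of the equilibrium
flux) yields a coarse chain with its own Kemeny constant $\zeta_S$, and

$$\Delta K(S) \;=\; \zeta - \zeta_S \;\in\; [0, \zeta]$$

is the relaxation content destroyed by the partition: $0$ for the identity
partition, $\zeta$ for a single cluster. Minimizing
$\Delta K(S) + \eta \sum_L e^{-n_L^2/2\sigma^2}$ (the penalty only forbids
empty clusters; defaults $\sigma = 1$, $\eta = 15$) over soft assignments
produced by small graph neural networks — GraphSAGE or GATv2 encoders with
linear or transformer decoders, trained as populations of independently
initialized models under Adam — yields partitions that preserve the slow
dynamics. $\Delta K$ is differentiated end-to-end through the lumping and a
fundamental-matrix linear solve by the package's own reverse-mode tape
(compiled kernels for the attention contractions).

The package also provides exact spectral kinetics (equilibrium, MFPTs,
Kemeny constants, with every identity double-checked internally), synthetic
kinetic-network generators (stochastic block models turned into random-walk
rate matrices; a 100-node four-well 1D-potential chain), nine node-feature
families, and partition metrics (modularity, cut size, Davies–Bouldin
index).

## Worked example

Cluster a 4-community kinetic network and compare partitions:

```r
library(kemenet)

set.seed(1)
sbm   <- sample_sbm(60, n_blocks = 4, regime = "A", seed = 101)
chain <- markov_from_rate(laplacian_rate(sbm$adjacency))  # discretize
graph <- graph_data(chain, feature_spec("mfpt"))
graph
#> <graph_data> 60 nodes, 269 edges, features 'mfpt' (d_feat 60), zeta = 105.76

pop <- train_population(graph,
                        model_config("graphsage", "linear", n_clusters = 4),
                        train_config(n_models = 20, n_steps = 250, seed = 7))
pop
#> <population_result> 20 runs (0 culled), best crisp dK = 91.9727

reports <- compare_partitions(chain, list(
  planted = sbm$labels,
  learned = pop$best_record$crisp_labels,
  single  = rep(1, 60)))
as.data.frame(reports)[, c("method", "delta_k", "delta_k_over_zeta", "min_cut")]
#>          method   delta_k delta_k_over_zeta min_cut
#> planted planted  91.97266         0.8695962      56
#> learned learned  91.97266         0.8695962      56
#> single   single 105.76479         1.0000000       0
```

Here the chain's total relaxation content is $\zeta = 105.8$ steps; the
planted 4-block partition retains $\zeta_S = 13.8$ of it (the three slow
inter-community modes), and the best of twenty trained models lands on
exactly the planted communities. Lower `delta_k` is better; `single` shows
the worst case $\Delta K = \zeta$.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/kemenet.R generate sbm --n 150 --seed 1 --out data/
Rscript inst/cli/kemenet.R train --matrix data/rate_matrix.csv --out run/
Rscript inst/cli/kemenet.R evaluate --matrix data/rate_matrix.csv \
        --labels run/best_labels.csv --out report.json
```

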