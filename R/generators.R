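#' Random reversible chain generator
#'
#' Draws a random irreducible, reversible chain by sampling a symmetric
#' positive conductance matrix \eqn{C} and a positive target distribution
#' \eqn{p}, then setting \eqn{K_{ji} = C_{ij}/p_i} for \eqn{j \ne i}: detailed
#' balance \eqn{p_i K_{ji} = p_j K_{ij} = C_{ij}} holds by construction and
#' \eqn{p} is the stationary vector. For `kind = "markov"` the rate matrix is
#' embedded as \eqn{Q = I + \tau K} with \eqn{\tau = 0.9/\max_i |K_{ii}|},
#' which preserves reversibility and keeps all probabilities in \eqn{[0,1]}.
#'
#' @param n number of states.
#' @param density probability that an off-diagonal pair is connected (a
#'   spanning random tree keeps the chain irreducible at low densities).
#' @param kind `"rate"` or `"markov"`.
#' @param seed optional integer seed (uses and restores the global RNG).
#' @return a validated `kinetic_chain`.
#' @export
random_reversible_chain <- function(n, density = 0.6, kind = c("rate", "markov"),
                                    seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  p <- stats::rgamma(n, shape = 2, rate = 1)
  p <- p / sum(p)
  con <- matrix(0, n, n)
  up <- upper.tri(con)
  con[up] <- stats::runif(sum(up)) * (stats::runif(sum(up)) < density)
  # spanning chain of edges so the graph is always connected
  for (i in seq_len(n - 1L)) if (con[i, i + 1L] == 0) con[i, i + 1L] <- stats::runif(1, 0.05, 1)
  con <- con + t(con)
  con <- con * 0.25 / max(con)
  k <- t(con / p)            # K[j, i] = C[i, j] / p[i] for j != i
  diag(k) <- 0
  diag(k) <- -colSums(k)
  if (kind == "rate") return(rate_matrix(k))
  tau <- 0.9 / max(abs(diag(k)))
  markov_matrix(diag(n) + tau * k, lag_tau = tau)
}

#' Stochastic block model graphs with planted communities
#'
#' Samples an undirected, simple graph whose edge probabilities depend only on
#' the block (community) membership of the endpoints. Two regimes are
#' provided: in regime `"A"` the intra-block probability is a constant
#' (default 0.5) and the inter-block probabilities are drawn from a Gaussian
#' scaled to lie in `inter_range` (default \eqn{[0, 0.25]}); in regime
#' `"B"` *all* block probabilities, intra and inter, come from the same
#' scaled Gaussian, giving graphs whose optimal partitioning is less clear.
#' The Gaussian is folded at zero with standard deviation one third of the
#' range (values beyond the upper edge are clamped), so inter-block
#' probabilities concentrate near the low end and regime-A communities stay
#' well separated, while still spanning the full stated range.
#' Graphs containing a degree-zero node (or, more generally, a disconnected
#' component, which would break irreducibility downstream) are discarded and
#' resampled.
#'
#' @param n_nodes number of nodes; split into equal blocks, remainder going to
#'   the last block.
#' @param n_blocks number of planted blocks (default 4).
#' @param regime `"A"` (constant intra) or `"B"` (all sampled).
#' @param intra_prob intra-block edge probability for regime A.
#' @param inter_range range into which the Gaussian samples are rescaled.
#' @param seed optional integer seed.
#' @param max_resample rejection limit before failing
#'   (`kemenet_generation` condition).
#' @return list with `adjacency` (binary symmetric N x N, zero diagonal),
#'   `labels` (planted block ids, 1-based integers) and `block_probs`
#'   (the realized block probability matrix).
#' @export
sample_sbm <- function(n_nodes, n_blocks = 4L, regime = c("A", "B"),
                       intra_prob = 0.5, inter_range = c(0, 0.25),
                       seed = NULL, max_resample = 1000L) {
  regime <- match.arg(regime)
  if (!is.null(seed)) set.seed(seed)
  if (n_nodes < 2L * n_blocks)
    stop_kemenet("generation", "need at least two nodes per block")
  sizes <- rep(n_nodes %/% n_blocks, n_blocks)
  sizes[n_blocks] <- sizes[n_blocks] + n_nodes %% n_blocks
  labels <- rep(seq_len(n_blocks), sizes)
  draw_probs <- function(k, range) {
    pmin(range[1L] + abs(stats::rnorm(k, 0, diff(range) / 3)), range[2L])
  }
  for (attempt in seq_len(max_resample)) {
    bp <- matrix(0, n_blocks, n_blocks)
    n_pairs <- n_blocks * (n_blocks - 1L) / 2L
    if (regime == "A") {
      bp[upper.tri(bp)] <- draw_probs(n_pairs, inter_range)
      bp <- bp + t(bp)
      diag(bp) <- intra_prob
    } else {
      all_p <- draw_probs(n_pairs + n_blocks, inter_range)
      bp[upper.tri(bp)] <- all_p[seq_len(n_pairs)]
      bp <- bp + t(bp)
      diag(bp) <- all_p[n_pairs + seq_len(n_blocks)]
    }
    pmat <- bp[labels, labels]
    adj <- matrix(0L, n_nodes, n_nodes)
    up <- upper.tri(adj)
    adj[up] <- as.integer(stats::runif(sum(up)) < pmat[up])
    adj <- adj + t(adj)
    if (min(colSums(adj)) >= 1L && is_irreducible(adj))
      return(list(adjacency = adj, labels = labels, block_probs = bp))
  }
  stop_kemenet("generation", sprintf(
    "no connected SBM graph found in %d resamples", max_resample))
}

#' Rate matrix of the random walk on a graph
#'
#' Builds the generator of the continuous-time random walk from the
#' random-walk normalized Laplacian \eqn{L_{rw} = I - D^{-1}A}: in the
#' column-stochastic orientation the generator is \eqn{K = -L_{rw}^T}, whose
#' off-diagonal entries \eqn{K_{ji} = A_{ij}/d_i \ge 0} and columns sum to
#' zero. The walk is reversible with stationary distribution proportional to
#' the node degrees.
#'
#' @param adjacency binary symmetric adjacency matrix without self-loops.
#' @return a validated `rate_matrix`.
#' @export
laplacian_rate <- function(adjacency) {
  assert_square(adjacency)
  if (any(adjacency != t(adjacency)) || any(diag(adjacency) != 0))
    stop_kemenet("adjacency", "adjacency must be symmetric with zero diagonal")
  deg <- colSums(adjacency)
  if (any(deg == 0))
    stop_kemenet("degree_zero", sprintf("node %d has degree 0", which(deg == 0)[1L]))
  k <- t(adjacency / deg)    # K[j, i] = A[i, j] / d_i
  diag(k) <- -1
  rate_matrix(k)
}

#' Nearest-neighbour chain from a four-well 1D potential
#'
#' Discretizes a one-dimensional potential onto `n_nodes` ordered nodes on
#' \eqn{[0, 1]} and assigns Metropolis transition rates between neighbours,
#' \eqn{k_{i \to i\pm1} = \nu\,\min\{1, e^{-(V_{i\pm1} - V_i)/k_BT}\}}, so the
#' tridiagonal generator satisfies detailed balance with respect to the
#' Boltzmann weights \eqn{p_i \propto e^{-V_i/k_BT}} exactly. The
#' potential is a sum of four negative Gaussians whose centres and widths
#' match a well layout of 20/20/20/40 nodes, plus Gaussian barrier bumps at
#' the three well boundaries.
#'
#' The default depths are deliberately distinct (3.5, 2.5, 4, 3
#' \eqn{k_BT}, bumps of 1): with four identical wells the Kemeny-optimal
#' 4-partition isolates a low-population transition region and merges two
#' wells rather than separating the four metastable states, whereas the
#' asymmetric default landscape has its optimum exactly at the well
#' boundaries (verified in the test-suite by exhaustive enumeration of
#' contiguous 4-partitions).
#'
#' @param n_nodes number of nodes (default 100).
#' @param well_node_counts nodes per well, summing to `n_nodes`
#'   (default `c(20, 20, 20, 40)`).
#' @param well_depths well depths in units of \eqn{k_BT}.
#' @param barrier_heights heights of the boundary bumps.
#' @param kBT thermal energy (default 1).
#' @param nu attempt frequency \eqn{\nu} (default 1).
#' @return list with `chain` (a `rate_matrix`), `positions`, `energies`,
#'   `well_id` (which well each node belongs to) and `p_eq`.
#' @export
chain_from_potential <- function(n_nodes = 100L,
                                 well_node_counts = c(20L, 20L, 20L, 40L),
                                 well_depths = c(3.5, 2.5, 4, 3),
                                 barrier_heights = c(1, 1, 1),
                                 kBT = 1, nu = 1) {
  if (sum(well_node_counts) != n_nodes)
    stop_kemenet("potential", "well node counts must sum to n_nodes")
  if (any(!is.finite(well_depths)) || any(!is.finite(barrier_heights)))
    stop_kemenet("potential", "depths and barrier heights must be finite")
  well_depths <- rep_len(well_depths, length(well_node_counts))
  barrier_heights <- rep_len(barrier_heights, length(well_node_counts) - 1L)
  x <- (seq_len(n_nodes) - 0.5) / n_nodes
  bounds <- cumsum(well_node_counts) / n_nodes      # right edges of wells
  left <- c(0, bounds[-length(bounds)])
  centers <- (left + bounds) / 2
  widths <- (bounds - left) / 5                     # ~96% of mass inside well
  v <- rep(0, n_nodes)
  for (w in seq_along(centers))
    v <- v - well_depths[w] * exp(-(x - centers[w])^2 / (2 * widths[w]^2))
  for (b in seq_along(barrier_heights))
    v <- v + barrier_heights[b] * exp(-(x - bounds[b])^2 / (2 * (0.01)^2))
  k <- matrix(0, n_nodes, n_nodes)
  for (i in seq_len(n_nodes - 1L)) {
    k[i + 1L, i] <- nu * min(1, exp(-(v[i + 1L] - v[i]) / kBT))  # i -> i+1
    k[i, i + 1L] <- nu * min(1, exp(-(v[i] - v[i + 1L]) / kBT))  # i+1 -> i
  }
  diag(k) <- -colSums(k)
  chain <- rate_matrix(k)
  w_boltz <- exp(-(v - min(v)) / kBT)
  list(chain = chain, positions = x, energies = v,
       well_id = findInterval(x, bounds, left.open = TRUE) + 1L,
       p_eq = w_boltz / sum(w_boltz))
}
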