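#' Mean first passage times from the spectral decomposition
#'
#' For a reversible chain the deviation (group-inverse) kernel
#' \eqn{G = \sum_{l \ge 2} \theta_l \psi^{(l)} (\phi^{(l)})^T}, with
#' \eqn{\theta_l = 1/|\lambda_l|} in continuous time and
#' \eqn{\theta_l = 1/(1-\lambda_l)} in discrete time, yields the mean first
#' passage times
#' \deqn{t_{ji} = \frac{G_{jj} - G_{ji}}{p^{eq}_j},}
#' the expected time (or number of steps) for a walk started in state
#' \eqn{i} to first reach state \eqn{j}. The diagonal is zero by construction.
#'
#' @param decomp a `spectral_decomposition`.
#' @return N x N matrix `t` with `t[j, i]` the MFPT from state `i` to state
#'   `j`, in the chain's time units (steps for discrete chains).
#' @seealso [kemeny_constant()], [coarse_grain()]
#' @export
mfpt <- function(decomp) {
  theta <- relaxation_times(decomp)
  psi <- decomp$right[, -1L, drop = FALSE]
  phi <- decomp$left[, -1L, drop = FALSE]
  g <- psi %*% (theta * t(phi))
  t_mat <- (diag(g) - g) / decomp$p_eq
  diag(t_mat) <- 0
  if (any(t_mat[row(t_mat) != col(t_mat)] <= 0))
    stop_kemenet("mfpt_sign", "non-positive off-diagonal MFPT: chain may be numerically reducible")
  t_mat
}

#' Kemeny constant of a kinetic chain
#'
#' The population-weighted mean first passage time
#' \eqn{\zeta = \sum_{j \ne i} p^{eq}_j t_{ji}} is independent of the start
#' state \eqn{i}, and equals the sum of the chain's relaxation times
#' \eqn{\sum_{l \ge 2} \theta_l}. Both routes are evaluated and must agree;
#' their disagreement, or a spread across start states, indicates a numerically
#' inconsistent decomposition and raises `kemenet_inconsistency`.
#'
#' @param decomp a `spectral_decomposition`.
#' @param mfpt_matrix optional precomputed [mfpt()] matrix.
#' @param tol internal-consistency tolerance (relative).
#' @return scalar \eqn{\zeta}, with attributes `"spread"` (max deviation across
#'   start states) and `"route_gap"` (difference between the two routes).
#' @export
kemeny_constant <- function(decomp, mfpt_matrix = NULL, tol = 1e-8) {
  t_mat <- mfpt_matrix %||% mfpt(decomp)
  zeta_spec <- sum(relaxation_times(decomp))
  per_start <- colSums(decomp$p_eq * t_mat)
  spread <- max(abs(per_start - zeta_spec))
  if (spread > tol * max(1, zeta_spec))
    stop_kemenet("inconsistency", sprintf(
      "Kemeny sum varies with start state (spread %.3g, zeta %.6g)", spread, zeta_spec))
  structure(zeta_spec, spread = max(per_start) - min(per_start),
            route_gap = spread)
}

#' Equilibrium population of clusters under a soft assignment
#'
#' \eqn{\hat P^{eq}_L = \sum_i S_{iL}\, p^{eq}_i}: the population of a cluster
#' is the (soft) sum of the populations of its nodes.
#'
#' @param S N x M row-stochastic soft assignment matrix.
#' @param p_eq equilibrium distribution of the fine chain.
#' @return length-M vector summing to 1.
#' @export
cluster_equilibrium <- function(S, p_eq) {
  S <- validate_assignment(S, length(p_eq))
  as.vector(crossprod(S, p_eq))
}

# Row-stochastic soft assignment validator (entries in [0,1], rows sum to 1).
validate_assignment <- function(S, n = NULL, tol = 1e-8) {
  if (!is.matrix(S)) S <- as.matrix(S)
  if (!is.null(n) && nrow(S) != n)
    stop_kemenet("dimension", sprintf("assignment has %d rows, chain has %d states", nrow(S), n))
  if (any(S < -tol) || any(S > 1 + tol) || any(abs(rowSums(S) - 1) > tol))
    stop_kemenet("assignment", "assignment rows must be probability vectors summing to 1")
  S
}

#' One-hot assignment matrix from integer cluster labels
#'
#' @param labels integer vector of cluster ids (0-based or 1-based; anything
#'   coercible to consecutive use via `factor` levels is refused — ids must be
#'   integers in `[0, M)` or `[1, M]`).
#' @param n_clusters number of clusters M; default `max(labels) (+1)`.
#' @return N x M crisp (0/1) assignment matrix.
#' @export
labels_to_assignment <- function(labels, n_clusters = NULL) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop_kemenet("labels", "labels must be integers")
  if (min(labels) == 0L) labels <- labels + 1L
  m <- n_clusters %||% max(labels)
  if (min(labels) < 1L || max(labels) > m)
    stop_kemenet("labels", "labels out of range for the stated number of clusters")
  S <- matrix(0, length(labels), m)
  S[cbind(seq_along(labels), labels)] <- 1
  S
}

#' Coarse-grain a kinetic chain under a (soft) assignment
#'
#' Local-equilibrium lumping: with the equilibrium flux matrix
#' \eqn{G = K\,\mathrm{diag}(p^{eq})} (or \eqn{Q\,\mathrm{diag}(p^{eq})}), the
#' coarse generator is the cluster-aggregated flux renormalized by the cluster
#' populations,
#' \deqn{\hat K = S^T G S \,\mathrm{diag}(\hat P^{eq})^{-1},}
#' which is column-stochastic (columns sum to 0 resp. 1), has stationary
#' vector \eqn{\hat P^{eq}}, and reduces to the identity lumping when
#' \eqn{S = I}. For a reversible fine chain the lumped chain is reversible for
#' any soft S, because the aggregated flux \eqn{S^T G S} stays symmetric.
#'
#' The coarse Kemeny constant and MFPTs are computed from the lumped chain's
#' own fundamental matrix: with \eqn{A = \hat P 1^T - \hat K} (continuous) or
#' \eqn{A = I - \hat Q + \hat P 1^T} (discrete), \eqn{Z = A^{-1}},
#' \eqn{\zeta_S = \mathrm{tr}(Z) - 1} and
#' \eqn{\hat t_{LK} = (Z_{LL} - Z_{LK})/\hat P_L}. The identity
#' \eqn{\zeta_S = \sum_L \hat P_L \hat t_{LK}} (any start cluster K) is
#' verified internally.
#'
#' @param chain validated `kinetic_chain`.
#' @param p_eq equilibrium distribution of `chain`.
#' @param S N x M soft assignment.
#' @param tol consistency tolerance for the coarse Kemeny identity.
#' @return object of class `coarse_chain`: list with `P_eq_hat`, `Q_hat` (the
#'   lumped generator or Markov matrix), `t_hat`, `zeta_S`, `kind`,
#'   `n_clusters`.
#' @export
coarse_grain <- function(chain, p_eq, S, tol = 1e-6) {
  S <- validate_assignment(S, chain$n_states)
  m <- ncol(S)
  p_hat <- as.vector(crossprod(S, p_eq))
  if (any(p_hat < 1e-12))
    stop_kemenet("degenerate_cluster", sprintf(
      "cluster %d has total equilibrium weight below 1e-12", which.min(p_hat)))
  g_hat <- crossprod(S, chain_matrix(chain) %*% (p_eq * S))
  q_hat <- sweep(g_hat, 2L, p_hat, "/")
  if (m == 1L) {
    out <- list(P_eq_hat = 1, Q_hat = q_hat, t_hat = matrix(0, 1, 1),
                zeta_S = 0, kind = chain$kind, n_clusters = 1L)
    return(structure(out, class = "coarse_chain"))
  }
  a <- if (is_rate(chain)) outer(p_hat, rep(1, m)) - q_hat
       else diag(m) - q_hat + outer(p_hat, rep(1, m))
  z <- tryCatch(solve(a), error = function(e)
    stop_kemenet("degenerate_cluster", "lumped chain is singular (assignment too close to uniform mixing of a rate matrix)"))
  zeta_s <- sum(diag(z)) - 1
  t_hat <- (diag(z) - z) / p_hat
  diag(t_hat) <- 0
  start_sums <- colSums(p_hat * t_hat)
  if (max(abs(start_sums - zeta_s)) > tol * max(1, abs(zeta_s)))
    stop_kemenet("inconsistency", "coarse Kemeny constant disagrees with the population-weighted coarse MFPT sum")
  structure(list(P_eq_hat = p_hat, Q_hat = q_hat, t_hat = t_hat,
                 zeta_S = zeta_s, kind = chain$kind, n_clusters = m),
            class = "coarse_chain")
}

#' @export
print.coarse_chain <- function(x, ...) {
  cat(sprintf("<coarse_chain> %d clusters (%s time), zeta_S = %.6g\n",
              x$n_clusters, if (x$kind == "rate") "continuous" else "discrete", x$zeta_S))
  invisible(x)
}

#' Kemeny-constant difference of a partitioning
#'
#' \eqn{\Delta K = \zeta - \zeta_S}: the sum of relaxation times lost by
#' coarse-graining. Zero for the identity partition (M = N), equal to
#' \eqn{\zeta} for the single-cluster partition (M = 1), and non-negative for
#' crisp partitions of reversible chains; smaller means more kinetic
#' information is preserved.
#'
#' @param zeta Kemeny constant of the fine chain.
#' @param zeta_S Kemeny constant of the coarse-grained chain (scalar or a
#'   `coarse_chain`).
#' @return scalar \eqn{\Delta K}.
#' @export
delta_k <- function(zeta, zeta_S) {
  if (inherits(zeta_S, "coarse_chain")) zeta_S <- zeta_S$zeta_S
  as.numeric(zeta) - as.numeric(zeta_S)
}

#' Delta-K of a labelled partition in one call
#'
#' Convenience wrapper: spectral decomposition, Kemeny constant, crisp
#' lumping and [delta_k()] for an integer labelling of the chain's states.
#'
#' @param chain validated `kinetic_chain`.
#' @param labels integer cluster labels (or an N x M soft assignment).
#' @param n_clusters number of clusters; default inferred from labels.
#' @return scalar Delta-K; attribute `"zeta"` carries the fine Kemeny constant.
#' @export
partition_delta_k <- function(chain, labels, n_clusters = NULL) {
  S <- if (is.matrix(labels) && ncol(labels) > 1) labels
       else labels_to_assignment(labels, n_clusters)
  dec <- spectral_decompose(chain)
  zeta <- kemeny_constant(dec)
  cg <- coarse_grain(chain, dec$p_eq, S)
  structure(delta_k(zeta, cg), zeta = as.numeric(zeta))
}
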