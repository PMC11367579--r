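#' Modularity of a (soft) partitioning
#'
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left(A_{ij} - \frac{d_i d_j}{2m}\right)
#'       \sum_L S_{iL} S_{jL},}
#' the excess of intra-cluster connectivity over a degree-matched random
#' graph. For crisp assignments this is the classical community-detection
#' score in \eqn{[-1, 1]}; soft assignments are evaluated with the same
#' bilinear form.
#'
#' @param adjacency binary symmetric adjacency.
#' @param S N x M soft assignment, or an integer label vector.
#' @return scalar modularity.
#' @export
modularity <- function(adjacency, S) {
  if (!is.matrix(S)) S <- labels_to_assignment(S)
  m2 <- sum(adjacency)              # 2m
  if (m2 < 2) stop_kemenet("empty_graph", "modularity needs at least one edge")
  d <- colSums(adjacency)
  sum((adjacency - outer(d, d) / m2) * tcrossprod(S)) / m2
}

#' Cut size of a (soft) partitioning
#'
#' \eqn{C = \frac{1}{2}\sum_{ij} A_{ij}\,(1 - \sum_L S_{iL} S_{jL})}: for a
#' crisp assignment, the number of edges between clusters.
#'
#' @inheritParams modularity
#' @return scalar cut size.
#' @export
min_cut <- function(adjacency, S) {
  if (!is.matrix(S)) S <- labels_to_assignment(S)
  sum(adjacency * (1 - tcrossprod(S))) / 2
}

#' Davies-Bouldin index of a crisp partitioning
#'
#' Cluster centroids are per-cluster feature means; the diameter
#' \eqn{\sigma_L} is the mean Euclidean node-centroid distance, and the index
#' averages, over clusters, the worst ratio
#' \eqn{(\sigma_K + \sigma_L)/\Delta_{KL}} against any other cluster. Lower is
#' better; zero for well-separated zero-diameter clusters. Coincident
#' centroids with non-zero diameters yield an infinite ratio and a warning
#' rather than an error.
#'
#' @param features N x d feature matrix (for kinetic comparisons, the columns
#'   of the Markov matrix are the conventional choice).
#' @param labels integer cluster labels covering all of `1..M` (or `0..M-1`).
#' @return scalar DBI (non-negative).
#' @export
dbi <- function(features, labels) {
  labels <- as.integer(labels)
  if (min(labels) == 0L) labels <- labels + 1L
  m <- max(labels)
  if (m < 2L) stop_kemenet("dbi", "DBI needs at least two clusters")
  if (length(unique(labels)) < m)
    stop_kemenet("empty_cluster", "every cluster must be non-empty")
  features <- as.matrix(features)
  cent <- t(vapply(seq_len(m), function(l)
    colMeans(features[labels == l, , drop = FALSE]), numeric(ncol(features))))
  sig <- vapply(seq_len(m), function(l) {
    d <- features[labels == l, , drop = FALSE] -
      matrix(cent[l, ], sum(labels == l), ncol(features), byrow = TRUE)
    mean(sqrt(rowSums(d^2)))
  }, 1.0)
  r <- matrix(0, m, m)
  for (k in seq_len(m - 1L)) for (l in (k + 1L):m) {
    delta <- sqrt(sum((cent[k, ] - cent[l, ])^2))
    r[k, l] <- r[l, k] <- if (delta < 1e-300) {
      if (sig[k] + sig[l] < 1e-300) 0 else {
        warning("coincident centroids with non-zero diameters", call. = FALSE)
        Inf
      }
    } else (sig[k] + sig[l]) / delta
  }
  diag(r) <- -Inf
  mean(apply(r, 1L, max))
}

#' Chance-adjusted agreement between two labelings
#'
#' Permutation-invariant agreement score in \eqn{[-1, 1]} (adjusted Rand
#' index): 1 for labelings identical up to cluster renaming, about 0 for
#' independent labelings. Used for planted-partition recovery checks.
#'
#' @param labels_a,labels_b equal-length integer label vectors.
#' @return scalar agreement score.
#' @export
label_agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop_kemenet("dimension", "labelings have different lengths")
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Evaluate and compare partitionings of one kinetic network
#'
#' Builds one report per named labeling: crisp \eqn{\Delta K} (through the
#' full coarse-graining path), the ratio \eqn{\Delta K/\zeta}, DBI (on the
#' chain-matrix columns unless features are supplied), modularity, cut size
#' and cluster sizes. Externally produced labelings (for instance from a
#' spectral metastability method) can be read with [read_labels()] and
#' compared on equal footing.
#'
#' @param chain validated `kinetic_chain`.
#' @param adjacency binary adjacency of the comparison graph (built from the
#'   chain when `NULL`).
#' @param partitions named list of integer label vectors (0- or 1-based).
#' @param features feature matrix for the DBI (default: chain-matrix columns).
#' @return list of `partition_report` lists, one per method; also collected
#'   into a data.frame by [as.data.frame.partition_comparison()].
#' @export
compare_partitions <- function(chain, partitions, adjacency = NULL,
                               features = NULL) {
  if (is.null(adjacency))
    adjacency <- if (is_rate(chain)) adjacency_from_rate(chain)
                 else adjacency_from_markov(chain)
  if (is.null(features)) features <- t(chain_matrix(chain))
  dec <- spectral_decompose(chain)
  zeta <- as.numeric(kemeny_constant(dec))
  reports <- lapply(names(partitions), function(nm) {
    labels <- as.integer(partitions[[nm]])
    if (length(labels) != chain$n_states)
      stop_kemenet("dimension", sprintf(
        "labeling '%s' has %d labels for %d states", nm, length(labels),
        chain$n_states))
    if (min(labels) == 0L) labels <- labels + 1L
    m <- max(labels)
    S <- labels_to_assignment(labels, m)
    cg <- coarse_grain(chain, dec$p_eq, S)
    dk <- delta_k(zeta, cg)
    empty <- length(unique(labels)) < m
    dbi_val <- if (m >= 2L && !empty) dbi(features, labels) else NA_real_
    structure(list(method_name = nm, crisp_labels = labels - 1L,
                   delta_k = dk, delta_k_over_zeta = dk / zeta,
                   dbi = dbi_val, dbi_omitted = m < 2L || empty,
                   modularity = modularity(adjacency, S),
                   min_cut = min_cut(adjacency, S),
                   cluster_sizes = tabulate(labels, m), zeta = zeta),
              class = "partition_report")
  })
  names(reports) <- names(partitions)
  class(reports) <- "partition_comparison"
  reports
}

#' @export
as.data.frame.partition_comparison <- function(x, ...) {
  do.call(rbind, lapply(x, function(r)
    data.frame(method = r$method_name, delta_k = r$delta_k,
               delta_k_over_zeta = r$delta_k_over_zeta, dbi = r$dbi,
               modularity = r$modularity, min_cut = r$min_cut,
               n_clusters = length(r$cluster_sizes))))
}

#' @export
print.partition_report <- function(x, ...) {
  cat(sprintf("<partition_report '%s'> dK = %.6g (dK/zeta = %.4g), DBI = %s, Q = %.4g, cut = %g\n",
              x$method_name, x$delta_k, x$delta_k_over_zeta,
              if (is.na(x$dbi)) "NA" else format(x$dbi, digits = 4),
              x$modularity, x$min_cut))
  invisible(x)
}
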