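#' Cutoff adjacency from a Markov matrix
#'
#' Connects node pairs whose symmetrized transition probability strictly
#' exceeds a cutoff: edge \eqn{(i, j)} iff \eqn{(Q_{ij} + Q_{ji})/2 > c}.
#' The default cutoff \eqn{c = 0.015} is sufficient for the moderately dense
#' kinetic networks targeted here; sparser or denser chains may need a
#' different value. Boundary values (exactly equal to `c`) are excluded.
#'
#' @param chain a `markov_matrix` (for a `rate_matrix` see
#'   [adjacency_from_rate()], where connectivity is structural).
#' @param c cutoff probability.
#' @return binary symmetric N x N adjacency with zero diagonal. If the cutoff
#'   isolates nodes a warning reports them (training can still proceed; the
#'   isolated nodes simply receive no messages).
#' @export
adjacency_from_markov <- function(chain, c = 0.015) {
  if (!inherits(chain, "markov_matrix"))
    stop_kemenet("bad_kind", "adjacency_from_markov expects a markov_matrix")
  q <- chain_matrix(chain)
  adj <- ((q + t(q)) / 2 > c) * 1L
  diag(adj) <- 0L
  iso <- which(colSums(adj) == 0)
  if (length(iso))
    warning(sprintf("cutoff c = %g isolates node(s) %s", c,
                    paste(iso, collapse = ", ")), call. = FALSE)
  adj
}

#' Structural adjacency of a rate matrix
#'
#' For a generator, two states are adjacent when a direct transition exists in
#' either direction (symmetrized non-zero rate above `c`, default 0).
#'
#' @param chain a `rate_matrix`.
#' @param c rate cutoff (strict inequality).
#' @return binary symmetric adjacency, zero diagonal.
#' @export
adjacency_from_rate <- function(chain, c = 0) {
  if (!is_rate(chain))
    stop_kemenet("bad_kind", "adjacency_from_rate expects a rate_matrix")
  k <- chain_matrix(chain)
  diag(k) <- 0
  adj <- ((k + t(k)) / 2 > c) * 1L
  adj
}

#' Principal-component projection of a node-by-node matrix
#'
#' PCA implemented as the singular value decomposition: node \eqn{i}'s
#' coordinates are row \eqn{i} of \eqn{M V_{1:dim}}, the projection onto the
#' top right singular directions. By default the matrix is *not* centred
#' (pure SVD); set `center = TRUE` for classical PCA. Columns are ordered by
#' descending singular value (ties keep the decomposition's index order), and
#' each column's sign is fixed so that its largest-magnitude coordinate is
#' positive.
#'
#' @param m N x N numeric matrix.
#' @param dim number of components, `dim <= N`.
#' @param center subtract column means first? default `FALSE`.
#' @return N x dim score matrix; attribute `"d"` carries all singular values.
#' @export
pca_project <- function(m, dim, center = FALSE) {
  if (dim > nrow(m)) stop_kemenet("dimension", "pca dim exceeds matrix size")
  if (center) m <- sweep(m, 2L, colMeans(m))
  sv <- svd(m, nu = 0, nv = dim)
  scores <- m %*% sv$v
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  structure(scores, d = sv$d)
}

#' Node feature specification
#'
#' The nine feature families compared in this package: raw matrix columns
#' (`adjacency`, `rate`, `mfpt`), their PCA projections (`*_pca`), leading
#' eigenvectors of the chain (`eigenvectors`), a `trainable_embedding`
#' look-up table (weights live with the model parameters), and a
#' `linear_combination` of adjacency, rate/Markov and MFPT columns through one
#' trainable linear map. On discrete chains the Markov-matrix columns stand in
#' for the rate columns.
#'
#' @param kind one of `"adjacency"`, `"adjacency_pca"`, `"rate"`,
#'   `"rate_pca"`, `"mfpt"`, `"mfpt_pca"`, `"eigenvectors"`,
#'   `"trainable_embedding"`, `"linear_combination"`.
#' @param pca_dim dimension for `*_pca` kinds (default 8).
#' @param embedding_dim dimension of the trainable embedding (default 32,
#'   shared with the model's embedding width).
#' @param scale standardize columns of MFPT/rate features to zero mean, unit
#'   variance? Raw MFPTs span orders of magnitude and destabilize
#'   initialization, so the default is `TRUE`.
#' @param center center matrices before PCA (default `FALSE`, pure SVD).
#' @return a `feature_spec` list.
#' @export
feature_spec <- function(kind = "mfpt", pca_dim = 8L, embedding_dim = 32L,
                         scale = TRUE, center = FALSE) {
  kinds <- c("adjacency", "adjacency_pca", "rate", "rate_pca", "mfpt",
             "mfpt_pca", "eigenvectors", "trainable_embedding",
             "linear_combination")
  if (!kind %in% kinds)
    stop_kemenet("feature_kind", sprintf("unknown feature kind '%s'", kind))
  structure(list(kind = kind, pca_dim = as.integer(pca_dim),
                 embedding_dim = as.integer(embedding_dim),
                 scale = isTRUE(scale), center = isTRUE(center)),
            class = "feature_spec")
}

standardize_cols <- function(f) {
  mu <- colMeans(f)
  sd <- apply(f, 2L, stats::sd)
  sd[sd < 1e-12] <- 1
  sweep(sweep(f, 2L, mu), 2L, sd, "/")
}

#' Build node features for the partitioning models
#'
#' Assembles the `N x d_feat` feature matrix `F` for a given [feature_spec()].
#' Node \eqn{i}'s raw features are column \eqn{i} of the respective
#' node-by-node matrix (adjacency, rate/Markov, MFPT); PCA kinds project that
#' matrix with [pca_project()]; `eigenvectors` uses the first
#' `min(8, N - 1)` non-stationary right eigenvectors. The two trainable kinds
#' return the fixed part of their input (node ids, resp. the concatenated
#' column matrix) plus a contract describing the trainable map, whose weights
#' are created by [generate_params()].
#'
#' @param spec a [feature_spec()].
#' @param chain validated `kinetic_chain`.
#' @param decomp optional precomputed [spectral_decompose()] result.
#' @param mfpt_matrix optional precomputed [mfpt()] matrix.
#' @param adjacency optional precomputed adjacency (built from the chain if
#'   missing).
#' @return a `graph_features` list: `F` (numeric matrix, the fixed input),
#'   `kind`, `d_feat` (dimension entering the encoder), `trainable` (NULL or a
#'   contract list for the trainable kinds).
#' @export
build_features <- function(spec, chain, decomp = NULL, mfpt_matrix = NULL,
                           adjacency = NULL) {
  n <- chain$n_states
  need_kinetics <- spec$kind %in% c("mfpt", "mfpt_pca", "eigenvectors",
                                    "linear_combination")
  if (need_kinetics && is.null(decomp)) decomp <- spectral_decompose(chain)
  if (spec$kind %in% c("mfpt", "mfpt_pca", "linear_combination") &&
      is.null(mfpt_matrix)) mfpt_matrix <- mfpt(decomp)
  if (is.null(adjacency))
    adjacency <- if (is_rate(chain)) adjacency_from_rate(chain)
                 else adjacency_from_markov(chain)
  rate_cols <- t(chain_matrix(chain))   # row i = column i of K (or Q)
  mfpt_cols <- if (!is.null(mfpt_matrix)) t(mfpt_matrix)
  trainable <- NULL
  f <- switch(spec$kind,
    adjacency = adjacency * 1,
    adjacency_pca = pca_project(adjacency * 1, spec$pca_dim, spec$center),
    rate = if (spec$scale) standardize_cols(rate_cols) else rate_cols,
    rate_pca = pca_project(rate_cols, spec$pca_dim, spec$center),
    mfpt = if (spec$scale) standardize_cols(mfpt_cols) else mfpt_cols,
    mfpt_pca = pca_project(mfpt_cols, spec$pca_dim, spec$center),
    eigenvectors = decomp$right[, 1L + seq_len(min(8L, n - 1L)), drop = FALSE],
    trainable_embedding = {
      trainable <- list(type = "embedding", n_nodes = n, dim = spec$embedding_dim)
      matrix(seq_len(n), ncol = 1L)   # node ids; looked up in the embedding table
    },
    linear_combination = {
      base <- cbind(adjacency * 1,
                    if (spec$scale) standardize_cols(rate_cols) else rate_cols,
                    if (spec$scale) standardize_cols(mfpt_cols) else mfpt_cols)
      trainable <- list(type = "linear", d_in = ncol(base), dim = spec$embedding_dim)
      base
    })
  f <- unclass(f)
  attributes(f) <- attributes(f)["dim"]
  if (any(!is.finite(f)))
    stop_kemenet("nonfinite", "feature matrix contains non-finite values")
  d_feat <- if (is.null(trainable)) ncol(f) else trainable$dim
  structure(list(F = f, kind = spec$kind, d_feat = d_feat,
                 trainable = trainable, spec = spec),
            class = "graph_features")
}

#' Assemble the full GNN input for a chain
#'
#' Bundles adjacency, features and the precomputed loss context (equilibrium
#' flux, fine Kemeny constant) into one `graph_data` object consumed by the
#' training functions.
#'
#' @param chain validated `kinetic_chain` (the chain the loss is computed on).
#' @param spec a [feature_spec()].
#' @param cutoff cutoff for [adjacency_from_markov()] (ignored for rate
#'   matrices, whose adjacency is structural).
#' @return `graph_data` list: `adjacency`, `features` (a `graph_features`),
#'   `chain`, `decomp`, `p_eq`, `zeta`, `n_nodes`.
#' @export
graph_data <- function(chain, spec = feature_spec(), cutoff = 0.015) {
  adjacency <- if (is_rate(chain)) adjacency_from_rate(chain)
               else adjacency_from_markov(chain, c = cutoff)
  decomp <- spectral_decompose(chain)
  tm <- mfpt(decomp)
  feats <- build_features(spec, chain, decomp, tm, adjacency)
  zeta <- as.numeric(kemeny_constant(decomp, tm))
  structure(list(adjacency = adjacency, features = feats, chain = chain,
                 decomp = decomp, p_eq = decomp$p_eq, zeta = zeta,
                 n_nodes = chain$n_states),
            class = "graph_data")
}

#' @export
print.graph_data <- function(x, ...) {
  cat(sprintf("<graph_data> %d nodes, %d edges, features '%s' (d_feat %d), zeta = %.5g\n",
              x$n_nodes, sum(x$adjacency) / 2, x$features$kind,
              x$features$d_feat, x$zeta))
  invisible(x)
}
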