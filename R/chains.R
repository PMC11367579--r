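#' Kinetic chains: rate matrices and Markov matrices
#'
#' A kinetic network is represented either by an infinitesimal generator
#' ("rate matrix") \eqn{K} in continuous time or by a transition-probability
#' ("Markov") matrix \eqn{Q(\tau)} at a fixed lag time \eqn{\tau}. Both use the
#' column-stochastic convention: probability is a column vector and evolves as
#' \eqn{p(t) = e^{Kt} p(0)} (equivalently \eqn{p(l\tau) = Q^l p(0)}), so each
#' column of \eqn{K} sums to 0 and each column of \eqn{Q} sums to 1. Matrices
#' laid out row-stochastically can be transposed at load time
#' (see [read_kinetic_matrix()]).
#'
#' @param m square numeric matrix, column-stochastic orientation.
#' @param tol structural tolerance for the column-sum (conservation) check.
#' @param lag_tau lag time associated with a Markov matrix (time units).
#'
#' @return An object of class `rate_matrix` or `markov_matrix` (both inherit
#'   from `kinetic_chain`): a list with elements `matrix`, `n_states`, `kind`
#'   and, for Markov matrices, `lag_tau`.
#'
#' @details Validation enforces (i) non-negative off-diagonal rates /
#'   probabilities in \eqn{[0,1]}, (ii) conservation of probability (column
#'   sums 0 resp. 1 within `tol`), and (iii) irreducibility, checked as strong
#'   connectivity of the graph of non-zero entries. Each violation raises a
#'   distinct condition class (`kemenet_negative_rate`,
#'   `kemenet_probability_range`, `kemenet_conservation`, `kemenet_reducible`).
#'   Column sums within `tol` are re-symmetrized exactly by adjusting the
#'   diagonal so that downstream spectral computations see an exact generator.
#' @examples
#' rate_matrix(matrix(c(-1, 1, 1, -1), 2))
#' markov_matrix(matrix(c(0.9, 0.1, 0.2, 0.8), 2))
#' @export
rate_matrix <- function(m, tol = 1e-10) {
  assert_square(m)
  off <- m
  diag(off) <- 0
  if (any(off < 0))
    stop_kemenet("negative_rate", sprintf(
      "rate matrix has %d negative off-diagonal entr%s",
      sum(off < 0), if (sum(off < 0) == 1L) "y" else "ies"))
  cs <- colSums(m)
  bad <- which(abs(cs) > tol * max(1, max(abs(m))))
  if (length(bad))
    stop_kemenet("conservation", sprintf(
      "column %d sums to %.6g (conservation of probability requires 0)",
      bad[1L], cs[bad[1L]]))
  diag(m) <- diag(m) - cs  # enforce exact conservation
  if (!is_irreducible(m))
    stop_kemenet("reducible", "chain is reducible (more than one communicating class)")
  structure(list(matrix = unname(m), n_states = nrow(m), kind = "rate"),
            class = c("rate_matrix", "kinetic_chain"))
}

#' @rdname rate_matrix
#' @export
markov_matrix <- function(m, lag_tau = 1, tol = 1e-10) {
  assert_square(m)
  if (any(m < -tol) || any(m > 1 + tol))
    stop_kemenet("probability_range", "Markov matrix entries must lie in [0, 1]")
  m[m < 0] <- 0
  m[m > 1] <- 1
  cs <- colSums(m)
  bad <- which(abs(cs - 1) > tol)
  if (length(bad))
    stop_kemenet("conservation", sprintf(
      "column %d sums to %.6g (conservation of probability requires 1)",
      bad[1L], cs[bad[1L]]))
  m <- sweep(m, 2L, cs, "/")  # exact column stochasticity
  if (!is_irreducible(m))
    stop_kemenet("reducible", "chain is reducible (more than one communicating class)")
  if (!is.numeric(lag_tau) || length(lag_tau) != 1L || lag_tau <= 0)
    stop_kemenet("bad_lag", "lag_tau must be a positive scalar")
  structure(list(matrix = unname(m), n_states = nrow(m), kind = "markov",
                 lag_tau = lag_tau),
            class = c("markov_matrix", "kinetic_chain"))
}

#' Validate a kinetic matrix of a stated kind
#'
#' Thin dispatcher over [rate_matrix()] / [markov_matrix()] for code paths
#' (file loading, configuration) where the kind arrives as data.
#'
#' @param m square numeric matrix.
#' @param kind `"rate"` or `"markov"`.
#' @param tolerance structural tolerance, default `1e-10`.
#' @param lag_tau lag time, used for `kind = "markov"` only.
#' @return a validated `kinetic_chain`.
#' @export
validate_chain <- function(m, kind = c("rate", "markov"), tolerance = 1e-10,
                           lag_tau = 1) {
  kind <- match.arg(kind)
  if (kind == "rate") rate_matrix(m, tol = tolerance)
  else markov_matrix(m, lag_tau = lag_tau, tol = tolerance)
}

#' @export
print.kinetic_chain <- function(x, ...) {
  cat(sprintf("<%s> %d states%s\n",
              class(x)[1L], x$n_states,
              if (x$kind == "markov") sprintf(", lag_tau = %g", x$lag_tau) else ""))
  invisible(x)
}

chain_matrix <- function(chain) chain$matrix

is_rate <- function(chain) inherits(chain, "rate_matrix")

#' Stationary (equilibrium) distribution of a kinetic chain
#'
#' Solves \eqn{K p = 0} (or \eqn{Q p = p}) together with \eqn{\sum_i p_i = 1}
#' as a bordered linear system, which is well posed exactly when the dominant
#' eigenspace is one-dimensional, i.e. when the chain is irreducible.
#'
#' @param chain validated `kinetic_chain`.
#' @param tol residual tolerance on \eqn{K p} (resp. \eqn{Q p - p}).
#' @return numeric vector `p_eq` of positive entries summing to 1.
#' @export
equilibrium <- function(chain, tol = 1e-8) {
  m <- chain_matrix(chain)
  n <- nrow(m)
  a <- if (is_rate(chain)) m else m - diag(n)
  sys <- rbind(a[-1L, , drop = FALSE], rep(1, n))
  b <- c(rep(0, n - 1L), 1)
  p <- tryCatch(solve(sys, b), error = function(e)
    stop_kemenet("reducible", "stationary system is singular: dominant eigenspace is degenerate"))
  if (any(p <= 0))
    stop_kemenet("reducible", "stationary vector has non-positive entries; chain is not irreducible")
  p <- p / sum(p)
  if (max(abs(a %*% p)) > tol * max(1, max(abs(m))))
    stop_kemenet("reducible", "stationary residual exceeds tolerance")
  p
}

#' Detailed-balance diagnostic
#'
#' A chain is reversible when the equilibrium fluxes balance pairwise,
#' \eqn{p_i K_{ji} = p_j K_{ij}} (and likewise for \eqn{Q}). Reversibility
#' guarantees a real spectrum and is assumed by the spectral machinery.
#'
#' @param chain validated `kinetic_chain`.
#' @param p_eq optional precomputed equilibrium distribution.
#' @param tol relative tolerance on the flux asymmetry.
#' @return logical; attribute `"residual"` carries the maximum relative
#'   flux asymmetry.
#' @export
detailed_balance <- function(chain, p_eq = NULL, tol = 1e-8) {
  p <- p_eq %||% equilibrium(chain)
  f <- chain_matrix(chain) %*% diag(p)   # flux matrix, symmetric under reversibility
  res <- max(abs(f - t(f))) / max(abs(f))
  structure(res <= tol, residual = res)
}

#' Spectral decomposition of a reversible kinetic chain
#'
#' Eigenvalues and biorthonormal left/right eigenvectors, computed through the
#' symmetrizing similarity transform
#' \eqn{B = \mathrm{diag}(p)^{-1/2} K\, \mathrm{diag}(p)^{1/2}}, which is
#' symmetric exactly when the chain satisfies detailed balance, so the spectrum
#' is real by construction. Eigenvalues are sorted in descending order with
#' \eqn{\lambda_1 = 0} (rate matrix) or \eqn{\lambda_1 = 1} (Markov matrix).
#' Eigenvectors are scaled to the conventions
#' \eqn{\sum_j \phi^{(l)}_j \psi^{(m)}_j = \delta_{lm}} and
#' \eqn{\sum_j \psi^{(l)}_j = \delta_{l1}}, so \eqn{\psi^{(1)} = p^{eq}} and
#' \eqn{\phi^{(1)} = 1}.
#'
#' @param chain validated `kinetic_chain`.
#' @param p_eq optional precomputed equilibrium distribution.
#' @param tol detailed-balance tolerance; beyond it the decomposition refuses
#'   to proceed (condition class `kemenet_detailed_balance`).
#' @return object of class `spectral_decomposition`: list with `eigenvalues`
#'   (descending), `right` (columns \eqn{\psi^{(l)}}), `left` (columns
#'   \eqn{\phi^{(l)}}), `p_eq`, `is_continuous`.
#' @export
spectral_decompose <- function(chain, p_eq = NULL, tol = 1e-8) {
  p <- p_eq %||% equilibrium(chain)
  db <- detailed_balance(chain, p, tol = tol)
  if (!db) {
    ev <- eigen(chain_matrix(chain), only.values = TRUE)$values
    stop_kemenet("detailed_balance", sprintf(
      paste0("detailed balance violated (relative flux asymmetry %.3g, ",
             "largest imaginary eigenvalue magnitude %.3g)"),
      attr(db, "residual"), max(abs(Im(ev)))))
  }
  sq <- sqrt(p)
  b <- chain_matrix(chain) * outer(1 / sq, sq)
  b <- (b + t(b)) / 2                      # symmetrize roundoff
  es <- eigen(b, symmetric = TRUE)         # values already descending
  u <- es$vectors
  # orient: stationary mode positive, others by their largest-|.| entry
  for (l in seq_len(ncol(u))) {
    j <- which.max(abs(u[, l]))
    if (u[j, l] < 0) u[, l] <- -u[, l]
  }
  psi <- u * sq          # right eigenvectors, psi^(1) = p
  phi <- u / sq          # left eigenvectors,  phi^(1) = 1
  structure(list(eigenvalues = es$values, right = psi, left = phi,
                 p_eq = p, is_continuous = is_rate(chain),
                 lag_tau = if (is_rate(chain)) NULL else chain$lag_tau),
            class = "spectral_decomposition")
}

#' @export
print.spectral_decomposition <- function(x, ...) {
  cat(sprintf("<spectral_decomposition> %d states (%s time), slowest relaxation %0.4g\n",
              length(x$eigenvalues),
              if (x$is_continuous) "continuous" else "discrete",
              relaxation_times(x)[1L]))
  invisible(x)
}

# Relaxation times 1/|lambda_l| (continuous) or 1/(1 - lambda_l) (discrete),
# one per non-stationary mode, in descending order.
relaxation_times <- function(decomp) {
  lam <- decomp$eigenvalues[-1L]
  if (decomp$is_continuous) 1 / abs(lam) else 1 / (1 - lam)
}

#' Discretize a rate matrix into a Markov matrix at a lag time
#'
#' Computes \eqn{Q(\tau) = e^{K\tau}} by matrix exponential. The conversion is
#' always explicit: no function in the package silently switches a chain
#' between the continuous and discrete representations.
#'
#' @param chain a `rate_matrix`.
#' @param tau lag time; default `1/max|K_ii|`, the fastest expected waiting
#'   time, which keeps the transition probabilities well away from both 0
#'   and 1.
#' @return a validated `markov_matrix` with `lag_tau = tau`.
#' @export
markov_from_rate <- function(chain, tau = NULL) {
  if (!is_rate(chain)) stop_kemenet("bad_kind", "markov_from_rate expects a rate_matrix")
  k <- chain_matrix(chain)
  tau <- tau %||% (1 / max(abs(diag(k))))
  q <- as.matrix(Matrix::expm(Matrix::Matrix(k * tau)))
  markov_matrix(q, lag_tau = tau)
}
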