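# Shared fixtures, built in code.

two_state_rate <- function(a = 1, b = 1) {
  rate_matrix(matrix(c(-a, a, b, -b), 2))
}

# random-walk generator of the 3-cycle: eigenvalues 0, -1.5, -1.5
cycle3_rate <- function() {
  adj <- matrix(1, 3, 3) - diag(3)
  laplacian_rate(adj)
}

# uniform 3-cycle rate matrix with all rates 1: eigenvalues 0, -3, -3
cycle3_rate_unit <- function() {
  k <- matrix(1, 3, 3)
  diag(k) <- -2
  rate_matrix(k)
}

# discrete symmetric 3-cycle: hop 1/2 to each neighbour
cycle3_markov <- function() {
  markov_matrix(matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3))
}

# Independent MFPT oracle: for each target state j, delete row/column j of the
# (row-oriented) generator and solve the hitting-time linear system.
mfpt_linear_solve <- function(chain) {
  n <- chain$n_states
  m <- chain$matrix
  out <- matrix(0, n, n)
  if (inherits(chain, "rate_matrix")) {
    r <- t(m)
    for (j in seq_len(n)) out[j, -j] <- solve(r[-j, -j], rep(-1, n - 1L))
  } else {
    p_row <- t(m)
    a <- diag(n) - p_row
    for (j in seq_len(n)) out[j, -j] <- solve(a[-j, -j], rep(1, n - 1L))
  }
  out
}

# Explicit crisp-lumping oracle: build the lumped chain directly from integer
# labels by summing fluxes, then take its Kemeny constant spectrally.
crisp_lump_kc <- function(chain, labels) {
  labels <- as.integer(labels)
  if (min(labels) == 0L) labels <- labels + 1L
  m <- max(labels)
  p <- equilibrium(chain)
  flux <- chain$matrix %*% diag(p)
  gh <- matrix(0, m, m)
  for (k in seq_len(m)) for (l in seq_len(m))
    gh[k, l] <- sum(flux[labels == k, labels == l, drop = FALSE])
  p_hat <- vapply(seq_len(m), function(l) sum(p[labels == l]), 1.0)
  qh <- sweep(gh, 2L, p_hat, "/")
  if (m == 1L) return(0)
  coarse <- if (inherits(chain, "rate_matrix")) rate_matrix(qh, tol = 1e-8)
            else markov_matrix(qh, tol = 1e-8)
  as.numeric(kemeny_constant(spectral_decompose(coarse)))
}

random_soft_assignment <- function(n, m) {
  s <- matrix(stats::runif(n * m), n)
  s / rowSums(s)
}
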