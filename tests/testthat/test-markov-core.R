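test_that("chain validation accepts valid generators and Markov matrices", {
  ch <- rate_matrix(matrix(c(-1, 1, 1, -1), 2))
  expect_s3_class(ch, "rate_matrix")
  expect_equal(ch$n_states, 2L)
  mm <- markov_matrix(matrix(c(0.9, 0.1, 0.2, 0.8), 2))
  expect_s3_class(mm, "markov_matrix")
  expect_equal(colSums(mm$matrix), c(1, 1))
})

test_that("each validation failure raises its own condition class", {
  expect_error(rate_matrix(matrix(1:6, 2, 3)), class = "kemenet_nonsquare")
  expect_error(rate_matrix(matrix(c(-1, 1, -0.5, 0.5), 2)),
               class = "kemenet_negative_rate")
  # conservation violated: column 2 sums to -1
  expect_error(rate_matrix(matrix(c(-1, 1, 0, -1), 2)),
               class = "kemenet_conservation")
  expect_error(markov_matrix(matrix(c(0.5, 0.5, 1.2, -0.2), 2)),
               class = "kemenet_probability_range")
  # two disconnected 2-state blocks
  block <- matrix(c(-1, 1, 1, -1), 2)
  k4 <- as.matrix(Matrix::bdiag(block, block))
  expect_error(rate_matrix(k4), class = "kemenet_reducible")
})

test_that("equilibrium distributions match closed forms", {
  expect_equal(equilibrium(two_state_rate(1, 1)), c(0.5, 0.5))
  # 2-state detailed balance a p1 = b p2
  expect_equal(equilibrium(two_state_rate(2, 1)), c(1 / 3, 2 / 3))
  # doubly stochastic chain is uniform
  expect_equal(equilibrium(cycle3_markov()), rep(1 / 3, 3))
})

test_that("spectral decomposition satisfies the stated conventions", {
  for (ch in list(two_state_rate(2, 5), random_reversible_chain(12, seed = 4),
                  random_reversible_chain(9, kind = "markov", seed = 5))) {
    dec <- spectral_decompose(ch)
    n <- ch$n_states
    lead <- if (dec$is_continuous) 0 else 1
    expect_equal(dec$eigenvalues[1L], lead, tolerance = 1e-10)
    expect_true(all(dec$eigenvalues[-1L] < lead))
    # biorthonormality and the right-eigenvector sum convention
    expect_equal(t(dec$left) %*% dec$right, diag(n), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(colSums(dec$right), c(1, rep(0, n - 1L)), tolerance = 1e-8)
    expect_equal(dec$right[, 1L], dec$p_eq, tolerance = 1e-10)
  }
})

test_that("known spectra are reproduced", {
  expect_equal(spectral_decompose(two_state_rate())$eigenvalues, c(0, -2))
  expect_equal(spectral_decompose(cycle3_rate())$eigenvalues, c(0, -1.5, -1.5),
               tolerance = 1e-10)
})

test_that("a one-way cycle is flagged as violating detailed balance", {
  k <- matrix(c(-1, 1, 0, 0, -1, 1, 1, 0, -1), 3)  # 1 -> 2 -> 3 -> 1 only
  ch <- rate_matrix(k)
  expect_false(detailed_balance(ch))
  expect_error(spectral_decompose(ch), class = "kemenet_detailed_balance")
})

test_that("MFPTs match closed forms and the linear-solve oracle", {
  # exponential waiting times of the 2-state chain: t21 = 1/a, t12 = 1/b
  tm <- mfpt(spectral_decompose(two_state_rate(2, 5)))
  expect_equal(tm, matrix(c(0, 0.5, 0.2, 0), 2), tolerance = 1e-12)
  # symmetric discrete 3-cycle: all off-diagonal MFPTs are 2 steps
  tm3 <- mfpt(spectral_decompose(cycle3_markov()))
  expect_equal(tm3, matrix(2, 3, 3) - 2 * diag(3), tolerance = 1e-12)
  # random reversible chains vs the independent linear solve, both kinds
  for (kind in c("rate", "markov")) {
    ch <- random_reversible_chain(10, kind = kind, seed = 11)
    spec <- mfpt(spectral_decompose(ch))
    oracle <- mfpt_linear_solve(ch)
    rel <- abs(spec - oracle) / (oracle + diag(10))
    expect_lt(max(rel), 1e-8)
  }
})

test_that("the Kemeny constant agrees across both routes and start states", {
  expect_equal(as.numeric(kemeny_constant(spectral_decompose(two_state_rate()))), 0.5)
  # all-rates-1 3-cycle: eigenvalues (0, -3, -3), zeta = 1/3 + 1/3
  expect_equal(spectral_decompose(cycle3_rate_unit())$eigenvalues, c(0, -3, -3),
               tolerance = 1e-12)
  expect_equal(as.numeric(kemeny_constant(spectral_decompose(cycle3_rate_unit()))),
               2 / 3, tolerance = 1e-12)
  expect_equal(as.numeric(kemeny_constant(spectral_decompose(cycle3_markov()))),
               4 / 3, tolerance = 1e-12)
  set.seed(20)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    ch <- random_reversible_chain(n, kind = sample(c("rate", "markov"), 1))
    dec <- spectral_decompose(ch)
    z <- kemeny_constant(dec)   # errors if either identity fails beyond 1e-8
    expect_lt(attr(z, "spread"), 1e-8 * max(1, z))
    expect_equal(as.numeric(z), sum(kemenet:::relaxation_times(dec)),
                 tolerance = 1e-10)
  }
})

test_that("cluster equilibrium reduces correctly in the limiting assignments", {
  ch <- random_reversible_chain(8, seed = 3)
  p <- equilibrium(ch)
  expect_equal(cluster_equilibrium(diag(8), p), p)
  expect_equal(cluster_equilibrium(matrix(1, 8, 1), p), 1)
  expect_equal(cluster_equilibrium(matrix(1 / 4, 8, 4), p), rep(1 / 4, 4))
})

test_that("coarse-graining reproduces the identity and single-cluster limits", {
  ch <- random_reversible_chain(10, seed = 9)
  dec <- spectral_decompose(ch)
  zeta <- as.numeric(kemeny_constant(dec))
  cg_id <- coarse_grain(ch, dec$p_eq, diag(10))
  expect_equal(cg_id$Q_hat, ch$matrix, tolerance = 1e-12)
  expect_lt(abs(delta_k(zeta, cg_id)), 1e-10)
  cg_one <- coarse_grain(ch, dec$p_eq, matrix(1, 10, 1))
  expect_identical(cg_one$zeta_S, 0)
  expect_lt(abs(delta_k(zeta, cg_one) - zeta), 1e-10)
})

test_that("lumped-chain Kemeny constants match the explicit crisp oracle", {
  s <- sample_sbm(40, 4, regime = "A", seed = 21)
  ch <- laplacian_rate(s$adjacency)
  dec <- spectral_decompose(ch)
  cg <- coarse_grain(ch, dec$p_eq, labels_to_assignment(s$labels))
  expect_equal(cg$zeta_S, crisp_lump_kc(ch, s$labels), tolerance = 1e-8)
  # discrete chain, 2-cluster partition {1}, {2, 3} of the 3-cycle
  m3 <- cycle3_markov()
  dec3 <- spectral_decompose(m3)
  lab <- c(1L, 2L, 2L)
  cg3 <- coarse_grain(m3, dec3$p_eq, labels_to_assignment(lab))
  expect_equal(cg3$zeta_S, crisp_lump_kc(m3, lab), tolerance = 1e-10)
  dk <- delta_k(kemeny_constant(dec3), cg3)
  expect_equal(dk, 4 / 3 - crisp_lump_kc(m3, lab), tolerance = 1e-10)
})

test_that("degenerate clusters are rejected", {
  ch <- random_reversible_chain(6, seed = 2)
  p <- equilibrium(ch)
  s <- cbind(rep(1, 6), rep(0, 6))
  expect_error(coarse_grain(ch, p, s), class = "kemenet_degenerate_cluster")
})

test_that("Delta-K is within [0, zeta] over exhaustive 2-cluster partitions", {
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(4:8, 1)
    ch <- random_reversible_chain(n, kind = sample(c("rate", "markov"), 1))
    dec <- spectral_decompose(ch)
    zeta <- as.numeric(kemeny_constant(dec))
    # all 2^(n-1) - 1 bipartitions (node 1 fixed to cluster 1)
    for (code in 1:(2^(n - 1L) - 1L)) {
      lab <- c(1L, 1L + as.integer(intToBits(code)[seq_len(n - 1L)]))
      cg <- coarse_grain(ch, dec$p_eq, labels_to_assignment(lab))
      dk <- delta_k(zeta, cg)
      expect_gte(dk, -1e-8)
      expect_lte(dk, zeta + 1e-8)
    }
  }
})

test_that("explicit rate-to-Markov discretization preserves the kinetics", {
  ch <- random_reversible_chain(8, seed = 17)
  q <- markov_from_rate(ch, tau = 0.3)
  expect_equal(q$lag_tau, 0.3)
  expect_equal(equilibrium(q), equilibrium(ch), tolerance = 1e-9)
  # eigenvalues embed as exp(tau * lambda)
  lam_k <- spectral_decompose(ch)$eigenvalues
  lam_q <- spectral_decompose(q)$eigenvalues
  expect_equal(lam_q, exp(0.3 * lam_k), tolerance = 1e-9)
})
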