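clique_pair <- function(n_clique = 4L, bridge = FALSE) {
  n <- 2L * n_clique
  adj <- matrix(0L, n, n)
  idx1 <- seq_len(n_clique)
  idx2 <- n_clique + idx1
  adj[idx1, idx1] <- 1L
  adj[idx2, idx2] <- 1L
  diag(adj) <- 0L
  if (bridge) adj[1, n_clique + 1L] <- adj[n_clique + 1L, 1] <- 1L
  adj
}

test_that("modularity matches known values and bounds", {
  adj <- clique_pair()
  labels <- rep(1:2, each = 4)
  expect_equal(modularity(adj, labels), 0.5, tolerance = 1e-12)
  # single cluster: the null term cancels the edge fraction exactly
  expect_equal(modularity(adj, rep(1L, 8)), 0, tolerance = 1e-12)
  # any labelling of a complete graph is never positive (exhaustive, N = 6)
  k6 <- matrix(1L, 6, 6) - diag(6L)
  for (code in 0:(3^5 - 1)) {
    digits <- (code %/% 3^(0:4)) %% 3
    lab <- c(1L, as.integer(digits) + 1L)
    expect_lte(modularity(k6, lab), 1e-8)
  }
  expect_error(modularity(matrix(0L, 3, 3), rep(1L, 3)),
               class = "kemenet_empty_graph")
})

test_that("cut sizes count intercluster edges", {
  adj <- clique_pair(bridge = TRUE)
  labels <- rep(1:2, each = 4)
  expect_equal(min_cut(adj, labels), 1)
  expect_equal(min_cut(adj, rep(1L, 8)), 0)
  # identity partition of a 3-cycle cuts all 3 edges
  c3 <- matrix(1L, 3, 3) - diag(3L)
  expect_equal(min_cut(c3, 1:3), 3)
})

test_that("soft and crisp evaluations coincide for crisp assignments", {
  set.seed(4)
  s <- sample_sbm(20, 4, seed = 5)
  labels <- s$labels
  S <- labels_to_assignment(labels)
  expect_identical(modularity(s$adjacency, labels), modularity(s$adjacency, S))
  expect_identical(min_cut(s$adjacency, labels), min_cut(s$adjacency, S))
  # relabeling invariance
  perm <- c(3L, 1L, 4L, 2L)
  expect_equal(modularity(s$adjacency, perm[labels]),
               modularity(s$adjacency, labels))
  expect_equal(min_cut(s$adjacency, perm[labels]), min_cut(s$adjacency, labels))
})

test_that("DBI matches direct evaluation and an independent implementation", {
  # two zero-diameter clusters at distinct centroids
  f0 <- rbind(matrix(1, 3, 2), matrix(-1, 3, 2))
  expect_equal(dbi(f0, rep(1:2, each = 3)), 0)
  # duplicated configuration: both clusters the same point set, shifted
  pts <- matrix(c(0, 0, 1, 0, 0.5, 1), 3, byrow = TRUE)
  shift <- cbind(pts[, 1] + 10, pts[, 2])
  f <- rbind(pts, shift)
  lab <- rep(1:2, each = 3)
  sigma <- mean(sqrt(rowSums((pts - matrix(colMeans(pts), 3, 2,
                                           byrow = TRUE))^2)))
  expect_equal(dbi(f, lab), 2 * sigma / 10, tolerance = 1e-12)
  # independent straight-from-definition implementation on random data
  ref_dbi <- function(f, lab) {
    m <- max(lab)
    cent <- lapply(1:m, function(l) colMeans(f[lab == l, , drop = FALSE]))
    sig <- sapply(1:m, function(l)
      mean(sqrt(colSums((t(f[lab == l, , drop = FALSE]) - cent[[l]])^2))))
    mean(sapply(1:m, function(k)
      max(sapply((1:m)[-k], function(l)
        (sig[k] + sig[l]) / sqrt(sum((cent[[k]] - cent[[l]])^2))))))
  }
  set.seed(9)
  for (i in 1:5) {
    f <- matrix(rnorm(40 * 3), 40)
    lab <- sample(1:4, 40, replace = TRUE)
    while (length(unique(lab)) < 4) lab <- sample(1:4, 40, replace = TRUE)
    expect_equal(dbi(f, lab), ref_dbi(f, lab), tolerance = 1e-8)
  }
  expect_error(dbi(f0, c(1, 1, 1, 3, 3, 3)), class = "kemenet_empty_cluster")
})

test_that("label agreement is permutation invariant and chance adjusted", {
  lab <- rep(1:4, each = 10)
  expect_equal(label_agreement(lab, lab), 1)
  perm <- c(2L, 4L, 1L, 3L)
  expect_equal(label_agreement(lab, perm[lab]), 1)
  set.seed(12)
  a <- sample(1:4, 1000, replace = TRUE)
  b <- sample(1:4, 1000, replace = TRUE)
  expect_lt(abs(label_agreement(a, b)), 0.05)
  expect_error(label_agreement(1:3, 1:4), class = "kemenet_dimension")
})

test_that("partition comparison reports are consistent and ordered", {
  s <- sample_sbm(24, 4, seed = 6)
  ch <- laplacian_rate(s$adjacency)
  set.seed(2)
  reports <- compare_partitions(ch, list(
    planted = s$labels,
    single = rep(1L, 24),
    identity = 1:24,
    random = sample(1:4, 24, replace = TRUE)))
  zeta <- reports$planted$zeta
  # the stated limits: identity has dK 0, single cluster has dK = zeta
  expect_lt(abs(reports$identity$delta_k), 1e-9)
  expect_equal(reports$single$delta_k, zeta, tolerance = 1e-9)
  # planted labels preserve more kinetics than random ones on regime A
  expect_lt(reports$planted$delta_k, reports$random$delta_k)
  expect_true(reports$single$dbi_omitted)
  df <- as.data.frame(reports)
  expect_identical(nrow(df), 4L)
  expect_true(all(df$delta_k_over_zeta >= -1e-9 &
                  df$delta_k_over_zeta <= 1 + 1e-9))
})
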