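test_that("GraphSAGE layer obeys the degenerate-input contracts", {
  set.seed(2)
  adj <- matrix(c(0, 1, 1, 1, 0, 0, 1, 0, 0), 3)
  h <- matrix(rnorm(6), 3)
  w0 <- matrix(0, 4, 5)
  b0 <- matrix(0, 1, 5)
  expect_equal(graphsage_layer(h, adj, w0, b0), matrix(0, 3, 5))
  # a node with no neighbours aggregates a zero vector: output depends only
  # on its own state
  adj_iso <- matrix(0, 2, 2)
  w <- matrix(rnorm(20), 4)
  h2 <- matrix(rnorm(4), 2)
  out <- graphsage_layer(h2, adj_iso, w, matrix(0, 1, 5))
  expect_equal(out, pmax(cbind(h2, 0 * h2) %*% w, 0))
})

test_that("encoders are permutation equivariant", {
  set.seed(3)
  s <- sample_sbm(16, 2, seed = 4)
  q <- markov_from_rate(laplacian_rate(s$adjacency))
  for (enc in c("graphsage", "gatv2")) {
    cfg <- model_config(enc, "linear", n_clusters = 3, n_encoder_layers = 2,
                        d_hidden = 8, d_embed = 4, attention_heads = 2)
    g <- graph_data(q, feature_spec("adjacency"))
    par <- generate_params(cfg, g, 5)
    s_out <- predict_assignment(g, cfg, par)
    # relabel nodes: permute feature rows and the adjacency accordingly
    perm <- sample(16)
    g2 <- g
    g2$adjacency <- g$adjacency[perm, perm]
    g2$features$F <- g$features$F[perm, , drop = FALSE]
    s_perm <- predict_assignment(g2, cfg, par)
    expect_equal(s_perm, s_out[perm, ], tolerance = 1e-10)
  }
})

test_that("GATv2 attention is a proper neighbourhood distribution", {
  set.seed(6)
  adj <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)
  hp <- list(list(Wl = matrix(rnorm(4), 2), Wr = matrix(rnorm(4), 2),
                  a = matrix(rnorm(2), 2)))
  # identical node states: uniform attention 1/|N(i)| over the attended set
  h_same <- matrix(rep(c(0.3, -0.2), each = 3), 3)
  res <- gatv2_layer(h_same, adj, hp, b = matrix(0, 1, 2))
  expect_equal(res$attention[[1]], matrix(1 / 3, 3, 3), tolerance = 1e-12)
  # random states: rows still sum to one over the mask
  h_rnd <- matrix(rnorm(6), 3)
  res2 <- gatv2_layer(h_rnd, adj, hp, b = matrix(0, 1, 2))
  expect_equal(rowSums(res2$attention[[1]]), rep(1, 3), tolerance = 1e-8)
  # single node with a self-loop attends to itself with weight exactly 1
  res1 <- gatv2_layer(matrix(c(1, 2), 1), matrix(0, 1, 1),
                      list(list(Wl = matrix(rnorm(4), 2),
                                Wr = matrix(rnorm(4), 2),
                                a = matrix(rnorm(2), 2))), b = matrix(0, 1, 2))
  expect_equal(res1$attention[[1]][1, 1], 1)
})

test_that("decoders emit row-stochastic assignments with softmax invariances", {
  set.seed(8)
  ch <- random_reversible_chain(10, kind = "markov", seed = 9)
  g <- graph_data(ch, feature_spec("mfpt"))
  for (dec in c("linear", "transformer")) {
    cfg <- model_config("graphsage", dec, n_clusters = 4,
                        n_encoder_layers = 2, d_hidden = 8, d_embed = 4,
                        attention_heads = 2, dropout_rate = 0)
    par <- generate_params(cfg, g, 3)
    s_out <- predict_assignment(g, cfg, par)
    expect_true(all(s_out >= 0 & s_out <= 1))
    expect_equal(rowSums(s_out), rep(1, 10), tolerance = 1e-8)
    # evaluation mode is deterministic
    expect_identical(s_out, predict_assignment(g, cfg, par))
  }
  # zero final-layer weights: exactly uniform assignment
  cfg <- model_config("graphsage", "linear", n_clusters = 5,
                      n_encoder_layers = 2, d_hidden = 8, d_embed = 4)
  par <- generate_params(cfg, g, 3)
  par$dec2_W[] <- 0
  par$dec2_b[] <- 0
  expect_equal(predict_assignment(g, cfg, par), matrix(1 / 5, 10, 5),
               tolerance = 1e-12)
})

test_that("the cluster-size penalty matches its closed form", {
  pp <- penalty_params()          # sigma = 1, eta = 15
  # a soft size-0 cluster contributes exactly eta
  s0 <- cbind(rep(1, 6), rep(0, 6))
  expect_equal(penalty(s0, pp), 15 * (1 + exp(-18)))
  # size 1 and size 3 contributions
  expect_equal(15 * exp(-1 / 2), 9.0979599, tolerance = 1e-6)
  expect_equal(15 * exp(-4.5), 0.16663495, tolerance = 1e-6)
  # monotone decreasing in every soft cluster size
  sizes <- seq(0, 4, by = 0.25)
  contrib <- pp$eta * exp(-sizes^2 / (2 * pp$sigma^2))
  expect_true(all(diff(contrib) < 0))
  expect_lt(contrib[sizes == 3], 0.2)
})

test_that("the soft loss reproduces the Delta-K limits", {
  ch <- random_reversible_chain(8, kind = "markov", seed = 12)
  # crisp identity assignment: Delta-K term 0, loss = penalty of unit clusters
  res_id <- kemeny_loss(diag(8), ch)
  expect_lt(abs(res_id$delta_k), 1e-10)
  expect_equal(res_id$loss, 8 * 15 * exp(-1 / 2), tolerance = 1e-10)
  # single cluster: loss = zeta + negligible penalty
  zeta <- as.numeric(kemeny_constant(spectral_decompose(ch)))
  res_one <- kemeny_loss(matrix(1, 8, 1), ch)
  expect_equal(res_one$delta_k, zeta, tolerance = 1e-10)
  expect_equal(res_one$loss, zeta + 15 * exp(-32), tolerance = 1e-10)
})

test_that("analytic loss gradients match central differences", {
  set.seed(42)
  ch <- random_reversible_chain(6, kind = "markov", seed = 3)
  s <- random_soft_assignment(6, 2)
  res <- kemeny_loss(s, ch, gradient = TRUE)
  num <- matrix(0, 6, 2)
  eps <- 1e-6
  for (i in seq_along(s)) {
    sp <- s; sp[i] <- sp[i] + eps
    sm <- s; sm[i] <- sm[i] - eps
    num[i] <- (kemeny_loss(sp, ch)$loss - kemeny_loss(sm, ch)$loss) / (2 * eps)
  }
  expect_lt(max(abs(res$gradient - num) / pmax(abs(num), 1e-8)), 1e-5)
})

test_that("model gradients match central differences through all layers", {
  set.seed(7)
  ch <- random_reversible_chain(6, kind = "markov", seed = 3)
  g <- graph_data(ch, feature_spec("mfpt"))
  lctx <- kemenet:::loss_context(g$chain, g$p_eq, g$zeta)
  for (arch in list(c("graphsage", "linear"), c("gatv2", "transformer"))) {
    cfg <- model_config(arch[1], arch[2], n_clusters = 2,
                        n_encoder_layers = 2, d_hidden = 8, d_embed = 4,
                        attention_heads = 2, dropout_rate = 0)
    par <- generate_params(cfg, g, 11)
    ctx <- kemenet:::model_context(g, cfg)
    loss_of <- function(p) {
      s_n <- kemenet:::model_forward(lapply(p, kemenet:::ad_const), ctx, cfg)
      kemenet:::kemeny_loss_node(s_n, lctx)$loss$value[1]
    }
    pn <- lapply(par, kemenet:::ad_param)
    parts <- kemenet:::kemeny_loss_node(
      kemenet:::model_forward(pn, ctx, cfg), lctx)
    kemenet:::ad_backward(parts$loss)
    worst <- 0
    for (nm in names(par)) {
      gr <- pn[[nm]]$grad
      if (is.null(gr)) next
      for (i in sample(length(par[[nm]]), min(3, length(par[[nm]])))) {
        eps <- 1e-6
        pp <- par; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- par; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
        # relative where the gradient is appreciable, absolute where the
        # finite difference itself is at cancellation level (the loss is
        # O(10), so central differences carry ~1e-9 absolute noise)
        worst <- max(worst, abs(gr[i] - num) / max(abs(num), 1e-3))
      }
    }
    expect_lt(worst, 1e-5)
  }
})

test_that("all four architectures produce valid assignments on generator output", {
  s <- sample_sbm(20, 4, seed = 13)
  q <- markov_from_rate(laplacian_rate(s$adjacency))
  g <- graph_data(q, feature_spec("mfpt"))
  for (enc in c("graphsage", "gatv2")) for (dec in c("linear", "transformer")) {
    cfg <- model_config(enc, dec, n_clusters = 4, n_encoder_layers = 2,
                        d_hidden = 8, d_embed = 4, attention_heads = 2)
    s_out <- predict_assignment(g, cfg, generate_params(cfg, g, 2))
    expect_equal(rowSums(s_out), rep(1, 20), tolerance = 1e-8,
                 info = paste(enc, dec))
    expect_true(all(is.finite(s_out)))
  }
})
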