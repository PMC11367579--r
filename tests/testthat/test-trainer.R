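small_problem <- function() {
  s <- sample_sbm(16, 2, regime = "A", seed = 2)
  q <- markov_from_rate(laplacian_rate(s$adjacency))
  list(graph = graph_data(q, feature_spec("mfpt")), labels = s$labels)
}

small_config <- function(...) {
  model_config("graphsage", "linear", n_clusters = 2, n_encoder_layers = 2,
               d_hidden = 8, d_embed = 4, ...)
}

test_that("parameter generation is seed-deterministic with Glorot scaling", {
  pr <- small_problem()
  cfg <- model_config(n_clusters = 4)   # full-size: 64 x 64 hidden weights
  p1 <- generate_params(cfg, pr$graph, 7)
  p2 <- generate_params(cfg, pr$graph, 7)
  expect_identical(p1, p2)
  p3 <- generate_params(cfg, pr$graph, 8)
  expect_false(identical(p1, p3))
  # Glorot: empirical variance of a square hidden weight near 2/(fi + fo)
  w <- p1$enc2_W        # (2*64) x 64
  expect_lt(abs(stats::var(as.vector(w)) / (2 / (128 + 64)) - 1), 0.2)
  # Kaiming alternative
  pk <- generate_params(cfg, pr$graph, 7, scheme = "kaiming")
  expect_lt(abs(stats::var(as.vector(pk$enc2_W)) / (2 / 128) - 1), 0.2)
})

test_that("training runs are bit-reproducible and zero-step runs are finite", {
  pr <- small_problem()
  cfg <- small_config()
  tc <- train_config(n_models = 2, n_steps = 10, seed = 3)
  r1 <- train_one(pr$graph, cfg, tc, 999)
  r2 <- train_one(pr$graph, cfg, tc, 999)
  expect_identical(r1$loss_trace, r2$loss_trace)
  expect_identical(r1$crisp_labels, r2$crisp_labels)
  expect_identical(r1$soft_assignment, r2$soft_assignment)
  tc0 <- train_config(n_models = 1, n_steps = 0, seed = 3)
  r0 <- train_one(pr$graph, cfg, tc0, 999)
  expect_true(is.finite(r0$final_loss))
  expect_identical(r0$steps_completed, 0L)
  # the zero-step loss equals the initial model's loss
  s0 <- predict_assignment(pr$graph, cfg, generate_params(cfg, pr$graph, 999))
  l0 <- kemeny_loss(s0, pr$graph$chain, pr$graph$p_eq)
  expect_equal(r0$final_loss, l0$loss, tolerance = 1e-12)
})

test_that("the loss decreases under training on a block-structured graph", {
  pr <- small_problem()
  cfg <- small_config()
  tc <- train_config(n_steps = 50, seed = 3)
  decreased <- 0L
  for (i in 1:10) {
    r <- train_one(pr$graph, cfg, tc, 100 + i)
    if (tail(r$loss_trace, 1) < r$loss_trace[1]) decreased <- decreased + 1L
  }
  expect_gte(decreased, 8L)
})

test_that("population results are invariant to the worker count", {
  pr <- small_problem()
  cfg <- small_config()
  tc1 <- train_config(n_models = 4, n_steps = 5, seed = 11, n_workers = 1)
  tc4 <- train_config(n_models = 4, n_steps = 5, seed = 11, n_workers = 4)
  pop1 <- train_population(pr$graph, cfg, tc1)
  pop4 <- train_population(pr$graph, cfg, tc4)
  for (i in 1:4) {
    expect_identical(pop1$records[[i]]$model_seed, pop4$records[[i]]$model_seed)
    expect_identical(pop1$records[[i]]$loss_trace, pop4$records[[i]]$loss_trace)
    expect_identical(pop1$records[[i]]$crisp_labels,
                     pop4$records[[i]]$crisp_labels)
  }
  # the best record minimizes the crisp Delta-K over non-culled runs
  dks <- vapply(pop1$records, function(r) r$final_delta_k, 1.0)
  expect_equal(pop1$best_record$final_delta_k, min(dks, na.rm = TRUE))
})

test_that("culling and termination policies honour their contracts", {
  expect_false(default_cull(c(5, 4, 3), 100, list()))
  expect_true(default_terminate(list(n_done = 3, n_models = 3)))
  expect_false(default_terminate(list(n_done = 1, n_models = 3)))
  pr <- small_problem()
  cfg <- small_config()
  # a threshold policy culls a run whose loss exceeds a bound
  tc <- train_config(n_models = 2, n_steps = 6, seed = 5, culling_interval = 2,
                     cull_fn = function(trace, step, state) tail(trace, 1) > -Inf)
  r <- train_one(pr$graph, cfg, tc, 77)
  expect_true(r$culled)
  expect_lte(r$steps_completed, 2L)
  # culled runs are excluded from best-record selection
  pop <- train_population(pr$graph, cfg, tc)
  expect_null(pop$best_record[["never"]])  # structure intact
  expect_true(all(vapply(pop$records, function(x) isTRUE(x$culled), TRUE)))
  expect_true(is.na(pop$best_index) || is.null(pop$best_record))
  # an early-termination policy stops the sequential population
  tc2 <- train_config(n_models = 6, n_steps = 2, seed = 5,
                      terminate_fn = function(state) state$n_done >= 2)
  pop2 <- train_population(pr$graph, cfg, tc2)
  expect_identical(length(pop2$records), 2L)
})

test_that("pretraining replicates a reference assignment", {
  pr <- small_problem()
  cfg <- small_config()
  # reference = the model's own initial output: zero loss from step one
  par0 <- generate_params(cfg, pr$graph, 21)
  s_self <- predict_assignment(pr$graph, cfg, par0)
  pre0 <- pretrain_to_reference(pr$graph, cfg, s_self, steps = 1,
                                model_seed = 21)
  expect_lt(pre0$mse_trace[1], 1e-20)
  # a crisp two-cluster reference is replicated in argmax after pretraining
  s_ref <- labels_to_assignment(pr$labels)
  pre <- pretrain_to_reference(pr$graph, cfg, s_ref, steps = 400,
                               model_seed = 21)
  s_fit <- predict_assignment(pr$graph, cfg, pre$params)
  expect_identical(max.col(s_fit), pr$labels)
  # pretrained parameters drop straight into Kemeny training
  tc <- train_config(n_steps = 3, seed = 1)
  r <- train_one(pr$graph, cfg, tc, 22, init_params = pre$params)
  expect_s3_class(r, "run_record")
  expect_true(is.finite(r$final_loss))
  expect_error(pretrain_to_reference(pr$graph, cfg, cbind(s_ref, 0)),
               class = "kemenet_dimension")
})

test_that("hyperparameter sweeps reduce to their cells and summarize correctly", {
  pr <- small_problem()
  cfg <- small_config()
  tc <- train_config(n_models = 3, n_steps = 4, seed = 9)
  sw <- hyperparameter_sweep(pr$graph, cfg, tc, list(d_hidden = c(4L, 8L)))
  expect_identical(nrow(sw), 2L)
  expect_true(all(c("d_hidden", "best_delta_k", "mean_delta_k", "sd_delta_k",
                    "frac_best") %in% names(sw)))
  # summary statistics match recomputation from the raw records
  pop <- train_population(pr$graph,
                          { c2 <- cfg; c2$d_hidden <- 4L; c2 }, tc)
  dks <- vapply(pop$records, function(r) r$final_delta_k, 1.0)
  dks <- dks[is.finite(dks)]
  expect_equal(sw$best_delta_k[1], min(dks))
  expect_equal(sw$mean_delta_k[1], mean(dks))
  expect_equal(sw$sd_delta_k[1], stats::sd(dks))
})
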