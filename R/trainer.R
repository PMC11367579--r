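#' Training configuration
#'
#' Population-based training: `n_models` independently initialized models are
#' optimized by Adam for `n_steps` gradient steps each, at learning rate
#' `1e-4` by default, in 64-bit arithmetic. Runs are fully determined by
#' their model seed (derived from `seed` by a counter scheme), so the result
#' set is identical for any worker count.
#'
#' @param n_models population size.
#' @param n_steps gradient steps per model.
#' @param learning_rate Adam learning rate.
#' @param n_workers parallel workers (forked; each run is self-contained).
#' @param culling_interval steps between culling checks.
#' @param seed master seed; model seed for run i is
#'   `(seed * 1000003 + i) mod (2^31 - 1)`.
#' @param init_scheme `"glorot"` (default) or `"kaiming"`.
#' @param cull_fn `NULL` for the default policy (never cull: runs terminate
#'   after the predetermined number of steps) or a
#'   `function(trace, step, population_state) -> logical`.
#' @param terminate_fn `NULL` for the default policy (stop when all runs have
#'   finished or been culled) or a `function(population_state) -> logical`,
#'   consulted after each completed run; early termination requires
#'   `n_workers = 1` to keep results order-independent.
#' @param penalty a [penalty_params()].
#' @param trace_thin keep every `trace_thin`-th loss value (1 = full trace).
#' @return a `train_config` list.
#' @export
train_config <- function(n_models = 100L, n_steps = 250L,
                         learning_rate = 1e-4, n_workers = 1L,
                         culling_interval = 50L, seed = 1L,
                         init_scheme = c("glorot", "kaiming"),
                         cull_fn = NULL, terminate_fn = NULL,
                         penalty = penalty_params(), trace_thin = 1L) {
  init_scheme <- match.arg(init_scheme)
  stopifnot(n_models >= 1L, n_steps >= 0L, learning_rate > 0, n_workers >= 1L)
  structure(list(n_models = as.integer(n_models), n_steps = as.integer(n_steps),
                 learning_rate = learning_rate, n_workers = as.integer(n_workers),
                 culling_interval = as.integer(culling_interval),
                 seed = as.integer(seed), init_scheme = init_scheme,
                 cull_fn = cull_fn, terminate_fn = terminate_fn,
                 penalty = penalty, trace_thin = as.integer(trace_thin)),
            class = "train_config")
}

model_seed_for <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 1000003 + i) %% 2147483647)
}

#' Default culling policy: never cull
#'
#' All runs terminate after the predetermined number of training steps.
#' Pluggable policies receive the loss trace so far, the current step, and a
#' population-state list (possibly empty under parallel execution).
#'
#' @param trace numeric loss trace so far.
#' @param step current step index.
#' @param population_state list of population statistics.
#' @return logical.
#' @export
default_cull <- function(trace, step, population_state = list()) FALSE

#' Default termination policy: all runs finished or culled
#'
#' @param population_state list with at least `n_done`, `n_models` and
#'   `records` (completed run records so far).
#' @return logical.
#' @export
default_terminate <- function(population_state) {
  population_state$n_done >= population_state$n_models
}

# --- Adam --------------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Sequential execution in forked batches: long training populations keep a
# flat memory profile when each batch of runs lives in a short-lived child
# process (every run seeds its own random stream, so results are identical
# to a plain lapply). Falls back to lapply where fork is unavailable.
run_in_batches <- function(seeds, run, batch_size = 8L) {
  if (.Platform$OS.type != "unix") return(lapply(seeds, run))
  out <- vector("list", length(seeds))
  i <- 1L
  while (i <= length(seeds)) {
    idx <- i:min(i + batch_size - 1L, length(seeds))
    job <- parallel::mcparallel(lapply(seeds[idx], run), silent = TRUE)
    got <- parallel::mccollect(job)[[1L]]
    if (!is.list(got) || length(got) != length(idx)) {
      got <- lapply(seeds[idx], run)   # fork failed; redo in-process
    }
    out[idx] <- got
    i <- i + batch_size
  }
  out
}

# --- single-run training -----------------------------------------------------

crisp_labels_of <- function(S) max.col(S, ties.method = "first") - 1L

# Crisp Delta-K of argmax labels; +Inf when a cluster is empty (the
# partitioning is invalid and must never win best-record selection).
crisp_delta_k <- function(graph, labels, m) {
  if (length(unique(labels)) < m) return(Inf)
  S <- labels_to_assignment(labels + 1L, m)
  cg <- coarse_grain(graph$chain, graph$p_eq, S)
  delta_k(graph$zeta, cg)
}

#' Train one partitioning model
#'
#' Runs `n_steps` of Adam on the Kemeny loss for a single model whose
#' initialization (and any dropout) is fully determined by `model_seed`.
#' The loss is \eqn{\Delta K(S) + \mathrm{penalty}(S)} through the soft
#' lumping path; the returned crisp labels are the row-wise argmax of the
#' final soft assignment (ties broken toward the lowest cluster index) and
#' `final_delta_k` is the crisp partitioning's \eqn{\Delta K}.
#'
#' @param graph a [graph_data()] whose chain carries the loss (use a discrete
#'   chain; see the vignette on why rate matrices are discretized first).
#' @param config a [model_config()].
#' @param tc a [train_config()] (its `n_models`/`n_workers` are ignored here).
#' @param model_seed integer seed for this run.
#' @param init_params optional pretrained parameters to start from (e.g. from
#'   [pretrain_to_reference()]); initialization randomness is still consumed
#'   so dropout streams stay aligned.
#' @param population_state forwarded to the culling policy.
#' @return a `run_record` list: `model_seed`, `final_loss`, `final_delta_k`,
#'   `crisp_labels` (0-based), `soft_assignment`, `loss_trace`,
#'   `steps_completed`, `culled`.
#' @export
train_one <- function(graph, config, tc, model_seed, init_params = NULL,
                      population_state = list()) {
  set.seed(model_seed)
  params <- generate_params(config, graph, model_seed, tc$init_scheme)
  if (!is.null(init_params)) params <- init_params
  ctx <- model_context(graph, config)
  lctx <- loss_context(graph$chain, graph$p_eq, graph$zeta, tc$penalty)
  st <- adam_state(params)
  cull_fn <- tc$cull_fn %||% default_cull
  trace <- numeric(0)
  culled <- FALSE
  steps_done <- 0L
  for (step in seq_len(tc$n_steps)) {
    pn <- lapply(params, ad_param)
    s_node <- model_forward(pn, ctx, config, training = TRUE)
    parts <- kemeny_loss_node(s_node, lctx)
    lv <- parts$loss$value[1L]
    if (!is.finite(lv)) {
      culled <- TRUE
      attr(culled, "failed_step") <- step
      break
    }
    if (step %% tc$trace_thin == 0L) trace <- c(trace, lv)
    ad_backward(parts$loss)
    upd <- adam_step(params, lapply(pn, function(n) n$grad), st,
                     tc$learning_rate)
    params <- upd$params
    st <- upd$state
    steps_done <- step
    if (step %% tc$culling_interval == 0L &&
        isTRUE(cull_fn(trace, step, population_state))) {
      culled <- TRUE
      break
    }
  }
  s_final <- ad_value(model_forward(lapply(params, ad_const), ctx, config,
                                    training = FALSE))
  final_parts <- kemeny_loss_node(ad_const(s_final), lctx)
  labels <- crisp_labels_of(s_final)
  structure(list(model_seed = model_seed,
                 final_loss = final_parts$loss$value[1L],
                 final_delta_k = if (culled) NA_real_
                                 else crisp_delta_k(graph, labels, config$n_clusters),
                 crisp_labels = labels,
                 soft_assignment = s_final,
                 loss_trace = trace,
                 steps_completed = steps_done,
                 culled = culled),
            class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record seed %d> %d steps, loss %.6g, crisp dK %s%s\n",
              x$model_seed, x$steps_completed, x$final_loss,
              format(x$final_delta_k, digits = 6),
              if (x$culled) " [culled]" else ""))
  invisible(x)
}

#' Train a population of independently initialized models
#'
#' Optimizes `n_models` models with seeds derived from the master seed by the
#' counter scheme, optionally across forked workers. Because each run seeds
#' its own random stream, the returned record set is bit-identical for any
#' `n_workers`. The best record is the non-culled run with the lowest crisp
#' \eqn{\Delta K}.
#'
#' @param graph a [graph_data()].
#' @param config a [model_config()].
#' @param tc a [train_config()].
#' @param init_params optional shared starting parameters for every run.
#' @return `population_result`: list with `records`, `best_record`,
#'   `best_index`, `config`, `train_config`.
#' @export
train_population <- function(graph, config, tc, init_params = NULL) {
  seeds <- vapply(seq_len(tc$n_models), function(i) model_seed_for(tc$seed, i), 1L)
  run <- function(s) {
    tryCatch(train_one(graph, config, tc, s, init_params = init_params),
             error = function(e) structure(
               list(model_seed = s, final_loss = NA_real_,
                    final_delta_k = NA_real_, crisp_labels = integer(0),
                    soft_assignment = NULL, loss_trace = numeric(0),
                    steps_completed = 0L, culled = TRUE, error = conditionMessage(e)),
               class = "run_record"))
  }
  term_fn <- tc$terminate_fn
  if (!is.null(term_fn) && tc$n_workers == 1L) {
    records <- list()
    for (i in seq_along(seeds)) {
      records[[i]] <- run(seeds[i])
      state <- list(n_done = i, n_models = tc$n_models, records = records)
      if (isTRUE(term_fn(state))) break
    }
  } else if (tc$n_workers > 1L) {
    records <- parallel::mclapply(seeds, run, mc.cores = tc$n_workers,
                                  mc.preschedule = TRUE)
  } else {
    records <- run_in_batches(seeds, run)
  }
  dks <- vapply(records, function(r)
    if (isTRUE(r$culled) || !is.finite(r$final_delta_k)) Inf else r$final_delta_k,
    1.0)
  best <- if (all(!is.finite(dks))) NA_integer_ else which.min(dks)
  structure(list(records = records,
                 best_record = if (is.na(best)) NULL else records[[best]],
                 best_index = best, config = config, train_config = tc),
            class = "population_result")
}

#' @export
print.population_result <- function(x, ...) {
  n_culled <- sum(vapply(x$records, function(r) isTRUE(r$culled), TRUE))
  cat(sprintf("<population_result> %d runs (%d culled), best crisp dK = %s\n",
              length(x$records), n_culled,
              if (is.null(x$best_record)) "NA"
              else format(x$best_record$final_delta_k, digits = 6)))
  invisible(x)
}

#' Pretrain a model to replicate a reference assignment
#'
#' Minimizes the mean squared difference between the model's soft assignment
#' and a reference assignment (for instance one produced by an external
#' metastability method and read from file), returning parameters that can
#' seed subsequent Kemeny-loss training.
#'
#' @param graph a [graph_data()].
#' @param config a [model_config()].
#' @param S_ref N x M row-stochastic reference assignment.
#' @param steps pretraining steps.
#' @param model_seed seed for the initialization.
#' @param learning_rate Adam learning rate (a larger default than the Kemeny
#'   phase since the MSE surface is benign).
#' @return list with `params` (a `model_params`) and `mse_trace`.
#' @export
pretrain_to_reference <- function(graph, config, S_ref, steps = 500L,
                                  model_seed = 1L, learning_rate = 1e-3) {
  S_ref <- validate_assignment(S_ref, graph$n_nodes)
  if (ncol(S_ref) != config$n_clusters)
    stop_kemenet("dimension", "reference assignment has the wrong number of clusters")
  set.seed(model_seed)
  params <- generate_params(config, graph, model_seed)
  ctx <- model_context(graph, config)
  ref_c <- ad_const(S_ref)
  scale <- 1 / length(S_ref)
  st <- adam_state(params)
  trace <- numeric(steps)
  for (step in seq_len(steps)) {
    pn <- lapply(params, ad_param)
    s_node <- model_forward(pn, ctx, config, training = TRUE)
    diff <- ad_sub(s_node, ref_c)
    loss <- ad_mul_const(ad_sum(ad_mul(diff, diff)), scale)
    trace[step] <- loss$value[1L]
    ad_backward(loss)
    upd <- adam_step(params, lapply(pn, function(n) n$grad), st, learning_rate)
    params <- upd$params
    st <- upd$state
  }
  list(params = params, mse_trace = trace)
}

#' Grid search over model hyperparameters
#'
#' Runs [train_population()] for every cell of a hyperparameter grid and
#' summarizes each cell. Errors in a cell are recorded without aborting the
#' sweep.
#'
#' @param graph a [graph_data()].
#' @param base_config a [model_config()] supplying the non-swept fields.
#' @param tc a [train_config()].
#' @param grid named list of vectors over `model_config` fields, e.g.
#'   `list(d_hidden = c(32, 64), n_decoder_layers = 1:3)`.
#' @param best_tol runs within `best_tol` (relative) of the overall best crisp
#'   \eqn{\Delta K} count as having reached it.
#' @return data.frame: one row per cell with the grid values, `best_delta_k`,
#'   `mean_delta_k`, `sd_delta_k`, `frac_best` and `error`.
#' @export
hyperparameter_sweep <- function(graph, base_config, tc, grid,
                                 best_tol = 1e-6) {
  cells <- expand.grid(grid, stringsAsFactors = FALSE)
  results <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- base_config
    for (nm in names(cells)) cfg[[nm]] <- cells[[nm]][i]
    results[[i]] <- tryCatch(train_population(graph, cfg, tc),
                             error = function(e) e)
  }
  all_best <- suppressWarnings(min(vapply(results, function(r)
    if (inherits(r, "error") || is.null(r$best_record)) Inf
    else r$best_record$final_delta_k, 1.0)))
  summarize <- function(r) {
    if (inherits(r, "error"))
      return(data.frame(best_delta_k = NA_real_, mean_delta_k = NA_real_,
                        sd_delta_k = NA_real_, frac_best = NA_real_,
                        error = conditionMessage(r)))
    dks <- vapply(r$records, function(x)
      if (isTRUE(x$culled)) NA_real_ else x$final_delta_k, 1.0)
    dks <- dks[is.finite(dks)]
    data.frame(best_delta_k = if (length(dks)) min(dks) else NA_real_,
               mean_delta_k = if (length(dks)) mean(dks) else NA_real_,
               sd_delta_k = if (length(dks) > 1L) stats::sd(dks) else NA_real_,
               frac_best = if (length(dks))
                 mean(dks <= all_best * (1 + best_tol) + best_tol) else NA_real_,
               error = NA_character_)
  }
  cbind(cells, do.call(rbind, lapply(results, summarize)))
}
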