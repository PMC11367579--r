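#' Partitioning model configuration
#'
#' Four architectures are available: a GraphSAGE or GATv2 message-passing
#' encoder mapping `d_feat`-dimensional node features to `d_embed`-dimensional
#' embeddings through `n_encoder_layers` layers of width `d_hidden`, followed
#' by either a stack of linear layers or a two-block transformer decoder that
#' emits `n_clusters` logits per node; a row-wise softmax yields the soft
#' assignment. Defaults mirror the reference protocol: 4 encoder layers, 2
#' decoder layers, \eqn{d_{hidden} = 64}, \eqn{d_{embed} = 32}. Hidden layers
#' use rectified-linear activations; attention uses 4 heads whose outputs are
#' concatenated.
#'
#' @param encoder `"graphsage"` or `"gatv2"`.
#' @param decoder `"linear"` or `"transformer"`.
#' @param n_clusters number of clusters M.
#' @param n_encoder_layers,n_decoder_layers stack depths.
#' @param d_hidden,d_embed hidden and embedding widths.
#' @param attention_heads heads for GATv2 and the transformer decoder
#'   (must divide `d_hidden` and `d_embed`).
#' @param dropout_rate dropout between the two transformer blocks
#'   (training mode only).
#' @param leaky_slope negative slope of the leaky rectifier inside the GATv2
#'   attention score.
#' @return a `model_config` list.
#' @export
model_config <- function(encoder = c("graphsage", "gatv2"),
                         decoder = c("linear", "transformer"),
                         n_clusters = 4L,
                         n_encoder_layers = 4L, n_decoder_layers = 2L,
                         d_hidden = 64L, d_embed = 32L,
                         attention_heads = 4L, dropout_rate = 0.1,
                         leaky_slope = 0.2) {
  encoder <- match.arg(encoder)
  decoder <- match.arg(decoder)
  stopifnot(n_clusters >= 1L, n_encoder_layers >= 1L, n_decoder_layers >= 1L,
            d_hidden >= 1L, d_embed >= 1L)
  if (encoder == "gatv2" &&
      (d_hidden %% attention_heads != 0L || d_embed %% attention_heads != 0L))
    stop_kemenet("config", "attention_heads must divide d_hidden and d_embed")
  structure(list(encoder = encoder, decoder = decoder,
                 n_clusters = as.integer(n_clusters),
                 n_encoder_layers = as.integer(n_encoder_layers),
                 n_decoder_layers = as.integer(n_decoder_layers),
                 d_hidden = as.integer(d_hidden), d_embed = as.integer(d_embed),
                 attention_heads = as.integer(attention_heads),
                 dropout_rate = dropout_rate, leaky_slope = leaky_slope),
            class = "model_config")
}

#' Cluster-size penalty parameters
#'
#' The penalty \eqn{\eta \sum_L \exp(-n_L^2 / 2\sigma^2)}, with soft cluster
#' size \eqn{n_L = \sum_i S_{iL}}, is a Gaussian centred at zero: it
#' contributes exactly \eqn{\eta} for an empty cluster, decreases
#' monotonically with cluster size, and is negligible from about one node
#' upward (\eqn{\eta e^{-1/2} \approx 9.1} at size 1, \eqn{\approx 0.17} at
#' size 3 with the defaults \eqn{\sigma = 1}, \eqn{\eta = 15}).
#'
#' @param sigma width of the Gaussian (soft nodes).
#' @param eta penalty strength.
#' @return a `penalty_params` list.
#' @export
penalty_params <- function(sigma = 1.0, eta = 15) {
  stopifnot(sigma > 0, eta >= 0)
  structure(list(sigma = sigma, eta = eta), class = "penalty_params")
}

#' Cluster-size penalty of a soft assignment
#'
#' @param S N x M soft assignment matrix.
#' @param params a [penalty_params()].
#' @return non-negative scalar.
#' @export
penalty <- function(S, params = penalty_params()) {
  n_l <- colSums(S)
  params$eta * sum(exp(-n_l^2 / (2 * params$sigma^2)))
}

# --- parameter shapes and initialization -------------------------------------

# Deterministic, ordered list of (name, nrow, ncol, init) for one model.
# init: "weight" (fan-based), "zero", "one", "attn" (fan = d_head -> 1),
# "embed" (treated as a weight).
param_shapes <- function(config, d_feat, n_nodes, trainable = NULL) {
  sh <- list()
  addw <- function(name, r, c, kind = "weight")
    sh[[length(sh) + 1L]] <<- list(name = name, r = r, c = c, kind = kind)
  if (!is.null(trainable)) {
    if (trainable$type == "embedding") addw("feat_table", n_nodes, trainable$dim, "embed")
    if (trainable$type == "linear") {
      addw("feat_W", trainable$d_in, trainable$dim)
      addw("feat_b", 1L, trainable$dim, "zero")
    }
  }
  t_layers <- config$n_encoder_layers
  for (t in seq_len(t_layers)) {
    d_in <- if (t == 1L) d_feat else config$d_hidden
    d_out <- if (t == t_layers) config$d_embed else config$d_hidden
    if (config$encoder == "graphsage") {
      addw(sprintf("enc%d_W", t), 2L * d_in, d_out)
      addw(sprintf("enc%d_b", t), 1L, d_out, "zero")
    } else {
      d_head <- d_out %/% config$attention_heads
      for (k in seq_len(config$attention_heads)) {
        addw(sprintf("enc%d_h%d_Wl", t, k), d_in, d_head)
        addw(sprintf("enc%d_h%d_Wr", t, k), d_in, d_head)
        addw(sprintf("enc%d_h%d_a", t, k), d_head, 1L, "attn")
      }
      addw(sprintf("enc%d_b", t), 1L, d_out, "zero")
    }
  }
  if (config$decoder == "linear") {
    l_layers <- config$n_decoder_layers
    for (l in seq_len(l_layers)) {
      d_in <- if (l == 1L) config$d_embed else config$d_hidden
      d_out <- if (l == l_layers) config$n_clusters else config$d_hidden
      addw(sprintf("dec%d_W", l), d_in, d_out)
      addw(sprintf("dec%d_b", l), 1L, d_out, "zero")
    }
  } else {
    addw("pos_W", 2L * config$d_embed, config$d_embed)
    addw("pos_b", 1L, config$d_embed, "zero")
    addw("tin_W", config$d_embed, config$d_hidden)
    addw("tin_b", 1L, config$d_hidden, "zero")
    d_head <- config$d_hidden %/% config$attention_heads
    for (b in seq_len(config$n_decoder_layers)) {
      for (k in seq_len(config$attention_heads)) {
        addw(sprintf("blk%d_h%d_Wq", b, k), config$d_hidden, d_head)
        addw(sprintf("blk%d_h%d_Wk", b, k), config$d_hidden, d_head)
        addw(sprintf("blk%d_h%d_Wv", b, k), config$d_hidden, d_head)
      }
      addw(sprintf("blk%d_Wo", b), config$d_hidden, config$d_hidden)
      addw(sprintf("blk%d_bo", b), 1L, config$d_hidden, "zero")
      addw(sprintf("blk%d_ln1_g", b), 1L, config$d_hidden, "one")
      addw(sprintf("blk%d_ln1_b", b), 1L, config$d_hidden, "zero")
      addw(sprintf("blk%d_f1_W", b), config$d_hidden, config$d_hidden)
      addw(sprintf("blk%d_f1_b", b), 1L, config$d_hidden, "zero")
      addw(sprintf("blk%d_f2_W", b), config$d_hidden, config$d_hidden)
      addw(sprintf("blk%d_f2_b", b), 1L, config$d_hidden, "zero")
      addw(sprintf("blk%d_ln2_g", b), 1L, config$d_hidden, "one")
      addw(sprintf("blk%d_ln2_b", b), 1L, config$d_hidden, "zero")
    }
    addw("tout_W", config$d_hidden, config$n_clusters)
    addw("tout_b", 1L, config$n_clusters, "zero")
  }
  sh
}

#' Initialize model parameters
#'
#' Draws a complete, named parameter set for one model, fully determined by
#' `model_seed`. Weights use Glorot (default) or Kaiming initialization;
#' biases start at zero and layer-norm gains at one. Glorot uniform draws from
#' \eqn{U(\pm\sqrt{6/(fan_{in}+fan_{out})})}, giving variance
#' \eqn{2/(fan_{in}+fan_{out})}.
#'
#' @param config a [model_config()].
#' @param graph a [graph_data()] (supplies `d_feat`, node count and any
#'   trainable-feature contract).
#' @param model_seed integer seed.
#' @param scheme `"glorot"` or `"kaiming"`.
#' @return named list of numeric matrices (class `model_params`).
#' @export
generate_params <- function(config, graph, model_seed,
                            scheme = c("glorot", "kaiming")) {
  scheme <- match.arg(scheme)
  set.seed(model_seed)
  sh <- param_shapes(config, graph$features$d_feat, graph$n_nodes,
                     graph$features$trainable)
  params <- list()
  for (s in sh) {
    params[[s$name]] <- switch(s$kind,
      zero = matrix(0, s$r, s$c),
      one = matrix(1, s$r, s$c),
      attn = ,
      embed = ,
      weight = {
        if (scheme == "glorot") {
          lim <- sqrt(6 / (s$r + s$c))
          matrix(stats::runif(s$r * s$c, -lim, lim), s$r, s$c)
        } else {
          matrix(stats::rnorm(s$r * s$c, 0, sqrt(2 / s$r)), s$r, s$c)
        }
      })
  }
  class(params) <- "model_params"
  params
}

# --- forward passes (tape) ---------------------------------------------------

# Static per-graph tensors shared by every forward call.
model_context <- function(graph, config) {
  adj <- graph$adjacency
  deg <- rowSums(adj)
  anorm <- adj / pmax(deg, 1)            # mean aggregation; isolated rows -> 0
  att_mask <- adj
  diag(att_mask) <- 1                    # self-loops for attention only
  list(anorm = anorm, att_mask = att_mask, n_nodes = graph$n_nodes,
       f = graph$features$F, trainable = graph$features$trainable)
}

sage_forward <- function(h, anorm_c, w, b, activate) {
  agg <- ad_matmul(anorm_c, h)
  z <- ad_add_bias(ad_matmul(ad_cbind(list(h, agg)), w), b)
  if (activate) ad_relu(z) else z
}

gatv2_forward <- function(h, mask, pn, t, heads, slope, b, activate) {
  outs <- vector("list", heads)
  for (k in seq_len(heads)) {
    hl <- ad_matmul(h, pn[[sprintf("enc%d_h%d_Wl", t, k)]])
    hr <- ad_matmul(h, pn[[sprintf("enc%d_h%d_Wr", t, k)]])
    outs[[k]] <- ad_gatv2_head(hl, hr, pn[[sprintf("enc%d_h%d_a", t, k)]],
                               mask, slope)
  }
  z <- ad_add_bias(ad_cbind(outs), b)
  if (activate) ad_relu(z) else z
}

attention_block <- function(x, pn, b, heads, d_head) {
  outs <- vector("list", heads)
  for (k in seq_len(heads)) {
    q <- ad_matmul(x, pn[[sprintf("blk%d_h%d_Wq", b, k)]])
    kk <- ad_matmul(x, pn[[sprintf("blk%d_h%d_Wk", b, k)]])
    v <- ad_matmul(x, pn[[sprintf("blk%d_h%d_Wv", b, k)]])
    outs[[k]] <- ad_sdpa(q, kk, v, 1 / sqrt(d_head))
  }
  a <- ad_add_bias(ad_matmul(ad_cbind(outs), pn[[sprintf("blk%d_Wo", b)]]),
                   pn[[sprintf("blk%d_bo", b)]])
  x <- ad_layer_norm(ad_add(x, a), pn[[sprintf("blk%d_ln1_g", b)]],
                     pn[[sprintf("blk%d_ln1_b", b)]])
  f <- ad_add_bias(ad_matmul(ad_relu(
         ad_add_bias(ad_matmul(x, pn[[sprintf("blk%d_f1_W", b)]]),
                     pn[[sprintf("blk%d_f1_b", b)]])),
         pn[[sprintf("blk%d_f2_W", b)]]), pn[[sprintf("blk%d_f2_b", b)]])
  ad_layer_norm(ad_add(x, f), pn[[sprintf("blk%d_ln2_g", b)]],
                pn[[sprintf("blk%d_ln2_b", b)]])
}

# Full model: features -> encoder -> decoder -> row-stochastic S (tape node).
model_forward <- function(param_nodes, ctx, config, training = FALSE) {
  pn <- param_nodes
  h <- if (is.null(ctx$trainable)) {
    ad_const(ctx$f)
  } else if (ctx$trainable$type == "embedding") {
    pn$feat_table
  } else {
    ad_add_bias(ad_matmul(ad_const(ctx$f), pn$feat_W), pn$feat_b)
  }
  anorm_c <- ad_const(ctx$anorm)
  t_layers <- config$n_encoder_layers
  for (t in seq_len(t_layers)) {
    act <- t < t_layers
    h <- if (config$encoder == "graphsage") {
      sage_forward(h, anorm_c, pn[[sprintf("enc%d_W", t)]],
                   pn[[sprintf("enc%d_b", t)]], act)
    } else {
      gatv2_forward(h, ctx$att_mask, pn, t, config$attention_heads,
                    config$leaky_slope, pn[[sprintf("enc%d_b", t)]], act)
    }
  }
  if (config$decoder == "linear") {
    x <- h
    l_layers <- config$n_decoder_layers
    for (l in seq_len(l_layers)) {
      x <- ad_add_bias(ad_matmul(x, pn[[sprintf("dec%d_W", l)]]),
                       pn[[sprintf("dec%d_b", l)]])
      if (l < l_layers) x <- ad_relu(x)
    }
    ad_row_softmax(x)
  } else {
    pos <- sage_forward(h, anorm_c, pn$pos_W, pn$pos_b, FALSE)
    x <- ad_add(h, pos)
    x <- ad_add_bias(ad_matmul(x, pn$tin_W), pn$tin_b)
    d_head <- config$d_hidden %/% config$attention_heads
    n_blocks <- config$n_decoder_layers
    for (b in seq_len(n_blocks)) {
      x <- attention_block(x, pn, b, config$attention_heads, d_head)
      if (b < n_blocks && training && config$dropout_rate > 0) {
        keep <- (matrix(stats::runif(ctx$n_nodes * config$d_hidden),
                        ctx$n_nodes) >= config$dropout_rate) /
                (1 - config$dropout_rate)
        x <- ad_mul_const(x, keep)
      }
    }
    ad_row_softmax(ad_add_bias(ad_matmul(x, pn$tout_W), pn$tout_b))
  }
}

# --- the Kemeny loss head ----------------------------------------------------

# Constant tensors of the loss: equilibrium flux matrix G = Q diag(p) (or
# K diag(p)), the fine Kemeny constant, and the chain kind.
loss_context <- function(chain, p_eq, zeta, penalty = penalty_params()) {
  list(g = chain_matrix(chain) %*% diag(p_eq),
       p = matrix(p_eq, ncol = 1L),
       zeta = zeta, continuous = is_rate(chain), penalty = penalty)
}

# S (tape node) -> list of tape nodes: loss = DK(S) + penalty(S), plus parts.
# DK runs through the soft lumping path: P-hat = S^T p, G-hat = S^T G S,
# Q-hat = G-hat diag(P-hat)^-1, and zeta_S = tr(A^-1) - 1 with
# A = P-hat 1^T - K-hat (continuous) or I - Q-hat + P-hat 1^T (discrete).
kemeny_loss_node <- function(s_node, lctx) {
  m <- ncol(s_node$value)
  st <- ad_transpose(s_node)
  p_hat <- ad_matmul(st, ad_const(lctx$p))
  g_hat <- ad_matmul(ad_matmul(st, ad_const(lctx$g)), s_node)
  q_hat <- ad_col_scale(g_hat, p_hat)
  a <- ad_sub(ad_matmul(p_hat, ad_const(matrix(1, 1L, m))), q_hat)
  if (!lctx$continuous) a <- ad_add_const(a, diag(m))
  zeta_s <- ad_add_const(ad_trace_inv(a), -1)
  dk <- ad_add_const(ad_mul_const(zeta_s, -1), lctx$zeta)
  nsz <- ad_colsums(s_node)
  pen <- ad_mul_const(ad_sum(ad_exp(ad_mul_const(ad_mul(nsz, nsz),
         -1 / (2 * lctx$penalty$sigma^2)))), lctx$penalty$eta)
  list(loss = ad_add(dk, pen), dk = dk, zeta_s = zeta_s, pen = pen)
}

#' Soft-assignment Kemeny loss
#'
#' Evaluates the training objective \eqn{\Delta K(S) + \mathrm{penalty}(S)}
#' for an explicit soft assignment, with \eqn{\Delta K} computed through the
#' same differentiable soft-lumping path the optimizer uses. Optionally also
#' returns the analytic gradient with respect to `S`.
#'
#' @param S N x M soft assignment matrix.
#' @param chain validated `kinetic_chain` (discrete chains are the intended
#'   training representation; see the package vignette).
#' @param p_eq optional equilibrium distribution.
#' @param params a [penalty_params()].
#' @param gradient also return `d loss / d S`?
#' @return list with `loss`, `delta_k`, `zeta_S`, `penalty` and (optionally)
#'   `gradient`.
#' @export
kemeny_loss <- function(S, chain, p_eq = NULL, params = penalty_params(),
                        gradient = FALSE) {
  # loose row-sum tolerance: the loss extends smoothly off the simplex, which
  # finite-difference probes of the gradient rely on
  S <- validate_assignment(S, chain$n_states, tol = 1e-4)
  p <- p_eq %||% equilibrium(chain)
  dec_zeta <- as.numeric(kemeny_constant(spectral_decompose(chain, p)))
  lctx <- loss_context(chain, p, dec_zeta, params)
  s_node <- ad_param(S)
  parts <- kemeny_loss_node(s_node, lctx)
  if (!is.finite(parts$loss$value[1L]))
    stop_kemenet("nonfinite", sprintf(
      "non-finite loss (delta_k = %g, penalty = %g)",
      parts$dk$value[1L], parts$pen$value[1L]))
  out <- list(loss = parts$loss$value[1L], delta_k = parts$dk$value[1L],
              zeta_S = parts$zeta_s$value[1L], penalty = parts$pen$value[1L])
  if (gradient) {
    ad_backward(parts$loss)
    out$gradient <- s_node$grad
  }
  out
}

# --- numeric single-layer entry points (documented building blocks) ----------

#' Single GraphSAGE layer (numeric)
#'
#' Mean-aggregates each node's neighbour states, concatenates them with the
#' node's own state, applies one affine map and (optionally) a rectifier.
#' Exposed mainly for inspection and testing; training uses the same code on
#' the differentiation tape.
#'
#' @param h N x d input states.
#' @param adjacency binary adjacency.
#' @param W,b weight `(2d x d')` and bias `(1 x d')`.
#' @param activate apply the rectifier?
#' @return N x d' matrix.
#' @export
graphsage_layer <- function(h, adjacency, W, b, activate = TRUE) {
  deg <- rowSums(adjacency)
  anorm <- adjacency / pmax(deg, 1)
  ad_value(sage_forward(ad_const(h), ad_const(anorm), ad_const(W), ad_const(b),
                        activate))
}

#' Single GATv2 layer (numeric)
#'
#' Attention scores over each node's neighbourhood (self-loops included) via
#' the GATv2 form \eqn{a^T \mathrm{LeakyReLU}(W_l h_i + W_r h_j)}, softmax
#' normalization over the neighbourhood, and an attention-weighted sum of the
#' transformed neighbour states, one head per element of `heads_params`.
#'
#' @param h N x d input states.
#' @param adjacency binary adjacency (self-loops are added internally).
#' @param heads_params list of per-head lists with `Wl`, `Wr` (d x d_head)
#'   and `a` (d_head x 1).
#' @param b bias `(1 x d')` with `d' = heads * d_head`.
#' @param slope leaky slope.
#' @param activate apply the rectifier?
#' @return list with `output` (N x d') and `attention` (list of row-stochastic
#'   N x N attention matrices, one per head).
#' @export
gatv2_layer <- function(h, adjacency, heads_params, b, slope = 0.2,
                        activate = TRUE) {
  mask <- adjacency
  diag(mask) <- 1
  if (any(rowSums(mask) == 0))
    stop_kemenet("empty_neighbourhood", "node with empty attended set")
  hc <- ad_const(h)
  outs <- list(); att <- list()
  for (k in seq_along(heads_params)) {
    hp <- heads_params[[k]]
    if (length(hp$a) != ncol(hp$Wl) || ncol(hp$Wl) != ncol(hp$Wr))
      stop_kemenet("dimension", "attention vector length must equal the head width")
    hl <- ad_matmul(hc, ad_const(hp$Wl))
    hr <- ad_matmul(hc, ad_const(hp$Wr))
    alpha <- ad_row_softmax(ad_gatv2_scores(hl, hr, ad_const(hp$a), slope),
                            mask = mask)
    att[[k]] <- ad_value(alpha)
    outs[[k]] <- ad_matmul(alpha, hr)
  }
  z <- ad_value(ad_add_bias(ad_cbind(outs), ad_const(b)))
  list(output = if (activate) pmax(z, 0) else z, attention = att)
}

#' Encode and decode with explicit parameters (numeric)
#'
#' Runs the configured architecture once in evaluation mode (no dropout) and
#' returns the soft assignment.
#'
#' @param graph a [graph_data()].
#' @param config a [model_config()].
#' @param params a parameter set from [generate_params()].
#' @return N x M row-stochastic soft assignment matrix.
#' @export
predict_assignment <- function(graph, config, params) {
  ctx <- model_context(graph, config)
  ad_value(model_forward(lapply(params, ad_const), ctx, config,
                         training = FALSE))
}
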