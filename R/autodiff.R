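# Tape-based reverse-mode automatic differentiation on dense matrices.
#
# Every value is a base-R numeric matrix (scalars are 1x1). Operations build
# the computation graph eagerly; ad_backward() runs one reverse sweep and
# accumulates gradients into $grad on every node. Model parameters are just
# nodes whose gradients are read off after the sweep. The engine is minimal by
# design: only the operations needed by the partitioning models and the
# Kemeny loss head exist, and each is validated against central differences
# in the test-suite.

.ad_env <- new.env(parent = emptyenv())
.ad_env$counter <- 0L

ad_node <- function(value, parents = NULL, backfn = NULL) {
  .ad_env$counter <- .ad_env$counter + 1L
  e <- new.env(parent = emptyenv())
  e$id <- .ad_env$counter
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  class(e) <- "ad_node"
  e
}

ad_const <- function(x) ad_node(as.matrix(x))
ad_param <- ad_const   # identical structurally; semantics live in the caller

ad_value <- function(n) n$value

#' @export
print.ad_node <- function(x, ...) {
  cat(sprintf("<ad_node %d> %dx%d\n", x$id, nrow(x$value), ncol(x$value)))
  invisible(x)
}

# --- primitive operations ----------------------------------------------------

ad_matmul <- function(a, b) {
  ad_node(a$value %*% b$value, list(a, b), function(g, self)
    list(tcrossprod(g, self$parents[[2L]]$value),
         crossprod(self$parents[[1L]]$value, g)))
}

ad_add <- function(a, b) {
  ad_node(a$value + b$value, list(a, b), function(g, self) list(g, g))
}

ad_sub <- function(a, b) {
  ad_node(a$value - b$value, list(a, b), function(g, self) list(g, -g))
}

# X (N x d) plus a 1 x d bias broadcast over rows
ad_add_bias <- function(x, b) {
  n <- nrow(x$value)
  ad_node(x$value + rep(as.vector(b$value), each = n), list(x, b),
          function(g, self) list(g, matrix(colSums(g), 1L)))
}

ad_mul <- function(a, b) {
  ad_node(a$value * b$value, list(a, b), function(g, self)
    list(g * self$parents[[2L]]$value, g * self$parents[[1L]]$value))
}

# multiply / add a fixed (non-differentiated) matrix or scalar
ad_mul_const <- function(x, c) {
  ad_node(x$value * c, list(x), function(g, self) list(g * c))
}

ad_add_const <- function(x, c) {
  ad_node(x$value + c, list(x), function(g, self) list(g))
}

ad_relu <- function(x) {
  ad_node(pmax(x$value, 0), list(x), function(g, self)
    list(g * (self$parents[[1L]]$value > 0)))
}

ad_exp <- function(x) {
  out <- ad_node(exp(x$value), list(x), NULL)
  out$backfn <- function(g, self) list(g * self$value)
  out
}

ad_sum <- function(x) {
  ad_node(matrix(sum(x$value), 1L, 1L), list(x), function(g, self)
    list(matrix(g[1L], nrow(self$parents[[1L]]$value), ncol(self$parents[[1L]]$value))))
}

ad_colsums <- function(x) {
  ad_node(matrix(colSums(x$value), 1L), list(x), function(g, self)
    list(matrix(g, nrow(self$parents[[1L]]$value), ncol(g), byrow = TRUE)))
}

ad_transpose <- function(x) {
  ad_node(t(x$value), list(x), function(g, self) list(t(g)))
}

ad_cbind <- function(nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), 1L)
  ad_node(do.call(cbind, lapply(nodes, ad_value)), nodes, function(g, self) {
    stops <- cumsum(widths)
    starts <- c(1L, stops[-length(stops)] + 1L)
    lapply(seq_along(widths), function(i) g[, starts[i]:stops[i], drop = FALSE])
  })
}

# Row-wise softmax; with an optional 0/1 mask the softmax runs over the
# unmasked entries of each row only (masked entries get probability 0).
ad_row_softmax <- function(x, mask = NULL) {
  v <- x$value
  if (!is.null(mask)) v[mask == 0] <- -Inf
  rmax <- v[cbind(seq_len(nrow(v)), max.col(v, ties.method = "first"))]
  y <- exp(v - rmax)
  y <- y / rowSums(y)
  ad_node(y, list(x), function(g, self) {
    yy <- self$value
    list((g - rowSums(g * yy)) * yy)
  })
}

# Y[, L] = X[, L] / v[L]  with v an M x 1 node (column renormalization)
ad_col_scale <- function(x, v) {
  n <- nrow(x$value)
  vv <- rep(as.vector(v$value), each = n)
  out <- ad_node(x$value / vv, list(x, v), NULL)
  out$backfn <- function(g, self) {
    vv <- as.vector(self$parents[[2L]]$value)
    list(g / rep(vv, each = nrow(g)),
         matrix(-colSums(g * self$value) / vv, ncol = 1L))
  }
  out
}

# trace of the matrix inverse: the differentiable core of the Kemeny head
ad_trace_inv <- function(a) {
  inv <- solve(a$value)
  out <- ad_node(matrix(sum(diag(inv)), 1L, 1L), list(a), NULL)
  out$aux <- inv
  out$backfn <- function(g, self) list(-g[1L] * t(self$aux %*% self$aux))
  out
}

# Row-wise layer normalization with learnable gain/offset (1 x d each).
ad_layer_norm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  n <- nrow(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  sd <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sd
  y <- xhat * rep(as.vector(gamma$value), each = n) +
    rep(as.vector(beta$value), each = n)
  out <- ad_node(y, list(x, gamma, beta), NULL)
  out$aux <- list(xhat = xhat, sd = sd)
  out$backfn <- function(g, self) {
    xhat <- self$aux$xhat; sd <- self$aux$sd
    gam <- as.vector(self$parents[[2L]]$value)
    dxhat <- g * rep(gam, each = nrow(g))
    gx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd
    list(gx, matrix(colSums(g * xhat), 1L), matrix(colSums(g), 1L))
  }
  out
}

# GATv2 attention scores: S[i, j] = sum_k a_k * lrelu(Hl[i, k] + Hr[j, k]).
# Hl/Hr are N x d per-head transforms, a is d x 1. Dense N x N output; the
# neighbourhood restriction happens in the masked softmax that follows.
# The O(N^2 d) contraction runs in compiled code (src/gatv2.cpp).
ad_gatv2_scores <- function(hl, hr, a, slope = 0.2) {
  s <- gatv2_scores_fwd(hl$value, hr$value, as.vector(a$value), slope)
  out <- ad_node(s, list(hl, hr, a), NULL)
  out$backfn <- function(g, self) {
    b <- gatv2_scores_bwd(g, self$parents[[1L]]$value,
                          self$parents[[2L]]$value,
                          as.vector(self$parents[[3L]]$value), slope)
    list(b$ghl, b$ghr, matrix(b$ga, ncol = 1L))
  }
  out
}

# Fused GATv2 attention head: scores -> masked softmax -> weighted sum of the
# transformed neighbour states (compiled; see src/gatv2.cpp). `mask` is a
# plain 0/1 matrix (adjacency + self-loops), not a tape node.
ad_gatv2_head <- function(hl, hr, a, mask, slope = 0.2) {
  f <- gatv2_head_fwd(hl$value, hr$value, as.vector(a$value), mask, slope)
  out <- ad_node(f$out, list(hl, hr, a), NULL)
  out$aux <- f$alpha
  out$backfn <- function(g, self) {
    b <- gatv2_head_bwd(g, self$aux, self$parents[[1L]]$value,
                        self$parents[[2L]]$value,
                        as.vector(self$parents[[3L]]$value), slope)
    list(b$ghl, b$ghr, matrix(b$ga, ncol = 1L))
  }
  out
}

# Fused scaled-dot-product attention head (compiled).
ad_sdpa <- function(q, k, v, scale) {
  f <- sdpa_fwd(q$value, k$value, v$value, scale)
  out <- ad_node(f$out, list(q, k, v), NULL)
  out$aux <- f$p
  out$backfn <- function(g, self) {
    b <- sdpa_bwd(g, self$aux, self$parents[[1L]]$value,
                  self$parents[[2L]]$value, self$parents[[3L]]$value, scale)
    list(b$gq, b$gk, b$gv)
  }
  out
}

# --- backward sweep ----------------------------------------------------------

ad_backward <- function(root) {
  order <- vector("list", 256L)
  n_ord <- 0L
  seen <- new.env(parent = emptyenv())
  visit <- function(node) {
    key <- as.character(node$id)
    if (!is.null(seen[[key]])) return(invisible())
    assign(key, TRUE, envir = seen)
    for (p in node$parents) visit(p)
    n_ord <<- n_ord + 1L
    if (n_ord > length(order)) length(order) <<- 2L * n_ord
    order[[n_ord]] <<- node
  }
  visit(root)
  root$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_len(n_ord))) {
    node <- order[[i]]
    if (is.null(node$backfn) || is.null(node$grad)) next
    grads <- node$backfn(node$grad, node)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      p$grad <- if (is.null(p$grad)) grads[[j]] else p$grad + grads[[j]]
    }
  }
  invisible(root)
}
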