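# Classed error conditions so callers (and tests) can distinguish failure modes.

stop_kemenet <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(paste0("kemenet_", class), "kemenet_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_square <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 2L)
    stop_kemenet("nonsquare", "input must be a square numeric matrix with N >= 2")
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m)))
    stop_kemenet("nonfinite", "matrix contains missing or non-finite entries")
  invisible(m)
}

# Strong connectivity of the directed graph on non-zero off-diagonal entries.
# Irreducibility of the chain is equivalent to this.
is_irreducible <- function(m) {
  n <- nrow(m)
  adj <- (m != 0)
  diag(adj) <- FALSE
  reach <- function(a) {
    seen <- logical(n)
    seen[1L] <- TRUE
    frontier <- 1L
    while (length(frontier)) {
      nxt <- which(colSums(a[frontier, , drop = FALSE] > 0) > 0 & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    all(seen)
  }
  # note: a[i, j] != 0 means j -> i can happen under the column convention,
  # but strong connectivity is orientation-symmetric over {adj, t(adj)}
  reach(t(adj)) && reach(adj)
}
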