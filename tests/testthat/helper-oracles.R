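# Independent oracles used to verify the package's graph predicates and
# numerical routines. Deliberately naive implementations (matrix powers,
# normal equations, explicit set algebra) kept separate from the code paths
# they check.

adj_matrix <- function(arcs, nodes) {
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(arcs))) A[arcs$from[i], arcs$to[i]] <- 1
  A
}

# acyclic iff no matrix power of the adjacency has a nonzero diagonal
oracle_acyclic <- function(arcs, nodes) {
  A <- adj_matrix(arcs, nodes)
  P <- A
  for (k in seq_along(nodes)) {
    if (any(diag(P) > 0)) return(FALSE)
    P <- P %*% A
  }
  TRUE
}

# weakly connected iff the symmetrized reachability closure is complete
oracle_weakly_connected <- function(arcs, nodes) {
  n <- length(nodes)
  A <- adj_matrix(arcs, nodes)
  S <- (A + t(A) + diag(n)) > 0
  R <- S
  for (k in seq_len(n)) R <- (R %*% S) > 0
  all(R)
}

# textbook covariance-formula Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# explicit normal-equations OLS: beta = (X'X)^-1 X'y
oracle_ols <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  rss <- sum((y - X %*% beta)^2)
  list(beta = as.vector(beta), rss = rss)
}

# exhaustive simulation of the greedy loop-breaking removal: visit arcs in
# the given order once, removing each arc unless removal increases the
# number of weakly connected components
oracle_greedy_removal <- function(arcs, nodes, order_idx) {
  count_wcc <- function(keep) {
    sub <- arcs[keep, , drop = FALSE]
    n <- length(nodes)
    A <- adj_matrix(sub, nodes)
    S <- (A + t(A) + diag(n)) > 0
    R <- S
    for (k in seq_len(n)) R <- (R %*% S) > 0
    comp <- rep(NA_integer_, n)
    cid <- 0L
    for (i in seq_len(n)) {
      if (is.na(comp[i])) { cid <- cid + 1L; comp[R[i, ]] <- cid }
    }
    cid
  }
  keep <- rep(TRUE, nrow(arcs))
  base <- count_wcc(keep)
  removed <- integer(0)
  for (i in order_idx) {
    keep[i] <- FALSE
    if (count_wcc(keep) > base) keep[i] <- TRUE else removed <- c(removed, i)
  }
  list(kept = which(keep), removed = removed)
}

# random small digraph as an arc data.frame (no self-loops, no duplicates)
random_digraph <- function(n_nodes, n_arcs, seed) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs[sample.int(nrow(pairs), min(n_arcs, nrow(pairs))), , drop = FALSE]
}
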