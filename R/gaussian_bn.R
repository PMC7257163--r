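# ---------------------------------------------------------------------------
# Linear-Gaussian local models and BIC scoring. Each node is modeled as
# normally distributed around an intercept plus a linear combination of its
# parents; model selection uses BIC = n*log(RSS/n) + k*log(n) (natural log,
# lower is better), with k = number of regression coefficients including the
# intercept. This bookkeeping makes an arc addition cost delta-k = 1 and an
# arc reversal delta-k = 0.
# ---------------------------------------------------------------------------

#' Fit the linear-Gaussian local model of one node
#'
#' Ordinary least squares of the node's expression profile on its parents'
#' profiles plus an intercept. With no parents this reduces to the sample
#' mean, and the residual sum of squares is the total sum of squares.
#' A rank-deficient design (collinear parents) is resolved by the
#' minimum-norm least-squares solution, with a warning.
#'
#' @param node node identifier (must be a row of `expr`).
#' @param parents character vector of parent identifiers (possibly empty).
#' @param expr expression matrix, nodes in rows.
#' @return an object of class `local_model` with fields `node`, `parents`,
#'   `a0` (intercept), `a` (named coefficients), `sigma` (ML residual SD,
#'   sqrt(rss/n)), `rss`, `tss`, `k` (= length(parents) + 1) and `n`.
#' @export
fit_local <- function(node, parents, expr) {
  parents <- as.character(parents)
  miss <- setdiff(c(node, parents), rownames(expr))
  if (length(miss) > 0)
    stop("no expression row for: ", paste(miss, collapse = ", "))
  y <- expr[node, ]
  n <- length(y)
  k <- length(parents) + 1L
  if (n <= k) stop(sprintf("insufficient samples for %s: n=%d, k=%d", node, n, k))
  tss <- sum((y - mean(y))^2)
  if (k == 1L) {
    a0 <- mean(y)
    coefs <- numeric(0)
    rss <- tss
  } else {
    X <- cbind(1, t(expr[parents, , drop = FALSE]))
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      warning(sprintf("rank-deficient design for %s; using minimum-norm solution", node))
      beta <- as.vector(MASS::ginv(X) %*% y)
    } else {
      beta <- qr.coef(qx, y)
    }
    fitted <- as.vector(X %*% beta)
    rss <- sum((y - fitted)^2)
    a0 <- beta[1]
    coefs <- beta[-1]
    names(coefs) <- parents
  }
  structure(
    list(node = node, parents = parents, a0 = unname(a0), a = coefs,
         sigma = sqrt(max(rss, 0) / n), rss = max(rss, 0), tss = tss,
         k = k, n = n),
    class = "local_model")
}

# raw score; callers are responsible for rss > 0
bic_formula <- function(rss, k, n) n * log(rss / n) + k * log(n)

#' Node-level BIC of a fitted local model
#'
#' `BIC = n*log(RSS/n) + k*log(n)` with natural logarithms; lower is better.
#' An exact fit (RSS = 0, possible on noiseless synthetic data) is clamped to
#' `1e-12 * TSS` with a warning, since the score is undefined at zero.
#'
#' @param local a `local_model`.
#' @param n number of observations (defaults to the fit's own `n`).
#' @return numeric BIC score.
#' @export
bic_node <- function(local, n = local$n) {
  rss <- local$rss
  if (rss <= 0 || (local$tss > 0 && rss < 1e-12 * local$tss)) {
    floor_val <- if (local$tss > 0) 1e-12 * local$tss else 1e-300
    warning(sprintf("RSS ~ 0 for node %s; clamped to %.3g", local$node, floor_val))
    rss <- floor_val
  }
  bic_formula(rss, local$k, n)
}

#' BIC improvement of a candidate structural move
#'
#' `delta_BIC = BIC_old - BIC_new = n*log(RSS_old/RSS_new) - delta_k*log(n)`;
#' a positive value means the move improves the model. `delta_k` is 1 for an
#' arc addition and 0 for an arc reversal.
#'
#' @param rss_old,rss_new positive residual sums of squares before/after.
#' @param n number of observations.
#' @param delta_k change in parameter count.
#' @return numeric score difference (old minus new).
#' @export
delta_bic <- function(rss_old, rss_new, n, delta_k) {
  if (rss_old <= 0 || rss_new <= 0) stop("RSS must be positive")
  n * log(rss_old / rss_new) - delta_k * log(n)
}

#' Construct a Gaussian Bayesian network over an acyclic structure
#'
#' Fits one linear-Gaussian local model per node of the structure and records
#' the global score, i.e. the sum of the node BICs (the decomposability
#' property of the score).
#'
#' @param arcs data.frame of directed arcs (`from`, `to`); must be acyclic.
#' @param nodes character vector of all node identifiers (isolated nodes get
#'   intercept-only models).
#' @param expr expression matrix covering every node.
#' @return object of class `gaussian_bn` with fields `nodes`, `parents`
#'   (named list), `locals` (named list of `local_model`), `n`, `bic_global`.
#' @export
gaussian_bn <- function(arcs, nodes, expr) {
  validate_expression(expr)
  nodes <- as.character(nodes)
  if (nrow(arcs) > 0 && !is_acyclic(as_igraph(arcs, nodes = nodes)))
    stop("structure contains a directed cycle")
  parents <- setNames(vector("list", length(nodes)), nodes)
  for (nd in nodes) parents[[nd]] <- character(0)
  if (nrow(arcs) > 0) {
    sp <- split(as.character(arcs$from), as.character(arcs$to))
    for (nd in names(sp)) parents[[nd]] <- sp[[nd]]
  }
  locals <- lapply(nodes, function(nd) fit_local(nd, parents[[nd]], expr))
  names(locals) <- nodes
  bn <- structure(
    list(nodes = nodes, parents = parents, locals = locals,
         n = ncol(expr), bic_global = NA_real_),
    class = "gaussian_bn")
  bn$bic_global <- bic_global(bn)
  bn
}

#' Global BIC of a Gaussian Bayesian network
#'
#' Sum of the node-level BIC scores over all local models.
#'
#' @param bn a `gaussian_bn`.
#' @return numeric global score (lower is better).
#' @export
bic_global <- function(bn) {
  if (any(vapply(bn$locals, is.null, logical(1)))) stop("unfitted local model")
  sum(vapply(bn$locals, bic_node, numeric(1), n = bn$n))
}

#' @export
print.gaussian_bn <- function(x, ...) {
  cat(sprintf("Gaussian BN: %d nodes, %d arcs, n = %d, global BIC = %.4f\n",
              length(x$nodes), sum(lengths(x$parents)), x$n, x$bic_global))
  invisible(x)
}
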