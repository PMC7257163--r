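# ---------------------------------------------------------------------------
# Hybrid greedy structure search over the whitelist: correlation-guided arc
# sampling, candidate evaluation (add / reverse) against the current model,
# acceptance of the single best move per iteration when it beats the stop
# threshold, and a local-optimum escape procedure with an enlarged sampling
# set. The TF-gene arcs are fixed throughout; only TF-TF structure is
# searched.
# ---------------------------------------------------------------------------

#' Search configuration
#'
#' @param w arcs sampled from the whitelist per iteration.
#' @param escape_attempts consecutive enlarged-sample rounds tried when no
#'   move beats the threshold before the search stops.
#' @param escape_multiplier factor applied to `w` during escape rounds (the
#'   enlarged set is not cumulatively enlarged across attempts).
#' @param n_runs number of independent search runs for [run_ensemble()].
#' @param seed integer base seed; run `i` of an ensemble uses `seed + i - 1`.
#' @param max_iterations safety cap on accepted-move iterations; default
#'   (`NULL`) resolves to `10 * |whitelist|` at run time.
#' @return a `search_config` list.
#' @export
search_config <- function(w = 100L, escape_attempts = 10L,
                          escape_multiplier = 2, n_runs = 100L, seed = 1L,
                          max_iterations = NULL) {
  stopifnot(w >= 1, escape_attempts >= 0, escape_multiplier >= 1, n_runs >= 1)
  structure(list(w = as.integer(w),
                 escape_attempts = as.integer(escape_attempts),
                 escape_multiplier = escape_multiplier,
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 max_iterations = max_iterations),
            class = "search_config")
}

#' Sample candidate arcs from the whitelist
#'
#' Weighted sampling without replacement: each draw picks an arc with
#' probability proportional to its `prob`, then renormalizes over the
#' remainder. Deterministic given the RNG state.
#'
#' @param whitelist a `whitelist` with `prob` set.
#' @param size number of arcs to draw; capped at the whitelist size.
#' @return integer vector of row indices into `whitelist` (empty if the
#'   whitelist is empty).
#' @export
sample_arcs <- function(whitelist, size) {
  m <- nrow(whitelist)
  if (m == 0) return(integer(0))
  if (anyNA(whitelist$prob)) stop("whitelist sampling probabilities not set")
  size <- min(size, m)
  sample.int(m, size = size, replace = FALSE, prob = whitelist$prob)
}

# directed reachability from `from` to `to` in the TF-TF children map
tf_reaches <- function(children, from, to) {
  if (from == to) return(TRUE)
  seen <- character(0)
  stack <- from
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    kids <- children[[v]]
    if (is.null(kids)) next
    if (to %in% kids) return(TRUE)
    new <- setdiff(kids, seen)
    seen <- c(seen, new)
    stack <- c(stack, new)
  }
  FALSE
}

#' Evaluate one whitelist arc against the current model
#'
#' Cases: (add) neither direction present and the arc closes no directed
#' cycle -- the target's local model is refit with the extra parent
#' (delta_k = 1); (reverse) the opposite arc is present and the reversal is
#' acyclic -- the old target drops the parent and the old source gains one
#' (delta_k = 0), the score change summing both local deltas; otherwise the
#' candidate is rejected (already present, or cycle-creating). Evaluations
#' are independent of each other: each is scored against the current model.
#'
#' @param bn a `gaussian_bn` (the current model).
#' @param u,v candidate arc source and target (both TFs in the model).
#' @param expr expression matrix.
#' @param tf_children adjacency list of the current TF-TF subgraph
#'   (node -> character vector of TF children); computed from `bn` if `NULL`.
#' @param tf_ids TF identifiers (needed when `tf_children` is `NULL`).
#' @return `NULL` if rejected, else a list with `move` (`"add"` or
#'   `"reverse"`), `delta_bic`, and the refit `local_model`s needed to apply
#'   the move.
#' @export
evaluate_candidate <- function(bn, u, v, expr, tf_children = NULL,
                               tf_ids = NULL) {
  if (is.null(tf_children)) {
    if (is.null(tf_ids)) stop("tf_ids required to derive the TF-TF subgraph")
    tf_children <- tf_children_map(bn, tf_ids)
  }
  miss <- setdiff(c(u, v), rownames(expr))
  if (length(miss) > 0)
    stop("no expression row for: ", paste(miss, collapse = ", "))
  pv <- bn$parents[[v]]
  pu <- bn$parents[[u]]
  if (u %in% pv) return(NULL)                       # already present
  if (v %in% pu) {
    # candidate reversal of existing v -> u; acyclic iff, with v -> u gone,
    # no directed path v ~> u remains
    ch2 <- tf_children
    ch2[[v]] <- setdiff(ch2[[v]], u)
    if (tf_reaches(ch2, v, u)) return(NULL)
    new_u <- fit_local(u, setdiff(pu, v), expr)
    new_v <- fit_local(v, c(pv, u), expr)
    d <- (bic_node(bn$locals[[u]], bn$n) - bic_node(new_u, bn$n)) +
         (bic_node(bn$locals[[v]], bn$n) - bic_node(new_v, bn$n))
    return(list(move = "reverse", delta_bic = d,
                refits = list(new_u, new_v)))
  }
  if (tf_reaches(tf_children, v, u)) return(NULL)   # would close a cycle
  new_v <- fit_local(v, c(pv, u), expr)
  d <- bic_node(bn$locals[[v]], bn$n) - bic_node(new_v, bn$n)
  list(move = "add", delta_bic = d, refits = list(new_v))
}

tf_children_map <- function(bn, tf_ids) {
  ch <- setNames(vector("list", length(tf_ids)), tf_ids)
  for (tf in tf_ids) ch[[tf]] <- character(0)
  for (nd in intersect(names(bn$parents), tf_ids)) {
    for (p in intersect(bn$parents[[nd]], tf_ids))
      ch[[p]] <- c(ch[[p]], nd)
  }
  ch
}

#' Learn a transcriptional BN structure from an initialized model
#'
#' Greedy whitelist-constrained search. Each iteration samples `w` arcs from
#' the whitelist (correlation-guided, without replacement), evaluates every
#' candidate against the current model, and applies the single best move if
#' its score improvement exceeds the stop threshold
#' `tau = 10 / |BIC_global(initial model)|`. Ties are broken by higher
#' sampling probability, then lexicographic arc identity. An accepted arc is
#' retired from the whitelist; a reversal also retires the opposite
#' direction, so a resolved pair cannot oscillate. When no sampled move beats
#' `tau`, up to `escape_attempts` rounds with sampling size
#' `w * escape_multiplier` are tried; the first improving move resumes the
#' normal search, and if all attempts fail the run stops.
#'
#' @param init a `tbn_init` (already intersected with the expression data,
#'   whitelist probabilities set).
#' @param expr expression matrix.
#' @param config a [search_config()]; its `seed` drives all sampling.
#' @return object of class `learned_model`: `tf_tf_arcs`, `tf_gene_arcs`,
#'   `bic_global`, `moves` (from, to, move, delta_bic, iteration), `seed`,
#'   `n`, `tau`, `bic_initial`.
#' @export
learn_structure <- function(init, expr, config = search_config()) {
  stopifnot(inherits(init, "tbn_init"))
  validate_expression(expr)
  nodes <- c(init$tf_ids, init$gene_ids)
  arcs0 <- rbind(init$dag[, c("from", "to")], init$tf_gene_arcs[, c("from", "to")])
  bn <- gaussian_bn(arcs0, nodes, expr)
  if (!is.finite(bn$bic_global))
    stop("non-finite initial global score; check the expression data")
  tau <- 10 / abs(bn$bic_global)
  bic_init <- bn$bic_global

  wl <- as.data.frame(init$whitelist)
  active <- rep(TRUE, nrow(wl))
  wl_key <- paste(wl$from, wl$to, sep = "\r")
  max_iter <- config$max_iterations
  if (is.null(max_iter)) max_iter <- max(10L * nrow(wl), 10L)

  children <- tf_children_map(bn, init$tf_ids)
  moves <- list()
  iteration <- 0L
  escaping <- FALSE
  escape_left <- 0L

  withr_seed(config$seed, {
    repeat {
      if (!any(active) || iteration >= max_iter) break
      size <- if (escaping) ceiling(config$w * config$escape_multiplier)
              else config$w
      sub <- which(active)
      wl_act <- wl[sub, , drop = FALSE]
      wl_act$prob <- wl_act$prob / sum(wl_act$prob)
      picked <- sub[sample_arcs(new_whitelist(wl_act), size)]
      best <- NULL
      for (j in picked) {
        res <- evaluate_candidate(bn, wl$from[j], wl$to[j], expr,
                                  tf_children = children)
        if (is.null(res)) next
        if (res$delta_bic <= tau) next
        if (is.null(best) ||
            res$delta_bic > best$delta_bic + 1e-15 ||
            (abs(res$delta_bic - best$delta_bic) <= 1e-15 &&
             (wl$prob[j] > wl$prob[best$j] ||
              (wl$prob[j] == wl$prob[best$j] &&
               paste(wl$from[j], wl$to[j]) < paste(wl$from[best$j], wl$to[best$j]))))) {
          best <- c(res, list(j = j))
        }
      }
      if (is.null(best)) {
        if (!escaping) { escaping <- TRUE; escape_left <- config$escape_attempts }
        else escape_left <- escape_left - 1L
        if (escape_left <= 0L) break
        next
      }
      # apply the single best move
      u <- wl$from[best$j]; v <- wl$to[best$j]
      iteration <- iteration + 1L
      if (best$move == "add") {
        bn$parents[[v]] <- c(bn$parents[[v]], u)
        bn$locals[[v]] <- best$refits[[1]]
        children[[u]] <- c(children[[u]], v)
      } else {
        bn$parents[[u]] <- setdiff(bn$parents[[u]], v)
        bn$parents[[v]] <- c(bn$parents[[v]], u)
        bn$locals[[u]] <- best$refits[[1]]
        bn$locals[[v]] <- best$refits[[2]]
        children[[v]] <- setdiff(children[[v]], u)
        children[[u]] <- c(children[[u]], v)
      }
      bn$bic_global <- bn$bic_global - best$delta_bic
      active[best$j] <- FALSE
      displaced <- match(paste(v, u, sep = "\r"), wl_key)
      if (best$move == "reverse" && !is.na(displaced)) active[displaced] <- FALSE
      # in-loop acyclicity assertion: no directed path from v back to v
      if (any(vapply(children[[v]], function(k) tf_reaches(children, k, v),
                     logical(1))))
        stop("internal error: accepted move created a cycle")
      moves[[length(moves) + 1L]] <-
        data.frame(from = u, to = v, move = best$move,
                   delta_bic = best$delta_bic, iteration = iteration,
                   stringsAsFactors = FALSE)
      escaping <- FALSE
    }
  })

  tf_tf <- do.call(rbind, c(list(data.frame(from = character(0), to = character(0),
                                            stringsAsFactors = FALSE)),
                            lapply(init$tf_ids, function(tf) {
                              pp <- intersect(bn$parents[[tf]], init$tf_ids)
                              if (length(pp) == 0) return(NULL)
                              data.frame(from = pp, to = tf, stringsAsFactors = FALSE)
                            })))
  structure(
    list(tf_tf_arcs = tf_tf,
         tf_gene_arcs = init$tf_gene_arcs[, c("from", "to")],
         bic_global = bn$bic_global,
         moves = if (length(moves)) do.call(rbind, moves) else empty_moves(),
         seed = config$seed, n = bn$n, tau = tau, bic_initial = bic_init),
    class = "learned_model")
}

#' @export
print.learned_model <- function(x, ...) {
  cat(sprintf("Learned transcriptional BN: %d TF-TF arcs, %d moves, BIC = %.4f (seed %d)\n",
              nrow(x$tf_tf_arcs), nrow(x$moves), x$bic_global, x$seed))
  invisible(x)
}

#' Recompute a learned model's global score from scratch
#'
#' Refits every local model on the final structure and sums the node BICs;
#' used to verify the incremental score bookkeeping of the search.
#'
#' @param model a `learned_model`.
#' @param init the `tbn_init` the model was learned from.
#' @param expr expression matrix.
#' @return numeric global BIC.
#' @export
recompute_bic_global <- function(model, init, expr) {
  nodes <- c(init$tf_ids, init$gene_ids)
  arcs <- rbind(model$tf_tf_arcs[, c("from", "to")],
                model$tf_gene_arcs[, c("from", "to")])
  gaussian_bn(arcs, nodes, expr)$bic_global
}

#' Run an ensemble of independent structure-learning searches
#'
#' Executes `config$n_runs` runs of [learn_structure()] with seeds
#' `config$seed, config$seed + 1, ...`; the output order is the seed order.
#'
#' @inheritParams learn_structure
#' @param verbose print one line per completed run.
#' @return list of `learned_model`s of class `tbn_ensemble`.
#' @export
run_ensemble <- function(init, expr, config = search_config(), verbose = FALSE) {
  seeds <- config$seed + seq_len(config$n_runs) - 1L
  models <- lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- as.integer(s)
    t0 <- proc.time()[["elapsed"]]
    m <- tryCatch(learn_structure(init, expr, cfg),
                  error = function(e) stop("ensemble run with seed ", s,
                                           " failed: ", conditionMessage(e)))
    m$elapsed <- proc.time()[["elapsed"]] - t0
    if (verbose)
      message(sprintf("run seed %d: %d moves, BIC %.2f (%.2fs)",
                      s, nrow(m$moves), m$bic_global, m$elapsed))
    m
  })
  class(models) <- c("tbn_ensemble", "list")
  models
}
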