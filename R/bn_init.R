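# ---------------------------------------------------------------------------
# From a loopy TF binding network to a Bayesian-model starting point:
# decompose, break loops into a minimal connected DAG plus an arc whitelist,
# reassemble, intersect with expression, attach correlation probabilities.
# ---------------------------------------------------------------------------

#' Decompose a regulatory network into TF-TF and TF-gene components
#'
#' @param trn a [regnet()].
#' @return a list with elements `tf_tf` and `tf_gene`, both `regnet`s; their
#'   arc sets partition the input's arcs.
#' @export
decompose_trn <- function(trn) {
  validate_regnet(trn)
  is_tt <- trn$arcs$to %in% trn$tf_ids
  if (!any(is_tt)) stop("degenerate TF-TF component: no TF-TF arcs")
  tf_tf <- regnet(trn$arcs[is_tt, , drop = FALSE],
                  tf_ids = trn$tf_ids, gene_ids = character(0))
  tf_gene <- regnet(trn$arcs[!is_tt, , drop = FALSE],
                    tf_ids = trn$tf_ids, gene_ids = trn$gene_ids)
  list(tf_tf = tf_tf, tf_gene = tf_gene)
}

#' Break regulatory loops into a minimal connected DAG and a whitelist
#'
#' Iteratively removes TF-TF arcs, starting from the lowest binding weight
#' (or, for unweighted networks, in a seed-determined uniform shuffle with
#' equal weights), skipping any arc whose removal would disconnect its weakly
#' connected component. The survivors form a tree skeleton per component
#' (n - 1 arcs for n TFs), which is acyclic under any arc orientation; every
#' removed arc joins the whitelist with its original weight.
#'
#' @param tf_tf a `regnet` whose arcs are all TF-TF.
#' @param seed integer seed governing the unweighted shuffle and equal-weight
#'   tie order.
#' @return a list of class `loopbreak_result`:
#'   \describe{
#'     \item{dag}{`regnet` with the retained skeleton arcs}
#'     \item{whitelist}{data.frame of class `whitelist` (`from`, `to`,
#'       `weight`) of removed arcs, in removal order}
#'     \item{provenance}{list with `seed`, `weighted`, `removal_order`}
#'   }
#' @export
break_loops <- function(tf_tf, seed = 1L) {
  validate_regnet(tf_tf)
  arcs <- tf_tf$arcs
  if (nrow(arcs) == 0) stop("empty TF-TF component")
  weighted <- tf_tf$weighted
  m <- nrow(arcs)

  if (weighted) {
    ord <- order(arcs$weight, seq_len(m))  # increasing weight, stable ties
  } else {
    ord <- withr_seed(seed, sample.int(m))
  }

  nodes <- unique(c(arcs$from, arcs$to))
  isolated <- setdiff(tf_tf$tf_ids, nodes)
  if (length(isolated) > 0)
    warning(length(isolated), " isolated TF(s) contribute no skeleton arcs")

  g <- igraph::graph_from_data_frame(
    data.frame(from = arcs$from, to = arcs$to, aid = seq_len(m)),
    directed = TRUE, vertices = data.frame(name = nodes))
  n_comp0 <- igraph::count_components(g, mode = "weak")

  keep <- rep(TRUE, m)
  removal_order <- integer(0)
  for (i in ord) {
    eid <- which(igraph::E(g)$aid == i)
    g2 <- igraph::delete_edges(g, eid)
    if (igraph::count_components(g2, mode = "weak") == n_comp0) {
      g <- g2
      keep[i] <- FALSE
      removal_order <- c(removal_order, i)
    }
  }

  dag_arcs <- arcs[keep, , drop = FALSE]
  rownames(dag_arcs) <- NULL
  wl <- arcs[removal_order, , drop = FALSE]
  rownames(wl) <- NULL
  dag <- regnet(dag_arcs, tf_ids = tf_tf$tf_ids, gene_ids = character(0))
  stopifnot(is_acyclic(dag))
  structure(
    list(dag = dag,
         whitelist = new_whitelist(wl),
         provenance = list(seed = as.integer(seed), weighted = weighted,
                           removal_order = removal_order)),
    class = "loopbreak_result")
}

# evaluate expr under a temporarily-set RNG state, restoring it afterwards
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

new_whitelist <- function(df) {
  for (col in c("weight", "r", "prob"))
    if (!col %in% names(df)) df[[col]] <- rep(NA_real_, nrow(df))
  df <- df[, c("from", "to", "weight", "r", "prob")]
  rownames(df) <- NULL
  class(df) <- c("whitelist", "data.frame")
  df
}

#' Join the loop-broken DAG with the TF-gene component
#'
#' @param dag `regnet` (or `loopbreak_result`) holding the TF-TF skeleton.
#' @param tf_gene `regnet` with the TF-to-gene arcs.
#' @return a `regnet` over the union node set whose arcs are the disjoint
#'   union of both inputs.
#' @export
assemble_tbn <- function(dag, tf_gene) {
  if (inherits(dag, "loopbreak_result")) dag <- dag$dag
  collision <- intersect(arc_key(dag$arcs), arc_key(tf_gene$arcs))
  if (length(collision) > 0)
    stop("arc(s) present in both components; inputs are not a valid decomposition: ",
         gsub("\r", " -> ", paste(head(collision, 5), collapse = ", ")))
  arcs <- rbind(dag$arcs, tf_gene$arcs)
  regnet(arcs, tf_ids = union(dag$tf_ids, tf_gene$tf_ids),
         gene_ids = tf_gene$gene_ids)
}

#' Restrict a model and whitelist to nodes with expression data
#'
#' Nodes lacking an expression row are dropped with all incident arcs, from
#' both the assembled network and the whitelist. If dropping disconnects the
#' network, only the largest weakly connected component is retained (with a
#' message reporting the loss).
#'
#' @param tbn assembled `regnet`.
#' @param whitelist a `whitelist` data.frame.
#' @param expr expression matrix (see [read_expression()]).
#' @return list with `tbn`, `whitelist` and `dropped` (character vector of
#'   removed node IDs).
#' @export
intersect_with_expression <- function(tbn, whitelist, expr) {
  validate_expression(expr)
  have <- rownames(expr)
  nodes <- c(tbn$tf_ids, tbn$gene_ids)
  dropped <- setdiff(nodes, have)
  keep_nodes <- intersect(nodes, have)
  arcs <- tbn$arcs[tbn$arcs$from %in% keep_nodes & tbn$arcs$to %in% keep_nodes, ,
                   drop = FALSE]
  if (nrow(arcs) > 0) {
    g <- igraph::graph_from_data_frame(arcs[, c("from", "to")], directed = TRUE)
    comp <- igraph::components(g, mode = "weak")
    if (comp$no > 1) {
      biggest <- which.max(comp$csize)
      in_main <- names(comp$membership)[comp$membership == biggest]
      lost <- setdiff(keep_nodes, in_main)
      message("expression intersection disconnected the network; keeping the ",
              "largest component (", length(in_main), " nodes), dropping ",
              length(lost))
      dropped <- c(dropped, lost)
      keep_nodes <- intersect(keep_nodes, in_main)
      arcs <- arcs[arcs$from %in% keep_nodes & arcs$to %in% keep_nodes, ,
                   drop = FALSE]
    }
  }
  surv_tf <- intersect(tbn$tf_ids, keep_nodes)
  if (length(surv_tf) < 2) stop("insufficient observable network")
  tbn2 <- regnet(arcs, tf_ids = surv_tf,
                 gene_ids = intersect(tbn$gene_ids, keep_nodes))
  wl2 <- whitelist[whitelist$from %in% keep_nodes & whitelist$to %in% keep_nodes, ,
                   drop = FALSE]
  list(tbn = tbn2, whitelist = new_whitelist(as.data.frame(wl2)),
       dropped = dropped)
}

#' Attach correlation-based sampling probabilities to a whitelist
#'
#' For each whitelisted TF-TF arc, the Pearson correlation between the two
#' TFs' expression profiles is stored in `r`; the sampling probability is
#' `|r|` normalized to sum to one over the whitelist. Repressive (negative)
#' correlations are as informative a prior as activating ones, so the
#' magnitude drives sampling while the signed value is retained for
#' reporting. Near-zero magnitudes are floored at 1e-12 before normalization
#' so every arc remains reachable.
#'
#' @param whitelist a `whitelist` data.frame.
#' @param expr expression matrix containing every whitelisted TF.
#' @return the whitelist with `r` and `prob` columns filled; probabilities
#'   sum to 1 (tolerance 1e-9).
#' @export
compute_arc_probabilities <- function(whitelist, expr) {
  validate_expression(expr)
  wl <- as.data.frame(whitelist)
  if (nrow(wl) == 0) return(new_whitelist(wl))
  tfs <- unique(c(wl$from, wl$to))
  missing <- setdiff(tfs, rownames(expr))
  if (length(missing) > 0)
    stop("no expression row for TF(s): ", paste(head(missing, 5), collapse = ", "))
  sds <- apply(expr[tfs, , drop = FALSE], 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance expression profile for TF(s): ",
         paste(head(tfs[sds == 0], 5), collapse = ", "))
  wl$r <- vapply(seq_len(nrow(wl)), function(i) {
    stats::cor(expr[wl$from[i], ], expr[wl$to[i], ])
  }, numeric(1))
  mag <- pmax(abs(wl$r), 1e-12)
  wl$prob <- mag / sum(mag)
  new_whitelist(wl)
}

#' Initialize a transcriptional Bayesian model from a binding network
#'
#' Convenience pipeline: decompose the network, break TF-TF loops, reassemble
#' the DAG with the TF-gene component, intersect everything with the
#' expression matrix, and compute whitelist sampling probabilities.
#'
#' @param trn a [regnet()] with at least one TF-TF arc.
#' @param expr expression matrix.
#' @param seed integer seed for the unweighted loop-breaking shuffle.
#' @return an object of class `tbn_init` with fields `dag` (TF-TF skeleton
#'   arcs data.frame), `tf_gene_arcs`, `whitelist`, `tf_ids`, `gene_ids`,
#'   `provenance`.
#' @export
initialize_model <- function(trn, expr, seed = 1L) {
  parts <- decompose_trn(trn)
  lb <- break_loops(parts$tf_tf, seed = seed)
  tbn <- assemble_tbn(lb$dag, parts$tf_gene)
  ix <- intersect_with_expression(tbn, lb$whitelist, expr)
  wl <- compute_arc_probabilities(ix$whitelist, expr)
  tt <- ix$tbn$arcs$to %in% ix$tbn$tf_ids
  structure(
    list(dag = ix$tbn$arcs[tt, , drop = FALSE],
         tf_gene_arcs = ix$tbn$arcs[!tt, , drop = FALSE],
         whitelist = wl,
         tf_ids = ix$tbn$tf_ids,
         gene_ids = ix$tbn$gene_ids,
         provenance = c(lb$provenance, list(dropped = ix$dropped))),
    class = "tbn_init")
}

#' @export
print.tbn_init <- function(x, ...) {
  cat(sprintf(paste0("Initialized transcriptional BN: %d TFs, %d genes, ",
                     "%d skeleton + %d TF-gene arcs, whitelist %d\n"),
              length(x$tf_ids), length(x$gene_ids), nrow(x$dag),
              nrow(x$tf_gene_arcs), nrow(x$whitelist)))
  invisible(x)
}
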