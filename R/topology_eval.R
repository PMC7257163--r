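# ---------------------------------------------------------------------------
# Topological statistics on the TF-TF subgraph (degrees, hierarchy layers),
# network overlap comparison, and the false-prior robustness harness.
# ---------------------------------------------------------------------------

tf_tf_arcs_of <- function(net) {
  if (inherits(net, "consensus_network")) return(consensus_arcs(net)[, c("from", "to")])
  if (inherits(net, "regnet")) {
    arcs <- net$arcs[net$arcs$to %in% net$tf_ids, c("from", "to"), drop = FALSE]
    return(arcs)
  }
  as_arc_df(net)[, c("from", "to")]
}

net_tfs_of <- function(net, arcs) {
  if (inherits(net, "regnet")) net$tf_ids
  else unique(c(arcs$from, arcs$to))
}

#' Per-node degree statistics of the TF-TF subgraph
#'
#' @param net a `regnet`, `consensus_network`, or arc data.frame.
#' @return list with `per_node` (data.frame `node`, `out_degree`,
#'   `in_degree`), `mean_total_degree` (average of in+out per node) and
#'   `arcs_per_node` (|E|/|V|, the alternative connectivity convention).
#' @export
degree_stats <- function(net) {
  arcs <- tf_tf_arcs_of(net)
  tfs <- net_tfs_of(net, arcs)
  if (length(tfs) == 0) stop("empty network")
  out_deg <- table(factor(arcs$from, levels = tfs))
  in_deg <- table(factor(arcs$to, levels = tfs))
  per_node <- data.frame(node = tfs,
                         out_degree = as.integer(out_deg),
                         in_degree = as.integer(in_deg),
                         stringsAsFactors = FALSE)
  list(per_node = per_node,
       mean_total_degree = mean(per_node$out_degree + per_node$in_degree),
       arcs_per_node = nrow(arcs) / length(tfs))
}

#' Stratify TFs into hierarchy layers
#'
#' Computes the hierarchy height `h = (out - in) / (out + in)` per TF on the
#' TF-TF subgraph and assigns layers: `master_regulator` when `h` exceeds the
#' upper cutoff, `workhorse` below the lower cutoff, `middle_manager`
#' otherwise. Isolated TFs (no TF-TF arcs) get `h = 0`, the middle layer, and
#' an `isolated` flag.
#'
#' @param net a `regnet`, `consensus_network`, or arc data.frame.
#' @param cutoffs numeric length-2 vector `(low, high)`, default `(-1/3, 1/3)`.
#' @return data.frame `node`, `out_degree`, `in_degree`, `h`, `layer`,
#'   `isolated`.
#' @export
hierarchy_layers <- function(net, cutoffs = c(-1/3, 1/3)) {
  stopifnot(length(cutoffs) == 2, cutoffs[1] <= cutoffs[2])
  deg <- degree_stats(net)$per_node
  tot <- deg$out_degree + deg$in_degree
  h <- ifelse(tot > 0, (deg$out_degree - deg$in_degree) / tot, 0)
  layer <- ifelse(tot == 0, "middle_manager",
           ifelse(h > cutoffs[2], "master_regulator",
           ifelse(h < cutoffs[1], "workhorse", "middle_manager")))
  data.frame(deg, h = h, layer = layer, isolated = tot == 0,
             stringsAsFactors = FALSE)
}

#' Compare the arc sets of two networks
#'
#' @param net_a,net_b networks (`regnet`, consensus, or arc data.frames)
#'   over overlapping node universes.
#' @param restrict_to_common_regulators when `TRUE`, only arcs whose source
#'   is a TF present (as a source) in both networks are compared.
#' @return list with `shared`, `a_only`, `b_only` (arc counts),
#'   `shared_fraction` (of net_a's compared arcs) and `common_regulators`.
#' @export
edge_overlap <- function(net_a, net_b, restrict_to_common_regulators = TRUE) {
  aa <- tf_tf_arcs_of(net_a); bb <- tf_tf_arcs_of(net_b)
  nodes_a <- unique(c(aa$from, aa$to)); nodes_b <- unique(c(bb$from, bb$to))
  if (length(intersect(nodes_a, nodes_b)) == 0)
    stop("networks share no nodes")
  common <- intersect(unique(aa$from), unique(bb$from))
  if (restrict_to_common_regulators) {
    aa <- aa[aa$from %in% common, , drop = FALSE]
    bb <- bb[bb$from %in% common, , drop = FALSE]
  }
  ka <- arc_key(aa); kb <- arc_key(bb)
  shared <- length(intersect(ka, kb))
  list(shared = shared,
       a_only = length(setdiff(ka, kb)),
       b_only = length(setdiff(kb, ka)),
       shared_fraction = if (length(ka) > 0) shared / length(ka) else NA_real_,
       common_regulators = common)
}

#' Inject false TF-TF arcs into a gold-standard network
#'
#' Adds `round(fraction * |TF-TF arcs|)` arcs (round-half-even) drawn
#' uniformly from the ordered TF pairs absent from the network (no
#' self-loops, no duplicates). Injected arcs of a weighted network receive
#' weights drawn uniformly between the existing minimum and maximum, so they
#' are indistinguishable from genuine binding scores downstream.
#'
#' @param net the gold `regnet`.
#' @param fraction nonnegative fraction of the TF-TF arc count to inject.
#' @param seed integer seed.
#' @return list with `corrupted` (`regnet`) and `injected` (data.frame
#'   `from`, `to` of the added arcs).
#' @export
inject_false_arcs <- function(net, fraction, seed = 1L) {
  stopifnot(fraction >= 0)
  tt <- tf_tf_arcs_of(net)
  n_add <- round(fraction * nrow(tt))
  if (n_add == 0)
    return(list(corrupted = net,
                injected = data.frame(from = character(0), to = character(0))))
  tfs <- net$tf_ids
  all_pairs <- expand.grid(from = tfs, to = tfs, stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  absent <- all_pairs[!(arc_key(all_pairs) %in% arc_key(net$arcs)), , drop = FALSE]
  if (nrow(absent) < n_add)
    stop("insufficient absent TF pairs: need ", n_add, ", have ", nrow(absent))
  withr_seed(seed, {
    pick <- absent[sample.int(nrow(absent), n_add), , drop = FALSE]
    w <- if (net$weighted)
      runif(n_add, min(net$arcs$weight), max(net$arcs$weight))
    else NA_real_
  })
  injected <- data.frame(from = pick$from, to = pick$to, stringsAsFactors = FALSE)
  corrupted_arcs <- rbind(net$arcs,
                          data.frame(from = pick$from, to = pick$to, weight = w))
  corrupted <- regnet(corrupted_arcs, tf_ids = net$tf_ids, gene_ids = net$gene_ids)
  list(corrupted = corrupted, injected = injected)
}

#' Precision of a consensus network against a gold standard
#'
#' Direction-sensitive accounting: a selected arc is a true positive when it
#' appears (same direction) in the gold arc set, otherwise a false positive.
#' A selected arc whose reverse is in gold is reported separately in
#' `reversed` for diagnostics (still counted as FP).
#'
#' @param consensus a `consensus_network` or data.frame of selected arcs.
#' @param gold_arcs gold TF-TF arcs (`regnet` or data.frame).
#' @param injected_arcs optional data.frame of injected false-prior arcs,
#'   reported as `injected_in_consensus`.
#' @return list of class `robustness_report`: `consensus_size`, `tp`, `fp`,
#'   `pct_fp` (percentage of selected arcs that are FP), `precision`,
#'   `reversed`, `injected_in_consensus`.
#' @export
precision_report <- function(consensus, gold_arcs, injected_arcs = NULL) {
  sel <- if (inherits(consensus, "consensus_network")) consensus_arcs(consensus)
         else as_arc_df(consensus)
  if (nrow(sel) == 0) stop("empty consensus")
  gold <- tf_tf_arcs_of(gold_arcs)
  ks <- paste(sel$from, sel$to, sep = "\r")
  kg <- arc_key(gold)
  tp <- sum(ks %in% kg)
  fp <- sum(!(ks %in% kg))
  rev_k <- paste(sel$to, sel$from, sep = "\r")
  reversed <- sum(!(ks %in% kg) & (rev_k %in% kg))
  inj <- if (!is.null(injected_arcs) && nrow(injected_arcs) > 0)
    sum(ks %in% paste(injected_arcs$from, injected_arcs$to, sep = "\r"))
  else 0L
  structure(
    list(consensus_size = nrow(sel), tp = tp, fp = fp,
         pct_fp = 100 * fp / nrow(sel), precision = tp / (tp + fp),
         reversed = reversed, injected_in_consensus = inj),
    class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("Consensus BN size (# of edges): %d | %% FPs added: %.0f%% | Precision: %.2f\n",
              x$consensus_size, x$pct_fp, x$precision))
  invisible(x)
}
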