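# ---------------------------------------------------------------------------
# Consensus transcriptional BN: accumulate per-arc strength across an
# ensemble of learned models, threshold at a weight percentile, and repair
# the selection to an acyclic, direction-unique subgraph.
# ---------------------------------------------------------------------------

# Per-model strength used to accumulate edge weights. Summing raw global BIC
# scores would reward presence in *worse* models whenever scores are
# positive, and the sign of the score depends only on the data scale. The
# shifted strength S(m) = (worst score) - score(m) + delta, with
# delta = |worst| * 1e-6 + 1, is strictly positive, increases as a model's
# score improves, and reduces to plain frequency counting when all models
# score equally. `mode = "raw"` gives the literal raw-sum alternative.
model_strengths <- function(scores, mode = c("shifted", "raw")) {
  mode <- match.arg(mode)
  if (mode == "raw") return(scores)
  worst <- max(scores)
  worst - scores + (abs(worst) * 1e-6 + 1)
}

#' Accumulated edge strengths over an ensemble
#'
#' For every directed TF-TF arc present in at least one learned structure,
#' reports its frequency (number of containing models) and its weight: the
#' sum, over containing models, of the model strength derived from the
#' global BIC. With the default `"shifted"` strength, presence in more and
#' in better-scoring models strictly increases the weight.
#'
#' @param models list of `learned_model`s (a `tbn_ensemble`).
#' @param mode `"shifted"` (default) or `"raw"` (literal sum of global BICs).
#' @return data.frame `from`, `to`, `frequency`, `weight`, sorted by
#'   decreasing weight then lexicographically.
#' @export
edge_strengths <- function(models, mode = c("shifted", "raw")) {
  mode <- match.arg(mode)
  if (length(models) == 0) stop("empty ensemble")
  scores <- vapply(models, function(m) m$bic_global, numeric(1))
  S <- model_strengths(scores, mode)
  tallies <- new.env(parent = emptyenv())
  for (i in seq_along(models)) {
    aa <- models[[i]]$tf_tf_arcs
    if (nrow(aa) == 0) next
    keys <- paste(aa$from, aa$to, sep = "\r")
    for (k in keys) {
      cur <- if (exists(k, envir = tallies)) get(k, envir = tallies) else c(0, 0)
      assign(k, c(cur[1] + 1, cur[2] + S[i]), envir = tallies)
    }
  }
  keys <- ls(tallies)
  if (length(keys) == 0)
    return(data.frame(from = character(0), to = character(0),
                      frequency = integer(0), weight = numeric(0)))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    from = vapply(parts, `[`, character(1), 1),
    to = vapply(parts, `[`, character(1), 2),
    frequency = vapply(keys, function(k) as.integer(get(k, envir = tallies)[1]),
                       integer(1)),
    weight = vapply(keys, function(k) get(k, envir = tallies)[2], numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$weight, out$from, out$to), ]
  rownames(out) <- NULL
  out
}

#' Distill an ensemble into a consensus transcriptional BN
#'
#' Candidates with weight at or above the `percentile`-th percentile of the
#' candidate weight distribution (linear-interpolation percentile) are
#' selected, then repaired: if both directions of a TF pair survive, the
#' higher-weight direction wins (ties: higher frequency, then lexicographic);
#' while a directed cycle remains, the lowest-weight cycle arc is dropped;
#' finally weak connectivity of the selected TF-TF arcs together with the
#' fixed TF-gene arcs is verified (a warning reports the components
#' otherwise).
#'
#' @param models list of `learned_model`s.
#' @param percentile threshold percentile in \[0, 100\] (e.g. 5 for a strict
#'   noise filter, 25 for a smaller prior network).
#' @param mode strength mode, see [edge_strengths()].
#' @return object of class `consensus_network`: `candidate_edges` (with
#'   `selected` flag), `fixed_tf_gene_arcs`, `percentile`, `n_models`.
#' @export
build_consensus <- function(models, percentile = 5, mode = c("shifted", "raw")) {
  if (percentile < 0 || percentile > 100) stop("percentile must be in [0, 100]")
  cand <- edge_strengths(models, mode)
  if (nrow(cand) == 0) stop("ensemble contains no TF-TF arcs")
  thr <- as.numeric(quantile(cand$weight, percentile / 100, type = 7))
  cand$selected <- cand$weight >= thr

  # direction uniqueness
  sel <- which(cand$selected)
  key <- paste(cand$from, cand$to, sep = "\r")
  rev_key <- paste(cand$to, cand$from, sep = "\r")
  for (i in sel) {
    if (!cand$selected[i]) next
    j <- match(rev_key[i], key)
    if (!is.na(j) && cand$selected[j]) {
      drop <- if (cand$weight[i] != cand$weight[j]) {
        if (cand$weight[i] < cand$weight[j]) i else j
      } else if (cand$frequency[i] != cand$frequency[j]) {
        if (cand$frequency[i] < cand$frequency[j]) i else j
      } else {
        if (key[i] < key[j]) j else i
      }
      cand$selected[drop] <- FALSE
    }
  }

  # acyclicity repair: drop the lowest-weight arc lying on a cycle
  repeat {
    sel_arcs <- cand[cand$selected, , drop = FALSE]
    if (nrow(sel_arcs) == 0) break
    g <- igraph::graph_from_data_frame(sel_arcs[, c("from", "to")])
    if (igraph::is_dag(g)) break
    on_cycle <- vapply(seq_len(nrow(sel_arcs)), function(i) {
      # arc (a, b) lies on a directed cycle iff b reaches a
      d <- igraph::distances(g, v = sel_arcs$to[i], to = sel_arcs$from[i],
                             mode = "out")
      is.finite(d[1, 1])
    }, logical(1))
    cyc <- sel_arcs[on_cycle, , drop = FALSE]
    ord <- order(cyc$weight, cyc$from, cyc$to)
    victim <- cyc[ord[1], ]
    idx <- which(cand$from == victim$from & cand$to == victim$to)
    cand$selected[idx] <- FALSE
  }

  fixed <- models[[1]]$tf_gene_arcs[, c("from", "to")]
  all_arcs <- rbind(cand[cand$selected, c("from", "to")], fixed)
  if (nrow(all_arcs) > 0) {
    g <- igraph::graph_from_data_frame(all_arcs)
    comp <- igraph::components(g, mode = "weak")
    if (comp$no > 1)
      warning("consensus plus fixed arcs is not weakly connected: ",
              comp$no, " components of sizes ",
              paste(sort(comp$csize, decreasing = TRUE), collapse = ", "))
  }
  structure(
    list(candidate_edges = cand, fixed_tf_gene_arcs = fixed,
         percentile = percentile, n_models = length(models),
         threshold = thr),
    class = "consensus_network")
}

#' Selected consensus TF-TF arcs
#' @param consensus a `consensus_network`.
#' @return data.frame `from`, `to`, `frequency`, `weight` of selected arcs.
#' @export
consensus_arcs <- function(consensus) {
  ce <- consensus$candidate_edges
  out <- ce[ce$selected, c("from", "to", "frequency", "weight")]
  rownames(out) <- NULL
  out
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("Consensus BN: %d/%d candidate TF-TF arcs selected (%gth percentile, %d models)\n",
              sum(x$candidate_edges$selected), nrow(x$candidate_edges),
              x$percentile, x$n_models))
  invisible(x)
}
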