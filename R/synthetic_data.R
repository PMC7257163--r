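# ---------------------------------------------------------------------------
# Synthetic ground truth: loop-rich TF binding networks with an acyclic
# generative core, linear-Gaussian expression sampled from that core, a
# planted-arc scenario for structure-recovery checks, and robustness
# fixtures with injected false prior arcs.
# ---------------------------------------------------------------------------

#' Specification for a synthetic regulatory-network fixture
#'
#' The observed network consists of an acyclic generative core (weakly
#' connected over the TFs) plus `loop_fraction` of the TF-TF arc budget added
#' as cycle-closing arcs with no generative effect, mimicking the feedback
#' loops of real binding networks while keeping the data-generating model
#' well defined. Core arcs receive stochastically higher binding weights
#' than loop arcs.
#'
#' @param n_tf,n_gene node counts.
#' @param tf_tf_arcs total TF-TF arcs in the observed network (core + loops);
#'   must be at least `n_tf - 1`.
#' @param tf_gene_arcs total TF-to-gene arcs (at most `n_tf * n_gene`, at
#'   least `n_gene` so every gene has a regulator).
#' @param loop_fraction fraction of `tf_tf_arcs` added as cycle-closing arcs.
#' @param coeff_range positive range for the magnitude of regulatory
#'   coefficients.
#' @param sign_prob probability that a coefficient is positive (activation).
#' @param noise_sigma residual standard deviation of the expression model.
#' @param n_samples number of expression samples (>= 3).
#' @param weighted whether the observed network carries binding weights.
#' @param seed integer seed; fixtures are pure functions of (spec, seed).
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_tf, n_gene, tf_tf_arcs, tf_gene_arcs,
                           loop_fraction = 0.3, coeff_range = c(0.5, 1.5),
                           sign_prob = 0.5, noise_sigma = 1.0,
                           n_samples = 100L, weighted = TRUE, seed = 1L) {
  stopifnot(n_tf >= 2, n_gene >= 0, tf_tf_arcs >= n_tf - 1,
            n_samples >= 3, all(coeff_range > 0), length(coeff_range) == 2,
            loop_fraction >= 0, loop_fraction <= 1,
            sign_prob >= 0, sign_prob <= 1, noise_sigma >= 0)
  n_loop <- round(loop_fraction * tf_tf_arcs)
  if (tf_tf_arcs - n_loop < n_tf - 1)
    stop("loop_fraction leaves fewer core arcs than a spanning tree needs")
  if (tf_tf_arcs - n_loop > n_tf * (n_tf - 1) / 2)
    stop("core arc budget exceeds the capacity of an acyclic tournament")
  if (n_gene > 0 && (tf_gene_arcs < n_gene || tf_gene_arcs > n_tf * n_gene))
    stop("tf_gene_arcs must lie in [n_gene, n_tf * n_gene]")
  structure(list(n_tf = as.integer(n_tf), n_gene = as.integer(n_gene),
                 tf_tf_arcs = as.integer(tf_tf_arcs),
                 tf_gene_arcs = as.integer(tf_gene_arcs),
                 loop_fraction = loop_fraction, n_loop = as.integer(n_loop),
                 coeff_range = coeff_range, sign_prob = sign_prob,
                 noise_sigma = noise_sigma, n_samples = as.integer(n_samples),
                 weighted = weighted, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# reachability matrix over node indices for an acyclic arc list whose
# topological order is given by `topo` (a permutation of 1..n)
reach_matrix <- function(n, from_idx, to_idx, topo) {
  R <- diag(n) > 0
  kids <- split(to_idx, factor(from_idx, levels = seq_len(n)))
  for (v in rev(topo)) {
    for (k in kids[[v]]) R[v, ] <- R[v, ] | R[k, ]
  }
  R
}

#' Simulate a loop-rich TF binding network
#'
#' Builds a random weakly-connected acyclic core over the TFs (a random
#' recursive spanning tree plus extra forward arcs under a random topological
#' order), then adds cycle-closing arcs: the first closes a 2-cycle (the
#' reversal of a core arc) and the rest are reversals of core directed paths,
#' so every added arc closes a directed cycle with the core. TF-to-gene arcs
#' are attached with every gene receiving at least one regulator. Weights:
#' core arcs Uniform(1, 3), loop arcs Uniform(0.5, 2), TF-gene arcs
#' Uniform(0.5, 3).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `network` (the observed loopy `regnet`),
#'   `generative_arcs` (data.frame of core TF-TF plus TF-gene arcs; always
#'   acyclic) and `core_tf_tf` (data.frame of the core TF-TF arcs).
#' @export
simulate_trn <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr_seed(spec$seed, {
    n <- spec$n_tf
    tfs <- sprintf("TF%02d", seq_len(n))
    genes <- if (spec$n_gene > 0) sprintf("G%03d", seq_len(spec$n_gene)) else character(0)
    ordv <- sample(n)                      # topological order of the core
    # spanning tree: each node after the first attaches to a random earlier one
    tree_from <- vapply(2:n, function(i) ordv[sample.int(i - 1, 1)], integer(1))
    core <- cbind(tree_from, ordv[2:n])
    # extra forward arcs among pairs (ordv[i], ordv[j]), i < j, not yet used
    n_core <- spec$tf_tf_arcs - spec$n_loop
    need <- n_core - (n - 1)
    if (need > 0) {
      pos <- match(seq_len(n), ordv)       # node -> position in order
      cand <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)  # i < j positions
      cand_from <- ordv[cand[, 1]]; cand_to <- ordv[cand[, 2]]
      used <- paste(core[, 1], core[, 2])
      free <- !(paste(cand_from, cand_to) %in% used)
      pick <- sample(which(free), need)
      core <- rbind(core, cbind(cand_from[pick], cand_to[pick]))
    }
    # loop-closing arcs: reversals of directed core paths
    loops <- NULL
    if (spec$n_loop > 0) {
      R <- reach_matrix(n, core[, 1], core[, 2], topo = ordv)
      diag(R) <- FALSE
      back <- which(R, arr.ind = TRUE)     # u reaches v  =>  arc v -> u closes a cycle
      back_from <- back[, 2]; back_to <- back[, 1]
      if (length(back_from) < spec$n_loop)
        stop("not enough cycle-closing candidates; increase core density")
      # guarantee a 2-cycle: reverse one random core arc first
      e1 <- sample.int(nrow(core), 1)
      first <- c(core[e1, 2], core[e1, 1])
      rest_ok <- !(back_from == first[1] & back_to == first[2])
      n_rest <- spec$n_loop - 1L
      idx <- which(rest_ok)
      if (length(idx) < n_rest) stop("not enough cycle-closing candidates")
      pick <- if (n_rest > 0) sample(idx, n_rest) else integer(0)
      loops <- rbind(first, cbind(back_from[pick], back_to[pick]))
    }
    # TF -> gene arcs: one guaranteed regulator per gene, rest uniform
    tg <- NULL
    if (spec$n_gene > 0) {
      g_first <- cbind(sample.int(n, spec$n_gene, replace = TRUE),
                       seq_len(spec$n_gene))
      extra <- spec$tf_gene_arcs - spec$n_gene
      if (extra > 0) {
        all_tg <- expand.grid(tf = seq_len(n), g = seq_len(spec$n_gene))
        free <- !(paste(all_tg$tf, all_tg$g) %in% paste(g_first[, 1], g_first[, 2]))
        pick <- sample(which(free), extra)
        tg <- rbind(g_first, cbind(all_tg$tf[pick], all_tg$g[pick]))
      } else tg <- g_first
    }
    w_core <- runif(nrow(core), 1, 3)
    w_loop <- if (!is.null(loops)) runif(nrow(loops), 0.5, 2) else numeric(0)
    w_tg <- if (!is.null(tg)) runif(nrow(tg), 0.5, 3) else numeric(0)

    core_df <- data.frame(from = tfs[core[, 1]], to = tfs[core[, 2]],
                          weight = w_core, stringsAsFactors = FALSE)
    loop_df <- if (!is.null(loops))
      data.frame(from = tfs[loops[, 1]], to = tfs[loops[, 2]],
                 weight = w_loop, stringsAsFactors = FALSE)
    else core_df[0, ]
    tg_df <- if (!is.null(tg))
      data.frame(from = tfs[tg[, 1]], to = genes[tg[, 2]],
                 weight = w_tg, stringsAsFactors = FALSE)
    else core_df[0, ]
    arcs <- rbind(core_df, loop_df, tg_df)
    if (!spec$weighted) arcs$weight <- NA_real_
    net <- regnet(arcs, tf_ids = tfs, gene_ids = genes)
    gen <- rbind(core_df, tg_df)
    if (!spec$weighted) gen$weight <- NA_real_
    list(network = net, generative_arcs = gen[, c("from", "to")],
         core_tf_tf = core_df[, c("from", "to")])
  })
}

#' Simulate linear-Gaussian expression from an acyclic generative structure
#'
#' Nodes are sampled in topological order: each node equals its intercept
#' plus a linear combination of its parents plus i.i.d. Gaussian noise.
#' Coefficient magnitudes are drawn from `spec$coeff_range` with sign
#' positive with probability `spec$sign_prob`; intercepts are
#' Uniform(-1, 1).
#'
#' @param arcs data.frame of generative arcs (`from`, `to`); must be acyclic.
#' @param nodes character vector of all node identifiers.
#' @param spec a [synthetic_spec()] providing `noise_sigma`, `n_samples`,
#'   `coeff_range`, `sign_prob` and the seed.
#' @param seed optional override of `spec$seed` (the expression draw uses
#'   `seed + 1000` internally so it is decoupled from the network draw).
#' @param coefficients optional data.frame `from`, `to`, `coef` fixing some
#'   or all coefficients instead of drawing them.
#' @return list with `expr` (matrix nodes x samples), `coefficients`
#'   (data.frame `from`, `to`, `coef`) and `intercepts` (named vector).
#' @export
simulate_expression <- function(arcs, nodes, spec, seed = NULL,
                                coefficients = NULL) {
  g <- as_igraph(arcs, nodes = nodes)
  if (!igraph::is_dag(g)) stop("generative structure must be acyclic")
  base_seed <- if (is.null(seed)) spec$seed else seed
  withr_seed(base_seed + 1000L, {
    m <- nrow(arcs)
    coef <- runif(m, spec$coeff_range[1], spec$coeff_range[2]) *
      ifelse(runif(m) < spec$sign_prob, 1, -1)
    if (!is.null(coefficients)) {
      k <- match(paste(arcs$from, arcs$to),
                 paste(coefficients$from, coefficients$to))
      coef[!is.na(k)] <- coefficients$coef[k[!is.na(k)]]
    }
    a0 <- setNames(runif(length(nodes), -1, 1), nodes)
    topo <- names(igraph::topo_sort(g, mode = "out"))
    ns <- spec$n_samples
    expr <- matrix(0, nrow = length(nodes), ncol = ns,
                   dimnames = list(nodes, sprintf("S%03d", seq_len(ns))))
    par_list <- split(seq_len(m), arcs$to)
    for (nd in topo) {
      x <- rep(a0[[nd]], ns)
      for (i in par_list[[nd]]) x <- x + coef[i] * expr[arcs$from[i], ]
      expr[nd, ] <- x + rnorm(ns, 0, spec$noise_sigma)
    }
    list(expr = expr,
         coefficients = data.frame(from = arcs$from, to = arcs$to,
                                   coef = coef, stringsAsFactors = FALSE),
         intercepts = a0)
  })
}

#' Planted-arc structure-recovery scenario
#'
#' Builds a small fixture in which expression is generated from a TF tree
#' plus one strong held-out TF-TF arc; the initial model contains the tree
#' but not the planted arc, and the whitelist holds the planted arc plus
#' zero-effect decoys. A correct learner should accept the planted arc first.
#'
#' @param n_tf,n_gene,n_decoys,n_samples scenario dimensions.
#' @param effect coefficient of the planted arc (strong relative to the
#'   default coefficient range and unit noise).
#' @param seed integer seed.
#' @return list with `init` (a `tbn_init` with whitelist probabilities set),
#'   `expr`, `planted` (length-2 character vector `from`, `to`),
#'   `decoys` (data.frame), `truth` (coefficients data.frame).
#' @export
simulate_planted_arc <- function(n_tf = 6, n_gene = 10, n_decoys = 10,
                                 n_samples = 200, effect = 1.5, seed = 1L) {
  spec <- synthetic_spec(n_tf = n_tf, n_gene = n_gene,
                         tf_tf_arcs = n_tf - 1, tf_gene_arcs = 2 * n_gene,
                         loop_fraction = 0, n_samples = n_samples, seed = seed)
  sim <- simulate_trn(spec)
  tfs <- sim$network$tf_ids
  core <- sim$core_tf_tf
  withr_seed(seed + 2000L, {
    # pick a planted arc: forward under the core's topological order and
    # absent from the tree, so core + planted stays acyclic
    g <- as_igraph(core, nodes = tfs)
    topo <- names(igraph::topo_sort(g))
    pos <- match(tfs, topo)
    cand <- expand.grid(from = tfs, to = tfs, stringsAsFactors = FALSE)
    cand <- cand[pos[match(cand$from, tfs)] < pos[match(cand$to, tfs)], ]
    cand <- cand[!(arc_key(cand) %in% arc_key(core)), ]
    planted <- cand[sample.int(nrow(cand), 1), ]
    # decoys: any ordered TF pair not in core, not the planted arc
    dec_pool <- expand.grid(from = tfs, to = tfs, stringsAsFactors = FALSE)
    dec_pool <- dec_pool[dec_pool$from != dec_pool$to, ]
    dec_pool <- dec_pool[!(arc_key(dec_pool) %in%
                             c(arc_key(core), arc_key(planted))), ]
    decoys <- dec_pool[sample.int(nrow(dec_pool), min(n_decoys, nrow(dec_pool))), ]
  })
  gen_arcs <- rbind(core, planted, sim$generative_arcs[
    !(arc_key(sim$generative_arcs) %in% arc_key(core)), ])
  nodes <- c(tfs, sim$network$gene_ids)
  ex <- simulate_expression(
    gen_arcs, nodes, spec, seed = seed,
    coefficients = data.frame(from = planted$from, to = planted$to,
                              coef = effect))
  wl <- new_whitelist(rbind(
    data.frame(planted, weight = NA_real_),
    data.frame(decoys, weight = NA_real_)))
  wl <- compute_arc_probabilities(wl, ex$expr)
  tg <- sim$generative_arcs[!(sim$generative_arcs$to %in% tfs), ]
  init <- structure(
    list(dag = data.frame(core, weight = NA_real_),
         tf_gene_arcs = data.frame(tg, weight = NA_real_),
         whitelist = wl, tf_ids = tfs, gene_ids = sim$network$gene_ids,
         provenance = list(seed = seed, weighted = FALSE,
                           planted = unlist(planted, use.names = FALSE))),
    class = "tbn_init")
  list(init = init, expr = ex$expr,
       planted = c(from = planted$from, to = planted$to),
       decoys = decoys, truth = ex$coefficients)
}

#' Robustness fixture: gold network, corrupted prior, and expression
#'
#' Composes [simulate_trn()], [simulate_expression()] (on the acyclic
#' generative structure) and [inject_false_arcs()] into one reproducible
#' fixture mirroring the false-prior experiment design: the corrupted network
#' is the gold binding network plus a stated fraction of random false TF-TF
#' arcs, while expression reflects only the true regulatory core.
#'
#' @param spec a [synthetic_spec()].
#' @param fp_fraction fraction of TF-TF arcs to inject as false priors.
#' @param seed optional seed override for the injection draw (defaults to
#'   `spec$seed`).
#' @return list with `gold` (`regnet`), `corrupted` (`regnet`), `expr`,
#'   `injected` (data.frame), `generative_arcs`, `truth` (coefficients).
#' @export
make_robustness_fixture <- function(spec, fp_fraction, seed = NULL) {
  stopifnot(fp_fraction >= 0, fp_fraction <= 1)
  if (is.null(seed)) seed <- spec$seed
  sim <- simulate_trn(spec)
  nodes <- c(sim$network$tf_ids, sim$network$gene_ids)
  ex <- simulate_expression(sim$generative_arcs, nodes, spec)
  inj <- inject_false_arcs(sim$network, fp_fraction, seed = seed + 3000L)
  list(gold = sim$network, corrupted = inj$corrupted, expr = ex$expr,
       injected = inj$injected, generative_arcs = sim$generative_arcs,
       truth = ex$coefficients)
}
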