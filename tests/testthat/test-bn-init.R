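test_that("decomposition splits TF-TF from TF-gene arcs and conserves the multiset", {
  net <- toy_net()
  parts <- decompose_trn(net)
  expect_equal(parts$tf_tf$arcs$from, "A")
  expect_equal(parts$tf_tf$arcs$to, "B")
  expect_equal(nrow(parts$tf_gene$arcs), 2)

  # random network: union of parts equals the input arc set
  spec <- synthetic_spec(n_tf = 8, n_gene = 10, tf_tf_arcs = 20,
                         tf_gene_arcs = 15, seed = 5)
  sim <- simulate_trn(spec)
  p <- decompose_trn(sim$network)
  got <- sort(c(tbnfuse:::arc_key(p$tf_tf$arcs), tbnfuse:::arc_key(p$tf_gene$arcs)))
  expect_equal(got, sort(tbnfuse:::arc_key(sim$network$arcs)))

  genes_only <- regnet(data.frame(from = "A", to = "G1"), tf_ids = c("A", "B"))
  expect_error(decompose_trn(genes_only), "degenerate TF-TF component")
})

test_that("loop-breaking leaves a directed tree untouched", {
  tree <- regnet(data.frame(from = c("A", "A", "B"), to = c("B", "C", "D"),
                            weight = c(1, 2, 3)), tf_ids = c("A", "B", "C", "D"))
  lb <- break_loops(tree)
  expect_equal(lb$dag$arcs, tree$arcs)
  expect_equal(nrow(lb$whitelist), 0)
})

test_that("weighted removal follows the sorted greedy simulation exactly", {
  # 4 nodes, 6 weighted arcs including a 2-cycle and a 3-cycle
  arcs <- data.frame(from = c("A", "B", "B", "C", "C", "D"),
                     to   = c("B", "A", "C", "A", "D", "B"),
                     weight = c(5, 1, 4, 2, 6, 3))
  net <- regnet(arcs, tf_ids = c("A", "B", "C", "D"))
  lb <- break_loops(net)
  expect_equal(nrow(lb$dag$arcs), 3)
  expect_equal(nrow(lb$whitelist), 3)
  oracle <- oracle_greedy_removal(arcs, c("A", "B", "C", "D"),
                                  order(arcs$weight))
  expect_setequal(tbnfuse:::arc_key(lb$dag$arcs),
                  tbnfuse:::arc_key(arcs[oracle$kept, ]))
  expect_equal(tbnfuse:::arc_key(lb$whitelist),
               tbnfuse:::arc_key(arcs[oracle$removed, ]))
  # removed arcs carry their original weights into the whitelist
  expect_equal(lb$whitelist$weight, arcs$weight[oracle$removed])
})

test_that("loop-breaking obeys the n-1 size law, conservation, and acyclicity", {
  for (seed in c(2, 9, 23)) {
    spec <- synthetic_spec(n_tf = 12, n_gene = 0, tf_tf_arcs = 40,
                           tf_gene_arcs = 0, loop_fraction = 0.4, seed = seed)
    sim <- simulate_trn(spec)
    tf_tf <- decompose_trn(sim$network)$tf_tf
    lb <- break_loops(tf_tf, seed = seed)
    expect_equal(nrow(lb$dag$arcs), 11)                       # n - 1
    expect_equal(nrow(lb$dag$arcs) + nrow(lb$whitelist), 40)  # conservation
    expect_true(is_acyclic(lb$dag))
    expect_true(is_weakly_connected(lb$dag))
  }
})

test_that("unweighted mode is seed-shuffled but size-invariant across seeds", {
  spec <- synthetic_spec(n_tf = 10, n_gene = 0, tf_tf_arcs = 25,
                         tf_gene_arcs = 0, loop_fraction = 0.3,
                         weighted = FALSE, seed = 4)
  tf_tf <- decompose_trn(simulate_trn(spec)$network)$tf_tf
  lb1 <- break_loops(tf_tf, seed = 1)
  lb2 <- break_loops(tf_tf, seed = 2)
  expect_equal(nrow(lb1$dag$arcs), 9)
  expect_equal(nrow(lb2$dag$arcs), 9)
  expect_true(is_acyclic(lb1$dag))
  expect_true(is_acyclic(lb2$dag))
  # same seed reproduces the same skeleton
  expect_identical(break_loops(tf_tf, seed = 1)$dag$arcs, lb1$dag$arcs)
})

test_that("mixed weighted/unweighted arcs are rejected", {
  expect_error(
    regnet(data.frame(from = c("A", "B"), to = c("B", "C"), weight = c(1, NA)),
           tf_ids = c("A", "B", "C")),
    "all arcs or on none")
})

test_that("TBN assembly is the disjoint union of skeleton and TF-gene arcs", {
  net <- toy_net()
  parts <- decompose_trn(net)
  lb <- break_loops(parts$tf_tf)
  tbn <- assemble_tbn(lb$dag, parts$tf_gene)
  expect_equal(nrow(tbn$arcs), 3)

  # empty TF-gene part: assembly is the skeleton itself
  empty_tg <- regnet(data.frame(from = character(0), to = character(0),
                                weight = numeric(0)),
                     tf_ids = net$tf_ids, gene_ids = character(0))
  expect_equal(assemble_tbn(lb$dag, empty_tg)$arcs, lb$dag$arcs)

  # re-assembly of a random decomposition equals the original minus whitelist
  spec <- synthetic_spec(n_tf = 8, n_gene = 12, tf_tf_arcs = 22,
                         tf_gene_arcs = 20, seed = 6)
  sim <- simulate_trn(spec)
  p <- decompose_trn(sim$network)
  lb2 <- break_loops(p$tf_tf, seed = 6)
  tbn2 <- assemble_tbn(lb2$dag, p$tf_gene)
  expect_setequal(
    tbnfuse:::arc_key(tbn2$arcs),
    setdiff(tbnfuse:::arc_key(sim$network$arcs), tbnfuse:::arc_key(lb2$whitelist)))

  # arc collision means the inputs were not a valid decomposition
  overlap <- regnet(data.frame(from = "A", to = "B", weight = 1),
                    tf_ids = c("A", "B"), gene_ids = character(0))
  expect_error(assemble_tbn(overlap, overlap), "not a valid decomposition")
})

test_that("expression intersection drops unobserved nodes and their arcs", {
  net <- regnet(data.frame(from = c("A", "A", "B", "B"),
                           to = c("B", "G1", "G1", "G2")),
                tf_ids = c("A", "B"))
  wl <- tbnfuse:::new_whitelist(data.frame(from = "B", to = "A",
                                           weight = NA_real_))
  expr <- toy_expr(c("A", "B", "G1"))
  ix <- intersect_with_expression(net, wl, expr)
  expect_false("G2" %in% c(ix$tbn$tf_ids, ix$tbn$gene_ids))
  expect_equal(ix$dropped, "G2")
  expect_true(all(ix$tbn$arcs$to %in% rownames(expr)))

  # full coverage: identity
  expr_all <- toy_expr(c("A", "B", "G1", "G2"))
  ix2 <- intersect_with_expression(net, wl, expr_all)
  expect_equal(ix2$tbn$arcs, net$arcs)
  expect_length(ix2$dropped, 0)

  # every surviving arc has both endpoints observed (random fixture)
  spec <- synthetic_spec(n_tf = 8, n_gene = 15, tf_tf_arcs = 20,
                         tf_gene_arcs = 25, seed = 8)
  sim <- simulate_trn(spec)
  nodes <- c(sim$network$tf_ids, sim$network$gene_ids)
  expr3 <- toy_expr(sample(nodes, length(nodes) - 5), seed = 8)
  p <- decompose_trn(sim$network)
  lb <- break_loops(p$tf_tf, seed = 8)
  tbn <- assemble_tbn(lb$dag, p$tf_gene)
  ix3 <- suppressMessages(intersect_with_expression(tbn, lb$whitelist, expr3))
  expect_true(all(ix3$tbn$arcs$from %in% rownames(expr3)))
  expect_true(all(ix3$tbn$arcs$to %in% rownames(expr3)))
  expect_true(all(ix3$whitelist$from %in% rownames(expr3)))
  expect_true(all(ix3$whitelist$to %in% rownames(expr3)))
})

test_that("arc probabilities equal |Pearson r| normalized over the whitelist", {
  expr <- rbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4), C = c(3, 2, 1, 0),
                D = c(1, 3, 2, 5), E = c(2, 2, 3, 1))
  colnames(expr) <- paste0("s", 1:4)

  wl1 <- tbnfuse:::new_whitelist(data.frame(from = "A", to = "B",
                                            weight = NA_real_))
  expect_equal(compute_arc_probabilities(wl1, expr)$r, 1.0)

  wl2 <- tbnfuse:::new_whitelist(data.frame(from = "A", to = "C",
                                            weight = NA_real_))
  out2 <- compute_arc_probabilities(wl2, expr)
  expect_equal(out2$r, -1.0)
  expect_equal(out2$prob, 1.0)   # |r| normalized over a singleton

  # five arcs against the textbook covariance-formula oracle
  wl5 <- tbnfuse:::new_whitelist(
    data.frame(from = c("A", "A", "C", "D", "E"),
               to = c("C", "D", "D", "E", "A"), weight = NA_real_))
  out5 <- compute_arc_probabilities(wl5, expr)
  r_or <- mapply(function(f, t) oracle_pearson(expr[f, ], expr[t, ]),
                 wl5$from, wl5$to)
  expect_equal(out5$r, unname(r_or), tolerance = 1e-12)
  expect_equal(out5$prob, unname(abs(r_or) / sum(abs(r_or))), tolerance = 1e-12)
  expect_equal(sum(out5$prob), 1, tolerance = 1e-9)

  flat <- rbind(expr, Z = rep(1, 4))
  wlz <- tbnfuse:::new_whitelist(data.frame(from = "Z", to = "A",
                                            weight = NA_real_))
  expect_error(compute_arc_probabilities(wlz, flat), "zero-variance.*Z")
})
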