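test_that("simulated networks meet their arc budgets and connectivity", {
  spec0 <- synthetic_spec(n_tf = 10, n_gene = 5, tf_tf_arcs = 20,
                          tf_gene_arcs = 10, loop_fraction = 0, seed = 2)
  sim0 <- simulate_trn(spec0)
  expect_true(is_acyclic(sim0$network))   # no loop arcs: fully acyclic

  spec <- synthetic_spec(n_tf = 15, n_gene = 10, tf_tf_arcs = 60,
                         tf_gene_arcs = 25, loop_fraction = 0.3, seed = 3)
  sim <- simulate_trn(spec)
  tt <- sim$network$arcs[sim$network$arcs$to %in% sim$network$tf_ids, ]
  expect_equal(nrow(tt), 60)
  expect_equal(nrow(sim$network$arcs), 60 + 25)
  expect_true(is_weakly_connected(as_igraph(tt, nodes = sim$network$tf_ids)))
  expect_false(is_acyclic(as_igraph(tt, nodes = sim$network$tf_ids)))

  # the generative core is a subgraph of the observed network
  expect_true(all(tbnfuse:::arc_key(sim$generative_arcs) %in%
                    tbnfuse:::arc_key(sim$network$arcs)))

  # every loop arc closes a directed cycle with the core: its reverse
  # endpoint pair is connected by a core path
  core_g <- as_igraph(sim$core_tf_tf, nodes = sim$network$tf_ids)
  loop_arcs <- tt[!(tbnfuse:::arc_key(tt) %in% tbnfuse:::arc_key(sim$core_tf_tf)), ]
  expect_gt(nrow(loop_arcs), 0)
  for (i in seq_len(nrow(loop_arcs))) {
    d <- igraph::distances(core_g, v = loop_arcs$to[i], to = loop_arcs$from[i],
                           mode = "out")
    expect_true(is.finite(d[1, 1]))
  }
  # a 2-cycle is guaranteed when loops are requested
  expect_true(any(tbnfuse:::arc_key(loop_arcs) %in%
                    paste(sim$core_tf_tf$to, sim$core_tf_tf$from, sep = "\r")))

  expect_error(synthetic_spec(n_tf = 10, n_gene = 0, tf_tf_arcs = 5,
                              tf_gene_arcs = 0),
               "tf_tf_arcs")
})

test_that("expression generation follows the linear-Gaussian model exactly at sigma 0", {
  # all-zero coefficients, no noise: constant at the intercept
  spec <- synthetic_spec(n_tf = 4, n_gene = 0, tf_tf_arcs = 3, tf_gene_arcs = 0,
                         loop_fraction = 0, noise_sigma = 0, n_samples = 5,
                         coeff_range = c(1e-12, 2e-12), seed = 4)
  sim <- simulate_trn(spec)
  ex <- simulate_expression(sim$generative_arcs, sim$network$tf_ids, spec)
  for (nd in sim$network$tf_ids)
    expect_equal(unname(ex$expr[nd, ]), rep(ex$intercepts[[nd]], 5),
                 tolerance = 1e-9)

  # single arc A -> B with fixed coefficient 2 and sigma 0: exact linearity
  spec1 <- synthetic_spec(n_tf = 2, n_gene = 0, tf_tf_arcs = 1, tf_gene_arcs = 0,
                          loop_fraction = 0, noise_sigma = 0, n_samples = 6,
                          seed = 5)
  arcs <- data.frame(from = "A", to = "B")
  ex1 <- simulate_expression(arcs, c("A", "B"), spec1,
                             coefficients = data.frame(from = "A", to = "B",
                                                       coef = 2))
  expect_equal(unname(ex1$expr["B", ]),
               unname(2 * ex1$expr["A", ] + ex1$intercepts[["B"]]),
               tolerance = 1e-12)

  # cyclic generative input is refused
  expect_error(simulate_expression(data.frame(from = c("A", "B"),
                                              to = c("B", "A")),
                                   c("A", "B"), spec1),
               "acyclic")
})

test_that("a two-node chain matches the closed-form covariance", {
  spec <- synthetic_spec(n_tf = 2, n_gene = 0, tf_tf_arcs = 1, tf_gene_arcs = 0,
                         loop_fraction = 0, noise_sigma = 1, n_samples = 10000,
                         seed = 6)
  ex <- simulate_expression(data.frame(from = "A", to = "B"), c("A", "B"), spec)
  a <- ex$coefficients$coef[1]
  expect_equal(cov(ex$expr["A", ], ex$expr["B", ]), a * var(ex$expr["A", ]),
               tolerance = 0.05)
})

test_that("refitting local models recovers the generative coefficients", {
  # scaled-down recovery check; the acceptance suite runs the 20-seed version
  hits <- 0L; total <- 0L
  for (seed in 1:4) {
    spec <- synthetic_spec(n_tf = 8, n_gene = 8, tf_tf_arcs = 12,
                           tf_gene_arcs = 16, loop_fraction = 0,
                           n_samples = 500, seed = seed)
    sim <- simulate_trn(spec)
    nodes <- c(sim$network$tf_ids, sim$network$gene_ids)
    ex <- simulate_expression(sim$generative_arcs, nodes, spec)
    parents <- split(ex$coefficients$from, ex$coefficients$to)
    for (nd in names(parents)) {
      fit <- fit_local(nd, parents[[nd]], ex$expr)
      X <- cbind(1, t(ex$expr[parents[[nd]], , drop = FALSE]))
      se <- sqrt(diag(solve(t(X) %*% X)) * fit$rss / (fit$n - fit$k))[-1]
      truth <- ex$coefficients$coef[ex$coefficients$to == nd][
        match(parents[[nd]], ex$coefficients$from[ex$coefficients$to == nd])]
      hits <- hits + sum(abs(fit$a - truth) <= 3 * se)
      total <- total + length(truth)
    }
  }
  expect_gte(hits / total, 0.97)
})

test_that("robustness fixtures are pure functions of spec and seed", {
  spec <- synthetic_spec(n_tf = 10, n_gene = 20, tf_tf_arcs = 30,
                         tf_gene_arcs = 40, seed = 7)
  f1 <- make_robustness_fixture(spec, 0.2)
  f2 <- make_robustness_fixture(spec, 0.2)
  expect_identical(f1$corrupted$arcs, f2$corrupted$arcs)
  expect_identical(f1$expr, f2$expr)
  expect_identical(f1$injected, f2$injected)

  # fp 0: corrupted equals gold
  f0 <- make_robustness_fixture(spec, 0)
  expect_identical(f0$corrupted$arcs, f0$gold$arcs)

  # yeast-scale arc bookkeeping: 33 TFs, 437 genes, 3299 arcs, 249 TF-TF
  spec_y <- synthetic_spec(n_tf = 33, n_gene = 437, tf_tf_arcs = 249,
                           tf_gene_arcs = 3050, loop_fraction = 0.3,
                           n_samples = 3, seed = 8)
  sim_y <- simulate_trn(spec_y)
  expect_equal(nrow(sim_y$network$arcs), 3299)
  tt <- sim_y$network$arcs[sim_y$network$arcs$to %in% sim_y$network$tf_ids, ]
  expect_equal(nrow(tt), 249)
  expect_length(sim_y$network$gene_ids, 437)
})

test_that("the planted-arc scenario wires the planted signal into the whitelist", {
  sc <- simulate_planted_arc(seed = 17)
  wl_keys <- tbnfuse:::arc_key(sc$init$whitelist)
  expect_true(paste(sc$planted[["from"]], sc$planted[["to"]], sep = "\r") %in% wl_keys)
  expect_equal(nrow(sc$init$whitelist), 11)   # planted + 10 decoys
  expect_equal(sum(sc$init$whitelist$prob), 1, tolerance = 1e-9)
  # the planted coefficient really is in the generative truth
  expect_true(any(sc$truth$from == sc$planted[["from"]] &
                    sc$truth$to == sc$planted[["to"]] &
                    sc$truth$coef == 1.5))
})
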