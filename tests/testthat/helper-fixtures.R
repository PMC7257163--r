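# Small reusable fixtures, all built in code at test time.

write_edges <- function(lines) {
  path <- tempfile("edges", fileext = ".tsv")
  writeLines(lines, path)
  path
}

write_tfs <- function(tfs) {
  path <- tempfile("tfs", fileext = ".txt")
  writeLines(tfs, path)
  path
}

# three-arc toy network: A -> B (TF-TF), A -> G1, B -> G1
toy_net <- function() {
  regnet(data.frame(from = c("A", "A", "B"), to = c("B", "G1", "G1"),
                    weight = c(2, 1, 3)),
         tf_ids = c("A", "B"))
}

# minimal expression matrix for given nodes: deterministic, full rank
toy_expr <- function(nodes, n_samples = 6, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(length(nodes) * n_samples), nrow = length(nodes),
              dimnames = list(nodes, sprintf("S%d", seq_len(n_samples))))
  m
}

# a hand-built learned_model for consensus tests
fake_model <- function(tf_tf, bic, seed = 0L,
                       tf_gene = data.frame(from = character(0), to = character(0))) {
  structure(list(tf_tf_arcs = tf_tf, tf_gene_arcs = tf_gene,
                 bic_global = bic, moves = tbnfuse:::empty_moves(),
                 seed = seed, n = 10L),
            class = "learned_model")
}

# small end-to-end fixture shared by several tests
small_pipeline_fixture <- function(seed = 3, fp = 0.2, n_samples = 100) {
  spec <- synthetic_spec(n_tf = 10, n_gene = 30, tf_tf_arcs = 30,
                         tf_gene_arcs = 60, loop_fraction = 0.3,
                         n_samples = n_samples, seed = seed)
  make_robustness_fixture(spec, fp)
}
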