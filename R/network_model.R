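#' @importFrom stats cor quantile rnorm runif setNames
#' @importFrom utils read.delim write.table head
NULL

# ---------------------------------------------------------------------------
# Regulatory network: a directed TF -> TF / TF -> gene graph with optional
# nonnegative binding-score weights. Arcs are kept as a data.frame in first-
# appearance order so that all downstream procedures are deterministic.
# ---------------------------------------------------------------------------

#' Construct a regulatory network
#'
#' A `regnet` is a directed graph over two disjoint node classes: transcription
#' factors (TFs), which may have outgoing arcs, and target genes, which may
#' not. Arcs optionally carry a nonnegative binding-score weight; either all
#' arcs are weighted or none are.
#'
#' @param arcs data.frame with columns `from`, `to` and optionally `weight`.
#' @param tf_ids character vector of regulator identifiers. If `NULL`, every
#'   node appearing as an arc source is taken to be a TF.
#' @param gene_ids character vector of target-only identifiers. If `NULL`,
#'   inferred as all arc endpoints not in `tf_ids`.
#' @return An object of class `regnet` with fields `tf_ids`, `gene_ids`,
#'   `arcs` (data.frame `from`, `to`, `weight`) and logical `weighted`.
#' @examples
#' arcs <- data.frame(from = c("A", "A"), to = c("B", "G1"), weight = c(2, 1))
#' net <- regnet(arcs, tf_ids = c("A", "B"))
#' net$gene_ids
#' @export
regnet <- function(arcs, tf_ids = NULL, gene_ids = NULL) {
  stopifnot(is.data.frame(arcs), all(c("from", "to") %in% names(arcs)))
  arcs$from <- as.character(arcs$from)
  arcs$to <- as.character(arcs$to)
  if (!"weight" %in% names(arcs)) arcs$weight <- NA_real_
  arcs$weight <- as.numeric(arcs$weight)
  arcs <- arcs[, c("from", "to", "weight")]
  rownames(arcs) <- NULL
  if (is.null(tf_ids)) tf_ids <- unique(arcs$from)
  tf_ids <- as.character(tf_ids)
  endpoints <- unique(c(arcs$from, arcs$to))
  if (is.null(gene_ids)) gene_ids <- setdiff(endpoints, tf_ids)
  gene_ids <- as.character(gene_ids)
  net <- structure(
    list(tf_ids = tf_ids, gene_ids = gene_ids, arcs = arcs,
         weighted = !anyNA(arcs$weight)),
    class = "regnet"
  )
  validate_regnet(net)
  net
}

#' Validate a regulatory network
#'
#' Checks the structural invariants of a [regnet()]: TF/gene disjointness,
#' arc endpoints drawn from the declared node sets, arcs originating only from
#' TFs, no self-loops, no duplicate arcs, and all-or-none nonnegative weights.
#'
#' @param net a `regnet` object.
#' @return `net`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_regnet <- function(net) {
  arcs <- net$arcs
  if (anyDuplicated(net$tf_ids)) stop("duplicate TF identifiers")
  overlap <- intersect(net$tf_ids, net$gene_ids)
  if (length(overlap) > 0)
    stop("node(s) declared both TF and gene: ", paste(head(overlap, 5), collapse = ", "))
  bad_src <- setdiff(arcs$from, net$tf_ids)
  if (length(bad_src) > 0)
    stop("arc source(s) not declared as TF: ", paste(head(bad_src, 5), collapse = ", "))
  nodes <- c(net$tf_ids, net$gene_ids)
  bad_tgt <- setdiff(arcs$to, nodes)
  if (length(bad_tgt) > 0)
    stop("arc target(s) not in node set: ", paste(head(bad_tgt, 5), collapse = ", "))
  if (any(arcs$from == arcs$to))
    stop("self-loop(s) not allowed: ",
         paste(head(arcs$from[arcs$from == arcs$to], 5), collapse = ", "))
  key <- paste(arcs$from, arcs$to, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate arc(s): ",
         gsub("\r", " -> ", paste(head(key[duplicated(key)], 5), collapse = ", ")))
  na_w <- is.na(arcs$weight)
  if (any(na_w) && !all(na_w))
    stop("weights must be present on all arcs or on none")
  if (!any(na_w) && any(arcs$weight < 0)) stop("negative arc weight(s)")
  invisible(net)
}

#' @export
print.regnet <- function(x, ...) {
  cat(sprintf("Regulatory network: %d TFs, %d genes, %d arcs (%s)\n",
              length(x$tf_ids), length(x$gene_ids), nrow(x$arcs),
              if (x$weighted) "weighted" else "unweighted"))
  invisible(x)
}

#' Number of arcs in a network or arc table
#' @param x a `regnet` or an arc data.frame.
#' @return integer arc count.
#' @export
n_arcs <- function(x) {
  if (inherits(x, "regnet")) nrow(x$arcs) else nrow(x)
}

arc_key <- function(arcs) paste(arcs$from, arcs$to, sep = "\r")

as_arc_df <- function(x) {
  if (inherits(x, "regnet")) x$arcs
  else if (is.data.frame(x)) x
  else stop("expected a regnet or an arc data.frame")
}

#' Convert a network to an igraph object
#'
#' @param x a `regnet` or an arc data.frame.
#' @param nodes optional character vector of vertex names (defaults to the
#'   network's node set, or to arc endpoints for a bare data.frame).
#' @return a directed `igraph` graph.
#' @export
as_igraph <- function(x, nodes = NULL) {
  arcs <- as_arc_df(x)
  if (is.null(nodes)) {
    nodes <- if (inherits(x, "regnet")) c(x$tf_ids, x$gene_ids)
             else unique(c(arcs$from, arcs$to))
  }
  igraph::graph_from_data_frame(arcs[, c("from", "to")], directed = TRUE,
                                vertices = data.frame(name = nodes))
}

# ---------------------------------------------------------------------------
# Structural predicates
# ---------------------------------------------------------------------------

#' Test whether a directed graph is acyclic
#' @param x a `regnet`, arc data.frame, or igraph object.
#' @return logical scalar.
#' @export
is_acyclic <- function(x) {
  g <- if (inherits(x, "igraph")) x else as_igraph(x)
  if (igraph::vcount(g) == 0) stop("empty graph")
  igraph::is_dag(g)
}

#' Test whether a directed graph is weakly connected
#'
#' Direction-blind connectivity: the graph is weakly connected when its
#' undirected skeleton is connected.
#'
#' @inheritParams is_acyclic
#' @return logical scalar.
#' @export
is_weakly_connected <- function(x) {
  g <- if (inherits(x, "igraph")) x else as_igraph(x)
  if (igraph::vcount(g) == 0) stop("empty graph")
  igraph::is_connected(g, mode = "weak")
}

# ---------------------------------------------------------------------------
# File input
# ---------------------------------------------------------------------------

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty file: ", path)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a regulatory network from a delimiter-separated edge list
#'
#' The file must have columns source, target and optionally weight (tab- or
#' comma-separated, auto-detected; a header row is accepted and detected by a
#' non-numeric third column named like "weight" or by the literal header
#' "source"). Duplicate (source, target) rows are collapsed keeping the
#' maximum weight; first-appearance row order is preserved.
#'
#' @param path path to the edge-list file.
#' @param tf_list optional path to a plain-text file naming the regulators,
#'   one identifier per line. When absent, every node that appears as a
#'   source is treated as a TF.
#' @return a validated [regnet()].
#' @export
read_edge_list <- function(path, tf_list = NULL) {
  delim <- detect_delim(path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty file: ", path)
  fields <- strsplit(lines, delim, fixed = TRUE)
  # header detection: explicit "source"/"from" first token
  first_tok <- trimws(tolower(fields[[1]][1]))
  start <- if (first_tok %in% c("source", "from")) 2L else 1L
  n_rows <- length(fields) - start + 1L
  if (n_rows < 1) stop("edge list has no data rows")
  from <- to <- character(n_rows)
  weight <- rep(NA_real_, n_rows)
  for (i in seq_len(n_rows)) {
    f <- trimws(fields[[start + i - 1L]])
    line_no <- start + i - 1L
    if (length(f) < 2 || !nzchar(f[1]) || !nzchar(f[2]))
      stop(sprintf("malformed row at line %d of %s", line_no, path))
    from[i] <- f[1]; to[i] <- f[2]
    if (length(f) >= 3 && nzchar(f[3])) {
      w <- suppressWarnings(as.numeric(f[3]))
      if (is.na(w))
        stop(sprintf("malformed weight at line %d of %s", line_no, path))
      if (w < 0)
        stop(sprintf("negative weight at line %d of %s", line_no, path))
      weight[i] <- w
    }
  }
  arcs <- data.frame(from = from, to = to, weight = weight,
                     stringsAsFactors = FALSE)
  # collapse duplicates keeping the maximum weight, first-appearance order
  key <- arc_key(arcs)
  if (anyDuplicated(key)) {
    mx <- tapply(arcs$weight, key, function(w) if (all(is.na(w))) NA_real_ else max(w, na.rm = TRUE))
    keep <- !duplicated(key)
    arcs <- arcs[keep, , drop = FALSE]
    arcs$weight <- as.numeric(mx[arc_key(arcs)])
    rownames(arcs) <- NULL
  }
  tfs <- if (!is.null(tf_list)) {
    v <- trimws(readLines(tf_list))
    v[nzchar(v)]
  } else NULL
  regnet(arcs, tf_ids = tfs)
}

#' Read an expression matrix from delimiter-separated text
#'
#' Expects a header row (`id` followed by sample identifiers) and one row per
#' node: identifier then numeric values. The matrix must be complete (no
#' missing cells) with at least 3 samples.
#'
#' @param path path to the file (tab- or comma-separated, auto-detected).
#' @return a numeric matrix, nodes in rows (rownames) and samples in columns
#'   (colnames), row order as in the file.
#' @export
read_expression <- function(path) {
  delim <- detect_delim(path)
  tab <- read.delim(path, sep = delim, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs an id column plus samples")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate node ID(s): ",
         paste(head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  validate_expression(vals)
  vals
}

#' Validate an expression matrix
#'
#' @param expr numeric matrix with unique rownames (node IDs) and colnames
#'   (sample IDs); all values finite; at least 3 samples.
#' @return `expr`, invisibly, if valid.
#' @export
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) stop("expression must be a numeric matrix")
  if (is.null(rownames(expr))) stop("expression matrix must have node rownames")
  if (anyDuplicated(rownames(expr))) stop("duplicate node ID(s) in expression matrix")
  if (ncol(expr) < 3) stop("n_samples >= 3 required, got ", ncol(expr))
  bad <- which(!is.finite(expr), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    r <- rownames(expr)[bad[1, 1]]
    s <- if (!is.null(colnames(expr))) colnames(expr)[bad[1, 2]] else bad[1, 2]
    stop(sprintf("missing value at (%s, %s)", r, s))
  }
  invisible(expr)
}

# ---------------------------------------------------------------------------
# File output and round-trippable serialization
# ---------------------------------------------------------------------------

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

#' Write a network to disk
#'
#' Supported formats: `tsv` (source, target, weight columns; weight column
#' holds 17-significant-digit decimals and is empty for unweighted networks),
#' `sif` (Cytoscape simple interaction format, relation `regulates`), and
#' `graphml` (with a `weight` arc attribute when weighted). Consensus
#' networks ([build_consensus()]) written as `tsv` carry the columns
#' `source, target, frequency, weight, selected`.
#'
#' @param net a `regnet`, a `consensus_network`, or an arc data.frame.
#' @param path output path.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (inherits(net, "consensus_network")) {
    if (format != "tsv")
      net <- regnet(net$candidate_edges[net$candidate_edges$selected,
                                        c("from", "to", "weight")],
                    tf_ids = unique(c(net$candidate_edges$from,
                                      net$candidate_edges$to)))
    else {
      ce <- net$candidate_edges
      out <- data.frame(source = ce$from, target = ce$to,
                        frequency = ce$frequency, weight = fmt_num(ce$weight),
                        selected = ce$selected)
      write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
      return(invisible(path))
    }
  }
  arcs <- as_arc_df(net)
  if (format == "tsv") {
    out <- data.frame(source = arcs$from, target = arcs$to,
                      weight = fmt_num(arcs$weight))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    writeLines(paste(arcs$from, "regulates", arcs$to, sep = "\t"), path)
  } else {
    g <- as_igraph(net)
    if (!anyNA(arcs$weight)) igraph::E(g)$weight <- arcs$weight
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Serialize an ensemble of learned models to structured text
#'
#' Writes a JSON document (schema version 1) holding, for each model, the
#' final TF-TF arcs, the fixed TF-to-gene arcs, the global BIC, the accepted
#' move trace and the run seed. Floating-point values survive a round trip
#' exactly (17 significant digits).
#'
#' @param models a list of `learned_model` objects (see [learn_structure()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(models, path) {
  if (length(models) == 0) stop("empty ensemble")
  if (inherits(models, "learned_model")) models <- list(models)
  payload <- list(
    schema_version = 1L,
    n_models = length(models),
    models = lapply(models, function(m) {
      list(seed = m$seed,
           bic_global = m$bic_global,
           n_samples = m$n,
           tf_tf_arcs = m$tf_tf_arcs[, c("from", "to")],
           tf_gene_arcs = m$tf_gene_arcs[, c("from", "to")],
           moves = m$moves)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' Read an ensemble of learned models
#'
#' @param path path to a file written by [write_ensemble()].
#' @return a list of `learned_model` objects.
#' @export
read_ensemble <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = TRUE)
  if (is.null(payload$schema_version) || payload$schema_version != 1L)
    stop("unknown ensemble schema version")
  mods <- payload$models
  rebuild_df <- function(x, cols) {
    if (is.null(x) || length(x) == 0 || (is.data.frame(x) && nrow(x) == 0)) {
      out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
      return(out)
    }
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  # jsonlite::read_json simplification gives either a data.frame of lists
  # (column-wise models) or a list of records; normalize both.
  get_model <- function(i) {
    if (is.data.frame(mods)) {
      list(seed = mods$seed[i], bic_global = mods$bic_global[i],
           n_samples = mods$n_samples[i],
           tf_tf_arcs = mods$tf_tf_arcs[[i]],
           tf_gene_arcs = mods$tf_gene_arcs[[i]],
           moves = mods$moves[[i]])
    } else mods[[i]]
  }
  n <- if (is.data.frame(mods)) nrow(mods) else length(mods)
  lapply(seq_len(n), function(i) {
    m <- get_model(i)
    structure(
      list(tf_tf_arcs = rebuild_df(m$tf_tf_arcs, c("from", "to")),
           tf_gene_arcs = rebuild_df(m$tf_gene_arcs, c("from", "to")),
           bic_global = as.numeric(m$bic_global),
           n = as.integer(m$n_samples),
           moves = {
             mv <- m$moves
             if (is.null(mv) || length(mv) == 0 ||
                 (is.data.frame(mv) && nrow(mv) == 0)) empty_moves()
             else as.data.frame(mv, stringsAsFactors = FALSE)
           },
           seed = as.integer(m$seed)),
      class = "learned_model")
  })
}

empty_moves <- function() {
  data.frame(from = character(0), to = character(0),
             move = character(0), delta_bic = numeric(0),
             iteration = integer(0), stringsAsFactors = FALSE)
}

#' Read a network written as TSV
#'
#' Inverse of `write_network(..., format = "tsv")` for plain networks.
#'
#' @param path path to the TSV file.
#' @param tf_list optional TF list file, as in [read_edge_list()].
#' @return a [regnet()].
#' @export
read_network <- function(path, tf_list = NULL) read_edge_list(path, tf_list)
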