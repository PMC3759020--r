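#' Planar Maximally Filtered Graph of a correlation matrix
#'
#' Filters the complete weighted word-correlation network down to its PMFG:
#' candidate edges are ranked by signed correlation, descending (ties broken
#' lexicographically by word pair, which makes the construction fully
#' deterministic), and inserted one at a time whenever the growing graph
#' stays planar, stopping once the maximal planar edge count 3(N - 2) is
#' reached. The result is binarized — every retained edge gets weight 1 —
#' and is always planar, connected and simple.
#'
#' @param cm a [correlation_matrix()] (or a plain symmetric weight matrix
#'   with word dimnames) on at least 3 words.
#' @param network_kind optional provenance tag, e.g. `"SMCN"` or `"WMCN"`.
#' @param group optional group label; defaults to the matrix's own label.
#' @return an [igraph::igraph] semantic network with vertex `name`s equal to
#'   the vocabulary, all edge weights 1, and graph attributes
#'   `network_kind`, `group_label` and `source_digest`.
#' @export
build_pmfg <- function(cm, network_kind = NA_character_, group = NULL) {
  if (inherits(cm, "correlation_matrix")) {
    W <- cm$C
    if (is.null(group)) group <- cm$group
  } else if (is.matrix(cm) && is.numeric(cm)) {
    W <- cm
    if (is.null(group)) group <- NA_character_
  } else {
    stop_fl("cm must be a correlation_matrix or a numeric matrix", "format_error")
  }
  n <- nrow(W)
  if (n < 3L) stop_fl("PMFG is only defined for 3 or more nodes", "size_error")
  off <- W[upper.tri(W)]
  if (any(!is.finite(off)) || any(!is.finite(W[lower.tri(W)]))) {
    stop_fl("off-diagonal weights must be finite", "input_error")
  }
  if (max(abs(W - t(W))) > 1e-12) stop_fl("weight matrix must be symmetric", "input_error")
  vocab <- colnames(W)
  if (is.null(vocab)) vocab <- sprintf("w%03d", seq_len(n))

  edges <- .pmfg_edges(W) + 1L
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- vocab
  g <- igraph::add_edges(g, as.vector(t(edges)))
  igraph::E(g)$weight <- 1
  g <- igraph::set_graph_attr(g, "network_kind", as.character(network_kind))
  g <- igraph::set_graph_attr(g, "group_label", as.character(group))
  g <- igraph::set_graph_attr(g, "source_digest", weight_digest(W))
  g
}

# cheap provenance checksum of the source weight matrix
weight_digest <- function(W) {
  b <- serialize(round(unname(W), 12), NULL)
  sprintf("%dx%d-%08x", nrow(W), ncol(W),
          sum(as.integer(b)) %% .Machine$integer.max)
}

edge_matrix <- function(g) {
  e <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(e) <- "integer"
  e - 1L
}

#' Test whether a graph is planar
#'
#' Left-right (de Fraysseix–Rosenstiehl) planarity criterion, linear in the
#' size of the graph.
#'
#' @param g an igraph graph, or a 2-column edge matrix (with `n` given).
#' @param n node count when `g` is an edge matrix.
#' @return `TRUE` iff the graph admits a planar embedding.
#' @export
is_planar <- function(g, n = NULL) {
  if (inherits(g, "igraph")) {
    return(.lr_is_planar(igraph::vcount(g), edge_matrix(g)))
  }
  if (is.matrix(g) && ncol(g) == 2L) {
    if (is.null(n)) n <- max(g) + 1L
    e <- g
    storage.mode(e) <- "integer"
    return(.lr_is_planar(as.integer(n), e))
  }
  stop_fl("g must be an igraph graph or a 2-column edge matrix", "format_error")
}

#' Test whether adding one edge keeps a graph planar
#'
#' @param g an igraph graph (planar or not).
#' @param edge length-2 vector: vertex names or indices of the candidate
#'   edge, which must not already be present.
#' @return `TRUE` iff `g` plus the edge admits a planar embedding.
#' @export
is_planar_with <- function(g, edge) {
  stopifnot(inherits(g, "igraph"), length(edge) == 2L)
  idx <- if (is.character(edge)) match(edge, igraph::V(g)$name) else as.integer(edge)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > igraph::vcount(g))) {
    stop_fl("unknown vertex in candidate edge", "lookup_error")
  }
  if (idx[1L] == idx[2L]) stop_fl("self-loops are not allowed", "input_error")
  if (igraph::are_adjacent(g, idx[1L], idx[2L])) {
    stop_fl("candidate edge already present", "input_error")
  }
  e <- rbind(edge_matrix(g), sort(idx) - 1L)
  .lr_is_planar(igraph::vcount(g), e)
}

#' Export a semantic network to GraphML
#'
#' Node attributes carry the word labels; graph attributes carry provenance
#' (`network_kind`, `group_label`, `source_digest`). Suitable for external
#' viewers such as Cytoscape.
#'
#' @param g an igraph semantic network.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a semantic network as a two-column edge-list CSV
#'
#' @param g an igraph semantic network with named vertices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  e <- igraph::as_edgelist(g, names = TRUE)
  write.csv(data.frame(from = e[, 1L], to = e[, 2L], stringsAsFactors = FALSE),
            path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
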