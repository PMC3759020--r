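#' Average shortest path length (ASPL)
#'
#' Mean of the shortest-path hop counts over all unordered pairs of distinct
#' nodes of a connected unweighted graph.
#'
#' @param g a connected igraph graph.
#' @return ASPL in hops.
#' @export
aspl <- function(g) {
  check_connected(g)
  igraph::mean_distance(g, directed = FALSE, weights = NA)
}

#' Network diameter
#'
#' Maximum shortest-path hop count over all node pairs of a connected
#' unweighted graph.
#'
#' @param g a connected igraph graph.
#' @return diameter in hops.
#' @export
net_diameter <- function(g) {
  check_connected(g)
  igraph::diameter(g, directed = FALSE, unconnected = FALSE, weights = NA)
}

check_connected <- function(g) {
  stopifnot(inherits(g, "igraph"))
  if (igraph::vcount(g) < 2L) stop_fl("need at least 2 nodes", "size_error")
  if (!igraph::is_connected(g)) {
    stop_fl("graph is disconnected; path metrics are undefined (consider the largest-component policy)",
            "disconnected_error")
  }
  invisible(g)
}

# largest connected component, for the configurable fallback policy
largest_component <- function(g) {
  comp <- igraph::components(g)
  igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
}

#' Mean local clustering coefficient
#'
#' Watts–Strogatz clustering: per node, the fraction of its neighbour pairs
#' that are themselves connected, averaged over nodes. Nodes of degree < 2
#' have no neighbour pairs and contribute 0.
#'
#' @param g an igraph graph.
#' @return clustering coefficient in \[0, 1\].
#' @export
clustering_coef <- function(g) {
  stopifnot(inherits(g, "igraph"))
  if (igraph::vcount(g) == 0L) stop_fl("empty graph", "size_error")
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  mean(cc)
}

#' Mean node degree
#'
#' @param g an igraph graph.
#' @return 2E/N.
#' @export
mean_degree <- function(g) {
  stopifnot(inherits(g, "igraph"))
  2 * igraph::ecount(g) / igraph::vcount(g)
}

#' Small-world-ness index
#'
#' S = (CC / CC_rand) / (L / L_rand), the ratio of normalized clustering to
#' normalized path length against a matched random reference; S > 1
#' classifies a network as small-world.
#'
#' @param cc,l observed clustering coefficient and ASPL.
#' @param cc_rand,l_rand reference values from a size- and density-matched
#'   Erdos-Renyi network.
#' @return the scalar S.
#' @export
small_worldness <- function(cc, cc_rand, l, l_rand) {
  vals <- c(cc = cc, cc_rand = cc_rand, l = l, l_rand = l_rand)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_fl("all inputs to small_worldness must be positive and finite", "input_error")
  }
  (cc / cc_rand) / (l / l_rand)
}

#' Small-world summary statistics of a network
#'
#' Computes the scalar summary block used to characterize each semantic
#' network: node count N, ASPL L, diameter D, clustering coefficient CC,
#' mean degree, plus the Erdos-Renyi reference values CC_rand and L_rand
#' (reference matched in node count and edge probability) and the
#' small-world-ness S. The reference defaults to the mean over a seeded
#' batch of ER realizations, which is more stable than a single draw; set
#' `reference = "single"` for a one-realization reference.
#'
#' @param g a connected igraph network.
#' @param reference `"mean"` (default) or `"single"`.
#' @param realizations number of ER reference draws when `reference = "mean"`.
#' @param seed RNG seed for the reference draws.
#' @param disconnection policy for disconnected ER draws, see [simulate_er()].
#' @return object of class `network_metrics`: named list with fields `N`,
#'   `L`, `D`, `CC`, `mean_degree`, `CC_rand`, `L_rand`, `S`.
#' @export
summarize_network <- function(g, reference = c("mean", "single"),
                              realizations = 100L, seed = NULL,
                              disconnection = c("largest_component", "resample")) {
  reference <- match.arg(reference)
  disconnection <- match.arg(disconnection)
  check_connected(g)
  n <- igraph::vcount(g)
  p <- igraph::ecount(g) / choose(n, 2)
  reps <- if (reference == "single") 1L else as.integer(realizations)
  null <- simulate_er(er_spec(n, p, realizations = reps, seed = seed),
                      disconnection = disconnection)
  out <- list(
    N = n,
    L = aspl(g),
    D = net_diameter(g),
    CC = clustering_coef(g),
    mean_degree = mean_degree(g),
    CC_rand = null$CC$mean,
    L_rand = null$L$mean
  )
  out$S <- small_worldness(out$CC, out$CC_rand, out$L, out$L_rand)
  structure(out, class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(
    "<network_metrics> N=%d L=%.3f D=%g CC=%.3f <k>=%.2f CCrand=%.3f Lrand=%.3f S=%.2f\n",
    x$N, x$L, x$D, x$CC, x$mean_degree, x$CC_rand, x$L_rand, x$S))
  invisible(x)
}

#' Write a metrics row (Table-style layout) as CSV
#'
#' One row with columns N, L, D, CC, mean_degree, CC_rand, L_rand, S.
#'
#' @param x a `network_metrics` object (or a named list of them, written as
#'   one row each with a leading `network` column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(x, path) {
  if (inherits(x, "network_metrics")) x <- list(network = x)
  rows <- do.call(rbind, lapply(x, function(m) as.data.frame(unclass(m))))
  rows <- cbind(network = names(x), rows)
  write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
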