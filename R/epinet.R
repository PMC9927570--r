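# Thresholded statistical epistasis networks built from pairwise
# information-gain scores, plus the threshold-sweep profile used for
# feature selection.

#' Build the epistasis network at a threshold
#'
#' Keeps every variant pair whose information gain strictly exceeds `tau`
#' as an undirected weighted edge; nodes are exactly the endpoints of the
#' surviving edges (variants with no edge are not carried).
#'
#' @param scores A `pair_scores` object from
#'   [all_pairs_information_gain()].
#' @param tau Information-gain threshold in bits (strict: edges require
#'   ig > tau).
#' @return An object of class `epi_network`: a list with `edges`
#'   (data.frame `from`, `to`, `ig`), `nodes` (character vector) and `tau`.
#'   An empty network is permitted.
#' @export
build_network <- function(scores, tau) {
  et <- pair_table(scores)
  et <- et[!is.na(et$ig) & et$ig > tau, , drop = FALSE]
  names(et) <- c("from", "to", "ig")
  rownames(et) <- NULL
  nodes <- sort(unique(c(et$from, et$to)))
  structure(list(edges = et, nodes = nodes, tau = tau),
            class = "epi_network")
}

#' @export
print.epi_network <- function(x, ...) {
  cat(sprintf("epi_network: %d nodes, %d edges (tau = %g bits)\n",
              length(x$nodes), nrow(x$edges), x$tau))
  invisible(x)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' Connected components of an epistasis network
#'
#' @param network An `epi_network`.
#' @return A list of character vectors of variant ids, one per component,
#'   ordered by decreasing size with ties broken by the lexicographically
#'   smallest member; members sorted within each component.
#' @export
connected_components <- function(network) {
  if (!length(network$nodes)) return(list())
  comp <- igraph::components(as_igraph(network))
  parts <- split(names(comp$membership), comp$membership)
  parts <- lapply(parts, sort)
  ord <- order(-lengths(parts), vapply(parts, `[`, character(1), 1L))
  unname(parts[ord])
}

#' Select network components larger than a size cutoff
#'
#' Components with strictly more than `min_size` nodes are retained, each
#' with its induced subnetwork.
#'
#' @param network An `epi_network`.
#' @param min_size Node-count cutoff (strict).
#' @return A list with `components` (list of node vectors) and
#'   `subnetworks` (list of induced `epi_network` objects), both ordered as
#'   [connected_components()].
#' @export
select_components <- function(network, min_size) {
  stopifnot(min_size >= 0)
  comps <- connected_components(network)
  comps <- comps[lengths(comps) > min_size]
  subs <- lapply(comps, function(v) induced_subnetwork(network, v))
  list(components = comps, subnetworks = subs)
}

#' Induced subnetwork on a node subset
#'
#' @param network An `epi_network`.
#' @param nodes Character vector of variant ids.
#' @return An `epi_network` containing the edges with both endpoints in
#'   `nodes`.
#' @export
induced_subnetwork <- function(network, nodes) {
  et <- network$edges
  et <- et[et$from %in% nodes & et$to %in% nodes, , drop = FALSE]
  rownames(et) <- NULL
  structure(list(edges = et, nodes = sort(unique(c(et$from, et$to))),
                 tau = network$tau), class = "epi_network")
}

#' Network characteristics across an information-gain threshold sweep
#'
#' For each threshold, builds the network and records node count, edge
#' count, mean node degree, number of connected components and the size of
#' the largest component — the statistics used to pick a working threshold.
#'
#' @param scores A `pair_scores` object.
#' @param tau_grid Numeric vector of thresholds (any order; reported as
#'   given).
#' @return data.frame with columns `tau`, `n_nodes`, `n_edges`,
#'   `mean_degree`, `n_components`, `largest_component_size`.
#' @export
network_profile <- function(scores, tau_grid) {
  if (!length(tau_grid)) stop("empty threshold grid")
  rows <- lapply(tau_grid, function(tau) {
    net <- build_network(scores, tau)
    comps <- connected_components(net)
    data.frame(tau = tau,
               n_nodes = length(net$nodes),
               n_edges = nrow(net$edges),
               mean_degree = if (length(net$nodes))
                 2 * nrow(net$edges) / length(net$nodes) else 0,
               n_components = length(comps),
               largest_component_size = if (length(comps))
                 length(comps[[1]]) else 0L)
  })
  do.call(rbind, rows)
}

#' Node degrees in an epistasis network
#'
#' @param network An `epi_network`.
#' @return Named integer vector of degrees over `network$nodes`.
#' @export
network_degrees <- function(network) {
  d <- setNames(integer(length(network$nodes)), network$nodes)
  tab <- table(c(network$edges$from, network$edges$to))
  d[names(tab)] <- as.integer(tab)
  d
}

#' Export an epistasis network
#'
#' Writes the edge list as TSV (`variant_a`, `variant_b`,
#' `information_gain`) or the full graph as GraphML.
#'
#' @param network An `epi_network`.
#' @param path Output path.
#' @param format `"tsv"` or `"graphml"`.
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    et <- network$edges
    names(et) <- c("variant_a", "variant_b", "information_gain")
    data.table::fwrite(et, path, sep = "\t")
  } else {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  }
  invisible(path)
}

#' Read an epistasis network from a TSV edge list
#'
#' @param path Path written by [write_network()] (tsv format).
#' @param tau Threshold to record on the object (default `-Inf`).
#' @return An `epi_network`.
#' @export
read_network <- function(path, tau = -Inf) {
  et <- data.table::fread(path, sep = "\t", data.table = FALSE)
  names(et) <- c("from", "to", "ig")
  structure(list(edges = et, nodes = sort(unique(c(et$from, et$to))),
                 tau = tau), class = "epi_network")
}
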