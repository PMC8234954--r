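#' Over-representation of gene sets among network nodes
#'
#' One-sided hypergeometric test per set: the urn is the gene universe, the
#' draw is the network's node list, and success is membership in the set.
#' Benjamini-Hochberg q-values are computed across sets and results are
#' sorted by ascending p-value.
#'
#' @param network An `igraph` gene network.
#' @param sets A [gene_sets()] collection.
#' @param universe Character vector of gene IDs; must contain every network
#'   node.  Default enrichment universe is the whole input gene list, which
#'   callers should pass explicitly when it is wider than the network.
#' @param connected_only The inferred network records every tested gene as a
#'   vertex; with `TRUE` (default) the tested node list is restricted to the
#'   genes participating in at least one retained edge, which is what "in the
#'   network" means after thresholding.  Ignored when the network is edgeless.
#' @return Data frame with `set_name`, `overlap`, `set_size`, `network_size`,
#'   `universe_size`, `p_value`, `q_value`.
#' @export
enrich <- function(network, sets, universe = igraph::V(network)$name,
                   connected_only = TRUE) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0L) stop("empty enrichment universe")
  nodes <- unique(toupper(igraph::V(network)$name))
  if (connected_only && igraph::ecount(network) > 0L)
    nodes <- unique(toupper(igraph::V(network)$name[igraph::degree(network) > 0]))
  if (!all(nodes %in% universe)) stop("universe must contain every network node")
  res <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    overlap <- length(intersect(members, nodes))
    # P(X >= overlap) for X ~ Hypergeom(white = set, black = rest, drawn = nodes)
    p <- phyper(overlap - 1L, length(members),
                length(universe) - length(members), length(nodes),
                lower.tail = FALSE)
    data.frame(set_name = nm, overlap = overlap, set_size = length(members),
               network_size = length(nodes), universe_size = length(universe),
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res[order(res$p_value, res$set_name), , drop = FALSE]
}

#' Extract the induced subnetwork of a gene set
#'
#' Induces the subgraph of the network on the intersection of the set with
#' the network's nodes; set members absent from the network are dropped with
#' a log entry.
#'
#' @param network An `igraph` gene network.
#' @param set_members Character vector of gene IDs.
#' @param process Process label stored on the subnetwork.
#' @return An `igraph` subnetwork carrying a `process` graph attribute.
#' @export
extract_subnetwork <- function(network, set_members, process = "") {
  set_members <- unique(toupper(set_members))
  nodes <- igraph::V(network)$name
  present <- intersect(set_members, nodes)
  if (length(present) == 0L) stop("gene set has no overlap with the network")
  if (length(present) < length(set_members))
    log_msg("process '%s': dropped %d set member(s) absent from the network",
            process, length(set_members) - length(present))
  sub <- igraph::induced_subgraph(network, present)
  igraph::set_graph_attr(sub, "process", process)
}

#' Detect hub genes by degree thresholding
#'
#' Hubs are the genes whose total degree (undirected view) is at least
#' `degree_threshold`.  With `promote_radiation = TRUE`, annotated
#' radiation-induced members of the subnetwork are retained as hubs
#' regardless of degree, which reconciles a degree threshold with hub tables
#' that list degree-1 genes.
#'
#' @param subnet An `igraph` subnetwork.
#' @param degree_threshold Minimum total degree (>= 1; typical working ranges
#'   are 5-34 for low-radiation-dose subnetworks and 19-47 for very high
#'   dose; default 5).
#' @param catalog Optional [gene_catalog()] for the promotion rule.
#' @param promote_radiation Promote catalog radiation-induced genes to hubs.
#' @return The subnetwork with `hubs` and `hub_threshold` graph attributes
#'   set (and a `radiation` vertex attribute when a catalog is given).
#' @export
detect_hubs <- function(subnet, degree_threshold = 5, catalog = NULL,
                        promote_radiation = FALSE) {
  if (degree_threshold < 1) stop("degree_threshold must be >= 1")
  deg <- igraph::degree(subnet, mode = "all")
  hubs <- names(deg)[deg >= degree_threshold]
  if (!is.null(catalog)) {
    rad <- igraph::V(subnet)$name %in% catalog$radiation_induced
    subnet <- igraph::set_vertex_attr(subnet, "radiation", value = rad)
    if (promote_radiation)
      hubs <- union(hubs, igraph::V(subnet)$name[rad])
  }
  if (length(hubs) == 0L)
    log_msg("no gene reaches degree %d: empty hub set", degree_threshold)
  subnet <- igraph::set_graph_attr(subnet, "hubs", hubs)
  igraph::set_graph_attr(subnet, "hub_threshold", degree_threshold)
}
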