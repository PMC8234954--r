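# Dense adjacency of a network; binarized (0/1) or |weight|-weighted.
adjacency_matrix <- function(network, weighted = FALSE) {
  attr_name <- if (weighted && "weight" %in% igraph::edge_attr_names(network)) "weight" else NULL
  A <- as.matrix(igraph::as_adjacency_matrix(network, attr = attr_name, sparse = FALSE))
  if (is.null(attr_name)) A[A != 0] <- 1 else A <- abs(A)
  A
}

#' Degree distribution of a network
#'
#' Per-gene total, in- and out-degree (equal for undirected networks) plus
#' the degree histogram as fractions of vertices.
#'
#' @param network An `igraph` network.
#' @return List with `table` (data.frame `gene`, `k_total`, `k_in`, `k_out`)
#'   and `histogram` (data.frame `degree`, `fraction`; fractions sum to 1).
#' @export
degree_distribution <- function(network) {
  k_total <- igraph::degree(network, mode = "all")
  k_in <- igraph::degree(network, mode = "in")
  k_out <- igraph::degree(network, mode = "out")
  tab <- data.frame(gene = igraph::V(network)$name %||% as.character(seq_len(igraph::vcount(network))),
                    k_total = as.integer(k_total), k_in = as.integer(k_in),
                    k_out = as.integer(k_out), stringsAsFactors = FALSE)
  counts <- table(factor(k_total, levels = sort(unique(k_total))))
  hist <- data.frame(degree = as.integer(names(counts)),
                     fraction = as.numeric(counts) / max(1L, igraph::vcount(network)))
  list(table = tab, histogram = hist)
}

#' Subgraph centrality
#'
#' The weighted sum over closed walks of every length r starting and ending
#' at a node, weighted by 1/r!; equivalently the diagonal of the matrix
#' exponential of the adjacency,
#' `SC(i) = sum_j u_j(i)^2 exp(lambda_j)` from the eigendecomposition
#' `A = U diag(lambda) U'`.  Computed on the binarized undirected adjacency,
#' which is the convention under which a hub whose neighborhood is a star
#' with n leaves scores exactly `cosh(sqrt(n))`.
#'
#' @param network An `igraph` network (directed input is collapsed to its
#'   undirected support).
#' @return Named numeric vector (>= 1 for every node; an isolated node's only
#'   closed walk is the length-0 one).
#' @export
subgraph_centrality <- function(network) {
  und <- igraph::as_undirected(network, mode = "collapse")
  A <- adjacency_matrix(und, weighted = FALSE)
  if (nrow(A) == 0L) return(setNames(numeric(0), character(0)))
  e <- eigen(A, symmetric = TRUE)
  sc <- as.numeric((e$vectors^2) %*% exp(e$values))
  setNames(sc, igraph::V(und)$name %||% as.character(seq_len(nrow(A))))
}

#' Adjacency and normalized (random-walk) spectral gaps
#'
#' The adjacency gap is `|lambda_1| - |lambda_2|` of the symmetric adjacency,
#' eigenvalues ordered by absolute value (weighted by |r| when `weighted =
#' TRUE` and weights are present, else binarized).  The normalized gap is
#' `1 - |lambda_2|` of `D^{-1/2} A D^{-1/2}` on the binarized adjacency with
#' isolated nodes excluded from the degree inversion; it lies in `[0, 1]` and
#' is 0 exactly when the graph (restricted to non-isolated nodes) is
#' disconnected or bipartite.
#'
#' @param network An `igraph` network.
#' @param weighted Use |weight| for the adjacency gap (default `TRUE`).
#' @return List with `adjacency` and `normalized` gaps (`normalized` is `NA`
#'   with a log entry when no edges exist).
#' @export
spectral_gaps <- function(network, weighted = TRUE) {
  if (igraph::vcount(network) == 0L) stop("spectral gaps of an empty network")
  und <- igraph::as_undirected(network, mode = "collapse", edge.attr.comb = "first")
  A <- adjacency_matrix(und, weighted = weighted)
  ev <- sort(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
             decreasing = TRUE)
  adj_gap <- if (length(ev) >= 2L) ev[1L] - ev[2L] else ev[1L]

  B <- adjacency_matrix(und, weighted = FALSE)
  deg <- rowSums(B)
  keep <- deg > 0
  if (!any(keep)) {
    log_msg("all nodes isolated: normalized spectral gap undefined")
    return(list(adjacency = adj_gap, normalized = NA_real_))
  }
  Bk <- B[keep, keep, drop = FALSE]
  dinv <- 1 / sqrt(deg[keep])
  N <- Bk * outer(dinv, dinv)
  nv <- sort(abs(eigen(N, symmetric = TRUE, only.values = TRUE)$values),
             decreasing = TRUE)
  norm_gap <- if (length(nv) >= 2L) 1 - nv[2L] else 1
  norm_gap <- max(0, min(1, norm_gap))  # clip eigen-solver noise
  list(adjacency = adj_gap, normalized = norm_gap)
}

#' Girth via traces of adjacency powers
#'
#' The smallest positive integer r with `Trace(A^r) > 0` on the binarized
#' adjacency, i.e. the shortest cycle length; `Inf` for an acyclic graph.
#' Meaningful on a directed view: on an undirected graph every edge is a
#' closed walk of length 2, making the trace definition return 2 always, so
#' a warning is emitted for undirected input.
#'
#' @param network An `igraph` network (directed view expected).
#' @return Integer cycle length or `Inf`.
#' @export
graph_girth <- function(network) {
  if (!igraph::is_directed(network))
    warning("girth by adjacency-power traces is degenerate on undirected graphs ",
            "(any edge yields a length-2 closed walk)")
  A <- adjacency_matrix(network, weighted = FALSE)
  nv <- nrow(A)
  if (nv == 0L) return(Inf)
  P <- diag(1, nv)
  for (r in seq_len(nv)) {
    P <- (P %*% A) > 0  # boolean powers: walk existence, no overflow
    storage.mode(P) <- "double"
    if (sum(diag(P)) > 0) return(r)
  }
  Inf
}

#' Diameter, average shortest path and component count
#'
#' Components are the weakly-connected components of the directed view
#' (identical to the components of the undirected view).  The diameter is the
#' maximum finite unweighted eccentricity within components, and the average
#' shortest path is the mean distance over reachable ordered pairs.
#'
#' @param network An `igraph` network.
#' @return List with `diameter`, `avg_shortest_path`, `n_components`.
#' @export
diameter_and_paths <- function(network) {
  if (igraph::vcount(network) == 0L) stop("path measures of an empty network")
  D <- igraph::distances(network, mode = "all", weights = NA)
  finite <- is.finite(D) & D > 0
  comps <- igraph::components(network, mode = "weak")
  list(diameter = if (any(finite)) max(D[finite]) else Inf,
       avg_shortest_path = if (any(finite)) mean(D[finite]) else NaN,
       n_components = comps$no)
}

#' Graph density
#'
#' Ratio of realized to possible edges: `2|E| / (|V|(|V|-1))` undirected,
#' `|E| / (|V|(|V|-1))` directed.
#'
#' @param network An `igraph` network with at least 2 vertices.
#' @return Density in `[0, 1]`.
#' @export
network_density <- function(network) {
  nv <- igraph::vcount(network)
  if (nv < 2L) stop("density requires at least 2 vertices")
  ne <- igraph::ecount(network)
  if (igraph::is_directed(network)) ne / (nv * (nv - 1)) else 2 * ne / (nv * (nv - 1))
}

#' Jaccard similarity of two gene neighborhoods
#'
#' Intersection over union of the open neighborhoods (the gene itself is
#' excluded), within one network or across two subnetworks.  The cross-network
#' mode compares the same or different genes between two process subnetworks;
#' excluding the focal genes is what lets a gene with identical interaction
#' partners in two subnetworks reach an index of exactly 1.
#'
#' @param network_a,network_b `igraph` networks (`network_b` defaults to
#'   `network_a` for the same-network mode).
#' @param gene_u,gene_v Gene IDs present in their respective networks
#'   (`gene_v` defaults to `gene_u`).
#' @return List with `gene_u`, `gene_v`, `index` in `[0, 1]`.
#' @export
jaccard_similarity <- function(network_a, gene_u, network_b = network_a,
                               gene_v = gene_u) {
  if (!gene_u %in% igraph::V(network_a)$name) stop("gene_u not in network_a: ", gene_u)
  if (!gene_v %in% igraph::V(network_b)$name) stop("gene_v not in network_b: ", gene_v)
  nu <- setdiff(names(igraph::neighbors(network_a, gene_u, mode = "all")), gene_u)
  nv <- setdiff(names(igraph::neighbors(network_b, gene_v, mode = "all")), gene_v)
  if (length(nu) == 0L && length(nv) == 0L) {
    warning("both neighborhoods empty: Jaccard index defined as 0")
    idx <- 0
  } else {
    idx <- length(intersect(nu, nv)) / length(union(nu, nv))
  }
  list(gene_u = gene_u, gene_v = gene_v, index = idx)
}

#' Per-gene centrality feature table
#'
#' Degrees, subgraph centrality, closeness, PageRank and eigenvector
#' centrality -- the features consumed by the logistic-regression gene
#' ranking.  Closeness follows the per-component convention
#' `(number reachable) / (sum of distances)` (0 for isolated nodes); PageRank
#' uses damping 0.85; eigenvector centrality is computed on the largest
#' connected component and L2-normalized, other nodes scoring 0.
#'
#' @param network An `igraph` network.
#' @return Data frame with columns `gene`, `degree_total`, `degree_in`,
#'   `degree_out`, `subgraph_centrality`, `closeness`, `pagerank`,
#'   `eigenvector`.
#' @export
centrality_features <- function(network) {
  if (igraph::vcount(network) == 0L) stop("centrality features of an empty network")
  deg <- degree_distribution(network)$table
  sc <- subgraph_centrality(network)

  D <- igraph::distances(network, mode = "all", weights = NA)
  closeness <- apply(D, 1L, function(d) {
    d <- d[is.finite(d) & d > 0]
    if (length(d) == 0L) 0 else length(d) / sum(d)
  })

  pr <- igraph::page_rank(network, damping = 0.85)$vector

  eig <- setNames(rep(0, igraph::vcount(network)), igraph::V(network)$name)
  if (igraph::ecount(network) == 0L) {
    warning("edgeless network: eigenvector centrality reported as zeros")
  } else {
    comps <- igraph::components(network, mode = "weak")
    big <- which.max(comps$csize)
    sub <- igraph::induced_subgraph(network, which(comps$membership == big))
    v <- igraph::eigen_centrality(igraph::as_undirected(sub, mode = "collapse"),
                                  weights = NA)$vector
    v <- v / sqrt(sum(v^2))
    eig[names(v)] <- v
  }

  data.frame(gene = deg$gene, degree_total = deg$k_total, degree_in = deg$k_in,
             degree_out = deg$k_out,
             subgraph_centrality = as.numeric(sc[deg$gene]),
             closeness = as.numeric(closeness[deg$gene]),
             pagerank = as.numeric(pr[deg$gene]),
             eigenvector = as.numeric(eig[deg$gene]),
             stringsAsFactors = FALSE)
}

#' Whole-network summary of topological and spectral measures
#'
#' @param network An `igraph` network.
#' @param weighted Use |weight| for the adjacency spectral gap.
#' @return List with `spectral_gap_adjacency`, `spectral_gap_normalized`,
#'   `girth` (on the directed view when the input is directed; `NA` for
#'   undirected input where the trace definition degenerates), `diameter`,
#'   `avg_shortest_path`, `n_components`, `density`, `n_nodes`, `n_edges`,
#'   and the ordered adjacency `eigenvalues`.
#' @export
network_summary <- function(network, weighted = TRUE) {
  gaps <- spectral_gaps(network, weighted = weighted)
  paths <- diameter_and_paths(network)
  und <- igraph::as_undirected(network, mode = "collapse", edge.attr.comb = "first")
  A <- adjacency_matrix(und, weighted = weighted)
  ev <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  list(spectral_gap_adjacency = gaps$adjacency,
       spectral_gap_normalized = gaps$normalized,
       girth = if (igraph::is_directed(network)) graph_girth(network) else NA,
       diameter = paths$diameter,
       avg_shortest_path = paths$avg_shortest_path,
       n_components = paths$n_components,
       density = if (igraph::vcount(network) >= 2L) network_density(network) else NA_real_,
       n_nodes = igraph::vcount(network),
       n_edges = igraph::ecount(network),
       eigenvalues = ev)
}
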