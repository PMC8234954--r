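test_that("degree distribution covers triangle, star, and handshake invariant", {
  tri <- igraph::make_ring(3)
  igraph::V(tri)$name <- c("A", "B", "C")
  dd <- degree_distribution(tri)
  expect_true(all(dd$table$k_total == 2L))
  expect_equal(sum(dd$histogram$fraction), 1)

  star <- make_named_star(12)
  dd <- degree_distribution(star)
  expect_equal(dd$table$k_total[dd$table$gene == "HUB"], 12L)
  expect_true(all(dd$table$k_total[dd$table$gene != "HUB"] == 1L))

  g <- random_named_gnp(30, 0.2, seed = 9)
  dd <- degree_distribution(g)
  expect_equal(sum(dd$table$k_total), 2L * igraph::ecount(g))
})

test_that("subgraph centrality matches eigen, series oracle and star closed forms", {
  # isolated node: only the length-0 walk
  iso <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(iso)$name <- "X"
  expect_equal(unname(subgraph_centrality(iso)), 1.0)

  # endpoint of an isolated edge: cosh(1)
  edge <- igraph::make_graph(~ A - B)
  expect_equal(unname(subgraph_centrality(edge)), rep(cosh(1), 2), tolerance = 1e-10)

  # star closed forms: hub cosh(sqrt(n)), leaf 1 + (cosh(sqrt(n)) - 1)/n
  for (n in c(1, 2, 4, 6, 7, 9, 12, 20)) {
    sc <- subgraph_centrality(make_named_star(n))
    expect_equal(unname(sc["HUB"]), cosh(sqrt(n)), tolerance = 1e-10)
    expect_equal(unname(sc["LEAF01"]), 1 + (cosh(sqrt(n)) - 1) / n, tolerance = 1e-10)
  }

  # eigendecomposition equals the truncated factorial series on small graphs
  for (seed in 1:8) {
    g <- random_named_gnp(sample(3:8, 1), 0.4, seed = seed)
    expect_equal(subgraph_centrality(g), sc_series_oracle(g), tolerance = 1e-8)
  }
})

test_that("spectral gaps: complete graphs, disconnection, bipartiteness, single edge", {
  for (n in 3:8) {
    kn <- igraph::make_full_graph(n)
    igraph::V(kn)$name <- paste0("K", 1:n)
    gaps <- spectral_gaps(kn)
    expect_equal(gaps$normalized, 1 - 1 / (n - 1), tolerance = 1e-10)
  }
  two_cliques <- igraph::disjoint_union(igraph::make_full_graph(4),
                                        igraph::make_full_graph(3))
  igraph::V(two_cliques)$name <- paste0("V", 1:7)
  expect_equal(spectral_gaps(two_cliques)$normalized, 0, tolerance = 1e-10)

  ring4 <- make_named_ring(4)  # bipartite: |lambda_2| = 1
  expect_equal(spectral_gaps(ring4)$normalized, 0, tolerance = 1e-10)

  edge <- igraph::make_graph(~ A - B)  # adjacency eigenvalues +1, -1
  expect_equal(spectral_gaps(edge)$adjacency, 0, tolerance = 1e-12)

  # weighted adjacency gap uses |r|
  we <- igraph::make_graph(~ A - B)
  igraph::E(we)$weight <- -0.5
  g2 <- spectral_gaps(we, weighted = TRUE)
  expect_equal(sort(abs(eigen(matrix(c(0, .5, .5, 0), 2))$values), decreasing = TRUE),
               c(0.5, 0.5))
  expect_equal(g2$adjacency, 0, tolerance = 1e-12)

  iso <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(iso)$name <- paste0("I", 1:3)
  expect_message(gi <- spectral_gaps(iso), "isolated")
  expect_true(is.na(gi$normalized))

  # normalized gap bounded in [0, 1] on random graphs
  for (seed in 1:5) {
    g <- random_named_gnp(15, 0.25, seed = seed)
    ng <- spectral_gaps(g)$normalized
    expect_gte(ng, 0); expect_lte(ng, 1)
  }
})

test_that("girth by adjacency-power traces on the directed view", {
  c3 <- igraph::make_ring(3, directed = TRUE)
  igraph::V(c3)$name <- c("A", "B", "C")
  expect_equal(graph_girth(c3), 3)

  dag <- igraph::graph_from_literal(A --+ B, A --+ C, B --+ C)
  expect_equal(graph_girth(dag), Inf)

  expect_warning(graph_girth(igraph::make_graph(~ A - B)), "degenerate")

  for (seed in 1:10) {
    g <- random_named_gnp(sample(3:7, 1), 0.35, seed = 100 + seed, directed = TRUE)
    expect_equal(graph_girth(g), directed_girth_oracle(g))
  }
})

test_that("diameter, average shortest path and components match BFS oracles", {
  edge <- igraph::make_graph(~ A - B)
  r <- diameter_and_paths(edge)
  expect_equal(r$diameter, 1)
  expect_equal(r$avg_shortest_path, 1)
  expect_equal(r$n_components, 1L)

  two_edges <- igraph::make_graph(~ A - B, C - D)
  r <- diameter_and_paths(two_edges)
  expect_equal(r$diameter, 1)
  expect_equal(r$n_components, 2L)

  p6 <- igraph::make_ring(6, circular = FALSE)
  igraph::V(p6)$name <- paste0("P", 1:6)
  r <- diameter_and_paths(p6)
  expect_equal(r$diameter, 5)
  D <- bfs_oracle(p6)
  expect_equal(r$avg_shortest_path, mean(D[is.finite(D) & D > 0]))

  for (seed in 1:5) {
    g <- random_named_gnp(30, 0.08, seed = 200 + seed)
    r <- diameter_and_paths(g)
    D <- bfs_oracle(g)
    fin <- is.finite(D) & D > 0
    expect_equal(r$diameter, if (any(fin)) max(D[fin]) else Inf)
    expect_equal(r$avg_shortest_path, mean(D[fin]))
    # independent component count: count connected blocks from the BFS matrix
    reach <- is.finite(D)
    comp_ids <- apply(reach, 1, function(x) min(which(x)))
    expect_equal(r$n_components, length(unique(comp_ids)))
  }
})

test_that("density follows the possible-edges ratio", {
  k5 <- igraph::make_full_graph(5)
  expect_equal(network_density(k5), 1.0)
  e4 <- igraph::make_empty_graph(4, directed = FALSE)
  expect_equal(network_density(e4), 0.0)
  g <- igraph::make_graph(~ A - B, B - C, C - D)
  expect_equal(network_density(g), 0.5)  # 3 / C(4,2)
  expect_error(network_density(igraph::make_empty_graph(1)), "at least 2")
  # invariant under relabeling
  h <- random_named_gnp(12, 0.3, seed = 31)
  h2 <- igraph::permute(h, sample(igraph::vcount(h)))
  expect_equal(network_density(h2), network_density(h))
})

test_that("jaccard similarity on open neighborhoods", {
  # identical neighborhoods across two networks -> 1 (focal gene excluded)
  ga <- igraph::make_graph(~ G - A, G - B, G - C)
  gb <- igraph::make_graph(~ G - A, G - B, G - C, A - B)
  expect_equal(jaccard_similarity(ga, "G", gb, "G")$index, 1.0)

  # disjoint neighborhoods
  gd <- igraph::make_graph(~ U - A, U - B, V - C, V - D)
  expect_equal(jaccard_similarity(gd, "U", gd, "V")$index, 0.0)

  # N(u) = {a,b,c}, N(v) = {b,c,d} -> 2/4
  g <- igraph::make_graph(~ U - A, U - B, U - C, V - B, V - C, V - D)
  j <- jaccard_similarity(g, "U", g, "V")
  expect_equal(j$index, 0.5)
  expect_equal(jaccard_similarity(g, "V", g, "U")$index, j$index)  # symmetry

  iso <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(iso)$name <- c("X", "Y")
  expect_warning(jz <- jaccard_similarity(iso, "X", iso, "Y"), "empty")
  expect_equal(jz$index, 0)
  expect_error(jaccard_similarity(g, "NOPE"), "not in network")
})

test_that("centrality features: star monotonicity, ring transitivity, pagerank sum", {
  star <- make_named_star(8)
  cf <- centrality_features(star)
  hub <- cf[cf$gene == "HUB", ]
  leaves <- cf[cf$gene != "HUB", ]
  for (feat in c("closeness", "pagerank", "eigenvector", "subgraph_centrality"))
    expect_true(all(hub[[feat]] > leaves[[feat]]))

  ring <- make_named_ring(7)
  cf <- centrality_features(ring)
  for (feat in c("closeness", "pagerank", "eigenvector", "degree_total"))
    expect_lt(diff(range(cf[[feat]])), 1e-9)

  g <- random_named_gnp(50, 0.1, seed = 77)
  cf <- centrality_features(g)
  expect_equal(sum(cf$pagerank), 1, tolerance = 1e-9)
  # power-iteration oracle for pagerank
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  n <- nrow(A); d <- 0.85
  deg <- rowSums(A)
  P <- A / ifelse(deg == 0, 1, deg)
  P[deg == 0, ] <- 1 / n   # dangling nodes jump uniformly
  v <- rep(1 / n, n)
  for (i in 1:200) v <- (1 - d) / n + d * as.numeric(t(P) %*% v)
  expect_equal(unname(cf$pagerank), unname(v), tolerance = 1e-6)

  expect_warning(centrality_features(igraph::make_empty_graph(3, directed = FALSE)),
                 "edgeless")
})

test_that("network_summary assembles the measure set consistently", {
  g <- random_named_gnp(15, 0.25, seed = 5)
  s <- network_summary(g)
  expect_equal(s$density, network_density(g))
  expect_equal(s$n_components, igraph::components(g)$no)
  expect_equal(s$spectral_gap_normalized, spectral_gaps(g)$normalized)
  expect_equal(length(s$eigenvalues), igraph::vcount(g))
  expect_true(is.na(s$girth))  # undirected view: trace definition degenerate
  d <- igraph::make_ring(4, directed = TRUE)
  igraph::V(d)$name <- paste0("D", 1:4)
  expect_equal(network_summary(d)$girth, 4)
})
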