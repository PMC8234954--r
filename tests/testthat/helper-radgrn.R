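# Shared fixtures and oracles, all built in code.

quietly <- function(expr) suppressMessages(suppressWarnings(expr))

# Undirected star: one named hub plus n_leaves leaves.
make_named_star <- function(n_leaves, hub = "HUB") {
  g <- igraph::make_star(n_leaves + 1L, mode = "undirected", center = 1L)
  igraph::V(g)$name <- c(hub, sprintf("LEAF%02d", seq_len(n_leaves)))
  g
}

make_named_ring <- function(n, prefix = "R") {
  g <- igraph::make_ring(n)
  igraph::V(g)$name <- sprintf("%s%02d", prefix, seq_len(n))
  g
}

random_named_gnp <- function(n, p, seed, directed = FALSE) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p, directed = directed)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}

# Independent truncated-factorial-series oracle for subgraph centrality:
# SC(i) = sum_{r=0..r_max} (A^r)_{ii} / r!
sc_series_oracle <- function(g, r_max = 40L) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A[A != 0] <- 1
  P <- diag(1, nrow(A))
  out <- diag(P)
  fact <- 1
  for (r in seq_len(r_max)) {
    P <- P %*% A
    fact <- fact * r
    out <- out + diag(P) / fact
  }
  setNames(out, igraph::V(g)$name)
}

# Brute-force all-pairs BFS oracle (no igraph distance machinery).
bfs_oracle <- function(g) {
  n <- igraph::vcount(g)
  adj <- lapply(seq_len(n), function(v)
    as.integer(igraph::neighbors(g, v, mode = "all")))
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) for (w in adj[[v]]) if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        nxt <- c(nxt, w)
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

# Shortest directed cycle by exhaustive search over edges: for each edge
# (u, v), shortest cycle through it is 1 + dist(v, u).
directed_girth_oracle <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0L) return(Inf)
  D <- igraph::distances(g, mode = "out", weights = NA)
  best <- Inf
  for (k in seq_len(nrow(el)))
    best <- min(best, 1 + D[el[k, 2L], el[k, 1L]])
  best
}

# Small expression fixture written to a temp file.
write_expr_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
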