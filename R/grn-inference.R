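#' Pearson correlation coefficient of two sample vectors
#'
#' Covariance divided by the product of the standard deviations.  With the
#' 3-8 replicate values typical of the expression tables this is the edge
#' weight of the inferred network.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero-variance vector: correlation undefined")
  r <- cor(x, y)
  max(-1, min(1, r))
}

#' t-test for a Pearson correlation
#'
#' Tests whether a correlation differs from zero:
#' `t = r * sqrt((n - 2) / (1 - r^2))` referred to a Student t distribution
#' with `n - 2` degrees of freedom (two-sided).  `|r| = 1` returns `p = 0`
#' exactly.  Vectorized over `r`.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @param n Number of paired observations (>= 3).
#' @return List with `t_stat` and `p_value`.
#' @export
correlation_test <- function(r, n) {
  if (any(n < 3L)) stop("correlation test requires n >= 3")
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must not exceed 1")
  r <- pmax(-1, pmin(1, r))
  df <- n - 2L
  t_stat <- ifelse(abs(r) == 1, sign(r) * Inf, r * sqrt(df / (1 - r^2)))
  p <- ifelse(abs(r) == 1, 0, 2 * pt(abs(t_stat), df, lower.tail = FALSE))
  list(t_stat = t_stat, p_value = p)
}

#' Infer a Pearson-correlation gene regulatory network
#'
#' Every gene pair is tested; an edge is kept iff its (optionally corrected)
#' two-sided p-value is `<= p_threshold` (ties at the threshold retained).
#' Edge weights are the correlation coefficients.  Zero-variance genes cannot
#' be tested and are excluded with a log entry.
#'
#' @param expr Numeric genes-by-samples matrix with gene rownames (>= 3
#'   samples).
#' @param p_threshold Retention threshold on the p-value (default `0.0005`,
#'   the operative filter for small-replicate expression data).
#' @param correction `"none"` (default), `"bonferroni"` or `"bh"` multiplicity
#'   correction applied across all tested pairs before thresholding.
#' @param directed If `TRUE` the undirected network is returned as a mutual
#'   directed graph (correlation itself carries no direction; see
#'   [orient_to_hubs()] for the presentation-layer hub orientation).
#' @return An `igraph` network; vertices are the usable genes, edges carry
#'   `weight` (r), `t_stat`, `p_value` and `n` attributes, and the graph
#'   carries `p_threshold` and `correction` attributes.
#' @export
build_grn <- function(expr, p_threshold = 0.0005,
                      correction = c("none", "bonferroni", "bh"),
                      directed = FALSE) {
  correction <- match.arg(correction)
  expr <- validate_expression(expr)
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must lie in (0, 1)")
  n <- ncol(expr)
  vars <- apply(expr, 1L, var)
  if (any(vars == 0)) {
    log_msg("excluding %d zero-variance gene(s) from correlation testing", sum(vars == 0))
    expr <- expr[vars > 0, , drop = FALSE]
  }
  if (nrow(expr) < 2L) stop("fewer than 2 usable genes")
  genes <- rownames(expr)
  C <- cor(t(expr))
  idx <- which(upper.tri(C), arr.ind = TRUE)
  r <- C[idx]
  test <- correlation_test(r, n)
  p <- switch(correction,
              none = test$p_value,
              bonferroni = pmin(1, test$p_value * length(test$p_value)),
              bh = p.adjust(test$p_value, method = "BH"))
  keep <- p <= p_threshold
  edges <- data.frame(from = genes[idx[keep, 1L]],
                      to = genes[idx[keep, 2L]],
                      weight = r[keep],
                      t_stat = test$t_stat[keep],
                      p_value = p[keep],
                      n = rep(n, sum(keep)),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = genes))
  g <- igraph::set_graph_attr(g, "p_threshold", p_threshold)
  g <- igraph::set_graph_attr(g, "correction", correction)
  if (directed) g <- igraph::as_directed(g, mode = "mutual")
  g
}

#' Directed presentation view of a subnetwork
#'
#' Correlation is symmetric, so direction is presentation-layer only: each
#' edge incident to a hub is oriented from the non-hub gene to the hub
#' (hub genes are "activated by" their neighbors); edges between two hubs or
#' two non-hubs become mutual pairs.
#'
#' @param network An undirected `igraph` network.
#' @param hubs Character vector of hub gene IDs (defaults to the network's
#'   `hubs` graph attribute).
#' @return A directed `igraph` network.
#' @export
orient_to_hubs <- function(network, hubs = igraph::graph_attr(network, "hubs")) {
  if (is.null(hubs)) stop("no hub set supplied or recorded on the network")
  el <- igraph::as_edgelist(network, names = TRUE)
  w <- igraph::edge_attr(network, "weight") %||% rep(1, nrow(el))
  from <- el[, 1]; to <- el[, 2]
  a_hub <- from %in% hubs; b_hub <- to %in% hubs
  # exactly one endpoint is a hub: orient non-hub -> hub
  swap <- a_hub & !b_hub
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  both <- (a_hub & b_hub) | (!a_hub & !b_hub)
  df <- data.frame(from = c(from, to[both]), to = c(to, from[both]),
                   weight = c(w, w[both]), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    df, directed = TRUE,
    vertices = data.frame(name = igraph::V(network)$name))
  igraph::set_graph_attr(g, "hubs", hubs)
}
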