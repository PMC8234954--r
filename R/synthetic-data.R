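#' Configuration for the modular expression simulator
#'
#' The generator emulates the structure of small-replicate spaceflight
#' transcriptomes: a handful of expression values per gene (3-8 replicates),
#' block-correlated gene modules built around hub genes, star-shaped hub
#' neighborhoods reaching into the background gene pool, and a binary
#' radiation-induced label on a fraction of genes.
#'
#' @param n_genes Total number of genes.
#' @param n_samples Replicate count per gene (>= 3; the emulated studies have
#'   3-8, default 5, the mid-range).
#' @param n_modules Number of correlated modules.
#' @param module_sizes Integer vector of module sizes (length `n_modules`);
#'   their sum must not exceed `n_genes`.
#' @param hub_leaf_counts Integer vector (length `n_modules`): number of
#'   background "leaf" genes attached star-wise to each module's hub.
#' @param within_module_corr Expected pairwise correlation of genes inside a
#'   module, strictly in (0, 1).
#' @param noise_sd Overall expression amplitude (> 0); correlations are
#'   invariant to it.
#' @param frac_radiation_induced Fraction of genes labeled radiation-induced.
#' @param hub_bias If `TRUE` (default) the radiation labels are assigned
#'   preferentially to hub genes, then module genes; if `FALSE`, uniformly.
#' @param seed Integer RNG seed.  Mandatory for reproducible runs; if `NULL`
#'   one is drawn and reported with a warning.
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 200, n_samples = 5, n_modules = 3,
                              module_sizes = rep(10L, n_modules),
                              hub_leaf_counts = rep(8L, n_modules),
                              within_module_corr = 0.7, noise_sd = 1,
                              frac_radiation_induced = 0.15,
                              hub_bias = TRUE, seed = NULL) {
  if (n_genes < 1) stop("n_genes must be positive")
  if (n_samples < 3) stop("n_samples must be >= 3 (correlation test needs df = n - 2 >= 1)")
  if (length(module_sizes) != n_modules || any(module_sizes < 1))
    stop("module_sizes must list a positive size for each of the ", n_modules, " modules")
  if (length(hub_leaf_counts) != n_modules || any(hub_leaf_counts < 0))
    stop("hub_leaf_counts must list a non-negative count per module")
  if (sum(module_sizes) > n_genes)
    stop("sum(module_sizes) exceeds n_genes")
  if (within_module_corr <= 0 || within_module_corr >= 1)
    stop("within_module_corr must lie strictly in (0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (frac_radiation_induced < 0 || frac_radiation_induced > 1)
    stop("frac_radiation_induced must lie in [0, 1]")
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
    warning("no seed supplied; using generated seed ", seed)
  }
  structure(list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
                 n_modules = as.integer(n_modules),
                 module_sizes = as.integer(module_sizes),
                 hub_leaf_counts = as.integer(hub_leaf_counts),
                 within_module_corr = within_module_corr, noise_sd = noise_sd,
                 frac_radiation_induced = frac_radiation_induced,
                 hub_bias = isTRUE(hub_bias), seed = as.integer(seed)),
            class = "simulation_config")
}

# Deterministic synthetic AGI-form identifiers: AT1G00010, AT2G00020, ...
synthetic_gene_ids <- function(n) {
  sprintf("AT%dG%05d", ((seq_len(n) - 1L) %% 5L) + 1L, seq_len(n) * 10L)
}

#' Simulate a modular expression matrix with planted structure
#'
#' Genes within module m share a latent factor:
#' `x_g = sqrt(rho) * f_m + sqrt(1 - rho) * eps_g` with
#' `rho = within_module_corr`, so the expected pairwise correlation inside a
#' module is exactly `rho`.  The first gene of each module is its hub; the
#' hub's (unit-variance) signal is additionally shared with
#' `hub_leaf_counts[m]` background leaf genes
#' (`x_leaf = sqrt(rho) * x_hub + sqrt(1 - rho) * eps`), which plants a
#' star-shaped neighborhood of expected correlation `sqrt(rho)` around every
#' hub.  Remaining background genes are independent noise.  All values are
#' scaled by `noise_sd`.
#'
#' @param config A [simulation_config()].
#' @return List with `expression` (genes-by-samples matrix) and `truth`, a
#'   ground-truth record with `module_assignment` (named integer, 0 =
#'   background), `hubs`, `hub_leaves` (list per module), `true_edges`
#'   (data.frame `from`, `to`, `type` in module/star) and `radiation_labels`
#'   (named logical).
#' @export
generate_modular_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes; p <- config$n_samples
  rho <- config$within_module_corr
  genes <- synthetic_gene_ids(n)
  X <- matrix(rnorm(n * p), nrow = n, dimnames = list(genes, sprintf("S%d", seq_len(p))))

  assignment <- setNames(integer(n), genes)
  hubs <- character(config$n_modules)
  hub_leaves <- vector("list", config$n_modules)
  edges_from <- character(); edges_to <- character(); edges_type <- character()

  offset <- 0L
  bg_pool <- setdiff(seq_len(n), seq_len(sum(config$module_sizes)))
  for (m in seq_len(config$n_modules)) {
    members <- offset + seq_len(config$module_sizes[m])
    offset <- offset + config$module_sizes[m]
    assignment[members] <- m
    f <- rnorm(p)
    X[members, ] <- sqrt(rho) * matrix(f, length(members), p, byrow = TRUE) +
      sqrt(1 - rho) * X[members, , drop = FALSE]
    hub <- members[1L]
    hubs[m] <- genes[hub]
    if (length(members) > 1L) {
      pairs <- utils::combn(genes[members], 2L)
      edges_from <- c(edges_from, pairs[1L, ]); edges_to <- c(edges_to, pairs[2L, ])
      edges_type <- c(edges_type, rep("module", ncol(pairs)))
    }
    k <- min(config$hub_leaf_counts[m], length(bg_pool))
    if (k < config$hub_leaf_counts[m])
      log_msg("module %d: only %d background genes left for %d requested leaves",
              m, k, config$hub_leaf_counts[m])
    if (k > 0L) {
      leaves <- bg_pool[seq_len(k)]
      bg_pool <- bg_pool[-seq_len(k)]
      hub_signal <- X[hub, ]  # unit variance by construction
      X[leaves, ] <- sqrt(rho) * matrix(hub_signal, k, p, byrow = TRUE) +
        sqrt(1 - rho) * X[leaves, , drop = FALSE]
      hub_leaves[[m]] <- genes[leaves]
      edges_from <- c(edges_from, rep(genes[hub], k)); edges_to <- c(edges_to, genes[leaves])
      edges_type <- c(edges_type, rep("star", k))
    } else {
      hub_leaves[[m]] <- character()
    }
  }
  X <- X * config$noise_sd

  n_rad <- round(config$frac_radiation_induced * n)
  labels <- setNames(rep(FALSE, n), genes)
  if (n_rad > 0L) {
    if (config$hub_bias) {
      pref <- unique(c(hubs, genes[assignment > 0], genes))
      labels[pref[seq_len(n_rad)]] <- TRUE
    } else {
      labels[sample(genes, n_rad)] <- TRUE
    }
  }

  truth <- structure(list(
    module_assignment = assignment,
    hubs = hubs,
    hub_leaves = setNames(hub_leaves, hubs),
    true_edges = data.frame(from = edges_from, to = edges_to, type = edges_type,
                            stringsAsFactors = FALSE),
    radiation_labels = labels,
    config = config), class = "ground_truth")
  list(expression = X, truth = truth)
}

#' Construct a linear-Gaussian Bayesian-network structure
#'
#' @param edges Data frame with columns `from`, `to` and optionally `coef`
#'   (linear coefficient, default 1).  The structure must be acyclic.
#' @param nodes Character vector of node names (defaults to those appearing
#'   in `edges`).
#' @param noise_sd Per-node Gaussian noise SD (recycled; default 1).
#' @return Object of class `"bn_dag"` with a topological node order.
#' @export
bn_dag <- function(edges, nodes = NULL, noise_sd = 1) {
  if (is.null(edges)) edges <- data.frame(from = character(), to = character())
  if (is.null(edges$coef)) edges$coef <- rep(1, nrow(edges))
  if (any(!is.finite(edges$coef))) stop("all linear coefficients must be finite")
  nodes <- nodes %||% unique(c(edges$from, edges$to))
  if (any(noise_sd <= 0)) stop("noise variances must be positive")
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = TRUE,
                                     vertices = data.frame(name = nodes))
  if (!igraph::is_acyclic(g)) stop("cyclic structure: a Bayesian network must be acyclic")
  order <- names(igraph::topo_sort(g, mode = "out"))
  structure(list(nodes = nodes, edges = edges,
                 noise_sd = setNames(rep_len(noise_sd, length(nodes)), nodes),
                 topo_order = order), class = "bn_dag")
}

#' Random linear-Gaussian DAG
#'
#' Edges are placed independently with probability `edge_prob` respecting a
#' random topological order; coefficients are drawn uniformly from
#' `coef_range` with random sign.
#'
#' @param n_nodes Number of variables.
#' @param edge_prob Edge probability between ordered pairs.
#' @param coef_range Magnitude range of linear coefficients.
#' @param seed Integer RNG seed.
#' @return A [bn_dag()].
#' @export
generate_bn_dag <- function(n_nodes, edge_prob = 0.2, coef_range = c(0.5, 1.5),
                            seed = NULL) {
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
    warning("no seed supplied; using generated seed ", seed)
  }
  set.seed(seed)
  nodes <- sprintf("V%02d", seq_len(n_nodes))
  order <- sample(nodes)
  from <- character(); to <- character()
  for (i in seq_len(n_nodes - 1L)) for (j in seq((i + 1L), n_nodes)) {
    if (runif(1) < edge_prob) { from <- c(from, order[i]); to <- c(to, order[j]) }
  }
  coefs <- runif(length(from), coef_range[1], coef_range[2]) *
    sample(c(-1, 1), length(from), replace = TRUE)
  bn_dag(data.frame(from = from, to = to, coef = coefs, stringsAsFactors = FALSE),
         nodes = nodes)
}

#' Sample observations from a linear-Gaussian Bayesian network
#'
#' Each variable equals the stated linear combination of its parents plus
#' Gaussian noise, generated in topological order.
#'
#' @param dag A [bn_dag()].
#' @param n_obs Number of observations.
#' @param seed Integer RNG seed.
#' @return Numeric matrix, `n_obs` rows by one column per variable.
#' @export
generate_bn_data <- function(dag, n_obs, seed = NULL) {
  stopifnot(inherits(dag, "bn_dag"))
  if (n_obs < 1) stop("n_obs must be positive")
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
    warning("no seed supplied; using generated seed ", seed)
  }
  set.seed(seed)
  X <- matrix(0, n_obs, length(dag$nodes), dimnames = list(NULL, dag$nodes))
  for (v in dag$topo_order) {
    x <- rnorm(n_obs, sd = dag$noise_sd[[v]])
    inc <- dag$edges[dag$edges$to == v, , drop = FALSE]
    for (k in seq_len(nrow(inc))) x <- x + inc$coef[k] * X[, inc$from[k]]
    X[, v] <- x
  }
  X
}

#' d-separation oracle: the true Markov blanket of a DAG node
#'
#' Parents, children, and spouses (other parents of common children) read
#' directly off the generating structure.
#'
#' @param dag A [bn_dag()].
#' @param target Node name.
#' @return Character vector of blanket members.
#' @export
true_markov_blanket <- function(dag, target) {
  stopifnot(target %in% dag$nodes)
  parents <- dag$edges$from[dag$edges$to == target]
  children <- dag$edges$to[dag$edges$from == target]
  spouses <- dag$edges$from[dag$edges$to %in% children]
  setdiff(unique(c(parents, children, spouses)), target)
}

#' Generate gene sets with planted enrichment positives
#'
#' One set per simulated module (so enrichment testing has a planted
#' positive), plus `n_sets - n_modules` decoy sets drawn from background
#' genes.  `overlap_frac` contaminates each module set with that fraction of
#' extra genes drawn from outside the module.
#'
#' @param truth Ground truth from [generate_modular_expression()].
#' @param n_sets Total number of sets (>= number of modules).
#' @param overlap_frac Fraction in `[0, 1)` of extra out-of-module members
#'   added to each module set.
#' @param include_leaves Add each hub's star leaves to its module's set
#'   (default `FALSE`: a set is exactly one module's genes).  Process sets
#'   that include the hub neighborhood make the extracted subnetwork retain
#'   the planted star, which is how the hub-degree/centrality tables come
#'   out star-shaped.
#' @param seed Integer RNG seed.
#' @return A [gene_sets()] collection.
#' @export
generate_gene_sets <- function(truth, n_sets = NULL, overlap_frac = 0,
                               include_leaves = FALSE, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  n_modules <- length(truth$hubs)
  n_sets <- n_sets %||% (n_modules + 5L)
  if (n_sets < n_modules) stop("n_sets must be at least the number of modules")
  if (overlap_frac < 0 || overlap_frac >= 1) stop("overlap_frac must lie in [0, 1)")
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
    warning("no seed supplied; using generated seed ", seed)
  }
  set.seed(seed)
  assignment <- truth$module_assignment
  genes <- names(assignment)
  background <- genes[assignment == 0L]
  sets <- list(); desc <- character()
  for (m in seq_len(n_modules)) {
    members <- genes[assignment == m]
    if (include_leaves) members <- c(members, truth$hub_leaves[[m]])
    n_extra <- round(overlap_frac * length(members))
    if (n_extra > 0L)
      members <- c(members, sample(setdiff(genes, members), n_extra))
    nm <- sprintf("module_process_%d", m)
    sets[[nm]] <- members
    desc[nm] <- sprintf("planted set for simulated module %d", m)
  }
  size <- max(2L, round(stats::median(lengths(sets))))
  for (d in seq_len(n_sets - n_modules)) {
    nm <- sprintf("decoy_process_%d", d)
    sets[[nm]] <- sample(background, min(size, length(background)))
    desc[nm] <- "decoy set drawn from background genes"
  }
  gene_sets(sets, desc)
}

#' Serialize a ground-truth record as JSON
#' @param truth Ground truth from [generate_modular_expression()].
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(
    module_assignment = as.list(truth$module_assignment),
    hubs = truth$hubs,
    hub_leaves = truth$hub_leaves,
    true_edges = truth$true_edges,
    radiation_labels = as.list(truth$radiation_labels),
    seed = truth$config$seed), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
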