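#' Pipeline configuration
#'
#' Exactly one input source must be given: file paths (`expression`,
#' `sets`, `catalog`) or a [simulation_config()] block.  All thresholds
#' default to the documented working values (correlation p-value cut 0.0005,
#' enrichment and IAMB alpha 0.05, hub degree threshold 5).
#'
#' @param expression,sets,catalog Input file paths (expression table, GMT
#'   gene sets, gene catalog JSON / ID list).
#' @param simulation A [simulation_config()].
#' @param p_threshold,correction Passed to [build_grn()].
#' @param enrichment_alpha q-value cut for process selection.
#' @param hub_threshold,promote_radiation Passed to [detect_hubs()].
#' @param iamb_alpha Significance level for the causal stage.
#' @param ranking_label,ranking_by Passed to [build_features()] /
#'   [rank_genes()].
#' @param seed Integer seed for every random draw in the run (defaults to the
#'   simulation seed when simulating).
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(expression = NULL, sets = NULL, catalog = NULL,
                            simulation = NULL, p_threshold = 0.0005,
                            correction = "none", enrichment_alpha = 0.05,
                            hub_threshold = 5, promote_radiation = FALSE,
                            iamb_alpha = 0.05, ranking_label = "radiation",
                            ranking_by = "score", seed = NULL) {
  has_files <- !is.null(expression)
  has_sim <- !is.null(simulation)
  if (has_files == has_sim)
    stop("config must name exactly one input source: ",
         "'expression' file paths or a 'simulation' block")
  if (has_sim && !inherits(simulation, "simulation_config"))
    stop("'simulation' must be a simulation_config object")
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold out of range (0,1)")
  if (enrichment_alpha <= 0 || enrichment_alpha >= 1) stop("enrichment_alpha out of range (0,1)")
  if (iamb_alpha <= 0 || iamb_alpha >= 1) stop("iamb_alpha out of range (0,1)")
  if (hub_threshold < 1) stop("hub_threshold must be >= 1")
  seed <- seed %||% (if (has_sim) simulation$seed else NULL)
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
    warning("no seed supplied; using generated seed ", seed)
  }
  structure(list(expression = expression, sets = sets, catalog = catalog,
                 simulation = simulation, p_threshold = p_threshold,
                 correction = correction, enrichment_alpha = enrichment_alpha,
                 hub_threshold = hub_threshold,
                 promote_radiation = isTRUE(promote_radiation),
                 iamb_alpha = iamb_alpha, ranking_label = ranking_label,
                 ranking_by = ranking_by, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_as_list <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$simulation)) cfg$simulation <- unclass(cfg$simulation)
  cfg
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

safe_name <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, correlation-network inference, enrichment-based
#' subnetwork extraction with hub detection, network measurement, Markov-
#' blanket causal discovery (when the replicate count admits the Fisher-z
#' test, i.e. at least 8 observations), and logistic-regression gene ranking.
#' Every intermediate artifact is persisted in `out_dir`, and a
#' `manifest.json` records the package version, the configuration, its MD5
#' hash, the seed and the MD5 of every artifact -- re-running an identical
#' configuration reproduces the manifest byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results and artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- function(...) file.path(out_dir, sprintf(...))
  stage <- "ingest"
  withCallingHandlers({
    # --- simulate / ingest -------------------------------------------------
    truth <- NULL
    if (!is.null(config$simulation)) {
      sim <- generate_modular_expression(config$simulation)
      expr <- sim$expression
      truth <- sim$truth
      sets <- generate_gene_sets(truth, include_leaves = TRUE,
                                 seed = (config$seed %% 900000000L) + 1L)
      catalog <- gene_catalog(names(truth$radiation_labels)[truth$radiation_labels])
      write_ground_truth(truth, art("ground_truth.json"))
    } else {
      expr <- read_expression(config$expression)
      sets <- read_gene_sets(config$sets)
      catalog <- if (!is.null(config$catalog)) read_gene_catalog(config$catalog)
                 else gene_catalog(character(0))
    }
    write_expression(expr, art("expression.tsv"))
    write_gene_sets(sets, art("gene_sets.gmt"))
    write_gene_catalog(catalog, art("catalog.json"))

    # --- infer -------------------------------------------------------------
    stage <- "infer"
    grn <- build_grn(expr, p_threshold = config$p_threshold,
                     correction = config$correction)
    write_network(grn, art("network.graphml"), "graphml")

    # --- enrich + extract ---------------------------------------------------
    stage <- "extract"
    universe <- rownames(expr)
    enr <- enrich(grn, sets, universe = universe)
    write.table(enr, art("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    chosen <- enr$set_name[enr$q_value <= config$enrichment_alpha]
    if (length(chosen) == 0L) {
      log_msg("no set passes q <= %g; keeping the top-ranked set", config$enrichment_alpha)
      chosen <- enr$set_name[1L]
    }
    subnets <- list()
    for (nm in chosen) {
      sub <- extract_subnetwork(grn, sets[[nm]], process = nm)
      sub <- detect_hubs(sub, degree_threshold = config$hub_threshold,
                         catalog = catalog,
                         promote_radiation = config$promote_radiation)
      subnets[[nm]] <- sub
      write_network(sub, art("subnetwork_%s.graphml", safe_name(nm)), "graphml")
    }

    # --- measure -------------------------------------------------------------
    stage <- "measure"
    measures <- list(); summaries <- list()
    for (nm in names(subnets)) {
      measures[[nm]] <- centrality_features(subnets[[nm]])
      write.table(measures[[nm]], art("measures_%s.tsv", safe_name(nm)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summaries[[nm]] <- network_summary(subnets[[nm]])
      summaries[[nm]]$diameter <- unbox_inf(summaries[[nm]]$diameter)
      write_json_file(summaries[[nm]], art("summary_%s.json", safe_name(nm)))
    }

    # --- causal --------------------------------------------------------------
    stage <- "causal"
    causal <- NULL
    hubs_all <- unique(unlist(lapply(subnets, igraph::graph_attr, "hubs")))
    if (ncol(expr) >= 8L && length(hubs_all) > 0L) {
      data <- t(expr)
      targets <- head(sort(hubs_all), 10L)
      causal <- causal_network(data, targets, alpha = config$iamb_alpha,
                               catalog = catalog)
      write_network(causal$graph, art("causal_network.graphml"), "graphml")
      write_json_file(list(
        targets = targets,
        blankets = lapply(causal$blankets, function(b)
          list(blanket = b$blanket, roles = as.list(b$roles))),
        one_to_one = causal$one_to_one), art("markov_blankets.json"))
    } else {
      log_msg("causal stage skipped: needs >= 8 replicate observations and a non-empty hub set")
    }

    # --- rank ----------------------------------------------------------------
    stage <- "rank"
    rankings <- list()
    for (nm in names(subnets)) {
      ft <- tryCatch(build_features(subnets[[nm]], measures = measures[[nm]],
                                    catalog = catalog,
                                    label = config$ranking_label),
                     error = function(e) {
                       log_msg("ranking skipped for '%s': %s", nm, conditionMessage(e))
                       NULL
                     })
      if (is.null(ft)) next
      model <- fit_logistic(ft)
      rankings[[nm]] <- rank_genes(model, ft, by = config$ranking_by,
                                   catalog = catalog)
      write.table(rankings[[nm]], art("ranking_%s.tsv", safe_name(nm)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }

    # --- manifest ------------------------------------------------------------
    stage <- "manifest"
    cfg_path <- art("config.json")
    write_json_file(config_as_list(config), cfg_path)
    artifacts <- sort(setdiff(list.files(out_dir), "manifest.json"))
    manifest <- list(
      package = "radgrn",
      version = as.character(utils::packageVersion("radgrn")),
      seed = config$seed,
      config_md5 = unname(tools::md5sum(cfg_path)),
      stages = list(causal_run = !is.null(causal)),
      artifacts = as.list(setNames(unname(tools::md5sum(file.path(out_dir, artifacts))),
                                   artifacts)))
    write_json_file(manifest, art("manifest.json"))

    invisible(list(dir = out_dir, expression = expr, truth = truth,
                   network = grn, enrichment = enr, subnetworks = subnets,
                   measures = measures, summaries = summaries, causal = causal,
                   rankings = rankings, manifest = manifest))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

# JSON has no Inf; serialize as the string "Inf".
unbox_inf <- function(x) if (is.infinite(x)) "Inf" else x

#' Tabular report over a completed run directory
#'
#' Re-reads the persisted artifacts and writes three report tables mirroring
#' the usual presentation: per-hub degree and subgraph centrality per
#' subnetwork (`report_hubs.tsv`), per-subnetwork topological/spectral
#' summary (`report_summary.tsv`), and cross-subnetwork Jaccard similarity of
#' shared hub genes (`report_jaccard.tsv`, empty when fewer than two
#' subnetworks exist).
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @return List of the three data frames, invisibly written as TSV.
#' @export
pipeline_report <- function(run_dir) {
  if (!file.exists(file.path(run_dir, "manifest.json")))
    warning("run directory has no manifest; reporting whatever artifacts exist")
  sub_files <- list.files(run_dir, pattern = "^subnetwork_.*\\.graphml$",
                          full.names = TRUE)
  subnets <- lapply(sub_files, read_network)
  names(subnets) <- vapply(subnets, function(g)
    igraph::graph_attr(g, "process") %||% "unnamed", character(1))

  hub_rows <- list(); sum_rows <- list()
  for (nm in names(subnets)) {
    g <- subnets[[nm]]
    hubs <- strsplit(igraph::graph_attr(g, "hubs") %||% "", " ")[[1]]
    sc <- subgraph_centrality(g)
    deg <- igraph::degree(g, mode = "all")
    if (length(hubs) && any(nzchar(hubs)))
      hub_rows[[nm]] <- data.frame(subnetwork = nm, gene = hubs,
                                   degree = as.integer(deg[hubs]),
                                   subgraph_centrality = round(as.numeric(sc[hubs]), 4),
                                   stringsAsFactors = FALSE)
    s <- network_summary(g)
    sum_rows[[nm]] <- data.frame(subnetwork = nm,
                                 spectral_gap_adjacency = s$spectral_gap_adjacency,
                                 spectral_gap_normalized = s$spectral_gap_normalized,
                                 density = s$density, diameter = s$diameter,
                                 avg_shortest_path = s$avg_shortest_path,
                                 n_components = s$n_components,
                                 stringsAsFactors = FALSE)
  }
  hub_table <- if (length(hub_rows)) do.call(rbind, hub_rows) else
    data.frame(subnetwork = character(), gene = character(),
               degree = integer(), subgraph_centrality = numeric())
  summary_table <- if (length(sum_rows)) do.call(rbind, sum_rows) else
    data.frame()

  jac_rows <- list()
  nms <- names(subnets)
  if (length(nms) >= 2L) {
    for (i in seq_len(length(nms) - 1L)) for (j in seq((i + 1L), length(nms))) {
      shared <- intersect(igraph::V(subnets[[i]])$name, igraph::V(subnets[[j]])$name)
      for (g in shared) {
        jp <- suppressWarnings(
          jaccard_similarity(subnets[[i]], g, subnets[[j]], g))
        jac_rows[[paste(i, j, g)]] <- data.frame(
          gene = g, subnetwork_a = nms[i], subnetwork_b = nms[j],
          jaccard = jp$index, stringsAsFactors = FALSE)
      }
    }
  }
  jaccard_table <- if (length(jac_rows)) do.call(rbind, jac_rows) else
    data.frame(gene = character(), subnetwork_a = character(),
               subnetwork_b = character(), jaccard = numeric())

  for (pair in list(list(hub_table, "report_hubs.tsv"),
                    list(summary_table, "report_summary.tsv"),
                    list(jaccard_table, "report_jaccard.tsv")))
    write.table(pair[[1]], file.path(run_dir, pair[[2]]), sep = "\t",
                quote = FALSE, row.names = FALSE)
  list(hubs = hub_table, summary = summary_table, jaccard = jaccard_table)
}
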