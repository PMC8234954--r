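#' Read a gene expression matrix from delimited text
#'
#' Expects a header row of sample names and gene identifiers in the first
#' column (AGI form `ATnGnnnnn`, any case; upper-cased on ingest).  Rows with
#' missing values are dropped and reported; duplicated gene identifiers are an
#' error, as is a table with fewer than three samples (the correlation t-test
#' needs `n - 2 >= 1`).
#'
#' @param path Path to a TSV or CSV file.
#' @param delimiter `"auto"` (default, sniffed from the header), `"tab"` or
#'   `"comma"`.
#' @return Numeric matrix, genes in rows (rownames = gene IDs), samples in
#'   columns (colnames = sample IDs).
#' @export
read_expression <- function(path, delimiter = c("auto", "tab", "comma")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop("expression file not found: ", path)
  sep <- switch(delimiter, auto = "auto", tab = "\t", comma = ",")
  dt <- data.table::fread(path, sep = sep, header = TRUE, fill = FALSE,
                          data.table = FALSE, check.names = FALSE)
  if (ncol(dt) < 2L) stop("unparseable expression table (need gene column + samples): ", path)
  genes <- toupper(as.character(dt[[1L]]))
  values <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric expression values in ", path)
  rownames(values) <- genes
  validate_expression(values)
}

#' @noRd
validate_expression <- function(values) {
  if (ncol(values) < 3L)
    stop("expression matrix must have at least 3 samples (has ", ncol(values), ")")
  genes <- rownames(values)
  if (is.null(genes)) stop("expression matrix must carry gene IDs as rownames")
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in expression matrix")
  bad <- !is_agi(genes)
  if (any(bad))
    log_msg("%d gene identifier(s) do not match the AGI pattern (kept as-is)", sum(bad))
  keep <- complete.cases(values)
  if (!all(keep)) {
    log_msg("dropped %d gene row(s) with missing values", sum(!keep))
    values <- values[keep, , drop = FALSE]
  }
  storage.mode(values) <- "double"
  values
}

#' Write an expression matrix as delimited text
#'
#' First column `gene_id`, then one column per sample.  Full double precision
#' is preserved, so write/read round-trips are exact.
#'
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param delimiter `"tab"` (default) or `"comma"`.
#' @export
write_expression <- function(expr, path, delimiter = c("tab", "comma")) {
  delimiter <- match.arg(delimiter)
  sep <- if (delimiter == "tab") "\t" else ","
  df <- data.frame(gene_id = rownames(expr),
                   format(expr, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(expr))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: `name TAB description TAB member TAB member ...`.
#' Member identifiers are upper-cased and de-duplicated; lines with no members
#' are skipped with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (one per set) with a
#'   `"descriptions"` attribute (named character vector), class `"gene_sets"`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("gene-set file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    members <- unique(toupper(parts[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(parts) < 3L || length(members) == 0L) {
      warning("skipping empty gene set line: ", parts[1L])
      next
    }
    sets[[parts[1L]]] <- members
    desc[parts[1L]] <- parts[2L]
  }
  gene_sets(sets, desc)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene IDs.
#' @param descriptions Optional named character vector of set descriptions.
#' @return Object of class `"gene_sets"`.
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (length(sets) == 0L || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("gene sets must be a non-empty named list")
  sets <- lapply(sets, function(g) unique(toupper(g)))
  if (any(lengths(sets) == 0L)) stop("every gene set must be non-empty")
  if (is.null(descriptions)) descriptions <- setNames(rep("", length(sets)), names(sets))
  attr(sets, "descriptions") <- descriptions[names(sets)]
  class(sets) <- "gene_sets"
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets A `"gene_sets"` object (or named list of gene ID vectors).
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a gene catalog
#'
#' A catalog records which genes carry the binary "radiation-induced" label
#' (the experimentally determined ATR/ATM-responsive set) and optional display
#' names.
#'
#' @param radiation_induced Character vector of gene IDs.
#' @param display_name Optional named character vector (gene ID -> short name).
#' @param universe Optional gene universe; if given, `radiation_induced` must
#'   be contained in it.
#' @return Object of class `"gene_catalog"`.
#' @export
gene_catalog <- function(radiation_induced, display_name = NULL, universe = NULL) {
  radiation_induced <- unique(toupper(radiation_induced))
  if (!is.null(universe) && !all(radiation_induced %in% toupper(universe)))
    stop("radiation-induced genes outside the supplied gene universe")
  structure(list(radiation_induced = radiation_induced,
                 display_name = display_name),
            class = "gene_catalog")
}

#' Read a gene catalog from JSON or a flat ID list
#'
#' JSON files must contain a `radiation_induced` array (and optionally a
#' `display_name` object); any other extension is read as one gene ID per line.
#'
#' @param path Input path.
#' @return A [gene_catalog()].
#' @export
read_gene_catalog <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    gene_catalog(obj$radiation_induced, display_name = obj$display_name)
  } else {
    gene_catalog(readLines(path, warn = FALSE))
  }
}

#' Write a gene catalog as JSON
#' @param catalog A [gene_catalog()].
#' @param path Output path.
#' @export
write_gene_catalog <- function(catalog, path) {
  jsonlite::write_json(list(radiation_induced = catalog$radiation_induced,
                            display_name = catalog$display_name),
                       path, auto_unbox = FALSE, pretty = TRUE, null = "null")
  invisible(path)
}

#' Export a gene network
#'
#' GraphML keeps the correlation weight as an edge attribute named `weight`
#' and the directedness flag on the graph element.  The edge-list dialect is
#' `source TAB target TAB weight` with the weight printed to 6 decimals.
#'
#' @param network An `igraph` network with a `name` vertex attribute.
#' @param path Output path.
#' @param format `"graphml"` or `"edgelist"`.
#' @export
write_network <- function(network, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    # GraphML attributes must be scalar strings/numbers: collapse vector
    # graph attributes (e.g. the hub set) and cast logicals to 0/1
    for (a in igraph::graph_attr_names(network)) {
      v <- igraph::graph_attr(network, a)
      if (length(v) != 1L)
        network <- igraph::set_graph_attr(network, a, paste(v, collapse = " "))
    }
    for (a in igraph::vertex_attr_names(network)) {
      v <- igraph::vertex_attr(network, a)
      if (is.logical(v))
        network <- igraph::set_vertex_attr(network, a, value = as.integer(v))
    }
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(network, names = TRUE)
    w <- igraph::edge_attr(network, "weight") %||% rep(1, nrow(el))
    lines <- if (nrow(el)) sprintf("%s\t%s\t%.6f", el[, 1], el[, 2], w) else character()
    writeLines(c("source\ttarget\tweight", lines), path)
  }
  invisible(path)
}

#' Import a gene network written by [write_network()]
#'
#' @param path Input path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return An `igraph` network.
#' @export
read_network <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
  } else {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) < 1L || lines[1L] != "source\ttarget\tweight")
      stop("not a radgrn edge-list file: ", path)
    if (length(lines) == 1L) {
      g <- igraph::make_empty_graph(directed = FALSE)
    } else {
      df <- read.table(text = lines[-1L], sep = "\t",
                       col.names = c("source", "target", "weight"),
                       stringsAsFactors = FALSE)
      g <- igraph::graph_from_data_frame(df, directed = FALSE)
    }
  }
  g
}
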