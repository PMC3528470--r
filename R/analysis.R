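# Structural interrogation of estimated or ground-truth graphs.

#' Nodes of degree zero
#' @param g An igraph object (estimated or ground-truth graph).
#' @return Character vector of isolated node names, in node order.
#' @export
isolated_nodes <- function(g) {
  igraph::V(g)$name[igraph::degree(g) == 0]
}

#' Connected components as a partition of the node set
#' @param g An igraph object.
#' @return List of character vectors, one per component, ordered by the
#'   smallest member; nodes sorted within each component.
#' @export
connected_components <- function(g) {
  comp <- igraph::components(g)
  out <- split(igraph::V(g)$name, comp$membership)
  out <- lapply(out, sort)
  names(out) <- NULL
  out[order(vapply(out, `[`, "", 1))]
}

#' Enumerate simple paths between two nodes
#'
#' All simple paths from `source` to `sink` with at most `max_len` edges,
#' in deterministic order (shorter first, then lexicographic on the joined
#' node sequence).
#'
#' @param g An igraph object.
#' @param source,sink Distinct node names.
#' @param max_len Maximum path length in edges; default 10.
#' @return List of character vectors (node sequences including endpoints).
#' @export
enumerate_paths <- function(g, source, sink, max_len = 10) {
  if (identical(source, sink)) stop("source and sink must differ", call. = FALSE)
  check_nodes(g, c(source, sink))
  paths <- igraph::all_simple_paths(g, from = source, to = sink,
                                    cutoff = max_len)
  paths <- lapply(paths, function(p) igraph::V(g)$name[as.integer(p)])
  key <- vapply(paths, paste, "", collapse = "\r")
  paths[order(lengths(paths), key)]
}

check_nodes <- function(g, nodes) {
  unknown <- setdiff(nodes, igraph::V(g)$name)
  if (length(unknown))
    stop("unknown node: ", paste(unknown, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Adjacency and separation report for node pairs
#'
#' For each pair, reports whether the nodes are adjacent; for non-adjacent
#' connected pairs, whether every connecting path intersects the node set
#' `through` (checked by deleting `through` and testing reachability), and
#' the simple paths up to `max_len`.
#'
#' @param g An igraph object.
#' @param pairs Two-column character matrix or data frame of node pairs.
#' @param through Optional character vector: the candidate separating set.
#' @param max_len Path-length cap for the enumerated paths; default 10.
#' @return Data frame of class `separation_report` with one row per pair and
#'   columns `a`, `b`, `adjacent`, `connected`, `n_paths`,
#'   `all_paths_through` (NA when `through` is NULL or the pair is adjacent
#'   or disconnected); the enumerated paths are in `attr(, "paths")`.
#' @export
separation_report <- function(g, pairs, through = NULL, max_len = 10) {
  pairs <- as.matrix(pairs)
  check_nodes(g, unique(c(pairs)))
  if (!is.null(through)) check_nodes(g, through)
  rows <- vector("list", nrow(pairs))
  all_paths <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    adjacent <- igraph::are_adjacent(g, a, b)
    dist <- igraph::distances(g, v = a, to = b)[1, 1]
    connected <- is.finite(dist)
    paths <- if (!adjacent && connected) enumerate_paths(g, a, b, max_len) else list()
    apt <- NA
    if (!adjacent && connected && !is.null(through)) {
      gg <- igraph::delete_vertices(g, setdiff(through, c(a, b)))
      apt <- !is.finite(igraph::distances(gg, v = a, to = b)[1, 1])
    }
    rows[[i]] <- data.frame(a = a, b = b, adjacent = adjacent,
                            connected = connected, n_paths = length(paths),
                            all_paths_through = apt)
    all_paths[[i]] <- paths
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "paths") <- all_paths
  class(out) <- c("separation_report", class(out))
  out
}

#' Compare an estimated graph to the ground truth
#'
#' @param estimate A `cig` (or any igraph) over the same node set as `truth`.
#' @param truth A `ground_truth` (or any igraph).
#' @return List with edge counts `tp`, `fp`, `fn`, `tn`, and `precision` /
#'   `recall` (NA when undefined).
#' @export
compare_graphs <- function(estimate, truth) {
  ve <- sort(igraph::V(estimate)$name)
  vt <- sort(igraph::V(truth)$name)
  if (!identical(ve, vt)) stop("node sets differ between estimate and truth",
                               call. = FALSE)
  ekeys <- function(g) {
    em <- edge_matrix(g)
    if (!nrow(em)) character(0) else paste(em[, 1], em[, 2], sep = "|")
  }
  est <- ekeys(estimate); tru <- ekeys(truth)
  p <- length(ve)
  total <- p * (p - 1) / 2
  tp <- length(intersect(est, tru))
  fp <- length(setdiff(est, tru))
  fn <- length(setdiff(tru, est))
  tn <- total - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Macro-removal sensitivity check
#'
#' Estimates the graph twice with matched seeds — once on all variables and
#' once with the three canton-level macro indicators removed — and reports
#' the symmetric difference of the micro-level edge sets. The published
#' claim is that removing the macro variables leaves the connectivity of
#' the micro-level component unchanged.
#'
#' @param tab A `modeling_table` including the macro columns.
#' @param macro Names of the macro variables to remove.
#' @param ... Passed to [estimate_graph()] (scheme, bounds, control,
#'   pi_thr, seed).
#' @return List with both graphs, the micro edge sets, their symmetric
#'   difference (`added` / `removed` relative to the full model) and the
#'   flag `unchanged`.
#' @export
macro_sensitivity <- function(tab, macro = c("canton_gdp", "canton_gini",
                                             "canton_crime"), ...) {
  vars <- modeling_vars(tab)
  miss <- setdiff(macro, vars)
  if (length(miss))
    stop("table lacks macro columns: ", paste(miss, collapse = ", "), call. = FALSE)
  g_full <- estimate_graph(tab, ..., keep_stability = FALSE)
  sc <- attr(tab, "scales")
  tab2 <- as.data.frame(tab)[, c(setdiff(vars, macro),
                                 intersect("canton_id", names(tab)))]
  if (!is.null(sc))
    tab2 <- structure(tab2, scales = sc[setdiff(vars, macro)],
                      class = c("modeling_table", "data.frame"))
  g_red <- estimate_graph(tab2, ..., keep_stability = FALSE)
  micro_keys <- function(g) {
    em <- edge_matrix(g)
    if (!nrow(em)) return(character(0))
    keep <- !(em[, 1] %in% macro) & !(em[, 2] %in% macro)
    paste(em[keep, 1], em[keep, 2], sep = "|")
  }
  full_micro <- micro_keys(g_full)
  red_micro <- micro_keys(g_red)
  list(full = g_full, reduced = g_red,
       micro_edges_full = sort(full_micro),
       micro_edges_reduced = sort(red_micro),
       added = sort(setdiff(red_micro, full_micro)),
       removed = sort(setdiff(full_micro, red_micro)),
       unchanged = setequal(full_micro, red_micro))
}

#' Write a graph to GraphML, DOT or an edge-list CSV
#'
#' @param g An igraph object (`cig` or `ground_truth`).
#' @param path Output file path.
#' @param format `"graphml"`, `"dot"` or `"csv"` (edge list with min-bound
#'   and frequency columns when present); default inferred from the file
#'   extension.
#' @return `path`, invisibly.
#' @export
write_cig <- function(g, path, format = c("auto", "graphml", "dot", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, graphml = "graphml", dot = "dot", gv = "dot",
                     csv = "csv",
                     stop("cannot infer graph format from extension: ", ext,
                          call. = FALSE))
  }
  gg <- g
  class(gg) <- "igraph"
  if (!is.null(igraph::graph_attr(gg, "stability")))
    gg <- igraph::delete_graph_attr(gg, "stability")
  ord <- igraph::graph_attr(gg, "generation_order")
  if (!is.null(ord) && length(ord) > 1)   # GraphML attributes are scalar
    gg <- igraph::set_graph_attr(gg, "generation_order",
                                 paste(ord, collapse = ","))
  for (a in igraph::vertex_attr_names(gg))   # DOT has no boolean type
    if (is.logical(igraph::vertex_attr(gg, a)))
      gg <- igraph::set_vertex_attr(gg, a,
                                    value = as.integer(igraph::vertex_attr(gg, a)))
  if (format == "csv") {
    if (inherits(g, "cig") && !is.null(igraph::edge_attr(g, "min_bound"))) {
      e <- edge_table(g)
      names(e) <- c("node_a", "node_b", "min_bound", "frequency")
    } else {
      em <- edge_matrix(g)
      e <- data.frame(node_a = em[, 1], node_b = em[, 2])
    }
    utils::write.csv(e, path, row.names = FALSE)
  } else {
    igraph::write_graph(gg, path, format = format)
  }
  invisible(path)
}

#' Read a ground-truth graph from GraphML
#'
#' The generation order is taken from the graph attribute
#' `generation_order` (a comma-separated string or vector) when present,
#' otherwise recomputed.
#'
#' @param path GraphML file.
#' @return A `ground_truth` graph.
#' @export
read_truth_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ord <- igraph::graph_attr(g, "generation_order")
  if (!is.null(ord) && length(ord) == 1 && grepl(",", ord))
    ord <- strsplit(ord, ",")[[1]]
  ground_truth_graph(igraph::as_edgelist(g), nodes = igraph::V(g)$name,
                     generation_order = ord)
}
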