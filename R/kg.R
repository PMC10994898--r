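#' Build a knowledge graph from an edge list
#'
#' @param edges Data frame with columns `source`, `relation`, `target`.
#'   Duplicate (source, relation, target) triples are collapsed. Path search
#'   treats the graph as undirected and unweighted; the relation string is
#'   kept as an edge annotation only.
#' @param node_types Optional data frame with columns `id` and `type`
#'   (`gene`, `process`, `disease`, `other`); nodes without a type get
#'   `"other"`.
#' @return An undirected `igraph` object with vertex attribute `type` and
#'   edge attribute `relation`.
#' @export
kg_from_edges <- function(edges, node_types = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("source", "relation", "target") %in% names(edges)))
  edges <- dplyr::distinct(edges, .data$source, .data$relation, .data$target)
  ids <- unique(c(edges$source, edges$target))
  vdf <- data.frame(name = ids, type = "other", stringsAsFactors = FALSE)
  if (!is.null(node_types)) {
    node_types <- as.data.frame(node_types)
    idx <- match(vdf$name, node_types$id)
    vdf$type[!is.na(idx)] <- node_types$type[idx[!is.na(idx)]]
  }
  igraph::graph_from_data_frame(
    data.frame(from = edges$source, to = edges$target,
               relation = edges$relation),
    directed = FALSE, vertices = vdf
  )
}

#' Read a knowledge graph from TSV files
#'
#' @param edge_path Three-column TSV (source, relation, target), with header.
#' @param node_type_path Optional two-column TSV (id, type), with header.
#' @return An igraph knowledge graph (see [kg_from_edges()]).
#' @export
read_kg <- function(edge_path, node_type_path = NULL) {
  edges <- utils::read.delim(edge_path, stringsAsFactors = FALSE)
  names(edges)[1:3] <- c("source", "relation", "target")
  types <- NULL
  if (!is.null(node_type_path)) {
    types <- utils::read.delim(node_type_path, stringsAsFactors = FALSE)
    names(types)[1:2] <- c("id", "type")
  }
  kg_from_edges(edges, types)
}

#' Depth-bounded neighborhood of seed nodes
#'
#' Induced subgraph on all nodes whose hop distance from any seed is at most
#' `max_depth`.
#'
#' @param graph An igraph knowledge graph.
#' @param seeds Character vector of node identifiers.
#' @param max_depth Connectivity depth in hops (default 3).
#' @return The induced igraph subgraph (relations preserved).
#' @export
kg_neighborhood <- function(graph, seeds, max_depth = 3L) {
  stopifnot(igraph::is_igraph(graph), max_depth >= 0)
  known <- igraph::V(graph)$name
  missing <- setdiff(seeds, known)
  if (length(missing) > 0) {
    stop("unknown seed node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d <- igraph::distances(graph, v = seeds, mode = "all")
  keep <- known[apply(d, 2, min) <= max_depth]
  igraph::induced_subgraph(graph, keep)
}

#' Shortest-path bridge from a process to two diseases
#'
#' Extracts the union of all shortest paths from a biological-process node to
#' each of two disease nodes (unweighted, undirected), as the induced
#' subgraph with the original relations. When a disease is unreachable, the
#' reachable half is returned with a warning.
#'
#' @param graph An igraph knowledge graph.
#' @param process,disease_a,disease_b Node identifiers.
#' @return Induced igraph subgraph on all nodes lying on a shortest
#'   process-to-disease path.
#' @export
kg_process_bridge <- function(graph, process, disease_a, disease_b) {
  stopifnot(igraph::is_igraph(graph))
  known <- igraph::V(graph)$name
  missing <- setdiff(c(process, disease_a, disease_b), known)
  if (length(missing) > 0) {
    stop("unknown node(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  half <- function(target) {
    d <- igraph::distances(graph, v = process, to = target, mode = "all")
    if (!is.finite(d[1, 1])) {
      warning(sprintf("%s is unreachable from %s", target, process),
              call. = FALSE)
      return(character(0))
    }
    paths <- igraph::all_shortest_paths(graph, from = process, to = target,
                                        mode = "all")$vpaths
    unique(unlist(lapply(paths, function(p) igraph::V(graph)$name[p])))
  }
  nodes <- unique(c(half(disease_a), half(disease_b)))
  if (length(nodes) == 0) nodes <- process
  igraph::induced_subgraph(graph, intersect(known, nodes))
}

#' Write a knowledge (sub)graph as a TSV edge list
#'
#' @param graph An igraph knowledge graph.
#' @param path Output TSV (source, relation, target).
#' @return The edge tibble, invisibly.
#' @export
write_kg <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  out <- tibble::tibble(source = el$from,
                        relation = if ("relation" %in% names(el)) el$relation else "",
                        target = el$to)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
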