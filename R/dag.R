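#' Directed acyclic graph over a node set
#'
#' Light container for the causal structure: a node set plus a tibble of arcs
#' `(from, to)`. Construction validates that every endpoint exists, that there
#' are no self-loops, and that the graph is acyclic.
#'
#' @param nodes Node-set tibble, e.g. [canonical_nodes()].
#' @param arcs Tibble or data frame with character columns `from` and `to`;
#'   may have zero rows.
#' @return An object of class `bn_dag`.
#' @export
bn_dag <- function(nodes, arcs = tibble::tibble(from = character(), to = character())) {
  validate_nodes(nodes)
  arcs <- tibble::as_tibble(arcs)
  if (!all(c("from", "to") %in% names(arcs))) {
    abort_escbn("`arcs` needs columns `from` and `to`.", "escbn_structure_error")
  }
  arcs <- tibble::tibble(from = as.character(arcs$from), to = as.character(arcs$to))
  bad <- setdiff(unique(c(arcs$from, arcs$to)), nodes$node_id)
  if (length(bad)) {
    abort_escbn(
      sprintf("Arc endpoint(s) not in node set: %s", paste(bad, collapse = ", ")),
      "escbn_structure_error"
    )
  }
  loops <- arcs$from == arcs$to
  if (any(loops)) {
    abort_escbn(
      sprintf("Self-loop on node '%s'.", arcs$from[which(loops)[1]]),
      "escbn_structure_error"
    )
  }
  arcs <- dplyr::distinct(arcs)
  g <- igraph::graph_from_data_frame(
    arcs, directed = TRUE,
    vertices = data.frame(name = nodes$node_id)
  )
  if (!igraph::is_dag(g)) {
    abort_escbn("Arc set contains a directed cycle.", "escbn_structure_error")
  }
  structure(list(nodes = nodes, arcs = arcs), class = "bn_dag")
}

#' @export
print.bn_dag <- function(x, ...) {
  cat(sprintf("<bn_dag> %d nodes, %d arcs\n", nrow(x$nodes), nrow(x$arcs)))
  if (nrow(x$arcs)) {
    print(x$arcs, n = Inf)
  }
  invisible(x)
}

#' @method tidy bn_dag
#' @export
tidy.bn_dag <- function(x, ...) {
  dplyr::mutate(
    x$arcs,
    from_tier = vapply(.data$from, function(v) tier_of(x$nodes, v), integer(1)),
    to_tier = vapply(.data$to, function(v) tier_of(x$nodes, v), integer(1))
  )
}

parents_of <- function(dag, node) {
  dag$arcs$from[dag$arcs$to == node]
}

children_of <- function(dag, node) {
  dag$arcs$to[dag$arcs$from == node]
}

topo_order <- function(dag) {
  g <- igraph::graph_from_data_frame(
    dag$arcs, directed = TRUE,
    vertices = data.frame(name = dag$nodes$node_id)
  )
  as.character(igraph::topo_sort(g)$name)
}

# Sub-DAG spanned by a node set and all of its ancestors.
ancestral_dag <- function(dag, nodes_wanted) {
  keep <- unique(nodes_wanted)
  repeat {
    more <- unique(dag$arcs$from[dag$arcs$to %in% keep])
    new <- setdiff(more, keep)
    if (!length(new)) break
    keep <- c(keep, new)
  }
  bn_dag(
    dag$nodes[dag$nodes$node_id %in% keep, , drop = FALSE],
    dag$arcs[dag$arcs$to %in% keep & dag$arcs$from %in% keep, , drop = FALSE]
  )
}

#' Write / read a DAG as JSON
#'
#' The format is `{nodes: [...], arcs: [{from, to}]}` with nodes carrying
#' `node_id`, `label`, `tier` and `states`.
#'
#' @param dag A `bn_dag`.
#' @param path File path.
#' @return `write_dag_json()` returns `path` invisibly; `read_dag_json()`
#'   returns a `bn_dag`.
#' @export
write_dag_json <- function(dag, path) {
  payload <- list(
    nodes = lapply(seq_len(nrow(dag$nodes)), function(i) {
      list(
        node_id = dag$nodes$node_id[[i]],
        label = dag$nodes$label[[i]],
        tier = dag$nodes$tier[[i]],
        states = dag$nodes$states[[i]]
      )
    }),
    arcs = lapply(seq_len(nrow(dag$arcs)), function(i) {
      list(from = dag$arcs$from[[i]], to = dag$arcs$to[[i]])
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dag_json
#' @export
read_dag_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  nodes <- tibble::tibble(
    node_id = vapply(raw$nodes, `[[`, character(1), "node_id"),
    label = vapply(raw$nodes, `[[`, character(1), "label"),
    tier = vapply(raw$nodes, function(x) as.integer(x$tier), integer(1)),
    states = lapply(raw$nodes, function(x) as.character(unlist(x$states)))
  )
  arcs <- tibble::tibble(
    from = vapply(raw$arcs, `[[`, character(1), "from"),
    to = vapply(raw$arcs, `[[`, character(1), "to")
  )
  bn_dag(nodes, arcs)
}
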