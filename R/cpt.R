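#' Conditional probability table
#'
#' A CPT stores `P(child | parents)` as an array whose first dimension runs
#' over the child's states and whose remaining dimensions run over the parent
#' states; each column (fixed parent configuration) sums to 1.
#'
#' @param child Node id of the child variable.
#' @param parents Character vector of parent node ids (possibly empty).
#' @param prob Numeric array of dimension `c(card(child), cards(parents)...)`,
#'   or for a root node a probability vector over the child's states.
#' @param nodes Node-set tibble supplying the state spaces.
#' @return Object of class `bn_cpt`.
#' @export
cpt <- function(child, parents, prob, nodes) {
  validate_nodes(nodes)
  child_states <- states_of(nodes, child)
  parent_states <- lapply(parents, states_of, nodes = nodes)
  dims <- c(length(child_states), vapply(parent_states, length, integer(1)))
  prob <- array(as.numeric(prob), dim = dims,
                dimnames = c(list(child_states), parent_states))
  names(dimnames(prob)) <- c(child, parents)
  if (any(prob < -1e-12)) {
    abort_escbn(sprintf("CPT for '%s' has negative entries.", child), "escbn_cpt_error")
  }
  prob[prob < 0] <- 0
  sums <- if (length(parents) == 0L) sum(prob) else {
    apply(prob, seq_along(dims)[-1], sum)
  }
  if (any(abs(sums - 1) > 1e-9)) {
    abort_escbn(
      sprintf("CPT rows for '%s' do not sum to 1 (max deviation %.3g).",
              child, max(abs(sums - 1))),
      "escbn_cpt_error"
    )
  }
  structure(list(child = child, parents = parents, prob = prob),
            class = "bn_cpt")
}

#' Discrete Bayesian network
#'
#' Couples a [bn_dag()] with one CPT per node; the joint distribution is the
#' product of each node's CPT given its parents.
#'
#' @param dag A `bn_dag`.
#' @param cpts Named list of `bn_cpt`, one per node; each CPT's parent list
#'   must equal the node's parents in `dag`.
#' @return Object of class `discrete_bn`.
#' @export
discrete_bn <- function(dag, cpts) {
  ids <- dag$nodes$node_id
  if (!setequal(names(cpts), ids)) {
    abort_escbn("`cpts` must be a named list with exactly one CPT per node.",
                "escbn_cpt_error")
  }
  for (id in ids) {
    ct <- cpts[[id]]
    if (!inherits(ct, "bn_cpt") || ct$child != id) {
      abort_escbn(sprintf("Entry '%s' of `cpts` is not a CPT for that node.", id),
                  "escbn_cpt_error")
    }
    if (!setequal(ct$parents, parents_of(dag, id))) {
      abort_escbn(
        sprintf("CPT parents for '%s' do not match the DAG.", id),
        "escbn_cpt_error"
      )
    }
  }
  structure(list(dag = dag, cpts = cpts[ids]), class = "discrete_bn")
}

#' @export
print.discrete_bn <- function(x, ...) {
  cat(sprintf("<discrete_bn> %d nodes, %d arcs\n",
              nrow(x$dag$nodes), nrow(x$dag$arcs)))
  invisible(x)
}

#' Tidy a fitted or constructed network into one row per CPT cell
#'
#' @param x A `discrete_bn`.
#' @param ... Unused.
#' @return Tibble with columns `node`, `state`, `parents` (a `|`-separated
#'   parent configuration label, empty for roots) and `probability`.
#' @method tidy discrete_bn
#' @export
tidy.discrete_bn <- function(x, ...) {
  rows <- lapply(x$cpts, function(ct) {
    dn <- dimnames(ct$prob)
    grid <- expand.grid(dn, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    parent_lab <- if (length(ct$parents)) {
      do.call(paste, c(lapply(ct$parents, function(p) {
        paste0(p, "=", grid[[p]])
      }), sep = "|"))
    } else {
      rep("", nrow(grid))
    }
    tibble::tibble(
      node = ct$child,
      state = grid[[ct$child]],
      parents = parent_lab,
      probability = as.vector(ct$prob)
    )
  })
  dplyr::bind_rows(rows)
}

#' @method glance discrete_bn
#' @export
glance.discrete_bn <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$dag$nodes),
    n_arcs = nrow(x$dag$arcs),
    n_parameters = sum(vapply(x$cpts, function(ct) {
      p <- prod(dim(ct$prob)[-1])
      if (is.na(p)) p <- 1
      (dim(ct$prob)[1] - 1) * p
    }, numeric(1)))
  )
}

#' Write / read a network as JSON
#'
#' Format: `{structure: {nodes, arcs}, cpts: [{child, parents, rows:
#' [{parent_states, probs}]}]}`.
#'
#' @param bn A `discrete_bn`.
#' @param path File path.
#' @return `write_bn_json()` returns `path` invisibly; `read_bn_json()` a
#'   `discrete_bn`.
#' @export
write_bn_json <- function(bn, path) {
  cpt_payload <- lapply(bn$cpts, function(ct) {
    dims <- dim(ct$prob)
    n_cfg <- prod(dims[-1])
    if (is.na(n_cfg)) n_cfg <- 1L
    mat <- matrix(ct$prob, nrow = dims[1])
    cfg_grid <- if (length(ct$parents)) {
      expand.grid(dimnames(ct$prob)[-1], stringsAsFactors = FALSE,
                  KEEP.OUT.ATTRS = FALSE)
    } else {
      NULL
    }
    rows <- lapply(seq_len(n_cfg), function(j) {
      list(
        parent_states = if (is.null(cfg_grid)) list() else as.list(cfg_grid[j, , drop = FALSE]),
        probs = mat[, j]
      )
    })
    list(child = ct$child, parents = ct$parents, rows = rows)
  })
  payload <- list(
    structure = list(
      nodes = lapply(seq_len(nrow(bn$dag$nodes)), function(i) {
        list(
          node_id = bn$dag$nodes$node_id[[i]],
          label = bn$dag$nodes$label[[i]],
          tier = bn$dag$nodes$tier[[i]],
          states = bn$dag$nodes$states[[i]]
        )
      }),
      arcs = lapply(seq_len(nrow(bn$dag$arcs)), function(i) {
        list(from = bn$dag$arcs$from[[i]], to = bn$dag$arcs$to[[i]])
      })
    ),
    cpts = unname(cpt_payload)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bn_json
#' @export
read_bn_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  nodes <- tibble::tibble(
    node_id = vapply(raw$structure$nodes, `[[`, character(1), "node_id"),
    label = vapply(raw$structure$nodes, `[[`, character(1), "label"),
    tier = vapply(raw$structure$nodes, function(x) as.integer(x$tier), integer(1)),
    states = lapply(raw$structure$nodes, function(x) as.character(unlist(x$states)))
  )
  arcs_raw <- raw$structure$arcs
  arcs <- tibble::tibble(
    from = vapply(arcs_raw, `[[`, character(1), "from"),
    to = vapply(arcs_raw, `[[`, character(1), "to")
  )
  dag <- bn_dag(nodes, arcs)
  cpts <- lapply(raw$cpts, function(entry) {
    child <- entry$child
    parents <- as.character(unlist(entry$parents))
    child_states <- states_of(nodes, child)
    parent_states <- lapply(parents, states_of, nodes = nodes)
    dims <- c(length(child_states), vapply(parent_states, length, integer(1)))
    n_cfg <- prod(dims[-1])
    if (is.na(n_cfg)) n_cfg <- 1L
    mat <- matrix(NA_real_, dims[1], n_cfg)
    strides <- cumprod(c(1, utils::head(dims[-1], -1)))
    for (row in entry$rows) {
      j <- 1L
      if (length(parents)) {
        for (k in seq_along(parents)) {
          idx <- match(row$parent_states[[parents[k]]], parent_states[[k]])
          j <- j + (idx - 1L) * strides[k]
        }
      }
      mat[, j] <- as.numeric(unlist(row$probs))
    }
    cpt(child, parents, array(mat, dim = dims), nodes)
  })
  names(cpts) <- vapply(raw$cpts, `[[`, character(1), "child")
  discrete_bn(dag, cpts)
}

# Look up CPT probabilities for vectors of child/parent state indices.
# idx: integer matrix with columns named c(child, parents).
cpt_lookup <- function(ct, idx) {
  dims <- dim(ct$prob)
  cols <- c(ct$child, ct$parents)
  lin <- idx[, cols[1]]
  stride <- dims[1]
  if (length(cols) > 1) {
    for (k in 2:length(cols)) {
      lin <- lin + (idx[, cols[k]] - 1L) * stride
      stride <- stride * dims[k]
    }
  }
  ct$prob[lin]
}
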