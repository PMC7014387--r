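# Information-theoretic edge arbitration and conditional-independence pruning.
# All quantities are plug-in estimates from contingency tables, in bits.

#' Mutual information between two categorical variables
#'
#' Plug-in estimate `I(Xi; Xj) = sum p(xi, xj) log2( p(xi, xj) / (p(xi) p(xj)) )`
#' over cells with positive joint frequency. Records missing either variable
#' are dropped pairwise.
#'
#' @param data Records tibble (character columns, `NA` = missing).
#' @param xi,xj Column names.
#' @param base Logarithm base; 2 (bits) by default, matching the scale on
#'   which the 0.015 edge-retention threshold is interpreted.
#' @return Non-negative mutual information, symmetric in its arguments.
#' @export
mutual_information <- function(data, xi, xj, base = 2) {
  x <- data[[xi]]
  y <- data[[xj]]
  if (is.null(x) || is.null(y)) {
    abort_escbn("Both variables must be columns of `data`.", "escbn_data_error")
  }
  keep <- !is.na(x) & !is.na(y)
  if (!any(keep)) {
    abort_escbn(sprintf("No complete pairs for (%s, %s).", xi, xj),
                "escbn_insufficient_data")
  }
  counts <- table(x[keep], y[keep])
  mi_from_counts(counts, base)
}

mi_from_counts <- function(counts, base = 2) {
  n <- sum(counts)
  pxy <- counts / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  expected <- outer(px, py)
  pos <- pxy > 0
  max(0, sum(pxy[pos] * log(pxy[pos] / expected[pos], base = base)))
}

#' Conditional mutual information given a set of nodes
#'
#' Plug-in estimate of `I(Xi; Xj | C)` in bits, computed listwise-complete
#' over `{xi, xj} union given`. Conditioning strata with zero count contribute
#' nothing. With `given = character(0)` this reduces to
#' [mutual_information()].
#'
#' @inheritParams mutual_information
#' @param given Character vector of conditioning column names (may be empty).
#' @return Non-negative conditional mutual information in bits.
#' @export
conditional_mutual_information <- function(data, xi, xj, given = character(0),
                                           base = 2) {
  if (!length(given)) {
    return(mutual_information(data, xi, xj, base = base))
  }
  cols <- c(xi, xj, given)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort_escbn(sprintf("Column(s) not in data: %s",
                        paste(missing_cols, collapse = ", ")),
                "escbn_data_error")
  }
  sub <- data[cols]
  keep <- stats::complete.cases(sub)
  if (!any(keep)) {
    abort_escbn(sprintf("No listwise-complete records for (%s, %s | %s).",
                        xi, xj, paste(given, collapse = ",")),
                "escbn_insufficient_data")
  }
  sub <- sub[keep, , drop = FALSE]
  strat <- interaction(sub[given], drop = TRUE, sep = "\r")
  n <- nrow(sub)
  total <- 0
  for (lev in levels(strat)) {
    rows <- strat == lev
    w <- sum(rows) / n
    counts <- table(sub[[xi]][rows], sub[[xj]][rows])
    total <- total + w * mi_from_counts(counts, base)
  }
  max(0, total)
}

#' Arbitrate expert-uncertain edges by mutual information
#'
#' Candidate arcs on which the fused expert opinion remained uncertain are
#' retained when the estimated mutual information between the endpoints
#' exceeds the threshold `epsilon` (strictly), and dropped otherwise.
#'
#' @param data Records tibble.
#' @param uncertain Tibble with columns `from`, `to` listing the arcs.
#' @param epsilon Retention threshold in bits (default 0.015).
#' @return Tibble: `from`, `to`, `conditioning_set` (empty), `statistic_bits`,
#'   `threshold`, `accepted`.
#' @export
arbitrate_uncertain_edges <- function(data, uncertain, epsilon = 0.015) {
  stopifnot_scalar_number(epsilon, "epsilon", lower = 1e-12)
  rows <- lapply(seq_len(nrow(uncertain)), function(i) {
    mi <- mutual_information(data, uncertain$from[[i]], uncertain$to[[i]])
    tibble::tibble(
      from = uncertain$from[[i]], to = uncertain$to[[i]],
      conditioning_set = "", statistic_bits = mi,
      threshold = epsilon, accepted = mi > epsilon
    )
  })
  dplyr::bind_rows(rows)
}

#' Assemble the preliminary DAG
#'
#' Unions the expert-accepted arcs with the MI-arbitrated arcs over the node
#' set. Every arc must run from a lower causal tier to a strictly higher one,
#' which guarantees acyclicity; violations raise a structure error naming the
#' arc.
#'
#' @param nodes Node-set tibble.
#' @param expert_edges,mi_edges Tibbles with columns `from`, `to` (either may
#'   be empty).
#' @return A `bn_dag`.
#' @export
build_preliminary_dag <- function(nodes, expert_edges,
                                  mi_edges = tibble::tibble(from = character(),
                                                            to = character())) {
  arcs <- dplyr::distinct(dplyr::bind_rows(
    expert_edges[, c("from", "to")],
    mi_edges[, c("from", "to")]
  ))
  for (i in seq_len(nrow(arcs))) {
    u <- arcs$from[[i]]
    v <- arcs$to[[i]]
    if (u == v) {
      abort_escbn(sprintf("Self-loop arc %s -> %s.", u, v), "escbn_structure_error")
    }
    if (!(u %in% nodes$node_id) || !(v %in% nodes$node_id)) {
      abort_escbn(sprintf("Arc %s -> %s has an endpoint outside the node set.", u, v),
                  "escbn_structure_error")
    }
    if (rank_of(nodes, u) >= rank_of(nodes, v)) {
      abort_escbn(
        sprintf("Arc %s -> %s does not run to a strictly higher causal rank.", u, v),
        "escbn_structure_error"
      )
    }
  }
  bn_dag(nodes, arcs)
}

#' Prune a DAG by conditional-independence tests
#'
#' For every arc `u -> v`, estimates the conditional mutual information
#' between `u` and `v` given the *other* parents of `v` in the original DAG.
#' Arcs whose statistic falls strictly below `epsilon` are removed; all tests
#' use the original parent sets and removals are applied simultaneously, so
#' the result does not depend on arc order. Arcs whose test cannot be
#' computed for lack of data are retained with a warning flag in the log.
#'
#' @param dag A `bn_dag`.
#' @param data Records tibble.
#' @param epsilon Independence threshold in bits (default 0.015).
#' @return List with elements `dag` (the pruned structure) and `log`, a
#'   tibble of per-arc test results (`from`, `to`, `conditioning_set`,
#'   `statistic_bits`, `threshold`, `removed`, `insufficient_data`).
#' @export
prune_by_ci <- function(dag, data, epsilon = 0.015) {
  stopifnot_scalar_number(epsilon, "epsilon", lower = 1e-12)
  arcs <- dag$arcs
  if (!nrow(arcs)) {
    return(list(dag = dag, log = tibble::tibble(
      from = character(), to = character(), conditioning_set = character(),
      statistic_bits = numeric(), threshold = numeric(),
      removed = logical(), insufficient_data = logical()
    )))
  }
  rows <- lapply(seq_len(nrow(arcs)), function(i) {
    u <- arcs$from[[i]]
    v <- arcs$to[[i]]
    cond <- setdiff(parents_of(dag, v), u)
    res <- tryCatch(
      list(stat = conditional_mutual_information(data, u, v, cond), bad = FALSE),
      escbn_insufficient_data = function(e) list(stat = NA_real_, bad = TRUE)
    )
    tibble::tibble(
      from = u, to = v,
      conditioning_set = paste(cond, collapse = ","),
      statistic_bits = res$stat,
      threshold = epsilon,
      removed = !res$bad && res$stat < epsilon,
      insufficient_data = res$bad
    )
  })
  log <- dplyr::bind_rows(rows)
  if (any(log$insufficient_data)) {
    rlang::warn("Some arcs were retained because their CI test had insufficient data.")
  }
  kept <- arcs[!log$removed, , drop = FALSE]
  list(dag = bn_dag(dag$nodes, kept), log = log)
}
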