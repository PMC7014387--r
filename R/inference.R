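# Exact inference by variable elimination. Factors are dense arrays over
# small categorical scopes; the 14-node injury network never produces a
# factor large enough to need log-space or sparse storage.

new_factor <- function(vars, cards, values) {
  list(vars = vars, cards = as.integer(cards), values = as.numeric(values))
}

factor_from_cpt <- function(ct) {
  dims <- dim(ct$prob)
  new_factor(c(ct$child, ct$parents), dims, as.vector(ct$prob))
}

# Linear indices of each cell of the union scope into factor f.
factor_expand_index <- function(f, union_vars, union_cards) {
  total <- prod(union_cards)
  lin <- rep.int(1L, total)
  stride_f <- 1L
  union_strides <- cumprod(c(1, union_cards[-length(union_cards)]))
  for (k in seq_along(f$vars)) {
    v <- f$vars[k]
    pos <- match(v, union_vars)
    cells <- ((seq_len(total) - 1L) %/% union_strides[pos]) %% union_cards[pos]
    lin <- lin + cells * stride_f
    stride_f <- stride_f * f$cards[k]
  }
  lin
}

factor_multiply <- function(f1, f2) {
  union_vars <- union(f1$vars, f2$vars)
  union_cards <- integer(length(union_vars))
  union_cards[match(f1$vars, union_vars)] <- f1$cards
  union_cards[match(f2$vars, union_vars)] <- f2$cards
  v1 <- f1$values[factor_expand_index(f1, union_vars, union_cards)]
  v2 <- f2$values[factor_expand_index(f2, union_vars, union_cards)]
  new_factor(union_vars, union_cards, v1 * v2)
}

factor_marginalize <- function(f, var) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  arr <- array(f$values, dim = f$cards)
  keep <- setdiff(seq_along(f$vars), pos)
  if (!length(keep)) {
    return(new_factor(character(0), integer(0), sum(arr)))
  }
  out <- apply(arr, keep, sum)
  new_factor(f$vars[keep], f$cards[keep], as.numeric(out))
}

factor_reduce <- function(f, var, state_index) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  arr <- array(f$values, dim = f$cards)
  idx <- rep(list(quote(expr = )), length(f$vars))
  idx[[pos]] <- state_index
  out <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  keep <- setdiff(seq_along(f$vars), pos)
  if (!length(keep)) {
    return(new_factor(character(0), integer(0), as.numeric(out)))
  }
  new_factor(f$vars[keep], f$cards[keep], as.numeric(out))
}

# Greedy min-size elimination: repeatedly eliminate the variable whose
# combined factor would be smallest.
eliminate_all <- function(factors, to_eliminate) {
  for (rounds in seq_along(to_eliminate)) {
    if (!length(to_eliminate)) break
    sizes <- vapply(to_eliminate, function(v) {
      scope_vars <- character(0)
      scope_cards <- integer(0)
      for (f in factors) {
        if (v %in% f$vars) {
          new <- setdiff(f$vars, scope_vars)
          scope_cards <- c(scope_cards, f$cards[match(new, f$vars)])
          scope_vars <- c(scope_vars, new)
        }
      }
      prod(scope_cards)
    }, numeric(1))
    v <- to_eliminate[which.min(sizes)]
    involved <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (any(involved)) {
      prod_f <- Reduce(factor_multiply, factors[involved])
      factors <- c(factors[!involved], list(factor_marginalize(prod_f, v)))
    }
    to_eliminate <- setdiff(to_eliminate, v)
  }
  factors
}

# Joint array over `query` (in that order) given evidence, exact.
posterior_over <- function(bn, query, evidence = NULL) {
  nodes <- bn$dag$nodes
  ev_idx <- evidence_indices(nodes, evidence)
  if (any(names(ev_idx) %in% query)) {
    # evidence nodes may be queried; handled by caller (posterior_table)
    query_free <- setdiff(query, names(ev_idx))
  } else {
    query_free <- query
  }
  factors <- lapply(bn$cpts, factor_from_cpt)
  for (v in names(ev_idx)) {
    factors <- lapply(factors, factor_reduce, var = v, state_index = ev_idx[[v]])
  }
  elim <- setdiff(nodes$node_id, c(query_free, names(ev_idx)))
  factors <- eliminate_all(factors, elim)
  res <- Reduce(factor_multiply, factors)
  z <- sum(res$values)
  if (!is.finite(z) || z <= 0) {
    abort_escbn("Evidence has zero probability under the network.",
                "escbn_impossible_evidence")
  }
  vals <- res$values / z
  # expand evidence nodes back as point masses if they were queried
  out_vars <- res$vars
  out_cards <- res$cards
  arr <- array(vals, dim = if (length(out_cards)) out_cards else 1L)
  for (v in intersect(query, names(ev_idx))) {
    card_v <- length(states_of(nodes, v))
    point <- rep(0, card_v)
    point[ev_idx[[v]]] <- 1
    pf <- new_factor(v, card_v, point)
    cur <- new_factor(out_vars, out_cards, as.numeric(arr))
    comb <- factor_multiply(cur, pf)
    out_vars <- comb$vars
    out_cards <- comb$cards
    arr <- array(comb$values, dim = out_cards)
  }
  # permute to requested order
  perm <- match(query, out_vars)
  if (length(query) > 1) {
    arr <- aperm(array(arr, dim = out_cards), perm)
  } else {
    arr <- as.numeric(arr)
  }
  dn <- lapply(query, states_of, nodes = nodes)
  names(dn) <- query
  array(arr, dim = vapply(dn, length, integer(1)), dimnames = dn)
}

evidence_indices <- function(nodes, evidence) {
  if (is.null(evidence) || length(evidence) == 0) return(integer(0))
  if (is.null(names(evidence)) || any(names(evidence) == "")) {
    abort_escbn("`evidence` must be a named list/vector of node = state.",
                "escbn_data_error")
  }
  if (anyDuplicated(names(evidence))) {
    abort_escbn("Evidence names duplicated.", "escbn_data_error")
  }
  out <- integer(0)
  for (v in names(evidence)) {
    st <- states_of(nodes, v)
    i <- match(as.character(evidence[[v]]), st)
    if (is.na(i)) {
      abort_escbn(sprintf("Evidence state '%s' is not a state of '%s'.",
                          evidence[[v]], v), "escbn_data_error")
    }
    out[v] <- i
  }
  out
}

#' Posterior distribution of one node given evidence
#'
#' Exact inference by variable elimination with a greedy minimum-size
#' elimination ordering. With empty evidence this is the node's marginal.
#'
#' @param bn A `discrete_bn`.
#' @param query Node id to query.
#' @param evidence Named list or character vector `node = state`; `NULL` for
#'   the marginal. Evidence with zero probability raises an error.
#' @return Named probability vector over the query node's states.
#' @examples
#' gt <- calibrate_ground_truth()
#' posterior(gt$bn, "ambulance")
#' posterior(gt$bn, "injured_region", evidence = c(ambulance = "yes"))
#' @export
posterior <- function(bn, query, evidence = NULL) {
  arr <- posterior_over(bn, query, evidence)
  stats::setNames(as.numeric(arr), dimnames(arr)[[1]])
}

#' Posterior table over every node
#'
#' Computes the posterior of every node under the given evidence; evidence
#' nodes appear as point masses. This is the report format of the injury
#' probability analysis (empty evidence) and the severity analyses
#' (ambulance/claim evidence).
#'
#' @inheritParams posterior
#' @return A tibble of class `posterior_tbl` with columns `node`, `state`,
#'   `probability`; each node's probabilities sum to 1.
#' @export
posterior_table <- function(bn, evidence = NULL) {
  rows <- lapply(bn$dag$nodes$node_id, function(v) {
    p <- posterior(bn, v, evidence)
    tibble::tibble(node = v, state = names(p), probability = as.numeric(p))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("posterior_tbl", class(out))
  attr(out, "evidence") <- evidence
  out
}

#' Joint probability of a complete assignment
#'
#' The product of one CPT entry per node: the network's factorization of the
#' joint distribution.
#'
#' @param bn A `discrete_bn`.
#' @param assignment Named character vector/list with a state for every node.
#' @return A probability in `[0, 1]`.
#' @export
joint_probability <- function(bn, assignment) {
  nodes <- bn$dag$nodes
  missing_nodes <- setdiff(nodes$node_id, names(assignment))
  if (length(missing_nodes)) {
    abort_escbn(
      sprintf("Assignment is missing node(s): %s",
              paste(missing_nodes, collapse = ", ")),
      "escbn_data_error"
    )
  }
  idx <- matrix(NA_integer_, 1, nrow(nodes), dimnames = list(NULL, nodes$node_id))
  for (v in nodes$node_id) {
    i <- match(as.character(assignment[[v]]), states_of(nodes, v))
    if (is.na(i)) {
      abort_escbn(sprintf("'%s' is not a state of '%s'.", assignment[[v]], v),
                  "escbn_data_error")
    }
    idx[1, v] <- i
  }
  prod(vapply(bn$cpts, cpt_lookup, numeric(1), idx = idx))
}

#' Exhaustive joint distribution
#'
#' Enumerates the full joint as a dense array over all node state spaces.
#' Intended as a test oracle for small networks; refuses state spaces beyond
#' `cap` cells.
#'
#' @param bn A `discrete_bn`.
#' @param cap Maximum number of joint cells (default 2e6).
#' @return Array with one dimension per node (dimnames = states) whose
#'   entries sum to 1.
#' @export
enumerate_joint <- function(bn, cap = 2e6) {
  nodes <- bn$dag$nodes
  cards <- cards_of(nodes)
  total <- prod(cards)
  if (total > cap) {
    abort_escbn(sprintf("Joint has %.0f cells, above the cap of %.0f.", total, cap),
                "escbn_data_error")
  }
  strides <- cumprod(c(1, cards[-length(cards)]))
  cells <- seq_len(total) - 1L
  idx <- matrix(0L, total, length(cards), dimnames = list(NULL, nodes$node_id))
  for (k in seq_along(cards)) {
    idx[, k] <- (cells %/% strides[k]) %% cards[k] + 1L
  }
  p <- rep(1, total)
  for (ct in bn$cpts) {
    p <- p * cpt_lookup(ct, idx)
  }
  dn <- nodes$states
  names(dn) <- nodes$node_id
  array(p, dim = cards, dimnames = dn)
}
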