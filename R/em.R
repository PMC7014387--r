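# Parameter learning: closed-form complete-data MLE and EM for incomplete
# records. The E step marginalizes each record's missing cells by exact
# inference restricted to the families that touch them, grouping records by
# missingness pattern so the accumulation stays vectorized.

#' EM configuration
#'
#' @param seed RNG seed for the random CPT initializations (mandatory).
#' @param tol Absolute change in observed-data log-likelihood below which EM
#'   stops (default 1e-6).
#' @param max_iter Iteration cap (default 500).
#' @param pseudo_count Laplace smoothing constant added to every expected
#'   count in the M step (default 1).
#' @param n_restarts Number of random restarts; the fit with the best final
#'   log-likelihood is kept (default 3).
#' @return A list of class `em_config`.
#' @export
em_config <- function(seed, tol = 1e-6, max_iter = 500, pseudo_count = 1,
                      n_restarts = 3) {
  stopifnot_scalar_number(seed, "seed")
  stopifnot_scalar_number(tol, "tol", lower = 1e-300)
  stopifnot_scalar_number(max_iter, "max_iter", lower = 1)
  stopifnot_scalar_number(pseudo_count, "pseudo_count", lower = 0)
  stopifnot_scalar_number(n_restarts, "n_restarts", lower = 1)
  structure(list(seed = as.integer(seed), tol = tol,
                 max_iter = as.integer(max_iter),
                 pseudo_count = pseudo_count,
                 n_restarts = as.integer(n_restarts)),
            class = "em_config")
}

family_cols <- function(dag) {
  lapply(stats::setNames(dag$nodes$node_id, dag$nodes$node_id), function(v) {
    c(v, parents_of(dag, v))
  })
}

# Linear (1-based) index of each record into a CPT array, split into the
# contribution of columns in `fixed_cols` (row-varying) and `combo_cols`
# (pattern-varying); either part may be empty.
family_linear_parts <- function(ct, idx_rows, combos, miss_ids) {
  cols <- c(ct$child, ct$parents)
  dims <- dim(ct$prob)
  row_part <- rep(0, nrow(idx_rows))
  combo_part <- rep(0, nrow(combos))
  stride <- 1
  for (k in seq_along(cols)) {
    v <- cols[k]
    if (v %in% miss_ids) {
      combo_part <- combo_part + (combos[, v] - 1) * stride
    } else {
      row_part <- row_part + (idx_rows[, v] - 1) * stride
    }
    stride <- stride * dims[k]
  }
  list(row = row_part, combo = combo_part)
}

# Expected sufficient statistics and observed-data log-likelihood.
# idx: integer matrix of state indices (NA = missing), columns = node ids.
expected_counts_idx <- function(bn, idx) {
  nodes <- bn$dag$nodes
  fams <- family_cols(bn$dag)
  counts <- lapply(bn$cpts, function(ct) array(0, dim = dim(ct$prob)))
  loglik <- 0
  n_skipped <- 0
  if (!nrow(idx)) {
    return(list(counts = counts, loglik = 0, n_skipped = 0))
  }
  miss_mat <- is.na(idx)
  pattern <- apply(miss_mat, 1, function(r) paste(which(r), collapse = ","))
  groups <- split(seq_len(nrow(idx)), pattern)
  for (gi in seq_along(groups)) {
    rows <- groups[[gi]]
    key <- names(groups)[gi]
    miss_cols <- if (key == "") integer(0) else as.integer(strsplit(key, ",")[[1]])
    miss_ids <- nodes$node_id[miss_cols]
    idx_rows <- idx[rows, , drop = FALSE]
    touched <- vapply(fams, function(cols) any(cols %in% miss_ids), logical(1))
    # fully observed families: hard counts and exact log-probabilities
    for (v in nodes$node_id[!touched[nodes$node_id]]) {
      ct <- bn$cpts[[v]]
      parts <- family_linear_parts(ct, idx_rows,
                                   matrix(0, 1, 0, dimnames = list(NULL, NULL)),
                                   character(0))
      lin <- parts$row + 1
      counts[[v]] <- counts[[v]] +
        array(tabulate(lin, nbins = length(ct$prob)), dim = dim(ct$prob))
      loglik <- loglik + sum(log(ct$prob[lin]))
    }
    if (!length(miss_ids)) next
    # enumerate the missing cells' state combinations
    cards <- cards_of(nodes, miss_ids)
    combos <- as.matrix(expand.grid(lapply(cards, seq_len),
                                    KEEP.OUT.ATTRS = FALSE))
    colnames(combos) <- miss_ids
    touched_ids <- nodes$node_id[touched[nodes$node_id]]
    parts_list <- lapply(touched_ids, function(v) {
      family_linear_parts(bn$cpts[[v]], idx_rows, combos, miss_ids)
    })
    names(parts_list) <- touched_ids
    # chunk rows to bound the (rows x combos) weight matrix
    chunk <- max(1L, floor(5e6 / nrow(combos)))
    starts <- seq(1L, length(rows), by = chunk)
    for (s in starts) {
      take <- s:min(s + chunk - 1L, length(rows))
      w <- matrix(1, length(take), nrow(combos))
      lin_mats <- lapply(touched_ids, function(v) {
        p <- parts_list[[v]]
        outer(p$row[take], p$combo, `+`) + 1
      })
      names(lin_mats) <- touched_ids
      for (v in touched_ids) {
        pv <- bn$cpts[[v]]$prob
        w <- w * matrix(pv[as.vector(lin_mats[[v]])], nrow = nrow(w))
      }
      tot <- rowSums(w)
      ok <- tot > 0
      if (!all(ok)) {
        n_skipped <- n_skipped + sum(!ok)
        w <- w[ok, , drop = FALSE]
        tot <- tot[ok]
        lin_mats <- lapply(lin_mats, function(m) m[ok, , drop = FALSE])
      }
      if (!length(tot)) next
      loglik <- loglik + sum(log(tot))
      wn <- w / tot
      for (v in touched_ids) {
        agg <- rowsum(as.vector(wn), group = as.vector(lin_mats[[v]]))
        pos <- as.integer(rownames(agg))
        counts[[v]][pos] <- counts[[v]][pos] + agg[, 1]
      }
    }
  }
  if (n_skipped > 0) {
    rlang::warn(sprintf(
      "%d record(s) had zero probability under the model and were skipped.",
      n_skipped
    ))
  }
  list(counts = counts, loglik = loglik, n_skipped = n_skipped)
}

#' Expected sufficient statistics (E step)
#'
#' For each record, missing cells are marginalized exactly given the record's
#' observed cells under the current network, and the resulting fractional
#' counts are accumulated per CPT cell. Fully observed records contribute
#' ordinary 0/1 counts.
#'
#' @param bn Current `discrete_bn`.
#' @param data Records tibble (`NA` = missing).
#' @return List with `counts` (one array per node, shaped like its CPT),
#'   `loglik` (observed-data log-likelihood of `bn` on `data`) and
#'   `n_skipped` (records with zero probability, skipped with a warning).
#' @export
expected_counts <- function(bn, data) {
  validate_records(data, bn$dag$nodes)
  expected_counts_idx(bn, records_to_indices(data, bn$dag$nodes))
}

m_step <- function(dag, counts, pseudo_count, nodes) {
  cpts <- lapply(dag$nodes$node_id, function(v) {
    cnt <- counts[[v]] + pseudo_count
    dims <- dim(cnt)
    mat <- matrix(cnt, nrow = dims[1])
    tot <- colSums(mat)
    zero <- tot <= 0
    if (any(zero)) {
      mat[, zero] <- 1 / dims[1]  # unseen parent configuration: uniform
      tot[zero] <- 1
    }
    mat <- sweep(mat, 2, tot, `/`)
    cpt(v, parents_of(dag, v), array(mat, dim = dims), nodes)
  })
  names(cpts) <- dag$nodes$node_id
  discrete_bn(dag, cpts)
}

#' Closed-form maximum-likelihood CPTs from complete data
#'
#' Each CPT row is `(count + pseudo_count) / (row total + pseudo_count *
#' arity)`. With `pseudo_count = 0`, parent configurations never observed get
#' a uniform row (documented convention).
#'
#' @param dag A `bn_dag`.
#' @param data Fully observed records tibble.
#' @param pseudo_count Laplace smoothing constant (default 0).
#' @return A `discrete_bn`.
#' @export
mle_complete <- function(dag, data, pseudo_count = 0) {
  validate_records(data, dag$nodes)
  if (!nrow(data)) {
    abort_escbn("Cannot fit maximum-likelihood CPTs from an empty dataset.",
                "escbn_data_error")
  }
  idx <- records_to_indices(data, dag$nodes)
  if (anyNA(idx[, dag$nodes$node_id, drop = FALSE])) {
    abort_escbn("`mle_complete()` requires fully observed records; use em_fit().",
                "escbn_data_error")
  }
  counts <- lapply(stats::setNames(dag$nodes$node_id, dag$nodes$node_id), function(v) {
    ps <- parents_of(dag, v)
    cols <- c(v, ps)
    cards <- cards_of(dag$nodes, cols)
    lin <- rep(1L, nrow(idx))
    stride <- 1L
    for (k in seq_along(cols)) {
      lin <- lin + (idx[, cols[k]] - 1L) * stride
      stride <- stride * cards[k]
    }
    array(tabulate(lin, nbins = prod(cards)), dim = cards)
  })
  m_step(dag, counts, pseudo_count, dag$nodes)
}

random_bn <- function(dag) {
  nodes <- dag$nodes
  cpts <- lapply(nodes$node_id, function(v) {
    ps <- parents_of(dag, v)
    cards <- cards_of(nodes, c(v, ps))
    raw <- matrix(stats::rexp(prod(cards)), nrow = cards[1])  # Dirichlet(1) rows
    mat <- sweep(raw, 2, colSums(raw), `/`)
    cpt(v, ps, array(mat, dim = cards), nodes)
  })
  names(cpts) <- nodes$node_id
  discrete_bn(dag, cpts)
}

#' Fit CPTs from incomplete records by EM
#'
#' Alternates exact expected counts (E) with smoothed count normalization (M)
#' until the observed-data log-likelihood changes by less than `tol` or
#' `max_iter` is reached; the best of `n_restarts` random Dirichlet(1)
#' initializations (by final log-likelihood) is returned. The structure is
#' fixed throughout. Deterministic given `config$seed`.
#'
#' With `pseudo_count > 0` the M step maximizes the Dirichlet-smoothed
#' (penalized) likelihood, so the guaranteed-monotone quantity is the
#' penalized objective reported in `objective_trace`; the raw observed-data
#' log-likelihood in `loglik_trace` coincides with it at `pseudo_count = 0`
#' and may in rare cases dip by a smoothing-sized amount otherwise.
#'
#' @param dag A `bn_dag`.
#' @param data Records tibble; missing cells are `NA`.
#' @param config An [em_config()].
#' @return Object of class `em_result`: `bn`, `loglik_trace`,
#'   `objective_trace` (non-decreasing), `loglik`, `converged`, `iterations`,
#'   `n_restarts`.
#' @export
em_fit <- function(dag, data, config) {
  if (!inherits(config, "em_config")) {
    abort_escbn("`config` must be an em_config().", "escbn_config_error")
  }
  validate_records(data, dag$nodes)
  if (!nrow(data)) {
    abort_escbn("Cannot fit from an empty dataset.", "escbn_data_error")
  }
  idx <- records_to_indices(data, dag$nodes)
  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    bn <- with_seed(derive_seed(config$seed, "em_init") + r, random_bn(dag))
    trace <- numeric(0)
    objective <- numeric(0)
    converged <- FALSE
    penalty <- function(b) {
      if (config$pseudo_count == 0) return(0)
      config$pseudo_count * sum(vapply(b$cpts, function(ct) {
        sum(log(pmax(ct$prob, 1e-300)))
      }, numeric(1)))
    }
    for (it in seq_len(config$max_iter)) {
      ec <- expected_counts_idx(bn, idx)
      trace[it] <- ec$loglik
      objective[it] <- ec$loglik + penalty(bn)
      bn <- m_step(dag, ec$counts, config$pseudo_count, dag$nodes)
      if (it > 1 && abs(trace[it] - trace[it - 1]) < config$tol) {
        converged <- TRUE
        break
      }
    }
    final_ll <- expected_counts_idx(bn, idx)$loglik
    cand <- list(bn = bn, loglik_trace = trace, objective_trace = objective,
                 loglik = final_ll,
                 converged = converged, iterations = length(trace))
    if (is.null(best) || cand$loglik > best$loglik) {
      best <- cand
    }
  }
  best$n_restarts <- config$n_restarts
  structure(best, class = "em_result")
}

#' @export
print.em_result <- function(x, ...) {
  cat(sprintf("<em_result> loglik %.3f after %d iteration(s)%s\n",
              x$loglik, x$iterations,
              if (x$converged) " (converged)" else " (not converged)"))
  invisible(x)
}

#' @method tidy em_result
#' @export
tidy.em_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$loglik_trace), loglik = x$loglik_trace)
}

#' @method glance em_result
#' @export
glance.em_result <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, iterations = x$iterations,
    converged = x$converged, n_restarts = x$n_restarts
  )
}

#' Observed-data log-likelihood
#'
#' Sum over records of `log P(observed cells)` with missing cells
#' marginalized exactly. A record with zero probability contributes
#' `-Inf` and is flagged via the `"n_impossible"` attribute.
#'
#' @param bn A `discrete_bn`.
#' @param data Records tibble.
#' @return The log-likelihood (0 for an empty dataset).
#' @export
log_likelihood <- function(bn, data) {
  validate_records(data, bn$dag$nodes)
  if (!nrow(data)) {
    return(structure(0, n_impossible = 0L))
  }
  ec <- suppressWarnings(
    expected_counts_idx(bn, records_to_indices(data, bn$dag$nodes))
  )
  ll <- if (ec$n_skipped > 0) -Inf else ec$loglik
  structure(ll, n_impossible = ec$n_skipped)
}
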