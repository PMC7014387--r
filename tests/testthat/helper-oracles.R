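# Independent oracles and fixture builders used across the suite. Each
# oracle is a deliberately naive implementation (full enumeration, closed
# form) kept separate from the package's own code paths.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force Dempster combination: enumerate every tuple of focal sets
# across the input BPAs, accumulate products on set intersections.
oracle_ds <- function(bpas) {
  frame <- bpas[[1]]$frame
  keysets <- lapply(bpas, function(b) names(b$masses))
  grid <- expand.grid(lapply(keysets, seq_along), KEEP.OUT.ATTRS = FALSE)
  acc <- list()
  conflict <- 0
  for (i in seq_len(nrow(grid))) {
    els <- frame
    m <- 1
    for (j in seq_along(bpas)) {
      key <- keysets[[j]][grid[i, j]]
      m <- m * bpas[[j]]$masses[[key]]
      els <- intersect(els, strsplit(key, "+", fixed = TRUE)[[1]])
    }
    if (!length(els)) {
      conflict <- conflict + m
    } else {
      key <- paste(frame[sort(match(els, frame))], collapse = "+")
      acc[[key]] <- (acc[[key]] %||% 0) + m
    }
  }
  masses <- unlist(acc)
  list(conflict = conflict, masses = masses / (1 - conflict))
}

# Random BPA with at most `max_focal` focal sets over `frame`.
random_bpa <- function(frame, max_focal = 4) {
  subsets <- list()
  n <- length(frame)
  for (i in 1:(2^n - 1)) {
    subsets[[length(subsets) + 1]] <- frame[as.logical(intToBits(i)[1:n])]
  }
  pick <- sample(seq_along(subsets), min(max_focal, length(subsets)))
  w <- stats::rexp(length(pick))
  w <- w / sum(w)
  masses <- vapply(seq_along(pick), function(j) w[j], numeric(1))
  names(masses) <- vapply(pick, function(p) paste(subsets[[p]], collapse = "+"),
                          character(1))
  bpa(frame, masses)
}

# Entropy-identity mutual information oracle: I = H(X) + H(Y) - H(X, Y).
oracle_mi_entropy <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  ent <- function(tab) {
    p <- tab / sum(tab)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  ent(table(x)) + ent(table(y)) - ent(table(paste(x, y, sep = "\r")))
}

# Brute-force conditional MI: full triple sum over the 3-way table.
oracle_cmi <- function(x, y, z) {
  keep <- !is.na(x) & !is.na(y) & !is.na(z)
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  n <- length(x)
  total <- 0
  for (zl in unique(z)) {
    sel <- z == zl
    pz <- sum(sel) / n
    tab <- table(x[sel], y[sel])
    pxy <- tab / sum(tab)
    px <- rowSums(pxy)
    py <- colSums(pxy)
    for (i in seq_len(nrow(pxy))) {
      for (j in seq_len(ncol(pxy))) {
        if (pxy[i, j] > 0) {
          total <- total + pz * pxy[i, j] * log2(pxy[i, j] / (px[i] * py[j]))
        }
      }
    }
  }
  unname(total)
}

# Small random network over `n_nodes` chain-tiered nodes (cards 2..3).
random_small_bn <- function(n_nodes = 4, p_arc = 0.5) {
  ids <- paste0("n", seq_len(n_nodes))
  cards <- sample(2:3, n_nodes, replace = TRUE)
  nodes <- tibble::tibble(
    node_id = ids, label = ids,
    tier = as.integer(pmin(seq_len(n_nodes), 5L)),
    states = lapply(cards, function(k) paste0("s", seq_len(k)))
  )
  arcs <- tibble::tibble(from = character(), to = character())
  for (j in 2:n_nodes) {
    for (i in 1:(j - 1)) {
      if (stats::runif(1) < p_arc) {
        arcs <- dplyr::bind_rows(arcs, tibble::tibble(from = ids[i], to = ids[j]))
      }
    }
  }
  dag <- bn_dag(nodes, arcs)
  cpts <- lapply(ids, function(v) {
    ps <- dag$arcs$from[dag$arcs$to == v]
    dims <- c(cards[match(v, ids)], cards[match(ps, ids)])
    raw <- matrix(stats::rexp(prod(dims)) + 0.05, nrow = dims[1])
    cpt(v, ps, array(sweep(raw, 2, colSums(raw), `/`), dim = dims), nodes)
  })
  names(cpts) <- ids
  discrete_bn(dag, cpts)
}

# Marginalize an enumerated joint array onto one node, optionally slicing
# evidence first (named list node = state index).
oracle_posterior <- function(joint, query, evidence = list()) {
  dn <- dimnames(joint)
  vars <- names(dn)
  idx <- rep(list(quote(expr = )), length(vars))
  for (v in names(evidence)) {
    idx[[match(v, vars)]] <- evidence[[v]]
  }
  sl <- do.call(`[`, c(list(joint), idx, list(drop = FALSE)))
  pos <- match(query, vars)
  out <- apply(sl, pos, sum)
  out / sum(out)
}

# Cached expensive fixtures (built once per test run).
.fixture_env <- new.env(parent = emptyenv())

cached_ground_truth <- function() {
  if (is.null(.fixture_env$gt)) {
    .fixture_env$gt <- calibrate_ground_truth()
  }
  .fixture_env$gt
}

cached_sample_50k <- function() {
  if (is.null(.fixture_env$d50)) {
    .fixture_env$d50 <- sample_dataset(cached_ground_truth(), 50000, seed = 101)
  }
  .fixture_env$d50
}

cached_em_fit_50k <- function() {
  if (is.null(.fixture_env$fit50)) {
    dm <- inject_missingness(cached_sample_50k(), 0.1, seed = 101)
    .fixture_env$fit50 <- em_fit(
      canonical_dag(), dm,
      em_config(seed = 101, tol = 0.01, max_iter = 100,
                pseudo_count = 0.1, n_restarts = 1)
    )
  }
  .fixture_env$fit50
}

tier_of_pub <- function(nodes, v) {
  nodes$tier[[match(v, nodes$node_id)]]
}
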