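# Synthetic study generator: canonical network structures, ancestral
# sampling of incident records, MCAR missingness, and simulated expert
# elicitation -- everything needed to exercise the pipeline without the
# proprietary incident registry.

#' Canonical injury-network structure
#'
#' The pruned 14-node DAG used as ground truth: passenger and environment
#' roots feed the four rider behaviors, the behaviors determine the hazard
#' pattern, hazard and age determine the injured body region, and the two
#' severity proxies (ambulance, claim) sit downstream. It deliberately lacks
#' the two arcs that the conditional-independence test removes from the
#' preliminary structure (gender to other-tasks, travel direction to hazard
#' pattern).
#'
#' @return A `bn_dag` over [canonical_nodes()].
#' @export
canonical_dag <- function() {
  arcs <- tibble::tribble(
    ~from, ~to,
    "age", "other_tasks",
    "company", "other_tasks",
    "age", "stand_firm_fail",
    "gender", "stand_firm_fail",
    "escalator_type", "stand_firm_fail",
    "accident_time", "handrail_not_held",
    "age", "handrail_not_held",
    "accident_time", "other_passenger_movement",
    "travel_direction", "other_passenger_movement",
    "stand_firm_fail", "hazard_pattern",
    "other_tasks", "hazard_pattern",
    "handrail_not_held", "hazard_pattern",
    "other_passenger_movement", "hazard_pattern",
    "hazard_pattern", "injured_region",
    "age", "injured_region",
    "injured_region", "ambulance",
    "age", "ambulance",
    "gender", "ambulance",
    "ambulance", "claim",
    "injured_region", "claim",
    "hazard_pattern", "claim"
  )
  bn_dag(canonical_nodes(), arcs)
}

#' Preliminary (pre-pruning) network structure
#'
#' [canonical_dag()] plus the two arcs that the conditional-independence test
#' removes: `gender -> other_tasks` and `travel_direction -> hazard_pattern`.
#' Used to exercise [prune_by_ci()].
#'
#' @return A `bn_dag`.
#' @export
preliminary_dag <- function() {
  base <- canonical_dag()
  extra <- tibble::tibble(
    from = c("gender", "travel_direction"),
    to = c("other_tasks", "hazard_pattern")
  )
  bn_dag(base$nodes, dplyr::bind_rows(base$arcs, extra))
}

#' Sample incident records by ancestral sampling
#'
#' Draws `n` complete records from a network in topological order;
#' deterministic given `seed`.
#'
#' @param truth A `ground_truth` (from [calibrate_ground_truth()]) or a
#'   `discrete_bn`.
#' @param n Number of records (>= 0).
#' @param seed RNG seed.
#' @return Records tibble with `n` rows and one column per node.
#' @export
sample_dataset <- function(truth, n, seed) {
  bn <- if (inherits(truth, "ground_truth")) truth$bn else truth
  if (!inherits(bn, "discrete_bn")) {
    abort_escbn("`truth` must be a ground_truth or discrete_bn.", "escbn_data_error")
  }
  stopifnot_scalar_number(n, "n", lower = 0)
  nodes <- bn$dag$nodes
  n <- as.integer(n)
  idx <- matrix(NA_integer_, n, nrow(nodes), dimnames = list(NULL, nodes$node_id))
  if (n > 0) {
    with_seed(derive_seed(seed, "sample_records"), {
      for (v in topo_order(bn$dag)) {
        ct <- bn$cpts[[v]]
        dims <- dim(ct$prob)
        card <- dims[1]
        # linear parent-configuration index per record
        cfg <- rep(1L, n)
        stride <- 1L
        for (p in ct$parents) {
          card_p <- length(states_of(nodes, p))
          cfg <- cfg + (idx[, p] - 1L) * stride
          stride <- stride * card_p
        }
        probmat <- matrix(ct$prob, nrow = card)
        cum <- apply(probmat, 2, cumsum)
        u <- stats::runif(n)
        # state = first index whose cumulative probability reaches u
        below <- cum[, cfg, drop = FALSE] < rep(u, each = card)
        idx[, v] <- colSums(below) + 1L
      }
    })
  }
  indices_to_records(idx, nodes)
}

#' Inject MCAR missingness
#'
#' Sets each non-exempt cell to missing independently with probability
#' `rate`; deterministic given `seed`.
#'
#' @param data Records tibble.
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed RNG seed.
#' @param exempt Node ids whose columns are left fully observed.
#' @return Records tibble with `NA` cells injected.
#' @export
inject_missingness <- function(data, rate, seed, exempt = character(0)) {
  stopifnot_scalar_number(rate, "rate", 0, 1 - 1e-12)
  out <- data
  if (rate == 0 || !nrow(data)) {
    return(out)
  }
  cols <- setdiff(names(data), exempt)
  with_seed(derive_seed(seed, "missingness"), {
    for (cl in cols) {
      hit <- stats::runif(nrow(out)) < rate
      out[[cl]][hit] <- NA_character_
    }
  })
  out
}

#' Simulate expert opinions about candidate arcs
#'
#' Each expert assigns, for every candidate arc, a basic probability
#' assignment over {present, absent}: mass `reliability * (1 - uncertainty)`
#' on the arc's true status in `true_dag`, `(1 - reliability) * (1 -
#' uncertainty)` on the opposite status, and `uncertainty` on the whole
#' frame, jittered per expert by Dirichlet noise. Arcs listed in `ambiguous`
#' are instead given near-vacuous opinions, which routes them to
#' mutual-information arbitration downstream.
#'
#' @param true_dag The generating `bn_dag`.
#' @param candidate_edges Tibble with columns `from`, `to`.
#' @param n_experts Number of experts (default 5).
#' @param reliability Probability mass an expert puts on the truth, before
#'   ignorance (default 0.8).
#' @param uncertainty Mass on the whole frame (ignorance; default 0.3).
#' @param noise Dirichlet jitter scale in `[0, 1]`; 0 gives identical,
#'   noise-free experts (default 0.1).
#' @param ambiguous Optional tibble of arcs forced near-vacuous.
#' @param seed RNG seed.
#' @return Long opinions tibble for [fuse_edge_opinions()].
#' @export
simulate_expert_opinions <- function(true_dag, candidate_edges, n_experts = 5,
                                     reliability = 0.8, uncertainty = 0.3,
                                     noise = 0.1, ambiguous = NULL, seed = 1) {
  stopifnot_scalar_number(n_experts, "n_experts", lower = 1)
  stopifnot_scalar_number(reliability, "reliability", 0, 1)
  stopifnot_scalar_number(uncertainty, "uncertainty", 0, 1)
  stopifnot_scalar_number(noise, "noise", 0, 1)
  truth_key <- paste(true_dag$arcs$from, true_dag$arcs$to, sep = "\r")
  amb_key <- if (is.null(ambiguous)) character(0) else {
    paste(ambiguous$from, ambiguous$to, sep = "\r")
  }
  draw_masses <- function(base) {
    if (noise <= 0) return(base)
    conc <- base * (3 / noise)
    g <- stats::rgamma(3, shape = conc)  # shape 0 draws exact zeros
    if (sum(g) <= 0) base else g / sum(g)
  }
  rows <- with_seed(derive_seed(seed, "experts"), {
    out <- vector("list", n_experts * nrow(candidate_edges))
    k <- 0L
    for (e in seq_len(n_experts)) {
      for (i in seq_len(nrow(candidate_edges))) {
        key <- paste(candidate_edges$from[[i]], candidate_edges$to[[i]], sep = "\r")
        if (key %in% amb_key) {
          m <- draw_masses(c(0.15, 0.15, 0.70))
        } else {
          present_true <- key %in% truth_key
          m_true <- reliability * (1 - uncertainty)
          m_false <- (1 - reliability) * (1 - uncertainty)
          base <- if (present_true) c(m_true, m_false, uncertainty) else
            c(m_false, m_true, uncertainty)
          m <- draw_masses(base)
        }
        k <- k + 1L
        out[[k]] <- tibble::tibble(
          expert_id = sprintf("expert_%02d", e),
          from = candidate_edges$from[[i]],
          to = candidate_edges$to[[i]],
          m_present = m[1], m_absent = m[2], m_theta = m[3]
        )
      }
    }
    out
  })
  dplyr::bind_rows(rows)
}
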