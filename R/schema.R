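#' The canonical 14-node injury schema
#'
#' Returns the node set used throughout the escalator-injury analyses: one row
#' per categorical variable of an incident record, with its human-readable
#' label, ordered state list and causal tier. Tiers order the variables from
#' passenger/environment roots (tier 1) through rider behaviors (2), the
#' hazard pattern (3), the injured body region (4), to the severity proxies
#' (5: ambulance call and compensation claim). Arcs in every network built by
#' this package run along increasing causal rank: strictly upward in tier,
#' except that within the severity tier the claim node sits downstream of the
#' ambulance node (a claim is judged after the injury's severity is apparent).
#'
#' Age bands follow the non-overlapping partition <=6, 7-17, 18-40, 41-65,
#' >=66 years.
#'
#' @return A tibble with columns `node_id`, `label`, `tier` and a `states`
#'   list-column of state identifiers (each node has at least two).
#' @examples
#' canonical_nodes()
#' @export
canonical_nodes <- function() {
  spec <- list(
    list("age", "Passenger age band", 1L,
         c("age_0_6", "age_7_17", "age_18_40", "age_41_65", "age_66_plus")),
    list("gender", "Passenger gender", 1L, c("male", "female")),
    list("accident_time", "Time of incident", 1L,
         c("before_0730", "t0730_0929", "t0930_1729", "t1730_1959", "after_1930")),
    list("escalator_type", "Escalator type", 1L, c("long", "conventional")),
    list("travel_direction", "Escalator travel direction", 1L, c("upward", "downward")),
    list("company", "Riding with company", 1L, c("with_company", "without_company")),
    list("other_tasks", "Carrying out other tasks", 2L, c("yes", "no")),
    list("stand_firm_fail", "Failing to stand firm", 2L, c("yes", "no")),
    list("handrail_not_held", "Not holding the handrail", 2L, c("yes", "no")),
    list("other_passenger_movement", "Another passenger's movement", 2L, c("yes", "no")),
    list("hazard_pattern", "Hazard pattern", 3L,
         c("fall", "entrapment", "falling_object", "other_unknown")),
    list("injured_region", "Injured body region", 4L,
         c("multiple", "head_neck", "lower_extremity", "upper_extremity", "trunk", "unknown")),
    list("claim", "Claim against the operator", 5L,
         c("compensation", "tendency", "reserve_right", "no_claim", "unknown")),
    list("ambulance", "Ambulance called", 5L, c("yes", "no"))
  )
  tibble::tibble(
    node_id = vapply(spec, `[[`, character(1), 1L),
    label = vapply(spec, `[[`, character(1), 2L),
    tier = vapply(spec, `[[`, integer(1), 3L),
    states = lapply(spec, `[[`, 4L)
  )
}

#' Validate a node-set tibble
#'
#' Checks the invariants every node specification must satisfy: unique node
#' ids, at least two unique states per node, and tiers in 1..5.
#'
#' @param nodes A tibble with columns `node_id`, `label`, `tier`, `states`.
#' @return `nodes`, invisibly, if valid; otherwise an error naming the
#'   offending node.
#' @export
validate_nodes <- function(nodes) {
  required <- c("node_id", "label", "tier", "states")
  if (!is.data.frame(nodes) || !all(required %in% names(nodes))) {
    abort_escbn(
      "A node set needs columns node_id, label, tier and states.",
      "escbn_schema_error"
    )
  }
  if (anyDuplicated(nodes$node_id)) {
    dup <- nodes$node_id[duplicated(nodes$node_id)][1]
    abort_escbn(sprintf("Duplicate node_id '%s'.", dup), "escbn_schema_error")
  }
  for (i in seq_len(nrow(nodes))) {
    st <- nodes$states[[i]]
    id <- nodes$node_id[[i]]
    if (!is.character(st) || length(st) < 2L) {
      abort_escbn(
        sprintf("Node '%s' must have at least 2 states.", id),
        "escbn_schema_error"
      )
    }
    if (anyDuplicated(st)) {
      abort_escbn(sprintf("Node '%s' has duplicated states.", id), "escbn_schema_error")
    }
    tier <- nodes$tier[[i]]
    if (!is.numeric(tier) || is.na(tier) || !(tier %in% 1:5)) {
      abort_escbn(sprintf("Node '%s' has tier outside 1..5.", id), "escbn_schema_error")
    }
  }
  invisible(nodes)
}

#' Read a node specification from JSON or YAML
#'
#' The file holds an array of objects with keys `node_id`, `label`, `states`
#' and `tier`; the bundled canonical specification is at
#' `system.file("extdata", "node_spec.json", package = "escbn")`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated node-set tibble (see [canonical_nodes()]).
#' @export
load_node_spec <- function(path) {
  if (!file.exists(path)) {
    abort_escbn(sprintf("Node spec file not found: %s", path), "escbn_schema_error")
  }
  raw <- tryCatch(
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    },
    error = function(e) {
      abort_escbn(
        sprintf("Could not parse node spec '%s': %s", path, conditionMessage(e)),
        "escbn_schema_error"
      )
    }
  )
  if (!is.list(raw) || length(raw) == 0) {
    abort_escbn("Node spec must be a non-empty array of node objects.", "escbn_schema_error")
  }
  nodes <- tibble::tibble(
    node_id = vapply(raw, function(x) as.character(x$node_id %||% NA_character_), character(1)),
    label = vapply(raw, function(x) as.character(x$label %||% x$node_id), character(1)),
    tier = vapply(raw, function(x) as.integer(x$tier %||% NA_integer_), integer(1)),
    states = lapply(raw, function(x) as.character(unlist(x$states)))
  )
  validate_nodes(nodes)
  nodes
}

# ---- internal lookups ----------------------------------------------------

states_of <- function(nodes, node_id) {
  i <- match(node_id, nodes$node_id)
  if (is.na(i)) {
    abort_escbn(sprintf("Unknown node '%s'.", node_id), "escbn_schema_error")
  }
  nodes$states[[i]]
}

cards_of <- function(nodes, ids = nodes$node_id) {
  vapply(ids, function(id) length(states_of(nodes, id)), integer(1))
}

tier_of <- function(nodes, node_id) {
  nodes$tier[[match(node_id, nodes$node_id)]]
}

# Causal ordering rank: the published tier, refined inside the severity tier
# so that the claim node ranks after the ambulance node (a claim is
# conditioned on whether an ambulance was needed, fixing that arc's
# direction).
rank_of <- function(nodes, node_id) {
  r <- as.numeric(tier_of(nodes, node_id))
  if (identical(node_id, "claim")) r <- r + 0.5
  r
}
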