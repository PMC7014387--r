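test_that("canonical structure encodes the documented arcs and exclusions", {
  dag <- canonical_dag()
  has_arc <- function(d, u, v) any(d$arcs$from == u & d$arcs$to == v)
  expect_true(has_arc(dag, "accident_time", "handrail_not_held"))
  expect_false(has_arc(dag, "gender", "other_tasks"))
  expect_false(has_arc(dag, "travel_direction", "hazard_pattern"))
  # roots are exactly the six tier-1 passenger/environment factors
  roots <- setdiff(dag$nodes$node_id, unique(dag$arcs$to))
  expect_setequal(roots, c("age", "gender", "accident_time", "escalator_type",
                           "travel_direction", "company"))
  # every arc runs to a strictly higher tier, except the documented
  # within-severity ordering ambulance -> claim
  td <- tidy(dag)
  expect_true(all(td$from_tier < td$to_tier |
                    (td$from == "ambulance" & td$to == "claim")))
  prelim <- preliminary_dag()
  expect_true(has_arc(prelim, "gender", "other_tasks"))
  expect_true(has_arc(prelim, "travel_direction", "hazard_pattern"))
  expect_equal(nrow(prelim$arcs), nrow(dag$arcs) + 2)
})

test_that("calibrated truth reproduces every published cell within tolerance", {
  gt <- cached_ground_truth()
  cells <- gt$report$cells
  marg <- cells[cells$block == "marginal", ]
  expect_true(all(marg$abs_error <= 0.01))
  amb <- cells[cells$block == "ambulance_yes", ]
  expect_true(all(amb$abs_error <= 0.03))
  claim <- cells[cells$block == "claim_compensation", ]
  expect_true(all(claim$abs_error <= 0.03))
  # headline cells, asserted directly against the network
  bn <- gt$bn
  expect_lt(abs(posterior(bn, "gender")["female"] - 0.64), 0.01)
  expect_lt(abs(posterior(bn, "injured_region",
                          c(ambulance = "yes"))["head_neck"] - 0.38), 0.03)
  expect_lt(abs(posterior(bn, "ambulance",
                          c(claim = "compensation"))["yes"] - 0.73), 0.03)
})

test_that("pruned pairs are conditionally independent in the exact joint", {
  gt <- cached_ground_truth()
  expect_lt(max(gt$report$removed_cmi$cmi_bits), 1e-12)
})

test_that("dependence is injected across arcs, except the table-pinned pair", {
  gt <- cached_ground_truth()
  mi <- gt$report$arc_mi
  pinned <- (mi$to == "ambulance") & (mi$from %in% c("age", "gender"))
  expect_true(all(mi$mi_bits[!pinned] > 0.015))
  # the two ambulance arcs stay weak because the published severity
  # conditionals cap them, but they are not degenerate
  expect_true(all(mi$mi_bits[pinned] > 0))
})

test_that("ancestral sampling is deterministic and consistent with the truth", {
  gt <- cached_ground_truth()
  d1 <- sample_dataset(gt, 400, seed = 11)
  d2 <- sample_dataset(gt, 400, seed = 11)
  expect_identical(d1, d2)
  d3 <- sample_dataset(gt, 400, seed = 12)
  expect_false(identical(d1, d3))
  expect_equal(nrow(sample_dataset(gt, 0, seed = 1)), 0)
  d <- cached_sample_50k()
  expect_equal(mean(d$gender == "female"),
               unname(posterior(gt$bn, "gender")["female"]), tolerance = 0.01)
  expect_equal(mean(d$hazard_pattern == "fall"),
               unname(posterior(gt$bn, "hazard_pattern")["fall"]),
               tolerance = 0.01)
})

test_that("MCAR injection hits the requested rate and honors exemptions", {
  gt <- cached_ground_truth()
  d <- sample_dataset(gt, 20000, seed = 13)
  expect_identical(inject_missingness(d, 0, seed = 1), d)
  dm <- inject_missingness(d, 0.1, seed = 14, exempt = "gender")
  expect_equal(mean(is.na(as.matrix(dm[setdiff(names(dm), "gender")]))),
               0.1, tolerance = 0.005)
  expect_false(anyNA(dm$gender))
  expect_identical(inject_missingness(d, 0.1, seed = 14),
                   inject_missingness(d, 0.1, seed = 14))
  expect_error(inject_missingness(d, 1.2, seed = 1), class = "escbn_config_error")
})

test_that("noise-free reliable experts reproduce the true structure exactly", {
  dag <- canonical_dag()
  candidates <- preliminary_dag()$arcs
  ops <- simulate_expert_opinions(dag, candidates, n_experts = 5,
                                  reliability = 1, uncertainty = 0,
                                  noise = 0, seed = 1)
  dec <- decide_edges(fuse_edge_opinions(ops), accept_threshold = 0.7)
  accepted <- dec[dec$status == "accepted", c("from", "to")]
  expect_equal(dplyr::arrange(accepted, from, to),
               dplyr::arrange(dag$arcs, from, to))
  # full ignorance: every fused opinion stays vacuous
  ops_vac <- simulate_expert_opinions(dag, candidates, n_experts = 5,
                                      reliability = 1, uncertainty = 1,
                                      noise = 0, seed = 1)
  dec_vac <- decide_edges(fuse_edge_opinions(ops_vac), accept_threshold = 0.7)
  expect_true(all(dec_vac$status == "uncertain"))
})

test_that("fusion of noisy experts outperforms individuals and flags ambiguity", {
  dag <- canonical_dag()
  candidates <- preliminary_dag()$arcs
  amb <- candidates[candidates$from == "travel_direction" &
                      candidates$to == "hazard_pattern", ]
  ops <- simulate_expert_opinions(dag, candidates, n_experts = 5,
                                  reliability = 0.8, uncertainty = 0.3,
                                  noise = 0.2, ambiguous = amb, seed = 21)
  fused <- fuse_edge_opinions(ops)
  truth_key <- paste(dag$arcs$from, dag$arcs$to, sep = "\r")
  wins <- 0
  n_edges <- 0
  for (i in seq_len(nrow(fused))) {
    key <- paste(fused$from[i], fused$to[i], sep = "\r")
    if (key %in% paste(amb$from, amb$to, sep = "\r")) next
    n_edges <- n_edges + 1
    true_col <- if (key %in% truth_key) "m_present" else "m_absent"
    per_expert <- ops[ops$from == fused$from[i] & ops$to == fused$to[i], ][[true_col]]
    if (fused[[true_col]][i] > max(per_expert)) wins <- wins + 1
  }
  expect_gte(wins / n_edges, 0.9)
  dec <- decide_edges(fused, accept_threshold = 0.7)
  amb_status <- dec$status[dec$from == "travel_direction" &
                             dec$to == "hazard_pattern"]
  expect_equal(amb_status, "uncertain")
})

test_that("generic calibration: uniform targets on a chain give uniform CPTs", {
  nodes <- tibble::tibble(
    node_id = c("a", "b", "c"), label = c("a", "b", "c"), tier = c(1L, 2L, 3L),
    states = rep(list(c("s1", "s2")), 3)
  )
  dag <- bn_dag(nodes, tibble::tibble(from = c("a", "b"), to = c("b", "c")))
  targets <- structure(list(
    marginals = list(a = c(s1 = .5, s2 = .5), b = c(s1 = .5, s2 = .5),
                     c = c(s1 = .5, s2 = .5)),
    ambulance_conditionals = list(), claim_conditionals = list()
  ), class = "calibration_targets")
  gt0 <- calibrate_ground_truth(targets, dag, mi_floor = 0)
  for (v in c("a", "b", "c")) {
    expect_equal(as.numeric(gt0$bn$cpts[[v]]$prob),
                 rep(0.5, length(gt0$bn$cpts[[v]]$prob)), tolerance = 1e-9)
  }
  expect_true(all(gt0$report$cells$abs_error < 1e-9))
  # with a floor, marginals stay exact while arcs become dependent
  gt1 <- calibrate_ground_truth(targets, dag, mi_floor = 0.02)
  expect_equal(unname(posterior(gt1$bn, "b")["s1"]), 0.5, tolerance = 1e-9)
  expect_true(all(gt1$report$arc_mi$mi_bits >= 0.02))
})

test_that("infeasible targets are rejected", {
  tg <- calibration_targets()
  tg$marginals$gender <- c(male = 0.7, female = 0.7)
  expect_error(validate_targets(tg), class = "escbn_calibration_error")
  tg2 <- calibration_targets()
  # conditional mass exceeding what total probability allows
  tg2$ambulance_conditionals$injured_region["unknown"] <- 0.5
  tg2$ambulance_conditionals$injured_region <-
    tg2$ambulance_conditionals$injured_region /
    sum(tg2$ambulance_conditionals$injured_region)
  expect_error(validate_targets(tg2), class = "escbn_calibration_error")
})
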