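counts_to_records <- function(counts, xi = "x", xj = "y") {
  # expand a 2x2 count matrix into a two-column record tibble
  grid <- expand.grid(a = rownames(counts), b = colnames(counts),
                      stringsAsFactors = FALSE)
  out <- tibble::tibble(
    !!xi := rep(grid$a, times = as.vector(counts)),
    !!xj := rep(grid$b, times = as.vector(counts))
  )
  out
}

test_that("mutual information matches closed forms on 2x2 tables", {
  mk <- function(m) counts_to_records(matrix(m, 2, dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(mutual_information(mk(c(25, 25, 25, 25)), "x", "y"), 0)
  expect_equal(mutual_information(mk(c(50, 0, 0, 50)), "x", "y"), 1)
  # frozen via the entropy identity on the same table
  d <- mk(c(40, 10, 10, 40))
  expect_equal(mutual_information(d, "x", "y"), 0.278072, tolerance = 1e-5)
  expect_equal(mutual_information(d, "x", "y"),
               oracle_mi_entropy(d$x, d$y), tolerance = 1e-12)
})

test_that("MI is symmetric, non-negative, and equals the entropy identity", {
  withr::local_seed(3)
  for (rep in 1:20) {
    n <- 300
    d <- tibble::tibble(
      x = sample(letters[1:3], n, replace = TRUE),
      y = sample(letters[1:4], n, replace = TRUE, prob = c(.4, .3, .2, .1))
    )
    mi <- mutual_information(d, "x", "y")
    expect_gte(mi, 0)
    expect_equal(mi, mutual_information(d, "y", "x"), tolerance = 1e-12)
    expect_equal(mi, oracle_mi_entropy(d$x, d$y), tolerance = 1e-12)
  }
})

test_that("MI uses pairwise-complete records and errors without any", {
  d <- tibble::tibble(x = c("a", "b", NA, "a"), y = c("u", NA, "u", "v"))
  expect_equal(mutual_information(d, "x", "y"),
               oracle_mi_entropy(d$x, d$y), tolerance = 1e-12)
  d_none <- tibble::tibble(x = c("a", NA), y = c(NA, "u"))
  expect_error(mutual_information(d_none, "x", "y"),
               class = "escbn_insufficient_data")
})

test_that("conditional MI reduces to MI with empty set and matches brute force", {
  withr::local_seed(5)
  for (rep in 1:15) {
    n <- 400
    z <- sample(c("p", "q"), n, replace = TRUE)
    x <- ifelse(stats::runif(n) < ifelse(z == "p", .7, .3), "a", "b")
    y <- ifelse(stats::runif(n) < ifelse(x == "a", .6, .4), "u", "v")
    d <- tibble::tibble(x = x, y = y, z = z)
    expect_equal(conditional_mutual_information(d, "x", "y", character(0)),
                 mutual_information(d, "x", "y"), tolerance = 1e-12)
    cmi <- conditional_mutual_information(d, "x", "y", "z")
    expect_gte(cmi, 0)
    expect_equal(cmi, oracle_cmi(x, y, z), tolerance = 1e-12)
    expect_equal(cmi, conditional_mutual_information(d, "y", "x", "z"),
                 tolerance = 1e-12)
  }
})

test_that("CMI is zero on data that factorizes exactly within strata", {
  # balanced counts with x independent of y inside each z stratum
  d <- tidyr::expand_grid(x = c("a", "b"), y = c("u", "v"), z = c("p", "q"))
  d <- d[rep(seq_len(nrow(d)), times = c(9, 4, 3, 4, 3, 4, 1, 4)), ]
  expect_equal(conditional_mutual_information(d, "x", "y", "z"), 0,
               tolerance = 1e-12)
})

test_that("uncertain-edge arbitration applies the strict threshold rule", {
  withr::local_seed(8)
  n <- 2000
  x <- sample(c("a", "b"), n, replace = TRUE)
  d <- tibble::tibble(
    x = x,
    y_dep = ifelse(stats::runif(n) < ifelse(x == "a", .8, .2), "u", "v"),
    y_ind = sample(c("u", "v"), n, replace = TRUE)
  )
  res <- arbitrate_uncertain_edges(
    d, tibble::tibble(from = c("x", "x"), to = c("y_dep", "y_ind")),
    epsilon = 0.015
  )
  expect_true(res$accepted[res$to == "y_dep"])
  expect_false(res$accepted[res$to == "y_ind"])
  # statistic exactly at the threshold is rejected (strict "greater than")
  res_eq <- arbitrate_uncertain_edges(
    d, tibble::tibble(from = "x", to = "y_dep"),
    epsilon = mutual_information(d, "x", "y_dep")
  )
  expect_false(res_eq$accepted)
})

test_that("preliminary DAG assembly unions edges and enforces tier order", {
  nodes <- canonical_nodes()
  prelim <- build_preliminary_dag(
    nodes,
    expert_edges = preliminary_dag()$arcs,
    mi_edges = tibble::tibble(from = "age", to = "other_tasks")  # duplicate
  )
  expect_equal(nrow(prelim$arcs), nrow(preliminary_dag()$arcs))
  expect_true(any(prelim$arcs$from == "gender" & prelim$arcs$to == "other_tasks"))
  expect_true(any(prelim$arcs$from == "travel_direction" &
                    prelim$arcs$to == "hazard_pattern"))
  expect_error(
    build_preliminary_dag(nodes, tibble::tibble(from = "age", to = "age")),
    class = "escbn_structure_error"
  )
  expect_error(
    build_preliminary_dag(nodes, tibble::tibble(from = "hazard_pattern",
                                                to = "other_tasks")),
    class = "escbn_structure_error"
  )
  empty <- build_preliminary_dag(nodes, tibble::tibble(from = character(),
                                                       to = character()))
  expect_equal(nrow(empty$arcs), 0)
})

test_that("CI pruning uses original parent sets, is simultaneous and idempotent", {
  d <- cached_sample_50k()
  pruned <- prune_by_ci(preliminary_dag(), d, epsilon = 0.015)
  # the log records one test per arc against the ORIGINAL co-parents
  expect_equal(nrow(pruned$log), nrow(preliminary_dag()$arcs))
  ot_row <- pruned$log[pruned$log$from == "gender" & pruned$log$to == "other_tasks", ]
  expect_setequal(strsplit(ot_row$conditioning_set, ",")[[1]], c("age", "company"))
  # pruning a pruned DAG with the same data changes nothing
  again <- prune_by_ci(pruned$dag, d, epsilon = 0.015)
  expect_equal(dplyr::arrange(again$dag$arcs, from, to),
               dplyr::arrange(pruned$dag$arcs, from, to))
  # a DAG with no arcs passes through untouched
  none <- prune_by_ci(bn_dag(canonical_nodes()), d)
  expect_equal(nrow(none$log), 0)
  expect_equal(nrow(none$dag$arcs), 0)
})

test_that("single-parent arcs reduce to a marginal MI test", {
  gt <- cached_ground_truth()
  d <- sample_dataset(gt, 5000, seed = 77)
  nodes <- canonical_nodes()
  dag1 <- bn_dag(nodes, tibble::tibble(from = "age", to = "stand_firm_fail"))
  res <- prune_by_ci(dag1, d, epsilon = 0.015)
  expect_equal(res$log$conditioning_set, "")
  expect_equal(res$log$statistic_bits,
               mutual_information(d, "age", "stand_firm_fail"),
               tolerance = 1e-12)
})
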