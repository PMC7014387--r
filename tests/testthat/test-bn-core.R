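test_that("joint probability multiplies CPT rows and normalizes over the grid", {
  nodes <- tibble::tibble(
    node_id = c("a", "b"), label = c("a", "b"), tier = c(1L, 2L),
    states = list(c("x", "y"), c("x", "y"))
  )
  dag <- bn_dag(nodes, tibble::tibble(from = "a", to = "b"))
  bn <- discrete_bn(dag, list(
    a = cpt("a", character(0), c(.5, .5), nodes),
    b = cpt("b", "a", matrix(.5, 2, 2), nodes)
  ))
  for (sa in c("x", "y")) for (sb in c("x", "y")) {
    expect_equal(joint_probability(bn, c(a = sa, b = sb)), 0.25)
  }
  j <- enumerate_joint(bn)
  expect_equal(length(j), 4)
  expect_equal(sum(j), 1, tolerance = 1e-12)
  expect_error(joint_probability(bn, c(a = "x")), class = "escbn_data_error")
})

test_that("arc-free networks give product-of-priors joints", {
  nodes <- tibble::tibble(
    node_id = c("a", "b", "c"), label = c("a", "b", "c"), tier = c(1L, 1L, 1L),
    states = rep(list(c("x", "y")), 3)
  )
  dag <- bn_dag(nodes)
  bn <- discrete_bn(dag, stats::setNames(lapply(nodes$node_id, function(v) {
    cpt(v, character(0), c(.5, .5), nodes)
  }), nodes$node_id))
  expect_equal(joint_probability(bn, c(a = "x", b = "y", c = "x")), 0.125)
})

test_that("variable elimination equals full-joint enumeration on random nets", {
  withr::local_seed(19)
  for (rep in 1:40) {
    bn <- random_small_bn(n_nodes = sample(3:5, 1))
    j <- enumerate_joint(bn)
    expect_equal(sum(j), 1, tolerance = 1e-9)
    ids <- bn$dag$nodes$node_id
    q <- sample(ids, 1)
    # marginal query
    expect_equal(posterior(bn, q),
                 oracle_posterior(j, q),
                 tolerance = 1e-9, ignore_attr = TRUE)
    # conditional query on a random other node
    ev_node <- sample(setdiff(ids, q), 1)
    ev_states <- bn$dag$nodes$states[[match(ev_node, ids)]]
    ev_state <- sample(ev_states, 1)
    ev <- stats::setNames(ev_state, ev_node)
    p_ev <- oracle_posterior(j, ev_node)[match(ev_state, ev_states)]
    if (p_ev > 0) {
      expect_equal(posterior(bn, q, ev),
                   oracle_posterior(j, q, stats::setNames(
                     list(match(ev_state, ev_states)), ev_node)),
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
})

test_that("conditioning on a node returns a point mass; empty evidence the prior", {
  bn <- cached_ground_truth()$bn
  p <- posterior(bn, "gender", c(gender = "female"))
  expect_equal(unname(p["female"]), 1)
  root_prior <- as.numeric(bn$cpts$gender$prob)
  expect_equal(unname(posterior(bn, "gender")), root_prior, tolerance = 1e-9)
})

test_that("law of total probability holds for evidence decompositions", {
  bn <- cached_ground_truth()$bn
  p_amb <- posterior(bn, "ambulance")
  total <- p_amb["yes"] * posterior(bn, "age", c(ambulance = "yes")) +
    p_amb["no"] * posterior(bn, "age", c(ambulance = "no"))
  expect_equal(unname(total), unname(posterior(bn, "age")), tolerance = 1e-9)
})

test_that("impossible evidence raises a typed error instead of NaN", {
  nodes <- tibble::tibble(
    node_id = c("a", "b"), label = c("a", "b"), tier = c(1L, 2L),
    states = list(c("x", "y"), c("x", "y"))
  )
  dag <- bn_dag(nodes, tibble::tibble(from = "a", to = "b"))
  bn <- discrete_bn(dag, list(
    a = cpt("a", character(0), c(1, 0), nodes),
    b = cpt("b", "a", matrix(c(1, 0, 0, 1), 2), nodes)
  ))
  expect_error(posterior(bn, "b", c(a = "y")), class = "escbn_impossible_evidence")
})

test_that("the canonical joint enumerates every cell and sums to one", {
  bn <- cached_ground_truth()$bn
  j <- enumerate_joint(bn)
  expect_equal(length(j), 1536000)
  expect_equal(sum(j), 1, tolerance = 1e-9)
  # spot-check variable elimination against the enumerated joint
  expect_equal(posterior(bn, "hazard_pattern"),
               oracle_posterior(j, "hazard_pattern"),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(enumerate_joint(bn, cap = 1000), class = "escbn_data_error")
})

test_that("posterior tables normalize per node and respect evidence", {
  bn <- cached_ground_truth()$bn
  tab <- posterior_table(bn, c(ambulance = "yes"))
  sums <- tapply(tab$probability, tab$node, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(tab$probability[tab$node == "ambulance" & tab$state == "yes"], 1)
})

test_that("network JSON round-trips CPTs exactly", {
  withr::local_seed(23)
  bn <- random_small_bn(4)
  f <- withr::local_tempfile(fileext = ".json")
  write_bn_json(bn, f)
  back <- read_bn_json(f)
  for (v in names(bn$cpts)) {
    expect_equal(back$cpts[[v]]$prob, bn$cpts[[v]]$prob, tolerance = 1e-12)
  }
  expect_equal(dplyr::arrange(back$dag$arcs, from, to),
               dplyr::arrange(bn$dag$arcs, from, to))
})

test_that("CPT validation rejects malformed tables", {
  nodes <- tibble::tibble(
    node_id = c("a", "b"), label = c("a", "b"), tier = c(1L, 2L),
    states = list(c("x", "y"), c("x", "y"))
  )
  expect_error(cpt("a", character(0), c(.7, .7), nodes), class = "escbn_cpt_error")
  expect_error(cpt("b", "a", matrix(c(-.2, 1.2, .5, .5), 2), nodes),
               class = "escbn_cpt_error")
  dag <- bn_dag(nodes, tibble::tibble(from = "a", to = "b"))
  expect_error(
    discrete_bn(dag, list(a = cpt("a", character(0), c(.5, .5), nodes))),
    class = "escbn_cpt_error"
  )
})
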