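two_node_nodes <- tibble::tibble(
  node_id = c("a", "b"), label = c("a", "b"), tier = c(1L, 2L),
  states = list(c("x", "y"), c("x", "y"))
)

test_that("complete-data MLE recovers frequencies and Laplace arithmetic", {
  nodes <- tibble::tibble(node_id = "g", label = "g", tier = 1L,
                          states = list(c("female", "male")))
  dag <- bn_dag(nodes)
  d <- tibble::tibble(g = rep(c("female", "male"), c(64, 36)))
  fit <- mle_complete(dag, d, pseudo_count = 0)
  expect_equal(as.numeric(fit$cpts$g$prob), c(0.64, 0.36))
  d1 <- tibble::tibble(g = "female")
  fit1 <- mle_complete(dag, d1, pseudo_count = 1)
  expect_equal(as.numeric(fit1$cpts$g$prob), c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_error(mle_complete(dag, d1[0, ]), class = "escbn_data_error")
  expect_error(mle_complete(dag, tibble::tibble(g = NA_character_)),
               class = "escbn_data_error")
})

test_that("unseen parent configurations get uniform rows at zero smoothing", {
  dag <- bn_dag(two_node_nodes, tibble::tibble(from = "a", to = "b"))
  d <- tibble::tibble(a = c("x", "x"), b = c("x", "y"))  # a = y never seen
  fit <- mle_complete(dag, d, pseudo_count = 0)
  expect_equal(as.numeric(fit$cpts$b$prob[, "y"]), c(.5, .5))
})

test_that("expected counts are exact tabulations on complete data", {
  withr::local_seed(29)
  bn <- random_small_bn(4)
  d <- sample_dataset(bn, 300, seed = 2)
  ec <- expected_counts(bn, d)
  mle <- mle_complete(bn$dag, d, pseudo_count = 0)
  n_obs <- vapply(ec$counts, sum, numeric(1))
  expect_true(all(abs(n_obs - 300) < 1e-9))
  # counts reproduce the closed-form MLE after normalization
  for (v in names(ec$counts)) {
    dims <- dim(bn$cpts[[v]]$prob)
    mat <- matrix(ec$counts[[v]], nrow = dims[1])
    tot <- colSums(mat)
    mat <- sweep(mat, 2, pmax(tot, 1), `/`)
    mat[, tot == 0] <- 1 / dims[1]
    expect_equal(array(mat, dims), unclass(mle$cpts[[v]]$prob),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("a missing binary cell contributes its posterior as fractional counts", {
  nodes <- two_node_nodes
  dag <- bn_dag(nodes, tibble::tibble(from = "a", to = "b"))
  bn <- discrete_bn(dag, list(
    a = cpt("a", character(0), c(.6, .4), nodes),
    b = cpt("b", "a", matrix(c(.9, .1, .2, .8), 2), nodes)
  ))
  d <- tibble::tibble(a = NA_character_, b = "x")
  ec <- expected_counts(bn, d)
  # P(a | b = x) = (.6*.9, .4*.2) normalized = (27/31, 4/31)
  expect_equal(as.numeric(ec$counts$a), c(27, 4) / 31, tolerance = 1e-12)
  expect_equal(ec$loglik, log(.6 * .9 + .4 * .2), tolerance = 1e-12)
  # an all-missing record contributes the model's joint as counts
  d_all <- tibble::tibble(a = NA_character_, b = NA_character_)
  ec_all <- expected_counts(bn, d_all)
  expect_equal(as.numeric(ec_all$counts$a), c(.6, .4), tolerance = 1e-12)
  expect_equal(sum(ec_all$counts$b), 1, tolerance = 1e-12)
  expect_equal(ec_all$loglik, 0, tolerance = 1e-12)
})

test_that("EM reduces to the closed-form MLE on complete data", {
  withr::local_seed(31)
  bn <- random_small_bn(4)
  d <- sample_dataset(bn, 400, seed = 5)
  fit <- em_fit(bn$dag, d, em_config(seed = 1, pseudo_count = 0, n_restarts = 1))
  mle <- mle_complete(bn$dag, d, pseudo_count = 0)
  for (v in names(fit$bn$cpts)) {
    expect_equal(fit$bn$cpts[[v]]$prob, mle$cpts[[v]]$prob, tolerance = 1e-9)
  }
  expect_lte(fit$iterations, 3)  # one effective iteration plus the stop check
})

test_that("EM log-likelihood is monotone across many random problems", {
  withr::local_seed(37)
  for (rep in 1:12) {
    bn <- random_small_bn(sample(3:4, 1))
    d <- sample_dataset(bn, 150, seed = rep)
    d <- inject_missingness(d, 0.25, seed = rep)
    fit0 <- em_fit(bn$dag, d, em_config(seed = rep, tol = 1e-7, max_iter = 60,
                                        pseudo_count = 0, n_restarts = 1))
    expect_true(all(diff(fit0$loglik_trace) > -1e-8))
    fit_s <- em_fit(bn$dag, d, em_config(seed = rep, tol = 1e-7, max_iter = 60,
                                         pseudo_count = 0.5, n_restarts = 1))
    expect_true(all(diff(fit_s$objective_trace) > -1e-8))
  }
})

test_that("EM is deterministic given the seed and invariant to record order", {
  withr::local_seed(41)
  bn <- random_small_bn(4)
  d <- inject_missingness(sample_dataset(bn, 200, seed = 1), 0.2, seed = 2)
  cfg <- em_config(seed = 9, tol = 1e-6, max_iter = 40, n_restarts = 2)
  f1 <- em_fit(bn$dag, d, cfg)
  f2 <- em_fit(bn$dag, d, cfg)
  expect_identical(f1$loglik, f2$loglik)
  d_shuffled <- d[sample(nrow(d)), ]
  f3 <- em_fit(bn$dag, d_shuffled, cfg)
  expect_equal(f1$loglik, f3$loglik, tolerance = 1e-8)
  for (v in names(f1$bn$cpts)) {
    expect_equal(f1$bn$cpts[[v]]$prob, f3$bn$cpts[[v]]$prob, tolerance = 1e-8)
  }
})

test_that("log-likelihood matches the enumeration oracle with missing cells", {
  withr::local_seed(43)
  for (rep in 1:8) {
    bn <- random_small_bn(4)
    j <- enumerate_joint(bn)
    d <- inject_missingness(sample_dataset(bn, 25, seed = rep), 0.3, seed = rep)
    ll <- as.numeric(log_likelihood(bn, d))
    # oracle: sum the joint over every cell compatible with the observed part
    ids <- bn$dag$nodes$node_id
    ll_oracle <- 0
    for (i in seq_len(nrow(d))) {
      idx <- lapply(ids, function(v) {
        st <- bn$dag$nodes$states[[match(v, ids)]]
        if (is.na(d[[v]][i])) seq_along(st) else match(d[[v]][i], st)
      })
      ll_oracle <- ll_oracle + log(sum(do.call(`[`, c(list(j), idx))))
    }
    expect_equal(ll, ll_oracle, tolerance = 1e-9)
  }
  expect_equal(as.numeric(log_likelihood(bn, sample_dataset(bn, 0, seed = 1))), 0)
})

test_that("best-of-restarts is selected by final log-likelihood", {
  withr::local_seed(47)
  bn <- random_small_bn(3)
  d <- inject_missingness(sample_dataset(bn, 120, seed = 3), 0.3, seed = 4)
  f3 <- em_fit(bn$dag, d, em_config(seed = 5, tol = 1e-6, max_iter = 50,
                                    n_restarts = 3))
  f1 <- em_fit(bn$dag, d, em_config(seed = 5, tol = 1e-6, max_iter = 50,
                                    n_restarts = 1))
  expect_gte(f3$loglik + 1e-9, f1$loglik)
})
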