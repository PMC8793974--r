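test_that("the RBF kernel evaluates, bounds and errors as defined", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), gamma = 3), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 1), gamma = 0.5), exp(-1))
  expect_equal(round(rbf_kernel(c(0, 0), c(1, 1), 0.5), 4), 0.3679)
  expect_equal(rbf_kernel(c(0, 3), c(2, -1), 1), rbf_kernel(c(2, -1), c(0, 3), 1))
  expect_gt(rbf_kernel(c(0, 0), c(100, 0), gamma = 1e-9), 0.99) # gamma -> 0+
  expect_error(rbf_kernel(c(0), c(1), gamma = 0), "gamma")
  expect_error(rbf_kernel(c(0), c(1, 2), gamma = 1), "equal length")
})

test_that("the two-point problem puts the boundary midway", {
  d <- tibble::tibble(x = c(0, 1), y = c(-1, 1))
  fit <- wsvm_fit(d, weights = "none", cost = 100, gamma = 1,
                  standardize = FALSE)
  dec <- predict(fit, tibble::tibble(x = c(0, 1, 0.5)), type = "decision")
  expect_equal(dec[1], -dec[2], tolerance = 1e-6)
  expect_equal(dec[3], 0, tolerance = 1e-8)
  expect_equal(predict(fit, d), d$y)
})

test_that("a decision value of exactly zero classifies as +1", {
  # hand-built model whose decision at the midpoint is exactly 0: two
  # support vectors with opposite coefficients, identical kernel values
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    container = "wsvm-model", version = 1, features = "x",
    support_vectors = list(x = c(0, 1)), dual_coefs = c(-2, 2),
    bias = 0, gamma = 1, cost = 1, n = 2, objective = 0,
    weights = NULL, standardization = NULL
  ), path, auto_unbox = TRUE, digits = NA)
  m <- wsvm_from_json(path)
  expect_identical(predict(m, tibble::tibble(x = 0.5), type = "decision"), 0)
  expect_equal(predict(m, tibble::tibble(x = 0.5)), 1)
})

test_that("the dual equality constraint holds on random fits", {
  for (seed in 1:5) {
    d <- random_dataset(n = 30, p = 3, seed = seed, delta = c(1, 0, 0))
    fit <- wsvm_fit(d, weights = "none", cost = 2, gamma = 0.5)
    expect_lt(abs(sum(fit$alpha * d$y)), 1e-6)
    expect_true(all(fit$alpha >= -1e-12 & fit$alpha <= 2 + 1e-12))
    expect_lt(fit$kkt_gap, 1e-4)
  }
})

test_that("the SMO dual objective matches the interior-point QP oracle", {
  for (seed in 1:8) {
    n <- 4 + (seed %% 5)
    d <- random_dataset(n = n, p = 2, seed = 200 + seed)
    if (length(unique(d$y)) < 2) next
    fit <- wsvm_fit(d, weights = "none", cost = 1, gamma = 1,
                    standardize = FALSE)
    X <- as.matrix(d[c("x1", "x2")])
    K <- exp(-1 * as.matrix(stats::dist(X))^2)
    alpha_ip <- ipop_svm_dual(K, d$y, C = 1)
    expect_equal(dual_objective(fit$alpha, K, d$y),
                 dual_objective(alpha_ip, K, d$y),
                 tolerance = 1e-4)
    # solver-reported objective is the same quantity
    expect_equal(fit$objective, dual_objective(fit$alpha, K, d$y),
                 tolerance = 1e-8)
  }
})

test_that("decision values equal the double-loop kernel expansion", {
  d <- random_dataset(n = 25, p = 3, seed = 42, delta = c(1.5, 0, 0))
  fit <- wsvm_fit(d, weights = "none", cost = 1, gamma = 0.7,
                  standardize = FALSE)
  queries <- as.matrix(random_dataset(n = 10, p = 3, seed = 43)[paste0("x", 1:3)])
  dec <- predict(fit, queries, type = "decision")
  oracle <- kernel_sum_oracle(fit$support_vectors, fit$dual_coefs, fit$bias,
                              0.7, queries)
  expect_equal(dec, oracle, tolerance = 1e-10)
})

test_that("separable training data is classified perfectly at large cost", {
  d <- random_dataset(n = 40, p = 2, seed = 17, delta = c(8, 8))
  fit <- wsvm_fit(d, weights = "none", cost = 1000, gamma = 1)
  expect_equal(predict(fit, d), d$y)
})

test_that("single-class input and bad parameters are rejected", {
  d <- tibble::tibble(x = rnorm(10), y = rep(1, 10))
  expect_error(wsvm_fit(d), "Both classes")
  d2 <- random_dataset(n = 10, p = 1, seed = 1)
  expect_error(wsvm_fit(d2, cost = -1), "cost")
  expect_error(wsvm_fit(d2, gamma = 0), "gamma")
  fit <- wsvm_fit(d2)
  expect_error(predict(fit, tibble::tibble(z = 1)), "lacks feature")
})

test_that("uniform weights with width g equal the unweighted SVM at g/p^2", {
  for (seed in 1:3) {
    p <- 4
    d <- random_dataset(n = 30, p = p, seed = 300 + seed, delta = c(1, 1, 0, 0))
    f_w <- wsvm_fit(d, weights = "uniform", cost = 1, gamma = 1,
                    standardize = FALSE)
    f_u <- wsvm_fit(d, weights = "none", cost = 1, gamma = 1 / p^2,
                    standardize = FALSE)
    expect_equal(f_w$alpha, f_u$alpha, tolerance = 1e-8)
    q <- random_dataset(n = 15, p = p, seed = 400 + seed)[paste0("x", 1:p)]
    expect_identical(predict(f_w, q), predict(f_u, q))
  }
})

test_that("raising the cost never increases training misclassifications", {
  d <- random_dataset(n = 60, p = 2, seed = 88, delta = c(1, 0.5))
  errs <- vapply(c(0.01, 0.1, 1, 10, 100), function(C) {
    fit <- wsvm_fit(d, weights = "none", cost = C, gamma = 1)
    sum(predict(fit, d) != d$y)
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
})

test_that("JSON serialization round-trips to identical predictions", {
  d <- generate_synthetic(synthetic_spec(n = 60, seed = 21))
  fit <- wsvm_fit(d, cost = 2)
  path <- tempfile(fileext = ".json")
  wsvm_to_json(fit, path)
  fit2 <- wsvm_from_json(path)
  expect_equal(predict(fit2, d, type = "decision"),
               predict(fit, d, type = "decision"), tolerance = 1e-12)
  expect_identical(predict(fit2, d), predict(fit, d))
})

test_that("tuning selects by CV error with the documented tie-break", {
  d <- random_dataset(n = 60, p = 2, seed = 55, delta = c(2, 0))
  one <- wsvm_tune(d, grid = wsvm_grid(cost = 1, gamma = 0.5), k = 5, seed = 3)
  expect_equal(one$best$cost, 1)
  expect_equal(one$best$gamma, 0.5)
  expect_equal(nrow(one$grid), 1)

  grid <- wsvm_grid(cost = c(0.5, 2), gamma = c(0.1, 0.5))
  t1 <- wsvm_tune(d, grid = grid, k = 5, seed = 9)
  t2 <- wsvm_tune(d, grid = grid, k = 5, seed = 9)
  expect_identical(t1$grid, t2$grid)
  expect_identical(t1$best, t2$best)
  expect_equal(t1$best$cv_error, min(t1$grid$cv_error))
  # tie-break: smallest cost then smallest gamma among minimisers
  mins <- t1$grid[t1$grid$cv_error == min(t1$grid$cv_error), ]
  ord <- order(mins$cost, mins$gamma)
  expect_equal(t1$best$cost, mins$cost[ord[1]])
  expect_equal(t1$best$gamma, mins$gamma[ord[1]])
})

test_that("near-separable synthetic data tunes to a low CV error", {
  d <- random_dataset(n = 200, p = 2, seed = 66, delta = c(3, 3))
  tn <- wsvm_tune(d, grid = wsvm_grid(cost = c(1, 8), gamma = c(0.125, 0.5)),
                  k = 10, seed = 12)
  expect_lte(tn$best$cv_error, 0.05)
})

test_that("tuning preconditions are enforced", {
  d <- random_dataset(n = 12, p = 1, seed = 5)
  expect_error(wsvm_tune(d, k = 13), "exceed")
  expect_error(wsvm_tune(d, grid = tibble::tibble()), "non-empty")
  skew <- tibble::tibble(x = rnorm(12), y = c(rep(1, 11), -1))
  expect_error(wsvm_tune(skew, k = 10, grid = wsvm_grid(1, 1)),
               "single class.*smaller k")
})
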