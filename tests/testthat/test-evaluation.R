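test_that("stratified splitting reproduces the published size arithmetic", {
  d <- cleveland_sized_labels() # 137 positive, 160 negative
  sp <- make_split(d, ratio = 0.8, seed = 1)
  expect_equal(length(sp$train_ids), 238) # 110 + 128
  expect_equal(length(sp$test_ids), 59)
  expect_setequal(c(sp$train_ids, sp$test_ids), seq_len(297))
  # per-class composition
  expect_equal(sum(d$y[sp$train_ids] == 1), 110)
  expect_equal(sum(d$y[sp$train_ids] == -1), 128)
  # size arithmetic is deterministic across seeds
  sizes <- vapply(1:20, function(s) {
    length(make_split(d, 0.8, seed = s)$test_ids)
  }, numeric(1))
  expect_true(all(sizes == 59))
})

test_that("splits are reproducible and validated", {
  d <- cleveland_sized_labels()
  s1 <- make_split(d, 0.5, seed = 42)
  s2 <- make_split(d, 0.5, seed = 42)
  expect_identical(s1$train_ids, s2$train_ids)
  expect_false(identical(make_split(d, 0.5, seed = 43)$train_ids, s1$train_ids))

  small <- tibble::tibble(x = 1:8, y = rep(c(1, -1), 4))
  expect_error(make_split(small, ratio = 0.05, seed = 1), "empty in the training")
  expect_error(make_split(small, ratio = 0.95, seed = 1), "test set empty")
  expect_error(make_split(small, ratio = 1.2, seed = 1), "inside")

  uns <- make_split(small, 0.5, seed = 1, stratified = FALSE)
  expect_equal(length(uns$train_ids), 4)
})

test_that("confusion counts fill the four cells", {
  perfect <- confusion(rep(1, 5), rep(1, 5))
  expect_equal(tidy(perfect), tibble::tibble(tp = 5, fp = 0, fn = 0, tn = 0, n = 5))

  inverted <- confusion(c(1, -1, 1), c(-1, 1, -1))
  expect_equal(inverted$tp + inverted$tn, 0)
  expect_equal(inverted$fp, 2)
  expect_equal(inverted$fn, 1)

  pred <- rep(c(1, 1, -1, -1), c(9, 1, 2, 8))
  truth <- rep(c(1, -1, 1, -1), c(9, 1, 2, 8))
  cm <- confusion(pred, truth)
  expect_equal(tidy(cm)[1:4], tibble::tibble(tp = 9, fp = 1, fn = 2, tn = 8))

  expect_error(confusion(c(1, 0), c(1, 1)), "-1/\\+1")
  expect_error(confusion(numeric(0), numeric(0)), "non-empty|-1/\\+1")
})

test_that("the seven indices follow their defining ratios", {
  out <- perf_indices(list(tp = 9, fp = 1, fn = 2, tn = 8))
  expect_equal(out$acc, 0.85)
  expect_equal(out$mer, 0.15)
  expect_equal(round(out$se, 4), 0.8182)
  expect_equal(round(out$sp, 4), 0.8889)
  expect_equal(out$p_plus, 0.9)
  expect_equal(out$p_minus, 0.8)
  expect_equal(out$ji, 0.75)

  perfect <- perf_indices(list(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_equal(unlist(perfect[c("acc", "se", "sp", "p_plus", "p_minus", "ji")]),
               c(acc = 1, se = 1, sp = 1, p_plus = 1, p_minus = 1, ji = 1))
  expect_equal(perfect$mer, 0)

  worst <- perf_indices(list(tp = 0, fp = 3, fn = 2, tn = 0))
  expect_equal(worst$acc, 0)
  expect_equal(worst$mer, 1)
  expect_equal(worst$ji, 0)
})

test_that("zero-denominator indices are flagged undefined, not zeroed", {
  no_pos <- perf_indices(list(tp = 0, fp = 0, fn = 0, tn = 4))
  expect_true(is.na(no_pos$se))
  expect_true(is.na(no_pos$p_plus))
  expect_true(is.na(no_pos$ji))
  expect_equal(no_pos$acc, 1)
  expect_error(perf_indices(list(tp = 0, fp = 0, fn = 0, tn = 0)), "N = 0")
  expect_error(perf_indices(list(tp = -1, fp = 0, fn = 0, tn = 2)),
               "non-negative")
})

test_that("a single MCCV iteration is its own mean", {
  d <- generate_synthetic(synthetic_spec(n = 100, seed = 13))
  rep1 <- mccv(d, ratio = 0.8, n_iter = 1, seed = 7,
               pipeline = wsvm_pipeline(tune = FALSE))
  expect_equal(as.numeric(rep1$mean_report),
               as.numeric(rep1$per_iteration[names(rep1$mean_report)]))
})

test_that("MCCV is reproducible from the master seed and brackets its mean", {
  d <- generate_synthetic(synthetic_spec(n = 100, seed = 14))
  pl <- wsvm_pipeline(tune = FALSE)
  r1 <- mccv(d, ratio = 0.75, n_iter = 8, seed = 21, pipeline = pl)
  r2 <- mccv(d, ratio = 0.75, n_iter = 8, seed = 21, pipeline = pl)
  expect_identical(r1$per_iteration, r2$per_iteration)
  expect_identical(r1$mean_report, r2$mean_report)

  for (idx in c("acc", "mer", "se", "sp")) {
    v <- r1$per_iteration[[idx]]
    m <- r1$mean_report[[idx]]
    expect_gte(m, min(v, na.rm = TRUE))
    expect_lte(m, max(v, na.rm = TRUE))
  }
  # accuracy and error are complements, iteration by iteration
  expect_equal(r1$per_iteration$acc + r1$per_iteration$mer, rep(1, 8))
})

test_that("near-separable data yields a low mean MCCV error", {
  d <- random_dataset(n = 300, p = 2, seed = 19, delta = c(3, 3))
  rep <- mccv(d, ratio = 0.8, n_iter = 50, seed = 5,
              pipeline = wsvm_pipeline(tune = FALSE, cost = 10, gamma = 0.5))
  expect_lte(rep$mean_report$mer, 0.05)
})

test_that("weight modes and failed iterations are handled", {
  d <- generate_synthetic(synthetic_spec(n = 80, seed = 23))
  full <- mccv(d, ratio = 0.8, n_iter = 2, seed = 3,
               pipeline = wsvm_pipeline(weights_mode = "full", tune = FALSE))
  per <- mccv(d, ratio = 0.8, n_iter = 2, seed = 3,
              pipeline = wsvm_pipeline(weights_mode = "per_split", tune = FALSE))
  expect_false(identical(full$mean_report, per$mean_report))
  expect_equal(full$n_failed, 0)
})

test_that("a single-method comparison is exactly an MCCV run", {
  d <- generate_synthetic(synthetic_spec(n = 100, seed = 31))
  pl <- wsvm_pipeline(tune = FALSE)
  cmp <- compare_classifiers(d, ratios = 0.8, methods = "wsvm",
                             n_iter = 4, seed = 11, pipeline = pl)
  rep <- mccv(d, ratio = 0.8, n_iter = 4, seed = 11, pipeline = pl)
  expect_equal(cmp$summary$mean_mer, rep$mean_report$mer)
  expect_equal(cmp$per_iteration$mer, rep$per_iteration$mer)
})

test_that("multi-method comparisons share splits and reproduce exactly", {
  d <- generate_synthetic(synthetic_spec(n = 90, seed = 37))
  pl <- wsvm_pipeline(tune = FALSE)
  c1 <- compare_classifiers(d, ratios = c(0.8, 0.5), methods = c("wsvm", "svm", "rf", "nb"),
                            n_iter = 2, seed = 2, pipeline = pl)
  c2 <- compare_classifiers(d, ratios = c(0.8, 0.5), methods = c("wsvm", "svm", "rf", "nb"),
                            n_iter = 2, seed = 2, pipeline = pl)
  expect_identical(c1$summary, c2$summary)
  expect_equal(nrow(c1$summary), 8) # 4 methods x 2 ratios, no missing cells
  # seeds are shared across methods within a (ratio, iteration) cell
  seeds <- tidyr::pivot_wider(c1$per_iteration[c("method", "ratio", "iteration", "seed")],
                              names_from = "method", values_from = "seed")
  expect_equal(seeds$wsvm, seeds$svm)
  expect_equal(seeds$wsvm, seeds$rf)
  expect_error(compare_classifiers(d, methods = "boost"), "subset")
})
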