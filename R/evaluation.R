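round_half_up <- function(x) floor(x + 0.5)

#' Random train/test split at a fixed ratio
#'
#' Stratified by default: each class contributes a share of the training set
#' equal to the ratio, with per-class sizes rounded to the nearest integer
#' (half rounds up). On the 297-record heart-disease data at ratio 0.80 this
#' gives 110 + 128 = 238 training and 59 test records for every seed.
#'
#' @param data Data frame containing the label column.
#' @param ratio Training fraction, strictly inside (0, 1).
#' @param seed Integer seed; membership is deterministic given the seed.
#' @param stratified Stratify by label (default `TRUE`).
#' @param response Label column (unquoted), coded -1/+1. Default `y`.
#' @return An object of class `wsvm_split` with integer row indices
#'   `train_ids` and `test_ids` (disjoint, covering all rows).
#' @export
make_split <- function(data, ratio, seed, stratified = TRUE, response = y) {
  parts <- split_response(data, enquo(response))
  yv <- parts$y
  n <- length(yv)
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio <= 0 || ratio >= 1) {
    abort("`ratio` must lie strictly inside (0, 1).")
  }
  train_ids <- integer(0)
  with_seed(seed, {
    if (isTRUE(stratified)) {
      for (cls in c(-1, 1)) {
        idx <- which(yv == cls)
        n_tr <- round_half_up(ratio * length(idx))
        if (length(idx) > 0 && n_tr == 0) {
          abort(sprintf(
            "Ratio %.3f leaves class %+d empty in the training set.", ratio, cls
          ))
        }
        train_ids <- c(train_ids, sample(idx, n_tr))
      }
    } else {
      n_tr <- round_half_up(ratio * n)
      if (n_tr == 0) abort("Ratio leaves the training set empty.")
      train_ids <- sample(seq_len(n), min(n_tr, n))
    }
  })
  train_ids <- sort(train_ids)
  test_ids <- setdiff(seq_len(n), train_ids)
  if (length(test_ids) == 0) {
    abort(sprintf("Ratio %.3f leaves the test set empty for n = %d.", ratio, n))
  }
  structure(
    list(train_ids = train_ids, test_ids = test_ids, ratio = ratio,
         seed = as.integer(seed), stratified = isTRUE(stratified)),
    class = "wsvm_split"
  )
}

#' @export
print.wsvm_split <- function(x, ...) {
  cat(sprintf("<wsvm_split> ratio %.2f (%s): %d train / %d test, seed %d\n",
              x$ratio, if (x$stratified) "stratified" else "simple",
              length(x$train_ids), length(x$test_ids), x$seed))
  invisible(x)
}

#' Confusion matrix for a -1/+1 prediction task
#'
#' @param pred,truth Label vectors in \{-1, +1\} of equal length.
#' @return An object of class `wsvm_confusion` with counts `tp` (both +1),
#'   `fp` (predicted +1, truly -1), `fn` (predicted -1, truly +1), `tn`
#'   (both -1) and `n = tp + fp + fn + tn`.
#' @export
#' @examples
#' confusion(c(1, 1, -1), c(1, -1, -1))
confusion <- function(pred, truth) {
  pred <- as_pm1(pred)
  truth <- as_pm1(truth)
  if (length(pred) != length(truth) || length(pred) < 1) {
    abort("`pred` and `truth` must be non-empty vectors of equal length.")
  }
  structure(
    list(
      tp = sum(pred == 1 & truth == 1),
      fp = sum(pred == 1 & truth == -1),
      fn = sum(pred == -1 & truth == 1),
      tn = sum(pred == -1 & truth == -1),
      n = length(pred)
    ),
    class = "wsvm_confusion"
  )
}

#' @export
print.wsvm_confusion <- function(x, ...) {
  cat(sprintf("<wsvm_confusion> N = %d\n", x$n))
  print(matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
               dimnames = list(predicted = c("+1", "-1"),
                               truth = c("+1", "-1"))))
  invisible(x)
}

#' @export
tidy.wsvm_confusion <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn, n = x$n)
}

index_names <- c("acc", "mer", "se", "sp", "p_plus", "p_minus", "ji")

#' Seven performance indices from a confusion matrix
#'
#' Accuracy `(TP+TN)/N`, misclassification error rate `(FP+FN)/N`,
#' sensitivity `TP/(TP+FN)`, specificity `TN/(FP+TN)`, positive predictive
#' value `TP/(TP+FP)`, negative predictive value `TN/(TN+FN)` and the
#' Jaccard index `TP/(TP+FP+FN)`. An index whose denominator is zero is
#' undefined and reported as `NA`, never silently as 0.
#'
#' @param cm A `wsvm_confusion` from [confusion()], or a data frame / list
#'   with fields `tp`, `fp`, `fn`, `tn`.
#' @return A one-row tibble with columns `acc`, `mer`, `se`, `sp`,
#'   `p_plus`, `p_minus`, `ji`, all in \[0, 1\].
#' @export
#' @examples
#' perf_indices(confusion(c(1, 1, -1, -1), c(1, -1, -1, -1)))
perf_indices <- function(cm) {
  need <- c("tp", "fp", "fn", "tn")
  if (!all(need %in% names(cm))) {
    abort("`cm` must carry counts `tp`, `fp`, `fn`, `tn`.")
  }
  cnt <- lapply(cm[need], as.numeric)
  if (any(vapply(cnt, function(v) length(v) != 1 || is.na(v) || v < 0 ||
                   v != floor(v), logical(1)))) {
    abort("Counts must be single non-negative integers.")
  }
  tp <- cnt$tp; fp <- cnt$fp; fn <- cnt$fn; tn <- cnt$tn
  n <- tp + fp + fn + tn
  if (n < 1) abort("Empty confusion matrix (N = 0).")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    acc = (tp + tn) / n,
    mer = (fp + fn) / n,
    se = safe_div(tp, tp + fn),
    sp = safe_div(tn, fp + tn),
    p_plus = safe_div(tp, tp + fp),
    p_minus = safe_div(tn, tn + fn),
    ji = safe_div(tp, tp + fp + fn)
  )
}

#' Configure the per-iteration w-SVM pipeline
#'
#' Bundles the modelling choices repeated inside every Monte-Carlo
#' cross-validation iteration.
#'
#' @param weights_mode How feature weights are obtained per iteration:
#'   `"per_split"` (default) recomputes point-biserial weights on the
#'   training portion only, so no test information leaks into the weighting;
#'   `"full"` computes them once from the complete dataset (mirroring a
#'   published full-data weight table); `"uniform"` and `"none"` disable
#'   differential weighting.
#' @param tune Re-tune `(cost, gamma)` by k-fold CV inside each training set.
#' @param grid,k Tuning grid and fold count, used when `tune = TRUE`.
#' @param cost,gamma Hyperparameters used when `tune = FALSE`
#'   (`gamma = NULL` means `1/p`).
#' @param standardize Z-score continuous features with training statistics.
#' @return A `wsvm_pipeline` configuration list.
#' @export
wsvm_pipeline <- function(weights_mode = c("per_split", "full", "uniform", "none"),
                          tune = FALSE, grid = wsvm_grid(), k = 10,
                          cost = 1, gamma = NULL, standardize = TRUE) {
  weights_mode <- match.arg(weights_mode)
  structure(
    list(weights_mode = weights_mode, tune = isTRUE(tune), grid = grid,
         k = k, cost = cost, gamma = gamma, standardize = isTRUE(standardize)),
    class = "wsvm_pipeline"
  )
}

# Subset rows of a dataset, preserving the metadata attribute.
subset_keep_meta <- function(data, ids) {
  out <- data[ids, , drop = FALSE]
  attr(out, "meta") <- attr(data, "meta")
  out
}

# One MCCV iteration: split -> (weights, tuning) on train -> fit -> test
# indices. Shared by mccv() and compare_classifiers() so a single-method
# comparison is exactly an mccv run.
wsvm_iteration <- function(data, resp, ratio, iter_seed, pipeline,
                           stratified, full_weights = NULL) {
  sp <- make_split(data, ratio, iter_seed, stratified = stratified,
                   response = !!rlang::sym(resp))
  train <- subset_keep_meta(data, sp$train_ids)
  test <- subset_keep_meta(data, sp$test_ids)
  weights <- switch(pipeline$weights_mode,
    per_split = "auto",
    full = full_weights,
    uniform = "uniform",
    none = "none"
  )
  cost <- pipeline$cost
  gamma <- pipeline$gamma
  if (pipeline$tune) {
    tn <- wsvm_tune(train, response = !!rlang::sym(resp), grid = pipeline$grid,
                    k = pipeline$k, seed = derive_seed(iter_seed, 1),
                    weights = weights, standardize = pipeline$standardize)
    cost <- tn$best$cost
    gamma <- tn$best$gamma
  }
  fit <- wsvm_fit(train, response = !!rlang::sym(resp), weights = weights,
                  cost = cost, gamma = gamma,
                  standardize = pipeline$standardize)
  pred <- predict(fit, test)
  cm <- confusion(pred, as_pm1(test[[resp]]))
  list(split = sp, train = train, test = test, fit = fit, cm = cm,
       indices = perf_indices(cm), cost = cost,
       gamma = if (is.null(gamma)) 1 / (ncol(data) - 1) else gamma)
}

#' Monte-Carlo cross-validation of the w-SVM
#'
#' Repeats, `n_iter` times: draw a stratified train/test split at the given
#' ratio, compute feature weights (and optionally tune hyperparameters) on
#' the training portion, fit the w-SVM, and score the seven performance
#' indices on the held-out test records. Each iteration's seed is derived
#' from `seed` and the iteration counter, so any single iteration can be
#' reproduced in isolation.
#'
#' The summary reports arithmetic means of the per-iteration indices; an
#' index undefined in some iteration (zero denominator, possible with very
#' small test sets) is excluded from that index's mean and counted in
#' `undefined_counts`. A pooled summary (indices of the summed confusion
#' counts) is also provided.
#'
#' @param data Data frame of numeric predictors plus the label column.
#' @param ratio Training fraction (default 0.8, the usual 80:20 rule).
#' @param n_iter Number of Monte-Carlo iterations.
#' @param seed Master seed.
#' @param pipeline A [wsvm_pipeline()] configuration.
#' @param stratified Stratify the splits by label.
#' @param response Label column (unquoted), coded -1/+1. Default `y`.
#' @return An object of class `wsvm_mccv`: `per_iteration` tibble (seeds,
#'   chosen hyperparameters, confusion counts and indices), `mean_report`,
#'   `pooled_report`, `undefined_counts` and provenance fields.
#' @export
#' @examples
#' d <- generate_synthetic(synthetic_spec(n = 120, seed = 5))
#' rep <- mccv(d, ratio = 0.8, n_iter = 3, seed = 42)
#' glance(rep)
mccv <- function(data, ratio = 0.8, n_iter = 1000, seed = 1L,
                 pipeline = wsvm_pipeline(), stratified = TRUE,
                 response = y) {
  if (!is.numeric(n_iter) || n_iter < 1) abort("`n_iter` must be >= 1.")
  if (!inherits(pipeline, "wsvm_pipeline")) {
    abort("`pipeline` must come from wsvm_pipeline().")
  }
  resp <- as_name(enquo(response))
  full_weights <- NULL
  if (pipeline$weights_mode == "full") {
    full_weights <- pb_weights(pb_correlations(data, response = !!rlang::sym(resp)))
  }
  rows <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    iter_seed <- derive_seed(seed, it)
    res <- tryCatch(
      wsvm_iteration(data, resp, ratio, iter_seed, pipeline, stratified,
                     full_weights),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      rows[[it]] <- tibble::tibble(
        iteration = it, seed = iter_seed, cost = NA_real_, gamma = NA_real_,
        tp = NA_integer_, fp = NA_integer_, fn = NA_integer_, tn = NA_integer_,
        acc = NA_real_, mer = NA_real_, se = NA_real_, sp = NA_real_,
        p_plus = NA_real_, p_minus = NA_real_, ji = NA_real_,
        error = conditionMessage(res)
      )
    } else {
      rows[[it]] <- dplyr::bind_cols(
        tibble::tibble(iteration = it, seed = iter_seed, cost = res$cost,
                       gamma = res$gamma),
        tidy(res$cm)[c("tp", "fp", "fn", "tn")],
        res$indices,
        tibble::tibble(error = NA_character_)
      )
    }
  }
  per_iteration <- dplyr::bind_rows(rows)
  ok <- is.na(per_iteration$error)
  n_failed <- sum(!ok)
  if (n_failed > 0) {
    warn(sprintf("%d of %d MCCV iterations failed; see the `error` column.",
                 n_failed, n_iter))
  }
  mean_report <- dplyr::summarise(
    per_iteration[ok, ],
    dplyr::across(dplyr::all_of(index_names), ~ mean(.x, na.rm = TRUE))
  )
  undefined_counts <- dplyr::summarise(
    per_iteration[ok, ],
    dplyr::across(dplyr::all_of(index_names), ~ sum(is.na(.x)))
  )
  pooled <- dplyr::summarise(
    per_iteration[ok, ],
    dplyr::across(c("tp", "fp", "fn", "tn"), ~ sum(.x))
  )
  pooled_report <- if (nrow(per_iteration[ok, ]) > 0) {
    perf_indices(pooled)
  } else {
    mean_report
  }
  structure(
    list(ratio = ratio, n_iter = as.integer(n_iter),
         per_iteration = per_iteration, mean_report = mean_report,
         pooled_report = pooled_report, undefined_counts = undefined_counts,
         n_failed = n_failed, master_seed = as.integer(seed),
         pipeline = pipeline, stratified = isTRUE(stratified)),
    class = "wsvm_mccv"
  )
}

#' @export
print.wsvm_mccv <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo cross-validation: ratio %.2f, %d iterations (seed %d)\n",
    x$ratio, x$n_iter, x$master_seed
  ))
  m <- x$mean_report
  cat(sprintf(
    "  mean indices (%%): Acc %.2f | MER %.2f | Se %.2f | Sp %.2f | P+ %.2f | P- %.2f | JI %.2f\n",
    100 * m$acc, 100 * m$mer, 100 * m$se, 100 * m$sp, 100 * m$p_plus,
    100 * m$p_minus, 100 * m$ji
  ))
  if (x$n_failed > 0) cat(sprintf("  failed iterations: %d\n", x$n_failed))
  invisible(x)
}

#' @export
tidy.wsvm_mccv <- function(x, ...) x$per_iteration

#' @export
glance.wsvm_mccv <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(ratio = x$ratio, n_iter = x$n_iter,
                   master_seed = x$master_seed, n_failed = x$n_failed),
    x$mean_report
  )
}

#' Distribution of the performance indices across MCCV iterations
#'
#' @param object A `wsvm_mccv` report.
#' @param ... Unused.
#' @return A ggplot: one boxplot per performance index, mean marked.
#' @export
autoplot.wsvm_mccv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_iteration,
                              dplyr::all_of(index_names),
                              names_to = "index", values_to = "value")
  long$index <- factor(long$index, levels = index_names)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red") +
    ggplot2::labs(
      x = NULL, y = "value",
      title = sprintf("MCCV indices: ratio %.2f, %d iterations",
                      object$ratio, object$n_iter)
    ) +
    ggplot2::theme_minimal()
}

#' Paired comparison of classifiers under shared MCCV splits
#'
#' Runs the same Monte-Carlo split sequence for every method so the mean
#' misclassification error rates are paired: within one (ratio, iteration)
#' cell all methods see the identical training and test records. The w-SVM
#' is this package's implementation; the baselines delegate to established
#' implementations (`e1071::svm` with the same RBF parameters on identically
#' standardized data, `randomForest::randomForest`, `e1071::naiveBayes`).
#'
#' @param data Data frame of numeric predictors plus the label column.
#' @param ratios Training fractions to sweep.
#' @param methods Subset of `c("wsvm", "svm", "rf", "nb")`.
#' @param n_iter Iterations per ratio.
#' @param seed Master seed (same derivation as [mccv()], so a
#'   single-method comparison reproduces the mccv MER exactly).
#' @param pipeline A [wsvm_pipeline()] applied to the w-SVM arm; its
#'   `cost`/`gamma` (when `tune = FALSE`) are shared with the unweighted
#'   SVM baseline for a like-for-like contrast.
#' @param stratified Stratify the splits by label.
#' @param response Label column (unquoted), coded -1/+1. Default `y`.
#' @return An object of class `wsvm_comparison`: `summary` tibble of mean
#'   MER per (method, ratio) and the full `per_iteration` tibble.
#' @export
compare_classifiers <- function(data, ratios = c(0.95, 0.9, 0.8, 0.75, 0.5),
                                methods = c("wsvm", "svm", "rf", "nb"),
                                n_iter = 50, seed = 1L,
                                pipeline = wsvm_pipeline(),
                                stratified = TRUE, response = y) {
  allowed <- c("wsvm", "svm", "rf", "nb")
  if (!all(methods %in% allowed)) {
    abort(sprintf("`methods` must be a subset of {%s}.",
                  paste(allowed, collapse = ", ")))
  }
  needs <- c(svm = "e1071", nb = "e1071", rf = "randomForest")
  for (m in intersect(methods, names(needs))) {
    if (!requireNamespace(needs[[m]], quietly = TRUE)) {
      warn(sprintf("Package '%s' unavailable: skipping method '%s'.",
                   needs[[m]], m))
      methods <- setdiff(methods, m)
    }
  }
  if (length(methods) == 0) abort("No requested method is available.")
  resp <- as_name(enquo(response))
  full_weights <- if (pipeline$weights_mode == "full") {
    pb_weights(pb_correlations(data, response = !!rlang::sym(resp)))
  } else {
    NULL
  }
  p <- ncol(data) - 1
  base_gamma <- if (is.null(pipeline$gamma)) 1 / p else pipeline$gamma

  rows <- list()
  for (ratio in ratios) {
    for (it in seq_len(n_iter)) {
      iter_seed <- derive_seed(seed, it)
      res <- wsvm_iteration(data, resp, ratio, iter_seed, pipeline,
                            stratified, full_weights)
      train <- res$train; test <- res$test
      y_tr <- factor(as_pm1(train[[resp]]), levels = c(-1, 1))
      y_te <- as_pm1(test[[resp]])
      x_tr <- train[setdiff(names(train), resp)]
      x_te <- test[setdiff(names(test), resp)]
      for (m in methods) {
        # each method draws from its own derived seed so stochastic
        # learners (random forest) are reproducible run to run
        mer <- with_seed(derive_seed(iter_seed, match(m, allowed)), switch(m,
          wsvm = res$indices$mer,
          svm = {
            st <- standardization_stats(x_tr, attr(train, "meta"))
            fit <- e1071::svm(
              x = as.matrix(apply_standardization(x_tr, st)),
              y = y_tr, kernel = "radial", cost = pipeline$cost,
              gamma = base_gamma, scale = FALSE
            )
            pr <- predict(fit, as.matrix(apply_standardization(x_te, st)))
            mean(as.numeric(as.character(pr)) != y_te)
          },
          rf = {
            fit <- randomForest::randomForest(x = as.data.frame(x_tr), y = y_tr)
            pr <- predict(fit, as.data.frame(x_te))
            mean(as.numeric(as.character(pr)) != y_te)
          },
          nb = {
            fit <- e1071::naiveBayes(x = as.data.frame(x_tr), y = y_tr)
            pr <- predict(fit, as.data.frame(x_te))
            mean(as.numeric(as.character(pr)) != y_te)
          }
        ))
        rows[[length(rows) + 1]] <- tibble::tibble(
          method = m, ratio = ratio, iteration = it, seed = iter_seed,
          mer = mer
        )
      }
    }
  }
  per_iteration <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    dplyr::group_by(per_iteration, .data$method, .data$ratio),
    mean_mer = mean(.data$mer), .groups = "drop"
  )
  structure(
    list(summary = summary, per_iteration = per_iteration,
         methods = methods, ratios = ratios, n_iter = as.integer(n_iter),
         master_seed = as.integer(seed), pipeline = pipeline),
    class = "wsvm_comparison"
  )
}

#' @export
print.wsvm_comparison <- function(x, ...) {
  cat(sprintf("Paired classifier comparison (%d iterations per ratio, seed %d)\n",
              x$n_iter, x$master_seed))
  wide <- tidyr::pivot_wider(x$summary, names_from = "ratio",
                             values_from = "mean_mer")
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.wsvm_comparison <- function(x, ...) x$summary

#' Mean misclassification error rate by method and splitting ratio
#'
#' @param object A `wsvm_comparison`.
#' @param ... Unused.
#' @return A ggplot: mean MER versus training fraction, one line per method.
#' @export
autoplot.wsvm_comparison <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$ratio, y = .data$mean_mer,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "training fraction", y = "mean MER",
                  colour = "method",
                  title = "Paired MCCV misclassification error") +
    ggplot2::theme_minimal()
}
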