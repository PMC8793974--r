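#' Default hyperparameter grid for w-SVM tuning
#'
#' A log2 ladder over the soft-margin cost and the RBF width:
#' `C in 2^{-3, -1, ..., 9}`, `gamma in 2^{-9, -7, ..., 1}`.
#'
#' @param cost,gamma Candidate values; the grid is their cross product.
#' @return A tibble with columns `cost` and `gamma`.
#' @export
wsvm_grid <- function(cost = 2^seq(-3, 9, by = 2),
                      gamma = 2^seq(-9, 1, by = 2)) {
  tidyr::expand_grid(cost = cost, gamma = gamma)
}

# Stratified fold assignment: within each class, shuffle a balanced
# repetition of 1..k. Deterministic given the seed.
stratified_folds <- function(yv, k, seed) {
  n <- length(yv)
  folds <- integer(n)
  with_seed(seed, {
    for (cls in c(-1, 1)) {
      idx <- which(yv == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Select w-SVM hyperparameters by stratified k-fold cross-validation
#'
#' For every `(cost, gamma)` candidate the misclassification rate is averaged
#' over `k` stratified folds (weights and standardization statistics are
#' recomputed on each fold's training portion, so no validation information
#' leaks into the weighting). The candidate with the smallest mean error
#' wins; ties break towards the smallest cost, then the smallest gamma
#' (smoother models preferred).
#'
#' @param data Data frame of numeric predictors plus the label column.
#' @param response Label column (unquoted), coded -1/+1. Default `y`.
#' @param grid Candidate tibble from [wsvm_grid()] (columns `cost`, `gamma`).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param weights,standardize Passed on to [wsvm_fit()].
#' @return An object of class `wsvm_tuning`: the evaluated `grid` with a
#'   `cv_error` column, the selected `best` row, `k` and `folds_seed`.
#' @export
wsvm_tune <- function(data, response = y, grid = wsvm_grid(), k = 10,
                      seed = 1L, weights = "auto", standardize = TRUE) {
  rq <- enquo(response)
  parts <- split_response(data, rq)
  n <- nrow(parts$x)
  if (!is.data.frame(grid) || nrow(grid) == 0 ||
      !all(c("cost", "gamma") %in% names(grid))) {
    abort("`grid` must be a non-empty data frame with columns `cost` and `gamma`.")
  }
  if (k > n) abort(sprintf("k = %d folds exceed n = %d observations.", k, n))
  if (k < 2) abort("At least 2 folds are required.")
  folds <- stratified_folds(parts$y, k, seed)
  for (f in sort(unique(folds))) {
    if (length(unique(parts$y[folds != f])) < 2) {
      abort(sprintf(
        "Training portion of fold %d contains a single class; use a smaller k.", f
      ))
    }
  }
  data_tb <- tibble::as_tibble(data)
  attr(data_tb, "meta") <- attr(data, "meta")
  resp <- parts$response

  cv_error <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- vapply(sort(unique(folds)), function(f) {
      tr <- data_tb[folds != f, , drop = FALSE]
      attr(tr, "meta") <- attr(data_tb, "meta")
      va <- data_tb[folds == f, , drop = FALSE]
      fit <- wsvm_fit(tr, response = !!rlang::sym(resp), weights = weights,
                      cost = grid$cost[g], gamma = grid$gamma[g],
                      standardize = standardize)
      mean(predict(fit, va) != as_pm1(va[[resp]]))
    }, numeric(1))
    mean(errs)
  }, numeric(1))

  res <- tibble::as_tibble(grid)
  res$cv_error <- cv_error
  ord <- order(res$cv_error, res$cost, res$gamma)
  best <- res[ord[1], , drop = FALSE]
  structure(
    list(grid = res, best = best, k = as.integer(k),
         folds_seed = as.integer(seed)),
    class = "wsvm_tuning"
  )
}

#' @export
print.wsvm_tuning <- function(x, ...) {
  cat(sprintf("w-SVM %d-fold CV tuning over %d candidates (folds seed %d)\n",
              x$k, nrow(x$grid), x$folds_seed))
  cat(sprintf("  best: cost = %g, gamma = %g, cv error = %.4f\n",
              x$best$cost, x$best$gamma, x$best$cv_error))
  invisible(x)
}

#' @export
tidy.wsvm_tuning <- function(x, ...) x$grid

#' @export
glance.wsvm_tuning <- function(x, ...) {
  tibble::tibble(
    k = x$k, n_candidates = nrow(x$grid), folds_seed = x$folds_seed,
    best_cost = x$best$cost, best_gamma = x$best$gamma,
    best_cv_error = x$best$cv_error
  )
}

#' Heatmap of the cross-validated tuning surface
#'
#' @param object A `wsvm_tuning` result.
#' @param ... Unused.
#' @return A ggplot: CV misclassification rate over the (cost, gamma) grid,
#'   the selected candidate outlined.
#' @export
autoplot.wsvm_tuning <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = factor(.data$gamma), y = factor(.data$cost),
                               fill = .data$cv_error)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = object$best, fill = NA, colour = "red",
                       linewidth = 1) +
    ggplot2::scale_fill_viridis_c(name = "CV error") +
    ggplot2::labs(x = expression(gamma), y = "cost C",
                  title = "10-fold CV tuning surface") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
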