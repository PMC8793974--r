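#' Point-biserial correlation between a numeric feature and a binary label
#'
#' Computed in the group-mean form
#' \deqn{r = \frac{\bar X_{+1} - \bar X_{-1}}{S_X}
#'       \sqrt{p_{+1} p_{-1} \frac{n}{n-1}},}
#' where \eqn{\bar X_{+1}, \bar X_{-1}} are the class means,
#' \eqn{p_{+1}, p_{-1}} the class proportions and \eqn{S_X} the sample
#' (n-1 denominator) standard deviation. This is algebraically identical to
#' the Pearson correlation of `x` against `y` recoded 0/1.
#'
#' @param x Numeric vector (length >= 3, non-constant).
#' @param y Labels in \{-1, +1\}; both classes must be present.
#' @return The correlation, a single number in \[-1, 1\].
#' @export
#' @examples
#' point_biserial(c(1, 2, 3, 4), c(-1, -1, 1, 1))
point_biserial <- function(x, y) {
  if (!is.numeric(x)) abort("`x` must be numeric.")
  y <- as_pm1(y)
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length.")
  if (n < 3) abort("At least 3 observations are required.")
  if (anyNA(x)) abort("`x` must not contain missing values.")
  n_plus <- sum(y == 1)
  if (n_plus == 0 || n_plus == n) {
    abort("Both classes must be present in `y`.")
  }
  s_x <- sd(x)
  if (s_x == 0) abort("`x` is constant: the point-biserial correlation is undefined.")
  p_plus <- n_plus / n
  p_minus <- 1 - p_plus
  r <- (mean(x[y == 1]) - mean(x[y == -1])) / s_x *
    sqrt(p_plus * p_minus * n / (n - 1))
  unname(r)
}

#' Point-biserial correlations of every predictor in a dataset
#'
#' @param data Data frame of numeric predictors plus the label column.
#' @param response Label column (unquoted), coded -1/+1. Default `y`.
#' @return A tibble with columns `variable` and `r`, one row per predictor,
#'   in column order.
#' @seealso [point_biserial()], [pb_weights()]
#' @export
pb_correlations <- function(data, response = y) {
  parts <- split_response(data, enquo(response))
  tibble::tibble(
    variable = names(parts$x),
    r = vapply(parts$x, point_biserial, numeric(1), y = parts$y)
  )
}

#' Normalise point-biserial correlations into unit-trace feature weights
#'
#' Each weight is the absolute correlation divided by the sum of absolute
#' correlations, \eqn{\omega_j = |r_j| / \sum_k |r_k|}, so the weights are
#' non-negative and sum to one (the diagonal weight matrix has unit trace).
#' Ranks are assigned by descending weight (1 = most associated feature).
#'
#' @param r Either a numeric vector of correlations (optionally named) or a
#'   data frame with columns `variable` and `r`, as returned by
#'   [pb_correlations()].
#' @return A `wsvm_weights` tibble with columns `variable`, `r`, `weight`
#'   and `rank`.
#' @export
#' @examples
#' pb_weights(cleveland_correlations())
pb_weights <- function(r) {
  if (is.data.frame(r)) {
    if (!all(c("variable", "r") %in% names(r))) {
      abort("A data-frame `r` must have columns `variable` and `r`.")
    }
    variable <- as.character(r$variable)
    rv <- as.numeric(r$r)
  } else if (is.numeric(r)) {
    rv <- as.numeric(r)
    variable <- if (is.null(names(r))) paste0("x", seq_along(r)) else names(r)
  } else {
    abort("`r` must be a numeric vector or a data frame with `variable`, `r`.")
  }
  if (length(rv) < 1) abort("At least one correlation is required.")
  if (anyNA(rv)) abort("Correlations must not be missing.")
  total <- sum(abs(rv))
  if (total < 1e-10) {
    abort("All correlations are (numerically) zero: weights are undefined.")
  }
  w <- abs(rv) / total
  out <- tibble::tibble(
    variable = variable,
    r = rv,
    weight = w,
    rank = rank(-w, ties.method = "first")
  )
  class(out) <- c("wsvm_weights", class(out))
  out
}

#' Scale predictor columns by their feature weights
#'
#' Forms the weighted data matrix `Z = X diag(w)`: column `j` of the
#' predictors is multiplied by weight `w_j`. Weights are matched to columns
#' by variable name when names are available, otherwise by position.
#'
#' @param data Data frame of numeric predictors (a label column named as
#'   `response` is carried through untouched), or a numeric matrix.
#' @param weights A `wsvm_weights` tibble from [pb_weights()] or a numeric
#'   vector of per-column weights.
#' @param response Label column to pass through unscaled (unquoted);
#'   default `y`. Ignored when absent or when `data` is a matrix.
#' @return A tibble of the same shape (or a matrix for matrix input).
#' @export
apply_weights <- function(data, weights, response = y) {
  w <- weight_vector(weights)
  if (is.matrix(data)) {
    if (length(w) != ncol(data)) {
      abort(sprintf("Got %d weights for %d columns.", length(w), ncol(data)))
    }
    if (!is.null(names(w)) && !is.null(colnames(data))) {
      if (!setequal(names(w), colnames(data))) {
        abort("Weight names do not match the matrix column names.")
      }
      w <- w[colnames(data)]
    }
    return(sweep(data, 2, w, `*`))
  }
  if (!is.data.frame(data)) abort("`data` must be a data frame or matrix.")
  rq <- enquo(response)
  resp <- if (rlang::quo_is_null(rq)) character(0) else as_name(rq)
  feat <- setdiff(names(data), resp)
  if (length(w) != length(feat)) {
    abort(sprintf("Got %d weights for %d predictor columns.",
                  length(w), length(feat)))
  }
  if (!is.null(names(w))) {
    if (!setequal(names(w), feat)) {
      abort("Weight names do not match the predictor column names.")
    }
    w <- w[feat]
  }
  out <- tibble::as_tibble(data)
  for (j in seq_along(feat)) {
    out[[feat[j]]] <- out[[feat[j]]] * w[[j]]
  }
  out
}

# Extract a named numeric weight vector from the accepted representations.
weight_vector <- function(weights) {
  if (inherits(weights, "wsvm_weights") ||
      (is.data.frame(weights) && all(c("variable", "weight") %in% names(weights)))) {
    w <- weights$weight
    names(w) <- weights$variable
  } else if (is.numeric(weights)) {
    w <- weights
  } else {
    abort("`weights` must be a `wsvm_weights` table or a numeric vector.")
  }
  if (any(w < 0) || anyNA(w)) abort("Weights must be non-negative and non-missing.")
  w
}

#' @export
print.wsvm_weights <- function(x, ...) {
  cat("# Point-biserial feature weights (sum = 1)\n")
  NextMethod()
}
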