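#' Radial basis function kernel
#'
#' `exp(-gamma * ||u - v||^2)`, the similarity in (0, 1] between two feature
#' vectors under RBF width `gamma`.
#'
#' @param u,v Numeric vectors of equal length.
#' @param gamma Positive kernel width.
#' @return A single number in (0, 1].
#' @export
#' @examples
#' rbf_kernel(c(0, 0), c(1, 1), gamma = 0.5)  # exp(-1)
rbf_kernel <- function(u, v, gamma) {
  check_scalar_number(gamma, "gamma", lower = 0, strict = TRUE)
  if (!is.numeric(u) || !is.numeric(v) || length(u) != length(v)) {
    abort("`u` and `v` must be numeric vectors of equal length.")
  }
  exp(-gamma * sum((u - v)^2))
}

# Dense RBF Gram matrix between the rows of A and B.
rbf_gram <- function(A, B, gamma) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

# Training-set standardization statistics for the continuous predictors.
# When `meta` is available only `kind == "continuous"` columns are z-scored
# (integer factor codes stay as printed); otherwise every non-constant
# column is treated as continuous.
standardization_stats <- function(x, meta = NULL) {
  vars <- names(x)
  cont <- if (!is.null(meta) && all(vars %in% meta$name)) {
    vars[meta$kind[match(vars, meta$name)] == "continuous"]
  } else {
    vars
  }
  center <- stats::setNames(rep(0, length(vars)), vars)
  scale <- stats::setNames(rep(1, length(vars)), vars)
  for (v in cont) {
    s <- sd(x[[v]])
    if (is.na(s) || s == 0) next
    center[[v]] <- mean(x[[v]])
    scale[[v]] <- s
  }
  tibble::tibble(variable = vars, center = unname(center), scale = unname(scale))
}

apply_standardization <- function(x, stats) {
  if (is.null(stats)) return(x)
  for (j in seq_len(nrow(stats))) {
    v <- stats$variable[j]
    x[[v]] <- (x[[v]] - stats$center[j]) / stats$scale[j]
  }
  x
}

#' Fit a weighted RBF-kernel support vector machine
#'
#' Trains the w-SVM: point-biserial feature weights (unit trace) scale the
#' predictor columns, and an RBF-kernel soft-margin SVM is fitted on the
#' weighted data by solving the dual quadratic program
#' \deqn{\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{i,j} \alpha_i \alpha_j
#'   y_i y_j K(z_i, z_j), \quad 0 \le \alpha_i \le C, \ \sum_i \alpha_i y_i = 0,}
#' via sequential minimal optimization with maximal-violating-pair selection.
#'
#' @param data Data frame of numeric predictors plus the label column.
#' @param response Label column (unquoted), coded -1/+1. Default `y`.
#' @param weights Feature weighting: `"auto"` (default) computes
#'   point-biserial weights from this training data; `"uniform"` uses
#'   `1/p` for every feature; `"none"` skips weighting; or pass a
#'   `wsvm_weights` table / numeric vector directly.
#' @param cost Soft-margin box constraint `C > 0`.
#' @param gamma RBF width; defaults to `1/p`.
#' @param standardize Z-score continuous predictors with training-set
#'   statistics before weighting (integer factor codes are left as is).
#' @param tol Stopping tolerance on the dual projected-gradient gap.
#' @param kkt_tol Largest acceptable KKT gap at the returned solution.
#' @param max_iter Iteration cap for the SMO sweep.
#' @return An object of class `wsvm`: support vectors (in weighted,
#'   standardized coordinates), dual coefficients `alpha_i y_i`, bias,
#'   kernel and cost parameters, the weight table and standardization
#'   statistics used, and solver diagnostics.
#' @seealso [predict.wsvm()], [wsvm_tune()], [pb_weights()]
#' @export
#' @examples
#' d <- generate_synthetic(synthetic_spec(n = 80, seed = 3))
#' fit <- wsvm_fit(d, cost = 1)
#' fit
wsvm_fit <- function(data, response = y, weights = "auto", cost = 1,
                     gamma = NULL, standardize = TRUE,
                     tol = 1e-8, kkt_tol = 1e-4, max_iter = 500000L) {
  parts <- split_response(data, enquo(response))
  x <- parts$x
  yv <- parts$y
  n <- nrow(x); p <- ncol(x)
  if (n < 2) abort("At least two observations are required.")
  if (length(unique(yv)) < 2) abort("Both classes must be present for fitting.")
  check_scalar_number(cost, "cost", lower = 0, strict = TRUE)
  if (is.null(gamma)) gamma <- 1 / p
  check_scalar_number(gamma, "gamma", lower = 0, strict = TRUE)

  stats <- if (isTRUE(standardize)) {
    standardization_stats(x, attr(data, "meta"))
  } else {
    NULL
  }
  xs <- apply_standardization(x, stats)

  wt <- NULL
  if (is.character(weights) && length(weights) == 1) {
    wt <- switch(weights,
      auto = pb_weights(tibble::tibble(
        variable = names(xs),
        # a predictor constant within this training sample carries no
        # association information: give it zero weight rather than fail
        r = vapply(xs, function(v) {
          tryCatch(point_biserial(v, yv), error = function(e) 0)
        }, numeric(1))
      )),
      uniform = pb_weights(stats::setNames(rep(1, p), names(xs))),
      none = NULL,
      abort('`weights` must be "auto", "uniform", "none", a weight table or a numeric vector.')
    )
  } else if (!is.null(weights)) {
    wv <- weight_vector(weights)
    if (is.null(names(wv))) names(wv) <- names(xs)
    wt <- pb_weights(stats::setNames(wv, names(wv)))
    wt$weight <- unname(wv[wt$variable]) # keep caller's scale, no renormalisation
    wt$r <- NA_real_
  }
  z <- if (is.null(wt)) xs else apply_weights(xs, wt, response = NULL)
  zmat <- as.matrix(z)

  K <- rbf_gram(zmat, zmat, gamma)
  sol <- smo_solve(K, yv, cost, tol, as.integer(max_iter))
  if (!sol$converged) {
    abort(sprintf(
      "SMO did not converge in %d iterations (KKT gap %.3g, tol %.3g); increase `max_iter` or `tol`.",
      max_iter, sol$kkt_gap, tol
    ))
  }
  if (sol$kkt_gap > kkt_tol) {
    abort(sprintf("Solver stalled with KKT gap %.3g > kkt_tol %.3g.",
                  sol$kkt_gap, kkt_tol))
  }
  alpha <- sol$alpha
  sv_idx <- which(alpha > 1e-8 * cost)
  structure(
    list(
      support_vectors = zmat[sv_idx, , drop = FALSE],
      sv_index = sv_idx,
      dual_coefs = alpha[sv_idx] * yv[sv_idx],
      alpha = alpha,
      bias = sol$bias,
      gamma = gamma,
      cost = cost,
      weights = wt,
      standardization = stats,
      features = names(x),
      objective = sol$objective,
      kkt_gap = sol$kkt_gap,
      eq_residual = sol$eq_residual,
      iterations = sol$iterations,
      n = n
    ),
    class = "wsvm"
  )
}

# Map new observations into the model's weighted, standardized coordinates.
transform_newdata <- function(object, newdata) {
  if (is.matrix(newdata)) {
    if (ncol(newdata) != length(object$features)) {
      abort(sprintf("`newdata` has %d columns; the model uses %d features.",
                    ncol(newdata), length(object$features)))
    }
    newdata <- tibble::as_tibble(as.data.frame(newdata))
    names(newdata) <- object$features
  }
  if (!is.data.frame(newdata)) abort("`newdata` must be a data frame or matrix.")
  miss <- setdiff(object$features, names(newdata))
  if (length(miss) > 0) {
    abort(sprintf("`newdata` lacks feature columns: %s.",
                  paste(miss, collapse = ", ")))
  }
  x <- tibble::as_tibble(newdata[object$features])
  x <- apply_standardization(x, object$standardization)
  if (!is.null(object$weights)) x <- apply_weights(x, object$weights, response = NULL)
  as.matrix(x)
}

#' Predict from a fitted w-SVM
#'
#' The decision value of a query `z` is
#' `f(z) = sum_i alpha_i y_i K(z_i, z) + b` over the support vectors; the
#' class is `sign(f(z))` with the deterministic tie rule `sign(0) -> +1`.
#'
#' @param object A fitted [wsvm_fit()] model.
#' @param newdata Data frame (or matrix) of query observations; a label
#'   column, if present, is ignored.
#' @param type `"class"` for -1/+1 labels (default), `"decision"` for raw
#'   decision values.
#' @param ... Unused.
#' @return A numeric vector, one element per row of `newdata`.
#' @export
predict.wsvm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  zmat <- transform_newdata(object, newdata)
  K <- rbf_gram(object$support_vectors, zmat, object$gamma)
  dec <- drop(crossprod(K, object$dual_coefs)) + object$bias
  if (type == "decision") return(dec)
  ifelse(dec >= 0, 1, -1)
}

#' @export
print.wsvm <- function(x, ...) {
  cat("Weighted RBF-kernel SVM\n")
  cat(sprintf("  n = %d, features = %d, support vectors = %d\n",
              x$n, length(x$features), nrow(x$support_vectors)))
  cat(sprintf("  cost C = %g, gamma = %g, bias = %.4f\n", x$cost, x$gamma, x$bias))
  cat(sprintf("  dual objective = %.6f, KKT gap = %.2e\n", x$objective, x$kkt_gap))
  if (is.null(x$weights)) {
    cat("  feature weighting: none\n")
  } else {
    top <- x$weights[order(x$weights$rank), ]
    cat(sprintf("  top-weighted features: %s\n",
                paste(head(top$variable, 3), collapse = ", ")))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted w-SVM into a per-feature table
#'
#' @param x A `wsvm` model.
#' @param ... Unused.
#' @return A tibble with one row per feature: its point-biserial correlation
#'   (when the model computed weights itself), weight, weight rank, and the
#'   standardization statistics applied.
#' @export
tidy.wsvm <- function(x, ...) {
  out <- tibble::tibble(variable = x$features)
  if (!is.null(x$weights)) {
    out <- dplyr::left_join(out, x$weights, by = "variable")
  } else {
    out$r <- NA_real_; out$weight <- NA_real_; out$rank <- NA_integer_
  }
  if (!is.null(x$standardization)) {
    out <- dplyr::left_join(out, x$standardization, by = "variable")
  } else {
    out$center <- 0; out$scale <- 1
  }
  out
}

#' One-row summary of a fitted w-SVM
#'
#' @param x A `wsvm` model.
#' @param ... Unused.
#' @return A one-row tibble: training size, support-vector count, cost,
#'   gamma, bias, dual objective and solver diagnostics.
#' @export
glance.wsvm <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_sv = nrow(x$support_vectors), cost = x$cost, gamma = x$gamma,
    bias = x$bias, objective = x$objective, kkt_gap = x$kkt_gap,
    iterations = x$iterations
  )
}

#' Serialize a fitted w-SVM to JSON
#'
#' Writes everything needed for a reload-and-predict round trip: support
#' vectors, dual coefficients, bias, kernel and cost parameters, feature
#' weights and standardization statistics.
#'
#' @param model A `wsvm` model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
wsvm_to_json <- function(model, path) {
  if (!inherits(model, "wsvm")) abort("`model` must be a `wsvm` object.")
  payload <- list(
    container = "wsvm-model", version = 1L,
    features = model$features,
    support_vectors = unclass(as.data.frame(model$support_vectors)),
    dual_coefs = model$dual_coefs,
    bias = model$bias, gamma = model$gamma, cost = model$cost,
    n = model$n, objective = model$objective,
    weights = if (is.null(model$weights)) NULL else unclass(as.data.frame(model$weights)),
    standardization = if (is.null(model$standardization)) NULL else
      unclass(as.data.frame(model$standardization))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname wsvm_to_json
#' @export
wsvm_from_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$container) || payload$container != "wsvm-model") {
    abort("Not a serialized wsvm model.")
  }
  sv <- as.matrix(as.data.frame(payload$support_vectors))
  colnames(sv) <- payload$features
  structure(
    list(
      support_vectors = sv,
      sv_index = NA_integer_,
      dual_coefs = payload$dual_coefs,
      alpha = NULL,
      bias = payload$bias, gamma = payload$gamma, cost = payload$cost,
      weights = if (length(payload$weights) == 0) NULL else {
        w <- tibble::as_tibble(payload$weights)
        class(w) <- c("wsvm_weights", class(w)); w
      },
      standardization = if (length(payload$standardization) == 0) NULL else
        tibble::as_tibble(payload$standardization),
      features = payload$features,
      objective = payload$objective, kkt_gap = NA_real_,
      eq_residual = NA_real_, iterations = NA_integer_, n = payload$n
    ),
    class = "wsvm"
  )
}
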