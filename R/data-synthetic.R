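#' Map a standardized mean difference to a population point-biserial correlation
#'
#' For a continuous feature generated as `x = delta * y / 2 + Normal(0, 1)`
#' with labels `y = +/-1` and `P(y = +1) = class_prob`, the population
#' point-biserial correlation is
#' `r = delta * sqrt(q (1 - q)) / sqrt(1 + delta^2 q (1 - q))` with
#' `q = class_prob`. For balanced classes this reduces to
#' `r = delta / (2 sqrt(1 + delta^2 / 4))`. [r_to_delta()] is the inverse.
#'
#' @param delta Standardized mean difference(s) between the class means.
#' @param r Target point-biserial correlation(s), `|r| < 1`.
#' @param class_prob Probability of the +1 class.
#' @return Numeric vector of correlations (resp. mean differences).
#' @export
delta_to_r <- function(delta, class_prob = 0.5) {
  v <- class_prob * (1 - class_prob)
  delta * sqrt(v) / sqrt(1 + delta^2 * v)
}

#' @rdname delta_to_r
#' @export
r_to_delta <- function(r, class_prob = 0.5) {
  if (any(abs(r) >= 1)) abort("`r` must satisfy |r| < 1.")
  v <- class_prob * (1 - class_prob)
  r / sqrt(v * (1 - r^2))
}

# Class-conditional category probabilities emulating the Cleveland factors:
# marginals follow the published frequency table, and the between-class tilt
# is sized so the factor/outcome associations keep the published ordering
# (THAL and CA strongest, FBS essentially null).
cleveland_like_factors <- function() {
  list(
    Sex   = list(codes = c(0, 1),
                 p_minus = c(0.45, 0.55), p_plus = c(0.17, 0.83)),
    CP    = list(codes = c(1, 2, 3, 4),
                 p_minus = c(0.12, 0.25, 0.38, 0.25),
                 p_plus  = c(0.03, 0.07, 0.16, 0.74)),
    FBS   = list(codes = c(0, 1),
                 p_minus = c(0.145, 0.855), p_plus = c(0.145, 0.855)),
    RECGR = list(codes = c(0, 1, 2),
                 p_minus = c(0.560, 0.015, 0.425),
                 p_plus  = c(0.420, 0.011, 0.569)),
    EXANG = list(codes = c(0, 1),
                 p_minus = c(0.86, 0.14), p_plus = c(0.45, 0.55)),
    SLOPE = list(codes = c(1, 2, 3),
                 p_minus = c(0.60, 0.34, 0.06),
                 p_plus  = c(0.31, 0.60, 0.09)),
    CA    = list(codes = c(0, 1, 2, 3),
                 p_minus = c(0.79, 0.14, 0.05, 0.02),
                 p_plus  = c(0.35, 0.31, 0.22, 0.12)),
    THAL  = list(codes = c(3, 6, 7),
                 p_minus = c(0.79, 0.05, 0.16),
                 p_plus  = c(0.27, 0.08, 0.65))
  )
}

#' Specify a synthetic binary-outcome dataset
#'
#' Describes a mixed continuous/categorical dataset with a dichotomous
#' response, mirroring the structure the w-SVM method assumes. The defaults
#' emulate the Cleveland heart-disease data: 297 records with a 46.1% +1
#' class, five continuous covariates whose standardized class-mean
#' differences are back-computed (via [r_to_delta()]) from the published
#' point-biserial correlations, and eight integer-coded factors with
#' class-conditional category probabilities that keep the published
#' marginals and association ordering.
#'
#' @param n Sample size (>= 4).
#' @param class_prob Probability of the +1 class, strictly inside (0, 1).
#' @param continuous_effects Named numeric vector: per continuous feature,
#'   the standardized mean difference `delta` between the +1 and -1 class
#'   means (features are Normal with unit variance within class).
#' @param categorical_effects Named list: per factor, a list with `codes`
#'   (>= 2 integer codes) and probability vectors `p_plus`, `p_minus`
#'   (one per class, each summing to 1).
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return An object of class `synthetic_spec`.
#' @export
#' @examples
#' spec <- synthetic_spec(n = 100, seed = 7)
#' d <- generate_synthetic(spec)
#' class_proportions(d)
synthetic_spec <- function(n = 297,
                           class_prob = 137 / 297,
                           continuous_effects = NULL,
                           categorical_effects = NULL,
                           seed = 1L) {
  check_scalar_number(n, "n", lower = 4)
  check_scalar_number(seed, "seed")
  if (!is.numeric(class_prob) || length(class_prob) != 1 ||
      class_prob <= 0 || class_prob >= 1) {
    abort("`class_prob` must lie strictly inside (0, 1).")
  }
  if (is.null(continuous_effects)) {
    r_cont <- c(Age = 0.2271, RBP = 0.1535, Chol = 0.0803,
                MHRA = 0.4238, OLDPK = 0.4241)
    continuous_effects <- r_to_delta(r_cont, class_prob)
  }
  if (is.null(categorical_effects)) categorical_effects <- cleveland_like_factors()
  if (length(continuous_effects) > 0 && is.null(names(continuous_effects))) {
    names(continuous_effects) <- paste0("x", seq_along(continuous_effects))
  }
  for (nm in names(categorical_effects)) {
    f <- categorical_effects[[nm]]
    if (!all(c("codes", "p_plus", "p_minus") %in% names(f))) {
      abort(sprintf("Factor `%s` needs `codes`, `p_plus` and `p_minus`.", nm))
    }
    if (length(f$codes) < 2) abort(sprintf("Factor `%s` needs >= 2 codes.", nm))
    for (side in c("p_plus", "p_minus")) {
      p <- f[[side]]
      if (length(p) != length(f$codes) || any(p < 0) ||
          abs(sum(p) - 1) > 1e-8) {
        abort(sprintf(
          "`%s` of factor `%s` must be a probability vector over its codes.",
          side, nm
        ))
      }
    }
  }
  if (length(continuous_effects) + length(categorical_effects) < 1) {
    abort("At least one feature is required.")
  }
  structure(
    list(n = as.integer(n), class_prob = class_prob,
         continuous_effects = continuous_effects,
         categorical_effects = categorical_effects,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic dataset from a specification
#'
#' Labels are drawn Bernoulli(`class_prob`) and mapped to -1/+1; continuous
#' feature `j` is drawn Normal(`delta_j * y / 2`, 1); each categorical
#' feature is drawn from its class-conditional category probabilities.
#' Generation is deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with one numeric column per feature plus the label
#'   column `y`; feature metadata travels as attribute `"meta"`.
#' @export
generate_synthetic <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    abort("`spec` must be a `synthetic_spec` object.")
  }
  with_seed(spec$seed, {
    n <- spec$n
    y <- ifelse(rbinom(n, 1, spec$class_prob) == 1, 1, -1)
    cols <- list()
    for (nm in names(spec$continuous_effects)) {
      d <- spec$continuous_effects[[nm]]
      cols[[nm]] <- rnorm(n, mean = d * y / 2, sd = 1)
    }
    for (nm in names(spec$categorical_effects)) {
      f <- spec$categorical_effects[[nm]]
      v <- numeric(n)
      plus <- y == 1
      v[plus] <- sample(f$codes, sum(plus), replace = TRUE, prob = f$p_plus)
      v[!plus] <- sample(f$codes, sum(!plus), replace = TRUE, prob = f$p_minus)
      cols[[nm]] <- v
    }
    out <- tibble::as_tibble(cols)
    out$y <- y
    meta <- tibble::tibble(
      name = c(names(spec$continuous_effects), names(spec$categorical_effects)),
      kind = c(rep("continuous", length(spec$continuous_effects)),
               rep("categorical", length(spec$categorical_effects))),
      codes = c(rep(list(NULL), length(spec$continuous_effects)),
                lapply(spec$categorical_effects, `[[`, "codes")),
      description = NA_character_
    )
    attr(out, "meta") <- meta
    attr(out, "spec") <- spec
    out
  })
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> n = %d, P(y = +1) = %.3f, %d continuous + %d categorical features, seed = %d\n",
    x$n, x$class_prob, length(x$continuous_effects),
    length(x$categorical_effects), x$seed
  ))
  invisible(x)
}
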