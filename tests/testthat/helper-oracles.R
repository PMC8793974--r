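# Independent oracles and small fixture builders shared across test files.

# Pearson correlation of x against the labels recoded 0/1 — the reference
# form the group-mean point-biserial must reproduce.
pearson01 <- function(x, y) stats::cor(x, (y + 1) / 2)

# Dual objective W(alpha) = sum(alpha) - 1/2 (alpha y)' K (alpha y),
# evaluated by explicit matrix algebra.
dual_objective <- function(alpha, K, y) {
  ay <- alpha * y
  sum(alpha) - 0.5 * drop(crossprod(ay, K %*% ay))
}

# Generic constrained-QP solve of the SVM dual via kernlab's interior-point
# solver: min 1/2 a'Ha + c'a  s.t.  A a = b, l <= a <= u.
ipop_svm_dual <- function(K, y, C) {
  n <- length(y)
  # tiny ridge keeps the interior-point iterations well conditioned; it
  # perturbs the optimum far below the comparison tolerance
  H <- (y %o% y) * K + diag(1e-8, n)
  sol <- kernlab::ipop(
    c = rep(-1, n), H = H,
    A = matrix(y, nrow = 1), b = 0, r = 0,
    l = rep(0, n), u = rep(C, n),
    sigf = 7, maxiter = 100
  )
  kernlab::primal(sol)
}

# Explicit double-loop RBF kernel expansion for decision values.
kernel_sum_oracle <- function(sv, coefs, bias, gamma, queries) {
  vapply(seq_len(nrow(queries)), function(q) {
    s <- 0
    for (i in seq_len(nrow(sv))) {
      s <- s + coefs[i] * exp(-gamma * sum((sv[i, ] - queries[q, ])^2))
    }
    s + bias
  }, numeric(1))
}

# Small random binary dataset with p continuous features.
random_dataset <- function(n, p, seed, delta = rep(0, p), class_prob = 0.5) {
  generate_synthetic(synthetic_spec(
    n = n, class_prob = class_prob,
    continuous_effects = stats::setNames(delta, paste0("x", seq_len(p))),
    categorical_effects = list(),
    seed = seed
  ))
}

# A dataset with the published Cleveland class counts (137 diseased of 297).
cleveland_sized_labels <- function() {
  tibble::tibble(x = seq_len(297), y = rep(c(1, -1), c(137, 160)))
}

# Write a small file in the UCI processed-Cleveland dialect (13 predictors
# plus the 0-4 response, "?" for missing). `rows` is a character vector of
# ready-made lines.
write_uci_file <- function(rows) {
  path <- tempfile(fileext = ".data")
  writeLines(rows, path)
  path
}

# Synthetic stand-in rows in the Cleveland dialect: valid codes, plausible
# continuous ranges, deterministic content.
synthetic_cleveland_rows <- function(n = 40, seed = 1, n_missing = 0) {
  meta <- cleveland_meta()
  withr::with_seed(seed, {
    cols <- lapply(seq_len(nrow(meta)), function(j) {
      if (meta$kind[j] == "continuous") {
        round(stats::runif(n, 1, 100), 1)
      } else {
        sample(meta$codes[[j]], n, replace = TRUE)
      }
    })
    cols <- c(cols, list(sample(0:4, n, replace = TRUE)))
    m <- do.call(cbind, lapply(cols, as.character))
    if (n_missing > 0) {
      for (i in seq_len(n_missing)) m[i, 1 + (i %% ncol(m))] <- "?"
    }
    apply(m, 1, paste, collapse = ",")
  })
}
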