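#' Variable metadata for the Cleveland heart-disease predictors
#'
#' Declarative description of the 13 predictors in the UCI Cleveland
#' heart-disease data: variable name, whether it is continuous or an
#' integer-coded categorical factor, and the permitted integer codes for
#' the categorical ones. The angiographic response (`num` in the raw file,
#' dichotomised to -1/+1 by [binarize_response()]) is not part of this table.
#'
#' `CA` (number of major vessels coloured by fluoroscopy) takes ordered
#' integer values 0-3 and enters the design matrix as those values; `THAL`
#' keeps its historical codes 3 (normal), 6 (fixed defect), 7 (reversible
#' defect).
#'
#' @return A tibble with columns `name`, `kind` (`"continuous"` or
#'   `"categorical"`), `codes` (list column of permitted integer codes,
#'   `NULL` for continuous variables) and `description`.
#' @seealso [read_uci_csv()], [clean_encode()]
#' @export
#' @examples
#' cleveland_meta()
cleveland_meta <- function() {
  tibble::tibble(
    name = c("Age", "Sex", "CP", "RBP", "Chol", "FBS", "RECGR", "MHRA",
             "EXANG", "OLDPK", "SLOPE", "CA", "THAL"),
    kind = c("continuous", "categorical", "categorical", "continuous",
             "continuous", "categorical", "categorical", "continuous",
             "categorical", "continuous", "categorical", "categorical",
             "categorical"),
    codes = list(NULL, c(0, 1), c(1, 2, 3, 4), NULL, NULL, c(0, 1),
                 c(0, 1, 2), NULL, c(0, 1), NULL, c(1, 2, 3), c(0, 1, 2, 3),
                 c(3, 6, 7)),
    description = c(
      "Patient age in years",
      "Patient sex (1 = male, 0 = female)",
      "Chest pain type (1 typical angina .. 4 asymptomatic)",
      "Resting blood pressure (mm Hg)",
      "Serum cholesterol (mg/dL)",
      "Fasting blood sugar > 120 mg/dL (1 yes, 0 no)",
      "Resting electrocardiographic result (0 normal, 1 abnormality, 2 LVH)",
      "Maximum heart rate achieved",
      "Exercise-induced angina (1 yes, 0 no)",
      "ST depression induced by exercise relative to rest",
      "Slope of the peak exercise ST segment (1 up, 2 flat, 3 down)",
      "Number of major vessels coloured by fluoroscopy (0-3)",
      "Thallium scan defect type (3 normal, 6 fixed, 7 reversible)"
    )
  )
}

#' Published point-biserial correlations for the Cleveland predictors
#'
#' The point-biserial correlation between each of the 13 Cleveland predictors
#' and the dichotomised angiographic outcome, as computed on the 297 complete
#' cases of the public dataset. These are the canonical worked-example inputs
#' for [pb_weights()]: normalising their absolute values gives the w-SVM
#' feature weights (THAL largest at 0.1347, FBS smallest at 0.0008).
#'
#' @return A tibble with columns `variable` and `r`.
#' @seealso [pb_weights()], [pb_correlations()]
#' @export
#' @examples
#' pb_weights(cleveland_correlations())
cleveland_correlations <- function() {
  tibble::tibble(
    variable = c("Age", "Sex", "CP", "RBP", "Chol", "FBS", "RECGR", "MHRA",
                 "EXANG", "OLDPK", "SLOPE", "CA", "THAL"),
    r = c(0.2271, 0.2785, 0.4089, 0.1535, 0.0803, 0.0032, 0.1663, 0.4238,
          0.4214, 0.4241, 0.3331, 0.4632, 0.5266)
  )
}

#' Read a UCI-dialect heart-disease CSV
#'
#' Parses the comma-separated, headerless dialect used by the UCI repository's
#' `processed.cleveland.data` (13 predictors plus the integer angiographic
#' grade `num`; `"?"` marks a missing cell). Missing cells become `NA`; no row
#' is dropped at this stage, so incomplete records remain visible to the
#' caller (and to [clean_encode()], which removes them).
#'
#' @param path Path to the CSV file.
#' @param missing String marking a missing cell. Default `"?"`.
#' @param meta Predictor metadata tibble as from [cleveland_meta()]; only the
#'   variable names (and their count) are used here.
#' @param header Set `TRUE` for the headered variant of the file, in which
#'   case the first line is checked against the expected column names and
#'   skipped.
#' @return A tibble with one numeric column per predictor plus `num`;
#'   missing cells are `NA`.
#' @export
read_uci_csv <- function(path, missing = "?", meta = cleveland_meta(),
                         header = FALSE) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort(sprintf("File not found: %s", as.character(path)[1]))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  col_names <- c(meta$name, "num")
  if (header) {
    if (length(lines) < 1) abort("Empty file (header expected).")
    got <- trimws(strsplit(lines[1], ",", fixed = TRUE)[[1]])
    if (length(got) != length(col_names)) {
      abort(sprintf("Header has %d fields; expected %d.",
                    length(got), length(col_names)))
    }
    lines <- lines[-1]
  }
  if (length(lines) == 0) abort("Empty file: no data rows.")
  fields <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(col_names))
  if (length(bad) > 0) {
    abort(sprintf(
      "Line %d has %d comma-separated fields; expected %d.",
      bad[1] + as.integer(header), nf[bad[1]], length(col_names)
    ))
  }
  mat <- matrix(trimws(unlist(fields)), ncol = length(col_names), byrow = TRUE)
  mat[mat == missing] <- NA_character_
  out <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE))
  names(out) <- col_names
  for (j in seq_along(out)) {
    v <- suppressWarnings(as.numeric(out[[j]]))
    newly_na <- is.na(v) & !is.na(out[[j]])
    if (any(newly_na)) {
      abort(sprintf(
        "Non-numeric value '%s' in column %s, line %d.",
        out[[j]][which(newly_na)[1]], col_names[j],
        which(newly_na)[1] + as.integer(header)
      ))
    }
    out[[j]] <- v
  }
  out
}

#' Dichotomise the angiographic disease grade
#'
#' The raw UCI response `num` grades angiographic narrowing 0-4. The
#' classification task uses presence/absence only: grade 0 maps to -1
#' (no disease), any grade of at least 1 maps to +1 (disease present).
#'
#' @param num Vector of non-negative integer grades; `NA` passes through
#'   (rows with missing responses are removed by [clean_encode()]).
#' @return Numeric vector of labels in \{-1, +1\} (with `NA` preserved).
#' @export
#' @examples
#' binarize_response(c(0, 1, 3, 0))
binarize_response <- function(num) {
  if (!is.numeric(num)) abort("`num` must be numeric.")
  ok <- is.na(num) | (num >= 0 & num == floor(num))
  if (!all(ok)) {
    abort(sprintf("Invalid response grade '%s': must be a non-negative integer.",
                  format(num[!ok][1])))
  }
  ifelse(is.na(num), NA_real_, ifelse(num >= 1, 1, -1))
}

#' Clean and encode a raw heart-disease table
#'
#' Drops every record with any missing field (the analysis uses complete
#' cases only; on the public Cleveland file this removes 6 of 303 records,
#' leaving 297), validates categorical codes against the metadata, and
#' dichotomises the response with [binarize_response()]. Surviving rows are
#' carried over unchanged: categorical predictors keep their integer codes
#' as numeric values, with no one-hot expansion.
#'
#' @param raw Tibble from [read_uci_csv()] (predictor columns plus `num`).
#' @param meta Predictor metadata as from [cleveland_meta()].
#' @return A tibble with the numeric predictor columns and a `y` column in
#'   \{-1, +1\}; the metadata travels along as attribute `"meta"`.
#' @export
clean_encode <- function(raw, meta = cleveland_meta()) {
  if (!is.data.frame(raw)) abort("`raw` must be a data frame.")
  need <- c(meta$name, "num")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(sprintf("Raw table lacks columns: %s.", paste(miss, collapse = ", ")))
  }
  raw <- raw[need]
  keep <- complete.cases(raw)
  out <- raw[keep, , drop = FALSE]
  for (j in seq_len(nrow(meta))) {
    if (meta$kind[j] != "categorical") next
    v <- out[[meta$name[j]]]
    bad <- which(!v %in% meta$codes[[j]])
    if (length(bad) > 0) {
      abort(sprintf(
        "Value %s of %s (row %d after cleaning) is not a permitted code {%s}.",
        format(v[bad[1]]), meta$name[j], bad[1],
        paste(meta$codes[[j]], collapse = ", ")
      ))
    }
  }
  out$y <- binarize_response(out$num)
  out$num <- NULL
  out <- tibble::as_tibble(out)
  attr(out, "meta") <- meta
  out
}

#' Class proportions of a binary-labelled dataset
#'
#' @param data A data frame containing the label column.
#' @param response Label column (unquoted), coded -1/+1. Default `y`.
#' @return A one-row tibble with `n`, `n_plus`, `n_minus`, `p_plus`,
#'   `p_minus` (`p_plus + p_minus = 1`).
#' @export
#' @examples
#' d <- tibble::tibble(y = c(1, 1, -1, -1))
#' class_proportions(d)
class_proportions <- function(data, response = y) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort("`data` must be a non-empty data frame.")
  }
  resp <- as_name(enquo(response))
  if (!resp %in% names(data)) {
    abort(sprintf("Response column `%s` not found.", resp))
  }
  yv <- as_pm1(data[[resp]])
  n <- length(yv)
  n_plus <- sum(yv == 1)
  tibble::tibble(
    n = n, n_plus = n_plus, n_minus = n - n_plus,
    p_plus = n_plus / n, p_minus = (n - n_plus) / n
  )
}
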