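# Internal helpers shared across the fitting engines and the pipeline.

#' Build a design matrix with an explicit intercept
#'
#' Thin wrapper used throughout the pipeline: takes a data frame and a
#' character vector of predictor columns and returns a numeric matrix whose
#' first column is the intercept.
#'
#' @param data data frame holding the predictors.
#' @param predictors character vector of column names; may be empty for an
#'   intercept-only design.
#' @return numeric matrix with `length(predictors) + 1` columns named
#'   `"(Intercept)"` followed by the predictor names.
#' @keywords internal
build_design <- function(data, predictors = character()) {
  n <- nrow(data)
  X <- matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "(Intercept)"))
  for (p in predictors) {
    v <- data[[p]]
    if (is.null(v)) stop("predictor column not found: ", p, call. = FALSE)
    if (is.factor(v) || is.character(v)) {
      v <- as.numeric(as.factor(v)) - 1
    }
    X <- cbind(X, as.numeric(v))
    colnames(X)[ncol(X)] <- p
  }
  X
}

# Listwise deletion over a design matrix and outcome; returns the kept row
# index and logs the dropped count via an attribute.
complete_rows <- function(X, y) {
  keep <- stats::complete.cases(X) & !is.na(y)
  structure(which(keep), n_dropped = sum(!keep))
}

# Symmetrise and invert an information matrix with a tiny ridge for
# numerical safety.
safe_solve <- function(H, ridge = 1e-8) {
  H <- (H + t(H)) / 2
  solve(H + diag(ridge, nrow(H)))
}

# Derive a bounded sub-seed from a master seed (kept below 2^31).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
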