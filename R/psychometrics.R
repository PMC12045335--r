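# Psychometrics for the psychosocial battery: sampling adequacy (KMO,
# Bartlett), principal components with direct-oblimin rotation, the
# loading-based item-retention rule, standardized compound scores, and
# Cronbach's alpha.

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO: the ratio of summed squared off-diagonal correlations to the
#' same sum plus the summed squared anti-image partial correlations. Values
#' above 0.7 are conventionally considered adequate for component analysis.
#'
#' @param item_table numeric data frame or matrix of items (columns).
#' @return scalar in `[0, 1]`.
#' @export
kmo <- function(item_table) {
  R <- item_cor(item_table)
  p <- ncol(R)
  if (p < 2) stop("need at least 2 items", call. = FALSE)
  S <- tryCatch(solve(R), error = function(e)
    stop("singular item correlation matrix", call. = FALSE))
  d <- 1 / sqrt(diag(S))
  Q <- -S * outer(d, d)          # anti-image partial correlations
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
}

#' Bartlett test of sphericity
#'
#' Tests whether the item correlation matrix is an identity (no shared
#' variance to extract). `statistic = -(n - 1 - (2p + 5)/6) * log det(R)`
#' with `df = p (p - 1) / 2`.
#'
#' @inheritParams kmo
#' @return an `acp_test` list: `statistic`, `df`, `p`.
#' @export
bartlett_sphericity <- function(item_table) {
  X <- as.matrix(item_table)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than items", call. = FALSE)
  R <- item_cor(item_table)
  ld <- determinant(R, logarithm = TRUE)
  if (ld$sign <= 0) stop("non-positive determinant of correlation matrix",
                         call. = FALSE)
  stat <- -(n - 1 - (2 * p + 5) / 6) * as.numeric(ld$modulus)
  new_test(max(stat, 0), p * (p - 1) / 2)
}

item_cor <- function(item_table) {
  X <- as.matrix(item_table)
  if (!is.numeric(X)) stop("items must be numeric", call. = FALSE)
  stats::cor(X, use = "complete.obs")
}

# --- oblimin rotation ------------------------------------------------------

# Oblimin criterion value and gradient at loading matrix L. gamma = 0 gives
# direct quartimin, the common default for oblique rotation.
oblimin_vg <- function(L, gamma = 0) {
  k <- ncol(L); p <- nrow(L)
  L2 <- L^2
  N <- matrix(1, k, k) - diag(k)
  X <- if (gamma == 0) L2 %*% N else {
    (diag(p) - matrix(gamma / p, p, p)) %*% L2 %*% N
  }
  list(f = sum(L2 * X) / 4, G = L * X)
}

# Oblique gradient-projection rotation of an initial loading matrix A,
# minimizing the oblimin criterion over oblique rotation matrices with
# unit-length columns.
rotate_oblimin <- function(A, gamma = 0, eps = 1e-6, max_iter = 1000L) {
  k <- ncol(A)
  if (k < 2) {
    return(list(pattern = A, phi = diag(k), criterion = 0,
                converged = TRUE, iterations = 0L))
  }
  Tm <- diag(k)
  Ti <- diag(k)
  L <- A
  vg <- oblimin_vg(L, gamma)
  f <- vg$f
  G <- -t(t(L) %*% vg$G %*% Ti)
  al <- 1
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Gp <- G - Tm %*% diag(colSums(Tm * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < eps) { converged <- TRUE; break }
    al <- 2 * al
    ok <- FALSE
    for (half in 0:25) {
      Xt <- Tm - al * Gp
      nrm <- sqrt(colSums(Xt^2))
      if (any(nrm == 0)) { al <- al / 2; next }
      Tt <- Xt %*% diag(1 / nrm, k)
      Ti_t <- tryCatch(solve(Tt), error = function(e) NULL)
      if (!is.null(Ti_t)) {
        Lt <- A %*% t(Ti_t)
        vgt <- oblimin_vg(Lt, gamma)
        if (vgt$f < f - 0.5 * s^2 * al) { ok <- TRUE; break }
      }
      al <- al / 2
    }
    if (!ok) { converged <- TRUE; break }   # no descent direction left
    Tm <- Tt; Ti <- Ti_t; L <- Lt; f <- vgt$f
    G <- -t(t(L) %*% vgt$G %*% Ti)
  }
  if (!converged) {
    stop("oblimin rotation did not converge; criterion = ", signif(f, 6),
         call. = FALSE)
  }
  list(pattern = L, phi = t(Tm) %*% Tm, criterion = f,
       converged = converged, iterations = iter)
}

#' Principal component analysis with direct-oblimin rotation
#'
#' Components are extracted from the item correlation matrix and rotated
#' obliquely (oblimin, default `gamma = 0` i.e. direct quartimin), allowing
#' correlated components — the expected situation for psychosocial
#' constructs such as negative affect and health anxiety.
#'
#' Component retention uses the Kaiser criterion (eigenvalue > 1) by
#' default, or a fixed number via `retention = "fixed_k"`. After rotation
#' each component is sign-aligned (dominant loading positive) and components
#' are ordered by their unrotated eigenvalues.
#'
#' @inheritParams kmo
#' @param retention `"kaiser"` or `"fixed_k"`.
#' @param k number of components when `retention = "fixed_k"`.
#' @param gamma oblimin parameter; 0 = direct quartimin.
#' @param adequacy_warn warn when KMO <= 0.7 or Bartlett p >= 0.05.
#' @return an object of class `component_model` with `eigenvalues`,
#'   `pattern`, `structure` (= pattern x phi), `phi`, `k`, `var_explained`
#'   (per-component proportion of total item variance, unrotated
#'   eigenvalue convention), `kmo`, `bartlett`, and rotation metadata.
#' @export
pca_oblimin <- function(item_table, retention = c("kaiser", "fixed_k"),
                        k = 3, gamma = 0, adequacy_warn = TRUE) {
  retention <- match.arg(retention)
  X <- as.matrix(item_table)
  R <- item_cor(X)
  p <- ncol(R)
  kmo_val <- kmo(X)
  bart <- bartlett_sphericity(X)
  if (adequacy_warn && (kmo_val <= 0.7 || bart$p >= 0.05)) {
    warning(sprintf("sampling adequacy questionable (KMO = %.3f, Bartlett p = %.3g)",
                    kmo_val, bart$p), call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE)
  eigenvalues <- ev$values
  k_ret <- if (retention == "kaiser") sum(eigenvalues > 1) else as.integer(k)
  if (k_ret < 1) stop("no components retained", call. = FALSE)
  A <- ev$vectors[, seq_len(k_ret), drop = FALSE] %*%
    diag(sqrt(pmax(eigenvalues[seq_len(k_ret)], 0)), k_ret)
  rot <- rotate_oblimin(A, gamma = gamma)
  pattern <- rot$pattern
  phi <- rot$phi
  # sign-align: dominant |loading| of each component positive
  for (j in seq_len(k_ret)) {
    if (pattern[which.max(abs(pattern[, j])), j] < 0) {
      pattern[, j] <- -pattern[, j]
      phi[j, -j] <- -phi[j, -j]
      phi[-j, j] <- -phi[-j, j]
    }
  }
  cn <- paste0("comp", seq_len(k_ret))
  dimnames(pattern) <- list(colnames(X) %||% paste0("item", seq_len(p)), cn)
  dimnames(phi) <- list(cn, cn)
  structure_mat <- pattern %*% phi
  structure(list(
    eigenvalues = eigenvalues,
    pattern = pattern,
    structure = structure_mat,
    phi = phi,
    k = k_ret,
    var_explained = eigenvalues[seq_len(k_ret)] / p,
    kmo = kmo_val,
    bartlett = bart,
    rotation = list(gamma = gamma, criterion = rot$criterion,
                    iterations = rot$iterations),
    n_obs = nrow(X)
  ), class = "component_model")
}

#' Assign items to components by the 0.4 loading rule
#'
#' An item is retained iff exactly one component carries an absolute pattern
#' loading of at least `threshold` for it; items loading on no component or
#' cross-loading on several are removed before compound-score calculation.
#'
#' @param pattern items x components rotated pattern matrix.
#' @param threshold absolute loading cut-off (default 0.4).
#' @return data frame with one row per item: `item`, `component` (integer,
#'   `NA` = removed) and `loading` (the signed loading on the assigned
#'   component).
#' @export
assign_items <- function(pattern, threshold = 0.4) {
  pattern <- as.matrix(pattern)
  if (any(!is.finite(pattern))) stop("non-finite loadings", call. = FALSE)
  hits <- abs(pattern) >= threshold
  n_hit <- rowSums(hits)
  comp <- ifelse(n_hit == 1, apply(hits, 1, function(r) which(r)[1]),
                 NA_integer_)
  loading <- ifelse(is.na(comp), NA_real_,
                    pattern[cbind(seq_len(nrow(pattern)), comp)])
  out <- data.frame(
    item = rownames(pattern) %||% paste0("item", seq_len(nrow(pattern))),
    component = as.integer(comp),
    loading = loading,
    stringsAsFactors = FALSE
  )
  if (all(is.na(out$component))) {
    warning("no item reached the loading threshold; empty assignment",
            call. = FALSE)
  }
  out
}

#' Standardized compound scores per component
#'
#' Unit-weighted composite: each retained item is z-scored and sign-aligned
#' with its loading, the per-component mean is taken, and the result is
#' re-standardized to mean 0, SD 1.
#'
#' @inheritParams kmo
#' @param retained_map output of [assign_items()].
#' @return numeric matrix, participants x components, columns
#'   `comp<j>` for every component with at least one retained item.
#' @export
compound_scores <- function(item_table, retained_map) {
  X <- as.matrix(item_table)
  comps <- sort(unique(retained_map$component[!is.na(retained_map$component)]))
  if (length(comps) == 0) stop("no retained items", call. = FALSE)
  out <- matrix(NA_real_, nrow(X), length(comps),
                dimnames = list(NULL, paste0("comp", comps)))
  for (j in seq_along(comps)) {
    rows <- retained_map[!is.na(retained_map$component) &
                           retained_map$component == comps[j], ]
    cols <- rows$item
    sds <- apply(X[, cols, drop = FALSE], 2, stats::sd, na.rm = TRUE)
    if (any(sds == 0)) {
      warning("zero-variance item dropped: ",
              paste(cols[sds == 0], collapse = ", "), call. = FALSE)
      rows <- rows[sds > 0, ]
      cols <- rows$item
    }
    if (length(cols) == 0) next
    Z <- scale(X[, cols, drop = FALSE])
    Z <- sweep(Z, 2, sign(rows$loading), `*`)
    sc <- rowMeans(Z, na.rm = TRUE)
    out[, j] <- as.vector(scale(sc))
  }
  out
}

#' Cronbach's alpha
#'
#' Internal consistency of a multi-item composite:
#' `alpha = k/(k - 1) * (1 - sum(item variances) / total variance)`.
#'
#' @param items numeric data frame or matrix with >= 2 item columns.
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(items) {
  X <- as.matrix(items)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  k <- ncol(X)
  if (k < 2) stop("need at least 2 items", call. = FALSE)
  total_var <- stats::var(rowSums(X))
  if (total_var == 0) stop("zero total variance; alpha undefined",
                           call. = FALSE)
  k / (k - 1) * (1 - sum(apply(X, 2, stats::var)) / total_var)
}

#' Full component model: PCA, rotation, retention, scores and alphas
#'
#' Convenience wrapper chaining [pca_oblimin()], [assign_items()],
#' [compound_scores()] and per-component [cronbach_alpha()] (items entering
#' alpha are sign-aligned with their loadings).
#'
#' @inheritParams pca_oblimin
#' @param threshold loading threshold for item retention.
#' @return the `component_model` from [pca_oblimin()] augmented with
#'   `retained_map`, `scores` and `alphas`.
#' @export
fit_components <- function(item_table, retention = c("kaiser", "fixed_k"),
                           k = 3, gamma = 0, threshold = 0.4,
                           adequacy_warn = TRUE) {
  model <- pca_oblimin(item_table, retention = retention, k = k,
                       gamma = gamma, adequacy_warn = adequacy_warn)
  model$retained_map <- assign_items(model$pattern, threshold = threshold)
  model$scores <- compound_scores(item_table, model$retained_map)
  X <- as.matrix(item_table)
  model$alphas <- vapply(seq_len(model$k), function(j) {
    rows <- model$retained_map[!is.na(model$retained_map$component) &
                                 model$retained_map$component == j, ]
    if (nrow(rows) < 2) return(NA_real_)
    Z <- scale(X[, rows$item, drop = FALSE])
    Z <- sweep(Z, 2, sign(rows$loading), `*`)
    cronbach_alpha(Z)
  }, numeric(1))
  names(model$alphas) <- paste0("comp", seq_len(model$k))
  model
}

#' @export
print.component_model <- function(x, ...) {
  cat(sprintf("Component model: %d components from %d items (n = %d)\n",
              x$k, nrow(x$pattern), x$n_obs))
  cat(sprintf("  KMO = %.3f, Bartlett chi2(%d) = %.1f (p = %.3g)\n",
              x$kmo, x$bartlett$df, x$bartlett$statistic, x$bartlett$p))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  if (!is.null(x$alphas)) {
    cat("  Cronbach alpha:",
        paste(sprintf("%.2f", x$alphas), collapse = ", "), "\n")
  }
  invisible(x)
}
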