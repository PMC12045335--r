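# Maximum-likelihood engines for the four model families used by the
# symptom-perception pipeline: multinomial logit, cumulative-logit
# proportional odds, binary logit, and ordinary least squares, plus the
# likelihood-ratio machinery (parallel-lines test, LR test, pseudo-R2).
#
# All fitters are Newton-Raphson with step-halving, convergence on
# |change in log-likelihood| < tol, and a tiny ridge on the information
# matrix for numerical safety.

.GLM_TOL <- 1e-8
.GLM_MAXIT <- 100L
.GLM_RIDGE <- 1e-8
.SEPARATION_BOUND <- 15

# --- multinomial -----------------------------------------------------------

#' Fit a multinomial logistic model by maximum likelihood
#'
#' Baseline-category multinomial logit fitted by Newton-Raphson on the full
#' log-likelihood. One linear predictor is estimated per non-reference
#' outcome level, so predictor effects may differ across levels — the
#' "less restrictive" alternative to a proportional-odds model when the
#' parallel-lines assumption fails.
#'
#' @param design numeric matrix, `n x p`, including an intercept column.
#' @param y outcome vector (integer, factor or character); every level must
#'   be observed at least once.
#' @param ref_category the baseline level. Defaults to the lowest level,
#'   which for symptom items scored 1-5 is "1 — not at all".
#' @param tol,max_iter Newton-Raphson convergence controls.
#' @return an object of class `multinomial_fit`: `categories` (ordered level
#'   set), `ref_category`, `coef` ((K-1) x p matrix, one row per non-reference
#'   level), `cov` (inverse observed information of the stacked coefficient
#'   vector), `loglik`, `n_obs`, `n_dropped`, `converged`, `iterations`.
#' @examples
#' X <- cbind(1, rnorm(300))
#' y <- sample(1:3, 300, replace = TRUE)
#' fit <- fit_multinomial(X, y)
#' head(predict_category_probs(fit, X))
#' @export
fit_multinomial <- function(design, y, ref_category = NULL,
                            tol = .GLM_TOL, max_iter = .GLM_MAXIT) {
  design <- as.matrix(design)
  keep <- complete_rows(design, y)
  n_dropped <- attr(keep, "n_dropped")
  design <- design[keep, , drop = FALSE]
  y <- y[keep]
  check_design(design)

  lev <- sort(unique(as.character(y)))
  if (is.factor(y)) lev <- levels(droplevels(y))
  counts <- table(factor(as.character(y), levels = lev))
  if (any(counts == 0)) {
    stop("empty outcome category: ", paste(lev[counts == 0], collapse = ", "),
         call. = FALSE)
  }
  K <- length(lev)
  if (K < 2) stop("outcome must have at least 2 observed levels", call. = FALSE)
  ref <- if (is.null(ref_category)) lev[1] else as.character(ref_category)
  if (!ref %in% lev) stop("ref_category not among observed levels", call. = FALSE)
  nonref <- setdiff(lev, ref)

  n <- nrow(design); p <- ncol(design)
  if (p >= n) stop("more parameters than observations", call. = FALSE)
  # indicator matrix n x (K-1) for the non-reference levels
  Y <- vapply(nonref, function(l) as.numeric(as.character(y) == l), numeric(n))

  B <- matrix(0, K - 1, p, dimnames = list(nonref, colnames(design)))
  ll <- multinom_loglik(B, design, Y)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    P <- multinom_probs_nonref(B, design)            # n x (K-1)
    grad <- as.vector(crossprod(design, Y - P))      # stacked by category
    H <- multinom_info(design, P)
    step <- tryCatch(safe_solve(H, .GLM_RIDGE) %*% grad,
                     error = function(e) stop("singular information matrix",
                                              call. = FALSE))
    step_mat <- matrix(step, K - 1, p, byrow = TRUE)
    alpha <- 1
    repeat {
      B_new <- B + alpha * step_mat
      ll_new <- multinom_loglik(B_new, design, Y)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) { ll_new <- ll; B_new <- B; break }
    }
    delta <- ll_new - ll
    B <- B_new; ll <- ll_new
    if (abs(delta) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  P <- multinom_probs_nonref(B, design)
  H <- multinom_info(design, P)
  cov <- safe_solve(H, .GLM_RIDGE)
  if (!converged) {
    warning("multinomial fit did not converge in ", max_iter,
            " iterations; returning last iterate", call. = FALSE)
  }
  structure(list(
    categories = lev, ref_category = ref, coef = B, cov = cov,
    loglik = ll, n_obs = n, n_dropped = n_dropped,
    converged = converged, iterations = iter
  ), class = "multinomial_fit")
}

multinom_eta <- function(B, X) X %*% t(B)   # n x (K-1)

multinom_probs_nonref <- function(B, X) {
  eta <- multinom_eta(B, X)
  m <- pmax(apply(eta, 1, max), 0)
  denom <- exp(-m) + rowSums(exp(eta - m))
  exp(eta - m) / denom
}

multinom_loglik <- function(B, X, Y) {
  eta <- multinom_eta(B, X)
  m <- pmax(apply(eta, 1, max), 0)
  logdenom <- m + log(exp(-m) + rowSums(exp(eta - m)))
  sum(rowSums(Y * eta) - logdenom)
}

# Observed information of the stacked (category-major) coefficient vector.
multinom_info <- function(X, P) {
  Km1 <- ncol(P); p <- ncol(X)
  H <- matrix(0, Km1 * p, Km1 * p)
  for (k in seq_len(Km1)) {
    for (l in k:Km1) {
      w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
      blk <- crossprod(X, X * w)
      ri <- (k - 1) * p + seq_len(p); ci <- (l - 1) * p + seq_len(p)
      H[ri, ci] <- blk
      H[ci, ri] <- t(blk)
    }
  }
  H
}

#' Predicted category probabilities from a multinomial fit
#'
#' Softmax inversion of the fitted linear predictors; the reference level's
#' predictor is identically zero.
#'
#' @param fit a `multinomial_fit`.
#' @param design numeric matrix with the same columns as the fitting design.
#' @return `m x K` matrix of probabilities, columns in `fit$categories`
#'   order; every row sums to 1.
#' @export
predict_category_probs <- function(fit, design) {
  stopifnot(inherits(fit, "multinomial_fit"))
  design <- as.matrix(design)
  if (ncol(design) != ncol(fit$coef)) {
    stop("design has ", ncol(design), " columns but the fit expects ",
         ncol(fit$coef), call. = FALSE)
  }
  Pnr <- multinom_probs_nonref(fit$coef, design)
  P <- cbind(1 - rowSums(Pnr), Pnr)
  colnames(P) <- c(fit$ref_category, rownames(fit$coef))
  P[, fit$categories, drop = FALSE]
}

# --- ordinal (proportional odds) ------------------------------------------

#' Fit a cumulative-logit proportional-odds model
#'
#' Maximum likelihood for the ordinal regression model
#' `logit P(Y <= k) = theta_k - x'beta` (so positive `beta` shifts mass
#' towards higher categories). Thresholds are kept strictly increasing by
#' step-halving any Newton step that would violate monotonicity.
#'
#' An intercept column in `design` is dropped automatically: the thresholds
#' play that role.
#'
#' @inheritParams fit_multinomial
#' @return an object of class `ordinal_fit`: `thresholds` (K-1 increasing
#'   cut-points), `slopes`, `loglik`, `cov`, `converged`, `n_obs`,
#'   `categories`, and `sign_convention`.
#' @export
fit_ordinal_po <- function(design, y, tol = .GLM_TOL, max_iter = .GLM_MAXIT) {
  design <- as.matrix(design)
  keep <- complete_rows(design, y)
  n_dropped <- attr(keep, "n_dropped")
  design <- design[keep, , drop = FALSE]
  y <- y[keep]
  # thresholds absorb the intercept
  const <- apply(design, 2, function(v) stats::var(v) == 0)
  X <- design[, !const, drop = FALSE]
  check_design(cbind(1, X))

  lev <- sort(unique(as.character(y)))
  if (is.factor(y)) lev <- levels(droplevels(y))
  yc <- match(as.character(y), lev)
  K <- length(lev)
  if (K < 2) stop("outcome must have at least 2 observed levels", call. = FALSE)
  n <- nrow(X); p <- ncol(X)

  cum <- cumsum(tabulate(yc, K) / n)[-K]
  theta <- stats::qlogis(pmin(pmax(cum, 1e-6), 1 - 1e-6))
  beta <- rep(0, p)
  psi <- c(theta, beta)

  ll <- ordinal_loglik(psi, X, yc, K)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    gH <- ordinal_grad_hess(psi, X, yc, K)
    step <- tryCatch(safe_solve(-gH$H, .GLM_RIDGE) %*% gH$g,
                     error = function(e) stop("singular information matrix",
                                              call. = FALSE))
    alpha <- 1
    repeat {
      psi_new <- psi + alpha * as.vector(step)
      th <- psi_new[seq_len(K - 1)]
      monotone <- K == 2 || all(diff(th) > 0)
      ll_new <- if (monotone) ordinal_loglik(psi_new, X, yc, K) else -Inf
      if (monotone && is.finite(ll_new) && ll_new >= ll - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) { psi_new <- psi; ll_new <- ll; break }
    }
    delta <- ll_new - ll
    psi <- psi_new; ll <- ll_new
    if (abs(delta) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warning("ordinal fit did not converge in ", max_iter,
            " iterations; returning last iterate", call. = FALSE)
  }
  gH <- ordinal_grad_hess(psi, X, yc, K)
  cov <- safe_solve(-gH$H, .GLM_RIDGE)
  theta <- psi[seq_len(K - 1)]
  beta <- psi[-seq_len(K - 1)]
  names(beta) <- colnames(X)
  structure(list(
    thresholds = theta, slopes = beta, loglik = ll, cov = cov,
    converged = converged, iterations = iter, n_obs = n,
    n_dropped = n_dropped, categories = lev,
    sign_convention = "logit P(Y <= k) = theta_k - x'beta"
  ), class = "ordinal_fit")
}

ordinal_loglik <- function(psi, X, yc, K) {
  theta <- psi[seq_len(K - 1)]
  beta <- psi[-seq_len(K - 1)]
  eta <- if (ncol(X)) as.vector(X %*% beta) else numeric(nrow(X))
  upper <- ifelse(yc == K, Inf, theta[pmin(yc, K - 1)] - eta)
  lower <- ifelse(yc == 1, -Inf, theta[pmax(yc - 1, 1)] - eta)
  pi <- stats::plogis(upper) - stats::plogis(lower)
  if (any(pi <= 0)) return(-Inf)
  sum(log(pi))
}

# Analytic gradient and Hessian of the cumulative-logit log-likelihood in
# psi = (theta_1..theta_{K-1}, beta).
ordinal_grad_hess <- function(psi, X, yc, K) {
  theta <- psi[seq_len(K - 1)]
  beta <- psi[-seq_len(K - 1)]
  n <- nrow(X); p <- ncol(X); q <- K - 1 + p
  eta <- if (p) as.vector(X %*% beta) else numeric(n)

  a <- ifelse(yc == K, Inf, theta[pmin(yc, K - 1)] - eta)
  b <- ifelse(yc == 1, -Inf, theta[pmax(yc - 1, 1)] - eta)
  Fa <- stats::plogis(a); Fb <- stats::plogis(b)
  fa <- ifelse(is.finite(a), Fa * (1 - Fa), 0)
  fb <- ifelse(is.finite(b), Fb * (1 - Fb), 0)
  fpa <- ifelse(is.finite(a), fa * (1 - 2 * Fa), 0)
  fpb <- ifelse(is.finite(b), fb * (1 - 2 * Fb), 0)
  pi <- Fa - Fb
  u <- fa / pi; v <- fb / pi
  d2a <- fpa / pi - u^2        # d2 loglik / da2
  d2b <- -fpb / pi - v^2       # d2 loglik / db2
  dab <- u * v                 # cross term

  g <- numeric(q)
  H <- matrix(0, q, q)
  # Per-observation derivative maps: da/dtheta_k = [k == yc], da/dbeta = -x;
  # db/dtheta_k = [k == yc - 1], db/dbeta = -x.
  ia <- ifelse(yc <= K - 1, yc, NA_integer_)      # theta index behind a
  ib <- ifelse(yc >= 2, yc - 1L, NA_integer_)     # theta index behind b

  for (k in seq_len(K - 1)) {
    sa <- which(ia == k); sb <- which(ib == k)
    g[k] <- sum(u[sa]) - sum(v[sb])
    # theta_k x theta_k
    H[k, k] <- sum(d2a[sa]) + sum(d2b[sb])
    # theta_k x theta_{k-1} (a of one obs pairs with b on the next threshold)
    if (k >= 2) {
      sab <- which(ia == k & ib == (k - 1))
      H[k, k - 1] <- H[k, k - 1] + sum(dab[sab])
      H[k - 1, k] <- H[k, k - 1]
    }
    if (p) {
      # theta_k x beta: a contributes -x d2a - x dab(b term); b contributes
      # -x d2b - x dab(a term)
      hb <- -colSums(X[sa, , drop = FALSE] * (d2a[sa] + dab[sa])) -
        colSums(X[sb, , drop = FALSE] * (d2b[sb] + dab[sb]))
      H[k, K - 1 + seq_len(p)] <- hb
      H[K - 1 + seq_len(p), k] <- hb
    }
  }
  if (p) {
    w <- d2a + d2b + 2 * dab
    Hbb <- crossprod(X, X * w)
    H[K - 1 + seq_len(p), K - 1 + seq_len(p)] <- Hbb
    g[K - 1 + seq_len(p)] <- -colSums(X * (u - v))
  }
  list(g = g, H = H)
}

# --- parallel lines --------------------------------------------------------

#' Likelihood-ratio test of the parallel-lines (proportional-odds) assumption
#'
#' Compares a proportional-odds fit against the unrestricted multinomial fit
#' on the same data: `statistic = 2 (loglik_multinomial - loglik_ordinal)`,
#' with `df = p_slope * (K - 2)` extra slope parameters, referred to the
#' upper tail of the chi-squared distribution. A significant result means a
#' single shared slope cannot capture the association across all cumulative
#' splits of the ordinal outcome.
#'
#' @param ordinal an `ordinal_fit`.
#' @param multinomial a `multinomial_fit` on the same observations.
#' @return an `acp_test` list: `statistic`, `df`, `p`.
#' @export
test_parallel_lines <- function(ordinal, multinomial) {
  stopifnot(inherits(ordinal, "ordinal_fit"),
            inherits(multinomial, "multinomial_fit"))
  if (ordinal$n_obs != multinomial$n_obs ||
      length(ordinal$categories) != length(multinomial$categories)) {
    stop("the two fits must be computed on identical data", call. = FALSE)
  }
  K <- length(ordinal$categories)
  p_slope <- length(ordinal$slopes)
  stat <- 2 * (multinomial$loglik - ordinal$loglik)
  if (stat < -1e-8 * max(1, abs(multinomial$loglik))) {
    # The multinomial relaxation is not strictly nested above the
    # cumulative-logit model, so a better-fitting proportional-odds model
    # can push the statistic (slightly) negative; that outcome carries no
    # evidence against parallel lines and is reported as 0.
    warning("proportional-odds fit exceeds the multinomial fit ",
            "(statistic ", signif(stat, 4),
            "); no evidence against parallel lines", call. = FALSE)
  }
  stat <- max(stat, 0)
  df <- max(p_slope * (K - 2), 1L)
  new_test(stat, df)
}

new_test <- function(stat, df) {
  structure(list(statistic = stat, df = as.integer(df),
                 p = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "acp_test")
}

# --- binary logistic -------------------------------------------------------

#' Fit a binary logistic model by maximum likelihood
#'
#' Newton-Raphson logistic regression with Wald standard errors, odds ratios
#' and 95% confidence intervals. Complete or quasi-complete separation is
#' detected via diverging coefficients and reported as an error naming the
#' offending predictor.
#'
#' @param design numeric `n x p` matrix including an intercept column.
#' @param y binary outcome (0/1, logical, or two-level factor).
#' @inheritParams fit_multinomial
#' @return an object of class `binary_fit`: `coef`, `se`, `or_`, `ci95`
#'   (`p x 2` matrix), `p_value` (Wald), `loglik`, `cov`, `converged`,
#'   `n_obs`.
#' @examples
#' x <- rep(c(0, 1), each = 30)
#' y <- rep(c(0, 1, 0, 1), c(20, 10, 10, 20))
#' exp(fit_logistic(cbind(1, x), y)$coef[2])  # sample odds ratio 4
#' @export
fit_logistic <- function(design, y, tol = .GLM_TOL, max_iter = .GLM_MAXIT) {
  design <- as.matrix(design)
  if (is.factor(y)) y <- as.numeric(y) - 1
  if (is.logical(y)) y <- as.numeric(y)
  keep <- complete_rows(design, y)
  n_dropped <- attr(keep, "n_dropped")
  design <- design[keep, , drop = FALSE]
  y <- y[keep]
  check_design(design)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2) stop("outcome has a single class", call. = FALSE)
  n <- nrow(design); p <- ncol(design)
  if (p >= n) stop("more parameters than observations", call. = FALSE)

  beta <- rep(0, p)
  ll <- logistic_loglik(beta, design, y)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mu <- stats::plogis(as.vector(design %*% beta))
    g <- crossprod(design, y - mu)
    H <- crossprod(design, design * (mu * (1 - mu)))
    step <- as.vector(safe_solve(H, .GLM_RIDGE) %*% g)
    alpha <- 1
    repeat {
      beta_new <- beta + alpha * step
      ll_new <- logistic_loglik(beta_new, design, y)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) { beta_new <- beta; ll_new <- ll; break }
    }
    delta <- ll_new - ll
    beta <- beta_new; ll <- ll_new
    if (abs(delta) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  nm <- colnames(design) %||% paste0("x", seq_len(p))
  if (any(abs(beta) > .SEPARATION_BOUND)) {
    stop("separation detected for predictor: ",
         nm[which.max(abs(beta))], call. = FALSE)
  }
  mu <- stats::plogis(as.vector(design %*% beta))
  cov <- safe_solve(crossprod(design, design * (mu * (1 - mu))), .GLM_RIDGE)
  se <- sqrt(diag(cov))
  names(beta) <- names(se) <- nm
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  rownames(ci) <- nm
  structure(list(
    coef = beta, se = se, or_ = exp(beta), ci95 = ci,
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    loglik = ll, cov = cov, converged = converged, iterations = iter,
    n_obs = n, n_dropped = n_dropped
  ), class = "binary_fit")
}

logistic_loglik <- function(beta, X, y) {
  eta <- as.vector(X %*% beta)
  sum(y * eta - log1p(exp(pmin(eta, 700))) - pmax(eta - 700, 0))
}

# --- linear ----------------------------------------------------------------

#' Fit a linear model by least squares
#'
#' QR-based ordinary least squares with the Gaussian maximum-likelihood
#' log-likelihood attached, so linear models can enter the same nested
#' likelihood-ratio bookkeeping as the logistic and multinomial fits.
#'
#' @inheritParams fit_logistic
#' @param y continuous outcome.
#' @return an object of class `linear_fit`: `coef`, `r2`, `resid_var`
#'   (ML estimate, SSR/n), `loglik`, `n_obs`. A zero-variance outcome gives
#'   `r2 = 0` with a warning.
#' @export
fit_linear <- function(design, y) {
  design <- as.matrix(design)
  keep <- complete_rows(design, y)
  n_dropped <- attr(keep, "n_dropped")
  design <- design[keep, , drop = FALSE]
  y <- as.numeric(y[keep])
  n <- nrow(design); p <- ncol(design)
  if (p >= n) stop("more parameters than observations", call. = FALSE)
  qr_fit <- qr(design)
  beta <- qr.coef(qr_fit, y)
  resid <- y - as.vector(design %*% ifelse(is.na(beta), 0, beta))
  ssr <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    warning("outcome has zero variance; r2 set to 0", call. = FALSE)
    r2 <- 0
  } else {
    r2 <- 1 - ssr / sst
  }
  sigma2 <- ssr / n
  loglik <- if (sigma2 > 0) -n / 2 * (log(2 * pi * sigma2) + 1) else Inf
  names(beta) <- colnames(design)
  structure(list(coef = beta, r2 = r2, resid_var = sigma2, loglik = loglik,
                 n_obs = n, n_dropped = n_dropped, n_param = p),
            class = "linear_fit")
}

# --- likelihood-ratio machinery -------------------------------------------

#' Pseudo-R-squared measures from a pair of log-likelihoods
#'
#' Cox & Snell, Nagelkerke (Cox & Snell rescaled to a 0-1 range) and
#' McFadden variants. Nagelkerke is the conventional headline choice when a
#' single unnamed "pseudo R2" is reported.
#'
#' @param fit_loglik log-likelihood of the fitted model.
#' @param null_loglik log-likelihood of the intercept-only model on the same
#'   data.
#' @param n number of observations.
#' @return class `pseudo_r2` list: `cox_snell`, `nagelkerke`, `mcfadden`.
#' @export
pseudo_r2 <- function(fit_loglik, null_loglik, n) {
  if (fit_loglik < null_loglik - 1e-8 * max(1, abs(null_loglik))) {
    stop("fitted log-likelihood below the null log-likelihood", call. = FALSE)
  }
  fit_loglik <- max(fit_loglik, null_loglik)
  cs <- 1 - exp(2 * (null_loglik - fit_loglik) / n)
  if (null_loglik == 0) {
    warning("degenerate null model (loglik 0); nagelkerke undefined",
            call. = FALSE)
    nag <- NA_real_
  } else {
    nag <- cs / (1 - exp(2 * null_loglik / n))
  }
  mcf <- if (null_loglik == 0) NA_real_ else 1 - fit_loglik / null_loglik
  structure(list(cox_snell = cs, nagelkerke = nag, mcfadden = mcf),
            class = "pseudo_r2")
}

#' Likelihood-ratio test between two nested fits
#'
#' @param nested_loglik,full_loglik log-likelihoods of the nested and full
#'   model on identical data.
#' @param df_diff difference in parameter count (>= 1).
#' @return an `acp_test` list: `statistic`, `df`, `p`.
#' @export
lr_test <- function(nested_loglik, full_loglik, df_diff) {
  if (df_diff < 1) stop("df_diff must be at least 1", call. = FALSE)
  stat <- 2 * (full_loglik - nested_loglik)
  if (stat < -1e-8 * max(1, abs(full_loglik))) {
    stop("inconsistent fits: full log-likelihood below nested", call. = FALSE)
  }
  new_test(max(stat, 0), df_diff)
}

check_design <- function(X) {
  if (any(!is.finite(X))) stop("non-finite values in design", call. = FALSE)
  if (ncol(X) > 1) {
    sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
    if (any(sds == 0)) {
      nm <- colnames(X)[-1][sds == 0]
      stop("constant non-intercept column: ",
           paste(nm, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.acp_test <- function(x, ...) {
  cat(sprintf("chi-squared = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' @export
print.multinomial_fit <- function(x, ...) {
  cat("Multinomial logistic fit (baseline category:", x$ref_category, ")\n")
  cat("  levels:", paste(x$categories, collapse = ", "), "\n")
  cat(sprintf("  n = %d, loglik = %.3f, converged = %s\n",
              x$n_obs, x$loglik, x$converged))
  print(round(x$coef, 4))
  invisible(x)
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat("Proportional-odds fit:", x$sign_convention, "\n")
  cat(sprintf("  n = %d, loglik = %.3f, converged = %s\n",
              x$n_obs, x$loglik, x$converged))
  cat("  thresholds:", paste(round(x$thresholds, 4), collapse = ", "), "\n")
  cat("  slopes:\n")
  print(round(x$slopes, 4))
  invisible(x)
}

#' @export
print.binary_fit <- function(x, ...) {
  cat(sprintf("Binary logistic fit: n = %d, loglik = %.3f\n",
              x$n_obs, x$loglik))
  print(round(cbind(coef = x$coef, se = x$se, OR = x$or_, x$ci95,
                    p = x$p_value), 4))
  invisible(x)
}
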