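# Independent oracles: explicitly written negative log-likelihoods handed
# to generic numerical optimizers, plus small simulators for fixture data.
# These never call the package's own fitting code paths.

# multinomial logit NLL; theta stacked category-major, ref = first level
oracle_multinom_nll <- function(theta, X, y, levels) {
  p <- ncol(X); K <- length(levels)
  B <- matrix(theta, K - 1, p, byrow = TRUE)
  eta <- X %*% t(B)
  logdenom <- log(1 + rowSums(exp(eta)))
  idx <- match(as.character(y), levels) - 1L   # 0 = reference
  pick <- ifelse(idx == 0, 0, eta[cbind(seq_along(idx), pmax(idx, 1))])
  -sum(pick - logdenom)
}

# cumulative-logit NLL; psi = (theta_1..theta_{K-1}, beta),
# logit P(Y <= k) = theta_k - x'beta
oracle_ordinal_nll <- function(psi, X, y, levels) {
  K <- length(levels)
  theta <- psi[seq_len(K - 1)]
  beta <- psi[-seq_len(K - 1)]
  if (any(diff(theta) <= 0)) return(1e10)
  eta <- as.vector(X %*% beta)
  k <- match(as.character(y), levels)
  up <- ifelse(k == K, 1, stats::plogis(theta[pmin(k, K - 1)] - eta))
  lo <- ifelse(k == 1, 0, stats::plogis(theta[pmax(k - 1, 1)] - eta))
  if (any(up - lo <= 0)) return(1e10)
  -sum(log(up - lo))
}

oracle_logistic_nll <- function(beta, X, y) {
  eta <- as.vector(X %*% beta)
  -sum(y * eta - log1p(exp(eta)))
}

# simulate from a known multinomial logit model (ref = first level)
sim_multinom <- function(n, B, seed) {
  set.seed(seed)
  p <- ncol(B)
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
  eta <- X %*% t(B)
  P <- cbind(1, exp(eta)) / (1 + rowSums(exp(eta)))
  y <- apply(P, 1, function(pr) sample(seq_len(ncol(P)), 1, prob = pr))
  list(X = X, y = y)
}

# simulate from a proportional-odds model with the theta_k - x'beta convention
sim_po <- function(n, theta, beta, seed) {
  set.seed(seed)
  p <- length(beta)
  X <- cbind(1, matrix(rnorm(n * p), n, p))
  eta <- as.vector(X[, -1, drop = FALSE] %*% beta)
  u <- runif(n)
  cum <- vapply(theta, function(t) plogis(t - eta), numeric(n))
  y <- 1L + rowSums(u > cum)
  list(X = X, y = y)
}

# columns orthonormalized so the sample correlation matrix is exactly the
# target R (up to floating point)
exact_cor_data <- function(n, R, seed) {
  set.seed(seed)
  p <- ncol(R)
  # orthonormalize against the constant so columns are mean-zero and
  # mutually uncorrelated, then color with chol(R)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))
  X <- Q[, 1 + seq_len(p), drop = FALSE] %*% chol(R)
  X
}
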