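# The four ML fitters against closed forms and independent generic
# optimizers on the explicitly written log-likelihoods.

test_that("intercept-only multinomial reproduces empirical frequencies", {
  y <- rep(1:3, each = 40)
  X <- matrix(1, 120, 1)
  fit <- fit_multinomial(X, y)
  P <- predict_category_probs(fit, X)
  expect_equal(unname(P[1, ]), rep(1 / 3, 3), tolerance = 1e-9)

  y2 <- rep(1:3, c(70, 20, 10))
  fit2 <- fit_multinomial(matrix(1, 100, 1), y2)
  P2 <- predict_category_probs(fit2, matrix(1, 1, 1))
  expect_equal(unname(P2[1, ]), c(0.7, 0.2, 0.1), tolerance = 1e-9)
})

test_that("two-level multinomial equals the binary logistic fit", {
  set.seed(11)
  X <- cbind(1, rnorm(200))
  y <- rbinom(200, 1, plogis(-0.3 + 0.9 * X[, 2])) + 1
  mn <- fit_multinomial(X, y)
  bn <- fit_logistic(X, as.numeric(y == 2))
  expect_equal(unname(mn$coef[1, ]), unname(bn$coef), tolerance = 1e-7)
  expect_equal(mn$loglik, bn$loglik, tolerance = 1e-9)
})

test_that("multinomial ML matches a generic optimizer of the explicit log-likelihood", {
  B <- rbind(c(0.4, 0.9, -0.6), c(-0.5, -0.2, 0.7))
  d <- sim_multinom(200, B, seed = 21)
  fit <- fit_multinomial(d$X, d$y)
  o <- optim(rep(0, 6), oracle_multinom_nll, X = d$X, y = d$y,
             levels = as.character(1:3), method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-15))
  ours <- as.vector(t(fit$coef))
  expect_lt(max(abs(ours - o$par) / pmax(abs(o$par), 1)), 1e-6)
  expect_equal(fit$loglik, -o$value, tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("multinomial rejects empty categories and bad designs", {
  X <- cbind(1, rnorm(50))
  expect_error(fit_multinomial(X, factor(rep(1, 50), levels = 1:2)),
               "empty|single|2 observed")
  expect_error(fit_multinomial(cbind(1, rep(2, 60)), rep(1:3, 20)),
               "constant")
})

test_that("predicted probability rows sum to one and match the softmax form", {
  set.seed(3)
  B <- rbind(c(log(2), 0), c(0, 0))
  fit <- structure(list(categories = c("1", "2", "3"), ref_category = "1",
                        coef = rbind(`2` = c(log(2), 0), `3` = c(0, 0))),
                   class = "multinomial_fit")
  P <- predict_category_probs(fit, cbind(1, 0))
  expect_equal(unname(P[1, ]), c(0.25, 0.5, 0.25), tolerance = 1e-12)

  Xm <- cbind(1, rnorm(40))
  Bm <- rbind(`2` = c(0.2, -1.1), `3` = c(-0.4, 0.8))
  fit2 <- structure(list(categories = c("1", "2", "3"), ref_category = "1",
                         coef = Bm), class = "multinomial_fit")
  P2 <- predict_category_probs(fit2, Xm)
  expect_lt(max(abs(rowSums(P2) - 1)), 1e-12)
  # direct softmax oracle
  e2 <- exp(Xm %*% Bm[1, ]); e3 <- exp(Xm %*% Bm[2, ])
  expect_equal(unname(P2[, 2]), as.vector(e2 / (1 + e2 + e3)),
               tolerance = 1e-12)
  expect_error(predict_category_probs(fit2, cbind(1, 1, 1)), "columns")
})

test_that("intercept-only ordinal thresholds are cumulative logits", {
  y <- rep(1:3, c(50, 30, 20))
  fit <- fit_ordinal_po(matrix(1, 100, 1), y)
  expect_equal(unname(fit$thresholds), c(0, log(4)), tolerance = 1e-7)
})

test_that("two-level ordinal reduces to binary logistic under the sign convention", {
  set.seed(5)
  X <- cbind(1, rnorm(300))
  y <- 1 + rbinom(300, 1, plogis(-0.4 + 0.8 * X[, 2]))
  of <- fit_ordinal_po(X, y)
  bf <- fit_logistic(X, as.numeric(y == 2))
  # logit P(Y=2) = x'beta - theta_1
  expect_equal(unname(of$slopes), unname(bf$coef[2]), tolerance = 1e-7)
  expect_equal(unname(of$thresholds), unname(-bf$coef[1]), tolerance = 1e-7)
})

test_that("ordinal ML matches a generic optimizer of the explicit log-likelihood", {
  d <- sim_po(500, theta = c(-0.8, 0.4, 1.5), beta = c(0.7, -0.5), seed = 31)
  fit <- fit_ordinal_po(d$X, d$y)
  expect_true(all(diff(fit$thresholds) > 0))
  start <- c(qlogis(cumsum(prop.table(table(d$y)))[-4]), 0, 0)
  o <- optim(start, oracle_ordinal_nll, X = d$X[, -1], y = d$y,
             levels = as.character(1:4), method = "BFGS",
             control = list(maxit = 5000, reltol = 1e-15))
  ours <- c(fit$thresholds, fit$slopes)
  expect_lt(max(abs(ours - o$par) / pmax(abs(o$par), 1)), 1e-6)
  expect_equal(fit$loglik, -o$value, tolerance = 1e-8)
})

test_that("parallel-lines test: df bookkeeping and null behavior", {
  # K = 2: ordinal and multinomial are the same model, statistic ~ 0, p ~ 1
  set.seed(41)
  X <- cbind(1, rnorm(200))
  y <- 1 + rbinom(200, 1, plogis(0.5 * X[, 2]))
  pl0 <- test_parallel_lines(fit_ordinal_po(X, y), fit_multinomial(X, y))
  expect_equal(pl0$statistic, 0, tolerance = 1e-6)
  expect_equal(pl0$p, 1, tolerance = 1e-4)

  # p_slope = 2, K = 5 gives df = 6
  d <- sim_po(400, theta = c(-1.5, -0.5, 0.5, 1.5), beta = c(0.6, -0.4),
              seed = 42)
  pl <- test_parallel_lines(fit_ordinal_po(d$X, d$y),
                            fit_multinomial(d$X, d$y))
  expect_identical(pl$df, 6L)
  expect_gte(pl$statistic, 0)
})

test_that("parallel-lines test holds its size under proportional odds", {
  reps <- 50
  sig <- vapply(seq_len(reps), function(r) {
    d <- sim_po(400, theta = c(-1, 0.5), beta = 0.8, seed = 1000 + r)
    pl <- suppressWarnings(
      test_parallel_lines(fit_ordinal_po(d$X, d$y),
                          fit_multinomial(d$X, d$y)))
    pl$p < 0.05
  }, logical(1))
  expect_gte(mean(!sig), 0.9)
})

test_that("logistic fit reproduces closed-form odds ratios", {
  x <- rep(c(0, 1), each = 30)
  y <- rep(c(1, 0, 1, 0), c(10, 20, 20, 10))
  fit <- fit_logistic(cbind(1, x), y)
  expect_equal(unname(fit$or_[2]), 4, tolerance = 1e-7)
  expect_equal(unname(fit$coef[2]), log(4), tolerance = 1e-7)
  expect_true(all(fit$ci95[, "lower"] < fit$or_ & fit$or_ < fit$ci95[, "upper"]))

  y2 <- rep(c(1, 0, 1, 0), each = 15)
  fit2 <- fit_logistic(cbind(1, x), y2)
  expect_equal(unname(fit2$coef[2]), 0, tolerance = 1e-8)
})

test_that("logistic standard errors match the numerical-Hessian oracle", {
  set.seed(51)
  X <- cbind(1, rnorm(300), rbinom(300, 1, 0.4))
  y <- rbinom(300, 1, plogis(-0.5 + 0.8 * X[, 2] - 0.6 * X[, 3]))
  fit <- fit_logistic(X, y)
  H <- optimHess(fit$coef, oracle_logistic_nll, X = X, y = y)
  se_oracle <- sqrt(diag(solve(H)))
  expect_lt(max(abs(fit$se - se_oracle) / se_oracle), 1e-4)
  o <- optim(rep(0, 3), oracle_logistic_nll, X = X, y = y, method = "BFGS",
             control = list(reltol = 1e-15, maxit = 2000))
  expect_lt(max(abs(fit$coef - o$par) / pmax(abs(o$par), 1)), 1e-6)
})

test_that("separation is reported with the offending predictor", {
  set.seed(61)
  x <- rnorm(100)
  y <- as.numeric(x > 0)
  expect_error(fit_logistic(cbind(`(Intercept)` = 1, sep_var = x), y),
               "separation.*sep_var")
})

test_that("linear fit: exact fit, degenerate outcome, and normal-equations oracle", {
  x <- rnorm(50)
  f1 <- fit_linear(cbind(1, x), 2 * x)
  expect_equal(f1$r2, 1, tolerance = 1e-12)
  expect_equal(unname(f1$coef), c(0, 2), tolerance = 1e-10)

  expect_warning(f0 <- fit_linear(cbind(1, x), rep(3, 50)), "zero variance")
  expect_equal(f0$r2, 0)

  set.seed(71)
  X <- cbind(1, matrix(rnorm(200), 100, 2))
  y <- rnorm(100)
  fit <- fit_linear(X, y)
  beta_oracle <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(fit$coef), as.vector(beta_oracle), tolerance = 1e-10)
  r2_oracle <- 1 - sum((y - X %*% beta_oracle)^2) / sum((y - mean(y))^2)
  expect_equal(fit$r2, r2_oracle, tolerance = 1e-12)
})

test_that("pseudo-R2 formulas: boundary cases and formula oracle", {
  z <- pseudo_r2(-100, -100, 200)
  expect_equal(unlist(z), c(cox_snell = 0, nagelkerke = 0, mcfadden = 0))

  perfect <- pseudo_r2(0, -120, 180)
  expect_equal(perfect$nagelkerke, 1, tolerance = 1e-12)

  fit_ll <- -432.1; null_ll <- -512.7; n <- 800
  z2 <- pseudo_r2(fit_ll, null_ll, n)
  cs <- 1 - exp(2 * (null_ll - fit_ll) / n)
  expect_equal(z2$cox_snell, cs, tolerance = 1e-12)
  expect_equal(z2$nagelkerke, cs / (1 - exp(2 * null_ll / n)),
               tolerance = 1e-12)
  expect_equal(z2$mcfadden, 1 - fit_ll / null_ll, tolerance = 1e-12)
  expect_gte(z2$nagelkerke, z2$cox_snell)
})

test_that("likelihood-ratio test matches the chi-squared survival function", {
  eq <- lr_test(-50, -50, 2)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  t1 <- lr_test(-250.4, -244.15, 3)
  expect_equal(t1$statistic, 2 * (250.4 - 244.15), tolerance = 1e-12)
  expect_equal(t1$p, pchisq(t1$statistic, 3, lower.tail = FALSE),
               tolerance = 1e-15)
  expect_error(lr_test(-50, -49, 0), "df_diff")
})

test_that("log-likelihood is nondecreasing along nested predictor sequences", {
  set.seed(81)
  X <- cbind(1, matrix(rnorm(900), 300, 3))
  y <- 1 + rbinom(300, 2, plogis(0.4 * X[, 2]))
  lls <- vapply(1:4, function(p)
    suppressWarnings(fit_multinomial(X[, seq_len(p), drop = FALSE], y))$loglik,
    numeric(1))
  expect_true(all(diff(lls) >= -1e-8))
  # hence pseudo-R2 nondecreasing along the sequence
  pr <- vapply(lls, function(ll) pseudo_r2(ll, lls[1], 300)$nagelkerke,
               numeric(1))
  expect_true(all(diff(pr) >= -1e-10))
})

test_that("Wald confidence intervals for the logistic OR attain nominal coverage", {
  beta_true <- c(-0.3, 0.7)
  reps <- 1000
  covered <- vapply(seq_len(reps), function(r) {
    set.seed(5000 + r)
    X <- cbind(1, rnorm(500))
    y <- rbinom(500, 1, plogis(X %*% beta_true))
    fit <- fit_logistic(X, y)
    fit$ci95[2, "lower"] <= exp(beta_true[2]) &&
      exp(beta_true[2]) <= fit$ci95[2, "upper"]
  }, logical(1))
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})
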