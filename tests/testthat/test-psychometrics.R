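# Sampling adequacy, PCA with oblimin rotation, item retention, compound
# scores and internal consistency.

test_that("KMO is exactly 0.5 for any two-item battery", {
  set.seed(31)
  x <- rnorm(80)
  items <- cbind(a = x + rnorm(80), b = 0.5 * x + rnorm(80))
  expect_equal(kmo(items), 0.5, tolerance = 1e-12)
})

test_that("KMO matches the explicit partial-correlation oracle for 3 items", {
  R <- matrix(c(1, 0.5, 0.3,
                0.5, 1, 0.4,
                0.3, 0.4, 1), 3, 3)
  X <- exact_cor_data(120, R, seed = 33)
  # oracle: first-order partial correlations r_ij.k written out directly
  pc <- function(rij, rik, rjk) (rij - rik * rjk) /
    sqrt((1 - rik^2) * (1 - rjk^2))
  q12 <- pc(R[1, 2], R[1, 3], R[2, 3])
  q13 <- pc(R[1, 3], R[1, 2], R[3, 2])
  q23 <- pc(R[2, 3], R[2, 1], R[3, 1])
  r2 <- R[1, 2]^2 + R[1, 3]^2 + R[2, 3]^2
  q2 <- q12^2 + q13^2 + q23^2
  expect_equal(kmo(X), r2 / (r2 + q2), tolerance = 1e-10)
})

test_that("a strongly block-structured battery is sampling-adequate", {
  b <- simulate_battery(2000, seed = 35)
  expect_gt(kmo(b$items), 0.7)
  expect_lt(bartlett_sphericity(b$items)$p, 0.01)
})

test_that("Bartlett statistic is 0 on an exact identity correlation", {
  X <- exact_cor_data(100, diag(6), seed = 37)
  bt <- bartlett_sphericity(X)
  expect_equal(bt$statistic, 0, tolerance = 1e-8)
  expect_equal(bt$p, 1, tolerance = 1e-6)
  expect_identical(bt$df, as.integer(6 * 5 / 2))
  # df = p(p-1)/2 for p = 12
  X12 <- exact_cor_data(100, diag(12), seed = 38)
  expect_identical(bartlett_sphericity(X12)$df, 66L)
})

test_that("Bartlett statistic matches the formula oracle on a stated R", {
  R <- matrix(c(1, 0.4, 0.2,
                0.4, 1, 0.5,
                0.2, 0.5, 1), 3, 3)
  X <- exact_cor_data(100, R, seed = 39)
  bt <- bartlett_sphericity(X)
  stat_oracle <- -(100 - 1 - (2 * 3 + 5) / 6) * log(det(R))
  expect_equal(bt$statistic, stat_oracle, tolerance = 1e-10)
  expect_equal(bt$p, pchisq(stat_oracle, 3, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("two independent item blocks are recovered with near-zero phi", {
  set.seed(41)
  n <- 2000
  f1 <- rnorm(n); f2 <- rnorm(n)
  items <- cbind(
    sapply(1:4, function(i) sqrt(0.6) * f1 + sqrt(0.4) * rnorm(n)),
    sapply(1:4, function(i) sqrt(0.6) * f2 + sqrt(0.4) * rnorm(n))
  )
  colnames(items) <- paste0("it", 1:8)
  cm <- suppressWarnings(pca_oblimin(items, retention = "kaiser"))
  expect_identical(cm$k, 2L)
  dominant <- apply(abs(cm$pattern), 1, which.max)
  expect_true(length(unique(dominant[1:4])) == 1)
  expect_true(length(unique(dominant[5:8])) == 1)
  expect_false(dominant[1] == dominant[5])
  expect_lt(max(abs(cm$phi - diag(2))), 0.05)
})

test_that("rotation never worsens the oblimin criterion and structure = pattern * phi", {
  for (seed in c(43, 44, 45)) {
    b <- simulate_battery(800, seed = seed)
    cm <- pca_oblimin(b$items, retention = "fixed_k", k = 3)
    ev <- eigen(cor(b$items), symmetric = TRUE)
    A <- ev$vectors[, 1:3] %*% diag(sqrt(ev$values[1:3]))
    f_unrot <- acpscore:::oblimin_vg(A)$f
    expect_lte(cm$rotation$criterion, f_unrot + 1e-10)
    expect_equal(cm$structure, cm$pattern %*% cm$phi, tolerance = 1e-12)
    expect_equal(diag(cm$phi), c(comp1 = 1, comp2 = 1, comp3 = 1),
                 tolerance = 1e-10)
  }
})

test_that("items are retained iff exactly one loading passes 0.4", {
  pat <- rbind(one = c(0.8, 0.1), cross = c(0.5, 0.45), weak = c(0.3, 0.2),
               neg = c(-0.6, 0.05))
  m <- assign_items(pat)
  expect_equal(m$component, c(1L, NA, NA, 1L))
  expect_equal(m$loading[1], 0.8)
  expect_equal(m$loading[4], -0.6)
  expect_warning(assign_items(rbind(c(0.1, 0.2))), "no item")
})

test_that("compound scores: single item, duplicated item, and z-mean-z oracle", {
  set.seed(47)
  x <- rnorm(60, mean = 5, sd = 2)
  tbl <- data.frame(a = x, b = x, c = rnorm(60))
  map1 <- data.frame(item = "a", component = 1L, loading = 0.9)
  s1 <- compound_scores(tbl, map1)
  expect_equal(unname(s1[, 1]), as.vector(scale(x)), tolerance = 1e-12)

  map2 <- data.frame(item = c("a", "b"), component = 1L, loading = 0.8)
  s2 <- compound_scores(tbl, map2)
  expect_equal(unname(s2[, 1]), as.vector(scale(x)), tolerance = 1e-12)

  map3 <- data.frame(item = c("a", "c"), component = 1L,
                     loading = c(0.7, -0.5))
  s3 <- compound_scores(tbl, map3)
  z <- cbind(scale(tbl$a), -scale(tbl$c))
  oracle <- as.vector(scale(rowMeans(z)))
  expect_equal(unname(s3[, 1]), oracle, tolerance = 1e-12)
  expect_equal(mean(s3[, 1]), 0, tolerance = 1e-12)
  expect_equal(sd(s3[, 1]), 1, tolerance = 1e-12)
})

test_that("Cronbach alpha: closed form for two items, unity for clones, formula oracle", {
  R <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  X <- exact_cor_data(90, R, seed = 49)
  expect_equal(cronbach_alpha(X), 2 * 0.5 / 1.5, tolerance = 1e-10)

  x <- rnorm(40)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1, tolerance = 1e-12)

  set.seed(51)
  Y <- matrix(rnorm(300), 100, 3) %*% matrix(c(1, .3, .3, .3, 1, .3, .3, .3, 1), 3)
  k <- 3
  oracle <- k / (k - 1) * (1 - sum(apply(Y, 2, var)) / var(rowSums(Y)))
  expect_equal(cronbach_alpha(Y), oracle, tolerance = 1e-12)

  # invariance to item rescaling once items are standardized
  Z <- scale(Y)
  expect_equal(cronbach_alpha(Z), cronbach_alpha(Z %*% diag(c(1, 1, 1))),
               tolerance = 1e-12)
  expect_error(cronbach_alpha(cbind(rep(1, 10), rep(2, 10))), "zero total")
})

test_that("variance-explained shares are positive, descending, and bounded", {
  b <- simulate_battery(1500, seed = 53)
  cm <- fit_components(b$items)
  expect_true(all(cm$var_explained > 0))
  expect_true(all(diff(cm$var_explained) <= 0))
  expect_lte(sum(cm$var_explained), 1)
})

test_that("the component pipeline recovers the generating 3-block structure", {
  blocks <- battery_blocks()
  hits <- numeric(0)
  cors <- numeric(0)
  for (seed in 1:5) {
    b <- simulate_battery(5000, seed = 100 + seed)
    cm <- fit_components(b$items)
    expect_identical(cm$k, 3L)
    rm <- cm$retained_map
    # map each component to its dominant generating block
    comp_block <- sapply(1:3, function(j) {
      it <- rm$item[!is.na(rm$component) & rm$component == j]
      as.integer(names(which.max(table(blocks$block[match(it, blocks$item)]))))
    })
    expect_identical(sort(comp_block), 1:3)
    assigned_block <- comp_block[rm$component]
    hits <- c(hits, mean(assigned_block == blocks$block, na.rm = TRUE) *
                mean(!is.na(rm$component)))
    for (j in 1:3) {
      cors <- c(cors, abs(cor(cm$scores[, j], b$factors[, comp_block[j]])))
    }
  }
  expect_gte(mean(hits), 0.95)
  expect_true(all(cors > 0.9))
})
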