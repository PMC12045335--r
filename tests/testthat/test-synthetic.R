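# The synthetic cohort generator: determinism, calibration to the target
# population moments, distribution shape, and recovery of the generative
# parameters.

test_that("configuration validation rejects impossible settings", {
  expect_error(synth_config(p_female = 1.2), "proportions")
  expect_error(synth_config(thresholds = c(1, 1, 2, 3)), "increasing")
  bad <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3, 3)
  expect_error(synth_config(factor_corr = bad), "positive definite")
})

test_that("the same config and seed reproduce the same cohort", {
  cfg <- synth_config(n = 500, seed = 77)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  c3 <- generate_cohort(synth_config(n = 500, seed = 78))
  expect_false(identical(c1$fev1pct_pred, c3$fev1pct_pred))
})

test_that("generated physiology matches the target population moments", {
  cohort <- generate_cohort(synth_config(n = 50000, seed = 101))
  ctrl <- cohort[!cohort$asthma_copd, ]
  expect_lt(abs(mean(ctrl$fev1pct_pred) - 96.7), 0.2)
  expect_lt(abs(sd(ctrl$fev1pct_pred) - 12.2), 0.2)
  ac <- cohort[cohort$asthma_copd, ]
  expect_lt(abs(mean(ac$fev1pct_pred) - 85.3), 0.5)
  expect_lt(abs(mean(cohort$asthma_copd) - 0.121), 0.01)
  expect_lt(abs(mean(cohort$sex == "female") - 0.59), 0.01)
  expect_lt(abs(mean(ctrl$bmi) - 25.8), 0.15)
})

test_that("the dyspnea item is right-skewed with the target presence rate", {
  cohort <- generate_cohort(synth_config(n = 50000, seed = 103))
  shares <- prop.table(table(cohort$scl_dyspnea))
  expect_gt(shares[["1"]], 0.5)                      # majority report none
  expect_true(all(diff(as.numeric(shares)) < 0))     # monotone tail
  present <- mean(dichotomize_dyspnea(cohort$scl_dyspnea))
  expect_lt(abs(present - 0.096), 0.03)
  ctrl_present <- mean(dichotomize_dyspnea(
    cohort$scl_dyspnea[!cohort$asthma_copd]))
  expect_lt(abs(ctrl_present - 0.071), 0.03)
})

test_that("cohort table invariants hold on every generated table", {
  for (seed in c(105, 106)) {
    cohort <- generate_cohort(synth_config(n = 2000, seed = seed))
    expect_true(all(cohort$scl_dyspnea %in% 1:5))
    expect_true(all(cohort$dyspnea_sumscore %in% 0:5))
    expect_true(all(cohort$scl_som_sumscore >= 12 &
                      cohort$scl_som_sumscore <= 60))
    expect_true(all(cohort$fev1pct_pred >= 16 & cohort$fev1pct_pred <= 225))
    expect_true(all(cohort$weight_kg > 0))
    expect_true(all(cohort$education %in% c("low", "medium", "high")))
    expect_true(all(vapply(battery_blocks()$item,
                           function(cl) cl %in% names(cohort), logical(1))))
  }
})

test_that("true_params returns the exact generative values", {
  cfg <- synth_config(physio_coefs = c(fev1 = 0.4, weight = 0.2), seed = 9)
  tp <- true_params(cfg)
  expect_identical(tp$physio_coefs, c(fev1 = 0.4, weight = 0.2))
  expect_identical(tp$thresholds, cfg$thresholds)
  expect_identical(tp$distortion_weights, cfg$distortion_weights)
})

test_that("the fitted multinomial recovers the implied probability surface", {
  cfg <- synth_config(n = 20000,
                      distortion_weights = c(na = 0, fear = 0, worry = 0),
                      p_asthma_copd = 0, group_offset = 0,
                      physio_coefs = c(fev1 = 0.6, weight = 0.25),
                      exclusion_rates = c(cvd = 0, gad = 0, pd = 0,
                                          invalid_spirometry = 0),
                      seed = 109)
  cohort <- generate_cohort(cfg)
  X <- acpscore:::build_design(cohort, c("fev1pct_pred", "weight_kg"))
  fit <- suppressWarnings(fit_multinomial(X, cohort$scl_dyspnea))
  grid_fev1 <- seq(75, 115, by = 10)
  grid_wt <- seq(60, 95, by = 10)
  grid <- expand.grid(fev1 = grid_fev1, wt = grid_wt)
  Pg <- predict_category_probs(fit, cbind(1, grid$fev1, grid$wt))
  Pt <- true_category_probs(cfg, grid$fev1, grid$wt)
  expect_lt(max(abs(Pg[, seq_len(ncol(Pt))] - Pt)), 0.02)
})

test_that("stronger distortion lowers the accuracy of the physiology-only model", {
  meds <- vapply(c(0, 0.6, 1.5), function(w) {
    cfg <- synth_config(n = 8000,
                        distortion_weights = c(na = w, fear = w, worry = w),
                        exclusion_rates = c(cvd = 0, gad = 0, pd = 0,
                                            invalid_spirometry = 0),
                        seed = 111)
    cohort <- generate_cohort(cfg)
    ctrl <- cohort[!cohort$asthma_copd, ]
    X <- acpscore:::build_design(ctrl, c("fev1pct_pred", "weight_kg"))
    fit <- suppressWarnings(fit_multinomial(X, ctrl$scl_dyspnea))
    median(compute_acp(fit, X, ctrl$scl_dyspnea))
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("the non-parallel switch produces detectable parallel-lines failure", {
  cfg <- synth_config(n = 20000, nonparallel_fev1 = 0.35, seed = 113,
                      exclusion_rates = c(cvd = 0, gad = 0, pd = 0,
                                          invalid_spirometry = 0))
  cohort <- generate_cohort(cfg)
  ctrl <- cohort[!cohort$asthma_copd, ]
  X <- acpscore:::build_design(ctrl, c("fev1pct_pred", "weight_kg"))
  pl <- suppressWarnings(test_parallel_lines(
    fit_ordinal_po(X, ctrl$scl_dyspnea),
    fit_multinomial(X, ctrl$scl_dyspnea)))
  expect_lt(pl$p, 0.05)
})
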