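# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: physiology calibrated to published cohort moments, a
# 3-factor psychosocial item battery, and an ordinal dyspnea report whose
# dependence on physiology can be distorted by the latent psychosocial
# factors. The report propensity follows a cumulative-logit latent-variable
# model, so the proportional-odds assumption holds by construction unless
# the non-parallel switch is turned on.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: 59% female,
#' 12.1% asthma/COPD prevalence, FEV1%pred 96.7 (SD 12.2) in controls and
#' 85.3 (SD 14.3) in asthma/COPD, BMI 25.8 (4.24) and 26.7 (4.93), and
#' dyspnea-report thresholds calibrated so that about 7.1% of controls and
#' 27.8% of the asthma/COPD group (9.6% overall) report dyspnea (score >= 2
#' on the 5-level item). The physiology coefficients are deliberately weak
#' (physiology explains only a few percent of report variance in general
#' population cohorts) while the asthma/COPD report offset carries the
#' diagnosed group's excess symptom reporting.
#'
#' @param n number of participants.
#' @param p_female,p_asthma_copd,p_unconfirmed_asthma marginal proportions.
#' @param age_mean,age_sd age distribution (years).
#' @param fev1_params,bmi_params per-group `c(mean, sd)` lists with elements
#'   `control` and `asthma_copd`.
#' @param height_params sex-specific `c(mean, sd)` in meters.
#' @param factor_corr 3x3 latent factor correlation matrix (negative affect,
#'   fear of illness, worry of contracting disease); must be positive
#'   definite with unit diagonal.
#' @param loadings per-block item loadings on the latent factors; see
#'   [battery_blocks()]. Values span 0.6-0.8.
#' @param whitely_prevalence endorsement probability used to binarize the
#'   Whitely-like items.
#' @param physio_coefs effect of the standardized physiological predictors
#'   `c(fev1, weight)` on the report propensity; the FEV1 coefficient
#'   applies to the *negative* z-score (worse lung function, more dyspnea).
#' @param distortion_weights per-factor contribution of the latent
#'   psychosocial factors to the report propensity; zero weights make the
#'   report a function of physiology and noise only.
#' @param group_offset additive propensity shift for asthma/COPD
#'   participants.
#' @param thresholds 4 strictly increasing cut-points mapping the latent
#'   propensity to the 5-level dyspnea item.
#' @param nonparallel_fev1 threshold-varying FEV1 effect; non-zero values
#'   break the proportional-odds assumption by construction.
#' @param fev1_ref,weight_ref fixed `c(mean, sd)` standardization constants
#'   (control-population reference).
#' @param sum_item_coef,sum_item_cuts dyspnea sumscore generation: 5 binary
#'   items thresholding `sum_item_coef * propensity` plus logistic noise.
#' @param som_coef,som_na_weight,som_cuts somatization sumscore generation:
#'   12 ordinal 1-5 items driven by a mix of the report propensity and the
#'   negative-affect factor.
#' @param exclusion_rates prevalence of the exclusion flags
#'   (`cvd`, `gad`, `pd`, `invalid_spirometry`).
#' @param p_smoking,education_probs covariate distributions.
#' @param seed RNG seed; all randomness flows from it.
#' @return a `synth_config` list, validated.
#' @export
synth_config <- function(n = 10000,
                         p_female = 0.59,
                         p_asthma_copd = 0.121,
                         p_unconfirmed_asthma = 0.004,
                         age_mean = 42.3, age_sd = 11.0,
                         fev1_params = list(control = c(mean = 96.7, sd = 12.2),
                                            asthma_copd = c(mean = 85.3, sd = 14.3)),
                         bmi_params = list(control = c(mean = 25.8, sd = 4.24),
                                           asthma_copd = c(mean = 26.7, sd = 4.93)),
                         height_params = list(male = c(mean = 1.81, sd = 0.07),
                                              female = c(mean = 1.68, sd = 0.065)),
                         factor_corr = matrix(c(1, 0.3, 0.2,
                                                0.3, 1, 0.25,
                                                0.2, 0.25, 1), 3, 3),
                         loadings = NULL,
                         whitely_prevalence = 0.3,
                         physio_coefs = c(fev1 = 0.25, weight = 0.10),
                         distortion_weights = c(na = 0.5, fear = 0.5, worry = 0.4),
                         group_offset = 1.58,
                         thresholds = c(3.00, 4.15, 5.22, 6.32),
                         nonparallel_fev1 = 0,
                         fev1_ref = c(mean = 96.7, sd = 12.2),
                         weight_ref = c(mean = 77.7, sd = 15.3),
                         sum_item_coef = 0.5,
                         sum_item_cuts = c(2.5, 3.0, 3.5, 4.0, 4.5),
                         som_coef = 0.25,
                         som_na_weight = 0.15,
                         som_cuts = c(1.75, 3.0, 4.2, 5.3),
                         exclusion_rates = c(cvd = 0.088, gad = 0.042,
                                             pd = 0.002,
                                             invalid_spirometry = 0.296),
                         p_smoking = 0.215,
                         education_probs = c(low = 0.28, medium = 0.41,
                                             high = 0.31),
                         seed = 1L) {
  if (is.null(loadings)) loadings <- default_loadings()
  cfg <- list(
    n = as.integer(n), p_female = p_female, p_asthma_copd = p_asthma_copd,
    p_unconfirmed_asthma = p_unconfirmed_asthma,
    age_mean = age_mean, age_sd = age_sd,
    fev1_params = fev1_params, bmi_params = bmi_params,
    height_params = height_params, factor_corr = factor_corr,
    loadings = loadings, whitely_prevalence = whitely_prevalence,
    physio_coefs = physio_coefs, distortion_weights = distortion_weights,
    group_offset = group_offset, thresholds = thresholds,
    nonparallel_fev1 = nonparallel_fev1,
    fev1_ref = fev1_ref, weight_ref = weight_ref,
    sum_item_coef = sum_item_coef, sum_item_cuts = sum_item_cuts,
    som_coef = som_coef, som_na_weight = som_na_weight, som_cuts = som_cuts,
    exclusion_rates = exclusion_rates, p_smoking = p_smoking,
    education_probs = education_probs, seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  props <- c(cfg$p_female, cfg$p_asthma_copd, cfg$p_unconfirmed_asthma,
             cfg$whitely_prevalence, cfg$exclusion_rates, cfg$p_smoking,
             cfg$education_probs)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]",
                                       call. = FALSE)
  if (any(diff(cfg$thresholds) <= 0)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  fc <- cfg$factor_corr
  if (!isTRUE(all.equal(fc, t(fc))) || any(diag(fc) != 1) ||
      any(eigen(fc, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("factor_corr must be symmetric positive definite with unit diagonal",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Psychosocial battery layout
#'
#' The default battery matches the study's stated PCA inputs in count and
#' type: 6 NEO-neuroticism-facet-like sums and 10 PANAS-NA-like items
#' loading on the negative-affect factor; 14 binary Whitely-like items, the
#' first 10 loading on the fear-of-illness factor and the last 4 on the
#' worry factor; and 2 stressor sums (life events, long-term difficulties)
#' loading on the worry factor.
#'
#' @return data frame with `item`, `block` (factor index 1-3) and `type`
#'   (`continuous` or `binary`).
#' @export
battery_blocks <- function() {
  data.frame(
    item = c(paste0("neo_", c("anx", "host", "dep", "selfc", "imp", "vuln")),
             paste0("panas_na_", 1:10),
             paste0("whitely_", 1:14),
             "lte_sum", "ltd_sum"),
    block = c(rep(1L, 16), rep(2L, 10), rep(3L, 4), rep(3L, 2)),
    type = c(rep("continuous", 16), rep("binary", 14),
             rep("continuous", 2)),
    stringsAsFactors = FALSE
  )
}

# Fixed, evenly spaced loadings spanning 0.6-0.8 within each block.
default_loadings <- function() {
  blocks <- battery_blocks()
  unsplit(lapply(split(seq_len(nrow(blocks)), blocks$block), function(idx) {
    seq(0.6, 0.8, length.out = length(idx))
  }), blocks$block)
}

#' Simulate a clean 3-factor item battery
#'
#' Continuous standardized items generated as
#' `loading * factor + sqrt(1 - loading^2) * noise` from correlated latent
#' factors — the idealized version of the psychosocial battery used for
#' structure-recovery checks of the component pipeline.
#'
#' @param n sample size.
#' @param blocks item-to-factor map (default [battery_blocks()]).
#' @param loadings per-item loadings (default evenly spaced 0.6-0.8 per
#'   block).
#' @param factor_corr latent factor correlation matrix.
#' @param seed RNG seed.
#' @return list with `items` (n x p matrix), `factors` (n x 3), `blocks`,
#'   `loadings`.
#' @export
simulate_battery <- function(n, blocks = battery_blocks(),
                             loadings = default_loadings(),
                             factor_corr = matrix(c(1, 0.3, 0.2,
                                                    0.3, 1, 0.25,
                                                    0.2, 0.25, 1), 3, 3),
                             seed = 1L) {
  set.seed(seed)
  k <- max(blocks$block)
  Fm <- matrix(stats::rnorm(n * k), n, k) %*% chol(factor_corr)
  colnames(Fm) <- c("na", "fear", "worry")[seq_len(k)]
  p <- nrow(blocks)
  E <- matrix(stats::rnorm(n * p), n, p)
  items <- sapply(seq_len(p), function(j) {
    lam <- loadings[j]
    lam * Fm[, blocks$block[j]] + sqrt(1 - lam^2) * E[, j]
  })
  colnames(items) <- blocks$item
  list(items = items, factors = Fm, blocks = blocks, loadings = loadings)
}

#' Generate a synthetic cohort table
#'
#' Draws disease group, sex and physiology; three correlated latent
#' psychosocial factors and the item battery; the ordinal dyspnea report
#' from a cumulative-logit latent propensity combining standardized
#' physiology, the latent factors (weighted by the distortion weights) and
#' the asthma/COPD report offset; the dyspnea and somatization sumscores as
#' monotone noisy transforms of the same propensity; and the exclusion
#' flags at their configured rates.
#'
#' The returned data frame carries the latent factors and the noiseless
#' report propensity in the attribute `"latents"` for recovery testing;
#' these are not part of the cohort table proper and are dropped on write.
#'
#' @param config a [synth_config()].
#' @return a cohort data frame (one row per participant).
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  set.seed(config$seed)
  n <- config$n

  sex <- ifelse(stats::runif(n) < config$p_female, "female", "male")
  asthma_copd <- stats::runif(n) < config$p_asthma_copd
  self_reported_asthma <- asthma_copd |
    (!asthma_copd & stats::runif(n) < config$p_unconfirmed_asthma)
  physician_confirmed_asthma <- asthma_copd
  age <- round(truncnorm(n, config$age_mean, config$age_sd, 18, 95), 1)

  grp <- ifelse(asthma_copd, "asthma_copd", "control")
  fev1 <- numeric(n); bmi <- numeric(n)
  for (g in c("control", "asthma_copd")) {
    idx <- grp == g
    fp <- config$fev1_params[[g]]; bp <- config$bmi_params[[g]]
    fev1[idx] <- truncnorm(sum(idx), fp[["mean"]], fp[["sd"]], 16, 225)
    bmi[idx] <- truncnorm(sum(idx), bp[["mean"]], bp[["sd"]], 14, 60)
  }
  height <- numeric(n)
  for (s in c("male", "female")) {
    idx <- sex == s
    hp <- config$height_params[[s]]
    height[idx] <- truncnorm(sum(idx), hp[["mean"]], hp[["sd"]], 1.4, 2.2)
  }
  weight <- round(bmi * height^2, 1)

  # latent psychosocial factors and battery
  k <- ncol(config$factor_corr)
  Fm <- matrix(stats::rnorm(n * k), n, k) %*% chol(config$factor_corr)
  colnames(Fm) <- c("na", "fear", "worry")
  blocks <- battery_blocks()
  p <- nrow(blocks)
  E <- matrix(stats::rnorm(n * p), n, p)
  zitems <- sapply(seq_len(p), function(j) {
    lam <- config$loadings[j]
    lam * Fm[, blocks$block[j]] + sqrt(1 - lam^2) * E[, j]
  })
  battery <- as.data.frame(lapply(seq_len(p), function(j) {
    z <- zitems[, j]
    it <- blocks$item[j]
    if (blocks$type[j] == "binary") {
      as.integer(z > stats::qnorm(1 - config$whitely_prevalence))
    } else if (grepl("^neo_", it)) {
      pmin(pmax(round(24 + 6 * z), 8), 40)        # facet sums, 8 items 1-5
    } else if (grepl("^panas_", it)) {
      pmin(pmax(round(2 + 0.8 * z), 1), 5)        # single 1-5 items
    } else if (it == "lte_sum") {
      pmin(pmax(round(2 + 1.8 * z), 0), 12)       # event count 0-12
    } else {
      pmin(pmax(round(4 + 3 * z), 0), 24)         # difficulty sum 0-24
    }
  }))
  names(battery) <- blocks$item

  # report propensity (noiseless core) and the ordinal dyspnea item
  zf <- (fev1 - config$fev1_ref[["mean"]]) / config$fev1_ref[["sd"]]
  zw <- (weight - config$weight_ref[["mean"]]) / config$weight_ref[["sd"]]
  eta <- config$physio_coefs[["fev1"]] * (-zf) +
    config$physio_coefs[["weight"]] * zw +
    as.vector(Fm %*% config$distortion_weights) +
    config$group_offset * asthma_copd
  eps <- stats::rlogis(n)
  th <- config$thresholds
  # optional threshold-varying FEV1 effect breaking proportional odds
  np <- config$nonparallel_fev1 * seq(-1.5, 1.5, length.out = length(th))
  scl_dyspnea <- 1L + rowSums(outer(eta + eps, seq_along(th),
                                    function(e, j) e > th[j] - np[j] * zf))

  # dyspnea sumscore: 5 binary items off the same propensity
  dysp_sum <- rowSums(sapply(config$sum_item_cuts, function(cut) {
    config$sum_item_coef * eta + stats::rlogis(n) > cut
  }))

  # somatization sumscore: 12 ordinal 1-5 items with extra NA loading
  eta_som <- config$som_coef * eta + config$som_na_weight * Fm[, "na"]
  som_items <- sapply(seq_len(12), function(j) {
    1L + rowSums(sapply(config$som_cuts, function(cut) {
      eta_som + stats::rlogis(n) > cut
    }))
  })
  som_sum <- rowSums(som_items)

  ex <- config$exclusion_rates
  cohort <- data.frame(
    id = seq_len(n),
    sex = sex,
    age = age,
    asthma_copd = asthma_copd,
    self_reported_asthma = self_reported_asthma,
    physician_confirmed_asthma = physician_confirmed_asthma,
    cvd = stats::runif(n) < ex[["cvd"]],
    gad = stats::runif(n) < ex[["gad"]],
    pd = stats::runif(n) < ex[["pd"]],
    spirometry_valid = stats::runif(n) >= ex[["invalid_spirometry"]],
    fev1pct_pred = round(fev1, 1),
    weight_kg = weight,
    bmi = round(bmi, 1),
    smoking = stats::runif(n) < config$p_smoking,
    education = sample(names(config$education_probs), n, replace = TRUE,
                       prob = config$education_probs),
    scl_dyspnea = as.integer(scl_dyspnea),
    dyspnea_sumscore = as.integer(dysp_sum),
    scl_som_sumscore = as.integer(som_sum),
    stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, battery)
  attr(cohort, "latents") <- data.frame(Fm, propensity = eta)
  cohort
}

truncnorm <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Ground-truth generative parameters
#'
#' Returns the exact coefficients, thresholds, loadings and block map used
#' by [generate_cohort()] under a given configuration, for
#' parameter-recovery assertions.
#'
#' @param config a [synth_config()].
#' @return list with `physio_coefs`, `distortion_weights`, `group_offset`,
#'   `thresholds`, `factor_corr`, `loadings`, `blocks`, `fev1_ref`,
#'   `weight_ref`.
#' @export
true_params <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  list(physio_coefs = config$physio_coefs,
       distortion_weights = config$distortion_weights,
       group_offset = config$group_offset,
       thresholds = config$thresholds,
       factor_corr = config$factor_corr,
       loadings = config$loadings,
       blocks = battery_blocks(),
       fev1_ref = config$fev1_ref,
       weight_ref = config$weight_ref)
}

#' Analytic category probabilities implied by the generator
#'
#' For zero distortion weights the ordinal dyspnea report given physiology
#' follows the cumulative-logit model exactly; this evaluates the implied
#' `P(Y = k | fev1, weight, group)` surface, the oracle for
#' parameter-recovery checks of the fitted multinomial model.
#'
#' @param config a [synth_config()] (distortion weights must be zero for
#'   the surface to be the exact conditional law).
#' @param fev1,weight physiological values (recycled).
#' @param group `"control"` or `"asthma_copd"`.
#' @return matrix of category probabilities, one row per input, columns
#'   `1:5`.
#' @export
true_category_probs <- function(config, fev1, weight, group = "control") {
  zf <- (fev1 - config$fev1_ref[["mean"]]) / config$fev1_ref[["sd"]]
  zw <- (weight - config$weight_ref[["mean"]]) / config$weight_ref[["sd"]]
  eta <- config$physio_coefs[["fev1"]] * (-zf) +
    config$physio_coefs[["weight"]] * zw +
    config$group_offset * (group == "asthma_copd")
  cum <- vapply(config$thresholds, function(t) stats::plogis(t - eta),
                numeric(length(eta)))
  cum <- cbind(cum, 1)
  P <- cbind(cum[, 1, drop = FALSE], t(apply(cum, 1, diff)))
  colnames(P) <- as.character(seq_len(ncol(P)))
  P
}
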