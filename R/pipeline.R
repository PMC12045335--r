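# Cohort analysis pipeline: exclusion filters, descriptives, ACP
# construction, association models and the cumulative explained-variance
# decomposition, stratified by disease group (and optionally sex).

#' Apply the study's exclusion rules
#'
#' Removes participants with cardiovascular disease, generalized anxiety
#' disorder or panic disorder (conditions that present with dyspnea without
#' a straightforward spirometric correlate), participants whose
#' self-reported asthma lacks physician confirmation, and — for
#' spirometry-dependent steps — participants without technically valid
#' spirometry. Each removed row is counted once, under the first rule that
#' claims it.
#'
#' @param table cohort data frame.
#' @param require_spirometry drop rows with invalid spirometry (use `FALSE`
#'   for questionnaire-only descriptives).
#' @return list with `cohort` (filtered data frame) and `log` (data frame of
#'   `reason`, `n_removed`, plus `rows_in` / `rows_out` attributes mirrored
#'   in rows `input` and `retained`).
#' @export
filter_cohort <- function(table, require_spirometry = TRUE) {
  flags <- c("cvd", "gad", "pd")
  if (require_spirometry) flags <- c(flags, "spirometry_valid")
  needed <- c(flags, "self_reported_asthma", "physician_confirmed_asthma")
  miss <- setdiff(needed, names(table))
  if (length(miss)) {
    stop("missing flag column: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  n_in <- nrow(table)
  claimed <- rep(FALSE, n_in)
  log <- data.frame(reason = character(0), n_removed = integer(0))
  add <- function(log, reason, hit) {
    new_hit <- hit & !claimed
    claimed <<- claimed | hit
    rbind(log, data.frame(reason = reason, n_removed = sum(new_hit)))
  }
  log <- add(log, "cvd", isTRUE_vec(table$cvd))
  log <- add(log, "gad", isTRUE_vec(table$gad))
  log <- add(log, "pd", isTRUE_vec(table$pd))
  log <- add(log, "unconfirmed_asthma",
             isTRUE_vec(table$self_reported_asthma) &
               !isTRUE_vec(table$physician_confirmed_asthma))
  if (require_spirometry) {
    log <- add(log, "invalid_spirometry", !isTRUE_vec(table$spirometry_valid))
  }
  out <- table[!claimed, , drop = FALSE]
  log <- rbind(log,
               data.frame(reason = "input", n_removed = n_in),
               data.frame(reason = "retained", n_removed = nrow(out)))
  list(cohort = out, log = log)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Dichotomize the 5-level dyspnea item
#'
#' Presence of dyspnea is a score of 2 or more on the 5-level item
#' ("at least a little bit" of bother).
#'
#' @param scl_dyspnea integer vector with values in 1-5.
#' @return integer 0/1 presence flag (NA preserved).
#' @export
dichotomize_dyspnea <- function(scl_dyspnea) {
  bad <- which(!is.na(scl_dyspnea) &
                 (scl_dyspnea < 1 | scl_dyspnea > 5 |
                    scl_dyspnea != round(scl_dyspnea)))
  if (length(bad)) {
    stop("scl_dyspnea out of range 1-5 at row ", bad[1], call. = FALSE)
  }
  as.integer(scl_dyspnea >= 2)
}

#' Descriptive statistics by disease stratum
#'
#' Counts and percentages for categorical columns, mean (SD) for
#' approximately normal columns, median (IQR bounds) for skewed ones,
#' stratified into control and asthma/COPD columns.
#'
#' @param table cohort data frame (post-exclusion).
#' @return long data frame with `variable`, `stat`, `control`,
#'   `asthma_copd`.
#' @export
describe_cohort <- function(table) {
  if (nrow(table) == 0) stop("empty cohort", call. = FALSE)
  strata <- list(control = table[!table$asthma_copd, , drop = FALSE],
                 asthma_copd = table[table$asthma_copd, , drop = FALSE])
  rows <- list()
  push <- function(variable, stat, fn) {
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, stat = stat,
      control = fn(strata$control), asthma_copd = fn(strata$asthma_copd))
  }
  push("n", "count", nrow)
  push("female", "pct", function(d) 100 * mean(d$sex == "female", na.rm = TRUE))
  push("age", "mean", function(d) mean(d$age, na.rm = TRUE))
  push("age", "sd", function(d) stats::sd(d$age, na.rm = TRUE))
  for (lev in c("low", "medium", "high")) {
    push(paste0("education_", lev), "pct",
         function(d) 100 * mean(d$education == lev, na.rm = TRUE))
  }
  if ("bmi" %in% names(table)) {
    push("bmi", "mean", function(d) mean(d$bmi, na.rm = TRUE))
    push("bmi", "sd", function(d) stats::sd(d$bmi, na.rm = TRUE))
  }
  push("smoking", "pct", function(d) 100 * mean(isTRUE_vec(d$smoking)))
  push("dyspnea_present", "pct", function(d)
    100 * mean(dichotomize_dyspnea(d$scl_dyspnea), na.rm = TRUE))
  push("scl_som_sumscore", "mean", function(d)
    mean(d$scl_som_sumscore, na.rm = TRUE))
  push("scl_som_sumscore", "sd", function(d)
    stats::sd(d$scl_som_sumscore, na.rm = TRUE))
  spiro <- function(d) d[isTRUE_vec(d$spirometry_valid), , drop = FALSE]
  push("spirometry_valid", "pct", function(d)
    100 * mean(isTRUE_vec(d$spirometry_valid)))
  push("fev1pct_pred", "mean", function(d)
    mean(spiro(d)$fev1pct_pred, na.rm = TRUE))
  push("fev1pct_pred", "sd", function(d)
    stats::sd(spiro(d)$fev1pct_pred, na.rm = TRUE))
  push("weight_kg", "median", function(d)
    stats::median(d$weight_kg, na.rm = TRUE))
  do.call(rbind, rows)
}

#' Construct the symptom-perception accuracy measure
#'
#' Per stratum (disease group, optionally crossed with sex): fits the
#' proportional-odds model of the 5-level dyspnea item on FEV1%pred and
#' body weight, tests the parallel-lines assumption (a failed test is the
#' justification for the multinomial alternative), fits the unrestricted
#' multinomial model, computes every participant's actual category
#' probability, and performs the within-stratum median split.
#'
#' @param table filtered cohort with valid spirometry (rows with
#'   `spirometry_valid == FALSE` are dropped with a message).
#' @param stratify `"group"` (control vs asthma/COPD) or `"group-sex"`.
#' @param predictors physiological predictor columns.
#' @param ref_category baseline dyspnea level for the multinomial model.
#' @return object of class `acp_measure`: `scores` (data frame `id`,
#'   `stratum`, `acp`, `stratum_median`, `high_flag`), `strata` (per-stratum
#'   fits and parallel-lines tests), `summaries` (per-stratum
#'   [acp_summary()]), `stratify`.
#' @export
build_accuracy_measure <- function(table,
                                   stratify = c("group", "group-sex"),
                                   predictors = c("fev1pct_pred", "weight_kg"),
                                   ref_category = NULL) {
  stratify <- match.arg(stratify)
  if ("spirometry_valid" %in% names(table)) {
    drop_n <- sum(!isTRUE_vec(table$spirometry_valid))
    if (drop_n > 0) {
      message("build_accuracy_measure: dropping ", drop_n,
              " rows without valid spirometry")
      table <- table[isTRUE_vec(table$spirometry_valid), , drop = FALSE]
    }
  }
  grp <- ifelse(table$asthma_copd, "asthma_copd", "control")
  stratum <- if (stratify == "group-sex") paste(grp, table$sex, sep = ".")
             else grp
  strata_out <- list()
  score_rows <- list()
  for (s in unique(stratum)) {
    sub <- table[stratum == s, , drop = FALSE]
    lev_n <- table(sub$scl_dyspnea)
    if (length(lev_n) < 5) {
      warning("stratum '", s, "': only ", length(lev_n),
              " dyspnea levels observed; fitting on observed levels",
              call. = FALSE)
    }
    X <- build_design(sub, predictors)
    ord <- fit_ordinal_po(X, sub$scl_dyspnea)
    mnl <- fit_multinomial(X, sub$scl_dyspnea, ref_category = ref_category)
    pl <- test_parallel_lines(ord, mnl)
    acp <- compute_acp(mnl, X, sub$scl_dyspnea)
    strata_out[[s]] <- list(ordinal = ord, multinomial = mnl,
                            parallel_lines = pl, n = nrow(sub))
    score_rows[[s]] <- data.frame(id = sub$id, stratum = s, acp = acp)
  }
  scores <- do.call(rbind, score_rows)
  rownames(scores) <- NULL
  split_df <- median_split(scores$acp, scores$stratum)
  scores$stratum_median <- split_df$stratum_median
  scores$high_flag <- split_df$high_flag
  summaries <- lapply(split(scores$acp, scores$stratum), acp_summary)
  structure(list(scores = scores, strata = strata_out,
                 summaries = summaries, stratify = stratify),
            class = "acp_measure")
}

#' @export
print.acp_measure <- function(x, ...) {
  cat("ACP measure (", x$stratify, "-stratified)\n", sep = "")
  for (s in names(x$summaries)) {
    sm <- x$summaries[[s]]
    pl <- x$strata[[s]]$parallel_lines
    cat(sprintf("  %s: n = %d, median ACP = %.3f (IQR %.3f-%.3f), %.1f%% <= 0.5; parallel-lines chi2(%d) = %.1f, p = %.3g\n",
                s, sm$n, sm$median, sm$iqr[1], sm$iqr[2],
                100 * sm$frac_at_or_below_half, pl$df, pl$statistic, pl$p))
  }
  invisible(x)
}

#' Associate the dichotomized ACP with psychosocial compound scores
#'
#' Binary logistic models of the high-accuracy flag on sex and the compound
#' scores, fitted per disease stratum; optionally with sex-by-score
#' interaction terms or stratified by sex.
#'
#' @param data cohort rows joined with `high_flag`, `stratum` and the
#'   compound-score columns.
#' @param score_cols names of the compound-score columns.
#' @param interactions add `sex x score` interaction terms.
#' @param sex_stratified fit separately per sex (drops the sex main
#'   effect).
#' @return data frame: `stratum`, `term`, `or`, `ci_lower`, `ci_upper`,
#'   `p`, `n`.
#' @export
associate_acp <- function(data, score_cols, interactions = FALSE,
                          sex_stratified = FALSE) {
  stopifnot(all(c("high_flag", "stratum") %in% names(data)),
            all(score_cols %in% names(data)))
  groups <- if (sex_stratified) {
    split(data, list(data$stratum, data$sex), drop = TRUE)
  } else {
    split(data, data$stratum)
  }
  out <- lapply(names(groups), function(g) {
    sub <- groups[[g]]
    sub$sex_male <- as.numeric(sub$sex == "male")
    use_sex <- !sex_stratified && length(unique(sub$sex_male)) > 1
    preds <- c(if (use_sex) "sex_male", score_cols)
    X <- build_design(sub, preds)
    if (interactions && use_sex) {
      for (sc in score_cols) {
        X <- cbind(X, sub$sex_male * sub[[sc]])
        colnames(X)[ncol(X)] <- paste0("sex_male:", sc)
      }
    }
    fit <- fit_logistic(X, sub$high_flag)
    data.frame(stratum = g, term = names(fit$coef), or = fit$or_,
               ci_lower = fit$ci95[, "lower"], ci_upper = fit$ci95[, "upper"],
               p = fit$p_value, n = fit$n_obs, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Cumulative explained-variance decomposition
#'
#' For each disease stratum by sex cell, fits four nested models per
#' outcome — physiology + smoking, then cumulatively adding the three
#' compound scores — and reports the explained variance at each step:
#' Nagelkerke pseudo-R2 for the multinomial 5-level dyspnea item, ordinary
#' R2 for the dyspnea and somatization sumscores, with a likelihood-ratio
#' p-value for every addition.
#'
#' @param data cohort rows (valid spirometry) with the compound-score
#'   columns attached.
#' @param score_cols compound-score columns, in addition order (negative
#'   affect, fear of illness, worry of contracting disease).
#' @param base_predictors step-1 predictors.
#' @return data frame: `stratum`, `sex`, `model`, `step`, `label`,
#'   `r2_metric`, `value`, `lr_p`, `n`.
#' @export
variance_decomposition <- function(data, score_cols,
                                   base_predictors = c("fev1pct_pred",
                                                       "weight_kg",
                                                       "smoking")) {
  stopifnot(all(score_cols %in% names(data)))
  outcomes <- list(
    scl_item = list(col = "scl_dyspnea", kind = "multinomial"),
    dyspnea_sum = list(col = "dyspnea_sumscore", kind = "linear"),
    som_sum = list(col = "scl_som_sumscore", kind = "linear")
  )
  labels <- c("physiology+smoking", paste0("+", score_cols))
  grp <- ifelse(data$asthma_copd, "asthma_copd", "control")
  rows <- list()
  for (st in unique(grp)) for (sx in unique(data$sex)) {
    sub <- data[grp == st & data$sex == sx, , drop = FALSE]
    if (nrow(sub) < 50) next
    sub$smoking <- as.numeric(isTRUE_vec(sub$smoking))
    for (m in names(outcomes)) {
      oc <- outcomes[[m]]
      y <- sub[[oc$col]]
      prev_ll <- NULL; prev_np <- NULL
      for (step in 1:4) {
        preds <- c(base_predictors, score_cols[seq_len(step - 1)])
        X <- build_design(sub, preds)
        if (oc$kind == "multinomial") {
          fit <- fit_multinomial(X, y)
          K <- length(fit$categories)
          null_fit <- fit_multinomial(X[, 1, drop = FALSE], y)
          val <- pseudo_r2(fit$loglik, null_fit$loglik, fit$n_obs)$nagelkerke
          ll <- fit$loglik; np <- (K - 1) * ncol(X)
        } else {
          fit <- fit_linear(X, y)
          val <- fit$r2
          ll <- fit$loglik; np <- ncol(X)
        }
        lr_p <- if (step == 1) NA_real_ else
          lr_test(prev_ll, ll, np - prev_np)$p
        prev_ll <- ll; prev_np <- np
        rows[[length(rows) + 1]] <- data.frame(
          stratum = st, sex = sx, model = m, step = step,
          label = labels[step],
          r2_metric = if (oc$kind == "multinomial") "pseudo" else "linear",
          value = val, lr_p = lr_p, n = nrow(sub))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Label components by their dominant item block
#'
#' Maps each retained component to the battery block (negative affect,
#' fear of illness, worry of contracting disease) contributing the
#' majority of its retained items; unmatched components keep their generic
#' name.
#'
#' @param model a [fit_components()] result.
#' @param blocks item-block map (default [battery_blocks()]).
#' @return named character vector, `comp<j>` -> label.
#' @export
label_components <- function(model, blocks = battery_blocks()) {
  block_names <- c("na", "fear", "worry")
  rm <- model$retained_map
  out <- character(model$k)
  names(out) <- paste0("comp", seq_len(model$k))
  for (j in seq_len(model$k)) {
    items <- rm$item[!is.na(rm$component) & rm$component == j]
    bl <- blocks$block[match(items, blocks$item)]
    bl <- bl[!is.na(bl)]
    out[j] <- if (length(bl)) {
      paste0("score_", block_names[as.integer(names(which.max(table(bl))))])
    } else {
      paste0("comp", j)
    }
  }
  # disambiguate duplicates
  dup <- duplicated(out)
  out[dup] <- paste0(out[dup], ".", which(dup))
  out
}

#' Run the full analysis pipeline
#'
#' Generates (or takes) a cohort, applies the exclusion rules, computes
#' descriptives, fits the psychosocial component model and compound scores,
#' constructs the ACP measure with its median split, fits the association
#' models, computes Spearman coherence of FEV1%pred with the symptom
#' measures, and assembles the cumulative explained-variance table. The
#' result is a pure function of `(cohort or config, options, seed)`.
#'
#' @param config a [synth_config()] used to generate the cohort when
#'   `cohort` is `NULL`.
#' @param cohort optional externally supplied cohort data frame.
#' @param stratify stratification for the ACP model (`"group"` or
#'   `"group-sex"`).
#' @param retention,k component retention rule passed to
#'   [fit_components()].
#' @param interactions include sex-by-score interactions in the
#'   association models.
#' @param outdir optional output directory for the manifest, summary and
#'   tables.
#' @return list of class `acp_run`: `config`, `n_input`, `filter_log`,
#'   `descriptives`, `components`, `component_labels`, `acp`,
#'   `associations`, `spearman`, `variance`, `report`.
#' @export
run_pipeline <- function(config = synth_config(), cohort = NULL,
                         stratify = c("group", "group-sex"),
                         retention = "kaiser", k = 3,
                         interactions = FALSE, outdir = NULL) {
  stratify <- match.arg(stratify)
  if (is.null(cohort)) cohort <- generate_cohort(config)
  n_input <- nrow(cohort)

  quest <- filter_cohort(cohort, require_spirometry = FALSE)
  spiro <- filter_cohort(cohort, require_spirometry = TRUE)
  descriptives <- describe_cohort(quest$cohort)

  batt_cols <- intersect(battery_blocks()$item, names(cohort))
  components <- fit_components(quest$cohort[, batt_cols, drop = FALSE],
                               retention = retention, k = k)
  labels <- label_components(components)
  scores <- components$scores
  colnames(scores) <- labels[colnames(scores)]
  scored <- cbind(quest$cohort, scores)

  acp <- build_accuracy_measure(spiro$cohort, stratify = stratify)
  assoc_data <- merge(acp$scores, scored, by = "id")
  associations <- associate_acp(assoc_data, score_cols = unname(labels),
                                interactions = interactions)

  spiro_scored <- scored[isTRUE_vec(scored$spirometry_valid), , drop = FALSE]
  rho <- list(
    fev1_vs_scl_item = spearman(spiro_scored$fev1pct_pred,
                                spiro_scored$scl_dyspnea),
    fev1_vs_dyspnea_sum = spearman(spiro_scored$fev1pct_pred,
                                   spiro_scored$dyspnea_sumscore),
    fev1_vs_som_sum = spearman(spiro_scored$fev1pct_pred,
                               spiro_scored$scl_som_sumscore),
    acp_vs_scl_item = lapply(split(assoc_data, assoc_data$stratum),
                             function(d) spearman(d$acp, d$scl_dyspnea))
  )
  variance <- variance_decomposition(spiro_scored,
                                     score_cols = unname(labels))
  run <- list(config = config, n_input = n_input,
              filter_log = list(questionnaire = quest$log,
                                spirometry = spiro$log),
              descriptives = descriptives,
              components = components, component_labels = labels,
              acp = acp, associations = associations,
              spearman = rho, variance = variance)
  run$report <- assemble_report(run, outdir = outdir)
  class(run) <- "acp_run"
  run
}

#' @export
print.acp_run <- function(x, ...) {
  cat(x$report$summary, sep = "\n")
  invisible(x)
}
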