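# Readers and writers: cohort tables as comma-separated text with a
# codebook, configurations as JSON, and the run manifest.

#' Default codebook for the cohort table
#'
#' Maps every column the pipeline consumes to a role, a storage type, and a
#' plausibility range mirroring the instruments: the 5-level dyspnea item,
#' the 0-5 dyspnea sumscore, the 12-60 somatization sumscore and the
#' 16-225% FEV1%pred window.
#'
#' @return data frame with columns `column`, `role`, `type`, `min`, `max`,
#'   `levels`, `missing_token`.
#' @export
default_codebook <- function() {
  blocks <- battery_blocks()
  core <- data.frame(
    column = c("id", "sex", "age", "asthma_copd", "self_reported_asthma",
               "physician_confirmed_asthma", "cvd", "gad", "pd",
               "spirometry_valid", "fev1pct_pred", "weight_kg", "bmi",
               "smoking", "education", "scl_dyspnea", "dyspnea_sumscore",
               "scl_som_sumscore"),
    role = c("id", "sex", "age", "asthma_copd", "self_reported_asthma",
             "physician_confirmed_asthma", "cvd", "gad", "pd",
             "spirometry_valid", "fev1pct_pred", "weight_kg", "bmi",
             "smoking", "education", "scl_dyspnea", "dyspnea_sumscore",
             "scl_som_sumscore"),
    type = c("integer", "categorical", "continuous", rep("flag", 7),
             "continuous", "continuous", "continuous", "flag",
             "categorical", "ordinal", "integer", "integer"),
    min = c(1, NA, 18, rep(NA, 7), 16, 20, 10, NA, NA, 1, 0, 12),
    max = c(NA, NA, 110, rep(NA, 7), 225, 250, 80, NA, NA, 5, 5, 60),
    levels = c(NA, "male|female", rep(NA, 12), "low|medium|high",
               rep(NA, 3)),
    stringsAsFactors = FALSE
  )
  batt <- data.frame(
    column = blocks$item,
    role = "psychosocial",
    type = "integer",
    min = ifelse(blocks$type == "binary", 0, NA_real_),
    max = ifelse(blocks$type == "binary", 1, NA_real_),
    levels = NA_character_,
    stringsAsFactors = FALSE
  )
  cb <- rbind(core, batt)
  cb$missing_token <- ""
  cb
}

#' Read a cohort table against a codebook
#'
#' Comma-separated UTF-8 text with a mandatory header. Columns are typed
#' per the codebook, configured missing tokens become `NA`, and range
#' violations of the ordinal/integer instruments are rejected with the row
#' and column named.
#'
#' @param path CSV file.
#' @param codebook codebook data frame (default [default_codebook()]) or
#'   path to a codebook CSV.
#' @param required roles that must be present; defaults to all codebook
#'   columns found in the file plus the instrument columns.
#' @return typed cohort data frame.
#' @export
read_cohort <- function(path, codebook = default_codebook(),
                        required = c("scl_dyspnea")) {
  if (is.character(codebook)) codebook <- read_codebook(codebook)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  miss_req <- setdiff(required, names(raw))
  if (length(miss_req)) {
    stop("required column missing from input: ",
         paste(miss_req, collapse = ", "), call. = FALSE)
  }
  out <- raw
  for (i in seq_len(nrow(codebook))) {
    col <- codebook$column[i]
    if (!col %in% names(raw)) next
    v <- raw[[col]]
    v[v == codebook$missing_token[i]] <- NA
    v <- switch(codebook$type[i],
      flag = parse_flag(v, col),
      ordinal = ,
      integer = as.integer(v),
      continuous = as.numeric(v),
      categorical = as.character(v),
      v
    )
    lo <- codebook$min[i]; hi <- codebook$max[i]
    if (codebook$type[i] %in% c("ordinal", "integer", "continuous")) {
      bad <- which(!is.na(v) & ((!is.na(lo) & v < lo) | (!is.na(hi) & v > hi)))
      if (length(bad)) {
        stop("out-of-range value in column '", col, "', row ", bad[1],
             " (value ", v[bad[1]], ")", call. = FALSE)
      }
    }
    if (!is.na(codebook$levels[i])) {
      lv <- strsplit(codebook$levels[i], "|", fixed = TRUE)[[1]]
      bad <- which(!is.na(v) & !v %in% lv)
      if (length(bad)) {
        stop("unknown level in column '", col, "', row ", bad[1],
             " (value ", v[bad[1]], ")", call. = FALSE)
      }
    }
    out[[col]] <- v
  }
  n_miss <- sum(is.na(out))
  if (n_miss > 0) {
    message("read_cohort: ", n_miss,
            " missing values parsed; models use listwise deletion")
  }
  out
}

parse_flag <- function(v, col) {
  lv <- tolower(v)
  res <- rep(NA, length(v))
  res[lv %in% c("true", "t", "1", "yes")] <- TRUE
  res[lv %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(!is.na(v) & is.na(res))
  if (length(bad)) {
    stop("unparseable flag in column '", col, "', row ", bad[1], call. = FALSE)
  }
  res
}

#' Write a cohort table (and optionally its codebook) as CSV
#'
#' @param cohort cohort data frame.
#' @param path output CSV path.
#' @param codebook_path optional path for the matching codebook CSV.
#' @param codebook codebook to write.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, codebook_path = NULL,
                         codebook = default_codebook()) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  if (!is.null(codebook_path)) write_codebook(codebook, codebook_path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
write_codebook <- function(codebook, path) {
  utils::write.csv(codebook, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_cohort
#' @export
read_codebook <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(missing_token = "character"))
}

#' Read or write a generator/pipeline configuration as JSON
#'
#' @param path JSON file.
#' @return for `read_synth_config`, a validated [synth_config()].
#' @export
read_synth_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$factor_corr)) raw$factor_corr <- as.matrix(raw$factor_corr)
  for (nm in c("fev1_params", "bmi_params", "height_params")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- lapply(raw[[nm]], unlist)
  }
  for (nm in c("physio_coefs", "distortion_weights", "fev1_ref",
               "weight_ref", "exclusion_rates", "education_probs")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(synth_config, raw)
}

#' @rdname read_synth_config
#' @param config a `synth_config`.
#' @export
write_synth_config <- function(config, path) {
  # named atomic vectors become JSON objects so names survive the round-trip
  namedify <- function(x) {
    if (is.list(x)) lapply(x, namedify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(namedify(unclass(config)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# Deterministic hash of an arbitrary configuration object: md5 of its
# canonical JSON serialization.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Assemble the run manifest and human-readable summary
#'
#' The manifest records everything needed to audit a run: the configuration
#' hash and seed, the exclusion log, model summaries (coefficients,
#' log-likelihoods, convergence), per-stratum ACP summaries, odds-ratio
#' tables and the cumulative explained-variance table. The summary renders
#' the descriptives and variance tables in their conventional layouts.
#' Content is a pure function of the run artifacts: no timestamps.
#'
#' @param run a pipeline result from [run_pipeline()].
#' @param outdir optional directory; writes `manifest.json` and
#'   `summary.txt` (plus the scores and variance tables as CSV) when given.
#' @return list with `manifest` (list) and `summary` (character vector).
#' @export
assemble_report <- function(run, outdir = NULL) {
  manifest <- list(
    package = "acpscore",
    config_hash = config_hash(run$config),
    seed = run$config$seed %||% NA,
    n_input = run$n_input,
    exclusions = run$filter_log,
    adequacy = list(kmo = run$components$kmo,
                    bartlett = unclass(run$components$bartlett)),
    components = list(
      var_explained = run$components$var_explained,
      alphas = run$components$alphas,
      phi = run$components$phi,
      n_retained_items = sum(!is.na(run$components$retained_map$component)),
      labels = run$component_labels
    ),
    acp = lapply(run$acp$summaries, function(s) {
      s$histogram <- NULL
      s
    }),
    parallel_lines = lapply(run$acp$strata, function(s)
      unclass(s$parallel_lines)),
    model_loglik = lapply(run$acp$strata, function(s)
      list(ordinal = s$ordinal$loglik, multinomial = s$multinomial$loglik,
           converged = s$multinomial$converged, n = s$multinomial$n_obs)),
    spearman = run$spearman,
    associations = run$associations,
    variance_table = run$variance
  )
  summary_txt <- c(
    "== Cohort descriptives ==",
    format_descriptives(run$descriptives),
    "",
    "== ACP by stratum ==",
    vapply(names(run$acp$summaries), function(s) {
      x <- run$acp$summaries[[s]]
      sprintf("%s: median ACP %.3f (IQR %.3f-%.3f), %.1f%% at or below 0.5 (n = %d)",
              s, x$median, x$iqr[1], x$iqr[2],
              100 * x$frac_at_or_below_half, x$n)
    }, character(1)),
    "",
    "== Cumulative explained variance ==",
    format_variance_table(run$variance)
  )
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    writeLines(summary_txt, file.path(outdir, "summary.txt"))
    utils::write.csv(run$acp$scores, file.path(outdir, "acp_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(run$variance, file.path(outdir, "variance_table.csv"),
                     row.names = FALSE)
    utils::write.csv(run$associations, file.path(outdir, "associations.csv"),
                     row.names = FALSE)
  }
  list(manifest = manifest, summary = summary_txt)
}

format_descriptives <- function(d) {
  vapply(seq_len(nrow(d)), function(i) {
    sprintf("%-38s %12s %12s",
            paste0(d$variable[i], " [", d$stat[i], "]"),
            signif(d$control[i], 4), signif(d$asthma_copd[i], 4))
  }, character(1))
}

format_variance_table <- function(v) {
  out <- character(0)
  for (m in unique(v$model)) {
    out <- c(out, paste0("-- ", m, " --"))
    sub <- v[v$model == m, ]
    for (st in unique(sub$step)) {
      row <- sub[sub$step == st, ]
      cells <- vapply(seq_len(nrow(row)), function(i)
        sprintf("%s/%s %.1f%%", row$stratum[i], row$sex[i],
                100 * row$value[i]), character(1))
      out <- c(out, sprintf("  step %d (%s): %s", st, row$label[1],
                            paste(cells, collapse = "  ")))
    }
  }
  out
}
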