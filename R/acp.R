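# The actual category probability (ACP): the fitted multinomial model's
# probability of each participant's observed symptom category given their
# physiology. High ACP = the physiological predictors classify the person's
# self-report accurately; low ACP = reported symptoms diverge from what the
# physiology predicts.

#' Per-participant actual category probabilities
#'
#' For each row, the predicted probability of the participant's *observed*
#' outcome category under a fitted multinomial model. With an intercept-only
#' model this reduces to the empirical share of the observed category.
#'
#' @param fit a converged [fit_multinomial()] result.
#' @param design design matrix matching the fit.
#' @param y observed outcome vector; levels must be a subset of the fit's
#'   categories.
#' @return numeric vector of probabilities in (0, 1), one per row.
#' @export
compute_acp <- function(fit, design, y) {
  stopifnot(inherits(fit, "multinomial_fit"))
  if (!fit$converged) {
    warning("ACP computed from a non-converged fit", call. = FALSE)
  }
  ych <- as.character(y)
  if (!all(ych %in% fit$categories)) {
    stop("outcome contains levels unseen by the fit: ",
         paste(setdiff(unique(ych), fit$categories), collapse = ", "),
         call. = FALSE)
  }
  P <- predict_category_probs(fit, design)
  P[cbind(seq_along(ych), match(ych, colnames(P)))]
}

#' Median split of ACP values within strata
#'
#' Dichotomizes ACP against each stratum's own median ("respective
#' medians"). The tie rule is strict: `high_flag = 1` iff `acp > median`,
#' keeping the high-accuracy class conservative; ties at the median are
#' flagged low.
#'
#' @param acp_values numeric vector of ACP values.
#' @param strata stratum label per value (single stratum if omitted).
#' @return a data frame with `acp`, `stratum`, `stratum_median` and
#'   `high_flag` (integer 0/1).
#' @export
median_split <- function(acp_values, strata = NULL) {
  if (is.null(strata)) strata <- rep("all", length(acp_values))
  strata <- as.character(strata)
  stopifnot(length(strata) == length(acp_values))
  med <- numeric(length(acp_values))
  flag <- integer(length(acp_values))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) == 0) stop("empty stratum: ", s, call. = FALSE)
    if (length(idx) < 2) {
      warning("stratum '", s, "' has fewer than 2 values; all flagged low",
              call. = FALSE)
      med[idx] <- acp_values[idx]
      flag[idx] <- 0L
      next
    }
    m <- stats::median(acp_values[idx])
    med[idx] <- m
    flag[idx] <- as.integer(acp_values[idx] > m)
  }
  data.frame(acp = acp_values, stratum = strata,
             stratum_median = med, high_flag = flag)
}

#' Summary of an ACP distribution
#'
#' Median, interquartile range (linear-interpolation quantile convention,
#' i.e. `quantile(type = 7)`), the fraction of participants with an ACP of
#' 0.5 or below (the share the physiological model would misclassify more
#' often than not), and a fixed-breaks histogram for distribution-shape
#' reporting.
#'
#' @param acp_values non-empty numeric vector in (0, 1).
#' @param breaks histogram breakpoints on `[0, 1]`.
#' @return list with `median`, `iqr` (length-2 vector), `frac_at_or_below_half`,
#'   `n`, and `histogram` (data frame of bin mids and counts).
#' @export
acp_summary <- function(acp_values, breaks = seq(0, 1, by = 0.05)) {
  if (length(acp_values) == 0) stop("empty ACP vector", call. = FALSE)
  q <- stats::quantile(acp_values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  h <- graphics::hist(acp_values, breaks = breaks, plot = FALSE)
  list(
    median = q[2],
    iqr = c(lower = q[1], upper = q[3]),
    frac_at_or_below_half = mean(acp_values <= 0.5),
    n = length(acp_values),
    histogram = data.frame(mid = h$mids, count = h$counts)
  )
}

#' Spearman rank correlation with large-sample p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties) with the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom for the two-sided p-value.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` and `p`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero rank variance; correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}
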