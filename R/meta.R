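#' Reconstruct event counts from a printed percentage
#'
#' Trial tables print response rates as percentages; pooling needs integer
#' event counts. Events are recovered by nearest-integer rounding with
#' ties rounded half up, so `reconstruct_events(71, 355)` gives 252.
#'
#' @param pct Percentage(s) in \[0, 100\].
#' @param n Cohort size(s), positive integers.
#' @return Integer event count(s), guaranteed within \[0, n\].
#' @export
reconstruct_events <- function(pct, n) {
  if (any(!is.finite(pct)) || any(pct < 0) || any(pct > 100))
    stop("pct must lie in [0, 100]")
  if (any(!is.finite(n)) || any(n < 1) || any(n != round(n)))
    stop("n must be a positive integer")
  # floor(x + 0.5) rounds half up; a tiny nudge guards binary artefacts
  # like 38.3/100 * 94 evaluating just below 36.0
  x <- floor(pct / 100 * n + 0.5 + 1e-9)
  as.integer(pmin(pmax(x, 0), n))
}

#' Freeman-Tukey double-arcsine transform of a binomial proportion
#'
#' t = asin(sqrt(x/(n+1))) + asin(sqrt((x+1)/(n+1))), with within-study
#' variance 1/(n + 0.5). The transform stabilises the variance of a
#' proportion so studies with p near 0 or 1 can be pooled by inverse
#' variance.
#'
#' @param x Event count(s), 0 <= x <= n.
#' @param n Cohort size(s) >= 1.
#' @return data.frame with columns `t` and `var`.
#' @export
ft_transform <- function(x, n) {
  if (any(x < 0) || any(x > n) || any(n < 1))
    stop("need 0 <= x <= n, n >= 1")
  data.frame(t = asin(sqrt(x / (n + 1))) + asin(sqrt((x + 1) / (n + 1))),
             var = 1 / (n + 0.5))
}

#' Invert the double-arcsine transform (Miller)
#'
#' Back-transforms a pooled value on the double-arcsine scale to a
#' proportion, using the harmonic mean of the study sizes:
#' p = (1 - sign(cos t) * sqrt(1 - (sin t + (sin t - 1/sin t)/n)^2)) / 2,
#' clamped to \[0, 1\]. Values t <= 0 map to 0 and t >= pi to 1.
#'
#' @param t Pooled transformed value(s).
#' @param n_har Harmonic mean of the study sizes.
#' @return Proportion(s) in \[0, 1\].
#' @export
ft_backtransform <- function(t, n_har) {
  if (n_har <= 0) stop("n_har must be positive")
  vapply(t, function(ti) {
    if (ti <= 0) return(0)
    if (ti >= pi) return(1)
    s <- sin(ti)
    inner <- s + (s - 1 / s) / n_har
    p <- 0.5 * (1 - sign(cos(ti)) * sqrt(pmax(0, 1 - inner^2)))
    min(max(p, 0), 1)
  }, numeric(1))
}

#' Logit transform of a binomial proportion
#'
#' Alternative effect scale: t = log(p / (1 - p)) with var = 1/x +
#' 1/(n - x); a 0.5 continuity correction is applied when x = 0 or x = n.
#'
#' @inheritParams ft_transform
#' @return data.frame with columns `t` and `var`.
#' @export
logit_transform <- function(x, n) {
  if (any(x < 0) || any(x > n) || any(n < 1))
    stop("need 0 <= x <= n, n >= 1")
  cc <- x == 0 | x == n
  xa <- ifelse(cc, x + 0.5, x)
  na <- ifelse(cc, n + 1, n)
  data.frame(t = log(xa / (na - xa)), var = 1 / xa + 1 / (na - xa))
}

#' Fixed-effect inverse-variance pooling
#'
#' @param t Transformed per-study effects.
#' @param var Their within-study variances.
#' @return list with `t_bar` (pooled value), `var_bar` (its variance) and
#'   `weights` (normalised inverse-variance weights).
#' @export
pool_fixed <- function(t, var) {
  if (length(t) == 0) stop("no studies to pool")
  stopifnot(length(t) == length(var), all(var > 0))
  w <- 1 / var
  list(t_bar = sum(w * t) / sum(w), var_bar = 1 / sum(w),
       weights = w / sum(w))
}

#' Cochran's Q, I-squared and DerSimonian-Laird tau-squared
#'
#' Q is the weighted squared dispersion of per-study effects about the
#' fixed-effect mean; I2 = max(0, (Q - df)/Q) * 100 expresses the share
#' of total variation attributable to between-study heterogeneity; the
#' DerSimonian-Laird moment estimator gives tau2 = max(0, (Q - df) /
#' (sum(w) - sum(w^2)/sum(w))). With a single study all are zero.
#'
#' @inheritParams pool_fixed
#' @return list with `Q`, `df`, `I2`, `tau2`.
#' @export
heterogeneity <- function(t, var) {
  k <- length(t)
  if (k < 2)
    return(list(Q = 0, df = 0, I2 = 0, tau2 = 0))
  w <- 1 / var
  t_bar <- sum(w * t) / sum(w)
  Q <- sum(w * (t - t_bar)^2)
  df <- k - 1
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  list(Q = Q, df = df, I2 = I2, tau2 = tau2)
}

#' Random-effects pooling with a given between-study variance
#'
#' Inverse-variance pooling with weights 1 / (var_i + tau2); tau2 = 0
#' reduces exactly to [pool_fixed()].
#'
#' @inheritParams pool_fixed
#' @param tau2 Between-study variance >= 0.
#' @export
pool_random <- function(t, var, tau2) {
  stopifnot(tau2 >= 0)
  pool_fixed(t, var + tau2)
}

#' Exact per-study confidence interval for a proportion
#'
#' Clopper-Pearson interval, used for forest-plot whiskers.
#'
#' @param x Events; `n` cohort size; `level` confidence level.
#' @param n,level See above.
#' @return Numeric vector `c(low, high)`.
#' @export
study_ci <- function(x, n, level = 0.95) {
  as.numeric(stats::binom.test(x, n, conf.level = level)$conf.int)
}

#' Meta-analysis of a response proportion over trial cohorts
#'
#' Runs the full pooling pipeline over a study table: event counts are
#' reconstructed from the printed percentages, transformed
#' (double-arcsine by default), heterogeneity is estimated
#' (DerSimonian-Laird), the random-effects model is selected when
#' I2 > `i2_cutoff` (else fixed), and the pooled value and its Wald
#' interval (t_bar +/- 1.96 se at the default level) are back-transformed
#' to the proportion scale using the harmonic mean of the cohort sizes.
#'
#' @param studies data.frame with columns `study_id`, `tumor_type`, `n`
#'   and the endpoint percentage column (`orr_pct` or `dcr_pct`), as
#'   returned by [read_study_table()].
#' @param endpoint `"ORR"` or `"DCR"`. Cohorts with a missing endpoint
#'   value are dropped with a warning.
#' @param transform `"double_arcsine"` (default) or `"logit"`.
#' @param i2_cutoff I2 percentage above which (strictly) the
#'   random-effects model is used. Default 50.
#' @param level Confidence level; the normal quantile 1.96 is used at the
#'   default 0.95.
#' @return An object of class `pooled_result`: list with `endpoint`, `k`,
#'   `estimate`, `ci_low`, `ci_high` (proportions), `model`
#'   (`"fixed"`/`"random"`), `het` (Q, df, I2, tau2), `weights`
#'   (normalised, from the selected model), `t_bar`, `se_t`, `n_harmonic`
#'   and the per-study `data`.
#' @examples
#' trials <- read_study_table(system.file("extdata", "table1.tsv",
#'                                        package = "icblenv"))
#' meta_analyze(trials, "ORR")
#' @export
meta_analyze <- function(studies, endpoint = c("ORR", "DCR"),
                         transform = c("double_arcsine", "logit"),
                         i2_cutoff = 50, level = 0.95) {
  endpoint <- match.arg(endpoint)
  transform <- match.arg(transform)
  if (is.null(studies) || nrow(studies) == 0)
    stop("empty study table")
  col <- if (endpoint == "ORR") "orr_pct" else "dcr_pct"
  if (is.null(studies[[col]]))
    stop("study table lacks column ", col)
  keep <- !is.na(studies[[col]])
  if (!all(keep))
    warning(sum(!keep), " cohort(s) dropped: missing ", endpoint)
  studies <- studies[keep, , drop = FALSE]
  if (nrow(studies) == 0)
    stop("no cohorts with ", endpoint, " available")

  x <- reconstruct_events(studies[[col]], studies$n)
  ef <- switch(transform,
               double_arcsine = ft_transform(x, studies$n),
               logit = logit_transform(x, studies$n))
  het <- heterogeneity(ef$t, ef$var)
  model <- if (het$I2 > i2_cutoff) "random" else "fixed"
  pooled <- if (model == "random")
    pool_random(ef$t, ef$var, het$tau2)
  else pool_fixed(ef$t, ef$var)

  # 1.96 exactly at the conventional level, matching the printed analyses
  z <- if (identical(level, 0.95)) 1.96 else stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(pooled$var_bar)
  lo_t <- pooled$t_bar - z * se
  hi_t <- pooled$t_bar + z * se
  n_har <- 1 / mean(1 / studies$n)
  back <- switch(transform,
                 double_arcsine = function(t) ft_backtransform(t, n_har),
                 logit = function(t) stats::plogis(t))
  est <- back(pooled$t_bar)
  ci <- sort(back(c(lo_t, hi_t)))

  structure(list(endpoint = endpoint, k = nrow(studies),
                 estimate = est, ci_low = ci[1], ci_high = ci[2],
                 model = model, transform = transform, het = het,
                 weights = pooled$weights, t_bar = pooled$t_bar,
                 se_t = se, n_harmonic = n_har,
                 data = data.frame(study_id = studies$study_id,
                                   tumor_type = studies$tumor_type,
                                   n = studies$n, events = x,
                                   p = x / studies$n)),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, digits = 3, ...) {
  cat(sprintf("Pooled %s over %d cohorts (%s effects, %s)\n",
              x$endpoint, x$k, x$model, x$transform))
  cat(sprintf("  estimate %.*f, 95%% CI (%.*f, %.*f)\n",
              digits, x$estimate, digits, x$ci_low, digits, x$ci_high))
  cat(sprintf("  Q = %.2f (df %d), I2 = %.1f%%, tau2 = %.4f\n",
              x$het$Q, x$het$df, x$het$I2, x$het$tau2))
  invisible(x)
}

#' Forest-plot data for a pooled endpoint
#'
#' One row per cohort (proportion, exact Clopper-Pearson interval and the
#' normalised weight under the selected model) plus a final pooled row
#' flagged with `pooled = TRUE`.
#'
#' @inheritParams meta_analyze
#' @param ... Passed to [meta_analyze()].
#' @return data.frame with columns `study_id`, `tumor_type`, `events`,
#'   `n`, `p`, `ci_low`, `ci_high`, `weight`, `pooled`.
#' @export
forest_data <- function(studies, endpoint = c("ORR", "DCR"), ...) {
  res <- meta_analyze(studies, endpoint, ...)
  d <- res$data
  ci <- t(mapply(study_ci, d$events, d$n))
  rows <- data.frame(study_id = d$study_id, tumor_type = d$tumor_type,
                     events = d$events, n = d$n, p = d$p,
                     ci_low = ci[, 1], ci_high = ci[, 2],
                     weight = res$weights, pooled = FALSE)
  pooled <- data.frame(study_id = "POOLED", tumor_type = "",
                       events = NA_integer_, n = NA_integer_,
                       p = res$estimate, ci_low = res$ci_low,
                       ci_high = res$ci_high, weight = 1, pooled = TRUE)
  rbind(rows, pooled)
}
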