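#' Sample-by-cell-type immune infiltration table
#'
#' Estimated infiltration fractions/scores (CIBERSORT- or TIDE-style)
#' per tumor sample, with an optional tumor-purity column used for
#' purity-adjusted correlations.
#'
#' @param values Numeric matrix or data.frame, samples in rows (rownames
#'   = sample ids), cell types in columns (e.g. `CD8_T`, `Treg`,
#'   `M2_macrophage`, `MDSC`, `DC`). Values must be finite and >= 0.
#' @param cancer_type Cancer-type code.
#' @param purity Optional per-sample tumor purity in \[0, 1\].
#' @return Object of class `infiltration_table`.
#' @export
infiltration_table <- function(values, cancer_type, purity = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have sample rownames")
  if (any(!is.finite(values)) || any(values < 0))
    stop("infiltration values must be finite and >= 0")
  if (!is.null(purity)) {
    if (length(purity) != nrow(values) || any(purity < 0 | purity > 1))
      stop("purity must be per-sample values in [0, 1]")
  }
  structure(list(values = values, cancer_type = toupper(cancer_type),
                 purity = purity),
            class = "infiltration_table")
}

# Spearman correlation, optionally partial with respect to purity:
# both variables are rank-transformed, regressed on the purity ranks,
# and the residuals correlated (Pearson on rank residuals).
.spearman <- function(x, y, purity = NULL, method = "spearman") {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NaN)
  if (is.null(purity))
    return(stats::cor(x, y, method = method))
  if (method == "spearman") {
    x <- rank(x); y <- rank(y); p <- rank(purity)
  } else p <- purity
  rx <- stats::residuals(stats::lm(x ~ p))
  ry <- stats::residuals(stats::lm(y ~ p))
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NaN)
  stats::cor(rx, ry)
}

#' Correlate target-gene expression with immune infiltration
#'
#' Spearman rank correlation (TIMER convention) of each lenvatinib
#' target gene's log2(x + 1) tumor expression against each infiltrate
#' cell type, over the samples shared by the two tables. When the
#' infiltration table carries tumor purity, a purity-adjusted partial
#' Spearman correlation is computed instead (both variables
#' rank-regressed on purity ranks, residuals correlated).
#'
#' @param em An [expression_matrix()].
#' @param infil An [infiltration_table()].
#' @param panel A [target_panel()].
#' @param genes Genes to correlate; defaults to the 11 lenvatinib
#'   targets (the box rules below consume exactly those).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data.frame with columns `gene`, `cell_type`, `r`, `n`.
#' @export
gene_infiltration_correlation <- function(em, infil,
                                          panel = target_panel(),
                                          genes = panel$lenvatinib_targets,
                                          method = c("spearman", "pearson")) {
  method <- match.arg(method)
  tv <- log2(tumor_values(em) + 1)
  shared <- intersect(colnames(tv), rownames(infil$values))
  if (length(shared) < 3) stop("need >= 3 shared samples")
  tv <- tv[, shared, drop = FALSE]
  iv <- infil$values[shared, , drop = FALSE]
  pur <- if (is.null(infil$purity)) NULL
  else infil$purity[match(shared, rownames(infil$values))]
  genes <- resolve_symbol(genes, panel)
  out <- expand.grid(gene = genes, cell_type = colnames(iv),
                     stringsAsFactors = FALSE)
  out$r <- mapply(function(g, ct) .spearman(tv[g, ], iv[, ct], pur, method),
                  out$gene, out$cell_type)
  if (any(is.nan(out$r)))
    warning("constant gene or cell-type vector: r recorded as NaN")
  out$n <- length(shared)
  out
}

#' CD8+ T-cell depletion box rule
#'
#' A cancer is flagged when the lenvatinib targets are broadly
#' negatively correlated with CD8+ T-cell infiltration: at least 8
#' of the 11 correlations are negative AND more than four of them
#' (i.e. at least 5) reach r <= -0.15. NaN values are ignored.
#'
#' @param r Numeric vector of up to 11 correlations (lenvatinib genes vs
#'   CD8_T).
#' @param min_neg Minimum count of negative correlations (default 8).
#' @param strong_cut Strong-correlation cutoff (default -0.15, inclusive).
#' @param min_strong Minimum count at the strong cutoff (default 5).
#' @return TRUE/FALSE.
#' @export
cd8_box_flag <- function(r, min_neg = 8, strong_cut = -0.15,
                         min_strong = 5) {
  r <- r[!is.nan(r) & !is.na(r)]
  sum(r < 0) >= min_neg && sum(r <= strong_cut) >= min_strong
}

#' Suppressive-cell enrichment box rule
#'
#' Mirror of [cd8_box_flag()] for immunosuppressive infiltrates (Treg,
#' M2 macrophages, MDSC): at least 8 positive correlations AND >= 5 of
#' them with r >= 0.15.
#'
#' @param r Numeric vector of up to 11 correlations.
#' @param min_pos,strong_cut,min_strong Rule constants (8, 0.15, 5).
#' @return TRUE/FALSE.
#' @export
suppressive_box_flag <- function(r, min_pos = 8, strong_cut = 0.15,
                                 min_strong = 5) {
  r <- r[!is.nan(r) & !is.na(r)]
  sum(r > 0) >= min_pos && sum(r >= strong_cut) >= min_strong
}

#' Classify an infiltrate as a survival risk or protective factor
#'
#' Univariate Cox proportional-hazards fit (Efron tie handling) of
#' survival on the standardized covariate; z = beta / se(beta) with its
#' Wald p-value. The call is `risk` when p < alpha and z > 0 (high
#' infiltration predicts shorter survival), `protective` when p < alpha
#' and z < 0, otherwise `neutral`. Standardization leaves the sign and z
#' unchanged and makes z comparable across covariates.
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicator, 1 = death, 0 = censored.
#' @param covariate Infiltration level (or expression) per subject.
#' @param alpha Significance level, default 0.05.
#' @return data.frame row: `z`, `p`, `call`, `n`, `events`.
#' @export
cox_classify <- function(time, event, covariate, alpha = 0.05) {
  n <- length(time)
  stopifnot(length(event) == n, length(covariate) == n)
  if (n < 10) stop("need >= 10 records")
  if (any(time < 0) || !all(event %in% c(0, 1)))
    stop("invalid survival data")
  if (sum(event) < 1 || stats::sd(covariate) == 0) {
    warning("no events or constant covariate; call is neutral")
    return(data.frame(z = NA_real_, p = NA_real_, call = "neutral",
                      n = n, events = sum(event)))
  }
  x <- as.numeric(scale(covariate))
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "efron"),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit) || !is.finite(sqrt(fit$var[1, 1]))) {
    warning("Cox fit failed to converge; call is neutral")
    return(data.frame(z = NA_real_, p = NA_real_, call = "neutral",
                      n = n, events = sum(event)))
  }
  z <- unname(fit$coefficients[1] / sqrt(fit$var[1, 1]))
  p <- 2 * stats::pnorm(-abs(z))
  call <- if (p < alpha && z > 0) "risk"
  else if (p < alpha && z < 0) "protective" else "neutral"
  data.frame(z = z, p = p, call = call, n = n, events = sum(event))
}

#' Kaplan-Meier comparison of high vs low infiltration
#'
#' Splits subjects at a quantile of the covariate (median by default;
#' ties at the split go to the high group) and compares survival with
#' the two-group log-rank test.
#'
#' @inheritParams cox_classify
#' @param split Quantile at which to split, default 0.5 (median).
#' @return list with `chi_square`, `p`, `group_medians` (median survival
#'   of the low/high groups) and `groups` (the per-subject labels).
#' @export
km_logrank <- function(time, event, covariate, split = 0.5) {
  cut <- stats::quantile(covariate, split)
  grp <- factor(ifelse(covariate >= cut, "high", "low"),
                levels = c("low", "high"))
  if (length(unique(grp)) < 2)
    stop("degenerate split: all subjects fall in one group")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ grp)
  med <- summary(sf)$table[, "median"]
  list(chi_square = unname(sd_$chisq), p = p,
       group_medians = med, groups = grp)
}
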