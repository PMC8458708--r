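#' Gene-by-sample expression matrix with tumor/normal labels
#'
#' Light container for TPM-like, pre-normalised expression values of the
#' panel genes in one cancer type. Values must be finite and
#' non-negative; all statistics downstream are computed on log2(x + 1).
#'
#' @param values Numeric matrix, genes in rows (rownames = canonical
#'   symbols or aliases, normalised on construction), samples in columns.
#' @param condition Character vector, one of `"tumor"`/`"normal"` per
#'   sample (column).
#' @param cancer_type Cancer-type code (free string, upper-cased).
#' @param panel A [target_panel()] used to normalise row names; rows not
#'   in the panel are kept verbatim.
#' @return Object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, condition, cancer_type,
                              panel = target_panel()) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("values must have gene rownames")
  if (length(condition) != ncol(values))
    stop("condition must label every sample column")
  condition <- tolower(as.character(condition))
  if (!all(condition %in% c("tumor", "normal")))
    stop("condition labels must be 'tumor' or 'normal'")
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and >= 0")
  rn <- rownames(values)
  known <- toupper(trimws(rn)) %in% names(panel$alias_map)
  rn[known] <- resolve_symbol(rn[known], panel)
  rownames(values) <- rn
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  structure(list(values = values, condition = condition,
                 cancer_type = toupper(cancer_type)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s: %d genes x %d samples (%d tumor, %d normal)\n",
              x$cancer_type, nrow(x$values), ncol(x$values),
              sum(x$condition == "tumor"), sum(x$condition == "normal")))
  invisible(x)
}

#' Subset an expression matrix to tumor samples
#' @param em An [expression_matrix()].
#' @return Numeric matrix of the tumor columns.
#' @export
tumor_values <- function(em) {
  em$values[, em$condition == "tumor", drop = FALSE]
}

#' Tumor-versus-normal differential expression of the panel genes
#'
#' Per gene, a two-sided Welch (unequal-variance) t-test on log2(x + 1)
#' values, tumor against normal. A gene counts as "highly expressed"
#' (`significant_up`) only when the tumor mean exceeds the normal mean
#' AND p < `alpha`; significantly down-regulated genes never do. No
#' multiple-testing correction is applied across the panel: calls are
#' per-gene at the nominal alpha, as portal-style tumor/normal screens
#' report them.
#'
#' @param em An [expression_matrix()] with >= 2 samples per condition.
#' @param alpha Significance level, default 0.05.
#' @return data.frame with one row per gene: `gene`, `mean_log_tumor`,
#'   `mean_log_normal`, `p_value`, `up`, `significant_up`, `testable`.
#'   Genes in a condition with < 2 samples are flagged `testable = FALSE`
#'   (p = NA) and excluded from downstream counts.
#' @export
differential_expression <- function(em, alpha = 0.05) {
  stopifnot(inherits(em, "expr_matrix"))
  lv <- log2(em$values + 1)
  tum <- lv[, em$condition == "tumor", drop = FALSE]
  nor <- lv[, em$condition == "normal", drop = FALSE]
  testable <- ncol(tum) >= 2 && ncol(nor) >= 2
  if (!testable)
    warning("a condition has < 2 samples in ", em$cancer_type,
            "; genes flagged untestable")
  res <- lapply(rownames(lv), function(g) {
    a <- tum[g, ]
    b <- nor[g, ]
    if (!testable)
      return(data.frame(gene = g, mean_log_tumor = mean(a),
                        mean_log_normal = mean(b), p_value = NA_real_,
                        up = mean(a) > mean(b), significant_up = FALSE,
                        testable = FALSE))
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate: no within-group variability; identical means carry
      # no evidence (p = 1), distinct constant means are a sure
      # difference (p = 0)
      if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else {
      stats::t.test(a, b, var.equal = FALSE)$p.value
    }
    up <- mean(a) > mean(b)
    data.frame(gene = g, mean_log_tumor = mean(a), mean_log_normal = mean(b),
               p_value = p, up = up, significant_up = up && p < alpha,
               testable = TRUE)
  })
  out <- do.call(rbind, res)
  attr(out, "cancer_type") <- em$cancer_type
  attr(out, "alpha") <- alpha
  out
}

#' Classify a cancer's panel-expression pattern
#'
#' Counts significantly up-regulated targets per therapy arm and applies
#' the bubble-chart rule: `high` when >= `lenv_min` (default 4)
#' lenvatinib targets AND >= `icb_min` (default 2) ICB targets are up;
#' `moderate` when exactly one of those holds; `low` when no target of
#' either arm is up; otherwise `unclassified` (the three printed rules do
#' not partition all outcomes).
#'
#' @param de data.frame from [differential_expression()] (possibly a
#'   subset of the 15 genes).
#' @param panel A [target_panel()].
#' @param lenv_min,icb_min Inclusive count thresholds.
#' @return One-row data.frame: `cancer_type`, `lenv_up_count`,
#'   `icb_up_count`, `category`.
#' @export
classify_expression <- function(de, panel = target_panel(),
                                lenv_min = 4, icb_min = 2) {
  ct <- attr(de, "cancer_type")
  de <- de[de$testable, , drop = FALSE]
  lenv_up <- sum(de$significant_up & de$gene %in% panel$lenvatinib_targets)
  icb_up <- sum(de$significant_up & de$gene %in% panel$icb_targets)
  lenv_ok <- lenv_up >= lenv_min
  icb_ok <- icb_up >= icb_min
  category <- if (lenv_ok && icb_ok) "high"
  else if (xor(lenv_ok, icb_ok)) "moderate"
  else if (lenv_up == 0 && icb_up == 0) "low"
  else "unclassified"
  data.frame(cancer_type = ct %||% NA_character_,
             lenv_up_count = lenv_up, icb_up_count = icb_up,
             category = category)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
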