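#' Lenvatinib-by-ICB target-gene correlation matrix
#'
#' Pearson correlation of each lenvatinib target (rows, 11) against each
#' ICB target (columns, 4), computed on log2(x + 1) over tumor samples
#' only, as the pan-cancer portals correlate within tumors. A constant
#' gene yields NaN in its cells (with a warning); NaN cells are excluded
#' from all counts rather than treated as zero.
#'
#' @param em An [expression_matrix()] containing the panel genes,
#'   with at least 3 tumor samples.
#' @param panel A [target_panel()].
#' @return Numeric 11 x 4 matrix (rownames lenvatinib targets, colnames
#'   ICB targets) with attributes `n_samples` and `cancer_type`.
#' @export
pairwise_correlation <- function(em, panel = target_panel()) {
  tv <- log2(tumor_values(em) + 1)
  if (ncol(tv) < 3) stop("need >= 3 tumor samples")
  missing <- setdiff(panel_genes(panel), rownames(tv))
  if (length(missing))
    stop("expression matrix lacks panel genes: ",
         paste(missing, collapse = ", "))
  const <- rownames(tv)[apply(tv, 1, stats::sd) == 0]
  if (length(intersect(const, panel_genes(panel))))
    warning("constant gene(s), correlations recorded as NaN: ",
            paste(intersect(const, panel_genes(panel)), collapse = ", "))
  r <- suppressWarnings(
    stats::cor(t(tv[panel$lenvatinib_targets, , drop = FALSE]),
               t(tv[panel$icb_targets, , drop = FALSE]),
               method = "pearson"))
  r[is.na(r)] <- NaN
  attr(r, "n_samples") <- ncol(tv)
  attr(r, "cancer_type") <- em$cancer_type
  r
}

#' Count positively correlated gene pairs
#'
#' Number of non-NaN cells with r >= `threshold` (inclusive, so a cell
#' at exactly 0.1 counts). At most 44 pairs (11 x 4).
#'
#' @param cm Matrix from [pairwise_correlation()].
#' @param threshold Inclusive correlation cutoff, default 0.1.
#' @return Integer count.
#' @export
count_positive_pairs <- function(cm, threshold = 0.1) {
  sum(cm >= threshold, na.rm = TRUE)
}

#' Per-cancer correlation summary
#'
#' @param cm Matrix from [pairwise_correlation()].
#' @param threshold Cutoff for a "positive" pair (default 0.1).
#' @param strong_threshold Cutoff for a "strong" pair (default 0.15).
#' @return list with `cancer_type`, `positive_pair_count` and
#'   `strong_pairs` (data.frame of lenvatinib/ICB gene pairs with
#'   r >= `strong_threshold`).
#' @export
correlation_summary <- function(cm, threshold = 0.1,
                                strong_threshold = 0.15) {
  idx <- which(cm >= strong_threshold & !is.nan(cm), arr.ind = TRUE)
  strong <- data.frame(lenvatinib = rownames(cm)[idx[, 1]],
                       icb = colnames(cm)[idx[, 2]],
                       r = cm[idx])
  list(cancer_type = attr(cm, "cancer_type"),
       positive_pair_count = count_positive_pairs(cm, threshold),
       strong_pairs = strong[order(-strong$r), , drop = FALSE])
}

#' Split cancers into high/low correlation groups
#'
#' Sorts cancers by their positive-pair count (descending; ties broken
#' by cancer code alphabetically, so the order is deterministic) and
#' labels the upper half -- the top ceiling(k/2) -- as the high
#' correlation group, the remainder low.
#'
#' @param counts data.frame with columns `cancer_type` and
#'   `positive_pair_count` (one row per cancer), or a named integer
#'   vector.
#' @return data.frame ordered by rank with an added `group` column
#'   (`"high"`/`"low"`).
#' @export
rank_cancers_by_correlation <- function(counts) {
  if (!is.data.frame(counts))
    counts <- data.frame(cancer_type = names(counts),
                         positive_pair_count = as.integer(counts))
  if (nrow(counts) == 0) stop("no cancers to rank")
  o <- order(-counts$positive_pair_count, counts$cancer_type)
  counts <- counts[o, , drop = FALSE]
  n_high <- ceiling(nrow(counts) / 2)
  counts$group <- rep(c("high", "low"),
                      c(n_high, nrow(counts) - n_high))
  rownames(counts) <- NULL
  counts
}

#' Pan-cancer lenvatinib-by-ICB correlation
#'
#' Either pools the tumor samples of all cancers into one correlation
#' (`mode = "pooled"`, the default) or averages the per-cancer
#' correlation matrices cell-wise (`mode = "mean_r"`).
#'
#' @param ems List of [expression_matrix()] objects.
#' @param panel A [target_panel()].
#' @param mode `"pooled"` or `"mean_r"`.
#' @return 11 x 4 correlation matrix as in [pairwise_correlation()].
#' @export
pan_cancer_correlation <- function(ems, panel = target_panel(),
                                   mode = c("pooled", "mean_r")) {
  mode <- match.arg(mode)
  if (mode == "mean_r") {
    mats <- lapply(ems, pairwise_correlation, panel = panel)
    r <- Reduce(`+`, mats) / length(mats)
    attr(r, "n_samples") <- sum(vapply(mats, attr, 0L, "n_samples"))
    attr(r, "cancer_type") <- "PANCAN"
    return(r)
  }
  tv <- do.call(cbind, lapply(ems, tumor_values))
  em <- expression_matrix(tv, rep("tumor", ncol(tv)), "PANCAN", panel)
  pairwise_correlation(em, panel)
}
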