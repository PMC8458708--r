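#' Assemble per-cancer evidence flags and the candidate call
#'
#' Combines the scoring stages into three boolean treatment-related
#' characteristics per cancer and calls a cancer a combination-therapy
#' candidate when at least two hold:
#'
#' * `char_expression` -- the expression category is `high` (>= 4
#'   lenvatinib and >= 2 ICB targets significantly up);
#' * `char_alteration` -- the cancer is in the top-m total
#'   mutational-load set AND its lenvatinib driver frequency reaches the
#'   9% flag (conjunction: high load alone or drivers alone do not
#'   qualify). The PD-L1 amplification >= 2% flag is carried in the
#'   table for reference but does not enter the characteristic;
#' * `char_cd8` -- the CD8+ T-cell depletion box rule holds.
#'
#' A cancer missing from a stage input gets `FALSE` for that flag (with
#' a warning): absent evidence is never counted as positive.
#'
#' @param expression_high Cancer codes whose expression category is
#'   high.
#' @param top_load Cancer codes in the top-m mutational-load set.
#' @param lenvatinib_driver_high Cancer codes with lenvatinib driver
#'   frequency >= 9%.
#' @param cd8_negative Cancer codes passing the CD8 box rule.
#' @param pdl1_driver_high Optional codes with CD274 amplification at
#'   or above 2% (reported, not scored).
#' @param cancers Universe of cancers for the table; defaults to the
#'   union of all inputs.
#' @param min_characteristics Candidate threshold, default 2.
#' @return Object of class `evidence_table`: data.frame in alphabetical
#'   cancer order with the three flags, `pdl1_driver_high`,
#'   `n_characteristics` and `candidate`.
#' @examples
#' crit <- read_criteria(system.file("extdata", "paper_criteria.json",
#'                                   package = "icblenv"))
#' ev <- do.call(build_evidence, crit)
#' candidates(ev)
#' @export
build_evidence <- function(expression_high = character(0),
                           top_load = character(0),
                           lenvatinib_driver_high = character(0),
                           cd8_negative = character(0),
                           pdl1_driver_high = character(0),
                           cancers = NULL,
                           min_characteristics = 2) {
  up <- function(x) toupper(as.character(x))
  expression_high <- up(expression_high)
  top_load <- up(top_load)
  lenvatinib_driver_high <- up(lenvatinib_driver_high)
  cd8_negative <- up(cd8_negative)
  pdl1_driver_high <- up(pdl1_driver_high)
  if (is.null(cancers))
    cancers <- union(union(expression_high, top_load),
                     union(union(lenvatinib_driver_high, cd8_negative),
                           pdl1_driver_high))
  cancers <- sort(unique(up(cancers)))
  ev <- data.frame(
    cancer_type = cancers,
    char_expression = cancers %in% expression_high,
    char_alteration = cancers %in% top_load &
      cancers %in% lenvatinib_driver_high,
    char_cd8 = cancers %in% cd8_negative,
    pdl1_driver_high = cancers %in% pdl1_driver_high)
  ev$n_characteristics <- rowSums(ev[, c("char_expression",
                                         "char_alteration", "char_cd8")])
  ev$candidate <- ev$n_characteristics >= min_characteristics
  class(ev) <- c("evidence_table", "data.frame")
  ev
}

#' Build the evidence table from stage outputs
#'
#' Convenience wrapper taking the objects the scoring stages return
#' directly: expression categories ([classify_expression()] rows bound
#' together), the mutational-load ranking
#' ([total_target_mutational_load()]), the driver flags
#' ([flag_driver_enriched()]) and a named logical vector of CD8 box
#' flags per cancer. Stages passed as `NULL` contribute no positive
#' flags (warned).
#'
#' @param expr_cats data.frame of expression categories or NULL.
#' @param load_table Ranked load table or NULL.
#' @param driver_flags Driver-flag table or NULL.
#' @param cd8_flags Named logical vector or NULL.
#' @param ... Passed to [build_evidence()].
#' @return An `evidence_table`.
#' @export
build_evidence_from_stages <- function(expr_cats = NULL, load_table = NULL,
                                       driver_flags = NULL,
                                       cd8_flags = NULL, ...) {
  miss <- c("expression", "alteration load", "driver flags", "CD8")[
    vapply(list(expr_cats, load_table, driver_flags, cd8_flags),
           is.null, logical(1))]
  if (length(miss))
    warning("stage(s) missing, flags default to FALSE: ",
            paste(miss, collapse = ", "))
  cancers <- unique(c(
    if (!is.null(expr_cats)) expr_cats$cancer_type,
    if (!is.null(load_table)) load_table$cancer_type,
    if (!is.null(driver_flags)) driver_flags$cancer_type,
    if (!is.null(cd8_flags)) names(cd8_flags)))
  build_evidence(
    expression_high = if (is.null(expr_cats)) character(0)
    else expr_cats$cancer_type[expr_cats$category == "high"],
    top_load = if (is.null(load_table)) character(0)
    else attr(load_table, "top_set"),
    lenvatinib_driver_high = if (is.null(driver_flags)) character(0)
    else driver_flags$cancer_type[driver_flags$lenvatinib_driver_high],
    cd8_negative = if (is.null(cd8_flags)) character(0)
    else names(cd8_flags)[cd8_flags],
    pdl1_driver_high = if (is.null(driver_flags)) character(0)
    else driver_flags$cancer_type[driver_flags$pdl1_driver_high],
    cancers = cancers, ...)
}

#' Candidate cancers from an evidence table
#' @param evidence An `evidence_table`.
#' @return Character vector of candidate cancer codes (alphabetical).
#' @export
candidates <- function(evidence) {
  evidence$cancer_type[evidence$candidate]
}

#' Human-readable justification for one cancer's call
#'
#' @param evidence An `evidence_table`.
#' @param cancer Cancer code present in the table.
#' @return Character vector of justification lines (also printed).
#' @export
explain_evidence <- function(evidence, cancer) {
  cancer <- toupper(cancer)
  row <- evidence[evidence$cancer_type == cancer, , drop = FALSE]
  if (nrow(row) == 0) stop("unknown cancer: ", cancer)
  lines <- c(
    sprintf("%s: %d of 3 characteristics%s", cancer, row$n_characteristics,
            if (row$candidate) " -- candidate for ICB + lenvatinib" else ""),
    sprintf("  [%s] target-gene expression high (>=4 lenvatinib and >=2 ICB targets up, p < 0.05)",
            if (row$char_expression) "x" else " "),
    sprintf("  [%s] high mutational load (top-m set) AND lenvatinib driver frequency >= 9%%",
            if (row$char_alteration) "x" else " "),
    sprintf("  [%s] lenvatinib targets negatively correlated with CD8+ T-cell infiltration (>=8 negative, >=5 at r <= -0.15)",
            if (row$char_cd8) "x" else " "),
    sprintf("  (PD-L1 amplification >= 2%%: %s; reported, not scored)",
            if (row$pdl1_driver_high) "yes" else "no"))
  cat(lines, sep = "\n")
  invisible(lines)
}
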