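ALTERATION_CLASSES <- c("missense", "truncating", "inframe", "fusion",
                        "amplification", "deep_deletion", "other")

#' Validate a MAF-like alteration table
#'
#' @param records data.frame with columns `sample_id`, `cancer_type`,
#'   `gene`, `alteration_class` and optionally `protein_change`. Gene
#'   symbols are normalised through the panel alias map.
#' @param panel A [target_panel()].
#' @return The validated table with canonical gene symbols.
#' @export
alteration_records <- function(records, panel = target_panel()) {
  need <- c("sample_id", "cancer_type", "gene", "alteration_class")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("alteration table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(records$alteration_class), ALTERATION_CLASSES)
  if (length(bad))
    stop("unknown alteration class(es): ", paste(bad, collapse = ", "))
  records$gene <- resolve_symbol(records$gene, panel)
  records$cancer_type <- toupper(records$cancer_type)
  if (is.null(records$protein_change))
    records$protein_change <- NA_character_
  records
}

#' Build a driver-annotation catalog
#'
#' Each entry marks a set of alterations of one gene as oncogenic
#' drivers, in the style of curated resources (OncoKB / Cancer
#' Hotspots): `match_type = "protein_change"` matches one hotspot
#' literal (e.g. "S249C"), `"class"` matches every record of that
#' alteration class (e.g. any amplification of CD274), and `"any"`
#' matches all records of the gene. Records matching no entry are
#' variants of unknown significance (VUS) and are treated as likely
#' passengers.
#'
#' @param entries data.frame with columns `gene`, `match_type`
#'   (`any`/`class`/`protein_change`) and `value` (empty for `any`).
#' @param panel A [target_panel()].
#' @return Object of class `driver_catalog`.
#' @export
driver_catalog <- function(entries, panel = target_panel()) {
  if (nrow(entries) == 0) {
    entries <- data.frame(gene = character(0), match_type = character(0),
                          value = character(0))
  } else {
    stopifnot(all(c("gene", "match_type") %in% names(entries)))
    bad <- setdiff(entries$match_type, c("any", "class", "protein_change"))
    if (length(bad)) stop("unknown match_type: ", paste(bad, collapse = ", "))
    entries$gene <- resolve_symbol(entries$gene, panel)
    if (is.null(entries$value)) entries$value <- NA_character_
  }
  structure(list(entries = entries), class = "driver_catalog")
}

#' Keep only driver alterations
#'
#' Filters a record table down to the records matching a driver-catalog
#' entry; everything else is excluded as a likely passenger (VUS). Order
#' is preserved and the operation is idempotent.
#'
#' @param records Table from [alteration_records()].
#' @param catalog A [driver_catalog()].
#' @param panel A [target_panel()].
#' @return The driver subset of `records`.
#' @export
filter_drivers <- function(records, catalog, panel = target_panel()) {
  records <- alteration_records(records, panel)
  e <- catalog$entries
  if (nrow(records) == 0 || nrow(e) == 0)
    return(records[integer(0), , drop = FALSE])
  keep <- vapply(seq_len(nrow(records)), function(i) {
    g <- e[e$gene == records$gene[i], , drop = FALSE]
    any(g$match_type == "any") ||
      any(g$match_type == "class" & g$value == records$alteration_class[i]) ||
      (!is.na(records$protein_change[i]) &&
         any(g$match_type == "protein_change" &
               g$value == records$protein_change[i]))
  }, logical(1))
  records[keep, , drop = FALSE]
}

#' Panel genes with annotated driver potential
#'
#' FLT1 (VEGFR1), FLT4 (VEGFR3), PDCD1, LAG3 and CTLA4 carry
#' insufficient evidence of driving alterations in the annotation
#' resources and are removed, leaving 10 genes; CD274 (PD-L1) is the
#' only ICB target retained.
#'
#' @param panel A [target_panel()].
#' @return Character vector of 10 canonical symbols.
#' @export
eligible_driver_genes <- function(panel = target_panel()) {
  setdiff(panel_genes(panel), c("FLT1", "FLT4", "PDCD1", "LAG3", "CTLA4"))
}

#' Altered-sample frequency of a gene set per cancer
#'
#' Portal-style "altered / profiled" semantics: a sample counts once no
#' matter how many qualifying records it carries, so duplicated records
#' never change a frequency.
#'
#' @param records Alteration table (typically driver-filtered).
#' @param gene_set Canonical symbols defining the set.
#' @param profiled Named integer vector, cancer code -> number of
#'   profiled samples; must cover every cancer in `records`.
#' @param classes Optional restriction to alteration classes (e.g.
#'   `"amplification"`).
#' @param panel A [target_panel()].
#' @return data.frame with `cancer_type`, `altered_samples`, `profiled`,
#'   `frequency` (in \[0, 1\]), one row per cancer in `profiled`.
#' @export
set_driver_frequency <- function(records, gene_set, profiled,
                                 classes = NULL, panel = target_panel()) {
  records <- alteration_records(records, panel)
  if (is.null(names(profiled)) || any(profiled < 1))
    stop("profiled must be a named vector of positive counts")
  missing <- setdiff(unique(records$cancer_type), names(profiled))
  if (length(missing))
    stop("no profiled count for cancer(s): ", paste(missing, collapse = ", "))
  r <- records[records$gene %in% gene_set, , drop = FALSE]
  if (!is.null(classes))
    r <- r[r$alteration_class %in% classes, , drop = FALSE]
  hits <- tapply(r$sample_id, r$cancer_type,
                 function(s) length(unique(s)))
  ct <- names(profiled)
  altered <- as.integer(ifelse(is.na(hits[ct]), 0L, hits[ct]))
  data.frame(cancer_type = ct, altered_samples = altered,
             profiled = as.integer(profiled),
             frequency = altered / as.integer(profiled),
             row.names = NULL)
}

#' Driver-enrichment flags per cancer
#'
#' Applies the printed frequency thresholds to driver-filtered records:
#' `lenvatinib_driver_high` when drivers in the eligible lenvatinib
#' targets reach >= 9% of profiled samples (inclusive), and
#' `pdl1_driver_high` when CD274 amplification drivers reach >= 2%
#' (inclusive; the CD274 drivers are amplifications in all cases, so
#' only amplification records are counted).
#'
#' @param driver_records Driver-filtered table from [filter_drivers()].
#' @param profiled Named profiled-sample counts per cancer.
#' @param lenv_threshold,pdl1_threshold Inclusive frequency thresholds,
#'   defaults 0.09 and 0.02.
#' @param panel A [target_panel()].
#' @return data.frame per cancer: `cancer_type`, `lenv_driver_freq`,
#'   `pdl1_amp_freq`, `lenvatinib_driver_high`, `pdl1_driver_high`.
#' @export
flag_driver_enriched <- function(driver_records, profiled,
                                 lenv_threshold = 0.09,
                                 pdl1_threshold = 0.02,
                                 panel = target_panel()) {
  elig <- eligible_driver_genes(panel)
  lenv <- set_driver_frequency(driver_records,
                               intersect(elig, panel$lenvatinib_targets),
                               profiled, panel = panel)
  pdl1 <- set_driver_frequency(driver_records, "CD274", profiled,
                               classes = "amplification", panel = panel)
  data.frame(cancer_type = lenv$cancer_type,
             lenv_driver_freq = lenv$frequency,
             pdl1_amp_freq = pdl1$frequency,
             lenvatinib_driver_high = lenv$frequency >= lenv_threshold,
             pdl1_driver_high = pdl1$frequency >= pdl1_threshold)
}

#' Total mutational load of the target panel per cancer
#'
#' Fraction of profiled samples carrying at least one alteration of any
#' class -- driver or VUS -- in any of the 15 panel genes, ranked
#' descending (ties broken alphabetically by cancer code). The top `m`
#' cancers form the high-load set used by the integration stage.
#' Restricting to drivers only is available via `drivers_only` together
#' with a catalog.
#'
#' @param records Full (unfiltered) alteration table.
#' @param profiled Named profiled-sample counts.
#' @param panel A [target_panel()].
#' @param top_m Size of the high-load set, default 16.
#' @param drivers_only If TRUE, filter through `catalog` first.
#' @param catalog A [driver_catalog()], required when `drivers_only`.
#' @return data.frame ranked by load with columns `cancer_type`,
#'   `altered_samples`, `profiled`, `load`, `rank`, `in_top`; the top
#'   set is also in `attr(, "top_set")`.
#' @export
total_target_mutational_load <- function(records, profiled,
                                         panel = target_panel(),
                                         top_m = 16, drivers_only = FALSE,
                                         catalog = NULL) {
  if (drivers_only) {
    if (is.null(catalog)) stop("drivers_only requires a catalog")
    records <- filter_drivers(records, catalog, panel)
  }
  tab <- set_driver_frequency(records, panel_genes(panel), profiled,
                              panel = panel)
  names(tab)[names(tab) == "frequency"] <- "load"
  tab <- tab[order(-tab$load, tab$cancer_type), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$in_top <- tab$rank <= top_m
  rownames(tab) <- NULL
  attr(tab, "top_set") <- tab$cancer_type[tab$in_top]
  tab
}

#' Alteration-class composition per gene and per cancer
#'
#' Normalised proportions of each alteration class, grouped per gene and
#' per cancer type; proportions sum to 1 within each group.
#'
#' @param records Alteration table.
#' @param panel A [target_panel()].
#' @return list of two data.frames, `by_gene` and `by_cancer`, each with
#'   columns group, `alteration_class`, `count`, `proportion`.
#' @export
summarize_alteration_composition <- function(records,
                                             panel = target_panel()) {
  comp <- function(key) {
    if (nrow(records) == 0)
      return(data.frame(group = character(0),
                        alteration_class = character(0),
                        count = integer(0), proportion = numeric(0)))
    tab <- as.data.frame(table(group = records[[key]],
                               alteration_class = records$alteration_class),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0, , drop = FALSE]
    tot <- tapply(tab$Freq, tab$group, sum)
    data.frame(group = tab$group, alteration_class = tab$alteration_class,
               count = tab$Freq,
               proportion = tab$Freq / as.numeric(tot[tab$group]),
               row.names = NULL)
  }
  if (nrow(records) > 0) records <- alteration_records(records, panel)
  list(by_gene = comp("gene"), by_cancer = comp("cancer_type"))
}
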