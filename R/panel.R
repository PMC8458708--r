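#' Target-gene panel for ICB plus lenvatinib
#'
#' Lenvatinib is a multi-target tyrosine-kinase inhibitor of VEGFR1-3
#' (FLT1, KDR, FLT4), FGFR1-4, PDGFRA/B, KIT and RET; immune-checkpoint
#' blockade (ICB) acts on PD-1 (PDCD1), PD-L1 (CD274), LAG3 and CTLA4.
#' The panel carries the 15 canonical HGNC symbols split into the two
#' therapy arms, plus an alias map so receptor names (VEGFR2, PD-L1, ...)
#' are accepted anywhere a gene symbol is.
#'
#' @param path Path to a panel TSV with columns `canonical`, `arm`,
#'   `aliases` (comma-separated, may be empty). Defaults to the bundled
#'   panel resource.
#' @return An object of class `target_panel`: a list with character
#'   vectors `lenvatinib_targets` (11), `icb_targets` (4) and a named
#'   character vector `alias_map` (upper-cased alias -> canonical).
#' @examples
#' p <- target_panel()
#' resolve_symbol("VEGFR2", p)
#' @export
target_panel <- function(path = system.file("extdata", "panel.tsv",
                                            package = "icblenv")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", fill = TRUE)
  stopifnot(all(c("canonical", "arm") %in% names(tab)))
  if (is.null(tab$aliases)) tab$aliases <- ""
  lenv <- tab$canonical[tab$arm == "lenvatinib"]
  icb <- tab$canonical[tab$arm == "icb"]
  all_genes <- c(lenv, icb)
  if (anyDuplicated(all_genes))
    stop("panel genes must be unique")
  alias_map <- character(0)
  for (i in seq_len(nrow(tab))) {
    al <- strsplit(tab$aliases[i], ",", fixed = TRUE)[[1]]
    al <- trimws(al[nzchar(trimws(al))])
    if (length(al))
      alias_map[toupper(al)] <- tab$canonical[i]
  }
  # canonical names resolve to themselves
  alias_map[toupper(all_genes)] <- all_genes
  structure(list(lenvatinib_targets = lenv,
                 icb_targets = icb,
                 alias_map = alias_map),
            class = "target_panel")
}

#' @export
print.target_panel <- function(x, ...) {
  cat("Target panel:", length(x$lenvatinib_targets), "lenvatinib +",
      length(x$icb_targets), "ICB genes\n")
  cat("  lenvatinib:", paste(x$lenvatinib_targets, collapse = " "), "\n")
  cat("  ICB:       ", paste(x$icb_targets, collapse = " "), "\n")
  invisible(x)
}

#' All 15 panel genes
#'
#' @param panel A [target_panel()].
#' @return Character vector of the canonical symbols, lenvatinib arm first.
#' @export
panel_genes <- function(panel = target_panel()) {
  c(panel$lenvatinib_targets, panel$icb_targets)
}

#' Resolve a gene symbol or alias to its canonical panel symbol
#'
#' Matching is case-insensitive and tolerant of surrounding whitespace.
#' Vectorised over `name`.
#'
#' @param name Gene symbol(s) or registered alias(es).
#' @param panel A [target_panel()].
#' @return Canonical symbol(s).
#' @examples
#' resolve_symbol(c("VEGFR2", "PD-L1", "KDR"))
#' @export
resolve_symbol <- function(name, panel = target_panel()) {
  key <- toupper(trimws(as.character(name)))
  if (any(!nzchar(key)))
    stop("unknown gene: empty symbol")
  hit <- panel$alias_map[key]
  if (anyNA(hit))
    stop("unknown gene: ", paste(unique(name[is.na(hit)]), collapse = ", "))
  unname(hit)
}

#' Which therapy arm a panel gene belongs to
#'
#' @param gene Canonical symbol(s) or alias(es).
#' @param panel A [target_panel()].
#' @return `"lenvatinib"` or `"icb"` per gene.
#' @export
panel_membership <- function(gene, panel = target_panel()) {
  g <- resolve_symbol(gene, panel)
  ifelse(g %in% panel$lenvatinib_targets, "lenvatinib", "icb")
}

#' TCGA cancer-type codes
#'
#' Convenience table of the TCGA study abbreviations used across the
#' pan-cancer stages. Cancer-type codes elsewhere in the package are free
#' strings; this table is not an enum.
#'
#' @return A data.frame with columns `code` and `label`.
#' @export
tcga_codes <- function() {
  utils::read.delim(system.file("extdata", "tcga_codes.tsv",
                                package = "icblenv"),
                    stringsAsFactors = FALSE)
}
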