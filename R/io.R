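.read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, fill = TRUE,
                           check.names = FALSE, na.strings = c("NA", ""))
  if (nrow(tab) == 0) stop("empty table: ", path)
  tab
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trial-cohort study table
#'
#' TSV/CSV (sniffed by extension) with header columns `study_id`,
#' `tumor_type`, `n`, `orr_pct` and optionally `dcr_pct`; extra columns
#' are preserved and ignored. Percentages must lie in \[0, 100\] (blank
#' = missing); `n` must be a positive integer. The bundled
#' `table1.tsv` resource transcribes the 20 published trial cohorts of
#' ICB plus lenvatinib.
#'
#' @param path Path to the file.
#' @return Validated data.frame, row order preserved.
#' @examples
#' trials <- read_study_table(system.file("extdata", "table1.tsv",
#'                                        package = "icblenv"))
#' nrow(trials)
#' @export
read_study_table <- function(path) {
  tab <- .read_table(path)
  need <- c("study_id", "tumor_type", "n", "orr_pct")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("study table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(tab$dcr_pct)) tab$dcr_pct <- NA_real_
  for (col in c("n", "orr_pct", "dcr_pct")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " in row ", bad[1])
    tab[[col]] <- v
  }
  if (any(is.na(tab$n) | tab$n < 1 | tab$n != round(tab$n)))
    stop("n must be a positive integer in every row")
  for (col in c("orr_pct", "dcr_pct")) {
    bad <- which(!is.na(tab[[col]]) & (tab[[col]] < 0 | tab[[col]] > 100))
    if (length(bad))
      stop(col, " outside [0, 100] in row ", bad[1])
  }
  tab$tumor_type <- toupper(tab$tumor_type)
  tab
}

#' Read a wide expression matrix with a sample-annotation file
#'
#' The expression file is a wide TSV/CSV: first column gene symbols,
#' remaining columns samples, TPM-like values. The annotation file has
#' columns `sample` and `condition` (`tumor`/`normal`).
#'
#' @param path Expression file.
#' @param annotation_path Sample-annotation file.
#' @param cancer_type Cancer code for the matrix.
#' @param panel A [target_panel()].
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, annotation_path, cancer_type,
                                   panel = target_panel()) {
  tab <- .read_table(path)
  ann <- .read_table(annotation_path)
  stopifnot(all(c("sample", "condition") %in% names(ann)))
  genes <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- genes
  idx <- match(colnames(vals), ann$sample)
  if (anyNA(idx))
    stop("sample(s) missing from annotation: ",
         paste(colnames(vals)[is.na(idx)], collapse = ", "))
  expression_matrix(vals, ann$condition[idx], cancer_type, panel)
}

#' Write an expression matrix (and its annotation) to TSV
#'
#' @param em An [expression_matrix()].
#' @param path Expression TSV path.
#' @param annotation_path Annotation TSV path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(em, path, annotation_path) {
  out <- data.frame(gene = rownames(em$values), em$values,
                    check.names = FALSE)
  .write_tsv(out, path)
  .write_tsv(data.frame(sample = colnames(em$values),
                        condition = em$condition), annotation_path)
  invisible(path)
}

#' Read a MAF-like alteration table
#' @param path TSV/CSV with columns `sample_id`, `cancer_type`, `gene`,
#'   `alteration_class`, optional `protein_change`.
#' @param panel A [target_panel()].
#' @return Validated record table (see [alteration_records()]).
#' @export
read_alteration_table <- function(path, panel = target_panel()) {
  alteration_records(.read_table(path), panel)
}

#' Read a driver-annotation catalog
#' @param path TSV/CSV with columns `gene`, `match_type`, `value`.
#' @param panel A [target_panel()].
#' @return A [driver_catalog()].
#' @export
read_driver_catalog <- function(path, panel = target_panel()) {
  driver_catalog(.read_table(path), panel)
}

#' Read per-cancer profiled-sample counts
#' @param path TSV/CSV with columns `cancer_type`, `profiled`.
#' @return Named integer vector.
#' @export
read_profiled_counts <- function(path) {
  tab <- .read_table(path)
  stopifnot(all(c("cancer_type", "profiled") %in% names(tab)))
  stats::setNames(as.integer(tab$profiled), toupper(tab$cancer_type))
}

#' Read an infiltration table
#' @param path TSV/CSV: first column sample ids, remaining columns cell
#'   types, optional `purity` column.
#' @param cancer_type Cancer code.
#' @return An [infiltration_table()].
#' @export
read_infiltration_table <- function(path, cancer_type) {
  tab <- .read_table(path)
  ids <- tab[[1]]
  tab <- tab[, -1, drop = FALSE]
  purity <- NULL
  if ("purity" %in% names(tab)) {
    purity <- tab$purity
    tab <- tab[, names(tab) != "purity", drop = FALSE]
  }
  vals <- as.matrix(tab)
  rownames(vals) <- ids
  infiltration_table(vals, cancer_type, purity)
}

#' Read a survival table
#' @param path TSV/CSV with columns `sample_id`, `time`, `event` and
#'   optionally `covariate`.
#' @return Validated data.frame.
#' @export
read_survival_table <- function(path) {
  tab <- .read_table(path)
  stopifnot(all(c("sample_id", "time", "event") %in% names(tab)))
  if (any(tab$time < 0) || !all(tab$event %in% c(0, 1)))
    stop("time must be >= 0 and event in {0, 1}")
  tab
}

#' Read a per-characteristic criteria file
#'
#' JSON listing, per characteristic, the cancer codes satisfying it
#' (keys `expression_high`, `top_mutational_load`,
#' `lenvatinib_driver_high`, `pdl1_driver_high`, `cd8_negative`). The
#' bundled `paper_criteria.json` resource transcribes the published
#' per-criterion lists; feeding it to [build_evidence()] reproduces the
#' nine-candidate worked example.
#'
#' @param path JSON path.
#' @return Named list of character vectors with names matching the
#'   arguments of [build_evidence()].
#' @export
read_criteria <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(expression_high = as.character(j$expression_high),
       top_load = as.character(j$top_mutational_load),
       lenvatinib_driver_high = as.character(j$lenvatinib_driver_high),
       cd8_negative = as.character(j$cd8_negative),
       pdl1_driver_high = as.character(j$pdl1_driver_high))
}

#' Default pipeline parameters
#'
#' All defaults equal the published constants: alpha 0.05; positive /
#' strong correlation thresholds 0.1 and 0.15; lenvatinib / PD-L1
#' driver-frequency thresholds 0.09 and 0.02; top-m 16; I2 cutoff 50;
#' double-arcsine transform; 95% CI.
#'
#' @param ... Overrides for any listed parameter.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(alpha = 0.05, cor_threshold = 0.1, strong_threshold = 0.15,
            lenv_threshold = 0.09, pdl1_threshold = 0.02, top_m = 16,
            i2_cutoff = 50, level = 0.95, transform = "double_arcsine",
            pan_cancer_mode = "pooled", min_characteristics = 2)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  utils::modifyList(p, over)
}

#' Run the full evidence-integration pipeline
#'
#' Executes whichever stages have inputs: meta-analysis of the study
#' table (ORR and, when present, DCR); per-cancer differential
#' expression, category classification and target-gene correlation;
#' driver filtering, frequency flags and mutational load; immune
#' infiltration correlation, CD8 box flags and survival classification;
#' and the final evidence integration. Alternatively a `criteria` list
#' (see [read_criteria()]) bypasses the scoring stages for the
#' integration step.
#'
#' @param study_table Study data.frame (or NULL).
#' @param expression Named list of [expression_matrix()] per cancer (or
#'   NULL).
#' @param alterations list with `records`, `catalog`, `profiled` (or
#'   NULL).
#' @param infiltration Named list of [infiltration_table()] (or NULL).
#' @param survival Named list of survival data.frames with a
#'   `covariate` column (or NULL).
#' @param criteria Criteria list overriding the scoring stages for
#'   integration (or NULL).
#' @param params [pipeline_params()].
#' @param outdir Optional directory; when given, stage outputs are
#'   written as TSV/JSON plus a `manifest.json` with the parameters and
#'   per-stage row counts.
#' @param panel A [target_panel()].
#' @return list with elements `meta` (list of `pooled_result`),
#'   `expression` (DE tables + `categories`), `correlation` (matrices +
#'   `ranking`), `alterations` (flags + `load`), `immune` (correlations,
#'   `cd8_flags`, `prognosis`), `evidence` and `candidates`; stages not
#'   run are NULL.
#' @export
run_pipeline <- function(study_table = NULL, expression = NULL,
                         alterations = NULL, infiltration = NULL,
                         survival = NULL, criteria = NULL,
                         params = pipeline_params(), outdir = NULL,
                         panel = target_panel()) {
  out <- list()

  if (!is.null(study_table)) {
    out$meta <- list(ORR = meta_analyze(study_table, "ORR",
                                        transform = params$transform,
                                        i2_cutoff = params$i2_cutoff,
                                        level = params$level))
    if (any(!is.na(study_table$dcr_pct)))
      out$meta$DCR <- meta_analyze(study_table, "DCR",
                                   transform = params$transform,
                                   i2_cutoff = params$i2_cutoff,
                                   level = params$level)
  }

  if (!is.null(expression)) {
    de <- lapply(expression, differential_expression, alpha = params$alpha)
    cats <- do.call(rbind, lapply(de, classify_expression, panel = panel))
    rownames(cats) <- NULL
    cms <- lapply(expression, pairwise_correlation, panel = panel)
    counts <- data.frame(
      cancer_type = vapply(cms, attr, "", "cancer_type"),
      positive_pair_count = vapply(cms, count_positive_pairs,
                                   0, threshold = params$cor_threshold))
    out$expression <- list(de = de, categories = cats)
    out$correlation <- list(matrices = cms,
                            ranking = rank_cancers_by_correlation(counts))
  }

  if (!is.null(alterations)) {
    drv <- filter_drivers(alterations$records, alterations$catalog, panel)
    flags <- flag_driver_enriched(drv, alterations$profiled,
                                  lenv_threshold = params$lenv_threshold,
                                  pdl1_threshold = params$pdl1_threshold,
                                  panel = panel)
    load <- total_target_mutational_load(alterations$records,
                                         alterations$profiled,
                                         panel = panel,
                                         top_m = params$top_m)
    out$alterations <- list(drivers = drv, flags = flags, load = load,
                            composition =
                              summarize_alteration_composition(
                                alterations$records, panel))
  }

  if (!is.null(infiltration) && !is.null(expression)) {
    shared <- intersect(names(infiltration), names(expression))
    corrs <- lapply(shared, function(ct)
      gene_infiltration_correlation(expression[[ct]], infiltration[[ct]],
                                    panel = panel))
    names(corrs) <- shared
    cd8 <- vapply(corrs, function(gc)
      cd8_box_flag(gc$r[gc$cell_type == "CD8_T"]), logical(1))
    out$immune <- list(correlations = corrs, cd8_flags = cd8)
    if (!is.null(survival)) {
      prog <- lapply(intersect(names(survival), shared), function(ct) {
        s <- survival[[ct]]
        cbind(cancer_type = ct,
              cox_classify(s$time, s$event, s$covariate,
                           alpha = params$alpha))
      })
      out$immune$prognosis <- do.call(rbind, prog)
    }
  }

  if (!is.null(criteria)) {
    out$evidence <- do.call(build_evidence,
                            c(criteria,
                              list(min_characteristics =
                                     params$min_characteristics)))
  } else if (!is.null(out$expression) || !is.null(out$alterations) ||
             !is.null(out$immune)) {
    out$evidence <- build_evidence_from_stages(
      expr_cats = out$expression$categories,
      load_table = out$alterations$load,
      driver_flags = out$alterations$flags,
      cd8_flags = out$immune$cd8_flags,
      min_characteristics = params$min_characteristics)
  }
  if (!is.null(out$evidence)) out$candidates <- candidates(out$evidence)

  if (!is.null(outdir)) .write_pipeline_outputs(out, params, outdir)
  out
}

.write_pipeline_outputs <- function(out, params, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "icblenv",
                   version = as.character(utils::packageVersion("icblenv")),
                   params = params, stages = list())
  if (!is.null(out$meta)) {
    for (ep in names(out$meta)) {
      m <- out$meta[[ep]]
      jsonlite::write_json(
        list(endpoint = m$endpoint, k = m$k, estimate = m$estimate,
             ci_low = m$ci_low, ci_high = m$ci_high, model = m$model,
             Q = m$het$Q, df = m$het$df, I2 = m$het$I2, tau2 = m$het$tau2),
        file.path(outdir, paste0("meta_", tolower(ep), ".json")),
        auto_unbox = TRUE, digits = NA)
    }
    manifest$stages$meta <- names(out$meta)
  }
  if (!is.null(out$expression)) {
    .write_tsv(out$expression$categories,
               file.path(outdir, "expression_categories.tsv"))
    manifest$stages$expression <- nrow(out$expression$categories)
  }
  if (!is.null(out$correlation)) {
    .write_tsv(out$correlation$ranking,
               file.path(outdir, "correlation_ranking.tsv"))
    manifest$stages$correlation <- nrow(out$correlation$ranking)
  }
  if (!is.null(out$alterations)) {
    .write_tsv(out$alterations$flags,
               file.path(outdir, "driver_flags.tsv"))
    .write_tsv(out$alterations$load,
               file.path(outdir, "mutational_load.tsv"))
    manifest$stages$alterations <- nrow(out$alterations$flags)
  }
  if (!is.null(out$immune)) {
    .write_tsv(data.frame(cancer_type = names(out$immune$cd8_flags),
                          cd8_box = out$immune$cd8_flags),
               file.path(outdir, "cd8_flags.tsv"))
    if (!is.null(out$immune$prognosis))
      .write_tsv(out$immune$prognosis,
                 file.path(outdir, "prognosis.tsv"))
    manifest$stages$immune <- length(out$immune$cd8_flags)
  }
  if (!is.null(out$evidence)) {
    .write_tsv(as.data.frame(out$evidence),
               file.path(outdir, "evidence.tsv"))
    jsonlite::write_json(out$candidates,
                         file.path(outdir, "candidates.json"))
    manifest$stages$integration <- nrow(out$evidence)
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
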