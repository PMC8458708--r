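#' Derive a child seed from a master seed
#'
#' All generators draw from R's default Mersenne-Twister stream seeded
#' with `set.seed()`. A master seed expands to per-stage child seeds by
#' the fixed affine map `(seed + k * 1013904223) mod (2^31 - 1)`
#' (computed in double precision, exact far below 2^53), so stages can
#' be regenerated independently and deterministically.
#'
#' @param seed Master seed (non-negative integer).
#' @param k Stage index.
#' @return Integer child seed.
#' @export
child_seed <- function(seed, k) {
  as.integer((as.double(seed) + k * 1013904223) %% 2147483647)
}

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

#' Simulate a TPM-like tumor/normal expression matrix
#'
#' log2-expression is multivariate normal: normals centred at
#' `base_mean` with sd `base_sd` and inter-gene correlation
#' `correlation`; tumors additionally shifted by log2(`fold_change`)
#' per gene. Values are 2^z, so they are log-normal on the natural
#' scale, non-negative and TPM-like.
#'
#' @param cancer_type Cancer code for the matrix.
#' @param n_tumor,n_normal Samples per condition (defaults 100 / 50,
#'   TCGA-like proportions).
#' @param genes Gene symbols; default the 15-gene panel.
#' @param base_mean,base_sd Baseline log2 location and scale (defaults
#'   5 and 1).
#' @param fold_change Multiplicative tumor shift per gene: scalar or
#'   named vector (unnamed genes default to 1).
#' @param correlation Optional gene-correlation matrix (Gaussian
#'   copula on the log2 scale); must be positive semi-definite.
#'   Default independent genes.
#' @param seed Seed; all randomness flows from it.
#' @param panel A [target_panel()].
#' @return An [expression_matrix()].
#' @export
simulate_expression <- function(cancer_type, n_tumor = 100, n_normal = 50,
                                genes = panel_genes(panel),
                                base_mean = 5, base_sd = 1,
                                fold_change = 1, correlation = NULL,
                                seed = 1, panel = target_panel()) {
  set.seed(seed)
  g <- length(genes)
  fc <- rep(1, g); names(fc) <- genes
  if (!is.null(names(fold_change))) {
    fc[names(fold_change)] <- fold_change
  } else fc[] <- fold_change
  mu <- rep(base_mean, g)
  sdv <- rep(base_sd, length.out = g)
  n <- n_tumor + n_normal
  if (is.null(correlation)) {
    z <- matrix(stats::rnorm(g * n, mu, sdv), nrow = g)
  } else {
    correlation <- as.matrix(correlation)
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("gene correlation matrix is not positive semi-definite")
    Sigma <- diag(sdv) %*% correlation %*% diag(sdv)
    z <- t(MASS::mvrnorm(n, mu, Sigma))
  }
  cond <- rep(c("tumor", "normal"), c(n_tumor, n_normal))
  z[, cond == "tumor"] <- z[, cond == "tumor"] + log2(fc)
  vals <- 2^z
  rownames(vals) <- genes
  colnames(vals) <- sprintf("%s_%s%03d", cancer_type,
                            ifelse(cond == "tumor", "T", "N"), seq_len(n))
  expression_matrix(vals, cond, cancer_type, panel)
}

#' Simulate MAF-like alteration records with a driver catalog
#'
#' Per sample and gene an alteration occurs with probability
#' `rates[gene]` (Bernoulli, independent); its class is drawn from
#' `class_probs`, and mutation classes (missense/truncating/inframe)
#' receive a protein change drawn from a small per-gene hotspot pool.
#' A fraction `driver_fraction` of the distinct (gene, protein_change)
#' and (gene, class) keys observed is entered into the driver catalog,
#' so `driver_fraction = 1` makes [filter_drivers()] the identity on
#' the generated records.
#'
#' @param cancer_type Cancer code.
#' @param profiled Number of profiled samples (default 500).
#' @param genes Genes at risk; default the eligible driver genes.
#' @param rates Per-sample, per-gene alteration probability: scalar or
#'   named vector (default 0.01).
#' @param class_probs Named probabilities over the alteration classes.
#' @param driver_fraction Probability that an observed alteration key is
#'   catalogued as a driver (default 0.7).
#' @param seed Seed.
#' @param panel A [target_panel()].
#' @return list with `records` (MAF-like data.frame), `catalog`
#'   ([driver_catalog()]) and `profiled` (named count).
#' @export
simulate_alterations <- function(cancer_type, profiled = 500,
                                 genes = eligible_driver_genes(panel),
                                 rates = 0.01,
                                 class_probs = c(missense = 0.55,
                                                 truncating = 0.12,
                                                 inframe = 0.05,
                                                 fusion = 0.03,
                                                 amplification = 0.15,
                                                 deep_deletion = 0.05,
                                                 other = 0.05),
                                 driver_fraction = 0.7, seed = 1,
                                 panel = target_panel()) {
  set.seed(seed)
  stopifnot(all(names(class_probs) %in% ALTERATION_CLASSES))
  r <- rep(0, length(genes)); names(r) <- genes
  if (!is.null(names(rates))) r[names(rates)] <- rates else r[] <- rates
  stopifnot(all(r >= 0 & r <= 1))
  samples <- sprintf("%s_S%04d", cancer_type, seq_len(profiled))
  hot_pool <- lapply(genes, function(g)
    sprintf("%s%dX", sample(LETTERS, 4, replace = TRUE),
            sample(50:900, 4)))
  names(hot_pool) <- genes
  recs <- list()
  for (g in genes) {
    hit <- samples[stats::runif(profiled) < r[g]]
    if (!length(hit)) next
    cls <- sample(names(class_probs), length(hit), replace = TRUE,
                  prob = class_probs)
    pc <- ifelse(cls %in% c("missense", "truncating", "inframe"),
                 sample(hot_pool[[g]], length(hit), replace = TRUE),
                 NA_character_)
    recs[[g]] <- data.frame(sample_id = hit, cancer_type = cancer_type,
                            gene = g, alteration_class = cls,
                            protein_change = pc)
  }
  records <- if (length(recs)) do.call(rbind, recs)
  else data.frame(sample_id = character(0), cancer_type = character(0),
                  gene = character(0), alteration_class = character(0),
                  protein_change = character(0))
  rownames(records) <- NULL
  keys <- unique(data.frame(
    gene = records$gene,
    match_type = ifelse(is.na(records$protein_change), "class",
                        "protein_change"),
    value = ifelse(is.na(records$protein_change),
                   records$alteration_class, records$protein_change)))
  keep <- stats::runif(nrow(keys)) < driver_fraction
  catalog <- driver_catalog(keys[keep, , drop = FALSE], panel)
  prof <- stats::setNames(as.integer(profiled), cancer_type)
  list(records = if (nrow(records)) alteration_records(records, panel)
       else records,
       catalog = catalog, profiled = prof)
}

#' Simulate immune infiltration linked to expression, plus survival
#'
#' Each cell-type score is softplus(w . z + noise) where z are the
#' standardized log2 tumor expression values of the panel genes and w
#' the cell type's gene weights; softplus keeps scores positive while
#' preserving monotone (Spearman-visible) links. Survival times are
#' exponential with log-hazard `hazard_coef` times the standardized
#' infiltration of `hazard_cell`; censoring is independent exponential
#' calibrated so about `censor_rate` of subjects are censored.
#'
#' @param em An [expression_matrix()] (tumor samples are used).
#' @param weights Named list: cell type -> either a named gene-weight
#'   vector or a single scalar applied to all lenvatinib targets.
#'   Omitted cell types get weight 0 (pure noise).
#' @param cell_types Cell types to emit; default CD8_T, Treg,
#'   M2_macrophage, MDSC, DC.
#' @param noise_sd Gaussian noise sd on the linear predictor (default
#'   0.5).
#' @param normalize If TRUE, rescale each sample's scores to sum to 1
#'   (strict compositional fractions); default FALSE, matching
#'   deconvolution outputs of varying convention.
#' @param hazard_cell Cell type driving the hazard (default `CD8_T`).
#' @param hazard_coef Log-hazard per sd of infiltration (default 0).
#' @param base_rate Baseline exponential event rate (default 0.1 per
#'   time unit).
#' @param censor_rate Target censored fraction in \[0, 1), default 0.3.
#' @param seed Seed.
#' @param panel A [target_panel()].
#' @return list with `infiltration` (an [infiltration_table()]) and
#'   `survival` (data.frame `sample_id`, `time`, `event`, `covariate`).
#' @export
simulate_infiltration_survival <- function(em, weights = list(),
                                           cell_types = c("CD8_T", "Treg",
                                                          "M2_macrophage",
                                                          "MDSC", "DC"),
                                           noise_sd = 0.5,
                                           normalize = FALSE,
                                           hazard_cell = "CD8_T",
                                           hazard_coef = 0,
                                           base_rate = 0.1,
                                           censor_rate = 0.3, seed = 1,
                                           panel = target_panel()) {
  set.seed(seed)
  tv <- log2(tumor_values(em) + 1)
  z <- t(scale(t(tv)))
  z[is.nan(z)] <- 0  # constant genes contribute nothing
  n <- ncol(tv)
  vals <- sapply(cell_types, function(ct) {
    w <- rep(0, nrow(z)); names(w) <- rownames(z)
    spec <- weights[[ct]]
    if (!is.null(spec)) {
      if (is.null(names(spec))) {
        w[intersect(panel$lenvatinib_targets, names(w))] <- spec
      } else w[names(spec)] <- spec
    }
    softplus(as.numeric(crossprod(z, w)) + stats::rnorm(n, 0, noise_sd))
  })
  rownames(vals) <- colnames(tv)
  if (normalize) vals <- vals / pmax(rowSums(vals), .Machine$double.eps)
  infil <- infiltration_table(vals, em$cancer_type)

  cov <- as.numeric(scale(vals[, hazard_cell]))
  rate <- base_rate * exp(hazard_coef * cov)
  t_event <- stats::rexp(n, rate)
  if (censor_rate > 0) {
    c_rate <- base_rate * censor_rate / (1 - censor_rate)
    t_cens <- stats::rexp(n, c_rate)
  } else t_cens <- rep(Inf, n)
  surv <- data.frame(sample_id = colnames(tv),
                     time = pmin(t_event, t_cens),
                     event = as.integer(t_event <= t_cens),
                     covariate = vals[, hazard_cell])
  list(infiltration = infil, survival = surv)
}

#' Simulate a trial-cohort study table
#'
#' Per-cohort true proportions are drawn from a logit-normal
#' distribution centred at `true_p` with between-study variance `tau2`
#' on the logit scale; events are binomial and the printed percentages
#' are derived from them, mirroring how trial tables report rates.
#'
#' @param k Number of cohorts (default 20).
#' @param true_p True mean response proportion (default 0.4).
#' @param tau2 Between-study variance on the logit scale (default 0).
#' @param n_range Inclusive range of cohort sizes (default 20--120).
#' @param true_p_dcr Optional true disease-control proportion; when
#'   NULL (default) the DCR column is left missing.
#' @param seed Seed.
#' @return data.frame of study records (`study_id`, `tumor_type`, `n`,
#'   `orr_pct`, `dcr_pct`).
#' @export
simulate_study_table <- function(k = 20, true_p = 0.4, tau2 = 0,
                                 n_range = c(20, 120), true_p_dcr = NULL,
                                 seed = 1) {
  set.seed(seed)
  stopifnot(k >= 1, true_p >= 0, true_p <= 1, tau2 >= 0)
  n <- sample(seq(n_range[1], n_range[2]), k, replace = TRUE)
  draw_pct <- function(p0) {
    if (p0 %in% c(0, 1)) p <- rep(p0, k)
    else p <- stats::plogis(stats::rnorm(k, stats::qlogis(p0), sqrt(tau2)))
    100 * stats::rbinom(k, n, p) / n
  }
  orr <- draw_pct(true_p)
  dcr <- if (is.null(true_p_dcr)) rep(NA_real_, k) else draw_pct(true_p_dcr)
  data.frame(study_id = sprintf("SIM%02d", seq_len(k)),
             tumor_type = sprintf("C%02d", seq_len(k)),
             n = n, orr_pct = orr, dcr_pct = dcr)
}

#' Simulate a full multi-omics bundle for a planted and a null cancer
#'
#' Produces every input the pipeline consumes, for two synthetic
#' cancers: `planted` carries the positive treatment-related signal in
#' all three characteristics (>= 4 lenvatinib and >= 2 ICB targets
#' up-shifted 3-fold; lenvatinib driver alterations at a set-level rate
#' of about 20% of samples with `driver_fraction = 1`; a strong
#' negative expression link to CD8+ T-cell infiltration and a positive
#' log-hazard on it), while `null` has fold change 1, a 0.5% per-gene
#' alteration rate and no infiltration link. Stage child seeds derive
#' from `seed` via [child_seed()].
#'
#' @param seed Master seed.
#' @param planted,null Cancer codes for the two cohorts.
#' @param n_tumor,n_normal,profiled Sample sizes (defaults 60 / 40 /
#'   300).
#' @param panel A [target_panel()].
#' @return list with `expression` (named list of matrices),
#'   `alterations` (`records`, `catalog`, `profiled` merged over
#'   cancers), `infiltration`, `survival` (named lists) and
#'   `study_table`.
#' @export
simulate_multiomics <- function(seed = 1, planted = "PLNT", null = "NULC",
                                n_tumor = 60, n_normal = 40,
                                profiled = 300, panel = target_panel()) {
  up_genes <- c("FLT1", "KDR", "FLT4", "FGFR1", "FGFR2", "FGFR3",
                "PDCD1", "CD274", "CTLA4")
  fc <- stats::setNames(rep(3, length(up_genes)), up_genes)
  g <- length(panel_genes(panel))
  corr <- diag(g)
  lenv_idx <- seq_len(length(panel$lenvatinib_targets))
  corr[lenv_idx, lenv_idx] <- 0.5
  diag(corr) <- 1

  expr <- list(
    simulate_expression(planted, n_tumor, n_normal, fold_change = fc,
                        correlation = corr, seed = child_seed(seed, 1),
                        panel = panel),
    simulate_expression(null, n_tumor, n_normal,
                        seed = child_seed(seed, 2), panel = panel))
  names(expr) <- c(planted, null)

  elig_lenv <- intersect(eligible_driver_genes(panel),
                         panel$lenvatinib_targets)
  # per-gene rate giving a set-level altered fraction of ~0.20
  r_plant <- 1 - (1 - 0.20)^(1 / length(elig_lenv))
  alt_p <- simulate_alterations(planted, profiled,
                                rates = stats::setNames(
                                  rep(r_plant, length(elig_lenv)),
                                  elig_lenv),
                                driver_fraction = 1,
                                seed = child_seed(seed, 3), panel = panel)
  alt_n <- simulate_alterations(null, profiled, rates = 0.005,
                                driver_fraction = 1,
                                seed = child_seed(seed, 4), panel = panel)
  alterations <- list(
    records = rbind(alt_p$records, alt_n$records),
    catalog = driver_catalog(rbind(alt_p$catalog$entries,
                                   alt_n$catalog$entries), panel),
    profiled = c(alt_p$profiled, alt_n$profiled))

  is_p <- simulate_infiltration_survival(
    expr[[planted]], weights = list(CD8_T = -1), noise_sd = 0.5,
    hazard_cell = "CD8_T", hazard_coef = 0.7,
    seed = child_seed(seed, 5), panel = panel)
  is_n <- simulate_infiltration_survival(
    expr[[null]], seed = child_seed(seed, 6), panel = panel)

  list(expression = expr,
       alterations = alterations,
       infiltration = stats::setNames(list(is_p$infiltration,
                                           is_n$infiltration),
                                      c(planted, null)),
       survival = stats::setNames(list(is_p$survival, is_n$survival),
                                  c(planted, null)),
       study_table = simulate_study_table(seed = child_seed(seed, 7)))
}
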