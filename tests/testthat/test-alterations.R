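toy_records <- function() {
  data.frame(
    sample_id = c("s1", "s1", "s2", "s3", "s4", "s5", "s6", "s7", "s8", "s9"),
    cancer_type = "TSTA",
    gene = c("FGFR3", "CD274", "FGFR3", "KDR", "FGFR2", "KIT",
             "FGFR3", "CD274", "RET", "PDGFRA"),
    alteration_class = c("missense", "amplification", "missense",
                         "amplification", "fusion", "missense",
                         "truncating", "amplification", "missense",
                         "deep_deletion"),
    protein_change = c("S249C", NA, "S249C", NA, NA, "D816V",
                       "R248X", NA, "M918T", NA))
}

toy_catalog <- function() {
  driver_catalog(data.frame(
    gene = c("FGFR3", "CD274", "KIT"),
    match_type = c("protein_change", "class", "protein_change"),
    value = c("S249C", "amplification", "D816V")))
}

test_that("driver filtering keeps exactly the catalogued records", {
  rec <- toy_records()
  empty <- driver_catalog(data.frame(gene = character(0),
                                     match_type = character(0),
                                     value = character(0)))
  expect_equal(nrow(filter_drivers(rec, empty)), 0)
  # S249C twice, CD274 amp twice, KIT D816V once = 5 of 10
  kept <- filter_drivers(rec, toy_catalog())
  expect_equal(nrow(kept), 5)
  expect_setequal(unique(kept$gene), c("FGFR3", "CD274", "KIT"))
  # gene-level "any" retains every record of that gene
  anycat <- driver_catalog(data.frame(gene = "FGFR3", match_type = "any",
                                      value = NA))
  expect_equal(nrow(filter_drivers(rec, anycat)), 3)
  # idempotent and order preserving
  again <- filter_drivers(kept, toy_catalog())
  expect_identical(again$sample_id, kept$sample_id)
})

test_that("insufficient-evidence genes are excluded from the driver set", {
  elig <- eligible_driver_genes()
  expect_length(elig, 10)
  expect_true("CD274" %in% elig)
  expect_false(any(c("FLT1", "FLT4", "PDCD1", "LAG3", "CTLA4") %in% elig))
  expect_setequal(intersect(elig, target_panel()$icb_targets), "CD274")
})

test_that("frequencies use distinct-sample counting", {
  rec <- toy_records()
  f <- set_driver_frequency(rec, "FGFR3", c(TSTA = 100))
  expect_equal(f$frequency, 3 / 100)
  # one sample altered in several set genes counts once
  multi <- data.frame(sample_id = "s1", cancer_type = "TSTA",
                      gene = c("FGFR3", "KDR", "KIT"),
                      alteration_class = "missense",
                      protein_change = NA)
  f2 <- set_driver_frequency(multi, c("FGFR3", "KDR", "KIT"),
                             c(TSTA = 50))
  expect_equal(f2$altered_samples, 1L)
  # duplicating a record never changes a frequency
  f3 <- set_driver_frequency(rbind(rec, rec[1, ]), "FGFR3", c(TSTA = 100))
  expect_equal(f3$frequency, f$frequency)
  expect_equal(set_driver_frequency(rec[0, ], "FGFR3",
                                    c(TSTA = 10))$frequency, 0)
  expect_error(set_driver_frequency(rec, "FGFR3", c(OTHER = 10)), "TSTA")
})

test_that("frequency counting equals a brute-force per-sample scan", {
  set.seed(31)
  for (i in 1:10) {
    cts <- c("AA", "BB", "CC")
    genes <- eligible_driver_genes()
    rec <- data.frame(
      sample_id = sprintf("s%02d", sample(1:30, 60, replace = TRUE)),
      cancer_type = sample(cts, 60, replace = TRUE),
      gene = sample(genes, 60, replace = TRUE),
      alteration_class = sample(c("missense", "amplification"), 60,
                                replace = TRUE),
      protein_change = NA)
    prof <- c(AA = 30, BB = 30, CC = 30)
    gset <- sample(genes, 4)
    ours <- set_driver_frequency(rec, gset, prof)
    oracle <- freq_oracle(rec, gset, prof)
    expect_equal(stats::setNames(ours$frequency, ours$cancer_type),
                 oracle[ours$cancer_type])
  }
})

test_that("driver-enrichment thresholds are inclusive", {
  mk <- function(n_lenv, n_pdl1, profiled = 1000) {
    lenv <- if (n_lenv > 0)
      data.frame(sample_id = sprintf("L%03d", 1:n_lenv),
                 cancer_type = "TSTA", gene = "FGFR3",
                 alteration_class = "missense", protein_change = "S249C")
    pdl1 <- if (n_pdl1 > 0)
      data.frame(sample_id = sprintf("P%03d", 1:n_pdl1),
                 cancer_type = "TSTA", gene = "CD274",
                 alteration_class = "amplification", protein_change = NA)
    flag_driver_enriched(rbind(lenv, pdl1), c(TSTA = profiled))
  }
  expect_true(mk(90, 0)$lenvatinib_driver_high)    # exactly 9%
  expect_false(mk(89, 0)$lenvatinib_driver_high)   # 8.9%
  expect_true(mk(0, 20)$pdl1_driver_high)          # exactly 2%
  expect_false(mk(0, 19)$pdl1_driver_high)
})

test_that("only amplification counts toward the PD-L1 driver flag", {
  rec <- data.frame(sample_id = sprintf("s%03d", 1:50),
                    cancer_type = "TSTA", gene = "CD274",
                    alteration_class = "missense", protein_change = "A1X")
  f <- flag_driver_enriched(rec, c(TSTA = 100))
  expect_equal(f$pdl1_amp_freq, 0)
  expect_false(f$pdl1_driver_high)
})

test_that("mutational load ranks cancers with deterministic ties", {
  mk <- function(ct, k) data.frame(
    sample_id = sprintf("%s%03d", ct, seq_len(k)), cancer_type = ct,
    gene = "KDR", alteration_class = "missense", protein_change = NA)
  rec <- rbind(mk("AA", 30), mk("BB", 10), mk("CC", 10))
  prof <- c(AA = 100, BB = 100, CC = 100, DD = 100)
  tab <- total_target_mutational_load(rec, prof, top_m = 1)
  expect_equal(tab$cancer_type, c("AA", "BB", "CC", "DD"))
  expect_equal(attr(tab, "top_set"), "AA")
  expect_equal(tab$load[tab$cancer_type == "DD"], 0)
  expect_equal(tab$rank[tab$cancer_type == "DD"], 4)
})

test_that("total load dominates the driver-set frequency", {
  sim <- simulate_alterations("TSTA", profiled = 400, rates = 0.02,
                              driver_fraction = 0.5, seed = 32)
  drv <- filter_drivers(sim$records, sim$catalog)
  load <- total_target_mutational_load(sim$records, sim$profiled)
  dfreq <- set_driver_frequency(drv, eligible_driver_genes(), sim$profiled)
  expect_gte(load$load[1], dfreq$frequency[1])
})

test_that("alteration-class composition normalises within groups", {
  one <- toy_records()[1, ]
  c1 <- summarize_alteration_composition(one)
  expect_equal(c1$by_gene$proportion, 1)
  rec <- data.frame(sample_id = sprintf("s%d", 1:4), cancer_type = "TSTA",
                    gene = "FGFR2",
                    alteration_class = c("missense", "missense",
                                         "missense", "fusion"),
                    protein_change = NA)
  c2 <- summarize_alteration_composition(rec)
  expect_setequal(c2$by_gene$proportion, c(0.75, 0.25))
  agg <- tapply(c2$by_cancer$proportion, c2$by_cancer$group, sum)
  expect_true(all(abs(agg - 1) < 1e-12))
  c0 <- summarize_alteration_composition(toy_records()[0, ])
  expect_equal(nrow(c0$by_gene), 0)
})
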