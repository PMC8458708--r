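sim_em_infil <- function(n = 60, seed = 41, link = 0, noise = 0.5) {
  em <- simulate_expression("TST", n_tumor = n, n_normal = 2, seed = seed)
  is_ <- simulate_infiltration_survival(
    em, weights = if (link != 0) list(CD8_T = link) else list(),
    noise_sd = noise, seed = seed + 1)
  list(em = em, infil = is_$infiltration, surv = is_$survival)
}

test_that("a monotone link yields Spearman r = 1", {
  em <- simulate_expression("TST", n_tumor = 20, n_normal = 2, seed = 42)
  tv <- log2(tumor_values(em) + 1)
  vals <- cbind(CD8_T = exp(tv["KDR", ]))  # strictly monotone in KDR
  rownames(vals) <- colnames(tv)
  gc <- gene_infiltration_correlation(em, infiltration_table(vals, "TST"),
                                      genes = "KDR")
  expect_equal(gc$r, 1)
  # and is invariant under a further monotone transform
  vals2 <- cbind(CD8_T = vals[, 1]^3)
  rownames(vals2) <- colnames(tv)
  gc2 <- gene_infiltration_correlation(em, infiltration_table(vals2, "TST"),
                                       genes = "KDR")
  expect_equal(gc2$r, gc$r)
})

test_that("planted negative links produce strongly negative r", {
  em <- simulate_expression("TST", n_tumor = 300, n_normal = 2, seed = 43)
  is_ <- simulate_infiltration_survival(
    em, weights = list(CD8_T = c(KDR = -1)), noise_sd = 0.3, seed = 44)
  gc <- gene_infiltration_correlation(em, is_$infiltration)
  cd8 <- gc$r[gc$cell_type == "CD8_T"]
  expect_length(cd8, 11)
  expect_lte(cd8[gc$gene[gc$cell_type == "CD8_T"] == "KDR"], -0.5)
  # a diffuse link across all 11 lenvatinib targets turns most genes
  # mildly negative without any single dominant correlation
  x <- sim_em_infil(n = 300, seed = 43, link = -1, noise = 0.3)
  gc2 <- gene_infiltration_correlation(x$em, x$infil)
  expect_gte(sum(gc2$r[gc2$cell_type == "CD8_T"] < 0), 10)
})

test_that("independent gene and cell stay near zero correlation", {
  ok <- 0
  for (seed in 1:50) {
    x <- sim_em_infil(n = 300, seed = 100 + seed, link = 0)
    gc <- gene_infiltration_correlation(x$em, x$infil, genes = "KDR")
    if (abs(gc$r[gc$cell_type == "CD8_T"]) < 0.15) ok <- ok + 1
  }
  expect_gte(ok, 45)
})

test_that("purity adjustment removes a purity-driven correlation", {
  set.seed(44)
  n <- 200
  purity <- runif(n, 0.2, 0.9)
  g <- panel_genes(PANEL)
  z <- matrix(rnorm(15 * n, 5, 1), nrow = 15, dimnames = list(g, NULL))
  z["KDR", ] <- 5 + 3 * purity + rnorm(n, 0, 0.3)
  em <- em_from_log2(z, rep("tumor", n))
  vals <- cbind(CD8_T = softplus_oracle(2 * purity + rnorm(n, 0, 0.3)))
  rownames(vals) <- colnames(em$values)
  raw <- gene_infiltration_correlation(
    em, infiltration_table(vals, "TST"), genes = "KDR")$r
  adj <- gene_infiltration_correlation(
    em, infiltration_table(vals, "TST", purity = purity), genes = "KDR")$r
  expect_gt(raw, 0.5)
  expect_lt(abs(adj), 0.2)
})

test_that("box rules count negatives and strong cells as printed", {
  r9 <- c(rep(-0.2, 5), rep(-0.05, 4), 0.1, 0.2)  # 9 neg, 5 strong
  expect_true(cd8_box_flag(r9))
  r84 <- c(rep(-0.2, 4), rep(-0.05, 4), 0.1, 0.2, 0.3)  # 8 neg, 4 strong
  expect_false(cd8_box_flag(r84))
  expect_false(cd8_box_flag(rep(0, 11)))
  expect_true(suppressive_box_flag(c(rep(0.2, 6), rep(0.05, 4), -0.1)))
  expect_false(suppressive_box_flag(c(rep(0.2, 4), rep(0.05, 7))))
  expect_false(suppressive_box_flag(c(rep(0.5, 5), rep(-0.1, 6))))
  # NaN cells are ignored, not counted as zero
  expect_true(cd8_box_flag(c(rep(-0.2, 8), rep(NaN, 3))))
})

test_that("box flags are monotone in the rule's direction", {
  set.seed(45)
  for (i in 1:50) {
    r <- runif(11, -0.5, 0.5)
    if (cd8_box_flag(r)) {
      r2 <- r - runif(11, 0, 0.3)  # every r more negative
      expect_true(cd8_box_flag(r2))
    }
    if (suppressive_box_flag(r)) {
      expect_true(suppressive_box_flag(r + runif(11, 0, 0.3)))
    }
  }
})

test_that("Cox classification recovers a planted hazard and its sign", {
  set.seed(46)
  n <- 500
  cov <- rnorm(n)
  time <- rexp(n, 0.1 * exp(0.7 * scale(cov)[, 1]))
  res <- cox_classify(time, rep(1, n), cov)
  expect_equal(res$call, "risk")
  expect_gt(res$z, 0)
  flipped <- cox_classify(time, rep(1, n), -cov)
  expect_equal(flipped$z, -res$z, tolerance = 1e-8)
  expect_equal(flipped$call, "protective")
})

test_that("degenerate survival inputs fall back to neutral", {
  expect_error(cox_classify(1:5, rep(1, 5), 1:5), ">= 10")
  expect_warning(res <- cox_classify(1:20, rep(0, 20), rnorm(20)),
                 "neutral")
  expect_equal(res$call, "neutral")
  expect_warning(resc <- cox_classify(1:20, rep(1, 20), rep(2, 20)),
                 "neutral")
  expect_equal(resc$call, "neutral")
})

test_that("planted beta is covered by its Wald interval", {
  set.seed(47)
  cover <- 0
  for (i in 1:100) {
    n <- 200
    cov <- rnorm(n)
    time <- rexp(n, 0.1 * exp(0.5 * cov))
    fit <- survival::coxph(survival::Surv(time, rep(1, n)) ~ cov)
    b <- fit$coefficients[1]; se <- sqrt(fit$var[1, 1])
    if (abs(b - 0.5) <= 2 * se) cover <- cover + 1
  }
  expect_gte(cover, 90)
})

test_that("log-rank matches direct risk-set arithmetic", {
  # fixed six-subject example with a tie
  time <- c(1, 2, 2, 3, 5, 6)
  event <- c(1, 1, 0, 1, 1, 0)
  covariate <- c(0.1, 0.9, 0.2, 0.8, 0.3, 0.7)
  res <- km_logrank(time, event, covariate)
  expect_equal(res$chi_square,
               logrank_oracle(time, event, res$groups),
               tolerance = 1e-10)
  # random instances
  set.seed(48)
  for (i in 1:10) {
    n <- 40
    cov <- rnorm(n)
    time <- round(rexp(n, 0.2 * exp(0.5 * cov)), 1) + 0.1
    event <- rbinom(n, 1, 0.8)
    res <- km_logrank(time, event, cov)
    expect_equal(res$chi_square, logrank_oracle(time, event, res$groups),
                 tolerance = 1e-8)
  }
})

test_that("log-rank separates strongly different exponential groups", {
  set.seed(49)
  cov <- rep(c(0, 1), each = 100)
  time <- rexp(200, ifelse(cov == 1, 0.3, 0.1))
  res <- km_logrank(time, rep(1, 200), cov)
  expect_lt(res$p, 0.05)
  expect_error(km_logrank(1:10, rep(1, 10), rep(1, 10)), "degenerate")
})

test_that("identical groups give a near-zero log-rank statistic", {
  time <- rep(c(1, 2, 3, 4, 6, 8), 2)
  event <- rep(1, 12)
  cov <- rep(c(0, 1), each = 6)
  res <- km_logrank(time, event, cov)
  expect_lt(res$chi_square, 1e-10)
  expect_gt(res$p, 0.99)
})
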