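test_that("event counts round half up from printed percentages", {
  expect_identical(reconstruct_events(71.0, 355), 252L)
  expect_identical(reconstruct_events(100.0, 29), 29L)
  expect_identical(reconstruct_events(16.1, 31), 5L)
  expect_identical(reconstruct_events(38.3, 94), 36L)
  expect_identical(reconstruct_events(0, 10), 0L)
  expect_error(reconstruct_events(101, 10), "\\[0, 100\\]")
  expect_error(reconstruct_events(50, 0), "positive integer")
})

test_that("double-arcsine transform matches its closed form", {
  ef <- ft_transform(0, 10)
  expect_equal(ef$t, 0.30627, tolerance = 1e-4)
  expect_equal(ef$var, 1 / 10.5)
  expect_equal(ft_transform(10, 10)$t, pi - ft_transform(0, 10)$t,
               tolerance = 1e-12)
  # symmetry on a modest grid (full grid exercised in the acceptance suite)
  for (n in c(1, 7, 20)) {
    x <- 0:n
    expect_equal(ft_transform(x, n)$t + ft_transform(n - x, n)$t,
                 rep(pi, n + 1), tolerance = 1e-12)
  }
})

test_that("back-transform inverts the transform within 1/n", {
  expect_equal(ft_backtransform(0, 50), 0)
  expect_equal(ft_backtransform(pi, 50), 1)
  n <- 20
  for (x in 0:n) {
    p <- ft_backtransform(ft_transform(x, n)$t, n)
    expect_lt(abs(p - x / n), 1 / n)
  }
})

test_that("fixed-effect pooling is inverse-variance weighting", {
  one <- pool_fixed(0.8, 0.01)
  expect_equal(one$t_bar, 0.8)
  expect_equal(one$weights, 1)
  two <- pool_fixed(c(0.8, 0.8), c(0.02, 0.02))
  expect_equal(two$t_bar, 0.8)
  expect_equal(two$var_bar, 0.01)
  # hand-worked three-study case
  t <- c(0.5, 0.9, 1.2); v <- c(0.04, 0.01, 0.02)
  w <- 1 / v
  expect_equal(pool_fixed(t, v)$t_bar, sum(w * t) / sum(w))
  expect_equal(pool_fixed(t, v)$var_bar, 1 / sum(w))
  expect_error(pool_fixed(numeric(0), numeric(0)), "no studies")
})

test_that("heterogeneity statistics behave at the boundaries", {
  h <- heterogeneity(rep(0.7, 5), rep(0.02, 5))
  expect_equal(h$Q, 0); expect_equal(h$I2, 0); expect_equal(h$tau2, 0)
  expect_equal(heterogeneity(0.7, 0.02)$df, 0)
  # Q <= df truncates tau2 at zero so random == fixed
  t <- c(0.70, 0.71, 0.69); v <- rep(0.05, 3)
  h <- heterogeneity(t, v)
  expect_lte(h$Q, h$df)
  expect_equal(h$tau2, 0)
  expect_equal(pool_random(t, v, h$tau2)$t_bar, pool_fixed(t, v)$t_bar)
})

test_that("DerSimonian-Laird tau2 recovers a planted value", {
  set.seed(402)
  truth <- 0.04
  est <- replicate(200, {
    k <- 40
    v <- 1 / (sample(30:150, k, replace = TRUE) + 0.5)
    t <- stats::rnorm(k, 1.3, sqrt(truth + v))
    heterogeneity(t, v)$tau2
  })
  expect_gt(mean(est), truth * 0.5)
  expect_lt(mean(est), truth * 1.5)
})

test_that("random-effects weights flatten as tau2 grows", {
  t <- c(0.5, 0.9, 1.2); v <- c(0.04, 0.01, 0.02)
  expect_equal(pool_random(t, v, 0), pool_fixed(t, v))
  big <- pool_random(t, v, 1e8)
  expect_equal(big$weights, rep(1 / 3, 3), tolerance = 1e-6)
  expect_equal(big$t_bar, mean(t), tolerance = 1e-6)
})

test_that("meta_analyze handles degenerate and replicated inputs", {
  one <- data.frame(study_id = "s", tumor_type = "X", n = 10,
                    orr_pct = 50, dcr_pct = NA)
  r <- meta_analyze(one, "ORR")
  expect_equal(r$model, "fixed")
  expect_equal(r$estimate, 0.5, tolerance = 0.05)
  # k copies of one study: proportion recovered, no heterogeneity
  for (k in c(2, 5, 9)) {
    tab <- data.frame(study_id = paste0("s", 1:k), tumor_type = "X",
                      n = 40, orr_pct = 30, dcr_pct = NA)
    rk <- meta_analyze(tab, "ORR")
    expect_equal(rk$het$I2, 0)
    expect_equal(rk$estimate, 0.3, tolerance = 1 / 40)
  }
  expect_error(meta_analyze(one[0, ], "ORR"), "empty")
  two <- rbind(one, data.frame(study_id = "t", tumor_type = "Y", n = 20,
                               orr_pct = NA, dcr_pct = 80))
  expect_warning(r2 <- meta_analyze(two, "ORR"), "dropped")
  expect_equal(r2$k, 1)
})

test_that("pooled estimate stays inside the observed range", {
  set.seed(77)
  for (i in 1:25) {
    k <- sample(2:12, 1)
    n <- sample(10:200, k, replace = TRUE)
    x <- stats::rbinom(k, n, stats::runif(1, 0.05, 0.95))
    tab <- data.frame(study_id = seq_len(k), tumor_type = "X", n = n,
                      orr_pct = 100 * x / n, dcr_pct = NA)
    r <- meta_analyze(tab, "ORR")
    expect_gte(r$estimate, min(x / n) - 1e-9)
    expect_lte(r$estimate, max(x / n) + 1e-9)
  }
})

test_that("pooling agrees with metafor's double-arcsine + DL route", {
  trials <- read_study_table(system.file("extdata", "table1.tsv",
                                         package = "icblenv"))
  for (ep in c("ORR", "DCR")) {
    ours <- meta_analyze(trials, ep)
    col <- if (ep == "ORR") trials$orr_pct else trials$dcr_pct
    x <- reconstruct_events(col, trials$n)
    es <- metafor::escalc(measure = "PFT", xi = x, ni = trials$n)
    fit <- metafor::rma(yi, vi, data = es, method = "DL")
    nh <- 1 / mean(1 / trials$n)
    expect_equal(ours$estimate,
                 metafor::transf.ipft(as.numeric(coef(fit)), nh),
                 tolerance = 1e-8)
    expect_equal(ours$het$I2, fit$I2, tolerance = 1e-6)
    # metafor parameterises the transform as t/2 (var / 4), so its tau2
    # sits on a scale a factor 4 below ours; I2 and the back-transformed
    # estimate are scale-free
    expect_equal(ours$het$tau2, 4 * fit$tau2, tolerance = 1e-8)
    # CI differs only by 1.96 vs the exact normal quantile
    expect_equal(ours$ci_low, metafor::transf.ipft(fit$ci.lb, nh),
                 tolerance = 1e-4)
    expect_equal(ours$ci_high, metafor::transf.ipft(fit$ci.ub, nh),
                 tolerance = 1e-4)
  }
})

test_that("logit transform alternative pools sensibly", {
  trials <- read_study_table(system.file("extdata", "table1.tsv",
                                         package = "icblenv"))
  r <- meta_analyze(trials, "ORR", transform = "logit")
  expect_equal(r$transform, "logit")
  expect_gt(r$estimate, 0.25); expect_lt(r$estimate, 0.55)
  expect_true(r$ci_low < r$estimate && r$estimate < r$ci_high)
})

test_that("exact per-study intervals hit the binomial boundaries", {
  expect_equal(study_ci(0, 10)[1], 0)
  expect_equal(study_ci(10, 10)[2], 1)
  ci <- study_ci(5, 10)
  expect_equal(ci, c(0.187, 0.813), tolerance = 1e-3)
})

test_that("forest data has one row per cohort plus the pooled row", {
  trials <- read_study_table(system.file("extdata", "table1.tsv",
                                         package = "icblenv"))
  fd <- forest_data(trials, "ORR")
  expect_equal(nrow(fd), 21)
  expect_equal(sum(fd$pooled), 1)
  expect_equal(sum(fd$weight[!fd$pooled]), 1, tolerance = 1e-9)
  expect_identical(fd$study_id[1:20], trials$study_id)
  one <- forest_data(data.frame(study_id = "s", tumor_type = "X",
                                n = 10, orr_pct = 50, dcr_pct = NA), "ORR")
  expect_equal(nrow(one), 2)
  expect_equal(one$weight[1], 1)
})
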