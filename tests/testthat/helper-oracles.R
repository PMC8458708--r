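# Independent brute-force oracles, deliberately written with plain loops
# and no shared code with the package implementation.

PANEL <- target_panel()

# full meta-analysis pipeline on the transformed scale
meta_oracle <- function(x, n, i2_cutoff = 50) {
  k <- length(x)
  t <- numeric(k); v <- numeric(k)
  for (i in seq_len(k)) {
    t[i] <- asin(sqrt(x[i] / (n[i] + 1))) + asin(sqrt((x[i] + 1) / (n[i] + 1)))
    v[i] <- 1 / (n[i] + 0.5)
  }
  sw <- 0; swt <- 0; sw2 <- 0
  for (i in seq_len(k)) {
    w <- 1 / v[i]
    sw <- sw + w; swt <- swt + w * t[i]; sw2 <- sw2 + w * w
  }
  tb <- swt / sw
  Q <- 0
  for (i in seq_len(k)) Q <- Q + (t[i] - tb)^2 / v[i]
  I2 <- if (k > 1 && Q > 0) max(0, (Q - (k - 1)) / Q * 100) else 0
  tau2 <- if (k > 1) max(0, (Q - (k - 1)) / (sw - sw2 / sw)) else 0
  model <- if (I2 > i2_cutoff) "random" else "fixed"
  if (model == "random") {
    sw <- 0; swt <- 0
    for (i in seq_len(k)) {
      w <- 1 / (v[i] + tau2)
      sw <- sw + w; swt <- swt + w * t[i]
    }
    tb <- swt / sw
  }
  list(t_bar = tb, se = sqrt(1 / sw), Q = Q, I2 = I2, tau2 = tau2,
       model = model)
}

# altered-sample fraction by naive per-sample scan
freq_oracle <- function(records, gene_set, profiled) {
  out <- numeric(length(profiled))
  names(out) <- names(profiled)
  for (ct in names(profiled)) {
    hit <- 0
    seen <- character(0)
    for (i in seq_len(nrow(records))) {
      if (records$cancer_type[i] == ct &&
          records$gene[i] %in% gene_set &&
          !(records$sample_id[i] %in% seen)) {
        seen <- c(seen, records$sample_id[i])
        hit <- hit + 1
      }
    }
    out[ct] <- hit / profiled[[ct]]
  }
  out
}

# two-group log-rank chi-square by direct risk-set arithmetic
logrank_oracle <- function(time, event, group) {
  times <- sort(unique(time[event == 1]))
  obs <- 0; expc <- 0; varc <- 0
  for (tt in times) {
    at1 <- sum(time >= tt & group == levels(group)[1])
    at2 <- sum(time >= tt & group == levels(group)[2])
    nn <- at1 + at2
    d1 <- sum(time == tt & event == 1 & group == levels(group)[1])
    d <- sum(time == tt & event == 1)
    obs <- obs + d1
    expc <- expc + d * at1 / nn
    if (nn > 1)
      varc <- varc + d * (at1 / nn) * (at2 / nn) * (nn - d) / (nn - 1)
  }
  (obs - expc)^2 / varc
}

softplus_oracle <- function(x) log(1 + exp(x))

# small expression matrix with explicit log2-scale values:
# values are 2^z - 1 so that log2(x + 1) recovers z exactly
em_from_log2 <- function(z, condition, cancer = "TST") {
  expression_matrix(2^z - 1, condition, cancer, PANEL)
}

# a DE table shaped like differential_expression() output, for testing
# the classification rule in isolation
fake_de <- function(up_genes, cancer = "TST",
                    genes = panel_genes(PANEL)) {
  de <- data.frame(gene = genes,
                   mean_log_tumor = 1, mean_log_normal = 0,
                   p_value = ifelse(genes %in% up_genes, 0.001, 0.5),
                   up = TRUE,
                   significant_up = genes %in% up_genes,
                   testable = TRUE)
  attr(de, "cancer_type") <- cancer
  de
}
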