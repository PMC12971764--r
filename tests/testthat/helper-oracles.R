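# Independent oracles shared between unit and acceptance tests.

# Brute-force metric recount with explicit loops.
metrics_oracle <- function(true, pred) {
  acc <- mean(true == pred)
  f1 <- numeric(3); sup <- numeric(3)
  prec <- numeric(3); rec <- numeric(3)
  for (c in 1:3) {
    tp <- sum(true == c & pred == c)
    fp <- sum(true != c & pred == c)
    fn <- sum(true == c & pred != c)
    prec[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c] <- if (prec[c] + rec[c] > 0) {
      2 * prec[c] * rec[c] / (prec[c] + rec[c])
    } else 0
    sup[c] <- sum(true == c)
  }
  list(accuracy = acc, weighted_f1 = sum(f1 * sup) / sum(sup),
       precision = prec, recall = rec, f1 = f1)
}

# Literal transcription of the published multi-rater kappa formula.
fleiss_oracle <- function(counts) {
  n <- nrow(counts); r <- sum(counts[1, ]); q <- ncol(counts)
  pj <- numeric(q)
  for (j in 1:q) pj[j] <- sum(counts[, j]) / (n * r)
  Pi <- numeric(n)
  for (i in 1:n) {
    s <- 0
    for (j in 1:q) s <- s + counts[i, j] * (counts[i, j] - 1)
    Pi[i] <- s / (r * (r - 1))
  }
  (mean(Pi) - sum(pj^2)) / (1 - sum(pj^2))
}

# Brute-force two-way ANOVA decomposition via aov().
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(score = as.vector(m),
                   item = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  sm <- summary(stats::aov(score ~ item + rater, data = df))[[1]]
  rn <- trimws(rownames(sm))
  MSR <- sm[which(rn == "item"), "Mean Sq"]
  MSC <- sm[which(rn == "rater"), "Mean Sq"]
  MSE <- sm[which(rn == "Residuals"), "Mean Sq"]
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}
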