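# Generative SDT observer: a single evidence sample drives both the choice
# (sign vs criterion 0) and confidence (quantile bins of |evidence|). For
# this observer meta-d' equals d' in expectation, which makes it the
# parameter-recovery oracle for the meta-d' MLE.
gen_sdt_observer <- function(n, d, K = 4, subject = "s") {
  stim <- sample(c("S1", "S2"), n, TRUE)
  x <- rnorm(n, ifelse(stim == "S2", d / 2, -d / 2))
  resp <- ifelse(x > 0, "S2", "S1")
  conf <- as.integer(cut(abs(x),
                         c(-Inf, quantile(abs(x), (1:(K - 1)) / K), Inf)))
  trial_table(subject, stim, resp, conf, runif(n, 300, 900), K = K)
}

# Random small trial table with an arbitrary secondary variable, for
# oracle-equivalence sweeps.
random_table_sv <- function(n = NULL, K = NULL) {
  if (is.null(n)) n <- sample(10:200, 1)
  if (is.null(K)) K <- sample(2:6, 1)
  stim <- sample(c("S1", "S2"), n, TRUE)
  correct <- runif(n) < runif(1, 0.2, 0.8)
  resp <- ifelse(correct, stim, ifelse(stim == "S1", "S2", "S1"))
  if (all(correct) || all(!correct)) return(random_table_sv(n, K))
  lev <- sample.int(K, n, TRUE)
  tt <- trial_table("s", stim, resp, confidence = lev, rt = runif(n, 200, 1500),
                    K = K)
  list(table = tt, sv = metaRT:::secondary_variable(lev, K, "confidence"))
}

# Brute-force type-2 AUC: enumerate every cutoff, count "high" trials
# directly, and integrate the polygon with an explicit loop.
auc_oracle <- function(correct, lev, K) {
  xs <- 0; ys <- 0
  for (cc in K:2) {
    xs <- c(xs, sum(lev >= cc & !correct) / sum(!correct))
    ys <- c(ys, sum(lev >= cc & correct) / sum(correct))
  }
  xs <- c(xs, 1); ys <- c(ys, 1)
  area <- 0
  for (i in seq_len(length(xs) - 1)) {
    area <- area + (xs[i + 1] - xs[i]) * (ys[i] + ys[i + 1]) / 2
  }
  area
}

# Independent meta-observer log-likelihood (response-conditional), written
# as straight-line code over explicit cell loops. Takes padded counts and
# the absolute criteria (length 2K-1 with meta_c at position K).
metad_loglik_oracle <- function(n1, n2, meta_d, criteria) {
  K <- (length(criteria) + 1) / 2
  b <- c(-Inf, criteria, Inf)
  ll <- 0
  for (s in 1:2) {
    mu <- c(-1, 1)[s] * meta_d / 2
    n <- list(n1, n2)[[s]]
    p_resp1 <- pnorm(criteria[K] - mu)
    for (i in seq_len(2 * K)) {
      p_cell <- pnorm(b[i + 1] - mu) - pnorm(b[i] - mu)
      p_side <- if (i <= K) p_resp1 else 1 - p_resp1
      ll <- ll + n[i] * log(max(p_cell, 1e-300) / max(p_side, 1e-300))
    }
  }
  ll
}
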