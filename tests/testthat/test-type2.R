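test_that("quantile binning: tertile cutoffs, equal counts, tie handling", {
  # nine RTs, three bins, descending: the fastest tertile gets the top level
  expect_equal(as.integer(bin_by_quantiles(seq(100, 900, 100), 3, "descending")),
               c(3, 3, 3, 2, 2, 2, 1, 1, 1))
  # exact equal counts for distinct values
  set.seed(11)
  v <- runif(1000)
  lev <- bin_by_quantiles(v, 10, "ascending")
  expect_equal(unname(table(as.integer(lev))), rep(100L, 10),
               ignore_attr = TRUE)
  # a value equal to a cutoff goes to the lower level
  lev2 <- bin_by_quantiles(c(1, 2, 3, 4, 5, 6), 2, "ascending")
  expect_equal(as.integer(lev2), c(1, 1, 1, 2, 2, 2))
})

test_that("degenerate binning merges duplicate cutoffs with a warning", {
  expect_warning(lev <- bin_by_quantiles(c(rep(1, 9), 2), 5, "ascending"),
                 "degenerate")
  expect_lt(attr(lev, "K"), 5)
  expect_warning(lev1 <- bin_by_quantiles(rep(3.5, 8), 4), "identical")
  expect_equal(as.integer(lev1), rep(1L, 8))
  expect_equal(attr(lev1, "K"), 1L)
})

test_that("counts_by_cell uses the nR_S1/nR_S2 layout and conserves trials", {
  tt <- trial_table("s", "S1", "S1", 2, 400, K = 2)
  cm <- counts_by_cell(tt)
  expect_equal(cm$nR_S1, c(1L, 0L, 0L, 0L))  # S1 response, highest level
  expect_equal(cm$nR_S2, rep(0L, 4))
  for (i in 1:10) {
    rt <- random_table_sv()
    cm <- counts_by_cell(rt$table, rt$sv)
    expect_equal(sum(cm$nR_S1) + sum(cm$nR_S2), nrow(rt$table))
  }
})

test_that("regrouping counts by correctness reproduces the correct/incorrect margins", {
  set.seed(21)
  rt <- random_table_sv(150, 3)
  cm <- counts_by_cell(rt$table, rt$sv)
  K <- cm$K
  lev <- as.integer(rt$sv)
  for (j in 1:K) {
    # correct cells: stim S1/resp S1 slot K+1-j (levels run K..1) plus
    # stim S2/resp S2 slot K+j (levels run 1..K)
    expect_equal(cm$nR_S1[K + 1 - j] + cm$nR_S2[K + j],
                 sum(rt$table$correct & lev == j))
    expect_equal(cm$nR_S2[K + 1 - j] + cm$nR_S1[K + j],
                 sum(!rt$table$correct & lev == j))
  }
})

test_that("type-2 AUC equals the brute-force cutoff-enumeration oracle", {
  set.seed(31)
  for (i in 1:100) {
    rt <- random_table_sv()
    curve <- type2_roc(rt$table, rt$sv)
    expect_equal(curve$auc,
                 auc_oracle(rt$table$correct, as.integer(rt$sv), attr(rt$sv, "K")),
                 tolerance = 1e-12)
  }
})

test_that("worked type-2 curves: independence, 0.75 case, perfect separation", {
  # identical level distributions for correct and incorrect -> AUC 0.5
  stim <- rep("S1", 80)
  resp <- c(rep("S1", 40), rep("S2", 40))
  conf <- rep(c(2, 2, 1, 1), 20)
  tt <- trial_table("s", stim, resp, conf, rep(500, 80), K = 2)
  expect_equal(type2_roc(tt)$auc, 0.5, tolerance = 1e-12)
  # correct 30 high / 10 low, incorrect 10 high / 30 low
  conf2 <- c(rep(2, 30), rep(1, 10), rep(2, 10), rep(1, 30))
  tt2 <- trial_table("s", stim, resp, conf2, rep(500, 80), K = 2)
  cv <- type2_roc(tt2)
  expect_equal(cv$points$far2, 0.25)
  expect_equal(cv$points$hr2, 0.75)
  expect_equal(cv$auc, 0.75, tolerance = 1e-12)
  # perfect separation passes through (0, 1)
  conf3 <- c(rep(2, 40), rep(1, 40))
  tt3 <- trial_table("s", stim, resp, conf3, rep(500, 80), K = 2)
  cv3 <- type2_roc(tt3)
  expect_equal(c(cv3$points$far2, cv3$points$hr2), c(0, 1))
  expect_equal(cv3$auc,
               auc_oracle(tt3$correct, conf3, 2), tolerance = 1e-12)
})

test_that("AUC is invariant to strictly monotone relabeling of levels", {
  set.seed(41)
  for (i in 1:20) {
    rt <- random_table_sv()
    K <- attr(rt$sv, "K")
    relabel <- sort(sample(1:(3 * K), K))  # strictly increasing map
    sv2 <- metaRT:::secondary_variable(relabel[as.integer(rt$sv)],
                                       K = max(relabel), kind = "confidence")
    expect_equal(type2_roc(rt$table, rt$sv)$auc,
                 type2_roc(rt$table, sv2)$auc, tolerance = 1e-12)
  }
})

test_that("slowing incorrect trials never decreases RT-based AUC", {
  set.seed(51)
  for (i in 1:20) {
    n <- 120
    stim <- sample(c("S1", "S2"), n, TRUE)
    correct <- runif(n) < 0.7
    resp <- ifelse(correct, stim, ifelse(stim == "S1", "S2", "S1"))
    rt <- runif(n, 300, 1200)
    tt <- trial_table("s", stim, resp, rep(1:2, length.out = n), rt)
    auc1 <- type2_roc(tt, bin_by_quantiles(tt$rt, 4, "descending"))$auc
    rt2 <- rt + ifelse(correct, 0, runif(1, 50, 400))
    tt2 <- trial_table("s", stim, resp, rep(1:2, length.out = n), rt2)
    auc2 <- type2_roc(tt2, bin_by_quantiles(tt2$rt, 4, "descending"))$auc
    expect_gte(auc2, auc1 - 1e-12)
  }
})

test_that("type-2 ROC refuses tables without both outcomes", {
  tt <- trial_table("s", c("S1", "S2"), c("S1", "S2"), c(1, 2), c(400, 500))
  expect_error(type2_roc(tt), "at least one correct and one incorrect")
})
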