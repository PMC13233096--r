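test_that("Spearman-Brown and disattenuation match their closed forms", {
  for (r in seq(-0.9, 0.9, by = 0.1)) {
    expect_equal(spearman_brown(r), 2 * r / (1 + r), tolerance = 1e-12)
  }
  expect_equal(disattenuate(0.3, 1, 1)$r, 0.3, tolerance = 1e-12)
  d <- disattenuate(0.3, 0.36, 0.36)
  expect_equal(d$r, 0.3 / 0.36, tolerance = 1e-12)
  expect_false(d$over_corrected)
  cl <- disattenuate(0.5, 0.2, 0.2)
  expect_equal(cl$raw_ratio, 2.5, tolerance = 1e-12)
  expect_equal(cl$r, 1)
  expect_true(cl$over_corrected)
  expect_error(disattenuate(0.3, 0, 0.5), "non-positive")
})

test_that("partial correlation matches the residual-regression oracle", {
  set.seed(171)
  for (i in 1:10) {
    n <- 50
    z <- rnorm(n); x <- 0.5 * z + rnorm(n); y <- -0.3 * z + rnorm(n)
    pc <- partial_correlation(x, y, z)
    oracle <- cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
    expect_equal(pc$r, oracle, tolerance = 1e-12)
  }
  # exact-independence identity
  set.seed(172)
  x <- rnorm(40); y <- rnorm(40)
  z0 <- rnorm(40)
  z <- resid(lm(z0 ~ x + y))   # orthogonal to both by construction
  pc <- partial_correlation(x, y, z)
  expect_equal(pc$r, cor(x, y), tolerance = 1e-12)
  # degenerate control variable
  expect_error(partial_correlation(x, y, x), "degenerate")
})

test_that("partial correlation recovers a known trivariate structure", {
  set.seed(181)
  n <- 10000
  z <- rnorm(n)
  x <- 0.6 * z + sqrt(1 - 0.36) * rnorm(n)
  e <- rnorm(n)
  y <- 0.6 * z + sqrt(1 - 0.36) * (0.4 * scale(resid(lm(x ~ z))) + sqrt(1 - 0.16) * e)
  pc <- partial_correlation(x, y, z)
  expect_equal(pc$r, 0.4, tolerance = 0.02)
  expect_true(pc$ci[1] < pc$r && pc$r < pc$ci[2])
})

test_that("random-effects pooling matches metafor's DerSimonian-Laird to 1e-10", {
  skip_if_not_installed("metafor")
  per <- data.frame(r = c(0.10, 0.35, 0.52, 0.28, -0.05),
                    n = c(40, 90, 55, 200, 33))
  m <- meta_analyze_r(per)
  rma <- metafor::rma(yi = atanh(per$r), vi = 1 / (per$n - 3), method = "DL")
  expect_equal(m$pooled_r, tanh(as.numeric(rma$beta)), tolerance = 1e-10)
  expect_equal(m$tau2, as.numeric(rma$tau2), tolerance = 1e-10)
  expect_equal(m$pooled_ci, tanh(c(rma$ci.lb, rma$ci.ub)), tolerance = 1e-10)
  expect_equal(m$p_value, as.numeric(rma$pval), tolerance = 1e-10)
})

test_that("meta-analysis identities: single study, homogeneity, errors", {
  m1 <- meta_analyze_r(data.frame(r = 0.4, n = 50))
  expect_equal(m1$pooled_r, 0.4, tolerance = 1e-12)
  expect_equal(m1$tau2, 0)
  mh <- meta_analyze_r(data.frame(r = rep(0.3, 4), n = c(30, 60, 90, 120)))
  expect_equal(mh$pooled_r, 0.3, tolerance = 1e-12)
  expect_equal(mh$tau2, 0)
  expect_error(meta_analyze_r(data.frame(r = 1, n = 50)), "Fisher")
})

test_that("pooled CI narrows as homogeneous studies accumulate", {
  width <- function(k) {
    m <- meta_analyze_r(data.frame(r = rep(0.3, k), n = rep(60, k)))
    diff(m$pooled_ci)
  }
  w <- vapply(c(2, 5, 10, 20), width, numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("duplicated trials give exactly equal odd and even meta-d'", {
  set.seed(191)
  base <- gen_sdt_observer(300, 1.4, K = 3)
  idx <- rep(seq_len(300), each = 2)
  dup <- trial_table("s", base$stimulus[idx], base$response[idx],
                     base$confidence[idx], base$rt[idx], K = 3)
  sh <- split_half_metad(dup, "confidence")
  expect_equal(sh$meta_d_odd, sh$meta_d_even, tolerance = 1e-12)
})

test_that("split-half reliability is positive for stationary heterogeneous observers", {
  set.seed(201)
  n_subj <- 30
  tabs <- lapply(seq_len(n_subj), function(i) {
    d <- runif(1, 0.5, 2.5)
    tt <- gen_sdt_observer(1200, d, K = 4, subject = sprintf("s%02d", i))
    # heterogeneous metacognitive noise: degrade confidence for some subjects
    if (i %% 2 == 0) {
      swap <- runif(1200) < 0.5
      tt$confidence[swap] <- sample(tt$confidence[swap])
    }
    tt
  })
  tab <- do.call(rbind, tabs)
  attr(tab, "K") <- 4
  class(tab) <- c("trial_table", "data.frame")
  sh <- split_half_metad(tab, "confidence")
  expect_gte(nrow(sh), 25)
  rel <- reliability(sh)
  expect_gt(rel$r_half, 0.3)
  expect_equal(rel$r_sb, 2 * rel$r_half / (1 + rel$r_half), tolerance = 1e-12)
})

test_that("small samples fail the Spearman-Brown screen", {
  set.seed(211)
  n_subj <- 12
  tabs <- lapply(seq_len(n_subj), function(i) {
    gen_sdt_observer(40, runif(1, 0.8, 1.6), K = 2, subject = sprintf("s%02d", i))
  })
  tab <- do.call(rbind, tabs)
  attr(tab, "K") <- 2
  class(tab) <- c("trial_table", "data.frame")
  sh <- suppressMessages(split_half_metad(tab, "confidence", min_trials = 10))
  if (nrow(sh) >= 4) {
    rel <- reliability(sh, threshold = 0.45)
    expect_type(rel$passes_screen, "logical")
  } else {
    succeed("too few fittable subjects at n = 40, as expected for tiny halves")
  }
})
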