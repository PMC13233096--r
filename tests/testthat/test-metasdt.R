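test_that("type-1 fit matches the closed-form SDT expressions", {
  # symmetric counts: HR == FAR -> d' = 0
  cm <- structure(list(nR_S1 = c(20L, 30L, 30L, 20L),
                       nR_S2 = c(20L, 30L, 30L, 20L), K = 2L),
                  class = "count_matrix")
  t1 <- fit_type1(cm, padding = 0)
  expect_equal(t1$d_prime, 0)
  # HR = 0.84, FAR = 0.16 -> d' = 2 z(0.84)
  cm2 <- structure(list(nR_S1 = c(42L, 42L, 8L, 8L),
                        nR_S2 = c(8L, 8L, 42L, 42L), K = 2L),
                   class = "count_matrix")
  t2 <- fit_type1(cm2, padding = 0)
  expect_equal(t2$d_prime, 2 * qnorm(0.84), tolerance = 1e-12)
  expect_equal(t2$c, 0, tolerance = 1e-12)
  # extreme counts with padding stay finite; without padding they error
  cm3 <- structure(list(nR_S1 = c(50L, 50L, 0L, 0L),
                        nR_S2 = c(0L, 0L, 50L, 50L), K = 2L),
                   class = "count_matrix")
  expect_true(is.finite(fit_type1(cm3)$d_prime))
  expect_error(fit_type1(cm3, padding = 0), "padding")
})

test_that("meta-d' recovers the sensitivity of an ideal SDT observer", {
  set.seed(61)
  tt <- gen_sdt_observer(20000, 1.5, K = 4)
  fit <- fit_meta_d(counts_by_cell(tt))
  expect_true(fit$converged)
  expect_gt(fit$m_ratio, 0.9)
  expect_lt(fit$m_ratio, 1.1)
})

test_that("uninformative secondary variables give meta-d' near zero", {
  set.seed(71)
  # identical level distributions within each response for both stimuli
  tt <- gen_sdt_observer(10000, 1.5, K = 4)
  tt$confidence <- sample(tt$confidence)   # shuffle breaks the type-2 link
  fits <- replicate(5, {
    tt$confidence <- sample(tt$confidence)
    fit_meta_d(counts_by_cell(tt))$meta_d_prime
  })
  expect_lt(abs(mean(fits)), 0.05)
})

test_that("reported log-likelihood matches an independent evaluator and dominates random feasible points", {
  set.seed(81)
  tt <- gen_sdt_observer(2000, 1.2, K = 3)
  cm <- counts_by_cell(tt)
  fit <- fit_meta_d(cm)
  K <- cm$K
  pad <- 1 / (2 * K)
  n1 <- cm$nR_S1 + pad
  n2 <- cm$nR_S2 + pad
  crit <- sort(c(fit$t2_criteria, fit$meta_c))
  ll <- metad_loglik_oracle(n1, n2, fit$meta_d_prime, crit)
  expect_equal(fit$loglik, ll, tolerance = 1e-5)
  c_rel <- fit$c / fit$d_prime
  for (i in 1:100) {
    md <- runif(1, -3, 3)
    mc <- c_rel * md
    gaps <- exp(runif(2 * K - 2, -2, 1))
    crit_r <- c(mc - rev(cumsum(rev(gaps[1:(K - 1)]))), mc,
                mc + cumsum(gaps[K:(2 * K - 2)]))
    expect_gte(fit$loglik + 1e-6, metad_loglik_oracle(n1, n2, md, crit_r))
  }
})

test_that("meta-d' is invariant to a global S1/S2 label swap", {
  set.seed(91)
  tt <- gen_sdt_observer(4000, 1.0, K = 4)
  swap <- function(x) ifelse(x == "S1", "S2", "S1")
  tt2 <- trial_table(tt$subject, swap(tt$stimulus), swap(tt$response),
                     tt$confidence, tt$rt, K = 4)
  f1 <- fit_meta_d(counts_by_cell(tt))
  f2 <- fit_meta_d(counts_by_cell(tt2))
  expect_equal(f1$meta_d_prime, f2$meta_d_prime, tolerance = 1e-3)
  expect_equal(f1$d_prime, f2$d_prime, tolerance = 1e-12)
  expect_equal(f1$c, -f2$c, tolerance = 1e-12)
})

test_that("anti-diagnostic secondary variables yield negative meta-d', unclamped", {
  set.seed(101)
  tt <- gen_sdt_observer(6000, 1.5, K = 4)
  tt$confidence <- 5L - tt$confidence   # reverse: high confidence on errors
  fit <- fit_meta_d(counts_by_cell(tt))
  expect_lt(fit$meta_d_prime, -0.5)
})

test_that("exclusion partitions fits by convergence and the d' range", {
  mk <- function(d, md, conv) {
    structure(list(d_prime = d, meta_d_prime = md, m_ratio = md / d,
                   converged = conv), class = "meta_sdt_fit")
  }
  fits <- list(a = mk(4.2, 1, TRUE),    # d' out of range
               b = mk(1.0, 0.5, TRUE),  # retained
               c = mk(1.0, 0.5, FALSE), # non-convergent
               d = mk(4.0, -1.0, TRUE), # endpoints are inclusive
               e = mk(2.0, -1.2, TRUE)) # meta-d' out of range
  part <- exclude_subjects(fits)
  expect_equal(part$retained, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(part$reason[c(1, 3, 5)],
               c("out-of-range", "non-convergence", "out-of-range"))
})

test_that("meta-d' criteria are ordered around meta-c", {
  set.seed(111)
  tt <- gen_sdt_observer(3000, 1.0, K = 4)
  fit <- fit_meta_d(counts_by_cell(tt))
  K <- 4
  expect_true(all(diff(fit$t2_criteria) > 0))
  expect_true(all(fit$t2_criteria[1:(K - 1)] < fit$meta_c))
  expect_true(all(fit$t2_criteria[K:(2 * K - 2)] > fit$meta_c))
})
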