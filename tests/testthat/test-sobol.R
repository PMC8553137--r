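test_that("Saltelli designs are reproducible, in-range, and well-formed", {
  dsg <- sample_design(gsa_ranges, N = 2, seed = 9,
                       targets = list("beta_dark", c("k_R", "k_E")))
  dsg2 <- sample_design(gsa_ranges, N = 2, seed = 9,
                        targets = list("beta_dark", c("k_R", "k_E")))
  expect_identical(dsg$A, dsg2$A)
  expect_identical(dsg$B, dsg2$B)
  expect_equal(names(dsg$AB), c("beta_dark", "k_R:k_E"))
  # AB has B's columns at the target and A's elsewhere
  expect_equal(dsg$AB[["beta_dark"]]$beta_dark, dsg$B$beta_dark)
  expect_equal(dsg$AB[["beta_dark"]]$k_R, dsg$A$k_R)
  expect_equal(dsg$AB[["k_R:k_E"]]$k_R, dsg$B$k_R)
  expect_equal(dsg$AB[["k_R:k_E"]]$k_E, dsg$B$k_E)

  big <- sample_design(gsa_ranges, N = 100000, seed = 10, targets = list("k_R"))
  for (nm in names(big$A)) {
    lohi <- conesens:::range_of(gsa_ranges, nm)
    expect_true(all(big$A[[nm]] >= lohi[1] & big$A[[nm]] <= lohi[2]))
  }
  # CLT: empirical means approach range midpoints within 3 sigma
  for (nm in c("beta_dark", "a_min", "f_Ca")) {
    lohi <- conesens:::range_of(gsa_ranges, nm)
    se <- diff(lohi) / sqrt(12) / sqrt(100000)
    expect_lt(abs(mean(big$A[[nm]]) - mean(lohi)), 3 * se)
  }
  expect_error(sample_design(gsa_ranges, N = 4, seed = 1,
                             targets = list("not_a_param")), "missing")
})

test_that("estimators recover additive-model indices, with S = S_tot", {
  fx <- make_gsa_smoke_fixture("additive")
  res <- sobol_indices(fx$f, fx$ranges, N = 40000, seed = 21,
                       targets = list("k_R", "k_E"))
  expect_lt(abs(res$S[1] - fx$exact$S1), 0.03)
  expect_lt(abs(res$S[2] - fx$exact$S2), 0.03)
  expect_lt(abs(res$S_tot[1] - fx$exact$S_tot1), 0.03)
  # additive model: first-order and total indices coincide
  expect_lt(abs(res$S[1] - res$S_tot[1]), 0.03)
  expect_lt(abs(res$S[2] - res$S_tot[2]), 0.03)
  # all variance accounted for
  expect_lt(abs(res$S[1] + res$S[2] - 1), 0.05)
})

test_that("estimators recover the Ishigami closed-form indices", {
  fx <- make_gsa_smoke_fixture("ishigami")
  expect_equal(fx$exact$S1, 0.3139, tolerance = 1e-3)
  expect_equal(fx$exact$S2, 0.4424, tolerance = 1e-3)
  expect_equal(fx$exact$S_tot3, 0.2437, tolerance = 1e-3)
  res <- sobol_indices(fx$f, fx$ranges, N = 10000, seed = 22,
                       targets = list("k_R", "k_E", "k_GE"))
  # within 3 Monte Carlo standard errors (read off the 95% numerator CIs)
  se_S <- (res$ci90_S_hi - res$ci90_S_lo) / (2 * 1.96)
  se_T <- (res$ci90_S_tot_hi - res$ci90_S_tot_lo) / (2 * 1.96)
  exact_S <- c(fx$exact$S1, fx$exact$S2, fx$exact$S3)
  exact_T <- c(fx$exact$S_tot1, fx$exact$S_tot2, fx$exact$S_tot3)
  expect_true(all(abs(res$S - exact_S) < 3 * pmax(se_S, 1e-3)))
  expect_true(all(abs(res$S_tot - exact_T) < 3 * pmax(se_T, 1e-3)))
  # S <= S_tot within Monte Carlo noise, and the x3 first-order index may be
  # slightly negative but is preserved unclamped
  expect_true(all(res$S <= res$S_tot + 3 * (se_S + se_T)))

  # constant functional: estimator refuses
  fc <- make_gsa_smoke_fixture("constant")
  expect_error(sobol_indices(fc$f, fc$ranges, N = 100, seed = 1,
                             targets = list("k_R")), "constant functional")
})

test_that("confidence intervals shrink as N^(-1/2) and match the bootstrap", {
  fx <- make_gsa_smoke_fixture("ishigami")
  r1 <- sobol_indices(fx$f, fx$ranges, N = 2500, seed = 30, targets = list("k_R"))
  r4 <- sobol_indices(fx$f, fx$ranges, N = 10000, seed = 30, targets = list("k_R"))
  w1 <- r1$ci90_S_hi - r1$ci90_S_lo
  w4 <- r4$ci90_S_hi - r4$ci90_S_lo
  expect_equal(w1 / w4, 2, tolerance = 0.35)

  dsg <- sample_design(fx$ranges, N = 10000, seed = 31, targets = list("k_R"))
  fA <- fx$f(dsg$A); fB <- fx$f(dsg$B)
  fAB <- lapply(dsg$AB, fx$f)
  res <- estimate_indices(fA, fB, fAB)
  bs <- bootstrap_ci(fA, fB, fAB, "k_R", B_boot = 1000, seed = 5)
  w_norm <- res$ci90_S_hi - res$ci90_S_lo
  w_boot <- bs$S[2] - bs$S[1]
  # the division-bound interval stacks two 95% normal intervals, so it is
  # conservative: it must contain the 90% percentile bootstrap interval and
  # stay on the same scale (within a factor of two)
  expect_lte(res$ci90_S_lo, bs$S[1] + 1e-9)
  expect_gte(res$ci90_S_hi, bs$S[2] - 1e-9)
  expect_gt(w_boot, 0.5 * w_norm)
  # bootstrap interval covers the point estimate
  expect_gt(res$S[1], bs$S[1] - 0.02)
  expect_lt(res$S[1], bs$S[2] + 0.02)
})

test_that("failed evaluations are excluded pairwise and counted", {
  fx <- make_gsa_smoke_fixture("additive")
  f_flaky <- function(X) {
    y <- fx$f(X)
    y[seq_along(y) %% 97 == 0] <- NA_real_
    y
  }
  res <- sobol_indices(f_flaky, fx$ranges, N = 20000, seed = 33,
                       targets = list("k_R"))
  expect_gt(res$n_failed[1], 0)
  expect_lt(res$N[1], 20000)
  expect_equal(res$S[1], fx$exact$S1, tolerance = 0.03)
})

test_that("a variance CI straddling zero is flagged as unbounded", {
  # one extreme outlier at tiny N: the normal CI of the pooled variance
  # crosses zero, so the ratio interval is infinite
  fA <- c(0, 0, 100)
  fB <- c(0, 0, 0)
  fAB <- list(x = c(0, 0, 50))
  res <- estimate_indices(fA, fB, fAB)
  expect_true(is.infinite(res$ci90_S_lo) && is.infinite(res$ci90_S_hi))
  expect_true(is.finite(res$S))
})
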