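test_that("rms error has exact values on constructed targets", {
  tg <- generate_experiment(best_fit, intensities = 940, t_end = 0.3,
                            noise_sd = 0, seed = 1)
  # self-target, zero noise: error vanishes
  expect_lt(rms_error(best_fit, tg, 940), 1e-9)
  # constant offset c: rms equals |c|
  tg2 <- tg
  tg2$drop_940 <- tg2$drop_940 + 0.7
  expect_equal(rms_error(best_fit, tg2, 940), 0.7, tolerance = 1e-9)
  # iid noise of sd 0.5: rms concentrates near 0.5
  tg3 <- generate_experiment(best_fit, intensities = 940, t_end = 0.5,
                             dt = 1e-4, noise_sd = 0.5, seed = 2)
  expect_equal(rms_error(best_fit, tg3, 940), 0.5, tolerance = 0.05)
  # no dark state: infinite error, zero density
  pbad <- update_params(best_fit,
                        Jex_sat = 0.51 * best_fit$JcG_max * best_fit$f_Ca)
  expect_equal(rms_error(pbad, tg, 940), Inf)
})

test_that("stationary density applies penalties and hard constraints exactly", {
  tg <- generate_experiment(best_fit, intensities = 940, t_end = 0.3,
                            noise_sd = 0, seed = 1)
  cfg <- mcmc_config(gamma = 5, beta = 2)
  # a point inside every soft interval carries zero penalty:
  # log pi = -beta log(rms) exactly
  p_in <- update_params(best_fit, G_sigma = 600, PDE_sigma = 90)
  lp <- log_density(p_in, tg, config = cfg)
  expect_equal(as.numeric(lp), -cfg$beta * log(attr(lp, "rms")),
               tolerance = 1e-9)
  # pushing an inert parameter one interval-width outside multiplies the
  # density by exactly 2^-gamma (the rms is untouched by D_R)
  p_out <- update_params(p_in, D_R = 3)  # soft range [1, 2], dist = 1
  lp2 <- log_density(p_out, tg, config = cfg)
  expect_equal(as.numeric(lp) - as.numeric(lp2), cfg$gamma * log(2),
               tolerance = 1e-9)
  expect_equal(attr(lp2, "rms"), attr(lp, "rms"), tolerance = 1e-12)
  # the best-fit point itself is penalized for G_sigma and PDE_sigma lying
  # below/above their expected ranges (noisy target keeps the rms away from
  # the numerical floor so the identity is exact)
  tgn <- generate_experiment(best_fit, intensities = 940, t_end = 0.3,
                             noise_sd = 0.2, seed = 12)
  lp3 <- log_density(best_fit, tgn, config = cfg)
  dist <- (500 - best_fit$G_sigma) / 1000 + (best_fit$PDE_sigma - 100) / 90
  expect_equal(as.numeric(lp3),
               -cfg$gamma * log(2) * dist - cfg$beta * log(attr(lp3, "rms")),
               tolerance = 1e-6)
  # violating a derived hard constraint (J_dark window) zeroes the density
  p_hot <- update_params(best_fit, JcG_max = 4200)
  expect_gt(solve_dark_state(p_hot)$J_dark, 27)
  expect_equal(as.numeric(log_density(p_hot, tg, config = cfg)), -Inf)
})

test_that("the MH kernel has the right stationary law on toy densities", {
  # flat density on [0,1]: every in-box proposal is accepted and the
  # marginal is uniform (KS test at the 1% level on thinned samples)
  logf_flat <- function(x) if (x >= 0 && x <= 1) 0 else -Inf
  set.seed(17)
  run <- conesens:::mh_kernel(logf_flat, 0.5, scales = 0.25, n_steps = 20000)
  thinned <- run$samples[seq(50, 20000, by = 20), 1]
  expect_gt(stats::ks.test(thinned, "punif")$p.value, 0.01)
  # acceptance equals the fraction of proposals landing inside the box
  expect_gt(mean(run$accepted), 0.5)

  # standard normal target
  logf_n <- function(x) -0.5 * x^2
  set.seed(18)
  run2 <- conesens:::mh_kernel(logf_n, 0, scales = 1.5, n_steps = 20000)
  thinned2 <- run2$samples[seq(50, 20000, by = 20), 1]
  expect_gt(stats::ks.test(thinned2, "pnorm")$p.value, 0.01)

  # detailed balance of the acceptance ratio: r(x->y) r(y->x) = 1
  x <- 0.3; y <- 1.2
  r_xy <- exp(logf_n(y) - logf_n(x))
  r_yx <- exp(logf_n(x) - logf_n(y))
  expect_equal(r_xy * r_yx, 1, tolerance = 1e-12)
})

test_that("chains are reproducible and honor the hard constraint set", {
  tg <- generate_experiment(best_fit, intensities = 940, t_end = 0.3,
                            noise_sd = 0.3, seed = 4)
  cfg <- mcmc_config(n_steps = 250, seed = 23)
  ch1 <- run_chain(tg, config = cfg)
  ch2 <- run_chain(tg, config = cfg)
  expect_identical(ch1$samples, ch2$samples)
  expect_identical(ch1$errors, ch2$errors)
  # every retained sample satisfies the hard constraints
  audit <- unique(c(1, seq(10, nrow(ch1$samples), by = 10)))
  for (i in audit) {
    p <- params_from_values(setNames(as.numeric(ch1$samples[i, ]),
                                     names(ch1$samples)))
    expect_true(satisfies_hard(p, hard_ranges))
  }
  # best-so-far error is monotone nonincreasing
  expect_true(all(diff(cummin(ch1$errors)) <= 0))
  expect_true(is.finite(ch1$best_rms))
})

test_that("the chain descends toward a noisy self-target", {
  tg <- generate_experiment(best_fit, intensities = 940, noise_sd = 0.5,
                            seed = 6)
  cfg <- mcmc_config(beta = 50, proposal_scale = 0.01, n_steps = 6000,
                     seed = 29)
  ch <- run_chain(tg, config = cfg)
  # best fit within twice the noise floor
  expect_lt(ch$best_rms, 2 * 0.5)
  expect_true(satisfies_hard(ch$best_params, hard_ranges))
})
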