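test_that("integer-degree binning takes medians with banker's rounding", {
  ds <- timing_dataset(1:3, c(18.2, 18.4, 17.9), c(30, 32, 34))
  b <- bin_medians(ds)
  expect_equal(nrow(b), 1)
  expect_equal(b$temperature_c, 18)
  expect_equal(b$median_duration, 32)
  expect_equal(b$n, 3L)

  b1 <- bin_medians(timing_dataset("a", 21.7, 40))
  expect_equal(b1$temperature_c, 22)
  expect_equal(b1$median_duration, 40)

  bdup <- bin_medians(timing_dataset(1:4, rep(20, 4), c(25, 25, 25, 31)))
  expect_equal(bdup$median_duration, 25)

  ## round-half-to-even at the .5 boundary
  b5 <- bin_medians(timing_dataset(1:2, c(18.5, 19.5), c(10, 20)))
  expect_equal(b5$temperature_c, c(18, 20))

  ## configured exclusions drop bins (lowest-temperature outlier rule)
  bx <- bin_medians(timing_dataset(1:3, c(10, 15, 20), c(50, 40, 30)),
                    exclude_bins = 10)
  expect_equal(bx$temperature_c, c(15, 20))
})

test_that("the Arrhenius fitter is exact on noiseless data and equivariant", {
  law <- arrhenius_law_anchored(30, 75, t_ref = 20)
  ds <- gen_embryo_timings(law, 12:21, n_per_temperature = 5, noise_cv = 0)
  b <- bin_medians(ds)
  fit <- fit_arrhenius(b)
  expect_rel(coef(fit)[["ea"]], 75, 1e-9)
  expect_lt(fit$mse_log, 1e-18)

  ## two points interpolate exactly
  fit2 <- fit_arrhenius(bin_medians(ds)[c(1, 8), ])
  expect_lt(fit2$mse_log, 1e-18)
  expect_error(fit_arrhenius(b[1, , drop = FALSE]), "at least 2")

  ## unit equivariance: scaling durations changes the prefactor, never Ea
  b2 <- b; b2$median_duration <- b2$median_duration * 60
  expect_rel(coef(fit_arrhenius(b2))[["ea"]], coef(fit)[["ea"]], 1e-10)

  ## idempotence: refitting the fitted curve returns the same parameters
  b3 <- b
  b3$median_duration <- predict(fit)
  expect_equal(coef(fit_arrhenius(b3)), coef(fit), tolerance = 1e-8)

  ## noisy recovery lands inside its own bootstrap interval
  dsn <- gen_embryo_timings(law, 12:21, n_per_temperature = 200,
                            noise_cv = 0.05, seed = 11)
  boot <- bootstrap_ea(dsn, n_boot = 200, seed = 3)
  expect_gt(75, boot$ci_90[1])
  expect_lt(75, boot$ci_90[2])
})

test_that("the two-step double-exponential fitter recovers its own law", {
  true <- u_shaped_law(d_ref = 30, ea_cold = 75, ea_hot = 320, t_opt = 28)
  tt <- seq(8, 34)
  b <- data.frame(temperature_c = tt,
                  median_duration = eval_duration(true, tt), n = 1L)
  class(b) <- c("binned_medians", "data.frame")
  fit <- fit_double_exp(b, arrhenius_interval = c(8, 20))
  expect_lt(fit$mse_log, 1e-10)

  ## minimum-duration temperature reproduced within half a degree
  fine <- seq(8, 34, by = 0.01)
  t_true <- fine[which.min(eval_duration(true, fine))]
  t_fit <- fine[which.min(eval_duration(fit$law, fine, check_valid = FALSE))]
  expect_lt(abs(t_fit - t_true), 0.5)

  ## nesting: on pure Arrhenius data the DE fit is at least as good as SE
  se_law <- arrhenius_law_anchored(30, 75, t_ref = 20)
  ba <- bin_medians(gen_embryo_timings(se_law, 10:26, 3, noise_cv = 0))
  fit_se <- fit_arrhenius(ba)
  fit_de <- suppressWarnings(fit_double_exp(ba, arrhenius_interval = c(10, 18)))
  expect_lte(fit_de$mse_log, fit_se$mse_log + 1e-12)
})

test_that("QE and PE fitters are exact for linear-in-log-parameters data", {
  qe <- quad_exp_law(3, -55, 35)
  tt <- 10:30
  bq <- data.frame(temperature_c = tt, median_duration = eval_duration(qe, tt),
                   n = 1L)
  class(bq) <- c("binned_medians", "data.frame")
  fq <- fit_quad_exp(bq)
  expect_equal(unname(coef(fq)), unname(coef(qe)), tolerance = 1e-6)
  expect_lt(fq$mse_log, 1e-18)

  ## b = 0 generator: recovers the exponential parameters, b near zero
  qe0 <- quad_exp_law(3, -55, 0)
  bq0 <- bq; bq0$median_duration <- eval_duration(qe0, tt)
  fq0 <- fit_quad_exp(bq0)
  expect_rel(coef(fq0)[["ea"]], -55, 1e-6)
  expect_lt(abs(coef(fq0)[["b"]]), 1e-4)

  pe <- power_exp_law(2, 1.3, -60)
  bp <- data.frame(temperature_c = tt, median_duration = eval_duration(pe, tt),
                   n = 1L)
  class(bp) <- c("binned_medians", "data.frame")
  fp <- fit_power_exp(bp)
  expect_equal(unname(coef(fp)), unname(coef(pe)), tolerance = 1e-5)

  pe0 <- power_exp_law(2, 0, -60)
  bp0 <- bp; bp0$median_duration <- eval_duration(pe0, tt)
  fp0 <- fit_power_exp(bp0)
  expect_rel(coef(fp0)[["ea"]], -60, 1e-6)
  expect_lt(abs(coef(fp0)[["b"]]), 1e-4)

  expect_error(fit_quad_exp(bq[1:2, ]), "at least 3")
})

test_that("fit comparison ranks laws by log-scale error, unit-invariantly", {
  ## U-shaped data: the double exponential must beat the single
  true <- u_shaped_law(d_ref = 30, ea_cold = 75, ea_hot = 320, t_opt = 28)
  tt <- seq(8, 34)
  b <- data.frame(temperature_c = tt,
                  median_duration = eval_duration(true, tt), n = 1L)
  class(b) <- c("binned_medians", "data.frame")
  fits <- list(SE = fit_arrhenius(b, interval = c(8, 20)),
               DE = fit_double_exp(b, arrhenius_interval = c(8, 20)))
  tab <- compare_fits(b, fits)
  expect_lt(tab$mse_log[tab$law == "DE"], tab$mse_log[tab$law == "SE"])

  ## ordering invariant to the duration unit
  b2 <- b; b2$median_duration <- b2$median_duration / 60
  fits2 <- list(SE = fit_arrhenius(b2, interval = c(8, 20)),
                DE = fit_double_exp(b2, arrhenius_interval = c(8, 20)))
  tab2 <- compare_fits(b2, fits2)
  expect_identical(order(tab$mse_log), order(tab2$mse_log))

  ## identical law lists give identical tables
  expect_identical(compare_fits(b, fits), compare_fits(b, fits))

  ## SE on exactly Arrhenius data is essentially perfect
  se_law <- arrhenius_law_anchored(25, 70)
  ba <- bin_medians(gen_embryo_timings(se_law, 12:21, 2, noise_cv = 0))
  expect_lt(compare_fits(ba, list(SE = fit_arrhenius(ba)))$mse_log, 1e-18)
})

test_that("the stratified bootstrap is deterministic and degenerate on noiseless data", {
  law <- arrhenius_law_anchored(30, 75, t_ref = 20)
  ds0 <- gen_embryo_timings(law, 12:20, n_per_temperature = 4, noise_cv = 0)
  b0 <- bootstrap_ea(ds0, n_boot = 50, seed = 5)
  expect_true(all(abs(b0$ea_samples - 75) < 1e-9))

  dsn <- gen_embryo_timings(law, 12:20, n_per_temperature = 20,
                            noise_cv = 0.05, seed = 2)
  ba <- bootstrap_ea(dsn, n_boot = 100, seed = 9)
  bb <- bootstrap_ea(dsn, n_boot = 100, seed = 9)
  expect_identical(ba$ea_samples, bb$ea_samples)
  expect_lte(ba$ci_90[1], ba$ci_90[2])
})

test_that("bootstrap intervals cover the generating energy at the nominal rate", {
  law <- arrhenius_law_anchored(30, 75, t_ref = 20)
  hits <- 0L
  n_meta <- 25L
  for (i in seq_len(n_meta)) {
    ds <- gen_embryo_timings(law, 12:21, n_per_temperature = 30,
                             noise_cv = 0.05, seed = 100 + i)
    boot <- bootstrap_ea(ds, n_boot = 120, seed = 200 + i)
    if (boot$ci_90[1] <= 75 && 75 <= boot$ci_90[2]) hits <- hits + 1L
  }
  expect_gte(hits / n_meta, 0.8)
})
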