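test_that("the right-hand side has the stated structure", {
  p <- ref_params()
  ## empty system is stationary when nothing is synthesised
  p0 <- ref_params()
  p0$ks <- 1e-12
  expect_equal(cellcycle_rhs(c(0, 0), p0), c(1e-12, 0))

  ## cyc = cdk1a kills the activation term, so cdk1a can only fall
  d <- cellcycle_rhs(c(40, 40), p)
  expect_lte(d[2], 0)

  ## rhs vanishes at computed fixed points (root-finding cross-check)
  fp <- fixed_points(p)
  for (j in seq_len(nrow(fp))) {
    d <- cellcycle_rhs(c(fp$cyc[j], fp$cdk1a[j]), p)
    expect_lt(max(abs(d)), 1e-6)
  }
})

test_that("compiled and pure-R right-hand sides integrate identically", {
  p <- ref_params()
  s1 <- simulate(p, t_end = 60, compiled = TRUE)
  s2 <- simulate(p, t_end = 60, compiled = FALSE)
  expect_lt(max(abs(s1$cyc - s2$cyc)), 1e-4)
  expect_lt(max(abs(s1$cdk1a - s2$cdk1a)), 1e-4)
})

test_that("the reference set oscillates with sawtooth cyclin dynamics", {
  sim <- ref_sim()
  pr <- detect_period(sim)
  expect_true(pr$oscillating)
  ## sawtooth asymmetry: cyclin builds up slowly and is destroyed fast
  pk <- pr$peak_times
  late <- sim[sim$time > pk[length(pk) - 1] & sim$time <= pk[length(pk)], ]
  rise_time <- mean(diff(late$cyc) > 0)
  expect_gt(rise_time, 0.6)

  ## ks = 0-like decay: no production, trajectory decays, no oscillation
  p0 <- ref_params()
  p0$ks <- 1e-9
  s0 <- simulate(p0, t_end = 300, init = c(cyc = 40, cdk1a = 5))
  expect_false(detect_period(s0)$oscillating)
  expect_lt(s0$cyc[nrow(s0)], 1)
})

test_that("trajectories preserve 0 <= cdk1a <= cyc and stay finite", {
  for (ks in c(1.2, 2.2, 2.8)) {
    sim <- simulate(ref_params(ks = ks), t_end = 200,
                    init = c(cyc = 10, cdk1a = 2))
    expect_true(all(is.finite(sim$cyc)), info = paste("ks =", ks))
    expect_true(all(sim$cdk1a <= sim$cyc + 1e-6))
    expect_true(all(sim$cdk1a >= -1e-6))
  }
})

test_that("relaxation limit: shrinking eps barely changes the period", {
  pr1 <- detect_period(simulate(ref_params(eps = 0.02), t_end = 300))
  pr2 <- detect_period(simulate(ref_params(eps = 0.002), t_end = 300))
  expect_rel(pr2$period, pr1$period, 0.05)
})

test_that("rate/time rescaling divides the period by the same factor", {
  lam <- 2
  p <- ref_params()
  ps <- ref_params(ks = p$ks * lam, kd = p$kd * lam,
                   ka = p$ka * lam, ki = p$ki * lam)
  ## eps is a ratio of timescales: both sides of the fast equation carry
  ## lambda, so eps stays; time compresses uniformly
  pr <- detect_period(ref_sim())
  prs <- detect_period(simulate(ps, t_end = 300, dt = 0.05))
  expect_rel(prs$period, pr$period / lam, 0.01)
})

test_that("nullclines depend only on the rate ratios and locate fixed points", {
  p <- ref_params()
  grid <- seq(1, 110, length.out = 200)
  nc <- nullclines(p, grid)

  p2 <- ref_params(ks = p$ks * 3, kd = p$kd * 3)
  nc2 <- nullclines(p2, grid)
  expect_equal(nc2$cyc_cyclin_nc, nc$cyc_cyclin_nc, tolerance = 1e-12)

  p3 <- ref_params(ka = p$ka * 5, ki = p$ki * 5)
  nc3 <- nullclines(p3, grid)
  expect_equal(nc3$cyc_cdk1_nc, nc$cyc_cdk1_nc, tolerance = 1e-12)

  ## intersections coincide with fixed points found independently
  fp <- fixed_points(p)
  f <- function(y) {
    p$ks / (p$kd * eval_hill(p$deg, y)) -
      y * (1 + (p$ki * eval_hill(p$wee1, y)) / (p$ka * eval_hill(p$cdc25, y)))
  }
  for (y in fp$cdk1a) expect_lt(abs(f(y)), 1e-6)
})

test_that("fixed-point stability classifies cell-cycle arrest states", {
  ## reference set: single unstable fixed point, sustained limit cycle
  fp <- fixed_points(ref_params())
  expect_equal(nrow(fp), 1)
  expect_false(fp$stable)
  expect_identical(fp$arrest_class, "none")

  ## starving the oscillator of cyclin synthesis arrests in interphase
  fp_lo <- fixed_points(ref_params(ks = 2.2 * 0.3))
  expect_true(all(fp_lo$stable))
  expect_true("interphase-like" %in% fp_lo$arrest_class)
  expect_false(detect_period(simulate(ref_params(ks = 2.2 * 0.3),
                                      t_end = 400))$oscillating)

  ## excess synthesis arrests in an M-phase-like high-Cdk1 state
  fp_hi <- fixed_points(ref_params(ks = 2.2 * 4))
  expect_true(all(fp_hi$stable))
  expect_true("m-phase-like" %in% fp_hi$arrest_class)
  expect_false(detect_period(simulate(ref_params(ks = 2.2 * 4),
                                      t_end = 400))$oscillating)
})

test_that("oscillation coincides with a unique unstable steady state across a ks scan", {
  for (f in c(0.4, 0.7, 1, 1.8, 3.2)) {
    p <- ref_params(ks = 2.2 * f)
    fp <- fixed_points(p)
    osc <- detect_period(simulate(p, t_end = 500))$oscillating
    only_unstable <- nrow(fp) == 1 && !fp$stable[1]
    expect_identical(osc, only_unstable, info = paste("ks factor", f))
  }
})

test_that("temperature maps anchor, scale and extrapolate as declared", {
  p <- ref_params()
  ## anchoring: the reference temperature returns the reference parameters
  m <- case1_map(75)
  expect_equal(params_at_temperature(m, 20)$ks, p$ks, tolerance = 1e-12)

  ## equal activation energies keep the rate ratios temperature-invariant
  pa <- params_at_temperature(m, 10); pb <- params_at_temperature(m, 30)
  expect_rel(pa$ks / pa$kd, pb$ks / pb$kd, 1e-12)
  expect_rel(pa$ka / pa$ki, pb$ka / pb$ki, 1e-12)

  ## Ea(ks) > Ea(kd) makes ks/kd strictly increasing in temperature
  m3 <- case3_map()
  ratios <- vapply(seq(10, 30, by = 5), function(tc) {
    q <- params_at_temperature(m3, tc); q$ks / q$kd
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))

  ## outside the declared interval: warn, extrapolate
  expect_warning(params_at_temperature(m3, 50), "extrapolating")

  ## titration factors act on the anchor only
  ms <- scale_map(m3, synthesis_factor = 2, degradation_factor = 0.5)
  q0 <- params_at_temperature(m3, 25); q1 <- params_at_temperature(ms, 25)
  expect_rel(q1$ks, 2 * q0$ks, 1e-12)
  expect_rel(q1$kd, 0.5 * q0$kd, 1e-12)

  ## biphasic curve peaks at its stated optimum
  cv <- rate_curve_biphasic(2, 113, 300, t_opt = 30, t_ref = 20)
  tt <- seq(20, 40, by = 0.25)
  k <- vapply(tt, function(x) eval_rate(cv, x), numeric(1))
  expect_lt(abs(tt[which.max(k)] - 30), 0.5)
  expect_equal(eval_rate(cv, 20), 2, tolerance = 1e-12)
})
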