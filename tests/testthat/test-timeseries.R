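sawtooth_droplet <- function(period = 40, rise = 30, t_end = 400, dt = 1,
                             id = "d1", radius = 80, start = 0, temp = 20) {
  tt <- seq(start, t_end, by = dt)
  ph <- (tt %% period)
  x <- ifelse(ph < rise, ph / rise, 1 - (ph - rise) / (period - rise))
  droplet_record(id, radius, start, temp, tt, 0.9 + 0.5 * x)
}

test_that("QC keeps small early-tracked droplets and logs rejection reasons", {
  d_ok <- sawtooth_droplet(id = "ok", radius = 80, start = 10)
  d_big <- sawtooth_droplet(id = "big", radius = 120, start = 10)
  d_late <- sawtooth_droplet(id = "late", radius = 80, start = 61)
  res <- qc_filter(list(d_ok, d_big, d_late))
  expect_equal(vapply(res$kept, function(d) d$droplet_id, ""), "ok")
  expect_equal(res$rejected$droplet_id, c("big", "late"))
  expect_equal(res$rejected$reason, c("radius", "track_start"))
})

test_that("cycle segmentation recovers constructed sawtooth phases", {
  d <- sawtooth_droplet(period = 40, rise = 30, dt = 1)
  seg <- segment_cycles(d)
  expect_gt(nrow(seg), 5)
  ## alternation and additivity contracts
  expect_true(all(seg$trough_time < seg$peak_time))
  expect_true(all(seg$peak_time < seg$next_trough_time))
  expect_equal(seg$rising_duration + seg$falling_duration, seg$period,
               tolerance = 1e-9)
  mid <- seg[seg$cycle >= 2, ]
  expect_equal(median(mid$rising_duration), 30, tolerance = 1)
  expect_equal(median(mid$falling_duration), 10, tolerance = 1)

  ## monotone series: empty segmentation, not an error
  tt <- seq(0, 100, by = 1)
  mono <- droplet_record("m", 50, 0, 20, tt, 1 + 0.001 * tt)
  expect_equal(nrow(segment_cycles(mono)), 0)

  ## model-generated proxy: interphase occupies most of the cycle
  dm <- gen_droplets(extract_map(), 20, n_droplets_per_temperature = 1,
                     obs_noise_sd = 0, seed = 3, t_end = 300)[[1]]
  segm <- segment_cycles(dm)
  segm <- segm[segm$cycle >= 2, ]
  expect_true(all(segm$rising_duration > segm$falling_duration))
})

test_that("segmentation and period detection agree on the same series", {
  sim <- ref_sim()
  seg <- segment_cycles(data.frame(time = sim$time, value = sim$cdk1a),
                        min_separation = 5)
  pr <- detect_period(sim)
  expect_equal(median(seg$period), pr$period, tolerance = 0.2)
})

test_that("cycle selection implements both windowing rules", {
  seg <- segment_cycles(sawtooth_droplet(period = 40, rise = 30, t_end = 400))
  s24 <- select_cycles(seg, "cycles_2_to_4")
  expect_equal(s24$cycle, 2:4)

  s300 <- select_cycles(seg, "first_300_min")
  expect_true(all(s300$trough_time < 300))
  ## boundary rule: a cycle belongs iff its starting trough is before 300
  expect_equal(nrow(s300), sum(seg$trough_time < 300))

  one <- seg[1, , drop = FALSE]
  expect_equal(nrow(select_cycles(one, "cycles_2_to_4")), 0)
})

test_that("the interphase slope reads the synthesis rate off the rising segment", {
  ## exactly linear rising segment returns its slope, offset-invariantly
  d <- sawtooth_droplet(period = 40, rise = 30, dt = 1)
  seg <- segment_cycles(d)
  sl <- interphase_slope(d, seg, 2)
  expect_equal(sl, 0.5 / 30, tolerance = 1e-2)
  d2 <- d; d2$fret_ratio <- d$fret_ratio + 3
  expect_equal(interphase_slope(d2, seg, 2), sl, tolerance = 1e-12)

  ## model property: in the relaxation regime the slope responds
  ## proportionally to a small change in ks alone (measured in native
  ## cdk1a units; larger ks changes also move the waveform's excursion,
  ## so proportionality is a local property)
  slope_at <- function(ks_factor) {
    sim <- simulate(ref_params(ks = 2.2 * ks_factor, eps = 0.02),
                    t_end = 300)
    sub <- sim[sim$time %in% seq(0, 300, by = 1), ]
    dn <- droplet_record("n", 50, 0, 20, sub$time, sub$cdk1a)
    segn <- segment_cycles(dn, min_separation = 10)
    median(vapply(segn$cycle[segn$cycle >= 2 & segn$cycle <= 5],
                  function(k) interphase_slope(dn, segn, k), numeric(1)))
  }
  expect_rel(slope_at(1.05) / slope_at(1), 1.05, 0.05)
})

test_that("waveform averaging is phase-aligned and tracks dispersion", {
  d <- sawtooth_droplet(period = 40, rise = 30, dt = 1, t_end = 300)
  avg <- average_waveform(list(d), n_phase_bins = 41)
  ## identical cycles: dispersion essentially zero, shape equals the cycle
  expect_lt(max(avg$sd), 0.02)
  expect_equal(avg$mean[which.max(avg$mean)], 1.4, tolerance = 0.02)
  expect_equal(avg$phase[which.max(avg$mean)], 0.75, tolerance = 0.05)

  ## phase-shifted copies average to the same shape
  d2 <- sawtooth_droplet(period = 40, rise = 30, dt = 1, t_end = 300,
                         start = 13)
  avg2 <- average_waveform(list(d2), n_phase_bins = 41)
  expect_lt(max(abs(avg2$mean - avg$mean)), 0.03)

  ## additive noise on a model-generated ensemble appears as pointwise
  ## dispersion of matching size (edge-anchored alignment is noise-robust)
  drn <- gen_droplets(case1_map(75), 20, n_droplets_per_temperature = 4,
                      obs_noise_sd = 0.02, drift_per_cycle = 0, seed = 12,
                      t_end = 300, sampling_interval = 3)
  avgn <- average_waveform(drn, n_phase_bins = 41,
                           select_mode = "first_300_min")
  expect_gt(median(avgn$sd), 0.5 * 0.02)
  expect_lt(median(avgn$sd), 2 * 0.02)

  expect_error(average_waveform(list(sawtooth_droplet(t_end = 50))),
               "at least 3")
})

test_that("assay rates are recovered from linear and exponential series", {
  tt <- seq(0, 60, by = 4)
  ## exact line
  lin <- fit_rate(tt, 1 + 2 * tt, "synthesis")
  expect_equal(lin$rate, 2, tolerance = 1e-9)

  ## exact exponential decay without baseline
  dec <- fit_rate(seq(0, 100, by = 4), exp(-0.1 * seq(0, 100, by = 4)),
                  "degradation")
  expect_equal(dec$rate, 0.1, tolerance = 1e-2)

  ## decay onto a plateau: baseline estimated from the tail
  tt2 <- seq(0, 100, by = 2)
  sig <- 0.2 + 1 * exp(-0.1 * tt2)
  dec2 <- suppressWarnings(fit_rate(tt2, sig, "degradation"))
  expect_equal(dec2$rate, 0.1, tolerance = 1e-3)
  expect_equal(dec2$baseline, 0.2, tolerance = 1e-2)

  ## the linear window stops growing when curvature appears; a strict
  ## threshold pins the window exactly to the linear stretch
  tt3 <- seq(0, 40, by = 2)
  bend <- ifelse(tt3 <= 20, 2 * tt3, 40 + 0.1 * (tt3 - 20))
  fb <- fit_rate(tt3, bend, "kinase", r2_min = 0.999)
  expect_equal(fb$rate, 2, tolerance = 1e-6)
  expect_equal(fb$window[2], 20)

  expect_error(fit_rate(tt[1:3], (1:3) * 1.0, "synthesis"))
})

test_that("per-temperature rates map onto activation energies with bootstrap", {
  ## noiseless Arrhenius rates are recovered exactly
  assays <- gen_assays("synthesis", ea = 87, rate_ref = 0.05,
                       temperatures = 16:26, n_per_temperature = 3,
                       noise_sd = 0, seed = 1)
  rates <- do.call(rbind, lapply(assays, function(a)
    data.frame(series_id = attr(a, "series_id"),
               temperature_c = attr(a, "temperature_c"),
               rate = fit_rate(a$time, a$signal, attr(a, "assay_kind"))$rate)))
  res <- rates_to_ea(rates, n_boot = 100, seed = 2)
  expect_rel(coef(res$fit)[["ea"]], 87, 1e-6)

  ## unit change of the signal leaves the activation energy untouched
  rates2 <- rates; rates2$rate <- rates2$rate * 2
  res2 <- rates_to_ea(rates2, n_boot = 100, seed = 2)
  expect_rel(coef(res2$fit)[["ea"]], coef(res$fit)[["ea"]], 1e-9)

  ## synthesis (87) and degradation (51) distributions separate
  mk <- function(kind, ea, seed) {
    aa <- gen_assays(kind, ea = ea, rate_ref = 0.05, temperatures = 16:26,
                     n_per_temperature = 10, noise_sd = 0, seed = seed)
    rr <- do.call(rbind, lapply(aa, function(a) {
      r <- fit_rate(a$time, a$signal, attr(a, "assay_kind"))$rate
      data.frame(series_id = attr(a, "series_id"),
                 temperature_c = attr(a, "temperature_c"),
                 ## cv 0.1 noise on the fitted rate
                 rate = r)
    }))
    set.seed(seed + 1)
    rr$rate <- rr$rate * exp(rnorm(nrow(rr), 0, sqrt(log(1 + 0.1^2))))
    rr
  }
  bs <- rates_to_ea(mk("synthesis", 87, 31), n_boot = 300, seed = 7)$bootstrap
  bd <- rates_to_ea(mk("degradation", 51, 41), n_boot = 300, seed = 7)$bootstrap
  ## 90% intervals do not meaningfully overlap
  expect_gt(bs$ci_90[1], bd$ci_90[2] - 0.1 * diff(bd$ci_90))
})
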