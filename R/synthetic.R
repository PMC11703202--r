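#' Generate synthetic embryo event-timing data
#'
#' Durations are drawn from the true scaling law with multiplicative
#' lognormal noise, \eqn{\Delta t_{ij} = \Delta t(T_i) e^{\varepsilon}},
#' \eqn{\varepsilon \sim N(0, \sqrt{\ln(1 + cv^2)})}. The noise is centred
#' on the log scale so the per-bin median equals the law exactly in
#' expectation (durations are positive and the fitting pipeline works on
#' binned medians, which this noise model leaves unbiased).
#'
#' @param law the true `scaling_law`.
#' @param temperatures temperatures to sample at, degrees Celsius.
#' @param n_per_temperature embryos per temperature (>= 1).
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (>= 0; 0 reproduces the law exactly).
#' @param seed RNG seed (datasets are bit-identical under a fixed seed).
#' @param interval_name interval label for the records.
#' @return a [timing_dataset()].
#' @export
gen_embryo_timings <- function(law, temperatures, n_per_temperature = 10,
                               noise_cv = 0.05, seed = 1,
                               interval_name = "cycle") {
  stopifnot(noise_cv >= 0, n_per_temperature >= 1)
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  rows <- list()
  uid <- 0L
  for (tc in temperatures) {
    mu <- eval_duration(law, tc, check_valid = FALSE)
    eps <- if (noise_cv > 0) rnorm(n_per_temperature, 0, sdlog) else
      rep(0, n_per_temperature)
    rows[[length(rows) + 1]] <- data.frame(
      unit_id = sprintf("embryo_%04d", uid + seq_len(n_per_temperature)),
      temperature_c = tc, duration_min = mu * exp(eps))
    uid <- uid + n_per_temperature
  }
  df <- do.call(rbind, rows)
  timing_dataset(df$unit_id, df$temperature_c, df$duration_min,
                 interval_name = interval_name)
}

## piecewise-linear time warp implementing per-cycle period drift:
## base-trajectory cycle j (between consecutive cdk1a troughs) is stretched
## by (1 + drift)^(j-1) on the droplet clock.
drift_warp <- function(base_knots, drift) {
  durations <- diff(base_knots)
  stretched <- durations * (1 + drift)^(seq_along(durations) - 1)
  droplet_knots <- c(base_knots[1], base_knots[1] + cumsum(stretched))
  function(tau) approx(droplet_knots, base_knots, xout = tau, rule = 2)$y
}

#' Generate synthetic droplet FRET recordings
#'
#' Simulates the two-ODE model at each temperature through the parameter
#' map, converts active Cdk1 to a FRET-ratio proxy by an affine map onto
#' `fret_range` (only shape and timing matter downstream), optionally
#' applies a per-cycle period drift (each completed cycle is longer than
#' the previous by a factor `1 + drift_per_cycle`, emulating the slowing
#' of extract cycles over time), samples at `sampling_interval` minutes
#' from the droplet's track start, and adds Gaussian observation noise.
#' Radii are lognormal and track starts uniform, so some droplets fail the
#' QC thresholds by construction.
#'
#' @param map a `temperature_map`.
#' @param temperatures temperatures, degrees Celsius.
#' @param n_droplets_per_temperature droplets per temperature.
#' @param obs_noise_sd additive noise on the FRET proxy (ratio units).
#' @param drift_per_cycle fractional period lengthening per completed
#'   cycle (>= 0).
#' @param radius_meanlog,radius_sdlog lognormal radius parameters (um).
#' @param track_start_max track starts are uniform on [0, this], minutes.
#' @param sampling_interval sampling step, minutes.
#' @param t_end recording end on the droplet clock, minutes.
#' @param fret_range affine target range of the FRET proxy.
#' @param seed RNG seed.
#' @param ... forwarded to [simulate.cellcycle_model()].
#' @return list of [droplet_record()]s; the underlying noiseless model
#'   trajectory parameters are attached as attribute `truth`.
#' @export
gen_droplets <- function(map, temperatures, n_droplets_per_temperature = 5,
                         obs_noise_sd = 0.01, drift_per_cycle = 0,
                         radius_meanlog = log(50), radius_sdlog = 0.35,
                         track_start_max = 30, sampling_interval = 5,
                         t_end = 500, fret_range = c(0.9, 1.4), seed = 1,
                         ...) {
  stopifnot(sampling_interval > 0, drift_per_cycle >= 0)
  set.seed(seed)
  droplets <- list()
  uid <- 0L
  for (tc in temperatures) {
    p <- suppressWarnings(params_at_temperature(map, tc))
    sim <- simulate(p, t_end = t_end * (1 + drift_per_cycle)^1 + 100, ...)
    lo <- min(sim$cdk1a); hi <- max(sim$cdk1a)
    fret <- fret_range[1] + (sim$cdk1a - lo) / (hi - lo) * diff(fret_range)
    tr <- find_troughs(sim$time, sim$cdk1a,
                       min_prominence = 0.1 * (hi - lo), min_separation = 5)
    knots <- unique(c(0, tr$time, max(sim$time)))
    warp <- drift_warp(knots, drift_per_cycle)
    for (k in seq_len(n_droplets_per_temperature)) {
      uid <- uid + 1L
      radius <- rlnorm(1, radius_meanlog, radius_sdlog)
      start <- runif(1, 0, track_start_max)
      tau <- seq(start, t_end, by = sampling_interval)
      base_t <- warp(tau)
      y <- approx(sim$time, fret, xout = base_t, rule = 2)$y
      if (obs_noise_sd > 0) y <- y + rnorm(length(y), 0, obs_noise_sd)
      droplets[[uid]] <- droplet_record(
        droplet_id = sprintf("drop_%04d", uid), radius_um = radius,
        track_start_min = start, temperature_c = tc,
        time_min = tau, fret_ratio = y)
    }
  }
  attr(droplets, "truth") <- list(map = map, drift_per_cycle = drift_per_cycle,
                                  sampling_interval = sampling_interval,
                                  fret_range = fret_range)
  droplets
}

#' Generate synthetic in-vitro assay series
#'
#' Linear kinds (synthesis, kinase, phosphatase) produce a straight line
#' with the true per-temperature slope; degradation produces
#' `baseline + amplitude * exp(-k t)`. The true rate at each temperature
#' comes from an Arrhenius law anchored at `rate_ref` (at `t_ref`).
#' Gaussian noise is added to the signal.
#'
#' @param assay_kind see [fit_rate()].
#' @param ea activation energy of the true rate, kJ/mol.
#' @param rate_ref true rate at `t_ref` (a.u./min, or 1/min for
#'   degradation).
#' @param t_ref anchor temperature, degrees Celsius.
#' @param temperatures assay temperatures, degrees Celsius.
#' @param n_per_temperature repeats per temperature.
#' @param duration_min length of each series, minutes.
#' @param dt_min sampling step, minutes.
#' @param noise_sd additive Gaussian noise, signal units.
#' @param baseline plateau of degradation series.
#' @param amplitude initial excess over baseline (degradation) or signal
#'   at time zero offset (linear kinds' intercept).
#' @param seed RNG seed.
#' @return list of assay series; each element is a data frame with
#'   columns `time`, `signal` and attributes `temperature_c`,
#'   `assay_kind`, `true_rate`, `series_id`.
#' @export
gen_assays <- function(assay_kind = "synthesis", ea = 87, rate_ref = 0.05,
                       t_ref = 20, temperatures = 16:26,
                       n_per_temperature = 3, duration_min = 100, dt_min = 4,
                       noise_sd = 0, baseline = 0.2, amplitude = 1, seed = 1) {
  set.seed(seed)
  curve <- rate_curve_arrhenius(rate_ref, ea, t_ref = t_ref)
  out <- list()
  uid <- 0L
  times <- seq(0, duration_min, by = dt_min)
  for (tc in temperatures) {
    k <- eval_rate(curve, tc)
    for (r in seq_len(n_per_temperature)) {
      uid <- uid + 1L
      signal <- if (assay_kind == "degradation")
        baseline + amplitude * exp(-k * times)
      else amplitude + k * times
      if (noise_sd > 0) signal <- signal + rnorm(length(times), 0, noise_sd)
      ser <- data.frame(time = times, signal = signal)
      attr(ser, "temperature_c") <- tc
      attr(ser, "assay_kind") <- assay_kind
      attr(ser, "true_rate") <- k
      attr(ser, "series_id") <- sprintf("%s_%03d", assay_kind, uid)
      out[[uid]] <- ser
    }
  }
  out
}
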