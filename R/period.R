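## Local maxima of a sampled series with prominence and separation filters.
## Prominence of a peak: height minus the higher of the two minima separating
## it from the nearest higher ground on each side (series ends count as
## boundaries). Peak times are refined by a local quadratic through the
## three samples around each maximum so periods are not quantised to the
## sampling step.
find_peaks <- function(times, x, min_prominence = 0, min_separation = 0,
                       refine = TRUE) {
  n <- length(x)
  if (n < 3) return(data.frame(time = numeric(0), value = numeric(0)))
  isl <- which(diff(sign(diff(x))) < 0) + 1
  ## plateau handling: keep first index of flat tops
  if (!length(isl)) return(data.frame(time = numeric(0), value = numeric(0)))
  keep <- logical(length(isl))
  prom <- numeric(length(isl))
  for (k in seq_along(isl)) {
    i <- isl[k]
    ## walk left to the nearest strictly higher sample
    jl <- i - 1; lmin <- x[i]
    while (jl >= 1 && x[jl] <= x[i]) { if (x[jl] < lmin) lmin <- x[jl]; jl <- jl - 1 }
    jr <- i + 1; rmin <- x[i]
    while (jr <= n && x[jr] <= x[i]) { if (x[jr] < rmin) rmin <- x[jr]; jr <- jr + 1 }
    base <- if (jl >= 1 && jr <= n) max(lmin, rmin) else min(lmin, rmin)
    prom[k] <- x[i] - base
    keep[k] <- prom[k] >= min_prominence
  }
  isl <- isl[keep]; prom <- prom[keep]
  ## enforce minimum separation, keeping the more prominent peak
  if (min_separation > 0 && length(isl) > 1) {
    ord <- order(prom, decreasing = TRUE)
    sel <- logical(length(isl))
    taken <- numeric(0)
    for (k in ord) {
      tk <- times[isl[k]]
      if (!length(taken) || all(abs(taken - tk) >= min_separation)) {
        sel[k] <- TRUE
        taken <- c(taken, tk)
      }
    }
    isl <- sort(isl[sel])
  }
  pt <- times[isl]; pv <- x[isl]
  if (refine && length(isl)) {
    for (k in seq_along(isl)) {
      i <- isl[k]
      if (i > 1 && i < n) {
        y0 <- x[i - 1]; y1 <- x[i]; y2 <- x[i + 1]
        den <- y0 - 2 * y1 + y2
        if (is.finite(den) && den < 0) {
          delta <- 0.5 * (y0 - y2) / den
          delta <- max(min(delta, 0.5), -0.5)
          h <- (times[i + 1] - times[i - 1]) / 2
          pt[k] <- times[i] + delta * h
          pv[k] <- y1 - 0.25 * (y0 - y2) * delta
        }
      }
    }
  }
  data.frame(time = pt, value = pv)
}

find_troughs <- function(times, x, min_prominence = 0, min_separation = 0,
                         refine = TRUE) {
  tr <- find_peaks(times, -x, min_prominence, min_separation, refine)
  tr$value <- -tr$value
  tr
}

#' Detect the limit-cycle period of a simulated trajectory
#'
#' Peaks are found on the cyclin variable (local maxima with a minimum
#' prominence of `peak_prominence` times the series range and a minimum
#' separation of `min_separation` minutes). The period is the time between
#' the last two peaks. The system is classified as oscillating only when
#' those two peak heights agree to within `amp_tol` (relative): decaying
#' peaks indicate damped, not sustained, oscillation. Rising and falling
#' phase durations are measured on the active-Cdk1 variable over the final
#' full trough-peak-trough cycle.
#'
#' @param ts a `cellcycle_sim` or data frame with a `time` column plus
#'   `cyc` (and optionally `cdk1a`) columns; a single unnamed value column
#'   is used for both roles.
#' @param peak_prominence minimum peak prominence as a fraction of the
#'   series range.
#' @param min_separation minimum peak separation, minutes of model time.
#' @param amp_tol relative tolerance on the heights of the last two peaks.
#' @return an object of class `period_result`: list with `oscillating`,
#'   `period` (min, `NA` when not oscillating), `peak_times`,
#'   `rising_duration`, `falling_duration`.
#' @export
detect_period <- function(ts, peak_prominence = 0.1, min_separation = 5,
                          amp_tol = 0.05) {
  stopifnot(is.data.frame(ts), "time" %in% names(ts))
  vcols <- setdiff(names(ts), "time")
  ccol <- if ("cyc" %in% vcols) "cyc" else vcols[1]
  acol <- if ("cdk1a" %in% vcols) "cdk1a" else ccol
  tt <- ts$time; x <- ts[[ccol]]
  rng <- diff(range(x))
  res <- list(oscillating = FALSE, period = NA_real_,
              peak_times = numeric(0),
              rising_duration = NA_real_, falling_duration = NA_real_)
  class(res) <- "period_result"
  if (rng <= 0) return(res)
  pk <- find_peaks(tt, x, min_prominence = peak_prominence * rng,
                   min_separation = min_separation)
  res$peak_times <- pk$time
  if (nrow(pk) < 2) return(res)
  if (nrow(pk) < 3)
    warning("fewer than 3 peaks detected; trajectory may be too short")
  h1 <- pk$value[nrow(pk) - 1]; h2 <- pk$value[nrow(pk)]
  if (abs(h2 - h1) > amp_tol * max(abs(h1), abs(h2))) return(res)
  res$oscillating <- TRUE
  res$period <- pk$time[nrow(pk)] - pk$time[nrow(pk) - 1]
  ## rising/falling on the cdk1a variable, final full cycle
  y <- ts[[acol]]
  ypk <- find_peaks(tt, y, min_prominence = peak_prominence * diff(range(y)),
                    min_separation = min_separation)
  ytr <- find_troughs(tt, y, min_prominence = peak_prominence * diff(range(y)),
                      min_separation = min_separation)
  if (nrow(ypk) >= 1 && nrow(ytr) >= 2) {
    lastpk <- max(ypk$time[ypk$time < max(ytr$time)], -Inf)
    if (is.finite(lastpk)) {
      t_next <- min(ytr$time[ytr$time > lastpk])
      prev <- ytr$time[ytr$time < lastpk]
      if (length(prev)) {
        t_prev <- max(prev)
        res$rising_duration <- lastpk - t_prev
        res$falling_duration <- t_next - lastpk
      }
    }
  }
  res
}

#' @export
print.period_result <- function(x, ...) {
  if (x$oscillating)
    cat(sprintf("oscillating, period %.2f min (rising %.2f, falling %.2f)\n",
                x$period, x$rising_duration, x$falling_duration))
  else cat("not oscillating\n")
  invisible(x)
}

sweep_one <- function(map, temp, t_end, dt, rtol, atol, detect_args) {
  p <- suppressWarnings(params_at_temperature(map, temp))
  sim <- simulate(p, t_end = t_end, dt = dt, rtol = rtol, atol = atol)
  do.call(detect_period, c(list(sim), detect_args))
}

#' Period versus temperature for a parameter map
#'
#' Simulates the oscillator at each grid temperature, detects the period
#' and phase durations, and locates the thermal limits of oscillation.
#' The outermost oscillating grid points are refined by bisection against
#' their non-oscillating neighbours to `limit_resolution` degrees; when
#' the system oscillates at a grid end the corresponding limit is `NA`
#' (undetermined at that grid). `t_opt` is the period-minimising
#' temperature (quadratic interpolation around the grid argmin).
#'
#' @param map a `temperature_map`.
#' @param grid temperatures in degrees Celsius, sorted increasing.
#' @param t_end,dt,rtol,atol forwarded to [simulate.cellcycle_model()].
#' @param refine_limits bisect the thermal limits.
#' @param limit_resolution bisection resolution, degrees Celsius.
#' @param detect_args list of overrides for [detect_period()].
#' @return an object of class `period_curve`: data frame with columns
#'   `temperature_c`, `period`, `rising`, `falling`, `oscillating`, and
#'   attributes `t_min`, `t_max`, `t_opt`.
#' @export
temperature_sweep <- function(map, grid, t_end = 1000, dt = 0.1,
                              rtol = 1e-8, atol = 1e-10,
                              refine_limits = TRUE, limit_resolution = 0.1,
                              detect_args = list()) {
  stopifnot(!is.unsorted(grid))
  res <- lapply(grid, function(tc)
    sweep_one(map, tc, t_end, dt, rtol, atol, detect_args))
  curve <- data.frame(
    temperature_c = grid,
    period = vapply(res, function(r) r$period, numeric(1)),
    rising = vapply(res, function(r) r$rising_duration, numeric(1)),
    falling = vapply(res, function(r) r$falling_duration, numeric(1)),
    oscillating = vapply(res, function(r) r$oscillating, logical(1))
  )
  osc <- which(curve$oscillating)
  t_min <- t_max <- t_opt <- NA_real_
  if (length(osc)) {
    lo <- min(osc); hi <- max(osc)
    oscillates_at <- function(tc)
      sweep_one(map, tc, t_end, dt, rtol, atol, detect_args)$oscillating
    bisect <- function(t_yes, t_no) {
      while (abs(t_yes - t_no) > limit_resolution) {
        mid <- (t_yes + t_no) / 2
        if (oscillates_at(mid)) t_yes <- mid else t_no <- mid
      }
      (t_yes + t_no) / 2
    }
    if (lo > 1) t_min <- if (refine_limits) bisect(grid[lo], grid[lo - 1]) else grid[lo]
    if (hi < length(grid)) t_max <- if (refine_limits) bisect(grid[hi], grid[hi + 1]) else grid[hi]
    ## interpolated period minimum
    i0 <- osc[which.min(curve$period[osc])]
    t_opt <- grid[i0]
    if (i0 > 1 && i0 < nrow(curve) &&
        curve$oscillating[i0 - 1] && curve$oscillating[i0 + 1]) {
      y0 <- curve$period[i0 - 1]; y1 <- curve$period[i0]; y2 <- curve$period[i0 + 1]
      den <- y0 - 2 * y1 + y2
      if (is.finite(den) && den > 0)
        t_opt <- grid[i0] + 0.5 * (y0 - y2) / den *
          (grid[i0 + 1] - grid[i0 - 1]) / 2
    }
  }
  structure(curve, t_min = t_min, t_max = t_max, t_opt = t_opt,
            class = c("period_curve", "data.frame"))
}

#' Thermal limits of a period curve
#' @param curve a `period_curve`.
#' @return named vector `c(t_min, t_max, t_opt)` in degrees Celsius
#'   (`NA` where undetermined).
#' @export
thermal_limits <- function(curve) {
  c(t_min = attr(curve, "t_min"), t_max = attr(curve, "t_max"),
    t_opt = attr(curve, "t_opt"))
}

#' @export
print.period_curve <- function(x, ...) {
  cat(sprintf("<period curve: %d temperatures, %d oscillating>\n",
              nrow(x), sum(x$oscillating)))
  lim <- thermal_limits(x)
  cat(sprintf("  t_min = %s, t_max = %s, t_opt = %s degC\n",
              format(lim[1]), format(lim[2]), format(lim[3])))
  print.data.frame(x)
  invisible(x)
}

#' @export
plot.period_curve <- function(x, log_arrhenius = FALSE, ...) {
  ok <- x$oscillating
  if (log_arrhenius) {
    plot(1 / kelvin(x$temperature_c[ok]), log(x$period[ok]),
         xlab = "1/T (1/K)", ylab = "ln period", ...)
  } else {
    plot(x$temperature_c[ok], x$period[ok], type = "b",
         xlab = "temperature (degC)", ylab = "period (min)", ...)
  }
  invisible(x)
}

#' Fit an Arrhenius law to a period curve
#'
#' Convenience wrapper: treats each oscillating grid point's period as a
#' duration measurement and runs the standard log-linear fit, returning
#' the apparent activation energy of the cycle.
#'
#' @param curve a `period_curve`.
#' @param interval optional fitting interval, degrees Celsius.
#' @return a `scaling_fit` (see [fit_arrhenius()]).
#' @export
fit_period_arrhenius <- function(curve, interval = NULL) {
  ok <- curve$oscillating
  b <- data.frame(temperature_c = curve$temperature_c[ok],
                  median_duration = curve$period[ok],
                  n = 1L)
  class(b) <- c("binned_medians", "data.frame")
  fit_arrhenius(b, interval = interval)
}

#' Synthesis/degradation titration scan
#'
#' Re-runs the temperature sweep for every combination of synthesis and
#' degradation anchor factors (the factors multiply the reference-
#' temperature rates, leaving the temperature dependence untouched),
#' emulating cyclin-B synthesis titration.
#'
#' @param map a `temperature_map`.
#' @param synthesis_factors,degradation_factors positive multipliers.
#' @param grid temperature grid, degrees Celsius.
#' @param ... forwarded to [temperature_sweep()].
#' @return a list of `period_curve`s with a `factors` data frame attribute;
#'   element names are `"s<f>_d<f>"`.
#' @export
titration_scan <- function(map, synthesis_factors = 1, degradation_factors = 1,
                           grid, ...) {
  stopifnot(all(synthesis_factors > 0), all(degradation_factors > 0))
  combos <- expand.grid(synthesis = synthesis_factors,
                        degradation = degradation_factors)
  out <- vector("list", nrow(combos))
  for (j in seq_len(nrow(combos))) {
    m <- scale_map(map, combos$synthesis[j], combos$degradation[j])
    out[[j]] <- temperature_sweep(m, grid, ...)
  }
  names(out) <- sprintf("s%g_d%g", combos$synthesis, combos$degradation)
  attr(out, "factors") <- combos
  out
}
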