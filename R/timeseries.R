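#' Droplet FRET-ratio record
#'
#' One encapsulated-extract droplet: metadata plus its Cdk1 FRET-ratio
#' time series.
#'
#' @param droplet_id identifier.
#' @param radius_um droplet radius, micrometres (> 0).
#' @param track_start_min time the track started, minutes.
#' @param temperature_c temperature, degrees Celsius.
#' @param time_min sampling times, minutes, strictly increasing.
#' @param fret_ratio FRET ratio values (dimensionless).
#' @return an object of class `droplet_record`.
#' @export
droplet_record <- function(droplet_id, radius_um, track_start_min,
                           temperature_c, time_min, fret_ratio) {
  stopifnot(radius_um > 0, length(time_min) == length(fret_ratio),
            !is.unsorted(time_min, strictly = TRUE), all(is.finite(fret_ratio)))
  structure(list(droplet_id = droplet_id, radius_um = radius_um,
                 track_start_min = track_start_min,
                 temperature_c = temperature_c,
                 time_min = time_min, fret_ratio = fret_ratio),
            class = "droplet_record")
}

#' @export
print.droplet_record <- function(x, ...) {
  cat(sprintf("<droplet %s: r = %.1f um, start %.1f min, %g degC, %d samples>\n",
              x$droplet_id, x$radius_um, x$track_start_min, x$temperature_c,
              length(x$time_min)))
  invisible(x)
}

#' Quality-control filter for droplets
#'
#' Keeps droplets with radius below `max_radius_um` and a track start
#' within the first `max_track_start_min` minutes; everything else is
#' rejected with a per-droplet reason.
#'
#' @param droplets list of [droplet_record()]s.
#' @param max_radius_um radius threshold, micrometres.
#' @param max_track_start_min track-start threshold, minutes.
#' @return list with `kept` (list of records) and `rejected` (data frame
#'   of `droplet_id`, `reason`).
#' @export
qc_filter <- function(droplets, max_radius_um = 100, max_track_start_min = 60) {
  keep <- logical(length(droplets))
  reasons <- character(0); ids <- character(0)
  for (j in seq_along(droplets)) {
    d <- droplets[[j]]
    if (d$radius_um >= max_radius_um) {
      ids <- c(ids, as.character(d$droplet_id)); reasons <- c(reasons, "radius")
    } else if (d$track_start_min > max_track_start_min) {
      ids <- c(ids, as.character(d$droplet_id)); reasons <- c(reasons, "track_start")
    } else keep[j] <- TRUE
  }
  list(kept = droplets[keep],
       rejected = data.frame(droplet_id = ids, reason = reasons))
}

#' Segment a droplet time series into cycles
#'
#' Auto-selects FRET peaks and troughs (local extrema with a prominence of
#' at least `min_prominence` times the per-droplet signal range and a
#' minimum separation of `min_separation` minutes), enforces alternation
#' (exactly one peak per trough-to-trough cycle, keeping the highest), and
#' cuts the series into trough-to-trough cycles.
#'
#' Relaxation-oscillator waveforms have fast switching edges (abrupt Cdk1
#' activation and the cyclin-destruction drop) separated by slow ramps, so
#' raw extremum samples quantise phase durations to the sampling interval.
#' `segment_cycles` therefore refines extremum times by anchoring on the
#' fast edges, pooling shape information across the droplet's own cycles:
#' the M-phase decline slope (common-slope fit with per-cycle intercepts),
#' the ceiling and trough-floor levels, and the fold level at which the
#' destruction drop begins (minimum observed decline value with an
#' order-statistic bias correction). Peak times extrapolate the first
#' post-jump sample back to the ceiling along the decline; trough times
#' either interpolate a mid-drop sample down to the floor or place the
#' decline-line crossing of the fold level plus the estimated drop
#' duration (from the observed frequency of mid-drop samples). Every
#' refinement is clamped to the bracketing samples and falls back to the
#' sample midpoint when the pooled fits are unavailable.
#'
#' @param d a [droplet_record()], or a data frame with `time`/`value`
#'   columns.
#' @param min_prominence prominence threshold as a fraction of the signal
#'   range.
#' @param min_separation minimum extremum separation, minutes (extract
#'   periods are ~30 min or more).
#' @return an object of class `cycle_segmentation`: data frame with
#'   columns `cycle`, `trough_time`, `peak_time`, `next_trough_time`,
#'   `rising_duration`, `falling_duration`, `period`. Zero detected cycles
#'   give an empty (valid) segmentation.
#' @export
segment_cycles <- function(d, min_prominence = 0.2, min_separation = 15) {
  if (inherits(d, "droplet_record")) {
    tt <- d$time_min; x <- d$fret_ratio
  } else {
    tt <- d$time; x <- d$value
  }
  empty <- data.frame(cycle = integer(0), trough_time = numeric(0),
                      peak_time = numeric(0), next_trough_time = numeric(0),
                      rising_duration = numeric(0),
                      falling_duration = numeric(0), period = numeric(0))
  class(empty) <- c("cycle_segmentation", "data.frame")
  rng <- diff(range(x))
  if (length(x) < 3 || rng <= 0) return(empty)
  pk <- find_peaks(tt, x, min_prominence = min_prominence * rng,
                   min_separation = min_separation, refine = FALSE)
  tr <- find_troughs(tt, x, min_prominence = min_prominence * rng,
                     min_separation = min_separation, refine = FALSE)
  if (nrow(pk) == 0 || nrow(tr) < 2) return(empty)
  n <- length(x)
  dt_med <- median(diff(tt))
  idx_of <- function(tm) which.min(abs(tt - tm))

  ## raw cycles with their jump (steepest rise) and drop (steepest fall)
  cycles <- list()
  for (j in seq_len(nrow(tr) - 1)) {
    between <- pk[pk$time > tr$time[j] & pk$time < tr$time[j + 1], , drop = FALSE]
    if (nrow(between) == 0) next
    praw <- between$time[which.max(between$value)]
    i_tr0 <- idx_of(tr$time[j]); i_pk <- idx_of(praw)
    i_tr1 <- idx_of(tr$time[j + 1])
    if (i_pk - i_tr0 < 1 || i_tr1 - i_pk < 1) next
    dj <- diff(x[i_tr0:i_pk]); ju <- i_tr0 + which.max(dj) - 1
    dd <- diff(x[i_pk:i_tr1]); dr <- i_pk + which.min(dd) - 1
    cycles[[length(cycles) + 1]] <-
      list(i_tr0 = i_tr0, i_pk = i_pk, i_tr1 = i_tr1, ju = ju, dr = dr,
           t_tr0 = tr$time[j], t_tr1 = tr$time[j + 1])
  }
  m <- length(cycles)
  if (!m) return(empty)

  ## relaxation-shape gates: the edge-anchored refinement only applies when
  ## the steepest rise/fall step sits next to the raw extremum and carries a
  ## substantial fraction of the amplitude (a fast switching edge); smooth
  ## waveforms (e.g. near-triangular signals) fall back to local quadratic
  ## refinement of the raw extremum
  jump_ok <- vapply(cycles, function(cc) {
    i_pk <- cc$i_pk
    (i_pk - cc$ju) <= 2 && (x[cc$ju + 1] - x[cc$ju]) >= 0.15 * rng
  }, logical(1))
  drop_ok <- vapply(cycles, function(cc) {
    i_tr1 <- cc$i_tr1
    (i_tr1 - (cc$dr + 1)) <= 2 && (x[cc$dr] - x[cc$dr + 1]) >= 0.15 * rng
  }, logical(1))

  ## pooled waveform quantities (relaxation cycles only)
  v1 <- max(x)
  v0 <- median(vapply(cycles, function(cc) min(x[cc$dr:min(cc$dr + 2, n)]),
                      numeric(1)))
  ts <- c(); xs <- c(); cid <- c()
  for (k in seq_len(m)) {
    if (!jump_ok[k] || !drop_ok[k]) next
    cc <- cycles[[k]]
    ii <- (cc$ju + 1):cc$dr
    ts <- c(ts, tt[ii]); xs <- c(xs, x[ii]); cid <- c(cid, rep(k, length(ii)))
  }
  s1 <- NA_real_
  if (length(ts) >= 3) {
    tb <- stats::ave(ts, cid); xb <- stats::ave(xs, cid)
    den <- sum((ts - tb)^2)
    if (den > 0) s1 <- sum((ts - tb) * (xs - xb)) / den
  }
  v_fold <- NA_real_
  if (is.finite(s1) && s1 < -1e-8) {
    vf0 <- min(xs)
    decl_dur <- (v1 - vf0) / (-s1)
    corr <- (-s1) * decl_dur / (length(xs) + 1)
    v_fold <- vf0 - corr
    v1 <- v1 + corr
  }
  amp <- v1 - v0
  middrop <- rep(FALSE, m)
  if (is.finite(v_fold)) for (k in seq_len(m)) {
    xm <- x[cycles[[k]]$dr + 1]
    middrop[k] <- drop_ok[k] && xm > v0 + 0.06 * amp && xm < v_fold - 0.06 * amp
  }
  dd_est <- max(0.3, min(dt_med * sum(middrop) / max(sum(drop_ok), 1), dt_med))

  ## local quadratic refinement of a raw extremum sample (fallback path)
  quad_time <- function(i) {
    if (i <= 1 || i >= n) return(tt[i])
    y0 <- x[i - 1]; y1 <- x[i]; y2 <- x[i + 1]
    den <- y0 - 2 * y1 + y2
    if (!is.finite(den) || den == 0) return(tt[i])
    delta <- max(min(0.5 * (y0 - y2) / den, 0.5), -0.5)
    tt[i] + delta * (tt[i + 1] - tt[i - 1]) / 2
  }

  refine_trough <- function(cc, k) {
    if (!drop_ok[k]) return(quad_time(cc$i_tr1))
    i1 <- cc$dr; i2 <- cc$dr + 1
    if (middrop[k]) {
      frac <- (x[i2] - v0) / (v_fold - v0)
      min(tt[i2] + frac * dd_est, tt[min(i2 + 1, n)])
    } else if (is.finite(v_fold) && is.finite(s1) && s1 < -1e-8) {
      tcross <- tt[i1] + (x[i1] - v_fold) / (-s1)
      max(min(tcross + dd_est, tt[i2]), tt[i1])
    } else (tt[i1] + tt[i2]) / 2
  }
  refine_peak <- function(cc, k) {
    if (!jump_ok[k]) return(quad_time(cc$i_pk))
    i2 <- cc$ju + 1
    if (is.finite(s1) && s1 < -1e-8)
      max(min(tt[i2] - (v1 - x[i2]) / (-s1), tt[i2]), tt[cc$ju])
    else (tt[cc$ju] + tt[i2]) / 2
  }

  t_pk <- vapply(seq_len(m), function(k) refine_peak(cycles[[k]], k),
                 numeric(1))
  t_tr_next <- vapply(seq_len(m), function(k) refine_trough(cycles[[k]], k),
                      numeric(1))
  ## refined starting trough of cycle k is cycle k-1's refined next trough;
  ## the first cycle has no preceding drop, so it gets the quadratic estimate
  t_tr0 <- c(quad_time(cycles[[1]]$i_tr0), t_tr_next[-m])
  seg <- data.frame(cycle = seq_len(m), trough_time = t_tr0, peak_time = t_pk,
                    next_trough_time = t_tr_next,
                    rising_duration = t_pk - t_tr0,
                    falling_duration = t_tr_next - t_pk,
                    period = t_tr_next - t_tr0)
  class(seg) <- c("cycle_segmentation", "data.frame")
  seg
}

#' Select cycles for downstream analysis
#'
#' Either cycles 2-4 (1-based indexing from the first complete
#' trough-to-trough cycle) or every cycle whose starting trough falls
#' within the first 300 minutes.
#'
#' @param seg a `cycle_segmentation`.
#' @param mode `"cycles_2_to_4"` or `"first_300_min"`.
#' @param window_min window length for the time-based mode.
#' @return the selected subset (possibly empty), same class.
#' @export
select_cycles <- function(seg, mode = c("cycles_2_to_4", "first_300_min"),
                          window_min = 300) {
  mode <- match.arg(mode)
  out <- if (mode == "cycles_2_to_4") {
    seg[seg$cycle >= 2 & seg$cycle <= 4, , drop = FALSE]
  } else {
    ## a cycle belongs to the window iff its starting trough is < window_min
    seg[seg$trough_time < window_min, , drop = FALSE]
  }
  class(out) <- c("cycle_segmentation", "data.frame")
  out
}

#' Interphase slope of the FRET signal
#'
#' Least-squares slope of the FRET ratio over the central 10-90% (by time)
#' of a cycle's rising segment. During interphase the signal rises
#' approximately linearly with cyclin accumulation, so this slope serves
#' as a direct proxy for the cyclin synthesis rate.
#'
#' @param d the [droplet_record()] the segmentation came from.
#' @param seg a `cycle_segmentation` of `d`.
#' @param cycle_index which cycle (value of `seg$cycle`).
#' @return slope in ratio units per minute, or `NA` (with a warning) when
#'   fewer than 4 samples fall in the segment.
#' @export
interphase_slope <- function(d, seg, cycle_index) {
  row <- seg[seg$cycle == cycle_index, , drop = FALSE]
  if (nrow(row) != 1) stop("cycle ", cycle_index, " not present in segmentation")
  t0 <- row$trough_time; t1 <- row$peak_time
  lo <- t0 + 0.1 * (t1 - t0); hi <- t0 + 0.9 * (t1 - t0)
  sel <- d$time_min >= lo & d$time_min <= hi
  if (sum(sel) < 4) {
    warning("fewer than 4 samples in the interphase segment; slope undefined")
    return(NA_real_)
  }
  unname(coef(lm(d$fret_ratio[sel] ~ d$time_min[sel]))[2])
}

#' Average cycle waveform across droplets
#'
#' Each selected cycle is rescaled to phase in [0, 1] (trough to trough),
#' linearly resampled onto `n_phase_bins` points and averaged pointwise;
#' amplitude is left in native ratio units. Phase alignment by the trough
#' makes the average invariant to time shifts between cycles.
#'
#' @param droplets list of [droplet_record()]s at one temperature.
#' @param n_phase_bins number of phase samples.
#' @param select_mode cycle selection mode, see [select_cycles()].
#' @param ... forwarded to [segment_cycles()].
#' @return data frame with columns `phase`, `mean`, `sd`, `n_cycles`
#'   (attribute). Requires at least 3 usable cycles.
#' @export
average_waveform <- function(droplets, n_phase_bins = 50,
                             select_mode = "cycles_2_to_4", ...) {
  phases <- seq(0, 1, length.out = n_phase_bins)
  shapes <- list()
  for (d in droplets) {
    seg <- select_cycles(segment_cycles(d, ...), mode = select_mode)
    for (j in seq_len(nrow(seg))) {
      t0 <- seg$trough_time[j]; t1 <- seg$next_trough_time[j]
      sel <- d$time_min >= t0 & d$time_min <= t1
      if (sum(sel) < 4) next
      ph <- (d$time_min[sel] - t0) / (t1 - t0)
      shapes[[length(shapes) + 1]] <-
        approx(ph, d$fret_ratio[sel], xout = phases, rule = 2)$y
    }
  }
  if (length(shapes) < 3) stop("need at least 3 usable cycles for an average waveform")
  m <- do.call(rbind, shapes)
  out <- data.frame(phase = phases, mean = colMeans(m),
                    sd = apply(m, 2, sd))
  attr(out, "n_cycles") <- length(shapes)
  out
}

#' Fit a rate from an in-vitro assay time series
#'
#' Synthesis, kinase and phosphatase assays produce an initially linear
#' signal: the rate is the least-squares slope over the initial linear
#' window, grown greedily from the first four points for as long as the
#' linear fit keeps R^2 >= `r2_min`. Degradation assays decay
#' exponentially to a plateau: the baseline is estimated as the mean of
#' the final 10% of samples, and the decay constant comes from least
#' squares of log(signal - baseline) against time (non-positive excess
#' values are dropped with a warning).
#'
#' @param times sampling times, minutes (>= 4 points).
#' @param signal assay signal (band intensity normalised to a CSF
#'   reference, or fluorescence a.u.).
#' @param assay_kind one of `"synthesis"`, `"degradation"`, `"kinase"`,
#'   `"phosphatase"`.
#' @param r2_min linear-window growth threshold.
#' @return list with `rate` (a.u./min for linear kinds, 1/min for
#'   degradation), `assay_kind`, and `window` (linear kinds) or `baseline`
#'   (degradation).
#' @export
fit_rate <- function(times, signal,
                     assay_kind = c("synthesis", "degradation", "kinase",
                                    "phosphatase"),
                     r2_min = 0.95) {
  assay_kind <- match.arg(assay_kind)
  stopifnot(length(times) >= 4, length(times) == length(signal),
            !is.unsorted(times))
  if (assay_kind == "degradation") {
    ntail <- max(2L, ceiling(0.1 * length(signal)))
    baseline <- mean(signal[(length(signal) - ntail + 1):length(signal)])
    excess <- signal - baseline
    ## restrict the log fit to points well above the baseline: near the
    ## plateau the subtraction error dominates and biases the slope
    ok <- excess > 0.02 * max(excess)
    if (any(excess <= 0))
      warning(sum(excess <= 0),
              " non-positive points after baseline subtraction dropped")
    if (sum(ok) < 3) stop("too few points above baseline to fit a decay")
    m <- lm(log(excess[ok]) ~ times[ok])
    k0 <- -unname(coef(m)[2]); a0 <- exp(unname(coef(m)[1]))
    ## refine jointly (baseline, amplitude, decay) by nonlinear least
    ## squares seeded by the log fit; removes the tail-mean baseline bias
    nls <- tryCatch(
      minpack.lm::nls.lm(par = c(b = baseline, a = a0, k = k0),
                         fn = function(p)
                           signal - (p[1] + p[2] * exp(-p[3] * times)),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(nls) && is.finite(nls$par[3]) && nls$par[3] > 0) {
      baseline <- unname(nls$par[1]); k0 <- unname(nls$par[3])
    }
    return(list(rate = k0, assay_kind = assay_kind, baseline = baseline))
  }
  r2 <- function(k) {
    m <- lm(signal[1:k] ~ times[1:k])
    sst <- sum((signal[1:k] - mean(signal[1:k]))^2)
    if (sst <= 0) return(1)
    1 - sum(residuals(m)^2) / sst
  }
  k <- 4L
  while (k < length(times) && r2(k + 1L) >= r2_min) k <- k + 1L
  m <- lm(signal[1:k] ~ times[1:k])
  list(rate = unname(coef(m)[2]), assay_kind = assay_kind,
       window = c(times[1], times[k]))
}

#' Arrhenius analysis of per-temperature rates
#'
#' Takes per-series fitted rates (one row per assay repeat), computes the
#' median rate per integer temperature bin, fits an Arrhenius law to the
#' corresponding durations (1/rate; the activation energy is the same
#' either way) and bootstraps the apparent activation energy over the
#' individual fitted series within their bins.
#'
#' @param rates data frame with columns `temperature_c` and `rate`
#'   (positive) and optionally `series_id`.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @param interval optional fit interval, degrees Celsius.
#' @return list with `fit` (a `scaling_fit`; its `ea` coefficient is the
#'   apparent activation energy of the rate, kJ/mol) and `bootstrap`
#'   (an `ea_bootstrap`).
#' @export
rates_to_ea <- function(rates, n_boot = 1000, seed = 1, interval = NULL) {
  stopifnot(all(rates$rate > 0))
  if (length(unique(round(rates$temperature_c))) < 3)
    stop("need rates at >= 3 temperatures")
  ds <- timing_dataset(unit_id = if (!is.null(rates$series_id))
                         rates$series_id else seq_len(nrow(rates)),
                       temperature_c = rates$temperature_c,
                       duration_min = 1 / rates$rate,
                       interval_name = "assay")
  fit <- fit_arrhenius(bin_medians(ds), interval = interval)
  boot <- bootstrap_ea(ds, n_boot = n_boot, form = "SE", interval = interval,
                       seed = seed)
  list(fit = fit, bootstrap = boot)
}
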