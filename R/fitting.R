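#' Create a timing dataset
#'
#' One row per measured interval: an embryo/droplet identifier, the
#' temperature at which it was measured and the interval duration.
#'
#' @param unit_id identifier of the measured unit.
#' @param temperature_c temperature, degrees Celsius.
#' @param duration_min interval duration, minutes (> 0).
#' @param interval_name name of the measured interval.
#' @return a data frame of class `timing_dataset`.
#' @export
timing_dataset <- function(unit_id, temperature_c, duration_min,
                           interval_name = "cycle") {
  stopifnot(all(duration_min > 0), all(is.finite(temperature_c)))
  ds <- data.frame(unit_id = unit_id, temperature_c = temperature_c,
                   interval_name = interval_name, duration_min = duration_min)
  class(ds) <- c("timing_dataset", "data.frame")
  ds
}

#' Median duration per integer-degree temperature bin
#'
#' Bins records at the integer-rounded temperature (round-half-to-even,
#' i.e. base R rounding) and takes the median duration per occupied bin.
#' All scaling-law fits operate on these binned medians.
#'
#' @param ds a `timing_dataset` (or any data frame with `temperature_c`
#'   and `duration_min` columns).
#' @param exclude_bins integer temperatures to drop after binning
#'   (per-dataset outlier exclusions, e.g. a lowest-temperature outlier).
#' @return data frame of class `binned_medians` with columns
#'   `temperature_c` (integer), `median_duration`, `n`.
#' @export
bin_medians <- function(ds, exclude_bins = NULL) {
  stopifnot(nrow(ds) > 0)
  bin <- round(ds$temperature_c)
  agg <- do.call(rbind, lapply(split(ds$duration_min, bin), function(v)
    data.frame(median_duration = median(v), n = length(v))))
  out <- data.frame(temperature_c = as.numeric(rownames(agg)),
                    median_duration = agg$median_duration, n = agg$n)
  out <- out[order(out$temperature_c), , drop = FALSE]
  if (!is.null(exclude_bins))
    out <- out[!(out$temperature_c %in% exclude_bins), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("binned_medians", "data.frame")
  out
}

in_interval <- function(x, interval) {
  if (is.null(interval)) rep(TRUE, length(x))
  else x >= min(interval) & x <= max(interval)
}

new_scaling_fit <- function(law, b, interval, extra = list()) {
  sel <- in_interval(b$temperature_c, interval)
  pred <- eval_duration(law, b$temperature_c, check_valid = FALSE)
  resid_log <- log(b$median_duration) - log(pred)
  fit <- c(list(law = law,
                fit_interval = if (is.null(interval))
                  range(b$temperature_c) else range(interval),
                mse_log = mean(resid_log[sel]^2),
                residuals_log = resid_log,
                data = b),
           extra)
  class(fit) <- "scaling_fit"
  fit
}

#' Fit an Arrhenius law to binned medians
#'
#' Ordinary least squares of \eqn{\ln \Delta t} on \eqn{1/T_K}:
#' the slope times R gives the apparent activation energy, the intercept
#' gives \eqn{\ln(1/A)}.
#'
#' @param b a `binned_medians` data frame.
#' @param interval optional fit interval, degrees Celsius; bins outside it
#'   are ignored by the fit (but kept for residual reporting).
#' @return an object of class `scaling_fit` holding the fitted law, the
#'   fit interval, `mse_log` (mean squared error on log durations over the
#'   fitted bins) and log residuals.
#' @export
fit_arrhenius <- function(b, interval = NULL) {
  sel <- in_interval(b$temperature_c, interval)
  if (sum(sel) < 2) stop("need at least 2 bins in the fit interval")
  x <- 1 / kelvin(b$temperature_c[sel])
  y <- log(b$median_duration[sel])
  m <- lm(y ~ x)
  ea_j <- coef(m)[["x"]] * GAS_R
  a <- exp(-coef(m)[["(Intercept)"]])
  law <- arrhenius_law(a, ea_j / 1000, valid = range(b$temperature_c[sel]))
  new_scaling_fit(law, b, interval, extra = list(lm = m))
}

de_duration <- function(theta, tk) {
  ## theta = (log a1, ea1 [J/mol], log a2, ea2 [J/mol])
  exp(theta[1]) * exp(-theta[2] / (GAS_R * tk)) +
    exp(theta[3]) * exp(-theta[4] / (GAS_R * tk))
}

#' Fit a double-exponential law (two-step initialisation + nonlinear fit)
#'
#' Step 1 fits an Arrhenius law on a caller-selected Arrhenius interval.
#' Step 2 fits a second Arrhenius term to the positive residual durations
#' outside that interval, so the sum of the two terms describes the whole
#' curve. Step 3 refines all four parameters by nonlinear least squares on
#' the durations, seeded by steps 1-2 (amplitudes are kept positive via a
#' log parameterisation). If no residual duration outside the interval is
#' positive the fit falls back to the pure Arrhenius law (`a2 = 0`) with a
#' warning. Model comparison always uses `mse_log`, which is reported on
#' the full bin set.
#'
#' @param b a `binned_medians` data frame.
#' @param arrhenius_interval interval (degrees Celsius) on which the
#'   single-exponential behaviour holds.
#' @return a `scaling_fit` whose law is a [double_exp_law()].
#' @export
fit_double_exp <- function(b, arrhenius_interval) {
  sel <- in_interval(b$temperature_c, arrhenius_interval)
  if (!any(sel)) stop("no bins inside the Arrhenius interval")
  step1 <- fit_arrhenius(b, arrhenius_interval)
  p1 <- step1$law$params  # duration = (1/A) exp(+ea/RT) = a1 exp(-(-ea)/RT)
  a1 <- 1 / p1$prefactor_a
  ea1 <- -p1$ea
  pred1 <- eval_duration(step1$law, b$temperature_c, check_valid = FALSE)
  resid <- b$median_duration - pred1
  out <- !sel & resid > 0
  if (sum(out) >= 2) {
    x <- 1 / kelvin(b$temperature_c[out])
    y <- log(resid[out])
    m2 <- lm(y ~ x)
    a2 <- exp(coef(m2)[["(Intercept)"]])
    ea2 <- -coef(m2)[["x"]] * GAS_R
  } else if (sum(out) == 1) {
    ## single residual point: match it with a steep term
    a2 <- resid[out]
    ea2 <- 0
  } else {
    warning("no positive residual durations outside the Arrhenius interval; falling back to a2 = 0")
    law <- double_exp_law(a1, ea1 / 1000, 0, 0,
                          valid = range(b$temperature_c))
    return(new_scaling_fit(law, b, NULL))
  }
  start <- c(log(a1), ea1, log(a2), ea2)
  tk <- kelvin(b$temperature_c)
  obj <- function(theta) b$median_duration - de_duration(theta, tk)
  nls <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = obj,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  theta <- if (!is.null(nls)) nls$par else start
  ## keep the better of seed and refinement (on duration SSE, as fitted)
  if (sum(obj(theta)^2) > sum(obj(start)^2)) theta <- start
  law <- double_exp_law(exp(theta[1]), theta[2] / 1000,
                        exp(theta[3]), theta[4] / 1000,
                        valid = range(b$temperature_c))
  new_scaling_fit(law, b, NULL)
}

#' Fit a quadratic-exponential law
#'
#' Linear least squares of \eqn{\ln \Delta t} on \eqn{(1/T_K, 1/T_K^2)};
#' the law is linear in its parameters on the log scale, so noiseless
#' recovery is exact.
#'
#' @inheritParams fit_arrhenius
#' @return a `scaling_fit` whose law is a [quad_exp_law()].
#' @export
fit_quad_exp <- function(b, interval = NULL) {
  sel <- in_interval(b$temperature_c, interval)
  if (sum(sel) < 3) stop("need at least 3 bins to fit the quadratic-exponential law")
  x1 <- 1 / kelvin(b$temperature_c[sel])
  x2 <- x1^2
  y <- log(b$median_duration[sel])
  m <- lm(y ~ x1 + x2)
  if (any(is.na(coef(m)))) stop("rank-deficient design: too few distinct bins")
  c0 <- coef(m)[["(Intercept)"]]; c1 <- coef(m)[["x1"]]; c2 <- coef(m)[["x2"]]
  ea_j <- -c1 * GAS_R
  bcoef <- if (abs(c1) > 0) c2 / c1 else 0
  law <- quad_exp_law(exp(c0), ea_j / 1000, bcoef,
                      valid = range(b$temperature_c[sel]))
  new_scaling_fit(law, b, interval, extra = list(lm = m))
}

#' Fit a power-law-exponential law
#'
#' Linear least squares of \eqn{\ln \Delta t} on \eqn{(\ln T_K, 1/T_K)}.
#'
#' @inheritParams fit_arrhenius
#' @return a `scaling_fit` whose law is a [power_exp_law()].
#' @export
fit_power_exp <- function(b, interval = NULL) {
  sel <- in_interval(b$temperature_c, interval)
  if (sum(sel) < 3) stop("need at least 3 bins to fit the power-exponential law")
  tk <- kelvin(b$temperature_c[sel])
  x1 <- log(tk); x2 <- 1 / tk
  y <- log(b$median_duration[sel])
  m <- lm(y ~ x1 + x2)
  if (any(is.na(coef(m)))) stop("rank-deficient design: too few distinct bins")
  law <- power_exp_law(exp(coef(m)[["(Intercept)"]]), coef(m)[["x1"]],
                       -coef(m)[["x2"]] * GAS_R / 1000,
                       valid = range(b$temperature_c[sel]))
  new_scaling_fit(law, b, interval, extra = list(lm = m))
}

#' Fit any of the four scaling-law forms
#'
#' @param b a `binned_medians` data frame.
#' @param form `"SE"`, `"DE"`, `"QE"` or `"PE"`.
#' @param interval fit interval (for `"DE"` this is the Arrhenius interval
#'   of the two-step initialisation).
#' @export
fit_scaling <- function(b, form = c("SE", "DE", "QE", "PE"), interval = NULL) {
  form <- match.arg(form)
  switch(form,
         SE = fit_arrhenius(b, interval),
         DE = fit_double_exp(b, interval),
         QE = fit_quad_exp(b, interval),
         PE = fit_power_exp(b, interval))
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling fit: %s law on [%g, %g] degC, mse_log = %.4g>\n",
              x$law$form, x$fit_interval[1], x$fit_interval[2], x$mse_log))
  print(coef(x$law))
  invisible(x)
}

#' @export
coef.scaling_fit <- function(object, ...) coef(object$law)

#' @export
predict.scaling_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data$temperature_c
  eval_duration(object$law, newdata, check_valid = FALSE)
}

#' @export
residuals.scaling_fit <- function(object, ...) object$residuals_log

#' @export
plot.scaling_fit <- function(x, ...) {
  tt <- x$data$temperature_c
  plot(1 / kelvin(tt), log(x$data$median_duration),
       xlab = "1/T (1/K)", ylab = "ln duration (min)", ...)
  tg <- seq(min(tt), max(tt), length.out = 200)
  lines(1 / kelvin(tg), log(eval_duration(x$law, tg, check_valid = FALSE)),
        col = "firebrick")
  invisible(x)
}

#' Compare the goodness of fit of several laws
#'
#' Mean squared error on log durations of the binned medians, per fitted
#' law and evaluation interval. The ordering of laws is invariant to the
#' duration unit.
#'
#' @param b a `binned_medians` data frame.
#' @param fits named list of `scaling_fit` objects (or `scaling_law`s).
#' @param intervals named list of evaluation intervals, degrees Celsius
#'   (default: the full bin range).
#' @return data frame with one row per law/interval.
#' @export
compare_fits <- function(b, fits, intervals = NULL) {
  if (is.null(intervals)) intervals <- list(full = range(b$temperature_c))
  rows <- list()
  for (fn in names(fits)) {
    law <- if (inherits(fits[[fn]], "scaling_fit")) fits[[fn]]$law else fits[[fn]]
    pred <- eval_duration(law, b$temperature_c, check_valid = FALSE)
    rl <- log(b$median_duration) - log(pred)
    for (int in names(intervals)) {
      sel <- in_interval(b$temperature_c, intervals[[int]])
      rows[[length(rows) + 1]] <- data.frame(
        law = fn, interval = int, mse_log = mean(rl[sel]^2))
    }
  }
  do.call(rbind, rows)
}

#' Bootstrap distribution of the apparent activation energy
#'
#' Resamples individual measurements with replacement within each integer
#' temperature bin (stratified, preserving the temperature design),
#' re-bins, re-fits the requested law form and collects the apparent
#' activation energy. For non-Arrhenius forms the apparent Ea is evaluated
#' at `ea_at` degrees Celsius. Resamples yielding fewer than two occupied
#' bins are redrawn (count recorded).
#'
#' @param ds a `timing_dataset`.
#' @param n_boot number of bootstrap replicates (>= 100 for production
#'   use; smaller values are allowed for quick checks).
#' @param form law form to refit, see [fit_scaling()].
#' @param interval fit interval, degrees Celsius.
#' @param seed RNG seed (results are bit-identical under a fixed seed).
#' @param ea_at temperature at which non-Arrhenius apparent Ea is read.
#' @param exclude_bins forwarded to [bin_medians()].
#' @return an object of class `ea_bootstrap`: list with `ea_samples`
#'   (kJ/mol), `mean`, `ci_90` (5th/95th percentiles), `n_redrawn`.
#' @export
bootstrap_ea <- function(ds, n_boot = 1000, form = "SE", interval = NULL,
                         seed = 1, ea_at = 20, exclude_bins = NULL) {
  set.seed(seed)
  bins <- split(seq_len(nrow(ds)), round(ds$temperature_c))
  samples <- numeric(n_boot)
  n_redrawn <- 0L
  for (i in seq_len(n_boot)) {
    repeat {
      idx <- unlist(lapply(bins, function(ii) ii[sample.int(length(ii),
                                                            replace = TRUE)]))
      bm <- bin_medians(ds[idx, , drop = FALSE], exclude_bins = exclude_bins)
      nsel <- sum(in_interval(bm$temperature_c, interval))
      if (nsel >= 2) break
      n_redrawn <- n_redrawn + 1L
    }
    fit <- fit_scaling(bm, form = form, interval = interval)
    samples[i] <- apparent_ea(fit$law, ea_at)
  }
  structure(list(ea_samples = samples, mean = mean(samples),
                 ci_90 = unname(quantile(samples, c(0.05, 0.95))),
                 n_redrawn = n_redrawn),
            class = "ea_bootstrap")
}

#' @export
print.ea_bootstrap <- function(x, ...) {
  cat(sprintf("<Ea bootstrap: %d samples, mean %.1f kJ/mol, 90%% CI [%.1f, %.1f]>\n",
              length(x$ea_samples), x$mean, x$ci_90[1], x$ci_90[2]))
  invisible(x)
}
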