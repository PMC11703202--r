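#' Hill-type regulatory response
#'
#' A bounded, monotone response of a regulator (APC/C-mediated degradation,
#' Cdc25, Wee1) to the instantaneous active-Cdk1 concentration, obtained
#' after the quasi-steady-state elimination of the fast phosphorylation
#' reactions. Output lies in `[basal, basal + amplitude]`.
#'
#' @param basal baseline response, dimensionless (>= 0).
#' @param amplitude response amplitude, dimensionless (> 0).
#' @param ec50 half-maximal active-Cdk1 concentration, nM.
#' @param hill_n Hill coefficient (>= 1).
#' @param direction `"increasing"` (degradation, Cdc25) or `"decreasing"`
#'   (Wee1).
#' @return an object of class `hill_response`.
#' @export
hill_response <- function(basal, amplitude, ec50, hill_n,
                          direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  stopifnot(basal >= 0, amplitude > 0, ec50 > 0, hill_n >= 1)
  structure(list(basal = basal, amplitude = amplitude, ec50 = ec50,
                 hill_n = hill_n, direction = direction),
            class = "hill_response")
}

#' Evaluate a Hill response
#' @param h a `hill_response`.
#' @param x active Cdk1 concentration(s), nM (negative values are clipped to 0).
#' @export
eval_hill <- function(h, x) {
  x <- pmax(x, 0)
  f <- x^h$hill_n / (h$ec50^h$hill_n + x^h$hill_n)
  if (h$direction == "decreasing") f <- 1 - f
  h$basal + h$amplitude * f
}

## analytic derivative d eval_hill / dx, used by the Jacobian
hill_deriv <- function(h, x) {
  x <- pmax(x, 0)
  n <- h$hill_n
  en <- h$ec50^n
  d <- h$amplitude * n * en * x^(n - 1) / (en + x^n)^2
  if (h$direction == "decreasing") d <- -d
  d
}

#' Two-ODE cell-cycle oscillator parameter set
#'
#' Kinetic parameters and regulatory responses of the cyclin B-Cdk1
#' relaxation oscillator:
#' \deqn{dcyc/dt = k_s - k_d \, d(cdk1_a) \, cyc}
#' \deqn{\epsilon \, dcdk1_a/dt = k_a \, a(cdk1_a)(cyc - cdk1_a) -
#'       k_i \, i(cdk1_a) \, cdk1_a}
#' where `d`, `a`, `i` are the Hill responses of APC/C-driven degradation,
#' Cdc25 and Wee1 to active Cdk1. `eps` sets the time-scale separation
#' between the slow cyclin turnover and the fast Cdk1 (in)activation
#' switch; relaxation oscillations require `eps` well below 1.
#'
#' @param ks cyclin synthesis rate, nM/min.
#' @param kd cyclin degradation scale, 1/min.
#' @param ka Cdk1 activation scale, 1/min.
#' @param ki Cdk1 inactivation scale, 1/min.
#' @param eps time-scale separation, dimensionless (> 0).
#' @param deg,cdc25,wee1 [hill_response()] objects; `deg` and `cdc25`
#'   increasing, `wee1` decreasing.
#' @return an object of class `cellcycle_model`.
#' @export
two_ode_params <- function(ks, kd, ka, ki, eps, deg, cdc25, wee1) {
  stopifnot(ks > 0, kd > 0, ka > 0, ki > 0, eps > 0,
            inherits(deg, "hill_response"), deg$direction == "increasing",
            inherits(cdc25, "hill_response"), cdc25$direction == "increasing",
            inherits(wee1, "hill_response"), wee1$direction == "decreasing")
  structure(list(ks = ks, kd = kd, ka = ka, ki = ki, eps = eps,
                 deg = deg, cdc25 = cdc25, wee1 = wee1),
            class = "cellcycle_model")
}

#' Reference parameter set of the oscillator
#'
#' The packaged default configuration: Hill responses parameterised after
#' steady-state response measurements in frog egg extracts (sharply
#' ultrasensitive APC/C response, ultrasensitive Cdc25, shallower Wee1),
#' with the cyclin synthesis rate calibrated so the reference set
#' oscillates with a period of about 30 minutes at the reference
#' temperature. This function is the single source of truth for default
#' numeric values; pass overrides to change any of them.
#'
#' @param ... named overrides for any `two_ode_params()` argument.
#' @export
oscitemp_defaults <- function(...) {
  base <- list(
    ks = 2.2,         # nM/min, calibrated for a ~30 min reference period
    kd = 1.5,         # 1/min scale; effective degradation = kd * deg(cdk1a)
    ka = 1.0,         # 1/min scale; effective activation = ka * cdc25(cdk1a)
    ki = 1.0,
    eps = 0.1,
    deg = hill_response(0.01, 0.06, 32, 17, "increasing"),
    cdc25 = hill_response(0.16, 0.80, 35, 11, "increasing"),
    wee1 = hill_response(0.08, 0.40, 30, 3.5, "decreasing")
  )
  ov <- list(...)
  base[names(ov)] <- ov
  do.call(two_ode_params, base)
}

#' @export
print.cellcycle_model <- function(x, ...) {
  cat("<two-ODE cell-cycle oscillator>\n")
  cat(sprintf("  ks = %.4g nM/min, kd = %.4g /min, ka = %.4g /min, ki = %.4g /min, eps = %.4g\n",
              x$ks, x$kd, x$ka, x$ki, x$eps))
  for (nm in c("deg", "cdc25", "wee1")) {
    h <- x[[nm]]
    cat(sprintf("  %-5s %s Hill: basal %.3g, amp %.3g, EC50 %.3g nM, n %.3g\n",
                nm, h$direction, h$basal, h$amplitude, h$ec50, h$hill_n))
  }
  invisible(x)
}

#' Right-hand side of the two-ODE oscillator
#'
#' Pure function returning the time derivatives of total cyclin B and
#' active Cdk1. This is the reference R implementation; [simulate()] uses
#' an equivalent compiled version by default.
#'
#' @param state numeric vector `c(cyc, cdk1a)` in nM.
#' @param p a `cellcycle_model`.
#' @return numeric vector `c(dcyc, dcdk1a)` in nM/min.
#' @export
cellcycle_rhs <- function(state, p) {
  cyc <- state[[1]]; y <- state[[2]]
  dcyc <- p$ks - p$kd * eval_hill(p$deg, y) * cyc
  dy <- (p$ka * eval_hill(p$cdc25, y) * (cyc - y) -
           p$ki * eval_hill(p$wee1, y) * y) / p$eps
  c(dcyc, dy)
}

## flatten params to the 17-vector consumed by the compiled rhs
pack_parms <- function(p) {
  c(p$ks, p$kd, p$ka, p$ki, p$eps,
    p$deg$basal, p$deg$amplitude, p$deg$ec50, p$deg$hill_n,
    p$cdc25$basal, p$cdc25$amplitude, p$cdc25$ec50, p$cdc25$hill_n,
    p$wee1$basal, p$wee1$amplitude, p$wee1$ec50, p$wee1$hill_n)
}

#' Simulate the cell-cycle oscillator
#'
#' Integrates the two-ODE model with a stiff-capable solver (default
#' `lsoda`, tight tolerances because period detection differentiates peak
#' positions). The default horizon is 1000 minutes from the origin state.
#'
#' @param object a `cellcycle_model`.
#' @param nsim unused (kept for the `simulate()` generic).
#' @param seed unused (the model is deterministic).
#' @param t_end simulation horizon, minutes.
#' @param init initial state `c(cyc, cdk1a)` in nM.
#' @param dt output sampling step, minutes.
#' @param rtol,atol solver tolerances.
#' @param compiled use the compiled right-hand side (fast) or the pure R
#'   one (reference).
#' @param method deSolve integration method (stiff-capable).
#' @param ... ignored.
#' @return a data frame of class `cellcycle_sim` with columns `time`,
#'   `cyc`, `cdk1a`; the parameter set is attached as attribute `params`.
#' @export
simulate.cellcycle_model <- function(object, nsim = 1, seed = NULL,
                                     t_end = 1000, init = c(cyc = 0, cdk1a = 0),
                                     dt = 0.1, rtol = 1e-8, atol = 1e-10,
                                     compiled = TRUE, method = "lsoda", ...) {
  stopifnot(t_end > 0)
  times <- seq(0, t_end, by = dt)
  y0 <- c(cyc = unname(init[[1]]), cdk1a = unname(init[[2]]))
  out <- if (compiled) {
    deSolve::ode(y = y0, times = times, func = "cellcycle_derivs",
                 parms = pack_parms(object), dllname = "oscitemp",
                 initfunc = "cellcycle_init", nout = 0,
                 method = method, rtol = rtol, atol = atol)
  } else {
    deSolve::ode(y = y0, times = times,
                 func = function(t, y, parms) list(cellcycle_rhs(y, parms)),
                 parms = object, method = method, rtol = rtol, atol = atol)
  }
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(times))
    stop(sprintf("ODE solver failed (last state: t=%.2f, cyc=%.3g, cdk1a=%.3g; ks=%.3g, kd=%.3g, ka=%.3g, ki=%.3g, eps=%.3g)",
                 out[nrow(out), 1], out[nrow(out), 2], out[nrow(out), 3],
                 object$ks, object$kd, object$ka, object$ki, object$eps))
  sim <- as.data.frame(out)
  names(sim) <- c("time", "cyc", "cdk1a")
  attr(sim, "params") <- object
  class(sim) <- c("cellcycle_sim", "data.frame")
  sim
}

#' @export
plot.cellcycle_sim <- function(x, ...) {
  graphics::matplot(x$time, cbind(x$cyc, x$cdk1a), type = "l", lty = 1,
                    col = c("steelblue", "firebrick"),
                    xlab = "time (min)", ylab = "concentration (nM)", ...)
  graphics::legend("topright", legend = c("cyclin B", "active Cdk1"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Nullclines of the two-ODE oscillator
#'
#' The cyclin nullcline \eqn{cyc = k_s / (k_d \, d(cdk1_a))} depends only on
#' the ratio ks/kd; the Cdk1 nullcline
#' \eqn{cyc = cdk1_a (1 + k_i i(cdk1_a) / (k_a a(cdk1_a)))} depends only on
#' ki/ka and is S-shaped for the reference responses.
#'
#' @param p a `cellcycle_model`.
#' @param cdk1a_grid active-Cdk1 grid, nM.
#' @return data frame with columns `cdk1a`, `cyc_cyclin_nc`, `cyc_cdk1_nc`.
#'   Grid points where a Hill basal of zero makes the cyclin nullcline
#'   diverge are returned as `NA` (flagged, not an error).
#' @export
nullclines <- function(p, cdk1a_grid = seq(0, 120, length.out = 401)) {
  d <- eval_hill(p$deg, cdk1a_grid)
  cyc1 <- ifelse(d > 0, p$ks / (p$kd * d), NA_real_)
  a <- eval_hill(p$cdc25, cdk1a_grid)
  i <- eval_hill(p$wee1, cdk1a_grid)
  cyc2 <- ifelse(a > 0, cdk1a_grid * (1 + (p$ki * i) / (p$ka * a)), NA_real_)
  data.frame(cdk1a = cdk1a_grid, cyc_cyclin_nc = cyc1, cyc_cdk1_nc = cyc2)
}

## Jacobian of the vector field at (cyc, cdk1a)
cellcycle_jacobian <- function(p, cyc, y) {
  dgy <- eval_hill(p$deg, y); dgy1 <- hill_deriv(p$deg, y)
  ay <- eval_hill(p$cdc25, y); ay1 <- hill_deriv(p$cdc25, y)
  iy <- eval_hill(p$wee1, y); iy1 <- hill_deriv(p$wee1, y)
  j11 <- -p$kd * dgy
  j12 <- -p$kd * dgy1 * cyc
  j21 <- p$ka * ay / p$eps
  j22 <- (p$ka * ay1 * (cyc - y) - p$ka * ay - p$ki * iy1 * y - p$ki * iy) / p$eps
  matrix(c(j11, j12, j21, j22), nrow = 2, byrow = TRUE)
}

#' Fixed points of the oscillator and arrest classification
#'
#' Finds all intersections of the two nullclines by a bracketed root
#' search along the Cdk1 nullcline, classifies linear stability from the
#' Jacobian eigenvalues, and labels stable states as interphase-like
#' (low active Cdk1, below the Cdc25 half-activation point) or
#' M-phase-like (high active Cdk1). At least one intersection always
#' exists for positive rates.
#'
#' @param p a `cellcycle_model`.
#' @param cdk1a_max upper end of the search range, nM. Defaults to a value
#'   safely above the cyclin nullcline plateau.
#' @param n_grid number of bracketing grid points.
#' @return data frame with columns `cyc`, `cdk1a`, `stable`,
#'   `arrest_class` (one of `"interphase-like"`, `"m-phase-like"`, `"none"`).
#' @export
fixed_points <- function(p, cdk1a_max = NULL, n_grid = 2000) {
  if (is.null(cdk1a_max)) {
    ## cyc at fixed point is bounded by ks/(kd*deg_min); cdk1a <= cyc there
    cdk1a_max <- 1.5 * p$ks / (p$kd * eval_hill(p$deg, 0))
  }
  f <- function(y) {
    cyc1 <- p$ks / (p$kd * eval_hill(p$deg, y))
    cyc2 <- y * (1 + (p$ki * eval_hill(p$wee1, y)) / (p$ka * eval_hill(p$cdc25, y)))
    cyc2 - cyc1
  }
  grid <- seq(1e-9, cdk1a_max, length.out = n_grid)
  fv <- vapply(grid, f, numeric(1))
  roots <- numeric(0)
  for (j in seq_len(n_grid - 1)) {
    if (is.finite(fv[j]) && is.finite(fv[j + 1]) && fv[j] * fv[j + 1] < 0) {
      r <- uniroot(f, c(grid[j], grid[j + 1]), tol = 1e-12)$root
      roots <- c(roots, r)
    } else if (fv[j] == 0) roots <- c(roots, grid[j])
  }
  roots <- sort(unique(roots))
  stopifnot(length(roots) >= 1)  # guaranteed for positive rates
  res <- lapply(roots, function(y) {
    cyc <- p$ks / (p$kd * eval_hill(p$deg, y))
    ev <- eigen(cellcycle_jacobian(p, cyc, y), only.values = TRUE)$values
    stable <- all(Re(ev) < 0)
    cls <- if (!stable) "none"
           else if (y < p$cdc25$ec50) "interphase-like"
           else "m-phase-like"
    data.frame(cyc = cyc, cdk1a = y, stable = stable, arrest_class = cls)
  })
  do.call(rbind, res)
}
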