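#' Prior specification for ABC-SMC
#'
#' Independent priors, one per sampled parameter: uniform for activation
#' energies (kJ/mol; negative values express biphasic/declining branches)
#' and log-uniform for positive rate anchors.
#'
#' @param ... named length-2 numeric vectors `c(lo, hi)` for uniform
#'   priors, or values wrapped in [log_uniform()] for log-uniform priors.
#' @return an object of class `abc_priors`.
#' @export
abc_priors <- function(...) {
  specs <- list(...)
  stopifnot(length(specs) > 0, !is.null(names(specs)), all(nzchar(names(specs))))
  specs <- lapply(specs, function(s) {
    if (inherits(s, "abc_prior_1d")) return(s)
    stopifnot(is.numeric(s), length(s) == 2, s[1] < s[2])
    structure(list(type = "uniform", lo = s[1], hi = s[2]),
              class = "abc_prior_1d")
  })
  structure(specs, class = "abc_priors")
}

#' Log-uniform prior bounds
#' @param lo,hi positive bounds, `lo < hi`.
#' @export
log_uniform <- function(lo, hi) {
  stopifnot(lo > 0, lo < hi)
  structure(list(type = "loguniform", lo = lo, hi = hi),
            class = "abc_prior_1d")
}

prior_sample <- function(priors, n) {
  out <- vapply(priors, function(s) {
    if (s$type == "uniform") runif(n, s$lo, s$hi)
    else exp(runif(n, log(s$lo), log(s$hi)))
  }, numeric(n))
  if (n == 1) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(priors)))
  out
}

prior_density <- function(priors, theta) {
  d <- 1
  for (nm in names(priors)) {
    s <- priors[[nm]]; x <- theta[[nm]]
    d <- d * if (s$type == "uniform") {
      if (x >= s$lo && x <= s$hi) 1 / (s$hi - s$lo) else 0
    } else {
      if (x >= s$lo && x <= s$hi) 1 / (x * (log(s$hi) - log(s$lo))) else 0
    }
  }
  d
}

#' ABC-SMC configuration
#'
#' @param population_size number of accepted particles per generation
#'   (>= 50 recommended for production runs, >= 8 for quick checks).
#' @param max_generations maximum number of SMC generations.
#' @param seed RNG seed; runs are deterministic under a fixed seed (the
#'   sampler is sequential, so results do not depend on a worker count).
#' @param eps_quantile epsilon schedule: each generation's acceptance
#'   threshold is this quantile of the previous generation's accepted
#'   distances (median by default).
#' @param eps_stop_rel stop when the relative epsilon change between
#'   generations falls below this value.
#' @param max_draws_per_gen safety cap on proposal draws per generation.
#' @export
abc_config <- function(population_size = 200, max_generations = 8, seed = 1,
                       eps_quantile = 0.5, eps_stop_rel = 0.01,
                       max_draws_per_gen = 50 * population_size) {
  stopifnot(population_size >= 8, max_generations >= 1)
  structure(list(population_size = population_size,
                 max_generations = max_generations, seed = seed,
                 eps_quantile = eps_quantile, eps_stop_rel = eps_stop_rel,
                 max_draws_per_gen = max_draws_per_gen),
            class = "abc_config")
}

#' Observed duration summary for ABC distances
#'
#' Binned median durations per temperature: either the full period or the
#' rising/falling phase durations (both channels), matching the model's
#' temperature sweep output bin-by-bin.
#'
#' @param temperature_c bin temperatures, degrees Celsius.
#' @param period,rising,falling median durations, minutes; give `period`
#'   or both `rising` and `falling`.
#' @export
observed_summary <- function(temperature_c, period = NULL, rising = NULL,
                             falling = NULL) {
  stopifnot(!is.null(period) || (!is.null(rising) && !is.null(falling)))
  for (v in list(period, rising, falling))
    if (!is.null(v)) stopifnot(length(v) == length(temperature_c), all(v > 0))
  structure(list(temperature_c = temperature_c, period = period,
                 rising = rising, falling = falling),
            class = "observed_summary")
}

match_bins <- function(sim, obs) {
  idx <- match(round(obs$temperature_c), round(sim$temperature_c))
  if (all(is.na(idx))) return(NULL)
  idx
}

sq_log_channel <- function(sim_vals, sim_osc, obs_vals, penalty) {
  ifelse(sim_osc & is.finite(sim_vals) & sim_vals > 0,
         (log(sim_vals) - log(obs_vals))^2,
         penalty)
}

#' Squared-log distance between simulated and observed periods
#'
#' Mean over the shared temperature bins of the squared difference of log
#' periods. Bins where the simulation fails to oscillate while the data
#' show cycles contribute a fixed penalty `penalty` to the pool (the fits
#' implicitly require oscillation across the data range). Zero temperature
#' overlap gives an infinite distance.
#'
#' @param sim a `period_curve`.
#' @param obs an [observed_summary()] with a `period` channel.
#' @param penalty non-oscillation penalty added per failed bin.
#' @return dimensionless distance (>= 0; 0 iff equal on shared bins).
#' @export
distance_periods <- function(sim, obs, penalty = 10) {
  stopifnot(!is.null(obs$period))
  idx <- match_bins(sim, obs)
  if (is.null(idx)) return(Inf)
  ok <- !is.na(idx)
  mean(sq_log_channel(sim$period[idx[ok]], sim$oscillating[idx[ok]],
                      obs$period[ok], penalty))
}

#' Squared-log distance on rising and falling phase durations
#'
#' As [distance_periods()] but averaged with equal weight over the two
#' phase-duration channels.
#'
#' @inheritParams distance_periods
#' @param obs an [observed_summary()] with `rising` and `falling` channels.
#' @export
distance_phases <- function(sim, obs, penalty = 10) {
  stopifnot(!is.null(obs$rising), !is.null(obs$falling))
  idx <- match_bins(sim, obs)
  if (is.null(idx)) return(Inf)
  ok <- !is.na(idx)
  r <- sq_log_channel(sim$rising[idx[ok]], sim$oscillating[idx[ok]],
                      obs$rising[ok], penalty)
  f <- sq_log_channel(sim$falling[idx[ok]], sim$oscillating[idx[ok]],
                      obs$falling[ok], penalty)
  (mean(r) + mean(f)) / 2
}

#' Map builder over activation energies
#'
#' Returns a closure mapping a named parameter vector to a
#' [temperature_map()]. Sampled names of the form `ea_<p>` set the
#' Arrhenius activation energy of parameter `<p>` (kJ/mol); names of the
#' form `anchor_<p>` multiply its reference-temperature value.
#'
#' @param ref_params reference `cellcycle_model`.
#' @param t_ref reference temperature, degrees Celsius.
#' @param ea_fixed named vector of fixed activation energies for
#'   parameters not being sampled.
#' @param valid declared temperature interval of the produced maps.
#' @export
make_ea_map_builder <- function(ref_params, t_ref = 20, ea_fixed = NULL,
                                valid = c(4, 44)) {
  force(ref_params); force(t_ref); force(ea_fixed); force(valid)
  function(theta) {
    nm <- names(theta)
    ea <- ea_fixed
    for (k in nm[startsWith(nm, "ea_")])
      ea[sub("^ea_", "", k)] <- theta[[k]]
    p <- ref_params
    for (k in nm[startsWith(nm, "anchor_")]) {
      pk <- sub("^anchor_", "", k)
      p[[pk]] <- p[[pk]] * theta[[k]]
    }
    ea_map(p, ea = ea, t_ref = t_ref, valid = valid)
  }
}

#' Likelihood-free inference of temperature-scaling parameters (ABC-SMC)
#'
#' Sequential Monte Carlo ABC: generation 1 draws from the prior and keeps
#' the `population_size` particles with the smallest distances; each later
#' generation resamples the previous population by weight, perturbs with a
#' Gaussian kernel (per-parameter standard deviation = sqrt(2 x weighted
#' variance) of the previous population), simulates a temperature sweep,
#' and accepts particles whose distance falls below the shrinking epsilon
#' (a quantile of the previous accepted distances). Importance weights
#' follow the standard prior/kernel ratio. Stops when the epsilon change
#' is below `eps_stop_rel`, the generation budget is exhausted, or a
#' generation yields no acceptances (warning; the last completed
#' generation is returned).
#'
#' @param map_builder function mapping a named parameter vector to a
#'   `temperature_map` (see [make_ea_map_builder()]).
#' @param priors an [abc_priors()].
#' @param obs an [observed_summary()].
#' @param config an [abc_config()].
#' @param distance distance function `(period_curve, obs) -> numeric`.
#' @param sweep_args list of arguments for [temperature_sweep()]; thermal-
#'   limit refinement is disabled inside the sampler for speed.
#' @return an object of class `abc_posterior`: data frame of particles
#'   with columns per parameter plus `weight` and `distance`; attributes
#'   `epsilons`, `n_sims`, `generations`.
#' @export
run_abc <- function(map_builder, priors, obs, config = abc_config(),
                    distance = distance_phases,
                    sweep_args = list(t_end = 400, dt = 0.25, rtol = 1e-6,
                                      atol = 1e-8)) {
  set.seed(config$seed)
  grid <- sort(round(obs$temperature_c))
  simulate_distance <- function(theta) {
    m <- map_builder(theta)
    curve <- suppressWarnings(do.call(temperature_sweep,
      c(list(map = m, grid = grid, refine_limits = FALSE), sweep_args)))
    distance(curve, obs)
  }
  npar <- length(priors)
  pnames <- names(priors)
  n <- config$population_size
  n_sims <- 0L

  ## generation 1: sample from the prior, keep the best n of 2n draws
  n0 <- 2L * n
  th <- prior_sample(priors, n0)
  d0 <- numeric(n0)
  for (i in seq_len(n0)) {
    d0[i] <- simulate_distance(setNames(th[i, ], pnames))
    n_sims <- n_sims + 1L
  }
  keep <- order(d0)[seq_len(n)]
  particles <- th[keep, , drop = FALSE]
  dists <- d0[keep]
  weights <- rep(1 / n, n)
  epsilons <- quantile(dists, config$eps_quantile, names = FALSE)
  gen <- 1L

  while (gen < config$max_generations) {
    eps <- epsilons[length(epsilons)]
    sdk <- sqrt(2 * pmax(apply(particles, 2, function(col)
      weighted_var(col, weights)), 1e-12))
    new_p <- matrix(NA_real_, n, npar, dimnames = list(NULL, pnames))
    new_d <- numeric(n)
    new_w <- numeric(n)
    acc <- 0L; draws <- 0L
    while (acc < n && draws < config$max_draws_per_gen) {
      draws <- draws + 1L
      j <- sample.int(n, 1, prob = weights)
      prop <- particles[j, ] + rnorm(npar, 0, sdk)
      names(prop) <- pnames
      pd <- prior_density(priors, as.list(prop))
      if (pd <= 0) next
      d <- simulate_distance(prop)
      n_sims <- n_sims + 1L
      if (d <= eps) {
        acc <- acc + 1L
        new_p[acc, ] <- prop
        new_d[acc] <- d
        kern <- vapply(seq_len(n), function(jj)
          prod(stats::dnorm(prop, particles[jj, ], sdk)), numeric(1))
        new_w[acc] <- pd / sum(weights * kern)
      }
    }
    if (acc == 0L) {
      warning(sprintf("generation %d: no acceptances below eps = %.4g; returning generation %d",
                      gen + 1L, eps, gen))
      break
    }
    if (acc < n) {
      warning(sprintf("generation %d: only %d/%d acceptances within the draw budget",
                      gen + 1L, acc, n))
      new_p <- new_p[seq_len(acc), , drop = FALSE]
      new_d <- new_d[seq_len(acc)]
      new_w <- new_w[seq_len(acc)]
    }
    particles <- new_p
    dists <- new_d
    weights <- new_w / sum(new_w)
    gen <- gen + 1L
    eps_new <- quantile(dists, config$eps_quantile, names = FALSE)
    epsilons <- c(epsilons, eps_new)
    if (abs(eps - eps_new) < config$eps_stop_rel * eps) break
  }

  out <- as.data.frame(particles)
  out$weight <- weights
  out$distance <- dists
  structure(out, epsilons = epsilons, n_sims = n_sims, generations = gen,
            class = c("abc_posterior", "data.frame"))
}

weighted_var <- function(x, w) {
  m <- sum(w * x) / sum(w)
  sum(w * (x - m)^2) / sum(w)
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("<ABC posterior: %d particles, %d generations, %d simulations>\n",
              nrow(x), attr(x, "generations"), attr(x, "n_sims")))
  cat("epsilon schedule:", paste(signif(attr(x, "epsilons"), 3), collapse = " -> "), "\n")
  print(posterior_summary(x))
  invisible(x)
}

#' Weighted posterior summaries
#'
#' Per parameter: importance-weighted mean, mode of a weighted Gaussian
#' kernel density (bandwidth by Silverman's rule on the weighted sample),
#' and the central 90% interval (weighted 5th/95th percentiles). Mean and
#' mode are reported separately because skewed posteriors separate them.
#'
#' @param ps an `abc_posterior`.
#' @return data frame with one row per parameter.
#' @export
posterior_summary <- function(ps) {
  stopifnot(nrow(ps) > 0)
  pnames <- setdiff(names(ps), c("weight", "distance"))
  w <- ps$weight / sum(ps$weight)
  rows <- lapply(pnames, function(nm) {
    x <- ps[[nm]]
    m <- sum(w * x)
    mode <- weighted_kde_mode(x, w)
    ci <- weighted_quantile(x, w, c(0.05, 0.95))
    data.frame(parameter = nm, mean = m, mode = mode,
               q05 = ci[1], q95 = ci[2])
  })
  do.call(rbind, rows)
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

weighted_kde_mode <- function(x, w) {
  if (length(unique(x)) == 1) return(x[1])
  bw <- bw.nrd0(x)
  grid <- seq(min(x) - 2 * bw, max(x) + 2 * bw, length.out = 512)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm(g, x, bw)), numeric(1))
  grid[which.max(dens)]
}

#' Best-fit particle of an ABC posterior
#' @param ps an `abc_posterior`.
#' @return named numeric vector of the particle with the smallest distance.
#' @export
abc_best_fit <- function(ps) {
  pnames <- setdiff(names(ps), c("weight", "distance"))
  unlist(ps[which.min(ps$distance), pnames])
}

#' Direct minimisation of the sweep distance
#'
#' The non-Bayesian counterpart of [run_abc()]: Nelder-Mead minimisation
#' of the same distance over the same parameterisation, returning a point
#' estimate. Useful for quick optimal fits of the scaling scenarios.
#'
#' @param map_builder,priors,obs,distance,sweep_args as in [run_abc()].
#' @param init optional named start vector (defaults to prior midpoints).
#' @param maxit optimiser iteration budget.
#' @return list with `par` (named vector) and `distance`.
#' @export
fit_sweep_direct <- function(map_builder, priors, obs,
                             distance = distance_phases, init = NULL,
                             sweep_args = list(t_end = 400, dt = 0.25,
                                               rtol = 1e-6, atol = 1e-8),
                             maxit = 200) {
  pnames <- names(priors)
  if (is.null(init))
    init <- vapply(priors, function(s)
      if (s$type == "uniform") (s$lo + s$hi) / 2
      else sqrt(s$lo * s$hi), numeric(1))
  grid <- sort(round(obs$temperature_c))
  fn <- function(theta) {
    names(theta) <- pnames
    if (prior_density(priors, as.list(theta)) <= 0) return(1e6)
    m <- map_builder(theta)
    curve <- suppressWarnings(do.call(temperature_sweep,
      c(list(map = m, grid = grid, refine_limits = FALSE), sweep_args)))
    distance(curve, obs)
  }
  opt <- optim(init, fn, method = "Nelder-Mead", control = list(maxit = maxit))
  list(par = setNames(opt$par, pnames), distance = opt$value)
}
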