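#' Rate scaling curve
#'
#' A positive rate as a function of temperature, defined as the reciprocal
#' of a duration scaling law and anchored so that the rate equals `k_ref`
#' at `t_ref` degrees Celsius. When the underlying law is Arrhenius the
#' rate is exactly \eqn{A e^{-E_a/RT}}; a double-exponential law yields a
#' biphasic rate with a thermal optimum.
#'
#' @param duration_law a `scaling_law` describing the relative duration.
#' @param k_ref rate at the anchor temperature (units of the parameter the
#'   curve will drive, e.g. nM/min for synthesis, 1/min for the others).
#' @param t_ref anchor temperature, degrees Celsius.
#' @return an object of class `rate_curve`.
#' @export
rate_curve <- function(duration_law, k_ref, t_ref = 20) {
  stopifnot(inherits(duration_law, "scaling_law"), k_ref > 0)
  structure(list(law = duration_law, k_ref = k_ref, t_ref = t_ref),
            class = "rate_curve")
}

#' Arrhenius rate curve anchored at a reference temperature
#'
#' @param k_ref rate at `t_ref`.
#' @param ea apparent activation energy of the rate, kJ/mol (positive:
#'   faster at higher temperature).
#' @param t_ref anchor temperature, degrees Celsius.
#' @export
rate_curve_arrhenius <- function(k_ref, ea, t_ref = 20) {
  rate_curve(arrhenius_law_anchored(1, ea, t_ref = t_ref), k_ref, t_ref)
}

#' Biphasic rate curve with a thermal optimum
#'
#' Builds a double-exponential duration law whose reciprocal rate rises
#' with apparent activation energy `ea_cold` on the cold side, peaks at
#' `t_opt`, and falls off above it with a slope of magnitude `ea_hot`
#' (e.g. enzyme denaturation). The curve is anchored to `k_ref` at `t_ref`.
#'
#' @param k_ref rate at `t_ref`.
#' @param ea_cold apparent activation energy of the rising branch, kJ/mol (> 0).
#' @param ea_hot magnitude of the falling branch's slope, kJ/mol (> 0);
#'   denaturation-like declines are typically steep (hundreds of kJ/mol).
#' @param t_opt temperature of the rate maximum, degrees Celsius.
#' @param t_ref anchor temperature, degrees Celsius.
#' @export
rate_curve_biphasic <- function(k_ref, ea_cold, ea_hot, t_opt, t_ref = 20) {
  stopifnot(ea_cold > 0, ea_hot > 0)
  ## duration terms (DE sign convention): term1 ~ exp(-ea1/RT) with
  ## ea1 = -ea_cold (duration falls as T rises), term2 with ea2 = +ea_hot.
  ea1 <- -ea_cold * 1000
  ea2 <- ea_hot * 1000
  tko <- kelvin(t_opt)
  ## duration minimum at t_opt: setting d/dT of a1 e^{-ea1/RT} + a2 e^{-ea2/RT}
  ## to zero gives a2/a1 = -(ea1/ea2) exp(+(ea2 - ea1)/(R T_opt))
  ratio <- -(ea1 / ea2) * exp((ea2 - ea1) / (GAS_R * tko))
  law <- double_exp_law(1, ea1 / 1000, ratio, ea2 / 1000)
  rate_curve(law, k_ref, t_ref)
}

#' Evaluate a rate curve
#'
#' @param curve a `rate_curve`.
#' @param temperature_c temperature(s), degrees Celsius.
#' @return rate(s), same units as the curve's `k_ref`.
#' @export
eval_rate <- function(curve, temperature_c) {
  stopifnot(inherits(curve, "rate_curve"))
  curve$k_ref * eval_duration(curve$law, curve$t_ref, check_valid = FALSE) /
    eval_duration(curve$law, temperature_c, check_valid = FALSE)
}

#' @export
print.rate_curve <- function(x, ...) {
  cat(sprintf("<rate curve: %s duration law, k(%g degC) = %g>\n",
              x$law$form, x$t_ref, x$k_ref))
  invisible(x)
}

#' Temperature-to-parameter map for the oscillator model
#'
#' Associates a [rate_curve()] with each temperature-scaled kinetic
#' parameter of the two-ODE model. Only `ks`, `kd`, `ka`, `ki` and the
#' inverse time-scale separation `inv_eps` scale with temperature; the Hill
#' response shapes are temperature-independent. Parameters without a curve
#' stay at their reference value.
#'
#' @param ref_params a `cellcycle_model` giving the parameter values at
#'   the reference temperature (see [two_ode_params()]).
#' @param t_ref reference temperature, degrees Celsius.
#' @param curves named list of `rate_curve`s; allowed names are
#'   `"ks"`, `"kd"`, `"ka"`, `"ki"`, `"inv_eps"`. Curves are re-anchored so
#'   that the mapped parameter equals its reference value at `t_ref`.
#' @param valid declared temperature interval, degrees Celsius; evaluating
#'   outside it warns but extrapolates.
#' @return an object of class `temperature_map`.
#' @export
temperature_map <- function(ref_params, t_ref = 20, curves = list(),
                            valid = c(4, 44)) {
  stopifnot(inherits(ref_params, "cellcycle_model"))
  allowed <- c("ks", "kd", "ka", "ki", "inv_eps")
  bad <- setdiff(names(curves), allowed)
  if (length(bad)) stop("unknown mapped parameters: ", paste(bad, collapse = ", "))
  for (nm in names(curves)) stopifnot(inherits(curves[[nm]], "rate_curve"))
  structure(list(ref = ref_params, t_ref = t_ref, curves = curves,
                 valid = valid),
            class = "temperature_map")
}

#' Arrhenius-scaled temperature map from activation energies
#'
#' Convenience constructor used for the temperature-scaling scenarios:
#' each named kinetic parameter gets an Arrhenius rate curve anchored at
#' its reference value, with the given activation energy.
#'
#' @param ref_params reference `cellcycle_model`.
#' @param ea named numeric vector of activation energies in kJ/mol; names
#'   from `ks`, `kd`, `ka`, `ki`, `inv_eps`. Unnamed parameters stay
#'   temperature-independent.
#' @param t_ref reference temperature, degrees Celsius.
#' @param valid declared temperature interval.
#' @export
ea_map <- function(ref_params, ea, t_ref = 20, valid = c(4, 44)) {
  curves <- lapply(ea, function(e) rate_curve_arrhenius(1, e, t_ref = t_ref))
  temperature_map(ref_params, t_ref = t_ref, curves = curves, valid = valid)
}

#' Extract-like temperature map
#'
#' The packaged default map emulating the temperature dependence inferred
#' from cycling-extract phase durations: cyclin synthesis is biphasic
#' (steep Arrhenius rise of ~113 kJ/mol on the cold side, a thermal
#' optimum near 30 degC, and a steep denaturation-like decline above it),
#' cyclin degradation scales weakly (~40 kJ/mol), and the Cdk1 switch
#' speeds up with temperature through the inverse time-scale separation
#' (~60 kJ/mol). Hill shapes and the activation/inactivation scales stay
#' temperature-independent.
#'
#' @param ref_params reference parameter set (defaults to
#'   [oscitemp_defaults()]).
#' @param t_ref reference temperature, degrees Celsius.
#' @param ea_ks_cold,ea_kd,ea_inv_eps activation energies, kJ/mol.
#' @param ea_ks_hot magnitude of the synthesis decline above the optimum,
#'   kJ/mol.
#' @param t_opt_ks temperature of maximal synthesis, degrees Celsius.
#' @param valid declared temperature interval.
#' @export
extract_map <- function(ref_params = oscitemp_defaults(), t_ref = 20,
                        ea_ks_cold = 113, ea_ks_hot = 300, t_opt_ks = 30,
                        ea_kd = 40, ea_inv_eps = 60, valid = c(4, 44)) {
  temperature_map(ref_params, t_ref = t_ref, curves = list(
    ks = rate_curve_biphasic(1, ea_ks_cold, ea_ks_hot, t_opt_ks, t_ref = t_ref),
    kd = rate_curve_arrhenius(1, ea_kd, t_ref = t_ref),
    inv_eps = rate_curve_arrhenius(1, ea_inv_eps, t_ref = t_ref)
  ), valid = valid)
}

#' Evaluate a temperature map
#'
#' Returns the full two-ODE parameter set at a temperature. Kinetic
#' parameters follow their rate curves (relative to the reference value);
#' `eps` is mapped through the `inv_eps` curve (1/eps scales like a rate,
#' so eps shrinks as temperature rises); Hill shapes are copied unchanged.
#'
#' @param map a `temperature_map`.
#' @param temperature_c temperature, degrees Celsius (scalar).
#' @return a `cellcycle_model` parameter set.
#' @export
params_at_temperature <- function(map, temperature_c) {
  stopifnot(inherits(map, "temperature_map"), length(temperature_c) == 1)
  if (!is.null(map$valid) &&
      (temperature_c < min(map$valid) || temperature_c > max(map$valid)))
    warning(sprintf("temperature %g degC outside map interval [%g, %g]; extrapolating",
                    temperature_c, min(map$valid), max(map$valid)))
  p <- map$ref
  rel <- function(nm) {
    cv <- map$curves[[nm]]
    if (is.null(cv)) return(1)
    eval_rate(cv, temperature_c) / eval_rate(cv, map$t_ref)
  }
  p$ks <- p$ks * rel("ks")
  p$kd <- p$kd * rel("kd")
  p$ka <- p$ka * rel("ka")
  p$ki <- p$ki * rel("ki")
  p$eps <- p$eps / rel("inv_eps")
  p
}

#' Scale the synthesis/degradation anchors of a map
#'
#' Multiplies the reference-temperature values of the cyclin synthesis
#' and degradation rates by constant factors, preserving their temperature
#' dependence (activation energies and curve shapes are untouched). Used
#' for titration scans emulating cyclin-B morpholino knockdown.
#'
#' @param map a `temperature_map`.
#' @param synthesis_factor multiplier on `ks` (> 0).
#' @param degradation_factor multiplier on `kd` (> 0).
#' @export
scale_map <- function(map, synthesis_factor = 1, degradation_factor = 1) {
  stopifnot(synthesis_factor > 0, degradation_factor > 0)
  map$ref$ks <- map$ref$ks * synthesis_factor
  map$ref$kd <- map$ref$kd * degradation_factor
  map
}

#' @export
print.temperature_map <- function(x, ...) {
  cat(sprintf("<temperature map: t_ref = %g degC, interval [%g, %g] degC>\n",
              x$t_ref, min(x$valid), max(x$valid)))
  if (length(x$curves)) {
    for (nm in names(x$curves)) {
      cv <- x$curves[[nm]]
      cat(sprintf("  %-8s %s law, apparent Ea at t_ref = %.1f kJ/mol\n",
                  nm, cv$law$form, apparent_ea(cv$law, x$t_ref)))
    }
  } else cat("  (no scaled parameters)\n")
  invisible(x)
}
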