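#' @useDynLib oscitemp, .registration = TRUE
#' @importFrom stats lm coef median approx optim quantile sd runif rnorm rlnorm
#'   uniroot weighted.mean bw.nrd0 predict residuals simulate setNames
#' @importFrom graphics lines points legend abline matplot
#' @importFrom utils read.csv write.csv packageVersion
"_PACKAGE"

## Gas constant, J mol^-1 K^-1 (exact by convention here)
GAS_R <- 8.314
KELVIN0 <- 273.15

#' Convert degrees Celsius to kelvin
#'
#' All thermodynamic formulas in the package consume absolute temperature;
#' user-facing interfaces take degrees Celsius.
#'
#' @param celsius temperature in degrees Celsius.
#' @return temperature in kelvin.
#' @export
kelvin <- function(celsius) {
  k <- celsius + KELVIN0
  if (any(k <= 0)) stop("temperature below absolute zero")
  k
}

new_scaling_law <- function(form, params, subclass) {
  structure(list(form = form, params = params),
            class = c(subclass, "scaling_law"))
}

#' Arrhenius scaling law
#'
#' The single-exponential (SE) law. The rate form is
#' \eqn{k(T) = A e^{-E_a/RT}} and the duration form is its reciprocal,
#' \eqn{\Delta t(T) = (1/A) e^{+E_a/RT}}, so that \eqn{\Delta t \cdot k = 1}
#' at every temperature.
#'
#' @param prefactor_a pre-exponential factor \eqn{A} (1/min), must be positive.
#' @param ea apparent activation energy in kJ/mol (stored internally in J/mol).
#' @param valid optional validity interval in degrees Celsius, length 2.
#' @return an object of class `c("arrhenius_law", "scaling_law")`.
#' @seealso [double_exp_law()], [quad_exp_law()], [power_exp_law()],
#'   [eval_duration()]
#' @export
arrhenius_law <- function(prefactor_a, ea, valid = NULL) {
  stopifnot(is.numeric(prefactor_a), length(prefactor_a) == 1, prefactor_a > 0)
  law <- new_scaling_law("SE",
                         list(prefactor_a = prefactor_a, ea = ea * 1000),
                         "arrhenius_law")
  law$valid <- valid
  law
}

#' Arrhenius law anchored to a duration at a reference temperature
#'
#' Convenience constructor: the law passes exactly through
#' `duration_ref` minutes at `t_ref` degrees Celsius.
#'
#' @param duration_ref duration in minutes at the anchor temperature.
#' @param ea apparent activation energy, kJ/mol.
#' @param t_ref anchor temperature, degrees Celsius.
#' @inheritParams arrhenius_law
#' @export
arrhenius_law_anchored <- function(duration_ref, ea, t_ref = 20, valid = NULL) {
  tk <- kelvin(t_ref)
  a <- exp(ea * 1000 / (GAS_R * tk)) / duration_ref
  arrhenius_law(a, ea, valid = valid)
}

#' Double-exponential scaling law
#'
#' Duration form \eqn{\Delta t(T) = A_1 e^{-E_{a1}/RT} + A_2 e^{-E_{a2}/RT}}.
#' With `a2 = 0` it reduces to an Arrhenius duration (note the sign flip:
#' the single-exponential duration carries \eqn{+E_a/RT}, so the nested
#' Arrhenius has `ea = -ea1` and `prefactor_a = 1/a1`). A U-shaped duration
#' curve has `ea1` and `ea2` of opposite sign.
#'
#' @param a1,a2 amplitudes, minutes; `a1 > 0`, `a2 >= 0`.
#' @param ea1,ea2 activation energies of the two terms, kJ/mol.
#' @param valid optional validity interval in degrees Celsius.
#' @export
double_exp_law <- function(a1, ea1, a2, ea2, valid = NULL) {
  stopifnot(a1 > 0, a2 >= 0)
  law <- new_scaling_law("DE",
                         list(a1 = a1, ea1 = ea1 * 1000,
                              a2 = a2, ea2 = ea2 * 1000),
                         "double_exp_law")
  law$valid <- valid
  law
}

#' Quadratic-exponential scaling law
#'
#' Duration form \eqn{\Delta t(T) = A e^{-(E_a/R)(1/T + B/T^2)}}, a
#' three-parameter generalisation of the Arrhenius form with curvature
#' coefficient `b` (kelvin). `b = 0` collapses to a single exponential.
#'
#' @param a amplitude, minutes.
#' @param ea activation energy, kJ/mol.
#' @param b curvature coefficient, kelvin.
#' @param valid optional validity interval in degrees Celsius.
#' @export
quad_exp_law <- function(a, ea, b, valid = NULL) {
  stopifnot(a > 0)
  law <- new_scaling_law("QE", list(a = a, ea = ea * 1000, b = b),
                         "quad_exp_law")
  law$valid <- valid
  law
}

#' Power-law-exponential scaling law
#'
#' Duration form \eqn{\Delta t(T) = A T^{B} e^{-E_a/RT}}.
#'
#' @param a amplitude, min K^(-b).
#' @param b dimensionless temperature exponent.
#' @param ea activation energy, kJ/mol.
#' @param valid optional validity interval in degrees Celsius.
#' @export
power_exp_law <- function(a, b, ea, valid = NULL) {
  stopifnot(a > 0)
  law <- new_scaling_law("PE", list(a = a, b = b, ea = ea * 1000),
                         "power_exp_law")
  law$valid <- valid
  law
}

#' Evaluate a scaling law as a duration
#'
#' @param law a `scaling_law` object.
#' @param temperature_c temperature(s) in degrees Celsius.
#' @param check_valid warn when evaluating outside the law's declared
#'   validity interval (never an error).
#' @return duration(s) in minutes, positive and finite.
#' @export
eval_duration <- function(law, temperature_c, check_valid = TRUE) {
  stopifnot(inherits(law, "scaling_law"))
  if (check_valid && !is.null(law$valid)) {
    out <- temperature_c < min(law$valid) | temperature_c > max(law$valid)
    if (any(out))
      warning(sprintf("evaluating %s law outside its validity interval [%g, %g] degC",
                      law$form, min(law$valid), max(law$valid)))
  }
  tk <- kelvin(temperature_c)
  p <- law$params
  d <- switch(law$form,
    SE = exp(p$ea / (GAS_R * tk)) / p$prefactor_a,
    DE = {
      t1 <- p$a1 * exp(-p$ea1 / (GAS_R * tk))
      t2 <- p$a2 * exp(-p$ea2 / (GAS_R * tk))
      if (any(!is.finite(t1))) stop("double-exponential term 1 overflowed")
      if (any(!is.finite(t2))) stop("double-exponential term 2 overflowed")
      t1 + t2
    },
    QE = p$a * exp(-(p$ea / GAS_R) * (1 / tk + p$b / tk^2)),
    PE = p$a * tk^p$b * exp(-p$ea / (GAS_R * tk)),
    stop("unknown scaling-law form: ", law$form)
  )
  if (any(!is.finite(d)))
    stop(sprintf("%s law evaluated to a non-finite duration (exponential overflow)",
                 law$form))
  d
}

#' Evaluate a scaling law as a rate
#'
#' The reciprocal of [eval_duration()], in 1/min.
#' @inheritParams eval_duration
#' @export
eval_rate_law <- function(law, temperature_c, check_valid = TRUE) {
  1 / eval_duration(law, temperature_c, check_valid = check_valid)
}

#' @export
predict.scaling_law <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- newdata$temperature_c
  eval_duration(object, newdata)
}

#' @export
print.scaling_law <- function(x, ...) {
  cat(sprintf("<scaling law: %s>\n", x$form))
  print(coef(x))
  if (!is.null(x$valid))
    cat(sprintf("valid on [%g, %g] degC\n", min(x$valid), max(x$valid)))
  invisible(x)
}

#' @export
coef.scaling_law <- function(object, ...) {
  p <- object$params
  ## report energies in kJ/mol (user-facing unit)
  for (nm in names(p)) if (grepl("^ea", nm)) p[[nm]] <- p[[nm]] / 1000
  unlist(p)
}

#' Local Q10 of a scaling law
#'
#' The factor by which the implied rate speeds up over the 10-degree
#' interval starting at `temperature_c`:
#' \eqn{Q_{10}(T) = \Delta t(T) / \Delta t(T + 10)}.
#' For an Arrhenius law this equals [q10_from_ea()] exactly.
#'
#' @inheritParams eval_duration
#' @return dimensionless ratio (vectorised over `temperature_c`).
#' @export
local_q10 <- function(law, temperature_c, check_valid = TRUE) {
  eval_duration(law, temperature_c, check_valid = check_valid) /
    eval_duration(law, temperature_c + 10, check_valid = check_valid)
}

#' Q10 implied by an activation energy
#'
#' Closed form for an Arrhenius process:
#' \eqn{Q_{10} = \exp[(E_a/R)(1/T_K - 1/(T_K+10))]}.
#'
#' @param ea apparent activation energy, kJ/mol.
#' @param temperature_c anchor temperature, degrees Celsius.
#' @export
q10_from_ea <- function(ea, temperature_c = 20) {
  tk <- kelvin(temperature_c)
  exp((ea * 1000 / GAS_R) * (1 / tk - 1 / (tk + 10)))
}

#' Apparent activation energy of any scaling law at a temperature
#'
#' Defined as the local slope of \eqn{\ln \Delta t} versus \eqn{1/T_K}
#' times R, in the duration sign convention of the Arrhenius form (so a
#' process that speeds up with temperature has positive apparent Ea).
#' Closed forms are used for every law.
#'
#' @inheritParams eval_duration
#' @return apparent activation energy in kJ/mol.
#' @export
apparent_ea <- function(law, temperature_c) {
  tk <- kelvin(temperature_c)
  p <- law$params
  ea_j <- switch(law$form,
    SE = rep(p$ea, length(tk)),
    DE = {
      t1 <- p$a1 * exp(-p$ea1 / (GAS_R * tk))
      t2 <- p$a2 * exp(-p$ea2 / (GAS_R * tk))
      -(p$ea1 * t1 + p$ea2 * t2) / (t1 + t2)
    },
    QE = -p$ea * (1 + 2 * p$b / tk),
    PE = -p$ea - p$b * GAS_R * tk
  )
  ea_j / 1000
}

#' Summary statistics for a set of activation energies
#'
#' Mean, population standard deviation (normalised by n, not n-1) and
#' coefficient of variation. Units follow the input (kJ/mol throughout
#' the package).
#'
#' @param eas numeric vector of activation energies, non-empty.
#' @return named list with `mean`, `std`, `cv`.
#' @export
ea_summary <- function(eas) {
  if (length(eas) == 0 || !is.numeric(eas))
    stop("'eas' must be a non-empty numeric vector")
  m <- mean(eas)
  s <- sqrt(mean((eas - m)^2))
  list(mean = m, std = s, cv = s / m)
}

#' Serialize a scaling law to JSON
#'
#' Records have the shape
#' `{"form": "SE|DE|QE|PE", "params": {...}, "units": {"ea": "kJ/mol"}}`.
#' @param law a `scaling_law`.
#' @export
law_to_json <- function(law) {
  p <- as.list(coef(law))
  jsonlite::toJSON(list(form = law$form, params = p,
                        units = list(ea = "kJ/mol", duration = "min"),
                        valid = law$valid),
                   auto_unbox = TRUE, digits = NA, null = "null")
}

#' Deserialize a scaling law from JSON
#' @param txt JSON text or file path produced by [law_to_json()].
#' @export
law_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt)
  p <- x$params
  v <- x$valid
  switch(x$form,
    SE = arrhenius_law(p$prefactor_a, p$ea, valid = v),
    DE = double_exp_law(p$a1, p$ea1, p$a2, p$ea2, valid = v),
    QE = quad_exp_law(p$a, p$ea, p$b, valid = v),
    PE = power_exp_law(p$a, p$b, p$ea, valid = v),
    stop("unknown form in JSON: ", x$form)
  )
}
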