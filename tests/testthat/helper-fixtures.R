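# shared fixtures, built in code (no stored data)

ref_params <- function(...) oscitemp_defaults(...)

# all-equal-Ea map (uniform Arrhenius scaling of the four rates)
case1_map <- function(ea = 75, ...) {
  ea_map(ref_params(...), ea = c(ks = ea, kd = ea, ka = ea, ki = ea),
         t_ref = 20)
}

# synthesis/degradation imbalance map (thermal limits emerge)
case3_map <- function(ea_ks = 113, ea_kd = 40, ...) {
  ea_map(ref_params(...), ea = c(ks = ea_ks, kd = ea_kd, ka = 60, ki = 60),
         t_ref = 20)
}

# short reference simulation reused across tests
ref_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate(oscitemp_defaults(), t_end = 300)
    cache
  }
})

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}

# U-shaped double-exponential duration law: minimum at t_opt, passing
# through d_ref minutes at t_ref
u_shaped_law <- function(d_ref = 30, ea_cold = 75, ea_hot = 320,
                         t_opt = 28, t_ref = 20) {
  base <- rate_curve_biphasic(1, ea_cold, ea_hot, t_opt, t_ref = t_ref)$law
  s <- d_ref / eval_duration(base, t_ref, check_valid = FALSE)
  p <- base$params
  double_exp_law(p$a1 * s, p$ea1 / 1000, p$a2 * s, p$ea2 / 1000)
}
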