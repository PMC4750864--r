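# Lifestyle scenarios as time-dependent multiplier schedules.  Each scenario
# carries four piecewise-linear, continuous multiplier functions of simulation
# time — co_g (glucuronidation Vmax), co_s (sulfation Vmax), co_ox (oxidation
# Vmax) and k_gen_mult (GSH regeneration coefficient) — plus a scalar
# initial_gsh_fraction scaling the starting hepatic GSH pool.  Schedules are
# stored as breakpoint tables (time_min, value) and held constant beyond the
# last breakpoint.

.schedule <- function(time_min, value) {
  stopifnot(length(time_min) == length(value), !is.unsorted(time_min))
  data.frame(time_min = time_min, value = value)
}

.constant_schedule <- function(value) .schedule(0, value)

.new_scenario <- function(name, co_g, co_s, co_ox, k_gen, initial_gsh_fraction) {
  structure(list(name = name, co_g = co_g, co_s = co_s, co_ox = co_ox,
                 k_gen = k_gen, initial_gsh_fraction = initial_gsh_fraction),
            class = "apap_scenario")
}

#' Neutral (healthy, well-fed) scenario
#'
#' All multipliers are identically 1 and the initial GSH pool is at its
#' normal value.
#' @return An `apap_scenario`.
#' @export
scenario_normal <- function() {
  one <- .constant_schedule(1)
  .new_scenario("normal", one, one, one, one, 1)
}

#' Chronic APAP intake schedule
#'
#' Chronic intake induces glucuronidation and depletes sulfation capacity:
#' `co_g` rises linearly from 1 at t = 0 to its dose-tier maximum at 4320 min
#' (3 days, the first experimentally observed time point) and then holds;
#' `co_s` falls likewise to its tier minimum. Tier maxima are (1.5, 0.5) for
#' 1 g per administration and (2.25, 0.3) for 2 g; doses above 2 g use the
#' 2 g tier because induction has not been measured beyond it. Oxidation and
#' GSH regeneration are unaffected.
#'
#' @param dose_g Per-administration dose in grams (> 0); selects the tier.
#' @param kinetics An `apap_kinetics` object supplying the tier table and
#'   ramp duration.
#' @return An `apap_scenario`.
#' @examples
#' evaluate_modifiers(chronic_apap_schedule(1), c(0, 2160, 4320))
#' @export
chronic_apap_schedule <- function(dose_g, kinetics = default_kinetics()) {
  stopifnot(dose_g > 0)
  sc <- kinetics$scenario_constants
  tiers <- sc$chronic_tiers
  tiers <- tiers[order(tiers$dose_g), ]
  i <- findInterval(dose_g, tiers$dose_g)
  i <- max(i, 1L) # doses below the lowest tier use the lowest tier
  ramp <- sc$ramp_chronic_min
  one <- .constant_schedule(1)
  .new_scenario(
    sprintf("chronic-%gg", dose_g),
    co_g = .schedule(c(0, ramp), c(1, tiers$co_g_max[i])),
    co_s = .schedule(c(0, ramp), c(1, tiers$co_s_max[i])),
    co_ox = one, k_gen = one, initial_gsh_fraction = 1
  )
}

#' Post-binge alcohol schedule
#'
#' Time zero is the moment drinking stops. The CYP2E1 oxidation multiplier
#' starts at its maximal ethanol induction (2.14) and decays linearly back to
#' 1 over 7200 min (5 days, consistent with the ~60 h CYP2E1 half-life); the
#' hepatic GSH pool starts halved and its regeneration coefficient recovers
#' linearly from 0.5 to 1 over 1440 min (24 h). Glucuronidation and sulfation
#' are unaffected.
#'
#' @param kinetics An `apap_kinetics` object supplying the constants.
#' @return An `apap_scenario`.
#' @export
alcohol_schedule <- function(kinetics = default_kinetics()) {
  sc <- kinetics$scenario_constants
  one <- .constant_schedule(1)
  .new_scenario(
    "alcohol",
    co_g = one, co_s = one,
    co_ox = .schedule(c(0, sc$ramp_alcohol_cyp_min),
                      c(sc$alcohol_cyp_factor, 1)),
    k_gen = .schedule(c(0, sc$ramp_alcohol_gsh_min),
                      c(sc$alcohol_gsh_fraction, 1)),
    initial_gsh_fraction = sc$alcohol_gsh_fraction
  )
}

#' Fasting / malnutrition modifiers
#'
#' Constant (non-ramped) modifiers: glucuronidation reduced by 40%
#' (`co_g = 0.6`), sulfation by 30% (`co_s = 0.7`), oxidation induced by 50%
#' (`co_ox = 1.5`), the initial GSH pool reduced by 25% and the GSH
#' regeneration coefficient reduced to the configured fasting fraction
#' (default 0.75, mirroring the pool reduction).
#'
#' @param kinetics An `apap_kinetics` object supplying the constants.
#' @return An `apap_scenario`.
#' @export
fasting_modifiers <- function(kinetics = default_kinetics()) {
  f <- kinetics$scenario_constants$fasting
  .new_scenario(
    "fasting",
    co_g = .constant_schedule(f$co_g),
    co_s = .constant_schedule(f$co_s),
    co_ox = .constant_schedule(f$co_ox),
    k_gen = .constant_schedule(f$k_gen_fraction),
    initial_gsh_fraction = f$gsh_fraction
  )
}

#' Combined chronic APAP + alcohol scenario
#'
#' The pointwise product of the chronic and alcohol schedules on each
#' coefficient, with both clocks starting at t = 0 (drinking stops as chronic
#' dosing starts). The initial GSH fraction is the product of the two (i.e.
#' the alcohol halving). Because for every coefficient at most one of the two
#' component schedules is non-constant, the product remains piecewise linear.
#'
#' @inheritParams chronic_apap_schedule
#' @return An `apap_scenario`.
#' @export
combined_chronic_alcohol <- function(dose_g, kinetics = default_kinetics()) {
  a <- chronic_apap_schedule(dose_g, kinetics)
  b <- alcohol_schedule(kinetics)
  prod_sched <- function(s1, s2) {
    tt <- sort(unique(c(s1$time_min, s2$time_min)))
    .schedule(tt, .eval_schedule(s1, tt) * .eval_schedule(s2, tt))
  }
  .new_scenario(
    sprintf("chronic+alcohol-%gg", dose_g),
    co_g = prod_sched(a$co_g, b$co_g),
    co_s = prod_sched(a$co_s, b$co_s),
    co_ox = prod_sched(a$co_ox, b$co_ox),
    k_gen = prod_sched(a$k_gen, b$k_gen),
    initial_gsh_fraction = a$initial_gsh_fraction * b$initial_gsh_fraction
  )
}

# Internal: evaluate one breakpoint table at times tt (held constant beyond
# the ends).
.eval_schedule <- function(s, tt) {
  if (nrow(s) == 1) return(rep(s$value, length(tt)))
  stats::approx(s$time_min, s$value, xout = tt, rule = 2)$y
}

#' Evaluate scenario multipliers at given times
#'
#' Exact piecewise-linear evaluation of the four multiplier schedules;
#' schedules are continuous and held constant beyond their last breakpoint.
#'
#' @param scenario An `apap_scenario`.
#' @param time_min Numeric vector of times (minutes, >= 0).
#' @return A data frame with columns `time_min`, `co_g`, `co_s`, `co_ox`,
#'   `k_gen_mult`.
#' @examples
#' evaluate_modifiers(alcohol_schedule(), c(0, 3600, 7200))
#' @export
evaluate_modifiers <- function(scenario, time_min) {
  stopifnot(inherits(scenario, "apap_scenario"))
  if (any(time_min < 0)) stop("modifier times must be >= 0", call. = FALSE)
  data.frame(
    time_min = time_min,
    co_g = .eval_schedule(scenario$co_g, time_min),
    co_s = .eval_schedule(scenario$co_s, time_min),
    co_ox = .eval_schedule(scenario$co_ox, time_min),
    k_gen_mult = .eval_schedule(scenario$k_gen, time_min)
  )
}

#' @export
print.apap_scenario <- function(x, ...) {
  rng <- function(s) sprintf("%g..%g", min(s$value), max(s$value))
  cat(sprintf(
    "APAP scenario '%s': co_g %s, co_s %s, co_ox %s, k_gen %s, initial GSH fraction %g\n",
    x$name, rng(x$co_g), rng(x$co_s), rng(x$co_ox), rng(x$k_gen),
    x$initial_gsh_fraction))
  invisible(x)
}
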