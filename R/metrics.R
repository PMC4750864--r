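# Headline quantities: GSH depletion extrema and toxicity-threshold
# crossings, cumulative GSH demand, quasi-steady-state reduction, threshold
# searches, clearance-route fractions, and the baseline GSH calibration.

.sim_table <- function(x) {
  if (inherits(x, "apap_sim")) return(as.data.frame(x))
  if (is.data.frame(x) && all(c("time_min", "gsh_mmolL") %in% names(x))) {
    return(x)
  }
  stop("expected an apap_sim or a time-series data frame", call. = FALSE)
}

.sim_kinetics <- function(x, kinetics) {
  if (!is.null(kinetics)) return(kinetics)
  if (inherits(x, "apap_sim")) return(x$kinetics)
  stop("kinetics must be supplied when assessing a bare time series",
       call. = FALSE)
}

#' Assess hepatotoxicity of a simulated run
#'
#' Computes the liver GSH trace as a fraction of the normal concentration
#' `[GSH]_N`, its minimum and time of minimum, and whether/when it first
#' crosses the toxicity threshold (30% of normal by default). The crossing
#' time is refined by linear interpolation between output grid points.
#'
#' @param result An `apap_sim` or a time-series data frame from
#'   [read_timeseries()].
#' @param kinetics An `apap_kinetics`; taken from the simulation when
#'   omitted.
#' @return A list of class `apap_toxicity`: `min_gsh_fraction`,
#'   `time_of_min_min`, `toxic`, `first_crossing_min` (`NA` when never
#'   toxic), and the threshold used.
#' @export
assess_toxicity <- function(result, kinetics = NULL) {
  k <- .sim_kinetics(result, kinetics)
  df <- .sim_table(result)
  gn <- k$gsh$gsh_normal_mmol_l
  thr <- k$gsh$toxicity_fraction
  frac <- df$gsh_mmolL / gn
  i_min <- which.min(frac)
  toxic <- frac[i_min] < thr
  crossing <- NA_real_
  if (toxic) {
    below <- which(frac < thr)
    i <- below[1]
    if (i == 1) {
      crossing <- df$time_min[1]
    } else {
      # linear interpolation across the crossing interval
      t0 <- df$time_min[i - 1]; t1 <- df$time_min[i]
      f0 <- frac[i - 1]; f1 <- frac[i]
      crossing <- t0 + (thr - f0) / (f1 - f0) * (t1 - t0)
    }
  }
  structure(list(
    min_gsh_fraction = frac[i_min],
    time_of_min_min = df$time_min[i_min],
    toxic = toxic,
    first_crossing_min = crossing,
    toxicity_fraction = thr
  ), class = "apap_toxicity")
}

#' @export
print.apap_toxicity <- function(x, ...) {
  cat(sprintf("Minimum liver GSH: %.1f%% of normal at t = %g min\n",
              100 * x$min_gsh_fraction, x$time_of_min_min))
  if (x$toxic) {
    cat(sprintf("TOXIC: crosses the %g%% threshold at t = %.0f min (%.2f days)\n",
                100 * x$toxicity_fraction, x$first_crossing_min,
                x$first_crossing_min / 1440))
  } else {
    cat(sprintf("Non-toxic (threshold %g%% of normal)\n",
                100 * x$toxicity_fraction))
  }
  invisible(x)
}

#' Cumulative hepatic GSH demand
#'
#' Total NAPQI-GSH conjugation over the run (the final value of the
#' cumulative conjugation flux), the model's measure of how much
#' detoxification capacity a regimen consumed.
#'
#' @inheritParams assess_toxicity
#' @return mmol of GSH consumed by conjugation.
#' @export
gsh_demand_auc <- function(result) {
  df <- .sim_table(result)
  df$cum_gsh_conjugated[nrow(df)]
}

#' Quasi-steady-state GSH reduction
#'
#' Percent reduction of the liver GSH pool relative to normal, measured as
#' the mean over the final `window_min` minutes (default 24 h) — a plateau
#' statement robust to dosing-grid phase. The run is flagged non-converged
#' when the mean over the final window drifts more than 1% from the mean over
#' the preceding window.
#'
#' @inheritParams assess_toxicity
#' @param window_min Averaging window, minutes.
#' @return Percent reduction (0 = no depletion), with attribute `converged`.
#' @export
steady_state_reduction <- function(result, window_min = 1440,
                                   kinetics = NULL) {
  k <- .sim_kinetics(result, kinetics)
  df <- .sim_table(result)
  gn <- k$gsh$gsh_normal_mmol_l
  t_end <- df$time_min[nrow(df)]
  if (t_end < 2 * window_min) {
    stop("run too short for the requested steady-state window", call. = FALSE)
  }
  in_win <- df$time_min > t_end - window_min
  in_prev <- df$time_min > t_end - 2 * window_min & !in_win
  m1 <- mean(df$gsh_mmolL[in_win])
  m0 <- mean(df$gsh_mmolL[in_prev])
  converged <- abs(m1 - m0) / gn <= 0.01
  if (!converged) {
    warning("cycle-to-cycle GSH mean drift exceeds 1%; steady state not reached",
            call. = FALSE)
  }
  structure(100 * (1 - m1 / gn), converged = converged)
}

#' Minimal CYP multiplier driving a regimen toxic
#'
#' Bisection (to +/- `tol`) for the smallest static multiplier on the
#' oxidation-pathway Vmax at which the given regimen/scenario crosses the
#' GSH toxicity threshold. Assumes monotonicity of depletion in the
#' multiplier (which holds in this model: more oxidation means more NAPQI).
#'
#' @param regimen An `apap_regimen`.
#' @param scenario An `apap_scenario`.
#' @param t_end Simulation end, minutes.
#' @param cap Upper search bound (a not-found result is returned when even
#'   `cap` is non-toxic).
#' @param tol Bisection half-width on the multiplier.
#' @param ... Passed to [simulate_apap()] (e.g. `physiology`, `kinetics`,
#'   `solver`, `qss_napqi`).
#' @return A list: `multiplier` (the smallest toxic multiplier found, `NA`
#'   when not found below `cap`), `found`, and the final non-toxic/toxic
#'   `bracket`.
#' @export
find_minimal_cyp_multiplier <- function(regimen, scenario = scenario_normal(),
                                        t_end, cap = 100, tol = 0.5, ...) {
  is_toxic <- function(m) {
    sim <- simulate_apap(regimen, scenario, t_end = t_end,
                         vmax_multipliers = c(oxidation = m), ...)
    assess_toxicity(sim)$toxic
  }
  if (is_toxic(1)) {
    return(list(multiplier = 1, found = TRUE, bracket = c(1, 1)))
  }
  if (!is_toxic(cap)) {
    return(list(multiplier = NA_real_, found = FALSE, bracket = c(cap, NA)))
  }
  lo <- 1; hi <- cap
  while (hi - lo > 2 * tol) {
    mid <- (lo + hi) / 2
    if (is_toxic(mid)) hi <- mid else lo <- mid
  }
  list(multiplier = hi, found = TRUE, bracket = c(lo, hi))
}

#' Minimal GSH-regeneration reduction driving a regimen toxic
#'
#' Scans integer divisors f = 2, 3, ... of the regeneration coefficient
#' `k_gen` and returns the smallest one that makes the regimen toxic,
#' together with the threshold-crossing time at that divisor.
#'
#' @inheritParams find_minimal_cyp_multiplier
#' @param kinetics An `apap_kinetics` (divided-`k_gen` copies are derived
#'   from it).
#' @return A list: `factor` (integer divisor, `NA` when not found below
#'   `cap`), `found`, `crossing_min` and `crossing_days`.
#' @export
find_minimal_kgen_reduction <- function(regimen, scenario = scenario_normal(),
                                        t_end, kinetics = default_kinetics(),
                                        cap = 100, ...) {
  run <- function(f) {
    k <- kinetics
    k$gsh$k_gen_per_min <- kinetics$gsh$k_gen_per_min / f
    assess_toxicity(simulate_apap(regimen, scenario, kinetics = k,
                                  t_end = t_end, ...))
  }
  base <- run(1)
  if (base$toxic) {
    return(list(factor = 1L, found = TRUE,
                crossing_min = base$first_crossing_min,
                crossing_days = base$first_crossing_min / 1440))
  }
  for (f in 2:cap) {
    tox <- run(f)
    if (tox$toxic) {
      return(list(factor = as.integer(f), found = TRUE,
                  crossing_min = tox$first_crossing_min,
                  crossing_days = tox$first_crossing_min / 1440))
    }
  }
  list(factor = NA_integer_, found = FALSE, crossing_min = NA_real_,
       crossing_days = NA_real_)
}

#' Clearance-route fractions
#'
#' Cumulative glucuronide, sulfate, oxidized and renal fluxes normalized by
#' the absorbed dose, plus the residual body burden; the five quantities sum
#' to 1 (mass conservation). A warning flag is set when less than 95% of the
#' absorbed dose has been cleared by the end of the run.
#'
#' @param result An `apap_sim`.
#' @return A list of class `apap_route_fractions`: `glucuronide`, `sulfate`,
#'   `oxidized`, `renal`, `residual`, `cleared_fraction`,
#'   `sufficient_clearance`.
#' @export
route_fractions <- function(result) {
  stopifnot(inherits(result, "apap_sim"))
  n <- length(result$time_min)
  absorbed <- result$absorbed_mmol
  cum <- result$cum[n, ]
  if (absorbed == 0) {
    out <- list(glucuronide = 0, sulfate = 0, oxidized = 0, renal = 0,
                residual = 0, cleared_fraction = 0,
                sufficient_clearance = TRUE)
    class(out) <- "apap_route_fractions"
    return(out)
  }
  cleared <- sum(cum[c("cum_glucuronide", "cum_sulfate", "cum_oxidized",
                       "cum_renal")]) / absorbed
  if (cleared < 0.95) {
    warning(sprintf("only %.1f%% of the absorbed dose cleared; route fractions are provisional",
                    100 * cleared), call. = FALSE)
  }
  out <- list(
    glucuronide = unname(cum["cum_glucuronide"]) / absorbed,
    sulfate = unname(cum["cum_sulfate"]) / absorbed,
    oxidized = unname(cum["cum_oxidized"]) / absorbed,
    renal = unname(cum["cum_renal"]) / absorbed,
    residual = 1 - cleared,
    cleared_fraction = cleared,
    sufficient_clearance = cleared >= 0.95
  )
  class(out) <- "apap_route_fractions"
  out
}

#' @export
print.apap_route_fractions <- function(x, ...) {
  cat(sprintf(
    "Route fractions of absorbed dose: glucuronide %.3f, sulfate %.3f, oxidized %.3f, renal %.3f, residual %.3f\n",
    x$glucuronide, x$sulfate, x$oxidized, x$renal, x$residual))
  invisible(x)
}

#' Calibrate the normal hepatic GSH concentration
#'
#' Root-finds (bisection on `bracket`, to `tol` mmol/L) the normal hepatic
#' GSH concentration `[GSH]_N` at which a single `dose_g` oral dose depletes
#' the liver GSH pool by exactly `target_depletion` at its minimum — the
#' model's calibration anchor (15 g, 70% depletion: the accepted single-dose
#' limit before hepatic injury). Depletion is monotone decreasing in
#' `[GSH]_N`, so the bisection is well posed; an error is raised when the
#' bracket does not straddle the target.
#'
#' @param target_depletion Peak fractional depletion to anchor (default
#'   0.70).
#' @param dose_g Anchoring single oral dose, grams (default 15).
#' @param kinetics,physiology Parameter sets (all constants other than
#'   `[GSH]_N` are held fixed).
#' @param t_end Simulation horizon for the anchor dose, minutes.
#' @param bracket Search interval for `[GSH]_N`, mmol/L.
#' @param tol Bisection tolerance on `[GSH]_N`, mmol/L.
#' @param ... Passed to [simulate_apap()].
#' @return The calibrated `[GSH]_N` in mmol/L.
#' @export
calibrate_baseline <- function(target_depletion = 0.70, dose_g = 15,
                               kinetics = default_kinetics(),
                               physiology = default_physiology(),
                               t_end = 2880, bracket = c(1, 20),
                               tol = 1e-3, ...) {
  stopifnot(target_depletion > 0, target_depletion < 1, dose_g > 0)
  reg <- apap_regimen(dose_g, route = "oral")
  target_fraction <- 1 - target_depletion
  min_fraction <- function(gn) {
    k <- kinetics
    k$gsh$gsh_normal_mmol_l <- gn
    sim <- simulate_apap(reg, scenario_normal(), physiology, k,
                         t_end = t_end, ...)
    min(sim$gsh) / gn
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- min_fraction(lo) - target_fraction
  f_hi <- min_fraction(hi) - target_fraction
  if (f_lo * f_hi > 0) {
    stop(sprintf(
      "calibration failure: no sign change on [%g, %g] mmol/L (endpoint fractions %.3f, %.3f)",
      lo, hi, f_lo + target_fraction, f_hi + target_fraction), call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- min_fraction(mid) - target_fraction
    if (f_mid * f_lo <= 0) {
      hi <- mid
    } else {
      lo <- mid
      f_lo <- f_mid
    }
  }
  (lo + hi) / 2
}

#' Plasma exposure summary
#'
#' Cmax/Tmax of the venous blood concentration and its trapezoidal AUC.
#'
#' @param result An `apap_sim`.
#' @return A list `cmax_mmol_l`, `tmax_min`, `auc_mmol_min_l`.
#' @export
plasma_exposure <- function(result) {
  stopifnot(inherits(result, "apap_sim"))
  cv <- result$conc[, "venous_blood"]
  tt <- result$time_min
  i <- which.max(cv)
  auc <- sum(diff(tt) * (utils::head(cv, -1) + utils::tail(cv, -1)) / 2)
  list(cmax_mmol_l = cv[i], tmax_min = tt[i], auc_mmol_min_l = auc)
}
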