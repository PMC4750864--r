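# Dose regimens.  Doses are instantaneous boluses (Dirac inputs): an iv dose
# is added to the venous blood pool; an oral dose is added to the gut tissue
# scaled by bioavailability F.  Regimens are either an explicit event table
# or a periodic spec (dose, interval, count).

#' Define a periodic dosing regimen
#'
#' @param dose_g Dose per administration, grams.
#' @param interval_min Interval between administrations, minutes.
#' @param n_doses Number of administrations; events occur at
#'   `0, T, 2T, ..., (n-1)T`.
#' @param route `"oral"` (bolus into gut tissue, scaled by bioavailability) or
#'   `"iv"` (bolus into venous blood).
#' @return An object of class `apap_regimen`.
#' @examples
#' apap_regimen(1, 360, 20, "oral") # 1 g every 6 h for 5 days
#' @export
apap_regimen <- function(dose_g, interval_min = 360, n_doses = 1,
                         route = c("oral", "iv")) {
  route <- match.arg(route)
  stopifnot(is.numeric(dose_g), length(dose_g) == 1, dose_g >= 0,
            is.numeric(interval_min), interval_min > 0,
            n_doses >= 1, n_doses == as.integer(n_doses))
  structure(
    list(periodic = list(dose_g = dose_g, interval_min = interval_min,
                         n_doses = as.integer(n_doses), route = route),
         events = NULL),
    class = "apap_regimen"
  )
}

#' Define a regimen from an explicit dose-event table
#'
#' @param events A data frame with columns `time_min`, `amount_g`, `route`
#'   (`"oral"` or `"iv"`); times must be >= 0 and amounts >= 0.
#' @return An object of class `apap_regimen`.
#' @export
regimen_from_events <- function(events) {
  stopifnot(is.data.frame(events),
            all(c("time_min", "amount_g", "route") %in% names(events)))
  if (nrow(events) > 0) {
    stopifnot(all(events$time_min >= 0), all(events$amount_g >= 0),
              all(events$route %in% c("oral", "iv")))
  }
  structure(list(periodic = NULL,
                 events = events[c("time_min", "amount_g", "route")]),
            class = "apap_regimen")
}

#' Expand a regimen to an explicit, sorted dose-event table
#'
#' Periodic specs are expanded to events at `0, T, ..., (n-1)T`; explicit
#' tables are sorted by time. Simultaneous events of the same route are merged
#' by summing their amounts, so the expansion is idempotent.
#'
#' @param regimen An `apap_regimen`.
#' @return A data frame with columns `time_min`, `amount_g`, `route`, strictly
#'   ascending in time within each route.
#' @examples
#' expand_regimen(apap_regimen(1, 360, 3, "oral"))$time_min # 0 360 720
#' @export
expand_regimen <- function(regimen) {
  stopifnot(inherits(regimen, "apap_regimen"))
  if (!is.null(regimen$periodic)) {
    p <- regimen$periodic
    ev <- data.frame(
      time_min = p$interval_min * (seq_len(p$n_doses) - 1),
      amount_g = rep(p$dose_g, p$n_doses),
      route = rep(p$route, p$n_doses),
      stringsAsFactors = FALSE
    )
  } else {
    ev <- regimen$events
  }
  if (nrow(ev) == 0) return(ev)
  agg <- stats::aggregate(amount_g ~ time_min + route, data = ev, FUN = sum)
  agg <- agg[order(agg$time_min, agg$route), c("time_min", "amount_g", "route")]
  rownames(agg) <- NULL
  agg
}

#' Convert a dose event to millimoles entering the system
#'
#' An iv dose contributes `amount_g * 1000 / M` mmol to venous blood; an oral
#' dose contributes that quantity times the bioavailability F (default 0.79)
#' to the gut tissue. M is the APAP molar mass, 151.16 g/mol.
#'
#' @param time_min,amount_g,route A single dose event.
#' @param kinetics An `apap_kinetics` object supplying F and the molar mass.
#' @return A list with `moles_mmol` (mmol reaching the circulation) and
#'   `target` (`"venous_blood"` or `"gut"`).
#' @examples
#' dose_to_moles(0, 1, "iv", default_kinetics())$moles_mmol # 6.615...
#' @export
dose_to_moles <- function(time_min, amount_g, route, kinetics) {
  stopifnot(route %in% c("oral", "iv"), amount_g >= 0)
  base <- amount_g * 1000 / kinetics$apap_molar_mass_g_mol
  if (route == "oral") {
    list(moles_mmol = base * kinetics$oral_bioavailability, target = "gut")
  } else {
    list(moles_mmol = base, target = "venous_blood")
  }
}

#' Total absorbed moles over a regimen
#'
#' @inheritParams expand_regimen
#' @param kinetics An `apap_kinetics` object.
#' @return Total mmol entering the circulation (oral doses scaled by F).
#' @export
regimen_total_moles <- function(regimen, kinetics) {
  ev <- expand_regimen(regimen)
  if (nrow(ev) == 0) return(0)
  sum(vapply(seq_len(nrow(ev)), function(i) {
    dose_to_moles(ev$time_min[i], ev$amount_g[i], ev$route[i],
                  kinetics)$moles_mmol
  }, numeric(1)))
}

#' @export
print.apap_regimen <- function(x, ...) {
  ev <- expand_regimen(x)
  if (nrow(ev) == 0) {
    cat("APAP regimen: no doses\n")
  } else {
    cat(sprintf("APAP regimen: %d dose event(s), %g g total, t = %g..%g min\n",
                nrow(ev), sum(ev$amount_g), min(ev$time_min), max(ev$time_min)))
  }
  invisible(x)
}
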