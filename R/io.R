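# Time-series and summary output, YAML run configuration, named fixtures.

.ts_columns <- function(physiology = default_physiology()) {
  c("time_min", physiology$name, "gsh_mmolL", "napqi_mmolL",
    "cum_glucuronide", "cum_sulfate", "cum_oxidized", "cum_renal",
    "cum_gsh_conjugated", "co_g", "co_s", "co_ox", "k_gen_mult")
}

#' Write a simulation time series to CSV
#'
#' Fixed dialect: comma separator, dot decimal, one header row, stable column
#' order (`time_min`, the 14 compartments, `gsh_mmolL`, `napqi_mmolL`, the
#' five `cum_*` fluxes, the four modifier traces). Values are written with 15
#' significant digits so a write/read round trip preserves at least 12.
#'
#' @param result An `apap_sim` or a data frame in the canonical column
#'   order.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(result, path) {
  df <- if (inherits(result, "apap_sim")) as.data.frame(result) else result
  stopifnot(is.data.frame(df))
  body <- if (nrow(df) > 0) {
    fmt <- vapply(df, function(col) {
      if (is.numeric(col)) sprintf("%.15g", col) else as.character(col)
    }, FUN.VALUE = character(nrow(df)))
    apply(matrix(fmt, nrow = nrow(df)), 1, paste, collapse = ",")
  } else {
    character(0)
  }
  writeLines(c(paste(names(df), collapse = ","), body), path)
  invisible(path)
}

#' Read a simulation time series from CSV
#'
#' @param path A CSV written by [write_timeseries()].
#' @return A data frame in the canonical column order.
#' @export
read_timeseries <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "numeric"),
    error = function(e) stop("malformed time-series file '", path, "': ",
                             conditionMessage(e), call. = FALSE),
    warning = function(w) stop("malformed time-series file '", path, "': ",
                               conditionMessage(w), call. = FALSE)
  )
  need <- c("time_min", "gsh_mmolL")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("time-series file lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' Summarize a simulation as a JSON-ready list (optionally written to file)
#'
#' @param result An `apap_sim`.
#' @param path Optional output path for a JSON file.
#' @return A list: minimum GSH fraction and its time, toxicity flag and
#'   crossing time, clearance-route fractions, and plasma Cmax/Tmax/AUC.
#' @export
simulation_summary <- function(result, path = NULL) {
  tox <- assess_toxicity(result)
  rf <- suppressWarnings(route_fractions(result))
  pe <- plasma_exposure(result)
  out <- list(
    min_gsh_fraction = tox$min_gsh_fraction,
    time_of_min_min = tox$time_of_min_min,
    toxic = tox$toxic,
    first_crossing_min = tox$first_crossing_min,
    toxicity_fraction = tox$toxicity_fraction,
    route_fractions = rf[c("glucuronide", "sulfate", "oxidized", "renal",
                           "residual")],
    cleared_fraction = rf$cleared_fraction,
    plasma_cmax_mmol_l = pe$cmax_mmol_l,
    plasma_tmax_min = pe$tmax_min,
    plasma_auc_mmol_min_l = pe$auc_mmol_min_l,
    gsh_demand_mmol = gsh_demand_auc(result),
    mass_balance_error = result$mass_balance_error
  )
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  out
}

# ---------------------------------------------------------------------------
# Run configuration (YAML)

.default_run_config <- function() {
  list(
    regimen = list(dose_g = 1, interval_min = 360, n_doses = 1,
                   route = "oral", events = NULL),
    scenario = list(name = "normal", dose_g = NULL),
    t_end = 1440,
    solver = list(rtol = 1e-8, atol = 1e-10, dt_out = 1),
    seed = NULL, # reserved; the model is deterministic
    kinetics = NULL,   # nested overrides onto default_kinetics()
    physiology = NULL, # list(name = list(field = value)) overrides
    vmax_multipliers = NULL,
    qss_napqi = FALSE
  )
}

# Recursively merge overrides into a base list, erroring on unknown keys.
.merge_config <- function(base, override, path = "") {
  if (is.null(override)) return(base)
  if (!is.list(override) || !is.list(base)) return(override)
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      stop("unknown configuration key: ", full, call. = FALSE)
    }
    base[[key]] <- .merge_config(base[[key]], override[[key]], full)
  }
  base
}

#' Resolve a run configuration into simulation inputs
#'
#' Validates and resolves a configuration list (as produced by
#' [generate_fixture()] or [read_run_config()]) into the complete set of
#' objects [simulate_apap()] needs, applying kinetics/physiology overrides
#' onto the packaged defaults. Unknown keys are an error.
#'
#' @param config A run-configuration list.
#' @return A list with `regimen`, `scenario`, `physiology`, `kinetics`,
#'   `t_end`, `solver`, `vmax_multipliers`, `qss_napqi`.
#' @export
resolve_run_config <- function(config) {
  cfg <- .merge_config(.default_run_config(), config)
  kin <- default_kinetics()
  if (!is.null(cfg$kinetics)) {
    kin <- .merge_config(unclass(kin), cfg$kinetics, "kinetics")
    class(kin) <- "apap_kinetics"
  }
  phys <- default_physiology()
  if (!is.null(cfg$physiology)) {
    for (nm in names(cfg$physiology)) {
      i <- match(nm, phys$name)
      if (is.na(i)) stop("unknown physiology compartment: ", nm,
                         call. = FALSE)
      for (field in names(cfg$physiology[[nm]])) {
        if (!field %in% names(phys)) {
          stop("unknown physiology field: ", field, call. = FALSE)
        }
        phys[[field]][i] <- cfg$physiology[[nm]][[field]]
      }
    }
  }
  reg <- if (!is.null(cfg$regimen$events)) {
    regimen_from_events(as.data.frame(cfg$regimen$events))
  } else {
    apap_regimen(cfg$regimen$dose_g, cfg$regimen$interval_min,
                 cfg$regimen$n_doses, cfg$regimen$route)
  }
  sc <- switch(cfg$scenario$name,
    normal = scenario_normal(),
    chronic = chronic_apap_schedule(cfg$scenario$dose_g %||%
                                      cfg$regimen$dose_g, kin),
    alcohol = alcohol_schedule(kin),
    fasting = fasting_modifiers(kin),
    `chronic+alcohol` = combined_chronic_alcohol(cfg$scenario$dose_g %||%
                                                   cfg$regimen$dose_g, kin),
    stop("unknown scenario: ", cfg$scenario$name, call. = FALSE)
  )
  vm <- cfg$vmax_multipliers
  if (!is.null(vm)) vm <- unlist(vm)
  list(regimen = reg, scenario = sc, physiology = phys, kinetics = kin,
       t_end = cfg$t_end,
       solver = solver_settings(rtol = cfg$solver$rtol,
                                atol = cfg$solver$atol,
                                dt_out = cfg$solver$dt_out),
       vmax_multipliers = vm, qss_napqi = isTRUE(cfg$qss_napqi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configuration
#'
#' @param config A run-configuration list (see [resolve_run_config()]).
#' @return An `apap_sim` (or, for the `toy-one-compartment` fixture, the
#'   one-compartment data frame).
#' @export
run_config <- function(config) {
  if (identical(config$special, "one_compartment")) {
    oc <- config$one_compartment
    return(simulate_one_compartment(oc$volume_l, oc$clearance_l_min,
                                    oc$dose_mmol, config$t_end))
  }
  r <- resolve_run_config(config[setdiff(names(config),
                                         c("special", "one_compartment",
                                           "description"))])
  simulate_apap(r$regimen, r$scenario, r$physiology, r$kinetics,
                t_end = r$t_end, solver = r$solver,
                vmax_multipliers = r$vmax_multipliers,
                qss_napqi = r$qss_napqi)
}

#' Write / read a run configuration as YAML
#'
#' Numeric values are serialized with 17 significant digits so that a
#' write/read round trip reproduces every field bit-exactly.
#'
#' @param config A run-configuration list.
#' @param path File path.
#' @return `read_run_config` returns the configuration list; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  # %.17g guarantees an exact double round trip (the yaml precision argument
  # caps below that); "verbatim" keeps the numbers unquoted.
  handlers <- list(numeric = function(v) {
    structure(sprintf("%.17g", v), class = "verbatim")
  })
  writeLines(yaml::as.yaml(config, handlers = handlers), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Named experiment fixtures
#'
#' Returns the exact run configuration used by the package's validation and
#' acceptance experiments:
#'
#' * `validation-iv-1g`: single 1 g iv bolus, normal scenario, 8 h.
#' * `chronic-1g` / `chronic-2g` / `chronic-5g`: that dose orally every
#'   6 h for 5 days (20 doses) under the chronic induction schedule.
#' * `alcohol-therapeutic`: 1 g oral every 6 h for 5 days starting when
#'   drinking stops, full alcohol scenario.
#' * `fasting-4g`: single 4 g oral dose under the fasting modifiers, 48 h.
#' * `combined`: 2 g oral every 6 h for 5 days under the combined
#'   chronic+alcohol scenario.
#' * `toy-one-compartment`: single-pool analytic-oracle configuration
#'   (1 g iv into a 42 L pool cleared at 0.0247 L/min).
#'
#' @param name One of the fixture names above.
#' @return A run-configuration list consumable by [run_config()].
#' @export
generate_fixture <- function(name) {
  fixtures <- list(
    `validation-iv-1g` = list(
      description = "single 1 g iv bolus, normal scenario",
      regimen = list(dose_g = 1, interval_min = 360, n_doses = 1,
                     route = "iv"),
      scenario = list(name = "normal"), t_end = 480),
    `chronic-1g` = list(
      description = "1 g oral every 6 h for 5 days, chronic induction",
      regimen = list(dose_g = 1, interval_min = 360, n_doses = 20,
                     route = "oral"),
      scenario = list(name = "chronic", dose_g = 1), t_end = 7200),
    `chronic-2g` = list(
      description = "2 g oral every 6 h for 5 days, chronic induction",
      regimen = list(dose_g = 2, interval_min = 360, n_doses = 20,
                     route = "oral"),
      scenario = list(name = "chronic", dose_g = 2), t_end = 7200),
    `chronic-5g` = list(
      description = "5 g oral every 6 h for 5 days, chronic induction (2 g tier)",
      regimen = list(dose_g = 5, interval_min = 360, n_doses = 20,
                     route = "oral"),
      scenario = list(name = "chronic", dose_g = 5), t_end = 7200),
    `alcohol-therapeutic` = list(
      description = "1 g oral every 6 h for 5 days after binge drinking stops",
      regimen = list(dose_g = 1, interval_min = 360, n_doses = 20,
                     route = "oral"),
      scenario = list(name = "alcohol"), t_end = 7200),
    `fasting-4g` = list(
      description = "single 4 g oral dose while fasting/malnourished",
      regimen = list(dose_g = 4, interval_min = 360, n_doses = 1,
                     route = "oral"),
      scenario = list(name = "fasting"), t_end = 2880),
    combined = list(
      description = "2 g oral every 6 h for 5 days, chronic + alcohol",
      regimen = list(dose_g = 2, interval_min = 360, n_doses = 20,
                     route = "oral"),
      scenario = list(name = "chronic+alcohol", dose_g = 2), t_end = 7200),
    `toy-one-compartment` = list(
      description = "single-pool analytic oracle: mono-exponential decay",
      special = "one_compartment",
      one_compartment = list(volume_l = 42, clearance_l_min = 0.0247,
                             dose_mmol = 1000 / 151.16),
      t_end = 1440)
  )
  if (!name %in% names(fixtures)) {
    stop("unknown fixture '", name, "'; valid names: ",
         paste(names(fixtures), collapse = ", "), call. = FALSE)
  }
  fixtures[[name]]
}
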