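# The coupled ODE system.  Per-tissue perfusion-limited mass balance
# (well-stirred compartments); lung in series between the venous and arterial
# pools; portal topology for liver inflow; saturable three-pathway hepatic
# metabolism driven by the liver outflow (venous-equilibrated) concentration;
# fixed-extraction renal elimination acting on the arterial concentration
# entering the kidney; and the liver-local GSH/NAPQI pair
#
#   d[GSH]/dt   = m(t) k_gen ([GSH]_N - [GSH]) - k_II [NAPQI][GSH]
#   d[NAPQI]/dt = v_ox / V_liver            - k_II [NAPQI][GSH]
#
# The GSH ceiling is structural: regeneration is proportional to the deficit
# and vanishes at [GSH]_N, so the pool can never overshoot it.
#
# Internal units: mmol, L, min.  The bimolecular constant (tabulated in
# mL/(mmol min)) and all volumes/flows (tabulated in mL) are converted at
# build time.

#' Solver settings
#'
#' @param rtol Relative tolerance of the adaptive (lsoda) integrator.
#' @param atol Absolute tolerance, mmol/L.
#' @param max_step Maximum internal step, minutes (`NULL` for no bound).
#' @param dt_out Output grid spacing, minutes.
#' @return A list of class `apap_solver_settings`.
#' @export
solver_settings <- function(rtol = 1e-8, atol = 1e-10, max_step = NULL,
                            dt_out = 1) {
  stopifnot(rtol > 0, atol > 0, dt_out > 0,
            is.null(max_step) || max_step > 0)
  structure(list(rtol = rtol, atol = atol, max_step = max_step,
                 dt_out = dt_out),
            class = "apap_solver_settings")
}

#' Perfusion-limited tissue mass balance
#'
#' Rate of change of a well-stirred tissue's drug concentration:
#' `(Q * (c_in - c_tissue / (Kp * BP)) - elimination) / V`, with Q the tissue
#' blood flow, V its volume and Kp its tissue:plasma partition coefficient.
#'
#' @param c_tissue Tissue concentration, mmol/L.
#' @param c_in Inflowing blood concentration, mmol/L.
#' @param compartment A one-row subset of an `apap_physiology` data frame (or
#'   a list with `volume_ml`, `blood_flow_ml_min`, `partition_coefficient`).
#' @param bp Blood:plasma concentration ratio (default 1).
#' @param elimination_mmol_min Local elimination rate subtracted from the
#'   balance, mmol/min (default 0).
#' @return d(concentration)/dt in mmol/L/min.
#' @examples
#' adipose <- subset(default_physiology(), name == "adipose")
#' tissue_derivative(0, 1, adipose) # 325/8372
#' @export
tissue_derivative <- function(c_tissue, c_in, compartment, bp = 1,
                              elimination_mmol_min = 0) {
  q <- compartment$blood_flow_ml_min / 1000
  v <- compartment$volume_ml / 1000
  kp <- compartment$partition_coefficient
  (q * (c_in - c_tissue / (kp * bp)) - elimination_mmol_min) / v
}

#' Liver inflow concentration (portal topology)
#'
#' Flow-weighted mix of hepatic arterial blood and the gut and spleen venous
#' outflows: `(Q_ha * C_art + Q_gut * C_gut/Kp_gut/BP + Q_spleen *
#' C_spleen/Kp_spleen/BP) / Q_liver` with `Q_ha = Q_liver - Q_gut - Q_spleen`.
#'
#' @param c_arterial Arterial blood concentration, mmol/L.
#' @param c_gut,c_spleen Gut and spleen tissue concentrations, mmol/L.
#' @param physiology An `apap_physiology` object.
#' @param bp Blood:plasma ratio.
#' @return Concentration entering the liver, mmol/L.
#' @examples
#' liver_inflow_concentration(1, 0, 0, default_physiology()) # 390/1625
#' @export
liver_inflow_concentration <- function(c_arterial, c_gut, c_spleen,
                                       physiology, bp = 1) {
  p <- physiology
  q <- function(nm) p$blood_flow_ml_min[p$name == nm]
  kp <- function(nm) p$partition_coefficient[p$name == nm]
  q_liv <- p$blood_flow_ml_min[p$role == "liver"]
  q_ha <- q_liv - q("gut") - q("spleen")
  (q_ha * c_arterial +
     q("gut") * c_gut / (kp("gut") * bp) +
     q("spleen") * c_spleen / (kp("spleen") * bp)) / q_liv
}

#' Michaelis-Menten pathway rate
#'
#' `multiplier * Vmax_min * c / (Km + c)` with
#' `Vmax_min = vmax * body_weight / 60` converting the tabulated
#' mmol/(hr kg) capacity to mmol/min for the whole liver.
#'
#' @param c_driving Driving concentration, mmol/L (the liver outflow
#'   concentration in the assembled model).
#' @param pathway A list with `vmax_mmol_hr_kg` and `km_mmol_l`, or a pathway
#'   name looked up in `kinetics`.
#' @param multiplier Dimensionless scenario/search multiplier (>= 0).
#' @param body_weight_kg Body weight, kg.
#' @param kinetics Optional `apap_kinetics` used when `pathway` is a name.
#' @return Metabolic rate, mmol/min.
#' @examples
#' michaelis_menten_rate(6.89, "glucuronidation") # half of 0.97*70/60
#' @export
michaelis_menten_rate <- function(c_driving, pathway, multiplier = 1,
                                  body_weight_kg = 70,
                                  kinetics = default_kinetics()) {
  stopifnot(multiplier >= 0)
  if (is.character(pathway)) pathway <- .pathway(kinetics, pathway)
  vmax_min <- pathway$vmax_mmol_hr_kg * body_weight_kg / 60
  c_pos <- pmax(c_driving, 0)
  multiplier * vmax_min * c_pos / (pathway$km_mmol_l + c_pos)
}

#' Renal elimination rate
#'
#' Fixed-extraction elimination `E * Q_kidney * C_arterial` acting on the
#' concentration entering the kidney.
#'
#' @param c_arterial Arterial concentration, mmol/L.
#' @param physiology An `apap_physiology` object.
#' @param kinetics An `apap_kinetics` object supplying E.
#' @return Elimination rate, mmol/min.
#' @export
renal_elimination_rate <- function(c_arterial, physiology = default_physiology(),
                                   kinetics = default_kinetics()) {
  q_kid <- physiology$blood_flow_ml_min[physiology$role == "kidney"] / 1000
  kinetics$renal_extraction * q_kid * pmax(c_arterial, 0)
}

#' Hepatic GSH balance
#'
#' `k_gen_mult * k_gen * ([GSH]_N - gsh) - k_II' * napqi * gsh`, with `k_II'`
#' the bimolecular constant converted to L/(mmol min). Regeneration is
#' proportional to the deficit, so the pool cannot exceed `[GSH]_N`.
#'
#' @param gsh,napqi Concentrations, mmol/L.
#' @param kinetics An `apap_kinetics` object.
#' @param k_gen_multiplier Scenario multiplier on the regeneration
#'   coefficient.
#' @return d(GSH)/dt, mmol/L/min.
#' @export
gsh_derivative <- function(gsh, napqi, kinetics = default_kinetics(),
                           k_gen_multiplier = 1) {
  g <- kinetics$gsh
  k_ii <- g$k_ii_ml_mmol_min / 1000
  k_gen_multiplier * g$k_gen_per_min * (g$gsh_normal_mmol_l - gsh) -
    k_ii * napqi * gsh
}

#' Hepatic NAPQI balance
#'
#' NAPQI is liver-local (no transport terms): formation by APAP oxidation,
#' removal by bimolecular conjugation with GSH:
#' `oxidation_rate / V_liver - k_II' * napqi * gsh`.
#'
#' @param napqi,gsh Concentrations, mmol/L.
#' @param oxidation_rate_mmol_min APAP oxidation rate, mmol/min.
#' @param liver_volume_l Liver volume, litres.
#' @param kinetics An `apap_kinetics` object.
#' @return d(NAPQI)/dt, mmol/L/min.
#' @export
napqi_derivative <- function(napqi, gsh, oxidation_rate_mmol_min,
                             liver_volume_l = 1.799,
                             kinetics = default_kinetics()) {
  k_ii <- kinetics$gsh$k_ii_ml_mmol_min / 1000
  oxidation_rate_mmol_min / liver_volume_l - k_ii * napqi * gsh
}

# ---------------------------------------------------------------------------
# Model assembly

.state_names <- function(physiology) {
  c(physiology$name, "gsh", "napqi",
    "cum_glucuronide", "cum_sulfate", "cum_oxidized", "cum_renal",
    "cum_gsh_conjugated")
}

# Precompute everything the derivative needs into a flat environment and
# return the deSolve-style derivative closure plus bookkeeping.
.build_model <- function(physiology, kinetics, scenario, vmax_multipliers,
                         qss_napqi) {
  viol <- validate_physiology(physiology)
  if (length(viol)) {
    stop("invalid physiology:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  }
  viol <- validate_kinetics(kinetics)
  if (length(viol)) {
    stop("invalid kinetics:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  }
  p <- physiology
  bp <- attr(p, "blood_plasma_ratio")
  bw <- attr(p, "body_weight_kg")

  n <- nrow(p)
  V <- p$volume_ml / 1000
  Q <- p$blood_flow_ml_min / 1000
  kpbp <- p$partition_coefficient * bp

  idx <- function(role) which(p$role == role)
  i_liv <- idx("liver"); i_kid <- idx("kidney"); i_lung <- idx("lung")
  i_art <- idx("arterial-blood"); i_ven <- idx("venous-blood")
  i_gut <- which(p$name == "gut"); i_spl <- which(p$name == "spleen")
  if (length(i_gut) != 1 || length(i_spl) != 1) {
    stop("physiology must contain gut and spleen compartments (portal inflow)",
         call. = FALSE)
  }
  # Plain arterial-fed tissues returning directly to the venous pool.
  i_plain <- setdiff(seq_len(n), c(i_liv, i_kid, i_lung, i_art, i_ven,
                                   i_gut, i_spl))
  # Organs whose outflow feeds the venous pool (liver outflow counted once).
  i_sys <- setdiff(seq_len(n), c(i_lung, i_art, i_ven, i_gut, i_spl))

  q_co <- Q[i_lung]
  q_ha <- Q[i_liv] - Q[i_gut] - Q[i_spl]

  m <- match(c("glucuronidation", "sulfation", "oxidation"),
             kinetics$pathways$name)
  mult <- rep(1, 3)
  if (!is.null(vmax_multipliers)) {
    nm <- names(vmax_multipliers)
    stopifnot(!is.null(nm),
              all(nm %in% c("glucuronidation", "sulfation", "oxidation")),
              all(vmax_multipliers >= 0))
    mult[match(nm, c("glucuronidation", "sulfation", "oxidation"))] <-
      vmax_multipliers
  }
  vmax <- kinetics$pathways$vmax_mmol_hr_kg[m] * bw / 60 * mult
  km <- kinetics$pathways$km_mmol_l[m]

  E <- kinetics$renal_extraction
  q_kid <- Q[i_kid]
  k_gen <- kinetics$gsh$k_gen_per_min
  k_ii <- kinetics$gsh$k_ii_ml_mmol_min / 1000
  gsh_n <- kinetics$gsh$gsh_normal_mmol_l
  v_liv <- V[i_liv]

  sched_fun <- function(s) {
    if (nrow(s) == 1 || all(s$value == s$value[1])) {
      v <- s$value[1]
      function(t) v
    } else {
      stats::approxfun(s$time_min, s$value, rule = 2)
    }
  }
  f_cog <- sched_fun(scenario$co_g)
  f_cos <- sched_fun(scenario$co_s)
  f_cox <- sched_fun(scenario$co_ox)
  f_kgn <- sched_fun(scenario$k_gen)

  i_gsh <- n + 1L; i_nap <- n + 2L

  derivs <- function(t, y, parms) {
    conc <- y[1:n]
    gsh <- y[i_gsh]; nap <- y[i_nap]
    cog <- f_cog(t); cos_ <- f_cos(t); cox <- f_cox(t); kgn <- f_kgn(t)

    c_out <- conc / kpbp
    c_art <- conc[i_art]; c_ven <- conc[i_ven]
    c_in_liv <- (q_ha * c_art + Q[i_gut] * c_out[i_gut] +
                   Q[i_spl] * c_out[i_spl]) / Q[i_liv]

    c_drv <- max(c_out[i_liv], 0)
    v_g <- cog * vmax[1] * c_drv / (km[1] + c_drv)
    v_s <- cos_ * vmax[2] * c_drv / (km[2] + c_drv)
    v_o <- cox * vmax[3] * c_drv / (km[3] + c_drv)
    v_ren <- E * q_kid * max(c_art, 0)

    dc <- numeric(n)
    dc[i_plain] <- Q[i_plain] * (c_art - c_out[i_plain]) / V[i_plain]
    dc[i_gut] <- Q[i_gut] * (c_art - c_out[i_gut]) / V[i_gut]
    dc[i_spl] <- Q[i_spl] * (c_art - c_out[i_spl]) / V[i_spl]
    dc[i_kid] <- (Q[i_kid] * (c_art - c_out[i_kid]) - v_ren) / V[i_kid]
    dc[i_liv] <- (Q[i_liv] * (c_in_liv - c_out[i_liv]) - v_g - v_s - v_o) /
      V[i_liv]
    dc[i_lung] <- q_co * (c_ven - c_out[i_lung]) / V[i_lung]
    dc[i_art] <- q_co * (c_out[i_lung] - c_art) / V[i_art]
    dc[i_ven] <- (sum(Q[i_sys] * c_out[i_sys]) - q_co * c_ven) / V[i_ven]

    if (qss_napqi) {
      # NAPQI at quasi-steady state: every mole oxidized is conjugated at
      # once; the NAPQI state stays at 0.
      conj <- v_o / v_liv
      dgsh <- kgn * k_gen * (gsh_n - gsh) - conj
      dnap <- 0
    } else {
      conj <- k_ii * max(nap, 0) * max(gsh, 0)
      dgsh <- kgn * k_gen * (gsh_n - gsh) - conj
      dnap <- v_o / v_liv - conj
    }

    list(c(dc, dgsh, dnap, v_g, v_s, v_o, v_ren, conj * v_liv),
         c(co_g = cog, co_s = cos_, co_ox = cox, k_gen_mult = kgn))
  }

  list(derivs = derivs, n_comp = n, V = V, i_liver = i_liv,
       state_names = .state_names(p), bp = bp)
}

#' Simulate the APAP PBPK model
#'
#' Integrates the full coupled system — 14 perfusion-limited drug
#' compartments, the liver-local GSH/NAPQI pair, and five cumulative
#' clearance-route fluxes — from a drug-free initial state with the hepatic
#' GSH pool at its scenario-scaled starting value. Dose events are applied as
#' state discontinuities (mmol added to the target compartment divided by its
#' volume) with an integrator restart at each event, the numerically sound
#' treatment of bolus (Dirac) inputs. Scenario multipliers enter as exact
#' piecewise-linear functions of time.
#'
#' The stiff NAPQI-GSH conjugation (k_II ~ 1.9e6 mL/(mmol min)) is handled by
#' the adaptive stiff/non-stiff switching solver (`deSolve` lsoda). Setting
#' `qss_napqi = TRUE` replaces the NAPQI state by its quasi-steady-state
#' (every mole oxidized conjugates immediately), which removes the stiffness
#' and agrees with the full system to well under 0.1% on cumulative
#' conjugation whenever GSH is not nearly exhausted.
#'
#' @param regimen An `apap_regimen`.
#' @param scenario An `apap_scenario` (default: neutral).
#' @param physiology An `apap_physiology`.
#' @param kinetics An `apap_kinetics`.
#' @param t_end End of simulation, minutes (must exceed the last dose time).
#' @param solver An [solver_settings()] object.
#' @param vmax_multipliers Optional named static multipliers on pathway Vmax
#'   values (names among `glucuronidation`, `sulfation`, `oxidation`);
#'   applied on top of the scenario schedules. Used by threshold searches.
#' @param qss_napqi Use the quasi-steady-state NAPQI closure.
#' @param initial_conc Optional named vector of starting APAP concentrations
#'   (mmol/L) per compartment; defaults to drug-free. Intended for
#'   equilibrium/steady-state studies, not dosing (amounts present initially
#'   are excluded from the dose mass-balance accounting).
#' @return An object of class `apap_sim`: a list with the output `time_min`
#'   grid (1-min spacing by default, containing every dose time), the
#'   per-compartment concentration matrix `conc` (mmol/L), vectors `gsh` and
#'   `napqi` (mmol/L), the cumulative flux matrix `cum` (mmol; columns
#'   glucuronide, sulfate, oxidized, renal, GSH-conjugated), the applied
#'   modifier traces `modifiers`, the absorbed-dose bookkeeping and the
#'   maximal relative mass-balance error `mass_balance_error`.
#' @examples
#' \donttest{
#' sim <- simulate_apap(apap_regimen(1, route = "iv"), t_end = 360)
#' max(sim$conc[, "venous_blood"])
#' }
#' @export
simulate_apap <- function(regimen,
                          scenario = scenario_normal(),
                          physiology = default_physiology(),
                          kinetics = default_kinetics(),
                          t_end,
                          solver = solver_settings(),
                          vmax_multipliers = NULL,
                          qss_napqi = FALSE,
                          initial_conc = NULL) {
  stopifnot(inherits(regimen, "apap_regimen"),
            inherits(scenario, "apap_scenario"),
            is.numeric(t_end), t_end > 0)
  model <- .build_model(physiology, kinetics, scenario, vmax_multipliers,
                        qss_napqi)
  n <- model$n_comp
  ev <- expand_regimen(regimen)
  if (nrow(ev) > 0 && max(ev$time_min) >= t_end) {
    stop("t_end must exceed the last dose time", call. = FALSE)
  }

  # Dose events -> concentration jumps in the target compartment.
  jumps <- data.frame(var = character(0), time = numeric(0),
                      value = numeric(0), method = character(0))
  absorbed <- data.frame(time_min = numeric(0), moles_mmol = numeric(0))
  if (nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      dm <- dose_to_moles(ev$time_min[i], ev$amount_g[i], ev$route[i],
                          kinetics)
      tgt <- dm$target
      v_tgt <- model$V[match(tgt, physiology$name)]
      jumps <- rbind(jumps, data.frame(
        var = tgt, time = ev$time_min[i], value = dm$moles_mmol / v_tgt,
        method = "add", stringsAsFactors = FALSE))
      absorbed <- rbind(absorbed, data.frame(time_min = ev$time_min[i],
                                             moles_mmol = dm$moles_mmol))
    }
  }

  y0 <- stats::setNames(numeric(n + 7), model$state_names)
  y0["gsh"] <- kinetics$gsh$gsh_normal_mmol_l * scenario$initial_gsh_fraction
  init_mmol <- 0
  if (!is.null(initial_conc)) {
    stopifnot(!is.null(names(initial_conc)),
              all(names(initial_conc) %in% physiology$name))
    y0[names(initial_conc)] <- initial_conc
    init_mmol <- sum(initial_conc *
                       model$V[match(names(initial_conc), physiology$name)])
  }

  # Fold any t = 0 dose into the initial state; later doses become events.
  at0 <- jumps$time == 0
  if (any(at0)) {
    for (j in which(at0)) y0[jumps$var[j]] <- y0[jumps$var[j]] + jumps$value[j]
    jumps <- jumps[!at0, , drop = FALSE]
  }

  times <- sort(unique(c(seq(0, t_end, by = solver$dt_out), t_end,
                         jumps$time)))
  events <- if (nrow(jumps) > 0) list(data = jumps) else NULL

  out <- deSolve::ode(
    y = y0, times = times, func = model$derivs, parms = NULL,
    method = "lsoda", rtol = solver$rtol, atol = solver$atol,
    hmax = if (is.null(solver$max_step)) Inf else solver$max_step,
    events = events
  )
  istate <- attr(out, "istate")[1]
  if (!is.null(istate) && istate < 0) {
    stop(sprintf("ODE integration failed (istate %d) near t = %g min",
                 istate, max(out[, 1])), call. = FALSE)
  }
  if (nrow(out) < length(times)) {
    stop(sprintf("ODE integration stopped early at t = %g min",
                 out[nrow(out), 1]), call. = FALSE)
  }

  tt <- out[, 1]
  conc <- out[, 1 + seq_len(n), drop = FALSE]
  colnames(conc) <- physiology$name
  # The integrator reports the pre-event state at an event time; the grid
  # contract is the post-dose value, so apply the jump to the reported row.
  if (nrow(jumps) > 0) {
    for (j in seq_len(nrow(jumps))) {
      i_t <- match(jumps$time[j], tt)
      conc[i_t, jumps$var[j]] <- conc[i_t, jumps$var[j]] + jumps$value[j]
    }
  }
  gsh <- out[, 1 + n + 1]
  napqi <- out[, 1 + n + 2]
  cum <- out[, 1 + n + 2 + 1:5, drop = FALSE]
  colnames(cum) <- c("cum_glucuronide", "cum_sulfate", "cum_oxidized",
                     "cum_renal", "cum_gsh_conjugated")
  mods <- out[, 1 + n + 7 + 1:4, drop = FALSE]
  colnames(mods) <- c("co_g", "co_s", "co_ox", "k_gen_mult")

  neg_tol <- 1e-6
  if (min(conc) < -neg_tol || min(gsh) < -neg_tol || min(napqi) < -neg_tol) {
    stop(sprintf(
      "negative concentration excursion beyond tolerance (min %.3e) near t = %g min",
      min(conc, gsh, napqi), tt[which.min(apply(cbind(conc, gsh, napqi), 1, min))]),
      call. = FALSE)
  }
  gmax <- kinetics$gsh$gsh_normal_mmol_l * (1 + 1e-9)
  if (max(gsh) > gmax) {
    stop("GSH exceeded its normal ceiling; regeneration law violated",
         call. = FALSE)
  }

  # Mass balance: absorbed-so-far = sum of compartment amounts (drug-form
  # APAP plus the unconjugated NAPQI pool is counted at oxidation time in
  # cum_oxidized) + cumulative route fluxes.
  absorbed_cum <- init_mmol + vapply(tt, function(t) {
    sum(absorbed$moles_mmol[absorbed$time_min <= t])
  }, numeric(1))
  in_tissue <- as.vector(conc %*% model$V)
  accounted <- in_tissue + cum[, "cum_glucuronide"] + cum[, "cum_sulfate"] +
    cum[, "cum_oxidized"] + cum[, "cum_renal"]
  denom <- pmax(absorbed_cum, max(absorbed_cum) * 1e-3, 1e-12)
  mb_err <- max(abs(accounted - absorbed_cum) / denom)

  structure(list(
    time_min = tt, conc = conc, gsh = gsh, napqi = napqi, cum = cum,
    modifiers = mods,
    absorbed_mmol = sum(absorbed$moles_mmol),
    absorbed_events = absorbed,
    mass_balance_error = mb_err,
    physiology = physiology, kinetics = kinetics, scenario = scenario,
    regimen = regimen, solver = solver,
    vmax_multipliers = vmax_multipliers, qss_napqi = qss_napqi
  ), class = "apap_sim")
}

#' @export
print.apap_sim <- function(x, ...) {
  gn <- x$kinetics$gsh$gsh_normal_mmol_l
  cat(sprintf(
    "APAP PBPK simulation: scenario '%s', %d dose event(s), t = 0..%g min\n",
    x$scenario$name, nrow(x$absorbed_events), max(x$time_min)))
  cat(sprintf("  absorbed dose: %.4g mmol; min liver GSH: %.3g mmol/L (%.1f%% of normal)\n",
              x$absorbed_mmol, min(x$gsh), 100 * min(x$gsh) / gn))
  cat(sprintf("  mass-balance error: %.2e (relative)\n", x$mass_balance_error))
  invisible(x)
}

#' Coerce a simulation to its canonical time-series table
#'
#' @param x An `apap_sim`.
#' @param row.names,optional,... Ignored (base-generic signature).
#' @return A data frame with columns `time_min`, one column per compartment
#'   (mmol/L), `gsh_mmolL`, `napqi_mmolL`, the five `cum_*` fluxes (mmol) and
#'   the four applied modifier traces.
#' @export
as.data.frame.apap_sim <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  df <- data.frame(time_min = x$time_min, x$conc,
                   gsh_mmolL = x$gsh, napqi_mmolL = x$napqi,
                   x$cum, x$modifiers, check.names = FALSE)
  rownames(df) <- NULL
  df
}

#' One-compartment analytic reference model
#'
#' A single well-stirred blood pool with first-order (fixed-extraction)
#' elimination, integrated through the same adaptive solver configuration as
#' the full model. Its closed form is `C(t) = C0 exp(-CL/V t)`, which makes
#' it the analytic oracle for the solver and event machinery.
#'
#' @param volume_l Pool volume, L.
#' @param clearance_l_min Clearance `E * Q`, L/min.
#' @param dose_mmol Bolus at t = 0, mmol.
#' @param t_end End time, minutes.
#' @param solver An [solver_settings()] object.
#' @return A data frame with `time_min` and `conc` (mmol/L).
#' @export
simulate_one_compartment <- function(volume_l, clearance_l_min, dose_mmol,
                                     t_end, solver = solver_settings()) {
  stopifnot(volume_l > 0, clearance_l_min >= 0, t_end > 0)
  derivs <- function(t, y, p) list(-clearance_l_min / volume_l * y)
  times <- seq(0, t_end, by = solver$dt_out)
  out <- deSolve::ode(y = c(conc = dose_mmol / volume_l), times = times,
                      func = derivs, parms = NULL, method = "lsoda",
                      rtol = solver$rtol, atol = solver$atol)
  data.frame(time_min = out[, 1], conc = out[, 2])
}

#' Fixed-step explicit reference integrator
#'
#' A naive fixed-step second-order (midpoint) explicit integrator over the
#' same derivative field as [simulate_apap()], used as a brute-force oracle
#' for the adaptive solver. Only meaningful with `qss_napqi = TRUE` (the
#' explicit scheme cannot take the stiff bimolecular conjugation at practical
#' step sizes; the stiff pair is cross-checked separately via the
#' QSS-vs-full agreement).
#'
#' @inheritParams simulate_apap
#' @param dt Fixed step, minutes.
#' @param record_every Store the state every this many steps.
#' @return A matrix with a `time_min` column followed by all state variables.
#' @export
simulate_fixed_step <- function(regimen,
                                scenario = scenario_normal(),
                                physiology = default_physiology(),
                                kinetics = default_kinetics(),
                                t_end, dt = 0.001, record_every = 1000,
                                vmax_multipliers = NULL,
                                qss_napqi = TRUE) {
  model <- .build_model(physiology, kinetics, scenario, vmax_multipliers,
                        qss_napqi)
  n <- model$n_comp
  ev <- expand_regimen(regimen)
  y <- stats::setNames(numeric(n + 7), model$state_names)
  y["gsh"] <- kinetics$gsh$gsh_normal_mmol_l * scenario$initial_gsh_fraction
  if (nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      if (ev$time_min[i] != 0) {
        stop("simulate_fixed_step supports t = 0 doses only", call. = FALSE)
      }
      dm <- dose_to_moles(ev$time_min[i], ev$amount_g[i], ev$route[i],
                          kinetics)
      v_tgt <- model$V[match(dm$target, physiology$name)]
      y[dm$target] <- y[dm$target] + dm$moles_mmol / v_tgt
    }
  }
  f <- model$derivs
  n_steps <- ceiling(t_end / dt)
  keep <- seq(0, n_steps, by = record_every)
  rec <- matrix(NA_real_, nrow = length(keep), ncol = length(y) + 1,
                dimnames = list(NULL, c("time_min", names(y))))
  ki <- 1L
  t <- 0
  for (s in seq_len(n_steps + 1) - 1L) {
    if (ki <= length(keep) && s == keep[ki]) {
      rec[ki, ] <- c(t, y)
      ki <- ki + 1L
    }
    if (s == n_steps) break
    k1 <- f(t, y, NULL)[[1]]
    k2 <- f(t + dt / 2, y + dt / 2 * k1, NULL)[[1]]
    y <- y + dt * k2
    t <- (s + 1) * dt
  }
  rec
}
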