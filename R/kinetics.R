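# Kinetic constants: three hepatic Michaelis-Menten pathways, renal
# extraction, the GSH/NAPQI sub-model, and every scenario coefficient.
# Internal unit system is {mmol, mL -> L at model build, min}; pathway Vmax
# values are stored as tabulated (mmol per hour per kg body weight) and
# converted once at model build time via vmax * body_weight / 60.

#' Default kinetic parameters
#'
#' Returns the packaged kinetic constants for APAP metabolism and the hepatic
#' GSH/NAPQI toxicity sub-model:
#'
#' * three saturable hepatic pathways (Vmax in mmol/(hr kg body weight), Km in
#'   mmol/L): glucuronidation (0.97, 6.89), sulfation (0.011, 0.097) and
#'   CYP-mediated oxidation to NAPQI (0.035, 0.28);
#' * renal extraction ratio E = 0.02 and oral bioavailability F = 0.79;
#' * GSH sub-model: regeneration coefficient `k_gen` = 0.0026 per min,
#'   bimolecular NAPQI-GSH conjugation constant `k_ii` = 1.92e6 mL/(mmol min),
#'   the normal hepatic GSH concentration `gsh_normal` (the packaged value is
#'   the output of [calibrate_baseline()], which anchors a single 15 g oral
#'   dose to ~70% peak GSH depletion), and the 30%-of-normal toxicity
#'   threshold;
#' * scenario constants: chronic-intake glucuronidation/sulfation maxima per
#'   dose tier (1 g: 1.5/0.5; >= 2 g: 2.25/0.3) ramped over 4320 min, the
#'   2.14-fold alcohol CYP2E1 induction decaying over 7200 min, the halved
#'   alcoholic GSH pool recovering over 1440 min, and the fasting multipliers
#'   (glucuronidation 0.6, sulfation 0.7, oxidation 1.5, GSH pool 0.75,
#'   regeneration 0.75).
#'
#' @return An object of class `apap_kinetics` (a nested list; see Details in
#'   the package vignette for the full schema).
#' @seealso [validate_kinetics()], [calibrate_baseline()]
#' @export
default_kinetics <- function() {
  k <- list(
    pathways = data.frame(
      name = c("glucuronidation", "sulfation", "oxidation"),
      vmax_mmol_hr_kg = c(0.97, 0.011, 0.035),
      km_mmol_l = c(6.89, 0.097, 0.28),
      stringsAsFactors = FALSE
    ),
    renal_extraction = 0.02,
    oral_bioavailability = 0.79,
    apap_molar_mass_g_mol = 151.16,
    gsh = list(
      k_gen_per_min = 0.0026,
      k_ii_ml_mmol_min = 1.92e6,
      # Calibrated so that a single 15 g oral dose depletes liver GSH to 30%
      # of normal (see calibrate_baseline()).
      gsh_normal_mmol_l = 5.0701446533203125,
      toxicity_fraction = 0.30
    ),
    scenario_constants = list(
      chronic_tiers = data.frame(
        dose_g = c(1, 2),
        co_g_max = c(1.5, 2.25),
        co_s_max = c(0.5, 0.3),
        stringsAsFactors = FALSE
      ),
      alcohol_cyp_factor = 2.14,
      alcohol_gsh_fraction = 0.5,
      fasting = list(
        co_g = 0.6,
        co_s = 0.7,
        co_ox = 1.5,
        gsh_fraction = 0.75,
        k_gen_fraction = 0.75
      ),
      ramp_chronic_min = 4320,
      ramp_alcohol_cyp_min = 7200,
      ramp_alcohol_gsh_min = 1440
    )
  )
  class(k) <- "apap_kinetics"
  k
}

#' Validate a kinetic parameter set
#'
#' @param kinetics An `apap_kinetics` object as returned by
#'   [default_kinetics()] (possibly with overridden values).
#' @return A character vector of violation descriptions; empty when valid.
#' @export
validate_kinetics <- function(kinetics) {
  out <- character(0)
  k <- kinetics
  req <- c("pathways", "renal_extraction", "oral_bioavailability",
           "apap_molar_mass_g_mol", "gsh", "scenario_constants")
  if (!is.list(k) || !all(req %in% names(k))) {
    return(sprintf("kinetics must be a list with components %s",
                   paste(req, collapse = ", ")))
  }
  pw <- k$pathways
  if (!is.data.frame(pw) ||
        !setequal(pw$name, c("glucuronidation", "sulfation", "oxidation"))) {
    out <- c(out, "pathways must contain exactly glucuronidation, sulfation, oxidation")
  } else {
    if (any(pw$vmax_mmol_hr_kg <= 0)) out <- c(out, "pathway vmax must be > 0")
    if (any(pw$km_mmol_l <= 0)) out <- c(out, "pathway km must be > 0")
  }
  frac_in <- function(x, lo = 0, hi = 3) is.numeric(x) && is.finite(x) &&
    x > lo && x <= hi
  if (!frac_in(k$renal_extraction, 0, 1)) {
    out <- c(out, "renal_extraction must be in (0, 1]")
  }
  if (!frac_in(k$oral_bioavailability, 0, 1)) {
    out <- c(out, "oral_bioavailability must be in (0, 1]")
  }
  if (!is.numeric(k$apap_molar_mass_g_mol) || k$apap_molar_mass_g_mol <= 0) {
    out <- c(out, "apap_molar_mass_g_mol must be > 0")
  }
  g <- k$gsh
  for (nm in c("k_gen_per_min", "k_ii_ml_mmol_min", "gsh_normal_mmol_l")) {
    if (!is.numeric(g[[nm]]) || !is.finite(g[[nm]]) || g[[nm]] <= 0) {
      out <- c(out, sprintf("gsh$%s must be > 0", nm))
    }
  }
  if (!is.numeric(g$toxicity_fraction) || g$toxicity_fraction <= 0 ||
        g$toxicity_fraction >= 1) {
    out <- c(out, "gsh$toxicity_fraction must be in (0, 1)")
  }
  sc <- k$scenario_constants
  tiers <- sc$chronic_tiers
  if (!is.data.frame(tiers) || nrow(tiers) < 1 ||
        !all(c("dose_g", "co_g_max", "co_s_max") %in% names(tiers))) {
    out <- c(out, "scenario_constants$chronic_tiers must tabulate dose_g, co_g_max, co_s_max")
  } else if (any(tiers$co_g_max <= 0 | tiers$co_g_max > 3) ||
               any(tiers$co_s_max <= 0 | tiers$co_s_max > 3)) {
    out <- c(out, "chronic tier multipliers must be in (0, 3]")
  }
  for (nm in c("alcohol_cyp_factor", "alcohol_gsh_fraction")) {
    if (!frac_in(sc[[nm]])) out <- c(out, sprintf("%s must be in (0, 3]", nm))
  }
  for (nm in c("co_g", "co_s", "co_ox", "gsh_fraction", "k_gen_fraction")) {
    if (!frac_in(sc$fasting[[nm]])) {
      out <- c(out, sprintf("fasting$%s must be in (0, 3]", nm))
    }
  }
  for (nm in c("ramp_chronic_min", "ramp_alcohol_cyp_min",
               "ramp_alcohol_gsh_min")) {
    if (!is.numeric(sc[[nm]]) || sc[[nm]] <= 0) {
      out <- c(out, sprintf("%s must be > 0", nm))
    }
  }
  out
}

#' @export
print.apap_kinetics <- function(x, ...) {
  cat("APAP kinetic parameters\n")
  cat("  Hepatic Michaelis-Menten pathways (Vmax mmol/(hr kg), Km mmol/L):\n")
  for (i in seq_len(nrow(x$pathways))) {
    cat(sprintf("    %-15s Vmax %-7g Km %g\n", x$pathways$name[i],
                x$pathways$vmax_mmol_hr_kg[i], x$pathways$km_mmol_l[i]))
  }
  cat(sprintf("  Renal extraction E = %g, oral bioavailability F = %g\n",
              x$renal_extraction, x$oral_bioavailability))
  cat(sprintf("  GSH: k_gen %g /min, k_II %g mL/(mmol min), normal %g mmol/L, toxicity threshold %g\n",
              x$gsh$k_gen_per_min, x$gsh$k_ii_ml_mmol_min,
              x$gsh$gsh_normal_mmol_l, x$gsh$toxicity_fraction))
  invisible(x)
}

# Internal: look up one pathway row as a list(vmax, km).
.pathway <- function(kinetics, name) {
  i <- match(name, kinetics$pathways$name)
  if (is.na(i)) stop("unknown metabolic pathway: ", name, call. = FALSE)
  list(name = name,
       vmax_mmol_hr_kg = kinetics$pathways$vmax_mmol_hr_kg[i],
       km_mmol_l = kinetics$pathways$km_mmol_l[i])
}
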