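# Physiological and kinetic parameter sets: tabulated defaults, invariants,
# validation, and configuration round trips.

test_that("default physiology matches the reference organ table", {
  phys <- default_physiology()
  expect_s3_class(phys, "apap_physiology")
  expect_identical(nrow(phys), 14L)
  expect_identical(attr(phys, "body_weight_kg"), 70)
  expect_identical(attr(phys, "blood_plasma_ratio"), 1)

  expected <- list(
    #                 volume  flow     Kp
    adipose        = c(8372,  325,  0.312),
    bone           = c(5992,  325,  0.682),
    brain          = c(1400,  780,  1.05),
    gut            = c(1197, 1105,  0.92),
    heart          = c(329,   260,  0.852),
    kidney         = c(308,  1235,  0.906),
    liver          = c(1799, 1625,  0.93),
    lung           = c(532,  6500,  0.87),
    muscle         = c(28000, 1105, 0.88),
    rest_of_body   = c(13895, 520,  1),
    skin           = c(2597,  325,  0.853),
    spleen         = c(182,   130,  0.915),
    arterial_blood = c(1799, 6500,  1),
    venous_blood   = c(3598, 6500,  1)
  )
  for (nm in names(expected)) {
    row <- phys[phys$name == nm, ]
    expect_identical(nrow(row), 1L, info = nm)
    expect_identical(row$volume_ml, expected[[nm]][1], info = nm)
    expect_identical(row$blood_flow_ml_min, expected[[nm]][2], info = nm)
    expect_identical(row$partition_coefficient, expected[[nm]][3], info = nm)
  }
})

test_that("portal topology conserves flow: 390 mL/min hepatic artery, 6500 mL/min venous return", {
  phys <- default_physiology()
  q <- function(nm) phys$blood_flow_ml_min[phys$name == nm]
  expect_equal(q("liver") - q("gut") - q("spleen"), 390)
  systemic <- c("adipose", "bone", "brain", "heart", "kidney", "liver",
                "muscle", "rest_of_body", "skin")
  expect_identical(sum(vapply(systemic, q, numeric(1))), q("lung"))
  expect_identical(q("lung"), 6500)
})

test_that("default kinetics match the reference constants table", {
  k <- default_kinetics()
  expect_length(validate_kinetics(k), 0)
  pw <- k$pathways
  expect_identical(pw$vmax_mmol_hr_kg[match("glucuronidation", pw$name)], 0.97)
  expect_identical(pw$km_mmol_l[match("glucuronidation", pw$name)], 6.89)
  expect_identical(pw$vmax_mmol_hr_kg[match("sulfation", pw$name)], 0.011)
  expect_identical(pw$km_mmol_l[match("sulfation", pw$name)], 0.097)
  expect_identical(pw$vmax_mmol_hr_kg[match("oxidation", pw$name)], 0.035)
  expect_identical(pw$km_mmol_l[match("oxidation", pw$name)], 0.28)
  expect_identical(k$renal_extraction, 0.02)
  expect_identical(k$oral_bioavailability, 0.79)
  expect_identical(k$apap_molar_mass_g_mol, 151.16)
  expect_identical(k$gsh$k_gen_per_min, 0.0026)
  expect_identical(k$gsh$k_ii_ml_mmol_min, 1.92e6)
  expect_identical(k$gsh$toxicity_fraction, 0.30)
  sc <- k$scenario_constants
  expect_identical(sc$chronic_tiers$co_g_max, c(1.5, 2.25))
  expect_identical(sc$chronic_tiers$co_s_max, c(0.5, 0.3))
  expect_identical(sc$alcohol_cyp_factor, 2.14)
  expect_identical(sc$alcohol_gsh_fraction, 0.5)
  expect_identical(sc$fasting$co_g, 0.6)
  expect_identical(sc$fasting$co_s, 0.7)
  expect_identical(sc$fasting$co_ox, 1.5)
  expect_identical(sc$fasting$gsh_fraction, 0.75)
  expect_identical(sc$ramp_chronic_min, 4320)
  expect_identical(sc$ramp_alcohol_cyp_min, 7200)
  expect_identical(sc$ramp_alcohol_gsh_min, 1440)
})

test_that("validate_physiology flags broken flow topologies, not valid ones", {
  expect_length(validate_physiology(default_physiology()), 0)

  # gut flow 2000 makes the hepatic artery negative
  p <- default_physiology()
  p$blood_flow_ml_min[p$name == "gut"] <- 2000
  v <- validate_physiology(p)
  expect_true(any(grepl("hepatic arterial flow", v)))

  # muscle flow + 1 breaks venous-return/cardiac-output balance
  p <- default_physiology()
  p$blood_flow_ml_min[p$name == "muscle"] <-
    p$blood_flow_ml_min[p$name == "muscle"] + 1
  v <- validate_physiology(p)
  expect_true(any(grepl("venous return", v)))

  # structural violations
  p <- default_physiology()
  p$volume_ml[1] <- -1
  expect_true(any(grepl("volumes", validate_physiology(p))))
  p <- default_physiology()
  p$role[p$name == "kidney"] <- "non-eliminating"
  expect_true(any(grepl("kidney", validate_physiology(p))))
})

test_that("validate_kinetics flags out-of-range constants", {
  k <- default_kinetics()
  k$gsh$toxicity_fraction <- 1.2
  expect_true(any(grepl("toxicity_fraction", validate_kinetics(k))))
  k <- default_kinetics()
  k$pathways$vmax_mmol_hr_kg[1] <- 0
  expect_true(any(grepl("vmax", validate_kinetics(k))))
  k <- default_kinetics()
  k$oral_bioavailability <- 1.5
  expect_true(any(grepl("bioavailability", validate_kinetics(k))))
})

test_that("configuration round trip through YAML is bit-exact", {
  cfg <- list(
    regimen = list(dose_g = 1.23456789012345, interval_min = 360,
                   n_doses = 5, route = "oral"),
    scenario = list(name = "chronic", dose_g = 2),
    t_end = 4321,
    solver = list(rtol = 1e-8, atol = 1.234567890123456e-10, dt_out = 0.5),
    kinetics = list(
      gsh = list(k_gen_per_min = 0.002600000000000001,
                 gsh_normal_mmol_l = pi),
      pathways = list(vmax_mmol_hr_kg = c(0.97, 0.011, 0.035 * (1 + 1e-15)))
    )
  )
  path <- tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_identical(back$regimen$dose_g, cfg$regimen$dose_g)
  expect_identical(back$solver$atol, cfg$solver$atol)
  expect_identical(back$kinetics$gsh$k_gen_per_min,
                   cfg$kinetics$gsh$k_gen_per_min)
  expect_identical(back$kinetics$gsh$gsh_normal_mmol_l, pi)
  expect_identical(back$kinetics$pathways$vmax_mmol_hr_kg,
                   cfg$kinetics$pathways$vmax_mmol_hr_kg)
  unlink(path)
})

test_that("resolved config overrides land in the right parameter slots and unknown keys error", {
  r <- resolve_run_config(list(
    regimen = list(dose_g = 2, n_doses = 3),
    scenario = list(name = "chronic"),
    t_end = 2000,
    kinetics = list(gsh = list(k_gen_per_min = 0.001)),
    physiology = list(liver = list(volume_ml = 1800))
  ))
  expect_identical(r$kinetics$gsh$k_gen_per_min, 0.001)
  expect_identical(r$physiology$volume_ml[r$physiology$name == "liver"], 1800)
  expect_identical(nrow(expand_regimen(r$regimen)), 3L)
  expect_identical(r$scenario$name, "chronic-2g")

  expect_error(resolve_run_config(list(nonsense = 1)), "unknown configuration key")
  expect_error(resolve_run_config(list(kinetics = list(gsh = list(bogus = 1)))),
               "bogus")
  expect_error(resolve_run_config(list(physiology = list(pancreas = list(volume_ml = 1)))),
               "pancreas")
})
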