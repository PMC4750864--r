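# The ODE system: rate primitives, conservation laws, solver cross-checks.

test_that("tissue derivative obeys perfusion-limited mass balance", {
  phys <- default_physiology()
  adipose <- phys[phys$name == "adipose", ]
  # perfusion equilibrium: inflow equals outflow concentration
  expect_equal(tissue_derivative(0.312 * 2, 2, adipose), 0, tolerance = 1e-12)
  # influx only
  expect_equal(tissue_derivative(0, 1, adipose), 325 / 8372,
               tolerance = 1e-12)
  # elimination subtracts from the balance
  liver <- phys[phys$name == "liver", ]
  d0 <- tissue_derivative(0.93, 1, liver)
  d1 <- tissue_derivative(0.93, 1, liver, elimination_mmol_min = 0.5)
  expect_equal(d0 - d1, 0.5 / 1.799, tolerance = 1e-12)
})

test_that("liver inflow is the portal flow-weighted mixture", {
  phys <- default_physiology()
  # equal outflow concentrations pass through unchanged
  expect_equal(liver_inflow_concentration(1, 0.92, 0.915, phys), 1,
               tolerance = 1e-12)
  # arterial-only contribution is Q_ha / Q_liver
  expect_equal(liver_inflow_concentration(1, 0, 0, phys), 390 / 1625,
               tolerance = 1e-12)
  expect_identical(liver_inflow_concentration(0, 0, 0, phys), 0)
})

test_that("Michaelis-Menten rates saturate at body-weight-scaled Vmax", {
  expect_identical(michaelis_menten_rate(0, "glucuronidation"), 0)
  # at c = Km the rate is half the per-minute Vmax
  expect_equal(michaelis_menten_rate(6.89, "glucuronidation"),
               0.97 * 70 / 60 / 2, tolerance = 1e-12)
  # multiplier scales the asymptote: 2.14x oxidation far above Km
  expect_equal(michaelis_menten_rate(1000, "oxidation", multiplier = 2.14),
               2.14 * 0.035 * 70 / 60, tolerance = 1e-3)
  expect_error(michaelis_menten_rate(1, "oxidation", multiplier = -1))
})

test_that("renal elimination is linear in the arterial concentration", {
  expect_identical(renal_elimination_rate(0), 0)
  expect_equal(renal_elimination_rate(1), 0.02 * 1.235, tolerance = 1e-12)
  expect_equal(renal_elimination_rate(2), 2 * renal_elimination_rate(1),
               tolerance = 1e-12)
})

test_that("GSH and NAPQI balances have the stated fixed points", {
  k <- default_kinetics()
  gn <- k$gsh$gsh_normal_mmol_l
  # resting steady state
  expect_identical(gsh_derivative(gn, 0, k), 0)
  # half-depleted, no NAPQI: pure deficit-proportional regeneration
  expect_equal(gsh_derivative(gn / 2, 0, k), 0.0026 * gn / 2,
               tolerance = 1e-12)
  # exhausted pool: conjugation term vanishes, regeneration is maximal
  expect_equal(gsh_derivative(0, 5, k), 0.0026 * gn, tolerance = 1e-12)
  # NAPQI quasi-steady state zeroes its derivative
  v_ox <- 0.02; v_liv <- 1.799; gsh <- 3
  napqi_star <- v_ox / (v_liv * (k$gsh$k_ii_ml_mmol_min / 1000) * gsh)
  expect_equal(napqi_derivative(napqi_star, gsh, v_ox, v_liv, k), 0,
               tolerance = 1e-15)
  expect_identical(napqi_derivative(0, 3, 0, 1.799, k), 0)
})

test_that("zero-dose simulations stay drug-free with resting GSH", {
  sim <- simulate_apap(apap_regimen(0, n_doses = 1), t_end = 720,
                       solver = solver_settings(dt_out = 10))
  expect_true(all(sim$conc == 0))
  expect_equal(max(abs(sim$gsh - sim$kinetics$gsh$gsh_normal_mmol_l)), 0,
               tolerance = 1e-10)
  expect_true(all(sim$cum == 0))
})

test_that("mass balance holds to 1e-6 across routes, regimens and scenarios", {
  runs <- list(
    simulate_apap(apap_regimen(1, route = "iv"), t_end = 480),
    sim_oral_1g(),
    simulate_apap(apap_regimen(2, 360, 3, "oral"), fasting_modifiers(),
                  t_end = 1500, solver = solver_settings(dt_out = 5)),
    simulate_apap(apap_regimen(4, route = "oral"), alcohol_schedule(),
                  t_end = 1440, solver = solver_settings(dt_out = 5))
  )
  for (sim in runs) expect_lt(sim$mass_balance_error, 1e-6)
})

test_that("cumulative fluxes are non-decreasing and concentrations non-negative", {
  sim <- sim_oral_1g()
  expect_true(all(diff(sim$cum[, "cum_glucuronide"]) >= -1e-12))
  expect_true(all(diff(sim$cum[, "cum_oxidized"]) >= -1e-12))
  expect_true(all(diff(sim$cum[, "cum_renal"]) >= -1e-12))
  expect_true(all(sim$conc >= -1e-9))
  expect_true(all(sim$gsh >= 0))
})

test_that("GSH never exceeds its normal ceiling (structural regeneration law)", {
  gn <- default_kinetics()$gsh$gsh_normal_mmol_l
  # recovery from a halved pool climbs toward, but never above, normal
  sim <- simulate_apap(apap_regimen(0, n_doses = 1), alcohol_schedule(),
                       t_end = 7200, solver = solver_settings(dt_out = 10))
  expect_lte(max(sim$gsh), gn * (1 + 1e-9))
  expect_gt(sim$gsh[length(sim$gsh)], 0.95 * gn) # recovered
  expect_lte(max(sim_oral_1g()$gsh), gn * (1 + 1e-9))
})

test_that("a constant-equilibrium state is a fixed point (flow conservation)", {
  k <- default_kinetics()
  k$renal_extraction <- 1e-12
  p <- default_physiology()
  eq <- stats::setNames(p$partition_coefficient, p$name)
  sim <- simulate_apap(apap_regimen(0, n_doses = 1), kinetics = k,
                       t_end = 1440, solver = solver_settings(dt_out = 30),
                       vmax_multipliers = c(glucuronidation = 0,
                                            sulfation = 0, oxidation = 0),
                       initial_conc = eq)
  expect_lt(max(abs(sweep(sim$conc, 2, eq))), 1e-8)
})

test_that("one-compartment solve matches the closed-form exponential to 1e-6", {
  cfg <- generate_fixture("toy-one-compartment")
  oc <- run_config(cfg)
  p <- cfg$one_compartment
  analytic <- p$dose_mmol / p$volume_l *
    exp(-p$clearance_l_min / p$volume_l * oc$time_min)
  expect_lt(max(abs(oc$conc - analytic) / analytic), 1e-6)
})

test_that("a naive fixed-step integrator reproduces the adaptive solution", {
  # short-horizon cross-check; the full 6 h / dt = 0.001 oracle runs with the
  # acceptance suite
  bf <- simulate_fixed_step(apap_regimen(1, route = "oral"), t_end = 90,
                            dt = 0.005, record_every = 6000)
  ad <- simulate_apap(apap_regimen(1, route = "oral"), t_end = 90,
                      qss_napqi = TRUE, solver = solver_settings(dt_out = 30))
  df <- as.data.frame(ad)
  names(df)[names(df) == "gsh_mmolL"] <- "gsh"
  idx <- vapply(bf[, "time_min"],
                function(t) which.min(abs(df$time_min - t)), integer(1))
  cols <- setdiff(colnames(bf), c("time_min", "napqi"))
  for (cn in cols) {
    ref <- df[idx, cn]
    sc <- pmax(abs(ref), max(abs(ref)) * 1e-3, 1e-12)
    expect_lt(max(abs(bf[, cn] - ref) / sc), 1e-3)
  }
})

test_that("quasi-steady-state NAPQI closure agrees with the stiff system", {
  full <- sim_oral_1g()
  qss <- simulate_apap(apap_regimen(1, route = "oral"), t_end = 1440,
                       qss_napqi = TRUE)
  expect_lt(abs(gsh_demand_auc(full) - gsh_demand_auc(qss)) /
              gsh_demand_auc(full), 1e-3)
  expect_lt(max(abs(full$gsh - qss$gsh)) / min(full$gsh), 1e-3)
})

test_that("minimum GSH decreases strictly with the oxidation multiplier", {
  mins <- vapply(c(1, 3, 10), function(m) {
    min(simulate_apap(apap_regimen(1, route = "oral"), t_end = 1440,
                      solver = solver_settings(dt_out = 5),
                      vmax_multipliers = c(oxidation = m))$gsh)
  }, numeric(1))
  expect_true(all(diff(mins) < 0))
})

test_that("dose grid points carry the post-dose state", {
  sim <- simulate_apap(apap_regimen(1, 360, 2, "iv"), t_end = 720,
                       solver = solver_settings(dt_out = 5))
  i <- match(360, sim$time_min)
  # venous concentration jumps by dose/V at the dose time
  jump <- 1000 / 151.16 / 3.598
  expect_gt(sim$conc[i, "venous_blood"],
            sim$conc[i - 1, "venous_blood"] + 0.9 * jump)
})

test_that("simulation input errors are caught", {
  expect_error(simulate_apap(apap_regimen(1, 360, 3, "oral"), t_end = 700),
               "t_end")
  p <- default_physiology()
  p$blood_flow_ml_min[p$name == "gut"] <- 2000
  expect_error(simulate_apap(apap_regimen(1, route = "iv"), physiology = p,
                             t_end = 100),
               "invalid physiology")
  k <- default_kinetics()
  k$gsh$k_gen_per_min <- -1
  expect_error(simulate_apap(apap_regimen(1, route = "iv"), kinetics = k,
                             t_end = 100),
               "invalid kinetics")
})
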