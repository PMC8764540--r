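test_that("built-in archetypes carry the published endpoint values", {
  a <- builtin_archetypes()
  expect_equal(a$KT2440$final_pha_pct, 71.7)
  expect_equal(a$KT2440$growth_rate, 0.31)
  expect_equal(a$KT40Z$final_ha, 0.0)
  expect_equal(a$KT2440_dpha$final_viable_cells, 22.3)
  expect_equal(a$M4$growth_rate, 0.35)
  expect_equal(a$M4$final_total_biomass, 0.5)
  expect_equal(a$M4$final_ha, 0.5)
  for (arch in a) {
    expect_true(all(arch$pha_phase_weights >= 0))
    expect_equal(sum(arch$pha_phase_weights), 1)
    expect_equal(arch$octanoate_initial, 15)  # 15 mM feed
  }
})

test_that("noise-free generation reproduces the endpoint table", {
  for (nm in c("KT2440", "KT40Z", "M4")) {
    arch <- builtin_archetypes()[[nm]]
    arch$noise_cv <- 0
    tc <- make_strain_timecourse(arch, seed = 1)
    n <- length(tc$times)
    expect_equal(tc$total_biomass[n], arch$final_total_biomass,
                 tolerance = 0.01, label = paste(nm, "total biomass"))
    expect_equal(tc$pha_pct_cdw[n], arch$final_pha_pct,
                 tolerance = 0.011 * max(arch$final_pha_pct, 1))
    expect_equal(tc$ha_conc[n], arch$final_ha, tolerance = 0.01)
    expect_lt(tc$octanoate[n], 1e-9)  # feed exhausted at 24 h
    ## inoculum in the published 0.08-0.09 g/L window
    res0 <- residual_biomass(tc$total_biomass[1], tc$pha_pct_cdw[1])$residual
    expect_gte(res0, 0.08)
    expect_lte(res0, 0.09)
  }
})

test_that("generation is deterministic per seed and noisy across seeds", {
  arch <- builtin_archetypes()$M2
  t1 <- make_strain_timecourse(arch, seed = 5)
  t2 <- make_strain_timecourse(arch, seed = 5)
  t3 <- make_strain_timecourse(arch, seed = 6)
  expect_identical(t1$total_biomass, t2$total_biomass)
  expect_identical(t1$octanoate, t2$octanoate)
  expect_false(identical(t1$total_biomass, t3$total_biomass))
  ## generator must not disturb the caller's RNG stream
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(make_strain_timecourse(arch, seed = 7))
  expect_identical(stats::runif(1), before)
})

test_that("generated carbon bookkeeping closes at every time point", {
  c_bio <- core_biomass_carbon()
  mm <- monomer_mass_table()
  for (nm in names(builtin_archetypes())) {
    arch <- builtin_archetypes()[[nm]]
    arch$noise_cv <- 0
    tc <- make_strain_timecourse(arch, seed = 1)
    res <- residual_biomass(tc$total_biomass, tc$pha_pct_cdw)
    consumedC <- (tc$octanoate[1] - tc$octanoate) * 8 * 0.012011
    productC <- (res$residual - res$residual[1]) * c_bio +
      res$pha_conc * 8 * 0.012011 / mm$pha_repeat_unit +
      tc$ha_conc * 8 * 0.012011 / mm$ha_free_acid
    ## implied CO2 channel is non-negative throughout
    expect_true(all(consumedC - productC >= -1e-9), label = nm)
  }
})

test_that("growth-rate recovery closes the generator/estimator loop", {
  ## noise-free: exact recovery for every archetype
  for (nm in names(builtin_archetypes())) {
    arch <- builtin_archetypes()[[nm]]
    arch$noise_cv <- 0
    tc <- make_strain_timecourse(arch, seed = 1)
    mu <- compute_growth_rate(tc, segment_phases(tc)[[1]])
    expect_equal(mu, arch$growth_rate, tolerance = 1e-6, label = nm)
  }
  ## with measurement noise: recovery within a noise-scaled tolerance
  arch <- builtin_archetypes()$KT2440
  errs <- vapply(1:20, function(sd) {
    tc <- make_strain_timecourse(arch, seed = sd)
    compute_growth_rate(tc, segment_phases(tc)[[1]]) - 0.31
  }, numeric(1))
  expect_lt(stats::median(abs(errs)), 0.02)
})

test_that("od570 channel inverts back to the archetype CO2 fold", {
  folds <- vapply(c("KT2440", "M2", "M3", "M4"), function(nm) {
    arch <- builtin_archetypes()[[nm]]
    tc <- make_strain_timecourse(arch, seed = 1)
    od <- tc$od570[length(tc$times)]
    microresp_percent_co2(od)
  }, numeric(1))
  rel <- relative_co2(folds, "KT2440")
  expect_equal(unname(rel[c("M2", "M3", "M4")]), c(2.8, 3.2, 3.6),
               tolerance = 1e-6)
})

test_that("toy models match their documented optima", {
  expect_equal(fba(make_toy_model("chain"))$objective_value, 5,
               tolerance = 1e-9)
  expect_equal(fba(make_toy_model("interval"))$objective_value, 10,
               tolerance = 1e-9)
  expect_error(make_toy_model("nope"))
})

test_that("core model is balanced, feasible and biologically oriented", {
  m <- core_model_fixture()
  expect_identical(check_mass_balance(m), character(0))
  sol <- fba(set_bounds(m, "EX_octa_e", lb = -3.8))
  expect_identical(sol$status, "optimal")
  expect_gt(sol$objective_value, 0)
  ## oxygen consumed, CO2 produced
  expect_lt(sol$fluxes[["EX_o2_e"]], 0)
  expect_gt(sol$fluxes[["EX_co2_e"]], 0)
  ## declared biomass carbon matches the stoichiometric drain
  S <- stoichiometric_matrix(m)
  carbons <- vapply(m$metabolites$formula, function(f) {
    cnt <- phaflux:::parse_formula(f)
    if ("C" %in% names(cnt)) cnt[["C"]] else 0
  }, numeric(1))
  drain <- -sum(S[, "BIOMASS_core"] * carbons) * 0.012011
  expect_equal(core_biomass_carbon(), drain, tolerance = 1e-9)
})
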