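test_that("phase rates reproduce hand-computed values on a two-point course", {
  ## residual biomass 0.2 -> 0.4 over 5 h; PHA 0 -> 0.2844 g/L (2 mmol/L of
  ## the 0.14220 g/mmol repeat unit); HA 0 -> 0.16021 g/L (1 mmol/L);
  ## octanoate 10 -> 4 mM
  tc <- physio_timecourse("hand", c(0, 5),
                          total_biomass = c(0.2, 0.4 + 0.2844),
                          pha_pct_cdw = c(0, 100 * 0.2844 / (0.4 + 0.2844)),
                          ha_conc = c(0, 0.16021),
                          octanoate = c(10, 4))
  ph <- growth_phase("I", 0, 5, closed_end = TRUE)
  r <- build_phase_rates(tc, ph)
  xbar <- (0.2 + 0.4) / 2
  expect_equal(r$growth_rate, log(2) / 5, tolerance = 1e-9)
  expect_equal(r$octanoate_uptake, 6 / (5 * xbar), tolerance = 1e-9)
  expect_equal(r$pha_production, 2 / (5 * xbar), tolerance = 1e-6)
  expect_equal(r$ha_secretion, 1 / (5 * xbar), tolerance = 1e-6)
  expect_equal(r$initial_residual_biomass, 0.2, tolerance = 1e-9)
  expect_equal(r$mu_integrated, log(2) / 5, tolerance = 1e-9)
})

test_that("flat course yields all-zero rates", {
  tc <- physio_timecourse("flat", c(0, 5, 10),
                          total_biomass = rep(0.4, 3),
                          pha_pct_cdw = rep(0, 3), ha_conc = rep(0, 3),
                          octanoate = rep(5, 3))
  r <- build_phase_rates(tc, growth_phase("I", 0, 5, closed_end = TRUE))
  expect_equal(r$growth_rate, 0)
  expect_equal(r$octanoate_uptake, 0)
  expect_equal(r$pha_production, 0)
  expect_equal(r$ha_secretion, 0)
})

test_that("synthetic wild type recovers the published phase-I physiology", {
  tc <- noiseless_tc("KT2440")
  r <- build_phase_rates(tc, segment_phases(tc)[[1]])
  expect_equal(r$growth_rate, 0.31, tolerance = 1e-6)
  expect_gt(r$octanoate_uptake, 0)
})

test_that("fully clamped zero-rate model has FBA objective zero", {
  m <- make_toy_model("pha_mini")
  ph <- growth_phase("I", 0, 5)
  r <- phase_rates(ph, 0, 0, 0, 0, 0.1)
  cm <- apply_phase_constraints(
    m, r, tolerance = 0,
    reaction_map = rate_reaction_map("EX_oct", "DM_pha", "EX_ha"))
  sol <- fba(cm)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
})

test_that("with zero tolerance the prediction equals the observation exactly", {
  tc <- noiseless_tc("KT2440")
  r <- build_phase_rates(tc, segment_phases(tc)[[2]])
  cm <- apply_phase_constraints(core_model_fixture(), r, tolerance = 0,
                                strain = "KT2440")
  sol <- fba(cm)
  rep <- validate_phase(cm, sol, r, threshold = 1e-6)
  expect_true(all(abs(rep$rel_error) < 1e-6))
  expect_false(any(rep$flagged))
})

test_that("validation report flags a corrupted observation", {
  tc <- noiseless_tc("KT2440")
  r <- build_phase_rates(tc, segment_phases(tc)[[1]])
  cm <- apply_phase_constraints(core_model_fixture(), r, strain = "KT2440")
  sol <- fba(cm)
  bad <- r
  bad$octanoate_uptake <- r$octanoate_uptake * 2
  rep <- validate_phase(cm, sol, bad, threshold = 0.1)
  expect_true(rep$flagged[rep$quantity == "octanoate_uptake"])
})

test_that("wild-type condition models are feasible in all three phases", {
  tc <- noiseless_tc("KT2440")
  for (ph in segment_phases(tc)) {
    cm <- apply_phase_constraints(core_model_fixture(),
                                  build_phase_rates(tc, ph),
                                  strain = "KT2440")
    sol <- fba(cm)
    expect_identical(sol$status, "optimal")
    rep <- validate_phase(cm, sol, cm$provenance, threshold = 0.05 + 1e-9)
    expect_false(any(rep$flagged),
                 label = paste("phase", ph$label, "within tolerance band"))
  }
})

test_that("infeasible constraint sets name the applied bounds", {
  m <- make_toy_model("chain")
  ph <- growth_phase("I", 0, 5)
  ## demand growth with zero carbon: infeasible
  r <- phase_rates(ph, 5, 0, 0, 0, 0.1)
  expect_error(
    apply_phase_constraints(m, r, tolerance = 0,
                            reaction_map = rate_reaction_map("EX_A", "CONV", "BIO")),
    "infeasible.*EX_A")
})

test_that("constraints cannot reverse an irreversible base reaction", {
  m <- make_toy_model("pha_mini")
  m <- set_bounds(m, "EX_oct", lb = 0)  # uptake now thermodynamically closed
  r <- phase_rates(growth_phase("I", 0, 5), 0, 2, 0, 0, 0.1)
  expect_error(
    apply_phase_constraints(m, r,
                            reaction_map = rate_reaction_map("EX_oct", "DM_pha", "EX_ha"),
                            check_feasible = FALSE),
    "irreversible")
})
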