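test_that("packaged core model file loads with its objective intact", {
  path <- system.file("extdata", "pha_core.json", package = "phaflux")
  m <- load_model(path)
  expect_s3_class(m, "metabolic_model")
  expect_identical(m$objective_id, "BIOMASS_core")
  expect_true("PHAP2C80" %in% names(m$reactions))
})

test_that("write/load round trip preserves structure exactly", {
  m <- make_toy_model("branch")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- load_model(path)
  expect_identical(stoichiometric_matrix(m), stoichiometric_matrix(m2))
  expect_identical(reaction_bounds(m), reaction_bounds(m2))
  expect_identical(m$objective_id, m2$objective_id)
  expect_identical(names(m$reactions), names(m2$reactions))
})

test_that("community-dialect JSON (reaction-level objective) is honoured", {
  doc <- list(
    metabolites = list(list(id = "A", compartment = "c")),
    reactions = list(
      list(id = "EX_A", metabolites = list(A = -1),
           lower_bound = -5, upper_bound = 0, objective_coefficient = 0),
      list(id = "DM_A", metabolites = list(A = -1),
           lower_bound = 0, upper_bound = 1000, objective_coefficient = 1)))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  m <- load_model(path)
  expect_identical(m$objective_id, "DM_A")
  expect_equal(m$reactions$EX_A$lb, -5)
})

test_that("model validation rejects malformed structures", {
  mets <- data.frame(id = c("A", "A"), name = "", formula = NA,
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- list(list(id = "R1", stoich = c(A = 1), lb = 0, ub = 1,
                    subsystem = "", is_exchange = TRUE))
  expect_error(metabolic_model(mets, rxns, "R1"), "duplicate metabolite")
  mets2 <- mets[1, ]
  expect_error(
    metabolic_model(mets2, list(list(id = "R1", stoich = c(B = 1), lb = 0,
                                     ub = 1, subsystem = "",
                                     is_exchange = FALSE)), "R1"),
    "undeclared")
  expect_error(
    metabolic_model(mets2, list(list(id = "R1", stoich = c(A = 1), lb = 2,
                                     ub = 1, subsystem = "",
                                     is_exchange = FALSE)), "R1"),
    "lb > ub")
  expect_error(metabolic_model(mets2, rxns, "nope"), "objective")
})

test_that("mass-balance check flags forced imbalance and passes balanced pairs", {
  mets <- data.frame(id = c("A", "B"), name = "",
                     formula = c("C2H4O2", "C2H4O2"), compartment = "c",
                     stringsAsFactors = FALSE)
  rxns <- list(
    list(id = "AB", stoich = c(A = -1, B = 1), lb = 0, ub = 10,
         subsystem = "", is_exchange = FALSE),
    list(id = "EX_A", stoich = c(A = 1), lb = 0, ub = 10,
         subsystem = "", is_exchange = TRUE),
    list(id = "DM_B", stoich = c(B = -1), lb = 0, ub = 10,
         subsystem = "", is_exchange = TRUE))
  m <- metabolic_model(mets, rxns, "DM_B")
  expect_identical(check_mass_balance(m), character(0))
  m$metabolites$formula[2] <- "C1H2O1"  # shrink B: interior AB now unbalanced
  expect_identical(check_mass_balance(m), "AB")
  m$metabolites$formula[2] <- NA_character_
  expect_error(check_mass_balance(m), "metabolite 'B'")
})

test_that("formula parser returns integer element counts", {
  f <- phaflux:::parse_formula("C21H36N7O16P3S")
  expect_equal(f[["C"]], 21)
  expect_equal(f[["S"]], 1)
  expect_equal(f[["P"]], 3)
  expect_error(phaflux:::parse_formula("C2(H4)"), "cannot parse")
})

test_that("knockout clamps bounds on a copy and never mutates its input", {
  m <- core_model_fixture()
  m2 <- knockout(m, "PHAZ")
  expect_equal(m2$reactions$PHAZ$lb, 0)
  expect_equal(m2$reactions$PHAZ$ub, 0)
  expect_gt(m$reactions$PHAZ$ub, 0)  # original untouched
  expect_error(knockout(m, "NOT_A_REACTION"), "unknown reaction")
  ## idempotence on an already-closed reaction
  expect_identical(knockout(m2, "PHAZ")$reactions$PHAZ,
                   m2$reactions$PHAZ)
})

test_that("knocking out the sole substrate uptake zeroes the FBA objective", {
  chain <- make_toy_model("chain")
  expect_equal(fba(chain)$objective_value, 5, tolerance = 1e-9)
  dead <- knockout(chain, "EX_A")
  expect_equal(fba(dead)$objective_value, 0, tolerance = 1e-9)
})

test_that("depolymerase knockout abolishes free-monomer secretion", {
  mini <- make_toy_model("pha_mini")
  ko <- knockout(mini, "DEPO")
  sol <- fba(ko)
  expect_identical(sol$status, "optimal")
  expect_equal(unname(sol$fluxes["EX_ha"]), 0, tolerance = 1e-9)
  ## and across sampled points, not just one optimum
  s <- achr_sample(ko, n_samples = 200, seed = 5, thinning = 5)
  expect_true(all(abs(s$points[, "EX_ha"]) < 1e-8))
})
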