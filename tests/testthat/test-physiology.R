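test_that("residual biomass splits total CDW as in the endpoint tables", {
  ## wild-type endpoint row: 1.3 g/L total at 71.7 %CDW prints as
  ## PHA 1.0 g/L and residual 0.4 g/L
  r <- residual_biomass(1.3, 71.7)
  expect_equal(r$pha_conc, 0.9321, tolerance = 1e-9)
  expect_equal(r$residual, 0.3679, tolerance = 1e-9)
  ## within the printed error bands (1.0 +/- 0.1 and 0.4 +/- 0.0 rounding)
  expect_lte(abs(r$pha_conc - 1.0), 0.1)
  expect_lte(abs(r$residual - 0.4), 0.05)
  ## exact arithmetic cases
  expect_equal(residual_biomass(2, 50), list(residual = 1, pha_conc = 1))
  expect_equal(residual_biomass(0.7, 0), list(residual = 0.7, pha_conc = 0))
  ## complement identity over a grid
  tot <- c(0.1, 0.6, 1.3, 2.5)
  pct <- c(0, 12.5, 71.7, 100)
  r <- residual_biomass(tot, pct)
  expect_equal(r$residual + r$pha_conc, tot)
  expect_error(residual_biomass(1, 101), "0, 100")
})

test_that("growth rate is the ln-scale regression slope of residual biomass", {
  t <- 0:5
  tc <- physio_timecourse("t", t, total_biomass = 0.08 * exp(0.31 * t),
                          pha_pct_cdw = rep(0, 6), ha_conc = rep(0, 6),
                          octanoate = rep(1, 6))
  w <- growth_phase("I", 0, 5, closed_end = TRUE)
  ## oracle: independent least squares on the natural-log values
  oracle <- unname(stats::coef(stats::lm(log(0.08 * exp(0.31 * t)) ~ t))[2])
  expect_equal(compute_growth_rate(tc, w), oracle, tolerance = 1e-12)
  expect_equal(compute_growth_rate(tc, w), 0.31, tolerance = 1e-9)
  ## flat series
  tc2 <- physio_timecourse("f", t, rep(0.4, 6), rep(0, 6), rep(0, 6), rep(1, 6))
  expect_equal(compute_growth_rate(tc2, w), 0, tolerance = 1e-12)
  ## invariance under uniform biomass rescaling
  tc3 <- tc; tc3$total_biomass <- tc$total_biomass * 7.3
  expect_equal(compute_growth_rate(tc3, w), compute_growth_rate(tc, w),
               tolerance = 1e-12)
  ## half-open window: saturated boundary point excluded
  tcs <- tc
  tcs$total_biomass[6] <- tcs$total_biomass[5]  # saturation at t = 5
  w_open <- growth_phase("I", 0, 5)
  expect_equal(compute_growth_rate(tcs, w_open), 0.31, tolerance = 1e-9)
  expect_lt(compute_growth_rate(tcs, w), 0.31)
  expect_error(compute_growth_rate(tc, growth_phase("x", 4.2, 4.8)),
               "at least 2 points")
})

test_that("specific rates convert concentration deltas to mmol/gCDW/h", {
  ## 0.5 g/L HA over 5 h at 0.25 g/L biomass, 0.16021 g/mmol
  expect_equal(specific_rate(0.5, 5, 0.25, 0.16021), 2.4967, tolerance = 1e-4)
  expect_equal(specific_rate(0, 3, 0.5, 0.2), 0)
  expect_equal(specific_rate(-0.5, 5, 0.25, 0.16021), -2.4967,
               tolerance = 1e-4)
  ## linear in delta, inverse in interval and biomass
  base <- specific_rate(1, 2, 0.5, 0.1)
  expect_equal(specific_rate(3, 2, 0.5, 0.1), 3 * base)
  expect_equal(specific_rate(1, 4, 0.5, 0.1), base / 2)
  expect_equal(specific_rate(1, 2, 1.0, 0.1), base / 2)
  expect_error(specific_rate(1, 0, 0.5), "interval")
  expect_error(specific_rate(1, 2, 0), "residual biomass")
})

test_that("phase segmentation matches a brute-force assignment oracle", {
  tc <- noiseless_tc()
  ph <- segment_phases(tc)
  expect_length(ph, 3)
  expect_equal(vapply(ph, function(p) c(p$t_start, p$t_end), numeric(2)),
               matrix(c(0, 5, 5, 10, 10, 24), 2))
  ## every sample lands in exactly one phase
  lab <- phaflux:::phase_labels_at(tc$times, ph)
  expect_false(anyNA(lab))
  ## brute-force oracle for custom boundaries
  ph2 <- segment_phases(tc, c(4, 12))
  lab2 <- phaflux:::phase_labels_at(tc$times, ph2)
  oracle <- ifelse(tc$times < 4, "I", ifelse(tc$times < 12, "II", "III"))
  expect_identical(lab2, oracle)
  ## degenerate coverage: all samples below the first boundary
  tc_short <- physio_timecourse("s", c(0, 1, 2, 3), rep(0.1, 4), rep(0, 4),
                                rep(0, 4), rep(1, 4))
  expect_length(segment_phases(tc_short, 2.5), 2)
  expect_error(segment_phases(tc, c(10, 5)), "increasing")
})

test_that("MicroResp hyperbola maps OD570 to percent CO2", {
  calib <- calibration_curve()  # A = 1.73, B = -0.13
  expect_equal(calib$A, 1.73)
  expect_equal(calib$B, -0.13)
  expect_equal(microresp_percent_co2(0.26, calib), 3.46, tolerance = 1e-9)
  ## asymptote equals A in the large-x limit
  expect_equal(microresp_percent_co2(1e6, calib), 1.73, tolerance = 1e-6)
  ## monotone decreasing on the valid domain of the packaged calibration
  x <- seq(0.15, 5, length.out = 50)
  expect_true(all(diff(microresp_percent_co2(x, calib)) < 0))
  expect_error(microresp_percent_co2(0.10, calib), "asymptote")
  ## inverse is consistent
  expect_equal(phaflux:::microresp_od570(3.46, calib), 0.26, tolerance = 1e-9)
})

test_that("relative CO2 normalizes to the reference strain", {
  expect_equal(relative_co2(c(wt = 2, M4 = 6), "wt"), c(wt = 1, M4 = 3))
  expect_equal(relative_co2(c(wt = 2), "wt"), c(wt = 1))
  expect_error(relative_co2(c(wt = 0, M4 = 6), "wt"), "positive")
  expect_error(relative_co2(c(M4 = 6), "wt"), "not present")
})

test_that("time-course CSV round trips including optional columns", {
  tc <- make_strain_timecourse(builtin_archetypes()$M2, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_timecourse(tc, path)
  tc2 <- read_timecourse(path, strain = "M2")
  expect_equal(tc2$times, tc$times)
  expect_equal(tc2$total_biomass, tc$total_biomass, tolerance = 1e-9)
  expect_equal(tc2$octanoate, tc$octanoate, tolerance = 1e-9)
  expect_equal(tc2$od570, tc$od570, tolerance = 1e-9)
  ## optional columns may be absent
  df <- utils::read.csv(path)
  df$viable_cells_1e8ml <- NULL; df$od570 <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  tc3 <- read_timecourse(path)
  expect_null(tc3$od570)
  df$octanoate_mM <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_timecourse(path), "octanoate_mM")
})
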