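# Strain physiology: measured batch-culture trajectories and their
# conversion into model-ready specific rates.
#
# All biomass quantities are g/L of cell dry weight (CDW); PHA content is
# percent of CDW; free (R)-3-hydroxyalkanoates (HA) are g/L; octanoate is
# mM.  Residual biomass -- CDW free of polymer -- is the growth-relevant
# biomass and the denominator of every specific rate.

#' Construct a physiology time course
#'
#' @param strain strain label.
#' @param times sampling times in hours, strictly increasing, starting at 0.
#' @param total_biomass total CDW, g/L.
#' @param pha_pct_cdw PHA content, percent of CDW (0-100).
#' @param ha_conc free (R)-HA concentration, g/L.
#' @param octanoate residual octanoate, mM.
#' @param viable_cells optional viable cell counts, 1e8/ml (descriptive only).
#' @param od570 optional MicroResp absorbance readings (descriptive only).
#' @return object of class \code{physio_timecourse}.
#' @export
physio_timecourse <- function(strain, times, total_biomass, pha_pct_cdw,
                              ha_conc, octanoate,
                              viable_cells = NULL, od570 = NULL) {
  n <- length(times)
  stopifnot(length(total_biomass) == n, length(pha_pct_cdw) == n,
            length(ha_conc) == n, length(octanoate) == n)
  if (n < 2 || times[1] != 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing and start at 0")
  if (any(total_biomass < 0) || any(ha_conc < 0) || any(octanoate < 0))
    stop("concentrations must be non-negative")
  if (any(pha_pct_cdw < 0 | pha_pct_cdw > 100))
    stop("pha_pct_cdw must lie in [0, 100]")
  structure(list(strain = strain, times = times,
                 total_biomass = total_biomass, pha_pct_cdw = pha_pct_cdw,
                 ha_conc = ha_conc, octanoate = octanoate,
                 viable_cells = viable_cells, od570 = od570),
            class = "physio_timecourse")
}

#' Split total biomass into residual biomass and PHA
#'
#' Residual biomass is total CDW times (1 - PHA fraction); the complementary
#' polymer concentration is returned alongside so the two always sum to the
#' total exactly.
#'
#' @param total total biomass, g/L.
#' @param pha_pct PHA content, percent of CDW.
#' @return list with \code{residual} and \code{pha_conc}, both g/L.
#' @export
residual_biomass <- function(total, pha_pct) {
  if (any(total < 0)) stop("total biomass must be non-negative")
  if (any(pha_pct < 0 | pha_pct > 100))
    stop("pha_pct must lie in [0, 100]")
  list(residual = total * (1 - pha_pct / 100),
       pha_conc = total * pha_pct / 100)
}

#' Growth phase interval
#'
#' Phases are half-open \code{[t_start, t_end)} except the terminal phase of
#' a segmentation, which is closed at its right edge.
#'
#' @param label phase label ("I", "II", "III", ...).
#' @param t_start,t_end interval in hours.
#' @param closed_end if \code{TRUE} the right edge belongs to the phase
#'   (terminal phase of a segmentation).
#' @return object of class \code{growth_phase}.
#' @export
growth_phase <- function(label, t_start, t_end, closed_end = FALSE) {
  if (t_start >= t_end) stop("t_start must be < t_end")
  structure(list(label = label, t_start = t_start, t_end = t_end,
                 closed_end = closed_end),
            class = "growth_phase")
}

#' Segment a time course into growth phases
#'
#' Default boundaries at 5 and 10 h give phase I = [0, 5) (early
#' exponential), II = [5, 10) (late exponential) and III = [10, 24]
#' (stationary).  Every sample time is assigned to exactly one phase; only
#' phases containing at least one sample are returned.
#'
#' @param tc a \code{physio_timecourse}.
#' @param boundaries sorted interior boundaries, hours.
#' @return list of \code{growth_phase} objects.
#' @export
segment_phases <- function(tc, boundaries = c(5, 10)) {
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be strictly increasing")
  t0 <- tc$times[1]
  t1 <- tc$times[length(tc$times)]
  if (any(boundaries <= t0) || any(boundaries >= t1))
    stop("boundaries must lie strictly inside the time range")
  edges <- c(t0, boundaries, t1)
  labels <- c("I", "II", "III", as.character(seq(4, length.out = max(0, length(edges) - 4))))
  phases <- list()
  for (k in seq_len(length(edges) - 1)) {
    ph <- growth_phase(labels[k], edges[k], edges[k + 1],
                       closed_end = k == length(edges) - 1)
    inside <- tc$times >= ph$t_start &
      (tc$times < ph$t_end | (k == length(edges) - 1 & tc$times <= ph$t_end))
    if (any(inside)) phases[[length(phases) + 1L]] <- ph
  }
  phases
}

#' Assign each sample time to a phase label
#' @param times sample times (h).
#' @param phases list of \code{growth_phase} (ordered, contiguous).
#' @return character vector of phase labels.
#' @keywords internal
phase_labels_at <- function(times, phases) {
  lab <- rep(NA_character_, length(times))
  last <- length(phases)
  for (k in seq_along(phases)) {
    ph <- phases[[k]]
    hit <- times >= ph$t_start &
      (times < ph$t_end | (k == last & times <= ph$t_end))
    lab[hit] <- ph$label
  }
  lab
}

#' Specific growth rate from residual biomass
#'
#' Least-squares slope of log10(residual biomass) against time over the
#' window, multiplied by ln(10) (the conversion factor between decadic and
#' Napierian logarithms, 2.303 to four digits) to give 1/h.
#' Points with non-positive residual biomass are excluded with a warning.
#' The window follows the phase convention: half-open
#' \code{[t_start, t_end)}, closed at the right edge only for a phase with
#' \code{closed_end = TRUE} (the terminal phase).
#'
#' @param tc a \code{physio_timecourse}.
#' @param window a \code{growth_phase} giving the fit interval.
#' @return growth rate, 1/h.
#' @export
compute_growth_rate <- function(tc, window) {
  inside <- tc$times >= window$t_start &
    (tc$times < window$t_end |
       (isTRUE(window$closed_end) & tc$times <= window$t_end))
  res <- residual_biomass(tc$total_biomass, tc$pha_pct_cdw)$residual
  t <- tc$times[inside]
  x <- res[inside]
  pos <- x > 0
  if (any(!pos)) {
    warning(sum(!pos), " point(s) with non-positive residual biomass excluded")
    t <- t[pos]; x <- x[pos]
  }
  if (length(t) < 2)
    stop("need at least 2 points with positive residual biomass in the window")
  fit <- stats::lm.fit(cbind(1, t), log10(x))
  unname(fit$coefficients[2]) * log(10)
}

#' Specific rate from a concentration change
#'
#' Converts a concentration change over an interval into a biomass-specific
#' molar rate: \code{(delta_mass / molar_mass) / (interval * biomass)}.
#' The sign follows \code{delta_mass}, so consumption is negative.
#'
#' @param delta_mass concentration change, g/L (or mmol/L when
#'   \code{molar_mass = 1}, e.g. octanoate measured in mM).
#' @param interval interval length, h (> 0).
#' @param mean_residual_biomass mean residual biomass over the interval, g/L
#'   (> 0).
#' @param molar_mass g/mmol; use 1 for quantities already in mmol/L.
#' @return specific rate, mmol/gCDW/h.
#' @export
specific_rate <- function(delta_mass, interval, mean_residual_biomass,
                          molar_mass = 1) {
  if (interval <= 0) stop("interval must be positive")
  if (mean_residual_biomass <= 0)
    stop("mean residual biomass must be positive (got ",
         mean_residual_biomass, ")")
  if (molar_mass <= 0) stop("molar_mass must be positive")
  (delta_mass / molar_mass) / (interval * mean_residual_biomass)
}

#' Monomer molar masses used for unit conversion
#'
#' PHA is quantified as the C8 repeat unit (3-hydroxyoctanoate in chain,
#' dehydrated, 142.20 g/mol); free (R)-HA as 3-hydroxyoctanoic acid (160.21
#' g/mol).  Octanoate is measured in mM and needs no mass, but its molar
#' mass (144.21 g/mol as octanoic acid) is carried for completeness.
#'
#' @param pha_repeat_unit,ha_free_acid,octanoate g/mmol.
#' @return named list of masses (g/mmol).
#' @export
monomer_mass_table <- function(pha_repeat_unit = 0.14220,
                               ha_free_acid = 0.16021,
                               octanoate = 0.14421) {
  if (pha_repeat_unit <= 0 || ha_free_acid <= 0 || octanoate <= 0)
    stop("molar masses must be positive")
  list(pha_repeat_unit = pha_repeat_unit, ha_free_acid = ha_free_acid,
       octanoate = octanoate)
}

#' MicroResp calibration hyperbola
#'
#' The colorimetric CO2 detection plate is calibrated by a rectangular
#' hyperbola \code{y = A x / (B + x)} mapping OD570 readings to percent CO2.
#' With the packaged coefficients (A = 1.73, B = -0.13) the curve is
#' monotone decreasing in x on its valid domain x > -B and approaches the
#' asymptote A from above as x grows.
#'
#' @param A asymptotic percent CO2 (> 0).
#' @param B offset in OD570 units.
#' @return object of class \code{calibration_curve}.
#' @export
calibration_curve <- function(A = 1.73, B = -0.13) {
  if (A <= 0) stop("A must be positive")
  structure(list(A = A, B = B), class = "calibration_curve")
}

#' Convert a MicroResp OD570 reading to percent CO2
#'
#' @param od570 absorbance reading(s); must satisfy \code{od570 + B > 0}
#'   (right of the vertical asymptote; with the default calibration,
#'   od570 > 0.13).
#' @param calib a \code{calibration_curve}.
#' @return percent CO2.
#' @export
microresp_percent_co2 <- function(od570, calib = calibration_curve()) {
  if (any(od570 + calib$B <= 0))
    stop("od570 reading on or left of the calibration asymptote (od570 <= ",
         -calib$B, ")")
  calib$A * od570 / (calib$B + od570)
}

#' Invert the MicroResp calibration
#'
#' Maps a percent-CO2 value back to the OD570 reading that would produce it;
#' used by the synthetic generator to emit plausible od570 channels.
#'
#' @param pct_co2 percent CO2; must exceed the asymptote A when B < 0.
#' @param calib a \code{calibration_curve}.
#' @return OD570 reading.
#' @keywords internal
microresp_od570 <- function(pct_co2, calib = calibration_curve()) {
  x <- pct_co2 * calib$B / (calib$A - pct_co2)
  if (any(!is.finite(x)) || any(x + calib$B <= 0))
    stop("pct_co2 outside the invertible range of the calibration")
  x
}

#' Normalize CO2 production to a reference strain
#'
#' @param samples named numeric vector or list, strain -> percent CO2 (or
#'   any production measure on a common scale).
#' @param reference name of the reference strain (present, value > 0).
#' @return named numeric vector of fold changes; the reference maps to 1.
#' @export
relative_co2 <- function(samples, reference) {
  samples <- unlist(samples)
  if (!reference %in% names(samples))
    stop("reference strain '", reference, "' not present")
  ref <- samples[[reference]]
  if (ref <= 0) stop("reference value must be positive")
  samples / ref
}

#' Read a physiology time course from CSV
#'
#' Expected header: \code{time_h, total_biomass_gL, pha_pct_cdw, ha_gL,
#' octanoate_mM, viable_cells_1e8ml, od570}; the last two columns are
#' optional.
#'
#' @param path CSV path.
#' @param strain strain label; defaults to the file base name.
#' @return a \code{physio_timecourse}.
#' @export
read_timecourse <- function(path, strain = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "total_biomass_gL", "pha_pct_cdw", "ha_gL", "octanoate_mM")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("time-course CSV misses column(s): ", paste(missing_cols, collapse = ", "))
  physio_timecourse(
    strain = strain %||% sub("\\.csv$", "", basename(path)),
    times = df$time_h, total_biomass = df$total_biomass_gL,
    pha_pct_cdw = df$pha_pct_cdw, ha_conc = df$ha_gL,
    octanoate = df$octanoate_mM,
    viable_cells = df$viable_cells_1e8ml %||% NULL,
    od570 = df$od570 %||% NULL)
}

#' Write a physiology time course to CSV
#' @param tc a \code{physio_timecourse}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  df <- data.frame(time_h = tc$times, total_biomass_gL = tc$total_biomass,
                   pha_pct_cdw = tc$pha_pct_cdw, ha_gL = tc$ha_conc,
                   octanoate_mM = tc$octanoate)
  if (!is.null(tc$viable_cells)) df$viable_cells_1e8ml <- tc$viable_cells
  if (!is.null(tc$od570)) df$od570 <- tc$od570
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.physio_timecourse <- function(x, ...) {
  cat("physio_timecourse '", x$strain, "': ", length(x$times),
      " samples over [", x$times[1], ", ", x$times[length(x$times)], "] h\n",
      sep = "")
  invisible(x)
}
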