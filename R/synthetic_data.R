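# Synthetic study data: strain archetypes with the statistical structure of
# published batch-culture endpoints, a deterministic-plus-noise time-course
# generator, and hand-audited toy networks for oracle testing.
#
# The core octanoate/PHA network below is a curated ~50-reaction,
# carbon-balanced model of the pathways that matter for PHA-cycle
# physiology: octanoate activation and beta-oxidation, the two
# (R)-3-hydroxyacyl-CoA supply routes, the PHA polymerase/depolymerase/
# reactivation cycle, TCA cycle, glyoxylate shunt, gluconeogenic backbone,
# lumped oxidative phosphorylation and a precursor-based biomass reaction.
# It is explicitly NOT a genome-scale reconstruction; quantitative
# genome-scale predictions are out of its reach and all cross-strain
# comparisons on it are direction-level.
#
# Cofactor formulas are bookkeeping formulas: the proton released with each
# NAD(P)H is lumped into the reduced carrier so that redox reactions
# balance without a free proton species.

# grams of carbon per mmol of C8 monomer carbon skeleton
.C_PER_MMOL <- 0.012011

#' Strain archetype
#'
#' Encapsulates the 24 h endpoint targets and kinetic structure of one
#' strain growing under PHA accumulation conditions (nitrogen-limited
#' minimal medium, 15 mM octanoate): specific growth rate on residual
#' biomass, endpoint composition, and per-phase allocation weights saying
#' in which growth phase the PHA and free (R)-HA pools are built.
#'
#' @param name strain label.
#' @param growth_rate specific growth rate on residual biomass, 1/h.
#' @param final_total_biomass total CDW at 24 h, g/L.
#' @param final_pha_pct PHA content at 24 h, percent of CDW.
#' @param final_ha free (R)-HA at 24 h, g/L.
#' @param final_viable_cells viable cells at 24 h, 1e8/ml (descriptive).
#' @param initial_residual_biomass residual biomass at t = 0, g/L.
#' @param octanoate_initial octanoate at t = 0, mM.
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal measurement noise (per replicate observation).
#' @param pha_phase_weights,ha_phase_weights length-3 non-negative weights
#'   (phases I, II, III) that sum to 1; fraction of the endpoint pool
#'   accumulated in each phase.
#' @param co2_phase_weights length-3 weights distributing the strain's
#'   total CO2 release (the carbon not fixed in biomass, PHA or HA) over
#'   the three phases; encodes whether respiration tracks growth
#'   (accumulators) or persists into stationary phase (hydrolyzers).
#' @param co2_fold CO2 production at 24 h relative to the wild type
#'   (MicroResp scale; drives the generated od570 channel).
#' @return object of class \code{strain_archetype}.
#' @export
strain_archetype <- function(name, growth_rate, final_total_biomass,
                             final_pha_pct, final_ha, final_viable_cells,
                             initial_residual_biomass = 0.085,
                             octanoate_initial = 15,
                             noise_cv = 0.05,
                             pha_phase_weights = c(0.10, 0.65, 0.25),
                             ha_phase_weights = c(0.10, 0.65, 0.25),
                             co2_phase_weights = c(0.50, 0.35, 0.15),
                             co2_fold = 1) {
  stopifnot(growth_rate >= 0, final_total_biomass >= 0,
            final_pha_pct >= 0, final_pha_pct <= 100,
            final_ha >= 0, octanoate_initial > 0,
            length(pha_phase_weights) == 3, length(ha_phase_weights) == 3,
            length(co2_phase_weights) == 3,
            all(pha_phase_weights >= 0), all(ha_phase_weights >= 0),
            all(co2_phase_weights >= 0), sum(co2_phase_weights) > 0)
  normalize <- function(w) if (sum(w) > 0) w / sum(w) else w
  structure(list(name = name, growth_rate = growth_rate,
                 final_total_biomass = final_total_biomass,
                 final_pha_pct = final_pha_pct, final_ha = final_ha,
                 final_viable_cells = final_viable_cells,
                 initial_residual_biomass = initial_residual_biomass,
                 octanoate_initial = octanoate_initial,
                 noise_cv = noise_cv,
                 pha_phase_weights = normalize(pha_phase_weights),
                 ha_phase_weights = normalize(ha_phase_weights),
                 co2_phase_weights = normalize(co2_phase_weights),
                 co2_fold = co2_fold),
            class = "strain_archetype")
}

#' Built-in strain archetypes
#'
#' Archetypes for the wild type (KT2440), the depolymerase deletion strain
#' (KT40Z), the whole-cluster deletion (KT2440_dpha) and the constitutive
#' depolymerase dosage library (M1-M4), parameterized from 24 h endpoint
#' physiology under PHA accumulation conditions.  Strains fall into two
#' groups: PHA accumulators (KT2440, KT40Z, M1; polymer built mainly in
#' late exponential phase) and hydrolyzers (M2-M4; no polymer, sustained
#' free-monomer secretion into stationary phase).  Hydrolyzers carry the
#' elevated CO2 production observed for those strains.
#'
#' @return named list of \code{strain_archetype} objects.
#' @export
builtin_archetypes <- function() {
  accum <- c(0.10, 0.65, 0.25)
  hydro <- c(0.10, 0.55, 0.35)
  co2_accum <- c(0.50, 0.35, 0.15)  # respiration tracks growth/production
  co2_hydro <- c(0.30, 0.30, 0.40)  # respiration persists into stationary phase
  list(
    KT2440 = strain_archetype("KT2440", 0.31, 1.3, 71.7, 0.2, 1.8,
                              pha_phase_weights = accum,
                              ha_phase_weights = accum,
                              co2_phase_weights = co2_accum, co2_fold = 1.0),
    KT40Z = strain_archetype("KT40Z", 0.31, 1.4, 72.3, 0.0, 1.2,
                             pha_phase_weights = accum,
                             ha_phase_weights = accum,
                             co2_phase_weights = co2_accum, co2_fold = 1.0),
    KT2440_dpha = strain_archetype("KT2440_dpha", 0.34, 0.6, 0.0, 0.0, 22.3,
                                   pha_phase_weights = hydro,
                                   ha_phase_weights = hydro,
                                   co2_phase_weights = co2_hydro, co2_fold = 2.8),
    M1 = strain_archetype("M1", 0.30, 1.3, 70.2, 0.3, 4.1,
                          pha_phase_weights = accum,
                          ha_phase_weights = accum,
                          co2_phase_weights = co2_accum, co2_fold = 1.2),
    M2 = strain_archetype("M2", 0.29, 0.6, 0.3, 0.5, 16.5,
                          pha_phase_weights = hydro,
                          ha_phase_weights = hydro,
                          co2_phase_weights = co2_hydro, co2_fold = 2.8),
    M3 = strain_archetype("M3", 0.31, 0.7, 0.4, 0.6, 16.8,
                          pha_phase_weights = hydro,
                          ha_phase_weights = hydro,
                          co2_phase_weights = co2_hydro, co2_fold = 3.2),
    M4 = strain_archetype("M4", 0.35, 0.5, 0.7, 0.5, 15.4,
                          pha_phase_weights = hydro,
                          ha_phase_weights = hydro,
                          co2_phase_weights = co2_hydro, co2_fold = 3.6))
}

#' Default sampling grid for generated time courses (hours)
#'
#' Dense sampling during exponential growth (hourly plus an
#' end-of-exponential sample at 4.5 h), then sparser sampling through the
#' production and stationary phases.
#' @return numeric vector of times (h).
#' @export
default_sampling_times <- function() c(0, 1, 2, 3, 4, 4.5, 5, 6, 8, 10, 12, 24)

## deterministic (noise-free) state of an archetype at arbitrary times
.archetype_truth <- function(arch, times, c_bio = core_biomass_carbon()) {
  mm <- monomer_mass_table()
  Xf <- arch$final_total_biomass * (1 - arch$final_pha_pct / 100)
  X0 <- arch$initial_residual_biomass
  Pf <- arch$final_total_biomass * arch$final_pha_pct / 100
  Hf <- arch$final_ha
  X <- pmin(X0 * exp(arch$growth_rate * times), max(Xf, X0))
  edges <- c(0, 5, 10, 24)
  cum_weight <- function(w) {
    cw <- c(0, cumsum(w))
    vapply(times, function(t) {
      k <- findInterval(min(t, 24), edges, rightmost.closed = TRUE)
      k <- min(k, 3)
      cw[k] + w[k] * (min(t, 24) - edges[k]) / (edges[k + 1] - edges[k])
    }, numeric(1))
  }
  P <- Pf * cum_weight(arch$pha_phase_weights)
  H <- Hf * cum_weight(arch$ha_phase_weights)
  ## carbon bookkeeping: octanoate consumption = cumulative product carbon
  ## plus the explicit CO2 channel.  The strain's total CO2 carbon is the
  ## closure remainder (all octanoate is consumed by 24 h) and is released
  ## over the phases according to the archetype CO2 weights, so octanoate
  ## carbon consumed always dominates product carbon and hits zero at 24 h.
  c_pha <- 8 * .C_PER_MMOL / mm$pha_repeat_unit   # gC per g PHA
  c_ha <- 8 * .C_PER_MMOL / mm$ha_free_acid       # gC per g HA
  prodC <- (X - X0) * c_bio + P * c_pha + H * c_ha
  P24 <- Pf
  H24 <- Hf
  X24 <- max(Xf, X0)
  prodC24 <- (X24 - X0) * c_bio + P24 * c_pha + H24 * c_ha
  octC <- arch$octanoate_initial * 8 * .C_PER_MMOL
  if (prodC24 > octC)
    stop("archetype '", arch$name, "' fixes more carbon than the octanoate supplies")
  co2C24 <- octC - prodC24
  co2C <- co2C24 * cum_weight(arch$co2_phase_weights)
  oct <- arch$octanoate_initial * (1 - (prodC + co2C) / octC)
  list(X = X, P = P, H = H, oct = pmax(oct, 0),
       co2C = co2C, carbon_yield = prodC24 / octC)
}

#' Generate a strain physiology time course
#'
#' Deterministic trajectory: residual biomass grows exponentially at the
#' archetype growth rate until it reaches the endpoint residual biomass,
#' then stays flat; PHA and free (R)-HA accumulate piecewise linearly
#' within phases according to the archetype phase weights; octanoate
#' declines with cumulative product carbon plus an explicit CO2 channel
#' (the closure remainder, released per the archetype CO2 phase weights),
#' reaching 0 at 24 h.  Each observation is the mean of \code{n_replicates}
#' multiplicative lognormal measurement replicates with the archetype CV.
#' The od570 MicroResp channel is an endpoint assay and is only emitted at
#' the final time point (NA elsewhere).
#'
#' @param arch a \code{strain_archetype}.
#' @param times sampling times (h) within [0, 24], including 0 and 24.
#' @param seed integer seed; the output is deterministic per seed.
#' @param n_replicates measurement replicates averaged per observation.
#' @return a \code{physio_timecourse}.
#' @export
make_strain_timecourse <- function(arch, times = default_sampling_times(),
                                   seed = 1, n_replicates = 3) {
  if (times[1] != 0 || times[length(times)] != 24 ||
      any(times < 0 | times > 24) || is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing within [0, 24], including 0 and 24")
  truth <- .archetype_truth(arch, times)
  noisy <- with_seed(seed, {
    jitter <- function(x) {
      if (arch$noise_cv <= 0) return(x)
      sdlog <- sqrt(log(1 + arch$noise_cv^2))
      reps <- matrix(stats::rlnorm(length(x) * n_replicates,
                                   meanlog = -sdlog^2 / 2, sdlog = sdlog),
                     nrow = length(x))
      x * rowMeans(reps)
    }
    X <- jitter(truth$X)
    P <- jitter(truth$P)
    H <- jitter(truth$H)
    oct <- jitter(truth$oct)
    list(X = X, P = P, H = H, oct = oct)
  })
  total <- noisy$X + noisy$P
  pct <- ifelse(total > 0, 100 * noisy$P / total, 0)
  cells <- arch$final_viable_cells * truth$X / max(truth$X)
  od <- rep(NA_real_, length(times))
  baseline_pct_co2 <- 2.2  # wild-type endpoint MicroResp reading, %CO2
  od[length(times)] <- microresp_od570(baseline_pct_co2 * arch$co2_fold)
  physio_timecourse(strain = arch$name, times = times,
                    total_biomass = total, pha_pct_cdw = pct,
                    ha_conc = noisy$H, octanoate = noisy$oct,
                    viable_cells = cells, od570 = od)
}

#' Hand-audited toy metabolic networks
#'
#' Small networks with known exact FBA optima and sampling marginals, used
#' as oracle substrates in the test suite:
#' \describe{
#'   \item{interval}{one metabolite fed and drained at rates in [0, 10];
#'     the flux polytope is a segment with uniform marginal on [0, 10].}
#'   \item{box}{two independent fed/drained metabolites, each throughput in
#'     [0, 1]; the polytope is the unit square.}
#'   \item{chain}{uptake (max 10) converted at yield 0.5 into an objective
#'     metabolite; FBA optimum 5.}
#'   \item{branch}{uptake (max 12) split over a direct route (cap 8) and a
#'     two-step route (cap 3); FBA optimum 11.}
#'   \item{pha_mini}{10-reaction monomer/polymer cycle in which knocking
#'     out the depolymerase zeroes free-monomer secretion.}
#' }
#'
#' @param kind one of "interval", "box", "chain", "branch", "pha_mini".
#' @return a \code{metabolic_model}.
#' @export
make_toy_model <- function(kind = c("interval", "box", "chain", "branch",
                                    "pha_mini")) {
  kind <- match.arg(kind)
  met <- function(id, compartment = "c")
    data.frame(id = id, name = id, formula = NA_character_,
               compartment = compartment, stringsAsFactors = FALSE)
  rxn <- function(id, stoich, lb, ub, subsystem = "toy", exch = FALSE)
    list(id = id, stoich = stoich, lb = lb, ub = ub,
         subsystem = subsystem, is_exchange = exch)
  switch(kind,
    interval = metabolic_model(
      met("A"),
      list(rxn("SRC_A", c(A = 1), 0, 10, exch = TRUE),
           rxn("SNK_A", c(A = -1), 0, 1000, exch = TRUE)),
      objective_id = "SNK_A", name = "toy_interval"),
    box = metabolic_model(
      rbind(met("A"), met("B")),
      list(rxn("SRC_A", c(A = 1), 0, 1, exch = TRUE),
           rxn("SNK_A", c(A = -1), 0, 1, exch = TRUE),
           rxn("SRC_B", c(B = 1), 0, 1, exch = TRUE),
           rxn("SNK_B", c(B = -1), 0, 1, exch = TRUE)),
      objective_id = "SNK_A", name = "toy_box"),
    chain = metabolic_model(
      rbind(met("A"), met("B")),
      list(rxn("EX_A", c(A = -1), -10, 0, exch = TRUE),
           rxn("CONV", c(A = -1, B = 0.5), 0, 1000),
           rxn("BIO", c(B = -1), 0, 1000)),
      objective_id = "BIO", name = "toy_chain"),
    branch = metabolic_model(
      rbind(met("A"), met("B"), met("C")),
      list(rxn("EX_A", c(A = -1), -12, 0, exch = TRUE),
           rxn("AB", c(A = -1, B = 1), 0, 3),
           rxn("AC", c(A = -1, C = 1), 0, 8),
           rxn("BC", c(B = -1, C = 1), 0, 1000),
           rxn("EX_C", c(C = -1), 0, 1000, exch = TRUE)),
      objective_id = "EX_C", name = "toy_branch"),
    pha_mini = metabolic_model(
      rbind(met("oct_e", "e"), met("oct_c"), met("mcoa"), met("pha"),
            met("ha_c"), met("ha_e", "e")),
      list(rxn("EX_oct", c(oct_e = -1), -10, 0, exch = TRUE),
           rxn("OCTt", c(oct_e = -1, oct_c = 1), 0, 1000),
           rxn("ACT", c(oct_c = -1, mcoa = 1), 0, 1000),
           rxn("POLY", c(mcoa = -1, pha = 1), 0, 1000),
           rxn("DEPO", c(pha = -1, ha_c = 1), 0, 1000),
           rxn("REACT", c(ha_c = -1, mcoa = 1), 0, 1000),
           rxn("HAt", c(ha_c = -1, ha_e = 1), 0, 1000),
           rxn("EX_ha", c(ha_e = -1), 0, 1000, exch = TRUE),
           rxn("DM_pha", c(pha = -1), 0, 1000, exch = TRUE),
           rxn("BIO", c(mcoa = -1), 0, 1000)),
      objective_id = "BIO", name = "toy_pha_mini"))
}

#' Carbon drained per unit biomass flux in the core model
#'
#' Net carbon of the precursors consumed by the core biomass reaction
#' (gC per gCDW); declared alongside the model so dynamic simulations and
#' carbon audits use a value consistent with the stoichiometry.
#' @return grams of carbon per gram CDW.
#' @export
core_biomass_carbon <- function() {
  ## 5 acetyl-CoA (2C net) + 2 OAA (4C) + 1.5 AKG (5C) + 4.5 G3P (3C)
  (5 * 2 + 2 * 4 + 1.5 * 5 + 4.5 * 3) * .C_PER_MMOL
}

#' Core octanoate/PHA metabolic network
#'
#' Builds the packaged carbon-balanced core model: octanoate uptake and
#' activation, beta-oxidation of the C8 backbone with both
#' (R)-3-hydroxyacyl-CoA supply routes (the R-specific enoyl-CoA hydratase
#' RECOAH3 and the 3-oxoacyl reductase RHACOAR80 assisted by ECOAH3 and
#' HACD3i, which exchanges one NADH for one NADPH per monomer), the PHA
#' polymerase (PHAP2C80), depolymerase (PHAZ) and ATP-dependent
#' reactivation (FACOAL3HO), TCA cycle (CS, ACONTa/b, ICDHy, AKGDH,
#' SUCOAS, SUCDi, FUM, MDH), glyoxylate shunt (ICL, MALS), the
#' gluconeogenic backbone (PPCK, ENO, PGM, PGK, GAPD), lumped oxidative
#' phosphorylation, ATP maintenance, a precursor-based biomass reaction
#' free of polymer, and exchanges for octanoate, O2, CO2, ammonium,
#' phosphate, water and free (R)-HA plus a PHA sink.
#'
#' Every interior reaction is elementally balanced
#' (\code{check_mass_balance} returns an empty set); reduced cofactors
#' carry their proton as a bookkeeping convention.  The single biomass
#' reaction contains no polymer species: PHA accumulation is represented
#' by the sink \code{DM_pha_c}, so percent-CDW storage is expressible at
#' steady state.
#'
#' @return a \code{metabolic_model} named \code{"pha_core"} with objective
#'   \code{"BIOMASS_core"}.
#' @export
core_pha_model <- function() {
  M <- function(id, name, formula, compartment = "c")
    data.frame(id = id, name = name, formula = formula,
               compartment = compartment, stringsAsFactors = FALSE)
  mets <- rbind(
    M("octa_e", "octanoate", "C8H16O2", "e"),
    M("o2_e", "oxygen", "O2", "e"),
    M("co2_e", "carbon dioxide", "CO2", "e"),
    M("nh4_e", "ammonium", "NH3", "e"),
    M("pi_e", "phosphate", "H3PO4", "e"),
    M("h2o_e", "water", "H2O", "e"),
    M("rha_e", "(R)-3-hydroxyoctanoate", "C8H16O3", "e"),
    M("octa_c", "octanoate", "C8H16O2"),
    M("o2_c", "oxygen", "O2"),
    M("co2_c", "carbon dioxide", "CO2"),
    M("nh4_c", "ammonium", "NH3"),
    M("pi_c", "phosphate", "H3PO4"),
    M("h2o_c", "water", "H2O"),
    M("rha_c", "(R)-3-hydroxyoctanoate", "C8H16O3"),
    M("atp_c", "ATP", "C10H16N5O13P3"),
    M("adp_c", "ADP", "C10H15N5O10P2"),
    M("amp_c", "AMP", "C10H14N5O7P"),
    M("ppi_c", "pyrophosphate", "H4P2O7"),
    M("nad_c", "NAD", "C21H26N7O14P2"),
    M("nadh_c", "NADH (with lumped proton)", "C21H28N7O14P2"),
    M("nadp_c", "NADP", "C21H27N7O17P3"),
    M("nadph_c", "NADPH (with lumped proton)", "C21H29N7O17P3"),
    M("fad_c", "FAD", "C27H33N9O15P2"),
    M("fadh2_c", "FADH2", "C27H35N9O15P2"),
    M("coa_c", "coenzyme A", "C21H36N7O16P3S"),
    M("accoa_c", "acetyl-CoA", "C23H38N7O17P3S"),
    M("octcoa_c", "octanoyl-CoA", "C29H50N7O17P3S"),
    M("oct2coa_c", "trans-2-octenoyl-CoA", "C29H48N7O17P3S"),
    M("s3hocoa_c", "(S)-3-hydroxyoctanoyl-CoA", "C29H50N7O18P3S"),
    M("r3hocoa_c", "(R)-3-hydroxyoctanoyl-CoA", "C29H50N7O18P3S"),
    M("oxooctcoa_c", "3-oxooctanoyl-CoA", "C29H48N7O18P3S"),
    M("hexcoa_c", "hexanoyl-CoA", "C27H46N7O17P3S"),
    M("butcoa_c", "butanoyl-CoA", "C25H42N7O17P3S"),
    M("pha_c", "PHA C8 repeat unit", "C8H14O2"),
    M("oaa_c", "oxaloacetate", "C4H4O5"),
    M("cit_c", "citrate", "C6H8O7"),
    M("acon_c", "cis-aconitate", "C6H6O6"),
    M("icit_c", "isocitrate", "C6H8O7"),
    M("akg_c", "2-oxoglutarate", "C5H6O5"),
    M("succoa_c", "succinyl-CoA", "C25H40N7O19P3S"),
    M("succ_c", "succinate", "C4H6O4"),
    M("fum_c", "fumarate", "C4H4O4"),
    M("mal_c", "malate", "C4H6O5"),
    M("glx_c", "glyoxylate", "C2H2O3"),
    M("pyr_c", "pyruvate", "C3H4O3"),
    M("pep_c", "phosphoenolpyruvate", "C3H5O6P"),
    M("pg2_c", "2-phosphoglycerate", "C3H7O7P"),
    M("pg3_c", "3-phosphoglycerate", "C3H7O7P"),
    M("dpg13_c", "1,3-bisphosphoglycerate", "C3H8O10P2"),
    M("g3p_c", "glyceraldehyde 3-phosphate", "C3H7O6P"))

  R <- function(id, stoich, lb, ub, subsystem, exch = FALSE)
    list(id = id, stoich = stoich, lb = lb, ub = ub,
         subsystem = subsystem, is_exchange = exch)
  rxns <- list(
    ## exchanges and sinks (negative flux = uptake)
    R("EX_octa_e", c(octa_e = -1), -10, 0, "exchange", TRUE),
    R("EX_o2_e", c(o2_e = -1), -1000, 0, "exchange", TRUE),
    R("EX_co2_e", c(co2_e = -1), 0, 1000, "exchange", TRUE),
    R("EX_nh4_e", c(nh4_e = -1), -1000, 0, "exchange", TRUE),
    R("EX_pi_e", c(pi_e = -1), -1000, 0, "exchange", TRUE),
    R("EX_h2o_e", c(h2o_e = -1), -1000, 1000, "exchange", TRUE),
    R("EX_rha_e", c(rha_e = -1), 0, 1000, "exchange", TRUE),
    R("DM_pha_c", c(pha_c = -1), 0, 1000, "PHA cycle", TRUE),
    ## transport
    R("OCTAt", c(octa_e = -1, octa_c = 1), 0, 1000, "transport"),
    R("O2t", c(o2_e = -1, o2_c = 1), 0, 1000, "transport"),
    R("CO2t", c(co2_c = -1, co2_e = 1), 0, 1000, "transport"),
    R("NH4t", c(nh4_e = -1, nh4_c = 1), 0, 1000, "transport"),
    R("PIt", c(pi_e = -1, pi_c = 1), 0, 1000, "transport"),
    R("H2Ot", c(h2o_c = -1, h2o_e = 1), -1000, 1000, "transport"),
    R("RHAt", c(rha_c = -1, rha_e = 1), 0, 1000, "transport"),
    ## octanoate activation and beta-oxidation
    R("FACOAL80", c(octa_c = -1, coa_c = -1, atp_c = -1,
                    octcoa_c = 1, amp_c = 1, ppi_c = 1),
      0, 1000, "beta-oxidation"),
    R("PPA", c(ppi_c = -1, h2o_c = -1, pi_c = 2), 0, 1000, "energy"),
    R("ADK1", c(amp_c = -1, atp_c = -1, adp_c = 2), -1000, 1000, "energy"),
    R("ACOAD80", c(octcoa_c = -1, fad_c = -1, oct2coa_c = 1, fadh2_c = 1),
      0, 1000, "beta-oxidation"),
    R("RECOAH3", c(oct2coa_c = -1, h2o_c = -1, r3hocoa_c = 1),
      -1000, 1000, "PHA precursor supply"),
    R("ECOAH3", c(oct2coa_c = -1, h2o_c = -1, s3hocoa_c = 1),
      -1000, 1000, "beta-oxidation"),
    R("HACD3i", c(s3hocoa_c = -1, nad_c = -1, oxooctcoa_c = 1, nadh_c = 1),
      0, 1000, "beta-oxidation"),
    R("RHACOAR80", c(oxooctcoa_c = -1, nadph_c = -1,
                     r3hocoa_c = 1, nadp_c = 1),
      -1000, 1000, "PHA precursor supply"),
    R("KAT1", c(oxooctcoa_c = -1, coa_c = -1, hexcoa_c = 1, accoa_c = 1),
      0, 1000, "beta-oxidation"),
    R("BOXC6", c(hexcoa_c = -1, fad_c = -1, h2o_c = -1, nad_c = -1,
                 coa_c = -1, butcoa_c = 1, accoa_c = 1, fadh2_c = 1,
                 nadh_c = 1),
      0, 1000, "beta-oxidation"),
    R("BOXC4", c(butcoa_c = -1, fad_c = -1, h2o_c = -1, nad_c = -1,
                 coa_c = -1, accoa_c = 2, fadh2_c = 1, nadh_c = 1),
      0, 1000, "beta-oxidation"),
    ## PHA cycle
    R("PHAP2C80", c(r3hocoa_c = -1, pha_c = 1, coa_c = 1),
      0, 1000, "PHA cycle"),
    R("PHAZ", c(pha_c = -1, h2o_c = -1, rha_c = 1), 0, 1000, "PHA cycle"),
    R("FACOAL3HO", c(rha_c = -1, coa_c = -1, atp_c = -1,
                     r3hocoa_c = 1, amp_c = 1, ppi_c = 1),
      0, 1000, "PHA cycle"),
    ## TCA cycle
    R("CS", c(accoa_c = -1, oaa_c = -1, h2o_c = -1, cit_c = 1, coa_c = 1),
      0, 1000, "TCA cycle"),
    R("ACONTa", c(cit_c = -1, acon_c = 1, h2o_c = 1), -1000, 1000, "TCA cycle"),
    R("ACONTb", c(acon_c = -1, h2o_c = -1, icit_c = 1), -1000, 1000, "TCA cycle"),
    R("ICDHy", c(icit_c = -1, nadp_c = -1, akg_c = 1, co2_c = 1,
                 nadph_c = 1),
      0, 1000, "TCA cycle"),
    R("AKGDH", c(akg_c = -1, coa_c = -1, nad_c = -1, succoa_c = 1,
                 co2_c = 1, nadh_c = 1),
      0, 1000, "TCA cycle"),
    R("SUCOAS", c(succoa_c = -1, adp_c = -1, pi_c = -1, succ_c = 1,
                  coa_c = 1, atp_c = 1),
      -1000, 1000, "TCA cycle"),
    R("SUCDi", c(succ_c = -1, fad_c = -1, fum_c = 1, fadh2_c = 1),
      0, 1000, "TCA cycle"),
    R("FUM", c(fum_c = -1, h2o_c = -1, mal_c = 1), -1000, 1000, "TCA cycle"),
    R("MDH", c(mal_c = -1, nad_c = -1, oaa_c = 1, nadh_c = 1),
      -1000, 1000, "TCA cycle"),
    ## glyoxylate shunt
    R("ICL", c(icit_c = -1, succ_c = 1, glx_c = 1), 0, 1000, "glyoxylate shunt"),
    R("MALS", c(accoa_c = -1, glx_c = -1, h2o_c = -1, mal_c = 1, coa_c = 1),
      0, 1000, "glyoxylate shunt"),
    ## anaplerotic / pay-off routes
    R("ME2", c(mal_c = -1, nadp_c = -1, pyr_c = 1, co2_c = 1, nadph_c = 1),
      0, 1000, "anaplerosis"),
    R("PDH", c(pyr_c = -1, coa_c = -1, nad_c = -1, accoa_c = 1, co2_c = 1,
               nadh_c = 1),
      0, 1000, "pay-off"),
    ## gluconeogenic backbone
    R("PPCK", c(oaa_c = -1, atp_c = -1, pep_c = 1, co2_c = 1, adp_c = 1),
      0, 1000, "gluconeogenesis"),
    R("ENO", c(pg2_c = -1, pep_c = 1, h2o_c = 1), -1000, 1000, "gluconeogenesis"),
    R("PGM", c(pg2_c = -1, pg3_c = 1), -1000, 1000, "gluconeogenesis"),
    R("PGK", c(pg3_c = -1, atp_c = -1, dpg13_c = 1, adp_c = 1),
      -1000, 1000, "gluconeogenesis"),
    R("GAPD", c(g3p_c = -1, nad_c = -1, pi_c = -1, dpg13_c = 1, nadh_c = 1),
      -1000, 1000, "gluconeogenesis"),
    ## oxidative phosphorylation and energy
    R("NADHOP", c(nadh_c = -1, o2_c = -0.5, adp_c = -2, pi_c = -2,
                  nad_c = 1, atp_c = 2, h2o_c = 3),
      0, 1000, "oxidative phosphorylation"),
    R("FADHOP", c(fadh2_c = -1, o2_c = -0.5, adp_c = -1, pi_c = -1,
                  fad_c = 1, atp_c = 1, h2o_c = 2),
      0, 1000, "oxidative phosphorylation"),
    R("THD2", c(nadh_c = -1, nadp_c = -1, nad_c = 1, nadph_c = 1),
      -1000, 1000, "energy"),
    R("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1),
      0.92, 1000, "energy"),
    ## biomass: precursor drain, polymer-free (39 mmolC per gCDW)
    R("BIOMASS_core", c(accoa_c = -5, oaa_c = -2, akg_c = -1.5,
                        g3p_c = -4.5, nadph_c = -10, nh4_c = -8,
                        atp_c = -40, h2o_c = -35,
                        coa_c = 5, nadp_c = 10, adp_c = 40, pi_c = 40),
      0, 1000, "biomass"))
  m <- metabolic_model(mets, rxns, "BIOMASS_core", name = "pha_core")
  m
}

#' Run code with a temporary RNG seed
#'
#' Evaluates an expression under \code{set.seed(seed)} and restores the
#' caller's RNG state afterwards, so generator and sampler seeds never leak
#' into global state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
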