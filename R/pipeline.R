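# End-to-end orchestration: physiology -> condition models -> FBA
# validation -> polytope sampling -> median-flux comparison -> dFBA
# trajectory, with a manifest recording seeds and diagnostics.

#' Default strain-specific reaction knockouts
#'
#' Maps engineered-strain labels to the core-model reactions deleted in
#' them: the depolymerase deletion strain loses the depolymerase (and with
#' it monomer reactivation stays intact but unfed); the whole-cluster
#' deletion loses polymerase, depolymerase and monomer reactivation.
#'
#' @return named list, strain -> character vector of reaction ids.
#' @export
default_strain_knockouts <- function() {
  list(KT40Z = "PHAZ",
       KT2440_dpha = c("PHAP2C80", "PHAZ", "FACOAL3HO"))
}

#' Assemble a pipeline run configuration
#'
#' @param model a \code{metabolic_model} or path to a model file.
#' @param timecourses named list (strain -> \code{physio_timecourse} or
#'   CSV path).
#' @param boundaries interior phase boundaries, h.
#' @param tolerance constraint band half-width.
#' @param n_samples,thinning sampler configuration per condition model.
#' @param seed master seed; per-condition seeds are derived from it.
#' @param thresholds comparison ratio thresholds \code{c(lower, upper)}.
#' @param reference reference strain for flux ratios.
#' @param knockouts named list strain -> reaction ids to disable; defaults
#'   to \code{\link{default_strain_knockouts}} entries for known strains.
#' @param dt dFBA step, h.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(model, timecourses, boundaries = c(5, 10),
                       tolerance = 0.05, n_samples = 5000, thinning = 100,
                       seed = 1, thresholds = c(1 / 1.2, 1.2),
                       reference = "KT2440",
                       knockouts = default_strain_knockouts(),
                       dt = 0.01, out_dir = NULL) {
  if (is.character(model)) model <- load_model(model)
  timecourses <- lapply(timecourses, function(tc)
    if (is.character(tc)) read_timecourse(tc) else tc)
  if (is.null(names(timecourses)) || any(!nzchar(names(timecourses))))
    stop("timecourses must be a named list (strain -> time course)")
  structure(list(model = model, timecourses = timecourses,
                 boundaries = boundaries, tolerance = tolerance,
                 n_samples = n_samples, thinning = thinning, seed = seed,
                 thresholds = thresholds, reference = reference,
                 knockouts = knockouts, dt = dt, out_dir = out_dir),
            class = "run_config")
}

#' Run the full contextualization pipeline
#'
#' For every strain and growth phase: builds phase rates, a
#' condition-specific model and its FBA validation report, samples the
#' flux polytope and records median fluxes plus the mixed-fraction
#' diagnostic; then compares every non-reference strain to the reference
#' per phase and simulates each strain's full growth curve by dFBA.  A
#' manifest records package version, seeds and diagnostics.  Stage
#' failures abort with a stage-labelled error.  Reruns with the same
#' configuration are deterministic.
#'
#' @param cfg a \code{run_config}.
#' @return list of class \code{phaflux_run} with elements
#'   \code{conditions} (per strain x phase), \code{comparisons},
#'   \code{trajectories}, and \code{manifest}.
#' @export
run_contextualization <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", what, "] failed: ", conditionMessage(e), call. = FALSE))
  }
  strains <- names(cfg$timecourses)
  conditions <- list()
  trajectories <- list()
  idx <- 0L
  t0 <- proc.time()[["elapsed"]]
  for (si in seq_along(strains)) {
    strain <- strains[si]
    tc <- cfg$timecourses[[strain]]
    model <- cfg$model
    for (ko in cfg$knockouts[[strain]] %||% character(0))
      model <- stage(paste0(strain, "/knockout"), knockout(model, ko))
    phases <- stage(paste0(strain, "/phases"), segment_phases(tc, cfg$boundaries))
    rates_list <- list()
    for (pi in seq_along(phases)) {
      idx <- idx + 1L
      ph <- phases[[pi]]
      key <- paste0(strain, ".", ph$label)
      rates <- stage(paste0(key, "/rates"), build_phase_rates(tc, ph))
      rates_list[[pi]] <- rates
      cm <- stage(paste0(key, "/constraints"),
                  apply_phase_constraints(model, rates, cfg$tolerance,
                                          strain = strain))
      sol <- stage(paste0(key, "/fba"), fba(cm))
      report <- stage(paste0(key, "/validate"),
                      validate_phase(cm, sol, rates, threshold = cfg$tolerance + 1e-9))
      cond_seed <- (cfg$seed + 101L * si + 7L * pi) %% .Machine$integer.max
      samples <- stage(paste0(key, "/sampling"),
                       achr_sample(cm, n_samples = cfg$n_samples,
                                   seed = cond_seed, thinning = cfg$thinning))
      stage(paste0(key, "/feasibility"), assert_samples_feasible(samples, cm))
      conditions[[key]] <- list(
        strain = strain, phase = ph, rates = rates, condition_model = cm,
        fba = sol, validation = report, samples = samples,
        medians = median_fluxes(samples),
        mixed_fraction = mixed_fraction(samples),
        seed = cond_seed)
    }
    y0 <- list(residual_biomass = rates_list[[1]]$initial_residual_biomass,
               pha = 0, ha = 0, octanoate = tc$octanoate[1])
    trajectories[[strain]] <- stage(
      paste0(strain, "/dfba"),
      simulate_batch(model, rates_list, y0, dt = cfg$dt))
  }
  comparisons <- list()
  if (cfg$reference %in% strains) {
    ref_keys <- grep(paste0("^", cfg$reference, "\\."), names(conditions),
                     value = TRUE)
    for (strain in setdiff(strains, cfg$reference)) {
      for (rk in ref_keys) {
        lab <- sub("^.*\\.", "", rk)
        mk <- paste0(strain, ".", lab)
        if (!mk %in% names(conditions)) next
        comparisons[[paste0(strain, "_vs_", cfg$reference, ".", lab)]] <-
          stage(paste0(mk, "/compare"),
                compare_strains(conditions[[mk]]$samples,
                                conditions[[rk]]$samples,
                                thresholds = cfg$thresholds))
      }
    }
  }
  manifest <- list(
    package = "phaflux",
    version = as.character(utils::packageVersion("phaflux")),
    seed = cfg$seed,
    tolerance = cfg$tolerance,
    n_samples = cfg$n_samples,
    thinning = cfg$thinning,
    boundaries = cfg$boundaries,
    reference = cfg$reference,
    strains = strains,
    condition_seeds = lapply(conditions, `[[`, "seed"),
    mixed_fractions = lapply(conditions, `[[`, "mixed_fraction"),
    elapsed_s = proc.time()[["elapsed"]] - t0)
  run <- structure(list(conditions = conditions, comparisons = comparisons,
                        trajectories = trajectories, manifest = manifest),
                   class = "phaflux_run")
  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir, cfg$model)
  run
}

#' Write pipeline artifacts to a directory
#'
#' Emits, per condition model, the median flux table and validation
#' report; per comparison, the classified ratio table; per strain, the
#' dFBA trajectory; plus a JSON manifest.
#'
#' @param run a \code{phaflux_run}.
#' @param dir output directory (created if missing).
#' @param model the base model (for subsystem annotations).
#' @return \code{dir}, invisibly.
#' @export
write_run <- function(run, dir, model) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(run$conditions)) {
    cond <- run$conditions[[key]]
    write_flux_tsv(cond$medians, model,
                   file.path(dir, paste0("medians_", key, ".tsv")))
    utils::write.table(cond$validation,
                       file.path(dir, paste0("validation_", key, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (key in names(run$comparisons))
    utils::write.table(run$comparisons[[key]],
                       file.path(dir, paste0("comparison_", key, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (strain in names(run$trajectories))
    write_trajectory(run$trajectories[[strain]],
                     file.path(dir, paste0("trajectory_", strain, ".tsv")))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.phaflux_run <- function(x, ...) {
  cat("phaflux_run: ", length(x$conditions), " condition models, ",
      length(x$comparisons), " comparisons, ",
      length(x$trajectories), " dFBA trajectories\n", sep = "")
  mf <- unlist(x$manifest$mixed_fractions)
  if (length(mf))
    cat("mixed fractions: ",
        paste(names(mf), round(mf, 3), sep = "=", collapse = ", "), "\n",
        sep = "")
  invisible(x)
}
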