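# Shared fixtures: condition models are expensive enough to build once.

core_model_fixture <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- core_pha_model()
    m
  }
})

# noiseless time course for one archetype
noiseless_tc <- function(strain = "KT2440", seed = 1) {
  arch <- builtin_archetypes()[[strain]]
  arch$noise_cv <- 0
  make_strain_timecourse(arch, seed = seed)
}

# condition model for strain x phase label from a (default noiseless) course
condition_fixture <- function(strain, phase_label, tolerance = 0.05,
                              noise = FALSE, seed = 1) {
  arch <- builtin_archetypes()[[strain]]
  if (!noise) arch$noise_cv <- 0
  tc <- make_strain_timecourse(arch, seed = seed)
  model <- core_model_fixture()
  for (ko in default_strain_knockouts()[[strain]])
    model <- knockout(model, ko)
  phases <- segment_phases(tc)
  ph <- phases[[which(vapply(phases, function(p) p$label, "") == phase_label)]]
  apply_phase_constraints(model, build_phase_rates(tc, ph),
                          tolerance = tolerance, strain = strain)
}

# brute-force FBA oracle: maximum objective over enumerated vertices
vertex_fba_oracle <- function(model) {
  S <- stoichiometric_matrix(model)
  b <- reaction_bounds(model)
  V <- phaflux:::enumerate_vertices(S, b[, "lb"], b[, "ub"])
  obj <- as.numeric(colnames(S) == model$objective_id)
  max(V %*% obj)
}

# rejection-sampling oracle for uniform points on {S v = 0, lb <= v <= ub}
# parameterized by the free coordinates given in `free` (named list of
# c(lb, ub)); `lift` maps a draw of the free coordinates to the full vector.
rejection_oracle <- function(n, free, lift, seed) {
  phaflux:::with_seed(seed, {
    draws <- vapply(free, function(rng) stats::runif(n, rng[1], rng[2]),
                    numeric(n))
    if (is.null(dim(draws))) draws <- matrix(draws, nrow = n)
    t(apply(draws, 1, lift))
  })
}
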