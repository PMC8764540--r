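# Data structures and I/O for constraint-based metabolic models.
#
# A model is a plain list of metabolites and reactions with a designated
# biomass objective.  The JSON dialect mirrors the community COBRA layout
# (metabolites / reactions with a metabolite->coefficient map and
# lower_bound / upper_bound fields) so externally curated models load
# unchanged; only the fields documented in `load_model` are honoured.
#
# Sign convention: for exchange reactions negative flux is uptake and
# positive flux is secretion.  Report-facing "uptake rates" are positive
# magnitudes.

#' Construct a metabolic model
#'
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{formula}, \code{compartment}. \code{formula} may be \code{NA}.
#' @param reactions list of reactions, each a list with fields \code{id},
#'   \code{stoich} (named numeric, metabolite id -> signed coefficient),
#'   \code{lb}, \code{ub} (mmol/gCDW/h), \code{subsystem} and
#'   \code{is_exchange}.
#' @param objective_id id of the biomass (objective) reaction.
#' @param name model label.
#' @return object of class \code{metabolic_model}.
#' @export
metabolic_model <- function(metabolites, reactions, objective_id, name = "model") {
  names(reactions) <- vapply(reactions, function(r) r$id, character(1))
  m <- structure(
    list(metabolites = metabolites, reactions = reactions,
         objective_id = objective_id, name = name),
    class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate the structural invariants of a metabolic model
#'
#' Checks id uniqueness, bound ordering, that every stoichiometry key
#' resolves to a declared metabolite, that exchange reactions touch exactly
#' one metabolite, and that the objective reaction exists.
#'
#' @param model a \code{metabolic_model}.
#' @return the model, invisibly; errors describe the offending element.
#' @export
validate_model <- function(model) {
  met_ids <- model$metabolites$id
  if (anyDuplicated(met_ids))
    stop("duplicate metabolite id(s): ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  rxn_ids <- vapply(model$reactions, function(r) r$id, character(1))
  if (anyDuplicated(rxn_ids))
    stop("duplicate reaction id(s): ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  for (r in model$reactions) {
    if (!length(r$stoich))
      stop("reaction '", r$id, "' has empty stoichiometry")
    unknown <- setdiff(names(r$stoich), met_ids)
    if (length(unknown))
      stop("reaction '", r$id, "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    if (!is.finite(r$lb) || !is.finite(r$ub))
      stop("reaction '", r$id, "' has non-finite bounds")
    if (r$lb > r$ub)
      stop("reaction '", r$id, "' has lb > ub")
    if (isTRUE(r$is_exchange) && length(r$stoich) != 1L)
      stop("exchange reaction '", r$id, "' must touch exactly one metabolite")
  }
  if (!model$objective_id %in% rxn_ids)
    stop("objective reaction '", model$objective_id, "' not in model")
  invisible(model)
}

#' Stoichiometric matrix of a model
#'
#' @param model a \code{metabolic_model}.
#' @return dense numeric matrix, metabolites in rows, reactions in columns.
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- names(model$reactions)
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoich
    S[names(st), j] <- as.numeric(st)
  }
  S
}

#' Reaction bounds as a two-column matrix
#' @param model a \code{metabolic_model}.
#' @return matrix with columns \code{lb}, \code{ub} and reaction-id rownames.
#' @export
reaction_bounds <- function(model) {
  cbind(lb = vapply(model$reactions, function(r) r$lb, numeric(1)),
        ub = vapply(model$reactions, function(r) r$ub, numeric(1)))
}

#' Set bounds on one reaction
#' @param model a \code{metabolic_model}.
#' @param reaction_id reaction to modify.
#' @param lb,ub new bounds; \code{NULL} leaves a bound untouched.
#' @return modified copy of the model.
#' @export
set_bounds <- function(model, reaction_id, lb = NULL, ub = NULL) {
  if (!reaction_id %in% names(model$reactions))
    stop("unknown reaction id '", reaction_id, "'")
  if (!is.null(lb)) model$reactions[[reaction_id]]$lb <- lb
  if (!is.null(ub)) model$reactions[[reaction_id]]$ub <- ub
  validate_model(model)
  model
}

#' Knock out a reaction
#'
#' Returns a copy of the model with both bounds of the reaction clamped to
#' zero; the input model is not modified.
#'
#' @param model a \code{metabolic_model}.
#' @param reaction_id reaction to disable.
#' @return modified copy of the model.
#' @export
knockout <- function(model, reaction_id) {
  if (!reaction_id %in% names(model$reactions))
    stop("unknown reaction id '", reaction_id, "'")
  model$reactions[[reaction_id]]$lb <- 0
  model$reactions[[reaction_id]]$ub <- 0
  model
}

#' Parse an elemental formula
#'
#' Parses e.g. \code{"C8H16O2"} into a named vector of non-negative integer
#' element counts.
#'
#' @param formula character formula.
#' @return named integer vector of element counts.
#' @keywords internal
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  toks <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  pieces <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(pieces) || sum(nchar(pieces)) != nchar(formula))
    stop("cannot parse formula '", formula, "'")
  el <- sub("[0-9]*$", "", pieces)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", pieces),
                           sub("^[A-Za-z]+", "", pieces), "1"))
  tapply(cnt, el, sum)
}

#' Check elemental balance of interior reactions
#'
#' A reaction is reported as unbalanced when the net stoichiometric sum of
#' any element exceeds 1e-9 in absolute value.  Exchange reactions and the
#' biomass (objective) reaction are exempt, as are explicit sink/demand
#' reactions touching a single metabolite.
#'
#' @param model a \code{metabolic_model}; formulas must be present on every
#'   metabolite participating in a checked reaction.
#' @return character vector of unbalanced reaction ids (empty when clean).
#' @export
check_mass_balance <- function(model) {
  formulas <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  bad <- character(0)
  for (r in model$reactions) {
    if (isTRUE(r$is_exchange) || length(r$stoich) == 1L) next
    if (r$id == model$objective_id) next
    net <- numeric(0)
    for (met in names(r$stoich)) {
      f <- formulas[[met]]
      if (is.na(f) || !nzchar(f))
        stop("metabolite '", met, "' in reaction '", r$id,
             "' has no formula; cannot check balance")
      counts <- parse_formula(f)
      for (el in names(counts)) {
        net[el] <- (if (el %in% names(net)) net[[el]] else 0) +
          r$stoich[[met]] * counts[[el]]
      }
    }
    if (any(abs(net) > 1e-9)) bad <- c(bad, r$id)
  }
  bad
}

#' Flux balance analysis
#'
#' Maximizes the objective reaction flux subject to the steady-state
#' constraint \code{S v = 0} and the reaction bounds.  Deterministic for a
#' fixed model.  Condition models (see
#' \code{\link{apply_phase_constraints}}) are solved with their overridden
#' bounds.
#'
#' @param model a \code{metabolic_model} or \code{condition_model}.
#' @return object of class \code{flux_solution}: \code{status} one of
#'   "optimal", "infeasible", "unbounded"; \code{objective_value} (1/h for a
#'   biomass objective); named \code{fluxes} (mmol/gCDW/h); and the solver
#'   feasibility \code{tolerance}.
#' @export
fba <- function(model) {
  base <- as_metabolic_model(model)
  S <- stoichiometric_matrix(base)
  bnds <- reaction_bounds(base)
  obj <- as.numeric(names(base$reactions) == base$objective_id)
  res <- lp_solve(obj, S, rep(0, nrow(S)), bnds[, "lb"], bnds[, "ub"])
  status <- res$status
  if (status == "maxit") status <- "infeasible"
  fluxes <- if (status == "optimal")
    stats::setNames(res$x, names(base$reactions))
  else NULL
  structure(list(status = status,
                 objective_value = if (status == "optimal") res$objective else NA_real_,
                 fluxes = fluxes, tolerance = 1e-9),
            class = "flux_solution")
}

#' Coerce to a plain metabolic model
#' @param x a \code{metabolic_model} or \code{condition_model}.
#' @return a \code{metabolic_model} with any condition bounds applied.
#' @export
as_metabolic_model <- function(x) {
  if (inherits(x, "condition_model")) {
    m <- x$base
    for (id in names(x$applied_bounds)) {
      m$reactions[[id]]$lb <- x$applied_bounds[[id]][1]
      m$reactions[[id]]$ub <- x$applied_bounds[[id]][2]
    }
    return(m)
  }
  if (!inherits(x, "metabolic_model"))
    stop("expected a metabolic_model or condition_model")
  x
}

#' Load a metabolic model from JSON or SBML
#'
#' The JSON dialect is the canonical format; the honoured fields are
#' \code{name}, \code{objective} (or a reaction-level
#' \code{objective_coefficient} of 1), \code{metabolites[].id/name/formula/
#' compartment} and \code{reactions[].id/metabolites/lower_bound/
#' upper_bound/subsystem/is_exchange}.  When \code{is_exchange} is absent it
#' is inferred for single-metabolite reactions.  SBML (Level 3 with the fbc
#' package) is read-only, best effort, and requires the \pkg{xml2} package.
#'
#' @param path file path.
#' @param format "json" or "sbml"; guessed from the extension by default.
#' @return a validated \code{metabolic_model}.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "json") load_model_json(path) else load_model_sbml(path)
}

load_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed model JSON in '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("malformed model JSON: missing 'metabolites' or 'reactions' element")
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) m$id %||% stop("metabolite without id"), character(1)),
    name = vapply(doc$metabolites, function(m) m$name %||% "", character(1)),
    formula = vapply(doc$metabolites, function(m) m$formula %||% NA_character_, character(1)),
    compartment = vapply(doc$metabolites, function(m) m$compartment %||% "c", character(1)),
    stringsAsFactors = FALSE)
  objective <- doc$objective
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction without id in '", path, "'")
    st <- unlist(r$metabolites)
    if (!length(st)) stop("reaction '", r$id, "' has empty stoichiometry")
    list(id = r$id,
         stoich = st,
         lb = as.numeric(r$lower_bound %||% -1000),
         ub = as.numeric(r$upper_bound %||% 1000),
         subsystem = r$subsystem %||% "",
         is_exchange = isTRUE(r$is_exchange) ||
           (is.null(r$is_exchange) && length(st) == 1L &&
              grepl("^(EX_|DM_|SK_)", r$id)))
  })
  if (is.null(objective)) {
    oc <- vapply(doc$reactions, function(r)
      as.numeric(r$objective_coefficient %||% 0), numeric(1))
    if (any(oc != 0)) objective <- rxns[[which(oc != 0)[1]]]$id
  }
  if (is.null(objective)) stop("model JSON declares no objective reaction")
  metabolic_model(mets, rxns, objective, name = doc$name %||% "model")
}

load_model_sbml <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("SBML input requires the 'xml2' package")
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")), "", xml2::xml_attr(sp, "name")),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    compartment = ifelse(is.na(xml2::xml_attr(sp, "compartment")), "c",
                         xml2::xml_attr(sp, "compartment")),
    stringsAsFactors = FALSE)
  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- lapply(rx, function(node) {
    id <- xml2::xml_attr(node, "id")
    get_side <- function(tag, sign) {
      refs <- xml2::xml_find_all(node, paste0("./", tag, "/speciesReference"))
      stats::setNames(sign * as.numeric(ifelse(is.na(xml2::xml_attr(refs, "stoichiometry")),
                                               "1", xml2::xml_attr(refs, "stoichiometry"))),
                      xml2::xml_attr(refs, "species"))
    }
    st <- c(get_side("listOfReactants", -1), get_side("listOfProducts", 1))
    lbp <- xml2::xml_attr(node, "lowerFluxBound")
    ubp <- xml2::xml_attr(node, "upperFluxBound")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb <- if (!is.na(lbp) && lbp %in% names(parval)) parval[[lbp]] else if (rev) -1000 else 0
    ub <- if (!is.na(ubp) && ubp %in% names(parval)) parval[[ubp]] else 1000
    list(id = id, stoich = st, lb = min(lb, ub), ub = max(lb, ub),
         subsystem = "", is_exchange = length(st) == 1L)
  })
  objref <- xml2::xml_find_first(doc, ".//listOfObjectives//fluxObjective")
  objective <- if (!inherits(objref, "xml_missing"))
    xml2::xml_attr(objref, "reaction")
  else stop("SBML file declares no flux objective")
  nm <- xml2::xml_attr(xml2::xml_find_first(doc, ".//model"), "id")
  metabolic_model(mets, rxns, objective, name = nm %||% "model")
}

#' Write a metabolic model to the canonical JSON dialect
#'
#' \code{load_model(write_model(m))} preserves ids, bounds and coefficients
#' exactly.
#'
#' @param model a \code{metabolic_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path) {
  doc <- list(
    name = model$name,
    objective = model$objective_id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      row <- model$metabolites[i, ]
      out <- list(id = row$id, name = row$name, compartment = row$compartment)
      if (!is.na(row$formula)) out$formula <- row$formula
      out
    }),
    reactions = unname(lapply(model$reactions, function(r) {
      list(id = r$id, metabolites = as.list(r$stoich),
           lower_bound = r$lb, upper_bound = r$ub,
           subsystem = r$subsystem, is_exchange = isTRUE(r$is_exchange))
    })))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a flux table as TSV
#'
#' @param fluxes named numeric vector of fluxes.
#' @param model the model the fluxes belong to (for subsystem labels).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_flux_tsv <- function(fluxes, model, path) {
  subsys <- vapply(model$reactions[names(fluxes)],
                   function(r) r$subsystem %||% "", character(1))
  utils::write.table(
    data.frame(reaction = names(fluxes), subsystem = subsys,
               value = as.numeric(fluxes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model '", x$name, "': ",
      nrow(x$metabolites), " metabolites x ",
      length(x$reactions), " reactions; objective ", x$objective_id, "\n",
      sep = "")
  invisible(x)
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution: status", x$status)
  if (x$status == "optimal")
    cat(", objective", format(x$objective_value, digits = 6))
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
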