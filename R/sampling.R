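# Uniform sampling of the flux polytope by artificial-centering
# hit-and-run (ACHR), with mixing diagnostics, median-flux summaries and
# mutant/wild-type comparisons.
#
# Directions are differences between stored points and the running center,
# so every move stays in the null space of S and feasibility reduces to
# the chord intersection with the bound box.  Points are re-projected onto
# the steady-state subspace periodically to keep accumulated roundoff far
# below the feasibility tolerance.

#' Warmup points on the flux polytope
#'
#' Generates feasible extreme-ish points by optimizing coordinate
#' objectives (+/- each reaction, for small models) and, beyond that,
#' random +/-1 objective vectors.  All points satisfy the steady-state and
#' bound constraints.
#'
#' @param cm a \code{condition_model} or \code{metabolic_model}.
#' @param n number of warmup points (default twice the reaction count).
#' @param seed seed for the random objectives (used only when
#'   \code{n > 2 * n_reactions}).
#' @return matrix (n x n_reactions) of feasible flux vectors.
#' @export
warmup_points <- function(cm, n = NULL, seed = 1) {
  model <- as_metabolic_model(cm)
  S <- stoichiometric_matrix(model)
  bnds <- reaction_bounds(model)
  nr <- nrow(bnds)
  if (is.null(n)) n <- 2L * nr
  stopifnot(n >= 2)
  objs <- matrix(0, nr, min(n, 2L * nr))
  for (j in seq_len(ncol(objs)))
    objs[(j + 1) %/% 2, j] <- if (j %% 2 == 1) 1 else -1
  if (n > 2L * nr) {
    extra <- with_seed(seed, matrix(sample(c(-1, 1), nr * (n - 2L * nr),
                                           replace = TRUE), nr))
    objs <- cbind(objs, extra)
  }
  pts <- matrix(NA_real_, n, nr, dimnames = list(NULL, rownames(bnds)))
  for (j in seq_len(n)) {
    res <- lp_solve(objs[, j], S, rep(0, nrow(S)), bnds[, "lb"], bnds[, "ub"])
    if (res$status != "optimal")
      stop("model infeasible: warmup objective ", j, " returned ", res$status)
    pts[j, ] <- res$x
  }
  pts
}

#' Sample the flux polytope by artificial-centering hit-and-run
#'
#' Classic ACHR: at each step the direction is the difference between a
#' randomly chosen stored point and the running center of all stored
#' points, the feasible chord along that direction is computed from the
#' bounds, and the next point is uniform on the chord.  The chain is
#' seeded with warmup points, advanced \code{n_samples * thinning} steps,
#' and every \code{thinning}-th point is kept.  Bit-reproducible for a
#' fixed seed and configuration.
#'
#' @param cm a \code{condition_model} or \code{metabolic_model}.
#' @param n_samples number of points to keep.
#' @param seed integer seed.
#' @param thinning chain steps per kept point.
#' @param n_warmup number of warmup points (default \code{2 * n_reactions}).
#' @param warmup optional precomputed warmup matrix.
#' @return object of class \code{flux_sample_set}: \code{points}
#'   (n_samples x n_reactions), \code{reaction_ids}, \code{seed},
#'   \code{n_warmup}, \code{thinning}, \code{chain_length}.
#' @export
achr_sample <- function(cm, n_samples = 5000, seed = 1, thinning = 100,
                        n_warmup = NULL, warmup = NULL) {
  stopifnot(n_samples >= 1, thinning >= 1)
  model <- as_metabolic_model(cm)
  S <- stoichiometric_matrix(model)
  bnds <- reaction_bounds(model)
  lb <- bnds[, "lb"]; ub <- bnds[, "ub"]
  nr <- length(lb)
  if (is.null(warmup)) warmup <- warmup_points(cm, n_warmup, seed = seed)
  n_keep_dirs <- nrow(warmup)
  ## orthonormal basis projection used to scrub roundoff drift off S v = 0
  qrS <- qr(t(S))
  project <- function(v) v - qr.fitted(qrS, v)

  pts <- matrix(NA_real_, n_samples, nr, dimnames = list(NULL, names(lb)))
  with_seed(seed, {
    store <- warmup
    center <- colMeans(store)
    cur <- center
    n_store <- nrow(store)
    total <- n_samples * thinning
    kept <- 0L
    for (step in seq_len(total)) {
      ok <- FALSE
      for (try in 1:50) {
        pick <- store[sample.int(n_store, 1L), ]
        d <- pick - center
        nd <- sqrt(sum(d * d))
        if (nd < 1e-12) next
        d <- d / nd
        lo <- -Inf; hi <- Inf
        live <- abs(d) > 1e-11
        if (any(live)) {
          dl <- d[live]
          room_up <- (ub[live] - cur[live]) / dl
          room_dn <- (lb[live] - cur[live]) / dl
          hi <- min(pmax(room_up, room_dn))
          lo <- max(pmin(room_up, room_dn))
        }
        if (!is.finite(lo) || !is.finite(hi) || hi - lo < 1e-12) next
        alpha <- stats::runif(1, lo, hi)
        cur <- cur + alpha * d
        ok <- TRUE
        break
      }
      if (!ok)
        stop("ACHR could not find a usable chord after 50 direction resamples")
      if (step %% 997L == 0L) {
        cur <- project(cur)
        cur <- pmin(pmax(cur, lb), ub)
      }
      ## running center over everything generated so far
      center <- center + (cur - center) / (n_store + step)
      if (step %% thinning == 0L) {
        kept <- kept + 1L
        pts[kept, ] <- cur
      }
    }
  })
  structure(list(points = pts, reaction_ids = names(lb), seed = seed,
                 n_warmup = nrow(warmup), thinning = thinning,
                 chain_length = n_samples * thinning),
            class = "flux_sample_set")
}

#' Check sample feasibility
#'
#' Asserts that every point satisfies \code{S v = 0} within \code{tol_sv}
#' and the bounds within \code{tol_bound}.
#'
#' @param s a \code{flux_sample_set}.
#' @param cm the model it was drawn from.
#' @param tol_sv,tol_bound tolerances.
#' @return TRUE invisibly; errors with the worst violation otherwise.
#' @export
assert_samples_feasible <- function(s, cm, tol_sv = 1e-6, tol_bound = 1e-8) {
  model <- as_metabolic_model(cm)
  S <- stoichiometric_matrix(model)
  bnds <- reaction_bounds(model)
  sv <- max(abs(S %*% t(s$points)))
  lo <- max(0, max(sweep(s$points, 2, bnds[, "lb"]) * -1))
  hi <- max(0, max(sweep(s$points, 2, bnds[, "ub"])))
  if (sv > tol_sv)
    stop("sample violates S v = 0 by ", format(sv))
  if (max(lo, hi) > tol_bound)
    stop("sample violates bounds by ", format(max(lo, hi)))
  invisible(TRUE)
}

#' Mixed-fraction mixing diagnostic
#'
#' Splits the kept chain into halves, pairs the i-th first-half point with
#' the i-th second-half point and, per reaction, counts the fraction of
#' pairs lying on opposite sides of that reaction's overall sample median.
#' The mean over non-constant reactions is returned; 0.5 indicates perfect
#' mixing (independent halves), values near 0 or 1 indicate a slowly
#' moving chain.
#'
#' @param s a \code{flux_sample_set} with at least 2 points.
#' @return scalar mixed fraction, or \code{NA} (with a warning) when every
#'   reaction is constant across the sample set.
#' @export
mixed_fraction <- function(s) {
  pts <- s$points
  n <- nrow(pts)
  if (n < 2) stop("mixed fraction needs a chain of length >= 2")
  half <- n %/% 2
  a <- pts[seq_len(half), , drop = FALSE]
  b <- pts[half + seq_len(half), , drop = FALSE]
  fracs <- vapply(seq_len(ncol(pts)), function(j) {
    col <- pts[, j]
    if (max(col) - min(col) <= 1e-9) return(NA_real_)
    med <- stats::median(col)
    mean((a[, j] < med & b[, j] > med) | (a[, j] > med & b[, j] < med))
  }, numeric(1))
  if (all(is.na(fracs))) {
    warning("all reactions constant across the sample set; mixed fraction undefined")
    return(NA_real_)
  }
  mean(fracs, na.rm = TRUE)
}

#' Per-reaction median fluxes
#'
#' The median of the sampled flux distribution is used as the most
#' probable flux value for each reaction.
#'
#' @param s a \code{flux_sample_set}.
#' @return named numeric vector of medians (mmol/gCDW/h).
#' @export
median_fluxes <- function(s) {
  stats::setNames(apply(s$points, 2, stats::median), s$reaction_ids)
}

#' Compare median flux distributions of two strains
#'
#' Per reaction, takes the ratio of the sample medians (a / b, typically
#' mutant / wild type) and classifies the reaction as \code{increased}
#' (ratio above the upper threshold), \code{reduced} (below the lower
#' threshold), \code{unaffected} (between), or \code{undefined} (the
#' reference median is below the floor in magnitude, making the ratio
#' meaningless).  Ratios are of signed net fluxes.
#'
#' @param a,b \code{flux_sample_set}s over identical reaction lists.
#' @param thresholds \code{c(lower, upper)} ratio thresholds; the defaults
#'   1/1.2 and 1.2 are symmetric on the log scale.
#' @param floor magnitude below which the reference median counts as zero.
#' @return data.frame (class \code{flux_comparison}) with reaction,
#'   median_a, median_b, ratio and class.
#' @export
compare_strains <- function(a, b, thresholds = c(1 / 1.2, 1.2),
                            floor = 1e-6) {
  if (!identical(a$reaction_ids, b$reaction_ids)) {
    d <- c(setdiff(a$reaction_ids, b$reaction_ids),
           setdiff(b$reaction_ids, a$reaction_ids))
    stop("sample sets cover different reactions: ", paste(d, collapse = ", "))
  }
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  ma <- median_fluxes(a)
  mb <- median_fluxes(b)
  ratio <- ifelse(abs(mb) < floor, NA_real_, ma / mb)
  cls <- ifelse(abs(mb) < floor, "undefined",
         ifelse(ratio > thresholds[2], "increased",
         ifelse(ratio < thresholds[1], "reduced", "unaffected")))
  out <- data.frame(reaction = a$reaction_ids, median_a = unname(ma),
                    median_b = unname(mb), ratio = unname(ratio),
                    class = unname(cls), stringsAsFactors = FALSE)
  class(out) <- c("flux_comparison", "data.frame")
  out
}

#' Named summary reports over median fluxes
#'
#' \code{atp_production_summary}: sum of the positive ATP contributions of
#' every reaction's median flux, excluding the ATP maintenance drain --
#' i.e. total median ATP synthesis.  \code{respiration_summary}: magnitude
#' of the oxygen-exchange median.  \code{co2_production_summary}: the
#' CO2-exchange median.  Each definition is deliberately small and named
#' so users can swap it.
#'
#' @param s a \code{flux_sample_set}.
#' @param model the model sampled.
#' @param atp_id,atpm_id,o2_ex,co2_ex species/reaction ids (core-model
#'   defaults).
#' @return scalar summary value (mmol/gCDW/h).
#' @export
atp_production_summary <- function(s, model, atp_id = "atp_c",
                                   atpm_id = "ATPM") {
  med <- median_fluxes(s)
  S <- stoichiometric_matrix(as_metabolic_model(model))
  if (!atp_id %in% rownames(S)) stop("no metabolite '", atp_id, "' in model")
  contrib <- S[atp_id, ] * med[colnames(S)]
  contrib <- contrib[names(contrib) != atpm_id]
  sum(pmax(contrib, 0))
}

#' @rdname atp_production_summary
#' @export
respiration_summary <- function(s, model, o2_ex = "EX_o2_e") {
  abs(median_fluxes(s)[[o2_ex]])
}

#' @rdname atp_production_summary
#' @export
co2_production_summary <- function(s, model, co2_ex = "EX_co2_e") {
  median_fluxes(s)[[co2_ex]]
}

#' Write a sample set as TSV with a YAML sidecar
#'
#' @param s a \code{flux_sample_set}.
#' @param path TSV output path; the sidecar is written to
#'   \code{paste0(path, ".yaml")}.
#' @param diagnostics optional named list merged into the sidecar.
#' @return \code{path}, invisibly.
#' @export
write_sample_set <- function(s, path, diagnostics = list()) {
  utils::write.table(as.data.frame(s$points), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- c(list(seed = s$seed, n_warmup = s$n_warmup,
                 thinning = s$thinning, chain_length = s$chain_length,
                 n_samples = nrow(s$points)),
            diagnostics)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @export
print.flux_sample_set <- function(x, ...) {
  cat("flux_sample_set: ", nrow(x$points), " points x ",
      ncol(x$points), " reactions (seed ", x$seed, ", thinning ",
      x$thinning, ")\n", sep = "")
  invisible(x)
}
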