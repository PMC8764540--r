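test_that("warmup points hit both endpoints of a 1-D polytope", {
  m <- make_toy_model("interval")
  w <- warmup_points(m)
  thru <- w[, "SRC_A"]
  expect_equal(min(thru), 0, tolerance = 1e-9)
  expect_equal(max(thru), 10, tolerance = 1e-9)
})

test_that("warmup on the box recovers all four vertices", {
  m <- make_toy_model("box")
  ## coordinate objectives give the per-axis extremes; the seeded random
  ## +/-1 objectives beyond them reach the mixed corners
  w <- warmup_points(m, n = 24, seed = 1)
  xy <- unique(round(w[, c("SRC_A", "SRC_B")], 7))
  for (v in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
    expect_true(any(apply(xy, 1, function(p) all(abs(p - v) < 1e-6))),
                label = paste("vertex", paste(v, collapse = ",")))
})

test_that("warmup errors on an infeasible model before sampling", {
  m <- make_toy_model("chain")
  m <- set_bounds(m, "BIO", lb = 100, ub = 200)
  expect_error(warmup_points(m), "infeasible")
})

test_that("ACHR samples are feasible, seeded and reproducible", {
  cm <- condition_fixture("KT2440", "I")
  s1 <- achr_sample(cm, n_samples = 300, seed = 42, thinning = 5)
  s2 <- achr_sample(cm, n_samples = 300, seed = 42, thinning = 5)
  s3 <- achr_sample(cm, n_samples = 300, seed = 43, thinning = 5)
  expect_identical(s1$points, s2$points)       # bit-reproducible
  expect_false(identical(s1$points, s3$points))
  expect_true(assert_samples_feasible(s1, cm))
  ## clamped reactions stay constant across all samples
  fixed <- names(which(apply(reaction_bounds(as_metabolic_model(cm)), 1,
                             function(b) b[2] - b[1] < 1e-12)))
  for (id in fixed)
    expect_lt(max(s1$points[, id]) - min(s1$points[, id]), 1e-8)
})

test_that("box marginals match the rejection oracle", {
  m <- make_toy_model("box")
  n <- 4000
  s <- achr_sample(m, n_samples = n, seed = 7, thinning = 10)
  oracle <- rejection_oracle(n, list(a = c(0, 1), b = c(0, 1)),
                             function(x) c(x[1], x[1], x[2], x[2]), seed = 8)
  for (j in 1:2) {
    coord <- c("SRC_A", "SRC_B")[j]
    se <- sqrt(stats::var(s$points[, coord]) / n + stats::var(oracle[, j]) / n)
    expect_lt(abs(mean(s$points[, coord]) - mean(oracle[, j])), 3 * se)
  }
  expect_true(assert_samples_feasible(s, m))
})

test_that("two-reaction chain collapses to a uniform 1-D marginal", {
  m <- make_toy_model("interval")
  s <- achr_sample(m, n_samples = 3000, seed = 9, thinning = 5)
  ## both coordinates equal in every sample (S v = 0)
  expect_lt(max(abs(s$points[, "SRC_A"] - s$points[, "SNK_A"])), 1e-6)
  ## marginal indistinguishable from U(0, 10)
  ks <- suppressWarnings(stats::ks.test(s$points[, "SRC_A"], "punif", 0, 10))
  expect_gt(ks$p.value, 0.001)
})

test_that("mixed fraction matches enumeration and limiting cases", {
  mk <- function(x) structure(list(points = matrix(x, ncol = 1),
                                   reaction_ids = "r"),
                              class = "flux_sample_set")
  ## hand-built chain {1,2,9,10}: median 5.5, both pairs cross it
  expect_equal(mixed_fraction(mk(c(1, 2, 9, 10))), 1.0)
  ## sorted chain that never crosses after the midpoint swap: {1,2},{3,4}...
  expect_equal(mixed_fraction(mk(c(1, 2, 3, 4))), 1.0)
  expect_equal(mixed_fraction(mk(c(1, 9, 2, 10))), 0.0)
  ## degenerate chain of identical points is an explicit undefined signal
  expect_warning(out <- mixed_fraction(mk(rep(2, 10))), "undefined")
  expect_true(is.na(out))
  ## i.i.d. points sit near 1/2
  iid <- phaflux:::with_seed(1, matrix(stats::runif(20000), ncol = 2))
  s_iid <- structure(list(points = iid, reaction_ids = c("a", "b")),
                     class = "flux_sample_set")
  expect_gt(mixed_fraction(s_iid), 0.45)
  expect_lt(mixed_fraction(s_iid), 0.55)
})

test_that("median fluxes are per-reaction sample medians", {
  s <- structure(list(points = cbind(r1 = c(1, 2, 100), r2 = rep(7, 3)),
                      reaction_ids = c("r1", "r2")),
                 class = "flux_sample_set")
  expect_equal(median_fluxes(s), c(r1 = 2, r2 = 7))
})

test_that("strain comparison classifies ratios against thresholds", {
  mk <- function(vals) structure(
    list(points = matrix(rep(vals, each = 5), nrow = 5,
                         dimnames = list(NULL, names(vals))),
         reaction_ids = names(vals)),
    class = "flux_sample_set")
  a <- mk(c(up = 2, same = 1, down = 0.5, dead = 1))
  b <- mk(c(up = 1, same = 1, down = 1, dead = 0))
  cmp <- compare_strains(a, b, thresholds = c(0.8, 1.2))
  expect_identical(cmp$class, c("increased", "unaffected", "reduced",
                                "undefined"))
  expect_equal(cmp$ratio[1], 2)
  ## self-comparison: all unaffected, all ratios 1
  cmp2 <- compare_strains(a, a)
  expect_true(all(cmp2$class %in% c("unaffected", "undefined")))
  expect_true(all(cmp2$ratio[!is.na(cmp2$ratio)] == 1))
  ## mismatched reaction lists are an error naming the difference
  bad <- mk(c(up = 1, other = 2))
  expect_error(compare_strains(a, bad), "other")
})

test_that("sample sets persist as TSV with a YAML sidecar", {
  m <- make_toy_model("box")
  s <- achr_sample(m, n_samples = 50, seed = 3, thinning = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sample_set(s, path, diagnostics = list(mixed_fraction = 0.5))
  back <- utils::read.delim(path)
  expect_equal(dim(back), c(50, 4))
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  expect_equal(meta$seed, 3)
  expect_equal(meta$mixed_fraction, 0.5)
})
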