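test_that("critical c/h2 follows the tail-quantile formula", {
  # constant draws pin the quantiles exactly
  same <- criticalCOverH2(posteriorDraws(rep(0.5, 200), "Pst"),
                          posteriorDraws(rep(0.5, 200), "Fst"))
  expect_equal(same, 1)
  v <- criticalCOverH2(posteriorDraws(rep(0.9, 200), "Pst"),
                       posteriorDraws(rep(0.1, 200), "Fst"))
  expect_equal(v, (0.1 * 0.1) / (0.9 * 0.9))
  # monotone: raising the F_ST upper tail raises the critical ratio
  p <- posteriorDraws(rep(0.5, 200), "Pst")
  vals <- sapply(c(0.2, 0.4, 0.6), function(f)
    criticalCOverH2(p, posteriorDraws(rep(f, 200), "Fst")))
  expect_true(all(diff(vals) > 0))
})

test_that("critical ratio falls as the P_ST distribution shifts right", {
  set.seed(31)
  base <- pmin(pmax(rbeta(2000, 4, 4), 1e-6), 1 - 1e-6)
  f <- posteriorDraws(rbeta(2000, 2, 10), "Fst")
  vals <- sapply(c(0, 0.1, 0.2, 0.3), function(sh)
    criticalCOverH2(posteriorDraws(pmin(base + sh, 1 - 1e-9), "Pst"), f))
  expect_true(all(diff(vals) < 0))
})

test_that("degenerate tails flag an infinite critical ratio", {
  expect_warning(
    v <- criticalCOverH2(posteriorDraws(rep(0, 200), "Pst"),
                         posteriorDraws(rep(0.5, 200), "Fst")),
    "degenerate")
  expect_true(is.infinite(v))
})

test_that("KDE overlap is symmetric, bounded and order-invariant", {
  set.seed(32)
  a <- rbeta(500, 2, 5)
  b <- rbeta(500, 5, 2)
  o1 <- kdeOverlap(a, b)
  expect_identical(o1, kdeOverlap(b, a))
  expect_identical(o1, kdeOverlap(sample(a), b))
  expect_gte(o1, 0)
  expect_lte(o1, 1)
  expect_gte(kdeOverlap(a, a), 0.999)
  expect_error(kdeOverlap(a - 2, b), "\\[0, 1\\]")
  expect_error(kdeOverlap(a[1:50], b), "100")
})

test_that("each boundary-reflected KDE integrates to one on the grid", {
  set.seed(33)
  for (x in list(rbeta(400, 0.5, 5), rbeta(400, 8, 2), runif(400))) {
    grid <- seq(0, 1, length.out = 512)
    f <- coaldrift:::boundedKde(x, grid, stats::bw.nrd0(x))
    expect_equal(coaldrift:::simpsonIntegral(f, grid[2] - grid[1]), 1,
                 tolerance = 0.01)
  }
})

test_that("disjoint concentrated samples have essentially no overlap", {
  set.seed(34)
  a <- pmin(pmax(rnorm(1000, 0.05, 0.01), 0), 1)
  b <- pmin(pmax(rnorm(1000, 0.95, 0.01), 0), 1)
  expect_lt(kdeOverlap(a, b), 0.001)
})

test_that("overlap of Beta samples matches the analytic min-integral", {
  set.seed(35)
  a <- rbeta(20000, 2, 8)
  b <- rbeta(20000, 8, 2)
  est <- kdeOverlap(a, b)
  truth <- integrate(function(x) pmin(dbeta(x, 2, 8), dbeta(x, 8, 2)),
                     0, 1)$value
  expect_lt(abs(est - truth), 0.03)
})

test_that("driftCompare renders verdicts from overlap and tails", {
  hi <- posteriorDraws(pmin(pmax(rnorm(500, 0.99, 0.002), 0), 1), "Pst")
  lo <- posteriorDraws(pmin(pmax(rnorm(500, 0.01, 0.002), 0.001), 1),
                       "Fst", "A")
  cmp <- driftCompare(hi, lo, trait = "call_frequency")
  expect_identical(cmp@verdict, "drift_rejected")
  expect_lt(cmp@overlap, 0.01)
  expect_identical(cmp@focal_population, "A")

  set.seed(36)
  x <- rbeta(500, 3, 3)
  cmp2 <- driftCompare(posteriorDraws(x, "Pst"),
                       posteriorDraws(x, "Fst"), trait = "t")
  expect_identical(cmp2@verdict, "drift_not_rejected")
  expect_gt(cmp2@overlap, 0.9)
  expect_error(driftCompare(hi, lo, overlap_threshold = 0.7), "threshold")
})

test_that("drift reports are deterministic, uniquely keyed JSON", {
  set.seed(37)
  mk <- function(trait, pop) {
    driftCompare(posteriorDraws(rbeta(300, 6, 2), "Pst"),
                 posteriorDraws(rbeta(300, 2, 6), "Fst", pop),
                 trait = trait)
  }
  cmps <- list(mk("mass", "A"), mk("mass", "B"), mk("freq", "A"))
  rep1 <- driftReport(cmps)
  expect_length(rep1$comparisons, 3)
  expect_identical(names(rep1$comparisons),
                   sort(c("mass|A", "mass|B", "freq|A")))
  tmp1 <- tempfile(fileext = ".json"); tmp2 <- tempfile(fileext = ".json")
  driftReport(cmps, path = tmp1)
  driftReport(cmps, path = tmp2)
  expect_identical(readLines(tmp1), readLines(tmp2))
  expect_error(driftReport(list(cmps[[1]], cmps[[1]])), "duplicate")
  expect_error(driftReport(list()), "at least one")
})
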