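#' Critical c/h-squared ratio for a P_ST versus F_ST comparison
#'
#' The smallest additive-contribution ratio c/h^2 at which the lower tail
#' of the P_ST posterior still exceeds the upper tail of the F_ST
#' distribution:
#' \deqn{\left.\frac{c}{h^2}\right|_{crit} =
#'   \frac{(1 - P_{ST,0.05})\,F_{ST,0.95}}{P_{ST,0.05}\,(1 - F_{ST,0.95})},}
#' evaluated at the 5 percent empirical quantile of the P_ST draws and the
#' 95 percent empirical quantile of the F_ST draws (type-7 quantiles). A
#' low critical value means the conclusion that trait divergence exceeds
#' the neutral expectation is robust over a wide range of unknown c/h^2.
#'
#' @param pst_draws [PosteriorDraws-class] of P_ST values in (0, 1).
#' @param fst_draws [PosteriorDraws-class] of F_ST values in (0, 1).
#' @return The critical ratio (>= 0); \code{Inf} with a warning when the
#'   P_ST 5 percent quantile is 0 or the F_ST 95 percent quantile is 1.
#' @export
criticalCOverH2 <- function(pst_draws, fst_draws) {
  p <- drawsVector(pst_draws)
  f <- drawsVector(fst_draws)
  p05 <- unname(stats::quantile(p, 0.05, type = 7))
  f95 <- unname(stats::quantile(f, 0.95, type = 7))
  if (p05 <= 0 || f95 >= 1) {
    warning(sprintf(
      "degenerate tails (P_ST 5%% = %g, F_ST 95%% = %g); critical ratio infinite",
      p05, f95))
    return(Inf)
  }
  ((1 - p05) * f95) / (p05 * (1 - f95))
}

drawsVector <- function(x) {
  if (methods::is(x, "PosteriorDraws")) x@draws else as.numeric(x)
}

# Gaussian KDE on [0, 1] with reflection at both boundaries, evaluated on
# a shared uniform grid. Reflection keeps mass near 0 and 1 (where F_ST
# and P_ST often sit) from leaking outside the support.
boundedKde <- function(x, grid, bw) {
  f <- numeric(length(grid))
  for (g in seq_along(grid)) {
    z <- grid[g]
    f[g] <- sum(stats::dnorm((z - x) / bw) +
                stats::dnorm((z + x) / bw) +
                stats::dnorm((z - (2 - x)) / bw))
  }
  f / (length(x) * bw)
}

# Composite Simpson integration on a uniform grid; with an odd number of
# intervals the final interval is handled by the trapezoidal rule.
simpsonIntegral <- function(y, h) {
  n <- length(y) - 1L                       # number of intervals
  if (n < 2L) return(h * sum(y) / 2)
  m <- if (n %% 2L == 0L) n else n - 1L
  i <- seq_len(m - 1L) + 1L
  s <- h / 3 * (y[1] + y[m + 1L] +
                sum(y[i] * ifelse((i - 1L) %% 2L == 1L, 4, 2)))
  if (n %% 2L == 1L) s <- s + h * (y[n] + y[n + 1L]) / 2
  s
}

#' Kernel-density overlap of two distributions on [0, 1]
#'
#' Estimates each sample's density by a Gaussian KDE with Silverman
#' bandwidth, boundary-corrected by reflection at 0 and 1, on a shared
#' uniform grid over [0, 1]; the overlap is the numerical integral
#' (Simpson's rule) of the pointwise minimum of the two densities. The
#' statistic is symmetric in its arguments and lies in [0, 1]; two
#' identical samples give 1 and disjoint samples give ~0.
#'
#' @param a,b [PosteriorDraws-class] objects or numeric vectors of >= 100
#'   draws each, all values in [0, 1] (differentiation indices).
#' @param n_grid number of grid points (default 512).
#' @return Overlap in [0, 1].
#' @export
kdeOverlap <- function(a, b, n_grid = 512L) {
  a <- drawsVector(a); b <- drawsVector(b)
  if (length(a) < 100L || length(b) < 100L)
    stop("need at least 100 draws in each sample")
  if (any(a < 0 | a > 1) || any(b < 0 | b > 1))
    stop("draws must lie in [0, 1] (differentiation indices)")
  grid <- seq(0, 1, length.out = n_grid)
  h <- grid[2] - grid[1]
  fa <- boundedKde(a, grid, max(stats::bw.nrd0(a), 1e-6))
  fb <- boundedKde(b, grid, max(stats::bw.nrd0(b), 1e-6))
  min(max(simpsonIntegral(pmin(fa, fb), h), 0), 1)
}

#' Compare a P_ST posterior with an F_ST distribution
#'
#' Assembles the kernel-density overlap, the tail quantiles (P_ST 5
#' percent, F_ST 95 percent), and the critical c/h^2 ratio, and renders a
#' verdict: drift is rejected as the sole explanation of the trait
#' divergence when the overlap falls below \code{overlap_threshold} AND
#' the P_ST lower tail clears the F_ST upper tail. Both criteria are
#' always reported; the verdict is a reporting convention.
#'
#' @param pst a [TraitFit-class] object or [PosteriorDraws-class] of P_ST.
#' @param fst a [PosteriorDraws-class] of F_ST (or numeric vector).
#' @param overlap_threshold verdict threshold in (0, 0.5); default 0.05.
#' @param trait trait label for the report (defaults to the fit's trait).
#' @return A [DriftComparison-class] object.
#' @export
driftCompare <- function(pst, fst, overlap_threshold = 0.05,
                         trait = NULL) {
  if (overlap_threshold <= 0 || overlap_threshold >= 0.5)
    stop("overlap_threshold must be in (0, 0.5)")
  if (methods::is(pst, "TraitFit")) {
    if (is.null(trait)) trait <- pst@spec$trait
    pst <- pstDraws(pst)
  }
  if (is.null(trait)) trait <- "trait"
  p <- drawsVector(pst); f <- drawsVector(fst)
  if (!length(p) || !length(f)) stop("empty draws")
  pop <- if (methods::is(fst, "PosteriorDraws") &&
             !is.na(fst@population)) fst@population else "NA"
  ov <- kdeOverlap(p, f)
  p05 <- unname(stats::quantile(p, 0.05, type = 7))
  f95 <- unname(stats::quantile(f, 0.95, type = 7))
  crit <- suppressWarnings(criticalCOverH2(posteriorDraws(p, "Pst"),
                                           posteriorDraws(f, "Fst")))
  verdict <- if (ov < overlap_threshold && p05 > f95) "drift_rejected"
             else "drift_not_rejected"
  new("DriftComparison", trait = trait, focal_population = pop,
      overlap = ov, fst_q95 = f95, pst_q05 = p05,
      c_over_h2_critical = crit, verdict = verdict,
      overlap_threshold = overlap_threshold)
}

comparisonAsList <- function(cmp) {
  list(trait = cmp@trait, focal_population = cmp@focal_population,
       overlap = cmp@overlap, fst_q95 = cmp@fst_q95,
       pst_q05 = cmp@pst_q05,
       c_over_h2_critical = cmp@c_over_h2_critical,
       verdict = cmp@verdict,
       overlap_threshold = cmp@overlap_threshold)
}

#' Machine-readable drift-test report
#'
#' Collects one or more [DriftComparison-class] results into a
#' deterministic JSON document (entries keyed \code{trait|population},
#' sorted), optionally writing the kernel-density curves of each
#' distribution pair as a CSV for plotting. Overlaps are always reported
#' as proportions, never percentages.
#'
#' @param comparisons list of [DriftComparison-class] objects.
#' @param path optional file path for the JSON report.
#' @param density_path optional CSV path for the density curves; requires
#'   \code{fits_and_fsts}, a list of \code{list(pst = , fst = )} draw
#'   pairs parallel to \code{comparisons}.
#' @param fits_and_fsts see \code{density_path}.
#' @return The report as a named list (invisibly when written to file).
#' @export
driftReport <- function(comparisons, path = NULL, density_path = NULL,
                        fits_and_fsts = NULL) {
  if (!length(comparisons)) stop("need at least one comparison")
  stopifnot(all(vapply(comparisons, methods::is, logical(1),
                       "DriftComparison")))
  keys <- vapply(comparisons, function(cmp)
    paste(cmp@trait, cmp@focal_population, sep = "|"), character(1))
  if (anyDuplicated(keys)) stop("duplicate trait|population keys")
  entries <- stats::setNames(lapply(comparisons, comparisonAsList), keys)
  entries <- entries[order(names(entries))]
  report <- list(comparisons = entries,
                 n_comparisons = length(entries),
                 generated_by = paste0("coaldrift ",
                                       utils::packageVersion("coaldrift")))
  if (!is.null(density_path) && !is.null(fits_and_fsts)) {
    grid <- seq(0, 1, length.out = 512L)
    curves <- do.call(rbind, lapply(seq_along(comparisons), function(i) {
      p <- drawsVector(if (methods::is(fits_and_fsts[[i]]$pst, "TraitFit"))
        pstDraws(fits_and_fsts[[i]]$pst) else fits_and_fsts[[i]]$pst)
      f <- drawsVector(fits_and_fsts[[i]]$fst)
      data.frame(key = keys[i], x = grid,
                 pst_density = boundedKde(p, grid,
                                          max(stats::bw.nrd0(p), 1e-6)),
                 fst_density = boundedKde(f, grid,
                                          max(stats::bw.nrd0(f), 1e-6)))
    }))
    utils::write.table(curves, density_path, sep = ",", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(path)) {
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), path)
    return(invisible(report))
  }
  report
}
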