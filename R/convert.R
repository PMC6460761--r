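#' F_ST expected under the finite island model, from the number of migrants
#'
#' Wright's island-model relationship between the fixation index and the
#' effective number of migrants per generation, with Takahata's correction
#' for a finite number d of populations:
#' \deqn{F_{ST} = \frac{1}{1 + 4 N_e m \, d^2/(d-1)^2}.}
#' Used here in the forward direction, transforming posterior draws of Nm
#' into draws of F_ST.
#'
#' @param nm effective number of migrants per generation (vectorized,
#'   each element >= 0).
#' @param d number of demes (integer >= 2; default 2, two island
#'   populations).
#' @return F_ST value(s) in (0, 1]; 1 at nm = 0, decreasing in nm.
#' @examples
#' fstFromNm(0.325)        # 1 / (1 + 4 * 0.325 * 4)
#' fstFromNm(0, d = 2)     # complete differentiation
#' @export
fstFromNm <- function(nm, d = 2L) {
  checkDemeCount(d)
  if (any(!is.finite(nm)) || any(nm < 0))
    stop("nm must be finite and >= 0")
  1 / (1 + 4 * nm * (d^2 / (d - 1)^2))
}

checkDemeCount <- function(d) {
  if (length(d) != 1L || !is.finite(d) || d < 2 || d != round(d))
    stop("d must be a single integer >= 2 (the correction d^2/(d-1)^2 is undefined at d = 1)")
  invisible(as.integer(d))
}

#' Transform a posterior of Nm into a posterior of F_ST
#'
#' Applies [fstFromNm()] to every draw, preserving order and draw count, so
#' the full posterior uncertainty in the migration estimate propagates into
#' the F_ST distribution.
#'
#' @param nm_draws a [PosteriorDraws-class] object with non-negative draws
#'   (parameter typically \code{"Nm"}).
#' @param d number of demes (>= 2).
#' @return A [PosteriorDraws-class] object with parameter \code{"Fst"} and
#'   the same population label.
#' @export
fstDistribution <- function(nm_draws, d = 2L) {
  stopifnot(methods::is(nm_draws, "PosteriorDraws"))
  checkDemeCount(d)
  x <- nm_draws@draws
  bad <- which(!is.finite(x) | x < 0)
  if (length(bad))
    stop(sprintf("invalid Nm draw at index %d (value %g)", bad[1], x[bad[1]]))
  posteriorDraws(fstFromNm(x, d), "Fst", nm_draws@population)
}

#' Effective number of migrants from paired theta and m draws
#'
#' Nm is a compound parameter: with theta = 4 Ne mu and m = M / mu,
#' theta * m / 4 = Ne * M, independent of the mutation rate. Draws must be
#' paired by MCMC iteration (same genealogy sample), because theta and m
#' are correlated in the joint posterior; unequal draw counts are rejected
#' rather than recycled. Note that the mode of the resulting Nm draws is a
#' property of the joint density and generally differs from the product of
#' the marginal theta and m modes.
#'
#' @param theta_draws [PosteriorDraws-class] of theta (>= 0).
#' @param m_draws [PosteriorDraws-class] of m (>= 0), same length.
#' @return A [PosteriorDraws-class] object with parameter \code{"Nm"},
#'   carrying the population label of \code{m_draws} (migration is
#'   directional).
#' @export
nmFromThetaM <- function(theta_draws, m_draws) {
  stopifnot(methods::is(theta_draws, "PosteriorDraws"),
            methods::is(m_draws, "PosteriorDraws"))
  if (length(theta_draws@draws) != length(m_draws@draws))
    stop("theta and m draw counts differ; draws must be paired by iteration")
  posteriorDraws(theta_draws@draws * m_draws@draws / 4, "Nm",
                 m_draws@population)
}

#' Effective population size from coalescent-scaled theta
#'
#' Converts theta = 4 Ne mu to Ne = theta / (4 mu), with mu the multilocus
#' substitution rate per locus per generation.
#'
#' @param theta coalescent-scaled population size (vectorized, >= 0).
#' @param mu_per_generation substitution rate per locus per generation
#'   (> 0).
#' @return Effective population size in individuals.
#' @examples
#' neFromTheta(0.625, 1.13e-6)  # ~138,000
#' @export
neFromTheta <- function(theta, mu_per_generation) {
  if (length(mu_per_generation) != 1L || !is.finite(mu_per_generation) ||
      mu_per_generation <= 0)
    stop("mu_per_generation must be a positive scalar")
  if (any(!is.finite(theta)) || any(theta < 0))
    stop("theta must be finite and >= 0")
  theta / (4 * mu_per_generation)
}

#' Population splitting time from coalescent-scaled tau
#'
#' Converts tau = t * mu to t = tau / mu years, with mu the multilocus
#' substitution rate per locus per year.
#'
#' @param tau coalescent-scaled splitting time (vectorized, >= 0).
#' @param mu_per_year substitution rate per locus per year (> 0).
#' @return Splitting time in years.
#' @examples
#' splitTimeFromTau(0.703, 5.67e-7) / 1e6  # ~1.24 Ma
#' @export
splitTimeFromTau <- function(tau, mu_per_year) {
  if (length(mu_per_year) != 1L || !is.finite(mu_per_year) ||
      mu_per_year <= 0)
    stop("mu_per_year must be a positive scalar")
  if (any(!is.finite(tau)) || any(tau < 0))
    stop("tau must be finite and >= 0")
  tau / mu_per_year
}

#' Geometric mean of locus-specific substitution rates
#'
#' @param locus_rates positive numeric vector of per-locus rates.
#' @return \code{exp(mean(log(locus_rates)))}.
#' @export
geometricMeanRate <- function(locus_rates) {
  if (!length(locus_rates)) stop("need at least one rate")
  if (any(!is.finite(locus_rates)) || any(locus_rates <= 0))
    stop("all rates must be positive and finite")
  exp(mean(log(locus_rates)))
}

#' Per-generation substitution rate from a per-year rate
#'
#' @param rate_per_year substitution rate per locus per year (> 0).
#' @param generation_time_years generation time in years (> 0).
#' @return Rate per locus per generation (the product).
#' @examples
#' perGenerationRate(5.67e-7, 2)  # 1.13e-6
#' @export
perGenerationRate <- function(rate_per_year, generation_time_years) {
  if (any(!is.finite(rate_per_year)) || any(rate_per_year <= 0))
    stop("rate_per_year must be positive")
  if (length(generation_time_years) != 1L ||
      !is.finite(generation_time_years) || generation_time_years <= 0)
    stop("generation_time_years must be a positive scalar")
  rate_per_year * generation_time_years
}

# Human-readable rounding conventions for summaries: Ne to the nearest
# thousand, times to two decimals in Ma. Raw values are always retained in
# machine output.
roundNe <- function(ne) round(ne / 1000) * 1000
roundMa <- function(years) round(years / 1e6, 2)
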