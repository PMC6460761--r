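#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats density quantile var sd rnorm runif rgamma rcauchy
#'   rlnorm rmultinom rbinom acf dnorm median setNames
#' @importFrom utils read.table write.table packageVersion
NULL

#' Posterior draws of a scalar population-genetic parameter
#'
#' A labelled vector of retained MCMC draws for one scalar parameter of an
#' isolation-with-migration (or similar) model: a coalescent-scaled
#' population size (theta = 4*Ne*mu), migration rate (m = M/mu), splitting
#' time (tau = t*mu), the effective number of migrants Nm, a fixation index
#' F_ST, or a trait differentiation index P_ST.
#'
#' @slot parameter single character token naming the parameter
#'   (e.g. \code{"theta"}, \code{"m"}, \code{"tau"}, \code{"Nm"},
#'   \code{"Fst"}, \code{"Pst"}).
#' @slot population population label the parameter refers to, or
#'   \code{NA_character_} for shared parameters.
#' @slot draws numeric vector of draws, in MCMC iteration order.
#' @slot units free-text units annotation.
#'
#' @details Validity requires non-empty, finite draws; non-negative draws
#' for theta/m/tau/Nm; and draws in (0, 1] for F_ST (P_ST may be 0 when the
#' between-population variance draw is 0).
#'
#' @seealso [posteriorDraws()], [fstDistribution()], [summarizePosterior()]
#' @export
setClass("PosteriorDraws",
  representation(
    parameter  = "character",
    population = "character",
    draws      = "numeric",
    units      = "character"
  ),
  prototype(parameter = "draws", population = NA_character_, units = "")
)

setValidity("PosteriorDraws", function(object) {
  msg <- character(0)
  if (length(object@parameter) != 1L || !nzchar(object@parameter))
    msg <- c(msg, "'parameter' must be a single non-empty string")
  if (length(object@population) != 1L)
    msg <- c(msg, "'population' must be a single label (or NA)")
  d <- object@draws
  if (length(d) == 0L)
    msg <- c(msg, "'draws' must be non-empty")
  if (length(d) && any(!is.finite(d)))
    msg <- c(msg, "all draws must be finite")
  if (length(d) && object@parameter %in% c("theta", "m", "tau", "Nm") &&
      any(d < 0))
    msg <- c(msg, sprintf("%s draws must be >= 0", object@parameter))
  if (length(d) && object@parameter == "Fst" && any(d <= 0 | d > 1))
    msg <- c(msg, "Fst draws must lie in (0, 1]")
  if (length(d) && object@parameter == "Pst" && any(d < 0 | d > 1))
    msg <- c(msg, "Pst draws must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a PosteriorDraws object
#'
#' @param draws numeric vector of MCMC draws (iteration order preserved).
#' @param parameter parameter name token; one of \code{"theta"},
#'   \code{"m"}, \code{"tau"}, \code{"Nm"}, \code{"Fst"}, \code{"Pst"} or a
#'   free-form label.
#' @param population population label, or \code{NA}.
#' @param units free-text units string.
#' @return A [PosteriorDraws-class] object.
#' @examples
#' nm <- posteriorDraws(rlnorm(1000, log(0.3), 0.5), "Nm", "Hispaniola")
#' nm
#' @export
posteriorDraws <- function(draws, parameter = "draws",
                           population = NA_character_, units = "") {
  new("PosteriorDraws", parameter = as.character(parameter),
      population = as.character(population),
      draws = as.numeric(draws), units = as.character(units))
}

#' @describeIn PosteriorDraws-class number of retained draws
#' @param x,object a \code{PosteriorDraws} object
#' @export
setMethod("length", "PosteriorDraws", function(x) length(x@draws))

setMethod("show", "PosteriorDraws", function(object) {
  cat(sprintf("PosteriorDraws: %s%s, %d draws%s\n",
              object@parameter,
              if (is.na(object@population)) "" else
                paste0(" [", object@population, "]"),
              length(object@draws),
              if (nzchar(object@units)) paste0(" (", object@units, ")")
              else ""))
  q <- stats::quantile(object@draws, c(0.025, 0.5, 0.975), type = 7)
  cat(sprintf("  median %.4g  (2.5%%: %.4g, 97.5%%: %.4g)\n",
              q[2], q[1], q[3]))
})

#' Extract the numeric draws from a draws container
#'
#' @param object a [PosteriorDraws-class] object.
#' @return Numeric vector of draws.
#' @export
setGeneric("draws", function(object) standardGeneric("draws"))

#' @rdname draws
#' @export
setMethod("draws", "PosteriorDraws", function(object) object@draws)

#' Substitution-rate set for natural-parameter conversion
#'
#' Holds per-locus substitution rates (per year), the generation time, and
#' the derived multilocus rates: the geometric mean across loci (per year)
#' and its per-generation counterpart.
#'
#' @slot locus_rates_per_year positive numeric vector (may be empty when the
#'   multilocus rate is supplied directly).
#' @slot generation_time_years positive scalar.
#' @slot multilocus_rate_per_year positive scalar; geometric mean of the
#'   locus rates when those are present.
#' @slot multilocus_rate_per_generation positive scalar; per-year rate
#'   times the generation time.
#' @seealso [rateSet()], [geometricMeanRate()], [perGenerationRate()]
#' @export
setClass("RateSet",
  representation(
    locus_rates_per_year          = "numeric",
    generation_time_years         = "numeric",
    multilocus_rate_per_year      = "numeric",
    multilocus_rate_per_generation = "numeric"
  )
)

setValidity("RateSet", function(object) {
  msg <- character(0)
  if (length(object@locus_rates_per_year) &&
      any(object@locus_rates_per_year <= 0))
    msg <- c(msg, "locus rates must be positive")
  if (length(object@generation_time_years) != 1L ||
      object@generation_time_years <= 0)
    msg <- c(msg, "generation time must be a positive scalar")
  if (length(object@multilocus_rate_per_year) != 1L ||
      object@multilocus_rate_per_year <= 0)
    msg <- c(msg, "multilocus per-year rate must be a positive scalar")
  if (length(object@locus_rates_per_year)) {
    gm <- exp(mean(log(object@locus_rates_per_year)))
    if (abs(gm - object@multilocus_rate_per_year) >
        1e-12 * max(gm, object@multilocus_rate_per_year))
      msg <- c(msg,
        "multilocus per-year rate must equal the geometric mean of the locus rates")
  }
  expect <- object@multilocus_rate_per_year * object@generation_time_years
  if (abs(expect - object@multilocus_rate_per_generation) >
      1e-12 * expect)
    msg <- c(msg,
      "per-generation rate must equal per-year rate times generation time")
  if (length(msg)) msg else TRUE
})

#' Construct a RateSet
#'
#' Either \code{locus_rates_per_year} (from which the geometric-mean
#' multilocus rate is computed) or \code{multilocus_rate_per_year} must be
#' supplied.
#'
#' @param locus_rates_per_year positive per-locus substitution rates
#'   (substitutions/locus/year).
#' @param generation_time_years generation time in years (default 2).
#' @param multilocus_rate_per_year optional direct multilocus rate; computed
#'   as the geometric mean of the locus rates when omitted.
#' @return A [RateSet-class] object.
#' @examples
#' rateSet(multilocus_rate_per_year = 5.67e-7, generation_time_years = 2)
#' @export
rateSet <- function(locus_rates_per_year = numeric(0),
                    generation_time_years = 2,
                    multilocus_rate_per_year = NULL) {
  if (is.null(multilocus_rate_per_year)) {
    if (!length(locus_rates_per_year))
      stop("supply locus_rates_per_year or multilocus_rate_per_year")
    multilocus_rate_per_year <- geometricMeanRate(locus_rates_per_year)
  }
  new("RateSet",
      locus_rates_per_year = as.numeric(locus_rates_per_year),
      generation_time_years = as.numeric(generation_time_years),
      multilocus_rate_per_year = as.numeric(multilocus_rate_per_year),
      multilocus_rate_per_generation =
        as.numeric(multilocus_rate_per_year * generation_time_years))
}

setMethod("show", "RateSet", function(object) {
  cat(sprintf(
    "RateSet: %.4g subs/locus/year (geometric mean of %d loci)\n",
    object@multilocus_rate_per_year, length(object@locus_rates_per_year)))
  cat(sprintf("  generation time %.3g yr -> %.4g subs/locus/generation\n",
              object@generation_time_years,
              object@multilocus_rate_per_generation))
})

#' Summary of a posterior sample: mode, HPD interval, quantiles
#'
#' @slot mode kernel-density mode of the draws (grid argmax of a Gaussian
#'   KDE with Silverman bandwidth on 512 points spanning the draw range).
#' @slot hpd_low,hpd_high bounds of the shortest interval of sorted draws
#'   containing \code{hpd_mass} of the sample.
#' @slot hpd_mass nominal mass of the HPD interval, in (0, 1).
#' @slot quantiles named numeric vector of empirical quantiles (type 7).
#' @slot n_draws number of draws summarized.
#' @slot multimodal_flag TRUE when the KDE mode falls outside the HPD
#'   interval (possible multimodality).
#' @seealso [summarizePosterior()]
#' @export
setClass("PosteriorSummary",
  representation(
    mode = "numeric", hpd_low = "numeric", hpd_high = "numeric",
    hpd_mass = "numeric", quantiles = "numeric", n_draws = "integer",
    multimodal_flag = "logical"
  )
)

setValidity("PosteriorSummary", function(object) {
  msg <- character(0)
  if (object@hpd_mass <= 0 || object@hpd_mass >= 1)
    msg <- c(msg, "hpd_mass must be in (0, 1)")
  if (object@hpd_low > object@hpd_high)
    msg <- c(msg, "hpd_low must be <= hpd_high")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PosteriorSummary", function(object) {
  cat(sprintf("PosteriorSummary (n = %d)\n", object@n_draws))
  cat(sprintf("  mode %.6g; %d%% HPD [%.6g, %.6g]%s\n",
              object@mode, round(100 * object@hpd_mass),
              object@hpd_low, object@hpd_high,
              if (object@multimodal_flag) "  [mode outside HPD]" else ""))
  if (length(object@quantiles)) {
    cat("  quantiles:\n")
    print(object@quantiles)
  }
})

#' Per-locus diversity components for G'_ST
#'
#' Nei–Chesser small-sample-corrected heterozygosities for one locus, with
#' haplotypes treated as alleles.
#'
#' @slot locus_name locus label.
#' @slot hs mean within-population expected heterozygosity (unbiased).
#' @slot ht total expected heterozygosity (unbiased).
#' @slot k number of populations.
#' @slot n_harmonic harmonic mean of per-population sequence counts.
#' @slot ht_clamped TRUE when the raw ht estimate fell below hs and was
#'   clamped up to hs.
#' @seealso [locusHeterozygosities()], [gprimeSt()]
#' @export
setClass("LocusDiversity",
  representation(
    locus_name = "character", hs = "numeric", ht = "numeric",
    k = "integer", n_harmonic = "numeric", ht_clamped = "logical"
  ),
  prototype(ht_clamped = FALSE)
)

setValidity("LocusDiversity", function(object) {
  msg <- character(0)
  if (object@hs < 0 || object@hs > 1 || object@ht < 0 || object@ht > 1)
    msg <- c(msg, "hs and ht must lie in [0, 1]")
  if (object@ht < object@hs)
    msg <- c(msg, "ht must be >= hs (clamp applied upstream)")
  if (object@k < 2L) msg <- c(msg, "k must be >= 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LocusDiversity", function(object) {
  cat(sprintf(
    "LocusDiversity '%s': Hs = %.4f, Ht = %.4f (k = %d, n~ = %.2f)%s\n",
    object@locus_name, object@hs, object@ht, object@k, object@n_harmonic,
    if (object@ht_clamped) " [ht clamped to hs]" else ""))
})

#' Multi-locus G'_ST estimate with bootstrap interval
#'
#' @slot gst pooled G_ST point estimate.
#' @slot gprime_st pooled Hedrick-standardized G'_ST, clamped to [0, 1].
#' @slot per_locus list of [LocusDiversity-class] objects (informative loci).
#' @slot excluded_loci labels of monomorphic loci excluded from pooling.
#' @slot ci_low,ci_high 2.5/97.5 percentile bootstrap interval for G'_ST.
#' @slot n_boot number of bootstrap replicates.
#' @slot seed RNG seed that produced the interval.
#' @seealso [bootstrapGprime()], [multilocusGprimeSt()]
#' @export
setClass("GstResult",
  representation(
    gst = "numeric", gprime_st = "numeric", per_locus = "list",
    excluded_loci = "character", ci_low = "numeric", ci_high = "numeric",
    n_boot = "integer", seed = "integer"
  ),
  prototype(excluded_loci = character(0), ci_low = NA_real_,
            ci_high = NA_real_, n_boot = 0L, seed = NA_integer_)
)

setValidity("GstResult", function(object) {
  msg <- character(0)
  if (object@gprime_st < 0 || object@gprime_st > 1)
    msg <- c(msg, "gprime_st must lie in [0, 1]")
  if (!is.na(object@ci_low) && !is.na(object@ci_high) &&
      object@ci_low > object@ci_high)
    msg <- c(msg, "ci_low must be <= ci_high")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GstResult", function(object) {
  cat(sprintf("GstResult: G'_ST = %.4f (G_ST = %.4f), %d loci pooled\n",
              object@gprime_st, object@gst, length(object@per_locus)))
  if (object@n_boot > 0L)
    cat(sprintf("  bootstrap 95%% CI [%.4f, %.4f] (%d replicates)\n",
                object@ci_low, object@ci_high, object@n_boot))
  if (length(object@excluded_loci))
    cat("  excluded monomorphic loci:",
        paste(object@excluded_loci, collapse = ", "), "\n")
})

#' Multi-locus haplotype alignment for one locus
#'
#' Wraps a \code{Biostrings::DNAStringSet} of equal-length haplotype
#' sequences with a locus label. Sequence names are the sample identifiers
#' and must be unique.
#'
#' @slot locus_name locus label.
#' @slot sequences a \code{DNAStringSet}; all elements the same width,
#'   names unique and non-empty.
#' @seealso [haplotypeAlignment()], [filterInfiniteSites()]
#' @export
setClass("HaplotypeAlignment",
  representation(locus_name = "character", sequences = "DNAStringSet")
)

setValidity("HaplotypeAlignment", function(object) {
  msg <- character(0)
  s <- object@sequences
  if (length(s) < 2L)
    msg <- c(msg, "need at least 2 sequences")
  w <- Biostrings::width(s)
  if (length(w) && length(unique(w)) != 1L)
    msg <- c(msg, "all sequences must have equal length")
  nm <- names(s)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    msg <- c(msg, "sequence names (sample ids) must be unique and non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypeAlignment
#'
#' @param sequences a \code{DNAStringSet} or named character vector of
#'   equal-length sequences over \{A, C, G, T, -, N\} (case-insensitive).
#' @param locus_name locus label.
#' @param sample_ids sample identifiers; defaults to \code{names(sequences)}.
#' @return A [HaplotypeAlignment-class] object.
#' @export
haplotypeAlignment <- function(sequences, locus_name = "locus",
                               sample_ids = NULL) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (!is.null(sample_ids)) names(sequences) <- sample_ids
  new("HaplotypeAlignment", locus_name = as.character(locus_name),
      sequences = sequences)
}

#' @describeIn HaplotypeAlignment-class number of sequences
#' @param x,object a \code{HaplotypeAlignment}
#' @export
setMethod("length", "HaplotypeAlignment", function(x) length(x@sequences))

setMethod("show", "HaplotypeAlignment", function(object) {
  cat(sprintf("HaplotypeAlignment '%s': %d sequences x %d sites\n",
              object@locus_name, length(object@sequences),
              if (length(object@sequences))
                Biostrings::width(object@sequences)[1] else 0L))
  rm <- removedSites(object)
  if (length(rm))
    cat("  sites removed by infinite-sites filter:",
        paste(rm, collapse = ", "), "\n")
})

#' Sample identifiers of an alignment
#' @param object a [HaplotypeAlignment-class] object.
#' @return Character vector of sample ids.
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "HaplotypeAlignment",
          function(object) names(object@sequences))

#' Locus label accessor
#' @param object an object with a locus label.
#' @return Character scalar.
#' @export
setGeneric("locusName", function(object) standardGeneric("locusName"))

#' @rdname locusName
#' @export
setMethod("locusName", "HaplotypeAlignment",
          function(object) object@locus_name)

#' @rdname locusName
#' @export
setMethod("locusName", "LocusDiversity", function(object) object@locus_name)

#' Indices of alignment columns removed by the infinite-sites filter
#'
#' Returns the 1-based column indices (in the original alignment) that
#' [filterInfiniteSites()] removed, or \code{integer(0)} for an unfiltered
#' alignment.
#' @param object a [HaplotypeAlignment-class] object.
#' @return Integer vector.
#' @export
setGeneric("removedSites", function(object) standardGeneric("removedSites"))

#' @rdname removedSites
#' @export
setMethod("removedSites", "HaplotypeAlignment", function(object) {
  rm <- attr(object@sequences, "removed_sites")
  if (is.null(rm)) integer(0) else rm
})

#' Fitted Bayesian hierarchical trait model
#'
#' Posterior draws and convergence diagnostics from [fitTraitModel()]. The
#' draws matrix stacks chains row-wise; the \code{chain} slot gives the
#' chain index of each row. Columns include the grand mean \code{mu},
#' island effects \code{a.<pop>}, sex effects (\code{sex_male} or
#' \code{sex_male.<pop>}), covariate coefficients \code{beta.<name>}, the
#' variances \code{sigma_b2} and \code{sigma_w2}, the correlation
#' \code{rho} when enabled, and the derived \code{pst} (at c = h-squared).
#'
#' @slot draws numeric matrix, one column per saved parameter.
#' @slot chain integer vector, chain index per row of \code{draws}.
#' @slot diagnostics data.frame with columns parameter, psrf, ess.
#' @slot spec list echoing the model specification.
#' @slot config list echoing the MCMC configuration.
#' @slot data_used data.frame of the records actually modeled (after
#'   missing-data exclusions).
#' @seealso [fitTraitModel()], [pstDraws()], [psrf()],
#'   [effectiveSampleSize()]
#' @export
setClass("TraitFit",
  representation(
    draws = "matrix", chain = "integer", diagnostics = "data.frame",
    spec = "list", config = "list", data_used = "data.frame"
  )
)

setValidity("TraitFit", function(object) {
  msg <- character(0)
  if (nrow(object@draws) != length(object@chain))
    msg <- c(msg, "chain index length must match draw rows")
  need <- c("sigma_b2", "sigma_w2", "pst")
  if (!all(need %in% colnames(object@draws)))
    msg <- c(msg, "draws must include sigma_b2, sigma_w2 and pst columns")
  if (all(need %in% colnames(object@draws))) {
    if (any(object@draws[, "sigma_w2"] <= 0))
      msg <- c(msg, "sigma_w2 draws must be positive")
    p <- object@draws[, "pst"]
    if (any(p < 0 | p > 1)) msg <- c(msg, "pst draws must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TraitFit", function(object) {
  cat(sprintf("TraitFit: trait '%s', %d draws x %d parameters, %d chains\n",
              object@spec$trait, nrow(object@draws), ncol(object@draws),
              length(unique(object@chain))))
  p <- object@draws[, "pst"]
  cat(sprintf("  P_ST (c = h^2): median %.3f (2.5%%: %.3f, 97.5%%: %.3f)\n",
              stats::median(p),
              stats::quantile(p, 0.025, type = 7),
              stats::quantile(p, 0.975, type = 7)))
  worst <- object@diagnostics[which.max(object@diagnostics$psrf), ]
  cat(sprintf("  worst PSRF %.4f (%s); min ESS %.0f\n",
              worst$psrf, worst$parameter, min(object@diagnostics$ess)))
})

#' Posterior P_ST draws from a fitted trait model
#'
#' @param object a [TraitFit-class] object.
#' @param c_over_h2 additive-contribution ratio c/h-squared at which to
#'   evaluate P_ST; the default 1 is the stored per-draw value (c equal to
#'   h-squared). Other ratios are recomputed from the stored variance draws
#'   via [pstFromVariances()].
#' @return A [PosteriorDraws-class] object with parameter \code{"Pst"}.
#' @export
setGeneric("pstDraws", function(object, c_over_h2 = 1)
  standardGeneric("pstDraws"))

#' @rdname pstDraws
#' @export
setMethod("pstDraws", "TraitFit", function(object, c_over_h2 = 1) {
  p <- if (identical(c_over_h2, 1)) object@draws[, "pst"] else
    pstFromVariances(object@draws[, "sigma_b2"],
                     object@draws[, "sigma_w2"], c_over_h2)
  posteriorDraws(p, "Pst", NA_character_)
})

#' Diagnostics accessor
#' @param object a [TraitFit-class] object.
#' @return data.frame with columns parameter, psrf, ess.
#' @export
setGeneric("diagnostics", function(object) standardGeneric("diagnostics"))

#' @rdname diagnostics
#' @export
setMethod("diagnostics", "TraitFit", function(object) object@diagnostics)

#' Result of one P_ST versus F_ST drift comparison
#'
#' @slot trait trait name.
#' @slot focal_population label of the population whose directional F_ST
#'   was used.
#' @slot overlap kernel-density overlap of the two distributions, in [0,1].
#' @slot fst_q95 95 percent empirical quantile of the F_ST draws.
#' @slot pst_q05 5 percent empirical quantile of the P_ST draws.
#' @slot c_over_h2_critical smallest c/h-squared ratio at which P_ST still
#'   exceeds F_ST; \code{Inf} flags a degenerate tail.
#' @slot verdict \code{"drift_rejected"} or \code{"drift_not_rejected"}.
#' @slot overlap_threshold the threshold used for the verdict.
#' @seealso [driftCompare()], [criticalCOverH2()], [kdeOverlap()]
#' @export
setClass("DriftComparison",
  representation(
    trait = "character", focal_population = "character",
    overlap = "numeric", fst_q95 = "numeric", pst_q05 = "numeric",
    c_over_h2_critical = "numeric", verdict = "character",
    overlap_threshold = "numeric"
  )
)

setValidity("DriftComparison", function(object) {
  msg <- character(0)
  if (object@overlap < 0 || object@overlap > 1)
    msg <- c(msg, "overlap must lie in [0, 1]")
  if (object@c_over_h2_critical < 0)
    msg <- c(msg, "c_over_h2_critical must be >= 0")
  if (!object@verdict %in% c("drift_rejected", "drift_not_rejected"))
    msg <- c(msg, "verdict must be drift_rejected or drift_not_rejected")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DriftComparison", function(object) {
  cat(sprintf("DriftComparison: %s vs F_ST[%s]\n",
              object@trait, object@focal_population))
  cat(sprintf("  overlap %.4g (threshold %.3g); P_ST 5%% = %.4f; F_ST 95%% = %.4f\n",
              object@overlap, object@overlap_threshold,
              object@pst_q05, object@fst_q95))
  cat(sprintf("  critical c/h^2 = %.4g; verdict: %s\n",
              object@c_over_h2_critical, object@verdict))
})
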