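withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Generate lognormal stand-in posterior draws of Nm
#'
#' Emulates the posterior of the effective number of migrants from an
#' isolation-with-migration analysis with a lognormal sample of a given
#' median and log-scale spread. The lognormal shape (strictly positive,
#' right-skewed, long upper tail) mirrors the typical coalescent Nm
#' posterior; the generator replaces the external MCMC, whose draws the
#' pipeline otherwise consumes as a table.
#'
#' @param median median of the distribution (> 0); the lognormal median is
#'   exp(meanlog).
#' @param log_sd standard deviation on the log scale (> 0).
#' @param n number of draws (>= 1000).
#' @param seed integer RNG seed; draws are a pure function of the
#'   arguments.
#' @param population population label for the draws.
#' @return A [PosteriorDraws-class] object with parameter \code{"Nm"}.
#' @export
genNmDraws <- function(median, log_sd, n = 10000L, seed = 1L,
                       population = NA_character_) {
  if (median <= 0) stop("median must be positive")
  if (log_sd <= 0) stop("log_sd must be positive")
  if (n < 1000L) stop("n must be >= 1000")
  d <- withSeed(seed, stats::rlnorm(n, meanlog = log(median), sdlog = log_sd))
  posteriorDraws(d, "Nm", population, units = "migrants/generation")
}

#' Generate a two-island trait table with known ground truth
#'
#' Per individual, trait = island mean + sex effect + Normal(0, sigma_w)
#' noise. The defaults emulate a two-island field study: modest
#' per-island, per-sex sample sizes and a single continuous trait. The
#' ground-truth parameters are attached as the \code{"truth"} attribute.
#'
#' @param island_means named numeric vector, population -> mean.
#' @param sex_effects named numeric vector of male effects per population
#'   (females are the baseline), recycled if length 1; default 0.
#' @param sigma_w within-population residual SD (>= 0).
#' @param n_per_cell individuals per (population x sex) cell, recycled;
#'   default 15.
#' @param trait trait column name.
#' @param seed integer RNG seed.
#' @return data.frame with columns individual_id, population, sex and the
#'   trait, plus a \code{"truth"} attribute.
#' @export
genTraits <- function(island_means, sex_effects = 0, sigma_w = 1,
                      n_per_cell = 15L, trait = "trait", seed = 1L) {
  if (is.null(names(island_means)) || length(island_means) < 2L)
    stop("island_means must be a named vector with >= 2 populations")
  pops <- names(island_means)
  if (length(sex_effects) == 1L)
    sex_effects <- stats::setNames(rep(sex_effects, length(pops)), pops)
  if (length(n_per_cell) == 1L)
    n_per_cell <- stats::setNames(rep(as.integer(n_per_cell),
                                      2L * length(pops)),
                                  paste(rep(pops, each = 2),
                                        c("female", "male"), sep = "."))
  if (any(n_per_cell < 1L)) stop("all cell counts must be >= 1")
  if (sigma_w < 0) stop("sigma_w must be >= 0")

  withSeed(seed, {
    rows <- do.call(rbind, lapply(pops, function(p) {
      do.call(rbind, lapply(c("female", "male"), function(s) {
        n <- n_per_cell[[paste(p, s, sep = ".")]]
        mu <- island_means[[p]] + if (s == "male") sex_effects[[p]] else 0
        data.frame(population = p, sex = s,
                   value = mu + stats::rnorm(n, 0, sigma_w),
                   stringsAsFactors = FALSE)
      }))
    }))
    rows <- cbind(individual_id = sprintf("ind%03d", seq_len(nrow(rows))),
                  rows)
    names(rows)[names(rows) == "value"] <- trait
    attr(rows, "truth") <- list(island_means = island_means,
                                sex_effects = sex_effects,
                                sigma_w = sigma_w)
    rows
  })
}

#' Generate multi-locus haplotype alignments from known frequencies
#'
#' For each locus, draws haplotype labels multinomially per population
#' from the supplied frequency vectors and emits concrete biallelic
#' sequences realizing those labels: a fixed reference string with one
#' designated substitution site per non-reference haplotype, so every
#' generated alignment passes [filterInfiniteSites()] unchanged.
#' Optionally injects gap/ambiguity characters to exercise the
#' missing-data rules.
#'
#' @param haplotype_freqs named list, population -> frequency vector (all
#'   vectors the same length, each summing to 1).
#' @param n_sequences named integer vector, population -> number of
#'   sequences per locus.
#' @param n_loci number of loci.
#' @param seq_length sequence length per locus (>= number of haplotypes).
#' @param missing_rate per-base probability of replacing a base with 'N'
#'   (default 0, off).
#' @param seed integer RNG seed.
#' @return list with elements \code{alignments} (list of
#'   [HaplotypeAlignment-class]) and \code{popmap} (named vector
#'   sample_id -> population).
#' @export
genHaplotypes <- function(haplotype_freqs, n_sequences, n_loci = 5L,
                          seq_length = 120L, missing_rate = 0,
                          seed = 1L) {
  pops <- names(haplotype_freqs)
  if (is.null(pops) || length(pops) < 2L)
    stop("haplotype_freqs must be a named list with >= 2 populations")
  H <- unique(lengths(haplotype_freqs))
  if (length(H) != 1L)
    stop("frequency vectors must all have the same length")
  if (any(abs(vapply(haplotype_freqs, sum, numeric(1)) - 1) > 1e-9))
    stop("frequency vectors must sum to 1")
  if (H < 2L) stop("need >= 2 distinct haplotypes")
  if (seq_length < H) stop("seq_length must be >= number of haplotypes")
  n_sequences <- n_sequences[pops]
  if (any(is.na(n_sequences)) || any(n_sequences < 1L))
    stop("n_sequences must cover every population with counts >= 1")

  withSeed(seed, {
    bases <- c("A", "C", "G", "T")
    popmap <- character(0)
    alns <- lapply(seq_len(n_loci), function(l) {
      ref <- sample(bases, seq_length, replace = TRUE)
      # haplotype h > 1 carries a private substitution at site h - 1
      haps <- vapply(seq_len(H), function(h) {
        s <- ref
        if (h > 1L) {
          alt <- setdiff(bases, s[h - 1L])[1]
          s[h - 1L] <- alt
        }
        paste(s, collapse = "")
      }, character(1))
      seqs <- character(0); ids <- character(0)
      for (p in pops) {
        counts <- drop(stats::rmultinom(1, n_sequences[[p]],
                                        haplotype_freqs[[p]]))
        lab <- rep(seq_len(H), counts)
        seqs <- c(seqs, haps[lab])
        ids <- c(ids, sprintf("%s_s%02d", p, seq_len(n_sequences[[p]])))
      }
      if (missing_rate > 0) {
        seqs <- vapply(seqs, function(s) {
          ch <- strsplit(s, "")[[1]]
          hit <- stats::runif(length(ch)) < missing_rate
          ch[hit] <- "N"
          paste(ch, collapse = "")
        }, character(1), USE.NAMES = FALSE)
      }
      haplotypeAlignment(stats::setNames(seqs, ids),
                         locus_name = sprintf("locus%02d", l))
    })
    popmap <- unlist(lapply(pops, function(p)
      stats::setNames(rep(p, n_sequences[[p]]),
                      sprintf("%s_s%02d", p, seq_len(n_sequences[[p]])))))
    list(alignments = alns, popmap = popmap)
  })
}

#' Bundled study scenarios with known ground truth
#'
#' Fixed end-to-end scenarios for testing the whole pipeline without any
#' external data. Both share the same migration regime — Nm draws
#' lognormal with median 0.325 (a realistically low inter-island exchange)
#' and log-sd 0.9, giving an F_ST distribution centred near 0.16 with a
#' long upper tail — and two islands with 15 individuals per sex each,
#' residual SD 1.
#' \describe{
#'   \item{drift}{island trait gap consistent with the same F_ST: gap =
#'     \eqn{2\sigma_B} with \eqn{\sigma_B^2 = 2\sigma_W^2 F/(1-F)} at the
#'     median F_ST, so the P_ST posterior overlaps the F_ST distribution.}
#'   \item{selection}{island trait gap of 8 within-population SDs, far
#'     beyond what drift at that migration level produces.}
#' }
#'
#' @param name \code{"drift"} or \code{"selection"}.
#' @param seed integer RNG seed used for all generated pieces.
#' @return list with fields name, nm_median, nm_log_sd, island_means,
#'   sex_effects, sigma_w, n_per_cell, haplotype_freqs, n_sequences,
#'   n_loci, seed.
#' @export
scenarioConfig <- function(name = c("drift", "selection"), seed = 1L) {
  name <- match.arg(name)
  nm_median <- 0.325
  f_med <- fstFromNm(nm_median)             # ~0.161
  sigma_w <- 1
  gap <- if (name == "drift")
    2 * sqrt(2 * sigma_w^2 * f_med / (1 - f_med)) else 8 * sigma_w
  list(name = name, nm_median = nm_median, nm_log_sd = 0.9,
       island_means = c(islandA = 0, islandB = gap),
       sex_effects = c(islandA = 0, islandB = 0),
       sigma_w = sigma_w, n_per_cell = 15L,
       haplotype_freqs = list(islandA = c(0.7, 0.2, 0.1),
                              islandB = c(0.1, 0.3, 0.6)),
       n_sequences = c(islandA = 20L, islandB = 20L),
       n_loci = 5L, seed = as.integer(seed))
}

#' Run one bundled scenario end to end
#'
#' Generates Nm draws, transforms them to F_ST, simulates the trait table,
#' fits the hierarchical model, and compares the posteriors. Intended for
#' calibration checks: the \code{"drift"} scenario should typically give
#' \code{drift_not_rejected}, the \code{"selection"} scenario
#' \code{drift_rejected}.
#'
#' @param cfg a [scenarioConfig()] list.
#' @param mcmc an [mcmcConfig()]; default is a short two-chain run sized
#'   for calibration loops.
#' @return list with fields fst (PosteriorDraws), fit (TraitFit),
#'   comparison (DriftComparison).
#' @export
runScenario <- function(cfg, mcmc = mcmcConfig(n_chains = 2L,
                                               burn_in = 1000L,
                                               n_iter = 2000L, thin = 2L,
                                               seed = cfg$seed)) {
  nm <- genNmDraws(cfg$nm_median, cfg$nm_log_sd, n = 4000L,
                   seed = cfg$seed, population = "islandB")
  fst <- fstDistribution(nm, d = 2L)
  traits <- genTraits(cfg$island_means, cfg$sex_effects, cfg$sigma_w,
                      cfg$n_per_cell, trait = "trait", seed = cfg$seed + 1L)
  fit <- fitTraitModel(traits, modelSpec("trait", sex_effect = "none"),
                       mcmc)
  list(fst = fst, fit = fit,
       comparison = driftCompare(fit, fst))
}
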