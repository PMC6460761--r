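#' Remove sites violating the infinite-sites model
#'
#' Restricts an alignment to columns with at most two distinct nucleotide
#' states. Under the infinite-sites mutation model each site mutates at
#' most once, so a site with more than two states is inconsistent with the
#' model and is removed before haplotype-based analyses. Gap (\code{-})
#' and ambiguity (\code{N}) characters are ignored when counting states;
#' comparison is case-insensitive (sequences are stored upper-case).
#'
#' The indices (in the original alignment) of removed columns are recorded
#' and retrievable with [removedSites()]. The operation is idempotent: a
#' second application removes nothing and preserves the recorded indices.
#'
#' @param aln a [HaplotypeAlignment-class] object.
#' @return A filtered [HaplotypeAlignment-class] object.
#' @export
filterInfiniteSites <- function(aln) {
  stopifnot(methods::is(aln, "HaplotypeAlignment"))
  mat <- as.matrix(aln@sequences)
  if (ncol(mat) == 0L) stop("empty alignment")
  keep <- vapply(seq_len(ncol(mat)), function(j) {
    states <- unique(mat[, j])
    states <- states[states %in% c("A", "C", "G", "T")]
    length(states) <= 2L
  }, logical(1))
  removed_now <- which(!keep)
  prior <- removedSites(aln)
  # map indices of the current (possibly pre-filtered) alignment back to
  # the original coordinate system recorded on a previous pass
  if (length(prior)) {
    orig_cols <- setdiff(seq_len(ncol(mat) + length(prior)), prior)
    removed_all <- sort(c(prior, orig_cols[removed_now]))
  } else {
    removed_all <- removed_now
  }
  seqs <- if (length(removed_now)) {
    kept <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
    Biostrings::DNAStringSet(stats::setNames(kept, rownames(mat)))
  } else {
    aln@sequences
  }
  attr(seqs, "removed_sites") <- as.integer(removed_all)
  new("HaplotypeAlignment", locus_name = aln@locus_name, sequences = seqs)
}

# Call haplotypes as alleles: exact sequence identity after filtering.
# Sequences still containing '-' or 'N' have undefined haplotype identity
# and are dropped with a warning. Returns a k x H count matrix
# (populations x haplotypes).
haplotypeCounts <- function(aln, pops) {
  ids <- sampleIds(aln)
  unassigned <- setdiff(ids, names(pops))
  if (length(unassigned))
    stop("samples missing from population map: ",
         paste(unassigned, collapse = ", "))
  seqs <- as.character(aln@sequences)
  incomplete <- grepl("[-N]", seqs)
  if (any(incomplete)) {
    warning(sprintf(
      "locus '%s': dropping %d sequence(s) with missing data after filtering (%s)",
      aln@locus_name, sum(incomplete),
      paste(ids[incomplete], collapse = ", ")))
    seqs <- seqs[!incomplete]
    ids <- ids[!incomplete]
  }
  pop <- as.character(pops[ids])
  hap <- match(seqs, unique(seqs))
  table(factor(pop, levels = sort(unique(as.character(pops)))), hap)
}

#' Nei–Chesser heterozygosities for one locus
#'
#' Treats whole haplotypes as alleles and computes small-sample-corrected
#' within-population (Hs) and total (Ht) expected heterozygosity:
#' \deqn{H_S = \frac{\tilde n}{\tilde n - 1}\Big(1 - \overline{\sum_i \hat p_i^2}\Big), \qquad
#'       H_T = 1 - \sum_i \bar p_i^2 + \frac{H_S}{\tilde n k},}
#' with \eqn{\tilde n} the harmonic mean of per-population sequence counts,
#' \eqn{\hat p_i} within-population haplotype frequencies and
#' \eqn{\bar p_i} their unweighted mean across the k populations. For
#' haploid sequence data the observed-heterozygosity correction term is
#' zero. If the corrected Ht falls below Hs it is clamped up to Hs and the
#' result flagged.
#'
#' @param aln a [HaplotypeAlignment-class] object (typically already passed
#'   through [filterInfiniteSites()]).
#' @param pops a population map: named vector \code{sample_id -> population}
#'   covering every sequence, with >= 2 populations.
#' @return A [LocusDiversity-class] object.
#' @export
locusHeterozygosities <- function(aln, pops) {
  stopifnot(methods::is(aln, "HaplotypeAlignment"))
  counts <- haplotypeCounts(aln, pops)
  n_j <- rowSums(counts)
  if (any(n_j == 0))
    stop("population(s) with zero sequences at locus '", aln@locus_name,
         "': ", paste(rownames(counts)[n_j == 0], collapse = ", "))
  k <- nrow(counts)
  if (k < 2L) stop("need >= 2 populations")
  n_tilde <- k / sum(1 / n_j)
  p_hat <- counts / n_j                       # within-pop frequencies
  hs_raw <- 1 - mean(rowSums(p_hat^2))
  hs <- n_tilde / (n_tilde - 1) * hs_raw
  p_bar <- colMeans(p_hat)
  ht <- 1 - sum(p_bar^2) + hs / (n_tilde * k)
  clamped <- ht < hs
  if (clamped) ht <- hs
  new("LocusDiversity", locus_name = aln@locus_name,
      hs = hs, ht = min(ht, 1), k = as.integer(k),
      n_harmonic = n_tilde, ht_clamped = clamped)
}

#' Hedrick's standardized G'_ST for one locus
#'
#' \eqn{G_{ST} = (H_T - H_S)/H_T}, standardized by its maximum attainable
#' value given the within-population diversity and the number of
#' populations:
#' \deqn{G'_{ST} = G_{ST} \frac{k - 1 + H_S}{(k - 1)(1 - H_S)},}
#' clamped to [0, 1].
#'
#' @param ld a [LocusDiversity-class] object.
#' @return G'_ST in [0, 1], or \code{NA_real_} for a monomorphic locus
#'   (Ht = 0, differentiation undefined); such loci are excluded from
#'   multi-locus pooling.
#' @export
gprimeSt <- function(ld) {
  stopifnot(methods::is(ld, "LocusDiversity"))
  gprimeFromHsHt(ld@hs, ld@ht, ld@k)
}

gprimeFromHsHt <- function(hs, ht, k) {
  if (ht <= 0) return(NA_real_)
  gst <- (ht - hs) / ht
  if (gst == 0) return(0)
  gp <- gst * (k - 1 + hs) / ((k - 1) * (1 - hs))
  min(max(gp, 0), 1)
}

#' Pooled multi-locus G'_ST
#'
#' Pools Hs and Ht by their arithmetic means across informative
#' (polymorphic) loci, then applies the Hedrick standardization to the
#' pooled values. Monomorphic loci (Ht = 0) are excluded with a notice.
#'
#' @param loci list of [LocusDiversity-class] objects.
#' @return Pooled G'_ST (numeric scalar).
#' @export
multilocusGprimeSt <- function(loci) {
  pooledDiversity(loci)$gprime_st
}

pooledDiversity <- function(loci) {
  stopifnot(length(loci) >= 1L,
            all(vapply(loci, methods::is, logical(1), "LocusDiversity")))
  informative <- vapply(loci, function(ld) ld@ht > 0, logical(1))
  excluded <- vapply(loci[!informative], locusName, character(1))
  if (length(excluded))
    message("excluding monomorphic loci from pooling: ",
            paste(excluded, collapse = ", "))
  loci <- loci[informative]
  if (!length(loci)) stop("all loci are monomorphic; G'_ST undefined")
  k <- unique(vapply(loci, function(ld) ld@k, integer(1)))
  if (length(k) != 1L) stop("inconsistent population counts across loci")
  hs <- mean(vapply(loci, function(ld) ld@hs, numeric(1)))
  ht <- mean(vapply(loci, function(ld) ld@ht, numeric(1)))
  list(hs = hs, ht = ht, k = k,
       gst = if (ht > 0) (ht - hs) / ht else NA_real_,
       gprime_st = gprimeFromHsHt(hs, ht, k),
       per_locus = loci, excluded = excluded)
}

#' Multi-locus G'_ST with a stratified bootstrap interval
#'
#' Computes the pooled multi-locus G'_ST point estimate and a bootstrap
#' distribution around it: each replicate resamples individuals with
#' replacement within each population (preserving per-population sample
#' sizes, the quantity the Nei–Chesser estimators correct for), recomputes
#' the pooled G'_ST over all loci, and the 2.5/97.5 empirical percentiles
#' of the replicates give the interval. Deterministic given \code{seed}.
#'
#' @param alns list of [HaplotypeAlignment-class] objects, one per locus.
#' @param pops population map (named vector \code{sample_id -> population}).
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer RNG seed.
#' @return A [GstResult-class] object.
#' @export
bootstrapGprime <- function(alns, pops, n_boot = 1000L, seed = 1L) {
  if (n_boot < 100L)
    stop("n_boot must be >= 100 (percentiles unstable below that)")
  pops <- popmapVector(pops)
  point <- pooledDiversity(lapply(alns, locusHeterozygosities, pops = pops))

  all_ids <- unique(unlist(lapply(alns, sampleIds)))
  all_ids <- intersect(names(pops), all_ids)
  by_pop <- split(all_ids, as.character(pops[all_ids]))

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  seq_by_locus <- lapply(alns, function(a)
    stats::setNames(as.character(a@sequences), sampleIds(a)))
  reps <- vapply(seq_len(n_boot), function(b) {
    picked <- unlist(lapply(by_pop, function(ids)
      sample(ids, length(ids), replace = TRUE)), use.names = FALSE)
    new_ids <- sprintf("bs%04d_%s", seq_along(picked), picked)
    lds <- lapply(seq_along(alns), function(li) {
      sv <- seq_by_locus[[li]]
      present <- picked %in% names(sv)
      aln_b <- haplotypeAlignment(sv[picked[present]],
                                  alns[[li]]@locus_name,
                                  sample_ids = new_ids[present])
      locusHeterozygosities(
        aln_b, stats::setNames(as.character(pops[picked[present]]),
                               new_ids[present]))
    })
    suppressMessages(tryCatch(pooledDiversity(lds)$gprime_st,
                              error = function(e) NA_real_))
  }, numeric(1))

  ci <- stats::quantile(reps, c(0.025, 0.975), type = 7, na.rm = TRUE)
  new("GstResult", gst = point$gst, gprime_st = point$gprime_st,
      per_locus = point$per_locus,
      excluded_loci = as.character(point$excluded),
      ci_low = unname(ci[1]), ci_high = unname(ci[2]),
      n_boot = as.integer(n_boot), seed = as.integer(seed))
}

# accept a named vector, or a data.frame with columns (sample_id, population)
popmapVector <- function(pops) {
  if (is.data.frame(pops)) {
    stopifnot(ncol(pops) >= 2L)
    pops <- stats::setNames(as.character(pops[[2]]), as.character(pops[[1]]))
  }
  if (is.null(names(pops))) stop("population map must be named by sample id")
  pops
}
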