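popmap2 <- function(n1, n2, pops = c("A", "B")) {
  setNames(rep(pops, c(n1, n2)),
           c(sprintf("a%02d", seq_len(n1)), sprintf("b%02d", seq_len(n2))))
}

test_that("infinite-sites filter removes >2-state columns only", {
  aln <- haplotypeAlignment(c(s1 = "ACGT", s2 = "ACGT", s3 = "AGGA"))
  # column 2: C/C/G (2 states, kept); column 4: T/T/A (2 states, kept)
  expect_identical(removedSites(filterInfiniteSites(aln)), integer(0))

  aln3 <- haplotypeAlignment(c(s1 = "AAGT", s2 = "CAGT", s3 = "GAGT"))
  f <- filterInfiniteSites(aln3)               # column 1 has {A,C,G}
  expect_identical(removedSites(f), 1L)
  expect_identical(unname(as.character(f@sequences)),
                   c("AGT", "AGT", "AGT"))
})

test_that("gaps and Ns are ignored when counting site states", {
  aln <- haplotypeAlignment(c(s1 = "AA", s2 = "AA", s3 = "-A",
                              s4 = "NA", s5 = "CA"))
  f <- filterInfiniteSites(aln)                # column 1: {A, C} + missing
  expect_identical(removedSites(f), integer(0))
  expect_identical(Biostrings::width(f@sequences)[1], 2L)
})

test_that("infinite-sites filter is idempotent", {
  set.seed(9)
  h <- genHaplotypes(list(A = c(0.5, 0.3, 0.2), B = c(0.2, 0.3, 0.5)),
                     c(A = 8L, B = 8L), n_loci = 1, seed = 5)
  aln <- haplotypeAlignment(c(s1 = "AAGT", s2 = "CAGT", s3 = "GAGA"))
  f1 <- filterInfiniteSites(aln)
  f2 <- filterInfiniteSites(f1)
  expect_identical(as.character(f1@sequences), as.character(f2@sequences))
  expect_identical(removedSites(f1), removedSites(f2))
  # generated alignments pass unchanged by construction
  g <- filterInfiniteSites(h$alignments[[1]])
  expect_identical(removedSites(g), integer(0))
})

test_that("heterozygosities match an independent direct-frequency oracle", {
  # pop1 freqs (0.5, 0.5), pop2 (1.0, 0), n = 10 each
  seqs <- c(rep("AAA", 5), rep("ACA", 5), rep("AAA", 10))
  aln <- haplotypeAlignment(setNames(seqs, names(popmap2(10, 10))))
  pm <- popmap2(10, 10)
  ld <- locusHeterozygosities(aln, pm)
  o <- oracleGst(hapLabels(aln, pm))
  expect_equal(ld@hs, o$hs, tolerance = 1e-12)
  expect_equal(ld@ht, o$ht, tolerance = 1e-12)
  expect_equal(gprimeSt(ld), o$gprime, tolerance = 1e-12)

  # randomized instances, <= 20 sequences and <= 10 haplotypes
  set.seed(77)
  for (rep in 1:20) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    H <- sample(2:6, 1)
    haps <- vapply(seq_len(H), function(h) {
      s <- rep("A", H); s[h] <- "C"; paste(s, collapse = "")
    }, character(1))
    s1 <- sample(haps, n1, TRUE); s2 <- sample(haps, n2, TRUE)
    pm <- popmap2(n1, n2)
    aln <- haplotypeAlignment(setNames(c(s1, s2), names(pm)))
    ld <- locusHeterozygosities(aln, pm)
    o <- oracleGst(hapLabels(aln, pm))
    expect_equal(ld@hs, o$hs, tolerance = 1e-12)
    expect_equal(ld@ht, o$ht, tolerance = 1e-12)
    g <- gprimeSt(ld)
    if (is.na(g)) expect_true(is.na(o$gprime)) else
      expect_equal(g, o$gprime, tolerance = 1e-12)
  }
})

test_that("G'_ST hits its closed-form landmarks", {
  mk <- function(hs, ht) new("LocusDiversity", locus_name = "l", hs = hs,
                             ht = ht, k = 2L, n_harmonic = 10,
                             ht_clamped = FALSE)
  expect_equal(gprimeSt(mk(0, 0.5)), 1)       # maximal differentiation
  expect_equal(gprimeSt(mk(0.4, 0.4)), 0)     # none
  expect_equal(gprimeSt(mk(0.2, 0.4)), 0.5 * 1.2 / 0.8)
  expect_true(is.na(gprimeSt(mk(0, 0))))      # monomorphic
})

test_that("Hedrick standardization never shrinks G_ST", {
  set.seed(31)
  for (rep in 1:50) {
    hs <- runif(1, 0, 0.9)
    ht <- runif(1, hs, min(1, hs + 0.5))
    ld <- new("LocusDiversity", locus_name = "l", hs = hs, ht = ht,
              k = 2L, n_harmonic = 10, ht_clamped = FALSE)
    gst <- (ht - hs) / ht
    expect_gte(gprimeSt(ld) + 1e-12, gst)
  }
})

test_that("multi-locus pooling averages hs and ht across loci", {
  pm <- popmap2(10, 10)
  seqsA <- setNames(c(rep("AAA", 5), rep("ACA", 5), rep("AAA", 10)),
                    names(pm))
  seqsB <- setNames(c(rep("GGG", 10), rep("GTG", 10)), names(pm))
  seqsC <- setNames(c(rep("TTT", 2), rep("TAT", 8), rep("TAT", 3),
                      rep("TTT", 7)), names(pm))
  l1 <- locusHeterozygosities(haplotypeAlignment(seqsA, "l1"), pm)
  l2 <- locusHeterozygosities(haplotypeAlignment(seqsB, "l2"), pm)
  l3 <- locusHeterozygosities(haplotypeAlignment(seqsC, "l3"), pm)
  expect_equal(multilocusGprimeSt(list(l1)), gprimeSt(l1))
  expect_equal(multilocusGprimeSt(list(l1, l1)), gprimeSt(l1))
  # heterogeneous loci: pooled means, computed directly
  hs <- mean(c(l1@hs, l2@hs, l3@hs))
  ht <- mean(c(l1@ht, l2@ht, l3@ht))
  gst <- (ht - hs) / ht
  expect_equal(multilocusGprimeSt(list(l1, l2, l3)),
               gst * (2 - 1 + hs) / ((2 - 1) * (1 - hs)),
               tolerance = 1e-12)
})

test_that("fixed differences give a degenerate bootstrap at 1", {
  h <- genHaplotypes(list(A = c(1, 0), B = c(0, 1)), c(A = 10L, B = 10L),
                     n_loci = 2, seed = 5)
  r <- bootstrapGprime(h$alignments, h$popmap, n_boot = 100, seed = 3)
  expect_equal(r@gprime_st, 1)
  expect_equal(c(r@ci_low, r@ci_high), c(1, 1))
})

test_that("bootstrap is deterministic given the seed", {
  h <- genHaplotypes(list(A = c(0.6, 0.3, 0.1), B = c(0.1, 0.2, 0.7)),
                     c(A = 12L, B = 12L), n_loci = 3, seed = 8)
  r1 <- bootstrapGprime(h$alignments, h$popmap, n_boot = 150, seed = 21)
  r2 <- bootstrapGprime(h$alignments, h$popmap, n_boot = 150, seed = 21)
  expect_equal(c(r1@ci_low, r1@ci_high), c(r2@ci_low, r2@ci_high))
  expect_error(bootstrapGprime(h$alignments, h$popmap, n_boot = 50),
               "n_boot")
})

test_that("permuting population labels destroys the differentiation signal", {
  h <- genHaplotypes(list(A = c(0.9, 0.1), B = c(0.1, 0.9)),
                     c(A = 15L, B = 15L), n_loci = 4, seed = 13)
  lds <- lapply(h$alignments, locusHeterozygosities, pops = h$popmap)
  observed <- multilocusGprimeSt(lds)
  set.seed(99)
  perm <- replicate(200, {
    pm <- setNames(sample(unname(h$popmap)), names(h$popmap))
    suppressMessages(tryCatch(
      multilocusGprimeSt(lapply(h$alignments, locusHeterozygosities,
                                pops = pm)),
      error = function(e) NA_real_))
  })
  expect_lt(mean(perm, na.rm = TRUE), observed)
})

test_that("bootstrap interval covers the point estimate in simulation", {
  set.seed(55)
  hits <- 0L
  for (rep in 1:50) {
    h <- genHaplotypes(list(A = c(0.7, 0.2, 0.1), B = c(0.2, 0.3, 0.5)),
                       c(A = 15L, B = 15L), n_loci = 4, seed = 1000 + rep)
    r <- bootstrapGprime(h$alignments, h$popmap, n_boot = 200,
                         seed = 2000 + rep)
    if (r@gprime_st >= r@ci_low && r@gprime_st <= r@ci_high)
      hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})
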