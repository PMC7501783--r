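test_that("single-locus spectra put the count in the right cell", {
  # one derived copy on a pop1 haplotype only
  a <- matrix(0L, 1, 8)
  a[1, 1] <- 1L
  d <- makeDataset(a, 2, 2)
  v <- sfsValues(buildJointSFS(d, polarized = TRUE))
  expect_equal(v[2, 1], 1)
  expect_equal(sum(v), 1)
})

test_that("spectrum counting matches a brute-force per-locus loop", {
  d <- quickDataset(seed = 17, L = 200)
  sfs <- buildJointSFS(d, polarized = TRUE)
  a <- alleleMatrix(d)
  hp <- hapPop(d)
  ref <- matrix(0, 2 * 3 + 1, 2 * 3 + 1)
  for (l in seq_len(nrow(a))) {
    i <- sum(a[l, hp == "pop1"])
    j <- sum(a[l, hp == "pop2"])
    ref[i + 1, j + 1] <- ref[i + 1, j + 1] + 1
  }
  ref[1, 1] <- 0
  ref[7, 7] <- 0  # masked corners are zeroed by construction
  expect_equal(sfsValues(sfs), ref)
  # conservation: unmasked polarized total = locus count (no fixed cells
  # can occur in a variable-locus dataset)
  expect_equal(sfsTotal(sfs), nLoci(d))
})

test_that("folding reflects, halves the diagonal, and conserves mass", {
  # n1 = n2 = 1 (2+2 haplotypes): cell (2,1) reflects onto (0,1)
  v <- matrix(0, 3, 3)
  v[3, 2] <- 3
  f <- foldSFS(jointSFS(v, 1, 1))
  expect_equal(sfsValues(f)[1, 2], 3)
  expect_true(isFolded(f))
  # diagonal rule: i + j = half receives the average of the pair
  v2 <- matrix(0, 3, 3)
  v2[1, 3] <- 2  # (0,2)
  v2[3, 1] <- 4  # (2,0), its reflection
  f2 <- foldSFS(jointSFS(v2, 1, 1))
  # both conjugate diagonal cells carry the average, conserving mass
  expect_equal(sfsValues(f2)[1, 3], 3)
  expect_equal(sfsValues(f2)[3, 1], 3)
  expect_false(sfsMask(f2)[3, 1])
  # conservation on random spectra
  set.seed(2)
  for (rep in 1:5) {
    v3 <- matrix(rpois(5 * 7, 3), 5, 7)
    u <- jointSFS(v3, 2, 3)
    expect_equal(sfsTotal(foldSFS(u)), sfsTotal(u))
  }
  expect_error(foldSFS(f), "already folded")
})

test_that("spectrum files round-trip", {
  d <- quickDataset(seed = 23, L = 150)
  for (sfs in list(buildJointSFS(d), buildJointSFS(d, polarized = TRUE))) {
    path <- tempfile(fileext = ".fs")
    writeSpectrum(sfs, path)
    back <- readSpectrum(path)
    expect_equal(sfsValues(back), sfsValues(sfs))
    expect_identical(sfsMask(back), sfsMask(sfs))
    expect_identical(isFolded(back), isFolded(sfs))
  }
})

test_that("subsampling keeps whole individuals and drops monomorphic loci", {
  d <- quickDataset(seed = 29, L = 400)
  expect_error(subsampleIndividuals(d, 4), "k must be in")
  # k = full size returns the same multiset of individuals
  full <- subsampleIndividuals(d, 3, seed = 1)
  expect_identical(alleleMatrix(full), alleleMatrix(d))
  expect_identical(sampleIds(full), sampleIds(d))
  # a locus private to one non-sampled individual must vanish
  a <- rbind(c(1L, rep(0L, 7)), c(1L, 1L, 1L, 0L, 0L, 1L, 0L, 1L))
  toy <- makeDataset(a, 2, 2)
  s <- NULL
  for (sd in 1:50) {
    cand <- subsampleIndividuals(toy, 1, seed = sd)
    if (!"a1" %in% sampleIds(cand)) { s <- cand; break }
  }
  expect_false(is.null(s))
  expect_equal(nLoci(s), 1L)
  expect_equal(s@provenance$n_monomorphic_dropped, 1L)
})

test_that("subsampling draws individuals uniformly without replacement", {
  d <- quickDataset(seed = 37, L = 120, n1 = 6, n2 = 6)
  counts <- setNames(numeric(6), sampleIds(d)[1:6])
  nDraw <- 4000
  for (s in seq_len(nDraw)) {
    ids <- sampleIds(subsampleIndividuals(d, 2, seed = s))
    inPop1 <- ids[ids %in% names(counts)]
    counts[inPop1] <- counts[inPop1] + 1
  }
  p <- counts / nDraw
  se <- sqrt((2 / 6) * (1 - 2 / 6) / nDraw)
  expect_true(all(abs(p - 2 / 6) < 4 * se))
})

test_that("Weir-Cockerham F_ST matches an independent variance decomposition", {
  # oracle: explicit ANOVA sums of squares on allele indicators
  # (pops / individuals within pops / haplotypes within individuals):
  # a = (MSP - MSI) / (2 nc), b = (MSI - MSG) / 2, c = MSG
  wcOracle <- function(dataset) {
    a <- alleleMatrix(dataset)
    pl <- popLabels(dataset)
    pops <- popNames(dataset)
    n <- c(sum(pl == pops[1]), sum(pl == pops[2]))
    N <- sum(n)
    r <- 2
    nc <- (N - sum(n^2) / N) / (r - 1)
    num <- den <- 0
    for (l in seq_len(nrow(a))) {
      y <- a[l, ]
      ind <- rep(seq_len(N), each = 2)
      popOf <- rep(pl, each = 2)
      yInd <- tapply(y, ind, mean)[as.character(ind)]
      yPopTab <- tapply(y, popOf, mean)
      yPop <- yPopTab[popOf]
      grand <- sum(n * yPopTab[pops]) / N
      msg <- sum((y - yInd)^2) / N
      msi <- sum((yInd - yPop)^2) / (N - r)
      msp <- sum((yPop - grand)^2) / (r - 1)
      aC <- (msp - msi) / (2 * nc)
      bC <- (msi - msg) / 2
      cC <- msg
      num <- num + aC
      den <- den + aC + bC + cC
    }
    num / den
  }
  d <- quickDataset(seed = 41, L = 300, n1 = 4, n2 = 3)
  got <- wcFst(d)
  expect_equal(got$fst, wcOracle(d), tolerance = 1e-10)
  expect_lte(got$fst, 1)
  # fixed differences at every locus -> F_ST = 1
  fixed <- makeDataset(rbind(c(1, 1, 1, 1, 0, 0, 0, 0),
                             c(1, 1, 1, 1, 0, 0, 0, 0)), 2, 2)
  expect_equal(wcFst(fixed)$fst, 1)
  # identical frequencies, no differentiation: F_ST near zero on large data
  big <- simulateDataset(simConfig(6, 6, 3000, panmicticParams(), 0.05,
                                   seed = 51))
  expect_lt(abs(wcFst(big)$fst), 0.01)
})
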