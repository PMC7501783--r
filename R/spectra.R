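#' Construct a JointSFS
#'
#' Low-level constructor; the fixed corners (0,0) and (2n1,2n2) are always
#' masked and their values zeroed.
#'
#' @param values (2n1+1) x (2n2+1) non-negative matrix.
#' @param n1,n2 diploid sample sizes.
#' @param folded logical.
#' @param mask optional logical matrix; corner masking is enforced on top.
#' @return a \linkS4class{JointSFS}.
#' @export
jointSFS <- function(values, n1, n2, folded = FALSE, mask = NULL) {
  d <- dim(values)
  if (is.null(mask)) mask <- matrix(FALSE, d[1], d[2])
  mask[1, 1] <- TRUE
  mask[d[1], d[2]] <- TRUE
  values[mask] <- 0
  new("JointSFS", values = values, mask = mask, folded = folded,
      n1 = as.integer(n1), n2 = as.integer(n2))
}

#' @rdname sfsAccessors
#' @export
sfsValues <- function(sfs) sfs@values

#' Accessors for JointSFS
#'
#' @param sfs a \linkS4class{JointSFS}.
#' @return \code{sfsValues}: the value matrix; \code{sfsMask}: the logical
#'   mask; \code{isFolded}: the folded flag; \code{sfsTotal}: total
#'   unmasked mass.
#' @name sfsAccessors
#' @export
sfsMask <- function(sfs) sfs@mask

#' @rdname sfsAccessors
#' @export
isFolded <- function(sfs) sfs@folded

#' @rdname sfsAccessors
#' @export
sfsTotal <- function(sfs) sum(sfs@values[!sfs@mask])

#' Build the joint site-frequency spectrum of a dataset
#'
#' Cell (i, j) counts loci with i derived copies among the 2n1 population-1
#' haplotypes and j among the 2n2 population-2 haplotypes.  With
#' \code{polarized = FALSE} (default) the spectrum is folded onto
#' minor-allele counts, the conservative choice when ancestral states are
#' not known from an outgroup.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param polarized keep derived-allele polarization (unfolded spectrum)?
#' @return a \linkS4class{JointSFS}.
#' @export
buildJointSFS <- function(dataset, polarized = FALSE) {
  if (nLoci(dataset) == 0L) stop("empty dataset")
  hp <- hapPop(dataset)
  pops <- popNames(dataset)
  a <- alleleMatrix(dataset)
  i <- rowSums(a[, hp == pops[1], drop = FALSE])
  j <- rowSums(a[, hp == pops[2], drop = FALSE])
  n1h <- sum(hp == pops[1])
  n2h <- sum(hp == pops[2])
  values <- matrix(0, n1h + 1L, n2h + 1L)
  for (l in seq_along(i))
    values[i[l] + 1L, j[l] + 1L] <- values[i[l] + 1L, j[l] + 1L] + 1
  sfs <- jointSFS(values, n1 = n1h / 2, n2 = n2h / 2, folded = FALSE)
  if (polarized) sfs else foldSFS(sfs)
}

#' Fold a joint spectrum onto minor-allele counts
#'
#' Adds each cell to its point reflection through the center:
#' \code{S'[i,j] = S[i,j] + S[2n1-i, 2n2-j]} for cells below the
#' half-frequency diagonal; cells exactly on the diagonal receive the
#' average of the pair; cells above it are masked.  Total unmasked mass is
#' preserved.  Folding an already folded spectrum is an error.
#'
#' @param sfs an unfolded \linkS4class{JointSFS}.
#' @return the folded spectrum.
#' @export
foldSFS <- function(sfs) {
  if (isFolded(sfs)) stop("spectrum is already folded")
  v <- sfs@values
  d <- dim(v)
  tot <- (d[1] - 1L) + (d[2] - 1L)
  ij <- outer(0:(d[1] - 1L), 0:(d[2] - 1L), "+")
  rev_v <- v[d[1]:1, d[2]:1, drop = FALSE]
  out <- v + rev_v
  out[ij == tot / 2] <- out[ij == tot / 2] / 2
  out[ij > tot / 2] <- 0
  mask <- sfs@mask | (sfs@mask[d[1]:1, d[2]:1, drop = FALSE] & ij < tot / 2)
  mask[ij > tot / 2] <- TRUE
  jointSFS(out, sfs@n1, sfs@n2, folded = TRUE, mask = mask)
}

#' Symmetric subsampling of diploid individuals
#'
#' Draws k individuals uniformly without replacement from each population
#' independently, keeping both haplotypes of every chosen individual.
#' Loci rendered monomorphic by the draw are removed (they carry no
#' frequency-spectrum information); the number removed is recorded in the
#' provenance as \code{n_monomorphic_dropped}.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param k diploid individuals to keep per population,
#'   \code{1 <= k <= min(n1, n2)}.
#' @param seed integer seed (local RNG stream).
#' @return a \linkS4class{GenotypeDataset} of 2k individuals.
#' @export
subsampleIndividuals <- function(dataset, k, seed = NULL) {
  pops <- popNames(dataset)
  pl <- popLabels(dataset)
  n <- popSizes(dataset)
  if (k < 1 || k > min(n))
    stop("k must be in [1, ", min(n), "] for this dataset")
  pick <- withSeed(seed, {
    i1 <- sort(sample(which(pl == pops[1]), k))
    i2 <- sort(sample(which(pl == pops[2]), k))
    c(i1, i2)
  })
  hapCols <- as.vector(rbind(2L * pick - 1L, 2L * pick))
  a <- alleleMatrix(dataset)[, hapCols, drop = FALSE]
  dc <- rowSums(a)
  keep <- dc >= 1L & dc <= ncol(a) - 1L
  if (!any(keep))
    stop("subsample has zero variable loci")
  new("GenotypeDataset",
      alleles = a[keep, , drop = FALSE],
      sampleIds = sampleIds(dataset)[pick],
      pop = pl[pick],
      locusIds = dataset@locusIds[keep],
      provenance = c(dataset@provenance[intersect(c("config", "seed"),
                       names(dataset@provenance))],
                     list(subsample_k = k, subsample_seed = seed,
                          subsample_ids = sampleIds(dataset)[pick],
                          n_monomorphic_dropped = sum(!keep))))
}

#' Weir-Cockerham F_ST
#'
#' Two-population Weir & Cockerham (1984) estimator from diploid
#' genotypes, as the ratio of summed variance components across loci:
#' \eqn{\hat F_{ST} = \sum_l a_l / \sum_l (a_l + b_l + c_l)}, with a, b, c
#' the among-population, among-individual and within-individual
#' components.
#'
#' @param dataset a \linkS4class{GenotypeDataset} with >= 1 diploid
#'   individual per population.
#' @return list with \code{fst} and per-locus component sums
#'   (\code{a}, \code{b}, \code{c} vectors, plus their totals).
#' @export
wcFst <- function(dataset) {
  pops <- popNames(dataset)
  pl <- popLabels(dataset)
  a <- alleleMatrix(dataset)
  nind <- popSizes(dataset)
  hp <- hapPop(dataset)
  r <- 2
  n1 <- nind[1]; n2 <- nind[2]
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  g1 <- a[, hp == pops[1], drop = FALSE]
  g2 <- a[, hp == pops[2], drop = FALSE]
  p1 <- rowSums(g1) / (2 * n1)
  p2 <- rowSums(g2) / (2 * n2)
  hetProp <- function(g, n) {
    odd <- g[, 2 * seq_len(n) - 1, drop = FALSE]
    evn <- g[, 2 * seq_len(n), drop = FALSE]
    rowSums(odd != evn) / n
  }
  h1 <- hetProp(g1, n1)
  h2 <- hetProp(g2, n2)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  if (nbar <= 1)
    stop("Weir-Cockerham components need more than one diploid individual ",
         "per population on average")
  aComp <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  bComp <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cComp <- hbar / 2
  den <- sum(aComp + bComp + cComp)
  if (den == 0)
    stop("F_ST undefined: zero total variance across loci (0/0)")
  list(fst = sum(aComp) / den,
       a = aComp, b = bComp, c = cComp,
       a_sum = sum(aComp), b_sum = sum(bComp), c_sum = sum(cComp))
}

#' Write / read the plain-text spectrum format
#'
#' Header line \code{"<2n1> <2n2> <folded 0/1>"}, then the value matrix
#' row by row, then the mask matrix (1 = masked) row by row.
#'
#' @param sfs a \linkS4class{JointSFS}.
#' @param path file path.
#' @return \code{writeSpectrum}: \code{path} invisibly;
#'   \code{readSpectrum}: a \code{JointSFS}.
#' @export
writeSpectrum <- function(sfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- dim(sfs@values)
  writeLines(paste(d[1] - 1L, d[2] - 1L, as.integer(sfs@folded)), con)
  writeLines(apply(format(sfs@values, digits = 17, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(apply(sfs@mask * 1L, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname writeSpectrum
#' @export
readSpectrum <- function(path) {
  lines <- readLines(path)
  hd <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]])
  nr <- hd[1] + 1
  nc <- hd[2] + 1
  parse <- function(rows)
    matrix(as.numeric(unlist(strsplit(trimws(rows), "\\s+"))),
           nrow = nr, ncol = nc, byrow = TRUE)
  values <- parse(lines[2:(1 + nr)])
  mask <- parse(lines[(2 + nr):(1 + 2 * nr)]) > 0
  jointSFS(values, n1 = hd[1] / 2, n2 = hd[2] / 2, folded = hd[3] == 1,
           mask = mask)
}
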