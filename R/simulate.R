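#' Simulation configuration for a split-migration SNP dataset
#'
#' Bundles everything needed to regenerate a dataset: diploid sample
#' sizes, number of loci attempted, demographic parameters, the per-locus
#' scaled mutation parameter \eqn{\Theta_{loc} = 4 N_{ref} \mu_{loc}}, and
#' the root seed.  Defaults emulate a UCE-style SNP panel: 6 diploid
#' individuals per population and a per-locus theta of 0.05, the scale
#' implied by aggregate \eqn{\Theta} estimates of order 100-200 spread
#' over ~2,500 loci.
#'
#' @param n1,n2 diploid individuals per population (haplotypes = 2n).
#' @param L number of loci attempted; loci with no mutation are dropped.
#' @param params \linkS4class{SplitMigParams}.
#' @param thetaLocus per-locus scaled mutation parameter (> 0).
#' @param seed integer root seed recorded in all outputs.
#' @return a list of class \code{"simConfig"}.
#' @export
simConfig <- function(n1 = 6, n2 = 6, L = 3000, params, thetaLocus = 0.05,
                      seed = 1) {
  stopifnot(n1 >= 1, n2 >= 1, L >= 1, thetaLocus > 0,
            is(params, "SplitMigParams"))
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2),
                 L = as.integer(L), params = params,
                 thetaLocus = thetaLocus, seed = as.integer(seed)),
            class = "simConfig")
}

checkParamsFinite <- function(params) {
  v <- paramVector(params)
  if (any(!is.finite(v)))
    stop("non-finite split-migration parameters: ",
         paste(names(v)[!is.finite(v)], collapse = ", "))
  invisible(v)
}

#' Simulate one structured-coalescent genealogy
#'
#' Backward-in-time two-deme coalescent under the split-migration model:
#' for t < T, deme k coalesces pairwise at rate \eqn{1/\nu_k} and each
#' lineage migrates at rate m/2; at t = T all lineages join a single
#' ancestral deme of relative size 1.  Times are in units of
#' \eqn{2 N_{ref}} generations.
#'
#' @param n1,n2 haplotype sample sizes (>= 1 each).
#' @param params \linkS4class{SplitMigParams}.
#' @param seed integer seed.
#' @return list with \code{branches} (matrix: length, n_pop1, n_pop2 of
#'   subtended sampled haplotypes per branch), \code{times} (coalescence
#'   times, increasing toward the root) and \code{total_length}.
#' @export
simulateGenealogy <- function(n1, n2, params, seed = 1) {
  if (n1 < 1 || n2 < 1)
    stop("need at least one sampled haplotype per population")
  if (n1 + n2 > 64) stop("at most 64 haplotypes are supported")
  checkParamsFinite(params)
  g <- sim_genealogy_cpp(n1, n2, params@nu1, params@nu2, params@T,
                         params@m, as.double(seed))
  g$times <- sort(g$times)
  g
}

#' Simulate a two-population SNP dataset
#'
#' For each of \code{L} independent genealogies, mutations fall as a
#' Poisson process with intensity \code{thetaLocus/2} per unit branch
#' length (infinite sites, no intra-locus recombination).  Loci with at
#' least one mutation are retained and thinned to a single SNP chosen
#' uniformly among the locus's mutations, matching a one-SNP-per-locus
#' marker panel.  Per-locus RNG streams are derived from the root seed, so
#' increasing \code{L} extends the dataset without reshuffling earlier
#' loci.
#'
#' @param config a \code{\link{simConfig}}.
#' @return a \linkS4class{GenotypeDataset}; its \code{provenance} records
#'   the config, seed and number of loci attempted/variable.
#' @examples
#' p <- splitMigParams(2, 4, 0.5, 0.5)
#' d <- simulateDataset(simConfig(n1 = 4, n2 = 4, L = 500, params = p, seed = 7))
#' d
#' @export
simulateDataset <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  p <- config$params
  checkParamsFinite(p)
  n1h <- 2L * config$n1
  n2h <- 2L * config$n2
  sim <- sim_loci_cpp(n1h, n2h, p@nu1, p@nu2, p@T, p@m,
                      config$thetaLocus, config$L, as.double(config$seed))
  if (nrow(sim$alleles) == 0L)
    stop("no variable loci: theta_locus = ", config$thetaLocus,
         " produced zero mutated genealogies in ", config$L, " loci")
  ids1 <- sprintf("pop1_ind%02d", seq_len(config$n1))
  ids2 <- sprintf("pop2_ind%02d", seq_len(config$n2))
  new("GenotypeDataset",
      alleles = sim$alleles,
      sampleIds = c(ids1, ids2),
      pop = c(rep("pop1", config$n1), rep("pop2", config$n2)),
      locusIds = sprintf("locus%05d", sim$kept_locus),
      provenance = list(config = config, seed = config$seed,
                        n_attempted = config$L,
                        n_variable = nrow(sim$alleles),
                        n_mutations = sim$n_mut,
                        pi_tree = sim$pi_tree))
}

#' Simulate a fixed-size SNP panel
#'
#' Builds a dataset containing exactly \code{nSNPs} variable loci — the
#' footing on which one-SNP-per-locus datasets are reported (a "2,400-locus
#' dataset" in this literature is 2,400 variable loci; loci without a SNP
#' never enter a dataset).  Implemented by extending the attempted-locus
#' stream until \code{nSNPs} variable loci accumulate and truncating to
#' the first \code{nSNPs}; per-locus RNG streams are keyed to the locus
#' index, so the retained prefix is invariant to how far the stream was
#' extended.
#'
#' @param config a \code{\link{simConfig}}; its \code{L} is used as the
#'   initial number of attempts.
#' @param nSNPs number of variable loci required.
#' @param maxAttempts cap on attempted loci (guards tiny
#'   \code{thetaLocus}).
#' @return a \linkS4class{GenotypeDataset} with \code{nSNPs} loci.
#' @export
simulateSNPPanel <- function(config, nSNPs, maxAttempts = 1e6) {
  stopifnot(inherits(config, "simConfig"), nSNPs >= 1)
  L <- max(config$L, 2L * nSNPs)
  repeat {
    cfg <- config
    cfg$L <- as.integer(L)
    d <- simulateDataset(cfg)
    if (nLoci(d) >= nSNPs) break
    if (L >= maxAttempts)
      stop("could not accumulate ", nSNPs, " variable loci within ",
           maxAttempts, " attempts (thetaLocus = ", config$thetaLocus, ")")
    L <- min(maxAttempts, L * 4L)
  }
  d@alleles <- d@alleles[seq_len(nSNPs), , drop = FALSE]
  d@locusIds <- d@locusIds[seq_len(nSNPs)]
  d@provenance$n_panel <- nSNPs
  validObject(d)
  d
}

#' @rdname accessors
#' @aliases alleleMatrix
#' @export
alleleMatrix <- function(dataset) dataset@alleles

#' Accessors for GenotypeDataset
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @return \code{alleleMatrix}: loci x haplotype 0/1 matrix;
#'   \code{sampleIds}: diploid individual ids; \code{popLabels}:
#'   population label per individual; \code{hapPop}: population label per
#'   haplotype column; \code{popNames}: the two labels, population 1
#'   first; \code{nLoci}: number of (variable) loci.
#' @name accessors
#' @export
sampleIds <- function(dataset) dataset@sampleIds

#' @rdname accessors
#' @export
popLabels <- function(dataset) dataset@pop

#' @rdname accessors
#' @export
hapPop <- function(dataset) rep(dataset@pop, each = 2L)

#' @rdname accessors
#' @export
popNames <- function(dataset) unique(dataset@pop)

#' @rdname accessors
#' @export
nLoci <- function(dataset) nrow(dataset@alleles)

# diploid sample sizes as c(n1, n2), in popNames order
popSizes <- function(dataset) {
  pops <- popNames(dataset)
  c(sum(dataset@pop == pops[1]), sum(dataset@pop == pops[2]))
}
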