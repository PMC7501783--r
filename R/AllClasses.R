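#' @import methods
#' @importFrom stats lm coef optim runif sd setNames
#' @importFrom utils read.table write.table
#' @useDynLib sfsize, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Split-migration model parameters
#'
#' Parameters of the two-population split-migration
#' (isolation-with-migration) model in standard coalescent units: an
#' ancestral population of size \eqn{N_{ref}} splits \eqn{T} time units ago
#' (time in units of \eqn{2 N_{ref}} generations) into two populations of
#' relative sizes \eqn{\nu_1} and \eqn{\nu_2} that exchange migrants
#' symmetrically, each lineage migrating at rate \eqn{m/2} per unit
#' coalescent time.
#'
#' @slot nu1,nu2 contemporary population sizes relative to the ancestral
#'   \eqn{N_{ref}}.
#' @slot T time since divergence in units of \eqn{2 N_{ref}} generations.
#' @slot m symmetric scaled migration rate.
#' @slot bounds numeric matrix with rows \code{lower}, \code{upper} and
#'   columns \code{nu1, nu2, T, m}; all parameters must lie inside.
#' @export
setClass("SplitMigParams",
  representation(nu1 = "numeric", nu2 = "numeric", T = "numeric",
                 m = "numeric", bounds = "matrix"),
  validity = function(object) {
    v <- paramVector(object)
    b <- object@bounds
    if (!is.numeric(b) || !identical(dim(b), c(2L, 4L)))
      return("bounds must be a 2 x 4 numeric matrix (lower, upper)")
    if (any(!is.finite(b)))
      return("bounds must be finite")
    if (any(!is.finite(v)) || any(v <= 0))
      return("all parameters must be finite and strictly positive")
    if (any(v < b[1, ] | v > b[2, ]))
      return("parameters must lie within bounds")
    TRUE
  })

#' Joint site-frequency spectrum
#'
#' A \eqn{(2 n_1 + 1) \times (2 n_2 + 1)} array over derived-allele copy
#' numbers in the two populations.  \code{values} holds observed counts
#' \eqn{S_{ij}} (or model expectations \eqn{M_{ij}}), \code{mask} marks
#' cells excluded from analysis: the fixed corners \eqn{(0,0)} and
#' \eqn{(2n_1, 2n_2)} always, plus the redundant half of a folded
#' spectrum.
#'
#' @slot values non-negative numeric matrix.
#' @slot mask logical matrix, \code{TRUE} = excluded.
#' @slot folded logical flag; a folded spectrum is indexed by minor-allele
#'   counts and cells with \eqn{i + j} above half the total haplotypes are
#'   masked.
#' @slot n1,n2 diploid sample sizes per population.
#' @export
setClass("JointSFS",
  representation(values = "matrix", mask = "matrix", folded = "logical",
                 n1 = "integer", n2 = "integer"),
  validity = function(object) {
    d <- c(2L * object@n1 + 1L, 2L * object@n2 + 1L)
    if (!identical(dim(object@values), d))
      return("values must be (2*n1+1) x (2*n2+1)")
    if (!identical(dim(object@mask), d))
      return("mask must match values in shape")
    if (any(object@values < 0, na.rm = TRUE))
      return("values must be non-negative")
    if (!object@mask[1, 1] || !object@mask[d[1], d[2]])
      return("corner cells (0,0) and (2n1,2n2) must be masked")
    if (object@folded) {
      tot <- 2L * (object@n1 + object@n2)
      ij <- outer(0:(d[1] - 1L), 0:(d[2] - 1L), "+")
      if (any(ij > tot / 2 & !object@mask))
        return("folded spectrum must mask cells with i + j > (2n1+2n2)/2")
    }
    TRUE
  })

#' Two-population phased SNP dataset
#'
#' Phased biallelic genotypes, one SNP per locus, for two labelled
#' populations with complete calls.  Haplotype columns come in pairs per
#' diploid individual (\code{<id>_a}, \code{<id>_b}), population 1 first.
#'
#' @slot alleles integer matrix, loci x haplotypes, entries 0 (ancestral)
#'   or 1 (derived); every locus is variable.
#' @slot sampleIds character, one id per diploid individual.
#' @slot pop character, population label per individual
#'   (\code{"pop1"}/\code{"pop2"} or user labels).
#' @slot locusIds character, one id per locus.
#' @slot provenance list with simulation config / file origin, including
#'   the RNG seed and counts of loci dropped along the way.
#' @export
setClass("GenotypeDataset",
  representation(alleles = "matrix", sampleIds = "character",
                 pop = "character", locusIds = "character",
                 provenance = "list"),
  validity = function(object) {
    a <- object@alleles
    nind <- length(object@sampleIds)
    if (length(object@pop) != nind)
      return("pop must have one label per individual")
    if (length(unique(object@pop)) != 2L)
      return("exactly two populations are required")
    if (ncol(a) != 2L * nind)
      return("alleles must have two haplotype columns per individual")
    if (nrow(a) != length(object@locusIds))
      return("locusIds must have one entry per locus")
    if (any(is.na(a)) || !all(a %in% c(0L, 1L)))
      return("alleles must be 0/1 with no missing calls")
    dc <- rowSums(a)
    if (any(dc < 1L | dc > ncol(a) - 1L))
      return("every locus must be variable (derived count in [1, 2n-1])")
    TRUE
  })

#' Composite-likelihood fit result
#'
#' @slot params \linkS4class{SplitMigParams} point estimate.
#' @slot thetaHat profiled \eqn{\hat\Theta} (\eqn{4 N_{ref} \mu} summed
#'   over loci) at the optimum.
#' @slot logLik maximized Poisson composite log-likelihood.
#' @slot converged logical optimizer flag.
#' @slot nEvals number of objective evaluations.
#' @slot hitBounds named logical: estimate within 1\% (log10 scale) of a
#'   bound.
#' @slot seed run seed.
#' @slot runs data.frame with one row per optimization run (for
#'   \code{\link{fitBestOf}}).
#' @export
setClass("FitResult",
  representation(params = "SplitMigParams", thetaHat = "numeric",
                 logLik = "numeric", converged = "logical",
                 nEvals = "integer", hitBounds = "logical",
                 seed = "numeric", runs = "data.frame"))

setMethod("show", "SplitMigParams", function(object) {
  cat("SplitMigParams: nu1 =", format(object@nu1, digits = 4),
      " nu2 =", format(object@nu2, digits = 4),
      " T =", format(object@T, digits = 4),
      " m =", format(object@m, digits = 4), "\n")
})

setMethod("show", "JointSFS", function(object) {
  cat(sprintf("JointSFS: %d x %d (%s), %d unmasked cells, total mass %.4g\n",
              nrow(object@values), ncol(object@values),
              if (object@folded) "folded" else "unfolded",
              sum(!object@mask), sum(object@values[!object@mask])))
})

setMethod("show", "GenotypeDataset", function(object) {
  tab <- table(object@pop)
  cat(sprintf("GenotypeDataset: %d variable loci, %s diploid individuals (%s)\n",
              nrow(object@alleles),
              paste(tab, collapse = " + "),
              paste(names(tab), collapse = ", ")))
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult (log composite likelihood ",
      format(object@logLik, digits = 8), ")\n", sep = "")
  show(object@params)
  cat("  theta_hat =", format(object@thetaHat, digits = 6),
      " converged =", object@converged,
      " bound hits:", if (any(object@hitBounds))
        paste(names(object@hitBounds)[object@hitBounds], collapse = ",")
      else "none", "\n")
})
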