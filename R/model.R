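#' Expected joint SFS under the split-migration model
#'
#' Monte Carlo expectation engine: the expected spectrum at \eqn{\Theta = 1}
#' is \eqn{M_{ij} = \frac{1}{2} E[\ell_{ij}]}, where \eqn{\ell_{ij}} is the
#' total genealogy branch length subtending exactly i population-1 and j
#' population-2 haplotypes, averaged over \code{R} structured-coalescent
#' genealogies.  Replicate streams are keyed to \code{seed} (common random
#' numbers), so the same seed yields the same genealogy stream at every
#' parameter value and the induced likelihood surface is deterministic and
#' smooth enough for simplex optimization.
#'
#' In the panmictic limit (T -> 0, nu = 1) the marginal over total derived
#' count reduces to the standard neutral expectation
#' \eqn{E[\xi_i] = \Theta / i}, which is the engine's primary correctness
#' oracle.
#'
#' @param params \linkS4class{SplitMigParams}.
#' @param n1,n2 diploid sample sizes.
#' @param R number of genealogy replicates (>= 100; 1e4 is adequate for
#'   fitting, 1e5 for final reporting).
#' @param seed integer stream key.
#' @param folded fold the expectation (to match folded data)?
#' @param regularize floor zero unmasked cells at
#'   \code{eps = 1e-12 * sum(M)} so the Poisson log-likelihood stays
#'   finite; the floor used is attached as attribute \code{"eps"}.
#' @param strict error (instead of warn) if no unmasked cell is positive
#'   before regularization.
#' @return a \linkS4class{JointSFS} of expectations with attributes
#'   \code{engine = list(R, seed, eps)}.
#' @export
expectedSFS <- function(params, n1, n2, R = 10000, seed = 1,
                        folded = TRUE, regularize = TRUE, strict = FALSE) {
  stopifnot(R >= 100)
  checkParamsFinite(params)
  M <- branch_sfs_cpp(2L * n1, 2L * n2, params@nu1, params@nu2,
                      params@T, params@m, as.integer(R), as.double(seed))
  sfs <- jointSFS(M, n1, n2, folded = FALSE)
  if (folded) sfs <- foldSFS(sfs)
  eps <- 0
  if (regularize) {
    un <- !sfs@mask
    if (all(sfs@values[un] <= 0)) {
      msg <- paste0("all unmasked expected-SFS cells are zero at R = ", R)
      if (strict) stop(msg) else warning(msg)
    }
    eps <- 1e-12 * sum(sfs@values[un])
    zero <- un & sfs@values < eps
    sfs@values[zero] <- eps
  }
  attr(sfs, "engine") <- list(R = R, seed = seed, eps = eps)
  sfs
}

checkShapes <- function(data, model) {
  if (!identical(dim(data@values), dim(model@values)))
    stop("data and model spectra have different shapes")
  if (!identical(data@folded, model@folded))
    stop("data and model spectra differ in folding")
  invisible(TRUE)
}

#' Poisson random-field composite log-likelihood
#'
#' Treats unmasked spectrum cells as independent Poisson counts with means
#' \eqn{\theta M_{ij}}:
#' \deqn{\ell = \sum_{ij} S_{ij} \log(\theta M_{ij}) - \theta M_{ij}
#'       - \log\Gamma(S_{ij} + 1).}
#' Cells masked in either spectrum are excluded.
#'
#' @param data observed \linkS4class{JointSFS} (counts).
#' @param model expected \linkS4class{JointSFS} at theta = 1.
#' @param theta non-negative scale; \code{theta = 0} with any observed
#'   count returns \code{-Inf}.
#' @return the log composite likelihood (numeric scalar).
#' @export
poissonLogLik <- function(data, model, theta) {
  checkShapes(data, model)
  stopifnot(theta >= 0)
  un <- !(data@mask | model@mask)
  S <- data@values[un]
  M <- model@values[un]
  mu <- theta * M
  if (any(mu <= 0 & S > 0)) return(-Inf)
  term <- ifelse(S > 0, S * log(mu), 0)
  sum(term - mu - lgamma(S + 1))
}

#' Profiled theta estimate
#'
#' The Poisson composite likelihood is maximized in \eqn{\theta} at the
#' ratio of total observed to total expected mass over unmasked cells:
#' \eqn{\hat\theta = \sum S_{ij} / \sum M_{ij}}.  This is the aggregate
#' \eqn{\Theta = 4 N_{ref} \mu} over loci on the model's scale.
#'
#' @inheritParams poissonLogLik
#' @return \eqn{\hat\theta} (numeric scalar).
#' @export
optimalTheta <- function(data, model) {
  checkShapes(data, model)
  un <- !(data@mask | model@mask)
  if (!any(un)) stop("no unmasked cells")
  sM <- sum(model@values[un])
  if (sM <= 0) stop("total expected mass is zero")
  sum(data@values[un]) / sM
}
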