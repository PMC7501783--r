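#' Configuration for composite-likelihood optimization
#'
#' @param start \linkS4class{SplitMigParams} starting values (typically
#'   the full-dataset optimum when fitting subsamples).
#' @param perturbFold multiplicative perturbation half-width in log2 units
#'   applied to the start of each run (0 = start exactly at \code{start}).
#' @param kRuns independent optimization runs per dataset for
#'   \code{\link{fitBestOf}}.
#' @param maxEvals maximum objective evaluations per run.
#' @param funcTol relative function-value convergence tolerance of the
#'   Nelder-Mead simplex.
#' @param engineR genealogy replicates per expected-SFS evaluation.
#' @param engineSeed common-random-numbers stream key shared by every
#'   objective evaluation, making the surface deterministic.
#' @param seed run seed driving the start perturbations.
#' @return list of class \code{"fitConfig"}.
#' @export
fitConfig <- function(start, perturbFold = 1, kRuns = 5, maxEvals = 400,
                      funcTol = 1e-8, engineR = 10000, engineSeed = 1,
                      seed = 1) {
  stopifnot(is(start, "SplitMigParams"), kRuns >= 1, perturbFold >= 0,
            maxEvals >= 10, engineR >= 100)
  structure(list(start = start, perturbFold = perturbFold,
                 kRuns = as.integer(kRuns), maxEvals = as.integer(maxEvals),
                 funcTol = funcTol, engineR = as.integer(engineR),
                 engineSeed = engineSeed, seed = seed),
            class = "fitConfig")
}

sfsSampleSizes <- function(sfs) {
  c(n1 = sfs@n1, n2 = sfs@n2)
}

#' Single optimization run
#'
#' Maximizes the profiled Poisson composite likelihood over
#' \eqn{(\nu_1, \nu_2, T, m)} by Nelder-Mead in log10 space, with
#' \eqn{\theta} profiled out analytically at every evaluation
#' (\code{\link{optimalTheta}}).  The start is
#' \code{perturbParams(config$start, config$perturbFold)}; box bounds are
#' enforced by clipping inside the objective, and estimates ending within
#' 1\% (log10 scale) of a bound are flagged in \code{hitBounds}.
#'
#' @param data observed \linkS4class{JointSFS} (counts; folded or not —
#'   the model expectation is folded to match).
#' @param config a \code{\link{fitConfig}}.
#' @return a \linkS4class{FitResult}; if every evaluation is degenerate
#'   the result carries \code{converged = FALSE} and \code{logLik = -Inf}
#'   rather than raising an error.
#' @export
fitOnce <- function(data, config) {
  stopifnot(is(data, "JointSFS"), inherits(config, "fitConfig"))
  if (sfsTotal(data) <= 0) stop("data spectrum is empty")
  n <- sfsSampleSizes(data)
  b <- config$start@bounds
  lo <- log10(b[1, ]); hi <- log10(b[2, ])
  start <- perturbParams(config$start, config$perturbFold,
                         seed = childSeed(config$seed, 101))
  # keep the start strictly inside the box: the simplex needs room to
  # move in every coordinate (its initial steps are one-sided)
  inset <- 0.02 * (hi - lo)
  logStart <- pmin(pmax(log10(paramVector(start)), lo + inset), hi - inset)
  nEvals <- 0L
  anyFinite <- FALSE
  cache <- new.env(parent = emptyenv())
  objective <- function(logp) {
    logp <- pmin(pmax(logp, lo), hi)
    key <- paste(format(logp, digits = 12), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]]$nll)
    nEvals <<- nEvals + 1L
    p <- updateParams(config$start, setNames(10^logp, names(lo)))
    M <- expectedSFS(p, n[["n1"]], n[["n2"]], R = config$engineR,
                     seed = config$engineSeed, folded = isFolded(data))
    th <- optimalTheta(data, M)
    ll <- poissonLogLik(data, M, th)
    if (is.finite(ll)) anyFinite <<- TRUE
    res <- list(nll = if (is.finite(ll)) -ll else 1e12,
                theta = th, loglik = ll)
    cache[[key]] <- res
    res$nll
  }
  opt <- optim(logStart, objective, method = "Nelder-Mead",
               control = list(maxit = config$maxEvals,
                              reltol = config$funcTol))
  logp <- pmin(pmax(opt$par, lo), hi)
  best <- cache[[paste(format(logp, digits = 12), collapse = ",")]]
  if (is.null(best)) { objective(logp); best <- cache[[paste(
    format(logp, digits = 12), collapse = ",")]] }
  pHat <- updateParams(config$start, setNames(10^logp, names(lo)))
  hit <- (logp - lo <= 0.01) | (hi - logp <= 0.01)
  new("FitResult",
      params = pHat,
      thetaHat = best$theta,
      logLik = best$loglik,
      converged = anyFinite && opt$convergence == 0L,
      nEvals = nEvals,
      hitBounds = setNames(as.logical(hit), names(lo)),
      seed = as.numeric(config$seed),
      runs = data.frame())
}

#' Best-of-k optimization
#'
#' Runs \code{\link{fitOnce}} \code{config$kRuns} times with independent
#' perturbation seeds derived from \code{config$seed} and returns the run
#' with the highest log composite likelihood; all runs are summarized in
#' the result's \code{runs} slot.
#'
#' @inheritParams fitOnce
#' @return the best \linkS4class{FitResult}.
#' @export
fitBestOf <- function(data, config) {
  fits <- vector("list", config$kRuns)
  for (r in seq_len(config$kRuns)) {
    cfg <- config
    cfg$seed <- childSeed(config$seed, r)
    fits[[r]] <- fitOnce(data, cfg)
  }
  lls <- vapply(fits, function(f) f@logLik, numeric(1))
  runs <- do.call(rbind, lapply(seq_along(fits), function(r) {
    f <- fits[[r]]
    v <- paramVector(f@params)
    data.frame(run = r, seed = f@seed, nu1 = v[["nu1"]], nu2 = v[["nu2"]],
               T = v[["T"]], m = v[["m"]], theta = f@thetaHat,
               loglik = f@logLik, converged = f@converged,
               n_evals = f@nEvals)
  }))
  if (all(!is.finite(lls))) {
    best <- fits[[1]]
    best@runs <- runs
    best@converged <- FALSE
    return(best)
  }
  best <- fits[[which.max(lls)]]
  best@runs <- runs
  best
}

#' Fit the split-migration model to a dataset
#'
#' Convenience wrapper: builds the (folded by default) joint SFS and runs
#' \code{\link{fitBestOf}}.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param start starting \linkS4class{SplitMigParams}.
#' @param polarized use the unfolded spectrum?
#' @param ... passed to \code{\link{fitConfig}}.
#' @return a \linkS4class{FitResult}.
#' @export
fitDataset <- function(dataset, start, polarized = FALSE, ...) {
  sfs <- buildJointSFS(dataset, polarized = polarized)
  fitBestOf(sfs, fitConfig(start = start, ...))
}
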