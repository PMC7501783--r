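#' Default optimization bounds for split-migration parameters
#'
#' Wide box constraints in natural units: \eqn{\nu \in [10^{-2}, 30]},
#' \eqn{T \in [10^{-3}, 10]}, \eqn{m \in [10^{-5}, 10]}.  Chosen so that
#' empirically plausible values (relative sizes up to ~20, divergence
#' times up to ~8 in 2N units) are well interior; estimates near a bound
#' are flagged by the fitter rather than silently truncated.
#'
#' @return 2 x 4 numeric matrix with rows \code{lower}, \code{upper}.
#' @export
defaultBounds <- function() {
  matrix(c(1e-2, 30, 1e-2, 30, 1e-3, 10, 1e-5, 10), nrow = 2,
         dimnames = list(c("lower", "upper"), c("nu1", "nu2", "T", "m")))
}

#' Construct split-migration parameters
#'
#' @param nu1,nu2 population sizes relative to the ancestral reference.
#' @param T time since divergence in units of 2 N_ref generations.
#' @param m symmetric scaled migration rate (each lineage migrates at rate
#'   m/2 per unit coalescent time).
#' @param bounds 2 x 4 matrix of box constraints, see
#'   \code{\link{defaultBounds}}.
#' @return a \linkS4class{SplitMigParams} object.
#' @examples
#' splitMigParams(2, 4, 0.5, 0.5)
#' @export
splitMigParams <- function(nu1, nu2, T, m, bounds = defaultBounds()) {
  new("SplitMigParams", nu1 = as.numeric(nu1), nu2 = as.numeric(nu2),
      T = as.numeric(T), m = as.numeric(m), bounds = bounds)
}

#' @describeIn splitMigParams parameters as a named numeric vector
#'   \code{c(nu1, nu2, T, m)}.
#' @param object,params a \code{SplitMigParams} object.
#' @export
paramVector <- function(object) {
  c(nu1 = object@nu1, nu2 = object@nu2, T = object@T, m = object@m)
}

#' @describeIn splitMigParams the bounds matrix.
#' @export
paramBounds <- function(object) object@bounds

#' @describeIn splitMigParams rebuild from a named vector, keeping bounds.
#' @param x named numeric vector with elements \code{nu1, nu2, T, m}.
#' @export
updateParams <- function(params, x) {
  splitMigParams(x[["nu1"]], x[["nu2"]], x[["T"]], x[["m"]],
                 bounds = params@bounds)
}

#' Multiplicatively perturb parameters
#'
#' Each parameter is multiplied by \code{2^u} with \code{u} drawn
#' independently from Uniform(-fold, fold), then clipped into the bounds.
#' With \code{fold = 1} every start lies within a factor of two of the
#' input, the conventional jitter for multi-start composite-likelihood
#' optimization.
#'
#' @param params a \linkS4class{SplitMigParams} object.
#' @param fold non-negative half-width of the log2 perturbation.
#' @param seed integer seed (uses R's RNG locally, leaving the global
#'   \code{.Random.seed} untouched when supplied).
#' @return a perturbed \code{SplitMigParams}.
#' @export
perturbParams <- function(params, fold = 1, seed = NULL) {
  stopifnot(fold >= 0)
  v <- paramVector(params)
  u <- withSeed(seed, runif(4, -fold, fold))
  v <- v * 2^u
  b <- params@bounds
  v <- pmin(pmax(v, b[1, ]), b[2, ])
  updateParams(params, v)
}

# evaluate `expr` under a locally-seeded RNG; NULL seed = use current stream
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic child-seed derivation (31-bit, stays a valid R integer)
childSeed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed) %% 2147483647
  for (i in idx) x <- (x * 48271 + as.double(i) * 65537 + 12345) %% 2147483647
  as.integer(x)
}
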