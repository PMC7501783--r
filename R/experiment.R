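#' Run the symmetric subsampling experiment
#'
#' For every size k in \code{sizes}, draws \code{reps} independent k:k
#' subsamples of diploid individuals, builds each subsample's (folded)
#' joint SFS, and fits the split-migration model best-of-\code{runs} with
#' the full-dataset estimates as optimizer start (each run perturbed by
#' \code{perturbFold} in log2 units).  All seeds are derived
#' deterministically from \code{seed}, so a rerun with the same root seed
#' reproduces the experiment exactly.  Replicates whose subsample retains
#' no variable loci are marked failed and excluded from summaries.
#'
#' @param dataset the full \linkS4class{GenotypeDataset}.
#' @param fullFit converged \linkS4class{FitResult} on the full dataset.
#' @param sizes diploid individuals per population to subsample to;
#'   default 1 .. (full size - 1).
#' @param reps replicate subsampled datasets per size (study protocol:
#'   25).
#' @param runs optimization runs per replicate, best kept (study
#'   protocol: 5).
#' @param seed root seed.
#' @param engineR genealogy replicates per likelihood evaluation.
#' @param perturbFold per-run start perturbation (log2 half-width).
#' @param polarized fit unfolded spectra?
#' @param maxEvals per-run evaluation cap.
#' @return list of class \code{"experimentResult"} with elements
#'   \code{replicates} (one row per size x replicate), \code{summary}
#'   (per-size mean and SEM per parameter, from
#'   \code{\link{summarizeExperiment}}), \code{full} (full-fit estimates)
#'   and \code{design}.
#' @export
runExperiment <- function(dataset, fullFit, sizes = NULL, reps = 25,
                          runs = 5, seed = 1, engineR = 10000,
                          perturbFold = 1, polarized = FALSE,
                          maxEvals = 400) {
  stopifnot(is(dataset, "GenotypeDataset"), is(fullFit, "FitResult"),
            reps >= 2)
  if (!fullFit@converged)
    stop("full-dataset fit did not converge; refit before subsampling")
  nFull <- min(popSizes(dataset))
  if (is.null(sizes)) sizes <- seq_len(nFull - 1L)
  stopifnot(all(sizes >= 1), all(sizes <= nFull - 1L))
  engineSeed <- childSeed(seed, 999983)
  rows <- list()
  for (k in sizes) {
    for (r in seq_len(reps)) {
      subSeed <- childSeed(seed, k, r, 1)
      fitSeed <- childSeed(seed, k, r, 2)
      row <- data.frame(size = k, rep = r, nu1 = NA_real_, nu2 = NA_real_,
                        T = NA_real_, m = NA_real_, theta = NA_real_,
                        loglik = NA_real_, converged = FALSE,
                        n_loci = NA_integer_, n_dropped = NA_integer_,
                        ids = NA_character_, failed = TRUE)
      sub <- tryCatch(subsampleIndividuals(dataset, k, seed = subSeed),
                      error = function(e) NULL)
      if (!is.null(sub)) {
        sfs <- buildJointSFS(sub, polarized = polarized)
        cfg <- fitConfig(start = fullFit@params, perturbFold = perturbFold,
                         kRuns = runs, maxEvals = maxEvals,
                         engineR = engineR, engineSeed = engineSeed,
                         seed = fitSeed)
        fit <- fitBestOf(sfs, cfg)
        v <- paramVector(fit@params)
        row$nu1 <- v[["nu1"]]; row$nu2 <- v[["nu2"]]
        row$T <- v[["T"]]; row$m <- v[["m"]]
        row$theta <- fit@thetaHat
        row$loglik <- fit@logLik
        row$converged <- fit@converged
        row$n_loci <- nLoci(sub)
        row$n_dropped <- sub@provenance$n_monomorphic_dropped
        row$ids <- paste(sampleIds(sub), collapse = ",")
        row$failed <- !is.finite(fit@logLik)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  replicates <- do.call(rbind, rows)
  res <- structure(list(replicates = replicates,
                        full = c(paramVector(fullFit@params),
                                 theta = fullFit@thetaHat),
                        design = list(sizes = sizes, reps = reps,
                                      runs = runs, seed = seed,
                                      engineR = engineR,
                                      perturbFold = perturbFold,
                                      n_full = nFull,
                                      n_failed = sum(replicates$failed))),
                   class = "experimentResult")
  res$summary <- summarizeExperiment(res)
  res
}

#' Per-size parameter summaries
#'
#' Mean and standard error of the mean (sample SD / sqrt(n)) of each
#' parameter estimate across the successful replicates at each size.
#' Sizes with fewer than two successful replicates are omitted with a
#' warning.
#'
#' @param result an \code{"experimentResult"} from
#'   \code{\link{runExperiment}}.
#' @return data.frame with columns \code{size}, \code{parameter},
#'   \code{mean}, \code{sem}, \code{n}.
#' @export
summarizeExperiment <- function(result) {
  reps <- result$replicates[!result$replicates$failed, , drop = FALSE]
  pars <- c("nu1", "nu2", "T", "m", "theta")
  out <- list()
  for (k in sort(unique(result$replicates$size))) {
    sub <- reps[reps$size == k, , drop = FALSE]
    if (nrow(sub) < 2L) {
      warning("size ", k, " has fewer than 2 successful replicates; omitted")
      next
    }
    for (p in pars) {
      x <- sub[[p]]
      out[[length(out) + 1L]] <- data.frame(
        size = k, parameter = p, mean = mean(x),
        sem = sd(x) / sqrt(length(x)), n = length(x))
    }
  }
  do.call(rbind, out)
}

#' @export
print.experimentResult <- function(x, ...) {
  cat(sprintf(
    "Subsampling experiment: sizes {%s}, %d reps x best-of-%d runs, seed %s\n",
    paste(x$design$sizes, collapse = ","), x$design$reps, x$design$runs,
    format(x$design$seed)))
  cat(sprintf("  %d/%d replicates failed\n", x$design$n_failed,
              nrow(x$replicates)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
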