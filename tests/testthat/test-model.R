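test_that("expected SFS is deterministic and symmetric under population swap", {
  p <- recoveryTruth()
  M1 <- expectedSFS(p, 3, 3, R = 2000, seed = 5, folded = FALSE)
  M2 <- expectedSFS(p, 3, 3, R = 2000, seed = 5, folded = FALSE)
  expect_identical(sfsValues(M1), sfsValues(M2))
  swapped <- splitMigParams(4, 2, 0.5, 0.5)
  M3 <- expectedSFS(swapped, 3, 3, R = 60000, seed = 5, folded = FALSE,
                    regularize = FALSE)
  M4 <- expectedSFS(p, 3, 3, R = 60000, seed = 6, folded = FALSE,
                    regularize = FALSE)
  # cellwise MC agreement between t(M(nu2, nu1)) and M(nu1, nu2)
  a <- t(sfsValues(M3))
  b <- sfsValues(M4)
  un <- !sfsMask(M4)
  expect_lt(max(abs(a[un] - b[un]) / (b[un] + 0.01)), 0.15)
})

test_that("neutral-limit marginal matches E[xi_i] = theta / i", {
  M <- expectedSFS(panmicticParams(), 2, 2, R = 40000, seed = 3,
                   folded = FALSE, regularize = FALSE)
  v <- sfsValues(M)
  itot <- outer(0:4, 0:4, "+")
  marg <- vapply(1:7, function(i) sum(v[itot == i]), numeric(1))
  expect_lt(max(abs(marg * (1:7) - 1)), 0.05)
})

test_that("isolation concentrates polymorphism within populations", {
  # m ~ 0 and deep split: almost all expected mass in private cells
  p <- splitMigParams(1, 1, 30, 1e-12, bounds = wideBounds())
  M <- expectedSFS(p, 3, 3, R = 5000, seed = 11, folded = FALSE,
                   regularize = FALSE)
  v <- sfsValues(M)
  private <- outer(0:6, 0:6, function(i, j) i == 0 | j == 0 |
                                            (i == 6 & j == 6))
  expect_gt(sum(v[private]) / sum(v), 0.999)
  # private-polymorphism marginal matches a single-population engine run
  single <- expectedSFS(panmicticParams(), 3, 3, R = 60000, seed = 12,
                        folded = FALSE, regularize = FALSE)
  vs <- sfsValues(single)
  onePop <- vapply(1:5, function(i) sum(vs[outer(0:6, 0:6, "+") == i]),
                   numeric(1))
  # deme of relative size 1 sampled with 6 haplotypes: interior classes
  inPop1 <- v[2:6, 1] + v[2:6, 7]
  expect_lt(max(abs(inPop1 - onePop) / onePop), 0.1)
})

test_that("regularization floors zero cells and is recorded", {
  M <- expectedSFS(recoveryTruth(), 2, 2, R = 150, seed = 1, folded = TRUE)
  eng <- attr(M, "engine")
  expect_true(eng$eps > 0)
  un <- !sfsMask(M)
  expect_true(all(sfsValues(M)[un] > 0))
})

test_that("Poisson composite log-likelihood matches closed forms", {
  M <- expectedSFS(recoveryTruth(), 2, 2, R = 2000, seed = 8, folded = TRUE)
  un <- !sfsMask(M)
  zero <- jointSFS(matrix(0, 5, 5), 2, 2, folded = TRUE, mask = sfsMask(M))
  expect_equal(poissonLogLik(zero, M, 1), -sum(sfsValues(M)[un]))
  # integer S = theta*M: compare against the dpois mass function
  v <- matrix(0, 5, 5)
  v[un] <- round(100 * sfsValues(M)[un]) + 1
  S <- jointSFS(v, 2, 2, folded = TRUE, mask = sfsMask(M))
  th <- 100
  ref <- sum(dpois(sfsValues(S)[un], th * sfsValues(M)[un], log = TRUE))
  expect_equal(poissonLogLik(S, M, th), ref, tolerance = 1e-12)
  # scale invariance: (c*M, theta/c) leaves the likelihood unchanged
  M2 <- M
  M2@values <- M@values * 7
  expect_equal(poissonLogLik(S, M2, th / 7), poissonLogLik(S, M, th),
               tolerance = 1e-10)
  # theta = 0 with observed counts is -Inf
  expect_identical(poissonLogLik(S, M, 0), -Inf)
  # shape / fold mismatches are errors
  expect_error(poissonLogLik(S, expectedSFS(recoveryTruth(), 2, 2, R = 500,
                                            seed = 1, folded = FALSE)),
               "folding|shapes")
})

test_that("profiled theta maximizes the likelihood", {
  M <- expectedSFS(recoveryTruth(), 2, 2, R = 2000, seed = 9, folded = TRUE)
  un <- !sfsMask(M)
  # S = 3M exactly
  S3 <- jointSFS(sfsValues(M) * 3, 2, 2, folded = TRUE, mask = sfsMask(M))
  expect_equal(optimalTheta(S3, M), 3, tolerance = 1e-12)
  # all-zero data
  zero <- jointSFS(matrix(0, 5, 5), 2, 2, folded = TRUE, mask = sfsMask(M))
  expect_equal(optimalTheta(zero, M), 0)
  # random spectra: agree with numeric 1-D maximization to 1e-8 relative
  set.seed(31)
  for (rep in 1:20) {
    v <- matrix(0, 5, 5)
    v[un] <- rpois(sum(un), 20 * sfsValues(M)[un])
    S <- jointSFS(v, 2, 2, folded = TRUE, mask = sfsMask(M))
    th <- optimalTheta(S, M)
    num <- optimize(function(x) poissonLogLik(S, M, x),
                    lower = th / 50, upper = th * 50, maximum = TRUE,
                    tol = 1e-10 * th)$maximum
    expect_lt(abs(th - num) / th, 1e-5)  # golden-section accuracy floor
    # profiling optimality over a grid
    grid <- th * c(0.5, 0.9, 0.99, 1.01, 1.1, 2)
    expect_true(all(poissonLogLik(S, M, th) >=
                    vapply(grid, function(x) poissonLogLik(S, M, x),
                           numeric(1))))
  }
})

test_that("Monte Carlo error of the expected spectrum scales as 1/sqrt(R)", {
  p <- recoveryTruth()
  cellSD <- function(R, seeds) {
    vals <- vapply(seeds, function(s)
      sfsValues(expectedSFS(p, 2, 2, R = R, seed = s, folded = FALSE,
                            regularize = FALSE))[2, 2], numeric(1))
    sd(vals)
  }
  s1 <- cellSD(400, 1:24)
  s2 <- cellSD(1600, 101:124)
  expect_gt(s1 / s2, 1.3)  # expect ~2, allow MC slack
})
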