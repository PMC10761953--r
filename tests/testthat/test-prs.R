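test_that("Fibonacci force sets follow the golden-angle formula and are near-isotropic", {
  f1 <- fibonacciForceSet(1)
  expect_equal(unname(f1@directions[1, ]), c(1, 0, 0))
  f2 <- fibonacciForceSet(2)
  expect_equal(sort(f2@directions[, 3]), c(-0.5, 0.5))
  expect_equal(unname(sqrt(rowSums(f2@directions^2))), c(1, 1))

  f100 <- fibonacciForceSet(100)
  expect_lte(sqrt(sum(colMeans(f100@directions)^2)), 0.05)
  ## minimum pairwise angle above 10 degrees
  G <- f100@directions %*% t(f100@directions)
  diag(G) <- -1
  expect_gt(acos(max(G)) * 180 / pi, 10)
  expect_error(fibonacciForceSet(0), ">= 1")
})

test_that("linear response is C.F/kT with the force injected at one residue", {
  ## identity kernel: displacement appears only at the perturbed residue
  Cid <- new("CovarianceModel", matrix = diag(9), kT = 1, source = "ensemble",
             nZeroModesRemoved = 0L)
  dr <- lrtResponse(Cid, 2, c(1, 0, 0))
  expect_equal(dr, rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0)))
  expect_equal(lrtResponse(Cid, 2, c(0, 0, 0)), matrix(0, 3, 3))
  expect_error(lrtResponse(Cid, 4, c(1, 0, 0)), "out of range")

  ## random 3-residue covariance vs dense matrix-vector product
  withr::with_seed(3, {
    A <- matrix(rnorm(81), 9)
    C <- crossprod(A)
    cv <- new("CovarianceModel", matrix = C, kT = 2, source = "ensemble",
              nZeroModesRemoved = 0L)
    force <- rnorm(3)
    Fv <- rep(0, 9); Fv[4:6] <- force
    expect_equal(as.vector(t(lrtResponse(cv, 2, force))),
                 as.vector(C %*% Fv) / 2, tolerance = 1e-12)
  })
})

test_that("PRS response matches the closed-form trace on a 2-residue toy covariance", {
  withr::with_seed(5, {
    A <- matrix(rnorm(36), 6)
    C <- crossprod(A)
  })
  cv <- new("CovarianceModel", matrix = C, kT = 1, source = "ensemble",
            nZeroModesRemoved = 0L)
  res <- prsScan(cv, analyticForceSet())
  ## hand-computed spherical average: <|C_block(j,i) u|^2> = tr(B^T B)/3
  for (i in 1:2) for (j in 1:2) {
    B <- C[(3*j-2):(3*j), (3*i-2):(3*i)]
    expect_equal(responseMatrix(res)[i, j], sum(B^2) / 3, tolerance = 1e-12)
  }
})

test_that("identity covariance gives an identity normalized response", {
  cv <- new("CovarianceModel", matrix = diag(12), kT = 1, source = "ensemble",
            nZeroModesRemoved = 0L)
  res <- prsScan(cv, fibonacciForceSet(50))
  expect_equal(normalizedResponse(res), diag(4))
})

test_that("Fibonacci sampling converges to the analytic isotropic limit", {
  cov <- anmCovariance(buildANMHessian(makeHelix(20), 13))
  exact <- responseMatrix(prsScan(cov, analyticForceSet()))
  r100 <- responseMatrix(prsScan(cov, fibonacciForceSet(100)))
  r1000 <- responseMatrix(prsScan(cov, fibonacciForceSet(1000)))
  expect_lte(max(abs(r100 - exact) / exact), 0.02)
  expect_lt(norm(r1000 - exact, "F"), norm(r100 - exact, "F"))
})

test_that("normalized PRS has exact unit diagonal, non-negative entries, and scale invariance", {
  cov <- anmCovariance(buildANMHessian(makeHelix(15), 13))
  res <- prsScan(cov, fibonacciForceSet(100))
  Z <- normalizedResponse(res)
  expect_identical(unname(diag(Z)), rep(1, 15))
  expect_true(all(responseMatrix(res) >= 0))
  expect_true(all(effectorProfile(res) >= 0, sensorProfile(res) >= 0))

  ## overall covariance scale cancels in the normalized matrix
  sc <- new("CovarianceModel", matrix = 7.3 * covMatrix(cov), kT = 1,
            source = "anm", nZeroModesRemoved = 6L)
  expect_equal(normalizedResponse(prsScan(sc, analyticForceSet())),
               normalizedResponse(prsScan(cov, analyticForceSet())),
               tolerance = 1e-12)
})

test_that("PRS is invariant under rigid rotation of the input structure", {
  h <- makeHelix(12)
  th <- 0.83
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  rot <- coords(h) %*% t(Rz) + matrix(rep(c(3, -1, 2), each = 12), 12)
  z1 <- normalizedResponse(prsScan(anmCovariance(buildANMHessian(coords(h), 13)),
                                   analyticForceSet()))
  z2 <- normalizedResponse(prsScan(anmCovariance(buildANMHessian(rot, 13)),
                                   analyticForceSet()))
  expect_lt(max(abs(z1 - z2)), 1e-8)
})

test_that("key residues are z-score outliers of the effector profile, ties deterministic", {
  mk <- function(profile) {
    n <- length(profile)
    Z <- matrix(profile, n, n)  # row i constant = profile[i]
    diag(Z) <- 1
    new("PRSResult", response = abs(Z), normalized = Z,
        effectorProfile = profile, sensorProfile = rep(1, n),
        nForces = 1L, scheme = "analytic")
  }
  one_big <- mk(c(rep(1, 9), 10))
  kr <- keyResidues(one_big, 1.0)
  expect_equal(kr$residue[1], 10L)

  expect_warning(kr0 <- keyResidues(mk(rep(2, 8))), "constant")
  expect_equal(nrow(kr0), 0)

  ## equal scores rank by ascending residue index
  tied <- mk(c(rep(1, 8), 5, 5))
  kr2 <- keyResidues(tied, 1.0)
  expect_equal(kr2$residue, c(9L, 10L))
})

test_that("planted channel is enriched among mediation counts against a permutation null", {
  db <- makeDumbbell(12, 3, seed = 4)
  n <- nAtoms(db$model)
  res <- prsScan(anmCovariance(buildANMHessian(db$model, 18)),
                 analyticForceSet())
  g <- assignEdgeWeights(buildContactGraph(db$model, 10), res)
  med <- mediationProfile(allPairsPaths(g, 1:12, (n - 11):n), n)
  counts <- mediationCounts(med)
  obs <- sum(counts[db$channel])
  null <- withr::with_seed(99, replicate(1000, {
    sum(counts[sample(n, length(db$channel))])
  }))
  p <- (sum(null >= obs) + 1) / 1001
  expect_lt(p, 0.05)
})
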