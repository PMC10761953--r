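test_that("Kabsch recovers rigid transforms exactly and matches the quaternion oracle", {
  withr::with_seed(2, {
    X <- matrix(rnorm(30), 10)
  })
  fit <- kabschSuperpose(X, X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)

  th <- 37 * pi / 180
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  Y <- X %*% t(Rz) + matrix(rep(c(5, -2, 1), each = 10), 10)
  expect_lt(kabschSuperpose(X, Y)$rmsd, 1e-9)

  ## independent quaternion-method oracle on random clouds
  withr::with_seed(9, {
    for (trial in 1:10) {
      A <- matrix(rnorm(18), 6)
      B <- matrix(rnorm(18), 6)
      expect_equal(kabschSuperpose(A, B)$rmsd, quaternion_rmsd(A, B),
                   tolerance = 1e-8)
    }
  })
  expect_error(kabschSuperpose(X[1:2, ], X[1:2, ]), "at least 3")
})

test_that("RMSD is symmetric and invariant under a common rigid transform", {
  withr::with_seed(4, {
    A <- matrix(rnorm(24), 8); B <- matrix(rnorm(24), 8)
  })
  expect_equal(kabschSuperpose(A, B)$rmsd, kabschSuperpose(B, A)$rmsd,
               tolerance = 1e-9)
  th <- 1.1
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  expect_equal(kabschSuperpose(A %*% t(Rz) + 2, B %*% t(Rz) + 2)$rmsd,
               kabschSuperpose(A, B)$rmsd, tolerance = 1e-9)
})

test_that("RMSD series is zero for identical or rigidly moved frames", {
  h <- makeHelix(10)
  th <- 0.6
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  ens <- CoordinateEnsemble(h, list(coords(h), coords(h),
                                    coords(h) %*% t(Rz) + 4))
  s <- rmsdSeries(ens)
  expect_lt(max(metricValues(s)), 1e-9)
  expect_error(rmsdSeries(ens, referenceFrame = 9), "out of range")
})

test_that("RMSF recovers planted fluctuation scales", {
  ## iid Gaussian jitter: RMSF -> sigma * sqrt(3)
  h <- makeHelix(40)
  sigma <- 0.5
  fr <- withr::with_seed(6, lapply(1:2000, function(f)
    coords(h) + matrix(rnorm(120, sd = sigma), 40)))
  r <- rmsfProfile(CoordinateEnsemble(h, fr))
  expect_equal(mean(r), sigma * sqrt(3), tolerance = 0.1)

  ## two frames, one displaced atom: that atom's RMSF is d/2
  base <- coords(makeHelix(30))
  moved <- base; moved[1, ] <- moved[1, ] + c(0, 0, 1.0)
  r2 <- rmsfProfile(CoordinateEnsemble(makeHelix(30), list(base, moved)))
  expect_equal(r2[1], 0.5, tolerance = 0.05)
  expect_lt(max(r2[-1]), 0.1)

  expect_error(rmsfProfile(CoordinateEnsemble(h, fr[1])), "at least 2")
  ## static ensemble: all zeros
  r0 <- rmsfProfile(CoordinateEnsemble(h, list(coords(h), coords(h))))
  expect_lt(max(r0), 1e-12)
})

test_that("radius of gyration has its closed forms and invariances", {
  expect_equal(radiusOfGyration(matrix(c(1, 2, 3), 1)), 0)
  expect_equal(radiusOfGyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1.0)
  s <- 3.2
  square <- rbind(c(0, 0, 0), c(s, 0, 0), c(s, s, 0), c(0, s, 0))
  expect_equal(radiusOfGyration(square), s / sqrt(2), tolerance = 1e-12)
  ## rigid motion invariance; linear scaling
  withr::with_seed(10, {
    X <- matrix(rnorm(30), 10)
  })
  th <- 0.9
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  expect_equal(radiusOfGyration(X %*% t(Rz) + 5), radiusOfGyration(X),
               tolerance = 1e-12)
  expect_equal(radiusOfGyration(2.5 * X), 2.5 * radiusOfGyration(X),
               tolerance = 1e-12)
  expect_error(radiusOfGyration(X, masses = rep(-1, 10)), "positive")
})

test_that("SASA matches analytic sphere formulas", {
  lone <- StructureModel(
    data.frame(serial = 1L, name = "C1", element = "C", resname = "LIG",
               resid = 1L, chain = "A", stringsAsFactors = FALSE),
    matrix(0, 1, 3))
  got <- sasa(lone, probeRadius = 1.4, nSpherePoints = 960)
  expect_equal(got$total, 4 * pi * 3.1^2, tolerance = 0.01)

  two_far <- StructureModel(
    data.frame(serial = 1:2, name = c("C1", "C2"), element = "C",
               resname = "LIG", resid = c(1L, 2L), chain = "A",
               stringsAsFactors = FALSE),
    rbind(c(0, 0, 0), c(20, 0, 0)))
  expect_equal(sasa(two_far)$total, 2 * got$total, tolerance = 1e-9)

  ## overlapping equal spheres vs the spherical-cap closed form
  two_close <- StructureModel(
    data.frame(serial = 1:2, name = c("C1", "C2"), element = "C",
               resname = "LIG", resid = c(1L, 2L), chain = "A",
               stringsAsFactors = FALSE),
    rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(sasa(two_close, 1.4, 960)$total, two_sphere_area(3.1, 2),
               tolerance = 0.01)

  ## unknown element errors
  odd <- StructureModel(
    data.frame(serial = 1L, name = "XX", element = "Zz", resname = "LIG",
               resid = 1L, chain = "A", stringsAsFactors = FALSE),
    matrix(0, 1, 3))
  expect_error(sasa(odd), "unknown element")
})

test_that("SASA decreases as a neighbor approaches and converges in sphere points", {
  mk2 <- function(d) StructureModel(
    data.frame(serial = 1:2, name = c("C1", "C2"), element = "C",
               resname = "LIG", resid = c(1L, 2L), chain = "A",
               stringsAsFactors = FALSE),
    rbind(c(0, 0, 0), c(d, 0, 0)))
  areas <- vapply(c(7, 5, 4, 3, 2), function(d) sasa(mk2(d))$perAtom[1],
                  numeric(1))
  expect_true(all(diff(areas) < 0))
  a960 <- sasa(mk2(2.5), 1.4, 960)$total
  a1920 <- sasa(mk2(2.5), 1.4, 1920)$total
  expect_lt(abs(a1920 - a960) / a960, 0.005)
})

test_that("hydrogen bonds follow the geometric distance and angle criteria", {
  ## linear O-H...O at 2.8 A -> one bond; bent to 90 deg -> none;
  ## exactly at the 3.0 A cutoff -> counted (inclusive)
  ens <- hbond_toy_ensemble(list(c(2.8, 0, 0),
                                 c(1.0, 1.8, 0),
                                 c(3.0, 0, 0),
                                 c(3.0001, 0, 0)))
  s <- hbondSeries(ens, donors = 1, acceptors = 3)
  expect_equal(metricValues(s), c(1, 0, 1, 0))
  expect_error(hbondSeries(ens, donors = integer(0), acceptors = 3),
               "empty selection")
})

test_that("histograms are equal-width, normalized, and boundary-inclusive", {
  mk <- function(v) new("MetricSeries", name = "rg", values = v,
                        histogram = list())
  hconst <- metricHistogram(mk(rep(4.2, 25)), 10)@histogram
  expect_equal(sum(hconst$freq), 1, tolerance = 1e-12)
  expect_equal(sum(hconst$freq > 0), 1)

  grid <- metricHistogram(mk((0:99 + 0.5) / 100), 10)@histogram
  expect_equal(grid$freq, rep(0.1, 10), tolerance = 1e-12)

  withr::with_seed(13, {
    h <- metricHistogram(mk(rnorm(500)), 50)@histogram
  })
  expect_equal(sum(h$freq), 1, tolerance = 1e-9)
  expect_equal(sum(h$freq * 500), 500)  # counts conserve series length
  expect_error(metricHistogram(mk(numeric(0))), "empty")
})

test_that("k-means clustering recovers planted conformers and is reproducible", {
  hA <- coords(makeHelix(15))
  hB <- hA; hB[, 3] <- hB[, 3] + 8  # stretched far apart in z per-atom
  hB[1:7, 1] <- hB[1:7, 1] + 6      # genuinely different shape
  frames <- withr::with_seed(17, c(
    lapply(1:100, function(i) hA + matrix(rnorm(45, sd = 0.1), 15)),
    lapply(1:100, function(i) hB + matrix(rnorm(45, sd = 0.1), 15))))
  ens <- CoordinateEnsemble(makeHelix(15), frames)
  cl <- clusterFrames(ens, k = 2, seed = 5)
  lab <- cl@labels
  expect_equal(length(unique(lab[1:100])), 1)
  expect_equal(length(unique(lab[101:200])), 1)
  expect_true(lab[1] != lab[101])

  ## fixed seed reproduces bit-identically
  cl2 <- clusterFrames(ens, k = 2, seed = 5)
  expect_identical(cl@labels, cl2@labels)
  expect_identical(cl@representatives, cl2@representatives)

  ## k = nFrames: every frame its own cluster
  small <- CoordinateEnsemble(makeHelix(15), frames[1:4])
  clk <- clusterFrames(small, k = 4, seed = 1)
  expect_equal(sort(clk@labels), 1:4)
  expect_equal(clk@representatives, 1:4)

  ## k = 1: representative is the frame closest to the mean
  cl1 <- clusterFrames(small, k = 1, seed = 1)
  expect_equal(cl1@k, 1L)
  expect_length(cl1@representatives, 1)
  expect_error(clusterFrames(small, k = 9), "exceeds")
})
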