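test_that("contact graph contains exactly the pairs within cutoff", {
  three <- rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0))
  g <- buildContactGraph(three, 6)
  expect_equal(edges(g)[, c("i", "j")],
               data.frame(i = c(1L, 2L), j = c(2L, 3L)))
  expect_equal(nrow(edges(buildContactGraph(three, 4))), 0)

  ## brute-force O(N^2) oracle on the helix
  h <- makeHelix(20)
  g2 <- buildContactGraph(h, 10)
  pos <- coords(h)
  expected <- NULL
  for (i in 1:19) for (j in (i + 1):20)
    if (sqrt(sum((pos[i, ] - pos[j, ])^2)) <= 10)
      expected <- rbind(expected, c(i, j))
  got <- as.matrix(edges(g2)[, c("i", "j")])
  got <- got[order(got[, 1], got[, 2]), ]
  dimnames(got) <- NULL
  expected <- expected[order(expected[, 1], expected[, 2]), ]
  expect_equal(got, expected)
})

test_that("edge weights are -ln of clipped symmetrized PRS coupling", {
  g <- new("ResidueGraph", nNodes = 3L,
           edges = data.frame(i = c(1L, 2L), j = c(2L, 3L), weight = c(1, 1)),
           contactCutoff = 10, weighting = "unit")
  Z <- matrix(c(1, 1,    0.5,
                0.25, 1, 1e-9,
                0.1, 1e-8, 1), 3, 3, byrow = TRUE)
  prs <- new("PRSResult", response = abs(Z), normalized = Z,
             effectorProfile = rep(1, 3), sensorProfile = rep(1, 3),
             nForces = 1L, scheme = "analytic")
  gw <- assignEdgeWeights(g, prs, epsilon = 1e-6)
  expect_equal(gw@weighting, "prs")
  ## pair (1,2): max(1, 0.25) = 1 -> weight 0
  expect_equal(edges(gw)$weight[1], 0)
  ## pair (2,3): max(1e-9, 1e-8) clipped to 1e-6 -> -ln(1e-6)
  expect_equal(edges(gw)$weight[2], -log(1e-6), tolerance = 1e-12)
  expect_error(assignEdgeWeights(g, prs, epsilon = 0), "epsilon")
  expect_error(assignEdgeWeights(g, prs, epsilon = 1), "epsilon")

  ## monotone: stronger coupling gives cheaper edges
  withr::with_seed(8, {
    p <- sort(runif(50, 1e-6, 1))
    w <- -log(pmin(pmax(p, 1e-6), 1))
    expect_true(all(diff(w) <= 0))
    expect_true(all(is.finite(w) & w >= 0))
  })
})

test_that("shortest paths match the chain and report disconnection", {
  chain <- new("ResidueGraph", nNodes = 4L,
               edges = data.frame(i = 1:3, j = 2:4, weight = rep(1, 3)),
               contactCutoff = 0, weighting = "unit")
  p <- shortestPath(chain, 1, 4)
  expect_equal(pathNodes(p), 1:4)
  expect_equal(pathWeight(p), 3)

  split <- new("ResidueGraph", nNodes = 4L,
               edges = data.frame(i = 1L, j = 2L, weight = 1),
               contactCutoff = 0, weighting = "unit")
  expect_error(shortestPath(split, 1, 4), "disconnected.*1.*4")
  expect_error(shortestPath(chain, 2, 2), "differ")
})

test_that("Dijkstra with tie-breaking equals exhaustive enumeration on random graphs", {
  withr::with_seed(1234, {
    agree <- 0; trials <- 0
    while (trials < 100) {
      n <- sample(4:8, 1)
      g <- random_graph(n)
      s <- 1L; t <- as.integer(n)
      best <- enumerate_best_path(n, edges(g), s, t)
      if (is.null(best)) {
        expect_error(shortestPath(g, s, t), "disconnected")
        agree <- agree + 1
      } else {
        p <- shortestPath(g, s, t)
        expect_equal(pathWeight(p), best$weight, tolerance = 1e-9)
        expect_equal(pathNodes(p), as.integer(best$nodes))
        agree <- agree + 1
      }
      trials <- trials + 1
    }
    expect_equal(agree, 100)
  })
})

test_that("unit-weight shortest paths minimize hop count (BFS oracle)", {
  withr::with_seed(77, {
    for (trial in 1:20) {
      n <- sample(5:8, 1)
      g <- random_graph(n)
      g@edges$weight <- rep(1, nrow(g@edges))
      ig <- igraph::graph_from_data_frame(g@edges[, 1:2], directed = FALSE,
                                          vertices = data.frame(name = 1:n))
      hops <- igraph::distances(ig, v = "1", to = as.character(n),
                                weights = NA)[1, 1]
      if (is.infinite(hops)) next
      p <- shortestPath(g, 1, n)
      expect_equal(length(pathNodes(p)) - 1, unname(hops))
    }
  })
})

test_that("path weight recomputed from edges matches the stored total", {
  withr::with_seed(21, {
    for (trial in 1:10) {
      g <- random_graph(7)
      best <- enumerate_best_path(7, edges(g), 1, 7)
      if (is.null(best)) next
      p <- shortestPath(g, 1, 7)
      e <- edges(g)
      key <- paste(e$i, e$j)
      w <- 0
      nd <- pathNodes(p)
      for (k in seq_len(length(nd) - 1)) {
        a <- min(nd[k], nd[k + 1]); b <- max(nd[k], nd[k + 1])
        w <- w + e$weight[match(paste(a, b), key)]
      }
      expect_equal(pathWeight(p), w, tolerance = 1e-12)
    }
  })
})

test_that("all-pairs paths come back source-major with unreachable pairs skipped", {
  chain <- new("ResidueGraph", nNodes = 6L,
               edges = data.frame(i = 1:4, j = 2:5, weight = rep(1, 4)),
               contactCutoff = 0, weighting = "unit")
  ps <- allPairsPaths(chain, c(1, 2), c(4, 5))
  expect_equal(names(ps), c("1->4", "1->5", "2->4", "2->5"))
  expect_equal(pathNodes(ps[["1->4"]]), pathNodes(shortestPath(chain, 1, 4)))

  ## node 6 is isolated: pair reported, rest still computed
  expect_warning(ps2 <- allPairsPaths(chain, 1, c(5, 6)), "disconnected")
  expect_equal(names(ps2), "1->5")
  expect_error(allPairsPaths(chain, c(1, 2), c(2, 5)), "disjoint")
})

test_that("mediation counts interior nodes only and conserves totals", {
  p159 <- new("AllostericPath", nodes = c(1L, 5L, 9L), totalWeight = 2)
  med <- mediationProfile(list(p159), 9)
  expect_equal(mediationCounts(med)[5], 1L)
  expect_equal(mediationCounts(med)[c(1, 9)], c(0L, 0L))

  ## star graph: hub mediates every leaf-to-leaf path
  star <- new("ResidueGraph", nNodes = 5L,
              edges = data.frame(i = rep(1L, 4), j = 2:5, weight = rep(1, 4)),
              contactCutoff = 0, weighting = "unit")
  ps <- allPairsPaths(star, c(2, 3), c(4, 5))
  med2 <- mediationProfile(ps, 5)
  expect_equal(mediationCounts(med2)[1], length(ps))
  expect_equal(topMediators(med2), 1L)

  ## conservation: sum(counts) = sum(len - 2)
  withr::with_seed(31, {
    for (trial in 1:5) {
      g <- random_graph(8, p = 0.6)
      ps <- suppressWarnings(allPairsPaths(g, 1:2, 7:8))
      if (length(ps) == 0) next
      med <- mediationProfile(ps, 8)
      expect_equal(sum(mediationCounts(med)),
                   sum(vapply(ps, function(p) length(pathNodes(p)) - 2L,
                              integer(1))))
    }
  })
})

test_that("dumbbell source-to-sink paths are forced through the planted channel", {
  db <- makeDumbbell(10, 3, seed = 42)
  n <- nAtoms(db$model)
  res <- prsScan(anmCovariance(buildANMHessian(db$model, 18)),
                 analyticForceSet())
  g <- assignEdgeWeights(buildContactGraph(db$model, 10), res)
  ps <- allPairsPaths(g, 1:3, (n - 2):n)
  expect_length(ps, 9)
  expect_true(all(vapply(ps, function(p)
    any(pathNodes(p) %in% db$channel), logical(1))))
  ## every path visits every channel bead, so the channel attains the
  ## maximum mediation count (domain funnel residues may tie, not beat)
  med <- mediationProfile(ps, n)
  expect_true(any(topMediators(med) %in% db$channel))
  expect_equal(max(mediationCounts(med)),
               max(mediationCounts(med)[db$channel]))
  expect_equal(unname(mediationCounts(med)[db$channel]),
               rep(length(ps), 3L))
})
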