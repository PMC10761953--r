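#' @include energetics.R
NULL

## CA-only StructureModel from bare coordinates (poly-ALA, chain A)
.ca_model_from_coords <- function(pos, title = "") {
  n <- nrow(pos)
  atoms <- data.frame(
    serial = seq_len(n), name = rep("CA", n), element = rep("C", n),
    resname = rep("ALA", n), resid = seq_len(n), chain = rep("A", n),
    stringsAsFactors = FALSE)
  StructureModel(atoms, pos, title = title)
}

#' Ideal alpha-helix CA trace
#'
#' Canonical helix geometry: 1.5 Angstrom rise per residue, 2.3 Angstrom
#' radius, 100 degrees twist per residue, giving the familiar ~3.8
#' Angstrom consecutive CA-CA distance. Residues are numbered 1..n.
#'
#' @param nResidues number of residues (>= 3).
#' @return a CA-only \linkS4class{StructureModel}
#' @export
makeHelix <- function(nResidues) {
  if (nResidues < 3) stop("need at least 3 residues")
  k <- seq_len(nResidues) - 1
  th <- k * 100 * pi / 180
  pos <- cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * k)
  .ca_model_from_coords(pos, title = sprintf("ideal helix n=%d", nResidues))
}

#' Straight bead-chain CA trace
#'
#' @param nResidues number of residues (>= 3).
#' @param spacing consecutive bead spacing in Angstrom (default 3.8).
#' @return a CA-only \linkS4class{StructureModel}
#' @export
makeChain <- function(nResidues, spacing = 3.8) {
  if (nResidues < 3) stop("need at least 3 residues")
  pos <- cbind((seq_len(nResidues) - 1) * spacing, 0, 0)
  .ca_model_from_coords(pos, title = sprintf("bead chain n=%d", nResidues))
}

## rejection-sample n points in a ball with a minimum separation
.sample_domain <- function(n, min_sep = 3.0, max_tries = 20000L) {
  R <- 2.4 * n^(1/3) + 0.5
  pts <- matrix(NA_real_, n, 3)
  placed <- 0L
  for (t_ in seq_len(max_tries)) {
    p <- stats::runif(3, -R, R)
    if (sum(p^2) > R^2) next
    if (placed > 0) {
      d2 <- rowSums(sweep(pts[seq_len(placed), , drop = FALSE], 2, p)^2)
      if (min(d2) < min_sep^2) next
    }
    placed <- placed + 1L
    pts[placed, ] <- p
    if (placed == n) return(pts)
  }
  NULL
}

.graph_connected_between <- function(pos, cutoff, setA, setB, drop = integer(0)) {
  ## is any node of setA connected to any node of setB once `drop` nodes
  ## are removed?
  keep <- setdiff(seq_len(nrow(pos)), drop)
  sub <- pos[keep, , drop = FALSE]
  pairs <- .contact_pairs(sub, cutoff)
  g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  if (nrow(pairs) > 0) g <- igraph::add_edges(g, rbind(pairs$i, pairs$j))
  comp <- igraph::components(g)$membership
  a <- comp[match(intersect(setA, keep), keep)]
  b <- comp[match(intersect(setB, keep), keep)]
  any(outer(a, b, `==`))
}

#' Two-domain dumbbell with a planted allosteric channel
#'
#' Builds two compact random domains separated beyond the contact cutoff
#' and joins them by a linear channel of beads, so that at the default
#' cutoff the ONLY inter-domain contacts run through the channel. The
#' defining property — removing the channel nodes disconnects the
#' domains — is asserted at generation time; placement failures error
#' after bounded retries rather than silently overlapping.
#'
#' @param nPerDomain residues per domain (>= 5).
#' @param channelResidues channel bead count (>= 1).
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @param cutoff contact cutoff the channel property is guaranteed at
#'   (default 10 Angstrom).
#' @param anmCutoff cutoff at which the fixture additionally guarantees a
#'   mechanically well-posed elastic network (exactly 6 zero modes).
#'   Default 18 Angstrom: the thin bead bottleneck transmits at most
#'   three spring constraints per bead, so the springs must reach across
#'   two bead spacings (~3x the 5.8 Angstrom spacing) to brace the
#'   domains against relative swing and torsion.
#' @return list(model = \linkS4class{StructureModel}, channel = integer
#'   indices of the channel residues)
#' @export
makeDumbbell <- function(nPerDomain, channelResidues = 3L, seed = 1L,
                         cutoff = 10, anmCutoff = 18) {
  if (nPerDomain < 5) stop("nPerDomain must be >= 5")
  if (channelResidues < 1) stop("channelResidues must be >= 1")
  withr::with_seed(seed, {
    for (attempt in seq_len(500L)) {
      A <- .sample_domain(nPerDomain)
      B <- .sample_domain(nPerDomain)
      if (is.null(A) || is.null(B)) next
      c_ <- as.integer(channelResidues)
      ## bead spacing ~0.58 * cutoff makes the channel a strict chain at
      ## the contact cutoff (next-nearest beads 1.16 * cutoff apart, so no
      ## bead can be skipped: every inter-domain path visits every bead)
      ## while still bracing next-nearest neighbours at the larger ANM
      ## cutoff, which keeps the network mechanically well-posed
      spacing <- 0.58 * cutoff
      gap <- spacing * (c_ + 1)
      ia <- which.max(A[, 1]); ib <- which.min(B[, 1])
      ## translate B so its facing extreme atom sits exactly `gap` along
      ## +x from A's; all A-B atom pairs then separate by > gap in x
      B <- sweep(B, 2, A[ia, ] + c(gap, 0, 0) - B[ib, ], `+`)
      v <- c(gap, 0, 0)
      ## helical off-axis offsets: a perfectly collinear channel would
      ## leave perpendicular bead motions and inter-domain torsion
      ## unpenalized by pairwise springs
      u <- c(0, 1, 0); w <- c(0, 0, 1)
      chan <- t(vapply(seq_len(c_), function(k)
        A[ia, ] + v * k / (c_ + 1) +
          1.2 * (u * cos(2.4 * k) + w * sin(2.4 * k)), numeric(3)))
      pos <- rbind(A, chan, B)
      nA <- nPerDomain
      chanIdx <- seq.int(nA + 1L, nA + c_)
      idxA <- seq_len(nA)
      idxB <- seq.int(nA + c_ + 1L, nrow(pos))
      dAll <- as.matrix(stats::dist(pos))
      diag(dAll) <- Inf
      ## channel beads must not collide with anything
      if (min(dAll[chanIdx, ]) < 2.8) next
      ## strict chain at the contact cutoff: consecutive links in
      ## contact, and no shortcuts that skip a bead (non-adjacent channel
      ## pairs, or a domain atom reaching past the first/last bead)
      link <- rbind(A[ia, ], chan, B[ib, ])
      if (any(sqrt(rowSums(diff(link)^2)) > 0.95 * cutoff)) next
      shortcut <- FALSE
      for (k in seq_len(c_)) {
        others <- setdiff(chanIdx, chanIdx[k] + c(-1L, 0L, 1L))
        reach <- c(others,
                   if (k >= 2) idxA else integer(0),
                   if (k <= c_ - 1) idxB else integer(0))
        if (length(reach) && min(dAll[chanIdx[k], reach]) <= cutoff) {
          shortcut <- TRUE; break
        }
      }
      if (shortcut) next
      ## domains internally connected, whole graph connected through the
      ## channel, and disconnected once the channel is removed
      pairsA <- .contact_pairs(A, cutoff)
      pairsB <- .contact_pairs(B, cutoff)
      if (!.is_connected(nA, pairsA) || !.is_connected(nA, pairsB)) next
      if (!.is_connected(nrow(pos), .contact_pairs(pos, cutoff))) next
      if (.graph_connected_between(pos, cutoff, idxA, idxB, drop = chanIdx)) next
      ## the elastic network on the fixture must be mechanically
      ## well-posed: a marginally braced bottleneck can leave floppy
      ## inter-domain mechanisms (> 6 zero modes), which would poison any
      ## covariance built on it
      lam <- eigen(buildANMHessian(pos, cutoff = anmCutoff)@hessian,
                   symmetric = TRUE, only.values = TRUE)$values
      if (sum(abs(lam) < 1e-8 * max(abs(lam))) != 6) next
      model <- .ca_model_from_coords(
        pos, title = sprintf("dumbbell n=%d channel=%d seed=%d",
                             nPerDomain, c_, seed))
      return(list(model = model, channel = chanIdx))
    }
    stop("dumbbell placement failed after 500 attempts")
  })
}

#' Sample a synthetic ensemble from ANM normal modes
#'
#' Draws frames x_f = mean + sum_k sqrt(kT / lambda_k) z_k v_k over the
#' non-zero modes with z_k iid standard normal, so the population
#' covariance of the frames is exactly the ANM pseudo-inverse covariance.
#' The ground-truth generator for covariance-recovery tests.
#'
#' @param network \linkS4class{ElasticNetwork}.
#' @param nFrames frames to draw (>= 2).
#' @param kT thermal-energy scale (default 1).
#' @param seed RNG seed.
#' @return a \linkS4class{CoordinateEnsemble}
#' @export
sampleANMEnsemble <- function(network, nFrames, kT = 1, seed = 1L) {
  if (nFrames < 2) stop("need at least 2 frames")
  eig <- eigen(network@hessian, symmetric = TRUE)
  lam <- eig$values
  nzero <- sum(abs(lam) < 1e-8 * max(abs(lam)))
  if (nzero != 6) stop("degenerate network: expected 6 zero modes, found ", nzero)
  keep <- seq_len(length(lam) - 6)
  V <- eig$vectors[, keep, drop = FALSE]
  amp <- sqrt(kT / lam[keep])
  mean_flat <- as.vector(t(network@positions))
  Z <- withr::with_seed(seed,
    matrix(stats::rnorm(nFrames * length(keep)), nFrames, length(keep)))
  X <- Z %*% (t(V) * amp)      # each row: sum_k amp_k z_k v_k
  frames <- lapply(seq_len(nFrames), function(f)
    matrix(mean_flat + X[f, ], ncol = 3, byrow = TRUE))
  topo <- .ca_model_from_coords(network@positions, title = "ANM-sampled mean")
  CoordinateEnsemble(topo, frames)
}
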