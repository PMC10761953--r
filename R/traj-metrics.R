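#' @include pathways.R
NULL

.kabsch_core <- function(mobile, reference) {
  cx <- colMeans(mobile)
  cy <- colMeans(reference)
  Xc <- sweep(mobile, 2, cx)
  Yc <- sweep(reference, 2, cy)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cy - as.vector(R %*% cx), Xc = Xc, Yc = Yc, cy = cy)
}

## superpose frame onto reference, returning transformed coordinates
.kabsch_apply <- function(mobile, reference) {
  k <- .kabsch_core(mobile, reference)
  sweep(k$Xc %*% t(k$R), 2, k$cy, `+`)
}

#' Kabsch superposition of two point sets
#'
#' Optimal least-squares rigid transform: centered cross-covariance SVD
#' with determinant sign correction so only proper rotations are
#' returned. The RMSD is over the transformed mobile set:
#' sqrt(sum |R x_i + t - y_i|^2 / n).
#'
#' @param mobile n x 3 coordinates to transform.
#' @param reference n x 3 target coordinates.
#' @return list(rotation 3x3, translation 3-vector, rmsd)
#' @export
kabschSuperpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) stop("point counts differ")
  if (nrow(mobile) < 3) stop("need at least 3 points")
  if (qr(scale(mobile, scale = FALSE))$rank < 2 ||
      qr(scale(reference, scale = FALSE))$rank < 2)
    warning("collinear point set: superposition is not unique")
  k <- .kabsch_core(mobile, reference)
  dev <- k$Xc %*% t(k$R) - k$Yc
  list(rotation = k$R, translation = k$t,
       rmsd = sqrt(mean(rowSums(dev^2))))
}

.resolve_selection <- function(n, selection) {
  if (is.null(selection)) return(seq_len(n))
  if (is.logical(selection)) selection <- which(selection)
  selection <- as.integer(selection)
  if (length(selection) == 0) stop("empty selection")
  if (any(selection < 1 | selection > n)) stop("selection out of range")
  selection
}

#' Per-frame RMSD against a reference frame
#'
#' Kabsch RMSD of every frame versus the chosen reference frame over the
#' selected atoms; the conventional stability trace of a trajectory
#' against its initial structure.
#'
#' @param ensemble \linkS4class{CoordinateEnsemble}.
#' @param referenceFrame 1-based reference frame index (default 1).
#' @param selection atom indices or logical mask (default all atoms).
#' @return a \linkS4class{MetricSeries} named "rmsd"
#' @export
rmsdSeries <- function(ensemble, referenceFrame = 1L, selection = NULL) {
  F_ <- nFrames(ensemble)
  if (referenceFrame < 1 || referenceFrame > F_)
    stop("reference frame out of range")
  sel <- .resolve_selection(nAtoms(ensemble), selection)
  ref <- ensemble@frames[[referenceFrame]][sel, , drop = FALSE]
  vals <- vapply(ensemble@frames, function(f)
    kabschSuperpose(f[sel, , drop = FALSE], ref)$rmsd, numeric(1))
  new("MetricSeries", name = "rmsd", values = vals, histogram = list())
}

#' Per-atom root mean square fluctuation
#'
#' Superposes all frames onto the iteratively refined mean structure, then
#' RMSF_i = sqrt(<|r_i - <r_i>|^2>) over frames.
#'
#' @param ensemble \linkS4class{CoordinateEnsemble} with >= 2 frames.
#' @param selection atom indices or logical mask (default all).
#' @return numeric vector of per-atom RMSF (Angstrom)
#' @export
rmsfProfile <- function(ensemble, selection = NULL) {
  if (nFrames(ensemble) < 2) stop("need at least 2 frames for RMSF")
  sel <- .resolve_selection(nAtoms(ensemble), selection)
  fr <- lapply(ensemble@frames, function(f) f[sel, , drop = FALSE])
  aligned <- .iterated_mean_superpose(fr)
  mean_xyz <- Reduce(`+`, aligned) / length(aligned)
  msd <- Reduce(`+`, lapply(aligned, function(f)
    rowSums((f - mean_xyz)^2))) / length(aligned)
  sqrt(msd)
}

#' Radius of gyration of one conformation
#'
#' Rg = sqrt(sum m_i |r_i - r_com|^2 / sum m_i); a compactness measure.
#'
#' @param frame n x 3 coordinates (or a StructureModel).
#' @param masses per-atom masses (default all 1).
#' @return Rg in Angstrom
#' @export
radiusOfGyration <- function(frame, masses = NULL) {
  xyz <- if (is(frame, "StructureModel")) coords(frame) else as.matrix(frame)
  n <- nrow(xyz)
  if (n < 1) stop("empty coordinates")
  if (is.null(masses)) masses <- rep(1, n)
  if (length(masses) != n || any(masses <= 0)) stop("masses must be positive, one per atom")
  com <- colSums(xyz * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(xyz, 2, com)^2)) / sum(masses))
}

#' Radius-of-gyration series over an ensemble
#'
#' @param ensemble \linkS4class{CoordinateEnsemble}.
#' @param masses per-atom masses (default all 1).
#' @return a \linkS4class{MetricSeries} named "rg"
#' @export
rgSeries <- function(ensemble, masses = NULL) {
  vals <- vapply(ensemble@frames, radiusOfGyration, numeric(1),
                 masses = masses)
  new("MetricSeries", name = "rg", values = vals, histogram = list())
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Scatters quasi-uniform Fibonacci test points on each atom's expanded
#' sphere (vdW radius + probe); a point is exposed iff it lies outside
#' every neighbour's expanded sphere. Per-atom area is the exposed
#' fraction of 4 pi (r_i + probe)^2.
#'
#' @param model \linkS4class{StructureModel} with resolvable radii.
#' @param probeRadius probe radius in Angstrom (default 1.4, water).
#' @param nSpherePoints test points per atom (default 960).
#' @return list(total, perAtom) in Angstrom^2
#' @export
sasa <- function(model, probeRadius = 1.4, nSpherePoints = 960L) {
  if (probeRadius < 0) stop("probeRadius must be >= 0")
  xyz <- coords(model)
  r <- model@atoms$vdw
  if (any(is.na(r)))
    stop("unknown element radius for atom(s): ",
         paste(unique(model@atoms$element[is.na(r)]), collapse = ", "),
         " (supply a user radius table)")
  R <- r + probeRadius
  n <- nrow(xyz)
  pts <- fibonacciForceSet(nSpherePoints)@directions
  d2 <- as.matrix(stats::dist(xyz))^2
  per <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    test <- sweep(pts * R[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, nrow(test))
    for (j in nb) {
      dj2 <- rowSums(sweep(test, 2, xyz[j, ])^2)
      exposed <- exposed & dj2 >= R[j]^2
      if (!any(exposed)) break
    }
    per[i] <- 4 * pi * R[i]^2 * mean(exposed)
  }
  list(total = sum(per), perAtom = per)
}

#' SASA series over an ensemble
#'
#' @param ensemble \linkS4class{CoordinateEnsemble}.
#' @param probeRadius probe radius (Angstrom).
#' @param nSpherePoints test points per atom.
#' @return a \linkS4class{MetricSeries} named "sasa" (total area per frame)
#' @export
sasaSeries <- function(ensemble, probeRadius = 1.4, nSpherePoints = 960L) {
  topo <- ensemble@topology
  vals <- vapply(ensemble@frames, function(f) {
    m <- topo; m@coords <- f
    sasa(m, probeRadius, nSpherePoints)$total
  }, numeric(1))
  new("MetricSeries", name = "sasa", values = vals, histogram = list())
}

#' Hydrogen-bond acceptance criteria
#'
#' @param maxDaDistance donor-acceptor heavy-atom cutoff, Angstrom
#'   (default 3.0, inclusive).
#' @param minDhaAngle minimum donor-hydrogen-acceptor angle, degrees
#'   (default 135, inclusive).
#' @return an \linkS4class{HBondCriteria}
#' @export
hbondCriteria <- function(maxDaDistance = 3.0, minDhaAngle = 135) {
  new("HBondCriteria", maxDaDistance = maxDaDistance,
      minDhaAngle = minDhaAngle)
}

.angle_deg <- function(a, b, c) {
  ## angle at b of the triangle a-b-c
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Per-frame hydrogen-bond counts
#'
#' Geometric criterion: a donor-acceptor pair is bonded in a frame iff
#' the heavy-atom distance is within \code{maxDaDistance} (inclusive) and
#' some hydrogen attached to the donor makes a D-H...A angle of at least
#' \code{minDhaAngle}. Hydrogens are attached by a bonding heuristic
#' (element H within 1.25 Angstrom of the donor heavy atom). Each (D, A)
#' pair counts at most once per frame.
#'
#' @param ensemble \linkS4class{CoordinateEnsemble} with an all-atom
#'   topology carrying hydrogens.
#' @param donors indices of donor heavy atoms.
#' @param acceptors indices of acceptor heavy atoms.
#' @param criteria \linkS4class{HBondCriteria}.
#' @return a \linkS4class{MetricSeries} named "hbond_count"
#' @export
hbondSeries <- function(ensemble, donors, acceptors,
                        criteria = hbondCriteria()) {
  n <- nAtoms(ensemble)
  donors <- .resolve_selection(n, donors)
  acceptors <- .resolve_selection(n, acceptors)
  if (length(donors) == 0 || length(acceptors) == 0)
    stop("donor and acceptor selections must be non-empty")
  elem <- ensemble@topology@atoms$element
  hyd <- which(elem == "H")
  vals <- vapply(ensemble@frames, function(f) {
    count <- 0L
    for (d in donors) {
      dh <- hyd[sqrt(rowSums(sweep(f[hyd, , drop = FALSE], 2, f[d, ])^2)) <= 1.25]
      if (length(dh) == 0) next
      for (a in acceptors) {
        if (a == d) next
        if (sqrt(sum((f[d, ] - f[a, ])^2)) > criteria@maxDaDistance) next
        ang <- vapply(dh, function(h) .angle_deg(f[d, ], f[h, ], f[a, ]),
                      numeric(1))
        if (any(ang >= criteria@minDhaAngle)) count <- count + 1L
      }
    }
    as.numeric(count)
  }, numeric(1))
  new("MetricSeries", name = "hbond_count", values = vals, histogram = list())
}

#' Attach a relative-frequency histogram to a metric series
#'
#' Equal-width bins spanning [min, max] of the series; the right-most bin
#' is inclusive; frequencies are normalized to sum to 1. A constant
#' series occupies a single bin.
#'
#' @param series \linkS4class{MetricSeries}.
#' @param nBins number of bins (default 50).
#' @return the series with its histogram slot filled
#' @export
metricHistogram <- function(series, nBins = 50L) {
  x <- series@values
  if (length(x) == 0) stop("empty series")
  if (nBins < 1) stop("nBins must be >= 1")
  lo <- min(x); hi <- max(x)
  if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  edges <- seq(lo, hi, length.out = nBins + 1)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = nBins)
  out <- series
  out@histogram <- list(edges = edges, freq = counts / length(x))
  out
}

.kmeanspp_centers <- function(X, k, seed) {
  withr::with_seed(seed, {
    n <- nrow(X)
    centers <- integer(k)
    centers[1] <- sample.int(n, 1)
    if (k > 1) {
      d2 <- rowSums(sweep(X, 2, X[centers[1], ])^2)
      for (c_ in 2:k) {
        prob <- d2 / sum(d2)
        centers[c_] <- sample.int(n, 1, prob = prob)
        d2 <- pmin(d2, rowSums(sweep(X, 2, X[centers[c_], ])^2))
      }
    }
    centers
  })
}

#' Cluster ensemble frames by k-means
#'
#' Superposes frames onto the iterated mean, flattens the coordinates and
#' runs Lloyd k-means with k-means++-style seeding from the fixed seed
#' (at most 500 iterations). Euclidean distance on superposed flattened
#' coordinates stands proxy for pairwise-RMSD clustering. The
#' representative of each cluster is its member frame nearest the
#' centroid; ten representatives per system is the conventional default.
#'
#' @param ensemble \linkS4class{CoordinateEnsemble}.
#' @param k number of clusters (default 10).
#' @param seed RNG seed for reproducible seeding.
#' @return a \linkS4class{ClusterResult}
#' @export
clusterFrames <- function(ensemble, k = 10L, seed = 1L) {
  F_ <- nFrames(ensemble)
  if (k < 1) stop("k must be >= 1")
  if (k > F_) stop(sprintf("k = %d exceeds the %d frames", k, F_))
  aligned <- .iterated_mean_superpose(frames(ensemble))
  X <- do.call(rbind, lapply(aligned, function(f) as.vector(t(f))))
  if (k == F_) {
    return(new("ClusterResult", labels = seq_len(F_),
               representatives = seq_len(F_), k = as.integer(k)))
  }
  init <- .kmeanspp_centers(X, k, seed)
  km <- suppressWarnings(
    stats::kmeans(X, centers = X[init, , drop = FALSE],
                  iter.max = 500L, algorithm = "Lloyd"))
  labels <- as.integer(km$cluster)
  reps <- vapply(seq_len(k), function(c_) {
    members <- which(labels == c_)
    d2 <- rowSums(sweep(X[members, , drop = FALSE], 2, km$centers[c_, ])^2)
    members[which.min(d2)]
  }, integer(1))
  new("ClusterResult", labels = labels, representatives = reps,
      k = as.integer(k))
}

#' Write cluster representatives as a multi-model PDB
#'
#' @param ensemble source \linkS4class{CoordinateEnsemble}.
#' @param clusters \linkS4class{ClusterResult}.
#' @param path output PDB path.
#' @export
writeRepresentatives <- function(ensemble, clusters, path) {
  sub <- CoordinateEnsemble(ensemble@topology,
                            ensemble@frames[clusters@representatives],
                            ensemble@frameInterval)
  writeEnsemble(sub, path)
}
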