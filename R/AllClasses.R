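#' @import methods
NULL

## Default van der Waals radii (Angstrom) used for SASA and atom records.
## Unknown elements carry NA and only error when a radius is actually needed.
.vdw_table <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

#' StructureModel: one conformer at atomic resolution
#'
#' Holds an ordered atom table and an n x 3 coordinate matrix (Angstrom).
#' Atom order is preserved from the source file; residue indices must be
#' non-decreasing within each chain.
#'
#' @slot atoms data.frame with columns serial, name, element, resname,
#'   resid, chain, vdw (vdw may be NA for elements outside the built-in
#'   radius table; operations needing radii check at point of use).
#' @slot coords numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @slot title free-text description.
#' @export
setClass("StructureModel",
  slots = c(atoms = "data.frame", coords = "matrix", title = "character"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  xyz <- object@coords
  need <- c("serial", "name", "element", "resname", "resid", "chain", "vdw")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) != nrow(xyz)) return("atoms and coords row counts differ")
  if (ncol(xyz) != 3) return("coords must have 3 columns")
  if (nrow(xyz) > 0 && !all(is.finite(xyz))) return("non-finite coordinates")
  if (any(!is.na(a$vdw) & a$vdw <= 0)) return("vdw radii must be positive")
  for (ch in unique(a$chain)) {
    r <- a$resid[a$chain == ch]
    if (is.unsorted(r)) return(sprintf("residue indices decrease within chain %s", ch))
  }
  TRUE
})

#' CoordinateEnsemble: an ordered set of conformations sharing one topology
#'
#' @slot topology a \linkS4class{StructureModel} describing the atoms.
#' @slot frames list of n_atoms x 3 coordinate matrices (Angstrom).
#' @slot frameInterval time per stored frame (informational; any unit).
#' @export
setClass("CoordinateEnsemble",
  slots = c(topology = "StructureModel", frames = "list",
            frameInterval = "numeric"))

setValidity("CoordinateEnsemble", function(object) {
  n <- nrow(object@topology@coords)
  if (length(object@frames) < 1) return("ensemble needs at least one frame")
  ok <- vapply(object@frames, function(f)
    is.matrix(f) && nrow(f) == n && ncol(f) == 3 && all(is.finite(f)), logical(1))
  if (!all(ok)) return("every frame must be a finite n_atoms x 3 matrix")
  TRUE
})

#' ElasticNetwork: ANM Hessian built on CA coordinates
#'
#' @slot positions N x 3 CA coordinates (Angstrom).
#' @slot cutoff contact cutoff r_c (Angstrom).
#' @slot gamma uniform spring constant (arbitrary energy/A^2 units).
#' @slot hessian 3N x 3N ANM Hessian.
#' @export
setClass("ElasticNetwork",
  slots = c(positions = "matrix", cutoff = "numeric", gamma = "numeric",
            hessian = "matrix"))

setValidity("ElasticNetwork", function(object) {
  H <- object@hessian
  n <- nrow(object@positions)
  if (nrow(H) != 3 * n || ncol(H) != 3 * n) return("hessian must be 3N x 3N")
  rel <- max(abs(H - t(H))) / max(abs(H), 1e-300)
  if (rel > 1e-10) return("hessian not symmetric")
  TRUE
})

#' CovarianceModel: 3N x 3N positional covariance with provenance
#'
#' The kernel that linear response theory consumes. Source records whether
#' it came from an ANM pseudo-inverse or a superposed ensemble.
#'
#' @slot matrix 3N x 3N covariance.
#' @slot kT thermal-energy scale (dimensionless; default 1).
#' @slot source "anm" or "ensemble".
#' @slot nZeroModesRemoved number of rigid-body modes dropped (6 for ANM).
#' @export
setClass("CovarianceModel",
  slots = c(matrix = "matrix", kT = "numeric", source = "character",
            nZeroModesRemoved = "integer"))

setValidity("CovarianceModel", function(object) {
  C <- object@matrix
  if (nrow(C) != ncol(C)) return("covariance must be square")
  if (nrow(C) %% 3 != 0) return("covariance dimension must be 3N")
  if (max(abs(C - t(C))) > 1e-8 * max(abs(C), 1e-300))
    return("covariance not symmetric")
  if (!object@source %in% c("anm", "ensemble"))
    return("source must be 'anm' or 'ensemble'")
  if (object@kT <= 0) return("kT must be positive")
  TRUE
})

#' ForceSet: unit force directions for perturbation scanning
#'
#' @slot directions M x 3 matrix of unit vectors.
#' @slot scheme "fibonacci" (sampled) or "analytic" (exact isotropic limit;
#'   directions then only informational).
#' @export
setClass("ForceSet",
  slots = c(directions = "matrix", scheme = "character"))

setValidity("ForceSet", function(object) {
  d <- object@directions
  if (ncol(d) != 3) return("directions must be M x 3")
  if (nrow(d) < 1) return("at least one direction required")
  nrm <- sqrt(rowSums(d^2))
  if (any(abs(nrm - 1) > 1e-12)) return("directions must be unit vectors")
  if (!object@scheme %in% c("fibonacci", "analytic"))
    return("scheme must be 'fibonacci' or 'analytic'")
  TRUE
})

#' PRSResult: perturbation response matrices and profiles
#'
#' Element (i, j) of \code{response} is the mean squared displacement
#' magnitude at residue j when residue i is perturbed. \code{normalized}
#' divides row i by its self-response so the diagonal is exactly 1.
#'
#' @slot response N x N raw response matrix.
#' @slot normalized N x N row-normalized response (unit diagonal).
#' @slot effectorProfile length-N row means of normalized, diagonal excluded.
#' @slot sensorProfile length-N column means of normalized, diagonal excluded.
#' @slot nForces number of force directions used (M).
#' @slot scheme sampling scheme the result came from.
#' @export
setClass("PRSResult",
  slots = c(response = "matrix", normalized = "matrix",
            effectorProfile = "numeric", sensorProfile = "numeric",
            nForces = "integer", scheme = "character"))

setValidity("PRSResult", function(object) {
  R <- object@response
  Z <- object@normalized
  if (any(dim(R) != dim(Z))) return("response/normalized dims differ")
  if (nrow(R) != ncol(R)) return("response must be square")
  if (any(R < 0)) return("response must be non-negative")
  if (any(abs(diag(Z) - 1) > 0)) return("normalized diagonal must be exactly 1")
  if (length(object@effectorProfile) != nrow(R)) return("effector profile length")
  if (length(object@sensorProfile) != nrow(R)) return("sensor profile length")
  TRUE
})

#' ResidueGraph: residue interaction graph for pathway extraction
#'
#' Undirected; each pair stored once with i < j. Weights are non-negative
#' and finite; unit weights until PRS couplings are assigned.
#'
#' @slot nNodes number of residues.
#' @slot edges data.frame(i, j, weight) with i < j.
#' @slot contactCutoff CA-CA contact cutoff (Angstrom).
#' @slot weighting "unit" or "prs".
#' @export
setClass("ResidueGraph",
  slots = c(nNodes = "integer", edges = "data.frame",
            contactCutoff = "numeric", weighting = "character"))

setValidity("ResidueGraph", function(object) {
  e <- object@edges
  if (!all(c("i", "j", "weight") %in% names(e)))
    return("edges needs columns i, j, weight")
  if (nrow(e) > 0) {
    if (any(e$i >= e$j)) return("edges must satisfy i < j (no self-edges)")
    if (any(e$j > object@nNodes)) return("edge endpoint beyond nNodes")
    if (any(!is.finite(e$weight)) || any(e$weight < 0))
      return("weights must be finite and >= 0")
    if (anyDuplicated(paste(e$i, e$j))) return("duplicate edges")
  }
  if (!object@weighting %in% c("unit", "prs"))
    return("weighting must be 'unit' or 'prs'")
  TRUE
})

#' AllostericPath: one weighted residue path from a source to a sink
#'
#' @slot nodes ordered residue indices, source first, sink last.
#' @slot totalWeight sum of edge weights along the path.
#' @export
setClass("AllostericPath",
  slots = c(nodes = "integer", totalWeight = "numeric"))

setValidity("AllostericPath", function(object) {
  if (length(object@nodes) < 2) return("path needs at least two nodes")
  if (!is.finite(object@totalWeight) || object@totalWeight < 0)
    return("total weight must be finite and >= 0")
  TRUE
})

#' MediationProfile: interior-node path counts per residue
#'
#' counts[r] is the number of source-sink shortest paths in which residue r
#' appears strictly between the endpoints; endpoints are never counted.
#'
#' @slot counts length-N integer vector.
#' @slot nPaths number of paths profiled.
#' @export
setClass("MediationProfile",
  slots = c(counts = "integer", nPaths = "integer"))

setValidity("MediationProfile", function(object) {
  if (any(object@counts < 0)) return("counts must be >= 0")
  if (object@nPaths < 0) return("nPaths must be >= 0")
  TRUE
})

#' MetricSeries: a per-frame scalar trajectory metric
#'
#' @slot name one of "rmsd", "rg", "sasa", "hbond_count".
#' @slot values per-frame scalars (Angstrom, Angstrom, Angstrom^2, count).
#' @slot histogram list(edges, freq) from \code{metricHistogram}, or empty.
#' @export
setClass("MetricSeries",
  slots = c(name = "character", values = "numeric", histogram = "list"))

setValidity("MetricSeries", function(object) {
  if (!object@name %in% c("rmsd", "rg", "sasa", "hbond_count"))
    return("name must be rmsd/rg/sasa/hbond_count")
  if (length(object@histogram) > 0) {
    h <- object@histogram
    if (!all(c("edges", "freq") %in% names(h))) return("histogram needs edges, freq")
    if (abs(sum(h$freq) - 1) > 1e-9) return("histogram frequencies must sum to 1")
  }
  TRUE
})

#' HBondCriteria: geometric hydrogen-bond acceptance thresholds
#'
#' @slot maxDaDistance maximum donor-heavy to acceptor-heavy distance (Angstrom).
#' @slot minDhaAngle minimum donor-hydrogen-acceptor angle (degrees).
#' @export
setClass("HBondCriteria",
  slots = c(maxDaDistance = "numeric", minDhaAngle = "numeric"))

setValidity("HBondCriteria", function(object) {
  if (object@maxDaDistance <= 0) return("distance cutoff must be positive")
  if (object@minDhaAngle <= 0 || object@minDhaAngle > 180)
    return("angle must be in (0, 180]")
  TRUE
})

#' ClusterResult: frame clustering with representatives
#'
#' @slot labels per-frame cluster index in 1..k.
#' @slot representatives one frame index per cluster (closest to centroid).
#' @slot k requested cluster count.
#' @export
setClass("ClusterResult",
  slots = c(labels = "integer", representatives = "integer", k = "integer"))

setValidity("ClusterResult", function(object) {
  if (any(object@labels < 1L | object@labels > object@k))
    return("labels must lie in 1..k")
  if (any(object@representatives < 1L | object@representatives > length(object@labels)))
    return("representatives must be valid frame indices")
  TRUE
})
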