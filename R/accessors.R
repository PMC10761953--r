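#' @include AllGenerics.R
NULL

#' @describeIn nAtoms atoms in a StructureModel
#' @export
setMethod("nAtoms", "StructureModel", function(x) nrow(x@coords))

#' @describeIn nAtoms atoms in an ensemble's topology
#' @export
setMethod("nAtoms", "CoordinateEnsemble", function(x) nrow(x@topology@coords))

#' @describeIn coords coordinates of a StructureModel (n x 3)
#' @export
setMethod("coords", "StructureModel", function(x, ...) x@coords)

#' @describeIn coords coordinates of ensemble frame \code{i}
#' @param i frame index
#' @export
setMethod("coords", "CoordinateEnsemble", function(x, i = 1L, ...) {
  if (i < 1L || i > length(x@frames)) stop("frame index out of range: ", i)
  x@frames[[i]]
})

#' @describeIn atomData atom table of a StructureModel
#' @export
setMethod("atomData", "StructureModel", function(x) x@atoms)

#' @describeIn residueIndices residue index per atom
#' @export
setMethod("residueIndices", "StructureModel", function(x) x@atoms$resid)

#' @describeIn nFrames frames stored in an ensemble
#' @export
setMethod("nFrames", "CoordinateEnsemble", function(x) length(x@frames))

#' @describeIn frames list of frame matrices
#' @export
setMethod("frames", "CoordinateEnsemble", function(x) x@frames)

#' @describeIn topology topology StructureModel
#' @export
setMethod("topology", "CoordinateEnsemble", function(x) x@topology)

#' @describeIn hessian 3N x 3N ANM Hessian
#' @export
setMethod("hessian", "ElasticNetwork", function(x) x@hessian)

#' @describeIn covMatrix 3N x 3N covariance
#' @export
setMethod("covMatrix", "CovarianceModel", function(x) x@matrix)

#' @describeIn responseMatrix raw N x N response
#' @export
setMethod("responseMatrix", "PRSResult", function(x) x@response)

#' @describeIn normalizedResponse normalized N x N response
#' @export
setMethod("normalizedResponse", "PRSResult", function(x) x@normalized)

#' @describeIn effectorProfile length-N effector scores
#' @export
setMethod("effectorProfile", "PRSResult", function(x) x@effectorProfile)

#' @describeIn sensorProfile length-N sensor scores
#' @export
setMethod("sensorProfile", "PRSResult", function(x) x@sensorProfile)

#' @describeIn edges edge data.frame (i, j, weight)
#' @export
setMethod("edges", "ResidueGraph", function(x) x@edges)

#' @describeIn pathNodes ordered residue indices
#' @export
setMethod("pathNodes", "AllostericPath", function(x) x@nodes)

#' @describeIn pathWeight total path weight
#' @export
setMethod("pathWeight", "AllostericPath", function(x) x@totalWeight)

#' @describeIn mediationCounts per-residue interior counts
#' @export
setMethod("mediationCounts", "MediationProfile", function(x) x@counts)

#' @describeIn metricValues per-frame scalars
#' @export
setMethod("metricValues", "MetricSeries", function(x) x@values)

setMethod("show", "StructureModel", function(object) {
  cat(sprintf("StructureModel: %d atoms, %d residues",
              nrow(object@coords), length(unique(paste(object@atoms$chain, object@atoms$resid)))))
  if (nzchar(object@title)) cat(" |", object@title)
  cat("\n")
})

setMethod("show", "CoordinateEnsemble", function(object) {
  cat(sprintf("CoordinateEnsemble: %d frames x %d atoms\n",
              length(object@frames), nrow(object@topology@coords)))
})

setMethod("show", "ElasticNetwork", function(object) {
  cat(sprintf("ElasticNetwork (ANM): N=%d, cutoff=%.1f A, gamma=%g\n",
              nrow(object@positions), object@cutoff, object@gamma))
})

setMethod("show", "CovarianceModel", function(object) {
  cat(sprintf("CovarianceModel: 3N=%d, source=%s, kT=%g, zero modes removed=%d\n",
              nrow(object@matrix), object@source, object@kT,
              object@nZeroModesRemoved))
})

setMethod("show", "PRSResult", function(object) {
  cat(sprintf("PRSResult: N=%d residues, scheme=%s, M=%d forces\n",
              nrow(object@response), object@scheme, object@nForces))
})

setMethod("show", "ResidueGraph", function(object) {
  cat(sprintf("ResidueGraph: %d nodes, %d edges, cutoff=%.1f A, weighting=%s\n",
              object@nNodes, nrow(object@edges), object@contactCutoff,
              object@weighting))
})

setMethod("show", "AllostericPath", function(object) {
  cat(sprintf("AllostericPath: %s (weight %.4f)\n",
              paste(object@nodes, collapse = " -> "), object@totalWeight))
})

setMethod("show", "MediationProfile", function(object) {
  top <- which(object@counts == max(object@counts))
  cat(sprintf("MediationProfile over %d paths; most-mediated residue(s): %s (count %d)\n",
              object@nPaths, paste(top, collapse = ", "), max(object@counts)))
})

setMethod("show", "MetricSeries", function(object) {
  cat(sprintf("MetricSeries '%s': %d frames, mean %.4g\n",
              object@name, length(object@values), mean(object@values)))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: k=%d over %d frames; representatives: %s\n",
              object@k, length(object@labels),
              paste(object@representatives, collapse = ", ")))
})
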