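#' @include AllClasses.R
NULL

#' Number of atoms in a structure or ensemble topology
#' @param x object
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Coordinate access
#' @param x object
#' @param ... passed on
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' Atom metadata table
#' @param x object
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' Residue indices of atoms
#' @param x object
#' @export
setGeneric("residueIndices", function(x) standardGeneric("residueIndices"))

#' Number of frames in an ensemble
#' @param x object
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' List of frame coordinate matrices
#' @param x object
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' Topology of an ensemble
#' @param x object
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Hessian matrix of an elastic network
#' @param x object
#' @export
setGeneric("hessian", function(x) standardGeneric("hessian"))

#' Covariance matrix
#' @param x object
#' @export
setGeneric("covMatrix", function(x) standardGeneric("covMatrix"))

#' Raw PRS response matrix
#' @param x object
#' @export
setGeneric("responseMatrix", function(x) standardGeneric("responseMatrix"))

#' Row-normalized PRS response matrix (unit diagonal)
#' @param x object
#' @export
setGeneric("normalizedResponse", function(x) standardGeneric("normalizedResponse"))

#' Effector profile (row means of the normalized response, diagonal excluded)
#' @param x object
#' @export
setGeneric("effectorProfile", function(x) standardGeneric("effectorProfile"))

#' Sensor profile (column means of the normalized response, diagonal excluded)
#' @param x object
#' @export
setGeneric("sensorProfile", function(x) standardGeneric("sensorProfile"))

#' Edge table of a residue graph
#' @param x object
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' Node sequence of a path
#' @param x object
#' @export
setGeneric("pathNodes", function(x) standardGeneric("pathNodes"))

#' Total weight of a path
#' @param x object
#' @export
setGeneric("pathWeight", function(x) standardGeneric("pathWeight"))

#' Mediation counts per residue
#' @param x object
#' @export
setGeneric("mediationCounts", function(x) standardGeneric("mediationCounts"))

#' Per-frame values of a metric series
#' @param x object
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))
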