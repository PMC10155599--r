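#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal rowSums colSums t crossprod
NULL

#' Number of vertices
#'
#' @param x a \linkS4class{SphereMesh} or surface data object.
#' @return integer vertex count.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' Number of faces of a mesh
#' @param x a \linkS4class{SphereMesh}.
#' @return integer face count.
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' Subdivision level
#' @param x a \linkS4class{SphereMesh} or object carrying a mesh level.
#' @return integer icosphere subdivision level.
#' @export
setGeneric("meshLevel", function(x) standardGeneric("meshLevel"))

#' One-ring neighborhoods
#'
#' Per-vertex neighbor index lists, each ordered counter-clockwise as seen
#' from outside the sphere, starting at the lowest-index neighbor.
#'
#' @param x a \linkS4class{SphereMesh}.
#' @return list of integer vectors (1-based vertex indices).
#' @export
setGeneric("oneRing", function(x) standardGeneric("oneRing"))

#' Vertex inclusion mask
#'
#' Logical length-V mask; \code{TRUE} marks cortical vertices that enter
#' losses and metrics, \code{FALSE} marks excluded vertices (medial wall).
#'
#' @param x a surface data object.
#' @return logical vector.
#' @export
setGeneric("vertexMask", function(x) standardGeneric("vertexMask"))

#' Data matrix of a surface object
#' @param x a surface data object.
#' @return numeric V x K matrix (timepoints, channels or contrasts in columns).
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' Subject identifier
#' @param x a surface data object.
#' @return character scalar.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' Contrast names of a multi-channel map
#' @param x a \linkS4class{ContrastMaps}.
#' @return character vector.
#' @export
setGeneric("contrastNames", function(x) standardGeneric("contrastNames"))

#' Channel names of a connectome
#' @param x a \linkS4class{Connectome}.
#' @return character vector of ROI channel names.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
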