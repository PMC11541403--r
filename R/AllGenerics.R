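#' @rdname TriangleMesh-class
#' @param x a TriangleMesh
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("vertexLabels", function(x) standardGeneric("vertexLabels"))

#' Volume enclosed by a closed mesh (mm^3)
#' @param x a TriangleMesh
#' @export
setGeneric("meshVolume", function(x) standardGeneric("meshVolume"))

#' Watertightness test
#'
#' TRUE when every edge is shared by exactly two faces with consistent
#' winding (a closed, orientable, manifold surface).
#' @param x a TriangleMesh
#' @export
setGeneric("isWatertight", function(x) standardGeneric("isWatertight"))

#' Apply a rigid/similarity transform to points or meshes
#' @param transform a RigidTransform
#' @param x a TriangleMesh, LandmarkSet or point matrix
#' @export
setGeneric("applyTransform", function(transform, x) standardGeneric("applyTransform"))

#' Number of retained deformation modes
#' @param x a MorphableModel
#' @export
setGeneric("modelRank", function(x) standardGeneric("modelRank"))

#' @rdname modelRank
#' @export
setGeneric("modeSD", function(x) standardGeneric("modeSD"))

#' Mean shape of a morphable model, as a mesh on the reference topology
#' @param x a MorphableModel
#' @export
setGeneric("meanMesh", function(x) standardGeneric("meanMesh"))
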