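#' Triangle surface mesh in millimetres
#'
#' The common container for all surfaces handled by the package: the
#' patient's face model (FM), the reconstructed nose model (NM), the
#' prosthesis model (PM) and the mold shells. Vertices are a numeric
#' \code{n x 3} matrix in mm; faces are an integer \code{m x 3} matrix of
#' 1-based vertex indices. \code{vertexLabels} optionally carries one integer
#' tag per vertex (e.g. a region id) and is either empty or of length
#' \code{n}.
#'
#' @slot vertices numeric matrix, \code{n x 3} (mm)
#' @slot faces integer matrix, \code{m x 3}, 1-based indices into vertices
#' @slot vertexLabels integer vector, length 0 or \code{n}
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix", vertexLabels = "integer"),
  prototype(vertices = matrix(numeric(0), 0, 3), faces = matrix(integer(0), 0, 3),
            vertexLabels = integer(0)))

setValidity("TriangleMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3) return("vertices must have 3 columns")
  if (ncol(f) != 3) return("faces must have 3 columns")
  if (!is.numeric(v)) return("vertices must be numeric")
  if (nrow(f) > 0) {
    if (!is.numeric(f)) return("faces must be integer-valued")
    if (min(f) < 1 || max(f) > nrow(v)) return("face index out of [1, vertex count]")
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
      return("a face repeats a vertex index")
  }
  if (length(object@vertexLabels) != 0 && length(object@vertexLabels) != nrow(v))
    return("vertexLabels length must be 0 or the vertex count")
  if (any(!is.finite(v))) return("vertices must be finite")
  TRUE
})

#' Rigid (or similarity) transform
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1
#' @slot translation length-3 numeric (mm)
#' @slot scale positive scalar; 1 for a strictly rigid transform
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric", scale = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0), scale = 1))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6) return("rotation must be orthonormal")
  if (det(R) < 0) return("rotation must not mirror (det must be +1)")
  if (length(object@translation) != 3) return("translation must have length 3")
  if (length(object@scale) != 1 || object@scale <= 0) return("scale must be a positive scalar")
  TRUE
})

#' Named anatomical landmarks
#'
#' A named set of 3D points (mm) used for rigid alignment, e.g. the
#' exocanthi, glabella and pogonion. At least three landmarks are required
#' for alignment.
#'
#' @slot coords numeric \code{k x 3} matrix with unique rownames
#' @export
setClass("LandmarkSet", representation(coords = "matrix"),
  prototype(coords = matrix(numeric(0), 0, 3)))

setValidity("LandmarkSet", function(object) {
  co <- object@coords
  if (ncol(co) != 3) return("coords must have 3 columns")
  if (nrow(co) > 0 && (is.null(rownames(co)) || anyDuplicated(rownames(co))))
    return("landmark names must be present and unique")
  TRUE
})

#' Per-vertex region mask
#'
#' Boolean flags on the vertices of a specific mesh topology (identified by
#' its vertex count), used for defect erasure, nose cropping and targeted
#' smoothing.
#'
#' @slot flags logical vector, one flag per vertex
#' @export
setClass("RegionMask", representation(flags = "logical"),
  prototype(flags = logical(0)))

setValidity("RegionMask", function(object) {
  if (anyNA(object@flags)) return("flags must not contain NA")
  TRUE
})

#' Morphable shape model
#'
#' Mean shape plus orthonormal deformation basis with per-mode standard
#' deviations: the statistical face model (MFM). Coordinates are stacked as
#' \code{(x1, y1, z1, x2, ...)} so the mean is a \code{3N} vector and the
#' basis a \code{3N x r} matrix. Mode coefficients are standardized (units
#' of per-mode SD).
#'
#' @slot faces reference topology: integer \code{m x 3} face matrix
#' @slot mean numeric vector of length \code{3N} (mm)
#' @slot basis numeric \code{3N x r} matrix with orthonormal columns
#' @slot modeSD numeric vector of length \code{r}, positive, non-increasing (mm)
#' @export
setClass("MorphableModel",
  representation(faces = "matrix", mean = "numeric", basis = "matrix", modeSD = "numeric"))

setValidity("MorphableModel", function(object) {
  n3 <- length(object@mean)
  if (n3 %% 3 != 0) return("mean length must be a multiple of 3")
  B <- object@basis
  if (nrow(B) != n3) return("basis rows must match mean length")
  r <- ncol(B)
  if (r > n3) return("rank exceeds 3N")
  if (length(object@modeSD) != r) return("modeSD length must equal basis rank")
  if (r > 0) {
    if (any(object@modeSD <= 0)) return("modeSD must be strictly positive")
    if (any(diff(object@modeSD) > 1e-9)) return("modeSD must be non-increasing")
    G <- crossprod(B)
    if (max(abs(G - diag(r))) > 1e-6) return("basis columns must be orthonormal")
  }
  if (nrow(object@faces) > 0 && max(object@faces) > n3 / 3)
    return("reference topology indexes beyond vertex count")
  TRUE
})

#' Fitting configuration
#'
#' Hyperparameters of the iterative model-to-scan fit. All distances in mm,
#' angles in degrees; \code{regularizationWeight} is the unitless ridge
#' penalty on standardized coefficients; \code{coeffBound} clips
#' coefficients to plus/minus that many SDs.
#'
#' @slot maxIterations integer
#' @slot corrMaxDistance mm, correspondence rejection distance
#' @slot corrMaxNormalAngle degrees, correspondence rejection normal angle
#' @slot regularizationWeight unitless, >= 0
#' @slot coeffBound SD units, >= 1
#' @slot convergenceTol mm, stop when the RMS change falls below this
#' @slot withScale logical, estimate a uniform scale in the rigid updates
#' @export
setClass("FitConfig",
  representation(maxIterations = "integer", corrMaxDistance = "numeric",
                 corrMaxNormalAngle = "numeric", regularizationWeight = "numeric",
                 coeffBound = "numeric", convergenceTol = "numeric", withScale = "logical"),
  prototype(maxIterations = 50L, corrMaxDistance = 5, corrMaxNormalAngle = 60,
            regularizationWeight = 0.1, coeffBound = 3, convergenceTol = 0.01,
            withScale = FALSE))

setValidity("FitConfig", function(object) {
  if (object@maxIterations < 1) return("maxIterations must be positive")
  for (s in c("corrMaxDistance", "corrMaxNormalAngle", "convergenceTol"))
    if (slot(object, s) <= 0) return(paste(s, "must be positive"))
  if (object@regularizationWeight < 0) return("regularizationWeight must be >= 0")
  if (object@coeffBound < 1) return("coeffBound must be >= 1")
  TRUE
})

#' Result of a morphable-model fit
#'
#' @slot coefficients standardized mode coefficients (SD units)
#' @slot fittedMesh the full fitted surface on the reference topology, in
#'   scan coordinates
#' @slot residualTrace per-iteration correspondence RMS (mm)
#' @slot transform the rigid transform mapping model space to scan space
#' @export
setClass("FitResult",
  representation(coefficients = "numeric", fittedMesh = "TriangleMesh",
                 residualTrace = "numeric", transform = "RigidTransform"))

#' Geometric parameters of the prosthesis/mold protocol
#'
#' Defaults follow the printed protocol values: a 6 mm prosthesis wall, a
#' 0.3 mm mold closure gap and 4 mm mold shell walls. The remaining
#' parameters (blend band width/depth, densification target, smoothing
#' iterations, face backing depth, flange extent) parameterize the steps the
#' protocol leaves to the operator.
#'
#' @slot prosthesisWall mm, wall thickness of the solidified nose model
#' @slot moldGap mm, closure offset between the two mold flanges
#' @slot moldWall mm, wall thickness of both mold shells
#' @slot blendWidth mm, width of the border blending band
#' @slot blendDepth mm, how far the border is sunk inward of the face
#' @slot densifyEdge mm, target edge length for pre-processing densification
#' @slot smoothIterations integer, iterations for the protocol smoothing steps
#' @slot backingDepth mm, depth to which the face surface is closed into a solid
#' @slot flangeExtent mm, radial extent of the mold flange ring
#' @slot resolution mm, voxel pitch of the implicit-surface extractions
#' @export
setClass("DesignParams",
  representation(prosthesisWall = "numeric", moldGap = "numeric", moldWall = "numeric",
                 blendWidth = "numeric", blendDepth = "numeric", densifyEdge = "numeric",
                 smoothIterations = "integer", backingDepth = "numeric",
                 flangeExtent = "numeric", resolution = "numeric"),
  prototype(prosthesisWall = 6, moldGap = 0.3, moldWall = 4, blendWidth = 3,
            blendDepth = 0.5, densifyEdge = 0.5, smoothIterations = 10L,
            backingDepth = 30, flangeExtent = 10, resolution = 0.4))

setValidity("DesignParams", function(object) {
  for (s in c("prosthesisWall", "moldGap", "moldWall", "blendWidth", "blendDepth",
              "densifyEdge", "backingDepth", "flangeExtent", "resolution"))
    if (slot(object, s) <= 0) return(paste(s, "must be positive"))
  if (object@smoothIterations < 0) return("smoothIterations must be >= 0")
  if (object@moldGap >= object@moldWall) return("moldGap must be smaller than moldWall")
  if (object@blendDepth >= object@prosthesisWall)
    return("blendDepth must be smaller than prosthesisWall")
  TRUE
})

#' Nostril sculpting specification
#'
#' Zero, one or two capped cylinders subtracted from the prosthesis model.
#' Each row of \code{entry} is the cylinder entry point (mm), each row of
#' \code{axis} the (unit) drilling direction; \code{radius} and \code{depth}
#' are per-nostril in mm.
#'
#' @slot entry numeric \code{k x 3} matrix, k in 0..2
#' @slot axis numeric \code{k x 3} matrix of directions
#' @slot radius numeric vector, positive (mm)
#' @slot depth numeric vector, positive (mm)
#' @export
setClass("NostrilSpec",
  representation(entry = "matrix", axis = "matrix", radius = "numeric", depth = "numeric"),
  prototype(entry = matrix(numeric(0), 0, 3), axis = matrix(numeric(0), 0, 3),
            radius = numeric(0), depth = numeric(0)))

setValidity("NostrilSpec", function(object) {
  k <- nrow(object@entry)
  if (k > 2) return("at most two nostrils")
  if (nrow(object@axis) != k || length(object@radius) != k || length(object@depth) != k)
    return("entry, axis, radius and depth must agree in length")
  if (k > 0 && (any(object@radius <= 0) || any(object@depth <= 0)))
    return("radius and depth must be positive")
  TRUE
})

#' Two-part mold assembly
#'
#' The anterior (visible-surface) and posterior (skin-facing) mold shells.
#' Both are watertight, their interiors are disjoint, and the cavity of the
#' closed assembly reproduces the prosthesis model.
#'
#' @slot anteriorShell watertight TriangleMesh
#' @slot posteriorShell watertight TriangleMesh
#' @slot closureGap mm, the flange-to-flange closure offset
#' @slot parting list describing the parting frame (plane center/normal and
#'   the per-angle prosthesis edge radius), used by the gap measurement
#' @export
setClass("MoldAssembly",
  representation(anteriorShell = "TriangleMesh", posteriorShell = "TriangleMesh",
                 closureGap = "numeric", parting = "list"),
  prototype(parting = list()))

setValidity("MoldAssembly", function(object) {
  if (length(object@closureGap) != 1 || object@closureGap <= 0)
    return("closureGap must be a positive scalar")
  TRUE
})
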