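# Synthetic face population: smooth height-field faces on a shared (u,v)
# grid topology with a parametric nose (bridge ridge, tip lobe, nostril
# dents), simulated rhinectomy defects, and a CT-emulating voxelization
# route. Every face shares the identical triangulation, so a generated
# population feeds buildModel directly.
#
# The generator emulates the role of a licensed face-scan database: it is a
# synthetic stand-in with parametric, low-rank shape variation, not a
# photorealistic face model.

#' Shared grid topology for generated faces
#'
#' @slot nu,nv grid resolution in the two surface directions
#' @export
setClass("GridTopology96", representation(nu = "integer", nv = "integer"),
  prototype(nu = 96L, nv = 96L))

setValidity("GridTopology96", function(object) {
  if (object@nu < 8 || object@nv < 8) return("grid must be at least 8 x 8")
  TRUE
})

#' @rdname GridTopology96-class
#' @param nu,nv grid resolution (vertex counts per direction)
#' @export
faceTopology <- function(nu = 96, nv = 96) {
  new("GridTopology96", nu = as.integer(nu), nv = as.integer(nv))
}

#' Face shape parameters
#'
#' Six interpretable parameters (all mm) driving the generator. Defaults
#' are the population means; \code{\link{generatePopulation}} samples each
#' from an independent normal with the SDs documented there.
#'
#' @slot noseLength,noseWidth,bridgeHeight,tipProjection,nostrilRadius,faceBreadth
#'   mm
#' @export
setClass("FaceParams",
  representation(noseLength = "numeric", noseWidth = "numeric",
                 bridgeHeight = "numeric", tipProjection = "numeric",
                 nostrilRadius = "numeric", faceBreadth = "numeric"),
  prototype(noseLength = 50, noseWidth = 34, bridgeHeight = 8,
            tipProjection = 18, nostrilRadius = 5, faceBreadth = 140))

setValidity("FaceParams", function(object) {
  for (s in c("noseLength", "noseWidth", "nostrilRadius", "faceBreadth"))
    if (slot(object, s) <= 0) return(paste(s, "must be positive"))
  if (object@bridgeHeight < 0 || object@tipProjection < 0)
    return("bridgeHeight and tipProjection must be >= 0")
  if (object@nostrilRadius >= object@noseWidth / 2)
    return("nostrilRadius must be below half the nose width")
  TRUE
})

#' @rdname FaceParams-class
#' @param noseLength,noseWidth,bridgeHeight,tipProjection,nostrilRadius,faceBreadth
#'   parameters in mm
#' @export
faceParams <- function(noseLength = 50, noseWidth = 34, bridgeHeight = 8,
                       tipProjection = 18, nostrilRadius = 5, faceBreadth = 140) {
  new("FaceParams", noseLength = noseLength, noseWidth = noseWidth,
      bridgeHeight = bridgeHeight, tipProjection = tipProjection,
      nostrilRadius = nostrilRadius, faceBreadth = faceBreadth)
}

# population sampling distributions (means from the prototype above)
faceParamSDs <- c(noseLength = 4, noseWidth = 2.5, bridgeHeight = 1.2,
                  tipProjection = 2.2, nostrilRadius = 0.4, faceBreadth = 4)

# fixed anatomical frame of the generator
FACE_HALF_HEIGHT <- 90     # y in [-90, 90] mm
NOSE_BRIDGE_TOP_Y <- 25    # y where the nasal bridge starts
TIP_T <- 0.78              # normalized position of the tip lobe along the nose
NOSE_MASK_THRESHOLD <- 0.3 # mm of nose contribution that defines the mask

# landmark positions in normalized (u, v) in [-1, 1]^2 (off the nose, so
# they survive a rhinectomy)
landmarkUV <- rbind(
  exocanthion_right = c(-0.62, 0.32),
  exocanthion_left  = c(0.62, 0.32),
  glabella          = c(0, 0.46),
  pogonion          = c(0, -0.80),
  cheek_right       = c(-0.48, -0.22),
  cheek_left        = c(0.48, -0.22))

#' Named landmark vertex indices on a grid topology
#' @param topology a grid topology from \code{\link{faceTopology}}
#' @return named integer vector of vertex indices
#' @export
faceLandmarkIndices <- function(topology = faceTopology()) {
  nu <- topology@nu; nv <- topology@nv
  iu <- round((landmarkUV[, 1] + 1) / 2 * (nu - 1)) + 1
  iv <- round((landmarkUV[, 2] + 1) / 2 * (nv - 1)) + 1
  idx <- as.integer((iv - 1) * nu + iu)
  names(idx) <- rownames(landmarkUV)
  idx
}

# Height field of the face at physical coordinates (x, y), given params.
# Returns list(z, nose) where `nose` is the nose-only contribution in mm.
#
# Besides the nose bump itself, the nasal parameters shape nearby intact
# anatomy (glabella prominence, upper-lip/philtrum region, paranasal
# cheeks). This emulates the face-nose correlation of real populations that
# statistical reconstruction exploits: after a rhinectomy, the remaining
# face retains information about the lost nose. The coupling terms are kept
# outside the nose mask so erasing the defect never removes them.
faceHeight <- function(x, y, p) {
  A <- 0.64 * p@faceBreadth
  base <- 55 * sqrt(pmax(0, 1 - (x / A)^2 - (y / 110)^2))
  t <- (NOSE_BRIDGE_TOP_Y - y) / p@noseLength
  tc <- pmin(pmax(t, 0), 1)
  gTip <- exp(-((t - TIP_T) / 0.16)^2)
  gBridge <- sin(pi * tc)^2 * (1 - 0.8 * gTip)
  H <- p@bridgeHeight * gBridge + p@tipProjection * gTip
  halfw <- p@noseWidth / 2 * (0.45 + 0.75 * tc)
  W <- cos(pi / 2 * pmin(abs(x) / halfw, 1))^2
  nose <- H * W
  # nostril indentations near the alar base, vanishing with the nose itself
  dentDepth <- 1.2 * pmin(1, (p@bridgeHeight + p@tipProjection) / 10)
  yN <- NOSE_BRIDGE_TOP_Y - 0.92 * p@noseLength
  xN <- 0.28 * p@noseWidth
  dents <- dentDepth * (exp(-((x - xN)^2 + (y - yN)^2) / p@nostrilRadius^2) +
                        exp(-((x + xN)^2 + (y - yN)^2) / p@nostrilRadius^2))
  # correlated peri-nasal anatomy (intact after a rhinectomy)
  yLip <- NOSE_BRIDGE_TOP_Y - 1.25 * p@noseLength
  glabella <- 0.6 * p@bridgeHeight * exp(-((y - 38)^2) / 12^2) * exp(-(x^2) / 10^2)
  lip <- 0.4 * p@tipProjection * exp(-((y - yLip)^2) / 8^2) * exp(-(x^2) / 12^2)
  cheek <- 0.3 * p@noseWidth * exp(-((y - yN)^2) / 10^2) *
    (exp(-((x - 30)^2) / 10^2) + exp(-((x + 30)^2) / 10^2))
  list(z = base + nose - dents + glabella + lip + cheek, nose = nose)
}

#' Generate one synthetic face
#'
#' Deterministic given the parameters: a smooth height-field face
#' (ellipsoidal base plus parametric nose with nostril indentations)
#' sampled on the shared grid. The nose mask flags vertices where the nose
#' contribution exceeds a fixed 0.3 mm threshold; landmarks sit at
#' analytically known grid positions away from the nose.
#'
#' @param params a \linkS4class{FaceParams}
#' @param topology a grid topology from \code{\link{faceTopology}}
#' @return list with \code{mesh}, \code{noseMask} (RegionMask),
#'   \code{landmarks} (LandmarkSet), \code{noseArea} (mm^2 of the masked
#'   patch) and \code{params}
#' @export
generateFace <- function(params = faceParams(), topology = faceTopology()) {
  validObject(params)
  nu <- topology@nu; nv <- topology@nv
  u <- seq(-1, 1, length.out = nu)
  v <- seq(-1, 1, length.out = nv)
  x <- rep(u, times = nv) * params@faceBreadth / 2
  y <- rep(v, each = nu) * FACE_HALF_HEIGHT
  h <- faceHeight(x, y, params)
  verts <- cbind(x, y, h$z)
  faces <- gridFaces(nu, nv)
  maskFlags <- h$nose > NOSE_MASK_THRESHOLD
  mesh <- TriangleMesh(verts, faces, as.integer(maskFlags))
  fmask <- maskFlags[faces[, 1]] & maskFlags[faces[, 2]] & maskFlags[faces[, 3]]
  noseArea <- if (any(fmask)) sum(faceAreas(mesh)[fmask]) else 0
  li <- faceLandmarkIndices(topology)
  co <- verts[li, , drop = FALSE]
  rownames(co) <- names(li)
  list(mesh = mesh, noseMask = new("RegionMask", flags = maskFlags),
       landmarks = new("LandmarkSet", coords = co), noseArea = noseArea,
       params = params)
}

#' Generate a reproducible face population
#'
#' Samples the six face parameters from independent normals
#' (means = \code{faceParams()} defaults; SDs 4, 2.5, 1.2, 2.2, 0.4 and
#' 4 mm respectively) and generates one face per draw on the shared
#' topology. The seed is a mandatory argument; there is no hidden global
#' randomness.
#'
#' @param n population size, >= 2
#' @param seed integer RNG seed
#' @param topology shared grid topology
#' @return list of TriangleMesh (with the drawn parameters in
#'   \code{attr(, "params")} and the per-face outputs in
#'   \code{attr(, "faces")})
#' @export
generatePopulation <- function(n, seed, topology = faceTopology()) {
  if (n < 2) stop("population size must be at least 2")
  if (missing(seed)) stop("seed is a mandatory argument")
  set.seed(seed)
  mu <- faceParams()
  draws <- data.frame(
    noseLength = rnorm(n, mu@noseLength, faceParamSDs["noseLength"]),
    noseWidth = rnorm(n, mu@noseWidth, faceParamSDs["noseWidth"]),
    bridgeHeight = rnorm(n, mu@bridgeHeight, faceParamSDs["bridgeHeight"]),
    tipProjection = rnorm(n, mu@tipProjection, faceParamSDs["tipProjection"]),
    nostrilRadius = rnorm(n, mu@nostrilRadius, faceParamSDs["nostrilRadius"]),
    faceBreadth = rnorm(n, mu@faceBreadth, faceParamSDs["faceBreadth"]))
  # keep draws physically valid
  draws$noseLength <- pmax(draws$noseLength, 30)
  draws$noseWidth <- pmax(draws$noseWidth, 20)
  draws$bridgeHeight <- pmax(draws$bridgeHeight, 2)
  draws$tipProjection <- pmax(draws$tipProjection, 6)
  draws$faceBreadth <- pmax(draws$faceBreadth, 110)
  draws$nostrilRadius <- pmin(pmax(draws$nostrilRadius, 3), draws$noseWidth * 0.4)
  outs <- lapply(seq_len(n), function(i) {
    p <- do.call(faceParams, as.list(draws[i, ]))
    generateFace(p, topology)
  })
  meshes <- lapply(outs, `[[`, "mesh")
  attr(meshes, "params") <- draws
  attr(meshes, "faces") <- outs
  meshes
}

#' Dilate a vertex region by a Euclidean margin
#' @param mesh the mesh carrying the region
#' @param mask a RegionMask
#' @param margin dilation distance in mm, >= 0
#' @return the dilated RegionMask
#' @export
dilateRegion <- function(mesh, mask, margin) {
  if (margin < 0) stop("margin must be >= 0")
  flags <- mask@flags
  if (margin == 0 || !any(flags) || all(flags)) return(mask)
  v <- mesh@vertices
  mv <- v[flags, , drop = FALSE]
  d2 <- outer(rowSums(v^2), rowSums(mv^2), "+") - 2 * v %*% t(mv)
  near <- sqrt(pmax(apply(d2, 1, min), 0)) <= margin
  new("RegionMask", flags = flags | near)
}

#' Nose region on the reference topology
#'
#' The crop region for \code{\link{cropNose}}, defined once on the shared
#' grid topology as the mean-parameter face's nose mask dilated by
#' \code{margin}; by shared topology it transfers to any fitted instance.
#'
#' @param topology the shared grid topology
#' @param margin dilation in mm (default 2, so the crop covers the border
#'   band to be blended)
#' @return a RegionMask on the reference topology
#' @export
referenceNoseMask <- function(topology = faceTopology(), margin = 2) {
  gf <- generateFace(faceParams(), topology)
  dilateRegion(gf$mesh, gf$noseMask, margin)
}

#' Simulate a rhinectomy defect
#'
#' Removes the nose mask dilated by \code{margin} mm and optionally
#' roughens the crater rim with Gaussian noise along the vertex normals (a
#' scar-tissue stand-in). The ground-truth face is returned alongside for
#' error scoring. Uses the current RNG state when \code{noiseSd > 0}.
#'
#' @param face a generated face mesh
#' @param noseMask its nose RegionMask
#' @param margin dilation in mm, >= 0
#' @param noiseSd rim noise SD in mm (0.1 mm emulates optical-scan noise)
#' @return list with \code{fm} (the defect scan), \code{groundTruth},
#'   \code{removed} (vertex indices) and \code{defectMask}
#' @export
simulateRhinectomy <- function(face, noseMask, margin = 3, noiseSd = 0.1) {
  if (margin < 0) stop("margin must be >= 0")
  flags <- noseMask@flags
  if (length(flags) != nVertices(face)) stop("mask does not match the face topology")
  flags <- dilateRegion(face, noseMask, margin)@flags
  fm <- eraseRegion(face, new("RegionMask", flags = flags))
  if (noiseSd > 0) {
    bl <- boundaryLoops(fm)
    if (length(bl$vertices) > 0) {
      nrm <- vertexNormals(fm)
      vv <- fm@vertices
      vv[bl$vertices, ] <- vv[bl$vertices, , drop = FALSE] +
        rnorm(length(bl$vertices), 0, noiseSd) * nrm[bl$vertices, , drop = FALSE]
      fm <- TriangleMesh(vv, fm@faces, fm@vertexLabels)
    }
  }
  list(fm = fm, groundTruth = face, removed = which(flags),
       defectMask = new("RegionMask", flags = flags))
}

#' CT-emulating voxelization route
#'
#' Voxelizes the face solid at the given (possibly anisotropic) spacing and
#' extracts the skin isosurface, emulating a surface model obtained from CT
#' instead of optical scanning. Spacing coarser than the nose features
#' (> 5 mm) is refused.
#'
#' @param face a face surface mesh
#' @param spacing length-3 voxel spacing in mm, e.g. \code{c(0.46, 0.46, 1)}
#' @param backing depth (mm) to which the face sheet is closed into a solid
#' @return the re-extracted skin surface (open TriangleMesh)
#' @export
voxelizeCtRoute <- function(face, spacing, backing = 20) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  if (any(spacing > 5)) stop("voxel spacing coarser than 5 mm cannot resolve the nose")
  grid <- gridFromMeshes(list(face), spacing, pad = backing / 2 + 3 * max(spacing))
  fl <- gridField(face, grid)
  s <- fl$field
  d <- abs(s)
  F <- pmax(s, -backing - s)
  F[fl$boundary] <- pmax(F[fl$boundary], d[fl$boundary], max(spacing) * 1e-3)
  solid <- extractIso(F, grid)
  if (nFaces(solid) == 0) stop("voxelization produced an empty surface")
  # keep the skin-facing isosurface: drop the backing sheet, the rim skirt
  # and any folds of the deep inward offset, none of which are within a
  # voxel diagonal of the source sheet
  q <- meshQuery(face)
  cl <- cpp_closest(q, solid@vertices)
  vOk <- !cl$boundary & cl$distance < 0.85 * sqrt(sum(spacing^2))
  keep <- vOk[solid@faces[, 1]] & vOk[solid@faces[, 2]] & vOk[solid@faces[, 3]]
  cleanMesh(TriangleMesh(solid@vertices, solid@faces[keep, , drop = FALSE]))
}
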